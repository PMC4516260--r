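test_that("simulate_tree is reproducible and structurally correct", {
  t1 <- simulate_tree(72, seed = 4)
  t2 <- simulate_tree(72, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 72L)
  expect_equal(t1$Nnode, 71L)  # binary rooted: n - 1 internal splits
  cherry <- simulate_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2L)
  expect_equal(cherry$Nnode, 1L)
  expect_error(simulate_tree(1), ">= 2")
})

test_that("identical config and seed give byte-identical alignments", {
  cfg <- coevol_config(n_species = 30, length_a = 10, length_b = 10,
                       site_rate = 0.5, seed = 99,
                       planted_pairs = data.frame(col_a = 2, col_b = 3, rho = 0.7),
                       error_rate = 0.02, gap_rate = 0.01)
  s1 <- evolve_pair_msas(cfg)
  s2 <- evolve_pair_msas(cfg)
  expect_identical(unclass(s1$paired$a), unclass(s2$paired$a))
  expect_identical(unclass(s1$paired$b), unclass(s2$paired$b))
  expect_identical(s1$truth, s2$truth)
})

test_that("config validation rejects inconsistent setups", {
  expect_error(coevol_config(length_a = 5,
                             planted_pairs = data.frame(col_a = 9, col_b = 1, rho = 1)),
               "exceed")
  expect_error(coevol_config(
    planted_pairs = data.frame(col_a = 2, col_b = 3, rho = 1),
    clade_artifacts = data.frame(col_a = 2, col_b = 5, clade = "x"),
    clades = list(x = "sp001")), "disjoint")
  expect_error(coevol_config(
    clade_artifacts = data.frame(col_a = 2, col_b = 5, clade = "x")),
    "clades")
  expect_error(coevol_config(planted_pairs = data.frame(col_a = 1, col_b = 1, rho = 2)))
  # artifact clade absent from the tree errors at simulation time
  cfg <- coevol_config(n_species = 10, length_a = 4, length_b = 4, seed = 1,
                       clade_artifacts = data.frame(col_a = 2, col_b = 2, clade = "x"),
                       clades = list(x = c("nope1", "nope2")))
  expect_error(evolve_pair_msas(cfg), "absent")
})

test_that("zero site rate leaves all columns invariant downstream", {
  cfg <- coevol_config(n_species = 12, length_a = 6, length_b = 6,
                       site_rate = 0, seed = 2)
  sim <- evolve_pair_msas(cfg)
  expect_true(all(invariant_columns(sim$paired$a)))
  expect_error(mi_matrix(sim$paired), "non-invariant")
})

test_that("downsampling is a seeded uniform subset preserving order", {
  cfg <- coevol_config(n_species = 40, length_a = 8, length_b = 8,
                       site_rate = 0.5, seed = 6)
  p <- evolve_pair_msas(cfg)$paired
  expect_identical(downsample_species(p, 40, seed = 1), p)
  d1 <- downsample_species(p, 15, seed = 3)
  d2 <- downsample_species(p, 15, seed = 3)
  expect_identical(d1$species, d2$species)
  expect_equal(length(d1$species), 15L)
  expect_identical(d1$species, intersect(p$species, d1$species))
  expect_error(downsample_species(p, 41), "exceeds")
})

test_that("planted-pair Z signal is monotone in the coupling strength rho", {
  rhos <- c(0.2, 0.5, 0.9)
  med_z <- vapply(rhos, function(rho) {
    zs <- vapply(1:50, function(seed) {
      cfg <- coevol_config(n_species = 40, length_a = 8, length_b = 8,
                           site_rate = 0.6, seed = 7000 + seed,
                           planted_pairs = data.frame(col_a = 3, col_b = 4, rho = rho))
      p <- evolve_pair_msas(cfg)$paired
      z <- z_matrix(mi_matrix(p))
      ia <- match(3, z$cols_a); ib <- match(4, z$cols_b)
      if (is.na(ia) || is.na(ib)) NA_real_ else z$values[ia, ib]
    }, numeric(1))
    stats::median(zs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_z) >= 0))
  # paired one-sided comparison between extreme rho levels
  expect_gt(med_z[3], med_z[1])
})

test_that("rho = 0 planted labels carry no signal", {
  zs <- sapply(1:50, function(seed) {
    cfg <- coevol_config(n_species = 30, length_a = 6, length_b = 6,
                         site_rate = 0.6, seed = 8000 + seed,
                         planted_pairs = data.frame(col_a = 2, col_b = 2, rho = 0))
    p <- evolve_pair_msas(cfg)$paired
    z <- z_matrix(mi_matrix(p))
    ia <- match(2, z$cols_a); ib <- match(2, z$cols_b)
    c(planted = if (is.na(ia) || is.na(ib)) NA_real_ else z$values[ia, ib],
      q975 = unname(stats::quantile(z$values, 0.975, na.rm = TRUE)),
      q025 = unname(stats::quantile(z$values, 0.025, na.rm = TRUE)))
  })
  med <- stats::median(zs["planted", ], na.rm = TRUE)
  expect_lt(med, stats::median(zs["q975", ], na.rm = TRUE))
  expect_gt(med, stats::median(zs["q025", ], na.rm = TRUE))
})

test_that("pseudocount damps error-driven false positives on null data", {
  # with misreads injected, the count of extreme Z values should not be
  # larger under lambda = 1.5 than under lambda = 0 (directional property)
  extreme <- function(lambda) {
    sum(vapply(1:50, function(seed) {
      cfg <- coevol_config(n_species = 35, length_a = 7, length_b = 7,
                           site_rate = 0.4, error_rate = 0.02,
                           seed = 8500 + seed)
      p <- evolve_pair_msas(cfg)$paired
      z <- z_matrix(mi_matrix(p, lambda = lambda))
      sum(z$values > 4, na.rm = TRUE)
    }, numeric(1)))
  }
  expect_lte(extreme(1.5), extreme(0))
})

test_that("simulation output files round-trip through the readers", {
  cfg <- coevol_config(n_species = 15, length_a = 6, length_b = 5,
                       site_rate = 0.5, seed = 12,
                       planted_pairs = data.frame(col_a = 2, col_b = 4, rho = 1))
  sim <- evolve_pair_msas(cfg)
  prefix <- tempfile()
  paths <- write_simulation(sim, prefix)
  a <- read_alignment(paths[1], "fasta")
  b <- read_alignment(paths[2], "fasta")
  expect_identical(unclass(a), unclass(sim$paired$a))
  expect_identical(unclass(b), unclass(sim$paired$b))
  truth <- read.delim(paths[3])
  expect_equal(truth$col_a, sim$truth$col_a)
  expect_equal(truth$kind, sim$truth$kind)
})
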