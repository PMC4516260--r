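test_that("pseudocount site frequencies match the defining formula", {
  # s = 2, column "AA", lambda = 1.5: f'(A) = (2/33.5)(0.75 + 1),
  # every other symbol (2/33.5) * 0.75
  model <- pseudocount_model(s = 2, lambda = 1.5)
  sf <- site_frequencies(c("A", "A"), model)
  expect_equal(sf$f_prime[["A"]], (2 / 33.5) * (0.75 + 1), tolerance = 1e-12)
  expect_equal(unname(sf$f_prime[["C"]]), (2 / 33.5) * 0.75, tolerance = 1e-12)
  expect_equal(sum(sf$f_prime), 1, tolerance = 1e-12)
  # lambda = 0 leaves raw frequencies untouched
  m0 <- pseudocount_model(s = 4, lambda = 0)
  sf0 <- site_frequencies(c("A", "A", "T", "T"), m0)
  expect_identical(sf0$f_prime, sf0$f_raw)
  expect_error(site_frequencies(c("A", "X"), model), "alphabet")
  expect_error(pseudocount_model(s = 1), "2 species")
  expect_error(pseudocount_model(s = 5, lambda = -1), "lambda")
})

test_that("single and joint corrected frequencies normalize to 1e-12", {
  for (seed in 1:10) {
    set.seed(seed)
    s <- sample(2:40, 1)
    lam <- sample(c(0.5, 1, 1.5, 3), 1)
    model <- pseudocount_model(s, lam)
    ci <- sample(ALPHA21, s, replace = TRUE)
    cj <- sample(ALPHA21, s, replace = TRUE)
    expect_equal(sum(site_frequencies(ci, model)$f_prime), 1, tolerance = 1e-12)
    jf <- joint_frequencies(ci, cj, model)
    expect_equal(sum(jf$f_raw), 1, tolerance = 1e-12)
    expect_equal(sum(jf$f_prime), 1, tolerance = 1e-12)
    expect_true(all(jf$f_prime >= 0))
  }
})

test_that("joint frequencies match a hand computation on a 4-species fixture", {
  model <- pseudocount_model(s = 4, lambda = 1.5)
  jf <- joint_frequencies(c("A", "A", "T", "T"), c("C", "C", "G", "G"), model)
  want <- oracle_joint_freq(c("A", "A", "T", "T"), c("C", "C", "G", "G"), 1.5)
  expect_equal(unname(jf$f_raw), want$raw, tolerance = 1e-12)
  expect_equal(unname(jf$f_prime), want$prime, tolerance = 1e-12)
  # lambda = 0 joint equals raw
  m0 <- pseudocount_model(4, 0)
  jf0 <- joint_frequencies(c("A", "A", "T", "T"), c("C", "C", "G", "G"), m0)
  expect_identical(jf0$f_prime, jf0$f_raw)
})

test_that("mutual information has its closed-form limits at lambda = 0", {
  m0 <- pseudocount_model(4, 0)
  mi_perfect <- mutual_information(
    joint_frequencies(c("A", "A", "T", "T"), c("C", "C", "G", "G"), m0),
    site_frequencies(c("A", "A", "T", "T"), m0),
    site_frequencies(c("C", "C", "G", "G"), m0))
  expect_equal(mi_perfect, log(2), tolerance = 1e-12)
  mi_indep <- mutual_information(
    joint_frequencies(c("A", "A", "T", "T"), c("C", "G", "C", "G"), m0),
    site_frequencies(c("A", "A", "T", "T"), m0),
    site_frequencies(c("C", "G", "C", "G"), m0))
  expect_equal(mi_indep, 0, tolerance = 1e-12)
  # MI >= 0 at lambda = 0 for random columns
  for (seed in 1:5) {
    set.seed(seed)
    ci <- sample(c("A", "T", "G"), 12, replace = TRUE)
    cj <- sample(c("C", "D", "E"), 12, replace = TRUE)
    mm <- pseudocount_model(12, 0)
    expect_gte(mutual_information(joint_frequencies(ci, cj, mm),
                                  site_frequencies(ci, mm),
                                  site_frequencies(cj, mm)), -1e-12)
  }
})

test_that("MI and Z matrices equal the brute-force oracle on small alignments", {
  for (seed in 1:4) {
    a <- random_alignment(6, 6, seed = 100 + seed, gap_prob = 0.1)
    got <- mi_matrix(a, lambda = 1.5)
    want <- oracle_mi_matrix_intra(unclass(a), 1.5)
    expect_equal(got$cols_a, want$cols)
    expect_equal(got$values, want$M, tolerance = 1e-10)
    z <- z_matrix(got)
    expect_equal(z$values, oracle_z_intra(want$M), tolerance = 1e-10)
  }
  # inter mode against the oracle
  for (seed in 1:4) {
    a <- random_alignment(6, 5, seed = 200 + seed)
    b <- random_alignment(6, 6, seed = 300 + seed)
    rownames(b) <- rownames(a); b <- alignment(unclass(b))
    p <- pair_by_species(a, b)
    got <- mi_matrix(p, lambda = 1.5)
    want <- oracle_mi_matrix_inter(unclass(a), unclass(b), 1.5)
    expect_equal(got$values, want$M, tolerance = 1e-10)
    z <- z_matrix(got)
    expect_equal(z$values, oracle_z_inter(want$M), tolerance = 1e-10)
  }
})

test_that("MI and Z are symmetric in intra mode", {
  a <- random_alignment(10, 8, seed = 77)
  mi <- mi_matrix(a)
  z <- z_matrix(mi)
  expect_equal(mi$values, t(mi$values))
  expect_equal(z$values, t(z$values))
})

test_that("alignments with no variable columns are rejected", {
  a <- alignment(c(sp1 = "MKTA", sp2 = "MKTA", sp3 = "MKTA"))
  expect_error(mi_matrix(a), "non-invariant")
})

test_that("sigma guard yields Z = 0 when all MI values are equal", {
  mi <- coevoscan:::new_scorematrix("MI", matrix(0.3, 4, 5), "inter", 1:4, 1:5)
  z <- z_matrix(mi)
  expect_true(all(z$values == 0))
})

test_that("Z matrix on a small rectangle matches hand-computed values", {
  set.seed(4)
  M <- matrix(runif(12), 3, 4)
  mi <- coevoscan:::new_scorematrix("MI", M, "inter", 1:3, 1:4)
  z <- z_matrix(mi)
  expect_equal(z$values, oracle_z_inter(M), tolerance = 1e-12)
})

test_that("rank_pairs sorts descending with deterministic tie-break", {
  M <- matrix(c(0.5, 0.9, 0.9, 0.1), 2, 2)  # ties at 0.9
  sc <- coevoscan:::new_scorematrix("Z", M, "inter", c(3L, 8L), c(2L, 6L))
  r <- rank_pairs(sc, 4)
  expect_equal(r$score, c(0.9, 0.9, 0.5, 0.1))
  # tie broken lexicographically on (col_a, col_b): (3,6) before (8,2)
  expect_equal(r$col_a[1:2], c(3L, 8L))
  expect_equal(r$col_b[1:2], c(6L, 2L))
  # k beyond the pair count warns and returns all
  expect_warning(rall <- rank_pairs(sc, 99), "exceeds")
  expect_equal(nrow(rall), 4L)
  # unique maximum is rank 1
  expect_equal(rank_pairs(sc, 1)$score, 0.9)
  # intra mode lists each unordered pair once
  a <- random_alignment(8, 5, seed = 31)
  z <- z_matrix(mi_matrix(a))
  ri <- rank_pairs(z, k = choose(length(z$cols_a), 2))
  expect_false(any(duplicated(paste(pmin(ri$col_a, ri$col_b),
                                    pmax(ri$col_a, ri$col_b)))))
  expect_true(all(ri$col_a < ri$col_b))
})

test_that("reference numbering propagates into ranked output", {
  a <- alignment(c(hum = "M-KTA", oth = "MAKTA", th3 = "MAKCA", th4 = "MAGTC"))
  b <- alignment(c(hum = "AC-DE", oth = "ACQDE", th3 = "AWQDE", th4 = "GWQDC"))
  p <- pair_by_species(a, b)
  z <- z_matrix(mi_matrix(p, reference_a = "hum", reference_b = "hum"))
  r <- rank_pairs(z, 3)
  # column 2 of a is gapped in hum -> NA; others shift by the gap
  ref_for <- function(cols, aln) map_columns(column_to_reference(aln, "hum"), cols)
  expect_equal(r$ref_a, ref_for(r$col_a, p$a))
  expect_equal(r$ref_b, ref_for(r$col_b, p$b))
})

test_that("ranked TSV round-trips with MI annotation", {
  a <- random_alignment(8, 6, seed = 55)
  mi <- mi_matrix(a)
  z <- z_matrix(mi)
  r <- rank_pairs(z, 5)
  path <- tempfile(fileext = ".tsv")
  write_ranked_tsv(r, path, mi = mi)
  back <- read.delim(path)
  expect_equal(nrow(back), 5L)
  expect_true(all(c("rank", "col_a", "col_b", "score", "mi_nats") %in% names(back)))
  # annotated MI agrees with the matrix
  ia <- match(back$col_a[1], mi$cols_a); ib <- match(back$col_b[1], mi$cols_b)
  expect_equal(back$mi_nats[1], mi$values[ia, ib], tolerance = 1e-6)
})
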