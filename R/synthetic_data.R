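# Simulator of coevolving alignment pairs with known ground truth: neutral
# sites drift independently down a shared species tree, planted pairs
# co-substitute with tunable probability, clade artifacts place a single
# joint substitution on one lineage, and a final error layer misreads
# symbols uniformly.  Every pipeline stage can thus be scored against truth.

#' Simulate a random species tree
#'
#' Coalescent topology with branch lengths, reproducible under a seed.
#'
#' @param n_species Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return An \code{ape} \code{phylo} with leaves \code{sp001, sp002, ...}.
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  if (n_species < 2L) stop("n_species must be >= 2")
  set.seed(seed)
  tr <- ape::rcoal(n_species)
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Cut a tree into monophyletic-ish clade groups
#'
#' Utility for clade annotations on simulated (ultrametric) trees: cuts the
#' tree at a height giving \code{k} groups.
#'
#' @param tree Ultrametric \code{phylo}.
#' @param k Number of groups.
#' @return Named list: \code{clades} (list label -> species vector) and
#'   \code{annotation} (data frame \code{species}, \code{clade}).
#' @export
tree_clades <- function(tree, k) {
  grp <- stats::cutree(ape::as.hclust.phylo(tree), k = k)
  labels <- paste0("clade", grp)
  ann <- data.frame(species = names(grp), clade = labels,
                    stringsAsFactors = FALSE)
  clades <- split(ann$species, ann$clade)
  list(clades = clades, annotation = ann)
}

#' Configuration for the coevolution simulator
#'
#' @param n_species Number of species (ignored when \code{tree} is given).
#' @param tree Optional \code{phylo} with branch lengths; otherwise a
#'   coalescent tree is simulated from the seed.
#' @param length_a,length_b Columns per protein block.
#' @param site_rate Expected substitutions per site per unit branch length.
#' @param planted_pairs Data frame with columns \code{col_a}, \code{col_b},
#'   \code{rho}: compensatory pairs (column of A, column of B) whose
#'   co-substitution probability is \code{rho} in \code{[0, 1]}.
#' @param clade_artifacts Data frame with columns \code{col_a}, \code{col_b},
#'   \code{clade}: pairs receiving a single joint substitution on the stem
#'   of the named clade (a pure phylogenetic artifact).
#' @param clades Named list mapping clade label -> species vector; required
#'   when \code{clade_artifacts} is non-empty.
#' @param error_rate Per-symbol probability of a uniform misread.
#' @param gap_rate Per-symbol probability of replacement by a gap
#'   (off by default).
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A validated \code{coev_simconfig} list.
#' @export
coevol_config <- function(n_species = 72L, tree = NULL,
                          length_a = 40L, length_b = 40L,
                          site_rate = 0.3,
                          planted_pairs = NULL, clade_artifacts = NULL,
                          clades = NULL,
                          error_rate = 0, gap_rate = 0, seed = 1L) {
  planted_pairs <- planted_pairs %||%
    data.frame(col_a = integer(), col_b = integer(), rho = numeric())
  clade_artifacts <- clade_artifacts %||%
    data.frame(col_a = integer(), col_b = integer(), clade = character())
  if (!is.null(tree)) n_species <- length(tree$tip.label)
  stopifnot(n_species >= 2L, length_a >= 1L, length_b >= 1L, site_rate >= 0,
            error_rate >= 0, error_rate <= 1, gap_rate >= 0, gap_rate <= 1,
            all(planted_pairs$rho >= 0), all(planted_pairs$rho <= 1))
  if (any(planted_pairs$col_a > length_a) || any(planted_pairs$col_b > length_b) ||
      any(clade_artifacts$col_a > length_a) || any(clade_artifacts$col_b > length_b)) {
    stop("planted/artifact columns exceed block lengths")
  }
  if (length(intersect(planted_pairs$col_a, clade_artifacts$col_a)) ||
      length(intersect(planted_pairs$col_b, clade_artifacts$col_b))) {
    stop("planted and artifact columns must be disjoint")
  }
  if (anyDuplicated(c(planted_pairs$col_a, clade_artifacts$col_a)) ||
      anyDuplicated(c(planted_pairs$col_b, clade_artifacts$col_b))) {
    stop("special columns must be distinct")
  }
  if (nrow(clade_artifacts) > 0L && is.null(clades)) {
    stop("clade_artifacts require a 'clades' list")
  }
  structure(list(n_species = as.integer(n_species), tree = tree,
                 length_a = as.integer(length_a), length_b = as.integer(length_b),
                 site_rate = site_rate, planted_pairs = planted_pairs,
                 clade_artifacts = clade_artifacts, clades = clades,
                 error_rate = error_rate, gap_rate = gap_rate,
                 seed = as.integer(seed)),
            class = "coev_simconfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- coev_alphabet()[1:20]

# Evolve a set of independent neutral columns down the tree.
# Returns character matrix leaves x n_col (rownames = tip labels).
evolve_neutral <- function(tree, n_col, rate) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_character_, n_node, n_col)
  root <- n_tip + 1L
  states[root, ] <- sample(AA20, n_col, replace = TRUE)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; chd <- edges[e, 2L]
    p <- 1 - exp(-rate * elen[e])
    tog <- stats::runif(n_col) < p
    st <- states[par, ]
    if (any(tog)) {
      st[tog] <- vapply(st[tog], function(cur)
        sample(setdiff(AA20, cur), 1L), character(1L))
    }
    states[chd, ] <- st
  }
  out <- states[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# Evolve one planted compensatory pair: both columns are two-state
# (a1/a2, b1/b2).  On each branch column A toggles with the neutral
# substitution probability; with probability rho column B mirrors A's event
# on that branch, otherwise it toggles independently at the same rate, so
# rho = 0 is fully independent and rho = 1 perfectly compensatory.
evolve_planted_pair <- function(tree, rate, rho) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sa <- sample(AA20, 2L); sb <- sample(AA20, 2L)
  state <- matrix(NA_integer_, n_node, 2L)   # 1 or 2 per column
  state[n_tip + 1L, ] <- c(1L, 1L)
  tro <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tro$edge))) {
    par <- tro$edge[e, 1L]; chd <- tro$edge[e, 2L]
    p <- 1 - exp(-rate * tro$edge.length[e])
    a_tog <- stats::runif(1L) < p
    b_tog <- if (stats::runif(1L) < rho) a_tog else stats::runif(1L) < p
    st <- state[par, ]
    if (a_tog) st[1L] <- 3L - st[1L]
    if (b_tog) st[2L] <- 3L - st[2L]
    state[chd, ] <- st
  }
  list(col_a = sa[state[seq_len(n_tip), 1L]],
       col_b = sb[state[seq_len(n_tip), 2L]])
}

#' Simulate a coevolving pair of alignments
#'
#' Neutral columns substitute independently down the tree (uniform over the
#' 19 alternative amino acids, probability \code{1 - exp(-rate * branch)}
#' per branch).  Planted pairs follow a two-state compensatory cycle whose
#' co-substitution probability is \code{rho}.  Clade artifacts hold a single
#' joint substitution carried by exactly one clade.  Finally gaps and
#' uniform misreads are injected at the configured rates.
#'
#' @param config A \code{coev_simconfig}.
#' @return List: \code{paired} (a \code{coev_paired}), \code{truth} (data
#'   frame \code{col_a}, \code{col_b}, \code{rho}, \code{kind}),
#'   \code{tree}, \code{annotation} (species -> clade, or \code{NULL}).
#' @export
evolve_pair_msas <- function(config) {
  stopifnot(inherits(config, "coev_simconfig"))
  set.seed(config$seed)
  tree <- config$tree %||% ape::rcoal(config$n_species)
  if (is.null(config$tree)) tree$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  sp <- tree$tip.label
  n <- length(sp)
  A <- matrix(NA_character_, n, config$length_a, dimnames = list(sp, NULL))
  B <- matrix(NA_character_, n, config$length_b, dimnames = list(sp, NULL))
  special_a <- c(config$planted_pairs$col_a, config$clade_artifacts$col_a)
  special_b <- c(config$planted_pairs$col_b, config$clade_artifacts$col_b)
  neutral_a <- setdiff(seq_len(config$length_a), special_a)
  neutral_b <- setdiff(seq_len(config$length_b), special_b)
  if (length(neutral_a))
    A[, neutral_a] <- evolve_neutral(tree, length(neutral_a), config$site_rate)
  if (length(neutral_b))
    B[, neutral_b] <- evolve_neutral(tree, length(neutral_b), config$site_rate)
  pp <- config$planted_pairs
  for (r in seq_len(nrow(pp))) {
    ev <- evolve_planted_pair(tree, config$site_rate, pp$rho[r])
    A[, pp$col_a[r]] <- ev$col_a
    B[, pp$col_b[r]] <- ev$col_b
  }
  ca <- config$clade_artifacts
  for (r in seq_len(nrow(ca))) {
    members <- config$clades[[ca$clade[r]]]
    if (is.null(members)) stop("clade '", ca$clade[r], "' not defined")
    if (!all(members %in% sp)) stop("clade '", ca$clade[r], "' has species absent from the tree")
    if (length(members) == 0L || length(members) >= n) {
      stop("artifact clade must be a proper non-empty subset of species")
    }
    base <- sample(AA20, 2L)
    mut <- c(sample(setdiff(AA20, base[1L]), 1L),
             sample(setdiff(AA20, base[2L]), 1L))
    A[, ca$col_a[r]] <- ifelse(sp %in% members, mut[1L], base[1L])
    B[, ca$col_b[r]] <- ifelse(sp %in% members, mut[2L], base[2L])
  }
  inject <- function(M) {
    if (config$gap_rate > 0) {
      g <- stats::runif(length(M)) < config$gap_rate
      M[g] <- "-"
    }
    if (config$error_rate > 0) {
      e <- which(stats::runif(length(M)) < config$error_rate)
      M[e] <- vapply(M[e], function(cur)
        sample(setdiff(AA20, cur), 1L), character(1L))
    }
    M
  }
  A <- inject(A); B <- inject(B)
  paired <- pair_by_species(alignment(A), alignment(B))
  truth <- rbind(
    if (nrow(pp)) data.frame(col_a = pp$col_a, col_b = pp$col_b, rho = pp$rho,
                             kind = "planted", stringsAsFactors = FALSE),
    if (nrow(ca)) data.frame(col_a = ca$col_a, col_b = ca$col_b, rho = NA_real_,
                             kind = "artifact", stringsAsFactors = FALSE)
  ) %||% data.frame(col_a = integer(), col_b = integer(), rho = numeric(),
                    kind = character())
  annotation <- if (!is.null(config$clades)) {
    data.frame(species = unlist(config$clades, use.names = FALSE),
               clade = rep(names(config$clades), lengths(config$clades)),
               stringsAsFactors = FALSE)
  }
  list(paired = paired, truth = truth, tree = tree, annotation = annotation)
}

#' Randomly downsample the species of a paired alignment
#'
#' Uniform subset without replacement, reproducible under the seed;
#' emulates repeating an analysis on a reduced species panel.
#'
#' @param paired A \code{coev_paired}.
#' @param n_keep Number of species to retain.
#' @param seed Integer seed.
#' @return A \code{coev_paired} with \code{n_keep} species (original order).
#' @export
downsample_species <- function(paired, n_keep, seed = 1L) {
  stopifnot(inherits(paired, "coev_paired"))
  n <- length(paired$species)
  if (n_keep > n) stop("n_keep exceeds the species count")
  if (n_keep == n) return(paired)
  set.seed(seed)
  keep <- sort(sample.int(n, n_keep))
  subset_species(paired, paired$species[keep], mode = "keep")
}

#' Write simulator output to disk
#'
#' Writes the two aligned FASTA blocks and the ground-truth TSV.
#'
#' @param sim Result of \code{\link{evolve_pair_msas}}.
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_simulation <- function(sim, prefix) {
  pa <- paste0(prefix, "_a.fasta"); pb <- paste0(prefix, "_b.fasta")
  pt <- paste0(prefix, "_truth.tsv")
  write_alignment(sim$paired$a, pa)
  write_alignment(sim$paired$b, pb)
  utils::write.table(sim$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pa, pb, pt))
}
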