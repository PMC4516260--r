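# Phylogenetic robustness diagnostics.  A high Z-value can reflect a single
# co-substitution on one lineage rather than repeated, independent
# compensatory change; these checks probe how a ranked pair behaves when
# over-represented relatives are removed, whether its minority state arose
# in at least two non-sister clades, and how its Z compares with a
# species-permutation null.

z_rank_of_pair <- function(zsc, col_a, col_b) {
  ia <- match(col_a, zsc$cols_a)
  ib <- match(col_b, zsc$cols_b)
  if (is.na(ia) || is.na(ib)) return(list(z = NA_real_, rank = NA_integer_))
  ranked <- rank_pairs(zsc, k = length(zsc$values[!is.na(zsc$values)]))
  hit <- which(ranked$col_a == col_a & ranked$col_b == col_b)
  if (zsc$mode == "intra" && length(hit) == 0L) {
    hit <- which(ranked$col_a == col_b & ranked$col_b == col_a)
  }
  list(z = zsc$values[ia, ib], rank = ranked$rank[hit[1L]])
}

#' Leave-species-out rank trajectory for a tracked pair
#'
#' Removes species one by one (cumulatively by default) and recomputes the
#' full inter-protein MI/Z analysis at every step, recording the tracked
#' pair's Z-value and rank.  A pair whose rank survives removal of the
#' species carrying its minority state is unlikely to owe its rank to
#' over-representation of close relatives.
#'
#' @param p A \code{coev_paired}.
#' @param pair Length-2 integer vector: alignment column in block A,
#'   alignment column in block B.
#' @param removal_sequence Character vector of species, removed in order.
#' @param lambda Pseudocount weight.
#' @param cumulative If \code{TRUE} (default) each step removes all species
#'   up to that point; if \code{FALSE} each species is removed alone.
#' @return Data frame: \code{step}, \code{removed} (comma-joined set),
#'   \code{n_species}, \code{z_value}, \code{rank} (\code{NA} when a pair
#'   column has become invariant).
#' @export
leave_species_out <- function(p, pair, removal_sequence = character(),
                              lambda = 1.5, cumulative = TRUE) {
  stopifnot(inherits(p, "coev_paired"), length(pair) == 2L)
  unknown <- setdiff(removal_sequence, p$species)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  steps <- c(list(character()),
             lapply(seq_along(removal_sequence), function(i)
               if (cumulative) removal_sequence[seq_len(i)] else removal_sequence[i]))
  rows <- lapply(seq_along(steps), function(si) {
    rem <- steps[[si]]
    sub <- if (length(rem)) subset_species(p, rem, mode = "drop") else p
    res <- tryCatch({
      z <- z_matrix(mi_matrix(sub, lambda = lambda))
      z_rank_of_pair(z, pair[1L], pair[2L])
    }, error = function(e) list(z = NA_real_, rank = NA_integer_))
    data.frame(step = si - 1L,
               removed = paste(rem, collapse = ","),
               n_species = length(sub$species),
               z_value = res$z, rank = res$rank,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Merge sister clades into groups using the declared adjacency; returns the
# number of mutually non-sister groups represented by `clades`.
count_non_sister <- function(clades, sisters = NULL) {
  clades <- unique(clades)
  if (length(clades) <= 1L || is.null(sisters) || nrow(sisters) == 0L) {
    return(length(clades))
  }
  group <- stats::setNames(seq_along(clades), clades)
  for (r in seq_len(nrow(sisters))) {
    a <- sisters[[1L]][r]; b <- sisters[[2L]][r]
    if (a %in% clades && b %in% clades) {
      ga <- group[[a]]; gb <- group[[b]]
      group[group == gb] <- ga
    }
  }
  length(unique(group))
}

#' Non-sister clade support for a tracked pair
#'
#' Identifies the minority joint symbol state at the tracked column pair
#' and counts the distinct, non-sister clades containing at least one
#' species carrying it.  A pattern carried by a single clade is compatible
#' with one ancestral co-substitution (a phylogenetic artifact); support
#' from two or more independent clades requires the pair to have arisen
#' repeatedly.
#'
#' @param p A \code{coev_paired}.
#' @param pair Length-2 integer vector (column in A, column in B).
#' @param annotation Data frame \code{species}, \code{clade} covering every
#'   species of \code{p}.
#' @param sisters Optional two-column data frame of clade label pairs
#'   declared sister; sister clades count once.  Absent a declaration all
#'   distinct labels count as non-sister.
#' @param reference_species Optional species used to break ties between
#'   equally rare joint states (the state absent from the reference wins).
#' @return List: \code{n_clades}, \code{clades} (labels), \code{passes}
#'   (\code{n_clades >= 2}), \code{minority_state}, \code{species}.
#' @export
clade_support <- function(p, pair, annotation, sisters = NULL,
                          reference_species = NULL) {
  stopifnot(inherits(p, "coev_paired"), length(pair) == 2L)
  miss <- setdiff(p$species, annotation$species)
  if (length(miss)) stop("species missing from annotation: ",
                         paste(miss, collapse = ", "))
  sa <- unclass(p$a)[, pair[1L]]
  sb <- unclass(p$b)[, pair[2L]]
  joint <- paste0(sa, sb)
  tab <- sort(table(joint))
  if (length(tab) < 2L) stop("tracked pair columns are jointly invariant")
  minority <- names(tab)[tab == tab[1L]]
  if (length(minority) > 1L && !is.null(reference_species)) {
    ref_state <- joint[match(reference_species, p$species)]
    pref <- setdiff(minority, ref_state)
    if (length(pref)) minority <- pref
  }
  minority <- sort(minority)[1L]
  carriers <- p$species[joint == minority]
  clades <- unique(annotation$clade[match(carriers, annotation$species)])
  n <- count_non_sister(clades, sisters)
  list(n_clades = n, clades = clades, passes = n >= 2L,
       minority_state = minority, species = carriers)
}

#' Permutation null for a tracked pair's Z-value
#'
#' Breaks the species correspondence between the two proteins by permuting
#' whole rows of block B (preserving each protein's internal phylogenetic
#' structure) and recomputes the tracked pair's Z-value under each
#' permutation.  The p-value uses the add-one estimator
#' \code{(1 + #\{null >= observed\}) / (n_perm + 1)}.
#'
#' @param p A \code{coev_paired}.
#' @param pair Length-2 integer vector (column in A, column in B).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param lambda Pseudocount weight.
#' @return List: \code{observed} (Z), \code{null} (numeric vector of length
#'   \code{n_perm}), \code{p_value}.
#' @export
permutation_null <- function(p, pair, n_perm = 200L, seed = 1L, lambda = 1.5) {
  stopifnot(inherits(p, "coev_paired"), length(pair) == 2L)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  cols_a <- which(!invariant_columns(p$a))
  cols_b <- which(!invariant_columns(p$b))
  if (!(pair[1L] %in% cols_a) || !(pair[2L] %in% cols_b)) {
    stop("tracked pair must be non-invariant in both blocks")
  }
  enc_a <- encode_alignment(p$a)[, cols_a, drop = FALSE]
  enc_b <- encode_alignment(p$b)[, cols_b, drop = FALSE]
  ia <- match(pair[1L], cols_a); ib <- match(pair[2L], cols_b)
  s <- nrow(enc_a)
  # Z of the tracked pair needs only MI of column a vs all B columns and of
  # column b vs all A columns; row permutations leave single columns (and
  # hence invariance and single-site frequencies) unchanged.
  z_of <- function(eb) {
    enc_row <- cbind(enc_a[, ia], eb)
    row_mi <- mi_pairs(enc_row, rbind(1L, 1L + seq_len(ncol(eb))), lambda)
    enc_col <- cbind(eb[, ib], enc_a)
    col_mi <- mi_pairs(enc_col, rbind(1L, 1L + seq_len(ncol(enc_a))), lambda)
    mij <- row_mi[ib]
    rm <- mean(row_mi); rs <- stats::sd(row_mi) * sqrt((length(row_mi) - 1) / length(row_mi))
    cm <- mean(col_mi); cs <- stats::sd(col_mi) * sqrt((length(col_mi) - 1) / length(col_mi))
    0.5 * ((if (rs > 1e-9) (mij - rm) / rs else 0) +
           (if (cs > 1e-9) (mij - cm) / cs else 0))
  }
  observed <- z_of(enc_b)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    z_of(enc_b[sample.int(s), , drop = FALSE])
  }, numeric(1L))
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1))
}

#' Detect conserved sequence regions
#'
#' Scans the reference-mapped columns for maximal runs where the modal
#' symbol's frequency is at least \code{min_identity}, reporting runs of at
#' least \code{min_length} consecutive reference residues.
#'
#' @param a A \code{coev_aln}.
#' @param reference_species Species providing the residue numbering.
#' @param min_identity Minimum modal-symbol frequency per column (default
#'   0.9).
#' @param min_length Minimum run length in residues (default 5).
#' @return Data frame \code{start}, \code{end} (reference residue numbers),
#'   \code{length}.
#' @export
conserved_regions <- function(a, reference_species, min_identity = 0.9,
                              min_length = 5L) {
  stopifnot(inherits(a, "coev_aln"))
  refmap <- column_to_reference(a, reference_species)
  cols <- as.integer(names(refmap$column_to_residue))
  res <- unname(refmap$column_to_residue)
  cons <- apply(unclass(a)[, cols, drop = FALSE], 2L, function(col)
    max(table(col)) / length(col))
  ok <- cons >= min_identity
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_length
  data.frame(start = res[starts[keep]], end = res[ends[keep]],
             length = runs$lengths[keep], row.names = NULL)
}
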