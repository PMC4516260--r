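# Structure-based benchmarking of ranked pair lists.  A residue pair is a
# contact when its closest heavy-atom distance is at or under the cutoff in
# at least one source structure (union over conformers, e.g. oxy and deoxy
# forms of the same complex).

read_structure <- function(path) {
  if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
}

# Heavy-atom records only, highest-occupancy alternate conformer per atom,
# waters/heteroatoms excluded.
clean_atoms <- function(pdb) {
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$elesy %in% c("H", "D")) | is.na(at$elesy), , drop = FALSE]
  occ <- at$o
  occ[is.na(occ)] <- 1
  at <- at[order(at$chain, at$resno, at$elety, -occ), , drop = FALSE]
  at[!duplicated(at[, c("chain", "resno", "insert", "elety")]), , drop = FALSE]
}

# Minimum heavy-atom distance per residue pair between two atom tables.
# Returns data.frame(res_a, res_b, min_distance).
min_res_dist <- function(at_a, at_b, cutoff, exclude_self = FALSE) {
  if (nrow(at_a) == 0L || nrow(at_b) == 0L) {
    return(data.frame(res_a = integer(), res_b = integer(),
                      min_distance = numeric()))
  }
  xa <- as.matrix(at_a[, c("x", "y", "z")])
  xb <- as.matrix(at_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  ia <- split(seq_len(nrow(at_a)), at_a$resno)
  ib <- split(seq_len(nrow(at_b)), at_b$resno)
  res <- expand.grid(res_a = as.integer(names(ia)), res_b = as.integer(names(ib)),
                     KEEP.OUT.ATTRS = FALSE)
  if (exclude_self) res <- res[res$res_a < res$res_b, , drop = FALSE]
  md <- vapply(seq_len(nrow(res)), function(k) {
    sqrt(min(d2[ia[[as.character(res$res_a[k])]],
                ib[[as.character(res$res_b[k])]]]))
  }, numeric(1L))
  res$min_distance <- md
  res[res$min_distance <= cutoff, , drop = FALSE]
}

#' Residue-residue contact map from structures
#'
#' Extracts all residue pairs whose closest heavy-atom distance is at or
#' below the cutoff in any of the listed structures.  In intra mode each
#' chain in \code{chains_a} contributes its internal contacts (residue
#' pairs unordered, a < b); in inter mode every chain-A/chain-B combination
#' contributes.  Residue identity follows the author numbering of the
#' structure files; hydrogens, waters and heteroatoms are excluded, and
#' only the highest-occupancy alternate conformer of each atom is used.
#'
#' @param structures Character vector of PDB or mmCIF file paths.
#' @param chains_a Chain identifiers for protein A.
#' @param chains_b Chain identifiers for protein B (inter mode only).
#' @param cutoff Distance cutoff in Angstroms (default 7).
#' @param mode \code{"intra"} or \code{"inter"}.
#' @return A \code{coev_contacts}: list with \code{pairs} (data frame
#'   \code{res_a}, \code{res_b}, \code{min_distance}, \code{source}),
#'   \code{cutoff}, \code{mode}, \code{sources}.
#' @export
contact_map <- function(structures, chains_a, chains_b = NULL, cutoff = 7,
                        mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  if (mode == "inter" && is.null(chains_b)) stop("inter mode requires chains_b")
  all_pairs <- list()
  for (path in structures) {
    pdb <- read_structure(path)
    at <- clean_atoms(pdb)
    have <- unique(at$chain)
    need <- c(chains_a, if (mode == "inter") chains_b)
    missing <- setdiff(need, have)
    if (length(missing)) {
      stop("chain(s) ", paste(missing, collapse = ", "), " not found in ", path)
    }
    src <- basename(path)
    if (mode == "intra") {
      for (ch in chains_a) {
        sub <- at[at$chain == ch, , drop = FALSE]
        pr <- min_res_dist(sub, sub, cutoff, exclude_self = TRUE)
        if (nrow(pr)) { pr$source <- src; all_pairs[[length(all_pairs) + 1L]] <- pr }
      }
    } else {
      for (ca in chains_a) for (cb in chains_b) {
        pr <- min_res_dist(at[at$chain == ca, , drop = FALSE],
                           at[at$chain == cb, , drop = FALSE], cutoff)
        if (nrow(pr)) { pr$source <- src; all_pairs[[length(all_pairs) + 1L]] <- pr }
      }
    }
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else
    data.frame(res_a = integer(), res_b = integer(),
               min_distance = numeric(), source = character())
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$res_a, pairs$res_b, pairs$min_distance), ,
                   drop = FALSE]
    pairs <- pairs[!duplicated(pairs[, c("res_a", "res_b")]), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, cutoff = cutoff, mode = mode,
                 sources = basename(structures)),
            class = "coev_contacts")
}

#' @export
print.coev_contacts <- function(x, ...) {
  cat("<coev_contacts> ", nrow(x$pairs), " ", x$mode, " contacts at <= ",
      x$cutoff, " A (", paste(x$sources, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

in_contacts <- function(ref_a, ref_b, contacts) {
  cp <- contacts$pairs
  if (contacts$mode == "intra") {
    key <- paste(pmin(cp$res_a, cp$res_b), pmax(cp$res_a, cp$res_b))
    q <- paste(pmin(ref_a, ref_b), pmax(ref_a, ref_b))
  } else {
    key <- paste(cp$res_a, cp$res_b)
    q <- paste(ref_a, ref_b)
  }
  q %in% key
}

#' Precision at k of a ranked pair list against a contact map
#'
#' Fraction of the top-k ranked pairs (by reference residue numbering)
#' present in the contact set.  Pairs whose residues are unmapped
#' (\code{NA}) count as misses.
#'
#' @param ranked Data frame from \code{\link{rank_pairs}} with \code{ref_a},
#'   \code{ref_b}.
#' @param contacts A \code{coev_contacts}.
#' @param k Depth (> 0); capped at the list length.
#' @return Fraction in \code{[0, 1]}.
#' @export
precision_at_k <- function(ranked, contacts, k) {
  if (k <= 0) stop("k must be positive")
  k <- min(k, nrow(ranked))
  top <- ranked[seq_len(k), , drop = FALSE]
  hit <- !is.na(top$ref_a) & !is.na(top$ref_b) &
    in_contacts(top$ref_a, top$ref_b, contacts)
  mean(hit)
}

#' Histogram of contacts along a ranked list
#'
#' Counts how many of the ranked pairs falling in each rank bin are true
#' contacts; the bins cover the whole list, so the counts sum to the number
#' of contact pairs present anywhere in the ranking.
#'
#' @param ranked Data frame from \code{\link{rank_pairs}}.
#' @param contacts A \code{coev_contacts}.
#' @param bin_size Ranks per bin (e.g. 500).
#' @return Data frame \code{bin_start}, \code{bin_end}, \code{n_contacts}.
#' @export
contact_rank_histogram <- function(ranked, contacts, bin_size) {
  stopifnot(bin_size >= 1)
  n <- nrow(ranked)
  hit <- !is.na(ranked$ref_a) & !is.na(ranked$ref_b) &
    in_contacts(ranked$ref_a, ranked$ref_b, contacts)
  bins <- ceiling(ranked$rank / bin_size)
  counts <- tapply(hit, bins, sum)
  starts <- (as.integer(names(counts)) - 1L) * bin_size + 1L
  data.frame(bin_start = starts,
             bin_end = pmin(starts + bin_size - 1L, n),
             n_contacts = as.integer(counts), row.names = NULL)
}

#' Serialize a contact map as TSV
#'
#' @param contacts A \code{coev_contacts}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
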