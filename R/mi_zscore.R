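# Mutual information with pseudocount-corrected frequencies, and the
# Z-value normalization that ranks column pairs by how far their MI stands
# above each member column's background.

#' Pseudocount model for frequency estimation
#'
#' Small species counts make raw amino-acid frequencies noisy, and a single
#' sequencing error can fabricate a perfectly covarying rare state.  The
#' pseudocount lambda adds a uniform prior mass to every symbol before
#' normalization, damping both effects.
#'
#' @param s Number of species in the alignment (>= 2).
#' @param lambda Pseudocount weight, dimensionless, >= 0.  Default 1.5.
#' @return A \code{coev_pcmodel} list with \code{lambda}, \code{s},
#'   \code{n_symbols}.
#' @export
pseudocount_model <- function(s, lambda = 1.5) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (s < 2) stop("at least 2 species are required")
  structure(list(lambda = lambda, s = as.integer(s), n_symbols = N_SYMBOLS),
            class = "coev_pcmodel")
}

col_as_int <- function(column) {
  if (is.character(column)) {
    column <- toupper(column)
    column[column == "."] <- "-"
    ci <- match(column, coev_alphabet())
    if (anyNA(ci)) stop("symbol outside the 21-letter alphabet: ",
                        paste(unique(column[is.na(ci)]), collapse = ", "))
    ci
  } else {
    if (any(column < 1L | column > N_SYMBOLS)) stop("integer states must be in 1..21")
    as.integer(column)
  }
}

#' Single-site symbol frequencies with pseudocount correction
#'
#' Raw frequencies are counts over species, \code{f_i(m) = n_m / s}.  The
#' corrected frequencies are
#' \deqn{f'_i(m) = \frac{s}{s + 21\lambda}\left(\frac{\lambda}{s} + f_i(m)\right)}
#' which sums to 1 exactly and is strictly positive whenever lambda > 0.
#'
#' @param column Symbol vector (characters from the 21-letter alphabet, or
#'   integer states 1..21) of length \code{model$s}.
#' @param model A \code{coev_pcmodel}.
#' @return A \code{coev_sitefreq} list with \code{f_raw} and \code{f_prime},
#'   each a length-21 named numeric vector.
#' @export
site_frequencies <- function(column, model) {
  stopifnot(inherits(model, "coev_pcmodel"))
  ci <- col_as_int(column)
  if (length(ci) != model$s) stop("column length must equal model$s")
  s <- model$s; lam <- model$lambda
  f_raw <- tabulate(ci, nbins = N_SYMBOLS) / s
  f_prime <- (s / (s + N_SYMBOLS * lam)) * (lam / s + f_raw)
  names(f_raw) <- names(f_prime) <- coev_alphabet()
  structure(list(f_raw = f_raw, f_prime = f_prime), class = "coev_sitefreq")
}

#' Joint two-site symbol frequencies with pseudocount correction
#'
#' Raw joint frequencies count species carrying the symbol pair (m, n).
#' The corrected joint uses the already-corrected single-site frequencies in
#' its pseudocount term:
#' \deqn{f'_{ij}(m,n) = \frac{s}{s + 42\lambda}\left(\frac{\lambda}{s} f'_i(m)
#'   + \frac{\lambda}{s} f'_j(n) + f_{ij}(m,n)\right)}
#' This normalizes to 1 exactly.  Note the corrected joint is deliberately
#' not re-marginalized: \code{f_prime} rows do not sum to \code{f'_i}.
#'
#' @param col_i,col_j Symbol vectors of equal length \code{model$s}.
#' @param model A \code{coev_pcmodel}.
#' @return A \code{coev_jointfreq} list with 21 x 21 matrices \code{f_raw}
#'   and \code{f_prime}.
#' @export
joint_frequencies <- function(col_i, col_j, model) {
  stopifnot(inherits(model, "coev_pcmodel"))
  ci <- col_as_int(col_i); cj <- col_as_int(col_j)
  if (length(ci) != length(cj)) stop("columns differ in length")
  if (length(ci) != model$s) stop("column length must equal model$s")
  s <- model$s; lam <- model$lambda
  f_raw <- matrix(tabulate(ci + N_SYMBOLS * (cj - 1L), nbins = N_SYMBOLS^2) / s,
                  N_SYMBOLS, N_SYMBOLS,
                  dimnames = list(coev_alphabet(), coev_alphabet()))
  fpi <- site_frequencies(ci, model)$f_prime
  fpj <- site_frequencies(cj, model)$f_prime
  f_prime <- (s / (s + 2 * N_SYMBOLS * lam)) *
    ((lam / s) * outer(fpi, rep(1, N_SYMBOLS)) +
     (lam / s) * outer(rep(1, N_SYMBOLS), fpj) + f_raw)
  dimnames(f_prime) <- dimnames(f_raw)
  structure(list(f_raw = f_raw, f_prime = f_prime), class = "coev_jointfreq")
}

#' Mutual information between two alignment columns (nats)
#'
#' \deqn{MI_{ij} = \sum_{m,n} f'_{ij}(m,n)\,
#'   \ln\frac{f'_{ij}(m,n)}{f'_i(m) f'_j(n)}}
#' summed over all 21 x 21 symbol pairs including gaps; terms with
#' \code{f_prime == 0} (possible only at lambda = 0) contribute 0.
#'
#' @param joint A \code{coev_jointfreq}.
#' @param a,b The matching \code{coev_sitefreq} objects.
#' @return MI in nats.
#' @export
mutual_information <- function(joint, a, b) {
  fij <- joint$f_prime
  fi <- a$f_prime; fj <- b$f_prime
  pos <- fij > 0
  sum(fij[pos] * (log(fij[pos]) - (log(fi)[row(fij)[pos]] + log(fj)[col(fij)[pos]])))
}

# Internal vectorized MI over column pairs.
# enc: integer matrix s x L (states 1..21); pairs: 2 x npair matrix of
# column indices into enc.  Returns numeric vector of MI values.
mi_pairs <- function(enc, pairs, lambda) {
  s <- nrow(enc)
  c1 <- s / (s + N_SYMBOLS * lambda)
  c2 <- s / (s + 2 * N_SYMBOLS * lambda)
  lam_s <- lambda / s
  L <- ncol(enc)
  # corrected single-site frequencies per column, 21 x L
  fp <- vapply(seq_len(L), function(j)
    c1 * (lam_s + tabulate(enc[, j], nbins = N_SYMBOLS) / s),
    numeric(N_SYMBOLS))
  lfp <- log(fp)
  one <- rep(1, N_SYMBOLS)
  vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    raw <- matrix(tabulate(enc[, i] + N_SYMBOLS * (enc[, j] - 1L),
                           nbins = N_SYMBOLS^2) / s, N_SYMBOLS, N_SYMBOLS)
    fij <- c2 * (lam_s * outer(fp[, i], one) + lam_s * outer(one, fp[, j]) + raw)
    pos <- fij > 0
    lr <- log(fij[pos]) - outer(lfp[, i], lfp[, j], `+`)[pos]
    sum(fij[pos] * lr)
  }, numeric(1L))
}

new_scorematrix <- function(kind, values, mode, cols_a, cols_b,
                            ref_a = NULL, ref_b = NULL) {
  structure(list(kind = kind, values = values, mode = mode,
                 cols_a = cols_a, cols_b = cols_b,
                 ref_a = ref_a, ref_b = ref_b),
            class = "coev_scores")
}

#' @export
print.coev_scores <- function(x, ...) {
  cat("<coev_scores> kind=", x$kind, " mode=", x$mode, " ",
      nrow(x$values), " x ", ncol(x$values), " (non-invariant columns)\n",
      sep = "")
  invisible(x)
}

#' Mutual information matrix over non-invariant column pairs
#'
#' For a single alignment (intra mode) computes MI between all unordered
#' pairs of non-invariant columns; for a paired alignment (inter mode)
#' computes the rectangular MI matrix between non-invariant columns of
#' protein A and of protein B.  Invariant columns are excluded from the
#' axes entirely.
#'
#' @param x A \code{coev_aln} (intra) or \code{coev_paired} (inter).
#' @param lambda Pseudocount weight (default 1.5).
#' @param reference_a,reference_b Optional reference species for residue
#'   numbering of the reported axes (\code{reference_b} ignored in intra
#'   mode).
#' @return A \code{coev_scores} with \code{kind = "MI"}; \code{values} is
#'   square symmetric (intra, diagonal \code{NA}) or rectangular (inter),
#'   with axis columns stored in \code{cols_a}, \code{cols_b}.
#' @export
mi_matrix <- function(x, lambda = 1.5, reference_a = NULL, reference_b = NULL) {
  if (inherits(x, "coev_aln")) {
    inv <- invariant_columns(x)
    cols <- which(!inv)
    if (length(cols) < 2L) {
      stop("fewer than 2 non-invariant columns; nothing to correlate")
    }
    enc <- encode_alignment(x)[, cols, drop = FALSE]
    np <- length(cols)
    pairs <- utils::combn(np, 2L)
    mi <- mi_pairs(enc, pairs, lambda)
    M <- matrix(NA_real_, np, np)
    M[t(pairs)] <- mi
    M[t(pairs[2:1, , drop = FALSE])] <- mi
    ref <- if (!is.null(reference_a)) column_to_reference(x, reference_a)
    new_scorematrix("MI", M, "intra", cols, cols, ref, ref)
  } else if (inherits(x, "coev_paired")) {
    inv_a <- invariant_columns(x$a)
    inv_b <- invariant_columns(x$b)
    cols_a <- which(!inv_a); cols_b <- which(!inv_b)
    if (length(cols_a) < 2L || length(cols_b) < 2L) {
      stop("fewer than 2 non-invariant columns on an axis; nothing to correlate")
    }
    enc <- cbind(encode_alignment(x$a)[, cols_a, drop = FALSE],
                 encode_alignment(x$b)[, cols_b, drop = FALSE])
    na <- length(cols_a); nb <- length(cols_b)
    pairs <- rbind(rep(seq_len(na), times = nb),
                   rep(na + seq_len(nb), each = na))
    M <- matrix(mi_pairs(enc, pairs, lambda), na, nb)
    ref_a <- if (!is.null(reference_a)) column_to_reference(x$a, reference_a)
    ref_b <- if (!is.null(reference_b)) column_to_reference(x$b, reference_b)
    new_scorematrix("MI", M, "inter", cols_a, cols_b, ref_a, ref_b)
  } else {
    stop("x must be a coev_aln or coev_paired")
  }
}

#' Z-value normalization of an MI matrix
#'
#' For each pair the Z-value measures how many standard deviations its MI
#' exceeds the average MI of each member column against all its possible
#' partners:
#' \deqn{Z_{ij} = 0.5\left[\frac{MI_{ij} - \overline{MI_i}}{\sigma_i}
#'   + \frac{MI_{ij} - \overline{MI_j}}{\sigma_j}\right]}
#' In inter mode the averages run over all non-invariant partner columns of
#' the opposite protein; in intra mode over all other non-invariant columns
#' of the same protein (self-pair excluded).  Standard deviations are
#' population (divide by N).  A column whose MI values are all equal has
#' sigma = 0; its term is defined as 0, which keeps Z finite and symmetric.
#' Sigmas below 1e-9 nats are treated as zero (a degenerate row, not real
#' spread; MI values are of order 0.1-3 nats).
#'
#' @param mi A \code{coev_scores} with \code{kind = "MI"}.
#' @return A \code{coev_scores} with \code{kind = "Z"} on the same axes.
#' @export
z_matrix <- function(mi) {
  stopifnot(inherits(mi, "coev_scores"), mi$kind == "MI")
  M <- mi$values
  if (mi$mode == "inter") {
    if (nrow(M) < 2L || ncol(M) < 2L) stop("each axis needs at least 2 columns")
    rmean <- rowMeans(M)
    rsd <- sqrt(pmax(rowMeans(M^2) - rmean^2, 0))
    cmean <- colMeans(M)
    csd <- sqrt(pmax(colMeans(M^2) - cmean^2, 0))
    term_i <- (M - rmean) / ifelse(rsd > 1e-9, rsd, Inf)
    term_j <- sweep(M, 2L, cmean) / rep(ifelse(csd > 1e-9, csd, Inf), each = nrow(M))
    Z <- 0.5 * (term_i + term_j)
  } else {
    n <- nrow(M)
    if (n < 2L) stop("axis with a single column")
    offsum <- rowSums(M, na.rm = TRUE)
    m_i <- offsum / (n - 1L)
    sq <- rowSums(M^2, na.rm = TRUE)
    sd_i <- sqrt(pmax(sq / (n - 1L) - m_i^2, 0))
    term <- (M - m_i) / ifelse(sd_i > 1e-9, sd_i, Inf)
    Z <- 0.5 * (term + t(term))
    diag(Z) <- NA_real_
  }
  new_scorematrix("Z", Z, mi$mode, mi$cols_a, mi$cols_b, mi$ref_a, mi$ref_b)
}

#' Rank column pairs by score
#'
#' Sorts pairs by descending score; intra mode lists each unordered pair
#' once (a < b).  Ties break lexicographically on (column A, column B) so
#' rankings are deterministic.  Residues are reported in reference numbering
#' when the score matrix carries reference maps (\code{NA} where the
#' reference row is gapped).
#'
#' @param scores A \code{coev_scores}.
#' @param k Number of top pairs to return (>= 1).  If larger than the number
#'   of pairs, all pairs are returned with a warning.
#' @return Data frame with columns \code{rank}, \code{col_a}, \code{col_b}
#'   (alignment columns), \code{ref_a}, \code{ref_b} (reference residue
#'   numbers or \code{NA}), \code{score}.
#' @export
rank_pairs <- function(scores, k = 10L) {
  stopifnot(inherits(scores, "coev_scores"))
  if (k < 1L) stop("k must be >= 1")
  M <- scores$values
  if (scores$mode == "intra") {
    idx <- which(upper.tri(M), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(nrow(M)), col = seq_len(ncol(M))))
  }
  sc <- M[idx]
  keep <- !is.na(sc)
  idx <- idx[keep, , drop = FALSE]; sc <- sc[keep]
  ca <- scores$cols_a[idx[, 1L]]
  cb <- scores$cols_b[idx[, 2L]]
  ord <- order(-sc, ca, cb)
  if (k > length(sc)) {
    warning("k = ", k, " exceeds the ", length(sc), " available pairs; returning all")
    k <- length(sc)
  }
  top <- ord[seq_len(k)]
  data.frame(
    rank = seq_len(k),
    col_a = ca[top],
    col_b = cb[top],
    ref_a = if (!is.null(scores$ref_a)) map_columns(scores$ref_a, ca[top]) else NA_integer_,
    ref_b = if (!is.null(scores$ref_b)) map_columns(scores$ref_b, cb[top]) else NA_integer_,
    score = sc[top],
    row.names = NULL
  )
}

#' Write a ranked pair table as TSV
#'
#' @param ranked Data frame from \code{\link{rank_pairs}}.
#' @param mi Optional matching MI \code{coev_scores} to add an
#'   \code{mi_nats} column.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ranked_tsv <- function(ranked, path, mi = NULL) {
  out <- ranked
  if (!is.null(mi)) {
    stopifnot(inherits(mi, "coev_scores"), mi$kind == "MI")
    ia <- match(ranked$col_a, mi$cols_a)
    ib <- match(ranked$col_b, mi$cols_b)
    out$mi_nats <- mi$values[cbind(ia, ib)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
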