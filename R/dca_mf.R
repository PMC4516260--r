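# Mean-field direct coupling analysis.  Pairwise couplings are obtained by
# inverting the regularized covariance matrix of single- and two-site
# frequencies (naive mean-field / small-coupling expansion); each pair's
# direct information (DI) is the mutual information of a two-site model
# built from its coupling block alone, with single-site fields tuned so the
# model marginals match the regularized frequencies.  This removes
# transitive correlations that inflate plain MI.

Q_STATES <- 21L   # 20 amino acids + gap; the gap is the reference state
Q_RED <- 20L      # states kept after dropping the reference symbol

#' DCA parameters
#'
#' @param theta Sequence-identity threshold for reweighting redundant
#'   sequences, in \code{[0, 1]}.  A sequence's weight is the reciprocal of
#'   the number of alignment members within fractional identity
#'   \code{>= 1 - theta} of it.  \code{theta = 0} means no reweighting: all
#'   sequences count equally (the default here).
#' @param pseudocount_weight Fraction of uniform prior mixed into the
#'   weighted frequencies, in \code{[0, 1)}.  Default 0.5; must be > 0 for
#'   the covariance matrix to be invertible.
#' @return A \code{coev_dcaparams} list.
#' @export
dca_params <- function(theta = 0, pseudocount_weight = 0.5) {
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  if (pseudocount_weight < 0 || pseudocount_weight >= 1) {
    stop("pseudocount_weight must be in [0, 1)")
  }
  structure(list(theta = theta, pseudocount_weight = pseudocount_weight),
            class = "coev_dcaparams")
}

#' Sequence weights for redundancy correction
#'
#' Down-weights near-duplicate sequences: the weight of sequence k is
#' \code{1 / m_k} where \code{m_k} counts alignment members (including k
#' itself) whose fractional identity to k is at least \code{1 - theta},
#' identity measured over all alignment columns with the gap as an ordinary
#' symbol.  \code{theta = 0} switches reweighting off entirely, so every
#' weight is 1 and the effective sequence count equals the species count.
#'
#' @param x A \code{coev_aln} or \code{coev_paired} (concatenated).
#' @param theta Identity threshold in \code{[0, 1]}.
#' @return A \code{coev_seqweights} list with \code{weights} (named by
#'   species) and \code{m_eff} (sum of weights).
#' @export
sequence_weights <- function(x, theta = 0) {
  if (inherits(x, "coev_paired")) x <- concat_paired(x)
  stopifnot(inherits(x, "coev_aln"))
  s <- nrow(x)
  if (theta == 0) {
    w <- rep(1, s)
  } else {
    enc <- encode_alignment(x)
    L <- ncol(enc)
    # pairwise identity via one-hot cross-product: id(k,l) = matches / L
    A <- matrix(0, s, L * Q_STATES)
    A[cbind(rep(seq_len(s), L),
            (rep(seq_len(L), each = s) - 1L) * Q_STATES + as.vector(enc))] <- 1
    matches <- tcrossprod(A)
    w <- 1 / rowSums(matches / L >= 1 - theta)
  }
  names(w) <- rownames(x)
  structure(list(weights = w, m_eff = sum(w)), class = "coev_seqweights")
}

# One-hot encoding over the reduced 20-state alphabet: s x (L*20) matrix;
# a gap at a column contributes no indicator (reference state).
one_hot_reduced <- function(enc) {
  s <- nrow(enc); L <- ncol(enc)
  A <- matrix(0, s, L * Q_RED)
  st <- as.vector(enc)
  keep <- st <= Q_RED
  rows <- rep(seq_len(s), L)[keep]
  cols <- ((rep(seq_len(L), each = s) - 1L) * Q_RED + st)[keep]
  A[cbind(rows, cols)] <- 1
  A
}

#' Regularized weighted frequencies for DCA
#'
#' Weighted empirical single-site and pair frequencies mixed with the
#' uniform distribution: \code{(1 - pc) * f_weighted + pc / 21} for single
#' sites and \code{pc / 21^2} for pairs of distinct columns; same-column
#' "pair" blocks are diagonal and receive \code{pc / 21} on the diagonal,
#' keeping the regularized statistics consistent with a single site.
#'
#' @param x A \code{coev_aln} or \code{coev_paired}.
#' @param weights A \code{coev_seqweights} (or \code{NULL} for uniform).
#' @param pseudocount_weight Regularization fraction in \code{[0, 1)}.
#' @param columns Integer columns to include (default: all non-invariant).
#' @return A \code{coev_dcafreq} list: \code{fi} (21 x L regularized
#'   single-site frequencies), \code{pair_block} (the (L*20) x (L*20)
#'   regularized pair-frequency matrix over reduced states), \code{columns},
#'   \code{m_eff}.
#' @export
regularized_frequencies <- function(x, weights = NULL, pseudocount_weight = 0.5,
                                    columns = NULL) {
  aln <- if (inherits(x, "coev_paired")) concat_paired(x) else x
  stopifnot(inherits(aln, "coev_aln"))
  if (is.null(columns)) columns <- which(!invariant_columns(aln))
  enc <- encode_alignment(aln)[, columns, drop = FALSE]
  s <- nrow(enc); L <- ncol(enc)
  w <- if (is.null(weights)) rep(1, s) else weights$weights
  stopifnot(length(w) == s)
  m_eff <- sum(w)
  pc <- pseudocount_weight
  # single-site weighted frequencies over 21 states
  fi_w <- vapply(seq_len(L), function(j) {
    out <- numeric(Q_STATES)
    tab <- rowsum(w, enc[, j])
    out[as.integer(rownames(tab))] <- tab
    out / m_eff
  }, numeric(Q_STATES))
  fi <- (1 - pc) * fi_w + pc / Q_STATES
  # pair frequencies over reduced states via weighted cross-product
  A <- one_hot_reduced(enc)
  fij_w <- crossprod(A * w, A) / m_eff
  pair_block <- (1 - pc) * fij_w + pc / Q_STATES^2
  # same-column blocks: exactly diagonal, regularized toward (pc/21) * I
  for (i in seq_len(L)) {
    sel <- (i - 1L) * Q_RED + seq_len(Q_RED)
    blk <- matrix(0, Q_RED, Q_RED)
    diag(blk) <- (1 - pc) * diag(fij_w[sel, sel, drop = FALSE]) + pc / Q_STATES
    pair_block[sel, sel] <- blk
  }
  structure(list(fi = fi, pair_block = pair_block, columns = columns,
                 m_eff = m_eff, pseudocount_weight = pc),
            class = "coev_dcafreq")
}

#' Mean-field coupling matrix
#'
#' Builds the covariance matrix \code{C[(i,m),(j,n)] = f_ij(m,n) -
#' f_i(m) f_j(n)} over the 20 non-reference symbols of each column and
#' returns the naive mean-field couplings \code{e = -C^{-1}} (block
#' \code{(i, j)} holds \code{e_ij(m, n)}).
#'
#' @param freqs A \code{coev_dcafreq}.
#' @return A \code{coev_couplings} list: \code{e} (the (L*20) x (L*20)
#'   coupling matrix), \code{fi}, \code{columns}.
#' @export
coupling_matrix <- function(freqs) {
  stopifnot(inherits(freqs, "coev_dcafreq"))
  fi_red <- freqs$fi[seq_len(Q_RED), , drop = FALSE]
  marg <- as.vector(fi_red)
  C <- freqs$pair_block - tcrossprod(marg)
  e <- tryCatch(-solve(C),
                error = function(err) {
                  stop("covariance matrix is singular; use pseudocount_weight > 0 ",
                       "(underlying error: ", conditionMessage(err), ")")
                })
  structure(list(e = e, fi = freqs$fi, columns = freqs$columns),
            class = "coev_couplings")
}

# Two-site model for one column pair: W = exp(-e_ij) padded to 21 states
# (reference state couplings are zero), fields fitted by alternating
# marginal matching.
two_site_model <- function(W, fi, fj, tol = 1e-8, max_iter = 500L) {
  q <- Q_STATES
  mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
  for (it in seq_len(max_iter)) {
    scra1 <- as.vector(W %*% mu2)
    scra2 <- as.vector(crossprod(W, mu1))
    new1 <- fi / scra1; new1 <- new1 / sum(new1)
    new2 <- fj / scra2; new2 <- new2 / sum(new2)
    delta <- max(abs(new1 - mu1), abs(new2 - mu2))
    mu1 <- new1; mu2 <- new2
    if (delta < tol) {
      p <- W * outer(mu1, mu2)
      return(p / sum(p))
    }
  }
  stop("marginal matching did not converge within ", max_iter, " iterations")
}

#' Direct information for one column pair
#'
#' Builds the two-site distribution \code{P_ij(m,n)} from the pair's
#' coupling block with single-site fields tuned so its marginals match the
#' regularized frequencies, then scores
#' \deqn{DI_{ij} = \sum_{m,n} P_{ij}(m,n) \ln\frac{P_{ij}(m,n)}{f_i(m) f_j(n)}}
#' DI is non-negative up to numerical tolerance and is exactly 0 when the
#' coupling block is zero.
#'
#' @param e_block 20 x 20 coupling block for the pair.
#' @param fi,fj Regularized 21-state frequency vectors of the two columns.
#' @param tol,max_iter Marginal-matching controls.
#' @return DI value (nats).
#' @export
direct_information <- function(e_block, fi, fj, tol = 1e-8, max_iter = 500L) {
  W <- matrix(1, Q_STATES, Q_STATES)
  W[seq_len(Q_RED), seq_len(Q_RED)] <- exp(-e_block)
  p <- two_site_model(W, fi, fj, tol = tol, max_iter = max_iter)
  ref <- outer(fi, fj)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / ref[pos]))
}

#' Mean-field DCA pipeline
#'
#' Runs the full mean-field analysis: sequence reweighting, regularized
#' frequency estimation over non-invariant columns, covariance inversion,
#' and per-pair direct information.  For a paired alignment the couplings
#' are estimated on the concatenated alignment (so intra- and inter-protein
#' pairs compete in the same covariance model) and the inter-protein block
#' of the DI matrix is returned.
#'
#' @param x A \code{coev_aln} (intra mode) or \code{coev_paired} (inter
#'   mode).
#' @param params A \code{coev_dcaparams}.
#' @param reference_a,reference_b Optional reference species for residue
#'   numbering.
#' @return A \code{coev_scores} with \code{kind = "DI"}.
#' @export
dca_pipeline <- function(x, params = dca_params(),
                         reference_a = NULL, reference_b = NULL) {
  stopifnot(inherits(params, "coev_dcaparams"))
  w <- sequence_weights(x, params$theta)
  freqs <- regularized_frequencies(x, w, params$pseudocount_weight)
  cpl <- coupling_matrix(freqs)
  cols <- freqs$columns
  L <- length(cols)
  block <- function(i, j) {
    cpl$e[(i - 1L) * Q_RED + seq_len(Q_RED),
          (j - 1L) * Q_RED + seq_len(Q_RED), drop = FALSE]
  }
  if (inherits(x, "coev_aln")) {
    if (L < 2L) stop("fewer than 2 non-invariant columns")
    M <- matrix(NA_real_, L, L)
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        M[i, j] <- M[j, i] <- direct_information(block(i, j),
                                                 freqs$fi[, i], freqs$fi[, j])
      }
    }
    ref <- if (!is.null(reference_a)) column_to_reference(x, reference_a)
    new_scorematrix("DI", M, "intra", cols, cols, ref, ref)
  } else {
    ia <- which(cols <= x$boundary)
    ib <- which(cols > x$boundary)
    if (length(ia) < 2L || length(ib) < 2L) {
      stop("fewer than 2 non-invariant columns on an axis")
    }
    M <- matrix(NA_real_, length(ia), length(ib))
    for (u in seq_along(ia)) {
      for (v in seq_along(ib)) {
        i <- ia[u]; j <- ib[v]
        M[u, v] <- direct_information(block(i, j), freqs$fi[, i], freqs$fi[, j])
      }
    }
    ref_a <- if (!is.null(reference_a)) column_to_reference(x$a, reference_a)
    ref_b <- if (!is.null(reference_b)) column_to_reference(x$b, reference_b)
    new_scorematrix("DI", M, "inter", cols[ia], cols[ib] - x$boundary,
                    ref_a, ref_b)
  }
}
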