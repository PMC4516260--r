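# Independent brute-force oracles written directly from the defining
# formulas with explicit loops.  They deliberately share no code with the
# package implementation.

ALPHA21 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

oracle_site_freq <- function(column, lambda) {
  s <- length(column)
  f <- numeric(21)
  for (m in seq_len(21)) f[m] <- sum(column == ALPHA21[m]) / s
  fp <- numeric(21)
  for (m in seq_len(21)) fp[m] <- (s / (s + 21 * lambda)) * (lambda / s + f[m])
  list(raw = f, prime = fp)
}

oracle_joint_freq <- function(col_i, col_j, lambda) {
  s <- length(col_i)
  f <- matrix(0, 21, 21)
  for (k in seq_len(s)) {
    m <- match(col_i[k], ALPHA21); n <- match(col_j[k], ALPHA21)
    f[m, n] <- f[m, n] + 1 / s
  }
  fpi <- oracle_site_freq(col_i, lambda)$prime
  fpj <- oracle_site_freq(col_j, lambda)$prime
  fp <- matrix(0, 21, 21)
  for (m in seq_len(21)) for (n in seq_len(21)) {
    fp[m, n] <- (s / (s + 42 * lambda)) *
      (lambda / s * fpi[m] + lambda / s * fpj[n] + f[m, n])
  }
  list(raw = f, prime = fp)
}

oracle_mi <- function(col_i, col_j, lambda) {
  fp <- oracle_joint_freq(col_i, col_j, lambda)$prime
  fpi <- oracle_site_freq(col_i, lambda)$prime
  fpj <- oracle_site_freq(col_j, lambda)$prime
  mi <- 0
  for (m in seq_len(21)) for (n in seq_len(21)) {
    if (fp[m, n] > 0) mi <- mi + fp[m, n] * log(fp[m, n] / (fpi[m] * fpj[n]))
  }
  mi
}

oracle_invariant <- function(mat) {
  out <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) out[j] <- length(unique(mat[, j])) == 1L
  out
}

# Full intra MI matrix over non-invariant columns of a character matrix.
oracle_mi_matrix_intra <- function(mat, lambda) {
  cols <- which(!oracle_invariant(mat))
  np <- length(cols)
  M <- matrix(NA_real_, np, np)
  for (u in seq_len(np)) for (v in seq_len(np)) {
    if (u != v) M[u, v] <- oracle_mi(mat[, cols[u]], mat[, cols[v]], lambda)
  }
  list(cols = cols, M = M)
}

oracle_mi_matrix_inter <- function(mat_a, mat_b, lambda) {
  ca <- which(!oracle_invariant(mat_a))
  cb <- which(!oracle_invariant(mat_b))
  M <- matrix(NA_real_, length(ca), length(cb))
  for (u in seq_along(ca)) for (v in seq_along(cb)) {
    M[u, v] <- oracle_mi(mat_a[, ca[u]], mat_b[, cb[v]], lambda)
  }
  list(cols_a = ca, cols_b = cb, M = M)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Z per formula with population sd; degenerate sigma (constant row, up to
# floating noise) contributes 0, matching the documented guard.
oracle_z_inter <- function(M) {
  Z <- matrix(NA_real_, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    si <- pop_sd(M[i, ]); sj <- pop_sd(M[, j])
    ti <- if (si > 1e-9) (M[i, j] - mean(M[i, ])) / si else 0
    tj <- if (sj > 1e-9) (M[i, j] - mean(M[, j])) / sj else 0
    Z[i, j] <- 0.5 * (ti + tj)
  }
  Z
}

oracle_z_intra <- function(M) {
  n <- nrow(M)
  Z <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    mi_part <- M[i, -i]; mj_part <- M[j, -j]
    si <- pop_sd(mi_part); sj <- pop_sd(mj_part)
    ti <- if (si > 1e-9) (M[i, j] - mean(mi_part)) / si else 0
    tj <- if (sj > 1e-9) (M[i, j] - mean(mj_part)) / sj else 0
    Z[i, j] <- 0.5 * (ti + tj)
  }
  Z
}

# O(s^2) reweighting oracle: weight = 1 / #{l : identity(k, l) >= 1 - theta}
oracle_weights <- function(mat, theta) {
  s <- nrow(mat)
  w <- numeric(s)
  for (k in seq_len(s)) {
    cnt <- 0L
    for (l in seq_len(s)) {
      id <- mean(mat[k, ] == mat[l, ])
      if (id >= 1 - theta) cnt <- cnt + 1L
    }
    w[k] <- 1 / cnt
  }
  w
}

random_alignment <- function(s, L, seed, gap_prob = 0) {
  set.seed(seed)
  symbols <- if (gap_prob > 0) ALPHA21 else ALPHA21[1:20]
  prob <- if (gap_prob > 0) c(rep((1 - gap_prob) / 20, 20), gap_prob) else NULL
  m <- matrix(sample(symbols, s * L, replace = TRUE, prob = prob), s, L)
  rownames(m) <- sprintf("sp%02d", seq_len(s))
  alignment(m)
}

# Minimal synthetic PDB writer for contact tests: atoms is a data frame
# with columns chain, resno, name, elem, x, y, z.
write_synthetic_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, atoms$name[i], "ALA", atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], 1.0, 0.0, atoms$elem[i])
  }, character(1L))
  writeLines(c(lines, "END"), path)
  path
}
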