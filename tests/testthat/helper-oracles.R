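# Independent brute-force oracles kept deliberately naive: plain loops,
# no shared code with the implementation.

naive_t1 <- function(g_i, g_j) {
  het <- 0L; opp <- 0L
  for (l in seq_along(g_i)) {
    a <- g_i[l]; b <- g_j[l]
    if (is.na(a) || is.na(b)) next
    if (a == 1 && b == 1) het <- het + 1L
    if ((a == 0 && b == 2) || (a == 2 && b == 0)) opp <- opp + 1L
  }
  het / (het + opp)
}

naive_v <- function(D, convention = "population") {
  n <- nrow(D)
  V <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffs <- c()
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      diffs <- c(diffs, D[i, k] - D[j, k])
    }
    m <- mean(diffs)
    v <- sum((diffs - m)^2) /
      (if (convention == "population") length(diffs) else length(diffs) - 1)
    V[i, j] <- V[j, i] <- v
  }
  V
}

naive_amova <- function(M, part) {
  n <- nrow(M)
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) sst <- sst + M[i, j]
  sst <- sst / (2 * n)
  ssw <- 0
  for (g in unique(part)) {
    idx <- which(part == g)
    acc <- 0
    for (i in idx) for (j in idx) acc <- acc + M[i, j]
    ssw <- ssw + acc / (2 * length(idx))
  }
  list(ss_total = sst, ss_within = ssw, ss_among = sst - ssw)
}

random_sym_matrix <- function(n, scale = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, scale)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("S", seq_len(n))
  m
}

# strip everything but dim/dimnames for pure-content comparisons
bare <- function(m) {
  out <- as.vector(m)
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

# Procrustes residual after optimal translation + rotation/reflection
procrustes_residual <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sqrt(sum((Y %*% R - X)^2))
}
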