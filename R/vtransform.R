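#' Variance-of-distance-differences transformation (V matrix)
#'
#' Transforms a dissimilarity matrix D into V, where for each pair (i, j)
#' the entry `V_ij` is the variance of the differences `d_ik - d_jk` taken
#' over all other individuals `k` (the two terms with `k` equal to `i` or
#' `j` are excluded, leaving N - 2 differences). If two individuals belong
#' to the same random-mating population, their distance profiles to everyone
#' else differ only by noise, so `V_ij` collapses to twice the error
#' variance; across populations a term proportional to the squared
#' between-population distance remains. The transformation therefore cancels
#' within-population variation and amplifies between-population signal.
#'
#' For a noise-free additive two-group configuration with group sizes
#' `n_I`, `n_J` and between-group distance `d`, the population-convention
#' variance gives exactly
#' `V = 4 (n_I - 1)(n_J - 1) / (n_I + n_J - 2)^2 * d^2`
#' for between-group pairs (which is `d^2` at equal sizes and 0 when either
#' group is a singleton) and 0 for within-group pairs; see
#' [v_theory_oracle()].
#'
#' @param D dissimilarity matrix (symmetric, zero diagonal, N >= 4).
#' @param convention `"population"` (divide by the number of retained
#'   differences, N - 2; the default, which reproduces the analytic limits
#'   exactly) or `"sample"` (divide by N - 3).
#' @return a [dissim_matrix()] with role `"V"`; the variance convention is
#'   recorded in the `"variance_convention"` attribute.
#' @examples
#' D <- two_group_additive_matrix(c(5, 5), d_between = 0.2, seed = 1)
#' V <- v_matrix(D)
#' V[1, 6]  # 0.04 = d_between^2
#' @export
v_matrix <- function(D, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  m <- as_dissim_values(D)
  n <- nrow(m)
  if (n < 4L) stop("V transformation needs at least 4 individuals")
  nk <- n - 2L
  # For pair (i,j) over k not in {i,j}:
  #   sum_k (d_ik - d_jk)            = R_i - R_j             (diagonal is 0)
  #   sum_k (d_ik - d_jk)^2          = S_i + S_j - 2 (M M)_ij - 2 d_ij^2
  # where R, S are row sums of entries and squared entries.
  R <- rowSums(m)
  S <- rowSums(m^2)
  cross <- tcrossprod(m)
  ssq <- outer(S, S, "+") - 2 * cross - 2 * m^2
  mu <- outer(R, R, "-") / nk
  v <- ssq / nk - mu^2
  if (convention == "sample") v <- v * nk / (nk - 1L)
  # numeric round-off can leave tiny negatives on exact-zero pairs
  v[v < 0] <- 0
  diag(v) <- 0
  out <- dissim_matrix((v + t(v)) / 2, role = "V", samples = rownames(m))
  attr(out, "variance_convention") <- convention
  out
}

#' Analytic V for the two-group additive model
#'
#' Closed-form expectation of the V entry for the simplest configuration the
#' transformation is designed around: two groups of sizes `n_I` and `n_J`
#' whose pairwise distances are additive along paths
#' (individual -> group -> individual), separated by between-group distance
#' `d_between`, with i.i.d. Gaussian noise of standard deviation `sigma` on
#' each pairwise distance.
#'
#' Within-group pairs have expectation `2 sigma^2`; between-group pairs
#' `4 (n_I - 1)(n_J - 1) / (n_I + n_J - 2)^2 * d_between^2 + 2 sigma^2`,
#' which reduces to `d_between^2 + 2 sigma^2` at equal group sizes and to
#' `2 sigma^2` when either group is a singleton (a singleton's distance to
#' its own group cannot be separated from the between-group distance, so a
#' lone individual contributes no detectable structure).
#'
#' @param group_sizes integer vector of length 2 (`n_I`, `n_J`).
#' @param d_between between-group distance.
#' @param sigma standard deviation of the additive noise on each distance.
#' @return list with `within` and `between` expected V values.
#' @export
v_theory_oracle <- function(group_sizes, d_between, sigma = 0) {
  if (length(group_sizes) != 2L)
    stop("oracle derived for the two-group case only")
  n_i <- group_sizes[1L]; n_j <- group_sizes[2L]
  if (n_i < 1 || n_j < 1) stop("group sizes must be at least 1")
  between <- 4 * (n_i - 1) * (n_j - 1) / (n_i + n_j - 2)^2 * d_between^2 +
    2 * sigma^2
  list(within = 2 * sigma^2, between = between)
}

#' Build a noise-free (or noisy) two-group additive distance matrix
#'
#' Distances follow the additive path model: for individuals i, j the
#' distance is `a_i + a_j` within a group and `a_i + d_between + a_j` across
#' groups, where `a_i` is individual i's distance to its group vertex, drawn
#' from `U(0.5, 1)`. Optional i.i.d. Gaussian noise is added per pair.
#'
#' @param group_sizes integer vector of length 2.
#' @param d_between between-group distance.
#' @param sigma noise standard deviation (0 for the exact analytic case).
#' @param offsets optional numeric vector of per-individual distances to the
#'   group vertex (overrides the uniform draw).
#' @param seed optional integer seed.
#' @return a [dissim_matrix()] (role `"generic"`) with a `"labels"`
#'   attribute giving the true group of each individual.
#' @export
two_group_additive_matrix <- function(group_sizes, d_between, sigma = 0,
                                      offsets = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(group_sizes)
  grp <- rep(seq_along(group_sizes), group_sizes)
  if (is.null(offsets)) offsets <- stats::runif(n, 0.5, 1)
  base <- outer(offsets, offsets, "+") + d_between * outer(grp, grp, "!=")
  if (sigma > 0) {
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- stats::rnorm(n * (n - 1) / 2, 0, sigma)
    eps <- eps + t(eps)
    base <- base + eps
  }
  diag(base) <- 0
  out <- dissim_matrix(base, samples = paste0("S", seq_len(n)))
  attr(out, "labels") <- paste0("G", grp)
  out
}
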