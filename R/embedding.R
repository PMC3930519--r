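#' Classical multidimensional scaling with Cailliez correction
#'
#' Classical (metric) MDS of a dissimilarity matrix: double-centering of
#' -1/2 the squared dissimilarities, eigendecomposition, coordinates from
#' the top eigenpairs. If the configuration is non-Euclidean (a negative
#' eigenvalue appears), the Cailliez additive constant is applied to the
#' off-diagonal dissimilarities and the scaling recomputed, so no retained
#' eigenvalue is negative. Per-dimension explained variance is reported as
#' the share of the positive eigenvalue mass.
#'
#' @param matrix dissimilarity matrix.
#' @param n_dims number of dimensions to return (at most N - 1).
#' @return object of class `"mds_embedding"`: `coordinates`
#'   (N x n_dims), `eigenvalues` (nonincreasing), `variance_fraction`
#'   (per returned dimension), `additive_constant` (0 when the input was
#'   already Euclidean).
#' @examples
#' pts <- cbind(rnorm(5), rnorm(5))
#' emb <- classical_mds(as.matrix(dist(pts)), 2)
#' emb$additive_constant
#' @export
classical_mds <- function(matrix, n_dims = 2L) {
  m <- as_dissim_values(matrix)
  n <- nrow(m)
  if (n_dims >= n) stop("n_dims must be smaller than the number of samples")
  fit <- stats::cmdscale(m, k = n_dims, eig = TRUE)
  ac <- 0
  if (min(fit$eig) < -1e-8 * max(abs(fit$eig))) {
    fit <- stats::cmdscale(m, k = n_dims, eig = TRUE, add = TRUE)
    ac <- fit$ac
  }
  pos <- fit$eig[fit$eig > 0]
  eig_sorted <- sort(fit$eig, decreasing = TRUE)
  structure(list(coordinates = unname(fit$points),
                 eigenvalues = eig_sorted,
                 variance_fraction = eig_sorted[seq_len(n_dims)] / sum(pos),
                 additive_constant = ac,
                 samples = rownames(m)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("Classical MDS: %d samples, %d dimensions (additive constant %.4g)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$additive_constant))
  cat(sprintf("  variance explained per dimension: %s\n",
              paste(sprintf("%.2f%%", 100 * x$variance_fraction), collapse = ", ")))
  invisible(x)
}

#' Gaussian-mixture clustering of embedding coordinates with BIC selection
#'
#' Fits Gaussian mixture models over a range of component counts to the
#' first `n_dims_used` embedding dimensions (via `mclust`), and returns the
#' assignment of the BIC-optimal model. BIC uses mclust's higher-is-better
#' sign convention.
#'
#' @param coordinates numeric matrix of embedding coordinates (or an
#'   `"mds_embedding"`).
#' @param k_min,k_max range of mixture sizes to consider.
#' @param n_dims_used number of leading dimensions used (clipped to the
#'   available columns); 10 by default.
#' @param seed integer seed (mixture initialization).
#' @return list with `partition` (integer assignment), `K` (selected
#'   number of clusters), `bic` (matrix of BIC values per K and model,
#'   higher is better; `NA` where a fit failed and was skipped) and
#'   `model` (the fitted `Mclust` object).
#' @export
gmm_bic_cluster <- function(coordinates, k_min = 1L, k_max = 9L,
                            n_dims_used = 10L, seed = 1L) {
  if (inherits(coordinates, "mds_embedding"))
    coordinates <- coordinates$coordinates
  coordinates <- as.matrix(coordinates)
  if (k_min < 1L || k_max > nrow(coordinates) || k_min > k_max)
    stop("invalid cluster range")
  d <- min(n_dims_used, ncol(coordinates))
  X <- coordinates[, seq_len(d), drop = FALSE]
  # Mclust() resolves mclustBIC in the calling frame, so bind it locally to
  # keep the package usable without mclust attached
  mclustBIC <- mclust::mclustBIC
  fit <- with_seed(seed,
    mclust::Mclust(X, G = k_min:k_max, verbose = FALSE))
  if (is.null(fit)) stop("no mixture model could be fitted")
  if (anyNA(fit$BIC))
    warning("some mixture sizes/models failed to fit and were skipped")
  list(partition = as.integer(fit$classification), K = fit$G,
       bic = unclass(fit$BIC), model = fit)
}
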