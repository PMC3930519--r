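#' Construct a genotype matrix
#'
#' A genotype matrix holds diploid biallelic SNP calls for N individuals
#' (rows) at M loci (columns), coded as the dosage of one of the two alleles:
#' 0 and 2 are the two homozygotes, 1 the heterozygote, `NA` a missing call.
#' Which allele is counted is irrelevant for every statistic in this package:
#' the T1 similarity only distinguishes the pattern classes
#' {same homozygote, opposite homozygotes, heterozygote}, so flipping the
#' polarity of any locus leaves all results unchanged.
#'
#' @param calls numeric or integer matrix with values in `{0, 1, 2, NA}`.
#' @param samples character vector of unique sample identifiers
#'   (default: rownames of `calls`, or `S1..SN`).
#' @param loci character vector of unique locus identifiers
#'   (default: colnames of `calls`, or `L1..LM`).
#' @return an integer matrix of class `"genotype_matrix"` with sample
#'   rownames and locus colnames.
#' @examples
#' g <- genotype_matrix(rbind(c(0, 1, 2), c(2, 1, 0)))
#' t1_pair(g[1, ], g[2, ])
#' @export
genotype_matrix <- function(calls, samples = NULL, loci = NULL) {
  calls <- as.matrix(calls)
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop("genotype matrix needs at least one sample and one locus")
  if (is.null(samples)) samples <- rownames(calls)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  if (is.null(loci)) loci <- colnames(calls)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(calls)))
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(loci))
    stop("duplicate locus identifiers: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  if (length(samples) != nrow(calls) || length(loci) != ncol(calls))
    stop("identifier lengths do not match matrix dimensions")
  bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype code %s at sample '%s', locus '%s' (allowed: 0, 1, 2, NA)",
                 format(calls[bad][1L]), samples[idx[1L]], loci[idx[2L]]))
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(samples, loci)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d loci (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Construct a dissimilarity matrix
#'
#' Square symmetric nonnegative matrix with zero diagonal over a set of
#' samples. The `role` attribute records what the entries are: `"D"` for the
#' genetic distance 1 - T1 (entries additionally bounded by 1), `"V"` for the
#' variance-of-distance-differences transform, `"generic"` otherwise.
#'
#' @param values square numeric matrix.
#' @param role one of `"generic"`, `"D"`, `"V"`.
#' @param samples sample identifiers (default rownames, or `S1..SN`).
#' @param tol symmetry tolerance used for validation.
#' @return a numeric matrix of class `"dissim_matrix"` with a `role`
#'   attribute; stored exactly symmetric (upper triangle mirrored).
#' @export
dissim_matrix <- function(values, role = c("generic", "D", "V"),
                          samples = NULL, tol = 1e-8) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("dissimilarity matrix must be square")
  if (is.null(samples)) samples <- rownames(values)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (any(!is.finite(values))) stop("dissimilarity matrix has non-finite entries")
  if (max(abs(values - t(values))) > tol)
    stop("dissimilarity matrix is not symmetric")
  if (any(abs(diag(values)) > tol))
    stop("dissimilarity matrix diagonal must be zero")
  if (any(values < -tol)) stop("dissimilarity matrix has negative entries")
  if (role == "D" && any(values > 1 + tol))
    stop("D-matrix entries must lie in [0, 1]")
  # store exactly symmetric, clean diagonal, clamp round-off negatives
  values[] <- (values + t(values)) / 2
  diag(values) <- 0
  values[values < 0] <- 0
  dimnames(values) <- list(samples, samples)
  attr(values, "role") <- role
  class(values) <- c("dissim_matrix", class(values))
  values
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("Dissimilarity matrix (role %s): %d samples, off-diagonal range [%.4g, %.4g]\n",
              attr(x, "role"), nrow(x),
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

# strip class/attrs for numeric work
unwrap_matrix <- function(m) {
  a <- as.matrix(m)
  attr(a, "role") <- NULL
  class(a) <- "matrix"
  a
}

# validate an arbitrary object as a usable dissimilarity matrix and return
# it as a plain numeric matrix (tolerant entry point used by most modules)
as_dissim_values <- function(m, tol = 1e-8) {
  if (!inherits(m, "dissim_matrix")) m <- dissim_matrix(m, tol = tol)
  unwrap_matrix(m)
}

matrix_role <- function(m) {
  r <- attr(m, "role")
  if (is.null(r)) "generic" else r
}
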