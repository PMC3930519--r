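#' Genotype pattern counts for a pair of individuals
#'
#' Counts, over loci where both calls are present, the two informative
#' diploid genotype patterns on which the T1 similarity is built: both
#' individuals heterozygous, and the two individuals homozygous for opposite
#' alleles. All other patterns (shared homozygote, homozygote/heterozygote)
#' carry no information about excess or deficit of allele sharing under
#' Hardy-Weinberg equilibrium and are ignored.
#'
#' @param g_i,g_j genotype vectors of equal length with calls in
#'   `{0, 1, 2, NA}`. Loci where either call is `NA` are excluded from all
#'   counts (pairwise-complete deletion).
#' @return list with `n_het_het`, `n_opp_hom`, `n_informative`
#'   (their sum) and `n_compared` (loci with both calls present).
#' @export
pattern_counts <- function(g_i, g_j) {
  if (length(g_i) != length(g_j))
    stop("genotype vectors must have equal length")
  ok <- !is.na(g_i) & !is.na(g_j)
  a <- g_i[ok]
  b <- g_j[ok]
  n_het <- sum(a == 1L & b == 1L)
  n_opp <- sum((a == 0L & b == 2L) | (a == 2L & b == 0L))
  list(n_het_het = n_het, n_opp_hom = n_opp,
       n_informative = n_het + n_opp, n_compared = sum(ok))
}

#' T1 pairwise genotype similarity
#'
#' T1 is the fraction of informative genotype patterns in which both
#' individuals are heterozygous:
#' `T1 = n_hethet / (n_hethet + n_opphom)`.
#' Under Hardy-Weinberg equilibrium its expectation for two unrelated
#' individuals from the same random-mating population is 2/3 at every allele
#' frequency (4p^2q^2 / (4p^2q^2 + 2p^2q^2)); relatives exceed 2/3 (opposite
#' homozygotes become rare) and pairs drawn from diverged populations fall
#' below it.
#'
#' @inheritParams pattern_counts
#' @return T1 in `[0, 1]`.
#' @seealso [distance_matrix()] for the derived distance 1 - T1.
#' @export
t1_pair <- function(g_i, g_j) {
  pc <- pattern_counts(g_i, g_j)
  if (pc$n_informative == 0L)
    stop("uninformative pair: no both-heterozygous or opposite-homozygote loci")
  pc$n_het_het / pc$n_informative
}

# Vectorized T1 for all pairs. Uses indicator cross-products:
# het %*% t(het) counts both-het loci; hom0 %*% t(hom2) + hom2 %*% t(hom0)
# counts opposite homozygotes. NA calls contribute 0 to every indicator,
# which realizes pairwise-complete deletion.
t1_all_pairs <- function(calls) {
  het  <- (calls == 1L); het[is.na(het)] <- FALSE; storage.mode(het) <- "double"
  hom0 <- (calls == 0L); hom0[is.na(hom0)] <- FALSE; storage.mode(hom0) <- "double"
  hom2 <- (calls == 2L); hom2[is.na(hom2)] <- FALSE; storage.mode(hom2) <- "double"
  n_het <- tcrossprod(het)
  n_opp <- tcrossprod(hom0, hom2)
  n_opp <- n_opp + t(n_opp)
  denom <- n_het + n_opp
  list(t1 = n_het / denom, n_informative = denom)
}

#' Pairwise genetic distance matrix D = 1 - T1
#'
#' Computes T1 for every pair of individuals and returns the distance
#' `d_ij = 1 - T1_ij`. A pair with no informative locus has no defined
#' distance and raises an error naming the pair; silent defaults would
#' corrupt the downstream V transformation.
#'
#' @param G a [genotype_matrix()] (or plain matrix of 0/1/2/NA calls) with
#'   at least two samples.
#' @return a [dissim_matrix()] with role `"D"`.
#' @examples
#' G <- simulate_hwe_population(6, 500, seed = 1)
#' D <- distance_matrix(G)
#' mean(D[upper.tri(D)])  # about 1/3 for one HWE population
#' @export
distance_matrix <- function(G) {
  if (!inherits(G, "genotype_matrix")) G <- genotype_matrix(G)
  if (nrow(G) < 2L) stop("need at least two samples")
  res <- t1_all_pairs(unclass(G))
  bad <- res$n_informative == 0
  diag(bad) <- FALSE
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("uninformative pair ('%s', '%s'): no informative loci",
                 rownames(G)[ij[1L]], rownames(G)[ij[2L]]))
  }
  d <- 1 - res$t1
  diag(d) <- 0
  dissim_matrix(d, role = "D", samples = rownames(G))
}

#' Mean distance of each individual to its own sampling population
#'
#' For each labelled individual, the mean D-distance to the other members of
#' its population. Under random mating within the population this mean has
#' expectation 1/3 (the complement of E(T1) = 2/3); individuals whose mean
#' exceeds 1/3 look, on average, as if they were sampled from a different
#' random-mating population, and are flagged.
#'
#' @param D a D-role dissimilarity matrix.
#' @param labels character/factor vector of population labels, one per
#'   sample (in matrix order), or a named vector matched by sample id.
#' @return data.frame with `sample`, `population`, `mean_dist`
#'   (`NA` for members of singleton populations, with a warning) and
#'   `flagged` (`mean_dist > 1/3`).
#' @export
mean_distance_to_population <- function(D, labels) {
  m <- as_dissim_values(D)
  labels <- match_labels(labels, rownames(m))
  n <- nrow(m)
  out <- data.frame(sample = rownames(m), population = as.character(labels),
                    mean_dist = NA_real_, flagged = NA,
                    stringsAsFactors = FALSE)
  singleton <- FALSE
  for (i in seq_len(n)) {
    co <- which(labels == labels[i])
    co <- co[co != i]
    if (length(co) == 0L) { singleton <- TRUE; next }
    out$mean_dist[i] <- mean(m[i, co])
  }
  if (singleton)
    warning("singleton population(s): mean distance undefined for their members")
  out$flagged <- out$mean_dist > 1 / 3
  out
}

# Resolve a label vector against matrix/sample ids: accepts unnamed vector in
# order, named vector, or two-column data.frame (sample, label).
match_labels <- function(labels, samples) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L) stop("label table needs columns sample, label")
    labels <- stats::setNames(as.character(labels[[2L]]), as.character(labels[[1L]]))
  }
  if (!is.null(names(labels)) && !all(names(labels) == "")) {
    if (anyDuplicated(names(labels))) stop("duplicate sample in label table")
    if (!setequal(names(labels), samples))
      stop("label table samples do not match matrix samples")
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    stop("labels must have one entry per sample")
  }
  as.character(labels)
}
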