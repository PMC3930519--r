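#' Best-overall-match percentage
#'
#' For each individual, its best overall match (BOM) is the other individual
#' with the smallest dissimilarity to it. The BOM percentage is the share of
#' individuals whose best match carries the same population label — a
#' direct, clustering-free measure of how well a matrix groups individuals
#' by origin. Ties on the row minimum are broken by smallest sample index
#' (deterministic); the number of tied rows is reported.
#'
#' @param matrix dissimilarity matrix.
#' @param labels population labels (vector, named vector or data.frame).
#' @return list with `percentage` (in `[0, 100]`), `per_population`
#'   (named vector of within-population BOM percentages), `matches`
#'   (logical per sample), `bom_index` (index of each sample's best match)
#'   and `n_ties`.
#' @examples
#' m <- two_group_additive_matrix(c(5, 5), 2, seed = 3)
#' bom_percentage(v_matrix(m), attr(m, "labels"))$percentage
#' @export
bom_percentage <- function(matrix, labels) {
  m <- as_dissim_values(matrix)
  labels <- match_labels(labels, rownames(m))
  n <- nrow(m)
  diag(m) <- Inf
  bom <- integer(n)
  n_ties <- 0L
  for (i in seq_len(n)) {
    mins <- which(m[i, ] == min(m[i, ]))
    if (length(mins) > 1L) n_ties <- n_ties + 1L
    bom[i] <- mins[1L]
  }
  matches <- labels[bom] == labels
  per_pop <- tapply(matches, labels, function(z) 100 * mean(z))
  list(percentage = 100 * mean(matches),
       per_population = per_pop[sort(unique(labels))],
       matches = matches, bom_index = bom, n_ties = n_ties)
}

#' Cramer's V association between clusters and populations
#'
#' Measures agreement between an inferred clustering and the known sampling
#' populations: `V = sqrt(chi^2 / (N (k - 1)))`, where `chi^2` is Pearson's
#' chi-squared statistic of the clusters-by-populations contingency table
#' (no continuity correction; no test is performed) and `k` is the smaller
#' of the table's dimensions. Ranges from 0 (random assignment) to 1 (each
#' cluster matches one population exactly); defined as 0 when either margin
#' has a single level.
#'
#' @param cluster_labels,pop_labels vectors of equal length.
#' @return Cramer's V in `[0, 1]`.
#' @export
cramers_v <- function(cluster_labels, pop_labels) {
  if (length(cluster_labels) != length(pop_labels))
    stop("label vectors must have equal length")
  tab <- table(cluster_labels, pop_labels)
  k <- min(nrow(tab), ncol(tab))
  if (k < 2L) return(0)
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (sum(tab) * (k - 1)))
  min(v, 1)
}

#' Informativeness for assignment between two populations
#'
#' Rosenberg's entropy-based informativeness of a set of cluster
#' frequencies for telling two populations apart:
#' \deqn{I_n = \sum_c \left[-\bar p_c \ln \bar p_c +
#'   \frac{p_{sc}\ln p_{sc} + p_{tc}\ln p_{tc}}{2}\right],
#'   \quad \bar p_c = \frac{p_{sc}+p_{tc}}{2},}
#' with the convention `0 ln 0 = 0` and natural logarithms. Ranges from 0
#' (the cluster frequencies are identical, the populations cannot be
#' distinguished) to `ln 2` (disjoint cluster support, perfectly
#' distinguishable).
#'
#' @param freq_s,freq_t cluster-frequency vectors of equal length, each
#'   summing to 1.
#' @return I_n in `[0, ln 2]`.
#' @export
informativeness_in <- function(freq_s, freq_t) {
  if (length(freq_s) != length(freq_t))
    stop("frequency vectors must have equal length")
  if (abs(sum(freq_s) - 1) > 1e-6 || abs(sum(freq_t) - 1) > 1e-6)
    stop("frequency vectors must each sum to 1")
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  pbar <- (freq_s + freq_t) / 2
  sum(-xlx(pbar) + (xlx(freq_s) + xlx(freq_t)) / 2)
}

#' Minimum pairwise informativeness per population
#'
#' For each population, the minimum informativeness for assignment
#' ([informativeness_in()]) against every other population, computed from
#' the frequencies of the inferred clusters within each population. A
#' population whose minimum is `ln 2` is perfectly separated from all
#' others by the clustering; a minimum of 0 means at least one other
#' population is indistinguishable from it. The mean of the minima
#' summarizes overall sampling-site resolution.
#'
#' @param cluster_labels,pop_labels vectors of equal length.
#' @return list with `min_in` (named per-population vector), `mean_min_in`
#'   and `freq` (the population-by-cluster frequency table).
#' @export
min_in_per_population <- function(cluster_labels, pop_labels) {
  if (length(cluster_labels) != length(pop_labels))
    stop("label vectors must have equal length")
  pops <- sort(unique(as.character(pop_labels)))
  if (length(pops) < 2L) stop("need at least two populations")
  tab <- table(pop_labels, cluster_labels)
  freq <- sweep(tab, 1, rowSums(tab), "/")
  mins <- stats::setNames(rep(NA_real_, length(pops)), pops)
  for (s in pops) {
    others <- setdiff(pops, s)
    mins[s] <- min(vapply(others, function(t)
      informativeness_in(freq[s, ], freq[t, ]), numeric(1)))
  }
  list(min_in = mins, mean_min_in = mean(mins), freq = freq)
}
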