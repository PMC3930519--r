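#' Fit a population-substructure partition by GA-driven AMOVA maximization
#'
#' The main entry point. Starting from genotypes (or a precomputed
#' dissimilarity matrix), computes the T1-based genetic distance
#' D = 1 - T1, transforms it (by default) into the V matrix — the per-pair
#' variance of the difference between the two individuals' distance profiles
#' to all others, which cancels within-population variation — and searches
#' the space of partitions of the N individuals into at most K clusters with
#' a genetic algorithm maximizing the among-population sum of squares of the
#' AMOVA decomposition.
#'
#' @param x a [genotype_matrix()] (or plain 0/1/2/NA matrix), or a
#'   [dissim_matrix()].
#' @param K maximum number of clusters the search may use.
#' @param labels optional known population labels; when supplied, summary
#'   statistics comparing the fitted clusters to the labels (best-overall-
#'   match percentage, Cramer's V, mean minimum informativeness) are
#'   computed.
#' @param transform `"V"` (default) to run the search on the transformed
#'   matrix, `"D"` to run it on the raw distance matrix.
#' @param square_entries passed to [amova_ss()] for the fitness (default
#'   `FALSE`: entries consumed as squared distances).
#' @param config a [ga_config()]; its `seed` fixes the whole fit.
#' @return object of class `"gaga"` with components `partition`,
#'   `amova` (decomposition of the search matrix at the fitted partition),
#'   `ga` (the [optimize_partition()] result), `D`, `V` (when computed),
#'   `search_matrix` (`"D"` or `"V"`), `labels` and `evaluation` (when
#'   labels were given).
#' @examples
#' G <- simulate_balding_nichols(8, 800, fst = 0.2, seed = 5)
#' fit <- gaga(G, K = 2, labels = attr(G, "labels"),
#'             config = ga_config(max_generations = 200, seed = 1))
#' summary(fit)
#' @export
gaga <- function(x, K, labels = NULL, transform = c("V", "D"),
                 square_entries = FALSE, config = ga_config()) {
  transform <- match.arg(transform)
  if (inherits(x, "dissim_matrix")) {
    D <- if (matrix_role(x) == "V") NULL else x
    search <- if (transform == "V" && matrix_role(x) != "V") v_matrix(x) else x
    V <- if (matrix_role(search) == "V") search else NULL
  } else {
    D <- distance_matrix(x)
    V <- if (transform == "V") v_matrix(D) else NULL
    search <- if (transform == "V") V else D
  }
  if (!is.null(labels)) labels <- match_labels(labels, rownames(search))
  ga <- optimize_partition(unwrap_matrix(search), K = K, config = config)
  dec <- amova_ss(search, ga$best_partition, square_entries = square_entries)
  evaluation <- NULL
  if (!is.null(labels)) {
    evaluation <- list(
      bom = bom_percentage(search, labels),
      cramers_v = cramers_v(ga$best_partition, labels),
      min_in = if (length(unique(labels)) >= 2L)
        min_in_per_population(ga$best_partition, labels) else NULL)
  }
  structure(list(partition = ga$best_partition, amova = dec, ga = ga,
                 D = D, V = V, search_matrix = matrix_role(search),
                 K = as.integer(K), labels = labels,
                 evaluation = evaluation, call = match.call()),
            class = "gaga")
}

#' @export
print.gaga <- function(x, ...) {
  cat("GA-driven AMOVA partition fit\n")
  cat(sprintf("  search matrix: %s; K <= %d; clusters used: %d\n",
              x$search_matrix, x$K, length(unique(x$partition))))
  cat(sprintf("  SS(AP)/SS(T) at fitted partition: %.4f%%\n",
              100 * x$amova$ratio_among))
  invisible(x)
}

#' @export
summary.gaga <- function(object, ...) {
  out <- list(fit = object,
              cluster_sizes = table(object$partition),
              amova = object$amova,
              evaluation = object$evaluation)
  class(out) <- "summary.gaga"
  out
}

#' @export
print.summary.gaga <- function(x, ...) {
  print(x$fit)
  cat("\nCluster sizes:\n")
  print(x$cluster_sizes)
  cat("\n")
  print(x$amova)
  if (!is.null(x$evaluation)) {
    cat(sprintf("\nAgainst known labels:\n  BOM%%: %.2f\n  Cramer's V: %.4f\n",
                x$evaluation$bom$percentage, x$evaluation$cramers_v))
    if (!is.null(x$evaluation$min_in))
      cat(sprintf("  mean min I_n: %.4f\n", x$evaluation$min_in$mean_min_in))
  }
  invisible(x)
}

#' @export
plot.gaga <- function(x, ...) {
  trace <- x$ga$fitness_trace
  graphics::plot(seq_along(trace), trace, type = "l",
                 xlab = "generation", ylab = "best SS(AP)",
                 main = "GA fitness trace", ...)
  invisible(x)
}
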