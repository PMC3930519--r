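#' Genetic-algorithm configuration
#'
#' Hyperparameters of the partition-search genetic algorithm. The defaults
#' follow standard GA practice for grouping problems: modest population,
#' binary tournament selection, high crossover rate, per-gene mutation at
#' 1/N, single-elite survival and a stagnation stop.
#'
#' @param population_size number of candidate partitions per generation.
#' @param max_generations hard generation cap.
#' @param stagnation_limit stop after this many generations without
#'   improvement of the best fitness.
#' @param crossover_rate probability a selected parent pair is recombined.
#' @param mutation_rate per-sample reassignment probability (`NULL` =
#'   1/N, resolved at run time).
#' @param elitism_count number of best individuals copied unchanged.
#' @param seed integer seed for reproducibility.
#' @return list of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 50L, max_generations = 2000L,
                      stagnation_limit = 100L, crossover_rate = 0.9,
                      mutation_rate = NULL, elitism_count = 1L, seed = 1L) {
  if (population_size < 2L) stop("population_size must be >= 2")
  if (elitism_count >= population_size)
    stop("elitism_count must be smaller than population_size")
  stopifnot(crossover_rate >= 0, crossover_rate <= 1)
  if (!is.null(mutation_rate))
    stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 stagnation_limit = as.integer(stagnation_limit),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Canonicalize a partition
#'
#' Relabels clusters in order of first appearance so that partitions that
#' differ only by a permutation of cluster labels compare equal, with
#' indices contiguous from 1.
#'
#' @param partition integer assignment vector.
#' @return integer vector with labels 1..K' in first-appearance order.
#' @export
canonicalize_partition <- function(partition) {
  as.integer(factor(partition, levels = unique(partition)))
}

#' Subcluster-swap crossover for partitions
#'
#' Grouping-problem recombination: one non-empty cluster is chosen at random
#' from each parent and imposed on the other. The imposed members form a
#' cluster of their own (keeping the donor's label); members of the
#' recipient that previously held that label but are not part of the
#' imposed cluster fall back to their label in the donor parent, which is
#' guaranteed to differ from the imposed label. Identical parents are a
#' fixed point.
#'
#' @param parent_a,parent_b integer assignment vectors over the same
#'   samples with labels within 1..K.
#' @param K cluster-count upper bound.
#' @return list of two offspring assignment vectors (canonicalized).
#' @export
subcluster_swap_crossover <- function(parent_a, parent_b, K) {
  if (length(parent_a) != length(parent_b))
    stop("parents must cover the same samples")
  impose <- function(recipient, donor) {
    labs <- unique(donor)
    c_lab <- labs[[sample.int(length(labs), 1L)]]
    members <- donor == c_lab
    child <- recipient
    displaced <- !members & child == c_lab
    child[members] <- c_lab
    child[displaced] <- donor[displaced]  # donor label != c_lab by construction
    child
  }
  list(canonicalize_partition(impose(parent_a, parent_b)),
       canonicalize_partition(impose(parent_b, parent_a)))
}

#' Mutate a partition
#'
#' Each sample is independently reassigned, with probability `rate`, to a
#' cluster drawn uniformly from 1..K (possibly its current one, so the
#' expected fraction of samples actually moved is `rate * (K - 1) / K`).
#'
#' @param partition integer assignment vector.
#' @param K cluster-count upper bound.
#' @param rate per-sample mutation probability.
#' @return mutated assignment vector (not canonicalized).
#' @export
mutate_partition <- function(partition, K, rate) {
  if (rate <= 0 || K < 2L) return(partition)
  hit <- stats::runif(length(partition)) < rate
  if (any(hit)) partition[hit] <- sample.int(K, sum(hit), replace = TRUE)
  partition
}

#' Search for the partition maximizing the among-population sum of squares
#'
#' Runs a genetic algorithm over assignments of N individuals to at most K
#' clusters, maximizing SS(AP) of [amova_ss()] (equivalently minimizing
#' SS(WP), since SS(T) is fixed by the matrix). K is an upper bound: empty
#' clusters are allowed throughout the search. Identical
#' (matrix, K, config) inputs give identical results.
#'
#' @param matrix dissimilarity matrix (entries consumed as squared
#'   distances, the package-wide AMOVA default).
#' @param K maximum number of clusters (2..N).
#' @param config a [ga_config()].
#' @return object of class `"ga_result"`: `best_partition` (canonical
#'   integer vector), `best_fitness` (SS(AP)), `fitness_trace`
#'   (per-generation best, nondecreasing), `evaluations` (count of distinct
#'   fitness evaluations) and `generations`.
#' @examples
#' m <- two_group_additive_matrix(c(5, 5), 1, seed = 2)
#' fit <- optimize_partition(v_matrix(m), K = 2)
#' table(fit$best_partition, attr(m, "labels"))
#' @export
optimize_partition <- function(matrix, K, config = ga_config()) {
  m <- as_dissim_values(matrix)
  n <- nrow(m)
  K <- as.integer(K)
  if (K > n) stop("K cannot exceed the number of samples")
  if (n < 2L || K < 2L) stop("need at least 2 samples and K >= 2")
  ss_total <- sum(m) / (2 * n)
  if (ss_total == 0) {
    warning("degenerate all-zero matrix: every partition has fitness 0")
    return(structure(list(best_partition = rep(1L, n), best_fitness = 0,
                          fitness_trace = 0, evaluations = 0L,
                          generations = 0L, ss_total = 0),
                     class = "ga_result"))
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  mut_rate <- if (is.null(config$mutation_rate)) 1 / n else config$mutation_rate
  pop_size <- config$population_size
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evals <- 0L
  fitness <- function(p) {
    key <- paste(canonicalize_partition(p), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    evals <<- evals + 1L
    f <- ss_total - ss_within_cpp(m, p, K)
    cache[[key]] <- f
    f
  }

  pop <- replicate(pop_size, sample.int(K, n, replace = TRUE), simplify = FALSE)
  pop[[1L]] <- rep(seq_len(K), length.out = n)  # one spread-out seed partition
  fit <- vapply(pop, fitness, numeric(1))
  best_i <- which.max(fit)
  best <- pop[[best_i]]; best_f <- fit[best_i]
  trace <- numeric(0)
  stagnant <- 0L
  gen <- 0L
  while (gen < config$max_generations && stagnant < config$stagnation_limit) {
    gen <- gen + 1L
    ord <- order(fit, decreasing = TRUE)
    new_pop <- pop[ord[seq_len(config$elitism_count)]]
    while (length(new_pop) < pop_size) {
      pa <- pop[[tournament(fit, 2L)]]
      pb <- pop[[tournament(fit, 2L)]]
      if (stats::runif(1) < config$crossover_rate) {
        kids <- subcluster_swap_crossover(pa, pb, K)
      } else {
        kids <- list(pa, pb)
      }
      for (kid in kids) {
        if (length(new_pop) < pop_size)
          new_pop[[length(new_pop) + 1L]] <- mutate_partition(kid, K, mut_rate)
      }
    }
    pop <- new_pop
    fit <- vapply(pop, fitness, numeric(1))
    gen_best <- max(fit)
    if (gen_best > best_f + 1e-12) {
      best_f <- gen_best
      best <- pop[[which.max(fit)]]
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    trace[gen] <- best_f
  }
  structure(list(best_partition = canonicalize_partition(best),
                 best_fitness = best_f, fitness_trace = trace,
                 evaluations = evals, generations = gen,
                 ss_total = ss_total),
            class = "ga_result")
}

tournament <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  cand[which.max(fit[cand])]
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA partition search: best SS(AP) = %.6g (%.3f%% of SS(T)) after %d generations, %d evaluations\n",
              x$best_fitness,
              if (x$ss_total > 0) 100 * x$best_fitness / x$ss_total else 0,
              x$generations, x$evaluations))
  cat(sprintf("  clusters used: %d\n", length(unique(x$best_partition))))
  invisible(x)
}

#' Exhaustive partition search (oracle for small N)
#'
#' Enumerates all K^N assignments (after fixing the first sample to cluster
#' 1 to quotient out one label symmetry) and returns the SS(AP)-optimal
#' partition. Intended as an independent check of [optimize_partition()] on
#' instances with N <= ~12.
#'
#' @inheritParams optimize_partition
#' @return list with `best_partition` and `best_fitness`.
#' @export
exhaustive_partition_search <- function(matrix, K) {
  m <- as_dissim_values(matrix)
  n <- nrow(m)
  if (K^(n - 1) > 2e6) stop("instance too large for exhaustive search")
  ss_total <- sum(m) / (2 * n)
  best <- NULL; best_f <- -Inf
  assign <- rep(1L, n)
  grid <- rep(list(seq_len(K)), n - 1L)
  combos <- as.matrix(expand.grid(grid))
  for (r in seq_len(nrow(combos))) {
    assign[-1L] <- combos[r, ]
    f <- ss_total - ss_within_cpp(m, assign, K)
    if (f > best_f) { best_f <- f; best <- assign }
  }
  list(best_partition = canonicalize_partition(best), best_fitness = best_f)
}
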