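# Run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

# Draw diploid dosage genotypes for one deme given per-locus allele
# frequencies: binomial(2, p) per individual per locus.
draw_genotypes <- function(freqs, n_ind) {
  matrix(stats::rbinom(n_ind * length(freqs), 2L, rep(freqs, each = n_ind)),
         nrow = n_ind)
}

#' Simulate one Hardy-Weinberg population
#'
#' Independent biallelic SNP genotypes for a single random-mating
#' population: per-locus allele frequencies are drawn (by default uniformly
#' on (0.05, 0.95)) and each individual's dosage is binomial(2, p). The
#' workhorse fixture for the T1 expectation E(T1) = 2/3 for unrelated pairs.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_snps number of independent SNPs.
#' @param freqs optional per-locus allele frequencies in (0, 1) (length
#'   `n_snps`); default `runif(n_snps, 0.05, 0.95)`.
#' @param seed optional integer seed.
#' @return a [genotype_matrix()].
#' @export
simulate_hwe_population <- function(n_individuals, n_snps, freqs = NULL,
                                    seed = NULL) {
  with_seed(seed, {
    if (is.null(freqs)) freqs <- stats::runif(n_snps, 0.05, 0.95)
    if (any(freqs <= 0 | freqs >= 1)) stop("frequencies must lie in (0, 1)")
    genotype_matrix(draw_genotypes(freqs, n_individuals))
  })
}

#' Mendelian offspring of two parents
#'
#' One gamete is drawn from each parent (an allele transmitted with
#' probability dosage/2); the offspring dosage is their sum. At a biallelic
#' locus a parent and its offspring can never be homozygous for opposite
#' alleles (absent mutation), which is what pushes T1 above 2/3 for
#' parent-offspring pairs.
#'
#' @param parent_a,parent_b genotype vectors (0/1/2) of equal length.
#' @param seed optional integer seed.
#' @return offspring genotype vector.
#' @export
mendelian_offspring <- function(parent_a, parent_b, seed = NULL) {
  if (length(parent_a) != length(parent_b))
    stop("parents must have the same loci")
  with_seed(seed, {
    stats::rbinom(length(parent_a), 1L, parent_a / 2) +
      stats::rbinom(length(parent_b), 1L, parent_b / 2)
  })
}

#' Simulate demes diverged under the Balding-Nichols model
#'
#' Per locus, an ancestral frequency p is drawn uniformly on (0.05, 0.95)
#' and each deme's frequency from Beta(p (1-F)/F, (1-p)(1-F)/F), so that
#' demes are at differentiation F (an FST-like parameter) from the
#' ancestor; genotypes are then Hardy-Weinberg within demes.
#'
#' @param n_per_deme individuals per deme.
#' @param n_snps number of SNPs.
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param n_demes number of demes.
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] with a `"labels"` attribute of deme names.
#' @export
simulate_balding_nichols <- function(n_per_deme, n_snps, fst, n_demes = 2L,
                                     seed = NULL) {
  stopifnot(fst > 0, fst < 1)
  with_seed(seed, {
    p_anc <- stats::runif(n_snps, 0.05, 0.95)
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    blocks <- lapply(seq_len(n_demes), function(d) {
      p_d <- stats::rbeta(n_snps, a, b)
      draw_genotypes(p_d, n_per_deme)
    })
    G <- genotype_matrix(do.call(rbind, blocks))
    attr(G, "labels") <- rep(paste0("deme", seq_len(n_demes)),
                             each = n_per_deme)
    G
  })
}

#' Configuration for the additive graph toy model
#'
#' The toy model places three parental populations around a central group
#' vertex and one admixed population attached (half-and-half by default) to
#' two of the parental populations; each population holds `n_per_pop`
#' individuals whose edge to the population vertex is drawn from U(0.5, 1).
#' Pairwise distances are path sums through the graph plus Gaussian noise.
#' The three binary regime switches reproduce the eight simulated
#' scenarios: individual distances constant or not, group-edge lengths
#' constant or not, and group edges larger (U(m, 1)) or smaller (U(0, m))
#' than the minimum individual distance m.
#'
#' @param n_per_pop individuals per population.
#' @param individual_constant all individuals share one edge length?
#' @param group_constant all group edges share one length?
#' @param group_larger group edges drawn above (`TRUE`) or below (`FALSE`)
#'   the minimum individual edge length.
#' @param noise_sd standard deviation of the additive noise per pair.
#' @param admix_weights mixing weights of the admixed population towards
#'   parental populations 1 and 2.
#' @param n_replicates replicates per call of [simulate_graph_model()].
#' @param seed integer seed.
#' @return list of class `"graph_model_config"`.
#' @export
graph_model_config <- function(n_per_pop = 10L, individual_constant = FALSE,
                               group_constant = FALSE, group_larger = TRUE,
                               noise_sd = 0.05, admix_weights = c(0.5, 0.5),
                               n_replicates = 1L, seed = 1L) {
  stopifnot(noise_sd >= 0, n_per_pop >= 2L,
            length(admix_weights) == 2L, abs(sum(admix_weights) - 1) < 1e-9)
  structure(list(n_per_pop = as.integer(n_per_pop),
                 individual_constant = individual_constant,
                 group_constant = group_constant,
                 group_larger = group_larger,
                 noise_sd = noise_sd, admix_weights = admix_weights,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "graph_model_config")
}

#' Simulate distance matrices under the additive graph toy model
#'
#' Generates `n_replicates` true distance matrices with known population
#' labels under the configuration of [graph_model_config()]: four
#' populations (three parental, one admixed), path-additive distances, and
#' N(0, noise_sd) error per pair.
#'
#' @param config a [graph_model_config()].
#' @return list of replicates, each a list with `D` (a [dissim_matrix()])
#'   and `labels`.
#' @export
simulate_graph_model <- function(config) {
  stopifnot(inherits(config, "graph_model_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_replicates), function(r)
      graph_model_replicate(config))
  })
}

graph_model_replicate <- function(cfg) {
  npp <- cfg$n_per_pop
  n <- 4L * npp
  pop <- rep(1:4, each = npp)
  # individual -> population-vertex edges
  a <- if (cfg$individual_constant) rep(stats::runif(1, 0.5, 1), n)
       else stats::runif(n, 0.5, 1)
  m_ind <- min(a)
  draw_edge <- function(k) {
    if (cfg$group_larger) stats::runif(k, m_ind, 1) else stats::runif(k, 0, m_ind)
  }
  h <- if (cfg$group_constant) rep(draw_edge(1L), 3L) else draw_edge(3L)
  # population-level distances through the central group vertex
  P <- matrix(0, 4, 4)
  for (x in 1:3) for (y in 1:3) if (x != y) P[x, y] <- h[x] + h[y]
  w <- cfg$admix_weights
  for (y in 1:3) {
    P[4, y] <- w[1] * P[1, y] + w[2] * P[2, y]
    P[y, 4] <- P[4, y]
  }
  D <- outer(a, a, "+") + P[cbind(rep(pop, n), rep(pop, each = n))]
  if (cfg$noise_sd > 0) {
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- stats::rnorm(n * (n - 1) / 2, 0, cfg$noise_sd)
    D <- D + eps + t(eps)
  }
  diag(D) <- 0
  list(D = dissim_matrix(D, samples = paste0("S", seq_len(n))),
       labels = paste0("P", pop))
}

#' Configuration for the demographic simulators
#'
#' Shared parameter container for the 2-D stepping-stone and
#' sequential-split genotype simulators. Both draw per-locus ancestral
#' frequencies uniformly on (0.05, 0.95) and evolve deme allele frequencies
#' forward in time with binomial Wright-Fisher drift (the frequency-model
#' backend; SNPs are independent, as if one SNP were sampled per
#' recombinationally independent fragment). Differentiation grows as the
#' migration fraction `m` shrinks (stepping stone) or the split interval
#' `t` grows (sequential split).
#'
#' @param model `"stepping_stone_2d"` or `"sequential_split"`.
#' @param n_pops number of demes (must be a perfect square for the grid
#'   model; 25 by default).
#' @param diploids_per_pop sampled individuals per deme.
#' @param n_snps number of independent SNPs.
#' @param migration_fraction m, per-generation fraction of each deme
#'   exchanged with its grid neighbours (stepping stone).
#' @param split_interval t, generations between successive splits
#'   (sequential split).
#' @param ne diploid effective size per deme. Default (`NULL`) resolves to
#'   100 for the stepping stone and 500 for the sequential split, whose
#'   founder chain accumulates drift across all 24 splits. In the
#'   sequential-split model the s-th new deme is founded at `ne/s`, floored
#'   at `ne/10`, so late founders drift strongly without fixing every
#'   locus.
#' @param generations forward generations simulated (stepping stone).
#' @param seed integer seed.
#' @return list of class `"demographic_config"`.
#' @export
demographic_config <- function(model = c("stepping_stone_2d", "sequential_split"),
                               n_pops = 25L, diploids_per_pop = 10L,
                               n_snps = 5000L, migration_fraction = 0.05,
                               split_interval = 20L, ne = NULL,
                               generations = 200L, seed = 1L) {
  model <- match.arg(model)
  if (is.null(ne)) ne <- if (model == "sequential_split") 500L else 100L
  stopifnot(n_snps >= 1L, diploids_per_pop >= 1L, ne >= 2L)
  if (model == "stepping_stone_2d") {
    side <- sqrt(n_pops)
    if (side != floor(side))
      stop("stepping-stone model needs a square number of demes")
    stopifnot(migration_fraction >= 0, migration_fraction <= 1)
  } else {
    if (split_interval <= 0) stop("split interval t must be positive")
  }
  structure(list(model = model, n_pops = as.integer(n_pops),
                 diploids_per_pop = as.integer(diploids_per_pop),
                 n_snps = as.integer(n_snps),
                 migration_fraction = migration_fraction,
                 split_interval = as.integer(split_interval),
                 ne = as.integer(ne), generations = as.integer(generations),
                 seed = as.integer(seed)),
            class = "demographic_config")
}

grid_adjacency <- function(side) {
  n <- side * side
  A <- matrix(0, n, n)
  for (r in seq_len(side)) for (c in seq_len(side)) {
    i <- (r - 1L) * side + c
    if (r > 1L) A[i, i - side] <- 1
    if (r < side) A[i, i + side] <- 1
    if (c > 1L) A[i, i - 1L] <- 1
    if (c < side) A[i, i + 1L] <- 1
  }
  A
}

sample_deme_genotypes <- function(freq_mat, n_ind, deme_names) {
  blocks <- lapply(seq_len(nrow(freq_mat)), function(d)
    draw_genotypes(freq_mat[d, ], n_ind))
  G <- genotype_matrix(do.call(rbind, blocks))
  attr(G, "labels") <- rep(deme_names, each = n_ind)
  G
}

#' Simulate genotypes under a 2-D stepping-stone model
#'
#' Demes sit on a square grid; each generation a fraction m of every deme is
#' replaced by an even mixture of its rook neighbours, then allele
#' frequencies drift by binomial sampling of 2*ne gametes. After
#' `generations` generations, `diploids_per_pop` individuals are sampled
#' from each deme under within-deme Hardy-Weinberg proportions.
#'
#' @param config a [demographic_config()] with model `"stepping_stone_2d"`.
#' @return a [genotype_matrix()] with attributes `"labels"` (deme of
#'   sampling) and `"backend"` (`"wright_fisher_frequency"`).
#' @export
simulate_stepping_stone <- function(config) {
  stopifnot(inherits(config, "demographic_config"),
            config$model == "stepping_stone_2d")
  with_seed(config$seed, {
    n_pops <- config$n_pops
    side <- as.integer(sqrt(n_pops))
    A <- grid_adjacency(side)
    W <- A / rowSums(A)
    m <- config$migration_fraction
    two_ne <- 2L * config$ne
    M <- config$n_snps
    P <- matrix(stats::runif(M, 0.05, 0.95), n_pops, M, byrow = TRUE)
    for (g in seq_len(config$generations)) {
      Pm <- (1 - m) * P + m * (W %*% P)
      P <- matrix(stats::rbinom(n_pops * M, two_ne, Pm), n_pops, M) / two_ne
    }
    G <- sample_deme_genotypes(P, config$diploids_per_pop,
                               paste0("deme", seq_len(n_pops)))
    attr(G, "backend") <- "wright_fisher_frequency"
    attr(G, "config") <- config
    G
  })
}

#' Simulate genotypes under a sequential-split (serial founder) model
#'
#' A single founder deme evolves under drift; every `split_interval`
#' generations the youngest deme splits in two, the new deme taking
#' effective size `ne / s` after the s-th split (the serial founder
#' effect). After the last split, one further interval elapses, then
#' individuals are sampled per deme. No migration between demes.
#'
#' @param config a [demographic_config()] with model `"sequential_split"`.
#' @return a [genotype_matrix()] with attributes `"labels"` and
#'   `"backend"`.
#' @export
simulate_sequential_split <- function(config) {
  stopifnot(inherits(config, "demographic_config"),
            config$model == "sequential_split")
  with_seed(config$seed, {
    M <- config$n_snps
    t_int <- config$split_interval
    n_pops <- config$n_pops
    freqs <- list(stats::runif(M, 0.05, 0.95))
    ne <- c(config$ne)
    drift <- function() {
      for (d in seq_along(freqs)) {
        two_ne <- 2L * ne[d]
        freqs[[d]] <<- stats::rbinom(M, two_ne, freqs[[d]]) / two_ne
      }
    }
    for (s in seq_len(n_pops - 1L)) {
      for (g in seq_len(t_int)) drift()
      young <- length(freqs)
      freqs[[young + 1L]] <- freqs[[young]]
      # serial founder effect: size shrinks with the split count, floored at
      # ne/10 so late demes drift strongly but do not fix outright
      ne <- c(ne, max(as.integer(ceiling(config$ne / 10)), 2L,
                      as.integer(round(config$ne / s))))
    }
    for (g in seq_len(t_int)) drift()
    P <- do.call(rbind, freqs)
    G <- sample_deme_genotypes(P, config$diploids_per_pop,
                               paste0("deme", seq_len(n_pops)))
    attr(G, "backend") <- "wright_fisher_frequency"
    attr(G, "config") <- config
    G
  })
}
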