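test_that("simulators are deterministic under a fixed seed", {
  a <- simulate_hwe_population(5, 50, seed = 1)
  b <- simulate_hwe_population(5, 50, seed = 1)
  expect_identical(unclass(a), unclass(b))

  cfg <- graph_model_config(n_replicates = 2, seed = 2)
  expect_identical(simulate_graph_model(cfg), simulate_graph_model(cfg))

  sc <- demographic_config("stepping_stone_2d", n_pops = 9, n_snps = 100,
                           generations = 20, seed = 3)
  expect_identical(unclass(simulate_stepping_stone(sc)),
                   unclass(simulate_stepping_stone(sc)))

  qc <- demographic_config("sequential_split", n_pops = 4, n_snps = 100,
                           split_interval = 3, seed = 4)
  expect_identical(unclass(simulate_sequential_split(qc)),
                   unclass(simulate_sequential_split(qc)))
})

test_that("HWE simulation has the expected heterozygote fraction", {
  G <- simulate_hwe_population(40, 2000, freqs = rep(0.5, 2000), seed = 5)
  expect_equal(mean(G == 1L), 0.5, tolerance = 0.01)
})

test_that("Mendelian offspring have no opposite homozygotes with a parent", {
  set.seed(6)
  for (r in 1:10) {
    p1 <- as.integer(simulate_hwe_population(1, 500)[1, ])
    p2 <- as.integer(simulate_hwe_population(1, 500)[1, ])
    child <- mendelian_offspring(p1, p2)
    expect_true(all(child %in% 0:2))
    expect_equal(pattern_counts(p1, child)$n_opp_hom, 0L)
  }
})

test_that("graph-model distances are path sums plus noise", {
  # all individual edges equal a, all group edges equal h, no noise:
  # within-pair D = 2a, parental cross-pair D = 2a + 2h
  cfg <- graph_model_config(individual_constant = TRUE, group_constant = TRUE,
                            group_larger = TRUE, noise_sd = 0, seed = 7)
  rep1 <- simulate_graph_model(cfg)[[1]]
  D <- unclass(rep1$D)
  lab <- rep1$labels
  within <- D[lab == "P1", lab == "P1"]
  within <- within[upper.tri(within)]
  expect_equal(max(within) - min(within), 0, tolerance = 1e-12)
  a2 <- within[1]                       # 2a
  cross12 <- D[lab == "P1", lab == "P2"]
  expect_equal(max(cross12) - min(cross12), 0, tolerance = 1e-12)
  g12 <- cross12[1] - a2                # 2h
  expect_gt(g12, 0)
  # same group edge for all parental pairs under the constant regime
  cross13 <- D[lab == "P1", lab == "P3"]
  expect_equal(cross13[1] - a2, g12, tolerance = 1e-12)
  # admixed population sits midway between its two parents
  cross4 <- D[lab == "P1", lab == "P4"]
  expect_equal(cross4[1] - a2, g12 / 2, tolerance = 1e-12)
})

test_that("noise-free graph replicates make V match the additive theory", {
  cfg <- graph_model_config(noise_sd = 0, n_replicates = 3, seed = 8)
  for (rep1 in simulate_graph_model(cfg)) {
    V <- v_matrix(rep1$D)
    lab <- rep1$labels
    for (p in unique(lab)) {
      w <- V[lab == p, lab == p]
      expect_lt(max(abs(w)), 1e-10)  # within-population V collapses to 0
    }
  }
})

test_that("all eight graph regimes produce valid replicates", {
  for (ic in c(TRUE, FALSE)) for (gc in c(TRUE, FALSE)) for (gl in c(TRUE, FALSE)) {
    cfg <- graph_model_config(individual_constant = ic, group_constant = gc,
                              group_larger = gl, n_replicates = 1,
                              seed = 9)
    rep1 <- simulate_graph_model(cfg)[[1]]
    expect_s3_class(rep1$D, "dissim_matrix")
    expect_equal(length(rep1$labels), 40L)
  }
})

test_that("stepping-stone differentiation increases as migration decreases", {
  ratios <- sapply(c(0.5, 0.02, 0.001), function(m) {
    cfg <- demographic_config("stepping_stone_2d", n_pops = 9,
                              diploids_per_pop = 6, n_snps = 1500,
                              migration_fraction = m, generations = 100,
                              seed = 50)
    G <- simulate_stepping_stone(cfg)
    amova_report(distance_matrix(G), attr(G, "labels"))$ratio_among
  })
  expect_true(all(diff(ratios) > 0))
  # near-panmixia sits close to the permuted-label baseline
  cfg <- demographic_config("stepping_stone_2d", n_pops = 9,
                            diploids_per_pop = 6, n_snps = 1500,
                            migration_fraction = 0.5, generations = 100,
                            seed = 51)
  G <- simulate_stepping_stone(cfg)
  D <- distance_matrix(G)
  lab <- attr(G, "labels")
  obs <- amova_report(D, lab)$ratio_among
  set.seed(52)
  perm <- replicate(20, amova_report(D, sample(lab))$ratio_among)
  expect_lt(obs, mean(perm) + 4 * sd(perm) + 0.02)
})

test_that("sequential-split differentiation increases with the split interval", {
  ratios <- sapply(c(1, 4, 16), function(t) {
    cfg <- demographic_config("sequential_split", n_pops = 8,
                              diploids_per_pop = 6, n_snps = 1500,
                              split_interval = t, seed = 60)
    G <- simulate_sequential_split(cfg)
    amova_report(distance_matrix(G), attr(G, "labels"))$ratio_among
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("simulator configs validate their inputs", {
  expect_error(demographic_config("stepping_stone_2d", n_pops = 7), "square")
  expect_error(demographic_config("sequential_split", split_interval = 0),
               "positive")
  expect_error(simulate_hwe_population(5, 10, freqs = rep(1.2, 10)), "0, 1")
  expect_error(graph_model_config(noise_sd = -1))
})

test_that("Balding-Nichols demes are more diverged at higher FST", {
  G1 <- simulate_balding_nichols(10, 2000, fst = 0.02, seed = 70)
  G2 <- simulate_balding_nichols(10, 2000, fst = 0.3, seed = 70)
  r1 <- amova_report(distance_matrix(G1), attr(G1, "labels"))$ratio_among
  r2 <- amova_report(distance_matrix(G2), attr(G2, "labels"))$ratio_among
  expect_gt(r2, r1)
})
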