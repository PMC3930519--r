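test_that("BOM percentage on constructed matrices", {
  # block-diagonal: within << between -> 100%
  m <- matrix(1, 6, 6)
  m[1:3, 1:3] <- 0.1; m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  labels <- rep(c("a", "b"), each = 3)
  expect_equal(bom_percentage(m, labels)$percentage, 100)

  # every nearest neighbour cross-population -> 0%
  m2 <- matrix(1, 4, 4)
  m2[1, 3] <- m2[3, 1] <- 0.1
  m2[2, 4] <- m2[4, 2] <- 0.1
  diag(m2) <- 0
  expect_equal(bom_percentage(m2, c("a", "a", "b", "b"))$percentage, 0)

  # 6 samples, 4 same-population nearest neighbours -> 66.67%
  m3 <- matrix(10, 6, 6)
  pairs <- list(c(1, 2), c(3, 4), c(5, 2), c(6, 1))  # bom of 5 and 6 cross
  vals <- c(1, 2, 3, 4)
  for (k in seq_along(pairs))
    m3[pairs[[k]][1], pairs[[k]][2]] <- m3[pairs[[k]][2], pairs[[k]][1]] <- vals[k]
  diag(m3) <- 0
  lab3 <- c("p", "p", "q", "q", "r", "r")
  # hand check: 1<->2 same pop (hits for 1 and 2), 3<->4 same (hits), 5->2, 6->1 miss
  res <- bom_percentage(m3, lab3)
  expect_equal(res$percentage, 100 * 4 / 6, tolerance = 1e-9)
  expect_identical(res$bom_index[1:4], c(2L, 1L, 4L, 3L))
})

test_that("BOM is invariant under strictly increasing transforms and ties are logged", {
  set.seed(23)
  m <- random_sym_matrix(10)
  labels <- rep(c("x", "y"), 5)
  base <- bom_percentage(m, labels)
  for (f in list(function(z) z^2, function(z) log1p(z), function(z) 5 * z + 2)) {
    mt <- f(m); diag(mt) <- 0
    expect_equal(bom_percentage(mt, labels)$percentage, base$percentage)
  }
  tie <- matrix(1, 3, 3); diag(tie) <- 0
  res <- bom_percentage(tie, c("a", "a", "b"))
  expect_equal(res$n_ties, 3L)
  expect_identical(res$bom_index[3], 1L)  # smallest index wins
})

test_that("Cramer's V spans its range and matches the hand-computed table", {
  pops <- rep(c("a", "b"), each = 40)
  expect_equal(cramers_v(pops, pops), 1)
  expect_equal(cramers_v(rep(1, 80), pops), 0)
  # contingency [[30,10],[10,30]]: chi2 = 20, N = 80, V = 0.5
  clusters <- c(rep(1, 30), rep(2, 10), rep(1, 10), rep(2, 30))
  expect_equal(cramers_v(clusters, pops), 0.5)
  # invariant to relabelling
  relab <- c("z", "w")[clusters]
  expect_equal(cramers_v(relab, rev(pops)), 0.5)
})

test_that("informativeness attains its bounds and the worked value", {
  expect_equal(informativeness_in(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(informativeness_in(c(1, 0), c(0, 1)), log(2))
  expect_equal(informativeness_in(c(1, 0), c(0.5, 0.5)),
               0.75 * log(4 / 3))  # direct evaluation of the formula
  expect_equal(informativeness_in(c(1, 0), c(0.5, 0.5)), 0.2157616, tolerance = 1e-6)
})

test_that("informativeness is symmetric and bounded on random frequency pairs", {
  set.seed(24)
  for (r in 1:50) {
    k <- sample(2:6, 1)
    ps <- as.vector(stats::rmultinom(1, 40, runif(k))) / 40
    pt <- as.vector(stats::rmultinom(1, 40, runif(k))) / 40
    a <- informativeness_in(ps, pt)
    expect_equal(a, informativeness_in(pt, ps))
    expect_gte(a, -1e-12)
    expect_lte(a, log(2) + 1e-12)
  }
})

test_that("per-population minimum informativeness", {
  # population a has a private cluster; b and c share one cluster
  clusters <- c(rep("c1", 4), rep("c2", 4), rep("c2", 4))
  pops <- rep(c("a", "b", "c"), each = 4)
  res <- min_in_per_population(clusters, pops)
  expect_equal(unname(res$min_in["a"]), log(2))
  expect_equal(unname(res$min_in["b"]), 0)  # identical to c
  expect_equal(unname(res$min_in["c"]), 0)
  expect_equal(res$mean_min_in, mean(c(log(2), 0, 0)))
  expect_error(min_in_per_population(clusters, rep("one", 12)), "two populations")
})

test_that("per-population minima equal an independent pairwise loop", {
  set.seed(25)
  clusters <- sample(paste0("c", 1:4), 60, replace = TRUE)
  pops <- rep(paste0("p", 1:3), each = 20)
  res <- min_in_per_population(clusters, pops)
  freq <- prop.table(table(pops, clusters), 1)
  for (s in rownames(freq)) {
    vals <- c()
    for (t in setdiff(rownames(freq), s))
      vals <- c(vals, informativeness_in(freq[s, ], freq[t, ]))
    expect_equal(unname(res$min_in[s]), min(vals))
  }
})
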