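test_that("tree construction: branch counts, shapes, power-of-2 guard", {
  bal <- build_tree(8, balanced = TRUE)
  cat8 <- build_tree(8, balanced = FALSE)
  for (tr in list(bal, cat8)) {
    expect_equal(nrow(tr$edge), 14L)                 # 2n - 2
    expect_equal(sum(tr$edge[, 2] <= 8), 8L)         # external branches
  }
  # pectinate shape: deepest tip sits below 6 internal nodes
  depth <- function(tree, node) {
    d <- 0L
    while (node != 9L) {                              # root id = n_tip + 1
      node <- tree$edge[tree$edge[, 2] == node, 1]
      d <- d + 1L
    }
    d
  }
  expect_equal(max(vapply(1:8, function(i) depth(cat8, i), integer(1))), 7L)
  expect_equal(max(vapply(1:8, function(i) depth(bal, i), integer(1))), 3L)
  expect_error(build_tree(6, balanced = TRUE))
})

test_that("branch lengths meet the mean and stemminess targets exactly", {
  tr <- assign_branch_lengths(build_tree(8, TRUE), mean_bl = 0.25, stemminess = 0.5)
  expect_equal(sum(tr$edge.length), 3.5)
  ext <- tr$edge[, 2] <= 8
  expect_equal(sum(tr$edge.length[!ext]), 1.75)
  expect_equal(sum(tr$edge.length[ext]), 1.75)

  tr9 <- assign_branch_lengths(build_tree(16, TRUE), 0.1, 0.9)
  expect_equal(sum(tr9$edge.length[tr9$edge[, 2] > 16]) / sum(tr9$edge.length), 0.9)
  expect_equal(stemminess_of_tree(tr9), 0.9, tolerance = 1e-12)
  expect_equal(mean(tr9$edge.length), 0.1, tolerance = 1e-12)
})

test_that("sampled GTR models are valid, reproducible, Dirichlet-centred", {
  m1 <- sample_gtr_model(seed = 99)
  m2 <- sample_gtr_model(seed = 99)
  expect_identical(m1, m2)
  expect_true(all(m1$exchangeabilities > 0))
  expect_equal(sum(m1$exchangeabilities), 1)
  expect_equal(m1$gamma_shape, 1)

  set.seed(12)
  draws <- t(replicate(10000, sample_gtr_model()$exchangeabilities))
  expect_true(all(abs(colMeans(draws) - 1 / 6) < 0.005))
})

test_that("rate matrices have unit mean rate and correct stationarity", {
  m <- sample_gtr_model(seed = 4, base_freqs = c(0.4, 0.3, 0.2, 0.1))
  Q <- entsat:::model_Q(m)
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(m$base_freqs * diag(Q)), 1, tolerance = 1e-12)
  expect_equal(drop(m$base_freqs %*% Q), rep(0, 4), tolerance = 1e-12)
})

test_that("evolution limits: zero branches, invariant sites, JC expectation", {
  tr <- build_tree(8, TRUE)
  tr$edge.length <- rep(0, 14)
  a <- evolve_sequences(tr, 50, jc_model(), seed = 2)
  expect_true(all(a$states == rep(a$states[1, ], each = 8)))

  tr$edge.length <- rep(0.4, 14)
  a2 <- evolve_sequences(tr, 200, gtr_model(rep(1, 6), gamma_shape = 1,
                                            p_invariant = 1), seed = 2)
  expect_true(all(apply(a2$states, 2, function(x) length(unique(x)) == 1L)))

  two <- ape::read.tree(text = "(a:0.05,b:0.05);")
  a3 <- evolve_sequences(two, 1e5, jc_model(), seed = 5)
  p_hat <- mean(a3$states[1, ] != a3$states[2, ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e5))
})

test_that("GTR with equal exchangeabilities and uniform freqs matches JC", {
  two <- ape::read.tree(text = "(a:0.1,b:0.1);")
  g <- gtr_model(rep(1, 6), gamma_shape = NULL)
  a <- evolve_sequences(two, 4e4, g, seed = 8)
  p_hat <- mean(a$states[1, ] != a$states[2, ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  expect_lt(abs(p_hat - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / 4e4))
})

test_that("simulate_dataset is deterministic, shaped, and stationary", {
  cfg <- sim_config(8, 250, 0.3, 0.5, model = jc_model(), seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$aln$states, s2$aln$states)
  expect_identical(s1$tree$edge, s2$tree$edge)
  expect_equal(s1$aln$n_taxa, 8L)
  expect_equal(s1$aln$n_sites, 250L)

  big <- simulate_dataset(sim_config(16, 2000, 0.3, 0.5, model = jc_model(),
                                     seed = 13))
  p <- base_frequencies(big$aln)$p
  expect_true(all(abs(p - 0.25) < 0.02))
})

test_that("deep saturation gives multinomial-like site patterns", {
  # at mean branch length 5 every column should look like an iid draw;
  # chi-square test of the per-column A-count histogram against Binomial(8, pA)
  reject <- 0L
  runs <- 60L
  for (i in seq_len(runs)) {
    sim <- simulate_dataset(sim_config(8, 500, 5, 0.5, model = jc_model(),
                                       seed = 4000 + i))
    pA <- base_frequencies(sim$aln)$p[1]
    ka <- colSums(sim$aln$states == 1L)
    obs <- tabulate(ka + 1L, nbins = 9L)
    expc <- stats::dbinom(0:8, 8, pA) * 500
    # pool sparse bins from the right so expected counts stay above 5
    while (length(expc) > 2L && expc[length(expc)] < 5) {
      k <- length(expc)
      expc[k - 1L] <- expc[k - 1L] + expc[k]
      obs[k - 1L] <- obs[k - 1L] + obs[k]
      expc <- expc[-k]; obs <- obs[-k]
    }
    X2 <- sum((obs - expc)^2 / expc)
    if (X2 > stats::qchisq(0.99, df = length(expc) - 1L)) reject <- reject + 1L
  }
  expect_lte(reject, ceiling(0.05 * runs))
})
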