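test_that("gradient experiment is reproducible and honours its ranges", {
  rg <- list(mean_bl = c(0.1, 0.3), stemminess = c(0.4, 0.6),
             seq_len = c(150, 250), p_const = c(0, 0.2))
  r1 <- run_gradient_experiment(10, taxa_choices = c(8L, 16L), ranges = rg, seed = 6)
  r2 <- run_gradient_experiment(10, taxa_choices = c(8L, 16L), ranges = rg, seed = 6)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10L)
  expect_true(all(r1$mean_bl >= 0.1 & r1$mean_bl <= 0.3))
  expect_true(all(r1$seq_len >= 150 & r1$seq_len <= 250))

  deg <- list(mean_bl = c(0.2, 0.2), stemminess = c(0.5, 0.5),
              seq_len = c(200, 200), p_const = c(0, 0))
  rd <- run_gradient_experiment(6, taxa_choices = 8L, ranges = deg, seed = 6)
  expect_equal(unique(rd$mean_bl), 0.2)
  expect_equal(unique(rd$seq_len), 200)
  expect_equal(unique(rd$n_taxa), 8L)
})

test_that("records are exactly reproducible from their stored seeds", {
  rg <- list(mean_bl = c(0.1, 0.5), stemminess = c(0.2, 0.8),
             seq_len = c(150, 300), p_const = c(0, 0.3))
  rec <- run_gradient_experiment(5, taxa_choices = 8L, ranges = rg, seed = 30)
  i <- 3L
  redo <- entsat:::rec_one(rec$n_taxa[i], rec$seq_len[i], rec$mean_bl[i],
                           rec$stemminess[i], rec$balanced[i], rec$model[i],
                           rec$p_invariant[i], rec$seed[i])
  expect_equal(redo$t_inf, rec$t_inf[i])
  expect_equal(redo$rf_norm, rec$rf_norm[i])
  expect_equal(redo$tl_error, rec$tl_error[i])
})

test_that("ROC: separation, monotone vectors, degenerate inputs", {
  set.seed(41)
  pos <- c(rep(TRUE, 60), rep(FALSE, 40))
  sep <- synth_records(100, stat = ifelse(pos, stats::runif(100, 0, 1),
                                          stats::runif(100, 2, 3)), positive = pos)
  roc <- compute_roc(sep, "t_inf", "topology")
  expect_equal(max(roc$tpr - roc$fpr), 1)
  expect_false(is.unsorted(roc$tpr))
  expect_false(is.unsorted(roc$fpr))
  expect_false(is.unsorted(roc$thresholds))

  shuffled <- synth_records(1000, stat = stats::rnorm(1000),
                            positive = sample(c(TRUE, FALSE), 1000, TRUE))
  roc2 <- compute_roc(shuffled, "t_inf", "topology")
  expect_lt(max(roc2$tpr - roc2$fpr), 0.15)  # permutation-baseline noise

  allpos <- synth_records(10, stat = stats::rnorm(10), positive = rep(TRUE, 10))
  expect_error(compute_roc(allpos, "t_inf", "topology"))
})

test_that("tree-length positives use the 50 percent rule", {
  rec <- synth_records(6, stat = 1:6, positive = rep(FALSE, 6))
  rec$tl_error <- c(-0.6, -0.5, -0.2, 0, 0.49, 0.5)
  roc <- compute_roc(rec, "t_inf", "tree_length")
  expect_equal(roc$n_pos, 3L)  # -0.6, -0.5, +0.5
  expect_equal(roc$n_neg, 3L)
})

test_that("select_tcrit equals an exhaustive scan with conservative ties", {
  set.seed(43)
  stat <- stats::rnorm(300)
  pos <- stats::runif(300) < stats::plogis(-stat)   # lower stat -> more positive
  rec <- synth_records(300, stat = stat, positive = pos)
  roc <- compute_roc(rec, "t_inf", "topology")
  brute <- sapply(sort(unique(stat)), function(th)
    sum(stat < th & pos) - sum(stat < th & !pos))
  expect_equal(select_tcrit(roc), sort(unique(stat))[which.max(brute)])

  # duplicated statistic values: which.max takes the first (smallest) optimum
  rec2 <- synth_records(6, stat = c(0, 0, 1, 1, 2, 2),
                        positive = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  roc2 <- compute_roc(rec2, "t_inf", "topology")
  diffs <- roc2$tp - roc2$fp
  expect_equal(select_tcrit(roc2), roc2$thresholds[which.max(diffs)])
  expect_equal(select_tcrit(roc2), min(roc2$thresholds[diffs == max(diffs)]))
})

test_that("critical-value regression: exact recovery and the adjusted R2 formula", {
  pb <- expand.grid(n_taxa = c(8, 32, 128), len_mid = c(375, 625, 875, 1125))
  pb$chosen_tcrit <- 2 + 3 * sqrt(pb$n_taxa) - 0.5 * sqrt(pb$len_mid)
  pb$tpr <- 0.8; pb$fpr <- 0.1; pb$n <- 100
  # lm warns about the residual-free exact fit; the recovery itself is the point
  fit <- suppressWarnings(fit_crit_model(pb))
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(fit$coef_sqrt_taxa, 3, tolerance = 1e-9)
  expect_equal(fit$coef_sqrt_len, -0.5, tolerance = 1e-9)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)

  set.seed(47)
  pb$chosen_tcrit <- pb$chosen_tcrit + stats::rnorm(nrow(pb), 0, 2)
  fit2 <- fit_crit_model(pb)
  pred <- fit2$intercept + fit2$coef_sqrt_taxa * sqrt(pb$n_taxa) +
    fit2$coef_sqrt_len * sqrt(pb$len_mid)
  r2 <- 1 - sum((pb$chosen_tcrit - pred)^2) /
    sum((pb$chosen_tcrit - mean(pb$chosen_tcrit))^2)
  n <- nrow(pb)
  expect_equal(fit2$adjusted_r2, 1 - (1 - r2) * (n - 1) / (n - 2 - 1),
               tolerance = 1e-10)

  expect_error(fit_crit_model(pb[pb$n_taxa == 8 & pb$len_mid < 700, ]))
})

test_that("predict_tcrit: nearest-bin rates, extrapolation flag, monotone surface", {
  crit <- default_crit_model()
  b <- crit$bins[7, ]
  pr <- predict_tcrit(crit, b$n_taxa, b$len_mid)
  expect_equal(pr$expected_tpr, b$tpr)
  expect_equal(pr$expected_fpr, b$fpr)
  expect_false(pr$extrapolation)
  expect_true(predict_tcrit(crit, 2048, 500)$extrapolation)
  expect_true(predict_tcrit(crit, 32, 5000)$extrapolation)

  lens <- seq(300, 1200, by = 100)
  preds <- vapply(lens, function(l) predict_tcrit(crit, 32, l)$t_crit, numeric(1))
  expect_true(all(diff(preds) > 0) || all(diff(preds) < 0))  # linear in sqrt(len)
})

test_that("critical-value model round-trips through its text serialization", {
  crit <- default_crit_model()
  f <- withr::local_tempfile(fileext = ".txt")
  write_crit_model(crit, f)
  back <- read_crit_model(f)
  expect_equal(back$intercept, crit$intercept)
  expect_equal(back$coef_sqrt_taxa, crit$coef_sqrt_taxa)
  expect_equal(back$coef_sqrt_len, crit$coef_sqrt_len)
  expect_equal(back$bins$chosen_tcrit, crit$bins$chosen_tcrit)
  expect_equal(back$calibration_range, crit$calibration_range)
})

test_that("factorial experiment crosses levels with models and shapes", {
  lev <- list(n_taxa = 8L, seq_len = c(120L, 240L), mean_bl = c(0.1, 0.5),
              stemminess = 0.5, p_invariant = 0)
  rec <- factorial_experiment(lev, reps_per_cell = 2L, seed = 9)
  expect_equal(nrow(rec), 2 * 2 * 2 * 2 * 2)   # len x bl x model x shape x reps
  expect_setequal(unique(rec$model), c("JC", "GTRG"))
  expect_setequal(unique(rec$balanced), c(TRUE, FALSE))
  rec2 <- factorial_experiment(lev, reps_per_cell = 2L, seed = 9)
  expect_identical(rec, rec2)
})

test_that("saturated, low-stemminess, imbalanced scenarios yield more topology positives", {
  rg_hard <- list(mean_bl = c(0.65, 0.65), stemminess = c(0.1, 0.1),
                  seq_len = c(500, 500), p_const = c(0, 0))
  rg_easy <- list(mean_bl = c(0.05, 0.05), stemminess = c(0.9, 0.9),
                  seq_len = c(500, 500), p_const = c(0, 0))
  hard <- run_gradient_experiment(60, taxa_choices = 32L, ranges = rg_hard,
                                  models = "JC", seed = 51)
  easy <- run_gradient_experiment(60, taxa_choices = 32L, ranges = rg_easy,
                                  models = "JC", seed = 52)
  frac <- function(r) mean(r$rf_norm > 0, na.rm = TRUE)
  expect_gt(frac(hard), frac(easy))
})

test_that("interaction regression finds a planted effect and adjusts p-values", {
  set.seed(53)
  n <- 300
  rec <- synth_records(n, stat = stats::rnorm(n), positive = rep(c(TRUE, FALSE), n / 2))
  rec$n_taxa <- sample(c(8L, 32L, 128L), n, TRUE)
  rec$seq_len <- round(stats::runif(n, 250, 1500))
  rec$mean_bl <- stats::runif(n, 0.05, 0.65)
  rec$stemminess <- stats::runif(n, 0.1, 0.9)
  rec$balanced <- sample(c(TRUE, FALSE), n, TRUE)
  rec$model <- sample(c("JC", "GTRG"), n, TRUE)
  rec$n_variable <- rpois(n, 300)
  tree_len <- rec$mean_bl * (2 * rec$n_taxa - 2)
  y <- 2 * tree_len + stats::rnorm(n, 0, 1)
  tab <- interaction_regression(rec, response = y)
  expect_true(all(c("term", "estimate", "t_value", "p_value", "p_adj") %in% names(tab)))
  expect_lt(tab$p_adj[tab$term == "tree_length"], 1e-6)
  expect_true(any(grepl(":", tab$term)))               # pairwise interactions present
  expect_true(all(tab$p_adj >= tab$p_value - 1e-15))   # BH never lowers a p-value
})

test_that("constant design arms are dropped instead of breaking the fit", {
  set.seed(59)
  n <- 120
  rec <- synth_records(n, stat = stats::rnorm(n), positive = rep(c(TRUE, FALSE), n / 2))
  rec$n_taxa <- sample(c(8L, 32L), n, TRUE)
  rec$seq_len <- round(stats::runif(n, 250, 1500))
  rec$mean_bl <- stats::runif(n, 0.05, 0.65)
  rec$stemminess <- stats::runif(n, 0.1, 0.9)
  rec$model <- "JC"                    # single-model records: factor collapses
  rec$balanced <- TRUE
  rec$n_variable <- rpois(n, 300)
  tab <- interaction_regression(rec, response = stats::rnorm(n))
  expect_false(any(grepl("model", tab$term)))
  expect_false(any(grepl("imbalance", tab$term)))
})
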