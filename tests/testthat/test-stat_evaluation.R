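test_that("DeLong AUC equals brute-force pair counting and handles edge cases", {
  expect_equal(roc_auc_delong(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))$auc, 1)
  expect_equal(roc_auc_delong(rep(5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc_delong(1:5, rep(TRUE, 5)), "both correct and incorrect")

  set.seed(501)
  for (i in 1:100) {
    labels <- c(TRUE, FALSE, runif(28) > 0.5)
    scores <- round(runif(30, 0, 10), sample(0:2, 1))  # ties likely
    res <- roc_auc_delong(scores, labels)
    expect_close(res$auc, auc_pair_count(scores, labels))
    expect_true(res$ci[1] <= res$auc && res$auc <= res$ci[2])
  }
})

test_that("DeLong variance and CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(502)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  res <- roc_auc_delong(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                direction = "<", levels = c(FALSE, TRUE)),
                      method = "delong")
  expect_equal(res$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(res$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-8)
})

test_that("DeLong SE shrinks with sample size at fixed true AUC", {
  ses <- vapply(c(50, 200, 800), function(n) {
    withr::with_seed(503 + n, {
      labels <- rep(c(TRUE, FALSE), n / 2)
      scores <- rnorm(n, mean = ifelse(labels, 0.8, 0))
      roc_auc_delong(scores, labels)$se
    })
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("Spearman association matches rank-then-Pearson and bands correctly", {
  set.seed(504)
  for (i in 1:30) {
    n <- 20
    scores <- runif(n)
    labels <- as.numeric(runif(n) < 0.4 + 0.4 * scores)
    if (length(unique(labels)) < 2) next
    res <- spearman_assoc(scores, labels)
    expect_close(res$rho, stats::cor(rank(scores), rank(labels)))
    expect_true(res$ci[1] <= res$rho && res$rho <= res$ci[2])
    ref_band <- cut(abs(res$rho), c(-Inf, 0.10, 0.39, 0.69, 0.89, Inf),
                    labels = c("negligible", "weak", "moderate", "strong",
                               "very strong"))
    expect_equal(res$band, as.character(ref_band))
  }
  # increasing scores with sorted labels associate positively
  expect_gt(spearman_assoc(1:10, rep(0:1, each = 5))$rho, 0)
  expect_error(spearman_assoc(rep(1, 10), rep(0:1, 5)), "constant")
})

test_that("fixed-bin ECE matches a per-bin hand summation", {
  expect_equal(ece_fixed_bins(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0)
  expect_equal(ece_fixed_bins(rep(1, 5), rep(0, 5)), 1)
  # a confidence of exactly 1.0 lands in the last (right-closed) bin
  expect_equal(ece_fixed_bins(1, 1), 0)
  expect_error(ece_fixed_bins(c(0.5, 1.2), c(1, 0)), "\\[0, 1\\]")

  set.seed(505)
  for (i in 1:30) {
    conf <- round(runif(50), 3)
    correct <- as.numeric(runif(50) < conf)
    expect_close(ece_fixed_bins(conf, correct), ece_by_hand(conf, correct),
                 tol = 1e-12)
  }
})

test_that("binary Brier score equals the mean squared gap", {
  expect_equal(brier_binary(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  expect_equal(brier_binary(c(0, 1, 1), c(0, 1, 1)), 0)
  set.seed(506)
  conf <- runif(40); correct <- as.numeric(runif(40) < 0.5)
  expect_close(brier_binary(conf, correct), mean((conf - correct)^2))
})

test_that("the reliability table reconstructs the ECE", {
  set.seed(507)
  conf <- runif(80); correct <- as.numeric(runif(80) < conf)
  tab <- reliability_table(conf, correct)
  ece <- sum(tab$count / sum(tab$count) *
               abs(tab$mean_conf - tab$accuracy), na.rm = TRUE)
  expect_close(ece, ece_fixed_bins(conf, correct), tol = 1e-12)
  expect_equal(sum(tab$count), 80L)
})

test_that("bootstrap intervals are seeded, degenerate-safe and bracket the estimate", {
  conf <- c(0.9, 0.8, 0.3, 0.6, 0.7, 0.2)
  correct <- c(1, 1, 0, 1, 0, 0)
  ci1 <- bootstrap_ci(brier_binary, conf, correct, iters = 200, seed = 99)
  ci2 <- bootstrap_ci(brier_binary, conf, correct, iters = 200, seed = 99)
  expect_identical(as.numeric(ci1), as.numeric(ci2))

  flat <- bootstrap_ci(function(cf, cr) 0.42, conf, correct, iters = 50, seed = 1)
  expect_equal(as.numeric(flat), c(0.42, 0.42))

  # failing resamples are redrawn and counted
  need_both <- function(cf, cr) roc_auc_delong(cf, cr)$auc
  ci3 <- bootstrap_ci(need_both, c(0.9, 0.2, 0.4), c(1, 0, 0),
                      iters = 100, seed = 3)
  expect_gt(attr(ci3, "n_redrawn"), 0)

  # percentile interval brackets the point estimate under resampling
  set.seed(508)
  hits <- 0L
  for (r in 1:200) {
    cf <- runif(40); cr <- as.numeric(runif(40) < cf)
    point <- brier_binary(cf, cr)
    ci <- bootstrap_ci(brier_binary, cf, cr, iters = 200, seed = r)
    hits <- hits + (ci[1] <= point && point <= ci[2])
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Mann-Whitney U agrees with enumeration, approximation and the AUC identity", {
  # complete separation of two triples: 2 of the 20 assignments are as extreme
  res <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res$U, 9)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")

  same <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p, 1)

  set.seed(509)
  x <- rnorm(20); y <- rnorm(15) - 0.5   # tie-free continuous draws
  res2 <- mann_whitney(x, y)
  expect_close(res2$U / (20 * 15), auc_pair_count(c(x, y),
               rep(c(TRUE, FALSE), c(20, 15))))
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(res2$p, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), y), "nonempty")
})

test_that("model evaluation pairs metrics with their own correctness and flags entropy", {
  sim <- simulate_model(synth_config(n_cases = 80, seed = 510), "m")
  prof <- build_profiles(group_responses(sim$responses, sim$cases), depths = 20)
  ev <- evaluate_model(prof, "m", depth = 20, iters = 50, seed = 7)
  expect_setequal(ev$metric, c("self_reported_first", "self_reported_mean",
                               "r_h", "majority_pct", "tws", "shannon_entropy"))
  # sign-flipped entropy discriminates identically to the relative entropy score
  expect_identical(ev$auc[ev$metric == "shannon_entropy"],
                   ev$auc[ev$metric == "r_h"])
  expect_true(is.na(ev$ece[ev$metric == "shannon_entropy"]))
  expect_true(all(ev$ece[!is.na(ev$ece)] >= 0 & ev$ece[!is.na(ev$ece)] <= 1))
  expect_true(all(ev$auc_lo <= ev$auc & ev$auc <= ev$auc_hi))
  expect_true(all(ev$ece_lo[!is.na(ev$ece)] <= ev$ece[!is.na(ev$ece)] + 1e-12))

  # single-class profiles are rejected
  allright <- prof
  for (col in grep("^correct_", names(allright), value = TRUE))
    allright[[col]] <- TRUE
  expect_error(evaluate_model(allright, "m", depth = 20, iters = 0),
               "both correctness classes")

  # a metric absent on most cases is skipped, not fabricated
  sparse <- prof
  sparse$first_conf[seq_len(70)] <- NA
  expect_warning(ev2 <- evaluate_model(sparse, "m", depth = 20, iters = 0),
                 "skipped")
  expect_false("self_reported_first" %in% ev2$metric)
})

test_that("correct-vs-incorrect score comparisons run per metric", {
  sim <- simulate_model(synth_config(n_cases = 60, seed = 511), "m")
  prof <- build_profiles(group_responses(sim$responses, sim$cases), depths = 20)
  cmp <- compare_correct_incorrect(prof, "m", depth = 20)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_true("tws" %in% cmp$metric)
  # the entropy row flips sign, so its medians mirror r_h's ordering
  rh <- cmp[cmp$metric == "r_h", ]
  expect_gt(rh$median_correct, rh$median_incorrect)
})
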