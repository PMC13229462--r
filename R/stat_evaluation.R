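# Evaluation stack relating each confidence metric to the correctness of
# its representative answer across cases: discrimination (ROC AUC with
# DeLong variance), association (Spearman rho with Fisher-z CIs and
# interpretation bands), calibration (fixed-bin expected calibration error
# and binary Brier score, bootstrap percentile CIs), and group-difference
# tests (Mann-Whitney U between correct and incorrect cases).

#' ROC AUC with DeLong variance
#'
#' AUC by the midrank (Mann-Whitney) estimator -- tied scores earn half
#' credit -- with the standard error from DeLong's structural components:
#' per-positive and per-negative placement values.  The 95% CI is the
#' normal interval truncated to `[0, 1]`; the p value tests AUC = 0.5
#' (no discrimination), two-sided.
#'
#' @param scores numeric confidence scores, higher = more confident.
#' @param labels binary outcomes (logical, or 0/1), `TRUE`/1 = correct.
#' @return List with `auc`, `ci` (`c(lo, hi)`), `se`, and `p`.
#' @references DeLong ER, DeLong DM, Clarke-Pearson DL (1988). Comparing
#'   the areas under two or more correlated receiver operating
#'   characteristic curves. Biometrics 44(3), 837-845.
#' @export
roc_auc_delong <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  m <- sum(labels); n <- sum(!labels)
  if (m < 1 || n < 1)
    stopf("AUC undefined: both correct and incorrect cases are required")
  x <- scores[labels]    # positives (correct)
  y <- scores[!labels]   # negatives (incorrect)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  # placement values: V10_i = P(score_i > Y) (+ half ties), V01_j likewise
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se)
       else as.numeric(auc == 0.5)
  list(auc = auc, ci = ci, se = se, p = p)
}

#' Spearman association between a confidence metric and correctness
#'
#' Spearman's rho on midranks, with a 95% CI from the Fisher z transform
#' (SE `1/sqrt(n - 3)`) and a two-sided p value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.  The coefficient is labelled
#' by the conventional interpretation bands: negligible (|rho| <= 0.10),
#' weak (<= 0.39), moderate (<= 0.69), strong (<= 0.89), very strong
#' above that.
#'
#' @param scores numeric metric values.
#' @param labels binary (or numeric) outcomes paired with `scores`.
#' @return List with `rho`, `ci`, `p`, and `band`.
#' @export
spearman_assoc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n <- length(scores)
  if (n < 4) stopf("Spearman association needs n >= 4, got %d", n)
  if (stats::sd(scores) == 0 || stats::sd(labels) == 0)
    stopf("Spearman association undefined for a constant vector")
  rho <- stats::cor(rank(scores), rank(labels))
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  zci <- z + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, ci = tanh(zci), p = p, band = rho_band(rho))
}

rho_band <- function(rho) {
  a <- abs(rho)
  if (a <= 0.10) "negligible"
  else if (a <= 0.39) "weak"
  else if (a <= 0.69) "moderate"
  else if (a <= 0.89) "strong"
  else "very strong"
}

kappa_band <- function(kappa) {
  if (kappa > 0.8) "almost perfect"
  else if (kappa > 0.60) "substantial"
  else if (kappa > 0.40) "moderate"
  else if (kappa > 0.20) "fair"
  else "poor"
}

ece_bin_index <- function(conf, n_bins) {
  # equal-width bins on [0,1], half-open [lo, hi), last bin closed at 1
  pmin(floor(conf * n_bins) + 1L, n_bins)
}

#' Expected calibration error with fixed equal-width bins
#'
#' Confidences (on `[0, 1]`; rescaling percent-valued metrics is the
#' caller's duty) are assigned to `n_bins` fixed equal-width bins,
#' half-open except the last, which is closed so a confidence of exactly
#' 1 is counted.  ECE is the bin-size-weighted mean absolute gap between
#' mean confidence and accuracy; empty bins contribute nothing.
#'
#' @param conf numeric confidences in `[0, 1]`.
#' @param correct binary outcomes.
#' @param n_bins number of bins (default 10).
#' @return ECE in `[0, 1]`.
#' @export
ece_fixed_bins <- function(conf, correct, n_bins = 10L) {
  correct <- as.numeric(correct)
  if (length(conf) != length(correct)) stopf("conf and correct differ in length")
  if (length(conf) < 1) stopf("calibration input is empty")
  if (anyNA(conf) || anyNA(correct)) stopf("calibration input contains NA")
  if (any(conf < 0 | conf > 1))
    stopf("confidences must lie in [0, 1]; rescale percent metrics first")
  bin <- ece_bin_index(conf, n_bins)
  n <- length(conf)
  ece <- 0
  for (b in unique(bin)) {
    in_b <- bin == b
    ece <- ece + sum(in_b) / n * abs(mean(conf[in_b]) - mean(correct[in_b]))
  }
  ece
}

#' Reliability diagram table
#'
#' Per-bin mean confidence, accuracy and count under the same fixed-bin
#' scheme as [ece_fixed_bins()]; the raw material of a reliability
#' diagram.
#'
#' @inheritParams ece_fixed_bins
#' @return Data frame with `bin`, `lo`, `hi`, `mean_conf`, `accuracy`,
#'   `count` (empty bins kept with `NA` summaries).
#' @export
reliability_table <- function(conf, correct, n_bins = 10L) {
  correct <- as.numeric(correct)
  if (any(conf < 0 | conf > 1)) stopf("confidences must lie in [0, 1]")
  bin <- ece_bin_index(conf, n_bins)
  data.frame(
    bin = seq_len(n_bins),
    lo = (seq_len(n_bins) - 1) / n_bins,
    hi = seq_len(n_bins) / n_bins,
    mean_conf = vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(conf[bin == b]) else NA_real_, numeric(1)),
    accuracy = vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(correct[bin == b]) else NA_real_, numeric(1)),
    count = vapply(seq_len(n_bins), function(b) sum(bin == b), integer(1))
  )
}

#' Binary Brier score
#'
#' Mean squared difference between confidence (on `[0, 1]`) and the binary
#' correctness of the representative answer -- not a multiclass score over
#' the option set.
#'
#' @inheritParams ece_fixed_bins
#' @return Brier score in `[0, 1]`.
#' @export
brier_binary <- function(conf, correct) {
  correct <- as.numeric(correct)
  if (length(conf) != length(correct)) stopf("conf and correct differ in length")
  if (length(conf) < 1) stopf("calibration input is empty")
  if (anyNA(conf) || anyNA(correct)) stopf("calibration input contains NA")
  if (any(conf < 0 | conf > 1))
    stopf("confidences must lie in [0, 1]; rescale percent metrics first")
  mean((conf - correct)^2)
}

#' Bootstrap percentile confidence interval for a calibration statistic
#'
#' Cases are the exchangeable unit: each iteration resamples case indices
#' with replacement and recomputes the statistic; the interval is the
#' 2.5/97.5 percentile of the bootstrap distribution.  A resample on which
#' the statistic fails (e.g. a single-class draw for an AUC) is redrawn,
#' and the number of redraws reported.  Identical seeds give identical
#' intervals.
#'
#' @param stat function of `(conf, correct)` returning a scalar.
#' @param conf,correct case-level inputs.
#' @param iters bootstrap iterations (default 1000).
#' @param seed integer seed, or `NULL` to use the current stream.
#' @return `c(lo, hi)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(stat, conf, correct, iters = 1000L, seed = NULL) {
  n <- length(conf)
  if (n < 2) stopf("bootstrap needs n >= 2")
  local_seed(seed, {
    vals <- numeric(iters)
    redraws <- 0L
    for (i in seq_len(iters)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(stat(conf[idx], correct[idx]), error = function(e) NULL)
        if (!is.null(v)) break
        redraws <- redraws + 1L
        if (redraws > 100L * iters) stopf("bootstrap: statistic failed on too many resamples")
      }
      vals[i] <- v
    }
    ci <- unname(stats::quantile(vals, c(0.025, 0.975)))
    structure(ci, n_redrawn = redraws)
  })
}

#' Mann-Whitney U test between correct-case and incorrect-case scores
#'
#' U counts pairs where a correct case outscores an incorrect one (ties
#' half).  With both groups of size <= 8 the two-sided p value comes from
#' exact enumeration of all assignments of the pooled scores to groups
#' (valid under ties); otherwise from the normal approximation with tie
#' correction.
#'
#' @param scores_correct scores of correct cases.
#' @param scores_incorrect scores of incorrect cases.
#' @return List with `U`, `p`, and `method`.
#' @export
mann_whitney <- function(scores_correct, scores_incorrect) {
  x <- scores_correct[!is.na(scores_correct)]
  y <- scores_incorrect[!is.na(scores_incorrect)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stopf("both groups must be nonempty")
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= 8 && n2 <= 8) {
    pooled <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
    p <- if (sigma > 0) 2 * stats::pnorm(-abs(U - mu) / sigma) else 1
    p <- min(p, 1)
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

# metric registry: score column, correctness column, divisor to reach the
# common [0,1] calibration domain, and whether calibration is meaningful
metric_registry <- function() {
  data.frame(
    metric = c("self_reported_first", "self_reported_mean", "r_h",
               "majority_pct", "tws", "shannon_entropy"),
    score_col = c("first_conf", "mean_conf_majority", "r_h",
                  "majority_pct", "tws", "entropy_H"),
    correct_col = c("correct_first", "correct_mean", "correct_rh",
                    "correct_majority", "correct_tws", "correct_rh"),
    rescale = c(100, 100, 1, 100, 100, NA),
    flip = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Evaluate every confidence metric for one model at one depth
#'
#' For each metric, pairs the metric value with the correctness of that
#' metric's representative answer across cases and computes: DeLong ROC
#' AUC with 95% CI and p (vs 0.5); Spearman rho with Fisher-z CI, p, and
#' interpretation band; fixed-bin ECE and binary Brier score, each with a
#' bootstrap percentile CI.  Before calibration, every metric is mapped to
#' the common `[0, 1]` domain (percent-valued metrics divided by 100; R_H
#' used as is).  Shannon entropy enters discrimination with sign-flipped
#' scores -- so higher always means more confident, and its AUC equals
#' R_H's exactly -- but has no calibration row, since it does not live on
#' a probability scale.
#'
#' @param profiles profile data frame from [build_profiles()].
#' @param model_id model to evaluate.
#' @param depth repetition depth to evaluate at (must exist in `profiles`).
#' @param n_bins ECE bins (default 10).
#' @param iters bootstrap iterations for the calibration CIs; 0 skips the
#'   bootstrap (CIs become `NA`).
#' @param seed integer seed driving the bootstrap; per-metric streams are
#'   derived from it, so adding a metric never perturbs another's draws.
#' @param min_coverage a metric observed on fewer than this fraction of
#'   cases is skipped with a warning (default 0.5).
#' @return Data frame with one row per metric: point estimates, CI bounds
#'   and p values for AUC and rho, `rho_band`, ECE and Brier with CI
#'   bounds, and `n_cases`.
#' @export
evaluate_model <- function(profiles, model_id, depth, n_bins = 10L,
                           iters = 1000L, seed = NULL, min_coverage = 0.5) {
  sub <- profiles[profiles$model_id == model_id & profiles$depth == depth, ,
                  drop = FALSE]
  if (nrow(sub) < 2)
    stopf("need >= 2 profiles for model %s at depth %s", model_id, depth)
  reg <- metric_registry()
  rows <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    met <- reg[i, ]
    score <- sub[[met$score_col]]
    correct <- sub[[met$correct_col]]
    ok <- !is.na(score) & !is.na(correct)
    if (mean(ok) < min_coverage) {
      warnf("metric %s missing for more than %d%% of cases; skipped",
            met$metric, round(100 * (1 - min_coverage)))
      next
    }
    score <- score[ok]; correct <- correct[ok]
    if (length(unique(correct)) < 2)
      stopf("metric %s: both correctness classes required for evaluation",
            met$metric)
    disc_score <- if (met$flip) -score else score
    auc <- roc_auc_delong(disc_score, correct)
    # a metric constant across cases has no defined rank association;
    # report NA rather than aborting the whole evaluation
    rho <- tryCatch(spearman_assoc(disc_score, correct),
                    error = function(e)
                      list(rho = NA_real_, ci = c(NA_real_, NA_real_),
                           p = NA_real_, band = NA_character_))
    if (!is.na(met$rescale)) {
      conf01 <- score / met$rescale
      ece <- ece_fixed_bins(conf01, correct, n_bins)
      brier <- brier_binary(conf01, correct)
      if (iters > 0) {
        met_seed <- if (is.null(seed)) NULL else seed + 101L * i
        ece_ci <- bootstrap_ci(function(cf, cr) ece_fixed_bins(cf, cr, n_bins),
                               conf01, correct, iters = iters, seed = met_seed)
        brier_ci <- bootstrap_ci(brier_binary, conf01, correct,
                                 iters = iters,
                                 seed = if (is.null(met_seed)) NULL else met_seed + 1L)
      } else ece_ci <- brier_ci <- c(NA_real_, NA_real_)
    } else {
      ece <- brier <- NA_real_
      ece_ci <- brier_ci <- c(NA_real_, NA_real_)
    }
    rows[[i]] <- data.frame(
      model_id = model_id, metric = met$metric, depth = as.integer(depth),
      n_cases = length(score),
      auc = auc$auc, auc_lo = auc$ci[1], auc_hi = auc$ci[2], auc_p = auc$p,
      rho = rho$rho, rho_lo = rho$ci[1], rho_hi = rho$ci[2], rho_p = rho$p,
      rho_band = rho$band,
      ece = ece, ece_lo = ece_ci[1], ece_hi = ece_ci[2],
      brier = brier, brier_lo = brier_ci[1], brier_hi = brier_ci[2],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare metric scores between correct and incorrect cases
#'
#' For each metric, splits the cases by the correctness of that metric's
#' representative answer and tests the score difference with the
#' Mann-Whitney U test, the usual companion of a per-metric ROC analysis.
#'
#' @inheritParams evaluate_model
#' @return Data frame with one row per metric: group medians, `U`, `p`,
#'   and the test method used.
#' @export
compare_correct_incorrect <- function(profiles, model_id, depth) {
  sub <- profiles[profiles$model_id == model_id & profiles$depth == depth, ,
                  drop = FALSE]
  reg <- metric_registry()
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    met <- reg[i, ]
    score <- sub[[met$score_col]]
    if (met$flip) score <- -score
    correct <- sub[[met$correct_col]]
    ok <- !is.na(score) & !is.na(correct)
    score <- score[ok]; correct <- correct[ok]
    if (!any(correct) || all(correct)) return(NULL)
    mw <- mann_whitney(score[correct], score[!correct])
    data.frame(
      model_id = model_id, metric = met$metric, depth = as.integer(depth),
      median_correct = stats::median(score[correct]),
      median_incorrect = stats::median(score[!correct]),
      U = mw$U, p = mw$p, method = mw$method, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
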