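# Repetition-depth analyses: majority-vote accuracy across repetition
# counts, Cochran Q across depth conditions, Fleiss kappa repeatability,
# and a Fisher-exact temporal holdout probing training-data contamination.

#' Accuracy by repetition depth
#'
#' Depth 1 scores the first output; deeper conditions score the
#' majority-vote answer over the first `depth` repetitions (ties broken by
#' canonical option order, as everywhere in the package).
#'
#' @param sets list of `response_set` objects.
#' @param depths depths to evaluate (default `c(1, 5, 10, 15, 20)`).
#' @param model_id restrict to one model (default: all sets, grouped).
#' @return Data frame with `model_id`, `depth`, `n_correct`, `n_cases`,
#'   `accuracy_pct`.
#' @export
depth_accuracy <- function(sets, depths = c(1L, 5L, 10L, 15L, 20L),
                           model_id = NULL) {
  if (!is.null(model_id))
    sets <- Filter(function(s) s$model_id == model_id, sets)
  if (length(sets) == 0L) stopf("no response sets to evaluate")
  ns <- vapply(sets, `[[`, integer(1), "n")
  short <- ns < max(depths)
  if (any(short))
    stopf("set(s) with fewer than %d repetitions: %s", max(depths),
          paste(vapply(sets[short], `[[`, character(1), "case_id"), collapse = ", "))
  correct <- depth_correct_matrix(sets, depths)
  models <- vapply(sets, `[[`, character(1), "model_id")
  out <- do.call(rbind, lapply(unique(models), function(m) {
    sub <- correct[models == m, , drop = FALSE]
    data.frame(
      model_id = m, depth = as.integer(depths),
      n_correct = as.integer(colSums(sub)), n_cases = nrow(sub),
      accuracy_pct = 100 * colMeans(sub), stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Case-by-condition correctness matrix
#'
#' The binary matrix behind the Cochran Q test: one row per response set,
#' one column per depth condition; entry `TRUE` when the first output
#' (depth 1) or the majority-vote answer (depth > 1) is correct.
#'
#' @inheritParams depth_accuracy
#' @return Logical matrix, rows named by `case::model`, columns by depth.
#' @export
depth_correct_matrix <- function(sets, depths = c(1L, 5L, 10L, 15L, 20L)) {
  mat <- vapply(depths, function(d) {
    vapply(sets, function(s) {
      ans <- if (d == 1L) s$answers[1L] else majority_vote(tally(s, d))$option
      ans == s$ground_truth
    }, logical(1))
  }, logical(length(sets)))
  mat <- matrix(mat, nrow = length(sets),
                dimnames = list(names(sets), as.character(depths)))
  mat
}

#' Cochran Q test for repeated binary outcomes
#'
#' Tests whether the proportion of correct answers differs across matched
#' conditions (here, repetition-depth conditions on the same cases).
#' `Q = (m-1) * (m * sum(G_j^2) - T^2) / (m*T - sum(L_i^2))` with `m`
#' conditions, column totals `G_j`, row totals `L_i`, grand total `T`;
#' referred to a chi-square with `m - 1` degrees of freedom.  Rows
#' constant across conditions contribute nothing; if every row is
#' constant, `Q = 0` and `p = 1` by convention.
#'
#' @param binary_matrix cases x conditions matrix of 0/1 or logical.
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(binary_matrix) {
  x <- matrix(as.numeric(binary_matrix), nrow = nrow(binary_matrix))
  if (ncol(x) < 2 || nrow(x) < 2)
    stopf("Cochran Q needs >= 2 cases and >= 2 conditions")
  if (anyNA(x) || !all(x %in% c(0, 1))) stopf("matrix must be binary")
  m <- ncol(x)
  G <- colSums(x)
  L <- rowSums(x)
  T_ <- sum(G)
  denom <- m * T_ - sum(L^2)
  Q <- if (denom == 0) 0 else (m - 1) * (m * sum(G^2) - T_^2) / denom
  list(Q = Q, df = m - 1L,
       p = if (denom == 0) 1 else stats::pchisq(Q, df = m - 1, lower.tail = FALSE))
}

#' Agreement table for repeatability analysis
#'
#' One row per response set, one column per option label (the union over
#' sets, in first-seen canonical order), entries counting how often that
#' option was chosen among the first `depth` repetitions.  Constant row
#' sums -- the Fleiss kappa prerequisite -- follow when all sets are
#' truncated to a common depth.
#'
#' @param sets list of `response_set` objects.
#' @param depth repetitions per set to count (default: the common minimum).
#' @return Integer matrix of counts.
#' @export
agreement_table <- function(sets, depth = NULL) {
  if (length(sets) == 0L) stopf("no response sets")
  depth <- depth %||% min(vapply(sets, `[[`, integer(1), "n"))
  opts <- unique(unlist(lapply(sets, `[[`, "options")))
  mat <- t(vapply(sets, function(s) {
    ans <- s$answers[seq_len(depth)]
    vapply(opts, function(o) sum(ans == o), integer(1))
  }, integer(length(opts))))
  dimnames(mat) <- list(names(sets), opts)
  mat
}

#' Fleiss kappa for repeated categorical ratings
#'
#' Chance-corrected agreement `kappa = (Pbar - Pe) / (1 - Pe)` over items
#' rated `n` times each: `Pbar` averages the per-item pairwise agreement
#' `(sum_j n_ij^2 - n) / (n (n - 1))` and `Pe = sum_j p_j^2` from the
#' marginal category proportions.  Here the "raters" are a model's
#' repeated generations, so kappa measures within-model repeatability.
#' Bands: > 0.8 almost perfect, 0.61-0.80 substantial, 0.41-0.60 moderate,
#' 0.21-0.40 fair, below that poor.
#'
#' @param table items x categories count matrix with constant row sum
#'   >= 2 (see [agreement_table()]).
#' @return List with `kappa` and `band`.
#' @export
fleiss_kappa <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2) stopf("Fleiss kappa needs >= 2 cases")
  rs <- rowSums(x)
  n <- rs[1L]
  if (n < 2 || any(rs != n)) stopf("row sums must be constant and >= 2")
  N <- nrow(x)
  P_i <- (rowSums(x^2) - n) / (n * (n - 1))
  p_j <- colSums(x) / (N * n)
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (1 - Pe <= 0)
    stopf("Fleiss kappa undefined: all ratings fall in one category")
  kappa <- (Pbar - Pe) / (1 - Pe)
  list(kappa = kappa, band = kappa_band(kappa))
}

#' Fleiss kappa at each repetition depth
#'
#' Repeats [fleiss_kappa()] on the first-`d` agreement tables, tracing how
#' repeatability evolves with the number of repetitions.
#'
#' @param sets list of `response_set` objects (one model's).
#' @param depths depths at which to compute kappa (each >= 2).
#' @return Data frame with `depth`, `kappa`, `band`.
#' @export
kappa_by_depth <- function(sets, depths = c(5L, 10L, 15L, 20L)) {
  if (any(depths < 2)) stopf("kappa needs depth >= 2")
  out <- do.call(rbind, lapply(depths, function(d) {
    fk <- fleiss_kappa(agreement_table(sets, d))
    data.frame(depth = as.integer(d), kappa = fk$kappa, band = fk$band,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Temporal-holdout contamination check
#'
#' Compares majority-vote correctness between cases published before and
#' after a cutoff date (a proxy for the generator's training cutoff) with
#' a two-sided Fisher exact test.  A significant accuracy drop on
#' post-cutoff cases would suggest the pre-cutoff material leaked into
#' training.  Cases without a publication date are excluded and counted.
#'
#' @param profiles profile data frame ([build_profiles()]), one model.
#' @param cases case table with `published_date`.
#' @param cutoff_date cutoff (`Date` or ISO string); "before" means
#'   strictly earlier.
#' @param depth repetition depth whose majority correctness is compared
#'   (default: the maximum present).
#' @return List with the 2x2 `table` (stratum x correctness), Fisher `p`,
#'   `odds_ratio`, and `n_excluded`.
#' @export
temporal_holdout <- function(profiles, cases, cutoff_date, depth = NULL) {
  cutoff_date <- as.Date(cutoff_date)
  depth <- depth %||% max(profiles$depth)
  sub <- profiles[profiles$depth == depth, , drop = FALSE]
  pub <- cases$published_date[match(sub$case_id, cases$case_id)]
  n_excluded <- sum(is.na(pub))
  keep <- !is.na(pub)
  sub <- sub[keep, , drop = FALSE]; pub <- pub[keep]
  stratum <- factor(ifelse(pub < cutoff_date, "pre", "post"),
                    levels = c("pre", "post"))
  if (any(tabulate(stratum, 2L) == 0L))
    stopf("both temporal strata must be nonempty")
  tab <- table(stratum,
               factor(ifelse(sub$correct_majority, "correct", "incorrect"),
                      levels = c("correct", "incorrect")))
  ft <- stats::fisher.test(tab)
  list(table = tab, p = ft$p.value, odds_ratio = unname(ft$estimate),
       n_excluded = n_excluded)
}
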