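# Confidence metrics for repeated categorical answers.
#
# Given n repeated answers to a k-option question, three families of
# confidence signals are computed:
#   * self-reported  - the confidence the generator verbalizes itself
#     (first response, and the mean over responses voting with the majority);
#   * consistency    - agreement among the n answers: Shannon entropy H of
#     the answer frequencies, its normalized complement R_H = 1 - H/log2(k),
#     and the majority-vote percentage;
#   * hybrid         - a per-option weighted score
#     (frequency x mean self-reported confidence) / n, whose maximum over
#     options is the Top Weighted Score (TWS).
# Each metric is paired with a representative answer whose correctness the
# evaluation stack uses: the majority-voted option for R_H, majority-vote %
# and mean self-reported confidence; the highest-weighted option for TWS;
# and the first response for first self-reported confidence.

#' Tally repeated answers over a case's option set
#'
#' Counts each option's frequency among the first `depth` repetitions and
#' averages the verbalized confidence of the responses that chose it.
#' Zero-count options are kept (count 0) with missing mean confidence --
#' never 0 -- so they cannot spuriously win the Top Weighted Score.  The
#' per-option weighted score is `count * mean_conf / depth`.
#'
#' @param set a `response_set` from [group_responses()].
#' @param depth number of leading repetitions to use (in generation order;
#'   truncation is never a random subsample).
#' @return Data frame with one row per option in canonical order: `option`,
#'   `count`, `mean_conf`, `weighted_score`; attributes `n` (= `depth`) and
#'   `k`.
#' @examples
#' set <- simulate_model(synth_config(n_cases = 1, seed = 1), "m")
#' tally(group_responses(set$responses, set$cases)[[1]], depth = 5)
#' @export
tally <- function(set, depth = set$n) {
  stopifnot(inherits(set, "response_set"))
  if (!is_scalar(depth) || depth < 1 || depth > set$n || depth != round(depth))
    stopf("depth must be an integer in [1, %d], got %s", set$n,
          paste(depth, collapse = ","))
  ans <- set$answers[seq_len(depth)]
  conf <- set$conf[seq_len(depth)]
  counts <- vapply(set$options, function(o) sum(ans == o), integer(1))
  mean_conf <- vapply(set$options, function(o) {
    c_o <- conf[ans == o]
    c_o <- c_o[!is.na(c_o)]
    if (length(c_o)) mean(c_o) else NA_real_
  }, numeric(1))
  structure(
    data.frame(
      option = set$options,
      count = counts,
      mean_conf = mean_conf,
      weighted_score = counts * mean_conf / depth,
      stringsAsFactors = FALSE,
      row.names = NULL
    ),
    n = as.integer(depth), k = length(set$options)
  )
}

#' Shannon entropy of an answer tally
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} in bits, where \eqn{p_i} is the
#' relative frequency of option i among the repetitions; the \eqn{0 \log 0}
#' terms contribute 0.  H is 0 for unanimous answers and \eqn{\log_2 k}
#' when all k options are hit equally often.
#'
#' @param tallies tally data frame from [tally()].
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(tallies) {
  n <- sum(tallies$count)
  if (n < 1) stopf("empty tally: no responses")
  p <- tallies$count[tallies$count > 0] / n
  -sum(p * log2(p))
}

#' Relative entropy confidence score
#'
#' \eqn{R_H = 1 - H / \log_2 k}: a normalized agreement score that is 1
#' for perfectly consistent (unanimous) answer patterns, 0 for complete
#' inconsistency (uniform over all k options), and rewards concentration
#' of the dissenting answers -- the pattern AAABB scores higher than AAABC,
#' which the majority-vote percentage cannot distinguish.
#'
#' @param tallies tally data frame from [tally()].
#' @param k number of answer options; defaults to the tally's option count.
#' @return Score in `[0, 1]`.
#' @examples
#' # unanimous -> 1; one answer per option -> 0
#' @export
relative_entropy_score <- function(tallies, k = nrow(tallies)) {
  if (!is_scalar(k) || k < 2) stopf("k must be >= 2, got %s", k)
  1 - shannon_entropy(tallies) / log2(k)
}

#' Majority-vote option and percentage
#'
#' The modal answer and its share of the repetitions (in percent).  A
#' frequency tie is broken by canonical option order (the first label in
#' the case's option list) and flagged, so downstream analyses can inspect
#' or exclude tied cases.
#'
#' @param tallies tally data frame from [tally()].
#' @return List with `option`, `pct` in `(0, 100]`, and logical `tie`.
#' @export
majority_vote <- function(tallies) {
  n <- sum(tallies$count)
  if (n < 1) stopf("empty tally: no responses")
  top <- max(tallies$count)
  winners <- which(tallies$count == top)
  list(
    option = tallies$option[winners[1L]],
    pct = 100 * top / n,
    tie = length(winners) > 1L
  )
}

#' Top Weighted Score
#'
#' The maximum over options of the weighted confidence score
#' `(frequency x mean self-reported confidence) / n` -- a hybrid of
#' response consistency and verbalized confidence.  Options with missing
#' mean confidence (zero count, or no chooser reported a confidence) are
#' excluded; score ties are broken by canonical option order and flagged.
#'
#' @param tallies tally data frame from [tally()].
#' @return List with `option`, `score` in `[0, 100]`, and logical `tie`.
#' @export
top_weighted_score <- function(tallies) {
  ok <- !is.na(tallies$weighted_score)
  if (!any(ok))
    stopf("Top Weighted Score undefined: no option has a mean confidence")
  scores <- tallies$weighted_score[ok]
  top <- max(scores)
  winners <- which(ok)[scores == top]
  list(
    option = tallies$option[winners[1L]],
    score = top,
    tie = length(winners) > 1L
  )
}

#' Self-reported confidence metrics
#'
#' `first_conf` is the confidence verbalized with the very first response
#' (repetition 1; missing propagates).  `mean_conf_majority` averages the
#' confidences of the responses, among the first `depth`, that chose the
#' majority-vote option at that depth; if none of them carries a
#' confidence the mean is missing.
#'
#' @param set a `response_set`.
#' @param depth repetitions to use.
#' @param majority_at `"depth"` (default) recomputes the majority within
#'   the first `depth` repetitions; `"full"` reuses the full-depth majority
#'   option when averaging at shallower depths.
#' @return List with `first_conf` and `mean_conf_majority` (either may be
#'   `NA`).
#' @export
self_reported <- function(set, depth = set$n, majority_at = c("depth", "full")) {
  majority_at <- match.arg(majority_at)
  tal <- tally(set, depth)
  maj <- if (majority_at == "full") majority_vote(tally(set, set$n))
         else majority_vote(tal)
  conf <- set$conf[seq_len(depth)]
  pick <- set$answers[seq_len(depth)] == maj$option & !is.na(conf)
  list(
    first_conf = set$conf[1L],
    mean_conf_majority = if (any(pick)) mean(conf[pick]) else NA_real_
  )
}

#' Build the confidence profile of one response set at one depth
#'
#' Computes every metric on the first `depth` repetitions and fills the
#' correctness map according to each metric's representative answer: the
#' majority-voted option for R_H, majority-vote percentage and mean
#' self-reported confidence; the option with the highest weighted score
#' for TWS; the first response for first self-reported confidence.
#'
#' @param set a `response_set`.
#' @param depth repetitions to use.
#' @param majority_at passed to [self_reported()].
#' @return One-row data frame: identifiers (`case_id`, `model_id`,
#'   `depth`), metric values (`entropy_H`, `r_h`, `majority_pct`,
#'   `first_conf`, `mean_conf_majority`, `tws`), representative answers
#'   (`first_answer`, `majority_option`, `tws_option`), tie flags, and one
#'   logical `correct_*` column per metric.
#' @export
build_profile <- function(set, depth = set$n,
                          majority_at = c("depth", "full")) {
  majority_at <- match.arg(majority_at)
  tal <- tally(set, depth)
  k <- attr(tal, "k")
  H <- shannon_entropy(tal)
  maj <- majority_vote(tal)
  tws <- top_weighted_score(tal)
  sr <- self_reported(set, depth, majority_at = majority_at)
  truth <- set$ground_truth
  data.frame(
    case_id = set$case_id,
    model_id = set$model_id,
    depth = as.integer(depth),
    entropy_H = H,
    r_h = 1 - H / log2(k),
    majority_option = maj$option,
    majority_pct = maj$pct,
    majority_tie = maj$tie,
    first_conf = sr$first_conf,
    mean_conf_majority = sr$mean_conf_majority,
    tws_option = tws$option,
    tws = tws$score,
    tws_tie = tws$tie,
    first_answer = set$answers[1L],
    correct_first = set$answers[1L] == truth,
    correct_mean = maj$option == truth,
    correct_rh = maj$option == truth,
    correct_majority = maj$option == truth,
    correct_tws = tws$option == truth,
    stringsAsFactors = FALSE
  )
}

#' Build confidence profiles for many response sets and depths
#'
#' @param sets list of `response_set` objects ([group_responses()]).
#' @param depths repetition depths to profile at; each must not exceed any
#'   set's repetition count.
#' @param majority_at passed to [self_reported()].
#' @return Data frame with one row per (set, depth), as [build_profile()].
#' @export
build_profiles <- function(sets, depths = NULL,
                           majority_at = c("depth", "full")) {
  majority_at <- match.arg(majority_at)
  if (length(sets) == 0L) stopf("no response sets supplied")
  depths <- depths %||% min(vapply(sets, `[[`, integer(1), "n"))
  rows <- vector("list", length(sets) * length(depths))
  i <- 0L
  for (set in sets) for (d in depths) {
    i <- i + 1L
    rows[[i]] <- build_profile(set, d, majority_at = majority_at)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
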