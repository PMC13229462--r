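# Per-call resource accounting: what repeated sampling costs.  Consistency
# metrics need many generations per case, so the cumulative time and token
# bill per case, by repetition-count condition, is part of the method's
# practical evaluation.

#' Summarize cumulative resource use by repetition-count condition
#'
#' For each (case, model), sums processing time and token counts over the
#' first `d` calls (by repetition index), then averages across cases: the
#' mean and SD cumulative cost of analysing a single case at each
#' repetition depth.  Calls missing a resource field are excluded from
#' the affected aggregate, with exclusion counts reported as attributes.
#' Individual calls whose processing time exceeds `extreme_threshold_s`
#' are censused per condition -- sporadic extreme latencies matter for
#' deployment even when rare.
#'
#' @param records response record data frame ([read_responses()]).
#' @param depths repetition-count conditions (default `c(1, 5, 10, 15, 20)`).
#' @param extreme_threshold_s per-call processing-time threshold in
#'   seconds (default 500).
#' @return Data frame with one row per (model, depth): `mean_time_s`,
#'   `sd_time_s`, `mean_total_tokens`, `sd_total_tokens`,
#'   `mean_input_tokens`, `mean_output_tokens`, `n_extreme_calls`,
#'   `extreme_threshold_s`; attributes `n_missing_time` and
#'   `n_missing_tokens` count excluded calls.
#' @export
summarize_resources <- function(records, depths = c(1L, 5L, 10L, 15L, 20L),
                                extreme_threshold_s = 500) {
  if (nrow(records) == 0L) stopf("no records")
  has_time <- !is.na(records$processing_time_s)
  has_tok <- !is.na(records$input_tokens) & !is.na(records$output_tokens)
  if (!any(has_time) && !any(has_tok))
    stopf("no resource data in any record")
  n_missing_time <- sum(!has_time)
  n_missing_tokens <- sum(!has_tok)

  cum_stat <- function(sub, col, d) {
    # cumulative sum of the first d calls of each case (NA calls dropped)
    per_case <- vapply(split(sub, sub$case_id), function(cs) {
      cs <- cs[order(cs$repetition_index), , drop = FALSE]
      v <- cs[[col]][seq_len(min(d, nrow(cs)))]
      sum(v, na.rm = TRUE)
    }, numeric(1))
    per_case
  }

  out <- do.call(rbind, lapply(unique(records$model_id), function(m) {
    sub <- records[records$model_id == m, , drop = FALSE]
    sub$total_tokens <- sub$input_tokens + sub$output_tokens
    do.call(rbind, lapply(depths, function(d) {
      tm <- cum_stat(sub, "processing_time_s", d)
      tt <- cum_stat(sub, "total_tokens", d)
      ti <- cum_stat(sub, "input_tokens", d)
      to <- cum_stat(sub, "output_tokens", d)
      n_extreme <- sum(vapply(split(sub, sub$case_id), function(cs) {
        cs <- cs[order(cs$repetition_index), , drop = FALSE]
        v <- cs$processing_time_s[seq_len(min(d, nrow(cs)))]
        sum(!is.na(v) & v > extreme_threshold_s)
      }, numeric(1)))
      data.frame(
        model_id = m, depth = as.integer(d),
        mean_time_s = mean(tm), sd_time_s = stats::sd(tm),
        mean_total_tokens = mean(tt), sd_total_tokens = stats::sd(tt),
        mean_input_tokens = mean(ti), mean_output_tokens = mean(to),
        n_extreme_calls = as.integer(n_extreme),
        extreme_threshold_s = extreme_threshold_s,
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  structure(out, n_missing_time = n_missing_time,
            n_missing_tokens = n_missing_tokens)
}
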