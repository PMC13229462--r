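# Fixture builders used across the suite.  Everything goes through the
# public construction path (records data frame + case table ->
# group_responses) so the plumbing is exercised, not bypassed.

make_cases <- function(case_ids = "c1", options = "A|B|C|D|E",
                       truth = "A", dates = as.Date(NA), tags = "") {
  data.frame(
    case_id = case_ids,
    options = options,
    ground_truth = truth,
    published_date = dates,
    tags = tags,
    stringsAsFactors = FALSE
  )
}

make_records <- function(answers, conf = NA_real_, case_id = "c1",
                         model_id = "m", time = NA_real_,
                         in_tok = NA_real_, out_tok = NA_real_) {
  n <- length(answers)
  data.frame(
    case_id = case_id,
    model_id = model_id,
    repetition_index = seq_len(n),
    answer = answers,
    confidence_pct = rep_len(as.numeric(conf), n),
    processing_time_s = rep_len(as.numeric(time), n),
    input_tokens = rep_len(as.numeric(in_tok), n),
    output_tokens = rep_len(as.numeric(out_tok), n),
    stringsAsFactors = FALSE
  )
}

# one response set built from an answer pattern like c("A","A","B")
make_set <- function(answers, conf = NA_real_, options = "A|B|C|D|E",
                     truth = "A", model_id = "m") {
  cases <- make_cases(options = options, truth = truth)
  recs <- make_records(answers, conf = conf, model_id = model_id)
  group_responses(recs, cases)[[1L]]
}

# a random response set over k options, n repetitions, confidences present
random_set <- function(n, k, truth_idx = 1L) {
  opts <- LETTERS[seq_len(k)]
  make_set(sample(opts, n, replace = TRUE),
           conf = round(stats::runif(n, 20, 100), 2),
           options = paste(opts, collapse = "|"),
           truth = opts[truth_idx])
}

expect_close <- function(x, y, tol = 1e-12) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max |diff| = %.3g", max(abs(x - y))))
}
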