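# Reading, validating and writing response logs, case tables and metric
# profiles.  A response log holds one row per generation: which option the
# model chose on that repetition, the confidence it verbalized, and the
# per-call resource footprint.  Option membership is checked when records
# are joined to their cases (group_responses), not here, because the log
# format alone does not know each case's option set.

RESPONSE_FIELDS <- c(
  "case_id", "model_id", "repetition_index", "answer",
  "confidence_pct", "processing_time_s", "input_tokens", "output_tokens"
)

#' Parse verbalized confidence values
#'
#' Confidence ratings come back from answer generators as free text inside
#' structured output and are rarely clean numbers: `"85"`, `"85%"`,
#' `" 85 % "` and `85` must all map to `85`.  Non-numeric strings become
#' `NA` and are counted rather than raising, because a handful of malformed
#' ratings should not abort a 2000-call log.
#'
#' @param raw character or numeric vector of raw confidence values.
#' @param fraction if `TRUE`, values in `(0, 1]` are treated as
#'   probabilities and rescaled to percent. Off by default: a model that
#'   answers "1" almost always means 1 percent, not certainty.
#' @return Numeric vector in `[0, 100]` (`NA` where unparseable), with
#'   attributes `n_unparseable` and `n_clamped` counting deviations.
#'   Values outside `[0, 100]` are clamped, with a warning.
#' @examples
#' parse_confidence(c("80%", " 95 ", "high", "120"))
#' @export
parse_confidence <- function(raw, fraction = FALSE) {
  if (is.list(raw)) raw <- vapply(raw, function(v) {
    if (is.null(v) || length(v) == 0L) NA_character_ else as.character(v[[1L]])
  }, character(1))
  txt <- trimws(as.character(raw))
  txt <- sub("%\\s*$", "", txt)
  txt[!nzchar(txt)] <- NA_character_
  val <- suppressWarnings(as.numeric(txt))
  n_unparseable <- sum(is.na(val) & !is.na(txt))
  if (fraction) {
    frac <- !is.na(val) & val > 0 & val <= 1
    val[frac] <- val[frac] * 100
  }
  out_of_range <- !is.na(val) & (val < 0 | val > 100)
  n_clamped <- sum(out_of_range)
  if (n_clamped > 0L) {
    warnf("%d confidence value(s) outside [0, 100] clamped", n_clamped)
    val <- pmin(pmax(val, 0), 100)
  }
  structure(val, n_unparseable = n_unparseable, n_clamped = n_clamped)
}

validate_records <- function(df, strict, origin) {
  reasons <- character(nrow(df))
  bad <- function(cond, why) {
    hit <- which(cond & !nzchar(reasons))
    reasons[hit] <<- why
  }
  bad(is.na(df$case_id) | !nzchar(df$case_id), "missing case_id")
  bad(is.na(df$model_id) | !nzchar(df$model_id), "missing model_id")
  rep_ok <- !is.na(df$repetition_index) & df$repetition_index >= 1 &
    df$repetition_index == round(df$repetition_index)
  bad(!rep_ok, "repetition_index not a positive integer")
  bad(is.na(df$answer) | !nzchar(df$answer), "missing answer")
  bad(!is.na(df$processing_time_s) & df$processing_time_s < 0,
      "negative processing_time_s")
  bad(!is.na(df$input_tokens) & df$input_tokens < 0, "negative input_tokens")
  bad(!is.na(df$output_tokens) & df$output_tokens < 0, "negative output_tokens")

  rejected <- nzchar(reasons)
  if (any(rejected) && strict) {
    first <- which(rejected)[1L]
    stopf("invalid record at %s line %d: %s", origin, first, reasons[first])
  }
  rejects <- data.frame(
    line = which(rejected),
    reason = reasons[rejected],
    stringsAsFactors = FALSE
  )
  out <- df[!rejected, , drop = FALSE]
  rownames(out) <- NULL
  out$repetition_index <- as.integer(out$repetition_index)
  attr(out, "rejects") <- rejects
  out
}

#' Read a response log
#'
#' Reads per-repetition answer records from JSON-lines (one object per
#' line) or CSV with header.  Confidence strings are normalized through
#' [parse_confidence()].  Under the default lenient mode, records failing
#' validation are routed to a rejects table (attribute `"rejects"`, columns
#' `line` and `reason`) so exclusions stay auditable; under strict mode the
#' first invalid record raises an error naming its line.
#'
#' @param path file to read.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @param strict abort on the first invalid record instead of rejecting it.
#' @param fraction passed to [parse_confidence()].
#' @return A data frame with columns `case_id`, `model_id`,
#'   `repetition_index`, `answer`, `confidence_pct`, `processing_time_s`,
#'   `input_tokens`, `output_tokens`, plus a `"rejects"` attribute.
#' @seealso [write_responses()], [group_responses()]
#' @export
read_responses <- function(path, format = NULL, strict = FALSE,
                           fraction = FALSE) {
  if (!file.exists(path)) stopf("cannot read response log: %s", path)
  format <- format %||%
    (if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv")
  format <- match.arg(format, c("jsonl", "csv"))
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    pick <- function(field) lapply(recs, function(r) r[[field]] %||% NA)
    df <- data.frame(
      case_id = as.character(unlist(pick("case_id"))),
      model_id = as.character(unlist(pick("model_id"))),
      repetition_index = suppressWarnings(as.numeric(unlist(pick("repetition_index")))),
      answer = as.character(unlist(pick("answer"))),
      stringsAsFactors = FALSE
    )
    df$confidence_pct <- as.numeric(parse_confidence(pick("confidence_pct"),
                                                     fraction = fraction))
    df$processing_time_s <- suppressWarnings(as.numeric(unlist(pick("processing_time_s"))))
    df$input_tokens <- suppressWarnings(as.numeric(unlist(pick("input_tokens"))))
    df$output_tokens <- suppressWarnings(as.numeric(unlist(pick("output_tokens"))))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    missing_cols <- setdiff(c("case_id", "model_id", "repetition_index", "answer"),
                            names(df))
    if (length(missing_cols))
      stopf("response CSV lacks column(s): %s", paste(missing_cols, collapse = ", "))
    for (f in setdiff(RESPONSE_FIELDS, names(df))) df[[f]] <- NA_character_
    df <- df[RESPONSE_FIELDS]
    df$repetition_index <- suppressWarnings(as.numeric(df$repetition_index))
    df$confidence_pct <- as.numeric(parse_confidence(df$confidence_pct,
                                                     fraction = fraction))
    for (f in c("processing_time_s", "input_tokens", "output_tokens"))
      df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }
  validate_records(df, strict = strict, origin = path)
}

#' Write a response log
#'
#' Inverse of [read_responses()]: emits the same JSON-lines or CSV dialect,
#' so `read_responses(write_responses(x))` round-trips field for field.
#'
#' @param records response record data frame.
#' @param path output file.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  records <- as.data.frame(records)[RESPONSE_FIELDS]
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      row <- as.list(records[i, ])
      row <- row[!vapply(row, function(v) is.na(v), logical(1))]
      as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(records, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a case table
#'
#' One row per quiz case: its ordered option labels (serialized as a
#' `"|"`-joined string), the designated ground-truth option, an optional
#' ISO-8601 publication date, and free-form tags.
#'
#' @param path CSV file with columns `case_id`, `options`, `ground_truth`,
#'   and optionally `published_date` and `tags`.
#' @return Data frame with `options` and `tags` kept as `"|"`-joined
#'   strings and `published_date` parsed to `Date`.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stopf("cannot read case table: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  need <- c("case_id", "options", "ground_truth")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("case table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if ("published_date" %in% names(df)) {
    blank <- is.na(df$published_date) | !nzchar(df$published_date)
    df$published_date[blank] <- NA
    df$published_date <- as.Date(df$published_date)
  } else df$published_date <- as.Date(NA)
  if (!"tags" %in% names(df)) df$tags <- ""
  validate_cases(df)
  df
}

validate_cases <- function(cases) {
  if (anyDuplicated(cases$case_id))
    stopf("duplicate case_id in case table: %s",
          paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "))
  for (i in seq_len(nrow(cases))) {
    opts <- case_options(cases$options[i])
    if (length(opts) < 2L || anyDuplicated(opts))
      stopf("case %s: needs >= 2 distinct options, got '%s'",
            cases$case_id[i], cases$options[i])
    if (!cases$ground_truth[i] %in% opts)
      stopf("case %s: ground truth '%s' not among options '%s'",
            cases$case_id[i], cases$ground_truth[i], cases$options[i])
  }
  invisible(cases)
}

#' Split a serialized option string into labels
#'
#' @param options `"|"`-joined option string, e.g. `"A|B|C|D|E"`.
#' @return Character vector of labels in canonical (stated) order.
#' @export
case_options <- function(options) strsplit(options, "|", fixed = TRUE)[[1L]]

#' Write a case table
#'
#' @param cases case data frame as returned by [read_cases()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  out <- as.data.frame(cases)
  out$published_date <- format(out$published_date, "%Y-%m-%d")
  out$published_date[is.na(out$published_date)] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Group response records into per-(case, model) response sets
#'
#' Joins a response log to its case table and partitions it into one
#' response set per `(case_id, model_id)` pair, ordered by repetition
#' index.  Membership of every answer in its case's option set is enforced
#' here, at join time.
#'
#' @param records response record data frame ([read_responses()]).
#' @param cases case table ([read_cases()]).
#' @return List of `response_set` objects; each carries the case's option
#'   set and ground truth plus parallel vectors `answers`, `conf`,
#'   `processing_time_s`, `input_tokens`, `output_tokens` ordered by
#'   `repetition_index`.
#' @export
group_responses <- function(records, cases) {
  if (nrow(records) == 0L) return(list())
  validate_cases(cases)
  orphans <- setdiff(unique(records$case_id), cases$case_id)
  if (length(orphans))
    stopf("records reference unknown case id(s): %s",
          paste(orphans, collapse = ", "))
  case_idx <- match(records$case_id, cases$case_id)
  key <- paste(records$case_id, records$model_id, sep = "\r")
  sets <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    sub <- records[idx, , drop = FALSE]
    ci <- case_idx[idx[1L]]
    opts <- case_options(cases$options[ci])
    dup <- sub$repetition_index[duplicated(sub$repetition_index)]
    if (length(dup))
      stopf("case %s, model %s: duplicate repetition_index %s",
            sub$case_id[1L], sub$model_id[1L], paste(unique(dup), collapse = ", "))
    bad <- !(sub$answer %in% opts)
    if (any(bad))
      stopf("case %s, model %s, repetition %s: answer '%s' not in option set {%s}",
            sub$case_id[1L], sub$model_id[1L],
            sub$repetition_index[which(bad)[1L]], sub$answer[which(bad)[1L]],
            paste(opts, collapse = ", "))
    ord <- order(sub$repetition_index)
    sub <- sub[ord, , drop = FALSE]
    structure(list(
      case_id = sub$case_id[1L],
      model_id = sub$model_id[1L],
      options = opts,
      ground_truth = cases$ground_truth[ci],
      published_date = cases$published_date[ci],
      repetition_index = sub$repetition_index,
      answers = sub$answer,
      conf = sub$confidence_pct,
      processing_time_s = sub$processing_time_s,
      input_tokens = sub$input_tokens,
      output_tokens = sub$output_tokens,
      n = nrow(sub)
    ), class = "response_set")
  })
  names(sets) <- vapply(sets, function(s) paste(s$case_id, s$model_id, sep = "::"),
                        character(1))
  sets[order(names(sets))]
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set> case %s, model %s: %d repetition(s), options {%s}, truth %s\n",
              x$case_id, x$model_id, x$n, paste(x$options, collapse = ""),
              x$ground_truth))
  invisible(x)
}

#' Write confidence profiles to CSV
#'
#' Flat table, one row per (case, model, repetition depth), carrying every
#' metric value, each metric's representative answer and its correctness
#' flag.  Numeric columns survive a write/read round trip to at least 12
#' significant digits.
#'
#' @param profiles profile data frame from [build_profiles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    stopf("no profiles to write")
  utils::write.csv(profiles, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read confidence profiles written by [write_profiles()]
#'
#' @param path CSV path.
#' @return Profile data frame with the original column types restored.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stopf("cannot read profiles: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (col in grep("^correct_", names(df), value = TRUE))
    df[[col]] <- as.logical(df[[col]])
  for (col in intersect(c("majority_tie", "tws_tie"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}
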