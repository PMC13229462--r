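# Dirichlet-multinomial response simulator.
#
# The generator emulates the statistical structure of repeated
# multiple-choice querying of a stochastic answer generator: per case a
# latent modal option (equal to the truth with probability `accuracy`),
# an answer-probability vector drawn from a Dirichlet concentrated on
# that modal option, i.i.d. categorical answers from it, and verbalized
# confidences clustered high around option-dependent means.  Agreement is
# allowed to depend on correctness -- a separate, lower concentration when
# the modal answer is wrong reproduces the empirical regime in which a
# model dithers more on the cases it gets wrong, which is exactly what
# makes consistency-based confidence metrics discriminative.  Confidence
# is tied to the latent modal option, not the truth, so the generator
# reproduces confidently-wrong behaviour; a calibrated mode instead sets
# confidence to the case's true correctness probability, for
# calibration-oracle checks.

#' Configuration for the response simulator
#'
#' Defaults describe the regime the pipeline targets: 94 cases with k = 5
#' options and 20 repetitions each; accuracy 0.6 (the middle of the
#' 44-74% range typical of current multimodal models on such quizzes);
#' Dirichlet concentrations 70 (modal answer correct) and 22 (modal
#' answer wrong), which together yield high but imperfect agreement
#' (overall Fleiss kappa near 0.75-0.80) with visibly more dissent on
#' wrong cases; and high, overconfident verbalized confidences (means
#' 85/72 against a 60% accuracy).
#'
#' @param n_cases number of quiz cases.
#' @param k options per case (default 5).
#' @param n_reps repetitions per (case, model) (default 20).
#' @param accuracy probability the latent modal option equals the truth.
#' @param concentration Dirichlet weight on the modal option when the
#'   modal answer is correct (all other options get weight 1); larger
#'   means higher agreement, `Inf` (capped internally) means unanimity.
#' @param concentration_incorrect Dirichlet weight on the modal option
#'   when the modal answer is wrong; lower than `concentration` makes
#'   wrong cases less consistent, the mechanism behind consistency-based
#'   discrimination.  Set equal to `concentration` for a fully
#'   exchangeable (consistency-uninformative) generator.
#' @param conf_mu_correct,conf_mu_incorrect mean verbalized confidence
#'   when the chosen option is / is not the latent modal option.
#' @param conf_sd confidence noise SD (>= 0).
#' @param overconfidence_shift added to every confidence before clamping
#'   to `[0, 100]`.
#' @param conf_mode `"verbalized"` (default) draws noisy option-linked
#'   confidences; `"calibrated"` sets every confidence to 100 x the
#'   case's probability mass on the true option.
#' @param conf_link in verbalized mode, whether the high confidence mean
#'   attaches to responses choosing the latent modal option (default --
#'   the generator stays confidently wrong on wrong-modal cases) or to
#'   responses choosing the `"truth"` (an independently informative
#'   verbalized channel).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cases = 94L, k = 5L, n_reps = 20L,
                         accuracy = 0.6, concentration = 70,
                         concentration_incorrect = 22,
                         conf_mu_correct = 85, conf_mu_incorrect = 72,
                         conf_sd = 8, overconfidence_shift = 0,
                         conf_mode = c("verbalized", "calibrated"),
                         conf_link = c("modal", "truth"),
                         seed = 1L) {
  conf_mode <- match.arg(conf_mode)
  conf_link <- match.arg(conf_link)
  stopifnot(
    is_scalar(n_cases) && n_cases >= 1,
    is_scalar(k) && k >= 2,
    is_scalar(n_reps) && n_reps >= 1,
    is_scalar(accuracy) && accuracy > 0 && accuracy <= 1,
    length(concentration) == 1L && concentration > 0,
    length(concentration_incorrect) == 1L && concentration_incorrect > 0,
    is_scalar(conf_mu_correct) && conf_mu_correct >= 0 && conf_mu_correct <= 100,
    is_scalar(conf_mu_incorrect) && conf_mu_incorrect >= 0 && conf_mu_incorrect <= 100,
    is_scalar(conf_sd) && conf_sd >= 0,
    is_scalar(overconfidence_shift),
    is_scalar(seed)
  )
  structure(list(
    n_cases = as.integer(n_cases), k = as.integer(k),
    n_reps = as.integer(n_reps), accuracy = accuracy,
    concentration = min(concentration, 1e8),
    concentration_incorrect = min(concentration_incorrect, 1e8),
    conf_mu_correct = conf_mu_correct, conf_mu_incorrect = conf_mu_incorrect,
    conf_sd = conf_sd, overconfidence_shift = overconfidence_shift,
    conf_mode = conf_mode, conf_link = conf_link, seed = as.integer(seed)
  ), class = "synth_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) {                       # huge concentration underflow guard
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Simulate a response log for one model
#'
#' Per case: a uniformly drawn ground truth; a latent modal option equal
#' to the truth with probability `accuracy`, otherwise uniform over the
#' remaining options; an answer-probability vector from a Dirichlet with
#' weight `concentration` (modal correct) or `concentration_incorrect`
#' (modal wrong) on the modal option and 1 elsewhere; `n_reps` i.i.d.
#' answers from it.  Verbalized mode draws each confidence from a normal
#' around `conf_mu_correct` (answer = the `conf_link` target) or
#' `conf_mu_incorrect`, shifts by `overconfidence_shift`, and clamps to
#' `[0, 100]`; calibrated mode reports 100 x the case's probability mass
#' on the true option (plus the shift).
#' Processing times and token counts are log-normal draws (arbitrary but
#' documented scales: time around 20 s, input around 4000 and output
#' around 800 tokens per call) so resource accounting is exercised.
#' Publication dates are drawn so roughly three quarters of cases predate
#' 2025-02-01, giving both temporal strata.
#'
#' @param config a [synth_config()].
#' @param model_id model identifier stamped on every record.
#' @param cases optionally, an existing case table to answer (the study
#'   design queries every model on the same cases); its option sets and
#'   ground truths are reused and `config$n_cases`/`config$k` must match.
#'   By default a fresh case table is drawn.
#' @return List with `cases` (case table) and `responses` (response record
#'   data frame), both in the package's standard dialects, plus `latent`:
#'   the per-case modal option, whether it equals the truth, the
#'   probability mass on the truth, and the drawn answer-probability
#'   vector (columns `p_1..p_k`) -- the generator-side quantities oracle
#'   checks compare against.
#' @export
simulate_model <- function(config, model_id = "synthetic-model",
                           cases = NULL) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    k <- config$k
    opts <- if (k <= 26) LETTERS[seq_len(k)] else paste0("O", seq_len(k))
    n <- config$n_reps
    if (is.null(cases)) {
      case_ids <- sprintf("case%03d", seq_len(config$n_cases))
      truth_idx <- sample.int(k, config$n_cases, replace = TRUE)
      pre <- stats::runif(config$n_cases) < 72 / 94
      dates <- as.Date(ifelse(
        pre,
        as.Date("2000-07-28") + floor(stats::runif(config$n_cases) *
          as.numeric(as.Date("2025-01-31") - as.Date("2000-07-28") + 1)),
        as.Date("2025-02-01") + floor(stats::runif(config$n_cases) *
          as.numeric(as.Date("2025-12-25") - as.Date("2025-02-01") + 1))
      ), origin = "1970-01-01")
      tags <- sample(c("ultrasound", "ct", "mri", "radiograph"),
                     config$n_cases, replace = TRUE)
      cases <- data.frame(
        case_id = case_ids,
        options = paste(opts, collapse = "|"),
        ground_truth = opts[truth_idx],
        published_date = dates,
        tags = tags,
        stringsAsFactors = FALSE
      )
    } else {
      validate_cases(cases)
      if (nrow(cases) != config$n_cases)
        stopf("config expects %d cases but the supplied table has %d",
              config$n_cases, nrow(cases))
      if (any(vapply(cases$options, function(o) length(case_options(o)),
                     integer(1)) != k))
        stopf("supplied case table does not have k = %d options per case", k)
      opts_by_case <- lapply(cases$options, case_options)
      if (any(vapply(opts_by_case, function(o) !identical(o, opts), logical(1))))
        stopf("supplied case table uses a different option labelling")
      case_ids <- cases$case_id
      truth_idx <- match(cases$ground_truth, opts)
    }
    rows <- vector("list", config$n_cases)
    latent <- data.frame(case_id = case_ids, modal = NA_character_,
                         modal_correct = NA, p_truth = NA_real_,
                         stringsAsFactors = FALSE)
    pmat <- matrix(NA_real_, config$n_cases, k,
                   dimnames = list(NULL, paste0("p_", seq_len(k))))
    for (i in seq_len(config$n_cases)) {
      modal_ok <- stats::runif(1) < config$accuracy
      modal <- if (modal_ok) truth_idx[i]
               else sample(setdiff(seq_len(k), truth_idx[i]), 1L)
      alpha <- rep(1, k)
      alpha[modal] <- if (modal_ok) config$concentration
                      else config$concentration_incorrect
      p <- rdirichlet1(alpha)
      ans_idx <- sample.int(k, n, replace = TRUE, prob = p)
      conf <- if (config$conf_mode == "calibrated") {
        rep(100 * p[truth_idx[i]], n)
      } else {
        target <- if (config$conf_link == "truth") truth_idx[i] else modal
        mu <- ifelse(ans_idx == target, config$conf_mu_correct,
                     config$conf_mu_incorrect)
        stats::rnorm(n, mu, config$conf_sd)
      }
      conf <- pmin(pmax(conf + config$overconfidence_shift, 0), 100)
      latent$modal[i] <- opts[modal]
      latent$modal_correct[i] <- modal == truth_idx[i]
      latent$p_truth[i] <- p[truth_idx[i]]
      pmat[i, ] <- p
      rows[[i]] <- data.frame(
        case_id = case_ids[i],
        model_id = model_id,
        repetition_index = seq_len(n),
        answer = opts[ans_idx],
        confidence_pct = round(conf, 6),
        processing_time_s = round(stats::rlnorm(n, log(20), 0.4), 3),
        input_tokens = round(stats::rlnorm(n, log(4000), 0.25)),
        output_tokens = round(stats::rlnorm(n, log(800), 0.35)),
        stringsAsFactors = FALSE
      )
    }
    responses <- do.call(rbind, rows)
    rownames(responses) <- NULL
    list(cases = cases, responses = responses,
         latent = cbind(latent, as.data.frame(pmat)))
  })
}

#' Monte-Carlo Fleiss-kappa target of a generator configuration
#'
#' Simulates a large number of cases directly from the generator's answer
#' mechanism (no pipeline involved) and returns the Fleiss kappa of the
#' resulting agreement table -- the reference value a pipeline run on the
#' same configuration should approach.
#'
#' @param config a [synth_config()].
#' @param n_mc_cases Monte-Carlo sample size (default 2000).
#' @param seed seed for the target computation (independent of the
#'   generator's own seed).
#' @return Scalar kappa target.
#' @export
kappa_target <- function(config, n_mc_cases = 2000L, seed = 990001L) {
  local_seed(seed, {
    k <- config$k
    n <- config$n_reps
    tab <- t(vapply(seq_len(n_mc_cases), function(i) {
      modal <- sample.int(k, 1L)
      alpha <- rep(1, k)
      alpha[modal] <- if (stats::runif(1) < config$accuracy)
        config$concentration else config$concentration_incorrect
      p <- rdirichlet1(alpha)
      tabulate(sample.int(k, n, replace = TRUE, prob = p), k)
    }, integer(k)))
    fleiss_kappa(tab)$kappa
  })
}

#' Default recovery grid
#'
#' The canonical cells exercised by the recovery suite: a zero-information
#' null (uniform answer probabilities, constant confidence), a calibrated
#' cell (confidence = true correctness probability), an overconfident
#' cell (calibrated + 20-point shift), an informative cell where both
#' consistency and verbalized confidence carry signal, and a 3-point
#' concentration ladder for the kappa trend.
#'
#' @param n_cases_null,n_cases_cal cases for the null and
#'   calibrated/overconfident cells.
#' @return Data frame of cell definitions consumed by [recovery_suite()].
#' @export
recovery_grid <- function(n_cases_null = 300L, n_cases_cal = 500L) {
  data.frame(
    cell = c("null", "calibrated", "overconfident", "informative",
             "kappa_lo", "kappa_mid", "kappa_hi"),
    n_cases = c(n_cases_null, n_cases_cal, n_cases_cal, n_cases_null,
                n_cases_null, n_cases_null, n_cases_null),
    accuracy = c(0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6),
    concentration = c(1, 70, 70, 70, 10, 35, 120),
    concentration_incorrect = c(1, 22, 22, 22, 10, 35, 120),
    conf_mode = c("verbalized", "calibrated", "calibrated", "verbalized",
                  "verbalized", "verbalized", "verbalized"),
    conf_link = c("modal", "modal", "modal", "truth",
                  "modal", "modal", "modal"),
    conf_mu_correct = c(80, NA, NA, 85, 85, 85, 85),
    conf_mu_incorrect = c(80, NA, NA, 65, 72, 72, 72),
    conf_sd = c(0, NA, NA, 8, 8, 8, 8),
    overconfidence_shift = c(0, 0, 20, 0, 0, 0, 0),
    replicates = c(1L, 1L, 1L, 5L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Run the full pipeline over a grid of generator configurations
#'
#' For every grid cell (and replicate), simulates a response log, writes
#' nothing, pushes the log through grouping, profile construction and
#' model evaluation at full depth, and records the realized Fleiss kappa
#' (with its Monte-Carlo target), majority-vote accuracy, and each
#' metric's AUC and ECE.  The suite is the package's parameter-recovery
#' harness: on cells with no information all AUCs should hover at 0.5, on
#' calibrated cells ECE should be small, on overconfident cells the
#' self-reported ECE should inflate, and realized kappa should track the
#' concentration ladder.
#'
#' @param grid data frame of cells as produced by [recovery_grid()].
#' @param seed master seed; per-(cell, replicate) seeds are derived from
#'   it so cells are independent and reproducible.
#' @param n_reps repetitions per case (default 20).
#' @param k options per case (default 5).
#' @return Data frame, one row per (cell, replicate), with columns
#'   `kappa`, `kappa_target`, `accuracy_majority_pct`, and per-metric
#'   `auc_*` / `ece_*` values.
#' @export
recovery_suite <- function(grid = recovery_grid(), seed = 20260101L,
                           n_reps = 20L, k = 5L) {
  if (nrow(grid) == 0L) stopf("empty recovery grid")
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    for (r in seq_len(cell$replicates)) {
      cell_seed <- (seed + 7919L * g + 104729L * r) %% .Machine$integer.max
      cfg <- synth_config(
        n_cases = cell$n_cases, k = k, n_reps = n_reps,
        accuracy = cell$accuracy, concentration = cell$concentration,
        concentration_incorrect = cell$concentration_incorrect,
        conf_mu_correct = if (is.na(cell$conf_mu_correct)) 85 else cell$conf_mu_correct,
        conf_mu_incorrect = if (is.na(cell$conf_mu_incorrect)) 72 else cell$conf_mu_incorrect,
        conf_sd = if (is.na(cell$conf_sd)) 8 else cell$conf_sd,
        overconfidence_shift = cell$overconfidence_shift,
        conf_mode = cell$conf_mode,
        conf_link = cell$conf_link,
        seed = cell_seed
      )
      sim <- simulate_model(cfg, model_id = cell$cell)
      sets <- group_responses(sim$responses, sim$cases)
      profiles <- build_profiles(sets, depths = n_reps)
      ev <- evaluate_model(profiles, cell$cell, depth = n_reps, iters = 0L)
      fk <- fleiss_kappa(agreement_table(sets, n_reps))
      row <- data.frame(
        cell = cell$cell, replicate = r, n_cases = cell$n_cases,
        concentration = cell$concentration,
        kappa = fk$kappa,
        kappa_target = kappa_target(cfg),
        accuracy_majority_pct = 100 * mean(profiles$correct_majority),
        stringsAsFactors = FALSE
      )
      for (m in ev$metric) {
        row[[paste0("auc_", m)]] <- ev$auc[ev$metric == m]
        row[[paste0("ece_", m)]] <- ev$ece[ev$metric == m]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
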