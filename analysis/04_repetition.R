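#!/usr/bin/env Rscript
# Repetition-depth analyses: first-output vs majority-vote accuracy with a
# Cochran Q test per model, Fleiss kappa repeatability by depth, and the
# Fisher-exact temporal holdout around the 2025-02-01 cutoff.  Outputs:
# results/depth_accuracy.csv, results/kappa_by_depth.csv,
# results/temporal_holdout.csv.

suppressMessages(library(repconf))

data_dir <- file.path("results", "data")
records <- read_responses(file.path(data_dir, "responses.jsonl"))
cases <- read_cases(file.path(data_dir, "cases.csv"))
sets <- group_responses(records, cases)
profiles <- read_profiles(file.path("results", "profiles.csv"))

depths <- c(1L, 5L, 10L, 15L, 20L)
models <- sort(unique(vapply(sets, `[[`, character(1), "model_id")))

acc <- NULL
kap <- NULL
hold <- NULL
for (m in models) {
  msets <- Filter(function(s) s$model_id == m, sets)
  da <- depth_accuracy(msets, depths = depths)
  cq <- cochran_q(depth_correct_matrix(msets, depths))
  da$cochran_q <- cq$Q
  da$cochran_p <- cq$p
  acc <- rbind(acc, da)

  kd <- kappa_by_depth(msets)
  kd$model_id <- m
  kap <- rbind(kap, kd)

  th <- temporal_holdout(profiles[profiles$model_id == m, ], cases,
                         cutoff_date = "2025-02-01", depth = 20L)
  hold <- rbind(hold, data.frame(
    model_id = m,
    pre_correct = th$table["pre", "correct"],
    pre_incorrect = th$table["pre", "incorrect"],
    post_correct = th$table["post", "correct"],
    post_incorrect = th$table["post", "incorrect"],
    odds_ratio = th$odds_ratio, p = th$p, n_excluded = th$n_excluded,
    stringsAsFactors = FALSE
  ))
  message(sprintf(
    "%s: first %.1f%% -> majority@20 %.1f%% (Cochran Q %.2f, p %.3f); kappa@20 %.2f (%s); holdout p %.2f",
    m, da$accuracy_pct[da$depth == 1], da$accuracy_pct[da$depth == 20],
    cq$Q, cq$p, kd$kappa[kd$depth == 20], kd$band[kd$depth == 20], th$p))
}

utils::write.csv(acc, file.path("results", "depth_accuracy.csv"), row.names = FALSE)
utils::write.csv(kap, file.path("results", "kappa_by_depth.csv"), row.names = FALSE)
utils::write.csv(hold, file.path("results", "temporal_holdout.csv"), row.names = FALSE)
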