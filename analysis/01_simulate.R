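#!/usr/bin/env Rscript
# Generate the study bed: four synthetic answer generators spanning the
# accuracy range seen in current multimodal models on multiple-choice
# radiology quizzes (three "reasoner" profiles and one faster, less
# accurate "general" profile), each queried 20 times on the same 94
# five-option cases.  Logs are written in the package's JSON-lines / CSV
# dialects under results/data/.

suppressMessages(library(repconf))

seed <- 20260101L
out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

models <- data.frame(
  model_id = c("reasoner_1", "reasoner_2", "reasoner_3", "general_1"),
  accuracy = c(0.74, 0.67, 0.55, 0.44),
  stringsAsFactors = FALSE
)

# one shared case table, answered by every model
cases <- simulate_model(synth_config(n_cases = 94L, seed = seed), "draft")$cases
write_cases(cases, file.path(out_dir, "cases.csv"))

all_responses <- NULL
for (i in seq_len(nrow(models))) {
  cfg <- synth_config(n_cases = 94L, accuracy = models$accuracy[i],
                      seed = seed + i)
  sim <- simulate_model(cfg, models$model_id[i], cases = cases)
  all_responses <- rbind(all_responses, sim$responses)
  message(sprintf("%s: accuracy setting %.2f, %d records",
                  models$model_id[i], models$accuracy[i], nrow(sim$responses)))
}

write_responses(all_responses, file.path(out_dir, "responses.jsonl"), "jsonl")
message(sprintf("wrote %d records for %d models to %s",
                nrow(all_responses), nrow(models), out_dir))
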