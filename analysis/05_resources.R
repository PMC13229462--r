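#!/usr/bin/env Rscript
# Cumulative per-case processing time and token consumption by
# repetition-count condition, with a census of extreme (> 500 s) calls.
# Output: results/resources.csv.

suppressMessages(library(repconf))

records <- read_responses(file.path("results", "data", "responses.jsonl"))
rs <- summarize_resources(records)
utils::write.csv(rs, file.path("results", "resources.csv"), row.names = FALSE)

for (m in unique(rs$model_id)) {
  sub <- rs[rs$model_id == m & rs$depth == 20L, ]
  message(sprintf("%s @ 20 reps: %.1f (SD %.1f) s, %.0f (SD %.0f) tokens, %d extreme call(s)",
                  m, sub$mean_time_s, sub$sd_time_s, sub$mean_total_tokens,
                  sub$sd_total_tokens, sub$n_extreme_calls))
}
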