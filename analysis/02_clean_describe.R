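#!/usr/bin/env Rscript
# Step 2: read the raw CSV back, apply the exclusion rule (any 0/-1 code
# drops the whole record), and tabulate per-item descriptives.

library(affecthmm)

tab <- read_submissions("scratch/analysis/dataset.csv")
cl <- clean_submissions(tab)

cat(sprintf("cleaning: %d records in, %d excluded for invalid codes, %d retained (%.2f%%)\n",
            cl$report$n_input, cl$report$excluded_invalid_code,
            cl$report$n_retained, 100 * cl$report$survivor_fraction))

jsonlite::write_json(cl$report, "results/analysis/02_exclusion_report.json",
                     auto_unbox = TRUE, pretty = TRUE)

desc <- descriptive_stats(cl$sequence)
write.csv(desc$overall, "results/analysis/02_descriptives.csv",
          row.names = FALSE)
cat("per-item descriptives (1-5 Likert scale):\n")
print(desc$overall, digits = 3)

write_observations(cl$sequence, "scratch/analysis/cleaned.csv")

bins <- assign_time_bins(cl$sequence)
cat("time-bin counts:\n")
print(table(bins))
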