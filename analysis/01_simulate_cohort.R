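#!/usr/bin/env Rscript
# Step 1: generate the synthetic rat cohort that stands in for the study's
# concentration data — IV bolus n = 5, oral gavage n = 3, 4-h supralingual
# patch n = 3, all at 0.5 mg/kg, sampled on the study schedules, with
# lognormal between-animal variability at the published mean +/- SD level,
# 15% proportional assay noise, and LLOQ censoring at 0.5 ng/mL.

suppressPackageStartupMessages(library(ehrpk))
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(seed = 20210417 %% 1e6)
cohort <- generate_cohort(spec)
write_dataset(cohort, "results/cohort.csv")

cat("Simulated", length(unique(cohort$subject_id)), "animals,",
    nrow(cohort), "records ->  results/cohort.csv\n")
for (r in ROUTES) {
  sub <- cohort[cohort$route == r, ]
  cat(sprintf("  %-12s %d animals, %d records, %d BLQ (%.0f%%)\n", r,
              length(unique(sub$subject_id)), nrow(sub), sum(sub$blq),
              100 * mean(sub$blq)))
}
cat("The supralingual records stay BLQ before the 0.5 h release lag and\n",
    "mostly single-digit ng/mL afterwards - the patch keeps systemic\n",
    "exposure far below the other routes.\n")
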