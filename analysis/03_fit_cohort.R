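#!/usr/bin/env Rscript

# Step 3 — trait estimation and parameter recovery.
#
# Fits the full trait model to each synthetic rat by simulation-based
# maximum likelihood on the joint RGT + reversal profiles (50 simulated
# sessions per likelihood evaluation, common random numbers), then
# compares estimated and generating traits: correlations, median-split
# group correlations, and re-simulation classification agreement.

suppressPackageStartupMessages(library(rgtraits))

dir.create("results", showWarnings = FALSE)
cohort <- gen_cohort(cohort_spec(n_good = 6, n_poor = 6, seed = 1))
ids <- vapply(cohort, `[[`, "", "rat_id")

fits <- setNames(vector("list", length(cohort)), ids)
for (i in seq_along(cohort)) {
  r <- cohort[[i]]
  fits[[r$rat_id]] <- fit_joint(r$rgt_profile, r$reversal_profile,
                                seed = 1000 + i)
  cat(sprintf("%s (%s): logL = %.2f\n", r$rat_id, r$archetype,
              fits[[r$rat_id]]$log_likelihood))
  write_fit_json(fits[[r$rat_id]],
                 file.path("results", paste0("fit_", r$rat_id, ".json")))
}

report <- recovery_report(cohort, fits, seed = 7)
write.csv(report$trait_table, "results/recovery_traits.csv",
          row.names = FALSE)
write.csv(report$per_rat, "results/recovery_per_rat.csv",
          row.names = FALSE)

cat("\nPer-trait recovery (true vs estimated):\n")
print(report$trait_table)
cat(sprintf("\nClassification agreement (archetype vs re-simulated fit): %.0f%%\n",
            100 * report$classification_agreement))
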