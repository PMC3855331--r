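#!/usr/bin/env Rscript

# Step 5 — trait profiling statistics.
#
# On the 12-rat ground-truth cohort: end-of-session Q-value summary by
# group (poor decision makers over-value the disadvantageous pair),
# median-split trait profiles (poor rats accumulate high marks across
# traits), the sum-of-ranks global index, and Monte-Carlo permutation
# correlations between behavioural measures and generating traits.

suppressPackageStartupMessages(library(rgtraits))

dir.create("results", showWarnings = FALSE)
cohort <- gen_cohort(cohort_spec(n_good = 6, n_poor = 6, seed = 1))
tab <- cohort_table(cohort)

# Q-value valuation by classification group
recs <- split(lapply(cohort, `[[`, "rgt_record"), tab$group_label)
qs <- qvalue_summary(recs)
write.csv(qs, "results/qvalue_summary.csv", row.names = FALSE)
cat("End-of-session valuations by group:\n")
print(qs)

# behavioural battery: orientations map each measure to its poor-like side
measures <- tab[, c("collect_latency_s", "emergence_latency_s",
                    "risk_assessments", "fi_presses",
                    "flexibility_percent")]
ori <- c(collect_latency_s = -1,    # short latency = reward seeking
         emergence_latency_s = -1,  # early emergence = risk taking
         risk_assessments = -1,     # few assessments = risk taking
         fi_presses = 1,            # high activity = impulsivity-like
         flexibility_percent = -1)  # low flexibility = inflexibility

marks <- median_split_profile(measures, ori)
marks <- cbind(rat_id = tab$rat_id, archetype = tab$archetype, marks)
write.csv(marks, "results/median_split_profile.csv", row.names = FALSE)
cat("\nHigh-trait marks per rat (median split):\n")
print(aggregate(n_high ~ archetype, marks, mean))

gi <- global_index(measures, ori)
gi <- cbind(rat_id = tab$rat_id, archetype = tab$archetype, gi)
write.csv(gi, "results/global_index.csv", row.names = FALSE)

# permutation correlations between measures and generating traits
set.seed(99)
cors <- rbind(
  data.frame(pair = "omega_vs_collect_latency",
             with(tab, mc_permutation_corr(omega, collect_latency_s,
                                           n_perm = 10000))[c("r", "p_value")]),
  data.frame(pair = "rho_vs_risk_assessments",
             with(tab, mc_permutation_corr(rho, risk_assessments,
                                           n_perm = 10000))[c("r", "p_value")]),
  data.frame(pair = "area_alpha_vs_flexibility",
             with(tab, mc_permutation_corr(area_under_alpha,
                                           flexibility_percent,
                                           n_perm = 10000))[c("r", "p_value")]),
  data.frame(pair = "global_index_vs_rho",
             mc_permutation_corr(gi$index, tab$rho,
                                 n_perm = 10000)[c("r", "p_value")])
)
write.csv(cors, "results/trait_correlations.csv", row.names = FALSE)
cat("\nPermutation correlations (measures vs generating traits):\n")
print(cors)
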