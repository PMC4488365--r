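#!/usr/bin/env Rscript
# Step 3 — exposure associations with growth-pattern membership.
#
# With the model structure chosen in step 2 (K = 4, independence), each
# log10 serum exposure enters the concomitant multinomial-logit model one
# at a time, unadjusted and adjusted for the four confounders; the full
# mixture is re-estimated each time. Relative risk ratios compare each
# group to the flat reference group (group 4) for a ten-fold concentration
# increase, with Wald 95% CIs from the observed information of the full
# mixture likelihood. Sensitivity refits drop preterm and low-birth-weight
# children.

suppressPackageStartupMessages(library(trajmix))

seed <- 20260930L %% 100000L
panel <- filter_min_visits(read_long_panel("results/cohort_panel.csv"), 4)
baseline <- read_baseline("results/cohort_baseline.csv")

exposures <- c("log10_opDDT", "log10_ppDDT", "log10_ppDDE")
confounders <- c("years_usa", "mat_bmi", "birth_weight_kg",
                 "breastfeed_months")

rrr_tab <- suppressMessages(adjusted_and_unadjusted(
  panel, baseline, exposures = exposures, confounders = confounders,
  K = 4, cov_kind = "independence", seed = seed + 17L,
  n_starts = 4, burn_iter = 8))
write.csv(rrr_tab, "results/rrr_table.csv", row.names = FALSE)
cat("adjusted RRRs (ten-fold exposure increase, vs flat group 4):\n")
print(subset(rrr_tab, adjusted), digits = 3, row.names = FALSE)

sens_rows <- list()
for (rule in c("exclude_preterm", "exclude_low_birth_weight")) {
  sub <- stratify(panel, baseline, by = rule)[[1L]]
  tab <- suppressMessages(adjusted_and_unadjusted(
    sub$panel, sub$baseline, exposures = "log10_ppDDE",
    confounders = confounders, K = 4, cov_kind = "independence",
    seed = seed + 29L, n_starts = 4, burn_iter = 8))
  tab <- subset(tab, adjusted)
  tab$subset <- rule
  sens_rows[[rule]] <- tab
  cat(sprintf("\nsensitivity (%s): %d subjects retained\n",
              rule, length(panel_subjects(sub$panel))))
}
write.csv(do.call(rbind, c(sens_rows, make.row.names = FALSE)),
          "results/sensitivity_rrr.csv", row.names = FALSE)

scan <- suppressMessages(interaction_scan(
  panel, baseline, exposure = "log10_ppDDE",
  modifiers = confounders, K = 4, cov_kind = "independence",
  seed = seed + 43L, ci_method = "two_stage", n_starts = 3,
  burn_iter = 8))
write.csv(scan, "results/interaction_scan.csv", row.names = FALSE)
cat("\ninteraction scan (exposure x modifier, two-stage SEs):\n")
print(scan, digits = 3, row.names = FALSE)
cat("\nwrote results/rrr_table.csv, sensitivity_rrr.csv, interaction_scan.csv\n")
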