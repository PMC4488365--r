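#!/usr/bin/env Rscript
# Step 4 — end-to-end pipeline run and consolidated report.
#
# Re-runs the whole analysis through run_pipeline() on the simulated
# cohort (same seed), which reproduces steps 2-3 and adds the summary
# tables: per-sex group sizes, raw-BMI summaries by assigned group and
# visit age, posterior-uncertainty fractions, and dense mean-curve grids
# for plotting. Everything is written under results/pipeline/.

suppressPackageStartupMessages(library(trajmix))

seed <- 20260930L %% 100000L
panel <- read_long_panel("results/cohort_panel.csv")
baseline <- read_baseline("results/cohort_baseline.csv")

cfg <- pipeline_config(
  cohort = list(panel = panel, baseline = baseline),
  exposures = c("log10_opDDT", "log10_ppDDT", "log10_ppDDE"),
  confounders = c("years_usa", "mat_bmi", "birth_weight_kg",
                  "breastfeed_months"),
  em = list(n_starts = 8L),
  seed = seed, out_dir = "results/pipeline")

bundle <- suppressMessages(suppressWarnings(run_pipeline(cfg)))

cat("group sizes by sex:\n")
print(bundle$report$group_sizes, row.names = FALSE)
cat("\nraw BMI by assigned group and visit age (first rows):\n")
print(head(bundle$report$trajectory_summary, 10), digits = 3,
      row.names = FALSE)
cat("\nposterior uncertainty (fraction in (0.1, 0.9)):\n")
print(bundle$report$uncertainty, digits = 3, row.names = FALSE)
cat("\nwrote", length(list.files("results/pipeline")),
    "files under results/pipeline/\n")
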