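#!/usr/bin/env Rscript
# Reporter stage: gate the control and knockdown flow-event tables into
# HR (GFP+) and mutagenic-NHEJ (RFP+) percentages among BFP+ cells, and
# normalize both to the control's total repair efficiency.
# Reads results/data/reporter_*.csv; writes results/reporter/.

suppressPackageStartupMessages(library(nanofoci))

ind <- file.path("results", "data")
out <- file.path("results", "reporter")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ctl_ev <- read.csv(file.path(ind, "reporter_control.csv"))
kd_ev <- read.csv(file.path(ind, "reporter_knockdown.csv"))

ctl <- gate_events(ctl_ev)
kd <- gate_events(kd_ev)
rel_ctl <- normalize_repair(ctl, ctl)
rel_kd <- normalize_repair(kd, ctl)

message(sprintf("  control:   %.2f%% HR, %.2f%% NHEJ of %d BFP+ events",
                ctl$pct_hr, ctl$pct_nhej, ctl$n_bfp_pos))
message(sprintf("  knockdown: %.2f%% HR, %.2f%% NHEJ of %d BFP+ events",
                kd$pct_hr, kd$pct_nhej, kd$n_bfp_pos))
message(sprintf("  relative HR after knockdown: %.2f (control = %.2f)",
                rel_kd$rel_hr, rel_ctl$rel_hr))
message(sprintf("  HR reduced to %.0f%% of control",
                100 * rel_kd$rel_hr / rel_ctl$rel_hr))

jsonlite::write_json(
  list(control = c(ctl[c("pct_hr", "pct_nhej", "n_bfp_pos")],
                   rel_ctl, thresholds = list(ctl$thresholds)),
       knockdown = c(kd[c("pct_hr", "pct_nhej", "n_bfp_pos")],
                     rel_kd, thresholds = list(kd$thresholds)),
       hr_ratio_kd_vs_control = rel_kd$rel_hr / rel_ctl$rel_hr),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
message("done; outputs under ", out)
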