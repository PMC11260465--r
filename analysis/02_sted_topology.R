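#!/usr/bin/env Rscript
# STED stage: detect nanodomains in the simulated scenes (projection ->
# prominence maxima -> sub-pixel Gaussian fits), reconstruct focus
# topology (counts and radial distances within the 500 nm gate), average
# the focus-centred signal, and compare the two stainings with the
# two-tailed Mann-Whitney U test.
# Reads results/data/ from 01_simulate_data.R; writes results/topology/.

suppressPackageStartupMessages(library(nanofoci))

ind <- file.path("results", "data")
out <- file.path("results", "topology")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
stopifnot(dir.exists(ind))

analyse_condition <- function(nm) {
  files <- Sys.glob(file.path(ind, sprintf("sted_%s_*.tif", nm)))
  stopifnot(length(files) > 0)
  tabs <- list(); nanodomains <- list()
  avg_acc <- NULL; avg_n <- 0L
  params <- topology_params(crop_halfwidth_px = 10L)
  for (f in files) {
    st <- read_image_stack(f)
    nd <- rbind(detect_nanodomains(st, "center", tolerance = 10),
                detect_nanodomains(st, "partner", tolerance = 10))
    nd$image_id <- basename(f)
    nanodomains[[f]] <- nd
    tp <- focus_topology(nd, params = params)
    tp$table$image_id <- basename(f)
    tabs[[f]] <- tp$table
    if (nrow(tp$foci) > 0) {
      sa <- signal_average(max_intensity_project(st, "partner"), tp$foci,
                           params)
      avg_acc <- if (is.null(avg_acc)) sa$average$values * sa$n_used
                 else avg_acc + sa$average$values * sa$n_used
      avg_n <- avg_n + sa$n_used
    }
  }
  tab <- do.call(rbind, tabs)
  write.csv(do.call(rbind, nanodomains),
            file.path(out, sprintf("nanodomains_%s.csv", nm)),
            row.names = FALSE)
  write.csv(tab, file.path(out, sprintf("foci_%s.csv", nm)),
            row.names = FALSE)
  write_image_stack(
    image_stack(array(avg_acc / avg_n, c(1, 1, nrow(avg_acc),
                                         ncol(avg_acc))),
                22, 149.7, "partner_average"),
    file.path(out, sprintf("signal_average_%s.tif", nm)))
  message(sprintf(
    "  %s: %d foci | partner count %.2f +- %.2f | min dist %.0f +- %.0f nm",
    nm, nrow(tab), mean(tab$n_partners), sd(tab$n_partners),
    mean(tab$min_dist_nm, na.rm = TRUE),
    sd(tab$min_dist_nm, na.rm = TRUE)))
  tab
}

message("== Topology per condition ==")
prox <- analyse_condition("proximal")
peri <- analyse_condition("peripheral")

message("== Proximal vs peripheral ==")
cmp_min <- compare_groups(prox, peri, "min_dist")
cmp_cnt <- compare_groups(prox, peri, "count")
message(sprintf("  min distance: U = %g, p = %.3g (direction %d)",
                cmp_min$statistic_U, cmp_min$p_two_sided,
                cmp_min$direction))
message(sprintf("  counts:       U = %g, p = %.3g",
                cmp_cnt$statistic_U, cmp_cnt$p_two_sided))

summary <- list(
  proximal = list(n_foci = nrow(prox),
                  count_mean = mean(prox$n_partners),
                  count_sd = sd(prox$n_partners),
                  min_dist_mean_nm = mean(prox$min_dist_nm, na.rm = TRUE),
                  min_dist_sd_nm = sd(prox$min_dist_nm, na.rm = TRUE)),
  peripheral = list(n_foci = nrow(peri),
                    count_mean = mean(peri$n_partners),
                    count_sd = sd(peri$n_partners),
                    min_dist_mean_nm = mean(peri$min_dist_nm, na.rm = TRUE),
                    min_dist_sd_nm = sd(peri$min_dist_nm, na.rm = TRUE)),
  comparison = list(
    min_dist = list(U = cmp_min$statistic_U, p = cmp_min$p_two_sided),
    count = list(U = cmp_cnt$statistic_U, p = cmp_cnt$p_two_sided)))
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
message("done; outputs under ", out)
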