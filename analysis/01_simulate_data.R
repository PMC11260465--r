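#!/usr/bin/env Rscript
# Generate the synthetic study data every later stage consumes:
#  - dual-channel STED scenes of repair foci for two "stainings": a
#    centre-proximal partner (RAD18-like, counts 2-3, radii ~150 nm) and a
#    peripheral partner (53BP1-like, counts 5-6, radii ~280 nm);
#  - one high-content field of 1000 nuclei with DAPI/EdU/foci channels;
#  - traffic-light-reporter event tables for a control and an HR-impaired
#    ("knockdown") condition sharing the control's random stream.
# Outputs go to results/data/.

suppressPackageStartupMessages(library(nanofoci))

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
n_fields <- 15L   # 15 fields x 20 foci = 300 foci per condition

message("== STED scenes ==")
sted_sets <- list(
  proximal = list(count = dist_uniform_set(c(2L, 3L)),
                  radial = dist_gamma(9, 17), seed0 = 2000L),
  peripheral = list(count = dist_uniform_set(c(5L, 6L)),
                    radial = dist_gamma(20, 14), seed0 = 4000L))
for (nm in names(sted_sets)) {
  s <- sted_sets[[nm]]
  for (i in seq_len(n_fields)) {
    cfg <- sted_sim_config(n_foci = 20, seed = s$seed0 + i,
                           field_size_px = c(512L, 512L),
                           partner_count_dist = s$count,
                           radial_dist = s$radial)
    sc <- simulate_sted_scene(cfg)
    base <- file.path(out, sprintf("sted_%s_%02d", nm, i))
    write_image_stack(sc$stack, paste0(base, ".tif"))
    write.csv(sc$truth, paste0(base, "_truth.csv"), row.names = FALSE)
  }
  message(sprintf("  %s: %d fields x 20 foci written", nm, n_fields))
}

message("== High-content field ==")
hcs <- simulate_hcs_field(hcs_sim_config(n_cells = 1000,
                                         field_size_px = c(1600L, 1600L),
                                         seed = 77L))
vals <- array(0, c(3, 1, 1600, 1600))
vals[1, 1, , ] <- hcs$channels$dapi$values
vals[2, 1, , ] <- hcs$channels$edu$values
vals[3, 1, , ] <- hcs$channels$foci$values
st <- image_stack(vals, pixel_size_nm = 320, z_step_nm = 1,
                  channel_names = c("dapi", "edu", "foci"))
write_image_stack(st, file.path(out, "hcs_field.tif"))
write.csv(hcs$truth, file.path(out, "hcs_truth.csv"), row.names = FALSE)
message(sprintf("  1000 nuclei, phases: %s",
                paste(capture.output(print(table(hcs$truth$phase))),
                      collapse = " ")))

message("== Reporter events ==")
ctl <- simulate_reporter_events(reporter_sim_config(
  n_events = 10000, p_hr = 0.10, p_nhej = 0.20, seed = 88L))
kd <- simulate_reporter_events(reporter_sim_config(
  n_events = 10000, p_hr = 0.10 * 0.6, p_nhej = 0.20, seed = 88L))
write.csv(ctl, file.path(out, "reporter_control.csv"), row.names = FALSE)
write.csv(kd, file.path(out, "reporter_knockdown.csv"), row.names = FALSE)
message(sprintf("  control outcomes: %s",
                paste(names(table(ctl$outcome)), table(ctl$outcome),
                      collapse = ", ")))
message("done; data under ", out)
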