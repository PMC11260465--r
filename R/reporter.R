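## Traffic-light-reporter quantification: gate trichromatic flow events
## into HR (GFP) and mutagenic-NHEJ (RFP) fractions among transfected
## (BFP-positive) cells, and normalize conditions to a control's total
## repair efficiency.

#' Gate reporter flow events into repair fractions
#'
#' Restricts to BFP-positive (transfected) events and reports the
#' percentage that are GFP-positive (homologous recombination restored the
#' fluorophore) and RFP-positive (+2 frameshift mutagenic end joining).
#' Auto thresholds are deterministic 2-class splits on the log intensity
#' of each channel.
#'
#' @param events data frame with columns `bfp`, `gfp`, `rfp`
#'   (non-negative intensities), e.g. from [simulate_reporter_events()] or
#'   an exported CSV.
#' @param thresholds named list/vector with `t_bfp`, `t_gfp`, `t_rfp`
#'   (positive numbers) or `"auto"` entries.
#' @return A `repair_fractions` list: `pct_hr`, `pct_nhej` (percentages of
#'   the BFP-positive population), `n_bfp_pos`, `n_events`, and the
#'   resolved `thresholds`.
#' @examples
#' ev <- simulate_reporter_events(reporter_sim_config(seed = 1))
#' gate_events(ev)
#' @export
gate_events <- function(events,
                        thresholds = list(t_bfp = "auto", t_gfp = "auto",
                                          t_rfp = "auto")) {
  stopifnot(all(c("bfp", "gfp", "rfp") %in% names(events)))
  if (any(!is.finite(as.matrix(events[, c("bfp", "gfp", "rfp")]))) ||
      any(events$bfp < 0 | events$gfp < 0 | events$rfp < 0)) {
    stop("event intensities must be finite and non-negative")
  }
  resolve <- function(t, x, nm) {
    if (identical(t, "auto")) {
      t <- split_1d_log(x)
      if (is.null(t)) stop("auto threshold degenerate for ", nm)
    }
    stopifnot(is.numeric(t), t > 0)
    t
  }
  t_bfp <- resolve(thresholds$t_bfp, events$bfp, "bfp")
  t_gfp <- resolve(thresholds$t_gfp, events$gfp, "gfp")
  t_rfp <- resolve(thresholds$t_rfp, events$rfp, "rfp")
  bpos <- events$bfp >= t_bfp
  n_b <- sum(bpos)
  if (n_b == 0L) stop("no BFP-positive events; fractions undefined")
  structure(list(pct_hr = 100 * sum(bpos & events$gfp >= t_gfp) / n_b,
                 pct_nhej = 100 * sum(bpos & events$rfp >= t_rfp) / n_b,
                 n_bfp_pos = n_b, n_events = nrow(events),
                 thresholds = list(t_bfp = t_bfp, t_gfp = t_gfp,
                                   t_rfp = t_rfp)),
            class = "repair_fractions")
}

#' Normalize repair fractions to a control's total repair efficiency
#'
#' Divides a sample's HR and mutagenic-NHEJ percentages by the control's
#' total (HR + NHEJ) percentage, so the control normalized against itself
#' satisfies `rel_hr + rel_nhej = 1` exactly.
#'
#' @param sample,control `repair_fractions` from [gate_events()].
#' @return A list: `rel_hr`, `rel_nhej`.
#' @examples
#' ctl <- structure(list(pct_hr = 5, pct_nhej = 10), class = "repair_fractions")
#' normalize_repair(ctl, ctl)  # 1/3 and 2/3
#' @export
normalize_repair <- function(sample, control) {
  stopifnot(inherits(sample, "repair_fractions"),
            inherits(control, "repair_fractions"))
  total <- control$pct_hr + control$pct_nhej
  if (total <= 0) stop("control total repair efficiency is zero")
  list(rel_hr = sample$pct_hr / total,
       rel_nhej = sample$pct_nhej / total)
}
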