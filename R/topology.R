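## Repair-focus topology: select isolated BRCA1-anchored centres, assign
## partner nanodomains within the radial gate, and compute the per-focus
## count and distance statistics.

#' Parameters of the focus-topology analysis
#'
#' @param r_max_nm radial gate: partner nanodomains farther than this from
#'   their focus centre are excluded (default 500 nm; the exclusion is
#'   strict, so a distance of exactly `r_max_nm` is retained).
#' @param min_center_separation_nm minimum distance to any other
#'   centre-channel nanodomain for a focus to count as non-overlapping
#'   (default 1000 nm, twice the radial gate, so two analysis disks cannot
#'   intersect). Must be at least `r_max_nm`.
#' @param crop_halfwidth_px half-width of the square crop used for signal
#'   averaging.
#' @return A validated `topology_params` list.
#' @export
topology_params <- function(r_max_nm = 500,
                            min_center_separation_nm = 1000,
                            crop_halfwidth_px = 23L) {
  stopifnot(r_max_nm > 0, min_center_separation_nm >= r_max_nm,
            crop_halfwidth_px >= 1)
  structure(list(r_max_nm = r_max_nm,
                 min_center_separation_nm = min_center_separation_nm,
                 crop_halfwidth_px = as.integer(crop_halfwidth_px)),
            class = "topology_params")
}

#' Select non-overlapping focus centres
#'
#' Retains a centre-channel nanodomain as a focus centre iff no other
#' centre-channel nanodomain lies within `min_center_separation_nm` of it.
#' Centres closer than that are all rejected (the overlap is mutual), which
#' operationalizes the requirement of isolated foci containing a single
#' central nanodomain.
#'
#' @param centers data frame of centre-channel nanodomains with columns
#'   `x_nm`, `y_nm` (e.g. from [refine_subpixel()]), all from one image.
#' @param params a [topology_params()].
#' @return A data frame of focus centres: `focus_id`, `x_nm`, `y_nm`,
#'   ordered by `(y_nm, x_nm)`.
#' @export
select_foci <- function(centers, params = topology_params()) {
  stopifnot(inherits(params, "topology_params"))
  if (is.null(centers) || nrow(centers) == 0L) {
    return(data.frame(focus_id = integer(), x_nm = numeric(),
                      y_nm = numeric()))
  }
  n <- nrow(centers)
  keep <- rep(TRUE, n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(cbind(centers$x_nm, centers$y_nm)))
    diag(d) <- Inf
    keep <- apply(d, 1L, min) >= params$min_center_separation_nm
  }
  sel <- centers[keep, c("x_nm", "y_nm"), drop = FALSE]
  sel <- sel[order(sel$y_nm, sel$x_nm), , drop = FALSE]
  data.frame(focus_id = seq_len(nrow(sel)), x_nm = sel$x_nm,
             y_nm = sel$y_nm)
}

#' Assign partner nanodomains to focus centres within the radial gate
#'
#' Each partner nanodomain is assigned to its nearest focus centre by 2D
#' Euclidean distance on the projection; assigned partners farther than
#' `r_max_nm` from that centre are excluded (strictly greater: a partner at
#' exactly `r_max_nm` is retained). Every partner appears in at most one
#' focus record.
#'
#' @param foci focus centres from [select_foci()].
#' @param partners data frame of partner-channel nanodomains (`x_nm`,
#'   `y_nm`).
#' @param params a [topology_params()].
#' @return A list of focus records, one per focus: `focus_id`, `center`
#'   (x/y nm), `partner_distances_nm` (sorted increasing), `n_partners`.
#' @export
assign_nanodomains <- function(foci, partners,
                               params = topology_params()) {
  stopifnot(inherits(params, "topology_params"))
  recs <- lapply(seq_len(nrow(foci)), function(i) {
    list(focus_id = foci$focus_id[i],
         center = c(x_nm = foci$x_nm[i], y_nm = foci$y_nm[i]),
         partner_distances_nm = numeric(0), n_partners = 0L)
  })
  if (nrow(foci) > 0L && !is.null(partners) && nrow(partners) > 0L) {
    dx <- outer(partners$x_nm, foci$x_nm, "-")
    dy <- outer(partners$y_nm, foci$y_nm, "-")
    dm <- sqrt(dx^2 + dy^2)               # partners x foci
    nearest <- max.col(-dm, ties.method = "first")
    dmin <- dm[cbind(seq_len(nrow(partners)), nearest)]
    ok <- dmin <= params$r_max_nm         # strict ">" exclusion
    for (i in which(ok)) {
      f <- nearest[i]
      recs[[f]]$partner_distances_nm <-
        c(recs[[f]]$partner_distances_nm, dmin[i])
    }
    for (f in seq_along(recs)) {
      recs[[f]]$partner_distances_nm <- sort(recs[[f]]$partner_distances_nm)
      recs[[f]]$n_partners <- length(recs[[f]]$partner_distances_nm)
    }
  }
  recs
}

#' Per-focus topology table and aggregate summary
#'
#' Computes, per focus, the partner-nanodomain count and the minimal and
#' mean radial distance from the centre; aggregates report mean and SD of
#' counts over all foci, and of the minimal/mean distances over foci with
#' at least one partner. Foci with zero partners contribute to the count
#' statistics but are excluded from the distance statistics (an undefined
#' minimum is not imputed); their number is reported so the exclusion is
#' auditable.
#'
#' @param records focus records from [assign_nanodomains()] (possibly
#'   concatenated over images).
#' @return A list with `table` (data frame: `focus_id`, `n_partners`,
#'   `min_dist_nm`, `mean_dist_nm`) and `summary` (list of aggregates;
#'   `defined = FALSE` and `NA` aggregates for empty input).
#' @export
focus_statistics <- function(records) {
  if (length(records) == 0L) {
    return(list(table = data.frame(focus_id = integer(),
                                   n_partners = integer(),
                                   min_dist_nm = numeric(),
                                   mean_dist_nm = numeric()),
                summary = list(defined = FALSE, n_foci = 0L)))
  }
  tab <- do.call(rbind, lapply(records, function(r) {
    d <- r$partner_distances_nm
    data.frame(focus_id = r$focus_id, n_partners = r$n_partners,
               min_dist_nm = if (length(d)) min(d) else NA_real_,
               mean_dist_nm = if (length(d)) mean(d) else NA_real_)
  }))
  withd <- tab[tab$n_partners >= 1L, , drop = FALSE]
  list(table = tab,
       summary = list(
         defined = TRUE,
         n_foci = nrow(tab),
         n_foci_zero_partners = sum(tab$n_partners == 0L),
         count_mean = mean(tab$n_partners),
         count_sd = stats::sd(tab$n_partners),
         min_dist_mean = if (nrow(withd)) mean(withd$min_dist_nm)
                         else NA_real_,
         min_dist_sd = if (nrow(withd) > 1) stats::sd(withd$min_dist_nm)
                       else NA_real_,
         mean_dist_mean = if (nrow(withd)) mean(withd$mean_dist_nm)
                          else NA_real_,
         mean_dist_sd = if (nrow(withd) > 1) stats::sd(withd$mean_dist_nm)
                        else NA_real_))
}

#' Average the image signal over focus-centred crops
#'
#' Pixel-wise arithmetic mean of square crops of half-width
#' `crop_halfwidth_px` centred on each focus (nearest-pixel centring). Foci
#' whose crop would extend beyond the image are skipped and counted.
#'
#' @param img an `nf_image2d`.
#' @param foci focus centres from [select_foci()].
#' @param params a [topology_params()]; `crop_halfwidth_px` sets the crop.
#' @return A list with `average` (an `nf_image2d` of size
#'   `(2w+1) x (2w+1)`), `n_used` and `n_skipped`.
#' @export
signal_average <- function(img, foci, params = topology_params()) {
  stopifnot(inherits(img, "nf_image2d"), inherits(params, "topology_params"))
  if (nrow(foci) == 0L) stop("signal_average: no foci given")
  w <- params$crop_halfwidth_px
  px <- img$pixel_size_nm
  ny <- nrow(img$values); nx <- ncol(img$values)
  acc <- matrix(0, 2L * w + 1L, 2L * w + 1L)
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(foci))) {
    cx <- as.integer(floor(foci$x_nm[i] / px))   # 0-based nearest pixel
    cy <- as.integer(floor(foci$y_nm[i] / px))
    if (cx - w < 0L || cx + w > nx - 1L || cy - w < 0L || cy + w > ny - 1L) {
      skipped <- skipped + 1L
      next
    }
    acc <- acc + img$values[(cy - w):(cy + w) + 1L,
                            (cx - w):(cx + w) + 1L]
    used <- used + 1L
  }
  if (used == 0L) stop("signal_average: no usable crops (all clipped)")
  list(average = image2d(acc / used, px), n_used = used,
       n_skipped = skipped)
}

#' Compare a topology variable between two groups
#'
#' Two-tailed Mann-Whitney U test on a per-focus variable (partner count,
#' minimal distance or mean distance) between two topology tables, e.g.
#' wild-type versus knockout.
#'
#' @param table_a,table_b per-focus tables from [focus_statistics()].
#' @param variable one of `"count"`, `"min_dist"`, `"mean_dist"`.
#' @return A [mann_whitney_u()] result with the group sizes and the
#'   direction of the effect (sign of the difference in group medians).
#' @export
compare_groups <- function(table_a, table_b,
                           variable = c("count", "min_dist", "mean_dist")) {
  variable <- match.arg(variable)
  col <- switch(variable, count = "n_partners", min_dist = "min_dist_nm",
                mean_dist = "mean_dist_nm")
  x <- table_a[[col]][!is.na(table_a[[col]])]
  y <- table_b[[col]][!is.na(table_b[[col]])]
  if (length(x) == 0L || length(y) == 0L) {
    stop(sprintf("variable '%s' has no defined values in one group",
                 variable))
  }
  res <- mann_whitney_u(x, y)
  res$direction <- sign(stats::median(x) - stats::median(y))
  res
}

#' Run the full topology chain on a detected-nanodomain table
#'
#' Splits a nanodomain table into centre and partner channels, selects
#' isolated foci, assigns partners within the radial gate and returns the
#' per-focus table plus summary.
#'
#' @param nanodomains data frame from [detect_nanodomains()] (must carry a
#'   `channel` column).
#' @param center_channel,partner_channel channel labels.
#' @param params a [topology_params()].
#' @return As [focus_statistics()], plus `foci` (the selected centres).
#' @export
focus_topology <- function(nanodomains, center_channel = "center",
                           partner_channel = "partner",
                           params = topology_params()) {
  centers <- nanodomains[nanodomains$channel == center_channel, ,
                         drop = FALSE]
  partners <- nanodomains[nanodomains$channel == partner_channel, ,
                          drop = FALSE]
  foci <- select_foci(centers, params)
  recs <- assign_nanodomains(foci, partners, params)
  out <- focus_statistics(recs)
  out$foci <- foci
  out
}
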