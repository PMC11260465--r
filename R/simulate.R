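## Synthetic data generators: STED scenes, high-content fields, reporter
## flow events. Ground truth is returned alongside every image so each
## downstream stage can be verified without the deposited raw data.

# Run expr with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Discrete and radial distribution helpers for simulation configs
#'
#' `dist_uniform_set()` describes a uniform discrete distribution over a set
#' of non-negative integers (used for partner nanodomain counts per focus);
#' `dist_gamma()` describes a gamma law for radial distances in nm.
#'
#' @param values non-negative integers with equal probability.
#' @param probs optional probability weights (default equal).
#' @param shape,scale gamma parameters; the mean is `shape * scale` nm.
#' @return A list with a `family` tag understood by the simulators.
#' @examples
#' dist_uniform_set(c(2, 3))       # mean partner count 2.5
#' dist_gamma(shape = 4, scale = 30) # mean radius 120 nm
#' @export
dist_uniform_set <- function(values, probs = NULL) {
  values <- as.integer(values)
  stopifnot(length(values) >= 1, all(values >= 0))
  if (is.null(probs)) probs <- rep(1 / length(values), length(values))
  stopifnot(length(probs) == length(values), all(probs >= 0),
            abs(sum(probs) - 1) < 1e-9)
  list(family = "discrete", values = values, probs = probs,
       mean = sum(values * probs))
}

#' @rdname dist_uniform_set
#' @export
dist_gamma <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  list(family = "gamma", shape = shape, scale = scale, mean = shape * scale)
}

draw_count <- function(dist, n) {
  stopifnot(identical(dist$family, "discrete"))
  dist$values[sample.int(length(dist$values), n, replace = TRUE,
                         prob = dist$probs)]
}

draw_radius <- function(dist, n) {
  switch(dist$family,
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    discrete = dist$values[sample.int(length(dist$values), n, replace = TRUE,
                                      prob = dist$probs)],
    stop("unknown radial distribution family: ", dist$family))
}

#' Configuration for a synthetic two-channel STED scene
#'
#' Describes a dual-channel STED acquisition of ionizing-radiation-induced
#' repair foci: channel `center` carries one nanodomain per focus (the
#' BRCA1-marked focus centre), channel `partner` carries a random number of
#' partner nanodomains (53BP1 or RAD18) placed at gamma-distributed radial
#' distances and uniform angles around each centre. Defaults mirror the
#' acquisition geometry of the study design: 22 nm lateral voxels and five
#' optical sections 149.7 nm apart.
#'
#' @param field_size_px integer pair `(ny, nx)`.
#' @param pixel_size_nm lateral pixel size, nm.
#' @param n_z number of optical sections.
#' @param z_step_nm axial step, nm.
#' @param n_foci number of repair foci to place.
#' @param partner_count_dist discrete distribution of partner nanodomains per
#'   focus (see [dist_uniform_set()]).
#' @param radial_dist distribution of partner distance from the focus centre,
#'   nm (see [dist_gamma()]).
#' @param center_photons,partner_photons expected photon budget per
#'   nanodomain.
#' @param psf_sigma_nm isotropic Gaussian PSF sd per channel
#'   (length 2: center, partner), nm.
#' @param background_rate expected background photons per pixel per section.
#' @param noise `"poisson"` (photon-counting detector) or `"none"`.
#' @param min_focus_separation_nm minimum centre-to-centre distance between
#'   placed foci.
#' @param min_partner_separation_nm minimum distance between partner
#'   nanodomains of one focus. Nanodomains are discrete chromatin clusters
#'   of finite (tens of nm) extent, so two cannot occupy the same spot; the
#'   default 80 nm reflects that physical exclusion.
#' @param seed integer RNG seed; identical config and seed give identical
#'   output.
#' @return A `sted_sim_config` list, validated.
#' @export
sted_sim_config <- function(field_size_px = c(256L, 256L),
                            pixel_size_nm = 22,
                            n_z = 5L,
                            z_step_nm = 149.7,
                            n_foci = 20L,
                            partner_count_dist = dist_uniform_set(c(2L, 3L)),
                            radial_dist = dist_gamma(shape = 9, scale = 17),
                            center_photons = 2000,
                            partner_photons = 1000,
                            psf_sigma_nm = c(25, 25),
                            background_rate = 0.1,
                            noise = c("poisson", "none"),
                            min_focus_separation_nm = 1200,
                            min_partner_separation_nm = 80,
                            seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(field_size_px) == 2, all(field_size_px >= 8),
            pixel_size_nm > 0, n_z >= 1, z_step_nm > 0, n_foci >= 0,
            center_photons >= 0, partner_photons >= 0,
            length(psf_sigma_nm) %in% c(1L, 2L), all(psf_sigma_nm > 0),
            background_rate >= 0, min_focus_separation_nm > 0,
            min_partner_separation_nm >= 0)
  if (length(psf_sigma_nm) == 1L) psf_sigma_nm <- rep(psf_sigma_nm, 2L)
  structure(list(field_size_px = as.integer(field_size_px),
                 pixel_size_nm = pixel_size_nm, n_z = as.integer(n_z),
                 z_step_nm = z_step_nm, n_foci = as.integer(n_foci),
                 partner_count_dist = partner_count_dist,
                 radial_dist = radial_dist,
                 center_photons = center_photons,
                 partner_photons = partner_photons,
                 psf_sigma_nm = psf_sigma_nm,
                 background_rate = background_rate, noise = noise,
                 min_focus_separation_nm = min_focus_separation_nm,
                 min_partner_separation_nm = min_partner_separation_nm,
                 seed = seed),
            class = "sted_sim_config")
}

# Integrated 2D Gaussian patch at physical position (x_nm, y_nm): per-pixel
# mass via pnorm differences so the photon budget is conserved up to the
# +-5 sigma truncation window. Returns the local window (0-based pixel
# ranges) and the patch matrix, or NULL when fully outside the image.
spot_patch <- function(x_nm, y_nm, photons, sigma_nm, px, ny, nx) {
  halfw <- 5 * sigma_nm
  ix0 <- max(0L, floor((x_nm - halfw) / px))
  ix1 <- min(nx - 1L, ceiling((x_nm + halfw) / px))
  iy0 <- max(0L, floor((y_nm - halfw) / px))
  iy1 <- min(ny - 1L, ceiling((y_nm + halfw) / px))
  if (ix0 > ix1 || iy0 > iy1) return(NULL)
  xs <- ix0:ix1; ys <- iy0:iy1
  mx <- stats::pnorm((xs + 1) * px, x_nm, sigma_nm) -
        stats::pnorm(xs * px, x_nm, sigma_nm)
  my <- stats::pnorm((ys + 1) * px, y_nm, sigma_nm) -
        stats::pnorm(ys * px, y_nm, sigma_nm)
  list(ys = ys, xs = xs, patch = photons * outer(my, mx))
}

# Add one rendered spot into an image matrix (rows = y)
render_spot <- function(img, x_nm, y_nm, photons, sigma_nm, px) {
  sp <- spot_patch(x_nm, y_nm, photons, sigma_nm, px, nrow(img), ncol(img))
  if (is.null(sp)) return(img)
  img[sp$ys + 1L, sp$xs + 1L] <- img[sp$ys + 1L, sp$xs + 1L] + sp$patch
  img
}

# Discrete Gaussian axial profile over n_z sections, centred on a continuous
# z0 (slice units), sd 1 slice, renormalized so the stack conserves photons.
axial_profile <- function(z0, n_z, sd_z = 1) {
  w <- stats::dnorm(seq_len(n_z) - 1, mean = z0, sd = sd_z)
  w / sum(w)
}

place_points_min_sep <- function(n, x_range, y_range, min_sep,
                                 max_attempts = 1000L, what = "focus") {
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- stats::runif(1, x_range[1], x_range[2])
      y <- stats::runif(1, y_range[1], y_range[2])
      if (i == 1L ||
          all((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2 >=
              min_sep^2)) {
        xs[i] <- x; ys[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok) {
      stop(sprintf(
        "could not place %s %d with min separation %.1f after %d attempts",
        what, i, min_sep, max_attempts))
    }
  }
  data.frame(x = xs, y = ys)
}

#' Simulate a two-channel STED scene of repair foci
#'
#' Places `n_foci` focus centres uniformly in the field (rejection sampling
#' under the minimum-separation constraint), draws a partner-nanodomain count
#' and radial positions per focus, renders every nanodomain as an isotropic
#' 2D Gaussian whose photons are split across z sections by a discrete
#' Gaussian axial profile, adds uniform background, and finally applies
#' Poisson noise if requested.
#'
#' @param config a [sted_sim_config()].
#' @return A list with `stack` (an `nf_image_stack`, channels
#'   `center`/`partner`) and `truth`, a data frame with one row per emitted
#'   nanodomain: `focus_id`, `channel`, `x_nm`, `y_nm`, `photons`.
#' @examples
#' sc <- simulate_sted_scene(sted_sim_config(n_foci = 3, seed = 1))
#' table(sc$truth$channel)
#' @export
simulate_sted_scene <- function(config) {
  stopifnot(inherits(config, "sted_sim_config"))
  with_seed(config$seed, {
    ny <- config$field_size_px[1]; nx <- config$field_size_px[2]
    px <- config$pixel_size_nm
    margin <- max(500, 6 * max(config$psf_sigma_nm))
    if (margin * 2 >= min(nx, ny) * px) {
      stop("field too small for the placement margin")
    }
    vals <- array(0, c(2L, config$n_z, ny, nx))
    truth <- data.frame(focus_id = integer(), channel = character(),
                        x_nm = numeric(), y_nm = numeric(),
                        photons = numeric())
    if (config$n_foci > 0) {
      centers <- place_points_min_sep(
        config$n_foci, c(margin, nx * px - margin),
        c(margin, ny * px - margin), config$min_focus_separation_nm)
      rows <- vector("list", config$n_foci)
      sep2 <- config$min_partner_separation_nm^2
      for (f in seq_len(config$n_foci)) {
        k <- draw_count(config$partner_count_dist, 1L)
        px_nm <- numeric(k); py_nm <- numeric(k)
        for (j in seq_len(k)) {
          placed <- FALSE
          for (a in 1:1000) {
            r <- draw_radius(config$radial_dist, 1L)
            th <- stats::runif(1, 0, 2 * pi)
            xj <- centers$x[f] + r * cos(th)
            yj <- centers$y[f] + r * sin(th)
            if (j == 1L ||
                all((px_nm[seq_len(j - 1)] - xj)^2 +
                    (py_nm[seq_len(j - 1)] - yj)^2 >= sep2)) {
              px_nm[j] <- xj; py_nm[j] <- yj; placed <- TRUE; break
            }
          }
          if (!placed) {
            stop("could not place partner nanodomain with min separation ",
                 config$min_partner_separation_nm, " nm after 1000 attempts")
          }
        }
        rows[[f]] <- data.frame(
          focus_id = f,
          channel = c("center", rep("partner", k)),
          x_nm = c(centers$x[f], px_nm),
          y_nm = c(centers$y[f], py_nm),
          photons = c(config$center_photons,
                      rep(config$partner_photons, k)))
      }
      truth <- do.call(rbind, rows)
      # clamp stray partners into the field (rare; radial tail)
      truth$x_nm <- pmin(pmax(truth$x_nm, 0.51 * px), (nx - 0.51) * px)
      truth$y_nm <- pmin(pmax(truth$y_nm, 0.51 * px), (ny - 0.51) * px)
      z0 <- stats::runif(nrow(truth), 0, config$n_z - 1)
      for (i in seq_len(nrow(truth))) {
        ci <- if (truth$channel[i] == "center") 1L else 2L
        w <- axial_profile(z0[i], config$n_z)
        sp <- spot_patch(truth$x_nm[i], truth$y_nm[i], truth$photons[i],
                         config$psf_sigma_nm[ci], px, ny, nx)
        if (is.null(sp)) next
        for (zi in seq_len(config$n_z)) {
          vals[ci, zi, sp$ys + 1L, sp$xs + 1L] <-
            vals[ci, zi, sp$ys + 1L, sp$xs + 1L] + w[zi] * sp$patch
        }
      }
    }
    vals <- vals + config$background_rate
    if (config$noise == "poisson") {
      vals[] <- stats::rpois(length(vals), vals)
    }
    list(stack = image_stack(vals, px, config$z_step_nm,
                             c("center", "partner")),
         truth = truth)
  })
}

#' Configuration for a synthetic high-content field
#'
#' Describes a field of non-overlapping circular nuclei carrying three
#' channels: DAPI (integrated intensity proportional to DNA content, 2n in
#' G1, 4n in G2/M, in between in S), EdU (S cells positive after pulse
#' labelling, others at background) and a focus marker rendered as discrete
#' diffraction-limited spots.
#'
#' @param n_cells number of nuclei.
#' @param phase_fractions probabilities `(G1, S, G2M)` summing to 1.
#' @param dapi_2n_mean mean integrated DAPI intensity of a 2n (G1) nucleus.
#' @param dapi_cv coefficient of variation of DAPI content within a phase.
#' @param edu_s_mean mean per-pixel EdU intensity in S-phase nuclei.
#' @param edu_background per-pixel EdU intensity outside S.
#' @param foci_rate_per_phase named vector `(G1, S, G2M)` of mean foci per
#'   nucleus (Poisson).
#' @param nucleus_radius_px nucleus radius in pixels.
#' @param field_size_px integer pair `(ny, nx)`.
#' @param pixel_size_nm lateral pixel size, nm (high-content scale).
#' @param seed integer RNG seed.
#' @return An `hcs_sim_config` list, validated.
#' @export
hcs_sim_config <- function(n_cells = 200L,
                           phase_fractions = c(G1 = 0.6, S = 0.25,
                                               G2M = 0.15),
                           dapi_2n_mean = 1e4,
                           dapi_cv = 0.08,
                           edu_s_mean = 60,
                           edu_background = 2,
                           foci_rate_per_phase = c(G1 = 2, S = 8, G2M = 4),
                           nucleus_radius_px = 12,
                           field_size_px = c(512L, 512L),
                           pixel_size_nm = 320,
                           seed = NULL) {
  stopifnot(length(phase_fractions) == 3,
            abs(sum(phase_fractions) - 1) < 1e-9,
            all(phase_fractions >= 0),
            dapi_2n_mean > 0, dapi_cv >= 0, edu_s_mean >= 0,
            edu_background >= 0, length(foci_rate_per_phase) == 3,
            all(foci_rate_per_phase >= 0), nucleus_radius_px > 1,
            length(field_size_px) == 2, n_cells >= 0, pixel_size_nm > 0)
  names(phase_fractions) <- c("G1", "S", "G2M")
  names(foci_rate_per_phase) <- c("G1", "S", "G2M")
  structure(list(n_cells = as.integer(n_cells),
                 phase_fractions = phase_fractions,
                 dapi_2n_mean = dapi_2n_mean, dapi_cv = dapi_cv,
                 edu_s_mean = edu_s_mean, edu_background = edu_background,
                 foci_rate_per_phase = foci_rate_per_phase,
                 nucleus_radius_px = nucleus_radius_px,
                 field_size_px = as.integer(field_size_px),
                 pixel_size_nm = pixel_size_nm, seed = seed),
            class = "hcs_sim_config")
}

#' Simulate a high-content microscopy field with cell-cycle structure
#'
#' Nuclei are placed without overlap by rejection sampling; each is assigned
#' a cell-cycle phase from `phase_fractions`, a DAPI content (G1 around the
#' 2n mean, G2/M around twice that, S uniformly in between, all with
#' lognormal-like spread `dapi_cv`), an EdU level (S positive) and a
#' Poisson-distributed number of marker foci rendered inside the nucleus.
#'
#' @param config an [hcs_sim_config()].
#' @return A list with `channels` (named list of `nf_image2d`: `dapi`,
#'   `edu`, `foci`) and `truth`, one row per cell: `cell_id`, `phase`,
#'   `dapi_total`, `edu_mean`, `n_foci`, `x_px`, `y_px`, `radius_px`.
#' @examples
#' f <- simulate_hcs_field(hcs_sim_config(n_cells = 20, seed = 1))
#' table(f$truth$phase)
#' @export
simulate_hcs_field <- function(config) {
  stopifnot(inherits(config, "hcs_sim_config"))
  with_seed(config$seed, {
    ny <- config$field_size_px[1]; nx <- config$field_size_px[2]
    r <- config$nucleus_radius_px
    dapi <- matrix(0, ny, nx); edu <- matrix(0, ny, nx)
    foci <- matrix(0, ny, nx)
    truth <- data.frame(cell_id = integer(), phase = character(),
                        dapi_total = numeric(), edu_mean = numeric(),
                        n_foci = integer(), x_px = numeric(),
                        y_px = numeric(), radius_px = numeric())
    if (config$n_cells > 0) {
      margin <- r + 3
      if (2 * margin >= min(nx, ny)) stop("field too small for nuclei")
      pos <- place_points_min_sep(config$n_cells, c(margin, nx - margin),
                                  c(margin, ny - margin), 2 * r + 3,
                                  what = "nucleus")
      phases <- sample(c("G1", "S", "G2M"), config$n_cells, replace = TRUE,
                       prob = config$phase_fractions)
      m2n <- config$dapi_2n_mean
      content <- vapply(phases, function(p) {
        base <- switch(p, G1 = m2n, G2M = 2 * m2n,
                       S = m2n * (1 + stats::runif(1)))
        base * exp(stats::rnorm(1, 0, config$dapi_cv))
      }, numeric(1))
      edu_mu <- ifelse(phases == "S", config$edu_s_mean,
                       config$edu_background)
      n_foci_true <- integer(config$n_cells)
      edu_meas <- numeric(config$n_cells)
      for (i in seq_len(config$n_cells)) {
        xs <- max(1L, floor(pos$x[i] - r)):min(nx, ceiling(pos$x[i] + r))
        ys <- max(1L, floor(pos$y[i] - r)):min(ny, ceiling(pos$y[i] + r))
        disk <- outer((ys - 0.5 - pos$y[i])^2, (xs - 0.5 - pos$x[i])^2,
                      "+") <= r^2
        area <- sum(disk)
        dw <- dapi[ys, xs]; ew <- edu[ys, xs]
        dw[disk] <- dw[disk] + content[i] / area
        ew[disk] <- ew[disk] + edu_mu[i]
        dapi[ys, xs] <- dw; edu[ys, xs] <- ew
        edu_meas[i] <- edu_mu[i]
        k <- stats::rpois(1, config$foci_rate_per_phase[[phases[i]]])
        if (k > 0) {
          # foci are kept apart so they stay individually detectable;
          # dense draws can jam a rejection pass, so restart and finally
          # relax the separation rather than fail (best-effort spacing)
          fp <- NULL
          for (sep in c(4, 4, 4, 2.5, 0)) {
            fp <- tryCatch(place_points_min_sep(
              k, c(pos$x[i] - 0.7 * r, pos$x[i] + 0.7 * r),
              c(pos$y[i] - 0.7 * r, pos$y[i] + 0.7 * r),
              min_sep = sep, what = "focus"), error = function(e) NULL)
            if (!is.null(fp)) break
          }
          # keep inside the 0.7 r disk so foci stay within the nucleus
          for (j in seq_len(k)) {
            d <- sqrt((fp$x[j] - pos$x[i])^2 + (fp$y[j] - pos$y[i])^2)
            if (d > 0.7 * r) {
              s <- 0.7 * r / d
              fp$x[j] <- pos$x[i] + (fp$x[j] - pos$x[i]) * s
              fp$y[j] <- pos$y[i] + (fp$y[j] - pos$y[i]) * s
            }
            sp <- spot_patch(fp$x[j] * config$pixel_size_nm,
                             fp$y[j] * config$pixel_size_nm,
                             photons = 500,
                             sigma_nm = 1.2 * config$pixel_size_nm,
                             px = config$pixel_size_nm, ny, nx)
            if (!is.null(sp)) {
              foci[sp$ys + 1L, sp$xs + 1L] <-
                foci[sp$ys + 1L, sp$xs + 1L] + sp$patch
            }
          }
        }
        n_foci_true[i] <- k
      }
      truth <- data.frame(cell_id = seq_len(config$n_cells),
                          phase = phases, dapi_total = content,
                          edu_mean = edu_meas, n_foci = n_foci_true,
                          x_px = pos$x, y_px = pos$y, radius_px = r)
    }
    list(channels = list(dapi = image2d(dapi, config$pixel_size_nm),
                         edu = image2d(edu, config$pixel_size_nm),
                         foci = image2d(foci, config$pixel_size_nm)),
         truth = truth)
  })
}

#' Configuration for synthetic traffic-light-reporter flow events
#'
#' Models the trichromatic readout of the reporter assay: a fraction of
#' events is transfected (BFP positive); among those, a repair outcome is
#' drawn — homologous recombination (restores GFP), mutagenic end joining
#' (+2 frameshift, produces RFP), or neither. Channel intensities come from
#' lognormal positive/negative populations.
#'
#' @param n_events number of flow events.
#' @param frac_bfp_pos probability an event is transfected.
#' @param p_hr,p_nhej outcome probabilities among transfected events
#'   (`p_hr + p_nhej <= 1`).
#' @param neg_meanlog,neg_sdlog,pos_meanlog,pos_sdlog log-scale location and
#'   spread of the negative and positive intensity populations (shared
#'   across BFP/GFP/RFP).
#' @param seed integer RNG seed.
#' @return A `reporter_sim_config` list, validated.
#' @export
reporter_sim_config <- function(n_events = 10000L,
                                frac_bfp_pos = 0.5,
                                p_hr = 0.05,
                                p_nhej = 0.10,
                                neg_meanlog = log(100), neg_sdlog = 0.5,
                                pos_meanlog = log(5000), pos_sdlog = 0.5,
                                seed = NULL) {
  stopifnot(n_events >= 0, frac_bfp_pos >= 0, frac_bfp_pos <= 1,
            p_hr >= 0, p_nhej >= 0, p_hr + p_nhej <= 1,
            neg_sdlog > 0, pos_sdlog > 0, pos_meanlog > neg_meanlog)
  structure(list(n_events = as.integer(n_events),
                 frac_bfp_pos = frac_bfp_pos, p_hr = p_hr, p_nhej = p_nhej,
                 neg_meanlog = neg_meanlog, neg_sdlog = neg_sdlog,
                 pos_meanlog = pos_meanlog, pos_sdlog = pos_sdlog,
                 seed = seed),
            class = "reporter_sim_config")
}

#' Simulate traffic-light-reporter flow events
#'
#' @param config a [reporter_sim_config()].
#' @return A data frame with one row per event: `event_id`, `outcome`
#'   (`untransfected`, `none`, `HR`, `mutNHEJ`), and `bfp`, `gfp`, `rfp`
#'   intensities in arbitrary fluorescence units.
#' @examples
#' ev <- simulate_reporter_events(reporter_sim_config(n_events = 100, seed = 1))
#' table(ev$outcome)
#' @export
simulate_reporter_events <- function(config) {
  stopifnot(inherits(config, "reporter_sim_config"))
  with_seed(config$seed, {
    n <- config$n_events
    transfected <- stats::runif(n) < config$frac_bfp_pos
    u <- stats::runif(n)
    outcome <- rep("untransfected", n)
    outcome[transfected] <- "none"
    outcome[transfected & u < config$p_hr] <- "HR"
    outcome[transfected & u >= config$p_hr &
            u < config$p_hr + config$p_nhej] <- "mutNHEJ"
    draw <- function(pos) {
      ifelse(pos,
             stats::rlnorm(n, config$pos_meanlog, config$pos_sdlog),
             stats::rlnorm(n, config$neg_meanlog, config$neg_sdlog))
    }
    data.frame(event_id = seq_len(n),
               outcome = outcome,
               bfp = draw(transfected),
               gfp = draw(outcome == "HR"),
               rfp = draw(outcome == "mutNHEJ"))
  })
}
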