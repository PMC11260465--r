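## High-content quantification: nucleus segmentation, per-nucleus features,
## DAPI/EdU cell-cycle gating, foci counting, ploidy normalization and
## colocalization.

#' Segment nuclei from a DAPI image
#'
#' Global Otsu threshold, hole filling, distance-transform watershed to
#' split touching nuclei, and an area filter. Returns an integer label
#' mask (0 = background) with contiguous labels `1..n`.
#'
#' @param dapi an `nf_image2d` of the DAPI channel.
#' @param min_area_px,max_area_px area filter bounds in pixels.
#' @return An integer matrix of labels with the image's shape.
#' @export
segment_nuclei <- function(dapi, min_area_px = 50, max_area_px = Inf) {
  stopifnot(inherits(dapi, "nf_image2d"), min_area_px >= 0,
            max_area_px >= min_area_px)
  v <- dapi$values
  mx <- max(v)
  if (mx <= 0) return(matrix(0L, nrow(v), ncol(v)))
  x <- v / mx
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  mask <- x > th
  if (!any(mask)) return(matrix(0L, nrow(v), ncol(v)))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(EBImage::distmap(mask))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(v), ncol(v))
  areas <- tabulate(lab)
  drop <- which(areas < min_area_px | areas > max_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel contiguously
  keep <- sort(unique(lab[lab > 0L]))
  if (length(keep)) {
    remap <- integer(max(keep))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Per-nucleus intensity features
#'
#' For every label: pixel area, integrated DAPI intensity (`dapi_total`)
#' and mean EdU intensity (`edu_mean`).
#'
#' @param mask integer label matrix from [segment_nuclei()].
#' @param channels named list of `nf_image2d` containing at least `dapi`
#'   and `edu`, all of the mask's shape.
#' @return A data frame: `cell_id`, `area_px`, `dapi_total`, `edu_mean`.
#' @export
extract_cell_features <- function(mask, channels) {
  stopifnot(is.matrix(mask), all(c("dapi", "edu") %in% names(channels)))
  for (ch in channels) {
    if (!identical(dim(ch$values), dim(mask))) {
      stop("channel shape does not match the mask")
    }
  }
  n <- max(mask, 0L)
  if (n == 0L) {
    return(data.frame(cell_id = integer(), area_px = integer(),
                      dapi_total = numeric(), edu_mean = numeric()))
  }
  lab <- as.vector(mask)
  inside <- lab > 0L
  lab <- lab[inside]
  area <- tabulate(lab, n)
  dsum <- as.vector(rowsum(as.vector(channels$dapi$values)[inside], lab))
  esum <- as.vector(rowsum(as.vector(channels$edu$values)[inside], lab))
  data.frame(cell_id = seq_len(n), area_px = area,
             dapi_total = dsum, edu_mean = esum / area)
}

#' Gate configuration for cell-cycle classification
#'
#' @param edu_threshold EdU gate on `edu_mean`, or `"auto"`.
#' @param dapi_split G1/G2M boundary on `dapi_total` among EdU-negative
#'   cells, or `"auto"`.
#' @param d_2n_reference 2n DAPI reference used by
#'   [normalize_foci_to_ploidy()], or `"auto"` (median `dapi_total` of G1
#'   cells).
#' @return A `gate_config` list.
#' @export
gate_config <- function(edu_threshold = "auto", dapi_split = "auto",
                        d_2n_reference = "auto") {
  chk <- function(v, nm) {
    if (!identical(v, "auto") && (!is.numeric(v) || v <= 0)) {
      stop(nm, " must be 'auto' or a positive number")
    }
  }
  chk(edu_threshold, "edu_threshold"); chk(dapi_split, "dapi_split")
  chk(d_2n_reference, "d_2n_reference")
  structure(list(edu_threshold = edu_threshold, dapi_split = dapi_split,
                 d_2n_reference = d_2n_reference), class = "gate_config")
}

# Deterministic 2-class 1D split on log intensities: k-means initialized at
# the observed extremes (robust when one class is rare, where quantile
# initialization puts both centres inside the majority mode); returns the
# raw-scale midpoint of the two centres, or NULL for a degenerate
# (single-cluster) distribution.
split_1d_log <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NULL)
  eps <- max(x, 1) * 1e-9
  lx <- log(x + eps)
  if (diff(range(lx)) < 1e-9) return(NULL)
  q <- range(lx)
  km <- suppressWarnings(stats::kmeans(lx, centers = matrix(q, 2, 1)))
  cen <- sort(km$centers[, 1])
  if (diff(cen) < 1e-6) return(NULL)
  exp(mean(cen)) - eps
}

#' Assign cell-cycle phases from DAPI and EdU intensities
#'
#' S phase is called from the EdU gate (`edu_mean >= edu_threshold`);
#' EdU-negative cells are split into G1 and G2/M at `dapi_split` on their
#' integrated DAPI intensity (2n versus 4n DNA content). Auto thresholds
#' are midpoints of deterministic 2-class splits on log intensities; with
#' fewer than 10 cells or a degenerate distribution the affected gate
#' falls back (no S cells / all EdU-negative cells G1) with a warning.
#'
#' @param cells data frame from [extract_cell_features()].
#' @param gates a [gate_config()].
#' @return `cells` with a `phase` column (`G1`, `S`, `G2M`, `unassigned`)
#'   and the resolved thresholds in `attr(, "gates")`.
#' @export
gate_cell_cycle <- function(cells, gates = gate_config()) {
  stopifnot(inherits(gates, "gate_config"))
  n <- nrow(cells)
  phase <- rep("unassigned", n)
  edu_t <- gates$edu_threshold
  if (identical(edu_t, "auto")) {
    edu_t <- if (n >= 10L) split_1d_log(cells$edu_mean) else NULL
    if (is.null(edu_t)) {
      warning("EdU gate degenerate or too few cells; calling no S cells")
      edu_t <- Inf
    }
  }
  ok <- is.finite(cells$edu_mean) & is.finite(cells$dapi_total)
  s <- ok & cells$edu_mean >= edu_t
  phase[s] <- "S"
  neg <- ok & !s
  dapi_t <- gates$dapi_split
  if (identical(dapi_t, "auto")) {
    dapi_t <- if (sum(neg) >= 10L) split_1d_log(cells$dapi_total[neg])
              else NULL
    if (is.null(dapi_t)) {
      warning("DAPI gate degenerate or too few cells; ",
              "calling all EdU-negative cells G1")
      dapi_t <- Inf
    }
  }
  phase[neg & cells$dapi_total < dapi_t] <- "G1"
  phase[neg & cells$dapi_total >= dapi_t] <- "G2M"
  cells$phase <- phase
  attr(cells, "gates") <- list(edu_threshold = edu_t, dapi_split = dapi_t)
  cells
}

#' Count marker foci per nucleus
#'
#' Runs prominence-based maxima detection on the focus-marker channel and
#' counts, per nucleus label, the detected peaks falling inside it.
#'
#' @param mask integer label matrix.
#' @param focus_channel an `nf_image2d`.
#' @param tolerance prominence threshold; default [auto_tolerance()].
#' @return Integer vector of counts indexed by `cell_id`.
#' @export
count_foci_per_cell <- function(mask, focus_channel, tolerance = NULL) {
  stopifnot(identical(dim(focus_channel$values), dim(mask)))
  n <- max(mask, 0L)
  if (n == 0L) return(integer(0))
  if (is.null(tolerance)) tolerance <- auto_tolerance(focus_channel)
  pk <- find_maxima(focus_channel, tolerance)
  counts <- integer(n)
  if (nrow(pk)) {
    lab <- mask[cbind(pk$iy + 1L, pk$ix + 1L)]
    tl <- tabulate(lab[lab > 0L], n)
    counts <- counts + tl
  }
  counts
}

#' Normalize foci counts to 2n DNA content
#'
#' Expresses each cell's foci count per 2n DNA equivalent:
#' `normalized_foci = foci_count * d_2n_reference / dapi_total`, so a G2/M
#' cell with twice the 2n DAPI total and the same raw count reports half
#' the normalized count. The reference defaults to the median `dapi_total`
#' of G1 cells.
#'
#' @param cells gated cells with `foci_count` and `dapi_total` columns.
#' @param d_2n_reference positive reference, or `NULL` to derive it from
#'   the G1 cells (requires at least one).
#' @return `cells` with a `normalized_foci` column (`NA` where
#'   `dapi_total` is zero) and the reference in
#'   `attr(, "d_2n_reference")`.
#' @export
normalize_foci_to_ploidy <- function(cells, d_2n_reference = NULL) {
  stopifnot(all(c("foci_count", "dapi_total") %in% names(cells)))
  if (is.null(d_2n_reference)) {
    g1 <- cells$dapi_total[cells$phase == "G1"]
    if (length(g1) == 0L) {
      stop("no G1 cells to define the 2n DAPI reference; supply one")
    }
    d_2n_reference <- stats::median(g1)
  }
  stopifnot(d_2n_reference > 0)
  norm <- ifelse(cells$dapi_total > 0,
                 cells$foci_count * d_2n_reference / cells$dapi_total,
                 NA_real_)
  cells$normalized_foci <- norm
  attr(cells, "d_2n_reference") <- d_2n_reference
  cells
}

#' Per-cell colocalization of two focus channels
#'
#' For every nucleus: the Pearson correlation of the two intensity
#' channels over the nuclear pixels, and the fraction of A-foci with a
#' B-focus of the same cell within `radius_nm` (plus the symmetric
#' counterpart). A constant channel within a nucleus yields an undefined
#' (`NA`) correlation, flagged rather than raised.
#'
#' @param mask integer label matrix.
#' @param foci_a,foci_b data frames with `x_nm`, `y_nm` (image
#'   coordinates).
#' @param channel_a,channel_b `nf_image2d` intensity channels.
#' @param radius_nm matching radius (default 500).
#' @return A data frame: `cell_id`, `pearson_r`, `n_a`, `n_b`,
#'   `frac_a_near_b`, `frac_b_near_a`.
#' @export
colocalize <- function(mask, foci_a, foci_b, channel_a, channel_b,
                       radius_nm = 500) {
  stopifnot(radius_nm > 0,
            identical(dim(channel_a$values), dim(mask)),
            identical(dim(channel_b$values), dim(mask)))
  px <- channel_a$pixel_size_nm
  n <- max(mask, 0L)
  if (n == 0L) {
    return(data.frame(cell_id = integer(), pearson_r = numeric(),
                      n_a = integer(), n_b = integer(),
                      frac_a_near_b = numeric(), frac_b_near_a = numeric()))
  }
  cell_of <- function(f) {
    if (is.null(f) || nrow(f) == 0L) return(integer(0))
    iy <- pmin(pmax(floor(f$y_nm / px), 0), nrow(mask) - 1L)
    ix <- pmin(pmax(floor(f$x_nm / px), 0), ncol(mask) - 1L)
    mask[cbind(iy + 1L, ix + 1L)]
  }
  ca <- cell_of(foci_a); cb <- cell_of(foci_b)
  out <- data.frame(cell_id = seq_len(n), pearson_r = NA_real_,
                    n_a = 0L, n_b = 0L, frac_a_near_b = NA_real_,
                    frac_b_near_a = NA_real_)
  near_frac <- function(fx, fy, gx, gy) {
    if (length(fx) == 0L) return(NA_real_)
    if (length(gx) == 0L) return(0)
    mean(vapply(seq_along(fx), function(i) {
      any((fx[i] - gx)^2 + (fy[i] - gy)^2 <= radius_nm^2)
    }, logical(1)))
  }
  for (cid in seq_len(n)) {
    inside <- mask == cid
    va <- channel_a$values[inside]; vb <- channel_b$values[inside]
    if (length(va) >= 3L && stats::sd(va) > 0 && stats::sd(vb) > 0) {
      out$pearson_r[cid] <- stats::cor(va, vb)
    }
    ia <- which(ca == cid); ib <- which(cb == cid)
    out$n_a[cid] <- length(ia); out$n_b[cid] <- length(ib)
    out$frac_a_near_b[cid] <- near_frac(foci_a$x_nm[ia], foci_a$y_nm[ia],
                                        foci_b$x_nm[ib], foci_b$y_nm[ib])
    out$frac_b_near_a[cid] <- near_frac(foci_b$x_nm[ib], foci_b$y_nm[ib],
                                        foci_a$x_nm[ia], foci_a$y_nm[ia])
  }
  out
}
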