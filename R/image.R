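#' Image containers with physical calibration
#'
#' `image2d()` wraps a numeric matrix of non-negative intensities (rows = y,
#' columns = x) together with its lateral pixel size in nanometres.
#' `image_stack()` wraps a 4-dimensional array indexed
#' `(channel, z, y, x)` with lateral and axial calibration.
#'
#' Pixel coordinates use a 0-based index convention throughout the package:
#' the centre of pixel `(ix, iy)` lies at physical position
#' `((ix + 0.5) * pixel_size_nm, (iy + 0.5) * pixel_size_nm)`.
#'
#' @param values numeric matrix (`image2d`) of non-negative intensities, or
#'   a 4-d numeric array `(channel, z, y, x)` (`image_stack`).
#' @param pixel_size_nm positive lateral pixel size in nm.
#' @param z_step_nm positive axial step in nm (stacks only).
#' @param channel_names optional character vector naming the channels.
#' @return An object of class `nf_image2d` or `nf_image_stack`.
#' @examples
#' img <- image2d(matrix(0, 8, 8), pixel_size_nm = 22)
#' dim(img$values)
#' @export
image2d <- function(values, pixel_size_nm) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(values) >= 1)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("image2d: values must be finite and non-negative")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0) {
    stop("image2d: pixel_size_nm must be a positive scalar")
  }
  structure(list(values = values, pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "nf_image2d")
}

#' @rdname image2d
#' @export
image_stack <- function(values, pixel_size_nm, z_step_nm,
                        channel_names = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 4)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("image_stack: values must be finite and non-negative")
  }
  if (pixel_size_nm <= 0 || z_step_nm <= 0) {
    stop("image_stack: calibration must be positive")
  }
  nc <- dim(values)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc) - 1L)
  stopifnot(length(channel_names) == nc)
  structure(list(values = values,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 z_step_nm = as.numeric(z_step_nm),
                 channel_names = as.character(channel_names)),
            class = "nf_image_stack")
}

#' @export
print.nf_image2d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<nf_image2d> %d x %d px @ %.3g nm/px, range [%.3g, %.3g]\n",
              d[2], d[1], x$pixel_size_nm, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.nf_image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<nf_image_stack> %d channel(s) [%s], %d z, %d x %d px @ %.3g nm/px, z-step %.4g nm\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[4], d[3],
    x$pixel_size_nm, x$z_step_nm))
  invisible(x)
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) {
      stop(sprintf("channel '%s' not found (have: %s)", channel,
                   paste(stack$channel_names, collapse = ", ")))
    }
    return(idx)
  }
  idx <- as.integer(channel)
  if (idx < 1L || idx > dim(stack$values)[1]) {
    stop(sprintf("channel index %d out of range 1..%d", idx,
                 dim(stack$values)[1]))
  }
  idx
}

#' Maximum-intensity projection of a stack channel
#'
#' Collapses one channel of an `nf_image_stack` along z by taking the
#' per-pixel maximum over optical sections, the standard reduction applied
#' to STED z-stacks before nanodomain detection. Calibration is propagated.
#'
#' @param stack an `nf_image_stack`.
#' @param channel channel name or 1-based index.
#' @return An `nf_image2d` with the same lateral size and pixel calibration.
#' @examples
#' a <- array(0, c(1, 3, 4, 4)); a[1, 2, 2, 3] <- 7
#' mip <- max_intensity_project(image_stack(a, 22, 149.7), 1)
#' mip$values[2, 3]
#' @export
max_intensity_project <- function(stack, channel) {
  stopifnot(inherits(stack, "nf_image_stack"))
  ci <- resolve_channel(stack, channel)
  v <- stack$values[ci, , , , drop = FALSE]
  dim(v) <- dim(stack$values)[2:4]
  proj <- apply(v, c(2, 3), max)
  image2d(proj, stack$pixel_size_nm)
}

#' Write / read calibrated images as TIFF plus JSON sidecar
#'
#' Stacks are written as multi-page 32-bit float TIFF, channel-major then z,
#' with intensities scaled into `[0, 1]`; the sidecar `<path>.json` records
#' `pixel_size_nm`, `z_step_nm`, `channel_names`, dimensions and the
#' `intensity_scale` needed to restore the original photon counts.
#' `read_image_stack()` inverts the transform (up to 32-bit float rounding).
#'
#' @param stack an `nf_image_stack`.
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns an `nf_image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "nf_image_stack"))
  d <- dim(stack$values)
  scale <- max(stack$values, 1e-12)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ci in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      pages[[k]] <- matrix(stack$values[ci, zi, , ] / scale, d[3], d[4])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               z_step_nm = stack$z_step_nm,
               channel_names = stack$channel_names,
               n_channels = d[1], n_z = d[2], ny = d[3], nx = d[4],
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  vals <- array(0, c(meta$n_channels, meta$n_z, meta$ny, meta$nx))
  k <- 1L
  for (ci in seq_len(meta$n_channels)) {
    for (zi in seq_len(meta$n_z)) {
      vals[ci, zi, , ] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  image_stack(vals, meta$pixel_size_nm, meta$z_step_nm, meta$channel_names)
}
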