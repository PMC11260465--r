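# Independent oracles used across the suite. These are deliberately naive
# (enumeration, level-set flooding, dense grids) and share no code with the
# implementations they check.

# shift a matrix by (dy, dx), padding with `fill`
nb_shift <- function(m, dy, dx, fill = -Inf) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny); xs <- seq_len(nx)
  ysrc <- ys - dy; xsrc <- xs - dx
  oky <- ysrc >= 1 & ysrc <= ny; okx <- xsrc >= 1 & xsrc <= nx
  out[ys[oky], xs[okx]] <- m[ysrc[oky], xsrc[okx]]
  out
}

OFF8 <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dx = c(-1, 0, 1, -1, 1, -1, 0, 1))

# 8-connected component labels among `active` pixels; if `values` given,
# adjacency additionally requires equal values. Iterative min-label
# propagation (converges within the mask diameter).
label_cc <- function(active, values = NULL) {
  ny <- nrow(active); nx <- ncol(active)
  lab <- matrix(seq_len(ny * nx), ny, nx)
  lab[!active] <- Inf
  repeat {
    new <- lab
    for (k in seq_len(nrow(OFF8))) {
      cand <- nb_shift(lab, OFF8[k, 1], OFF8[k, 2], Inf)
      ok <- active & is.finite(cand)
      if (!is.null(values)) {
        vn <- nb_shift(values, OFF8[k, 1], OFF8[k, 2], NA)
        ok <- ok & !is.na(vn) & vn == values
      }
      new[ok] <- pmin(new[ok], cand[ok])
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Reference prominence-based maxima finder, straight from the definition:
# enumerate peak plateaus, then for each peak scan thresholds from its value
# downward; the first level whose >=L component (containing the peak) holds
# a strictly higher pixel is the key saddle.
oracle_find_maxima <- function(v, tolerance) {
  ny <- nrow(v); nx <- ncol(v)
  nbmax <- matrix(-Inf, ny, nx)
  for (k in seq_len(nrow(OFF8))) {
    nbmax <- pmax(nbmax, nb_shift(v, OFF8[k, 1], OFF8[k, 2], -Inf))
  }
  plat <- label_cc(matrix(TRUE, ny, nx), values = v)
  peaks <- list()
  for (id in unique(as.vector(plat))) {
    px <- which(plat == id)
    if (all(nbmax[px] <= v[px][1])) {
      y0 <- (px - 1) %% ny; x0 <- (px - 1) %/% ny
      peaks[[length(peaks) + 1]] <- list(
        ix = as.integer(floor(mean(x0) + 0.5)),
        iy = as.integer(floor(mean(y0) + 0.5)),
        value = v[px][1], anchor = px[1])
    }
  }
  lev <- sort(unique(as.vector(v)), decreasing = TRUE)
  vmin <- min(v)
  rows <- lapply(peaks, function(p) {
    prom <- p$value - vmin
    for (L in lev[lev <= p$value]) {
      cc <- label_cc(v >= L)
      mycomp <- cc == cc[p$anchor] & is.finite(cc)
      if (any(v[mycomp] > p$value)) {
        prom <- p$value - L
        break
      }
    }
    data.frame(ix = p$ix, iy = p$iy, value = p$value, prominence = prom)
  })
  out <- do.call(rbind, rows)
  out <- out[out$prominence >= tolerance, , drop = FALSE]
  out <- out[order(-out$value, out$iy, out$ix), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of ranks
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  pr <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Balanced two-way ANOVA sums of squares from cell means
anova_ss_oracle <- function(values, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(values)
  am <- tapply(values, a, mean); bm <- tapply(values, b, mean)
  cm <- tapply(values, list(a, b), mean)
  nc <- table(a, b)
  stopifnot(length(unique(as.vector(nc))) == 1)  # balanced only
  r <- nc[1, 1]
  ss_a <- sum(nlevels(b) * r * (am - gm)^2)
  ss_b <- sum(nlevels(a) * r * (bm - gm)^2)
  ss_cells <- sum(r * (cm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((values - gm)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
       ss_resid = ss_tot - ss_cells, ss_total = ss_tot)
}

# Dense-grid chi-square minimization for the centre of a noise-free
# Gaussian spot (amplitude/offset/width profiled by least squares at each
# candidate centre)
grid_fit_oracle <- function(v, x_range, y_range, step = 0.001, sigma = 1.2) {
  ny <- nrow(v); nx <- ncol(v)
  pxx <- rep(seq_len(nx) - 0.5, each = ny)
  pyy <- rep(seq_len(ny) - 0.5, nx)
  val <- as.vector(v)
  xs <- seq(x_range[1], x_range[2], by = step)
  ys <- seq(y_range[1], y_range[2], by = step)
  best <- c(NA, NA); best_sse <- Inf
  for (x0 in xs) {
    gx <- exp(-(pxx - x0)^2 / (2 * sigma^2))
    for (y0 in ys) {
      g <- gx * exp(-(pyy - y0)^2 / (2 * sigma^2))
      fit <- stats::lm.fit(cbind(1, g), val)   # profile A and b
      sse <- sum(fit$residuals^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(x0, y0) }
    }
  }
  list(x0 = best[1], y0 = best[2], sse = best_sse)
}

# Match segmented labels to simulated cells by nearest centroid
match_labels_to_truth <- function(mask, truth) {
  stopifnot(max(mask) > 0)
  ys <- row(mask); xs <- col(mask)
  cx <- tapply(xs[mask > 0], mask[mask > 0], mean)
  cy <- tapply(ys[mask > 0], mask[mask > 0], mean)
  vapply(seq_along(cx), function(i) {
    which.min((truth$x_px - cx[i])^2 + (truth$y_px - cy[i])^2)
  }, integer(1))
}

# Poisson-count test image: a few Gaussian bumps over a flat rate, then
# Poisson sampling -- integer-valued, so plateaus and ties are common
random_poisson_image <- function(ny = 32, nx = 32, n_bumps = 3,
                                 bg = 2, amp = 25) {
  mu <- matrix(bg, ny, nx)
  for (i in seq_len(n_bumps)) {
    cx <- runif(1, 4, nx - 4); cy <- runif(1, 4, ny - 4)
    s <- runif(1, 1, 2.5)
    mu <- mu + amp * exp(-(outer((seq_len(ny) - 0.5 - cy)^2,
                                 (seq_len(nx) - 0.5 - cx)^2, "+")) /
                           (2 * s^2))
  }
  matrix(rpois(ny * nx, mu), ny, nx)
}
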