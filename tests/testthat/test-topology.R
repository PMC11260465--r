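nd_frame <- function(x, y, channel = "partner") {
  data.frame(channel = rep(channel, length(x)), x_nm = x, y_nm = y)
}

test_that("focus selection enforces mutual isolation", {
  p <- topology_params()
  one <- select_foci(nd_frame(1000, 1000, "center"), p)
  expect_equal(nrow(one), 1)

  two <- select_foci(nd_frame(c(1000, 1400), c(1000, 1000), "center"), p)
  expect_equal(nrow(two), 0)    # 400 nm apart: both rejected

  none <- select_foci(nd_frame(numeric(0), numeric(0), "center"), p)
  expect_equal(nrow(none), 0)
})

test_that("focus selection matches an all-pairs brute-force filter", {
  set.seed(5)
  for (rep in 1:5) {
    pts <- nd_frame(runif(50, 0, 12000), runif(50, 0, 12000), "center")
    sel <- select_foci(pts, topology_params())
    keep <- logical(50)
    for (i in 1:50) {
      ok <- TRUE
      for (j in 1:50) {
        if (i != j) {
          d <- sqrt((pts$x_nm[i] - pts$x_nm[j])^2 +
                    (pts$y_nm[i] - pts$y_nm[j])^2)
          if (d < 1000) ok <- FALSE
        }
      }
      keep[i] <- ok
    }
    ref <- pts[keep, ]
    ref <- ref[order(ref$y_nm, ref$x_nm), ]
    expect_equal(sel$x_nm, ref$x_nm)
    expect_equal(sel$y_nm, ref$y_nm)
  }
})

test_that("radial gate is strict beyond 500 nm and inclusive at 500.0 nm", {
  foci <- select_foci(nd_frame(5000, 5000, "center"))
  at100 <- assign_nanodomains(foci, nd_frame(5100, 5000))
  expect_equal(at100[[1]]$partner_distances_nm, 100)

  at500 <- assign_nanodomains(foci, nd_frame(5500, 5000))
  expect_equal(at500[[1]]$partner_distances_nm, 500)

  at5001 <- assign_nanodomains(foci, nd_frame(5500.1, 5000))
  expect_equal(at5001[[1]]$n_partners, 0)
})

test_that("partners go to the nearest centre only, and assignment partitions", {
  foci <- select_foci(nd_frame(c(1000, 2500), c(1000, 1000), "center"),
                      topology_params(min_center_separation_nm = 1000))
  # partner 300 nm from focus B, 1200 nm from focus A
  rec <- assign_nanodomains(foci, nd_frame(2200, 1000))
  expect_equal(rec[[1]]$n_partners, 0)
  expect_equal(rec[[2]]$partner_distances_nm, 300)

  set.seed(9)
  partners <- nd_frame(runif(200, 0, 4000), runif(200, 0, 2000))
  recs <- assign_nanodomains(foci, partners)
  expect_lte(sum(vapply(recs, function(r) r$n_partners, integer(1))), 200)
  expect_true(all(unlist(lapply(recs, function(r) r$partner_distances_nm))
                  <= 500))
})

test_that("focus statistics: arithmetic, zero-partner contract, empty input", {
  recs <- list(list(focus_id = 1L, center = c(0, 0),
                    partner_distances_nm = c(100, 200), n_partners = 2L),
               list(focus_id = 2L, center = c(0, 0),
                    partner_distances_nm = numeric(0), n_partners = 0L))
  fs <- focus_statistics(recs)
  expect_equal(fs$table$n_partners, c(2L, 0L))
  expect_equal(fs$table$min_dist_nm, c(100, NA))
  expect_equal(fs$table$mean_dist_nm, c(150, NA))
  expect_equal(fs$summary$count_mean, 1)            # zero-partner focus counts
  expect_equal(fs$summary$min_dist_mean, 100)       # but is excluded here
  expect_equal(fs$summary$n_foci_zero_partners, 1L)

  empty <- focus_statistics(list())
  expect_false(empty$summary$defined)
  expect_equal(nrow(empty$table), 0)
})

test_that("topology is invariant to a constant translation of all coordinates", {
  set.seed(13)
  centers <- nd_frame(runif(10, 2000, 10000), runif(10, 2000, 10000),
                      "center")
  partners <- nd_frame(runif(60, 1500, 10500), runif(60, 1500, 10500))
  run <- function(dx, dy) {
    ca <- centers; ca$x_nm <- ca$x_nm + dx; ca$y_nm <- ca$y_nm + dy
    pa <- partners; pa$x_nm <- pa$x_nm + dx; pa$y_nm <- pa$y_nm + dy
    focus_statistics(assign_nanodomains(select_foci(ca), pa))$table
  }
  a <- run(0, 0); b <- run(777.7, -321.3)
  expect_equal(a$n_partners, b$n_partners)
  expect_equal(a$min_dist_nm, b$min_dist_nm)
  expect_equal(a$mean_dist_nm, b$mean_dist_nm)
})

test_that("signal averaging is idempotent, matches (A+B)/2, and skips clipped crops", {
  set.seed(17)
  v <- matrix(runif(60 * 60), 60, 60)
  img <- image2d(v, 22)
  p <- topology_params(crop_halfwidth_px = 5)
  # two identical positions -> average equals the crop
  f2 <- data.frame(focus_id = 1:2, x_nm = rep(30.5 * 22, 2),
                   y_nm = rep(20.5 * 22, 2))
  sa <- signal_average(img, f2, p)
  expect_equal(sa$n_used, 2)
  expect_equal(sa$average$values, v[16:26, 26:36])

  # two different positions -> naive (A+B)/2
  fab <- data.frame(focus_id = 1:2, x_nm = c(15.5, 40.5) * 22,
                    y_nm = c(15.5, 40.5) * 22)
  sab <- signal_average(img, fab, p)
  ref <- (v[11:21, 11:21] + v[36:46, 36:46]) / 2
  expect_equal(sab$average$values, ref)

  # crop at the border is skipped and counted
  fb <- data.frame(focus_id = 1:2, x_nm = c(2.5, 30.5) * 22,
                   y_nm = c(30.5, 30.5) * 22)
  sb <- signal_average(img, fb, p)
  expect_equal(sb$n_used, 1)
  expect_equal(sb$n_skipped, 1)
  expect_error(signal_average(img, fb[1, , drop = FALSE], p), "usable")
})

test_that("group comparison wraps the U test with direction", {
  ta <- data.frame(n_partners = c(1L, 2L, 3L), min_dist_nm = c(1, 2, 3),
                   mean_dist_nm = c(1, 2, 3))
  tb <- data.frame(n_partners = c(4L, 5L, 6L), min_dist_nm = c(4, 5, 6),
                   mean_dist_nm = c(4, 5, 6))
  r <- compare_groups(ta, tb, "min_dist")
  expect_equal(r$statistic_U, 0)
  expect_equal(r$p_two_sided, 0.1)
  expect_equal(r$direction, -1)

  same <- compare_groups(ta, ta, "count")
  expect_equal(same$p_two_sided, 1)

  tb$min_dist_nm <- NA_real_
  expect_error(compare_groups(ta, tb, "min_dist"), "no defined values")
})

test_that("end-to-end: pipeline recovers the generator count distribution", {
  # noise-free scenes so detection is exact; chi-square goodness of fit of
  # recovered counts against uniform{2,3} must not reject at alpha = 0.01
  counts <- integer(0)
  for (s in 1:15) {
    cfg <- sted_sim_config(n_foci = 20, seed = s, noise = "none",
                           field_size_px = c(512L, 512L))
    sc <- simulate_sted_scene(cfg)
    nd <- rbind(detect_nanodomains(sc$stack, "center", tolerance = 10),
                detect_nanodomains(sc$stack, "partner", tolerance = 10))
    counts <- c(counts, focus_topology(nd)$table$n_partners)
  }
  expect_gte(length(counts), 290)
  obs <- c(sum(counts == 2), sum(counts == 3))
  expect_gte(sum(obs) / length(counts), 0.98)   # essentially all 2s and 3s
  chi <- suppressWarnings(chisq.test(obs, p = c(0.5, 0.5)))
  expect_gt(chi$p.value, 0.01)
})
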