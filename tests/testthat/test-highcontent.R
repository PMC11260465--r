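disk_image <- function(ny, nx, cx, cy, r, value = 1) {
  m <- outer((seq_len(ny) - 0.5 - cy)^2, (seq_len(nx) - 0.5 - cx)^2, "+")
  matrix(ifelse(m <= r^2, value, 0), ny, nx)
}

test_that("segmentation: blank image, single disk, simulated field", {
  expect_equal(max(segment_nuclei(image2d(matrix(0, 32, 32), 320))), 0)

  d <- disk_image(64, 64, 30, 34, 10, 5)
  mask <- segment_nuclei(image2d(d, 320))
  expect_equal(max(mask), 1)
  expect_lt(abs(sum(mask == 1) - sum(d > 0)) / sum(d > 0), 0.05)

  f <- simulate_hcs_field(hcs_sim_config(n_cells = 40, seed = 12))
  mask2 <- segment_nuclei(f$channels$dapi, min_area_px = 100)
  expect_equal(max(mask2), 40)
})

test_that("cell features match a naive accumulation loop", {
  set.seed(3)
  mask <- matrix(0L, 20, 20)
  mask[3:8, 3:8] <- 1L; mask[12:18, 10:16] <- 2L
  dapi <- matrix(runif(400, 0, 10), 20, 20)
  edu <- matrix(runif(400, 0, 5), 20, 20)
  cells <- extract_cell_features(mask, list(dapi = image2d(dapi, 320),
                                            edu = image2d(edu, 320)))
  for (cid in 1:2) {
    a <- 0; ds <- 0; es <- 0
    for (y in 1:20) for (x in 1:20) {
      if (mask[y, x] == cid) {
        a <- a + 1; ds <- ds + dapi[y, x]; es <- es + edu[y, x]
      }
    }
    expect_equal(cells$area_px[cid], a)
    expect_equal(cells$dapi_total[cid], ds)
    expect_equal(cells$edu_mean[cid], es / a)
  }
  # constant intensity: total = area * c
  cst <- extract_cell_features(mask, list(dapi = image2d(matrix(2, 20, 20),
                                                         320),
                                          edu = image2d(matrix(0, 20, 20),
                                                        320)))
  expect_equal(cst$dapi_total, cst$area_px * 2)
  expect_equal(cst$edu_mean, c(0, 0))
  expect_error(extract_cell_features(mask,
    list(dapi = image2d(matrix(0, 5, 5), 320),
         edu = image2d(matrix(0, 5, 5), 320))), "shape")
})

test_that("gating partitions cells and handles degenerate EdU", {
  set.seed(8)
  cells <- data.frame(cell_id = 1:40, area_px = 100,
                      dapi_total = c(rnorm(30, 100, 5), rnorm(10, 200, 8)),
                      edu_mean = 0)
  expect_warning(g <- gate_cell_cycle(cells), "EdU")
  expect_true(all(g$phase %in% c("G1", "G2M", "unassigned")))
  expect_false(any(g$phase == "S"))
  expect_true(all(table(g$phase)[c("G1", "G2M")] == c(30, 10)))

  # explicit split: EdU-negative cell at twice the G1 mode lands in G2M
  g2 <- gate_cell_cycle(data.frame(dapi_total = c(rep(100, 20), 200),
                                   edu_mean = 0),
                        gate_config(edu_threshold = 1, dapi_split = 150))
  expect_equal(g2$phase[21], "G2M")
  expect_true(all(g2$phase[1:20] == "G1"))
})

test_that("simulated 1000-cell field is gated with >= 95% accuracy", {
  f <- simulate_hcs_field(hcs_sim_config(n_cells = 1000,
                                         field_size_px = c(1600L, 1600L),
                                         seed = 23))
  mask <- segment_nuclei(f$channels$dapi, min_area_px = 100)
  cells <- gate_cell_cycle(extract_cell_features(mask, f$channels))
  truth_idx <- match_labels_to_truth(mask, f$truth)
  acc <- mean(cells$phase == f$truth$phase[truth_idx])
  expect_gte(acc, 0.95)
  expect_true(all(cells$phase %in% c("G1", "S", "G2M", "unassigned")))
})

test_that("foci counting matches constructed ground truth", {
  mask <- matrix(0L, 40, 40)
  mask[5:20, 5:20] <- 1L; mask[25:38, 22:38] <- 2L
  px <- 320
  ch <- matrix(0, 40, 40)
  spots1 <- cbind(x = c(8, 12, 16), y = c(8, 15, 10))
  for (i in 1:3) {
    ch <- ch + 50 * exp(-(outer((seq_len(40) - 0.5 - spots1[i, "y"])^2,
                                (seq_len(40) - 0.5 - spots1[i, "x"])^2,
                                "+")) / (2 * 1.2^2))
  }
  counts <- count_foci_per_cell(mask, image2d(ch, px), tolerance = 10)
  expect_equal(counts, c(3L, 0L))
  blank <- count_foci_per_cell(mask, image2d(matrix(0, 40, 40), px),
                               tolerance = 10)
  expect_equal(blank, c(0L, 0L))
})

test_that("ploidy normalization: identities and gain invariance", {
  cells <- data.frame(cell_id = 1:3,
                      dapi_total = c(100, 200, 0),
                      foci_count = c(4L, 10L, 2L),
                      phase = c("G1", "G2M", "G1"))
  out <- normalize_foci_to_ploidy(cells, d_2n_reference = 100)
  expect_equal(out$normalized_foci[1], 4)    # at the reference: unchanged
  expect_equal(out$normalized_foci[2], 5)    # doubled DAPI halves the count
  expect_true(is.na(out$normalized_foci[3])) # zero DAPI flagged

  # global DAPI gain cancels when the reference is derived from the data
  set.seed(4)
  cells2 <- data.frame(cell_id = 1:50,
                       dapi_total = c(rnorm(35, 100, 5), rnorm(15, 200, 8)),
                       foci_count = rpois(50, 5),
                       phase = rep(c("G1", "G2M"), c(35, 15)))
  a <- normalize_foci_to_ploidy(cells2)
  cells3 <- cells2; cells3$dapi_total <- cells3$dapi_total * 7.3
  b <- normalize_foci_to_ploidy(cells3)
  expect_equal(a$normalized_foci, b$normalized_foci)

  expect_error(normalize_foci_to_ploidy(
    data.frame(dapi_total = 1, foci_count = 1L, phase = "S")), "G1")
})

test_that("colocalization: identity, constant channel, symmetry", {
  mask <- matrix(0L, 30, 30); mask[5:25, 5:25] <- 1L
  set.seed(6)
  ch <- image2d(matrix(runif(900), 30, 30), 320)
  foci <- data.frame(x_nm = c(10, 20) * 320, y_nm = c(10, 18) * 320)
  r <- colocalize(mask, foci, foci, ch, ch, radius_nm = 500)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$frac_a_near_b, 1)
  expect_equal(r$frac_b_near_a, 1)

  cst <- image2d(matrix(1, 30, 30), 320)
  r2 <- colocalize(mask, foci, foci, ch, cst, radius_nm = 500)
  expect_true(is.na(r2$pearson_r))

  ch2 <- image2d(matrix(runif(900), 30, 30), 320)
  r_ab <- colocalize(mask, foci, foci[1, ], ch, ch2, 500)
  r_ba <- colocalize(mask, foci[1, ], foci, ch2, ch, 500)
  expect_equal(r_ab$pearson_r, r_ba$pearson_r)
  expect_equal(r_ab$frac_a_near_b, r_ba$frac_b_near_a)
})

test_that("colocalized fraction is recovered from a simulated mixture", {
  set.seed(31)
  mask <- matrix(1L, 200, 200)
  px <- 320
  n <- 120
  ax <- runif(n, 10, 190) * px; ay <- runif(n, 10, 190) * px
  paired <- runif(n) < 0.6
  bx <- ifelse(paired, ax + rnorm(n, 0, 60), runif(n, 10, 190) * px)
  by <- ifelse(paired, ay + rnorm(n, 0, 60), runif(n, 10, 190) * px)
  ch <- image2d(matrix(runif(4e4), 200, 200), px)
  r <- colocalize(mask, data.frame(x_nm = ax, y_nm = ay),
                  data.frame(x_nm = bx, y_nm = by), ch, ch, radius_nm = 500)
  # binomial 99% CI around 0.6 (unpaired B foci rarely land within 500 nm)
  expect_gte(r$frac_a_near_b * n, qbinom(0.005, n, 0.6))
  expect_lte(r$frac_a_near_b * n, qbinom(0.995, n, 0.65))
})
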