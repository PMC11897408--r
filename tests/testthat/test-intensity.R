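test_that("mask means are exact and linear in intensity scaling", {
  m <- matrix(7, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:5, 3:5] <- TRUE
  expect_equal(mean_on_mask(m, mask), 7)
  expect_error(mean_on_mask(m, matrix(FALSE, 10, 10)), "empty")

  g <- make_two_channel_cell(two_channel_params(seed = 2))
  expect_equal(mean_on_mask(g$marker, g$ground_truth$rim_mask),
               g$ground_truth$rim_intensity)

  set.seed(5)
  noisy <- matrix(runif(400), 20, 20)
  mask2 <- matrix(runif(400) > 0.5, 20, 20)
  loop_mean <- {
    s <- 0; n <- 0
    for (i in 1:20) for (j in 1:20) if (mask2[i, j]) {
      s <- s + noisy[i, j]; n <- n + 1
    }
    s / n
  }
  expect_equal(mean_on_mask(noisy, mask2), loop_mean)
  expect_equal(mean_on_mask(noisy * 4.2, mask2), 4.2 * loop_mean)
})

test_that("background ROI sampling is seeded, in-cytoplasm and distribution-uniform", {
  g <- make_two_channel_cell(two_channel_params(seed = 3))
  gt <- g$ground_truth
  b1 <- sample_background(g$marker, g$true_mask, gt$cell_mask, seed = 11)
  b2 <- sample_background(g$marker, g$true_mask, gt$cell_mask, seed = 11)
  expect_identical(b1$center, b2$center)
  expect_equal(b1$background_mean, gt$cytoplasm_intensity)  # uniform cytoplasm
  expect_false(any(b1$roi_mask & g$true_mask))

  # gradient cytoplasm: background mean bounded by cytoplasm min/max
  grad <- matrix(seq(0, 1, length.out = 192), 192, 192)
  bg <- sample_background(grad, g$true_mask, gt$cell_mask, seed = 4)
  expect_gte(bg$background_mean, min(grad[gt$cytoplasm_mask]))
  expect_lte(bg$background_mean, max(grad[gt$cytoplasm_mask]))

  # impossible radius errors with advice
  expect_error(sample_background(g$marker, g$true_mask, gt$cell_mask,
                                 radius_px = 90, seed = 1), "radius")

  # uniformity over the admissible region: chi-squared on quadrant counts
  centers <- t(vapply(1:2000, function(s) {
    sample_background(g$marker, g$true_mask, gt$cell_mask,
                      radius_px = 10, seed = s)$center
  }, c(0, 0)))
  dmap <- EBImage::imageData(EBImage::distmap(
    (gt$cell_mask & !decondenseR:::dilate_disc(g$true_mask, 4)) * 1))
  admissible <- dmap > 10
  mid <- (dim(admissible) - 1) / 2
  quad <- function(r, c) 1 + (r > mid[1]) + 2 * (c > mid[2])
  obs <- tabulate(quad(centers[, 1], centers[, 2]), 4)
  adm <- which(admissible, arr.ind = TRUE) - 1
  expected <- tabulate(quad(adm[, 1], adm[, 2]), 4) / nrow(adm)
  expect_gt(chisq.test(obs, p = expected)$p.value, 0.01)
})

test_that("corrected intensity subtracts the cytoplasmic background", {
  g <- make_two_channel_cell(two_channel_params(rim_intensity = 100 / 255,
                                                cytoplasm_intensity = 20 / 255,
                                                seed = 6))
  gt <- g$ground_truth
  meas <- corrected_intensity(g$marker, gt$rim_mask, gt$cell_mask, seed = 2)
  expect_equal(meas$corrected, 80 / 255)
  expect_false(meas$negative_flag)

  # linearity: doubling the marker doubles on-mask and background means
  m2 <- as_mat(g$marker) * 2
  meas2 <- corrected_intensity(m2, gt$rim_mask, gt$cell_mask, seed = 2)
  expect_equal(meas2$corrected, 2 * meas$corrected)

  # zero marker: corrected is minus the background, flagged negative
  measz <- corrected_intensity(matrix(0, 192, 192), gt$rim_mask,
                               gt$cell_mask, seed = 2)
  expect_equal(measz$corrected, 0)
  measz2 <- corrected_intensity(pmax(as_mat(g$marker) - 1, 0) +
                                  0.01 * gt$cytoplasm_mask, gt$rim_mask,
                                gt$cell_mask, seed = 2)
  expect_lt(measz2$corrected, 0)
  expect_true(measz2$negative_flag)
})

test_that("line scans sample 200 bilinear values inclusive of endpoints", {
  const <- matrix(50, 64, 64)
  ls <- line_scan(const, c(10, 5), c(40, 60))
  expect_identical(nrow(ls), 200L)
  expect_equal(ls$value, rep(50, 200))

  ramp <- matrix(rep(0:199, each = 20), 20, 200)
  lr <- line_scan(ramp, c(10, 0), c(10, 199))
  expect_equal(lr$value, seq(0, 199, length.out = 200))
  expect_equal(lr$value[1], 0); expect_equal(lr$value[200], 199)

  expect_error(line_scan(const, c(-1, 0), c(10, 10)), "outside")

  # profile across a cell with a bright perichromatin rim peaks at the two
  # rim crossings
  g <- make_two_channel_cell(two_channel_params(seed = 8))
  ctr <- (dim(g$true_mask) - 1) / 2
  prof <- line_scan(g$marker, c(ctr[1], 20), c(ctr[1], dim(g$true_mask)[2] - 21))
  peaks <- prof$value >= g$ground_truth$rim_intensity - 1e-9
  expect_gte(sum(peaks), 2)
  runs <- rle(peaks)
  expect_identical(sum(runs$values), 2L)  # two separated rim crossings
})

test_that("foci detection matches generator ground truth and respects region exclusions", {
  g0 <- make_two_channel_cell(two_channel_params(n_foci = 0,
                                                 marker_noise_sd = 0.01,
                                                 seed = 9))
  r0 <- detect_foci(g0$marker, g0$true_mask, g0$ground_truth$cell_mask)
  expect_identical(nrow(r0$foci), 0L)
  expect_false(r0$big_foci_present)

  g3 <- make_two_channel_cell(two_channel_params(n_foci = 3,
                                                 focus_radius_px = 4,
                                                 focus_intensity = 0.9,
                                                 cytoplasm_intensity = 0.15,
                                                 seed = 10))
  r3 <- detect_foci(g3$marker, g3$true_mask, g3$ground_truth$cell_mask)
  expect_identical(nrow(r3$foci), 3L)
  expect_true(r3$big_foci_present)
  # detected centres match the generated ones within a pixel
  d <- as.matrix(dist(rbind(cbind(r3$foci$row, r3$foci$col),
                            cbind(g3$ground_truth$foci$row,
                                  g3$ground_truth$foci$col))))
  match_d <- apply(d[1:3, 4:6, drop = FALSE], 1, min)
  expect_true(all(match_d < 1))

  # count recovery across seeds
  for (s in 1:8) {
    gg <- make_two_channel_cell(two_channel_params(n_foci = 2,
                                                   focus_intensity = 0.9,
                                                   seed = s))
    rr <- detect_foci(gg$marker, gg$true_mask, gg$ground_truth$cell_mask)
    expect_identical(nrow(rr$foci), 2L)
  }

  # a bright blob painted on the rim is not a cytoplasmic focus
  m <- as_mat(g0$marker)
  rim_px <- which(g0$ground_truth$rim_mask, arr.ind = TRUE)
  m[rim_px[1:20, ]] <- 0.95
  rrim <- detect_foci(m, g0$true_mask, g0$ground_truth$cell_mask)
  expect_identical(nrow(rrim$foci), 0L)

  expect_error(detect_foci(m, g0$ground_truth$cell_mask,
                           g0$ground_truth$cell_mask), "cytoplasm")
})
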