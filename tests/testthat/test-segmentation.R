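test_that("median denoise matches its contract (identity, constants, hot pixels, edges)", {
  m <- matrix(runif(100), 10, 10)
  expect_identical(denoise_median(m, 1), m)
  expect_equal(denoise_median(matrix(5, 7, 7), 3), matrix(5, 7, 7))
  expect_error(denoise_median(m, 4), "odd")

  hot <- matrix(10, 5, 5); hot[3, 3] <- 255
  den <- denoise_median(hot, 3)
  nb <- sort(as.vector(hot[2:4, 2:4]))
  expect_equal(den[3, 3], nb[5])  # brute-force neighbourhood median
  expect_equal(den[3, 3], 10)

  # reflect padding: corner pixel of a constant-with-edge-noise image uses
  # its own reflected values, checked against the explicit majority oracle
  set.seed(1)
  bm <- matrix(runif(64) > 0.5, 8, 8)
  soft <- soften_border(bm, 3)
  for (p in list(c(1, 1), c(1, 8), c(8, 8), c(4, 5))) {
    expect_identical(soft[p[1], p[2]],
                     brute_binary_median_at(bm, p[1], p[2], 3))
  }
})

test_that("Otsu threshold equals the exhaustive between-class-variance sweep", {
  # bimodal {10, 200}: mask separates exactly the bright pixels
  m <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- otsu_threshold(m, to_8bit = TRUE)
  expect_identical(res$mask, m > 10)

  expect_error(otsu_threshold(matrix(3, 5, 5)), "degenerate")
  empty <- otsu_threshold(matrix(3, 5, 5), on_degenerate = "empty")
  expect_false(any(empty$mask))

  # property: sweep oracle over 20 seeded random 8-bit images
  rescale_oracle <- function(m) round((m - min(m)) / (max(m) - min(m)) * 255)
  set.seed(42)
  for (i in 1:20) {
    q <- matrix(sample(0:255, 400, replace = TRUE,
                       prob = runif(256)^2), 20, 20)
    res <- otsu_threshold(q, to_8bit = TRUE)
    t_pkg <- round((res$threshold - min(q)) / (max(q) - min(q)) * 255)
    expect_identical(as.integer(t_pkg), brute_otsu(rescale_oracle(q)))
  }
})

test_that("Otsu agrees with EBImage's implementation on a continuous image", {
  set.seed(7)
  img <- matrix(runif(4096)^3, 64, 64)
  res <- otsu_threshold(img, to_8bit = FALSE)
  ref <- EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256)
  expect_lt(abs(res$threshold - ref), diff(range(img)) / 256 + 1e-12)
})

test_that("hole filling fills enclosed background only, is idempotent and monotone", {
  dims <- c(41, 41); cc <- c(20, 20)
  annulus <- digital_disk(dims, cc, 15) & !digital_disk(dims, cc, 8)
  filled <- fill_holes(annulus)
  expect_identical(filled, digital_disk(dims, cc, 15))
  expect_identical(fill_holes(filled), filled)

  solid <- digital_disk(dims, cc, 12)
  expect_identical(fill_holes(solid), solid)

  # border-connected background stays background
  stripe <- matrix(FALSE, 10, 10); stripe[4:6, ] <- TRUE
  expect_identical(fill_holes(stripe), stripe)

  # output is always a superset; cross-check against EBImage::fillHull
  set.seed(3)
  for (i in 1:5) {
    rnd <- matrix(runif(900) > 0.6, 30, 30)
    f <- fill_holes(rnd)
    expect_true(all(f[rnd]))
    ref <- EBImage::imageData(EBImage::fillHull(rnd * 1)) > 0
    expect_identical(f, ref)
  }
})

test_that("in-vitro segmentation recovers noise-free synthetic masses within 2%", {
  for (a in c(0, 0.1, 0.2, 0.3)) {
    g <- make_chromatin_mass(mass_params(roughness_amplitude = a,
                                         radius_px = 40, noise_sd = 0,
                                         seed = 31))
    mask <- segment_invitro(g$frame)
    expect_lt(abs(sum(mask) - sum(g$true_mask)) / sum(g$true_mask), 0.02)
  }
  expect_error(segment_invitro(matrix(0, 32, 32)), "degenerate")
  g <- make_chromatin_mass(mass_params(seed = 8, noise_sd = 0.05))
  expect_identical(segment_invitro(g$frame), segment_invitro(g$frame))
})

test_that("segmentation recipes are translation-equivariant and affine-intensity invariant", {
  g <- make_chromatin_mass(mass_params(radius_px = 25, seed = 12,
                                       noise_sd = 0,
                                       image_size_px = c(128, 128)))
  img <- as_mat(g$frame)
  # circular shift preserves the intensity histogram exactly
  cshift <- function(m, dr, dc) {
    m[(seq_len(nrow(m)) - 1 - dr) %% nrow(m) + 1,
      (seq_len(ncol(m)) - 1 - dc) %% ncol(m) + 1]
  }
  m0 <- segment_invitro(img)
  m1 <- segment_invitro(cshift(img, 7, 9))
  expect_identical(m1, cshift(m0, 7, 9))

  m2 <- segment_invitro(img * 3.7 + 0.2)
  expect_identical(m2, m0)

  l0 <- segment_livecell(img)
  l2 <- segment_livecell(img * 3.7 + 0.2)
  expect_gt(sum(l0 & l2) / sum(l0 | l2), 0.995)
})

test_that("live-cell recipe: sigma 0 reduces to threshold + fill, object count non-increasing in sigma", {
  g <- make_chromatin_mass(mass_params(seed = 5, noise_sd = 0))
  cfg <- segmentation_config(to_8bit = FALSE)
  m0 <- segment_livecell(g$frame, cfg, sigma = 0)
  ref <- fill_holes(otsu_threshold(as_mat(g$frame))$mask)
  expect_identical(m0, ref)

  tl <- make_decondensation_timelapse(timelapse_params(seed = 6))
  last <- tl$lapse$frames[[20]]
  objs <- extract_objects(segment_livecell(last, cfg), min_area_px2 = 20)
  expect_length(objs, 2)

  noisy <- make_chromatin_mass(mass_params(seed = 14, noise_sd = 0.15))
  counts <- vapply(c(0.5, 1.5, 4), function(s) {
    length(extract_objects(segment_livecell(noisy$frame, cfg, sigma = s),
                           min_area_px2 = 4))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("object extraction is 8-connected, sorted, filtered, with exact centroids", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE; m[8:10, 8:10] <- TRUE
  objs <- extract_objects(m, min_area_px2 = 1, pixel_size_um = 0.5)
  expect_length(objs, 2)
  expect_equal(vapply(objs, function(o) o$area_px2, 0), c(9, 9))
  expect_equal(objs[[1]]$area_um2, 9 * 0.25)
  expect_equal(unname(objs[[1]]$centroid), c(2, 2))  # 0-based mean of 2:4 - 1

  expect_length(extract_objects(m, min_area_px2 = 10), 0)

  # diagonal touch is one 8-connected component
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_length(extract_objects(d), 1)

  set.seed(99)
  for (i in 1:5) {
    rnd <- matrix(runif(400) > 0.7, 20, 20)
    expect_length(extract_objects(rnd), brute_component_count(rnd))
  }
})
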