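# build per-frame object lists from (area, row, col) rows; one list element
# per frame
obj_frames <- function(...) {
  lapply(list(...), function(fr) {
    if (is.null(fr)) return(list())
    lapply(seq_len(nrow(fr)), function(i) {
      fake_object(fr[i, 1], fr[i, 2], fr[i, 3])
    })
  })
}

test_that("object linking keeps trajectories and resolves 2-object assignment optimally", {
  static <- obj_frames(rbind(c(100, 10, 10)), rbind(c(100, 10, 10)),
                       rbind(c(100, 10, 10)))
  traj <- link_objects(static, frame_interval_min = 3)
  expect_length(traj$frames, 3)
  expect_identical(traj$n_objects, rep(1L, 3))

  expect_error(link_objects(obj_frames(rbind(c(10, 1, 1), c(9, 5, 5),
                                             c(8, 9, 9)))), "ambiguous")

  # two objects drifting so their order by column swaps: assignment must
  # minimize summed displacement (2-permutation brute force)
  f1 <- rbind(c(50, 10, 10), c(60, 10, 20))
  f2 <- rbind(c(50, 10, 19), c(60, 10, 11))  # each moved ~9 px toward the other
  traj2 <- link_objects(obj_frames(f1, f2))
  prev <- traj2$frames[[1]]; cur <- traj2$frames[[2]]
  d_linked <- sqrt(sum((prev[[1]]$centroid - cur[[1]]$centroid)^2)) +
    sqrt(sum((prev[[2]]$centroid - cur[[2]]$centroid)^2))
  perms <- list(c(1, 2), c(2, 1))
  d_best <- min(vapply(perms, function(p) {
    sqrt(sum((prev[[1]]$centroid - f2[p[1], 2:3])^2)) +
      sqrt(sum((prev[[2]]$centroid - f2[p[2], 2:3])^2))
  }, 0))
  expect_equal(d_linked, d_best)
})

test_that("anaphase onset is the first persistent qualifying split", {
  tl <- make_decondensation_timelapse(timelapse_params(onset_frame = 10,
                                                       n_frames = 20,
                                                       seed = 2))
  cfg <- pipeline_config()
  res <- analyze_trajectory(tl$lapse, cfg, "c")
  expect_identical(res$onset, 10L)

  # single object throughout: no-mitosis error
  single <- obj_frames(rbind(c(100, 5, 5)), rbind(c(100, 5, 5)),
                       rbind(c(100, 5, 5)))
  expect_error(detect_anaphase_onset(link_objects(single)), "no-mitosis")

  # 1-frame spurious split at frame 6, true split at 10: persistence decides
  frames <- c(
    lapply(0:5, function(f) rbind(c(100, 20, 30))),
    list(rbind(c(45, 20, 25), c(45, 20, 35))),   # frame 6: noise blob split
    lapply(7:9, function(f) rbind(c(100, 20, 30))),
    lapply(10:15, function(f) rbind(c(55, 20, 20), c(55, 20, 40))))
  traj <- link_objects(do.call(obj_frames, frames))
  expect_identical(detect_anaphase_onset(traj), 10L)

  # daughters below the minimum fraction never qualify
  tiny <- c(lapply(0:4, function(f) rbind(c(100, 20, 30))),
            lapply(5:9, function(f) rbind(c(10, 20, 20), c(10, 20, 40))))
  expect_error(detect_anaphase_onset(link_objects(do.call(obj_frames, tiny))),
               "no-mitosis")
})

test_that("area curves are anchored at 1 at onset with exact arithmetic", {
  fr <- c(lapply(c(90, 95), function(a) rbind(c(a, 10, 30))),
          list(rbind(c(50, 10, 20), c(50, 10, 40)),
               rbind(c(55, 10, 19), c(55, 10, 41)),
               rbind(c(60.5, 10, 18), c(60.5, 10, 42))))
  traj <- link_objects(do.call(obj_frames, fr), frame_interval_min = 3)
  curve <- normalize_area_curve(traj, onset = 2)
  expect_equal(curve$time_min, c(-6, -3, 0, 3, 6))
  expect_equal(curve$normalized_area[3:5], c(1, 1.10, 1.21))
  expect_equal(curve$normalized_area[1], 0.9)

  per <- normalize_area_curve(traj, onset = 2, per_daughter = TRUE)
  expect_equal(per$normalized_area[per$time_min == 3], c(0.55, 0.55))

  zero <- obj_frames(rbind(c(100, 5, 5)), NULL)
  expect_error(normalize_area_curve(link_objects(zero), onset = 1), "zero")
})

test_that("expansion-rate recovery on noise-free synthetic lapses is within 10%", {
  cfg <- pipeline_config()
  for (k in c(0.02, 0.1)) {
    tl <- make_decondensation_timelapse(timelapse_params(expansion_rate = k,
                                                         seed = 7))
    res <- analyze_trajectory(tl$lapse, cfg, "c")
    expect_lt(abs(fit_expansion_rate(res$curve) - k) / k, 0.1)
  }
  # k = 0: curve stays at 1 within segmentation tolerance
  tl0 <- make_decondensation_timelapse(timelapse_params(expansion_rate = 0,
                                                        seed = 7))
  res0 <- analyze_trajectory(tl0$lapse, cfg, "c")
  post <- res0$curve$normalized_area[res0$curve$time_min >= 0]
  expect_true(all(abs(post - 1) < 0.02))
})

test_that("phase classification follows the size rules and matches generator truth", {
  p <- timelapse_params(onset_frame = 6, n_frames = 24, expansion_rate = 0.1,
                        seed = 12)
  tl <- make_decondensation_timelapse(p)
  th <- phase_thresholds(interphase_reference_area_px2 =
                           p$interphase_reference_area_px2)
  cfg <- pipeline_config(phases = th, segmentation =
                           segmentation_config(to_8bit = FALSE))
  res <- analyze_trajectory(tl$lapse, cfg, "c")
  agreement <- mean(res$phases$table$phase == tl$ground_truth$phase)
  expect_gte(agreement, 0.9)

  # all-interphase trajectory: single large stable mass
  fr <- do.call(obj_frames, lapply(1:6, function(i) rbind(c(800, 30, 30))))
  traj <- link_objects(fr)
  ph <- classify_phases(traj, phase_thresholds())
  expect_true(all(ph$table$phase == "interphase"))

  # rule arithmetic: onset 10, anaphase window 2
  frames <- c(lapply(0:9, function(f) rbind(c(100, 20, 30))),
              lapply(10:15, function(f) rbind(c(55, 20, 20), c(55, 20, 40))))
  traj2 <- link_objects(do.call(obj_frames, frames), frame_interval_min = 3)
  th2 <- phase_thresholds(interphase_reference_area_px2 = 300)
  ph2 <- classify_phases(traj2, th2, onset = 10)
  expect_identical(ph2$table$phase[11:12], c("anaphase", "anaphase"))
  expect_true(all(ph2$table$phase[13:16] == "telophase"))

  expect_error(phase_thresholds(metaphase_area_frac = 1.4), "fraction")
})

test_that("dwell times are run lengths times the frame interval", {
  lab <- c("metaphase", "metaphase", "anaphase", "anaphase", "telophase",
           "telophase", "telophase", "telophase", "interphase")
  ph <- structure(list(table = data.frame(frame = 0:8, phase = lab),
                       thresholds = phase_thresholds(
                         interphase_reference_area_px2 = 1),
                       frame_interval_min = 3, cell_id = "c"),
                  class = "phase_sequence")
  dw <- dwell_times(ph)
  expect_equal(unname(dw$minutes["telophase"]), 12)
  expect_equal(unname(dw$minutes["anaphase"]), 6)
  expect_equal(dw$runs$minutes[dw$runs$phase == "telophase"], 12)

  ph$table$phase <- rep("interphase", 9)
  expect_equal(unname(dwell_times(ph)$minutes["telophase"]), 0)
})

test_that("curve aggregation reports mean, s.e.m. and n per time point", {
  one <- data.frame(cell_id = "a", time_min = c(0, 3), normalized_area = c(1, 1.1))
  five <- do.call(rbind, lapply(1:5, function(i) one))
  agg <- aggregate_curves(five)
  expect_true(all(agg$sem == 0))
  expect_identical(agg$n, rep(5L, 2))

  two <- rbind(data.frame(cell_id = "a", time_min = 3, normalized_area = 1),
               data.frame(cell_id = "b", time_min = 3, normalized_area = 2))
  agg2 <- aggregate_curves(two)
  expect_equal(agg2$mean, 1.5)
  expect_equal(agg2$sem, sd(c(1, 2)) / sqrt(2))
  expect_equal(agg2$sem, 0.5)

  single <- aggregate_curves(one)
  expect_true(all(single$single_cell))
  expect_true(all(single$sem == 0))
  expect_equal(single$mean, one$normalized_area)
})
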