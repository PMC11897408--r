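#' Run the in-vitro border-smoothness pipeline
#'
#' Segments every image with the fixed-sample recipe, scores each chromatin
#' object, summarizes per condition hierarchically (experiment means,
#' overall mean, s.e.m.) and, with exactly two conditions, runs the
#' normality-gated two-sample test on the per-object scores. With
#' `config$out_dir` set, `scores.csv` and `report.json` are written
#' (deterministic given config and seed).
#'
#' @param config a [pipeline_config()].
#' @param inputs data.frame with columns `image` (an [image_frame()], list
#'   column, or a TIFF path), `condition`, `experiment`.
#' @param verbose log stage boundaries and discards.
#' @return list: `scores` (data.frame), `summaries` (per condition),
#'   `test` (gate result or `NULL`), `stamp`.
#' @export
run_invitro_pipeline <- function(config, inputs, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"),
            all(c("image", "condition", "experiment") %in% names(inputs)))
  log_msg(verbose, "segmenting and scoring %d images", nrow(inputs))
  rows <- lapply(seq_len(nrow(inputs)), function(i) {
    img <- inputs$image[[i]]
    if (is.character(img)) {
      img <- read_image(img, pixel_size_um = config$pixel_size_um)
    }
    sc <- withCallingHandlers(
      score_image(img, config$segmentation, config$smoothness,
                  image_id = sprintf("img%03d", i)),
      warning = function(w) {
        log_msg(verbose, "image %d: %s", i, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (nrow(sc)) {
      sc$condition <- inputs$condition[i]
      sc$experiment <- inputs$experiment[i]
    }
    sc
  })
  scores <- do.call(rbind, rows[vapply(rows, nrow, 0L) > 0])
  if (is.null(scores) || !nrow(scores)) stop("no scorable objects in any image")

  summaries <- lapply(split(scores, scores$condition), function(d) {
    summarize_hierarchical(d$s, d$experiment, basis = "experiments")
  })
  conditions <- names(summaries)
  test <- NULL
  if (length(conditions) == 2) {
    a <- scores$s[scores$condition == conditions[1]]
    b <- scores$s[scores$condition == conditions[2]]
    test <- choose_test(a, b, config$stats)
    test$conditions <- conditions
  } else if (length(conditions) == 1) {
    warning("single condition: summary only, no test")
  }
  out <- list(scores = scores, summaries = summaries, test = test,
              stamp = config_stamp(config))
  if (!is.null(config$out_dir)) write_invitro_outputs(out, config)
  out
}

write_invitro_outputs <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- out$scores
  # units in header names: s dimensionless, areas px^2
  names(sc)[names(sc) == "area_px2"] <- "area_px2"
  write.csv(sc, file.path(config$out_dir, "scores.csv"), row.names = FALSE)
  report <- list(
    stamp = out$stamp,
    summaries = lapply(out$summaries, unclass),
    test = out$test)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Run the live-cell mitotic-exit pipeline
#'
#' For every single-cell time-lapse: live-cell segmentation per frame,
#' object extraction, tracking, anaphase-onset detection, anaphase-aligned
#' normalized area curve, phase classification and dwell times. Trajectories
#' without a qualifying mitosis are discarded and logged with the reason.
#' Curves are aggregated per condition (mean and s.e.m. per time point).
#'
#' @param config a [pipeline_config()].
#' @param inputs data.frame with columns `lapse` (a [time_lapse()] list
#'   column or multi-page TIFF path), `cell_id`, `condition`.
#' @param verbose log discards and stage boundaries.
#' @return list: `curves` (per-cell rows), `aggregated` (per condition),
#'   `phases`, `dwell` (per-cell telophase and per-phase minutes),
#'   `discarded` (data.frame cell_id/reason), `stamp`.
#' @export
run_livecell_pipeline <- function(config, inputs, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"),
            all(c("lapse", "cell_id", "condition") %in% names(inputs)))
  curves <- list(); phases_tabs <- list(); dwell_rows <- list()
  discarded <- data.frame(cell_id = character(0), reason = character(0))
  for (i in seq_len(nrow(inputs))) {
    lp <- inputs$lapse[[i]]
    if (is.character(lp)) {
      lp <- read_image(lp, pixel_size_um = config$pixel_size_um,
                       frame_interval_min = config$frame_interval_min)
    }
    cell <- inputs$cell_id[i]
    res <- tryCatch(
      analyze_trajectory(lp, config, cell),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      log_msg(verbose, "discarding %s: %s", cell, res)
      discarded <- rbind(discarded,
                         data.frame(cell_id = cell, reason = res))
      next
    }
    res$curve$condition <- inputs$condition[i]
    curves[[length(curves) + 1]] <- res$curve
    pt <- res$phases$table
    pt$cell_id <- cell; pt$condition <- inputs$condition[i]
    phases_tabs[[length(phases_tabs) + 1]] <- pt
    dw <- res$dwell$minutes
    dwell_rows[[length(dwell_rows) + 1]] <- data.frame(
      cell_id = cell, condition = inputs$condition[i],
      onset_frame = res$onset, t(dw))
  }
  if (!length(curves)) {
    warning("no valid mitotic trajectory; all inputs discarded")
    return(list(curves = NULL, aggregated = NULL, phases = NULL,
                dwell = NULL, discarded = discarded,
                stamp = config_stamp(config)))
  }
  curves_df <- do.call(rbind, curves)
  aggregated <- lapply(split(curves_df, curves_df$condition),
                       aggregate_curves)
  out <- list(curves = curves_df,
              aggregated = aggregated,
              phases = do.call(rbind, phases_tabs),
              dwell = do.call(rbind, dwell_rows),
              discarded = discarded,
              stamp = config_stamp(config))
  if (!is.null(config$out_dir)) write_livecell_outputs(out, config)
  out
}

#' Analyze one single-cell mitotic time-lapse
#'
#' The per-cell core of [run_livecell_pipeline()]: live-cell segmentation of
#' every frame, object extraction (at most the two largest masses),
#' tracking, anaphase-onset detection, the anaphase-aligned normalized area
#' curve, phase classification and dwell times. Errors (e.g. no qualifying
#' mitosis) propagate; the cohort pipeline catches them and logs discards.
#'
#' @param lapse a [time_lapse()].
#' @param config a [pipeline_config()].
#' @param cell_id identifier stamped on outputs.
#' @return list: `onset` (0-based frame), `curve`, `phases`, `dwell`.
#' @export
analyze_trajectory <- function(lapse, config, cell_id = "cell") {
  frames <- lapply(lapse$frames, function(fr) {
    mask <- segment_livecell(fr, config$segmentation,
                             on_degenerate = "empty")
    extract_objects(mask, config$segmentation$min_object_area_px2,
                    pixel_size_um = config$pixel_size_um,
                    frame_index = attr(fr, "frame_index"))
  })
  # keep at most the two largest objects (extract_objects sorts by area)
  frames <- lapply(frames, function(objs) head(objs, 2))
  traj <- link_objects(frames, lapse$frame_interval_min, cell_id)
  onset <- detect_anaphase_onset(traj, config$phases)
  curve <- normalize_area_curve(traj, onset)
  phases <- classify_phases(traj, config$phases, onset = onset)
  list(onset = onset, curve = curve, phases = phases,
       dwell = dwell_times(phases))
}

write_livecell_outputs <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$curves, file.path(config$out_dir, "curves.csv"),
            row.names = FALSE)
  write.csv(out$phases, file.path(config$out_dir, "phases.csv"),
            row.names = FALSE)
  write.csv(out$dwell, file.path(config$out_dir, "dwell_min.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(stamp = out$stamp,
         discarded = out$discarded,
         aggregated = out$aggregated),
    file.path(config$out_dir, "livecell_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Fit the chromatin-area expansion rate
#'
#' Least-squares slope of `normalized_area - 1` against time (minutes) on
#' the post-onset part of a curve, an estimate of the per-minute expansion
#' rate k in the linear growth model A(t) = A0 (1 + k t).
#'
#' @param curve a [normalize_area_curve()] data.frame.
#' @return slope k in 1/min.
#' @export
fit_expansion_rate <- function(curve) {
  d <- curve[curve$time_min >= 0, ]
  stopifnot(nrow(d) >= 2)
  unname(coef(lm(I(normalized_area - 1) ~ 0 + time_min, data = d)))
}

#' Plot aggregated area curves
#'
#' Mean normalized chromatin area vs time since anaphase onset, one line
#' per condition, with s.e.m. ribbons rendered as vertical bars.
#'
#' @param aggregated named list of [aggregate_curves()] tables (one per
#'   condition).
#' @param ... passed to [graphics::plot()].
#' @export
plot_area_curves <- function(aggregated, ...) {
  stopifnot(length(aggregated) >= 1)
  xr <- range(unlist(lapply(aggregated, function(d) d$time_min)))
  yr <- range(unlist(lapply(aggregated, function(d)
    c(d$mean - d$sem, d$mean + d$sem))))
  graphics::plot(NA, xlim = xr, ylim = yr,
                 xlab = "time since anaphase onset (min)",
                 ylab = "normalized chromatin area", ...)
  cols <- grDevices::hcl.colors(max(2, length(aggregated)), "Dark 3")
  for (i in seq_along(aggregated)) {
    d <- aggregated[[i]]
    graphics::lines(d$time_min, d$mean, col = cols[i], lwd = 2)
    graphics::segments(d$time_min, d$mean - d$sem, d$time_min,
                       d$mean + d$sem, col = cols[i])
  }
  graphics::legend("topleft", legend = names(aggregated), col =
                     cols[seq_along(aggregated)], lwd = 2, bty = "n")
  invisible(NULL)
}
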