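#' Mitotic phase-classification thresholds
#'
#' Size-rule cut-offs for classifying frames from the areas of the tracked
#' chromatin masses, all expressed as fractions of an interphase reference
#' nuclear area.
#'
#' @param metaphase_area_frac single mass below this fraction of the
#'   interphase reference is called metaphase (condensed); default 0.4.
#' @param anaphase_min_daughter_frac each daughter must be at least this
#'   fraction of the pre-split mass for a split to count; default 0.2.
#' @param telophase_exit_frac a daughter reaching this fraction of the
#'   interphase reference ends telophase (interphase begins); default 0.8.
#' @param anaphase_frames frames labelled anaphase from onset; default 2.
#' @param interphase_reference_area_px2 interphase nuclear area; `NA` means
#'   estimate from the trajectory (median single-object area of the first 5
#'   frames when the trajectory starts in interphase).
#' @return a `phase_thresholds` list.
#' @export
phase_thresholds <- function(metaphase_area_frac = 0.4,
                             anaphase_min_daughter_frac = 0.2,
                             telophase_exit_frac = 0.8,
                             anaphase_frames = 2L,
                             interphase_reference_area_px2 = NA_real_) {
  fr <- c(metaphase_area_frac, anaphase_min_daughter_frac,
          telophase_exit_frac)
  if (any(fr <= 0) || any(fr > 1)) {
    stop("all fraction thresholds must lie in (0, 1]")
  }
  structure(list(metaphase_area_frac = as.numeric(metaphase_area_frac),
                 anaphase_min_daughter_frac = as.numeric(anaphase_min_daughter_frac),
                 telophase_exit_frac = as.numeric(telophase_exit_frac),
                 anaphase_frames = as.integer(anaphase_frames),
                 interphase_reference_area_px2 = as.numeric(interphase_reference_area_px2)),
            class = "phase_thresholds")
}

#' Link segmented objects across frames into a trajectory
#'
#' Keeps the largest (at most two) objects per frame and links them across
#' consecutive frames by nearest centroids; when two objects persist, the
#' pairing minimizing the summed centroid displacement is chosen. After a
#' 1 -> 2 split both children are retained.
#'
#' @param frames list (one element per frame) of `chromatin_object` lists,
#'   as returned by [extract_objects()].
#' @param frame_interval_min frame spacing in minutes.
#' @param cell_id identifier carried through outputs.
#' @return a `trajectory`: per-frame object lists (ordered so object 1
#'   links to object 1 of the previous frame), `n_objects` per frame,
#'   `frame_interval_min`, `cell_id`.
#' @export
link_objects <- function(frames, frame_interval_min = 3, cell_id = "cell") {
  stopifnot(length(frames) >= 1)
  linked <- vector("list", length(frames))
  prev <- NULL
  for (i in seq_along(frames)) {
    objs <- frames[[i]]
    if (length(objs) > 2) {
      areas <- vapply(objs, function(o) o$area_px2, 0)
      stop(sprintf(
        "frame %d has %d candidate objects (areas: %s); ambiguous linking",
        i - 1, length(objs), paste(sort(areas, decreasing = TRUE),
                                   collapse = ", ")))
    }
    if (length(objs) == 2 && length(prev) == 2) {
      # 2-permutation assignment minimizing summed displacement
      d_keep <- centroid_dist(prev[[1]], objs[[1]]) +
        centroid_dist(prev[[2]], objs[[2]])
      d_swap <- centroid_dist(prev[[1]], objs[[2]]) +
        centroid_dist(prev[[2]], objs[[1]])
      if (d_swap < d_keep) objs <- objs[c(2, 1)]
    } else if (length(objs) == 2 && length(prev) == 1) {
      # keep left daughter first for reproducible ordering
      if (objs[[1]]$centroid[2] > objs[[2]]$centroid[2]) objs <- objs[c(2, 1)]
    }
    linked[[i]] <- objs
    prev <- objs
  }
  structure(list(frames = linked,
                 n_objects = vapply(linked, length, 0L),
                 frame_interval_min = frame_interval_min,
                 cell_id = cell_id),
            class = "trajectory")
}

centroid_dist <- function(a, b) {
  sqrt(sum((a$centroid - b$centroid)^2))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d frames (%.3g min interval), objects per frame: %s\n",
              x$cell_id, length(x$frames), x$frame_interval_min,
              paste(x$n_objects, collapse = "")))
  invisible(x)
}

traj_areas <- function(traj) {
  vapply(traj$frames, function(objs) {
    if (!length(objs)) 0 else sum(vapply(objs, function(o) o$area_px2, 0))
  }, 0)
}

#' Detect anaphase onset in a trajectory
#'
#' Onset (t = 0) is the first frame where two daughter masses are
#' segmentable: the smallest frame index with exactly two objects, each at
#' least `anaphase_min_daughter_frac` of the preceding single-mass area,
#' with the two-object state persisting for at least `persistence`
#' consecutive frames (an anti-flicker guard against transient spurious
#' splits).
#'
#' @param traj a [link_objects()] trajectory.
#' @param thresholds a [phase_thresholds()].
#' @param persistence consecutive qualifying frames required; default 2.
#' @return 0-based onset frame index.
#' @export
detect_anaphase_onset <- function(traj, thresholds = phase_thresholds(),
                                  persistence = 2L) {
  n <- length(traj$frames)
  last_single_area <- NA_real_
  for (i in seq_len(n)) {
    objs <- traj$frames[[i]]
    if (length(objs) == 1) {
      last_single_area <- objs[[1]]$area_px2
      next
    }
    if (length(objs) == 2 && !is.na(last_single_area)) {
      if (qualifies_split(objs, last_single_area, thresholds)) {
        run_ok <- TRUE
        horizon <- min(n, i + persistence - 1L)
        if (horizon > i) {
          for (j in (i + 1):horizon) {
            oj <- traj$frames[[j]]
            if (length(oj) != 2 ||
                !qualifies_split(oj, last_single_area, thresholds)) {
              run_ok <- FALSE
              break
            }
          }
        }
        if (run_ok && (n - i + 1L) >= persistence) return(i - 1L)
      }
    }
  }
  stop("no-mitosis: no persistent 1 -> 2 split found; trajectory discarded")
}

qualifies_split <- function(objs, pre_area, th) {
  all(vapply(objs, function(o) o$area_px2, 0) >=
        th$anaphase_min_daughter_frac * pre_area)
}

#' Anaphase-aligned normalized area curve
#'
#' For each frame the summed area of the tracked masses is divided by the
#' summed area at the onset frame; time is `(frame - onset) *
#' frame_interval_min`, so the first anaphase frame sits at t = 0 with
#' normalized area exactly 1. Frames before onset appear at negative time,
#' normalized by the same denominator.
#'
#' @param traj a trajectory.
#' @param onset 0-based onset frame from [detect_anaphase_onset()].
#' @param per_daughter if `TRUE`, return one row per daughter mass
#'   (columns gain `object_id`), each normalized by the same summed-onset
#'   denominator.
#' @return `area_curve` data.frame: cell_id, time_min, normalized_area
#'   (and object_id in per-daughter mode).
#' @export
normalize_area_curve <- function(traj, onset, per_daughter = FALSE) {
  n <- length(traj$frames)
  stopifnot(onset >= 0, onset < n)
  denom <- sum(vapply(traj$frames[[onset + 1]], function(o) o$area_px2, 0))
  if (denom <= 0) stop("zero summed area at onset frame")
  times <- ((seq_len(n) - 1) - onset) * traj$frame_interval_min
  if (!per_daughter) {
    curve <- data.frame(cell_id = traj$cell_id, time_min = times,
                        normalized_area = traj_areas(traj) / denom)
  } else {
    rows <- lapply(seq_len(n), function(i) {
      objs <- traj$frames[[i]]
      if (!length(objs)) return(NULL)
      data.frame(cell_id = traj$cell_id, time_min = times[i],
                 object_id = seq_along(objs),
                 normalized_area = vapply(objs, function(o) o$area_px2, 0) / denom)
    })
    curve <- do.call(rbind, rows)
  }
  class(curve) <- c("area_curve", "data.frame")
  curve
}

#' Classify mitotic phases from chromatin-mass sizes
#'
#' Size-rule classification: a single mass at or above
#' `telophase_exit_frac` of the interphase reference is interphase; a
#' single mass below `metaphase_area_frac` of the reference is metaphase;
#' single masses in between are prophase. Two-object frames are anaphase
#' for the first `anaphase_frames` frames after onset, then telophase until
#' a daughter reaches `telophase_exit_frac` of the reference, after which
#' frames are interphase.
#'
#' @param traj a trajectory.
#' @param thresholds a [phase_thresholds()]; if its interphase reference is
#'   `NA` and the trajectory starts with a qualifying single mass, the
#'   median single-object area of the first 5 frames is used.
#' @param onset optional onset frame; detected if missing.
#' @return a `phase_sequence`: data.frame (frame, phase) plus the
#'   thresholds used.
#' @export
classify_phases <- function(traj, thresholds = phase_thresholds(),
                            onset = NULL) {
  th <- thresholds
  if (is.na(th$interphase_reference_area_px2)) {
    th$interphase_reference_area_px2 <- estimate_interphase_reference(traj, th)
  }
  ref <- th$interphase_reference_area_px2
  if (is.null(onset)) {
    onset <- tryCatch(detect_anaphase_onset(traj, th), error = function(e) NA)
  }
  n <- length(traj$frames)
  phase <- character(n)
  post_exit <- FALSE
  for (i in seq_len(n)) {
    f <- i - 1L
    objs <- traj$frames[[i]]
    areas <- vapply(objs, function(o) o$area_px2, 0)
    if (length(objs) >= 2 && !is.na(onset) && f >= onset) {
      if (f < onset + th$anaphase_frames) {
        phase[i] <- "anaphase"
      } else if (!post_exit && any(areas >= th$telophase_exit_frac * ref)) {
        post_exit <- TRUE
        phase[i] <- "interphase"
      } else {
        phase[i] <- if (post_exit) "interphase" else "telophase"
      }
    } else if (length(objs) == 1) {
      if (areas[1] >= th$telophase_exit_frac * ref) {
        phase[i] <- "interphase"
      } else if (areas[1] < th$metaphase_area_frac * ref) {
        phase[i] <- "metaphase"
      } else {
        phase[i] <- "prophase"
      }
    } else {
      phase[i] <- NA_character_
    }
  }
  structure(list(table = data.frame(frame = seq_len(n) - 1L, phase = phase),
                 thresholds = th,
                 frame_interval_min = traj$frame_interval_min,
                 cell_id = traj$cell_id),
            class = "phase_sequence")
}

# interphase reference nuclear area when none is supplied: the median
# single-object area of the first 5 frames for a non-mitotic (never-split)
# trajectory; for a mitotic trajectory (which starts in the last metaphase,
# where the interphase scale is not observable) the pre-split mass is taken
# as a metaphase plate occupying 35% of the interphase nuclear footprint
estimate_interphase_reference <- function(traj, th,
                                          metaphase_to_interphase = 0.35) {
  singles <- which(traj$n_objects == 1)
  if (!length(singles)) {
    stop("cannot estimate interphase reference: no single-object frame; ",
         "supply interphase_reference_area_px2")
  }
  areas <- vapply(traj$frames[singles], function(o) o[[1]]$area_px2, 0)
  if (!any(traj$n_objects >= 2)) {
    return(median(areas[singles <= 5][seq_len(min(5, length(areas)))]))
  }
  pre_split <- areas[length(areas)]
  last_single <- singles[length(singles)]
  if (any(traj$n_objects[seq_len(max(last_single - 1, 1))] >= 2)) {
    pre_split <- areas[1]  # use the first single mass if splits interleave
  }
  pre_split / metaphase_to_interphase
}

#' Per-phase dwell times
#'
#' Total minutes spent in each phase (frames labelled with the phase times
#' the frame interval), plus the table of contiguous runs. Telophase dwell
#' is the headline readout of delayed chromatin decondensation.
#'
#' @param phases a [classify_phases()] result.
#' @return list: `minutes` (named numeric, all five phases), `runs`
#'   (data.frame phase/start_frame/n_frames/minutes).
#' @export
dwell_times <- function(phases) {
  stopifnot(inherits(phases, "phase_sequence"))
  lab <- phases$table$phase
  interval <- phases$frame_interval_min
  all_phases <- c("interphase", "prophase", "metaphase", "anaphase",
                  "telophase")
  minutes <- vapply(all_phases,
                    function(p) sum(lab == p, na.rm = TRUE) * interval, 0)
  r <- rle(ifelse(is.na(lab), "<NA>", lab))
  ends <- cumsum(r$lengths)
  runs <- data.frame(phase = r$values,
                     start_frame = ends - r$lengths,
                     n_frames = r$lengths,
                     minutes = r$lengths * interval)
  list(minutes = minutes, runs = runs)
}

#' Aggregate normalized-area curves across cells
#'
#' Per time point: mean over the cells observed at that time, s.e.m. =
#' sd / sqrt(n) (0 when n = 1, flagged), and n. Ragged curve ends are
#' allowed; curves must share the frame interval.
#'
#' @param curves list of [normalize_area_curve()] data.frames (or one
#'   rbind-ed data.frame).
#' @return data.frame: time_min, mean, sem, n, single_cell (TRUE where
#'   n = 1).
#' @export
aggregate_curves <- function(curves) {
  df <- if (is.data.frame(curves)) curves else do.call(rbind, curves)
  stopifnot(all(c("time_min", "normalized_area") %in% names(df)))
  sp <- split(df$normalized_area, df$time_min)
  out <- data.frame(time_min = as.numeric(names(sp)),
                    mean = vapply(sp, mean, 0),
                    sem = vapply(sp, function(v) {
                      if (length(v) < 2) 0 else sd(v) / sqrt(length(v))
                    }, 0),
                    n = vapply(sp, length, 0L))
  out$single_cell <- out$n == 1L
  out <- out[order(out$time_min), ]
  rownames(out) <- NULL
  out
}
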