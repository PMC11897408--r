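#' Mean marker intensity over a mask
#'
#' @param marker an [image_frame()] or numeric matrix (the measured
#'   channel).
#' @param mask non-empty logical matrix (typically the chromatin mask from
#'   the first channel).
#' @return arithmetic mean of marker over mask pixels.
#' @export
mean_on_mask <- function(marker, mask) {
  m <- as_plain_matrix_any(marker)
  storage.mode(mask) <- "logical"
  stopifnot(all(dim(m) == dim(mask)))
  if (!any(mask)) stop("empty mask: mean undefined")
  mean(m[mask])
}

#' Randomly place a circular background ROI in the cytoplasm
#'
#' Rejection-samples a disk centre uniformly over the image until the whole
#' disk lies in the cytoplasm (cell mask minus the chromatin mask dilated
#' by `exclude_dilate_px`); gives up after `retry_cap` draws. Used for
#' background subtraction of marker measurements.
#'
#' @param marker marker channel.
#' @param chromatin_mask,cell_mask logical matrices.
#' @param radius_px ROI radius; default 10.
#' @param seed integer seed (same seed, same ROI).
#' @param exclude_dilate_px chromatin-mask dilation excluded from the
#'   cytoplasm; default 4, so a perichromatin rim stays out of the background.
#' @param retry_cap maximum draws; default 1000.
#' @return list: `center` (0-based row/col), `radius_px`, `roi_mask`,
#'   `background_mean`.
#' @export
sample_background <- function(marker, chromatin_mask, cell_mask,
                              radius_px = 10, seed = 1L,
                              exclude_dilate_px = 4L, retry_cap = 1000L) {
  m <- as_plain_matrix_any(marker)
  cyto <- cell_mask & !dilate_disc(chromatin_mask, exclude_dilate_px)
  dims <- dim(m)
  # centres whose whole disk lies in the cytoplasm: Euclidean distance to
  # the nearest non-cytoplasm pixel must exceed the radius (distance
  # transform computed once so each rejection draw is O(1))
  dmap <- EBImage::imageData(EBImage::distmap(cyto * 1))
  admissible <- dmap > radius_px
  # the whole disk must also lie inside the frame
  rr <- matrix(0:(dims[1] - 1), dims[1], dims[2])
  cc <- matrix(0:(dims[2] - 1), dims[1], dims[2], byrow = TRUE)
  admissible <- admissible & rr >= radius_px & rr <= dims[1] - 1 - radius_px &
    cc >= radius_px & cc <= dims[2] - 1 - radius_px
  with_seed(seed, {
    for (i in seq_len(retry_cap)) {
      center <- c(sample.int(dims[1], 1L), sample.int(dims[2], 1L)) - 1L
      if (!admissible[center[1] + 1, center[2] + 1]) next
      roi <- disk_mask(dims, center, radius_px)
      return(list(center = center, radius_px = radius_px, roi_mask = roi,
                  background_mean = mean(m[roi])))
    }
    stop("no admissible background ROI found in ", retry_cap,
         " draws; try a smaller radius_px")
  })
}

#' Background-corrected marker intensity on chromatin
#'
#' Mean marker intensity over the chromatin mask minus the mean inside a
#' randomly placed cytoplasmic ROI. Negative corrected values are allowed
#' and flagged.
#'
#' @inheritParams sample_background
#' @return an `intensity_measurement`: `on_mask_mean`, `background_mean`,
#'   `corrected`, `bg_roi_center`, `bg_roi_radius_px`, `rng_seed`,
#'   `negative_flag`.
#' @export
corrected_intensity <- function(marker, chromatin_mask, cell_mask,
                                radius_px = 10, seed = 1L,
                                exclude_dilate_px = 4L) {
  on_mean <- mean_on_mask(marker, chromatin_mask)
  bg <- sample_background(marker, chromatin_mask, cell_mask,
                          radius_px = radius_px, seed = seed,
                          exclude_dilate_px = exclude_dilate_px)
  corrected <- on_mean - bg$background_mean
  structure(list(on_mask_mean = on_mean,
                 background_mean = bg$background_mean,
                 corrected = corrected,
                 bg_roi_center = bg$center,
                 bg_roi_radius_px = radius_px,
                 rng_seed = seed,
                 negative_flag = corrected < 0),
            class = "intensity_measurement")
}

#' @export
print.intensity_measurement <- function(x, ...) {
  cat(sprintf("<intensity_measurement> on-mask %.4g - background %.4g = %.4g%s\n",
              x$on_mask_mean, x$background_mean, x$corrected,
              if (x$negative_flag) " [negative]" else ""))
  invisible(x)
}

#' Line-scan intensity profile
#'
#' 200 gray values sampled at equal spacing from `p0` to `p1` inclusive,
#' by bilinear interpolation on the pixel grid (0-based row/col pixel
#' centres).
#'
#' @param frame an [image_frame()] or numeric matrix.
#' @param p0,p1 endpoints, numeric (row, col), inside the frame.
#' @param n_samples number of samples; default 200.
#' @return data.frame: sample (1..n), row, col, value.
#' @export
line_scan <- function(frame, p0, p1, n_samples = 200L) {
  m <- as_plain_matrix_any(frame)
  dims <- dim(m)
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] > dims[1] - 1 || p[2] < 0 || p[2] > dims[2] - 1) {
      stop(sprintf("endpoint (%.1f, %.1f) outside the %d x %d frame",
                   p[1], p[2], dims[1], dims[2]))
    }
  }
  t <- seq(0, 1, length.out = n_samples)
  rows <- p0[1] + t * (p1[1] - p0[1])
  cols <- p0[2] + t * (p1[2] - p0[2])
  data.frame(sample = seq_len(n_samples), row = rows, col = cols,
             value = bilinear_at(m, rows, cols))
}

# bilinear interpolation at fractional 0-based (row, col) positions
bilinear_at <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(floor(rows), nr - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(cols), nc - 2); c0 <- pmax(c0, 0)
  fr <- rows - r0
  fc <- cols - c0
  i00 <- m[cbind(r0 + 1, c0 + 1)]
  i10 <- m[cbind(r0 + 2, c0 + 1)]
  i01 <- m[cbind(r0 + 1, c0 + 2)]
  i11 <- m[cbind(r0 + 2, c0 + 2)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

#' Detect cytoplasmic foci
#'
#' Algorithmic surrogate for visual foci scoring: the cytoplasm (cell mask
#' minus dilated chromatin mask) is thresholded at `fold` times its median
#' intensity; 8-connected components of at least `min_area_px2` are foci. A
#' cell shows "big" foci when any focus has area >= `big_area_px2` and mean
#' intensity >= `fold` times the cytoplasm median.
#'
#' @param marker marker channel.
#' @param chromatin_mask,cell_mask logical matrices.
#' @param fold intensity fold-threshold over the cytoplasm median;
#'   default 3.
#' @param min_area_px2 minimum focus area; default 4.
#' @param big_area_px2 "big focus" area; default 25.
#' @param exclude_dilate_px chromatin dilation excluded from cytoplasm (should exceed the perichromatin rim width);
#'   default 4, so a perichromatin rim stays out of the background.
#' @return a `foci_result`: `foci` (data.frame: focus_id, row, col,
#'   area_px2, mean_intensity), `big_foci_present`, `cytoplasm_median`,
#'   `threshold`, and the parameters used.
#' @export
detect_foci <- function(marker, chromatin_mask, cell_mask, fold = 3,
                        min_area_px2 = 4, big_area_px2 = 25,
                        exclude_dilate_px = 4L) {
  m <- as_plain_matrix_any(marker)
  cyto <- cell_mask & !dilate_disc(chromatin_mask, exclude_dilate_px)
  if (!any(cyto)) stop("empty cytoplasm region")
  med <- median(m[cyto])
  thr <- fold * med
  cand <- cyto & (m > thr)
  objs <- extract_objects(cand, min_area_px2)
  foci <- if (length(objs)) {
    do.call(rbind, lapply(seq_along(objs), function(i) {
      o <- objs[[i]]
      data.frame(focus_id = i, row = o$centroid[1], col = o$centroid[2],
                 area_px2 = o$area_px2, mean_intensity = mean(m[o$mask]))
    }))
  } else {
    data.frame(focus_id = integer(0), row = numeric(0), col = numeric(0),
               area_px2 = integer(0), mean_intensity = numeric(0))
  }
  big <- nrow(foci) > 0 &&
    any(foci$area_px2 >= big_area_px2 & foci$mean_intensity >= fold * med)
  structure(list(foci = foci, big_foci_present = big,
                 cytoplasm_median = med, threshold = thr,
                 fold = fold, min_area_px2 = min_area_px2,
                 big_area_px2 = big_area_px2),
            class = "foci_result")
}

#' @export
print.foci_result <- function(x, ...) {
  cat(sprintf("<foci_result> %d foci (threshold %.4g = %.3g x cytoplasm median), big foci: %s\n",
              nrow(x$foci), x$threshold, x$fold, x$big_foci_present))
  invisible(x)
}
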