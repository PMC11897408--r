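#' Segmentation configuration
#'
#' Holds the parameters of the two segmentation recipes: the fixed-sample
#' (in-vitro) recipe — median denoise, optional 8-bit conversion, Otsu
#' threshold, hole filling — and the live-cell recipe — Gaussian blur
#' (default sigma 1.5 px), Otsu threshold, hole filling.
#'
#' @param denoise_kernel_px odd median-filter kernel (>= 1); default 3, the
#'   smallest effective window.
#' @param gaussian_sigma_px blur sigma for the live-cell recipe; default 1.5.
#' @param min_object_area_px2 components below this area are dropped.
#' @param to_8bit rescale min -> 0, max -> 255 (integers) before
#'   thresholding; on for the in-vitro recipe, off for live-cell.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(denoise_kernel_px = 3L,
                                gaussian_sigma_px = 1.5,
                                min_object_area_px2 = 20,
                                to_8bit = TRUE) {
  if (denoise_kernel_px < 1 || denoise_kernel_px %% 2 == 0) {
    stop("denoise_kernel_px must be an odd integer >= 1")
  }
  if (gaussian_sigma_px < 0) stop("gaussian_sigma_px must be >= 0")
  structure(list(denoise_kernel_px = as.integer(denoise_kernel_px),
                 gaussian_sigma_px = as.numeric(gaussian_sigma_px),
                 min_object_area_px2 = as.numeric(min_object_area_px2),
                 to_8bit = to_8bit),
            class = "segmentation_config")
}

#' Median-filter denoising
#'
#' Each output pixel is the median of its kernel x kernel neighbourhood;
#' edges use reflect padding (edge pixel repeated), so a constant image is
#' unchanged and kernel 1 is the identity.
#'
#' @param frame an [image_frame()] or numeric matrix.
#' @param kernel_px odd integer kernel edge length.
#' @return same type as `frame`.
#' @export
denoise_median <- function(frame, kernel_px = 3L) {
  if (kernel_px < 1 || kernel_px %% 2 == 0) {
    stop("median kernel must be an odd integer >= 1")
  }
  if (kernel_px == 1) return(frame)
  out <- .median_filter_cpp(as_plain_matrix_any(frame), as.integer(kernel_px))
  restore_frame(out, frame)
}

as_plain_matrix_any <- function(x) {
  if (inherits(x, "image_frame")) as_plain_matrix(x) else x
}

restore_frame <- function(data, template) {
  if (inherits(template, "image_frame")) {
    image_frame(data, pixel_size_um = attr(template, "pixel_size_um"),
                channel = attr(template, "channel"),
                frame_index = attr(template, "frame_index"))
  } else data
}

# rescale to 0..255 integers (min -> 0, max -> 255)
rescale_8bit <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0, nrow(m), ncol(m)))
  round((m - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Otsu threshold
#'
#' Exhaustive sweep over the 256-bin histogram for the threshold maximizing
#' between-class variance; ties broken toward the smallest maximizing
#' threshold. The mask is `frame > threshold`. With `to_8bit` the frame is
#' first rescaled to 0-255 integers (as when images are converted to 8-bit
#' TIFF before quantification); otherwise the 256 bins span the intensity
#' range and the returned threshold is on the original scale.
#'
#' @param frame an [image_frame()] or numeric matrix with at least two
#'   distinct values.
#' @param to_8bit rescale to 8-bit integers first.
#' @param on_degenerate `"error"` (default) or `"empty"`: what to do when
#'   the image is constant and no threshold exists.
#' @return list with `threshold` (intensity, original scale) and `mask`
#'   (logical matrix).
#' @export
otsu_threshold <- function(frame, to_8bit = FALSE,
                           on_degenerate = c("error", "empty")) {
  on_degenerate <- match.arg(on_degenerate)
  m <- as_plain_matrix_any(frame)
  rng <- range(m)
  if (rng[1] == rng[2]) {
    if (on_degenerate == "error") {
      stop("degenerate input: constant image, no Otsu threshold exists")
    }
    return(list(threshold = NA_real_,
                mask = matrix(FALSE, nrow(m), ncol(m))))
  }
  if (to_8bit) {
    q <- rescale_8bit(m)
  } else {
    q <- pmin(floor((m - rng[1]) / (rng[2] - rng[1]) * 256), 255)
  }
  counts <- tabulate(as.integer(q) + 1L, nbins = 256L)
  t_bin <- otsu_sweep(counts)
  mask <- q > t_bin
  threshold <- if (to_8bit) {
    rng[1] + t_bin / 255 * (rng[2] - rng[1])
  } else {
    rng[1] + (t_bin + 1) / 256 * (rng[2] - rng[1])
  }
  list(threshold = threshold, mask = mask)
}

# between-class variance sweep over bins 0..254; smallest argmax
otsu_sweep <- function(counts) {
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)
  mu0 <- cumsum(counts * lev)
  mu_t <- mu0[256]
  bcv <- numeric(255)
  for (t in 1:255) {           # threshold bin t-1
    n0 <- w0[t]; n1 <- n - n0
    if (n0 == 0 || n1 == 0) { bcv[t] <- -Inf; next }
    m0 <- mu0[t] / n0
    m1 <- (mu_t - mu0[t]) / n1
    bcv[t] <- n0 / n * n1 / n * (m0 - m1)^2
  }
  which.max(bcv) - 1L          # which.max returns the first (smallest) max
}

#' Fill binary holes
#'
#' Background regions not 4-connected to the image border become
#' foreground; foreground pixels are never removed. Foreground components
#' are treated as 8-connected (the standard dual connectivity).
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  storage.mode(mask) <- "logical"
  .fill_holes_cpp(mask)
}

#' Segment a fixed-sample (in-vitro) chromatin image
#'
#' Median denoise, optional 8-bit conversion, Otsu threshold, hole filling
#' — the pipeline used for scoring chromatin substrates.
#'
#' @param frame an [image_frame()] or numeric matrix.
#' @param cfg a [segmentation_config()]; `to_8bit` defaults on here.
#' @param on_degenerate see [otsu_threshold()].
#' @return logical mask.
#' @export
segment_invitro <- function(frame, cfg = segmentation_config(),
                            on_degenerate = "error") {
  den <- denoise_median(frame, cfg$denoise_kernel_px)
  ot <- otsu_threshold(den, to_8bit = cfg$to_8bit,
                       on_degenerate = on_degenerate)
  if (all(!ot$mask)) return(ot$mask)
  fill_holes(ot$mask)
}

#' Segment a live-cell chromatin frame
#'
#' Gaussian blur (default sigma 1.5 px) then Otsu threshold then hole
#' filling — the recipe for H2B time-lapse frames. `sigma = 0` reduces to
#' thresholding plus hole filling. 8-bit conversion is off by default.
#'
#' @param frame an [image_frame()] or numeric matrix.
#' @param cfg a [segmentation_config()].
#' @param sigma blur sigma; defaults to `cfg$gaussian_sigma_px`.
#' @param on_degenerate see [otsu_threshold()].
#' @return logical mask.
#' @export
segment_livecell <- function(frame, cfg = segmentation_config(to_8bit = FALSE),
                             sigma = cfg$gaussian_sigma_px,
                             on_degenerate = "error") {
  if (sigma < 0) stop("sigma must be >= 0")
  m <- as_plain_matrix_any(frame)
  if (sigma > 0) {
    m <- as.matrix(EBImage::imageData(EBImage::gblur(m, sigma = sigma)))
  }
  ot <- otsu_threshold(m, to_8bit = cfg$to_8bit,
                       on_degenerate = on_degenerate)
  if (all(!ot$mask)) return(ot$mask)
  fill_holes(ot$mask)
}

#' Extract connected chromatin objects from a mask
#'
#' 8-connected components with area at least `min_area_px2`, sorted by
#' area descending. Centroids are arithmetic means of member pixel
#' coordinates (0-based row/col).
#'
#' @param mask logical matrix.
#' @param min_area_px2 minimum component area.
#' @param pixel_size_um physical pixel size used for `area_um2`.
#' @param frame_index frame index stamped on each object.
#' @return list of `chromatin_object`s: `mask`, `area_px2`, `area_um2`,
#'   `centroid` (row, col), `frame_index`.
#' @export
extract_objects <- function(mask, min_area_px2 = 0, pixel_size_um = 0.11,
                            frame_index = 0L) {
  storage.mode(mask) <- "logical"
  lab <- .label_components_cpp(mask)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  objs <- vector("list", nlab)
  keep <- logical(nlab)
  for (i in seq_len(nlab)) {
    omask <- lab == i
    area <- sum(omask)
    if (area < min_area_px2) next
    keep[i] <- TRUE
    px <- which(omask, arr.ind = TRUE) - 1L
    objs[[i]] <- structure(
      list(mask = omask, area_px2 = area,
           area_um2 = area * pixel_size_um^2,
           centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
           frame_index = as.integer(frame_index)),
      class = "chromatin_object")
  }
  objs <- objs[keep]
  objs[order(vapply(objs, function(o) o$area_px2, 0), decreasing = TRUE)]
}

#' @export
print.chromatin_object <- function(x, ...) {
  cat(sprintf("<chromatin_object> frame %d, area %d px^2 (%.2f um^2), centroid (%.1f, %.1f)\n",
              x$frame_index, x$area_px2, x$area_um2,
              x$centroid[1], x$centroid[2]))
  invisible(x)
}
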