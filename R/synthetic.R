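#' Parameters for a synthetic chromatin mass
#'
#' Describes one DAPI/H2B-like chromatin mass whose boundary in polar
#' coordinates is \deqn{r(\theta) = R (1 + a \sum_{j=1}^{m} c_j \cos(j\theta
#' + \phi_j)),} with seeded coefficients normalized so \eqn{\sum_j |c_j| =
#' 1}. The roughness amplitude `a` is therefore the maximum fractional
#' radial excursion and acts as the single "condensation" knob: `a = 0`
#' gives a perfect disk (a smooth, decondensed mass), large `a` a lobed,
#' rough cluster of condensed chromatin.
#'
#' @param image_size_px integer pair (rows, cols).
#' @param radius_px mean radius R in pixels.
#' @param roughness_amplitude a, dimensionless fraction of R (>= 0).
#' @param n_harmonics number of boundary harmonics m (>= 1).
#' @param foreground_intensity,background_intensity intensities on a [0, 1]
#'   scale; foreground must exceed background and both must be >= 0.
#' @param noise_sd additive Gaussian noise sd, intensity units (applied
#'   after blur; values clipped at 0).
#' @param blur_sigma_px Gaussian blur sigma in pixels, a point-spread
#'   surrogate (0 = none).
#' @param pixel_size_um physical pixel size.
#' @param seed integer seed; identical params + seed give bit-identical
#'   output.
#' @return a `mass_params` list, validated.
#' @export
mass_params <- function(image_size_px = c(160L, 160L),
                        radius_px = 40,
                        roughness_amplitude = 0,
                        n_harmonics = 8L,
                        foreground_intensity = 0.85,
                        background_intensity = 0.08,
                        noise_sd = 0,
                        blur_sigma_px = 1,
                        pixel_size_um = 0.11,
                        seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 8),
            radius_px > 0, n_harmonics >= 1, noise_sd >= 0,
            blur_sigma_px >= 0)
  if (roughness_amplitude < 0) stop("roughness_amplitude must be >= 0")
  if (background_intensity < 0 || foreground_intensity <= background_intensity) {
    stop("need foreground_intensity > background_intensity >= 0")
  }
  structure(list(image_size_px = as.integer(image_size_px),
                 radius_px = radius_px,
                 roughness_amplitude = roughness_amplitude,
                 n_harmonics = as.integer(n_harmonics),
                 foreground_intensity = foreground_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 blur_sigma_px = blur_sigma_px,
                 pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "mass_params")
}

# seeded harmonic boundary: list(cj, phij); sum(|cj|) == 1
draw_boundary_harmonics <- function(m) {
  cj <- rnorm(m)
  s <- sum(abs(cj))
  if (s == 0) cj[1] <- 1 else cj <- cj / s
  list(cj = cj, phij = runif(m, 0, 2 * pi))
}

# radial excursion S(theta) = sum_j cj cos(j theta + phij) for a matrix or
# vector of angles
boundary_excursion <- function(theta, harm) {
  s <- 0
  for (j in seq_along(harm$cj)) {
    s <- s + harm$cj[j] * cos(j * theta + harm$phij[j])
  }
  s
}

# rasterize pixel-center-in-region for boundary R(1 + a S(theta)) centered
# at center_rc (0-based row/col); returns logical matrix
rasterize_mass <- function(dims, center_rc, radius_px, amplitude, harm) {
  nr <- dims[1]; nc <- dims[2]
  dy <- matrix(0:(nr - 1) - center_rc[1], nr, nc)
  dx <- matrix(0:(nc - 1) - center_rc[2], nr, nc, byrow = TRUE)
  dist <- sqrt(dy^2 + dx^2)
  if (amplitude == 0) return(dist <= radius_px)
  theta <- atan2(dy, dx)
  dist <= radius_px * (1 + amplitude * boundary_excursion(theta, harm))
}

# maximum radius over a fine angular grid; used for fit-in-frame checks
max_boundary_radius <- function(radius_px, amplitude, harm) {
  if (amplitude == 0) return(radius_px)
  th <- seq(0, 2 * pi, length.out = 4096)
  radius_px * (1 + amplitude * max(boundary_excursion(th, harm)))
}

check_mass_fits <- function(dims, center_rc, rmax, margin = 1) {
  room <- min(center_rc[1], dims[1] - 1 - center_rc[1],
              center_rc[2], dims[2] - 1 - center_rc[2])
  if (rmax > room - margin) {
    stop(sprintf(
      "mass boundary (max radius %.2f px) exits the %d x %d frame", rmax,
      dims[1], dims[2]))
  }
}

# blur (EBImage gblur) then additive Gaussian noise, clipped at 0
render_intensity <- function(mask, fg, bg, blur_sigma, noise_sd) {
  img <- matrix(bg, nrow(mask), ncol(mask))
  img[mask] <- fg
  if (blur_sigma > 0) {
    img <- as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = blur_sigma)))
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  pmax(img, 0)
}

#' Generate a synthetic chromatin mass image with ground truth
#'
#' Draws one harmonic-boundary chromatin mass (see [mass_params()]),
#' rasterizes it (pixel-center-in-region rule, 0-based row/col, origin
#' top-left), renders intensity, applies Gaussian blur as a point-spread
#' surrogate and then additive Gaussian noise clipped at zero. The pre-blur
#' rasterization is returned as the true mask.
#'
#' @param params a [mass_params()] object.
#' @return list with `frame` (an [image_frame()]), `true_mask` (logical
#'   matrix) and `ground_truth` (list: roughness amplitude, radius, true
#'   area in px^2, center, harmonics).
#' @examples
#' g <- make_chromatin_mass(mass_params(roughness_amplitude = 0.2, seed = 3))
#' g$ground_truth$true_area_px2
#' @export
make_chromatin_mass <- function(params) {
  stopifnot(inherits(params, "mass_params"))
  with_seed(params$seed, {
    dims <- params$image_size_px
    center <- (dims - 1) / 2
    harm <- draw_boundary_harmonics(params$n_harmonics)
    rmax <- max_boundary_radius(params$radius_px, params$roughness_amplitude,
                                harm)
    check_mass_fits(dims, center, rmax)
    true_mask <- rasterize_mass(dims, center, params$radius_px,
                                params$roughness_amplitude, harm)
    img <- render_intensity(true_mask, params$foreground_intensity,
                            params$background_intensity,
                            params$blur_sigma_px, params$noise_sd)
    list(frame = image_frame(img, pixel_size_um = params$pixel_size_um),
         true_mask = true_mask,
         ground_truth = list(roughness_amplitude = params$roughness_amplitude,
                             radius_px = params$radius_px,
                             true_area_px2 = sum(true_mask),
                             center_rc = center,
                             harmonics = harm))
  })
}

#' Parameters for a synthetic mitotic-exit time-lapse
#'
#' Emulates an H2B-labelled single-cell mitotic trajectory: a condensed
#' metaphase mass up to `onset_frame`, then two daughter masses (mirror
#' images of one boundary draw) that separate at constant speed and expand
#' so the true summed daughter area follows \eqn{A(t) = A_0 (1 + k t)}
#' (t in minutes after onset, clipped at `area_max_px2`).
#'
#' @param n_frames number of frames.
#' @param frame_interval_min minutes between frames.
#' @param onset_frame 0-based index of the first two-daughter frame.
#' @param initial_area_px2 A0, the summed chromatin area at onset (equal to
#'   the metaphase-mass area).
#' @param expansion_rate k, per-minute fractional area growth (>= 0).
#' @param area_max_px2 ceiling for the true summed area.
#' @param separation_speed_px_per_frame centre-to-centre half-speed of the
#'   separating daughters.
#' @param initial_half_separation_px half distance between daughter centres
#'   at onset.
#' @param roughness_amplitude,n_harmonics boundary roughness (see
#'   [mass_params()]).
#' @param interphase_reference_area_px2 nuclear area of an interphase cell,
#'   used to derive ground-truth phase labels; default `initial_area_px2 /
#'   0.35` (a metaphase plate occupies roughly a third of the interphase
#'   nuclear footprint).
#' @param anaphase_frames number of frames labelled anaphase from onset.
#' @param telophase_exit_frac a daughter reaching this fraction of the
#'   interphase reference area ends telophase in the ground truth.
#' @param phase_truth optional explicit per-frame labels overriding the
#'   derived ones.
#' @param image_size_px,foreground_intensity,background_intensity,noise_sd,blur_sigma_px,pixel_size_um,seed
#'   as in [mass_params()].
#' @return a `timelapse_params` list.
#' @export
timelapse_params <- function(n_frames = 20L,
                             frame_interval_min = 3,
                             onset_frame = 8L,
                             initial_area_px2 = pi * 16^2,
                             expansion_rate = 0.05,
                             area_max_px2 = Inf,
                             separation_speed_px_per_frame = 2,
                             initial_half_separation_px = 14,
                             roughness_amplitude = 0.04,
                             n_harmonics = 6L,
                             interphase_reference_area_px2 = initial_area_px2 / 0.35,
                             anaphase_frames = 2L,
                             telophase_exit_frac = 0.8,
                             phase_truth = NULL,
                             image_size_px = c(128L, 256L),
                             foreground_intensity = 0.85,
                             background_intensity = 0.08,
                             noise_sd = 0,
                             blur_sigma_px = 1,
                             pixel_size_um = 0.11,
                             seed = 1L) {
  stopifnot(n_frames >= 2, frame_interval_min > 0,
            onset_frame >= 1, onset_frame < n_frames,
            initial_area_px2 > 0, expansion_rate >= 0,
            separation_speed_px_per_frame >= 0, anaphase_frames >= 1,
            telophase_exit_frac > 0, telophase_exit_frac <= 1)
  if (!is.null(phase_truth) && length(phase_truth) != n_frames) {
    stop("phase_truth must have one label per frame")
  }
  structure(as.list(environment()), class = "timelapse_params")
}

#' Generate a synthetic mitotic-exit time-lapse with ground truth
#'
#' See [timelapse_params()] for the model. Frames before `onset_frame`
#' contain exactly one mass; frames at and after onset contain two
#' non-touching daughter masses (the generator errors if the configured
#' geometry would make them touch or exit the frame).
#'
#' @param params a [timelapse_params()] object.
#' @return list with `lapse` (a [time_lapse()]), `true_masks` (list of
#'   logical matrices) and `ground_truth` (data.frame: frame, time_min,
#'   n_objects, true_area_px2 — summed raster area —, true_norm — the
#'   analytic \eqn{1 + kt} after clipping —, phase).
#' @export
make_decondensation_timelapse <- function(params) {
  stopifnot(inherits(params, "timelapse_params"))
  p <- params
  with_seed(p$seed, {
    dims <- p$image_size_px
    center <- (dims - 1) / 2
    harm <- draw_boundary_harmonics(p$n_harmonics)
    r0 <- sqrt(p$initial_area_px2 / pi)          # single metaphase mass
    r_daughter0 <- sqrt(p$initial_area_px2 / 2 / pi)

    frames <- vector("list", p$n_frames)
    true_masks <- vector("list", p$n_frames)
    truth <- data.frame(frame = 0:(p$n_frames - 1))
    truth$time_min <- (truth$frame - p$onset_frame) * p$frame_interval_min
    truth$n_objects <- ifelse(truth$frame < p$onset_frame, 1L, 2L)
    truth$true_norm <- NA_real_
    truth$true_area_px2 <- NA_real_

    for (f in seq_len(p$n_frames) - 1L) {
      if (f < p$onset_frame) {
        rmax <- max_boundary_radius(r0, p$roughness_amplitude, harm)
        check_mass_fits(dims, center, rmax)
        mask <- rasterize_mass(dims, center, r0, p$roughness_amplitude, harm)
        truth$true_norm[f + 1] <- NA_real_
      } else {
        t_min <- (f - p$onset_frame) * p$frame_interval_min
        scale <- min(1 + p$expansion_rate * t_min,
                     p$area_max_px2 / p$initial_area_px2)
        rd <- r_daughter0 * sqrt(scale)
        half_sep <- p$initial_half_separation_px +
          p$separation_speed_px_per_frame * (f - p$onset_frame)
        c1 <- c(center[1], center[2] - half_sep)
        c2 <- c(center[1], center[2] + half_sep)
        rmax <- max_boundary_radius(rd, p$roughness_amplitude, harm)
        check_mass_fits(dims, c1, rmax)
        check_mass_fits(dims, c2, rmax)
        if (2 * half_sep <= 2 * rmax + 1) {
          stop(sprintf("daughter masses touch at frame %d (separation %.1f, max radius %.1f)",
                       f, 2 * half_sep, rmax))
        }
        m1 <- rasterize_mass(dims, c1, rd, p$roughness_amplitude, harm)
        # mirror of the same boundary draw: reflect columns
        m2 <- rasterize_mass(dims, c(c2[1], (dims[2] - 1) - c2[2]), rd,
                             p$roughness_amplitude, harm)[, dims[2]:1]
        mask <- m1 | m2
        truth$true_norm[f + 1] <- scale
      }
      truth$true_area_px2[f + 1] <- sum(mask)
      img <- render_intensity(mask, p$foreground_intensity,
                              p$background_intensity, p$blur_sigma_px,
                              p$noise_sd)
      frames[[f + 1]] <- image_frame(img, pixel_size_um = p$pixel_size_um,
                                     frame_index = f)
      true_masks[[f + 1]] <- mask
    }

    truth$phase <- if (!is.null(p$phase_truth)) {
      as.character(p$phase_truth)
    } else {
      derive_phase_truth(truth, p)
    }
    list(lapse = time_lapse(frames, p$frame_interval_min),
         true_masks = true_masks,
         ground_truth = truth)
  })
}

# ground-truth phase labels from the analytic areas: metaphase before
# onset, anaphase for anaphase_frames from onset, telophase until one
# daughter reaches telophase_exit_frac of the interphase reference
derive_phase_truth <- function(truth, p) {
  phase <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    f <- truth$frame[i]
    if (f < p$onset_frame) {
      phase[i] <- "metaphase"
    } else if (f < p$onset_frame + p$anaphase_frames) {
      phase[i] <- "anaphase"
    } else {
      daughter_area <- p$initial_area_px2 * truth$true_norm[i] / 2
      exit <- daughter_area >=
        p$telophase_exit_frac * p$interphase_reference_area_px2
      phase[i] <- if (exit) "interphase" else "telophase"
    }
  }
  phase
}

#' Parameters for a synthetic two-channel cell
#'
#' Emulates a perichromatin immunostaining: channel 1 is the chromatin mass
#' (per [mass_params()]); channel 2 carries `rim_intensity` on the
#' perichromatin rim band (dilation of the chromatin mask by `rim_width_px`
#' minus the mask), `cytoplasm_intensity` elsewhere inside the cell disk,
#' plus `n_foci` bright cytoplasmic foci, before additive noise.
#'
#' @param chromatin a [mass_params()] object.
#' @param rim_width_px rim band width (dilation radius), >= 1.
#' @param rim_intensity,cytoplasm_intensity marker intensities.
#' @param cytoplasm_radius_px cell disk radius; the rim band must fit
#'   inside it.
#' @param n_foci number of cytoplasmic foci (>= 0).
#' @param focus_radius_px,focus_intensity focus geometry and brightness.
#' @param marker_noise_sd additive Gaussian noise on the marker channel.
#' @param seed integer seed.
#' @return a `two_channel_params` list.
#' @export
two_channel_params <- function(chromatin = mass_params(image_size_px = c(192L, 192L),
                                                       radius_px = 30),
                               rim_width_px = 3L,
                               rim_intensity = 0.6,
                               cytoplasm_intensity = 0.15,
                               cytoplasm_radius_px = 80,
                               n_foci = 0L,
                               focus_radius_px = 4,
                               focus_intensity = 0.9,
                               marker_noise_sd = 0,
                               seed = 1L) {
  stopifnot(inherits(chromatin, "mass_params"), rim_width_px >= 1,
            cytoplasm_radius_px > chromatin$radius_px,
            n_foci >= 0, focus_radius_px > 0, marker_noise_sd >= 0,
            rim_intensity >= 0, cytoplasm_intensity >= 0,
            focus_intensity >= 0)
  structure(as.list(environment()), class = "two_channel_params")
}

# disk mask around 0-based center
disk_mask <- function(dims, center_rc, radius) {
  dy <- matrix(0:(dims[1] - 1) - center_rc[1], dims[1], dims[2])
  dx <- matrix(0:(dims[2] - 1) - center_rc[2], dims[1], dims[2], byrow = TRUE)
  sqrt(dy^2 + dx^2) <= radius
}

# morphological dilation by a disc of the given radius (EBImage)
dilate_disc <- function(mask, radius) {
  if (radius < 1) return(mask)
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(mask * 1, brush)) > 0
}

#' Generate a synthetic two-channel cell with ground truth
#'
#' See [two_channel_params()]. Foci centres are rejection-sampled in the
#' cytoplasm (off chromatin and rim, fully inside the cell) with pairwise
#' separation of at least four focus radii; after 1000 failed draws an
#' error is raised.
#'
#' @param params a [two_channel_params()] object.
#' @return list with `chromatin` and `marker` ([image_frame()]s),
#'   `true_mask` (chromatin), and `ground_truth` (rim/cell/cytoplasm masks,
#'   intensities, foci centre table).
#' @export
make_two_channel_cell <- function(params) {
  stopifnot(inherits(params, "two_channel_params"))
  p <- params
  cp <- p$chromatin
  dims <- cp$image_size_px
  center <- (dims - 1) / 2
  with_seed(p$seed, {
    harm <- draw_boundary_harmonics(cp$n_harmonics)
    rmax <- max_boundary_radius(cp$radius_px, cp$roughness_amplitude, harm)
    check_mass_fits(dims, center, rmax)
    chrom_mask <- rasterize_mass(dims, center, cp$radius_px,
                                 cp$roughness_amplitude, harm)
    cell_mask <- disk_mask(dims, center, p$cytoplasm_radius_px)
    dilated <- dilate_disc(chrom_mask, p$rim_width_px)
    rim_mask <- dilated & !chrom_mask
    if (any(rim_mask & !cell_mask)) {
      stop("rim band exits the cell disk; increase cytoplasm_radius_px")
    }
    cyto_mask <- cell_mask & !dilated

    marker <- matrix(0, dims[1], dims[2])
    marker[cyto_mask] <- p$cytoplasm_intensity
    marker[rim_mask] <- p$rim_intensity

    foci <- data.frame(row = numeric(0), col = numeric(0))
    if (p$n_foci > 0) {
      foci <- place_foci(cyto_mask, p$n_foci, p$focus_radius_px)
      for (i in seq_len(nrow(foci))) {
        fm <- disk_mask(dims, c(foci$row[i], foci$col[i]), p$focus_radius_px)
        marker[fm] <- p$focus_intensity
      }
    }
    if (p$marker_noise_sd > 0) {
      marker <- pmax(marker + rnorm(length(marker), 0, p$marker_noise_sd), 0)
    }
    chrom_img <- render_intensity(chrom_mask, cp$foreground_intensity,
                                  cp$background_intensity, cp$blur_sigma_px,
                                  cp$noise_sd)
    list(chromatin = image_frame(chrom_img, pixel_size_um = cp$pixel_size_um,
                                 channel = "chromatin"),
         marker = image_frame(marker, pixel_size_um = cp$pixel_size_um,
                              channel = "marker"),
         true_mask = chrom_mask,
         ground_truth = list(rim_mask = rim_mask, cell_mask = cell_mask,
                             cytoplasm_mask = cyto_mask,
                             rim_intensity = p$rim_intensity,
                             cytoplasm_intensity = p$cytoplasm_intensity,
                             focus_intensity = p$focus_intensity,
                             focus_radius_px = p$focus_radius_px,
                             foci = foci))
  })
}

# rejection-sample n foci centres: focus disk fully inside the cytoplasm
# region, centres pairwise >= 4 * focus_radius apart
place_foci <- function(cyto_mask, n, focus_radius, retry_cap = 1000L) {
  dims <- dim(cyto_mask)
  # admissible centres: cytoplasm eroded so the focus disk fits
  idx <- which(cyto_mask, arr.ind = TRUE) - 1L  # 0-based
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > retry_cap) {
      stop("could not place foci after ", retry_cap,
           " draws; reduce n_foci or focus_radius_px")
    }
    cand <- idx[sample.int(nrow(idx), 1L), ]
    fm <- disk_mask(dims, cand, focus_radius)
    if (any(fm & !cyto_mask)) next
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      if (any(d < 4 * focus_radius)) next
    }
    centers <- rbind(centers, cand)
  }
  data.frame(row = centers[, 1], col = centers[, 2])
}
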