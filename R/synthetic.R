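## Synthetic-data generators. Every generator draws from a single explicit
## stream seeded by `seed` (restored on exit), and returns a `ground_truth`
## record whose realized entries can be recovered by recounting the emitted
## artifact.

# Rejection-sampled center placement with pairwise minimum separation.
place_centers <- function(n, shape, margin, min_sep, max_tries = 5000L) {
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  lo <- c(1 + margin, 1 + margin)
  hi <- c(shape[1] - margin, shape[2] - margin)
  if (any(hi < lo)) stop("placement error: image too small for requested margin")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (try in seq_len(max_tries)) {
    cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    ok <- placed == 0L ||
      all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                        matrix(cand, placed, 2, byrow = TRUE))^2)) >= min_sep)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n) {
        colnames(centers) <- c("row", "col")
        return(centers)
      }
    }
  }
  stop("placement error: could not place objects at the requested density")
}

#' Simulate a two-channel cell image with punctate condensates
#'
#' Draws `n_spots` isotropic Gaussian spots (truncated at 4 sigma) at
#' identical positions in two channels over a uniform diffuse background,
#' emulating co-localized condensates formed by an interacting bait-prey
#' pair. When `snr_target` is supplied, the spot amplitude is solved so that
#' the fraction of the image's integrated intensity lying inside the spot
#' ROIs (disks of radius 4 sigma) equals the target.
#'
#' @param n_spots Number of condensates (>= 0).
#' @param spot_sigma_px Gaussian sigma of each spot in pixels.
#' @param spot_amplitude Peak amplitude above background; ignored when
#'   `snr_target` is given.
#' @param background Uniform background intensity (> 0 when `snr_target`
#'   is used).
#' @param snr_target Desired in-spot integrated-intensity fraction in
#'   `[0, 1]`, or `NULL` to use `spot_amplitude` directly.
#' @param shape Image dimensions `c(rows, cols)`.
#' @param seed Integer seed.
#' @return A list with `channel1`, `channel2` ([image_plane]s) and
#'   `ground_truth` recording spot centers, the ROI radius and the realized
#'   in-spot intensity fraction (recounted from the emitted pixels).
#' @examples
#' sim <- make_condensate_cell(n_spots = 5, snr_target = 0.5, seed = 1)
#' sim$ground_truth$realized$in_spot_fraction
#' @export
make_condensate_cell <- function(n_spots, spot_sigma_px = 2,
                                 spot_amplitude = 100, background = 10,
                                 snr_target = NULL, shape = c(128, 128),
                                 seed = 1) {
  stopifnot(n_spots >= 0, spot_sigma_px > 0, background >= 0)
  withr::local_seed(seed)
  roi_r <- 4 * spot_sigma_px
  centers <- place_centers(n_spots, shape, margin = roi_r + 1,
                           min_sep = 2 * roi_r)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  unit <- matrix(0, shape[1], shape[2])   # sum of unit-amplitude spots
  roi <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(n_spots)) {
    d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
    inside <- d2 <= roi_r^2
    unit[inside] <- unit[inside] + exp(-d2[inside] / (2 * spot_sigma_px^2))
    roi <- roi | inside
  }
  if (!is.null(snr_target)) {
    stopifnot(snr_target >= 0, snr_target < 1)
    if (n_spots == 0 && snr_target > 0) {
      stop("cannot hit a positive snr_target with zero spots")
    }
    n_px <- prod(shape); roi_px <- sum(roi)
    if (n_spots > 0) {
      if (background <= 0) stop("snr_target requires a positive background")
      if (snr_target <= roi_px / n_px) {
        stop("snr_target below the background fraction already inside ROIs")
      }
      spot_sum <- background * (snr_target * n_px - roi_px) / (1 - snr_target)
      spot_amplitude <- spot_sum / sum(unit)
    }
  }
  img <- background + spot_amplitude * unit
  frac <- if (n_spots == 0) 0 else sum(img[roi]) / sum(img)
  gt <- ground_truth(
    kind = "condensate_cell",
    params = list(n_spots = n_spots, spot_sigma_px = spot_sigma_px,
                  background = background, snr_target = snr_target,
                  shape = shape),
    realized = list(centers = centers, roi_radius_px = roi_r,
                    spot_amplitude = spot_amplitude,
                    in_spot_fraction = frac),
    seed = seed
  )
  list(channel1 = image_plane(img, channel = "CFP"),
       channel2 = image_plane(img, channel = "RFP"),
       ground_truth = gt)
}

#' Simulate a population of cells scored for condensate formation
#'
#' Each co-transfected cell is condensate-positive with probability
#' `true_efficiency`; positive cells receive a condensate signal-to-noise
#' ratio drawn from a normal distribution truncated to `[0, 1]`.
#'
#' @param n_cells Number of co-transfected cells (>= 1).
#' @param true_efficiency Per-cell condensate-formation probability.
#' @param snr_mean,snr_sd Mean and SD of the per-cell SNR draw.
#' @param seed Integer seed.
#' @return A list with `records` (a data.frame of per-cell observations:
#'   `cell_id`, `cotransfected`, `colocalized_positive`, `snr`) and
#'   `ground_truth` with the realized positive count.
#' @examples
#' pop <- make_population(200, true_efficiency = 0.3, seed = 1)
#' pop$ground_truth$realized$n_positive
#' @export
make_population <- function(n_cells, true_efficiency, snr_mean = 0.5,
                            snr_sd = 0.15, seed = 1) {
  stopifnot(n_cells >= 1, true_efficiency >= 0, true_efficiency <= 1)
  withr::local_seed(seed)
  positive <- stats::rbinom(n_cells, 1, true_efficiency) == 1
  snr <- rep(NA_real_, n_cells)
  snr[positive] <- pmin(1, pmax(0, stats::rnorm(sum(positive),
                                                snr_mean, snr_sd)))
  records <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(n_cells)),
    cotransfected = TRUE,
    colocalized_positive = positive,
    snr = snr
  )
  gt <- ground_truth(
    kind = "population",
    params = list(n_cells = n_cells, true_efficiency = true_efficiency,
                  snr_mean = snr_mean, snr_sd = snr_sd),
    realized = list(n_positive = sum(positive),
                    efficiency_pct = 100 * sum(positive) / n_cells,
                    snr_mean = if (any(positive)) mean(snr[positive]) else 0),
    seed = seed
  )
  list(records = records, ground_truth = gt)
}

# Anti-aliased coverage of a rotated bar (axis at angle theta, math
# convention x = col, y = -row) by 4x4 supersampling per pixel.
draw_bar <- function(shape, center, length_px, width_px, angle_deg) {
  th <- deg2rad(angle_deg)
  half <- ceiling(sqrt(length_px^2 + width_px^2) / 2) + 1
  r0 <- max(1, floor(center[1] - half)); r1 <- min(shape[1], ceiling(center[1] + half))
  c0 <- max(1, floor(center[2] - half)); c1 <- min(shape[2], ceiling(center[2] + half))
  sub <- expand.grid(row = r0:r1, col = c0:c1)
  off <- (seq_len(4) - 2.5) / 4
  cover <- numeric(nrow(sub))
  for (dr in off) for (dc in off) {
    x <- (sub$col + dc) - center[2]
    y <- -((sub$row + dr) - center[1])
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    cover <- cover + (abs(u) <= length_px / 2 & abs(v) <= width_px / 2)
  }
  list(rows = sub$row, cols = sub$col, coverage = cover / 16)
}

#' Simulate an image of oriented fiber-like bars
#'
#' Draws one anti-aliased bar per requested axial angle, non-overlapping,
#' emulating segmented actin stress fibers. Ground truth records each bar's
#' nominal angle plus the pixel count and aspect ratio of the re-binarized
#' (coverage >= 0.5) mask actually drawn.
#'
#' @param angles_deg Axial angles in `[0, 180)`, one per fiber.
#' @param length_px,width_px Bar dimensions in pixels.
#' @param intensity Peak bar intensity above zero background.
#' @param noise_sd Gaussian noise SD added to the image (clamped at 0).
#' @param shape Image dimensions `c(rows, cols)`.
#' @param seed Integer seed.
#' @return A list with `image` (an [image_plane]) and `ground_truth`.
#' @examples
#' fib <- make_fiber_image(c(0, 45, 90), seed = 1)
#' fib$ground_truth$realized$objects
#' @export
make_fiber_image <- function(angles_deg, length_px = 30, width_px = 3,
                             intensity = 100, noise_sd = 0,
                             shape = c(128, 128), seed = 1) {
  stopifnot(all(angles_deg >= 0), all(angles_deg < 180))
  withr::local_seed(seed)
  n <- length(angles_deg)
  half_diag <- sqrt(length_px^2 + width_px^2) / 2
  centers <- place_centers(n, shape, margin = half_diag + 2,
                           min_sep = 2 * half_diag + 3)
  img <- matrix(0, shape[1], shape[2])
  objects <- vector("list", n)
  for (i in seq_len(n)) {
    bar <- draw_bar(shape, centers[i, ], length_px, width_px, angles_deg[i])
    idx <- cbind(bar$rows, bar$cols)
    img[idx] <- pmax(img[idx], intensity * bar$coverage)
    keep <- bar$coverage >= 0.5
    ell <- moment_ellipse(bar$rows[keep], bar$cols[keep])
    objects[[i]] <- data.frame(
      angle_deg = angles_deg[i], area_px = sum(keep),
      aspect_ratio = ell$aspect_ratio,
      centroid_row = mean(bar$rows[keep]), centroid_col = mean(bar$cols[keep])
    )
  }
  if (noise_sd > 0) {
    img <- pmax(0, img + stats::rnorm(length(img), 0, noise_sd))
  }
  gt <- ground_truth(
    kind = "fiber_image",
    params = list(angles_deg = angles_deg, length_px = length_px,
                  width_px = width_px, intensity = intensity,
                  noise_sd = noise_sd, shape = shape),
    realized = list(objects = do.call(rbind, objects), centers = centers),
    seed = seed
  )
  list(image = image_plane(img), ground_truth = gt)
}

#' Simulate a persistent-random-walk cell trajectory
#'
#' The heading evolves by wrapped-normal increments of SD `turn_sd_deg`
#' between constant-length steps; lag-1 directional correlation has the
#' closed form `exp(-sigma_rad^2 / 2)`, which makes recovery targets exact.
#'
#' @param n_steps Number of steps (>= 7 so 6-frame windows are defined).
#' @param step_len_um Step length in micrometres.
#' @param turn_sd_deg SD of the heading increment per step, degrees.
#' @param dt_min Frame interval in minutes.
#' @param cell_id Label for the trajectory.
#' @param seed Integer seed.
#' @return A list with `trajectory` (data.frame: `cell_id`, `frame`,
#'   `t_min`, `x_um`, `y_um`) and `ground_truth` recording the headings.
#' @examples
#' tr <- make_trajectory(100, turn_sd_deg = 30, seed = 1)
#' head(tr$trajectory)
#' @export
make_trajectory <- function(n_steps, step_len_um = 1, turn_sd_deg = 30,
                            dt_min = 10, cell_id = "cell1", seed = 1) {
  stopifnot(n_steps >= 7, step_len_um > 0, dt_min > 0)
  withr::local_seed(seed)
  heading <- stats::runif(1, 0, 2 * pi) +
    cumsum(c(0, stats::rnorm(n_steps - 1, 0, deg2rad(turn_sd_deg))))
  x <- c(0, cumsum(step_len_um * cos(heading)))
  y <- c(0, cumsum(step_len_um * sin(heading)))
  traj <- data.frame(
    cell_id = cell_id, frame = 0:n_steps,
    t_min = (0:n_steps) * dt_min, x_um = x, y_um = y
  )
  gt <- ground_truth(
    kind = "trajectory",
    params = list(n_steps = n_steps, step_len_um = step_len_um,
                  turn_sd_deg = turn_sd_deg, dt_min = dt_min),
    realized = list(headings_rad = heading),
    seed = seed
  )
  list(trajectory = traj, ground_truth = gt)
}

#' Simulate a moving cell mask movie with optional intensity channels
#'
#' Per frame, a disk-like mask (radius modulated by a slowly rotating
#' protrusion term) whose center drifts at a constant pixel velocity.
#' Optional channels paint a uniform "iRFP" field and a "GFP" field whose
#' intensity is multiplied inside a wedge around a known direction,
#' providing a ground-truth contrast for ratiometric region statistics.
#'
#' @param n_frames Number of frames.
#' @param base_radius_px Mean disk radius in pixels.
#' @param drift_px_per_frame Length-2 vector `(dx, dy)` in pixels/frame
#'   (x = column, y = row).
#' @param protrusion_amp Amplitude of the radial modulation in pixels.
#' @param intensity_fields Optional list with elements `irfp` (uniform
#'   value) and `gfp` (list `base`, `wedge_direction`, `wedge_factor`,
#'   `wedge_half_deg`).
#' @param shape Frame dimensions `c(rows, cols)`.
#' @param seed Integer seed.
#' @return A list with `masks` (rows x cols x frames binary array),
#'   `channels` (named list of intensity arrays, possibly empty) and
#'   `ground_truth` recording the nominal center path and realized mask
#'   centroids.
#' @examples
#' mv <- make_moving_mask(5, drift_px_per_frame = c(1, 0), seed = 1)
#' dim(mv$masks)
#' @export
make_moving_mask <- function(n_frames, base_radius_px = 30,
                             drift_px_per_frame = c(0, 0),
                             protrusion_amp = 0, intensity_fields = NULL,
                             shape = c(128, 128), seed = 1) {
  stopifnot(n_frames >= 1, base_radius_px > 2)
  withr::local_seed(seed)
  drift <- as.numeric(drift_px_per_frame)
  max_r <- base_radius_px + abs(protrusion_amp)
  total <- drift * (n_frames - 1)
  # start so the full drifted path stays inside the frame with a 2 px margin
  c0 <- c((shape[2] - total[1]) / 2, (shape[1] - total[2]) / 2)  # (x, y)
  centers <- cbind(x = c0[1] + drift[1] * (seq_len(n_frames) - 1),
                   y = c0[2] + drift[2] * (seq_len(n_frames) - 1))
  if (any(centers[, "x"] - max_r < 2) || any(centers[, "x"] + max_r > shape[2] - 1) ||
      any(centers[, "y"] - max_r < 2) || any(centers[, "y"] + max_r > shape[1] - 1)) {
    stop("generation error: mask would touch the frame border")
  }
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  masks <- array(0, c(shape[1], shape[2], n_frames))
  phase0 <- stats::runif(1, 0, 2 * pi)
  realized_centroid <- matrix(NA_real_, n_frames, 2,
                              dimnames = list(NULL, c("x", "y")))
  for (f in seq_len(n_frames)) {
    dx <- cc - centers[f, "x"]
    dy <- rr - centers[f, "y"]
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    rad <- base_radius_px +
      protrusion_amp * sin(3 * th + phase0 + 2 * pi * (f - 1) / max(n_frames, 2))
    m <- r <= rad
    masks[, , f] <- m
    realized_centroid[f, ] <- c(mean(cc[m]), mean(rr[m]))
  }
  channels <- list()
  wedge_spec <- NULL
  if (!is.null(intensity_fields)) {
    if (!is.null(intensity_fields$irfp)) {
      ir <- array(0, dim(masks))
      ir[masks > 0] <- intensity_fields$irfp$value
      channels$irfp <- ir
    }
    if (!is.null(intensity_fields$gfp)) {
      g <- intensity_fields$gfp
      half <- if (is.null(g$wedge_half_deg)) 45 else g$wedge_half_deg
      gf <- array(0, dim(masks))
      for (f in seq_len(n_frames)) {
        m <- masks[, , f] > 0
        plane <- matrix(0, shape[1], shape[2])
        plane[m] <- g$base
        if (!is.null(g$wedge_direction)) {
          dir_ang <- atan2(g$wedge_direction[2], g$wedge_direction[1])
          th <- atan2(rr - centers[f, "y"], cc - centers[f, "x"])
          dang <- abs(((th - dir_ang) + pi) %% (2 * pi) - pi)
          inw <- m & (dang <= deg2rad(half))
          plane[inw] <- g$base * g$wedge_factor
        }
        gf[, , f] <- plane
      }
      channels$gfp <- gf
      wedge_spec <- list(direction = g$wedge_direction, factor = g$wedge_factor,
                         half_deg = half)
    }
  }
  gt <- ground_truth(
    kind = "moving_mask",
    params = list(n_frames = n_frames, base_radius_px = base_radius_px,
                  drift_px_per_frame = drift, protrusion_amp = protrusion_amp,
                  shape = shape),
    realized = list(centers = centers, centroids = realized_centroid,
                    wedge = wedge_spec),
    seed = seed
  )
  list(masks = masks, channels = channels, ground_truth = gt)
}

#' Simulate an image of plateau-disk adhesion puncta
#'
#' Each punctum is drawn as a flat disk of the requested area and peak
#' intensity on a dim background. Ground truth flags which puncta fall in
#' the focal-adhesion acceptance band (mean intensity 1200-4500 AU, size
#' 0.5-15 in the configured unit), judged on the realized drawn object so
#' the flags are exactly recountable.
#'
#' @param puncta Data.frame (or list coercible to one) with columns
#'   `area_um2` and `peak_intensity`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param background Background intensity (below the detection band).
#' @param shape Image dimensions `c(rows, cols)`.
#' @param size_unit `"area_um2"` or `"diameter_um"`; unit used for the
#'   in-band flag.
#' @param seed Integer seed.
#' @return A list with `image` (an [image_plane]) and `ground_truth` whose
#'   realized table carries per-punctum drawn area and the in-band flag.
#' @examples
#' p <- data.frame(area_um2 = c(2, 40), peak_intensity = c(2000, 2000))
#' sim <- make_puncta_image(p, seed = 1)
#' sim$ground_truth$realized$objects$in_band
#' @export
make_puncta_image <- function(puncta, pixel_size_um = 0.2, background = 100,
                              shape = c(256, 256), size_unit = "area_um2",
                              seed = 1) {
  puncta <- as.data.frame(puncta)
  withr::local_seed(seed)
  n <- nrow(puncta)
  img <- matrix(background, shape[1], shape[2])
  if (n == 0) {
    gt <- ground_truth("puncta_image",
                       params = list(pixel_size_um = pixel_size_um,
                                     shape = shape, size_unit = size_unit),
                       realized = list(objects = data.frame(), n_in_band = 0),
                       seed = seed)
    return(list(image = image_plane(img, pixel_size_um), ground_truth = gt))
  }
  radius_px <- sqrt(puncta$area_um2 / pi) / pixel_size_um
  margin <- max(radius_px) + 2
  centers <- place_centers(n, shape, margin = margin,
                           min_sep = 2 * max(radius_px) + 3)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  objects <- vector("list", n)
  for (i in seq_len(n)) {
    inside <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius_px[i]^2
    img[inside] <- puncta$peak_intensity[i]
    area_real <- sum(inside) * pixel_size_um^2
    size_val <- if (size_unit == "diameter_um") {
      2 * sqrt(area_real / pi)
    } else {
      area_real
    }
    objects[[i]] <- data.frame(
      area_um2_nominal = puncta$area_um2[i],
      peak_intensity = puncta$peak_intensity[i],
      area_px = sum(inside), area_um2 = area_real,
      centroid_row = centers[i, 1], centroid_col = centers[i, 2],
      in_band = puncta$peak_intensity[i] >= 1200 &
        puncta$peak_intensity[i] <= 4500 &
        size_val >= 0.5 & size_val <= 15
    )
  }
  objects <- do.call(rbind, objects)
  gt <- ground_truth(
    kind = "puncta_image",
    params = list(pixel_size_um = pixel_size_um, shape = shape,
                  size_unit = size_unit, background = background),
    realized = list(objects = objects, n_in_band = sum(objects$in_band)),
    seed = seed
  )
  list(image = image_plane(img, pixel_size_um), ground_truth = gt)
}

#' Simulate a fluorescence-recovery (FRAP) curve
#'
#' Pre-bleach frames at normalized intensity 1, then a one-phase
#' association recovery `F(t) = f0 + (plateau - f0) * (1 - exp(-k t))`
#' with optional Gaussian noise.
#'
#' @param f0 Normalized intensity immediately after bleaching.
#' @param plateau Recovery asymptote (`f0 <= plateau <= 1`).
#' @param k Recovery rate constant (per unit of `t`).
#' @param t Post-bleach time grid starting at 0 (seconds).
#' @param noise_sd Gaussian noise SD.
#' @param pre_bleach_frames Number of pre-bleach frames (1 s spacing).
#' @param seed Integer seed.
#' @return A list with `curve` (data.frame: `t_s`, `value`, plus attribute
#'   columns `phase` marking pre/post) and `ground_truth`.
#' @examples
#' fr <- make_frap_curve(0.2, 0.8, 0.05, t = 0:120, seed = 1)
#' head(fr$curve)
#' @export
make_frap_curve <- function(f0, plateau, k, t = 0:120, noise_sd = 0,
                            pre_bleach_frames = 30, seed = 1) {
  stopifnot(f0 >= 0, f0 <= plateau, plateau <= 1, k > 0,
            pre_bleach_frames >= 1)
  withr::local_seed(seed)
  pre_t <- seq(-pre_bleach_frames, -1)
  post <- f0 + (plateau - f0) * (1 - exp(-k * t))
  value <- c(rep(1, pre_bleach_frames), post)
  if (noise_sd > 0) value <- value + stats::rnorm(length(value), 0, noise_sd)
  curve <- data.frame(
    t_s = c(pre_t, t), value = value,
    phase = c(rep("pre", pre_bleach_frames), rep("post", length(t)))
  )
  attr(curve, "pre_frames") <- pre_bleach_frames
  gt <- ground_truth(
    kind = "frap_curve",
    params = list(f0 = f0, plateau = plateau, k = k, noise_sd = noise_sd,
                  pre_bleach_frames = pre_bleach_frames),
    realized = list(t_half = log(2) / k,
                    mobile_fraction = (plateau - f0) / (1 - f0)),
    seed = seed
  )
  list(curve = curve, ground_truth = gt)
}
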