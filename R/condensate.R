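## Condensate detection and bait-prey pair scoring.
##
## A bait-prey interaction is read out from two-channel images of cells in
## which interacting pairs form phase-separated condensates. Per cell:
## condensates are detected by thresholding + particle analysis in each
## channel, the cell is condensate-positive when particles co-localize
## across channels, and the condensate SNR is the fraction of the cell's
## integrated fluorescence residing inside detected particles. Per pair:
## efficiency = % positive of co-transfected cells, and the raw protein
## interaction index (PI) = (efficiency/100) x mean SNR of positive cells.

resolve_threshold <- function(pixels, policy) {
  if (is.character(policy)) policy <- list(method = policy)
  method <- policy$method
  if (is.null(method)) stop("config error: threshold policy needs a method")
  switch(method,
    automatic = ,
    background = {
      # robust background estimate: condensates are a small pixel fraction,
      # so median + k*MAD tracks the diffuse background level
      k <- if (is.null(policy$value)) 3 else policy$value
      stats::median(pixels) + k * stats::mad(pixels)
    },
    otsu = {
      mx <- max(pixels)
      if (mx == 0) return(Inf)  # blank image: nothing can exceed threshold
      EBImage::otsu(EBImage::Image(pixels / mx), range = c(0, 1)) * mx
    },
    fixed = {
      if (is.null(policy$value)) stop("config error: fixed policy needs value")
      policy$value
    },
    percentile = {
      if (is.null(policy$value)) {
        stop("config error: percentile policy needs value")
      }
      stats::quantile(pixels, policy$value, names = FALSE)
    },
    stop("config error: unknown threshold policy '", method, "'")
  )
}

#' Detect condensates in an image plane
#'
#' Threshold-then-label particle analysis: pixels strictly above the
#' resolved threshold are grouped into 8-connected components; components
#' smaller than `min_area_px` are discarded. Each particle carries its
#' area, integrated intensity and centroid.
#'
#' The default `"automatic"` policy estimates the diffuse background as
#' median + 3 MAD of the plane, which keeps the dim outskirts of each
#' condensate inside its particle (condensates occupy a small pixel
#' fraction, so the median tracks the background). Otsu's method is also
#' available by name but bisects the spot intensity range and so clips
#' spot tails on strongly background-dominated images.
#'
#' @param plane An [image_plane] (or bare matrix).
#' @param threshold_policy Either a string or a list
#'   `list(method, value)`, with method one of `"automatic"`/`"background"`
#'   (median + value x MAD, default 3), `"otsu"`, `"fixed"` (value =
#'   threshold), `"percentile"` (value in `[0, 1]`).
#' @param min_area_px Minimum particle area in pixels (default 4,
#'   suppressing single-pixel shot noise).
#' @return A `condensate_set`: list with `particles` (data.frame),
#'   `threshold_used`, and `label_image`.
#' @examples
#' sim <- make_condensate_cell(5, snr_target = 0.5, seed = 1)
#' cs <- detect_condensates(sim$channel1)
#' nrow(cs$particles)
#' @export
detect_condensates <- function(plane, threshold_policy = "automatic",
                               min_area_px = 4) {
  px <- as_pixels(plane)
  thr <- resolve_threshold(px, threshold_policy)
  mask <- px > thr
  lab <- label_components(mask)
  st <- component_stats(lab, intensity = px)
  keep <- st$area_px >= min_area_px
  st <- st[keep, , drop = FALSE]
  lab[!(lab %in% st$label)] <- 0
  rownames(st) <- NULL
  structure(
    list(particles = st, threshold_used = thr, label_image = lab),
    class = "condensate_set"
  )
}

#' @export
print.condensate_set <- function(x, ...) {
  cat(sprintf("<condensate_set> %d particles, threshold %.4g\n",
              nrow(x$particles), x$threshold_used))
  invisible(x)
}

#' Condensate signal-to-noise ratio of a cell
#'
#' Fraction of the ROI's total integrated fluorescence that lies inside
#' detected condensates: the sum of particle integrated intensities divided
#' by the integrated intensity of the whole plane (the cell ROI, including
#' the condensates). Bounded in `[0, 1]`.
#'
#' @param plane The [image_plane] the condensates were detected on.
#' @param condensates A `condensate_set` from [detect_condensates()].
#' @return SNR fraction in `[0, 1]`.
#' @examples
#' sim <- make_condensate_cell(5, snr_target = 0.5, seed = 1)
#' compute_snr(sim$channel1, detect_condensates(sim$channel1, "otsu"))
#' @export
compute_snr <- function(plane, condensates) {
  px <- as_pixels(plane)
  total <- sum(px)
  if (total <= 0) stop("undefined value: total ROI intensity is zero")
  sum(condensates$particles$integrated_intensity) / total
}

#' Match condensates across two channels
#'
#' Greedy nearest-centroid matching: the globally closest unmatched pair is
#' matched repeatedly while its distance is `<= max_dist_px`. The cell is
#' called co-localization positive when at least `min_matched` pairs match.
#'
#' @param a,b `condensate_set`s from two registered channels.
#' @param max_dist_px Maximum centroid distance for a match.
#' @param min_matched Minimum number of matched pairs for a positive call.
#' @return List with `matches` (data.frame of `index_a`, `index_b`,
#'   `dist_px`), `n_matched`, and `positive`.
#' @export
colocalize <- function(a, b, max_dist_px = 5, min_matched = 1) {
  pa <- a$particles; pb <- b$particles
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    return(list(matches = data.frame(index_a = integer(0),
                                     index_b = integer(0),
                                     dist_px = numeric(0)),
                n_matched = 0L, positive = FALSE))
  }
  d <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), function(i, j) {
    sqrt((pa$centroid_row[i] - pb$centroid_row[j])^2 +
         (pa$centroid_col[i] - pb$centroid_col[j])^2)
  })
  matches <- list()
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (!is.finite(d[m]) || d[m] > max_dist_px) break
    matches[[length(matches) + 1]] <-
      data.frame(index_a = m[1], index_b = m[2], dist_px = d[m])
    d[m[1], ] <- Inf
    d[, m[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(index_a = integer(0), index_b = integer(0),
               dist_px = numeric(0))
  list(matches = matches, n_matched = nrow(matches),
       positive = nrow(matches) >= min_matched)
}

#' Condensate-formation efficiency of a cell population
#'
#' Percentage of co-transfected cells that are co-localized
#' condensate-positive.
#'
#' @param records Data.frame of per-cell records with logical columns
#'   `cotransfected` and `colocalized_positive`.
#' @return Efficiency in percent, `[0, 100]`.
#' @examples
#' pop <- make_population(200, 0.3, seed = 1)
#' efficiency(pop$records)
#' @export
efficiency <- function(records) {
  co <- records[records$cotransfected, , drop = FALSE]
  if (nrow(co) == 0) stop("undefined value: zero co-transfected cells")
  100 * sum(co$colocalized_positive) / nrow(co)
}

#' Score a bait-prey pair from per-cell records
#'
#' Combines efficiency with the mean condensate SNR over positive cells
#' into the raw protein interaction index
#' `pi_raw = (efficiency / 100) * snr_mean`. With no positive cells,
#' `snr_mean` is 0 and so is `pi_raw`.
#'
#' @param bait,prey Labels for the pair.
#' @param records Per-cell records as for [efficiency()], with an `snr`
#'   column defined on positive cells.
#' @return A `pair_score`: list with `bait`, `prey`, `efficiency_pct`,
#'   `snr_mean`, `pi_raw`, `n_cells`.
#' @examples
#' pop <- make_population(100, 0.5, seed = 2)
#' pair_score("Rac1", "PAK1", pop$records)
#' @export
pair_score <- function(bait, prey, records) {
  if (nrow(records) == 0) stop("records must be nonempty")
  eff <- efficiency(records)
  pos <- records$colocalized_positive & records$cotransfected
  snr_mean <- if (any(pos)) mean(records$snr[pos]) else 0
  structure(
    list(bait = bait, prey = prey, efficiency_pct = eff,
         snr_mean = snr_mean, pi_raw = (eff / 100) * snr_mean,
         n_cells = nrow(records)),
    class = "pair_score"
  )
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("<pair_score> %s-%s: efficiency %.1f%%, SNR %.3f, PI %.4f (n=%d)\n",
              x$bait, x$prey, x$efficiency_pct, x$snr_mean, x$pi_raw,
              x$n_cells))
  invisible(x)
}

#' Intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at `n_samples` evenly spaced
#' points between two endpoints, as used for line-scan colocalization plots.
#'
#' @param plane An [image_plane] or matrix.
#' @param p0,p1 Endpoints as `c(row, col)` (may be fractional), inside the
#'   image.
#' @param n_samples Number of sample points.
#' @return Numeric vector of length `n_samples`.
#' @export
line_profile <- function(plane, p0, p1, n_samples = 100) {
  px <- as_pixels(plane)
  pts <- cbind(seq(p0[1], p1[1], length.out = n_samples),
               seq(p0[2], p1[2], length.out = n_samples))
  if (any(pts[, 1] < 1 | pts[, 1] > nrow(px) |
          pts[, 2] < 1 | pts[, 2] > ncol(px))) {
    stop("bounds error: endpoints outside image")
  }
  bilinear_sample(px, pts[, 1], pts[, 2])
}

# Bilinear interpolation at fractional (row, col) positions.
bilinear_sample <- function(px, rows, cols) {
  r0 <- pmin(floor(rows), nrow(px) - 1); r0 <- pmax(r0, 1)
  c0 <- pmin(floor(cols), ncol(px) - 1); c0 <- pmax(c0, 1)
  fr <- rows - r0; fc <- cols - c0
  px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    px[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    px[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    px[cbind(r0 + 1, c0 + 1)] * fr * fc
}
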