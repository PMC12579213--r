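#' Calibrated 2D intensity image
#'
#' Light container for a single fluorescence image plane: a numeric matrix of
#' non-negative intensities (arbitrary units) plus spatial calibration.
#' Matrices are indexed `[row, col]`; the x coordinate of a pixel is its
#' column index and the y coordinate its row index.
#'
#' @param pixels Numeric matrix of intensities, all values >= 0.
#' @param pixel_size_um Physical size of one pixel edge in micrometres.
#' @param channel Optional channel label (e.g. `"CFP"`, `"RFP"`).
#' @param t Optional acquisition time in seconds.
#' @return An object of class `image_plane`.
#' @examples
#' img <- image_plane(matrix(runif(100), 10, 10), pixel_size_um = 0.2)
#' dim(img$pixels)
#' @export
image_plane <- function(pixels, pixel_size_um = 1, channel = NULL, t = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels))) {
    stop("pixels must be a finite numeric matrix")
  }
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("image must be at least 1x1")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = channel, t = t),
    class = "image_plane"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.4g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              if (!is.null(x$channel)) paste0(", channel ", x$channel) else ""))
  invisible(x)
}

# Accept either an image_plane or a bare matrix wherever a plane is expected.
as_pixels <- function(plane) {
  if (inherits(plane, "image_plane")) plane$pixels else as.matrix(plane)
}

#' Ground-truth record attached to every synthetic artifact
#'
#' Bundles the nominal generator parameters, the realized quantities actually
#' present in the emitted artifact (recountable from it), and the seed used.
#'
#' @param kind Label of the generated object kind.
#' @param params Named list of nominal generator parameters.
#' @param realized Named list of realized quantities.
#' @param seed Integer seed the generator was run with.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kind, params, realized, seed) {
  structure(list(kind = kind, params = params, realized = realized,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> kind=%s seed=%d\n", x$kind, x$seed))
  cat("  realized:", paste(names(x$realized), collapse = ", "), "\n")
  invisible(x)
}

## ---- shared numeric helpers -------------------------------------------------

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Acute axial difference between two orientations in degrees (mod 180).
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected; diagonal
# neighbours are merged afterwards with a union-find pass over label
# adjacencies, which keeps the labelling fully vectorised.
label_components <- function(mask, connectivity = 8) {
  mask <- (as_pixels(mask) > 0) * 1
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Per-label pixel statistics used by several detectors.
component_stats <- function(lab, intensity = NULL) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      integrated_intensity = numeric(0),
                      mean_intensity = numeric(0)))
  }
  lb <- lab[idx]
  rows <- ((idx - 1) %% nrow(lab)) + 1
  cols <- ((idx - 1) %/% nrow(lab)) + 1
  area <- as.vector(table(lb))
  labels <- as.integer(names(table(lb)))
  cr <- tapply(rows, lb, mean)
  cc <- tapply(cols, lb, mean)
  if (is.null(intensity)) {
    ii <- rep(NA_real_, length(labels)); mi <- ii
  } else {
    v <- as_pixels(intensity)[idx]
    ii <- tapply(v, lb, sum)
    mi <- tapply(v, lb, mean)
  }
  data.frame(label = labels, area_px = as.integer(area),
             centroid_row = as.numeric(cr), centroid_col = as.numeric(cc),
             integrated_intensity = as.numeric(ii),
             mean_intensity = as.numeric(mi))
}

# Second-moment (inertia-equivalent) ellipse of a pixel set given row/col
# coordinates. Orientation reported as an axial angle in [0, 180) measured in
# standard math convention (x = col, y = -row, counter-clockwise from +x).
moment_ellipse <- function(rows, cols) {
  x <- cols - mean(cols)
  y <- -(rows - mean(rows))
  mxx <- mean(x * x); myy <- mean(y * y); mxy <- mean(x * y)
  tr <- mxx + myy
  det <- mxx * myy - mxy * mxy
  disc <- sqrt(max((tr / 2)^2 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  ang <- rad2deg(theta) %% 180
  # 1/12 pixel variance of a unit square keeps single-row bars non-degenerate
  ar <- sqrt((l1 + 1 / 12) / (l2 + 1 / 12))
  list(major = l1, minor = l2, aspect_ratio = ar, orientation_deg = ang)
}

# Pearson correlation with the classical t-transform p-value (n - 2 d.f.).
# Kept as an explicit primitive because downstream scoring delegates to it.

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation between two equal-length sequences, with the
#' two-tailed p-value from the t transform on n - 2 degrees of freedom, as
#' reported for line-scan colocalization profiles.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A list with elements `r`, `p`, and `n`.
#' @examples
#' pearson_r(1:10, (1:10) + rnorm(10, sd = 0.1))
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}
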