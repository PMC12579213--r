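## Focal-adhesion puncta detection by the intensity and size acceptance
## band: pixel intensities 1200-4500 arbitrary units, object size 0.5-15
## (area in um^2 by default, equivalent-circle diameter optionally).

#' Detect focal-adhesion puncta
#'
#' Thresholds the image at the intensity band, labels 8-connected
#' components, and keeps components whose per-object mean intensity lies in
#' the band and whose size (area in um^2, or equivalent-circle diameter in
#' um) lies within the size band.
#'
#' @param plane An [image_plane] (pixel size required) or matrix together
#'   with `pixel_size_um`.
#' @param pixel_size_um Pixel size in micrometres (taken from the plane
#'   when omitted).
#' @param size_unit `"area_um2"` (particle-analysis convention, default)
#'   or `"diameter_um"`.
#' @param intensity_band Pixel/object mean intensity band (AU).
#' @param size_band Object size band in the configured unit.
#' @param cell_mask Optional `cell_mask` or binary matrix; when given, the
#'   cell area is reported alongside.
#' @return A `puncta_set`: list with `puncta` (data.frame: `area_um2`,
#'   `diameter_um`, `mean_intensity`, `centroid_row`, `centroid_col`),
#'   `n`, `mean_area_um2`, `cell_area_um2`, `size_unit`.
#' @examples
#' p <- data.frame(area_um2 = c(2, 40), peak_intensity = c(2000, 2000))
#' sim <- make_puncta_image(p, seed = 1)
#' detect_adhesions(sim$image)$n
#' @export
detect_adhesions <- function(plane, pixel_size_um = NULL,
                             size_unit = c("area_um2", "diameter_um"),
                             intensity_band = c(1200, 4500),
                             size_band = c(0.5, 15), cell_mask = NULL) {
  size_unit <- match.arg(size_unit)
  if (is.null(pixel_size_um)) {
    if (!inherits(plane, "image_plane")) {
      stop("config error: pixel size missing")
    }
    pixel_size_um <- plane$pixel_size_um
  }
  px <- as_pixels(plane)
  lab <- label_components(px >= intensity_band[1] & px <= intensity_band[2])
  st <- component_stats(lab, intensity = px)
  st$area_um2 <- st$area_px * pixel_size_um^2
  st$diameter_um <- 2 * sqrt(st$area_um2 / pi)
  size_val <- if (size_unit == "diameter_um") st$diameter_um else st$area_um2
  keep <- st$mean_intensity >= intensity_band[1] &
    st$mean_intensity <= intensity_band[2] &
    size_val >= size_band[1] & size_val <= size_band[2]
  st <- st[keep, c("area_um2", "diameter_um", "mean_intensity",
                   "centroid_row", "centroid_col"), drop = FALSE]
  rownames(st) <- NULL
  cell_area <- if (is.null(cell_mask)) NA_real_ else
    sum(as_mask(cell_mask) > 0) * pixel_size_um^2
  structure(
    list(puncta = st, n = nrow(st),
         mean_area_um2 = if (nrow(st) > 0) mean(st$area_um2) else NA_real_,
         cell_area_um2 = cell_area, size_unit = size_unit),
    class = "puncta_set"
  )
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta, mean area %.3g um^2\n",
              x$n, x$mean_area_um2))
  invisible(x)
}

#' Per-cell adhesion summary table
#'
#' @param sets Named (or unnamed) list of `puncta_set`s, one per cell.
#' @return Data.frame with `cell`, `n_puncta`, `mean_area_um2` (`NA` for
#'   cells with zero puncta), `cell_area_um2`.
#' @export
adhesion_summary <- function(sets) {
  if (length(sets) == 0) stop("nonempty list of puncta sets required")
  nm <- names(sets)
  if (is.null(nm)) nm <- sprintf("cell%d", seq_along(sets))
  data.frame(
    cell = nm,
    n_puncta = vapply(sets, function(s) s$n, numeric(1)),
    mean_area_um2 = vapply(sets, function(s) s$mean_area_um2, numeric(1)),
    cell_area_um2 = vapply(sets, function(s) s$cell_area_um2, numeric(1)),
    row.names = NULL
  )
}
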