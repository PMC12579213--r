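## File interfaces: TIFF images/stacks, trajectory and score CSVs, and
## ground-truth JSON sidecars for synthetic artifacts.

#' Read a TIFF image or stack
#'
#' @param path Path to a single- or multi-page TIFF.
#' @param pixel_size_um Pixel calibration to attach.
#' @return An [image_plane] for a single page; a rows x cols x frames
#'   array for a multi-page file.
#' @export
read_image <- function(path, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) == 1) {
    return(image_plane(pages[[1]], pixel_size_um))
  }
  array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
}

#' Write a matrix or stack as TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the global maximum (TIFF float
#' convention used by the tiff package).
#'
#' @param x Matrix, [image_plane], or rows x cols x frames array.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "image_plane")) x <- x$pixels
  mx <- max(x, 1e-12)
  if (length(dim(x)) == 3) {
    pages <- lapply(seq_len(dim(x)[3]), function(f) x[, , f] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(as.matrix(x) / mx, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Expected columns: `cell_id`, `frame`, `t_min`, `x_um`, `y_um`.
#'
#' @param path CSV path.
#' @return A list of per-cell trajectory data.frames, named by cell id.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  }
  split(df, df$cell_id)
}

#' Write trajectories to CSV
#'
#' @param trajs A trajectory data.frame or list of them.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  utils::write.csv(do.call(rbind, trajs), path, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth record as a JSON sidecar
#'
#' @param gt A [ground_truth()] record.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write ground-truth sidecars")
  }
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Write pair scores to CSV
#'
#' @param scores List of `pair_score` objects.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_pair_scores <- function(scores, path) {
  df <- do.call(rbind, lapply(scores, function(s) {
    data.frame(bait = s$bait, prey = s$prey,
               efficiency_pct = s$efficiency_pct, snr_mean = s$snr_mean,
               pi_raw = s$pi_raw, n_cells = s$n_cells)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read pair scores from CSV
#'
#' @param path CSV written by [write_pair_scores()].
#' @return List of `pair_score` objects.
#' @export
read_pair_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure(as.list(df[i, ]), class = "pair_score")
  })
}
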