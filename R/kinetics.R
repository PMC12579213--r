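## Recovery/formation kinetics: normalization and one-phase association
## fitting F(t) = F0 + (plateau - F0) * (1 - exp(-k t)), with half-time
## ln(2)/k and mobile fraction (plateau - F0) / (pre-level - F0).

curve_parts <- function(curve) {
  if (!is.null(curve$phase)) {
    pre <- curve$phase == "pre"
  } else {
    pf <- attr(curve, "pre_frames")
    if (is.null(pf)) stop("curve needs a 'phase' column or pre_frames attribute")
    pre <- seq_len(nrow(curve)) <= pf
  }
  list(pre = curve[pre, , drop = FALSE], post = curve[!pre, , drop = FALSE])
}

#' Normalize a recovery curve to its pre-bleach level
#'
#' Divides every value by the mean of the pre-bleach frames, so the
#' pre-bleach level becomes 1. Idempotent on an already-normalized curve.
#'
#' @param curve Data.frame with `t_s`, `value` and either a `phase`
#'   column (`"pre"`/`"post"`) or a `pre_frames` attribute.
#' @return The curve with `value` normalized.
#' @export
normalize_frap <- function(curve) {
  parts <- curve_parts(curve)
  if (nrow(parts$pre) < 1) stop("at least one pre-bleach frame required")
  base <- mean(parts$pre$value)
  if (base <= 0) stop("undefined value: non-positive pre-bleach mean")
  curve$value <- curve$value / base
  curve
}

#' Fit a one-phase association to a recovery curve
#'
#' Levenberg-Marquardt least squares of
#' `F(t) = F0 + (plateau - F0) * (1 - exp(-k t))` on the post-bleach
#' segment, with time measured from the first post-bleach frame and a
#' positivity bound on `k`. The baseline `F0` is estimated, not pinned to
#' the first post-bleach sample. Mobile fraction is computed against a
#' pre-bleach level of 1 (normalize first).
#'
#' @param curve A (normalized) curve as in [normalize_frap()].
#' @param pre_level Pre-bleach plateau the mobile fraction is referred to
#'   (default 1).
#' @return A `one_phase_fit`: list with `F0`, `plateau`, `k`, `t_half`,
#'   `mobile_fraction`, `immobile_fraction`, `rms_residual`, `fit`
#'   (the `nls` object), and `k_at_bound` flag.
#' @examples
#' fr <- make_frap_curve(0.2, 0.8, 0.05, t = 0:200, seed = 1)
#' fit_one_phase(fr$curve)$k
#' @export
fit_one_phase <- function(curve, pre_level = 1) {
  parts <- curve_parts(curve)
  post <- parts$post
  if (nrow(post) < 5) stop("need at least 5 post-event points")
  tt <- post$t_s - post$t_s[1]
  y <- post$value
  if (any(!is.finite(y))) stop("values must be finite")
  # data-driven starting values: k from the time of ~63% recovery
  f0_0 <- min(y[seq_len(max(3, length(y) %/% 10))])
  pl_0 <- mean(utils::tail(y, max(3, length(y) %/% 10)))
  span <- max(pl_0 - f0_0, 1e-6)
  i63 <- which(y - f0_0 >= 0.632 * span)[1]
  k_0 <- if (is.na(i63) || tt[i63] <= 0) 1 / max(tt[length(tt)], 1) else 1 / tt[i63]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ F0 + (plateau - F0) * (1 - exp(-k * tt)),
      start = list(F0 = f0_0, plateau = pl_0, k = k_0),
      lower = c(F0 = -Inf, plateau = -Inf, k = 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("fit error: ", conditionMessage(e))
  )
  cf <- stats::coef(fit)
  mobile <- (cf[["plateau"]] - cf[["F0"]]) / (pre_level - cf[["F0"]])
  structure(
    list(F0 = cf[["F0"]], plateau = cf[["plateau"]], k = cf[["k"]],
         t_half = log(2) / cf[["k"]],
         mobile_fraction = mobile, immobile_fraction = 1 - mobile,
         rms_residual = sqrt(mean(stats::residuals(fit)^2)),
         k_at_bound = cf[["k"]] <= 1.01e-10, fit = fit),
    class = "one_phase_fit"
  )
}

#' @export
print.one_phase_fit <- function(x, ...) {
  cat(sprintf(paste0("<one_phase_fit> F0=%.4g plateau=%.4g k=%.4g ",
                     "t_half=%.4g mobile=%.3f\n"),
              x$F0, x$plateau, x$k, x$t_half, x$mobile_fraction))
  invisible(x)
}

#' Half-time of a recovery curve
#'
#' Model-based mode returns `ln(2) / k` from a [fit_one_phase()] fit
#' (fitting first if a curve is supplied). Model-free mode linearly
#' interpolates the first crossing of the level halfway between the fit's
#' baseline and plateau (or, for a bare curve, between the first
#' post-event value and the final plateau estimate).
#'
#' @param x A curve data.frame or a `one_phase_fit`.
#' @param mode `"fit"` (default) or `"interp"`.
#' @param curve Required for `mode = "interp"` when `x` is a fit.
#' @return Half-time in the curve's time unit.
#' @examples
#' fr <- make_frap_curve(0.2, 0.8, 0.05, t = 0:200, seed = 1)
#' half_time(fr$curve)                   # ln(2) / 0.05
#' half_time(fr$curve, mode = "interp")
#' @export
half_time <- function(x, mode = c("fit", "interp"), curve = NULL) {
  mode <- match.arg(mode)
  if (mode == "fit") {
    fit <- if (inherits(x, "one_phase_fit")) x else fit_one_phase(x)
    return(fit$t_half)
  }
  if (inherits(x, "one_phase_fit")) {
    if (is.null(curve)) stop("interp mode needs the curve")
    f0 <- x$F0; pl <- x$plateau
  } else {
    curve <- x
    post <- curve_parts(curve)$post
    f0 <- post$value[1]
    pl <- mean(utils::tail(post$value, max(3, nrow(post) %/% 10)))
  }
  post <- curve_parts(curve)$post
  tt <- post$t_s - post$t_s[1]
  y <- post$value
  if (max(y) == min(y)) stop("undefined value: flat post-event curve")
  level <- (f0 + pl) / 2
  above <- which(y >= level)
  if (length(above) == 0) stop("undefined value: curve never reaches half level")
  i <- above[1]
  if (i == 1) return(tt[1])
  tt[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
}
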