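#' Display geometry model
#'
#' Describes the stimulus display: pixel resolution, angular subtense at the
#' reference viewing distance, and that distance.  Degrees of visual angle
#' are mapped to pixels with a constant (flat) scale per axis; over a
#' 43 x 25 degree field the tangent correction is below 1%, so a linear
#' mapping is used throughout.  Screen coordinates have their origin at the
#' top-left corner, x rightward and y downward; gaze-relative degrees are
#' measured from the point of regard.
#'
#' @param width_px,height_px display resolution in pixels.
#' @param width_deg,height_deg angular subtense of the display in degrees of
#'   visual angle at the reference distance.
#' @param reference_distance_cm viewing distance at which the subtense holds.
#' @return An object of class `display_model`.
#' @examples
#' d <- display_model()
#' deg_to_px(1, d)   # about 44.65 px per degree horizontally
#' @export
display_model <- function(width_px = 1920, height_px = 1080,
                          width_deg = 43, height_deg = 25,
                          reference_distance_cm = 65) {
  vals <- c(width_px, height_px, width_deg, height_deg, reference_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all display_model fields must be positive and finite")
  structure(
    list(width_px = width_px, height_px = height_px,
         width_deg = width_deg, height_deg = height_deg,
         reference_distance_cm = reference_distance_cm),
    class = "display_model")
}

#' @export
print.display_model <- function(x, ...) {
  cat(sprintf("<display_model> %d x %d px, %.4g x %.4g deg @ %.4g cm (%.2f / %.2f px/deg)\n",
              x$width_px, x$height_px, x$width_deg, x$height_deg,
              x$reference_distance_cm,
              x$width_px / x$width_deg, x$height_px / x$height_deg))
  invisible(x)
}

px_scale <- function(display, axis = c("x", "y", "mean")) {
  axis <- match.arg(axis)
  sx <- display$width_px / display$width_deg
  sy <- display$height_px / display$height_deg
  switch(axis, x = sx, y = sy, mean = (sx + sy) / 2)
}

#' Convert visual angle to pixels (and back)
#'
#' Linear conversion using the display's constant pixels-per-degree scale.
#' The horizontal and vertical scales differ slightly (1920/43 vs 1080/25);
#' `axis = "mean"` uses their average, which is what isotropic quantities
#' such as the phosphene Gaussian sigma use.
#'
#' @param angle_deg visual angle in degrees (vectorized).
#' @param display a [display_model()].
#' @param axis which scale to apply: `"x"`, `"y"`, or `"mean"`.
#' @return Length in pixels (resp. degrees for [px_to_deg()]).
#' @export
deg_to_px <- function(angle_deg, display = display_model(), axis = "x") {
  stop_if_not_finite(angle_deg, "angle_deg")
  angle_deg * px_scale(display, axis)
}

#' @rdname deg_to_px
#' @param length_px length in pixels.
#' @export
px_to_deg <- function(length_px, display = display_model(), axis = "x") {
  stop_if_not_finite(length_px, "length_px")
  length_px / px_scale(display, axis)
}

#' Letter x-height from a logMAR size
#'
#' logMAR is the log10 of the minimum angle of resolution (MAR) in
#' arcminutes.  Letter size follows the MNREAD x-height convention: the
#' lowercase x stands five MAR tall, so the x-height in degrees is
#' `5 * 10^logmar / 60`.
#'
#' @param logmar print size in logMAR (vectorized).
#' @return x-height in degrees of visual angle.
#' @examples
#' logmar_to_xheight_deg(0)    # 5 arcmin = 0.0833 deg
#' logmar_to_xheight_deg(1.5)  # about 2.64 deg
#' @export
logmar_to_xheight_deg <- function(logmar) {
  stop_if_not_finite(logmar, "logmar")
  5 * 10^logmar / 60
}

#' Adjust a nominal logMAR size for actual viewing distance
#'
#' A stimulus of fixed physical size viewed from farther away subtends a
#' smaller angle: its effective print size decreases by `log10(actual /
#' reference)` logMAR.  Used to quantify the impact of subjects sitting at
#' slightly different distances than the reference.
#'
#' @param nominal_logmar print size at the reference distance.
#' @param actual_cm,reference_cm actual and reference viewing distances.
#' @return Effective print size in logMAR at the actual distance.
#' @examples
#' distance_adjusted_logmar(1.0, 66.3, 65)  # ~0.0086 logMAR smaller
#' @export
distance_adjusted_logmar <- function(nominal_logmar, actual_cm, reference_cm = 65) {
  stop_if_not_finite(nominal_logmar, "nominal_logmar")
  if (any(!is.finite(c(actual_cm, reference_cm))) ||
      any(c(actual_cm, reference_cm) <= 0))
    stop("viewing distances must be positive")
  nominal_logmar - log10(actual_cm / reference_cm)
}

#' Expected acuity gain from a phosphene-count ratio
#'
#' Under a two-dimensional sampling-density argument, multiplying the number
#' of phosphenes across the visual field by a factor r improves the linear
#' sampling pitch by sqrt(r), i.e. an expected acuity improvement of
#' `0.5 * log10(r)` logMAR.  Doubling the count yields 0.15 logMAR.
#'
#' @param count_hi,count_lo phosphene counts of the denser and sparser
#'   patterns (vectorized).
#' @return Expected logMAR improvement (positive when `count_hi > count_lo`).
#' @examples
#' expected_acuity_gain(2, 1)        # 0.1505
#' expected_acuity_gain(1757, 1029)  # 0.116
#' @export
expected_acuity_gain <- function(count_hi, count_lo) {
  if (any(!is.finite(c(count_hi, count_lo))) || any(c(count_hi, count_lo) <= 0))
    stop("phosphene counts must be positive")
  0.5 * log10(count_hi / count_lo)
}
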