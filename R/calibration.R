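# Second-order gaze-calibration correction: a full bivariate quadratic
# surface per output axis maps raw tracker coordinates to screen-true
# coordinates, absorbing gain, offset, and minor distortions.  Fitted by
# least squares to repeated presentations of a 3x3 dot grid.

quad_design <- function(x, y) cbind(1, x, y, x^2, y^2, x * y)
QUAD_TERMS <- c("const", "x", "y", "x2", "y2", "xy")

#' Fit the second-order gaze correction
#'
#' Least-squares fit, per output axis, of the full bivariate quadratic
#' (constant, x, y, x^2, y^2, xy) mapping raw gaze positions to true target
#' positions.  A 3x3 calibration grid with repeats gives 9-27 point pairs;
#' at least 6 non-degenerate pairs are required.
#'
#' @param raw matrix or data frame of raw positions (columns x, y).
#' @param true matching true positions.
#' @return An object of class `gaze_correction`: coefficient matrix
#'   (6 terms x 2 axes) plus per-axis residual RMS.
#' @examples
#' pts <- expand.grid(x = c(100, 960, 1820), y = c(100, 540, 980))
#' m <- fit_correction(pts, pts)     # identity data
#' predict(m, data.frame(x = 500, y = 500))
#' @export
fit_correction <- function(raw, true) {
  raw <- as.matrix(raw)[, 1:2, drop = FALSE]
  true <- as.matrix(true)[, 1:2, drop = FALSE]
  if (nrow(raw) != nrow(true)) stop("raw and true point sets differ in length")
  if (nrow(raw) < 6L) stop("at least 6 point pairs are required for the quadratic fit")
  X <- quad_design(raw[, 1], raw[, 2])
  qr_x <- qr(X)
  if (qr_x$rank < 6L)
    stop(sprintf("rank-deficient calibration design (rank %d of 6): raw points do not span a quadratic surface (e.g. collinear or coincident targets)",
                 qr_x$rank))
  coefs <- qr.coef(qr_x, true)
  fitted <- X %*% coefs
  rms <- sqrt(colMeans((true - fitted)^2))
  dimnames(coefs) <- list(QUAD_TERMS, c("x", "y"))
  structure(list(coefficients = coefs,
                 residual_rms = c(x = rms[1], y = rms[2]),
                 n_points = nrow(raw)),
            class = "gaze_correction")
}

#' @export
print.gaze_correction <- function(x, ...) {
  cat(sprintf("<gaze_correction> quadratic surface fit to %d points; residual RMS x=%.4g, y=%.4g\n",
              x$n_points, x$residual_rms[1], x$residual_rms[2]))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.gaze_correction <- function(object, ...) object$coefficients

#' Apply the gaze correction
#'
#' Evaluates the fitted quadratic surfaces at raw positions.
#'
#' @param object a [fit_correction()] model.
#' @param newdata matrix or data frame of raw positions (columns x, y).
#' @param ... unused.
#' @return Matrix of corrected positions (columns x, y).
#' @export
predict.gaze_correction <- function(object, newdata, ...) {
  raw <- as.matrix(newdata)[, 1:2, drop = FALSE]
  out <- quad_design(raw[, 1], raw[, 2]) %*% object$coefficients
  colnames(out) <- c("x", "y")
  out
}

#' @rdname predict.gaze_correction
#' @param model a `gaze_correction`.
#' @param raw raw positions.
#' @export
apply_correction <- function(model, raw) predict(model, raw)

#' Calibration grid targets
#'
#' The 3x3 grid of dot locations spanning the stimulus display with a 5%
#' margin on each side.
#'
#' @param display a [display_model()].
#' @param margin fractional margin.
#' @return Data frame of 9 positions (x, y) in pixels.
#' @export
calibration_grid <- function(display = display_model(), margin = 0.05) {
  xs <- display$width_px * c(margin, 0.5, 1 - margin)
  ys <- display$height_px * c(margin, 0.5, 1 - margin)
  expand.grid(x = xs, y = ys)
}

#' Serialize a gaze correction to JSON
#'
#' @param model a `gaze_correction`.
#' @param path file path.
#' @return `read_correction_json()` returns the model.
#' @export
write_correction_json <- function(model, path) {
  obj <- list(coefficients = as.data.frame(model$coefficients),
              terms = QUAD_TERMS,
              residual_rms = as.list(model$residual_rms),
              n_points = model$n_points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correction_json
#' @export
read_correction_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.matrix(obj$coefficients)
  dimnames(coefs) <- list(QUAD_TERMS, c("x", "y"))
  structure(list(coefficients = coefs,
                 residual_rms = unlist(obj$residual_rms),
                 n_points = obj$n_points),
            class = "gaze_correction")
}
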