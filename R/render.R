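# Frames are plain numeric matrices with values in [0, 1]; rows are screen
# rows (y, downward), columns are screen columns (x, rightward), pixel
# centers at integer coordinates.

# Gaussian kernels are truncated at this many sigmas (< 1.2% mass loss).
KERNEL_TRUNCATION_SIGMAS <- 3

#' Create a blank frame
#'
#' @param display a [display_model()] giving the frame dimensions, or NULL
#'   if `width_px`/`height_px` are given directly.
#' @param value fill luminance in \[0, 1\].
#' @param width_px,height_px explicit dimensions (override `display`).
#' @return A `height_px` x `width_px` numeric matrix.
#' @export
new_frame <- function(display = display_model(), value = 0,
                      width_px = display$width_px, height_px = display$height_px) {
  if (value < 0 || value > 1) stop("frame luminance must be in [0, 1]")
  matrix(value, nrow = height_px, ncol = width_px)
}

check_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("a frame must be a numeric matrix")
  invisible(frame)
}

#' Sample stimulus brightness through a phosphene's averaging filter
#'
#' Returns the local average luminance of the stimulus image weighted by an
#' isotropic two-dimensional Gaussian centered at `center_px` with the given
#' sigma, evaluated over pixels within the truncation radius (3 sigma).
#' Near the image border the weights are renormalized over in-bounds pixels;
#' a filter with no in-bounds support returns 0.
#'
#' @param image stimulus frame (numeric matrix in \[0, 1\]).
#' @param center_px numeric `c(x, y)` position in pixels (may lie off-image).
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @return Brightness in \[0, 1\].
#' @export
sample_phosphene_brightness <- function(image, center_px, sigma_px) {
  check_frame(image)
  if (!is.finite(sigma_px) || sigma_px <= 0) stop("sigma_px must be positive")
  cpp_gauss_sample(image, center_px[1], center_px[2], sigma_px,
                   KERNEL_TRUNCATION_SIGMAS)
}

#' Draw one phosphene into a frame
#'
#' Adds a peak-normalized circular Gaussian, `amplitude * exp(-r^2 / (2
#' sigma^2))`, to the frame over its truncated support.  Phosphenes combine
#' additively; saturation at the display maximum is applied once after the
#' full composition (see [render_frame()]), so by default this function
#' returns the raw additive result.  Set `clip = TRUE` to saturate a
#' standalone splat.
#'
#' @param frame frame to draw into.
#' @param center_px numeric `c(x, y)` position in pixels.
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @param amplitude peak brightness in \[0, 1\].
#' @param clip clip the result to \[0, 1\] (display saturation).
#' @return The updated frame.
#' @export
splat_phosphene <- function(frame, center_px, sigma_px, amplitude, clip = FALSE) {
  check_frame(frame)
  if (!is.finite(sigma_px) || sigma_px <= 0) stop("sigma_px must be positive")
  if (!is.finite(amplitude) || amplitude < 0 || amplitude > 1)
    stop("amplitude must be in [0, 1]")
  out <- cpp_splat_add(frame, center_px[1], center_px[2], sigma_px, amplitude,
                       KERNEL_TRUNCATION_SIGMAS)
  if (clip) clip_frame(out) else out
}

#' @rdname splat_phosphene
#' @export
clip_frame <- function(frame) {
  check_frame(frame)
  frame[frame > 1] <- 1
  frame[frame < 0] <- 0
  frame
}

#' Render one gaze-contingent phosphene-vision frame
#'
#' The simulation pipeline for a single video frame: the phosphene pattern
#' is translated in visual space so that its origin sits on the
#' instantaneous point of regard; each phosphene samples the stimulus image
#' through a Gaussian averaging filter of its own sigma
#' ([sample_phosphene_brightness()]); a matching Gaussian of that brightness
#' is splatted at the same location; all splats combine additively and the
#' final frame saturates at the display maximum (clip to \[0, 1\]).
#' Phosphenes whose truncated support lies fully off-screen contribute
#' nothing; the gaze position itself may be off-screen.
#'
#' The horizontal and vertical pixel scales convert the pattern's
#' gaze-relative degrees per axis; the isotropic sigma uses the mean scale.
#'
#' @param stimulus stimulus frame (numeric matrix in \[0, 1\]) whose
#'   dimensions match `display`.
#' @param pattern a [generate_pattern()] result.
#' @param gaze_px numeric `c(x, y)` point of regard in pixels.
#' @param display a [display_model()].
#' @return A frame of the same dimensions, values in \[0, 1\].
#' @export
render_frame <- function(stimulus, pattern, gaze_px, display = display_model()) {
  check_frame(stimulus)
  stopifnot(inherits(pattern, "phosphene_pattern"))
  if (nrow(stimulus) != display$height_px || ncol(stimulus) != display$width_px)
    stop("stimulus dimensions do not match the display model")
  p <- pattern$phosphenes
  xs <- gaze_px[1] + deg_to_px(p$x_deg, display, axis = "x")
  ys <- gaze_px[2] + deg_to_px(p$y_deg, display, axis = "y")
  sig <- deg_to_px(p$sigma_deg, display, axis = "mean")
  cpp_render_frame(stimulus, xs, ys, sig, KERNEL_TRUNCATION_SIGMAS)
}

#' Read and write frames as 8-bit grayscale PNG
#'
#' @param frame a frame matrix in \[0, 1\].
#' @param path file path.
#' @return `read_frame_png()` returns a frame matrix; `write_frame_png()`
#'   returns `path` invisibly.
#' @export
write_frame_png <- function(frame, path) {
  check_frame(frame)
  png::writePNG(clip_frame(frame), path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
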