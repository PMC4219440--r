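# Reference ("oracle") implementations and shared fixtures for the tests.
# The oracles are deliberately naive and independent of the package code
# paths they check.

# ---- shared expensive fixtures (computed once per test run) ----------------

.fixtures <- new.env()

get_profile <- function() {
  if (is.null(.fixtures$profile))
    .fixtures$profile <- fit_density_profile()
  .fixtures$profile
}

get_pattern <- function(tier, seed) {
  key <- sprintf("%s_%d", tier, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_pattern(tier, get_profile(), seed = seed)
  .fixtures[[key]]
}

# small square display for renderer toys: 16 px per degree on both axes
toy_display <- function(n = 64)
  display_model(width_px = n, height_px = n,
                width_deg = n / 16, height_deg = n / 16)

# a phosphene_pattern built directly from coordinates (for renderer tests,
# where the density profile is irrelevant)
toy_pattern <- function(x_deg, y_deg, sigma_deg) {
  structure(list(tier = "High", seed = 1L, rho_max_deg = 45,
                 profile = NULL,
                 phosphenes = data.frame(x_deg = x_deg, y_deg = y_deg,
                                         sigma_deg = sigma_deg)),
            class = "phosphene_pattern")
}

# ---- renderer oracles (dense double loops) ---------------------------------

oracle_gauss_sample <- function(image, cx, cy, sigma, trunc = 3) {
  h <- nrow(image); w <- ncol(image)
  r <- trunc * sigma
  j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r))
  i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r))
  if (j0 > j1 || i0 > i1) return(0)
  num <- 0; den <- 0
  for (i in i0:i1) for (j in j0:j1) {
    d2 <- (j - cx)^2 + (i - cy)^2
    if (d2 <= r^2) {
      wgt <- exp(-d2 / (2 * sigma^2))
      num <- num + wgt * image[i, j]
      den <- den + wgt
    }
  }
  if (den == 0) 0 else num / den
}

oracle_splat_add <- function(frame, cx, cy, sigma, amplitude, trunc = 3) {
  h <- nrow(frame); w <- ncol(frame)
  r <- trunc * sigma
  j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r))
  i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r))
  if (j0 > j1 || i0 > i1) return(frame)
  for (i in i0:i1) for (j in j0:j1) {
    d2 <- (j - cx)^2 + (i - cy)^2
    if (d2 <= r^2)
      frame[i, j] <- frame[i, j] + amplitude * exp(-d2 / (2 * sigma^2))
  }
  frame
}

oracle_render <- function(stimulus, xs, ys, sigmas, trunc = 3) {
  out <- stimulus * 0
  for (k in seq_along(xs)) {
    b <- oracle_gauss_sample(stimulus, xs[k], ys[k], sigmas[k], trunc)
    out <- oracle_splat_add(out, xs[k], ys[k], sigmas[k], b, trunc)
  }
  out[out > 1] <- 1; out[out < 0] <- 0
  out
}

# ---- profile-integral oracle: brute-force 2-D grid quadrature --------------

oracle_expected_count <- function(profile, region, n = 1201L) {
  if (region$type == "circle") { hx <- region$r; hy <- region$r }
  else { hx <- region$w / 2; hy <- region$h / 2 }
  hx <- min(hx, profile$rho_max_deg); hy <- min(hy, profile$rho_max_deg)
  dx <- 2 * hx / n; dy <- 2 * hy / n
  xs <- seq(-hx + dx / 2, hx - dx / 2, length.out = n)
  ys <- seq(-hy + dy / 2, hy - dy / 2, length.out = n)
  rho <- sqrt(outer(ys^2, xs^2, "+"))
  dens <- profile_density(profile, rho)
  if (region$type == "circle") dens[rho > region$r] <- 0
  sum(dens) * dx * dy
}

# ---- window-count oracle: exhaustive distance test -------------------------

oracle_count_window <- function(pattern, window) {
  p <- pattern$phosphenes
  count <- 0L
  for (k in seq_len(nrow(p))) {
    inside <- if (window$type == "circle") {
      sqrt(p$x_deg[k]^2 + p$y_deg[k]^2) <= window$r
    } else {
      abs(p$x_deg[k]) <= window$w / 2 && abs(p$y_deg[k]) <= window$h / 2
    }
    if (inside) count <- count + 1L
  }
  count
}

# ---- line-break oracle: brute-force minimum of the maximum line ------------

oracle_min_max_line <- function(words) {
  n <- length(words)
  best <- Inf
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
    lens <- c(nchar(paste(words[1:i], collapse = " ")),
              nchar(paste(words[(i + 1L):j], collapse = " ")),
              nchar(paste(words[(j + 1L):n], collapse = " ")))
    best <- min(best, max(lens))
  }
  as.integer(best)
}

# ---- gap-filler oracle: naive per-sample repair ----------------------------

oracle_fill_gaps <- function(trace, max_interp_ms = 100) {
  valid_idx <- which(trace$valid)
  out <- trace
  for (i in which(!trace$valid)) {
    prev <- valid_idx[valid_idx < i]
    nxt <- valid_idx[valid_idx > i]
    prev <- if (length(prev)) max(prev) else NA
    nxt <- if (length(nxt)) min(nxt) else NA
    if (is.na(prev)) {
      out$x_px[i] <- trace$x_px[nxt]; out$y_px[i] <- trace$y_px[nxt]
    } else if (is.na(nxt) ||
               (trace$t_ms[nxt] - trace$t_ms[prev]) > max_interp_ms) {
      out$x_px[i] <- trace$x_px[prev]; out$y_px[i] <- trace$y_px[prev]
    } else {
      f <- (trace$t_ms[i] - trace$t_ms[prev]) /
           (trace$t_ms[nxt] - trace$t_ms[prev])
      out$x_px[i] <- trace$x_px[prev] + f * (trace$x_px[nxt] - trace$x_px[prev])
      out$y_px[i] <- trace$y_px[prev] + f * (trace$y_px[nxt] - trace$y_px[prev])
    }
    out$valid[i] <- TRUE
  }
  out
}

# scripted gaze trace builder: a sequence of (x, y, duration_ms) holds at a
# fixed sample interval, no noise
scripted_trace <- function(segments, dt_ms = 10) {
  t <- 0; rows <- list()
  for (s in segments) {
    n <- round(s[[3]] / dt_ms)
    rows[[length(rows) + 1L]] <- data.frame(
      t_ms = t + dt_ms * (seq_len(n) - 1L), x_px = s[[1]], y_px = s[[2]],
      valid = TRUE)
    t <- t + n * dt_ms
  }
  do.call(rbind, rows)
}
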