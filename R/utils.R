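# small numeric helpers used across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian smoothing of a regularly sampled series; sigma in samples.
# Edge handling: replicate-edge padding, which keeps plateaus flat.
gaussian_smooth <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0 || n < 3) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  xp <- x[pmin(pmax(seq.int(1 - r, n + r), 1L), n)]
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

# least-squares slope of y on t
reg_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * y) / sum(tc^2)
}

# trapezoidal integral of y over t
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

# camera model shared by the image generators: Poisson shot noise at
# `photon_scale` AU per photon, additive Gaussian read noise, then
# quantisation to integer counts clipped to the detector range.
add_camera_noise <- function(values, noise_sd, photon_scale, dynamic_range) {
  v <- as.numeric(values)
  if (photon_scale > 0)
    v <- photon_scale * stats::rpois(length(v), v / photon_scale)
  if (noise_sd > 0)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  pmin(pmax(round(v), 0), dynamic_range)
}
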