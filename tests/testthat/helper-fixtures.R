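# Shared fixtures built in code.

# A profile that is the sum of Gaussians of width sigma at the given centres,
# sampled on a uniform grid.
gaussian_profile <- function(centers, sigma = 1, spacing = 1, n = 64,
                             amplitudes = 1) {
  pos <- (seq_len(n) - 1) * spacing
  y <- rowSums(mapply(function(c0, a) a * exp(-(pos - c0)^2 / (2 * sigma^2)),
                      centers, rep_len(amplitudes, length(centers))))
  intensity_profile(pos, y)
}

# Dense-grid argmax oracle: maxima of a 1D function located by evaluation on
# a very fine grid.
dense_maxima <- function(f, lo, hi, n = 200001L) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  i <- which(diff(sign(diff(y))) < 0) + 1L
  x[i]
}

# Hand-built frame: two-leaflet membrane with explicit particle placement.
manual_frame <- function(particles, box = c(8, 8, 10)) {
  bilayer_frame(particles, box_nm = box)
}

# O(N^2) brute-force Coulomb oracle (independent double loop).
brute_coulomb <- function(x, y, z, q, box, cutoff) {
  e <- 0
  n <- length(x)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dx <- dx - box[1] * round(dx / box[1])
    dy <- y[i] - y[j]; dy <- dy - box[2] * round(dy / box[2])
    dz <- z[i] - z[j]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (r <= cutoff) e <- e + 138.935 * q[i] * q[j] / r
  }
  e
}
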