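# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most naive method available so they share no code
# path with the package implementation.

# O(n*w) sliding median with truncated windows at the edges
naive_median_filter <- function(x, w) {
  h <- w %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1L))
}

# exhaustive quadrant counting for the 2D KS statistic: for every evaluation
# point, count each sample's points in the four quadrants by a double loop
naive_ks2d_D <- function(a, b) {
  quad <- function(m, x0, y0) {
    q <- c(0, 0, 0, 0)
    for (r in seq_len(nrow(m))) {
      gx <- m[r, 1L] > x0
      gy <- m[r, 2L] > y0
      k <- if (gx && gy) 1L else if (!gx && gy) 2L else if (!gx && !gy) 3L else 4L
      q[k] <- q[k] + 1
    }
    q / nrow(m)
  }
  dmax_over <- function(pts) {
    d <- 0
    for (r in seq_len(nrow(pts))) {
      fa <- quad(a, pts[r, 1L], pts[r, 2L])
      fb <- quad(b, pts[r, 1L], pts[r, 2L])
      d <- max(d, max(abs(fa - fb)))
    }
    d
  }
  c(D1 = dmax_over(a), D2 = dmax_over(b))
}

# truncated-exponential mean by numeric integration (checks the closed form)
numeric_truncexp_mean <- function(tau, window) {
  norm <- integrate(function(t) exp(-t / tau), 0, window)$value
  integrate(function(t) t * exp(-t / tau), 0, window)$value / norm
}

# amplitude fraction of component 2 that yields intensity fraction f2
amp2_for_f2 <- function(f2, tau1, tau2) {
  if (f2 <= 0) return(0)
  if (f2 >= 1) return(1)
  (f2 / tau2) / (f2 / tau2 + (1 - f2) / tau1)
}

# quick mono-exponential stream: well-separated bright particles
make_stream <- function(n_cells = 20, tau = 2.5, photons = 2000,
                        arrival_rate = 20, background_rate = 0, seed = 1,
                        ...) {
  simulate_stream(
    population_spec(n_cells = n_cells, lifetime_mean = tau,
                    intensity_median = photons,
                    arrival_rate = arrival_rate,
                    background_rate = background_rate, ...),
    acquisition_config(), seed = seed)
}
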