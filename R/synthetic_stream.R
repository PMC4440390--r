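#' TCSPC acquisition configuration
#'
#' Describes the timing geometry of a time-correlated single photon
#' counting (TCSPC) acquisition in FIFO mode: the laser synchronisation
#' period, the usable micro-time window, the number of ADC channels the
#' micro time is digitised into, and the macro-time bin width used for
#' burst search.
#'
#' @param sync_period Laser sync period in ns. Default 12.5 ns (80 MHz
#'   pulsed excitation).
#' @param micro_window Usable micro-time window in ns; must not exceed
#'   `sync_period`. Defaults to the full sync period; a 10 ns ADC window
#'   is a common alternative preset.
#' @param adc_bins Number of micro-time histogram channels (>= 2).
#' @param bin_width Macro-time bin width in microseconds used when
#'   histogramming photon arrivals for burst search. Default 20 us.
#' @param channels Integer vector of detector channel ids (routed
#'   detectors). Default a single channel `1L`.
#' @param irf_sigma Standard deviation (ns) of an optional Gaussian
#'   instrument response applied by the simulator; 0 disables it.
#' @param pileup Logical; if `TRUE` the simulator censors all but the
#'   first photon falling into each sync period (pulse pile-up).
#'
#' @return An object of class `acq_config`.
#' @export
#' @examples
#' acquisition_config()
#' acquisition_config(micro_window = 10, adc_bins = 1024)
acquisition_config <- function(sync_period = 12.5,
                               micro_window = sync_period,
                               adc_bins = 256L,
                               bin_width = 20,
                               channels = 1L,
                               irf_sigma = 0,
                               pileup = FALSE) {
  stopifnot(is.numeric(sync_period), length(sync_period) == 1L, sync_period > 0)
  if (!is.numeric(micro_window) || micro_window <= 0)
    stop("`micro_window` must be a positive time in ns")
  if (micro_window > sync_period + 1e-12)
    stop("`micro_window` must not exceed `sync_period`")
  adc_bins <- as.integer(adc_bins)
  if (is.na(adc_bins) || adc_bins < 2L) stop("`adc_bins` must be >= 2")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0 (microseconds)")
  channels <- as.integer(channels)
  if (anyNA(channels) || anyDuplicated(channels) || length(channels) < 1L)
    stop("`channels` must be distinct detector ids")
  structure(
    list(sync_period = sync_period, micro_window = micro_window,
         adc_bins = adc_bins, bin_width = bin_width, channels = channels,
         irf_sigma = irf_sigma, pileup = isTRUE(pileup)),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat("TCSPC acquisition config\n")
  cat(sprintf("  sync period : %.4g ns (%.4g MHz)\n", x$sync_period, 1e3 / x$sync_period))
  cat(sprintf("  micro window: %.4g ns over %d ADC bins\n", x$micro_window, x$adc_bins))
  cat(sprintf("  bin width   : %.4g us; channels: %s\n", x$bin_width,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Cell population specification for the photon stream simulator
#'
#' Defines the distribution of per-cell lifetimes and brightness for a
#' population of particles transiting the illumination volume, together
#' with the particle arrival process and uncorrelated background.
#'
#' Per-cell lifetimes are drawn from a normal distribution (truncated at a
#' small positive floor); expected burst photon counts from a log-normal.
#' A signed coupling coefficient (ns per decade of intensity) reproduces
#' the expression-level dependence of the donor lifetime seen in highly
#' expressing cells: the per-cell lifetime is shifted by
#' `coupling * (log10(I) - mean(log10 I))`.
#'
#' @param n_cells Number of particles to simulate (>= 1).
#' @param lifetime_mean Mean lifetime(s) in ns; length 1 (mono-exponential
#'   decay) or 2 (bi-exponential, shared across the population).
#' @param lifetime_sd Cell-to-cell standard deviation (ns) of the first
#'   lifetime component. 0 gives a degenerate (identical) population.
#' @param amp_fraction2 Amplitude fraction of the second lifetime
#'   component (scalar, recycled per cell, or length `n_cells`). Ignored
#'   for mono-exponential populations.
#' @param intensity_median Median expected photons per burst.
#' @param intensity_sdlog Log-normal sdlog of the expected photon count
#'   (0 = all cells equally bright; ~1.15 spans two decades).
#' @param coupling Lifetime-intensity coupling in ns per decade of
#'   expected photon count (negative reproduces lifetime quenching at
#'   high expression). Default 0.
#' @param background_rate Uncorrelated background photons per second.
#' @param arrival_rate Particle arrival rate, particles per second
#'   (Poisson arrivals). 0 disables particles.
#' @param transit_fwhm Full width at half maximum (ms) of the Gaussian
#'   transit envelope. Default 2 ms.
#' @param channel_split Per-channel emission fractions (sums to 1); length
#'   must match the acquisition config's channel list.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells,
                            lifetime_mean,
                            lifetime_sd = 0,
                            amp_fraction2 = 0,
                            intensity_median = 2000,
                            intensity_sdlog = 0,
                            coupling = 0,
                            background_rate = 0,
                            arrival_rate = 50,
                            transit_fwhm = 2,
                            channel_split = 1) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) stop("`n_cells` must be >= 1")
  if (!length(lifetime_mean) %in% 1:2 || any(lifetime_mean <= 0))
    stop("`lifetime_mean` must be one or two positive lifetimes (ns)")
  if (lifetime_sd < 0) stop("`lifetime_sd` must be >= 0")
  if (any(amp_fraction2 < 0 | amp_fraction2 > 1))
    stop("`amp_fraction2` must lie in [0, 1]")
  if (intensity_median <= 0) stop("`intensity_median` must be > 0")
  if (background_rate < 0 || arrival_rate < 0) stop("rates must be >= 0")
  if (transit_fwhm <= 0) stop("`transit_fwhm` must be > 0 (ms)")
  if (abs(sum(channel_split) - 1) > 1e-9 || any(channel_split < 0))
    stop("`channel_split` must be non-negative fractions summing to 1")
  structure(
    list(n_cells = n_cells, lifetime_mean = lifetime_mean,
         lifetime_sd = lifetime_sd, amp_fraction2 = amp_fraction2,
         intensity_median = intensity_median,
         intensity_sdlog = intensity_sdlog, coupling = coupling,
         background_rate = background_rate, arrival_rate = arrival_rate,
         transit_fwhm = transit_fwhm, channel_split = channel_split),
    class = "population_spec"
  )
}

#' Truncated exponential decay on the micro-time window
#'
#' Density, CDF, random generation and mean of an exponential decay with
#' lifetime `tau` restricted to the observation window `[0, window)`, the
#' distribution of TCSPC micro times under pulsed re-excitation when
#' wrap-around is negligible.
#'
#' The mean has the closed form `tau - window / (exp(window/tau) - 1)`.
#'
#' @param x,q,n Values, quantiles, or number of draws.
#' @param tau Lifetime (ns), > 0.
#' @param window Window length (ns), > 0.
#' @return `dtruncexp`/`ptruncexp` return densities/probabilities,
#'   `rtruncexp` draws, `mean_truncexp` the expected value.
#' @export
dtruncexp <- function(x, tau, window) {
  z <- 1 - exp(-window / tau)
  out <- ifelse(x >= 0 & x < window, exp(-x / tau) / (tau * z), 0)
  out
}

#' @rdname dtruncexp
#' @export
ptruncexp <- function(q, tau, window) {
  z <- 1 - exp(-window / tau)
  pmin(pmax((1 - exp(-pmax(q, 0) / tau)) / z, 0), 1) * (q > 0)
}

#' @rdname dtruncexp
#' @export
rtruncexp <- function(n, tau, window) {
  u <- runif(n)
  -tau * log(1 - u * (1 - exp(-window / tau)))
}

#' @rdname dtruncexp
#' @export
mean_truncexp <- function(tau, window) {
  tau - window / (exp(window / tau) - 1)
}

## draw micro times for one cell: mono- or bi-exponential truncated decay.
## For a bi-exponential with amplitude fractions (a1, a2) the photon-count
## weight of component k over the window is a_k * tau_k * (1 - exp(-T/tau_k)).
draw_micro_times <- function(n, taus, amp2, window) {
  if (length(taus) == 1L || amp2 <= 0) {
    return(rtruncexp(n, taus[1L], window))
  }
  if (amp2 >= 1) return(rtruncexp(n, taus[2L], window))
  a <- c(1 - amp2, amp2)
  w <- a * taus * (1 - exp(-window / taus))
  comp <- 1L + (runif(n) < w[2L] / sum(w))
  rtruncexp(n, taus[comp], window)
}

#' Simulate a TCSPC FIFO photon stream
#'
#' Generates a photon stream from particles transiting a Gaussian
#' illumination envelope on top of uncorrelated background, with the full
#' ground truth attached. Particle arrivals are a Poisson process; each
#' particle emits a Poisson number of photons whose macro times follow a
#' Gaussian transit profile and whose micro times follow its (mono- or
#' bi-exponential) decay truncated to the micro-time window. Background
#' photons are uniform in both macro and micro time.
#'
#' Identical `(spec, config, seed)` reproduce the stream exactly.
#'
#' @param spec A [population_spec()].
#' @param config An [acquisition_config()].
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @param duration Acquisition length in seconds, only used when
#'   `arrival_rate` is 0 (otherwise inferred from the last arrival).
#'
#' @return An object of class `photon_stream`: a list with `records`
#'   (data.frame of `macro_time` in us, `micro_time` in ns, `channel`),
#'   `config`, and `truth` (one row per simulated particle).
#' @export
#' @examples
#' cfg <- acquisition_config()
#' spec <- population_spec(n_cells = 5, lifetime_mean = 2.5, arrival_rate = 20)
#' st <- simulate_stream(spec, cfg, seed = 1)
#' nrow(st$records)
simulate_stream <- function(spec, config, seed, duration = 1) {
  stopifnot(inherits(spec, "population_spec"), inherits(config, "acq_config"))
  if (duration <= 0) stop("zero-length acquisition")
  if (length(spec$channel_split) != length(config$channels))
    stop("`channel_split` length must match the number of detector channels")
  window <- config$micro_window

  withr::with_seed(seed, {
    n_part <- if (spec$arrival_rate > 0) spec$n_cells else 0L
    fwhm_us <- spec$transit_fwhm * 1e3
    sd_us <- fwhm_us / (2 * sqrt(2 * log(2)))

    if (n_part > 0L) {
      gaps <- rexp(n_part, spec$arrival_rate)        # seconds
      arrivals <- cumsum(gaps) * 1e6 + 4 * fwhm_us    # us, padded from t = 0
      duration_us <- arrivals[n_part] + 4 * fwhm_us
      exp_photons <- spec$intensity_median *
        exp(rnorm(n_part, 0, spec$intensity_sdlog))
      tau1 <- rnorm(n_part, spec$lifetime_mean[1L], spec$lifetime_sd)
      if (spec$coupling != 0) {
        tau1 <- tau1 + spec$coupling *
          (log10(exp_photons) - mean(log10(exp_photons)))
      }
      tau1 <- pmax(tau1, 0.02)
      tau2 <- if (length(spec$lifetime_mean) == 2L) spec$lifetime_mean[2L] else NA_real_
      amp2 <- rep_len(spec$amp_fraction2, n_part)
      n_ph <- rpois(n_part, exp_photons)
    } else {
      arrivals <- numeric(0)
      duration_us <- duration * 1e6
      exp_photons <- tau1 <- numeric(0)
      tau2 <- NA_real_
      amp2 <- numeric(0)
      n_ph <- integer(0)
    }

    mk_channel <- function(n) {
      if (length(config$channels) == 1L) rep(config$channels, n)
      else sample(config$channels, n, replace = TRUE, prob = spec$channel_split)
    }

    parts <- vector("list", n_part + 1L)
    for (i in seq_len(n_part)) {
      ni <- n_ph[i]
      if (ni == 0L) next
      taus <- if (is.na(tau2)) tau1[i] else c(tau1[i], tau2)
      parts[[i]] <- data.frame(
        macro_time = rnorm(ni, arrivals[i], sd_us),
        micro_time = draw_micro_times(ni, taus, amp2[i], window),
        channel = mk_channel(ni)
      )
    }
    n_bg <- rpois(1L, spec$background_rate * duration_us * 1e-6)
    if (n_bg > 0L) {
      parts[[n_part + 1L]] <- data.frame(
        macro_time = runif(n_bg, 0, duration_us),
        micro_time = runif(n_bg, 0, window),
        channel = mk_channel(n_bg)
      )
    }
    rec <- do.call(rbind, parts[!vapply(parts, is.null, logical(1L))])
    if (is.null(rec)) {
      rec <- data.frame(macro_time = numeric(0), micro_time = numeric(0),
                        channel = integer(0))
    }

    if (config$irf_sigma > 0 && nrow(rec) > 0L) {
      rec$micro_time <- (rec$micro_time +
                           rnorm(nrow(rec), 0, config$irf_sigma)) %% window
    }
    rec$macro_time <- pmax(rec$macro_time, 0)
    rec <- rec[order(rec$macro_time), , drop = FALSE]
    rownames(rec) <- NULL

    if (config$pileup && nrow(rec) > 1L) {
      sync_idx <- floor((rec$macro_time * 1e3 + rec$micro_time) /
                          config$sync_period)
      rec <- rec[!duplicated(sync_idx), , drop = FALSE]
      rownames(rec) <- NULL
    }

    truth <- data.frame(
      cell_id = seq_len(n_part),
      arrival = arrivals,
      transit_fwhm = rep(spec$transit_fwhm, n_part),
      expected_photons = exp_photons,
      n_photons = n_ph,
      tau1 = tau1,
      tau2 = rep(tau2, n_part),
      amp_fraction2 = amp2
    )
    structure(list(records = rec, config = config, truth = truth,
                   duration = duration_us),
              class = "photon_stream")
  })
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("TCSPC photon stream: %d records over %.3f s", nrow(x$records),
              x$duration * 1e-6))
  if (!is.null(x$truth) && nrow(x$truth) > 0)
    cat(sprintf(", %d truth particles", nrow(x$truth)))
  cat("\n")
  invisible(x)
}

#' Population specs matching reported lifetime means and spreads
#'
#' Builds one [population_spec()] per FRET construct from a table of
#' per-population mean lifetimes and cell-to-cell standard deviations, the
#' form in which lifetime flow cytometry results are reported (mean, SEM,
#' STD, n). Useful for emulating measured populations of FRET standards.
#'
#' @param params data.frame with columns `name`, `mean` (ns), `std` (ns),
#'   and optionally `n_cells`.
#' @param n_cells Default number of cells per population when `params`
#'   lacks an `n_cells` column.
#' @param coupling,intensity_sdlog,arrival_rate,background_rate Passed to
#'   every [population_spec()].
#' @return Named list of `population_spec` objects.
#' @export
simulate_fret_populations <- function(params, n_cells = 1000,
                                      coupling = 0, intensity_sdlog = 1.15,
                                      arrival_rate = 50, background_rate = 0) {
  stopifnot(is.data.frame(params), all(c("name", "mean", "std") %in% names(params)))
  if (any(params$mean <= 0)) stop("population mean lifetimes must be > 0")
  if (any(params$std < 0)) stop("population lifetime STDs must be >= 0")
  n <- if ("n_cells" %in% names(params)) params$n_cells else rep(n_cells, nrow(params))
  specs <- lapply(seq_len(nrow(params)), function(i) {
    population_spec(n_cells = n[i],
                    lifetime_mean = params$mean[i],
                    lifetime_sd = params$std[i],
                    intensity_sdlog = intensity_sdlog,
                    coupling = coupling,
                    arrival_rate = arrival_rate,
                    background_rate = background_rate)
  })
  names(specs) <- params$name
  specs
}

#' Draw a per-cell lifetime/intensity table from a population spec
#'
#' Samples the same per-cell ground truth the stream simulator attaches
#' (lifetime, expected burst photon count) without generating photons —
#' the natural input scale for testing FRET efficiency estimators on
#' populations of thousands of cells.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return data.frame with `cell_id`, `tau` (ns), `intensity` (expected
#'   photons per burst).
#' @export
simulate_cell_table <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  withr::with_seed(seed, {
    n <- spec$n_cells
    intensity <- spec$intensity_median * exp(rnorm(n, 0, spec$intensity_sdlog))
    tau <- rnorm(n, spec$lifetime_mean[1L], spec$lifetime_sd)
    if (spec$coupling != 0)
      tau <- tau + spec$coupling * (log10(intensity) - mean(log10(intensity)))
    data.frame(cell_id = seq_len(n), tau = pmax(tau, 0.02), intensity = intensity)
  })
}

#' Simulate three-channel intensity tables for ratiometric FRET
#'
#' Generates per-cell background-free donor (`I_DD`), sensitized (`I_DA`)
#' and direct-acceptor (`I_AA`) intensities for a set of donor-acceptor
#' fusion constructs under a linear three-cube mixing model, together with
#' donor-only and acceptor-only control populations carrying the same
#' bleed-through. With `noise_cv = 0` the tables are exactly invertible by
#' the ratiometric calibration: the recovered S factors, regression line
#' and per-cell efficiencies equal the simulation truth.
#'
#' Mixing model, per cell with expression level `X` and efficiency `E`
#' (detection efficiencies `d`, `s`, `a` for the three channels):
#' donor signal `D = d*X*(1-E)`, sensitized signal `Fc = s*X*E`, direct
#' acceptor signal `A = a*X`; measured channels
#' `I_DD = D`, `I_DA = Fc + S1*D + S2*A`, `I_AA = A + S3*D`.
#' Under this model `Fc/(I_AA - S3*I_DD)` is linear in
#' `I_DD/(I_AA - S3*I_DD)` with slope `k = -s/d` and intercept
#' `y0 = s/a`, so the calibration factor is `alpha = k/y0 = -a/d`.
#'
#' @param true_E Numeric vector of per-construct FRET efficiencies in
#'   `[0, 1)`, one construct per element (names kept if present).
#' @param S Bleed-through triple `c(S1, S2, S3)`.
#' @param det_eff Named channel detection efficiencies
#'   `c(donor=, sens=, accept=)`.
#' @param n_cells Cells per construct (also per control population).
#' @param expression_median,expression_sdlog Log-normal expression model.
#' @param noise_cv Multiplicative Gaussian noise CV applied per channel;
#'   negative intensities after noise are clipped at 0 and counted in the
#'   `clipped` attribute.
#' @param seed Integer seed.
#' @return List with `standards` (data.frame: `construct`, `E_true`,
#'   `I_DD`, `I_DA`, `I_AA`), `donor_only`, `acceptor_only` (same
#'   channels), and `truth` (list with `S`, `alpha`, `det_eff`).
#' @export
simulate_ratiometric_cells <- function(true_E,
                                       S = c(0, 0, 0),
                                       det_eff = c(donor = 1, sens = 0.6, accept = 0.8),
                                       n_cells = 500,
                                       expression_median = 1000,
                                       expression_sdlog = 1,
                                       noise_cv = 0,
                                       seed = 1) {
  if (any(true_E < 0 | true_E >= 1)) stop("`true_E` must lie in [0, 1)")
  if (length(S) != 3L || any(S < 0)) stop("`S` must be c(S1, S2, S3) >= 0")
  d <- det_eff[["donor"]]; s <- det_eff[["sens"]]; a <- det_eff[["accept"]]
  withr::with_seed(seed, {
    clipped <- 0L
    noisy <- function(x) {
      if (noise_cv > 0) {
        x <- x * (1 + rnorm(length(x), 0, noise_cv))
        clipped <<- clipped + sum(x < 0)
        x <- pmax(x, 0)
      }
      x
    }
    mix <- function(X, E, has_donor = TRUE, has_acceptor = TRUE) {
      D <- if (has_donor) d * X * (1 - E) else 0 * X
      Fc <- if (has_donor && has_acceptor) s * X * E else 0 * X
      A <- if (has_acceptor) a * X else 0 * X
      data.frame(I_DD = noisy(D),
                 I_DA = noisy(Fc + S[1L] * D + S[2L] * A),
                 I_AA = noisy(A + S[3L] * D))
    }
    nm <- if (is.null(names(true_E))) paste0("construct_", seq_along(true_E)) else names(true_E)
    standards <- do.call(rbind, lapply(seq_along(true_E), function(i) {
      X <- expression_median * exp(rnorm(n_cells, 0, expression_sdlog))
      data.frame(construct = nm[i], E_true = unname(true_E[i]),
                 mix(X, true_E[i]), row.names = NULL)
    }))
    Xd <- expression_median * exp(rnorm(n_cells, 0, expression_sdlog))
    donor_only <- mix(Xd, 0, has_acceptor = FALSE)
    Xa <- expression_median * exp(rnorm(n_cells, 0, expression_sdlog))
    acceptor_only <- mix(Xa, 0, has_donor = FALSE)
    out <- list(standards = standards, donor_only = donor_only,
                acceptor_only = acceptor_only,
                truth = list(S = setNames(S, c("S1", "S2", "S3")),
                             alpha = -a / d, det_eff = det_eff))
    attr(out, "clipped") <- clipped
    out
  })
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a photon stream as a self-describing text container
#'
#' The native on-disk format is a tab-separated text file with a
#' `#key=value` header carrying the acquisition configuration, followed by
#' one row per photon (`macro_time` in us, `micro_time` in ns, `channel`).
#' The ground-truth particle table, when present, is written to a CSV
#' sidecar at `<path>.truth.csv`. Doubles are serialised with 17
#' significant digits so that `read_stream(write_stream(s))` reproduces
#' the stream exactly.
#'
#' @param stream A `photon_stream`.
#' @param path Output file path.
#' @param truth Write the truth sidecar when available? Default `TRUE`.
#' @return `write_stream` returns `path` invisibly; `read_stream` returns
#'   a `photon_stream`.
#' @export
write_stream <- function(stream, path, truth = TRUE) {
  stopifnot(inherits(stream, "photon_stream"))
  cfg <- stream$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#biflow-photon-stream v1",
    paste0("#sync_period=", fmt_num(cfg$sync_period)),
    paste0("#micro_window=", fmt_num(cfg$micro_window)),
    paste0("#adc_bins=", cfg$adc_bins),
    paste0("#bin_width=", fmt_num(cfg$bin_width)),
    paste0("#channels=", paste(cfg$channels, collapse = ",")),
    paste0("#irf_sigma=", fmt_num(cfg$irf_sigma)),
    paste0("#pileup=", as.integer(cfg$pileup)),
    paste0("#duration=", fmt_num(stream$duration)),
    paste0("#n_records=", nrow(stream$records)),
    "macro_time\tmicro_time\tchannel"
  ), con)
  if (nrow(stream$records) > 0L) {
    writeLines(paste(fmt_num(stream$records$macro_time),
                     fmt_num(stream$records$micro_time),
                     stream$records$channel, sep = "\t"), con)
  }
  if (truth && !is.null(stream$truth) && nrow(stream$truth) > 0L) {
    tr <- stream$truth
    for (cn in names(tr)) if (is.double(tr[[cn]])) {
      tr[[cn]] <- ifelse(is.na(tr[[cn]]), NA, fmt_num(tr[[cn]]))
    }
    write.csv(tr, paste0(path, ".truth.csv"), row.names = FALSE,
              quote = FALSE, na = "NA")
  }
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 11L || lines[1L] != "#biflow-photon-stream v1")
    stop("malformed header: not a biflow photon stream file")
  hdr <- lines[2:10]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  h <- setNames(vals, keys)
  need <- c("sync_period", "micro_window", "adc_bins", "bin_width",
            "channels", "irf_sigma", "pileup", "duration", "n_records")
  if (!all(need %in% names(h))) stop("malformed header: missing keys")
  cfg <- acquisition_config(
    sync_period = as.numeric(h[["sync_period"]]),
    micro_window = as.numeric(h[["micro_window"]]),
    adc_bins = as.integer(h[["adc_bins"]]),
    bin_width = as.numeric(h[["bin_width"]]),
    channels = as.integer(strsplit(h[["channels"]], ",", fixed = TRUE)[[1L]]),
    irf_sigma = as.numeric(h[["irf_sigma"]]),
    pileup = as.integer(h[["pileup"]]) == 1L
  )
  n_rec <- as.integer(h[["n_records"]])
  if (lines[11L] != "macro_time\tmicro_time\tchannel")
    stop("malformed header: missing column line")
  body <- lines[-(1:11)]
  if (length(body) != n_rec) stop("record count does not match header")
  if (n_rec > 0L) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    rec <- data.frame(
      macro_time = as.numeric(vapply(fields, `[`, "", 1L)),
      micro_time = as.numeric(vapply(fields, `[`, "", 2L)),
      channel = as.integer(vapply(fields, `[`, "", 3L))
    )
    if (is.unsorted(rec$macro_time))
      stop("non-monotone macro times: stream is corrupt")
    if (!all(rec$channel %in% cfg$channels))
      stop("record channel outside the configured channel list")
  } else {
    rec <- data.frame(macro_time = numeric(0), micro_time = numeric(0),
                      channel = integer(0))
  }
  truth_path <- paste0(path, ".truth.csv")
  truth <- if (file.exists(truth_path)) {
    read.csv(truth_path, colClasses = c(
      cell_id = "integer", arrival = "numeric", transit_fwhm = "numeric",
      expected_photons = "numeric", n_photons = "integer",
      tau1 = "numeric", tau2 = "numeric", amp_fraction2 = "numeric"))
  } else NULL
  structure(list(records = rec, config = cfg, truth = truth,
                 duration = as.numeric(h[["duration"]])),
            class = "photon_stream")
}
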