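#' Micro-time decay histogram of one burst
#'
#' Bins the micro times of the photons belonging to a burst into
#' `adc_bins` equal-width channels spanning `[0, micro_window)`, giving
#' the fluorescence decay transient for that particle. Photon-conserving
#' per detector channel.
#'
#' @param stream A `photon_stream`.
#' @param burst One row of a `burst_table` produced with the stream
#'   attached (so that `first_photon`/`last_photon` are present).
#' @param adc_bins Number of micro-time bins; defaults to the config.
#' @param channel Optional detector channel id; `NULL` pools all
#'   channels.
#' @return Object of class `decay_histogram`: list with `edges`
#'   (`adc_bins + 1` bin edges in ns), `counts`, `window` (ns),
#'   `channel`, `n_photons`.
#' @export
histogram_micro_times <- function(stream, burst,
                                  adc_bins = stream$config$adc_bins,
                                  channel = NULL) {
  stopifnot(inherits(stream, "photon_stream"))
  if (is.null(burst$first_photon))
    stop("burst lacks a photon span; call segment_bursts() with `stream`")
  if (burst$last_photon < burst$first_photon)
    stop("insufficient photons: burst is empty")
  span <- burst$first_photon:burst$last_photon
  mts <- stream$records$micro_time[span]
  if (!is.null(channel)) mts <- mts[stream$records$channel[span] == channel]
  if (length(mts) == 0L) stop("insufficient photons: no photons in channel")
  decay_histogram(mts, stream$config$micro_window, adc_bins, channel)
}

#' Build a decay histogram from raw micro times
#'
#' @param micro_times Photon micro times in ns, all within
#'   `[0, window)`.
#' @param window Micro-time window length (ns).
#' @param adc_bins Number of equal-width bins.
#' @param channel Optional detector channel id stored for bookkeeping.
#' @return A `decay_histogram` (see [histogram_micro_times()]).
#' @export
decay_histogram <- function(micro_times, window, adc_bins = 256L,
                            channel = NULL) {
  adc_bins <- as.integer(adc_bins)
  if (adc_bins < 2L) stop("`adc_bins` must be >= 2")
  if (any(micro_times < 0 | micro_times >= window))
    stop("micro times must lie in [0, window)")
  edges <- seq(0, window, length.out = adc_bins + 1L)
  idx <- pmin(floor(micro_times / (window / adc_bins)) + 1L, adc_bins)
  counts <- tabulate(idx, nbins = adc_bins)
  structure(list(edges = edges, counts = counts, window = window,
                 channel = channel, n_photons = length(micro_times)),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("decay histogram: %d photons in %d bins over [0, %.4g) ns\n",
              x$n_photons, length(x$counts), x$window))
  invisible(x)
}

## per-bin probabilities of a truncated exponential over the histogram span
trunc_exp_bin_probs <- function(edges, tau) {
  p <- exp(-edges[-length(edges)] / tau) - exp(-edges[-1L] / tau)
  p / (exp(-edges[1L] / tau) - exp(-edges[length(edges)] / tau))
}

## binned log-likelihood; bg is the uniform-background mixture fraction
binned_loglik <- function(tau, counts, edges, bg = 0) {
  p <- trunc_exp_bin_probs(edges, tau)
  if (bg > 0) p <- (1 - bg) * p + bg / length(counts)
  sum(counts * log(pmax(p, 1e-300)))
}

#' Fit a mono-exponential lifetime to a decay histogram
#'
#' Default estimator is the maximum-likelihood fit of an exponential
#' decay truncated to the observation window (binned multinomial
#' likelihood), which is calibration-free and near-optimal at the low
#' photon counts of single bursts. For background-free data the MLE
#' coincides with the root of the closed-form score equation
#' `mean(t) = tau - T / (exp(T/tau) - 1)`. The alternative is
#' Levenberg-Marquardt weighted least squares with Poisson weights.
#'
#' @param hist A `decay_histogram`.
#' @param method `"mle"` (default) or `"ls"` (Levenberg-Marquardt).
#' @param background `"none"` (pure decay) or `"fit"` (adds a uniform
#'   background component; for `"ls"` a constant offset per bin).
#' @param min_photons Minimum photons required for a fit (default 100).
#' @param fit_start Optional micro time (ns) below which bins are
#'   excluded, for skipping the instrument-response rise.
#' @param tau_range Search interval for the lifetime (ns).
#' @return Object of class `mono_fit`: list with `tau` (ns),
#'   `amplitude` (expected counts in bin 1 scale), `offset`
#'   (background counts per bin), `bg_fraction`, `fit_quality` (reduced
#'   chi-square on Poisson errors), `logLik`, `n_photons`, `converged`,
#'   `method`.
#' @export
fit_mono <- function(hist, method = c("mle", "ls"),
                     background = c("none", "fit"),
                     min_photons = 100, fit_start = 0,
                     tau_range = c(0.01, 50)) {
  stopifnot(inherits(hist, "decay_histogram"))
  method <- match.arg(method)
  background <- match.arg(background)
  counts <- hist$counts
  edges <- hist$edges
  if (fit_start > 0) {
    keep <- edges[-length(edges)] >= fit_start   # contiguous tail of bins
    counts <- counts[keep]
    edges <- edges[c(keep, TRUE)]
  }
  n <- sum(counts)
  if (n < min_photons)
    stop(sprintf("insufficient photons for fit (%d < %d)", n, min_photons))
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: all photons in a single bin")

  nb <- length(counts)
  if (method == "mle") {
    if (background == "none") {
      opt <- optimize(function(tau) binned_loglik(tau, counts, edges),
                      interval = tau_range, maximum = TRUE, tol = 1e-8)
      tau <- opt$maximum
      bg <- 0
      ll <- opt$objective
      converged <- tau > tau_range[1L] * 1.01 && tau < tau_range[2L] * 0.99
    } else {
      nll <- function(par) {
        tau <- exp(par[1L]); bg <- stats::plogis(par[2L])
        -binned_loglik(tau, counts, edges, bg)
      }
      o <- optim(c(log(mean_start_tau(counts, edges)), stats::qlogis(0.01)),
                 nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
      tau <- exp(o$par[1L]); bg <- stats::plogis(o$par[2L])
      ll <- -o$value
      converged <- o$convergence == 0L
    }
    p <- trunc_exp_bin_probs(edges, tau)
    expected <- n * ((1 - bg) * p + bg / nb)
    amplitude <- expected[1L]
    offset <- n * bg / nb
  } else {
    mids <- (edges[-1L] + edges[-length(edges)]) / 2
    tau0 <- mean_start_tau(counts, edges)
    A0 <- max(counts)
    w <- 1 / pmax(counts, 1)
    resid_fn <- if (background == "fit") {
      function(par) sqrt(w) * (counts - (par[1L] * exp(-mids / par[2L]) + par[3L]))
    } else {
      function(par) sqrt(w) * (counts - par[1L] * exp(-mids / par[2L]))
    }
    par0 <- if (background == "fit") c(A0, tau0, 0) else c(A0, tau0)
    lower <- if (background == "fit") c(0, tau_range[1L], 0) else c(0, tau_range[1L])
    upper <- if (background == "fit") c(Inf, tau_range[2L], Inf) else c(Inf, tau_range[2L])
    fit <- minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    tau <- fit$par[2L]
    amplitude <- fit$par[1L]
    offset <- if (background == "fit") fit$par[3L] else 0
    expected <- amplitude * exp(-mids / tau) + offset
    bg <- offset * nb / n
    ll <- NA_real_
    converged <- fit$info %in% 1:4
  }
  dof <- nb - (if (background == "fit") 3L else 2L)
  chi2 <- sum((counts - expected)^2 / pmax(expected, 1e-12)) / max(dof, 1L)
  structure(list(tau = tau, amplitude = amplitude, offset = offset,
                 bg_fraction = bg, fit_quality = chi2, logLik = ll,
                 n_photons = n, converged = converged, method = method),
            class = "mono_fit")
}

## moment starting value: invert the truncated-exponential mean
mean_start_tau <- function(counts, edges) {
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  m <- sum(counts * mids) / sum(counts) - edges[1L]
  Tn <- edges[length(edges)] - edges[1L]
  if (m >= Tn / 2 * 0.999) return(Tn)  # near-uniform: lifetime >> window
  tryCatch(
    uniroot(function(tau) mean_truncexp(tau, Tn) - m,
            interval = c(1e-4, 1e4), tol = 1e-10)$root,
    error = function(e) m
  )
}

#' @export
print.mono_fit <- function(x, ...) {
  cat(sprintf("mono-exponential fit (%s): tau = %.4g ns, %d photons, chi2_r = %.3g%s\n",
              x$method, x$tau, x$n_photons, x$fit_quality,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

## bin-integrated component shapes; columns scale so coefficients are the
## decay amplitudes A_k of I(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)
biexp_design <- function(edges, taus) {
  vapply(taus, function(tk) {
    tk * (exp(-edges[-length(edges)] / tk) - exp(-edges[-1L] / tk))
  }, numeric(length(edges) - 1L))
}

#' Global bi-exponential decay analysis
#'
#' Fits the two-component decay `I(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)`
#' to a collection of per-cell (and per-channel) decay histograms. The two
#' lifetimes are shared by every histogram while the non-negative
#' amplitudes `A1`, `A2` are free per histogram — the global-analysis
#' scheme that extracts the mixing ratio of two photophysical states from
#' bursts too small for an unconstrained bi-exponential fit.
#'
#' With `free_taus = FALSE` each histogram's fit is a two-parameter
#' non-negative least-squares problem (convex; unique solution). With
#' `free_taus = TRUE` the shared lifetimes are refined by alternating a
#' joint lifetime update with the per-histogram amplitude solves until the
#' summed objective improves by less than `tol`.
#'
#' @param hists List of `decay_histogram` objects (one per cell/channel).
#' @param taus Initial (or fixed) lifetime pair `c(tau1, tau2)` in ns,
#'   `tau1 < tau2`.
#' @param free_taus Refine the shared lifetimes? Default `FALSE`.
#' @param min_photons Histograms with fewer photons are skipped and
#'   flagged (`fitted = FALSE`), not dropped.
#' @param tol Relative improvement tolerance for the alternation loop.
#' @param max_iter Maximum alternation iterations.
#' @return Object of class `global_biexp_fit`: list with `tau1`, `tau2`,
#'   `cells` (data.frame: `id`, `A1`, `A2`, `f1`, `f2`, `n_photons`,
#'   `fitted`), `objective` (final summed weighted SSR), `objective_trace`
#'   and `iterations` when lifetimes are refined.
#' @export
fit_biexp_global <- function(hists, taus, free_taus = FALSE,
                             min_photons = 100, tol = 1e-8, max_iter = 50) {
  if (inherits(hists, "decay_histogram")) hists <- list(hists)
  stopifnot(length(hists) >= 1L, all(vapply(hists, inherits, TRUE, "decay_histogram")))
  if (length(taus) != 2L || any(taus <= 0)) stop("`taus` must be two positive lifetimes")
  if (abs(taus[1L] - taus[2L]) < 1e-9) stop("tau1 = tau2 is degenerate")
  taus <- sort(taus)
  ids <- names(hists)
  if (is.null(ids)) ids <- as.character(seq_along(hists))
  ok <- vapply(hists, function(h) h$n_photons >= min_photons, TRUE)

  solve_amps <- function(taus) {
    A <- matrix(0, length(hists), 2L)
    obj <- 0
    for (i in seq_along(hists)) {
      if (!ok[i]) next
      h <- hists[[i]]
      X <- biexp_design(h$edges, taus)
      # unweighted least squares: observed-count Poisson weights would
      # overweight empty tail bins and bias the amplitude ratio
      sol <- pracma::lsqnonneg(X, h$counts)
      A[i, ] <- sol$x
      obj <- obj + sol$resid.norm
    }
    list(A = A, obj = obj)
  }

  fit <- solve_amps(taus)
  trace <- fit$obj
  iters <- 0L
  if (free_taus) {
    repeat {
      iters <- iters + 1L
      obj_tau <- function(par) {
        t1 <- exp(par[1L]); t2 <- t1 + exp(par[2L])
        solve_amps(c(t1, t2))$obj
      }
      o <- optim(c(log(taus[1L]), log(taus[2L] - taus[1L])), obj_tau,
                 method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-10))
      taus_new <- c(exp(o$par[1L]), exp(o$par[1L]) + exp(o$par[2L]))
      fit_new <- solve_amps(taus_new)
      if (fit_new$obj <= fit$obj) {
        improve <- (fit$obj - fit_new$obj) / max(fit$obj, 1e-12)
        taus <- taus_new
        fit <- fit_new
        trace <- c(trace, fit$obj)
        if (improve < tol || iters >= max_iter) break
      } else break
    }
  }

  A <- fit$A
  f <- t(apply(A, 1L, function(a) {
    if (sum(a) == 0) c(NA_real_, NA_real_)
    else fractional_intensity(a[1L], a[2L], taus[1L], taus[2L])
  }))
  cells <- data.frame(id = ids, A1 = A[, 1L], A2 = A[, 2L],
                      f1 = f[, 1L], f2 = f[, 2L],
                      n_photons = vapply(hists, `[[`, 0, "n_photons"),
                      fitted = ok)
  structure(list(tau1 = taus[1L], tau2 = taus[2L], cells = cells,
                 objective = fit$obj, objective_trace = trace,
                 iterations = iters),
            class = "global_biexp_fit")
}

#' @export
print.global_biexp_fit <- function(x, ...) {
  cat(sprintf("global bi-exponential fit: tau1 = %.4g ns, tau2 = %.4g ns, %d cells (%d fitted)\n",
              x$tau1, x$tau2, nrow(x$cells), sum(x$cells$fitted)))
  invisible(x)
}

#' Fractional intensities of a bi-exponential decay
#'
#' Intensity-weighted share of each lifetime component,
#' `f_k = A_k * tau_k / (A1 * tau1 + A2 * tau2)`; `f1 + f2 = 1`.
#' Invariant to joint rescaling of the amplitudes.
#'
#' @param A1,A2 Non-negative amplitudes (not both zero).
#' @param tau1,tau2 Positive lifetimes (ns).
#' @return Numeric `c(f1, f2)`.
#' @export
#' @examples
#' fractional_intensity(1, 1, 0.2, 2.95)
fractional_intensity <- function(A1, A2, tau1, tau2) {
  if (A1 < 0 || A2 < 0) stop("amplitudes must be >= 0")
  if (A1 == 0 && A2 == 0) stop("undefined for A1 = A2 = 0")
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be > 0")
  tot <- A1 * tau1 + A2 * tau2
  c(f1 = A1 * tau1 / tot, f2 = A2 * tau2 / tot)
}

#' Export per-cell fit results to CSV
#'
#' @param fit A `global_biexp_fit`, or a data.frame of per-cell mono-fit
#'   results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  tab <- if (inherits(fit, "global_biexp_fit")) {
    cbind(fit$cells, tau1 = fit$tau1, tau2 = fit$tau2)
  } else as.data.frame(fit)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
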