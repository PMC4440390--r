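#' Estimate a burst threshold from a binned trace
#'
#' Estimates the background level as the mean of the bins at or below the
#' trace's 90th percentile (bursts are sparse, so the bulk of bins is
#' background) and returns [suggest_threshold()] of it, with a floor of
#' one count per bin.
#'
#' @param trace A `binned_trace`.
#' @param k Poisson standard deviations above background (default 5).
#' @return Threshold in counts per bin.
#' @export
auto_threshold <- function(trace, k = 5) {
  stopifnot(inherits(trace, "binned_trace"))
  x <- trace$counts
  if (length(x) == 0L) return(1)
  bg <- mean(x[x <= quantile(x, 0.9)])
  max(suggest_threshold(bg, k), 1)
}

#' Run the burst-integrated lifetime pipeline on a photon stream
#'
#' Bins macro times, median-filters, thresholds, gates bursts by photon
#' count, histograms each burst's micro times and fits a per-burst
#' mono-exponential lifetime — producing the per-cell table (lifetime,
#' intensity, BD, MCR) that cytometry-style scatter plots and FRET
#' estimators consume.
#'
#' @param stream A `photon_stream`.
#' @param threshold Counts-per-bin burst threshold; `NULL` (default) uses
#'   [auto_threshold()].
#' @param median_window Median filter window in bins (odd; default 3).
#' @param min_PC,max_PC Photon-count gate (defaults 500 and 10000).
#' @param channel Detector channel to fit (`NULL` pools channels).
#' @param method,background,min_photons Passed to [fit_mono()].
#' @return data.frame of class `cell_table`: `cell_id`, `tau`,
#'   `intensity` (= PC of the fitted channel), `BD` (ms), `PC`, `MCR`
#'   (photons/ms), `fit_quality`, `converged`, plus per-channel counts
#'   when present. Attribute `threshold` records the value used.
#' @export
analyze_stream <- function(stream, threshold = NULL, median_window = 3L,
                           min_PC = 500, max_PC = 10000, channel = NULL,
                           method = "mle", background = "none",
                           min_photons = 100) {
  stopifnot(inherits(stream, "photon_stream"))
  raw <- bin_macro_times(stream)
  filt <- median_filter_trace(raw, median_window)
  if (is.null(threshold)) threshold <- auto_threshold(filt)
  bursts <- segment_bursts(raw, filt, threshold, stream = stream)
  bursts <- filter_bursts(bursts, min_PC, max_PC)
  n <- nrow(bursts)
  tau <- qual <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  inten <- bursts$PC
  for (i in seq_len(n)) {
    h <- tryCatch(
      histogram_micro_times(stream, bursts[i, ], channel = channel),
      error = function(e) NULL)
    if (is.null(h) || h$n_photons < min_photons) next
    if (!is.null(channel)) inten[i] <- h$n_photons
    f <- tryCatch(
      fit_mono(h, method = method, background = background,
               min_photons = min_photons),
      error = function(e) NULL)
    if (is.null(f)) next
    tau[i] <- f$tau
    qual[i] <- f$fit_quality
    conv[i] <- f$converged
  }
  out <- data.frame(cell_id = seq_len(n), tau = tau, intensity = inten,
                    BD = bursts$BD, PC = bursts$PC, MCR = bursts$MCR,
                    fit_quality = qual, converged = conv)
  for (cn in grep("^PC_ch", names(bursts), value = TRUE)) out[[cn]] <- bursts[[cn]]
  attr(out, "threshold") <- threshold
  class(out) <- c("cell_table", "data.frame")
  out
}
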