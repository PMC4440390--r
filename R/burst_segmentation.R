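#' Bin photon macro times into a count trace
#'
#' Histograms photon arrival macro times (all detector channels pooled)
#' into fixed-width bins, the first step of burst search. Bin index is
#' `floor((macro_time - t0) / bin_width)`; the operation conserves
#' photons.
#'
#' @param stream A `photon_stream`.
#' @param bin_width Bin width in microseconds; defaults to the
#'   acquisition config's value (20 us).
#' @return An object of class `binned_trace`: list with `counts` (per-bin
#'   photon counts), `bin_width` (us), and `t0` (us). An empty stream
#'   yields an empty trace.
#' @export
bin_macro_times <- function(stream, bin_width = stream$config$bin_width) {
  stopifnot(inherits(stream, "photon_stream"))
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  mt <- stream$records$macro_time
  t0 <- 0
  if (length(mt) == 0L) {
    counts <- integer(0)
  } else {
    idx <- floor((mt - t0) / bin_width) + 1
    counts <- tabulate(idx, nbins = max(idx))
  }
  structure(list(counts = counts, bin_width = bin_width, t0 = t0),
            class = "binned_trace")
}

#' @export
print.binned_trace <- function(x, ...) {
  cat(sprintf("binned trace: %d bins of %.4g us, %d photons\n",
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Sliding-window median filter
#'
#' Median-filters the binned count trace before thresholding, suppressing
#' single-bin shot-noise spikes while preserving burst plateaus. The
#' window must be odd; at the trace edges the window is truncated to the
#' available bins. `window = 1` is the identity.
#'
#' @param trace A `binned_trace`.
#' @param window Odd window length in bins (default 3).
#' @return A `binned_trace` of the same length with filtered counts.
#' @export
median_filter_trace <- function(trace, window = 3L) {
  stopifnot(inherits(trace, "binned_trace"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 1")
  x <- trace$counts
  n <- length(x)
  if (window == 1L || n == 0L) return(trace)
  h <- window %/% 2L
  if (n >= window) {
    out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  } else {
    out <- as.numeric(x)
  }
  # truncated windows at the edges
  for (i in seq_len(min(h, n))) {
    out[i] <- median(x[1:min(n, i + h)])
    j <- n - i + 1L
    out[j] <- median(x[max(1L, j - h):n])
  }
  trace$counts <- out
  trace
}

#' Suggest a burst threshold from the background level
#'
#' Returns `background_mean + k * sqrt(background_mean)` counts per bin, a
#' Poisson-noise-margin rule for separating particle bursts from the
#' baseline.
#'
#' @param background_mean Expected background counts per bin.
#' @param k Number of Poisson standard deviations above background
#'   (default 5).
#' @return Threshold in counts per bin.
#' @export
suggest_threshold <- function(background_mean, k = 5) {
  if (background_mean < 0) stop("`background_mean` must be >= 0")
  background_mean + k * sqrt(background_mean)
}

#' Segment a photon trace into particle bursts
#'
#' A burst is a maximal run of consecutive bins whose *filtered* counts
#' reach the threshold; its statistics — burst duration (BD), photon count
#' (PC), and mean count rate (MCR) — are computed from the *raw* bins
#' inside the run. Bursts are non-overlapping and ordered in time.
#'
#' @param raw Raw `binned_trace` from [bin_macro_times()].
#' @param filtered Median-filtered trace of the same length (defaults to
#'   `raw`, i.e. no filtering).
#' @param threshold Minimum filtered counts per bin for a bin to belong
#'   to a burst.
#' @param stream Optional `photon_stream`; when supplied, each burst also
#'   records the index span of its photons in the stream's record table
#'   and per-channel photon counts.
#' @return data.frame of class `burst_table` with one row per burst:
#'   `start_bin`, `end_bin` (half-open, 1-based), `BD` (ms), `PC`, `MCR`
#'   (photons/ms), and when `stream` is given `first_photon`,
#'   `last_photon`, plus one `PC_ch<k>` column per detector channel.
#' @export
segment_bursts <- function(raw, filtered = raw, threshold, stream = NULL) {
  stopifnot(inherits(raw, "binned_trace"), inherits(filtered, "binned_trace"))
  if (length(raw$counts) != length(filtered$counts))
    stop("raw and filtered traces must have the same length")
  above <- filtered$counts >= threshold
  n <- length(above)
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      BD = numeric(0), PC = integer(0), MCR = numeric(0))
  if (n == 0L || !any(above)) return(structure(empty, class = c("burst_table", "data.frame")))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  start_bin <- starts[keep]
  end_bin <- ends[keep] + 1L            # half-open
  csum <- cumsum(c(0L, raw$counts))
  PC <- csum[end_bin] - csum[start_bin]
  BD <- (end_bin - start_bin) * raw$bin_width / 1e3   # ms
  out <- data.frame(start_bin = start_bin, end_bin = end_bin,
                    BD = BD, PC = as.integer(PC), MCR = PC / BD)

  if (!is.null(stream)) {
    mt <- stream$records$macro_time
    # record index of the first photon at/after a bin boundary
    bstart_t <- raw$t0 + (start_bin - 1L) * raw$bin_width
    bend_t <- raw$t0 + (end_bin - 1L) * raw$bin_width
    first_photon <- findInterval(bstart_t, mt, left.open = TRUE) + 1L
    last_photon <- findInterval(bend_t, mt, left.open = TRUE)
    out$first_photon <- first_photon
    out$last_photon <- last_photon
    for (ch in stream$config$channels) {
      is_ch <- stream$records$channel == ch
      cch <- cumsum(c(0L, as.integer(is_ch)))
      out[[paste0("PC_ch", ch)]] <- cch[last_photon + 1L] - cch[first_photon]
    }
  }
  structure(out, class = c("burst_table", "data.frame"))
}

#' Gate bursts on photon count
#'
#' Keeps bursts whose photon count lies in `[min_PC, max_PC]` (inclusive
#' on both ends), the standard per-particle quality gate: very small
#' bursts carry too few photons for a lifetime fit, very large ones are
#' aggregates or coincident particles. Ordering is preserved.
#'
#' @param bursts A `burst_table`.
#' @param min_PC,max_PC Inclusive photon-count bounds (defaults 500 and
#'   10000, the usable single-particle burst range).
#' @return The filtered `burst_table`.
#' @export
filter_bursts <- function(bursts, min_PC = 500, max_PC = 10000) {
  stopifnot(is.data.frame(bursts))
  if (min_PC < 0 || min_PC > max_PC) stop("need 0 <= min_PC <= max_PC")
  out <- bursts[bursts$PC >= min_PC & bursts$PC <= max_PC, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a burst table to CSV
#'
#' @param bursts A `burst_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_burst_csv <- function(bursts, path) {
  write.csv(as.data.frame(bursts), path, row.names = FALSE)
  invisible(path)
}

#' Count overlapping particle transits in the simulation truth
#'
#' Brute-force interval-overlap oracle for burst coincidence: two
#' particles overlap when their transit intervals
#' `arrival +/- half_width * FWHM` intersect. Returns the ids of
#' particles involved in at least one overlap, the basis for checking the
#' merged-burst fraction recovered by segmentation.
#'
#' @param truth Truth data.frame from [simulate_stream()].
#' @param half_width Transit half-width in FWHM units (default 2, i.e.
#'   an interval of +/- 2 FWHM around the arrival).
#' @return Integer vector of overlapping `cell_id`s (possibly empty).
#' @export
overlapping_particles <- function(truth, half_width = 2) {
  n <- nrow(truth)
  if (n < 2L) return(integer(0))
  lo <- truth$arrival - half_width * truth$transit_fwhm * 1e3
  hi <- truth$arrival + half_width * truth$transit_fwhm * 1e3
  hit <- logical(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (lo[j] <= hi[i] && lo[i] <= hi[j]) hit[c(i, j)] <- TRUE
    }
  }
  truth$cell_id[hit]
}
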