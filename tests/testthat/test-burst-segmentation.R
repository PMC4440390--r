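# build a photon_stream directly from macro times (micro times irrelevant here)
stream_from_macro <- function(mt, cfg = acquisition_config()) {
  structure(list(records = data.frame(macro_time = sort(mt),
                                      micro_time = rep(1, length(mt)),
                                      channel = rep(1L, length(mt))),
                 config = cfg, truth = NULL,
                 duration = if (length(mt)) max(mt) else 0),
            class = "photon_stream")
}

test_that("macro-time binning conserves photons and places them by floor rule", {
  st <- stream_from_macro(c(5, 25, 27))
  tr <- bin_macro_times(st, bin_width = 20)
  expect_equal(tr$counts, c(1L, 2L))

  st2 <- make_stream(n_cells = 5, seed = 2, background_rate = 500)
  tr2 <- bin_macro_times(st2)
  expect_equal(sum(tr2$counts), nrow(st2$records))

  empty <- stream_from_macro(numeric(0))
  expect_length(bin_macro_times(empty)$counts, 0L)
})

test_that("a 2 ms transit produces an elevated region of about 100 bins", {
  st <- make_stream(n_cells = 1, photons = 5000, seed = 4)
  tr <- bin_macro_times(st)   # 20 us bins
  elevated <- sum(tr$counts >= 5)
  # +/- 1.2 FWHM of a Gaussian envelope holds ~99.5% of photons: ~100-250 bins
  expect_gt(elevated, 80)
  expect_lt(elevated, 300)
})

test_that("median filter matches the naive oracle and removes isolated spikes", {
  tr <- structure(list(counts = c(0, 0, 9, 0, 0), bin_width = 20, t0 = 0),
                  class = "binned_trace")
  expect_equal(median_filter_trace(tr, 3L)$counts, rep(0, 5))

  const <- structure(list(counts = rep(4, 17), bin_width = 20, t0 = 0),
                     class = "binned_trace")
  for (w in c(1L, 3L, 5L, 9L))
    expect_equal(median_filter_trace(const, w)$counts, rep(4, 17))

  withr::with_seed(8, {
    x <- rpois(200, 3)
    tr2 <- structure(list(counts = x, bin_width = 20, t0 = 0),
                     class = "binned_trace")
    for (w in c(3L, 5L, 7L))
      expect_equal(median_filter_trace(tr2, w)$counts, naive_median_filter(x, w))
  })
  expect_identical(median_filter_trace(tr, 1L)$counts, tr$counts)
  expect_error(median_filter_trace(tr, 4L), "odd")
})

test_that("rectangular pulses segment into the hand-computed bursts", {
  counts <- c(rep(0, 20), rep(50, 10), rep(0, 100), rep(50, 10), rep(0, 20))
  tr <- structure(list(counts = counts, bin_width = 20, t0 = 0),
                  class = "binned_trace")
  bursts <- segment_bursts(tr, tr, threshold = 5)
  expect_equal(nrow(bursts), 2L)
  expect_equal(bursts$BD, c(0.2, 0.2))       # 10 bins x 20 us
  expect_equal(bursts$PC, c(500L, 500L))
  expect_equal(bursts$MCR, c(2500, 2500))    # photons / ms
  expect_equal(bursts$start_bin, c(21L, 131L))

  zero <- structure(list(counts = rep(0, 50), bin_width = 20, t0 = 0),
                    class = "binned_trace")
  expect_equal(nrow(segment_bursts(zero, zero, 5)), 0L)
})

test_that("burst statistics come from raw bins while boundaries come from filtered", {
  raw <- structure(list(counts = c(0, 10, 0, 10, 0), bin_width = 20, t0 = 0),
                   class = "binned_trace")
  filt <- structure(list(counts = c(0, 8, 8, 8, 0), bin_width = 20, t0 = 0),
                    class = "binned_trace")
  b <- segment_bursts(raw, filt, threshold = 5)
  expect_equal(nrow(b), 1L)
  expect_equal(b$PC, 20L)          # raw photons inside the filtered run
  expect_equal(b$BD, 0.06)         # 3 bins
})

test_that("photon spans and per-channel counts are conserved", {
  spec <- population_spec(10, 2.5, intensity_median = 2000, arrival_rate = 20,
                          background_rate = 1000, channel_split = c(0.7, 0.3))
  st <- simulate_stream(spec, acquisition_config(channels = c(1L, 2L)), seed = 6)
  raw <- bin_macro_times(st)
  filt <- median_filter_trace(raw, 3L)
  bursts <- segment_bursts(raw, filt, threshold = 5, stream = st)
  expect_gt(nrow(bursts), 0L)
  in_burst <- bursts$last_photon - bursts$first_photon + 1L
  expect_equal(as.integer(bursts$PC), in_burst)
  expect_equal(bursts$PC_ch1 + bursts$PC_ch2, as.integer(bursts$PC))
  # photon conservation: in-burst + out-of-burst photons = stream size
  expect_lte(sum(bursts$PC), nrow(st$records))
})

test_that("photon-count gate is inclusive on both bounds and order preserving", {
  b <- structure(data.frame(start_bin = 1:3, end_bin = 2:4, BD = 1,
                            PC = c(499L, 500L, 10000L), MCR = 1),
                 class = c("burst_table", "data.frame"))
  kept <- filter_bursts(b, 500, 10000)
  expect_equal(kept$PC, c(500L, 10000L))
  expect_equal(filter_bursts(b, 0, Inf)$PC, b$PC)
  expect_error(filter_bursts(b, -1, 10), "min_PC")
})

test_that("well-separated particles are recovered one burst each after gating", {
  # mean gap 50 ms >> 2 ms transit; threshold crossings at the Gaussian tails
  # fragment into sub-500-photon slivers, which the standard PC gate removes
  st <- make_stream(n_cells = 60, photons = 2000, arrival_rate = 20, seed = 10)
  raw <- bin_macro_times(st)
  filt <- median_filter_trace(raw, 3L)
  bursts <- filter_bursts(segment_bursts(raw, filt, threshold = 5, stream = st),
                          500, 20000)
  # merged transits predicted by the interval-overlap oracle: two Gaussian
  # transits merge when their summed envelope stays above the threshold
  gaps_ms <- diff(st$truth$arrival) / 1e3
  sd_ms <- 2 / (2 * sqrt(2 * log(2)))
  peak <- 2000 * 0.02 * dnorm(0) / sd_ms
  d_eff <- 2 * sd_ms * sqrt(2 * log(2 * peak / 5))
  n_expected <- 60L - sum(gaps_ms < d_eff)
  expect_lte(abs(nrow(bursts) - n_expected), 1)
  expect_gte(nrow(bursts) / 60, 0.85)
})

test_that("raising the threshold never increases the total burst photon count", {
  st <- make_stream(n_cells = 20, seed = 12, background_rate = 2000)
  raw <- bin_macro_times(st)
  filt <- median_filter_trace(raw, 3L)
  pcs <- vapply(c(2, 5, 10, 20, 40), function(th) {
    sum(segment_bursts(raw, filt, th)$PC)
  }, 0)
  expect_true(all(diff(pcs) <= 0))
})

test_that("faster transits give shorter BD and higher MCR at constant PC", {
  fast <- make_stream(n_cells = 30, photons = 3000, transit_fwhm = 0.5,
                      seed = 14)
  slow <- make_stream(n_cells = 30, photons = 3000, transit_fwhm = 4,
                      seed = 14)
  seg <- function(st) {
    raw <- bin_macro_times(st)
    filter_bursts(segment_bursts(raw, median_filter_trace(raw, 3L), 5,
                                 stream = st), 500, 20000)
  }
  bf <- seg(fast); bs <- seg(slow)
  expect_lt(mean(bf$BD), mean(bs$BD))
  expect_gt(mean(bf$MCR), mean(bs$MCR))
})

test_that("threshold suggestion follows the background Poisson margin", {
  expect_equal(suggest_threshold(4), 4 + 5 * 2)
  expect_equal(suggest_threshold(0), 0)
  expect_error(suggest_threshold(-1), "background_mean")
})
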