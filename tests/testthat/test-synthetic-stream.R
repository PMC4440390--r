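test_that("config and spec constructors validate their invariants", {
  expect_error(acquisition_config(micro_window = 15), "micro_window")
  expect_error(acquisition_config(adc_bins = 1), "adc_bins")
  expect_error(acquisition_config(bin_width = 0), "bin_width")
  expect_error(population_spec(0, 2.5), "n_cells")
  expect_error(population_spec(10, -1), "lifetime_mean")
  expect_error(population_spec(10, 2.5, background_rate = -1), "rates")
  cfg <- acquisition_config(micro_window = 10)
  expect_equal(cfg$micro_window, 10)
  expect_equal(cfg$sync_period, 12.5)
})

test_that("no sources means an empty record list", {
  spec <- population_spec(1, 2.5, arrival_rate = 0, background_rate = 0)
  st <- simulate_stream(spec, acquisition_config(), seed = 1)
  expect_equal(nrow(st$records), 0L)
  expect_error(simulate_stream(spec, acquisition_config(), seed = 1,
                               duration = 0), "zero-length")
})

test_that("identical seeds reproduce identical streams; different seeds differ", {
  spec <- population_spec(5, 2.5, arrival_rate = 30, background_rate = 200)
  cfg <- acquisition_config()
  a <- simulate_stream(spec, cfg, seed = 42)
  b <- simulate_stream(spec, cfg, seed = 42)
  c <- simulate_stream(spec, cfg, seed = 43)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$records, c$records))
})

test_that("single-particle photon budget and micro-time mean match theory", {
  spec <- population_spec(1, 2.5, intensity_median = 2000, arrival_rate = 20)
  st <- simulate_stream(spec, acquisition_config(), seed = 7)
  n <- nrow(st$records)
  expect_lt(abs(n - 2000), 4 * sqrt(2000))
  # closed-form truncated-exponential mean, cross-checked by integration
  m_closed <- mean_truncexp(2.5, 12.5)
  expect_equal(m_closed, numeric_truncexp_mean(2.5, 12.5), tolerance = 1e-8)
  se <- sqrt(2.5^2) / sqrt(n)  # conservative SE bound for the mean
  expect_lt(abs(mean(st$records$micro_time) - m_closed), 3 * se)
})

test_that("total photons stay within 5 sigma of the Poisson budget over seeds", {
  spec <- population_spec(1, 2.5, intensity_median = 500, arrival_rate = 20)
  cfg <- acquisition_config()
  tot <- sum(vapply(1:100, function(s) nrow(simulate_stream(spec, cfg, s)$records), 0))
  expect_lt(abs(tot - 100 * 500), 5 * sqrt(100 * 500))
})

test_that("simulated micro times follow the truncated-decay law (KS distance)", {
  mt <- withr::with_seed(5, rtruncexp(1e5, 2.5, 12.5))
  ks <- suppressWarnings(stats::ks.test(mt, function(q) ptruncexp(q, 2.5, 12.5)))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("overlap fraction among Poisson arrivals matches the exponential-gap law", {
  # particle transits of duration d overlap a neighbour iff an adjacent gap
  # is < d; for Poisson arrivals the per-gap probability is 1 - exp(-lambda d)
  spec <- population_spec(400, 2.5, intensity_median = 50, arrival_rate = 40,
                          transit_fwhm = 2)
  st <- simulate_stream(spec, acquisition_config(), seed = 9)
  hw <- 1                                  # oracle interval: +/- 1 FWHM
  d_s <- 2 * hw * 2e-3                     # overlap iff gap < 4 ms
  flagged <- overlapping_particles(st$truth, half_width = hw)
  gaps <- diff(st$truth$arrival) * 1e-6
  p_gap <- 1 - exp(-40 * d_s)
  # fraction of gaps shorter than d equals the analytic law
  expect_lt(abs(mean(gaps < d_s) - p_gap), 4 * sqrt(p_gap * (1 - p_gap) / 399))
  # the interval-overlap oracle flags exactly the particles adjacent to such gaps
  short <- which(gaps < d_s)
  expect_setequal(flagged, union(short, short + 1L))
})

test_that("population specs built from reported moments reproduce them", {
  params <- data.frame(name = c("donor_only", "fret_7aa"),
                       mean = c(2.593, 2.038), std = c(0.13, 0.18),
                       n_cells = c(6270, 13874))
  specs <- simulate_fret_populations(params)
  tab <- simulate_cell_table(specs$donor_only, seed = 3)
  expect_equal(nrow(tab), 6270)
  expect_lt(abs(mean(tab$tau) - 2.593), 3 * 0.13 / sqrt(6270))
  expect_lt(abs(sd(tab$tau) - 0.13), 4 * 0.13 / sqrt(2 * 6270))
  expect_error(simulate_fret_populations(data.frame(name = "x", mean = -1, std = 0)),
               "mean")
  expect_error(simulate_fret_populations(data.frame(name = "x", mean = 2, std = -1)),
               "STD")
})

test_that("zero lifetime spread gives identical cells; coupling sets the trend sign", {
  spec0 <- population_spec(200, 2.5, lifetime_sd = 0, arrival_rate = 50)
  tab0 <- simulate_cell_table(spec0, seed = 1)
  expect_true(all(tab0$tau == 2.5))
  specc <- population_spec(2000, 2.5, lifetime_sd = 0.05, coupling = -0.1,
                           intensity_sdlog = 1.15, arrival_rate = 50)
  tabc <- simulate_cell_table(specc, seed = 2)
  expect_lt(cor(tabc$intensity, tabc$tau, method = "spearman"), 0)
})

test_that("ratiometric simulator is exactly invertible and obeys its mixing model", {
  sim <- simulate_ratiometric_cells(c(0.10, 0.20, 0.30), S = c(0.05, 0.1, 0.02),
                                    n_cells = 100, seed = 3)
  # donor-only cells show the S1 ratio by construction
  expect_equal(median(sim$donor_only$I_DA / sim$donor_only$I_DD), 0.05)
  # E = 0 with no bleed-through puts nothing in the sensitized channel
  sim0 <- simulate_ratiometric_cells(c(0), S = c(0, 0, 0), n_cells = 50, seed = 4)
  expect_true(all(sim0$standards$I_DA == 0))
  expect_error(simulate_ratiometric_cells(c(0.5, 1.0)), "true_E")
  # noisy negatives are clipped and counted
  simn <- simulate_ratiometric_cells(c(0.05), S = c(0, 0, 0), n_cells = 200,
                                     noise_cv = 2, seed = 5)
  expect_gt(attr(simn, "clipped"), 0)
  expect_true(all(simn$standards$I_DD >= 0))
})

test_that("streams round-trip through the text container bit-exactly", {
  # empty stream
  spec0 <- population_spec(1, 2.5, arrival_rate = 0, background_rate = 0)
  st0 <- simulate_stream(spec0, acquisition_config(), seed = 1)
  p0 <- withr::local_tempfile()
  write_stream(st0, p0)
  expect_identical(read_stream(p0)$records, st0$records)

  # large two-channel stream with truth
  spec <- population_spec(40, 2.5, intensity_median = 2500, arrival_rate = 30,
                          background_rate = 2000, channel_split = c(0.6, 0.4))
  cfg <- acquisition_config(channels = c(1L, 2L))
  st <- simulate_stream(spec, cfg, seed = 11)
  expect_gt(nrow(st$records), 5e4)
  p <- withr::local_tempfile()
  write_stream(st, p)
  back <- read_stream(p)
  expect_identical(back$records, st$records)
  expect_identical(back$truth, st$truth)
  expect_identical(back$config$channels, c(1L, 2L))

  # corrupt macro-time ordering is rejected with a diagnostic
  lines <- readLines(p)
  body <- lines[-(1:11)]
  writeLines(c(lines[1:11], rev(body)), p)
  expect_error(read_stream(p), "non-monotone")
  expect_error(read_stream(withr::local_tempfile(lines = "not a stream")),
               "malformed header")
})

test_that("IRF jitter and pile-up censoring act as configured", {
  spec <- population_spec(1, 0.5, intensity_median = 5000, arrival_rate = 20)
  st_irf <- simulate_stream(spec, acquisition_config(irf_sigma = 0.2), seed = 3)
  expect_true(all(st_irf$records$micro_time >= 0 &
                    st_irf$records$micro_time < 12.5))
  st_pile <- simulate_stream(spec, acquisition_config(pileup = TRUE), seed = 3)
  st_free <- simulate_stream(spec, acquisition_config(), seed = 3)
  expect_lt(nrow(st_pile$records), nrow(st_free$records))
})
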