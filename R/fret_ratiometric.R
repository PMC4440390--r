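#' Background-correct three-channel intensity tables
#'
#' Subtracts the per-channel location (mean by default, optionally
#' median) of an autofluorescence control population — cells carrying an
#' empty non-fluorescent vector — from every cell's `I_DD`, `I_DA` and
#' `I_AA`.
#'
#' @param cells data.frame with columns `I_DD`, `I_DA`, `I_AA` (raw
#'   intensities; other columns pass through).
#' @param controls data.frame of autofluorescence control cells, same
#'   channel columns.
#' @param center `"mean"` (default) or `"median"`.
#' @return `cells` with the three channels background-corrected.
#' @export
background_correct <- function(cells, controls, center = c("mean", "median")) {
  center <- match.arg(center)
  chans <- c("I_DD", "I_DA", "I_AA")
  stopifnot(all(chans %in% names(cells)))
  if (!is.data.frame(controls) || nrow(controls) == 0L)
    stop("empty background control population")
  stopifnot(all(chans %in% names(controls)))
  f <- if (center == "mean") mean else median
  for (ch in chans) cells[[ch]] <- cells[[ch]] - f(controls[[ch]])
  cells
}

#' Gate cells positive in all corrected channels
#'
#' Keeps cells with strictly positive background-corrected intensity in
#' all three channels, the standard positivity gate before ratiometric
#' analysis.
#'
#' @param cells data.frame with `I_DD`, `I_DA`, `I_AA`.
#' @return The gated data.frame.
#' @export
gate_positive <- function(cells) {
  keep <- cells$I_DD > 0 & cells$I_DA > 0 & cells$I_AA > 0
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bleed-through correction factors from single-fluorophore controls
#'
#' `S1 = median(I_DA / I_DD)` and `S3 = median(I_AA / I_DD)` over
#' donor-only (GFP-only) cells; `S2 = median(I_DA / I_AA)` over
#' acceptor-only (RFP-only) cells. Cells with a zero denominator are
#' excluded with a warning reporting the count.
#'
#' @param gfp_only Background-corrected donor-only control table.
#' @param rfp_only Background-corrected acceptor-only control table.
#' @return Object of class `bleedthrough`: list with `S1`, `S2`, `S3`
#'   and the control sizes used.
#' @export
bleedthrough_factors <- function(gfp_only, rfp_only) {
  stopifnot(is.data.frame(gfp_only), is.data.frame(rfp_only))
  if (nrow(gfp_only) == 0L || nrow(rfp_only) == 0L)
    stop("empty single-fluorophore control population")
  med_ratio <- function(num, den, label) {
    bad <- den == 0
    if (any(bad))
      warning(sprintf("%d cells with zero denominator excluded from %s",
                      sum(bad), label))
    if (all(bad)) stop(sprintf("no usable cells for %s", label))
    median(num[!bad] / den[!bad])
  }
  structure(list(
    S1 = med_ratio(gfp_only$I_DA, gfp_only$I_DD, "S1"),
    S2 = med_ratio(rfp_only$I_DA, rfp_only$I_AA, "S2"),
    S3 = med_ratio(gfp_only$I_AA, gfp_only$I_DD, "S3"),
    n_gfp = nrow(gfp_only), n_rfp = nrow(rfp_only)),
    class = "bleedthrough")
}

#' @export
print.bleedthrough <- function(x, ...) {
  cat(sprintf("bleed-through factors: S1 = %.4g, S2 = %.4g, S3 = %.4g\n",
              x$S1, x$S2, x$S3))
  invisible(x)
}

#' Bleed-through-corrected sensitized emission
#'
#' The FRET-sensitized acceptor signal after removing donor bleed-through
#' into the transfer channel and the directly excited acceptor
#' contribution:
#' `F_c = I_DA - S1 * I_DD - S2 * (I_AA - S3 * I_DD)`.
#' By construction of the S factors, `F_c` vanishes identically on
#' donor-only and acceptor-only populations; it reduces to `I_DA` when
#' all S factors are zero. Negative values are possible under noise and
#' are reported as-is.
#'
#' @param cells data.frame with `I_DD`, `I_DA`, `I_AA`
#'   (background-corrected, gated positive).
#' @param S A `bleedthrough` object or numeric `c(S1, S2, S3)`.
#' @return Numeric vector `F_c`, one value per cell.
#' @export
sensitized_emission <- function(cells, S) {
  s <- as_S_triple(S)
  cells$I_DA - s[1L] * cells$I_DD - s[2L] * (cells$I_AA - s[3L] * cells$I_DD)
}

as_S_triple <- function(S) {
  if (inherits(S, "bleedthrough")) c(S$S1, S$S2, S$S3)
  else if (is.numeric(S) && length(S) == 3L) as.numeric(S)
  else stop("`S` must be a bleedthrough object or c(S1, S2, S3)")
}

#' Calibrate the ratiometric alpha factor across FRET standards
#'
#' For each construct (a donor-acceptor fusion of fixed, known linker
#' length) the per-construct median of `R_F = F_c / I_AA'` is regressed
#' against the median of `I_DD / I_AA'`, where `I_AA' = I_AA - S3 * I_DD`
#' is the directly excited acceptor signal. Under the 1:1-stoichiometry
#' mixing model this relation is an exact straight line whose slope `k`
#' (negative when the constructs' transfer efficiencies differ) and
#' intercept `y0` encode the channel detection-efficiency ratios; the
#' calibration factor is their fraction `alpha = k / y0`. Per-cell
#' efficiency then follows as `E = F_c / (F_c - k * I_DD)`.
#'
#' @param standards Named list of background-corrected, gated
#'   data.frames, one per construct (>= 2 constructs), each with `I_DD`,
#'   `I_DA`, `I_AA`.
#' @param S Bleed-through factors ([bleedthrough_factors()] output or an
#'   S triple).
#' @param per_cell Regress on the per-cell scatter instead of
#'   per-construct medians (default `FALSE`: medians, robust to outliers).
#' @return Object of class `alpha_calibration`: list with `R_F`
#'   (per-construct medians), `abscissa`, `k`, `y0`, `alpha`, `S`.
#' @export
calibrate_alpha <- function(standards, S, per_cell = FALSE) {
  stopifnot(is.list(standards))
  if (length(standards) < 2L)
    stop("alpha calibration needs >= 2 FRET standard constructs")
  s <- as_S_triple(S)
  pts <- lapply(standards, function(df) {
    Fc <- sensitized_emission(df, s)
    Aprime <- df$I_AA - s[3L] * df$I_DD
    if (any(Aprime == 0)) stop("zero corrected acceptor signal")
    data.frame(y = Fc / Aprime, x = df$I_DD / Aprime)
  })
  if (per_cell) {
    xy <- do.call(rbind, pts)
  } else {
    xy <- data.frame(
      y = vapply(pts, function(p) median(p$y), 0),
      x = vapply(pts, function(p) median(p$x), 0))
  }
  if (length(unique(xy$x)) < 2L || sd(xy$x) == 0)
    stop("degenerate regression: zero-variance abscissa across constructs")
  fit <- lm(y ~ x, data = xy)
  k <- unname(coef(fit)[2L])
  y0 <- unname(coef(fit)[1L])
  structure(list(R_F = setNames(xy$y, rownames(xy)), abscissa = xy$x,
                 k = k, y0 = y0, alpha = k / y0, S = s,
                 per_cell = per_cell),
            class = "alpha_calibration")
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat(sprintf("alpha calibration: k = %.5g, y0 = %.5g, alpha = %.5g\n",
              x$k, x$y0, x$alpha))
  invisible(x)
}

#' Ratiometric per-cell FRET efficiency and trimmed summary
#'
#' Computes the per-cell efficiency `E = F_c / (F_c - k * I_DD)` from
#' background-corrected, gated three-channel intensities and an
#' [calibrate_alpha()] calibration, then summarizes the population after
#' excluding 10% of outliers (default: symmetric trimming, 5% from each
#' tail of the E distribution; alternatively the 10% of cells with the
#' largest absolute deviation from the median).
#'
#' @param cells Gated data.frame with `I_DD`, `I_DA`, `I_AA`.
#' @param calib An `alpha_calibration`.
#' @param trim Total outlier fraction excluded from the summary
#'   (default 0.10).
#' @param trim_method `"symmetric"` (default) or `"deviation"`.
#' @return List of class `ratiometric_result`: `E` (per-cell, untrimmed),
#'   `summary` (a `population_summary` on the trimmed E, in %), `n_trimmed`.
#' @export
efficiency_ratiometric <- function(cells, calib, trim = 0.10,
                                   trim_method = c("symmetric", "deviation")) {
  stopifnot(inherits(calib, "alpha_calibration"))
  trim_method <- match.arg(trim_method)
  Fc <- sensitized_emission(cells, calib$S)
  E <- Fc / (Fc - calib$k * cells$I_DD)
  keep <- trim_keep(E, trim, trim_method)
  if (!any(keep)) stop("empty population after trimming")
  structure(list(E = E,
                 summary = summarize_population(100 * E[keep]),
                 n_trimmed = sum(!keep), trim = trim,
                 trim_method = trim_method),
            class = "ratiometric_result")
}

trim_keep <- function(E, trim, trim_method) {
  n <- length(E)
  if (n == 0L) stop("empty population")
  drop_each <- floor(trim / 2 * n)
  if (trim_method == "symmetric") {
    o <- order(E)
    keep <- rep(TRUE, n)
    if (drop_each > 0L)
      keep[o[c(seq_len(drop_each), n + 1L - seq_len(drop_each))]] <- FALSE
  } else {
    dev <- abs(E - median(E))
    keep <- rank(-dev, ties.method = "first") > floor(trim * n)
  }
  keep
}

#' @export
print.ratiometric_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ratiometric FRET: mean E = %.2f%% (SEM %.3g, STD %.3g, n = %d; %d cells trimmed)\n",
              s$mean, s$SEM, s$STD, s$n, x$n_trimmed))
  invisible(x)
}
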