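#' Population summary: mean, SEM, STD, n
#'
#' Summary statistics in the reporting convention of cytometry tables:
#' sample standard deviation (n - 1 denominator), standard error of the
#' mean `SEM = STD / sqrt(n)`, and a rounding helper that rounds the mean
#' to the decimal place of the SEM. A single value has undefined STD/SEM
#' (`NA`, flagged).
#'
#' @param values Numeric vector (n >= 1).
#' @return Object of class `population_summary`: list with `mean`, `SEM`,
#'   `STD`, `n`.
#' @export
#' @examples
#' summarize_population(c(1, 2, 3))
summarize_population <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("empty input")
  std <- if (n > 1L) sd(values) else NA_real_
  structure(list(mean = mean(values), SEM = std / sqrt(n), STD = std, n = n),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  if (is.na(x$STD)) {
    cat(sprintf("mean %.6g (single value; STD/SEM undefined)\n", x$mean))
  } else {
    r <- round_to_sem(x$mean, x$SEM)
    cat(sprintf("mean %s  SEM %s  STD %.3g  n %d\n", r$mean, r$SEM, x$STD, x$n))
  }
  invisible(x)
}

#' Round a mean (and its SEM) to the SEM's decimal place
#'
#' Reporting convention for population tables: the SEM is rounded to one
#' significant digit and the mean to the same decimal place.
#'
#' @param mean,SEM Numeric scalars.
#' @return List with character `mean` and `SEM` as printed, and numeric
#'   `digits` (decimal places used).
#' @export
#' @examples
#' round_to_sem(2.0381, 0.18 / sqrt(13874))  # "2.038", SEM "0.002"
round_to_sem <- function(mean, SEM) {
  if (is.na(SEM) || SEM <= 0) return(list(mean = format(mean), SEM = format(SEM), digits = NA))
  sem1 <- signif(SEM, 1)
  digits <- max(0L, -floor(log10(sem1) + 1e-9))
  list(mean = formatC(round(mean, digits), format = "f", digits = digits),
       SEM = formatC(sem1, format = "f", digits = digits),
       digits = digits)
}

#' Percentile gate from a control population
#'
#' Builds a one-dimensional gate at an empirical percentile of a control
#' population (linear interpolation between order statistics, the default
#' quantile convention), e.g. the 99th-centile positivity gate used to
#' split a stained population on a control sample.
#'
#' @param control Numeric control values (non-empty).
#' @param percentile Percentile in (0, 100].
#' @param side `"above"` (default): cells pass when value > threshold;
#'   `"below"`: pass when value < threshold.
#' @param channel Optional channel/parameter name for bookkeeping.
#' @return Object of class `gate1d`: list with `threshold`, `side`,
#'   `channel`, `percentile`.
#' @export
percentile_gate <- function(control, percentile = 99, side = c("above", "below"),
                            channel = NULL) {
  side <- match.arg(side)
  control <- control[!is.na(control)]
  if (length(control) == 0L) stop("empty control population")
  if (percentile <= 0 || percentile > 100) stop("`percentile` must be in (0, 100]")
  thr <- unname(quantile(control, percentile / 100, type = 7))
  structure(list(threshold = thr, side = side, channel = channel,
                 percentile = percentile),
            class = "gate1d")
}

#' @rdname percentile_gate
#' @param gate A `gate1d`.
#' @param values Values to gate.
#' @return `apply_gate` returns a logical vector (pass/fail).
#' @export
apply_gate <- function(gate, values) {
  stopifnot(inherits(gate, "gate1d"))
  if (gate$side == "above") values > gate$threshold else values < gate$threshold
}

#' @export
print.gate1d <- function(x, ...) {
  cat(sprintf("gate: %s %s %.6g (%gth centile of control)\n",
              if (is.null(x$channel)) "value" else x$channel,
              if (x$side == "above") ">" else "<", x$threshold, x$percentile))
  invisible(x)
}

## fraction of (x, y) in each closed/open quadrant around (x0, y0);
## partition: q1 x>x0,y>y0; q2 x<=x0,y>y0; q3 x<=x0,y<=y0; q4 x>x0,y<=y0
quadrant_fractions <- function(x, y, x0, y0) {
  gx <- outer(x, x0, ">")
  gy <- outer(y, y0, ">")
  rbind(colMeans(gx & gy), colMeans(!gx & gy),
        colMeans(!gx & !gy), colMeans(gx & !gy))
}

max_quadrant_diff <- function(x1, y1, x2, y2, x0, y0) {
  f1 <- quadrant_fractions(x1, y1, x0, y0)
  f2 <- quadrant_fractions(x2, y2, x0, y0)
  max(abs(f1 - f2))
}

## Kolmogorov asymptotic survival function Q_KS(lambda)
q_ks <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample two-dimensional Kolmogorov-Smirnov test
#'
#' Fasano-Franceschini quadrant variant: around every data point the
#' plane is split into four quadrants and the maximal difference between
#' the two samples' quadrant fractions is recorded; `D` is the average of
#' the two per-sample maxima. The asymptotic p-value uses the
#' Kolmogorov distribution with the Fasano-Franceschini correlation
#' correction `1 + sqrt(1 - r^2) (0.25 - 0.75/sqrt(n))`, where `r^2`
#' averages the two samples' squared Pearson correlations and
#' `n = n1 n2 / (n1 + n2)`. An exact permutation p-value is available for
#' small samples.
#'
#' @param a,b Two-column matrices (or data.frames) of 2D points, >= 10
#'   rows each.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of permutations when `p_method = "permutation"`.
#' @return List of class `ks2d_result`: `D` (averaged statistic), `D1`,
#'   `D2` (per-sample maxima), `p_value`, `n1`, `n2`, `p_method`.
#' @export
ks2d <- function(a, b, p_method = c("asymptotic", "permutation"),
                 n_perm = 1000) {
  p_method <- match.arg(p_method)
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 2L || ncol(b) != 2L) stop("samples must be 2D point sets")
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 10L || n2 < 10L) stop("each sample needs >= 10 points")

  stat <- function(a, b) {
    d1 <- max_quadrant_diff(a[, 1L], a[, 2L], b[, 1L], b[, 2L], a[, 1L], a[, 2L])
    d2 <- max_quadrant_diff(a[, 1L], a[, 2L], b[, 1L], b[, 2L], b[, 1L], b[, 2L])
    c(d1, d2)
  }
  d <- stat(a, b)
  D <- mean(d)

  if (p_method == "asymptotic") {
    neff <- n1 * n2 / (n1 + n2)
    r2 <- mean(c(safe_cor(a)^2, safe_cor(b)^2))
    lambda <- sqrt(neff) * D / (1 + sqrt(1 - r2) * (0.25 - 0.75 / sqrt(neff)))
    p <- q_ks(lambda)
  } else {
    pool <- rbind(a, b)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n1 + n2, n1)
      dp <- mean(stat(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE]))
      if (dp >= D) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(D = D, D1 = d[1L], D2 = d[2L], p_value = p,
                 n1 = n1, n2 = n2, p_method = p_method),
            class = "ks2d_result")
}

safe_cor <- function(m) {
  if (sd(m[, 1L]) == 0 || sd(m[, 2L]) == 0) return(0)
  cor(m[, 1L], m[, 2L])
}

#' @export
print.ks2d_result <- function(x, ...) {
  cat(sprintf("2D KS test: D = %.4g (D1 = %.4g, D2 = %.4g), p = %.3g (%s), n = %d/%d\n",
              x$D, x$D1, x$D2, x$p_value, x$p_method, x$n1, x$n2))
  invisible(x)
}
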