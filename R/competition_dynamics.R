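# Frequency-dependent selection analysis and growth-rate estimation.

#' Attach frequency changes to competition records
#'
#' Validates a table of competition outcomes and computes the wild-type
#' frequency change df = f72 - f0 over the competition window.  Frequencies
#' outside their admissible ranges are rejected.
#'
#' @param records data.frame with \code{f0} in (0, 1) and \code{f72} in
#'   \[0, 1\] (and optionally \code{condition}).
#' @return the records with a \code{df} column appended.
#' @export
frequencyChange <- function(records) {
  if (!is.data.frame(records) || !all(c("f0", "f72") %in% names(records)))
    stop("'records' must be a data.frame with f0 and f72", call. = FALSE)
  if (any(!is.finite(records$f0)) || any(records$f0 <= 0 | records$f0 >= 1))
    stop("invalid record: f0 must lie strictly in (0, 1)", call. = FALSE)
  if (any(!is.finite(records$f72)) || any(records$f72 < 0 | records$f72 > 1))
    stop("invalid record: f72 must lie in [0, 1]", call. = FALSE)
  records$df <- records$f72 - records$f0
  records
}

# Fit df on the basis {f0(1-f0), f0^2(1-f0)} and locate an interior
# positive-to-negative zero crossing of the fitted curve.
fitCrossing <- function(f0, df) {
  X <- cbind(b1 = f0 * (1 - f0), b2 = f0^2 * (1 - f0))
  beta <- stats::lm.fit(X, df)$coefficients
  grid <- seq(0.01, 0.99, by = 0.005)
  g <- grid * (1 - grid) * (beta[1] + beta[2] * grid)
  pos <- g > 0
  fc <- NA_real_
  cross <- which(pos[-length(pos)] & !pos[-1])
  if (length(cross) == 1L && !any(!pos[-length(pos)] & pos[-1])) {
    lo <- grid[cross]; hi <- grid[cross + 1L]
    fn <- function(f) beta[1] + beta[2] * f
    if (fn(lo) > 0 && fn(hi) <= 0)
      fc <- stats::uniroot(fn, c(lo, hi))$root
    else
      fc <- (lo + hi) / 2
  }
  regime <- if (all(pos)) "uniform_positive"
    else if (all(!pos)) "uniform_negative"
    else if (is.finite(fc)) "negative_freq_dependent"
    else "none"
  list(beta = unname(beta), fc = fc, regime = regime)
}

#' Fit a frequency-dependent selection function
#'
#' Least-squares fit of the frequency change df against the initial
#' frequency f0 on the basis \{f0(1-f0), f0^2(1-f0)\}, which forces df to
#' vanish at the absorbing states f0 = 0 and f0 = 1.  The fitted curve is
#' classified by its sign on a fine grid over (0, 1): positive everywhere
#' (uniform positive selection for the wild type), negative everywhere
#' (uniform negative), or a single positive-to-negative crossing (negative
#' frequency-dependent selection), whose location - the critical
#' coexistence frequency - is found by root bisection.  A percentile
#' bootstrap over records yields a confidence interval for the crossing.
#'
#' @param records competition records (see [frequencyChange()]; the
#'   \code{df} column is computed if absent).
#' @param nBoot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param level confidence level for the percentile interval.
#' @return a [SelectionFit-class].
#' @examples
#' rec <- sampleCompetition(seq(0.1, 0.9, length.out = 30),
#'                          a = 1, fc = 0.6, noiseSd = 0.03, seed = 7)
#' fitSelectionFunction(rec, seed = 7)
#' @export
fitSelectionFunction <- function(records, nBoot = 1000, seed = NULL,
                                 level = 0.95) {
  records <- frequencyChange(records)
  n <- nrow(records)
  if (n < 8L)
    stop("insufficient data: need at least 8 records", call. = FALSE)
  if (diff(range(records$f0)) < 0.5)
    stop("insufficient data: records must span an f0 range of width >= 0.5",
         call. = FALSE)
  fit <- fitCrossing(records$f0, records$df)
  boot <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      fitCrossing(records$f0[idx], records$df[idx])$fc
    }, numeric(1))
  })
  ok <- boot[is.finite(boot)]
  ci <- if (length(ok) >= nBoot / 2) {
    stats::quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  } else c(NA_real_, NA_real_)
  new("SelectionFit", regime = fit$regime, fcHat = fit$fc,
      coefficients = fit$beta, ci = ci, boot = boot, records = records)
}

#' Maximum growth rate from an OD600 time series
#'
#' The maximum over all contiguous windows of the least-squares slope of OD
#' against time, i.e. the maximum slope of the growth curve.  A logarithmic
#' mode (slope of log OD, the exponential rate) is available via
#' \code{logOd = TRUE}.
#'
#' @param t time points (strictly increasing).
#' @param od OD600 readings, same length as \code{t}.
#' @param window window size in points (default 5; 2 h at 30-minute
#'   sampling).
#' @param logOd fit the slope of log(od) instead of od.
#' @return the maximum windowed slope (OD, or log OD, per unit time).
#' @export
maxGrowthRate <- function(t, od, window = 5, logOd = FALSE) {
  if (length(t) != length(od))
    stop("'t' and 'od' must have equal length", call. = FALSE)
  if (window < 2L || length(t) < window)
    stop("need at least 'window' (>= 2) points", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("'t' must be strictly increasing", call. = FALSE)
  y <- if (logOd) log(od) else od
  n <- length(t)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- t[idx]; yy <- y[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  max(slopes)
}

#' Wild-type frequency from strain counts
#'
#' @param wtCount,mutCount non-negative counts (e.g. effluent colony
#'   counts); their sum must be positive.
#' @return wild-type frequency wtCount / (wtCount + mutCount).
#' @export
effluentFrequency <- function(wtCount, mutCount) {
  if (any(wtCount < 0) || any(mutCount < 0))
    stop("counts must be non-negative", call. = FALSE)
  tot <- wtCount + mutCount
  if (any(tot <= 0))
    stop("undefined frequency: both counts are zero", call. = FALSE)
  wtCount / tot
}

#' Plot a fitted selection function
#'
#' Scatter of df versus f0 with the fitted curve, the zero line, and the
#' diagonal bound df = 1 - f0 (the maximum possible increase in wild-type
#' frequency).
#'
#' @param fit a [SelectionFit-class].
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, the fit.
#' @export
plotSelection <- function(fit, ...) {
  stopifnot(is(fit, "SelectionFit"))
  rec <- fit@records
  graphics::plot(rec$f0, rec$df, xlab = "initial WT frequency f0",
                 ylab = expression(Delta * f), xlim = c(0, 1), ...)
  graphics::abline(h = 0, col = "grey50")
  graphics::curve(1 - x, from = 0, to = 1, add = TRUE, col = "grey70",
                  lty = 2)
  b <- fit@coefficients
  graphics::curve(x * (1 - x) * (b[1] + b[2] * x), from = 0, to = 1,
                  add = TRUE, col = "firebrick", lwd = 2)
  if (is.finite(fit@fcHat))
    graphics::abline(v = fit@fcHat, col = "firebrick", lty = 3)
  invisible(fit)
}
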