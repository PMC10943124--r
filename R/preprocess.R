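#' Zero-phase band-pass filter of a dense time series
#'
#' Each vertex row is filtered identically with the two-pass (zero-phase)
#' magnitude response of a Butterworth band-pass filter, applied in the
#' frequency domain:
#' \deqn{G(f) = \frac{1}{1 + \left(\frac{f^2 - f_0^2}{B f}\right)^{2n}}}
#' with geometric band center \eqn{f_0 = \sqrt{f_{low} f_{high}}}, bandwidth
#' \eqn{B = f_{high} - f_{low}} and order \eqn{n}.  `G(0) = 0`, so every
#' output row is exactly zero-mean, and the filter introduces no temporal
#' shift.  Defaults follow the conventional resting-state band
#' 0.01-0.10 Hz.
#'
#' @param ts a [dense_timeseries()] with at least 16 frames.
#' @param band_low,band_high pass-band edges in Hz; must satisfy
#'   `0 < band_low < band_high < 1/(2 tr)`.
#' @param order Butterworth order (default 4).
#' @return The filtered [dense_timeseries()] (mask and FD unchanged).
#' @export
bandpass <- function(ts, band_low = 0.01, band_high = 0.10, order = 4L) {
  stopifnot(inherits(ts, "dense_timeseries"))
  nt <- ncol(ts$data)
  if (nt < 16L) stop("band-pass requires at least 16 frames")
  nyq <- 1 / (2 * ts$tr)
  if (!(band_low > 0 && band_low < band_high && band_high < nyq))
    stop(sprintf("band [%g, %g] Hz invalid for tr = %gs (Nyquist %g Hz)",
                 band_low, band_high, ts$tr, nyq))
  f <- (seq_len(nt) - 1L) / (nt * ts$tr)
  f <- pmin(f, 1 / ts$tr - f)           # two-sided spectrum
  g <- butterworth_gain(f, band_low, band_high, order)
  xf <- stats::mvfft(t(ts$data))
  out <- t(Re(stats::mvfft(xf * g, inverse = TRUE)) / nt)
  ts$data <- out
  ts
}

# Two-pass Butterworth band-pass power gain at frequencies f (Hz).
butterworth_gain <- function(f, band_low, band_high, order) {
  f0sq <- band_low * band_high
  bw <- band_high - band_low
  g <- numeric(length(f))
  nz <- f > 0
  x <- (f[nz]^2 - f0sq) / (bw * f[nz])
  g[nz] <- 1 / (1 + x^(2 * order))
  g
}

#' Censor high-motion frames and flag high-motion subjects
#'
#' Clears the frame mask wherever FD exceeds `fd_threshold` (default
#' 0.5 mm).  If the retained fraction of frames falls below
#' `min_retained_fraction` (default 0.5) the subject is flagged
#' `excluded = TRUE` and must not contribute maps downstream; exclusion is
#' a value, not an error.
#'
#' @param ts a [dense_timeseries()] with an FD trace.
#' @param fd_threshold FD censoring threshold in mm.
#' @param min_retained_fraction minimum retained fraction in (0, 1].
#' @return The [dense_timeseries()] with an updated `frame_mask`,
#'   `excluded` flag and a `retained_fraction` attribute.
#' @export
censor_high_motion <- function(ts, fd_threshold = 0.5,
                               min_retained_fraction = 0.5) {
  stopifnot(inherits(ts, "dense_timeseries"))
  keep <- ts$fd <= fd_threshold
  ts$frame_mask <- ts$frame_mask & keep
  frac <- mean(ts$frame_mask)
  ts$excluded <- frac < min_retained_fraction
  attr(ts, "retained_fraction") <- frac
  ts
}

#' Remove covariate effects from a per-subject measure
#'
#' Regresses the supplied covariates (typically mean FD, age, sex, race,
#' site/scanner) out of a per-subject vector by ordinary least squares and
#' returns the residuals re-centered on the grand mean.  Categorical
#' covariates are one-hot encoded dropping one level; covariates with a
#' single unique value are ignored (nothing to remove).  Residuals are
#' orthogonal to every retained covariate column.
#'
#' @param values numeric per-subject vector.
#' @param covariates data.frame of covariates, one row per subject.
#' @return Numeric vector: residuals plus the grand mean of `values`.
#' @export
residualize_group <- function(values, covariates) {
  values <- as.numeric(values)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values))
    stop("'covariates' must have one row per subject")
  keep <- vapply(covariates, function(col) length(unique(col)) > 1L,
                 logical(1L))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L) return(values)
  for (j in seq_along(covariates))
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  X <- stats::model.matrix(~ ., data = covariates)
  if (nrow(X) < ncol(X) + 2L)
    stop("need at least 2 more subjects than covariate columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    collinear <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(collinear, collapse = ", ")))
  }
  stats::lm.fit(X, values)$residuals + mean(values)
}

#' Grand-mean scaling by stratum
#'
#' Multiplies each subject's value by `grand mean / stratum mean`, so that
#' every stratum's mean equals the grand mean afterwards.  Used to remove
#' sex and race effects from gFCD before the handedness index.
#'
#' @param values numeric per-subject vector (positive-mean measure).
#' @param strata subgroup labels (factor/character), e.g. sex x race cells.
#' @return Scaled numeric vector.
#' @export
grand_mean_scale <- function(values, strata) {
  values <- as.numeric(values)
  strata <- factor(strata)
  if (length(strata) != length(values))
    stop("'strata' must have one label per subject")
  if (any(tabulate(strata, nlevels(strata)) == 0L))
    strata <- droplevels(strata)
  gm <- mean(values)
  sm <- tapply(values, strata, mean)
  if (any(sm <= 0))
    stop("grand-mean scaling undefined: a stratum mean is <= 0")
  values * as.vector(gm / sm)[as.integer(strata)]
}
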