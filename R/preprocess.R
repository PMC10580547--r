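# Signal conditioning: Butterworth band-pass per axis, mean removal, resultant
# magnitude. No trimming anywhere: output lengths equal input lengths.

#' Design a digital Butterworth band-pass filter
#'
#' Classic pole-placement design: analog low-pass prototype, low-pass to
#' band-pass transform, bilinear transform with frequency pre-warping. Returns
#' transfer-function coefficients usable with [bandpass_filter()].
#'
#' @param order Prototype filter order (the band-pass filter has `2 * order`
#'   poles). Default 5.
#' @param low,high Band edges in Hz. Defaults 1 and 16, the tremor-relevant
#'   band for hand/forearm recordings.
#' @param fs Sampling frequency in Hz.
#' @return A list with numerator `b` and denominator `a` polynomial
#'   coefficients (in decreasing powers of z).
#' @examples
#' bf <- butter_bandpass(5, 1, 16, fs = 50)
#' length(bf$a)  # 11 coefficients: 10 poles
#' @export
butter_bandpass <- function(order = 5, low = 1, high = 16, fs = 50) {
  stopifnot(order >= 1, low > 0, high > low)
  if (fs <= 2 * high) {
    stop("sampling frequency must exceed twice the upper band edge (", high,
         " Hz); got fs = ", fs)
  }
  # pre-warped analog edge frequencies (rad/s)
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog low-pass prototype: order poles on the unit circle, left half-plane
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each pole splits in two; order zeros at s = 0
  p_s <- p_lp * bw / 2
  p_bp <- c(p_s + sqrt(p_s^2 - w0^2), p_s - sqrt(p_s^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  k_bp <- bw^order
  # bilinear transform s -> 2 fs (z-1)/(z+1)
  fs2 <- 2 * fs
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- c((fs2 + z_bp) / (fs2 - z_bp), rep(-1 + 0i, length(p_bp) - length(z_bp)))
  k_z <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(z_z)) * k_z
  a <- Re(poly_from_roots(p_z))
  list(b = b, a = a, order = order, low = low, high = high, fs = fs)
}

# polynomial coefficients (decreasing powers) from complex roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  p
}

#' Band-pass filter a series
#'
#' Applies the 1--16 Hz 5th-order Butterworth filter (or a custom design).
#' Default mode is zero-phase: the filter runs forward and backward so the
#' waveform is not delayed, at the cost of squaring the magnitude response.
#' Odd (antisymmetric) end extensions suppress edge transients.
#'
#' @param x Numeric series.
#' @param fs Sampling frequency in Hz.
#' @param low,high,order Filter design parameters, see [butter_bandpass()].
#' @param zero_phase Forward-backward filtering (default `TRUE`); set `FALSE`
#'   for a single causal pass.
#' @return Filtered series, same length as `x`.
#' @examples
#' t <- seq(0, 10, by = 1 / 50)
#' y <- bandpass_filter(sin(2 * pi * 5 * t), fs = 50)
#' @export
bandpass_filter <- function(x, fs, low = 1, high = 16, order = 5,
                            zero_phase = TRUE) {
  des <- butter_bandpass(order, low, high, fs)
  nf <- length(des$a) - 1
  pad <- 3 * nf
  if (length(x) <= pad) {
    stop("series too short for the filter warm-up (need > ", pad, " samples)")
  }
  if (!zero_phase) {
    return(.iir_filter_cpp(des$b, des$a, x))
  }
  n <- length(x)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- .iir_filter_cpp(des$b, des$a, ext)
  y <- rev(.iir_filter_cpp(des$b, des$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Remove the mean of a series
#'
#' @param x Non-empty numeric series.
#' @return `x - mean(x)`.
#' @export
remove_mean <- function(x) {
  if (length(x) == 0) stop("empty series")
  x - mean(x)
}

#' Resultant magnitude of a 3-axis trial
#'
#' Collapses the three orthogonal axes of one sensor into a single orientation-
#' free series, `sqrt(sx^2 + sy^2 + sz^2)` at every sample.
#'
#' @param sx,sy,sz Equal-length numeric series, one per axis.
#' @return Non-negative series of the same length.
#' @examples
#' resultant_magnitude(3, 4, 0)  # 5
#' @export
resultant_magnitude <- function(sx, sy, sz) {
  if (length(sy) != length(sx) || length(sz) != length(sx)) {
    stop("axis series must have equal length")
  }
  sqrt(sx^2 + sy^2 + sz^2)
}

#' Preprocess one 3-axis trial into its resultant signal
#'
#' Per axis: band-pass filter (1--16 Hz, 5th-order Butterworth, zero-phase),
#' then mean removal; finally the resultant magnitude of the three processed
#' axes. The resultant itself is not re-detrended by default -- its mean is a
#' legitimate amplitude property -- but `detrend_resultant = TRUE` is available
#' for sensitivity analyses.
#'
#' @param trial Numeric matrix with 3 columns (x, y, z axes).
#' @param fs Sampling frequency in Hz.
#' @param low,high,order,zero_phase Passed to [bandpass_filter()].
#' @param detrend_resultant Also remove the mean of the resultant.
#' @return The resultant series (length `nrow(trial)`).
#' @export
preprocess_trial <- function(trial, fs, low = 1, high = 16, order = 5,
                             zero_phase = TRUE, detrend_resultant = FALSE) {
  stopifnot(is.matrix(trial), ncol(trial) == 3)
  ax <- lapply(1:3, function(j) {
    remove_mean(bandpass_filter(trial[, j], fs, low, high, order, zero_phase))
  })
  r <- resultant_magnitude(ax[[1]], ax[[2]], ax[[3]])
  if (detrend_resultant) r <- remove_mean(r)
  r
}
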