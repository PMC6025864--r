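#' Butterworth low-pass filter coefficients
#'
#' Designs a digital Butterworth low-pass filter by placing the analog
#' prototype poles on the Butterworth circle, pre-warping the cutoff and
#' applying the bilinear transform. The DC gain is normalized to 1.
#'
#' No pre-installed R package in this stack provides IIR filter design, so
#' the design is done here; its gain properties (DC, passband, -3 dB point
#' per pass, stopband) are asserted in the test suite.
#'
#' @param order filter order (4 is used throughout the pipeline).
#' @param cutoff cutoff frequency in Hz (-3 dB point of a single pass).
#' @param rate sampling rate in Hz; must exceed `2 * cutoff`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(order, cutoff, rate) {
  if (!(rate > 2 * cutoff)) {
    stop("filter-config error: sampling rate (", rate,
         " Hz) must exceed twice the cutoff (", cutoff, " Hz)")
  }
  if (order < 1) stop("filter-config error: order must be >= 1")
  wc <- 2 * rate * tan(pi * cutoff / rate)  # pre-warped analog cutoff
  k <- seq_len(order)
  p_analog <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * rate
  p_z <- (fs2 + p_analog) / (fs2 - p_analog)
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))  # zeros at Nyquist
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

# expand prod (x - r_i) into polynomial coefficients, highest degree first
poly_from_roots <- function(r) {
  coef <- 1
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

# causal direct-form IIR filter with zero initial conditions, built on
# stats::filter (C speed): FIR part by one-sided convolution, AR part by
# recursion.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  if (nb > 1) {
    xx <- c(rep(0, nb - 1), x)
    v <- stats::filter(xx, b, method = "convolution", sides = 1)
    v <- v[-seq_len(nb - 1)]
  } else {
    v <- b * x
  }
  if (length(a) > 1) {
    v <- stats::filter(v, -a[-1], method = "recursive")
  }
  as.numeric(v)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forward and backward so the net phase response is
#' zero; the magnitude response is applied twice. Edges are handled by
#' odd-reflection padding so that startup transients decay outside the
#' returned segment.
#'
#' @param b,a filter coefficients, e.g. from [butter_lowpass()].
#' @param x numeric vector.
#' @param padlen reflection pad length; defaults to a multiple of the
#'   filter's dominant time constant, capped at `length(x) - 1`.
#' @return filtered vector of the same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (n < 2) return(x)
  if (is.null(padlen)) {
    padlen <- 10 * max(length(a), length(b))
    # low cutoffs leave long transients; the pole closest to the unit
    # circle sets the decay scale
    r <- suppressWarnings(max(Mod(polyroot(rev(a / a[1])))))
    if (is.finite(r) && r < 1 && r > 0) {
      padlen <- max(padlen, ceiling(-25 / log(r)))
    }
    padlen <- min(n - 1, padlen)
  }
  padlen <- min(padlen, n - 1)
  front <- 2 * x[1] - x[(padlen + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- iir_filter(b, a, c(front, x, back))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}
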