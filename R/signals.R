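#' Uniformly sampled multichannel signal
#'
#' Lightweight container for uniformly sampled data such as triaxial
#' acceleration (channels `x` = anterior-posterior, `y` = mediolateral,
#' `z` = vertical, in g) or smoothed heart rate.
#'
#' @param data numeric matrix, one column per channel.
#' @param rate sampling rate in Hz.
#' @param start time of the first sample in seconds from session start.
#' @param labels channel names; defaults to existing column names.
#' @return an object of class `uniform_signal`.
#' @export
uniform_signal <- function(data, rate, start = 0, labels = colnames(data)) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("signal data must be numeric")
  if (!(rate > 0)) stop("sampling rate must be > 0")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(data)))
  colnames(data) <- labels
  structure(list(rate = rate, start = start, data = data),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples x %d channels [%s] @ %g Hz, t0 = %g s\n",
              nrow(x$data), ncol(x$data),
              paste(colnames(x$data), collapse = ","), x$rate, x$start))
  invisible(x)
}

# sample times of a uniform_signal
signal_times <- function(sig) {
  sig$start + (seq_len(nrow(sig$data)) - 1) / sig$rate
}

# row indices with sample time in [from, to]
signal_window_idx <- function(sig, from, to) {
  i0 <- ceiling((from - sig$start) * sig$rate) + 1
  i1 <- floor((to - sig$start) * sig$rate) + 1
  i0 <- max(1L, i0)
  i1 <- min(nrow(sig$data), i1)
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}

#' Decimate a signal to a lower sampling rate
#'
#' Anti-alias low-pass filtering (4th-order Butterworth, zero phase, cutoff
#' `0.4 * target_rate`) followed by keeping every k-th sample. The target
#' rate must divide the native rate.
#'
#' @param sig a [uniform_signal()].
#' @param target_rate desired rate in Hz.
#' @return decimated `uniform_signal`.
#' @export
decimate_signal <- function(sig, target_rate) {
  if (target_rate == sig$rate) return(sig)
  k <- sig$rate / target_rate
  if (abs(k - round(k)) > 1e-9) {
    stop("target rate ", target_rate, " Hz must divide the native rate ",
         sig$rate, " Hz")
  }
  k <- as.integer(round(k))
  ba <- butter_lowpass(4, 0.4 * target_rate, sig$rate)
  keep <- seq.int(1L, nrow(sig$data), by = k)
  out <- apply(sig$data, 2, function(ch) filtfilt(ba$b, ba$a, ch)[keep])
  uniform_signal(out, rate = target_rate, start = sig$start,
                 labels = colnames(sig$data))
}
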