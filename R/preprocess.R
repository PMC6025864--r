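#' Measured VO2max from a breath series
#'
#' The maximum over all 30-second windows of the mean VO2 inside the window.
#' Windows are time-based (breath sampling is irregular) and advanced sample
#' by sample, each window starting at a breath timestamp.
#'
#' @param breath data.frame with columns `t` (s, strictly increasing) and
#'   `vo2` (ml/kg/min).
#' @param window window length in seconds.
#' @return VO2max in ml/kg/min.
#' @export
compute_vo2max <- function(breath, window = 30) {
  tt <- breath$t
  v <- breath$vo2
  n <- length(tt)
  if (n < 1 || (tt[n] - tt[1]) < window) {
    stop("insufficient-data: breath series must span at least ", window, " s")
  }
  if (any(diff(tt) <= 0)) stop("breath timestamps must be strictly increasing")
  cs <- c(0, cumsum(v))
  best <- -Inf
  j <- 1L
  for (i in seq_len(n)) {
    hi <- tt[i] + window
    if (hi > tt[n]) break
    if (j < i) j <- i
    while (j < n && tt[j + 1] <= hi) j <- j + 1L
    m <- (cs[j + 1] - cs[i]) / (j - i + 1)
    if (m > best) best <- m
  }
  best
}

#' Smoothed heart-rate signal
#'
#' Breath-by-breath heart rate is averaged in consecutive 10-second bins
#' (anchored at the first breath timestamp), then smoothed with a 7-point
#' running median. At the edges the median window shrinks to the available
#' neighbours rather than padding. An empty bin is an error, not silently
#' interpolated.
#'
#' @param breath data.frame with columns `t` and `hr`.
#' @param bin bin width in seconds.
#' @return a [uniform_signal()] at `1/bin` Hz whose sample times are the bin
#'   centres.
#' @export
smooth_heart_rate <- function(breath, bin = 10) {
  if (nrow(breath) == 0) stop("insufficient-data: empty breath series")
  t0 <- breath$t[1]
  idx <- floor((breath$t - t0) / bin) + 1L
  nb <- max(idx)
  counts <- tabulate(idx, nb)
  if (any(counts == 0)) {
    k <- which(counts == 0)[1]
    stop(sprintf("gap error: no heart-rate samples in 10 s bin %d [%g, %g) s",
                 k, t0 + (k - 1) * bin, t0 + k * bin))
  }
  means <- as.numeric(rowsum(breath$hr, idx)) / counts
  sm <- running_median(means, half = 3)
  uniform_signal(matrix(sm, ncol = 1), rate = 1 / bin, start = t0 + bin / 2,
                 labels = "hr")
}

# running median with shrunken windows at the boundaries
running_median <- function(x, half = 3) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Low-pass filter an acceleration signal
#'
#' 4th-order Butterworth applied zero-phase (forward-backward) to every
#' channel; length is preserved. The cutoff defaults to 50 Hz, high enough
#' to keep the characteristics of running.
#'
#' @param sig a [uniform_signal()].
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order per pass.
#' @return filtered `uniform_signal`.
#' @export
lowpass_accel <- function(sig, cutoff = 50, order = 4) {
  ba <- butter_lowpass(order, cutoff, sig$rate)
  out <- sig
  for (j in seq_len(ncol(sig$data))) {
    out$data[, j] <- filtfilt(ba$b, ba$a, sig$data[, j])
  }
  out
}

#' Moe-Nilssen tilt correction
#'
#' Estimates sensor orientation from the whole-trial mean acceleration
#' vector (the stationary-mean assumption: over a long trial the mean is
#' gravity), rotates the axes so that this vector maps onto the vertical,
#' and subtracts the gravity magnitude from the vertical channel. After
#' correction the vertical channel has zero mean and the horizontal
#' channels have zero mean; the per-sample vector norm is preserved by the
#' rotation (before the gravity subtraction).
#'
#' @param sig a [uniform_signal()] with 3 channels (x, y, z) in g.
#' @return corrected `uniform_signal`.
#' @export
tilt_correct <- function(sig) {
  if (ncol(sig$data) != 3) stop("tilt correction needs 3 channels (x, y, z)")
  m <- colMeans(sig$data)
  g <- sqrt(sum(m^2))
  if (g < 0.5) {
    stop("implausible-orientation: mean acceleration norm ",
         format(g, digits = 3), " g is below 0.5 g")
  }
  u <- m / g
  R <- rotation_to_vertical(u)
  out <- sig
  out$data <- sig$data %*% t(R)
  out$data[, 3] <- out$data[, 3] - g
  colnames(out$data) <- c("x", "y", "z")
  out
}

# shortest rotation mapping unit vector u onto (0, 0, 1) (Rodrigues)
rotation_to_vertical <- function(u) {
  e3 <- c(0, 0, 1)
  c_ <- sum(u * e3)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # upside down: flip y, z
  v <- c(u[2] * e3[3] - u[3] * e3[2],
         u[3] * e3[1] - u[1] * e3[3],
         u[1] * e3[2] - u[2] * e3[1])
  s <- sqrt(sum(v^2))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Check the VO2max attainment criteria
#'
#' A test counts as a true maximal effort when at least two of four criteria
#' hold: (1) a VO2 plateau, i.e. an increase of less than 1.5 ml/kg/min
#' between the last two completed stages; (2) respiratory exchange ratio
#' above 1.15 (supplied as an external flag, since RER is measured by the
#' gas analyzer); (3) maximal heart rate above 95% of the age-predicted
#' maximum (220 - age); (4) a rating of perceived exertion of at least 19.
#'
#' @param breath data.frame with `t`, `vo2`, `hr`.
#' @param stages stage-window data.frame (`index`, `start`, `end`).
#' @param age subject age in years.
#' @param rpe_per_stage numeric vector of Borg 6-20 ratings, or `NULL`.
#' @param rer_above_115 logical flag from the metabolic cart, or `NA` when
#'   not available (criterion reported as not evaluable).
#' @return list with per-criterion logicals and `attained`.
#' @export
check_vo2max_attainment <- function(breath, stages, age,
                                    rpe_per_stage = NULL,
                                    rer_above_115 = NA) {
  if (nrow(stages) < 2) {
    stop("insufficient-data: need at least 2 completed stages")
  }
  stage_means <- vapply(seq_len(nrow(stages)), function(i) {
    sel <- breath$t >= stages$start[i] & breath$t <= stages$end[i]
    if (!any(sel)) NA_real_ else mean(breath$vo2[sel])
  }, numeric(1))
  if (any(is.na(stage_means))) {
    stop("insufficient-data: a stage has no breath samples")
  }
  k <- length(stage_means)
  plateau <- (stage_means[k] - stage_means[k - 1]) < 1.5
  hr_crit <- max(breath$hr) > 0.95 * (220 - age)
  rpe_crit <- if (is.null(rpe_per_stage)) FALSE else max(rpe_per_stage) >= 19
  crits <- c(plateau = plateau, rer = isTRUE(rer_above_115),
             hr = hr_crit, rpe = rpe_crit)
  list(plateau = plateau,
       rer = if (is.na(rer_above_115)) NA else isTRUE(rer_above_115),
       rer_evaluable = !is.na(rer_above_115),
       hr = hr_crit,
       rpe = rpe_crit,
       n_met = sum(crits),
       attained = sum(crits) >= 2)
}

#' Preprocess a raw session
#'
#' Applies the full measurement pipeline: 50 Hz zero-phase low-pass and tilt
#' correction on every accelerometer, 10 s binning plus 7-point median
#' smoothing of heart rate, and the 30 s rolling-mean VO2max label.
#'
#' @param session a `vo2_session` with raw signals.
#' @param accel_cutoff low-pass cutoff, Hz.
#' @return the session with corrected `accel`, an `hr_smooth` signal and
#'   `vo2max_measured` filled in; marked `preprocessed`.
#' @export
preprocess_session <- function(session, accel_cutoff = 50) {
  if (is.null(session$breath) || is.null(session$accel)) {
    stop("session has no raw signals; generate with signals = TRUE")
  }
  out <- session
  out$accel <- lapply(session$accel, function(sig) {
    tilt_correct(lowpass_accel(sig, cutoff = accel_cutoff))
  })
  out$hr_smooth <- smooth_heart_rate(session$breath)
  out$vo2max_measured <- compute_vo2max(session$breath)
  out$preprocessed <- TRUE
  out
}
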