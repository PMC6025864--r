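#' Detect foot-ground contacts from vertical lower-back acceleration
#'
#' Implements zero-crossing contact detection on the centre-of-mass
#' vertical acceleration: the tilt-corrected signal (gravity removed) is
#' smoothed with a 4th-order Butterworth low-pass at 15 Hz applied zero
#' phase, and a contact starts at a negative-to-positive zero crossing and
#' ends at the next positive-to-negative crossing (stance is the
#' positive-acceleration phase; flight sits near -1 g). Crossing times are
#' linearly interpolated between samples, and events outside the
#' physiological running range [0.1, 0.5] s are discarded.
#'
#' @param vertical_bl a [uniform_signal()] (single channel used: `z` if
#'   present, else the first) or a numeric vector with attribute-free
#'   samples at `rate`.
#' @param cutoff smoothing cutoff, Hz.
#' @param dur_range admissible contact durations, s.
#' @return data.frame with `start`, `end`, `duration` (s), one row per
#'   contact.
#' @export
detect_contacts <- function(vertical_bl, cutoff = 15,
                            dur_range = c(0.1, 0.5)) {
  sig <- vertical_bl
  x <- if ("z" %in% colnames(sig$data)) sig$data[, "z"] else sig$data[, 1]
  ba <- butter_lowpass(4, cutoff, sig$rate)
  sm <- filtfilt(ba$b, ba$a, x)
  sgn <- sign(sm)
  # treat exact zeros as belonging to the previous sign regime
  nz <- which(sgn != 0)
  if (length(nz) == 0 || all(sgn[nz] == sgn[nz[1]])) {
    stop("no-gait-detected: signal has no zero crossings")
  }
  idx <- which(sm[-1] * sm[-length(sm)] < 0)
  tcross <- sig$start + (idx - 1) / sig$rate +
    (0 - sm[idx]) / (sm[idx + 1] - sm[idx]) / sig$rate
  rising <- sm[idx] < 0
  up <- tcross[rising]
  dn <- tcross[!rising]
  if (length(up) == 0 || length(dn) == 0) {
    stop("no-gait-detected: signal has no zero crossings")
  }
  # pair each upward crossing with the next downward crossing
  j <- findInterval(up, dn) + 1
  ok <- j <= length(dn)
  events <- data.frame(start = up[ok], end = dn[j[ok]])
  events$duration <- events$end - events$start
  events <- events[events$duration >= dur_range[1] &
                     events$duration <= dur_range[2], ]
  rownames(events) <- NULL
  events
}

#' Average contact time within a stage
#'
#' Mean duration of the contacts whose start lies inside the stage window
#' (the complete stage is used, not a sub-interval).
#'
#' @param events data.frame from [detect_contacts()].
#' @param w stage window with `start` and `end`.
#' @param min_events minimum number of contacts required.
#' @return contact time in seconds.
#' @export
stage_contact_time <- function(events, w, min_events = 5) {
  sel <- events$start >= w$start & events$start < w$end
  if (sum(sel) < min_events) {
    stop("insufficient-steps: only ", sum(sel), " contacts in stage window [",
         w$start, ", ", w$end, ") s")
  }
  mean(events$duration[sel])
}

#' Contact-time / heart-rate ratio feature
#'
#' For stages 1-3 (the warm-up is omitted: the comparison protocol has no
#' warm-up), computes the stage contact time tc_i from the vertical
#' lower-back acceleration, the last-minute average heart rate HR_i, and the
#' ratio (1/tc_i)/HR_i; the feature value is the mean of the three ratios.
#'
#' @param session a preprocessed `vo2_session`.
#' @return list with `per_stage` (data.frame of tc, HR, ratio for stages
#'   1-3) and `value` (mean ratio, 1/(s.bpm)).
#' @export
weyand_ratio <- function(session) {
  if (!isTRUE(session$preprocessed)) session <- preprocess_session(session)
  events <- detect_contacts(session$accel$bl)
  hrf <- hr_stage_features(session$hr_smooth, session$stages)
  per <- lapply(1:3, function(i) {
    w <- session$stages[session$stages$index == i, ]
    if (nrow(w) != 1) stop("missing-feature: stage ", i, " absent")
    tc <- stage_contact_time(events, w)
    hr <- hrf[[paste0("HR_", i)]]
    if (is.na(hr)) stop("missing-feature: HR of stage ", i, " unavailable")
    data.frame(stage = i, tc = tc, hr = hr, ratio = (1 / tc) / hr)
  })
  per <- do.call(rbind, per)
  list(per_stage = per, value = mean(per$ratio))
}
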