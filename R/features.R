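#' The 490-name candidate feature registry
#'
#' Canonical column order of the candidate feature catalogue: 2 descriptive
#' features (`G`, `BM`), 8 heart-rate features (stage averages and their
#' inverses, stages 0-3 where stage 0 is the warm-up) and 480 accelerometer
#' features: 5 statistics (AVG, SD, VAR, RMS, P) x 3 locations (`t` tibia,
#' `bl` lower back, `bu` upper back) x 4 directions (`x`, `y`, `z`,
#' `total`) x 4 stages, each with its inverse adjacent.
#'
#' @return character vector of length 490.
#' @export
feature_registry <- function() {
  hr <- as.vector(t(outer(paste0("HR_", 0:3), c("", "_inv"), paste0)))
  acc <- character(0)
  for (stat in c("AVG", "SD", "VAR", "RMS", "P")) {
    for (l in c("t", "bl", "bu")) {
      for (d in c("x", "y", "z", "total")) {
        for (i in 0:3) {
          nm <- paste(stat, l, d, i, sep = "_")
          acc <- c(acc, nm, paste0(nm, "_inv"))
        }
      }
    }
  }
  c("G", "BM", hr, acc)
}

#' Candidate pools for the four feature-set combinations
#'
#' `F1` uses the descriptive base only (no selection); `F2` adds the 8
#' heart-rate candidates; `F3` adds the 480 accelerometer candidates; `F4`
#' adds both (488 candidates).
#'
#' @param combination one of `"F1"`, `"F2"`, `"F3"`, `"F4"`.
#' @return character vector of candidate feature names (possibly empty).
#' @export
combination_candidates <- function(combination = c("F1", "F2", "F3", "F4")) {
  combination <- match.arg(combination)
  reg <- feature_registry()
  hr <- reg[startsWith(reg, "HR_")]
  acc <- setdiff(reg, c("G", "BM", hr))
  switch(combination,
         F1 = character(0),
         F2 = hr,
         F3 = acc,
         F4 = c(hr, acc))
}

#' Trim a stage window for feature extraction
#'
#' The treadmill accelerates and decelerates at stage boundaries, so the
#' first and last ten seconds of each stage are discarded.
#'
#' @param w list or one-row data.frame with `start` and `end` (s).
#' @param trim seconds discarded at each end.
#' @return c(start, end) of the analysis window.
#' @export
trim_stage_window <- function(w, trim = 10) {
  if ((w$end - w$start) <= 2 * trim) {
    stop("degenerate-window error: stage of ", w$end - w$start,
         " s leaves no analysis window after trimming ", trim, " s per side")
  }
  c(w$start + trim, w$end - trim)
}

#' Heart-rate stage features
#'
#' For stages 0-3, the average of the smoothed heart rate over the last
#' minute of the stage (the heart rate drops during rests, so the last
#' minute is where it is stable), plus the inverse of each average:
#' 8 features. A stage whose last-minute window is covered by fewer than
#' half the expected smoothed samples yields `NA` (missing-feature flag).
#'
#' @param hr a [uniform_signal()] from [smooth_heart_rate()].
#' @param stages stage-window data.frame.
#' @return named numeric vector of 8 values.
#' @export
hr_stage_features <- function(hr, stages) {
  out <- numeric(0)
  for (i in 0:3) {
    w <- stages[stages$index == i, ]
    val <- NA_real_
    if (nrow(w) == 1) {
      idx <- signal_window_idx(hr, w$end - 60, w$end)
      expected <- 60 * hr$rate
      if (length(idx) >= expected / 2) val <- mean(hr$data[idx, 1])
    }
    out <- c(out, val, inv_guard(val))
    names(out)[length(out) - 1:0] <- c(paste0("HR_", i),
                                       paste0("HR_", i, "_inv"))
  }
  out
}

# inverse with an epsilon guard: near-zero base values flag the inverse as
# missing instead of producing infinities
inv_guard <- function(x, eps = 1e-9) {
  ifelse(is.na(x) | abs(x) < eps, NA_real_, 1 / x)
}

#' Accelerometer stage features
#'
#' Per trimmed stage window (stages 0-3), per location (`t`, `bl`, `bu`) and
#' per direction (x, y, z and the per-sample total \eqn{\sqrt{x^2+y^2+z^2}}):
#' the average, sample standard deviation (n-1 denominator), variance
#' (= SD^2), root mean square and power (mean of squares, = RMS^2), plus the
#' inverse of each: 5 x 2 x 4 x 3 x 4 = 480 values. Signals are expected to
#' be low-passed and tilt-corrected.
#'
#' @param accel named list of [uniform_signal()]s for locations `t`, `bl`,
#'   `bu`.
#' @param stages stage-window data.frame.
#' @return named numeric vector of 480 values in registry order.
#' @export
accel_stage_features <- function(accel, stages) {
  vals <- new.env(parent = emptyenv())
  for (l in c("t", "bl", "bu")) {
    sig <- accel[[l]]
    for (i in 0:3) {
      w <- stages[stages$index == i, ]
      ok <- nrow(w) == 1 && !is.null(sig)
      idx <- if (ok) {
        tw <- trim_stage_window(w)
        signal_window_idx(sig, tw[1], tw[2])
      } else integer(0)
      for (d in c("x", "y", "z", "total")) {
        if (length(idx) < 2) {
          stats5 <- rep(NA_real_, 5)
        } else {
          ch <- if (d == "total") {
            sqrt(rowSums(sig$data[idx, , drop = FALSE]^2))
          } else {
            sig$data[idx, d]
          }
          m <- mean(ch)
          rms <- sqrt(mean(ch^2))
          sdv <- stats::sd(ch)
          # VAR and P are derived from SD and RMS (same accumulation), so
          # VAR == SD^2 and P == RMS^2 hold exactly
          stats5 <- c(AVG = m, SD = sdv, VAR = sdv^2, RMS = rms,
                      P = rms^2)
        }
        for (k in seq_along(stats5)) {
          stat <- c("AVG", "SD", "VAR", "RMS", "P")[k]
          nm <- paste(stat, l, d, i, sep = "_")
          assign(nm, stats5[[k]], envir = vals)
          assign(paste0(nm, "_inv"), inv_guard(stats5[[k]]), envir = vals)
        }
      }
    }
  }
  reg <- feature_registry()
  acc_names <- reg[-(1:10)]
  out <- vapply(acc_names, function(nm) get(nm, envir = vals), numeric(1))
  names(out) <- acc_names
  out
}

#' Full feature vector of one session
#'
#' @param session a preprocessed `vo2_session`.
#' @return named numeric vector of 490 candidate features.
#' @export
session_features <- function(session) {
  if (!isTRUE(session$preprocessed)) session <- preprocess_session(session)
  c(G = session$subject$gender,
    BM = session$subject$body_mass,
    hr_stage_features(session$hr_smooth, session$stages),
    accel_stage_features(session$accel, session$stages))
}

#' Assemble the candidate feature table of a cohort
#'
#' One row per session: grouping keys (`subject_id`, `test_label`,
#' `session_id`), the measured VO2max outcome (`vo2max`) and the 490
#' candidate features in canonical registry order. Sessions may be raw
#' (preprocessing is applied), preprocessed, or signal-free stubs (whose
#' analytic feature values come from the planted truth).
#'
#' @param sessions list of `vo2_session` objects.
#' @return data.frame of class `vo2_feature_table`.
#' @export
assemble_feature_table <- function(sessions) {
  if (length(sessions) < 2) stop("need at least 2 sessions")
  reg <- feature_registry()
  rows <- lapply(sessions, function(s) {
    fv <- if (is.null(s$accel)) stub_features(s) else session_features(s)
    if (!identical(names(fv), reg)) {
      stop("schema error: feature columns of session ", session_id(s),
           " do not match the registry")
    }
    y <- if (!is.null(s$vo2max_measured)) s$vo2max_measured else
      compute_vo2max(s$breath)
    cbind(data.frame(subject_id = s$subject$subject_id,
                     test_label = s$subject$test_label,
                     session_id = session_id(s),
                     vo2max = y),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vo2_feature_table", "data.frame")
  out
}

# analytic features of a signal-free stub: the planted links fill the
# warm-up heart-rate and tibia-variance columns; everything else is flagged
# missing. Used by fast simulation studies at the feature level.
stub_features <- function(s) {
  reg <- feature_registry()
  fv <- rep(NA_real_, length(reg))
  names(fv) <- reg
  fv["G"] <- s$subject$gender
  fv["BM"] <- s$subject$body_mass
  hrss <- s$truth$hrss_stage[1:4]
  for (i in 0:3) {
    fv[paste0("HR_", i)] <- hrss[i + 1]
    fv[paste0("HR_", i, "_inv")] <- 1 / hrss[i + 1]
  }
  fv["VAR_t_total_0"] <- 1 / s$truth$varinv0
  fv["VAR_t_total_0_inv"] <- s$truth$varinv0
  fv["SD_t_total_0"] <- sqrt(1 / s$truth$varinv0)
  fv["SD_t_total_0_inv"] <- sqrt(s$truth$varinv0)
  fv
}
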