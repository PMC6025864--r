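#' The five evaluation metrics
#'
#' Explained variance (R2), mean absolute error and root mean squared error
#' in ml/kg/min, and mean absolute percentage error and root mean squared
#' relative error in percent, computed on pooled predictions:
#' \deqn{R^2 = 1 - \sum (\hat y_i - y_i)^2 / \sum (y_i - \bar y)^2}
#' \deqn{MAE = \frac1N \sum |\hat y_i - y_i|, \quad
#'       MAPE = \frac1N \sum \left|\frac{\hat y_i - y_i}{y_i}\right|}
#' \deqn{RMSE = \sqrt{\frac1N \sum (\hat y_i - y_i)^2}, \quad
#'       RMSRE = \sqrt{\frac1N \sum \left(\frac{\hat y_i - y_i}{y_i}\right)^2}}
#'
#' @param y observed values (must be non-zero for the relative metrics).
#' @param yhat predicted values.
#' @return list with `r2`, `mae`, `mape` (%), `rmse`, `rmsre` (%).
#' @export
compute_metrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0) {
    stop("y and yhat must have equal non-zero length")
  }
  if (any(y == 0)) stop("relative-metric error: observed value of 0")
  e <- yhat - y
  list(r2 = 1 - sum(e^2) / sum((y - mean(y))^2),
       mae = mean(abs(e)),
       mape = 100 * mean(abs(e / y)),
       rmse = sqrt(mean(e^2)),
       rmsre = 100 * sqrt(mean((e / y)^2)))
}

#' Outer leave-one-subject-out evaluation with per-fold re-selection
#'
#' For each subject, all of that subject's sessions (one or two tests) are
#' held out together; features are selected on the remaining subjects (the
#' inner LOSO loop runs inside the training data only), the mixed model is
#' refitted on those subjects with the selected features, and the held-out
#' sessions are predicted. Predictions are pooled over all sessions and the
#' five metrics computed on the pool.
#'
#' @param table feature table of the full cohort.
#' @param combination feature-set combination gating the candidate pool
#'   (`F1` = descriptive only, no selection; `F2` = + heart rate; `F3` = +
#'   accelerometer; `F4` = + both).
#' @param threshold forward-selection acceptance threshold.
#' @param mode prediction mode passed to the mixed model.
#' @return object of class `vo2_eval`: `metrics`, pooled `predictions`
#'   data.frame, per-fold selected features, `combination`, `N`.
#' @export
loso_evaluate <- function(table, combination = "F4", threshold = 0.05,
                          mode = "with_blup") {
  subjects <- unique(table$subject_id)
  if (length(subjects) < 3) stop("need at least 3 subjects")
  candidates <- intersect(combination_candidates(combination), names(table))
  per_fold <- list()
  pred_rows <- list()
  for (s in subjects) {
    hold <- table$subject_id == s
    train <- table[!hold, , drop = FALSE]
    sel <- if (length(candidates)) {
      tryCatch(
        greedy_forward_select(train, candidates = candidates,
                              threshold = threshold),
        error = function(e) {
          stop("fold ", s, " failed: ", conditionMessage(e))
        })
    } else NULL
    feats <- c("G", "BM", if (!is.null(sel)) sel$selected)
    fit <- fit_mixed(train, feats)
    yhat <- predict(fit, table[hold, , drop = FALSE], mode = mode)
    per_fold[[s]] <- list(subject_id = s, selected = feats,
                          y = table$vo2max[hold], yhat = yhat)
    pred_rows[[s]] <- data.frame(subject_id = s,
                                 session_id = table$session_id[hold],
                                 y = table$vo2max[hold], yhat = yhat)
  }
  predictions <- do.call(rbind, pred_rows)
  rownames(predictions) <- NULL
  structure(list(combination = combination,
                 N = nrow(predictions),
                 metrics = compute_metrics(predictions$y, predictions$yhat),
                 predictions = predictions,
                 per_fold = per_fold),
            class = "vo2_eval")
}

#' @export
print.vo2_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<vo2_eval> %s over %d tests: R2 %.3f, MAE %.2f, ",
                     "MAPE %.2f%%, RMSE %.2f, RMSRE %.2f%%\n"),
              x$combination, x$N, m$r2, m$mae, m$mape, m$rmse, m$rmsre))
  invisible(x)
}

#' Sampling-rate robustness of the tibia feature
#'
#' Emulates deploying the frozen model on a lower-rate accelerometer: for
#' each target rate the (already corrected) tibia signal is decimated
#' (anti-alias low-pass at 0.4 x target rate, then every k-th sample), only
#' the warm-up inverse tibia total-acceleration variance is recomputed, and
#' the frozen fit trained at the native rate is re-scored on the modified
#' feature table. Rates below 20 Hz trigger a warning but are computed.
#'
#' @param sessions list of preprocessed sessions (native rate).
#' @param rates target rates in Hz (the native rate yields the baseline).
#' @param fit frozen `vo2_mixed_fit` whose features include `feature`.
#' @param table feature table the fit was trained on.
#' @param feature the tibia feature column to recompute.
#' @param mode prediction mode.
#' @return data.frame with columns `rate` and `r2`.
#' @export
downsample_experiment <- function(sessions, rates, fit, table,
                                  feature = "VAR_t_total_0_inv",
                                  mode = "with_blup") {
  ids <- vapply(sessions, session_id, character(1))
  stopifnot(all(table$session_id %in% ids))
  out <- lapply(rates, function(r) {
    if (r < 20) warning("rate ", r, " Hz is below the 20 Hz feature floor")
    tab <- table
    for (s in sessions) {
      sig <- s$accel$t
      if (r != sig$rate) sig <- decimate_signal(sig, r)
      w <- s$stages[s$stages$index == 0, ]
      tw <- trim_stage_window(w)
      idx <- signal_window_idx(sig, tw[1], tw[2])
      tot <- sqrt(rowSums(sig$data[idx, , drop = FALSE]^2))
      v <- stats::var(tot)
      row <- tab$session_id == session_id(s)
      tab[[sub("_inv$", "", feature)]][row] <- v
      tab[[feature]][row] <- inv_guard(v)
    }
    yhat <- predict(fit, tab, mode = mode)
    data.frame(rate = r, r2 = compute_metrics(tab$vo2max, yhat)$r2)
  })
  do.call(rbind, out)
}
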