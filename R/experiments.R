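#' Run the data-driven feature-combination experiment
#'
#' End-to-end orchestration: preprocess the sessions, assemble the 490-column
#' feature table, then evaluate each requested feature-set combination with
#' nested leave-one-subject-out cross-validation (selection re-run inside
#' every outer fold). Also tallies how many folds selected each feature,
#' mirroring the per-combination fold-count tables.
#'
#' @param sessions list of `vo2_session` objects (raw, preprocessed, or
#'   stubs), or a `vo2_feature_table`.
#' @param combinations which combinations to evaluate.
#' @param threshold forward-selection acceptance threshold.
#' @param out_dir optional directory for artifacts (feature table, reports,
#'   `selected_features_<comb>.csv`).
#' @return named list of `vo2_eval` reports.
#' @export
run_experiment1 <- function(sessions,
                            combinations = c("F1", "F2", "F3", "F4"),
                            threshold = 0.05, out_dir = NULL) {
  table <- if (inherits(sessions, "vo2_feature_table")) sessions else
    assemble_feature_table(sessions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(table, file.path(out_dir, "features.csv"))
  }
  reports <- lapply(combinations, function(comb) {
    rep <- loso_evaluate(table, combination = comb, threshold = threshold)
    if (!is.null(out_dir)) {
      counts <- table(unlist(lapply(rep$per_fold, `[[`, "selected")))
      utils::write.csv(data.frame(feature = names(counts),
                                  folds = as.integer(counts)),
                       file.path(out_dir,
                                 paste0("selected_features_", comb, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(combination = comb, N = rep$N, metrics = rep$metrics),
        file.path(out_dir, paste0("report_", comb, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    rep
  })
  names(reports) <- combinations
  reports
}

#' Run the contact-time (ratio-feature) replication experiment
#'
#' Builds the per-session ratio feature (mean over stages 1-3 of
#' (1/contact time)/heart rate) from the vertical lower-back acceleration,
#' then evaluates the two historical model variants with leave-one-subject-
#' out cross-validation using fixed-effects linear regression: method 1
#' fits separate models per gender on the ratio alone; method 2 fits a
#' single model on gender plus the ratio.
#'
#' @param sessions list of raw or preprocessed `vo2_session` objects with
#'   lower-back acceleration.
#' @param out_dir optional artifact directory.
#' @return list with `method1` and `method2` evaluation reports and the
#'   per-session `ratio_table`.
#' @export
run_experiment2 <- function(sessions, out_dir = NULL) {
  rows <- lapply(sessions, function(s) {
    if (!isTRUE(s$preprocessed)) s <- preprocess_session(s)
    wr <- weyand_ratio(s)
    data.frame(subject_id = s$subject$subject_id,
               test_label = s$subject$test_label,
               session_id = session_id(s),
               G = s$subject$gender,
               ratio = wr$value,
               vo2max = if (!is.null(s$vo2max_measured)) s$vo2max_measured
                        else compute_vo2max(s$breath))
  })
  tab <- do.call(rbind, rows)
  subjects <- unique(tab$subject_id)
  if (length(subjects) < 3) stop("need at least 3 subjects")

  eval_method <- function(stratified) {
    preds <- lapply(subjects, function(s) {
      hold <- tab$subject_id == s
      train <- tab[!hold, , drop = FALSE]
      test <- tab[hold, , drop = FALSE]
      yhat <- if (stratified) {
        fits <- fit_fixed_only(train, "ratio", stratify_by = "G")
        vapply(seq_len(nrow(test)), function(i) {
          predict_fixed(fits[[as.character(test$G[i])]], test[i, ])
        }, numeric(1))
      } else {
        fit <- fit_fixed_only(train, c("G", "ratio"))
        vapply(seq_len(nrow(test)),
               function(i) predict_fixed(fit, test[i, ]), numeric(1))
      }
      data.frame(subject_id = s, session_id = test$session_id,
                 y = test$vo2max, yhat = yhat)
    })
    predictions <- do.call(rbind, preds)
    structure(list(combination = if (stratified) "weyand_m1" else "weyand_m2",
                   N = nrow(predictions),
                   metrics = compute_metrics(predictions$y, predictions$yhat),
                   predictions = predictions),
              class = "vo2_eval")
  }
  out <- list(method1 = eval_method(TRUE), method2 = eval_method(FALSE),
              ratio_table = tab)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "weyand_ratio.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(method1 = out$method1$metrics, method2 = out$method2$metrics),
      file.path(out_dir, "report_weyand.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}
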