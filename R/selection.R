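#' Inner leave-one-subject-out adjusted explained variance
#'
#' Scores a candidate feature set: for every subject in `table`, the mixed
#' model is fitted on the remaining subjects and the held-out subject's
#' sessions are predicted (with the test-level intercept, whose levels are
#' all present in every training fold). Predictions are pooled and
#'
#' \deqn{R^2 = 1 - \sum_i (\hat y_i - y_i)^2 / \sum_i (y_i - \bar y)^2}
#' \deqn{R^2_{adj} = 1 - \frac{n-1}{n-p-1} (1 - R^2)}
#'
#' with \eqn{\bar y} the pooled observed mean, `n` the number of rows and
#' `p` the number of features (the descriptive base counts; the intercept
#' does not).
#'
#' @param table feature table.
#' @param features feature names to score.
#' @param outcome,group column names.
#' @return adjusted explained variance (scalar).
#' @export
inner_cv_r2adj <- function(table, features, outcome = "vo2max",
                           group = "test_label") {
  n <- nrow(table)
  p <- length(features)
  if (n - p - 1 <= 0) {
    stop("undefined-adjustment error: n - p - 1 = ", n - p - 1)
  }
  subjects <- unique(table$subject_id)
  if (length(subjects) < 3) stop("need at least 3 subjects for inner LOSO")
  yhat <- numeric(n)
  for (s in subjects) {
    hold <- table$subject_id == s
    fit <- fit_mixed(table[!hold, , drop = FALSE], features,
                     outcome = outcome, group = group)
    yhat[hold] <- predict(fit, table[hold, , drop = FALSE],
                          mode = "with_blup")
  }
  y <- table[[outcome]]
  r2 <- 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)
  1 - (n - 1) / (n - p - 1) * (1 - r2)
}

# fast scorer: inner-LOSO pooled predictions for MANY candidate features at
# once. Per fold, the bordered normal equations [base | candidate] are
# solved for all candidates simultaneously via the Schur complement of the
# shared base block, and the profiled REML criterion in the variance ratio
# theta is minimized on a dense log-spaced grid (the criterion is smooth and
# flat near its optimum, so grid resolution 0.25 in log(theta) leaves
# R2adj errors ~1e-6). Equivalent to calling inner_cv_r2adj(table,
# c(base, f)) per candidate, at a small fraction of the cost.
score_candidates_r2adj <- function(table, base, candidates,
                                   outcome = "vo2max", group = "test_label") {
  n <- nrow(table)
  p <- length(base) + 1
  y <- table[[outcome]]
  B <- model_matrix(table, base)              # n x (1 + |base|)
  M <- as.matrix(as.data.frame(table)[, candidates, drop = FALSE])
  storage.mode(M) <- "double"
  # center and scale globally: a fixed affine reparametrization is absorbed
  # by the intercept, leaves predictions unchanged, and keeps the bordered
  # normal equations well conditioned (inverse features span ~1e-3..1e6)
  B[, -1] <- scale_safe(B[, -1, drop = FALSE])
  M <- scale_safe(M)
  g <- factor(table[[group]])
  gi <- as.integer(g)
  q <- nlevels(g)
  subjects <- unique(table$subject_id)
  K <- length(candidates)
  yhat <- matrix(NA_real_, n, K)
  usable <- colSums(is.na(M)) == 0            # skip flagged-missing candidates
  ugrid <- c(-40, seq(-12, 10, by = 0.75))    # -40 ~ the OLS boundary

  for (s in subjects) {
    hold <- table$subject_id == s
    Bi <- B[!hold, , drop = FALSE]
    Mi <- M[!hold, usable, drop = FALSE]
    yi <- y[!hold]
    gii <- gi[!hold]
    ni <- nrow(Bi)
    pb <- ncol(Bi)
    Ku <- ncol(Mi)
    if (Ku == 0) next
    pad_q <- function(m) {
      out <- matrix(0, q, ncol(m))
      out[as.integer(rownames(m)), ] <- m
      out
    }
    BtB <- crossprod(Bi)
    Bty <- drop(crossprod(Bi, yi))
    yty <- sum(yi * yi)
    ZtB <- pad_q(rowsum(Bi, gii))
    Zty <- drop(pad_q(rowsum(matrix(yi), gii)))
    nj <- tabulate(gii, q)
    BtM <- crossprod(Bi, Mi)
    Mty <- drop(crossprod(Mi, yi))
    MtM_diag <- colSums(Mi * Mi)
    ZtM <- pad_q(rowsum(Mi, gii))
    ZtM2 <- ZtM * ZtM

    # criterion pieces for one theta, all candidates at once
    eval_theta <- function(u) {
      th <- exp(u)
      d <- th / (1 + th * nj)
      Ab <- BtB - crossprod(ZtB, ZtB * d)
      ch <- tryCatch(chol(Ab), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      U <- BtM - crossprod(ZtB, ZtM * d)
      cc <- MtM_diag - colSums(ZtM2 * d)
      b0 <- Bty - drop(crossprod(ZtB, Zty * d))
      bc <- Mty - colSums(ZtM * (Zty * d))
      yVy <- yty - sum(d * Zty^2)
      sol <- backsolve(ch, forwardsolve(t(ch), cbind(b0, U)))
      alpha <- sol[, 1]
      T1 <- sol[, -1, drop = FALSE]
      ss <- cc - colSums(U * T1)              # Schur complements
      gam <- (bc - colSums(U * alpha)) / ss
      qk <- sum(b0 * alpha) + (bc - colSums(T1 * b0)) * gam
      rVr <- yVy - qk
      bad <- !is.finite(ss) | !is.finite(rVr) |
        ss <= MtM_diag * 1e-10 | rVr <= 0
      crit <- sum(log1p(th * nj)) + 2 * sum(log(diag(ch))) +
        log(pmax(ss, 1e-300)) + (ni - pb - 1) * log(pmax(rVr, 1e-300))
      crit[bad] <- Inf
      list(crit = crit, th = th, d = d, ch = ch, U = U, b0 = b0, bc = bc,
           alpha = alpha, T1 = T1, gam = gam)
    }

    best_crit <- rep(Inf, Ku)
    best_u <- rep(NA_real_, Ku)
    try_u <- function(u) {
      ev <- eval_theta(u)
      if (is.null(ev)) return(invisible(NULL))
      better <- ev$crit < best_crit
      best_crit[better] <<- ev$crit[better]
      best_u[better] <<- u
      invisible(NULL)
    }
    for (u in ugrid) try_u(u)
    # local refinement: halve the step around each candidate's best grid
    # point (grid values are shared, so each pass costs a few global evals)
    delta <- 0.375
    for (it in 1:4) {
      delta <- delta / 2
      offs <- unique(best_u[!is.na(best_u) & best_u > -40])
      for (u in unique(c(offs - delta, offs + delta))) try_u(u)
    }

    Bh <- B[hold, , drop = FALSE]
    Mh <- M[hold, usable, drop = FALSE]
    gh <- gi[hold]
    yh <- matrix(NA_real_, sum(hold), Ku)
    for (u in unique(best_u[!is.na(best_u)])) {
      ev <- eval_theta(u)
      ks <- which(!is.na(best_u) & best_u == u)
      beta_b <- ev$alpha - ev$T1[, ks, drop = FALSE] *
        rep(ev$gam[ks], each = pb)
      fixed_part <- Bh %*% beta_b +
        Mh[, ks, drop = FALSE] * rep(ev$gam[ks], each = nrow(Bh))
      S <- Zty - ZtB %*% beta_b - ZtM[, ks, drop = FALSE] *
        rep(ev$gam[ks], each = q)
      blup <- if (u <= -40) S * 0 else ev$th * S / (1 + ev$th * nj)
      yh[, ks] <- fixed_part + blup[gh, , drop = FALSE]
    }
    yhat[hold, usable] <- yh
  }

  sst <- sum((y - mean(y))^2)
  scores <- rep(NA_real_, K)
  for (k in which(usable)) {
    if (anyNA(yhat[, k])) next
    r2 <- 1 - sum((yhat[, k] - y)^2) / sst
    scores[k] <- 1 - (n - 1) / (n - p - 1) * (1 - r2)
  }
  scores
}

#' Greedy forward feature selection with inner-LOSO scoring
#'
#' Starts from the descriptive base set (gender and body mass) rather than
#' an empty set. Each iteration scores every remaining candidate `f` by the
#' inner-LOSO adjusted explained variance of `base + selected + f`; the best
#' candidate is accepted iff its score improves on the current set's score
#' by at least `threshold` (0.05, a countermeasure against overfitting).
#' Selection stops when no candidate meets the threshold. Ties break by
#' canonical registry order, and candidates with any flagged-missing value
#' in the training rows are skipped for that round. The procedure itself is
#' deterministic.
#'
#' @param table feature table.
#' @param base base feature names, always included.
#' @param candidates candidate pool; defaults to all 488 non-descriptive
#'   registry features present in `table`.
#' @param threshold minimal adjusted-R2 improvement for acceptance.
#' @param outcome,group column names.
#' @return object of class `vo2_selection`: `selected` (ordered names beyond
#'   the base), `base_r2adj`, `r2adj` (final score) and a per-iteration
#'   `trace`.
#' @export
greedy_forward_select <- function(table, base = c("G", "BM"),
                                  candidates = NULL, threshold = 0.05,
                                  outcome = "vo2max", group = "test_label") {
  if (is.null(candidates)) {
    candidates <- setdiff(intersect(feature_registry(), names(table)), base)
  }
  if (anyNA(as.matrix(as.data.frame(table)[, base, drop = FALSE]))) {
    stop("missing values in the base features")
  }
  current <- inner_cv_r2adj(table, base, outcome = outcome, group = group)
  base_r2adj <- current
  selected <- character(0)
  trace <- list()
  pool <- candidates
  repeat {
    if (length(pool) == 0) break
    if (nrow(table) - (length(base) + length(selected) + 1) - 1 <= 0) break
    scores <- score_candidates_r2adj(table, c(base, selected), pool,
                                     outcome = outcome, group = group)
    if (all(is.na(scores))) break
    best_i <- which.max(scores)  # first max: canonical-order tie-break
    best <- pool[best_i]
    gain <- scores[best_i] - current
    accepted <- isTRUE(gain >= threshold)
    trace[[length(trace) + 1]] <-
      data.frame(iteration = length(trace) + 1,
                 n_candidates = sum(!is.na(scores)),
                 best_feature = best,
                 best_r2adj = scores[best_i],
                 gain = gain, accepted = accepted)
    if (!accepted) break
    selected <- c(selected, best)
    current <- scores[best_i]
    pool <- setdiff(pool, best)
  }
  structure(list(selected = selected, base = base,
                 base_r2adj = base_r2adj, r2adj = current,
                 threshold = threshold,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame()),
            class = "vo2_selection")
}

#' @export
print.vo2_selection <- function(x, ...) {
  cat(sprintf("<vo2_selection> base R2adj %.3f -> %.3f; selected: %s\n",
              x$base_r2adj, x$r2adj,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  invisible(x)
}
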