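# Random-intercept linear mixed model, estimated by REML.
#
# The model is  y = X beta + Z b + e,  b ~ N(0, sigma2_b I_q),
# e ~ N(0, sigma2_e I_n), with Z the indicator matrix of the grouping
# factor (the pre/post test label; q = 2 in the intended use). The REML
# criterion is profiled down to the single variance ratio
# theta = sigma2_b / sigma2_e and optimized in one dimension. All linear
# algebra runs on cross-products via the Woodbury identity
# V^{-1} = I - Z diag(theta / (1 + theta n_j)) Z', which makes one fit
# cost microseconds -- the nested feature selection needs ~10^5 of them.
# Agreement with lme4's lmer (fixed effects, variance components, BLUPs)
# is asserted in the test suite.

# core fit from cross-products only:
#   XtX (p x p), Xty (p), yty, ZtX (q x p), Zty (q), nj (q), n
reml_ri_xprod <- function(XtX, Xty, yty, ZtX, Zty, nj, n) {
  p <- ncol(XtX)
  if (n <= p + 1) stop("too few observations (", n, ") for ", p, " columns")
  big <- 1e300  # finite sentinel: keeps optimize() quiet on degenerate fits
  crit <- function(u) {
    th <- exp(u)
    d <- th / (1 + th * nj)
    A <- XtX - crossprod(ZtX, ZtX * d)
    bb <- Xty - crossprod(ZtX, Zty * d)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(big)
    beta <- backsolve(ch, forwardsolve(t(ch), bb))
    rVr <- (yty - sum(d * Zty^2)) - sum(bb * beta)
    if (rVr <= 0) return(big)
    sum(log1p(th * nj)) + 2 * sum(log(diag(ch))) + (n - p) * log(rVr)
  }
  opt <- stats::optimize(crit, c(-18, 14), tol = 1e-7)
  th <- if (crit(-40) <= opt$objective + 1e-10) 0 else exp(opt$minimum)
  d <- th / (1 + th * nj)
  A <- XtX - crossprod(ZtX, ZtX * d)
  bb <- Xty - crossprod(ZtX, Zty * d)
  Ai <- solve(A)
  beta <- drop(Ai %*% bb)
  rVr <- (yty - sum(d * Zty^2)) - sum(bb * beta)
  s2e <- max(rVr, 0) / (n - p)
  S <- drop(Zty - ZtX %*% beta)
  list(beta = beta, sigma2_e = s2e, sigma2_b = th * s2e,
       blup = if (th > 0) th * S / (1 + th * nj) else rep(0, length(nj)),
       theta = th, cov_fixed = Ai * s2e)
}

# center/scale columns (population constants; NA-preserving). Constant
# columns are centered but not scaled.
scale_safe <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 2, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  sweep(sweep(m, 2, mu), 2, sd_, "/")
}

#' Fit the random-intercept mixed model
#'
#' Fits `vo2max ~ 1 + (1 | Test) + features` by REML, where `Test` is the
#' pre/post test label. When the random-intercept variance estimate hits the
#' zero boundary the fit degrades gracefully to ordinary least squares
#' (`sigma2_b = 0`, all BLUPs zero). No penalization is applied.
#'
#' @param table a feature table from [assemble_feature_table()] (or any
#'   data.frame with the outcome, grouping and feature columns).
#' @param features character vector of fixed-effect feature names.
#' @param outcome outcome column name.
#' @param group grouping column name for the random intercept.
#' @return object of class `vo2_mixed_fit`: fixed coefficients (intercept
#'   first), `sigma2_b`, `sigma2_e`, per-level `blup`, `features`, `n_obs`.
#' @export
fit_mixed <- function(table, features, outcome = "vo2max",
                      group = "test_label") {
  X <- model_matrix(table, features)
  y <- table[[outcome]]
  if (anyNA(X) || anyNA(y)) {
    stop("missing values among the chosen features or outcome")
  }
  # fit on centered/scaled columns (conditioning); back-transform after
  p1 <- ncol(X)
  mu <- if (p1 > 1) colMeans(X[, -1, drop = FALSE]) else numeric(0)
  sd_ <- if (p1 > 1) apply(X[, -1, drop = FALSE], 2, stats::sd) else numeric(0)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Xs <- X
  if (p1 > 1) {
    Xs[, -1] <- sweep(sweep(X[, -1, drop = FALSE], 2, mu), 2, sd_, "/")
  }
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity error: rank-deficient design, offending column(s): ",
         paste(bad, collapse = ", "))
  }
  g <- factor(table[[group]])
  gi <- as.integer(g)
  q <- nlevels(g)
  fit <- reml_ri_xprod(crossprod(Xs), drop(crossprod(Xs, y)), sum(y^2),
                       rowsum(Xs, gi), drop(rowsum(y, gi)),
                       tabulate(gi, q), nrow(Xs))
  if (p1 > 1) {
    bt <- fit$beta[-1] / sd_
    fit$beta <- c(fit$beta[1] - sum(bt * mu), bt)
    # back-transform the covariance: beta_orig = T beta_scaled
    Tm <- diag(c(1, 1 / sd_))
    Tm[1, -1] <- -mu / sd_
    fit$cov_fixed <- Tm %*% fit$cov_fixed %*% t(Tm)
  }
  names(fit$beta) <- colnames(X)
  dimnames(fit$cov_fixed) <- list(colnames(X), colnames(X))
  blup <- fit$blup
  names(blup) <- levels(g)
  se <- sqrt(pmax(0, diag(fit$cov_fixed)))
  names(se) <- colnames(X)
  structure(list(fixed = fit$beta, se_fixed = se,
                 sigma2_b = fit$sigma2_b,
                 sigma2_e = fit$sigma2_e, blup = blup,
                 features = features, n_obs = nrow(X),
                 group = group, outcome = outcome),
            class = "vo2_mixed_fit")
}

model_matrix <- function(table, features) {
  miss <- setdiff(features, names(table))
  if (length(miss)) {
    stop("prediction error: feature(s) absent from table: ",
         paste(miss, collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(table)[, features, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Predict VO2max from a fitted mixed model
#'
#' `fixed_only` returns the fixed-effect linear predictor; `with_blup` adds
#' the estimated intercept deviation of the row's test level when that level
#' was seen in training (0 otherwise). Inside cross-validation `with_blup`
#' is the default, since both test levels appear in every training fold.
#'
#' @param object a `vo2_mixed_fit`.
#' @param newdata data.frame containing the fit's features (and the grouping
#'   column for `with_blup`).
#' @param mode `"with_blup"` or `"fixed_only"`.
#' @param ... unused.
#' @return numeric vector of predictions, ml/kg/min.
#' @export
predict.vo2_mixed_fit <- function(object, newdata,
                                  mode = c("with_blup", "fixed_only"), ...) {
  mode <- match.arg(mode)
  X <- model_matrix(newdata, object$features)
  if (anyNA(X)) stop("prediction error: missing feature value")
  yhat <- unname(drop(X %*% object$fixed))
  if (mode == "with_blup") {
    lev <- as.character(newdata[[object$group]])
    add <- object$blup[lev]
    add[is.na(add)] <- 0
    yhat <- yhat + unname(add)
  }
  yhat
}

#' Fixed-effects-only linear predictors
#'
#' Ordinary least squares, either pooled or stratified (one predictor
#' function per stratum). Used for the contact-time model comparison, which
#' keeps the set-up of the original ratio-based model: method 1 fits
#' separate regressions for men and women on the ratio alone; method 2 fits
#' a single regression on gender plus the ratio.
#'
#' @param table data.frame with outcome and features.
#' @param features fixed-effect feature names.
#' @param stratify_by optional column name; one OLS fit per level.
#' @param outcome outcome column name.
#' @return a `vo2_predictor` (named coefficient vector with intercept), or a
#'   named list of them when stratified.
#' @export
fit_fixed_only <- function(table, features, stratify_by = NULL,
                           outcome = "vo2max") {
  fit1 <- function(tab, name) {
    if (nrow(tab) < 3) {
      stop("insufficient-data: stratum ", name, " has ", nrow(tab), " rows")
    }
    X <- model_matrix(tab, features)
    cf <- qr.coef(qr(X), tab[[outcome]])
    structure(list(name = name, coef = cf), class = "vo2_predictor")
  }
  if (is.null(stratify_by)) return(fit1(table, "pooled"))
  levs <- sort(unique(as.character(table[[stratify_by]])))
  out <- lapply(levs, function(l) {
    fit1(table[table[[stratify_by]] == l, , drop = FALSE], l)
  })
  names(out) <- levs
  out
}

#' Apply a fixed-coefficient predictor function
#'
#' @param pred a `vo2_predictor` (e.g. from [table4_predictors()]).
#' @param row data.frame or named list/vector with the predictor's features.
#' @return predicted VO2max, ml/kg/min.
#' @export
predict_fixed <- function(pred, row) {
  feats <- setdiff(names(pred$coef), "(Intercept)")
  row <- as.list(row)
  miss <- setdiff(feats, names(row))
  if (length(miss)) {
    stop("prediction error: missing feature value(s): ",
         paste(miss, collapse = ", "))
  }
  vals <- vapply(feats, function(f) as.numeric(row[[f]]), numeric(1))
  if (anyNA(vals)) stop("prediction error: missing feature value")
  unname(pred$coef["(Intercept)"] + sum(pred$coef[feats] * vals))
}

#' The four published predictor functions
#'
#' Fixed-effect coefficient sets of the four feature-set combinations as
#' learned from the complete original cohort, shipped as a frozen fixture
#' (`inst/extdata/table4_predictors.json`). The best combination, `F4`, uses
#' gender, body mass, the inverse warm-up heart rate and the inverse
#' warm-up tibia total-acceleration variance.
#'
#' @return named list of `vo2_predictor` objects `F1`..`F4`.
#' @export
table4_predictors <- function() {
  path <- system.file("extdata", "table4_predictors.json", package = "vo2pipe")
  raw <- jsonlite::read_json(path)
  out <- lapply(names(raw), function(nm) {
    cf <- unlist(raw[[nm]])
    structure(list(name = nm, coef = cf), class = "vo2_predictor")
  })
  names(out) <- names(raw)
  out
}

#' Serialize / restore model fits
#'
#' Coefficients are written at full double precision so fits round-trip
#' bit-exactly.
#'
#' @param fit a `vo2_mixed_fit` or `vo2_predictor`.
#' @param path JSON file path.
#' @export
write_fit <- function(fit, path) {
  obj <- lapply(unclass(fit), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  obj$cov_fixed <- NULL  # derived; se_fixed is kept
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- if (is.null(obj$fixed)) "vo2_predictor" else "vo2_mixed_fit"
  if (cls == "vo2_mixed_fit") {
    obj$fixed <- unlist(obj$fixed)
    obj$blup <- unlist(obj$blup)
    if (!is.null(obj$se_fixed)) obj$se_fixed <- unlist(obj$se_fixed)
  } else {
    obj$coef <- unlist(obj$coef)
  }
  structure(obj, class = cls)
}
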