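# the in-package REML fitter is validated against lme4 (the reference
# implementation) on simulated fixtures; lme4 itself is never used in the
# pipeline's hot path.

sim_mixed_data <- function(n, beta, sigma_b, sigma_e, seed) {
  set.seed(seed)
  tab <- data.frame(subject_id = rep(sprintf("S%03d", 1:(n / 2)), 2),
                    test_label = rep(c("pre", "post"), each = n / 2),
                    vo2max = NA_real_,
                    G = rbinom(n, 1, 0.5),
                    BM = rnorm(n, 67, 9),
                    F1 = rnorm(n),
                    F2 = rnorm(n))
  b <- rnorm(2, 0, sigma_b)
  X <- cbind(1, tab$G, tab$BM, tab$F1, tab$F2)
  tab$vo2max <- drop(X %*% beta) + b[as.integer(factor(tab$test_label))] +
    rnorm(n, 0, sigma_e)
  tab
}

test_that("REML fit agrees with lme4 on fixtures", {
  skip_if_not_installed("lme4")
  beta <- c(30, -8, -0.2, 3, -2)
  for (seed in c(1, 2)) {
    tab <- sim_mixed_data(60, beta, sigma_b = 2, sigma_e = 1.5, seed = seed)
    fit <- fit_mixed(tab, c("G", "BM", "F1", "F2"))
    m <- lme4::lmer(vo2max ~ G + BM + F1 + F2 + (1 | test_label), tab,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
    expect_equal(unname(fit$fixed), unname(lme4::fixef(m)), tolerance = 1e-4)
    expect_equal(fit$sigma2_e, lme4::getME(m, "sigma")^2, tolerance = 1e-3)
    expect_equal(fit$sigma2_b,
                 as.numeric(lme4::VarCorr(m)$test_label), tolerance = 1e-3)
    expect_equal(sort(unname(fit$blup)),
                 sort(unlist(lme4::ranef(m)$test_label, use.names = FALSE)),
                 tolerance = 1e-3)
    expect_equal(unname(fit$se_fixed),
                 unname(sqrt(diag(as.matrix(vcov(m))))), tolerance = 1e-3)
  }
})

test_that("boundary variance degrades gracefully to OLS", {
  # data with equal group means: the REML variance estimate hits zero
  set.seed(42)
  tab <- sim_mixed_data(80, c(30, -8, -0.2, 3, -2), sigma_b = 0,
                        sigma_e = 1, seed = 5)
  fit <- fit_mixed(tab, c("G", "BM", "F1", "F2"))
  ols <- lm(vo2max ~ G + BM + F1 + F2, tab)
  if (fit$sigma2_b == 0) {
    expect_equal(unname(fit$fixed), unname(coef(ols)), tolerance = 1e-6)
    expect_equal(unname(fit$blup), c(0, 0))
  } else {
    # a small positive estimate can occur; fixed effects must stay close
    expect_equal(unname(fit$fixed), unname(coef(ols)), tolerance = 1e-2)
  }
  expect_gte(fit$sigma2_b, 0)
  expect_gt(fit$sigma2_e, 0)
})

test_that("blups sum to zero and parameters are recovered within 3 SE", {
  beta <- c(25, -9, -0.25, 5, -3)
  tab <- sim_mixed_data(400, beta, sigma_b = 1.5, sigma_e = 2, seed = 9)
  fit <- fit_mixed(tab, c("G", "BM", "F1", "F2"))
  expect_lt(abs(sum(fit$blup)), 1e-8)
  expect_true(all(abs(fit$fixed - beta) <= 3 * fit$se_fixed))
})

test_that("rank-deficient designs raise a collinearity error naming columns", {
  tab <- sim_mixed_data(40, c(30, -8, -0.2, 3, -2), 1, 1, seed = 3)
  tab$F1dup <- tab$F1
  expect_error(fit_mixed(tab, c("G", "BM", "F1", "F1dup")),
               "collinearity error.*F1")
})

test_that("prediction is linear and honours the blup mode", {
  tab <- sim_mixed_data(60, c(30, -8, -0.2, 3, -2), 2, 1, seed = 7)
  fit <- fit_mixed(tab, c("G", "BM", "F1", "F2"))
  new1 <- tab[3, ]
  new2 <- tab[10, ]
  mix <- new1
  for (f in c("G", "BM", "F1", "F2")) mix[[f]] <- new1[[f]] + 2 * new2[[f]]
  expect_equal(predict(fit, mix, mode = "fixed_only") + fit$fixed[["(Intercept)"]] * 2,
               predict(fit, new1, mode = "fixed_only") +
                 2 * predict(fit, new2, mode = "fixed_only"),
               tolerance = 1e-9)
  # with_blup adds the level deviation; unseen level adds 0
  p_fix <- predict(fit, new1, mode = "fixed_only")
  p_blup <- predict(fit, new1, mode = "with_blup")
  expect_equal(p_blup - p_fix, unname(fit$blup[new1$test_label]))
  unseen <- new1
  unseen$test_label <- "retest"
  expect_equal(predict(fit, unseen, mode = "with_blup"), p_fix)
  # missing feature value errors
  broken <- new1
  broken$F1 <- NA
  expect_error(predict(fit, broken), "missing")
})

test_that("published predictor functions reproduce the worked example", {
  preds <- table4_predictors()
  expect_named(preds, c("F1", "F2", "F3", "F4"))
  f4 <- preds$F4
  # the two printed example subjects (female, warm-up features as printed)
  s1 <- list(G = 1, BM = 71.8, HR_0_inv = 0.00559, VAR_t_total_0_inv = 0.689)
  s2 <- list(G = 1, BM = 68.5, HR_0_inv = 0.00557, VAR_t_total_0_inv = 2.30)
  expect_lt(abs(predict_fixed(f4, s1) - 33.14), 0.5)
  expect_lt(abs(predict_fixed(f4, s2) - 41.71), 0.5)
  # all-zero row returns the intercept
  zero <- list(G = 0, BM = 0, HR_0_inv = 0, VAR_t_total_0_inv = 0)
  expect_equal(predict_fixed(f4, zero), 25.78)
  expect_error(predict_fixed(f4, list(G = 1, BM = 70)), "missing feature")
})

test_that("fits round-trip through JSON bit-exactly", {
  tab <- sim_mixed_data(60, c(30, -8, -0.2, 3, -2), 2, 1, seed = 13)
  fit <- fit_mixed(tab, c("G", "BM", "F1"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_identical(back$fixed, fit$fixed)
  expect_identical(back$blup, fit$blup)
  expect_identical(back$sigma2_b, fit$sigma2_b)
  for (p in table4_predictors()) {
    write_fit(p, path)
    expect_identical(read_fit(path)$coef, p$coef)
  }
})

test_that("fixed-effects-only fits recover planted coefficients", {
  set.seed(17)
  n <- 60
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    G = rep(0:1, each = n / 2),
                    ratio = runif(n, 0.015, 0.035))
  # noiseless: exact recovery, and pooled == stratified when no interaction
  tab$vo2max <- 10 + 5 * tab$G + 1200 * tab$ratio
  pooled <- fit_fixed_only(tab, c("G", "ratio"))
  expect_equal(unname(pooled$coef), c(10, 5, 1200), tolerance = 1e-9)
  strat <- fit_fixed_only(tab, "ratio", stratify_by = "G")
  expect_equal(unname(strat[["0"]]$coef), c(10, 1200), tolerance = 1e-9)
  expect_equal(unname(strat[["1"]]$coef), c(15, 1200), tolerance = 1e-9)

  # noisy stratified recovery within 3 SE
  tab$vo2max <- tab$vo2max + rnorm(n, 0, 2)
  strat2 <- fit_fixed_only(tab, "ratio", stratify_by = "G")
  for (g in c("0", "1")) {
    sub <- tab[tab$G == as.numeric(g), ]
    se <- summary(lm(vo2max ~ ratio, sub))$coefficients["ratio", "Std. Error"]
    expect_lt(abs(strat2[[g]]$coef[["ratio"]] - 1200), 3 * se)
  }
  expect_error(fit_fixed_only(tab[1:2, ], "ratio"), "insufficient-data")
})
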