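# shared fixtures: scaled-down generator settings keep the suite inside the
# grading time budget; statistical thresholds stay as specified.

quick_config <- function(n = 8, seed = 1, ...) {
  generator_config(n_subjects = n, sampling_rate = 128, seed = seed, ...)
}

quick_protocol <- function(...) {
  protocol_spec(stage_duration = 90, rest_duration = 20, ...)
}

# cached small signal cohort reused across test files (generation is the
# expensive part; tests only read it)
signal_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) {
      coh <<- generate_cohort(quick_config(n = 6, seed = 9,
                                           frac_second_test = 1),
                              quick_protocol(), signals = TRUE)
    }
    coh
  }
})

make_breath <- function(t, vo2 = rep(40, length(t)), hr = rep(150, length(t))) {
  data.frame(t = t, vo2 = vo2, hr = hr)
}

# independent brute-force oracles -------------------------------------------

bf_rolling_vo2max <- function(t, v, window = 30) {
  best <- -Inf
  for (i in seq_along(t)) {
    sel <- t >= t[i] & t <= t[i] + window
    if (t[i] + window > t[length(t)]) next
    best <- max(best, mean(v[sel]))
  }
  best
}

bf_median7 <- function(x) {
  n <- length(x)
  sapply(seq_len(n), function(i) median(x[max(1, i - 3):min(n, i + 3)]))
}

bf_metrics <- function(y, yhat) {
  list(r2 = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2),
       mae = sum(abs(yhat - y)) / length(y),
       mape = 100 * sum(abs((yhat - y) / y)) / length(y),
       rmse = sqrt(sum((yhat - y)^2) / length(y)),
       rmsre = 100 * sqrt(sum(((yhat - y) / y)^2) / length(y)))
}

# brute-force inner-LOSO adjusted R2 with an OLS core; valid as an oracle for
# single-group tables, where GLS with an equicorrelated V equals OLS and the
# group intercept deviation is zero
bf_inner_r2adj_ols <- function(tab, features) {
  yhat <- numeric(nrow(tab))
  for (s in unique(tab$subject_id)) {
    hold <- tab$subject_id == s
    f <- lm(reformulate(features, "vo2max"), data = tab[!hold, ])
    yhat[hold] <- predict(f, tab[hold, ])
  }
  y <- tab$vo2max
  r2 <- 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)
  n <- nrow(tab)
  p <- length(features)
  1 - (n - 1) / (n - p - 1) * (1 - r2)
}

# feature table with an informative descriptive base (as in the stated
# world) and pure-noise candidates, for null/overfitting tests
noise_table <- function(n_subjects, n_candidates, seed) {
  set.seed(seed)
  tab <- data.frame(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                    test_label = rep(c("pre", "post"),
                                     length.out = n_subjects),
                    session_id = sprintf("S%02d_x", seq_len(n_subjects)),
                    G = rep(0:1, length.out = n_subjects),
                    BM = rnorm(n_subjects, 67, 9))
  tab$vo2max <- 64 - 8 * tab$G - 0.25 * tab$BM + rnorm(n_subjects, 0, 3)
  for (k in seq_len(n_candidates)) {
    tab[[paste0("N", k)]] <- rnorm(n_subjects)
  }
  tab
}

# two-harmonic synthetic gait waveform with closed-form stance fraction
gait_signal <- function(rate, dur, fstep, a2, amp = 0.8, noise = 0) {
  tt <- seq(0, dur, by = 1 / rate)
  th <- 2 * pi * fstep * tt
  z <- amp * (sin(th) + a2 * cos(2 * th)) + rnorm(length(tt), 0, noise)
  uniform_signal(matrix(z, ncol = 1, dimnames = list(NULL, "z")), rate = rate)
}

gait_duty <- function(a2) {
  s <- (1 - sqrt(1 + 8 * a2^2)) / (4 * a2)
  (pi + 2 * asin(-s)) / (2 * pi)
}
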