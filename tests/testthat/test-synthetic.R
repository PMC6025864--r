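test_that("cohorts are deterministic in the seed", {
  cfg <- quick_config(n = 4, seed = 31)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  a <- generate_cohort(cfg, quick_protocol(), signals = TRUE)
  b <- generate_cohort(cfg, quick_protocol(), signals = TRUE)
  expect_identical(a, b)
  # stub truth agrees with full-signal truth (shared session streams)
  expect_identical(ground_truth_table(generate_cohort(cfg, quick_protocol())),
                   ground_truth_table(a))
})

test_that("config and protocol validation reject degenerate inputs", {
  expect_error(generator_config(n_subjects = 1), "invalid-config")
  expect_error(generator_config(sampling_rate = 64), "invalid-config")
  expect_error(generator_config(noise_sd_hr = -1), "invalid-config")
  expect_error(protocol_spec(n_stages = 2), "invalid-config")
  expect_error(protocol_spec(stage_duration = 0), "invalid-config")
})

test_that("large default cohort matches the target descriptives", {
  coh <- generate_cohort(generator_config(n_subjects = 1000, seed = 11))
  gt <- ground_truth_table(coh)
  sub <- gt[!duplicated(gt$subject_id), ]
  expect_equal(nrow(sub), 1000)
  # 3 standard errors of the configured pooled moments
  expect_lt(abs(mean(sub$vo2max_true) - 46.73), 3 * 6.51 / sqrt(1000))
  bm_m <- sub$body_mass[sub$gender == 0]
  bm_f <- sub$body_mass[sub$gender == 1]
  expect_lt(abs(mean(bm_m) - 75.34), 3 * 9.2 / sqrt(length(bm_m)))
  expect_lt(abs(mean(bm_f) - 61.55), 3 * 9.2 / sqrt(length(bm_f)))
  expect_lt(abs(sd(sub$vo2max_true) - 6.51), 0.7)
})

test_that("planted links are monotone in VO2max when other variation is off", {
  # heart-rate link only: truth varies solely through the inverse warm-up HR
  cfg_hr <- generator_config(n_subjects = 40, seed = 3, vo2max_sd = 1e-6,
                             bm_sd = 0, varinv_sd = 0, varinv_day_sd = 0,
                             hr0inv_day_sd = 0, sex_ratio = 1,
                             test_intercept_sd = 0, frac_second_test = 0)
  gt <- ground_truth_table(generate_cohort(cfg_hr))
  ord <- order(gt$vo2max_true)
  expect_true(all(diff(gt$hrss0[ord]) < 0))

  # tibia-variance link only: Var decreases as VO2max increases
  cfg_v <- generator_config(n_subjects = 40, seed = 3, vo2max_sd = 1e-6,
                            bm_sd = 0, hr0inv_sd = 0, hr0inv_day_sd = 0,
                            varinv_day_sd = 0, sex_ratio = 1,
                            test_intercept_sd = 0, frac_second_test = 0)
  gt <- ground_truth_table(generate_cohort(cfg_v))
  ord <- order(gt$vo2max_true)
  expect_true(all(diff(1 / gt$varinv0[ord]) < 0))
})

test_that("higher VO2max goes with lower tibia variance and lower HR", {
  gt <- ground_truth_table(generate_cohort(generator_config(n_subjects = 200,
                                                            seed = 21)))
  expect_gt(cor(gt$vo2max_true, gt$varinv0), 0.2)
  expect_lt(cor(gt$vo2max_true, gt$hrss0), -0.2)
})

test_that("protocol shape follows the staged test", {
  coh <- generate_cohort(generator_config(n_subjects = 4, seed = 2,
                                          sex_ratio = 0.5))
  for (s in coh) {
    st <- s$stages
    expect_gte(nrow(st), 4)
    expect_equal(st$end - st$start, rep(240, nrow(st)))
    expect_equal(st$start[-1] - st$end[-nrow(st)], rep(60, nrow(st) - 1))
    ws <- if (s$subject$gender == 0) 9 else 8
    expect_equal(st$speed[1:2], c(ws, ws))           # stage 1 repeats warm-up
    expect_equal(diff(st$speed[-1]), rep(1.5, nrow(st) - 2))
  }
  bad <- protocol_spec()
  bad$n_stages <- 2L
  expect_error(generate_session(coh[[1]]$subject, bad, quick_config()),
               "invalid-config")
})

test_that("noiseless sessions are exactly periodic within a stage", {
  # rate 130 Hz and warm-up speed 8 km/h give a step period of exactly
  # 50 samples (f = 2.2 + 0.05 * 8 = 2.6 Hz)
  cfg <- quick_config(n = 2, seed = 5, noise_sd_accel = 0, tilt_deg_max = 0)
  cfg$sampling_rate <- 130
  s <- generate_session(list(subject_id = "X", gender = 1, body_mass = 62,
                             vo2max_true = 45, test_label = "pre"),
                        protocol_spec(warmup_speed = 8, stage_duration = 90,
                                      rest_duration = 20),
                        cfg, seed = 77)
  z <- s$accel$t$data[, "z"]
  warm <- signal_window_idx(s$accel$t, 1, 89)
  expect_lt(max(abs(z[warm] - z[warm + 50])), 1e-9)
  # population variance over whole cycles is independent of cycle count
  pvar <- function(x) mean((x - mean(x))^2)
  v10 <- pvar(z[warm[1:500]])    # 10 cycles
  v40 <- pvar(z[warm[1:2000]])   # 40 cycles
  expect_lt(abs(v10 / v40 - 1), 1e-6)
})

test_that("warm-up tibia variance of the total acceleration hits the link", {
  coh <- signal_cohort()
  gt <- ground_truth_table(coh)
  tab <- assemble_feature_table(coh)
  expect_equal(tab$VAR_t_total_0_inv, gt$varinv0, tolerance = 0.02)
})

test_that("ground-truth table re-derives the analytic planted links", {
  # no day-to-day jitter: the session links equal the subject latents
  cfg <- generator_config(n_subjects = 30, seed = 13, frac_second_test = 0.5,
                          hr0inv_day_sd = 0, varinv_day_sd = 0)
  coh <- generate_cohort(cfg)
  gt <- ground_truth_table(coh)
  expect_equal(nrow(gt), length(coh))
  expect_equal(gt$vo2max_true,
               vapply(coh, function(s) s$subject$vo2max_true, numeric(1)))
  tm <- vo2pipe:::truth_model(cfg)
  for (s in coh) {
    is_post <- identical(s$subject$test_label, "post")
    # analytic warm-up HR steady state and inverse tibia variance
    expect_equal(1 / s$truth$hrss0,
                 s$subject$hr0inv +
                   is_post * (cfg$post_shift / 2) / cfg$coef_hr0inv,
                 tolerance = 1e-12)
    expect_equal(s$truth$varinv0,
                 s$subject$varinv +
                   is_post * (cfg$post_shift / 2) / cfg$coef_varinv0,
                 tolerance = 1e-12)
    # and the truth line itself
    bm_mu <- if (s$subject$gender == 0) cfg$bm_mean_male else cfg$bm_mean_female
    fixed_part <- tm$b0 + cfg$coef_g * s$subject$gender +
      cfg$coef_bm * (s$subject$body_mass - bm_mu) +
      cfg$coef_hr0inv * (s$subject$hr0inv - cfg$hr0inv_mean) +
      cfg$coef_varinv0 * (s$subject$varinv - cfg$varinv_mean)
    expect_lt(abs(s$subject$vo2max_true - fixed_part), 5 * tm$sd_eps + 1e-9)
  }
})

test_that("post tests shift VO2max by the configured amount", {
  cfg <- generator_config(n_subjects = 10, seed = 4, frac_second_test = 1,
                          hr0inv_day_sd = 0, varinv_day_sd = 0,
                          test_intercept_sd = 0)
  gt <- ground_truth_table(generate_cohort(cfg))
  pre <- gt[gt$test_label == "pre", ]
  post <- gt[gt$test_label == "post", ]
  expect_equal(post$vo2max_session[order(post$subject_id)] -
                 pre$vo2max_session[order(pre$subject_id)],
               rep(2, 10), tolerance = 1e-9)
})
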