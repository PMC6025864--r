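test_that("stage windows are trimmed by ten seconds per side", {
  expect_equal(trim_stage_window(list(start = 0, end = 240)), c(10, 230))
  expect_equal(trim_stage_window(list(start = 100, end = 340)), c(110, 330))
  expect_error(trim_stage_window(list(start = 0, end = 15)),
               "degenerate-window")
})

test_that("feature registry has the published catalogue structure", {
  reg <- feature_registry()
  expect_length(reg, 490)
  expect_length(unique(reg), 490)
  expect_equal(reg[1:2], c("G", "BM"))
  expect_length(grep("^HR_", reg), 8)
  expect_length(grep("^(AVG|SD|VAR|RMS|P)_", reg), 480)
  # inverses adjacent to their base feature
  base_idx <- which(reg == "VAR_t_total_0")
  expect_equal(reg[base_idx + 1], "VAR_t_total_0_inv")
  expect_equal(lengths(lapply(c("F1", "F2", "F3", "F4"),
                              combination_candidates)),
               c(0L, 8L, 480L, 488L))
})

test_that("heart-rate stage features use the last minute of each stage", {
  stages <- data.frame(index = 0:3, start = c(0, 300, 600, 900),
                       end = c(240, 540, 840, 1140), speed = 8)
  # constant 179 bpm
  hr <- uniform_signal(matrix(rep(179, 114), ncol = 1), rate = 0.1, start = 5,
                       labels = "hr")
  f <- hr_stage_features(hr, stages)
  expect_length(f, 8)
  expect_equal(unname(f["HR_0"]), 179)
  expect_equal(unname(f["HR_0_inv"]), 1 / 179, tolerance = 1e-6)
  expect_equal(unname(f["HR_0_inv"]), 0.005587, tolerance = 1e-4)

  # linear rise 150 -> 160 across the last-minute window averages to 155
  tt <- 5 + 10 * (0:113)
  vals <- approx(c(185, 235), c(150, 160), xout = tt, rule = 2)$y
  hr2 <- uniform_signal(matrix(vals, ncol = 1), rate = 0.1, start = 5,
                        labels = "hr")
  f2 <- hr_stage_features(hr2, stages)
  expect_equal(unname(f2["HR_0"]), 155)

  # missing coverage flags the feature
  short <- uniform_signal(matrix(rep(150, 20), ncol = 1), rate = 0.1,
                          start = 5, labels = "hr")
  f3 <- hr_stage_features(short, stages)
  expect_true(is.na(f3["HR_2"]) && is.na(f3["HR_2_inv"]))
})

test_that("accelerometer stage statistics satisfy the moment identities", {
  set.seed(4)
  stages <- data.frame(index = 0:3, start = c(0, 110, 220, 330),
                       end = c(90, 200, 310, 420), speed = 8)
  n <- 420 * 128 + 1
  mk <- function() {
    m <- cbind(x = rnorm(n), y = rnorm(n), z = rnorm(n))
    sweep(m, 2, colMeans(m))  # exactly zero-mean channels
  }
  accel <- list(t = uniform_signal(mk(), rate = 128),
                bl = uniform_signal(mk(), rate = 128),
                bu = uniform_signal(mk(), rate = 128))
  f <- accel_stage_features(accel, stages)
  expect_length(f, 480)
  expect_equal(sum(is.na(f)), 0L, tolerance = 0)  # no window empty
  # zero-mean unit-variance channel: AVG ~ 0, VAR ~ 1, RMS ~ SD
  expect_lt(abs(f[["AVG_t_x_1"]]), 0.05)
  expect_equal(f[["VAR_t_x_1"]], 1, tolerance = 0.05)
  expect_equal(f[["RMS_t_x_1"]], f[["SD_t_x_1"]], tolerance = 1e-3)
  # exact identities by construction
  for (nm in c("VAR_bl_y_2", "VAR_t_total_0")) {
    expect_identical(f[[nm]], f[[sub("VAR", "SD", nm)]]^2)
  }
  for (nm in c("P_bu_z_3", "P_t_total_1")) {
    expect_identical(f[[nm]], f[[sub("^P", "RMS", nm)]]^2)
  }
  # RMS^2 = AVG^2 + VAR * (n-1)/n
  nw <- length(signal_window_idx(accel$t, 10, 80))
  expect_equal(f[["RMS_bl_x_0"]]^2,
               f[["AVG_bl_x_0"]]^2 + f[["VAR_bl_x_0"]] * (nw - 1) / nw,
               tolerance = 1e-10)
  # inverse pairing
  reg <- names(f)
  base <- reg[!endsWith(reg, "_inv")]
  ok <- !is.na(f[base]) & abs(f[base]) >= 1e-9
  expect_true(all(abs(f[base][ok] * f[paste0(base, "_inv")][ok] - 1) < 1e-9))
})

test_that("a pure sinusoid has the closed-form RMS and power", {
  stages <- data.frame(index = 0:3, start = c(0, 110, 220, 330),
                       end = c(90, 200, 310, 420), speed = 8)
  tt <- seq(0, 420, by = 1 / 128)
  A <- 1.7
  z <- A * sin(2 * pi * 2 * tt)  # 2 Hz: the 70 s trimmed window is whole cycles
  m <- cbind(x = z, y = z, z = z)
  accel <- list(t = uniform_signal(m, rate = 128),
                bl = uniform_signal(m, rate = 128),
                bu = uniform_signal(m, rate = 128))
  f <- accel_stage_features(accel, stages)
  expect_equal(f[["RMS_t_z_0"]], A / sqrt(2), tolerance = 1e-3)
  expect_equal(f[["P_t_z_0"]], A^2 / 2, tolerance = 1e-3)
  # half-cycle phase shift changes whole-window statistics by < 1%
  m2 <- cbind(x = z, y = z, z = A * sin(2 * pi * 2 * tt + pi))
  accel2 <- list(t = uniform_signal(m2, rate = 128), bl = accel$bl,
                 bu = accel$bu)
  f2 <- accel_stage_features(accel2, stages)
  expect_equal(f2[["VAR_t_z_1"]], f[["VAR_t_z_1"]], tolerance = 0.01)
  expect_equal(f2[["RMS_t_z_2"]], f[["RMS_t_z_2"]], tolerance = 0.01)
})

test_that("feature tables assemble one complete row per session", {
  coh <- signal_cohort()
  tab <- assemble_feature_table(coh)
  expect_s3_class(tab, "vo2_feature_table")
  expect_equal(nrow(tab), length(coh))
  expect_identical(setdiff(names(tab), c("subject_id", "test_label",
                                         "session_id", "vo2max")),
                   feature_registry())
  # descriptive columns copied verbatim
  expect_equal(tab$G, vapply(coh, function(s) s$subject$gender, numeric(1)))
  expect_equal(tab$BM, vapply(coh, function(s) s$subject$body_mass,
                              numeric(1)))
  # order invariance
  tab2 <- assemble_feature_table(rev(coh))
  expect_equal(tab2[order(tab2$session_id), ],
               tab[order(tab$session_id), ], ignore_attr = TRUE)
  expect_error(assemble_feature_table(coh[1]), "at least 2")
})
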