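#' Configuration for the synthetic treadmill-session generator
#'
#' The defaults encode the cohort the pipeline was designed around:
#' 28 recreational runners (12 men, 16 women), pooled true VO2max
#' 46.73 +/- 6.51 ml/kg/min, gender-specific body mass 75.34 / 61.55 kg,
#' and 13/28 of subjects returning for a second ("post") test so that the
#' pre/post grouping has two levels. Accelerometry is nominally sampled at
#' 1024 Hz with a +/-16 g range.
#'
#' The strength of the planted links between true VO2max and the observable
#' signals (warm-up heart-rate steady state, tibia acceleration variance) is
#' not an empirically reported quantity; the gains and link noise below are
#' free parameters of the stated simulation world (see the methods vignette).
#'
#' @param n_subjects number of subjects (>= 2; leave-one-subject-out needs 2).
#' @param frac_second_test fraction of subjects with a second (post) test.
#' @param vo2max_mean,vo2max_sd pooled true VO2max moments, ml/kg/min.
#' @param sex_ratio proportion of male subjects.
#' @param bm_mean_male,bm_mean_female,bm_sd body-mass distribution, kg.
#' @param hr0inv_mean,hr0inv_sd distribution of the subject-level inverse
#'   warm-up heart-rate steady state, 1/bpm (default centre 1/165).
#' @param hr0inv_day_sd day-to-day (per-session) jitter of that latent.
#' @param varinv_mean,varinv_sd distribution of the subject-level inverse
#'   warm-up tibia total-acceleration variance, 1/g^2.
#' @param varinv_day_sd per-session jitter of the variance latent.
#' @param coef_g,coef_bm,coef_hr0inv,coef_varinv0 coefficients of the linear
#'   truth model (defaults: the published full-data predictor values).
#' @param noise_sd_accel accelerometer noise sd, g.
#' @param noise_sd_hr,noise_sd_vo2 breath-sample noise sds (bpm, ml/kg/min).
#' @param post_shift VO2max change from pre to post test, ml/kg/min.
#' @param test_intercept_sd sd of the shared test-level (pre/post) intercept.
#' @param tilt_deg_max maximal sensor mounting tilt, degrees.
#' @param impact_width_s duration of the per-step tibia impact transient, s.
#' @param label_noise_sd measurement noise on the analytic VO2max label used
#'   for signal-free ("stub") cohorts.
#' @param sampling_rate accelerometer rate, Hz (> 100).
#' @param seed root seed; every random draw in a cohort flows from it.
#' @return a list of class `vo2_generator_config`.
#' @export
generator_config <- function(n_subjects = 28,
                             frac_second_test = 13 / 28,
                             vo2max_mean = 46.73,
                             vo2max_sd = 6.51,
                             sex_ratio = 12 / 28,
                             bm_mean_male = 75.34,
                             bm_mean_female = 61.55,
                             bm_sd = 9.2,
                             hr0inv_mean = 1 / 165,
                             hr0inv_sd = 5.1e-4,
                             hr0inv_day_sd = 5e-5,
                             varinv_mean = 2.7,
                             varinv_sd = 0.58,
                             varinv_day_sd = 0.06,
                             coef_g = -8.861,
                             coef_bm = -0.2538,
                             coef_hr0inv = 5546,
                             coef_varinv0 = 4.879,
                             noise_sd_accel = 0.05,
                             noise_sd_hr = 2.0,
                             noise_sd_vo2 = 1.5,
                             post_shift = 2.0,
                             test_intercept_sd = 1.0,
                             tilt_deg_max = 5,
                             impact_width_s = 0.08,
                             label_noise_sd = 0.6,
                             sampling_rate = 1024,
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              frac_second_test = frac_second_test,
              vo2max_mean = vo2max_mean, vo2max_sd = vo2max_sd,
              sex_ratio = sex_ratio,
              bm_mean_male = bm_mean_male, bm_mean_female = bm_mean_female,
              bm_sd = bm_sd,
              hr0inv_mean = hr0inv_mean, hr0inv_sd = hr0inv_sd,
              hr0inv_day_sd = hr0inv_day_sd,
              varinv_mean = varinv_mean, varinv_sd = varinv_sd,
              varinv_day_sd = varinv_day_sd,
              coef_g = coef_g, coef_bm = coef_bm,
              coef_hr0inv = coef_hr0inv, coef_varinv0 = coef_varinv0,
              noise_sd_accel = noise_sd_accel,
              noise_sd_hr = noise_sd_hr, noise_sd_vo2 = noise_sd_vo2,
              post_shift = post_shift, test_intercept_sd = test_intercept_sd,
              tilt_deg_max = tilt_deg_max, impact_width_s = impact_width_s,
              label_noise_sd = label_noise_sd,
              sampling_rate = sampling_rate, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "vo2_generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 2) {
    stop("invalid-config: n_subjects must be >= 2 (LOSO needs 2 subjects)")
  }
  if (cfg$frac_second_test < 0 || cfg$frac_second_test > 1) {
    stop("invalid-config: frac_second_test must lie in [0, 1]")
  }
  sds <- c(cfg$vo2max_sd, cfg$bm_sd, cfg$hr0inv_sd, cfg$hr0inv_day_sd,
           cfg$varinv_sd, cfg$varinv_day_sd,
           cfg$noise_sd_accel, cfg$noise_sd_hr, cfg$noise_sd_vo2,
           cfg$test_intercept_sd, cfg$label_noise_sd)
  if (any(sds < 0)) stop("invalid-config: all sd parameters must be >= 0")
  if (cfg$sampling_rate <= 100) {
    stop("invalid-config: sampling_rate must exceed 100 Hz")
  }
  invisible(cfg)
}

#' Protocol of the incremental treadmill test
#'
#' A 4-minute warm-up (8 km/h for women, 9 km/h for men), then 4-minute
#' stages separated by 1 minute of rest. The first stage repeats the warm-up
#' speed and every later stage adds 1.5 km/h; the gradient is fixed at 1%.
#'
#' @param warmup_speed km/h; `NULL` selects 9 (men) / 8 (women) per subject.
#' @param stage_duration stage length, s.
#' @param rest_duration rest between stages, s.
#' @param speed_increment km/h added per stage beyond the first.
#' @param n_stages number of stages generated beyond the warm-up (>= 3).
#' @param gradient treadmill gradient, %.
#' @export
protocol_spec <- function(warmup_speed = NULL, stage_duration = 240,
                          rest_duration = 60, speed_increment = 1.5,
                          n_stages = 4, gradient = 1) {
  if (stage_duration <= 0 || rest_duration <= 0 || speed_increment <= 0) {
    stop("invalid-config: protocol durations and increment must be > 0")
  }
  if (n_stages < 3) {
    stop("invalid-config: need at least 4 stages including the warm-up")
  }
  structure(list(warmup_speed = warmup_speed,
                 stage_duration = stage_duration,
                 rest_duration = rest_duration,
                 speed_increment = speed_increment,
                 n_stages = as.integer(n_stages),
                 gradient = gradient),
            class = "vo2_protocol")
}

# stage windows for one subject: index 0 = warm-up, contiguous stages
# separated by rests; stage 1 repeats the warm-up speed
protocol_stages <- function(protocol, gender) {
  ws <- protocol$warmup_speed
  if (is.null(ws)) ws <- if (gender == 0) 9 else 8
  k <- protocol$n_stages
  idx <- 0:k
  speeds <- ws + pmax(0, idx - 1) * protocol$speed_increment
  starts <- idx * (protocol$stage_duration + protocol$rest_duration)
  data.frame(index = idx, start = starts,
             end = starts + protocol$stage_duration, speed = speeds)
}

#' Generate a synthetic cohort of treadmill sessions
#'
#' Draws subject descriptors and the per-session planted truth (the session's
#' true VO2max, the heart-rate and tibia-variance link values) under a single
#' root seed. Cohort-level draws consume the root stream in a fixed order and
#' each session gets its own derived seed, so a cohort is reproducible
#' whether or not raw signals are synthesized.
#'
#' With `signals = FALSE` (the default) the sessions are lightweight stubs:
#' subject, stage windows and planted truth, plus an analytic VO2max label.
#' With `signals = TRUE` every session additionally carries breath-by-breath
#' VO2/HR samples and triaxial acceleration at the tibia (`t`), lower back
#' (`bl`) and upper back (`bu`).
#'
#' @param config a [generator_config()].
#' @param protocol a [protocol_spec()].
#' @param signals synthesize raw signals? Stubs are cheap; signals at the
#'   default 1024 Hz cost ~100 MB per session.
#' @return list of `vo2_session` objects, class `vo2_cohort`.
#' @export
generate_cohort <- function(config = generator_config(),
                            protocol = protocol_spec(),
                            signals = FALSE) {
  validate_generator_config(config)
  n <- config$n_subjects
  set.seed(config$seed)

  # deterministic gender split (round(sex_ratio * n) males, permuted):
  # guarantees the cohort ratio and keeps every leave-one-subject-out
  # training fold gender-mixed for n >= 5
  n_male <- round(config$sex_ratio * n)
  gender <- sample(rep(c(0L, 1L), c(n_male, n - n_male)))
  bm_mean <- ifelse(gender == 0, config$bm_mean_male, config$bm_mean_female)
  body_mass <- stats::rnorm(n, bm_mean, config$bm_sd)

  # feature-first truth: subject-level wearable latents (inverse warm-up
  # heart rate, inverse warm-up tibia variance), then
  #   vo2max_true = b0 + cG*G + cBM*(BM - gender mean)
  #               + cH*(hr0inv - mu_H) + cV*(varinv - mu_V) + eps
  # with b0 and sd(eps) derived so the pooled marginal has exactly the
  # configured mean and sd
  tm <- truth_model(config)
  hr0inv <- stats::rnorm(n, config$hr0inv_mean, config$hr0inv_sd)
  varinv <- pmax(0.08, stats::rnorm(n, config$varinv_mean, config$varinv_sd))
  eps <- stats::rnorm(n, 0, tm$sd_eps)
  vo2_of <- function(i) {
    tm$b0 + config$coef_g * gender[i] +
      config$coef_bm * (body_mass[i] - bm_mean[i]) +
      config$coef_hr0inv * (hr0inv[i] - config$hr0inv_mean) +
      config$coef_varinv0 * (varinv[i] - config$varinv_mean) + eps[i]
  }
  vo2 <- vo2_of(seq_len(n))
  low <- which(vo2 < 20)
  while (length(low)) {  # truncation at 20 by rejection (seed-deterministic)
    hr0inv[low] <- stats::rnorm(length(low), config$hr0inv_mean,
                                config$hr0inv_sd)
    varinv[low] <- pmax(0.08, stats::rnorm(length(low), config$varinv_mean,
                                           config$varinv_sd))
    eps[low] <- stats::rnorm(length(low), 0, tm$sd_eps)
    vo2[low] <- vo2_of(low)
    low <- low[vo2[low] < 20]
  }

  has_post <- stats::runif(n) < config$frac_second_test
  b_test <- stats::rnorm(2, 0, config$test_intercept_sd)
  names(b_test) <- c("pre", "post")

  n_sessions <- n + sum(has_post)
  session_seed <- sample.int(.Machine$integer.max - 1L, n_sessions)

  sessions <- vector("list", n_sessions)
  si <- 0L
  for (i in seq_len(n)) {
    labels <- if (has_post[i]) c("pre", "post") else "pre"
    for (lab in labels) {
      si <- si + 1L
      subject <- list(subject_id = sprintf("S%03d", i),
                      gender = gender[i],
                      body_mass = body_mass[i],
                      vo2max_true = vo2[i],
                      test_label = lab,
                      hr0inv = hr0inv[i],
                      varinv = varinv[i])
      stub <- session_stub(subject, protocol, config,
                           seed = session_seed[si], b_test = b_test)
      sessions[[si]] <- if (signals) {
        generate_session(subject, protocol, config,
                         seed = session_seed[si], b_test = b_test)
      } else stub
    }
  }
  structure(sessions, class = "vo2_cohort")
}

# derived constants of the linear truth model: intercept and residual sd
# chosen so the pooled marginal of vo2max_true has the configured moments
truth_model <- function(config) {
  p <- config$sex_ratio
  fixed_var <- config$coef_g^2 * p * (1 - p) +
    config$coef_bm^2 * config$bm_sd^2 +
    config$coef_hr0inv^2 * config$hr0inv_sd^2 +
    config$coef_varinv0^2 * config$varinv_sd^2
  list(b0 = config$vo2max_mean - config$coef_g * (1 - p),
       sd_eps = sqrt(max(0, config$vo2max_sd^2 - fixed_var)))
}

# planted per-session truth; must be the FIRST draws under the session seed
# so that stub and full sessions agree
draw_session_truth <- function(subject, config, b_test, n_stages = 4) {
  is_post <- identical(subject$test_label, "post")
  cH <- config$coef_hr0inv
  cV <- config$coef_varinv0
  hr0inv_subj <- if (!is.null(subject$hr0inv)) subject$hr0inv else
    config$hr0inv_mean
  varinv_subj <- if (!is.null(subject$varinv)) subject$varinv else
    config$varinv_mean
  # the post-test fitness gain flows through the wearable latents (half of
  # the VO2max shift via each), keeping the truth exactly linear in the
  # session's feature values; day-to-day jitter moves fitness the same way
  shift_h <- if (is_post) (config$post_shift / 2) / cH else 0
  shift_v <- if (is_post) (config$post_shift / 2) / cV else 0
  hr0inv_s <- hr0inv_subj + shift_h + stats::rnorm(1, 0, config$hr0inv_day_sd)
  hr0inv_s <- min(1 / 100, max(1 / 220, hr0inv_s))
  varinv_s <- max(0.08, varinv_subj + shift_v +
                    stats::rnorm(1, 0, config$varinv_day_sd))
  v_fit <- subject$vo2max_true +
    cH * (hr0inv_s - hr0inv_subj) + cV * (varinv_s - varinv_subj)
  v_session <- v_fit + b_test[[subject$test_label]]
  hrss0 <- 1 / hr0inv_s
  varinv0 <- varinv_s
  a2 <- stats::runif(1, 0.25, 0.5)    # second-harmonic weight of COM accel
  duty <- contact_duty(a2)            # closed-form ground-contact fraction
  # stage-level physiological variability grows with intensity, so the
  # warm-up (stage 0) carries the cleanest link to VO2max
  idx <- 0:n_stages
  hrss_stage <- pmin(200, hrss0 + 12 * idx +
                       c(0, stats::rnorm(n_stages, 0,
                                         pmin(6 + 2 * idx[-1], 12))))
  tibia_stage_gain <- (1 + 0.05 * idx) *
    c(1, exp(stats::rnorm(n_stages, 0, 0.3)))
  list(v_fit = v_fit, vo2max_session = v_session,
       hrss0 = hrss0, varinv0 = varinv0, a2 = a2, duty = duty,
       hrss_stage = hrss_stage, tibia_stage_gain = tibia_stage_gain,
       b_test = b_test[[subject$test_label]])
}

# stance fraction of the two-harmonic COM waveform sin(th) + a2*cos(2*th):
# the positive phase spans pi + 2*asin(-s*) radians where s* is the negative
# root of -2*a2*s^2 + s + a2 = 0
contact_duty <- function(a2) {
  s <- (1 - sqrt(1 + 8 * a2^2)) / (4 * a2)
  (pi + 2 * asin(-s)) / (2 * pi)
}

session_stub <- function(subject, protocol, config, seed, b_test) {
  set.seed(seed)
  truth <- draw_session_truth(subject, config, b_test, protocol$n_stages)
  label <- truth$vo2max_session + stats::rnorm(1, 0, config$label_noise_sd)
  structure(list(subject = subject,
                 protocol = protocol,
                 stages = protocol_stages(protocol, subject$gender),
                 breath = NULL, accel = NULL,
                 vo2max_measured = label,
                 truth = truth, seed = seed),
            class = "vo2_session")
}

#' Generate one synthetic treadmill session with raw signals
#'
#' Breath-by-breath VO2 and heart rate follow first-order kinetics toward
#' stage-specific steady states (VO2 plateauing at the session's true VO2max
#' in the final stages; heart rate tied inversely to VO2max during warm-up).
#' Acceleration is a step-frequency-locked periodic template per stage plus,
#' at the tibia, a half-sine impact transient per step; tibia channels are
#' scaled so the warm-up variance of the total acceleration equals the
#' planted inverse-variance link. The vertical channel carries +1 g and an
#' optional mounting tilt so that tilt correction is exercised.
#'
#' @param subject list with `subject_id`, `gender` (0 = male, 1 = female),
#'   `body_mass` (kg), `vo2max_true` (ml/kg/min), `test_label` (pre/post).
#' @param protocol a [protocol_spec()].
#' @param config a [generator_config()].
#' @param seed session seed (defaults to `config$seed`).
#' @param b_test named pre/post test-level intercepts; defaults to zero.
#' @return a `vo2_session` with breath series and triaxial acceleration at
#'   locations `t`, `bl`, `bu`.
#' @export
generate_session <- function(subject, protocol = protocol_spec(),
                             config = generator_config(),
                             seed = config$seed,
                             b_test = c(pre = 0, post = 0)) {
  if (protocol$n_stages < 3) {
    stop("invalid-config: need at least 4 stages including the warm-up")
  }
  set.seed(seed)
  truth <- draw_session_truth(subject, config, b_test, protocol$n_stages)
  stages <- protocol_stages(protocol, subject$gender)
  total <- stages$end[nrow(stages)]

  breath <- synth_breath(stages, truth, config, total)
  accel <- synth_accel(stages, truth, config, total)

  structure(list(subject = subject, protocol = protocol, stages = stages,
                 breath = breath, accel = accel,
                 vo2max_measured = NULL, truth = truth, seed = seed),
            class = "vo2_session")
}

# piecewise-exponential relaxation toward per-segment targets, evaluated at
# arbitrary times; used for both VO2 and HR kinetics
relax_profile <- function(tt, segments, init) {
  out <- numeric(length(tt))
  entry <- init
  for (s in seq_len(nrow(segments))) {
    t0 <- segments$t0[s]; t1 <- segments$t1[s]
    target <- segments$target[s]; tau <- segments$tau[s]
    sel <- tt >= t0 & tt < t1
    if (s == nrow(segments)) sel <- tt >= t0 & tt <= t1
    out[sel] <- target + (entry - target) * exp(-(tt[sel] - t0) / tau)
    entry <- target + (entry - target) * exp(-(t1 - t0) / tau)
  }
  out
}

# stage/rest segment tables for the two profiles
kinetic_segments <- function(stages, truth, what) {
  k <- nrow(stages) - 1
  frac <- c(seq(0.55, 0.98, length.out = k), 1.0)
  hrss <- truth$hrss_stage[stages$index + 1]
  seg <- NULL
  for (i in seq_len(nrow(stages))) {
    tgt <- if (what == "vo2") frac[i] * truth$vo2max_session else hrss[i]
    tau <- if (what == "vo2") 25 else 30
    seg <- rbind(seg, data.frame(t0 = stages$start[i], t1 = stages$end[i],
                                 target = tgt, tau = tau))
    if (i < nrow(stages)) {
      rtgt <- if (what == "vo2") 0.3 * truth$vo2max_session else 100
      rtau <- if (what == "vo2") 35 else 45
      seg <- rbind(seg, data.frame(t0 = stages$end[i],
                                   t1 = stages$start[i + 1],
                                   target = rtgt, tau = rtau))
    }
  }
  seg
}

synth_breath <- function(stages, truth, config, total) {
  n_max <- ceiling(total / 2.5)
  dts <- 4 + stats::runif(n_max, -1, 1)  # jittered ~4 s inter-breath interval
  tt <- cumsum(dts)
  tt <- tt[tt <= total]
  vo2 <- relax_profile(tt, kinetic_segments(stages, truth, "vo2"),
                       init = 0.2 * truth$vo2max_session) +
    stats::rnorm(length(tt), 0, config$noise_sd_vo2)
  hr <- relax_profile(tt, kinetic_segments(stages, truth, "hr"), init = 80) +
    stats::rnorm(length(tt), 0, config$noise_sd_hr)
  data.frame(t = tt, vo2 = pmax(0, vo2), hr = pmin(240, pmax(30, hr)))
}

# step frequency rises weakly with treadmill speed (~2.6 Hz at 8 km/h)
step_frequency <- function(speed) 2.2 + 0.05 * speed

synth_accel <- function(stages, truth, config, total) {
  rate <- config$sampling_rate
  n <- floor(total * rate) + 1
  tt <- (seq_len(n) - 1) / rate
  wf <- config$impact_width_s

  run_templates <- function(spec) {
    # spec: function(theta, f, stage_i) -> n x 3 matrix (corrected space)
    out <- matrix(0, n, 3)
    for (i in seq_len(nrow(stages))) {
      sel <- which(tt >= stages$start[i] & tt <= stages$end[i])
      f <- step_frequency(stages$speed[i])
      theta <- 2 * pi * f * (tt[sel] - stages$start[i])
      m <- spec(theta, f, stages$index[i])
      m <- sweep(m, 2, colMeans(m))  # zero-mean running segments
      out[sel, ] <- m
    }
    out
  }

  impact <- function(theta, f) {
    ph <- (theta / (2 * pi)) %% 1
    w <- wf * f
    ifelse(ph < w, sin(pi * ph / w), 0)
  }

  tib <- run_templates(function(theta, f, i) {
    g <- truth$tibia_stage_gain[i + 1]
    imp <- impact(theta, f)
    cbind(g * (0.3 * sin(theta) + 0.4 * imp),
          g * 0.25 * sin(theta + 1.0),
          g * (0.5 * sin(theta) + imp))
  })
  # scale tibia so warm-up Var(total accel) hits the planted link exactly
  w0 <- which(tt >= stages$start[1] + 10 & tt <= stages$end[1] - 10)
  v0 <- stats::var(sqrt(rowSums(tib[w0, ]^2)))
  tib <- tib * sqrt((1 / truth$varinv0) / v0)

  a2 <- truth$a2
  bl <- run_templates(function(theta, f, i) {
    cbind(0.2 * sin(theta),
          0.18 * sin(theta + 0.7),
          0.8 * (sin(theta) + a2 * cos(2 * theta)))
  })
  bu <- run_templates(function(theta, f, i) {
    cbind(0.15 * sin(theta),
          0.12 * sin(theta + 0.5),
          0.5 * sin(theta) + 0.1 * cos(2 * theta))
  })

  finish <- function(m) {
    m <- m + matrix(stats::rnorm(length(m), 0, config$noise_sd_accel), n, 3)
    m[, 3] <- m[, 3] + 1  # static gravity on the vertical axis
    if (config$tilt_deg_max > 0) {
      ang <- stats::runif(2, -config$tilt_deg_max, config$tilt_deg_max) *
        pi / 180
      m <- m %*% t(rot_x(ang[2]) %*% rot_y(ang[1]))
    }
    m[m > 16] <- 16
    m[m < -16] <- -16
    uniform_signal(m, rate = rate, start = 0, labels = c("x", "y", "z"))
  }
  list(t = finish(tib), bl = finish(bl), bu = finish(bu))
}

rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)

#' Ground-truth table of a synthetic cohort
#'
#' One row per session with the subject's true VO2max, the session-level
#' value (including the post-test shift and the shared test intercept) and
#' the planted link values used by recovery tests: the analytic warm-up
#' heart-rate steady state and the inverse tibia-acceleration variance.
#'
#' @param cohort a list of sessions from [generate_cohort()].
#' @return data.frame with one row per session.
#' @export
ground_truth_table <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    data.frame(session_id = session_id(s),
               subject_id = s$subject$subject_id,
               test_label = s$subject$test_label,
               gender = s$subject$gender,
               body_mass = s$subject$body_mass,
               vo2max_true = s$subject$vo2max_true,
               vo2max_session = s$truth$vo2max_session,
               hrss0 = s$truth$hrss0,
               varinv0 = s$truth$varinv0,
               duty = s$truth$duty)
  })
  do.call(rbind, rows)
}

#' @export
session_id <- function(session) {
  paste(session$subject$subject_id, session$subject$test_label, sep = "_")
}

#' @export
print.vo2_session <- function(x, ...) {
  cat(sprintf("<vo2_session> %s: %s, %.1f kg, true VO2max %.1f, %d stages%s\n",
              session_id(x), if (x$subject$gender == 0) "male" else "female",
              x$subject$body_mass, x$subject$vo2max_true,
              nrow(x$stages),
              if (is.null(x$accel)) " (stub)" else ""))
  invisible(x)
}
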