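# Session directory layout:
#   meta.json          subject, protocol, stage windows, truth (if synthetic),
#                      accel rates/starts, vo2max_measured
#   breath.csv         t_s, vo2, hr
#   acc_<loc>.csv      t_s, ax, ay, az   for loc in t, bl, bu
# All numbers are written with 17 significant digits so sessions round-trip
# at full double precision.

fmt_num <- function(x) sprintf("%.17g", x)

write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a session directory
#'
#' @param session a `vo2_session` (raw or preprocessed; raw layout is
#'   written).
#' @param dir directory to create/read.
#' @return `read_session` returns a `vo2_session`; `write_session` the
#'   directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(subject = session$subject,
               protocol = unclass(session$protocol),
               stages = session$stages,
               vo2max_measured = session$vo2max_measured,
               truth = session$truth,
               seed = session$seed,
               accel_meta = lapply(session$accel, function(s) {
                 list(rate = s$rate, start = s$start)
               }))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  if (!is.null(session$breath)) {
    write_num_csv(data.frame(t_s = session$breath$t, vo2 = session$breath$vo2,
                             hr = session$breath$hr),
                  file.path(dir, "breath.csv"))
  }
  for (l in names(session$accel)) {
    sig <- session$accel[[l]]
    write_num_csv(data.frame(t_s = signal_times(sig), ax = sig$data[, 1],
                             ay = sig$data[, 2], az = sig$data[, 3]),
                  file.path(dir, paste0("acc_", l, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_session
#' @param locations accelerometer locations expected on disk.
#' @export
read_session <- function(dir, locations = c("t", "bl", "bu")) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("schema error: missing file meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  breath <- NULL
  bpath <- file.path(dir, "breath.csv")
  if (file.exists(bpath)) {
    b <- utils::read.csv(bpath)
    need <- c("t_s", "vo2", "hr")
    if (!all(need %in% names(b))) {
      stop("schema error: breath.csv lacks columns ",
           paste(setdiff(need, names(b)), collapse = ", "))
    }
    if (any(diff(b$t_s) <= 0)) {
      stop("validation error: non-monotone timestamps in breath.csv")
    }
    breath <- data.frame(t = b$t_s, vo2 = b$vo2, hr = b$hr)
  }
  accel <- list()
  for (l in locations) {
    apath <- file.path(dir, paste0("acc_", l, ".csv"))
    if (!file.exists(apath)) {
      stop("schema error: missing channel file acc_", l, ".csv")
    }
    a <- utils::read.csv(apath)
    need <- c("t_s", "ax", "ay", "az")
    if (!all(need %in% names(a))) {
      stop("schema error: acc_", l, ".csv lacks columns ",
           paste(setdiff(need, names(a)), collapse = ", "))
    }
    if (any(diff(a$t_s) <= 0)) {
      stop("validation error: non-monotone timestamps in acc_", l, ".csv")
    }
    am <- meta$accel_meta[[l]]
    rate <- if (!is.null(am)) am$rate else 1 / stats::median(diff(a$t_s))
    start <- if (!is.null(am)) am$start else a$t_s[1]
    accel[[l]] <- uniform_signal(cbind(x = a$ax, y = a$ay, z = a$az),
                                 rate = rate, start = start)
  }
  protocol <- meta$protocol
  class(protocol) <- "vo2_protocol"
  truth <- meta$truth
  structure(list(subject = meta$subject, protocol = protocol,
                 stages = as.data.frame(meta$stages),
                 breath = breath, accel = accel,
                 vo2max_measured = meta$vo2max_measured,
                 truth = truth, seed = meta$seed),
            class = "vo2_session")
}

#' Write a feature table as CSV (stable column order)
#'
#' @param table a `vo2_feature_table`.
#' @param path output CSV.
#' @export
write_feature_table <- function(table, path) {
  write_num_csv_mixed(table, path)
  invisible(path)
}

write_num_csv_mixed <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }), check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  class(tab) <- c("vo2_feature_table", "data.frame")
  tab
}
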