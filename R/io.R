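# File formats and the pipeline runner. All CSV schemas have fixed headers;
# JSON documents carry a schema_version and are rejected, not coerced, on
# unknown versions.

.schema_version <- "1.0"

.check_uniform_time <- function(time_s, tol = 1e-6) {
  if (length(time_s) > 1) {
    d <- diff(time_s)
    bad <- which(d <= 0)
    if (length(bad)) {
      stop("time_s not strictly increasing at data line ", bad[1] + 1L)
    }
    if ((max(d) - min(d)) > tol * stats::median(d)) {
      stop("non-uniform sampling: time steps vary beyond tolerance")
    }
  }
  invisible(TRUE)
}

.fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write hand-force CSV traces
#'
#' Plain CSV with header `time_s,force_n`; full-precision round trip.
#' Reading checks the header, strictly increasing time and uniform
#' sampling.
#'
#' @param path File path.
#' @param trace A [force_trace()].
#' @return `read_force_csv()` returns a [force_trace()];
#'   `write_force_csv()` returns `path` invisibly.
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("time_s", "force_n")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed force CSV: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  .check_uniform_time(df$time_s)
  rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else NA_real_
  force_trace(df$time_s, df$force_n, rate)
}

#' @rdname read_force_csv
#' @export
write_force_csv <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  df <- data.frame(time_s = .fmt_num(trace$time_s),
                   force_n = .fmt_num(trace$force_n))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write EAA command CSV traces
#'
#' Plain CSV with header `time_s,r_e,a_e`. Inactive (stimulation-off)
#' samples are stored with empty `r_e` and `a_e = 0`; on reading, a sample
#' is active iff `a_e > 0`.
#'
#' @param path File path.
#' @param trace An [eaa_trace()].
#' @param period Optional dominant period in s to attach on reading.
#' @return `read_eaa_csv()` returns an [eaa_trace()]; `write_eaa_csv()`
#'   returns `path` invisibly.
#' @export
read_eaa_csv <- function(path, period = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("time_s", "r_e", "a_e")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed EAA CSV: missing column(s) ", paste(miss, collapse = ", "))
  }
  .check_uniform_time(df$time_s)
  rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else NA_real_
  eaa_trace(df$time_s, df$r_e, df$a_e, active = df$a_e > 0,
            sample_rate = rate, period = period)
}

#' @rdname read_eaa_csv
#' @export
write_eaa_csv <- function(trace, path) {
  stopifnot(inherits(trace, "eaa_trace"))
  df <- data.frame(time_s = .fmt_num(trace$time_s),
                   r_e = ifelse(is.na(trace$r_e), "", .fmt_num(trace$r_e)),
                   a_e = .fmt_num(trace$a_e))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write subject calibrations as JSON
#'
#' Versioned JSON mirroring the calibration table: `subject_id`, and
#' per-muscle `i_max_ma` / `i_min_ma` under `flexor` and `extensor`.
#'
#' @param cal A [subject_calibration()].
#' @param path File path.
#' @return `read_calibration()` returns a [subject_calibration()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "subject_calibration"))
  jsonlite::write_json(list(
    schema_version = .schema_version,
    subject_id = cal$subject_id,
    flexor = list(i_max_ma = cal$flexor$i_max_ma,
                  i_min_ma = cal$flexor$i_min_ma),
    extensor = list(i_max_ma = cal$extensor$i_max_ma,
                    i_min_ma = cal$extensor$i_min_ma)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$schema_version) || x$schema_version != .schema_version) {
    stop("unknown calibration schema version: ",
         if (is.null(x$schema_version)) "<missing>" else x$schema_version)
  }
  subject_calibration(
    flexor = muscle_calibration(x$flexor$i_max_ma, x$flexor$i_min_ma),
    extensor = muscle_calibration(x$extensor$i_max_ma, x$extensor$i_min_ma),
    subject_id = if (is.null(x$subject_id)) "" else x$subject_id)
}

#' Read and write SOPDT models as JSON
#'
#' Versioned JSON with fields `k` (N per unit ratio), `omega_n` (rad/s),
#' `zeta`, `tau` (s).
#'
#' @param model An [sopdt_model()].
#' @param path File path.
#' @return `read_model_json()` returns an [sopdt_model()];
#'   `write_model_json()` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "sopdt_model"))
  jsonlite::write_json(list(
    schema_version = .schema_version,
    k = model$k, omega_n = model$omega_n, zeta = model$zeta,
    tau = model$tau),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$schema_version) || x$schema_version != .schema_version) {
    stop("unknown model schema version: ",
         if (is.null(x$schema_version)) "<missing>" else x$schema_version)
  }
  sopdt_model(x$k, x$omega_n, x$zeta, x$tau)
}

#' Run the full synthetic study end to end
#'
#' Samples a virtual subject, identifies its SOPDT model over the standard
#' period grid, runs the three verification experiments, and (optionally)
#' writes all artifacts: `subject.json` (ground truth and configuration),
#' `model.json`, `bode.csv`, `harmonic_fits.csv`, `reports.json` and
#' `manifest.json`. Fully deterministic given `seed`: the subject, every
#' trial noise stream, and therefore every output derive from it.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param noise_sd Measurement-noise SD in N (default 0.5).
#' @param periods Probe periods (default [frequency_grid()]).
#' @param n_trials Replicate trials per period (default 3).
#' @param quiet Suppress per-stage messages.
#' @return A list with `subject`, `identification`, `model`, `reports`
#'   (one [run_verification()] report per experiment), and `config`.
#' @export
run_pipeline <- function(seed, out_dir = NULL, noise_sd = 0.5,
                         periods = frequency_grid(), n_trials = 3,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  config <- list(seed = as.integer(seed), noise_sd = noise_sd,
                 periods = periods, n_trials = n_trials,
                 sample_rate = 1000,
                 package_version = as.character(utils::packageVersion("eaafes")),
                 schema_version = .schema_version)
  say("stage 1/3: sampling virtual subject (seed %d)", seed)
  subject <- sample_subject(seed, noise_sd = noise_sd)
  say("stage 2/3: identifying SOPDT model over %d periods", length(periods))
  ident <- identify_subject(subject, periods = periods, n_trials = n_trials,
                            seed = seed)
  say("stage 3/3: verification experiments")
  reports <- lapply(c("continuous", "stepwise", "voluntary"),
                    function(e) run_verification(subject, ident$model, e,
                                                 seed = seed))
  names(reports) <- c("continuous", "stepwise", "voluntary")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(
      schema_version = .schema_version,
      subject_id = subject$calibration$subject_id,
      ground_truth = list(k = subject$plant$k,
                          omega_n = subject$plant$omega_n,
                          zeta = subject$plant$zeta,
                          tau = subject$plant$tau),
      noise_sd = subject$noise_sd, seed = subject$seed),
      file.path(out_dir, "subject.json"), auto_unbox = TRUE, digits = NA)
    write_model_json(ident$model, file.path(out_dir, "model.json"))
    utils::write.csv(
      data.frame(omega_rad_s = ident$bode$omega,
                 gain_db = ident$bode$gain_db,
                 phase_rad = ident$bode$phase),
      file.path(out_dir, "bode.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(period_s = vapply(ident$fits, `[[`, numeric(1), "period"),
                 amplitude_n = vapply(ident$fits, `[[`, numeric(1), "amplitude"),
                 phase_rad = vapply(ident$fits, `[[`, numeric(1), "phase"),
                 offset_n = vapply(ident$fits, `[[`, numeric(1), "offset"),
                 r_squared = vapply(ident$fits, `[[`, numeric(1), "r_squared")),
      file.path(out_dir, "harmonic_fits.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(reports, function(r) list(
      experiment = r$experiment, r_squared = r$r_squared,
      r_squared_full = r$r_squared_full,
      max_abs_error = r$max_abs_error, segment = r$segment)),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(config, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(subject = subject, identification = ident, model = ident$model,
       reports = reports, config = config)
}
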