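# Validation: model predictions scored against "measured" virtual-subject
# force traces with the multiple coefficient of determination and maximum
# absolute error, for the three verification protocols (continuous
# composite input, stepwise input, bursts on a voluntary baseline).

#' Multiple coefficient of determination between traces
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the measured mean. Equals 1 for a perfect prediction, 0 for a
#' constant prediction at the measured mean, and can be negative.
#'
#' @param estimated Model-predicted trace ([force_trace()] or numeric).
#' @param measured Measured trace, same length.
#' @return \eqn{R^2} (dimensionless, \eqn{\le 1}).
#' @export
#' @examples
#' r_squared(c(1, 2, 4), c(1, 2, 3))  # 0.5
r_squared <- function(estimated, measured) {
  est <- if (inherits(estimated, "force_trace")) estimated$force_n else as.numeric(estimated)
  mea <- if (inherits(measured, "force_trace")) measured$force_n else as.numeric(measured)
  if (length(est) != length(mea)) stop("traces must have equal length")
  ss_tot <- sum((mea - mean(mea))^2)
  if (ss_tot == 0) stop("measured trace is constant: R^2 undefined (SS_tot = 0)")
  1 - sum((mea - est)^2) / ss_tot
}

#' Maximum absolute prediction error
#'
#' @inheritParams r_squared
#' @return Max |estimated - measured| in N.
#' @export
max_abs_error <- function(estimated, measured) {
  est <- if (inherits(estimated, "force_trace")) estimated$force_n else as.numeric(estimated)
  mea <- if (inherits(measured, "force_trace")) measured$force_n else as.numeric(measured)
  if (length(est) != length(mea)) stop("traces must have equal length")
  max(abs(est - mea))
}

# settled-window mask for a stepwise trace: the last `settle_s` seconds of
# each dwell
.step_settled_mask <- function(schedule, sample_rate, settle_s = 1) {
  n_dwell <- round(schedule$dwell * sample_rate)
  n_settle <- min(n_dwell, round(settle_s * sample_rate))
  rep(c(rep(FALSE, n_dwell - n_settle), rep(TRUE, n_settle)),
      length(schedule$levels))
}

#' Run a verification experiment on a virtual subject
#'
#' Reproduces one of the three hand-force verification protocols:
#' \describe{
#'   \item{`"continuous"`}{the two-period composite ratio input (0.6/0.4
#'     weights on 0.3/0.6 s periods); scored over one steady-state 0.6 s
#'     output cycle (the last full composite cycle).}
#'   \item{`"stepwise"`}{the 0.2-increment, 3 s dwell ratio staircase up
#'     and back down; scored over the settled final 1 s of each dwell.}
#'   \item{`"voluntary"`}{three 1 s sinusoidal bursts superimposed on a
#'     held voluntary force of `baseline_n` N; scored over the full trace.}
#' }
#' The "measured" trace is the trial-averaged subject response via
#' [run_protocol()]; the prediction is the model simulation of the same
#' command (plus the known baseline for `"voluntary"`). With a noiseless,
#' asymmetry-free subject and the subject's own plant as model, every
#' experiment scores \eqn{R^2 = 1}.
#'
#' @param subject A [virtual_subject()].
#' @param model The identified [sopdt_model()] used for prediction.
#' @param experiment One of `"continuous"`, `"stepwise"`, `"voluntary"`.
#' @param baseline_n Voluntary baseline in N for the `"voluntary"`
#'   experiment (default +10; use -10 for held flexion).
#' @param n_trials Trials averaged into the measured trace (default 3).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Noise-stream seed (default the subject's seed).
#' @return An object of class `validation_report`: `experiment`,
#'   `r_squared` (scored segment), `r_squared_full` (whole trace),
#'   `max_abs_error` (whole trace, N), `segment` (description), plus the
#'   traces (`measured`, `estimated`) and ids.
#' @export
run_verification <- function(subject, model,
                             experiment = c("continuous", "stepwise",
                                            "voluntary"),
                             baseline_n = 10, n_trials = 3,
                             sample_rate = 1000, seed = subject$seed) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(subject, "virtual_subject"),
            inherits(model, "sopdt_model"))
  if (experiment == "continuous") {
    trace <- composite_sinusoid(sample_rate = sample_rate)
    est <- sopdt_simulate(model, trace)
    subj_run <- subject
    segment <- "last full 0.6 s composite cycle"
    n_rep <- round(0.6 * sample_rate)
    n <- nrow(trace)
    seg_idx <- (n - n_rep + 1L):n
  } else if (experiment == "stepwise") {
    schedule <- step_schedule()
    trace <- step_trace(schedule, sample_rate)
    est <- sopdt_simulate(model, trace)
    subj_run <- subject
    segment <- "final 1 s of each 3 s dwell"
    seg_idx <- which(.step_settled_mask(schedule, sample_rate))
  } else {
    trace <- burst_trace(burst_spec(), sample_rate)
    est <- simulate_with_voluntary(model, trace, baseline_n)
    subj_run <- subject
    subj_run$baseline_force <- baseline_n
    segment <- "full trace"
    seg_idx <- seq_len(nrow(trace))
  }
  measured <- trial_average(run_protocol(subj_run, trace,
                                         n_trials = n_trials, seed = seed))
  structure(list(
    experiment = experiment,
    r_squared = r_squared(est$force_n[seg_idx], measured$force_n[seg_idx]),
    r_squared_full = r_squared(est$force_n, measured$force_n),
    max_abs_error = max_abs_error(est, measured),
    segment = segment,
    measured = measured, estimated = est, trace = trace,
    subject_id = subject$calibration$subject_id,
    model = model),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s experiment (subject '%s')\n",
              x$experiment, x$subject_id))
  cat(sprintf("  R^2 (%s): %.4f\n", x$segment, x$r_squared))
  cat(sprintf("  R^2 (full trace): %.4f, max |error| = %.3f N\n",
              x$r_squared_full, x$max_abs_error))
  invisible(x)
}
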