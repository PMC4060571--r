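# Synthetic virtual subject: a ground-truth SOPDT plant wrapped with the
# nonidealities of real measurements (sensor noise, flexor/extensor
# response-speed asymmetry, voluntary baseline force, activity-dependent
# stiffness), producing "measured" 1 kHz force traces from stimulation
# protocols.

#' Construct a virtual subject
#'
#' @param plant Ground-truth [sopdt_model()].
#' @param calibration A [subject_calibration()] (default the bundled
#'   subject-B calibration).
#' @param noise_sd Additive Gaussian measurement-noise SD in N at the 1 kHz
#'   sample level (default 0.5).
#' @param asymmetry Dimensionless \eqn{\ge 0}. Real recordings show the
#'   oscillation centre shifted toward extension when the input period is
#'   0.4 s or less, attributed to the extensor responding faster than the
#'   flexor. This generator reproduces that phenomenology with an explicitly
#'   synthetic rectified offset `asymmetry * K * max(0, 0.4 - T) / 0.4`
#'   added to the active-section force; it is not a mechanistic model.
#' @param baseline_force Voluntary hand force in N added to every sample
#'   (flexion negative).
#' @param omega_n_by_activity Optional monotone map from EAA activity to
#'   \eqn{\omega_n} (see [activity_omega_n_map()]); when present and the
#'   protocol runs at activity other than 1, the plant's natural frequency
#'   is substituted accordingly, and the effective gain scales with
#'   activity.
#' @param seed Integer seed governing the subject's noise draws.
#' @return An object of class `virtual_subject`.
#' @export
virtual_subject <- function(plant, calibration = example_calibration("B"),
                            noise_sd = 0.5, asymmetry = 0,
                            baseline_force = 0, omega_n_by_activity = NULL,
                            seed = 1L) {
  stopifnot(inherits(plant, "sopdt_model"),
            inherits(calibration, "subject_calibration"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (asymmetry < 0) stop("asymmetry must be >= 0")
  structure(list(plant = plant, calibration = calibration,
                 noise_sd = noise_sd, asymmetry = asymmetry,
                 baseline_force = baseline_force,
                 omega_n_by_activity = omega_n_by_activity,
                 seed = as.integer(seed)),
            class = "virtual_subject")
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat("<virtual_subject>\n  plant: ")
  print(x$plant)
  cat(sprintf("  noise_sd = %.3g N, asymmetry = %.3g, baseline = %.3g N, seed = %d\n",
              x$noise_sd, x$asymmetry, x$baseline_force, x$seed))
  invisible(x)
}

#' Piecewise-linear activity-to-omega_n map
#'
#' Interpolates \eqn{\omega_n} between anchor activity levels, clamped at
#' the extreme anchors. The default anchors are the bundled subject-A
#' triple ([activity_anchors()]).
#'
#' @param anchors Data frame with columns `a_e`, `omega_n`; `omega_n` must
#'   be nondecreasing in `a_e`.
#' @return A function `f(a_e)` returning \eqn{\omega_n} in rad/s.
#' @export
#' @examples
#' f <- activity_omega_n_map()
#' f(0.8)  # 19.0
activity_omega_n_map <- function(anchors = activity_anchors()) {
  stopifnot(is.data.frame(anchors), all(c("a_e", "omega_n") %in% names(anchors)))
  o <- order(anchors$a_e)
  a <- anchors$a_e[o]
  w <- anchors$omega_n[o]
  if (any(diff(w) < 0)) stop("omega_n anchors must be nondecreasing in a_e")
  function(a_e) stats::approx(a, w, xout = a_e, rule = 2)$y
}

#' Draw a random virtual subject
#'
#' Plant parameters are sampled independently and uniformly within the
#' ranges spanned by the six identified subjects:
#' \eqn{\omega_n \in [14.0, 31.4]} rad/s, \eqn{K \in [1.04, 11.22]} N,
#' \eqn{\tau \in [0.045, 0.100]} s, with \eqn{\zeta = 1}. Calibration
#' currents are drawn uniformly within the corresponding per-muscle bounds
#' of the bundled calibration table. Reproducible: the same seed always
#' yields the same subject.
#'
#' @param seed Integer seed.
#' @param noise_sd,asymmetry,baseline_force,omega_n_by_activity Passed to
#'   [virtual_subject()].
#' @return A `virtual_subject` whose `seed` equals `seed`.
#' @export
sample_subject <- function(seed, noise_sd = 0.5, asymmetry = 0,
                           baseline_force = 0, omega_n_by_activity = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  plant <- sopdt_model(k = stats::runif(1, 1.04, 11.22),
                       omega_n = stats::runif(1, 14.0, 31.4),
                       zeta = 1,
                       tau = stats::runif(1, 0.045, 0.100))
  cal <- subject_calibration(
    flexor = muscle_calibration(i_max_ma = stats::runif(1, 11.5, 15.5),
                                i_min_ma = stats::runif(1, 2.5, 7.0)),
    extensor = muscle_calibration(i_max_ma = stats::runif(1, 10.0, 15.0),
                                  i_min_ma = stats::runif(1, 4.0, 8.0)),
    subject_id = sprintf("synthetic-%d", seed))
  virtual_subject(plant, cal, noise_sd = noise_sd, asymmetry = asymmetry,
                  baseline_force = baseline_force,
                  omega_n_by_activity = omega_n_by_activity, seed = seed)
}

# effective plant for a protocol run at constant activity a:
# omega_n substituted through the activity map when a != 1, and gain
# scaled by a (total drive sets both stiffness and force displacement).
.effective_plant <- function(subject, a) {
  plant <- subject$plant
  wn <- plant$omega_n
  if (!is.null(subject$omega_n_by_activity) && abs(a - 1) > 1e-12) {
    wn <- subject$omega_n_by_activity(a)
  }
  sopdt_model(k = plant$k * a, omega_n = wn, zeta = plant$zeta,
              tau = plant$tau)
}

#' Run a stimulation protocol on a virtual subject
#'
#' Produces `n_trials` replicate "measured" force traces: the ground-truth
#' plant response to the command trace, plus the voluntary baseline, plus
#' the asymmetry offset on active samples when the protocol's dominant
#' period is 0.4 s or less, plus i.i.d. Gaussian measurement noise.
#' Replicates differ only in the noise draw.
#'
#' @param subject A [virtual_subject()].
#' @param trace An [eaa_trace()]; must be realizable under the subject's
#'   calibration (checked).
#' @param n_trials Number of replicate trials (default 3).
#' @param seed Seed for the noise stream (default the subject's seed).
#' @return An object of class `trial_set`: a list with elements `trials`
#'   (list of [force_trace()]), `trace`, `period`, `n_trials`.
#' @export
run_protocol <- function(subject, trace, n_trials = 3,
                         seed = subject$seed) {
  stopifnot(inherits(subject, "virtual_subject"), inherits(trace, "eaa_trace"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  command_trace_to_currents(trace, subject$calibration)  # realizability check
  a_lvls <- unique(trace$a_e[trace$active])
  a <- if (length(a_lvls)) max(a_lvls) else 1
  plant <- .effective_plant(subject, a)
  det <- sopdt_simulate(plant, trace)
  f0 <- det$force_n + subject$baseline_force
  period <- attr(trace, "period")
  if (subject$asymmetry > 0 && is.finite(period) && period <= 0.4) {
    off <- subject$asymmetry * subject$plant$k * (0.4 - period) / 0.4
    f0[trace$active] <- f0[trace$active] + off
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(f0)
  trials <- lapply(seq_len(n_trials), function(i) {
    noise <- if (subject$noise_sd > 0) stats::rnorm(n, 0, subject$noise_sd) else 0
    force_trace(det$time_s, f0 + noise, attr(det, "sample_rate"),
                period = period, onset = attr(det, "onset"))
  })
  structure(list(trials = trials, trace = trace, period = period,
                 n_trials = n_trials),
            class = "trial_set")
}

#' Average the replicate trials of a protocol run
#'
#' @param trial_set A `trial_set` from [run_protocol()].
#' @return A [force_trace()] of the pointwise trial mean.
#' @export
trial_average <- function(trial_set) {
  stopifnot(inherits(trial_set, "trial_set"))
  lens <- vapply(trial_set$trials, nrow, integer(1))
  if (length(unique(lens)) != 1) stop("trials have mismatched lengths")
  f <- rowMeans(vapply(trial_set$trials, function(tr) tr$force_n,
                       numeric(lens[1])))
  t1 <- trial_set$trials[[1]]
  force_trace(t1$time_s, f, attr(t1, "sample_rate"),
              period = attr(t1, "period"), onset = attr(t1, "onset"))
}

#' Stepwise-ratio runs across EAA activity levels
#'
#' Runs the stepwise ratio staircase at each activity level. Force
#' displacement grows with activity (stiffness), and the response speed
#' follows the subject's activity-to-\eqn{\omega_n} map when present.
#'
#' @param subject A [virtual_subject()].
#' @param a_levels Activity levels in \eqn{(0, 1]}.
#' @param schedule A [step_schedule()] (default the 0.2-increment, 3 s dwell
#'   staircase).
#' @param sample_rate Sampling rate in Hz.
#' @param n_trials Trials per level.
#' @param seed Base seed; level `i` uses `seed + i - 1`.
#' @return A named list of `trial_set` objects, one per activity level.
#' @export
activity_sweep <- function(subject, a_levels, schedule = step_schedule(),
                           sample_rate = 1000, n_trials = 1,
                           seed = subject$seed) {
  stopifnot(all(a_levels > 0), all(a_levels <= 1))
  out <- lapply(seq_along(a_levels), function(i) {
    tr <- step_trace(schedule, sample_rate, a_e = a_levels[i])
    run_protocol(subject, tr, n_trials = n_trials, seed = seed + i - 1L)
  })
  names(out) <- sprintf("a_e=%g", a_levels)
  out
}
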