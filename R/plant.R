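# SOPDT plant: second-order lag plus dead time between the EAA ratio and
# isometric hand force,
#   G(s) = K * omega_n^2 / (s^2 + 2*zeta*omega_n*s + omega_n^2) * exp(-tau*s)
# with the damping ratio fixed at zeta = 1 throughout the identification
# pipeline (critically damped).

#' Second-order-plus-dead-time model
#'
#' @param k Steady-state gain, N per unit EAA ratio. Positive gain means
#'   extensor-side (positive) force for high ratio; the global sign
#'   convention is flexion-negative.
#' @param omega_n Natural angular frequency, rad/s (> 0).
#' @param zeta Damping ratio (> 0; fixed at 1 in this workflow).
#' @param tau Dead time in s (>= 0), the stimulation-to-force latency.
#' @return An object of class `sopdt_model`.
#' @export
#' @examples
#' m <- sopdt_model(k = 11.22, omega_n = 20.5, zeta = 1, tau = 0.05)
#' sopdt_denominator(m)  # c(1, 41, 420.25)
sopdt_model <- function(k, omega_n, zeta = 1, tau = 0) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (!is.numeric(omega_n) || omega_n <= 0) stop("omega_n must be > 0")
  if (!is.numeric(zeta) || zeta <= 0) stop("zeta must be > 0")
  if (!is.numeric(tau) || tau < 0) stop("tau must be >= 0")
  structure(list(k = as.numeric(k), omega_n = as.numeric(omega_n),
                 zeta = as.numeric(zeta), tau = as.numeric(tau)),
            class = "sopdt_model")
}

#' @export
print.sopdt_model <- function(x, ...) {
  den <- sopdt_denominator(x)
  cat(sprintf(
    "<sopdt_model> G(s) = %.4g * %.4g / (s^2 + %.4g s + %.4g) * exp(-%.4g s)\n",
    x$k, den[3], den[2], den[3], x$tau))
  cat(sprintf("  K = %.4g N, omega_n = %.4g rad/s, zeta = %.4g, tau = %.4g s\n",
              x$k, x$omega_n, x$zeta, x$tau))
  invisible(x)
}

#' Denominator polynomial coefficients of the second-order lag
#'
#' @param model An [sopdt_model()].
#' @return `c(1, 2*zeta*omega_n, omega_n^2)` — coefficients of
#'   \eqn{s^2 + 2\zeta\omega_n s + \omega_n^2}.
#' @export
sopdt_denominator <- function(model) {
  stopifnot(inherits(model, "sopdt_model"))
  c(1, 2 * model$zeta * model$omega_n, model$omega_n^2)
}

#' Analytic frequency response of an SOPDT model
#'
#' Closed-form magnitude and phase of \eqn{G(j\omega)}:
#' \deqn{|G| = K\omega_n^2 / \sqrt{(\omega_n^2-\omega^2)^2 +
#'   (2\zeta\omega_n\omega)^2},\quad
#'   \arg G = -\mathrm{atan2}(2\zeta\omega_n\omega, \omega_n^2-\omega^2)
#'   - \tau\omega.}
#' For \eqn{\zeta = 1} the magnitude reduces to
#' \eqn{K\omega_n^2/(\omega_n^2+\omega^2)} and the lag term to
#' \eqn{-2\arctan(\omega/\omega_n)}.
#'
#' @param model An [sopdt_model()].
#' @param omega Angular frequencies in rad/s (vectorized, >= 0).
#' @return A data frame with columns `omega`, `gain` (dimensionless
#'   magnitude) and `phase` (rad, continuous in `omega`, not wrapped).
#' @export
analytic_response <- function(model, omega) {
  stopifnot(inherits(model, "sopdt_model"), is.numeric(omega))
  if (any(omega < 0)) stop("omega must be >= 0")
  wn <- model$omega_n
  z <- model$zeta
  gain <- model$k * wn^2 / sqrt((wn^2 - omega^2)^2 + (2 * z * wn * omega)^2)
  phase <- -atan2(2 * z * wn * omega, wn^2 - omega^2) - model$tau * omega
  data.frame(omega = omega, gain = gain, phase = phase)
}

#' Analytic Bode table of an SOPDT model over a period grid
#'
#' Convenience wrapper turning [analytic_response()] into the `bode_table`
#' layout produced by [bode_assemble()], for plotting or as a fitting
#' reference.
#'
#' @param model An [sopdt_model()].
#' @param periods Input periods in s (default [frequency_grid()]).
#' @return A `bode_table` data frame with columns `omega`, `gain_db`,
#'   `phase` (rad), ordered by increasing `omega`.
#' @export
analytic_bode <- function(model, periods = frequency_grid()) {
  omega <- sort(2 * pi / periods)
  resp <- analytic_response(model, omega)
  out <- data.frame(omega = omega, gain_db = 20 * log10(resp$gain),
                    phase = resp$phase)
  class(out) <- c("bode_table", "data.frame")
  out
}

# Discrete-time realization at step dt: exact matrix-exponential state
# transition with first-order-hold (linearly interpolated) input, reduced to
# a direct-form difference equation
#   y[k] = a1 y[k-1] + a2 y[k-2] + n0 u[k] + n1 u[k-1] + n2 u[k-2]
# (unit DC gain; K is applied by the caller). FOH is used rather than ZOH
# because a zero-order hold adds an effective dt/2 input delay that would
# bias the identified dead time and high-frequency phase.
.sopdt_discretize <- function(omega_n, zeta, dt) {
  wn <- omega_n
  A <- matrix(c(0, -wn^2, 1, -2 * zeta * wn), 2, 2)
  B <- c(0, wn^2)
  if (abs(zeta - 1) < 1e-12) {
    # critically damped: exp(A t) = e^{-wn t} (I + t (A + wn I))
    p <- exp(-wn * dt)
    Ad <- p * matrix(c(1 + wn * dt, -wn^2 * dt, dt, 1 - wn * dt), 2, 2)
  } else {
    Ad <- pracma::expm(A * dt)
  }
  I2 <- diag(2)
  M1 <- solve(A, Ad - I2)                     # int_0^dt exp(A s) ds
  S <- dt * (M1 - solve(A, Ad)) + solve(A, M1) # int_0^dt exp(A(dt-s)) s ds
  B1 <- as.numeric((S / dt) %*% B)
  B0 <- as.numeric((M1 - S / dt) %*% B)
  Bd <- as.numeric(Ad %*% B1 + B0)
  D <- B1[1]
  a1 <- Ad[1, 1] + Ad[2, 2]
  a2 <- -(Ad[1, 1] * Ad[2, 2] - Ad[1, 2] * Ad[2, 1])
  n0 <- D
  n1 <- Bd[1] - D * a1
  n2 <- (Ad[1, 2] * Bd[2] - Ad[2, 2] * Bd[1]) - D * a2
  list(ar = c(a1, a2), ma = c(n0, n1, n2))
}

#' Simulate an SOPDT model in the time domain
#'
#' Drives the plant with an EAA-ratio input from zero initial conditions.
#' The second-order core is advanced by the exact matrix-exponential state
#' transition per sample with first-order-hold input interpolation, so the
#' discrete response carries no artificial input delay; the dead time is an
#' integer-sample shift (`tau` rounded to the nearest sample).
#'
#' Steady state under a constant input `u` is `K * u`; on inactive samples
#' of an [eaa_trace()] the plant input is 0 (stimulation off).
#'
#' @param model An [sopdt_model()].
#' @param input An [eaa_trace()] (its `r_e` on active samples drives the
#'   plant) or a numeric input vector.
#' @param sample_rate Sampling rate in Hz; taken from the trace when `input`
#'   is an [eaa_trace()] (default 1000).
#' @return A [force_trace()] carrying the input's `period` and `onset`
#'   attributes when present.
#' @export
#' @examples
#' m <- sopdt_model(11.22, 20.5, 1, 0.05)
#' ft <- sopdt_simulate(m, rep(1, 2000), sample_rate = 1000)
#' tail(ft$force_n, 1)  # ~ 11.22 N
sopdt_simulate <- function(model, input, sample_rate = 1000) {
  stopifnot(inherits(model, "sopdt_model"))
  period <- NA_real_
  onset <- NA_integer_
  if (inherits(input, "eaa_trace")) {
    sample_rate <- attr(input, "sample_rate")
    period <- attr(input, "period")
    onset <- attr(input, "onset")
    u <- ifelse(input$active, input$r_e, 0)
  } else {
    u <- as.numeric(input)
  }
  if (any(!is.finite(u))) stop("input must be finite")
  dt <- 1 / sample_rate
  if (dt > 1e-3 + 1e-12) stop("dt must be <= 1 ms; use sample_rate >= 1000")
  if (model$omega_n * dt > 0.2) {
    warning("omega_n * dt > 0.2: time step coarse relative to plant dynamics")
  }
  n <- length(u)
  d <- as.integer(round(model$tau / dt))
  ud <- if (d > 0) c(rep(0, d), u[seq_len(max(0, n - d))]) else u
  co <- .sopdt_discretize(model$omega_n, model$zeta, dt)
  u1 <- c(0, ud[-n])
  u2 <- c(0, 0, ud[-c(n - 1, n)])[seq_len(n)]
  v <- co$ma[1] * ud + co$ma[2] * u1 + co$ma[3] * u2
  y <- as.numeric(stats::filter(v, co$ar, method = "recursive"))
  force_trace((seq_len(n) - 1L) / sample_rate, model$k * y, sample_rate,
              period = period, onset = onset)
}

#' Simulate stimulation superimposed on a voluntary force baseline
#'
#' The central movement command and the electrical command add linearly:
#' the measured force is the plant response to the stimulation ratio plus
#' the voluntary baseline force. With stimulation off everywhere the output
#' equals the baseline.
#'
#' @param model An [sopdt_model()].
#' @param trace An [eaa_trace()] (e.g. a [burst_trace()]).
#' @param baseline_n Voluntary hand force in N, a constant (e.g. +10 for a
#'   held extension, -10 for flexion) or a per-sample vector.
#' @return A [force_trace()].
#' @export
simulate_with_voluntary <- function(model, trace, baseline_n = 0) {
  out <- sopdt_simulate(model, trace)
  out$force_n <- out$force_n + baseline_n
  out
}

#' Sampled hand-force trace
#'
#' @param time_s Sample times in s (uniform).
#' @param force_n Hand force in N; negative is flexion, positive extension.
#' @param sample_rate Sampling rate in Hz.
#' @param period,onset Optional protocol metadata (dominant input period,
#'   index of the first stimulation-on sample) carried along for the
#'   identification stages.
#' @return A data frame of class `force_trace`.
#' @export
force_trace <- function(time_s, force_n, sample_rate,
                        period = NA_real_, onset = NA_integer_) {
  stopifnot(length(time_s) == length(force_n))
  if (any(!is.finite(force_n))) stop("force values must be finite")
  out <- data.frame(time_s = time_s, force_n = force_n)
  class(out) <- c("force_trace", "data.frame")
  attr(out, "sample_rate") <- sample_rate
  attr(out, "period") <- period
  attr(out, "onset") <- onset
  out
}
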