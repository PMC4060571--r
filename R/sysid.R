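# Frequency-response identification: steady-cycle extraction, sin-cos
# harmonic regression, Bode assembly, high-frequency slope estimation, and
# SOPDT fitting with zeta fixed at 1.

#' Average the steady-state cycles of a protocol run
#'
#' Reduces replicate force traces to one representative steady cycle:
#' trials are averaged pointwise, the post-onset record is divided into
#' whole input cycles, and cycles 3-8 (1-based, six cycles) are averaged.
#' The first two cycles absorb the onset transient; later cycles are held
#' in reserve.
#'
#' @param x A `trial_set` from [run_protocol()], a [force_trace()], or a
#'   list of equally long [force_trace()]s sharing a time base. Traces must
#'   carry `onset` and (unless `period` is given) `period` attributes.
#' @param period Input period in s; defaults to the `period` attribute.
#' @return A [force_trace()] of one cycle (`round(period * rate)` samples,
#'   time starting at 0), with the `period` attribute set.
#' @export
steady_cycle_average <- function(x, period = NULL) {
  if (inherits(x, "trial_set")) {
    avg <- trial_average(x)
  } else if (inherits(x, "force_trace")) {
    avg <- x
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "force_trace"))) {
    lens <- vapply(x, nrow, integer(1))
    if (length(unique(lens)) != 1) stop("trials have mismatched lengths")
    f <- rowMeans(vapply(x, function(tr) tr$force_n, numeric(lens[1])))
    avg <- force_trace(x[[1]]$time_s, f, attr(x[[1]], "sample_rate"),
                       period = attr(x[[1]], "period"),
                       onset = attr(x[[1]], "onset"))
  } else {
    stop("x must be a trial_set, force_trace, or list of force_traces")
  }
  if (is.null(period)) period <- attr(avg, "period")
  if (is.null(period) || !is.finite(period)) {
    stop("period is required (no finite 'period' attribute present)")
  }
  rate <- attr(avg, "sample_rate")
  onset <- attr(avg, "onset")
  if (is.null(onset) || is.na(onset)) onset <- 1L
  n_per <- round(period * rate)
  n_cyc <- (nrow(avg) - onset + 1L) %/% n_per
  if (n_cyc < 8) {
    stop("too few cycles after input onset: have ", n_cyc, ", need >= 8")
  }
  idx <- onset + (2L * n_per):(8L * n_per - 1L)
  cyc <- rowMeans(matrix(avg$force_n[idx], nrow = n_per))
  force_trace((seq_len(n_per) - 1L) / rate, cyc, rate, period = period)
}

#' Sin-cos harmonic regression on one cycle
#'
#' Least-squares fit of \eqn{f(t) \approx p\sin(2\pi t/T) + q\cos(2\pi t/T)
#' + c}, re-expressed as the single sinusoid \eqn{A\sin(2\pi t/T + \phi) +
#' c} with \eqn{A = \sqrt{p^2 + q^2}} and \eqn{\phi = \mathrm{atan2}(q, p)}
#' (the phase is the angle whose sine multiplies the cos-coefficient:
#' \eqn{p = A\cos\phi}, \eqn{q = A\sin\phi}). The fit is exact on any pure
#' single-harmonic input.
#'
#' @param cycle A [force_trace()] (one cycle) or numeric sample vector.
#' @param period Cycle period in s; defaults to the trace's `period`
#'   attribute.
#' @param t Sample times in s when `cycle` is a bare vector; defaults to
#'   uniform sampling from 0 at `sample_rate`.
#' @param sample_rate Sampling rate when `cycle` is a bare vector.
#' @return An object of class `harmonic_fit`: amplitude `amplitude` (>= 0),
#'   phase `phase` in (-pi, pi], offset `offset`, the raw regression
#'   coefficients `sin_coef` and `cos_coef`, `period`, and `r_squared`.
#' @export
#' @examples
#' tt <- (0:299) / 1000
#' harmonic_fit(2 * sin(2 * pi * tt / 0.3) + 3, period = 0.3, t = tt)
harmonic_fit <- function(cycle, period = NULL, t = NULL, sample_rate = 1000) {
  if (inherits(cycle, "force_trace")) {
    if (is.null(period)) period <- attr(cycle, "period")
    t <- cycle$time_s
    f <- cycle$force_n
  } else {
    f <- as.numeric(cycle)
    if (is.null(t)) t <- (seq_along(f) - 1L) / sample_rate
  }
  if (is.null(period) || !is.finite(period) || period <= 0) {
    stop("a positive period is required")
  }
  if (length(f) < 8) stop("need >= 8 samples per cycle")
  theta <- 2 * pi * t / period
  X <- cbind(1, sin(theta), cos(theta))
  qr_x <- qr(X)
  if (qr_x$rank < 3) stop("rank-deficient design: degenerate sample times")
  beta <- qr.coef(qr_x, f)
  c0 <- beta[1]; p <- beta[2]; q <- beta[3]
  res <- f - X %*% beta
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(amplitude = sqrt(p^2 + q^2), phase = atan2(q, p),
                 offset = c0, sin_coef = p, cos_coef = q,
                 period = period, r_squared = r2),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf(
    "<harmonic_fit> T = %.4g s: A = %.4g, phi = %.4g rad, c = %.4g (R^2 = %.4g)\n",
    x$period, x$amplitude, x$phase, x$offset, x$r_squared))
  invisible(x)
}

# wrap angles to (-pi, pi]
.wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# minimal-jump unwrapping along an ordered sequence
.unwrap_phase <- function(x) {
  for (i in seq_along(x)[-1]) {
    x[i] <- x[i] - 2 * pi * round((x[i] - x[i - 1]) / (2 * pi))
  }
  x
}

#' Assemble a Bode table from per-period harmonic fits
#'
#' Converts one [harmonic_fit()] per probe period into frequency-response
#' samples. The gain is the output amplitude per unit input amplitude (the
#' ratio sinusoid's amplitude, 0.5, by default), in dB. The phase is taken
#' relative to the input sinusoid \eqn{-0.5\sin(2\pi t/T) + 0.5} — i.e. the
#' fitted phase minus \eqn{\pi} — wrapped to \eqn{(-\pi, \pi]} and then
#' unwrapped across increasing frequency by minimal jumps.
#'
#' @param fits List of `harmonic_fit` objects, one per period.
#' @param input_amplitude Amplitude of the ratio input sinusoid (default
#'   0.5).
#' @return A data frame of class `bode_table` with columns `omega` (rad/s),
#'   `gain_db`, `phase` (rad, unwrapped), and `offset` (the fitted cycle
#'   mean, reported as the oscillation-centre diagnostic but not used in
#'   transfer-function fitting), ordered by increasing `omega`.
#' @export
bode_assemble <- function(fits, input_amplitude = 0.5) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "harmonic_fit")))
  if (input_amplitude <= 0) stop("input_amplitude must be > 0")
  amp <- vapply(fits, function(f) f$amplitude, numeric(1))
  if (any(amp <= 0)) stop("zero-amplitude fit: cannot form gain")
  per <- vapply(fits, function(f) f$period, numeric(1))
  phi <- vapply(fits, function(f) f$phase, numeric(1))
  off <- vapply(fits, function(f) f$offset, numeric(1))
  omega <- 2 * pi / per
  o <- order(omega)
  phase <- .unwrap_phase(.wrap_phase(phi[o] - pi))
  out <- data.frame(omega = omega[o], gain_db = 20 * log10(amp[o] / input_amplitude),
                    phase = phase, offset = off[o])
  class(out) <- c("bode_table", "data.frame")
  out
}

#' High-frequency gain slope in dB/decade
#'
#' Ordinary least squares of `gain_db` on `log10(omega)` over a
#' high-frequency band. A second-order lag rolls off at -40 dB/dec
#' asymptotically.
#'
#' @param bode A `bode_table`.
#' @param band Logical mask or index vector selecting the band; default the
#'   upper half of the sampled frequencies (omega >= its median).
#' @return Slope in dB/decade.
#' @export
fit_gain_slope <- function(bode, band = NULL) {
  stopifnot(inherits(bode, "bode_table"))
  if (is.null(band)) band <- bode$omega >= stats::median(bode$omega)
  sub <- bode[band, , drop = FALSE]
  if (nrow(sub) < 3) stop("need >= 3 points in the slope band")
  unname(stats::coef(stats::lm(gain_db ~ log10(omega), data = sub))[2])
}

#' Fit an SOPDT model to Bode samples
#'
#' Two-stage deterministic fit with the damping ratio fixed at
#' \eqn{\zeta = 1}. First \eqn{(K, \omega_n)} by least squares of the gain
#' curve in dB against \eqn{20\log_{10}(K\omega_n^2/(\omega_n^2+\omega^2))}:
#' for each candidate \eqn{\omega_n} the optimal \eqn{K} in dB is the mean
#' gain residual, so \eqn{\omega_n} is found by a log-grid search refined
#' with a bounded 1-D optimizer (no random restarts). Then the dead time by
#' regression through the origin of the residual phase
#' \eqn{\varphi + 2\arctan(\omega/\omega_n)} on \eqn{-\omega}, clamped at
#' \eqn{\tau \ge 0}. The fitted offsets never enter: only the amplitude
#' ratio and phase difference are modelled.
#'
#' @param bode A `bode_table` (>= 5 points recommended, spanning the corner
#'   frequency).
#' @param omega_n_range Search range for \eqn{\omega_n} in rad/s.
#' @param n_grid Coarse grid size for the \eqn{\omega_n} search.
#' @return An [sopdt_model()] with \eqn{\zeta = 1}.
#' @export
#' @examples
#' truth <- sopdt_model(8.91, 20.5, 1, 0.045)
#' fit_sopdt(analytic_bode(truth))
fit_sopdt <- function(bode, omega_n_range = c(5, 100), n_grid = 200) {
  stopifnot(inherits(bode, "bode_table"))
  if (nrow(bode) < 5) stop("need >= 5 Bode points to fit an SOPDT model")
  omega <- bode$omega
  gdb <- bode$gain_db
  sse <- function(lw) {
    wn <- exp(lw)
    mdb <- 20 * log10(wn^2 / (wn^2 + omega^2))
    kdb <- mean(gdb - mdb)
    sum((gdb - mdb - kdb)^2)
  }
  grid <- seq(log(omega_n_range[1]), log(omega_n_range[2]),
              length.out = n_grid)
  vals <- vapply(grid, sse, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(n_grid, i0 + 1L)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
  wn <- exp(opt$minimum)
  k <- 10^(mean(gdb - 20 * log10(wn^2 / (wn^2 + omega^2))) / 20)
  if (wn < min(omega) || wn > max(omega)) {
    warning("fitted corner frequency ", signif(wn, 4),
            " rad/s lies outside the sampled band [",
            signif(min(omega), 4), ", ", signif(max(omega), 4), "]")
  }
  resid_phase <- bode$phase + 2 * atan(omega / wn)
  tau <- max(0, -sum(resid_phase * omega) / sum(omega^2))
  sopdt_model(k = k, omega_n = wn, zeta = 1, tau = tau)
}

#' End-to-end frequency-response identification of a virtual subject
#'
#' Runs the full measurement and analysis pipeline: for each probe period,
#' generate the sinusoidal ratio sweep (balanced-hold lead-in plus enough
#' warm-up cycles to reach steady oscillation, then `n_cycles` recorded
#' cycles), collect `n_trials` replicate force traces from the subject,
#' average trials and steady cycles, fit the harmonic regression; then
#' assemble the Bode table and fit the SOPDT model.
#'
#' @param subject A [virtual_subject()].
#' @param periods Probe periods in s (default [frequency_grid()]).
#' @param n_trials Replicate trials per period (default 3).
#' @param n_cycles Recorded cycles per trial (default 10).
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @param warmup_s Minimum warm-up duration in s before the recorded
#'   cycles; converted to whole cycles per period (default 0.6).
#' @param seed Seed for the per-period trial noise streams (default the
#'   subject's seed).
#' @return A list of class `identification`: `model` (the fitted
#'   [sopdt_model()]), `bode` (the `bode_table`), `fits` (per-period
#'   `harmonic_fit`s), `periods`.
#' @export
identify_subject <- function(subject, periods = frequency_grid(),
                             n_trials = 3, n_cycles = 10,
                             sample_rate = 1000, warmup_s = 0.6,
                             seed = subject$seed) {
  stopifnot(inherits(subject, "virtual_subject"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, length(periods))
  fits <- vector("list", length(periods))
  for (i in seq_along(periods)) {
    T_i <- periods[i]
    tr <- sweep_sinusoid(T_i, n_cycles = n_cycles,
                         sample_rate = sample_rate,
                         warmup_cycles = ceiling(warmup_s / T_i))
    ts <- run_protocol(subject, tr, n_trials = n_trials,
                       seed = trial_seeds[i])
    fits[[i]] <- harmonic_fit(steady_cycle_average(ts))
  }
  bode <- bode_assemble(fits)
  structure(list(model = fit_sopdt(bode), bode = bode, fits = fits,
                 periods = periods),
            class = "identification")
}

#' @export
print.identification <- function(x, ...) {
  cat(sprintf("<identification> %d periods, %.3g-%.3g s\n",
              length(x$periods), min(x$periods), max(x$periods)))
  print(x$model)
  invisible(x)
}
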