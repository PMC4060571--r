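# Stimulation protocols: the sinusoidal EAA-ratio sweep used for frequency
# response measurement, the composite / stepwise / burst validation inputs,
# and the 60 Hz amplitude-modulated carrier.

#' Construct an EAA command trace
#'
#' A uniformly sampled time series of EAA commands. Inactive samples
#' (stimulation off) carry `a_e = 0` and `r_e = NA` — the ratio is undefined
#' when both channels are off.
#'
#' @param time_s Sample times (s), uniform and strictly increasing.
#' @param r_e EAA ratio series (`NA` where inactive).
#' @param a_e EAA activity series.
#' @param active Logical mask of stimulation-on samples.
#' @param sample_rate Sampling rate in Hz.
#' @param period Dominant input period in s (`NA` for aperiodic protocols);
#'   used by the identification stages for cycle segmentation.
#' @return A data frame of class `eaa_trace` with attributes `sample_rate`,
#'   `period` and `onset` (index of the first active sample, `NA` if none).
#' @export
eaa_trace <- function(time_s, r_e, a_e, active = a_e > 0,
                      sample_rate, period = NA_real_) {
  stopifnot(length(time_s) == length(r_e), length(r_e) == length(a_e),
            length(active) == length(time_s))
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing")
  }
  ok <- is.na(r_e) | (r_e >= 0 & r_e <= 1)
  if (any(active & !ok)) {
    stop("r_e outside [0, 1] on an active sample (index ",
         which(active & !ok)[1], ")")
  }
  out <- data.frame(time_s = time_s, r_e = r_e, a_e = a_e, active = active)
  class(out) <- c("eaa_trace", "data.frame")
  attr(out, "sample_rate") <- sample_rate
  attr(out, "period") <- period
  attr(out, "onset") <- if (any(active)) which(active)[1] else NA_integer_
  out
}

#' Sinusoidal EAA-ratio sweep at one period
#'
#' Generates the frequency-response probe input
#' \eqn{r_E(t) = -0.5 \sin(2\pi t/T) + 0.5} at constant activity, starting
#' after a stimulation-off lead-in. The ratio starts at 0.5 at input onset,
#' dips to 0 (pure flexor drive) at \eqn{T/4} and peaks at 1 (pure extensor)
#' at \eqn{3T/4}.
#'
#' During the `start_delay` lead-in the command holds the sinusoid centre
#' `r_e = 0.5` (balanced co-contraction), so the plant is at its operating
#' point when the probe begins; set `lead = "off"` for a stimulation-off
#' lead-in instead. `warmup_cycles` extra sinusoid cycles may be inserted
#' between the lead-in and the measured cycles so that the recorded window
#' is in steady oscillation; the trace's `onset` attribute always marks the
#' first measured-cycle sample.
#'
#' @param period Input period \eqn{T} in s.
#' @param n_cycles Number of measured cycles (default 10).
#' @param sample_rate Sampling rate in Hz (default 1000, the force
#'   acquisition rate).
#' @param start_delay Lead-in before the sinusoid starts, in s (default 0.5).
#' @param a_e Constant EAA activity during the sweep (default 1).
#' @param lead `"hold"` (default): stimulate at `r_e = 0.5` during the
#'   lead-in; `"off"`: both channels off.
#' @param warmup_cycles Unmeasured settling cycles preceding the measured
#'   ones (default 0).
#' @return An [eaa_trace()] whose `onset` attribute is the index of the
#'   first measured-cycle sample.
#' @export
#' @examples
#' tr <- sweep_sinusoid(period = 0.3)
#' range(tr$r_e[tr$active])
sweep_sinusoid <- function(period, n_cycles = 10, sample_rate = 1000,
                           start_delay = 0.5, a_e = 1,
                           lead = c("hold", "off"), warmup_cycles = 0) {
  lead <- match.arg(lead)
  if (!is.numeric(period) || period <= 0) stop("period must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  n_lead <- round(start_delay * sample_rate)
  n_per <- round(period * sample_rate)
  if (n_per < 8) stop("period too short for sample_rate: < 8 samples/cycle")
  n_warm <- warmup_cycles * n_per
  n <- n_lead + n_warm + n_cycles * n_per
  idx <- seq_len(n) - 1L
  time_s <- idx / sample_rate
  in_lead <- idx < n_lead
  active <- if (lead == "hold") rep(TRUE, n) else !in_lead
  tt <- (idx - n_lead - n_warm) / sample_rate  # 0 at measured-cycle onset
  r_e <- -0.5 * sin(2 * pi * tt / period) + 0.5
  r_e[in_lead] <- if (lead == "hold") 0.5 else NA_real_
  a <- ifelse(active, a_e, 0)
  out <- eaa_trace(time_s, r_e, a, active, sample_rate, period = period)
  attr(out, "onset") <- as.integer(n_lead + n_warm + 1)
  out
}

#' Measurement-period grid for frequency-response identification
#'
#' Periods from 0.1 s to 0.5 s in 0.025 s increments: 17 values covering
#' angular frequencies \eqn{2\pi/T \approx} 12.6–62.8 rad/s.
#'
#' @return Numeric vector of 17 periods in s.
#' @export
frequency_grid <- function() {
  round(seq(0.100, 0.500, by = 0.025), 10)
}

#' Composite (two-period) sinusoidal EAA-ratio input
#'
#' Pointwise convex combination of unit-amplitude ratio sinusoids
#' \eqn{\sum_i w_i(-0.5\sin(2\pi t/T_i) + 0.5)}. With weights summing to 1
#' the trace stays in \eqn{[0, 1]}. The default validation input combines
#' periods 0.3 s and 0.6 s with weights 0.6 and 0.4.
#'
#' @param weights Non-negative component weights.
#' @param periods Component periods in s, same length as `weights`.
#' @param duration Active duration in s.
#' @param sample_rate Sampling rate in Hz.
#' @param start_delay Stimulation-off lead-in in s.
#' @param a_e Constant EAA activity.
#' @return An [eaa_trace()] whose `period` attribute is the longest
#'   component period (the repeat period of the composite for harmonically
#'   related components).
#' @export
composite_sinusoid <- function(weights = c(0.6, 0.4), periods = c(0.3, 0.6),
                               duration = 6, sample_rate = 1000,
                               start_delay = 0.5, a_e = 1) {
  stopifnot(length(weights) == length(periods))
  if (any(weights < 0)) stop("weights must be >= 0")
  if (any(periods <= 0)) stop("periods must be > 0")
  n_lead <- round(start_delay * sample_rate)
  n_act <- round(duration * sample_rate)
  idx <- seq_len(n_lead + n_act) - 1L
  time_s <- idx / sample_rate
  active <- idx >= n_lead
  tt <- (idx - n_lead) / sample_rate
  r <- rep(0, length(idx))
  for (i in seq_along(weights)) {
    r <- r + weights[i] * (-0.5 * sin(2 * pi * tt / periods[i]) + 0.5)
  }
  if (any(active & (r < -1e-12 | r > 1 + 1e-12))) {
    stop("composite trace leaves [0, 1]; check weights")
  }
  r <- pmin(1, pmax(0, r))
  r[!active] <- NA_real_
  eaa_trace(time_s, r, ifelse(active, a_e, 0), active, sample_rate,
            period = max(periods))
}

#' Stepwise EAA-ratio schedule
#'
#' Describes a staircase of ratio levels: start at `start_level` and move by
#' `increment` every `dwell` seconds, going up, down, or up then back down.
#'
#' @param start_level Initial ratio (default 0).
#' @param increment Ratio step per dwell (default 0.2).
#' @param dwell Seconds per level (default 3).
#' @param direction One of `"up"`, `"down"`, `"up-down"` (default).
#' @return An object of class `step_schedule` with the expanded `levels`.
#' @export
step_schedule <- function(start_level = 0, increment = 0.2, dwell = 3,
                          direction = c("up-down", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(increment > 0, dwell > 0)
  up <- seq(start_level, 1, by = increment)
  down <- seq(start_level, 0, by = -increment)
  levels <- switch(direction,
                   "up" = up,
                   "down" = down,
                   "up-down" = c(up, rev(up)[-1]))
  if (any(levels < -1e-12 | levels > 1 + 1e-12)) {
    stop("step schedule escapes [0, 1]")
  }
  structure(list(start_level = start_level, increment = increment,
                 dwell = dwell, direction = direction,
                 levels = pmin(1, pmax(0, levels))),
            class = "step_schedule")
}

#' Piecewise-constant EAA-ratio trace from a step schedule
#'
#' @param schedule A [step_schedule()].
#' @param sample_rate Sampling rate in Hz.
#' @param a_e Constant EAA activity.
#' @return An [eaa_trace()] (aperiodic: `period` attribute is `NA`). Levels
#'   change exactly at dwell boundaries; sample `k` at time `k/rate` belongs
#'   to the half-open dwell interval containing it.
#' @export
#' @examples
#' tr <- step_trace(step_schedule())
#' tr$r_e[tr$time_s == 4]  # second level, 0.2
step_trace <- function(schedule, sample_rate = 1000, a_e = 1) {
  stopifnot(inherits(schedule, "step_schedule"))
  n_dwell <- round(schedule$dwell * sample_rate)
  r_e <- rep(schedule$levels, each = n_dwell)
  n <- length(r_e)
  time_s <- (seq_len(n) - 1L) / sample_rate
  eaa_trace(time_s, r_e, rep(a_e, n), rep(TRUE, n), sample_rate,
            period = NA_real_)
}

#' Burst specification for intermittent stimulation
#'
#' Short sinusoidal ratio bursts (default two 0.5 s cycles, i.e. 1 s of
#' stimulation) applied at given onset times with the channels off in
#' between.
#'
#' @param period Within-burst sinusoid period in s (default 0.5).
#' @param n_cycles Cycles per burst (default 2).
#' @param burst_starts Burst onset times in s (default `c(1, 4, 7)`).
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(period = 0.5, n_cycles = 2, burst_starts = c(1, 4, 7)) {
  stopifnot(period > 0, n_cycles >= 1, length(burst_starts) >= 1)
  burst_starts <- sort(burst_starts)
  len <- n_cycles * period
  if (length(burst_starts) > 1 &&
      any(diff(burst_starts) < len - 1e-12)) {
    stop("overlapping bursts: onsets closer than one burst length")
  }
  structure(list(period = period, n_cycles = n_cycles,
                 burst_starts = burst_starts),
            class = "burst_spec")
}

#' Burst EAA-ratio trace
#'
#' Inside each burst window \eqn{[a, a + n_{cycles} T)} the ratio follows
#' \eqn{r_E = -0.5\sin(2\pi (t - a)/T) + 0.5}; outside, both channels are
#' off (0 mA), not held at any ratio.
#'
#' @param spec A [burst_spec()].
#' @param sample_rate Sampling rate in Hz.
#' @param a_e EAA activity inside bursts.
#' @param tail Seconds of off-time appended after the last burst.
#' @return An [eaa_trace()] with `period` equal to the burst sinusoid period.
#' @export
burst_trace <- function(spec, sample_rate = 1000, a_e = 1, tail = 1) {
  stopifnot(inherits(spec, "burst_spec"))
  len <- spec$n_cycles * spec$period
  total <- max(spec$burst_starts) + len + tail
  n <- round(total * sample_rate)
  idx <- seq_len(n) - 1L
  time_s <- idx / sample_rate
  active <- rep(FALSE, n)
  r_e <- rep(NA_real_, n)
  for (a in spec$burst_starts) {
    k0 <- round(a * sample_rate)
    kk <- k0 + seq_len(round(len * sample_rate)) - 1L
    kk <- kk[kk >= 0 & kk < n]
    active[kk + 1L] <- TRUE
    tt <- time_s[kk + 1L] - a
    r_e[kk + 1L] <- -0.5 * sin(2 * pi * tt / spec$period) + 0.5
  }
  eaa_trace(time_s, r_e, ifelse(active, a_e, 0), active, sample_rate,
            period = spec$period)
}

#' Synthesize the 60 Hz amplitude-modulated stimulator waveform
#'
#' The stimulator delivers a fixed-frequency sine carrier whose amplitude is
#' the commanded current envelope: `waveform(t) = envelope(t) * sin(2*pi*f*t)`.
#' The envelope is linearly interpolated onto the (finer) output time grid.
#'
#' @param envelope_ma Non-negative current envelope in mA.
#' @param sample_rate Sampling rate of the envelope in Hz.
#' @param carrier_hz Carrier frequency (default 60 Hz).
#' @param output_rate Output waveform rate in Hz; must be at least 10 times
#'   the carrier (default 6000).
#' @return A data frame with columns `time_s`, `current_ma`.
#' @export
am_carrier <- function(envelope_ma, sample_rate = 1000, carrier_hz = 60,
                       output_rate = 6000) {
  if (any(envelope_ma < 0)) stop("envelope must be >= 0")
  if (output_rate < 10 * carrier_hz) {
    stop("output_rate must be >= 10x the carrier frequency")
  }
  t_env <- (seq_along(envelope_ma) - 1L) / sample_rate
  t_out <- seq(0, max(t_env), by = 1 / output_rate)
  env <- stats::approx(t_env, envelope_ma, xout = t_out, rule = 2)$y
  data.frame(time_s = t_out,
             current_ma = env * sin(2 * pi * carrier_hz * t_out))
}
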