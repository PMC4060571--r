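# EAA coding: conversion between co-contraction commands (r_e, a_e),
# normalized muscle intensities, and physical stimulation currents.

#' Per-muscle stimulation-current calibration
#'
#' Stores the calibration bounds of one stimulation channel: `i_min_ma`, the
#' smallest current (mA) at which the muscle begins to contract, and
#' `i_max_ma`, the largest current the subject tolerates without pain. The
#' normalized intensity scale \eqn{[0, 1]} maps affinely onto
#' \eqn{[I'_{min}, I'_{max}]}.
#'
#' @param i_max_ma Maximum tolerated stimulation current in mA.
#' @param i_min_ma Contraction-threshold current in mA.
#' @return An object of class `muscle_calibration`.
#' @seealso [subject_calibration()], [normalize_current()], [denormalize_current()]
#' @export
#' @examples
#' muscle_calibration(i_max_ma = 11.0, i_min_ma = 5.0)
muscle_calibration <- function(i_max_ma, i_min_ma) {
  stopifnot(is.numeric(i_max_ma), is.numeric(i_min_ma),
            length(i_max_ma) == 1L, length(i_min_ma) == 1L,
            is.finite(i_max_ma), is.finite(i_min_ma))
  if (i_min_ma < 0) {
    stop("i_min_ma must be >= 0 mA, got ", i_min_ma)
  }
  if (i_max_ma <= i_min_ma) {
    stop("i_max_ma (", i_max_ma, ") must exceed i_min_ma (", i_min_ma, ")")
  }
  structure(list(i_max_ma = as.numeric(i_max_ma),
                 i_min_ma = as.numeric(i_min_ma)),
            class = "muscle_calibration")
}

#' Two-muscle subject calibration
#'
#' Bundles the flexor (biceps) and extensor (triceps) channel calibrations
#' for one subject.
#'
#' @param flexor,extensor [muscle_calibration()] objects for the biceps and
#'   triceps channels respectively.
#' @param subject_id Optional label.
#' @return An object of class `subject_calibration`.
#' @export
subject_calibration <- function(flexor, extensor, subject_id = "") {
  stopifnot(inherits(flexor, "muscle_calibration"),
            inherits(extensor, "muscle_calibration"))
  structure(list(flexor = flexor, extensor = extensor,
                 subject_id = as.character(subject_id)),
            class = "subject_calibration")
}

#' @export
print.muscle_calibration <- function(x, ...) {
  cat(sprintf("<muscle_calibration> I'min = %.2f mA, I'max = %.2f mA\n",
              x$i_min_ma, x$i_max_ma))
  invisible(x)
}

#' @export
print.subject_calibration <- function(x, ...) {
  cat(sprintf("<subject_calibration> subject '%s'\n", x$subject_id))
  cat(sprintf("  flexor (biceps):    I'min = %.2f, I'max = %.2f mA\n",
              x$flexor$i_min_ma, x$flexor$i_max_ma))
  cat(sprintf("  extensor (triceps): I'min = %.2f, I'max = %.2f mA\n",
              x$extensor$i_min_ma, x$extensor$i_max_ma))
  invisible(x)
}

#' Decode EAA commands into normalized muscle intensities
#'
#' The EAA ratio \eqn{r_E = I_e / (I_f + I_e)} is the extensor share of the
#' total drive and sets the joint equilibrium point; the EAA activity
#' \eqn{a_E = I_f + I_e} is the total drive and sets joint stiffness.
#' Decoding inverts these definitions: \eqn{I_e = r_E a_E},
#' \eqn{I_f = (1 - r_E) a_E}.
#'
#' @param r_e EAA ratio in \eqn{[0, 1]} (vectorized).
#' @param a_e EAA activity, \eqn{\ge 0} (vectorized or scalar).
#' @param tol Intensities exceeding \eqn{[0, 1]} by at most `tol` are clamped;
#'   larger excursions raise an unrealizable-command error.
#' @return A data frame with columns `i_f`, `i_e` (normalized intensities).
#' @export
#' @examples
#' eaa_to_normalized(r_e = 0.5, a_e = 1)   # symmetric midpoint
#' eaa_to_normalized(r_e = 1.0, a_e = 1)   # pure extensor
eaa_to_normalized <- function(r_e, a_e, tol = 1e-9) {
  stopifnot(is.numeric(r_e), is.numeric(a_e))
  n <- max(length(r_e), length(a_e))
  r_e <- rep_len(r_e, n)
  a_e <- rep_len(a_e, n)
  if (any(!is.finite(r_e)) || any(!is.finite(a_e))) {
    stop("r_e and a_e must be finite")
  }
  if (any(r_e < -tol | r_e > 1 + tol)) {
    stop("r_e outside [0, 1] at index ", which(r_e < -tol | r_e > 1 + tol)[1])
  }
  if (any(a_e < -tol)) {
    stop("a_e must be >= 0 at index ", which(a_e < -tol)[1])
  }
  r_e <- pmin(1, pmax(0, r_e))
  a_e <- pmax(0, a_e)
  i_e <- r_e * a_e
  i_f <- (1 - r_e) * a_e
  bad_f <- i_f > 1 + tol
  bad_e <- i_e > 1 + tol
  if (any(bad_f)) {
    k <- which(bad_f)[1]
    stop("unrealizable command: flexor intensity ", format(i_f[k]),
         " exceeds 1 at index ", k)
  }
  if (any(bad_e)) {
    k <- which(bad_e)[1]
    stop("unrealizable command: extensor intensity ", format(i_e[k]),
         " exceeds 1 at index ", k)
  }
  data.frame(i_f = pmin(1, i_f), i_e = pmin(1, i_e))
}

#' Encode normalized muscle intensities as an EAA command
#'
#' Exact inverse of [eaa_to_normalized()] whenever \eqn{I_f + I_e > 0}. When
#' both channels are off the activity is 0 and the ratio is undefined; the
#' rest convention returns `r_e = NA`.
#'
#' @param i_f,i_e Normalized intensities, each \eqn{\ge 0} (vectorized).
#' @return A data frame with columns `r_e`, `a_e` (`r_e` is `NA` at rest).
#' @export
normalized_to_eaa <- function(i_f, i_e) {
  stopifnot(is.numeric(i_f), is.numeric(i_e))
  n <- max(length(i_f), length(i_e))
  i_f <- rep_len(i_f, n)
  i_e <- rep_len(i_e, n)
  if (any(i_f < 0) || any(i_e < 0)) {
    stop("normalized intensities must be >= 0")
  }
  a_e <- i_f + i_e
  r_e <- ifelse(a_e > 0, i_e / a_e, NA_real_)
  data.frame(r_e = r_e, a_e = a_e)
}

#' Map a normalized intensity to a physical stimulation current
#'
#' Inverts the per-muscle normalization \eqn{I = (I' - I'_{min}) /
#' (I'_{max} - I'_{min})}: the current is `i * (i_max - i_min) + i_min` mA.
#' Affine and monotone in `i`; `i = 0` gives the contraction threshold, not
#' zero current (a muscle that is switched off is handled by the trace-level
#' converters, see [command_trace_to_currents()]).
#'
#' @param i Normalized intensity in \eqn{[0, 1]} (vectorized).
#' @param cal A [muscle_calibration()].
#' @param tol Clamping tolerance for floating-point excess outside \eqn{[0,1]}.
#' @return Stimulation current in mA.
#' @export
#' @examples
#' triceps_b <- muscle_calibration(i_max_ma = 11.0, i_min_ma = 5.0)
#' denormalize_current(0.5, triceps_b)  # 8.0 mA
denormalize_current <- function(i, cal, tol = 1e-9) {
  stopifnot(inherits(cal, "muscle_calibration"), is.numeric(i))
  if (any(!is.finite(i))) stop("intensity must be finite")
  if (any(i < -tol | i > 1 + tol)) {
    k <- which(i < -tol | i > 1 + tol)[1]
    stop("normalized intensity ", format(i[k]), " outside [0, 1] at index ", k)
  }
  i <- pmin(1, pmax(0, i))
  i * (cal$i_max_ma - cal$i_min_ma) + cal$i_min_ma
}

#' Normalize a physical stimulation current
#'
#' Exact inverse of [denormalize_current()]: `(i_ma - i_min) / (i_max - i_min)`.
#'
#' @param i_ma Stimulation current in mA (vectorized).
#' @param cal A [muscle_calibration()].
#' @param tol Tolerance (mA) for currents marginally outside the calibrated
#'   range.
#' @return Normalized intensity in \eqn{[0, 1]}.
#' @export
normalize_current <- function(i_ma, cal, tol = 1e-9) {
  stopifnot(inherits(cal, "muscle_calibration"), is.numeric(i_ma))
  if (any(i_ma < cal$i_min_ma - tol | i_ma > cal$i_max_ma + tol)) {
    k <- which(i_ma < cal$i_min_ma - tol | i_ma > cal$i_max_ma + tol)[1]
    stop("current ", format(i_ma[k]), " mA outside calibrated range [",
         cal$i_min_ma, ", ", cal$i_max_ma, "] at index ", k)
  }
  x <- (i_ma - cal$i_min_ma) / (cal$i_max_ma - cal$i_min_ma)
  pmin(1, pmax(0, x))
}

#' Convert an EAA command trace to physical stimulation currents
#'
#' Composes EAA decoding and per-muscle denormalization over a sampled
#' command trace. On inactive samples (stimulation off) both channels output
#' 0 mA — below the contraction threshold, not at `i_min` — following the
#' rest convention that `a_e = 0` means both muscles off.
#'
#' @param trace An [eaa_trace()].
#' @param cal A [subject_calibration()].
#' @return A data frame with columns `time_s`, `i_f_ma`, `i_e_ma`, carrying
#'   the input trace's `sample_rate`, `period` and `onset` attributes.
#' @export
command_trace_to_currents <- function(trace, cal) {
  stopifnot(inherits(trace, "eaa_trace"), inherits(cal, "subject_calibration"))
  n <- nrow(trace)
  i_f_ma <- numeric(n)
  i_e_ma <- numeric(n)
  act <- trace$active
  if (any(act)) {
    norm <- tryCatch(
      eaa_to_normalized(trace$r_e[act], trace$a_e[act]),
      error = function(e) {
        stop("unrealizable command in trace (first active-sample indices ",
             "refer to the active subset): ", conditionMessage(e))
      })
    i_f_ma[act] <- denormalize_current(norm$i_f, cal$flexor)
    i_e_ma[act] <- denormalize_current(norm$i_e, cal$extensor)
  }
  out <- data.frame(time_s = trace$time_s, i_f_ma = i_f_ma, i_e_ma = i_e_ma)
  attr(out, "sample_rate") <- attr(trace, "sample_rate")
  attr(out, "period") <- attr(trace, "period")
  attr(out, "onset") <- attr(trace, "onset")
  out
}
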