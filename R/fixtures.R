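# Bundled reference data: per-subject stimulation-current calibrations,
# identified SOPDT plant parameters for six adult subjects (A-F) from an
# isometric elbow-joint FES experiment, and the omega_n-vs-activity anchors.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "eaafes")
  if (path == "") stop("bundled data file not found: ", file)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Bundled subject calibrations
#'
#' Stimulation-current calibration bounds (mA) for six subjects, biceps
#' (flexor) and triceps (extensor) channels.
#'
#' @return A named list of [subject_calibration()] objects, `"A"` to `"F"`.
#' @export
#' @examples
#' example_calibration("B")
example_calibrations <- function() {
  raw <- .extdata("calibrations.json")
  out <- lapply(names(raw$subjects), function(id) {
    s <- raw$subjects[[id]]
    subject_calibration(
      flexor = muscle_calibration(s$flexor$i_max_ma, s$flexor$i_min_ma),
      extensor = muscle_calibration(s$extensor$i_max_ma, s$extensor$i_min_ma),
      subject_id = id)
  })
  names(out) <- names(raw$subjects)
  out
}

#' @rdname example_calibrations
#' @param id Subject label, `"A"` to `"F"`.
#' @export
example_calibration <- function(id) {
  cals <- example_calibrations()
  if (!id %in% names(cals)) {
    stop("unknown subject id '", id, "'; available: ",
         paste(names(cals), collapse = ", "))
  }
  cals[[id]]
}

#' Bundled SOPDT plant models
#'
#' Identified plant parameters for the six subjects, plus `"demo"`, the
#' worked-example transfer function
#' \eqn{G(s) = 11.22 \cdot 420.25/(s^2 + 41 s + 420.25) \cdot e^{-0.05 s}}
#' used throughout the validation examples. All models have \eqn{\zeta = 1}.
#'
#' @return A named list of [sopdt_model()] objects.
#' @export
#' @examples
#' example_model("demo")
example_models <- function() {
  raw <- .extdata("models.json")
  out <- lapply(raw$models, function(m) {
    sopdt_model(k = m$k, omega_n = m$omega_n, zeta = m$zeta, tau = m$tau)
  })
  names(out) <- names(raw$models)
  out
}

#' @rdname example_models
#' @param id Model label: a subject `"A"`-`"F"` or `"demo"`.
#' @export
example_model <- function(id = "demo") {
  mods <- example_models()
  if (!id %in% names(mods)) {
    stop("unknown model id '", id, "'; available: ",
         paste(names(mods), collapse = ", "))
  }
  mods[[id]]
}

#' Natural-frequency anchors versus EAA activity
#'
#' Identified \eqn{\omega_n} of the elbow plant at three activity levels for
#' subject A: higher total drive stiffens the joint and raises the natural
#' frequency. Used as the default anchor set for
#' [activity_omega_n_map()].
#'
#' @return A data frame with columns `a_e`, `omega_n` (rad/s).
#' @export
activity_anchors <- function() {
  raw <- .extdata("activity_anchors.json")
  data.frame(
    a_e = vapply(raw$anchors, function(x) x$a_e, numeric(1)),
    omega_n = vapply(raw$anchors, function(x) x$omega_n, numeric(1)))
}
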