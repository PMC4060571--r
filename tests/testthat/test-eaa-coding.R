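# EAA ratio/activity coding and current calibration

cal_b <- subject_calibration(
  flexor = muscle_calibration(i_max_ma = 11.5, i_min_ma = 2.5),
  extensor = muscle_calibration(i_max_ma = 11.0, i_min_ma = 5.0),
  subject_id = "B")

test_that("EAA decoding reproduces the defining identities", {
  expect_equal(eaa_to_normalized(0.5, 1), data.frame(i_f = 0.5, i_e = 0.5))
  expect_equal(eaa_to_normalized(1.0, 1), data.frame(i_f = 0.0, i_e = 1.0))
  expect_equal(eaa_to_normalized(0.0, 1), data.frame(i_f = 1.0, i_e = 0.0))
  # conservation and ratio identity over a grid
  r <- rep(seq(0, 1, by = 0.1), times = 5)
  a <- rep(c(0, 0.2, 0.5, 1, 1.8), each = 11)
  keep <- (1 - r) * a <= 1 & r * a <= 1
  nm <- eaa_to_normalized(r[keep], a[keep])
  expect_equal(nm$i_f + nm$i_e, a[keep], tolerance = 1e-12)
  pos <- a[keep] > 0
  expect_equal((nm$i_e / (nm$i_f + nm$i_e))[pos], r[keep][pos],
               tolerance = 1e-12)
})

test_that("normalized_to_eaa inverts eaa_to_normalized; rest is NA", {
  expect_equal(normalized_to_eaa(0.5, 0.5), data.frame(r_e = 0.5, a_e = 1.0))
  expect_equal(normalized_to_eaa(0.2, 0.8), data.frame(r_e = 0.8, a_e = 1.0))
  back <- normalized_to_eaa(0, 0)
  expect_true(is.na(back$r_e))
  expect_identical(back$a_e, 0)
  # roundtrip property over a random grid of valid commands
  set.seed(7)
  r <- runif(200)
  a <- runif(200, 0.01, 1 / pmax(r, 1 - r))
  nm <- eaa_to_normalized(r, a)
  rt <- normalized_to_eaa(nm$i_f, nm$i_e)
  expect_equal(rt$r_e, r, tolerance = 1e-12)
  expect_equal(rt$a_e, a, tolerance = 1e-12)
})

test_that("monotonicity in the ratio at fixed activity", {
  r <- seq(0, 1, by = 0.01)
  nm <- eaa_to_normalized(r, 0.8)
  expect_true(all(diff(nm$i_e) >= 0))
  expect_true(all(diff(nm$i_f) <= 0))
})

test_that("unrealizable commands are rejected, naming the muscle", {
  expect_error(eaa_to_normalized(0.9, 1.5), "extensor")
  expect_error(eaa_to_normalized(0.1, 1.5), "flexor")
  # marginal floating-point excess is clamped
  nm <- eaa_to_normalized(1 + 1e-12, 1)
  expect_equal(nm$i_e, 1)
  expect_error(eaa_to_normalized(1.01, 1), "outside")
})

test_that("current (de)normalization is the calibrated affine map", {
  expect_equal(denormalize_current(0.5, cal_b$extensor), 8.0)
  expect_equal(denormalize_current(1.0, cal_b$flexor), 11.5)
  expect_equal(denormalize_current(0.0, cal_b$flexor), 2.5)
  expect_equal(normalize_current(8.0, cal_b$extensor), 0.5)
  expect_equal(normalize_current(5.0, cal_b$extensor), 0.0)
  expect_equal(normalize_current(11.0, cal_b$extensor), 1.0)
  expect_error(denormalize_current(1.2, cal_b$flexor), "outside")
  expect_error(normalize_current(1.0, cal_b$flexor), "outside")
  # roundtrip at random intensities
  set.seed(11)
  x <- runif(100)
  expect_equal(normalize_current(denormalize_current(x, cal_b$flexor),
                                 cal_b$flexor), x, tolerance = 1e-12)
})

test_that("calibration invariants are enforced", {
  expect_error(muscle_calibration(5, 5), "exceed")
  expect_error(muscle_calibration(5, -1), ">= 0")
})

test_that("subject-B sweep currents reproduce the worked-example sinusoids", {
  tr <- sweep_sinusoid(0.3)
  cur <- command_trace_to_currents(tr, cal_b)
  o <- attr(tr, "onset")
  tt <- (seq_len(nrow(tr)) - o) / 1000
  post <- tt >= 0
  expect_equal(cur$i_e_ma[post], -3.0 * sin(2 * pi * tt[post] / 0.3) + 8.0,
               tolerance = 1e-13)
  expect_equal(cur$i_f_ma[post], 4.5 * sin(2 * pi * tt[post] / 0.3) + 7.0,
               tolerance = 1e-13)
  # spot values: sin = 1 at T/4 and the offsets at onset
  at <- function(t) which.min(abs(tt - t))
  expect_equal(cur$i_f_ma[at(0.3 / 4)], 11.5, tolerance = 1e-12)
  expect_equal(cur$i_e_ma[at(0.3 / 4)], 5.0, tolerance = 1e-12)
  expect_equal(cur$i_f_ma[at(0)], 7.0, tolerance = 1e-12)
  expect_equal(cur$i_e_ma[at(0)], 8.0, tolerance = 1e-12)
})

test_that("rest maps to both channels off, not to threshold current", {
  tr <- sweep_sinusoid(0.3, lead = "off")
  cur <- command_trace_to_currents(tr, cal_b)
  lead <- !tr$active
  expect_true(any(lead))
  expect_true(all(cur$i_f_ma[lead] == 0))
  expect_true(all(cur$i_e_ma[lead] == 0))
  # constant midpoint command gives constant midpoint currents
  n <- 50
  tr2 <- eaa_trace((0:(n - 1)) / 1000, rep(0.5, n), rep(1, n),
                   rep(TRUE, n), 1000)
  cur2 <- command_trace_to_currents(tr2, cal_b)
  expect_true(all(cur2$i_f_ma == 7.0))
  expect_true(all(cur2$i_e_ma == 8.0))
})

test_that("trace conversion propagates unrealizable-command errors", {
  n <- 10
  tr <- eaa_trace((0:(n - 1)) / 1000, rep(0.9, n), rep(1.5, n),
                  rep(TRUE, n), 1000)
  expect_error(command_trace_to_currents(tr, cal_b), "unrealizable")
})
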