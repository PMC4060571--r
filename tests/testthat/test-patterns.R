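# Stimulation protocol generators

test_that("sinusoidal sweep hits its defining sample values", {
  tr <- sweep_sinusoid(0.3)
  o <- attr(tr, "onset")
  rate <- attr(tr, "sample_rate")
  expect_equal(tr$r_e[o], 0.5)                       # sin 0
  expect_equal(tr$r_e[o + round(0.3 / 4 * rate)], 0.0)   # sin = 1
  expect_equal(tr$r_e[o + round(3 * 0.3 / 4 * rate)], 1.0)  # sin = -1
  expect_true(all(tr$r_e[tr$active] >= 0 & tr$r_e[tr$active] <= 1))
  # measured window has exactly n_cycles * rate * T samples
  expect_identical(nrow(tr) - o + 1L, as.integer(10 * rate * 0.3))
  expect_type(o, "integer")
})

test_that("sweep lead-in is balanced hold by default, off on request", {
  tr_h <- sweep_sinusoid(0.2)
  lead <- seq_len(round(0.5 * 1000))
  expect_true(all(tr_h$active[lead]))
  expect_true(all(tr_h$r_e[lead] == 0.5))
  tr_o <- sweep_sinusoid(0.2, lead = "off")
  expect_true(all(!tr_o$active[lead]))
  expect_true(all(is.na(tr_o$r_e[lead])))
  expect_true(all(tr_o$a_e[lead] == 0))
  # warm-up cycles shift the measured onset but not the phase at onset
  tr_w <- sweep_sinusoid(0.2, warmup_cycles = 3)
  expect_identical(attr(tr_w, "onset"), 500L + 3L * 200L + 1L)
  expect_equal(tr_w$r_e[attr(tr_w, "onset")], 0.5)
})

test_that("frequency grid is 17 periods, 0.1 to 0.5 s in 0.025 s steps", {
  g <- frequency_grid()
  expect_length(g, 17)
  expect_equal(g[1], 0.1)
  expect_equal(g[17], 0.5)
  expect_equal(unique(round(diff(g), 10)), 0.025)
  omega <- 2 * pi / g
  expect_equal(range(omega), c(2 * pi / 0.5, 2 * pi / 0.1))
})

test_that("composite input is the weighted combination and stays in [0,1]", {
  tr <- composite_sinusoid(start_delay = 0)
  at <- function(t) tr$r_e[which.min(abs(tr$time_s - t))]
  expect_equal(at(0), 0.5)       # both components at centre
  expect_equal(at(0.15), 0.3)    # 0.6*0.5 + 0.4*0
  expect_true(all(tr$r_e[tr$active] >= 0 & tr$r_e[tr$active] <= 1))
  # degenerate single-component case reduces to the plain sweep
  tr1 <- composite_sinusoid(weights = 1, periods = 0.6, duration = 1.2,
                            start_delay = 0.5)
  sw <- sweep_sinusoid(0.6, n_cycles = 2)
  expect_equal(tr1$r_e[tr1$active], sw$r_e[attr(sw, "onset"):nrow(sw)],
               tolerance = 1e-12)
})

test_that("step trace follows the staircase schedule", {
  tr <- step_trace(step_schedule())
  at <- function(t) tr$r_e[which.min(abs(tr$time_s - t))]
  expect_equal(at(1), 0.0)    # first dwell
  expect_equal(at(4), 0.2)    # one increment after 3 s
  expect_equal(at(16), 1.0)   # five increments completed
  expect_equal(at(19), 0.8)   # descending limb
  expect_equal(max(tr$r_e), 1.0)
  expect_equal(tr$r_e[length(tr$r_e)], 0.0)
  # level changes exactly at dwell boundaries
  expect_equal(unique(tr$r_e[tr$time_s >= 3 & tr$time_s < 6]), 0.2)
  expect_error(step_trace(step_schedule(start_level = 0.1)), NA)
})

test_that("burst trace stimulates only inside the burst windows", {
  tr <- burst_trace(burst_spec())
  at <- function(t) which.min(abs(tr$time_s - t))
  expect_equal(tr$r_e[at(1.0)], 0.5)     # burst onset, sin 0
  expect_equal(tr$r_e[at(1.125)], 0.0)   # sin(pi/2) = 1
  expect_false(tr$active[at(3.0)])       # between bursts: off
  expect_true(is.na(tr$r_e[at(3.0)]))
  expect_equal(tr$a_e[at(3.0)], 0)
  expect_true(all(tr$active[at(4.0):at(4.99)]))
  # overlap rejected
  expect_error(burst_spec(burst_starts = c(1, 1.5)), "overlap")
  # degenerate single burst matches the sweep shape
  tr1 <- burst_trace(burst_spec(period = 0.5, n_cycles = 2, burst_starts = 0),
                     tail = 0)
  sw <- sweep_sinusoid(0.5, n_cycles = 2, start_delay = 0)
  expect_equal(tr1$r_e, sw$r_e[attr(sw, "onset"):nrow(sw)], tolerance = 1e-12)
})

test_that("AM carrier modulates a 60 Hz sine by the envelope", {
  # constant envelope: pure sinusoid of that amplitude
  w <- am_carrier(rep(8, 100), sample_rate = 1000)
  expect_equal(w$current_ma, 8 * sin(2 * pi * 60 * w$time_s), tolerance = 1e-12)
  expect_equal(am_carrier(rep(0, 50))$current_ma, rep(0, 295))
  expect_error(am_carrier(c(1, -1)), ">= 0")
  expect_error(am_carrier(rep(1, 10), output_rate = 300), "10x")
  # cycle-peak series tracks a slowly varying envelope (worked-example form)
  tt <- (0:999) / 1000
  env <- -3 * sin(2 * pi * tt / 0.3) + 8
  w2 <- am_carrier(env, sample_rate = 1000, output_rate = 6000)
  per <- 100  # samples per carrier cycle at 6 kHz
  n_cyc <- floor(nrow(w2) / per)
  peaks <- vapply(seq_len(n_cyc), function(k) {
    max(abs(w2$current_ma[((k - 1) * per + 1):(k * per)]))
  }, numeric(1))
  centres <- (seq_len(n_cyc) - 0.5) / 60
  env_at <- -3 * sin(2 * pi * centres / 0.3) + 8
  expect_lt(max(abs(peaks - env_at)), 0.6)
})
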