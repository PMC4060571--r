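# Identification pipeline: cycle averaging, harmonic regression, Bode
# assembly, slope and SOPDT fitting

test_that("harmonic regression is exact on single-harmonic input", {
  tt <- (0:299) / 1000
  fit <- harmonic_fit(2 * sin(2 * pi * tt / 0.3) + 3, period = 0.3, t = tt)
  expect_equal(fit$amplitude, 2, tolerance = 1e-12)
  expect_equal(fit$phase, 0, tolerance = 1e-12)
  expect_equal(fit$offset, 3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  fit2 <- harmonic_fit(cos(2 * pi * tt / 0.3), period = 0.3, t = tt)
  expect_equal(fit2$amplitude, 1, tolerance = 1e-12)
  expect_equal(fit2$phase, pi / 2, tolerance = 1e-12)
  expect_equal(fit2$offset, 0, tolerance = 1e-12)
  # zero residual for any p sin + q cos + c (phase convention pinned)
  set.seed(2)
  for (i in 1:5) {
    p <- rnorm(1); q <- rnorm(1); c0 <- rnorm(1)
    f <- p * sin(2 * pi * tt / 0.3) + q * cos(2 * pi * tt / 0.3) + c0
    ft <- harmonic_fit(f, period = 0.3, t = tt)
    expect_equal(ft$sin_coef, p, tolerance = 1e-10)
    expect_equal(ft$cos_coef, q, tolerance = 1e-10)
    expect_equal(ft$phase, atan2(q, p), tolerance = 1e-10)
    recon <- ft$amplitude * sin(2 * pi * tt / 0.3 + ft$phase) + ft$offset
    expect_equal(recon, f, tolerance = 1e-10)
  }
  expect_error(harmonic_fit(1:5, period = 0.3), ">= 8 samples")
})

test_that("steady-cycle averaging uses cycles 3-8 only", {
  rate <- 1000; T <- 0.2; np <- round(T * rate)
  one <- sin(2 * pi * (0:(np - 1)) / np)
  f10 <- rep(one, 10)
  ft <- force_trace((seq_along(f10) - 1) / rate, f10, rate,
                    period = T, onset = 1L)
  avg <- steady_cycle_average(ft)
  expect_equal(avg$force_n, one, tolerance = 1e-12)
  expect_equal(nrow(avg), np)
  # corrupting cycles 1, 2, 9, 10 leaves the average unchanged
  f_bad <- f10
  f_bad[c(1:(2 * np), (8 * np + 1):(10 * np))] <- 99
  ft_bad <- force_trace(ft$time_s, f_bad, rate, period = T, onset = 1L)
  expect_equal(steady_cycle_average(ft_bad)$force_n, one, tolerance = 1e-12)
  # too few cycles is an error
  short <- force_trace((0:(5 * np - 1)) / rate, rep(one, 5), rate,
                       period = T, onset = 1L)
  expect_error(steady_cycle_average(short), "too few cycles")
})

test_that("Bode assembly references the input sinusoid amplitude and phase", {
  mk_fit <- function(A, phi, T) {
    tt <- (0:(round(1000 * T) - 1)) / 1000
    harmonic_fit(A * sin(2 * pi * tt / T + phi) + 0.3, period = T, t = tt)
  }
  # output amplitude 0.5 = unity gain; in phase with the -sin input
  bode <- bode_assemble(list(mk_fit(0.5, pi, 0.5), mk_fit(0.25, pi, 0.25)))
  expect_equal(bode$gain_db, c(0, 20 * log10(0.5)))
  expect_equal(bode$phase, c(0, 0))
  expect_equal(bode$omega, 2 * pi / c(0.5, 0.25))
  expect_true(all(diff(bode$omega) > 0))
  # offsets are carried through as the oscillation-centre diagnostic
  expect_equal(bode$offset, c(0.3, 0.3))
})

test_that("phase unwrapping is monotone decreasing for an SOPDT truth", {
  m <- example_model("E")   # tau = 0.1: > 2*pi total lag over the grid
  fits <- lapply(frequency_grid(), function(T) {
    tr <- sweep_sinusoid(T, warmup_cycles = ceiling(1 / T))
    harmonic_fit(steady_cycle_average(sopdt_simulate(m, tr)))
  })
  bode <- bode_assemble(fits)
  expect_true(all(diff(bode$phase) < 0))
  expect_lt(min(bode$phase), -2 * pi)  # genuinely unwrapped
  an <- analytic_response(m, bode$omega)
  expect_equal(bode$phase, an$phase, tolerance = 0.005)
})

test_that("gain slope: -40 dB/dec on the asymptote, 0 on flat gain", {
  m <- sopdt_model(2, 15, 1, 0)
  omega <- 10^seq(log10(150), log10(1500), length.out = 12)
  bode <- analytic_bode(m, periods = 2 * pi / omega)
  expect_equal(fit_gain_slope(bode, band = rep(TRUE, 12)), -40,
               tolerance = 0.013)
  flat <- structure(data.frame(omega = omega, gain_db = 5,
                               phase = rep(0, 12)),
                    class = c("bode_table", "data.frame"))
  expect_equal(fit_gain_slope(flat, band = rep(TRUE, 12)), 0,
               tolerance = 1e-10)
  # over the standard measurement grid the slope is shallower than -40
  gr <- analytic_bode(sopdt_model(11.22, 20.5, 1, 0.05))
  sl <- fit_gain_slope(gr)
  expect_lt(sl, 0)
  expect_gt(sl, -40)
  expect_error(fit_gain_slope(gr, band = 1:2), ">= 3 points")
})

test_that("SOPDT fitting recovers parameters from analytic Bode data", {
  truth <- sopdt_model(8.91, 20.5, 1, 0.045)
  fit <- fit_sopdt(analytic_bode(truth))
  expect_equal(fit$k, truth$k, tolerance = 5e-3)
  expect_equal(fit$omega_n, truth$omega_n, tolerance = 5e-3)
  expect_equal(fit$tau, truth$tau, tolerance = 1e-4)
  expect_equal(fit$zeta, 1)
  # zero-dead-time system fits tau at (essentially) zero
  fit0 <- fit_sopdt(analytic_bode(sopdt_model(3, 22, 1, 0)))
  expect_lt(fit0$tau, 1e-3)
  expect_error(fit_sopdt(analytic_bode(truth, periods = c(0.1, 0.2, 0.3))),
               ">= 5")
})

test_that("identification is equivariant under force rescaling", {
  s <- sample_subject(17, noise_sd = 0)
  lambda <- 2.7
  fits <- list(); fits_l <- list()
  for (T in frequency_grid()[seq(1, 17, by = 4)]) {
    tr <- sweep_sinusoid(T, warmup_cycles = ceiling(0.6 / T))
    cyc <- steady_cycle_average(sopdt_simulate(s$plant, tr))
    cyc_l <- cyc
    cyc_l$force_n <- lambda * cyc$force_n
    fits[[length(fits) + 1]] <- harmonic_fit(cyc)
    fits_l[[length(fits_l) + 1]] <- harmonic_fit(cyc_l)
  }
  m1 <- fit_sopdt(bode_assemble(fits))
  m2 <- fit_sopdt(bode_assemble(fits_l))
  expect_equal(m2$k, lambda * m1$k, tolerance = 1e-9)
  expect_equal(m2$omega_n, m1$omega_n, tolerance = 1e-9)
  expect_equal(m2$tau, m1$tau, tolerance = 1e-12)
})

test_that("full pipeline recovers ground truth at zero noise", {
  s <- sample_subject(6, noise_sd = 0)
  id <- identify_subject(s, n_trials = 1)
  expect_equal(id$model$k, s$plant$k, tolerance = 5e-3)
  expect_equal(id$model$omega_n, s$plant$omega_n, tolerance = 5e-3)
  expect_lt(abs(id$model$tau - s$plant$tau), 1e-3)
})
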