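test_that("Welch dB spectra locate tones and scale logarithmically", {
  fs <- 600
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  psd <- compute_psd_db(rbind(x), fs)
  grid <- psd$frequencies
  expect_equal(grid[which.max(psd$psd_db[1, ])], 10)

  psd2 <- compute_psd_db(rbind(2 * x), fs)
  expect_equal(psd2$psd_db[1, ] - psd$psd_db[1, ],
               rep(20 * log10(2), length(grid)), tolerance = 1e-9)

  xna <- x; xna[5] <- NA
  expect_error(compute_psd_db(rbind(xna), fs), "NaN")
  expect_error(compute_psd_db(rbind(x), fs = 60), "sampling rate")
})

test_that("white noise has a flat dB spectrum", {
  set.seed(8)
  x <- matrix(rnorm(600 * 60), 1)
  psd <- compute_psd_db(x, fs = 600)
  slope <- coef(lm(psd$psd_db[1, ] ~ log10(psd$frequencies)))[2]
  expect_lt(abs(slope), 0.5)
})

test_that("timescale estimator realizes its definition on an exact-ACF signal", {
  # construct a signal whose circular autocorrelation is exactly
  # exp(-lag/tau): amplitude spectrum = sqrt(FFT of the ACF), random
  # phases
  fs <- 600; n <- fs * 60; tau <- 0.05
  k <- 0:(n - 1)
  r <- exp(-(pmin(k, n - k) / fs) / tau)
  S <- pmax(Re(fft(r)), 0)
  ph <- with_seed(13, runif(n / 2 - 1, 0, 2 * pi))
  X <- complex(modulus = sqrt(S), argument = 0)
  X[2:(n / 2)] <- complex(modulus = sqrt(S[2:(n / 2)]), argument = ph)
  X[n:(n / 2 + 2)] <- Conj(X[2:(n / 2)])
  x <- Re(fft(X, inverse = TRUE)) / n
  ts <- acf_timescale(matrix(x, 1), fs, band = NULL)
  expect_equal(ts$tau_acf, 50, tolerance = 2 / 50)  # one lag step = 1.67 ms
  expect_equal(ts$acf[1], 1)
})

test_that("timescale is monotone in the OU time constant", {
  fs <- 600; n <- fs * 60
  ou <- function(tau, seed) {
    with_seed(seed, as.numeric(
      stats::filter(rnorm(n), exp(-1 / (fs * tau)), "recursive")))
  }
  taus <- c(0.02, 0.05, 0.1)
  est <- sapply(1:8, function(s)
    sapply(taus, function(tg) acf_timescale(matrix(ou(tg, s), 1), fs,
                                            band = NULL)$tau_acf))
  expect_true(all(apply(est, 2, diff) > 0))
})

test_that("mean-ACF-first ordering is what the estimator computes", {
  # two regions with very different exact ACFs; averaging the ACFs first
  # gives a different crossing than averaging per-region crossings
  fs <- 600; n <- fs * 60
  mk <- function(tau, seed) {
    k <- 0:(n - 1)
    r <- exp(-(pmin(k, n - k) / fs) / tau)
    S <- pmax(Re(fft(r)), 0)
    ph <- with_seed(seed, runif(n / 2 - 1, 0, 2 * pi))
    X <- complex(modulus = sqrt(S), argument = 0)
    X[2:(n / 2)] <- complex(modulus = sqrt(S[2:(n / 2)]), argument = ph)
    X[n:(n / 2 + 2)] <- Conj(X[2:(n / 2)])
    Re(fft(X, inverse = TRUE)) / n
  }
  two <- rbind(mk(0.02, 1), mk(0.2, 2))
  ts <- acf_timescale(two, fs, band = NULL)
  # analytic mean-ACF crossing: mean(exp(-t/20ms), exp(-t/200ms)) = 1/e
  f <- function(t) 0.5 * (exp(-t / 20) + exp(-t / 200)) - exp(-1)
  t_mean_first <- uniroot(f, c(1, 500))$root
  t_then_avg <- (20 + 200) / 1  # per-region crossings are the taus
  expect_equal(ts$tau_acf, t_mean_first, tolerance = 0.05)
  expect_gt(abs(t_mean_first - mean(c(20, 200))), 20)  # orders disagree
})

test_that("timescale estimator raises on non-decaying input", {
  fs <- 600
  t <- seq(0, 12, by = 1 / fs)
  x <- sin(2 * pi * 0.2 * t)  # ACF oscillates slowly, stays high
  expect_error(acf_timescale(matrix(x[1:(fs * 12)], 1), fs, band = NULL,
                             max_lag_s = 0.05), "never drops")
  expect_error(acf_timescale(matrix(rnorm(fs * 2), 1), fs), "10 s")
})

test_that("spectral parameterization recovers constructed components", {
  freqs <- seq(1, 35, 0.5)
  lf <- log10(freqs)
  # pure 1/f^2 aperiodic input (exponent 2 in log10-power space)
  db_ap <- 10 * (2.5 - 2 * lf)
  ps <- parameterize_spectrum(db_ap, freqs)
  expect_lt(abs(ps$aperiodic_exponent - 2), 0.1)
  expect_identical(ps$n_peaks, 0L)
  expect_identical(ps$flag, "no_peaks")
  expect_true(is.na(ps$first_cf))

  g <- function(f, amp, cf, sd) amp * exp(-(f - cf)^2 / (2 * sd^2))
  # single peak at 10 Hz, bandwidth 3 Hz (sd 1.5), amplitude 0.6 log10
  db1 <- 10 * (2.5 - 1.5 * lf + g(freqs, 0.6, 10, 1.5))
  p1 <- parameterize_spectrum(db1, freqs)
  expect_lt(abs(p1$first_cf - 10), 0.25)
  expect_identical(p1$second_cf, p1$first_cf)  # duplication rule
  expect_gte(min(p1$peaks$bandwidth), 2)
  expect_lt(p1$rmse_db, 0.5)

  # two peaks at 6 and 10 Hz, ascending order
  db2 <- 10 * (2.2 - 1.2 * lf + g(freqs, 0.7, 6, 1.2) +
                 g(freqs, 0.5, 10, 1.5))
  p2 <- parameterize_spectrum(db2, freqs)
  expect_gte(p2$n_peaks, 2)
  expect_lt(abs(p2$first_cf - 6), 0.25)
  expect_lt(abs(p2$second_cf - 10), 0.25)
  expect_lt(p2$rmse_db, 0.5)
  expect_lt(abs(p2$aperiodic_exponent - 1.2), 0.1)

  expect_error(parameterize_spectrum(db1[1:5], freqs[1:5]), "10 grid")
})
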