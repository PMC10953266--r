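test_that("gamma ensemble response matches closed form and a discrete transform", {
  expect_identical(gamma_response_ft(0.01, 0), 1 + 0i)
  # w tau = 1: F = 1/(1+i)^2 = -0.5i
  tau <- 0.01
  f1 <- 1 / (2 * pi * tau)
  expect_equal(gamma_response_ft(tau, f1), -0.5i, tolerance = 1e-12)
  expect_equal(Mod(gamma_response_ft(tau, f1)), 0.5, tolerance = 1e-12)
  expect_error(gamma_response_ft(0, 5), "tau")

  # discrete-transform oracle: direct numerical Fourier integral of the
  # sampled kernel f(t) = (t/tau^2) exp(-t/tau)
  dt <- 1e-5
  t <- seq(0, 0.5, by = dt)
  ker <- (t / tau^2) * exp(-t / tau)
  for (f in c(1, 10, 35)) {
    num <- sum(ker * exp(-1i * 2 * pi * f * t)) * dt
    expect_lt(Mod(num - gamma_response_ft(tau, f)) /
                Mod(gamma_response_ft(tau, f)), 1e-3)
  }
})

test_that("local transfer function has the correct decoupled limits", {
  p <- sgm_params(10, 20, 0.5, 10, 0.001, 0.5, 10)
  p$g_ei <- 0  # decouple (below the optimization lower bound)
  lt0 <- local_transfer(p, 0)
  expect_equal(lt0$X_e, 0.010 + 0i, tolerance = 1e-12)

  f <- default_freqs()
  lt <- local_transfer(p, f)
  w <- 2 * pi * f
  Fe <- gamma_response_ft(0.010, f)
  Fi <- gamma_response_ft(0.020, f)
  expect_equal(lt$H_local,
               1 / (1i * w + Fe / 0.010) + 1 / (1i * w + 0.5 * Fi / 0.020),
               tolerance = 1e-12)
})

test_that("local transfer matches a time-domain simulation oracle", {
  p <- fix_params_mid()
  sim <- simulate_local(p, duration = 40, dt = 5e-4, noise_sd = 1,
                        impulse = 0, seed = 42, common_drive = TRUE)
  x <- sim$x_e + sim$x_i
  psd <- compute_psd_db(matrix(x, 1), fs = 2000, grid = default_freqs())
  href <- 20 * log10(Mod(local_transfer(p, default_freqs())$H_local))
  expect_gt(cor(psd$psd_db[1, ], href), 0.95)
})

test_that("model spectrum is symmetric when the graph is homogeneous", {
  n <- 6
  w <- matrix(1, n, n); diag(w) <- 0
  conn <- connectome(w, matrix(0, n, n))
  p <- fix_params_mid()
  for (drv in c("iid", "uniform")) {
    sp <- model_spectrum(p, conn, freqs = c(2, 10, 25), drive = drv)
    expect_lt(max(abs(sweep(sp$psd_db, 2, sp$psd_db[1, ]))), 1e-9)
  }
})

test_that("eigenmode expansion equals direct solve for both drive conventions", {
  conn <- fix_conn(10, seed = 17)
  p <- fix_params()
  for (drv in c("iid", "uniform")) {
    se <- model_spectrum(p, conn, method = "eigen", drive = drv)
    ss <- model_spectrum(p, conn, method = "solve", drive = drv)
    expect_lt(max(Mod(se$response - ss$response)), 1e-8)
  }
})

test_that("standard initial parameter set yields finite cortical PSD at scale", {
  conn <- gen_connectome(86, 0.3, seed = 11)
  sp <- model_spectrum(fix_params(), conn, method = "solve")
  expect_true(all(is.finite(sp$psd_db[conn$cortical_mask, ])))
  expect_equal(sp$psd_db, 20 * log10(Mod(sp$response)), tolerance = 1e-12)
})

test_that("uniform-drive response obeys conjugate symmetry in frequency", {
  conn <- fix_conn(8, seed = 19)
  p <- fix_params_mid()
  sp <- model_spectrum(p, conn, freqs = c(-12, 12), method = "eigen",
                       drive = "uniform")
  expect_equal(sp$response[, 1], Conj(sp$response[, 2]), tolerance = 1e-10)
})

test_that("|F_G| is strictly decreasing in frequency", {
  f <- default_freqs()
  for (tg in c(0.006, 0.015, 0.03)) {
    expect_true(all(diff(Mod(gamma_response_ft(tg, f))) < 0))
  }
})

test_that("PSD is continuous in the parameters", {
  conn <- fix_conn(10, seed = 23)
  p <- fix_params_mid()
  b <- sgm_bounds()
  base <- model_spectrum(p, conn, method = "solve")$psd_db
  v0 <- unlist(p[b$param])
  for (j in seq_len(7)) {
    v <- v0
    v[j] <- v[j] + 1e-6 * (b$upper[j] - b$lower[j])
    pj <- sgm_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7])
    pert <- model_spectrum(pj, conn, method = "solve")$psd_db
    expect_lt(max(abs(pert - base)), 0.1)
  }
})

test_that("stability criterion handles decoupled and reference cases", {
  p <- sgm_params(15, 40, 0.5, 10, 0.001, 1.5, 10)
  p$g_ei <- 0
  expect_true(is_stable(p))
  expect_true(is_stable(fix_params()))
  # strongly coupled gains beyond the stable region (verified against
  # the Euler simulation oracle)
  expect_false(is_stable(sgm_params(20, 40, 0.5, 8, 0.6, 1.4, 11)))
})

test_that("PSD csv round trip preserves values", {
  conn <- fix_conn(5, seed = 3)
  sp <- model_spectrum(fix_params_mid(), conn, freqs = c(2, 10, 30))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_psd_csv(sp$psd_db, sp$frequencies, path)
  back <- read_psd_csv(path)
  expect_equal(back$psd_db, sp$psd_db, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$frequencies, sp$frequencies)
})
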