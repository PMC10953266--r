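test_that("spectral correlation matches hand-computed Pearson values", {
  m <- rbind(c(1, 2, 3), c(4, 5, 6))
  expect_identical(spectral_correlation(m, m), 1)
  expect_identical(spectral_correlation(m, -m), -1)
  # region 1: r = 1 (exact linear); region 2: r = 0.5 by hand
  # (x = (1,2,3), y = (1,3,2): sum of centered products 1, sds sqrt(2))
  emp <- rbind(c(2, 4, 6), c(1, 3, 2))
  model <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(spectral_correlation(model, emp), 0.75, tolerance = 1e-12)
  expect_error(spectral_correlation(rbind(c(1, 1, 1)), rbind(c(1, 2, 3))),
               "zero-variance")
})

test_that("spectral correlation is invariant to additive dB shifts", {
  set.seed(4)
  a <- matrix(rnorm(30), 5)
  b <- matrix(rnorm(30), 5)
  expect_equal(spectral_correlation(a, b + 7.3),
               spectral_correlation(a, b), tolerance = 1e-12)
})

test_that("spatial correlation reduces to Pearson for zero connectivity", {
  x <- c(1, 2, 5, 3)
  y <- c(2, 1, 4, 4)
  C0 <- matrix(0, 4, 4)
  expect_equal(spatial_correlation(x, x, C0), 1, tolerance = 1e-12)
  expect_equal(spatial_correlation(x, -x, C0), -1, tolerance = 1e-12)
  expect_equal(spatial_correlation(x, y, C0), cor(x, y), tolerance = 1e-12)
  expect_error(spatial_correlation(c(1, 1, 1), c(1, 2, 3),
                                   matrix(0, 3, 3)), "constant")
})

test_that("spatial correlation matches explicit matrix arithmetic", {
  Crn <- matrix(c(0, .5, .5,
                  .5, 0, .5,
                  .5, .5, 0), 3, 3, byrow = TRUE)
  x <- c(1, 2, 3); y <- c(3, 2, 1)
  # independent hand evaluation
  zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  M <- Crn + 10 * diag(3)
  M <- M / rowSums(M)
  expected <- sum(zs(x) * (M %*% zs(y))) / 3
  expect_equal(spatial_correlation(x, y, Crn, w = 10), expected,
               tolerance = 1e-12)
})

test_that("alpha band power sums raw power on both sides", {
  freqs <- seq(1, 35, 0.5)
  sel <- freqs >= 8 & freqs <= 12
  # model side: flat |X| = 2 over the nine points of [8, 12]
  resp <- matrix(2 + 0i, 1, length(freqs))
  sp <- structure(list(frequencies = freqs, response = resp,
                       psd_db = 20 * log10(Mod(resp))),
                  class = "sgm_spectrum")
  expect_equal(sum(sel), 9)
  expect_equal(unname(alpha_band_power(sp)), 9 * 4)
  expect_error(alpha_band_power(sp, band = c(40, 50)), "band outside")
  # empirical de-log round trip
  pw <- runif(9, 1, 5)
  db <- 10 * log10(pw)
  expect_equal(10^(db / 10), pw, tolerance = 1e-12)
  emp <- regional_psd(freqs, matrix(0, 1, length(freqs)))
  expect_equal(unname(alpha_band_power(emp)), 9)
})

test_that("fit_subject is deterministic and respects its contracts", {
  conn <- fix_conn(10, seed = 31)
  truth <- fix_params_mid()
  emp <- fix_subject(truth, conn, id = "det")
  cfg <- fix_fast_cfg(seed = 42)
  f1 <- fit_subject(emp, conn, cfg)
  f2 <- fit_subject(emp, conn, cfg)
  expect_identical(params_to_vec(f1$params), params_to_vec(f2$params))
  expect_identical(f1$objective, f2$objective)

  # objective bookkeeping and stability postcondition
  expect_equal(f1$objective, f1$spectral_corr + f1$spatial_corr,
               tolerance = 1e-12)
  expect_true(all(f1$per_region_r >= -1 & f1$per_region_r <= 1))
  expect_true(is_stable(f1$params))
  # accepted objective is the max over the stage's restarts
  expect_gte(f1$objective + 1e-9, max(f1$start_objectives))
  expect_true(f1$stage_used %in% 1:3)
  expect_true(f1$start_index %in% 1:3)
})

test_that("noiseless refit recovers tau_G", {
  conn <- fix_conn(10, seed = 37)
  truth <- sgm_params(tau_e = 14, tau_i = 60, alpha = 0.6, v = 11,
                      g_ei = 0.3, g_ii = 0.7, tau_G = 12)
  expect_true(is_stable(truth))
  emp <- fix_subject(truth, conn, id = "rec")
  fr <- fit_subject(emp, conn, fit_config(maxiter = 40, n_inner = 8,
                                          polish_maxit = 60, seed = 9))
  expect_gt(fr$spectral_corr, 0.99)
  expect_lt(abs(fr$params$tau_G - truth$tau_G) / truth$tau_G, 0.15)
})

test_that("progressive refit attributes fit quality to the varying parameter", {
  conn <- fix_conn(10, seed = 41)
  # cohort in which only tau_G varies
  base <- c(tau_e = 12, tau_i = 50, alpha = 0.6, v = 10, g_ei = 0.25,
            g_ii = 0.5, tau_G = NA)
  tgs <- c(6, 11, 16, 24)
  psds <- list(); fits <- list()
  for (i in seq_along(tgs)) {
    v <- base; v["tau_G"] <- tgs[i]
    p <- vec_to_params(v)
    stopifnot(is_stable(p))
    psds[[i]] <- fix_subject(p, conn, id = paste0("s", i))
    fits[[i]] <- structure(list(params = p, converged = TRUE),
                           class = "sgm_fit")
  }
  cfg <- fit_config(maxiter = 15, n_inner = 6, polish_maxit = 25, seed = 3)
  prog <- progressive_refit(fits, psds, conn, cfg,
                            order = c("tau_G", "tau_e", "g_ii"))
  expect_equal(prog$freed, c("None", "tau_G", "tau_e", "g_ii"))
  # freeing tau_G produces the single largest increase
  inc <- diff(prog$mean_spectral_corr)
  expect_equal(which.max(inc), 1L)
  # with tau_G free the (otherwise true-valued) model is near perfect
  expect_gt(prog$mean_spectral_corr[2], 0.99)
  # step 0 cannot beat the full refit
  expect_lte(prog$mean_spectral_corr[1], max(prog$mean_spectral_corr) + 1e-9)
  expect_error(progressive_refit(list(), list(), conn, cfg, "tau_G"),
               "empty cohort")
})
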