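test_that("generated connectomes are valid, metric, and deterministic", {
  conn <- gen_connectome(20, 0.3, seed = 5)
  expect_s3_class(conn, "connectome")  # constructor enforces invariants
  expect_equal(sum(conn$cortical_mask), round(20 * 68 / 86))

  # Euclidean distances obey the triangle inequality on all triples
  d <- conn$distances
  worst <- max(vapply(1:20, function(k)
    max(d - outer(d[, k], d[k, ], "+")), numeric(1)))
  expect_lte(worst, 1e-9)

  conn2 <- gen_connectome(20, 0.3, seed = 5)
  expect_identical(conn$weights, conn2$weights)
  expect_identical(conn$distances, conn2$distances)
  conn3 <- gen_connectome(20, 0.3, seed = 6)
  expect_false(identical(conn$weights, conn3$weights))
  expect_error(gen_connectome(2), "n_regions")
})

test_that("cohort generation respects the degenerate-SD limit and linkages", {
  conn <- gen_connectome(12, 0.4, seed = 2)
  spec <- synth_cohort_spec(n_per_group = 3, seed = 4)
  spec$param_sds <- lapply(spec$param_sds, function(s) s * 0 + 1e-9)
  coh <- gen_cohort(spec, conn, freqs = seq(2, 30, 2))
  pat <- coh$subjects[coh$subjects$group == "patient", ]
  expect_equal(pat$true_tau_G, rep(13.90, 3), tolerance = 1e-6)
  expect_equal(pat$true_tau_e, rep(15.01, 3), tolerance = 1e-6)
  expect_equal(pat$true_g_ii, rep(0.46, 3), tolerance = 1e-6)
  ctl <- coh$subjects[coh$subjects$group == "control", ]
  expect_equal(ctl$true_tau_G, rep(7.50, 3), tolerance = 1e-6)
  expect_true(all(is.na(ctl$cdr_sob)))
  expect_true(all(pat$cdr_sob >= 0))
  expect_true(all(coh$subjects$mmse >= 0 & coh$subjects$mmse <= 30))
})

test_that("MMSE is negatively coupled to the true long-range time constant", {
  conn <- gen_connectome(12, 0.4, seed = 2)
  neg <- vapply(1:20, function(r) {
    spec <- synth_cohort_spec(n_per_group = 10, seed = 1000 + r)
    coh <- gen_cohort(spec, conn, freqs = seq(2, 30, 2))
    cor(coh$subjects$mmse, coh$subjects$true_tau_G) < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("cohort subjects carry stable ground truth and valid spectra", {
  conn <- gen_connectome(12, 0.4, seed = 3)
  spec <- synth_cohort_spec(n_per_group = 4, seed = 9)
  coh <- gen_cohort(spec, conn)
  expect_equal(nrow(coh$subjects), 8)
  for (i in seq_len(8)) {
    tv <- as.numeric(coh$subjects[i, paste0("true_", c(
      "tau_e", "tau_i", "alpha", "v", "g_ei", "g_ii", "tau_G"))])
    expect_true(is_stable(vec_to_params(tv)))
  }
  expect_true(all(vapply(coh$psds, function(p)
    all(is.finite(p$psd_db)), logical(1))))
  # determinism
  coh2 <- gen_cohort(spec, conn)
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$psds[[1]]$psd_db, coh2$psds[[1]]$psd_db)
})

test_that("surrogate time series reproduce the model spectra", {
  conn <- gen_connectome(10, 0.4, seed = 7)
  p <- fix_params_mid()
  ts1 <- gen_timeseries(p, conn, duration = 30, fs = 300, seed = 3)
  ts2 <- gen_timeseries(p, conn, duration = 30, fs = 300, seed = 3)
  expect_identical(ts1, ts2)
  expect_equal(dim(ts1), c(10, 9000))

  grid <- seq(1, 35, 1)
  emp <- compute_psd_db(ts1, fs = 300, grid = grid)
  mod <- model_spectrum(p, conn, freqs = grid, method = "solve")
  rs <- vapply(1:10, function(j) cor(emp$psd_db[j, ], mod$psd_db[j, ]),
               numeric(1))
  expect_gt(min(rs), 0.85)

  expect_error(gen_timeseries(sgm_params(20, 40, 0.5, 8, 0.6, 1.4, 11),
                              conn, duration = 12, fs = 300), "unstable")
})

test_that("doubling tau_G slows the intrinsic timescale", {
  conn <- gen_connectome(10, 0.4, seed = 8)
  base <- c(tau_e = 12, tau_i = 40, alpha = 0.7, v = 9, g_ei = 0.25,
            g_ii = 0.5, tau_G = NA)
  taus <- vapply(1:10, function(s) {
    est <- vapply(c(7, 14), function(tg) {
      v <- base; v["tau_G"] <- tg
      ts <- gen_timeseries(vec_to_params(v), conn, duration = 20,
                           fs = 300, seed = 100 + s)
      acf_timescale(ts, fs = 300)$tau_acf
    }, numeric(1))
    est[2] > est[1]
  }, logical(1))
  expect_gte(mean(taus), 0.8)
})

test_that("zero-noise spectra are essentially perfectly fittable", {
  conn <- gen_connectome(12, 0.4, seed = 11)
  spec <- synth_cohort_spec(n_per_group = 1, seed = 2,
                            spectrum_noise_db = 0)
  coh <- gen_cohort(spec, conn)
  fr <- fit_subject(coh$psds[[1]], conn,
                    fit_config(maxiter = 30, n_inner = 8,
                               polish_maxit = 40, seed = 6))
  expect_gt(fr$spectral_corr, 0.99)
})
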