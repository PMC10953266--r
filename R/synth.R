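# Synthetic-data generation: distance-embedded connectomes, per-group
# parameter draws with the reported effect directions, model-consistent
# spectra/time series, covariates and cognition scores — all with
# retained ground truth for recovery tests.

# Truncated-normal draw by rejection (bounds are Table-scale wide, so
# acceptance is high); deterministic given the RNG state.
rtruncnorm1 <- function(mean, sd, lower, upper) {
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncated-normal rejection failed; check mean/sd against bounds")
}

#' Cohort specification for the synthetic generator
#'
#' Group means default to the reported control/patient values of the
#' three group-shifted parameters (`tau_G` 7.50/13.90 ms, `tau_e`
#' 11.88/15.01 ms, `g_ii` 0.26/0.46) with SDs 3 ms / 3 ms / 0.15; the
#' remaining parameters are group-invariant at mid-bound. Cognition is
#' linked negatively to `tau_G` only.
#'
#' @param n_per_group subjects per group.
#' @param param_means,param_sds named lists with `control`/`patient`
#'   7-vectors (canonical order).
#' @param spectrum_noise_db additive dB noise SD on generated spectra.
#' @param mmse_model list `intercept`, `tau_G_coef` (negative), `sd`.
#' @param cdr_model list `intercept`, `tau_G_coef` (positive), `sd`
#'   (patients only).
#' @param age_dist list with `control`/`patient` `c(mean, sd)` in years.
#' @param seed base seed.
#' @return an object of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_per_group = 20,
                              param_means = NULL, param_sds = NULL,
                              spectrum_noise_db = 2,
                              mmse_model = list(intercept = 30,
                                                tau_G_coef = -0.6, sd = 3),
                              cdr_model = list(intercept = -1,
                                               tau_G_coef = 0.42, sd = 2),
                              age_dist = list(control = c(65.07, 9.92),
                                              patient = c(62.73, 8.64)),
                              seed = 1) {
  b <- sgm_bounds()
  mid <- (b$lower + b$upper) / 2
  names(mid) <- b$param
  base <- mid
  ctrl <- base; ctrl[c("tau_G", "tau_e", "g_ii")] <- c(7.50, 11.88, 0.26)
  pat <- base; pat[c("tau_G", "tau_e", "g_ii")] <- c(13.90, 15.01, 0.46)
  if (is.null(param_means)) param_means <- list(control = ctrl, patient = pat)
  if (is.null(param_sds)) {
    sds <- c(tau_e = 3, tau_i = 10, alpha = 0.1, v = 1.5, g_ei = 0.05,
             g_ii = 0.15, tau_G = 3)[SGM_PARAM_NAMES]
    param_sds <- list(control = sds, patient = sds)
  }
  for (g in c("control", "patient")) {
    m <- param_means[[g]][SGM_PARAM_NAMES]
    if (any(m < b$lower | m > b$upper))
      stop("param mean outside bounds for group ", g)
    if (any(param_sds[[g]] <= 0)) stop("param SDs must be positive")
  }
  structure(list(n_per_group = n_per_group, param_means = param_means,
                 param_sds = param_sds,
                 spectrum_noise_db = spectrum_noise_db,
                 mmse_model = mmse_model, cdr_model = cdr_model,
                 age_dist = age_dist, seed = seed),
            class = "synth_cohort_spec")
}

#' Generate a synthetic distance-embedded connectome
#'
#' Regions are placed uniformly in a 140 mm-diameter sphere; distances
#' are Euclidean (mm); weights follow an exponential distance rule
#' `exp(-d / 40)` thresholded to the target edge density, symmetrized
#' with zero diagonal. Any region isolated by the threshold keeps its
#' strongest edge so the graph stays connected. A fixed 79% subset
#' (the 68/86 cortical proportion) is marked cortical.
#'
#' @param n_regions number of regions (>= 3).
#' @param density target edge density in (0, 1].
#' @param seed RNG seed.
#' @return a [connectome()].
#' @export
gen_connectome <- function(n_regions = 86, density = 0.35, seed = 1) {
  stopifnot(n_regions >= 3, density > 0, density <= 1)
  with_seed(seed, {
    # uniform in a sphere of radius 70 mm
    pts <- matrix(NA_real_, n_regions, 3)
    k <- 0
    while (k < n_regions) {
      p <- runif(3, -70, 70)
      if (sum(p^2) <= 70^2) { k <- k + 1; pts[k, ] <- p }
    }
    d <- as.matrix(dist(pts))
    w <- exp(-d / 40)
    diag(w) <- 0
    ut <- w[upper.tri(w)]
    thr <- quantile(ut, 1 - density)
    w[w < thr] <- 0
    # re-link any isolated region through its strongest edge
    for (i in which(rowSums(w) == 0)) {
      j <- which.max(exp(-d[i, ] / 40) * (seq_len(n_regions) != i))
      w[i, j] <- w[j, i] <- exp(-d[i, j] / 40)
    }
    mask <- rep(FALSE, n_regions)
    mask[seq_len(round(n_regions * 68 / 86))] <- TRUE
    connectome(w, d, cortical_mask = mask)
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per subject: parameters drawn truncated-normal within bounds from the
#' group's distribution and rejection-sampled until stable; the regional
#' spectrum is the SGM forward prediction plus i.i.d. Gaussian dB noise;
#' age is drawn from the group distribution; MMSE is linear in the true
#' `tau_G` plus noise, clipped to `[0, 30]`; patients additionally get a
#' CDR score.
#'
#' @param spec a [synth_cohort_spec()].
#' @param conn a [connectome()].
#' @param freqs frequency grid for the generated spectra.
#' @return list with `subjects` (data.frame: id, group, age, mmse,
#'   cdr_sob, and `true_*` parameter columns) and `psds` (named list of
#'   [regional_psd()] restricted to cortical regions).
#' @export
gen_cohort <- function(spec, conn, freqs = default_freqs()) {
  b <- sgm_bounds()
  mask <- conn$cortical_mask
  subjects <- list(); psds <- list()
  for (grp in c("control", "patient")) {
    mns <- spec$param_means[[grp]][SGM_PARAM_NAMES]
    sds <- spec$param_sds[[grp]][SGM_PARAM_NAMES]
    for (i in seq_len(spec$n_per_group)) {
      id <- sprintf("%s_%02d", grp, i)
      sseed <- derive_seed(spec$seed, id)
      sub <- with_seed(sseed, {
        p <- NULL
        for (try in 1:1000) {
          v <- vapply(seq_len(7), function(j)
            rtruncnorm1(mns[j], sds[j], b$lower[j], b$upper[j]), numeric(1))
          names(v) <- SGM_PARAM_NAMES
          cand <- vec_to_params(v)
          if (is_stable(cand)) { p <- cand; break }
        }
        if (is.null(p)) stop("stability rejection loop exceeded 1000 draws")
        age <- max(30, rnorm(1, spec$age_dist[[grp]][1],
                             spec$age_dist[[grp]][2]))
        mmse <- min(30, max(0, spec$mmse_model$intercept +
                              spec$mmse_model$tau_G_coef * p$tau_G +
                              rnorm(1, 0, spec$mmse_model$sd)))
        cdr <- if (grp == "patient")
          max(0, spec$cdr_model$intercept +
                spec$cdr_model$tau_G_coef * p$tau_G +
                rnorm(1, 0, spec$cdr_model$sd))
        else NA_real_
        spct <- model_spectrum(p, conn, freqs, method = "solve")
        db <- spct$psd_db[mask, , drop = FALSE]
        if (spec$spectrum_noise_db > 0)
          db <- db + matrix(rnorm(length(db), 0, spec$spectrum_noise_db),
                            nrow(db))
        list(p = p, age = age, mmse = mmse, cdr = cdr, db = db)
      })
      row <- data.frame(id = id, group = grp, age = sub$age,
                        mmse = sub$mmse, cdr_sob = sub$cdr,
                        stringsAsFactors = FALSE)
      tv <- params_to_vec(sub$p)
      for (pn in SGM_PARAM_NAMES) row[[paste0("true_", pn)]] <- tv[[pn]]
      subjects[[id]] <- row
      psds[[id]] <- regional_psd(freqs, sub$db, subject_id = id)
    }
  }
  list(subjects = do.call(rbind, c(subjects, list(make.row.names = FALSE))),
       psds = psds)
}

#' Generate model-consistent regional time series
#'
#' Builds the full complex SGM frequency-response matrix at the FFT bin
#' frequencies, applies it to i.i.d. complex Gaussian bin amplitudes,
#' Hermitian-symmetrizes and inverse-FFTs, yielding real time series
#' whose auto- and cross-spectra follow the model.
#'
#' @param params a stable [sgm_params()].
#' @param conn a [connectome()].
#' @param duration length in seconds (>= 10).
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @param f_max responses above this frequency are set to zero (the
#'   model response is negligible there); default `min(100, fs/2)`.
#' @return regions x samples matrix (rows named by region).
#' @export
gen_timeseries <- function(params, conn, duration = 60, fs = 600, seed = 1,
                           f_max = min(100, fs / 2)) {
  stopifnot(duration >= 10)
  if (!is_stable(params)) stop("unstable parameter set")
  n <- conn$n
  nt <- round(duration * fs)
  nb <- nt %/% 2  # positive-frequency bins 1..nb (skip DC)
  fbin <- (1:nb) * fs / nt
  keep <- fbin <= f_max
  wnorm <- degree_normalize(conn$weights, "row")
  Z <- with_seed(seed, matrix(complex(real = rnorm(n * sum(keep)),
                                      imaginary = rnorm(n * sum(keep))) /
                                sqrt(2), n, sum(keep)))
  Y <- matrix(0i, n, nb)
  Y[, keep] <- .sgm_response_cpp(wnorm, conn$distances, fbin[keep],
                                 params$tau_e / 1000, params$tau_i / 1000,
                                 params$tau_G / 1000, params$g_ei,
                                 params$g_ii, params$g_ee, params$alpha,
                                 params$v, Z)
  spec <- matrix(0i, n, nt)
  spec[, 2:(nb + 1)] <- Y
  spec[, nt:(nt - nb + 1)] <- Conj(Y)  # Hermitian symmetry
  if (nt %% 2 == 0) spec[, nb + 1] <- Re(spec[, nb + 1])  # real Nyquist
  ts <- t(apply(spec, 1, function(s) Re(fft(s, inverse = TRUE)) / sqrt(nt)))
  rownames(ts) <- conn$labels
  ts
}
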