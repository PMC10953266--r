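# Per-subject SGM parameter inference: spectral + spatial correlation
# objective, bounded simulated annealing with staged stability bounds on
# the neural gains, and the progressive parameter-importance refit.

#' Container for an empirical regional power spectrum
#'
#' @param frequencies strictly increasing frequency grid, Hz.
#' @param psd_db regions x frequencies matrix in dB, rows named by region.
#' @param subject_id optional subject identifier.
#' @return an object of class `regional_psd`.
#' @export
regional_psd <- function(frequencies, psd_db, subject_id = NA_character_) {
  psd_db <- as.matrix(psd_db)
  stopifnot(length(frequencies) == ncol(psd_db))
  if (any(diff(frequencies) <= 0))
    stop("frequency grid must be strictly increasing")
  if (any(!is.finite(psd_db))) stop("non-finite PSD values")
  structure(list(frequencies = frequencies, psd_db = psd_db,
                 subject_id = subject_id),
            class = "regional_psd")
}

get_psd_db <- function(x) {
  if (inherits(x, c("regional_psd", "sgm_spectrum"))) x$psd_db
  else as.matrix(x)
}

#' Spectral correlation between modeled and empirical spectra
#'
#' Pearson r per region across frequencies (both sides in dB), averaged
#' over regions.
#'
#' @param model_psd,emp_psd matrices (regions x frequencies) or
#'   `regional_psd` / `sgm_spectrum` objects on the same region set and
#'   frequency grid.
#' @return mean Pearson r.
#' @export
spectral_correlation <- function(model_psd, emp_psd) {
  mean(row_pearson(get_psd_db(model_psd), get_psd_db(emp_psd)))
}

#' Connectome-smoothed spatial correlation of regional power maps
#'
#' Both maps are z-scored across regions (population convention), and the
#' statistic is `x' M y / N` with `M` the row-normalized `C + w I`. With
#' zero connectivity (`M = I`) this is exactly the Pearson correlation of
#' the two maps.
#'
#' @param x,y regional power vectors (same length, nonconstant).
#' @param C_rownorm row-degree-normalized connectivity matrix restricted
#'   to the regions of `x`/`y`.
#' @param w smoothing weight on the identity (default 10).
#' @return scalar spatial correlation.
#' @export
spatial_correlation <- function(x, y, C_rownorm, w = 10) {
  n <- length(x)
  stopifnot(length(y) == n, all(dim(C_rownorm) == c(n, n)))
  M <- row_normalize(C_rownorm + w * diag(n))
  as.numeric(zscore_pop(x) %*% M %*% zscore_pop(y)) / n
}

#' Regional band power
#'
#' Model spectra contribute `sum |X(f)|^2` over grid points in the band;
#' empirical dB spectra are de-logged first (`10^(dB/10)`), i.e. both
#' sides are raw power.
#'
#' @param psd an `sgm_spectrum` (model) or `regional_psd` / dB matrix
#'   with `freqs` supplied (empirical).
#' @param band frequency interval, Hz (default alpha, 8-12).
#' @param freqs grid when `psd` is a bare matrix.
#' @return named regional power vector.
#' @export
alpha_band_power <- function(psd, band = c(8, 12), freqs = NULL) {
  if (inherits(psd, "sgm_spectrum")) {
    sel <- psd$frequencies >= band[1] & psd$frequencies <= band[2]
    if (!any(sel)) stop("band outside frequency grid")
    return(rowSums(Mod(psd$response[, sel, drop = FALSE])^2))
  }
  if (inherits(psd, "regional_psd")) {
    freqs <- psd$frequencies
    psd <- psd$psd_db
  }
  if (is.null(freqs)) stop("freqs required for a bare dB matrix")
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band outside frequency grid")
  rowSums(10^(psd[, sel, drop = FALSE] / 10))
}

#' Configuration for per-subject SGM fitting
#'
#' @param bounds outer bounds data.frame, see [sgm_bounds()].
#' @param gain_stages list of per-stage `(g_ei upper, g_ii upper)` pairs;
#'   successive stages tighten the gain bounds toward the stable region.
#' @param initial_guesses matrix of starting points, see
#'   [sgm_initial_guesses()].
#' @param maxiter annealing iterations (500 for production fits; reduce
#'   for desk-scale runs).
#' @param spatial_weight smoothing weight `w` of the spatial correlation.
#' @param alpha_band band (Hz) for the spatial power map.
#' @param seed base seed; per-subject/stage/start chains are derived
#'   deterministically from it.
#' @param n_modes eigenmode truncation passed to the forward model
#'   (`NULL` = all modes, computed by direct solve).
#' @param n_inner proposals per annealing iteration.
#' @param polish run a bounded quasi-Newton polish from the annealed
#'   optimum.
#' @param polish_maxit iteration cap of the polish (its numerical
#'   gradients dominate cost at small `maxiter`).
#' @param polish_mode `"best"` polishes only the winning restart of a
#'   stage (cheaper); `"each"` polishes every restart.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(bounds = sgm_bounds(),
                       gain_stages = list(c(0.7, 2.0), c(0.5, 1.5),
                                          c(0.4, 1.5)),
                       initial_guesses = sgm_initial_guesses(),
                       maxiter = 500, spatial_weight = 10,
                       alpha_band = c(8, 12), seed = 1, n_modes = NULL,
                       n_inner = 14, polish = TRUE, polish_maxit = 100,
                       polish_mode = c("best", "each")) {
  stopifnot(maxiter >= 1, nrow(initial_guesses) == 3)
  for (k in seq_along(gain_stages)[-1]) {
    if (any(gain_stages[[k]] > gain_stages[[k - 1]] + 1e-12))
      stop("gain_stages must be non-expanding")
  }
  structure(list(bounds = bounds, gain_stages = gain_stages,
                 initial_guesses = initial_guesses, maxiter = maxiter,
                 spatial_weight = spatial_weight, alpha_band = alpha_band,
                 seed = seed, n_modes = n_modes, n_inner = n_inner,
                 polish = polish, polish_maxit = polish_maxit,
                 polish_mode = match.arg(polish_mode)),
            class = "fit_config")
}

# Reflect a proposal back into [lower, upper] (folding walk).
reflect_bounds <- function(x, lower, upper) {
  rng <- upper - lower
  y <- (x - lower) %% (2 * rng)
  pmin(pmax(lower + ifelse(y > rng, 2 * rng - y, y), lower), upper)
}

#' Bounded simulated annealing with local polish
#'
#' Generalized simulated annealing in the style of dual annealing:
#' Cauchy-distributed visiting moves scaled by a geometrically cooled
#' temperature, Metropolis acceptance, periodic restart from the
#' incumbent best, and a final bounded L-BFGS-B polish.
#'
#' @param fn scalar function to minimize.
#' @param x0 starting point.
#' @param lower,upper box bounds.
#' @param maxiter cooling iterations.
#' @param seed RNG seed for this chain.
#' @param n_inner proposals per iteration.
#' @param t0,tmin initial / final temperature.
#' @param polish run L-BFGS-B from the best point found.
#' @param polish_maxit L-BFGS-B iteration cap.
#' @return list with `par`, `value`, `evals`.
#' @export
sa_anneal <- function(fn, x0, lower, upper, maxiter = 100, seed = 1,
                      n_inner = 2 * length(x0), t0 = 1, tmin = 1e-3,
                      polish = TRUE, polish_maxit = 100) {
  with_seed(seed, {
    npar <- length(x0)
    rng <- upper - lower
    x <- pmin(pmax(x0, lower), upper)
    fx <- fn(x)
    best <- x; fbest <- fx
    evals <- 1L
    q <- (tmin / t0)^(1 / maxiter)
    Tk <- t0
    for (it in seq_len(maxiter)) {
      Tk <- Tk * q
      for (j in seq_len(n_inner)) {
        xn <- reflect_bounds(x + rcauchy(npar) * 0.1 * Tk * rng, lower, upper)
        fxn <- fn(xn)
        evals <- evals + 1L
        d <- fxn - fx
        if (d <= 0 || runif(1) < exp(-d / (0.1 * Tk))) { x <- xn; fx <- fxn }
        if (fxn < fbest) { best <- xn; fbest <- fxn }
      }
      if (it %% 20 == 0) { x <- best; fx <- fbest }
    }
    if (polish) {
      pr <- tryCatch(
        optim(best, fn, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = polish_maxit)),
        error = function(e) NULL)
      if (!is.null(pr) && is.finite(pr$value) && pr$value < fbest) {
        best <- pr$par; fbest <- pr$value
      }
    }
    list(par = best, value = fbest, evals = evals)
  })
}

# Objective closure: negative (spectral + spatial) correlation of the SGM
# forward model against an empirical PSD, with instability tracking.
# The heavy lifting (forward solve + correlations) happens in C++; the R
# layer only maps the free subspace and tracks the best stable point.
make_sgm_objective <- function(emp_db, emp_alpha, conn, cfg,
                               fixed = NULL, free = SGM_PARAM_NAMES) {
  wnorm <- degree_normalize(conn$weights, "row")
  mask <- conn$cortical_mask
  # row-normalize over the full graph, then restrict to cortical regions
  # (a cortical region may connect only to subcortex; + w I keeps the
  # smoother row sums positive)
  Csub <- wnorm[mask, mask, drop = FALSE]
  Msm <- row_normalize(Csub + cfg$spatial_weight * diag(sum(mask)))
  freqs <- attr(emp_db, "frequencies")
  band <- cfg$alpha_band
  bsel <- freqs >= band[1] & freqs <= band[2]
  if (!any(bsel)) stop("alpha band outside frequency grid")
  emp_c <- emp_db - rowMeans(emp_db)
  emp_norm <- sqrt(rowSums(emp_c^2))
  if (any(emp_norm == 0)) stop("zero-variance empirical spectrum")
  smooth_y <- as.numeric(Msm %*% zscore_pop(emp_alpha))
  mask_idx <- which(mask) - 1L
  band_idx <- which(bsel) - 1L
  free_idx <- match(free, SGM_PARAM_NAMES)
  base <- if (is.null(fixed)) rep(NA_real_, 7) else fixed

  env <- new.env(parent = emptyenv())
  env$best_stable <- NULL
  env$best_stable_val <- Inf

  full_theta <- function(theta) {
    v <- base
    v[free_idx] <- theta
    v
  }
  obj <- function(theta) {
    v <- full_theta(theta)
    val <- .sgm_objective_cpp(wnorm, conn$distances, freqs, v, mask_idx,
                              emp_c, emp_norm, band_idx, smooth_y)
    if (val < env$best_stable_val &&
        is_stable(vec_to_params(v, check = FALSE))) {
      env$best_stable_val <- val
      env$best_stable <- v
    }
    val
  }
  list(obj = obj, env = env, full_theta = full_theta)
}

# Evaluate spectral/spatial/per-region stats of a parameter vector.
eval_fit_stats <- function(v, emp_db, emp_alpha, conn, cfg) {
  p <- vec_to_params(v, check = FALSE)
  freqs <- attr(emp_db, "frequencies")
  spec <- model_spectrum(p, conn, freqs, n_modes = cfg$n_modes,
                         method = "solve")
  mask <- conn$cortical_mask
  db <- spec$psd_db[mask, , drop = FALSE]
  per_r <- row_pearson(db, emp_db)
  mp <- rowSums(Mod(spec$response[mask, freqs >= cfg$alpha_band[1] &
                                    freqs <= cfg$alpha_band[2],
                                  drop = FALSE])^2)
  Csub <- degree_normalize(conn$weights, "row")[mask, mask, drop = FALSE]
  sp <- spatial_correlation(mp, emp_alpha, Csub, cfg$spatial_weight)
  list(params = p, spectral_corr = mean(per_r), spatial_corr = sp,
       objective = mean(per_r) + sp, per_region_r = per_r)
}

#' Fit SGM parameters to a subject's regional spectra
#'
#' Maximizes spectral + spatial correlation by simulated annealing from
#' three initial guesses. Neural-gain bounds are tightened over up to
#' three stages: if the best fit of a stage is unstable the next, tighter
#' stage is run; if no stage yields a stable optimum, the best stable
#' candidate evaluated anywhere is returned (explicit failure if none
#' was ever seen).
#'
#' @param emp_psd a [regional_psd()] whose rows match the cortical
#'   regions of `conn` (by name when named, else by order).
#' @param conn a [connectome()].
#' @param cfg a [fit_config()].
#' @param subject_id identifier used for seed derivation and reporting.
#' @param free optionally restrict optimization to a subset of parameter
#'   names, holding the rest at `fixed`.
#' @param fixed full-length named vector of fixed parameter values
#'   (canonical order) used when `free` is a subset.
#' @return an object of class `sgm_fit` with the accepted parameters,
#'   correlations, per-region r, provenance (`stage_used`,
#'   `start_index`) and a `converged` flag.
#' @export
fit_subject <- function(emp_psd, conn, cfg = fit_config(),
                        subject_id = emp_psd$subject_id,
                        free = SGM_PARAM_NAMES, fixed = NULL) {
  mask <- conn$cortical_mask
  cort <- conn$labels[mask]
  emp_db <- emp_psd$psd_db
  if (!is.null(rownames(emp_db)) && all(cort %in% rownames(emp_db)))
    emp_db <- emp_db[cort, , drop = FALSE]
  if (nrow(emp_db) != length(cort))
    stop("empirical PSD rows do not match cortical regions")
  attr(emp_db, "frequencies") <- emp_psd$frequencies
  emp_alpha <- alpha_band_power(emp_psd, cfg$alpha_band)[
    rownames(emp_db) %||% seq_len(nrow(emp_db))]

  ob <- make_sgm_objective(emp_db, emp_alpha, conn, cfg, fixed = fixed,
                           free = free)
  free_idx <- match(free, SGM_PARAM_NAMES)
  b <- cfg$bounds
  sid <- if (is.na(subject_id) || is.null(subject_id)) "anon" else subject_id

  accepted <- NULL
  if (length(free) > 0) {
    for (stage in seq_along(cfg$gain_stages)) {
      up <- b$upper
      up[5] <- cfg$gain_stages[[stage]][1]
      up[6] <- cfg$gain_stages[[stage]][2]
      lo <- b$lower[free_idx]; hi <- up[free_idx]
      stage_best <- NULL
      start_obj <- numeric(nrow(cfg$initial_guesses))
      polish_each <- cfg$polish && cfg$polish_mode == "each"
      for (start in seq_len(nrow(cfg$initial_guesses))) {
        x0 <- pmin(pmax(cfg$initial_guesses[start, free_idx], lo), hi)
        res <- sa_anneal(ob$obj, x0, lo, hi, maxiter = cfg$maxiter,
                         seed = derive_seed(cfg$seed, sid, stage, start),
                         n_inner = cfg$n_inner, polish = polish_each,
                         polish_maxit = cfg$polish_maxit)
        start_obj[start] <- -res$value
        if (is.null(stage_best) || res$value < stage_best$value) {
          stage_best <- res
          stage_best$start <- start
        }
      }
      if (cfg$polish && cfg$polish_mode == "best") {
        pr <- tryCatch(
          optim(stage_best$par, ob$obj, method = "L-BFGS-B", lower = lo,
                upper = hi, control = list(maxit = cfg$polish_maxit)),
          error = function(e) NULL)
        if (!is.null(pr) && is.finite(pr$value) &&
            pr$value < stage_best$value) {
          stage_best$par <- pr$par
          stage_best$value <- pr$value
          start_obj[stage_best$start] <- -pr$value
        }
      }
      v <- ob$full_theta(stage_best$par)
      if (is_stable(vec_to_params(v, check = FALSE))) {
        accepted <- list(v = v, stage = stage, start = stage_best$start,
                         start_objectives = start_obj)
        break
      }
    }
  } else {
    accepted <- list(v = ob$full_theta(numeric(0)), stage = 0L, start = 0L)
  }
  if (is.null(accepted)) {
    if (is.null(ob$env$best_stable))
      return(structure(list(subject_id = sid, converged = FALSE,
                            params = NULL,
                            message = "no stable candidate in any stage"),
                       class = "sgm_fit"))
    accepted <- list(v = ob$env$best_stable, stage = NA_integer_,
                     start = NA_integer_)
  }
  st <- eval_fit_stats(accepted$v, emp_db, emp_alpha, conn, cfg)
  structure(c(st, list(stage_used = accepted$stage,
                       start_index = accepted$start,
                       start_objectives = accepted$start_objectives,
                       subject_id = sid, converged = TRUE)),
            class = "sgm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sgm_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("SGM fit FAILED for", x$subject_id, "-", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "SGM fit [%s]: spectral r = %.3f, spatial r = %.3f (stage %s, start %s)\n",
    x$subject_id, x$spectral_corr, x$spatial_corr, x$stage_used,
    x$start_index))
  print(x$params)
  invisible(x)
}

#' Progressive parameter-importance refit
#'
#' Step 0 fixes every parameter at the grand mean of the cohort's fitted
#' parameters (no optimization); step m frees the first m parameters of
#' `order` and refits each subject with the rest held at the grand
#' means. Reports the mean spectral correlation per step, quantifying how
#' much each parameter, in importance order, buys in spectral fit.
#'
#' @param cohort_fits list of converged [fit_subject()] results.
#' @param emp_psds list of matching [regional_psd()] objects.
#' @param conn a [connectome()].
#' @param cfg a [fit_config()].
#' @param order character vector: parameter names in importance order
#'   (a permutation prefix of the 7 names).
#' @return data.frame with `step`, `freed`, `mean_spectral_corr`.
#' @export
progressive_refit <- function(cohort_fits, emp_psds, conn, cfg, order) {
  if (length(cohort_fits) == 0) stop("empty cohort")
  stopifnot(all(order %in% SGM_PARAM_NAMES), !anyDuplicated(order),
            length(cohort_fits) == length(emp_psds))
  pm <- t(vapply(cohort_fits, function(f) params_to_vec(f$params),
                 numeric(7)))
  grand <- colMeans(pm)
  steps <- 0:length(order)
  msc <- numeric(length(steps))
  for (m in steps) {
    free <- if (m == 0) character(0) else order[seq_len(m)]
    rs <- vapply(seq_along(emp_psds), function(i) {
      fit_subject(emp_psds[[i]], conn, cfg,
                  subject_id = paste0("prog", m, "_", i),
                  free = free, fixed = grand)$spectral_corr
    }, numeric(1))
    msc[m + 1] <- mean(rs)
  }
  data.frame(step = steps, freed = c("None", order),
             mean_spectral_corr = msc, stringsAsFactors = FALSE)
}
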