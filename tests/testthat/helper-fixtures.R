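# Shared fixtures, all generated in code (no stored data).

# Canonical stable parameter set used across tests (first standard
# initial guess).
fix_params <- function() {
  sgm_params(tau_e = 15, tau_i = 10, alpha = 1, v = 5, g_ei = 0.3,
             g_ii = 0.6, tau_G = 6)
}

# Mid-range stable parameter set away from bound edges.
fix_params_mid <- function() {
  sgm_params(tau_e = 12, tau_i = 40, alpha = 0.7, v = 9, g_ei = 0.25,
             g_ii = 0.5, tau_G = 10)
}

# Small synthetic connectomes (deterministic).
fix_conn <- function(n = 10, density = 0.5, seed = 101) {
  gen_connectome(n, density, seed = seed)
}

# A hand-built 3-region connectome with simple numbers.
fix_conn3 <- function() {
  w <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3, byrow = TRUE)
  d <- matrix(c(0, 100, 50,
                100, 0, 80,
                50, 80, 0), 3, 3, byrow = TRUE)
  connectome(w, d, labels = c("A", "B", "C"))
}

# Random parameter draw within the outer bounds, uniform, optionally
# forced stable by rejection.
fix_random_params <- function(stable = TRUE, margin = 0) {
  b <- sgm_bounds()
  repeat {
    v <- runif(7, b$lower + margin * (b$upper - b$lower),
               b$upper - margin * (b$upper - b$lower))
    names(v) <- b$param
    p <- sgm_params(v[["tau_e"]], v[["tau_i"]], v[["alpha"]], v[["v"]],
                    v[["g_ei"]], v[["g_ii"]], v[["tau_G"]])
    if (!stable || is_stable(p)) return(p)
  }
}

# Noiseless model-generated subject on a connectome.
fix_subject <- function(params, conn, freqs = default_freqs(),
                        noise_db = 0, id = "synth", seed = 1) {
  sp <- model_spectrum(params, conn, freqs, method = "solve")
  db <- sp$psd_db[conn$cortical_mask, , drop = FALSE]
  if (noise_db > 0)
    db <- db + with_seed(seed, matrix(rnorm(length(db), 0, noise_db),
                                      nrow(db)))
  regional_psd(freqs, db, subject_id = id)
}

# Fast fitting profile for module tests.
fix_fast_cfg <- function(seed = 1, maxiter = 10) {
  fit_config(maxiter = maxiter, n_inner = 6, polish_maxit = 20, seed = seed)
}
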