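# Closed-form SGM forward model: Gamma ensemble response, local E-I
# transfer function, network spectrum via eigenmode expansion (with a
# direct-solve route as the fast/oracle path), and the pole-based
# stability criterion.

#' Default model frequency grid
#'
#' 1-35 Hz in 0.5 Hz steps, the broad band on which spectra are fitted.
#' @return numeric vector of frequencies, Hz.
#' @export
default_freqs <- function() seq(1, 35, by = 0.5)

#' Fourier transform of the Gamma-shaped ensemble response
#'
#' The unit-area kernel `f(t) = (t / tau^2) exp(-t / tau)` has transform
#' `F(w) = 1 / (1 + i w tau)^2`.
#'
#' @param tau time constant in seconds (> 0).
#' @param f frequency in Hz (vectorized).
#' @return complex vector `F(2 pi f)`.
#' @export
gamma_response_ft <- function(tau, f) {
  if (tau <= 0) stop("tau must be > 0")
  1 / (1 + 1i * 2 * pi * f * tau)^2
}

#' Local excitatory-inhibitory transfer function
#'
#' Solves the 2x2 frequency-domain E-I balance under unit white-noise
#' drive of both populations: with `a = iw + (g_ee/tau_e) F_e`,
#' `b = (g_ei/tau_e) F_e`, `c = (g_ei/tau_i) F_i`,
#' `d = iw + (g_ii/tau_i) F_i` and `Det = a d + b c`, the responses are
#' `X_e = (d - b)/Det`, `X_i = (c + a)/Det`, `H_local = X_e + X_i`.
#'
#' @param params an [sgm_params()] object.
#' @param f frequency in Hz (vectorized).
#' @return list with complex vectors `X_e`, `X_i`, `H_local`.
#' @export
local_transfer <- function(params, f) {
  w <- 2 * pi * f
  te <- params$tau_e / 1000
  ti <- params$tau_i / 1000
  Fe <- gamma_response_ft(te, f)
  Fi <- gamma_response_ft(ti, f)
  a <- 1i * w + (params$g_ee / te) * Fe
  b <- (params$g_ei / te) * Fe
  cc <- (params$g_ei / ti) * Fi
  d <- 1i * w + (params$g_ii / ti) * Fi
  det <- a * d + b * cc
  if (any(Mod(det) < 1e-15))
    stop("singular local system (parameters at instability)")
  list(X_e = (d - b) / det, X_i = (cc + a) / det,
       H_local = (d - b + cc + a) / det)
}

#' SGM network frequency response and power spectrum
#'
#' For each frequency the complex Laplacian `L(w)` of the connectome is
#' formed and the network transfer operator
#' `G(w) = (i w I + F_G(w)/tau_G L(w))^-1` is applied to the local
#' transfer output, either through the eigenmode expansion
#' `G(w) = U diag(1 / (i w + lambda_k F_G(w) / tau_G)) U^-1`
#' (default; supports mode truncation) or by the algebraically
#' equivalent direct linear solve (`method = "solve"`, the fast path;
#' the two routes cross-check each other). Under the default
#' `drive = "iid"` convention the returned response is the expected
#' root-power under independent unit white noise driving every region,
#' `|X_j| = sqrt(sum_k |G_jk|^2) |H_local|` (a real magnitude);
#' `drive = "uniform"` gives the coherent scalar-drive form
#' `X = G H 1`. PSD is `20 log10 |X|` (dB).
#'
#' @param params an [sgm_params()].
#' @param conn a [connectome()].
#' @param freqs frequency grid in Hz (default [default_freqs()]).
#' @param n_modes keep only the `n_modes` smallest-magnitude eigenmodes
#'   (`NULL` = all, exact).
#' @param mode degree normalization mode for the Laplacian.
#' @param method `"eigen"` or `"solve"` (equivalent when `n_modes` is
#'   `NULL`).
#' @param drive noise-drive convention: `"iid"` (independent per-region
#'   white noise, expected PSD; the default) or `"uniform"` (coherent
#'   unit drive of all regions).
#' @param hermitian_modes if `TRUE`, use the rank-one form
#'   `u_k u_k^H` instead of the exact `U ... U^-1` reconstruction (the
#'   two agree when the mode matrix is unitary).
#' @return an object of class `sgm_spectrum` with `frequencies`,
#'   `response` (N x F complex) and `psd_db` (N x F).
#' @export
model_spectrum <- function(params, conn, freqs = default_freqs(),
                           n_modes = NULL, mode = c("row", "symmetric"),
                           method = c("eigen", "solve"),
                           drive = c("iid", "uniform"),
                           hermitian_modes = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  drive <- match.arg(drive)
  n <- conn$n
  tg <- params$tau_G / 1000
  if (method == "solve" && is.null(n_modes) && !hermitian_modes &&
      mode == "row") {
    wnorm <- degree_normalize(conn$weights, "row")
    X <- .sgm_response_cpp(wnorm, conn$distances, freqs,
                           params$tau_e / 1000, params$tau_i / 1000, tg,
                           params$g_ei, params$g_ii, params$g_ee,
                           params$alpha, params$v,
                           matrix(1 + 0i, n, length(freqs)),
                           drive == "iid")
  } else {
    H <- local_transfer(params, freqs)$H_local
    Fg <- gamma_response_ft(tg, freqs)
    X <- matrix(0i, n, length(freqs))
    keep <- if (is.null(n_modes)) seq_len(n) else seq_len(min(n_modes, n))
    for (m in seq_along(freqs)) {
      f <- freqs[m]
      L <- complex_laplacian(conn, params$v, params$alpha, f, mode)
      if (method == "solve") {
        A <- 1i * 2 * pi * f * diag(n) + (Fg[m] / tg) * L
        G <- solve(A)
      } else {
        es <- eigensystem(L, f)
        filt <- 1 / (1i * 2 * pi * f + es$eigenvalues[keep] * Fg[m] / tg)
        Uk <- es$modes[, keep, drop = FALSE]
        Vk <- if (hermitian_modes) Conj(t(Uk))
              else es$modes_inverse[keep, , drop = FALSE]
        G <- Uk %*% (filt * Vk)
      }
      X[, m] <- if (drive == "iid")
        sqrt(rowSums(Mod(G)^2)) * Mod(H[m]) + 0i
      else G %*% rep(H[m] + 0i, n)
    }
  }
  if (any(!is.finite(Mod(X))))
    stop("non-finite model response; check parameter stability with is_stable()")
  rownames(X) <- conn$labels
  structure(list(frequencies = freqs, response = X,
                 psd_db = 20 * log10(Mod(X))),
            class = "sgm_spectrum")
}

#' @export
print.sgm_spectrum <- function(x, ...) {
  cat(sprintf("SGM spectrum: %d regions x %d frequencies (%.1f-%.1f Hz)\n",
              nrow(x$psd_db), length(x$frequencies), min(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

# Coefficients of the degree-6 stability polynomial in s: Det(s)
# multiplied by (1 + s tau_e)^2 (1 + s tau_i)^2 gives
# [s (1+s tau_e)^2 + g_ee/tau_e] [s (1+s tau_i)^2 + g_ii/tau_i]
#   + g_ei^2 / (tau_e tau_i).
# Coefficients returned in ascending powers of s.
stability_poly <- function(params) {
  te <- params$tau_e / 1000
  ti <- params$tau_i / 1000
  # s (1 + s t)^2 = s + 2 t s^2 + t^2 s^3, plus constant g/t
  pe <- c(params$g_ee / te, 1, 2 * te, te^2)
  pi_ <- c(params$g_ii / ti, 1, 2 * ti, ti^2)
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
        out[i:(i + length(b) - 1)] + a[i] * b
    out
  }
  p <- conv(pe, pi_)
  p[1] <- p[1] + params$g_ei^2 / (te * ti)
  p
}

#' Stability of the local E-I system
#'
#' Substitutes `s` for `i w` in the determinant of the local 2x2 system,
#' clears the Gamma-response denominators to obtain a degree-6 polynomial
#' in `s`, and declares the parameter set stable iff every root lies in
#' the open left half-plane.
#'
#' @param params an [sgm_params()] (validated against outer bounds).
#' @return logical.
#' @export
is_stable <- function(params) {
  r <- polyroot(stability_poly(params))
  all(Re(r) < 0)
}

#' Euler simulation of the local E-I system
#'
#' Time-domain realization of the same local circuit the frequency-domain
#' transfer function describes: each population's input is passed through
#' a cascade of two first-order stages with its Gamma time constant
#' (`x_e' = -(1/tau_e) [f_e * (g_ee x_e + g_ei x_i)] + P_e`,
#' `x_i' =  (1/tau_i) [f_i * (g_ei x_e - g_ii x_i)] + P_i`). Used as an
#' independent simulation oracle for [is_stable()] and [local_transfer()].
#'
#' @param params an [sgm_params()].
#' @param duration simulated time, s.
#' @param dt Euler step, s.
#' @param noise_sd white-noise drive SD (0 for impulse response).
#' @param impulse initial condition on `x_e` (impulse amplitude).
#' @param seed RNG seed when `noise_sd > 0`.
#' @param common_drive drive both populations with the same noise stream
#'   (the convention under which `H_local = X_e + X_i` is the scalar
#'   response); otherwise the two drives are independent.
#' @return list with `t`, `x_e`, `x_i` time courses.
#' @export
simulate_local <- function(params, duration = 2, dt = 1e-4, noise_sd = 0,
                           impulse = 1, seed = 1, common_drive = FALSE) {
  te <- params$tau_e / 1000
  ti <- params$tau_i / 1000
  nstep <- ceiling(duration / dt)
  xe <- numeric(nstep); xi <- numeric(nstep)
  s1e <- s2e <- s1i <- s2i <- 0
  xe[1] <- impulse
  noise <- if (noise_sd > 0)
    with_seed(seed, matrix(rnorm(2 * nstep, sd = noise_sd / sqrt(dt)),
                           nrow = 2))
  else matrix(0, 2, nstep)
  if (common_drive) noise[2, ] <- noise[1, ]
  for (k in seq_len(nstep - 1)) {
    inp_e <- params$g_ee * xe[k] + params$g_ei * xi[k]
    inp_i <- params$g_ei * xe[k] - params$g_ii * xi[k]
    s1e <- s1e + dt * (inp_e - s1e) / te
    s2e <- s2e + dt * (s1e - s2e) / te
    s1i <- s1i + dt * (inp_i - s1i) / ti
    s2i <- s2i + dt * (s1i - s2i) / ti
    xe[k + 1] <- xe[k] + dt * (-s2e / te + noise[1, k])
    xi[k + 1] <- xi[k] + dt * (s2i / ti + noise[2, k])
    if (!is.finite(xe[k + 1]) || !is.finite(xi[k + 1])) {
      xe[(k + 1):nstep] <- Inf; xi[(k + 1):nstep] <- Inf
      break
    }
  }
  list(t = (seq_len(nstep) - 1) * dt, x_e = xe, x_i = xi)
}

#' Write / read a regional PSD matrix as labeled CSV
#'
#' Rows are regions (first column `region`), remaining columns the
#' frequency grid (`f<Hz>` headers).
#'
#' @param psd_db regions x frequencies matrix with region rownames.
#' @param freqs frequency grid, Hz.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_psd_csv <- function(psd_db, freqs, path) {
  df <- data.frame(region = rownames(psd_db), psd_db, check.names = FALSE)
  colnames(df) <- c("region", sprintf("f%g", freqs))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psd_csv
#' @export
read_psd_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  freqs <- as.numeric(sub("^f", "", colnames(df)[-1]))
  list(psd_db = m, frequencies = freqs)
}
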