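# SGM biophysical parameters: the 7 free parameters plus the fixed
# excitatory gain g_ee = 1. Time constants are carried in milliseconds
# (the reporting unit); compute kernels convert to seconds.

# Canonical optimizer ordering of the free parameters.
SGM_PARAM_NAMES <- c("tau_e", "tau_i", "alpha", "v", "g_ei", "g_ii", "tau_G")

#' Outer optimization bounds for the SGM parameters
#'
#' Time constants in ms, speed in m/s, gains and coupling dimensionless.
#'
#' @return a data.frame with columns `param`, `lower`, `upper`.
#' @export
sgm_bounds <- function() {
  data.frame(
    param = SGM_PARAM_NAMES,
    lower = c(5, 5, 0.1, 5, 0.001, 0.001, 5),
    upper = c(30, 200, 1, 20, 0.7, 2.0, 30),
    stringsAsFactors = FALSE
  )
}

#' Standard initial guesses for SGM parameter estimation
#'
#' Three starting points spanning slow/fast local dynamics and weak/strong
#' coupling, in the canonical parameter order.
#'
#' @return a 3-row matrix, columns named by parameter.
#' @export
sgm_initial_guesses <- function() {
  m <- rbind(
    c(15, 10, 1, 5, 0.3, 0.6, 6),
    c(25, 8, 0.5, 10, 0.2, 0.1, 15),
    c(6, 150, 0.1, 18, 0.1, 1.2, 25)
  )
  colnames(m) <- SGM_PARAM_NAMES
  m
}

#' Construct a validated SGM parameter set
#'
#' @param tau_e,tau_i,tau_G excitatory / inhibitory / long-range (graph)
#'   time constants, ms.
#' @param alpha global coupling constant (dimensionless).
#' @param v transmission speed, m/s.
#' @param g_ei,g_ii excitatory-inhibitory and inhibitory-inhibitory gains.
#' @param check if `TRUE`, enforce the outer optimization bounds.
#' @return an object of class `sgm_params`; `g_ee` is always 1.
#' @export
sgm_params <- function(tau_e, tau_i, alpha, v, g_ei, g_ii, tau_G,
                       check = TRUE) {
  p <- list(tau_e = tau_e, tau_i = tau_i, alpha = alpha, v = v,
            g_ei = g_ei, g_ii = g_ii, tau_G = tau_G, g_ee = 1)
  p <- lapply(p, unname)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                         is.finite(x), logical(1))))
  if (check) {
    b <- sgm_bounds()
    vals <- unlist(p[SGM_PARAM_NAMES])
    bad <- which(vals < b$lower - 1e-12 | vals > b$upper + 1e-12)
    if (length(bad))
      stop("parameter out of bounds: ",
           paste(sprintf("%s = %g not in [%g, %g]", b$param[bad], vals[bad],
                         b$lower[bad], b$upper[bad]), collapse = "; "))
  }
  structure(p, class = "sgm_params")
}

#' @export
print.sgm_params <- function(x, ...) {
  cat("SGM parameters (g_ee fixed at 1):\n")
  cat(sprintf("  tau_e = %.3f ms, tau_i = %.3f ms, tau_G = %.3f ms\n",
              x$tau_e, x$tau_i, x$tau_G))
  cat(sprintf("  alpha = %.3f, v = %.3f m/s, g_ei = %.4f, g_ii = %.4f\n",
              x$alpha, x$v, x$g_ei, x$g_ii))
  invisible(x)
}

#' Convert between parameter objects and canonical-order vectors
#'
#' The canonical optimizer order is `tau_e, tau_i, alpha, v, g_ei,
#' g_ii, tau_G`.
#'
#' @param p an [sgm_params()].
#' @return `params_to_vec`: named length-7 numeric vector.
#' @export
params_to_vec <- function(p) unlist(p[SGM_PARAM_NAMES])

#' @rdname params_to_vec
#' @param v length-7 numeric vector in canonical order.
#' @param check enforce the outer bounds.
#' @return `vec_to_params`: an [sgm_params()].
#' @export
vec_to_params <- function(v, check = TRUE) {
  sgm_params(tau_e = v[1], tau_i = v[2], alpha = v[3], v = v[4],
             g_ei = v[5], g_ii = v[6], tau_G = v[7], check = check)
}

#' @export
as.data.frame.sgm_params <- function(x, ...) {
  as.data.frame(as.list(params_to_vec(x)))
}
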