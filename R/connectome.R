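# Structural connectome container and the frequency-dependent complex
# Laplacian whose eigenmodes carry the long-range model.

#' Construct a validated structural connectome
#'
#' @param weights N x N non-negative symmetric connectivity matrix
#'   (arbitrary units, zero diagonal).
#' @param distances N x N symmetric inter-region distance matrix (mm,
#'   zero diagonal).
#' @param labels character vector of N region names.
#' @param cortical_mask logical length-N vector marking the regions with
#'   empirical spectra (e.g. 68 cortical regions of an 86-region
#'   whole-brain parcellation). Defaults to all regions.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, distances, labels = NULL,
                       cortical_mask = NULL) {
  weights <- as.matrix(weights)
  distances <- as.matrix(distances)
  n <- nrow(weights)
  if (ncol(weights) != n || !all(dim(distances) == c(n, n)))
    stop("dimension mismatch: weights is ", nrow(weights), "x", ncol(weights),
         ", distances is ", nrow(distances), "x", ncol(distances))
  if (is.null(labels)) labels <- sprintf("region_%03d", seq_len(n))
  if (length(labels) != n)
    stop("dimension mismatch: ", length(labels), " labels for ", n, " regions")
  if (is.null(cortical_mask)) cortical_mask <- rep(TRUE, n)
  cortical_mask <- as.logical(cortical_mask)
  if (length(cortical_mask) != n)
    stop("dimension mismatch: cortical_mask length ", length(cortical_mask))

  check_sq <- function(m, what, tol = 1e-10) {
    if (any(!is.finite(m))) stop("non-finite ", what)
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop("negative ", what, " at (", neg[1, 1], ",", neg[1, 2], "): ",
           m[neg[1, , drop = FALSE]])
    asym <- abs(m - t(m))
    if (max(asym) > tol) {
      ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
      stop(what, " asymmetric beyond tolerance at (", ij[1], ",", ij[2],
           "): |", m[ij[1], ij[2]], " - ", m[ij[2], ij[1]], "|")
    }
    if (any(diag(m) != 0)) stop(what, " has nonzero diagonal")
  }
  check_sq(weights, "weight")
  check_sq(distances, "distance")
  rs <- rowSums(weights)
  if (any(rs <= 0))
    stop("isolated region (zero weight row sum): ", labels[which(rs <= 0)[1]])

  dimnames(weights) <- dimnames(distances) <- list(labels, labels)
  structure(list(weights = weights, distances = distances, labels = labels,
                 cortical_mask = cortical_mask, n = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d regions (%d cortical), density %.2f\n",
              x$n, sum(x$cortical_mask),
              mean(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Read a connectome from dense CSV matrix files
#'
#' Each file is a dense square matrix with a header row of region labels.
#'
#' @param weights_path,distances_path paths to CSV files.
#' @param labels optional region names (default: CSV header).
#' @param cortical_mask optional logical mask.
#' @return a validated [connectome()].
#' @export
load_connectome <- function(weights_path, distances_path, labels = NULL,
                            cortical_mask = NULL) {
  rd <- function(p) {
    m <- as.matrix(read.csv(p, check.names = FALSE))
    if (nrow(m) != ncol(m))
      stop("dimension mismatch: ", p, " parses to ", nrow(m), "x", ncol(m))
    m
  }
  w <- rd(weights_path)
  d <- rd(distances_path)
  if (is.null(labels)) labels <- colnames(w)
  connectome(w, d, labels = labels, cortical_mask = cortical_mask)
}

#' Write a connectome to dense CSV matrix files
#'
#' @param conn a [connectome()].
#' @param weights_path,distances_path output CSV paths.
#' @return `conn`, invisibly.
#' @export
write_connectome <- function(conn, weights_path, distances_path) {
  # %.17g so doubles round-trip bitwise through CSV
  wr <- function(m, p) {
    df <- as.data.frame(apply(m, 2, function(col) sprintf("%.17g", col)))
    colnames(df) <- colnames(m)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
  }
  wr(conn$weights, weights_path)
  wr(conn$distances, distances_path)
  invisible(conn)
}

#' Degree-normalize a connectivity matrix
#'
#' @param weights non-negative square matrix.
#' @param mode `"row"` (each row divided by its degree, the default used
#'   throughout the model) or `"symmetric"` (`c_jk / sqrt(deg_j deg_k)`).
#' @return normalized matrix.
#' @export
degree_normalize <- function(weights, mode = c("row", "symmetric")) {
  mode <- match.arg(mode)
  deg <- rowSums(weights)
  if (any(deg <= 0)) {
    nm <- if (!is.null(rownames(weights))) rownames(weights)[deg <= 0][1]
          else as.character(which(deg <= 0)[1])
    stop("zero row degree for region: ", nm)
  }
  if (mode == "row") weights / deg
  else weights / sqrt(outer(deg, deg))
}

#' Frequency-dependent complex Laplacian of a connectome
#'
#' `L(w) = I - alpha * C*(w)` where `C*(w)_jk = Cn_jk exp(-i w d_jk /
#' (1000 v))`, `Cn` the degree-normalized weights, `w = 2 pi f` rad/s,
#' distances in mm and speed in m/s (so `d/(1000 v)` is the conduction
#' delay in seconds).
#'
#' @param conn a [connectome()].
#' @param v transmission speed, m/s (within `[5, 20]`).
#' @param alpha global coupling constant.
#' @param f frequency, Hz (non-negative; negative `f` gives the complex
#'   conjugate, used in symmetry checks).
#' @param mode degree normalization mode, see [degree_normalize()].
#' @return N x N complex matrix.
#' @export
complex_laplacian <- function(conn, v, alpha, f, mode = c("row", "symmetric")) {
  mode <- match.arg(mode)
  if (v < 5 || v > 20) stop("transmission speed v = ", v, " outside [5, 20] m/s")
  cn <- degree_normalize(conn$weights, mode)
  w <- 2 * pi * f
  cw <- cn * exp(complex(real = 0, imaginary = -w) *
                   conn$distances / (1000 * v))
  L <- diag(conn$n) - alpha * cw
  if (any(!is.finite(Re(L)) | !is.finite(Im(L))))
    stop("non-finite complex Laplacian")
  L
}

#' Eigen-decomposition of a complex Laplacian
#'
#' Eigenvalues are sorted by ascending magnitude (ties by ascending
#' phase) so that mode truncation deterministically keeps the smoothest
#' graph modes; eigenvector columns are unit-normalized and the mode
#' inverse is computed once and cached on the object.
#'
#' @param L complex square matrix.
#' @param f frequency (Hz) recorded for provenance.
#' @return an object of class `eigensystem` with fields `frequency`,
#'   `eigenvalues`, `modes`, `modes_inverse`.
#' @export
eigensystem <- function(L, f = NA_real_) {
  if (any(!is.finite(Re(L)) | !is.finite(Im(L)))) stop("non-finite matrix")
  es <- eigen(L, symmetric = FALSE)
  ord <- order(Mod(es$values), Arg(es$values))
  lam <- es$values[ord]
  U <- es$vectors[, ord, drop = FALSE]
  U <- sweep(U, 2, sqrt(colSums(Mod(U)^2)), "/")
  sv <- svd(U, nu = 0, nv = 0)$d
  if (min(sv) <= 0 || max(sv) / min(sv) > 1e12)
    stop("numerically singular mode matrix (condition number > 1e12)")
  structure(list(frequency = f, eigenvalues = lam, modes = U,
                 modes_inverse = solve(U)),
            class = "eigensystem")
}
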