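# Empirical-side spectral features: Welch-style amplitude spectra in dB,
# the intrinsic timescale from the region-averaged autocorrelation, and
# aperiodic + periodic spectral parameterization with the two-peak rule.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Segment-averaged amplitude spectrum of one signal: Hann-windowed 50%
# overlapping segments, mean |FFT| across segments.
welch_amplitude <- function(x, fs, seg_sec = 2, overlap = 0.5) {
  nseg <- min(length(x), round(seg_sec * fs))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- hann_window(nseg)
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(fft(seg))[seq_along(acc)]
  }
  list(freq = (seq_along(acc) - 1) * fs / nseg, amp = acc / length(starts))
}

#' Regional dB power spectra from time series
#'
#' Welch-style segment-averaged amplitude spectra (2 s Hann segments,
#' 50% overlap), linearly interpolated onto the requested grid and
#' converted to dB as `20 log10` of the amplitude.
#'
#' @param timeseries regions x samples matrix.
#' @param fs sampling rate, Hz.
#' @param grid output frequency grid, Hz (default [default_freqs()]);
#'   must lie below `fs/2`.
#' @param subject_id recorded on the result.
#' @return a [regional_psd()].
#' @export
compute_psd_db <- function(timeseries, fs, grid = default_freqs(),
                           subject_id = NA_character_) {
  timeseries <- as.matrix(timeseries)
  if (any(is.na(timeseries))) stop("NaN samples in time series")
  if (fs <= 2 * max(grid)) stop("sampling rate too low for requested grid")
  if (ncol(timeseries) < fs) stop("need at least 1 s of data")
  out <- matrix(NA_real_, nrow(timeseries), length(grid))
  for (r in seq_len(nrow(timeseries))) {
    w <- welch_amplitude(timeseries[r, ], fs)
    out[r, ] <- approx(w$freq, w$amp, xout = grid)$y
  }
  rownames(out) <- rownames(timeseries)
  regional_psd(grid, 20 * log10(out), subject_id = subject_id)
}

# FFT-based band-pass filter (brick wall): zero all bins outside `band`.
fft_bandpass <- function(x, fs, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided bin frequencies
  X <- fft(x)
  X[f < band[1] | f > band[2]] <- 0i
  Re(fft(X, inverse = TRUE)) / n
}

#' Intrinsic timescale from the region-averaged autocorrelation
#'
#' Band-pass filters every regional signal, computes each region's
#' normalized autocorrelation function, averages the ACFs across regions
#' (mean-ACF-first), and returns the lag at which the mean ACF first
#' crosses `exp(-1)`, linearly interpolated between the bracketing lags.
#'
#' @param timeseries regions x samples matrix.
#' @param fs sampling rate, Hz.
#' @param band band-pass interval, Hz; `NULL` for no filtering.
#' @param max_lag_s lag window searched for the crossing, s.
#' @return an object of class `timescale_result` with `tau_acf` (ms) and
#'   the mean `acf` curve (with `lags_s` attribute).
#' @export
acf_timescale <- function(timeseries, fs, band = c(1, 35), max_lag_s = 1) {
  timeseries <- as.matrix(timeseries)
  if (ncol(timeseries) < 10 * fs) stop("need at least 10 s of data")
  if (!is.null(band) && (band[1] <= 0 || band[2] >= fs / 2))
    stop("band must lie within (0, fs/2)")
  lag_max <- round(max_lag_s * fs)
  acc <- numeric(lag_max + 1)
  for (r in seq_len(nrow(timeseries))) {
    x <- timeseries[r, ]
    if (!is.null(band)) x <- fft_bandpass(x, fs, band)
    a <- acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    acc <- acc + a
  }
  macf <- acc / nrow(timeseries)
  thr <- exp(-1)
  below <- which(macf < thr)
  if (!length(below))
    stop("mean ACF never drops below exp(-1) within the lag window")
  k <- below[1]  # first lag index (1-based; lag k-1) under threshold
  l1 <- k - 2; l2 <- k - 1  # bracketing lags in samples
  frac <- (macf[k - 1] - thr) / (macf[k - 1] - macf[k])
  tau_s <- (l1 + frac) / fs
  structure(list(tau_acf = 1000 * tau_s,
                 acf = structure(macf, lags_s = (0:lag_max) / fs)),
            class = "timescale_result")
}

#' @export
print.timescale_result <- function(x, ...) {
  cat(sprintf("intrinsic timescale: %.1f ms\n", x$tau_acf))
  invisible(x)
}

gauss_curve <- function(f, amp, cf, sd) amp * exp(-(f - cf)^2 / (2 * sd^2))

sum_gaussians <- function(f, peaks) {
  y <- numeric(length(f))
  if (nrow(peaks)) for (i in seq_len(nrow(peaks)))
    y <- y + gauss_curve(f, peaks$amp[i], peaks$cf[i], peaks$sd[i])
  y
}

# offset - exponent * log10(f), fitted by OLS then refit on the points
# hugging the aperiodic floor (lower half of residuals) to resist peaks.
fit_aperiodic <- function(logf, y) {
  for (pass in 1:3) {
    fit <- lm(y ~ logf)
    if (pass < 3) {
      r <- residuals(fit)
      keep <- r <= quantile(r, 0.5)
      logf <- logf[keep]; y <- y[keep]
    }
  }
  c(offset = unname(coef(fit)[1]), exponent = -unname(coef(fit)[2]))
}

#' Aperiodic + periodic parameterization of a power spectrum
#'
#' Decomposes a single-region dB spectrum into an aperiodic component
#' `offset - exponent * log10(f)` (fitted in log10-power space, i.e. on
#' `dB/10`, so the exponent matches the usual power-law convention:
#' a `1/f^2` spectrum has exponent 2) and up to `max_peaks` Gaussian
#' peaks fitted iteratively on the flattened spectrum, then refit
#' jointly. Peaks are kept when their amplitude exceeds
#' `peak_threshold` standard deviations of the flattened spectrum and
#' their bandwidth (2 Gaussian SDs) is at least `min_bandwidth`.
#' `first_cf`/`second_cf` are the two lowest center frequencies; with a
#' single peak the second is assigned the value of the first.
#'
#' @param psd_db single-region dB spectrum (vector).
#' @param freqs frequency grid, Hz (>= 10 points).
#' @param max_peaks maximum number of peaks (default 6).
#' @param min_bandwidth lower bandwidth limit, Hz (default 2).
#' @param peak_threshold relative detection threshold in SD units.
#' @return an object of class `peak_set` with `aperiodic_offset`
#'   (log10-power units), `aperiodic_exponent`, `peaks` (data.frame
#'   `cf`, `power`, `bandwidth` sorted by ascending `cf`), `first_cf`,
#'   `second_cf`, `n_peaks`, `rmse_db`, and a `flag` set to
#'   `"no_peaks"` when nothing was found.
#' @export
parameterize_spectrum <- function(psd_db, freqs, max_peaks = 6,
                                  min_bandwidth = 2, peak_threshold = 2) {
  stopifnot(length(psd_db) == length(freqs))
  if (length(freqs) < 10) stop("need at least 10 grid points")
  y <- psd_db / 10  # log10 power
  logf <- log10(freqs)
  sd_lo <- min_bandwidth / 2
  sd_hi <- (max(freqs) - min(freqs)) / 2

  ap <- fit_aperiodic(logf, y)
  flat <- y - (ap["offset"] - ap["exponent"] * logf)
  # detection threshold fixed from the initial flattened spectrum (with
  # a 0.1 dB absolute floor), so residual wiggles left by subtracted
  # peaks cannot register as further peaks
  thr <- max(peak_threshold * sd(flat), 0.01)

  # guess-and-subtract (no per-peak optimization: a lone Gaussian fitted
  # against the whole spectrum would happily bridge two overlapping
  # peaks; all refinement is deferred to the joint fit)
  guess_one <- function(flat) {
    i <- which.max(flat)
    amp0 <- flat[i]
    if (amp0 < thr) return(NULL)
    # bandwidth guess from twice the nearer half-height side, so a
    # neighboring overlapping peak cannot inflate the width estimate
    half <- amp0 / 2
    lo <- i; while (lo > 1 && flat[lo - 1] > half) lo <- lo - 1
    hi <- i; while (hi < length(flat) && flat[hi + 1] > half) hi <- hi + 1
    sides <- c(freqs[i] - freqs[lo], freqs[hi] - freqs[i])
    sides <- sides[sides > 0]
    fwhm <- if (length(sides)) 2 * min(sides) else min_bandwidth
    list(amp = amp0, cf = freqs[i],
         sd = min(max(fwhm / 2.355, sd_lo), sd_hi))
  }

  peaks <- data.frame(amp = numeric(0), cf = numeric(0), sd = numeric(0))
  work <- flat
  for (k in seq_len(max_peaks)) {
    g <- guess_one(work)
    if (is.null(g)) break
    peaks <- rbind(peaks, as.data.frame(g))
    work <- work - gauss_curve(freqs, g$amp, g$cf, g$sd)
  }

  if (nrow(peaks)) {
    # joint refit of all Gaussians on the flattened spectrum
    p0 <- as.numeric(t(as.matrix(peaks)))
    nk <- nrow(peaks)
    jf <- optim(p0, function(p) {
      pk <- matrix(p, ncol = 3, byrow = TRUE)
      sum((flat - sum_gaussians(freqs, data.frame(amp = pk[, 1],
                                                  cf = pk[, 2],
                                                  sd = pk[, 3])))^2)
    }, method = "L-BFGS-B",
    lower = rep(c(0, min(freqs), sd_lo), nk),
    upper = rep(c(max(flat) * 2 + 1, max(freqs), sd_hi), nk))
    pk <- matrix(jf$par, ncol = 3, byrow = TRUE)
    peaks <- data.frame(amp = pk[, 1], cf = pk[, 2], sd = pk[, 3])
    # refit aperiodic on the peak-removed spectrum; drop any peak the
    # joint refit left below the detection threshold
    ap <- fit_aperiodic(logf, y - sum_gaussians(freqs, peaks))
    peaks <- peaks[peaks$amp >= thr, , drop = FALSE]
  }
  model <- ap["offset"] - ap["exponent"] * logf + sum_gaussians(freqs, peaks)
  rmse_db <- sqrt(mean((10 * (y - model))^2))

  peaks <- peaks[order(peaks$cf), , drop = FALSE]
  out <- data.frame(cf = peaks$cf, power = peaks$amp,
                    bandwidth = 2 * peaks$sd)
  flag <- if (nrow(out) == 0) "no_peaks" else NA_character_
  structure(list(aperiodic_offset = unname(ap["offset"]),
                 aperiodic_exponent = unname(ap["exponent"]),
                 peaks = out,
                 first_cf = if (nrow(out)) out$cf[1] else NA_real_,
                 second_cf = if (nrow(out) >= 2) out$cf[2]
                             else if (nrow(out) == 1) out$cf[1]
                             else NA_real_,
                 n_peaks = nrow(out), rmse_db = rmse_db, flag = flag),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("aperiodic: offset %.2f, exponent %.2f; %d peak(s)\n",
              x$aperiodic_offset, x$aperiodic_exponent, x$n_peaks))
  if (x$n_peaks) print(x$peaks)
  invisible(x)
}
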