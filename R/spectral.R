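#' BOLD time-series grid
#'
#' Container for a set of voxel time series sampled at a fixed repetition
#' time (TR). Rows are voxels, columns are timepoints. This is the flat
#' (voxels x time) view of a 4D resting-state acquisition; use
#' [read_bold_nifti()] to build one from a NIfTI-1 file.
#'
#' @param values Numeric matrix, voxels x timepoints. All entries finite.
#' @param tr Repetition time in seconds (sampling interval), `> 0`.
#' @return An object of class `bold_ts`: a list with elements `values`,
#'   `tr` and `n_timepoints`.
#' @examples
#' ts <- bold_ts(matrix(rnorm(10 * 490), nrow = 10), tr = 0.735)
#' nyquist(ts$tr)
#' @export
bold_ts <- function(values, tr) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (voxels x timepoints)")
  }
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("'tr' must be a single positive number (seconds)")
  }
  if (ncol(values) < 4L) {
    stop("time series must have at least 4 timepoints, got ", ncol(values))
  }
  if (!all(is.finite(values))) {
    stop("non-finite values in BOLD time series")
  }
  structure(
    list(values = values, tr = tr, n_timepoints = ncol(values)),
    class = "bold_ts"
  )
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf(
    "BOLD time-series grid: %d voxels x %d timepoints, TR = %g s (Nyquist %.3f Hz)\n",
    nrow(x$values), x$n_timepoints, x$tr, nyquist(x$tr)
  ))
  invisible(x)
}

#' Nyquist frequency of a sampled time series
#'
#' The highest frequency resolvable at sampling interval `tr` is
#' `1 / (2 * tr)`. At the TR of 0.735 s used by the UK Biobank resting-state
#' protocol this is 0.680 Hz, which bounds the full fALFF denominator band.
#'
#' @param tr Repetition time (sampling interval) in seconds, `> 0`.
#' @return Nyquist frequency in Hz.
#' @examples
#' nyquist(0.735) # 0.680 Hz
#' @export
nyquist <- function(tr) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("'tr' must be a single positive number (seconds)")
  }
  1 / (2 * tr)
}

#' Number of timepoints for an acquisition duration
#'
#' @param duration_s Acquisition duration in seconds.
#' @param tr Repetition time in seconds.
#' @return Integer count of volumes, `round(duration_s / tr)`.
#' @examples
#' n_timepoints_for_duration(6 * 60, 0.735) # 490
#' @export
n_timepoints_for_duration <- function(duration_s, tr) {
  if (duration_s <= 0) stop("'duration_s' must be positive")
  if (tr <= 0) stop("'tr' must be positive")
  as.integer(round(duration_s / tr))
}

#' Frequency band specification
#'
#' A band is the half-open interval `(f_low, f_high]` on the discrete
#' Fourier bin grid; the DC bin never belongs to any band. The half-open
#' convention makes disjoint bands that tile `(0, nyquist]` partition the
#' spectrum exactly, so fALFF values over such a tiling sum to 1.
#'
#' Presets: [band_broad()] is 0--0.1164 Hz (the broad low-pass analysis
#' band), [band_narrow()] is 0.01--0.08 Hz (the classical fALFF band), and
#' [band_full()] is the whole detectable range `(0, 1/(2 tr)]`.
#'
#' @param f_low Lower edge in Hz (exclusive), `>= 0`.
#' @param f_high Upper edge in Hz (inclusive), `> f_low`.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec(0.01, 0.08)
#' band_full(0.735)
#' @export
band_spec <- function(f_low, f_high) {
  if (!is.numeric(f_low) || !is.numeric(f_high) ||
      length(f_low) != 1L || length(f_high) != 1L) {
    stop("band edges must be single numbers (Hz)")
  }
  if (!is.finite(f_low) || !is.finite(f_high) || f_low < 0 || f_high <= f_low) {
    stop("invalid band: need 0 <= f_low < f_high, got (", f_low, ", ", f_high, "]")
  }
  structure(list(f_low = f_low, f_high = f_high), class = "band_spec")
}

#' @rdname band_spec
#' @export
band_broad <- function() band_spec(0, 0.1164)

#' @rdname band_spec
#' @param tr Repetition time in seconds, used to place the Nyquist limit.
#' @rdname band_spec
#' @export
band_narrow <- function() band_spec(0.01, 0.08)

#' @rdname band_spec
#' @export
band_full <- function(tr) band_spec(0, nyquist(tr))

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("frequency band (%g, %g] Hz\n", x$f_low, x$f_high))
  invisible(x)
}

# Validate a band against a sampling rate; errors if it exceeds Nyquist.
check_band <- function(band, tr) {
  stopifnot(inherits(band, "band_spec"))
  ny <- nyquist(tr)
  if (band$f_high > ny * (1 + 1e-9)) {
    stop(sprintf(
      "band upper edge %g Hz exceeds the Nyquist limit %.4f Hz at TR %g s",
      band$f_high, ny, tr
    ))
  }
  invisible(band)
}

# Positive DFT bin frequencies for n timepoints at sampling interval tr:
# k / (n * tr) for k = 1 .. floor(n/2). Spacing 1/(n*tr); DC excluded.
dft_frequencies <- function(n, tr) {
  seq_len(n %/% 2L) / (n * tr)
}

# Indices of bins inside the half-open band (f_low, f_high]. A relative
# tolerance absorbs floating-point representation of edges that coincide
# with bin centers.
band_bin_index <- function(frequencies, band) {
  tol <- 1e-9
  which(frequencies > band$f_low * (1 + tol) + tol * 1e-3 &
        frequencies <= band$f_high * (1 + tol) + tol * 1e-3)
}

#' Remove the per-voxel linear trend
#'
#' Subtracts the least-squares line (intercept + slope over scan time) from
#' every voxel time series. Scanner drift concentrates at very low
#' frequencies and would otherwise bleed into the DC and first bins of the
#' power spectrum. Residuals are orthogonal to both the constant and the
#' linear regressor, and the operation is idempotent.
#'
#' @param ts A [bold_ts()].
#' @return A `bold_ts` of detrended series (same dimensions and TR).
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "bold_ts"))
  n <- ts$n_timepoints
  X <- cbind(1, seq_len(n) - (n + 1) / 2)
  Q <- qr.Q(qr(X))
  # residual of each row after projection onto span{1, t}
  fitted <- (ts$values %*% Q) %*% t(Q)
  bold_ts(ts$values - fitted, ts$tr)
}

#' Ideal frequency-domain bandpass filter
#'
#' Applies a boxcar mask in the discrete Fourier domain: coefficients at
#' positive bin frequencies `f` with `f_low < f <= f_high` (and their
#' conjugate bins) are retained, everything else -- including the DC
#' component -- is zeroed, and the inverse transform is returned. With this
#' ideal mask, filtering then computing the periodogram is identical to
#' masking the periodogram, which keeps ALFF numerators and fALFF
#' denominators mutually consistent.
#'
#' @param ts A [bold_ts()].
#' @param band A [band_spec()]; must lie within the Nyquist limit for
#'   `ts$tr`.
#' @return A `bold_ts` holding the filtered (real) series.
#' @export
bandpass <- function(ts, band) {
  stopifnot(inherits(ts, "bold_ts"))
  check_band(band, ts$tr)
  n <- ts$n_timepoints
  freqs <- dft_frequencies(n, ts$tr)
  keep_pos <- band_bin_index(freqs, band)
  keep <- rep(FALSE, n)
  keep[keep_pos + 1L] <- TRUE          # positive-frequency bins (1-based; bin k at index k+1)
  conj_idx <- n - keep_pos + 1L        # conjugate bins; Nyquist (even n) maps to itself
  keep[conj_idx[conj_idx <= n]] <- TRUE
  X <- stats::mvfft(t(ts$values))
  X[!keep, ] <- 0
  out <- Re(stats::mvfft(X, inverse = TRUE)) / n
  bold_ts(t(out), ts$tr)
}

#' One-sided voxelwise periodogram
#'
#' Squared-magnitude discrete Fourier spectrum of each voxel on the
#' `floor(n/2)` positive-frequency bins `k / (n * tr)`, `k = 1, ...,
#' floor(n/2)`; the DC bin is excluded (detrending drives it to zero).
#' Power is scaled as `|X_k|^2 / n` so that Parseval's identity holds in
#' time-domain units: counting interior bins twice (they have a conjugate
#' partner) and the Nyquist bin once when `n` is even, the total equals the
#' sum of squares of the mean-removed series.
#'
#' @param ts A [bold_ts()].
#' @return An object of class `power_spectrum`: list with `frequencies`
#'   (Hz, strictly increasing), `power` (voxels x bins, nonnegative),
#'   `tr`, `n_timepoints`.
#' @export
periodogram <- function(ts) {
  stopifnot(inherits(ts, "bold_ts"))
  n <- ts$n_timepoints
  if (n < 4L) stop("need at least 4 timepoints for a spectrum")
  h <- n %/% 2L
  X <- stats::mvfft(t(ts$values))
  power <- t(Mod(X[2:(h + 1L), , drop = FALSE])^2 / n)
  structure(
    list(
      frequencies = dft_frequencies(n, ts$tr),
      power = power,
      tr = ts$tr,
      n_timepoints = n
    ),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "one-sided power spectrum: %d voxels x %d bins, df = %.5f Hz, max %.4f Hz\n",
    nrow(x$power), length(x$frequencies),
    x$frequencies[1], max(x$frequencies)
  ))
  invisible(x)
}

new_amplitude_map <- function(values, band, kind) {
  structure(list(values = values, band = band, kind = kind),
            class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  cat(sprintf(
    "%s map: %d voxels, band (%g, %g] Hz, median %.4g (%d undefined)\n",
    x$kind, length(x$values), x$band$f_low, x$band$f_high,
    stats::median(x$values, na.rm = TRUE), sum(is.na(x$values))
  ))
  invisible(x)
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel, the mean of the square root of the periodogram over the bins
#' inside `band`. The square root converts power back to amplitude units.
#' By default the mean runs over the in-band bins only; `bins = "all"`
#' divides the in-band amplitude sum by the total bin count instead (the
#' post-filter spectrum is zero outside the band, so the two differ only by
#' the constant factor `n_band / n_total`, which cancels in fALFF).
#'
#' @param ps A [periodogram()] result.
#' @param band A [band_spec()]; must contain at least one bin.
#' @param bins `"band"` (default) to average over in-band bins, `"all"` to
#'   average the in-band amplitude over every bin.
#' @return An `amplitude_map` with `kind = "ALFF"`.
#' @export
alff <- function(ps, band, bins = c("band", "all")) {
  stopifnot(inherits(ps, "power_spectrum"))
  check_band(band, ps$tr)
  bins <- match.arg(bins)
  idx <- band_bin_index(ps$frequencies, band)
  if (length(idx) == 0L) {
    stop(sprintf("band (%g, %g] Hz contains no frequency bins",
                 band$f_low, band$f_high))
  }
  amp <- sqrt(ps$power[, idx, drop = FALSE])
  denom <- if (bins == "band") length(idx) else length(ps$frequencies)
  new_amplitude_map(rowSums(amp) / denom, band, "ALFF")
}

#' Fractional ALFF (fALFF)
#'
#' Per voxel, the sum of square-root power over the in-band bins divided by
#' the sum over all bins in `(0, nyquist]`. Because numerator and
#' denominator run over bin sums, this equals the ratio of bin-count-
#' weighted mean amplitudes (ALFF computed with `bins = "all"` over the
#' band, divided by ALFF of the full band): the "mean amplitude" phrasing
#' and the sum formulation are the same statistic. Values lie in `[0, 1]`
#' and are invariant to positive rescaling of the time series. A voxel with
#' an all-zero spectrum has no defined fraction and is returned as `NA`.
#'
#' @inheritParams alff
#' @return An `amplitude_map` with `kind = "fALFF"`; undefined voxels `NA`.
#' @export
falff <- function(ps, band) {
  stopifnot(inherits(ps, "power_spectrum"))
  check_band(band, ps$tr)
  idx <- band_bin_index(ps$frequencies, band)
  if (length(idx) == 0L) {
    stop(sprintf("band (%g, %g] Hz contains no frequency bins",
                 band$f_low, band$f_high))
  }
  amp <- sqrt(ps$power)
  num <- rowSums(amp[, idx, drop = FALSE])
  den <- rowSums(amp)
  vals <- ifelse(den > 0, num / den, NA_real_)
  new_amplitude_map(vals, band, "fALFF")
}

#' Detrend, transform and compute fALFF in one call
#'
#' Convenience wrapper for the standard chain: linear detrend, one-sided
#' periodogram, fractional ALFF over `band`. Because the bandpass filter is
#' an ideal spectral mask, explicit filtering before the periodogram is
#' redundant -- masking the spectrum is identical -- so this wrapper runs a
#' single transform and masks.
#'
#' @param ts A [bold_ts()].
#' @param band A [band_spec()].
#' @return An `amplitude_map` with `kind = "fALFF"`.
#' @export
compute_falff <- function(ts, band) {
  falff(periodogram(detrend_linear(ts)), band)
}
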