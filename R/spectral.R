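#' Welch power spectral density of epochs or a continuous segment
#'
#' Averaged-periodogram (Welch) estimate with Hann-tapered windows whose
#' length matches the analysis epoch (1 s by default, giving 1 Hz native
#' resolution). For an [eeg_epochs()] input the retained epochs are the
#' windows; for a continuous matrix or [eeg_recording()] input, windows
#' overlap by 50%. Density scaling is one-sided (microvolt^2/Hz): the PSD
#' integrated over frequency recovers the signal's mean power (Parseval).
#'
#' @param x an [eeg_epochs()] object, an [eeg_recording()], or a
#'   `channels x samples` matrix.
#' @param srate sampling rate, Hz (ignored when `x` carries one).
#' @param window_sec window length in seconds.
#' @return An object of class `spectral_frame`: list with `psd`
#'   (`channels x frequencies` matrix), `frequencies` (Hz), `resolution`
#'   (Hz) and `channels`.
#' @export
compute_psd <- function(x, srate = NULL, window_sec = 1) {
  if (inherits(x, "eeg_epochs")) {
    keep <- which(x$retained)
    if (!length(keep)) stop_pbci("no retained epochs")
    segs <- lapply(keep, function(e) t(x$epochs[e, , , drop = TRUE]))
    if (length(x$channels) == 1) segs <- lapply(keep, function(e)
      matrix(x$epochs[e, , ], ncol = 1))
    return(welch_psd(segs, x$srate, x$channels))
  }
  if (inherits(x, "eeg_recording")) {
    srate <- x$srate
    channels <- x$channels
    x <- x$data
  } else {
    x <- as.matrix(x)
    channels <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
    if (is.null(srate)) stop_pbci("srate is required for matrix input")
  }
  nwin <- floor(srate * window_sec)
  if (ncol(x) < nwin) stop_pbci("need at least one full window of data")
  starts <- seq(1, ncol(x) - nwin + 1, by = max(1, floor(nwin / 2)))
  segs <- lapply(starts, function(s) t(x[, s:(s + nwin - 1), drop = FALSE]))
  welch_psd(segs, srate, channels)
}

# segs: list of [nwin x channels] matrices
welch_psd <- function(segs, srate, channels) {
  nwin <- nrow(segs[[1]])
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / nwin) # periodic Hann
  scale <- 1 / (srate * sum(w^2))
  nfreq <- floor(nwin / 2) + 1
  acc <- matrix(0, nrow = length(channels), ncol = nfreq)
  for (seg in segs) {
    X <- stats::mvfft(seg * w)
    P <- (Mod(X[seq_len(nfreq), , drop = FALSE])^2) * scale
    # one-sided: double everything except DC (and Nyquist when nwin even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nwin %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + t(P * dbl)
  }
  psd <- acc / length(segs)
  rownames(psd) <- channels
  freqs <- (seq_len(nfreq) - 1) * srate / nwin
  structure(list(psd = psd, frequencies = freqs,
                 resolution = srate / nwin, channels = channels),
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf("<spectral_frame> %d channels x %d bins, %.3g Hz resolution (%.3g-%.3g Hz)\n",
              nrow(x$psd), length(x$frequencies), x$resolution,
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Estimate the individual alpha frequency from a resting spectrum
#'
#' Finds the peak of the channel-averaged PSD within the 7-13 Hz search
#' window and refines its position by parabolic interpolation over the
#' neighbouring bins. The estimate is flagged low-confidence — and the
#' conventional 10 Hz fallback returned — when the window contains no
#' interior local maximum (e.g. a monotone 1/f spectrum) or the maximum
#' sits on the search boundary. When two bins tie for the maximum, the
#' lower frequency is returned with a low-confidence flag.
#'
#' @param frame a `spectral_frame` from [compute_psd()] of a closed-eyes
#'   rest segment; must cover 7-13 Hz.
#' @param window search window, Hz.
#' @return List with `iaf` (Hz) and `confident` (logical).
#' @export
estimate_iaf <- function(frame, window = c(7, 13)) {
  stopifnot(inherits(frame, "spectral_frame"))
  f <- frame$frequencies
  if (min(f) > window[1] || max(f) < window[2]) {
    stop_pbci("spectrum does not cover the alpha search window")
  }
  avg <- colMeans(frame$psd)
  inw <- which(f >= window[1] & f <= window[2])
  pw <- avg[inw]
  imax <- which.max(pw) # first index on exact ties -> lower frequency
  tied <- sum(abs(pw - pw[imax]) <= 1e-12 * max(pw)) > 1
  gi <- inw[imax] # index into the full grid
  boundary <- gi <= min(inw) || gi >= max(inw)
  # interior local maximum w.r.t. the full-grid neighbours
  local_max <- gi > 1 && gi < length(f) &&
    avg[gi] >= avg[gi - 1] && avg[gi] >= avg[gi + 1] &&
    (avg[gi] > avg[gi - 1] || avg[gi] > avg[gi + 1])
  if (boundary || !local_max) {
    return(list(iaf = 10, confident = FALSE))
  }
  # parabolic refinement over the three bins around the peak
  y1 <- avg[gi - 1]; y2 <- avg[gi]; y3 <- avg[gi + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) < 1e-15) 0 else 0.5 * (y1 - y3) / denom
  delta <- max(-0.5, min(0.5, delta))
  list(iaf = f[gi] + delta * frame$resolution, confident = !tied)
}

#' Frequency band schemes
#'
#' `band_scheme_from_iaf()` anchors the four analysis bands on the
#' individual alpha frequency: theta `[IAF-6, IAF-2)`, alpha
#' `[IAF-2, IAF+2)`, beta `[IAF+2, IAF+16)` and high beta
#' `[IAF+11, IAF+16)` Hz (high beta is a sub-band of beta — the only
#' permitted overlap). `fixed_band_scheme()` returns the fixed comparison
#' bands used for the two-system spectral agreement analysis: theta 3-7,
#' alpha 7-13, beta 13-26 and high beta 21-26 Hz. The two schemes differ
#' by design (at IAF = 10 the anchored theta is 4-8 Hz while the fixed
#' theta is 3-7 Hz); callers choose which applies.
#'
#' @param iaf individual alpha frequency, Hz; must lie in [7, 13].
#' @return A `band_scheme`: list with `bands` (named list of `c(low, high)`
#'   in Hz), `origin` (`"iaf"` or `"fixed"`) and `iaf` (Hz or `NA`).
#' @export
band_scheme_from_iaf <- function(iaf) {
  if (!is.numeric(iaf) || length(iaf) != 1 || iaf < 7 || iaf > 13) {
    stop_pbci("iaf must be a single value in [7, 13] Hz")
  }
  structure(list(
    bands = list(theta = c(iaf - 6, iaf - 2),
                 alpha = c(iaf - 2, iaf + 2),
                 beta = c(iaf + 2, iaf + 16),
                 beta_high = c(iaf + 11, iaf + 16)),
    origin = "iaf", iaf = iaf), class = "band_scheme")
}

#' @rdname band_scheme_from_iaf
#' @export
fixed_band_scheme <- function() {
  structure(list(
    bands = list(theta = c(3, 7), alpha = c(7, 13),
                 beta = c(13, 26), beta_high = c(21, 26)),
    origin = "fixed", iaf = NA_real_), class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> origin=%s%s\n", x$origin,
              if (!is.na(x$iaf)) sprintf(" (IAF=%.2f Hz)", x$iaf) else ""))
  for (b in names(x$bands)) {
    cat(sprintf("  %-9s [%g, %g) Hz\n", b, x$bands[[b]][1], x$bands[[b]][2]))
  }
  invisible(x)
}

#' Band-integrated power per channel (global field power)
#'
#' Integrates the PSD over a frequency band by the trapezoid rule, per
#' channel, and averages over the requested channel set. Band edges that
#' fall between grid points are handled by linear interpolation of the
#' PSD at the edge, so a flat density `c` over a band of width `w`
#' integrates to exactly `c * w`. An edge shared by two adjacent bands
#' contributes half its weight to each, so disjoint bands never
#' double-count power.
#'
#' @param frame a `spectral_frame`.
#' @param scheme a `band_scheme`.
#' @param band band name (`"theta"`, `"alpha"`, `"beta"`, `"beta_high"`).
#' @param channels channel set to aggregate over; default all channels.
#' @return List with `per_channel` (named numeric, microvolt^2) and `gfp`
#'   (arithmetic mean over the channel set).
#' @export
band_power <- function(frame, scheme, band, channels = frame$channels) {
  stopifnot(inherits(frame, "spectral_frame"), inherits(scheme, "band_scheme"))
  if (!band %in% names(scheme$bands)) stop_pbci("unknown band '", band, "'")
  if (!length(channels)) stop_pbci("empty channel set")
  missing_ch <- setdiff(channels, frame$channels)
  if (length(missing_ch)) {
    stop_pbci("channel(s) not in frame: ", paste(missing_ch, collapse = ", "))
  }
  edges <- scheme$bands[[band]]
  f <- frame$frequencies
  if (edges[1] < min(f) - 1e-9 || edges[2] > max(f) + 1e-9) {
    stop_pbci("band [", edges[1], ", ", edges[2],
              ") outside the frame's frequency span")
  }
  per <- vapply(channels, function(ch) {
    integrate_band(f, frame$psd[ch, ], edges[1], edges[2])
  }, numeric(1))
  list(per_channel = per, gfp = mean(per))
}

# trapezoid integral of (f, p) over [low, high], interpolating the edges
integrate_band <- function(f, p, low, high) {
  inner <- f[f > low & f < high]
  grid <- c(low, inner, high)
  vals <- stats::approx(f, p, xout = grid, rule = 2)$y
  pracma::trapz(grid, vals)
}

# per-epoch, per-channel band powers via single-epoch Hann periodograms,
# batched through one FFT; returns array [epochs x channels x bands].
# Band integration is linear in the PSD, so each band reduces to a fixed
# weight vector over the frequency bins (trapezoid with interpolated
# edges, identical to band_power()).
epoch_band_powers <- function(epochs, scheme,
                              bands = names(scheme$bands),
                              channels = epochs$channels) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  nep <- n_epochs(epochs)
  sel <- match(channels, epochs$channels)
  spe <- dim(epochs$epochs)[3]
  srate <- epochs$srate
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, spe - 1) / spe)
  scale <- 1 / (srate * sum(w^2))
  nfreq <- floor(spe / 2) + 1
  freqs <- (seq_len(nfreq) - 1) * srate / spe
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (spe %% 2 == 0) dbl[nfreq] <- 1

  # [spe x (nep * nch)] matrix: one column per epoch-channel pair
  m <- matrix(aperm(epochs$epochs[, sel, , drop = FALSE], c(3, 1, 2)),
              nrow = spe)
  X <- stats::mvfft(m * w)
  P <- Mod(X[seq_len(nfreq), , drop = FALSE])^2 * (scale * dbl)

  out <- array(NA_real_, dim = c(nep, length(channels), length(bands)),
               dimnames = list(NULL, channels, bands))
  basis <- diag(nfreq)
  for (b in bands) {
    edges <- scheme$bands[[b]]
    if (edges[1] < min(freqs) - 1e-9 || edges[2] > max(freqs) + 1e-9) {
      stop_pbci("band [", edges[1], ", ", edges[2],
                ") outside the epochs' frequency span")
    }
    bw <- vapply(seq_len(nfreq), function(k) {
      integrate_band(freqs, basis[k, ], edges[1], edges[2])
    }, numeric(1))
    out[, , b] <- matrix(crossprod(P, bw), nrow = nep)
  }
  out
}
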