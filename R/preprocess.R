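#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fifth-order Butterworth band-pass (default 2-30 Hz)
#' forward and backward, so the net response is zero-phase with the
#' squared magnitude of the designed filter (effective order 10 in
#' magnitude). DC is removed by the high-pass edge.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges, Hz.
#' @param order filter order (of the underlying one-pass design).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low = 2, high = 30, order = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop_pbci("band edges must satisfy 0 < low < high < Nyquist (",
              nyq, " Hz)")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  sos <- as_biquads(bf$b, bf$a)
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x) sos_filtfilt(sos, x)))
  dimnames(out$data) <- dimnames(rec$data)
  out
}

# Factor a transfer function into second-order sections. Running the
# band-pass as cascaded biquads keeps the recursion well conditioned: the
# expanded order-2N polynomial has poles whose interactions amplify
# rounding error by orders of magnitude.
as_biquads <- function(b, a) {
  k <- b[1] / a[1]
  pair_up <- function(r) {
    sections <- list()
    while (length(r) > 1) {
      i <- which.max(Mod(r))
      mate <- which.min(Mod(r[-i] - Conj(r[i])))
      mate <- seq_along(r)[-i][mate]
      sections[[length(sections) + 1]] <- c(r[i], r[mate])
      r <- r[-c(i, mate)]
    }
    if (length(r) == 1) sections[[length(sections) + 1]] <- r
    sections
  }
  poles <- pair_up(polyroot(rev(a)))
  zeros <- pair_up(polyroot(rev(b)))
  n <- max(length(poles), length(zeros))
  lapply(seq_len(n), function(i) {
    coefs <- function(r) {
      if (is.null(r)) return(1)
      if (length(r) == 1) return(Re(c(1, -r)))
      Re(c(1, -(r[1] + r[2]), r[1] * r[2]))
    }
    list(b = coefs(if (i <= length(zeros)) zeros[[i]]) * if (i == 1) k else 1,
         a = coefs(if (i <= length(poles)) poles[[i]]))
  })
}

# Zero-phase cascade with odd-reflection padding: extending the signal by
# its mirrored continuation before filtering keeps start/end transients
# out of the data (plain zero padding leaves large boundary artifacts).
sos_filtfilt <- function(sos, x, pad = min(length(x) - 1L, 500L)) {
  n <- length(x)
  ext <- c(2 * x[1] - x[(pad + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - pad)])
  for (sec in sos) {
    ext <- signal::filtfilt(signal::Arma(b = sec$b, a = sec$a), ext)
  }
  ext[(pad + 1):(pad + n)]
}

#' Detect eye blinks on the frontal channels
#'
#' Template-matching blink detector: the mean frontal signal is
#' cross-correlated with a half-sine blink template (~300 ms) passed
#' through the standard 2-30 Hz band-pass (so the template matches the
#' blink waveform as it appears in preprocessed data), the correlation
#' trace is thresholded at 4 times its median absolute deviation,
#' candidate events must additionally be large-amplitude excursions of
#' the mean frontal channel (a robust-z gate: blinks are large by
#' definition, and an adaptive correlation threshold alone would fire on
#' blink-free records), and detections closer than 200 ms are merged.
#' Only frontal
#' channels are consulted; blink-like activity confined to parietal
#' channels is ignored by construction.
#'
#' @param rec an [eeg_recording()] containing at least one frontal channel.
#' @param template_dur template duration, seconds.
#' @param mad_mult detection threshold as a multiple of the MAD of the
#'   correlation trace.
#' @param amp_z minimum peak amplitude of the mean frontal signal within
#'   a candidate event, in robust standard deviations (scaled MAD) of
#'   that signal.
#' @param min_amplitude absolute lower bound on that peak, microvolt;
#'   blinks have a physical scale, so candidates smaller than this are
#'   never blinks no matter how quiet the background.
#' @param min_gap minimum separation between events, seconds.
#' @return Data frame of non-overlapping blink intervals (`start`, `end`, s).
#' @export
detect_blinks <- function(rec, template_dur = 0.3, mad_mult = 4,
                          amp_z = 5, min_amplitude = 15, min_gap = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"))
  front <- intersect(frontal_channels(), rec$channels)
  if (!length(front)) stop_pbci("blink detection needs a frontal channel")
  x <- colMeans(rec$data[front, , drop = FALSE])
  tpl <- blink_template(rec$srate, template_dur)
  if (rec$srate > 60) { # template as it appears after the standard band-pass
    bf <- signal::butter(5, c(2, 30) / (rec$srate / 2), type = "pass")
    pad <- rep(0, 2 * length(tpl))
    padded <- signal::filtfilt(bf, c(pad, tpl, pad))
    tpl <- padded[(length(pad) + 1):(length(pad) + length(tpl))]
  }
  tpl <- tpl - mean(tpl)
  # normalized cross-correlation via centred matched filter
  cc <- stats::filter(x, rev(tpl) / sqrt(sum(tpl^2)), sides = 2)
  cc[is.na(cc)] <- 0
  cc <- as.numeric(cc)
  thr <- stats::median(cc) + mad_mult * stats::mad(cc)
  above <- cc > thr
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  # local maxima of the trace above threshold, separated by >= min_gap
  idx <- which(above)
  peaks <- idx[c(TRUE, diff(idx) > 1)] # starts of runs
  runs <- split(idx, cumsum(c(TRUE, diff(idx) > 1)))
  peak_at <- vapply(runs, function(r) r[which.max(cc[r])], integer(1))
  # strongest-first non-maximum suppression: a blink's matched-filter
  # response has sidelobes within ~2 template lengths of its centre that
  # would otherwise register as separate events; the suppression radius
  # never drops below the minimum inter-event gap
  radius <- max(min_gap, 2 * template_dur) * rec$srate
  peak_at <- peak_at[order(cc[peak_at], decreasing = TRUE)]
  accepted <- integer(0)
  for (p in peak_at) {
    if (!length(accepted) || all(abs(accepted - p) >= radius)) {
      accepted <- c(accepted, p)
    }
  }
  peak_at <- sort(accepted)
  half_n <- floor(template_dur * rec$srate / 2)
  amp_floor <- max(amp_z * stats::mad(x), min_amplitude)
  big <- vapply(peak_at, function(p) {
    idx <- max(1, p - half_n):min(length(x), p + half_n)
    max(abs(x[idx])) >= amp_floor
  }, logical(1))
  peak_at <- peak_at[big]
  if (!length(peak_at)) return(data.frame(start = numeric(0), end = numeric(0)))
  half <- template_dur / 2
  start <- pmax(0, peak_at / rec$srate - half)
  end <- pmin(rec_duration(rec), peak_at / rec$srate + half)
  merge_intervals(data.frame(start = start, end = end))
}

merge_intervals <- function(iv, gap = 0) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$start), ]
  out <- iv[1, ]
  for (i in 2:nrow(iv)) {
    if (iv$start[i] <= out$end[nrow(out)] + gap) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], iv$end[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

interval_mask <- function(intervals, n, srate) {
  mask <- logical(n)
  if (is.null(intervals) || !nrow(intervals)) return(mask)
  for (i in seq_len(nrow(intervals))) {
    idx <- seq.int(max(1L, floor(intervals$start[i] * srate) + 1L),
                   min(n, ceiling(intervals$end[i] * srate)))
    mask[idx] <- TRUE
  }
  mask
}

#' Multi-channel Wiener-filter ocular correction
#'
#' Estimates the ocular component from the spatial covariance contrast
#' between blink segments and clean segments and subtracts it within the
#' blink intervals. With artifact-segment covariance `Ryy` and
#' clean-segment covariance `Rvv`, the artifact covariance
#' `Rdd = Ryy - Rvv` is clipped to positive semidefinite by zeroing
#' negative eigenvalues, and the spatial Wiener filter `W = Ryy^-1 Rdd`
#' yields the artifact estimate `W' y`, which is subtracted from the blink
#' samples. With no blink intervals the recording is returned untouched.
#'
#' @param rec an [eeg_recording()].
#' @param blink_intervals data frame (`start`, `end`, seconds) as returned
#'   by [detect_blinks()]; may have zero rows.
#' @return The corrected [eeg_recording()].
#' @export
mwf_correct <- function(rec, blink_intervals) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(blink_intervals) || nrow(blink_intervals) == 0) return(rec)
  n <- ncol(rec$data)
  mask <- interval_mask(blink_intervals, n, rec$srate)
  if (!any(mask)) return(rec)
  nch <- nrow(rec$data)
  if (sum(!mask) < 10 * nch) {
    stop_pbci("too few clean samples to estimate the clean covariance")
  }
  y_art <- rec$data[, mask, drop = FALSE]
  y_cln <- rec$data[, !mask, drop = FALSE]
  ryy <- tcrossprod(y_art) / ncol(y_art)
  rvv <- tcrossprod(y_cln) / ncol(y_cln)
  rdd <- ryy - rvv
  eg <- eigen(rdd, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rdd <- eg$vectors %*% (ev * t(eg$vectors))
  w <- solve(ryy, rdd) # spatial Wiener filter (lag 0)
  est <- t(w) %*% y_art
  out <- rec
  out$data[, mask] <- rec$data[, mask] - est
  out
}

#' Cut a recording into fixed-length epochs
#'
#' Segments the recording into consecutive non-overlapping epochs
#' (default 1 s, the unit of all downstream analysis); a trailing
#' remainder shorter than one epoch is dropped. Each epoch inherits the
#' condition label and run id of the annotation covering its midpoint;
#' epochs whose midpoint is not covered get label `""`.
#'
#' @param rec an [eeg_recording()].
#' @param length epoch length, seconds.
#' @return An [eeg_epochs()] object.
#' @export
epoch_recording <- function(rec, length = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- floor(rec$srate * length)
  nep <- floor(ncol(rec$data) / spe)
  if (nep < 1) stop_pbci("recording shorter than one epoch")
  arr <- array(0, dim = c(nep, nrow(rec$data), spe))
  for (e in seq_len(nep)) {
    arr[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe)]
  }
  t_start <- (seq_len(nep) - 1) * length
  mid <- t_start + length / 2
  lab <- rep("", nep)
  run <- rep(NA_integer_, nep)
  ann <- rec$annotations
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      hit <- mid >= ann$start[i] & mid < ann$end[i]
      lab[hit] <- ann$label[i]
      run[hit] <- ann$run[i]
    }
  }
  eeg_epochs(arr, rec$srate, rec$channels, lab, run, t_start)
}

#' Amplitude-threshold artifact rejection
#'
#' Marks as rejected every epoch whose absolute amplitude exceeds the
#' threshold (default +/-80 microvolt, strict inequality: an epoch peaking
#' exactly at the threshold is retained) on any channel. Per-channel
#' exceedance counts are attached for regional artifact statistics.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param threshold rejection threshold, microvolt.
#' @return The [eeg_epochs()] with its `retained` mask updated and a
#'   `channel_exceeded` logical matrix (`epochs x channels`) attached.
#' @export
reject_artifacts <- function(epochs, threshold = 80) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (n_epochs(epochs) == 0) stop_pbci("no epochs to screen")
  peaks <- apply(abs(epochs$epochs), c(1, 2), max)
  exceeded <- peaks > threshold
  colnames(exceeded) <- epochs$channels
  epochs$retained <- epochs$retained & !apply(exceeded, 1, any)
  epochs$channel_exceeded <- exceeded
  epochs
}

#' Run the full preprocessing chain on a recording
#'
#' Band-pass filter, blink detection, MWF ocular correction, 1-s epoching
#' and amplitude-threshold rejection, in the standard order.
#'
#' @param rec an [eeg_recording()].
#' @param low,high,order band-pass parameters (see [bandpass_filter()]).
#' @param threshold rejection threshold, microvolt.
#' @return List with `epochs` (screened [eeg_epochs()]), `recording` (the
#'   cleaned continuous recording) and `blink_intervals`.
#' @export
preprocess_recording <- function(rec, low = 2, high = 30, order = 5,
                                 threshold = 80) {
  filt <- bandpass_filter(rec, low, high, order)
  blinks <- detect_blinks(filt)
  clean <- mwf_correct(filt, blinks)
  ep <- reject_artifacts(epoch_recording(clean), threshold)
  list(epochs = ep, recording = clean, blink_intervals = blinks)
}
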