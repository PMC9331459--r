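#' Configuration for the synthetic EEG session generator
#'
#' Builds the parameter set for [simulate_session()]. The defaults describe
#' the reference session the package is validated on: an eight-channel
#' frontal/parietal montage sampled at 250 Hz, a 1-min closed-eyes and a
#' 1-min open-eyes rest, and two repetitions of paired low/high runs for
#' each monitored construct (workload, stress, vigilance), 60 s per run.
#'
#' Oscillatory activity is modelled as four amplitude-modulated narrowband
#' noise sources — frontal theta, parietal/occipital alpha centred on the
#' configured individual alpha frequency (IAF), right-frontal beta and
#' parietal high-beta — mixed onto the channels through fixed topographic
#' gains on top of 1/f background noise. During the "high" run of a
#' construct the corresponding source power is multiplied by the configured
#' effect factor (for workload the parietal alpha power is simultaneously
#' divided by it; for vigilance the beta increase is applied to the
#' low-vigilance runs, mirroring the beta rise that accompanies vigilance
#' decrement).
#'
#' @param srate sampling rate, Hz.
#' @param iaf individual alpha frequency, Hz (7-13).
#' @param run_plan data frame with columns `label`, `duration` (s) and
#'   optionally `run`; `NULL` for the default plan described above.
#' @param condition_effects named numeric vector of multiplicative
#'   band-power factors for the "high" condition of each construct.
#' @param source_rms named numeric vector, RMS amplitude (microvolt) of the
#'   four oscillatory sources under neutral conditions.
#' @param topographies `channels x sources` gain matrix; `NULL` for the
#'   default frontal-theta / parietal-alpha / right-frontal-beta /
#'   parietal-high-beta layout.
#' @param source_coherence squared coherence between channels driven by
#'   the same rhythm: each channel mixes a shared component with its own
#'   independent component in this proportion.
#' @param closed_eyes_alpha_factor multiplicative alpha-power boost during
#'   the closed-eyes rest (gives the resting spectrum its alpha peak).
#' @param noise_rms RMS (microvolt) of the 1/f background per channel.
#' @param noise_exponent spectral slope of the background (power ~ 1/f^a).
#' @param blink_rate blink events per minute.
#' @param blink_amplitude blink peak amplitude on AFz, microvolt.
#' @param gross_artifact_rate high-amplitude artifact events per minute.
#' @param gross_artifact_amplitude range (min, max) of artifact pulse
#'   amplitude, microvolt; pulses exceed the 80 microvolt rejection
#'   criterion by construction.
#' @param system_b_noise_scale background-noise multiplier for the paired
#'   second recording system.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   session bit for bit.
#' @return A list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7)
#' sess <- simulate_session(cfg)
#' sess$system_a
simulation_config <- function(srate = 250, iaf = 10, run_plan = NULL,
                              condition_effects = c(workload = 1.5,
                                                    stress = 1.5,
                                                    vigilance = 1.5),
                              source_rms = c(theta = 7.5, alpha = 8.5,
                                             beta = 6, beta_high = 5),
                              topographies = NULL,
                              source_coherence = 0.45,
                              closed_eyes_alpha_factor = 6,
                              noise_rms = 5.5, noise_exponent = 1,
                              blink_rate = 6, blink_amplitude = 120,
                              gross_artifact_rate = 0,
                              gross_artifact_amplitude = c(120, 300),
                              system_b_noise_scale = 1.4,
                              seed = 1L) {
  if (srate <= 0) stop_pbci("sampling rate must be positive")
  if (iaf < 7 || iaf > 13) stop_pbci("iaf must lie in [7, 13] Hz")
  if (any(condition_effects <= 0)) stop_pbci("effect factors must be positive")
  stopifnot(all(c("workload", "stress", "vigilance") %in% names(condition_effects)))
  if (is.null(run_plan)) run_plan <- default_run_plan()
  run_plan <- as.data.frame(run_plan)
  stopifnot(all(c("label", "duration") %in% names(run_plan)))
  if (any(run_plan$duration <= 0)) stop_pbci("run durations must be positive")
  if (is.null(run_plan$run)) run_plan$run <- default_run_ids(run_plan$label)
  if (is.null(topographies)) topographies <- default_topographies()
  topographies <- as.matrix(topographies)
  if (!identical(rownames(topographies), bci_channels()) ||
      !identical(colnames(topographies), names(source_rms))) {
    stop_pbci("topographies must be a channels x sources matrix matching ",
              "bci_channels() and names(source_rms)")
  }
  structure(
    list(srate = srate, iaf = iaf, run_plan = run_plan,
         condition_effects = condition_effects, source_rms = source_rms,
         topographies = topographies,
         source_coherence = source_coherence,
         closed_eyes_alpha_factor = closed_eyes_alpha_factor,
         noise_rms = noise_rms, noise_exponent = noise_exponent,
         blink_rate = blink_rate, blink_amplitude = blink_amplitude,
         gross_artifact_rate = gross_artifact_rate,
         gross_artifact_amplitude = gross_artifact_amplitude,
         system_b_noise_scale = system_b_noise_scale,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

default_run_plan <- function(run_length = 60) {
  labels <- c("closed_eyes", "open_eyes",
              "workload_low", "workload_high",
              "workload_low", "workload_high",
              "stress_low", "stress_high",
              "stress_low", "stress_high",
              "vigilance_high", "vigilance_low",
              "vigilance_high", "vigilance_low")
  data.frame(label = labels, duration = run_length,
             run = default_run_ids(labels))
}

# Repetition index within each label (1st workload_low run -> 1, 2nd -> 2 ...)
default_run_ids <- function(labels) {
  stats::ave(seq_along(labels), labels, FUN = seq_along)
}

default_topographies <- function() {
  ch <- bci_channels() # AFz AF3 AF4 AF7 AF8 Pz P3 P4
  m <- cbind(
    theta     = c(1.0, 1.0, 1.0, 0.8, 0.8, 0.25, 0.25, 0.25),
    alpha     = c(0.25, 0.25, 0.25, 0.25, 0.25, 1.0, 1.0, 1.0),
    beta      = c(0.4, 0.2, 1.0, 0.2, 1.0, 0.15, 0.15, 0.15),
    beta_high = c(0.15, 0.15, 0.15, 0.15, 0.15, 0.8, 1.0, 1.0)
  )
  rownames(m) <- ch
  m
}

# Narrowband noise source: white noise band-passed to [low, high] Hz,
# scaled to unit expected RMS. Band-limited noise carries its own
# stochastic amplitude envelope (decorrelating within ~1/bandwidth
# seconds), giving realistic waxing/waning rhythms. The scale factor is
# the filter's deterministic white-noise gain, NOT the realized session
# standard deviation: normalizing by the realized SD would pin the total
# session power and thereby force the per-run mean powers to
# anti-correlate (a compositional constraint that acts as a spurious
# condition effect at long temporal resolutions).
narrowband_noise <- function(n, srate, low, high, order = 2) {
  x <- stats::rnorm(n)
  bf <- signal::butter(order, c(low, high) / (srate / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / filtfilt_rms_gain(bf)
}

# expected RMS of filtfilt(bf, unit white noise): the zero-phase pass has
# amplitude response |H|^2, so the output variance is the frequency
# average of |H|^4
filtfilt_rms_gain <- function(bf, k = 4096) {
  w <- pi * (seq_len(k) - 0.5) / k
  hb <- vapply(w, function(wi) sum(bf$b * exp(-1i * wi * (seq_along(bf$b) - 1))),
               complex(1))
  ha <- vapply(w, function(wi) sum(bf$a * exp(-1i * wi * (seq_along(bf$a) - 1))),
               complex(1))
  sqrt(mean(Mod(hb / ha)^4))
}

# 1/f^a background noise via FFT spectral shaping, scaled to unit
# expected RMS (deterministic factor; see narrowband_noise for why the
# realized SD is not used).
pink_noise <- function(n, srate, exponent) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, srate, length.out = n + 1)[1:n]
  f[f > srate / 2] <- srate - f[f > srate / 2] # mirror for negative freqs
  w <- ifelse(f < 1, 1, f^(-exponent / 2))
  w[1] <- 0
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  y / sqrt(mean(w^2))
}

# Per-sample amplitude gain of each source implied by the run plan.
condition_gains <- function(cfg, n) {
  gains <- matrix(1, nrow = n, ncol = 4,
                  dimnames = list(NULL, c("theta", "alpha", "beta", "beta_high")))
  eff <- cfg$condition_effects
  bounds <- cumsum(cfg$run_plan$duration)
  starts <- c(0, utils::head(bounds, -1))
  for (i in seq_len(nrow(cfg$run_plan))) {
    idx <- seq.int(floor(starts[i] * cfg$srate) + 1L,
                   min(n, floor(bounds[i] * cfg$srate)))
    lab <- cfg$run_plan$label[i]
    if (lab == "closed_eyes") {
      gains[idx, "alpha"] <- sqrt(cfg$closed_eyes_alpha_factor)
    } else if (lab == "workload_high") {
      gains[idx, "theta"] <- sqrt(eff[["workload"]])
      gains[idx, "alpha"] <- 1 / sqrt(eff[["workload"]])
    } else if (lab == "stress_high") {
      gains[idx, "beta_high"] <- sqrt(eff[["stress"]])
    } else if (lab == "vigilance_low") {
      # vigilance decrement: right-frontal beta power rises
      gains[idx, "beta"] <- sqrt(eff[["vigilance"]])
    }
  }
  gains
}

#' Simulate a labelled two-system EEG session with ground truth
#'
#' Generates the multi-condition session described by a
#' [simulation_config()]: two recordings of the same underlying cortical
#' sources (system A and a paired system B that differs only in its
#' background-noise level), plus the ground truth needed to validate every
#' downstream stage — true blink intervals, epoch indices that exceed the
#' +/-80 microvolt rejection criterion by construction, the applied
#' band-power effect factors, and the per-sample condition labels.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `system_a`, `system_b` (both
#'   [eeg_recording()]) and `truth` (list with `blink_intervals`,
#'   `artifact_epochs`, `true_band_effects`, `condition_per_sample`).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  dur <- sum(cfg$run_plan$duration)
  n <- floor(dur * cfg$srate)
  bands <- source_bands(cfg$iaf)

  # each rhythm is a spatially extended source: a common component shared
  # by all channels plus per-channel independent components, mixed so the
  # squared coherence between channels is source_coherence
  gains <- condition_gains(cfg, n)
  nch <- nrow(cfg$topographies)
  brain <- matrix(0, nrow = nch, ncol = n,
                  dimnames = list(rownames(cfg$topographies), NULL))
  coh <- cfg$source_coherence
  with_seed(child_seed(cfg$seed, 1), {
    for (s in colnames(cfg$topographies)) {
      common <- narrowband_noise(n, cfg$srate, bands[[s]][1], bands[[s]][2])
      g <- cfg$source_rms[[s]] * gains[, s]
      for (ch in seq_len(nch)) {
        indep <- narrowband_noise(n, cfg$srate, bands[[s]][1], bands[[s]][2])
        x <- sqrt(coh) * common + sqrt(1 - coh) * indep
        brain[ch, ] <- brain[ch, ] + cfg$topographies[ch, s] * g * x
      }
    }
  })

  noise_a <- with_seed(child_seed(cfg$seed, 2), {
    t(vapply(seq_len(nrow(brain)), function(i)
      pink_noise(n, cfg$srate, cfg$noise_exponent), numeric(n)))
  }) * cfg$noise_rms
  noise_b <- with_seed(child_seed(cfg$seed, 3), {
    t(vapply(seq_len(nrow(brain)), function(i)
      pink_noise(n, cfg$srate, cfg$noise_exponent), numeric(n)))
  }) * cfg$noise_rms * cfg$system_b_noise_scale

  ann <- plan_annotations(cfg$run_plan)
  data_a <- brain + noise_a
  data_b <- brain + noise_b

  # blinks: one ocular source seen by both systems
  blink_intervals <- data.frame(start = numeric(0), end = numeric(0))
  if (cfg$blink_rate > 0) {
    ev <- with_seed(child_seed(cfg$seed, 4),
                    blink_events(dur, cfg$blink_rate, cfg$blink_amplitude))
    wave <- blink_waveform(ev, n, cfg$srate)
    data_a <- data_a + wave
    data_b <- data_b + wave
    blink_intervals <- ev[, c("start", "end")]
  }

  # gross artifacts: sensor-level, independent between systems
  if (cfg$gross_artifact_rate > 0) {
    data_a <- with_seed(child_seed(cfg$seed, 5),
                        add_gross_artifacts(data_a, cfg))
    data_b <- with_seed(child_seed(cfg$seed, 6),
                        add_gross_artifacts(data_b, cfg))
  }

  rec_a <- eeg_recording(data_a, cfg$srate, bci_channels(), ann)
  rec_b <- eeg_recording(data_b, cfg$srate, bci_channels(), ann)

  truth <- list(
    blink_intervals = blink_intervals,
    artifact_epochs = list(system_a = threshold_epochs(data_a, cfg$srate),
                           system_b = threshold_epochs(data_b, cfg$srate)),
    true_band_effects = cfg$condition_effects,
    condition_per_sample = sample_labels(cfg$run_plan, n, cfg$srate)
  )
  list(system_a = rec_a, system_b = rec_b, truth = truth)
}

# band edges of the four oscillatory sources, anchored on the IAF; the
# alpha source is kept narrow (+/-1 Hz) so its spectral bump peaks at IAF
source_bands <- function(iaf) {
  list(theta = c(iaf - 6, iaf - 2), alpha = c(iaf - 1, iaf + 1),
       beta = c(iaf + 2, iaf + 16), beta_high = c(iaf + 11, iaf + 16))
}

plan_annotations <- function(run_plan) {
  bounds <- cumsum(run_plan$duration)
  data.frame(start = c(0, utils::head(bounds, -1)), end = bounds,
             label = run_plan$label, run = run_plan$run)
}

sample_labels <- function(run_plan, n, srate) {
  ann <- plan_annotations(run_plan)
  lab <- character(n)
  for (i in seq_len(nrow(ann))) {
    idx <- seq.int(floor(ann$start[i] * srate) + 1L,
                   min(n, floor(ann$end[i] * srate)))
    lab[idx] <- ann$label[i]
  }
  lab
}

# 1-s epoch indices (1-based) whose raw amplitude exceeds +/-80 uV anywhere
threshold_epochs <- function(data, srate, threshold = 80) {
  spe <- floor(srate)
  nep <- floor(ncol(data) / spe)
  which(vapply(seq_len(nep), function(e) {
    idx <- ((e - 1) * spe + 1):(e * spe)
    any(abs(data[, idx]) > threshold)
  }, logical(1)))
}

blink_events <- function(dur, rate, amplitude) {
  n_ev <- round(rate * dur / 60)
  if (n_ev == 0) return(data.frame(start = numeric(0), end = numeric(0),
                                   amp = numeric(0)))
  blen <- 0.3
  # uniform non-overlapping placement with a minimum 0.4 s gap
  starts <- sort(stats::runif(n_ev * 4, 0.5, dur - blen - 0.5))
  keep <- c(TRUE, diff(starts) > blen + 0.4)
  starts <- starts[keep][seq_len(min(n_ev, sum(keep)))]
  while (length(starts) < n_ev) { # top up in pathological draws
    cand <- stats::runif(1, 0.5, dur - blen - 0.5)
    if (all(abs(cand - starts) > blen + 0.4)) starts <- sort(c(starts, cand))
  }
  data.frame(start = starts, end = starts + blen,
             amp = amplitude * stats::runif(length(starts), 0.8, 1.2))
}

# frontal-dominant spatial pattern of the ocular component
blink_topography <- function() {
  c(AFz = 1, AF3 = 0.9, AF4 = 0.9, AF7 = 0.55, AF8 = 0.55,
    Pz = 0.04, P3 = 0.04, P4 = 0.04)
}

blink_waveform <- function(events, n, srate) {
  wave <- matrix(0, nrow = 8, ncol = n,
                 dimnames = list(bci_channels(), NULL))
  if (!nrow(events)) return(wave)
  topo <- blink_topography()[bci_channels()]
  for (i in seq_len(nrow(events))) {
    i0 <- floor(events$start[i] * srate) + 1L
    tpl <- blink_template(srate, events$end[i] - events$start[i]) * events$amp[i]
    idx <- i0:min(n, i0 + length(tpl) - 1L)
    wave[, idx] <- wave[, idx] + outer(topo, tpl[seq_along(idx)])
  }
  wave
}

add_gross_artifacts <- function(data, cfg) {
  dur <- ncol(data) / cfg$srate
  n_ev <- round(cfg$gross_artifact_rate * dur / 60)
  if (n_ev == 0) return(data)
  front <- match(frontal_channels(), bci_channels())
  pari <- match(parietal_channels(), bci_channels())
  for (i in seq_len(n_ev)) {
    len <- stats::runif(1, 0.2, 0.8)
    start <- stats::runif(1, 0, dur - len)
    amp <- stats::runif(1, cfg$gross_artifact_amplitude[1],
                        cfg$gross_artifact_amplitude[2]) *
      sample(c(-1, 1), 1)
    ch <- if (stats::runif(1) < 0.75) sample(front, 1) else sample(pari, 1)
    idx <- (floor(start * cfg$srate) + 1L):min(ncol(data),
                                               floor((start + len) * cfg$srate))
    data[ch, idx] <- data[ch, idx] + amp
  }
  data
}

#' Inject stereotyped blink artifacts into a recording
#'
#' Adds a half-sine (~300 ms) blink template with a frontal-dominant
#' topography (AFz/AF3/AF4 strongest, AF7/AF8 intermediate, parietal
#' channels near zero), with per-event +/-20% amplitude jitter.
#'
#' @param rec an [eeg_recording()].
#' @param rate blink events per minute (>= 0).
#' @param amplitude peak amplitude on AFz, microvolt (>= 0).
#' @param seed integer seed for event placement and jitter.
#' @return List with `recording` (contaminated copy) and `intervals`
#'   (data frame of `start`, `end` in seconds).
#' @export
inject_blinks <- function(rec, rate, amplitude, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rate < 0) stop_pbci("blink rate must be non-negative")
  if (amplitude < 0) stop_pbci("blink amplitude must be non-negative")
  if (rate == 0) {
    return(list(recording = rec,
                intervals = data.frame(start = numeric(0), end = numeric(0))))
  }
  ev <- with_seed(seed, blink_events(rec_duration(rec), rate, amplitude))
  wave <- blink_waveform(ev, ncol(rec$data), rec$srate)[rec$channels, , drop = FALSE]
  out <- rec
  out$data <- rec$data + wave
  list(recording = out, intervals = ev[, c("start", "end")])
}

#' Simulate an electrode impedance log with regional drift
#'
#' Emulates impedance checks at fixed timepoints during a session, with a
#' configurable linear drift rate per scalp region (frontal electrodes dry
#' faster than parietal ones when so configured) plus measurement noise.
#'
#' @param start_kohm starting impedance, kOhm: a single value or a named
#'   vector per electrode.
#' @param drift_per_min named vector `c(frontal = , parietal = )` of drift
#'   rates in kOhm per minute.
#' @param timepoints measurement times in minutes (non-negative).
#' @param noise_sd measurement noise standard deviation, kOhm.
#' @param system label stored in the log (e.g. "water", "gel", "headset").
#' @param seed integer seed.
#' @return Data frame with columns `electrode`, `minute`, `kohm`, `system`.
#' @export
simulate_impedance_log <- function(start_kohm = 20,
                                   drift_per_min = c(frontal = 1, parietal = 0.2),
                                   timepoints = c(0, 10, 20, 30, 40),
                                   noise_sd = 0, system = "water", seed = 1L) {
  if (any(timepoints < 0)) stop_pbci("timepoints must be non-negative")
  if (any(start_kohm < 0)) stop_pbci("starting impedances must be non-negative")
  ch <- bci_channels()
  start <- if (length(start_kohm) == 1) stats::setNames(rep(start_kohm, 8), ch)
           else start_kohm[ch]
  drift <- ifelse(ch %in% frontal_channels(),
                  drift_per_min[["frontal"]], drift_per_min[["parietal"]])
  with_seed(seed, {
    grid <- expand.grid(electrode = ch, minute = sort(timepoints),
                        stringsAsFactors = FALSE)
    base <- start[grid$electrode] + drift[match(grid$electrode, ch)] * grid$minute
    grid$kohm <- pmax(0, base + stats::rnorm(nrow(grid), 0, noise_sd))
    grid$system <- system
    grid[order(grid$electrode, grid$minute), c("electrode", "minute", "kohm", "system")]
  })
}

#' Simulate a cohort of subjects
#'
#' Convenience wrapper generating `n` independent sessions whose IAFs are
#' drawn uniformly from `iaf_range` and whose seeds are derived from a
#' single cohort seed.
#'
#' @param n number of subjects.
#' @param seed cohort seed.
#' @param iaf_range range the per-subject IAF is drawn from, Hz.
#' @param ... further arguments passed to [simulation_config()].
#' @return List of `n` session lists as returned by [simulate_session()].
#' @export
simulate_subjects <- function(n, seed = 1L, iaf_range = c(8.5, 11.5), ...) {
  iafs <- with_seed(child_seed(seed, 99),
                    stats::runif(n, iaf_range[1], iaf_range[2]))
  lapply(seq_len(n), function(i) {
    cfg <- simulation_config(iaf = iafs[i], seed = child_seed(seed, i), ...)
    simulate_session(cfg)
  })
}
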