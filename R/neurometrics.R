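# Channel sets entering each neurometric, as used throughout the package.
construct_channels <- function(construct) {
  switch(construct,
    workload = list(theta = frontal_channels(),
                    alpha = parietal_channels()),
    stress = list(beta_high = c("P3", "P4")),
    vigilance = list(beta = c("AF4", "AF8")),
    stop_pbci("unknown construct '", construct, "'")
  )
}

#' Mental workload index
#'
#' Ratio of frontal theta to parietal alpha global field power: frontal
#' theta rises and parietal alpha falls with mental workload, so the index
#' increases monotonically with load. Inputs are channel-set mean band
#' powers (theta over AF7/AF8/AF3/AF4/AFz, alpha over P3/P4/Pz).
#'
#' @param theta_frontal frontal theta GFP, microvolt^2.
#' @param alpha_parietal parietal alpha GFP, microvolt^2.
#' @param eps denominator guard; a near-zero alpha power (possible on
#'   short, heavily rejected windows) is floored at `eps` with a warning.
#'   Set `eps = 0` to disable the guard, in which case a zero denominator
#'   is an error.
#' @return The workload index (dimensionless, vectorized over inputs).
#' @export
workload_index <- function(theta_frontal, alpha_parietal, eps = 1e-12) {
  if (any(theta_frontal < 0) || any(alpha_parietal < 0)) {
    stop_pbci("band powers must be non-negative")
  }
  if (eps <= 0) {
    if (any(alpha_parietal == 0)) {
      stop_pbci("zero parietal alpha power with the epsilon guard disabled")
    }
    return(theta_frontal / alpha_parietal)
  }
  if (any(alpha_parietal < eps)) {
    warning("parietal alpha power below epsilon guard; denominator floored",
            call. = FALSE)
  }
  theta_frontal / pmax(alpha_parietal, eps)
}

#' Stress index
#'
#' Parietal high-beta global field power (channel-set mean over P3 and
#' P4): high-beta parietal activity tracks sympathetic stress responses,
#' so the index increases with stress.
#'
#' @param beta_high_parietal parietal high-beta GFP, microvolt^2.
#' @return The stress index (microvolt^2, vectorized).
#' @export
stress_index <- function(beta_high_parietal) {
  if (any(beta_high_parietal < 0)) stop_pbci("band powers must be non-negative")
  beta_high_parietal
}

#' Vigilance index
#'
#' Negated right-frontal beta global field power (channel-set mean over
#' AF4 and AF8): right-frontal beta rises with vigilance decrement, so the
#' index decreases as vigilance declines and is always <= 0.
#'
#' @param beta_right_frontal right-frontal beta GFP, microvolt^2.
#' @return The vigilance index (<= 0, vectorized).
#' @export
vigilance_index <- function(beta_right_frontal) {
  if (any(beta_right_frontal < 0)) stop_pbci("band powers must be non-negative")
  -beta_right_frontal
}

#' Per-epoch neurometric series for a construct
#'
#' Computes the construct's index for every epoch of the construct's runs:
#' per-epoch per-channel band powers are obtained from single-epoch Hann
#' periodograms, averaged over the construct's channel set (arithmetic
#' mean), and combined by the construct's formula.
#'
#' @param epochs a screened [eeg_epochs()] object with condition labels of
#'   the form `"<construct>_<level>"`.
#' @param scheme a `band_scheme`.
#' @param construct `"workload"`, `"stress"` or `"vigilance"`.
#' @param all_epochs include epochs from all conditions (`TRUE`) or only
#'   the construct's own runs (default).
#' @return Data frame with columns `t_start` (s), `run`, `label`, `level`
#'   and `value`, one row per retained epoch.
#' @export
neurometric_series <- function(epochs, scheme, construct,
                               all_epochs = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sets <- construct_channels(construct)
  keep <- epochs$retained
  if (!all_epochs) keep <- keep & startsWith(epochs$labels, construct)
  idx <- which(keep)
  if (!length(idx)) stop_pbci("no retained epochs for construct '",
                              construct, "'")
  sub <- subset_epochs(epochs, idx)
  gfp <- lapply(names(sets), function(b) {
    pw <- epoch_band_powers(sub, scheme, bands = b, channels = sets[[b]])
    rowMeans(pw[, , 1, drop = FALSE])
  })
  names(gfp) <- names(sets)
  value <- switch(construct,
    workload = workload_index(gfp$theta, gfp$alpha),
    stress = stress_index(gfp$beta_high),
    vigilance = vigilance_index(gfp$beta)
  )
  data.frame(
    t_start = sub$t_start, run = sub$run, label = sub$labels,
    level = sub("^[a-z]+_", "", sub$labels), value = value
  )
}

subset_epochs <- function(epochs, idx) {
  eeg_epochs(epochs$epochs[idx, , , drop = FALSE], epochs$srate,
             epochs$channels, epochs$labels[idx], epochs$run[idx],
             epochs$t_start[idx], epochs$retained[idx])
}
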