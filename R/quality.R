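#' Interpolate an impedance log onto a regular time grid
#'
#' Piecewise-linear interpolation of per-electrode impedance measurements
#' onto a fixed grid (default every 10 min over a 40-min interval).
#' Measured timepoints on the grid are reproduced exactly; requesting a
#' grid point outside the measured span is an error (no extrapolation).
#'
#' @param log data frame with columns `electrode`, `minute`, `kohm` (and
#'   optionally `system`).
#' @param grid target timepoints, minutes.
#' @return Data frame `electrode`, `minute`, `kohm` (and `system`) on the
#'   grid.
#' @export
interpolate_impedance <- function(log, grid = c(0, 10, 20, 30, 40)) {
  stopifnot(all(c("electrode", "minute", "kohm") %in% names(log)))
  out <- lapply(split(log, log$electrode), function(d) {
    d <- d[order(d$minute), ]
    if (nrow(d) < 2) stop_pbci("need >= 2 measurements per electrode")
    if (min(grid) < min(d$minute) || max(grid) > max(d$minute)) {
      stop_pbci("grid extends outside the measured span (",
                min(d$minute), "-", max(d$minute), " min); no extrapolation")
    }
    res <- data.frame(electrode = d$electrode[1], minute = grid,
                      kohm = stats::approx(d$minute, d$kohm, xout = grid)$y)
    if (!is.null(d$system)) res$system <- d$system[1]
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Impedance drift significance per electrode
#'
#' Tests, for one electrode, whether impedance at each later timepoint
#' differs from the starting value across subjects, with a Wilcoxon
#' signed-rank test per timepoint and Bonferroni correction over the
#' number of later timepoints.
#'
#' @param values `subjects x timepoints` matrix of impedances (kOhm);
#'   column names are the timepoints in minutes, the first column the
#'   baseline.
#' @param alpha family-wise significance level.
#' @return Data frame `minute`, `W`, `p` (raw), `p_adj` (Bonferroni),
#'   `significant`.
#' @export
impedance_drift_test <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  if (nrow(values) < 6) stop_pbci("need >= 6 subjects")
  m <- ncol(values) - 1
  if (m < 1) stop_pbci("need at least one later timepoint")
  minutes <- suppressWarnings(as.numeric(colnames(values)))
  if (!length(minutes) || anyNA(minutes)) {
    minutes <- seq_len(ncol(values)) - 1
  }
  res <- lapply(seq_len(m) + 1, function(j) {
    w <- tryCatch(wilcoxon_signed_rank(values[, j], values[, 1]),
                  error = function(e) list(statistic = NA_real_, p_value = 1))
    data.frame(minute = minutes[j], W = w$statistic, p = w$p_value)
  })
  res <- do.call(rbind, res)
  res$p_adj <- pmin(1, res$p * m)
  res$significant <- res$p_adj < alpha
  res
}

#' Regional artifact percentages and paired comparisons
#'
#' Computes, per subject and recording system, the percentage of 1-s
#' epochs rejected in the frontal (AFz, AF3, AF4, AF7, AF8) and parietal
#' (Pz, P3, P4) channel groups — an epoch counts against a region when any
#' of the region's channels exceeded the rejection threshold — then
#' compares systems within each region and regions within each system by
#' paired Wilcoxon signed-rank tests.
#'
#' @param masks named list, one element per system; each element a list of
#'   per-subject `epochs x channels` logical exceedance matrices (the
#'   `channel_exceeded` attachment of [reject_artifacts()]).
#' @return List with `percentages` (data frame `subject`, `system`,
#'   `region`, `percent`) and `tests` (data frame of paired comparisons;
#'   a comparison whose differences are all zero is flagged `degenerate`
#'   with `p = 1`).
#' @export
artifact_percentage <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  regions <- list(frontal = frontal_channels(), parietal = parietal_channels())
  pct <- do.call(rbind, lapply(names(masks), function(sys) {
    do.call(rbind, lapply(seq_along(masks[[sys]]), function(s) {
      ex <- masks[[sys]][[s]]
      do.call(rbind, lapply(names(regions), function(reg) {
        ch <- intersect(regions[[reg]], colnames(ex))
        if (!length(ch)) stop_pbci("region '", reg, "' has no channels")
        data.frame(subject = s, system = sys, region = reg,
                   percent = 100 * mean(apply(ex[, ch, drop = FALSE], 1, any)))
      }))
    }))
  }))
  tests <- list()
  wide <- function(sys, reg) pct$percent[pct$system == sys & pct$region == reg]
  if (length(masks) >= 2) {
    sysn <- names(masks)[1:2]
    for (reg in names(regions)) {
      tests[[length(tests) + 1L]] <-
        paired_row(paste0(sysn[1], " vs ", sysn[2], " (", reg, ")"),
                   wide(sysn[1], reg), wide(sysn[2], reg))
    }
  }
  for (sys in names(masks)) {
    tests[[length(tests) + 1L]] <-
      paired_row(paste0("frontal vs parietal (", sys, ")"),
                 wide(sys, "frontal"), wide(sys, "parietal"))
  }
  list(percentages = pct, tests = do.call(rbind, tests))
}

paired_row <- function(comparison, a, b) {
  res <- tryCatch(wilcoxon_signed_rank(a, b), error = function(e) NULL)
  if (is.null(res)) {
    data.frame(comparison = comparison, W = NA_real_, p = 1,
               degenerate = TRUE)
  } else {
    data.frame(comparison = comparison, W = res$statistic, p = res$p_value,
               degenerate = FALSE)
  }
}

#' Per-band spectral correlation between two recording systems
#'
#' Pearson correlation between the PSDs of paired channels of two
#' simultaneous recordings, computed over the frequency bins of each band
#' of a (fixed) band scheme. A correlation is flagged significant when it
#' exceeds the critical value for the Bonferroni-corrected alpha given the
#' number of bins in the band (see [critical_r()]); the study convention
#' of alpha = 0.05 over 20 comparisons, i.e. per-comparison alpha 0.0025,
#' is the default, and the reference critical value 0.423 associated with
#' that alpha is available as [reference_r_threshold()].
#'
#' @param frame_a,frame_b `spectral_frame`s on a common frequency grid.
#' @param scheme a `band_scheme` (the fixed scheme by default).
#' @param couples channel pairs to correlate; default pairs each common
#'   channel with itself across systems.
#' @param alpha per-comparison significance level.
#' @return Data frame `couple`, `band`, `r`, `r_crit`, `significant`.
#' @export
spectral_correlation <- function(frame_a, frame_b,
                                 scheme = fixed_band_scheme(),
                                 couples = NULL,
                                 alpha = bonferroni_threshold(0.05, 20)) {
  stopifnot(inherits(frame_a, "spectral_frame"),
            inherits(frame_b, "spectral_frame"))
  if (!isTRUE(all.equal(frame_a$frequencies, frame_b$frequencies))) {
    stop_pbci("spectral frames must share a frequency grid")
  }
  if (is.null(couples)) {
    common <- intersect(frame_a$channels, frame_b$channels)
    couples <- data.frame(a = common, b = common)
  }
  f <- frame_a$frequencies
  out <- do.call(rbind, lapply(names(scheme$bands), function(band) {
    edges <- scheme$bands[[band]]
    bins <- which(f >= edges[1] & f < edges[2])
    if (length(bins) < 3) {
      stop_pbci("band '", band, "' spans fewer than 3 frequency bins")
    }
    rc <- critical_r(alpha, length(bins))
    do.call(rbind, lapply(seq_len(nrow(couples)), function(i) {
      r <- stats::cor(frame_a$psd[couples$a[i], bins],
                      frame_b$psd[couples$b[i], bins])
      data.frame(couple = paste0(couples$a[i], "-", couples$b[i]),
                 band = band, r = r, r_crit = rc, significant = r > rc)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Critical Pearson correlation for a given alpha and sample size
#'
#' The two-sided critical value of Pearson's r: correlations above it are
#' significant at level `alpha` for `n` paired observations, from the
#' exact t-distribution of `r sqrt(n-2)/sqrt(1-r^2)` under the null.
#'
#' @param alpha significance level.
#' @param n number of paired observations (frequency bins).
#' @return Critical correlation in `(0, 1)`.
#' @export
critical_r <- function(alpha, n) {
  if (n < 3) stop_pbci("need n >= 3")
  tq <- stats::qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(n - 2 + tq^2)
}

#' @rdname spectral_correlation
#' @export
reference_r_threshold <- function() 0.423

#' Wilcoxon signed-rank test (exact for small samples)
#'
#' Paired two-sided signed-rank test. Zero differences are discarded
#' (classical convention); ties among the remaining absolute differences
#' receive average ranks. For up to 25 non-zero differences the p-value
#' comes from the exact permutation distribution of the positive-rank sum
#' over all sign assignments; beyond that, a normal approximation with
#' continuity and tie correction is used.
#'
#' @param x,y paired numeric vectors, or differences in `x` when `y` is
#'   `NULL`.
#' @param exact_max largest n handled by exact enumeration.
#' @return List with `statistic` (W, the positive-rank sum), `n_used`
#'   (non-zero differences), `p_value` (two-sided) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_pbci("all differences are zero")
  if (n < 5) stop_pbci("need >= 5 non-zero differences (got ", n, ")")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = w, n_used = n, p_value = min(1, p), method = method)
}

# exact two-sided p for the positive-rank sum, by dynamic programming over
# the 2^n sign assignments (ranks doubled so tied half-ranks stay integer)
signed_rank_exact_p <- function(ranks, w) {
  r2 <- round(2 * ranks)
  total <- sum(r2)
  dist <- numeric(total + 1) # index s+1 holds count of assignments with sum s
  dist[1] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), dist[seq_len(length(dist) - v)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- round(2 * w)
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[seq.int(w2 + 1, length(dist))])
  min(1, 2 * min(p_le, p_ge))
}

#' Bonferroni-corrected per-comparison alpha
#'
#' @param alpha_family family-wise significance level.
#' @param m number of comparisons.
#' @return `alpha_family / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 20) # 0.0025
bonferroni_threshold <- function(alpha_family, m) {
  if (m < 1 || m != round(m)) stop_pbci("m must be a positive integer")
  if (alpha_family <= 0 || alpha_family > 1) {
    stop_pbci("alpha must lie in (0, 1]")
  }
  alpha_family / m
}
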