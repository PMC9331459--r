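test_that("impedance interpolation is linear, exact, and never extrapolates", {
  log <- data.frame(electrode = "AFz", minute = c(0, 40), kohm = c(20, 60))
  out <- interpolate_impedance(log)
  expect_equal(out$kohm[out$minute == 20], 40)
  expect_equal(out$kohm[out$minute == 0], 20)   # measured endpoints exact
  expect_equal(out$kohm[out$minute == 40], 60)
  expect_error(interpolate_impedance(log, grid = c(0, 50)), "extrapolation")

  # exact on affine inputs through arbitrary measured timepoints
  for (i in 1:10) {
    set.seed(i)
    a <- runif(1, -1, 2); b <- runif(1, 5, 50)
    tp <- sort(c(0, 40, runif(3, 1, 39)))
    log2 <- data.frame(electrode = "P3", minute = tp, kohm = a * tp + b)
    out2 <- interpolate_impedance(log2)
    expect_equal(out2$kohm, a * out2$minute + b, tolerance = 1e-12)
  }
})

test_that("impedance drift testing flags real drift and not constants", {
  const <- matrix(20, nrow = 10, ncol = 5,
                  dimnames = list(NULL, c(0, 10, 20, 30, 40)))
  res <- impedance_drift_test(const)
  expect_false(any(res$significant))
  expect_equal(res$p_adj, pmin(1, res$p * 4)) # Bonferroni over 4 timepoints

  # power: frontal drift of 1 kOhm/min across 20 subjects
  hits <- vapply(1:20, function(sd) {
    vals <- passivebci:::with_seed(sd, {
      t(vapply(1:20, function(s) {
        20 + 1 * c(0, 10, 20, 30, 40) + rnorm(5, sd = 3)
      }, numeric(5)))
    })
    colnames(vals) <- c(0, 10, 20, 30, 40)
    res <- impedance_drift_test(vals)
    res$significant[res$minute == 40]
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(impedance_drift_test(const[1:4, ]), "6 subjects")
})

test_that("artifact percentages aggregate by region and compare systems", {
  mk_mask <- function(n_bad_frontal, n_bad_parietal, n = 100) {
    m <- matrix(FALSE, n, 8, dimnames = list(NULL, bci_channels()))
    if (n_bad_frontal) m[seq_len(n_bad_frontal), "AF3"] <- TRUE
    if (n_bad_parietal) m[n - seq_len(n_bad_parietal) + 1, "P3"] <- TRUE
    m
  }
  res <- artifact_percentage(list(water = list(mk_mask(5, 2)),
                                  gel = list(mk_mask(5, 2))))
  pct <- res$percentages
  expect_equal(pct$percent[pct$system == "water" & pct$region == "frontal"], 5)
  expect_equal(pct$percent[pct$system == "gel" & pct$region == "parietal"], 2)
  # identical masks: between-system comparisons are degenerate with p = 1
  between <- res$tests[grepl("water vs gel", res$tests$comparison), ]
  expect_true(all(between$degenerate))
  expect_true(all(between$p == 1))

  # simulated frontal-dominant artifacts: frontal percentage exceeds parietal
  sess <- ref_session()
  scr <- reject_artifacts(epoch_recording(sess$system_a))
  res2 <- artifact_percentage(list(water = list(scr$channel_exceeded)))
  p2 <- res2$percentages
  expect_gt(p2$percent[p2$region == "frontal"],
            p2$percent[p2$region == "parietal"])
})

test_that("spectral correlation flags agreement against the critical r", {
  fr <- compute_psd(noise_recording(dur = 90, seed = 41), window_sec = 4)
  self <- spectral_correlation(fr, fr)
  expect_equal(nrow(self), 8 * 4)
  expect_true(all(abs(self$r - 1) < 1e-12))
  expect_true(all(self$significant))

  neg <- fr
  neg$psd <- -fr$psd + 2 * max(fr$psd)
  anti <- spectral_correlation(fr, neg)
  expect_true(all(abs(anti$r + 1) < 1e-12))
  expect_false(any(anti$significant))

  # argument symmetry and scale invariance
  fr2 <- compute_psd(noise_recording(dur = 90, seed = 42), window_sec = 4)
  r_ab <- spectral_correlation(fr, fr2)$r
  r_ba <- spectral_correlation(fr2, fr)$r
  expect_equal(r_ab, r_ba, tolerance = 1e-12)
  fr3 <- fr2
  fr3$psd <- fr2$psd * 7.3
  expect_equal(spectral_correlation(fr, fr3)$r, r_ab, tolerance = 1e-12)

  # independent spectra decorrelate
  rs <- vapply(1:30, function(sd) {
    a <- compute_psd(noise_recording(dur = 60, seed = 5000 + sd),
                     window_sec = 4)
    b <- compute_psd(noise_recording(dur = 60, seed = 6000 + sd),
                     window_sec = 4)
    mean(abs(spectral_correlation(a, b)$r))
  }, numeric(1))
  expect_lt(mean(rs), 0.3)
})

test_that("critical r matches the t-distribution and the study reference", {
  # inverse check: at the returned threshold the two-sided p equals alpha
  for (n in c(10, 30, 52)) {
    rc <- critical_r(0.0025, n)
    tstat <- rc * sqrt(n - 2) / sqrt(1 - rc^2)
    expect_equal(2 * (1 - pt(tstat, n - 2)), 0.0025, tolerance = 1e-10)
  }
  expect_equal(reference_r_threshold(), 0.423)
  # the reference value corresponds to roughly 49 bins at alpha = 0.0025
  expect_equal(critical_r(0.0025, 49), 0.423, tolerance = 0.005)
})

test_that("Wilcoxon signed-rank matches exact enumeration", {
  res <- wilcoxon_signed_rank(rep(1, 6) + 0:5) # n = 6, all positive
  expect_equal(res$p_value, 2 / 64)
  expect_identical(res$statistic, 21)

  anti <- wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3))
  expect_equal(anti$p_value, 1)

  expect_error(wilcoxon_signed_rank(c(1, 2, -1, 3)), "5 non-zero")
  expect_error(wilcoxon_signed_rank(rep(0, 10)), "zero")

  for (i in 1:30) {
    set.seed(i)
    n <- sample(5:10, 1)
    d <- round(rnorm(n), sample(0:1, 1)) # rounding creates ties and zeros
    d <- d[d != 0]
    if (length(d) < 5) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, signed_rank_bruteforce(d),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with the standard implementation without ties", {
  for (i in 1:15) {
    set.seed(100 + i)
    n <- sample(6:20, 1)
    d <- rnorm(n) # continuous: no ties, no zeros
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # large-sample normal path stays close to the reference
  set.seed(77)
  d <- rnorm(60, mean = 0.3)
  ours <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  expect_identical(ours$method, "normal approximation")
})

test_that("Bonferroni correction divides the family alpha", {
  expect_identical(bonferroni_threshold(0.05, 20), 0.0025)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 720), 6.944e-5, tolerance = 1e-3)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
  expect_error(bonferroni_threshold(1.5, 3), "alpha")
})
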