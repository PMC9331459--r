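test_that("Welch PSD satisfies Parseval and localizes a pure tone", {
  rec <- tone_recording(10, dur = 30, amp = 1)
  fr <- compute_psd(rec)
  expect_s3_class(fr, "spectral_frame")
  # mean power of a unit sinusoid is 0.5 uV^2
  total <- pracma::trapz(fr$frequencies, fr$psd[1, ])
  expect_equal(total, 0.5, tolerance = 0.05)
  expect_equal(fr$frequencies[which.max(fr$psd[1, ])], 10)

  zero <- eeg_recording(matrix(0, 8, 2500), 250, bci_channels())
  expect_true(all(compute_psd(zero)$psd == 0))
})

test_that("white-noise PSD is flat within Monte-Carlo bands", {
  rec <- noise_recording(dur = 120, sd = 1, seed = 12)
  fr <- compute_psd(rec)
  sel <- fr$frequencies >= 2 & fr$frequencies <= 30
  avg <- colMeans(fr$psd)[sel] # averaging channels tightens the bands
  rel <- avg / mean(avg)
  # ~239 half-overlapped windows x 8 channels: bin-wise sd well under 10%
  expect_true(all(rel > 0.7 & rel < 1.3))
  # density level: N(0,1) noise at 250 Hz has density 1/250 = 0.004
  expect_equal(mean(avg), 1 / 250, tolerance = 0.05)
})

test_that("PSD of epochs uses retained epochs only", {
  dat <- array(rnorm(20 * 8 * 250), dim = c(20, 8, 250))
  dat[3, , ] <- dat[3, , ] + 500 # would dominate if not excluded
  ep <- eeg_epochs(dat, 250, bci_channels(), labels = rep("x", 20),
                   run = rep(1L, 20), t_start = 0:19,
                   retained = c(TRUE, TRUE, FALSE, rep(TRUE, 17)))
  fr <- compute_psd(ep)
  expect_lt(max(fr$psd[, fr$frequencies == 0]), 1)
  ep$retained[] <- FALSE
  expect_error(compute_psd(ep), "retained")
})

test_that("IAF estimation refines the peak and falls back sensibly", {
  # synthetic frame: 1/f background with a clear bump at 9.4 Hz
  f <- 0:40
  bump <- function(centre) 5 * exp(-(f - centre)^2 / 2)
  mk_frame <- function(p) {
    structure(list(psd = rbind(p, p), frequencies = f, resolution = 1,
                   channels = c("AFz", "Pz")), class = "spectral_frame")
  }
  est <- estimate_iaf(mk_frame(10 / pmax(f, 1) + bump(9.4)))
  expect_true(est$confident)
  expect_lt(abs(est$iaf - 9.4), 0.3)

  # strictly monotone 1/f spectrum: fallback 10 Hz, low confidence
  est0 <- estimate_iaf(mk_frame(10 / pmax(f, 0.5)))
  expect_false(est0$confident)
  expect_identical(est0$iaf, 10)

  # two equal peaks at 8 and 12 Hz: lower one returned, flagged
  p <- rep(1, length(f)); p[f == 8] <- 5; p[f == 12] <- 5
  est2 <- estimate_iaf(mk_frame(p))
  expect_false(est2$confident)
  expect_lt(abs(est2$iaf - 8), 0.51)
  expect_lt(est2$iaf, 10)

  narrow <- structure(list(psd = matrix(1, 1, 5), frequencies = 8:12,
                           resolution = 1, channels = "AFz"),
                      class = "spectral_frame")
  expect_error(estimate_iaf(narrow), "window")
})

test_that("IAF-anchored bands reproduce the four interval formulas", {
  for (iaf in c(9, 10, 11.3)) {
    sch <- band_scheme_from_iaf(iaf)
    expect_equal(sch$bands$theta, c(iaf - 6, iaf - 2))
    expect_equal(sch$bands$alpha, c(iaf - 2, iaf + 2))
    expect_equal(sch$bands$beta, c(iaf + 2, iaf + 16))
    expect_equal(sch$bands$beta_high, c(iaf + 11, iaf + 16))
  }
  expect_identical(band_scheme_from_iaf(10)$bands$theta, c(4, 8))
  expect_identical(band_scheme_from_iaf(9)$bands$theta, c(3, 7))
  expect_identical(band_scheme_from_iaf(9)$bands$beta_high, c(20, 25))
  expect_error(band_scheme_from_iaf(0), "7")
})

test_that("the fixed comparison scheme holds the four printed bands", {
  sch <- fixed_band_scheme()
  expect_identical(length(sch$bands), 4L)
  expect_identical(sch$bands$theta, c(3, 7))
  expect_identical(sch$bands$alpha, c(7, 13))
  expect_identical(sch$bands$beta, c(13, 26))
  expect_identical(sch$bands$beta_high, c(21, 26))
  # documented discrepancy: at IAF = 10 the anchored theta band is the
  # fixed theta band shifted up by 1 Hz; the alpha bands differ in width
  # (4 vs 6 Hz) and are not a pure shift
  expect_equal(band_scheme_from_iaf(10)$bands$theta,
               fixed_band_scheme()$bands$theta + 1)
  expect_false(isTRUE(all.equal(diff(band_scheme_from_iaf(10)$bands$alpha),
                                diff(fixed_band_scheme()$bands$alpha))))
})

test_that("band power integrates the PSD with exact flat-density behaviour", {
  f <- 0:125
  fr <- structure(list(psd = matrix(2, 3, length(f),
                                    dimnames = list(c("AFz", "P3", "P4"), NULL)),
                       frequencies = f, resolution = 1,
                       channels = c("AFz", "P3", "P4")),
                  class = "spectral_frame")
  sch <- fixed_band_scheme()
  bp <- band_power(fr, sch, "theta") # flat density 2 over width 4 -> 8
  expect_equal(unname(bp$per_channel), rep(8, 3))
  expect_equal(bp$gfp, 8)
  one <- band_power(fr, sch, "theta", channels = "P3")
  expect_equal(one$gfp, unname(one$per_channel))

  # fractional edges: anchored bands at IAF 9.5 still integrate c * w
  sch2 <- band_scheme_from_iaf(9.5)
  expect_equal(band_power(fr, sch2, "alpha")$gfp, 2 * 4)

  expect_error(band_power(fr, sch, "gamma"), "unknown band")
  expect_error(band_power(fr, sch, "theta", channels = character(0)), "empty")
  expect_error(band_power(fr, sch, "theta", channels = "Cz"), "not in frame")
})

test_that("doubling the signal amplitude quadruples band power", {
  r1 <- tone_recording(10, dur = 20, amp = 1)
  r2 <- tone_recording(10, dur = 20, amp = 2)
  sch <- fixed_band_scheme()
  p1 <- band_power(compute_psd(r1), sch, "alpha")$gfp
  p2 <- band_power(compute_psd(r2), sch, "alpha")$gfp
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
})

test_that("disjoint band powers never exceed the total power", {
  fr <- compute_psd(bandpass_filter(ref_session()$system_a))
  sch <- ref_scheme()
  total <- vapply(fr$channels, function(ch) {
    sel <- fr$frequencies >= 2 & fr$frequencies <= 30
    pracma::trapz(fr$frequencies[sel], fr$psd[ch, sel])
  }, numeric(1))
  disjoint <- Reduce(`+`, lapply(c("theta", "alpha", "beta"), function(b) {
    band_power(fr, sch, b)$per_channel
  }))
  expect_true(all(disjoint <= total + 1e-9))
})

test_that("IAF recovery error stays small across random bump centres", {
  errs <- vapply(1:25, function(i) {
    centre <- passivebci:::with_seed(900 + i, runif(1, 8, 12))
    cfg <- simulation_config(iaf = centre, seed = 900 + i, blink_rate = 0,
                             run_plan = data.frame(label = "closed_eyes",
                                                   duration = 60))
    fr <- compute_psd(bandpass_filter(simulate_session(cfg)$system_a))
    abs(estimate_iaf(fr)$iaf - centre)
  }, numeric(1))
  expect_lt(mean(errs), 0.25)
})
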