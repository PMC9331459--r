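# Shared fixtures, generated in code and cached for the duration of a test
# run so expensive sessions are simulated once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# default-parameter reference session (IAF 9.6, blinks on, gross artifacts on)
ref_session <- function() {
  fixture("ref_session", simulate_session(
    simulation_config(iaf = 9.6, seed = 2024, gross_artifact_rate = 0.5)))
}

ref_prep <- function() {
  fixture("ref_prep", preprocess_recording(ref_session()$system_a))
}

ref_scheme <- function() band_scheme_from_iaf(9.6)

# small session builder: selected constructs only, configurable run length,
# reduced sampling rate for cheap property loops
mini_config <- function(constructs = "workload", reps = 2, run_length = 40,
                        rest = FALSE, srate = 128, seed = 1L, iaf = 10,
                        effects = c(workload = 1.5, stress = 1.5,
                                    vigilance = 1.5),
                        blink_rate = 0, ...) {
  labels <- character(0)
  if (rest) labels <- c("closed_eyes", "open_eyes")
  for (r in seq_len(reps)) {
    for (con in constructs) {
      lv <- if (con == "vigilance") c("high", "low") else c("low", "high")
      labels <- c(labels, paste0(con, "_", lv))
    }
  }
  plan <- data.frame(label = labels, duration = run_length)
  simulation_config(srate = srate, iaf = iaf, run_plan = plan,
                    condition_effects = effects, blink_rate = blink_rate,
                    seed = seed, ...)
}

# white-noise recording on the standard montage
noise_recording <- function(dur = 60, srate = 250, sd = 3, seed = 1L,
                            annotations = NULL) {
  dat <- passivebci:::with_seed(seed,
    matrix(stats::rnorm(8 * srate * dur, sd = sd), nrow = 8))
  eeg_recording(dat, srate, bci_channels(), annotations)
}

# single-sinusoid recording (same tone on every channel)
tone_recording <- function(freq, dur = 10, srate = 250, amp = 1) {
  t <- seq(0, dur - 1 / srate, by = 1 / srate)
  eeg_recording(matrix(rep(amp * sin(2 * pi * freq * t), each = 8),
                       nrow = 8, byrow = FALSE), srate, bci_channels())
}

intervals_overlap <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# exhaustive pairwise AUC oracle (ties counted one half)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# exhaustive sign-flip oracle for the signed-rank two-sided p-value
signed_rank_bruteforce <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
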