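# small deterministic feature table for classifier unit tests
toy_table <- function(n_per_class = 30, sep = 3, seed = 1, n_runs = 2) {
  passivebci:::with_seed(seed, {
    n <- 2 * n_per_class
    x1 <- c(rnorm(n_per_class), rnorm(n_per_class, mean = sep))
    x2 <- c(rnorm(n_per_class), rnorm(n_per_class, mean = sep))
    tab <- data.frame(
      label = factor(rep(c("low", "high"), each = n_per_class),
                     levels = c("low", "high")),
      rep = rep(rep(seq_len(n_runs), length.out = n_per_class), 2),
      t = rep(seq_len(n_per_class), 2),
      f1 = x1, f2 = x2)
    tab$run <- paste0(tab$label, ".", tab$rep)
    tab[, c("label", "rep", "run", "t", "f1", "f2")]
  })
}

test_that("feature tables carry exactly the construct's channel-band set", {
  ep <- ref_prep()$epochs
  sch <- ref_scheme()
  wl <- assemble_features(ep, sch, "workload")
  expect_setequal(passivebci:::feature_cols(wl),
                  c("AFz_theta", "AF3_theta", "AF4_theta", "AF7_theta",
                    "AF8_theta", "Pz_alpha", "P3_alpha", "P4_alpha"))
  st <- assemble_features(ep, sch, "stress")
  expect_setequal(passivebci:::feature_cols(st),
                  c("P3_beta_high", "P4_beta_high"))
  vg <- assemble_features(ep, sch, "vigilance")
  expect_setequal(passivebci:::feature_cols(vg), c("AF4_beta", "AF8_beta"))
  expect_true(all(table(wl$label) > 0))
  expect_false(anyNA(wl[, passivebci:::feature_cols(wl)]))

  none <- ep
  none$retained[] <- FALSE
  expect_error(assemble_features(none, sch, "stress"), "no retained")
  missing_ch <- passivebci:::subset_epochs(ep, seq_len(n_epochs(ep)))
  expect_error(assemble_features(ref_prep()$epochs, sch, "unknown"),
               "unknown construct")
})

test_that("ADASYN balances toward parity and only interpolates neighbours", {
  tab <- toy_table(30)
  expect_identical(balance_adasyn(tab, seed = 5), tab) # already balanced

  unb <- tab[c(1:30, 31:60, 31:60), ] # 30 low vs 60 high
  unb$t <- seq_len(nrow(unb))
  unb$run <- paste0(unb$label, ".", unb$rep)
  bal <- balance_adasyn(unb, k_neighbors = 5, seed = 5)
  counts <- table(bal$label)
  expect_lte(abs(counts[["low"]] - counts[["high"]]), 5 + 1)
  # originals preserved verbatim
  expect_equal(bal[seq_len(nrow(unb)), c("f1", "f2")],
               unb[, c("f1", "f2")], ignore_attr = TRUE)

  # every synthetic row lies on a segment between a minority point and one
  # of its k nearest minority neighbours
  synth <- bal[is.na(bal$run), c("f1", "f2")]
  minority <- as.matrix(unb[unb$label == "low", c("f1", "f2")])
  dmin <- as.matrix(dist(minority))
  on_segment <- vapply(seq_len(nrow(synth)), function(s) {
    p <- as.numeric(synth[s, ])
    for (i in seq_len(nrow(minority))) {
      nn <- order(dmin[i, -i])[1:5]
      nn_idx <- seq_len(nrow(minority))[-i][nn]
      for (j in nn_idx) {
        a <- minority[i, ]; b <- minority[j, ]
        seg <- b - a
        lam <- if (sum(seg^2) == 0) 0 else sum((p - a) * seg) / sum(seg^2)
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            sqrt(sum((a + lam * seg - p)^2)) < 1e-8) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
  expect_true(all(on_segment))

  tiny <- tab[c(1:4, 31:60), ]
  expect_error(balance_adasyn(tiny, k_neighbors = 5), "minority")
})

test_that("the random forest separates, is deterministic, and guards leakage", {
  tab <- toy_table(30, sep = 4)
  m1 <- train_model(tab, n_estimators = c(50, 150), max_depth = c(3, 10),
                    seed = 7)
  expect_s3_class(m1, "bci_model")
  sc <- predict_scores(m1, tab)
  expect_equal(auc(sc$score, tab$label == "high"), 1)

  m2 <- train_model(tab, n_estimators = c(50, 150), max_depth = c(3, 10),
                    seed = 7)
  expect_identical(m1$n_estimators, m2$n_estimators)
  expect_identical(m1$max_depth, m2$max_depth)
  expect_identical(predict_scores(m2, tab)$score, sc$score)

  # scoring never consults test labels
  shuffled <- tab
  shuffled$label <- sample(shuffled$label)
  expect_identical(predict_scores(m1, shuffled)$score, sc$score)

  single <- tab[tab$label == "low", ]
  expect_error(train_model(single), "two rows per class")
})

test_that("randomly permuted labels give chance-level held-out AUC", {
  aucs <- vapply(1:12, function(sd) {
    tab <- passivebci:::with_seed(700 + sd, {
      t0 <- toy_table(24, sep = 3, seed = 600 + sd)
      t0$label <- sample(t0$label)
      t0
    })
    train <- tab[tab$rep == 1, ]
    test <- tab[tab$rep == 2, ]
    if (length(unique(train$label)) < 2 || length(unique(test$label)) < 2) {
      return(NA_real_)
    }
    m <- train_model(train, n_estimators = 50, max_depth = 5, seed = sd)
    auc(predict_scores(m, test)$score, test$label == "high")
  }, numeric(1))
  expect_gt(mean(aucs, na.rm = TRUE), 0.35)
  expect_lt(mean(aucs, na.rm = TRUE), 0.65)
})

test_that("temporal aggregation matches brute-force window means", {
  tab <- toy_table(30)
  sc <- data.frame(run = tab$run, t = tab$t, label = tab$label,
                   score = seq_len(nrow(tab)) / nrow(tab))
  expect_identical(nrow(temporal_aggregate(sc, 1)), nrow(sc))

  one_run <- data.frame(run = "a.1", t = 1:60, label = "high",
                        score = runif(60))
  agg <- temporal_aggregate(one_run, 60)
  expect_identical(nrow(agg), 1L)
  expect_equal(agg$score, mean(one_run$score))

  # oracle: split each ordered run into floor(n/T) windows of T and average
  for (T in c(1, 2, 7, 13)) {
    agg <- temporal_aggregate(sc, T)
    for (r in unique(sc$run)) {
      xs <- sc$score[sc$run == r][order(sc$t[sc$run == r])]
      nw <- floor(length(xs) / T)
      expected <- vapply(seq_len(nw), function(w) {
        mean(xs[((w - 1) * T + 1):(w * T)])
      }, numeric(1))
      expect_equal(agg$score[agg$run == r], expected, tolerance = 1e-12)
    }
  }
  expect_error(temporal_aggregate(sc, 0), "positive integer")
  expect_error(temporal_aggregate(sc, 1000), "exceeds")
})

test_that("AUC equals exhaustive pair counting and handles ties", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(c(0.9, 0.3, 0.6, 0.5), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(auc(rep(0.7, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  for (i in 1:200) {
    set.seed(i)
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(round(runif(n), 2)) # rounding induces ties
    expect_identical(auc(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("k-fold calibration partitions time blocks and fills the curve", {
  tab <- toy_table(48, sep = 3, seed = 3, n_runs = 1)
  folds <- passivebci:::time_block_folds(tab, 3)
  expect_setequal(unique(folds), 1:3)
  expect_identical(length(folds), nrow(tab))
  for (r in unique(tab$run)) { # contiguous blocks within each run
    fr <- folds[tab$run == r][order(tab$t[tab$run == r])]
    expect_identical(fr, sort(fr))
  }

  cv <- kfold_calibrate(tab, k = 3, resolutions = c(1, 2, 4, 8),
                        seed = 2, n_estimators = 50, max_depth = 5)
  expect_identical(length(cv$auc), 4L)
  expect_true(all(!is.na(cv$auc)))
  expect_gt(cv$auc[4], 0.9) # separable toy problem
})

test_that("averaging over longer windows does not hurt a strong effect", {
  # runs slightly longer than 3 x 60 epochs so the occasional rejected
  # epoch still leaves a complete 60-s window in every test block
  cfg <- mini_config(constructs = "workload", reps = 1, run_length = 200,
                     seed = 51, srate = 128)
  sess <- simulate_session(cfg)
  ep <- reject_artifacts(epoch_recording(bandpass_filter(sess$system_a)))
  tab <- assemble_features(ep, band_scheme_from_iaf(10), "workload")
  cv <- kfold_calibrate(tab, k = 3, resolutions = c(1, 60), seed = 4,
                        n_estimators = 50, max_depth = 5)
  expect_false(anyNA(cv$auc))
  expect_gte(cv$auc[2], cv$auc[1] - 0.05)
})

test_that("run-split trains and tests on disjoint repetitions", {
  tab <- toy_table(40, sep = 3, seed = 9)
  cv <- runsplit_calibrate(tab, resolutions = c(1, 5), seed = 3,
                           n_estimators = 50, max_depth = 5)
  expect_identical(length(cv$auc), 2L)
  for (d in seq_along(cv$directions)) {
    test_reps <- unique(tab$rep[tab$run %in% cv$directions[[d]]$scores$run])
    expect_identical(length(test_reps), 1L) # scores come from one rep only
  }
  onerep <- tab[tab$rep == 1, ]
  expect_error(runsplit_calibrate(onerep), "two repetitions")
})

test_that("cross-task evaluation never touches the test task", {
  a <- toy_table(40, sep = 3, seed = 11)
  b <- toy_table(40, sep = 3, seed = 12)
  cv <- cross_task_evaluate(a, b, resolutions = c(1, 5), seed = 6,
                            n_estimators = 50, max_depth = 5)
  expect_identical(length(cv$auc), 2L)
  expect_identical(cv$model$fit$num.samples, nrow(a)) # trained on A only
  expect_true(all(cv$scores$run %in% b$run))

  bad <- b
  names(bad)[names(bad) == "f1"] <- "g1"
  expect_error(cross_task_evaluate(a, bad), "feature columns")
})

test_that("score-curve comparison returns Pearson r and RMSE", {
  x <- c(0.1, 0.5, 0.9)
  expect_equal(compare_score_curves(x, x),
               list(pearson_r = 1, rmse = 0, r_defined = TRUE))
  off <- compare_score_curves(x, x + 0.2)
  expect_equal(off$pearson_r, 1)
  expect_equal(off$rmse, 0.2)
  hand <- compare_score_curves(c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.9))
  expect_equal(hand$rmse, sqrt((0.01 + 0.01 + 0) / 3))
  const <- compare_score_curves(c(0.5, 0.5, 0.5), x)
  expect_false(const$r_defined)
  expect_true(is.na(const$pearson_r))
  expect_equal(const$rmse, sqrt(mean((0.5 - x)^2)))
  expect_error(compare_score_curves(1:2, 1:2), "length")
})

test_that("terminal AUC responds monotonically to the effect size", {
  factors <- c(1, 1.2, 1.5, 2)
  med <- vapply(factors, function(f) {
    aucs <- vapply(1:6, function(sd) {
      cfg <- mini_config(constructs = "workload", reps = 2, run_length = 70,
                         seed = 5000 + sd,
                         effects = c(workload = f, stress = 1, vigilance = 1))
      sess <- simulate_session(cfg)
      ep <- reject_artifacts(epoch_recording(bandpass_filter(sess$system_a)))
      tab <- assemble_features(ep, band_scheme_from_iaf(10), "workload")
      runsplit_calibrate(tab, resolutions = 60, seed = sd,
                         n_estimators = 50, max_depth = 5)$auc
    }, numeric(1))
    median(aucs)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_gt(med[4], med[1])
})
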