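#' Assemble the per-construct feature table
#'
#' Builds the classifier feature table from retained epochs of the
#' construct's runs: per-epoch per-channel band-integrated powers for the
#' construct's channel/band set — workload: AF7, AF8, AF3, AF4, AFz in
#' theta plus P3, P4, Pz in alpha (8 features); stress: P3, P4 in high
#' beta (2 features); vigilance: AF4, AF8 in beta (2 features).
#'
#' @param epochs a screened [eeg_epochs()] object.
#' @param scheme a `band_scheme`.
#' @param construct `"workload"`, `"stress"` or `"vigilance"`.
#' @return Data frame with columns `label` (factor low/high), `rep`
#'   (repetition id), `run` (unique run id), `t` (epoch start, s) and one
#'   column per feature (named `<channel>_<band>`); the construct is
#'   stored in attribute `"construct"`.
#' @export
assemble_features <- function(epochs, scheme, construct) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sets <- construct_channels(construct)
  needed <- unique(unlist(sets))
  absent <- setdiff(needed, epochs$channels)
  if (length(absent)) {
    stop_pbci("required channel(s) missing: ", paste(absent, collapse = ", "))
  }
  idx <- which(epochs$retained & startsWith(epochs$labels, paste0(construct, "_")))
  if (!length(idx)) stop_pbci("no retained epochs for construct '", construct, "'")
  sub <- subset_epochs(epochs, idx)
  feats <- do.call(cbind, lapply(names(sets), function(b) {
    pw <- epoch_band_powers(sub, scheme, bands = b, channels = sets[[b]])[, , 1, drop = FALSE]
    m <- matrix(pw, nrow = dim(pw)[1])
    colnames(m) <- paste0(sets[[b]], "_", b)
    m
  }))
  level <- sub("^[a-z]+_", "", sub$labels)
  if (length(unique(level)) < 2) {
    stop_pbci("retained epochs must cover both classes")
  }
  tab <- data.frame(label = factor(level, levels = c("low", "high")),
                    rep = sub$run,
                    run = paste0(sub$labels, ".", sub$run),
                    t = sub$t_start, feats, check.names = FALSE)
  attr(tab, "construct") <- construct
  tab
}

feature_cols <- function(tab) setdiff(names(tab), c("label", "rep", "run", "t",
                                                    "subject"))

#' ADASYN class balancing
#'
#' Adaptive synthetic oversampling of the minority class: each minority
#' point receives a weight proportional to the fraction of majority points
#' among its `k` nearest neighbours (the local density ratio, emphasizing
#' hard-to-learn regions), and that many synthetic points are generated by
#' uniform interpolation between the point and one of its `k` nearest
#' minority neighbours. Original rows are always preserved; an already
#' balanced table is returned unchanged.
#'
#' @param tab a feature table from [assemble_features()].
#' @param k_neighbors neighbourhood size.
#' @param seed integer seed.
#' @return The augmented feature table; synthetic rows carry `run = NA`
#'   and `t = NA`.
#' @export
balance_adasyn <- function(tab, k_neighbors = 5, seed = 1L) {
  fc <- feature_cols(tab)
  counts <- table(tab$label)
  if (length(counts) < 2 || any(counts == 0)) {
    stop_pbci("both classes must be present")
  }
  if (counts[1] == counts[2]) return(tab)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min < k_neighbors + 1) {
    stop_pbci("minority class has ", n_min, " rows; need at least ",
              k_neighbors + 1, " (lower k_neighbors)")
  }
  x <- as.matrix(tab[, fc, drop = FALSE])
  is_min <- tab$label == minority
  xi <- x[is_min, , drop = FALSE]
  d_all <- as.matrix(stats::dist(x))
  # density ratio: share of majority points among the k nearest neighbours
  min_idx <- which(is_min)
  r <- vapply(min_idx, function(i) {
    nn <- order(d_all[i, -i])[seq_len(k_neighbors)]
    others <- seq_len(nrow(x))[-i]
    mean(!is_min[others[nn]])
  }, numeric(1))
  g_total <- n_maj - n_min
  w <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
  g <- round(w * g_total)
  # minority-only neighbour lists for interpolation
  d_min <- as.matrix(stats::dist(xi))
  synth <- with_seed(seed, {
    rows <- list()
    for (i in seq_along(min_idx)) {
      if (g[i] == 0) next
      nn <- order(d_min[i, -i])[seq_len(min(k_neighbors, nrow(xi) - 1))]
      nn_idx <- seq_len(nrow(xi))[-i][nn]
      for (s in seq_len(g[i])) {
        j <- nn_idx[sample.int(length(nn_idx), 1)]
        lam <- stats::runif(1)
        rows[[length(rows) + 1L]] <- xi[i, ] + lam * (xi[j, ] - xi[i, ])
      }
    }
    rows
  })
  if (!length(synth)) return(tab)
  sm <- do.call(rbind, synth)
  colnames(sm) <- fc
  add <- tab[rep(1, nrow(sm)), , drop = FALSE]
  add[, fc] <- sm
  add$label <- factor(minority, levels = levels(tab$label))
  add$run <- NA_character_
  add$rep <- NA_integer_
  add$t <- NA_real_
  out <- rbind(tab, add)
  rownames(out) <- NULL
  attr(out, "construct") <- attr(tab, "construct")
  out
}

#' Train a Random-Forest mental-state classifier
#'
#' Fits a probability Random Forest, selecting the number of trees and
#' maximum tree depth by AUC on an inner stratified cross-validation split
#' of the training data. The searched values span the 50-500 tree and
#' 1-50 depth ranges on a coarse grid; ties resolve to the first (i.e.
#' smallest) grid entry. The result is deterministic for a fixed seed.
#'
#' @param train a feature table (training rows only).
#' @param n_estimators candidate numbers of trees.
#' @param max_depth candidate maximum depths.
#' @param inner_k inner cross-validation folds for the grid search.
#' @param seed integer seed.
#' @return An object of class `bci_model`: the fitted forest plus the
#'   selected hyperparameters, feature names and seed.
#' @export
train_model <- function(train,
                        n_estimators = c(50, 150, 300, 500),
                        max_depth = c(1, 3, 5, 10, 25, 50),
                        inner_k = 3, seed = 1L) {
  fc <- feature_cols(train)
  counts <- table(train$label)
  if (length(counts) < 2 || any(counts < 2)) {
    stop_pbci("need at least two rows per class")
  }
  stopifnot(all(n_estimators >= 50 & n_estimators <= 500),
            all(max_depth >= 1 & max_depth <= 50))
  x <- as.data.frame(train[, fc, drop = FALSE])
  y <- factor(train$label, levels = c("low", "high"))
  folds <- with_seed(child_seed(seed, 17), stratified_folds(y, inner_k))
  grid <- expand.grid(n_estimators = n_estimators, max_depth = max_depth)
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(inner_k), function(f) {
      tr <- folds != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) return(NA_real_)
      fit <- fit_ranger(x[tr, , drop = FALSE], y[tr],
                        grid$n_estimators[g], grid$max_depth[g],
                        child_seed(seed, 100 + g))
      sc <- predict_ranger(fit, x[!tr, , drop = FALSE])
      auc(sc, y[!tr] == "high")
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_auc) # first max on ties
  fit <- fit_ranger(x, y, grid$n_estimators[best], grid$max_depth[best],
                    child_seed(seed, 7))
  structure(list(fit = fit, n_estimators = grid$n_estimators[best],
                 max_depth = grid$max_depth[best], features = fc,
                 cv_auc = cv_auc[best], seed = as.integer(seed)),
            class = "bci_model")
}

#' @export
print.bci_model <- function(x, ...) {
  cat(sprintf("<bci_model> random forest: %d trees, max depth %d (inner-CV AUC %.3f)\n",
              x$n_estimators, x$max_depth, x$cv_auc))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

fit_ranger <- function(x, y, num_trees, depth, seed) {
  ranger::ranger(x = x, y = y, num.trees = num_trees, max.depth = depth,
                 probability = TRUE, seed = seed, num.threads = 1,
                 respect.unordered.factors = TRUE)
}

predict_ranger <- function(fit, x) {
  p <- stats::predict(fit, data = x, num.threads = 1)$predictions
  p[, "high"]
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Class-probability scores for a feature table
#'
#' @param model a `bci_model`.
#' @param tab a feature table with the model's feature columns.
#' @return Data frame `run`, `t`, `label`, `score` (probability of the
#'   "high" class), one row per input row.
#' @export
predict_scores <- function(model, tab) {
  stopifnot(inherits(model, "bci_model"))
  if (!all(model$features %in% names(tab))) {
    stop_pbci("feature columns do not match the model")
  }
  data.frame(run = tab$run, t = tab$t, label = tab$label,
             score = predict_ranger(model$fit,
                                    as.data.frame(tab[, model$features,
                                                      drop = FALSE])))
}

#' Aggregate per-second scores to a coarser temporal resolution
#'
#' Averages classifier probability scores over consecutive non-overlapping
#' windows of `T` epochs within each run; each window inherits the run's
#' condition label, and a trailing partial window is dropped. `T = 1` is
#' the identity.
#'
#' @param scores data frame from [predict_scores()] (columns `run`,
#'   `label`, `score`, optionally `t` for ordering).
#' @param T window length in epochs (seconds at 1-s epoching), 1-60.
#' @return Data frame `run`, `window`, `label`, `score`.
#' @export
temporal_aggregate <- function(scores, T) {
  if (T < 1 || T != round(T)) stop_pbci("T must be a positive integer")
  runs <- split(scores, scores$run)
  if (T > max(vapply(runs, nrow, integer(1)))) {
    stop_pbci("T exceeds the longest run (", max(vapply(runs, nrow, integer(1))),
              " epochs)")
  }
  out <- lapply(runs, function(r) {
    if (!is.null(r$t)) r <- r[order(r$t), , drop = FALSE]
    n_win <- floor(nrow(r) / T)
    if (n_win == 0) return(NULL)
    w <- rep(seq_len(n_win), each = T)
    data.frame(run = r$run[1], window = seq_len(n_win),
               label = r$label[1],
               score = as.numeric(tapply(r$score[seq_along(w)], w, mean)))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted one half —
#' equivalent to the normalized Mann-Whitney U statistic.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop_pbci("both classes must be present")
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluation curve: AUC as a function of temporal resolution
#'
#' @param resolutions integer window lengths (s).
#' @param auc AUC per resolution (`NA` where no complete window exists).
#' @param scores per-epoch score data frame the curve was computed from.
#' @return An object of class `evaluation_curve`.
#' @keywords internal
evaluation_curve <- function(resolutions, auc, scores = NULL) {
  stopifnot(length(resolutions) == length(auc))
  structure(list(resolutions = resolutions, auc = auc, scores = scores),
            class = "evaluation_curve")
}

#' @export
print.evaluation_curve <- function(x, ...) {
  ok <- !is.na(x$auc)
  cat(sprintf("<evaluation_curve> %d resolutions (%d evaluable), AUC %.3f-%.3f\n",
              length(x$resolutions), sum(ok),
              min(x$auc[ok]), max(x$auc[ok])))
  invisible(x)
}

#' @export
as.data.frame.evaluation_curve <- function(x, ...) {
  data.frame(resolution = x$resolutions, auc = x$auc)
}

curve_from_scores <- function(scores, resolutions) {
  aucs <- vapply(resolutions, function(T) {
    agg <- tryCatch(temporal_aggregate(scores, T), error = function(e) NULL)
    if (is.null(agg)) return(NA_real_)
    lab <- agg$label == "high"
    if (!any(lab) || all(lab)) return(NA_real_)
    auc(agg$score, lab)
  }, numeric(1))
  evaluation_curve(resolutions, aucs, scores)
}

#' k-fold calibration with time-blocked folds
#'
#' Splits each run into `k` contiguous time blocks, rotates each block set
#' through the test role (contiguous blocks limit temporal-autocorrelation
#' leakage between training and test), balances the training side with
#' ADASYN when imbalanced, grid-searches and fits the Random Forest on it,
#' and evaluates AUC at every requested temporal resolution on the
#' held-out blocks. The per-resolution AUC is the mean over the `k`
#' rotations; resolutions longer than a test block yield `NA`.
#'
#' @param tab a feature table.
#' @param k number of folds.
#' @param resolutions temporal resolutions, s.
#' @param seed integer seed.
#' @param ... passed to [train_model()].
#' @return An `evaluation_curve`; fold-level curves in `$folds`.
#' @export
kfold_calibrate <- function(tab, k = 3, resolutions = 1:60, seed = 1L, ...) {
  fold <- time_block_folds(tab, k)
  per_fold <- lapply(seq_len(k), function(f) {
    train <- tab[fold != f, , drop = FALSE]
    test <- tab[fold == f, , drop = FALSE]
    if (length(unique(test$label)) < 2 || length(unique(train$label)) < 2) {
      stop_pbci("fold ", f, " lacks a class")
    }
    train <- balance_if_needed(train, child_seed(seed, 30 + f))
    model <- train_model(train, seed = child_seed(seed, 60 + f), ...)
    curve_from_scores(predict_scores(model, test), resolutions)
  })
  aucs <- rowMeans(matrix(vapply(per_fold, function(cv) cv$auc,
                                 numeric(length(resolutions))),
                          nrow = length(resolutions)))
  out <- evaluation_curve(resolutions, aucs,
                          do.call(rbind, lapply(per_fold, `[[`, "scores")))
  out$folds <- per_fold
  out
}

time_block_folds <- function(tab, k) {
  fold <- integer(nrow(tab))
  for (r in unique(tab$run)) {
    idx <- which(tab$run == r)
    idx <- idx[order(tab$t[idx])]
    fold[idx] <- ceiling(seq_along(idx) / (length(idx) / k))
  }
  pmin(fold, k)
}

balance_if_needed <- function(tab, seed, k_neighbors = 5) {
  counts <- table(tab$label)
  if (counts[1] == counts[2]) return(tab)
  balance_adasyn(tab, k_neighbors = k_neighbors, seed = seed)
}

#' Run-split calibration
#'
#' For tasks recorded with two repetitions per condition: trains on one
#' repetition and tests on the other, in both directions, and averages the
#' two per-resolution AUC curves. No epoch ever appears on both sides of
#' a split.
#'
#' @param tab a feature table with at least two repetitions per class.
#' @param resolutions temporal resolutions, s.
#' @param seed integer seed.
#' @param ... passed to [train_model()].
#' @return An `evaluation_curve`; per-direction curves in `$directions`.
#' @export
runsplit_calibrate <- function(tab, resolutions = 1:60, seed = 1L, ...) {
  reps <- sort(unique(tab$rep))
  if (length(reps) < 2) stop_pbci("run-split needs two repetitions per condition")
  by_class <- tapply(tab$rep, tab$label, function(r) length(unique(r)))
  if (any(by_class < 2)) stop_pbci("each class needs two repetitions")
  dirs <- list(c(reps[1], reps[2]), c(reps[2], reps[1]))
  per_dir <- lapply(seq_along(dirs), function(d) {
    train <- tab[tab$rep == dirs[[d]][1], , drop = FALSE]
    test <- tab[tab$rep == dirs[[d]][2], , drop = FALSE]
    train <- balance_if_needed(train, child_seed(seed, 40 + d))
    model <- train_model(train, seed = child_seed(seed, 80 + d), ...)
    curve_from_scores(predict_scores(model, test), resolutions)
  })
  aucs <- rowMeans(matrix(vapply(per_dir, function(cv) cv$auc,
                                 numeric(length(resolutions))),
                          nrow = length(resolutions)))
  out <- evaluation_curve(resolutions, aucs,
                          do.call(rbind, lapply(per_dir, `[[`, "scores")))
  out$directions <- per_dir
  out
}

#' Cross-task evaluation
#'
#' Trains the model (with balancing and grid search) exclusively on the
#' calibration task's feature table and evaluates it on a different task's
#' table; no test-task row enters training.
#'
#' @param calibration feature table of the calibration task (e.g. a
#'   laboratory task).
#' @param test feature table of the transfer task (e.g. realistic
#'   driving); must have the same feature columns.
#' @param resolutions temporal resolutions, s.
#' @param seed integer seed.
#' @param ... passed to [train_model()].
#' @return An `evaluation_curve` with the fitted model in `$model`.
#' @export
cross_task_evaluate <- function(calibration, test, resolutions = 1:60,
                                seed = 1L, ...) {
  if (!setequal(feature_cols(calibration), feature_cols(test))) {
    stop_pbci("calibration and test tables must share feature columns")
  }
  train <- balance_if_needed(calibration, child_seed(seed, 51))
  model <- train_model(train, seed = child_seed(seed, 52), ...)
  out <- curve_from_scores(predict_scores(model, test), resolutions)
  out$model <- model
  out
}

#' Compare two probability score traces
#'
#' Pearson correlation and root-mean-squared difference between two
#' aligned classifier score traces (e.g. intra-task vs cross-task model
#' outputs on the same windows).
#'
#' @param scores_a,scores_b numeric vectors of equal length (>= 3).
#' @return List with `pearson_r` (`NA` with `r_defined = FALSE` when
#'   either trace is constant) and `rmse`.
#' @export
compare_score_curves <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 3) {
    stop_pbci("traces must have equal length >= 3")
  }
  rmse <- sqrt(mean((scores_a - scores_b)^2))
  constant <- stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0
  r <- if (constant) NA_real_ else stats::cor(scores_a, scores_b)
  list(pearson_r = r, rmse = rmse, r_defined = !constant)
}
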