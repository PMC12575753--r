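# Population decoding of AV delay from single-trial binned spike counts,
# with synthetic shifted-auditory and linear-sum control classes.
#
# Features are (neuron x 10 ms time bin) spike counts over the decoding
# window (default [0, 250) ms).  The linear classifier is a one-vs-rest
# maximum-margin machine on a precomputed linear Gram matrix (C-svc, C = 1,
# raw counts); the nonlinear alternative is a random forest.

#' Per-neuron binned features for one set of trials
#'
#' @param train A [spike_train].
#' @param events Trials to featurise (rows of an [event_table]).
#' @param window_ms Decoding window (default `c(0, 250)`).
#' @param bin_width_ms Feature bin width (default 10 ms).
#' @param align Alignment onset passed to [slice_trials()].
#' @return Trials-by-bins count matrix.
#' @export
decoding_features <- function(train, events, window_ms = c(0, 250),
                              bin_width_ms = 10, align = "stimulus") {
  trial_count_matrix(slice_trials(train, events, window_ms, align = align),
                     bin_width_ms, window_ms)
}

#' Synthetic shifted-auditory trials
#'
#' For each non-zero AV delay `d`, copies every unisensory auditory trial
#' with its spike times shifted by `+d` ms before binning, yielding the
#' `A_SHIFT(d)` control classes that carry the auditory timing of the AV
#' delay conditions without any visual response.  `d = 0` is not generated
#' (it would duplicate the `A` class).
#'
#' @param train A [spike_train].
#' @param events Session [event_table] (its `A` trials are used).
#' @param delays_ms Delays to generate (non-zero entries only are used).
#' @inheritParams decoding_features
#' @return Named list of count matrices, one per delay
#'   (`"A_SHIFT_<d>"`).
#' @export
build_shifted_auditory_trials <- function(train, events, delays_ms,
                                          window_ms = c(0, 250),
                                          bin_width_ms = 10) {
  delays_ms <- delays_ms[delays_ms != 0]
  a_sliced <- slice_trials(train, select_trials(events, "A"), window_ms +
                             c(-max(abs(delays_ms)), 0))
  out <- lapply(delays_ms, function(d) {
    shifted <- lapply(a_sliced, function(t) t + d)
    trial_count_matrix(shifted, bin_width_ms, window_ms)
  })
  names(out) <- paste0("A_SHIFT_", delays_ms)
  out
}

#' Synthetic linear-sum AV trials
#'
#' For each delay, pairs visual trials with (time-shifted) auditory trials
#' by a seeded random bijection and sums their binned counts, producing the
#' response expected under exact linear summation of unisensory inputs.
#' Because the sum of two recorded trials carries the baseline twice, the
#' neuron's expected baseline count per bin (cached `baseline_rate`, or
#' estimated from the pre-onset `[-200, 0)` ms of the unisensory trials) is
#' subtracted once, mirroring the baseline convention of
#' [linear_sum_response()].
#'
#' @inheritParams build_shifted_auditory_trials
#' @param delays_ms Delays to generate (0 allowed).
#' @param seed Seed for the trial pairing.
#' @return Named list of count matrices (`"LINSUM_<d>"`).
#' @export
build_linear_sum_trials <- function(train, events, delays_ms,
                                    window_ms = c(0, 250),
                                    bin_width_ms = 10, seed = 1L) {
  v <- decoding_features(train, select_trials(events, "V"), window_ms,
                         bin_width_ms)
  a_sliced <- slice_trials(train, select_trials(events, "A"), window_ms +
                             c(-max(abs(delays_ms), 1), 0))
  n <- min(nrow(v), length(a_sliced))
  if (nrow(v) != length(a_sliced))
    warning("unequal V and A trial counts; pairing to the minimum")
  base_hz <- train$baseline_rate
  if (!is.finite(base_hz)) {
    pre <- slice_trials(train, rbind(select_trials(events, "V"),
                                     select_trials(events, "A")),
                        c(-200, 0))
    base_hz <- sum(lengths(pre)) / (length(pre) * 0.2)
  }
  base_per_bin <- base_hz * bin_width_ms / 1000
  withr::with_seed(seed, {
    out <- lapply(delays_ms, function(d) {
      shifted <- lapply(a_sliced, function(t) t + d)
      a <- trial_count_matrix(shifted, bin_width_ms, window_ms)
      v[sample.int(n), , drop = FALSE] + a[sample.int(n), , drop = FALSE] -
        base_per_bin
    })
    names(out) <- paste0("LINSUM_", delays_ms)
    out
  })
}

#' Assemble a trial feature matrix for decoding
#'
#' Builds the trials-by-(neuron x bin) matrix for a chosen class set.
#' Observed classes are `"AV_<d>"`, `"V"`, `"A"`, `"BLANK"`; synthetic
#' classes are `"A_SHIFT_<d>"` and, when `linear_sum = TRUE`, AV classes are
#' *replaced* by `"LINSUM_<d>"` built from unisensory trials.
#'
#' For a single session the rows are true simultaneous trials.  When several
#' sessions are pooled, pseudo-trials are formed per class by a seeded random
#' permutation of repetition indices independently per neuron, which
#' destroys within-session noise correlations (the standard pseudo-population
#' construction).
#'
#' @param sessions One `av_session` or a list of them.
#' @param neuron_ids Neurons to include (default: all; ids must be unique
#'   across sessions).
#' @param include Observed classes to include: subset of
#'   `c("AV", "V", "A", "BLANK")`.
#' @param shifted_a Include the 10 shifted-auditory control classes.
#' @param linear_sum Replace observed AV classes by linear-sum synthetic
#'   trials.
#' @param window_ms,bin_width_ms Feature geometry.
#' @param seed Seed (pseudo-trial permutation and linear-sum pairing).
#' @return List of class `trial_features`: `x` (matrix), `y` (factor),
#'   `provenance` (`"observed"`, `"shifted_A"`, `"linear_sum"` per row),
#'   `neuron_ids`, `n_bins`.
#' @export
assemble_pseudopopulation <- function(sessions, neuron_ids = NULL,
                                      include = c("AV", "V", "A"),
                                      shifted_a = TRUE, linear_sum = FALSE,
                                      window_ms = c(0, 250),
                                      bin_width_ms = 10, seed = 1L) {
  if (inherits(sessions, "av_session")) sessions <- list(sessions)
  blocks <- list(); labels <- NULL; prov <- NULL
  for (s_i in seq_along(sessions)) {
    ses <- sessions[[s_i]]
    events <- ses$events
    delays <- sort(unique(events$av_delay_ms[!is.na(events$av_delay_ms)]))
    spikes <- ses$spikes
    if (!is.null(neuron_ids))
      spikes <- spikes[intersect(names(spikes), neuron_ids)]
    per_neuron <- lapply(spikes, function(tr) {
      parts <- list(); lab <- character(0); pv <- character(0)
      if ("AV" %in% include) {
        for (d in delays) {
          cls <- paste0("AV_", d)
          m <- if (linear_sum)
            build_linear_sum_trials(tr, events, d, window_ms, bin_width_ms,
                                    seed = child_seed(seed, paste0(
                                      tr$neuron_id, "ls", d)))[[1L]]
          else decoding_features(tr, select_trials(events, "AV", d),
                                 window_ms, bin_width_ms)
          parts <- c(parts, list(m))
          lab <- c(lab, rep(cls, nrow(m)))
          pv <- c(pv, rep(if (linear_sum) "linear_sum" else "observed",
                          nrow(m)))
        }
      }
      for (mod in intersect(include, c("V", "A", "BLANK"))) {
        m <- decoding_features(tr, select_trials(events, mod), window_ms,
                               bin_width_ms)
        parts <- c(parts, list(m))
        lab <- c(lab, rep(mod, nrow(m)))
        pv <- c(pv, rep("observed", nrow(m)))
      }
      if (shifted_a) {
        sh <- build_shifted_auditory_trials(tr, events, delays, window_ms,
                                            bin_width_ms)
        for (nm in names(sh)) {
          parts <- c(parts, list(sh[[nm]]))
          lab <- c(lab, rep(nm, nrow(sh[[nm]])))
          pv <- c(pv, rep("shifted_A", nrow(sh[[nm]])))
        }
      }
      list(x = do.call(rbind, parts), lab = lab, pv = pv)
    })
    lab <- per_neuron[[1L]]$lab
    x_s <- do.call(cbind, lapply(per_neuron, `[[`, "x"))
    blocks[[s_i]] <- list(x = x_s, lab = lab, pv = per_neuron[[1L]]$pv)
  }
  if (length(blocks) == 1L) {
    out <- blocks[[1L]]
  } else {
    # pseudo-trials: per class, permute repetition indices per session block
    common <- Reduce(intersect, lapply(blocks, function(b) unique(b$lab)))
    reps <- min(vapply(blocks, function(b) min(table(b$lab[b$lab %in%
                                                             common])), 0))
    xs <- list(); lab <- character(0); pv <- character(0)
    withr::with_seed(child_seed(seed, "pseudo"), {
      per_block <- lapply(blocks, function(b) {
        rows <- unlist(lapply(common, function(cl) {
          idx <- which(b$lab == cl)
          sample(idx, reps)
        }))
        b$x[rows, , drop = FALSE]
      })
      xs <- do.call(cbind, per_block)
      lab <- rep(common, each = reps)
      pv <- blocks[[1L]]$pv[unlist(lapply(common, function(cl)
        rep(which(blocks[[1L]]$lab == cl)[1L], reps)))]
    })
    out <- list(x = xs, lab = lab, pv = pv)
  }
  structure(list(x = out$x, y = factor(out$lab), provenance = out$pv,
                 neuron_ids = names(sessions[[1L]]$spikes),
                 n_bins = diff(window_ms) / bin_width_ms),
            class = "trial_features")
}

# --- classifiers -------------------------------------------------------------

# One-vs-rest linear maximum-margin classifier on a precomputed Gram matrix.
.ovr_svm_fit <- function(K, y, cost = 1) {
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    yk <- factor(ifelse(y == cl, "pos", "neg"), levels = c("neg", "pos"))
    m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yk, type = "C-svc",
                       C = cost)
    dv <- kernlab::predict(m, kernlab::as.kernelMatrix(
      K[, kernlab::SVindex(m), drop = FALSE]), type = "decision")
    flip <- mean(dv[yk == "pos"]) < mean(dv[yk == "neg"])
    list(model = m, flip = flip)
  })
  list(models = models, classes = classes)
}

.ovr_svm_predict <- function(fit, K_new) {
  dv <- vapply(fit$models, function(mm) {
    d <- kernlab::predict(mm$model, kernlab::as.kernelMatrix(
      K_new[, kernlab::SVindex(mm$model), drop = FALSE]), type = "decision")
    if (mm$flip) -as.numeric(d) else as.numeric(d)
  }, numeric(nrow(K_new)))
  factor(fit$classes[max.col(dv, ties.method = "first")],
         levels = fit$classes)
}

.fit_predict <- function(x_tr, y_tr, x_te, classifier, cost, ntree, seed,
                         scale = FALSE) {
  if (scale) {
    mu <- colMeans(x_tr)
    sdv <- pmax(apply(x_tr, 2L, sd), 1e-3)
    x_tr <- sweep(sweep(x_tr, 2L, mu), 2L, sdv, "/")
    x_te <- sweep(sweep(x_te, 2L, mu), 2L, sdv, "/")
  }
  if (classifier == "svm") {
    K <- tcrossprod(x_tr)
    fit <- .ovr_svm_fit(K, y_tr, cost)
    .ovr_svm_predict(fit, x_te %*% t(x_tr))
  } else {
    rf <- withr::with_seed(seed, randomForest::randomForest(
      x = x_tr, y = y_tr, ntree = ntree))
    stats::predict(rf, x_te)
  }
}

#' Train a delay decoder and score it on held-out trials
#'
#' Stratified 80/20 split; optional k-fold cross-validation within the
#' training portion (its mean accuracy is reported as `cv_accuracy`); the
#' headline `av_delay_accuracy` is the percentage of *AV-delay* test trials
#' classified correctly on the held-out 20%.
#'
#' @param features A `trial_features` object
#'   ([assemble_pseudopopulation()]), or a list with `x` and `y`.
#' @param classifier `"svm"` (one-vs-rest linear maximum-margin, C = 1, raw
#'   counts) or `"rf"` (random forest).
#' @param test_frac Held-out fraction (default 0.2).
#' @param folds Cross-validation folds within the training set (0 skips CV).
#' @param cost Linear-classifier regularisation constant.
#' @param ntree Random-forest trees.
#' @param shuffle_labels Shuffle class labels before splitting (chance-level
#'   control).
#' @param scale Standardise each feature by its training-set mean and SD
#'   before fitting (default `FALSE`: raw counts).
#' @param seed Seed controlling split, CV folds, label shuffling and forest.
#' @return List of class `decoding_result`: `confusion` (test-set matrix,
#'   true classes in rows), `av_delay_accuracy` (%), `overall_accuracy` (%),
#'   `cv_accuracy` (% or NA), `n_test`, `seed`.
#' @export
train_and_score <- function(features, classifier = c("svm", "rf"),
                            test_frac = 0.2, folds = 5, cost = 1,
                            ntree = 200, shuffle_labels = FALSE,
                            scale = FALSE, seed = 1L) {
  classifier <- match.arg(classifier)
  x <- features$x; y <- features$y
  if (nlevels(droplevels(y)) < 2L) stop("need >= 2 classes")
  withr::with_seed(seed, {
    if (shuffle_labels) y <- sample(y)
    te <- unlist(lapply(split(seq_along(y), y), function(idx)
      sample(idx, max(1L, round(length(idx) * test_frac)))))
  })
  tr <- setdiff(seq_along(y), te)
  if (any(table(y[tr]) == 0L) || any(table(y[te]) == 0L))
    stop("stratification failed: a class is missing from a split")
  cv_acc <- NA_real_
  if (folds > 0L) {
    fold_of <- withr::with_seed(child_seed(seed, "cv"), {
      f <- integer(length(tr))
      for (idx in split(seq_along(tr), droplevels(y[tr])))
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      f
    })
    accs <- vapply(seq_len(folds), function(f) {
      hold <- tr[fold_of == f]
      fit_on <- setdiff(tr, hold)
      pred <- .fit_predict(x[fit_on, , drop = FALSE],
                           droplevels(y[fit_on]),
                           x[hold, , drop = FALSE], classifier, cost,
                           ntree, child_seed(seed, paste0("cvf", f)),
                           scale = scale)
      is_av <- grepl("^AV_", y[hold])
      if (!any(is_av)) mean(as.character(pred) == as.character(y[hold]))
      else mean(as.character(pred[is_av]) ==
                  as.character(y[hold][is_av]))
    }, 0)
    cv_acc <- 100 * mean(accs)
  }
  pred <- .fit_predict(x[tr, , drop = FALSE], droplevels(y[tr]),
                       x[te, , drop = FALSE], classifier, cost, ntree,
                       child_seed(seed, "final"), scale = scale)
  truth <- factor(as.character(y[te]), levels = levels(y))
  pred <- factor(as.character(pred), levels = levels(y))
  confusion <- table(truth = truth, predicted = pred)
  is_av <- grepl("^AV_|^LINSUM_", as.character(truth))
  av_acc <- if (any(is_av))
    100 * mean(as.character(pred[is_av]) == as.character(truth[is_av]))
  else NA_real_
  structure(list(confusion = confusion,
                 av_delay_accuracy = av_acc,
                 overall_accuracy = 100 * mean(as.character(pred) ==
                                                 as.character(truth)),
                 cv_accuracy = cv_acc, n_test = length(te), seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result: AV-delay accuracy %.1f%% (overall %.1f%%, CV %.1f%%), %d test trials>\n",
              x$av_delay_accuracy, x$overall_accuracy, x$cv_accuracy,
              x$n_test))
  invisible(x)
}

#' Score a fitted decoder's predictions on a transfer test set
#'
#' Trains on one feature set and evaluates AV-delay accuracy on another
#' (e.g. train on linear-sum synthetic trials, test on observed AV trials).
#' Classes are matched by name, with `LINSUM_<d>` treated as `AV_<d>`.
#'
#' @param train_features,test_features `trial_features` objects with
#'   matching feature geometry.
#' @inheritParams train_and_score
#' @return A `decoding_result` (no CV).
#' @export
transfer_score <- function(train_features, test_features,
                           classifier = c("svm", "rf"), cost = 1,
                           ntree = 200, scale = FALSE, seed = 1L) {
  classifier <- match.arg(classifier)
  canon <- function(y) factor(sub("^LINSUM_", "AV_", as.character(y)))
  y_tr <- canon(train_features$y)
  y_te <- canon(test_features$y)
  te_av <- grepl("^AV_", as.character(y_te))
  pred <- .fit_predict(train_features$x, y_tr, test_features$x, classifier,
                       cost, ntree, seed, scale = scale)
  lev <- union(levels(y_tr), levels(y_te))
  truth <- factor(as.character(y_te), levels = lev)
  pred <- factor(as.character(pred), levels = lev)
  structure(list(confusion = table(truth = truth, predicted = pred),
                 av_delay_accuracy = 100 * mean(as.character(pred[te_av]) ==
                                                  as.character(truth[te_av])),
                 overall_accuracy = 100 * mean(as.character(pred) ==
                                                 as.character(truth)),
                 cv_accuracy = NA_real_, n_test = length(y_te),
                 prediction = pred, seed = seed),
            class = "decoding_result")
}

#' Misclassification metrics of a decoding result
#'
#' `mode = "rate_vs_shifted_A"`: percentage of AV-delay test trials
#' predicted as any shifted-auditory class (the false-negative confusion
#' that would arise if only auditory timing were decoded).
#' `mode = "error_ms"`: median absolute difference between true and
#' predicted delay over AV test trials (requires an AV-delay-only
#' classifier).
#'
#' @param result A `decoding_result`.
#' @param mode See above.
#' @return Scalar metric.
#' @export
misclassification_metrics <- function(result,
                                      mode = c("rate_vs_shifted_A",
                                               "error_ms")) {
  mode <- match.arg(mode)
  cm <- result$confusion
  true_lab <- rownames(cm); pred_lab <- colnames(cm)
  av_rows <- grepl("^AV_", true_lab)
  if (!any(av_rows)) stop("no AV-delay classes in the result")
  if (mode == "rate_vs_shifted_A") {
    sh_cols <- grepl("^A_SHIFT_", pred_lab)
    if (!any(sh_cols)) stop("result has no shifted-auditory classes")
    100 * sum(cm[av_rows, sh_cols]) / sum(cm[av_rows, ])
  } else {
    if (!all(grepl("^AV_", pred_lab)))
      stop("error_ms requires a classifier trained on AV-delay classes only")
    d_true <- as.numeric(sub("^AV_", "", true_lab[av_rows]))
    d_pred <- as.numeric(sub("^AV_", "", pred_lab))
    errs <- abs(outer(d_true, d_pred, "-"))
    counts <- cm[av_rows, , drop = FALSE]
    median(rep(as.vector(errs), as.vector(counts)))
  }
}

#' Decoding accuracy across subpopulations or anatomical bins
#'
#' For each pool of neurons and each population size, repeatedly samples
#' `n_neurons` (with replacement when the pool is smaller -- flagged),
#' assembles the features, trains a decoder and records the AV-delay
#' accuracy; reports mean and SD over iterations.
#'
#' @param session An `av_session`.
#' @param pools Named list of neuron-id vectors.
#' @param n_neurons Vector of population sizes.
#' @param n_iter Resampling iterations per cell (default 20).
#' @param classifier,folds Passed to [train_and_score()].
#' @param seed Master seed.
#' @param ... Passed to [assemble_pseudopopulation()].
#' @return Data.frame: `pool, n_neurons, mean_accuracy, sd_accuracy,
#'   n_iter, with_replacement`.
#' @export
subpopulation_sweep <- function(session, pools, n_neurons = 25, n_iter = 20,
                                classifier = "svm", folds = 0, seed = 1L,
                                ...) {
  rows <- list()
  for (pn in names(pools)) {
    pool <- pools[[pn]]
    for (nn in n_neurons) {
      wr <- length(pool) < nn
      accs <- vapply(seq_len(n_iter), function(it) {
        ids <- withr::with_seed(child_seed(seed, paste(pn, nn, it)),
                                sample(pool, nn, replace = wr))
        fe <- assemble_pseudopopulation(session, neuron_ids = unique(ids),
                                        seed = child_seed(seed,
                                                          paste(pn, nn, it,
                                                                "f")), ...)
        train_and_score(fe, classifier = classifier, folds = folds,
                        seed = child_seed(seed, paste(pn, nn, it,
                                                      "s")))$av_delay_accuracy
      }, 0)
      rows[[paste(pn, nn)]] <- data.frame(
        pool = pn, n_neurons = nn, mean_accuracy = mean(accs),
        sd_accuracy = sd(accs), n_iter = n_iter, with_replacement = wr,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Assign neurons to anatomical bins
#'
#' Divides the recorded volume into bins along the chosen axes (e.g. 2 x 2
#' over ML and AP for four bins, 2 x 2 x 2 for eight) using per-axis median
#' splits.
#'
#' @param neurons Data.frame with `neuron_id, ml_um, ap_um, dv_um`.
#' @param axes Subset of `c("ml", "ap", "dv")`.
#' @return Named list of neuron-id vectors, one per bin; neurons lacking
#'   coordinates are dropped.
#' @export
anatomical_bins <- function(neurons, axes = c("ml", "ap")) {
  cols <- paste0(axes, "_um")
  ok <- stats::complete.cases(neurons[, cols, drop = FALSE])
  df <- neurons[ok, , drop = FALSE]
  side <- lapply(cols, function(cl)
    ifelse(df[[cl]] <= median(df[[cl]]), "lo", "hi"))
  key <- do.call(paste, c(Map(function(a, s) paste0(a, s), axes, side),
                          sep = "_"))
  split(df$neuron_id, key)
}

#' Subset a trial feature object by rows
#'
#' @param features A `trial_features` object.
#' @param rows Integer row indices.
#' @return A `trial_features` with the selected rows.
#' @export
subset_features <- function(features, rows) {
  structure(list(x = features$x[rows, , drop = FALSE],
                 y = factor(as.character(features$y[rows]),
                            levels = levels(features$y)),
                 provenance = features$provenance[rows],
                 neuron_ids = features$neuron_ids,
                 n_bins = features$n_bins),
            class = "trial_features")
}

#' Observed versus linear-sum decoding comparison
#'
#' Quantifies how much nonlinear summation contributes to AV-delay decoding:
#' one decoder is trained on observed multisensory trials, the other on
#' synthetic linear-sum trials built from the same neurons' unisensory
#' responses; both include the unisensory, shifted-auditory and blank
#' control classes, and both are evaluated on the *same* held-out observed
#' AV-delay test trials.
#'
#' @param session An `av_session`.
#' @param neuron_ids Neurons to include (e.g. the planted delay-selective
#'   pool).
#' @param classifier,cost,ntree,scale Passed to the decoders.
#' @param folds Number of disjoint 20% test folds to average over
#'   (default 5, covering every observed trial once).
#' @param seed Seed (split, pairing, fits).
#' @return List: `observed_accuracy`, `linear_sum_accuracy` (mean % over
#'   folds on the shared observed AV test trials), `gap` (percentage
#'   points), and the per-fold accuracies.
#' @export
nonlinearity_benefit <- function(session, neuron_ids = NULL,
                                 classifier = "svm", cost = 1, ntree = 200,
                                 scale = FALSE, folds = 5, seed = 1L) {
  fe_obs <- assemble_pseudopopulation(
    session, neuron_ids = neuron_ids,
    include = c("AV", "V", "A", "BLANK"), shifted_a = TRUE,
    seed = child_seed(seed, "obs"))
  fe_lin <- assemble_pseudopopulation(
    session, neuron_ids = neuron_ids,
    include = c("AV", "V", "A", "BLANK"), shifted_a = TRUE,
    linear_sum = TRUE, seed = child_seed(seed, "lin"))
  y <- fe_obs$y
  fold_of <- withr::with_seed(child_seed(seed, "split"), {
    f <- integer(length(y))
    for (idx in split(seq_along(y), y))
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    f
  })
  # the linear-sum decoder never sees observed trials, so it is fitted once
  # and scored fold by fold on the same test partition
  av_rows <- which(grepl("^AV_", as.character(y)))
  r_lin_all <- transfer_score(fe_lin, subset_features(fe_obs, av_rows),
                              classifier = classifier, cost = cost,
                              ntree = ntree, scale = scale,
                              seed = child_seed(seed, "fl"))
  lin_correct <- as.character(r_lin_all$prediction) ==
    as.character(y[av_rows])
  acc_obs <- numeric(folds); acc_lin <- numeric(folds)
  for (k in seq_len(folds)) {
    te <- which(fold_of == k)
    tr <- which(fold_of != k)
    te_av <- te[grepl("^AV_", as.character(y[te]))]
    test_fe <- subset_features(fe_obs, te_av)
    r_obs <- transfer_score(subset_features(fe_obs, tr), test_fe,
                            classifier = classifier, cost = cost,
                            ntree = ntree, scale = scale,
                            seed = child_seed(seed, paste0("fo", k)))
    acc_obs[k] <- r_obs$av_delay_accuracy
    acc_lin[k] <- 100 * mean(lin_correct[av_rows %in% te_av])
  }
  list(observed_accuracy = mean(acc_obs),
       linear_sum_accuracy = mean(acc_lin),
       gap = mean(acc_obs) - mean(acc_lin),
       fold_observed = acc_obs, fold_linear_sum = acc_lin)
}
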