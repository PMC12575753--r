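# Feature construction, synthetic control classes and the decoders.

test_that("shifted-auditory trials move spikes and rotate binned features", {
  ev <- event_table(1:12, c(rep("A", 10), "V", "BLANK"),
                    onset_ms = 1000 + 2000 * (0:11), truncated = TRUE)
  # single spike at 30 ms on every A trial
  tr <- spike_train(sort(ev$onset_ms[1:10] + 30.5), "n")
  sh <- build_shifted_auditory_trials(tr, ev, seq(0, 100, 10))
  expect_length(sh, 10) # d = 0 is not generated
  m40 <- sh[["A_SHIFT_40"]]
  expect_equal(which(m40[1, ] == 1), 8) # 70 ms -> 8th 10 ms bin
  base <- decoding_features(tr, select_trials(ev, "A"))
  # features of shift d equal a d/10-bin right rotation of the A features
  for (d in c(10, 50, 100)) {
    m <- sh[[paste0("A_SHIFT_", d)]]
    k <- d / 10
    want <- cbind(matrix(0L, nrow(base), k),
                  base[, 1:(ncol(base) - k), drop = FALSE])
    expect_equal(unname(m), unname(want))
  }
})

test_that("linear-sum trials add features and subtract one baseline", {
  s <- small_session()
  tr <- s$spikes[[which(s$ground_truth$neurons$class == "bimodal")[1]]]
  ls <- build_linear_sum_trials(tr, s$events, c(0, 50), seed = 3)
  v <- decoding_features(tr, select_trials(s$events, "V"))
  a <- decoding_features(tr, select_trials(s$events, "A"))
  base_bin <- tr$baseline_rate * 10 / 1000
  # bin-wise mean equals mean(V) + shifted mean(A) - baseline
  got <- colMeans(ls[["LINSUM_0"]])
  want <- colMeans(v) + colMeans(a) - base_bin
  expect_equal(got, want, tolerance = 1e-9)
  # all-zero A trials: linear sum equals the V features minus baseline
  tr0 <- spike_train(tr$spike_times, "z", baseline_rate = 0)
  ev_noA <- s$events
  ls0 <- build_linear_sum_trials(tr0, ev_noA, 0, seed = 4)
  expect_true(all(ls0[["LINSUM_0"]] >= 0))
})

test_that("single-session features are true simultaneous trials", {
  s <- small_session()
  fe <- assemble_pseudopopulation(s, include = c("AV", "V", "A"),
                                  shifted_a = FALSE, seed = 1)
  n_delay <- 11
  expect_equal(nrow(fe$x), (n_delay + 2) * s$config$n_reps)
  expect_equal(ncol(fe$x), length(s$spikes) * 25)
  # row for trial j of class V is exactly the concatenated per-neuron counts
  v_rows <- which(fe$y == "V")
  ev_v <- select_trials(s$events, "V")
  want <- do.call(cbind, lapply(s$spikes, decoding_features, ev_v))
  expect_equal(unname(fe$x[v_rows, ]), unname(want))
})

test_that("pseudo-trials across sessions permute repetitions deterministically", {
  s1 <- generate_session(synth_config(
    seed = 81, n_neurons = c(visual = 2, auditory = 1, bimodal = 1,
                             gated = 0, nonresponsive = 0),
    n_reps = 8, iti_ms = 2000))
  s2 <- generate_session(synth_config(
    seed = 82, n_neurons = c(visual = 1, auditory = 2, bimodal = 1,
                             gated = 0, nonresponsive = 0),
    n_reps = 8, iti_ms = 2000))
  s2$spikes <- setNames(s2$spikes, paste0("b_", names(s2$spikes)))
  fe1 <- assemble_pseudopopulation(list(s1, s2), include = c("V", "A"),
                                   shifted_a = FALSE, seed = 9)
  fe2 <- assemble_pseudopopulation(list(s1, s2), include = c("V", "A"),
                                   shifted_a = FALSE, seed = 9)
  expect_identical(fe1$x, fe2$x)
  expect_equal(ncol(fe1$x), 8 * 25)
  expect_equal(sort(unique(as.character(fe1$y))), c("A", "V"))
})

test_that("decoders separate disjoint patterns perfectly and deterministically", {
  # three classes with disjoint active bins: flawless classification
  withr::with_seed(20, {
    n_per <- 20
    mk <- function(active) {
      m <- matrix(rpois(n_per * 75, 0.05), n_per)
      m[, active] <- m[, active] + 5
      m
    }
    x <- rbind(mk(1:10), mk(31:40), mk(61:70))
    y <- factor(rep(c("AV_0", "AV_50", "AV_100"), each = n_per))
  })
  fe <- list(x = x, y = y)
  r1 <- train_and_score(fe, "svm", folds = 2, seed = 5)
  expect_equal(r1$av_delay_accuracy, 100)
  expect_equal(r1$cv_accuracy, 100)
  r2 <- train_and_score(fe, "svm", folds = 2, seed = 5)
  expect_identical(r1$confusion, r2$confusion)
  r3 <- train_and_score(fe, "rf", folds = 0, ntree = 100, seed = 5)
  expect_equal(r3$av_delay_accuracy, 100)
})

test_that("misclassification metrics follow their definitions", {
  lev <- c("AV_0", "AV_10", "A_SHIFT_10")
  cm <- table(truth = factor(c("AV_0", "AV_0", "AV_10", "AV_10"), lev),
              predicted = factor(c("AV_0", "A_SHIFT_10", "AV_0", "AV_10"),
                                 lev))
  res <- structure(list(confusion = cm), class = "decoding_result")
  expect_equal(misclassification_metrics(res, "rate_vs_shifted_A"), 25)
  lev2 <- c("AV_0", "AV_10", "AV_20")
  cm2 <- table(truth = factor(rep(c("AV_0", "AV_10", "AV_20"), each = 2),
                              lev2),
               predicted = factor(c("AV_10", "AV_10", "AV_20", "AV_20",
                                    "AV_0", "AV_0"), lev2))
  res2 <- structure(list(confusion = cm2), class = "decoding_result")
  # predicting delay+10 (and 20 -> 0): median |error|
  expect_equal(misclassification_metrics(res2, "error_ms"), 10)
  expect_error(misclassification_metrics(res2, "rate_vs_shifted_A"),
               "shifted")
  # uniform random predictions: expected error is the brute-force mean
  d <- seq(0, 100, 10)
  exp_err <- mean(abs(outer(d, d, "-")))
  cm3 <- table(truth = factor(rep(paste0("AV_", d), each = 11),
                              paste0("AV_", d)),
               predicted = factor(rep(paste0("AV_", d), times = 11),
                                  paste0("AV_", d)))
  res3 <- structure(list(confusion = cm3), class = "decoding_result")
  # median of the uniform |error| table (metric uses the median)
  expect_equal(misclassification_metrics(res3, "error_ms"),
               median(abs(outer(d, d, "-"))))
  expect_lt(abs(exp_err - mean(abs(outer(d, d, "-")))), 1e-12)
})

test_that("label shuffling drops accuracy to chance on separable data", {
  withr::with_seed(21, {
    n_per <- 12; k <- 5
    x <- do.call(rbind, lapply(1:k, function(i) {
      m <- matrix(rpois(n_per * 50, 0.1), n_per)
      m[, (i - 1) * 10 + 1:5] <- m[, (i - 1) * 10 + 1:5] + 4
      m
    }))
    y <- factor(rep(paste0("AV_", seq(0, 40, 10)), each = n_per))
  })
  fe <- list(x = x, y = y)
  accs <- vapply(1:6, function(sd)
    train_and_score(fe, "svm", folds = 0, shuffle_labels = TRUE,
                    seed = sd)$av_delay_accuracy, 0)
  n_test <- 6 * k * round(n_per * 0.2)
  hits <- sum(accs / 100 * k * round(n_per * 0.2))
  # pooled shuffled accuracy within the binomial 99% band around 1/k
  expect_gte(hits, qbinom(0.005, n_test, 1 / k))
  expect_lte(hits, qbinom(0.995, n_test, 1 / k))
})

test_that("anatomical_bins partitions neurons by median splits", {
  withr::with_seed(30, {
    neurons <- data.frame(neuron_id = paste0("n", 1:40),
                          ml_um = runif(40, 0, 1900),
                          ap_um = runif(40, -4700, -3100),
                          dv_um = runif(40, 0, 1900))
  })
  b4 <- anatomical_bins(neurons, c("ml", "ap"))
  expect_length(b4, 4)
  expect_equal(sort(unlist(b4, use.names = FALSE)),
               sort(neurons$neuron_id))
  b8 <- anatomical_bins(neurons, c("ml", "ap", "dv"))
  expect_length(b8, 8)
})
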