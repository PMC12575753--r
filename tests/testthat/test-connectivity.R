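# Jitter-corrected cross-correlograms and connection inference.

blank_net_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      conns <- data.frame(pre = c(1, 3), post = c(2, 4),
                          lag_ms = c(2, 4), efficacy = c(0.3, 0.25))
      cache <<- generate_session(synth_config(
        seed = 55, protocol = "blank", n_reps = 150, iti_ms = 2500,
        n_neurons = c(visual = 0, auditory = 0, bimodal = 0, gated = 0,
                      nonresponsive = 8),
        baseline_hz = 10, baseline_sdlog = 0.2, connections = conns))
    }
    cache
  }
})

bin_all <- function(s) lapply(s$spikes, ccg_bin_trials, s$events,
                              c(1000, 2000))

test_that("an exact 3 ms shift produces a +3 ms correlogram peak", {
  s <- blank_net_session()
  t1 <- s$spikes[[5]]$spike_times
  sh <- spike_train(t1 + 3, "shifted")
  b1 <- ccg_bin_trials(s$spikes[[5]], s$events, c(1000, 2000))
  b2 <- ccg_bin_trials(sh, s$events, c(1000, 2000))
  cc <- compute_ccg(b1, b2)
  expect_equal(cc$peak_lag_ms, 3)
  expect_gt(cc$z, 5)
})

test_that("independent trains give near-zero corrected CCG and rare z > 5", {
  s <- blank_net_session()
  bts <- bin_all(s)
  zs <- c()
  for (i in 5:7) for (j in (i + 1):8) {
    cc <- compute_ccg(bts[[i]], bts[[j]])
    expect_lt(abs(mean(cc$corrected)),
              3 * sd(cc$corrected) / sqrt(length(cc$corrected)) + 1e-12)
    zs <- c(zs, cc$z)
  }
  expect_lt(max(zs), 5)
})

test_that("raw CCG is invariant to reference relabelling up to reflection", {
  s <- blank_net_session()
  bts <- bin_all(s)
  cc12 <- compute_ccg(bts[[1]], bts[[2]])
  cc21 <- compute_ccg(bts[[2]], bts[[1]])
  expect_equal(cc12$raw, rev(cc21$raw), tolerance = 1e-12)
})

test_that("analytic jitter expectation matches Monte-Carlo resampling", {
  s <- blank_net_session()
  bts <- bin_all(s)
  cca <- compute_ccg(bts[[1]], bts[[2]], jitter = "analytic")
  ccr <- compute_ccg(bts[[1]], bts[[2]], jitter = "resample",
                     n_jitter = 200, seed = 7)
  # Monte-Carlo error of the mean over 200 resamples is small relative to
  # the jittered expectation's scale
  expect_lt(max(abs(cca$jittered - ccr$jittered)),
            0.1 * max(cca$jittered))
  expect_equal(cca$raw, ccr$raw)
})

test_that("planted connections are detected at the planted lag", {
  s <- blank_net_session()
  det <- detect_connections(bin_all(s))
  gt <- s$ground_truth$connections
  found <- merge(det$connections, gt, by = c("pre", "post"))
  expect_equal(nrow(found), 2)
  expect_true(all(abs(found$lag_ms.x - found$lag_ms.y) <= 1))
  expect_true(all(found$z > 5))
  # no spurious detections among the unconnected pairs
  expect_lte(nrow(det$connections), 3)
})

test_that("lag-0 peaks are recorded as shared input, not connections", {
  s <- blank_net_session()
  base <- s$spikes[[6]]$spike_times
  # two neurons driven by the same spikes at 0 lag (plus private noise)
  t_a <- sort(c(base, runif(500, 0, max(base))))
  t_b <- sort(c(base, runif(500, 0, max(base))))
  bts <- list(a = ccg_bin_trials(spike_train(t_a, "a"), s$events,
                                 c(1000, 2000)),
              b = ccg_bin_trials(spike_train(t_b, "b"), s$events,
                                 c(1000, 2000)))
  det <- detect_connections(bts)
  expect_equal(nrow(det$connections), 0)
  expect_equal(nrow(det$shared_input), 1)
})

test_that("ccg_inclusion follows the responsiveness/rate rule", {
  expect_true(ccg_inclusion(TRUE, 0.5))
  expect_true(ccg_inclusion(FALSE, 12))
  expect_false(ccg_inclusion(FALSE, 3))
  expect_equal(ccg_inclusion(c(TRUE, FALSE), c(1, 1)), c(TRUE, FALSE))
})

test_that("false_positive_rate needs distinct sessions and stays low on independent data", {
  mk <- function(seed) {
    s <- generate_session(synth_config(
      seed = seed, protocol = "blank", n_reps = 60, iti_ms = 2500,
      n_neurons = c(visual = 0, auditory = 0, bimodal = 0, gated = 0,
                    nonresponsive = 6),
      baseline_hz = 12, baseline_sdlog = 0.2))
    list(bin_trains = lapply(s$spikes, ccg_bin_trials, s$events,
                             c(1000, 2000)),
         dv_um = vapply(s$spikes, function(tr) tr$position[["dv"]], 0))
  }
  sessions <- list(s1 = mk(61), s2 = mk(62), s3 = mk(63))
  expect_error(false_positive_rate(sessions["s1"]), ">= 2")
  expect_error(false_positive_rate(sessions[c(1, 1)]), "distinct")
  fpr <- suppressWarnings(false_positive_rate(sessions, seed = 9))
  expect_lt(fpr$fpr_pct, 5)
  expect_gt(fpr$n_assessed, 0)
})

test_that("class_connectivity aggregates percentages and input budgets", {
  classes <- c(n1 = "V", n2 = "V", n3 = "A", n4 = "D")
  conns <- data.frame(pre = c("n1", "n2"), post = c("n2", "n3"),
                      lag_ms = c(2, 3), strength = c(0.4, 0.6),
                      z = c(6, 7), stringsAsFactors = FALSE)
  cc <- class_connectivity(conns, classes, c("V", "A", "D"))
  expect_equal(cc$counts["V", "V"], 1)
  expect_equal(cc$counts["V", "A"], 1)
  expect_equal(cc$assessed["V", "V"], 2) # ordered pairs within class
  expect_equal(cc$pct["V", "V"], 50)
  # all of V's incoming strength comes from V; same for A
  expect_equal(cc$input_budget_pct["V", "V"], 100)
  expect_equal(cc$input_budget_pct["V", "A"], 100)
  expect_true(is.na(cc$pct["D", "D"])) # one D neuron: no assessable pairs
})

test_that("trend statistic matches prop.trend.test and permutation p behaves", {
  x <- c(2, 4, 7, 11, 15); n <- rep(40, 5); s <- 1:5
  z <- avdelay:::.ca_trend_z(x, n, s)
  ref <- suppressWarnings(prop.trend.test(x, n, score = s))
  expect_equal(z^2, unname(ref$statistic), tolerance = 1e-12)
  withr::with_seed(77, {
    pairs <- data.frame(
      session = rep(c("s1", "s2"), each = 150),
      signal_corr = runif(300, -1, 1))
    # connection probability strictly increasing in signal correlation
    pairs$connected <- runif(300) < (0.05 + 0.4 * (pairs$signal_corr + 1) / 2)
    tr <- rf_similarity_trend(pairs, n_bins = 5, n_shuffle = 400, seed = 5)
    expect_lt(tr$p, 0.01)
    expect_gt(tr$statistic, 0)
    # flat probability: p not extreme
    pairs$connected <- runif(300) < 0.2
    tr0 <- rf_similarity_trend(pairs, n_bins = 5, n_shuffle = 400, seed = 6)
    expect_gt(tr0$p, 0.01)
  })
})
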