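# Responsiveness testing, taxonomy, peak rate and latency.

test_that("peak_firing_rate follows the centred-window rule", {
  r <- numeric(250); r[100] <- 100
  expect_equal(as.numeric(peak_firing_rate(r)), 5) # 100 Hz / 20 bins
  expect_equal(as.numeric(peak_firing_rate(rep(10, 250))), 10)
  z <- peak_firing_rate(numeric(250))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "silent"))
  # edge clipping and tie-breaks match the brute-force oracle
  withr::with_seed(5, {
    for (i in 1:20) {
      r <- round(runif(250, 0, 3), 1)
      if (i <= 5) r[3] <- 10 # argmax near the left edge
      expect_equal(as.numeric(peak_firing_rate(r)), brute_peak(r))
    }
  })
})

test_that("estimate_latency assigns onset/offset by the fixed windows", {
  mk <- function(peak_bin) {
    r <- numeric(250); r[peak_bin + 1] <- 50
    psth(0:250, r)
  }
  v <- estimate_latency(mk(69), "V")
  expect_equal(v$latency_ms, 69)
  expect_equal(v$phase, "onset")
  expect_equal(estimate_latency(mk(150), "V")$phase, "offset")
  a <- estimate_latency(mk(21), "A")
  expect_equal(a$latency_ms, 21)
  expect_equal(a$phase, "onset")
  expect_equal(estimate_latency(mk(80), "A")$phase, "offset")
  flat <- estimate_latency(psth(0:250, rep(3, 250)), "V")
  expect_true(flat$flat)
  expect_true(is.na(flat$latency_ms))
})

test_that("population latency medians recover the planted values", {
  s <- generate_session(synth_config(
    seed = 21, n_neurons = c(visual = 25, auditory = 25, bimodal = 0,
                             gated = 0, nonresponsive = 0),
    n_reps = 50, iti_ms = 2000, p_offset = 0))
  gt <- s$ground_truth$neurons
  lat <- vapply(s$spikes, function(tr) {
    cls <- gt$class[gt$neuron_id == tr$neuron_id]
    mod <- if (cls == "visual") "V" else "A"
    ps <- compute_psth(slice_trials(tr, select_trials(s$events, mod),
                                    c(0, 250)), 1, c(0, 250))
    estimate_latency(ps, mod)$latency_ms
  }, 0)
  v <- lat[gt$class == "visual"]; a <- lat[gt$class == "auditory"]
  expect_lt(abs(median(v) - median(gt$lat_v[gt$class == "visual"])), 10)
  expect_lt(abs(median(a) - median(gt$lat_a[gt$class == "auditory"])), 6)
  expect_gt(median(v) - median(a), 20) # visual onset clearly later
})

test_that("test_responsiveness detects strong responses and is deterministic", {
  # 40 Hz evoked over a 5 Hz baseline at 50 reps: p at the permutation floor
  s <- generate_session(synth_config(
    seed = 31, n_neurons = c(visual = 2, auditory = 0, bimodal = 0,
                             gated = 0, nonresponsive = 1),
    amp_hz = 40, amp_sdlog = 0, baseline_hz = 5, baseline_sdlog = 0,
    n_reps = 50, iti_ms = 2000))
  vis <- s$spikes[[1]]
  p1 <- test_responsiveness(vis, s$events, "V", n_perm = 1000, seed = 4)
  expect_lt(as.numeric(p1), 0.005)
  p2 <- test_responsiveness(vis, s$events, "V", n_perm = 1000, seed = 4)
  expect_identical(as.numeric(p1), as.numeric(p2))
  nr <- s$spikes[["n003"]]
  p3 <- test_responsiveness(nr, s$events, "V", n_perm = 1000, seed = 4)
  expect_gt(as.numeric(p3), 0.01)
  ev_noblank <- s$events[s$events$modality != "BLANK", ]
  expect_error(test_responsiveness(vis, ev_noblank, "V"), "control")
})

test_that("classify_neuron implements the taxonomy truth table", {
  expect_equal(classify_neuron(0.001, 0.8, rep(0.5, 11))$label, "visual")
  expect_equal(classify_neuron(0.9, 0.001, rep(0.5, 11))$label, "auditory")
  expect_equal(classify_neuron(0.001, 0.002, NULL)$label, "bimodal")
  expect_equal(classify_neuron(0.8, 0.9, c(rep(0.9, 10), 1e-5))$label,
               "gated")
  expect_equal(classify_neuron(0.8, 0.9, rep(0.9, 11))$label,
               "nonresponsive")
  # BH correction can demote a borderline unisensory p
  cl <- classify_neuron(0.04, 0.9, rep(0.9, 11))
  expect_equal(cl$label, "nonresponsive")
})

test_that("high-SNR planted neurons recover their class", {
  s <- generate_session(synth_config(
    seed = 22, n_neurons = c(visual = 6, auditory = 6, bimodal = 6,
                             gated = 3, nonresponsive = 4),
    amp_hz = 40, baseline_hz = 5, baseline_sdlog = 0.2, amp_sdlog = 0.1,
    n_reps = 50, iti_ms = 2000))
  cls <- characterise_session(s, n_perm = 1000, seed = 5)
  gt <- s$ground_truth$neurons
  gt <- gt[match(cls$neuron_id, gt$neuron_id), ]
  # restrict to high-SNR responsive neurons: every planted kernel at least
  # 4x the baseline rate
  amp_min <- with(gt, ifelse(class == "visual", amp_v,
                      ifelse(class == "auditory", amp_a,
                      ifelse(class == "bimodal", pmin(amp_v, amp_a),
                      ifelse(class == "gated", gain, NA)))))
  hi <- !is.na(amp_min) & amp_min >= 4 * gt$baseline_hz
  hit <- cls$label[hi] == gt$class[hi]
  expect_gte(mean(hit), 0.9)
  # taxonomy is a partition
  expect_true(all(cls$label %in% c("visual", "auditory", "bimodal",
                                   "gated", "nonresponsive")))
})

test_that("responsiveness test holds its type-I rate on null neurons", {
  # condition trials exchangeable with blanks: rejection ~ alpha
  s <- generate_session(synth_config(
    seed = 23, n_neurons = c(visual = 0, auditory = 0, bimodal = 0,
                             gated = 0, nonresponsive = 60),
    n_reps = 20, iti_ms = 2000))
  p <- suppressWarnings(vapply(s$spikes, function(tr)
    as.numeric(test_responsiveness(tr, s$events, "V", n_perm = 400,
                                   seed = child_seed(3, tr$neuron_id))), 0))
  rej <- mean(p <= 0.05)
  # binomial 99% band around 0.05 at n = 60
  expect_lte(rej, qbinom(0.995, 60, 0.05) / 60)
  expect_warning(
    test_responsiveness(s$spikes[[1]], s$events, "V", n_perm = 400,
                        seed = 1), "coarse")
})
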