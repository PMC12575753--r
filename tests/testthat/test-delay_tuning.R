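# Delay-selectivity indices, linear-sum prediction and MII.

test_that("specificity and modulation indices match their definitions", {
  expect_equal(specificity_index(11, 11), 0)
  expect_equal(specificity_index(1, 11), 1 - 1 / 11)
  expect_equal(specificity_index(0, 11), 1)
  expect_error(specificity_index(12, 11), "between")
  expect_error(specificity_index(1, 0), "positive")

  expect_equal(fr_modulation_index(10, 10), 0)
  expect_equal(fr_modulation_index(15, 5), 0.5)
  expect_equal(fr_modulation_index(7, 0), 1)
  expect_true(is.na(fr_modulation_index(0, 0)))
  expect_error(fr_modulation_index(3, 5), "av_max")
})

test_that("preferred_delay uses significant-above flags with earliest ties", {
  d <- seq(0, 100, 10)
  flags <- rep(FALSE, 11); flags[6] <- TRUE
  expect_equal(preferred_delay(d, flags, rnorm(11, 10)), 50)
  flags <- rep(FALSE, 11); flags[c(4, 8)] <- TRUE
  pk <- numeric(11); pk[4] <- 12; pk[8] <- 15
  expect_equal(preferred_delay(d, flags, pk), 70)
  pk[4] <- 15
  expect_equal(preferred_delay(d, flags, pk), 30) # tie -> smallest delay
  expect_true(is.na(preferred_delay(d, rep(FALSE, 11), pk)))
})

test_that("reliability_index equals the brute-force pairwise mean", {
  m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(as.numeric(reliability_index(m)), 1)
  m2 <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(as.numeric(reliability_index(m2)), -1)
  withr::with_seed(8, {
    m3 <- matrix(rpois(3 * 25, 2), nrow = 3)
    want <- mean(c(cor(m3[1, ], m3[2, ]), cor(m3[1, ], m3[3, ]),
                   cor(m3[2, ], m3[3, ])))
    expect_equal(as.numeric(reliability_index(m3)), want)
  })
  # zero-variance repetitions contribute r = 0
  m4 <- rbind(c(1, 2, 3), c(0, 0, 0), c(1, 2, 3))
  ri <- reliability_index(m4)
  expect_equal(as.numeric(ri), 1 / 3)
  expect_equal(attr(ri, "n_zero_var"), 2)
  expect_error(reliability_index(m4[1, , drop = FALSE]), ">= 2")
})

test_that("chance reliability sits at zero for stationary spontaneous spiking", {
  s <- small_session()
  gt <- s$ground_truth$neurons
  ids <- gt$neuron_id[gt$baseline_hz > 4]
  ri <- vapply(ids[1:4], function(id)
    as.numeric(chance_reliability(s$spikes[[id]], s$events, n_reps = 40,
                                  seed = child_seed(9, id))), 0)
  expect_lt(abs(median(ri)), 0.05)
})

test_that("linear_sum_response shifts, subtracts baseline and matches brute force", {
  edges <- seq(-200, 350)
  t <- edges[-length(edges)] + 0.5
  a_rate <- 4 + 30 * exp(-((t - 21.5)^2) / 50)
  v_rate <- 6 + 40 * exp(-((t - 69.5)^2) / 200)
  base_a <- mean(a_rate[t < 0]) # empirical baseline, as the estimator uses
  pa <- psth(edges, a_rate); pv <- psth(edges, v_rate)
  # flat A at baseline: sum equals V
  pa_flat <- psth(edges, rep(4, length(t)))
  expect_equal(linear_sum_response(pv, pa_flat, 0)$rate_hz, pv$rate_hz)
  # d = 100 moves the 21 ms auditory peak to 121 ms
  out <- linear_sum_response(pv, pa, 100)
  aud_part <- out$rate_hz - pv$rate_hz
  expect_equal(t[which.max(aud_part)], 121.5)
  # brute-force elementwise construction
  brute <- vapply(seq_along(t), function(i) {
    ta <- t[i] - 100
    av <- if (ta >= min(t) && ta <= max(t))
      a_rate[which.min(abs(t - ta))] else base_a
    v_rate[i] + av - base_a
  }, 0)
  expect_equal(out$rate_hz, pmax(brute, 0))
  expect_error(linear_sum_response(pv, pa, 2.5), "multiple")
})

test_that("predicted_preferred_delay maximises the summed peak", {
  edges <- seq(-200, 350)
  t <- edges[-length(edges)] + 0.5
  pv <- psth(edges, 5 + 40 * exp(-((t - 69)^2) / 72))
  pa <- psth(edges, 5 + 40 * exp(-((t - 21)^2) / 72))
  d <- seq(0, 100, 10)
  # brute-force scan oracle
  peaks <- vapply(d, function(dd) {
    r <- linear_sum_response(pv, pa, dd)$rate_hz
    brute_peak(r[t >= 0 & t < 250])
  }, 0)
  expect_equal(predicted_preferred_delay(pv, pa, d), d[which.max(peaks)])
  # identical kernels: overlap maximal when the auditory peak lands on 69 ms
  expect_equal(predicted_preferred_delay(pv, pa, d), 50)
  flat <- psth(edges, rep(5, length(t)))
  expect_true(is.na(predicted_preferred_delay(pv, flat, d)))
})

test_that("mii value and classes follow the strict +/-0.5 rule", {
  expect_equal(mii(20, 20), list(mii = 0, class = "linear"))
  m <- mii(30, 20)
  expect_equal(m$mii, 0.5)
  expect_equal(m$class, "linear") # boundary is strict
  expect_equal(mii(30.2, 20)$class, "supralinear")
  expect_equal(mii(0, 20), list(mii = -1, class = "sublinear"))
  expect_true(is.na(mii(10, 0)$mii))
})

test_that("delay significance test is deterministic and flags strong delays", {
  s <- generate_session(synth_config(
    seed = 33, n_neurons = c(visual = 1, auditory = 0, bimodal = 0,
                             gated = 1, nonresponsive = 0),
    gated_amp_hz = 40, baseline_hz = 5, baseline_sdlog = 0,
    n_reps = 50, iti_ms = 2000))
  gt <- s$ground_truth$neurons
  id <- gt$neuron_id[gt$class == "gated"][1] # responds only to AV
  tr <- s$spikes[[id]]
  d_star <- gt$d_star[gt$neuron_id == id]
  m_av <- trial_count_matrix(slice_trials(
    tr, select_trials(s$events, "AV", d_star), c(0, 250)), 1, c(0, 250))
  m_v <- trial_count_matrix(slice_trials(
    tr, select_trials(s$events, "V"), c(0, 250)), 1, c(0, 250))
  r1 <- delay_significance_test(m_av, m_v, n_boot = 1000, seed = 3)
  r2 <- delay_significance_test(m_av, m_v, n_boot = 1000, seed = 3)
  expect_true(r1$significant)
  expect_true(r1$above)
  expect_identical(r1$observed, r2$observed)
  expect_identical(r1$significant, r2$significant)
  expect_error(delay_significance_test(m_av[1:5, ], m_v), ">= 10")
})

test_that("delay_tuning returns a coherent per-neuron table", {
  s <- small_session()
  gt <- s$ground_truth$neurons
  ids <- gt$neuron_id[gt$class %in% c("bimodal", "gated")]
  dt <- delay_tuning(s, neuron_ids = ids, n_boot = 500, seed = 6)
  expect_equal(nrow(dt), length(ids))
  expect_true(all(dt$si >= 0 & dt$si <= 1))
  expect_true(all(dt$fr_modulation >= 0 & dt$fr_modulation <= 1,
                  na.rm = TRUE))
  pd <- attr(dt, "per_delay")
  expect_equal(nrow(pd), length(ids) * 11)
  expect_true(all(pd$mii >= -1, na.rm = TRUE))
  # preferred delay, when defined, is among the selective set
  for (i in seq_len(nrow(dt))) {
    if (!is.na(dt$preferred_delay_ms[i])) {
      sel <- pd$selective[pd$neuron_id == dt$neuron_id[i]]
      expect_true(sel[match(dt$preferred_delay_ms[i], seq(0, 100, 10))])
    }
  }
})

test_that("estimated MII agrees with the planted-kernel expectation", {
  s <- generate_session(synth_config(
    seed = 16, n_neurons = c(visual = 0, auditory = 0, bimodal = 40,
                             gated = 0, nonresponsive = 0),
    amp_hz = 25, amp_sdlog = 0, baseline_hz = 5, baseline_sdlog = 0,
    sigma_d = 15, n_reps = 50, iti_ms = 2000))
  gt <- s$ground_truth$neurons
  dev <- vapply(seq_len(nrow(gt)), function(i) {
    id <- gt$neuron_id[i]
    mii_from_psths(s$spikes[[id]], s$events, gt$d_star[i])$mii -
      expected_mii(s, id, gt$d_star[i])
  }, 0)
  expect_lt(abs(median(dev)), 0.15)
})

test_that("chance reliability is centred on zero across neurons", {
  s <- generate_session(synth_config(
    seed = 18, n_neurons = c(visual = 4, auditory = 4, bimodal = 4,
                             gated = 0, nonresponsive = 0),
    n_reps = 30, iti_ms = 2500, baseline_sdlog = 0.3))
  ri <- vapply(s$spikes, function(tr)
    as.numeric(chance_reliability(tr, s$events, n_reps = 30,
                                  seed = child_seed(4, tr$neuron_id))), 0)
  expect_lt(abs(median(ri)), 0.01)
})
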