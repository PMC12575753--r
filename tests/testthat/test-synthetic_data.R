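# Generator: determinism, protocol structure, Poisson statistics, MII
# oracle, connection efficacy.

test_that("identical seeds give identical sessions", {
  cfg <- synth_config(seed = 7, n_neurons = c(visual = 2, auditory = 2,
                                              bimodal = 2, gated = 1,
                                              nonresponsive = 1),
                      n_reps = 5, iti_ms = 2000)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(lapply(s1$spikes, `[[`, "spike_times"),
                   lapply(s2$spikes, `[[`, "spike_times"))
  expect_identical(as.data.frame(s1$events), as.data.frame(s2$events))
  s3 <- generate_session(synth_config(seed = 8, n_neurons = cfg$n_neurons,
                                      n_reps = 5, iti_ms = 2000))
  expect_false(identical(lapply(s1$spikes, `[[`, "spike_times"),
                         lapply(s3$spikes, `[[`, "spike_times")))
})

test_that("delay protocol emits 11 AV conditions plus V, A and blank", {
  s <- small_session()
  key <- condition_key(s$events)
  reps <- table(key)
  expect_true(all(reps == s$config$n_reps))
  av <- grep("^AV_", names(reps), value = TRUE)
  expect_length(av, 11)
  expect_setequal(as.integer(sub("AV_", "", av)), seq(0, 100, 10))
  expect_setequal(setdiff(names(reps), av), c("V", "A", "BLANK"))
})

test_that("rf protocol emits 35 locations x modalities at 25 reps", {
  s <- generate_session(synth_config(
    seed = 9, protocol = "rf", iti_ms = 2000,
    n_neurons = c(visual = 1, auditory = 1, bimodal = 1, gated = 0,
                  nonresponsive = 0)))
  ev <- s$events
  locs <- unique(paste(ev$azimuth_deg, ev$elevation_deg))
  expect_length(locs, 35)
  reps <- table(condition_key(ev))
  expect_true(all(reps == 25))
  expect_length(reps, 35 * 3)
})

test_that("auditory-leading protocol uses negative delays at 25 ms steps", {
  s <- generate_session(synth_config(
    seed = 10, protocol = "auditory_leading", n_reps = 3, iti_ms = 2000,
    n_neurons = c(visual = 1, auditory = 0, bimodal = 1, gated = 0,
                  nonresponsive = 0)))
  d <- sort(unique(s$events$av_delay_ms[!is.na(s$events$av_delay_ms)]))
  expect_equal(d, seq(-100, 0, 25))
})

test_that("baseline spike counts follow the Poisson oracle", {
  # 10 Hz baseline, blanks only, 100 s: count within 3 SD of 1000
  s <- generate_session(synth_config(
    seed = 11, protocol = "blank", n_reps = 50, iti_ms = 2000,
    n_neurons = c(visual = 0, auditory = 0, bimodal = 0, gated = 0,
                  nonresponsive = 1),
    baseline_hz = 10, baseline_sdlog = 0))
  n <- n_spikes(s$spikes[[1]])
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
})

test_that("expected_mii matches construction and brute-force evaluation", {
  s <- small_session()
  gt <- s$ground_truth$neurons
  bi <- gt[gt$class == "bimodal", ]
  for (i in seq_len(nrow(bi))) {
    # at d*, the solved gain reproduces the target MII by construction
    expect_equal(expected_mii(s, bi$neuron_id[i], bi$d_star[i]),
                 bi$target_mii[i], tolerance = 1e-3)
  }
  # arbitrary delay: matches a brute-force evaluation on noiseless rates
  np <- as.list(bi[1, ])
  cfg <- s$config
  edges <- seq(-200, 400); tt <- edges[-length(edges)] + 0.5
  rate_of <- function(mod, d) np$baseline_hz +
    avdelay:::.evoked_rate(np, cfg, mod, d, tt, expected = TRUE)
  d <- 30
  p_av <- psth(edges, rate_of("AV", d))
  p_v <- psth(edges, rate_of("V", NA))
  p_a <- psth(edges, rate_of("A", NA))
  keep <- function(p) p$rate_hz[tt >= 0 & tt < 250]
  av_peak <- brute_peak(keep(p_av))
  sum_peak <- brute_peak(keep(linear_sum_response(p_v, p_a, d)))
  expect_equal(expected_mii(s, np$neuron_id, d),
               (av_peak - sum_peak) / sum_peak, tolerance = 1e-9)
  # gated neurons are excluded
  gid <- gt$neuron_id[gt$class == "gated"][1]
  expect_error(expected_mii(s, gid, 50), "gated")
})

test_that("zero gain yields empirical MII centred on zero", {
  s <- generate_session(synth_config(
    seed = 12, n_neurons = c(visual = 0, auditory = 0, bimodal = 30,
                             gated = 0, nonresponsive = 0),
    target_mii = 0, n_reps = 50, iti_ms = 2000))
  mii_d50 <- vapply(s$spikes, function(tr)
    mii_from_psths(tr, s$events, 50)$mii, 0)
  expect_lt(abs(median(mii_d50)), 0.1)
})

test_that("planted connection transmission probability approaches efficacy", {
  conns <- data.frame(pre = 1, post = 2, lag_ms = 3, efficacy = 0.25)
  s <- generate_session(synth_config(
    seed = 13, protocol = "blank", n_reps = 100, iti_ms = 2000,
    n_neurons = c(visual = 0, auditory = 0, bimodal = 0, gated = 0,
                  nonresponsive = 2),
    baseline_hz = 8, baseline_sdlog = 0, connections = conns))
  pre <- s$spikes[[1]]$spike_times
  post <- s$spikes[[2]]$spike_times
  hits <- sum((pre + 3) %in% post)
  phat <- hits / length(pre)
  # binomial tolerance around efficacy (duplicate-bin collapse and chance
  # coincidences shift it slightly; 4 sigma band)
  expect_lt(abs(phat - 0.25), 4 * sqrt(0.25 * 0.75 / length(pre)) + 0.02)
})

test_that("excessive rates are rejected", {
  expect_error(generate_session(synth_config(
    seed = 1, n_neurons = c(visual = 1, auditory = 0, bimodal = 0,
                            gated = 0, nonresponsive = 0),
    baseline_hz = 900, baseline_sdlog = 0, amp_hz = 500, amp_sdlog = 0,
    n_reps = 2, iti_ms = 2000)), "Bernoulli")
})
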