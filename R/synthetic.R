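# Synthetic session generator: inhomogeneous Bernoulli spike trains (1 ms
# resolution) with known ground truth for latencies, response classes, delay
# tuning, multisensory nonlinearity and pairwise connectivity.
#
# The generative model per neuron and 1 ms bin t is
#   p(t) = [ baseline * env(t)
#            + V-kernel(t)                          (visual shown)
#            + A-kernel(t - aud_onset)              (auditory shown)
#            + g * w(d - d*) * bump(t - aud_onset - lat_a)  (AV, bimodal/gated)
#          ] / 1000, clipped to [0, 1],
# after which each presynaptic spike of a planted connection adds an extra
# postsynaptic spike at lag `lag_ms` with probability `efficacy`.

.default_delays <- seq(0L, 100L, by = 10L)

#' Configuration for the synthetic session generator
#'
#' Defaults emulate the visual-leading delay protocol: 100 ms stimuli, AV
#' delays 0--100 ms in 10 ms steps plus unisensory visual, unisensory
#' auditory and blank conditions, 50 repetitions in randomised blocks.
#' `protocol = "rf"` gives the receptive-field grid (5 elevations x 7
#' azimuths at 18 deg steps, 25 repetitions per modality);
#' `protocol = "auditory_leading"` uses negative delays at 25 ms steps;
#' `protocol = "blank"` emits only blank trials (spontaneous activity, e.g.
#' for correlogram work).
#'
#' Latency medians (visual 69 ms, auditory 21 ms) match the reported
#' population medians; per-neuron latencies are drawn lognormally around them
#' (a modelling choice -- the full distributions are not specified by the
#' protocol) and clipped to the onset windows.
#'
#' @param seed Integer seed; fully determines the generated session.
#' @param n_neurons Named counts per planted class:
#'   `visual`, `auditory`, `bimodal`, `gated`, `nonresponsive`.  The default
#'   proportions (16 / 14 / 10 / 16 / 44 per 100) follow the reported
#'   population taxonomy.
#' @param protocol `"delay"`, `"auditory_leading"`, `"rf"` or `"blank"`.
#' @param n_reps Repetitions per condition (50 delay / 25 RF protocol).
#' @param iti_ms Inter-onset interval in ms (>= 2000 by default so the 1--2 s
#'   post-onset correlogram window never overlaps the next trial; the
#'   protocol itself does not fix it).
#' @param delays_ms AV delays tested (visual-leading, ms).
#' @param baseline_hz Median of the lognormal baseline-rate distribution.
#' @param baseline_sdlog Lognormal sdlog of baseline rates.
#' @param amp_hz Median evoked kernel amplitude (Hz) for responsive kernels.
#' @param amp_sdlog Lognormal sdlog of amplitudes.
#' @param lat_v_ms,lat_a_ms Median onset latencies (ms).
#' @param lat_sdlog_v,lat_sdlog_a Lognormal latency jitter across neurons.
#' @param kernel_sd_v,kernel_sd_a Gaussian kernel widths (ms).
#' @param trial_jitter_sd_v,trial_jitter_sd_a SD (ms) of the per-trial
#'   latency jitter of the visual and auditory/interaction pathways (single
#'   trials of real evoked responses do not repeat at fixed latency).
#' @param p_offset Probability that a visual neuron also has an offset
#'   response component (bump in the 129--250 ms window).
#' @param target_mii Target multisensory interaction index at the preferred
#'   delay for bimodal neurons: a single number, or a function drawing one
#'   value per neuron from `function(n)`.  The interaction gain `g` is solved
#'   per neuron so the noiseless MII at `d*` equals the target.
#' @param sigma_d Width (ms) of the Gaussian delay-tuning bump `w`.
#' @param gated_amp_hz Amplitude of the purely multisensory kernel of gated
#'   neurons: `NULL` (default) draws from the same lognormal evoked-amplitude
#'   distribution as the other classes; a number fixes it (0 silences gated
#'   neurons, the no-gain control).
#' @param d_star Preferred delays: `NULL` draws uniformly from `delays_ms`
#'   per multisensory neuron, or a vector recycled over those neurons.
#' @param connections `NULL`, or a data.frame `pre, post, lag_ms, efficacy`
#'   (neuron indices; `lag_ms` in 1--5; `efficacy` in \[0, 1\]).
#' @param envelope `NULL`, or `list(neurons =, sd_frac =, timescale_ms =)`:
#'   a common slow multiplicative rate envelope shared by the listed neuron
#'   indices (AR(1) on a 10 ms grid with the given correlation time),
#'   `rate -> rate * max(0, 1 + sd_frac * s(t))`.
#' @param rf_sigma_deg Receptive-field width used in the RF protocol.
#' @param rf_align_sd_deg Jitter between a neuron's visual and auditory RF
#'   centres (deg).
#' @param stim_duration_ms Stimulus duration (ms).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_neurons = c(visual = 16, auditory = 14,
                                       bimodal = 10, gated = 16,
                                       nonresponsive = 44),
                         protocol = c("delay", "auditory_leading", "rf",
                                      "blank"),
                         n_reps = NULL, iti_ms = 3000,
                         delays_ms = .default_delays,
                         baseline_hz = 5, baseline_sdlog = 0.5,
                         amp_hz = 25, amp_sdlog = 0.3,
                         lat_v_ms = 69, lat_a_ms = 21,
                         lat_sdlog_v = 0.25, lat_sdlog_a = 0.35,
                         kernel_sd_v = 12, kernel_sd_a = 6,
                         trial_jitter_sd_v = 5, trial_jitter_sd_a = 5,
                         p_offset = 0.3,
                         target_mii = 0.33, sigma_d = 15,
                         gated_amp_hz = NULL,
                         d_star = NULL, connections = NULL, envelope = NULL,
                         rf_sigma_deg = 20, rf_align_sd_deg = 5,
                         stim_duration_ms = 100) {
  protocol <- match.arg(protocol)
  if (protocol == "auditory_leading") delays_ms <- seq(0L, -100L, by = -25L)
  if (is.null(n_reps)) n_reps <- if (protocol == "rf") 25L else 50L
  if (!is.null(connections)) {
    stopifnot(all(c("pre", "post", "lag_ms", "efficacy") %in%
                    names(connections)),
              all(connections$lag_ms >= 1 & connections$lag_ms <= 5),
              all(connections$efficacy >= 0 & connections$efficacy <= 1))
  }
  structure(list(seed = as.integer(seed), n_neurons = n_neurons,
                 protocol = protocol, n_reps = as.integer(n_reps),
                 iti_ms = iti_ms, delays_ms = as.integer(delays_ms),
                 baseline_hz = baseline_hz, baseline_sdlog = baseline_sdlog,
                 amp_hz = amp_hz, amp_sdlog = amp_sdlog,
                 lat_v_ms = lat_v_ms, lat_a_ms = lat_a_ms,
                 lat_sdlog_v = lat_sdlog_v, lat_sdlog_a = lat_sdlog_a,
                 kernel_sd_v = kernel_sd_v, kernel_sd_a = kernel_sd_a,
                 trial_jitter_sd_v = trial_jitter_sd_v,
                 trial_jitter_sd_a = trial_jitter_sd_a,
                 p_offset = p_offset, target_mii = target_mii,
                 sigma_d = sigma_d, gated_amp_hz = gated_amp_hz,
                 d_star = d_star, connections = connections,
                 envelope = envelope, rf_sigma_deg = rf_sigma_deg,
                 rf_align_sd_deg = rf_align_sd_deg,
                 stim_duration_ms = stim_duration_ms),
            class = "synth_config")
}

# Evoked window length (ms past trial onset) covered by per-condition
# inhomogeneous generation; everything outside is baseline.
.EVOKED_LEN <- 400L

# --- event-table construction -----------------------------------------------

.build_events <- function(config) {
  if (config$protocol == "blank") {
    n <- config$n_reps
    return(event_table(trial = seq_len(n), modality = rep("BLANK", n),
                       onset_ms = 1000 + config$iti_ms * (seq_len(n) - 1),
                       min_iti_ms = min(2000, config$iti_ms)))
  }
  if (config$protocol == "rf") {
    az <- seq(-162, by = 18, length.out = 7)
    el <- seq(-36, 36, by = 18)
    grid <- expand.grid(az = az, el = el)
    cond <- data.frame(modality = rep(c("V", "A", "AV"), each = nrow(grid)),
                       av_delay_ms = rep(c(NA, NA, 0L), each = nrow(grid)),
                       azimuth_deg = rep(grid$az, 3),
                       elevation_deg = rep(grid$el, 3))
  } else {
    cond <- data.frame(modality = c("V", "A", rep("AV",
                                                  length(config$delays_ms)),
                                    "BLANK"),
                       av_delay_ms = c(NA, NA, config$delays_ms, NA),
                       azimuth_deg = NA_real_, elevation_deg = NA_real_)
  }
  # randomised block design: each repetition block presents every condition
  # once in a fresh random order
  ord <- unlist(lapply(seq_len(config$n_reps),
                       function(b) sample.int(nrow(cond))))
  rows <- cond[ord, , drop = FALSE]
  n <- nrow(rows)
  event_table(trial = seq_len(n), modality = rows$modality,
              onset_ms = 1000 + config$iti_ms * (seq_len(n) - 1),
              duration_ms = config$stim_duration_ms,
              av_delay_ms = rows$av_delay_ms,
              azimuth_deg = rows$azimuth_deg,
              elevation_deg = rows$elevation_deg,
              min_iti_ms = min(2000, config$iti_ms))
}

# --- neuron parameter table --------------------------------------------------

.draw_neuron_params <- function(config) {
  nn <- config$n_neurons
  classes <- rep(names(nn), nn)
  n <- length(classes)
  ids <- sprintf("n%03d", seq_len(n))
  base <- config$baseline_hz *
    exp(rnorm(n, 0, config$baseline_sdlog))
  amp <- config$amp_hz * exp(rnorm(n, 0, config$amp_sdlog))
  amp_v <- ifelse(classes %in% c("visual", "bimodal"), amp, 0)
  amp_a <- ifelse(classes %in% c("auditory", "bimodal"),
                  config$amp_hz * exp(rnorm(n, 0, config$amp_sdlog)), 0)
  lat_v <- pmin(pmax(config$lat_v_ms * exp(rnorm(n, 0, config$lat_sdlog_v)),
                     30), 125)
  lat_a <- pmin(pmax(config$lat_a_ms * exp(rnorm(n, 0, config$lat_sdlog_a)),
                     8), 74)
  has_offset <- classes %in% c("visual", "bimodal") &
    runif(n) < config$p_offset
  offset_lat <- pmin(pmax(160 * exp(rnorm(n, 0, 0.15)), 135), 240)
  multi <- classes %in% c("bimodal", "gated")
  d_star <- rep(NA_integer_, n)
  if (any(multi)) {
    d_star[multi] <- if (is.null(config$d_star))
      sample(config$delays_ms, sum(multi), replace = TRUE)
    else rep_len(as.integer(config$d_star), sum(multi))
  }
  int_lat <- runif(n, 10, 100) # interaction latency past auditory onset
  tm <- config$target_mii
  target <- rep(NA_real_, n)
  target[classes == "bimodal"] <- if (is.function(tm))
    tm(sum(classes == "bimodal")) else tm
  pos <- cbind(ml = runif(n, 200, 1800), ap = runif(n, -4600, -3200),
               dv = runif(n, 50, 1900))
  rf_az <- runif(n, -150, -66)
  rf_el <- runif(n, -20, 20)
  data.frame(neuron_id = ids, class = classes, baseline_hz = base,
             amp_v = amp_v, amp_a = amp_a, lat_v = lat_v, lat_a = lat_a,
             has_offset = has_offset, offset_lat = offset_lat,
             d_star = d_star, target_mii = target, gain = NA_real_,
             sigma_d = config$sigma_d, int_lat = int_lat,
             ml_um = pos[, "ml"], ap_um = pos[, "ap"], dv_um = pos[, "dv"],
             rf_az_v = rf_az, rf_el_v = rf_el,
             rf_az_a = rf_az + rnorm(n, 0, config$rf_align_sd_deg),
             rf_el_a = rf_el + rnorm(n, 0, config$rf_align_sd_deg),
             stringsAsFactors = FALSE)
}

# --- noiseless rate profiles -------------------------------------------------

.gauss_bump <- function(t, mu, sdv) exp(-((t - mu)^2) / (2 * sdv^2))

# Noiseless evoked-rate components (Hz) of one neuron for one condition, on
# an arbitrary ms grid relative to trial onset (= first stimulus onset).
# Returned separately (visual, auditory, interaction) so per-trial latency
# jitter can shift each pathway independently; `spatial_w` scales the evoked
# kernels (RF protocol); baseline not included.
# discrete jitter kernel matching round(rnorm(., 0, sd)) trial shifts
.jitter_kernel <- function(sd) {
  if (sd <= 0) return(1)
  j <- -ceiling(4 * sd):ceiling(4 * sd)
  k <- pnorm(j + 0.5, 0, sd) - pnorm(j - 0.5, 0, sd)
  k / sum(k)
}

# same-length convolution on a 1 ms grid (zero-padded edges)
.conv_same <- function(x, k) {
  if (length(k) == 1L) return(x)
  h <- (length(k) - 1L) %/% 2L
  y <- stats::convolve(c(numeric(h), x, numeric(h)), rev(k),
                       type = "filter")
  y
}

.evoked_components <- function(np, config, modality, delay = NA, t,
                               spatial_w_v = 1, spatial_w_a = 1,
                               expected = FALSE) {
  z <- numeric(length(t))
  v <- z; a <- z; inter <- z
  d <- if (is.na(delay)) 0 else delay
  vis_on <- max(-d, 0) # auditory-leading: visual starts late
  aud_on <- max(d, 0)
  if (modality %in% c("V", "AV") && np$amp_v > 0) {
    v <- spatial_w_v * np$amp_v *
      .gauss_bump(t, vis_on + np$lat_v, config$kernel_sd_v)
    if (np$has_offset)
      v <- v + spatial_w_v * 0.6 * np$amp_v *
        .gauss_bump(t, vis_on + np$offset_lat, config$kernel_sd_v)
  }
  if (modality %in% c("A", "AV") && np$amp_a > 0)
    a <- spatial_w_a * np$amp_a *
      .gauss_bump(t, aud_on + np$lat_a, config$kernel_sd_a)
  if (modality == "AV" && np$class %in% c("bimodal", "gated") &&
      !is.na(np$gain) && np$gain != 0) {
    # interaction component: locked to the onset of the completing
    # (auditory) stimulus with a neuron-specific interaction latency,
    # amplitude tuned to the AV delay
    w <- .gauss_bump(d, np$d_star, np$sigma_d)
    inter <- np$gain * w * .gauss_bump(t, aud_on + np$int_lat, 10)
  }
  if (expected) {
    # expectation of the trial-mean PSTH: each pathway smeared by its
    # per-trial latency-jitter distribution
    v <- .conv_same(v, .jitter_kernel(config$trial_jitter_sd_v))
    ka <- .jitter_kernel(config$trial_jitter_sd_a)
    a <- .conv_same(a, ka)
    inter <- .conv_same(inter, ka)
  }
  list(v = v, a = a, inter = inter)
}

.evoked_rate <- function(np, config, modality, delay = NA, t,
                         spatial_w_v = 1, spatial_w_a = 1,
                         expected = FALSE) {
  cmp <- .evoked_components(np, config, modality, delay, t, spatial_w_v,
                            spatial_w_a, expected = expected)
  pmax(cmp$v + cmp$a + cmp$inter, 0)
}

# integer circular-free shift of a rate vector (pads with zeros)
.shift_vec <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  out <- numeric(n)
  if (k > 0L) out[(k + 1L):n] <- x[1L:(n - k)]
  else out[1L:(n + k)] <- x[(1L - k):n]
  out
}

# Expected trial-mean PSTH (baseline included, per-trial latency jitter
# smeared in) over grid [-200, 400) at 1 ms, as used by the MII estimator
# conventions.
.noiseless_psth <- function(np, config, modality, delay = NA) {
  edges <- seq(-200, .EVOKED_LEN)
  t <- edges[-length(edges)] + 0.5
  rate <- np$baseline_hz +
    .evoked_rate(np, config, modality, delay, t, expected = TRUE)
  psth(edges, rate, n_reps = NA_integer_,
       condition = if (is.na(delay)) modality else paste0(modality, "_",
                                                          delay))
}

# MII implied by the noiseless rates, by the same shifted-sum and 20 ms
# peak-window rules as the estimator.
.noiseless_mii <- function(np, config, delay) {
  p_av <- .noiseless_psth(np, config, "AV", delay)
  p_v <- .noiseless_psth(np, config, "V")
  p_a <- .noiseless_psth(np, config, "A")
  av_peak <- .peak_rate_window(p_av, c(0, 250))
  sum_psth <- linear_sum_response(p_v, p_a, delay)
  sum_peak <- .peak_rate_window(sum_psth, c(0, 250))
  (av_peak - sum_peak) / sum_peak
}

# peak_firing_rate restricted to a response window of a wider psth
.peak_rate_window <- function(p, window_ms) {
  left <- head(p$bin_edges_ms, -1L)
  keep <- left >= window_ms[1L] & left < window_ms[2L]
  peak_firing_rate(p$rate_hz[keep])
}

#' Expected multisensory interaction index of a planted neuron
#'
#' Closed-form companion to the MII estimator: evaluates the index implied by
#' a neuron's configured kernels and interaction gain on the noiseless rate
#' functions, using the same shifted-sum construction and 20 ms peak-window
#' rule as [mii_from_psths()].
#'
#' @param session An `av_session` from [generate_session()] (or its
#'   `ground_truth` element).
#' @param neuron_id Neuron identifier (must be bimodal).
#' @param delay_ms AV delay at which to evaluate.
#' @return The expected MII (numeric scalar).
#' @export
expected_mii <- function(session, neuron_id, delay_ms) {
  gt <- if (!is.null(session$ground_truth)) session$ground_truth else session
  np <- gt$neurons[gt$neurons$neuron_id == neuron_id, ]
  if (nrow(np) != 1L) stop("unknown neuron_id: ", neuron_id)
  if (np$class == "gated")
    stop("expected MII undefined for gated neurons (A + V peak is baseline ",
         "only); they are excluded from MII summaries")
  if (np$class != "bimodal") stop("neuron is not bimodal")
  .noiseless_mii(as.list(np), gt$config, delay_ms)
}

# Solve the interaction gain g so that the noiseless MII at d* hits the
# neuron's target.  Monotone in g, solved by uniroot.
.solve_gain <- function(np, config) {
  np <- as.list(np)
  f <- function(g) {
    np$gain <- g
    .noiseless_mii(np, config, np$d_star) - np$target_mii
  }
  if (np$target_mii == 0 || abs(f(0)) < 1e-8) return(0)
  stats::uniroot(f, c(-500, 5000), extendInt = "upX", tol = 1e-4)$root
}

# --- spike generation --------------------------------------------------------

# Bernoulli draw of spike bins from per-bin probabilities; returns bin
# indices (1-based).  Exact per-bin iid Bernoulli.
.draw_bins <- function(p) which(runif(length(p)) < p)

# Homogeneous Bernoulli spikes over n_bins at probability p: binomial count,
# then uniform bins without replacement (exactly iid Bernoulli per bin).
.draw_bins_homog <- function(n_bins, p) {
  n <- rbinom(1L, n_bins, p)
  if (n == 0L) return(integer(0))
  sort(sample.int(n_bins, n))
}

#' Generate a synthetic session
#'
#' Draws spike trains from the inhomogeneous Bernoulli model described in
#' [synth_config()], builds the event table for the configured protocol, and
#' returns the planted ground truth.  The seed fully determines the output.
#'
#' Spikes are placed at bin centres (`t + 0.5` ms), so 1 ms binning recovers
#' the generating bins exactly.  Planted connections add, for each
#' presynaptic spike, an extra postsynaptic spike at `lag_ms` with
#' probability `efficacy` (duplicate bins are collapsed, so the realised
#' spike-transmission probability approaches `efficacy` from below at high
#' rates).
#'
#' @param config A [synth_config()].
#' @return An object of class `av_session`: list with `spikes` (named list of
#'   [spike_train]), `events` ([event_table]), `neurons` (coordinate table),
#'   `ground_truth` (`list(neurons, connections, config)`), and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, .generate_session_impl(config))
}

.generate_session_impl <- function(config) {
  events <- .build_events(config)
  params <- .draw_neuron_params(config)
  # interaction gains (deterministic given params)
  bi <- which(params$class == "bimodal")
  for (i in bi) params$gain[i] <- .solve_gain(params[i, ], config)
  ga <- which(params$class == "gated")
  params$gain[ga] <- if (is.null(config$gated_amp_hz))
    config$amp_hz * exp(rnorm(length(ga), 0, config$amp_sdlog))
  else config$gated_amp_hz
  n <- nrow(params)
  t_end <- max(events$onset_ms) + config$iti_ms
  n_bins_total <- as.integer(ceiling(t_end))
  max_rate <- max(c(0, params$baseline_hz + params$amp_v + params$amp_a +
                      ifelse(is.na(params$gain), 0, abs(params$gain))))
  if (max_rate > 1000)
    stop("rate too high for Bernoulli approximation (> 1000 Hz per 1 ms bin)")

  env <- .build_envelope(config, n_bins_total)
  cond_rows <- split(seq_len(nrow(events)), condition_key(events))
  evoked_t <- seq_len(.EVOKED_LEN) - 0.5

  trains <- vector("list", n)
  for (i in seq_len(n)) {
    np <- as.list(params[i, ])
    use_env <- !is.null(env) && (i %in% env$neurons)
    # baseline over the whole session
    if (use_env) {
      pbin <- np$baseline_hz / 1000 * env$mult_bin
      bins <- .draw_bins(pbin)
    } else {
      bins <- .draw_bins_homog(n_bins_total, np$baseline_hz / 1000)
    }
    if (config$protocol != "blank") {
      # replace baseline draws inside evoked windows with inhomogeneous draws
      stim_rows <- which(events$modality != "BLANK")
      if (length(stim_rows)) {
        on <- events$onset_ms[stim_rows]
        in_evoked <- rep(FALSE, n_bins_total)
        for (o in on) in_evoked[(o + 1):(o + .EVOKED_LEN)] <- TRUE
        bins <- bins[!in_evoked[bins]]
        for (ck in names(cond_rows)) {
          rows <- cond_rows[[ck]]
          if (events$modality[rows[1L]] == "BLANK") next
          e1 <- events[rows[1L], ]
          sw <- c(1, 1)
          if (config$protocol == "rf")
            sw <- .spatial_weights(np, e1$azimuth_deg, e1$elevation_deg,
                                   config$rf_sigma_deg)
          cmp <- .evoked_components(np, config, e1$modality, e1$av_delay_ms,
                                    evoked_t, sw[1L], sw[2L])
          ntr <- length(rows)
          jv <- as.integer(round(rnorm(ntr, 0, config$trial_jitter_sd_v)))
          ja <- as.integer(round(rnorm(ntr, 0, config$trial_jitter_sd_a)))
          P <- matrix(np$baseline_hz, ntr, .EVOKED_LEN)
          for (ti in seq_len(ntr))
            P[ti, ] <- P[ti, ] + .shift_vec(cmp$v, jv[ti]) +
              .shift_vec(cmp$a + cmp$inter, ja[ti])
          P <- pmin(pmax(P, 0) / 1000, 1)
          u <- matrix(runif(ntr * .EVOKED_LEN), nrow = ntr)
          hit <- which(u < P, arr.ind = TRUE)
          if (nrow(hit))
            bins <- c(bins, events$onset_ms[rows][hit[, 1L]] + hit[, 2L])
        }
      }
    }
    trains[[i]] <- sort(as.numeric(bins))
    names(trains)[i] <- np$neuron_id
  }
  # planted connections: copy presynaptic spikes forward with prob efficacy
  conns <- config$connections
  if (!is.null(conns) && nrow(conns)) {
    for (k in seq_len(nrow(conns))) {
      pre <- trains[[conns$pre[k]]]
      keep <- runif(length(pre)) < conns$efficacy[k]
      add <- pre[keep] + conns$lag_ms[k]
      post <- conns$post[k]
      newb <- union(trains[[post]], add[add <= n_bins_total])
      trains[[post]] <- sort(newb)
    }
  }
  spikes <- lapply(seq_len(n), function(i)
    spike_train(trains[[i]] - 0.5, # bin centres
                neuron_id = params$neuron_id[i], session_id = "s1",
                animal_id = "a1",
                position = c(params$ml_um[i], params$ap_um[i],
                             params$dv_um[i]),
                baseline_rate = params$baseline_hz[i]))
  names(spikes) <- params$neuron_id
  gt_conn <- if (is.null(conns)) {
    data.frame(pre = character(0), post = character(0), lag_ms = numeric(0),
               efficacy = numeric(0))
  } else {
    data.frame(pre = params$neuron_id[conns$pre],
               post = params$neuron_id[conns$post],
               lag_ms = conns$lag_ms, efficacy = conns$efficacy)
  }
  structure(list(spikes = spikes, events = events,
                 neurons = params[, c("neuron_id", "ml_um", "ap_um",
                                      "dv_um")],
                 ground_truth = list(neurons = params, connections = gt_conn,
                                     config = config),
                 config = config),
            class = "av_session")
}

.spatial_weights <- function(np, az, el, sigma) {
  c(.gauss_bump(az, np$rf_az_v, sigma) * .gauss_bump(el, np$rf_el_v, sigma),
    .gauss_bump(az, np$rf_az_a, sigma) * .gauss_bump(el, np$rf_el_a, sigma))
}

# Common slow rate envelope: AR(1) on a 10 ms grid (piecewise constant within
# each 10 ms block) with the configured correlation time, shared across the
# listed neurons.  Returns the per-1ms-bin multiplier.
.build_envelope <- function(config, n_bins_total) {
  e <- config$envelope
  if (is.null(e)) return(NULL)
  ts <- if (is.null(e$timescale_ms)) 200 else e$timescale_ms
  if (ts < 50) stop("envelope timescale must be >= 50 ms (slow envelope)")
  nb10 <- ceiling(n_bins_total / 10)
  rho <- exp(-10 / ts)
  s <- numeric(nb10)
  s[1L] <- rnorm(1L)
  innov <- rnorm(nb10 - 1L, 0, sqrt(1 - rho^2))
  for (k in 2:nb10) s[k] <- rho * s[k - 1L] + innov[k - 1L]
  mult <- pmax(0, 1 + e$sd_frac * s)
  list(neurons = e$neurons, mult_bin = rep(mult, each = 10)[1:n_bins_total])
}

#' @export
print.av_session <- function(x, ...) {
  cat(sprintf("<av_session: %d neurons, %d trials (%s protocol), seed %d>\n",
              length(x$spikes), nrow(x$events), x$config$protocol,
              x$config$seed))
  invisible(x)
}
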