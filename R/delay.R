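# AV delay tuning: merge/resplit selectivity test, preferred delay, the
# specificity / firing-rate-modulation / reliability indices, the
# multisensory interaction index, and the linear-sum delay prediction.

#' Bootstrap test of delay selectivity for one AV delay
#'
#' Tests whether the response at one AV delay differs from the response to
#' the preferred unisensory condition.  The 20 ms peak window is located
#' once on the pooled trials' windowed mean profile, and the statistic is
#' the difference in mean firing rate within that fixed window between the
#' multisensory and unisensory trial groups; the null merges the two trial
#' sets and re-splits them at random into groups of the observed sizes,
#' `n_boot` times.  The delay is
#' significant if the observed difference falls outside the 2.5th--97.5th
#' percentile range of the null.  The test is two-sided by construction;
#' delays significant but *below* the unisensory peak are flagged and later
#' excluded from the preferred-delay argmax.
#'
#' @param m_av,m_uni Trials-by-bins spike-count matrices (1 ms bins over the
#'   response window) for the AV-delay trials and the preferred-unisensory
#'   trials (see [trial_count_matrix()]).
#' @param n_boot Number of merge/resplit repetitions (default 10000).
#' @param seed Integer seed; deterministic given the seed.
#' @return List: `significant`, `above` (observed difference positive),
#'   `observed` (Hz), `lower`, `upper` (null percentile bounds).
#' @export
delay_significance_test <- function(m_av, m_uni, n_boot = 10000, seed = 1L) {
  if (nrow(m_av) < 10L || nrow(m_uni) < 10L)
    stop("need >= 10 repetitions in each arm")
  pd <- .peak_diff_null(m_av, m_uni, n_boot, seed)
  q <- quantile(pd$null, c(0.025, 0.975), names = FALSE, type = 7)
  list(significant = pd$observed < q[1L] || pd$observed > q[2L],
       above = pd$observed > 0,
       observed = pd$observed, lower = q[1L], upper = q[2L])
}

#' Preferred AV delay
#'
#' The delay eliciting the maximum peak firing rate among the delays whose
#' response significantly *exceeds* the preferred unisensory response; ties
#' break toward the smallest delay.
#'
#' @param delays_ms Vector of tested delays.
#' @param significant Logical flags (significant *and above* unisensory).
#' @param peak_rates Peak firing rate per delay (Hz).
#' @return The preferred delay in ms, or `NA` if no delay is significant
#'   (the neuron is not delay-selective).
#' @export
preferred_delay <- function(delays_ms, significant, peak_rates) {
  stopifnot(length(delays_ms) == length(significant),
            length(delays_ms) == length(peak_rates))
  if (!any(significant)) return(NA_integer_)
  d <- delays_ms[significant]
  r <- peak_rates[significant]
  d[order(-r, d)][1L]
}

#' Specificity index
#'
#' `SI = 1 - sig_delays / n_delays`: the proportion of tested AV delays that
#' did *not* significantly exceed the preferred unisensory response.  SI near
#' 1 means the neuron responds to few specific delays; near 0, to most.
#'
#' @param sig_delays Number of significant delays (0..n).
#' @param n_delays Number of delays tested (> 0).
#' @return SI in `[0, 1]`.
#' @export
specificity_index <- function(sig_delays, n_delays) {
  if (n_delays <= 0) stop("n_delays must be positive")
  if (sig_delays < 0 || sig_delays > n_delays)
    stop("sig_delays must be between 0 and n_delays")
  1 - sig_delays / n_delays
}

#' Firing-rate modulation index
#'
#' `(AV_max - AV_min) / (AV_max + AV_min)` on the 20 ms peak rates of the
#' preferred and least-effective AV delays.
#'
#' @param av_max,av_min Peak firing rates (Hz), `av_max >= av_min >= 0`.
#' @return Index in `[0, 1]`; `NA` (flagged) when both rates are zero.
#' @export
fr_modulation_index <- function(av_max, av_min) {
  if (av_min < 0 || av_max < av_min)
    stop("require av_max >= av_min >= 0")
  if (av_max + av_min == 0)
    return(structure(NA_real_, undefined = TRUE))
  (av_max - av_min) / (av_max + av_min)
}

#' Reliability index
#'
#' Mean pairwise Pearson correlation over all `R(R-1)/2` pairs of
#' single-repetition response vectors.  Pairs in which either vector has
#' zero variance contribute `r = 0` (keeping the index defined for sparse
#' responders) and are counted in the `n_zero_var` attribute.
#'
#' @param responses Repetitions-by-bins matrix of binned single-trial
#'   responses (default analyses use 10 ms bins over `[0, 250)` ms).
#' @return RI in `[-1, 1]` with attribute `n_zero_var`.
#' @export
reliability_index <- function(responses) {
  R <- nrow(responses)
  if (is.null(R) || R < 2L) stop("need >= 2 repetitions")
  v <- apply(responses, 1L, var)
  C <- suppressWarnings(cor(t(responses)))
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[pairs]
  zv <- v[pairs[, 1L]] == 0 | v[pairs[, 2L]] == 0
  r[zv] <- 0
  structure(mean(r), n_zero_var = sum(zv))
}

#' Chance-level reliability
#'
#' Reliability index computed on responses sampled at uniformly random times
#' within the session, independently of the trial structure (stimulus
#' windows are avoided), giving the RI expected by chance for the neuron's
#' spontaneous statistics.
#'
#' @param train A [spike_train].
#' @param events The session's [event_table] (used to avoid stimulus
#'   windows and delimit the session).
#' @param n_reps Number of random windows (match the trial count).
#' @param duration_ms,bin_width_ms Window length and bin width of the
#'   response vectors (defaults 250 and 10 ms).
#' @param seed Seed for window placement.
#' @return Chance RI (same form as [reliability_index()]).
#' @export
chance_reliability <- function(train, events, n_reps,
                               duration_ms = 250, bin_width_ms = 10,
                               seed = 1L) {
  t_max <- max(events$onset_ms) + 1000
  stim_on <- events$onset_ms[events$modality != "BLANK"]
  withr::with_seed(seed, {
    starts <- numeric(0)
    guard <- 0L
    while (length(starts) < n_reps && guard < 1000L) {
      cand <- runif(n_reps, 0, t_max - duration_ms)
      # reject windows overlapping any stimulus-evoked period
      ok <- vapply(cand, function(s)
        !any(stim_on > s - .EVOKED_LEN & stim_on < s + duration_ms), TRUE)
      starts <- c(starts, cand[ok])
      guard <- guard + 1L
    }
    starts <- starts[seq_len(n_reps)]
    m <- t(vapply(starts, function(s) {
      t <- train$spike_times
      t <- t[t >= s & t < s + duration_ms] - s
      tabulate(floor(t / bin_width_ms) + 1L,
               nbins = duration_ms / bin_width_ms)
    }, numeric(duration_ms / bin_width_ms)))
    reliability_index(m)
  })
}

#' Linear-sum (shifted) multisensory response prediction
#'
#' Builds the synthetic audiovisual PSTH expected under linear summation of
#' the unisensory responses: the auditory PSTH is shifted by the AV delay and
#' added to the visual PSTH, after subtracting the auditory baseline (mean
#' rate in `[-200, 0)` ms) so the sum's baseline is not double-counted.
#' Bins where the shifted auditory profile is undefined take its baseline,
#' i.e. contribute zero.
#'
#' @param psth_v,psth_a Unisensory [psth] objects on a common 1 ms grid
#'   covering at least `[-200, 350)` ms.
#' @param delay_ms AV delay in ms (a multiple of the bin width).
#' @return A [psth] of the predicted AV response on the same grid.
#' @export
linear_sum_response <- function(psth_v, psth_a, delay_ms) {
  bw <- bin_width(psth_v)
  if (abs(bw - bin_width(psth_a)) > 1e-9 ||
      !isTRUE(all.equal(psth_v$bin_edges_ms, psth_a$bin_edges_ms)))
    stop("psths must share one grid")
  if (abs(delay_ms / bw - round(delay_ms / bw)) > 1e-9)
    stop("delay must be a multiple of the bin width")
  left <- head(psth_v$bin_edges_ms, -1L)
  base_idx <- left >= -200 & left < 0
  if (!any(base_idx)) stop("grid must cover the [-200, 0) baseline window")
  base_a <- mean(psth_a$rate_hz[base_idx])
  k <- as.integer(round(delay_ms / bw))
  a_shift <- rep(base_a, length(left))
  if (k >= 0) {
    if (k < length(left))
      a_shift[(k + 1):length(left)] <- psth_a$rate_hz[1:(length(left) - k)]
  } else {
    if (-k < length(left))
      a_shift[1:(length(left) + k)] <- psth_a$rate_hz[(1 - k):length(left)]
  }
  rate <- pmax(psth_v$rate_hz + a_shift - base_a, 0)
  psth(psth_v$bin_edges_ms, rate, n_reps = psth_v$n_reps,
       condition = paste0("linear_sum_", delay_ms),
       alignment = psth_v$alignment)
}

#' Predicted preferred delay from unisensory responses
#'
#' Scans the tested delays, builds the linear-sum response for each, and
#' returns the delay whose summed profile has the largest 20 ms peak firing
#' rate within the response window (ties toward the smallest delay).
#'
#' @inheritParams linear_sum_response
#' @param delays_ms Delays to scan.
#' @param window_ms Response window for the peak (default `c(0, 250)`).
#' @return Predicted preferred delay (ms), or `NA` if either unisensory
#'   profile is flat.
#' @export
predicted_preferred_delay <- function(psth_v, psth_a, delays_ms,
                                      window_ms = c(0, 250)) {
  if (diff(range(psth_v$rate_hz)) == 0 || diff(range(psth_a$rate_hz)) == 0)
    return(NA_integer_)
  peaks <- vapply(delays_ms, function(d)
    .peak_rate_window(linear_sum_response(psth_v, psth_a, d), window_ms), 0)
  delays_ms[order(-peaks, delays_ms)][1L]
}

#' Multisensory interaction index
#'
#' `MII = (AV - (A + V)) / (A + V)` on 20 ms peak firing rates, where the
#' `A + V` peak is taken on the shifted-sum profile ([linear_sum_response()]),
#' not as the sum of the two unisensory peaks.  `MII > 0.5` is classified
#' supralinear, `MII < -0.5` sublinear, otherwise linear (strict
#' inequalities).
#'
#' @param av_peak Peak rate of the observed AV response (Hz).
#' @param sum_peak Peak rate of the shifted-sum response (Hz, must be > 0;
#'   gated neurons, whose unisensory profiles are baseline-only, are
#'   excluded by this precondition).
#' @return List `mii`, `class` (`"supralinear"`, `"linear"`, `"sublinear"`).
#' @export
mii <- function(av_peak, sum_peak) {
  if (sum_peak <= 0)
    return(list(mii = structure(NA_real_, undefined = TRUE),
                class = NA_character_))
  m <- (av_peak - sum_peak) / sum_peak
  list(mii = m,
       class = if (m > 0.5) "supralinear" else if (m < -0.5) "sublinear"
       else "linear")
}

#' MII of one neuron at one delay, from trial data
#'
#' Convenience wrapper: builds the observed AV PSTH and the shifted-sum
#' prediction on the `[-200, 350)` ms grid and applies [mii()] with peaks
#' restricted to the response window.
#'
#' @param train A [spike_train].
#' @param events Session [event_table].
#' @param delay_ms AV delay.
#' @param window_ms Response window for peaks.
#' @return As [mii()], plus `av_peak` and `sum_peak`.
#' @export
mii_from_psths <- function(train, events, delay_ms, window_ms = c(0, 250)) {
  grid <- c(-200, 350)
  p_av <- compute_psth(slice_trials(train,
                                    select_trials(events, "AV", delay_ms),
                                    grid), 1, grid, condition = "AV")
  p_v <- compute_psth(slice_trials(train, select_trials(events, "V"), grid),
                      1, grid, condition = "V")
  p_a <- compute_psth(slice_trials(train, select_trials(events, "A"), grid),
                      1, grid, condition = "A")
  av_peak <- .peak_rate_window(p_av, window_ms)
  sum_peak <- .peak_rate_window(linear_sum_response(p_v, p_a, delay_ms),
                                window_ms)
  c(mii(av_peak, sum_peak), list(av_peak = av_peak, sum_peak = sum_peak))
}

#' Full delay-tuning analysis for a set of neurons
#'
#' For each neuron: identifies the preferred unisensory modality (higher
#' 20 ms peak rate of V vs A), runs the merge/resplit selectivity test at
#' every AV delay, and derives the preferred delay, specificity index,
#' firing-rate modulation index, reliability index (with its chance level),
#' per-delay MII, MII at the preferred delay, and the linear-sum predicted
#' preferred delay.
#'
#' @param session An `av_session` (or `list(spikes =, events =)`).
#' @param neuron_ids Neurons to analyse (default: all).
#' @param n_boot Resplits per delay test.
#' @param window_ms Response window.
#' @param ri_bin_ms Bin width of the reliability-index response vectors.
#' @param seed Master seed (child seeds per neuron/delay).
#' @return A data.frame with one row per neuron and an attribute
#'   `per_delay` (long data.frame of per-delay flags, peaks and MII).
#' @export
delay_tuning <- function(session, neuron_ids = NULL, n_boot = 10000,
                         window_ms = c(0, 250), ri_bin_ms = 10, seed = 1L) {
  events <- session$events
  delays <- sort(unique(events$av_delay_ms[!is.na(events$av_delay_ms)]))
  if (!length(delays)) stop("no multisensory trials in events")
  spikes <- session$spikes
  if (!is.null(neuron_ids)) spikes <- spikes[neuron_ids]
  grid <- c(-200, 350)
  rows <- list(); per_delay <- list()
  for (tr in spikes) {
    sd0 <- child_seed(seed, tr$neuron_id)
    sl_v <- slice_trials(tr, select_trials(events, "V"), grid)
    sl_a <- slice_trials(tr, select_trials(events, "A"), grid)
    m_v <- trial_count_matrix(sl_v, 1, window_ms)
    m_a <- trial_count_matrix(sl_a, 1, window_ms)
    peak_v <- .peak_rate_vec(colMeans(m_v)) * 1000
    peak_a <- .peak_rate_vec(colMeans(m_a)) * 1000
    m_uni <- if (peak_v >= peak_a) m_v else m_a
    p_v <- compute_psth(sl_v, 1, grid, condition = "V")
    p_a <- compute_psth(sl_a, 1, grid, condition = "A")
    sum_peaks <- vapply(delays, function(d)
      .peak_rate_window(linear_sum_response(p_v, p_a, d), window_ms), 0)
    sig <- logical(length(delays)); above <- logical(length(delays))
    peaks <- numeric(length(delays)); mii_d <- numeric(length(delays))
    mii_class <- character(length(delays))
    av_counts <- vector("list", length(delays))
    for (k in seq_along(delays)) {
      ev_d <- select_trials(events, "AV", delays[k])
      m_av <- trial_count_matrix(slice_trials(tr, ev_d, window_ms), 1,
                                 window_ms)
      av_counts[[k]] <- m_av
      ts <- delay_significance_test(m_av, m_uni, n_boot = n_boot,
                                    seed = child_seed(sd0, paste0("d",
                                                                  delays[k])))
      sig[k] <- ts$significant
      above[k] <- ts$above
      peaks[k] <- .peak_rate_vec(colMeans(m_av)) * 1000
      mm <- mii(peaks[k], sum_peaks[k])
      mii_d[k] <- mm$mii
      mii_class[k] <- if (is.na(mm$mii)) NA_character_ else mm$class
    }
    sel <- sig & above
    pref <- preferred_delay(delays, sel, peaks)
    si <- specificity_index(sum(sel), length(delays))
    # AV_max is the preferred delay's peak when one exists, else the best
    av_max <- if (is.na(pref)) max(peaks) else peaks[match(pref, delays)]
    frmod <- fr_modulation_index(av_max, min(peaks))
    ri <- NA_real_; ri_chance <- NA_real_
    if (!is.na(pref)) {
      k <- match(pref, delays)
      resp <- trial_count_matrix(
        slice_trials(tr, select_trials(events, "AV", pref), window_ms),
        ri_bin_ms, window_ms)
      ri <- as.numeric(reliability_index(resp))
      ri_chance <- as.numeric(chance_reliability(
        tr, events, n_reps = nrow(resp),
        duration_ms = diff(window_ms), bin_width_ms = ri_bin_ms,
        seed = child_seed(sd0, "chance")))
    }
    pred <- predicted_preferred_delay(p_v, p_a, delays, window_ms)
    rows[[tr$neuron_id]] <- data.frame(
      neuron_id = tr$neuron_id, n_delays = length(delays),
      sig_delays = sum(sel), preferred_delay_ms = pref, si = si,
      fr_modulation = as.numeric(frmod), ri = ri, ri_chance = ri_chance,
      mii_at_preferred = if (is.na(pref)) NA_real_ else
        mii_d[match(pref, delays)],
      predicted_delay_ms = pred, peak_v = peak_v, peak_a = peak_a,
      stringsAsFactors = FALSE)
    per_delay[[tr$neuron_id]] <- data.frame(
      neuron_id = tr$neuron_id, delay_ms = delays, significant = sig,
      above = above, selective = sel, peak_hz = peaks, mii = mii_d,
      mii_class = mii_class, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  pd <- do.call(rbind, per_delay)
  rownames(pd) <- NULL
  attr(res, "per_delay") <- pd
  res
}
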