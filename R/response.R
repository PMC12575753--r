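# Responsiveness testing, neuron taxonomy and the shared merge/resplit
# permutation engine.

# Vectorised merge-and-resplit null for the difference in 20 ms peak firing
# rate between two trial groups.
#
# m1, m2: trials-by-bins count matrices at 1 ms bins over the response
# window.  The 20 ms peak window is located once on the pooled (all-trials)
# windowed mean profile -- a symmetric function of the merged data, so the
# resplit null remains exact -- and the statistic is the difference in mean
# firing rate within that fixed window.  The null merges all trials and
# re-splits them at random into groups of the observed sizes, n_boot times.
#
# Returns list(observed, null) with rates in Hz, and the window used.
.peak_diff_null <- function(m1, m2, n_boot, seed, window_bins = 20L) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  M <- rbind(m1, m2)
  n <- n1 + n2
  nb <- ncol(M)
  h <- window_bins %/% 2L
  prof <- colMeans(M)
  cs <- c(0, cumsum(prof))
  lo <- pmax(seq_len(nb) - h, 1L)
  hi <- pmin(seq_len(nb) + h - 1L, nb)
  j <- which.max((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  win <- lo[j]:hi[j]
  per_trial <- rowMeans(M[, win, drop = FALSE]) * 1000 # Hz within window
  tot <- sum(per_trial)
  obs <- mean(per_trial[seq_len(n1)]) - mean(per_trial[-seq_len(n1)])
  null <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    s1 <- sum(per_trial[sample.int(n, n1)])
    s1 / n1 - (tot - s1) / n2
  }, 0))
  list(observed = obs, null = null, window = win)
}

#' Permutation test of stimulus responsiveness
#'
#' Tests whether a neuron responds to a stimulus condition by comparing the
#' 20 ms peak-window firing rate between condition trials and blank trials.
#' The peak window is located once on the pooled trials' windowed mean
#' profile (a symmetric function of the merged data, keeping the permutation
#' null exact) and the statistic is the group difference in mean rate within
#' that window.  The null distribution is obtained by merging the two trial
#' sets and re-splitting them at random (label shuffling); the p-value is
#' two-sided.  This is the package's responsiveness test; an external test
#' can be substituted by supplying its p-values directly to
#' [classify_neuron()].
#'
#' @param train A [spike_train].
#' @param events An [event_table] containing the condition and blank trials.
#' @param modality Condition modality to test (`"V"`, `"A"`, `"AV"`).
#' @param av_delay_ms For `"AV"`, the delay to test.
#' @param window_ms Response window relative to trial onset (default
#'   `c(0, 250)` ms).
#' @param n_perm Number of permutations (>= 1000 recommended; smaller values
#'   give a coarse p-value and a warning).
#' @param alpha Unused here (kept for interface symmetry with callers that
#'   thread a significance level through).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return The two-sided permutation p-value, with attributes `observed`
#'   (peak-rate difference in Hz) and `n_perm`.
#' @export
test_responsiveness <- function(train, events, modality,
                                av_delay_ms = NULL, window_ms = c(0, 250),
                                n_perm = 1000, alpha = 0.05, seed = 1L) {
  if (n_perm < 1000)
    warning("n_perm < 1000 gives a coarse permutation p-value")
  cond <- select_trials(events, modality, av_delay_ms)
  blank <- select_trials(events, "BLANK")
  if (nrow(blank) == 0L) stop("no within-subject control (no blank trials)")
  if (nrow(cond) < 10L || nrow(blank) < 10L)
    stop("need >= 10 repetitions of the condition and of blanks")
  m1 <- trial_count_matrix(slice_trials(train, cond, window_ms), 1,
                           window_ms)
  m2 <- trial_count_matrix(slice_trials(train, blank, window_ms), 1,
                           window_ms)
  pd <- .peak_diff_null(m1, m2, n_perm, seed)
  p <- (1 + sum(abs(pd$null) >= abs(pd$observed) - 1e-12)) / (n_perm + 1)
  structure(p, observed = pd$observed, n_perm = n_perm)
}

#' Classify a neuron from per-condition responsiveness p-values
#'
#' Applies Benjamini--Hochberg correction across the family of stimulus
#' conditions tested for the neuron, then assigns the taxonomy: `visual`
#' (only V significant), `auditory` (only A), `bimodal` (V and A), `gated`
#' (neither unisensory condition but at least one multisensory condition),
#' `nonresponsive` otherwise.  "Multisensory" neurons are the union of
#' bimodal and gated.
#'
#' @param p_v,p_a Unadjusted p-values for the unisensory conditions.
#' @param p_av Numeric vector of unadjusted p-values for the multisensory
#'   conditions (one per AV delay tested); may be `NULL` if AV was not
#'   tested.
#' @param alpha Significance level applied to the BH-adjusted p-values.
#' @return A list of class `neuron_class`: `label`, adjusted p-values
#'   (`p_v_adj`, `p_a_adj`, `p_av_min_adj`), and the significance flags.
#' @export
classify_neuron <- function(p_v, p_a, p_av = NULL, alpha = 0.05) {
  fam <- c(V = p_v, A = p_a,
           if (length(p_av)) setNames(p_av, paste0("AV", seq_along(p_av))))
  adj <- bh_adjust(fam)
  sig <- adj <= alpha
  v <- sig[["V"]]; a <- sig[["A"]]
  av <- if (length(p_av)) any(sig[-(1:2)]) else FALSE
  label <- if (v && a) "bimodal"
  else if (v) "visual"
  else if (a) "auditory"
  else if (av) "gated"
  else "nonresponsive"
  structure(list(label = label, p_v_adj = adj[["V"]], p_a_adj = adj[["A"]],
                 p_av_min_adj = if (length(p_av)) min(adj[-(1:2)]) else
                   NA_real_,
                 significant = sig),
            class = "neuron_class")
}

#' Responsiveness, taxonomy and latency for every neuron of a session
#'
#' Runs [test_responsiveness()] for V, A and every AV delay, classifies each
#' neuron via [classify_neuron()], and estimates unisensory latency-to-peak
#' for the significant modalities.
#'
#' @param session An `av_session` (or `list(spikes =, events =)`).
#' @param n_perm Permutations per test.
#' @param alpha BH-adjusted significance level.
#' @param window_ms Response window.
#' @param seed Seed; per-neuron, per-condition child seeds are derived from
#'   it so results do not depend on iteration order.
#' @return A data.frame, one row per neuron: `neuron_id, label, p_v, p_a,
#'   p_av_min, latency_ms, phase` (latency of the dominant unisensory
#'   modality, `NA` if none).
#' @export
characterise_session <- function(session, n_perm = 1000, alpha = 0.05,
                                 window_ms = c(0, 250), seed = 1L) {
  events <- session$events
  delays <- sort(unique(events$av_delay_ms[!is.na(events$av_delay_ms)]))
  out <- lapply(session$spikes, function(tr) {
    sd_base <- child_seed(seed, tr$neuron_id)
    p_v <- test_responsiveness(tr, events, "V", n_perm = n_perm,
                               window_ms = window_ms, seed = sd_base)
    p_a <- test_responsiveness(tr, events, "A", n_perm = n_perm,
                               window_ms = window_ms,
                               seed = child_seed(sd_base, "A"))
    p_av <- vapply(delays, function(d)
      as.numeric(test_responsiveness(tr, events, "AV", av_delay_ms = d,
                                     n_perm = n_perm, window_ms = window_ms,
                                     seed = child_seed(sd_base,
                                                       paste0("AV", d)))),
      0)
    cls <- classify_neuron(p_v, p_a, p_av, alpha)
    lat <- list(latency_ms = NA_real_, phase = NA_character_)
    mod <- if (cls$label %in% c("visual", "bimodal")) "V"
    else if (cls$label == "auditory") "A" else NA
    if (!is.na(mod)) {
      ps <- compute_psth(slice_trials(tr, select_trials(events, mod),
                                      window_ms), 1, window_ms,
                         condition = mod)
      lat <- estimate_latency(ps, mod)
    }
    data.frame(neuron_id = tr$neuron_id, label = cls$label,
               p_v = as.numeric(p_v), p_a = as.numeric(p_a),
               p_av_min = if (length(p_av)) min(p_av) else NA_real_,
               latency_ms = lat$latency_ms, phase = lat$phase,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
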