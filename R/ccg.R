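# Jitter-corrected cross-correlogram connectivity inference.
#
# The correlogram of a neuron pair is computed on per-trial 1 ms binary bin
# trains over a late post-onset window (default 1--2 s, i.e. spontaneous
# activity), concatenated across repetitions:
#
#   CCG(tau) = (1/M) sum_i sum_t x1_i(t) x2_i(t + tau)
#              / ( theta(tau) sqrt(lambda1 lambda2) )
#
# with theta(tau) = N - |tau| the triangular overlap correction (N bins per
# trial) and lambda the in-window mean rates.  Slow and stimulus-locked
# co-modulation is removed by subtracting the correlogram expected when every
# spike is relocated uniformly within its fixed, non-overlapping 10 ms
# window (CCG_corrected = CCG - CCG_jittered).  The jittered expectation has
# a closed form -- the relocation kernel of a spike pair is the convolution
# of two discrete uniforms, a triangle over the window offset -- which is
# used by default; Monte-Carlo resampling is available for cross-checking.

#' Per-trial bin trains for correlogram analysis
#'
#' Slices a spike train into integer 1 ms bin indices per trial over an
#' analysis window (default the 1--2 s post-onset spontaneous window).
#'
#' @param train A [spike_train].
#' @param events Session [event_table].
#' @param window_ms Analysis window relative to trial onset.
#' @return List of integer vectors (0-based bin indices within the window),
#'   one per trial, with attribute `n_bins`.
#' @export
ccg_bin_trials <- function(train, events, window_ms = c(1000, 2000)) {
  sl <- slice_trials(train, events, window_ms)
  n_bins <- as.integer(diff(window_ms))
  out <- lapply(sl, function(t) as.integer(floor(t - window_ms[1L])))
  attr(out, "n_bins") <- n_bins
  out
}

# Spike-pair differences within +/- max_diff bins, across per-trial trains.
# b1/b2: concatenated bin vectors, tr1/tr2: trial index per spike.
# Returns data.frame(d = bin difference b2 - b1, dw = jitter-window
# difference) for same-trial pairs only.
.pair_diffs <- function(b1, tr1, b2, tr2, max_diff, jitter_window) {
  # offset each trial far apart so cross-trial pairs fall outside max_diff
  off <- (max(c(b1, b2, 0L)) + 10L * max_diff + 100L)
  g1 <- as.numeric(b1) + off * as.numeric(tr1)
  g2 <- as.numeric(b2) + off * as.numeric(tr2)
  o2 <- order(g2)
  g2s <- g2[o2]
  lo <- findInterval(g1 - max_diff - 0.5, g2s)
  hi <- findInterval(g1 + max_diff + 0.5, g2s)
  cnt <- hi - lo
  keep <- cnt > 0L
  if (!any(keep)) return(list(d = integer(0), dw = integer(0)))
  idx2 <- sequence(cnt[keep], from = lo[keep] + 1L)
  idx1 <- rep(which(keep), cnt[keep])
  d <- as.integer(g2s[idx2] - g1[idx1])
  w1 <- b1 %/% jitter_window
  w2 <- b2 %/% jitter_window
  gw1 <- w1 + 1000L * tr1
  gw2 <- (w2 + 1000L * tr2)[o2]
  list(d = d, dw = as.integer(gw2[idx2] - gw1[idx1]))
}

#' Jitter-corrected cross-correlogram of a neuron pair
#'
#' @param trials1,trials2 Per-trial bin trains from [ccg_bin_trials()]
#'   (equal trial counts; for cross-session surrogates, trials are aligned
#'   by index).
#' @param max_lag_ms Correlogram support (default 25 ms, covering the
#'   10--15 ms noise band with margin).
#' @param jitter_window_ms Jitter window (default 10 ms).
#' @param jitter `"analytic"` (exact expectation of the spike-relocation
#'   scheme; default) or `"resample"` (Monte-Carlo average over `n_jitter`
#'   relocations of both trains).
#' @param n_jitter Resamples for `jitter = "resample"`.
#' @param seed Seed for the resampling jitter.
#' @return Object of class `ccg`: `lags_ms`, `raw`, `jittered`, `corrected`,
#'   `lambda1`, `lambda2` (Hz), `m_trials`, `n_bins`, `noise_mean`,
#'   `noise_sd` (from the corrected values at `|lag|` in 10--15 ms),
#'   `peak_lag_ms`, `peak_value`, `z` (peak over `|lag|` in 1--5 ms), and
#'   `z0` (value at lag 0).  `valid = FALSE` when either train is silent.
#' @export
compute_ccg <- function(trials1, trials2, max_lag_ms = 25,
                        jitter_window_ms = 10,
                        jitter = c("analytic", "resample"), n_jitter = 100,
                        seed = 1L) {
  jitter <- match.arg(jitter)
  n_bins <- attr(trials1, "n_bins")
  if (is.null(n_bins) || !identical(n_bins, attr(trials2, "n_bins")))
    stop("trials must come from ccg_bin_trials with one window")
  M <- length(trials1)
  if (M != length(trials2) || M < 1L) stop("need equal, positive trial counts")
  W <- as.integer(max_lag_ms)
  lags <- -W:W
  b1 <- unlist(trials1); b2 <- unlist(trials2)
  n1 <- length(b1); n2 <- length(b2)
  if (n1 == 0L || n2 == 0L) {
    return(structure(list(valid = FALSE, lags_ms = lags), class = "ccg"))
  }
  tr1 <- rep(seq_len(M), lengths(trials1))
  tr2 <- rep(seq_len(M), lengths(trials2))
  lambda1 <- n1 / (M * n_bins / 1000)
  lambda2 <- n2 / (M * n_bins / 1000)
  theta <- n_bins - abs(lags)
  denom <- M * theta * sqrt(lambda1 * lambda2)
  jw <- as.integer(jitter_window_ms)
  # pairs out to max_diff so all jitter-kernel mass for |tau| <= W is seen
  pd <- .pair_diffs(b1, tr1, b2, tr2, max_diff = W + 2L * jw, jw)
  raw_counts <- tabulate(pd$d[abs(pd$d) <= W] + W + 1L, nbins = 2L * W + 1L)
  raw <- raw_counts / denom
  if (jitter == "analytic") {
    # relocation kernel: difference of two iid U{0..jw-1}
    kern <- (jw - abs(-(jw - 1L):(jw - 1L))) / jw^2
    dw_tab <- table(pd$dw[abs(pd$dw) <= (W %/% jw + 2L)])
    exp_counts <- numeric(2L * W + 1L)
    for (j in seq_along(dw_tab)) {
      dw <- as.integer(names(dw_tab)[j])
      taus <- dw * jw + (-(jw - 1L):(jw - 1L))
      ok <- abs(taus) <= W
      exp_counts[taus[ok] + W + 1L] <- exp_counts[taus[ok] + W + 1L] +
        dw_tab[[j]] * kern[ok]
    }
    jittered <- exp_counts / denom
  } else {
    w1 <- (b1 %/% jw) * jw
    w2 <- (b2 %/% jw) * jw
    acc <- numeric(2L * W + 1L)
    withr::with_seed(seed, {
      for (r in seq_len(n_jitter)) {
        j1 <- w1 + sample.int(jw, n1, replace = TRUE) - 1L
        j2 <- w2 + sample.int(jw, n2, replace = TRUE) - 1L
        pdj <- .pair_diffs(j1, tr1, j2, tr2, W, jw)
        acc <- acc + tabulate(pdj$d[abs(pdj$d) <= W] + W + 1L,
                              nbins = 2L * W + 1L)
      }
    })
    jittered <- acc / n_jitter / denom
  }
  corrected <- raw - jittered
  noise_idx <- abs(lags) >= 10 & abs(lags) <= 15
  noise_mean <- mean(corrected[noise_idx])
  noise_sd <- sd(corrected[noise_idx])
  peak_idx <- which(abs(lags) >= 1 & abs(lags) <= 5)
  pk <- peak_idx[which.max(corrected[peak_idx])]
  structure(list(valid = TRUE, lags_ms = lags, raw = raw,
                 jittered = jittered, corrected = corrected,
                 lambda1 = lambda1, lambda2 = lambda2, m_trials = M,
                 n_bins = n_bins, noise_mean = noise_mean,
                 noise_sd = noise_sd,
                 peak_lag_ms = lags[pk], peak_value = corrected[pk],
                 z = (corrected[pk] - noise_mean) / noise_sd,
                 z0 = (corrected[lags == 0] - noise_mean) / noise_sd),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  if (!isTRUE(x$valid)) cat("<ccg: invalid (silent train)>\n")
  else cat(sprintf(
    "<ccg: peak %.3g at %+d ms, z = %.2f (noise sd %.3g), %d trials>\n",
    x$peak_value, x$peak_lag_ms, x$z, x$noise_sd, x$m_trials))
  invisible(x)
}

#' @export
plot.ccg <- function(x, which = c("corrected", "raw", "jittered"), ...) {
  which <- match.arg(which)
  graphics::plot(x$lags_ms, x[[which]], type = "h", xlab = "lag (ms)",
                 ylab = which, ...)
  invisible(x)
}

#' Inclusion rule for correlogram analysis
#'
#' Neurons responsive to any stimulus are included regardless of baseline
#' rate; non-responsive neurons only if their baseline rate is at least
#' `min_rate_hz` (default 10 spikes/s).
#'
#' @param responsive Logical vector.
#' @param baseline_rate_hz Baseline rates (spikes/s).
#' @param min_rate_hz Rate floor for non-responsive neurons.
#' @return Logical inclusion flags.
#' @export
ccg_inclusion <- function(responsive, baseline_rate_hz, min_rate_hz = 10) {
  responsive | (baseline_rate_hz >= min_rate_hz)
}

#' Detect putative connections in a set of simultaneously recorded neurons
#'
#' Computes the jitter-corrected correlogram for every included pair and
#' applies the significance rule: the corrected peak within +/- 5 ms must
#' exceed `z_thresh` (default 5) standard deviations above the mean of the
#' noise band (corrected values at `|lag|` 10--15 ms).  Pairs whose overall
#' maximum (including lag 0) sits at lag 0 are recorded separately as
#' shared-input pairs; only peak lags of 1--5 ms count as putative
#' connections.  Direction follows the lag sign: the earlier-firing neuron
#' is presynaptic.
#'
#' @param bin_trains Named list of per-trial bin trains
#'   ([ccg_bin_trials()]), one element per included neuron.
#' @param z_thresh Significance threshold in noise SDs.
#' @param corrected Use the jitter-corrected correlogram (`TRUE`, default)
#'   or the raw one (for demonstrating the purpose of the correction).
#' @param ... Passed to [compute_ccg()].
#' @return List of class `connection_set`: `connections` (data.frame
#'   `pre, post, lag_ms, strength, z`), `shared_input` (data.frame
#'   `id1, id2, z`), `n_assessed`, `connection_pct`.
#' @export
detect_connections <- function(bin_trains, z_thresh = 5, corrected = TRUE,
                               ...) {
  ids <- names(bin_trains)
  n <- length(bin_trains)
  conns <- list(); shared <- list()
  n_assessed <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      cc <- compute_ccg(bin_trains[[i]], bin_trains[[j]], ...)
      if (!isTRUE(cc$valid)) next
      n_assessed <- n_assessed + 1L
      vals <- if (corrected) cc$corrected else cc$raw
      noise_idx <- abs(cc$lags_ms) >= 10 & abs(cc$lags_ms) <= 15
      nm <- mean(vals[noise_idx]); nsd <- sd(vals[noise_idx])
      if (nsd == 0) next
      win <- which(abs(cc$lags_ms) <= 5)
      pk <- win[which.max(vals[win])]
      z <- (vals[pk] - nm) / nsd
      if (z <= z_thresh) next
      lag <- cc$lags_ms[pk]
      if (lag == 0L) {
        shared[[length(shared) + 1L]] <-
          data.frame(id1 = ids[i], id2 = ids[j], z = z,
                     stringsAsFactors = FALSE)
      } else {
        pre <- if (lag > 0L) ids[i] else ids[j]
        post <- if (lag > 0L) ids[j] else ids[i]
        conns[[length(conns) + 1L]] <-
          data.frame(pre = pre, post = post, lag_ms = abs(lag),
                     strength = vals[pk], z = z, stringsAsFactors = FALSE)
      }
    }
  }
  empty_conn <- data.frame(pre = character(0), post = character(0),
                           lag_ms = integer(0), strength = numeric(0),
                           z = numeric(0))
  structure(list(
    connections = if (length(conns)) do.call(rbind, conns) else empty_conn,
    shared_input = if (length(shared)) do.call(rbind, shared) else
      data.frame(id1 = character(0), id2 = character(0), z = numeric(0)),
    n_assessed = n_assessed,
    connection_pct = if (n_assessed) 100 * length(conns) / n_assessed else
      NA_real_), class = "connection_set")
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("<connection_set: %d putative connections / %d pairs (%.2f%%), %d shared-input>\n",
              nrow(x$connections), x$n_assessed, x$connection_pct,
              nrow(x$shared_input)))
  invisible(x)
}

#' Cross-recording false-positive rate of connection detection
#'
#' For each session, builds a surrogate population of the same size whose
#' neurons are drawn from the *other* sessions, matching the dorso-ventral
#' depth histogram (13 bins of 150 um), and runs [detect_connections()] on
#' the surrogate with trial clocks aligned by trial index.  Because the
#' surrogate neurons were never recorded together, any detected "connection"
#' is a false positive of the threshold rule.
#'
#' @param sessions List of sessions; each needs `bin_trains` (named list per
#'   neuron, from [ccg_bin_trials()]) and `dv_um` (named depth vector).
#' @param depth_bin_um,n_depth_bins Depth binning (defaults 150 um x 13).
#' @param seed Seed for neuron sampling.
#' @param ... Passed to [detect_connections()].
#' @return List: `fpr_pct` (pooled surrogate connection percentage),
#'   `n_connections`, `n_assessed`.
#' @export
false_positive_rate <- function(sessions, depth_bin_um = 150,
                                n_depth_bins = 13, seed = 1L, ...) {
  if (length(sessions) < 2L) stop("need >= 2 sessions")
  if (anyDuplicated(names(sessions)))
    stop("sessions must be distinct (a session cannot be paired with itself)")
  tot_conn <- 0L; tot_pairs <- 0L
  withr::with_seed(seed, {
    for (s in seq_along(sessions)) {
      this <- sessions[[s]]
      others <- sessions[-s]
      pool_trains <- do.call(c, lapply(others, `[[`, "bin_trains"))
      pool_dv <- unlist(lapply(others, `[[`, "dv_um"))
      pool_bin <- pmin(floor(pool_dv / depth_bin_um), n_depth_bins - 1L)
      this_bin <- pmin(floor(this$dv_um / depth_bin_um), n_depth_bins - 1L)
      pick <- integer(0)
      for (b in unique(this_bin)) {
        need <- sum(this_bin == b)
        cand <- which(pool_bin == b)
        if (length(cand) == 0L) cand <- seq_along(pool_bin)
        replace <- length(cand) < need
        if (replace)
          warning("depth bin ", b, " unfillable without replacement")
        pick <- c(pick, sample(cand, need, replace = replace))
      }
      m_min <- min(vapply(pool_trains[pick], length, 0L))
      surr <- lapply(pool_trains[pick], function(tt) {
        out <- tt[seq_len(m_min)]
        attr(out, "n_bins") <- attr(tt, "n_bins")
        out
      })
      names(surr) <- paste0("surr", seq_along(surr))
      det <- detect_connections(surr, ...)
      tot_conn <- tot_conn + nrow(det$connections)
      tot_pairs <- tot_pairs + det$n_assessed
    }
  })
  list(fpr_pct = 100 * tot_conn / tot_pairs, n_connections = tot_conn,
       n_assessed = tot_pairs)
}

#' Connectivity matrices between functional subpopulations
#'
#' @param connections Connection data.frame (from [detect_connections()]).
#' @param classes Named character vector mapping neuron id to functional
#'   class (e.g. `"V"`, `"A"`, `"D"` delay-selective, `"M-D"` multisensory
#'   non-delay-selective).
#' @param class_levels Order of classes in the matrices.
#' @return List: `pct` (percentage of assessed ordered pairs connected,
#'   source class in rows, target in columns), `counts`, `assessed`,
#'   `input_budget_pct` (percentage of summed incoming interaction strength
#'   per target class, by source class).
#' @export
class_connectivity <- function(connections, classes,
                               class_levels = sort(unique(classes))) {
  cl <- factor(classes, levels = class_levels)
  tab_n <- table(cl)
  # assessed ordered pairs between classes (within one population)
  assessed <- outer(tab_n, tab_n)
  diag(assessed) <- tab_n * (pmax(tab_n - 1L, 0L))
  counts <- matrix(0, length(class_levels), length(class_levels),
                   dimnames = list(class_levels, class_levels))
  budget <- counts
  if (nrow(connections)) {
    pre_cl <- as.character(cl[match(connections$pre, names(classes))])
    post_cl <- as.character(cl[match(connections$post, names(classes))])
    for (k in seq_len(nrow(connections))) {
      counts[pre_cl[k], post_cl[k]] <- counts[pre_cl[k], post_cl[k]] + 1
      budget[pre_cl[k], post_cl[k]] <- budget[pre_cl[k], post_cl[k]] +
        connections$strength[k]
    }
  }
  pct <- 100 * counts / assessed
  pct[assessed == 0] <- NA
  tot_in <- colSums(budget)
  budget_pct <- 100 * sweep(budget, 2L, ifelse(tot_in > 0, tot_in, NA),
                            "/")
  list(pct = pct, counts = counts, assessed = assessed,
       input_budget_pct = budget_pct)
}

# Signed Cochran-Armitage trend z for binned binary outcomes.
# x: successes per bin, n: totals per bin, s: bin scores.
.ca_trend_z <- function(x, n, s) {
  N <- sum(n); pbar <- sum(x) / N
  num <- sum(s * (x - n * pbar))
  den <- sqrt(pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / N))
  num / den
}

#' Receptive-field-similarity trend in connection probability
#'
#' Bins neuron pairs by their multisensory RF signal correlation
#' (equal-count bins), computes the proportion of connected pairs per bin,
#' and evaluates a Cochran--Armitage trend (scores = per-bin mean
#' correlation).  Significance comes from a permutation null: signal
#' correlations are shuffled within sessions `n_shuffle` times (bin edges
#' and scores held fixed) and the one-sided p-value is
#' `(k + 1) / (n_shuffle + 1)`.
#'
#' @param pairs Data.frame with columns `session`, `signal_corr`,
#'   `connected` (logical).
#' @param n_bins Number of correlation bins (default 5).
#' @param n_shuffle Permutations (default 1000).
#' @param seed Seed.
#' @return List: `statistic` (trend z), `p`, `bin_prop` (connection
#'   proportion per bin), `bin_scores`, `bin_n`.
#' @export
rf_similarity_trend <- function(pairs, n_bins = 5, n_shuffle = 1000,
                                seed = 1L) {
  sc <- pairs$signal_corr
  if (length(unique(sc)) < 2L) stop("all pairs share one correlation value")
  qs <- quantile(sc, probs = seq(0, 1, length.out = n_bins + 1L),
                 names = FALSE)
  qs[1L] <- -Inf; qs[n_bins + 1L] <- Inf
  bin <- cut(sc, qs, labels = FALSE)
  if (length(unique(bin)) < 2L) stop("fewer than 2 populated bins")
  scores <- tapply(sc, bin, mean)
  tab <- function(b) {
    x <- tapply(pairs$connected, b, sum)
    n <- tapply(rep(1L, length(b)), b, sum)
    list(x = as.numeric(x), n = as.numeric(n))
  }
  tt <- tab(bin)
  obs <- .ca_trend_z(tt$x, tt$n, scores)
  perm <- withr::with_seed(seed, vapply(seq_len(n_shuffle), function(r) {
    sc_sh <- ave(sc, pairs$session, FUN = sample)
    bin_sh <- cut(sc_sh, qs, labels = FALSE)
    ts <- tapply(pairs$connected, bin_sh, sum)
    ns <- tapply(rep(1L, length(bin_sh)), bin_sh, sum)
    keep <- !is.na(ts)
    .ca_trend_z(as.numeric(ts[keep]), as.numeric(ns[keep]),
                scores[as.integer(names(ts))[keep]])
  }, 0))
  p <- (1 + sum(perm >= obs)) / (n_shuffle + 1)
  list(statistic = obs, p = p, bin_prop = tt$x / tt$n,
       bin_scores = as.numeric(scores), bin_n = tt$n)
}
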