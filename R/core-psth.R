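# Trial slicing, PSTH computation, peak rate and latency-to-peak.

#' Re-reference spike times to per-trial stimulus onsets
#'
#' For each trial the spike times are expressed relative to the alignment
#' onset and restricted to `[window_ms[1], window_ms[2])`.  Alignment
#' `"stimulus"` uses the trial onset (first stimulus); `"visual"` and
#' `"auditory"` use the onset of the respective modality, which for
#' multisensory trials differs from the trial onset by the AV delay (auditory
#' onset is `onset + d` for visual-leading delays `d > 0`, and the visual
#' onset is `onset + |d|` for auditory-leading delays `d < 0`).
#'
#' @param train A `spike_train` (or bare numeric vector of spike times in ms).
#' @param events An `event_table` (rows define the trials to slice).
#' @param window_ms Length-2 numeric `(start, stop)` relative to the alignment
#'   onset, `start < stop`.
#' @param align `"stimulus"`, `"visual"` or `"auditory"`.
#' @return A list with one numeric vector of re-referenced spike times per
#'   trial, in trial order.
#' @export
#' @examples
#' ev <- event_table(1, "V", onset_ms = 1000)
#' slice_trials(spike_train(c(1005, 1100), "n"), ev, c(0, 250))
slice_trials <- function(train, events, window_ms,
                         align = c("stimulus", "visual", "auditory")) {
  align <- match.arg(align)
  if (window_ms[1L] >= window_ms[2L]) stop("window start must be < stop")
  if (nrow(events) == 0L) stop("events is empty")
  times <- if (inherits(train, "spike_train")) train$spike_times else
    as.numeric(train)
  d <- ifelse(is.na(events$av_delay_ms), 0, events$av_delay_ms)
  ref <- switch(align,
    stimulus = events$onset_ms,
    visual   = events$onset_ms + pmax(-d, 0),
    auditory = events$onset_ms + pmax(d, 0))
  lo <- findInterval(ref + window_ms[1L], times, left.open = TRUE)
  hi <- findInterval(ref + window_ms[2L], times, left.open = TRUE)
  lapply(seq_along(ref), function(i) {
    if (hi[i] <= lo[i]) numeric(0)
    else times[(lo[i] + 1L):hi[i]] - ref[i]
  })
}

#' Per-trial spike-count matrix
#'
#' Bins sliced trials into a trials-by-bins count matrix with left-closed,
#' right-open uniform bins.  This is the workhorse representation for the
#' permutation tests and the decoder features.
#'
#' @param sliced List of per-trial spike-time vectors (from [slice_trials()]),
#'   already relative to the alignment onset.
#' @param bin_width_ms Bin width in ms; must divide the window length.
#' @param window_ms Length-2 window `(start, stop)` in ms.
#' @return Integer matrix, `length(sliced)` rows, one column per bin.
#' @export
trial_count_matrix <- function(sliced, bin_width_ms, window_ms) {
  len <- window_ms[2L] - window_ms[1L]
  nb <- len / bin_width_ms
  if (abs(nb - round(nb)) > 1e-9) stop("bin width must divide window length")
  nb <- as.integer(round(nb))
  edges <- window_ms[1L] + bin_width_ms * (0:nb)
  m <- matrix(0L, nrow = length(sliced), ncol = nb)
  for (i in seq_along(sliced)) {
    t <- sliced[[i]]
    t <- t[t >= window_ms[1L] & t < window_ms[2L]]
    if (length(t)) {
      idx <- floor((t - window_ms[1L]) / bin_width_ms) + 1
      tb <- tabulate(idx, nbins = nb)
      m[i, ] <- tb
    }
  }
  m
}

#' Compute a peristimulus time histogram
#'
#' Trial-averaged firing rate per bin:
#' `rate_hz[b] = total count in bin b across trials / (n_reps * bin_width_s)`.
#'
#' @inheritParams trial_count_matrix
#' @param condition,alignment Labels stored in the result.
#' @return A [psth] object.
#' @export
compute_psth <- function(sliced, bin_width_ms, window_ms,
                         condition = NA_character_, alignment = "stimulus") {
  if (length(sliced) == 0L) stop("no repetitions")
  m <- trial_count_matrix(sliced, bin_width_ms, window_ms)
  rate <- colSums(m) / (nrow(m) * bin_width_ms / 1000)
  nb <- ncol(m)
  psth(bin_edges_ms = window_ms[1L] + bin_width_ms * (0:nb), rate_hz = rate,
       n_reps = length(sliced), condition = condition, alignment = alignment)
}

# Averaging-window matrix: column j holds the weights of a `w`-bin window
# centred on bin j ([j - w/2, j + w/2 - 1]), clipped at the edges.
.window_mat <- function(nb, w = 20L) {
  W <- matrix(0, nb, nb)
  h <- w %/% 2L
  for (j in seq_len(nb)) {
    lo <- max(1L, j - h)
    hi <- min(nb, j + h - 1L)
    W[lo:hi, j] <- 1 / (hi - lo + 1L)
  }
  W
}

# Peak of one rate vector: the largest w-bin centred-window mean over all
# centres (windows clipped at the edges).  Equivalent to centring the window
# on the maximum of the 20 ms running-mean response profile, and robust to
# single-bin coincidences in sparse 1 ms histograms; ties break toward the
# earliest centre.
.peak_rate_vec <- function(rate, window_bins = 20L) {
  h <- window_bins %/% 2L
  n <- length(rate)
  cs <- c(0, cumsum(rate))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h - 1L, n)
  max((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Peak firing rate of a response profile
#'
#' The mean rate over the `window_ms` centred window at the maximum of the
#' windowed response profile, i.e. the largest 20 ms running-window mean
#' (windows clipped at the profile edges; ties broken toward the earliest
#' centre).  Centring on the windowed rather than the raw argmax makes the
#' statistic robust to single-bin spike coincidences in sparse 1 ms
#' histograms.  This 20 ms window peak is the single summary statistic used
#' by the responsiveness and delay-selectivity tests and by all tuning
#' indices.
#'
#' @param x A [psth] at 1 ms bins (or a bare rate vector at 1 ms bins).
#' @param window_ms Window length in ms (default 20).
#' @return Peak rate in Hz.  An all-zero profile returns 0 with attribute
#'   `silent = TRUE`.
#' @export
#' @examples
#' r <- numeric(250); r[70] <- 100
#' peak_firing_rate(r)  # 100 Hz spread over a 20 ms window -> 5 Hz
peak_firing_rate <- function(x, window_ms = 20) {
  rate <- if (inherits(x, "psth")) {
    if (abs(bin_width(x) - 1) > 1e-9)
      stop("peak_firing_rate expects 1 ms bins")
    x$rate_hz
  } else as.numeric(x)
  if (all(rate == 0)) return(structure(0, silent = TRUE))
  .peak_rate_vec(rate, window_bins = as.integer(window_ms))
}

#' Latency to peak of a unisensory response profile
#'
#' The latency is the left edge of the bin holding the maximum of a 1 ms
#' PSTH over `[0, 250)` ms.  The response phase is assigned by fixed windows:
#' visual onset `[0, 128]` ms / offset `[129, 250)` ms; auditory onset
#' `[0, 76]` ms / offset `[77, 250)` ms.
#'
#' @param x A [psth] at 1 ms bins covering `[0, 250)` ms.
#' @param modality `"V"` or `"A"` (determines the onset/offset windows).
#' @param onset_end_ms Override for the end of the onset window (ms).
#' @return A list with `latency_ms`, `phase` (`"onset"`/`"offset"`) and
#'   `modality`; a flat profile gives `latency_ms = NA` and `phase = NA` with
#'   `flat = TRUE`.
#' @export
estimate_latency <- function(x, modality = c("V", "A"), onset_end_ms = NULL) {
  modality <- match.arg(modality)
  if (!inherits(x, "psth")) stop("x must be a psth")
  if (abs(bin_width(x) - 1) > 1e-9) stop("estimate_latency expects 1 ms bins")
  if (x$bin_edges_ms[1L] > 0 ||
      x$bin_edges_ms[length(x$bin_edges_ms)] < 250)
    stop("psth must cover [0, 250) ms")
  keep <- head(x$bin_edges_ms, -1L) >= 0 & head(x$bin_edges_ms, -1L) < 250
  rate <- x$rate_hz[keep]
  left <- head(x$bin_edges_ms, -1L)[keep]
  if (diff(range(rate)) == 0)
    return(list(latency_ms = NA_real_, phase = NA_character_,
                modality = modality, flat = TRUE))
  if (is.null(onset_end_ms)) onset_end_ms <- if (modality == "V") 128 else 76
  lat <- left[which.max(rate)]
  list(latency_ms = lat,
       phase = if (lat <= onset_end_ms) "onset" else "offset",
       modality = modality, flat = FALSE)
}
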