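# Domain containers: spike trains, event tables, PSTHs.

#' Construct a spike train
#'
#' A spike train holds the sorted spike times of one neuron on the session
#' clock (milliseconds), together with its identity within the nested
#' recording structure (neuron within session within animal) and, optionally,
#' its anatomical position.
#'
#' @param spike_times Numeric vector of spike times in ms, non-decreasing,
#'   all `>= 0`.
#' @param neuron_id,session_id,animal_id Opaque identifiers (coerced to
#'   character).
#' @param position Either `NULL` (unknown) or a numeric vector of length 3,
#'   `c(ml, ap, dv)`: medio-lateral distance from the midline (um),
#'   antero-posterior distance from bregma (um), and dorso-ventral depth (um,
#'   `>= 0`).  Neurons without a position stay in tuning and decoding
#'   analyses but are excluded from anatomical binning.
#' @param baseline_rate Cached baseline firing rate in spikes/s (computed over
#'   inter-trial windows), or `NA` if not yet derived.
#'
#' @return An object of class `spike_train`.
#' @export
#' @examples
#' st <- spike_train(c(10, 250, 251.5), neuron_id = "n1")
#' n_spikes(st)
spike_train <- function(spike_times, neuron_id, session_id = "s1",
                        animal_id = "a1", position = NULL,
                        baseline_rate = NA_real_) {
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times)) stop("spike_times must not contain NA")
  if (length(spike_times) && (is.unsorted(spike_times) || spike_times[1L] < 0))
    stop("spike_times must be non-decreasing and >= 0")
  if (!is.null(position)) {
    position <- as.numeric(position)
    if (length(position) != 3L || !all(is.finite(position)))
      stop("position must be c(ml, ap, dv) with finite components")
    if (position[3L] < 0) stop("DV depth must be >= 0")
    names(position) <- c("ml", "ap", "dv")
  }
  structure(
    list(neuron_id = as.character(neuron_id),
         session_id = as.character(session_id),
         animal_id = as.character(animal_id),
         spike_times = spike_times,
         position = position,
         baseline_rate = as.numeric(baseline_rate)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  pos <- if (is.null(x$position)) "unknown position"
  else sprintf("ML %.0f, AP %.0f, DV %.0f um", x$position[1L],
               x$position[2L], x$position[3L])
  cat(sprintf("<spike_train %s (%s/%s): %d spikes, %s>\n", x$neuron_id,
              x$animal_id, x$session_id, length(x$spike_times), pos))
  invisible(x)
}

#' Number of spikes in a spike train
#' @param x A `spike_train`.
#' @return Integer count.
#' @export
n_spikes <- function(x) length(x$spike_times)

#' Construct a stimulus event table
#'
#' One row per trial, in presentation order.  `modality` is one of `"V"`,
#' `"A"`, `"AV"`, `"BLANK"` (the synthetic decoding class `"A_SHIFT"` never
#' appears in recorded tables).  `av_delay_ms` is the auditory-minus-visual
#' onset asynchrony and must be present exactly for multisensory trials;
#' positive values mean visual leads.  `onset_ms` is the onset of the first
#' stimulus of the trial.
#'
#' @param trial Integer trial indices (strictly increasing).
#' @param modality Character vector of condition modalities.
#' @param onset_ms Trial onset times in ms, strictly increasing with trial.
#' @param duration_ms Stimulus duration (default 100 ms).
#' @param av_delay_ms Integer AV delays in ms; `NA` for non-multisensory
#'   trials.
#' @param azimuth_deg,elevation_deg Stimulus location in degrees (`NA` when a
#'   single location was used).  Contralateral azimuths are negative.
#' @param min_iti_ms Minimum allowed inter-onset interval; the default 2000 ms
#'   guarantees that a 1--2 s post-onset correlogram window never overlaps the
#'   next trial.  Lower it explicitly for truncated tables.
#' @param truncated Set `TRUE` to skip the equal-repetition check (e.g. for a
#'   session cut short).
#'
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(trial, modality, onset_ms, duration_ms = 100,
                        av_delay_ms = NA_integer_, azimuth_deg = NA_real_,
                        elevation_deg = NA_real_, min_iti_ms = 2000,
                        truncated = FALSE) {
  df <- data.frame(trial = as.integer(trial),
                   modality = as.character(modality),
                   av_delay_ms = as.integer(av_delay_ms),
                   azimuth_deg = as.numeric(azimuth_deg),
                   elevation_deg = as.numeric(elevation_deg),
                   onset_ms = as.numeric(onset_ms),
                   duration_ms = as.numeric(duration_ms))
  validate_event_table(df, min_iti_ms = min_iti_ms, truncated = truncated)
  structure(df, class = c("event_table", "data.frame"),
            truncated = truncated)
}

validate_event_table <- function(df, min_iti_ms = 2000, truncated = FALSE) {
  stopifnot(all(c("trial", "modality", "av_delay_ms", "onset_ms",
                  "duration_ms") %in% names(df)))
  bad <- setdiff(unique(df$modality), c("V", "A", "AV", "A_SHIFT", "BLANK"))
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "))
  if (any(df$modality == "A_SHIFT"))
    stop("A_SHIFT is a synthetic decoding class, not a recorded condition")
  o <- order(df$trial)
  if (is.unsorted(df$onset_ms[o], strictly = TRUE))
    stop("onset_ms must be strictly increasing with trial")
  iti <- diff(df$onset_ms[o])
  if (length(iti) && min(iti) < min_iti_ms)
    stop(sprintf("inter-onset interval %.0f ms below minimum %.0f ms",
                 min(iti), min_iti_ms))
  multi <- df$modality == "AV"
  if (any(multi & is.na(df$av_delay_ms)))
    stop("av_delay_ms missing for multisensory trials")
  if (any(!multi & !is.na(df$av_delay_ms)))
    stop("av_delay_ms must be absent for non-multisensory trials")
  if (!truncated) {
    key <- condition_key(df)
    reps <- table(key)
    if (length(unique(reps)) > 1L)
      stop("unequal repetition counts per condition; ",
           "pass truncated = TRUE if the table was cut short")
  }
  invisible(df)
}

#' Condition key for an event table
#'
#' Collapses modality, AV delay and (when present) stimulus location into one
#' label per condition, e.g. `"AV_50"` or `"V@-90/0"`.
#'
#' @param events An `event_table` (or compatible data.frame).
#' @return Character vector, one entry per trial.
#' @export
condition_key <- function(events) {
  key <- events$modality
  i <- !is.na(events$av_delay_ms)
  key[i] <- paste0(key[i], "_", events$av_delay_ms[i])
  if (!is.null(events$azimuth_deg) && any(!is.na(events$azimuth_deg))) {
    j <- !is.na(events$azimuth_deg)
    key[j] <- paste0(key[j], "@", events$azimuth_deg[j], "/",
                     events$elevation_deg[j])
  }
  key
}

#' Subset an event table to one condition
#'
#' @param events An `event_table`.
#' @param modality Condition modality (`"V"`, `"A"`, `"AV"`, `"BLANK"`).
#' @param av_delay_ms For `"AV"`, the delay to select (omit for all delays).
#' @return The matching rows, trial order preserved.
#' @export
select_trials <- function(events, modality, av_delay_ms = NULL) {
  i <- events$modality == modality
  if (!is.null(av_delay_ms))
    i <- i & !is.na(events$av_delay_ms) & events$av_delay_ms == av_delay_ms
  events[i, , drop = FALSE]
}

#' Construct a peristimulus time histogram
#'
#' @param bin_edges_ms Uniform, increasing bin edges in ms (left-closed,
#'   right-open bins), relative to the alignment onset.
#' @param rate_hz Trial-averaged firing rate per bin (spikes/s, `>= 0`);
#'   length `length(bin_edges_ms) - 1`.
#' @param n_reps Number of repetitions averaged.
#' @param condition Condition label (free-form).
#' @param alignment Which stimulus onset defines t = 0 (`"stimulus"`,
#'   `"visual"` or `"auditory"`).
#' @return An object of class `psth`.
#' @export
psth <- function(bin_edges_ms, rate_hz, n_reps = NA_integer_,
                 condition = NA_character_, alignment = "stimulus") {
  bin_edges_ms <- as.numeric(bin_edges_ms)
  rate_hz <- as.numeric(rate_hz)
  w <- diff(bin_edges_ms)
  if (length(rate_hz) != length(bin_edges_ms) - 1L)
    stop("rate_hz must have one entry per bin")
  if (any(w <= 0) || diff(range(w)) > 1e-9 * w[1L])
    stop("bin edges must be uniform and increasing")
  if (any(rate_hz < 0)) stop("rate_hz must be >= 0")
  structure(list(bin_edges_ms = bin_edges_ms, rate_hz = rate_hz,
                 n_reps = as.integer(n_reps), condition = condition,
                 alignment = alignment),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth %s: [%g, %g) ms, %g ms bins, %s reps, peak %.1f Hz>\n",
              x$condition, x$bin_edges_ms[1L],
              x$bin_edges_ms[length(x$bin_edges_ms)],
              diff(x$bin_edges_ms[1:2]), x$n_reps, max(x$rate_hz)))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  mids <- head(x$bin_edges_ms, -1L) + diff(x$bin_edges_ms) / 2
  graphics::plot(mids, x$rate_hz, type = "s", xlab = "time (ms)",
                 ylab = "rate (Hz)", main = x$condition, ...)
  invisible(x)
}

#' Bin width of a PSTH in ms
#' @param x A `psth`.
#' @return Scalar bin width.
#' @export
bin_width <- function(x) diff(x$bin_edges_ms[1:2])
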