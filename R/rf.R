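# Spatial receptive-field estimation on the 5 x 7 stimulation grid and
# alignment statistics between modalities.

#' Fit a 2D Gaussian receptive field
#'
#' Least-squares fit of an axis-aligned two-dimensional Gaussian plus offset
#' to the peak firing rates measured on the azimuth/elevation grid,
#' initialised at the rate-weighted centroid with 18 deg widths.  The centre
#' is constrained to the grid extended by one step (18 deg) on each side.
#'
#' @param rates Peak firing rate per grid location (Hz).
#' @param azimuth_deg,elevation_deg Location coordinates (same length as
#'   `rates`).
#' @param grid_step_deg Grid spacing (default 18 deg), used for the centre
#'   bounds and width floor.
#' @return List of class `rf_fit`: `amplitude`, `centre_az`, `centre_el`,
#'   `sigma_az`, `sigma_el`, `offset`, `residual` (RMS), `converged`.
#'   A flat map returns `converged = FALSE` with undefined centre.
#' @export
fit_rf <- function(rates, azimuth_deg, elevation_deg, grid_step_deg = 18) {
  stopifnot(length(rates) == length(azimuth_deg),
            length(rates) == length(elevation_deg))
  if (!any(rates > 0) || diff(range(rates)) == 0)
    return(structure(list(amplitude = NA_real_, centre_az = NA_real_,
                          centre_el = NA_real_, sigma_az = NA_real_,
                          sigma_el = NA_real_, offset = mean(rates),
                          residual = 0, converged = FALSE),
                     class = "rf_fit"))
  w <- pmax(rates - min(rates), 0)
  cx <- sum(w * azimuth_deg) / sum(w)
  cy <- sum(w * elevation_deg) / sum(w)
  p0 <- c(amp = max(rates) - min(rates), cx = cx, cy = cy,
          sx = grid_step_deg, sy = grid_step_deg, off = min(rates))
  lo <- c(0, min(azimuth_deg) - grid_step_deg,
          min(elevation_deg) - grid_step_deg, grid_step_deg / 4,
          grid_step_deg / 4, -max(rates))
  hi <- c(10 * max(rates), max(azimuth_deg) + grid_step_deg,
          max(elevation_deg) + grid_step_deg, 10 * grid_step_deg,
          10 * grid_step_deg, max(rates))
  model <- function(p)
    p[1L] * exp(-((azimuth_deg - p[2L])^2 / (2 * p[4L]^2) +
                    (elevation_deg - p[3L])^2 / (2 * p[5L]^2))) + p[6L]
  obj <- function(p) sum((rates - model(p))^2)
  fit <- optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = 500))
  structure(list(amplitude = fit$par[[1L]], centre_az = fit$par[[2L]],
                 centre_el = fit$par[[3L]], sigma_az = fit$par[[4L]],
                 sigma_el = fit$par[[5L]], offset = fit$par[[6L]],
                 residual = sqrt(fit$value / length(rates)),
                 converged = fit$convergence == 0 && fit$par[[1L]] > 0),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  if (!x$converged) cat("<rf_fit: not converged>\n")
  else cat(sprintf(
    "<rf_fit: centre (%.1f, %.1f) deg, sigma (%.1f, %.1f), amp %.1f Hz>\n",
    x$centre_az, x$centre_el, x$sigma_az, x$sigma_el, x$amplitude))
  invisible(x)
}

#' Per-neuron grid response maps and receptive-field fits
#'
#' Computes, for each neuron and each modality present, the 20 ms peak
#' firing rate at every grid location and fits the 2D Gaussian.
#'
#' @param session An `av_session` recorded with the RF protocol.
#' @param modalities Modalities to map (default `c("V", "A", "AV")`).
#' @param window_ms Response window.
#' @return List: `maps` (data.frame `neuron_id, modality, azimuth_deg,
#'   elevation_deg, peak_hz`), `fits` (data.frame of fit parameters per
#'   neuron and modality).
#' @export
map_receptive_fields <- function(session, modalities = c("V", "A", "AV"),
                                 window_ms = c(0, 250)) {
  events <- session$events
  locs <- unique(data.frame(az = events$azimuth_deg,
                            el = events$elevation_deg))
  locs <- locs[stats::complete.cases(locs), ]
  maps <- list(); fits <- list()
  for (tr in session$spikes) {
    for (mod in modalities) {
      peaks <- vapply(seq_len(nrow(locs)), function(k) {
        ev <- events[events$modality == mod &
                       events$azimuth_deg == locs$az[k] &
                       events$elevation_deg == locs$el[k], , drop = FALSE]
        if (!nrow(ev)) return(NA_real_)
        as.numeric(peak_firing_rate(compute_psth(
          slice_trials(tr, ev, window_ms), 1, window_ms)))
      }, 0)
      maps[[paste(tr$neuron_id, mod)]] <- data.frame(
        neuron_id = tr$neuron_id, modality = mod,
        azimuth_deg = locs$az, elevation_deg = locs$el, peak_hz = peaks,
        stringsAsFactors = FALSE)
      f <- fit_rf(peaks, locs$az, locs$el)
      fits[[paste(tr$neuron_id, mod)]] <- data.frame(
        neuron_id = tr$neuron_id, modality = mod,
        amplitude = f$amplitude, centre_az = f$centre_az,
        centre_el = f$centre_el, sigma_az = f$sigma_az,
        sigma_el = f$sigma_el, offset = f$offset, residual = f$residual,
        converged = f$converged, stringsAsFactors = FALSE)
    }
  }
  list(maps = do.call(rbind, maps), fits = do.call(rbind, fits))
}

#' Visual/auditory receptive-field alignment
#'
#' Pearson correlation between visual and auditory RF centres (azimuth and
#' elevation separately), at the neuron level and at the session level
#' (session means of the paired centres), restricted to converged fits.
#' Session-level 90% confidence ellipses of the mean centre (chi-squared,
#' 2 df) are returned as per-session semi-axes.
#'
#' @param fits The `fits` data.frame from [map_receptive_fields()] with a
#'   `session_id` column (added automatically for single sessions).
#' @return List of class `rf_alignment`: `neuron` and `session` sub-lists
#'   with `azimuth`/`elevation` entries (`r`, `p`, `n`), plus
#'   `insufficient` when fewer than 3 pairs survive filtering.
#' @export
rf_alignment <- function(fits) {
  if (is.null(fits$session_id)) fits$session_id <- "s1"
  v <- fits[fits$modality == "V" & fits$converged, ]
  a <- fits[fits$modality == "A" & fits$converged, ]
  m <- merge(v, a, by = c("neuron_id", "session_id"),
             suffixes = c("_v", "_a"))
  if (nrow(m) < 3L)
    return(structure(list(insufficient = TRUE, n = nrow(m)),
                     class = "rf_alignment"))
  ct <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_, n = length(x)))
    h <- cor.test(x, y)
    list(r = unname(h$estimate), p = h$p.value, n = length(x))
  }
  ses <- do.call(rbind, lapply(split(m, m$session_id), function(d) {
    n <- nrow(d)
    cov_v <- stats::cov(cbind(d$centre_az_v, d$centre_el_v)) / n
    r90 <- sqrt(qchisq(0.90, df = 2))
    ev <- eigen(cov_v, symmetric = TRUE)$values
    data.frame(session_id = d$session_id[1L],
               az_v = mean(d$centre_az_v), el_v = mean(d$centre_el_v),
               az_a = mean(d$centre_az_a), el_a = mean(d$centre_el_a),
               ellipse_major = r90 * sqrt(max(ev, 0)),
               ellipse_minor = r90 * sqrt(max(min(ev), 0)), n = n)
  }))
  structure(list(
    insufficient = FALSE,
    neuron = list(azimuth = ct(m$centre_az_v, m$centre_az_a),
                  elevation = ct(m$centre_el_v, m$centre_el_a)),
    session = if (nrow(ses) >= 3L)
      list(azimuth = ct(ses$az_v, ses$az_a),
           elevation = ct(ses$el_v, ses$el_a))
    else list(insufficient = TRUE, n = nrow(ses)),
    session_means = ses), class = "rf_alignment")
}

#' Spatial signal correlation between two multisensory response profiles
#'
#' Pearson correlation over the grid locations of the two neurons'
#' multisensory (AV) response maps.
#'
#' @param profile1,profile2 Peak-rate vectors over the same grid locations.
#' @return Correlation in `[-1, 1]`; `NA` (pair excluded downstream) when a
#'   profile has zero variance.
#' @export
rf_signal_correlation <- function(profile1, profile2) {
  if (length(profile1) != length(profile2))
    stop("profiles must cover the same grid")
  if (sd(profile1) == 0 || sd(profile2) == 0) return(NA_real_)
  cor(profile1, profile2)
}
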