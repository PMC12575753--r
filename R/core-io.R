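# Readers and writers for spike and event data.
#
# Two dialects are supported: plain tabular CSV (spikes / neurons / events)
# and a Kilosort/Phy-style directory (spike_times.npy, spike_clusters.npy,
# cluster_info.tsv).  A minimal .npy (format v1.0, 1-D arrays) reader/writer
# is included because the Phy dialect stores arrays in that format.

#' Read a 1-D array from a .npy file
#'
#' Supports format version 1.0, C-order one-dimensional arrays of dtypes
#' `<f8`, `<f4`, `<i8`, `<i4`, `<u8`, `<u4` -- the types produced by
#' Kilosort/Phy for spike times and cluster assignments.
#'
#' @param path Path to the `.npy` file.
#' @return A numeric (or integer) vector.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, utf8ToInt("NUMPY")))))
    stop("not a .npy file: ", path)
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1L]) == 1L)
    readBin(con, "integer", 1L, size = 2L, endian = "little")
  else readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  if (grepl("'fortran_order':\\s*True", header))
    stop("fortran-order .npy arrays are not supported")
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape), ",")[[1]])
  if (length(dims) != 1L) stop("only 1-D .npy arrays are supported")
  n <- dims[1L]
  out <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8L, endian = "little",
                    signed = TRUE),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<u8" = ,
    "<i8_" = stop("unsupported dtype: ", descr),
    "<u4" = readBin(con, "double", n, size = 4L, endian = "little",
                    signed = FALSE),
    stop("unsupported dtype: ", descr))
  if (descr == "<i8") { # readBin has no 8-byte integer; reread as double bits
    con2 <- file(path, "rb")
    on.exit(close(con2), add = TRUE)
    readBin(con2, "raw", 10L + hlen)
    raw8 <- readBin(con2, "raw", n * 8L)
    out <- .int64_le_to_double(raw8)
  }
  if (length(out) != n) stop("truncated .npy file: ", path)
  out
}

# Interpret little-endian int64 bytes as doubles (exact below 2^53).
.int64_le_to_double <- function(raw8) {
  m <- matrix(as.integer(raw8), nrow = 8L)
  lo <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536 + m[4, ] * 16777216
  hi <- m[5, ] + m[6, ] * 256 + m[7, ] * 65536 + m[8, ] * 16777216
  neg <- m[8, ] >= 128
  v <- lo + hi * 4294967296
  v[neg] <- v[neg] - 18446744073709551616
  v
}

#' Write a 1-D array to a .npy file
#'
#' Writes format version 1.0 with dtype `<f8` (numeric) or `<i4` (integer).
#'
#' @param x Numeric or integer vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  descr <- if (is.integer(x)) "<i4" else "<f8"
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%d,), }",
                    descr, length(x))
  total <- 10L + nchar(header) + 1L # magic+ver+len, header, newline
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), as.raw(utf8ToInt("NUMPY")), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  if (is.integer(x)) writeBin(x, con, size = 4L, endian = "little")
  else writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read sorted spike data
#'
#' @param path Directory containing the data.
#' @param dialect `"tabular"`: `spikes.csv` (`neuron_id, t_ms`) and
#'   `neurons.csv` (`neuron_id, session_id, animal_id, ml_um, ap_um, dv_um`).
#'   `"phy"`: Kilosort/Phy output -- `spike_times.npy` (samples),
#'   `spike_clusters.npy`, and `cluster_info.tsv` with columns `cluster_id`,
#'   `group` (only `"good"` clusters are kept) and, optionally, `ml_um`,
#'   `ap_um`, `dv_um`.
#' @param sampling_rate_hz Sampling rate used to convert Phy sample indices to
#'   ms; if `NULL`, parsed from `params.py` (`sample_rate = ...`).
#' @return A named list of [spike_train] objects, ordered by `neuron_id`.
#' @export
read_spike_data <- function(path, dialect = c("tabular", "phy"),
                            sampling_rate_hz = NULL) {
  dialect <- match.arg(dialect)
  if (!dir.exists(path)) stop("directory not found: ", path)
  if (dialect == "tabular") .read_tabular(path) else
    .read_phy(path, sampling_rate_hz)
}

.require_file <- function(path, name) {
  f <- file.path(path, name)
  if (!file.exists(f)) stop("missing file: ", f)
  f
}

.read_tabular <- function(path) {
  spikes <- read.csv(.require_file(path, "spikes.csv"),
                     stringsAsFactors = FALSE)
  neurons <- read.csv(.require_file(path, "neurons.csv"),
                      stringsAsFactors = FALSE)
  .assemble_trains(spikes$neuron_id, spikes$t_ms, neurons)
}

.read_phy <- function(path, sampling_rate_hz) {
  st <- read_npy(.require_file(path, "spike_times.npy"))
  cl <- read_npy(.require_file(path, "spike_clusters.npy"))
  info <- read.delim(.require_file(path, "cluster_info.tsv"),
                     stringsAsFactors = FALSE)
  if (is.null(sampling_rate_hz)) {
    pf <- file.path(path, "params.py")
    if (!file.exists(pf))
      stop("sampling_rate_hz not given and params.py missing")
    ln <- grep("sample_rate", readLines(pf), value = TRUE)[1L]
    sampling_rate_hz <- as.numeric(sub(".*=\\s*", "", ln))
  }
  good <- info[info$group == "good", , drop = FALSE]
  keep <- cl %in% good$cluster_id
  t_ms <- st[keep] / sampling_rate_hz * 1000
  n_good <- nrow(good)
  col_or <- function(nm, default)
    if (nm %in% names(good)) good[[nm]] else rep(default, n_good)
  neurons <- data.frame(neuron_id = as.character(good$cluster_id),
                        session_id = col_or("session_id", "s1"),
                        animal_id = col_or("animal_id", "a1"),
                        ml_um = col_or("ml_um", NA_real_),
                        ap_um = col_or("ap_um", NA_real_),
                        dv_um = col_or("dv_um", NA_real_),
                        stringsAsFactors = FALSE)
  .assemble_trains(as.character(cl[keep]), t_ms, neurons)
}

.assemble_trains <- function(neuron_id, t_ms, neurons) {
  neurons$neuron_id <- as.character(neurons$neuron_id)
  neurons <- neurons[order(neurons$neuron_id), , drop = FALSE]
  split_t <- split(t_ms, factor(as.character(neuron_id),
                                levels = neurons$neuron_id))
  miss <- is.na(neurons$ml_um) | is.na(neurons$ap_um) | is.na(neurons$dv_um)
  if (any(miss))
    warning(sum(miss), " neuron(s) lack coordinates; excluded from ",
            "anatomical analyses only")
  out <- lapply(seq_len(nrow(neurons)), function(i) {
    pos <- if (miss[i]) NULL else
      c(neurons$ml_um[i], neurons$ap_um[i], neurons$dv_um[i])
    spike_train(sort(split_t[[i]]), neuron_id = neurons$neuron_id[i],
                session_id = neurons$session_id[i],
                animal_id = neurons$animal_id[i], position = pos)
  })
  names(out) <- neurons$neuron_id
  out
}

#' Read an event table from CSV
#'
#' Expects columns `trial, modality, av_delay_ms, azimuth_deg, elevation_deg,
#' onset_ms, duration_ms`.
#'
#' @param path CSV file path.
#' @param min_iti_ms,truncated Passed to the [event_table()] validator.
#' @return An `event_table`.
#' @export
read_events <- function(path, min_iti_ms = 2000, truncated = FALSE) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  event_table(trial = df$trial, modality = df$modality,
              onset_ms = df$onset_ms, duration_ms = df$duration_ms,
              av_delay_ms = df$av_delay_ms, azimuth_deg = df$azimuth_deg,
              elevation_deg = df$elevation_deg, min_iti_ms = min_iti_ms,
              truncated = truncated)
}

#' Write a session to disk in the tabular dialect
#'
#' Writes `spikes.csv`, `neurons.csv`, `events.csv` and, if present,
#' `ground_truth.csv` (neuron-level planted parameters) and
#' `ground_truth_connections.csv`.  Integer columns round-trip bit-exactly.
#'
#' @param session An `av_session` (see [generate_session()]) or a list with
#'   elements `spikes` (list of [spike_train]) and `events`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spikes <- do.call(rbind, lapply(session$spikes, function(tr)
    if (n_spikes(tr)) data.frame(neuron_id = tr$neuron_id,
                                 t_ms = tr$spike_times) else NULL))
  write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  neurons <- do.call(rbind, lapply(session$spikes, function(tr) {
    pos <- if (is.null(tr$position)) c(NA_real_, NA_real_, NA_real_) else
      tr$position
    data.frame(neuron_id = tr$neuron_id, session_id = tr$session_id,
               animal_id = tr$animal_id, ml_um = pos[1L], ap_um = pos[2L],
               dv_um = pos[3L])
  }))
  write.csv(neurons, file.path(dir, "neurons.csv"), row.names = FALSE)
  write.csv(as.data.frame(session$events), file.path(dir, "events.csv"),
            row.names = FALSE)
  if (!is.null(session$ground_truth)) {
    write.csv(session$ground_truth$neurons,
              file.path(dir, "ground_truth.csv"), row.names = FALSE)
    if (!is.null(session$ground_truth$connections) &&
        nrow(session$ground_truth$connections))
      write.csv(session$ground_truth$connections,
                file.path(dir, "ground_truth_connections.csv"),
                row.names = FALSE)
  }
  invisible(dir)
}

#' Write a session as a Phy-style directory
#'
#' Companion to the `"phy"` dialect of [read_spike_data()]: writes
#' `spike_times.npy` (sample indices), `spike_clusters.npy`,
#' `cluster_info.tsv` and `params.py`.
#'
#' @inheritParams write_session
#' @param sampling_rate_hz Sampling rate used to convert ms to samples.
#' @return `dir`, invisibly.
#' @export
write_phy_dir <- function(session, dir, sampling_rate_hz = 30000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(session$spikes, `[[`, "", "neuron_id")
  cl <- rep(seq_along(ids) - 1L,
            vapply(session$spikes, n_spikes, 0L))
  t_all <- unlist(lapply(session$spikes, `[[`, "spike_times"))
  o <- order(t_all)
  write_npy(round(t_all[o] / 1000 * sampling_rate_hz), # sample indices
            file.path(dir, "spike_times.npy"))
  write_npy(as.integer(cl[o]), file.path(dir, "spike_clusters.npy"))
  info <- do.call(rbind, lapply(seq_along(session$spikes), function(i) {
    tr <- session$spikes[[i]]
    pos <- if (is.null(tr$position)) c(NA_real_, NA_real_, NA_real_) else
      tr$position
    data.frame(cluster_id = i - 1L, group = "good",
               session_id = tr$session_id, animal_id = tr$animal_id,
               ml_um = pos[1L], ap_um = pos[2L], dv_um = pos[3L])
  }))
  write.table(info, file.path(dir, "cluster_info.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeLines(sprintf("sample_rate = %g", sampling_rate_hz),
             file.path(dir, "params.py"))
  invisible(dir)
}
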