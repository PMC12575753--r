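# End-to-end orchestration: simulate (or load) -> classify -> delay tuning /
# receptive fields -> decoding -> connectivity, with CSV/JSON artifacts.

#' Pipeline configuration
#'
#' Collects the tunables of every stage with the package defaults.  A single
#' master seed fans out to per-stage child seeds ([child_seed()]) so stages
#' are individually reproducible.  Configurations are serialisable to YAML
#' and the resolved configuration is embedded in the output bundle.
#'
#' @param seed Master seed.
#' @param simulate Generate a synthetic session (`TRUE`) or read data from
#'   `input_dir`.
#' @param synth A [synth_config()] (when simulating).
#' @param input_dir,dialect Input location and dialect for recorded data.
#' @param stages Character vector of stages to run, in order, from
#'   `c("classify", "rf", "delays", "decode", "connectivity")`.
#' @param n_perm,n_boot Permutations for responsiveness / delay tests.
#' @param alpha Significance level (BH-adjusted) for classification.
#' @param classifier Decoder type (`"svm"` or `"rf"`).
#' @param decode_folds CV folds for the decoder.
#' @param ccg_window_ms Correlogram analysis window.
#' @param z_thresh Connection significance threshold (noise SDs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, simulate = TRUE,
                            synth = synth_config(seed = seed),
                            input_dir = NULL, dialect = "tabular",
                            stages = c("classify", "delays", "decode",
                                       "connectivity"),
                            n_perm = 1000, n_boot = 2000, alpha = 0.05,
                            classifier = "svm", decode_folds = 0,
                            ccg_window_ms = c(1000, 2000), z_thresh = 5) {
  structure(list(seed = as.integer(seed), simulate = simulate,
                 synth = synth, input_dir = input_dir, dialect = dialect,
                 stages = stages, n_perm = n_perm, n_boot = n_boot,
                 alpha = alpha, classifier = classifier,
                 decode_folds = decode_folds,
                 ccg_window_ms = ccg_window_ms, z_thresh = z_thresh),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] defaults; a `synth` mapping
#' overrides [synth_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sy <- do.call(synth_config, c(y$synth,
                                if (is.null(y$synth$seed))
                                  list(seed = y$seed %||% 1L)))
  y$synth <- NULL
  do.call(pipeline_config, c(y, list(synth = sy)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the configured stages and writes the artifacts (`neuron_class
#' .csv`, `delay_tuning.csv`, `rf_fits.csv`, `decoding_results.csv`,
#' `connections.csv`, `summary.json`) to `out_dir`.  Reruns with an
#' identical configuration produce identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; `NULL` skips writing).
#' @return The report bundle (list), invisibly when writing.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  session <- if (isTRUE(config$simulate)) generate_session(config$synth)
  else {
    if (is.null(config$input_dir)) stop("input_dir required when not simulating")
    spikes <- read_spike_data(config$input_dir, config$dialect)
    events <- read_events(file.path(config$input_dir, "events.csv"))
    list(spikes = spikes, events = events,
         neurons = do.call(rbind, lapply(spikes, function(tr)
           data.frame(neuron_id = tr$neuron_id,
                      ml_um = if (is.null(tr$position)) NA else
                        tr$position[1L],
                      ap_um = if (is.null(tr$position)) NA else
                        tr$position[2L],
                      dv_um = if (is.null(tr$position)) NA else
                        tr$position[3L]))))
  }
  bundle <- list(config = config, counts = list(
    n_neurons = length(session$spikes), n_trials = nrow(session$events)))
  if ("classify" %in% config$stages) {
    bundle$neuron_class <- characterise_session(
      session, n_perm = config$n_perm, alpha = config$alpha,
      seed = child_seed(config$seed, "classify"))
    bundle$counts$per_class <- as.list(table(bundle$neuron_class$label))
  }
  if ("rf" %in% config$stages &&
      any(!is.na(session$events$azimuth_deg))) {
    rfm <- map_receptive_fields(session)
    bundle$rf_fits <- rfm$fits
    bundle$rf_maps <- rfm$maps
    bundle$rf_alignment <- rf_alignment(rfm$fits)
  }
  if ("delays" %in% config$stages &&
      any(!is.na(session$events$av_delay_ms))) {
    ids <- if (!is.null(bundle$neuron_class))
      bundle$neuron_class$neuron_id[bundle$neuron_class$label %in%
                                      c("visual", "auditory", "bimodal",
                                        "gated")]
    else names(session$spikes)
    bundle$delay_tuning <- delay_tuning(
      session, neuron_ids = ids, n_boot = config$n_boot,
      seed = child_seed(config$seed, "delays"))
    sel <- !is.na(bundle$delay_tuning$preferred_delay_ms)
    bundle$counts$pct_delay_selective <- 100 * mean(sel)
  }
  if ("decode" %in% config$stages &&
      any(!is.na(session$events$av_delay_ms))) {
    fe <- assemble_pseudopopulation(
      session, seed = child_seed(config$seed, "decode"))
    bundle$decoding <- train_and_score(
      fe, classifier = config$classifier, folds = config$decode_folds,
      seed = child_seed(config$seed, "decode_fit"))
    bundle$counts$av_delay_accuracy <- bundle$decoding$av_delay_accuracy
  }
  if ("connectivity" %in% config$stages) {
    responsive <- if (!is.null(bundle$neuron_class))
      setNames(bundle$neuron_class$label != "nonresponsive",
               bundle$neuron_class$neuron_id)
    else setNames(rep(TRUE, length(session$spikes)),
                  names(session$spikes))
    base <- vapply(session$spikes, function(tr) {
      bt <- ccg_bin_trials(tr, session$events, config$ccg_window_ms)
      sum(lengths(bt)) / (length(bt) * diff(config$ccg_window_ms) / 1000)
    }, 0)
    inc <- ccg_inclusion(responsive[names(session$spikes)], base)
    bts <- lapply(session$spikes[inc], ccg_bin_trials, session$events,
                  config$ccg_window_ms)
    bundle$connectivity <- detect_connections(bts,
                                              z_thresh = config$z_thresh)
    bundle$counts$connection_pct <- bundle$connectivity$connection_pct
  }
  if (!is.null(out_dir)) .write_bundle(bundle, session, out_dir)
  invisible(bundle)
}

.write_bundle <- function(bundle, session, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(bundle$neuron_class, "neuron_class.csv")
  wr(bundle$delay_tuning, "delay_tuning.csv")
  wr(bundle$rf_fits, "rf_fits.csv")
  if (!is.null(bundle$connectivity))
    wr(bundle$connectivity$connections, "connections.csv")
  if (!is.null(bundle$decoding))
    wr(as.data.frame(bundle$decoding$confusion), "confusion.csv")
  cfg <- bundle$config
  cfg$synth <- unclass(cfg$synth)
  summary <- list(counts = bundle$counts, config = unclass(cfg))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(out_dir)
}
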