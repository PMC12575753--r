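# Shared small synthetic sessions, built once per test run.

small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_session(synth_config(
        seed = 101,
        n_neurons = c(visual = 3, auditory = 3, bimodal = 4, gated = 1,
                      nonresponsive = 2),
        n_reps = 20, iti_ms = 2000))
    cache
  }
})

# brute-force windowed peak: loop over every candidate centre, average the
# w-bin centred window clipped at the edges, take the maximum (independent
# reimplementation for oracles)
brute_peak <- function(rate, w = 20) {
  max(vapply(seq_along(rate), function(j) {
    lo <- max(1, j - w %/% 2)
    hi <- min(length(rate), j + w %/% 2 - 1)
    mean(rate[lo:hi])
  }, 0))
}
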