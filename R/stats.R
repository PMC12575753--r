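# Hierarchical bootstrap for nested (animal / session / neuron) data,
# Benjamini-Hochberg adjustment, and seed fan-out.

#' Deterministic child seed
#'
#' Fans a master seed out to named sub-analyses so each stage is
#' individually reproducible and independent of iteration order.  Simple
#' multiplicative hash over the tag characters, kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param tag Character tag of the sub-analysis.
#' @return An integer seed.
#' @export
child_seed <- function(seed, tag) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(as.character(tag))) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Benjamini--Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone in the input ranks).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hierarchical bootstrap for nested data
#'
#' Resamples animals with replacement, then sessions within each chosen
#' animal, then units within each chosen session (resample sizes equal the
#' observed counts at each level), computes the summary statistic on each
#' resample, and derives a two-sided p-value `P = 2 min(q, 1 - q)`, where
#' `q` is the mid-rank quantile of `null_value` within the bootstrap
#' distribution of the statistic.  `P` is floored at `2 / (n_boot + 1)`.
#'
#' With one animal and one session this reduces to a flat bootstrap over
#' units.
#'
#' @param values Numeric vector of unit-level values.
#' @param animal,session Grouping vectors (same length as `values`); every
#'   session must belong to exactly one animal.
#' @param statistic Function of a numeric vector (default [median]).
#' @param n_boot Bootstrap resamples (>= 1000 recommended).
#' @param null_value Value tested against (default 0).
#' @param seed Seed.
#' @return List of class `hboot`: `observed`, `distribution`, `q`, `p`,
#'   `n_redraws`.
#' @export
hierarchical_bootstrap <- function(values, animal, session,
                                   statistic = median, n_boot = 1000,
                                   null_value = 0, seed = 1L) {
  stopifnot(length(animal) == length(values),
            length(session) == length(values))
  ses_animal <- tapply(as.character(animal), as.character(session),
                       function(a) unique(a))
  if (any(lengths(ses_animal) != 1L))
    stop("every session must belong to exactly one animal")
  by_animal <- split(as.character(session), as.character(animal))
  by_animal <- lapply(by_animal, unique)
  by_session <- split(values, as.character(session))
  animals <- names(by_animal)
  observed <- statistic(values)
  n_redraws <- 0L
  max_redraw <- max(1L, ceiling(0.01 * n_boot))
  dist <- withr::with_seed(seed, {
    one <- function() {
      a_pick <- sample(animals, length(animals), replace = TRUE)
      vals <- unlist(lapply(a_pick, function(a) {
        s_all <- by_animal[[a]]
        s_pick <- sample(s_all, length(s_all), replace = TRUE)
        unlist(lapply(s_pick, function(s) {
          v <- by_session[[s]]
          v[sample.int(length(v), length(v), replace = TRUE)]
        }))
      }))
      statistic(vals)
    }
    vapply(seq_len(n_boot), function(b) {
      st <- one()
      while (is.na(st)) {
        n_redraws <<- n_redraws + 1L
        if (n_redraws > max_redraw)
          stop("statistic undefined on more than 1% of resamples")
        st <- one()
      }
      st
    }, 0)
  })
  q <- (sum(dist < null_value) + 0.5 * sum(dist == null_value)) / n_boot
  p <- max(2 * min(q, 1 - q), 2 / (n_boot + 1))
  structure(list(observed = observed, distribution = dist, q = q,
                 p = min(p, 1), n_redraws = n_redraws),
            class = "hboot")
}

#' Two-sided p-value from a bootstrap quantile
#'
#' `P = 2 min(q, 1 - q)`, floored at `2 / (n_boot + 1)` and capped at 1.
#'
#' @param q Quantile of the null value within the bootstrap distribution.
#' @param n_boot Number of resamples used (controls the floor; `Inf` for no
#'   floor).
#' @return The p-value.
#' @export
bootstrap_pvalue <- function(q, n_boot = Inf) {
  min(1, max(2 * min(q, 1 - q), 2 / (n_boot + 1)))
}

#' @export
print.hboot <- function(x, ...) {
  cat(sprintf("<hierarchical bootstrap: observed %.4g, q = %.4f, P = %.4g>\n",
              x$observed, x$q, x$p))
  invisible(x)
}
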