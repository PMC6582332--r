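#' Run configuration
#'
#' Bundles and validates the two tunable parameters of the algorithm (the
#' percentile-set size and the overlap significance cut-off) together with the
#' bookkeeping needed for a reproducible run. The configuration is persisted
#' verbatim in the JSON manifest written next to every output set.
#'
#' @param percentile Fraction in (0, 0.5]: the top (or bottom) fraction of
#'   samples forming each gene's extremal set. The set size is
#'   `k = round(percentile * N)` (half-up), and must be at least 2.
#' @param direction `"high"` to examine the top of each gene's expression
#'   profile, `"low"` for the bottom.
#' @param cutoff Significance cut-off in (0, 1) applied to each gene pair's
#'   overlap test; pairs at or below the cut-off become graph edges.
#' @param cutoff_mode `"fdr"` to apply `cutoff` to Benjamini-Hochberg adjusted
#'   p-values (the default), `"raw"` to apply it to raw p-values.
#' @param seed Optional integer seed for randomized steps (the core pipeline is
#'   deterministic; the seed is recorded for provenance and used by helpers
#'   that simulate data).
#' @param min_distinct Optional integer: genes whose extremal-boundary tie
#'   group would exceed the set size by more than this many distinct values are
#'   dropped before graph construction (`NULL` disables the filter). Useful in
#'   the low direction where zero-inflation creates massive ties.
#' @param fdr_threshold Significance level used only when summarising scores
#'   into the quality index Q; never affects membership.
#'
#' @return A validated list of class `"tuba_config"`.
#' @export
#' @examples
#' cfg <- tuba_config(percentile = 0.05, cutoff = 1e-8)
tuba_config <- function(percentile = 0.05,
                        direction = c("high", "low"),
                        cutoff = 1e-8,
                        cutoff_mode = c("fdr", "raw"),
                        seed = NULL,
                        min_distinct = NULL,
                        fdr_threshold = 0.05) {
  direction <- match.arg(direction)
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(is.numeric(percentile), length(percentile) == 1L)
  if (!(percentile > 0 && percentile <= 0.5)) {
    stop("`percentile` must lie in (0, 0.5], got ", percentile)
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  if (!(cutoff > 0 && cutoff < 1)) {
    stop("`cutoff` must lie in (0, 1), got ", cutoff)
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, !is.na(seed))
  }
  if (!is.null(min_distinct)) {
    min_distinct <- as.integer(min_distinct)
    stopifnot(min_distinct >= 0L)
  }
  stopifnot(is.numeric(fdr_threshold), fdr_threshold > 0, fdr_threshold < 1)
  structure(
    list(percentile = percentile, direction = direction, cutoff = cutoff,
         cutoff_mode = cutoff_mode, seed = seed, min_distinct = min_distinct,
         fdr_threshold = fdr_threshold),
    class = "tuba_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file may define any subset of the [tuba_config()] fields; missing fields
#' take their defaults. Unknown fields are an error so that typos do not
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"tuba_config"` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(tuba_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(tuba_config, raw)
}

#' @export
print.tuba_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  percentile : %g (%s direction)\n", x$percentile, x$direction))
  cat(sprintf("  cutoff     : %g (%s)\n", x$cutoff, x$cutoff_mode))
  cat(sprintf("  seed       : %s\n", if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
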