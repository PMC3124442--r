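# broom-style tidiers for the package's result objects.

#' Tidy a region set
#'
#' @param x A `region_set`.
#' @param ... Unused.
#' @return A plain tibble of regions with a `length` column.
#' @export
tidy.region_set <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$length <- out$end - out$start
  out
}

#' One-row summary of a region set
#'
#' @param x A `region_set`.
#' @param ... Unused.
#' @return Tibble with `n_regions`, `total_kbp`, `median_length`,
#'   `max_additive_z` and the calling thresholds.
#' @export
glance.region_set <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_regions = nrow(x),
    total_kbp = sum(x$end - x$start) / 1000,
    median_length = if (nrow(x) > 0L) median(x$end - x$start) else NA_real_,
    max_additive_z = if (nrow(x) > 0L) max(x$additive_z) else NA_real_,
    z_probe = p$z_probe, z_region = p$z_region, merge_gap = p$merge_gap)
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return Tibble of the random statistics, one row per random set.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(set = seq_along(x$randoms), statistic = x$randoms)
}

#' One-row summary of an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return Tibble with `observed`, `n_exceed`, `q_total`, `p_value`.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, n_exceed = x$n_exceed,
                 q_total = x$q_total, p_value = x$p_value)
}

#' Tidy GC strata
#'
#' @param x A `gc_strata`.
#' @param ... Unused.
#' @return A plain tibble, one row per effective GC stratum.
#' @export
tidy.gc_strata <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of GC strata
#'
#' @param x A `gc_strata`.
#' @param ... Unused.
#' @return Tibble with stratum count, null-probe total, and the range of
#'   stratum medians (the size of the GC effect the correction removes).
#' @export
glance.gc_strata <- function(x, ...) {
  tibble::tibble(n_strata = nrow(x), n_null_probes = sum(x$n),
                 baseline_range = max(x$m) - min(x$m),
                 median_scale = median(x$s))
}
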