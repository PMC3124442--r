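# Region calling on smoothed adjusted tracks: per-probe Z-scores against
# the null-probe empirical distribution, seed-and-merge segmentation on
# additive Z, replicate-input FDR estimation, differential calls, and
# cutoff sensitivity analysis.

#' Per-probe Z-scores against the null-probe distribution
#'
#' `z_i = (value_i - m_g) / s_g`, where `m_g` and `s_g` are the median and
#' robust scale of the null probes in the same GC stratum, estimated on
#' the *adjusted, unsmoothed* track. The Z-score therefore counts how many
#' null SDs of the per-probe log-ratio the smoothed value sits from the
#' null median; under the null it is distributed as a running median of an
#' approximately standard normal variable, which concentrates well inside
#' the +/-1 band and makes the probe and region thresholds conservative.
#'
#' @param track A `signal_track` at stage `smoothed`.
#' @param strata A `gc_strata` estimated on the adjusted track (so `m_g`
#'   is ~0 and `s_g` is the unsmoothed per-probe null scale).
#' @param design A `probe_design`.
#' @return A `signal_track` at stage `z`.
#' @export
probe_z_scores <- function(track, strata, design) {
  assert_stage(track, "smoothed")
  b <- strata_rows(strata, design)
  new_signal_track(design, (track$value - strata$m[b]) / strata$s[b], "z")
}

#' Call methylated regions from a Z-score track
#'
#' Probes with `Z > z_probe` are seeds. Seeds on the same chromosome whose
#' start positions are strictly less than `merge_gap` apart are chained
#' into a candidate segment spanning the first seed's start to the last
#' seed's end. The additive Z of the segment is the sum of Z over all
#' probes spanned by the segment (set `sum_seeds_only = TRUE` to sum only
#' seed probes). Segments with additive Z strictly above `z_region` are
#' returned, ranked by additive Z descending (ties broken by genomic
#' position).
#'
#' @param z A `signal_track` at stage `z`.
#' @param design A `probe_design`.
#' @param z_probe Seed threshold (strict `>`).
#' @param z_region Additive-Z region threshold (strict `>`).
#' @param merge_gap Seed chaining distance in bp (strict `<`).
#' @param sum_seeds_only Sum Z over seed probes only.
#' @param sample Optional sample label stored with the result.
#' @return A `region_set` tibble with columns `chrom`, `start`, `end`,
#'   `additive_z`, `n_probes`, `max_probe_z`, `rank`.
#' @export
call_regions <- function(z, design, z_probe = 3, z_region = 4,
                         merge_gap = 250L, sum_seeds_only = FALSE,
                         sample = NULL) {
  assert_stage(z, "z")
  out <- list()
  for (cr in unique(design$chrom)) {
    idx <- which(design$chrom == cr)
    zv <- z$value[idx]
    seeds <- which(!is.na(zv) & zv > z_probe)
    if (length(seeds) == 0L) next
    starts <- design$start[idx]
    ends <- design$end[idx]
    grp <- cumsum(c(1L, as.integer(diff(starts[seeds]) >= merge_gap)))
    segs <- purrr::map_dfr(split(seeds, grp), function(s) {
      i1 <- s[1]; i2 <- s[length(s)]
      span <- i1:i2
      tibble::tibble(
        chrom = cr, start = starts[i1], end = ends[i2],
        additive_z = if (sum_seeds_only) sum(zv[s]) else sum(zv[span]),
        n_probes = length(span), max_probe_z = max(zv[span])
      )
    })
    out[[cr]] <- segs[segs$additive_z > z_region, ]
  }
  res <- if (length(out) > 0L) dplyr::bind_rows(out) else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   additive_z = double(), n_probes = integer(),
                   max_probe_z = double())
  }
  res <- res[order(-res$additive_z,
                   factor(res$chrom, levels = unique(design$chrom)),
                   res$start), ]
  res$rank <- seq_len(nrow(res))
  res <- genomic_order(res)
  structure(res, sample = sample,
            params = list(z_probe = z_probe, z_region = z_region,
                          merge_gap = merge_gap,
                          sum_seeds_only = sum_seeds_only),
            class = c("region_set", class(tibble::tibble())))
}

#' Run the full pre-processing chain for one sample
#'
#' Convenience wrapper: log-ratio, GC baseline estimation on the raw track,
#' adjustment, running-median smoothing, and Z-scores. The Z denominator
#' is the per-GC-stratum scale of the *adjusted unsmoothed* null values:
#' smoothing is a stabilizer, and the Z-score counts null SDs of the
#' per-probe log-ratio, so under the null the Z track behaves like a
#' running median of a standard normal variable.
#'
#' @inheritParams compute_log_ratio
#' @param nulls A `null_probes` set.
#' @param k Running-median window (odd).
#' @param min_bin_size Minimum null probes per GC stratum.
#' @return A `meth_tracks` tibble with columns `probe_id`, `chrom`,
#'   `start`, `log_ratio`, `adjusted`, `smoothed`, `z`; attributes
#'   `strata_raw` (baseline fit on the raw log-ratio) and `strata_adjusted`
#'   (the null scale used for Z) hold the two `gc_strata`.
#' @export
preprocess_sample <- function(intensity, design, nulls, sample,
                              numerator_channel = "M",
                              denominator_channel = "T",
                              numerator_replicate = NULL,
                              denominator_replicate = NULL,
                              k = 7L, min_bin_size = 200L) {
  lr <- compute_log_ratio(intensity, design, sample,
                          numerator_channel, denominator_channel,
                          numerator_replicate, denominator_replicate)
  strata_raw <- estimate_gc_baseline(lr, nulls, design, min_bin_size)
  adj <- adjust_signal(lr, strata_raw, design)
  strata_adj <- estimate_gc_baseline(adj, nulls, design, min_bin_size)
  sm <- smooth_running_median(adj, k)
  z <- probe_z_scores(sm, strata_adj, design)
  out <- tibble::tibble(probe_id = design$probe_id, chrom = design$chrom,
                        start = design$start, log_ratio = lr$value,
                        adjusted = adj$value, smoothed = sm$value,
                        z = z$value)
  structure(out, strata_raw = strata_raw, strata_adjusted = strata_adj,
            sample = sample, k = k,
            class = c("meth_tracks", class(tibble::tibble())))
}

#' Extract one stage of a `meth_tracks` table as a signal track
#'
#' @param tracks A `meth_tracks` tibble from [preprocess_sample()].
#' @param design The matching `probe_design`.
#' @param stage Stage column to extract.
#' @return A `signal_track`.
#' @export
get_track <- function(tracks, design, stage = c("z", "smoothed", "adjusted", "log_ratio")) {
  stage <- match.arg(stage)
  new_signal_track(design, tracks[[stage]], stage)
}

#' Estimate the false discovery rate from replicate total-input arrays
#'
#' Runs the identical pre-process + region-calling pipeline on
#' `log2(T_rep1 / T_rep2)`, a ratio in which no true methylation signal
#' exists, and divides the number of regions called on this absolute null
#' by the number called on the real M/T ratio.
#'
#' @param intensity Intensity tibble carrying channel `T` with two
#'   replicates for `sample`.
#' @param design A `probe_design`.
#' @param nulls A `null_probes` set.
#' @param sample Sample label.
#' @param n_called Number of regions called on the M/T ratio (> 0).
#' @param k,min_bin_size,z_probe,z_region,merge_gap Pipeline parameters,
#'   as used for the real calls.
#' @param replicates The two replicate labels to ratio.
#' @return FDR as a fraction in `[0, 1]`; attribute `n_null_regions`
#'   carries the null-region count.
#' @export
estimate_fdr <- function(intensity, design, nulls, sample, n_called,
                         k = 7L, min_bin_size = 200L, z_probe = 3,
                         z_region = 4, merge_gap = 250L,
                         replicates = c(1L, 2L)) {
  if (is.na(n_called) || n_called <= 0L) {
    abort("FDR is undefined when no regions were called (n_called must be > 0)")
  }
  tr <- preprocess_sample(intensity, design, nulls, sample,
                          numerator_channel = "T", denominator_channel = "T",
                          numerator_replicate = replicates[1],
                          denominator_replicate = replicates[2],
                          k = k, min_bin_size = min_bin_size)
  null_regions <- call_regions(get_track(tr, design, "z"), design,
                               z_probe = z_probe, z_region = z_region,
                               merge_gap = merge_gap)
  fdr <- nrow(null_regions) / n_called
  attr(fdr, "n_null_regions") <- nrow(null_regions)
  fdr
}

# Additive Z of arbitrary intervals: sum of z over probes whose start lies
# in [start, end), per interval. Used by differential calling.
interval_additive_z <- function(intervals, z, design) {
  purrr::pmap_dbl(intervals[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      idx <- which(design$chrom == chrom & design$start >= start &
                     design$start < end)
      sum(z$value[idx])
    })
}

#' Call differentially methylated regions between two samples
#'
#' Overlapping regions from the two per-sample region sets are merged into
#' union intervals; for each union interval the additive Z is recomputed in
#' both samples over the spanned probes. A call requires `Z > z_high` in
#' one sample, `Z < z_low` in the other, and interval length strictly
#' greater than `min_len` bp — the stringent criteria for presence of
#' methylation in one sample and absence in the other.
#'
#' @param regions_a,regions_b `region_set`s for the two samples.
#' @param z_a,z_b Matching Z-score `signal_track`s.
#' @param design Shared `probe_design`.
#' @param min_len Minimum interval length in bp (strict `>`).
#' @param z_high,z_low Z thresholds (strict).
#' @param labels Length-2 sample labels used in the `direction` column.
#' @return A tibble of differential calls: `chrom`, `start`, `end`,
#'   `length`, `z_a`, `z_b`, `direction`.
#' @export
call_differential <- function(regions_a, z_a, regions_b, z_b, design,
                              min_len = 500L, z_high = 4, z_low = 1,
                              labels = c("a", "b")) {
  if (!identical(z_a$probe_id, design$probe_id) ||
      !identical(z_b$probe_id, design$probe_id)) {
    abort("Z tracks must be on the supplied design")
  }
  comb <- dplyr::bind_rows(tibble::as_tibble(regions_a)[, c("chrom", "start", "end")],
                           tibble::as_tibble(regions_b)[, c("chrom", "start", "end")])
  if (nrow(comb) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), length = integer(),
                          z_a = double(), z_b = double(),
                          direction = character()))
  }
  merged <- purrr::map_dfr(split(comb, comb$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    tibble::tibble(chrom = d$chrom[1],
                   start = BiocGenerics::start(r) - 1L,
                   end = BiocGenerics::end(r))
  })
  merged$z_a <- interval_additive_z(merged, z_a, design)
  merged$z_b <- interval_additive_z(merged, z_b, design)
  merged$length <- merged$end - merged$start
  hyper_a <- merged$z_a > z_high & merged$z_b < z_low
  hyper_b <- merged$z_b > z_high & merged$z_a < z_low
  keep <- (hyper_a | hyper_b) & merged$length > min_len
  out <- merged[keep, ]
  out$direction <- ifelse(hyper_a[keep],
                          paste0(labels[1], "_hypermethylated"),
                          paste0(labels[2], "_hypermethylated"))
  genomic_order(out[, c("chrom", "start", "end", "length", "z_a", "z_b",
                        "direction")])
}

#' Sensitivity of region calls to the seed Z cutoff
#'
#' Re-calls regions at each candidate `z_probe` and counts, per cutoff,
#' how many called regions longer than `min_report_len` do not overlap any
#' region found at the reference cutoff.
#'
#' @param z A `signal_track` at stage `z`.
#' @param design A `probe_design`.
#' @param z_probe_values Candidate seed cutoffs; must include `reference`.
#' @param reference Reference seed cutoff.
#' @param z_region,merge_gap As in [call_regions()].
#' @param min_report_len Regions at most this long are ignored when
#'   counting novel regions.
#' @return Tibble with `z_probe`, `n_regions`, `n_new`.
#' @export
cutoff_sensitivity <- function(z, design, z_probe_values, reference = 3,
                               z_region = 4, merge_gap = 250L,
                               min_report_len = 200L) {
  if (!any(abs(z_probe_values - reference) < 1e-12)) {
    abort("z_probe_values must include the reference cutoff")
  }
  ref <- call_regions(z, design, z_probe = reference, z_region = z_region,
                      merge_gap = merge_gap)
  purrr::map_dfr(z_probe_values, function(zp) {
    rs <- call_regions(z, design, z_probe = zp, z_region = z_region,
                       merge_gap = merge_gap)
    long <- rs[rs$end - rs$start > min_report_len, ]
    new <- purrr::pmap_lgl(long[, c("chrom", "start", "end")],
      function(chrom, start, end) {
        !any(ref$chrom == chrom & ref$start < end & ref$end > start)
      })
    tibble::tibble(z_probe = zp, n_regions = nrow(rs), n_new = sum(new))
  })
}
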