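# Pre-processing of M/T tiling-array intensities: log-ratio formation,
# null-probe selection, GC-stratum bias correction, running-median
# smoothing, and diagnostics (autocorrelation, normality).

# 0-based start positions of CG dinucleotides in a sequence string.
cpg_starts <- function(seq) {
  m <- Biostrings::matchPattern("CG", Biostrings::DNAString(seq))
  BiocGenerics::start(m) - 1L
}

#' Local CpG density around genomic positions
#'
#' Counts CG dinucleotides in a window centred on each position and scales
#' the count to CpGs per 1000 bp. Windows are truncated at chromosome ends
#' and the density is scaled to the actual window length.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param position Integer vector of 0-based positions.
#' @param window Window size in bp (>= 100), centred on `position`.
#' @return Numeric vector of densities (CpGs per 1000 bp).
#' @export
local_cpg_density <- function(genome, chrom, position, window = 1000L) {
  if (window < 100L) abort("window must be >= 100 bp")
  if (chrom %not in% names(genome)) {
    abort(sprintf("unknown chromosome '%s'", chrom))
  }
  len <- nchar(genome[[chrom]])
  if (any(position < 0L | position >= len)) {
    abort("position outside chromosome")
  }
  cg <- cpg_starts(genome[[chrom]])
  lo <- pmax(position - window %/% 2L, 0L)
  hi <- pmin(position - window %/% 2L + window, len)
  # a CG counts if it lies wholly inside [lo, hi): its start in [lo, hi - 1]
  n <- findInterval(hi - 2L + 0.5, cg) - findInterval(lo - 0.5, cg)
  1000 * n / (hi - lo)
}

#' Select null probes by local CpG density
#'
#' Null probes interrogate regions of such low CpG density that genuine
#' methylation enrichment is impossible; their signal measures spurious
#' sequence effects. A probe is a null probe when the CpG density of the
#' window centred on its midpoint is strictly below `threshold`.
#'
#' @param design A `probe_design`.
#' @param genome Named character vector of chromosome sequences.
#' @param threshold Density cutoff in CpGs per 1000 bp (strict `<`).
#' @param window Window size in bp.
#' @param min_null Minimum acceptable number of null probes.
#' @return A `null_probes` tibble: the selected design rows plus their
#'   `cpg_density`.
#' @export
select_null_probes <- function(design, genome, threshold = 4, window = 1000L,
                               min_null = 500L) {
  dens <- rep(NA_real_, nrow(design))
  for (cr in unique(design$chrom)) {
    idx <- which(design$chrom == cr)
    mid <- design$start[idx] + (design$end[idx] - design$start[idx]) %/% 2L
    dens[idx] <- local_cpg_density(genome, cr, mid, window)
  }
  keep <- dens < threshold
  if (sum(keep) < min_null) {
    abort(sprintf(paste0(
      "only %d probes fall below the CpG density threshold (need >= %d); ",
      "consider raising `threshold` or changing `window`"),
      sum(keep), min_null))
  }
  out <- tibble::as_tibble(design)[keep, ]
  out$cpg_density <- dens[keep]
  structure(out, threshold = threshold, window = window,
            class = c("null_probes", class(tibble::tibble())))
}

#' Compute the per-probe log2 ratio between two channels
#'
#' For each probe, the log2 intensities of each channel are averaged over
#' replicates and the difference (numerator minus denominator) is the
#' log-ratio. The usual call is M over T; passing the same channel with
#' `numerator_replicate`/`denominator_replicate` set gives the
#' replicate-null ratio used for FDR estimation (e.g. T rep 1 over
#' T rep 2).
#'
#' @param intensity Intensity tibble (see [read_intensity_table()]).
#' @param design A `probe_design`.
#' @param sample Sample label to extract.
#' @param numerator_channel,denominator_channel Channel labels.
#' @param numerator_replicate,denominator_replicate Optional single
#'   replicate to use instead of the replicate mean.
#' @return A `signal_track` at stage `log_ratio`.
#' @export
compute_log_ratio <- function(intensity, design, sample,
                              numerator_channel = "M",
                              denominator_channel = "T",
                              numerator_replicate = NULL,
                              denominator_replicate = NULL) {
  channel_mean <- function(channel, replicate) {
    sub <- intensity[intensity$sample == sample & intensity$channel == channel, ]
    if (!is.null(replicate)) sub <- sub[sub$replicate == replicate, ]
    if (nrow(sub) == 0L) {
      abort(sprintf("sample %s has no data for channel %s%s", sample, channel,
                    if (is.null(replicate)) "" else sprintf(" replicate %d", replicate)))
    }
    per_rep <- table(sub$replicate)
    if (any(per_rep != nrow(design))) {
      abort(sprintf("channel %s of sample %s is missing probes in some replicate",
                    channel, sample))
    }
    agg <- sub |>
      dplyr::group_by(.data$probe_id) |>
      dplyr::summarise(v = mean(.data$log2_intensity), .groups = "drop")
    agg$v[match(design$probe_id, agg$probe_id)]
  }
  num <- channel_mean(numerator_channel, numerator_replicate)
  den <- channel_mean(denominator_channel, denominator_replicate)
  new_signal_track(design, num - den, "log_ratio")
}

# Map every integer GC value 0..max_gc to an effective bin by merging bins
# with fewer than min_bin_size null probes into their nearest populated
# neighbour (by GC distance).
merge_gc_bins <- function(gc_values, max_gc, min_bin_size) {
  counts <- tabulate(gc_values + 1L, nbins = max_gc + 1L)
  present <- which(counts > 0L) - 1L            # gc levels with data
  # each effective bin is a contiguous set of gc levels; start one per level
  bins <- lapply(present, identity)
  bin_n <- counts[present + 1L]
  repeat {
    if (length(bins) <= 1L) break
    small <- which(bin_n < min_bin_size)
    if (length(small) == 0L) break
    i <- small[which.min(bin_n[small])]
    # merge into the nearer neighbour by gc distance; ends have one choice
    left_gap <- if (i > 1L) min(bins[[i]]) - max(bins[[i - 1L]]) else Inf
    right_gap <- if (i < length(bins)) min(bins[[i + 1L]]) - max(bins[[i]]) else Inf
    j <- if (left_gap <= right_gap) i - 1L else i + 1L
    bins[[j]] <- sort(c(bins[[j]], bins[[i]]))
    bin_n[j] <- bin_n[j] + bin_n[i]
    bins[[i]] <- NULL
    bin_n <- bin_n[-i]
  }
  # assign every gc level 0..max_gc (including empty ones) to nearest bin
  reps <- purrr::map_dbl(bins, ~ mean(range(.x)))
  gc_map <- integer(max_gc + 1L)
  for (g in 0:max_gc) {
    direct <- purrr::detect_index(bins, ~ g %in% .x)
    gc_map[g + 1L] <- if (direct > 0L) direct else which.min(abs(reps - g))
  }
  list(bins = bins, gc_map = gc_map)
}

#' Estimate the GC-stratified null baseline of a track
#'
#' Over null probes only, and per GC stratum (integer G+C count of the
#' probe sequence), computes the median log-ratio `m_g` and a robust scale
#' `s_g` (1.4826 x MAD). Strata with fewer than `min_bin_size` null probes
#' are merged with their nearest neighbour until the size floor is met.
#' A stratum whose MAD is zero falls back to its sample SD, then to the
#' global robust scale of all null values.
#'
#' @param track A `signal_track` (any pre-Z stage; the raw `log_ratio`
#'   track gives the subtraction baseline, the `smoothed` track gives the
#'   empirical null used for Z-scores).
#' @param nulls A `null_probes` set.
#' @param design A `probe_design`.
#' @param min_bin_size Minimum null probes per effective stratum.
#' @return A `gc_strata` tibble with one row per effective stratum
#'   (`gc_min`, `gc_max`, `m`, `s`, `n`) and an attribute mapping every GC
#'   value to its stratum.
#' @export
estimate_gc_baseline <- function(track, nulls, design, min_bin_size = 200L) {
  assert_stage(track, c("log_ratio", "adjusted", "smoothed"))
  idx <- match(nulls$probe_id, design$probe_id)
  vals <- track$value[idx]
  gc <- design$gc_count[idx]
  ok <- !is.na(vals)
  if (!any(ok)) abort("all null-probe values are missing")
  vals <- vals[ok]; gc <- gc[ok]
  max_gc <- max(design$end - design$start)
  merged <- merge_gc_bins(gc, max_gc, min_bin_size)
  bin_of <- merged$gc_map[gc + 1L]

  global_scale <- mad(vals)
  if (global_scale == 0) global_scale <- sd(vals)
  fell_back <- FALSE
  rows <- purrr::map_dfr(seq_along(merged$bins), function(b) {
    v <- vals[bin_of == b]
    s <- mad(v)
    if (s == 0 || is.na(s)) s <- sd(v)
    if (is.na(s) || s == 0) { s <- global_scale; fell_back <<- TRUE }
    tibble::tibble(gc_min = min(merged$bins[[b]]), gc_max = max(merged$bins[[b]]),
                   m = median(v), s = s, n = length(v))
  })
  if (any(rows$s == 0 | is.na(rows$s))) {
    warn("null-probe values are constant; using unit scale")
    rows$s[rows$s == 0 | is.na(rows$s)] <- 1
  }
  structure(rows, gc_map = merged$gc_map, stage = track_stage(track),
            class = c("gc_strata", class(tibble::tibble())))
}

# Per-probe stratum row indices for a design.
strata_rows <- function(strata, design) {
  gc_map <- attr(strata, "gc_map")
  gc <- pmin(design$gc_count, length(gc_map) - 1L)
  gc_map[gc + 1L]
}

#' Subtract the GC-stratum baseline from a log-ratio track
#'
#' @param track A `signal_track` at stage `log_ratio`.
#' @param strata A `gc_strata` estimated from the same track kind.
#' @param design A `probe_design`.
#' @return A `signal_track` at stage `adjusted`.
#' @export
adjust_signal <- function(track, strata, design) {
  assert_stage(track, "log_ratio")
  b <- strata_rows(strata, design)
  new_signal_track(design, track$value - strata$m[b], "adjusted")
}

# Running median with symmetric shrinking windows at the edges; never
# crosses chromosome boundaries. k odd.
running_median_chrom <- function(x, k) {
  n <- length(x)
  if (n == 0L || k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  out <- if (n >= k) runmed(x, k, endrule = "keep") else x
  edge <- unique(c(seq_len(min(h, n)), seq.int(max(n - h + 1L, 1L), n)))
  for (i in edge) {
    m <- min(h, i - 1L, n - i)
    out[i] <- median(x[(i - m):(i + m)])
  }
  out
}

#' Smooth an adjusted track with a running median
#'
#' Centred window of `k` consecutive probes on the same chromosome; at
#' chromosome edges the window shrinks symmetrically to the largest odd
#' size available, so no probe is dropped.
#'
#' @param track A `signal_track` at stage `adjusted` (or `log_ratio`).
#' @param k Odd window size in probes (default 7, matching a ~250 bp
#'   window at 35 bp tiling, the modal fragment size).
#' @return A `signal_track` at stage `smoothed`.
#' @export
smooth_running_median <- function(track, k = 7L) {
  if (k %% 2L == 0L) abort("smoothing window k must be odd")
  if (k < 1L) abort("k must be >= 1")
  assert_stage(track, c("adjusted", "log_ratio"))
  val <- track$value
  for (cr in unique(track$chrom)) {
    idx <- which(track$chrom == cr)
    val[idx] <- running_median_chrom(track$value[idx], k)
  }
  out <- track
  out$value <- val
  attr(out, "stage") <- "smoothed"
  out
}

#' Lag-r autocorrelation of a track over a probe subset
#'
#' Pearson correlation of `(value_i, value_{i+lag})` over consecutive
#' subset probes on the same chromosome (consecutive in subset order, so
#' the statistic tracks the spatial structure of, e.g., the null probes).
#'
#' @param track A `signal_track`.
#' @param subset A `null_probes` set (or any tibble with `probe_id`).
#' @param lag Lag in subset-probe steps.
#' @return Correlation coefficient.
#' @export
autocorrelation <- function(track, subset, lag = 1L) {
  idx <- match(subset$probe_id, track$probe_id)
  if (length(idx) < 100L) abort("need >= 100 subset probes")
  xs <- ys <- list()
  for (cr in unique(track$chrom[idx])) {
    v <- track$value[idx[track$chrom[idx] == cr]]
    if (length(v) > lag) {
      xs[[cr]] <- v[seq_len(length(v) - lag)]
      ys[[cr]] <- v[-seq_len(lag)]
    }
  }
  x <- unlist(xs); y <- unlist(ys)
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in subset values")
  cor(x, y)
}

#' Quantile-gap normality diagnostic on null probes
#'
#' Standardises the subset values robustly (median / 1.4826 x MAD) and
#' compares their decile quantiles to the standard normal deciles. Small
#' gaps support treating the smoothed adjusted null distribution as
#' normal, which underlies the Z-score inference.
#'
#' @param track A `signal_track`.
#' @param subset Probe subset (typically the null probes).
#' @return Maximum absolute gap between observed and theoretical quantiles
#'   over the deciles 0.1..0.9.
#' @export
normality_diagnostic <- function(track, subset) {
  idx <- match(subset$probe_id, track$probe_id)
  if (length(idx) < 1000L) abort("need >= 1000 subset probes")
  v <- track$value[idx]
  z <- (v - median(v)) / mad(v)
  p <- seq(0.1, 0.9, by = 0.1)
  max(abs(quantile(z, p, names = FALSE) - qnorm(p)))
}
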