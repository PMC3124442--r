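# Synthetic-data generator: genomes with CpG islands and gene models,
# planted methylation ground truth, and M/T tiling-array intensities
# carrying the artifacts real arrays show — a saturating CpG-count
# enrichment response, a GC-dependent probe effect, and positional
# autocorrelation driven by smoothly varying base composition.

#' Simulation parameters
#'
#' Defaults describe the study conditions used throughout the test suite:
#' two 1 Mb chromosomes tiled with 25-mers every 35 bp, CpG islands at
#' ~25 CpGs/kbp against a ~2 CpGs/kbp background, a logistic (Hill-type)
#' enrichment response saturating near 3 log2 units, a GC probe effect of
#' 0.06 log2 units per G+C base, and Gaussian log2 noise with SD 0.3.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param probe_spacing,probe_length Tiling geometry in bp.
#' @param background_cpg_rate,island_cpg_rate CpGs per kbp outside/inside
#'   islands.
#' @param islands_per_mb,island_length_range Island placement density and
#'   size range (bp).
#' @param genes_per_mb Gene density.
#' @param exon_count_range,exon_length_range Exon structure per gene.
#' @param intron_short_range,intron_long_range Intron length classes (bp);
#'   genes draw introns from both so metagene profiles have members in
#'   each class.
#' @param meth_regions Number of planted methylated regions (per sample,
#'   across the whole genome).
#' @param meth_length_range Planted region lengths (bp); the default floor
#'   of 280 bp spans >= 8 probes at 35 bp tiling.
#' @param meth_cpg_rate CpGs per kbp planted inside methylated regions.
#' @param frag_modal_length Modal DNA fragment length (bp); fragments are
#'   i.i.d. gamma with this mode.
#' @param frag_shape Gamma shape of the fragment length distribution.
#' @param enrich_ceiling,enrich_half_sat,enrich_hill Saturating enrichment
#'   response: log2 ceiling, half-saturation methylated-CpG count, Hill
#'   coefficient.
#' @param gc_bias_coef GC probe effect, log2 units per G+C base above the
#'   design mean.
#' @param gc_field_amplitude,gc_field_scale_bp Amplitude (as fraction of
#'   GC probability) and correlation length of the smooth base-composition
#'   field that makes neighbouring probes share GC content.
#' @param noise_sd Gaussian noise SD on the log2 scale, per replicate.
#' @param affinity_sd SD of per-probe baseline affinity (log2).
#' @param t_baseline Mean total-input log2 intensity.
#' @param island_meth_frac Fraction of methylated regions forced inside
#'   CpG islands (used by the `island_enriched` scenario).
#' @param conserved_frac Fraction of intergenic space covered by
#'   high-conservation intervals.
#' @param tfbs_per_mb Density of transcription-factor binding site
#'   intervals.
#' @return A `sim_params` list.
#' @export
sim_params <- function(chrom_lengths = c(chrS1 = 1000000L, chrS2 = 1000000L),
                       probe_spacing = 35L, probe_length = 25L,
                       background_cpg_rate = 2, island_cpg_rate = 25,
                       islands_per_mb = 60, island_length_range = c(500L, 2000L),
                       genes_per_mb = 15,
                       exon_count_range = c(4L, 8L),
                       exon_length_range = c(100L, 300L),
                       intron_short_range = c(842L, 2715L),
                       intron_long_range = c(2715L, 11673L),
                       meth_regions = 200L,
                       meth_length_range = c(280L, 1000L),
                       meth_cpg_rate = 30,
                       frag_modal_length = 250, frag_shape = 4,
                       enrich_ceiling = 3, enrich_half_sat = 6,
                       enrich_hill = 2,
                       gc_bias_coef = 0.06,
                       gc_field_amplitude = 0.25, gc_field_scale_bp = 5000L,
                       noise_sd = 0.3, affinity_sd = 0.5, t_baseline = 10,
                       island_meth_frac = 0, conserved_frac = 0.05,
                       tfbs_per_mb = 40) {
  p <- as.list(environment())
  bad <- names(p)[vapply(p, function(x) any(!is.finite(as.numeric(x))) ||
                           any(as.numeric(x) < 0), logical(1))]
  if (length(bad) > 0L) {
    abort(sprintf("simulation parameters must be finite and non-negative: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(p, class = "sim_params")
}

#' Expected log2 enrichment as a function of methylated-CpG count
#'
#' A saturating Hill curve: zero response with no methylated CpGs (an
#' unmethylated fragment is not captured at all), rising through the
#' half-saturation count and plateauing at the ceiling — the nonlinear
#' dependence of affinity capture on methyl-CpG density.
#'
#' @param n_meth_cpg Number of methylated CpGs on the fragment (>= 0).
#' @param params A `sim_params` list.
#' @return Expected log2 enrichment.
#' @export
enrichment_response <- function(n_meth_cpg, params = sim_params()) {
  if (any(n_meth_cpg < 0)) abort("n_meth_cpg must be >= 0")
  n <- as.numeric(n_meth_cpg)
  h <- params$enrich_hill
  params$enrich_ceiling * n^h / (n^h + params$enrich_half_sat^h)
}

# Place `n` non-overlapping intervals with lengths drawn from len_range,
# uniformly on [0, chrom_len), with a margin between intervals. Optionally
# avoid a tibble of forbidden intervals. Returns sorted tibble.
place_intervals <- function(n, chrom_len, len_range, margin = 500L,
                            avoid = NULL, max_tries = 20000L) {
  starts <- numeric(0); ends <- numeric(0)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) abort("infeasible interval packing")
    len <- round(runif(1, len_range[1], len_range[2]))
    s <- floor(runif(1, 0, chrom_len - len))
    e <- s + len
    if (any(starts < e + margin & ends + margin > s)) next
    if (!is.null(avoid) && nrow(avoid) > 0L &&
        any(avoid$start < e & avoid$end > s)) next
    starts <- c(starts, s); ends <- c(ends, e)
  }
  ord <- order(starts)
  tibble::tibble(start = as.integer(starts[ord]), end = as.integer(ends[ord]))
}

# Raw sequence for one chromosome: base composition follows a smooth GC
# field (so neighbouring probes share GC content), accidental CG
# dinucleotides are removed, and CpGs are planted explicitly afterwards.
simulate_sequence <- function(len, params) {
  block <- 500L
  n_block <- ceiling(len / block)
  half_w <- max(1L, round(params$gc_field_scale_bp / block / 2))
  raw <- rnorm(n_block + 2L * half_w)
  sm <- stats::filter(raw, rep(1 / (2 * half_w + 1), 2 * half_w + 1), sides = 2)
  sm <- sm[(half_w + 1):(half_w + n_block)]
  sm <- sm / max(sd(sm), 1e-9)
  gcp <- pmin(pmax(0.40 * (1 + params$gc_field_amplitude * sm), 0.20), 0.65)
  gcp_pos <- rep(gcp, each = block)[seq_len(len)]
  u <- runif(len)
  base <- ifelse(u < gcp_pos / 2, "C",
          ifelse(u < gcp_pos, "G",
          ifelse(u < gcp_pos + (1 - gcp_pos) / 2, "A", "T")))
  # kill accidental CG dinucleotides: C followed by G -> C followed by A
  cg <- which(base[-len] == "C" & base[-1L] == "G")
  if (length(cg) > 0L) base[cg + 1L] <- "A"
  base
}

# Plant CpG dinucleotides at `rate` per kbp within [start, end) intervals
# of a base vector; candidate sites are every 3rd position so planted CpGs
# never overlap. Returns the modified base vector.
plant_cpgs <- function(base, intervals, rate) {
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    cand <- seq.int(s + 1L, max(s + 1L, e - 2L), by = 3L)  # 1-based C position
    take <- runif(length(cand)) < rate * 3 / 1000
    pos <- cand[take]
    base[pos] <- "C"; base[pos + 1L] <- "G"
  }
  base
}

#' Simulate a genome with CpG islands, genes, conservation and TFBS tracks
#'
#' Background sequence carries very low CpG density (below the null-probe
#' threshold), with high-CpG islands, strand-assigned multi-exon gene
#' models whose introns span both metagene length classes, a conservation
#' track covering part of the intergenic space, and TFBS intervals.
#'
#' @param params A `sim_params` list.
#' @param seed Integer seed; the output is a pure function of
#'   `(params, seed)`.
#' @return A list: `genome` (named character vector), `islands`, `genes`
#'   (a `gene_models`), `conservation` (bedGraph tibble), `tfbs`, and
#'   `params`.
#' @export
simulate_genome <- function(params = sim_params(), seed) {
  if (missing(seed)) abort("`seed` is required")
  set.seed(seed)
  genome <- list(); islands <- list(); genes <- list()
  conservation <- list(); tfbs <- list()
  for (cr in names(params$chrom_lengths)) {
    len <- params$chrom_lengths[[cr]]
    base <- simulate_sequence(len, params)
    n_isl <- round(params$islands_per_mb * len / 1e6)
    isl <- if (n_isl > 0L) {
      place_intervals(n_isl, len, params$island_length_range)
    } else tibble::tibble(start = integer(), end = integer())
    base <- plant_cpgs(base, tibble::tibble(start = 0L, end = len),
                       params$background_cpg_rate)
    if (nrow(isl) > 0L) base <- plant_cpgs(base, isl, params$island_cpg_rate)
    islands[[cr]] <- dplyr::mutate(isl, chrom = cr, .before = 1)

    n_gene <- round(params$genes_per_mb * len / 1e6)
    genes[[cr]] <- simulate_genes(cr, len, n_gene, params)

    intergenic_len <- len - sum(genes[[cr]]$end - genes[[cr]]$start)
    n_cons <- max(1L, round(params$conserved_frac * intergenic_len / 1500))
    cons <- place_intervals(n_cons, len, c(500L, 2500L), margin = 200L,
                            avoid = genes[[cr]][, c("start", "end")])
    conservation[[cr]] <- tibble::tibble(chrom = cr, start = cons$start,
                                         end = cons$end, score = 0.9)
    n_tf <- round(params$tfbs_per_mb * len / 1e6)
    tf <- place_intervals(n_tf, len, c(10L, 25L), margin = 100L)
    tfbs[[cr]] <- dplyr::mutate(tf, chrom = cr, .before = 1)

    genome[[cr]] <- paste(base, collapse = "")
  }
  list(genome = unlist(genome),
       islands = dplyr::bind_rows(islands),
       genes = as_gene_models(dplyr::bind_rows(genes)),
       conservation = dplyr::bind_rows(conservation),
       tfbs = dplyr::bind_rows(tfbs),
       params = params)
}

# Gene models for one chromosome: exon/intron structures built outward
# from random anchors, introns drawn half from the short and half from the
# long metagene class.
simulate_genes <- function(cr, chrom_len, n_gene, params) {
  out <- list()
  occupied <- tibble::tibble(start = integer(), end = integer())
  tries <- 0L
  while (length(out) < n_gene) {
    tries <- tries + 1L
    if (tries > 200L * n_gene) abort("infeasible gene packing")
    n_ex <- sample(params$exon_count_range[1]:params$exon_count_range[2], 1L)
    ex_len <- round(runif(n_ex, params$exon_length_range[1],
                          params$exon_length_range[2]))
    n_in <- n_ex - 1L
    short <- runif(n_in) < 0.5
    in_len <- ifelse(short,
      round(runif(n_in, params$intron_short_range[1],
                  params$intron_short_range[2] - 1L)),
      round(runif(n_in, params$intron_long_range[1],
                  params$intron_long_range[2])))
    span <- sum(ex_len) + sum(in_len)
    if (span >= chrom_len - 4000L) next
    s <- floor(runif(1, 2000, chrom_len - span - 2000))
    e <- s + span
    if (any(occupied$start < e + 4000L & occupied$end + 4000L > s)) next
    ex_starts <- s + cumsum(c(0L, head(ex_len, -1L) + in_len))
    occupied <- dplyr::bind_rows(occupied,
                                 tibble::tibble(start = s, end = e))
    out[[length(out) + 1L]] <- tibble::tibble(
      gene_id = sprintf("%s_g%03d", cr, length(out) + 1L),
      chrom = cr, start = as.integer(s), end = as.integer(e),
      strand = sample(c("+", "-"), 1L),
      exon_starts = list(as.integer(ex_starts)),
      exon_ends = list(as.integer(ex_starts + ex_len)))
  }
  genomic_order(dplyr::bind_rows(out))
}

#' Tile a probe design across a simulated genome
#'
#' @param genome Named character vector of sequences.
#' @param spacing,length Probe spacing and length in bp.
#' @return A `probe_design` with `gc_count` computed from the sequence.
#' @export
tile_design <- function(genome, spacing = 35L, length = 25L) {
  out <- purrr::imap(genome, function(seq, cr) {
    L <- nchar(seq)
    starts <- seq.int(0L, L - length, by = spacing)
    is_gc <- strsplit(seq, NULL)[[1]] %in% c("C", "G")
    cum <- c(0L, cumsum(is_gc))
    tibble::tibble(
      probe_id = sprintf("%s_p%07d", cr, seq_along(starts)),
      chrom = cr, start = starts, end = starts + length,
      gc_count = cum[starts + length + 1L] - cum[starts + 1L])
  })
  as_probe_design(dplyr::bind_rows(out))
}

#' Plant methylation ground truth
#'
#' Methylated intervals are planted with elevated CpG density (so the
#' saturating enrichment response produces signal) either anywhere in the
#' genome or preferentially inside CpG islands
#' (`params$island_meth_frac`). For two-sample designs a fraction of
#' sample-A intervals is withheld from sample B as the planted
#' differential set.
#'
#' @param sim Output of [simulate_genome()]; its genome is modified in
#'   place (CpGs planted inside methylated intervals) and returned.
#' @param params A `sim_params`.
#' @param seed Integer seed.
#' @param samples Sample labels.
#' @param differential_frac Fraction of intervals methylated in the first
#'   sample only.
#' @param target_compartments When `TRUE`, differential intervals are
#'   anchored on gene models so that the planted differential set spans
#'   all five genomic compartments (gene upstream, gene downstream, exon,
#'   intron, intergenic), with lengths above the differential-call length
#'   threshold so every planted interval is in principle callable.
#' @return `sim` with added `truth`: a list with `intervals` (tibble
#'   `chrom`, `start`, `end`, `in_island`, `differential`, plus one
#'   logical column per sample) and `meth_cpg` (per sample, sorted
#'   methylated CpG positions per chromosome).
#' @export
plant_methylation <- function(sim, params = sim$params, seed,
                              samples = "A", differential_frac = 0,
                              target_compartments = FALSE) {
  if (missing(seed)) abort("`seed` is required")
  set.seed(seed)
  n <- params$meth_regions
  n_targeted <- if (target_compartments) round(differential_frac * n) else 0L
  targeted <- if (n_targeted > 0L) {
    place_compartment_intervals(n_targeted, sim, params)
  } else NULL
  n <- n - n_targeted
  n_island <- round(params$island_meth_frac * n)
  per_chrom <- table(factor(
    sample(names(params$chrom_lengths), n, replace = TRUE,
           prob = as.numeric(params$chrom_lengths)),
    levels = names(params$chrom_lengths)))
  iv <- list()
  for (cr in names(params$chrom_lengths)) {
    k <- as.integer(per_chrom[[cr]])
    if (k == 0L) next
    isl <- sim$islands[sim$islands$chrom == cr, ]
    k_isl <- min(round(n_island * k / n), nrow(isl))
    inside <- if (k_isl > 0L) {
      pick <- sample.int(nrow(isl), k_isl)
      tibble::tibble(start = isl$start[pick], end = isl$end[pick],
                     in_island = TRUE)
    } else NULL
    k_out <- k - k_isl
    outside <- if (k_out > 0L) {
      place_intervals(k_out, params$chrom_lengths[[cr]],
                      params$meth_length_range, margin = 1000L,
                      avoid = dplyr::bind_rows(
                        isl[, c("start", "end")],
                        if (is.null(inside)) NULL else inside[, c("start", "end")],
                        if (is.null(targeted)) NULL else
                          targeted[targeted$chrom == cr, c("start", "end")])) |>
        dplyr::mutate(in_island = FALSE)
    } else NULL
    iv[[cr]] <- dplyr::bind_rows(inside, outside) |>
      dplyr::mutate(chrom = cr, .before = 1) |>
      dplyr::arrange(.data$start)
  }
  intervals <- dplyr::bind_rows(iv)
  if (nrow(intervals) == 0L) {
    intervals <- tibble::tibble(chrom = character(), start = integer(),
                                end = integer(), in_island = logical())
  }
  if (!is.null(targeted)) {
    intervals$differential <- FALSE
    targeted$differential <- TRUE
    intervals <- genomic_order(dplyr::bind_rows(intervals, targeted))
  } else {
    n_diff <- round(differential_frac * nrow(intervals))
    diff_idx <- if (n_diff > 0L) sample.int(nrow(intervals), n_diff) else integer(0)
    intervals$differential <- seq_len(nrow(intervals)) %in% diff_idx
  }
  # boost CpG density inside planted non-island intervals
  for (cr in unique(intervals$chrom)) {
    sub <- intervals[intervals$chrom == cr & !intervals$in_island, ]
    if (nrow(sub) == 0L) next
    base <- strsplit(sim$genome[[cr]], NULL)[[1]]
    base <- plant_cpgs(base, sub, params$meth_cpg_rate)
    sim$genome[[cr]] <- paste(base, collapse = "")
  }
  for (s in samples) {
    intervals[[paste0("meth_", s)]] <-
      if (s == samples[1]) TRUE else !intervals$differential
  }
  meth_cpg <- lapply(setNames(samples, samples), function(s) {
    lapply(setNames(names(sim$genome), names(sim$genome)), function(cr) {
      sub <- intervals[intervals$chrom == cr & intervals[[paste0("meth_", s)]], ]
      cg <- cpg_starts(sim$genome[[cr]])
      keep <- rep(FALSE, length(cg))
      for (i in seq_len(nrow(sub))) {
        keep <- keep | (cg >= sub$start[i] & cg < sub$end[i])
      }
      cg[keep]
    })
  })
  sim$truth <- list(intervals = intervals, meth_cpg = meth_cpg,
                    samples = samples)
  sim
}

#' Draw simulated DNA fragment lengths
#'
#' Fragment lengths are i.i.d. gamma with mode `frag_modal_length` —
#' a smooth stand-in for pooling several 4-cutter restriction digests,
#' which approximates unbiased fragmentation around a modal size.
#'
#' @param n Number of fragments.
#' @param params A `sim_params`.
#' @return Numeric vector of lengths (bp).
#' @export
simulate_fragment_lengths <- function(n, params = sim_params()) {
  rgamma(n, shape = params$frag_shape,
         scale = params$frag_modal_length / (params$frag_shape - 1))
}

# Place n intervals anchored on gene models so the set spans all five
# genomic compartments, cycling upstream -> downstream -> exon -> intron
# -> intergenic. Lengths exceed the differential-call length threshold.
place_compartment_intervals <- function(n, sim, params, max_tries = 500L) {
  genes <- sim$genes
  comps <- rep(c("gene_upstream", "gene_downstream", "exon", "intron",
                 "intergenic"), length.out = n)
  introns <- gene_introns(genes)
  introns <- introns[introns$length >= 1500L, ]
  placed <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer())
  out <- vector("list", n)
  clear <- function(cr, s, e) {
    !any(placed$chrom == cr & placed$start < e + 500L & placed$end + 500L > s) &&
      !any(sim$islands$chrom == cr & sim$islands$start < e & sim$islands$end > s) &&
      s >= 0L && e <= params$chrom_lengths[[cr]]
  }
  for (j in seq_len(n)) {
    cmp <- comps[j]
    done <- FALSE
    for (try in seq_len(max_tries)) {
      if (cmp == "intergenic") {
        len <- as.integer(round(runif(1, 600, 1000)))
        cr <- sample(names(params$chrom_lengths), 1L,
                     prob = as.numeric(params$chrom_lengths))
        s <- floor(runif(1, 0, params$chrom_lengths[[cr]] - len))
        e <- s + len
        g <- genes[genes$chrom == cr, ]
        if (any(g$start - 3500L < e & g$end + 3500L > s)) next
      } else {
        g <- genes[sample.int(nrow(genes), 1L), ]
        cr <- g$chrom
        plus <- g$strand == "+"
        if (cmp == "gene_upstream") {
          len <- as.integer(round(runif(1, 600, 1000)))
          s <- if (plus) g$start - len - 100L else g$end + 100L
        } else if (cmp == "gene_downstream") {
          len <- as.integer(round(runif(1, 600, 1000)))
          s <- if (plus) g$end + 100L else g$start - len - 100L
        } else if (cmp == "exon") {
          len <- as.integer(round(runif(1, 600, 800)))
          es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
          if (length(es) < 3L) next
          k <- sample(2:(length(es) - 1L), 1L)   # internal exon
          s <- (es[k] + ee[k]) %/% 2L - len %/% 2L
        } else {  # intron
          len <- as.integer(round(runif(1, 600, 800)))
          itr <- introns[introns$gene_id == g$gene_id, ]
          if (nrow(itr) == 0L) next
          itr <- itr[sample.int(nrow(itr), 1L), ]
          if (itr$length < len + 400L) next
          s <- itr$start + 200L +
            sample.int(itr$length - len - 400L + 1L, 1L) - 1L
        }
        e <- s + len
      }
      if (!clear(cr, s, e)) next
      placed <- dplyr::bind_rows(placed,
                                 tibble::tibble(chrom = cr, start = s, end = e))
      out[[j]] <- tibble::tibble(chrom = cr, start = as.integer(s),
                                 end = as.integer(e), in_island = FALSE,
                                 compartment = cmp)
      done <- TRUE
      break
    }
    if (!done) {
      abort(sprintf("could not place a differential interval in compartment %s",
                    cmp))
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate duplicate M and T array hybridizations
#'
#' The total-input channel measures per-probe baseline affinity plus
#' noise. The methylated-enriched channel adds a GC probe effect
#' (proportional to probe G+C count, hence spatially autocorrelated
#' through the smooth base-composition field) and the saturating
#' enrichment response to the number of methylated CpGs on the fragment
#' covering the probe (fragment lengths i.i.d. gamma with the modal
#' length). Replicates differ only in noise.
#'
#' @param design A `probe_design` over the simulated genome.
#' @param sim Output of [plant_methylation()].
#' @param params A `sim_params`.
#' @param seed Integer seed.
#' @param n_replicates Replicates per channel.
#' @return An intensity tibble (`probe_id`, `sample`, `channel`,
#'   `replicate`, `log2_intensity`).
#' @export
simulate_arrays <- function(design, sim, params = sim$params, seed,
                            n_replicates = 2L) {
  if (missing(seed)) abort("`seed` is required")
  set.seed(seed)
  n <- nrow(design)
  affinity <- rnorm(n, params$t_baseline, params$affinity_sd)
  gc_effect <- params$gc_bias_coef * (design$gc_count - mean(design$gc_count))
  mid <- design$start + (design$end - design$start) %/% 2L
  out <- list()
  for (s in sim$truth$samples) {
    frag_len <- simulate_fragment_lengths(n, params)
    frag_off <- runif(n)
    lo <- mid - frag_off * frag_len
    hi <- lo + frag_len
    n_meth <- integer(n)
    for (cr in unique(design$chrom)) {
      idx <- which(design$chrom == cr)
      cg <- sim$truth$meth_cpg[[s]][[cr]]
      n_meth[idx] <- findInterval(hi[idx], cg) - findInterval(lo[idx], cg)
    }
    enrich <- enrichment_response(n_meth, params)
    for (rep_i in seq_len(n_replicates)) {
      out[[paste(s, "M", rep_i)]] <- tibble::tibble(
        probe_id = design$probe_id, sample = s, channel = "M",
        replicate = rep_i,
        log2_intensity = affinity + gc_effect + enrich +
          rnorm(n, 0, params$noise_sd))
      out[[paste(s, "T", rep_i)]] <- tibble::tibble(
        probe_id = design$probe_id, sample = s, channel = "T",
        replicate = rep_i,
        log2_intensity = affinity + rnorm(n, 0, params$noise_sd))
    }
  }
  dplyr::bind_rows(out)
}

#' Build a complete named simulation scenario
#'
#' Scenarios (study conditions used throughout the test suite):
#' * `null` — no methylation anywhere; region calls are false positives.
#' * `basic` — 200 methylated regions planted genome-wide in one sample.
#' * `biased` — as `null` but with a strong GC probe effect, for
#'   demonstrating that GC adjustment removes positional autocorrelation.
#' * `differential` — two samples; 40% of sample-A regions absent from
#'   sample B.
#' * `island_enriched` — 80% of methylated regions placed inside CpG
#'   islands.
#'
#' @param name Scenario name.
#' @param seed Integer master seed; genome, truth and arrays derive their
#'   seeds from it.
#' @param params Base `sim_params`; scenario-specific fields are
#'   overridden.
#' @param dir Optional directory; when given, all fixture files (FASTA,
#'   BED/BED12/bedGraph, design and intensity TSVs, truth JSON) are
#'   written there.
#' @return A scenario bundle: `genome`, `islands`, `genes`,
#'   `conservation`, `tfbs`, `design`, `intensity`, `truth`, `params`,
#'   `scenario`, `seed`.
#' @export
make_scenario <- function(name = c("null", "basic", "biased", "differential",
                                   "island_enriched"),
                          seed, params = sim_params(), dir = NULL) {
  if (!is.character(name) || name[1] %not in%
        c("null", "basic", "biased", "differential", "island_enriched")) {
    abort(paste0("unknown scenario '", name[1], "'; valid scenarios: ",
                 "null, basic, biased, differential, island_enriched"))
  }
  name <- name[1]
  if (missing(seed)) abort("`seed` is required")
  samples <- c("A")
  differential_frac <- 0
  target_compartments <- FALSE
  if (name == "null") params$meth_regions <- 0L
  if (name == "biased") {
    params$meth_regions <- 0L
    params$gc_bias_coef <- 0.18
  }
  if (name == "differential") {
    samples <- c("A", "B")
    differential_frac <- 0.4
    target_compartments <- TRUE
  }
  if (name == "island_enriched") {
    params$island_meth_frac <- 0.8
    # keep the island demand below the island supply (60 islands per Mb)
    params$meth_regions <- min(params$meth_regions, 120L)
  }
  sim <- simulate_genome(params, seed = derive_seed(seed, "genome"))
  sim <- plant_methylation(sim, params, seed = derive_seed(seed, "truth"),
                           samples = samples,
                           differential_frac = differential_frac,
                           target_compartments = target_compartments)
  design <- tile_design(sim$genome, params$probe_spacing, params$probe_length)
  intensity <- simulate_arrays(design, sim, params,
                               seed = derive_seed(seed, "arrays"))
  bundle <- c(sim, list(design = design, intensity = intensity,
                        scenario = name, seed = seed))
  class(bundle) <- "tilemeth_scenario"
  if (!is.null(dir)) write_scenario(bundle, dir)
  bundle
}

#' Write a scenario bundle to a fixture directory
#'
#' @param bundle A `tilemeth_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_bed(bundle$islands, file.path(dir, "cpg_islands.bed"))
  write_genes_bed12(bundle$genes, file.path(dir, "genes.bed12"))
  write_bedgraph(bundle$conservation, file.path(dir, "conservation.bedgraph"))
  write_bed(bundle$tfbs, file.path(dir, "tfbs.bed"))
  write_probe_design(bundle$design, file.path(dir, "design.tsv"))
  write_intensity_table(bundle$intensity, file.path(dir, "intensity.tsv"))
  truth <- bundle$truth
  jsonlite::write_json(
    list(scenario = bundle$scenario, seed = bundle$seed,
         params = unclass(bundle$params),
         intervals = truth$intervals),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
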