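# Genomic-compartment annotation of called regions, annotation overlap
# statistics, matched random-region permutation testing, and the intron
# metagene profile.

# Derived compartment windows for a gene_models tibble: upstream and
# downstream flanks are strand-oriented; introns are the gaps between
# consecutive exons.
gene_compartments <- function(genes, upstream_bp = 2000L, downstream_bp = 2000L) {
  plus <- genes$strand == "+"
  upstream <- tibble::tibble(
    chrom = genes$chrom,
    start = ifelse(plus, genes$start - upstream_bp, genes$end),
    end = ifelse(plus, genes$start, genes$end + upstream_bp))
  downstream <- tibble::tibble(
    chrom = genes$chrom,
    start = ifelse(plus, genes$end, genes$start - downstream_bp),
    end = ifelse(plus, genes$end + downstream_bp, genes$start))
  exons <- tibble::tibble(
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts), end = unlist(genes$exon_ends))
  introns <- gene_introns(genes)[, c("chrom", "start", "end")]
  list(gene_upstream = upstream, gene_downstream = downstream,
       exon = exons, intron = introns,
       body = genes[, c("chrom", "start", "end")])
}

#' Derive introns from gene models
#'
#' @param genes A `gene_models` tibble.
#' @return Tibble with one row per intron: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `length`.
#' @export
gene_introns <- function(genes) {
  out <- purrr::pmap_dfr(genes, function(gene_id, chrom, strand, exon_starts,
                                         exon_ends, ...) {
    if (length(exon_starts) < 2L) return(NULL)
    tibble::tibble(gene_id = gene_id, chrom = chrom,
                   start = exon_ends[-length(exon_ends)],
                   end = exon_starts[-1], strand = strand)
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character())
  }
  dplyr::mutate(out, length = .data$end - .data$start)
}

# Total bp of overlap between each query interval and an interval set
# (set first reduced to avoid double counting).
bp_overlap_each <- function(queries, subject) {
  out <- numeric(nrow(queries))
  for (cr in unique(queries$chrom)) {
    qi <- which(queries$chrom == cr)
    s <- subject[subject$chrom == cr, ]
    if (nrow(s) == 0L) next
    sr <- IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end))
    qr <- IRanges::IRanges(queries$start[qi] + 1L, queries$end[qi])
    ov <- IRanges::findOverlaps(qr, sr)
    if (length(ov) == 0L) next
    w <- IRanges::width(IRanges::pintersect(
      qr[S4Vectors::queryHits(ov)], sr[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[qi[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

# Distance from each query to the nearest gene body (0 when overlapping).
distance_to_genes <- function(queries, genes) {
  out <- rep(Inf, nrow(queries))
  for (cr in unique(queries$chrom)) {
    qi <- which(queries$chrom == cr)
    g <- genes[genes$chrom == cr, ]
    if (nrow(g) == 0L) next
    qr <- IRanges::IRanges(queries$start[qi] + 1L, queries$end[qi])
    gr <- IRanges::IRanges(g$start + 1L, g$end)
    nearest <- IRanges::nearest(qr, gr, select = "arbitrary")
    ok <- !is.na(nearest)
    out[qi[ok]] <- IRanges::distance(qr[ok], gr[nearest[ok]])
  }
  out
}

#' Classify regions into genomic compartments
#'
#' Each region receives one of five labels: `gene_upstream` (within
#' `upstream_bp` of a TSS, strand-oriented), `gene_downstream` (within
#' `downstream_bp` past the TTS), `exon`, `intron`, or `intergenic`. The
#' label is decided by majority base-pair overlap, with ties broken by the
#' precedence upstream > downstream > exon > intron. A region overlapping
#' no compartment window is `intergenic` only when it lies strictly more
#' than `proximal_bp` from every gene body; otherwise it is assigned the
#' flank (upstream/downstream) on whose side of the nearest gene it sits.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param genes A `gene_models` tibble.
#' @param upstream_bp,downstream_bp Flank window sizes in bp.
#' @param proximal_bp Distance defining "gene proximal" vs distal
#'   intergenic.
#' @return `regions` with an added `compartment` column.
#' @export
classify_regions <- function(regions, genes, upstream_bp = 2000L,
                             downstream_bp = 2000L, proximal_bp = 3000L) {
  comps <- gene_compartments(genes, upstream_bp, downstream_bp)
  precedence <- c("gene_upstream", "gene_downstream", "exon", "intron")
  ov <- sapply(precedence, function(nm) bp_overlap_each(regions, comps[[nm]]))
  ov <- matrix(ov, nrow = nrow(regions),
               dimnames = list(NULL, precedence))
  best <- apply(ov, 1L, function(r) {
    if (all(r == 0)) NA_character_ else precedence[which.max(r)]
  })
  none <- is.na(best)
  if (any(none)) {
    dist <- distance_to_genes(regions[none, , drop = FALSE], genes)
    flank <- flank_side(regions[none, , drop = FALSE], genes)
    best[none] <- ifelse(dist > proximal_bp, "intergenic", flank)
  }
  out <- tibble::as_tibble(regions)
  out$compartment <- best
  out
}

# For regions near (but not overlapping) genes: are they on the upstream
# or downstream side of the nearest gene, given its strand?
flank_side <- function(regions, genes) {
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], ]
    if (nrow(g) == 0L) { out[i] <- "intergenic"; next }
    mid <- (regions$start[i] + regions$end[i]) / 2
    d <- pmax(g$start - regions$end[i], regions$start[i] - g$end, 0)
    j <- which.min(d)
    before <- mid < (g$start[j] + g$end[j]) / 2
    out[i] <- if ((before && g$strand[j] == "+") || (!before && g$strand[j] == "-"))
      "gene_upstream" else "gene_downstream"
  }
  out
}

#' Per-compartment percentages of a region set
#'
#' @param regions Non-empty region tibble.
#' @param genes A `gene_models` tibble.
#' @param ... Passed to [classify_regions()].
#' @return Tibble with one row per compartment: `compartment`, `n`,
#'   `pct_regions`, `bp`, `pct_bp`; attributes `n_regions` and
#'   `total_kbp`.
#' @export
compartment_fractions <- function(regions, genes, ...) {
  if (nrow(regions) == 0L) abort("region set is empty")
  cls <- classify_regions(regions, genes, ...)
  all_comps <- c("gene_upstream", "gene_downstream", "exon", "intron",
                 "intergenic")
  out <- cls |>
    dplyr::mutate(len = .data$end - .data$start,
                  compartment = factor(.data$compartment, levels = all_comps)) |>
    dplyr::group_by(.data$compartment, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), bp = sum(.data$len), .groups = "drop") |>
    dplyr::mutate(pct_regions = 100 * .data$n / sum(.data$n),
                  pct_bp = 100 * .data$bp / sum(.data$bp),
                  compartment = as.character(.data$compartment))
  structure(out[, c("compartment", "n", "pct_regions", "bp", "pct_bp")],
            n_regions = nrow(cls),
            total_kbp = sum(cls$end - cls$start) / 1000,
            class = c("compartment_fractions", class(tibble::tibble())))
}

#' Scalar annotation-overlap statistics for a region set
#'
#' @param regions Region tibble.
#' @param track Annotation intervals (`chrom`, `start`, `end`; for
#'   `conserved_bp`, a bedGraph tibble with a `score` column).
#' @param mode One of `"bp_overlap"` (total bp of overlap with the track),
#'   `"count_overlapping"` (number of regions overlapping any interval),
#'   `"cpg_per_kbp"` (CG dinucleotides per kbp of region sequence;
#'   requires `genome`), `"conserved_bp"` (bp overlapping track bases with
#'   `score` strictly above `score_threshold`).
#' @param genome Named sequence vector, required for `cpg_per_kbp`.
#' @param score_threshold Conservation score cutoff (strict `>`).
#' @return A single number.
#' @export
overlap_stats <- function(regions, track = NULL,
                          mode = c("bp_overlap", "count_overlapping",
                                   "cpg_per_kbp", "conserved_bp"),
                          genome = NULL, score_threshold = 0.8) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) abort(sprintf("unknown mode '%s'", mode[1])))
  if (nrow(regions) == 0L) return(0)
  switch(mode,
    bp_overlap = sum(bp_overlap_each(regions, track)),
    count_overlapping = sum(bp_overlap_each(regions, track) > 0),
    conserved_bp = {
      conserved <- track[track$score > score_threshold, ]
      sum(bp_overlap_each(regions, conserved))
    },
    cpg_per_kbp = {
      if (is.null(genome)) abort("cpg_per_kbp requires `genome`")
      n_cg <- 0
      for (cr in unique(regions$chrom)) {
        cg <- cpg_starts(genome[[cr]])
        r <- regions[regions$chrom == cr, ]
        # count CGs lying wholly inside each region
        n_cg <- n_cg + sum(findInterval(r$end - 2L + 0.5, cg) -
                             findInterval(r$start - 0.5, cg))
      }
      1000 * n_cg / sum(regions$end - regions$start)
    })
}

#' Generate random region sets matched for length and array coverage
#'
#' For each of `q` sets, regions with exactly the observed multiset of
#' lengths are placed in rank order at uniformly chosen probe start sites,
#' rejecting placements that run off the chromosome, overlap a previously
#' placed region of the same set, or are not covered by the array (an
#' inter-probe gap above `coverage_gap` inside the placed region).
#'
#' @param regions Observed region tibble (with a `rank` column if placement
#'   order matters; otherwise file order is used).
#' @param design A `probe_design`.
#' @param q Number of random sets.
#' @param seed Integer seed.
#' @param coverage_gap Maximum tolerated inter-probe gap in bp.
#' @param max_retries Proposals per region before giving up.
#' @return Tibble of placed regions with columns `set` (1..q), `chrom`,
#'   `start`, `end`.
#' @export
generate_matched_random <- function(regions, design, q = 500L, seed,
                                    coverage_gap = 250L,
                                    max_retries = 10000L) {
  if (missing(seed)) abort("`seed` is required")
  set.seed(seed)
  lens <- regions$end - regions$start
  if (!is.null(regions$rank)) lens <- lens[order(regions$rank)]
  chroms <- unique(design$chrom)
  # per-chromosome probe geometry, plus a "run id" that increments at every
  # inter-probe gap larger than coverage_gap, so coverage is O(1) to test
  geo <- lapply(chroms, function(cr) {
    idx <- which(design$chrom == cr)
    st <- design$start[idx]; en <- design$end[idx]
    gap_big <- c(FALSE, st[-1] - en[-length(en)] > coverage_gap)
    list(start = st, end = en, run = cumsum(gap_big), max = max(en))
  })
  names(geo) <- chroms
  n_per_chrom <- vapply(geo, function(g) length(g$start), integer(1))
  chrom_weight <- n_per_chrom / sum(n_per_chrom)

  place_set <- function(set_id) {
    placed <- lapply(chroms, function(cr) list(start = numeric(), end = numeric()))
    names(placed) <- chroms
    out_chrom <- character(length(lens))
    out_start <- integer(length(lens))
    for (ri in seq_along(lens)) {
      len <- lens[ri]
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cr <- sample(chroms, 1L, prob = chrom_weight)
        g <- geo[[cr]]
        pi <- sample.int(length(g$start), 1L)
        s <- g$start[pi]; e <- s + len
        if (e > g$max) next
        # coverage: last probe starting before e must be in the same run
        # and reach within coverage_gap of e
        pj <- findInterval(e - 0.5, g$start)
        if (g$run[pj] != g$run[pi] || e - g$end[pj] > coverage_gap) next
        # overlap with already placed regions of this set
        p <- placed[[cr]]
        if (length(p$start) > 0L) {
          k <- findInterval(e - 0.5, p$start)
          if (k > 0L && p$end[k] > s) next
        }
        ins <- findInterval(s, p$start)
        placed[[cr]] <- list(start = append(p$start, s, ins),
                             end = append(p$end, e, ins))
        out_chrom[ri] <- cr; out_start[ri] <- s
        ok <- TRUE
        break
      }
      if (!ok) {
        abort(sprintf("failed to place a region of length %d after %d retries (set %d)",
                      len, max_retries, set_id))
      }
    }
    tibble::tibble(set = set_id, chrom = out_chrom, start = out_start,
                   end = out_start + lens)
  }
  dplyr::bind_rows(lapply(seq_len(q), place_set))
}

#' Permutation p-value for annotation enrichment
#'
#' `p = N / Q` where `N` counts random sets whose statistic strictly
#' exceeds the observed one and `Q` is the number of random sets.
#'
#' @param observed Observed statistic.
#' @param randoms Numeric vector of statistics from random sets.
#' @return An `enrichment_result` list: `observed`, `randoms`, `n_exceed`,
#'   `q_total`, `p_value`.
#' @export
enrichment_p <- function(observed, randoms) {
  if (length(randoms) == 0L) abort("`randoms` must be non-empty")
  n_exceed <- sum(randoms > observed)
  structure(list(observed = observed, randoms = randoms,
                 n_exceed = n_exceed, q_total = length(randoms),
                 p_value = n_exceed / length(randoms)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment test: observed = %.4g, Q = %d, N(random > obs) = %d, p = %.4g\n",
              x$observed, x$q_total, x$n_exceed, x$p_value))
  invisible(x)
}

#' Matched-random enrichment test for one annotation
#'
#' Convenience wrapper chaining [overlap_stats()],
#' [generate_matched_random()] and [enrichment_p()].
#'
#' @inheritParams generate_matched_random
#' @inheritParams overlap_stats
#' @return An `enrichment_result`.
#' @export
test_enrichment <- function(regions, design, track, mode = "bp_overlap",
                            q = 500L, seed, genome = NULL,
                            score_threshold = 0.8, coverage_gap = 250L) {
  observed <- overlap_stats(regions, track, mode, genome, score_threshold)
  rand <- generate_matched_random(regions, design, q = q, seed = seed,
                                  coverage_gap = coverage_gap)
  randoms <- vapply(split(rand, rand$set), overlap_stats,
                    numeric(1), track = track, mode = mode, genome = genome,
                    score_threshold = score_threshold)
  enrichment_p(observed, unname(randoms))
}

#' Intron metagene profile of a smoothed track
#'
#' Each intron is rescaled to relative coordinates 0-100% (oriented so 0%
#' is the intron start in transcript direction), probe values are assigned
#' to bins by the relative position of the probe midpoint, averaged within
#' each intron per bin and then across introns per bin, separately for a
#' short and a long intron length class.
#'
#' @param track A `signal_track` at stage `smoothed`.
#' @param genes A `gene_models` tibble.
#' @param n_bins Number of relative-position bins.
#' @param short_range,long_range Intron length classes in bp; the short
#'   class is half-open `[short_range[1], short_range[2])`, the long class
#'   closed `[long_range[1], long_range[2]]`.
#' @return An `intron_profile` tibble: `class`, `bin`, `rel_pos`,
#'   `mean_signal`, `n_introns`.
#' @export
intron_profile <- function(track, genes, n_bins = 100L,
                           short_range = c(842L, 2715L),
                           long_range = c(2715L, 11673L)) {
  assert_stage(track, c("smoothed", "adjusted"))
  introns <- gene_introns(genes)
  introns$class <- dplyr::case_when(
    introns$length >= short_range[1] & introns$length < short_range[2] ~ "short",
    introns$length >= long_range[1] & introns$length <= long_range[2] ~ "long",
    TRUE ~ NA_character_)
  introns <- introns[!is.na(introns$class), ]
  profile_class <- function(cls) {
    sub <- introns[introns$class == cls, ]
    if (nrow(sub) == 0L) {
      return(tibble::tibble(class = cls, bin = integer(), rel_pos = double(),
                            mean_signal = double(), n_introns = 0L))
    }
    per_intron <- purrr::pmap_dfr(sub[, c("chrom", "start", "end", "strand")],
      function(chrom, start, end, strand) {
        idx <- which(track$chrom == chrom & track$start >= start &
                       track$start < end)
        if (length(idx) == 0L) return(NULL)
        mid <- track$start[idx] + 12L
        rel <- (mid - start) / (end - start)
        if (strand == "-") rel <- 1 - rel
        bin <- pmin(pmax(floor(rel * n_bins) + 1L, 1L), n_bins)
        tibble::tibble(intron = paste(chrom, start), bin = bin,
                       value = track$value[idx])
      })
    per_intron |>
      dplyr::group_by(.data$intron, .data$bin) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(mean_signal = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(class = cls, rel_pos = 100 * (.data$bin - 0.5) / n_bins,
                    n_introns = nrow(sub)) |>
      dplyr::select("class", "bin", "rel_pos", "mean_signal", "n_introns")
  }
  out <- dplyr::bind_rows(profile_class("short"), profile_class("long"))
  structure(out, n_bins = n_bins,
            class = c("intron_profile", class(tibble::tibble())))
}

#' Count regions overlapping intron-exon boundaries
#'
#' Boundary points are exon edges interior to a transcript (every exon
#' start except the first and every exon end except the last). A region
#' counts once if, after extension by `flank` on both sides, it covers at
#' least one boundary coordinate.
#'
#' @param regions Region tibble.
#' @param genes A `gene_models` tibble.
#' @param flank Extension in bp applied to each region before testing.
#' @return Number of regions covering a boundary.
#' @export
junction_overlap <- function(regions, genes, flank = 0L) {
  bounds <- purrr::pmap_dfr(genes, function(chrom, exon_starts, exon_ends, ...) {
    n <- length(exon_starts)
    if (n < 2L) return(NULL)
    tibble::tibble(chrom = chrom,
                   pos = c(exon_starts[-1], exon_ends[-n]))
  })
  if (nrow(bounds) == 0L || nrow(regions) == 0L) return(0L)
  hits <- logical(nrow(regions))
  for (cr in unique(regions$chrom)) {
    qi <- which(regions$chrom == cr)
    pos <- sort(bounds$pos[bounds$chrom == cr])
    if (length(pos) == 0L) next
    lo <- regions$start[qi] - flank
    hi <- regions$end[qi] + flank
    hits[qi] <- (findInterval(hi - 0.5, pos) - findInterval(lo - 0.5, pos)) > 0
  }
  sum(hits)
}
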