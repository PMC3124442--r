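# Compartment classification, overlap statistics, matched random sets,
# enrichment p-values, intron profiles and junction counting.

fixture_genes <- function() {
  as_gene_models(tibble::tibble(
    gene_id = c("g_plus", "g_minus"), chrom = "chrT",
    start = c(10000L, 60000L), end = c(20000L, 70000L),
    strand = c("+", "-"),
    exon_starts = list(c(10000L, 13000L, 18000L), c(60000L, 66000L)),
    exon_ends = list(c(10500L, 13400L, 20000L), c(60800L, 70000L))))
}

test_that("regions classify by majority overlap with precedence", {
  genes <- fixture_genes()
  regions <- tibble::tibble(
    chrom = "chrT",
    start = c(14000L, 9200L, 40000L, 19500L, 70100L),
    end = c(14600L, 10200L, 41000L, 20500L, 71100L))
  got <- classify_regions(regions, genes)$compartment
  # wholly inside an intron
  expect_equal(got[1], "intron")
  # straddles the TSS with most bp in the 2 kb upstream window
  expect_equal(got[2], "gene_upstream")
  # > 3 kb from every gene
  expect_equal(got[3], "intergenic")
  # straddles the TTS of g_plus with most bp downstream
  expect_equal(got[4], "gene_downstream")
  # just past the minus-strand gene's 5' end: upstream by strand
  expect_equal(got[5], "gene_upstream")
})

test_that("near-gene regions without window overlap use the proximal rule", {
  genes <- fixture_genes()
  # 2.5 kb upstream of g_plus: outside the 2 kb window but within 3 kb
  r_near <- tibble::tibble(chrom = "chrT", start = 7200L, end = 7400L)
  expect_equal(classify_regions(r_near, genes)$compartment, "gene_upstream")
  # 5 kb away: intergenic
  r_far <- tibble::tibble(chrom = "chrT", start = 4800L, end = 5000L)
  expect_equal(classify_regions(r_far, genes)$compartment, "intergenic")
})

test_that("compartment fractions sum to 100 and ignore region order", {
  genes <- fixture_genes()
  regions <- tibble::tibble(
    chrom = "chrT",
    start = c(14000L, 30000L, 40000L, 9200L, 61000L),
    end = c(14600L, 30500L, 41000L, 10200L, 61700L))
  cf <- compartment_fractions(regions, genes)
  expect_equal(sum(cf$pct_regions), 100)
  expect_equal(sum(cf$pct_bp), 100)
  expect_equal(attr(cf, "n_regions"), 5L)
  shuffled <- compartment_fractions(regions[c(3, 1, 5, 2, 4), ], genes)
  expect_equal(cf$pct_regions, shuffled$pct_regions)

  only_far <- tibble::tibble(chrom = "chrT", start = 40000L, end = 41000L)
  cf2 <- compartment_fractions(only_far, genes)
  expect_equal(cf2$pct_regions[cf2$compartment == "intergenic"], 100)
  expect_error(compartment_fractions(regions[0, ], genes), "empty")
})

test_that("overlap statistics match interval arithmetic", {
  track <- tibble::tibble(chrom = "chrT", start = c(1000L, 5000L),
                          end = c(1400L, 5600L))
  regions <- tibble::tibble(chrom = "chrT", start = c(900L, 5500L),
                            end = c(1100L, 5800L))
  # each region overlaps one island by 100 bp
  expect_equal(overlap_stats(regions, track, "bp_overlap"), 200)
  expect_equal(overlap_stats(regions, track, "count_overlapping"), 2)
  far <- tibble::tibble(chrom = "chrT", start = 90000L, end = 90100L)
  expect_equal(overlap_stats(far, track, "bp_overlap"), 0)
  expect_error(overlap_stats(regions, track, "bogus"), "unknown mode")

  # conserved_bp uses a strict score threshold
  cons <- tibble::tibble(chrom = "chrT", start = c(900L, 5500L),
                         end = c(1000L, 5700L), score = c(0.8, 0.81))
  expect_equal(overlap_stats(regions, cons, "conserved_bp"), 200)

  # random instances against the naive O(n*m) oracle
  set.seed(21)
  for (rep in 1:20) {
    nq <- sample(1:60, 1); ns <- sample(1:60, 1)
    qs <- sort(sample.int(20000L, nq)); ss <- sort(sample.int(20000L, ns))
    q <- tibble::tibble(chrom = "c", start = qs, end = qs + sample(10:400, nq, TRUE))
    s <- tibble::tibble(chrom = "c", start = ss, end = ss + sample(10:400, ns, TRUE))
    expect_equal(overlap_stats(q, s, "bp_overlap"),
                 oracle_bp_overlap(q$start, q$end, s$start, s$end))
  }
})

test_that("cpg_per_kbp counts dinucleotides in region sequence", {
  genome <- c(chrT = paste0(strrep("A", 100), "CGCG", strrep("T", 896)))
  regions <- tibble::tibble(chrom = "chrT", start = 0L, end = 500L)
  expect_equal(overlap_stats(regions, mode = "cpg_per_kbp", genome = genome),
               2 / 0.5)
  expect_error(overlap_stats(regions, mode = "cpg_per_kbp"), "genome")
})

test_that("enrichment p counts strict exceedances", {
  expect_equal(enrichment_p(10, rep(5, 500))$p_value, 0)       # ties favour significance
  expect_equal(enrichment_p(10, c(rep(5, 490), rep(11, 10)))$p_value, 0.02)
  expect_equal(enrichment_p(99, runif(500))$p_value, 0)
  res <- enrichment_p(0.5, runif(200))
  expect_equal(res$n_exceed / res$q_total, res$p_value)
  expect_error(enrichment_p(1, numeric(0)), "non-empty")
  g <- glance(res)
  expect_equal(g$q_total, 200L)
})

test_that("matched random sets preserve lengths, stay on probe starts, and respect the seed", {
  b <- small_basic()
  nulls <- select_null_probes(b$design, b$genome, min_null = 100L)
  tr <- preprocess_sample(b$intensity, b$design, nulls, "A")
  rs <- call_regions(get_track(tr, b$design, "z"), b$design)
  expect_gt(nrow(rs), 10L)

  rand <- generate_matched_random(rs, b$design, q = 5L, seed = 123L)
  for (si in 1:5) {
    set_i <- rand[rand$set == si, ]
    # exact length multiset
    expect_equal(sort(set_i$end - set_i$start), sort(rs$end - rs$start))
    # starts are probe starts
    expect_true(all(paste(set_i$chrom, set_i$start) %in%
                      paste(b$design$chrom, b$design$start)))
    # non-overlapping within the set
    for (cr in unique(set_i$chrom)) {
      sub <- dplyr::arrange(set_i[set_i$chrom == cr, ], start)
      if (nrow(sub) > 1L) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
  again <- generate_matched_random(rs, b$design, q = 5L, seed = 123L)
  expect_identical(rand, again)
  other <- generate_matched_random(rs, b$design, q = 5L, seed = 124L)
  expect_false(identical(rand, other))
})

test_that("random placement is deterministic when only one slot fits", {
  # design covers a single contiguous window barely larger than the region
  design <- as_probe_design(tibble::tibble(
    probe_id = sprintf("p%d", 1:3), chrom = "chrT",
    start = c(0L, 35L, 70L), end = c(25L, 60L, 95L), gc_count = 10L))
  rs <- tibble::tibble(chrom = "chrT", start = 0L, end = 95L, rank = 1L)
  rand <- generate_matched_random(rs, design, q = 3L, seed = 1L)
  expect_true(all(rand$start == 0L))
  # an unplaceable length errors with the stuck length
  rs_big <- tibble::tibble(chrom = "chrT", start = 0L, end = 900L, rank = 1L)
  expect_error(generate_matched_random(rs_big, design, q = 1L, seed = 1L,
                                       max_retries = 50L),
               "length 900")
})

test_that("enrichment p is uniform when there is nothing to find", {
  b <- small_basic()
  template <- tibble::tibble(chrom = "chrS1",
                             start = seq(1000L, 29000L, by = 1400L))
  template$end <- template$start + 400L
  template$rank <- seq_len(nrow(template))
  track <- b$islands
  set.seed(314)
  ps <- vapply(1:120, function(i) {
    sets <- generate_matched_random(template, b$design, q = 41L,
                                    seed = 10000L + i)
    stats <- vapply(split(sets, sets$set), overlap_stats, numeric(1),
                    track = track, mode = "bp_overlap")
    enrichment_p(stats[[1]], unname(stats[-1]))$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("intron profiles are flat for constant signal and mirror by strand", {
  genes <- fixture_genes()
  design <- toy_design(n = 2500L, chrom = "chrT")
  flat <- new_signal_track(design, rep(0.7, 2500), "adjusted")
  attr(flat, "stage") <- "smoothed"
  prof <- intron_profile(flat, genes, n_bins = 20L)
  expect_true(all(abs(prof$mean_signal - 0.7) < 1e-12))

  # gradient along the chromosome: a minus-strand intron yields the exact
  # mirror of the same intron on the plus strand
  grad <- new_signal_track(design, seq(0, 1, length.out = 2500), "adjusted")
  attr(grad, "stage") <- "smoothed"
  one_gene <- function(strand) as_gene_models(tibble::tibble(
    gene_id = "g", chrom = "chrT", start = 1000L, end = 9000L,
    strand = strand, exon_starts = list(c(1000L, 7000L)),
    exon_ends = list(c(2000L, 9000L))))   # intron 2000..7000, long class
  pp <- intron_profile(grad, one_gene("+"), n_bins = 10L)
  pm <- intron_profile(grad, one_gene("-"), n_bins = 10L)
  expect_gt(pp$mean_signal[pp$bin == 10], pp$mean_signal[pp$bin == 1])
  expect_equal(pm$mean_signal, rev(pp$mean_signal))

  # no introns in class -> empty profile with n = 0
  single <- as_gene_models(tibble::tibble(
    gene_id = "solo", chrom = "chrT", start = 100L, end = 400L, strand = "+",
    exon_starts = list(100L), exon_ends = list(400L)))
  p3 <- intron_profile(flat, single)
  expect_equal(nrow(p3), 0L)
})

test_that("junction overlap counts regions once regardless of boundary count", {
  genes <- fixture_genes()
  # strictly inside one exon, touching no boundary
  inside <- tibble::tibble(chrom = "chrT", start = 13100L, end = 13300L)
  expect_equal(junction_overlap(inside, genes), 0L)
  # spanning a whole exon covers two boundaries but counts once
  spanning <- tibble::tibble(chrom = "chrT", start = 12900L, end = 13500L)
  expect_equal(junction_overlap(spanning, genes), 1L)
  # beyond all genes
  far <- tibble::tibble(chrom = "chrT", start = 200000L, end = 201000L)
  expect_equal(junction_overlap(far, genes), 0L)
  # flank extension can reach a nearby boundary
  near <- tibble::tibble(chrom = "chrT", start = 13450L, end = 13480L)
  expect_equal(junction_overlap(near, genes), 0L)
  expect_equal(junction_overlap(near, genes, flank = 100L), 1L)
})
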