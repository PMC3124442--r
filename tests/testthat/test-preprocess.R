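# Pre-processing: CpG density, null-probe selection, log-ratios, GC strata,
# running-median smoothing, and the autocorrelation/normality diagnostics.

test_that("local CpG density counts CG dinucleotides per kbp", {
  genome <- c(flat = strrep("A", 2000),
              three = paste0(strrep("A", 100), "CG", strrep("T", 200), "CG",
                             strrep("A", 300), "CG", strrep("T", 1396)))
  expect_equal(local_cpg_density(genome, "flat", 1000L, 1000L), 0)
  expect_equal(local_cpg_density(genome, "three", 500L, 1000L), 3)
  expect_error(local_cpg_density(genome, "nope", 10L), "unknown chromosome")
  expect_error(local_cpg_density(genome, "flat", 10L, window = 50L), ">= 100")

  # brute-force oracle across a random sequence, including the truncated ends
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  g <- c(rand = seq)
  pos <- as.integer(seq(0, 9999, by = 97))
  got <- local_cpg_density(g, "rand", pos, 1000L)
  lo <- pmax(pos - 500L, 0L)
  hi <- pmin(pos - 500L + 1000L, 10000L)
  want <- 1000 * oracle_count_cg(seq, lo, hi) / (hi - lo)
  expect_equal(got, want)
})

test_that("null probes are selected by strict density threshold", {
  # CpG-free chromosome: every probe is a null probe
  genome <- c(chrT = strrep("AT", 20000))
  design <- toy_design(n = 800L, chrom = "chrT")
  nulls <- select_null_probes(design, genome, min_null = 100L)
  expect_equal(nrow(nulls), nrow(design))

  # density exactly at the threshold is excluded (strict <)
  expect_true(all(nulls$cpg_density < 4))
  # one probe, window holding exactly 4 CpGs -> density 4.0, excluded;
  # with 3 CpGs -> 3.0, selected
  mk <- function(ncg) {
    c(one = paste0(strrep("A", 300), strrep("CGA", ncg),
                   strrep("T", 2000 - 300 - 3 * ncg)))
  }
  one_probe <- as_probe_design(tibble::tibble(
    probe_id = "p1", chrom = "one", start = 488L, end = 513L, gc_count = 10L))
  expect_error(select_null_probes(one_probe, mk(4), min_null = 1L), "threshold")
  expect_equal(nrow(select_null_probes(one_probe, mk(3), min_null = 1L)), 1L)
  expect_error(select_null_probes(design, genome, threshold = 0, min_null = 10L),
               "threshold")

  # probe-by-probe agreement with direct recomputation on simulated genome
  b <- small_basic()
  ns <- select_null_probes(b$design, b$genome, min_null = 100L)
  idx <- sample(seq_len(nrow(b$design)), 300)
  for (cr in unique(b$design$chrom[idx])) {
    sel <- idx[b$design$chrom[idx] == cr]
    mid <- b$design$start[sel] + (b$design$end[sel] - b$design$start[sel]) %/% 2L
    dens <- local_cpg_density(b$genome, cr, mid, 1000L)
    expect_equal(b$design$probe_id[sel] %in% ns$probe_id, dens < 4)
  }
})

test_that("log-ratios average replicates per channel before differencing", {
  design <- toy_design(n = 1L)
  tab <- tibble::tibble(
    probe_id = design$probe_id, sample = "s",
    channel = c("M", "M", "T", "T"), replicate = c(1L, 2L, 1L, 2L),
    log2_intensity = c(4, 6, 3, 3))
  lr <- compute_log_ratio(tab, design, "s")
  expect_equal(lr$value, 2)  # mean(4,6) - mean(3,3)
  expect_equal(track_stage(lr), "log_ratio")

  # replicate-null mode: T rep1 over T rep2
  rn <- compute_log_ratio(tab, design, "s", "T", "T", 1L, 2L)
  expect_equal(rn$value, 0)

  # a probe absent from one replicate only is an error, not an imputation
  design2 <- toy_design(n = 2L)
  tab2 <- tidyr::expand_grid(probe_id = design2$probe_id, sample = "s",
                             channel = c("M", "T"), replicate = c(1L, 2L))
  tab2$log2_intensity <- 5
  dropped <- tab2[!(tab2$probe_id == design2$probe_id[1] &
                      tab2$channel == "M" & tab2$replicate == 2L), ]
  expect_error(compute_log_ratio(dropped, design2, "s"), "missing probes")
})

test_that("replicate-null log-ratio is centred at zero on simulator data", {
  b <- small_basic()
  rn <- compute_log_ratio(b$intensity, b$design, "A", "T", "T", 1L, 2L)
  expect_lt(abs(median(rn$value)), 0.01)
})

test_that("GC baseline recovers a planted gc-linear effect exactly", {
  design <- toy_design(n = 3000L)
  design$gc_count <- rep(5:14, 300)
  nulls <- structure(tibble::as_tibble(design),
                     class = c("null_probes", class(tibble::tibble())))
  track <- new_signal_track(design, 0.1 * design$gc_count, "log_ratio")
  strata <- estimate_gc_baseline(track, nulls, design, min_bin_size = 100L)
  b <- tilemeth:::strata_rows(strata, design)
  expect_equal(strata$m[b], 0.1 * design$gc_count, tolerance = 1e-12)

  # adjustment wipes the planted baseline to machine zero
  adj <- adjust_signal(track, strata, design)
  expect_equal(adj$value, rep(0, 3000), tolerance = 1e-12)
  expect_equal(track_stage(adj), "adjusted")

  # all-constant null values: medians exact, scale falls back
  const <- new_signal_track(design, rep(1.5, 3000), "log_ratio")
  expect_warning(s2 <- estimate_gc_baseline(const, nulls, design, 100L),
                 "constant")
  expect_true(all(s2$m == 1.5))
  expect_true(all(s2$s > 0))

  # identity when all stratum medians are zero
  zero_strata <- toy_strata(m = 0, s = 1)
  t3 <- new_signal_track(design, rnorm(3000), "log_ratio")
  expect_equal(adjust_signal(t3, zero_strata, design)$value, t3$value)
})

test_that("sparse GC bins merge to meet the size floor", {
  design <- toy_design(n = 1200L)
  design$gc_count <- c(rep(10L, 1100), rep(24L, 100))  # 24 is undersized
  nulls <- structure(tibble::as_tibble(design),
                     class = c("null_probes", class(tibble::tibble())))
  track <- new_signal_track(design, rnorm(1200), "log_ratio")
  strata <- estimate_gc_baseline(track, nulls, design, min_bin_size = 200L)
  expect_equal(nrow(strata), 1L)
  expect_gte(min(strata$n), 200L)
  # every GC value maps to exactly one effective bin
  expect_true(all(attr(strata, "gc_map") %in% seq_len(nrow(strata))))
})

test_that("running median matches the brute-force oracle everywhere", {
  x <- c(0, 1, 9, 2, 3, 8, 4)
  design <- toy_design(n = 7L)
  tr <- new_signal_track(design, x, "adjusted")
  sm <- smooth_running_median(tr, 7L)
  expect_equal(sm$value[4], 3)                       # full-window centre
  expect_equal(sm$value, oracle_running_median(x, 7L))
  expect_equal(track_stage(sm), "smoothed")
  expect_error(smooth_running_median(tr, 4L), "odd")

  set.seed(11)
  design2 <- as_probe_design(tibble::tibble(
    probe_id = sprintf("p%05d", 1:10000),
    chrom = rep(c("c1", "c2"), c(6000, 4000)),
    start = c((1:6000) * 35L, (1:4000) * 35L),
    end = c((1:6000) * 35L, (1:4000) * 35L) + 25L, gc_count = 10L))
  y <- rnorm(10000)
  tr2 <- new_signal_track(design2, y, "adjusted")
  for (k in c(5L, 7L, 9L)) {
    got <- smooth_running_median(tr2, k)$value
    want <- c(oracle_running_median(y[1:6000], k),
              oracle_running_median(y[6001:10000], k))
    expect_equal(got, want)
  }
})

test_that("running median is shift-invariant and scale-equivariant", {
  set.seed(3)
  x <- rnorm(500)
  design <- toy_design(n = 500L)
  sm <- function(v) smooth_running_median(new_signal_track(design, v, "adjusted"), 7L)$value
  base <- sm(x)
  expect_equal(sm(x + 2.5), base + 2.5)
  expect_equal(sm(3 * x), 3 * base)
})

test_that("autocorrelation recovers known serial dependence", {
  design <- toy_design(n = 20000L)
  nulls <- structure(tibble::as_tibble(design),
                     class = c("null_probes", class(tibble::tibble())))
  set.seed(5)
  iid <- new_signal_track(design, rnorm(20000), "adjusted")
  expect_lt(abs(autocorrelation(iid, nulls)), 3 / sqrt(20000))

  ar <- stats::filter(rnorm(20000), 0.6, method = "recursive")
  tr <- new_signal_track(design, as.numeric(ar), "adjusted")
  expect_equal(autocorrelation(tr, nulls), 0.6, tolerance = 0.05)

  expect_error(autocorrelation(iid, nulls[1:50, ]), ">= 100")
  flat <- new_signal_track(design, rep(1, 20000), "adjusted")
  expect_error(autocorrelation(flat, nulls), "zero variance")
})

test_that("normality diagnostic separates normal from heavy-tailed nulls", {
  design <- toy_design(n = 10000L)
  nulls <- structure(tibble::as_tibble(design),
                     class = c("null_probes", class(tibble::tibble())))
  set.seed(9)
  normal <- new_signal_track(design, rnorm(10000), "adjusted")
  expect_lt(normality_diagnostic(normal, nulls), 0.05)
  heavy <- new_signal_track(design, stats::rt(10000, df = 2), "adjusted")
  expect_gt(normality_diagnostic(heavy, nulls), 0.05)
})

test_that("pipeline null probes look normal and stay centred", {
  b <- small_basic()
  nulls <- select_null_probes(b$design, b$genome, min_null = 100L)
  tr <- preprocess_sample(b$intensity, b$design, nulls, "A")
  sm <- new_signal_track(b$design, tr$smoothed, "adjusted")
  expect_lt(normality_diagnostic(sm, nulls), 0.1)
  idx <- match(nulls$probe_id, tr$probe_id)
  expect_lt(abs(median(tr$smoothed[idx])), 0.01)
})

test_that("re-estimating strata on adjusted data gives near-zero baselines", {
  b <- small_basic()
  nulls <- select_null_probes(b$design, b$genome, min_null = 100L)
  lr <- compute_log_ratio(b$intensity, b$design, "A")
  strata <- estimate_gc_baseline(lr, nulls, b$design)
  adj <- adjust_signal(lr, strata, b$design)
  re <- estimate_gc_baseline(adj, nulls, b$design)
  expect_true(all(abs(re$m) < 3 * re$s / sqrt(re$n)))
})
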