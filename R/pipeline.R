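# End-to-end pipeline driver: simulate or load inputs, preprocess, call
# regions, estimate FDR, call differential regions, annotate and test
# enrichment, writing all outputs plus a checksummed manifest.

#' Assemble and validate a run configuration
#'
#' A flat list of pipeline parameters. Validation happens before any
#' compute, so a bad parameter never produces partial output.
#'
#' @param scenario Scenario name for simulated input (see
#'   [make_scenario()]), or `NULL` to read files from `input_dir`.
#' @param input_dir Directory holding `design.tsv`, `intensity.tsv`,
#'   `genome.fa`, `genes.bed12`, `cpg_islands.bed` (as written by
#'   [write_scenario()]). Ignored when `scenario` is set.
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param null_window_bp,null_density_threshold Null-probe selection.
#' @param min_bin_size GC stratum size floor.
#' @param smoothing_k Running-median window (odd).
#' @param z_probe,z_region,merge_gap Region-calling thresholds.
#' @param min_diff_len Differential-call length threshold (bp).
#' @param enrichment_q Number of matched random sets.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(scenario = "basic", input_dir = NULL, out_dir,
                       seed = 1L, null_window_bp = 1000L,
                       null_density_threshold = 4, min_bin_size = 200L,
                       smoothing_k = 7L, z_probe = 3, z_region = 4,
                       merge_gap = 250L, min_diff_len = 500L,
                       enrichment_q = 500L, log_level = "info") {
  cfg <- as.list(environment())
  if (cfg$smoothing_k %% 2L == 0L) abort("smoothing_k must be odd")
  if (cfg$null_window_bp < 100L) abort("null_window_bp must be >= 100")
  if (cfg$merge_gap <= 0L || cfg$min_diff_len <= 0L || cfg$enrichment_q < 1L) {
    abort("merge_gap, min_diff_len and enrichment_q must be positive")
  }
  if (is.null(scenario) && is.null(input_dir)) {
    abort("either `scenario` or `input_dir` must be given")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from flat YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

pipe_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[tilemeth] %s", sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) inputs, preprocesses every sample, calls
#' methylated regions, estimates the replicate-input FDR, calls
#' differential regions when two samples are present, annotates regions by
#' genomic compartment, and runs the CpG-island enrichment test. All
#' outputs are plain text under `cfg$out_dir`; a `manifest.json` with md5
#' checksums and the echoed configuration makes every run reproducible.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$scenario)) {
    pipe_log(cfg, "simulating scenario '%s' (seed %d)", cfg$scenario, cfg$seed)
    bundle <- make_scenario(cfg$scenario, seed = cfg$seed)
  } else {
    pipe_log(cfg, "loading inputs from %s", cfg$input_dir)
    f <- function(x) file.path(cfg$input_dir, x)
    for (x in c("design.tsv", "intensity.tsv", "genome.fa", "genes.bed12",
                "cpg_islands.bed")) {
      if (!file.exists(f(x))) abort(sprintf("missing input file: %s", f(x)))
    }
    design <- read_probe_design(f("design.tsv"))
    bundle <- list(design = design,
                   intensity = read_intensity_table(f("intensity.tsv"), design),
                   genome = read_genome_fasta(f("genome.fa")),
                   genes = read_genes_bed12(f("genes.bed12")),
                   islands = read_bed(f("cpg_islands.bed")),
                   truth = list(samples = NULL))
    bundle$truth$samples <- unique(bundle$intensity$sample)
  }
  design <- bundle$design
  samples <- if (!is.null(bundle$truth$samples)) bundle$truth$samples
             else unique(bundle$intensity$sample)

  pipe_log(cfg, "selecting null probes (density < %.3g per kbp, %d bp window)",
           cfg$null_density_threshold, cfg$null_window_bp)
  nulls <- select_null_probes(design, bundle$genome,
                              threshold = cfg$null_density_threshold,
                              window = cfg$null_window_bp)

  results <- list()
  for (s in samples) {
    pipe_log(cfg, "preprocessing sample %s (k = %d)", s, cfg$smoothing_k)
    tracks <- preprocess_sample(bundle$intensity, design, nulls, s,
                                k = cfg$smoothing_k,
                                min_bin_size = cfg$min_bin_size)
    pipe_log(cfg, "calling regions (Z_probe > %.3g, additive Z > %.3g, gap < %d bp)",
             cfg$z_probe, cfg$z_region, cfg$merge_gap)
    regions <- call_regions(get_track(tracks, design, "z"), design,
                            z_probe = cfg$z_probe, z_region = cfg$z_region,
                            merge_gap = cfg$merge_gap, sample = s)
    fdr <- if (nrow(regions) > 0L) {
      estimate_fdr(bundle$intensity, design, nulls, s, nrow(regions),
                   k = cfg$smoothing_k, min_bin_size = cfg$min_bin_size,
                   z_probe = cfg$z_probe, z_region = cfg$z_region,
                   merge_gap = cfg$merge_gap)
    } else NA_real_
    pipe_log(cfg, "sample %s: %d regions, FDR %.4f", s, nrow(regions),
             as.numeric(fdr))
    write_regions_bed(regions, file.path(cfg$out_dir,
                                         sprintf("regions_%s.bed", s)))
    write_track(get_track(tracks, design, "smoothed"),
                file.path(cfg$out_dir, sprintf("smoothed_%s.tsv", s)))
    results[[s]] <- list(tracks = tracks, regions = regions, fdr = fdr)
  }
  writeLines(
    vapply(samples, function(s) sprintf("%s\t%d\t%s", s,
                                        nrow(results[[s]]$regions),
                                        format(as.numeric(results[[s]]$fdr))),
           character(1)),
    file.path(cfg$out_dir, "fdr.tsv"))

  if (length(samples) >= 2L) {
    a <- samples[1]; b <- samples[2]
    pipe_log(cfg, "differential calls %s vs %s", a, b)
    diff <- call_differential(
      results[[a]]$regions, get_track(results[[a]]$tracks, design, "z"),
      results[[b]]$regions, get_track(results[[b]]$tracks, design, "z"),
      design, min_len = cfg$min_diff_len, labels = c(a, b))
    readr::write_tsv(diff, file.path(cfg$out_dir, "differential.tsv"),
                     progress = FALSE)
    results$differential <- diff
  }

  if (!is.null(bundle$genes)) {
    s1 <- samples[1]
    if (nrow(results[[s1]]$regions) > 0L) {
      annot <- classify_regions(results[[s1]]$regions, bundle$genes)
      readr::write_tsv(annot, file.path(cfg$out_dir, "annotation.tsv"),
                       progress = FALSE)
      results$annotation <- annot
      if (!is.null(bundle$islands) && nrow(bundle$islands) > 0L) {
        pipe_log(cfg, "CpG-island enrichment (Q = %d)", cfg$enrichment_q)
        enr <- test_enrichment(results[[s1]]$regions, design, bundle$islands,
                               mode = "bp_overlap", q = cfg$enrichment_q,
                               seed = derive_seed(cfg$seed, "enrichment"))
        readr::write_tsv(
          tibble::tibble(annotation = "cpg_islands", observed = enr$observed,
                         n_exceed = enr$n_exceed, q_total = enr$q_total,
                         p_value = enr$p_value),
          file.path(cfg$out_dir, "enrichment.tsv"), progress = FALSE)
        results$enrichment <- enr
      }
      prof <- intron_profile(get_track(results[[s1]]$tracks, design, "smoothed"),
                             bundle$genes)
      readr::write_tsv(prof, file.path(cfg$out_dir, "intron_profile.tsv"),
                       progress = FALSE)
      results$intron_profile <- prof
    }
  }

  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = unclass(cfg),
    outputs = lapply(setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
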