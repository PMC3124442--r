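# Readers and writers for the tabular interchange formats: probe designs,
# intensity tables, region sets, and annotation tracks. All genomic
# coordinates are 0-based half-open, on disk and in memory.

#' Read a tiling-array probe design
#'
#' The design file is a BED-like TSV with columns `chrom`, `start`, `end`,
#' `probe_id`, `gc_count` (0-based half-open coordinates). Probe length is
#' taken as `end - start`; `gc_count` is the G+C count of the probe
#' sequence and must not exceed the probe length.
#'
#' @param path Path to the design TSV.
#' @return A `probe_design` tibble with columns `probe_id`, `chrom`,
#'   `start`, `end`, `gc_count`, sorted by (chrom, start).
#' @export
read_probe_design <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "probe_id", "gc_count"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), probe_id = readr::col_character(),
      gc_count = readr::col_integer()
    ),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf("malformed probe design row at line %d of %s: %s",
                  probs$row[1], path, probs$expected[1]))
  }
  as_probe_design(df)
}

#' Build a validated probe design from a data frame
#'
#' @param df Data frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `gc_count`.
#' @return A sorted, validated `probe_design` tibble.
#' @export
as_probe_design <- function(df) {
  assert_columns(df, c("probe_id", "chrom", "start", "end", "gc_count"),
                 "probe design")
  df <- tibble::as_tibble(df)[, c("probe_id", "chrom", "start", "end", "gc_count")]
  if (anyDuplicated(df$probe_id)) {
    dup <- unique(df$probe_id[duplicated(df$probe_id)])
    abort(sprintf("duplicate probe_id(s) in design: %s",
                  paste(head(dup, 5L), collapse = ", ")))
  }
  if (any(df$end <= df$start)) abort("probe end must exceed probe start")
  if (any(df$gc_count < 0L | df$gc_count > df$end - df$start)) {
    abort("gc_count must lie in [0, probe length]")
  }
  sorted <- genomic_order(df)
  if (!identical(sorted$probe_id, df$probe_id)) {
    warn("probe design was not sorted by (chrom, start); sorting")
    df <- sorted
  }
  bad <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$start) > 0) || dplyr::n() == 1L)
  if (!all(bad$ok)) abort("probe starts must be strictly increasing within a chromosome")
  structure(df, class = c("probe_design", class(df)))
}

#' Write a probe design to a BED-like TSV
#'
#' @param design A `probe_design` tibble.
#' @param path Output path.
#' @export
write_probe_design <- function(design, path) {
  readr::write_tsv(design[, c("chrom", "start", "end", "probe_id", "gc_count")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a per-probe intensity table
#'
#' Long-format TSV with header columns `probe_id`, `sample`, `channel`
#' (`M` = methylated-enriched, `T` = total input), `replicate`, and
#' `log2_intensity`. Every `probe_id` must exist in `design`, and every
#' sample must carry both channels.
#'
#' @param path Path to the intensity TSV.
#' @param design A `probe_design` the table is keyed to.
#' @return An intensity tibble.
#' @export
read_intensity_table <- function(path, design) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      probe_id = readr::col_character(), sample = readr::col_character(),
      channel = readr::col_character(), replicate = readr::col_integer(),
      log2_intensity = readr::col_double()
    ),
    progress = FALSE
  )
  validate_intensity_table(df, design)
}

#' Validate an intensity table against a probe design
#'
#' @inheritParams read_intensity_table
#' @param df Long-format intensity data frame.
#' @return The validated tibble.
#' @export
validate_intensity_table <- function(df, design) {
  assert_columns(df, c("probe_id", "sample", "channel", "replicate", "log2_intensity"),
                 "intensity table")
  df <- tibble::as_tibble(df)
  unknown <- unique(df$probe_id[df$probe_id %not in% design$probe_id])
  if (length(unknown) > 0L) {
    abort(sprintf("intensity table contains probe_id(s) absent from design: %s%s",
                  paste(head(unknown, 5L), collapse = ", "),
                  if (length(unknown) > 5L) sprintf(" (+%d more)", length(unknown) - 5L) else ""))
  }
  chan <- df |>
    dplyr::distinct(.data$sample, .data$channel) |>
    dplyr::count(.data$sample)
  incomplete <- chan$sample[chan$n < 2L]
  if (length(incomplete) > 0L) {
    have <- df$channel[df$sample == incomplete[1]][1]
    abort(sprintf("sample %s is missing channel %s",
                  incomplete[1], setdiff(c("M", "T"), have)))
  }
  df
}

#' Write an intensity table
#'
#' @param intensity Intensity tibble.
#' @param path Output path.
#' @export
write_intensity_table <- function(intensity, path) {
  readr::write_tsv(intensity, path, progress = FALSE)
  invisible(path)
}

#' Write a region set as BED6
#'
#' The BED name column carries the region rank, the score column the
#' additive Z (clamped to `[0, 1000]` as BED requires), strand is `"."`.
#'
#' @param regions A `region_set` tibble (see [call_regions()]).
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- tibble::tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = regions$rank,
    score = pmin(pmax(regions$additive_z, 0), 1000),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 region file back into a region tibble
#'
#' @param path Path to a BED6 file written by [write_regions_bed()].
#' @return A tibble with columns `chrom`, `start`, `end`, `rank`,
#'   `additive_z`.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), rank = integer(),
                          additive_z = double()))
  }
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE)
  tibble::tibble(chrom = df$chrom, start = df$start, end = df$end,
                 rank = as.integer(df$name), additive_z = df$score)
}

#' Read a BED3+ interval track
#'
#' @param path Path to a BED file (first three columns chrom/start/end;
#'   extra columns ignored).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                        progress = FALSE)
  tibble::tibble(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                 end = as.integer(df[[3]]))
}

#' Write a 3-column BED file
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(intervals[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from BED12
#'
#' Returns one row per gene with exon block structure parsed into list
#' columns, ready for [classify_regions()] and [intron_profile()].
#'
#' @param path Path to a BED12 file.
#' @return A `gene_models` tibble with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, and list columns `exon_starts`, `exon_ends` (absolute,
#'   0-based half-open).
#' @export
read_genes_bed12 <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "thick_start", "thick_end", "rgb", "block_count",
                  "block_sizes", "block_starts"),
    col_types = "ciicdciicicc", progress = FALSE)
  parse_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  tibble::tibble(
    gene_id = df$name, chrom = df$chrom, start = df$start, end = df$end,
    strand = df$strand,
    exon_starts = purrr::map2(df$block_starts, df$start,
                              function(b, s) s + parse_ints(b)),
    exon_ends = purrr::pmap(list(df$block_starts, df$block_sizes, df$start),
                            function(b, z, s) s + parse_ints(b) + parse_ints(z))
  ) |>
    as_gene_models()
}

#' Build validated gene models from a tibble
#'
#' @param df Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `exon_starts`, `exon_ends` (list columns).
#' @return A `gene_models` tibble.
#' @export
as_gene_models <- function(df) {
  assert_columns(df, c("gene_id", "chrom", "start", "end", "strand",
                       "exon_starts", "exon_ends"), "gene models")
  if (!all(df$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  ok <- purrr::map2_lgl(df$exon_starts, df$exon_ends, function(s, e) {
    length(s) == length(e) && all(e > s) &&
      (length(s) < 2L || all(s[-1] > e[-length(e)]))
  })
  if (!all(ok)) abort("exons must be sorted and non-overlapping within each gene")
  structure(tibble::as_tibble(df), class = c("gene_models", class(tibble::tibble())))
}

#' Write gene models as BED12
#'
#' @param genes A `gene_models` tibble.
#' @param path Output path.
#' @export
write_genes_bed12 <- function(genes, path) {
  lines <- purrr::pmap_chr(genes, function(gene_id, chrom, start, end, strand,
                                           exon_starts, exon_ends, ...) {
    sizes <- exon_ends - exon_starts
    paste(chrom, start, end, gene_id, 0, strand, start, end, "0",
          length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(exon_starts - start, collapse = ","), ","),
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph score track
#'
#' @param path Path to a bedGraph file (chrom, start, end, score).
#' @return Tibble with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "score"),
                        col_types = "ciid", comment = "track", progress = FALSE)
  tibble::as_tibble(df)
}

#' Write a bedGraph score track
#' @param track Tibble with `chrom`, `start`, `end`, `score`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "score")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a genome FASTA into a named character vector of sequences
#'
#' @param path FASTA path.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write a genome to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}
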