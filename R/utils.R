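# Internal helpers shared across modules.

# Order a genomic tibble by (chrom, start); chrom order is first appearance
# unless already a factor.
genomic_order <- function(df) {
  dplyr::arrange(df, factor(.data$chrom, levels = unique(.data$chrom)), .data$start)
}

# Stable per-stage seed derived from a master seed: folds a stage name into
# the master seed so partial re-runs reproduce stage outputs. Kept < 2^31.
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483629)
}

# Positions (starts, sorted ascending) falling in [lo, hi): count via
# binary search. `pos` must be sorted.
count_in_window <- function(pos, lo, hi) {
  findInterval(hi - 1e-9, pos) - findInterval(lo - 1e-9, pos)
}

`%not in%` <- function(x, table) !(x %in% table)

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
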