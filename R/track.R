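# Signal tracks: one value per probe of a design, tagged with the pipeline
# stage it represents (log_ratio -> adjusted -> smoothed -> z).

track_stages <- c("log_ratio", "adjusted", "smoothed", "z")

#' Construct a signal track aligned to a probe design
#'
#' @param design A `probe_design` tibble.
#' @param value Numeric vector, one value per probe, in design order.
#' @param stage Pipeline stage label, one of `"log_ratio"`, `"adjusted"`,
#'   `"smoothed"`, `"z"`.
#' @return A `signal_track` tibble with columns `probe_id`, `chrom`,
#'   `start`, `value`.
#' @export
new_signal_track <- function(design, value, stage) {
  stage <- match.arg(stage, track_stages)
  if (length(value) != nrow(design)) {
    abort("track value length must equal number of probes in design")
  }
  out <- tibble::tibble(probe_id = design$probe_id, chrom = design$chrom,
                        start = design$start, value = as.double(value))
  structure(out, stage = stage,
            class = c("signal_track", class(tibble::tibble())))
}

#' Pipeline stage of a signal track
#' @param track A `signal_track`.
#' @return The stage label.
#' @export
track_stage <- function(track) attr(track, "stage") %||% "log_ratio"

assert_stage <- function(track, allowed) {
  st <- track_stage(track)
  if (st %not in% allowed) {
    abort(sprintf("track stage must be %s, got '%s'",
                  paste(sQuote(allowed), collapse = " or "), st))
  }
  invisible(track)
}

#' Write a signal track to TSV
#' @param track A `signal_track`.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  df <- tibble::as_tibble(track)
  df$stage <- track_stage(track)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a signal track from TSV
#' @param path Path written by [write_track()].
#' @param design The probe design the track belongs to.
#' @return A `signal_track`.
#' @export
read_track <- function(path, design) {
  df <- readr::read_tsv(path, col_types = "ccidc", progress = FALSE)
  if (!identical(df$probe_id, design$probe_id)) {
    abort("track probes do not match design")
  }
  new_signal_track(design, df$value, df$stage[1])
}
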