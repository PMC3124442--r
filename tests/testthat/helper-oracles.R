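# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles are deliberately naive (per-window sorts, pairwise
# interval arithmetic, explicit seed enumeration) so they stay independent
# of the implementation paths they check.

# naive running median: symmetric shrinking window at the edges
oracle_running_median <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    m <- min(h, i - 1L, n - i)
    median(x[(i - m):(i + m)])
  }, numeric(1))
}

# naive region caller: enumerate seeds, chain by gap < merge_gap on seed
# starts, sum z over the spanned probe run, filter by additive z
oracle_call_regions <- function(z, starts, ends, z_probe = 3, z_region = 4,
                                merge_gap = 250) {
  seeds <- which(z > z_probe)
  if (length(seeds) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      additive_z = double(), n_probes = integer()))
  }
  groups <- list(seeds[1])
  for (s in seeds[-1]) {
    last <- groups[[length(groups)]]
    if (starts[s] - starts[last[length(last)]] < merge_gap) {
      groups[[length(groups)]] <- c(last, s)
    } else {
      groups[[length(groups) + 1L]] <- s
    }
  }
  rows <- lapply(groups, function(g) {
    span <- g[1]:g[length(g)]
    data.frame(start = starts[g[1]], end = ends[g[length(g)]],
               additive_z = sum(z[span]), n_probes = length(span))
  })
  out <- do.call(rbind, rows)
  out[out$additive_z > z_region, , drop = FALSE]
}

# naive total bp overlap between two interval sets on one chromosome
oracle_bp_overlap <- function(q_start, q_end, s_start, s_end) {
  total <- 0
  cov <- rep(FALSE, max(c(q_end, s_end, 0)))
  for (j in seq_along(s_start)) {
    if (s_end[j] > s_start[j]) cov[(s_start[j] + 1L):s_end[j]] <- TRUE
  }
  for (i in seq_along(q_start)) {
    if (q_end[i] > q_start[i]) total <- total + sum(cov[(q_start[i] + 1L):q_end[i]])
  }
  total
}

# naive CG counter over a window of a sequence string (0-based half-open)
oracle_count_cg <- function(seq, lo, hi) {
  sub <- substr(rep(seq, length(lo)), lo + 1L, hi)
  vapply(gregexpr("CG", sub),
         function(m) sum(m > 0L), integer(1))
}

# compact uniform tiling design for constructed tracks
toy_design <- function(n = 20L, chrom = "chrT", spacing = 35L, len = 25L,
                       gc = 12L) {
  as_probe_design(tibble::tibble(
    probe_id = sprintf("%s_p%04d", chrom, seq_len(n)),
    chrom = chrom, start = (seq_len(n) - 1L) * spacing,
    end = (seq_len(n) - 1L) * spacing + len, gc_count = gc))
}

# flat gc_strata with given centre and scale for constructed z tracks
toy_strata <- function(m = 0, s = 1, max_gc = 25L) {
  structure(tibble::tibble(gc_min = 0L, gc_max = max_gc, m = m, s = s,
                           n = 1000L),
            gc_map = rep(1L, max_gc + 1L), stage = "adjusted",
            class = c("gc_strata", class(tibble::tibble())))
}

region_recall <- function(truth, called) {
  if (nrow(truth) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(truth)), function(i) {
    any(called$chrom == truth$chrom[i] & called$start < truth$end[i] &
          called$end > truth$start[i])
  }, logical(1)))
}

region_precision <- function(truth, called) {
  if (nrow(called) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(called)), function(i) {
    any(truth$chrom == called$chrom[i] & truth$start < called$end[i] &
          truth$end > called$start[i])
  }, logical(1)))
}

# scenarios are expensive; build each once per test run
.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(name, seed, params = NULL) {
  key <- paste(name, seed, is.null(params))
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  b <- if (is.null(params)) make_scenario(name, seed = seed)
       else make_scenario(name, seed = seed, params = params)
  .scenario_cache[[key]] <- b
  b
}

# reduced-scale study conditions for unit tests (full scale is exercised in
# the acceptance suite)
small_params <- function(...) {
  sim_params(chrom_lengths = c(chrS1 = 150000L, chrS2 = 150000L),
             meth_regions = 30L, ...)
}

small_basic <- function() {
  if (is.null(.scenario_cache$small_basic)) {
    .scenario_cache$small_basic <- make_scenario("basic", seed = 42,
                                                 params = small_params())
  }
  .scenario_cache$small_basic
}
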