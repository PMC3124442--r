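---
title: "Calling methylated regions from enrichment tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling methylated regions from enrichment tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilemeth)
```

# The measurement and its artifacts

In an MBD-chip (or MeDIP-chip) experiment, genomic DNA is fragmented,
split into a *total input* aliquot (T) and an aliquot enriched for
methylated fragments with a methyl-CpG-binding-domain reagent (M), and
both are hybridised to a tiling microarray — short probes laid across the
genome at a regular interval (here 25-mers every 35 bp). The per-probe
log2(M/T) ratio cancels probe affinity, because the input fraction should
carry uniform biological signal, and what remains is — ideally — the
methylation enrichment.

What remains in practice is enrichment plus two artifacts that this
package is built to remove and to exploit:

1. **A residual GC probe effect.** Even after taking the ratio, the
   log-ratio drifts upward with probe G+C content. Because neighbouring
   probes interrogate overlapping sequence, their GC contents are similar,
   so this bias also shows up as strong positional autocorrelation.
2. **A saturating, nonlinear enrichment response.** Capture efficiency
   rises with the number of methylated CpGs on a fragment and plateaus;
   fragments with very few CpGs are essentially not retained. Enrichment
   signal is therefore not a quantitative methylation level, and this
   package deliberately makes only qualitative (methylated / not
   methylated) calls.

The second artifact justifies the central statistical device: **null
probes**. In adult somatic cells methylation is restricted to CpG
dinucleotides, and the capture chemistry cannot retain fragments with
almost no CpGs — so probes in windows of extremely low CpG density
(default: fewer than 4 CpGs per 1000 bp in a 1 kb window centred on the
probe) can carry no true signal. Whatever structure their log-ratios show
is artifact, measured genome-wide for free.

# The pre-processing model

For each sample, per probe $i$ with GC count $g(i)$:

1. **Log-ratio.** Duplicate hybridisations are averaged per channel on the
   log2 scale and differenced: $r_i = \bar M_i - \bar T_i$. A missing
   probe in any replicate is an error, never an imputation.
2. **GC baseline.** Over null probes only, per GC stratum $g$ (integer GC
   count; strata with fewer than `min_bin_size = 200` null probes merge
   with their nearest neighbour), the stratum median $m_g$ is the probe
   effect. The adjusted value is $a_i = r_i - m_{g(i)}$. This
   simultaneously removes the GC trend, kills the positional
   autocorrelation it induced, and pins the unmethylated baseline at zero.
3. **Smoothing.** A running median over $k = 7$ consecutive probes
   (~250 bp at 35 bp tiling, the modal fragment size) stabilises the
   track: $s_i = \mathrm{med}(a_{i-3}, \ldots, a_{i+3})$. Windows never
   cross chromosome boundaries and shrink symmetrically at the ends, so no
   probe is dropped.
4. **Z-score.** $z_i = (s_i - m'_{g(i)}) / \sigma_{g(i)}$, where $m'_g$
   and $\sigma_g$ are the median and robust scale (1.4826 × MAD, falling
   back to the stratum SD and then the global scale if degenerate) of the
   null probes' **adjusted, unsmoothed** values in stratum $g$.

The choice in step 4 deserves emphasis, because it is the package's main
interpretive decision. The Z-score counts null SDs *of the per-probe
log-ratio*; the smoothed numerator is a stabiliser, not a rescaled
statistic. Under the null, $z_i$ is therefore distributed as a running
median of an approximately standard normal variable — strongly
concentrated, with essentially no mass beyond $|z| = 3$ — rather than as a
unit normal. Three consequences, all verified by the test suite:

* The probe threshold $z > 3$ and region threshold (additive $Z > 4$) are
  conservative: on a replicate-input null dataset (below) the pipeline
  calls essentially nothing, and the estimated FDR lands well below 5%.
* Lowering the probe cutoff from 3 to 2.57 (the normal 99.5th percentile)
  changes the called set only marginally — the region-level statistic, not
  the seed cutoff, is binding.
* The self-standardised alternative — re-estimating $\sigma$ from the
  *smoothed* null values — makes the null Z unit-normal, and smoothing
  then clusters the resulting ~1.4 × 10⁻³ tail exceedances into runs that
  chain into spurious regions at a rate near 4 × 10⁻⁴ per probe. At that
  rate the replicate-input FDR estimate rises to roughly 9–10%, and the
  cutoff-sensitivity analysis shows many novel regions at 2.57. Both
  contradict the behaviour this method is documented to have, which is
  why the unsmoothed-scale definition is used.

The upper normal tail at $Z = 4$ is below 3.2 × 10⁻⁵, so even read as a
unit-normal statistic the region threshold is a stringent bound.

# Region calling

Probes with $z >$ `z_probe` (default 3, strict) are *seeds*. Seeds on a
chromosome whose start coordinates are less than `merge_gap = 250` bp
apart (strict) are chained; each chain spans from its first seed's start
to its last seed's end, and the region's **additive Z** is the sum of
$z_i$ over all probes spanned. Regions with additive $Z >$ `z_region`
(default 4, strict) are kept and ranked by additive Z (ties broken by
genomic position), which deliberately promotes long regions over sharp
narrow peaks of similar amplitude. Summing over all spanned probes rather
than seeds only is the default (`sum_seeds_only = FALSE` exposes the
alternative); with conservative Z-scores the two differ little, because
spanned non-seed probes sit between seeds and carry similar values.

**FDR estimation** runs the identical pipeline — null-probe selection, GC
strata, adjustment, smoothing, Z, calling — on log2(T replicate 1 / T
replicate 2), a ratio in which no biological signal exists. The count of
regions called there, divided by the count called on log2(M/T), estimates
the false discovery rate. The replicate-null regions are not
length-filtered before counting.

**Differential calling** between two samples merges the union of both
samples' regions into maximal intervals, recomputes each sample's additive
Z over each union interval, and requires $Z > 4$ in one sample, $Z < 1$ in
the other, and interval length strictly over 500 bp. These criteria are
deliberately stringent: the absence criterion applies to the additive sum
over the whole interval, whose null fluctuation across tens of correlated
probes regularly exceeds 1, so genuinely differential regions pass it only
about half the time in simulation (the package's differential-scenario
test asserts recall ≥ 0.35 at precision ≥ 0.95). The trade is
intentional — what is called differential is very likely real.

# Annotation and enrichment

Called regions are classified into five genomic compartments — gene
upstream (within 2 kb of the TSS, strand-oriented), gene downstream
(within 2 kb past the TTS), exon, intron, intergenic — by majority
base-pair overlap with ties broken in that precedence order. A region
overlapping no compartment window is intergenic only if it lies more than
3 kb from every gene; otherwise it takes the flank on whose side of the
nearest gene it sits. The two distance scales (2 kb windows, 3 kb
proximal rule) are both configurable and coexist deliberately.

Whether a region set is *enriched* for an annotation (CpG islands,
conserved bases with scores strictly above 0.8, TFBS, junction overlap,
CpG content) is tested by permutation against **matched random region
sets**: each of $Q$ sets reproduces the observed multiset of region
lengths exactly, placed in rank order at uniformly sampled probe start
sites, rejecting placements that leave array coverage (an inter-probe gap
above 250 bp inside the placed region), run off a chromosome, or overlap
a previously placed region in the same set. The p-value is the fraction
of random sets whose statistic strictly exceeds the observed one — ties
favour significance, matching the strict-inequality definition. With
$Q = 500$, the smallest nonzero p is 0.002.

The intron metagene profile rescales every intron to 0–100% of its length
(oriented 5'→3' in transcript direction), averages the smoothed track per
bin within each intron and then across introns, separately for short
(842–2715 bp, half-open) and long (2715–11673 bp, closed) intron classes;
the half-open short class resolves the boundary duplication at 2715 bp.
Averaging within introns first prevents long, probe-rich introns from
dominating the profile.

# The simulator

Every stage above is testable without array data because the package
ships a generator that emulates the data-generating process end to end:

* **Genome.** Base composition follows a smooth random GC field
  (correlation length ~5 kb), so neighbouring probes share GC content —
  the precondition for GC bias to masquerade as autocorrelation.
  Accidental CG dinucleotides are removed and CpGs are planted explicitly:
  ~2 per kb background (below the null-probe threshold), ~25 per kb inside
  islands, ~30 per kb inside planted methylated intervals. Gene models
  carry 4–8 exons with introns drawn from both metagene length classes;
  conservation and TFBS tracks cover part of the intergenic space.
* **Arrays.** T = per-probe affinity + Gaussian log2 noise (SD 0.3 per
  replicate). M adds a GC probe effect (0.06 log2 units per G+C base,
  0.18 in the `biased` scenario — calibrated so the raw null-probe lag-1
  autocorrelation exceeds 0.3 before correction) and the enrichment
  response to the methylated-CpG count of a gamma-distributed fragment
  (mode 250 bp) covering the probe. The response is a Hill curve —
  zero at zero methylated CpGs, half-saturation at 6, ceiling 3 log2
  units — monotone over the canonical 0/6/10/37 titration grid.
* **Scenarios.** `null` (no methylation), `basic` (200 regions of ≥ 8
  probes on two 1 Mb chromosomes), `biased` (strong GC artifact, no
  methylation), `differential` (two samples, 40% of regions in sample A
  only, anchored so the differential truth spans all five compartments),
  `island_enriched` (80% of regions inside CpG islands). All generators
  are pure functions of (parameters, seed).

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real arrays — includes: heavy-tailed or spatially
structured hybridisation noise, probe-specific affinity differences that
survive the M/T ratio, cross-hybridisation from repeats (real designs
exclude repetitive sequence; the simulator tiles everything), copy-number
variation between samples, and incomplete methylation (planted intervals
are fully methylated). The conservative Z-definition is robust to modest
departures from normality, but the FDR and recovery rates measured here
are properties of the simulated conditions.

# Numerical choices and degenerate inputs

* Running-median edges shrink symmetrically to the largest odd window;
  `k` must be odd.
* A GC stratum with zero MAD falls back to its SD, then to the global
  robust scale; if every null value is identical the scale is set to 1
  with a warning (the track is then all-zero Z anyway).
* Probe "position" for gap chaining and for spanned-probe attribution is
  the probe start; region ends use the probe end.
* Region ranks break additive-Z ties by (chromosome, start).
* Random placement retries up to 10,000 proposals per region and reports
  the stuck length on failure; `q = 1` on a design with a single feasible
  slot is deterministic.
* FDR with zero called regions is an error (undefined), not zero.
* The three published null-probe density phrasings (4/1000 bp, 0.4%,
  5/10 kb) are near-equivalent; the first is the default and both the
  threshold and window are configuration keys.

# Problem sizes used in the checks

The shipped test-suite and acceptance script run the `basic` scenario at
its defining scale (two 1 Mb chromosomes, ~57,000 probes, 200 planted
regions, scenario seed 42 — FDR below 5% with recall and precision ≥ 0.9)
and the `island_enriched` scenario (scenario seed 7) with Q = 500 matched
random sets (island-overlap enrichment at p ≤ 0.002). Unit tests use
150–400 kb genomes, which keep every distributional property intact at a
few seconds per scenario; brute-force oracle comparisons run 1,000 seeded
trials at up to 500 probes.

# A worked example

```{r example, eval = FALSE}
library(tilemeth)

b <- make_scenario("basic", seed = 42)
nulls <- select_null_probes(b$design, b$genome)
tracks <- preprocess_sample(b$intensity, b$design, nulls, sample = "A")
regions <- call_regions(get_track(tracks, b$design, "z"), b$design,
                        sample = "A")
glance(regions)
estimate_fdr(b$intensity, b$design, nulls, "A", n_called = nrow(regions))

regions |> classify_regions(b$genes) |> dplyr::count(compartment)
test_enrichment(regions, b$design, b$islands, mode = "bp_overlap",
                q = 500, seed = 17)

autoplot(tracks, xlim = c(0, 100000))
autoplot(intron_profile(get_track(tracks, b$design, "smoothed"), b$genes))
```
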