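---
title: "Ensemble SNV consensus calling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SNV consensus calling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvensemble)
```

## The problem

Calling single-nucleotide variants jointly across thousands of low-coverage
(6–10×) whole genomes is dominated by two difficulties. Computationally, no
single machine holds the cohort, so calling is scattered over fixed-size
genomic windows and gathered afterwards. Statistically, every caller makes
algorithm-specific errors, and at low coverage those errors are plentiful;
running several callers with distinct algorithmic strategies and keeping
only sites that *k* of the *n* callers agree on suppresses
caller-specific artifacts without any tool-specific score filtering.
`snvensemble` implements the computation-defining stages of that design —
the window planner, the consensus filter, the evaluation protocol, the
imputation window scheduler — together with a synthetic cohort generator
and an analytic oracle that make every claimed property testable.

## Genome binning

`plan_windows()` tiles each chromosome with 0-based half-open windows of
`window_size` bp (default 1 Mbp), truncating the last window at the
chromosome end. The per-chromosome window count is
`ceiling(length / window_size)`; small remainders are kept as short windows
rather than merged, so the tiling is exactly disjoint and complete. Over
the bundled GRCh37 autosome table this yields 2897 windows.

`add_flanks()` extends each window by `flank` bp (default 10 Kbp) on each
side, clipped at the chromosome boundary, so reads near a window edge are
visible to the callers on both sides. Interior adjacent flanked windows
therefore overlap by `2 * flank`. The read-inclusion predicate
(`read_in_window()` / `slice_reads()`) includes every mapped read whose
aligned span overlaps the flanked extent, and reports the mates to pull:
mapped mates wherever they align, and unmapped mates of included reads.
Mate closure is implemented as a second pass over the read table — the
inclusion rule itself says nothing about mechanism, and two passes keep
the predicate purely functional.

`group_windows()` packs consecutive windows of a chromosome into groups of
at most `group_size` (default 10); groups never span chromosomes. Grouping
is what keeps the intermediate-file count manageable: scattering produces
`n_samples x n_windows` per-window slices, gathering stores `n_groups`
region directories, and `file_count_reduction()` reports the fold change.
For a 5297-sample cohort on the autosome plan (2897 windows, 300 groups)
that is `5297 * 2897 / 300 = 51151.4`, i.e. over 50,000-fold. The numerator
counts one sliced file per (sample, window); index files would scale both
sides equally and are left out.

Windows empty of data (centromere/telomere gaps) are excluded by id via
`exclude_empty()`. Which windows are empty is a property of the cohort, not
the plan, so the canonical path takes an explicit list;
`detect_empty_windows()` offers a coverage-based alternative for toy read
tables. The bundled `grch37_empty_windows_synthetic()` list carries 163 ids
placed around approximate centromere spans and chromosome ends — a
synthetic stand-in whose cardinality (2897 − 163 = 2734 retained windows)
matches what large real cohorts observe, while the specific ids are
illustrative.

Coordinates are 0-based half-open internally (BED convention); region
strings rendered for indexed-alignment queries (`plan_to_regions()`) are
1-based inclusive, the samtools convention.

## Consensus filtering

Site identity is the allele-aware quadruple `(chrom, pos, ref, alt)`. Two
callers reporting different alternate alleles at one position do *not*
corroborate each other; this is the conservative reading of cross-caller
matching, and `pct_known()` exposes a position-only mode for the looser
one. `tally()` counts, for every distinct site key, the number of callsets
containing it; `consensus_threshold(cons, k)` keeps sites with support
≥ k. Consensus is purely presence-based — no quality weighting, no
tool-specific filters — because agreement across algorithmically distinct
callers is itself the filter. The engine uses `data.table` grouping over
the concatenated keys; the test suite checks it against a brute-force
set-membership oracle on a thousand random instances, along with the
nesting property `threshold(k+1) ⊆ threshold(k)` and the stratum
decomposition of the union.

## The detection model and its oracle

The simulator (`simulate_truth()`, `simulate_callsets()`) draws two site
populations on a synthetic chromosome: true variants and a shared artifact
pool. Caller `c` detects a true site with probability `s_c` (optionally a
non-decreasing function of the site's allele count) and an artifact site
with probability `e_c`, independently across callers *given the class*.
Conditional independence plus the shared pool is the simplest error
structure that makes consensus false positives non-trivial: callers look
correlated on artifacts because they are offered the same artifacts, not
because their errors are coupled. Real callers' error correlation on true
sequencing artifacts is unknowable from callset-level data; this is an
explicit modeling choice, not an inference.

Under that model the support count of a site is Poisson-binomial, and
`expected_consensus()` gives the closed forms: consensus sensitivity
`P(X ≥ k)` with `X ~ PoisBin(s_1..s_n)`, artifact pass-rate `P(Y ≥ k)`
with `Y ~ PoisBin(e_1..e_n)`, and expected FDR as the ratio of
expectations `E[FP] / (E[FP] + E[TP])`. The ratio-of-expectations form
differs from the expectation of the ratio by `O(1/sqrt(n))` at the site
counts used here (10^4–10^5), which is far inside the Monte-Carlo noise
the tests allow (3σ binomial error).

Allele composition: a site is a transition with probability
`titv / (1 + titv)` — 2.1/3.1 for true sites, 0.5/1.5 for artifacts, the
genome-wide values for real human variation and random noise respectively.
Allele counts for true sites follow the truncated neutral spectrum
`P(AC = i) ∝ 1/i` over `1..(2N − 1)`; the spectrum is a configuration
field and can be replaced. Genotypes are drawn per sample under
Hardy–Weinberg equilibrium at `AF = AC/(2N)`; the test matrix is perturbed
by a per-cell genotype error (a wrong dosage, uniform over the other two
values) and masked by per-cell missingness, while the gold subset keeps
error-free genotypes, with artifact sites entering the gold standard as
assayed monomorphic-reference negatives.

Defaults mirror a large low-coverage cohort: 5297 samples, a gold subset
fraction of 4612/5297, consensus 3-of-4, and 10^5 + 10^5 sites for the
site-level experiments. Missingness (test 2 %, gold 1 %) and genotype error
(5 %) have no canonical published values at this level of abstraction; they
were chosen once as plausible magnitudes for low-coverage calling against
a deep-coverage gold standard, and the tests that depend on error structure
plant their own rates explicitly. Everything is driven by one mandatory
seed; stage substreams are derived as fixed offsets from it, and identical
seeds give byte-identical outputs.

What the simulator does *not* emulate: linkage disequilibrium and
population structure, depth-dependent error profiles, reference bias, and
any correlation of caller errors beyond the shared pool. Passing tests
therefore validate the consensus arithmetic and the direction of its
quality effects, not the numeric operating points of any real cohort.

## Evaluation protocol

`gold_standard()` derives positives (≥ 1 non-reference allele among gold
samples — no allele-count floor) and negatives (assayed, monomorphic
reference) from an assayed genotype matrix. `apply_gold_filters()` then
enforces two rules: negatives with any missing gold genotype are removed
(an uncalled gold cell could hide a variant), and sites whose test-side
missingness exceeds the threshold (default 5 %, strictly greater) leave
the sensitivity universe. `confusion()` counts TP/FP/FN/TN strictly within
the assayed footprint — callset sites outside it are unlabeled, not false
positives, which is the only reading under which specificities near 1 are
meaningful. Undefined metrics are reported as `NA` with a warning, with
one documented convention: an empty callset's FDR is 0.

Genotype concordance stratifies shared, doubly non-missing cells by the
*gold* genotype class (hom-ref / het / hom-alt) and reports the fraction
of agreeing cells per class; allele-count-stratified sensitivity bins gold
positives by their dosage-sum AC (default bins 1, 2, 3–5, 6+), isolating
the rare-variant regime where low-coverage recall collapses.

## Imputation windowing

`make_impute_windows()` cuts a chromosome's ordered SNV list into windows
of `size` SNVs (default 512) overlapping by `overlap` (default 256).
Windows start at multiples of `step = size − overlap`; the final window is
*anchored* — shifted back to `[n − size, n)` — rather than left as a short
tail, so every window sees a full-size haplotype context (its overlap with
its neighbour is then ≥ `overlap`). A chromosome with ≤ `size` SNVs gets
the single window `[0, n)`. The 512/256 operating point suits relatively
homogeneous cohorts; the per-window MCMC schedule of the downstream
sampler (56 iterations, 55 burn-in) is carried as metadata only.

Merging overlapped outputs needs each SNV owned exactly once:
`core_map()` bisects every overlap at its midpoint, which is symmetric
(both windows contribute equally near a boundary) and matches common
stitching practice. Cores provably partition `[0, n)`; the tests sweep
every `n` in `[0, 10000]` at (512, 256) plus randomized geometries against
a brute-force enumerator. For a 73-million-SNV autosomal callset the
budget is `n/256 + O(22)` ≈ 285,000 windows regardless of how SNVs split
across chromosomes (the alternative tail-window convention differs by at
most one window per chromosome).

## Numerical and interface conventions

* Chromosome order follows the genome table (natural order as fallback),
  never lexicographic; all sorts are total and deterministic.
* Multi-allelic records default to *drop* (the toolkit's universe is
  bi-allelic SNVs); a *split* mode keeps the SNV alleles as separate keys.
* Missing genotypes are `NA`, never dosage 0.
* Sites reported by two adjacent flanked windows are deduplicated to the
  window whose *core* contains the position.
* The CLI (`run_cli()`) exposes every threshold as a flag with the
  defaults above, exits 0/1/2 (success / usage / data error), and stamps a
  provenance JSON (version, config, config hash, seed) beside each output.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
up to 10^5 + 10^5 sites for the consensus experiments (where 3σ binomial
error is below 0.2 % absolute on the quantities compared), 2 × 10^4 sites
for Ti/Tv calibration checks, cohorts of 40–60 samples for genotype-level
fixtures, and exhaustive sweeps to n = 10^4 for the windowing oracles.
These sizes make every property statistically decidable while the whole
suite stays in the tens of seconds.

## Known limitations

Beyond the simulator's idealizations listed above: the toolkit plans and
accounts for BAM slicing but does not execute it (region strings are
emitted for an indexed-alignment tool to consume); genotype likelihoods,
imputation and phasing are scheduled but not computed; and per-bin
size-based instance assignment from production deployments is out of
scope. Published cohort-level values (SNV yields, FDR, concordance
triples from real data) are not reproducible from synthetic inputs and
are treated as definitions to implement, not numbers to match.
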