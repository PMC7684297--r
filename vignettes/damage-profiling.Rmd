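---
title: "Genome-wide 8-oxoguanine damage profiling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide 8-oxoguanine damage profiling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxoprofiler)
```

## The measurement and the question

7,8-dihydro-8-oxo-2′-deoxyguanosine (oxoG) is the main product of
ROS-mediated guanine oxidation; unrepaired, it mispairs with adenine and
causes G→T transversions, so its genomic density is a biomarker of oxidative
DNA damage. Anti-oxoG ChIP-seq immunoprecipitates fragmented genomic DNA
with an antibody against the modified base: where sequencing reads pile up,
damage is dense. The analytical question this package answers is simple but
easy to get subtly wrong: *given replicate anti-oxoG libraries from two cell
lines, does one carry systematically more damage signal across the genome
than the other?*

## The procedure

For each aligned library the pipeline applies, in order:

1. **Read filtering.** Keep primary, mapped, non-duplicate,
   non-supplementary reads with mapping quality ≥ 20 (inclusive threshold),
   and discard reads on the mitochondrial contig. The number of reads
   surviving all filters is the sample's *library size*. Each of the four
   alignment-class filters is an explicit, overridable switch in
   `filter_policy()`, so the minimal MAPQ-only filter is also expressible;
   whether duplicate/secondary reads were excluded before MAPQ filtering in
   any given upstream tool cannot be recovered from a description like
   "mapping quality ≥ 20", so the defaults here follow standard ChIP
   practice and are documented rather than hidden. Mates of a pair, when
   present, count as independent reads.

2. **Binning.** Each surviving read increments exactly one cell of a
   fixed-width genomic grid, keyed by the chromosome and the bin containing
   its first (leftmost) aligned base. Bins are half-open
   `[k·10000, (k+1)·10000)` windows; position 9,999 is bin 0 and position
   10,000 is bin 1. "First base" is taken as the leftmost reference
   coordinate regardless of strand, which is what alignment start fields
   store; `five_prime = TRUE` instead uses the biological 5′ end of
   reverse-strand reads. At 10-kb resolution the two choices differ by at
   most one bin for a tiny fraction of reads.

3. **Normalization and sparse-bin discard.** Each bin's count is scaled to
   reads per million filtered reads (`count × 10⁶ / library_size`), and bins
   with fewer than 10 *raw* hits are discarded (strictly fewer: a bin with
   exactly 10 hits is kept). The threshold is applied to raw counts by
   default because a "hit" is a counted read; applying a fixed threshold to
   normalized values would make the discard depend on the arbitrary
   reporting scale. `min_hits_on = "normalized"` is available because the
   ordering "normalize, then discard" admits both readings. The discard is
   per sample — a bin may survive in one library and not another; a shared
   cross-sample mask is a different statistic and is deliberately not the
   default.

4. **Aggregation.** Retained normalized values are summed per chromosome
   (chromosomes with no retained bins report 0), and per-chromosome totals
   are averaged across a condition's replicates.

5. **Paired test.** The two conditions' per-chromosome means are compared
   with a Wilcoxon signed-rank test on the paired differences (condition B
   minus condition A), two-sided by default, at α = 0.05.

The normalization scale (10⁶) affects reporting only: the signed-rank test
is invariant to any common positive rescaling of the differences, which the
test suite asserts.

## The exact signed-rank test

With *k* chromosomes there are at most 23 pairs, far below the range where
the normal approximation is trustworthy, so the exact distribution is the
default. Zero differences are removed; absolute differences are ranked with
midranks for ties; and the positive-rank sum W⁺ is referred to its exact
permutation distribution over all 2ⁿ sign assignments. The distribution is
computed by dynamic programming over achievable rank sums; because midranks
are multiples of ½, doubling the ranks makes every rank sum an integer, so
the same DP covers tied and untied data (the test suite checks it against
literal enumeration of all 2ⁿ assignments for n ≤ 12, ties and zeros
included). The two-sided p-value is twice the smaller tail probability,
capped at 1, matching the convention of common implementations. `"auto"`
switches to the tie-corrected normal approximation (optional continuity
correction) above n = 25, where the DP is still sub-second but the
approximation error is already negligible.

All-positive differences give the closed form p = 2/2ⁿ two-sided: 0.0625 at
n = 5, 0.03125 at n = 6, ≈ 2.4 × 10⁻⁷ at n = 23. These are the smallest
p-values attainable at each n — relevant when interpreting any reported
value near them.

## The 6-thioguanine mutant-frequency metric

The HPRT/6-TG colony assay estimates relative mutation frequency: cells
incorporating 6-TG via HPRT1 die, so colonies surviving selection carry
inactivating HPRT1 mutations. The induced mutant frequency is

\[
\frac{\text{resistant colonies}/N_{\text{selected}}}
     {\text{control colonies}/N_{\text{control}}},
\]

with the assay's standard plating numbers \(N_{\text{selected}} = 10^6\) and
\(N_{\text{control}} = 1500\) as field defaults rather than hard-coded
constants. The quantity is invariant to rescaling all four counts together,
and fold changes between assays satisfy
`frequency_fold(a,b) × frequency_fold(b,a) = 1`; both properties are
asserted over randomized assays in the tests. Colony counting itself (image
analysis) is out of scope; counts enter as integers.

## The synthetic-data generator

`sim_config()` / `build_intensity_map()` / `simulate_counts()` /
`simulate_reads()` emulate the statistical structure the pipeline consumes,
at two levels:

* **Count level** (`simulate_counts()`): one multinomial draw of the library
  over the bins of an intensity map. This is the fast path used for
  Monte-Carlo calibration.
* **Read level** (`simulate_reads()` + `write_sam()`): the same per-bin
  draws expanded to individual reads placed uniformly within their bin,
  with two-point mapping qualities (0 or 60 — only the ≥ 20 threshold
  matters downstream), a fraction of reads reassigned to the mitochondrial
  contig, a fraction flagged duplicate, and strands drawn at ½. With all
  noise fractions zero, binning the emitted reads reproduces the
  count-level draw exactly, which pins the equivalence of the two paths.

An intensity map designates a fraction of bins as *hotspots*, chosen
reproducibly from the seed and **shared between conditions**; conditions
differ in how much of the library the hotspots receive (`hotspot_mass`) and
in how the remaining mass is spread (`background_model`: `"uniform"` over
all background bins, or `"concentrated"` on a seed-chosen tenth of them).
This design reflects how a genuine damage increase can register in the
statistic at all: per-library normalization cancels any global scaling, so
a detectable difference must come from signal *concentration* — in the
enriched condition more of the library sits in bins that clear the 10-hit
cutoff, while a diffuse condition loses mass to the sparse-bin discard.

Defaults describe the scenario the calibration suites exercise: 2 × 10⁵
reads per sample, read length 100, two replicates per condition, hotspot
fraction 0.05, hotspot mass 0.1 (diffuse wild type) vs 0.5 (concentrated
mutant), 5% low-MAPQ reads, 1% mitochondrial contamination, 2% duplicates.
The generator emulates *per-bin intensities*, not sequence: there are no
base calls, no GC or mappability structure, no fragment-length model, no
paired-end mates, and real spatial autocorrelation of damage along the
genome is not modeled (the true spatial distribution of oxoG signal is not
established; the hotspot model is an assumption, stated as such). Passing
calibration on these data therefore validates the *arithmetic and the
statistic*, not the biology of any particular dataset.

## Simulation study sizes

The packaged Monte-Carlo checks use problem sizes chosen to make each
mechanism visible:

* **Null calibration**: 23 chromosomes × 50 bins (500-kb chromosomes at the
  10-kb grid), both conditions drawn from one intensity map, 2 replicates
  per condition, 1000 runs.
* **Power/direction**: 23 chromosomes × 2000 bins (20-Mb chromosomes).
  This size is what lets the sparse-bin mechanism operate at the default
  depth: the diffuse wild-type background spreads 90% of 2 × 10⁵ reads over
  ~43,700 bins (≈ 4 reads per bin, below the 10-hit cutoff, hence
  discarded), while the mutant's concentrated background (≈ 23 reads per
  bin) and hotspots are retained — 100 runs.

## A calibration finding: the test is conservative under the global null

Library-size normalization makes per-chromosome totals *compositional*:
each sample's totals share (up to sparse-bin discard) a fixed grand total.
Under a true null the paired per-chromosome differences are therefore
negatively correlated across chromosomes (ρ ≈ −1/(k−1) ≈ −0.04 at k = 23 in
the packaged simulations). The signed-rank statistic's variance contains the
cross-term ρ·((Σr)² − Σr²), which at k = 23 shrinks the variance to roughly
0.4× its nominal value — so the observed type-I error of the full pipeline
is far below the exact test's discreteness-limited size of 0.048 (empirical
rejection ≈ 0–0.003 at α = 0.05 in 1000-run simulations, at every library
depth tried). Two things follow. First, the procedure is *valid*: it rejects
a true null far less often than α, never more. Second, a small p-value from
this pipeline is stronger evidence than its face value suggests — and
conversely the test has less power than a nominally calibrated one. Users
comparing conditions whose *total* damage burden differs should remember
that the statistic responds to signal concentration relative to the
sparse-bin cutoff, not to absolute library-wide damage (which normalization
removes by construction).

## Numerical and degenerate-input choices

* Ingestion converts SAM's 1-based POS to the 0-based, half-open convention
  used internally and in bedGraph output; the boundary examples above pin
  the mapping.
* BED input (a fallback for deposited interval files) takes `chromStart` as
  the 0-based position and the score column as MAPQ; records without scores
  are treated as passing any MAPQ threshold, announced with a message.
* An empty filtered stream is an error (the normalization denominator would
  be 0), as is an all-zero difference vector (the signed-rank statistic is
  undefined).
* Ties in |differences| get midranks, with the standard tie-corrected
  variance in the normal approximation.
* bedGraph values are printed with `%.10g`, which makes
  write→parse→write round trips byte-identical.
* Chromosome universe = the declared genome model minus exclusions;
  per-chromosome results are reported for every analyzable chromosome,
  including zeros.

## Worked example

```{r example, eval = FALSE}
genome <- make_genome(23, 2e7)          # 23 chromosomes, 2000 bins each
cfg <- sim_config()                     # defaults described above
study <- simulate_study(genome, cfg, seed = 1)
cmp <- compare_conditions(study$wt, study$mut)
cmp
plot(cmp)
```

## Known limitations

* Conservativeness under the global null, as analyzed above — intrinsic to
  normalizing by library size and then pairing per-chromosome shares.
* Single test, no multiple-testing machinery: the design compares exactly
  two conditions once.
* No input/IgG subtraction, GC or mappability correction, peak calling or
  smoothing: the unit of inference is the 10-kb bin count as sequenced.
* The simulator's noise model is deliberately minimal (two-point MAPQ,
  uniform within-bin placement, no sequence content); results on real
  libraries additionally depend on alignment quality and duplicate-marking
  upstream of this package.
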