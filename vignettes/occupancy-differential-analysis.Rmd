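---
title: "Differential occupancy analysis with occudiff: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential occupancy analysis with occudiff: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occudiff)
```

## The problem

A ChIP-seq experiment maps where a protein sits on the genome. When the
same protein is profiled in two conditions — here the motivating setting
is an untreated cell population versus one under acute oxidative stress —
the scientific question is not just *where* the protein binds but *where
its binding changes*. occudiff implements the windowed-count comparison
used for this question: reads falling in a fixed window around each peak
center are counted in both conditions, normalized for sequencing depth,
and each site is classified as **induced**, **repressed**, or **common**.
Downstream, the package asks two follow-up questions about each class of
sites: in which genomic feature categories do they sit (promoter, TTS,
UTRs, exon, intron, intergenic), and how often do they contain a given
DNA-binding motif.

All coordinates in the package are 0-based half-open (BED-native), the
one frame in which interval arithmetic has no off-by-one ambiguity.
refGene-style inputs are already in this frame and are adopted as-is.

## The classification rule

For a site with window counts $c_A$, $c_B$ and total mapped depths
$d_A$, $d_B$ (condition B treated), the depth-normalized signal is reads
per ten million, and the fold change is pseudocount-guarded:

$$
\mathrm{FC} \;=\; \frac{c_B \cdot 10^7/d_B + \kappa}{c_A \cdot 10^7/d_A + \kappa},
\qquad \kappa = 1 .
$$

The pseudocount (one read per ten million, i.e. well below any signal of
interest) makes the fold change total and bounded; without it a single
zero count would be undefined or infinite. A site is **induced** when
$\mathrm{FC} \ge 4$ *and* $p \le 10^{-4}$, **repressed** when
$\mathrm{FC} \le 1/4$ *and* $p \le 10^{-4}$, and **common** otherwise.
Both thresholds are inclusive — a site at exactly 4-fold with
$p = 10^{-4}$ is significant — and all four numbers are ordinary
parameters of `diff_params()`.

### The significance test

The source analyses this package reproduces do not name their test. We
use the standard conditional exact test for comparing two Poisson-like
counts: conditioned on the total $n = c_A + c_B$, under the null
hypothesis of equal per-read occupancy $c_B$ is
$\mathrm{Binomial}\!\left(n,\; d_B/(d_A{+}d_B)\right)$. The two-sided
p-value sums all outcomes whose null probability does not exceed the
observed outcome's (the minimum-likelihood rule, with the conventional
$1 + 10^{-7}$ relative tolerance for floating-point ties). This choice
is exact at any count, has no tuning parameters, and is symmetric: the
implementation canonicalizes the orientation of the count/depth pair so
that swapping the two conditions provably swaps induced and repressed
labels site-for-site and maps every fold change to its reciprocal,
bit-for-bit. When both counts are zero the p-value is defined as 1.

### The evaluation set

Each condition contributes its own peak list, so the same physical site
can appear twice. The evaluation set is the union of all peak centers
(`floor((start+end)/2)`; flooring is the deterministic tie-break for
even-width peaks), deduplicated greedily: walking sorted centers, any
run of centers successively closer than half the window is one cluster,
and the cluster is represented by the center with the largest summed
window count $c_A + c_B$ — a condition-symmetric criterion. This makes
the comparison well-defined when a site was called in both conditions,
in only one, or at slightly shifted positions.

## Genomic categories and the enrichment test

Sites are assigned to seven categories: promoter (1 kb upstream of the
TSS, strand-aware), TTS (1 kb downstream of the transcription end),
5′ UTR, 3′ UTR, exon, intron, intergenic. Three resolution rules matter
and are applied identically to site annotation and to base-wise genomic
background fractions, because both are computed from one
priority-resolved partition of the genome (built with
GenomicRanges/IRanges set operations):

* **Priority.** Overlapping transcripts make categories ambiguous; the
  listed order (promoter first, intergenic last) wins. This matches the
  convention of standard annotation tools and makes "promoter" the
  strongest claim.
* **Exon means coding exon.** Since 5′/3′ UTR are separate categories,
  "exon" is exonic sequence overlapping the CDS — otherwise the UTR
  categories would be unreachable.
* **Non-coding transcripts** (`cdsStart == cdsEnd`) contribute promoter,
  TTS, exon, and intron bases but no UTR, which is undefined without a
  CDS.

Because the partition is exact, the seven background fractions sum to 1
for any gene set, and permuting the input gene list cannot change any
assignment — both are enforced by tests.

Category enrichment uses the binomial ("Bernoulli") model of classical
region-enrichment tools: with $k$ of $n$ sites in a category whose
genomic base fraction is $p_0$, the one-sided upper tail
$P(X \ge k),\; X \sim \mathrm{Binomial}(n, p_0)$ is computed **entirely
in log space** (`pbinom(..., log.p = TRUE)`). This matters: at the
scale of real experiments the p-value can be smaller than the smallest
positive double ($\approx 10^{-308}$), and a linear-space
implementation would silently report 0. `enrichment_test()` returns
$\log_{10} p$ and is validated against brute-force log-sum-exp
summation to $10^{-10}$ relative error.

## Motif-occurrence fractions

A position weight matrix is scored as summed log2 odds of
pseudocount-normalized frequencies over a background composition;
`N` scores as background (contributing 0). A window is motif-positive
when the best score over all offsets **on both strands** reaches a
fraction (default 0.8) of the maximum achievable score. Production
scanners do not publish a universal cutoff; a fraction of the maximum
is the one-knob, matrix-portable choice, and it is reported in every
output so results are interpretable. The background rate is estimated
empirically from seeded random genome windows of the same width
(default 10 000), matching the empirical notion of "background" used
when such fractions are reported; per-class fold-over-background is the
ratio of fractions. The bundled `ctcf_like_pwm()` is an explicitly
synthetic 19-column matrix built around the core CTCF consensus for
simulation and testing — real analyses should supply a curated matrix
via `read_pwm()`.

One deliberate deviation from a looser reading of the scan parameters:
the threshold fraction is restricted to $(0, 1]$; a threshold of 0
(everything is a hit) is representable only in the degenerate sense
that a uniform matrix scores 0 everywhere and therefore saturates.

## The synthetic experiment

`simulate_chip_experiment()` exists so that every pipeline stage has a
ground truth to be checked against. It emulates the *statistical*
structure the comparison consumes, not the physics of ChIP:

* A uniform-random genome (default one chromosome of 1 Mb) with 50
  non-overlapping transcripts of plausible exon/intron structure; with
  this layout promoters cover 5% of the genome.
* 50 sites per class. Site intensity is expressed as an enrichment over
  the background window rate $\lambda_{bg} = \text{depth} \times
  \text{background rate} \times \text{window}$ (20 reads per 200-bp
  window at the defaults). Induced sites have enrichment $(1, 8)$ in
  (untreated, treated), repressed sites the reverse, common sites 6 in
  both. The 8-fold effect is deliberately set at twice the 4-fold
  classification cut so that recovery failures indicate bugs, not power
  limits; the generator refuses `effect_fold <= 4` outright.
* Reads: each site adds $\mathrm{Poisson}((e-1)\lambda_{bg})$ midpoints
  placed uniformly within ±100 bp of its center; uniform background
  reads top the total up to the configured depth ($10^5$ per
  condition), so emitted reads always equal the declared depth exactly.
* Placement: half the induced sites sit at gene promoters — ten times
  the genomic promoter background, so planted enrichment is
  unambiguously detectable — and 5% of the other classes; the rest are
  intergenic on a 2-kb grid that keeps sites from merging.
* Motifs: the consensus of the configured matrix is substituted into
  the genome sequence at half the induced sites (and none elsewhere by
  default), giving a known per-class motif fraction.
* Peaks are emitted per condition as center ± 100 bp for sites whose
  observed window count clearly exceeds background
  (`qpois(1 - 1e-6, lambda_bg)`).

Everything is drawn from a single seeded stream, so a config is
byte-reproducible, and `simulate_genome()` replays the same genome the
full experiment uses.

What the simulator does **not** model: fragment-size distributions, GC
or mappability bias, PCR duplicates, replicates, diploidy, or peak
shape. Consequently, passing recovery tests demonstrates that the
statistical machinery is correct under its own assumptions — it does
not certify performance on real libraries, where the unmodeled effects
dominate the error budget.

## The minimal peak caller

`call_peaks()` is plumbing, not science: genome-tiling windows (200 bp,
step 50) are scored by the Poisson upper tail of the ChIP count against
the depth-scaled control expectation (with a genome-wide floor so empty
control bins cannot divide by zero), Benjamini–Hochberg adjusted, and
significant windows passing a fold filter are merged into
non-overlapping peaks. It exists so the synthetic end-to-end path needs
no external tool; real analyses should supply peaks from a production
caller, which this one does not attempt to match.

## Bench-assay statistics

Three small quantification formulas accompany the genomic pipeline: the
chromatin co-fractionation percentage
$100\,n_C/(n_C + 1.3\,n_S)$ (signals normalized to a loading control;
the 1.3 concentration factor is a parameter because it derives from
specific buffer volumes), percent survival
($100 \times$ treated/untreated viable cells), and a paired two-sided
t-test with explicit handling of degenerate inputs (identical pairs:
$t=0, p=1$; zero-variance nonzero differences: $p \to 0$, flagged).
Significance stars follow the usual convention (\*, \*\*, \*\*\* at
0.05, 0.01, 0.001).

## Problem sizes and determinism in the test suite

Module tests run the simulator at a reduced scale (300 kb genome, 45
sites, $3 \times 10^4$ reads per condition) chosen to exercise every
code path in seconds; the end-to-end recovery checks use the full
default configuration over 20 fixed seeds and require ≥ 95% correct
labels, detection of the planted promoter enrichment at
$\log_{10} p < -5$, and planted motif fractions recovered within 5
percentage points. All stochastic tests fix their seeds; tolerance
choices (e.g. $10^{-10}$ against brute-force oracles) reflect the
accumulation behavior of the underlying floating-point sums, not
statistical slack.

## Known limitations

* One sample per condition: without replicates the exact conditional
  test captures sampling noise only; biological variability is outside
  the model, which is why the fold-change filter does most of the work.
* The evaluation-set construction (union of centers, greedy dedup) is
  one reasonable convention among several; alternatives (per-condition
  evaluation, midpoint averaging) would shift a small number of
  borderline sites.
* The enrichment test treats sites as independent draws from the
  genomic base composition; clustered sites violate this mildly.
* PWM thresholds as a fraction of the maximum score are not calibrated
  to a false-positive rate; the package reports the empirical sampled
  background alongside every fraction for exactly this reason.
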