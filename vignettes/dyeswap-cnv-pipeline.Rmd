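---
title: "Calling CNVs from dye-swap aCGH: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CNVs from dye-swap aCGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapCGH)
```

This vignette is the package's own account of the science it implements:
the signal model behind the simulator, the statistical model behind each
correction, the tunable parameters with their defaults and units, and the
places where the design was genuinely open and a choice had to be made.

## 1. The measurement model

A two-color aCGH spot reports two channel intensities. After background
subtraction the log ratio *M* = log2(red/green) estimates the test/reference
copy ratio at that locus, and *A* = ½(log2 R + log2 G) the spot's overall
brightness. Between two diploid genomes, a heterozygous duplication in the
test sample is expected at *M* = log2(3/2) ≈ 0.58 and a heterozygous
deletion at log2(1/2) = −1; homozygous deletions are not modeled (the
simulator's truth sets restrict copy states to {1, 3} against the diploid
baseline 2, since two inbred strains of the same species are not expected
to differ by complete loss of both alleles at appreciable rates).

The simulator writes, per spot and array (log2 scale):

> M_raw = s·(log2(copy/2) + ε) + bias + gradient + block noise

with *s* = +1 on forward arrays (test in red) and −1 on reverse arrays.

* **ε ~ N(0, noise_sd)** is multiplicative noise on the *test-sample
  abundance*. Because it rides on the test sample it flips sign with the
  dye assignment and therefore survives orientation adjustment unchanged —
  whereas the dye terms do not. `noise_sd` defaults to 0.15 log2 units,
  a realistic per-spot spread for genomic hybridizations (clearly below
  the 0.58 gain signal but far from negligible at single-probe
  resolution).
* **bias** is a spot-specific dye offset on the red/green ratio, a
  property of the spot that is identical across arrays. It is drawn once
  per layout: N(0, 0.05) everywhere plus a ±0.4 offset on a 25% subset,
  reflecting the common observation that a substantial minority of spots
  on two-color chips is strongly dye-biased. With these defaults roughly a
  quarter to a third of spots test significant at p < 0.05 — the fraction
  is an output of the analysis, not a tuned quantity.
* **gradient** is a chip-level smooth polynomial in normalized grid
  coordinates (defaults to zero); **block noise** adds variance inside
  configured rectangles to emulate damaged chip regions for the QC stage.

Channels are reconstructed as R = 2^(A + M_raw/2), G = 2^(A − M_raw/2)
with A ~ N(10, 1), and a lognormal background is added to both, so that
foreground-minus-background subtraction is a meaningful operation rather
than an identity. One experiment seed drives everything; per-array
sub-seeds are derived from it, so a whole experiment is reproducible from
a single integer.

A useful identity follows from the noise placement: a forward/reverse pair
generated with the *same* noise seed differs, after orientation
adjustment, by exactly 2×(bias + gradient) at every spot. With the
gradient off this isolates the planted dye bias exactly, and the test
suite exploits it.

## 2. Preprocessing

**Quality control** applies two rules, never unflagging and never touching
intensities. Spot-level: nonpositive net signal in either channel.
Region-level: a sliding 10×10-spot window (half-window step) flags all its
spots when more than 40% of them deviate from the window median by more
than 3 array-wide MADs. The MAD is array-wide deliberately: a window's own
MAD is inflated inside a damaged region, which would mask exactly the
spots the rule is meant to catch. The window size and fractions are
pragmatic defaults for grids of a few thousand spots; a full
spatial-normalization treatment (trend estimation and correction rather
than flagging) is out of scope.

**Weighted-loess normalization** fits M on A with weight 1 for spots with
−1 ≤ M ≤ 1 and weight 0 otherwise — the literal binary reading of
"coefficients calculated from the M values between −1 and 1" — and
subtracts the fitted value from *all* spots. Span 0.3 with local-linear
fitting is standard MA-normalization practice. Robustness is an explicit
iterated loop (fit, drop |residual| > 3·MAD, refit, 3 iterations) rather
than a smooth downweighting family: hard rejection makes the robust fit
*equal* to a refit without the outliers, which both the tests and the
clean-data identity below rely on, and it degrades gracefully to the
plain fit when there are no outliers. Outside the fitted A range the curve
is extended flat from its nearest end. On zero-noise simulations this
chain is exact: the loess residual-rejection loop discards the CNV spots,
fits an exactly-zero curve through the diploid spots, and the
preprocessing chain returns the planted log2(copy/2) to within 1e-9.

**Orientation adjustment** multiplies reverse-array M by −1 (an
involution; A untouched), making all arrays read test over reference.

Two open points were settled as follows: background subtraction before
computing M (plain foreground − background; nonpositive results flagged,
not offset), and an A-dependent (MA) rather than position-dependent loess,
the convention of two-color normalization.

## 3. The per-spot dye model

Each spot's oriented values across the six arrays follow

> M_i = α + β·Dye_i + e_i,  Dye_i = +1 (forward) / −1 (reverse)

α is the genomic test/reference difference at the spot, β the dye bias
that survived normalization (orientation adjustment flips its sign, so it
does not average out). Ordinary least squares per spot, vectorized over
the chip: with the balanced 3+3 design α is the grand mean and
β = (mean_forward − mean_reverse)/2. The test on β is an ordinary t with
n − 2 degrees of freedom — *not* an empirical-Bayes moderated statistic:
the model is stated as least squares, moderation would change the
per-spot significance fractions, and with df = 4 the plain t is the
transparent choice. Under a null simulation its size is nominal (the
suite checks the 5% level within [0.04, 0.06] at 10,000 spots).

Correction subtracts β·Dye_i. Spots missing on some arrays are fitted on
what remains if both dye levels survive, otherwise skipped and passed
through unchanged (and reported). The Ward/Euclidean clustering diagnostic
brackets the correction: before, the two-group cut separates forward from
reverse arrays; after, dye-swap pairs merge first and the cut follows
samples. Dendrograms are exported as Newick text so the diagnostic is
testable rather than only plottable.

After correction, each sample's forward and reverse arrays are averaged,
then on-chip replicate probes of the same locus are averaged, giving one
M per locus per sample in genomic order.

## 4. Segmentation

Circular binary segmentation: the chromosome's probe sequence is treated
as a circle; every arc (i, j] is scored by the two-sample t statistic
comparing values inside vs outside the arc, with a pooled-SD denominator
(floored at 1e-12 so a noise-free step scores large and finite). The key
numerical observation exploited by the implementation: for a fixed arc
width, both the mean difference and the pooled SD are monotone in the
centered partial-sum difference |S_{i+k} − S_i − k·S_n/n| (the within- and
outside-arc sums of squares are quadratics minimized at the same point),
so the best arc per width is found with additions and comparisons only
and the full statistic is evaluated once per width. The O(n²) scan
reduces to cheap operations, which is what makes a permutation test
affordable; the scan itself lives in compiled code.

A split is accepted when the permutation p-value of the observed max-T —
probe order permuted within the tested stretch — falls below `alpha`
(default 0.01); `nperm` defaults to 10,000 with reduced values appropriate
for testing (1,000 throughout this package's own suites). The permutation
loop stops early once the exceedance count makes significance impossible,
which leaves null stretches cheap and true change-points the only
expensive cases. Ties in the arc scan break toward the smallest start then
smallest end; an arc and its circular complement induce the same split, so
equality there is immaterial. After recursion, adjacent segments whose
means differ by less than `merge_tol` (default 0.05 log2 units) are
re-merged — the explicit analog of the "undo" step segmentation packages
apply to suppress statistically significant but biologically meaningless
micro-splits. All permutation randomness is threaded from one seed;
results are bit-identical for a fixed seed.

## 5. CNVR definition and merging

A core is ≥3 consecutive probes (adjacent in genomic order; no maximum-gap
rule by default, a configurable `max_gap` exists for sensitivity analysis)
whose smoothed M all exceed +0.5 (gain) or fall below −0.5 (loss). The 0.5
cutoff sits just under log2(3/2) ≈ 0.58, the expected single-copy-gain
ratio, so a genuine heterozygous duplication clears it while diploid noise
does not. Cores run from the first probe's start to the last probe's end
and extend 5 Kb on each side — about half the 7.9 Kb median probe spacing,
i.e. the genomic footprint a single probe can claim on one side — clamped
to the chromosome. Extended same-status regions of one sample that touch
or overlap are merged, avoiding double-counted coverage. Across samples,
regions are unioned within status (book-ended regions count as
overlapping; with probe-resolution boundaries the distinction is below
the data's resolution anyway), supported by every contributing sample,
and named `cnv.<status>.<k>` in genomic order. Coordinates are 0-based
half-open internally and in BED output.

## 6. Interval statistics

Coverage accounting intersects the (merged) CNVR set with the merged gene
intervals and reports genic/intergenic lengths and percentages per status,
beside the whole-genome gene fraction. The significance of any observed
overlap is assessed by a placement null: each round draws as many
intervals as the query, with the query's exact lengths, uniformly over the
genome — chromosome chosen with probability proportional to its number of
valid start positions, every interval fully within its chromosome. Placed
intervals may overlap each other and their feature overlaps are summed,
not unioned (the statistic is a summed overlap length, and re-merging
would make the null subtly lighter-tailed than the query's own statistic).
The p-value uses the (k+1)/(n+1) pseudocount estimator, so it is never
exactly zero; a z-score (observed − null mean)/null SD is reported
alongside for the normal-approximation reading. The same machinery serves
depletion (genes) and depletion-of-conserved-elements style questions by
swapping the feature set. Assembly gaps are not modeled — the synthetic
genome has none, and a gap-aware null would need a gap annotation the
interface does not require.

## 7. Enrichment and expression consistency

Gene-set over-representation is the upper-tail hypergeometric probability
P(X ≥ k) for k query hits in a size-K set from a size-N universe,
BH-adjusted across the collection; the test is enrichment-only by design
(depletion of a gene set in a short query list is rarely the question
asked of CNV genes). Multiple mature forms of one miRNA have their target
sets unioned before testing. Identifiers are opaque strings: any orthology
or platform mapping must happen upstream.

The expression re-analysis collapses probesets to genes by the
most-often-maximal rule — count, per probeset, the samples where it
attains the gene's maximum; keep the strict winner; average exact ties —
then tests each gene with a Welch t on log2 intensities (pooled variance
available by flag; the unequal-variance form is the safer default when
group variances are unknown) and BH-adjusts across genes. The 0.2 FDR
threshold is deliberately permissive: it trades a known ≤20% false
discovery proportion for sensitivity, appropriate for a consistency
screen rather than a discovery claim. "Most often associated with the
highest expression level" was read as rank-1 counts across samples (not
mean rank); ties within a sample credit every tied probeset. Consistency
is then mechanical: gain∧up or loss∧down is consistent, the opposite
inconsistent, no significant direction untested.

## 8. Synthetic scenarios: what they do and do not show

The default end-to-end scenario — 8 chromosomes × 12 Mb, genes covering
21% of the genome, 3 samples × 40 CNVs of 50–500 Kb with 70% shared,
7.9 Kb median spacing (~12,000 probes), noise SD 0.15, dye bias on 25% of
spots — is sized so that a full run takes a few minutes on one CPU while
every stage still operates at realistic per-probe signal-to-noise: CNVs
span 6–60 probes, gains sit only 0.08 log2 units above the call threshold,
and the dye-bias magnitude (0.4) exceeds the gain signal itself. On this
scenario the pipeline recovers ≥90% of planted CNVs with matching status
and probe-resolution boundaries (observed in the suite: ~99% with zero
false calls at the default settings).

What passing these suites does *not* establish: robustness to probe
sequence effects, GC-dependent waves, cross-hybridization, reference-pool
heterogeneity (the simulated reference is noise-free apart from
measurement noise — the variance contributed by a real pooled reference
is absorbed, indistinguishably, into `noise_sd`), or saturation and
scanner nonlinearity. Those failure modes change the *inputs* to the
chain, not its algebra; the suites validate the algebra and its
calibration.

## 9. Parameter summary

| Parameter | Default | Units | Stage |
|---|---|---|---|
| `noise_sd` | 0.15 | log2 | simulator |
| `bias_sd` / `bias_frac_large` / `bias_large_mean` | 0.05 / 0.25 / 0.4 | log2 / – / log2 | simulator |
| `target_spacing` | 7900 | bp | layout |
| `span` | 0.3 | – | loess |
| QC window / outlier rule | 10×10 / 3 MAD, >40% | spots | QC |
| `alpha` | 0.01 | – | CBS split test |
| `nperm` | 10,000 (1,000 in suites) | – | CBS |
| `merge_tol` | 0.05 | log2 | CBS undo |
| `threshold` / `min_probes` / `flank` | 0.5 / 3 / 5000 | log2 / probes / bp | CNVR |
| `n_rounds` | 1000 | – | placement null |
| `fdr_threshold` | 0.2 | – | expression screen |

All of them are exposed through `pipeline_config()`; the manifest written
by `run_pipeline()` records the values used, and identical config + seed
reproduce every output byte-for-byte.
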