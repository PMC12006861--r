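---
title: "Methods: PQS enrichment analysis in binding-site sets"
author: "g4peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PQS enrichment analysis in binding-site sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4peaks)
```

## The question the package answers

Guanine-rich DNA can fold into four-stranded G-quadruplexes (G4s). When a
transcription factor's binding sites carry more putative G4-forming
sequences (PQS) than expected by chance, that is evidence the structures
participate in binding or regulation. `g4peaks` quantifies this: it calls
PQS with the G4Hunter statistic, overlays the calls with ChIP-seq peak
sets, and compares the observed PQS frequency with a null built from
Markov-randomized genomes of matched base composition. Companion modules
annotate PQS-bearing sites by transcript biotype and promoter windows,
locate p53 response elements (REs), and analyse yeast luciferase
reporter-assay readouts.

## The G4Hunter statistic

Every base receives a signed run score: a base inside a maximal guanine
homopolymer of length $L$ scores $+\min(L, 4)$, a base in a cytosine run
$-\min(L, 4)$, and A/T score 0. The score of a sequence is the arithmetic
mean of its base scores, so it lies in $[-4, 4]$ and is exactly
antisymmetric under reverse complementation. Detection slides a window of
25 nt (the published default) along each contig, keeps windows with
$|\text{mean}| \ge 1.2$ (the published default threshold), merges maximal
runs of consecutive qualifying windows into one region, and reports each
region with its score *recomputed on the region's own sequence*. The
recomputation rule matters: it is the only definition consistent with
reported scores of characterized oligonucleotides whose lengths differ
from the window, and it implies a merged region's score may fall below
the window threshold (merging dilutes the densest window). Sequences
shorter than the window are scored whole, which is how 19–24-nt
oligonucleotides carry scores equal to their whole-sequence mean.

Two numerical details. N scores 0 and breaks G/C runs: it is a neutral
placeholder, never evidence for or against a run. And because base scores
are integers and window means are ratios of integers, threshold
comparisons at 1.2 are exact in floating point (both sides round to the
same double), so no tolerance is applied.

Regions whose recomputed mean is positive are G-rich hits reported on
`+`; negative means are C-rich hits on `-`. No boundary refinement beyond
the window union is applied — no published rule specifies one.

## Interval conventions

In memory, all intervals are `GRanges` (1-based, closed), the Bioconductor
convention; BED input/output converts to and from 0-based half-open
coordinates at the file boundary, and `as_bed_frame()` is the single
conversion helper for display and export. Half-open semantics are
preserved exactly: intervals that merely touch do not overlap. Peak-set
algebra uses whole-interval semantics (a peak overlapping a control peak
is removed entirely, never clipped), matching how control binding sites
are subtracted from ChIP-seq peak lists.

The PQS *frequency* of a peak set is defined as the number of distinct
PQS overlapping at least one peak per kilobase of total peak length. The
published figures do not state their frequency unit; per-kb density was
chosen because it is invariant to peak-set size, which differs by orders
of magnitude between proteins. A PQS overlapping two peaks counts once —
the frequency describes PQS, not pairs. An empty peak set (a knockout
control with no binding) has frequency 0 by convention.

Promoter windows are $[-1000, +100)$ around the TSS, strand-aware: on `+`
the window runs 1000 bases upstream of the TSS to 100 bases into the
transcript, on `-` it is the mirror image; windows are clipped at contig
bounds. Annotation assigns a PQS-bearing target to *every* transcript it
overlaps (biotype tallies may legitimately multi-count), is
strand-agnostic by default (peaks are unstranded) with a strict-strand
option, and excludes unannotated targets from percentage denominators.

## The randomization null

The null genome generator fits a Markov model of order 1 by default —
"relationships between individual bases" means base-to-base transitions —
with exact transition counts pooled over contigs (windows containing N
are skipped; N is never emitted). Randomized genomes are produced by
ancestral sampling from the fitted chain, length-matched per contig, five
replicates by default, with consecutive seeds so the ensemble is
reproducible. A context with no observed transitions restarts the chain
from the initial distribution (counted and reported); with order 1 on any
realistic genome this never triggers. Sampling uses R's RNG through
compiled code, so a fixed seed gives byte-identical genomes. Model-based
sampling was chosen over an exact dinucleotide-preserving (Euler-path)
shuffle because the procedure being emulated is model-based
randomization; the exact shuffle is a possible future extension. The
Markov order is exposed for sensitivity analyses.

## The enrichment test, and an honest caveat

Each randomized genome is scanned with identical parameters and the
frequency recomputed against the *same* peak coordinates, giving one null
value per replicate. The test is a two-sided one-sample t-test of the
null values against the observed frequency as a fixed reference:

$$t = \frac{\overline{x}_{\text{null}} - f_{\text{obs}}}{s_{\text{null}}/\sqrt{n}},
\qquad \text{df} = n - 1.$$

This mirrors the design of plotting replicate means with standard
deviations against a single observed value; with one observed number a
two-sample test is impossible. If the null replicates have zero spread
the test degenerates (p = 0 unless the observed value equals the common
null value, then p = 1). Tiers follow the conventional stars (0.05,
0.01, 0.001, 0.0001; the 0.01 tier is an extension beyond the published
legend, emitted for completeness).

The caveat: treating the observed frequency as *fixed* ignores its own
sampling variability. If the observed value is exchangeable with the
null replicates — exactly the situation under a global null with no
planted signal — then
$\mathrm{Var}(\overline{x}_{\text{null}} - f_{\text{obs}}) =
\sigma^2(1 + 1/n)$, not $\sigma^2/n$, and the statistic is inflated by
roughly $\sqrt{n+1}$. The calibration simulation in the test suite
(500 generated datasets, 200 kb genomes, no planted motifs, uniformly
placed peaks) measures a rejection rate near 30% at nominal 5%, matching
this analysis. The test is therefore a *descriptive* comparison of an
observed value against a replicate ensemble — appropriate when the
observed excess is large, as in the planted-enrichment analyses where
$t$ is in the tens — not a calibrated hypothesis test near the null. For
a calibrated variant, `enrichment_test(..., method = "prediction")`
widens the denominator to $s\sqrt{1 + 1/n}$ (a prediction-interval test),
which restores type-I control under exchangeability. The default remains
the fixed-reference formula because that is the procedure the package
reimplements; the choice is isolated in one function so it can be
swapped.

## The response-element scanner

The p53 RE is two copies of the 10-mer half-site RRRC(A/T)(T/A)GYYY
separated by a 0–13 bp spacer. The scanner classifies each position
(purine / C / A-T / G / pyrimidine; N matches nothing), counts class
violations, and reports every (position, spacer) placement whose two
half-sites total at most `max_mismatch` violations — all placements, not
a best-per-locus reduction, so overlapping placements are visible. No
per-position weighting is applied because the consensus carries none.
The class pattern is its own reverse complement, so a forward-strand
scan covers both strands; only the canonical representative is
reported. This scanner is a desk-scale consensus tool: it does not
reproduce functional grading (grades 1–5) of dedicated RE classifiers,
and its mismatch count is not a functional grade.

RE–PQS distances are nearer-end gaps (0 for intervals that touch in
half-open terms); intervals sharing at least one base report
`"overlap"`, the convention used for characterized loci where the PQS
sits inside the RE region.

## The reporter-assay chain

Luminescence is normalized to culture density (RLU = lum / OD600), which
cancels any common gain. Per (strain, galactose, time) cell, the
empty-vector RLU pool is trimmed with the standard Tukey fence
(quartiles by linear interpolation, $k = 1.5$) — the phrase "1.5 times
the interquartile variance" in the source protocol is read as this
fence, the universal convention the wording points at — then averaged;
each expressing replicate's RLU is divided by that mean to give
replicate-level folds. Fewer than four values cannot support quartiles
and pass through unfiltered with a warning.

Fold values are analysed per (galactose, time) stratum with a
fixed-effects two-way ANOVA, `fold ~ strain * protein`, reported with
type II sums of squares (robust to the mild imbalance outlier trimming
induces). Dunnett comparisons contrast every strain against a named
control strain — the control is a required argument, never guessed —
within each protein level, all jointly adjusted as one family per
stratum: adjusted p-values are equicoordinate tail probabilities of the
central multivariate t with the pooled residual degrees of freedom and
the Dunnett correlation structure ($\rho_{ij} = \lambda_i\lambda_j$ for
comparisons sharing a control cell, 0 across protein levels), evaluated
by the seeded Genz–Bretz algorithm (1e5 integrand evaluations, absolute
tolerance 1e-4). Joint adjustment across protein levels makes the
familywise error exactly $\alpha$ per stratum, which the test suite
verifies over 500 simulated null datasets. A single comparison reduces
exactly to the unadjusted pooled t-test (computed in closed form, not by
integration); adjusted p-values are clamped to be at least the
unadjusted ones to guard against Monte-Carlo jitter at the integration
tolerance. A stratum with one protein level degenerates to a one-way
layout, which is how the two-group limit is reachable at all.

## What the synthetic generator emulates — and what it does not

The generators replace external ChIP-seq and genome resources with
inputs whose ground truth is known exactly, so every downstream stage's
recall is computable. Defaults, chosen once as study-shaped values:

| parameter | default | why |
|---|---|---|
| genome | 200 kb over contigs of 100/60/40 kb | desk-scale, multi-contig |
| GC content | 0.41 | human-like |
| planted motif | `GGGTGGGTGGGTGGGTGGG` | canonical G3N1 tract, score 40/19 ≈ 2.105, safely above 1.2 |
| planted count | 100 (0.5/kb) | the order of the human genome's PQS density at default G4Hunter parameters |
| peaks | 150 × 250 bp | ChIP-seq-scale peak widths |
| enrichment ρ | 0.5 | half the peaks sit on planted PQS |
| reporter design | 4 strains × (WT, R282W, empty) × 2 galactose × 2 times, n = 6 | the reporter study's shape, at least five replicates |
| noise CV | 0.15 | realistic plate-reader spread |

The background is i.i.d. (order 0) *by design*: the order-1 null then
models the background faithfully while remaining blind to planted
motifs, so randomization provably erases the planted signal and the
enrichment contrast is clean. Motifs are planted non-overlapping on
random strands; peaks with `on_pqs = TRUE` are centered on sampled
planted motifs, the rest are placed uniformly with manifest positions
rejected, so ρ = 0 yields only chance-level overlap. Reporter
luminescence is `baseline × true_fold × lognormal(0, cv) × OD600` with
OD600 uniform in a plausible band, so RLU recovers the planted fold
without bias (the lognormal mean offset cancels in the ratio).

A caution about false positives: i.i.d. DNA at GC 0.5 produces roughly
one qualifying 25-nt window per ~160 windows
($P(|\bar{w}| \ge 1.2) \approx 0.006$), about 12 merged background calls
per 10 kb; at the default GC 0.41 the rate is about 3-fold lower.
Background calls are therefore sparse but *not* negligible, and tests
treat them as part of the expected signal, not as errors.

What the generator does **not** emulate: repeat structure, isochores and
long-range composition gradients of real genomes; realistic GENCODE
transcript density and overlapping isoforms; N-gaps; chromatin state or
peak-calling artifacts. Passing tests on synthetic data show the
*pipeline arithmetic and statistics* are correct under known truth —
they do not show that real binding sites are G4-enriched, which requires
the real external data.

## Problem sizes used by the validation suite

The suite runs the brute-force oracle comparisons at 100 random
sequences up to 200 nt (detection) and 1000 × 1000 intervals
(intersection); the antisymmetry property at 1000 random sequences;
the enrichment calibration and power analyses at 500 simulated 200 kb
datasets; and the reporter calibration at 500 simulated designs with 30
seeds for fold recovery. These sizes give binomial/Monte-Carlo precision
comfortably finer than the tolerances being checked.

## Known limitations

* The enrichment t-test is descriptive near the null (see above); use
  `method = "prediction"` when calibrated inference matters.
* The Markov null does not preserve exact dinucleotide counts
  (model-based sampling, not an Euler-path shuffle).
* The RE scanner is a consensus filter, not a functional classifier.
* Four characterized oligonucleotides (PCNA, PIDD1, ASTN2, PURPL) carry
  reported scores inconsistent with the mean-per-base definition on
  their printed sequences under any normalization; `g4_oligos()` flags
  them and no agreement is forced.
* Genome-scale published frequencies require the original external peak
  sets and genome and are out of scope at desk scale.
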