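---
title: "Quantifying mitochondrial deletion heteroplasmy from split reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial deletion heteroplasmy from split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

## The problem

The human mitochondrial genome carries a pair of identical 9-bp direct
repeats (`CCCCCTCTA`) in the intergenic region between the COII and
tRNA-Lys genes. Loss of one copy — the "common 9-bp deletion" — is a
recurrent structural variant found across world populations, and because a
cell carries hundreds to thousands of mtDNA molecules the deletion is
usually *heteroplasmic*: only a fraction of genomes carry it. mitohet
detects such deletions from split sequencing reads and estimates that
fraction per sample, then aggregates estimates across samples stratified by
mitochondrial haplogroup.

Two library classes are supported. Deep present-day sequencing (local
depths in the thousands, ~100-bp reads) permits precise estimates; ancient
DNA libraries (local depths of tens, 30–100-bp fragments, residual
deamination damage) only support estimates with wide uncertainty, which the
package reports honestly via intervals.

## Breakpoint ambiguity and left alignment

A deletion of one repeat copy has no unique breakpoint: every placement of
the same length whose application yields the identical genome string is
observationally equivalent. For the 18-bp tandem tract this class has 10
placements. `equivalent_placements()` materialises the class by scanning
single-base shifts (`base(start-1) == base(end-1)` leftwards,
`base(start) == base(end)` rightwards — exactly string equality of the
deleted genomes, which the test suite verifies against a brute-force
oracle), and `left_align_deletion()` reports the smallest-start member as
the canonical event. All evidence is canonicalised before grouping, so
reads whose gaps were placed anywhere inside the tract support one event.

Reported coordinates are the canonical 1-based inclusive first and last
deleted base. VCF output uses the standard anchor-base normalisation (POS =
base before the deletion, REF = anchor + deleted bases, ALT = anchor) with
the inclusive span echoed in `INFO/SPAN`.

## Split-read detection

`align_read_split()` scores every placement of a read on the locus window
with at most one internal deletion gap (match +1, mismatch −2; ties broken
by smallest offset, then gap start, then gap length; `N` matches nothing).
It is exhaustive and therefore serves as its own specification; the batch
mapper `map_reads()` is a seed-and-extend fast path (13-mer exact seeds
every 7 bases, candidate offsets evaluated ungapped and as single-gap
splits, with an exhaustive fallback when seeds fail) whose decisions the
test suite checks against the exhaustive search. One deliberate choice: an
ungapped candidate placement is accepted without a split search only when
it is perfect. Near a deletion locus, a junction read whose overhang barely
clears the repeat copy has a *nearly* perfect ungapped placement (the
overhang partially matches the second copy), and a greedy acceptance
silently swallows exactly the reads that carry breakpoint information.

Each junction read is scored `min(left anchor, right anchor) − 2 ×
mismatches`, floored at 0 — thresholds then read as "shortest clean anchor
of at least that many bases". Detection keeps events with at least 5
score-passing reads (deduplicated by read id, so a mate pair cannot support
an event twice) at score ≥ 25 for present-day libraries. Ancient libraries
use the reduced threshold 20, with a sensitivity re-check at 15 whose
support count is monotone by construction (a property the acceptance suite
asserts). These filters and every other tunable live in
`pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 5 | supporting reads required for a call (inclusive) |
| `min_score` | 25 / 20 / 15 | split-read score threshold by mode |
| `high_het_threshold` | 0.15 | reporting filter on the heteroplasmy fraction (inclusive) |
| `flank` | 50 nt | local-depth window on each side of the repeat pair |
| `quant_margin` | 8 bp | anchor margin beyond the ambiguity tract for quantification-grade reads |
| `cluster_tol` | 3 bp | junction-clustering tolerance for quantification |
| `max_del` | 20 bp | largest deletion gap the aligner considers |
| `window_pad` | 500 bp | mapping window padding around the region |
| `min_n_for_sem` | 4 | carriers needed before a SEM is reported |
| `alpha` | 0.05 | significance level of cohort tests |

## The local-depth benchmark and the estimator

The denominator of the heteroplasmy estimate is the mean per-base depth
over the two 50-nt windows flanking the repeat pair — upstream of the left
copy and downstream of the right copy. The inter-copy positions are
excluded: they sit inside the deletion and would bias the denominator.
Junction-spanning deletion reads do cover the flanks, so both alleles are
counted and the ratio is a proportion of molecules.

Counting reads, however, mixes two geometries. A read covers a flank
*position* from any of its `r` placements, but it can express a junction
only from the placements that leave both anchors long enough — for an
ambiguity tract of length `a` and anchor margin `m`, from `r − (a + 2m) + 1`
of them. Dividing the raw junction count by the raw local depth therefore
underestimates heteroplasmy by exactly that placement ratio. The pipeline
scales the denominator by the empirical junction-expressing fraction
`mean((r − c + 1)+) / mean(r)` over the sample's aligned read lengths
(`c = a + 2m`), which keeps the estimator unbiased for any read-length
distribution, including the variable ancient fragments.

Quantification counts junction reads more permissively than detection:
every breakpoint-informative read (anchors clearing the tract by
`quant_margin = 8` bases) is counted, not only those passing the discovery
score. The margin of 8 is chosen so that counted reads are ones the mapper
recognises essentially always — overhangs shorter than that mismatch so
little against the reference that their detection probability varies, which
would re-introduce bias that the fixed placement correction cannot absorb.
A second repeat-locus subtlety: a sequencing error at a junction-critical
base makes a read genuinely match a placement shifted by a base or two
outside the equivalence class. Quantification therefore clusters
same-length events whose canonical breakpoint lies within `cluster_tol = 3`
bases of the target's class, the same re-attribution an indel realignment
step performs. The known distinct deletion variants at this locus differ
in length, so clustering cannot conflate them.

Discovery and quantification are deliberately separate: discovery uses the
strict thresholds to decide *which* events are real, quantification then
estimates *how much* of a configured (or discovered) event is present. In
`targeted` mode (the default) the configured repeat-pair deletion is
quantified in every sample — re-genotyping of a known event across a
cohort — with sub-threshold evidence flagged in the output notes rather
than silently dropped.

## Uncertainty

The 95% interval is a Wilson score interval. Two refinements size it
honestly. First, the junction count is Poisson rather than binomial — the
"trials" are read placements, not a fixed panel — so the trial count is
deflated to make the implied binomial variance match the delta-method
variance with a Poisson numerator. Second, the denominator is itself
estimated from the same sample; its squared coefficient of variation
(computed read-wise under Poisson thinning, `sqrt(sum(overlap^2))/total`)
is added. The positive covariance between numerator and denominator is
ignored, which makes the interval mildly conservative — preferable to
under-coverage for the ancient samples where the interval is the main
deliverable. With no options, `estimate_heteroplasmy()` reduces to the
plain Wilson interval on `round(local_depth)` trials:

```{r wilson}
estimate_heteroplasmy(5, 10) # h = 0.5, CI ~ (0.237, 0.763)
```

## Cohort statistics

`summarize_by_haplogroup()` groups high-heteroplasmy carriers (h ≥ 0.15,
boundary inclusive) by dataset and haplogroup and reports mean ± SEM, the
SEM gated at 4 carriers as is conventional for small lineage groups.
`compare_haplogroups()` reports, for every eligible pair, both a
least-squares-means style contrast (one-way fixed-effects linear model with
pooled error variance, computed through emmeans — the single-factor
completely-randomised-design analogue of a SAS GLM analysis) and an exact
rank-sum test. Raw p-values are flagged at α = 0.05 with Holm-adjusted
columns emitted alongside; no correction is applied by default because the
single-factor design reports raw pairwise contrasts.

The rank-sum and signed-rank tests are implemented with exact enumeration
up to 12 observations and a tie-corrected, continuity-corrected normal
approximation beyond. Enumeration is in-house because the cohort data are
tie-heavy (many samples share a rounded heteroplasmy value) and
`stats::wilcox.test()` declines exact p-values under ties; on tie-free data
the two agree exactly, which the test suite asserts. Disease association
compares cases against healthy samples per dataset with non-carriers
entering at h = 0 (absence of the event is informative; note this is a
different inclusion rule from the carrier-only summaries, and both are
explicit). Where a complete pairing key exists (e.g. mother–offspring
pairs) the paired signed-rank test is used instead.

## The synthetic-data generator

`make_synthetic_genome()` draws a random 16,569-bp circle with the exact
tandem `CCCCCTCTA` pair planted at positions 8272/8281 and re-draws the
background until the motif occurs nowhere else and the tract-flanking bases
do not extend the ambiguity class — so the class is exactly the 10
placements the tests assert. `simulate_reads()` mixes wild-type and
deletion haplotypes at a specified fraction: per-read haplotype is
Bernoulli, starts are uniform over the locus window (region ± 500 bp),
substitution errors default to 1%, and ancient mode draws fragment lengths
from a truncated normal (mean 55, sd 15, bounded 30–100) with 5' C→T
deamination at rate 0.02 decaying geometrically (factor 0.5 per position).
The damage default is small because the ancient libraries of interest are
UDG-treated; a high-damage setting exists for robustness exercises. Read
counts are chosen so the expected flank depth equals the configured depth.
Start positions are drawn with `sample.int()`; drawing them as
`floor(runif(n) * k)` immediately after the haplotype `rbinom()` block
exhibited a measurable lagged correlation between the two consecutive
Mersenne-Twister output blocks (junction-window deletion-read counts
overdispersed by ~1.4×), which `sample.int()`'s rejection sampling does not
show.

What the generator does *not* emulate: platform-specific error profiles,
paired-end insert sizes, mapping competition from the nuclear genome
(NUMTs), library duplicates, and coverage waviness. Passing tests therefore
certify the detection geometry, the estimator's calibration and the
statistical chain — not robustness to every artefact of real libraries;
SAM/BAM ingestion exists precisely so externally mapped real data can be
brought in with their own upstream handling.

## Problem sizes and numerical choices

The validation suite runs at desk scale chosen to exercise the claims
without excess: recovery at local depth 2000 with 40 replicate seeds per
heteroplasmy level (0.15/0.40/0.62/0.74), specificity on 40 deletion-free
samples at the same depth, ancient-mode coverage on 40 samples with depths
drawn from 22–149, and cohort power on 20 replicates of a 21-vs-23-sample
two-lineage contrast at depth 300 (measurement noise at that depth is
already negligible against the 0.05 between-sample spread). Degenerate
inputs are defined, not special-cased: empty alignment sets give all-zero
depth profiles; zero flank coverage marks the sample failed while the run
continues; all-tied test inputs return p = 1 with a warning; a zero-length
deletion is rejected at construction.

## Limitations

Only single-deletion split alignments are modelled (no dual gaps, no
inversions); origin-spanning deletions are supported by the coordinate
types but exercised only lightly; heteroplasmy of point variants is out of
scope. Haplogroups are consumed as metadata, never called. Ancient
estimates remain estimates: at local depth 30 the Wilson interval spans
tens of percentage points, and that width — not the point value — is the
result.
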