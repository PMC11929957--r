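# mitohet

Split-read detection and heteroplasmy quantification of mitochondrial
deletions, built around the common 9-bp deletion of the human mtDNA
COII/tRNA-Lys intergenic region.

## What it does, and for whom

Human mtDNA carries a tandem pair of identical 9-bp direct repeats
(`CCCCCTCTA`). Loss of one copy is a recurrent deletion that is almost
always *heteroplasmic*: only a fraction h of a sample's mitochondrial
genomes carry it. mitohet is for researchers who want to measure that
fraction from deep present-day sequencing or (with honest uncertainty)
from low-coverage ancient DNA libraries, and to compare it across
mitochondrial haplogroups and case/control groups.

The chain, end to end:

1. **Reference model** — circular coordinates; deletions inside the repeat
   tract have no unique breakpoint, so every event is left-aligned to the
   canonical member of its string-equality equivalence class
   (`equivalent_placements()`, `left_align_deletion()`).
2. **Detection** — junction evidence either from the built-in single-gap
   split aligner (`align_read_split()` exhaustive, `map_reads()` seeded
   fast path) or ingested from SAM/BAM CIGARs (`ingest_alignments()`).
   A read's split score is `min(left anchor, right anchor) − 2·mismatches`;
   an event is called with ≥ 5 score-passing reads at score ≥ 25
   (present-day), 20 (ancient), or 15 (ancient sensitivity re-check).
3. **Quantification** — the estimator is
   `h = n_support / (local_depth · junction_fraction)`, where
   `local_depth` is the mean per-base depth over the two 50-nt windows
   flanking the repeat pair and `junction_fraction = E[(r − c + 1)⁺]/E[r]`
   rescales per-base depth to junction-expressing read placements
   (c = ambiguity-tract length + 2 × anchor margin). A Wilson score
   interval sized for a Poisson numerator and an estimated denominator
   gives the 95% CI; the reporting filter keeps h ≥ 0.15.
4. **Cohort statistics** — carrier summaries (mean ± SEM, SEM gated at 4
   carriers) by dataset × haplogroup; pairwise least-squares-means t
   contrasts (pooled-variance one-way layout via emmeans) alongside exact
   rank-sum tests; exact Wilcoxon signed-rank for paired case/control
   designs. Exact p-values are computed by full enumeration up to n = 12,
   ties included.
5. **Simulator** — seeded synthetic circular genomes with the planted
   repeat pair, mixed wild-type/deletion read sets at any true h,
   present-day (100-bp reads, depth ~10³) and ancient (30–100-bp
   fragments, depth ~22–149, 5' C→T damage) modes, plus whole-cohort
   scenario bundles — so the entire chain is testable without downloading
   any sequencing archive.

## Worked example

```r
library(mitohet)

genome <- make_synthetic_genome(seed = 42)     # 16,569-bp circle, repeat pair at 8272/8281
params <- sim_params("present-day", true_h = 0.74, depth = 2000)
sim    <- simulate_reads(genome, params, seed = 11, sample_id = "T1")

q <- quantify_sample(sim$reads, ref = genome$ref, pair = genome$pair,
                     config = pipeline_config(), sample_id = "T1")
q
#>   sample_id        mode event_first event_last n_support n_detect local_depth
#> 1        T1 present-day        8272       8280      1145      703     2024.66
#>           h    ci_low   ci_high passes_high_het detected note
#> 1 0.7441145 0.6911485 0.7907473            TRUE     TRUE
```

Reading the output: the canonical deletion spans bases 8272–8280 (1-based,
left-aligned); 1145 breakpoint-informative junction reads were counted
against a flank depth of 2025 reads/base, giving ĥ = 0.744 with a 95% CI of
(0.691, 0.791) — covering the simulated truth of 0.74. `n_detect` is the
stricter score-filtered support that the discovery filter saw (well above
the 5-read minimum), and the call passes the 15% high-heteroplasmy
reporting filter.

A cohort run over many samples (`run_pipeline()`) adds the haplogroup
summary, pairwise contrasts, disease tests, and a report bundle
(TSV + VCF + run log). A thin command-line front end with verbs
`simulate | detect | quantify | cohort | run` is installed at
`inst/cli/mitohet`.

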