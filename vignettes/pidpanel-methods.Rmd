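---
title: "Methods: variant triage, artifact filtering and coverage QC for targeted panels"
author: "pidpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage, artifact filtering and coverage QC for targeted panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidpanel)
```

# Scope and model

`pidpanel` implements the downstream computation of a targeted gene-panel
diagnostic pipeline: pileup calling under permissive germline settings,
control-cohort background filtering, rule-based triage of SNVs, region
coverage QC, Sanger-concordance metrics, paired protocol comparison and a
reagent cost model. Upstream steps (capture chemistry, read mapping,
functional annotation, deleteriousness prediction) are out of scope; the
`predicted_deleterious` flag is an input annotation, never computed here.

Coordinates follow the two field standards and never mix: variant
positions are 1-based (VCF), all interval arithmetic is 0-based half-open
(BED). Every identity comparison between variants — blacklist matching,
cohort checks, concordance — operates on *normalized* keys
(`chrom:pos:ref:alt` after left-alignment and trimming), because INDEL
notation emitted by callers is frequently non-canonical and
identity-based filtering silently breaks without normalization.

## Variant normalization

`normalize_variant()` reduces any representation of an event to the
minimal left-aligned *anchored* form (the VCF convention: an INDEL keeps
one shared leading anchor base, so alleles are never empty). The
algorithm is the standard one: repeatedly trim a shared trailing base,
extending leftward through the reference whenever an allele would empty;
then trim shared leading bases down to the anchor. The operation is
idempotent, and the test suite verifies by brute-force enumeration of
equivalence classes (every representation over windows up to 30 bp that
yields the same edited haplotype) that all members map to a single key
and that no equivalent representation of the same allele shape lies
further left.

## Pileup caller

The caller evaluates candidate events per window column (SNVs per alt
base, deletions from maximal gap runs, insertions from insertion
observations) against the permissive germline thresholds carried in
`caller_settings()`: minimum coverage 6 (SNP) / 15 (INDEL), minimum
alt-supporting reads per strand 0 / 5, minimum variant score 10, minimum
allele frequency 0.1, maximum strand bias 0.95 / 0.85. Two quantities are
named but not defined by convention in such pipelines, so this package
fixes them explicitly:

* **Variant score.** The Phred-scaled binomial sequencing-error tail,
  `-10·log10 P[Binomial(depth, e) ≥ alt]`, with the caller's error-model
  rate `e = 0.01` (configurable; routine run accuracies sit near 99%).
  This is the simplest Phred-compatible law: score 0 for zero alt reads,
  monotone in the alt count, 400 for 20/20 alt reads at `e = 0.01`. The
  score is capped (default 1000) where the tail underflows.
* **Strand bias.** The majority-strand fraction of alt reads,
  `max(f, r)/(f + r)` — bounded in [0.5, 1], directly comparable to the
  0.95/0.85 cutoffs, and not evaluable when no alt reads carry strand
  information.

All thresholds are inclusive: `≥` passes, and bias `≤` the maximum
passes; the boundary convention is pinned by tests at the exact boundary
values. Deletions touching the first window column cannot be left-anchored
and are skipped; simulated windows carry margin so the case does not
arise in generated data. The caller is verified call-for-call against an
independently written brute-force enumerator on seeded random stacks, and
a property test asserts that tightening any single threshold never
enlarges the call set.

## Background filter

Permissive calling inflates recurrent platform artifacts. The filter
identifies them from healthy controls: a key enters the blacklist iff it
is flagged deleterious and occurs in **more than one** distinct control
sample — occurrence at any VAF or quality counts, because the filter acts
on recurrence, not call strength. Matching against patients is exact on
the full normalized key; positional-only matching was rejected because it
would erase true patient alleles at polymorphic sites. The blacklist
serializes as 4-column BED with the key in the name column (BED geometry
alone cannot carry alleles) and the control count as a fifth column.

## Triage criteria

`classify_variant()` evaluates eight criteria; `HIGH_CONFIDENCE` —
meaning orthogonal Sanger confirmation is not warranted — requires all
eight to pass. Anything else, including missing evidence, yields
`NEEDS_CONFIRMATION` with the non-passing criteria named in `reasons`
(the audit contract: reports must say *why* a call needs confirmation).

| criterion | rule | default |
|---|---|---|
| `q_score` | Phred q ≥ threshold | 30 |
| `depth` | total reads ≥ threshold | 20 |
| `vaf` | allele frequency ≥ threshold | 0.25 |
| `not_in_controls` | absent from all wild-type controls | — |
| `not_in_runmates` | absent from other samples in the run | — |
| `no_read_covariants` | no second variant on the alt reads | see below |
| `context` | no homopolymer/repeat in or adjacent | see below |
| `snv_type` | event is an SNV (INDELs always confirmed) | — |

Three rules are qualitative in clinical practice and are quantified here
as explicit, configurable parameters:

* **Sequence context.** A homopolymer is a run of ≥ 4 identical bases
  (`homopolymer_min_run`), tuned to the semiconductor-sequencing failure
  mode; a repeat region is a perfect tandem repeat of unit ≤ 3 bp
  spanning ≥ 8 bp. "Immediately adjacent" is a gap of at most 1 base
  between the run/repeat and the variant footprint. The scan needs the
  window to extend `repeat_min_span + adjacency` bases on both sides of
  the footprint; a shorter window makes the criterion not evaluable.
* **Same-read co-variants.** Among the reads carrying the alt allele, a
  second non-reference allele counts as a co-variant only when it is
  shared by ≥ 30% of the alt reads (`covariant_min_frac`, and at least
  2 reads). The fraction matters: at a realistic 1% per-base error rate
  and a few hundred reads, *some* pair of alt reads shares a random error
  at some window position in almost every stack, so a literal "any second
  mismatch" rule would flag essentially every true variant. A genuine cis
  co-variant (misalignment, chimeric capture, neighboring real variant)
  rides on essentially all alt-carrying molecules; 30% separates the two
  regimes by a wide margin in both directions.
* **Somatic-suspect annotation.** Calls with VAF below the triage
  threshold but ≥ 3 alt reads are annotated `somatic_suspect = TRUE`
  rather than auto-classified: depth at the locus decides whether a
  low-fraction somatic allele is detectable at all, and the alignment
  should be inspected manually.

Not-evaluable is deliberately conservative (it blocks
`HIGH_CONFIDENCE`): in a clinical posture, missing evidence must never
upgrade a call. The VAF boundary is inclusive (≥ 25% passes); the
convention is stated here because it is not fixed by practice.

## Coverage QC

Two distinct region rules coexist and are reported separately, never
conflated: **flagged** (mean depth < 20 *or* < 100% covered — the
clinical-report criterion) and **unreliable** (mean depth < 20 *and*
< 90% covered — systematic failure). All inequalities are strict, and
`unreliable ⊆ flagged` by construction. Percent coverage counts bases
with depth ≥ 1 by default; the per-base cutoff is a reporting convention
(`covered_min_depth`) rather than a biological constant, so it is
exposed. Gene-level rollups are length-weighted by default, with an
unweighted mode for reports that average per-region figures; a gene is
"suboptimal" when actual coverage is below 90% *and* more than 5 points
below its design expectation. The clinical coverage report lists every
flagged region and prominently warns when a user-supplied hotspot falls
inside one.

## Concordance

The evaluation domain is the intersection of the Sanger-interrogated
intervals with exons padded by ± 5 bases (`exon_flank_keep`): deeper
intronic positions are not reliably captured by exon-flank designs and
are excluded from the metrics. Within the domain, events match by
normalized key; each variant site occupies one evaluated base, and every
remaining interrogated base is a true negative. This per-base TN
accounting is what produces specificity denominators on the order of the
amplicon base count (~59k for a ~33-sample validation set); the
convention is recorded with the tally so scope can be reconciled.
Sensitivity/FN-rate and specificity/FP-rate are exact complements, and
the identities are asserted to 1e-9 before any rounding.

## Protocol comparison

Paired per-region mean depth and percent coverage are compared with the
Wilcoxon signed-rank test: zero differences dropped (Wilcoxon's original
convention), mid-ranks for ties, `V` the rank sum of positive
differences. For n ≤ 25 nonzero differences the two-sided p-value comes
from the exact null distribution, computed by convolving the rank
polynomials `(1 + x^{2r_i})` over doubled ranks — algebraically identical
to enumerating all `2^n` sign assignments, and valid under ties; beyond
that, the normal approximation with the usual tie correction (no
continuity correction) is used, and a test pins the two branches to
within 10% relative p-value at the crossover. The linear regression of
optimized on default (slope, intercept, R²) is reported descriptively
only. Flag-count deltas reuse the coverage-QC flag rule.

## Cost model

Sanger reagent cost is linear in amplicons ($10 each); the panel assay is
flat per sample ($580). The break-even count is the smallest `n` with
`10·n > 580`, i.e. 59 — note that prose summaries sometimes round this to
">60 amplicons"; the fixture documents the discrepancy rather than
resolving it. The packaged five-panel fixture ships its gene lists
verbatim; one published total (SCID, printed 199) disagrees with its own
gene list (sum 217; the printed total equals the sum without AK2), and
`panel_amplicons()` sums the gene list. Labor is excluded — it dominates
total cost and favours high-throughput methods, so its exclusion is
conservative toward Sanger — but a multiplier hook exists for sensitivity
analyses. Known-family single-amplicon confirmation is modeled as a
1-amplicon panel.

# The synthetic-data generator

`simulate_run()` produces everything the pipeline consumes, with a truth
manifest enumerating every planted event and its intended outcome, so
evaluation never re-derives intent from data. What it emulates:

* **Capture non-uniformity**: per-region mean depth is log-normal
  (`meanlog = log(300)`, `sdlog = 0.5` by default — heavy-tailed, with
  typical mean depths of a few hundred, matching routine panel runs);
  per-base depth is Poisson around the region mean.
* **Systematic failures**: each region fails independently with
  probability 0.018 (~1.8% of regions), forcing mean depth below 20 and
  zeroing a contiguous 15–50% stretch — reproducing the "unreliable"
  coverage signature.
* **Cohort structure**: 11 healthy controls in their own run (background
  filtering), 6 patients sharing a run (run-artifact detection), 35 clean
  germline SNVs per patient (VAF 0.5, 10% homozygous at 1.0) at
  context-safe positions, at most one per region per patient so planted
  variants never masquerade as co-variants of one another.
* **Artifacts**: homopolymer runs (6–8 bases) embedded mid-region with an
  SNV planted immediately 3′ of each; run-wide artifacts planted in every
  patient of the run; control-cohort artifacts shared by 2, 2, 3 and 1
  controls respectively (the ≥ 2 ones are blacklist-expected) and planted
  in one patient each.
* **A low-fraction somatic case**: one variant at VAF 0.03 in a region
  with depth forced to 257, detectable only when the caller's
  allele-frequency cutoff is disabled.

Read stacks are columnar allele observations: every read spans its whole
region window, the read count is the rounded mean of the region's depth
profile, planted alt counts are `Binomial(n_reads, vaf)`, errors are
independent substitutions at 1% per base, strands Bernoulli(0.5). What
the generator does **not** emulate — and what passing tests therefore do
not show about real data: flow-space/homopolymer-length error structure
(homopolymer artifacts are planted by position, not mechanistically
generated), base-quality variation within a stack (one Phred score per
call), read-length and mapping effects, pseudogene cross-mapping, and GC
-driven (as opposed to randomly assigned) coverage failure.

Determinism: a fixed seed yields byte-identical bundles. All RNG streams
derive from the config seed at fixed offsets; per-sample stacks are drawn
from one sequential stream in a fixed order.

## Problem sizes

Defaults were chosen once as a desk-scale panel a practitioner would
recognize: 60 regions of 150–300 bp, 17 samples, mean depth ~300,
giving ≥ 200 planted events per bundle (~14 s to simulate and ~12 s to
run through the pipeline on one core). The test suite uses smaller
configurations (12–20 regions, 2 patients) for module tests and one
default-size bundle for acceptance-level checks; statistical assertions
(failing-region fraction at the 2455-region panel scale, binomial alt
counts) run at the sizes stated in the tests.

# Numerical and degenerate-input choices

* Score tail probabilities that underflow map to the score cap; depth 0
  makes the score undefined (error), while an empty stack yields an empty
  call set, not an error.
* `strand_bias(0, 0)` is not evaluable (`NA`), and calls imported without
  strand counts keep `strand_known = FALSE`; strand-dependent checks
  treat them as not evaluable rather than guessing.
* All-zero paired differences make the signed-rank test explicitly not
  computable, as do empty metric denominators in concordance.
* Multi-allelic VCF records are split into per-allele rows *before* any
  filtering, so blacklist and cohort matching operate on single alleles.
* Ties in the signed-rank test use mid-ranks everywhere; the exact branch
  handles them correctly (the distribution is over the observed tied
  ranks, not the untied 1..n).

# Known limitations

* The caller assembles no MNVs and performs no realignment or genotype
  likelihood computation; INDEL candidates come only from gap/insertion
  observations in the stack.
* Equivalence with any specific vendor caller's score or bias definitions
  is not claimed; the laws above are this package's own, chosen to be
  threshold-compatible and testable.
* The file-based pipeline route carries no read stacks, so the co-variant
  criterion degrades to not-evaluable there — conservative, but it means
  file-only reruns can demote calls that the in-memory route passes.
* Detection of the 3%-VAF somatic case at 257× is intrinsically
  stochastic even with the cutoff disabled: the planted alt count is
  binomial, and the score threshold needs ≥ 6 alt reads at this depth, so
  a meaningful fraction of replicates (roughly a fifth) falls below the
  callable count. Deeper coverage, not settings, is the remedy — which is
  why the triage layer annotates somatic-suspect calls for manual review
  instead of automating the decision.
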