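---
title: "g4utr: models, design choices and limitations"
author: "g4utr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{g4utr: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4utr)
```

# Scope

`g4utr` implements an integrative analysis of putative G-quadruplex
(pG4) motifs in mRNA untranslated regions: motif discovery and genomic
projection, isoform-level classification, three complementary measures
of selective constraint (allele-frequency comparison, the
mutability-adjusted proportion of singletons, and a heptamer-context
observed/expected substitution model), a family of interval-annotation
enrichment tests, and a beta-binomial test of allelic imbalance. A
synthetic-data layer generates inputs with known truth for every stage.

This vignette records the models, the genuinely open design choices we
made, the numerical details, and what the synthetic validation does and
does not establish.

# Motif discovery

## The canonical pattern and its ambiguity

A canonical pG4 is four guanine tracts of length ≥ 3 separated by three
loops of 1–7 nucleotides, i.e. `G{3,}([ACGTN]{1,7}G{3,}){3}` on the
sense strand. As a regular expression this pattern is ambiguous wherever
G-runs exceed three guanines or candidate motifs overlap: a run of five
consecutive G-runs admits two four-tract parses, and greedy versus lazy
quantifiers report different spans.

`scanPG4` therefore implements a fixed, documented disambiguation
policy rather than delegating to a regex engine:

1. enumerate maximal G-runs of length ≥ 3 from left to right;
2. starting at the leftmost run, accept the first window of four
   consecutive runs whose three inter-run gaps each span 1–7 nt;
3. report that motif with every tract extended to its full maximal run,
   and resume scanning *after* its last tract, so reported motifs never
   share a G-run.

This mirrors greedy text-search semantics while making the output a
deterministic function of the sequence. The policy is pinned by a
property test against an independent brute-force oracle (run
enumeration via run-length encoding) over a thousand random sequences.
`N` is never a guanine: it breaks runs and counts as an ordinary loop
character, so a tract containing `N` is impossible by construction.

Motifs with more than four compatible consecutive runs are reported as
the leftmost four-tract window; whether overlapping parses should
instead be merged or multiply counted is not decidable from the motif
definition alone, and we chose non-overlapping leftmost reporting as
the most reproducible convention.

## Coordinates and strand

All offsets are 0-based half-open internally and in data-frame output;
`GRanges` objects follow the Bioconductor 1-based convention at the
interface to `GenomicRanges`. `projectToGenome` maps UTR offsets
through the exon blocks; on the minus strand, transcript offset 0 maps
to the *highest* genomic coordinate. Motifs spanning splice junctions
yield multiple genomic blocks whose widths sum to the motif length.

A motif whose genomic blocks intersect *any* annotated CDS block — of
any transcript, not only the motif's own gene — is flagged by
`flagCDSOverlap` and should be excluded downstream. The broad reading
(any transcript) is deliberate: an interval annotated as UTR in one
isoform but coding in another experiences coding-level selection and
would contaminate UTR constraint estimates.

## Isoform classification and the permutation null

A gene is *constitutive* for a UTR side when every protein-coding
isoform carries at least one surviving motif there, *alternative* when
at least one isoform carries one and at least one lacks one.
`permuteIsoformLabels` asks whether the observed
alternative:constitutive ratio exceeds what random motif placement
produces. Its null keeps each gene's isoform count fixed, redistributes
the total number of pG4-bearing transcripts uniformly over all valid
assignments, and requires every gene to retain at least one pG4
transcript.

Uniform sampling over the constrained assignments is done exactly, not
by rejection: the number of assignments with per-gene label counts
$(c_1, \dots, c_G)$ is $\prod_g \binom{n_g}{c_g}$, so per-gene counts
are drawn sequentially from a dynamic-programming table of suffix
counts kept in log space. Rejection sampling is astronomically
inefficient here — with many single-isoform pG4 genes the acceptance
probability decays geometrically in the number of genes — while the
exact sampler is linear in genes per draw and provably uniform, which
an exhaustive-enumeration test on small fixtures confirms. The p-value
uses the standard permutation estimator $(1 + k)/(B + 1)$.

`classifyExpression` applies the strict > 1 TPM rule to the
highest-expressed pG4 and non-pG4 isoform per tissue; exactly 1 TPM is
*not* expressed.

# Constraint analyses

## Variant filtering and frequency comparison

`filterVariants` keeps biallelic SNVs with random-forest true-positive
probability strictly above 0.40 ("did not exceed 40%" excludes the
boundary), allele number at least 80% of the dataset maximum, and no
segmental-duplication/low-complexity/decoy flag. The allele-number
ceiling is computed per chromosome type (autosome versus X/Y) from the
input itself when not supplied, because sex chromosomes have a lower
attainable maximum; a global override is available. Filtering is
idempotent.

`matchTranscriptsByLOEUF` samples one comparator transcript per target
without replacement from the same LOEUF bin. The bin width (default
0.1) trades bin occupancy against matching fidelity and is exposed as a
parameter; empty bins widen to the nearest occupied bin with a warning.
`compareAlleleFrequencies` then tests the summed AC / (AN − AC) 2×2
table with a two-sided Fisher exact test; the odds ratio is the sample
OR, Haldane-corrected only when a marginal is zero (flagged).

## MAPS

MAPS for a variant class is the observed singleton proportion minus the
proportion predicted from mutability alone:
$$\mathrm{MAPS} = \frac{\sum_i 1[\mathrm{singleton}_i] -
\sum_i \hat p(\mathrm{context}_i)}{n}.$$
The prediction $\hat p$ is a least-squares regression of per-context
singleton proportions of synonymous calibration variants on
context-specific mutation rates, with one point per (trinucleotide
context, alternate allele, methylation bin). CpG contexts carry three
methylation bins — none/low (< 0.2), intermediate (0.2–0.6, both
endpoints included), high (> 0.6) — with separate rates; everything
else uses the unadjusted context rate.

Numerical choices:

- the regression is weighted by per-context variant count (an
  unweighted option exists for sensitivity analysis); with weighting,
  the weighted-residual identity makes MAPS of the calibration set
  itself exactly zero, which the suite asserts at 1e−12;
- predictions are clamped to [0, 1] and clamping events are reported —
  clamping breaks the exact-zero identity, so a rate table whose range
  drives predictions out of [0, 1] is a sign of miscalibration;
- positional MAPS should be computed only on trinucleotide G-tracts;
  tracts longer than three guanines leave ambiguous which guanines
  stack, so they carry no positional labels.

`permuteMAPS` resamples class and comparator with replacement (the
comparator resample is sized to the class) and reports the proportion
of draws in which the class MAPS does not exceed the comparator's,
plus the 5%/95% bootstrap quantiles of the class MAPS. Fewer than 100
bootstrap iterations triggers an instability warning.

## Heptamer observed/expected model

The expected number of polymorphic sites in a region is the sum over
its positions of the cumulative substitution probability of the
position's 7-mer context (the sum over the three alternate alleles).
Because the context model carries no methylation adjustment, every
position that is the C or G of a CG dinucleotide is removed; scanning
the forward strand suffices since a reverse-strand CpG occupies the
same two positions. Published context models are strand-collapsed, so
tables are symmetrized on load (each entry averaged with its
reverse-complement entry); this is toggleable. Positions lacking a full
ACGT 7-mer (sequence edges, `N`) are dropped and logged.

`oeBootstrap` resamples positions with replacement, matching the
region's size, and reports the empirical 5%/95% ratio quantiles;
iterations with zero resampled expectation are discarded and logged.
`oeEmpiricalNull` builds the background from contiguous windows
(default 5000 windows of 25 nt) of constraint-matched UTR sequence and
pairs bootstrap draws of the target and background ratios. The
depletion p is the proportion of pairs in which the target ratio is at
least the background's — the complementary tail of the literal
"proportion less than" formulation, which for a depleted region would
approach 1 rather than 0 and cannot be what a reported p < 1e−4 means.
G-tracts and loop (gap) sequences are evaluated as separate region
classes with positions pooled across motifs; all polymorphic sites
count regardless of allele frequency.

# Enrichment statistics

All 2×2 enrichment tests share one engine: sample odds ratio with
Haldane–Anscombe correction on zero cells (flagged), Woolf log-OR 95%
interval, two-sided Fisher exact p on the raw table. Fisher and
hypergeometric p-values are pinned against direct tail-enumeration
oracles in the suite.

Module-specific conventions:

- **eQTL enrichment**: significant variants (lead per gene and tissue,
  all nominal, or externally fine-mapped causal candidates) versus
  tested non-significant SNPs, across pG4 versus remaining UTR. Lead
  ties on minimal p break by smallest genomic coordinate. An optional
  collapse counts at most one nominal eQTL per pG4 feature, guarding
  against stacks of linked eQTLs.
- **Direction bias**: every variant–tissue effect counts separately;
  the binarized normalized-effect-size sign is crossed with
  G-tract/loop membership. Half-open intervals make boundary
  membership unambiguous.
- **CLIP density**: overlapping peaks are merged into unique sites
  before counting; density is sites per kb of each region class. The
  significance test uses the Pearson chi-square statistic on the 2×2
  table of site counts versus non-site base counts with a *default of
  2 degrees of freedom*. A 2×2 table conventionally has 1 d.f.; the
  2-d.f. default preserves the procedure as published for this test
  and is internally inconsistent with the table's structure, so a
  `df = 1` switch is provided and the choice is surfaced in the
  result. The 2-d.f. reference is conservative (larger p).
- **Per-RBP enrichment**: upper-tail hypergeometric with all UTR peaks
  as the population; significance is Bonferroni-corrected at 0.001
  across RBPs; module membership additionally requires 20 unique pG4
  sites.
- **Knockdown DE**: per-experiment Fisher OR of DE × pG4 with
  Benjamini–Hochberg control at 0.001 within each cell line; direction
  is the sign of the median log2 fold-change over pG4 genes.
- **ClinVar density**: variants spanning ≤ 40 nt, excluding
  Benign/Likely_benign, restricted to genes with ≥ 1
  Pathogenic/Likely_pathogenic variant; variant counts versus base
  counts per region class.

# Allelic imbalance

Read counts at a heterozygous variant across samples are modeled
beta-binomially with mean $\rho$ (reference-allele proportion) and
overdispersion $\phi \in [0, 1)$, parameterized as
$\alpha = \rho(1-\phi)/\phi$, $\beta = (1-\rho)(1-\phi)/\phi$, so
$\phi \to 0$ recovers the binomial. Optimization runs on
$(\mathrm{logit}\,\rho, \mathrm{logit}\,\phi)$ — unconstrained, stable
near the binomial boundary — from moment-estimate starts; likelihoods
below $\phi = 10^{-8}$ use the exact binomial limit, which the suite
checks against `dbinom` at 1e−8.

`lrtNoBias` compares the free fit against $\rho = 0.5$ with the
dispersion *re-estimated under the null* (fixing it to the
alternative's estimate is an option; re-estimation is the default
because a misspecified null dispersion inflates the statistic). The
statistic $2(\ell_1 - \ell_0)$ is floored at zero and referred to
$\chi^2_1$ even when the dispersion MLE sits at a boundary; boundary
fits are flagged rather than switched to a mixture reference, keeping
p-values comparable across variants. Samples need at least one read by
default (`min_reads`); no deeper per-sample threshold is imposed, and
the parameter is exposed because the appropriate floor depends on the
upstream pipeline.

# The synthetic-data layer

The generators encode the statistical structure each analysis assumes,
with effect sizes as dials and truth tables emitted alongside:

- `simulateTranscriptome`: 200 genes, up to 5 isoforms, UTRs of
  100–2000 nt by default (a desk-scale transcriptome that keeps the
  full suite in minutes). Background sequence is rejection-sampled to
  contain *no* canonical motif at guanine content 0.20, so every motif
  present is planted and the truth table is complete; planting verifies
  scanner recovery at exact coordinates before accepting a sequence.
  Isoforms carrying a gene's motif share one motif-bearing UTR (and
  its genomic blocks) unless a nonidentical branch (10%) gives an
  isoform its own motif, emulating shared versus isoform-specific
  UTRs.
- `simulateVariantClass`: contexts drawn proportional to mutation
  rate; singleton probability linear in the rate plus a class excess
  δ. Linearity makes the MAPS calibration correctly specified, so δ
  maps directly onto expected MAPS and ordering recovery is a sharp
  test.
- `simulateNeutralRegion`: per-position polymorphism Bernoulli with
  the table's cumulative probability — O/E is 1 in expectation, and a
  thinning factor plants depletion of known size.
- `simulateEQTLs`, `simulateClipPeaks`, `simulateClinvar`,
  `simulateKnockdownDE`: planted odds/density multipliers so the
  estimators' recovery can be checked against truth.
- `simulateASECounts`: Poisson depths, beta-binomial reference counts;
  defaults (84 samples, ~50×) mirror a GTEx-style single-variant
  analysis.

What passing the synthetic suite shows: the estimators are unbiased
under their assumed generative models, hold their nominal error rates,
and recover planted effects. What it does not show: robustness to the
things real data add — linkage between sites, non-equilibrium
demography shaping the site-frequency spectrum, mapping bias in ASE
reads, correlated eQTLs from LD, sequencing-depth heterogeneity beyond
the AN filter, and motif-context confounding between G-content and
mutability. Those must be addressed by the upstream resources (WASP
filtering, constraint matching, context models), which this package
consumes rather than re-derives.

# Problem sizes in the validation suite

The test suite checks the scanner against its oracle on 1000 random
sequences; MAPS null-centering and monotonicity at $10^5$ variants per
class; O/E interval coverage over 500 neutral replicates (1200
positions, 400 bootstrap draws each) with the point check at $10^4$
positions; LRT size over 1000 null variants; exact-enumeration
agreement on several hundred random tables with totals up to 200; and
planted-enrichment recovery over 100 replicates per test. These sizes
were chosen so each property is measured well inside its sampling
noise while the suite stays desk-scale. `scripts/acceptance.R` runs
the corresponding end-to-end pipeline at the same scale.

# Known limitations

- Only the canonical four-tract motif is scanned: two-quartet, bulged
  and long-loop G4s, and score-based detectors (G4Hunter, cGcC) are out
  of scope, so constraint and enrichment estimates are conservative
  with respect to the full G4 repertoire.
- The motif disambiguation policy is a convention; alternative parses
  of long G-run clusters are defensible and would shift tract-position
  labels at a small minority of loci.
- MAPS power degrades at small variant counts; bootstrap quantiles are
  honest about this, but point estimates at a few hundred variants are
  noisy.
- The heptamer model is consumed, not re-derived; its calibration on
  the population used for the polymorphism table is assumed.
- The chi-square density test's 2-d.f. default is preserved for
  procedural fidelity despite its internal inconsistency; sensitivity
  to `df = 1` should be reported alongside.
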