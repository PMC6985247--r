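# g4utr

Population-genetic and functional analysis of putative G-quadruplex (pG4)
motifs in mRNA untranslated regions.

Guanine-rich RNA can fold into G-quadruplexes: four tracts of stacked
guanines connected by short loops. pG4 motifs are abundant in 5′ and 3′
UTRs, where they can modulate translation, stability and localization —
but most evidence for their importance is anecdotal. `g4utr` provides the
statistical machinery to ask, genome-wide, whether UTR pG4s behave like
functional elements: are they depleted of genetic variation (purifying
selection), enriched for regulatory associations (cis-eQTLs, RNA-binding
protein sites, pathogenic variants), and do pG4-disrupting alleles show
allelic imbalance in expression?

The package is aimed at statistical/population geneticists working with
gnomAD-style variant tables, GTEx-style eQTL and expression tables, and
ENCODE-style CLIP-seq peaks. Every analysis is also exercisable on
synthetic data with known truth, so the inference machinery can be
validated without any external download.

## What it computes

- **Motif discovery** (`scanPG4`, `partitionTracts`, `tractGuanines`,
  `projectToGenome`, `flagCDSOverlap`): canonical pG4 motifs
  `G{3,}([ACGTN]{1,7}G{3,}){3}` in sense-strand UTR sequence, partitioned
  into G-tracts and loops, with trinucleotide tracts labeled 5′G /
  central / 3′G, projected onto genomic coordinates (plus or minus
  strand, spliced UTRs), and filtered against annotated CDS.
- **Isoform architecture** (`classifyIsoforms`, `permuteIsoformLabels`,
  `classifyExpression`): constitutive versus alternative pG4 genes, an
  exact-null permutation test for the alternative:constitutive ratio, and
  per-tissue expression labels under the strict >1 TPM rule.
- **Allele-frequency constraint** (`filterVariants`,
  `matchTranscriptsByLOEUF`, `compareAlleleFrequencies`): gnomAD-style
  quality filtering (RF probability > 0.40, allele number ≥ 80% of the
  maximum, no segdup/LCR/decoy), LOEUF-binned comparator matching, and
  the aggregate AC/AN Fisher test.
- **MAPS** (`calibrateMutability`, `computeMAPS`, `permuteMAPS`): the
  mutability-adjusted proportion of singletons,
  `MAPS = (Σ 1[singleton] − Σ p̂(context)) / n`, where `p̂` comes from
  regressing per-context singleton proportions of synonymous calibration
  variants on trinucleotide mutation rates (methylation-binned at CpG:
  none/low < 0.2, intermediate 0.2–0.6, high > 0.6), with bootstrap
  quantiles and permutation p-values.
- **Heptamer observed/expected model** (`heptamerTable`,
  `expectedSubstitutions`, `oeBootstrap`, `oeEmpiricalNull`): expected
  polymorphic-site counts as the sum of per-position cumulative 7-mer
  substitution probabilities (CpG positions removed), bootstrap 90%
  intervals for O/E, and a one-sided depletion p against an empirical
  null built from 25-nt windows of constraint-matched UTRs.
- **Enrichment statistics** (`eqtlEnrichment`, `eqtlDirectionBias`,
  `clipDensity`, `rbpPG4Enrichment`, `rbpTargetOverlap`,
  `knockdownDEOdds`, `clinvarDensity`): Fisher, chi-square and
  hypergeometric tests with Woolf confidence intervals for eQTL density,
  effect-direction bias in G-tracts, CLIP-site density per kb, per-RBP
  pG4 preference, shared target modules, knockdown DE odds and ClinVar
  variant density.
- **Allelic imbalance** (`fitBetaBinomial`, `lrtNoBias`): beta-binomial
  maximum likelihood for the reference-allele proportion ρ and
  overdispersion φ across heterozygous samples, with a likelihood ratio
  test against the no-bias null ρ = 0.5 (χ², 1 d.f.).
- **Synthetic data** (`simulateTranscriptome`, `simulateVariantClass`,
  `simulateNeutralRegion`, `simulateEQTLs`, `simulateClipPeaks`,
  `simulateKnockdownDE`, `simulateClinvar`, `simulateASECounts`):
  generators with controllable effect sizes and truth tables for every
  stage.

## Worked example

```r
library(g4utr)

m <- scanPG4("ATTCGGGAGGGTTAGGGCAGGGTACCA")
m
#> G4MotifSet with 1 motif(s)
#>   start end n_tracts           sequence
#> 1     4  22        4 GGGAGGGTTAGGGCAGGG
partitionTracts(m)[[1]]$gaps
#>   start end length
#> 1     7   8      1
#> 2    11  14      3
#> 3    17  19      2
head(tractGuanines(m), 3)
#>   motif tract   label offset
#> 1     1     1     5pG      4
#> 2     1     1 central      5
#> 3     1     1     3pG      6
```

One motif spans sequence offsets [4, 22) (0-based half-open): four
G-tracts with loops of 1, 3 and 2 nt. `tractGuanines` names the guanine
most critical for quadruplex stability (`central`) in every
trinucleotide tract — these are the positions at which selective
constraint is strongest.

Allelic imbalance at a synthetic heterozygous variant measured in 84
samples at ~50× coverage, with a true reference-allele fraction of 0.8:

```r
d <- simulateASECounts(n_samples = 84, depth_mean = 50,
                       rho = 0.8, phi = 0.05, seed = 11)
lrtNoBias(d$ref, d$alt, variant_id = "rs_synthetic")
#> ASEFit 'rs_synthetic': rho = 0.7929, dispersion = 0.03597 (84 samples)
#>   LRT vs rho = 0.5: stat = 164.362, p = 1.261e-37
```

The fit recovers ρ near its true value and rejects the balanced null
decisively.

## Vignette

`vignettes/g4utr-methods.Rmd` documents the models, the disambiguation
policy of the motif scanner, the numerical choices (parameterizations,
clamping, tie-breaking), what the synthetic generators do and do not
emulate, and known limitations.
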