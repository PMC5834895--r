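---
title: "Measuring loss-of-function allele prevalence across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring loss-of-function allele prevalence across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the statistic

Selection against loss-of-function (LoF) alleles of essential genes is a
direct window on the strength of purifying selection in a species. Because a
LoF allele of an essential gene behaves approximately like a recessive lethal
with a heterozygous selection coefficient *s* of about 1%, its population
frequency should sit near the deterministic mutation–selection equilibrium

$$ q = u / s, $$

where *u* is the per-gene LoF mutation rate. For *s* ≈ 0.01 this equilibrium
is reached in any population with effective size above roughly 10⁴, so the
prevalence of such alleles is expected to be essentially independent of
drift — and the interesting comparative question becomes whether it varies
with life-history: highly fecund species can in principle afford stronger
selection (they can lose more offspring), but much of their offspring
mortality may be random rather than selective.

`lofprev` measures prevalence per diploid individual as

$$ p = \frac{N_{\mathrm{LoFHet}} + 2\,N_{\mathrm{LoFHom}}}{2N}, $$

where *N* is the number of ORFs fully sequenced in that individual and the
numerator counts gene *alleles* carrying at least one LoF variant
(heterozygous genes contribute one allele, homozygous genes two). LoF means
stopgain, stoploss, or frameshift; missense, synonymous and in-frame indels
are not LoF. The statistic is computed for three nested gene sets:

* **all** predicted ORFs,
* **core** genes — those present in a user-supplied catalogue of essential
  metazoan genes,
* **hard-core** genes — core genes with *no* homozygous LoF allele in any
  individual of any species of the panel (a homozygote anywhere removes the
  gene everywhere: a gene that tolerates homozygous loss somewhere is
  evidently not essential).

Species means of *p* are then rank-correlated (Spearman) with life-history
traits — lifetime fecundity, longevity, adult size, body mass, propagule
size — plus genome size and synonymous diversity πS, with Benjamini–Hochberg
correction over the full grid of tests.

## Pipeline stages and their rules

1. **ORF annotation** (`find_orfs`, `select_longest_orf`). Complete ORFs only:
   ATG to in-frame stop, no internal stop, protein ≥ 100 aa, all six frames.
   When a transcript yields several ORFs the longest is used; ties go to the
   plus strand, then the smallest start coordinate. Codons containing N are
   treated as neither start nor stop. 5′/3′-partial ORFs are deliberately not
   predicted: the length floor and longest-ORF rules are the only stated
   selection criteria, and complete ORFs make every downstream coordinate
   operation exact and reproducible.
2. **Site validity** (`site_thresholds`, `filter_variant_calls`). A call is
   valid with depth **strictly greater than 5×** and variant-calling and
   mapping qualities **strictly over 20**. A site at depth exactly 5 is
   invalid. The `strict20x` preset raises the depth rule to at-least-20×
   (depth > 19) as a robustness mode.
3. **"Fully sequenced"** (`fully_sequenced_orfs`). Read strictly: every CDS
   position must pass the depth floor. These genes form the denominator *N*;
   genes failing it contribute neither to *N* nor to the numerator.
4. **Individual exclusion** (`filter_individuals`). Mean coverage below 10×,
   alignment rate below 80%, fewer than 5000 covered ORFs or fewer than 100
   covered core genes exclude an individual. "Below" excludes, so exact
   boundary values (10.0, 0.80, 5000, 100) are kept.
5. **Species exclusion** (`filter_species`). Alignment rate below 70%, fewer
   than 5000 predicted ORFs or fewer than 100 core genes; haplodiploid
   species are excluded outright because haploid males expose recessive
   alleles to selection and break the diploid HWE accounting.
6. **Consequence calling** (`classify_snv`, `classify_indel`). Codon-aware,
   on the ORF strand. One deliberate edge rule: a substitution inside the
   stop codon that leaves it a stop codon is synonymous, not stopgain.
   Indels are frameshift when |len(ref) − len(alt)| mod 3 ≠ 0, and count as
   coding when at least one edited base (or the insertion point) lies inside
   the CDS. Multi-allelic VCF records are decomposed per alternate allele.
7. **Allele collapsing** (`collapse_gene_alleles`). The counting unit is the
   gene allele: any homozygous LoF variant makes the gene `hom_lof`;
   otherwise any heterozygous one makes it `het_lof`. Several heterozygous
   LoF variants collapse to a *single* het allele because phase is unknown
   from unphased genotypes — a conservative undercount of compound
   heterozygotes.
8. **Per-type statistics.** A gene is classed by the *set* of LoF types it
   carries, so a gene with both a nonsense and a frameshift variant counts in
   both type-specific statistics; the per-gene allele unit is used uniformly
   for all types (the per-variant alternative is computable from the
   annotated variant table, but the gene allele is the primary unit since it
   is the unit of the headline statistic).
9. **NMD window** (`last_n_window`, mode `last100nt`). Only LoF variants in
   the final 100 nt of the CDS (stop codon included) are counted, *N*
   unchanged — a positional proxy for the last exon, which nonsense-mediated
   decay spares.
10. **Correlation** (`spearman_test`, `bh_adjust`, `correlation_matrix`).
    Midrank Spearman ρ with the two-sided t-approximation
    t = ρ√((n−2)/(1−ρ²)) on n − 2 df; |ρ| = 1 gives p = 0. Missing trait
    values are dropped pairwise, never imputed. The BH family is the full
    emitted grid (measure–trait and trait–trait pairs); this matters for the
    adjusted p-values, so both raw and adjusted values are always written.

Missing values propagate as missing: an individual whose restricted gene set
is empty (e.g. no hard-core gene fully sequenced) yields `NA`, never 0, and
`NA` species never enter a correlation.

## The synthetic panel generator

Real inputs for this analysis are hundreds of population-transcriptomic
samples; the generator (`simulation_config`, `build_species_panel`,
`sample_individual_genotypes`) produces panels with the statistical structure
the analysis assumes, so every stage is testable end to end.

Per species *i*, lifetime fecundity is log-uniform on `fecundity_range`
(default 2–10⁶ offspring, the orders-of-magnitude span seen across
metazoans), selection is $s_i = s\,(F_i/F_{\mathrm{ref}})^\beta$ with
$F_{\mathrm{ref}}$ the geometric mean of the range, and every gene sits at
its deterministic equilibrium $q_g = \min(1, u/s_i)$. No drift is simulated —
by design: for s ≈ 1% the equilibrium is drift-insensitive at realistic
population sizes, and a deterministic q makes the expectation of every
downstream statistic available in closed form (`expected_lof_proportion`,
the mean q of a gene set). β = 0 (the default) gives identical expected
prevalence in every species: the statistical null for the trait test.

Defaults: 35 species, 5000 genes, 2 individuals per species (the median
sampling depth of the kind of panel this emulates), u = 2.2×10⁻⁵ per gene and
s = 0.01, hence q = 2.2×10⁻³; coding length 501 nt (167 codons, comfortably
above the 100-aa floor); 20% coverage dropout; mean depth 30×; 30% of
transcripts stored in reverse orientation to exercise minus-strand code
paths.

Genotypes are drawn under Hardy–Weinberg (hom with q², het with 2q(1−q)).
Each carrier gene receives one concrete variant — stopgain : frameshift :
stoploss at weights 0.20 : 0.75 : 0.05, proportional to the observed
relative abundance of the three classes in cross-species data — placed
uniformly in the CDS (stoploss in the stop codon by construction).
Background SNVs (rate 0.01 per gene per individual) exercise the classifier
but are non-LoF by construction, so LoF prevalence is governed entirely by
q and the Hardy–Weinberg draw. Other traits are noisy monotone transforms of
fecundity on the log scale (long-lived, large, heavy species have few
offspring and large propagules; πS rises with fecundity), with genome size
and πS missing for a realistic minority of species.

A single root seed drives everything; per-species and per-individual streams
are derived deterministically, so the same configuration always reproduces
byte-identical FASTA/VCF/TSV output.

### The calibration preset

`calibration_config()` reproduces the *scale* of published cross-species
results from the package's own equilibrium logic. Genes are a two-component
mixture: "constrained" genes at q = 0.0022 (the hard-core equilibrium:
u = 2.2×10⁻⁵, s = 0.01) and a small "relaxed" fraction with q ~ U(0.2, 0.8).
The relaxed fractions are solved so that the expected mean q is 0.0108 over
core genes and 0.0221 over all genes; a per-species lognormal factor
(sdlog 0.6) spreads species means over about an order of magnitude. Relaxed
genes almost surely reveal a homozygote somewhere in a 70-individual panel
and are purged from the hard-core set downstream, so the hard-core mean
lands near 0.0022 *emergently* — the preset encodes per-gene inputs, and the
pipeline's exclusion rule produces the hard-core value.

### What the generator does not emulate

Read-level error, assembly artefacts, isoform mixtures, annotation error
correlated with expression, linked selection, demography, and any dependence
of u on genome features. Passing tests on synthetic panels therefore
validate the *computational* chain — annotation, filtering, counting,
correlation — and the statistical calibration of the trait test; they do not
validate variant calling from reads, which this package deliberately
consumes as input.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere in R structures, matching
  the serialized forms (FASTA header `orf=start-end`, VCF POS) and the
  convention of the R/Bioconductor ecosystem, so no off-by-one translation
  layer exists anywhere in the package.
* **Boundary semantics** are encoded once: "more than"/"over" thresholds are
  strict; "below … excluded" floors are inclusive keeps.
* **Tie-breaks** (equal-length ORFs) are deterministic: + strand, then
  smallest start.
* **Degenerate inputs**: p with N = 0 is `NA`, not 0; Spearman with n < 3 or
  zero variance returns a missing result carrying a reason string.
* **Oracle testing**: the consequence classifier is validated against
  `translation_oracle`, which applies the edit to the raw sequence and
  re-derives the class from protein-level re-translation (substitutions) or
  from mapping the original start/stop coordinates through the edit
  (indels) — an independent computation path. Agreement is exhaustive over
  all 540 single-base edits of a toy ORF and over 10,000 random edits.
* **Replicate counts**: the type-I error of the fecundity test is estimated
  from 20,000 replicate panels (Monte-Carlo SE ≈ 0.16 percentage points);
  the measured size at n = 35 species is ≈ 5.5%, the familiar mild
  anti-conservatism of the t-approximation at moderate n. The parameter
  recovery check runs the full file-based pipeline at 35 × 5000 × 2 and
  compares each gene set's grand mean against its closed-form expectation
  within 3 Monte-Carlo SEs.
* **Exact-permutation p-values** are not used by default; the
  t-approximation matches the common default of statistical environments
  for tied data and is what the correlation contract specifies.

## Known limitations

* Compound heterozygotes are undercounted (phase-unaware collapsing).
* Species-level heterogeneity in the calibration preset is a single
  lognormal scale factor; real panels vary in coverage, assembly quality and
  annotation error in correlated ways.
* The hard-core definition makes the gene set data-dependent: with large q
  and many individuals the set conditions on the absence of homozygotes and
  its realized mean prevalence sits slightly below the unconditional mean q
  of its members; at the default q = 0.0022 the effect is negligible.
* Phylogenetic non-independence is not modelled (no PGLS/independent
  contrasts) — correlations are across species treated as exchangeable, as
  in the analysis this package operationalizes.
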