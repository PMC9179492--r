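---
title: "Sex-linked marker discovery: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-linked marker discovery: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartsex)
```

## The inference problem

In species with homomorphic sex chromosomes the sex-determination system
must be read off genotype–sex association. With a reduced-representation
panel (DArTseq-style SNP and presence/absence markers) scored on a cohort
of phenotypically sexed fish, a Y-linked (or W-linked) restriction-site
tag shows a characteristic pattern: present in every individual of the
heterogametic sex, absent from every individual of the other. Partial
recombination between a marker and the sex-determining locus degrades
that pattern gracefully — a marker at recombination fraction r is carried
by a fraction 1 − r of the heterogametic sex and r of the other.

`dartsex` operationalizes this as a ladder of carrier-frequency
thresholds. For each locus we estimate f_m and f_f, the carrier
frequencies among called males and called females. Under the XX/XY
hypothesis the locus passes threshold t ∈ {0.70, 0.80, 0.90, 1.00} when
f_m ≥ t and f_f ≤ 1 − t; the highest passed threshold is its tier. The
1.00 tier (sex-specific) additionally requires exactly (1.0, 0.0) — a
deliberate discontinuity, because "every male and no female" is the
pattern with a closed-form false-positive probability (below). The ZZ/ZW
scan mirrors the sexes; running both and comparing is how heterogamety is
inferred.

## What counts as "carrying" a SNP marker

A presence/absence marker carries itself. For SNP loci the default rule
is *alternate allele present* (heterozygote or alternate homozygote): a
Y-limited allele can never be homozygous in males, so sex-linked SNPs
appear heterozygous in the heterogametic sex and reference-homozygous in
the other. `het_only` and `alt_hom_only` are selectable for panels coded
the other way around. This choice is not forced by the data format and
is therefore a configuration knob, not a constant.

## Missing data and the low-call gate

All frequencies are computed over called individuals only. A locus
called in a single male could trivially reach f_m = 1.0, so
classification requires at least `min_called_fraction_per_sex` (default
0.8) of each sex to be called. The same gate applies inside every Monte
Carlo subsample. Loci with no called individual of either sex are
flagged uninformative rather than classified.

## Informativeness statistics

- **Cochran–Armitage trend test.** Scores (0, 1) for carrier tables and
  (0, 1, 2) for genotype tables, no continuity correction, p from the
  upper χ²(1) tail. The 2×2 case reduces to N(ad − bc)²/(R₁R₂C₁C₂) and
  attains its maximum, N, at perfect association — a useful sanity
  anchor (75 for the default cohort). The tests cross-check the general
  variant against `stats::prop.trend.test` and the 2×2 case against a
  permutation null; the asymptotic p agrees with the exact permutation
  p up to half the largest atom of the discrete null distribution, which
  is the correct equivalence for a lattice statistic.
- **PIC and heterozygosity.** Both the Botstein PIC
  (1 − Σp² − Σ_{i<j} 2p_i²p_j², bounded by 0.375 for biallelic loci) and
  expected heterozygosity (1 − Σp², bounded by 0.50) are reported,
  labelled explicitly, because published tables often quote "PIC up to
  0.50", which only expected heterozygosity can reach. For dominant PA
  markers the null-allele frequency is estimated as √(freq absent) under
  Hardy–Weinberg — the standard dominant-marker approximation; it biases
  He downward when the population deviates from HWE.
- **Hamming distance.** Proportion of mutually-called loci at which two
  individuals differ; pairs with no mutually-called locus are undefined
  rather than zero. Distance summaries are reported for three strata
  (between sexes, within males, within females) over unordered pairs.
- **Kruskal–Wallis tier comparison** (`tier_comparison()`) asks whether
  locus heterozygosity differs across tiers, with tie correction;
  all-identical groups return H = 0, p = 1 by convention.

## The spurious-linkage model

Under the null, each individual matches a locus's hypothetical sex
pattern with probability 0.5, independently, so a locus sequenced in n
individuals shows the perfect pattern with probability P = 0.5ⁿ, and a
panel of L loci is expected to contain L·0.5ⁿ spurious sex-specific
loci. The default is one-sided (the male pattern); `two_sided = TRUE`
doubles it to cover both sexes. At n = 75, P ≈ 2.65 × 10⁻²³; the tests
validate the model empirically by simulating 10⁶ null loci at n = 10 and
recovering the 2⁻¹⁰ rate inside a 99% binomial interval.

## Monte Carlo subsampling

The reproducibility test draws, per replicate, 10% of the cohort without
replacement, stratified by sex with per-sex ceilings (so 40/35 becomes
4 males + 4 females), reclassifies every locus inside the subsample, and
reports per-locus detection frequencies for the specific tier and for
at-least-linked. Stratification and without-replacement are defaults,
not dogma — unstratified and with-replacement modes exist behind flags,
since the sampling design is not uniquely determined by the phrase "10%
of the sampling population". Replicates are driven by a single mandatory
seed; the stream depends only on the replicate index and sample columns,
never on locus order.

## Genome mapping and the sex-determining region

Chromosome assignment consumes precomputed BLAST tabular hits rather
than running an aligner, so no genome needs to ship with the package.
Hits are filtered strictly (identity > 95, length > 65 bp, as printed in
the protocols this mirrors), and each locus takes its best surviving hit
(max bit score; ties: lower e-value, longer alignment, lexicographic
subject). A locus's point position is the midpoint of its subject
interval, rounded down — symmetric and strand-independent, since no
convention is imposed by the input. The sex-determining-region interval
is simply the [min, max] span of the placed sex-specific loci; its
Mb rendering rounds to one decimal. Membership of other loci in the
region uses closed-interval position containment.

## Repeat composition

The repeat module consumes RepeatMasker `.out` (or a simple TSV) and
rolls subclasses into a declared hierarchy: LTR retrotransposons
(Ty3/Gypsy, Ty1/Copia), non-LTR (LINE), DNA transposons (Helitron,
Polinton, TIR — with Maverick mapped to Polinton and the remaining
DNA/RC superfamilies to TIR), and unclassified. A fragment belongs to a
region iff its midpoint does (the same convention as locus positions),
and percentages divide by the grand total of top-level class fragments —
the only denominator under which class and subclass percentages are
mutually consistent.

## The synthetic cohort: what it does and does not emulate

`simulate_dataset()` generates the study conditions the package assumes:
40 males and 35 females spread round-robin over five populations; 2,000
SNP + 2,000 PA loci by default (a scaled-down panel that keeps the test
suite fast while preserving every structural property; the acceptance
checks that need the full-panel arithmetic use the printed panel sizes
directly); 50 fully sex-specific planted loci plus 50 each at r = 0.1,
0.2, 0.3 (200 planted, spanning the 90/80/70 tiers); planted positions
uniform inside a 26,285,178–31,930,103 bp window on chromosome BSP9;
autosomal PA carrier probabilities uniform on (0.1, 0.9) and SNP allele
frequencies uniform on (0.05, 0.95) under Hardy–Weinberg; 5% missingness
and 1% genotyping error per cell (typical DArTseq post-QC magnitudes).
Error is a symmetric state flip for PA and a move to an adjacent
genotype code for SNP. A `PSD` mode determines sex by a liability score
over unlinked switch loci with configurable weights — a minimal
quantitative stand-in for polygenic sex determination, which no source
specifies numerically.

What the generator does *not* emulate: linkage disequilibrium among
autosomal loci, population structure in allele frequencies (populations
differ only in membership, not in frequency), depth-dependent dropout
(missingness is uniform), and null alleles at PA loci. Passing tests on
this generator therefore demonstrates correctness of the classification
and statistics machinery under the stated generative model — not
robustness to structured real-world artefacts.

## Numerical choices

- Tier comparisons use a 10⁻⁹ tolerance on the threshold inequalities:
  carrier frequencies are ratios of small integers, and 1 − 0.9 is not
  exactly representable in binary. The sex-specific tier is exempt — it
  is an exact equality test against 1 and 0, both representable.
- The trend statistic is flagged undefined (NA) when a margin
  degenerates (all carriers, or one sex absent), never coerced to 0.
- QC thresholds are strict (>) throughout; a locus exactly at a
  threshold fails. The printed reproducibility threshold in the protocol
  family this follows (">3.5") is not interpretable on the 0–1 scale
  DArT reports; the default here is 0.95 on that scale, fully
  configurable.
- Whether QC was applied pooled or per population is unstated in the
  protocols; the default is pooled, with per-population available.
- Best-hit ties are broken deterministically (e-value, length, subject
  id) so assignments never depend on input order.
- All simulation and subsampling randomness flows through a single
  mandatory integer seed; runs are byte-reproducible, and the caller's
  RNG state is restored afterwards.

## Known limitations

- Per-population sex-specific counts need not sum to the pooled count: a
  locus can be specific in one population and merely linked in another.
  The scan reports both scopes and does not attempt a reconciliation
  rule.
- PA markers are dominant, so heterozygosity estimates for them lean on
  HWE; observed heterozygosity is reported for SNP loci only.
- The subsampling test interprets "detection" as tier membership within
  the subsample; with 4 + 4 individuals the specific tier is a demanding
  criterion and detection frequencies are correspondingly conservative.
- The pipeline consumes alignment and repeat annotations; it does not
  validate them biologically (e.g., a hit table against the wrong
  assembly will be summarized without complaint).
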