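---
title: "Methods: phylogenetically informed SV filtering and population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetically informed SV filtering and population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svclades)
```

## The problem

Structural variants (SVs — insertions, deletions and inversions of 50 bp and
up) are hard to genotype from read mapping: repeat-dense regions, imprecise
breakpoints and caller disagreement produce both false-positive loci and
miscalled genotypes at true loci. `svclades` implements an analysis stack for
SV cohorts sampled across two deeply diverged clades — the motivating design
is a songbird genus with a small jackdaw-like clade (8 diploid individuals)
and a larger crow-like clade (24 individuals), separated by roughly 13
million years. At that divergence the proportion of polymorphism shared by
descent is negligible, and under the infinite sites model the same mutation
is not expected to recur independently in both lineages. A variant genotyped
as segregating in *both* clades is therefore most plausibly an artifact, and
that observation can be turned into a genotype-quality filter that needs no
orthogonal validation data.

## The phylogenetic filter

Let the two clades act as reciprocal outgroups. For the clade-A variant set
we require the clade-B outgroup to be homozygous reference, tolerating up to
`tolerance(B)` discordant individuals (default 4 for a 24-individual
outgroup). For the clade-B set we require the clade-A outgroup to be *fixed*
— for either allele — tolerating `tolerance(A)` discordant individuals
(default 2 for 8 individuals). The asymmetry comes from polarization against
the reference assembly: a variant private to the deep outgroup lineage may
legitimately be fixed for either allele there, while the reference-proximal
clade should be uniformly homozygous reference at sites private to the other
clade. The union of the two per-clade sets is the retained call set.

Decisions that were genuinely open, and how they were fixed:

* **Missing calls are not errors.** Outgroup genotypes called `./.` (or
  half-calls such as `./1`, which ingest maps to missing) are excluded from
  the error count rather than counted against the tolerance; counting
  dropout as discordance would conflate two unrelated failure modes. The
  switch `missing_as_error` exposes the alternative.
* **Fixed-outgroup ties resolve to reference.** When the outgroup has
  equally many homozygous-reference and homozygous-alternate calls the
  majority state is taken as 0 — deterministic and conservative toward the
  reference.
* **Tolerances are clade-map fields**, defaulting to 4 (larger clade) and 2
  (smaller clade), so the filter generalizes to other cohort sizes.

The filter deliberately discards genuinely hypermutable loci (e.g. unstable
tandem-repeat arrays at intermediate frequency in both clades): they are
indistinguishable from genotyping error without manual curation, and the
retained set is meant to be conservative.

## Consensus merging and post-calling filters

Multi-caller call sets are merged by single-linkage clustering of start
breakpoints per chromosome (and per SV type by default) with a 1-kb window;
clusters must be supported by a minimum number of distinct callers. Two
presets mirror common configurations: `"sr"` (2 of 3 callers within 1 kb, no
size floor) and `"lr"` (single caller, 50 bp minimum). Single linkage is
transitive, so chains can exceed the window — accepted deliberately to match
the behavior of the standard breakpoint-window merging tools. The cluster
representative is the member with the median SV length (ties: leftmost
position), a choice this package fixes explicitly since merging tools leave
it undocumented. Distance is measured between start coordinates only; an
end-aware metric would change little for insertions and is configurable by
pre-transforming records. Support/length filtering keeps calls with 5–60
supporting reads and at most 100 kb length — excess read support marks
collapsed repeats as reliably as low support marks noise. Low-mapping-quality
masking removes calls overlapping (by ≥ 1 bp; adjacency is not overlap)
regions where low-MQ coverage exceeded a depth threshold, supplied as BED.

## Population-genetic summaries

**Folded AFS.** Per variant, the minor-allele count is `min(k, 2N' - k)` with
`N'` the non-missing diploid count; monomorphic variants enter no bin, so
spectrum mass equals the segregating-variant count — a conservation law the
tests assert. Spectra are computed per repeat class because different repeat
classes have different mutational dynamics: interspersed-element and
unannotated variants behave like low-recurrence mutations (rare-skewed
spectra), while tandem-repeat variants sit at intermediate frequencies.

**Weir–Cockerham F\_ST.** The per-variant estimator is computed from the
two-level variance components *a* (among populations), *b* (among
individuals within populations) and *c* (within individuals), using observed
heterozygosity and unequal sample sizes; θ̂ = a/(a+b+c) may be negative and
is kept as-is, including in percentile ranking. Monomorphic variants are
flagged undefined and excluded from scans. The test suite checks the closed
formulas against an independently coded nested-ANOVA evaluation (mean squares
over allele indicators) to 1e-10 on random small configurations — two
algebraically equivalent but independently implemented routes.

**Outliers and enrichment.** The outlier threshold is the linear-interpolation
quantile (R's type 7, the default of the common analysis stack; the method
must be pinned for reproducibility) of defined θ̂ values, with a strict `>`
cut, so a flat θ̂ distribution yields no outliers. Chromosomal enrichment is
the outlier share over the chromosome's length share of the assembly.

**Window densities** use 1-Mb tiling windows, assigning each record to the
window containing its start; overlapping same-type records are merged first
by default (the "non-overlapping SV" reading), and the flag
`collapse_overlapping = FALSE` gives raw counts.

**PCA** mean-imputes missing dosages per variant, centers, and
eigendecomposes the individual × individual covariance; signs are fixed by
making each component's largest-magnitude score positive.

## LTR insertion dating

The two long terminal repeats of a full-length LTR retrotransposon are
identical when it inserts; each copy then accumulates neutral substitutions
independently. With `k` differences (substitutions plus 1-bp indels) over an
LTR of `L` bp and a neutral rate `mu` per site per million years, the age is
`k / (2 * mu * L)` Myr. Gap runs of ≥ 2 bp are single mutational events of
unknown age and are excluded from both `k` and the effective `L` — the
conservative reading when only 1-bp indels are countable as clock ticks. The
estimate is an upper bound: differences still segregating as SNPs within a
population postdate nothing. The worked default `mu = 0.0158` is a corvid
genome-wide neutral rate; `k = 5, L = 296` dates the motivating insertion to
≈ 0.535 Myr. Input sequences must be pre-aligned (equal length, `-` gaps);
the substitution-only pairs from the simulator are aligned by construction,
and alignment construction is out of scope.

## Association models

Insertion genotypes are decomposed into an additive covariate (copies of the
non-inserted minor allele: 0, 1, 2) and a dominance indicator (heterozygote =
1). Models are ordinary least squares; the parameter count `p` in AIC/AICc/
BIC includes the intercept and the residual variance (this convention must be
fixed for ΔAICc values to be reproducible, and it matches R's `logLik.lm`
degrees of freedom). AICc = AIC + 2p(p+1)/(n−p−1). Model selection uses
ΔAICc ≥ 2; the BIC verdict is reported alongside and may disagree — with its
stronger complexity penalty, a candidate can clear the AICc bar while BIC
still prefers the simpler model. Both fits must be on the same observation
subset (listwise deletion of missing genotypes/phenotypes), enforced by an
equal-n check. For the hybrid-zone style comparison the genotype factors are
fitted as factors with an intercept-only baseline; no further covariates are
assumed.

## The synthetic cohort generator

`simulate_cohort()` produces the study conditions the analysis assumes, with
truth labels for every downstream stage:

* **Design**: 8 + 24 diploid individuals in clades A and B; variant counts
  per run are chosen per analysis (tests use 500–20,000).
* **Private variants** arise in one clade (probability proportional to clade
  size) with minor-allele counts drawn ∝ 1/i over i = 1..N — the neutral
  folded spectrum — for interspersed and unannotated classes; the other
  clade is homozygous reference before error injection.
* **Tandem-repeat loci** draw their frequency from a symmetric Beta(3, 3),
  emulating the intermediate-frequency convergence of hypermutable arrays.
* **Cross-clade false positives** (default 5% of loci) segregate at
  intermediate frequency in both clades (per-clade minor-allele count
  uniform over 35–65% of 2N). This models recurrent artifact/hypermutable
  calls — the kind the filter exists to remove — as opposed to
  fixed-in-both-clades differences, which the filter legitimately retains.
  At the default clade sizes and tolerances the construction guarantees a
  clean filter excludes every injected FP. Half of the FPs are placed within
  5% of a chromosome end (`fp_end_bias`), emulating artifact enrichment in
  repeat-dense subtelomeric regions.
* **Genotyping error** flips each call independently (default 1%) to one of
  the other two dosage states uniformly — the simplest symmetric model, as
  no empirical error profile is assumed; dropout (default 2%) sets calls to
  missing.
* **Lengths** are class-conditional: the LTR class is a Gaussian mixture
  with peaks at 0.9/2.4/6.5 kb over a log-normal background; other classes
  are log-normal; everything is clipped to [51 bp, 100 kb]. The class mix
  defaults to roughly half unannotated, a fifth tandem and a quarter LTR,
  matching the empirical composition of long-read avian SV sets.
* **Determinism**: one integer seed fans out to named substreams (classes,
  lengths, positions, genotypes, errors, missing, repeats), so adding a
  stage never perturbs another stage's draws.

What the generator does **not** emulate: linkage and recombination (variants
are independent), coalescent tree structure within clades, breakpoint
uncertainty in genotypes, reference bias, and sequence-level read evidence.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under the stated model, not robustness to every real
data pathology.

## Problem sizes and numerical choices

Simulation-backed tests run at 10,000–20,000 variants for distributional
checks (spectrum shape, truth recovery) and 200–1,000 replicates for
calibration checks (dating round trip, model-selection power, null p-value
uniformity) — sizes at which 3-standard-error bands are tight enough to be
informative while a full suite run stays in the minutes range on one core.
Quantiles are type 7; ties in repeat assignment break by overlap, then
score, then name; dosage encoding is phase-insensitive; all VCF coordinates
are 1-based inclusive internally, all BED output 0-based half-open.

## Worked example

```{r example, eval = FALSE}
co <- simulate_cohort(sim_params(m_variants = 2000, seed = 1))
pf <- apply_phylo_filter(co$genotypes, co$clades)
pf$counts
afs <- folded_afs(co$genotypes[pf$retained_union,
                               clade_individuals(co$clades, "B")])
fst <- fst_scan(co$genotypes, stats::setNames(co$clades$population,
                                              co$clades$individual))
fst_outliers(fst)$threshold
estimate_insertion_age(k = 5, L = 296, mu = 0.0158)
```

## Known limitations

* The filter cannot separate hypermutable true variants from artifacts; the
  retained set is intentionally conservative.
* F_ST requires at least two non-missing diploids overall per population and
  degenerates (flagged `NA`) when the mean sample size is ≤ 1.
* LTR dating assumes no saturation and equal rates on both copies; ages
  beyond the regime where `2 mu L t` approaches `L` are refused rather than
  corrected.
* The pipeline driver exchanges plain files (VCF/TSV/BED/YAML) between
  stages; very large cohorts would warrant a binary interchange format.
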