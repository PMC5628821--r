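---
title: "Designing a multi-breed SNP array and testing it: methods behind snpwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a multi-breed SNP array and testing it: methods behind snpwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpwave)
```

# Scope and model of the problem

`snpwave` re-implements, as reusable and testable components, the workflow
used to build medium-density genotyping arrays for livestock species with
several breeds of unequal economic weight — the motivating case being a 90K
Axiom array for river water buffalo (*Bubalus bubalis*), designed from
whole-genome sequence of four breeds (Mediterranean, Murrah, Jaffarabadi,
Nili-Ravi) and validated by genotyping river and swamp buffalo, Anoa and
Cape buffalo. The pipeline enters at per-breed multi-sample VCFs: read
alignment and variant calling are upstream tools and out of scope.

The components are:

1. **Variant intake** — discovery filters, per-breed minor allele
   frequencies, a species-corrected reference, 71-mer flank extraction.
2. **Probe design** — per-flank design rules, genome uniqueness by 16-mer
   counting, a deterministic conversion-score surrogate, probeset
   construction and accounting.
3. **Panel selection** — quality waves and the breed-weighted greedy
   gap-filling score.
4. **Genotype QC** — Axiom-style probeset categories, call rates,
   replicate reproducibility.
5. **GRAMMAR GWAS** — kinship matrices, REML polygenic fit, residual scan,
   genomic control.
6. **Synthetic data** — generators that emulate every input with known
   ground truth.

# The synthetic-data generator defines the test conditions

Every downstream claim the package's tests make is relative to what the
generator emulates, so its assumptions matter.

**Breed allele frequencies** follow a Balding–Nichols drift model: an
ancestral alternate-allele frequency $p$ is drawn per site from a Beta
spectrum (default shape $0.6, 0.6$, truncated to $[0.01, 0.99]$), and each
breed draws its frequency from
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, with
mean $p$ and variance $F\,p(1-p)$. One drift parameter per breed is enough
to reproduce the qualitative feature that motivated per-breed MAF handling
in the original design: strongly drifted breeds (the default panel gives
the Jaffarabadi-like breed $F = 0.25$ against $0.08$–$0.12$ for the
others) show a marked excess of low-MAF sites. The default panel holds 73
animals across the four breeds with selection weights 0.30 / 0.30 / 0.20 /
0.20, the discovery-panel conditions the package emulates. The generator
does *not* model linkage disequilibrium, recombination, coalescent
ancestry or sequencing-read error; a passing recovery test therefore says
the estimators are correct under drift + Hardy–Weinberg sampling, not that
they are robust to LD structure in real data.

**Sites** are scattered per chromosome as a Poisson process with a
guaranteed spacing of more than 30 bp between non-planted sites. Three
defect classes are planted deliberately and recorded in a truth slot:
pairs 1–9 bp apart (`cluster_fraction`), strand-ambiguous A/T and G/C
allele pairs (`ambiguous_fraction`), and sites with variant quality in
$(0, 10]$ (`low_quality_fraction`). Because the base spacing exceeds 30
bp while planted partners sit within 9 bp of their anchor, the sites
violating the 10 bp discovery rule are *exactly* the planted pairs, which
is what lets the filter-ledger tests demand exact agreement with the
truth record rather than approximate counts.

**Genotypes** are two independent allele draws per individual
(Hardy–Weinberg at the breed frequency). **Phenotypes** follow the
270-day lactation model used by the association module: mean 2,200 kg
plus fixed farm (4 levels), calving-year (pre/post-2010), season (4),
parity (2) and age-in-months effects, plus a polygenic term drawn with
covariance proportional to the VanRaden genomic relationship matrix of
the simulated genotypes, optional QTL effects, and Gaussian residuals.
The polygenic and residual draws are rescaled so the realized in-sample
ratio of genetic to total non-fixed variance equals the requested $h^2$
exactly; the target phenotypic standard deviation defaults to 400 kg, a
realistic spread for this trait. Pedigrees are generational cohorts with
parents sampled from the previous cohort — structurally valid (acyclic,
parents first) but *not* linked to the genotypes, which is sufficient for
testing the pedigree-matrix algebra and no more.

All generators take mandatory seeds and restore the caller's RNG state;
nothing uses global random state.

# Variant intake

The discovery filters retain a site when its variant quality satisfies
$Q > 10$ (strictly), no other discovered variant lies within 10 bp, and
at least one individual of the breed is heterozygous. Two points were
genuinely open and are resolved as follows:

* **Which variant list drives the spacing filter?** The pooled
  across-breeds list, not the per-breed list. A probe hybridizes against
  the DNA of any genotyped animal, so a neighbouring variant segregating
  only in another breed still interferes; pooling is the conservative
  reading.
* **What does $Q$ refer to?** Site-level QUAL, the quantity a
  UnifiedGenotyper-style caller emits per record; genotype-level qualities
  are not assumed to be present.

Each rejected site gets exactly one reason code with precedence
`quality` > `spacing` > `not_heterozygous`. The precedence is a reporting
choice only — membership in the retained set is unaffected — but fixing it
makes the ledger deterministic and exactly checkable. The accounting
invariant `retained + rejected = input` is tested per breed.

The species-corrected reference substitutes the alternate base wherever
*every* called individual across all breeds is homozygous-alternate; such
positions are fixed differences against the (cross-species) alignment
reference rather than polymorphisms. Substitution never changes sequence
lengths, and the operation is idempotent: on a second pass those positions
already carry the alternate base and are skipped rather than flagged as
mismatches.

Flanks are 71-mers with the target SNP at position 36 — 35 bases each
side. The forward-strand 71-mer and its reverse complement are the two
probe templates ("5′" and "3′" flanks); secondary variants in the window
are recorded as signed offsets, with terminal 5′/3′ flags when an offset
falls in the first or last 25 bases. Internally all coordinates are
1-based (as in VCF); there is no mixed convention anywhere in the package.

# Probe design

Genome uniqueness is operationalized as: every 16-mer of the flank occurs
exactly once in the reference, counting both strands (a palindromic
16-mer is counted once). "Occurs once" rather than "occurs at most some
small number" is the strict reading; since a genuine flank always matches
its own locus, multiplicity 1 is the minimum and any excess indicates
repetitive context.

The proprietary machine-learned conversion score of commercial pipelines
is replaced by a documented deterministic surrogate:

$$p_\text{convert} = 0.95 \cdot e^{-6\,d_{GC}} \cdot
  e^{-0.3\,\max(0,\,r - 5)} \cdot \frac{1}{m} \cdot
  \left(1 - e^{-d_s / 10}\right)$$

with $d_{GC}$ the GC-content deviation from the band $[0.35, 0.55]$, $r$
the longest homopolymer run, $m$ the 16-mer multiplicity, and $d_s$ the
distance (bp) to the nearest secondary polymorphism (the last factor is 1
when there is none). The constants are exposed via
`pconvert_constants()`. The surrogate is *not* a reimplementation of any
trained model; it is a transparent stand-in with the qualitative
properties that matter to the rest of the pipeline — each factor is
monotone in the assay-relevant direction, a clean balanced unique flank
scores 0.95 (comfortably above the 0.6 recommendation floor), and
degraded flanks fall below the 0.56 hard floor — so the two printed
thresholds retain their roles.

Per-flank classification treats each side of the SNP as its own probe
context: a secondary polymorphism within 20 bases *on that side* (or a
non-unique flank) makes the side non-recommended; secondary polymorphisms
only beyond 20 bases make it neutral; a side with no secondary
polymorphism, a unique flank and $p_\text{convert} > 0.6$ is recommended.
Probeset construction then discards flanks below 0.56, takes the
highest-scoring recommended flank when one exists (one probeset), and
otherwise keeps the SNP as a coverage candidate with one probeset per
surviving flank. Candidates whose best flank scores in $[0.56, 0.6)$ are
thus "neutral-only": they can enter only the relaxed waves of the
selection stage, which reconciles the two thresholds' coexistence. The
accounting identity `total probesets = single-flank SNPs + 2 × dual-flank
SNPs` is asserted inside `array_design()` on every call.

A note on an internal tension inherited from the original design: A/T and
G/C SNPs are excluded at intake, yet the wave table contains
dual-oligo tiers. The package keeps `oligo_count` as a candidate
attribute (2 for strand-ambiguous pairs) and lets the wave table address
both cases rather than resolving the contradiction by fiat.

# Panel selection

Candidates are banded into 70 quality waves (shipped both as
`wave_table_90k()` and as an editable YAML in `inst/extdata/`). A wave
prescribes a spacing tier (nearest discovered variant > 30 bp or > 10
bp), an oligo count, floors on the design score (0.8/0.7/0.6) and variant
quality (100/50), and a MAF rule — per-breed floors (> 0.20 / > 0.10 /
> 0.05 / > 0, strict) or "alt allele present in at least $n$ breeds"
($n = 3$, then 2) — with two catch-all waves at the end. All floors are
minima and assignment is first-match-wins, which reproduces the
descending-quality banding.

Within a wave the selector is greedy on the score

$$\text{score}_i = \sum_j w_j \, \mathrm{MAF}_{i,j} \, (B_{i,j} - A_{i,j})
  \left(1 - \frac{\left|\frac{A_{i,j}+B_{i,j}}{2} - P_i\right|}
  {(B_{i,j}-A_{i,j})/2}\right)$$

where $(A_{i,j}, B_{i,j})$ is the current gap of breed $j$ containing
$P_i$, delimited by already-selected loci *polymorphic in breed j* (a
selected locus with $\mathrm{MAF}_j = 0$ is transparent for that breed).
Gaps are initialized to $[0, \text{chromosome length}]$ — the natural
convention; nothing in the formula requires loci at the ends. Breeds with
MAF 0 contribute zero, as do degenerate gaps and boundary candidates.

The engine maintains a per-breed, per-chromosome sorted index of selected
positions. After each selection only candidates whose enclosing gap was
split are rescored; a property test asserts per insertion that no score
ever increases (gap splitting shrinks $B - A$), and the engine is proven
equal, selection-for-selection, to a naive oracle that rescans and
rescores every remaining candidate each round on dozens of random
instances. Ties break by chromosome name then position, making selection
fully deterministic.

Two knobs that the original table's "SNP Used < Total SNP" columns imply
but never specify — a per-wave cap and a score floor — are exposed as
`per_wave_cap` and `min_score`, defaulting to "exhaust each wave until
the target is reached". This is a documented divergence: without the
private candidate data there is no way to recover the exact per-wave
stopping rule, so the package makes it explicit configuration instead.

Gap statistics (min, max and the 1/5/25/50/75/95/99 percentiles of
consecutive inter-SNP distances within chromosomes) use linear
interpolation between order statistics; no percentile method was
prescribed, and this is R's default (`type = 7`).

# Genotype QC

Categories follow the Axiom vocabulary. Rule order on a probeset column:
call rate below the threshold → `CallRateBelowThreshold`; a single,
homozygous genotype class → `MonoHighResolution`; heterozygotes with
exactly one homozygote class → `NoMinorHom`; both homozygote classes with
at least `min_minor_obs` minor-allele carriers → `PolyHighResolution`;
anything else → `Other`. The thresholds (`cr_threshold = 0.97`,
`min_minor_obs = 2`) follow common Axiom practice and are exposed because
no values were printed for them. `VINO` is reserved in the category enum
but never assigned: it requires raw hybridization intensities, which are
out of scope. Replicate reproducibility pools concordant calls over
mutually called probesets across replicate pairs. Because published
validation reports are prone to mixing denominators, `category_report()`
always attaches the denominator its percentages refer to.

# GRAMMAR association pipeline

QC applies the published thresholds verbatim: replicated individuals
(pairwise IBS ≥ 0.99 — the 0.99 being this package's choice of what
"replicated" means operationally), samples with call rate below 10%,
SNPs with call rate below 10% or MAF below 1%. The sample call-rate rule
reads oddly low (90% is the conventional intent) and is therefore
config-exposed rather than hard-coded.

The genomic relationship matrix is VanRaden method 1 with observed
frequencies, $G = ZZ'/(2\sum p(1-p))$, mean-imputing missing calls per
SNP — the construction was unstated, and method 1 is the field default.
The pedigree matrix uses the tabular method with founders unrelated and
non-inbred. Population structure is summarized by classical MDS
(double-centred eigendecomposition) of $1 - \mathrm{IBS}$ distances.

The polygenic model $y = Xb + g + e$, $g \sim N(0, \sigma_a^2 K)$, is
fitted by REML through a single spectral decomposition of $K$ followed by
1-D optimization of $\lambda = \sigma_a^2/\sigma_e^2$ on the profiled
restricted likelihood — exact, fast and deterministic at the scales this
package targets (hundreds of samples), with no iterative convergence
tuning. Fixed effects are the 270-day lactation model: farm, calving-year
class, calving season, parity class, and age in months as a covariate.

The residuals passed to the scan are $y - X\hat b - \hat g$, i.e.
*excluding* the predicted polygenic values, the GRAMMAR convention (the
underlying model equation is silent on this; the whole point of the
two-step procedure is to remove family structure from the phenotype
before the per-SNP regressions). The scan itself is simple linear
regression of residuals on dosage with 1-df Wald chi-square statistics;
the genomic-control factor is $\lambda_{GC} = \mathrm{median}(\chi^2) /
0.4549$, floored at 1 (no deflation correction, the standard convention),
and the significance threshold $p \le 10^{-4}$ is corrected for residual
inflation but deliberately not for multiple testing.

When the kinship is the identity, the two-step residuals are proportional
to ordinary fixed-effect-adjusted residuals, so the scan reduces to
single-step regression — asserted in the tests as a consistency property.
With an estimated polygenic component the GRAMMAR scan is known to be
conservative; the calibration test therefore uses a fully null phenotype
($h^2 = 0$, no QTL), under which $\lambda_{GC} \approx 1$ and p-values
are uniform.

# Numerical and testing choices

* Problem sizes in the test-suite simulations (e.g. null calibration at
  10,000 SNPs × 400 samples; heritability recovery at 5,000 SNPs × 600
  samples × 20 seeds; oracle equivalence on 50 instances of ≤ 200
  candidates) were chosen as the smallest scales at which the targeted
  statistical tolerances are comfortably resolvable.
* Heritability recovery at a true $h^2 = 0.45$ — the genomic-relationship
  value for milk yield that the association module is built around — is
  required to land within ±0.1 of truth on the mean over 20 seeds.
* PSD checks on kinship matrices use a $10^{-8}$ relative tolerance; the
  phenotype simulator adds a $10^{-6}$ ridge before the Cholesky factor.
* Degenerate inputs are contracts, not crashes with stack traces: edge
  loci in flank extraction, missing QUAL records, monomorphic SNPs in the
  scan, empty candidate lists, parents listed after offspring all raise
  named errors or produce flagged/NA results, and each is tested.

# Known limitations

* The conversion-score surrogate shares only monotonicities with trained
  commercial models; absolute probeset counts from real flank data will
  differ.
* No LD in the generator means selection's gap statistics on synthetic
  panels are optimistic relative to real genomes with variant clustering.
* The pedigree generator is structural only; pedigree-vs-genomic
  heritability comparisons on synthetic data test the algebra, not the
  biology of incomplete pedigrees.
* VINO classification and intensity-space QC metrics are out of scope by
  construction.
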