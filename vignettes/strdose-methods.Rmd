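---
title: "STR dosage analysis of quantitative traits: models and methods"
author: "strdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STR dosage analysis of quantitative traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`strdose` analyses short tandem repeat (STR) copy-number dosage as a marker
for quantitative traits in pedigreed populations. This vignette is the
package's account of the science: the models it fits, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical and design choices behind the implementation.

## 1. STR identification

`scan_sequence()` reports every maximal *perfect* run of a tandemly repeated
1–6 bp unit. A run qualifies when it reaches both the per-period minimum
repeat count — 10, 5, 4, 3, 3, 3 for mono- through hexanucleotides — and the
minimum region length of 10 bp. These are the classic MISA defaults for
microsatellite surveys; the mononucleotide minimum of 10 repeats is the 10 bp
region rule expressed in repeat units. Three semantics matter:

* **Perfect repeats only.** No mismatches or interruptions, and no
  compound-SSR merging: each maximal run is an independent locus. The catalog
  is meant as a set of genotyping targets, where a clean, unambiguous repeat
  region is what a short-read STR caller needs.
* **Smallest primitive period.** A poly-A run also matches period 2 as
  "AA"; every run is reported once, at the smallest period whose unit is
  primitive (not itself a repetition of a shorter unit). This avoids double
  counting and matches MISA behaviour.
* **Trailing partial units are trimmed**, so `length_bp = period ×
  n_repeats` always holds. Runs never span an `N`; overlapping maximal runs
  of *different* motifs (e.g. a poly-A shoulder running into an AT repeat)
  are both reported when each passes the thresholds independently, with
  left-greedy start positions. This makes the scanner deterministic and
  checkable against a brute-force enumerator, which the test suite does on
  100 seeded random sequences.

Motif classes are canonicalised by cyclic rotation (`canonical_motif()`),
optionally pooling the reverse complement. Both modes exist because repeat
surveys are inconsistent on this point: dinucleotide classes are often
reported strand-specifically (AT/TA vs AG/GA) while trinucleotide classes
usually merge reverse complements (AAT ≡ ATT ≡ ...). Rather than guess one
intent, the class tables can be produced under either convention;
rotation-only is the default, reverse-complement merging is a flag.

Landscape statistics are straight arithmetic on the catalog: relative
abundance (loci/Mb), density (STR bp/Mb), percent of genome
(= density / 10⁴), unit-size and motif-class proportions. Marker evenness is
measured as the fraction of non-overlapping windows of a given size
containing at least one marker (`window_occupancy()`), and
`region_marker_density()` contrasts marker density inside versus outside a
region set (e.g. SNP density in STR-containing versus STR-free sequence); a
zero-extent side is reported as undefined (`NA`), never as density 0.

## 2. Genotypes: from HipSTR-dialect VCF to dosage

`read_str_vcf()` consumes a VCF whose per-sample fields carry the base-pair
length difference of each allele from the reference (`GB`), the call
posterior (`Q`), read depth (`DP`) and the counts of reads with stutter
artifacts (`DSTUTTER`) or flanking indels (`DFLANKINDEL`). The **relative
copy number** of an allele is its base-pair difference divided by the locus
period; the **dosage** of an individual at a locus is the sum over its two
alleles. A homozygous-reference call has dosage 0, and dosage is symmetric in
allele order.

Call-level QC removes a call when the posterior is below 0.90, more than 15%
of reads have a flank indel, or more than 15% have a stutter artifact.
Removed calls become missing; filtering is idempotent. Base-pair differences
that are not a multiple of the period (partial-unit indels, which read-level
STR callers can emit) are retained as rational copy numbers and flagged per
locus rather than silently dropped, which would bias dosage.

Locus-level filters differ by purpose, deliberately mirroring the two
different downstream uses: association testing keeps loci with a presence
rate strictly above 0.2 (a permissive floor so multiallelic loci with patchy
calling still contribute), while relationship-matrix construction keeps loci
with a missing rate strictly below 0.1 (a GRM wants well-observed loci).
Monomorphic loci are dropped in both cases. All rates use observed calls
only; missing genotypes never contribute zeros.

Marker informativeness is Botstein's polymorphism information content,

$$PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2,$$

with the conventional class boundaries: low < 0.25, medium in [0.25, 0.5],
high > 0.5. Hardy–Weinberg testing on a multiallelic locus defaults to an
exact-style Monte-Carlo test: the observed alleles are shuffled into random
genotype tables (10,000 shuffles by default, seeded) and the p-value is the
fraction of tables whose chi-square discrepancy from the HWE expectations is
at least the observed one. A plain chi-square test on k(k−1)/2 degrees of
freedom is available for speed. The Monte-Carlo p-value is valid but, like
all exact-style tests, conservative when the table is small and nearly
biallelic (ties concentrate probability mass at the observed statistic); on
tables with 3–6 alleles at realistic sample sizes its type-I error sits near
the nominal 5%, which is what the calibration test asserts.

## 3. Relationships: a VanRaden-style GRM for multiallelic dosage

VanRaden's genomic relationship matrix assumes biallelic 0/1/2 codes and the
scale `2Σp(1−p)`. STR dosages are signed and multiallelic, so that scale is
undefined; `vanraden_grm()` generalises it as

$$G = \frac{WW'}{s},\qquad s = \sum_j \mathrm{var}_j,$$

where `W` centres each locus by its mean dosage and `var_j` is the population
variance (divisor n) of the observed dosages at locus j. In the biallelic
case this reduces to VanRaden method 1 up to the sample/population variance
convention, and it keeps the expected diagonal near 1 for any allele system.
Missing dosages are mean-imputed before centring, so they contribute exactly
zero — standard GRM practice that avoids pairwise-complete instability. Two
invariances follow and are tested: adding a constant to any locus's dosages
and globally rescaling dosage both leave G unchanged.

Principal components come from the eigendecomposition of G (scores =
eigenvectors × √eigenvalues, top 5 by default), with a deterministic sign
convention (largest-magnitude loading positive). The PCs feed the GWAS fixed
effects; the package uses STR-GRM PCs because no separate marker set is
assumed to exist.

## 4. The mixed-model association scan

The association model for harvest body weight is

$$y = 1\mu + Xb + Su + Za + e,\qquad a \sim N(0, G\sigma_a^2),\;
  e \sim N(0, I\sigma_e^2),$$

with fixed effects: sex (two-level factor, reference dropped), the top five
PCs, and initial body weight nested in tank (one IBW slope per tank — tanks
may differ in growth regime, so a common slope would be misspecified).

**REML.** After rotating by the eigenvectors of G, the restricted likelihood
profiles down to one dimension in the variance ratio δ = σ²ₐ/σ²ₑ;
`reml_fit()` optimises log δ over [−12, 12] with `stats::optimize()`
(tolerance 1e−8) and compares against the δ → 0 boundary explicitly.
Boundary estimates are returned as converged with a flag, because σ²ₐ = 0 is
a legitimate answer, not a failure. The test suite checks the whole
criterion surface against a dense-matrix grid-search oracle.

**Per-locus testing.** The default is P3D/EMMAX-style: variance components
estimated once under the null, then each locus's dosage appended to the
fixed effects and tested by a GLS Wald test under
V = Gσ̂²ₐ + Iσ̂²ₑ. The GLS covariance is rescaled by the per-locus residual
quadratic form and referred to a t distribution on n − rank([X s]) degrees
of freedom; with G = I this collapses *exactly* to the OLS t-test, a
correspondence the tests assert to 6 decimals. `mode = "exact"` refits REML
per locus instead, the behaviour of a per-marker mixed-model package; P3D is
the default because it is orders of magnitude faster at genome scale and
agrees closely in calibrated settings (also asserted). Individuals missing a
locus's dosage are dropped for that locus only — the dosage is the tested
covariate, so imputing it would dilute the estimand — while the null-model
fit always uses all individuals. Complete loci take a fast rotated path; loci
with missingness use a Cholesky of the V submatrix.

Suggestive loci are exactly those with p < 5×10⁻⁴ — a deliberately lenient
genome-wide screen (no multiple-testing correction is applied, matching the
screening character of the analysis; downstream filters do the tightening).
Per-locus variance explained is

$$PVE = \hat u^2\,\mathrm{Var}(s)/\mathrm{Var}(y),$$

clipped to [0, 1]; the formula is recorded in the scan's metadata attribute
so results are auditable.

## 5. Adjusted phenotypes and the correlation filter

Suggestive associations are screened against an adjusted phenotype from the
pedigree animal model

$$y_{ij} = \mu + Sex_i + \beta_{(Sex_i)}\,IBW_j + a_j + e_{ij},\qquad
  a \sim N(0, A\sigma_a^2),$$

where A is the numerator relationship matrix (tabular method:
`a_ii = 1 + 0.5·a_{sd}`, `a_ij = 0.5(a_{js} + a_{jd})`, unknown parents
contribute 0; equal to twice the kinship matrix, which the tests verify
against an independent recursive oracle). Note the model contains sex and
IBW-within-sex but no tank: the two models are fitted exactly as their
equations state, not harmonised. Variance components are re-estimated by
REML on this pedigree model — the same eigen-profile engine with A in place
of G — rather than copied from the GWAS model, since they are different
models of the same trait.

Henderson's mixed-model equations give b̂ and â with λ = σ²ₑ/σ²ₐ;
individuals in the pedigree without phenotypes still receive breeding values
through their relatives. The adjusted phenotype is y* = â + ê, i.e. the
phenotype stripped of its fixed-effect fit; the identity
y* + Xb̂ = y holds to numerical tolerance and is tested. The correlation
filter keeps loci with |Pearson r| > 0.5 between dosage and y* over
pairwise-complete individuals; the t-transform p-value is reported but does
not enter the filter, because the screen is on effect size, not
significance.

## 6. Expression integration

FPKM is computed as `counts × 10⁹ / (length × library size)`. Differential
expression between high- and low-body-weight groups is a per-gene two-sided
two-sample t-test, Student's equal-variance version by default (the default
of the graphing software commonly used for such panels) with Welch as an
option, on untransformed FPKM by default with a `log2(x+1)` flag — the
field's practice is split on both points, so both are explicit options
rather than silent choices. Genes with zero variance in both groups are
flagged degenerate. STR loci are assigned to genes by interval logic: inside
a gene span, or within a configurable distance (default 25 kb — arbitrary
but declared, in the absence of a field standard) with a strand-aware
upstream/downstream relation. Several genes per locus are allowed, as an
intergenic STR between two nearby genes legitimately annotates to both.
Consequence-level annotation (splice region, intron, UTR) is out of scope;
the inside/near relation is the interval-logic reduction of it.

## 7. The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the pipeline targets: a
pedigreed aquaculture cohort of full-sib families (60 families × 6 genotyped
offspring by default, echoing a design of five-to-six individuals sampled
from each of sixty families), genotyped at multiallelic STR loci
(dinucleotide-dominated period distribution), with sex, tank and
initial-body-weight fixed effects, an additive polygenic background, and a
handful of causal STR dosage effects.

Choices that matter:

* **Polygenic values flow through the pedigree, not the markers.** Founders
  draw a ~ N(0, σ²ₐ); offspring get midparent plus Mendelian-sampling noise
  N(0, σ²ₐ/2). The marker-based GRM is therefore a *genuine estimate* of the
  simulated relatedness rather than an identity. The flip side: because the
  simulated breeding values carry no marker-linked Mendelian-sampling
  signal, within-family GRM deviations are noise with respect to them, and
  G-REML attenuates heritability relative to A-REML. Heritability-recovery
  checks therefore estimate under A (the generative covariance); G-REML
  recovery is verified separately on data simulated directly from a given G.
* **Variance budget.** Defaults: total phenotypic variance 60 g², h² = 0.3
  (so σ²ₐ = 18 g²), causal effects (1.5, 2, 3) g per copy, population mean
  30 g, male sex effect +2 g, per-tank IBW slopes (1.0, 1.4) on IBW of mean
  6.5/5.5 g (female/male), sd 1 g. Causal loci receive a fixed symmetric
  five-allele model (relative copies −2..2 with frequencies
  0.1/0.2/0.4/0.2/0.1, dosage variance 2.4), so the planted effect alone
  determines each locus's variance contribution; σ²ₑ absorbs the remainder
  of the budget, and an infeasible combination errors with the feasible h²
  range instead of silently rescaling.
* **Non-causal allele systems are random**: 2–6 alleles drawn from −3..+3
  with Dirichlet(1.5) frequencies, giving the spread of marker
  informativeness (PIC classes) real STR panels show.
* **Noise is planted, bookkept, and recoverable.** The VCF emitter writes a
  HipSTR-dialect file and plants configurable fractions of low-posterior
  calls, artifact-heavy calls and missing genotypes (defaults 3%/2%/2%/5%);
  the planted set is returned so tests can assert that the call filters
  remove exactly those calls. With all noise at zero the VCF round-trips the
  truth dosage losslessly.
* **Determinism.** The seed fully determines every output; the generator
  saves and restores the caller's RNG state.

What the generator does **not** emulate: linkage (loci are exchangeable and
unlinked, so LD-based confounding and proximal contamination of the GRM are
absent), genotyping error beyond the planted call-level noise model, stutter
*miscalls* (noise flags calls, it never perturbs the allele itself),
selection or multi-generation drift, maternal or dominance effects, and
read-level data. Passing tests on this cohort therefore demonstrate the
statistical machinery under its own assumptions — calibration, recovery,
filter bookkeeping — not robustness to the full messiness of resequencing
data.

`simulate_genome()` plants exact STR loci in rejection-sampled repeat-free
background sequence, fixing one flanking base on each side so a planted run
can neither extend nor phase-shift; scanner recall and precision against the
truth BED are then exactly measurable. `simulate_expression()` draws
negative-binomial counts with planted fold changes for DE power and
calibration checks.

## 8. Pipeline, problem sizes, and reproducibility

`run_pipeline()` chains the stages — VCF parsing, call filters, locus QC,
GRM + PCs, REML GWAS, pedigree BLUP, correlation filter, optional DE and
annotation — with per-stage record counts logged, every stage's table
written as TSV, the resolved configuration saved beside the outputs, and a
machine-readable summary JSON. Re-running a resolved configuration
reproduces byte-identical outputs.

The validation suites run at deliberate desk scale: scanner-oracle
equivalence on 100 random sequences up to ~6 kb; null-GWAS calibration on a
500-individual, 2,000-locus cohort (type-I error at α = 0.05 and genomic
inflation λ at the median); heritability recovery on 250-family cohorts,
averaged over replicates in the acceptance script because a full-sib design
identifies h² only through between-family contrasts; and the end-to-end run
on the default 60 × 6 cohort with 2,000 loci and three planted causal loci,
which must rank all three in the top 1% of p-values and pass the |r| filter
for the large-effect locus. These sizes are the package's own choice of a
thorough-but-quick validation scale; all of them are configurable upward.

## 9. Known limitations

* The scanner targets perfect repeats only; imperfect or compound
  microsatellites are out of scope by design.
* P3D reuses null-model variance components; loci with very large effects
  are tested slightly conservatively (use `mode = "exact"` where that
  matters).
* The Monte-Carlo HWE test is conservative on small nearly-biallelic tables
  (inherent to exact-style tests).
* The GRM mean-imputes missing dosages; at high missingness this shrinks
  relationships toward zero — hence the strict 10% missing-rate filter for
  GRM loci.
* A-matrix construction is dense (fine to a few thousand individuals;
  sparse-inverse methods are out of scope).
* The t-test DE stage is a two-group screen, not a count-model analysis;
  for real RNA-seq a negative-binomial framework is the better tool.
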