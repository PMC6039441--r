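---
title: "Quantifying adaptive protein evolution with hierarchical McDonald-Kreitman models"
author: "mkgamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adaptive protein evolution with hierarchical McDonald-Kreitman models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkgamma)
```

## The problem

Comparative population genomics of eusocial insects asks which genes
experienced adaptive protein evolution, and whether species with similar
social organisation (for example a primitively eusocial paper wasp and a
bumblebee, versus a honey bee) share those genes or the caste context in
which they are expressed. The raw material is a two-species resequencing
design: a focal species with several diploid genomes, a close outgroup
with a couple more, both mapped to the focal reference.

`mkgamma` implements the full desk-side analysis chain for such a
design:

1. **Variant filtering** — GATK-style hard filters, depth and
   missingness limits, homology masks, and a gene-level coverage rule.
2. **Effect annotation** — a purpose-built subset of variant-effect
   prediction (synonymous/non-synonymous and the disqualifying
   stop/start effects), plus the gene- and site-level exclusion rules.
3. **MK tables** — per-gene counts of non-synonymous and synonymous
   polymorphisms (PN, PS) and fixed differences (DN, DS).
4. **Selection inference** — a hierarchical Bayesian Poisson model that
   shrinks per-gene selection effects and maps them to the
   population-scaled selection coefficient $\gamma = 2 N_e s$.
5. **Orthology and caste statistics** — reciprocal-best-hit ortholog
   maps, gene-set overlap enrichment, proportion contrasts and
   ANOVA/Tukey comparisons of $\gamma$ across caste-biased gene
   classes.
6. **Synthetic data** — generators for every input with known ground
   truth, so the whole chain is testable without any external download.

## The model

For gene $i$, the four MK counts are modelled as independent Poisson
variables in a log-linear GLMM:

$$Y_{iRF} \sim \mathrm{Pois}(\mu_{iRF}), \qquad
\log \mu = \beta_0 + b_i + (\beta_R + r_i) R + \beta_F F +
(\beta_{RF} + s_i) R F$$

with indicator $R = 1$ for non-synonymous counts and $F = 1$ for fixed
differences, and independent gene-level random effects
$b_i \sim N(0, \sigma_b^2)$ (mutational target size / diversity),
$r_i \sim N(0, \sigma_r^2)$ (gene-specific non-synonymous opportunity
and constraint) and $s_i \sim N(0, \sigma_s^2)$. The **selection
effect** is $S_i = \beta_{RF} + s_i$: the log-scale excess of
non-synonymous divergence over what the gene's own polymorphism
predicts. Because the interaction contrast cancels $\theta_i$, $z_i$
and the divergence time, no a-priori divergence parameters are needed —
the genome-wide ensemble calibrates everything.

### From effects to selection coefficients

Poisson random field theory links $S$ to $\gamma = 2 N_e s$. Relative
to neutral mutations, mutations with coefficient $\gamma$ fix at rate

$$H(\gamma) = \frac{\gamma}{1 - e^{-\gamma}},$$

and contribute sampled polymorphism in proportion to

$$Q(\gamma, n) = \int_0^1
\frac{1 - e^{-\gamma(1-x)}}{1 - e^{-\gamma}} \cdot
\frac{1 - x^n - (1-x)^n}{x(1-x)}\, dx,$$

where $n$ is the haploid sample size. The identification is
$e^{S} = H(\gamma) / \mathrm{Qratio}(\gamma, n)$ with
$\mathrm{Qratio} = Q(\gamma, n)/Q(0, n)$; the right-hand side is
strictly increasing in $\gamma$, so the equation is inverted by
bisection on $[-100, 100]$ (`gamma_from_effect()`), with $S = 0$
mapping exactly to $\gamma = 0$. Note that $Q$ itself *increases* with
$\gamma$: advantageous alleles transit intermediate and high
frequencies where sampling detects them, while deleterious alleles are
pinned near zero frequency. Selection is still detected because
$H$ grows much faster than $Q$.

Genes with $\gamma > 1$ (strictly) are classified as positively
selected, the conventional reading that selection overcomes drift.

### Estimators

* `estimator = "empirical_bayes"` (default): the GLMM is fitted by
  Laplace approximation with `lme4::glmer()`; $S_i$ is the conditional
  mode $\hat\beta_{RF} + \hat s_i$, and intervals use the normal
  approximation combining the fixed-effect variance with the
  conditional variance of $s_i$. Deterministic and fast (a 500-gene
  genome fits in a few seconds).
* `estimator = "mcmc"`: the same model with Normal$(0, 5^2)$ priors on
  fixed effects and half-Normal$(1)$ priors on the random-effect
  standard deviations, sampled with JAGS. Chains are seeded
  individually, so runs are reproducible draw-for-draw; split-chain
  scale reduction below 1.05 on the shared parameters is reported as
  the `converged` flag. On simulated genomes the two estimators agree
  to correlation > 0.99; the MCMC route adds honest posterior tail
  probabilities at roughly 100x the cost.

Because the PRF link is monotone, posterior quantiles of $S$ map
directly to quantiles of $\gamma$; interval endpoints are transformed
rather than re-sampled.

Genes whose four counts are all zero carry no information about $S$;
they are reported with `no_gamma = TRUE` rather than dropped, mirroring
real analyses where $\gamma$ is computable for only a subset of
annotated genes (roughly 82% in the wasp design this package was
built around).

## Filtering and annotation choices

* **Internal coordinates are 1-based inclusive everywhere**;
  conversions happen only in `read_bed()`/`write_bed()`. This matches
  VCF and GFF3 and keeps off-by-one surface minimal.
* **Hard filters** default to the GATK germline SNV recommendations
  (QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5,
  ReadPosRankSum < -8); a metric absent from a record passes that
  filter. Depth and missingness limits are dataset-level choices:
  defaults are mean depth in $[8, 2 \times \mathrm{median}]$ and at
  most 20% missing genotypes for the larger focal panel, 0% for a
  two-sample outgroup. All values are configuration, echoed into run
  manifests.
* **Filter order is fixed** (hard filters, depth, missingness, mask) so
  every removal has a deterministic reason code.
* **Gene coverage rule**: a CDS base is low-coverage when its mean
  depth across samples is below the lower depth limit; a gene is
  removed when strictly more than 10% of its CDS is low-coverage
  (exactly 10% survives). The mean-across-samples reading is the least
  aggressive; bases absent from the depth table count as uncovered.
* **Effect prediction** substitutes one alternate base into the
  reference codon (strand-aware) under the standard nuclear code with
  ATG starts. Start-codon changes follow SnpEff semantics: a change to
  an alternative initiator codon (GTG/TTG/CTG) is `nonsyn_start`, any
  other change is `start_lost`. Both disqualify the gene, so downstream
  results do not depend on that boundary. Multiple SNVs in one codon
  are evaluated independently against the reference codon — a known
  simplification shared with per-variant annotators.
* **Triallelic rule**: a site's allele set is the bases with at least
  one *called* genotype copy in either species; a declared ALT that is
  never called does not count. Sites with more than two observed
  alleles are discarded as likely error, and — deliberately — they are
  also excluded from the gene-disqualification scan: an allele that is
  distrusted as sequencing error should not remove a gene.
* **Site classification precedence**: segregation in either species
  makes a site a (pooled) polymorphism; a fixed difference requires
  both species monomorphic and unequal; a shared fixed non-reference
  allele is removed. With only biallelic sites surviving, these
  categories partition all variable sites.
* **Absent sites are reference**: both call sets are made against the
  focal reference, so a site present in only one species' VCF is
  treated as homozygous reference in the other. This is what makes
  outgroup-fixed ALT calls readable as fixed differences.

## The synthetic-data generators

`simulate_mk_counts()` draws counts from exactly the PRF rates the
inference inverts:
$PS \sim \mathrm{Pois}(\theta)$,
$PN \sim \mathrm{Pois}(\theta z\, \mathrm{Qratio}(\gamma, n))$,
$DS \sim \mathrm{Pois}(\theta d)$,
$DN \sim \mathrm{Pois}(\theta d z H(\gamma))$.
Defaults mirror the two-species design the package targets: $n = 20$
haploid focal genomes (ten diploids) with a four-haploid outgroup,
opportunity ratio $z = 2.5$ (a typical codon-level non-synonymous to
synonymous opportunity; configurable), $d = 1$, and $\theta_s$
log-normal with median 6 and sdlog 1.2, emulating the spread of CDS
lengths so that a realistic minority of genes is count-sparse.
`simulate_gamma_mixture()` provides the selection regime: a
deleterious/neutral Normal$(-2, 1.5)$ component plus an
Exponential(mean 3) positive component; at weight 0.12 the analytic
share of genes with $\gamma > 1$ is about 10.6%, comparable to
genome-wide estimates in social insects.

`simulate_two_species_vcf()` builds a toy genome with multi-exon genes
on both strands, plants per-gene MK counts site by site, and plants one
exemplar of *every* removal rule (hard-filter failures, depth,
missingness, mask, triallelic, shared-fixed, low-coverage gene, the
four disqualifying effects, the three structural warnings), all
recorded in a manifest. The test suite audits that each planted
violation is removed by exactly the rule that targets it and that the
recovered MK tables equal the planted ones cell for cell, after a full
round trip through the FASTA/GFF3/VCF/BED/TSV readers.

What these generators do *not* emulate: linkage and coalescent noise
(counts are independent Poisson given the truth), base composition,
indels, multiple transcripts per gene, and model mis-specification
beyond a perturbable $z$. Passing tests therefore certify the
*machinery* — classification, counting, shrinkage, calibration — not
robustness to demography or linked selection, which the MK framework
itself only partially addresses.

## Numerical choices

* $H$ uses `expm1` and a first-order series below $|\gamma| < 10^{-8}$;
  $Q$ uses adaptive quadrature (`stats::integrate`, relative tolerance
  $10^{-10}$), cross-checked against a $10^6$-point Riemann sum.
* The effect-to-$\gamma$ inversion brackets on $[-100, 100]$ and
  polishes with `uniroot` to $10^{-12}$; round-tripping
  $\gamma \in [-20, 20]$ reproduces inputs to $10^{-8}$. Posterior
  draws outside the bracket (possible for nearly-empty genes' interval
  endpoints) clamp to the boundary rather than error inside a fit.
* The per-gene maximum-likelihood benchmark profiles $\theta$ out in
  closed form and optimises $\gamma$ by coarse grid plus
  golden-section; it exists to quantify what partial pooling buys on
  sparse genes, and loses to the hierarchical fit by design there.
* Tied bitscores in orthology retain all best subjects; reciprocity
  then decides, and surviving one-to-many pairs are flagged
  `ambiguous`. E-value comparison is inclusive at the threshold.
* Reported percentages round half away from zero to one decimal, the
  display convention of the literature the outputs are compared with.
* The two-proportion contrast defaults to the uncorrected Pearson
  chi-squared; Yates-corrected and Fisher-exact variants are available
  because published values in this literature do not always state
  their convention (and are not always exactly reproducible from their
  printed counts — the package reports all three rather than chase a
  convention).
* The three-way overlap test compares the 8-cell membership
  cross-classification to independence expectations with margins
  estimated from the data, on 4 degrees of freedom; cells with zero
  expectation contribute nothing.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen to keep the full suite in the minutes range
while leaving the statistical checks well-powered: 500-gene genomes for
recovery/specificity (empirical-Bayes estimator), an 80-gene genome for
the MCMC/EB agreement check, a 33-gene fixture for end-to-end
filtering fidelity, exhaustive Fisher verification over all 2x2 tables
with total at most 40, and 1000-replicate calibration runs for the
type-I error of the overlap and ANOVA batteries.

## Known limitations

* Unpolarized MK only: no ancestral-state inference, no
  Jukes-Cantor-style divergence correction, single outgroup.
* One transcript per gene; splice, UTR and indel effects are out of
  scope.
* The empirical-Bayes intervals are normal approximations; for
  publication-grade tail probabilities use the MCMC estimator.
* Pooling polymorphism across both species (the convention here)
  slightly mixes the two species' frequency spectra; a focal-only mode
  is the natural sensitivity analysis and the per-species breakdown is
  retained in the classification logs.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_mk_counts(n_genes = 500, seed = 1)
est <- fit_hierarchical_mk(sim$tables, mk_model_config())
cor(est$gamma, sim$truth$gamma_true, method = "spearman",
    use = "complete.obs")
#> [1] 0.851
mean(est$gamma > 1, na.rm = TRUE)   # share of genes called positive
table(classify_positive(est) %in%
        sim$truth$gene_id[sim$truth$gamma_true > 1])
```
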