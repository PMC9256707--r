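---
title: "Gene-based cross-ancestry polygenic risk scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based cross-ancestry polygenic risk scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Polygenic risk scores built from a single-ancestry discovery GWAS transfer
poorly to other populations: linkage-disequilibrium patterns, allele
frequencies, and marginal effect estimates all differ. When the discovery
cohort for the target ancestry is small, most variants passing a lenient
p-value screen are false positives, and the score drowns in noise.

`geneprs` implements a selection-first strategy built on two premises:
disease-causing genes are largely shared across populations, and the
variants that act on them sit inside (or near) those genes. A variant
nominally associated in **two** discovery GWAS from different ancestries,
with the **same direction of effect**, is far more likely to be causal than
a variant passing the same screen in one study: under the null the double
screen passes only $\alpha^2/2$ of variants (both p-values below $\alpha$,
independent studies, sign agreement a fair coin). Restricting further to
variants inside gene boundaries concentrates the selection on interpretable,
plausibly shared biology.

The pipeline:

1. **Harmonize** two summary-statistics tables to one effect allele.
   Strand-ambiguous variants (A/T, C/G pairs) are removed rather than
   strand-resolved. Variants are matched on (chromosome, position,
   unordered allele pair); when the effect alleles differ, the second
   study's $\beta$ is negated and its allele frequency mirrored.
2. **Select concordant variants**: $p < \alpha$ in both studies (strict
   inequality; default $\alpha = 0.05$) and matching non-zero effect signs.
3. **Partition** the concordant set into *intragenic* (within any gene body
   extended by a boundary window, default 1 kb each side) and *intergenic*
   variants. A window sweep up to 100 Mb shows how the split saturates.
4. **Weight** each variant by fixed-effect inverse-variance meta-analysis
   of the two studies,
   $\beta_{meta} = (\beta_1/se_1^2 + \beta_2/se_2^2)/(1/se_1^2 + 1/se_2^2)$,
   or import externally estimated posterior weights.
5. **Score** target-cohort imputed dosages:
   $PRS_i = \sum_j w_j d_{ij}$ for the gene, intergenic, and all-variant
   sets, then standardize to mean 0 / sd 1 in a reference group.
6. **Test** the association of each standardized score with case status by
   logistic regression (sex, genotype PCs, cohort indicator as covariates;
   a family random intercept where related samples are present), and
   stratify the gene-based score into deciles compared against the bottom
   decile by odds ratio.

```{r}
library(geneprs)
study <- make_study(sim_config(seed = 1))
ev <- evaluate_study(study)
ev$assoc$PRS_gene
```

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | p-value | nominal per-study screen; $\alpha^2/2$ null pass rate |
| `window_bp` | 1000 | bp | boundary extension defining "within a gene" |
| `maf_min` | 0.01 | frequency | post-imputation inclusion floor |
| `info_min` | 0.30 | $R^2$ | imputation-quality floor |
| `missing_max` | 0.05 | rate | per-variant missingness ceiling |
| `hwe_p_min` | 1e-4 | p-value | Hardy-Weinberg QC floor |
| `missing_policy` | mean_impute | — | missing dosage replaced by $2\,\hat p$ (PLINK-style); `skip` drops the variant for that sample |
| `k_pcs` | 10 | count | ancestry covariates when none supplied |

Raw scores are weighted **sums**, not averages over non-missing alleles;
standardization makes the distinction irrelevant for association testing
but keeps the raw numbers bit-compatible with summed PLINK `--score`
output.

## The synthetic generator

Real discovery GWAS and target cohorts for this design are controlled
access, so the package ships a generator (`sim_config()` / `make_study()`)
that emulates the data regime end to end and makes every claim testable
from a seed:

* **Population divergence** — ancestral allele frequencies uniform on
  [0.05, 0.95]; per-population frequencies Balding–Nichols,
  $p_{pop} \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ at $F_{ST} = 0.1$,
  so $E[p_{pop}] = p$ and $\mathrm{Var}[p_{pop}] = F\,p(1-p)$.
* **LD** — haplotype alleles within a block of 8 adjacent variants come
  from a Gaussian copula with latent correlation 0.7, thresholded at each
  variant's frequency; blocks are independent; genotype = two haplotypes.
* **Architecture** — 7.5% of variants are causal, all placed inside gene
  bodies by default (the shared-causal-gene premise in its cleanest form);
  effects on standardized genotypes are
  $N(0, h^2/m_{causal})$ with $h^2 = 0.3$, identical in both populations.
* **Phenotypes** — liability threshold: case iff
  $\sum_j \beta_j \tilde g_{ij} + e_i > \Phi^{-1}(1-K)$ at prevalence
  $K = 0.2$; optional sibships share a family-level Normal component.
* **Discovery GWAS** — two cohorts of 20,000 simulated at the individual
  level and then summarized per variant, so `se`, `eaf` and `p` are
  internally consistent; the target cohort (2,000, drawn from population
  2's frequencies) is written as VCF 4.2 with a `DS` dosage field.
* **Realistic nuisance** — ~10% of variants get strand-ambiguous allele
  pairs and ~30% of the second study's rows (and of VCF records) are
  emitted under swapped allele coding, so the harmonization and
  orientation machinery always has real work to do.

These sizes — 800 variants, 30 genes on a 4 Mb toy chromosome — are the
package's chosen study scale: large enough that the concordant set
contains both tagged intergenic variants and dozens of causal intragenic
ones, small enough that a 20-replicate contrast runs on a laptop.

What the generator does **not** emulate: coalescent LD (block copulas have
no recombination-map structure), admixture tracts, allele-frequency-
dependent architectures, genotyping batch effects, and imputation error
(`info` is emitted as 1). Passing tests therefore demonstrate the
*pipeline's* correctness and the qualitative gene-vs-intergenic contrast,
not calibration against any real cohort.

## Numerical and design choices

* **Discovery association engine.** Two engines produce the per-variant
  summary statistics: `"logistic"` fits each variant's ML logistic
  regression with a vectorized Newton–Raphson (verified against an
  independent `optim` oracle to 1e-6), and `"score"` — the generator's
  default — is the one-step score test ($\hat\beta = U/V$,
  $se = V^{-1/2}$), the standard choice at GWAS scale and numerically
  indistinguishable at the small per-variant effects simulated here.
  Quasi-separated variants run to a glm-style 25-iteration cap and report
  honest (large) standard errors.
* **Concordance uses strict inequality** ($p < \alpha$); a zero effect in
  either study has no direction and is never concordant.
* **Join key** is (chromosome, position, unordered allele pair), so rsID
  mismatches between studies do not lose variants; allele-incompatible
  pairs at a shared position are dropped and reported, never rescued by
  strand flipping. An id-based join is available.
* **Gene windows are symmetric and strand-agnostic by default**: with
  equal upstream/downstream extensions the strand-aware and symmetric
  readings coincide, so the strand only matters for asymmetric windows
  (`upstream_bp != downstream_bp`), which are supported.
* **Boundaries are closed** and coordinates 1-based inclusive internally;
  BED input is converted on read (`start + 1`).
* **A variant under several gene windows** counts toward all those genes
  but is scored exactly once.
* **Fixed-effect (not random-effects) meta-analysis**: the selection step
  targets variants presumed to share one effect across populations, the
  regime where precision weighting is efficient.
* **HWE test** is the 1-df chi-square goodness of fit; an exact test
  (conditional on allele counts) is available via `method = "exact"`.
  Monomorphic variants return p = 1 with a flag.
* **Random effects.** Family structure enters as a logistic random
  intercept (`lme4::glmer`, Laplace). With all-singleton families a
  per-observation Bernoulli random intercept is unidentifiable — Laplace
  leaves a small spurious variance and adaptive quadrature drifts to a
  non-zero mode — so the model deliberately reduces to plain logistic
  regression and flags `random_effect_dropped`.
* **Deciles** are rank-based with ties broken by sample id; group sizes
  differ by at most one, extras going to the lowest deciles; an all-tied
  score vector is flagged degenerate rather than shuffled. Odds ratios
  use Wald 95% intervals; a decile with no cases or no controls is
  flagged unstable, and a degenerate bottom decile is an error.
* **PCA** sign convention: each component's largest-magnitude loading is
  made positive, so repeated runs are bit-identical.
* **Null-calibration runs use unlinked variants** (no LD): the binomial
  interval around $\alpha^2/2$ presumes independent variants; under LD
  the point value is unchanged but the Monte-Carlo variance inflates.

## Known limitations

* Bi-allelic autosomal variants only; no lift-over, no X-chromosome dosage
  conventions, no multi-allelic handling.
* The inverse-variance weights are a transparent stand-in for
  continuous-shrinkage cross-population posteriors; externally estimated
  posterior weights can be imported for bit-compatible scoring, but no
  shrinkage estimation is performed in-package.
* The family model is a single random intercept, not a kinship-matrix
  mixed model; distant relatedness is not modeled.
* Intergenic variants are never assigned to a nearest gene; the partition
  is binary by design.
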