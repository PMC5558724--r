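---
title: "Genomic prediction with a four-component SNP-effect mixture: models, engines and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with a four-component SNP-effect mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybbr)
```

## The model

All three engines in this package fit variants of the linear mixed model

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{Z}\mathbf{g} + \mathbf{W}\mathbf{v} + \mathbf{e},$$

where $\mathbf{y}$ holds one phenotype record per animal (trait deviations
for cows, daughter trait deviations for bulls), $\mathbf{X}$ is a
fixed-effect design (overall mean, breed, sex, optionally the dosages of
named variants fitted as fixed covariates), $\mathbf{Z}$ is the
column-standardized genotype matrix
$Z^s_{ij} = (Z_{ij} - 2p_i)/\sqrt{2p_i(1-p_i)}$, $\mathbf{v}$ is a
pedigree polygenic effect with $\mathbf{v}\sim N(0,\mathbf{A}\sigma_a^2)$,
and $\mathbf{e}\sim N(0, \mathbf{E}\sigma_e^2)$ with $\mathbf{E}$ diagonal.
Each record's entry in $\mathbf{E}$ is the reciprocal of its information
weight: bulls with $d$ daughters get
$w = (1-h^2)/\{ch^2 + (4-h^2)/d\}$ and cows with $r$ records
$w = (1-h^2)/\{ch^2 + [1+(r-1)t]/r - h^2\}$, where $t$ is the
repeatability and $c$ the fraction of additive genetic variance not
captured by the markers. Heritability is the narrow-sense ratio
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_a^2+\sigma_e^2)$. The variance
components are inputs (estimated externally, e.g. by REML); none of the
engines update $\sigma_g^2$ or $\sigma_a^2$.

The defining prior is the four-component normal mixture on each SNP
effect:

$$p(g_i \mid \Pr) = \Pr_1 N(0, 0) + \Pr_2 N(0, 10^{-4}\sigma_g^2)
 + \Pr_3 N(0, 10^{-3}\sigma_g^2) + \Pr_4 N(0, 10^{-2}\sigma_g^2),$$

with $\Pr \sim \text{Dirichlet}(\alpha)$, $\alpha = (1,1,1,1)$. The class
variance scalings are fixed for the whole run; only the proportions are
learned. The spike ($k=1$) means a variant can be excluded from the model
entirely, which is what gives the mixture its QTL-mapping interpretation:
$P(i,4)$, the posterior probability that variant $i$ sits in the
largest-variance class, is the mapping signal.

## The three engines

**GBLUP** (`solve_mme`) replaces $\mathbf{Zg}$ by an animal-level genetic
value $\mathbf{u}\sim N(0,\mathbf{G}\sigma_g^2)$ with
$\mathbf{G} = Z^sZ^{s\prime}/m$ and solves Henderson's mixed-model
equations by direct factorization, which also yields the prediction error
variance (PEV) blocks needed elsewhere. Validation animals are predicted
by the conditional mean $\mathbf{G}_{vr}\mathbf{G}_{rr}^{-1}\hat{u}$.
Direct solves are the right tool up to a few tens of thousands of animals,
which covers the reference-population sizes this model family targets.

**Full MCMC** (`run_gibbs`) is the reference implementation of the
mixture model: per sweep it updates $\boldsymbol\beta$ (weighted least
squares on the partial residual; the prior is uninformative), every SNP in
input order (class indicator from its four-term full conditional with the
effect integrated out, then the effect from its conjugate normal),
$\Pr$ from Dirichlet$(\alpha + \text{counts})$, $\mathbf{v}$ from its
multivariate-normal full conditional, and $\sigma_e^2$ from a scaled
inverse chi-square with a flat prior ($\nu_0 = -2$, $S_0 = 0$). The
default layout is five chains of 40,000 iterations with the first half
discarded; chains are seeded `seed + chain - 1` and averaged. Residuals
are maintained incrementally and re-derived from scratch every 512
iterations; a drift beyond $10^{-6}$ triggers a warning (none is expected,
and the test suite asserts none occurs).

**Hybrid** (`run_hybrid`) runs expectation-maximization to convergence and
then a short warm-started chain. The EM stage initializes every effect at
0.01 and $\Pr = \{0.5, 0.487, 0.01, 0.003\}$, iterates
[$\boldsymbol\beta$, all SNPs, $\Pr$ (Dirichlet-MAP), $\mathbf{v}$ (BLUP),
$\mathbf{u}$ refresh, $\sigma_e^2$] and stops when
$(\hat g^q - \hat g^{q-1})'(\hat g^q - \hat g^{q-1}) / \hat g^{q\prime}\hat g^q < 10^{-10}$
(strictly; the boundary case is *not* converged). The MCMC stage starts
from the EM state, runs 4000 iterations (1000 burn-in by default), and
applies the speed-up rule: after iteration 500, any SNP whose running
spike probability exceeds 0.90 is frozen at zero and skipped thereafter.
Frozen SNPs count as spike members in every subsequent sample, which the
suite asserts exactly.

## The PEV correction: which algebraic form

During EM, the genetic-value term $\mathbf{u}$ absorbs signal that the
current $\mathbf{g}$ has not yet captured; it is refreshed once per
iteration by a GBLUP solve on the current residual signal (one
eigendecomposition at startup makes each refresh $O(n^2)$). Because
$\hat{\mathbf{u}}$ is itself uncertain, the per-SNP statistic
$r_i = Z_i'E^{-1}(\mathbf{e} + Z_i g_i)$ carries extra noise
$Z_i'E^{-1}(\mathbf{u}-\hat{\mathbf{u}})$, whose variance is exactly

$$\mathrm{pev}_i = \mathrm{tr}(E^{-1}Z_iZ_i'E^{-1}\,\mathrm{PEV}_u)
  = (E^{-1}Z_i)'\,\mathrm{PEV}_u\,(E^{-1}Z_i),$$

computed once before the iterations from the startup GBLUP's inverse
coefficient matrix. Two algebraic placements of this term are conceivable:
inflating the per-SNP *information* ($l_i \mapsto l_i +
\mathrm{pev}_i/\sigma_e^2$) or inflating the *noise variance* of $r_i$
($l_i\sigma_e^2 \mapsto \tau_i = l_i\sigma_e^2 + \mathrm{pev}_i$). This
package uses the variance-inflation form: it is the exact distributional
statement above, and in our experiments the information-inflation form
drives every responsibility onto the spike, after which the Dirichlet-MAP
proportions hit the degenerate corner $(1,0,0,0)$ and no class can
recover. Under variance inflation the class marginals become
$r_i \sim N(0, l_i^2\sigma_k^2 + \tau_i)$ and the M-step posterior mean
$\hat g_{ik} = r_i l_i/(l_i^2 + \tau_i/\sigma_k^2)$, which reduce to the
usual conjugate forms when $\mathrm{pev}_i = 0$. As a second guard against
the absorbing corner, the EM proportions are floored at $10^{-8}$ and
renormalized.

With the correction enabled the EM trades a little per-iteration progress
for robustness to the uncertainty in $\mathbf{u}$, and the alternation
between $\mathbf{g}$ and $\mathbf{u}$ can walk a flat ridge on small
datasets; convergence to $10^{-10}$ then takes a few hundred to a few
thousand cheap $O(nm)$ iterations. `pev_correction = FALSE` gives the
plain marker-model EM, which is also the configuration in which the
theoretical guarantees below are exact.

## The EM objective

A posterior-mean M-step does not climb the point-estimate log posterior,
and with a point mass in the prior no such objective is even well defined
off the spike. What the sweep does ascend - exactly, when
`pev_correction = FALSE` - is the variational free energy: the expected
complete-data log joint posterior under the per-SNP class/effect
posteriors, plus their entropy. Each sub-step is a coordinate ascent step
for this functional: the SNP update computes the exact conditional
posterior of $(g_i, b_i)$ given the other SNPs at their posterior means;
the Dirichlet-MAP update maximizes it over $\Pr$; the $\mathbf{v}$ update
is the conditional mode; and the $\sigma_e^2$ M-step maximizes it too,
*provided* the expected weighted sum of squares includes the per-SNP
posterior-variance term: $\hat\sigma_e^2 = (\mathbf{e}'E^{-1}\mathbf{e} +
\sum_i l_i \mathrm{Var}_q(g_i))/n$. This variance-corrected update is what
the package implements (a plain residual-sum-of-squares update differs
only by that non-negative term and coincides at convergence, but can
break monotonicity). `run_em` monitors the free energy every iteration
and records any decrease larger than $10^{-6}$; the suite asserts zero
violations in the exact configuration. With the PEV correction active the
E-step is deliberately tempered and the monitored objective is no longer
exactly the ascended functional; occasional transient decreases of order
$10^{-4}$ are possible and are reported in `monotone_violations` rather
than hidden.

## What the simulator emulates

`sim_dataset` generates the study conditions the inference engines are
validated under, mirroring a multi-breed dairy reference population at
desk scale:

* **Genotypes.** Haplotypes follow a latent Gaussian first-order Markov
  chain along each chromosome: allele frequencies are preserved exactly
  (the latent threshold is `qnorm(p)`) while the `ld_rho` parameter sets
  adjacent-variant LD with geometric decay. This is deliberately simple -
  no coalescent history, no breed structure, no imputation error - so a
  "pass" on simulated data says the *inference machinery* works, not that
  real cattle data will behave as cleanly.
* **Effects.** Classes are multinomial in the true proportions (default
  $(0.99, 0.007, 0.002, 0.001)$, the spike-heavy architecture typical of
  production traits); slab effects are normal with the class variances.
  The effect vector is then rescaled so the genic variance equals
  $\sigma_g^2$ exactly - without this, a handful of class-4 draws would
  make the realized heritability swing wildly between replicates. Planted
  QTL are forced into class 4 and scaled to a chosen share of the genic
  variance. `simulate_effects(scale_to = NULL)` gives the raw mixture
  draws (used when testing the per-class variances themselves).
* **Phenotypes.** Animals are bulls with probability `sex_mix`; bull
  daughter counts are $1+\mathrm{Pois}(49)$ and cow record counts
  $1+\mathrm{Pois}(2)$ - round numbers chosen to give bulls the
  several-fold information advantage seen in progeny-tested populations.
  Errors are heteroscedastic, $e_i \sim N(0, \sigma_e^2/w_i)$ with the
  bull/cow weights above ($t = 0.5$, $c = 0.1$ by default; $c$ is not
  pinned down by the source material, and 0.1 is a conventional value).
  $\sigma_e^2$ is calibrated against the realized genic variance and the
  mean error multiplier $\overline{1/w}$ so the *expected* realized
  heritability equals the target; the suite checks realized $h^2$ within
  $\pm 0.03$ over 20 replicates at $n = 2000$.

The default scenario is `n = 2000`, `m = 5000`, `h2 = 0.4`. One caveat
worth knowing: the identifiability of the spike against the
$10^{-4}\sigma_g^2$ class grows with $n\,\sigma_g^2/\sigma_e^2$, so at
desk scale the posterior happily splits null variants between classes 1
and 2 and the exclusion rule rarely fires at threshold 0.90 - exactly as
it should, since those two classes are then observationally equivalent.
The exclusion-contract study therefore uses a high-heritability bull-only
design ($n = 2000$, $m = 1500$, $h^2 = 0.9$) where the spike is
identifiable and the rule fires for ~98% of null variants.

## Problem sizes used by the validation suite

The packaged studies run the full method stack at sizes chosen so the
whole suite stays comfortably interactive on a single core; the
statistical contracts are unchanged by the scaling:

* mixed-model oracle equivalence: 20 random instances, $n \le 50$;
* conjugate-posterior oracle: $10^5$ single-SNP draws;
* EM/ridge fixed point: $n = 100$, $m = 200$;
* EM monotonicity: 10 datasets at $n = 200$, $m = 250$;
* hybrid vs full BayesR: $n = 800$ (150 held out), $m = 2000$; the full
  chain runs 15,000 iterations (7,500 burn-in), the hybrid its standard
  4000, with GEBV correlation required $\ge 0.98$ and validation-accuracy
  difference $\le 0.02$;
* sparse-architecture comparison: 10 replicates at $n = 1000$,
  $m = 1500$, 10 QTL carrying half the genic variance;
* QTL detection: 20 replicates at $n = 1000$, $m = 1000$, one QTL with
  10% of the genic variance, `ld_rho = 0.5`, hit = planted variant or an
  $r^2 > 0.8$ proxy in the top 10 by $P(i,4)$;
* simulator calibration: 20 replicates at $n = 2000$, $m = 1000$.

## Numerical choices

* $\mathbf{G}$ is $Z^sZ^{s\prime}/m$ (dividing by the variant count gives
  a mean diagonal near 1) with a $10^{-6}$ ridge so inversion inside the
  mixed-model equations is safe.
* Missing dosages are mean-imputed to $2p_i$, contributing exactly zero
  after centring; monomorphic variants are flagged and excluded from
  standardization.
* All class likelihoods are computed in log space with max-subtraction.
* The polygenic full conditional is sampled through a whitening transform
  computed once per run (a generalized eigendecomposition of $A^{-1}$ in
  the metric of $E^{-1}$), making every draw $O(n^2)$ even though
  $\sigma_e^2$ changes between iterations.
* SNPs are updated in input order each sweep; the posterior is invariant
  to the order (asserted up to Monte-Carlo error), so no permutation is
  applied.
* Tie-breaks in the QTL report: variants are sorted by $P(i,4)$
  descending, then chromosome, then position; ties at the threshold are
  all reported, so the report can exceed the count-matched size by the
  tie count.

## Known limitations

* Biallelic dosages only; no X-dosage compensation, no multi-allelic
  variants, no genotype imputation.
* One record per animal (trait deviations are already aggregates); the
  incidence matrices are identities internally.
* $\sigma_g^2$ and $\sigma_a^2$ are never updated in the chain - the
  variant of the sampler that re-estimates the genetic variance is a
  different method and out of scope.
* The exclusion threshold is global and fixed; trait-adaptive thresholds
  are not provided.
* The mixture's class-1/class-2 split is weakly identified in small
  samples; posterior proportions (and hence `architecture_summary`)
  should be read with that in mind. The same goes for recovery of a very
  sparse true architecture at desk scale: with a handful of true
  large-effect variants among a few thousand, the symmetric Dirichlet
  prior diffuses membership mass into the nonzero classes, and the
  class-4 percentage over-reports the truth severalfold. This is a
  property of the posterior itself, not of the hybrid shortcut - the
  full-length chain reports the same percentages to three decimals on
  identical data (e.g. 0.655 vs 0.647 at $n = 2000$, $m = 5000$) - and it
  fades as $m$ grows toward the million-variant scale the model is meant
  for, where the aggregate-variance constraint pins the proportions.

## A worked micro-example

```{r example, eval = FALSE}
sim <- sim_dataset(n = 600, m = 1500, h2 = 0.4, n_val = 100, seed = 42)
ref <- sim$ref; val <- sim$val
fit <- hybbr(sim$y[ref], sim$Zs[ref, ], method = "hybrid", vc = sim$vc,
             X = sim$X[ref, , drop = FALSE],
             weights = 1 / sim$E_diag[ref], seed = 1)
summary(fit)
accuracy_bias(predict(fit, sim$Zs[val, ]), sim$y[val])
plot(fit)   # Manhattan-style P(i,4) with the count-matched threshold
```
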