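---
title: "Discovering weak genetic associations by conditioning on known ones"
author: "cslmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering weak genetic associations by conditioning on known ones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cslmm)
```

## The model

`cslmm` fits a constrained sparse multi-locus linear mixed model (CS-LMM)
for genotype–phenotype association.  Writing $\mathbf{y}$ for the
phenotype of $n$ individuals and $\mathbf{X}$ for their $n \times p$
minor-allele dosage matrix,

$$
\mathbf{y} = \mathbf{X}\beta + \mathbf{Z}\mathbf{u} + \epsilon,
\qquad \mathbf{u} \sim N(0, \mathbf{I}\sigma_u^2),
\qquad \epsilon \sim N(0, \mathbf{I}\sigma_\epsilon^2),
$$

subject to $\|\beta\|_1 \le c$, $|\beta_i| > 0$ for every variant $i$ in a
*known set* $\mathcal{K}$, and $|\beta_j| < |\beta_i|$ for every candidate
$j \notin \mathcal{K}$.  $\mathbf{Z}\mathbf{u}$ is a random polygenic
effect whose covariance $\mathbf{Z}\mathbf{Z}'\sigma_u^2$ absorbs
population structure, family structure and cryptic relatedness.  The
constraints encode the working assumption: a handful of variants with
large, replicated effects are *already known*, and what remains to be
found are variants whose coefficients are strictly smaller — signals that
single-marker tests and unconditioned sparse regressions tend to miss
because the strong effects and confounding dominate.

Estimation is a three-step algorithm.

**Step I — known effects.**  The known variants are fitted jointly by
ordinary least squares with an intercept, and the phenotype is
residualized: $\mathbf{y}' = \mathbf{y} - \sum_{i \in \mathcal{K}}
\mathbf{X}^i \hat\beta_i$.  Although the per-coefficient notation of the
model suggests marginal fits, the residual sum of squares couples the
coefficients, so a joint fit is the consistent reading; the intercept is
required because dosages are not centered.  A rank-deficient known block
(collinear variants) is an error that names the offending variants.
Case/control phenotypes are used as 0/1 numeric responses with the same
linear machinery — the identity link deliberately, since a logistic
variant changes what the rotation in Step II whitens and degrades the
procedure.

**Step II — variance components and whitening.**  With the genomic
relationship matrix (GRM) $\mathbf{K} = \mathbf{W}\mathbf{W}'/p$ computed
from column-standardized dosages $\mathbf{W}$ and its eigendecomposition
$\mathbf{K} = \mathbf{V}\,\mathrm{diag}(\Gamma)\,\mathbf{V}'$, the
likelihood of $\mathbf{y}' - \bar{\mathbf{y}'} \sim
N(0, \sigma_u^2 \mathbf{K} + \sigma_\epsilon^2 \mathbf{I})$ is maximized
through the ratio $\delta = \sigma_\epsilon^2/\sigma_u^2$: for fixed
$\delta$ the genetic variance has the closed form $\hat\sigma_u^2 =
\frac1m \sum_i r_i^2/(\gamma_i + \delta)$ with $r = \mathbf{V}'(\mathbf{y}'
- \bar{\mathbf{y}'})$, so the problem is a one-dimensional search.  Both
data blocks are then rotated by
$(\mathrm{diag}(\Gamma) + \delta\mathbf{I})^{-1/2}\mathbf{V}'$, which maps
the mixed-model covariance to $\sigma_u^2\mathbf{I}$ exactly when $\delta$
equals the variance ratio — after rotation, ordinary sparse-regression
machinery is valid.

**Step III — weak effects.**  The ordering constraint is relaxed to an L1
penalty and

$$
\hat\beta = \arg\min_\beta \;\|\tilde{\mathbf{y}}' -
\tilde{\mathbf{X}}\beta\|_2^2 + \lambda\|\beta\|_1
$$

is solved over the candidate (non-known) variants by proximal gradient
descent.  Users ask either for a penalty $\lambda$ or for a support size
$K$; the latter triggers a search over $\lambda$ (below).  Step III is
wrapped in stability selection: 100 random half-subsamples, rerunning the
whole support-size search on each, keeping candidates selected in strictly
more than 75% of runs, and reporting coefficients from a single full-data
refit.  The original hard constraint $|\beta_j| < \min_i |\beta_i|$ is
*checked* on the result and violations are reported with a warning — it is
never enforced by projection, because the relaxation is the model actually
fitted and silently projecting would misrepresent it.

## Numerical choices

**Objective scaling.**  The squared loss is unscaled (no $1/2n$), so
$\lambda_{\max} = 2\|\tilde{\mathbf{X}}'\tilde{\mathbf{y}}'\|_\infty$ is
the smallest all-zero penalty and the KKT conditions read
$|2\tilde{\mathbf{x}}_j'(\tilde{\mathbf{y}}' - \tilde{\mathbf{X}}\beta)| =
\lambda$ on the support.  Users translating penalties from
$\tfrac{1}{2n}$-scaled conventions (e.g. glmnet) should divide by $2n$.

**Proximal gradient descent.**  Step size $1/L$ with
$L = 2\,\lambda_{\max}(\tilde{\mathbf{X}}'\tilde{\mathbf{X}})$ estimated
by 20 power iterations from a deterministic start (inflated 2% so an
underestimate cannot destabilize the iteration); each iteration applies
the gradient step then soft-thresholding at $s\lambda$, giving a provably
non-increasing objective; termination when the relative objective change
drops below `tol` (default `1e-6`) or at `max_iter` (default 1000);
$\beta$ starts at zero for reproducibility.  Inside the penalty search the
solver runs through an active-set wrapper: solve on a working set of
columns, verify the Karush–Kuhn–Tucker conditions on *all* columns, absorb
violators, repeat.  This returns the same minimizer (the final KKT pass
covers every coordinate) at a fraction of the cost when the support is
sparse, which is what makes desk-scale benchmarks with thousands of SNPs
run in seconds.

**Candidate standardization.**  Candidate dosage columns are standardized
to unit variance before rotation, and reported coefficients are rescaled
back to per-allele units.  With a single penalty shared across columns,
raw dosages would make selection scale-dependent: a rare variant
(sd $\approx 0.1$ at MAF 0.01) needs a ten-fold larger coefficient than a
common one to achieve the same loss reduction, so the penalty would
systematically evict exactly the rare, weak variants the method targets.
Unit-variance columns restore an even playing field; this is also the
near-universal Lasso convention.  Monomorphic candidates carry no signal
and are excluded.  Standardization commutes with the rotation, so the
whitening algebra is unchanged.

**The $\delta$ search.**  Profile log-likelihood scanned on a 101-point
grid over $\log_{10}\delta \in [-5, 5]$, then refined by golden-section
search to relative tolerance $10^{-4}$; the result is guarded never to
fall below the best grid point.  Degenerate spectral components — those
with both a (numerically) zero eigenvalue and a zero rotated residual —
are excluded from the likelihood.  One such component always exists:
column standardization makes the GRM annihilate the constant vector, and
mean-centering makes the residual orthogonal to it, so its
$\log(\gamma_i + \delta)$ term would otherwise push the likelihood without
bound as $\delta \to 0$ while carrying no information.  Genuine
rank-deficiency directions with non-zero residual are kept — they are
informative about $\sigma_\epsilon^2$.  Eigenvalues are clamped at zero
and $\gamma_i + \delta$ floored at $10^{-10}$ before inversion.  If all
eigenvalues are equal, $\delta$ is unidentifiable (only the total variance
is), which is reported as a warning with $\delta$ fixed at the grid
midpoint.  ML rather than REML matches the plain Gaussian likelihood of
the model statement.

**GRM normalization.**  The model's $\mathbf{Z}\mathbf{Z}'$ is computed
from standardized dosages and divided by $p$, the dominant GWAS
convention, so that $\Gamma$ has $O(1)$ scale and the fixed
$\log_{10}\delta$ grid is meaningful for any $p$ and MAF spectrum; a
raw-dosage GRM would make $\delta$'s scale drift with the data and
destabilize the one-dimensional search.  The rotation algebra is identical
either way.

**Support-size search.**  The penalty achieving exactly $K$ nonzeros is
found between $\lambda_{\max}$ and $10^{-6}\lambda_{\max}$ (at most 50
fits): first a geometric descent from $\lambda_{\max}$ (ratio 0.7,
warm-starting each fit from the previous solution) until the support
reaches $K$ — this stays in the cheap sparse regime instead of probing
dense solutions — then bisection on $\log\lambda$ of the bracketing
interval.  Because the Lasso path can jump support sizes, exactly $K$ may
be unattainable; the search then returns the fit with the smallest support
above $K$ and warns, so an inquiry for 20 variants can legitimately report
21.  Ties and reproducibility: the known set's Step-I coefficients break
result-table ties by absolute coefficient, then chromosome and position;
mode imputation breaks frequency ties toward the smaller dosage;
subsampling seeds derive from `(seed, run index)` so stability runs are
order-independent and bit-reproducible.

**No cross-validation.**  When neither $K$ nor $\lambda$ is given the tool
stops with an error rather than cross-validating: fixed-support inquiry is
the evaluation convention here precisely because CV-chosen penalties tend
to admit more false positives, and a silent CV default would undermine the
false-positive control the method is for.

## What the simulator emulates

`simulate_gwas()` generates the study conditions the method is designed
for:

* **Population structure** — individuals split evenly across $g = 3$
  populations $\times$ $f = 2$ subpopulations; per-SNP ancestral allele
  frequencies drift along the hierarchy by a two-level Balding–Nichols
  model (population frequencies Beta-distributed around the ancestral
  frequency with variance $F_{st,1}\,\pi(1-\pi)$, $F_{st,1} = 0.05$;
  subpopulation frequencies likewise with $F_{st,2} = 0.01$).  These drift
  values produce GRM structure of the magnitude seen between and within
  continental human populations.  Genotypes are
  $\mathrm{Binomial}(2, \text{subpopulation frequency})$.
* **Two SNP tiers** — 20% of SNPs form tier *v* (ancestral MAF
  $m_v = 0.1$), 80% tier *u* ($m_u = 0.01$ by default): the
  common/strong tier known variants come from, and the rare/weak
  discovery tier.
* **Tiered effects** — of $k = 10$ causal SNPs, 20% are drawn from tier
  *v* with coefficient $e_v c_j$ ($e_v = 50$) and the rest from tier *u*
  with $e_u c_j$ ($e_u = 25$ by default), $c_j \sim U(0,1)$; the tier-*v*
  causal SNPs play the "known" role in benchmarks, mirroring the fact that
  catalogued associations have higher MAFs and larger coefficients than
  what remains to be found.
* **Heritability control** — the trait is $\mathbf{y} =
  \mathbf{X}\beta + \epsilon$ with the noise variance set to
  $\mathrm{var}(\mathbf{X}\beta)(1 - h^2)/h^2$, so the realized
  heritability targets $h^2$ exactly in expectation (a fixed unit noise
  variance cannot sweep heritability; scaling the noise is the
  self-consistent way to do it).  A binary trait is obtained by
  standardizing the continuous one and sampling
  $\mathrm{Bernoulli}(\mathrm{logit}^{-1}(z))$.

Default sizes are desk-scale ($n = 500$, $p = 5000$) so that the full
benchmark — simulate, fit all methods, score — runs in minutes on one CPU;
genome-scale $p$ is a parameter, not a different code path.  The simulator
does **not** model linkage disequilibrium, recombination maps,
ascertainment sampling of cases, genotyping error, or realistic
minor-allele-count floors; passing tests therefore demonstrate correct
behaviour under idealized drift-structured independence, not performance
on real cohort data, where LD both helps (tagging) and hurts
(multiplicity of correlated hits).

## Evaluation protocol

Benchmarks follow a select-exactly-$K$ protocol: each method must name
exactly $k$ variants, and scoring first removes the known set from both
the selection and the truth, so precision and recall measure discovery of
the *weak* causal SNPs only.  CS-LMM receives the tier-*v* causal SNPs as
its known set and therefore asks Step III for $k - |\mathcal{K}|$
variants, keeping the total at $k$; the baselines (plain Lasso on
standardized dosages, Wald+BH taking the $k$ smallest p-values) receive no
prior.  Precision–recall curves rank candidates by stability frequency
with absolute coefficient as tie-break, and auROC uses the rank-sum
(Mann–Whitney) formulation with mean ranks for ties.  Per-replicate
metrics are summarized by medians rather than pooling selections across
replicates, which keeps the replicate a meaningful unit of variation.

## Known limitations

* Rotation mixes samples, so stability selection subsamples *rotated*
  rows rather than recomputing the rotation per subsample; recomputing
  would be cleaner statistically but couples every subsample fit to an
  $O(n^3)$ eigendecomposition, and at half-sampling the fitted rotation is
  close to the full-data one.
* The GRM includes the candidate SNPs themselves.  At desk-scale $p$ with
  few, strong causal variants, a noticeable fraction of the genetic signal
  then sits inside the GRM span and whitening attenuates it (proximal
  contamination); the effect shrinks as $p$ grows and is negligible at
  genome scale.  Leave-one-chromosome-out GRMs would remove it and are out
  of scope.
* Known variants are excluded from the Step III design: their effect is
  already removed by residualization, and re-admitting them would let the
  Lasso re-fit part of a strong effect as a spurious "weak" one.
* The linear model is applied to case/control traits as-is; this is
  deliberate (see Step I) but means reported coefficients for binary
  traits are on the linear-probability scale.
* $K$-inquiry and fixed-$\lambda$ are the only penalty policies; there is
  no cross-validation by design.

## Problem sizes used in the test suite

Unit and property tests run on instances from $n = 4$ (format round trips)
to $n = 2000$ (allele-frequency fidelity).  The heavier checks are: the
variance-component recovery study ($n = 200$, 50 replicates, true
$\delta = 1$); stability selection with 5 strong signals among 500
candidates over 100 subsample runs; simulator fidelity at $n = 500$,
$p = 2000$ over 20 replicates; and the benchmark ordering study at
$n = 500$, $p = 5000$, $k = 10$, $m_u = 0.01$, $e_u = 25$, ten simulation
replicates at each of $h^2 \in \{0.3, 0.5\}$, where the median recall of
CS-LMM over the eight weak causal SNPs is compared against the plain-Lasso
and Wald+BH baselines.  These sizes keep the whole suite under a few
minutes on a single CPU while leaving each check statistically meaningful.
```{r session}
sessionInfo()
```
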