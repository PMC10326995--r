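---
title: "Interaction QTL mapping, direction, sharing and mediated moderation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction QTL methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

For every cis phenotype–variant pair, iqtlkit fits ordinary least squares

$$Y = \beta_0 + \beta_G G + \beta_E E + \beta_{G\times E}\, G E + \gamma' C + \varepsilon,$$

with $Y$ a molecular phenotype (expression or methylation), $G$ the allelic
dosage in $[0,2]$, $E$ the mean-centered interaction variable, and $C$
covariates. Two-sided p-values use the t distribution on the residual
degrees of freedom. Assumptions: complete data after preprocessing (missing
dosages are mean-imputed per variant at load; phenotypes must be complete),
unrelated individuals (no mixed model), and a full-rank design — a
rank-deficient pair (e.g. a constant interaction variable) yields a flagged
record with missing estimates rather than a silent drop.

Three deliberate parameterization choices:

* **Covariates are not residualized out beforehand.** They enter every
  per-pair model directly. Residualizing first is faster but interacts badly
  with the product column (Frisch–Waugh does not carry over to $GE$ when $E$
  is shared across pairs).
* **Only $E$ is centered, never $G$.** With centered $E$, $\beta_G$ is the
  QTL effect at the cohort-mean of $E$. This is what licenses the direction
  rule below: $\beta_G$ and $\beta_{G\times E}$ share a common reference
  point.
* **$p_G$ is taken from the interaction model itself**, not from a separate
  no-interaction fit, so the direction call uses internally consistent
  estimates.

Cis windows are anchor-based and boundary-inclusive: $\pm$1 Mb of a gene's
TSS, $\pm$500 kb of a CpG site. Strand is ignored; the anchor coordinate
(stored 1-based; BED files on disk use the 0-based half-open convention)
fully defines the window.

# Preprocessing conventions

* **Inverse normal transform.** Values map to
  $\Phi^{-1}((r - c)/(n - 2c + 1))$ of their ranks with offset $c = 0.5$
  (Hazen positions, $(r-0.5)/n$), symmetric and finite. Ties are broken by
  Gaussian noise with variance $10^{-16}$ (SD $10^{-8}$) — large enough to
  randomize ties, orders of magnitude below data resolution. The scan does
  *not* transform by default (`transform = "none"`): effect sizes are then
  interpretable on the phenotype's own scale, which the recovery tests rely
  on; pass `transform = "int"` (or `--int` on the CLI) for the
  rank-normalized convention.
* **Outliers.** `exclude_outliers()` masks values more than $k = 3$ sample
  SDs from the mean. Note the rule cannot fire at very small $n$ (with $n$
  points the largest attainable $|z|$ is $(n-1)/\sqrt n$), so it is a
  large-cohort filter by construction. Exclusion happens *before* the
  half-split of the MAF filter; the opposite order is defensible but less
  conservative, and the choice is fixed here for determinism.
* **Interaction-aware MAF filter.** Samples are split into lower/upper
  halves of $E$ by rank (odd $n$: the median sample joins the lower half;
  value ties break by sample order, so the split is deterministic and
  invariant to monotone transforms of $E$). A variant is kept only when its
  MAF exceeds the threshold in *both* halves — 0.05 for cell-type
  interactions, 0.1 for trait interactions — preventing interaction
  estimates driven by a few carriers at one end of $E$. A global MAF > 0.01
  filter runs first.
* **Sentinel collapsing.** Methylation is locally correlated
  (co-methylation decays over roughly 1–2 kb), so per-CpG top records are
  greedily collapsed: take the smallest interaction p, discard every record
  within $\pm$1 kb on the same chromosome, repeat. Ties break by smaller
  position then variant id, making the output independent of input order.

# Hierarchical significance

Per phenotype, the top nominal interaction p-value is corrected by the
effective number of independent tests: variants are partitioned into
consecutive windows of at most 200, each window's dosage correlation matrix
is eigendecomposed, and the window contributes the smallest $k$ whose top
eigenvalues reach 99% of the trace. $p_{\mathrm{adj}} = \min(1,\,
p_{\mathrm{top}} \cdot m_{\mathrm{eff}})$ always lies between the nominal p
and the full Bonferroni bound. Benjamini–Hochberg then runs across
phenotypes (FDR 0.05 for cell-type, 0.25 for trait interactions). The
correlation is Pearson on dosages (standardizing genotypes first would give
the same eigen-structure up to scaling; dosage correlation is the
documented choice). Two-exam designs are combined by keeping, per phenotype
significant in either exam, the record with the smaller interaction p
(ties keep the earlier exam).

# Direction of effect

Continuous $E$ (three categories): $p_G > 0.05$ → *uncertain*; otherwise the
sign of $\beta_G \cdot \beta_{G\times E}$ gives *positive* (QTL effect grows
with $E$) or *negative*. A product of exactly zero — a measure-zero boundary
the two-sided rule does not address — is classed *uncertain*. Binary $E$
(four categories): the genotype effect is refit separately in both groups,
covariates retained (the conservative reading of "fit separately");
*no_effect_in_one*, *magnitude_difference*, *opposite_effect* or
*uncertain* follow from which per-group effects are nominally significant
and whether their signs agree. Recoding the counted allele ($G \to 2-G$)
flips both estimates and never the category.

# Sharing, reproducibility and inflation statistics

* **$\pi_1$**: Storey's fixed-$\lambda$ point estimator
  $\hat\pi_0 = \#\{p > \lambda\}/(n(1-\lambda))$, clamped to $[0,1]$;
  $\pi_1 = 1 - \hat\pi_0$. The replication convention selects $\lambda$ by
  sample size — undefined at $n \le 20$, $\lambda = 0.5$ for
  $20 < n \le 100$, $\lambda = 0.85$ for $n > 100$ (boundaries read
  strictly). The smoother-based $\pi_0$ estimator is intentionally absent.
  Note the $\lambda = 0.85$ estimator's Monte Carlo SD is substantial
  ($\approx 0.03$ at $n = 5000$); tests band it accordingly.
* **Inflation $\lambda$**: median of $\chi^2_1$ statistics obtained from the
  upper-tail transform of the p-values, divided by the null median
  $\chi^2_1(0.5) \approx 0.455$.
* **Normalized overlap**: fraction of query variants tagged by a validation
  variant ($r^2 \ge 0.5$ within 1 Mb, a variant tags itself), with the
  *smaller* of the two set sizes as denominator, capped at 1.
* **Odds ratios**: when any 2×2 cell is zero, 0.5 is added to *all* cells
  (Haldane–Anscombe) before computing $(ad)/(bc)$. The p-value comes from a
  two-sided exact conditional test (`fisher.test`) on the original counts —
  the source analysis reports a p-value without naming the test, and the
  exact conditional test is the documented assumption here.
* **Replication effect metrics**: allelic concordance (sign agreement,
  zeros excluded) and the absolute value of the median replication effect.

# Mediated moderation

The question: is a moderator's effect on the QTL ($G\times W$, e.g.
genotype-by-age) transmitted through a mediator's interaction ($G\times M$,
e.g. genotype-by-neutrophil-proportion)? The moderation path is
$XW \to XM \to Y$, so in mediation terms the "treatment" is the product
$G W$ and the "mediator" the product $G M$:

* mediator model: $GM = \beta_0 + \beta_1 G + \beta_2 W + a\, GW + \beta_4 M + \gamma'C + \varepsilon$
* outcome model: $Y = \beta_0 + \beta_1 G + \beta_2 W + d\, GW + \beta_4 M + b\, GM + \gamma'C + \varepsilon$

with $G$, $W$, $M$ mean-centered. For linear links the simulation-based ACME
coincides with the product of coefficients, so the point estimates are
closed-form: $\mathrm{ACME} = a b$, $\mathrm{ADE} = d$, total $= ab + d$,
proportion mediated $= ab/(ab+d)$ (flagged undefined at total $= 0$;
truncation of out-of-range proportions is available via `prop_truncate` but
off by default, so pathological sign disagreements remain visible). All
inference is a nonparametric bootstrap: whole rows resampled with
replacement (keeping $Y, G, W, M, C$ linked), both models refit per draw
(rank-deficient draws are redrawn, capped at $10\times$ the draw count),
default $k = 1000$ draws. Intervals are BCa: bias term
$z_0 = \Phi^{-1}(\mathrm{frac}(\hat\theta^* < \hat\theta))$ (the fraction
clamped to $[\tfrac{1}{2B}, 1-\tfrac{1}{2B}]$), acceleration from the
jackknife third-moment formula. Two-sided bootstrap p-values are
$2\min(\mathrm{frac} \le 0, \mathrm{frac} \ge 0)$, floored at $1/k$ — the
resolution of the draws. Seeded runs are bit-reproducible.

A practical note on size: the product statistic is degenerate when *both*
paths are null ($a = b = 0$) — its bootstrap test is then strongly
conservative (rejection $\sim \alpha^2$), which is a property of every
product-of-coefficients test, not an implementation artifact. The type-I
simulation in the acceptance suite therefore keeps the untested nuisance
path active ($b \ne 0$, $a = 0$, so ACME is exactly zero), the standard
calibration design under which the nominal 5% level is actually attained.

`screen_gxm_inflation()` implements the enrichment screen that motivates the
mediation analysis: refit every trait-iQTL pair with a cell proportion as
the interaction variable and compare the inflation $\lambda$ of those
p-values between records with a directed (positive/negative) call and the
uncertain group; strong inflation confined to the directed group is the
signature of trait interactions transmitted through cell composition.
Groups under 10 pairs are flagged low-confidence.

# The synthetic cohort

`simulate_dataset()` generates the world the analysis assumes, with known
truth:

* **Genotypes**: two latent Gaussian AR(1) haplotype chains per sample,
  thresholded at each variant's target allele frequency (drawn uniformly
  from `maf_range`, default 0.05–0.5) and summed — biallelic dosages in
  Hardy–Weinberg proportions with LD decaying as `ld_rho^distance`
  (default 0, linkage equilibrium). Note dosage $r^2$ between adjacent
  variants is additionally capped by MAF mismatch, so strong-LD properties
  are stated at matched MAFs.
* **Cell proportions**: a latent multivariate Gaussian (default panel:
  neutrophil 0.55, CD4 0.15, CD8 0.08, B 0.05, NK 0.07, monocyte 0.10;
  neutrophil anti-correlated −0.3 with the lymphoid types) pushed through a
  softmax, so rows sum to one and negative cross-type correlations are
  attainable — a Dirichlet cannot hit arbitrary correlation targets, which
  is why it was not used. Age enters the chosen cell type's latent score
  linearly; because the softmax attenuates latent correlations on the
  proportion scale, the loading is inflated by the delta-method factor
  $\kappa = a_k/\sqrt{a'Ra}$ with $a = p_k(\delta_k - p)$, so the *realized*
  age–proportion correlation hits the target (default 0.14, the reported
  age–neutrophil correlation in late-mid-life blood, over a 45–85 year
  enrollment window).
* **Phenotypes**: $y = \beta_G g + \beta_E e + \beta_{G\times E}\, g e +
  \gamma'C + \varepsilon$ per phenotype, one causal cis variant drawn from
  its disjoint 50-variant block. Effect sizes are defined on the
  *standardized* interaction variable (and the standardized variable is what
  the bundle stores under the scenario's `e_name`): raw blood-cell
  proportions have SDs near 0.05–0.08, on which fixed effect sizes like
  $\beta_{G\times E} = 0.5$ would be physically negligible. Scenarios:
  `null` (no interaction anywhere), `gxcell`, `gxtrait_direct` (explicit
  $g \cdot \mathrm{age}$ term), `gxtrait_mediated` — the interaction is with
  the cell proportion *only*, the proportion correlated with age, so any
  apparent genotype-by-age signal is transmitted entirely through the cell
  type (the package's causal-diagram scenario) — and `binary_e` (a
  Bernoulli(0.3) smoking-like variable).
* **Two exams**: `simulate_two_exams()` keeps genotypes, causal variants and
  effects, ages everyone by 10 years and re-draws proportions and noise —
  the design needed by between-exam reproducibility statistics.

Defaults are desk-scale: 800 samples, 200 phenotypes, 50 cis variants each.
For the mediated scenario the mediator–age correlation defaults to 0.5
rather than 0.14: a mediated interaction signal scales as
$\beta_{G\times M}\cdot \mathrm{cor}(M, W)$, and at $r = 0.14$, $n = 800$
the induced genotype-by-age t-statistic is about
$0.14\,\beta_{G\times M}\sqrt{n\,\mathrm{var}(G)} \approx 2.6$ per unit
effect — undetectable by design; 0.5 makes the scenario's defining signal
discoverable at desk scale while keeping the mechanism identical.

What a green test does **not** establish: the generator has Gaussian noise,
a single causal variant per phenotype, block-wise LD without realistic
haplotype structure, no batch or population-stratification effects, no
bounded methylation (beta-value) noise, and covariates independent of
everything. Results on real cohort data additionally depend on
deconvolution quality, hidden-factor correction and relatedness, none of
which are modeled here.

# Numerical choices and degenerate inputs

* Tie-breaks are deterministic everywhere: top-association (smaller
  position, then variant id), sentinels (smaller position, then variant
  id), exam combination (earlier exam), half-split (sample order).
* `eigenmt_meff` errors on zero-variance variants (they must be filtered
  upstream by the MAF filters); eigenvalues are clipped at zero before the
  cumulative sum.
* Bootstrap p-values cannot be smaller than $1/k$; BCa intervals degenerate
  to $[\hat\theta, \hat\theta]$ when all draws coincide.
* The empty-numerator regime of Storey's estimator (all $p \le \lambda$)
  yields $\pi_1 = 1$ after clamping.
* All TSV output keeps full double precision (15 significant digits);
  readers round-trip at serialized precision.

# Limitations

No trans scanning, no conditional/multi-signal mapping, no mixed-model
relatedness correction, no permutation/beta-approximation empirical
p-values (significance is eigen-correction + BH by design), no PEER/hidden
factor estimation, no reference-based deconvolution — estimated proportions
are an *input*. The eQTL-catalogue-style replication functions operate on
already-harmonized effect vectors; allele flipping against a reference
panel is out of scope.
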