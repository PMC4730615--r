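---
title: "The two-phase nonparametric procedure for non-normal quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-phase nonparametric procedure for non-normal quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A biallelic SNP with minor-allele count $G \in \{0, 1, 2\}$ is tested for
association with a quantitative trait $Y$ whose distribution is far from
normal — skewed, heavy-tailed, or truncated, as survival times, antibody
titers and tumor counts typically are. Linear-model tests lose validity or
power here; rank tests do not. But the *optimal* rank test depends on the
mode of inheritance (the genetic model): a recessive variant shifts only the
$G = 2$ group, a dominant variant shifts $G \in \{1, 2\}$ equally, an
additive variant shifts each copy. The model is almost never known in
advance, and the trend test matched to the wrong model can lose most of its
power.

`tppassoc` implements a two-phase answer: **first classify the genetic model
from the data with a rank statistic, then apply the trend test matched to
the selected model** — at an *adjusted* significance level that accounts for
having used the data twice.

## Win probabilities and their estimators

Everything is built from pairwise win probabilities between genotype groups,
$f_{ab} = \Pr(Y_a < Y_b)$, estimated by the Mann–Whitney functional
$$\hat f_{ab} = \frac{1}{n_a n_b} \sum_{i \in a}\sum_{j \in b} I(y_i < y_j),$$
with $f_{ab} = 1/2$ for all pairs under no association. The plug-in variance
estimator is the two-sample jackknife-style sum
$$\hat\sigma^2_{ab} = \frac{n_b - 1}{n_a^2 n_b}\sum_{i \in a}
  \Big[\bar I_{i\cdot} - \tfrac12\Big]^2
  + \frac{n_a - 1}{n_a n_b^2}\sum_{j \in b}
  \Big[\bar I_{\cdot j} - \tfrac12\Big]^2 + \frac{1}{4 n_a n_b},$$
where $\bar I_{i\cdot}$ is the share of group-$b$ values above $y_i$ and
$\bar I_{\cdot j}$ the share of group-$a$ values below $y_j$. Covariances
between two win probabilities sharing a group average the product of the two
centered shares over the shared group's members (`win_prob_cov()`, three
topologies). The terms are centered at the null value $1/2$ rather than at
the observed means — these are null-calibrated estimators, consistent when
the genotype groups share a common trait distribution, which is exactly the
regime in which they are used (sizing the tests). All six plug-ins are
computed in one $O(n \log n)$ pass per SNP (`win_prob_estimates()`).

Ties: the indicator is strict by default, the right choice for continuous
traits. For traits with point masses (imputed detection limits, heavy
rounding) `ties = "midrank"` scores ties $1/2$; it is off by default because
every calibration result in this package is established under continuous
errors.

## Phase 1: model selection

The selection statistic contrasts the two adjacent win probabilities,
$$Z_1 = \frac{\hat f_{01} - \hat f_{12}}
  {\sqrt{\hat\sigma^2_{01} - 2\hat\sigma^2_{01,12} + \hat\sigma^2_{12}}},$$
asymptotically $N(0,1)$ under the null. Under a dominant alternative
$f_{01} > f_{12}$ so $Z_1$ leans positive; recessive leans negative;
additive keeps $f_{01} = f_{12}$. The rule is: dominant if $Z_1 > \xi$,
recessive if $Z_1 < -\xi$, additive otherwise, with $\xi = \Phi^{-1}(0.90)
\approx 1.2816$ by default (boundary values go to additive). With no
genetic effect the additive model is therefore selected with probability
$2\Phi(\xi) - 1 = 0.80$, which the test suite checks empirically.

## Phase 2: the matched trend test

Each genetic model has its optimal nonparametric trend test, a studentized
combination of win probabilities:

* recessive: $\hat f_R = \frac{n_0 \hat f_{02} + n_1 \hat f_{12}}{n_0 + n_1}$,
  i.e. "groups 0 and 1 pooled against group 2";
* dominant: $\hat f_D = \frac{n_1 \hat f_{01} + n_2 \hat f_{02}}{n_1 + n_2}$,
  "group 0 against groups 1 and 2 pooled";
* additive: $\hat f_A = w_1 \hat f_{01} + w_2 \hat f_{12}$ with
  inverse-standard-deviation weights
  $w_k^\ast = \sqrt{(n_{k-1} + n_k) / [(n + n_1)\,\hat\sigma^2]}$,
  normalized to $w_1 + w_2 = 1$.

Each $Z_x = (\hat f_x - 1/2)/\hat\sigma_x$ is asymptotically standard
normal under the null; the package reports two-sided p-values.

## Size adjustment

Selecting the test with $Z_1$ and then testing with $Z_x$ uses the data
twice: under the null, $(Z_1, Z_x)$ is asymptotically bivariate normal with
correlation $\rho_x$, and testing naively at $\alpha$ would mis-size the
procedure. The overall size constraint
$$\alpha = \sum_{x \in \{R, A, D\}} \Pr_{H_0}\!\big(Z_1 \in \Omega_x,\;
  |Z_x| > z_{1-\alpha^*/2}\big)$$
over the selection regions $\Omega_R = (-\infty, -\xi)$,
$\Omega_A = [-\xi, \xi]$, $\Omega_D = (\xi, \infty)$ becomes, after
conditioning on $Z_1 = u$, a sum of three single integrals against
$d\Phi(u)$ that `adjusted_alpha()` solves for $\alpha^*$.

The correlations are estimated by the delta method: $Z_1$ and each $Z_x$
are linear forms in $(\hat f_{01}, \hat f_{12}, \hat f_{02})$ — with
numerator weights $(1, -1, 0)$ for $Z_1$, $(0, \frac{n_1}{n_0+n_1},
\frac{n_0}{n_0+n_1})$ for recessive, $(w_1, w_2, 0)$ for additive,
$(\frac{n_1}{n_1+n_2}, 0, \frac{n_2}{n_1+n_2})$ for dominant — so
$\hat\rho_x = a^\top \hat\Sigma b_x / \sqrt{a^\top \hat\Sigma a \cdot
b_x^\top \hat\Sigma b_x}$ with $\hat\Sigma$ the $3 \times 3$ plug-in
covariance matrix. The additive weights are treated as constants at their
observed values; their sampling variability is second order. The test suite
validates $\hat\rho_x$ against the empirical correlation of $(Z_1, Z_x)$
across null replicates.

Two remarks a user should know:

* $\alpha^*$ equals $\alpha$ exactly when all $\rho_x = 0$ (the regions
  partition the line) and in the degenerate limit $|\rho_x| = 1$ (the three
  events reassemble $\{|Z_1| > z_{1-\alpha^*/2}\}$); in between it is
  smaller than $\alpha$, i.e. the adjustment is conservative relative to
  naive two-phase testing. At the study conditions we observe mean
  $\alpha^* \approx 0.036$ at $\alpha = 0.05$, nearly flat in MAF.
* per-SNP $\alpha^*$: in a scan, each SNP's own $\hat\rho_x$ yields its own
  threshold (`tpp_scan(..., nominal_threshold = 5e-5)` reports the adjusted
  genome-wide threshold per SNP).

### Numerical choices

The integral is evaluated by Gauss–Legendre quadrature with 200 nodes per
segment on $u \in [-8, 8]$ split at $\pm\xi$ (tail mass beyond $|u| = 8$ is
below $10^{-15}$); nodes are cached per $(n, a, b)$. The right-hand side is
strictly increasing in $\alpha^*$, so bisection on $(10^{-12}, 1)$ to
absolute tolerance $10^{-10}$ finds the unique root. The degenerate branch
$|\rho_x| \ge 1 - 10^{-10}$ integrates the limiting indicator in closed form
(quadrature cannot track a jump). Any combination variance below $10^{-12}$
is treated as degenerate and raises an error rather than being divided
through; group sizes below 2 make the $(n-1)$ prefactors of the variance
estimators vanish and are likewise refused.

**Degenerate-group fallback.** At very low MAF the minor-homozygote group
can have fewer than 2 subjects (at MAF 0.05 and $n = 1500$ the expected
count is 3.75, and $\Pr(n_2 < 2)$ is non-negligible). Model selection is
then undefined; `tpp_test()` falls back to the two-group trend statistic on
the two well-populated groups — the $w_2 \to 0$ (or $w_1 \to 0$) limit of
the additive test — at the unadjusted level, with a warning, rather than
silently redrawing or failing. Experiment drivers count these replicates in
a `fallback_rate` column instead of discarding them.

## Comparators

* **Kruskal–Wallis** (`kruskal_wallis()`): the classical three-group rank
  test, delegated to `stats::kruskal.test()` (midrank H with tie
  correction, $\chi^2_2$ reference).
* **MAX3** (`max3_test()`): $\max(|Z_R|, |Z_A|, |Z_D|)$, the standard
  robust competitor. Its null law is evaluated under the trivariate normal
  with delta-method correlations (nested Gauss–Legendre for the rectangle
  probability, accuracy ~$10^{-6}$ for $|\rho| \le 0.999$; correlations are
  clamped slightly inside $\pm 1$), or by seeded permutation of genotype
  labels. The two routes are cross-checked in the test suite. In the
  permutation route, label arrangements that zero a combination variance
  (possible only in very small groups) score $0/0$ as 0 and $c/0$ as
  $\pm\infty$, which makes the permutation statistic well defined without
  biasing the exceedance count.

## The synthetic-cohort generator

The generator reproduces the calibration conditions: Hardy–Weinberg
genotype frequencies $(1-p)^2, 2p(1-p), p^2$ at MAF $p$ (the study
conditions fix only the MAF; equilibrium is the natural completion), and
$$Y = \beta_0 + s(G)\,\beta_1 + \varepsilon, \qquad
  \varepsilon \sim \mathrm{tGEV}(0, 0, d, 0),$$
a Gumbel with scale $d$ left-truncated at 0 — a heavy-tailed, positive
error emulating survival-type traits. Defaults are the study conditions:
$n = 1500$, $\beta_0 = \beta_1 = 0.5$, $d = 5$. The genotype scores are
$s_{REC} = (0, 0, 2)$, $s_{ADD} = (0, 1, 2)$, $s_{DOM} = (0, 2, 2)$, so the
homozygote contrast is $2\beta_1$ under every model — the standard
convention in the robust-trend-test literature. Left truncation follows
the survival-time motivation of the error law; the truncation side remains
a switchable parameter of `error_law()`, and the score scale and truncation
side were verified against the selection-rate and power behaviour they are
meant to produce before being frozen as defaults. Untruncated GEV and
centered-$t$ errors are available for sensitivity analyses.

Sampling is inverse-CDF on a uniform restricted to the truncation region,
so draws are exact and reproducible; an error is raised if the truncation
region carries less than $10^{-12}$ mass. Experiment drivers derive one
independent substream per grid cell from the master seed (recorded in the
output), making every table cell reproducible in isolation.

What the generator does *not* emulate: linkage disequilibrium between SNPs,
Hardy–Weinberg departures, genotyping error, covariate confounding and
population structure (only generic OLS residualization via `residualize()`
is provided — regress the trait on covariates, test the residuals).
Passing tests therefore demonstrate calibration under clean single-SNP
sampling, not robustness to those artefacts.

## Problem sizes used in the checks

The packaged test suite runs the null calibration at $n = 1500$ with
10,000 replicates (Kolmogorov–Smirnov against $N(0,1)$ at level 0.01 for
all four statistics), the estimator-consistency oracle at $n = 600$ with
5,000 replicates, and the selection-rate check with 5,000 replicates; the
acceptance script reruns the full experiment grid at 1,000–10,000 replicates per
cell. When comparing a plug-in estimator with a Monte Carlo oracle, the
oracle's own standard error is part of the comparison (bands are widened by
three oracle standard errors); Monte Carlo equalities are otherwise
asserted within three binomial standard errors.

## Known limitations

* The alternative is one-sided in the win-probability ordering
  ($f_{02} \ge f_{01} \ge 1/2$), but rejection is two-sided on $|Z_x|$;
  a one-sided variant is deliberately not offered.
* Asymptotic null laws: no exact finite-sample distributions; with every
  group $\ge 2$ but small, p-values are approximate (the permutation MAX3
  is the safer choice there).
* Win-probability estimators are null-centered; their variance plug-ins
  are calibrated for sizing, not for confidence intervals around
  $\hat f_{ab}$ under strong alternatives.
* No multiplicity handling across SNPs beyond the per-SNP adjusted
  threshold for a user-chosen genome-wide level.
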