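---
title: "Methods: segregation models and dispersal statistics for conidiophore morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation models and dispersal statistics for conidiophore morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conidiomorph)
```

# The segregation model

Crosses between homokaryotic parents of the three conidiophore
architectures (WT, Wrap, Bulky — genes A, B, C) yield progeny whose
phenotype counts per cross are modelled as multinomial with a
linear-probability parameterization:

$$p_i = \tfrac13\,\mathbf{1} + X_i\,\theta, \qquad
\theta = (\alpha, \beta, \gamma, \alpha\beta, \beta\gamma, \alpha\gamma)$$

Three allelic effects and three pairwise epistatic interactions perturb a
uniform baseline. The key assumptions are: progeny within a cross are
independent and identically distributed (the row total $n_i$ is fixed by
the experiment); the three crosses are independent; and effects act on
the probability scale (identity link). The identity link is the reading
under which the expected information is literally the $N X'AX$ weighting
with $A = \mathrm{diag}(1/\hat p)$, which is what ties the Fisher-scoring
iteration below to weighted least squares; a logit-type link would make
$A$ carry extra factors.

## The design matrices

The model family fixes *which* effects exist but not the numeric map from
effects to probability deviations. The package's default reconstruction
is: in the cross U×V (U before V in the order A < B < C), the deviation
of phenotype U is $\theta_U + \theta_{UV}$, of phenotype V is
$\theta_V - \theta_{UV}$, and of the remaining phenotype
$-\theta_U - \theta_V$. This choice is the simplest one satisfying three
structural requirements:

* every column sums to zero within a cross, so fitted probabilities sum
  to one identically — no normalization step, no rank-one information
  correction;
* the stacked $9 \times 6$ matrix has full column rank 6, so the full
  epistatic model is **saturated** on a three-cross table
  ($\chi^2 = 0$ on $0$ df) — six free parameters against six free
  observed proportions;
* each interaction is private to its own cross, giving the df ladder
  6, 5, 4, … that the hierarchy's bookkeeping (df $= 6 - $ #free
  parameters) requires.

The sign convention — the interaction enters with $+$ on the
alphabetically first gene — is arbitrary; flipping it relabels
$\theta_{UV} \mapsto -\theta_{UV}$ without changing any fit statistic of
the full or environmental models. Intermediate models *do* depend on the
reconstruction: their $\chi^2$ values and the parameter estimates are
meaningful relative to this documented design (overridable via
`read_design()`), and the package validates the fitter by oracle
equivalence and simulation recovery rather than by matching any
particular intermediate value. Design-independent quantities — the
environmental $\chi^2$, the saturated fit, the df accounting, nested
difference arithmetic, and heritability computed from given statistics —
carry no such caveat.

## Fitting: IRLS / Fisher scoring

With observed proportions $y_i$ and current probabilities $\hat p_i$:

$$U(\theta) = \sum_i n_i X_i' A_i (y_i - \hat p_i), \qquad
I(\theta) = \sum_i n_i X_i' A_i X_i, \qquad A_i = \mathrm{diag}(1/\hat p_{ij})$$

and the update is $\theta \leftarrow \theta + I^{-1}U$. Numerical
choices, all deliberate:

* **Initialization** at $\theta = 0$ (uniform probabilities):
  deterministic, always feasible, and inside the parameter region for any
  valid table.
* **Convergence** when $\max|\Delta\theta| / \max(1, \max|\theta|) <$
  `tol` (default $10^{-8}$), capped at `max_iter = 100`. On real-sized
  tables the saturated fit converges in a handful of iterations.
* **Step-halving** whenever a proposed step would push any fitted
  probability outside $(10^{-6}, 1 - 10^{-6})$; an underflowing step is
  an error rather than a silent boundary fit.
* **Zeroed parameters** are excluded from the design columns, not
  penalized, so they are exactly 0 in the output and the information
  matrix is the free-parameter block only.
* **Degenerate input**: a uniform count table yields $\hat\theta = 0$ in
  one step; a table with an empty row is rejected up front.
* **Negative nested differences** ($\chi^2_{H_0} < \chi^2_{H_A}$) cannot
  occur at exact optima and are clamped to zero with a warning, keeping
  the raw value in the result for inspection.
* **Standard errors** are $\sqrt{[I(\hat\theta)^{-1}]_{kk}}$; tests
  confirm they match parametric-bootstrap standard deviations and scale
  as $1/\sqrt{2}$ under count doubling.

Heritability is reported as
$H^2 = (\chi^2_{\text{env}} - \chi^2_{\text{add}})/\chi^2_{\text{env}}$;
it is undefined (and reported as such) when the environmental
$\chi^2$ is zero, i.e. when the data show no variation to partition.

```{r hierarchy}
hierarchy_table(f2_counts())
```

# Dispersal statistics

## Two-sample Kolmogorov–Smirnov tests

`ks_statistic()` is the sup-norm distance between the two empirical
distribution functions. For the p-value $P(D \ge d)$, two routes:

* **Exact** (no ties): lattice-path counting over the $(n_1, n_2)$ grid,
  run in probability units so no binomial coefficient is ever formed.
  Attainable deviations $|i n_2 - j n_1|$ are integers, so the threshold
  $d\,n_1 n_2$ is snapped to the nearest integer when within 0.1 — this
  makes the tail *include* paths that attain the observed $D$, and makes
  the computation robust to $D$ values reported rounded to a few digits
  (an upward-rounded $D$ would otherwise silently exclude the attained
  deviation and understate the p-value).
* **Asymptotic**: the alternating Kolmogorov series
  $2\sum_{k\ge1} (-1)^{k-1} e^{-2k^2\lambda^2}$ at
  $\lambda = d\sqrt{n_1 n_2/(n_1+n_2)}$, truncated when a term falls
  below $10^{-12}$ and clamped to $[0,1]$. No small-sample continuity
  correction is applied.

`method = "auto"` selects exact when $n_1 n_2 < 10^4$ and the pooled
sample is tie-free, otherwise asymptotic (with a message when ties force
the fallback). Distances measured from plate images are rounded, so real
dispersal data frequently carries ties and lands on the asymptotic
branch even at small $n$; the exact branch refuses ties explicitly
rather than returning a p-value whose null distribution no longer holds.
Exactness is tested against brute-force enumeration of all interleavings
for $n_1 + n_2 \le 12$ and against an independent reference routine, and
the two branches are tested to agree within 0.005 at $n_1 = n_2 = 100$.

## Normality and the maximum-distance test

`shapiro_wilk()` delegates to the standard Royston-approximation routine
(`stats::shapiro.test`) — the contract is the published algorithm, and
re-deriving its coefficient tables would add nothing but risk.

For the farthest colony: under a normally distributed dispersal
coordinate, the standardized distance
$z = (X_{\max} - \bar X)/s$ has $z^2$ approximately $\chi^2(1)$, and the
probability that the largest of $n$ such standardized maxima reaches
$z^2$ is the order-statistic tail $1 - F(z^2)^n$. `largest_rank_tail()`
computes this on the log scale (via `expm1`), so it stays meaningful
where $1 - F^n$ would underflow — at $z^2 \approx 200$ the single-draw
tail is $\sim 10^{-46}$ and naive arithmetic returns exactly 0. The
default `n_ranks = 3` treats the three strain maxima as order statistics
from one distribution; it is configurable because the choice is a
modelling judgement, not a mathematical necessity. The tail is monotone
(non-increasing in $z^2$, non-decreasing in $n$) and bounded by the
Bonferroni envelope $\min(1, n(1 - F(z^2)))$, and the tests assert
exactly those properties.

```{r maxdisp}
max_dispersal_test(25.78, 4.729, 2.165)
```

# Germination and penetrance

Germination rate is the mean colony count across replicate plates over
the expected colony count (suspension concentration × plated volume),
times 100. Because the concentration is only roughly calibrated, rates
above 100% are possible and are *reported as measured* — clamping would
hide calibration drift; a warning fires above 120%. The rate is
scale-equivariant: doubling counts and expectation together changes
nothing. The germination timeline flags a strain as germinating earlier
on a condition only when it strictly precedes *every* other strain
there; ties mean no flag. Penetrance is the majority-phenotype fraction
of a strain's classified conidiophores, with ties broken by the fixed
phenotype order (WT < Wrap < Bulky) and a warning — real classification
runs do not produce exact ties, but the rule must be deterministic.
Phenotype-by-category association uses the ordinary Pearson chi-squared
test of independence without continuity correction, warning when any
expected cell drops below 5.

# The synthetic-data generator

The generator produces data with exactly the statistical structure the
analyses assume:

* **Progeny counts**: independent multinomial draws per cross from the
  forward model $1/3 + X_i\theta$ — the sampling frame of the real
  crosses (about 300–400 classified conidiophores per cross; the
  packaged table's row totals are 396, 286, 366, and the generator's
  defaults mirror that scale).
* **Dispersal**: isotropic bivariate normal coordinates around the
  membrane centre, returned as radial distances, so distances are
  Rayleigh($\sigma$) and squared distances over $\sigma^2$ are
  $\chi^2(2)$ — the normal-coordinate assumption behind the
  maximum-distance test, stated as a distributional fact the tests can
  check.
* **Germination**: replicate counts Binomial(expected, rate) — every
  plated conidium germinates independently.

What it deliberately does **not** emulate: truncation of the dispersal
field at the platter boundary (real platters are finite, which biases
observed distance distributions inward), measurement rounding (and hence
the ties real distance data carries), classification error in phenotype
calls, and between-replicate overdispersion. Passing tests on synthetic
data therefore establish the *estimators'* correctness under the model,
not the model's adequacy for any particular plate.

## Validation scale

Parameter recovery runs 200 replicates at 5000 progeny per cross
(`recovery_experiment`, fixed seed): per-parameter absolute bias is
required below 0.01, and the 95% information-matrix intervals must cover
truth at 93–97% *pooled across the six parameters* — at 200 replicates a
single parameter's empirical coverage has Monte-Carlo standard error
near 1.5%, so the band is asserted on the pooled rate (1200 intervals,
SE ≈ 0.6%) rather than per parameter. The IRLS optimum is checked
against a derivative-free (Nelder–Mead) maximizer of the multinomial
likelihood to $10^{-5}$ on the packaged table and on simulated tables;
the KS type-I error is simulated over 500 null pairs.

```{r recovery}
recovery_experiment(c(0.06, -0.03, 0.03, 0.03, -0.03, 0),
                    n_per_cross = rep(500, 3), n_replicates = 50, seed = 2)
```

# Known limitations

* The three-locus family is the model's scope: it does not estimate the
  number of genes beyond three, map loci, or handle linkage.
* Intermediate-model statistics and effect estimates are interpretable
  only relative to the declared design matrices.
* The exact KS branch requires tie-free data; with ties only the
  asymptotic approximation is offered.
* The largest-rank tail takes the reference mean and variance as given
  constants; uncertainty in estimating them is not propagated, so
  extremely small tails should be read as order-of-magnitude statements.
* Germination rates inherit the calibration error of the expected colony
  count multiplicatively.
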