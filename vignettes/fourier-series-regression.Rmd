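---
title: "Fourier-series nonparametric regression: model, selection and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier-series nonparametric regression: model, selection and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourierreg)
```

## The model and its assumptions

`fourierreg` fits the additive nonparametric regression

$$y_i = \sum_{j=1}^{p}\Big(\frac{\mu_j}{2} + \beta_j x_{ij}
  + \sum_{t=1}^{T_j}\delta_{tj}\cos(t\,x_{ij})\Big) + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2)\ \text{i.i.d.}$$

Each predictor's unknown curve is approximated by a cosine series with a
linear trend: the constant $\mu_j/2$ sets the baseline, $\beta_j$ a drift,
and the $T_j$ cosine harmonics capture repeated patterns. The working
assumptions are additivity across predictors (no interactions), Gaussian
homoscedastic errors, and predictors measured without error. The cosine basis
is evaluated on the *raw* predictor values by default; if a predictor's range
is far from $[0, 2\pi]$ the harmonics can degenerate (all columns nearly
collinear), for which `fourier_spec(..., rescale = TRUE)` maps each predictor
linearly to $[0, \pi]$ first. Raw evaluation is the default because it is the
convention of the line of work this package implements; neither convention is
asserted as canonical, and results should be reported together with the
choice made.

## Estimation on an intrinsically rank-deficient design

Stacking the per-predictor blocks
$[\tfrac12, x_j, \cos x_j, \dots, \cos(T_j x_j)]$ gives an
$n \times L$ design with $L = \sum_j (T_j + 2)$ columns, of which the $p$
half-constant columns are identical. The design therefore has rank at most
$1 + p + \sum_j T_j$ — deficient by exactly $p - 1$ whenever the reduced
design is full rank. Rather than reparameterising (which would change the
coefficient bookkeeping users see), `fit_ols()` keeps the matrix exactly as
written and returns the **minimum-norm** least-squares solution through the
Moore–Penrose pseudoinverse of $X'X$ (computed once per design from an SVD,
with singular values below `max(dim(X)) * eps * d_1` treated as zero). Two
observable consequences motivate this choice:

* the shared intercept is split *equally* across the $p$ identical columns,
  so all $\hat\mu_j/2$ estimates coincide — the pattern a single shared
  intercept produces under any symmetric resolution;
* the degrees of freedom come out as $\mathrm{rank}(X) = 1 + p + \sum_j T_j$
  and $r = n - \mathrm{rank}(X)$, e.g. $21$ and $17$ for
  $p = 5$, $T = (1,2,4,3,5)$, $n = 38$.

The fitted values $X\hat\delta$ are invariant to which generalized inverse is
used (the test suite asserts agreement with `lm`'s pivoting solution), so
every fit-level quantity — residuals, $R^2$, GCV, the simultaneous statistic —
is unambiguous; only the split of the intercept is a convention.

One printed-source tension is worth recording: the degrees-of-freedom formula
appears in two variants, $n - p(T+1) + 1$ and $n - (p(T+1)+1)$. The worked
application uses $38 - 21 = 17$, which is the second form and equals
$n - \mathrm{rank}(X)$; that definition is used everywhere here.

## Selecting the oscillation parameters

`gcv_score()` implements
$\mathrm{GCV} = \frac{n^{-1} y'(I-U)'(I-U)y}{(n^{-1}\mathrm{tr}(I-U))^2}$.
Because $I - U$ is a projector, the numerator is $\mathrm{RSS}/n$ and the
trace is $n - \mathrm{rank}(X)$; the default path uses this reduced form
(no $n \times n$ matrix is formed), and a `dense = TRUE` path evaluates the
quotient literally so tests can compare the two.

Two searches are provided: `search_uniform()` over $T = 1..T_{\max}$ shared
by all predictors, and `search_combinations()` over the full grid
$\{1..T_{\max}\}^p$ ($3^5 = 243$, $5^5 = 3125$ candidates at $p = 5$). A
candidate budget (default 5000) guards the exponential blow-up; exceeding it
is an error unless `override = TRUE`. $T_j = 0$ (pure trend) is deliberately
not a candidate: the grid this package mirrors starts at one harmonic.
GCV ties are broken toward parsimony — smaller $\sum_j T_j$, then
lexicographically smaller $T$-vector; the tie-break is our choice, as the
selection rule itself says nothing about ties. Candidates whose rank reaches
$n$ (saturated) are skipped with a warning rather than scored.

## Hypothesis testing

Both tests are likelihood-ratio derived under the Gaussian model.

**Simultaneous.** $\Lambda = \frac{(X\hat\delta)'y / \mathrm{rank}(X)}
{Q / r}$ is referred to $F(\mathrm{rank}(X), r)$, rejecting in the upper
tail. The numerator $(X\hat\delta)'y$ is the explained quadratic form
*including* the intercept contribution — the statistic is implemented exactly
as defined. A consequence users should know: under a pure-noise null with
nonzero mean the statistic does not follow the central $F$, so the package's
own Monte-Carlo checks of $\Lambda$ use zero-mean noise, and the test should
be read as "all coefficients, intercept included, are zero".

**Partial.** For a single coefficient $\delta_l$ the constrained estimator
under $a_l\delta = 0$ has the closed Lagrange-multiplier form
$\hat\delta_\omega = \hat\delta - (X'X)^+ a_l' (a_l (X'X)^+ a_l')^{-1}
a_l\hat\delta$ (`constrained_fit()`), and the test statistic is
$Z = a_l\hat\delta / \sqrt{(Q/r)\, a_l (X'X)^+ a_l'} \sim t(r)$ under the
null, two-sided. The identity $Z^2 = y'My / (y'(I-U)y/r)$ with
$M = X(X'X)^+a_l'(a_l(X'X)^+a_l')^{-1}a_l(X'X)^+X'$ — $M$ symmetric,
idempotent, trace one, $M(I-U) = 0$ — is exposed as a runtime diagnostic
(`quadratic_form_check()`) and asserted to $10^{-10}$–$10^{-8}$ in the tests.
On the collinear intercept columns, $a_l(X'X)^+a_l'$ is evaluated with the
same pseudoinverse as estimation, i.e. the test addresses the minimum-norm
coefficient; this is the interpretation under which all $p$ intercept rows of
the coefficient-test table carry identical statistics. No multiplicity
correction is applied by default (matching the practice this package
mirrors); `partial_test_all(adjust = "bonferroni")` or `"BH"` are available.

## Residual diagnostics: the Glejser test, and one deliberate deviation

`glejser_test()` regresses $|e_i|$ on the *same* design object as the primary
fit (cosine columns included) and reports a simultaneous p-value plus
per-coefficient t tests. The design document for this package called for the
auxiliary overall test to reuse the raw $\Lambda$ form. Implementation showed
that cannot work: absolute residuals always have a positive mean, so a
statistic whose numerator includes the intercept contribution diverges from
its null reference and declares heteroscedasticity for essentially every
homoscedastic sample — while the worked application this package follows
reports a clearly non-significant Glejser result on well-behaved residuals.
The default is therefore the standard mean-corrected overall F,
$\big[(\mathrm{TSS}-\mathrm{RSS})/(\mathrm{rank}-1)\big] /
\big[\mathrm{RSS}/r\big]$ on $F(\mathrm{rank}-1, r)$, which the test suite
verifies rejects at $\approx \alpha$ under homoscedastic noise; the raw form
remains available via `form = "lambda"` for comparison.

## The synthetic-data generator: what it emulates and what it does not

`generate_dataset()` draws predictors i.i.d. uniform on configurable ranges
(default $[0, 2\pi]$, one full cosine period, so every harmonic is excited),
builds $y = X\delta^* + \varepsilon$ with known $\delta^*$ and
$\varepsilon \sim N(0, \sigma^2 I)$, and is bit-reproducible under a single
integer seed (predictors and noise use separate substreams at a fixed seed
offset, so either can be held fixed). `generate_null_dataset()` additionally
asserts that designated coefficients are truly zero, for type-I-error
studies.

What it does **not** emulate: correlated or clustered predictors, spatial or
administrative structure, non-Gaussian or heteroscedastic errors, and
misspecification (the truth is always exactly inside some Fourier model). A
green test therefore establishes correctness of the algebra and calibration
of the inference *under the model's own assumptions* — not robustness to
their violation.

Default "world" parameters were fixed once: true coefficients of order one
(uniform on $[-1.5, 1.5]$ under a fixed seed), $n = 38$–$200$ depending on
the scenario, and $\sigma = 0.1$ as "low noise" against order-one signals.

## A note on GCV structure recovery

One acceptance scenario asks GCV to recover a true uniform $T = 2$ at
$n = 200$ under low noise in at least 90% of replicates. An instructive fact,
found during implementation: when the truth lies exactly inside the candidate
model, the probability that GCV overfits is *independent of* $\sigma$ — both
the RSS drop from extra harmonics and the GCV penalty threshold scale with
$\sigma^2$. What controls recovery is the number of columns each extra
harmonic adds, i.e. $p$. At $p = 2$ the overfit probability is roughly 20%
(two extra columns buy too little penalty), and no noise level fixes that; at
$p = 5$ — the shape of the application this package mirrors, and the world
used in the acceptance suite — recovery is at the 90% boundary. The
recovery criterion is therefore run at $p = 5$, $T_{\max} = 5$, and its
margin should be understood as thin by the nature of GCV, not by
implementation quality.

## Numerical choices

* Rank / pseudoinverse tolerance: singular values below
  `max(n, L) * .Machine$double.eps * d_1` are zero.
* Constraint estimability: `a_l (X'X)^+ a_l'` at or below
  `L * eps * max(diag)` is an error ("constraint direction not estimable");
  in `partial_test_all()` such rows are reported as `NA`, not fatal.
* Saturated designs ($n \le \mathrm{rank}$) are errors in fitting and
  skipped-with-warning in searches.
* MAPE is reported as a proportion and is `NA` with a warning when any
  $y_i = 0$; MSE uses denominator $n$ (the MLE scale), matching the selection
  tables; $Q/r$ is used for inference.
* Critical values and p-values are stored at full precision; printing rounds.

## Limitations

* Only single-coefficient hypotheses ($a_l$ a selector vector); no general
  contrasts, no confidence intervals.
* No penalized (smoothness) estimation; OLS/minimum-norm only.
* Exhaustive search only; cost grows as $T_{\max}^p$.
* The simultaneous statistic's intercept-in-numerator behaviour (above)
  makes it unsuitable as a generic overall-regression F test.
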