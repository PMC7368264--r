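---
title: "Age-by-maternal-age demography of maternal effect senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-by-maternal-age demography of maternal effect senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momage)
```

## The problem and the model

Maternal effect senescence is the decline in offspring quality -- survival
and fertility -- with the age of the mother at the offspring's birth. It is
widespread (rotifers, *Daphnia*, *Drosophila*, mites, birds, mammals) and
puzzling: producing worse offspring late in life carries a fitness cost, so
why does selection tolerate it? The classical answer for ordinary age
senescence is that selection gradients on survival and fertility decline
with age; asking the same question about *maternal* age requires a model in
which an individual is classified jointly by its age $j$ and by its
maternal age class $i$ -- the age its mother had when it was born, fixed
for life.

`momage` implements that model as a block-structured matrix population
model. The population vector stacks maternal ages within age classes
(state $(i, j)$ at flat position $(j-1)s + i$, with $s$ maternal age
classes and $\omega$ age classes, both 16 d here and a projection interval
of one day). Each day an individual of state $(i, j)$ produces $f_{ij}$
daughters and survives to age $j+1$ with probability $p_{ij}$. The
survival matrix $U$ carries $p_{ij}$ on its block subdiagonal; the
fertility matrix $F$ is nonzero only in its first block row, because a
daughter of an age-$j$ mother starts life at age 1 *with maternal age
class $j$* -- this is the coupling that makes maternal effects heritable
demographic structure rather than a nuisance covariate. The projection
matrix is $A = U + F$, fitness is its dominant eigenvalue $\lambda$, the
stable structure $w$ and reproductive values $v$ are the corresponding
right and left eigenvectors, and the net reproductive rate is the dominant
eigenvalue of $F(I-U)^{-1}$.

Two derived analyses carry the scientific conclusions:

* **Selection gradients** $\partial\lambda/\partial p_{ij}$ and
  $\partial\lambda/\partial f_{ij}$, computed from the eigenvector
  sensitivity formula $v_r w_c / v^\top w$ at the single matrix position
  where each rate appears. Their decline with age and with maternal age is
  what permits senescence, and maternal effect senescence, to evolve.
* **LTRE decomposition** of a fitness difference between two models into
  per-rate contributions $(\theta^{(a)}_{ij} - \theta^{(ref)}_{ij})\,
  \partial\lambda/\partial\theta_{ij}$, with sensitivities evaluated at
  the midpoint model (vital rates averaged, matrix rebuilt). Midpoint
  evaluation is the standard first-order choice; the closure error
  $|\sum c - \Delta\lambda|$ is reported and a warning is raised above
  10% relative discrepancy, since the method is first-order by
  construction.

## Parametric vital rates

Survivorship is Weibull, $S_i(t) = \exp(-(t/b_i)^{k_i})$, with *both*
parameters log-linear in maternal age: $b_i = e^{a_0 + a_1 i}$,
$k_i = e^{c_0 + c_1 i}$. Modelling both is what allows the observed
crossover -- worse young-age survival but better old-age survival for
offspring of old mothers -- because a lowered shape flattens the hazard.
Daily survival uses the cohort life-table convention
$p_{ij} = S_i(j)/S_i(j-1)$, the probability of surviving the day-$j$
interval given survival to its start; $p_{i\omega} = 0$ is stored because
no age class exists beyond $\omega$, a bookkeeping convention of the
projection matrix rather than a biological death sentence (the simulator
and the fitters treat the final observation day accordingly; see below).

Fertility adapts the Coale--Trussell model from human demography:
$f_{ij} = n(j)\, e^{m_i \nu(j)}$, a "natural fertility" curve $n(j)$
depending only on age, reduced after a threshold age $j^* = 4$ d by a
control factor whose level $m_i = c_0 + c_1 i$ grows with maternal age.
The deviation schedule is the unit ramp $\nu(j) = -(j - j^*)_+$. Natural
fertility is log-quadratic in age, clamped to zero below a minimum
reproductive age. All schedules therefore coincide up to age 4 d and
diverge after it, declining earlier and faster for older maternal ages.

Design choices worth recording:

* **Minimum reproductive age 3 d.** First reproduction in the packaged
  default occurs at age 3. This does two things: it matches the sharp
  fertility onset between ages 2 and 4 d, and it makes maternal age
  classes 1--2 unreachable, so class 3 is the *youngest and best* class
  actually present. That is what makes the maternal-age-3 reference of
  the removal scenarios an upper envelope: replacing every class's
  schedules with class 3's is then an elementwise improvement on the
  reachable state space, and fitness can only rise.
* **Identifiability of the control factor.** Only the product
  $m_i \nu(j)$ enters the mean, so the ramp slope and the control
  coefficients are identified only up to a common scale. Following the
  classical formulation -- where $\nu$ is a fixed schedule -- the ramp is
  held fixed during fitting and only $n(j)$ and $m_i$ are estimated.
* **Counts are Poisson.** Daily offspring counts are modelled (and
  simulated) as Poisson with mean $f_{ij}$, the minimal count model; the
  fitter works on the per-cell sufficient statistics, so its cost is
  independent of cohort size.

## Fitting

Survival is fitted by interval-censored maximum likelihood: a death first
noticed at the day-$t$ check happened somewhere in $(t-1, t]$ and
contributes $\log(S_i(t-1) - S_i(t))$; an individual lost during day $t$
was last seen alive at the previous check and contributes $\log S_i(t-1)$,
as does one still alive on the final observation day (the last check
carries no survival draw, so survival beyond it is unobserved).
Optimisation is multi-start local search -- Nelder--Mead then BFGS from
five deterministic perturbations of a moment-based start (log-linear
regression of per-cohort mean lifetimes, coefficient-of-variation shape
estimate), relative tolerance $10^{-10}$ -- and the reported optimum is
checked against the initial guess. Standard errors come from the
numerically inverted Hessian. The fertility likelihood is validated in the
test suite against an independent Poisson GLM fit of the same linear
predictor, and the survival optimiser against a brute-force likelihood
grid; neither oracle is used in the implementation itself.

## The six scenarios

The fitted laboratory model `A` grows unrealistically fast, which
concentrates the stable population at young ages and young maternal ages
and thereby hides most of the cost of maternal effect senescence. Two
stationary variants probe other environments:

* `B` divides every fertility by $R_0$ (resource limitation). Because
  the next-generation matrix scales linearly in $F$, this yields
  $R_0 = 1$ and hence $\lambda = 1$ exactly, with survival untouched.
* `C` multiplies every survival probability by a constant $c$
  (predation/infection) chosen so that $\lambda(cU + F) = 1$.
  Multiplying survival by $c$ adds $-\log c$ to each day's integrated
  hazard, so this is an additive mortality hazard. The map
  $c \mapsto \lambda$ is strictly increasing, so $c$ is found by Brent's
  bracketed root search (bisection with interpolation steps) on
  $[10^{-6}, 1]$ followed by secant polish until
  $|\lambda - 1| \le 10^{-10}$.

Removal variants `A_r`, `B_r`, `C_r` give every maternal age class the
reference class's schedules, built at the vital-rate level and
reassembled so provenance stays clean. The reference class defaults to 3
but is a parameter.

## The synthetic experiment

The individual-based generator emulates the laboratory design the
analysis is shaped around: F1 cohorts collected at maternal ages 3, 5, 7
and 9 d, 72 individuals each (an F0 founding cohort of 187 is recorded
for provenance but not simulated, as its members have no defined maternal
age class), daily checks to age 16 d, and independent daily Bernoulli
loss (right censoring) at rate 0.01 -- the experiment's actual loss rate
is unreported, so a small value is used and is configurable. Each
individual draws from its own RNG stream derived from the master seed, so
per-cohort output is invariant to cohort ordering and identical seeds
give byte-identical life tables.

Within a day the generator draws loss first, then the offspring count,
then survival. Drawing offspring *before* the survival outcome matches
the projection matrix's accounting, in which a day's reproduction by an
individual present at the preceding check does not require surviving that
day; with this convention the mean lifetime offspring of a birth cohort
equals $R_0$ of the matrix exactly, an identity the test suite checks by
Monte Carlo. Offspring recorded on a death day are real observations
(neonates counted at the check even if the mother died) but carry no
fertility-likelihood information, since the fitters use only alive,
uncensored days.

The packaged default parameters are a qualitative stand-in, not a fit to
any real data set, chosen once to reproduce the study system's reported
patterns: fertility onset at age 3 d peaking near 4--5 d at roughly 4
daughters per day (25--30 over a lifetime), divergence across maternal
ages after age 4 d, cohort mean lifespans falling from about 13 d at
maternal age 3 to about 6 d at maternal age 9, young-age survival
declining with maternal age with a crossover at the oldest extrapolated
classes, and an assembled growth rate between 1.5 and 2.5 per day. What
the generator deliberately omits: grandmaternal synchronisation, sexual
(mictic) reproduction, overdispersed counts, and any frailty or
individual heterogeneity. Passing tests therefore demonstrate internal
consistency of the pipeline under its own assumptions, not the fit of
those assumptions to real rotifer data.

## Numerical choices

* **Eigenanalysis.** Full dense decomposition (256 x 256 is cheap),
  selecting the eigenvalue of maximal modulus with ties broken by the
  largest real part (the Perron root of an imprimitive matrix shares its
  modulus with complex partners). A genuinely complex dominant value is
  an error, never silently truncated. Because unreachable maternal age
  classes make the matrix reducible, the LAPACK eigenvector resolves the
  structurally zero and vanishingly small entries only to an absolute
  noise floor; the returned vector is therefore refined by power
  iteration, which keeps entries exactly nonnegative, drains unreachable
  states to exact zeros, and computes tiny entries with relative
  accuracy. Residuals $\|Aw - \lambda w\|_\infty$ are stored on the
  result.
* **Gradient monotonicity is checked from the first reproductive age.**
  Before reproduction begins, the ratio of successive survival gradients
  is $p_{ij}/p_{i,j+1}$, so a rising hazard produces a sub-percent
  *increase* across pre-reproductive ages; the orders-of-magnitude
  decline that matters biologically runs across the reproductive span,
  and that is what `gradient_profile_checks()` evaluates.
* **Degenerate inputs.** The zero matrix reports $\lambda = 0$ with the
  structure flagged undefined; empty life tables, single-cohort fits
  without fixed slopes, all-censored-on-entry data and all-zero count
  data raise distinct errors.
* **Problem sizes.** The test suite simulates cohorts of 150--2000
  individuals per maternal age (up to 20,000 for the Monte-Carlo
  $R_0$ identity), sizes at which parameter recovery is tight (about
  2% on Weibull coefficients at 2000 per cohort) while the whole suite
  completes in about a minute.

## Known limitations

The default parameter set is a stand-in; analyses of the real system
require its fitted matrices (the readers accept both whole-matrix and
per-age-block files for that purpose, validating the block structure and
rejecting nonzeros in forbidden positions). The LTRE is first-order and
its closure degrades for large perturbations. The model is linear --
no density dependence -- and treats maternal age as the only stage
variable; extending stage structure beyond maternal age is out of scope.
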