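# momage

Age-by-maternal-age matrix population models for the demography and
evolution of **maternal effect senescence** — the decline in offspring
survival and fertility with the age of the mother at the offspring's
birth.

The package is written for demographers and life-history biologists who
have individual daily life tables (as collected for rotifers, *Daphnia*,
or similar short-lived invertebrates, with cohorts founded at different
maternal ages) and want to move from those records to population-level
and evolutionary quantities: fitness, stable structure, selection
gradients, and a decomposition of the fitness cost of maternal effect
senescence.

## The model

Individuals are classified by age $j$ and maternal age class $i$ (the age
of their mother at their birth, fixed for life), $i \in 1..s$,
$j \in 1..\omega$, with a one-day projection interval. The population
vector stacks maternal ages within age classes; each day a state-$(i,j)$
individual produces $f_{ij}$ daughters and survives with probability
$p_{ij}$. Survival transitions fill the block subdiagonal of $U$;
fertility fills the first block row of $F$, a daughter of an age-$j$
mother entering age 1 with maternal age class $j$. Then

$$n(t+1) = (U + F)\,n(t) = A\,n(t),$$

fitness is the dominant eigenvalue $\lambda$ of $A$, the stable structure
$w$ and reproductive values $v$ are its Perron eigenvectors, the net
reproductive rate is $R_0 = \rho\!\left(F(I-U)^{-1}\right)$, selection
gradients are the eigenvalue sensitivities
$\partial\lambda/\partial p_{ij}$ and $\partial\lambda/\partial f_{ij}$,
and fitness differences between life histories are decomposed by LTRE
(life table response experiment) analysis.

Parametric vital rates: Weibull survivorship
$S_i(t)=\exp(-(t/b_i)^{k_i})$ with scale and shape log-linear in maternal
age, and a Coale–Trussell style fertility model
$f_{ij} = n(j)\,e^{m_i\nu(j)}$ in which maternal age supplies the control
level $m_i$ acting after a threshold age. Both are fitted to daily life
tables by maximum likelihood with right censoring, and an
individual-based simulator generates such life tables from any parameter
set, so the entire pipeline is testable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
experiment (four cohorts of 72 individuals at maternal ages 3, 5, 7, 9 d,
observed daily to 16 d):

```sh
Rscript analysis/01_simulate.R   # life-table CSV + generating truth
Rscript analysis/02_fit.R        # Weibull + Coale-Trussell MLE
Rscript analysis/03_build_model.R
Rscript analysis/04_scenarios.R
Rscript analysis/05_gradients.R
Rscript analysis/06_ltre.R
```

Stage 4 prints the six-scenario fitness comparison (values from one run
with the default seed):

```
scenario_set (six life histories):
  lambda(A) = 1.8479  lambda(A_r) = 1.8593
  lambda(B) = 1.0000  lambda(B_r) = 1.0215
  lambda(C) = 1.0000  lambda(C_r) = 1.0038
  R0(A) = 11.2532, hazard multiplier = 0.4292, reference maternal age = 3
young corner (ages 1-3 x maternal ages 1-5): A 82%, B 22%, C 90%
```

`A` is the fitted high-growth model; `B` and `C` are stationary variants
(fertility divided by $R_0$; survival multiplied by a root-found
constant); the `_r` models remove maternal effect senescence by giving
every class the maternal-age-3 schedules. Removal raises fitness in every
environment — that gap is the fitness cost of maternal effect senescence,
largest under low fertility (`B`), where the stable population is not
piled up at young ages. Stage 6 decomposes it:

```
-- B vs B_r --
LTRE: delta lambda = -0.021513, sum of contributions = -0.021479
  survival total -0.005721, fertility total -0.015758
```

so the cost is carried mainly by reduced fertility of offspring from
mid-aged mothers, not by their reduced survival. Stage 5 reports that
selection gradients decline with age within every maternal age class and
are concave in maternal age (rising to a peak at a young maternal age,
then dropping by ~9 orders of magnitude) — the pattern that lets maternal
effect senescence evolve by the same mutation-accumulation and
antagonistic-pleiotropy logic as ordinary senescence.

In code, the same pipeline is four calls:

```r
library(momage)
truth  <- default_truth()
lt     <- simulate_life_table(default_vital_rates(),
                              cohort_design(seed = 1))
vital  <- evaluate_vital_rates(fit_weibull(lt)$params,
                               fit_coale_trussell(lt)$params)
sc     <- scenario_set(vital)
ltre(sc$models$B, sc$models$B_r)
```

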