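# countpref

Hierarchical Bayesian analysis of replicated choice count data.

## The problem

Choice experiments in ecology and behaviour produce count tables: J
replicates (one female butterfly per oviposition arena, one cage, one
feeding station, ...) each distribute some total number of observations
(eggs laid, visits, deaths, ...) over the same K categories (host plants,
substrates, treatments).  The quantity of interest is *preference* — at the
level of each individual and of the population — yet the tests usually
applied (Friedman, Quade, ANOVA on transformed proportions) never estimate
it: they return a p-value about mean differences, ignore that a replicate
with 40 eggs carries more information than one with 5, and say nothing about
among-individual variation.

`countpref` implements the hierarchical Bayesian alternative.  Each
replicate's counts are multinomial with its own preference vector
p<sub>j</sub>, and those vectors are drawn from a population-level Dirichlet
whose parameter is decomposed as w·q:

- x<sub>j</sub> | p<sub>j</sub> ~ Multinomial(n<sub>j</sub>, p<sub>j</sub>)
- p<sub>j</sub> | q, w ~ Dirichlet(w·q)

with q the population mean preference (on the simplex) and w > 0 a
concentration, inversely proportional to the among-individual variance.  A
flat Dirichlet prior on q and a uniform prior on w complete the model.
Fitting is by Metropolis-within-Gibbs MCMC (exact conjugate Gibbs draws for
every p<sub>j</sub>, Metropolis–Hastings for q and w) with a compiled core.
For two-choice designs the model reduces to a beta-binomial hierarchy.

On top of the fit the package provides:

- posterior summaries and credible intervals for q, w, and every
  individual's preference (`summarize_chain`, `individual_variation`);
- pairwise posterior exceedance probabilities among choices — the Bayesian
  analogue of a post-hoc test (`pairwise_probabilities`);
- DIC model comparison: equal-preference (constrained) vs free-preference
  models (`compare_constrained`), and population grouping schemes in which
  populations in a group share one (q, w) (`fit_grouped`, `rank_schemes`);
- the classical comparators on the same tables (`friedman_test`,
  `quade_test` with total-count or classical block weights,
  `arcsine_anova`);
- a synthetic-data generator and calibration/recovery studies
  (`generate_dataset`, `run_null_calibration`, `run_recovery_study`).

## A worked example

```r
library(countpref)

# a simulated population with preference hierarchy q = (0.6, 0.3, 0.1)
# and moderate individual variation (w = 10): 20 females, 3 host plants
tab <- generate_dataset(sim_config(pop_q = c(0.6, 0.3, 0.1), pop_w = 10,
                                   seed = 2))
ch <- run_chain(tab, config = mcmc_config(seed = 5))
summarize_chain(ch)
#> Population preference (posterior mean and 95% CI):
#>   choice1      0.61 (0.52, 0.68)
#>   choice2      0.29 (0.22, 0.36)
#>   choice3      0.11 (0.06, 0.16)
#> Concentration w: 10.20 (4.82, 19.34)
```

The population mean preference is recovered (truth 0.60 / 0.30 / 0.10, all
inside the intervals), and the concentration posterior (mean 10.2) matches
the generating w = 10: individuals vary around the population mean but are
not polarized.

```r
pairwise_probabilities(ch)
#> P(row choice preferred over column choice):
#>         choice1 choice2 choice3
#> choice1       0       1       1
#> choice2       0       0       1
#> choice3       0       0       0
```

Every ordered pair is separated in (essentially) all post-burnin draws: the
posterior probability that the hierarchy is choice1 > choice2 > choice3 is
indistinguishable from 1 — the analogue of all post-hoc comparisons being
significant.

```r
compare_constrained(tab, config = mcmc_config(n_steps = 8000, burnin = 2000,
                                              seed = 7))
#> Constrained DIC:   133.95
#> Unconstrained DIC: 93.99
#> Delta (constrained - unconstrained): 39.96 (favors the unconstrained model)
```

The free-preference model beats the equal-preference model by ~40 DIC units
— far beyond the ~8-unit null band (see below), so the preference is real by
this criterion too.

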