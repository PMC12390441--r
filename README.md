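# fluxbmd

Toxicogenomic dose-response studies measure how a chemical shifts the
liver transcriptome, but pathway-enrichment readouts ignore the
stoichiometric coupling between metabolic reactions. `fluxbmd` closes that
gap for dose-response designs: it integrates each animal's gene expression
with a genome-scale metabolic model (GEM) to infer a per-animal flux
distribution, aggregates fluxes into metabolic subsystem activities,
scores dose-dependent alterations against controls, and estimates the
benchmark dose (BMD) — the exposure at which each metabolic subsystem
first departs from its control state. It is aimed at computational
toxicologists and systems biologists who want pathway-level points of
departure from transcriptomic dose-response data.

## The model at the core

Given a stoichiometric matrix $S$ with flux bounds, steady state confines
the fluxome to the polytope
$\mathcal{P} = \{v : Sv = 0,\ LB \le v \le UB\}$. Gene expression is
mapped to per-reaction weights $g_i$ through gene-protein-reaction rules
(AND = min over complex members, OR = sum over isozymes), and the fluxome
is the maximum-entropy point of the polytope:

$$\hat v \;=\; \arg\min_{v \in \mathcal{P}}\; \sum_i P_i \log \frac{P_i}{Q_i},
\qquad P_i = \frac{v_i}{\sum_j v_j},\; Q_i = \frac{g_i}{\sum_j g_j}.$$

No cellular objective function is assumed. Per subsystem and animal, the
activity is the mean absolute flux over the subsystem's reactions,
normalized by the animal's total absolute flux. Alterations are scored as
$z = (\mu_\text{dose} - \mu_\text{control}) / \sigma_\text{control}$, and
each (subsystem, chemical, sex) series is fed to continuous BMD modeling:
five model families (linear, polynomial, power, hill, exponential) fitted
by maximum likelihood, benchmark response of one control SD,
profile-likelihood BMDL/BMDU, viable/questionable/unusable classification,
and a highest-dose-dropping refit loop.

A synthetic-data module (toy GEMs with subsystems and GPRs, the full
multi-chemical study design, dose-responsive log2 expression with known
effects, and a noiseless ground-truth BMD oracle) makes the whole pipeline
testable end to end without any external data.

## Worked example

```r
library(fluxbmd)
library(dplyr)

net <- make_toy_network(n_subsystems = 4, reactions_per_subsystem = 5,
                        seed = 1)
net
#> <metabolic_network> 26 reactions, 18 metabolites, 38 genes
#>   subsystems: 6

design <- make_design(default_dose_grids()["6:1 FTOH"], sexes = "male")
es <- simulate_expression(design, net,
  effects = list(effect_spec("subsystem_A", e_max = 3, d50 = 50, h = 1.5)),
  seed = 3)

cohort <- infer_cohort(net, es)
cohort
#> <flux_cohort> 55/55 samples solved on 26 reactions

activity <- subsystem_activity(cohort) |> filter_subsystems(net)
z <- z_scores(group_means(activity, es$metadata))
filter(z, subsystem == "subsystem_A", dose >= 37)
#> # A tibble: 4 x 8
#>   subsystem   chemical sex    dose     z control_mean control_sd     n
#> 1 subsystem_A 6:1 FTOH male     37  13.8       0.0431    0.00125     5
#> 2 subsystem_A 6:1 FTOH male    111  23.8       0.0431    0.00125     5
#> 3 subsystem_A 6:1 FTOH male    333  28.6       0.0431    0.00125     5
#> 4 subsystem_A 6:1 FTOH male   1000  29.6       0.0431    0.00125     5

bmd <- bmd_screen(activity, es$metadata) |> filter_extrapolated()
select(bmd, subsystem, family, bmd, bmdl, bmdu, status)
#> # A tibble: 4 x 6
#>   subsystem   family        bmd  bmdl  bmdu status
#> 1 subsystem_A hill         3.91  3.64  4.23 viable
#> 2 subsystem_B exponential  7.99  6.63  9.64 viable
#> 3 subsystem_C exponential  8.27  6.49 10.5  viable
#> 4 subsystem_D hill         6.04  3.92  7.33 viable
```

Reading the output: the simulated chemical up-regulates the genes of
`subsystem_A` with a half-effect dose of 50 mg/kg, and its activity climbs
to ~30 control SDs at the top dose. The BMD screen places the onset of
alteration at 3.9 mg/kg (95% interval 3.6-4.2) with a hill model. The
other subsystems respond indirectly — activities are shares of total flux,
so a rising pathway depresses the others — and receive correspondingly
later BMDs.

`run_pipeline(pipeline_config(...))` performs all stages (including PCA
per chemical and sex, most-altered set algebra, Mann-Whitney flags,
correlation maps, and a wide BMD summary with blanks for "no viable
model") and writes the artifact bundle to a directory;
`inst/scripts/fluxbmd` wraps it for the shell. Real data enter through
`load_network()` (SBML Level 2/3 with fbc, groups, or legacy notes) and
`read_expression()` (gene x sample log2 tables with sample metadata).

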