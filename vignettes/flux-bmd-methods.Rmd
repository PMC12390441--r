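---
title: "Transcriptome-constrained flux inference and benchmark-dose analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-constrained flux inference and benchmark-dose analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fluxbmd` estimates, for each animal in a toxicogenomic dose-response
study, a genome-scale metabolic flux distribution consistent with that
animal's liver transcriptome, aggregates the fluxes into metabolic
subsystem activities, and asks at which dose a chemical begins to alter
each subsystem — a continuous benchmark dose (BMD) per pathway. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, what the bundled synthetic-data generator does and does
not emulate, and the numerical choices a user auditing results should know
about.

## Maximum-entropy flux inference

A genome-scale metabolic model (GEM) supplies a stoichiometric matrix $S$
($M$ metabolites $\times$ $N$ reactions), flux bounds, and
gene-protein-reaction (GPR) rules. Under the steady-state assumption the
feasible fluxomes form the polytope

$$\mathcal{P} = \{ v \in \mathbb{R}^N : S v = 0,\; LB \le v \le UB \},$$

with exchange (boundary) reactions opened to $\pm 1000$ mmol/gDW/h by
convention. Gene expression is mapped to a per-reaction weight $g_i$
through the GPR rules — AND (enzyme complex) takes the minimum of its
operand values, OR (isozymes) their sum — and the fluxome is the point of
$\mathcal{P}$ whose flux *proportions* are closest, in Kullback–Leibler
divergence, to the expression proportions:

$$\min_{v \in \mathcal{P}} \; D_{KL}(P \,\|\, Q), \qquad
  P_i = \frac{v_i}{\sum_j v_j}, \quad Q_i = \frac{g_i}{\sum_j g_j}.$$

No biomass or other cellular objective is assumed; the expression pattern
itself constrains the flux state. Because $P$ is a probability vector,
every reversible reaction is first split into nonnegative forward and
backward parts (`split_reversible()`); net fluxes are recovered by
subtraction afterwards.

**How it is solved.** On the unit-total-flux simplex the stationarity
conditions give $P_i \propto Q_i \exp(-(S^\top\lambda)_i)$, where the
metabolite multipliers $\lambda$ minimize the smooth convex dual
$\log \sum_i Q_i e^{-(S^\top\lambda)_i}$. A damped Newton iteration with a
small Levenberg ridge drives the steady-state residual $\max_i |S P|_i$
below $10^{-9}$ (typically 6–8 iterations). When a box constraint beyond
nonnegativity is active — a forced positive lower bound, or an upper bound
small enough that no rescaling of the proportions fits inside the box —
the solution is refined by a log-barrier optimization over null-space
coordinates (`constrOptim`). Solved fluxomes are validated, never assumed:
a result with base-network residual above $10^{-6}$ is reported as failed.

**Scale convention.** The objective depends on $v$ only through
proportions, so the physical flux scale is conventional; fluxomes are
reported with $\sum v = 1$ on the split network. Every downstream
statistic divides by the sample's total absolute flux, so this convention
cancels.

**Numerical guards.** A floor of $\varepsilon = 10^{-9}$ inside all
logarithms keeps the objective defined at zero flux; reactions with
$UB \le 0$ are excluded from the support; reactions with no usable
expression (empty GPR, or all genes unmeasured) receive the sample mean of
the measured genes so that $Q$ stays strictly positive, and the affected
reactions are recorded per sample.

## Subsystem activities and group statistics

For each sample the activity of subsystem $s$ with $r$ reactions is the
mean absolute net flux over its reactions divided by the sample's total
absolute flux — a dimensionless share that is invariant to uniform
rescaling of the fluxome. Subsystems are then filtered: bookkeeping
labels (miscellaneous, artificial reactions, pool reactions, biomass,
exchange, isolated, transport; matching is case-insensitive and the list
is configurable) are dropped when their reactions are associated with
fewer than two distinct genes, as are subsystems whose activity does not
vary across samples (SD = 0). The removals are returned as an audit table.

Group statistics follow the study design: controls are pooled per
(chemical, sex); each dose group is summarized by its mean activity; and
alterations are scored as

$$z = \frac{\mu_{s,\text{dose}} - \mu_{s,\text{control}}}{\sigma_{s,\text{control}}},$$

using the sample SD ($n-1$ denominator) of the pooled controls. A zero
control SD yields a flagged `NA`, never a silent drop. Two-sided
Mann–Whitney U tests compare each dose group against its controls (exact
null distribution for total $n \le 20$, normal approximation otherwise);
flags use raw $p < 0.05$ by default, with a `p.adjust` method switch for
users who prefer multiplicity control.

## PCA, most-altered subsystems, and correlation maps

Per (chemical, sex), samples (rows) by subsystem activities (columns) are
centered, standardized by default (activities span scales; a switch turns
standardization off), and decomposed. Component signs are fixed by making
each loading vector's largest-magnitude entry positive, so results are
reproducible run to run. "Most-altered" subsystems are the top $k$
features by absolute PC1 loading (ties broken lexicographically), $k = 10$
per chemical and sex and $k = 15$ for the control-only analysis. Per
chemical, male and female top lists are unioned; set algebra across
chemicals (union, pairwise and all-chemical intersections) summarizes
which alterations are shared. Correlation maps are Pearson correlations
(Spearman available) between group mean activity vectors over the
subsystem dimension.

One ambiguity deserves note: the most-altered lists could alternatively be
derived from a low-dose/high-dose contrast axis rather than PC1. We use
PC1 loadings of the per-(chemical, sex) PCA; in the synthetic studies the
dose gradient dominates PC1, making the two readings equivalent there.

## Benchmark-dose modeling

Per (subsystem, chemical, sex), the per-animal activities at each dose are
continuous dose-response data. Five model families are fitted by maximum
likelihood under normal errors with constant variance:

| family      | mean function | notes |
|-------------|------------------------------|-------|
| linear      | $a + b d$ | closed-form LS |
| polynomial  | $a + \sum_j b_j d^j$ | degree 2 default; coefficients restricted to one (adverse) direction, the standard continuous-model default — an unrestricted quadratic chases non-monotone noise |
| power       | $a + b d^g$, $g \in [1, 18]$ | profile grid over $g$ + 1-D refinement |
| hill        | $a + b\, d^g / (c^g + d^g)$, $g \ge 1$ | profile grid over $(c, g)$ + simplex refinement |
| exponential | nested variants $a e^{\pm b d}$, $a e^{\pm (b d)^g}$, $a(c - (c{-}1)e^{-b d})$, $a(c - (c{-}1)e^{-(b d)^g})$ | best variant by AIC |

All optimizations start from deterministic grids, so fits are exactly
reproducible. Goodness of fit is a likelihood-ratio test of the fitted
model against the saturated dose-group-means model (chi-square, df =
groups minus mean parameters).

**Benchmark response.** The BMD solves $|m(d) - m(0)| = 1 \cdot \sigma$.
By default $\sigma$ is the *control-group* SD — the benchmark response is
defined relative to the controls, matching the z-score convention used
throughout. This choice matters: subsystem activities are heteroscedastic
(a down-regulated subsystem's between-animal SD shrinks with dose), so the
pooled residual SD of a constant-variance fit systematically
underestimates the control-level variability and biases BMDs low. The
residual-SD convention remains available via
`bmd_options(sigma_source = "model")`. The linear and power families have
closed-form BMDs ($\sigma/|b|$ and $(\sigma/|b|)^{1/g}$); other families
use bracketed root finding on a 512-point grid refined by `uniroot`.

**Confidence limits.** BMDL and BMDU are two one-sided 95% limits from the
profile likelihood: the scale parameter is eliminated through the
benchmark-response equation so the BMD becomes a model parameter, the
remaining parameters are re-optimized at each candidate BMD, and the
interval endpoints solve $2(\hat\ell - \ell_p(b_0)) =
\chi^2_{1,0.90}$. With a control-referenced BMR the benchmark response is
a fixed quantity inside the profile. When the constrained profile cannot
reproduce the unconstrained maximum (a reparameterization failure, e.g.
for a non-monotone fit whose crossing direction differs from its endpoint
trend), the bounds are reported as not found rather than as a spuriously
tight interval. An upper profile that never reaches the cutoff within 100
times the top dose is likewise "not found" — an unbounded BMDU.

**Viability and the dropping loop.** Each fit is classified: *unusable*
(no convergence or no BMD in the tested range), *questionable*
(goodness-of-fit $p \le 0.10$, BMD/BMDL $> 20$, BMDL below one tenth of
the lowest nonzero dose, or BMDL not found), else *viable*; thresholds are
configurable and recorded. Among viable fits the lowest AIC wins. When no
fit is viable the highest dose is dropped and all families are refitted;
once dropping reaches three remaining dose levels the series is reported
as "no viable model" — results obtained at the floor are not accepted
(data *supplied* with only three dose levels, where no dropping ever
occurred, are still fitted once). Finally, results whose BMD or BMDU lies
outside the doses given to the fit describe the model curve rather than
the exposure range and are filtered out, with an audit trail.

## The synthetic-data generator

The generator exists so the whole pipeline can be exercised end to end
with known ground truth and no external data.

* `make_design()` enumerates the study structure: per chemical and sex, 10
  controls plus 9 nonzero dose groups of 5 animals (55 samples per
  chemical-sex analysis; 135 exposed females across the three default
  chemicals), over the built-in dose grids (0–1000 mg/kg for two
  chemicals, 0–475 mg/kg for the third).
* `make_toy_network()` builds a connected GEM in miniature: a shared
  uptake exchange and transport into a hub metabolite, one linear pathway
  per subsystem with an internal branch point, a secretion exchange per
  pathway, and a 1–3 gene GPR on every internal reaction. Tens of
  reactions keep a flux solve in the low milliseconds, so full synthetic
  studies run at desk scale. Networks serialize to SBML Level 3 (fbc +
  groups) with byte-deterministic output per seed.
* `simulate_expression()` multiplies each affected gene's log-normal
  baseline (median 100 counts, CV 1 across genes) by a saturating
  dose multiplier $m(d) = 1 + (E_{\max}-1)\, d^h/(d_{50}^h + d^h)$
  (reciprocal for down-effects) and by log-normal animal noise with mean 1
  and CV 0.10, emitting log2-scale tables. The defaults
  ($E_{\max} = 3$, $d_{50} = 50$ mg/kg, $h = 1.5$, noise CV 0.10) are the
  reference effect conditions used by the recovery analyses; the
  saturating form produces Hill-like subsystem dose-responses without
  privileging any single fitted family.
* `true_bmd_oracle()` defines ground truth through the same one-SD
  criterion the BMD engine targets, but on noiseless curves: it runs flux
  inference and aggregation on the expected (noise-free) expression over a
  fine log-spaced dose grid, estimates the control-level activity SD from
  Monte-Carlo noise replicates at dose 0, and interpolates the first dose
  at which the noiseless activity departs from control by one SD. Effects
  on one subsystem shift the activity *shares* of all subsystems, so
  indirectly responding subsystems also acquire a well-defined true BMD;
  recovery is therefore a genuine parameter-recovery test including flux
  coupling.

What the generator does **not** emulate: TempO-Seq probe/count
distributions, transcriptome-wide extrapolation, sex-specific baselines,
correlated gene modules beyond GPR co-membership, or genome-scale network
size. Passing tests demonstrate that the algorithms recover known signals
under the stated noise model at the study's design — not that a
real-data analysis is free of upstream normalization or model-curation
issues.

## Problem sizes and runtime choices

The validation analyses use toy networks of 4 subsystems x 5 reactions
(26 reactions, 18 metabolites, ~38 genes): 25 independent studies (100
subsystem-chemical pairs) for BMD recovery, 50 replicate null studies for
false-positive calibration, and brute-force grid searches over polytopes
with at most 3 free flux dimensions for solver verification. These sizes
make each full study solve in roughly a second while leaving every
statistic at the design's actual group sizes (10 controls, 5 per dose).

## Known limitations

* The KL objective couples the two halves of a split reversible reaction
  only through stoichiometry; maximum entropy can place flux on both
  halves (a futile pair), which inflates the absolute-flux activity of
  subsystems rich in reversible reactions. The pipeline's statistics use
  net fluxes, which removes the pair's net contribution.
* Constant-variance likelihoods are used for fitting even though
  activities are heteroscedastic; the control-referenced BMR compensates
  for the resulting bias in the benchmark response, but the
  goodness-of-fit test retains the constant-variance assumption. A
  power-of-mean variance model is a natural extension.
* Profile-likelihood bounds re-optimize a non-convex likelihood at every
  candidate BMD; with derivative-free restarts this occasionally fails on
  already-marginal fits, which is then reported (and classified) as
  "bounds not found" rather than silently interpolated.
* With ~8 candidate fits per drop level and up to seven drop levels, the
  dropping loop performs multiple comparisons; the viability rules keep
  the null viable-and-in-range rate below 10% in calibration runs, but
  individual spurious BMDs near the top of the dose range remain possible.
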