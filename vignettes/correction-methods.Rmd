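---
title: "Correcting enzyme turnover numbers across conditions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting enzyme turnover numbers across conditions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein-constrained genome-scale metabolic models (pcGEMs) couple each
reaction's flux to the abundance of its catalysing enzyme through the
turnover number kcat: a flux `v_j` (mmol gDW⁻¹ h⁻¹) through a reaction
catalysed by enzyme `i` consumes at least `v_j / (3600 kcat_ij)` mmol gDW⁻¹
of that enzyme (kcat in s⁻¹). In vitro kcat values systematically
underestimate in vivo capacity, so a pcGEM parameterised with them and
constrained by measured enzyme abundances typically cannot reach the
measured growth rate. This package fits an additive, non-negative
correction `delta_i` (s⁻¹) per enzyme, shared across all conditions, by a
single linear program over all experiments at once.

## The correction program

Each enzyme is assigned a single turnover number over all reactions it
catalyses, `kcat_i^min = min_j kcat_ij`. For every training condition `j`
with measured abundances `E_i^j` (mmol gDW⁻¹, for enzymes measured in
*every* condition, the set `M`) and measured growth rate `mu_j` (h⁻¹), the
program constrains a per-condition flux vector `v^j` by steady state
(`N v^j = 0`), the condition's nutrient uptake bounds, and per-enzyme
capacity

    sum_{r : i in GPR(r)} v_r^j  <=  3600 (kcat_i^min + delta_i) E_i^j ,

and minimises

    (1/|C|) sum_j omega_j  +  (lambda/|M|) sum_i delta_i ,

where `omega_j` is the relative growth error of condition `j` and `lambda`
weights fit against total correction. Corrections are bounded by a maximal
fold change (`delta_i <= (epsilon - 1) kcat_i^min`, `epsilon = 1e5`), an
absolute ceiling (`kcat_i^min + delta_i <= 5.75e7 s^-1`, the largest value
reported for any enzyme), and each `omega_j <= theta = 0.6`.

Two formulation details are deliberate choices:

* **Error linearisation.** Coupling `omega` to the error via
  `v_bio * omega >= |mu - v_bio|` is bilinear in two decision variables. The
  program instead uses the linear surrogate `mu * omega_j >= |mu - v_bio^j|`
  (constant measured denominator). At the relevant optimum
  (`v_bio ~ mu`) the two definitions agree to first order; both
  conventions are reported post hoc, and the measured-denominator form is
  the reporting definition throughout.
* **Capacity indexing.** The single-kcat assumption is read as a
  *per-enzyme* capacity over all reactions the enzyme catalyses. The
  per-reaction reading (summing fluxes of all enzymes of one reaction on
  the left) is dimensionally redundant once each split reaction copy has a
  single catalyst; after the directional and isozyme splitting performed
  here the two readings coincide reaction-wise, and the per-enzyme sum is
  the binding form.

The protein-pool row (`sum_i MW_i e_i <= Ptot f sigma`) and the usage
coupling of enzymes *not* in `M` are part of the condition models used for
prediction, but not of the correction program itself, which constrains
only the measured enzymes — corrections are identifiable only where
abundance data exist.

### Numerical choices

All programs are solved by a dense bounded-variable two-phase primal
simplex implemented in the package (`solve_lp()`), with row equilibration,
Dantzig pricing, a Bland fallback on stalls, periodic refactorisation, and
a default feasibility tolerance of `1e-9`. An industrial solver's default
dual tolerance (~1e-7) is too loose here: at `lambda = 1e-7` the reduced
costs of the correction columns are of order `1e-8` and would be treated
as zero, returning arbitrary alternative optima. The in-package solver
prices reliably down to `lambda/|M| ~ 1e-12`; below that the solution is
made deterministic by a second stage that fixes the attained objective and
minimises `sum(delta)`. This minimal-total-correction tie-break is applied
after every solve; it selects, among alternative optima, the solution a
parsimony argument prefers, and it makes the regularisation path
`Delta(lambda)` monotone by construction rather than by numerical
accident. Every returned solution is re-verified against all constraints
by an independent checker at tolerance `1e-6`.

Capacity rows are normalised by their largest coefficient before solving
(abundances span decades); this is configurable off
(`scale_rows = FALSE`).

## Model construction

`build_pc_model()` splits reversible reactions into irreversible pairs
(suffixes `_fwd`/`_rev`) and OR-type GPR rules into one reaction copy per
isozyme alternative (`_izN`), each copy inheriting the parent's bounds
(the standard arm convention; a positive lower bound is kept on the first
copy only). AND rules couple every subunit's usage to the same flux;
subunit copy numbers default to 1 and can be supplied per
(enzyme, reaction). Units: kcats are stored and reported in s⁻¹;
constraint matrices use h⁻¹ (factor 3600) so fluxes stay in
mmol gDW⁻¹ h⁻¹.

Condition data enter as an abundance matrix plus metadata. Replicates are
aggregated as the per-protein **maximum** abundance and the **mean**
growth/exchange rate. A missing total protein content is filled with the
maximum measured across the other conditions; unmeasured medium nutrients
default to an uptake bound of 1000 mmol gDW⁻¹ h⁻¹. Both policies are
explicit and logged, never silent. Scenario (i) uses only the pool cap and
default uptake bounds; (ii) adds measured uptake rates; (iii) additionally
bounds each measured enzyme's usage by its abundance. The pool cap
`Ptot f sigma` spans measured *and* unmeasured enzymes, so the enzyme mass
fraction `f` needs no per-scenario adjustment. Growth-associated
maintenance is carried as a per-condition input coefficient; in the toy
networks used here the biomass reaction has no ATP term, so it is recorded
but inert.

## Selecting lambda

`presto_crossval()` runs 3-fold cross-validation with 10 repetitions over
a log-spaced grid (default one point per decade, `1e-14` to `1e-1`; the
grid density is a package choice, only the interval ends are fixed by the
method). Training folds fit corrections; the held-out fold is scored by
predicting growth with the corrected kcats under the
pool-plus-measured-uptake scenario — without abundance constraints, which
counteracts overprediction in the proteomics-free setting. The
per-iteration validation error is the mean over all validation conditions
of that iteration, and the per-iteration total correction is the mean over
its folds. The score per lambda is the average over iterations of
(min-max-scaled error) x (log10-scaled total correction); degenerate
scalings contribute zero, and a zero total correction is floored at
`1e-12` before the logarithm. The selected lambda sits at the first sign
change of the second numerical gradient of the score (uniform log10
spacing, one-sided differences at the ends), scanning from the largest
lambda; without any sign change the argmin is used and logged.

On noise-free synthetic data this selection is intentionally degenerate:
once the deflated kcats are corrected, held-out conditions generated by
the same true model are predicted exactly, the validation error vanishes
for every lambda, and the fallback picks the smallest grid value. That is
the correct answer for clean data — the trade-off only becomes informative
when conditions are mutually inconsistent, as real proteomics data are.
Passing the synthetic tests therefore demonstrates the machinery, not the
hardness of real model selection.

## Precision of the corrections

`delta_variability()` fixes each condition's error variable within +/-1%
of its optimum and the total correction within +/-1e-3 (internal kcat
units, s⁻¹ — the tolerance is attached to `sum(delta)`, so it is a kcat
quantity) and minimises/maximises each `delta_i` over the remaining
polytope. `sample_corrections()` draws candidate vectors uniformly within
the per-enzyme intervals and projects each onto that polytope by
minimising the L1 distance (split auxiliary variables). The projection
does not produce a uniform sample *on* the polytope — it reproduces the
published scheme as described, interval draw plus distance-minimal
projection. Ties are resolved by the deterministic simplex vertex; an
optional lexicographic refinement (`tie_break = "lex"`) returns the
lexicographically least optimal vertex for exact reproducibility of
degenerate projections. Per-enzyme precision is summarised as the mean
absolute deviation of sampled corrected kcats around their mean, plus the
25th/75th percentiles.

## The control-coefficient baseline

The comparator heuristic scores each enzyme by the relative growth gain
when its turnover numbers are multiplied by 1000 in the pool-only
condition model, then replaces the top-ranked enzyme's kcats by the
maximum value reported for that enzyme across organisms (never
decreasing), iterating until predicted growth is within 10% of the
measurement or no coefficient exceeds 0.001 (ties broken by enzyme
identifier; at most one pass over the enzyme set). The relative-change
coefficient is the default ("scoring the effect" does not fix a formula);
an absolute-change variant is available. Condition-specific corrected
models are combined by `aggregate_union_max()` (per-reaction maximum).

## Negative corrections (second stage)

Positive corrections cannot reduce pool-only *over*-prediction, so an
optional second stage searches for non-positive corrections on the
measured set that minimise the mean pool-only error while leaving the
abundance-constrained errors of the first stage unchanged. Because
pool-only growth is itself an LP value, its dependence on the kcats is
piecewise linear; the stage solves a short sequence of linearised programs
(growth responses estimated by downward secants re-evaluated at each
iterate, a trust region of half the current kcat, an exact linear
achievability block that preserves the first-stage growth under the
abundance-capacity constraints) with a line search on the true FBA error,
and finally re-verifies preservation by FBA, halving the corrections until
the abundance-scenario errors change by at most 1e-6. Positive and
negative corrections are never sought in one objective — a joint L1
objective would simply drop the negative part wherever growth is
underpredicted. Reduced values are flagged as apparent catalytic rates:
they are averages over the considered conditions, not
condition-independent turnover numbers.

## Enrichment

Corrected enzymes are tested for pathway over-representation against the
background of enzymes measured in all conditions, with the standard
one-sided hypergeometric upper tail `P(X >= x)`; terms with fewer than two
corrected enzymes are excluded *before* testing and Benjamini-Hochberg
correction is applied over the tested terms only. A literal variant of the
tail sum whose index starts at 1 (thereby retaining the probability of
zero draws) is provided as `mode = "as_printed"` for comparability; the
standard tail is the default because the literal form is not a p-value for
the one-sided alternative (it exceeds the tail mass by `P(X = 0)`).

## The synthetic benchmark

`make_toy_network()` builds a substrate-uptake -> linear-chain ->
parallel-routes -> biomass topology with one enzyme per reaction, one
two-subunit complex on the second chain step and one isozyme pair on the
first parallel route; kcats are log-uniform on [0.1, 100] s⁻¹ and
molecular weights uniform on [20, 200] g mmol⁻¹. `simulate_conditions()`
draws a substrate uptake bound per condition (uniform on
[1, 10] mmol gDW⁻¹ h⁻¹), solves the true-kcat model, and exports the
optimum as the measured growth and the optimal usage — times a headroom
factor (default 1.2) and multiplicative lognormal noise — as the measured
abundances. The noise factor is floored so every abundance still supports
the optimal flux: measured growth stays attainable by the true model under
abundance constraints, which is the premise of a correction method (kcats
too low, not data inconsistent). Enzymes idle at the optimum receive a
small baseline abundance (5% of the smallest used abundance): real
proteomes have no exact zeros, and the baseline keeps idle routes
correctable in principle. Pool parameters are set so the pool holds with
slack 1.5 at the optimum (f = sigma = 0.5) — the abundance bounds, not the
pool, are the binding constraints, which is the regime the correction
method targets. `deflate_kcats()` divides chosen enzymes' kcats by factors
> 1 and records the exact correction that restores them.

What the generator does **not** emulate: heterogeneous growth media and
carbon sources, measurement error in growth rates, systematic biases
between proteomics platforms, promiscuous enzymes with widely different
per-reaction kcats, and thermodynamic or regulatory effects. Ground-truth
recovery is asserted only for enzymes whose capacity constraint binds in
at least one condition; corrections for enzymes that never limit flux are
unidentifiable from growth data, and the L1 penalty correctly leaves them
at zero.

Problem sizes used throughout the tests and the acceptance analysis — toy
networks of 6-9 reactions, 6-15 conditions, 8 enzymes, 1,000 sampled
corrections, 10 cross-validation repetitions — are chosen so the full
pipeline, including the brute-force grid oracles, runs in minutes on one
CPU while still exercising every structural feature (complexes, isozymes,
reversible splitting, parallel routes).

## Known limitations

* The dense simplex targets the package's toy-to-moderate problem sizes
  (hundreds of variables); genome-scale corrections would need a sparse
  industrial LP backend behind the same `solve_lp()` interface.
* The negative-correction stage is a linearised sequential scheme with a
  post-hoc preservation guarantee; it returns a conservative (possibly
  sub-optimal) set of reductions when pool-only growth responds
  non-smoothly.
* Corrections are additive per enzyme and shared across conditions by
  design; condition-specific kinetic effects (temperature, saturation
  shifts) are outside the model, which is why temperature-stress
  conditions should be excluded from the input set.
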