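---
title: "Life-history-structured allometric trophic network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-history-structured allometric trophic network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atnfish)
```

## The question the model addresses

Fish grow across orders of magnitude in body mass during their lives, and
with body mass change their diets, their predators and their metabolic
efficiency. Classical food-web dynamics models collapse each species into a
single node, so this ontogeny is invisible to them. `atnfish` implements a
food-web modelling pipeline in which fish species are resolved into
life-history stages — separate nodes, sized by a growth curve and wired
into the web by the same niche rules as everything else — and in which an
annual growth/reproduction step moves biomass between the stages. Running
the same web with and without stage structure, and with and without the
stage linkage, separates the effect of merely *adding nodes* from the
effect of *life-history dynamics*.

## Structural webs: the niche model

A web of `S` species at target connectance `C` (realized connectance is
directed links over `S^2` ordered pairs, cannibalistic self-links counted)
is generated by the niche model. Each species receives

* a niche value `n_i ~ Uniform(0, 1)`, read as a relative body-size rank;
* a diet-range fraction `x_i ~ Beta(1, beta)` with
  `beta = (1 - 2C) / (2C)`, so that the expected fraction of the niche
  axis covered by diets matches `C`; the range width is `r_i = x_i n_i`;
* a range center `c_i ~ Uniform(r_i / 2, n_i)`.

Species `i` eats exactly the species whose niche value falls inside
`[c_i - r_i/2, c_i + r_i/2]`. Note that the upper end of the interval may
exceed `n_i` (when `c_i + r_i/2 > n_i`); the membership test uses the
interval exactly as defined, with no post-hoc clamping.

Webs are rejection-sampled until four realism rules pass
(`validate_web()`): no isolated species; every species has an autotroph
down its food chain (a species whose only prey is itself counts as neither
basal nor connected to a basal chain); the web is one weak component; and
realized connectance is within a relative tolerance (default 5%) of the
target. The tolerance, and whether self-links count toward `L`, are not
pinned by the model's tradition; both are explicit configuration here
(self-links do count, `S^2` in the denominator).

```{r webgen}
web <- generate_valid_web(S = 30, C = 0.15, seed = 42)
web
```

## Trophic annotation and allometric scaling

Trophic positions use the short-weighted metric `T = (T1 + T2) / 2`:
`T1` is one plus the shortest prey-path to a basal species (self-links
ignored — a loop is never a shortest path), and `T2` solves the linear
system `T2_i = 1 + mean(T2_j over prey j)` with basal species fixed at 1.
Feeding loops, including cannibalism, are handled exactly by the linear
solve; cannibalistic links are retained in the prey average (they are
links). Webs whose `T2` system is singular are rejected and regenerated
rather than patched.

Guilds: basal species are autotrophs; the three consumers with the highest
`T` are fish; everything else is an invertebrate. Ties at the fish cutoff
break by (higher `T`, higher `n`, lower node id) — deterministic and
seed-independent. Relative body mass follows `M = Z^(T - 1)` with the
consumer-resource allometric ratio `Z = 100` by default, and mass-specific
metabolic rates follow the Kleiber-type allometry

```
x = 0                 (autotrophs)
x = 0.314 M^-0.15     (invertebrates)
x = 0.88  M^-0.11     (fish)
```

## Life-history stages

Each fish species is split into four stages (`t = 0..3`) sized by an
isometric von Bertalanffy curve `W(t) = W_inf (1 - exp(-K (t - t0)))^3`
with `K = 3 / t_max` and adults — stage `t_max`, which keeps the species'
original mass — at `W_max / W_inf = 0.9`. The curve's age offset is not a
free parameter: the two printed constraints pin it at
`t0 = t_max + log(1 - 0.9^(1/3)) / K` (for `t_max = 3`, `t0 ≈ -0.3666`
and the newborn stage sits at `W_0 / W_inf ≈ 0.0289`).

Wiring the stages into the web is genuinely under-determined by the
sources we build on, which defer the diet-split details to supplementary
material. The rule implemented (and exposed in configuration so
alternatives can be swapped in) is:

* the adult stage keeps the species' niche triple unchanged, so the
  species-level diet is preserved exactly;
* a younger stage of mass `W_t` gets trophic position
  `T = 1 + log_Z(W_t)` and a niche value from the web's own least-squares
  linear fit of `n` on `T` (clamped to (0, 1)); a web whose fit is
  degenerate (all `T` equal) is rejected;
* the stage reuses the species' range fraction `x_i = r_i / n_i`
  (`r_stage = x_i n_stage`) and draws its center
  `Uniform(r_stage / 2, n_stage)` from a species-deterministic sub-seed,
  so staging is reproducible given the web and master seed;
* the full adjacency is then rebuilt from the niche triples: stages may
  prey on other stages, including conspecific ones (the range decides —
  no special cannibalism exclusion), and are eaten by every consumer
  whose range contains their niche value.

A juvenile stage can end up with an empty diet; because the experiment
requires persistent fish, the default is to reject such webs and
regenerate (`on_empty_diet = "reject"`), with a permissive mode in which
the stage simply starves dynamically.

The annual transition is the biomass-conserving Leslie matrix: 90% of each
stage's biomass advances to the next stage, 10% remains, and 90% of the
terminal stage's biomass re-enters stage 0 as newborns. Every column sums
to 1, so species totals are conserved exactly at the step — a property the
test suite asserts to numerical tolerance.

## Seasonal bioenergetic dynamics

Within a 100-day growing season, biomasses follow the allometric
bioenergetic ODEs. Autotrophs grow logistically against one shared
carrying capacity and lose biomass to grazing; consumers balance
maintenance, intake and predation:

```
dB_i/dt = r_i (1 - sum_auto B_j / K) B_i - sum_j x_j y B_j F_ji e_ji
dB_i/dt = -fm x_i B_i + sum_j fa x_i y B_i F_ij - sum_j x_j y B_j F_ji e_ji
```

with the normalized functional response

```
F_ij = w_ij B_j^h / (B0_ij^h + sum_k c_kj p_ik B_k B0_kj^h + sum_l w_il B_l^h)
```

where `w_ij = 1/P_i` are uniform preferences, `p_ik` is the diet-overlap
fraction, `h` the Hill exponent, `B0` the half-saturation density and `c`
predator interference. Two deliberate choices deserve emphasis:

* **The efficiency placement in the loss term.** The growth equations as
  written above multiply the loss-to-predation term by `e_ji`, which
  departs from the older bioenergetic convention of dividing by it. The
  multiplicative form is the default (`loss_efficiency = "multiply"`);
  the conventional form is a one-line toggle, because the printed form
  may well be a typographic artifact of the lineage we reproduce.
* **`B0` and `c` defaults.** The tradition this model belongs to takes
  its half-saturation and interference constants from an empirical
  plankton parameterisation we could not reproduce as a table. The
  defaults are `B0 = 80` µgC/L uniformly and `c = 0` (no interference) —
  order-of-magnitude consistent with `K = 540` µgC/L — and both accept
  full node-by-node matrices. This is the largest quantitative
  uncertainty in the package: structural conclusions (which variant is
  more stable, how CV scales with mass) are robust to it in our tests,
  but absolute persistence fractions are not.

All remaining constants default to the standard set: `K = 540` µgC/L,
`r ~ N(0.9, 0.2^2)` truncated to `[0.6, 1.2]` d⁻¹ (drawn by inverse
transform), `y = 10` d⁻¹, `e = 0.45` on autotroph prey and `0.85`
otherwise, `h = 1.2`, `fa = 0.4`, `fm = 0.1`.

### Numerical choices

The derivative is evaluated in compiled C and integrated with `lsoda`
(via deSolve) at `rtol = 1e-6`, `atol = 1e-9`; the season is sampled
daily (101 points), which we read as reporting resolution rather than a
fixed-step mandate — halving the tolerances moves year-end biomasses by
less than 0.1% on fixture webs, which the suite asserts. Small negative
solver excursions are treated as zero biomass inside the derivative and
clamped in the reported trajectory. Extinction (biomass `< 1e-6` µgC/L,
set to exactly 0) is applied at season boundaries only; in the linked
variant the Leslie step runs after thresholding, so an extinct stage can
be revitalized by biomass aging into it. Between seasons nothing else
happens — no off-season mortality. A run is abandoned (and recorded as
such) if the solver fails or any biomass exceeds the blow-up ceiling
(`1e10` µgC/L).

```{r season}
aweb <- annotate_web(web)
staged <- insert_stages(aweb, stage_seed = 1)
set.seed(7)
traj <- run_simulation(staged, "linked", years = 10)
traj
```

## The three-model ensemble

`run_ensemble()` repeats, per replicate web: generate and validate a web
(regenerating on empty-diet staging), build the `original` / `unlinked` /
`linked` variants — which share the web, the growth-rate draws and the
species-level initial biomasses (`Uniform(5, 500)` µgC/L per species,
split equally over a fish's four stages so variants start from matched
totals) — and simulate 200 burn-in plus 100 analysis years each.

Summaries follow the conventions:

* **CV** is sample standard deviation over mean of the 100 annual
  (season-mean) biomass values, a ratio internally, a percentage when
  quoted.
* **Stabilization** has no closed-form definition in the lineage; here it
  is: burn-in completed, no blow-up during burn-in, and total fish
  biomass at the end of burn-in at or above the extinction threshold.
  The definition is configuration-exposed and reported with results.
* **Filters.** The preliminary filter keeps webs where at least one
  variant kept at least one fish species; the stringent filter requires
  every variant of the web to keep at least one fish species (stringent
  webs are a subset of preliminary webs — asserted as an invariant).
  Because the literature value's denominator is ambiguous, both the
  per-web fractions and the per-variant survivor-frequency table are
  reported.
* **Regressions.** Surviving fish species are pooled and four OLS fits
  relate mean ecosystem biomass, mean species biomass and their CVs to
  asymptotic mass `W_inf`. The predictor is `log10(W_inf)` by default:
  masses span six orders of magnitude, and the lineage's own normality
  checks could not hold on the raw scale (raw-mass fits are a toggle).
  Outlier rows with mass above `1e10` or a CV above 800% are removed
  before fitting. The fish columns analyse each species' own biomass;
  the run-total alternative is the `fish_scope` option.
* **Stage-size ordering.** Among runs with at least two surviving fish
  species: is the youngest stage of the largest species lighter than the
  adult stage of the smallest? Under the stage geometry
  (`W_0 ≈ 0.032 W_max`) this holds exactly when the adult mass ratio is
  below ≈ 31.

## What the generator does and does not emulate

The synthetic webs carry the structural signatures of real food webs that
the niche model is known to reproduce (interval diets, realistic degree
distributions, connectance control) and the bioenergetics carry empirically
grounded allometries. They do *not* emulate: environmental or demographic
stochasticity (the ODEs are deterministic given draws), seasonality beyond
the on/off growing season, species-specific life histories (every fish has
exactly four stages, the same maturity schedule and the same fecundity
weights), or empirically calibrated `B0`/`c` heterogeneity. Passing tests
therefore demonstrate internal correctness and the robustness of
*comparative* statements across model variants, not quantitative fidelity
to any real ecosystem.

## Problem sizes used in the checks

The package's own analyses (vignette, tests, acceptance script) use
500 webs for structural summaries and a 50-web by 3-variant by 300-year
ensemble for the dynamic summaries — sizes chosen so the full suite runs
on a single CPU in a few minutes while keeping Monte-Carlo error on the
reported fractions near the percentage point. The ensemble scales linearly
in webs and years; `run_ensemble()` takes both as arguments.

## Known limitations

* Absolute persistence fractions are sensitive to `B0`/`c`, which are not
  pinned by available sources (see above); comparisons across variants
  are the robust output.
* The stage diet-split rule is one documented choice among several
  defensible ones; alternatives can be implemented against the same
  `insert_stages()` surface.
* The Leslie step conserves biomass rather than modelling
  fecundity-weighted reproduction; variable stage counts and maturity
  schedules are out of scope.
* No fishing mortality, no stochastic forcing, no alternative structural
  models (cascade or generalized niche).
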