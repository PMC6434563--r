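# atnfish

Life-history-structured allometric trophic network (ATN) simulations for
aquatic food webs.

Most food-web dynamics models describe each species as a single node, even
though a fish's body mass — and with it its diet, predators and metabolism —
changes by orders of magnitude between larva and adult. `atnfish` is for
theoretical ecologists who want to ask what that ontogeny does to food-web
structure and stability. It:

1. generates **niche-model** webs (`S` species, target connectance `C`):
   each species gets a niche value `n_i ~ U(0,1)`, a diet-range fraction
   `x_i ~ Beta(1, (1-2C)/(2C))`, width `r_i = x_i n_i` and center
   `c_i ~ U(r_i/2, n_i)`, and eats exactly the species inside
   `[c_i - r_i/2, c_i + r_i/2]`; webs failing realism rules (isolated
   species, missing basal chains, disconnection, off-target connectance)
   are rejection-sampled away;
2. annotates webs with short-weighted trophic positions
   `T = (T1 + T2)/2` (shortest basal path; prey-averaged positions via an
   exact linear solve that handles feeding loops), assigns guilds
   (basal = autotroph, three most apex consumers = fish, rest
   invertebrate), and scales body masses `M = Z^(T-1)` (`Z = 100`) and
   metabolic rates `x = 0.314 M^-0.15` (invertebrates) /
   `0.88 M^-0.11` (fish);
3. splits each fish species into four **von Bertalanffy** life-history
   stages, `W(t) = W_inf (1 - e^{-K(t - t0)})^3` with `K = 3/t_max` and
   adults at `0.9 W_inf`, and wires the stages into the web through the
   niche rules;
4. integrates seasonal **bioenergetic ODEs** (shared-capacity logistic
   autotrophs; consumers with maintenance loss `f_m x_i B_i`, intake
   `f_a x_i y B_i F_ij` under a normalized Hill functional response with
   optional predator interference) over 100-day growing seasons, pausing
   each year for a biomass-conserving **Leslie matrix** step
   (90% of each stage advances / reproduces, 10% remains);
5. runs replicated three-variant ensembles — *original* (no stages),
   *unlinked* (stages as independent nodes), *linked* (stages coupled by
   the Leslie step) — and summarises fish persistence, biomass stability
   (coefficient of variation of annual biomass) and how stability scales
   with asymptotic fish mass.

## Worked example

```r
library(atnfish)

web <- generate_valid_web(S = 30, C = 0.15, seed = 42)
web
#> niche web: S = 30, target C = 0.150, realized C = 0.1478
#>   basal species: 5, links: 133

aweb <- annotate_web(web)
head(annotation_table(aweb)[, c("id", "guild", "T1", "T2", "T", "M", "x")], 4)
#>   id        guild T1       T2       T            M         x
#> 1  1 invertebrate  2 3.000000 2.50000    1000.0000 0.1114114
#> 2  2    autotroph  1 1.000000 1.00000       1.0000 0.0000000
#> 3  3         fish  3 5.553757 4.27688 3578962.5641 0.1673283
#> 4  4 invertebrate  2 3.375000 2.68750    2371.3737 0.0978768

staged <- insert_stages(aweb, stage_seed = 1)
staged
#> staged web: 39 nodes (30 base species, 3 fish x 4 stages)
staged$vb[["3"]]
#> von Bertalanffy stages: K = 1.000, t0 = -0.3665, W_inf = 3.977e+06
#>   stage weights:  114877 1644303 2959191 3578963

set.seed(7)
traj <- run_simulation(staged, "linked", years = 300)
fish_survival(traj)$count
#> [1] 3
yrs <- 201:300                      # 200-year burn-in, 100 analysis years
biomass_cv(rowSums(traj$annual_mean[yrs, ]))
#> [1] 0.01557316
```

The trajectory object holds annual season-mean and year-end biomass per
node; here all three fish species persist for 300 years and the total
ecosystem biomass varies by about 1.6% (CV 0.0156) around its mean over
the 100 analysis years.

A full comparative experiment is one call (about a minute for 50 webs on
one CPU):

```r
ens <- run_ensemble(n_webs = 50, burn_in = 200, analysis = 100,
                    seed = 20240901)
ens
#> ATN ensemble: 50 webs x {original, unlinked, linked}
#>   stabilized in >= 1 variant : 98.0%
#>   stringent (all variants)   : 72.0%
#>   stage-size ordering        : 80.7% (n = 83)
#>   survivor frequencies (rows sum to accepted runs):
#>             0  1  2  3
#>   original 13  7 14 15
#>   unlinked  0  6  5 38
#>   linked    1  8  6 34
#>   pooled linked-variant regressions on log10 asymptotic mass:
#>   response        slope           se         t  df            p   n
#>   mean_eco 143.40886444 8.942191e+01 1.6037330 115 1.115159e-01 117
#>  mean_fish   1.14603427 1.102587e+01 0.1039405 115 9.173976e-01 117
#>     cv_eco   0.00242977 3.842569e-04 6.3232938 115 5.050951e-09 117
#>    cv_fish   0.01993368 5.098317e-03 3.9098548 115 1.565934e-04 117
```

Reading the summary: webs with stage structure (unlinked/linked) keep all
three fish species far more often than the unstructured variant (38 and 34
of the accepted runs versus 15); the CVs of ecosystem and fish biomass
rise significantly with asymptotic fish mass (positive slopes,
`p < 0.001`), while mean biomasses show no mass correlation — larger fish
mean less stable, not more productive, ecosystems. `write_run_bundle()`
saves all tables with content hashes for audit.

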