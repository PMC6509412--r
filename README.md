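# lvmort

Added mortality reshapes microbial competition. In daily batch culture the
mortality knob is the dilution factor: every transfer discards a fixed
fraction of every population, acting like a continuous per-capita death rate
δ = ln(DF)/T (T the hours between transfers). `lvmort` is an R toolkit for
analysing what that knob does to competitive outcomes — for modellers
studying Lotka–Volterra communities under mortality, and for experimentalists
running serial-dilution cocultures who want to call outcomes from colony
counts and predict multispecies states from pairwise ones.

## The model

The package is built around the two-species (and n-species) Lotka–Volterra
competition model with an added death term,

    dN_i/dt = r_i N_i (1 − N_i − α_ij N_j) − δ N_i,

where N_i is density normalized to carrying capacity, r_i the maximum growth
rate, and α_ij the dimensionless inhibition of species i by species j. The
key analytic fact: this maps exactly onto the death-free model with
*effective* coefficients

    α̃_ij = α_ij (1 − δ/r_j) / (1 − δ/r_i),

so the qualitative outcome is read off the same phase diagram — coexistence
when both α̃ < 1, bistability when both α̃ > 1, exclusion otherwise. Because
α̃_ij α̃_ji is independent of δ, raising mortality slides a pair along a 45°
line in (log α̃_ij, log α̃_ji) space, always toward dominance of the faster
grower. If a slow, strong competitor wins at low mortality, the pair must
pass through a coexistence window (α_ij α_ji < 1) or a bistable window
(product > 1) on its way to fast-grower dominance, with closed-form critical
mortality rates at each crossing.

On top of the pair theory the package implements:

* **Dynamics** — stiff-safe integration of the model in continuous-death and
  discrete growth–dilution form, fixed points and their stability
  (`run_continuous`, `run_serial_dilution`, `pair_fixed_points`).
* **Phase analysis** — `effective_params`, `classify_pair`,
  `critical_mortalities`, `mortality_sweep`, numerical transition location.
* **Outcome inference from counts** — endpoint compositions with
  beta-distribution error bars, pair outcome calls (exclusion / coexistence /
  bistability, with non-LV mixtures flagged), multispecies state calls and
  "subway map" export (`endpoint_fractions`, `call_pair_outcome`,
  `call_community_state`).
* **Assembly rules** — a species survives in a community iff it coexists
  pairwise with every other survivor; survivor-set enumeration (bistable
  pairs giving alternative states), composition prediction by the weighted
  geometric mean of pairwise fractions, plus carrying-capacity and
  flat-simplex random baselines (`allowed_survivor_sets`,
  `predict_fractions`).
* **Metrics** — L2 composition error normalized by its maximum √2,
  qualitative error rates, beta SD `σ = √((a+1)(b+1)/((a+b+2)²(a+b+3)))`,
  bootstrap competitive scores, growth–score regression.
* **Growth rates** — time-to-threshold rates from OD600 curves (threshold
  0.1), explicit lag/exponential fits, lag-corrected effective rates.
* **Synthetic data** — seeded generation of ground-truth communities with a
  growth/competitive-ability tradeoff and simulation of the full
  serial-dilution design (6 dilution factors 10–10⁶, 7 × 24 h cycles,
  90–5–5 starting splits, multinomial colony sampling with Poisson(42)
  totals), so every stage can be validated against known truth.

## Worked example

A fast grower (r = 1/h) that is a weak competitor against a slow, strong
competitor (r = 0.5/h; α_fs = 2, α_sf = 0.4):

```r
library(lvmort)
pair <- community_params(
  species_ids = c("fast", "slow"),
  growth_rates = c(1.0, 0.5),
  alpha = matrix(c(1, 2.0, 0.4, 1), 2, 2, byrow = TRUE))

critical_mortalities(pair)
#>       delta coefficient dilution_factor
#> 1 0.3333333    alpha_12        2980.958
#> 2 0.3750000    alpha_21        8103.084

sw <- mortality_sweep(pair, dilution_factors = 10^(1:6))
sw[, c("dilution_factor", "delta", "category", "interior_fraction")]
#>   dilution_factor  delta             category interior_fraction
#> 1           1e+01 0.0959 species_2_excludes_1                NA
#> 2           1e+02 0.1919 species_2_excludes_1                NA
#> 3           1e+03 0.2878 species_2_excludes_1                NA
#> 4           1e+04 0.3838 species_1_excludes_2                NA
#> 5           1e+05 0.4797 species_1_excludes_2                NA
#> 6           1e+06 0.5756 species_1_excludes_2                NA
```

The slow grower wins at dilution factors up to 10³; between the two critical
rates (δ = 1/3 and 3/8, i.e. DF ≈ 2981–8103, between the tested factors
10³ and 10⁴) the pair coexists; beyond that the fast grower takes over — the
α product 0.8 < 1 makes the crossing regime coexistence rather than
bistability.

A full synthetic study — generate a 3-species tradeoff community, simulate
the dilution experiment with plating noise, call outcomes, predict the trio
from its pairs, and score against baselines:

```r
cfg <- run_config(out_dir = "demo", seed = 7, n_species = 3)
run_pipeline(cfg)

read.csv("demo/error_report.csv") |> subset(stratum == "trio")
#>   stratum              type mean_error      sem n
#> 1    trio          assembly   0.014202 0.009075 6
#> 2    trio carrying_capacity   0.106143 0.035235 6
#> 3    trio            random   0.548281 0.076830 6

truth <- read_community_config("demo/ground_truth.yaml")
render_subway(read.csv("demo/subway.csv"),
              growth_rates = truth$params$growth_rates)
#> DF:           1e1    1e2    1e3    1e4    1e5    1e6
#> sp1            --     --     --     --     ==     ==
#> sp1 /2                                     --     --
#> sp2            ==     ==     ==     ==     --     --
#> sp2 /2                                     ==     --
#> sp3            ==     ==     --     --     --     --
#> sp3 /2                                     --     --
```

The pairwise assembly rules beat the carrying-capacity null, which beats a
random composition, by a wide margin (mean normalized error 0.014 vs 0.106
vs 0.548 across the six dilution factors). The subway map shows the
community handed from the slower growers (sp2, sp3) to the fast grower (sp1)
as dilution increases, with an alternative stable state (`/2` rows) at
DF 10⁵ where the sp1–sp2 pair is bistable.

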