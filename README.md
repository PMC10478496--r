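# zoibsel

Bayesian used-versus-available microhabitat selection for proportion data,
with a companion colour-matching analysis. The package was built around a
field study of common lizards (*Zootoca vivipara*), a species with
co-occurring egg-laying (oviparous) and live-bearing (viviparous) lineages:
habitat composition is scored as per-category proportions on a 25-cell
quadrat grid at sites where lizards basked and at randomly sampled sites,
and the question is whether lizards — and lizards of a particular sex or
parity mode — occupy habitat that differs from what is randomly available,
and whether their dorsal colouration matches the colour of the sites they
choose.

It is intended for ecologists analysing quadrat-derived proportion data
with excess zeros and ones, and for anyone who wants a tested, reproducible
implementation of the zero-and-one-inflated beta (ZOIB) model-comparison
workflow.

## The model

Quadrat proportions contain exact zeros (category absent) and ones
(category fills the quadrat), so each habitat category is modelled with a
ZOIB distribution:

```
f(y; α, γ, μ, φ) =  α(1−γ)          y = 0
                    αγ              y = 1
                    (1−α) f(y;μ,φ)  0 < y < 1
```

where `α` is the probability of an atom, `γ` the probability that an atom
is a one, and `f(y; μ, φ)` a beta density with mean `μ` and precision `φ`
(shapes `μφ` and `(1−μ)φ`). When a category is never observed at 1, `γ` is
fixed at 0 (and at 1 when never observed at 0), determined once from the
pooled data.

Nine candidate models share this likelihood and differ in which
observations share parameters: a null model (lizard and random sites
pooled), a lizard model (lizard vs random), sex, parity-mode, and
parity-by-sex groupings — each, except the null, with the beta precision
either shared by all observations or split between lizard and random
sites. Priors are minimally informative normals on transformed scales
(`logit α, logit μ ~ N(0, 1000)`, `logit γ ~ N(0, 1)`,
`log φ ~ N(0, 100)`, second parameter read as a variance). Posteriors are
sampled by an adaptive random-walk Metropolis-within-Gibbs sampler;
model comparison uses the deviance information criterion
(`DIC = D̄ + pD`, `pD = D̄ − D̂`), preferring the model with the lowest DIC
unless a strictly simpler model lies within two DIC units, in which case
the simpler model wins.

The colour side converts calibrated RGB to hue/saturation/lightness and
fits the eight-model suite relating dorsal colour and patterning to sex,
parity, morphometrics, and basking-site and habitat colouration (least
squares, logistic regression, one-way ANOVA; raw p-values throughout).

## Worked example

Simulate grass proportions for 200 random and 200 lizard sites (interior
means 0.70 vs 0.55, atom mass 0.25, precision 10), fit the lizard model,
and summarise:

```r
library(zoibsel)

scenario <- preset_scenario("grass-lizard", seed = 42)
obs <- generate_habitat_dataset(scenario)
fit <- fit_zoib(obs, "grass", model_scheme("lizard", "shared"),
                config = mcmc_config(chains = 4, iterations = 5000,
                                     burn_in = 1000, seed = 7))
posterior_summary(fit)
#>   parameter  group   mean median lower_95 upper_95 rhat  ess
#> 1     alpha random  0.245  0.244    0.187    0.307    1 3594
#> 2     alpha lizard  0.234  0.234    0.176    0.294    1 3237
#> 3        mu random  0.698  0.699    0.676    0.720    1 3786
#> 4        mu lizard  0.526  0.526    0.503    0.549    1 3635
#> 5       phi    all 10.083 10.063    8.569   11.695    1 3459
compute_dic(fit)
#> DIC = 119.49 (Dbar = 114.46, Dhat = 109.43, pD = 5.03)
```

The posterior recovers the generating values: about 24% of sites have no
grass at all (`alpha`), and where grass is present it covers about 70% of
random quadrats but only 53% of lizard quadrats (`mu`), i.e. lizards sit
in less grassy spots than chance would put them. `pD ≈ 5` matches the five
free parameters.

The package ships the published nine-model DIC table
(`habitat_dic_reference()`); applying the selection rule to any of its
columns reproduces the study's preferred model for that habitat type:

```r
ref <- habitat_dic_reference()
select_model(data.frame(ref[1:2], dic = ref$moss))
#> selected model: parity/shared (DIC = 341.7, rationale = lowest)
```

`fit_all_models()` runs the full nine-model ladder on data,
`run_colour_models()` runs the colour suite on lizard records, and
`run_pipeline()` ties everything together into a seeded, manifest-backed
report bundle.

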