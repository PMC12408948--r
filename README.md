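# debipm

Dynamic Energy Budget Integral Projection Models (DEB-IPMs) for
comparative life-history analysis of length-structured species.

## The problem

Life-history strategies — how fast organisms grow, when they mature, how
much and how often they reproduce — emerge from individual energy
budgets, and they shift with food availability. `debipm` builds, from
just eight energy-budget parameters per species, a length-structured
population projection model; derives a standard set of life-history
traits plus population growth rate and demographic resilience; and then
asks the comparative questions: which major axes structure life-history
variation across species once phylogeny and body mass are accounted for,
do species move along those axes when feeding conditions change, and do
the axes predict population performance and conservation status?

It is aimed at population ecologists and comparative biologists working
with data-poor taxa (the motivating application is sharks, skates and
rays), where full demographic rate schedules are unavailable but growth
curves, size at birth/maturity and fecundity estimates exist.

## The model

Each species is described by the Kooijman–Metz parameters
`L_b` (length at birth), `L_p` (maturation), `L_m` (maximum length),
`r_B` (von Bertalanffy growth rate), `R_m` (maximum reproduction rate),
`mu_j`, `mu_a` (juvenile/adult mortality) and `kappa` (allocation
fraction). At experienced feeding level `E(Y) ∈ [0, 1]`:

- growth: `E[L'] = L + (E(Y)·L_m − L)(1 − e^{−r_B})` (Gaussian spread,
  cv 0.1); individuals above the asymptote `E(Y)·L_m` shrink;
- survival: `e^{−mu_j}` (juveniles) or `e^{−mu_a}` (adults), and 0 above
  the starvation threshold `L_m·E(Y)/kappa`;
- reproduction (adults): `R_m·E(Y)·L²/L_m²`, offspring sizes Gaussian
  around `L_b`.

The kernel is discretized on 200 length bins into component matrices
(survival `S`, growth `G`, reproduction `R`, offspring sizes `D`), giving
the annual projection `A = (DR + G)S`. From `A` and the fundamental
matrix `N = (I − GS)^{-1}` the package derives generation time `T`, age
at maturity `L_α`, progressive/retrogressive growth `γ`/`ρ`, mean
recruitment success `φ`, degree of iteroparity `S`, net reproductive
rate `R₀`, mature life expectancy `L_ω`, the growth rate `λ` (dominant
eigenvalue) and the damping ratio `ξ = λ/|λ₂|`.

The comparative layer is a varimax-rotated, phylogenetically corrected
PCA (GLS mean and evolutionary covariance under a maximum-likelihood
Pagel's λ transform, Kaiser retention, optional body-mass residual
correction, duplicate-tip handling for species observed at two feeding
levels), followed by linear models of `λ` and `ξ` on the axis scores, a
discriminant check for persistence bias, mixed models for habitat and
clade, and a proportional-odds regression on IUCN status.

## Worked example

```r
library(debipm)

sp <- deb_params(L_b = 20, L_p = 50, L_m = 100, r_B = 0.3, R_m = 40,
                 mu_j = 0.2, mu_a = 0.15, species = "example")
rbind(trait_vector(sp, 0.6), trait_vector(sp, 0.9))
#>   species  EY lambda    xi     T L_alpha  gamma     rho    phi S_itero    R0
#> 1 example 0.6  1.378 1.393 8.247   3.789 0.9105 0.07549 0.6544  0.9209 14.06
#> 2 example 0.9  2.146 1.537 5.682   2.113 0.9796 0.01753 1.5378  1.4375 76.62
#>   L_omega eta_e persistent
#> 1   2.030 5.819       TRUE
#> 2   4.204 6.317       TRUE
```

Raising the feeding level from 0.6 to 0.9 shortens generation time
(8.2 → 5.7 years), roughly halves the age at maturity, and multiplies
lifetime reproductive output `R₀` five-fold — the population grows at
λ = 2.15/yr instead of 1.38/yr and recovers faster from perturbations
(ξ = 1.54 vs 1.39). A whole comparative study runs as:

```r
study  <- synthetic_study(100, seed = 1)   # or your own species CSV + Newick tree
result <- run_pipeline(study, run_config(seed = 1))
print(result)
write_pipeline_outputs(result, "out/")
```

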