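# roadedge

Edge-effect analysis of dung beetle communities along tropical logging
roads.

Selective logging leaves behind a dense network of unpaved access roads, and
the forest alongside those roads is altered well beyond the road surface
itself. `roadedge` implements the statistical pipeline used to quantify that
influence with baited-pitfall dung beetle surveys: how *strongly* a community
metric differs near the road, how *far* the difference penetrates into the
forest, and how much the road network subtracts from the biodiversity of the
whole logged landscape. Because the underlying field data were never
deposited, the package ships a synthetic-data generator that reproduces the
survey's design and statistical structure, so every stage of the pipeline is
testable end to end.

It is aimed at community ecologists working on edge effects, linear
infrastructure, or count-based community metrics in general.

## The statistics

**Magnitude of edge influence (MEI).** For a per-trap variable with mean
`e` at one distance class from the road edge and mean `i` over interior
reference traps,

    MEI = (e − i) / (e + i)  ∈  [−1, 1],

0 when edge equals interior. Significance at each distance comes from the
**randomization test of edge influence (RTEI)**: the pooled edge + interior
values are re-split 10,000 times into groups of the original sizes and the
two-sided p-value is the (+1-corrected) share of permuted |MEI| values at
least as large as the observed one. The **distance of edge influence (DEI)**
is the contiguous range `[0, d_max]` over which every tested distance is
significant.

**Piecewise gradient models.** Counts are regressed on distance with a
negative-binomial GLM (log link) and a two-segment alternative with basis
`{d, (d − ψ)+}`; the breakpoint ψ is estimated by a profile-likelihood grid
search and the two models are compared by AIC (the piecewise model is
charged two extra parameters, β₂ and ψ).

**Community composition.** Distance-class assemblages are standardized to
proportions, ordinated by NMDS on Bray–Curtis dissimilarity, and the
edge (≤ 100 m) vs interior (≥ 170 m) contrast is tested with a multivariate
count-model statistic (sum over species of NB likelihood-ratio statistics,
null distribution by trap-level resampling).

**Vegetation mixed models.** Community metrics are related to eight
standardized vegetation measures with a negative-binomial GLMM (plot random
intercept, Laplace approximation); residual spatial autocorrelation is
screened with a Moran's I Monte-Carlo permutation test.

**Landscape accounting.** Road length `L` and the edge-effect limit `E`
give the affected area `A = L × E × 2`; interior and road-edge metric means
are combined in proportion to the landscape fractions, yielding percentage
declines attributable to roads beyond timber removal itself.

## Worked example

```r
library(roadedge)

# a synthetic survey: 24 road-edge plots x {0,6,12,25,50,100} m,
# 58 interior traps, 60 primary-forest traps
locations <- generate_design(study_design())
model     <- community_model()          # NB counts, breakpoint at 130 m
samples   <- generate_counts(locations, model, seed = 7)
traits    <- extrapolate_mass(model$species[, c("species","guild","diel",
                               "size_class","length_mm","width_mm","mean_mass_g")])
metrics   <- trap_metrics(samples, traits, locations)

# edge influence on abundance
sub <- metrics[metrics$habitat %in% c("road_edge", "interior"), ]
prof <- rtei_profile(sub$abundance, sub$distance_m,
                     sub$habitat == "interior", n_rand = 10000, seed = 1,
                     variable = "abundance")
prof$table
#>    variable distance_m         mei    p_value significant
#> 1 abundance          0 -0.33409432 0.00009999        TRUE
#> 2 abundance          6 -0.32618204 0.00009999        TRUE
#> 3 abundance         12 -0.33899061 0.00009999        TRUE
#> 4 abundance         25 -0.32821492 0.00009999        TRUE
#> 5 abundance         50 -0.14786243 0.04419558        TRUE
#> 6 abundance        100  0.03816728 0.60603940       FALSE
prof$dei
#> DEI: [0, 50] m

# breakpoint regression of abundance on distance
fit <- fit_piecewise(sub$abundance, sub$distance_m)
fit
#> piecewise negative-binomial fit: psi = 100 m, pre-break slope 0.007959/m, slope change -0.008061/m
#> AIC linear 2217.3 vs piecewise 2195.7 -> piecewise (dAIC = 21.63)

# landscape accounting for 2403 km of road with a 170 m edge zone
landscape_summary(2403, 170, 9078)$road_edge_area_km2
#> [1] 817.02
```

Abundance in this draw is depressed by roughly a third near the road (MEI
about −0.33 at 0–25 m) and the deficit stays detectable out to 50 m
(DEI = [0, 50] m), while the gradient model places the change-point at
about 100 m with a pre-break slope of +0.008 per m of log abundance — the
two statistics answer slightly different questions, and the piecewise model
beats the single slope by 21.6 AIC units. The strip formula then converts
the road network into 817 km² of edge-affected forest, about 9% of the
logged landscape.

The numbered scripts in `analysis/` run the same stages over a full
synthetic survey (simulation → per-trap metrics → RTEI/DEI profiles →
gradient models → composition → vegetation GLMM → landscape accounting) and
write their tables under `results/`.

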