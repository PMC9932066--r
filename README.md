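# pollinet

Quantitative plant–pollinator network analysis along urbanisation
gradients, for community ecologists studying how cityscapes reshape
flower-visitation networks in grassland habitats.

Urban studies of this kind record flower visits of wild bees, hoverflies,
butterflies and honey bees at a set of grassland patches spanning an
urbanisation gradient, and ask two questions: how do local habitat quality
and the surrounding cityscape affect the visitor communities, and how do
they affect the *architecture* of the plant–visitor interaction network?
`pollinet` implements that full analysis as a tested, reproducible R
pipeline:

* **Networks** — site-level quantitative bipartite networks (plants ×
  visitors) built from long-format interaction records, at species and
  genus resolution (`BipartiteNetwork`, `buildNetwork()`,
  `aggregateToGenus()`).
* **Metrics** — connectance; NODF nestedness; Barber's quantitative
  bipartite modularity `Q = (1/m) Σ_ij (a_ij − r_i c_j/m) δ(g_i, g_j)`
  maximised by simulated annealing; network specialisation
  `H2' = (H_max − H2)/(H_max − H_min)`; and visitor specialisation d′, the
  standardised Kullback–Leibler divergence of resource use from floral
  availability.
* **Null models** — Patefield fixed-margin random tables and the
  Δ-transformation `ΔN = N − mean(N_null)` (1000 draws per metric, 100 for
  modularity).
* **Landscape** — a building-height-modified Hanski connectivity index
  `S_i = Σ_j exp(−α (d_ij + λ H_ij)) A_j`, where `H_ij` sums building
  heights in 25 m corridors between patches, plus scale-of-effect selection
  for predictors measured at 100/500/1000 m radii.
* **Community & regression** — Wisconsin/square-root/Bray–Curtis
  preprocessing with permutation-based environmental vector fitting;
  VIF screening (cutoff 3), a Poisson → negative-binomial model ladder,
  all-subsets AIC selection (≤ 3 predictors), Moran's I residual
  diagnostics, and Δ-metric meta-statistics.
* **Synthetic data** — a seeded generator emulating an 11-site urban
  dry-grassland study design (pools of 105 bee / 38 hoverfly / 22
  butterfly species, 8 sampling rounds, bees and butterflies declining
  with impervious surface, hoverflies flat, honey bees and flower abundance
  increasing), so everything runs end to end without field data.

## Worked example

```r
library(pollinet)

cfg   <- syntheticConfig(seed = 7)    # the 11-site default design
study <- generateStudy(cfg)

net <- buildNetwork(study$records, "site03")
net
#> BipartiteNetwork [site site03, species resolution]
#>   13 plants x 46 visitors, 206 interactions
#>   visitor groups: butterfly=7, honey_bee=1, hoverfly=10, wild_bee=28

networkMetrics(net, seed = 1)[, 6:10]
#>  connectance nodf modularity h2prime mean_dprime
#>        0.211 29.9      0.346   0.442       0.264

deltaTransform(net, metrics = c("connectance", "nodf", "modularity"),
               nNull = 300, nNullModularity = 30, seed = 1)[, 1:3]
#>       metric observed null_mean   delta
#>  connectance    0.211     0.231 -0.0207
#>         nodf   29.880    37.581 -7.7007
#>   modularity    0.346     0.277  0.0698
```

The Δ values carry the structural signal: this network is *less* connected
and *less* nested, but *more* modular, than random tables with the same
margins — the signature of specialised, compartmentalised visitation.

Landscape side:

```r
head(siteConnectivity(study$landscape), 3)   # 3D connectivity S_i (m^2)
#> site01 site02 site03
#>     13   3535   2413

bees <- siteCommunitySummary(study$records, "wild_bee")
selectScale(bees$richness,
            study$siteData[c("imperv_100", "imperv_500", "imperv_1000")])
#> $radius
#> [1] 500                       # bees respond at the 500 m scale
#> $correlations
#> imperv_100 imperv_500 imperv_1000
#>     -0.429     -0.722      -0.608
```

Bee richness correlates most strongly (negatively) with impervious surface
in the 500 m buffer, so 500 m is that response's scale of effect. One call
runs everything — generation, networks, metrics, Δ-nulls, connectivity,
scale selection, community composition, regressions — with a reproducible
manifest:

```r
res <- runPipeline(cfg, nNull = 300, nNullModularity = 30)
res$deltaTests      # one-sample t-tests of each delta metric vs zero
res$scaleTable      # selected radius per response
res$models          # VIF screen + AIC-selected GLM/LM per response
```

## Further reading

The methods vignette (`vignettes/pollinet-methods.Rmd`) documents the
model assumptions, the exact-versus-heuristic standardisation bounds for
H2′/d′, the annealing schedule, all tunable parameters with defaults and
units, what the synthetic generator does and does not emulate, and known
limitations.
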