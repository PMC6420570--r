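# motifweb

Food-web **motif analysis along a plant-diversity gradient**: build
probabilistic plot-level food webs from a trophic metaweb plus local
abundances, census the 13 connected three-species motifs (directed
triads), benchmark the counts against degree-preserving Curveball null
models, and model how normalised motif representation shifts with sown
plant species richness in a blocked grassland biodiversity experiment
(sown richness 1/2/4/8/16/60 over 80 plots in 4 blocks, 4 sampling
periods, n = 320). A synthetic community generator reproduces the
experiment's structure so the entire pipeline runs with no external data.

Intended users: community ecologists and network scientists working with
trophic networks, experimental diversity gradients, or null-model motif
analysis.

## The model

A local interaction probability combines metaweb support `T_ij` (five
link types recording how each plausible link was assigned) with an
abundance-dependent encounter probability:

* link type 1 (specific literature records): `A_ij = 1`
* types 2–3 with a consumer or static resource (detritus, moss, algae,
  fungi, dung, carrion) as resource: `A_ij = 1`
* types 2–3 with a plant resource: `A_ij = min(1, α · n_i · n_j)`
* types 4–5 (predator–prey, trait-based): `A_ij = min(1, β · n_i · n_j)`

with `n` relative cover (plants) or within-stratum relative abundance
(consumers). Each plot-period matrix is sampled 50 times into binary
webs; every web is censused (induced triad census, so each triple counts
toward exactly one of the 13 classes s1–s5, d1–d8) both in full and on
its consumer sub-web (free-floating motifs). Counts are compared with
Curveball-rewired null webs — margins, and hence all degrees, preserved
exactly — via z-scores `z_i = (X_i − X̄_i)/σ_i`, normalised per web to a
unit-length significance profile `n_i = z_i / ‖z‖₂`, and trends along the
gradient are fitted with linear mixed models
(`log2(sown richness)` fixed; period and plot-in-block random; n = 320).

## Worked example

```r
library(motifweb)

cfg  <- generator_config(global_seed = 1, n_consumers = 150L)
comm <- generate_community(cfg)
comm
#> <motifweb_community>
#>   nodes:   216 (60 plants, 6 static resources, 150 consumers)
#>   metaweb: 4889 links
#>   design:  80 plots, 4 blocks, 4 period(s)

pw <- build_probabilistic_web(comm, "plot77", "T1", scalar_config(800, 100))
pw
#> <prob_web plot77/T1> 75 nodes, 331 supported links, sum(A)=108.4

bw <- sample_binary_web(pw, seed = 1)
round(census(bw))
#>  s1  s2  s3  s4  s5  d1  d2  d3  d4  d5  d6  d7  d8
#>  62   8   0 216 118   0   0   0   0   0   0   0   0

pr <- profile_pipeline(pw, iterations = 50, R = 50, seed = 1)
subset(pr, class %in% c("s1", "s2", "s4", "s5") & scope == "full")
#>   plot_id time_period scope class count_mean z_mean n_mean  n_se n_flagged
#> 1  plot77          T1  full    s1       89.1   0.23  0.143 0.045         0
#> 2  plot77          T1  full    s2        9.5  -0.83 -0.187 0.051         0
#> 4  plot77          T1  full    s4      260.8   0.22  0.120 0.045         0
#> 5  plot77          T1  full    s5      122.5   0.81  0.231 0.046         0
```

Reading the profile: on this 60-species plot the sampled webs average
89 tri-trophic chains, 261 apparent-competition and 123
exploitative-competition triads per web; relative to degree-preserving
null webs, chains and both competition motifs are over-represented
(positive mean normalised score) while omnivory is under-represented
(−0.19), with Monte-Carlo standard errors of about 0.05 from the 50
iterations. `n_flagged = 0` means no zero-variance null class needed the
degenerate-σ convention.

The full experiment — all 320 plot-periods, trends and summaries — is one
call:

```r
res <- run_pipeline(pipeline_config(global_seed = 1), out_dir = "results/run1")
res$trends        # mixed-model slopes per motif class x scope x measure
res$summaries     # motif shares and grounded fractions per richness level
```

## Layout

* `R/` — community model & TSV I/O, probabilistic web builder, triad
  census, Curveball null models, representation profiles, synthetic
  generator, mixed-model trends, pipeline orchestration
* `src/` — compiled triad census and Curveball trading core
* `vignettes/motif-analysis.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical conventions, limitations
* `tests/testthat/` — unit, property and end-to-end suites
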