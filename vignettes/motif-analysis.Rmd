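---
title: "Probabilistic food webs and motif representation along a plant-diversity gradient"
author: "motifweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic food webs and motif representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Plant diversity restructures the arthropod communities above it, but
species counts alone say little about how the *architecture* of trophic
interactions changes. A compact way to fingerprint that architecture is the
distribution of three-species motifs: excluding cannibalism, a directed
graph contains exactly 13 connected triad classes, of which four dominate
real food webs — tri-trophic chains (`s1`), omnivory (`s2`), apparent
competition (`s4`, two resources sharing a consumer) and exploitative
competition (`s5`, one resource shared by two consumers). `motifweb`
implements a complete pipeline for asking how the representation of these
motifs shifts along an experimental plant-diversity gradient, using
replicate plot-level webs from a grassland biodiversity experiment design
(sown richness 1, 2, 4, 8, 16 or 60 species over 80 plots in 4 blocks,
sampled in 4 time periods), with a synthetic community generator standing
in for field data.

## From metaweb to probabilistic web

Local webs are built by combining two ingredients, following the
population-level interaction framework in which the probability that
species $i$ is eaten by species $j$ factorises into trait-driven and
encounter-driven parts:

$$A_{ij} \propto N(i,j) \times T(i,j)$$

$T_{ij} \in \{0,1\}$ is the *metaweb*: the catalogue of plausible feeding
links among all species, independent of co-occurrence. Each metaweb link
carries a type recording how it was assigned: (1) specific literature
records, (2) generalised literature records, (3) trophic-guild rules, (4)
trait-based rules, (5) combined trait-based rules. The encounter term $N$
depends on the link type and the resource's role:

* type 1: $A_{ij} = 1$ — specifically documented interactions (e.g.
  monophagous herbivores) are realised whenever both partners co-occur;
* types 2–3, resource a consumer or a static node: $A_{ij} = 1$ — detritus
  and similar resources are ubiquitous, and documented consumer resources
  are sought out;
* types 2–3, resource a plant: $A_{ij} = \min(1,\ \alpha\, n_i n_j)$;
* types 4–5 (predator–prey): $A_{ij} = \min(1,\ \beta\, n_i n_j)$,

where $n_i$ is relative cover (plants, renormalised over the plants present
on the plot-period) or relative abundance (consumers, normalised separately
within the ground and herb strata; a species using both strata enters both
totals and takes the mean of its two shares — the field protocol samples
the two strata with different gear, so shares are only comparable within a
stratum). The proportionality licence in the framework is resolved by
clipping at 1, since $A_{ij}$ is used directly as a Bernoulli probability.
Higher-order context effects (an $\varepsilon$ term in the framework) are
set to zero throughout.

Each plot-period probability matrix is sampled 50 times into binary webs
(each supported link kept independently with probability $A_{ij}$); nodes
left with degree zero are dropped. All reported quantities are means over
these iterations. Free-floating motifs — those not involving any basal
node — are counted by deleting plant and static-resource nodes from the
*same* sampled iteration and re-counting on the consumer sub-web (the
alternative of re-sampling fresh iterations for the sub-web only adds
Monte-Carlo noise; both estimate the same mean).

## The triad census

The census is *induced*: every unordered node triple is assigned to exactly
one class, the isomorphism class of its induced subgraph, so a triple in an
omnivory arrangement is not additionally counted as the chain and
competition motifs embedded in it. The implementation is a compiled
edge-scan triad census (complexity proportional to edge count times mean
degree rather than $\binom{n}{3}$), classified through a 64-entry lookup
from the 6-bit induced-subgraph code to the standard 16-type triad
nomenclature; the three disconnected types (003, 012, 102) are excluded and
the remaining 13 mapped to `s1`–`s5`, `d1`–`d8`. With feeding links directed
resource → consumer, `s4` is the in-star (021U) and `s5` the out-star
(021D); `s2` is the transitive triangle (030T) and `s3` the cycle (030C).
The `d` classes (at least one mutual link) are rare in webs without
mutual feeding; their internal ordering (d1..d8 =
111D, 111U, 201, 120D, 120U, 120C, 210, 300) is this package's documented
convention, exposed in `motif_classes()`, and nothing downstream depends on
it — they enter the summaries only through the "other" aggregate
(`s3` + all `d`). Unit tests verify the census against brute-force
classification of every triple and against an independent graph library's
triad census.

## Null models and representation profiles

Raw motif counts covary with network size and connectance, which themselves
track plant richness. Each sampled web is therefore benchmarked against 250
degree-preserving randomisations (the package default; the acceptance-scale
runs described below use 50) generated with the Curveball algorithm: the
web is viewed as one row per consumer holding its resource set, and a trade
exchanges a random-sized random subset of two rows' exclusive elements.
Every trade preserves each node's in- and out-degree exactly, hence also
species number, link number and connectance, and structural constraints
such as "plants never consume" follow automatically from the margins. Two
implementation details matter:

* elements equal to the other row's owner are withheld from a trade, so a
  margin-preserving exchange can never manufacture a self-link
  (cannibalism stays excluded);
* each ensemble member is produced by an independent trade sequence
  restarted from the observed web (default $5\times$ the number of
  consumer rows), avoiding autocorrelation along a single chain. On a
  4×4 incidence problem whose margin-compatible matrices can be
  enumerated exhaustively (90 of them), the sampler's long-run
  distribution is uniform (tested at 100,000 samples).

For each motif $i$, representation is the z-score
$z_i = (X_i - \bar X_i)/\sigma_i$ against the ensemble mean and standard
deviation, and the profile is normalised to unit Euclidean norm,
$n_i = z_i / \sqrt{\sum_j z_j^2}$, because larger networks show more
extreme raw z-scores; the normalised profile carries the *relative*
importance of each motif and is comparable across web sizes. Degenerate
classes with $\sigma_i = 0$ give $z_i = 0$ when the observation equals the
null mean; otherwise the smallest nonzero $\sigma$ in that ensemble is
substituted (1 if none exists) to preserve direction without infinities —
such substitutions are counted in the `n_flagged` output column and are
expected only in very small webs. Normalisation is applied per iteration
and the normalised scores are then averaged over the 50 iterations (the
alternative order — average z, then normalise — discards the per-web
normalisation that motivates the statistic; the choice is documented here
because either reading is defensible).

## The synthetic community generator

`generator_config()` defines the study conditions. Its defaults emulate the
experiment's structure: 60 plants in four functional groups (16 grasses, 12
small herbs, 20 tall herbs, 12 legumes) spread over 15 families; six static
basal resources (detritus, moss, algae, fungi, dung, carrion) present on
every plot; and a consumer pool (default 400 species; the package's
acceptance runs use a reduced pool of 150 to keep a full experiment under a
few minutes) split into detritivores (15%), herbivores (38%), omnivores
(12%) and predators (35%) with lognormal body lengths and guild-typical
stratum use. The metaweb is generated from diet rules that mirror the five
link types: monophagous herbivores get one type-1 plant link, oligophagous
ones a plant family (type 2), generalists a functional group (type 3);
detritivores feed on static resources; predators feed on consumers inside a
body-size ratio window (prey 0.15–1.1 × predator length) with compatible
stratum use (type 4 where either party uses both strata, type 5 where the
stratum rule binds); omnivores combine a generalist plant diet, static
resources and predator-style animal links.

The design allocates the six richness levels to 16/16/16/16/12/4 of the 80
plots (the exact per-level allocation is not part of the published text;
this split sums to 80 and keeps the doubling series well replicated),
dealt round-robin over 4 blocks. Realised plant richness is a saturating
thinning of the sown set — each sown species persists with probability
$e^{-\lambda \log_2(\text{sown})}$, with $\lambda$ set so mean realised
richness at sown 60 is ~33 species. Covers follow a geometric rank series
(decay 0.85) scaled to 90% total cover. Consumer occupancy is a
guild-ordered colonisation model — detritivores, herbivores, omnivores,
then predators — in which presence probability is
$p_{\max}\,(b_0 + (1-b_0) f^{\gamma})$ with $f$ the fraction of the
species' metaweb diet present on the plot. The resource-independent
baseline $b_0$ (0 for detritivores and herbivores, 0.2 for omnivores, 0.3
for predators) encodes the vagility of higher trophic levels and produces
the attenuating richness response up the trophic hierarchy: herbivore
richness rises steeply with plant richness, predator richness only weakly,
and the omnivore share of the community declines. Counts for present
consumers are lognormal (meanlog $\log 4$, sdlog 1). This is a minimal
mechanism aimed at the documented marginal patterns; it makes no attempt to
mimic real taxa, phenology, spatial structure, or observation error, so
tests passing on it demonstrate correctness of the *pipeline* and
qualitative behaviour of the *method*, not reproduction of field results.

## Choosing the encounter scalars

`calibrate_scalars()` implements the calibration procedure: over a grid of
$(\alpha, \beta)$ pairs it builds and samples webs for the
highest-diversity plots and selects the pair whose median omnivore
generality is closest to a target of ~30 resource taxa (ties to the
smaller $\alpha$, then $\beta$), the target reflecting gut-content evidence
of strongly increasing omnivore diet breadth with plant richness. On the
synthetic communities this criterion constrains $\alpha$ tightly but
$\beta$ barely at all, and pushing the median to 30 requires scalars so
large that $\beta n_i n_j$ clips to 1 for most predator–prey pairs — at
which point encounter probability stops being density-dependent and the
consumer sub-web densifies uniformly across the gradient. The pipeline
defaults therefore fix $\alpha = 800$ (the scale the calibration criterion
selects) and $\beta = 100$, the regime in which predator–prey encounters
remain abundance-limited and sampled web sizes stay within the empirically
plausible envelope (roughly 20–100 species and 36–1060 links per web).
Both scalars are exposed in `pipeline_config()` and the calibration
procedure should be re-run when applying the pipeline to data with a
different abundance scale. A sensitivity scenario
(`diversity_scaled_scalars()`) additionally lowers $\beta$ linearly with
sown richness (down to $(1-s)\beta$ at 60 species) to represent prey
refugia in structurally complex vegetation.

## Trend models

Motif counts and normalised scores are analysed with linear mixed models:
fixed effect $\log_2$(sown richness) — the levels form a doubling series,
and a linear option is retained — with random intercepts for time period
(4) and plot (80) nested in block (4), giving 320 records per response.
Counts are $\log(x+1)$-transformed (zeros occur for rare classes);
normalised scores are analysed untransformed. P-values are two-tailed with
Satterthwaite degrees of freedom. A singular fit downgrades the random
structure stepwise — dropping block, then period — with a warning, ending
at ordinary least squares; the structure actually used is reported in every
result row. Classes with (nearly) all-zero counts, typically most `d`
classes, are excluded from modelling and listed, since their bimodal
zero-inflated distributions cannot support the linear model.

## Numerical and design choices

* **Seeds.** Every stochastic stage derives its seed deterministically from
  the global seed and its coordinates (plot, period, stage tag) via
  `derive_seed()`, so any stage can be re-run in isolation and a full rerun
  is bit-identical; the manifest records the rule and the configuration.
* **Degenerate inputs.** A plot-period with no plants and no consumers is
  rejected; an all-zero probability matrix yields an empty web (allowed);
  an empty or single-link web yields a zero census, a zero-variance null
  ensemble, and z = 0 by the conventions above.
* **Pruning.** Degree-zero nodes are removed from sampled webs. Isolated
  nodes carry no edges, cannot gain any under margin-preserving rewiring,
  and contribute no connected triads, so the compiled fast path skips
  explicit pruning without changing any reported count.
* **Problem sizes.** The packaged end-to-end runs use the full design (80
  plots × 4 periods), 50 sampling iterations, 50 null webs per iteration
  and the 150-consumer pool — about a minute and a half on one core; the
  per-plot default of R = 250 nulls matches the method's reference
  configuration and scales linearly.

## Limitations

Webs are binary: no interaction strengths, no dynamics, no stability
metrics. The generator's colonisation and abundance models are
phenomenological; parameter-recovery and directional tests on synthetic
data validate the machinery, not ecological conclusions about any real
system. Motifs larger than three nodes, alternative null models
(trophic-level-constrained rewiring, niche-model nulls) and weighted motif
variants are out of scope.
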