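# coocnet

Assembly rules from species co-occurrence networks.

`coocnet` is an R package for ecologists asking *which rules assemble a
multi-guild community* — environmental filtering, limiting similarity, or
neutral dynamics — from a site × species survey plus trait tables,
phylogenies and site-level predictors. It implements, end to end, the
network route to that question:

1. **Pairwise co-occurrence** — every species pair is classified
   positive / negative / random with the exact hypergeometric model:
   P(J = j) = C(N₁, j)·C(N−N₁, N₂−j)/C(N, N₂) for J jointly occupied of N
   sites, one-sided tails including the observed atom, α = 0.05, and a
   testability filter on the expected co-occurrence N₁N₂/N.
2. **Positive co-occurrence network** — species with at least one positive
   partner become vertices of an undirected simple graph spanning both
   guilds.
3. **Structure** — Newman modularity Q = Σ_c (e_cc − a_c²) with
   deterministic fast-greedy module detection, and NODF nestedness rescaled
   to [0, 1]; both compared to degree-preserving permutation nulls
   (`swap`, `tswap`, `quasiswap`) via SES = (obs − mean)/sd and lower-tail
   p = (1 + #{null < obs})/(1 + n_perm).
4. **Species importance** — knock-out deltas Δᵢ = initial − leave-one-out,
   standardized across species (SESᵢ); negative modularity SES marks
   species whose loss makes the network *more* modular.
5. **Assembly rules per module** — mean pairwise Gower (functional) and
   cophenetic (phylogenetic) distances within each module against a
   size-preserving reassignment null (p ≤ 0.05 convergence,
   p ≥ 0.95 divergence), plus Kruskal–Wallis / Fisher trait-shift tests
   across modules.
6. **Abundance counterpart** — FDis/PDis dispersion with species-identity
   permutation nulls, and RDA variance partitioning of
   Hellinger-transformed abundances over agricultural, soil and spatial
   predictor sets (adjusted-R² fractions by inclusion–exclusion,
   Freedman–Lane pseudo-F tests of the pure fractions), whole-data and per
   module.

A first-class **synthetic data generator** emulates a 48-site, two-guild
(197 plants + 22 orthopterans) grassland survey with planted modules, trait
convergence/divergence regimes, Brownian traits on ultrametric trees and
module-correlated environmental gradients, so the entire pipeline is
testable against ground truth.

## Worked example

```r
library(coocnet)

sc <- syntheticScenario(nSites = 30, nPlants = 40, nOrthopterans = 10,
                        nModules = 5)
b  <- generateBundle(sc, seed = 7)

pairs <- classifyPairs(b$presence)
table(pairs$classification)
#>   negative   positive     random untestable
#>          6         95        524        600

net <- buildNetwork(pairs, guild = guilds(b$presence))
net
#> CoocNetwork: 43 species, 95 positive co-occurrence edges
#>   guilds: orthopteran 7, plant 36

part <- greedyModules(net)
part
#> ModulePartition: 5 modules over 43 species (Q = 0.7710)
#>   sizes: 11, 9, 8, 8, 7

structureSES(net, "modularity", nPerm = 999, method = "quasiswap", seed = 8)
#> Null-model test (modularity, adjacency null, quasiswap): obs = 0.7710,
#>   null = 0.3636 +/- 0.0188
#>   SES = 21.618, lower-tail p = 1 (n_perm = 999)
```

The 95 significantly positive pairs (of 1225 scored; species without any
positive partner are filtered) form a network whose five detected modules
match the five planted ones, and whose modularity sits ~22 null standard
deviations above what its degree sequence alone would produce.

Within-module assembly rules for plants (module 2 here carries the planted
convergent trait regime):

```r
fd <- functionalDistance(b$plantTraits)
moduleDistanceSES(part, fd, guild = "plant", guildMap = guilds(b$presence),
                  nPerm = 999, seed = 9)[, c("module", "n", "observed",
                                             "SES", "p")]
#>   module n  observed        SES     p
#> 1      1 8 0.2476028 -0.9718620 0.170
#> 2      2 7 0.0899263 -5.0464571 0.001
#> 3      3 6 0.3007676  0.5466632 0.724
#> 4      4 8 0.2677133 -0.4189296 0.354
#> 5      5 7 0.2178137 -1.6864756 0.040
```

Module 2's mean functional distance (0.090) is far below its reassignment
null (SES −5.0, p = 0.001): environmental filtering, as planted. The other
modules are indistinguishable from chance at the two one-sided 0.05 reads.

`runPipeline(pipelineConfig(...))` chains every stage — classification,
network, structure nulls under all three permutation algorithms side by
side, knock-outs, module assembly tests, dispersion nulls, and per-module
plus whole-data variance partitioning — and writes CSV tables, a GraphML
export and a JSON report; identical config and seed reproduce every table
byte for byte. A thin CLI wrapper lives at `inst/scripts/coocnet.R`
(`generate` / `run` subcommands).

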