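---
title: "Assembly rules from species co-occurrence networks: models and choices"
author: "coocnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly rules from species co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocnet)
```

## The question the package answers

Species assemble into communities under several, possibly simultaneous,
rules: environmental filtering (co-occurring species are more similar than
chance), limiting similarity (they are less similar than chance), and
neutral dynamics (similarity is random). `coocnet` operationalises a
workflow for detecting these rules from a multi-guild site x species survey
— the motivating system is plants and orthopterans in permanent mountain
grasslands — by (i) building a positive co-occurrence network, (ii) showing
that the network is modular and/or nested beyond what its degrees impose,
(iii) scoring every species' contribution to that structure, (iv) testing
trait and phylogeny based assembly rules *within each module*, and (v)
contrasting all of this with abundance-based dispersion and
variance-partitioning analyses.

## Pairwise co-occurrence model

For two species occupying $N_1$ and $N_2$ of $N$ sites, the number $J$ of
jointly occupied sites under random independent placement is hypergeometric,

$$P(J=j) \;=\; \binom{N_1}{j}\binom{N-N_1}{N_2-j}\Big/\binom{N}{N_2},
\qquad \max(0, N_1+N_2-N) \le j \le \min(N_1, N_2).$$

`classifyPairs()` computes both one-sided tails including the atom at the
observed value ($p_{\le} = P(J \le j_{obs})$, $p_{\ge} = P(J \ge j_{obs})$)
and classifies a pair *positive* when $p_{\ge} < \alpha$, *negative* when
$p_{\le} < \alpha$, *random* otherwise. Defaults follow the probabilistic
co-occurrence model's conventions: $\alpha = 0.05$ and a testability filter
`minExpected = 1` on the expected co-occurrence $N_1 N_2 / N$; untestable
pairs (including species with zero occupancy) are reported but never become
edges. Within- and between-guild pairs are scored identically; the network
deliberately mixes guilds. Probabilities are computed in log space
(`lchoose`), so site numbers in the hundreds lose no precision.

`buildNetwork()` keeps exactly the positive pairs and drops species with no
positive partner; the retention counts per guild travel with the network
object. Negative co-occurrences are available in the pair table but are
never turned into an analysis graph.

## Modularity and nestedness

Modularity of a partition is Newman's
$Q = \sum_c (e_{cc} - a_c^2)$, with $e_{cc}$ the fraction of edges inside
module $c$ and $a_c$ the fraction of edge ends in $c$. Modules are found by
the classic fast-greedy agglomeration: start from singletons and repeatedly
merge the connected pair of communities with the largest
$\Delta Q = e_{ab} - 2a_a a_b$, keeping the partition at peak $Q$. Two
choices make the procedure exactly reproducible without a seed: ties in
$\Delta Q$ are broken by the lexicographically smallest community pair
(community index = smallest original vertex), and modules are renumbered by
decreasing size. The merge loop lives in C++; at the package's network
sizes (tens to a few hundred species) a dense $O(n^3)$ bookkeeping is
faster than heap-based variants. Exhaustive partition search on all graphs
we use with $\le 7$ vertices confirms the greedy optimum on the tested
families, and planted-partition simulations confirm recovery at realistic
sizes.

Nestedness is NODF on the binary adjacency, rescaled to $[0,1]$: for every
pair of rows (and of columns) with strictly decreasing fill, count the
shared neighbours as a fraction of the poorer row's fill; equal-fill pairs
contribute zero. Two consequences worth knowing:

* the value 1 is attained by a perfectly nested *rectangular* matrix (the
  "stair"), but never by a simple-graph adjacency — every simple graph has
  two vertices of equal degree, and the zero diagonal breaks containment —
  so observed network values sit well below 1 even for strongly nested
  graphs;
* the index is invariant to simultaneous row/column permutation, because
  fill ordering is internal to the formula.

## Permutation nulls for structure

The null model randomizes the *network adjacency* under fixed degrees
(row/column sums of the symmetric adjacency), which is the degree sequence
of the graph. Three samplers are provided and reported side by side, never
mixed:

* `swap` — sequential 2x2 checkerboard (double-edge) swaps, counting
  applied moves;
* `tswap` — the same chain counting trial moves whether or not applied;
* `quasiswap` — an independent draw per sample: stub matching with the
  exact degree sequence, repaired into a simple graph by swaps that strictly
  reduce loops/multi-edges, then mixed with trial swaps. The mixing step is
  a deliberate design choice: fill-repair constructions alone are known to
  sample the fixed-degree graph set non-uniformly, while checkerboard-swap
  chains have a symmetric proposal and therefore a uniform stationary
  distribution. With mixing, quasiswap keeps its defining property (the
  draw depends on the data only through the degree sequence) *and* passes a
  chi-square uniformity check over an enumerable graph class.

Chain defaults are burn-in $10|E|$ and thinning $5|E|$ attempted moves.
SES $= (\text{obs} - \bar{x}_{null})/s_{null}$ and the lower-tail
$p = (1 + \#\{null < obs\})/(1 + n_{perm})$; note this add-one formula
reaches exactly 1 when the observed value exceeds every draw. A null with
zero spread reports SES as undefined rather than 0. The default
$n_{perm} = 9999$ matches the workflow's reference setting; tests and the
bundled scripts use 999 or less, which the provenance block always records.
An alternative mode (`null = "matrix"`) permutes the site x species matrix
under fixed marginals (via `vegan`'s null models) and rebuilds the network
each draw; it is offered for sensitivity analysis because the description
of the original workflow is ambiguous about which object was permuted.

## Knock-out importance

Each species is removed in turn, module detection is re-run from scratch
(not reusing the original partition), and
$\Delta_i = \text{initial} - \text{leave-one-out}$ for both $Q$ and
nestedness. The vector of deltas is standardized,
$SES_i = (\Delta_i - \bar\Delta)/\sigma_\Delta$, with the *sample* standard
deviation by default (the formula's denominator is ambiguous; a population
switch is provided). Positive SES means the structure degrades when the
species is lost; a bridge between modules typically gets negative
modularity SES because its removal sharpens the modules. If all deltas are
equal (vertex-transitive graphs) the SES column is NA by design.

## Within-module assembly tests

For a distance matrix $d$ (functional Gower or phylogenetic cophenetic) and
a guild, the observed statistic per module is the mean pairwise distance
among the module's guild species. The null reassigns the guild's species to
modules at random, holding all module sizes fixed and the distance matrix
intact — a joint reassignment, not per-focal-module resampling. The
lower-tail $p$ is read twice at $\alpha = 0.05$: $p \le 0.05$ flags
convergence (filtering), $p \ge 0.95$ divergence (limiting similarity).
No multiplicity correction is applied to these flags; a Benjamini-Hochberg
column is emitted alongside for reference. Modules with fewer than two
guild species are reported as not testable.

Trait shifts across modules use `kruskal.test` for continuous traits and
`fisher.test` on the module x value table for binary traits, with constant
traits skipped and noted.

Functional distances are Gower: range-normalised absolute differences for
continuous traits, simple matching for binary ones, averaged over the
traits observed in both species (pairwise-complete weighting). The original
workflow does not name its functional distance; Gower is the de facto
standard for mixed trait tables and is invariant to affine rescaling of any
continuous trait (asserted in tests). Species with no usable trait are
excluded from functional analyses only.

## Abundance-based analyses

*Dispersion.* FDis embeds species by principal coordinates of $d$ (keeping
negative-eigenvalue axes as a correction term, so non-Euclidean Gower
matrices are handled exactly), then computes per site the
abundance-weighted mean distance of the present species to the site's
abundance-weighted centroid. PDis is the same index on the cophenetic
matrix. The null permutes species identities — whole abundance columns are
reassigned to species labels — which preserves each site's abundance
profile and richness exactly while randomizing which species carries which
abundance; guilds are permuted separately. The whole-dataset statistic is
the unweighted mean of per-site values.

*Variance partitioning.* Abundances are Hellinger-transformed
($y' = \sqrt{y_{ij}/y_{i\cdot}}$) and the adjusted $R^2$ of the
multivariate linear projection (RDA; canonical axes are never needed and
not computed) is decomposed over three predictor sets — agricultural
practices, soil, spatial location — into the seven fractions by
inclusion-exclusion over the seven models. Ezekiel's adjustment uses the
*rank* of each predictor matrix, so collinear or duplicated columns do not
distort fractions; the seven fractions sum to the full-model adjusted
$R^2$ exactly, and negative adjusted fractions are reported as computed.
The three pure fractions are tested by Freedman-Lane residual permutation
under the reduced model, on the pseudo-F scale: the raw semipartial $R^2$
is not pivotal under that scheme and we measured strong anti-conservatism
with it, while pseudo-F restores nominal type-I error (this matches
`vegan::anova.cca`'s choice of statistic).

Per-module analyses first split the *raw* abundance matrix by module and
Hellinger-transform each subset on its own. Transforming the whole matrix
first and then subsetting leaks signal between modules: when a gradient
drives one module's abundances, every other module's *relative* abundances
shift too, and non-driven modules get flagged. The whole-data analysis, by
contrast, uses the global transform, which is exactly the "ignore network
structure" reading.

## The synthetic data generator

Because the original field data are not deposited, the package carries a
first-class generator whose defaults are the study conditions at full
scale: 48 sites in five clusters, 197 plants spread evenly over five
modules, 22 orthopterans concentrated in modules 1, 2 and 4, occurrence
probability $p_{in} = 0.7$ at the module's cluster and $p_{out} = 0.05$
elsewhere, log-normal(0, 1) abundances. Trait regimes per module —
convergent (module mean + small sd), divergent (evenly spaced with jitter),
neutral (iid standard normal) — default to one divergent (module 3) and one
convergent (module 4) plant module. Trees are pure-birth ultrametric
(`ape::rphylo`); conserved traits evolve by Brownian motion along them.

Environmental effects are declared as (module, predictor set, size)
triples. The set's columns get a mean offset of `size` at the module's
cluster sites; by default the spatial set carries a monotone, elevation-like
gradient across clusters (sizes $-1.5 \dots 1.5$ — equal offsets for every
module would add a constant to all sites, i.e. no gradient at all) and the
agricultural set drives modules 2, 4 and 5. Species of a driven module load
on the driving set's site score with *heterogeneous* coefficients
$\beta_j \sim N(0, |size|)$ on the log scale. Heterogeneity is essential,
not cosmetic: a loading shared by all species of a module multiplies the
whole module by a common site factor, which cancels exactly under any
relative-abundance analysis (Hellinger rows are scale-invariant), leaving
the planted driver invisible by construction.

Every bundle is bit-identical regenerable from (scenario, seed): one master
seed drives sub-seeds per component in a fixed order. Ground-truth labels
live in fields that no analysis function accepts.

What the generator does **not** emulate: observation error on the
Braun-Blanquet scale, sweep-net sampling effort, spatial autocorrelation
beyond the cluster structure, phylogenetic clustering of module membership,
and trait correlations across traits. Passing the recovery tests therefore
shows the pipeline detects the *kinds* of structure it targets at realistic
sizes and noise — not that real grassland data would yield any particular
value. With the planted defaults, modularity SES on synthetic networks is
far larger than anything a field survey would produce, since block
structure with $p_{in}/p_{out} = 14$ is much cleaner than real communities;
and per-module driver recovery at default effect sizes has high power in
the focal driven module but only moderate power when two gradients compete
in one module.

## Numerical and procedural choices

* Braun-Blanquet codes 0-7 (0 = absent; 1-7 = r, +, 1, 2, 3, 4, 5) map to
  midpoint covers 0, 0.1, 0.5, 2.5, 15, 37.5, 62.5, 87.5 percent —
  conventional phytosociological midpoints, overridable.
* Species columns are canonicalised (sorted) on construction so permutation
  seeds reproduce across input orderings; all joins are by label, never by
  position.
* Greedy merges stop when no connected community pair remains, so
  disconnected components are never force-merged; the peak-Q partition is
  always at least as good as the single-module partition ($Q = 0$).
* Ties/atoms: both hypergeometric tails include $P(J = j_{obs})$, hence
  $p_{\le} + p_{\ge} \ge 1$.
* Degenerate nulls (zero spread) always surface as `SES = NA` plus a flag,
  never as 0.
* Sites with zero total abundance are dropped (with a warning) before
  Hellinger; per-module subsets drop their own empty sites and carry the
  matching predictor rows.
* Default problem sizes in the test-suite simulations: the full default
  scenario for network recovery (100 seeds, 999 permutations), 40-species
  trait scenarios for assembly power (100 seeds), 50 bundles for driver
  recovery — sizes chosen so the whole suite stays a desk-scale run while
  estimating each rate with usable precision.

## Known limitations

* The greedy optimiser is a heuristic; on arbitrary graphs its peak Q can
  sit slightly below the global optimum (and below other CNM variants'
  peaks, depending on tie order). The acceptance bar is exact optimality on
  small graphs and planted-structure recovery at scale, not global
  optimality in general.
* NODF on simple-graph adjacencies cannot reach 1 (equal-degree pairs zero
  out), so cross-study comparisons of absolute nestedness levels need care.
* The dispersion and reassignment nulls assume exchangeability within a
  guild; strong phylogenetic or spatial structure in who-is-where violates
  this and is exactly what the SES is meant to detect, but p-values for
  *other* hypotheses inherit mild miscalibration when rows are strongly
  non-exchangeable.
* Fisher's exact test on module x trait tables becomes expensive for many
  modules x many levels; the intended use (two-guild surveys, few modules,
  binary traits) keeps tables tiny.
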