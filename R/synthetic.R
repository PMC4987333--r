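#' @include AllClasses.R
NULL

.regime <- function(kind = "neutral", sd = 0.3, spread = 2) {
  list(kind = kind, sd = sd, spread = spread)
}

#' Define a synthetic grassland survey scenario
#'
#' Defaults mirror the scale and structure of a two-guild mountain grassland
#' survey: 48 sites in five site clusters, 197 plant and 22 orthopteran
#' species planted into five modules (orthopterans concentrated in modules
#' 1, 2 and 4), occurrence probability 0.7 at the module's cluster sites and
#' 0.05 elsewhere, log-normal abundances, trait regimes of convergence /
#' divergence / neutrality per module, and environmental gradients (spatial
#' set driving all modules, agricultural set driving modules 2, 4 and 5).
#'
#' @param nSites,nPlants,nOrthopterans,nModules scenario dimensions.
#' @param pIn,pOut within/outside-cluster occurrence probabilities.
#' @param orthopteranModules modules receiving orthopteran species.
#' @param plantRegimes,orthopteranRegimes per-module trait regimes; each a
#'   `list(kind, sd, spread)` with kind `"neutral"`, `"convergent"` or
#'   `"divergent"`.
#' @param phyloSignal simulate conserved traits by Brownian motion (TRUE) or
#'   iid (FALSE).
#' @param envEffects data.frame(module, set, size) mapping predictor sets to
#'   the modules they drive.
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance parameters.
#' @return A [SyntheticScenario-class].
#' @export
syntheticScenario <- function(nSites = 48, nPlants = 197,
                              nOrthopterans = 22, nModules = 5,
                              pIn = 0.7, pOut = 0.05,
                              orthopteranModules = c(1, 2, 4),
                              plantRegimes = NULL,
                              orthopteranRegimes = NULL,
                              phyloSignal = TRUE,
                              envEffects = NULL,
                              abundanceMeanlog = 0, abundanceSdlog = 1) {
  if (is.null(plantRegimes)) {
    # study-shaped default: one divergent and one convergent plant module
    plantRegimes <- replicate(nModules, .regime("neutral"), simplify = FALSE)
    if (nModules >= 3) plantRegimes[[3]] <- .regime("divergent")
    if (nModules >= 4) plantRegimes[[4]] <- .regime("convergent")
  }
  if (is.null(orthopteranRegimes))
    orthopteranRegimes <- replicate(nModules, .regime("neutral"),
                                    simplify = FALSE)
  if (is.null(envEffects)) {
    # spatial set forms a monotone (elevation-like) gradient across the site
    # clusters, touching every module; an equal offset for all modules would
    # be a constant shift, i.e. no gradient at all. Agriculture drives a
    # subset of modules.
    agMods <- intersect(c(2, 4, 5), seq_len(nModules))
    spSizes <- if (nModules > 1)
      seq(-1.5, 1.5, length.out = nModules) else 1.5
    envEffects <- data.frame(
      module = c(seq_len(nModules), agMods),
      set = c(rep("spatial", nModules), rep("agricultural", length(agMods))),
      size = c(spSizes, rep(1.5, length(agMods))))
  }
  new("SyntheticScenario", nSites = as.integer(nSites),
      nPlants = as.integer(nPlants),
      nOrthopterans = as.integer(nOrthopterans),
      nModules = as.integer(nModules), pIn = pIn, pOut = pOut,
      orthopteranModules = as.integer(orthopteranModules),
      plantRegimes = plantRegimes, orthopteranRegimes = orthopteranRegimes,
      phyloSignal = phyloSignal, envEffects = envEffects,
      abundanceMeanlog = abundanceMeanlog, abundanceSdlog = abundanceSdlog)
}

# even allocation of n items over the given bins, in order
.allocate <- function(n, bins) {
  sort(rep_len(bins, n))
}

#' Generate a planted-module occurrence matrix
#'
#' Sites are assigned to clusters matched 1:1 with modules; a species of
#' module k occurs at cluster-k sites with probability `pIn` and elsewhere
#' with `pOut` (independent Bernoulli draws). Plants are allocated evenly over
#' all modules; orthopterans evenly over `orthopteranModules`.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param seed integer seed (mandatory: a bundle is regenerable from
#'   (scenario, seed)).
#' @return List: `matrix` (presence [CommunityMatrix-class]), `truth`
#'   (data.frame species, guild, module), `siteCluster` (named integer).
#' @export
generateOccurrence <- function(scenario, seed) {
  stopifnot(is(scenario, "SyntheticScenario"))
  set.seed(seed)
  ns <- scenario@nSites; nm <- scenario@nModules
  siteCluster <- .allocate(ns, seq_len(nm))
  nIn <- min(table(siteCluster))
  expOcc <- nIn * scenario@pIn + (ns - nIn) * scenario@pOut
  if (expOcc < 2)
    stop("scenario rejected: expected occupancy below 2 sites per species")
  sites <- sprintf("S%02d", seq_len(ns))
  names(siteCluster) <- sites
  plants <- sprintf("P%03d", seq_len(scenario@nPlants))
  orth <- sprintf("O%02d", seq_len(scenario@nOrthopterans))
  truth <- data.frame(
    species = c(plants, orth),
    guild = c(rep("plant", length(plants)),
              rep("orthopteran", length(orth))),
    module = c(.allocate(length(plants), seq_len(nm)),
               .allocate(length(orth), scenario@orthopteranModules)),
    stringsAsFactors = FALSE)
  p <- matrix(scenario@pOut, ns, nrow(truth))
  for (k in seq_len(nm))
    p[siteCluster == k, truth$module == k] <- scenario@pIn
  occ <- matrix(rbinom(length(p), 1, p), ns, nrow(truth),
                dimnames = list(sites, truth$species))
  guild <- setNames(truth$guild, truth$species)
  list(matrix = communityMatrix(occ, guild = guild, valueKind = "presence"),
       truth = truth, siteCluster = siteCluster)
}

# one continuous trait column under per-module regimes; global scale ~ 1
.traitColumn <- function(modules, regimes) {
  n <- length(modules)
  x <- numeric(n)
  for (k in sort(unique(modules))) {
    idx <- modules == k
    reg <- regimes[[k]]
    x[idx] <- switch(reg$kind,
      neutral = rnorm(sum(idx)),
      convergent = rnorm(1) + rnorm(sum(idx), sd = reg$sd),
      divergent = {
        nk <- sum(idx)
        base <- if (nk == 1) 0 else
          seq(-reg$spread / 2, reg$spread / 2, length.out = nk)
        sample(base) + rnorm(nk, sd = 0.05)
      },
      stop("unknown regime kind: ", reg$kind))
  }
  x
}

#' Generate species traits under per-module assembly regimes
#'
#' Continuous traits: `neutral` modules draw iid standard normal values
#' (global sd 1); `convergent` modules draw from a module mean with small
#' within-module sd (environmental filtering); `divergent` modules get evenly
#' spaced values with jitter (limiting similarity: maximized nearest-neighbour
#' distance). Binary traits: module-biased Bernoulli (biased towards 1 in
#' non-neutral modules, 0.5 otherwise).
#'
#' @param truth data.frame (species, module) as returned by
#'   [generateOccurrence()], optionally filtered to one guild.
#' @param regimes list of per-module regimes (`list(kind, sd, spread)`).
#' @param nContinuous,nBinary numbers of traits to draw.
#' @param seed integer seed.
#' @return A [TraitTable-class].
#' @export
generateTraits <- function(truth, regimes, nContinuous = 4, nBinary = 0,
                           seed) {
  set.seed(seed)
  n <- nrow(truth)
  cols <- list()
  kinds <- character()
  for (t in seq_len(nContinuous)) {
    cols[[sprintf("trait_c%d", t)]] <- .traitColumn(truth$module, regimes)
    kinds[sprintf("trait_c%d", t)] <- "continuous"
  }
  for (t in seq_len(nBinary)) {
    pMod <- vapply(regimes, function(r)
      if (r$kind == "neutral") 0.5 else 0.85, numeric(1))
    cols[[sprintf("trait_b%d", t)]] <-
      rbinom(n, 1, pMod[truth$module])
    kinds[sprintf("trait_b%d", t)] <- "binary"
  }
  v <- do.call(cbind, cols)
  rownames(v) <- truth$species
  traitTable(v, kind = kinds)
}

#' Generate an ultrametric tree and (optionally conserved) traits
#'
#' Pure-birth ultrametric tree via [ape::rphylo()]; one trait simulated by
#' Brownian motion along its branches (`signal = TRUE`, via
#' [ape::rTraitCont()]) or iid normal (`signal = FALSE`).
#'
#' @param nSpecies number of tips (>= 3).
#' @param signal Brownian (TRUE) or iid (FALSE) trait.
#' @param seed integer seed.
#' @param tipLabels optional tip labels (length `nSpecies`).
#' @return List: `tree` ([ape::phylo]), `traits` ([TraitTable-class] with one
#'   continuous column `conserved`).
#' @export
generateTreeAndConservedTraits <- function(nSpecies, signal = TRUE, seed,
                                           tipLabels = NULL) {
  if (nSpecies < 3) stop("need >= 3 species")
  set.seed(seed)
  tree <- ape::rphylo(nSpecies, birth = 1, death = 0)
  if (!is.null(tipLabels)) tree$tip.label <- sample(tipLabels)
  x <- if (signal) ape::rTraitCont(tree, model = "BM", sigma = 1)
       else setNames(rnorm(nSpecies), tree$tip.label)
  v <- matrix(x[tree$tip.label], ncol = 1,
              dimnames = list(tree$tip.label, "conserved"))
  list(tree = tree, traits = traitTable(v, kind = c(conserved = "continuous")))
}

#' Generate environmental tables and abundances
#'
#' All predictor columns start as iid standard normal per site; for every
#' (module, set) entry of `effects`, the set's columns get a mean offset of
#' `size` at the module's cluster sites. Abundance is
#' presence x LogNormal(meanlog, sdlog), times exp(0.5 * size * z) for species
#' of driven modules, where z is the site score of the driving set (its
#' offset column mean), so driven species' abundances load linearly (on the
#' log scale) on their driving predictors. Abundance zeros coincide exactly
#' with presence zeros.
#'
#' @param presence presence [CommunityMatrix-class] from
#'   [generateOccurrence()].
#' @param truth,siteCluster ground truth from [generateOccurrence()].
#' @param effects data.frame(module, set, size).
#' @param meanlog,sdlog log-normal abundance parameters.
#' @param seed integer seed.
#' @return List: `env` ([EnvTables-class]), `abundance`
#'   ([CommunityMatrix-class]).
#' @export
generateEnvironmentAndAbundance <- function(presence, truth, siteCluster,
                                            effects,
                                            meanlog = 0, sdlog = 1, seed) {
  set.seed(seed)
  sites <- rownames(presence@values)
  ns <- length(sites)
  setCols <- list(
    agricultural = c("cutting", "grazing", "fertilizers"),
    soil = c("totalN", "CN", "CEC"),
    spatial = c("longitude", "latitude", "elevation"))
  env <- lapply(setCols, function(cn) {
    df <- as.data.frame(matrix(rnorm(ns * length(cn)), ns,
                               dimnames = list(sites, cn)))
    df
  })
  if (nrow(effects)) {
    for (r in seq_len(nrow(effects))) {
      k <- effects$module[r]; s <- effects$set[r]; e <- effects$size[r]
      env[[s]] <- env[[s]] + e * (siteCluster == k)
    }
  }
  # site score of a set = mean of its (offset) columns
  zBySet <- lapply(names(setCols), function(s) rowMeans(env[[s]]))
  names(zBySet) <- names(setCols)

  occ <- presence@values[, truth$species, drop = FALSE]
  ab <- occ * matrix(rlnorm(length(occ), meanlog, sdlog), nrow(occ))
  if (nrow(effects)) {
    for (r in seq_len(nrow(effects))) {
      k <- effects$module[r]; s <- effects$set[r]; e <- effects$size[r]
      spk <- truth$species[truth$module == k]
      # species respond to the gradient with heterogeneous loadings: a
      # shared multiplier would leave within-module composition (hence any
      # relative-abundance analysis) untouched
      beta <- rnorm(length(spk), 0, abs(e))
      ab[, spk] <- ab[, spk] *
        exp(outer(zBySet[[s]], beta))
    }
  }
  list(env = envTables(env$agricultural, env$soil, env$spatial),
       abundance = communityMatrix(ab, guild = presence@guild,
                                   valueKind = "abundance"))
}

#' Generate a complete synthetic data bundle
#'
#' Occurrence + abundance matrices, per-guild trait tables and ultrametric
#' trees with conserved traits, environmental tables, and ground-truth labels.
#' Bit-identical regenerable from (scenario, seed); ground truth is carried in
#' separate fields that no analysis function accepts.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param seed integer seed.
#' @return List with elements: presence, abundance
#'   ([CommunityMatrix-class]), plantTraits, orthopteranTraits
#'   ([TraitTable-class]), plantTree, orthopteranTree ([ape::phylo]),
#'   conservedPlant, conservedOrthopteran ([TraitTable-class]), env
#'   ([EnvTables-class]), truth (data.frame), siteCluster, scenario, seed.
#' @export
generateBundle <- function(scenario = syntheticScenario(), seed) {
  stopifnot(is(scenario, "SyntheticScenario"))
  occ <- generateOccurrence(scenario, seed = seed)
  truth <- occ$truth
  plantTruth <- truth[truth$guild == "plant", ]
  orthTruth <- truth[truth$guild == "orthopteran", ]
  plantTraits <- generateTraits(plantTruth, scenario@plantRegimes,
                                nContinuous = 4, nBinary = 0,
                                seed = seed + 1L)
  orthTraits <- generateTraits(orthTruth, scenario@orthopteranRegimes,
                               nContinuous = 0, nBinary = 4,
                               seed = seed + 2L)
  pt <- generateTreeAndConservedTraits(nrow(plantTruth),
                                       signal = scenario@phyloSignal,
                                       seed = seed + 3L,
                                       tipLabels = plantTruth$species)
  ot <- generateTreeAndConservedTraits(nrow(orthTruth),
                                       signal = scenario@phyloSignal,
                                       seed = seed + 4L,
                                       tipLabels = orthTruth$species)
  ea <- generateEnvironmentAndAbundance(occ$matrix, truth, occ$siteCluster,
                                        scenario@envEffects,
                                        meanlog = scenario@abundanceMeanlog,
                                        sdlog = scenario@abundanceSdlog,
                                        seed = seed + 5L)
  list(presence = occ$matrix, abundance = ea$abundance,
       plantTraits = plantTraits, orthopteranTraits = orthTraits,
       plantTree = pt$tree, orthopteranTree = ot$tree,
       conservedPlant = pt$traits, conservedOrthopteran = ot$traits,
       env = ea$env, truth = truth, siteCluster = occ$siteCluster,
       scenario = scenario, seed = seed)
}

#' Write a synthetic bundle to a directory
#'
#' CSVs for matrices, traits and environment, Newick for the trees, and a
#' JSON ground-truth file.
#'
#' @param bundle list from [generateBundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSiteSpecies(bundle$presence, file.path(dir, "presence.csv"))
  writeSiteSpecies(bundle$abundance, file.path(dir, "abundance.csv"))
  wtr <- function(tt, path)
    write.csv(data.frame(species = rownames(tt@values), tt@values,
                         check.names = FALSE), path, row.names = FALSE)
  wtr(bundle$plantTraits, file.path(dir, "plant_traits.csv"))
  wtr(bundle$orthopteranTraits, file.path(dir, "orthopteran_traits.csv"))
  writeNewick(bundle$plantTree, file.path(dir, "plant_tree.nwk"))
  writeNewick(bundle$orthopteranTree, file.path(dir, "orthopteran_tree.nwk"))
  env <- bundle$env
  wenv <- function(df, path)
    write.csv(data.frame(site = rownames(df), df, check.names = FALSE),
              path, row.names = FALSE)
  wenv(env@agricultural, file.path(dir, "env_agricultural.csv"))
  wenv(env@soil, file.path(dir, "env_soil.csv"))
  wenv(env@spatial, file.path(dir, "env_spatial.csv"))
  jsonlite::write_json(
    list(truth = bundle$truth,
         siteCluster = as.list(bundle$siteCluster),
         seed = bundle$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
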