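#' @include coocnet-package.R
NULL

.VALUE_KINDS <- c("presence", "braun_blanquet", "abundance")
.GUILDS <- c("plant", "orthopteran")
.DIST_KINDS <- c("functional", "phylogenetic")

#' Site-by-species community matrix
#'
#' Holds a sites x species matrix of occurrence values together with the guild
#' of every species and the kind of value stored: `"presence"` (0/1),
#' `"braun_blanquet"` (ordinal cover codes 0-7, where codes 1-7 are the seven
#' degrees r, +, 1, 2, 3, 4, 5 of the Braun-Blanquet scale) or `"abundance"`
#' (non-negative continuous). Species columns are kept in canonical
#' (alphabetical) order so that permutation seeds are reproducible.
#'
#' @slot values numeric matrix, sites in rows, species in columns, with
#'   dimnames.
#' @slot guild named character vector mapping every species to `"plant"` or
#'   `"orthopteran"`.
#' @slot valueKind one of `"presence"`, `"braun_blanquet"`, `"abundance"`.
#' @exportClass CommunityMatrix
setClass("CommunityMatrix",
  slots = c(values = "matrix", guild = "character", valueKind = "character"))

setValidity("CommunityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have site rownames and species colnames")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate site labels")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate species labels")
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (anyNA(v)) msg <- c(msg, "values must not contain NA")
  if (any(v < 0)) msg <- c(msg, "values must be non-negative")
  if (length(object@valueKind) != 1L || !object@valueKind %in% .VALUE_KINDS)
    msg <- c(msg, sprintf("valueKind must be one of %s",
                          paste(.VALUE_KINDS, collapse = ", ")))
  else {
    if (object@valueKind == "presence" && !all(v %in% c(0, 1)))
      msg <- c(msg, "presence values must all be 0 or 1")
    if (object@valueKind == "braun_blanquet" &&
        !all(v %in% 0:7))
      msg <- c(msg, "braun_blanquet values must be integer codes 0-7")
  }
  sp <- colnames(v)
  if (!all(sp %in% names(object@guild)))
    msg <- c(msg, sprintf("guild missing for species: %s",
      paste(setdiff(sp, names(object@guild)), collapse = ", ")))
  else if (!all(object@guild[sp] %in% .GUILDS))
    msg <- c(msg, "guild values must be 'plant' or 'orthopteran'")
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityMatrix
#'
#' @param values numeric matrix (sites x species) with dimnames.
#' @param guild named character vector (species -> `"plant"`/`"orthopteran"`);
#'   defaults to all `"plant"`.
#' @param valueKind `"presence"`, `"braun_blanquet"` or `"abundance"`.
#' @return A [CommunityMatrix-class] object with species columns sorted.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("spA", "spB")))
#' communityMatrix(m, valueKind = "presence")
#' @export
communityMatrix <- function(values,
                            guild = setNames(rep("plant", ncol(values)),
                                             colnames(values)),
                            valueKind = "presence") {
  ord <- order(colnames(values))
  values <- values[, ord, drop = FALSE]
  storage.mode(values) <- "double"
  new("CommunityMatrix", values = values, guild = guild,
      valueKind = valueKind)
}

#' Species trait table
#'
#' Species x traits matrix with a declared kind (`"continuous"` or `"binary"`)
#' for every trait. Missing values are allowed; binary traits must be 0/1/NA.
#'
#' @slot values numeric matrix, species in rows, traits in columns.
#' @slot kind named character vector, one entry per trait.
#' @exportClass TraitTable
setClass("TraitTable", slots = c(values = "matrix", kind = "character"))

setValidity("TraitTable", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have species rownames and trait colnames")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate species labels")
  tr <- colnames(v)
  if (!setequal(names(object@kind), tr))
    msg <- c(msg, "kind must be declared for every trait")
  else {
    if (!all(object@kind %in% c("continuous", "binary")))
      msg <- c(msg, "trait kind must be 'continuous' or 'binary'")
    for (t in tr[object@kind[tr] == "binary"]) {
      x <- v[, t]
      if (!all(x[!is.na(x)] %in% c(0, 1)))
        msg <- c(msg, sprintf("binary trait '%s' has values outside {0,1}", t))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TraitTable
#'
#' @param values numeric matrix (species x traits) with dimnames; NAs allowed.
#' @param kind named character vector giving `"continuous"` or `"binary"` per
#'   trait.
#' @return A [TraitTable-class] object.
#' @export
traitTable <- function(values, kind) {
  new("TraitTable", values = values, kind = kind)
}

#' Pairwise species distance matrix
#'
#' Symmetric non-negative matrix with zero diagonal, labelled by species, and
#' tagged as `"functional"` or `"phylogenetic"`.
#'
#' @slot d symmetric numeric matrix with zero diagonal.
#' @slot kind `"functional"` or `"phylogenetic"`.
#' @exportClass SpeciesDist
setClass("SpeciesDist", slots = c(d = "matrix", kind = "character"))

setValidity("SpeciesDist", function(object) {
  d <- object@d
  msg <- character()
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("distance matrix must have identical row and column species labels")
  if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicate species labels")
  if (any(d < 0, na.rm = TRUE)) msg <- c(msg, "distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-10)
    msg <- c(msg, "distance matrix must be symmetric")
  if (length(object@kind) != 1L || !object@kind %in% .DIST_KINDS)
    msg <- c(msg, "kind must be 'functional' or 'phylogenetic'")
  if (length(msg)) msg else TRUE
})

#' Construct a SpeciesDist
#'
#' @param d symmetric numeric matrix with zero diagonal and species dimnames,
#'   or a [stats::dist] object with labels.
#' @param kind `"functional"` or `"phylogenetic"`.
#' @return A [SpeciesDist-class] object.
#' @export
speciesDist <- function(d, kind) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  new("SpeciesDist", d = d, kind = kind)
}

#' Positive co-occurrence network
#'
#' Undirected simple graph over species classified as positively co-occurring;
#' stored as a symmetric 0/1 adjacency matrix with zero diagonal. Isolated
#' vertices are removed when the network is built.
#'
#' @slot adjacency symmetric 0/1 integer matrix, zero diagonal, species
#'   dimnames.
#' @slot guild named character vector for the retained species.
#' @exportClass CoocNetwork
setClass("CoocNetwork", slots = c(adjacency = "matrix", guild = "character"))

setValidity("CoocNetwork", function(object) {
  a <- object@adjacency
  msg <- character()
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    return("adjacency must have identical row/column species labels")
  if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
  if (any(diag(a) != 0)) msg <- c(msg, "self-loops are not allowed")
  if (!identical(a, t(a))) msg <- c(msg, "adjacency must be symmetric")
  if (!all(rownames(a) %in% names(object@guild)))
    msg <- c(msg, "guild missing for some network species")
  if (length(msg)) msg else TRUE
})

#' Species-to-module partition
#'
#' @slot membership named integer vector, species -> module id (contiguous
#'   from 1).
#' @slot Q Newman modularity of the partition on the network it was fitted to.
#' @exportClass ModulePartition
setClass("ModulePartition", slots = c(membership = "integer", Q = "numeric"))

setValidity("ModulePartition", function(object) {
  m <- object@membership
  msg <- character()
  if (is.null(names(m))) return("membership must be named by species")
  ids <- sort(unique(m))
  if (!identical(ids, seq_along(ids)))
    msg <- c(msg, "module ids must be contiguous integers starting at 1")
  if (length(msg)) msg else TRUE
})

#' Site-level explanatory tables
#'
#' Three predictor sets over a common site set: agricultural practices
#' (cutting, cuts/yr; grazing, livestock-unit days/ha/yr; fertilizers,
#' kg N/ha/yr), soil conditions (total N, C/N, CEC) and spatial location
#' (longitude, latitude, elevation).
#'
#' @slot agricultural data.frame with site rownames.
#' @slot soil data.frame with site rownames.
#' @slot spatial data.frame with site rownames.
#' @exportClass EnvTables
setClass("EnvTables",
  slots = c(agricultural = "data.frame", soil = "data.frame",
            spatial = "data.frame"))

setValidity("EnvTables", function(object) {
  s1 <- rownames(object@agricultural)
  msg <- character()
  if (!ncol(object@agricultural) || !ncol(object@soil) ||
      !ncol(object@spatial))
    msg <- c(msg, "each predictor set must be nonempty")
  if (!identical(s1, rownames(object@soil)) ||
      !identical(s1, rownames(object@spatial)))
    msg <- c(msg, "all three tables must share the same site set and order")
  if (length(msg)) msg else TRUE
})

#' Construct an EnvTables object
#'
#' @param agricultural,soil,spatial data.frames of numeric predictors with
#'   identical site rownames.
#' @return An [EnvTables-class] object.
#' @export
envTables <- function(agricultural, soil, spatial) {
  new("EnvTables", agricultural = agricultural, soil = soil,
      spatial = spatial)
}

#' Synthetic grassland survey scenario
#'
#' Parameters of the synthetic data generator. Defaults mirror the scale of a
#' two-guild grassland survey: 48 sites, 197 plant and 22 orthopteran species,
#' five planted modules with occurrence probabilities p_in = 0.7 inside the
#' module's site cluster and p_out = 0.05 elsewhere, log-normal abundances,
#' and environmental gradients driving selected modules.
#'
#' @slot nSites,nPlants,nOrthopterans,nModules integers.
#' @slot pIn,pOut occurrence probabilities inside/outside a species' module
#'   cluster (0 <= pOut < pIn <= 1).
#' @slot orthopteranModules integer vector of modules that receive
#'   orthopterans.
#' @slot plantRegimes,orthopteranRegimes lists of per-module trait regimes,
#'   each `list(kind = "neutral"|"convergent"|"divergent", sd = ..,
#'   spread = ..)`.
#' @slot phyloSignal logical; Brownian (TRUE) or iid (FALSE) conserved traits.
#' @slot envEffects data.frame with columns module, set
#'   (`"agricultural"`/`"soil"`/`"spatial"`), size.
#' @slot abundanceMeanlog,abundanceSdlog log-normal abundance parameters.
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  slots = c(nSites = "integer", nPlants = "integer", nOrthopterans = "integer",
            nModules = "integer", pIn = "numeric", pOut = "numeric",
            orthopteranModules = "integer", plantRegimes = "list",
            orthopteranRegimes = "list", phyloSignal = "logical",
            envEffects = "data.frame", abundanceMeanlog = "numeric",
            abundanceSdlog = "numeric"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (!(object@pOut >= 0 && object@pOut < object@pIn && object@pIn <= 1))
    msg <- c(msg, "need 0 <= pOut < pIn <= 1")
  if (object@nModules < 1L) msg <- c(msg, "nModules must be >= 1")
  if (object@nPlants < 2L * object@nModules)
    msg <- c(msg, "module sizes must be >= 2 (too few plants)")
  if (!all(object@orthopteranModules %in% seq_len(object@nModules)))
    msg <- c(msg, "orthopteranModules outside 1..nModules")
  if (length(object@plantRegimes) != object@nModules)
    msg <- c(msg, "one plant trait regime per module required")
  if (nrow(object@envEffects) &&
      !all(object@envEffects$set %in% c("agricultural", "soil", "spatial")))
    msg <- c(msg, "envEffects$set must be agricultural/soil/spatial")
  if (length(msg)) msg else TRUE
})
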