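#' @include AllClasses.R
NULL

#' Accessors for coocnet containers
#'
#' `siteNames()` and `speciesNames()` return the site/species labels;
#' `guilds()` the named guild vector; `valueKind()` the kind of value stored
#' in a [CommunityMatrix-class]; `moduleMembership()` the named species ->
#' module map of a [ModulePartition-class]; `nModules()` its number of
#' modules; `modularityQ()` its Newman Q; `degreeSequence()` and `edgeCount()`
#' the degrees and edge number of a [CoocNetwork-class]; `distKind()` the kind
#' of a [SpeciesDist-class]. `as.matrix()` returns the underlying numeric
#' matrix of a [CommunityMatrix-class], [SpeciesDist-class] or (adjacency of
#' a) [CoocNetwork-class].
#'
#' @param x a coocnet object.
#' @return See the individual accessor descriptions.
#' @name accessors
#' @aliases siteNames speciesNames guilds valueKind moduleMembership nModules
#'   modularityQ degreeSequence edgeCount distKind
NULL

#' @rdname accessors
#' @export
setGeneric("siteNames", function(x) standardGeneric("siteNames"))
#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setGeneric("guilds", function(x) standardGeneric("guilds"))
#' @rdname accessors
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))
#' @rdname accessors
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))
#' @rdname accessors
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))
#' @rdname accessors
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))
#' @rdname accessors
#' @export
setGeneric("degreeSequence", function(x) standardGeneric("degreeSequence"))
#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setGeneric("distKind", function(x) standardGeneric("distKind"))

#' @rdname accessors
setMethod("siteNames", "CommunityMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("speciesNames", "CommunityMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("guilds", "CommunityMatrix",
          function(x) x@guild[colnames(x@values)])
#' @rdname accessors
setMethod("valueKind", "CommunityMatrix", function(x) x@valueKind)
#' @rdname accessors
setMethod("speciesNames", "CoocNetwork", function(x) rownames(x@adjacency))
#' @rdname accessors
setMethod("guilds", "CoocNetwork",
          function(x) x@guild[rownames(x@adjacency)])
#' @rdname accessors
setMethod("degreeSequence", "CoocNetwork",
          function(x) rowSums(x@adjacency))
#' @rdname accessors
setMethod("edgeCount", "CoocNetwork", function(x) sum(x@adjacency) / 2)
#' @rdname accessors
setMethod("speciesNames", "SpeciesDist", function(x) rownames(x@d))
#' @rdname accessors
setMethod("distKind", "SpeciesDist", function(x) x@kind)
#' @rdname accessors
setMethod("speciesNames", "TraitTable", function(x) rownames(x@values))
#' @rdname accessors
setMethod("moduleMembership", "ModulePartition", function(x) x@membership)
#' @rdname accessors
setMethod("nModules", "ModulePartition",
          function(x) length(unique(x@membership)))
#' @rdname accessors
setMethod("modularityQ", "ModulePartition", function(x) x@Q)
#' @rdname accessors
setMethod("siteNames", "EnvTables", function(x) rownames(x@agricultural))

#' @rdname accessors
#' @export
setMethod("as.matrix", "CommunityMatrix", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("as.matrix", "SpeciesDist", function(x, ...) x@d)
#' @rdname accessors
#' @export
setMethod("as.matrix", "CoocNetwork", function(x, ...) x@adjacency)

setMethod("show", "CommunityMatrix", function(object) {
  v <- object@values
  g <- table(object@guild[colnames(v)])
  cat(sprintf("CommunityMatrix: %d sites x %d species (%s)\n",
              nrow(v), ncol(v), object@valueKind))
  cat(sprintf("  guilds: %s\n",
              paste(sprintf("%s %d", names(g), g), collapse = ", ")))
  cat(sprintf("  fill: %.1f%% nonzero\n", 100 * mean(v > 0)))
})

setMethod("show", "TraitTable", function(object) {
  cat(sprintf("TraitTable: %d species x %d traits (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%s:%s", colnames(object@values),
                            substr(object@kind[colnames(object@values)], 1, 4)),
                    collapse = ", ")))
})

setMethod("show", "SpeciesDist", function(object) {
  cat(sprintf("SpeciesDist (%s): %d species, range [%.3g, %.3g]\n",
              object@kind, nrow(object@d), min(object@d), max(object@d)))
})

setMethod("show", "CoocNetwork", function(object) {
  g <- table(object@guild[rownames(object@adjacency)])
  cat(sprintf("CoocNetwork: %d species, %d positive co-occurrence edges\n",
              nrow(object@adjacency), sum(object@adjacency) / 2))
  cat(sprintf("  guilds: %s\n",
              paste(sprintf("%s %d", names(g), g), collapse = ", ")))
})

setMethod("show", "ModulePartition", function(object) {
  tab <- table(object@membership)
  cat(sprintf("ModulePartition: %d modules over %d species (Q = %.4f)\n",
              length(tab), length(object@membership), object@Q))
  cat(sprintf("  sizes: %s\n", paste(as.integer(tab), collapse = ", ")))
})

setMethod("show", "EnvTables", function(object) {
  cat(sprintf(
    "EnvTables: %d sites; agricultural(%s), soil(%s), spatial(%s)\n",
    nrow(object@agricultural),
    paste(colnames(object@agricultural), collapse = ","),
    paste(colnames(object@soil), collapse = ","),
    paste(colnames(object@spatial), collapse = ",")))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: %d sites, %d plants + %d orthopterans, %d modules\n",
    object@nSites, object@nPlants, object@nOrthopterans, object@nModules))
  cat(sprintf("  pIn = %.2f, pOut = %.2f; orthopterans in modules %s\n",
              object@pIn, object@pOut,
              paste(object@orthopteranModules, collapse = ",")))
})
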