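#' @include AllClasses.R
NULL

#' Cophenetic distances between the tips of a phylogeny
#'
#' d(i, j) is the sum of branch lengths on the tree path between tips i and j
#' (computed with [ape::cophenetic.phylo()]).
#'
#' @param tree an [ape::phylo] tree with unique tip labels and branch lengths.
#' @return A [SpeciesDist-class] of kind `"phylogenetic"`.
#' @export
copheneticDistances <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  ord <- order(rownames(d))
  speciesDist(d[ord, ord], kind = "phylogenetic")
}

#' Gower distance over mixed traits
#'
#' Range-normalised absolute differences for continuous traits, simple
#' matching for binary traits, averaged over the traits observed for both
#' species (pairwise-complete weighting). Values are in \[0, 1\] and invariant
#' to affine rescaling of continuous traits. Species with no usable selected
#' trait are dropped with a warning (they remain available to phylogenetic
#' analyses).
#'
#' @param traits a [TraitTable-class].
#' @param traitSubset character vector of trait names (default: all traits).
#' @return A [SpeciesDist-class] of kind `"functional"`.
#' @export
functionalDistance <- function(traits, traitSubset = NULL) {
  stopifnot(is(traits, "TraitTable"))
  v <- traits@values
  if (is.null(traitSubset)) traitSubset <- colnames(v)
  if (!length(traitSubset)) stop("at least one trait must be selected")
  if (!all(traitSubset %in% colnames(v)))
    stop("unknown traits: ",
         paste(setdiff(traitSubset, colnames(v)), collapse = ", "))
  v <- v[, traitSubset, drop = FALSE]
  usable <- rowSums(!is.na(v)) > 0
  if (!all(usable)) {
    warning("species with all-missing selected traits dropped: ",
            paste(rownames(v)[!usable], collapse = ", "))
    v <- v[usable, , drop = FALSE]
  }
  if (nrow(v) < 2) stop("need >= 2 species with non-missing trait values")
  n <- nrow(v)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  kinds <- traits@kind[traitSubset]
  for (t in seq_along(traitSubset)) {
    x <- v[, t]
    ok <- outer(!is.na(x), !is.na(x), "&")
    if (kinds[t] == "continuous") {
      rg <- diff(range(x, na.rm = TRUE))
      dt <- if (rg > 0) abs(outer(x, x, "-")) / rg
            else matrix(0, n, n)
    } else {
      dt <- (outer(x, x, "!=")) + 0
    }
    dt[!ok] <- 0
    num <- num + dt
    den <- den + ok
  }
  if (any(den[upper.tri(den)] == 0))
    stop("some species pairs share no observed trait")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(v), rownames(v))
  ord <- order(rownames(d))
  speciesDist(d[ord, ord], kind = "functional")
}
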