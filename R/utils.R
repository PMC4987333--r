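#' @include AllClasses.R
NULL

# adjusted Rand index between two labelings over the same elements
.ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}

#' Agreement between a detected partition and planted module labels
#'
#' Adjusted Rand index between the module membership of a partition and a
#' reference labeling (e.g. the synthetic generator's ground truth), computed
#' over the species present in both.
#'
#' @param partition a [ModulePartition-class].
#' @param reference named vector of reference labels (species -> label) or a
#'   `truth` data.frame with columns species, module.
#' @return Adjusted Rand index (1 = identical partitions up to relabeling).
#' @export
moduleRecovery <- function(partition, reference) {
  stopifnot(is(partition, "ModulePartition"))
  if (is.data.frame(reference))
    reference <- setNames(reference$module, reference$species)
  sp <- intersect(names(partition@membership), names(reference))
  if (length(sp) < 2) stop("too few shared species")
  .ari(partition@membership[sp], reference[sp])
}
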