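#' @include AllClasses.R
NULL

# conventional midpoint percent cover for the seven Braun-Blanquet degrees
# (codes 1-7 = r, +, 1, 2, 3, 4, 5); code 0 = absent
.BB_MIDPOINTS <- c(`0` = 0, `1` = 0.1, `2` = 0.5, `3` = 2.5, `4` = 15,
                   `5` = 37.5, `6` = 62.5, `7` = 87.5)

#' Read a site-by-species table from CSV
#'
#' Expects sites as rows (first column = site labels) and species as columns.
#' Parse failures report the offending row/column.
#'
#' @param path CSV file path.
#' @param valueKind `"presence"`, `"braun_blanquet"` or `"abundance"`.
#' @param guild optional named character vector species -> guild; defaults to
#'   all `"plant"`.
#' @return A validated [CommunityMatrix-class].
#' @export
readSiteSpecies <- function(path, valueKind = "presence", guild = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a site-label column plus species columns")
  sites <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    cell <- which(is.na(suppressWarnings(as.numeric(df[[bad[1] + 1L]]))))[1]
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 cell, colnames(df)[bad[1] + 1L]))
  }
  storage.mode(m) <- "double"
  rownames(m) <- sites
  if (is.null(guild))
    guild <- setNames(rep("plant", ncol(m)), colnames(m))
  communityMatrix(m, guild = guild, valueKind = valueKind)
}

#' Write a CommunityMatrix to CSV
#'
#' Columns are written in the canonical (sorted) species order so output is
#' deterministic; round-trips through [readSiteSpecies()].
#'
#' @param m a [CommunityMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSiteSpecies <- function(m, path) {
  stopifnot(is(m, "CommunityMatrix"))
  df <- data.frame(site = rownames(m@values), m@values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a species trait table from CSV
#'
#' First column = species labels; remaining columns = traits. Empty cells are
#' missing values.
#'
#' @param path CSV file path.
#' @param kind named character vector giving `"continuous"` or `"binary"` per
#'   trait; traits not named are taken as continuous.
#' @return A [TraitTable-class].
#' @export
readTraitTable <- function(path, kind = character()) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sp <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- sp
  full <- setNames(rep("continuous", ncol(m)), colnames(m))
  full[names(kind)] <- kind
  traitTable(m, kind = full)
}

#' Read a precomputed species distance matrix from CSV
#'
#' Square matrix with species labels in the first column and as headers.
#'
#' @param path CSV file path.
#' @param kind `"functional"` or `"phylogenetic"`.
#' @return A [SpeciesDist-class].
#' @export
readDistanceMatrix <- function(path, kind) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  speciesDist(m, kind = kind)
}

#' Read the three site-level predictor tables
#'
#' @param agriculturalPath,soilPath,spatialPath CSV paths; first column = site
#'   labels.
#' @return An [EnvTables-class].
#' @export
readEnvTables <- function(agriculturalPath, soilPath, spatialPath) {
  rd <- function(p) {
    df <- read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
    rownames(df) <- as.character(df[[1]])
    df[, -1, drop = FALSE]
  }
  envTables(rd(agriculturalPath), rd(soilPath), rd(spatialPath))
}

#' Convert Braun-Blanquet cover codes to midpoint percent cover
#'
#' Codes 0-7 (0 = absent; 1-7 = the seven degrees r, +, 1, 2, 3, 4, 5) are
#' mapped to the conventional interval midpoints 0, 0.1, 0.5, 2.5, 15, 37.5,
#' 62.5 and 87.5 percent. The mapping is overridable.
#'
#' @param m a [CommunityMatrix-class] with `valueKind = "braun_blanquet"`.
#' @param midpoints named numeric vector mapping codes `"0"`-`"7"` to percent
#'   cover.
#' @return A [CommunityMatrix-class] with `valueKind = "abundance"`.
#' @export
braunBlanquetToCover <- function(m, midpoints = .BB_MIDPOINTS) {
  stopifnot(is(m, "CommunityMatrix"))
  if (m@valueKind != "braun_blanquet")
    stop("valueKind must be 'braun_blanquet'")
  v <- m@values
  if (!all(v %in% as.numeric(names(midpoints))))
    stop("cover class outside 0-7")
  out <- matrix(midpoints[as.character(v)], nrow(v), ncol(v),
                dimnames = dimnames(v))
  communityMatrix(out, guild = m@guild, valueKind = "abundance")
}

#' Reduce any community matrix to presence-absence
#'
#' Any positive value becomes 1. Idempotent; all-zero species columns are
#' retained (and flagged with a message) so downstream code can report them.
#'
#' @param m a [CommunityMatrix-class].
#' @return A [CommunityMatrix-class] with `valueKind = "presence"`.
#' @export
toPresence <- function(m) {
  stopifnot(is(m, "CommunityMatrix"))
  v <- (m@values > 0) + 0
  empty <- colnames(v)[colSums(v) == 0]
  if (length(empty))
    message("species with no occurrences retained: ",
            paste(empty, collapse = ", "))
  communityMatrix(v, guild = m@guild, valueKind = "presence")
}

#' Parse / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] and [ape::write.tree()] that
#' enforce the contracts the rest of the package relies on: unique tip
#' labels, branch lengths present (or imputed as 1 when
#' `missingLengths = "one"`).
#'
#' @param text Newick string (or `file`).
#' @param file optional path to read from instead of `text`.
#' @param missingLengths `"error"` (default) or `"one"` (impute 1.0).
#' @return An [ape::phylo] tree.
#' @export
parseNewick <- function(text = NULL, file = NULL,
                        missingLengths = c("error", "one")) {
  missingLengths <- match.arg(missingLengths)
  tree <- tryCatch(suppressWarnings(
    if (is.null(file)) ape::read.tree(text = text)
    else ape::read.tree(file = file)),
    error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick string")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) {
    if (missingLengths == "error") stop("tree has no branch lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' @rdname parseNewick
#' @param tree an [ape::phylo] tree.
#' @export
writeNewick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}
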