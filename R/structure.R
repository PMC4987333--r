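#' @include AllClasses.R cooccurrence.R
NULL

#' Newman modularity of a partition
#'
#' \deqn{Q = \sum_c (e_{cc} - a_c^2)} where e_cc is the fraction of edges with
#' both ends in module c and a_c the fraction of edge ends attached to c.
#' Invariant under relabelling of modules and vertices; Q = 0 for the
#' single-module partition of any graph.
#'
#' @param net a [CoocNetwork-class] (or a symmetric 0/1 adjacency matrix).
#' @param partition a [ModulePartition-class], or a named vector of module
#'   ids covering all network species.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
newmanQ <- function(net, partition) {
  adj <- if (is(net, "CoocNetwork")) net@adjacency else net
  mem <- if (is(partition, "ModulePartition")) partition@membership
         else partition
  sp <- rownames(adj)
  if (!all(sp %in% names(mem)))
    stop("partition must cover every network species")
  mem <- mem[sp]
  m2 <- sum(adj)
  if (m2 <= 0) stop("network has no edges")
  Q <- 0
  for (c in unique(mem)) {
    inC <- mem == c
    ecc <- sum(adj[inC, inC]) / m2
    ac <- sum(adj[inC, ]) / m2
    Q <- Q + ecc - ac^2
  }
  Q
}

# relabel a raw membership vector to contiguous ids 1..k, ordered by
# decreasing module size, ties broken by smallest member index
.canonicalModules <- function(raw, species) {
  sizes <- table(raw)
  firsts <- vapply(names(sizes), function(id) min(which(raw == id)),
                   numeric(1))
  ord <- order(-as.integer(sizes), firsts)
  map <- setNames(seq_along(ord), names(sizes)[ord])
  setNames(as.integer(map[as.character(raw)]), species)
}

#' Greedy module detection (agglomerative modularity maximisation)
#'
#' Starts from singleton communities and repeatedly merges the connected
#' community pair with the largest modularity gain, returning the partition at
#' peak Q. Ties are broken by the lexicographically smallest community pair
#' (community index = smallest member vertex), so the result is deterministic
#' and needs no seed. Modules are numbered by decreasing size (ties: smallest
#' member index).
#'
#' @param net a [CoocNetwork-class] with at least one edge.
#' @return A [ModulePartition-class]; its `Q` slot is recomputed exactly with
#'   [newmanQ()].
#' @export
greedyModules <- function(net) {
  stopifnot(is(net, "CoocNetwork"))
  adj <- net@adjacency
  if (sum(adj) <= 0) stop("network has no edges")
  res <- .cppGreedyModules(adj)
  mem <- .canonicalModules(res$membership, rownames(adj))
  new("ModulePartition", membership = mem, Q = newmanQ(adj, mem))
}

# NODF of a binary matrix (rows and columns both scored):
# a pair contributes 100 * |overlap| / fill(poorer) when fills strictly
# decrease, 0 otherwise (decreasing-fill rule); NODF is the mean paired value
# over all row pairs and column pairs.
.nodf <- function(A) {
  A <- (A > 0) + 0
  contrib <- function(M) {
    f <- rowSums(M)
    n <- nrow(M)
    if (n < 2) return(c(0, 0))
    O <- tcrossprod(M)
    gt <- outer(f, f, ">") & matrix(f > 0, n, n, byrow = TRUE)
    tot <- sum((O / pmax(matrix(f, n, n, byrow = TRUE), 1))[gt]) * 100
    c(tot, n * (n - 1) / 2)
  }
  r <- contrib(A)
  c2 <- contrib(t(A))
  (r[1] + c2[1]) / (r[2] + c2[2])
}

#' Nestedness of the co-occurrence network (NODF, rescaled to \[0, 1\])
#'
#' NODF over the binary adjacency: for every ordered pair of rows (and of
#' columns) with strictly decreasing fill, the paired overlap is the fraction
#' of the poorer row's neighbours shared with the richer row; equal-fill pairs
#' contribute zero. The 0-100 score is rescaled to \[0, 1\], 1 = perfectly
#' nested, 0 = no nested structure (e.g. a checkerboard). Invariant to
#' simultaneous row/column permutations (degree ordering is internal to the
#' formula).
#'
#' @param net a [CoocNetwork-class], or any binary matrix (the site-by-species
#'   matrix form is accepted so matrix-level nulls can reuse it).
#' @return Nestedness in \[0, 1\].
#' @export
nestedness <- function(net) {
  A <- if (is(net, "CoocNetwork")) net@adjacency else net
  if (nrow(A) < 2) stop("need >= 2 vertices")
  .nodf(A) / 100
}
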