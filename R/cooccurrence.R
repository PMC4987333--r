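#' @include AllClasses.R
NULL

#' Exact distribution of the number of jointly occupied sites
#'
#' Under random, independent placement of two species occupying N1 and N2 of
#' N sites, the number J of jointly occupied sites follows the hypergeometric
#' law \deqn{P(J = j) = \binom{N_1}{j} \binom{N - N_1}{N_2 - j} /
#' \binom{N}{N_2}} over the feasible range
#' max(0, N1 + N2 - N) <= j <= min(N1, N2). Computed in log space so large N
#' stay exact to machine precision.
#'
#' @param N number of sites.
#' @param N1,N2 occupancy counts of the two species.
#' @return Named numeric vector of probabilities over the feasible j values;
#'   sums to 1.
#' @examples
#' pairPmf(5, 2, 3)   # P(J = 2) = 0.3
#' @export
pairPmf <- function(N, N1, N2) {
  if (N < 0 || N1 < 0 || N2 < 0 || N1 > N || N2 > N)
    stop("infeasible counts: need 0 <= N1, N2 <= N")
  jmin <- max(0, N1 + N2 - N)
  jmax <- min(N1, N2)
  j <- jmin:jmax
  lp <- lchoose(N1, j) + lchoose(N - N1, N2 - j) - lchoose(N, N2)
  p <- exp(lp)
  setNames(p / sum(p), j)
}

# lower/upper tail probabilities including the atom at jObs
.pairTails <- function(N, N1, N2, jObs) {
  pmf <- pairPmf(N, N1, N2)
  j <- as.integer(names(pmf))
  list(pLT = sum(pmf[j <= jObs]), pGT = sum(pmf[j >= jObs]))
}

#' Classify all species pairs by their co-occurrence pattern
#'
#' Scores every unordered species pair (within and between guilds) with the
#' exact hypergeometric model of [pairPmf()]: `pLT = P(J <= j_obs)` and
#' `pGT = P(J >= j_obs)` (both include the atom at the observed value).
#' A pair is `positive` when `pGT < alpha`, `negative` when `pLT < alpha`,
#' otherwise `random`. Pairs whose expected co-occurrence `N1*N2/N` falls
#' below `minExpected`, or involving a species with zero occupancy, are marked
#' `untestable` and never become network edges.
#'
#' @param m a [CommunityMatrix-class] with `valueKind = "presence"`.
#' @param alpha one-sided significance level (default 0.05).
#' @param minExpected testability threshold on expected co-occurrence
#'   (default 1; set 0 to disable).
#' @return data.frame with one row per unordered pair: speciesA, speciesB,
#'   N, N1, N2, jObs, expected, pLT, pGT, classification.
#' @export
classifyPairs <- function(m, alpha = 0.05, minExpected = 1) {
  stopifnot(is(m, "CommunityMatrix"))
  if (m@valueKind != "presence") stop("valueKind must be 'presence'")
  x <- m@values
  if (nrow(x) < 2) stop("need >= 2 sites")
  if (ncol(x) < 2) stop("need >= 2 species")
  N <- nrow(x)
  occ <- colSums(x)
  J <- crossprod(x)
  idx <- which(upper.tri(J), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  n1 <- occ[a]; n2 <- occ[b]
  jObs <- J[idx]
  expected <- n1 * n2 / N

  # tails computed once per unique (min(N1,N2), max(N1,N2)) pair
  lo <- pmin(n1, n2); hi <- pmax(n1, n2)
  key <- paste(lo, hi)
  pLT <- numeric(length(a)); pGT <- numeric(length(a))
  for (k in unique(key)) {
    sel <- key == k
    nn <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    pmf <- pairPmf(N, nn[1], nn[2])
    cum <- cumsum(pmf)
    revcum <- rev(cumsum(rev(pmf)))
    jmin <- as.integer(names(pmf)[1])
    pos <- jObs[sel] - jmin + 1L
    pLT[sel] <- cum[pos]
    pGT[sel] <- revcum[pos]
  }

  cls <- rep("random", length(a))
  cls[pGT < alpha] <- "positive"
  cls[pLT < alpha] <- "negative"
  cls[expected < minExpected | n1 == 0 | n2 == 0] <- "untestable"
  sp <- colnames(x)
  data.frame(speciesA = sp[a], speciesB = sp[b], N = N,
             N1 = as.integer(n1), N2 = as.integer(n2),
             jObs = as.integer(jObs), expected = expected,
             pLT = pLT, pGT = pGT, classification = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the positive co-occurrence network
#'
#' Keeps exactly the pairs classified `positive`; species left without any
#' positive partner are filtered out (a retention report is attached as the
#' `"retained"` attribute, split by guild).
#'
#' @param pairs data.frame from [classifyPairs()].
#' @param guild named character vector species -> guild covering at least the
#'   retained species; defaults to all `"plant"`.
#' @return A [CoocNetwork-class]; errors if no pair is positive.
#' @export
buildNetwork <- function(pairs, guild = NULL) {
  pos <- pairs[pairs$classification == "positive", , drop = FALSE]
  allSp <- sort(unique(c(pairs$speciesA, pairs$speciesB)))
  if (!nrow(pos))
    stop("no positive co-occurrences: the network is empty (",
         nrow(pairs), " pairs scored, ",
         sum(pairs$classification == "random"), " random, ",
         sum(pairs$classification == "negative"), " negative, ",
         sum(pairs$classification == "untestable"), " untestable)")
  sp <- sort(unique(c(pos$speciesA, pos$speciesB)))
  if (is.null(guild)) guild <- setNames(rep("plant", length(sp)), sp)
  adj <- matrix(0L, length(sp), length(sp), dimnames = list(sp, sp))
  ia <- match(pos$speciesA, sp); ib <- match(pos$speciesB, sp)
  adj[cbind(ia, ib)] <- 1L
  adj[cbind(ib, ia)] <- 1L
  net <- new("CoocNetwork", adjacency = adj, guild = guild)
  retained <- data.frame(
    guild = .GUILDS,
    total = vapply(.GUILDS, function(g)
      sum(guild[allSp] == g, na.rm = TRUE), numeric(1)),
    retained = vapply(.GUILDS, function(g)
      sum(guild[sp] == g, na.rm = TRUE), numeric(1)))
  attr(net, "retained") <- retained
  net
}

#' Export a network as an edge list and/or GraphML
#'
#' @param net a [CoocNetwork-class].
#' @param edgeListPath optional CSV path for the two-column edge list.
#' @param graphmlPath optional GraphML path (written via igraph).
#' @return The edge list data.frame, invisibly.
#' @export
writeNetwork <- function(net, edgeListPath = NULL, graphmlPath = NULL) {
  stopifnot(is(net, "CoocNetwork"))
  adj <- net@adjacency
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  el <- data.frame(speciesA = rownames(adj)[idx[, 1]],
                   speciesB = rownames(adj)[idx[, 2]],
                   stringsAsFactors = FALSE)
  el <- el[order(el$speciesA, el$speciesB), , drop = FALSE]
  if (!is.null(edgeListPath)) write.csv(el, edgeListPath, row.names = FALSE)
  if (!is.null(graphmlPath)) {
    g <- .asIgraph(net)
    igraph::write_graph(g, graphmlPath, format = "graphml")
  }
  invisible(el)
}

.asIgraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected")
  igraph::set_vertex_attr(g, "guild",
                          value = unname(net@guild[rownames(net@adjacency)]))
}

# network with given vertices removed; remaining vertices kept even if their
# degree drops to zero (knock-out convention)
.dropVertices <- function(net, drop) {
  keep <- setdiff(rownames(net@adjacency), drop)
  new("CoocNetwork", adjacency = net@adjacency[keep, keep, drop = FALSE],
      guild = net@guild)
}
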