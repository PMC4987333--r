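#' @include structure.R
NULL

# default chain lengths, in attempted moves, scaled by edge count
.burnIn <- function(nEdges) max(10 * nEdges, 100)
.thin <- function(nEdges) max(5 * nEdges, 50)

.permMethods <- c("swap", "tswap", "quasiswap")

#' Degree-preserving randomization of a network
#'
#' Randomizes the symmetric adjacency while keeping every species' degree
#' (row and column sums) fixed, using 2x2 checkerboard moves mirrored across
#' the diagonal:
#' * `swap` - sequential chain counting only applied moves;
#' * `tswap` - trial-swap chain counting every attempted move;
#' * `quasiswap` - independent draw: a stub-matching start with the exact
#'   degree sequence, repaired to a simple graph and mixed with trial moves,
#'   so the draw depends on the input only through its degrees.
#'
#' No self-loops or multi-edges are ever introduced. A graph with no
#' swappable checkerboard is returned unchanged with a warning.
#'
#' @param net a [CoocNetwork-class].
#' @param method `"swap"`, `"tswap"` or `"quasiswap"`.
#' @param seed optional integer seed.
#' @param burnIn chain length (attempted moves for `tswap`/`quasiswap`
#'   mixing, applied moves for `swap`); default 10 x edge count.
#' @return A randomized [CoocNetwork-class] with identical degree sequence.
#' @export
permuteAdjacency <- function(net, method = c("quasiswap", "swap", "tswap"),
                             seed = NULL, burnIn = NULL) {
  stopifnot(is(net, "CoocNetwork"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  adj <- net@adjacency
  nE <- sum(adj) / 2
  if (is.null(burnIn)) burnIn <- .burnIn(nE)
  if (method == "quasiswap") {
    res <- .cppQuasiswap(adj, burnIn)
    if (res$fallback)
      warning("quasiswap construction failed; mixed copy of the original used")
    out <- res$adjacency
  } else {
    res <- .cppSwapChain(adj, burnIn, count_trials = (method == "tswap"))
    if (method == "swap" && res$swaps < burnIn)
      warning("no swappable checkerboard found; chain stopped after ",
              res$swaps, " of ", burnIn, " moves")
    out <- res$adjacency
  }
  dimnames(out) <- dimnames(adj)
  new("CoocNetwork", adjacency = out, guild = net@guild)
}

.statFuns <- list(
  modularity = function(adj) .cppGreedyModules(adj)$Q,
  nestedness = function(adj) .nodf(adj) / 100)

#' Permutation null for network modularity / nestedness
#'
#' Compares the observed statistic with its distribution over `nPerm`
#' degree-preserving randomizations of the network (`null = "adjacency"`,
#' the default) or over fixed-marginal randomizations of the site-by-species
#' matrix with the network rebuilt each draw (`null = "matrix"`, a sensitivity
#' mode; requires `m`). `swap`/`tswap` sample one mixed chain (burn-in then
#' thinned samples); `quasiswap` draws are independent. Reports
#' SES = (obs - mean(null)) / sd(null) and the lower-tail
#' p = (1 + #\{null < obs\}) / (1 + nPerm).
#'
#' @param net a [CoocNetwork-class].
#' @param statistic `"modularity"`, `"nestedness"`, or both (they are then
#'   evaluated on the same draws).
#' @param nPerm number of permutations (default 9999).
#' @param method permutation algorithm, see [permuteAdjacency()].
#' @param seed optional integer seed.
#' @param null `"adjacency"` or `"matrix"`.
#' @param m [CommunityMatrix-class] (presence), required for
#'   `null = "matrix"`.
#' @param alpha,minExpected passed to [classifyPairs()] in matrix mode.
#' @return For a single statistic, a list of class `"coocnetNull"`:
#'   statistic, observed, nPerm, nullMean, nullSD, SES (NA when sd = 0),
#'   p, method, null, seed, nullValues. For two statistics, a named list of
#'   such results.
#' @export
structureSES <- function(net, statistic = c("modularity", "nestedness"),
                         nPerm = 9999,
                         method = c("quasiswap", "swap", "tswap"),
                         seed = NULL, null = c("adjacency", "matrix"),
                         m = NULL, alpha = 0.05, minExpected = 1) {
  stopifnot(is(net, "CoocNetwork"))
  statistic <- match.arg(statistic, several.ok = TRUE)
  method <- match.arg(method)
  null <- match.arg(null)
  if (!is.null(seed)) set.seed(seed)
  adj <- net@adjacency
  nE <- sum(adj) / 2
  obs <- vapply(statistic, function(s) .statFuns[[s]](adj), numeric(1))

  nullVals <- matrix(NA_real_, nPerm, length(statistic),
                     dimnames = list(NULL, statistic))
  if (null == "adjacency" && identical(statistic, "modularity")) {
    # single-call C++ path: randomize and score in one loop
    nullVals[, 1] <- .cppModularityNull(
      adj, nPerm, match(method, .permMethods) - 1L,
      .burnIn(nE), .thin(nE))
  } else if (null == "adjacency") {
    if (method == "quasiswap") {
      for (i in seq_len(nPerm)) {
        a <- .cppQuasiswap(adj, .thin(nE))$adjacency
        for (s in statistic) nullVals[i, s] <- .statFuns[[s]](a)
      }
    } else {
      trials <- (method == "tswap")
      cur <- .cppSwapChain(adj, .burnIn(nE), count_trials = trials)$adjacency
      for (i in seq_len(nPerm)) {
        cur <- .cppSwapChain(cur, .thin(nE), count_trials = trials)$adjacency
        for (s in statistic) nullVals[i, s] <- .statFuns[[s]](cur)
      }
    }
  } else {
    if (is.null(m)) stop("null = 'matrix' requires the presence matrix 'm'")
    nm <- vegan::nullmodel(m@values, method)
    sims <- stats::simulate(nm, nsim = nPerm)
    for (i in seq_len(nPerm)) {
      x <- sims[, , i]
      dimnames(x) <- dimnames(m@values)
      cm <- communityMatrix(x, guild = m@guild, valueKind = "presence")
      pr <- classifyPairs(cm, alpha = alpha, minExpected = minExpected)
      a <- tryCatch(buildNetwork(pr, guild = m@guild)@adjacency,
                    error = function(e) NULL)
      for (s in statistic)
        nullVals[i, s] <- if (is.null(a)) NA_real_ else .statFuns[[s]](a)
    }
  }

  mk <- function(s) {
    nv <- nullVals[, s]
    nv <- nv[!is.na(nv)]
    mu <- mean(nv); sdv <- sd(nv)
    structure(list(
      statistic = s, observed = unname(obs[s]), nPerm = length(nv),
      nullMean = mu, nullSD = sdv,
      SES = if (sdv > 0) (obs[[s]] - mu) / sdv else NA_real_,
      p = (1 + sum(nv < obs[[s]])) / (1 + length(nv)),
      method = method, null = null, seed = seed, nullValues = nv),
      class = "coocnetNull")
  }
  if (length(statistic) == 1L) mk(statistic) else
    setNames(lapply(statistic, mk), statistic)
}

#' @export
print.coocnetNull <- function(x, ...) {
  cat(sprintf("Null-model test (%s, %s null, %s): obs = %.4f, null = %.4f +/- %.4f\n",
              x$statistic, x$null, x$method, x$observed, x$nullMean, x$nullSD))
  cat(sprintf("  SES = %s, lower-tail p = %.4g (n_perm = %d)\n",
              ifelse(is.na(x$SES), "undefined (null sd = 0)",
                     sprintf("%.3f", x$SES)), x$p, x$nPerm))
  invisible(x)
}

#' Knock-out importance of every species for network structure
#'
#' Removes each species in turn, recomputes modularity (fresh greedy module
#' detection) and nestedness on the reduced network, and forms
#' Delta_i = initial - leave-one-out value. SES_i = (Delta_i - mean(Delta)) /
#' sd(Delta) (sample sd by default). Positive SES marks species whose removal
#' degrades the structure (the statistic drops when they are knocked out);
#' species whose removal makes the network more modular get negative SES.
#' If all Delta are equal (sd = 0) the SES column is undefined (NA).
#'
#' @param net a [CoocNetwork-class] with >= 3 species.
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"`.
#' @return data.frame: species, module (from [greedyModules()] on the full
#'   network), degree, deltaQ, deltaNestedness, sesQ, sesNestedness, plus a
#'   logical `edgeless` flag for removals that empty the network (their
#'   deltas are NA and excluded from the standardization).
#' @export
knockoutImportance <- function(net, sdType = c("sample", "population")) {
  stopifnot(is(net, "CoocNetwork"))
  sdType <- match.arg(sdType)
  sp <- rownames(net@adjacency)
  if (length(sp) < 3) stop("need >= 3 species")
  part <- greedyModules(net)
  q0 <- part@Q
  n0 <- nestedness(net)
  dQ <- dN <- rep(NA_real_, length(sp))
  edgeless <- logical(length(sp))
  for (i in seq_along(sp)) {
    sub <- .dropVertices(net, sp[i])
    if (sum(sub@adjacency) == 0) { edgeless[i] <- TRUE; next }
    dQ[i] <- q0 - .cppGreedyModules(sub@adjacency)$Q
    dN[i] <- n0 - nestedness(sub)
  }
  ses <- function(d) {
    ok <- !is.na(d)
    s <- if (sdType == "sample") sd(d[ok])
         else sqrt(mean((d[ok] - mean(d[ok]))^2))
    if (is.na(s) || s == 0) return(rep(NA_real_, length(d)))
    (d - mean(d[ok])) / s
  }
  data.frame(species = sp,
             module = as.integer(part@membership[sp]),
             degree = as.integer(rowSums(net@adjacency)),
             deltaQ = dQ, deltaNestedness = dN,
             sesQ = ses(dQ), sesNestedness = ses(dN),
             edgeless = edgeless,
             stringsAsFactors = FALSE, row.names = NULL)
}
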