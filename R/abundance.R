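#' @include AllClasses.R
NULL

#' Hellinger transformation of an abundance matrix
#'
#' y'_ij = sqrt(y_ij / y_i.) (square root of relative abundance per site), so
#' every transformed site row has unit sum of squares. Sites with zero total
#' abundance are dropped with a warning. Delegates to
#' [vegan::decostand()] `method = "hellinger"`.
#'
#' @param m a [CommunityMatrix-class] with `valueKind = "abundance"`.
#' @return A [CommunityMatrix-class] (`valueKind = "abundance"`) of
#'   transformed values.
#' @export
hellingerTransform <- function(m) {
  stopifnot(is(m, "CommunityMatrix"))
  if (m@valueKind != "abundance") stop("valueKind must be 'abundance'")
  v <- m@values
  tot <- rowSums(v)
  if (any(tot == 0)) {
    warning("sites with zero total abundance dropped: ",
            paste(rownames(v)[tot == 0], collapse = ", "))
    v <- v[tot > 0, , drop = FALSE]
  }
  h <- as.matrix(vegan::decostand(v, method = "hellinger"))
  communityMatrix(h, guild = m@guild, valueKind = "abundance")
}

# principal-coordinates embedding of a distance matrix keeping positive and
# negative eigenvalue blocks separately (Anderson's correction for
# non-Euclidean distances): squared distances in the embedding are
# |x - y|^2_pos - |x - y|^2_neg
.pcoaEmbed <- function(D) {
  n <- nrow(D)
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  G <- G + mean(-0.5 * D^2)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  neg <- eg$values < -tol
  Epos <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos))
  Eneg <- eg$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eg$values[neg]), sum(neg))
  rownames(Epos) <- rownames(Eneg) <- rownames(D)
  list(pos = Epos, neg = Eneg)
}

# FDis per site from a precomputed embedding; rows of W (sites x species)
# aligned with embedding rows via `ord` (species index per column of W)
.fdisFromEmbedding <- function(W, emb, ord = seq_len(ncol(W))) {
  Epos <- emb$pos[ord, , drop = FALSE]
  Eneg <- emb$neg[ord, , drop = FALSE]
  out <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]
    pres <- which(w > 0)
    if (length(pres) < 2) { out[i] <- 0; next }
    w <- w[pres] / sum(w[pres])
    cp <- drop(w %*% Epos[pres, , drop = FALSE])
    cn <- drop(w %*% Eneg[pres, , drop = FALSE])
    z2 <- rowSums(sweep(Epos[pres, , drop = FALSE], 2, cp)^2)
    if (ncol(Eneg) > 0)
      z2 <- z2 - rowSums(sweep(Eneg[pres, , drop = FALSE], 2, cn)^2)
    out[i] <- sum(w * sqrt(pmax(z2, 0)))
  }
  out
}

#' Functional / phylogenetic dispersion (FDis, PDis) per site
#'
#' Species are embedded by principal coordinates of the distance matrix
#' (keeping negative-eigenvalue axes as a correction term); each site's
#' dispersion is the abundance-weighted mean distance of its species to the
#' site's abundance-weighted centroid. Computed on a functional distance
#' matrix this is FDis; on a cophenetic (phylogenetic) matrix, PDis. Sites
#' with fewer than two species present score 0; the index is invariant to
#' uniform rescaling of a site's abundances.
#'
#' @param m a [CommunityMatrix-class] with `valueKind = "abundance"`.
#' @param d a [SpeciesDist-class] covering the species of `m`.
#' @return Named numeric vector of per-site dispersion values (>= 0).
#' @export
dispersionIndex <- function(m, d) {
  stopifnot(is(m, "CommunityMatrix"), is(d, "SpeciesDist"))
  sp <- colnames(m@values)
  missing <- setdiff(sp, rownames(d@d))
  if (length(missing))
    stop("species missing from the distance matrix: ",
         paste(missing, collapse = ", "))
  emb <- .pcoaEmbed(d@d[sp, sp, drop = FALSE])
  setNames(.fdisFromEmbedding(m@values, emb), rownames(m@values))
}

#' Abundance-based dispersion null model
#'
#' Null: species identities are permuted, i.e. whole abundance columns are
#' reassigned to species labels (equivalently, rows of the trait/phylogeny
#' embedding are shuffled). This preserves every site's local abundance and
#' diversity while attributing random abundances to species. The statistic is
#' the unweighted mean over sites of the per-site dispersion; SES and
#' lower-tail p = (1 + #\{null < obs\}) / (1 + nPerm) as elsewhere.
#'
#' @inheritParams dispersionIndex
#' @param nPerm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @return List of class `"coocnetNull"` with fields statistic ("FDis" or
#'   "PDis" by distance kind), observed (mean over sites), perSite, nPerm,
#'   nullMean, nullSD, SES, p, seed.
#' @export
dispersionSES <- function(m, d, nPerm = 9999, seed = NULL) {
  stopifnot(is(m, "CommunityMatrix"), is(d, "SpeciesDist"))
  if (!is.null(seed)) set.seed(seed)
  sp <- colnames(m@values)
  if (length(sp) < 3) stop("need >= 3 species")
  missing <- setdiff(sp, rownames(d@d))
  if (length(missing))
    stop("species missing from the distance matrix: ",
         paste(missing, collapse = ", "))
  emb <- .pcoaEmbed(d@d[sp, sp, drop = FALSE])
  perSite <- .fdisFromEmbedding(m@values, emb)
  obs <- mean(perSite)
  nullVals <- vapply(seq_len(nPerm), function(i)
    mean(.fdisFromEmbedding(m@values, emb, ord = sample.int(length(sp)))),
    numeric(1))
  mu <- mean(nullVals); sdv <- sd(nullVals)
  structure(list(
    statistic = if (d@kind == "phylogenetic") "PDis" else "FDis",
    observed = obs, perSite = setNames(perSite, rownames(m@values)),
    nPerm = nPerm, nullMean = mu, nullSD = sdv,
    SES = if (sdv > 0) (obs - mu) / sdv else NA_real_,
    p = (1 + sum(nullVals < obs)) / (1 + nPerm),
    method = "species-identity permutation", null = "abundance",
    seed = seed, nullValues = nullVals), class = "coocnetNull")
}

# centered predictor matrix from a data.frame/matrix, dropping collinear
# columns (with a warning); returns the matrix and its rank
.predictorMatrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  Xc <- sweep(X, 2, colMeans(X))
  q <- qr(Xc)
  if (q$rank < ncol(Xc)) {
    keep <- q$pivot[seq_len(q$rank)]
    warning("collinear predictor columns dropped: ",
            paste(colnames(Xc)[-keep], collapse = ", "))
    Xc <- Xc[, keep, drop = FALSE]
  }
  Xc
}

# unadjusted multivariate redundancy R^2 of centered Y on centered X
.rdaR2 <- function(Yc, Xc) {
  fit <- qr.fitted(qr(Xc), Yc)
  sum(fit^2) / sum(Yc^2)
}

# Ezekiel adjustment with m = rank of the (centered) predictor matrix, so
# redundant columns never inflate the penalty
.adjR2 <- function(Yc, Xc) {
  q <- qr(Xc)
  n <- nrow(Yc)
  m <- q$rank
  if (n <= m + 1) stop("need more sites than predictors + 1")
  r2 <- sum(qr.fitted(q, Yc)^2) / sum(Yc^2)
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Adjusted redundancy R-squared (RDA)
#'
#' R^2 is the share of the total variance of (column-centered) Y captured by
#' its multivariate linear projection on the predictors X; adjusted with
#' Ezekiel's formula 1 - (1 - R^2)(n - 1)/(n - m - 1), m = number of
#' (independent) predictors. Canonical axes are never needed for the reported
#' quantities and are not computed.
#'
#' @param Y numeric response matrix (sites x species), e.g. Hellinger scores.
#' @param X predictor data.frame/matrix over the same sites.
#' @return Adjusted R-squared (can be negative).
#' @export
rdaAdjustedR2 <- function(Y, X) {
  Y <- as.matrix(Y)
  Xc <- .predictorMatrix(X)
  Yc <- sweep(Y, 2, colMeans(Y))
  .adjR2(Yc, Xc)
}

#' Variance partitioning of community data over three predictor sets
#'
#' Decomposes the adjusted R-squared of Y over X1, X2, X3 into the seven
#' non-overlapping fractions (pure X1 `[a]`, pure X2 `[b]`, pure X3 `[c]`,
#' pairwise joints `[d]`-`[f]`, triple joint `[g]`) by inclusion-exclusion
#' over the seven possible RDA models, plus the residual. The fractions sum
#' exactly to the full-model adjusted R-squared; individual fractions may be
#' negative. The three pure fractions are tested by permutation of the
#' residuals of the reduced model (the other two sets), with upper-tail
#' p = (1 + #\{null >= obs\}) / (1 + nPerm) on the semipartial R-squared.
#'
#' @param Y numeric response matrix (sites x species).
#' @param X1,X2,X3 predictor data.frames/matrices over the same sites.
#' @param nPerm permutations for the pure-fraction tests (default 999).
#' @param seed optional integer seed.
#' @return List of class `"coocnetVarpart"`: fractions (named numeric,
#'   a-g + residual), adjR2 (named, the 7 models), pureTests data.frame
#'   (fraction, semipartialR2, p), n, nPerm.
#' @export
variancePartition <- function(Y, X1, X2, X3, nPerm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Xs <- list(X1 = .predictorMatrix(X1), X2 = .predictorMatrix(X2),
             X3 = .predictorMatrix(X3))
  if (!all(vapply(Xs, nrow, integer(1)) == n))
    stop("predictor sets must cover the same sites as Y")
  mAll <- sum(vapply(Xs, ncol, integer(1)))
  if (n <= mAll + 1) stop("too few sites for the full model")
  Yc <- sweep(Y, 2, colMeans(Y))

  adj <- function(Xc) .adjR2(Yc, Xc)
  A1 <- adj(Xs$X1); A2 <- adj(Xs$X2); A3 <- adj(Xs$X3)
  A12 <- adj(cbind(Xs$X1, Xs$X2))
  A13 <- adj(cbind(Xs$X1, Xs$X3))
  A23 <- adj(cbind(Xs$X2, Xs$X3))
  A123 <- adj(cbind(Xs$X1, Xs$X2, Xs$X3))

  a <- A123 - A23
  b <- A123 - A13
  c <- A123 - A12
  d <- A13 + A23 - A123 - A3   # shared X1 & X2 only
  e <- A12 + A13 - A123 - A1   # shared X2 & X3 only
  f <- A12 + A23 - A123 - A2   # shared X1 & X3 only
  g <- A123 - a - b - c - d - e - f
  fractions <- c(a = a, b = b, c = c, d = d, e = e, f = f, g = g,
                 residual = 1 - A123)

  # residual-permutation (Freedman-Lane) test of each pure fraction, on the
  # pseudo-F scale (the raw R-squared difference is not pivotal under this
  # scheme; F is)
  testPure <- function(full, reduced) {
    qrFull <- qr(full)
    qrRed <- qr(reduced)
    mf <- qrFull$rank
    m1 <- mf - qrRed$rank
    fitRed <- qr.fitted(qrRed, Yc)
    res <- Yc - fitRed
    pseudoF <- function(Zc) {
      r2f <- sum(qr.fitted(qrFull, Zc)^2) / sum(Zc^2)
      r2r <- sum(qr.fitted(qrRed, Zc)^2) / sum(Zc^2)
      c(r2f - r2r, ((r2f - r2r) / m1) / ((1 - r2f) / (n - 1 - mf)))
    }
    o <- pseudoF(Yc)
    nullv <- vapply(seq_len(nPerm), function(i) {
      Yp <- fitRed + res[sample.int(n), , drop = FALSE]
      pseudoF(sweep(Yp, 2, colMeans(Yp)))[2]
    }, numeric(1))
    c(o[1], (1 + sum(nullv >= o[2])) / (1 + nPerm))
  }
  full <- cbind(Xs$X1, Xs$X2, Xs$X3)
  t1 <- testPure(full, cbind(Xs$X2, Xs$X3))
  t2 <- testPure(full, cbind(Xs$X1, Xs$X3))
  t3 <- testPure(full, cbind(Xs$X1, Xs$X2))
  structure(list(
    fractions = fractions,
    adjR2 = c(X1 = A1, X2 = A2, X3 = A3, X12 = A12, X13 = A13, X23 = A23,
              X123 = A123),
    pureTests = data.frame(
      fraction = c("a (pure X1)", "b (pure X2)", "c (pure X3)"),
      semipartialR2 = c(t1[1], t2[1], t3[1]),
      p = c(t1[2], t2[2], t3[2]), stringsAsFactors = FALSE),
    n = n, nPerm = nPerm), class = "coocnetVarpart")
}

#' @export
print.coocnetVarpart <- function(x, ...) {
  cat(sprintf("Variance partitioning over 3 predictor sets (n = %d)\n", x$n))
  cat("  fractions (adjusted R^2):\n")
  for (nm in names(x$fractions))
    cat(sprintf("    [%s] %8.4f\n", nm, x$fractions[nm]))
  cat("  pure-fraction permutation tests:\n")
  print(x$pureTests, row.names = FALSE)
  invisible(x)
}

#' Split an abundance matrix by network module
#'
#' One abundance matrix per module (sites unchanged); species absent from the
#' network are excluded from all subsets.
#'
#' @param m a [CommunityMatrix-class].
#' @param partition a [ModulePartition-class]; all its species must be in `m`.
#' @return Named list of [CommunityMatrix-class] objects (`module1`, ...).
#' @export
subsetByModule <- function(m, partition) {
  stopifnot(is(m, "CommunityMatrix"), is(partition, "ModulePartition"))
  mem <- partition@membership
  missing <- setdiff(names(mem), colnames(m@values))
  if (length(missing))
    stop("module species missing from the matrix: ",
         paste(missing, collapse = ", "))
  mods <- sort(unique(mem))
  out <- lapply(mods, function(k) {
    sp <- names(mem)[mem == k]
    communityMatrix(m@values[, sp, drop = FALSE], guild = m@guild,
                    valueKind = m@valueKind)
  })
  setNames(out, paste0("module", mods))
}
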