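test_that("Hellinger transform normalises rows to unit sum of squares", {
  x <- rbind(c(1, 1, 2), c(0, 5, 0), c(2, 2, 0))
  m <- makeCM(x, valueKind = "abundance")
  h <- hellingerTransform(m)
  H <- as.matrix(h)
  expect_equal(unname(H[1, ]), c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12)
  expect_equal(unname(H[2, ]), c(0, 1, 0))
  expect_equal(unname(rowSums(H^2)), rep(1, 3), tolerance = 1e-12)
  # zero-total sites dropped with a warning
  x0 <- rbind(x, c(0, 0, 0))
  expect_warning(h0 <- hellingerTransform(makeCM(x0, valueKind = "abundance")),
                 "zero total")
  expect_equal(nrow(as.matrix(h0)), 3)
  expect_error(hellingerTransform(makeCM((x > 0) + 0)), "abundance")
})

test_that("dispersion index reproduces hand cases and invariances", {
  sp <- c("a", "b")
  M <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(sp, sp))
  d <- speciesDist(M, "functional")
  # two species, distance 1, equal abundance: each is 0.5 from the centroid
  ab <- matrix(c(2, 2), 1, 2, dimnames = list("s1", sp))
  m <- communityMatrix(ab, guild = setNames(rep("plant", 2), sp),
                       valueKind = "abundance")
  expect_equal(unname(dispersionIndex(m, d)), 0.5)
  # doubling abundances changes nothing; single species scores 0
  ab2 <- rbind(s1 = c(4, 4), s2 = c(3, 0))
  colnames(ab2) <- sp
  m2 <- communityMatrix(ab2, guild = setNames(rep("plant", 2), sp),
                        valueKind = "abundance")
  v <- dispersionIndex(m2, d)
  expect_equal(unname(v["s1"]), 0.5)
  expect_equal(unname(v["s2"]), 0)
  # identical species in trait space: 0 everywhere
  sp4 <- sprintf("t%d", 1:4)
  Z <- matrix(0, 4, 4, dimnames = list(sp4, sp4))
  ab4 <- matrix(runif(12, 1, 5), 3, 4,
                dimnames = list(sprintf("s%d", 1:3), sp4))
  m4 <- communityMatrix(ab4, guild = setNames(rep("plant", 4), sp4),
                        valueKind = "abundance")
  expect_equal(unname(dispersionIndex(m4, speciesDist(Z, "functional"))),
               rep(0, 3))
  # species missing from the distance matrix is an error
  expect_error(dispersionIndex(m2, speciesDist(
    matrix(0, 1, 1, dimnames = list("a", "a")), "functional")), "missing")
})

test_that("dispersion index agrees with a direct 1-D computation", {
  # colinear trait: embedding is exactly the trait axis
  sp <- c("a", "b", "c")
  x <- c(0, 3, 10)
  M <- abs(outer(x, x, "-")); dimnames(M) <- list(sp, sp)
  ab <- matrix(c(1, 2, 3), 1, 3, dimnames = list("s1", sp))
  m <- communityMatrix(ab, guild = setNames(rep("plant", 3), sp),
                       valueKind = "abundance")
  w <- c(1, 2, 3) / 6
  cen <- sum(w * x)
  expect_equal(unname(dispersionIndex(m, speciesDist(M, "functional"))),
               sum(w * abs(x - cen)), tolerance = 1e-9)
})

test_that("dispersion null detects planted convergence and stays in range", {
  set.seed(91)
  nsp <- 20
  sp <- sprintf("sp%02d", seq_len(nsp))
  # dominant species clustered in trait space
  tr <- c(rnorm(5, 0, 0.05), rnorm(nsp - 5, 0, 1))
  M <- abs(outer(tr, tr, "-")); dimnames(M) <- list(sp, sp)
  ab <- matrix(rlnorm(10 * nsp, 0, 0.3), 10, nsp,
               dimnames = list(sprintf("s%02d", 1:10), sp))
  ab[, 1:5] <- ab[, 1:5] * 20   # the clustered species dominate
  m <- communityMatrix(ab, guild = setNames(rep("plant", nsp), sp),
                       valueKind = "abundance")
  res <- dispersionSES(m, speciesDist(M, "functional"), nPerm = 199,
                       seed = 92)
  expect_lt(res$SES, 0)
  expect_true(res$p > 0 && res$p <= 1)
  expect_identical(res$statistic, "FDis")
  # constant positive distances: every subset has the same geometry -> the
  # null is degenerate and SES is flagged undefined
  Mc <- matrix(1, 4, 4); diag(Mc) <- 0
  dimnames(Mc) <- list(sp[1:4], sp[1:4])
  ab2 <- ab[, 1:4]
  m2 <- communityMatrix(ab2, guild = setNames(rep("plant", 4), sp[1:4]),
                        valueKind = "abundance")
  resC <- dispersionSES(m2, speciesDist(Mc, "functional"), nPerm = 49,
                        seed = 93)
  expect_true(is.na(resC$SES))
  # PDis label follows the distance kind
  expect_identical(dispersionSES(m2, speciesDist(Mc, "phylogenetic"),
                                 nPerm = 9, seed = 1)$statistic, "PDis")
})

test_that("adjusted RDA R2 has its closed-form fixed points", {
  set.seed(94)
  n <- 30
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("x1", "x2", "x3")))
  # Y an exact linear map of X: R2 = 1, adjusted 1
  Y <- X %*% matrix(rnorm(9), 3)
  expect_equal(rdaAdjustedR2(Y, X), 1, tolerance = 1e-10)
  # Y orthogonal to X by construction: R2 = 0, adjusted < 0
  Xc <- sweep(X, 2, colMeans(X))
  Y2 <- matrix(rnorm(n * 4), n)
  Y2 <- Y2 - Xc %*% solve(crossprod(Xc), crossprod(Xc, Y2))
  expect_lt(rdaAdjustedR2(Y2, X), 0)
  expect_equal(rdaAdjustedR2(Y2, X),
               1 - (n - 1) / (n - 3 - 1), tolerance = 1e-9)
  # unbiased near zero for independent noise
  set.seed(95)
  sims <- vapply(1:200, function(i) {
    rdaAdjustedR2(matrix(rnorm(48 * 5), 48), matrix(rnorm(48 * 3), 48))
  }, numeric(1))
  expect_lt(abs(mean(sims)), 0.02)
  # agrees with vegan's RsquareAdj on an RDA fit
  Y3 <- matrix(rnorm(n * 6), n)
  ours <- rdaAdjustedR2(Y3, X)
  ref <- vegan::RsquareAdj(vegan::rda(Y3 ~ X))$adj.r.squared
  expect_equal(ours, ref, tolerance = 1e-10)
  # collinear columns dropped with a warning
  Xcol <- cbind(X, x4 = X[, 1] * 2)
  expect_warning(r <- rdaAdjustedR2(Y3, Xcol), "collinear")
  expect_equal(r, ours, tolerance = 1e-10)
})

test_that("variance partitioning sums exactly and matches vegan::varpart", {
  set.seed(96)
  n <- 40
  X1 <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("a", 1:3)))
  X2 <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("b", 1:3)))
  X3 <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("c", 1:3)))
  Y <- X3 %*% matrix(rnorm(3 * 8), 3) + matrix(rnorm(n * 8), n)
  vp <- variancePartition(Y, X1, X2, X3, nPerm = 99, seed = 97)
  # inclusion-exclusion identity, exact
  expect_lt(abs(sum(vp$fractions[1:7]) - vp$adjR2["X123"]), 1e-10)
  # against vegan's varpart fractions
  ref <- vegan::varpart(Y, X1, X2, X3)$part
  indiv <- ref$indfract$Adj.R.square
  expect_equal(unname(vp$fractions[1:7]), indiv[1:7], tolerance = 1e-8)
  # X3 generated Y: pure X3 dominates and is significant
  expect_gt(vp$fractions["c"], 0.2)
  expect_lt(vp$pureTests$p[3], 0.05)
  expect_gt(vp$pureTests$p[1], 0.05)

  # duplicated sets: pure fractions collapse onto the joint
  vp2 <- variancePartition(Y, X1, X1, X3, nPerm = 99, seed = 98)
  expect_lt(abs(vp2$fractions["a"]), 1e-10)
  expect_lt(abs(vp2$fractions["b"]), 1e-10)
})

test_that("per-module subsets partition the species set", {
  set.seed(99)
  x <- matrix(rlnorm(5 * 6), 5, 6)
  m <- makeCM(x, valueKind = "abundance")
  sp <- speciesNames(m)
  part <- new("ModulePartition",
              membership = setNames(c(1L, 1L, 2L, 2L, 2L, 1L), sp), Q = 0)
  subs <- subsetByModule(m, part)
  expect_named(subs, c("module1", "module2"))
  expect_setequal(unlist(lapply(subs, speciesNames)), sp)
  expect_equal(length(intersect(speciesNames(subs[[1]]),
                                speciesNames(subs[[2]]))), 0)
  expect_identical(siteNames(subs[[1]]), siteNames(m))
  # species missing from the matrix is an error naming the species
  part2 <- new("ModulePartition",
               membership = setNames(c(1L, 2L), c(sp[1], "ghost")), Q = 0)
  expect_error(subsetByModule(m, part2), "ghost")
})
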