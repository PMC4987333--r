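test_that("every randomization method preserves the degree sequence exactly", {
  set.seed(61)
  for (r in 1:5) {
    net <- randomNet(15, 0.3)
    if (edgeCount(net) < 2) next
    d0 <- degreeSequence(net)
    for (m in c("swap", "tswap", "quasiswap")) {
      for (k in 1:10) {
        p <- suppressWarnings(permuteAdjacency(net, method = m))
        a <- as.matrix(p)
        expect_identical(unname(rowSums(a)), unname(d0[rownames(a)]))
        expect_true(all(diag(a) == 0))
        expect_true(all(a %in% c(0, 1)))
        expect_identical(a, t(a))
      }
    }
  }
})

test_that("a 4-cycle only ever randomizes onto its degree-sequence class", {
  # degree sequence (2,2,2,2): the simple graphs are the three perfect
  # pairings of 4 vertices into two 2-paths... enumeration: exactly the
  # three 4-cycles (1-2-3-4, 1-3-2-4, 1-2-4-3)
  net <- edgeNet(list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 4)
  valid <- c("1-2;2-3;3-4;1-4", "1-3;2-3;2-4;1-4", "1-2;2-4;3-4;1-3")
  canon <- function(a) {
    idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    paste(idx[, 1], idx[, 2], sep = "-", collapse = ";")
  }
  validCanon <- vapply(valid, function(s) {
    a <- matrix(0L, 4, 4)
    for (e in strsplit(strsplit(s, ";")[[1]], "-"))
      { i <- as.integer(e[1]); j <- as.integer(e[2])
        a[i, j] <- 1L; a[j, i] <- 1L }
    canon(a)
  }, character(1))
  set.seed(62)
  seen <- character()
  for (m in c("swap", "tswap", "quasiswap"))
    for (k in 1:200)
      seen <- c(seen, canon(as.matrix(
        suppressWarnings(permuteAdjacency(net, method = m)))))
  expect_true(all(seen %in% validCanon))
  expect_setequal(unique(seen), unname(validCanon))
})

test_that("samplers are uniform over an enumerable fixed-degree graph set", {
  # all simple graphs with degree sequence (2,2,2,2,2) are the 12 labeled
  # 5-cycles; chi-square uniformity with 3000 draws per method
  adj <- matrix(0L, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; adj[i, j] <- 1L; adj[j, i] <- 1L }
  net <- makeNet(adj)
  canon <- function(a) {
    idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    paste(idx[, 1], idx[, 2], sep = "-", collapse = ";")
  }
  for (m in c("swap", "tswap", "quasiswap")) {
    set.seed(63)
    cur <- net
    ids <- character(3000)
    for (i in seq_len(3000)) {
      cur <- permuteAdjacency(if (m == "quasiswap") net else cur, method = m,
                              burnIn = if (m == "quasiswap") 50 else 25)
      ids[i] <- canon(as.matrix(cur))
    }
    tab <- table(ids)
    expect_equal(length(tab), 12, label = m)
    expect_gt(chisq.test(tab)$p.value, 0.01, label = m)
  }
})

test_that("structure SES separates planted structure from degree nulls", {
  # planted 5-module graph: strongly modular, SES must exceed 2
  set.seed(64)
  n <- 60; lab <- rep(1:5, each = 12)
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj), arr.ind = TRUE)
  adj[upper.tri(adj)] <- rbinom(nrow(up), 1,
    ifelse(lab[up[, 1]] == lab[up[, 2]], 0.6, 0.02))
  adj <- adj + t(adj)
  net <- makeNet(adj)
  res <- structureSES(net, "modularity", nPerm = 199, method = "quasiswap",
                      seed = 65)
  expect_gt(res$SES, 2)
  expect_equal(res$nPerm, 199)
  expect_true(res$p > 0 && res$p <= 1)

  # Erdos-Renyi graph: no structure beyond degrees, SES should be moderate
  set.seed(66)
  er <- randomNet(60, 0.2)
  resER <- structureSES(er, "modularity", nPerm = 199, method = "swap",
                        seed = 67)
  expect_lt(abs(resER$SES), 3.5)

  # both statistics on the same draws; p-values carry their n_perm
  both <- structureSES(net, c("modularity", "nestedness"), nPerm = 99,
                       method = "tswap", seed = 68)
  expect_named(both, c("modularity", "nestedness"))
  expect_equal(both$nestedness$nPerm, 99)

  # matrix-level null rebuilds the network each draw
  set.seed(69)
  x <- matrix(rbinom(20 * 12, 1, 0.45), 20, 12)
  cm <- makeCM(x)
  pr <- classifyPairs(cm, alpha = 0.3, minExpected = 0)
  netM <- buildNetwork(pr, guild = cm@guild)
  resM <- structureSES(netM, "modularity", nPerm = 49, method = "quasiswap",
                       null = "matrix", m = cm, alpha = 0.3, minExpected = 0,
                       seed = 70)
  expect_true(is.finite(resM$observed))
  expect_true(resM$nPerm <= 49)
})

test_that("SES p-values are calibrated under the null generator itself", {
  # generate degree-null graphs, test them against the same null: lower-tail
  # p should be approximately uniform
  set.seed(71)
  base <- randomNet(18, 0.3)
  ps <- vapply(1:120, function(r) {
    g <- permuteAdjacency(base, method = "quasiswap")
    structureSES(g, "nestedness", nPerm = 99, method = "quasiswap")$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("knock-out SES follows the stated formula and sign convention", {
  # arithmetic fixed point: deltas (1,2,3) standardize to (-1,0,1) with
  # sample sd, (-1.2247, 0, 1.2247) with population sd
  d <- c(1, 2, 3)
  expect_equal((d - mean(d)) / sd(d), c(-1, 0, 1))
  expect_equal((d - mean(d)) / sqrt(mean((d - mean(d))^2)),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  # two triangles joined through a bridge vertex: removing the bridge makes
  # the network more modular, so the bridge gets negative modularity SES
  bridge <- edgeNet(list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5),
                         c(5, 6), c(5, 7), c(6, 7)), 7)
  kt <- knockoutImportance(bridge)
  expect_equal(nrow(kt), 7)
  expect_lt(kt$sesQ[kt$species == "v04"], 0)
  # SES columns have mean 0 and sd 1 when defined
  expect_lt(abs(mean(kt$sesQ)), 1e-12)
  expect_equal(sd(kt$sesQ), 1, tolerance = 1e-12)
  expect_lt(abs(mean(kt$sesNestedness)), 1e-12)

  # population sd is smaller by sqrt((n-1)/n), so SES scales up by its inverse
  ktP <- knockoutImportance(bridge, sdType = "population")
  expect_equal(ktP$sesQ, kt$sesQ * sqrt(7 / 6), tolerance = 1e-9)

  # vertex-transitive graph: all deltas equal, sd = 0 -> SES undefined
  cyc <- edgeNet(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6)), 6)
  ktC <- knockoutImportance(cyc)
  expect_true(all(is.na(ktC$sesQ)))
  expect_true(all(is.na(ktC$sesNestedness)))
  # the deltas themselves are equal across vertices
  expect_lt(diff(range(ktC$deltaQ)), 1e-12)
})
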