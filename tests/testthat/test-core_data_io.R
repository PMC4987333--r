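test_that("site-species CSV round-trips and rejects invalid input", {
  x <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3,
              dimnames = list(c("s1", "s2"), c("b", "a", "c")))
  m <- makeCM(x)
  # canonical species order on construction
  expect_identical(speciesNames(m), c("a", "b", "c"))
  f <- tempfile(fileext = ".csv")
  writeSiteSpecies(m, f)
  m2 <- readSiteSpecies(f, valueKind = "presence")
  expect_identical(as.matrix(m2), as.matrix(m))
  expect_identical(valueKind(m2), "presence")

  # fractional value under presence kind violates the invariant
  writeLines("site,a,b\ns1,2.5,0\ns2,1,1", f)
  expect_error(readSiteSpecies(f, valueKind = "presence"), "presence")
  # non-numeric cell reported with location
  writeLines("site,a,b\ns1,x,0\ns2,1,1", f)
  expect_error(readSiteSpecies(f), "non-numeric")
  # duplicate labels rejected
  bad <- x; colnames(bad) <- c("a", "a", "c")
  expect_error(makeCM(bad), "duplicate")
})

test_that("Braun-Blanquet codes map to conventional midpoint covers", {
  codes <- matrix(0:7, 2, 4, dimnames = list(c("s1", "s2"), letters[1:4]))
  m <- makeCM(codes, valueKind = "braun_blanquet")
  cov <- braunBlanquetToCover(m)
  expect_identical(valueKind(cov), "abundance")
  got <- as.vector(as.matrix(cov))
  expect_equal(got, c(0, 0.1, 0.5, 2.5, 15, 37.5, 62.5, 87.5))
  # the two degrees named 3 (25-50%) and 5 (75-100%) on the original scale
  # are codes 5 and 7
  expect_equal(unname(got[6]), 37.5)
  expect_equal(unname(got[8]), 87.5)
  codes[1, 1] <- 8
  expect_error(braunBlanquetToCover(
    makeCM(codes, valueKind = "braun_blanquet")), "0-7")
  expect_error(braunBlanquetToCover(makeCM((codes > 0) + 0)),
               "braun_blanquet")
})

test_that("toPresence thresholds at zero, is idempotent, keeps empty species", {
  x <- matrix(c(0, 2.5, 87.5, 0, 0, 0), 1, 6,
              dimnames = list("s1", sprintf("sp%d", 1:6)))
  m <- makeCM(x, valueKind = "abundance")
  suppressMessages(p <- toPresence(m))
  expect_equal(unname(as.matrix(p)[1, ]), c(0, 1, 1, 0, 0, 0))
  suppressMessages(p2 <- toPresence(p))
  expect_identical(as.matrix(p2), as.matrix(p))
  expect_true(all(sprintf("sp%d", 1:6) %in% speciesNames(p)))
  expect_message(toPresence(m), "no occurrences")
})

test_that("Newick parsing round-trips and flags malformed input", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(ape::Ntip(tr), 3)
  s <- writeNewick(tr)
  tr2 <- parseNewick(s)
  M1 <- ape::cophenetic.phylo(tr); M2 <- ape::cophenetic.phylo(tr2)
  expect_equal(M1[rownames(M2), colnames(M2)], M2, ignore_attr = TRUE)
  expect_error(parseNewick("((A:1,B:1):1,C:2"), "")
  expect_error(parseNewick("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(parseNewick("((A,B),C);"), "branch lengths")
  tr3 <- parseNewick("((A,B),C);", missingLengths = "one")
  expect_true(all(tr3$edge.length == 1))
})

test_that("cophenetic distances equal brute-force path sums", {
  d <- copheneticDistances(parseNewick("((A:1,B:1):1,C:2);"))
  M <- as.matrix(d)
  expect_equal(M["A", "B"], 2)
  expect_equal(M["A", "C"], 4)
  expect_equal(M["B", "C"], 4)
  expect_equal(as.matrix(copheneticDistances(parseNewick("(A:1,B:1);")))["A", "B"], 2)

  # brute-force path sums on a random tree + four-point condition
  set.seed(11)
  tr <- ape::rtree(8)
  M <- as.matrix(copheneticDistances(tr))
  g <- igraph::graph_from_edgelist(tr$edge, directed = FALSE)
  igraph::E(g)$weight <- tr$edge.length
  bf <- igraph::distances(g)[seq_len(8), seq_len(8)]
  dimnames(bf) <- list(tr$tip.label, tr$tip.label)
  expect_equal(M[rownames(bf), colnames(bf)], bf, tolerance = 1e-12)
  quads <- combn(8, 4)
  tl <- sort(tr$tip.label)
  for (q in seq_len(ncol(quads))) {
    ij <- tl[quads[, q]]
    s <- sort(c(M[ij[1], ij[2]] + M[ij[3], ij[4]],
                M[ij[1], ij[3]] + M[ij[2], ij[4]],
                M[ij[1], ij[4]] + M[ij[2], ij[3]]))
    expect_lt(abs(s[2] - s[3]), 1e-9)  # two largest sums equal
  }

  # ultrametric tree: equal root-to-tip depth shows as constant max distance
  tru <- ape::rphylo(10, 1, 0)
  Mu <- as.matrix(copheneticDistances(tru))
  depth <- ape::node.depth.edgelength(tru)[seq_len(10)]
  expect_lt(diff(range(depth)), 1e-9)
})

test_that("Gower distance handles mixed traits, missings and rescaling", {
  v <- cbind(cont = c(0, 5, 10), bin = c(0, 1, 1))
  rownames(v) <- c("x", "y", "z")
  tt <- traitTable(v, kind = c(cont = "continuous", bin = "binary"))
  d1 <- as.matrix(functionalDistance(tt, "cont"))
  expect_equal(d1["x", "y"], 0.5)
  expect_equal(d1["x", "z"], 1.0)
  expect_equal(d1["y", "z"], 0.5)
  db <- as.matrix(functionalDistance(tt, "bin"))
  expect_equal(db["x", "y"], 1)
  expect_equal(db["y", "z"], 0)
  # identical species at distance zero
  v2 <- rbind(v, w = c(0, 0))
  tt2 <- traitTable(v2, kind = tt@kind)
  expect_equal(as.matrix(functionalDistance(tt2))["x", "w"], 0)
  # affine rescaling of a continuous trait leaves Gower unchanged
  v3 <- v; v3[, "cont"] <- 7 * v3[, "cont"] - 3
  tt3 <- traitTable(v3, kind = tt@kind)
  expect_equal(as.matrix(functionalDistance(tt3)),
               as.matrix(functionalDistance(tt)), tolerance = 1e-12)
  # pairwise-complete weighting with a missing value
  v4 <- v; v4[2, "bin"] <- NA
  tt4 <- traitTable(v4, kind = tt@kind)
  d4 <- as.matrix(functionalDistance(tt4))
  expect_equal(d4["x", "y"], 0.5)           # only the continuous trait counts
  expect_equal(d4["x", "z"], 1.0)
  # all-missing species dropped with a warning
  v5 <- v; v5[3, ] <- NA
  tt5 <- traitTable(v5, kind = tt@kind)
  expect_warning(d5 <- functionalDistance(tt5), "all-missing")
  expect_setequal(speciesNames(d5), c("x", "y"))
})

test_that("Gower agrees with cluster::daisy on complete continuous data", {
  set.seed(21)
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("s%02d", 1:10), sprintf("t%d", 1:4)))
  tt <- traitTable(v, kind = setNames(rep("continuous", 4), colnames(v)))
  ours <- as.matrix(functionalDistance(tt))
  ref <- as.matrix(cluster::daisy(as.data.frame(v), metric = "gower"))
  expect_equal(ours[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("every distance constructor enforces symmetry and zero diagonal", {
  set.seed(3)
  tr <- ape::rphylo(6, 1, 0)
  for (d in list(copheneticDistances(tr),
                 functionalDistance(traitTable(
                   matrix(rnorm(12), 6, 2,
                          dimnames = list(tr$tip.label, c("a", "b"))),
                   kind = c(a = "continuous", b = "continuous"))))) {
    M <- as.matrix(d)
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 0))
    expect_true(all(M >= 0))
  }
  expect_error(speciesDist(matrix(c(0, 1, 2, 0), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b"))), "functional"), "symmetric")
})
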