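# Independent oracles and fixture builders used across the suite.
# These deliberately use brute force / enumeration, never the package's own
# code paths.

# joint-occupancy distribution by enumerating every placement of two species
# occupying N1 and N2 of N sites
bfPairPmf <- function(N, N1, N2) {
  jmin <- max(0, N1 + N2 - N)
  jmax <- min(N1, N2)
  counts <- setNames(numeric(jmax - jmin + 1), jmin:jmax)
  pick <- function(k) {
    if (k == 0) return(list(integer(0)))
    combn(N, k, simplify = FALSE)
  }
  for (a in pick(N1)) for (b in pick(N2)) {
    j <- length(intersect(a, b))
    counts[as.character(j)] <- counts[as.character(j)] + 1
  }
  counts / sum(counts)
}

# literal NODF: loop over all ordered row pairs and column pairs
bfNODF <- function(A) {
  A <- (A > 0) + 0
  score <- function(M) {
    f <- rowSums(M)
    tot <- 0
    n <- nrow(M)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (f[i] > f[j] && f[j] > 0)
        tot <- tot + 100 * sum(M[i, ] * M[j, ]) / f[j]
    }
    c(tot, n * (n - 1) / 2)
  }
  r <- score(A); cc <- score(t(A))
  (r[1] + cc[1]) / (r[2] + cc[2])
}

# all set partitions of 1..n (Bell-number enumeration)
allPartitions <- function(n) {
  out <- list()
  rec <- function(i, labels, k) {
    if (i > n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (b in seq_len(k + 1)) {
      labels[i] <- b
      rec(i + 1, labels, max(k, b))
    }
  }
  rec(1, integer(n), 0)
  out
}

# exhaustive maximum of Newman Q over every partition of the vertex set
bfBestQ <- function(adj) {
  sp <- rownames(adj)
  best <- -Inf
  for (p in allPartitions(nrow(adj))) {
    q <- newmanQ(adj, setNames(p, sp))
    if (q > best) best <- q
  }
  best
}

# CoocNetwork from a symmetric 0/1 adjacency (labels added if missing)
makeNet <- function(adj, guild = NULL) {
  if (is.null(rownames(adj))) {
    lab <- sprintf("v%02d", seq_len(nrow(adj)))
    dimnames(adj) <- list(lab, lab)
  }
  storage.mode(adj) <- "integer"
  if (is.null(guild))
    guild <- setNames(rep("plant", nrow(adj)), rownames(adj))
  new("CoocNetwork", adjacency = adj, guild = guild)
}

# CoocNetwork from an edge list over n vertices
edgeNet <- function(edges, n) {
  adj <- matrix(0L, n, n)
  for (e in edges) { adj[e[1], e[2]] <- 1L; adj[e[2], e[1]] <- 1L }
  makeNet(adj)
}

# k disconnected cliques of the given size
cliqueNet <- function(k, size) {
  n <- k * size
  adj <- matrix(0L, n, n)
  for (c in seq_len(k)) {
    idx <- ((c - 1) * size + 1):(c * size)
    adj[idx, idx] <- 1L
  }
  diag(adj) <- 0L
  makeNet(adj)
}

# random simple graph with edge probability p (fixed seed handled by caller)
randomNet <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- rbinom(length(up), 1, p)
  adj <- adj + t(adj)
  makeNet(adj)
}

# canonical string id of a labeled graph (for null-distribution enumeration)
graphId <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  paste(idx[, 1], idx[, 2], sep = "-", collapse = ";")
}

# presence CommunityMatrix from a 0/1 matrix with default labels
makeCM <- function(x, valueKind = "presence", guild = NULL) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("sp%02d", seq_len(ncol(x)))
  if (is.null(guild))
    guild <- setNames(rep("plant", ncol(x)), colnames(x))
  communityMatrix(x, guild = guild, valueKind = valueKind)
}
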