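# Fixtures and independent brute-force oracles shared across the suite.
# Oracles are deliberately naive re-derivations from definitions; they never
# call the implementation paths they check.

# small 4-locus panel (3 single-copy + duplicated DYS385)
tinyPanel <- function() {
  LocusPanel(data.frame(
    locus = c("L1", "L2", "L3", "DYS385"),
    copy_number = c(1L, 1L, 1L, 2L),
    mutation_rate = c(0.002, 0.004, 0.008, 0.003),
    is_slow = c(TRUE, TRUE, FALSE, FALSE)), name = "tiny")
}

quickDataset <- function(alleles, haplogroup = "O", population = "P",
                         panel = tinyPanel(), lat = 30, lon = 110) {
  n <- nrow(alleles)
  info <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                     population = rep_len(population, n),
                     ethnicity = rep_len(population, n),
                     latitude = rep_len(lat, n),
                     longitude = rep_len(lon, n),
                     haplogroup = rep_len(haplogroup, n),
                     stringsAsFactors = FALSE)
  YStrDataset(info, alleles, panel)
}

randomTinyDataset <- function(n, nPop = 1L) {
  al <- cbind(L1 = sample(10:13, n, TRUE), L2 = sample(10:12, n, TRUE),
              L3 = sample(9:15, n, TRUE), DYS385a = sample(11:13, n, TRUE),
              DYS385b = sample(11:13, n, TRUE))
  hg <- sample(c("O2a1", "O1a", "C2a1a3", "R1a", "N1b"), n, TRUE)
  pop <- sample(paste0("P", seq_len(nPop)), n, TRUE)
  quickDataset(al, haplogroup = hg, population = pop)
}

# brute-force category statistics from raw keys (sort-and-count)
oracleStats <- function(keys) {
  keys <- sort(keys[!is.na(keys)])
  n <- length(keys)
  runs <- rle(keys)$lengths
  p <- runs / n
  list(n = n, K = length(runs), mp = sum(p^2),
       div = n * (1 - sum(p^2)) / (n - 1), dc = length(runs) / n)
}

# direct AMOVA Phi-ST from definitional sums of squares
oracleAmova <- function(D, grp) {
  n <- nrow(D)
  labs <- unique(grp)
  P <- length(labs)
  ssT <- sum(D) / (2 * n)
  ssW <- 0
  for (g in labs) {
    i <- which(grp == g)
    ssW <- ssW + sum(D[i, i]) / (2 * length(i))
  }
  ssA <- ssT - ssW
  sw <- ssW / (n - P)
  n0 <- (n - sum(table(grp)^2) / n) / (P - 1)
  sa <- (ssA / (P - 1) - sw) / n0
  if (sa + sw <= 0) 0 else sa / (sa + sw)
}

# hand-coded weighted character distance (mirror of the definition)
oracleDist <- function(a, b, w, isSTR) {
  d <- abs(a - b)
  d[!isSTR] <- as.numeric(d[!isSTR] != 0)
  sum(w * d)
}

oracleDistMatrix <- function(X, w, isSTR) {
  m <- nrow(X)
  D <- matrix(0, m, m, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(m)) for (j in seq_len(m))
    D[i, j] <- oracleDist(X[i, ], X[j, ], w, isSTR)
  D
}

# exhaustive minimum spanning tree cost by Prufer-sequence enumeration of
# every labeled tree (feasible for m <= 6)
oracleMstCost <- function(D) {
  m <- nrow(D)
  if (m <= 1) return(0)
  if (m == 2) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(m)), m - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    deg <- rep(1L, m)
    for (v in pr) deg[v] <- deg[v] + 1L
    cost <- 0
    for (v in pr) {
      leaf <- which(deg == 1L)[1L]
      cost <- cost + D[leaf, v]
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    u <- which(deg == 1L)
    cost <- cost + D[u[1L], u[2L]]
    if (cost < best) best <- cost
  }
  best
}

# MST-containment check: the network's edge set must contain every edge of
# an independently computed (igraph) MST over its node set, span all
# observed classes in one component, and cost no more than the MST over
# the observed classes alone (medians may only shorten the connection).
netContainsMst <- function(net) {
  ids <- rownames(net@characters)
  D <- oracleDistMatrix(net@characters, net@weights, net@isSTR)
  go <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                            weighted = TRUE)
  el <- igraph::as_edgelist(igraph::mst(go))
  edgeKey <- c(paste(net@edges$from, net@edges$to),
               paste(net@edges$to, net@edges$from))
  contained <- all(paste(el[, 1L], el[, 2L]) %in% edgeKey)
  g <- igraph::graph_from_data_frame(
    net@edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ids))
  connected <- igraph::components(g)$no == 1L
  Dobs <- D[net@observed, net@observed, drop = FALSE]
  goObs <- igraph::graph_from_adjacency_matrix(Dobs, mode = "undirected",
                                               weighted = TRUE)
  mstObsCost <- sum(igraph::E(igraph::mst(goObs))$weight)
  costOk <- networkCost(net) <= mstObsCost + 1e-9
  contained && connected && costOk
}

# deepest-consistent-node search over every tree node (assignment oracle)
oracleAssign <- function(snpStates, tree) {
  nodes <- tree@nodes
  stateOf <- function(hg) {
    s <- nodes$snp[match(hg, nodes$haplogroup)]
    if (is.na(s) || !s %in% names(snpStates)) "U" else snpStates[[s]]
  }
  best <- tree@root
  bestDepth <- -1L
  for (h in nodes$haplogroup) {
    if (stateOf(h) != "D") next
    anc <- ypopgen:::hgAncestors(tree, h)
    if (any(vapply(anc, function(a) stateOf(a) == "A", logical(1L)))) next
    if (length(anc) > bestDepth ||
        (length(anc) == bestDepth && h < best)) {
      best <- h
      bestDepth <- length(anc)
    }
  }
  best
}

# a star genealogy: every tip hangs directly off the root at depth t
starTree <- function(n, depth) {
  tree <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
               edge.length = rep(depth, n),
               tip.label = paste0("t", seq_len(n)), Nnode = 1L)
  class(tree) <- "phylo"
  tree
}

# full study-configured synthetic run, built once and cached for the session
studySim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateDataset(defaultSimConfig(),
                                                  seed = 20230814L)
    cache
  }
})
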