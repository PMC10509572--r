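#' Weighted SNP/STR network distance
#'
#' Distance between two mixed character vectors: weighted absolute
#' repeat-count difference for STR characters plus weighted mismatch for
#' binary SNP characters. SNP characters default to weight 99, STRs carry
#' their 1-5 rate-derived weights, so a single SNP difference outweighs any
#' plausible STR variation.
#'
#' @param a,b numeric character vectors over the same characters.
#' @param weights per-character weights.
#' @param isSTR logical per character; FALSE marks SNP characters.
#' @return nonnegative weighted distance.
#' @export
weightedDistance <- function(a, b, weights, isSTR) {
  if (length(a) != length(b) || length(a) != length(weights) ||
      length(a) != length(isSTR))
    stop("mismatched character sets")
  d <- abs(a - b)
  d[!isSTR] <- as.numeric(d[!isSTR] != 0)
  sum(weights * d)
}

# All pairwise weighted distances for a node matrix.
weightedDistanceMatrix <- function(X, weights, isSTR) {
  m <- nrow(X)
  D <- matrix(0, m, m, dimnames = list(rownames(X), rownames(X)))
  if (m < 2) return(D)
  for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
    D[i, j] <- D[j, i] <- weightedDistance(X[i, ], X[j, ], weights, isSTR)
  }
  D
}

# Prim MST total cost over a full distance matrix.
mstCost <- function(D) {
  m <- nrow(D)
  if (m < 2) return(0)
  inT <- logical(m); inT[1L] <- TRUE
  key <- D[1L, ]
  tot <- 0
  for (k in seq_len(m - 1L)) {
    cand <- which(!inT)
    pick <- cand[which.min(key[cand])]
    tot <- tot + unname(key[pick])
    inT[pick] <- TRUE
    key <- pmin(key, D[pick, ])
  }
  tot
}

# Epsilon-relaxed minimum spanning network: an edge (u,v) is feasible when
# u and v are not connected by links strictly shorter than d(u,v) - eps.
# Union-find with a two-pointer sweep (the threshold d - eps is monotone in
# the sweep order, so unions can be applied incrementally).
msnEdges <- function(D, epsilon = 0) {
  m <- nrow(D)
  if (m < 2) return(data.frame(from = character(), to = character(),
                               length = numeric()))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  dv <- D[pairs]
  ord <- order(dv)
  pairs <- pairs[ord, , drop = FALSE]
  dv <- dv[ord]
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  np <- length(dv)
  merged <- 1L  # next pair whose union has not been applied
  keepFrom <- integer(); keepTo <- integer(); keepD <- numeric()
  for (k in seq_len(np)) {
    thr <- dv[k] - epsilon - 1e-12
    while (merged <= np && dv[merged] < thr) {
      ra <- find(pairs[merged, 1L]); rb <- find(pairs[merged, 2L])
      if (ra != rb) parent[ra] <- rb
      merged <- merged + 1L
    }
    if (find(pairs[k, 1L]) != find(pairs[k, 2L])) {
      keepFrom <- c(keepFrom, pairs[k, 1L])
      keepTo <- c(keepTo, pairs[k, 2L])
      keepD <- c(keepD, dv[k])
    }
  }
  data.frame(from = rownames(D)[keepFrom], to = rownames(D)[keepTo],
             length = keepD)
}

#' Collapse samples into haplotype classes for network construction
#'
#' Builds the mixed character matrix over the single-copy STR loci (and,
#' optionally, binary SNP states derived from the haplogroup calls and a
#' tree), merging identical vectors into classes with multiplicities and
#' per-population composition. Samples with missing characters are dropped.
#'
#' @param ds a [YStrDataset-class].
#' @param loci STR loci (default: the single-copy set).
#' @param tree optional [HaplogroupTree-class]; when given, one binary
#'   character per defining SNP is added, derived (1) for samples whose
#'   haplogroup call lies at or below that SNP's node.
#' @return list with \code{characters} (classes x characters),
#'   \code{multiplicity}, \code{composition} (classes x populations),
#'   \code{weights}, \code{isSTR}.
#' @export
haplotypeClasses <- function(ds, loci = NULL, tree = NULL) {
  if (is.null(loci)) loci <- singleCopyLoci(ds@panel)
  X <- alleleMatrix(ds, loci)
  isSTR <- rep(TRUE, ncol(X))
  w <- networkWeights(ds@panel)[loci]
  weights <- unname(w)
  if (!is.null(tree)) {
    S <- snpStatesFromHaplogroups(ds, tree)
    X <- cbind(X, S)
    weights <- c(weights, rep(99, ncol(S)))
    isSTR <- c(isSTR, rep(FALSE, ncol(S)))
  }
  keep <- rowSums(is.na(X)) == 0
  X <- X[keep, , drop = FALSE]
  pops <- ds@info$population[keep]
  key <- apply(X, 1L, paste, collapse = "|")
  o <- order(key)
  uk <- unique(key[o])
  idx <- match(key, uk)
  C <- X[match(uk, key), , drop = FALSE]
  rownames(C) <- paste0("H", seq_along(uk))
  comp <- table(factor(idx, levels = seq_along(uk)), pops)
  composition <- matrix(as.numeric(comp), nrow(comp), ncol(comp),
                        dimnames = list(rownames(C), colnames(comp)))
  list(characters = C, multiplicity = as.numeric(rowSums(composition)),
       composition = composition, weights = weights, isSTR = isSTR)
}

#' Binary SNP states implied by haplogroup calls
#'
#' For every defining SNP in the tree, a sample is derived (1) when the
#' SNP's node lies on the root-to-call path of its haplogroup, ancestral
#' (0) otherwise.
#'
#' @param ds a [YStrDataset-class].
#' @param tree a [HaplogroupTree-class].
#' @return numeric matrix samples x SNPs.
#' @export
snpStatesFromHaplogroups <- function(ds, tree) {
  snps <- tree@nodes$snp
  hg2snp <- stats::setNames(tree@nodes$snp, tree@nodes$haplogroup)
  S <- matrix(0, nSamples(ds), length(snps),
              dimnames = list(ds@info$sample_id, snps))
  for (r in seq_len(nSamples(ds))) {
    h <- tryCatch(parseHaplogroup(ds@info$haplogroup[r]),
                  error = function(e) NULL)
    if (is.null(h)) next
    name <- renderHaplogroup(h, snp = FALSE, star = FALSE)
    if (!name %in% tree@nodes$haplogroup) next
    path <- c(name, hgAncestors(tree, name))
    S[r, hg2snp[path]] <- 1
  }
  S
}

#' Build a weighted median-joining network
#'
#' Iterative median-joining over mixed STR/SNP characters: (1) build the
#' epsilon-relaxed minimum spanning network over the current node set;
#' (2) for every mutually connected triplet compute the component-wise
#' quasi-median (numeric median for STR characters, majority state for
#' SNPs); (3) add the median that most reduces total connection cost
#' (minimum-spanning-tree length over the node set); repeat to a fixed
#' point; (4) delete median vectors whose removal leaves the connection
#' cost unchanged. Ties are broken lexicographically, so the result is
#' invariant to the input order of classes.
#'
#' @param classes list as returned by [haplotypeClasses()], or a bare
#'   numeric matrix of haplotype class vectors (then \code{weights},
#'   \code{isSTR}, \code{multiplicity} may be given directly).
#' @param epsilon relaxation parameter (0 = strict MJ).
#' @param weights,isSTR,multiplicity,composition used when \code{classes}
#'   is a bare matrix; default weight 1 and all-STR characters.
#' @param preprocess star-contraction pre-processing: leaf classes within
#'   \code{delta} of a more frequent neighbour are merged into it before
#'   network construction.
#' @param delta contraction radius (weighted distance units).
#' @return a [HaplotypeNetwork-class].
#' @export
buildMJNetwork <- function(classes, epsilon = 0, weights = NULL,
                           isSTR = NULL, multiplicity = NULL,
                           composition = NULL, preprocess = FALSE,
                           delta = 0) {
  if (is.list(classes) && !is.null(classes$characters)) {
    X <- classes$characters
    weights <- classes$weights
    isSTR <- classes$isSTR
    multiplicity <- classes$multiplicity
    composition <- classes$composition
  } else {
    X <- as.matrix(classes)
    if (is.null(weights)) weights <- rep(1, ncol(X))
    if (is.null(isSTR)) isSTR <- rep(TRUE, ncol(X))
    if (is.null(multiplicity)) multiplicity <- rep(1, nrow(X))
  }
  if (nrow(X) == 0) stop("no haplotype classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  if (is.null(composition))
    composition <- matrix(multiplicity, nrow(X), 1L,
                          dimnames = list(NULL, "all"))
  # canonical ordering: classes sorted lexicographically by their vectors
  key <- apply(X, 1L, paste, collapse = "|")
  o <- order(key)
  X <- X[o, , drop = FALSE]
  multiplicity <- multiplicity[o]
  composition <- composition[o, , drop = FALSE]
  rownames(X) <- paste0("H", seq_len(nrow(X)))
  rownames(composition) <- rownames(X)

  if (preprocess && nrow(X) > 2) {
    repeat {
      D <- weightedDistanceMatrix(X, weights, isSTR)
      merged <- FALSE
      for (i in seq_len(nrow(X))) {
        if (nrow(X) <= 2) break
        d <- D[i, ]; d[i] <- Inf
        hub <- which.min(d)
        if (d[hub] <= delta && multiplicity[hub] >= multiplicity[i] &&
            multiplicity[hub] > 0) {
          multiplicity[hub] <- multiplicity[hub] + multiplicity[i]
          composition[hub, ] <- composition[hub, ] + composition[i, ]
          X <- X[-i, , drop = FALSE]
          multiplicity <- multiplicity[-i]
          composition <- composition[-i, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }

  nObs <- nrow(X)
  obsNames <- rownames(X)
  medCount <- 0L
  repeat {
    D <- weightedDistanceMatrix(X, weights, isSTR)
    base <- mstCost(D)
    E <- msnEdges(D, epsilon)
    # adjacency for triplet enumeration
    adj <- matrix(FALSE, nrow(X), nrow(X),
                  dimnames = list(rownames(X), rownames(X)))
    if (nrow(E)) {
      adj[cbind(E$from, E$to)] <- TRUE
      adj <- adj | t(adj)
    }
    bestGain <- 0; bestQM <- NULL
    idx <- seq_len(nrow(X))
    nodeKeys <- apply(X, 1L, paste, collapse = "|")
    triedQM <- character()
    for (i in idx) for (j in idx[idx > i]) {
      if (!adj[i, j]) next
      for (k in idx[idx > j]) {
        if (!(adj[i, k] && adj[j, k])) next
        trip <- X[c(i, j, k), , drop = FALSE]
        qm <- apply(trip, 2L, stats::median)
        qKey <- paste(qm, collapse = "|")
        if (qKey %in% nodeKeys || qKey %in% triedQM) next
        triedQM <- c(triedQM, qKey)
        dq <- apply(X, 1L, weightedDistance, b = qm, weights = weights,
                    isSTR = isSTR)
        D2 <- rbind(cbind(D, dq), c(dq, 0))
        gain <- base - mstCost(D2)
        if (gain > bestGain + 1e-9 ||
            (bestGain > 0 && abs(gain - bestGain) <= 1e-9 &&
             !is.null(bestQM) && qKey < paste(bestQM, collapse = "|"))) {
          bestGain <- gain
          bestQM <- qm
        }
      }
    }
    if (is.null(bestQM)) break
    medCount <- medCount + 1L
    X <- rbind(X, bestQM)
    rownames(X)[nrow(X)] <- paste0("mv", medCount)
    multiplicity <- c(multiplicity, 0)
    composition <- rbind(composition, 0)
    rownames(composition) <- rownames(X)
  }

  # drop medians that no longer pay for themselves
  repeat {
    D <- weightedDistanceMatrix(X, weights, isSTR)
    cost <- mstCost(D)
    meds <- which(!rownames(X) %in% obsNames)
    dropped <- FALSE
    for (i in meds) {
      if (mstCost(D[-i, -i, drop = FALSE]) <= cost + 1e-9) {
        X <- X[-i, , drop = FALSE]
        multiplicity <- multiplicity[-i]
        composition <- composition[-i, , drop = FALSE]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  D <- weightedDistanceMatrix(X, weights, isSTR)
  E <- msnEdges(D, epsilon)
  if (nrow(E)) {
    E$changes <- vapply(seq_len(nrow(E)), function(k) {
      a <- X[E$from[k], ]; b <- X[E$to[k], ]
      ch <- which(a != b)
      paste(sprintf("%s:%+g", colnames(X)[ch], (b - a)[ch]), collapse = ";")
    }, character(1L))
  } else E$changes <- character()
  new("HaplotypeNetwork", characters = X,
      observed = rownames(X) %in% obsNames,
      multiplicity = multiplicity, composition = composition,
      edges = E, weights = weights, isSTR = isSTR, epsilon = epsilon)
}

#' Median-joining network of a dataset
#'
#' Convenience wrapper: collapses a (typically clade-restricted) dataset
#' into haplotype classes over the single-copy loci, optionally adds SNP
#' characters from a haplogroup tree, and runs [buildMJNetwork()].
#'
#' @inheritParams haplotypeClasses
#' @inheritParams buildMJNetwork
#' @export
mjNetwork <- function(ds, loci = NULL, tree = NULL, epsilon = 0,
                      preprocess = FALSE, delta = 0) {
  buildMJNetwork(haplotypeClasses(ds, loci, tree), epsilon = epsilon,
                 preprocess = preprocess, delta = delta)
}

# igraph view of a network; edge attribute `steps` carries the unweighted
# mutational step count (STR repeat differences + SNP changes).
networkGraph <- function(net) {
  steps <- vapply(seq_len(nrow(net@edges)), function(k) {
    a <- net@characters[net@edges$from[k], ]
    b <- net@characters[net@edges$to[k], ]
    d <- abs(a - b)
    d[!net@isSTR] <- as.numeric(d[!net@isSTR] != 0)
    sum(d)
  }, numeric(1L))
  g <- igraph::graph_from_data_frame(
    cbind(net@edges[, c("from", "to")], weight = net@edges$length,
          steps = steps),
    directed = FALSE,
    vertices = data.frame(name = rownames(net@characters)))
  g
}

#' Export a haplotype network
#'
#' Writes GraphML, DOT or a plain edge TSV. Nodes carry their multiplicity
#' and a per-population composition string (\code{"Han:3;Hui:1"}), the
#' pie-chart data of the usual network figures; edges carry their weighted
#' length and per-character change list.
#'
#' @param net a [HaplotypeNetwork-class].
#' @param path output file.
#' @param format \code{"graphml"}, \code{"dot"} or \code{"edge_tsv"}.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "dot",
                                                "edge_tsv")) {
  format <- match.arg(format)
  ids <- rownames(net@characters)
  compStr <- vapply(seq_along(ids), function(i) {
    x <- net@composition[i, ]
    x <- x[x > 0]
    if (!length(x)) "" else
      paste(sprintf("%s:%g", names(x), x), collapse = ";")
  }, character(1L))
  E <- net@edges
  if (format == "edge_tsv") {
    utils::write.table(E, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "dot") {
    lines <- c("graph mjnetwork {")
    lines <- c(lines, sprintf(
      "  \"%s\" [multiplicity=%g, composition=\"%s\", observed=%s];",
      ids, net@multiplicity, compStr, tolower(net@observed)))
    if (nrow(E))
      lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [len=%g];",
                                E$from, E$to, E$length))
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="d0" for="node" attr.name="multiplicity" attr.type="double"/>',
      '<key id="d1" for="node" attr.name="composition" attr.type="string"/>',
      '<key id="d2" for="node" attr.name="observed" attr.type="boolean"/>',
      '<key id="d3" for="edge" attr.name="length" attr.type="double"/>',
      '<key id="d4" for="edge" attr.name="changes" attr.type="string"/>',
      '<graph id="mj" edgedefault="undirected">')
    lines <- c(lines, sprintf(
      '<node id="%s"><data key="d0">%g</data><data key="d1">%s</data><data key="d2">%s</data></node>',
      ids, net@multiplicity, esc(compStr), tolower(net@observed)))
    if (nrow(E))
      lines <- c(lines, sprintf(
        '<edge source="%s" target="%s"><data key="d3">%g</data><data key="d4">%s</data></edge>',
        E$from, E$to, E$length, esc(E$changes)))
    lines <- c(lines, "</graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
setMethod("show", "HaplotypeNetwork", function(object) {
  cat(sprintf(
    "HaplotypeNetwork: %d observed classes + %d median vectors, %d edges (epsilon %g)\n",
    sum(object@observed), sum(!object@observed), nrow(object@edges),
    object@epsilon))
  cat(sprintf("  total connection cost: %g\n", networkCost(object)))
})

#' Total connection cost of a network
#'
#' Minimum-spanning-tree length over the network's node set under the
#' weighted distance; the quantity median insertion minimizes.
#'
#' @param net a [HaplotypeNetwork-class].
#' @export
networkCost <- function(net)
  mstCost(weightedDistanceMatrix(net@characters, net@weights, net@isSTR))
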