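test_that("weighted distance mixes STR repeat steps and SNP mismatches", {
  w <- c(3, 2, 99)
  isSTR <- c(TRUE, TRUE, FALSE)
  expect_equal(weightedDistance(c(12, 10, 0), c(12, 10, 0), w, isSTR), 0)
  expect_equal(weightedDistance(c(12, 10, 0), c(14, 10, 0), w, isSTR), 6)
  expect_equal(weightedDistance(c(12, 10, 0), c(12, 10, 1), w, isSTR), 99)
  expect_error(weightedDistance(c(1, 2), c(1, 2, 3), c(1, 1, 1), isSTR),
               "mismatch")
})

test_that("median joining solves the textbook Steiner triplet", {
  X <- rbind(A = c(0, 0, 0), B = c(1, 1, 0), C = c(1, 0, 1))
  net <- buildMJNetwork(X, isSTR = rep(FALSE, 3))
  expect_equal(sum(!net@observed), 1L)
  med <- net@characters[!net@observed, ]
  expect_equal(unname(med), c(1, 0, 0))
  expect_equal(networkCost(net), 3)  # vs 4 for any median-free tree
  expect_equal(oracleMstCost(oracleDistMatrix(X, rep(1, 3),
                                              rep(FALSE, 3))), 4)
  # star: all three observed nodes attach to the median
  deg <- table(c(net@edges$from, net@edges$to))
  expect_equal(unname(deg[rownames(net@characters)[!net@observed]]), 3L)
})

test_that("quasi-medians that coincide with observed nodes add nothing", {
  X <- rbind(c(10, 10), c(11, 10), c(10, 11))
  net <- buildMJNetwork(X)
  expect_equal(sum(!net@observed), 0L)
  expect_equal(nrow(net@edges), 2L)
  # star through (10,10)
  hub <- rownames(net@characters)[apply(net@characters, 1L, function(x)
    all(x == c(10, 10)))]
  expect_true(all(net@edges$from == hub | net@edges$to == hub))

  # two classes one step apart: a single edge, no medians
  n2 <- buildMJNetwork(rbind(c(12, 10), c(13, 10)))
  expect_equal(nrow(n2@edges), 1L)
  expect_equal(n2@edges$length, 1)
})

test_that("the network realizes an MST of the observed classes on random instances", {
  set.seed(21)
  for (i in 1:40) {
    m <- sample(3:8, 1L)
    nc <- sample(3:5, 1L)
    binary <- runif(1) < 0.5
    X <- if (binary)
      matrix(sample(0:1, m * nc, TRUE), m, nc)
    else
      matrix(sample(10:13, m * nc, TRUE), m, nc)
    X <- X[!duplicated(apply(X, 1L, paste, collapse = "|")), , drop = FALSE]
    if (nrow(X) < 3) next
    w <- sample(1:5, nc, TRUE)
    net <- buildMJNetwork(X, weights = w, isSTR = rep(!binary, nc))
    expect_true(netContainsMst(net))
    # total connection cost never exceeds the observed-class MST cost
    Dobs <- oracleDistMatrix(net@characters[net@observed, , drop = FALSE],
                             net@weights, net@isSTR)
    if (nrow(Dobs) <= 6) {
      mstExhaustive <- oracleMstCost(Dobs)
      expect_lte(networkCost(net), mstExhaustive + 1e-9)
      expect_equal(ypopgen:::mstCost(Dobs), mstExhaustive)
    }
  }
})

test_that("network output is invariant to the input order of classes", {
  set.seed(31)
  X <- matrix(sample(10:12, 6 * 4, TRUE), 6, 4)
  X <- X[!duplicated(apply(X, 1L, paste, collapse = "|")), , drop = FALSE]
  mult <- seq_len(nrow(X))
  net1 <- buildMJNetwork(X, multiplicity = mult)
  perm <- sample(nrow(X))
  net2 <- buildMJNetwork(X[perm, , drop = FALSE], multiplicity = mult[perm])
  expect_identical(net1@characters, net2@characters)
  expect_identical(net1@edges$from, net2@edges$from)
  expect_identical(net1@edges$to, net2@edges$to)
  expect_identical(net1@multiplicity, net2@multiplicity)
})

test_that("epsilon relaxation only widens the feasible link set", {
  set.seed(8)
  X <- matrix(sample(10:12, 5 * 3, TRUE), 5, 3)
  X <- X[!duplicated(apply(X, 1L, paste, collapse = "|")), , drop = FALSE]
  D <- oracleDistMatrix(X, rep(1, 3), rep(TRUE, 3))
  rownames(D) <- colnames(D) <- paste0("H", seq_len(nrow(D)))
  e0 <- ypopgen:::msnEdges(D, 0)
  e1 <- ypopgen:::msnEdges(D, 2)
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(e0) %in% key(e1)))
})

test_that("star contraction merges satellite singletons into their hub", {
  X <- rbind(c(12, 10), c(13, 10), c(12, 11), c(20, 20))
  mult <- c(10, 1, 1, 3)
  net <- buildMJNetwork(X, multiplicity = mult, preprocess = TRUE,
                        delta = 1)
  expect_equal(sum(net@observed), 2L)  # hub (absorbed) + distant class
  expect_equal(sum(net@multiplicity), sum(mult))
  expect_true(any(net@multiplicity == 12))
})

test_that("exports carry composition attributes and re-import intact", {
  ds <- randomTinyDataset(15, nPop = 2L)
  net <- mjNetwork(ds)
  tf <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, tf, "graphml")
  g <- igraph::read_graph(tf, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net@characters))
  expect_equal(igraph::ecount(g), nrow(net@edges))
  comp <- igraph::vertex_attr(g, "composition")
  expect_true(any(grepl("P[12]:[0-9]", comp)))

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  exportNetwork(net, tf2, "edge_tsv")
  edges <- utils::read.delim(tf2)
  expect_equal(nrow(edges), nrow(net@edges))

  tf3 <- withr::local_tempfile(fileext = ".dot")
  exportNetwork(net, tf3, "dot")
  expect_match(readLines(tf3, n = 1L), "graph")
  expect_error(exportNetwork(net, tf3, "png"), "arg")
})

test_that("SNP characters from haplogroup calls mark the root-to-call path", {
  ds <- randomTinyDataset(10)
  tr <- defaultHaplogroupTree()
  S <- snpStatesFromHaplogroups(ds, tr)
  i <- which(sampleInfo(ds)$haplogroup == "O2a1")[1L]
  if (!is.na(i)) {
    expect_equal(unname(S[i, c("L467", "M324", "M122", "M175")]),
                 rep(1, 4))
    expect_equal(unname(S[i, "M130"]), 0)
  }
})
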