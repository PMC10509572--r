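test_that("AMOVA Fst hits the analytic limit cases", {
  # two populations fixed for different haplotypes: all variance among
  al <- cbind(L1 = c(rep(10, 5), rep(14, 5)), L2 = 11, L3 = 10,
              DYS385a = 11, DYS385b = 14)
  ds <- quickDataset(al, population = rep(c("A", "B"), each = 5))
  for (mode in c("haplotype_identity", "stepwise")) {
    f <- pairwiseFst(ds, mode = mode, nPermutations = 199, seed = 1)
    expect_equal(f@fst["A", "B"], 1)
    expect_lt(f@pvalues["A", "B"], 0.05)
  }

  # identical haplotype multisets: among-group variance is exactly zero and
  # the unbiased estimator sits at its small negative floor -1/(m-1)
  m <- 30L
  base <- cbind(L1 = sample(10:13, m, TRUE), L2 = sample(10:12, m, TRUE),
                L3 = 10, DYS385a = 11, DYS385b = 14)
  ds2 <- quickDataset(rbind(base, base),
                      population = rep(c("A", "B"), each = m))
  f2 <- pairwiseFst(ds2, nPermutations = 199, seed = 2)
  expect_lt(abs(f2@fst["A", "B"]), 0.05)
  expect_gt(f2@pvalues["A", "B"], 0.5)
})

test_that("Fst equals the definitional AMOVA oracle on random small instances", {
  set.seed(99)
  for (i in 1:50) {
    nA <- sample(2:6, 1L); nB <- sample(2:6, 1L)
    al <- cbind(L1 = sample(10:12, nA + nB, TRUE),
                L2 = sample(10:12, nA + nB, TRUE),
                L3 = sample(9:15, nA + nB, TRUE),
                DYS385a = 11, DYS385b = 14)
    grp <- rep(c("A", "B"), c(nA, nB))
    ds <- quickDataset(al, population = grp)
    for (mode in c("haplotype_identity", "stepwise")) {
      f <- pairwiseFst(ds, mode = mode, nPermutations = 0)
      X <- alleleMatrix(ds, singleCopyLoci(panelOf(ds)))
      D <- if (mode == "stepwise") as.matrix(dist(X))^2 else
        outer(haplotypeKeys(ds, singleCopyLoci(panelOf(ds))),
              haplotypeKeys(ds, singleCopyLoci(panelOf(ds))),
              Negate(`==`)) * 1
      expect_equal(f@fst["A", "B"], oracleAmova(D, grp), tolerance = 1e-9)
    }
  }
})

test_that("Fst is invariant to sample order and symmetric in labels", {
  set.seed(4)
  ds <- randomTinyDataset(40, nPop = 2L)
  f1 <- pairwiseFst(ds, nPermutations = 99, seed = 7)
  perm <- sample(nSamples(ds))
  f2 <- pairwiseFst(subsetSamples(ds, perm), nPermutations = 99, seed = 7)
  expect_equal(f1@fst[f1@labels, f1@labels], f2@fst[f1@labels, f1@labels])
  expect_identical(f1@fst, t(f1@fst))
  expect_identical(f1@pvalues, t(f1@pvalues))
})

test_that("stepwise Fst reduces to identity Fst when all haplotypes are equidistant", {
  # single locus, alleles only 10 or 12: any two distinct haplotypes are
  # exactly 4 apart under squared stepwise distance, i.e. a scaled identity
  al <- cbind(L1 = sample(c(10, 12), 20, TRUE), L2 = 11, L3 = 10,
              DYS385a = 11, DYS385b = 14)
  ds <- quickDataset(al, population = rep(c("A", "B"), 10))
  fI <- pairwiseFst(ds, "haplotype_identity", nPermutations = 0)
  fS <- pairwiseFst(ds, "stepwise", nPermutations = 0)
  expect_equal(fI@fst["A", "B"], fS@fst["A", "B"], tolerance = 1e-12)
})

test_that("PCA of haplogroup frequencies orders simple gradients and fixes signs", {
  fm <- rbind(P1 = c(O = 0.1, C = 0.9), P2 = c(O = 0.5, C = 0.5),
              P3 = c(O = 0.9, C = 0.1))
  pc <- pcaHaplogroupFreq(fm, 1L)
  expect_true(all(diff(pc$coordinates[, 1L] *
                         sign(pc$coordinates[3L, 1L] -
                                pc$coordinates[1L, 1L])) > 0))
  expect_equal(sum(pcaHaplogroupFreq(fm, 1L)$explained), 1)  # rank 1

  fm2 <- rbind(A = c(0.2, 0.8), B = c(0.2, 0.8), C = c(0.6, 0.4))
  pc2 <- pcaHaplogroupFreq(fm2, 1L)
  expect_equal(pc2$coordinates["A", 1L], pc2$coordinates["B", 1L])

  expect_warning(pcaHaplogroupFreq(rbind(c(.5, .5), c(.5, .5)), 1L),
                 "zero variance")

  # deterministic sign: rebuilding from reordered rows gives the same axes
  pc3 <- pcaHaplogroupFreq(fm[c(3, 1, 2), ], 1L)
  expect_equal(sort(pc3$coordinates[, 1L]), sort(pc$coordinates[, 1L]),
               ignore_attr = TRUE)
})

test_that("frequency matrices have unit row sums and level-consistent columns", {
  set.seed(12)
  ds <- randomTinyDataset(60, nPop = 3L)
  fm <- haplogroupFrequencyMatrix(ds, level = 0)
  expect_equal(unname(rowSums(fm)), rep(1, nrow(fm)), tolerance = 1e-9)
  expect_true(all(fm >= 0))
  expect_true(all(nchar(colnames(fm)) == 1L))
})

test_that("IDW surfaces honour stations, stay within bounds and handle duplicates", {
  s1 <- data.frame(lat = 30, lon = 110, frequency = 0.4)
  surf <- idwSurface(s1, cellSize = 1, pad = 2)
  expect_true(all(abs(surf@values - 0.4) < 1e-12))

  s2 <- data.frame(lat = c(30, 30), lon = c(110, 114),
                   frequency = c(0.2, 0.6))
  surf2 <- idwSurface(s2, cellSize = 1, pad = 2, power = 2)
  # grid node at a station takes the station value exactly
  i <- which(surf2@lat == 30); j <- which(surf2@lon == 110)
  expect_identical(surf2@values[i, j], 0.2)
  # midpoint at equal distances averages the two stations
  jm <- which(surf2@lon == 112)
  expect_equal(surf2@values[i, jm], 0.4)
  # convexity: everything within the station range
  expect_true(all(surf2@values >= 0.2 - 1e-12 &
                    surf2@values <= 0.6 + 1e-12))

  dup <- data.frame(lat = c(30, 30), lon = c(110, 110),
                    frequency = c(0.2, 0.6))
  expect_error(idwSurface(dup), "duplicate")

  # station builder: frequencies of a clade per population
  ds <- randomTinyDataset(50, nPop = 2L)
  st <- haplogroupStations(ds, "O")
  expect_equal(nrow(st), 2L)
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
})
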