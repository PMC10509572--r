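test_that("association tables report per-haplogroup GD and spectra", {
  al <- cbind(L1 = c(13, 13, 13, 15, 16, 17), L2 = 11, L3 = 10,
              DYS385a = 11, DYS385b = 14)
  ds <- quickDataset(al, haplogroup = rep(c("O2", "C2"), each = 3))
  tab <- associationTable(ds, level = 1)
  o2 <- tab[tab$haplogroup == "O2" & tab$locus == "L1", ]
  expect_equal(o2$gd, 0)  # fixed for 13
  sp <- attr(tab, "spectra")[["O2|L1"]]
  expect_equal(unname(sp["13"]), 1)
  # disjoint allele sets between the two haplogroups at L1
  spC <- attr(tab, "spectra")[["C2|L1"]]
  expect_length(intersect(names(sp), names(spC)), 0L)
  # n < 2 classes are marked, not dropped
  ds2 <- quickDataset(al, haplogroup = c(rep("O2", 5), "C2"))
  tab2 <- associationTable(ds2, level = 1)
  expect_true(is.na(tab2$gd[tab2$haplogroup == "C2" & tab2$locus == "L1"]))
})

test_that("training produces smoothed, duplication-invariant profiles", {
  al <- cbind(L1 = c(15, 15, 12, 12), L2 = c(10, 11, 10, 11), L3 = 10,
              DYS385a = 11, DYS385b = 14)
  ds <- quickDataset(al, haplogroup = c("O2", "O2", "C2", "C2"))
  prof <- trainPredictor(ds, level = 1, pseudocount = 0.5)
  tab <- prof@tables[["L1"]]
  # allele 15 never seen in C2: pure pseudocount mass
  expect_equal(tab["C2", "15"], 0.5 / (2 + 0.5 * 3))
  expect_equal(unname(rowSums(tab)), c(1, 1), tolerance = 1e-12)

  dbl <- quickDataset(al[rep(seq_len(4), 2), ],
                      haplogroup = rep(c("O2", "O2", "C2", "C2"), 2))
  prof2 <- trainPredictor(dbl, level = 1, pseudocount = 0)
  prof1 <- trainPredictor(ds, level = 1, pseudocount = 0)
  expect_equal(prof2@tables, prof1@tables)

  # pseudocount 0 gives unseen alleles zero likelihood (documented hazard)
  pr <- predictHaplogroup(c(L1 = 15), prof1)
  expect_equal(unname(pr$posterior["C2"]), 0)

  expect_error(trainPredictor(quickDataset(al, haplogroup = "O2")),
               "two haplogroup classes")
})

test_that("prediction is a normalized Bayes posterior, order-invariant, underflow-safe", {
  set.seed(2)
  # strong profile: alleles 15 at L1 and L2 exclusive to O
  al <- cbind(L1 = c(rep(15, 20), rep(12, 20)),
              L2 = c(rep(15, 20), rep(11, 20)),
              L3 = sample(9:15, 40, TRUE),
              DYS385a = 11, DYS385b = 14)
  ds <- quickDataset(al, haplogroup = rep(c("O2", "C2"), each = 20))
  prof <- trainPredictor(ds, level = 1)
  pr <- predictHaplogroup(c(L1 = 15, L2 = 15), prof)
  expect_equal(pr$winner, "O2")
  expect_gt(pr$posterior[["O2"]], 0.99)
  expect_equal(sum(pr$posterior), 1)

  # symmetric two-class profile: exact 0.5/0.5
  alu <- cbind(L1 = rep(c(12, 15), 10), L2 = 11, L3 = 10, DYS385a = 11,
               DYS385b = 14)
  dsu <- quickDataset(alu, haplogroup = rep(c("O2", "C2"), 10))
  profu <- trainPredictor(dsu, level = 1)
  pru <- predictHaplogroup(c(L2 = 11), profu)
  expect_equal(unname(pru$posterior), c(0.5, 0.5))

  # locus evaluation order cannot matter
  h <- c(L1 = 15, L2 = 15, L3 = 12)
  p1 <- predictHaplogroup(h, prof)
  p2 <- predictHaplogroup(h[c(3, 1, 2)], prof)
  expect_equal(p1$posterior, p2$posterior)

  # 23-locus products stay finite in log space
  big <- studySim()$dataset
  profBig <- trainPredictor(subsetSamples(big, 1:500), level = 1)
  m <- alleleMatrix(subsetSamples(big, 501:520), profBig@loci)
  lp <- ypopgen:::predictorLogPost(m, profBig)
  expect_true(all(is.finite(lp[, "O2"]) | lp[, "O2"] == -Inf))
  expect_true(all(is.finite(apply(lp, 1L, max))))

  expect_error(predictHaplogroup(c(ZZ = 1), prof), "no profiled locus")
})

test_that("cross-validation is perfect on separable classes and honest on shuffles", {
  set.seed(13)
  n <- 60
  cls <- rep(c("O2", "C2", "N1"), each = n / 3)
  base <- c(O2 = 10, C2 = 20, N1 = 30)  # disjoint allele ranges
  al <- cbind(L1 = base[cls] + sample(0:2, n, TRUE),
              L2 = base[cls] + sample(0:2, n, TRUE),
              L3 = 10, DYS385a = 11, DYS385b = 14)
  ds <- quickDataset(al, haplogroup = cls)
  cv <- crossValidate(ds, level = 1, k = 5, seed = 3)
  expect_equal(cv$accuracy, 1)
  expect_equal(unname(cv$recall), rep(1, 3))

  # shuffled labels: accuracy within binomial noise of the majority share
  shuf <- ds
  set.seed(14)
  shuf@info$haplogroup <- sample(cls)
  cvs <- crossValidate(shuf, level = 1, k = 5, seed = 3)
  noise <- 3 * sqrt(cvs$baseline * (1 - cvs$baseline) / n)
  expect_lt(cvs$accuracy, cvs$baseline + noise + 0.15)

  expect_error(crossValidate(quickDataset(al, haplogroup = "O2")),
               "2 usable classes")
})

test_that("profiles survive the TSV round trip", {
  set.seed(4)
  ds <- randomTinyDataset(40)
  prof <- trainPredictor(ds, level = 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeProfile(prof, tf)
  prof2 <- readProfile(tf)
  expect_equal(prof2@priors, prof@priors)
  expect_equal(prof2@tables, prof@tables)
  h <- c(L1 = 12, L2 = 11)
  expect_equal(predictHaplogroup(h, prof2)$posterior,
               predictHaplogroup(h, prof)$posterior)
})
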