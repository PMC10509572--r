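test_that("haplotype tables read back what was written, with combinations order-free", {
  ds <- randomTinyDataset(30)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeHaplotypeTable(ds, tf)
  ds2 <- readHaplotypeTable(tf, panel = tinyPanel())
  expect_identical(haplotypeKeys(ds), haplotypeKeys(ds2))
  expect_identical(sampleInfo(ds)$haplogroup, sampleInfo(ds2)$haplogroup)
  expect_identical(sampleInfo(ds)$population, sampleInfo(ds2)$population)

  # a hand-written table: multi-copy order must not matter
  lines <- c(
    "sample_id\tpopulation\tethnicity\tlatitude\tlongitude\thaplogroup\tL1\tL2\tL3\tDYS385",
    "S1\tHan\tHan\t34.0\t113.0\tO2a2b1a1a1-F438\t12\t11\t10\t11-14",
    "S2\tHan\tHan\t34.0\t113.0\tO2a2b1a1a1-F438\t12\t11\t10\t14-11")
  tf2 <- withr::local_tempfile(lines = lines, fileext = ".tsv")
  ds3 <- readHaplotypeTable(tf2, panel = tinyPanel())
  k <- haplotypeKeys(ds3)
  expect_identical(k[1L], k[2L])
  expect_equal(unname(alleleMatrix(ds3)[1L, c("DYS385a", "DYS385b")]),
               c(11, 14))
})

test_that("DYS389b derivation follows DYS389II - DYS389I and rejects impossible rows", {
  expect_equal(deriveDYS389b(13, 29), 16)
  expect_equal(deriveDYS389b(13, 28), 15)
  expect_error(deriveDYS389b(13, 12), "derivation")
  expect_true(is.na(deriveDYS389b(NA, 29)))

  # a full-panel table with DYS389II instead of DYS389b
  panel <- defaultPanel()
  sim <- simulateDataset(local({
    cfg <- defaultSimConfig()
    cfg$populations <- cfg$populations[1L, ]
    cfg$populations$size <- 5L
    cfg
  }), seed = 3L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeHaplotypeTable(sim$dataset, tf)
  tab <- utils::read.delim(tf, check.names = FALSE,
                           colClasses = "character")
  tab$DYS389II <- as.character(as.numeric(tab$DYS389I) +
                                 as.numeric(tab$DYS389b))
  tab$DYS389b <- NULL
  writeLines(c(paste(names(tab), collapse = "\t"),
               apply(tab, 1L, paste, collapse = "\t")), tf)
  ds <- readHaplotypeTable(tf, panel)
  expect_equal(alleleMatrix(ds)[, "DYS389b"],
               alleleMatrix(sim$dataset)[, "DYS389b"])

  # DYS389II < DYS389I cannot yield a repeat count: row rejected, not kept
  tab$DYS389II[2L] <- "5"
  writeLines(c(paste(names(tab), collapse = "\t"),
               apply(tab, 1L, paste, collapse = "\t")), tf)
  expect_warning(ds2 <- readHaplotypeTable(tf, panel), "rejected")
  expect_equal(nSamples(ds2), 4L)
  expect_match(attr(ds2, "rejected"), "line 3")
})

test_that("format errors are reported by name, bad rows by line", {
  lines <- c(
    "sample_id\tpopulation\tethnicity\tlatitude\tlongitude\thaplogroup\tL1\tL2\tL3\tDYS385",
    "S1\tHan\tHan\t34\t113\tO2\t12\t11\t10\t11-14")
  noL2 <- sub("\tL2", "\tLX", lines)
  tf <- withr::local_tempfile(lines = noL2)
  expect_error(readHaplotypeTable(tf, tinyPanel()), "L2")

  dup <- c(lines, sub("^S1", "S1", lines[2L]))
  tf2 <- withr::local_tempfile(lines = dup)
  expect_error(readHaplotypeTable(tf2, tinyPanel()), "duplicate sample_id")

  badTok <- c(lines, "S2\tHan\tHan\t34\t113\tO2\t1x\t11\t10\t11-14")
  tf3 <- withr::local_tempfile(lines = badTok)
  expect_warning(ds <- readHaplotypeTable(tf3, tinyPanel()), "rejected")
  expect_equal(nSamples(ds), 1L)
  expect_match(attr(ds, "rejected"), "1x")
})

test_that("validateDataset reports completeness, range, coordinate and parse failures", {
  al <- cbind(L1 = c(12, 12, 12), L2 = c(11, NA, 11), L3 = c(10, 10, 95),
              DYS385a = 11, DYS385b = 14)
  ds <- quickDataset(al, haplogroup = c("O2", "2X", "C2a1a3"),
                     lat = c(30, 30, 95))
  rep_ <- validateDataset(ds)
  expect_setequal(unique(rep_$check),
                  c("completeness", "allele_range", "coordinate_range",
                    "haplogroup_parse"))
  expect_true(any(rep_$check == "completeness" & rep_$sample_id == "s002" &
                    rep_$detail == "L2"))
  expect_true(any(rep_$check == "coordinate_range" & rep_$sample_id == "s003"))

  ok <- randomTinyDataset(5)
  expect_equal(nrow(validateDataset(ok)), 0L)
})

test_that("the default panel has the study arithmetic: 27 STRs, 23 single-copy, 14 slow", {
  p <- defaultPanel()
  expect_equal(sum(p@loci$copy_number), 27)
  expect_length(singleCopyLoci(p), 23L)
  expect_length(slowLoci(p), 14L)
  expect_setequal(slowLoci(p),
                  c("DYS389I", "DYS389b", "DYS390", "DYS391", "DYS392",
                    "DYS393", "DYS437", "DYS438", "DYS439", "DYS448",
                    "DYS456", "DYS458", "DYS635", "YGATAH4"))
  expect_false(any(c("DYS385", "DYF387S1") %in% singleCopyLoci(p)))
  # panels survive a file round trip
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLocusPanel(p, tf)
  p2 <- readLocusPanel(tf)
  expect_equal(p2@loci$mutation_rate, p@loci$mutation_rate)
  expect_equal(p2@loci$is_single_copy, p@loci$is_single_copy)
})
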