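#' Construct a Y-STR dataset
#'
#' Low-level constructor; most users will get datasets from
#' [readHaplotypeTable()] or [simulateDataset()]. Multi-copy allele columns
#' are sorted into canonical (ascending) order here, so the unordered
#' combination convention holds by construction.
#'
#' @param info sample metadata data.frame (\code{sample_id},
#'   \code{population}, \code{ethnicity}, \code{latitude}, \code{longitude},
#'   \code{haplogroup}).
#' @param alleles numeric allele matrix with columns [alleleColumns] of the
#'   panel.
#' @param panel a [LocusPanel-class].
#' @return a [YStrDataset-class].
#' @export
YStrDataset <- function(info, alleles, panel = defaultPanel()) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "double"
  alleles <- alleles[, alleleColumns(panel), drop = FALSE]
  for (loc in panel@loci$locus[panel@loci$copy_number == 2L]) {
    cols <- paste0(loc, c("a", "b"))
    pair <- alleles[, cols, drop = FALSE]
    alleles[, cols] <- t(apply(pair, 1L, sort, na.last = TRUE))
  }
  rownames(alleles) <- info$sample_id
  new("YStrDataset", panel = panel, info = info, alleles = alleles)
}

#' @describeIn YStrDataset number of samples.
#' @param ds a [YStrDataset-class].
#' @export
nSamples <- function(ds) nrow(ds@info)

#' Sample metadata of a dataset
#' @param ds a [YStrDataset-class].
#' @export
sampleInfo <- function(ds) ds@info

#' Allele matrix of a dataset
#' @param ds a [YStrDataset-class].
#' @param loci optional loci to restrict to (columns of multi-copy loci are
#'   expanded).
#' @export
alleleMatrix <- function(ds, loci = NULL) {
  if (is.null(loci)) return(ds@alleles)
  cols <- unlist(lapply(loci, locusColumns, panel = ds@panel))
  ds@alleles[, cols, drop = FALSE]
}

#' Panel of a dataset
#' @param ds a [YStrDataset-class].
#' @export
panelOf <- function(ds) ds@panel

#' Population labels of a dataset
#' @param ds a [YStrDataset-class].
#' @export
populations <- function(ds) unique(ds@info$population)

#' Subset a dataset by sample index, population or haplogroup clade
#'
#' @param ds a [YStrDataset-class].
#' @param i integer or logical sample index.
#' @export
subsetSamples <- function(ds, i) {
  new("YStrDataset", panel = ds@panel,
      info = ds@info[i, , drop = FALSE],
      alleles = ds@alleles[i, , drop = FALSE])
}

#' @rdname subsetSamples
#' @param population population label(s) to keep.
#' @export
subsetByPopulation <- function(ds, population)
  subsetSamples(ds, ds@info$population %in% population)

#' @rdname subsetSamples
#' @param clade haplogroup name; samples whose (parsed) haplogroup collapses
#'   into this clade are kept.
#' @export
subsetByClade <- function(ds, clade) {
  cl <- parseHaplogroup(clade)
  lvl <- length(cl$path)
  keep <- vapply(ds@info$haplogroup, function(h) {
    p <- tryCatch(parseHaplogroup(h), error = function(e) NULL)
    if (is.null(p)) return(FALSE)
    renderHaplogroup(collapseHaplogroup(p, lvl), snp = FALSE, star = FALSE) ==
      renderHaplogroup(cl, snp = FALSE, star = FALSE)
  }, logical(1L), USE.NAMES = FALSE)
  subsetSamples(ds, keep)
}

#' Haplotype identity keys
#'
#' One string per sample identifying its haplotype over the chosen loci,
#' with multi-copy loci contributing their sorted allele combination.
#' Samples missing any used allele get \code{NA} and are excluded from
#' haplotype-based statistics.
#'
#' @param ds a [YStrDataset-class].
#' @param loci loci to include (default: all panel loci).
#' @return character vector, \code{NA} where alleles are missing.
#' @export
haplotypeKeys <- function(ds, loci = NULL) {
  m <- alleleMatrix(ds, loci)
  key <- apply(m, 1L, function(x) paste(fmtAllele(x), collapse = "|"))
  key[rowSums(is.na(m)) > 0] <- NA_character_
  unname(key)
}

#' Derive DYS389b from DYS389I and DYS389II
#'
#' DYS389II amplicons contain the DYS389I repeat stretch, so the b segment
#' is obtained by subtraction: DYS389b = DYS389II - DYS389I.
#'
#' @param dys389I,dys389II numeric allele values (vectors allowed).
#' @return DYS389b repeat counts; \code{NA} where either input is missing.
#' @export
deriveDYS389b <- function(dys389I, dys389II) {
  out <- dys389II - dys389I
  bad <- !is.na(out) & out <= 0
  if (any(bad))
    stop("DYS389b derivation failed: DYS389II <= DYS389I for ",
         sum(bad), " sample(s)")
  out
}

# Parse one allele cell into a numeric vector of length copy_number.
# Accepts integers, decimal intermediates (17.2) and "-"-joined multi-copy
# combinations; empty/NA cells give NA.
parseAlleleToken <- function(token, copies) {
  if (is.na(token) || !nzchar(trimws(token)))
    return(rep(NA_real_, copies))
  parts <- strsplit(trimws(token), "-", fixed = TRUE)[[1L]]
  if (length(parts) != copies)
    stop(sprintf("expected %d allele(s), got '%s'", copies, token))
  if (!all(grepl("^[0-9]+(\\.[0-9])?$", parts)))
    stop(sprintf("unparseable allele token '%s'", token))
  sort(as.numeric(parts))
}

#' Read a per-male haplotype table
#'
#' Reads a tab- or comma-separated table with a header row containing the
#' metadata columns (\code{sample_id}, \code{population}, \code{ethnicity},
#' \code{latitude}, \code{longitude}, \code{haplogroup}) and one column per
#' panel locus. Multi-copy alleles are "-"-joined combinations (e.g.
#' \code{11-14}; order is irrelevant). If a \code{DYS389b} column is absent
#' but \code{DYS389II} is present, DYS389b is derived. Rows that fail
#' validation are dropped with line-numbered diagnostics (returned in the
#' \code{"rejected"} attribute and reported as a warning).
#'
#' @param path file path.
#' @param panel a [LocusPanel-class].
#' @return a [YStrDataset-class].
#' @export
readHaplotypeTable <- function(path, panel = defaultPanel()) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  meta <- c("sample_id", "population", "ethnicity", "latitude", "longitude",
            "haplogroup")
  miss <- setdiff(meta, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  loci <- lociNames(panel)
  present <- loci %in% names(df)
  if (!present[match("DYS389b", loci)] && "DYS389II" %in% names(df) &&
      "DYS389I" %in% names(df))
    present[match("DYS389b", loci)] <- TRUE  # derivable
  if (!all(present))
    stop("missing locus column(s): ",
         paste(loci[!present], collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))

  cols <- alleleColumns(panel)
  al <- matrix(NA_real_, nrow(df), length(cols),
               dimnames = list(NULL, cols))
  rejected <- character()
  keep <- rep(TRUE, nrow(df))
  for (r in seq_len(nrow(df))) {
    line <- r + 1L  # header is line 1
    err <- tryCatch({
      for (i in seq_len(nrow(panel@loci))) {
        loc <- panel@loci$locus[i]
        copies <- panel@loci$copy_number[i]
        if (loc == "DYS389b" && !"DYS389b" %in% names(df)) {
          v1 <- parseAlleleToken(df$DYS389I[r], 1L)
          v2 <- parseAlleleToken(df$DYS389II[r], 1L)
          al[r, "DYS389b"] <- deriveDYS389b(v1, v2)
        } else {
          al[r, locusColumns(panel, loc)] <-
            parseAlleleToken(df[[loc]][r], copies)
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(err)) {
      rejected <- c(rejected, sprintf("line %d (%s): %s", line,
                                      df$sample_id[r], err))
      keep[r] <- FALSE
    }
  }
  info <- data.frame(sample_id = df$sample_id,
                     population = df$population,
                     ethnicity = df$ethnicity,
                     latitude = as.numeric(df$latitude),
                     longitude = as.numeric(df$longitude),
                     haplogroup = df$haplogroup,
                     stringsAsFactors = FALSE)
  ds <- YStrDataset(info[keep, , drop = FALSE], al[keep, , drop = FALSE],
                    panel)
  if (length(rejected)) {
    warning(length(rejected), " row(s) rejected; see attr(., 'rejected')")
    attr(ds, "rejected") <- rejected
  }
  ds
}

#' Write a dataset as a haplotype TSV
#'
#' Inverse of [readHaplotypeTable()]: metadata columns followed by one
#' column per locus, multi-copy combinations joined by "-".
#'
#' @param ds a [YStrDataset-class].
#' @param path output file.
#' @export
writeHaplotypeTable <- function(ds, path) {
  fmt <- function(x) ifelse(is.na(x), "", sub("\\.0$", "",
                                              format(x, trim = TRUE)))
  out <- ds@info
  for (i in seq_len(nrow(ds@panel@loci))) {
    loc <- ds@panel@loci$locus[i]
    cols <- locusColumns(ds@panel, loc)
    m <- ds@alleles[, cols, drop = FALSE]
    out[[loc]] <- apply(m, 1L, function(x) {
      if (anyNA(x)) "" else paste(fmt(x), collapse = "-")
    })
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a dataset
#'
#' Runs the standard battery of structural checks: locus completeness,
#' allele ranges, copy-number conformity, coordinate ranges, and haplogroup
#' parseability. Failures are collected into a report, not raised.
#'
#' @param ds a [YStrDataset-class].
#' @return data.frame with columns \code{check}, \code{sample_id},
#'   \code{detail}; zero rows when everything passes. The \code{"n_checked"}
#'   attribute carries the sample count.
#' @export
validateDataset <- function(ds) {
  rep_ <- list()
  add <- function(check, id, detail)
    rep_[[length(rep_) + 1L]] <<- data.frame(check = check, sample_id = id,
                                             detail = detail)
  al <- ds@alleles
  info <- ds@info
  for (loc in lociNames(ds@panel)) {
    m <- al[, locusColumns(ds@panel, loc), drop = FALSE]
    bad <- which(rowSums(is.na(m)) > 0)
    for (r in bad) add("completeness", info$sample_id[r], loc)
  }
  frac <- round((al - floor(al)) * 10)
  oob <- which(!is.na(al) &
                 (al < 5 | al > 60 | !(frac %in% c(0, 1, 2, 3))),
               arr.ind = TRUE)
  if (nrow(oob))
    for (k in seq_len(nrow(oob)))
      add("allele_range", info$sample_id[oob[k, 1L]],
          sprintf("%s=%s", colnames(al)[oob[k, 2L]], al[oob[k, 1L], oob[k, 2L]]))
  bad <- which(is.na(info$latitude) | abs(info$latitude) > 90 |
               is.na(info$longitude) | abs(info$longitude) > 180)
  for (r in bad) add("coordinate_range", info$sample_id[r],
                     sprintf("lat=%s lon=%s", info$latitude[r],
                             info$longitude[r]))
  for (r in seq_len(nrow(info))) {
    ok <- tryCatch({ parseHaplogroup(info$haplogroup[r]); TRUE },
                   error = function(e) FALSE)
    if (!ok) add("haplogroup_parse", info$sample_id[r], info$haplogroup[r])
  }
  out <- if (length(rep_)) do.call(rbind, rep_) else
    data.frame(check = character(), sample_id = character(),
               detail = character())
  attr(out, "n_checked") <- nrow(info)
  out
}

#' @export
setMethod("show", "YStrDataset", function(object) {
  info <- object@info
  cat(sprintf("YStrDataset: %d samples, %d populations, panel '%s'\n",
              nrow(info), length(unique(info$population)),
              object@panel@name))
  tab <- sort(table(info$ethnicity), decreasing = TRUE)
  cat("  ethnicities:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- sum(is.na(object@alleles))
  if (miss) cat("  missing allele calls:", miss, "\n")
})
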