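#' Frequency spectrum by direct counting
#'
#' Counts categories in a dataset: whole 27-STR haplotypes, haplogroups at
#' a collapse level, or alleles at one locus (multi-copy loci contribute
#' their sorted allele combination as the category). Samples missing the
#' required information are excluded from the spectrum only; the number
#' excluded is recorded in the \code{"n_excluded"} attribute.
#'
#' @param ds a [YStrDataset-class].
#' @param key \code{"haplotype"}, \code{"haplogroup"} or \code{"allele"}.
#' @param level collapse level for the haplogroup key (\code{NULL} =
#'   terminal calls as given).
#' @param locus locus name for the allele key.
#' @return a [FrequencySpectrum-class].
#' @export
frequencySpectrum <- function(ds, key = c("haplotype", "haplogroup",
                                          "allele"),
                              level = NULL, locus = NULL) {
  key <- match.arg(key)
  cats <- switch(key,
    haplotype = haplotypeKeys(ds),
    haplogroup = {
      vapply(ds@info$haplogroup, function(h) {
        tryCatch({
          p <- parseHaplogroup(h)
          if (!is.null(level)) p <- collapseHaplogroup(p, level)
          renderHaplogroup(p, snp = FALSE)
        }, error = function(e) NA_character_)
      }, character(1L), USE.NAMES = FALSE)
    },
    allele = {
      if (is.null(locus)) stop("allele key needs a locus")
      m <- alleleMatrix(ds, locus)
      k <- apply(m, 1L, function(x) paste(fmtAllele(x), collapse = "-"))
      k[rowSums(is.na(m)) > 0] <- NA_character_
      unname(k)
    })
  keep <- !is.na(cats)
  if (!any(keep)) stop("empty dataset after missing-data exclusion")
  tab <- table(cats[keep])
  out <- new("FrequencySpectrum",
             counts = stats::setNames(as.numeric(tab), names(tab)),
             n = sum(keep),
             kind = if (key == "allele") "allele" else key)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Category frequencies of a spectrum
#' @param spec a [FrequencySpectrum-class].
#' @export
frequencies <- function(spec) spec@counts / spec@n

#' Sample-size corrected diversity
#'
#' The forensic gene/haplotype/haplogroup diversity
#' \deqn{h = n (1 - \sum_i p_i^2) / (n - 1)}
#' where \eqn{p_i} are category frequencies and \eqn{n} the sample size.
#' Equals 0 for a monomorphic sample and exactly 1 when all \eqn{n}
#' categories are singletons.
#'
#' @param spec a [FrequencySpectrum-class] (n >= 2 required).
#' @return diversity value in \[0, 1\], with attributes \code{n},
#'   \code{sumPiSq} and \code{kind}.
#' @export
diversityIndex <- function(spec) {
  n <- spec@n
  if (n < 2) stop("diversity undefined for n < 2")
  s <- sum((spec@counts / n)^2)
  structure(n * (1 - s) / (n - 1), n = n, sumPiSq = s, kind = spec@kind)
}

#' Discrimination capacity
#'
#' DC = number of observed haplotypes / number of samples; only defined for
#' haplotype spectra.
#'
#' @param spec a haplotype [FrequencySpectrum-class].
#' @export
discriminationCapacity <- function(spec) {
  if (spec@kind != "haplotype")
    stop("discrimination capacity is defined on haplotype spectra")
  length(spec@counts) / spec@n
}

#' Match probability
#'
#' MP = sum of squared category frequencies: the chance that two randomly
#' chosen males share a haplotype.
#'
#' @param spec a [FrequencySpectrum-class].
#' @export
matchProbability <- function(spec) sum(frequencies(spec)^2)

#' Per-locus gene diversity
#'
#' Gene diversity for every panel locus; for the duplicated DYS385 and
#' DYF387S1 the unordered allele combination is the counted unit, in line
#' with their treatment as allelic combinations throughout.
#'
#' @param ds a [YStrDataset-class].
#' @return data.frame with columns \code{locus}, \code{n}, \code{gd}.
#' @export
perLocusGeneDiversity <- function(ds) {
  loci <- lociNames(ds@panel)
  rows <- lapply(loci, function(loc) {
    spec <- tryCatch(frequencySpectrum(ds, "allele", locus = loc),
                     error = function(e) NULL)
    if (is.null(spec) || spec@n < 2)
      return(data.frame(locus = loc, n = if (is.null(spec)) 0L else spec@n,
                        gd = NA_real_))
    data.frame(locus = loc, n = spec@n, gd = as.numeric(diversityIndex(spec)))
  })
  do.call(rbind, rows)
}

#' @export
setMethod("show", "FrequencySpectrum", function(object) {
  cat(sprintf("FrequencySpectrum (%s): %d categories, n = %d\n",
              object@kind, length(object@counts), as.integer(object@n)))
  top <- sort(frequencies(object), decreasing = TRUE)
  top <- utils::head(top, 5L)
  cat("  top:", paste(sprintf("%s %.3f", names(top), top), collapse = ", "),
      "\n")
})

#' Per-population summary of the forensic statistics
#'
#' Convenience wrapper computing haplotype diversity, discrimination
#' capacity, match probability, haplotype count and (terminal-level)
#' haplogroup diversity for each population or ethnicity.
#'
#' @param ds a [YStrDataset-class].
#' @param by group by \code{"population"} or \code{"ethnicity"}.
#' @return data.frame, one row per group.
#' @export
forensicSummary <- function(ds, by = c("ethnicity", "population")) {
  by <- match.arg(by)
  groups <- unique(ds@info[[by]])
  rows <- lapply(groups, function(g) {
    sub <- subsetSamples(ds, ds@info[[by]] == g)
    hs <- frequencySpectrum(sub, "haplotype")
    gs <- frequencySpectrum(sub, "haplogroup")
    data.frame(group = g, n = nSamples(sub),
               n_haplotypes = length(hs@counts),
               hd = as.numeric(diversityIndex(hs)),
               dc = discriminationCapacity(hs),
               mp = matchProbability(hs),
               haplogroup_diversity = as.numeric(diversityIndex(gs)))
  })
  do.call(rbind, rows)
}
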