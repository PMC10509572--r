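#' Construct a locus panel
#'
#' @param loci data.frame with columns \code{locus}, \code{copy_number},
#'   \code{mutation_rate}, and optionally \code{network_weight},
#'   \code{is_slow}, \code{is_single_copy}. Missing optional columns are
#'   filled: weights by quintile-binning of mutation rates (slowest bin 5,
#'   fastest 1), \code{is_single_copy} from copy number and the DYS385 /
#'   DYF387S1 rule, \code{is_slow} defaults to FALSE.
#' @param name panel label.
#' @return a [LocusPanel-class].
#' @export
LocusPanel <- function(loci, name = "custom") {
  loci <- as.data.frame(loci)
  if (is.null(loci$network_weight))
    loci$network_weight <- weightsFromRates(loci$mutation_rate)
  if (is.null(loci$is_slow)) loci$is_slow <- FALSE
  loci$copy_number <- as.integer(loci$copy_number)
  loci$is_single_copy <- loci$copy_number == 1L &
    !(loci$locus %in% c("DYS385", "DYF387S1"))
  new("LocusPanel", name = name, loci = loci)
}

#' Map mutation rates to median-joining network weights
#'
#' STR network weights run from 1 to 5 according to mutation rate: loci are
#' ranked and binned into quintiles, the slowest bin getting weight 5 and
#' the fastest weight 1, so slow loci dominate the network topology.
#'
#' @param rates per-generation mutation rates.
#' @return integer weights in 1..5.
#' @export
weightsFromRates <- function(rates) {
  r <- rank(rates, ties.method = "first")
  bin <- ceiling(r / length(rates) * 5)
  as.integer(6L - bin)
}

#' The default 27 Y-STR panel
#'
#' Covers 27 Y-STRs as 25 loci: 23 single-copy loci plus the two-copy
#' DYS385 and DYF387S1, whose alleles are treated as unordered combinations.
#' DYS389b (= DYS389II - DYS389I) stands in for DYS389II. The 14-locus
#' slowly-mutating subset (DYS389I, DYS389b, DYS390, DYS391, DYS392,
#' DYS393, DYS437, DYS438, DYS439, DYS448, DYS456, DYS458, DYS635, YGATAH4)
#' is flagged for TMRCA work. Mutation rates are package defaults of
#' YHRD-like magnitude, not measured data; override via [readLocusPanel()]
#' or [LocusPanel()] when locus-specific estimates matter.
#'
#' @return a [LocusPanel-class] with 25 loci (27 STRs).
#' @export
defaultPanel <- function() {
  slow <- c(DYS389I = 0.0025, DYS389b = 0.0028, DYS390 = 0.0021,
            DYS391 = 0.0026, DYS392 = 0.0005, DYS393 = 0.0011,
            DYS437 = 0.0011, DYS438 = 0.0004, DYS439 = 0.0050,
            DYS448 = 0.0018, DYS456 = 0.0042, DYS458 = 0.0064,
            DYS635 = 0.0037, YGATAH4 = 0.0028)
  fast <- c(DYS19 = 0.0021, DYS449 = 0.0122, DYS460 = 0.0057,
            DYS481 = 0.0050, DYS518 = 0.0184, DYS533 = 0.0041,
            DYS570 = 0.0124, DYS576 = 0.0143, DYS627 = 0.0123)
  multi <- c(DYS385 = 0.0021, DYF387S1 = 0.0159)
  rates <- c(slow, fast, multi)
  loci <- data.frame(
    locus = names(rates),
    copy_number = ifelse(names(rates) %in% names(multi), 2L, 1L),
    mutation_rate = unname(rates),
    is_slow = names(rates) %in% names(slow))
  LocusPanel(loci, name = "YfilerPlus27")
}

#' Read a locus panel from TSV
#'
#' Expected columns: \code{locus}, \code{copy_number}, \code{mutation_rate},
#' optionally \code{network_weight}, \code{is_slow}.
#'
#' @param path file path.
#' @param name panel label (defaults to the file name).
#' @return a [LocusPanel-class].
#' @export
readLocusPanel <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  LocusPanel(df, name = name)
}

#' Write a locus panel to TSV
#' @param panel a [LocusPanel-class].
#' @param path output file.
#' @export
writeLocusPanel <- function(panel, path) {
  utils::write.table(panel@loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn defaultPanel locus names of a panel.
#' @param panel a [LocusPanel-class].
#' @export
lociNames <- function(panel) panel@loci$locus

#' Names of the single-copy loci (the 23-locus Fst/network set)
#' @param panel a [LocusPanel-class].
#' @export
singleCopyLoci <- function(panel) panel@loci$locus[panel@loci$is_single_copy]

#' Names of the slowly-mutating loci (the 14-locus TMRCA set)
#' @param panel a [LocusPanel-class].
#' @export
slowLoci <- function(panel) panel@loci$locus[panel@loci$is_slow]

#' Per-generation mutation rates, named by locus
#' @param panel a [LocusPanel-class].
#' @param loci optional subset of loci.
#' @export
mutationRates <- function(panel, loci = NULL) {
  r <- stats::setNames(panel@loci$mutation_rate, panel@loci$locus)
  if (!is.null(loci)) r <- r[loci]
  r
}

#' Network weights, named by locus
#' @param panel a [LocusPanel-class].
#' @export
networkWeights <- function(panel)
  stats::setNames(panel@loci$network_weight, panel@loci$locus)

# Column names of the allele matrix implied by a panel: single-copy loci by
# name, duplicated loci as <locus>a/<locus>b.
alleleColumns <- function(panel) {
  unlist(lapply(seq_len(nrow(panel@loci)), function(i) {
    loc <- panel@loci$locus[i]
    if (panel@loci$copy_number[i] == 1L) loc else paste0(loc, c("a", "b"))
  }), use.names = FALSE)
}

# Columns of the allele matrix belonging to one locus.
locusColumns <- function(panel, locus) {
  i <- match(locus, panel@loci$locus)
  if (is.na(i)) stop("unknown locus: ", locus)
  if (panel@loci$copy_number[i] == 1L) locus else paste0(locus, c("a", "b"))
}

#' @export
setMethod("show", "LocusPanel", function(object) {
  df <- object@loci
  cat(sprintf("LocusPanel '%s': %d loci (%d STRs), %d single-copy, %d slow\n",
              object@name, nrow(df), sum(df$copy_number),
              sum(df$is_single_copy), sum(df$is_slow)))
})
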