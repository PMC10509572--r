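#' @import methods
NULL

#' Y-STR locus panel
#'
#' Describes the STR loci of a typing panel: copy number (1 for single-copy
#' loci, 2 for the duplicated DYS385 and DYF387S1), per-generation mutation
#' rate, median-joining network weight, and membership in the 14-locus
#' slowly-mutating set and the 23-locus single-copy set used for Fst and
#' network analyses.
#'
#' @slot name panel label.
#' @slot loci data.frame with columns \code{locus}, \code{copy_number},
#'   \code{mutation_rate}, \code{network_weight}, \code{is_slow},
#'   \code{is_single_copy}.
#' @seealso [defaultPanel()], [readLocusPanel()]
#' @export
setClass("LocusPanel",
  representation(name = "character", loci = "data.frame"))

setValidity("LocusPanel", function(object) {
  df <- object@loci
  need <- c("locus", "copy_number", "mutation_rate", "network_weight",
            "is_slow", "is_single_copy")
  if (!all(need %in% names(df)))
    return(paste("loci table missing columns:",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  if (anyDuplicated(df$locus)) return("duplicate locus names")
  if (!all(df$copy_number %in% c(1L, 2L))) return("copy_number must be 1 or 2")
  if (!all(df$mutation_rate > 0 & df$mutation_rate < 0.1))
    return("mutation rates must lie in (0, 0.1)")
  if (!all(df$network_weight >= 1 & df$network_weight <= 99))
    return("network weights must lie in [1, 99]")
  multi <- c("DYS385", "DYF387S1")
  want_single <- df$copy_number == 1L & !(df$locus %in% multi)
  if (!identical(as.logical(df$is_single_copy), want_single))
    return("is_single_copy must hold exactly for copy-1 loci other than DYS385/DYF387S1")
  TRUE
})

#' Per-male Y-STR haplotype dataset
#'
#' The central container: one row per sampled male, carrying population,
#' ethnicity, sampling coordinates, the terminal haplogroup call, and the
#' full STR haplotype. Alleles live in a numeric matrix with one column per
#' STR copy; the two copies of a duplicated locus are stored sorted
#' ascending, so "11-14" and "14-11" are the same haplotype.
#'
#' @slot panel a [LocusPanel-class].
#' @slot info data.frame with columns \code{sample_id}, \code{population},
#'   \code{ethnicity}, \code{latitude}, \code{longitude}, \code{haplogroup}.
#' @slot alleles numeric matrix, rows = samples, columns = STR copies
#'   (duplicated loci as \code{<locus>a}, \code{<locus>b}); \code{NA} = missing.
#' @seealso [readHaplotypeTable()], [simulateDataset()]
#' @export
setClass("YStrDataset",
  representation(panel = "LocusPanel", info = "data.frame",
                 alleles = "matrix"))

setValidity("YStrDataset", function(object) {
  info <- object@info
  al <- object@alleles
  need <- c("sample_id", "population", "ethnicity", "latitude", "longitude",
            "haplogroup")
  if (!all(need %in% names(info)))
    return(paste("info missing columns:",
                 paste(setdiff(need, names(info)), collapse = ", ")))
  if (nrow(info) != nrow(al)) return("info and allele matrix row counts differ")
  if (anyDuplicated(info$sample_id)) return("duplicate sample_id")
  if (!identical(colnames(al), alleleColumns(object@panel)))
    return("allele matrix columns do not match the panel")
  # content checks (allele ranges, fractional parts, coordinate ranges) are
  # the business of validateDataset(), which reports rather than refuses
  # multi-copy columns must be stored in sorted order
  for (loc in object@panel@loci$locus[object@panel@loci$copy_number == 2L]) {
    a <- al[, paste0(loc, "a")]
    b <- al[, paste0(loc, "b")]
    if (any(!is.na(a) & !is.na(b) & a > b))
      return(sprintf("multi-copy locus %s not stored sorted", loc))
  }
  TRUE
})

#' Y-haplogroup nomenclature tree
#'
#' Rooted tree of ISOGG-style haplogroup names, each node tagged with its
#' defining SNP. Parents are implied by nomenclature (the name of a node
#' extends the name of its parent), with a synthetic root above the trunk
#' letters.
#'
#' @slot nodes data.frame with columns \code{haplogroup}, \code{parent},
#'   \code{snp}.
#' @slot root name of the synthetic root node.
#' @seealso [readHaplogroupTree()], [assignHaplogroup()]
#' @export
setClass("HaplogroupTree",
  representation(nodes = "data.frame", root = "character"))

setValidity("HaplogroupTree", function(object) {
  df <- object@nodes
  if (!all(c("haplogroup", "parent", "snp") %in% names(df)))
    return("nodes need haplogroup/parent/snp columns")
  if (anyDuplicated(df$haplogroup)) return("duplicate haplogroup names")
  sn <- df$snp[!is.na(df$snp) & nzchar(df$snp)]
  if (anyDuplicated(sn)) return("defining SNPs must be unique")
  if (!all(df$parent %in% c(object@root, df$haplogroup)))
    return("every parent must be the root or another node")
  # acyclicity: walking up from every node must reach the root
  parent <- stats::setNames(df$parent, df$haplogroup)
  for (h in df$haplogroup) {
    seen <- character(); cur <- h
    while (cur != object@root) {
      if (cur %in% seen) return("cycle in tree")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (is.null(cur)) return("dangling parent")
    }
  }
  TRUE
})

#' Frequency spectrum by direct counting
#'
#' Category counts (haplogroups at some collapse level, alleles at a locus,
#' or whole haplotypes) with the total sample size, the common input to the
#' diversity statistics.
#'
#' @slot counts named numeric vector of category counts (all >= 1).
#' @slot n total number of counted samples.
#' @slot kind one of \code{"haplogroup"}, \code{"allele"}, \code{"haplotype"}.
#' @export
setClass("FrequencySpectrum",
  representation(counts = "numeric", n = "numeric", kind = "character"))

setValidity("FrequencySpectrum", function(object) {
  if (length(object@counts) && is.null(names(object@counts)))
    return("counts must be named")
  if (any(object@counts < 1)) return("zero-count categories must be absent")
  if (!isTRUE(all.equal(sum(object@counts), object@n)))
    return("counts must sum to n")
  TRUE
})

#' Pairwise Fst matrix with permutation p-values
#'
#' @slot labels population names.
#' @slot fst symmetric matrix of AMOVA Fst estimates (diagonal 0).
#' @slot pvalues symmetric matrix of permutation p-values.
#' @slot nPermutations permutations per pair.
#' @slot mode distance mode, \code{"haplotype_identity"} or \code{"stepwise"}.
#' @export
setClass("FstResult",
  representation(labels = "character", fst = "matrix", pvalues = "matrix",
                 nPermutations = "integer", mode = "character"))

#' Interpolated haplogroup frequency surface
#'
#' Inverse-distance-weighted frequency field over a latitude/longitude
#' lattice, supported by per-population station values.
#'
#' @slot lat,lon grid cell-centre coordinates.
#' @slot values matrix of interpolated frequencies (rows = lat, cols = lon).
#' @slot stations data.frame with \code{lat}, \code{lon}, \code{frequency}.
#' @slot power IDW exponent.
#' @export
setClass("FrequencySurface",
  representation(lat = "numeric", lon = "numeric", values = "matrix",
                 stations = "data.frame", power = "numeric"))

#' Median-joining haplotype network
#'
#' Observed haplotype classes plus inferred median vectors, connected by the
#' epsilon-relaxed minimum spanning network under the weighted SNP/STR
#' distance.
#'
#' @slot characters numeric matrix, one row per node (observed classes then
#'   median vectors), one column per character (STR allele or 0/1 SNP state).
#' @slot observed logical, TRUE for observed classes.
#' @slot multiplicity per-node sample multiplicity (0 for medians).
#' @slot composition matrix node x population of sample counts.
#' @slot edges data.frame \code{from}, \code{to}, \code{length}.
#' @slot weights per-character network weights (STRs 1-5, SNPs 99).
#' @slot isSTR logical per character; FALSE marks binary SNP characters.
#' @slot epsilon relaxation parameter used.
#' @export
setClass("HaplotypeNetwork",
  representation(characters = "matrix", observed = "logical",
                 multiplicity = "numeric", composition = "matrix",
                 edges = "data.frame", weights = "numeric", isSTR = "logical",
                 epsilon = "numeric"))

setValidity("HaplotypeNetwork", function(object) {
  m <- nrow(object@characters)
  if (length(object@observed) != m || length(object@multiplicity) != m)
    return("per-node slots disagree in length")
  if (ncol(object@characters) != length(object@weights) ||
      ncol(object@characters) != length(object@isSTR))
    return("per-character slots disagree in length")
  if (nrow(object@edges) &&
      !all(c(object@edges$from, object@edges$to) %in%
           rownames(object@characters)))
    return("edge endpoints must be node ids")
  TRUE
})

#' TMRCA estimate
#'
#' Time to the most recent common ancestor in generations and years with an
#' uncertainty interval, tagged by the estimator that produced it.
#'
#' @slot method \code{"asd"}, \code{"rho"} or \code{"mcmc"}.
#' @slot generations,years point estimate.
#' @slot lower,upper interval bounds in generations.
#' @slot generationTime years per generation (default 25).
#' @slot details method-specific extras (bootstrap draws, MCMC trace, ...).
#' @export
setClass("TmrcaEstimate",
  representation(method = "character", generations = "numeric",
                 years = "numeric", lower = "numeric", upper = "numeric",
                 generationTime = "numeric", details = "list"))

setValidity("TmrcaEstimate", function(object) {
  if (object@generations < 0) return("negative TMRCA")
  if (!isTRUE(all.equal(object@years,
                        object@generations * object@generationTime)))
    return("years must equal generations * generationTime")
  if (object@lower > object@generations + 1e-9 ||
      object@upper < object@generations - 1e-9)
    return("interval must bracket the point estimate")
  TRUE
})

#' Haplogroup allele-frequency profile (naive Bayes model)
#'
#' Smoothed per-haplogroup, per-locus allele frequencies with class priors,
#' trained from single-copy STR data; the model behind
#' [predictHaplogroup()].
#'
#' @slot level haplogroup collapse level of the classes.
#' @slot pseudocount additive smoothing constant per allele category.
#' @slot priors named class prior probabilities (training proportions).
#' @slot tables list per locus: matrix class x allele category of smoothed
#'   frequencies; the last category \code{".other"} absorbs unseen alleles.
#' @slot trainingSizes named training sample counts per class.
#' @slot loci loci the profile covers.
#' @export
setClass("HaplogroupProfile",
  representation(level = "integer", pseudocount = "numeric",
                 priors = "numeric", tables = "list",
                 trainingSizes = "numeric", loci = "character"))
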