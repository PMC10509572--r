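#' STR-haplogroup association table
#'
#' For every haplogroup (at a collapse level) and single-copy locus:
#' sample count, gene diversity and the allele frequency spectrum. The
#' descriptive basis of STR-based haplogroup prediction: loci whose
#' spectra differ strongly between haplogroups carry predictive signal.
#'
#' @param ds a [YStrDataset-class] with haplogroup calls.
#' @param level haplogroup collapse level.
#' @return data.frame (haplogroup, locus, n, gd), gene diversity \code{NA}
#'   (marked) where a haplogroup has n < 2; per-cell spectra in the
#'   \code{"spectra"} attribute (named \code{<haplogroup>|<locus>}).
#' @export
associationTable <- function(ds, level = 1L) {
  grpSpec <- frequencySpectrum(ds, "haplogroup", level = level)
  classes <- names(grpSpec@counts)
  cls <- collapsedCalls(ds, level)
  loci <- singleCopyLoci(ds@panel)
  spectra <- list()
  rows <- list()
  for (h in classes) {
    sub <- subsetSamples(ds, !is.na(cls) & cls == h)
    for (loc in loci) {
      spec <- tryCatch(frequencySpectrum(sub, "allele", locus = loc),
                       error = function(e) NULL)
      gd <- if (!is.null(spec) && spec@n >= 2)
        as.numeric(diversityIndex(spec)) else NA_real_
      n <- if (is.null(spec)) 0L else as.integer(spec@n)
      rows[[length(rows) + 1L]] <-
        data.frame(haplogroup = h, locus = loc, n = n, gd = gd)
      if (!is.null(spec))
        spectra[[paste(h, loc, sep = "|")]] <- frequencies(spec)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spectra") <- spectra
  out
}

# collapsed haplogroup call per sample (NA where unparseable)
collapsedCalls <- function(ds, level) {
  vapply(ds@info$haplogroup, function(h) {
    tryCatch(renderHaplogroup(collapseHaplogroup(parseHaplogroup(h), level),
                              snp = FALSE),
             error = function(e) NA_character_)
  }, character(1L), USE.NAMES = FALSE)
}

#' Train the naive-Bayes haplogroup predictor
#'
#' A conditional-independence model over the single-copy loci: smoothed
#' per-haplogroup allele frequencies with additive (pseudocount) smoothing
#' and training-proportion class priors. Each locus table carries a final
#' \code{".other"} category holding the pure pseudocount mass, so alleles
#' unseen in training keep nonzero likelihood (with pseudocount 0 they
#' yield zero likelihood - a documented hazard).
#'
#' @param ds training [YStrDataset-class].
#' @param level haplogroup collapse level of the classes (default 1, major
#'   clades such as O1 vs O2).
#' @param pseudocount additive smoothing per allele category.
#' @param loci loci to model (default: single-copy set).
#' @return a [HaplogroupProfile-class].
#' @export
trainPredictor <- function(ds, level = 1L, pseudocount = 0.5, loci = NULL) {
  if (is.null(loci)) loci <- singleCopyLoci(ds@panel)
  cls <- collapsedCalls(ds, level)
  keep <- !is.na(cls)
  classes <- sort(unique(cls[keep]))
  if (length(classes) < 2) stop("need at least two haplogroup classes")
  m <- alleleMatrix(ds, loci)[keep, , drop = FALSE]
  cls <- cls[keep]
  sizes <- table(cls)
  tables <- lapply(loci, function(loc) {
    x <- m[, loc]
    cats <- sort(unique(x[!is.na(x)]))
    catNames <- c(fmtAllele(cats), ".other")
    tab <- matrix(0, length(classes), length(catNames),
                  dimnames = list(classes, catNames))
    for (h in classes) {
      xa <- x[cls == h & !is.na(x)]
      cnt <- c(vapply(cats, function(a) sum(xa == a), numeric(1L)), 0)
      tab[h, ] <- (cnt + pseudocount) /
        (length(xa) + pseudocount * length(catNames))
    }
    tab
  })
  names(tables) <- loci
  new("HaplogroupProfile", level = as.integer(level),
      pseudocount = pseudocount,
      priors = stats::setNames(as.numeric(sizes[classes]) / sum(sizes),
                               classes),
      tables = tables,
      trainingSizes = stats::setNames(as.numeric(sizes[classes]), classes),
      loci = loci)
}

# n x C matrix of log-posteriors (normalized) for an allele matrix
predictorLogPost <- function(m, profile) {
  classes <- names(profile@priors)
  lp <- matrix(rep(log(profile@priors), each = nrow(m)), nrow(m),
               length(classes), dimnames = list(NULL, classes))
  covered <- rep(FALSE, nrow(m))
  for (loc in profile@loci) {
    if (!loc %in% colnames(m)) next
    x <- m[, loc]
    tab <- profile@tables[[loc]]
    cat <- match(fmtAllele(x), colnames(tab))
    cat[is.na(cat) & !is.na(x)] <- ncol(tab)  # unseen -> .other
    has <- !is.na(x)
    covered <- covered | has
    idx <- which(has)
    if (length(idx))
      lp[idx, ] <- lp[idx, ] + t(log(tab[, cat[idx], drop = FALSE]))
  }
  if (any(!covered)) lp[!covered, ] <- NA_real_
  # normalize rows (log-sum-exp)
  mx <- apply(lp, 1L, max)
  lp - (mx + log(rowSums(exp(lp - mx))))
}

#' Predict the haplogroup of a Y-STR haplotype
#'
#' Posterior over haplogroup classes proportional to prior times the
#' product of smoothed allele frequencies over the covered single-copy
#' loci; missing loci are skipped, multi-copy loci are never used.
#' Computation is in log space, so 23-locus products cannot underflow.
#'
#' @param h named numeric allele vector (names = loci), or a one-row
#'   [YStrDataset-class].
#' @param profile a [HaplogroupProfile-class].
#' @return list with \code{posterior} (named, sorted decreasing),
#'   \code{winner} and \code{margin} (top minus runner-up posterior).
#' @export
predictHaplogroup <- function(h, profile) {
  if (is(h, "YStrDataset")) {
    m <- alleleMatrix(h, intersect(profile@loci, lociNames(h@panel)))
  } else {
    m <- matrix(h, 1L, dimnames = list(NULL, names(h)))
  }
  if (!any(profile@loci %in% colnames(m)))
    stop("haplotype covers no profiled locus")
  lp <- predictorLogPost(m, profile)[1L, ]
  if (anyNA(lp)) stop("haplotype covers no profiled locus")
  post <- sort(exp(lp), decreasing = TRUE)
  list(posterior = post, winner = names(post)[1L],
       margin = post[1L] - if (length(post) > 1) post[2L] else 0)
}

#' Stratified cross-validation of the haplogroup predictor
#'
#' Deterministic (seeded) stratified k-fold accuracy with per-class recall
#' and a confusion matrix. Classes with fewer than k samples are excluded
#' with a warning.
#'
#' @param ds a [YStrDataset-class].
#' @param level haplogroup collapse level.
#' @param k folds.
#' @param seed RNG seed.
#' @param pseudocount smoothing for the fold models.
#' @return list with \code{accuracy}, \code{recall}, \code{confusion},
#'   \code{baseline} (majority-class share), \code{n}.
#' @export
crossValidate <- function(ds, level = 1L, k = 5L, seed = 1L,
                          pseudocount = 0.5) {
  stopifnot(k >= 2)
  cls <- collapsedCalls(ds, level)
  keep <- !is.na(cls)
  tab <- table(cls[keep])
  usable <- names(tab)[tab >= k]
  if (length(usable) < length(tab))
    warning("class(es) with < k samples excluded: ",
            paste(setdiff(names(tab), usable), collapse = ", "))
  if (length(usable) < 2) stop("fewer than 2 usable classes")
  keep <- keep & cls %in% usable
  idx <- which(keep)
  cls <- cls[keep]
  fold <- integer(length(idx))
  withSeed(seed, for (h in usable) {
    ih <- which(cls == h)
    fold[ih] <- sample(rep_len(seq_len(k), length(ih)))
  })
  pred <- character(length(idx))
  for (f in seq_len(k)) {
    train <- subsetSamples(ds, idx[fold != f])
    prof <- trainPredictor(train, level = level, pseudocount = pseudocount)
    m <- alleleMatrix(subsetSamples(ds, idx[fold == f]), prof@loci)
    lp <- predictorLogPost(m, prof)
    pred[fold == f] <- colnames(lp)[max.col(lp, ties.method = "first")]
  }
  conf <- table(truth = cls, predicted = factor(pred,
                                                levels = sort(unique(c(pred, cls)))))
  acc <- mean(pred == cls)
  recall <- diag(conf[usable, usable, drop = FALSE]) / rowSums(conf)[usable]
  list(accuracy = acc, recall = recall, confusion = conf,
       baseline = max(tab[usable]) / sum(tab[usable]),
       n = length(idx))
}

#' Persist / load a haplogroup profile
#'
#' TSV with columns (haplogroup, locus, allele, frequency) plus a JSON
#' metadata sidecar-free header comment line carrying level, pseudocount,
#' priors and training sizes.
#'
#' @param profile a [HaplogroupProfile-class].
#' @param path output TSV path.
#' @export
writeProfile <- function(profile, path) {
  meta <- jsonlite::toJSON(list(level = profile@level,
                                pseudocount = profile@pseudocount,
                                priors = as.list(profile@priors),
                                trainingSizes = as.list(profile@trainingSizes)),
                           auto_unbox = TRUE, digits = NA)
  rows <- do.call(rbind, lapply(names(profile@tables), function(loc) {
    tab <- profile@tables[[loc]]
    data.frame(haplogroup = rep(rownames(tab), ncol(tab)),
               locus = loc,
               allele = rep(colnames(tab), each = nrow(tab)),
               frequency = as.vector(tab))
  }))
  con <- file(path, "w")
  writeLines(paste0("# ", meta), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeProfile
#' @param path TSV path written by [writeProfile()].
#' @export
readProfile <- function(path) {
  meta <- jsonlite::fromJSON(sub("^# ", "", readLines(path, n = 1L)))
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                          colClasses = c(allele = "character"))
  loci <- unique(df$locus)
  tables <- lapply(loci, function(loc) {
    d <- df[df$locus == loc, ]
    cats <- unique(d$allele)
    classes <- unique(d$haplogroup)
    tab <- matrix(d$frequency, length(classes), length(cats),
                  dimnames = list(classes, cats))
    tab
  })
  names(tables) <- loci
  new("HaplogroupProfile", level = as.integer(meta$level),
      pseudocount = meta$pseudocount,
      priors = unlist(meta$priors),
      tables = tables,
      trainingSizes = unlist(meta$trainingSizes),
      loci = loci)
}

#' @export
setMethod("show", "HaplogroupProfile", function(object) {
  cat(sprintf(
    "HaplogroupProfile: %d classes at level %d, %d loci (pseudocount %g)\n",
    length(object@priors), object@level, length(object@loci),
    object@pseudocount))
  cat("  classes:", paste(names(object@priors), collapse = ", "), "\n")
})
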