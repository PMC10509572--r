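#' Pairwise AMOVA Fst between populations
#'
#' Fst (Phi-ST) from one-level AMOVA variance components on inter-haplotype
#' distances over the single-copy loci, with significance by permutation of
#' individuals across each population pair. Two distance modes are
#' provided, since the classical software leaves the choice implicit:
#' \code{"haplotype_identity"} scores haplotype pairs 0/1 (different
#' haplotypes are equidistant) and \code{"stepwise"} uses the summed squared
#' repeat-count difference (Rst-like). Samples missing any single-copy
#' allele are excluded. P-values use the (b+1)/(m+1) estimator, so they
#' never reach zero.
#'
#' @param ds a [YStrDataset-class] with >= 2 populations.
#' @param mode distance mode.
#' @param nPermutations permutations per pair.
#' @param seed RNG seed (permutations are deterministic given it).
#' @param by group by \code{"population"} or \code{"ethnicity"}.
#' @return an [FstResult-class]. Pairs involving a population with fewer
#'   than 2 usable samples are \code{NA} (with a warning).
#' @export
pairwiseFst <- function(ds, mode = c("haplotype_identity", "stepwise"),
                        nPermutations = 10000L, seed = 1L,
                        by = c("population", "ethnicity")) {
  mode <- match.arg(mode)
  by <- match.arg(by)
  loci <- singleCopyLoci(ds@panel)
  if (!length(loci)) stop("no shared single-copy loci")
  m <- alleleMatrix(ds, loci)
  keep <- rowSums(is.na(m)) == 0
  m <- m[keep, , drop = FALSE]
  grp <- ds@info[[by]][keep]
  labels <- unique(ds@info[[by]])
  P <- length(labels)
  if (P < 2) stop("need at least two populations")
  fst <- matrix(0, P, P, dimnames = list(labels, labels))
  pv <- matrix(NA_real_, P, P, dimnames = list(labels, labels))
  diag(pv) <- 1
  sizes <- table(factor(grp, levels = labels))
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("population(s) with < 2 samples skipped: ",
            paste(small, collapse = ", "))
  withSeed(seed, for (i in seq_len(P - 1L)) for (j in seq((i + 1L), P)) {
    a <- labels[i]; b <- labels[j]
    if (sizes[[a]] < 2 || sizes[[b]] < 2) { fst[i, j] <- fst[j, i] <- NA; next }
    idx <- grp %in% c(a, b)
    res <- amovaPair(m[idx, , drop = FALSE], grp[idx] == a, mode,
                     nPermutations)
    fst[i, j] <- fst[j, i] <- res$fst
    pv[i, j] <- pv[j, i] <- res$p
  })
  new("FstResult", labels = labels, fst = fst, pvalues = pv,
      nPermutations = as.integer(nPermutations), mode = mode)
}

# Squared inter-individual distance matrix for AMOVA.
amovaDistances <- function(m, mode) {
  if (mode == "stepwise") {
    as.matrix(stats::dist(m))^2
  } else {
    key <- apply(m, 1L, paste, collapse = "|")
    outer(key, key, Negate(`==`)) * 1
  }
}

# One-level AMOVA Phi-ST for a 2-population split given group indicator,
# plus a permutation p-value. Permutations are evaluated through one BLAS
# product (quadratic forms v'Dv for all permutation indicators at once),
# which keeps full-size population pairs tractable.
amovaPair <- function(m, inA, mode, nPermutations) {
  D <- amovaDistances(m, mode)
  n <- nrow(D)
  nA <- sum(inA)
  tot <- sum(D)
  r <- rowSums(D)
  phi2 <- function(sAA, sBB) {
    nB <- n - nA
    ssTotal <- tot / (2 * n)
    ssWithin <- sAA / (2 * nA) + sBB / (2 * nB)
    ssAmong <- ssTotal - ssWithin
    sigmaW <- ssWithin / (n - 2)
    n0 <- n - (nA^2 + nB^2) / n  # df_among = 1 for a pair
    sigmaA <- (ssAmong - sigmaW) / n0
    denom <- sigmaA + sigmaW
    ifelse(denom <= 0, 0, sigmaA / denom)
  }
  v <- as.numeric(inA)
  sAA <- drop(v %*% D %*% v)
  sBB <- tot - 2 * sum(v * r) + sAA
  obs <- phi2(sAA, sBB)
  if (nPermutations < 1L) return(list(fst = obs, p = NA_real_))
  V <- matrix(0, n, nPermutations)
  for (k in seq_len(nPermutations)) V[sample.int(n, nA), k] <- 1
  DV <- D %*% V
  sAAp <- colSums(V * DV)
  vD1 <- drop(crossprod(V, r))
  sBBp <- tot - 2 * vD1 + sAAp
  phis <- phi2(sAAp, sBBp)
  hits <- sum(phis >= obs - 1e-12)
  list(fst = obs, p = (hits + 1) / (nPermutations + 1))
}

#' @export
setMethod("show", "FstResult", function(object) {
  cat(sprintf("FstResult (%s): %d populations, %d permutations\n",
              object@mode, length(object@labels), object@nPermutations))
  print(round(object@fst, 4))
})

#' Haplogroup frequency matrix
#'
#' Per-group haplogroup frequencies at a collapse level by direct counting;
#' the input of [pcaHaplogroupFreq()] and of frequency surfaces.
#'
#' @param ds a [YStrDataset-class].
#' @param level collapse level (0 = trunk letters).
#' @param by group by \code{"population"} or \code{"ethnicity"}.
#' @return matrix, rows = groups (each summing to 1), cols = haplogroups.
#' @export
haplogroupFrequencyMatrix <- function(ds, level = 0L,
                                      by = c("population", "ethnicity")) {
  by <- match.arg(by)
  groups <- unique(ds@info[[by]])
  specs <- lapply(groups, function(g)
    frequencySpectrum(subsetSamples(ds, ds@info[[by]] == g), "haplogroup",
                      level = level))
  cats <- sort(unique(unlist(lapply(specs, function(s) names(s@counts)))))
  fm <- matrix(0, length(groups), length(cats),
               dimnames = list(groups, cats))
  for (k in seq_along(groups)) fm[k, names(specs[[k]]@counts)] <-
    frequencies(specs[[k]])
  fm
}

#' PCA of a haplogroup frequency matrix
#'
#' Column-centred singular value decomposition (covariance PCA, no
#' correlation scaling) of population-by-haplogroup frequencies. The sign
#' of each component is fixed so its largest-magnitude loading is positive,
#' making coordinates reproducible across platforms.
#'
#' @param fm frequency matrix (rows = populations).
#' @param nComponents number of components to keep.
#' @return list with \code{coordinates} (populations x components),
#'   \code{explained} (variance fractions over the full rank) and
#'   \code{loadings}.
#' @export
pcaHaplogroupFreq <- function(fm, nComponents = 2L) {
  if (nrow(fm) < 2) stop("need at least two populations")
  if (nComponents >= min(dim(fm)) )
    nComponents <- min(dim(fm)) - 1L
  ctr <- scale(fm, center = TRUE, scale = FALSE)
  if (all(abs(ctr) < 1e-12)) {
    warning("constant frequency matrix: zero variance")
    co <- matrix(0, nrow(fm), nComponents,
                 dimnames = list(rownames(fm),
                                 paste0("PC", seq_len(nComponents))))
    return(list(coordinates = co,
                explained = rep(0, nComponents),
                loadings = matrix(0, ncol(fm), nComponents)))
  }
  pc <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    peak <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[peak, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(nComponents)
  list(coordinates = pc$x[, keep, drop = FALSE],
       explained = expl[keep],
       loadings = pc$rotation[, keep, drop = FALSE])
}

#' Per-population frequency stations for one haplogroup
#'
#' Computes, for each population, its frequency of the given clade and a
#' representative coordinate (mean of sample coordinates), producing the
#' support points of an interpolated frequency surface.
#'
#' @param ds a [YStrDataset-class].
#' @param clade haplogroup name (samples collapsing into it are counted).
#' @return data.frame with \code{population}, \code{lat}, \code{lon},
#'   \code{frequency}.
#' @export
haplogroupStations <- function(ds, clade) {
  cl <- parseHaplogroup(clade)
  lvl <- length(cl$path)
  target <- renderHaplogroup(cl, snp = FALSE, star = FALSE)
  pops <- populations(ds)
  rows <- lapply(pops, function(p) {
    sub <- subsetSamples(ds, ds@info$population == p)
    hit <- vapply(sub@info$haplogroup, function(h) {
      q <- tryCatch(parseHaplogroup(h), error = function(e) NULL)
      !is.null(q) &&
        renderHaplogroup(collapseHaplogroup(q, lvl), snp = FALSE,
                         star = FALSE) == target
    }, logical(1L), USE.NAMES = FALSE)
    data.frame(population = p,
               lat = mean(sub@info$latitude, na.rm = TRUE),
               lon = mean(sub@info$longitude, na.rm = TRUE),
               frequency = mean(hit))
  })
  do.call(rbind, rows)
}

#' Inverse-distance-weighted frequency surface
#'
#' Interpolates station frequencies onto a regular latitude/longitude
#' lattice with weights \eqn{w_i = d_i^{-power}} (distances in degree
#' space). A cell within half a cell size of a station takes the station
#' value exactly, so supports are honoured. Values are convex combinations
#' of station values and therefore bounded by their range.
#'
#' @param stations data.frame with \code{lat}, \code{lon}, \code{frequency}.
#' @param cellSize lattice spacing in degrees.
#' @param pad bounding-box padding in degrees.
#' @param power IDW exponent (> 0).
#' @return a [FrequencySurface-class].
#' @export
idwSurface <- function(stations, cellSize = 0.5, pad = 2, power = 2) {
  stopifnot(power > 0, nrow(stations) >= 1)
  key <- paste(stations$lat, stations$lon)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    vals <- stations$frequency[key %in% dup]
    if (length(unique(vals)) > 1)
      stop("duplicate station coordinates with different values")
    stations <- stations[!duplicated(key), , drop = FALSE]
  }
  lat <- seq(min(stations$lat) - pad, max(stations$lat) + pad, by = cellSize)
  lon <- seq(min(stations$lon) - pad, max(stations$lon) + pad, by = cellSize)
  vals <- matrix(NA_real_, length(lat), length(lon))
  for (i in seq_along(lat)) {
    d2 <- (stations$lat - lat[i])^2
    for (j in seq_along(lon)) {
      d <- sqrt(d2 + (stations$lon - lon[j])^2)
      near <- which.min(d)
      if (d[near] <= cellSize / 2) {
        vals[i, j] <- stations$frequency[near]
      } else {
        w <- d^(-power)
        vals[i, j] <- sum(w * stations$frequency) / sum(w)
      }
    }
  }
  new("FrequencySurface", lat = lat, lon = lon, values = vals,
      stations = as.data.frame(stations), power = power)
}

#' @export
setMethod("show", "FrequencySurface", function(object) {
  cat(sprintf(
    "FrequencySurface: %d x %d grid from %d stations (power %.1f)\n",
    length(object@lat), length(object@lon), nrow(object@stations),
    object@power))
  cat(sprintf("  value range: %.3f .. %.3f\n", min(object@values),
              max(object@values)))
})

#' Export a frequency surface as a long-format TSV
#' @param surface a [FrequencySurface-class].
#' @param path output file.
#' @export
writeSurface <- function(surface, path) {
  grid <- expand.grid(lat = surface@lat, lon = surface@lon)
  grid$value <- as.vector(surface@values)
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
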