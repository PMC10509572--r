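#' Modal (founder-proxy) haplotype
#'
#' Component-wise most frequent allele over the chosen loci, ties broken
#' toward the smaller allele: the usual founder proxy for ASD and rho
#' dating.
#'
#' @param ds a [YStrDataset-class].
#' @param loci loci to include (default: the slow single-copy set).
#' @return named numeric vector over allele columns.
#' @export
modalHaplotype <- function(ds, loci = NULL) {
  if (is.null(loci)) loci <- slowLoci(ds@panel)
  m <- alleleMatrix(ds, loci)
  out <- vapply(colnames(m), function(cn) {
    x <- m[, cn]
    x <- x[!is.na(x)]
    if (!length(x)) stop("all alleles missing at ", cn)
    xs <- sort(unique(x))
    cnt <- vapply(xs, function(a) sum(x == a), numeric(1L))
    xs[which.max(cnt)]  # which.max takes the first, i.e. smallest, on ties
  }, numeric(1L))
  out
}

#' ASD TMRCA estimate
#'
#' Average squared distance dating: per locus the mean squared allele
#' difference from the founder haplotype has expectation \eqn{\mu t} under
#' the stepwise mutation model, so \eqn{\hat t} is the mean over loci of
#' \eqn{ASD_l / \mu_l}. The interval is a seeded bootstrap over samples.
#'
#' @param ds a [YStrDataset-class] (typically one clade).
#' @param rates named per-generation mutation rates (default: panel rates).
#' @param loci loci to use (default: the 14-locus slow set).
#' @param founder founder haplotype (named numeric over allele columns);
#'   default [modalHaplotype()].
#' @param generationTime years per generation.
#' @param nBoot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return a [TmrcaEstimate-class] (method \code{"asd"}).
#' @export
asdTmrca <- function(ds, rates = NULL, loci = NULL, founder = NULL,
                     generationTime = 25, nBoot = 1000L, seed = 1L) {
  if (is.null(loci)) loci <- slowLoci(ds@panel)
  if (!length(loci)) stop("no loci")
  if (is.null(rates)) rates <- mutationRates(ds@panel)
  if (is.null(founder)) founder <- modalHaplotype(ds, loci)
  m <- alleleMatrix(ds, loci)
  founder <- founder[colnames(m)]
  if (anyNA(founder)) stop("founder undefined at some loci")
  mu <- rates[lociOfColumns(colnames(m), names(rates))]
  if (anyNA(mu)) stop("mutation rates missing for some loci")
  est <- function(idx) {
    sq <- sweep(m[idx, , drop = FALSE], 2L, founder)^2
    asd <- colMeans(sq, na.rm = TRUE)
    mean(asd / mu)
  }
  tHat <- est(seq_len(nrow(m)))
  boot <- if (nBoot >= 1)
    withSeed(seed, replicate(nBoot, est(sample.int(nrow(m),
                                                   replace = TRUE))))
  else tHat
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  new("TmrcaEstimate", method = "asd", generations = tHat,
      years = tHat * generationTime,
      lower = min(ci[1L], tHat), upper = max(ci[2L], tHat),
      generationTime = generationTime,
      details = list(bootstrap = boot, founder = founder,
                     perLocusASD = colMeans(
                       sweep(m, 2L, founder)^2, na.rm = TRUE)))
}

#' Rho TMRCA estimate
#'
#' The rho statistic: the multiplicity-weighted mean number of mutational
#' steps (unweighted character changes) separating each observed haplotype
#' class from a designated root node of the network, divided by the total
#' per-generation mutation rate of the STR characters. The interval uses
#' the sigma_rho = sqrt(rho / n) convention with n the total sample
#' multiplicity.
#'
#' @param net a [HaplotypeNetwork-class].
#' @param root node id of the root haplotype (e.g. \code{"H3"}).
#' @param rates named per-generation mutation rates covering the network's
#'   STR characters.
#' @param generationTime years per generation.
#' @return a [TmrcaEstimate-class] (method \code{"rho"}).
#' @export
rhoTmrca <- function(net, root, rates, generationTime = 25) {
  ids <- rownames(net@characters)
  if (!root %in% ids) stop("root is not a node of the network")
  g <- networkGraph(net)
  d <- igraph::distances(g, v = root,
                         weights = igraph::E(g)$steps)[1L, ids]
  obs <- net@observed
  w <- net@multiplicity[obs]
  rho <- sum(w * d[obs]) / sum(w)
  strCols <- colnames(net@characters)[net@isSTR]
  mu <- rates[lociOfColumns(strCols, names(rates))]
  if (anyNA(mu)) stop("mutation rates missing for network loci")
  totalMu <- sum(mu)
  tHat <- rho / totalMu
  sigmaRho <- sqrt(rho / sum(w))
  lo <- max(0, (rho - 1.96 * sigmaRho)) / totalMu
  hi <- (rho + 1.96 * sigmaRho) / totalMu
  new("TmrcaEstimate", method = "rho", generations = tHat,
      years = tHat * generationTime,
      lower = min(lo, tHat), upper = max(hi, tHat),
      generationTime = generationTime,
      details = list(rho = rho, sigmaRho = sigmaRho, totalRate = totalMu,
                     convention = "sigma_rho = sqrt(rho/n)"))
}

#' MCMC configuration
#'
#' Run-length, seed and prior settings for [mcmcTmrca()]. The
#' \code{"production"} preset collects two million samples after a
#' 3000-iteration burn-in; \code{"scaled_down"} (10,000 after 500) is for
#' tests and quick exploration and is labelled as such in the output.
#'
#' @param preset \code{"production"} or \code{"scaled_down"}.
#' @param nSamples,burnIn,thinning,seed run-length controls.
#' @param priorN lognormal prior on effective size:
#'   \code{c(meanlog, sdlog)}; \code{sdlog = 0} fixes N at
#'   \code{exp(meanlog)}.
#' @param priorGrowth exponential prior rate on the scaled growth
#'   \code{g = N * r}; \code{0} fixes growth at zero.
#' @param latticePad lattice bound: observed allele range plus this many
#'   repeats each side.
#' @return a list of class \code{"mcmcConfig"}.
#' @export
mcmcConfig <- function(preset = c("production", "scaled_down"),
                       nSamples = NULL, burnIn = NULL, thinning = 1L,
                       seed = 1L, priorN = c(log(1000), 1),
                       priorGrowth = 1, latticePad = 10L) {
  preset <- match.arg(preset)
  if (is.null(nSamples)) nSamples <- if (preset == "production") 2e6 else 1e4
  if (is.null(burnIn)) burnIn <- if (preset == "production") 3000 else 500
  stopifnot(burnIn < nSamples, thinning >= 1)
  structure(list(preset = preset, nSamples = as.integer(nSamples),
                 burnIn = as.integer(burnIn),
                 thinning = as.integer(thinning), seed = as.integer(seed),
                 priorN = priorN, priorGrowth = priorGrowth,
                 latticePad = as.integer(latticePad)),
            class = "mcmcConfig")
}

# phylo -> parent/child/time arrays (0-based; tips 0..n-1 in tip order)
phyloToArrays <- function(tree) {
  n <- length(tree$tip.label)
  nn <- 2L * n - 1L
  parent <- rep(-1L, nn)
  child1 <- rep(-1L, nn)
  child2 <- rep(-1L, nn)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L] - 1L
    c_ <- tree$edge[k, 2L] - 1L
    parent[c_ + 1L] <- p
    if (child1[p + 1L] == -1L) child1[p + 1L] <- c_ else child2[p + 1L] <- c_
  }
  depth <- ape::node.depth.edgelength(tree)
  tm <- max(depth) - depth
  list(parent = parent, child1 = child1, child2 = child2, time = tm,
       n = n)
}

#' Bayesian coalescent MCMC TMRCA
#'
#' Metropolis-Hastings sampling of single-population coalescent genealogies
#' with exponential growth, with the STR likelihood computed by pruning
#' under a symmetric single-step mutation model on a bounded integer allele
#' lattice. Reports the posterior median tree height and a central 95%
#' credibility interval; deterministic given the config seed. A split-half
#' comparison of the sampled heights flags non-convergence with a warning
#' (and in \code{details$converged}), never silently.
#'
#' @param ds a [YStrDataset-class] subset (>= 2 samples); samples missing
#'   any used allele are dropped.
#' @param rates named mutation rates (default: panel rates).
#' @param loci loci to use (default: the 14-locus slow set).
#' @param config an [mcmcConfig()] list.
#' @param generationTime years per generation.
#' @param useLikelihood \code{FALSE} runs the sampler against the prior
#'   alone (a correctness baseline).
#' @return a [TmrcaEstimate-class] (method \code{"mcmc"}) with the thinned
#'   trace in \code{details$trace}.
#' @export
mcmcTmrca <- function(ds, rates = NULL, loci = NULL,
                      config = mcmcConfig("scaled_down"),
                      generationTime = 25, useLikelihood = TRUE) {
  if (is.null(loci)) loci <- slowLoci(ds@panel)
  if (is.null(rates)) rates <- mutationRates(ds@panel)
  m <- alleleMatrix(ds, loci)
  keep <- rowSums(is.na(m)) == 0
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 complete samples")
  mu <- rates[lociOfColumns(colnames(m), names(rates))]
  if (anyNA(mu)) stop("mutation rates missing for some loci")

  N0 <- exp(config$priorN[1L])
  seedState <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(seedState))
    assign(".Random.seed", seedState, globalenv()))
  init <- simulateTree(n, N = N0, growth = 0)
  arr <- phyloToArrays(init)

  locusData <- lapply(seq_len(ncol(m)), function(j) {
    a <- round(m[, j])
    lo <- min(a) - config$latticePad
    hi <- max(a) + config$latticePad
    K <- hi - lo + 1L
    A <- matrix(0, K, K)
    for (i in seq_len(K)) {
      if (i > 1) A[i, i - 1L] <- 0.5
      if (i < K) A[i, i + 1L] <- 0.5
      A[i, i] <- -(as.numeric(i > 1) + as.numeric(i < K)) / 2
    }
    e <- eigen(A, symmetric = TRUE)
    list(V = e$vectors, lambda = e$values, mu = unname(mu[j]),
         tip = as.integer(a - lo))
  })

  res <- .mcmc_run(locusData, arr$parent, arr$child1, arr$child2,
                   arr$time, arr$n,
                   as.integer(config$nSamples), as.integer(config$burnIn),
                   as.integer(config$thinning),
                   config$priorN[1L], config$priorN[2L],
                   config$priorGrowth,
                   N0, 0, isTRUE(useLikelihood))
  tr <- as.data.frame(res$trace)
  h <- tr$height
  med <- stats::median(h)
  ci <- stats::quantile(h, c(0.025, 0.975), names = FALSE)

  half <- seq_len(floor(length(h) / 2))
  q <- seq(0.1, 0.9, by = 0.2)
  q1 <- stats::quantile(h[half], q)
  q2 <- stats::quantile(h[-half], q)
  iqr <- stats::IQR(h)
  converged <- iqr == 0 || max(abs(q1 - q2)) / iqr < 0.75
  if (!converged)
    warning("split-half height distributions differ; chain may not have converged")

  new("TmrcaEstimate", method = "mcmc", generations = med,
      years = med * generationTime,
      lower = min(ci[1L], med), upper = max(ci[2L], med),
      generationTime = generationTime,
      details = list(trace = tr, acceptance = res$acceptance,
                     converged = converged, config = config,
                     n = n, loci = loci,
                     scaled_down = config$preset == "scaled_down"))
}

#' Write an MCMC trace as TSV
#' @param est a [TmrcaEstimate-class] from [mcmcTmrca()].
#' @param path output file.
#' @export
writeTrace <- function(est, path) {
  tr <- est@details$trace
  if (is.null(tr)) stop("estimate carries no trace")
  tr <- cbind(iteration = seq_len(nrow(tr)), tr)
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
setMethod("show", "TmrcaEstimate", function(object) {
  cat(sprintf(
    "TmrcaEstimate (%s): %.1f generations = %.0f years (95%%: %.0f-%.0f gen; %g y/gen)\n",
    object@method, object@generations, object@years, object@lower,
    object@upper, object@generationTime))
})

#' Export a TMRCA estimate as JSON
#' @param est a [TmrcaEstimate-class].
#' @param path output file (NULL returns the JSON string).
#' @export
tmrcaJson <- function(est, path = NULL) {
  x <- list(method = est@method, generations = est@generations,
            years = est@years,
            interval_generations = c(est@lower, est@upper),
            generation_time = est@generationTime)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
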