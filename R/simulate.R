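#' Simulate a coalescent genealogy
#'
#' Haploid coalescent with optional exponential growth: with k lineages the
#' pairwise coalescence rate is k(k-1)/2 divided by N(t) = N exp(-growth t)
#' (backward time), sampled exactly through the usual time transformation.
#' E(TMRCA) = N for n = 2 and 2N(1 - 1/n) in general when growth = 0.
#'
#' @param n number of tips (>= 2).
#' @param N effective (haploid) population size at sampling time.
#' @param growth forward exponential growth rate per generation.
#' @param seed optional RNG seed.
#' @return an \code{ape::phylo} tree with edge lengths in generations, the
#'   root height in attribute \code{"tmrca"} and node times (tips first) in
#'   attribute \code{"times"}.
#' @export
simulateTree <- function(n, N, growth = 0, seed = NULL) {
  stopifnot(n >= 2, N > 0)
  if (!is.null(seed)) set.seed(seed)
  nodeTime <- c(rep(0, n), rep(NA_real_, n - 1L))
  active <- seq_len(n)
  s <- 0
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  lens <- numeric(2L * (n - 1L))
  e <- 0L
  for (j in seq_len(n - 1L)) {
    k <- length(active)
    dLam <- stats::rexp(1L, rate = k * (k - 1) / 2)
    if (growth > 0) {
      lam <- (exp(growth * s) - 1) / (growth * N)
      s <- log(1 + growth * N * (lam + dLam)) / growth
    } else {
      s <- s + N * dLam
    }
    newNode <- 2L * n - j  # last event lands on n+1, the ape root
    pick <- sample(k, 2L)
    ch <- active[pick]
    nodeTime[newNode] <- s
    for (c_ in ch) {
      e <- e + 1L
      edges[e, ] <- c(newNode, c_)
      lens[e] <- s - nodeTime[c_]
    }
    active <- c(active[-pick], newNode)
  }
  tree <- list(edge = edges, edge.length = lens,
               tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "tmrca") <- s
  attr(tree, "times") <- nodeTime
  tree
}

# net SMM displacement after `count` mutations, each +-1 with prob 1/2
smmNet <- function(count) {
  out <- integer(length(count))
  nz <- count > 0
  out[nz] <- 2L * stats::rbinom(sum(nz), count[nz], 0.5) - count[nz]
  out
}

# reflect a repeat count into the valid [5, 60] band (mutations cannot
# carry an allele out of the reportable range)
reflectAllele <- function(x) {
  while (any(x < 5 | x > 60)) {
    x[x < 5] <- 10 - x[x < 5]
    x[x > 60] <- 120 - x[x > 60]
  }
  x
}

#' Drop stepwise STR mutations along a genealogy
#'
#' On each branch of length t, each STR copy accumulates
#' Poisson(mu * t) mutations, each changing the repeat count by +-1 with
#' equal probability (the symmetric single-step model); the founder
#' haplotype sits at the root.
#'
#' @param tree an \code{ape::phylo} with edge lengths in generations.
#' @param founder named numeric vector over allele columns (copies of
#'   duplicated loci as \code{<locus>a}/\code{<locus>b}).
#' @param rates named per-generation rates by locus (copies share their
#'   locus rate).
#' @param seed optional RNG seed.
#' @return numeric matrix of tip haplotypes (rows = tips, in tip order).
#' @export
mutateStr <- function(tree, founder, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- rates[lociOfColumns(names(founder), names(rates))]
  if (anyNA(mu)) stop("rates must cover all founder loci")
  mu <- unname(mu)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  val <- matrix(NA_real_, nn, length(founder))
  root <- n + 1L
  val[root, ] <- founder
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; c_ <- tree$edge[k, 2L]
    len <- tree$edge.length[k]
    cnt <- stats::rpois(length(founder), mu * len)
    val[c_, ] <- reflectAllele(val[p, ] + smmNet(cnt))
  }
  out <- val[seq_len(n), , drop = FALSE]
  dimnames(out) <- list(tree$tip.label, names(founder))
  out
}

#' Study-like default simulation configuration
#'
#' Emulates the five-ethnicity Chinese study design: population sizes
#' 1266 (Han), 654 (Hui), 680 (Mongolia), 427 (Yi) and 314 (Kyrgyz)
#' (the reciprocals of the published per-population minimum haplotype
#' frequencies), haplogroup mixtures matching the published major-clade
#' frequency table (Han O 0.800, Kyrgyz R 0.455, ...), subclade splits
#' following the qualitative descriptions of the networks (e.g. Kyrgyz C
#' concentrated in C2a1a3, no O1 in Kyrgyz), and representative sampling
#' coordinates per ethnicity. Within-clade genealogies use an expansion
#' regime (N = 3000 with growth 0.005 per generation, i.e. expected clade
#' TMRCAs near 17 000 years at 25 y/generation and star-like trees, the
#' post-glacial signature such datasets carry); haplogroup founder
#' haplotypes drift apart along the nomenclature tree at 480 generations
#' per tree edge, and each population's clade founder drifts a further
#' 100 generations, which is what makes haplogroups (and, more weakly,
#' populations) separable from STRs alone.
#'
#' @param panel a [LocusPanel-class].
#' @param tree a [HaplogroupTree-class].
#' @return a list understood by [simulateDataset()].
#' @export
defaultSimConfig <- function(panel = defaultPanel(),
                             tree = defaultHaplogroupTree()) {
  pops <- data.frame(
    label = c("Han", "Hui", "Mongolia", "Yi", "Kyrgyz"),
    ethnicity = c("Han", "Hui", "Mongolia", "Yi", "Kyrgyz"),
    size = c(1266L, 654L, 680L, 427L, 314L),
    latitude = c(34.8, 36.0, 45.8, 27.9, 41.1),
    longitude = c(113.6, 103.8, 111.7, 102.3, 80.3))
  level0 <- list(
    Han = c(C = .083, D = .013, E = .002, F = .001, G = .004, N = .062,
            O = .800, Q = .026, R = .010),
    Hui = c(C = .083, D = .012, E = .026, F = .005, G = .015, H = .023,
            I = .011, J = .097, L = .020, N = .075, O = .474, Q = .040,
            R = .118),
    Mongolia = c(C = .346, D = .041, E = .009, G = .007, I = .006,
                 J = .018, L = .001, N = .115, O = .365, Q = .027,
                 R = .065),
    Yi = c(C = .037, D = .244, F = .049, N = .077, O = .583, Q = .009),
    Kyrgyz = c(C = .347, D = .048, E = .006, F = .006, G = .003, J = .067,
               L = .013, N = .006, O = .035, Q = .013, R = .455))
  splits <- list(
    Han = list(C = c("C2b1" = .45, "C2b1b" = .35, "C2a1a3" = .10,
                     "C*" = .10),
               D = c("D1a1a1a1b" = .5, "D1a1b1a" = .5),
               N = c("N1a2" = .5, "N1b" = .25, "N1a1a1a1a3" = .25),
               O = c("O1a" = .15, "O1b1a1a1a" = .10, "O2a1" = .20,
                     "O2a2a1" = .15, "O2a2b1a1a1" = .20,
                     "O2a2b1a2a1a" = .20),
               R = c("R1a" = .7, "R1b" = .3)),
    Hui = list(C = c("C2a1a1b1" = .3, "C2a1a2" = .2, "C2a1a3" = .2,
                     "C2b1" = .2, "C*" = .1),
               D = c("D1a1a1a1b" = .5, "D1a1b1a" = .5),
               N = c("N1a1a1a1a3" = 1/3, "N1a2" = 1/3, "N1b" = 1/3),
               O = c("O1a" = .05, "O1b1a1a1a" = .05, "O2a1" = .30,
                     "O2a2a1" = .20, "O2a2b1a1a1" = .20,
                     "O2a2b1a2a1a" = .20),
               R = c("R1a" = .4, "R1b" = .3, "R2" = .3)),
    Mongolia = list(C = c("C2a1a1b1" = .3, "C2a1a2" = .3, "C2a1a3" = .3,
                          "C2b1" = .1),
                    D = c("D1a1a1a1b" = .5, "D1a1b1a" = .5),
                    N = c("N1a1a1a1a3" = .5, "N1a2" = .3, "N1b" = .2),
                    O = c("O1a" = .05, "O1b1a1a1a" = .05, "O2a1" = .35,
                          "O2a2a1" = .15, "O2a2b1a1a1" = .20,
                          "O2a2b1a2a1a" = .20),
                    R = c("R1a" = .5, "R2" = .5)),
    Yi = list(C = c("C*" = .5, "C2b1b" = .5),
              D = c("D1a1a1a1b" = .9, "D1a1b1a" = .1),
              N = c("N1b" = .8, "N1a2" = .2),
              O = c("O1a" = .10, "O1b1a1a1a" = .15, "O2a1" = .25,
                    "O2a2a1" = .20, "O2a2b1a1a1" = .15,
                    "O2a2b1a2a1a" = .15)),
    Kyrgyz = list(C = c("C2a1a3" = .6, "C2a1a2" = .25, "C2a1a1b1" = .15),
                  D = c("D1a1b1a" = 1),
                  N = c("N1a1a1a1a3" = 1/3, "N1a2" = 1/3, "N1b" = 1/3),
                  O = c("O2a1" = .50, "O2a2a1" = .25, "O2a2b1a1a1" = .25),
                  R = c("R1a1a1b2a2" = .9, "R1b" = .1)))
  mixtures <- lapply(pops$label, function(p) {
    lv0 <- level0[[p]] / sum(level0[[p]])
    out <- numeric(0)
    for (cl in names(lv0)) {
      sp <- splits[[p]][[cl]]
      if (is.null(sp)) sp <- stats::setNames(1, cl)
      out <- c(out, lv0[[cl]] * sp / sum(sp))
    }
    out
  })
  names(mixtures) <- pops$label
  founder <- c(
    DYS389I = 13, DYS389b = 16, DYS390 = 24, DYS391 = 10, DYS392 = 13,
    DYS393 = 12, DYS437 = 14, DYS438 = 10, DYS439 = 12, DYS448 = 19,
    DYS456 = 15, DYS458 = 16, DYS635 = 21, YGATAH4 = 12, DYS19 = 15,
    DYS449 = 30, DYS460 = 11, DYS481 = 22, DYS518 = 38, DYS533 = 11,
    DYS570 = 17, DYS576 = 18, DYS627 = 21,
    DYS385a = 13, DYS385b = 14, DYF387S1a = 36, DYF387S1b = 38)
  list(panel = panel, tree = tree, populations = pops,
       mixtures = mixtures, founder = founder[alleleColumns(panel)],
       rates = mutationRates(panel), N = 3000, growth = 0.005,
       driftGens = 100, cladeEdgeGens = 480)
}

# terminal haplogroup label with its defining-SNP suffix ("C2a1a3-M504");
# star calls keep the parent's SNP ("C*-M130")
hgLabel <- function(tree, name) {
  base <- sub("\\*$", "", name)
  snp <- tree@nodes$snp[match(base, tree@nodes$haplogroup)]
  if (is.na(snp)) name else paste0(name, "-", snp)
}

#' Simulate a multi-population Y-haplotype dataset
#'
#' Generates the dataset structure the analyses assume: per population,
#' haplogroup labels are drawn from the configured mixture; per population
#' and haplogroup, one shared coalescent genealogy is simulated and
#' stepwise STR mutations dropped along it; haplogroup founder haplotypes
#' are themselves evolved along the nomenclature tree so that haplogroups
#' carry real STR signal. Fully deterministic given the seed, with one
#' derived RNG substream per population-by-haplogroup cell.
#'
#' @param config list as from [defaultSimConfig()].
#' @param seed master RNG seed.
#' @return list with \code{dataset} (a [YStrDataset-class]) and
#'   \code{truth} (per population x haplogroup true TMRCA in generations,
#'   plus the generating parameters).
#' @export
simulateDataset <- function(config = defaultSimConfig(), seed = 1L) {
  seedState <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(seedState))
    assign(".Random.seed", seedState, globalenv()))
  set.seed(seed)
  tree <- config$tree
  panel <- config$panel
  rates <- config$rates
  pops <- config$populations

  # founder haplotypes drift along the nomenclature tree, root first
  nodeFounder <- list(ROOT = config$founder)
  pending <- tree@nodes$haplogroup[tree@nodes$parent == tree@root]
  while (length(pending)) {
    h <- pending[1L]; pending <- pending[-1L]
    par <- tree@nodes$parent[match(h, tree@nodes$haplogroup)]
    base <- nodeFounder[[par]]
    cnt <- stats::rpois(length(base),
                        unname(rates[lociOfColumns(names(base),
                                                   names(rates))]) *
                          config$cladeEdgeGens)
    nodeFounder[[h]] <- reflectAllele(base + smmNet(cnt))
    pending <- c(pending, hgChildren(tree, h))
  }

  # one named substream per population x haplogroup
  allHg <- sort(unique(unlist(lapply(config$mixtures, names))))
  subseeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                nrow(pops) * length(allHg)),
                     nrow(pops), length(allHg),
                     dimnames = list(pops$label, allHg))

  infos <- list(); mats <- list(); truth <- list()
  for (pi in seq_len(nrow(pops))) {
    p <- pops$label[pi]
    mix <- config$mixtures[[p]]
    bad <- setdiff(sub("\\*$", "", names(mix)), tree@nodes$haplogroup)
    if (length(bad))
      stop("mixture names haplogroups absent from the tree: ",
           paste(bad, collapse = ", "))
    counts <- as.vector(stats::rmultinom(1L, pops$size[pi],
                                         mix / sum(mix)))
    names(counts) <- names(mix)
    popTruth <- list()
    for (hg in names(counts)[counts > 0]) {
      m <- counts[[hg]]
      set.seed(subseeds[p, hg])
      base <- nodeFounder[[sub("\\*$", "", hg)]]
      cnt <- stats::rpois(length(base),
                          unname(rates[lociOfColumns(names(base),
                                                     names(rates))]) *
                            config$driftGens)
      popFounder <- reflectAllele(base + smmNet(cnt))
      if (m >= 2) {
        gtree <- simulateTree(m, config$N, config$growth)
        tips <- mutateStr(gtree, popFounder, rates)
        tm <- attr(gtree, "tmrca")
      } else {
        gtree <- simulateTree(2L, config$N, config$growth)
        tips <- mutateStr(gtree, popFounder, rates)[1L, , drop = FALSE]
        tm <- attr(gtree, "tmrca")
      }
      lab <- hgLabel(tree, hg)
      id0 <- sprintf("%s_%s_%03d", p, gsub("[*]", "s", hg), seq_len(m))
      infos[[length(infos) + 1L]] <- data.frame(
        sample_id = id0, population = p, ethnicity = pops$ethnicity[pi],
        latitude = pops$latitude[pi], longitude = pops$longitude[pi],
        haplogroup = lab, stringsAsFactors = FALSE)
      mats[[length(mats) + 1L]] <- tips
      popTruth[[hg]] <- list(n = m, tmrca_generations = tm)
    }
    truth[[p]] <- popTruth
  }
  info <- do.call(rbind, infos)
  al <- do.call(rbind, mats)
  ds <- YStrDataset(info, al, panel)
  list(dataset = ds,
       truth = list(seed = seed, N = config$N, growth = config$growth,
                    driftGens = config$driftGens,
                    cladeEdgeGens = config$cladeEdgeGens,
                    populations = truth))
}

#' Write per-sample SNP states implied by the haplogroup calls
#'
#' Long-format TSV (sample_id, snp, state) with state D on the
#' root-to-call path and A elsewhere, matching the convention of
#' [assignHaplogroup()].
#'
#' @param ds a [YStrDataset-class].
#' @param tree a [HaplogroupTree-class].
#' @param path output file.
#' @export
writeSnpStates <- function(ds, tree, path) {
  S <- snpStatesFromHaplogroups(ds, tree)
  long <- data.frame(sample_id = rep(rownames(S), ncol(S)),
                     snp = rep(colnames(S), each = nrow(S)),
                     state = ifelse(as.vector(S) == 1, "D", "A"))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
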