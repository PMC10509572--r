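#' Parse an ISOGG-style haplogroup name
#'
#' Names consist of a trunk capital letter, a refinement path alternating
#' numbers and lowercase letters (e.g. \code{O2a2b1a1a1}), an optional
#' paraphyletic star (\code{C*}) and an optional defining-SNP suffix after a
#' hyphen (\code{C2a1a3-M504}).
#'
#' @param s haplogroup name string.
#' @return list with elements \code{trunk}, \code{path} (character vector of
#'   alternating number/letter tokens), \code{snp} (or \code{NA}),
#'   \code{star} (logical).
#' @export
parseHaplogroup <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("empty haplogroup name")
  body <- s
  snp <- NA_character_
  dash <- regexpr("-", body, fixed = TRUE)
  if (dash > 0) {
    snp <- substring(body, dash + 1L)
    body <- substring(body, 1L, dash - 1L)
    if (!nzchar(snp) || !nzchar(body)) stop("malformed name: ", s)
  }
  star <- grepl("\\*$", body)
  if (star) body <- sub("\\*$", "", body)
  trunk <- substring(body, 1L, 1L)
  if (!grepl("^[A-Z]$", trunk))
    stop("haplogroup trunk must be a capital letter: ", s)
  rest <- substring(body, 2L)
  path <- character()
  expectDigit <- TRUE
  while (nzchar(rest)) {
    if (expectDigit) {
      m <- regmatches(rest, regexpr("^[0-9]+", rest))
      if (!length(m)) stop("path must alternate number/letter: ", s)
    } else {
      m <- regmatches(rest, regexpr("^[a-z]", rest))
      if (!length(m)) stop("path must alternate number/letter: ", s)
    }
    path <- c(path, m)
    rest <- substring(rest, nchar(m) + 1L)
    expectDigit <- !expectDigit
  }
  list(trunk = trunk, path = path, snp = snp, star = star)
}

#' Render a parsed haplogroup name
#'
#' Inverse of [parseHaplogroup()]: \code{renderHaplogroup(parseHaplogroup(s))}
#' returns \code{s} for canonical names.
#'
#' @param hg parsed name (list) or string.
#' @param snp,star include the SNP suffix / star flag?
#' @return name string.
#' @export
renderHaplogroup <- function(hg, snp = TRUE, star = TRUE) {
  if (is.character(hg)) hg <- parseHaplogroup(hg)
  out <- paste0(hg$trunk, paste(hg$path, collapse = ""))
  if (star && isTRUE(hg$star)) out <- paste0(out, "*")
  if (snp && !is.na(hg$snp)) out <- paste0(out, "-", hg$snp)
  out
}

#' Collapse a haplogroup name to a coarser level
#'
#' Truncates the refinement path to \code{level} tokens after the trunk
#' (level 0 keeps the trunk only). Names already at or above the level are
#' returned unchanged (so the operation is idempotent); when truncation
#' occurs the SNP suffix and star no longer apply and are dropped.
#'
#' @param hg parsed name or string.
#' @param level integer >= 0.
#' @return same type as the input (string in, string out).
#' @export
collapseHaplogroup <- function(hg, level) {
  stopifnot(level >= 0)
  asString <- is.character(hg)
  p <- if (asString) parseHaplogroup(hg) else hg
  if (length(p$path) > level) {
    p$path <- p$path[seq_len(level)]
    p$snp <- NA_character_
    p$star <- FALSE
  }
  if (asString) renderHaplogroup(p) else p
}

#' Construct a haplogroup tree
#'
#' Builds the rooted nomenclature tree from (haplogroup, defining SNP)
#' pairs. Parents are inferred from nomenclature: the parent of a node is
#' its longest proper name-prefix (under the alternating token grammar)
#' present in the table, falling back to the synthetic root.
#'
#' @param nodes data.frame with columns \code{haplogroup} and \code{snp}.
#' @param root synthetic root name.
#' @return a [HaplogroupTree-class].
#' @export
HaplogroupTree <- function(nodes, root = "ROOT") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  plain <- vapply(nodes$haplogroup,
                  function(s) renderHaplogroup(parseHaplogroup(s),
                                               snp = FALSE, star = FALSE),
                  character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(plain))
    stop("duplicate haplogroup names (ignoring SNP suffix): ",
         paste(unique(plain[duplicated(plain)]), collapse = ", "))
  nodes$haplogroup <- plain
  parent <- character(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    p <- parseHaplogroup(nodes$haplogroup[i])
    parent[i] <- root
    if (length(p$path) || TRUE) {
      for (lev in rev(seq_len(length(p$path))) - 1L) {
        cand <- renderHaplogroup(collapseHaplogroup(p, lev),
                                 snp = FALSE, star = FALSE)
        if (cand != nodes$haplogroup[i] && cand %in% plain) {
          parent[i] <- cand
          break
        }
      }
    }
  }
  nodes$parent <- parent
  new("HaplogroupTree", nodes = nodes[, c("haplogroup", "parent", "snp")],
      root = root)
}

#' Read a haplogroup tree from a two-column TSV
#'
#' Columns: \code{haplogroup}, \code{snp}. Parent relationships are inferred
#' from nomenclature, see [HaplogroupTree()].
#'
#' @param path file path.
#' @return a [HaplogroupTree-class].
#' @export
readHaplogroupTree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  HaplogroupTree(df)
}

# Chain of ancestors of a node, from its parent up to (excluding) the root.
hgAncestors <- function(tree, name) {
  parent <- stats::setNames(tree@nodes$parent, tree@nodes$haplogroup)
  out <- character()
  cur <- parent[[name]]
  while (!is.null(cur) && cur != tree@root) {
    out <- c(out, cur)
    cur <- if (cur %in% names(parent)) parent[[cur]] else NULL
  }
  out
}

hgChildren <- function(tree, name)
  tree@nodes$haplogroup[tree@nodes$parent == name]

#' Assign a haplogroup from SNP derived/ancestral states
#'
#' Returns the haplogroup of the deepest tree node whose defining SNP is
#' derived and whose every typed ancestor-defining SNP is also derived.
#' Untyped SNPs are treated as unknown, never as ancestral. A derived SNP
#' off the root-to-result path is a lineage conflict and raises an error
#' naming the offending SNPs. With no derived SNP the root name is
#' returned. When every typed daughter SNP of the result is ancestral the
#' paraphyletic star form (e.g. \code{"C2*"}) is returned; with untyped
#' daughters the plain name is returned.
#'
#' @param snpStates named character vector, values \code{"A"} (ancestral),
#'   \code{"D"} (derived) or \code{"U"} (untyped); names are SNP ids.
#' @param tree a [HaplogroupTree-class].
#' @return haplogroup name string.
#' @export
assignHaplogroup <- function(snpStates, tree) {
  nodes <- tree@nodes
  snp2hg <- stats::setNames(nodes$haplogroup, nodes$snp)
  hg2snp <- stats::setNames(nodes$snp, nodes$haplogroup)
  stateOf <- function(hg) {
    s <- hg2snp[[hg]]
    if (is.na(s) || !s %in% names(snpStates)) "U" else snpStates[[s]]
  }
  derivedNodes <- nodes$haplogroup[vapply(nodes$haplogroup,
                                          function(h) stateOf(h) == "D",
                                          logical(1L))]
  if (!length(derivedNodes)) return(tree@root)
  # consistent: all typed ancestors derived
  consistent <- Filter(function(h) {
    anc <- hgAncestors(tree, h)
    all(vapply(anc, function(a) stateOf(a) != "A", logical(1L)))
  }, derivedNodes)
  if (!length(consistent))
    stop("conflicting SNP states: no consistent lineage for derived SNPs ",
         paste(hg2snp[derivedNodes], collapse = ", "))
  depth <- vapply(consistent, function(h) length(hgAncestors(tree, h)),
                  integer(1L))
  best <- sort(consistent[depth == max(depth)])[1L]
  onPath <- c(best, hgAncestors(tree, best))
  off <- setdiff(derivedNodes, onPath)
  if (length(off))
    stop("conflicting derived SNPs off the assigned lineage: ",
         paste(sort(hg2snp[off]), collapse = ", "))
  kids <- hgChildren(tree, best)
  if (length(kids)) {
    st <- vapply(kids, stateOf, character(1L))
    if (all(st == "A")) return(paste0(best, "*"))
  }
  best
}

#' @export
setMethod("show", "HaplogroupTree", function(object) {
  cat(sprintf("HaplogroupTree: %d nodes under root '%s'\n",
              nrow(object@nodes), object@root))
  trunks <- sort(unique(substring(object@nodes$haplogroup, 1L, 1L)))
  cat("  trunks:", paste(trunks, collapse = " "), "\n")
})

#' Study-like default haplogroup tree
#'
#' A compact ISOGG-2019-style tree covering the major East Asian clades
#' (C, D, E, F, G, H, I, J, L, T, N, O, P, Q, R) and the named subclades
#' that structure the five-ethnicity analyses (e.g. C2a1a3-M504,
#' C2b1b-F845, O2a2b1a1a1-F438, R1a1a1b2a2-Z2124). Intended as the default
#' input for simulation and haplogroup assignment; real studies should
#' supply their own tree via [readHaplogroupTree()].
#'
#' @return a [HaplogroupTree-class].
#' @export
defaultHaplogroupTree <- function() {
  nodes <- data.frame(
    haplogroup = c(
      "C", "C2", "C2a", "C2a1a", "C2a1a1b1", "C2a1a2", "C2a1a3",
      "C2b", "C2b1", "C2b1b",
      "D", "D1a1a1a1b", "D1a1b1a",
      "E", "F", "G", "H", "I", "J", "L", "T",
      "N", "N1a", "N1a1a1a1a3", "N1a2", "N1b",
      "O", "O1", "O1a", "O1b", "O1b1a1a1a",
      "O2", "O2a", "O2a1", "O2a2", "O2a2a1", "O2a2b1a1a1", "O2a2b1a2a1a",
      "P", "Q",
      "R", "R1", "R1a", "R1a1a1b2a2", "R1b", "R2"),
    snp = c(
      "M130", "M217", "L1373", "F3447", "F1756", "M48", "M504",
      "F1067", "Z1338", "F845",
      "M174", "SK541", "M533",
      "M96", "M89", "M201", "M69", "M170", "M304", "M20", "M70",
      "M231", "F1206", "B197", "F1008", "F2930",
      "M175", "F265", "M119", "M268", "F1252",
      "M122", "M324", "L467", "P201", "F2588", "F438", "F46",
      "P295", "M242",
      "M207", "M173", "M420", "Z2124", "M343", "M479"),
    stringsAsFactors = FALSE)
  HaplogroupTree(nodes)
}
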