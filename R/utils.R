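# Canonical allele formatting: value-wise, trailing ".0" stripped, one
# decimal kept for intermediate alleles, so "12" and 12.0 always collide
# and 17.2 never does.
fmtAllele <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sub("\\.0$", "", sprintf("%.1f", v))
  }, character(1L), USE.NAMES = FALSE)
}

# Map allele-matrix column names to locus names: copy columns of duplicated
# loci carry an a/b suffix, but locus names themselves may end in a letter
# (DYS389b), so only strip the suffix when the stripped form is a known
# locus and the full form is not.
lociOfColumns <- function(cols, known) {
  ifelse(cols %in% known, cols,
         ifelse(sub("[ab]$", "", cols) %in% known,
                sub("[ab]$", "", cols), cols))
}

# Run seeded code without clobbering the caller's RNG stream: the stream
# is restored on exit, so seeded estimators can be used inside a caller's
# own replicate loops.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}
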