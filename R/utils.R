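## Leaf labels are "SPECIES|GENEID". Six study species, four great apes
## plus the macaque/gibbon outgroup pair in which rates are measured.

#' @export
study_species <- function() {
  c("human", "chimp", "gorilla", "orangutan", "gibbon", "macaque")
}

#' @export
great_apes <- function() {
  c("human", "chimp", "gorilla", "orangutan")
}

#' Species component of "SPECIES|GENEID" leaf labels
#' @param labels character vector of leaf labels.
#' @return Character vector of species names.
#' @export
label_species <- function(labels) {
  vapply(strsplit(labels, "|", fixed = TRUE), `[[`, character(1), 1L)
}

#' Gene-id component of "SPECIES|GENEID" leaf labels
#' @param labels character vector of leaf labels.
#' @export
label_gene <- function(labels) {
  vapply(strsplit(labels, "|", fixed = TRUE), function(x)
    if (length(x) > 1) paste(x[-1], collapse = "|") else x[[1]],
    character(1))
}

## Patristic distance matrix of a phylo, rows/cols named by tip label.
patristic <- function(tree) {
  stats::cophenetic(tree)
}

## deterministic sub-seed streams: one master seed fans out to per-unit
## seeds so any family is reproducible in isolation
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
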