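## Gene-tree classification: prune to the six study species, count gene
## copies per species, and separate recent great-ape duplications from
## ancestral duplication followed by loss using the patristic-distance
## rule (the distance A between two sister paralogs must be strictly less
## than the distances B and C from each paralog to the gibbon ortholog).

#' Prune a gene tree to a species set
#'
#' Drops leaves of species outside `species_set`; unary internal nodes are
#' collapsed with their branch lengths summed, so patristic distances
#' between retained leaves are preserved.
#'
#' @param tree phylo with "SPECIES|GENE" tip labels.
#' @param species_set species to retain.
#' @return Pruned phylo, or `NULL` when no leaves remain (the family must
#'   be excluded as missing).
#' @export
prune_to_species <- function(tree, species_set = study_species()) {
  sp <- label_species(tree$tip.label)
  keep <- tree$tip.label[sp %in% species_set]
  if (!length(keep)) return(NULL)
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1) {
    ## single-leaf remnant: ape cannot represent it cleanly; signal missing
    return(NULL)
  }
  ape::keep.tip(tree, keep)
}

#' Gene copy counts per species
#'
#' @param tree pruned phylo.
#' @param species species to tabulate (default the six study species).
#' @return Named integer vector of leaf counts.
#' @export
copy_counts <- function(tree, species = study_species()) {
  sp <- label_species(tree$tip.label)
  vapply(species, function(s) sum(sp == s), integer(1))
}

#' Distance rule for dating a duplication
#'
#' A duplication is called recent (post-speciation) when the patristic
#' distance A between the two paralogs is strictly smaller than both
#' distances B and C from each paralog to the gibbon ortholog; ties fail
#' the rule, conservatively leaving ancestral duplication unexcluded.
#'
#' @param A patristic distance between the two closest paralogs.
#' @param B,C patristic distances from each paralog to the gibbon gene.
#' @return `"recent"` or `"ancestral_ambiguous"`.
#' @export
duplication_timing_test <- function(A, B, C) {
  stopifnot(A >= 0, B >= 0, C >= 0)
  if (A < B && A < C) "recent" else "ancestral_ambiguous"
}

## pick the two most closely related paralogs of one species; exact ties
## broken lexicographically by gene id for determinism
closest_paralog_pair <- function(dmat, tips) {
  tips <- tips[order(tips)]
  best <- NULL
  bestd <- Inf
  for (a in seq_len(length(tips) - 1)) {
    for (b in (a + 1):length(tips)) {
      d <- dmat[tips[a], tips[b]]
      if (d < bestd - 1e-15) {
        bestd <- d
        best <- c(tips[a], tips[b])
      }
    }
  }
  list(pair = best, A = bestd)
}

#' Split a tree with multiple macaque/gibbon genes into ancestral subtrees
#'
#' When a family contains more than one macaque and/or gibbon gene the
#' duplication may predate the primates; if the topology decomposes into
#' maximal clades each holding exactly one macaque and one gibbon gene
#' (plus great-ape orthologs), those clades are returned as separate
#' family trees. Otherwise the family is flagged not decomposable.
#'
#' @param tree pruned phylo.
#' @return List of phylo subtrees, or an empty list with attribute
#'   `reason = "excluded_ambiguous_loss"` when the tree cannot be split.
#' @export
split_ancestral_subtrees <- function(tree) {
  cc <- copy_counts(tree)
  if (cc["macaque"] <= 1 && cc["gibbon"] <= 1) return(list(tree))
  ntip <- length(tree$tip.label)
  sp <- label_species(tree$tip.label)

  tips_below <- function(node) {
    if (node <= ntip) return(node)
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      ch <- tree$edge[tree$edge[, 1] == nd, 2]
      out <- c(out, ch[ch <= ntip])
      stack <- c(stack, ch[ch > ntip])
    }
    out
  }

  nodes <- (ntip + 1):(ntip + tree$Nnode)
  ok <- logical(length(nodes))
  below <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    tb <- tips_below(nodes[k])
    below[[k]] <- tb
    ok[k] <- sum(sp[tb] == "macaque") == 1 && sum(sp[tb] == "gibbon") == 1
  }
  ## maximal qualifying clades: qualifying nodes with no qualifying ancestor
  qn <- nodes[ok]
  has_qualifying_ancestor <- function(node) {
    repeat {
      par <- tree$edge[tree$edge[, 2] == node, 1]
      if (!length(par)) return(FALSE)
      if (par %in% qn) return(TRUE)
      node <- par
    }
  }
  maximal <- qn[!vapply(qn, has_qualifying_ancestor, logical(1))]
  covered <- sort(unique(unlist(below[match(maximal, nodes)])))
  if (!length(maximal) || !identical(covered, seq_len(ntip))) {
    out <- list()
    attr(out, "reason") <- "excluded_ambiguous_loss"
    return(out)
  }
  lapply(maximal, function(nd) ape::extract.clade(tree, nd))
}

#' Classify a gene family tree
#'
#' Applies the family-definition pipeline: families lacking a macaque or
#' gibbon gene are excluded as missing; families with more than one
#' macaque/gibbon gene are split into ancestral subtrees when possible
#' (label `"split"`) or excluded; families with one gene per species are
#' singletons; families with extra great-ape copies are tested per
#' duplicated species with the distance rule on the two most closely
#' related paralogs, giving `"duplicable"` when at least one species shows
#' a recent duplication and `"excluded_ambiguous_loss"` otherwise.
#'
#' @param tree phylo (pruned or not; pruning to the six species is applied).
#' @return Object of class `"family_classification"`: `label`, `evidence`
#'   (per-species A, B, C for tested species), `subtrees` (when split).
#' @export
classify_family <- function(tree) {
  out <- function(label, evidence = NULL, subtrees = NULL)
    structure(list(label = label, evidence = evidence, subtrees = subtrees),
              class = "family_classification")
  if (is.null(tree)) return(out("excluded_missing"))
  tree <- prune_to_species(tree)
  if (is.null(tree)) return(out("excluded_missing"))
  cc <- copy_counts(tree)
  if (cc["macaque"] == 0 || cc["gibbon"] == 0) return(out("excluded_missing"))
  if (cc["macaque"] > 1 || cc["gibbon"] > 1) {
    subs <- split_ancestral_subtrees(tree)
    if (!length(subs)) return(out("excluded_ambiguous_loss"))
    return(out("split", subtrees = subs))
  }
  if (all(cc == 1)) return(out("singleton"))

  dmat <- patristic(tree)
  sp <- label_species(tree$tip.label)
  gib <- tree$tip.label[sp == "gibbon"]
  ev <- NULL
  for (s in great_apes()[cc[great_apes()] > 1]) {
    tips <- tree$tip.label[sp == s]
    cp <- closest_paralog_pair(dmat, tips)
    A <- cp$A
    B <- dmat[cp$pair[1], gib]
    C <- dmat[cp$pair[2], gib]
    ev <- rbind(ev, data.frame(
      species = s, paralog1 = cp$pair[1], paralog2 = cp$pair[2],
      A = A, B = B, C = C,
      verdict = duplication_timing_test(A, B, C),
      stringsAsFactors = FALSE))
  }
  if (any(ev$verdict == "recent")) out("duplicable", evidence = ev)
  else out("excluded_ambiguous_loss", evidence = ev)
}

#' @export
print.family_classification <- function(x, ...) {
  cat("Family classification:", x$label, "\n")
  if (!is.null(x$evidence)) {
    cat("  evidence (patristic distances):\n")
    print(x$evidence[, c("species", "A", "B", "C", "verdict")],
          row.names = FALSE)
  }
  if (!is.null(x$subtrees))
    cat("  split into", length(x$subtrees), "subtrees\n")
  invisible(x)
}

#' Classify every family of a dataset
#'
#' @param families named list of phylo trees.
#' @return Data frame: family_id, label, dup_species, A, B, C.
#' @export
classify_families <- function(families) {
  rows <- lapply(names(families), function(id) {
    cl <- classify_family(families[[id]])
    if (cl$label == "duplicable") {
      ev <- cl$evidence[cl$evidence$verdict == "recent", , drop = FALSE]
      data.frame(family_id = id, label = cl$label,
                 dup_species = paste(ev$species, collapse = ","),
                 A = ev$A[1], B = ev$B[1], C = ev$C[1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(family_id = id, label = cl$label,
                 dup_species = NA_character_, A = NA_real_, B = NA_real_,
                 C = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
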