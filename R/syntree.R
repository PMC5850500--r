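## Synthetic primate gene-family generator: a fixed six-species tree
## (four great apes with a gibbon/macaque outgroup pair), a minority class
## of families carrying one recent great-ape duplication, per-family omega
## drawn from group-specific log-normals, codon sequences evolved along the
## tree under the Goldman-Yang model, and covariates (expression, CDS
## length, genomic length) with the negative rate correlations the
## downstream analysis assumes.

#' Default six-species primate tree
#'
#' Branch lengths are in expected substitutions per codon, calibrated so
#' that the macaque-gibbon pairwise dS lands around 0.08-0.10 under the
#' default omega distributions.
#'
#' @return An `ape` phylo object with tips labelled by species.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((human:0.008,chimp:0.008):0.004,gorilla:0.011):0.006,",
    "orangutan:0.020):0.013,gibbon:0.055):0.012,macaque:0.068);"))
}

## fixed position-specific nucleotide frequencies (T, C, A, G) typical of
## mammalian coding sequence; GC3 around 56%
.default_pos_freqs <- function() {
  rbind(c(0.17, 0.25, 0.26, 0.32),
        c(0.27, 0.23, 0.31, 0.19),
        c(0.26, 0.30, 0.18, 0.26))
}

.pi_from_pos_freqs <- function(freq) {
  nt <- c("T", "C", "A", "G")
  colnames(freq) <- nt
  cm <- do.call(rbind, strsplit(sense_codons(), ""))
  pi <- freq[1, cm[, 1]] * freq[2, cm[, 2]] * freq[3, cm[, 3]]
  pi / sum(pi)
}

#' Simulation configuration
#'
#' Collects the free parameters of the synthetic gene-family generator.
#' Defaults encode the study conditions of the analysis: ~5% duplicable
#' families, group median omega 0.36 (duplicable) vs 0.27 (singleton),
#' expression negatively correlated with omega (Spearman magnitude around
#' 0.35), CDS length weakly negatively correlated with omega (around 0.1),
#' duplicable genes slightly more expressed and shorter.
#'
#' @param n_families number of gene families.
#' @param fraction_duplicable proportion of families with a recent
#'   great-ape duplication.
#' @param omega_singleton,omega_duplicable log-normal (meanlog, sdlog) of
#'   per-family omega by class.
#' @param kappa transition/transversion rate ratio.
#' @param species_tree phylo with the six study species as tips; branch
#'   lengths in substitutions/codon.
#' @param dup_time_range interval (fractions of the duplicated species'
#'   terminal branch, measured from the speciation node) on which the
#'   duplication node is placed uniformly.
#' @param n_codons log-normal CDS length model in codons: `meanlog`,
#'   `sdlog`, `slope` (decrease in log-length per SD of log omega),
#'   `group_offset` (added to meanlog for duplicable families), and
#'   truncation `range`.
#' @param expression_model log2(RPKM)-like expression: `mean`, `sd`,
#'   `slope` (decrease per SD of log omega), `group_offset` (added for
#'   duplicable families); values are floored at 0.
#' @param genomic_length_model log10 intron inflation over CDS length:
#'   `mean`, `sd` of the added log10 factor.
#' @param postdup_omega_factor multiplier applied to omega on the branches
#'   descending from the duplication node (1 = no post-duplication shift).
#' @param pos_freqs 3x4 matrix of position-specific nucleotide frequencies
#'   (T, C, A, G order) defining the F3x4 root/stationary distribution.
#' @param seed integer master seed; per-family seeds are derived from it so
#'   any family is reproducible in isolation.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 400,
                       fraction_duplicable = 0.05,
                       omega_singleton = list(meanlog = log(0.27), sdlog = 0.25),
                       omega_duplicable = list(meanlog = log(0.36), sdlog = 0.25),
                       kappa = 2,
                       species_tree = default_species_tree(),
                       dup_time_range = c(0.2, 0.8),
                       n_codons = list(meanlog = log(480), sdlog = 0.45,
                                       slope = 0.047, group_offset = -0.26,
                                       range = c(60, 2000)),
                       expression_model = list(mean = 2.7, sd = 1.5,
                                               slope = 0.586,
                                               group_offset = 1.4),
                       genomic_length_model = list(mean = 1.2, sd = 0.45),
                       postdup_omega_factor = 1,
                       pos_freqs = .default_pos_freqs(),
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              fraction_duplicable = fraction_duplicable,
              omega_singleton = omega_singleton,
              omega_duplicable = omega_duplicable,
              kappa = kappa, species_tree = species_tree,
              dup_time_range = dup_time_range, n_codons = n_codons,
              expression_model = expression_model,
              genomic_length_model = genomic_length_model,
              postdup_omega_factor = postdup_omega_factor,
              pos_freqs = pos_freqs, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_families < 1) stop("n_families must be >= 1")
  if (cfg$fraction_duplicable < 0 || cfg$fraction_duplicable > 1)
    stop("fraction_duplicable must be in [0, 1]")
  if (cfg$kappa <= 0) stop("kappa must be > 0")
  for (d in list(cfg$omega_singleton, cfg$omega_duplicable)) {
    if (!is.finite(d$meanlog) || !is.finite(d$sdlog) || d$sdlog < 0)
      stop("invalid omega distribution parameters")
  }
  if (!inherits(cfg$species_tree, "phylo"))
    stop("species_tree must be a phylo object")
  if (any(cfg$species_tree$edge.length < 0))
    stop("species tree branch lengths must be >= 0")
  if (!all(sort(cfg$species_tree$tip.label) == sort(study_species())))
    stop("species_tree tips must be exactly the six study species")
  r <- cfg$dup_time_range
  if (length(r) != 2 || r[1] < 0 || r[2] > 1 || r[1] > r[2])
    stop("dup_time_range must be an ordered interval within [0, 1]")
  if (cfg$n_codons$sdlog < 0 || cfg$n_codons$meanlog <= 0)
    stop("invalid n_codons distribution parameters")
  if (cfg$postdup_omega_factor <= 0)
    stop("postdup_omega_factor must be > 0")
  invisible(cfg)
}

## standardized log-omega relative to the singleton distribution; the
## covariate models are linear in this z-score
.omega_z <- function(cfg, omega) {
  (log(omega) - cfg$omega_singleton$meanlog) /
    max(cfg$omega_singleton$sdlog, 1e-8)
}

## draw the per-family latent parameters (uses the current RNG stream)
draw_family_params <- function(cfg, class_label, family_id) {
  dup <- class_label == "duplicable"
  dist <- if (dup) cfg$omega_duplicable else cfg$omega_singleton
  omega <- stats::rlnorm(1, dist$meanlog, dist$sdlog)
  z <- .omega_z(cfg, omega)
  nc <- cfg$n_codons
  lnc <- nc$meanlog + (if (dup) nc$group_offset else 0) - nc$slope * z +
    stats::rnorm(1, 0, nc$sdlog)
  n_codons <- round(exp(lnc))
  n_codons <- min(max(n_codons, nc$range[1]), nc$range[2])
  dup_species <- if (dup) sample(great_apes(), 1) else NA_character_
  dup_frac <- if (dup) stats::runif(1, cfg$dup_time_range[1],
                                    cfg$dup_time_range[2]) else NA_real_
  list(family_id = family_id, class = class_label, omega = omega,
       omega_z = z, n_codons = as.integer(n_codons),
       dup_species = dup_species, dup_frac = dup_frac,
       omega_postdup = if (dup) omega * cfg$postdup_omega_factor else NA_real_)
}

## Splice a duplication node into the terminal branch of `species`.
## frac is measured from the parent (speciation) node; the two paralog
## tips each get the remaining (1 - frac) of the original branch.
add_duplication <- function(tree, species, frac, tip_labels) {
  tip <- which(tree$tip.label == species)
  L <- tree$edge.length[tree$edge[, 2] == tip]
  nwk <- ape::write.tree(tree)
  sub <- sprintf("(%s:%.10f,%s:%.10f):%.10f", tip_labels[1], (1 - frac) * L,
                 tip_labels[2], (1 - frac) * L, frac * L)
  pat <- paste0(species, ":[0-9.eE+-]+")
  out <- sub(pat, sub, nwk)
  ape::read.tree(text = out)
}

## evolve codon states along a tree; omega_edge gives the dN/dS used on
## each edge (tree edge order)
sim_codon_states <- function(tree, pi, kappa, omega_edge, n_codons) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  ## map edge omegas through the reorder
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  omega_edge <- omega_edge[ord]
  el <- tree$edge.length[ord]
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tr$Nnode)
  states[[root]] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  type <- codon_type_matrix()
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- cpp_pmatrix(pi, kappa, omega_edge[e], type, el[e])
    ps <- states[[par]]
    cs <- integer(n_codons)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      cs[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[[ch]] <- cs
  }
  out <- states[seq_len(ntip)]
  names(out) <- tr$tip.label
  out
}

#' Simulate one gene family
#'
#' Builds the gene tree (singletons: one gene per species; duplicable: one
#' extra paralog created by splicing a duplication node into a great-ape
#' terminal branch, strictly more recent than the speciation so the
#' distance rule holds on true distances) and evolves an in-frame codon
#' alignment along it: root codons from the F3x4 stationary frequencies,
#' then a Goldman-Yang substitution process with the family's omega
#' (optionally rescaled on post-duplication branches).
#'
#' @param cfg a [sim_config()].
#' @param class_label `"singleton"` or `"duplicable"`.
#' @param family_id identifier used in gene names.
#' @param seed optional integer seed for this family's stream.
#' @param sequences simulate sequences (set `FALSE` for tree-only studies).
#' @return List with `tree` (phylo, tips "SPECIES|GENE"), `alignment`
#'   (named character vector of equal-length in-frame sequences, or NULL),
#'   and `truth` (one-row data frame).
#' @export
simulate_family <- function(cfg, class_label = c("singleton", "duplicable"),
                            family_id = "FAM1", seed = NULL,
                            sequences = TRUE) {
  class_label <- match.arg(class_label)
  if (!is.null(seed)) set.seed(seed)
  par <- draw_family_params(cfg, class_label, family_id)
  sp_tree <- cfg$species_tree

  if (class_label == "duplicable") {
    dup_tmp <- c(paste0(par$dup_species, "DUPA"),
                 paste0(par$dup_species, "DUPB"))
    tree <- add_duplication(sp_tree, par$dup_species, par$dup_frac, dup_tmp)
  } else {
    tree <- sp_tree
  }

  ## relabel tips as SPECIES|GENE
  lab <- tree$tip.label
  genes <- character(length(lab))
  for (k in seq_along(lab)) {
    sp <- sub("DUP[AB]$", "", lab[k])
    copy <- if (grepl("DUPB$", lab[k])) "_2" else
      if (grepl("DUPA$", lab[k])) "_1" else ""
    genes[k] <- paste0(sp, "|", family_id, "_", sp, copy)
    lab[k] <- genes[k]
  }
  tree$tip.label <- lab

  aln <- NULL
  if (sequences) {
    pi <- .pi_from_pos_freqs(cfg$pos_freqs)
    omega_edge <- rep(par$omega, nrow(tree$edge))
    if (class_label == "duplicable" && cfg$postdup_omega_factor != 1) {
      ptips <- which(label_species(tree$tip.label) == par$dup_species)
      mrca <- ape::getMRCA(tree, ptips)
      below <- which(tree$edge[, 1] == mrca)
      omega_edge[below] <- par$omega_postdup
    }
    st <- sim_codon_states(tree, pi, cfg$kappa, omega_edge, par$n_codons)
    cods <- sense_codons()
    aln <- vapply(st, function(s) paste(cods[s], collapse = ""), character(1))
  }

  truth <- data.frame(family_id = family_id, class = class_label,
                      omega = par$omega, omega_z = par$omega_z,
                      n_codons = par$n_codons,
                      dup_species = par$dup_species,
                      dup_frac = par$dup_frac,
                      omega_postdup = par$omega_postdup,
                      stringsAsFactors = FALSE)
  list(tree = tree, alignment = aln, truth = truth)
}

#' Simulate per-family covariates
#'
#' Expression (log2-RPKM-like, floored at 0) decreases with the family's
#' standardized log omega and carries a positive duplicable-group offset;
#' CDS length comes from the family truth (already omega- and
#' group-dependent); genomic length is CDS length inflated by a log10
#' intron factor with no group structure.
#'
#' @param cfg a [sim_config()].
#' @param truth data frame as produced by [simulate_family()] /
#'   [simulate_dataset()] (columns family_id, class, omega, n_codons).
#' @param seed optional seed for the covariate stream.
#' @return Data frame with gene_id, family_id, group, expression,
#'   cds_length, genomic_length.
#' @export
simulate_covariates <- function(cfg, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  dup <- truth$class == "duplicable"
  z <- .omega_z(cfg, truth$omega)
  em <- cfg$expression_model
  expr <- em$mean + em$group_offset * dup - em$slope * z +
    stats::rnorm(n, 0, em$sd)
  expr <- pmax(expr, 0)
  gm <- cfg$genomic_length_model
  cds_length <- 3 * truth$n_codons
  genomic_length <- round(cds_length *
                            10^stats::rnorm(n, gm$mean, gm$sd))
  data.frame(gene_id = paste0(truth$family_id, "_macaque"),
             family_id = truth$family_id,
             group = truth$class,
             expression = expr,
             cds_length = cds_length,
             genomic_length = pmax(genomic_length, cds_length),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic dataset
#'
#' @param cfg a [sim_config()].
#' @param sequences simulate codon alignments (default TRUE).
#' @return Object of class `"synthetic_dataset"`: `families` (named list
#'   of phylo), `alignments` (named list), `covariates`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg, sequences = TRUE) {
  n <- cfg$n_families
  seeds <- derive_seeds(cfg$seed, n + 2L)
  set.seed(seeds[n + 2L])
  n_dup <- if (cfg$fraction_duplicable > 0)
    max(1L, round(n * cfg$fraction_duplicable)) else 0L
  dup_idx <- if (n_dup > 0) sample.int(n, n_dup) else integer(0)
  classes <- rep("singleton", n)
  classes[dup_idx] <- "duplicable"
  ids <- sprintf("FAM%04d", seq_len(n))

  fams <- vector("list", n)
  for (i in seq_len(n)) {
    fams[[i]] <- simulate_family(cfg, classes[i], ids[i], seed = seeds[i],
                                 sequences = sequences)
  }
  truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
  covars <- simulate_covariates(cfg, truth, seed = seeds[n + 1L])
  structure(list(
    families = stats::setNames(lapply(fams, `[[`, "tree"), ids),
    alignments = stats::setNames(lapply(fams, `[[`, "alignment"), ids),
    covariates = covars, truth = truth, config = cfg),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic gene-family dataset: %d families (%d duplicable)\n",
              length(x$families), sum(x$truth$class == "duplicable")))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' One Newick file per family, one FASTA per family (in-frame, aligned),
#' a covariates TSV and a truth TSV, plus a manifest listing every file.
#'
#' @param ds a `"synthetic_dataset"`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a data frame manifest (family_id/kind/path).
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(file.path(out_dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  rows <- list()
  for (id in names(ds$families)) {
    tp <- file.path(out_dir, "trees", paste0(id, ".nwk"))
    ape::write.tree(ds$families[[id]], file = tp)
    rows[[length(rows) + 1]] <- data.frame(family_id = id, kind = "tree",
                                           path = tp)
    aln <- ds$alignments[[id]]
    if (!is.null(aln)) {
      ap <- file.path(out_dir, "alignments", paste0(id, ".fasta"))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln), ap)
      rows[[length(rows) + 1]] <- data.frame(family_id = id, kind = "alignment",
                                             path = ap)
    }
  }
  cv <- file.path(out_dir, "covariates.tsv")
  utils::write.table(ds$covariates, cv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tt <- file.path(out_dir, "truth.tsv")
  utils::write.table(ds$truth, tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rows[[length(rows) + 1]] <- data.frame(family_id = NA, kind = "covariates",
                                         path = cv)
  rows[[length(rows) + 1]] <- data.frame(family_id = NA, kind = "truth",
                                         path = tt)
  manifest <- do.call(rbind, rows)
  ## manifest on disk records paths relative to the run directory so the
  ## bundle is relocatable (and identical across reruns)
  rel <- manifest
  rel$path <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\])", "\\\\\\1", out_dir),
                         "/?"), "", rel$path)
  utils::write.table(rel, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing trees/, alignments/, covariates.tsv.
#' @return A `"synthetic_dataset"`-shaped list (truth may be absent for
#'   real data).
#' @export
read_dataset <- function(dir) {
  tfiles <- list.files(file.path(dir, "trees"), pattern = "\\.nwk$",
                       full.names = TRUE)
  ids <- sub("\\.nwk$", "", basename(tfiles))
  fams <- stats::setNames(lapply(tfiles, ape::read.tree), ids)
  alns <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    ap <- file.path(dir, "alignments", paste0(id, ".fasta"))
    if (file.exists(ap)) {
      x <- Biostrings::readDNAStringSet(ap)
      alns[[id]] <- stats::setNames(as.character(x), names(x))
    }
  }
  cv <- file.path(dir, "covariates.tsv")
  covars <- if (file.exists(cv))
    utils::read.delim(cv, stringsAsFactors = FALSE) else NULL
  tt <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(tt))
    utils::read.delim(tt, stringsAsFactors = FALSE) else NULL
  structure(list(families = fams, alignments = alns, covariates = covars,
                 truth = truth, config = NULL),
            class = "synthetic_dataset")
}
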