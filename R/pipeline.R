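## End-to-end orchestration: simulate (or load) gene families, classify
## them, estimate proxy-ancestral rates on the macaque-gibbon pair, filter,
## compare groups, run the covariate residual/randomization analysis and
## the post-duplication LRTs, and bundle everything into one reproducible
## report.

#' Run the full duplicability analysis
#'
#' @param cfg a [sim_config()] used when `data` is NULL.
#' @param data optional dataset (a `"synthetic_dataset"` or the result of
#'   [read_dataset()]); when NULL, one is simulated from `cfg`.
#' @param n_sims randomization draws for the covariate tests.
#' @param kde_perms label permutations for the 2D KDE residual-space test.
#' @param ds_min,omega_max rate filters (pairs with dS below `ds_min` or
#'   omega above `omega_max` are excluded from the rate analysis).
#' @param lowess_f LOWESS span.
#' @param run_lrt run the per-family asymmetry/acceleration LRTs.
#' @param run_covariates run the covariate analysis.
#' @param seed seed for the randomization/permutation stages (the
#'   simulation stage uses `cfg$seed`).
#' @return Object of class `"duplicability_run"`.
#' @export
run_duplicability <- function(cfg = sim_config(), data = NULL,
                              n_sims = 10000, kde_perms = 999,
                              ds_min = 0.01, omega_max = 10,
                              lowess_f = 0.3, run_lrt = TRUE,
                              run_covariates = TRUE, seed = 1L) {
  ds <- if (is.null(data)) simulate_dataset(cfg) else data
  n_input <- length(ds$families)

  ## ---- classification ------------------------------------------------
  cls <- classify_families(ds$families)
  counts <- table(factor(cls$label,
                         levels = c("singleton", "duplicable", "split",
                                    "excluded_missing",
                                    "excluded_ambiguous_loss")))
  stopifnot(sum(counts) == n_input)

  ## expand split families: each clean subtree becomes its own family,
  ## sharing the parent family's alignment
  fams <- ds$families
  alns <- ds$alignments
  for (id in cls$family_id[cls$label == "split"]) {
    sub <- classify_family(ds$families[[id]])$subtrees
    for (k in seq_along(sub)) {
      sid <- paste0(id, ".s", k)
      fams[[sid]] <- sub[[k]]
      alns[[sid]] <- ds$alignments[[id]]
      cls <- rbind(cls, classify_families(stats::setNames(sub[k], sid)))
    }
  }
  use <- cls[cls$label %in% c("singleton", "duplicable"), , drop = FALSE]

  ## ---- proxy-ancestral rates (macaque vs gibbon) ---------------------
  rate_rows <- list()
  for (r in seq_len(nrow(use))) {
    id <- use$family_id[r]
    aln <- alns[[id]]
    tree <- fams[[id]]
    if (is.null(aln)) next
    aln <- aln[names(aln) %in% tree$tip.label]
    sp <- label_species(names(aln))
    gi <- which(sp == "gibbon")[1]
    ma <- which(sp == "macaque")[1]
    est <- dnds_ml(aln[[gi]], aln[[ma]], names(aln)[c(gi, ma)])
    rate_rows[[id]] <- data.frame(
      family_id = id, group = use$label[r], dN = est$dN, dS = est$dS,
      omega = est$omega, kappa = est$kappa, t = est$t,
      gc3 = gc3_pair(aln), flag = est$flag, stringsAsFactors = FALSE)
  }
  rates <- do.call(rbind, rate_rows)
  rownames(rates) <- NULL
  fl <- rate_filter(rates, ds_min = ds_min, omega_max = omega_max)
  kept <- fl$retained

  ## ---- group comparison of rates -------------------------------------
  dup <- kept$group == "duplicable"
  group_stats <- list(
    n_duplicable = sum(dup), n_singleton = sum(!dup),
    medians = if (any(dup) && any(!dup)) list(
      dN = tapply(kept$dN, kept$group, stats::median),
      dS = tapply(kept$dS, kept$group, stats::median),
      omega = tapply(kept$omega, kept$group, stats::median)) else NULL)
  if (any(dup) && any(!dup)) {
    group_stats$mwu <- lapply(c(dN = "dN", dS = "dS", omega = "omega"),
                              function(v) mwu_test(kept[[v]][dup],
                                                   kept[[v]][!dup]))
    group_stats$mwu_omega_onesided <-
      suppressWarnings(stats::wilcox.test(kept$omega[dup], kept$omega[!dup],
                                          alternative = "greater"))$p.value
  } else {
    group_stats$no_duplicable <- !any(dup)
  }

  ## ---- covariate analysis --------------------------------------------
  covres <- NULL
  if (run_covariates && !is.null(ds$covariates) && any(dup) && any(!dup)) {
    rec <- merge(kept, ds$covariates[, c("family_id", "expression",
                                         "cds_length", "genomic_length")],
                 by = "family_id")
    rec$expression_log <- log10(rec$expression + 1)
    rec$cds_length_log10 <- log10(rec$cds_length)
    rec$genomic_length_log10 <- log10(rec$genomic_length)
    covs <- c("expression_log", "cds_length_log10",
              "genomic_length_log10", "gc3")
    set.seed(seed)
    covres <- list(records = rec)
    covres$correlations <- lapply(stats::setNames(covs, covs), function(v)
      tryCatch(correlate(rec$omega, rec[[v]], "spearman"),
               error = function(e) list(estimate = NA_real_, p = NA_real_)))
    covres$tests <- lapply(stats::setNames(covs, covs), function(v)
      covariate_randomization_test(rec, v, n_sims = n_sims, f = lowess_f))
    if (min(sum(rec$group == "duplicable"),
            sum(rec$group == "singleton")) >= 3)
      covres$model_selection <- dn_ds_model_selection(rec)
    re <- lowess_fit(rec$expression_log, rec$omega, f = lowess_f)$residuals
    rc <- lowess_fit(rec$cds_length_log10, rec$omega, f = lowess_f)$residuals
    rdup <- rec$group == "duplicable"
    if (sum(rdup) >= 5 && sum(!rdup) >= 5) {
      covres$kde2 <- kde2_test(cbind(re, rc)[rdup, , drop = FALSE],
                               cbind(re, rc)[!rdup, , drop = FALSE],
                               n_perms = kde_perms)
    }
  }

  ## ---- post-duplication LRTs -----------------------------------------
  lrt <- NULL
  if (run_lrt) {
    dup_ids <- use$family_id[use$label == "duplicable"]
    ## the asymmetry analysis keeps low-dS families (recent duplications);
    ## only the omega cap applies. The acceleration analysis applies both.
    pass_cap <- rates$family_id[!is.na(rates$omega) &
                                  rates$omega <= omega_max]
    pass_full <- fl$retained$family_id
    asym_rows <- list(); accel_rows <- list()
    for (id in dup_ids) {
      species <- strsplit(use$dup_species[use$family_id == id], ",")[[1]][1]
      tree <- fams[[id]]; aln <- alns[[id]]
      if (is.null(aln)) next
      aln <- aln[names(aln) %in% tree$tip.label]
      if (id %in% pass_cap) {
        at <- asymmetry_test(tree, aln, species)
        asym_rows[[id]] <- data.frame(family_id = id, species = species,
                                      lnL0 = at$lnL_null, lnL1 = at$lnL_alt,
                                      stat = at$statistic, df = at$df,
                                      p_raw = at$p_raw)
      }
      if (id %in% pass_full) {
        ac <- acceleration_test(tree, aln, species)
        accel_rows[[id]] <- data.frame(family_id = id, species = species,
                                       lnL0 = ac$lnL_null, lnL1 = ac$lnL_alt,
                                       stat = ac$statistic, df = ac$df,
                                       p_raw = ac$p_raw,
                                       direction = ac$direction,
                                       omega0 = ac$omegas_alt[1],
                                       omega1 = ac$omegas_alt[2])
      }
    }
    asym <- if (length(asym_rows)) do.call(rbind, asym_rows) else NULL
    accel <- if (length(accel_rows)) do.call(rbind, accel_rows) else NULL
    lrt <- list(asymmetry = asym, acceleration = accel)
    if (!is.null(asym)) {
      asym$p_fdr <- bh_fdr(asym$p_raw)
      lrt$asymmetry <- asym
      pp <- pmax(asym$p_raw, 1e-300)
      lrt$fisher_asymmetry <- fisher_combine(pp)
    }
    if (!is.null(accel)) {
      accel$p_fdr <- bh_fdr(accel$p_raw)
      lrt$acceleration <- accel
      k_fast <- sum(accel$direction == "faster")
      lrt$split <- list(faster = k_fast, slower = nrow(accel) - k_fast,
                        binomial_p = binomial_two_sided(k_fast, nrow(accel)))
      fast <- accel$p_raw[accel$direction == "faster"]
      if (length(fast))
        lrt$fisher_acceleration_faster <- fisher_combine(pmax(fast, 1e-300))
    }
  }

  structure(list(
    classification = cls, counts = as.list(counts), n_input = n_input,
    rates = rates, rates_retained = kept, rate_exclusions = fl$excluded,
    group_stats = group_stats, covariates = covres, lrt = lrt,
    truth = ds$truth, seed = seed, config = if (is.null(data)) cfg else NULL),
    class = "duplicability_run")
}

#' Classification accuracy against simulation truth
#'
#' @param run a `"duplicability_run"` with truth available.
#' @return Proportion of families whose label matches the simulated class.
#' @export
classification_accuracy <- function(run) {
  if (is.null(run$truth)) stop("no simulation truth in this run")
  m <- merge(run$classification, run$truth[, c("family_id", "class")],
             by = "family_id")
  mean(m$label == m$class)
}

#' @export
print.duplicability_run <- function(x, ...) {
  cat("Duplicability analysis run\n")
  cat(sprintf("  families: %d in; %d singleton, %d duplicable, %d split, %d excluded\n",
              x$n_input, x$counts$singleton, x$counts$duplicable,
              x$counts$split,
              x$counts$excluded_missing + x$counts$excluded_ambiguous_loss))
  cat(sprintf("  rate filter: %d retained, %d excluded\n",
              nrow(x$rates_retained), nrow(x$rate_exclusions)))
  gs <- x$group_stats
  if (!is.null(gs$medians)) {
    cat(sprintf("  median omega: duplicable %.3f vs singleton %.3f (MWU p = %.4g)\n",
                gs$medians$omega[["duplicable"]],
                gs$medians$omega[["singleton"]], gs$mwu$omega$p))
  } else if (isTRUE(gs$no_duplicable)) {
    cat("  no duplicable families after filtering\n")
  }
  if (!is.null(x$lrt$split))
    cat(sprintf("  acceleration split: %d faster / %d slower (binomial p = %.3g)\n",
                x$lrt$split$faster, x$lrt$split$slower,
                x$lrt$split$binomial_p))
  invisible(x)
}

#' @method summary duplicability_run
#' @export
summary.duplicability_run <- function(object, ...) {
  x <- report_list(object)
  class(x) <- "summary.duplicability_run"
  x
}

#' @export
print.summary.duplicability_run <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null"), "\n")
  invisible(x)
}

## flatten a run into plain lists for JSON
report_list <- function(run) {
  gs <- run$group_stats
  out <- list(
    n_input = run$n_input,
    counts = run$counts,
    rate_exclusions = as.list(table(run$rate_exclusions$reason)),
    n_retained = nrow(run$rates_retained),
    seed = run$seed)
  if (!is.null(gs$medians)) {
    out$medians <- lapply(gs$medians, as.list)
    out$mwu_p <- lapply(gs$mwu, `[[`, "p")
    out$mwu_W <- lapply(gs$mwu, `[[`, "W")
    out$mwu_omega_onesided_p <- gs$mwu_omega_onesided
  }
  if (isTRUE(gs$no_duplicable)) out$no_duplicable_families <- TRUE
  if (!is.null(run$covariates)) {
    out$correlations <- lapply(run$covariates$correlations, function(z)
      list(rho = z$estimate, p = z$p))
    out$covariate_tests <- lapply(run$covariates$tests, function(z)
      list(p_uncorrected = z$p_uncorrected, p_residual = z$p_residual,
           direction = z$direction, p_randomization = z$p_randomization,
           median_sim_p = z$median_sim_p, n_sims = z$n_sims))
    out$model_selection <- run$covariates$model_selection
    if (!is.null(run$covariates$kde2))
      out$kde2 <- run$covariates$kde2
  }
  if (!is.null(run$lrt)) {
    if (!is.null(run$lrt$asymmetry)) {
      out$asymmetry <- list(
        n = nrow(run$lrt$asymmetry),
        n_sig_raw = sum(run$lrt$asymmetry$p_raw < 0.05),
        n_sig_fdr = sum(run$lrt$asymmetry$p_fdr < 0.05),
        fisher = run$lrt$fisher_asymmetry)
    }
    if (!is.null(run$lrt$acceleration)) {
      out$acceleration <- list(
        n = nrow(run$lrt$acceleration),
        n_sig_raw = sum(run$lrt$acceleration$p_raw < 0.05),
        n_sig_fdr = sum(run$lrt$acceleration$p_fdr < 0.05),
        split = run$lrt$split,
        fisher_faster = run$lrt$fisher_acceleration_faster)
    }
  }
  if (!is.null(run$truth)) out$classification_accuracy <-
    classification_accuracy(run)
  out
}

#' Write a run report
#'
#' Emits a machine-readable JSON file and a human-readable markdown
#' summary whose every number is traceable to a JSON field.
#'
#' @param run a `"duplicability_run"`.
#' @param dir output directory.
#' @return Invisibly, the report list.
#' @export
report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lst <- report_list(run)
  jsonlite::write_json(lst, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  md <- c("# Duplicability analysis summary", "",
          sprintf("- families in: %d", lst$n_input),
          sprintf("- classification: %s",
                  paste(names(lst$counts), unlist(lst$counts),
                        sep = " = ", collapse = ", ")),
          sprintf("- rate-filter exclusions: %s",
                  if (length(lst$rate_exclusions))
                    paste(names(lst$rate_exclusions),
                          unlist(lst$rate_exclusions),
                          sep = " = ", collapse = ", ") else "none"),
          sprintf("- retained for rate analysis: %d", lst$n_retained))
  if (!is.null(lst$medians)) {
    md <- c(md, sprintf(
      "- median dN/dS: duplicable %.3f, singleton %.3f (MWU p = %.4g)",
      lst$medians$omega$duplicable, lst$medians$omega$singleton,
      lst$mwu_p$omega))
  }
  if (isTRUE(lst$no_duplicable_families))
    md <- c(md, "- no duplicable families after filtering")
  if (!is.null(lst$classification_accuracy))
    md <- c(md, sprintf("- classification accuracy vs truth: %.3f",
                        lst$classification_accuracy))
  writeLines(md, file.path(dir, "summary.md"))
  invisible(lst)
}
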