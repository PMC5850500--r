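## Codon-model likelihood on gene trees (Felsenstein pruning over the 61
## sense codons) with branch-class specific omega, powering the
## likelihood-ratio tests for post-duplication rate asymmetry and
## acceleration, plus the meta-analytic helpers (BH FDR, Fisher's method,
## chi-square tails, exact binomial split test).

## compress an alignment into tip-state patterns for the pruning core
aln_tipstates <- function(tree, aln) {
  labs <- tree$tip.label
  miss <- setdiff(labs, names(aln))
  if (length(miss))
    stop("alignment lacks sequences for: ", paste(miss, collapse = ", "))
  mats <- lapply(labs, function(l) codon_states(aln[[l]], l))
  len <- unique(vapply(mats, length, integer(1)))
  if (length(len) != 1) stop("sequences differ in codon length")
  m <- do.call(rbind, mats)          # ntip x ncodons
  m[is.na(m)] <- 0L
  key <- apply(m, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(tipstate = m[, first, drop = FALSE], w = as.numeric(tab))
}

.postorder_parts <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  list(edge = tr$edge, ord = ord, ntip = length(tree$tip.label),
       nnode = tree$Nnode)
}

#' Codon-model log-likelihood of a gene tree
#'
#' Exact pruning-algorithm log-likelihood of an in-frame codon alignment
#' on a rooted tree under the Goldman-Yang model, with a possibly distinct
#' omega per branch class. The model is time-reversible, so the value is
#' invariant to root placement.
#'
#' @param tree phylo; tip labels must index `aln`.
#' @param aln named character vector of aligned in-frame sequences.
#' @param kappa transition/transversion ratio.
#' @param omegas numeric vector, one omega per branch class.
#' @param branch_class integer vector (one entry per row of `tree$edge`)
#'   of 1-based indices into `omegas`; default all 1.
#' @param pi codon frequencies; default F3x4 from all sequences present in
#'   the tree.
#' @return Log-likelihood (numeric scalar).
#' @export
codon_loglik <- function(tree, aln, kappa, omegas, branch_class = NULL,
                         pi = NULL) {
  if (is.null(branch_class)) branch_class <- rep(1L, nrow(tree$edge))
  if (length(branch_class) != nrow(tree$edge))
    stop("branch_class must label every edge")
  if (max(branch_class) > length(omegas))
    stop("branch_class refers to a missing omega class")
  if (is.null(pi)) pi <- f3x4_frequencies(aln[tree$tip.label])
  ts <- aln_tipstates(tree, aln)
  po <- .postorder_parts(tree)
  cpp_tree_loglik(po$edge, tree$edge.length[po$ord],
                  as.integer(branch_class[po$ord]), po$ntip, po$nnode,
                  kappa, omegas, pi, codon_type_matrix(), ts$tipstate, ts$w)
}

#' Fit a branch-class codon model by maximum likelihood
#'
#' Maximizes the pruning likelihood over all branch lengths, kappa, and
#' one omega per branch class (bounded quasi-Newton on log parameters,
#' fixed restart schedule, so fits are deterministic).
#'
#' @inheritParams codon_loglik
#' @param kappa_init,omegas_init starting values; branch lengths start at
#'   the input tree's lengths.
#' @param extra_start add one perturbed restart (default TRUE).
#' @return Object of class `"codon_fit"`: fitted `tree` (updated edge
#'   lengths), `kappa`, `omegas`, `logL`, `npar`, `convergence`.
#' @export
fit_codon_model <- function(tree, aln, branch_class = NULL,
                            kappa_init = 2, omegas_init = NULL,
                            pi = NULL, extra_start = TRUE) {
  if (is.null(branch_class)) branch_class <- rep(1L, nrow(tree$edge))
  branch_class <- as.integer(branch_class)
  K <- max(branch_class)
  if (is.null(omegas_init)) omegas_init <- rep(0.3, K)
  if (length(omegas_init) != K)
    stop("need one initial omega per branch class")
  if (is.null(pi)) pi <- f3x4_frequencies(aln[tree$tip.label])
  ts <- aln_tipstates(tree, aln)
  po <- .postorder_parts(tree)
  type <- codon_type_matrix()
  E <- nrow(tree$edge)
  cls <- as.integer(branch_class[po$ord])

  negll <- function(par) {
    el <- exp(par[seq_len(E)])
    kappa <- exp(par[E + 1])
    om <- exp(par[E + 1 + seq_len(K)])
    -cpp_tree_loglik(po$edge, el, cls, po$ntip, po$nnode, kappa, om, pi,
                     type, ts$tipstate, ts$w)
  }
  ## analytic gradient for the branch lengths (bidirectional pruning),
  ## forward differences for kappa and the omegas
  negll_gr <- function(par) {
    el <- exp(par[seq_len(E)])
    kappa <- exp(par[E + 1])
    om <- exp(par[E + 1 + seq_len(K)])
    g <- cpp_tree_loglik_grad(po$edge, el, cls, po$ntip, po$nnode, kappa,
                              om, pi, type, ts$tipstate, ts$w)
    h <- 1e-5
    gk <- vapply(seq_len(K + 1), function(j) {
      pj <- par
      pj[E + j] <- pj[E + j] + h
      (negll(pj) + g$logL) / h
    }, numeric(1))
    c(-g$grad_el * el, gk)
  }
  lower <- c(rep(log(1e-7), E), log(0.05), rep(log(1e-4), K))
  upper <- c(rep(log(5), E), log(100), rep(log(50), K))
  el0 <- pmax(tree$edge.length[po$ord], 1e-6)
  start0 <- c(log(el0), log(kappa_init), log(omegas_init))
  starts <- list(start0)
  if (extra_start)
    starts <- c(starts, list(start0 + c(rep(0.3, E), 0.2, rep(-0.5, K))))

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    fit <- try(stats::optim(pmin(pmax(s, lower), upper), negll,
                            gr = negll_gr,
                            method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(factr = 1e7, maxit = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("branch-model optimization failed")
  tree_fit <- tree
  tree_fit$edge.length[po$ord] <- exp(best$par[seq_len(E)])
  structure(list(tree = tree_fit,
                 kappa = exp(best$par[E + 1]),
                 omegas = exp(best$par[E + 1 + seq_len(K)]),
                 branch_class = branch_class,
                 logL = -best$value,
                 npar = E + 1 + K,
                 pi = pi,
                 convergence = if (conv) "ok" else "no_convergence"),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("Branch-class codon model fit: logL = %.3f (%d parameters%s)\n",
              x$logL, x$npar,
              if (x$convergence != "ok") ", NOT converged" else ""))
  cat("  kappa =", format(x$kappa, digits = 4),
      " omega:", paste(format(x$omegas, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$logL, df = object$npar, class = "logLik")
}

#' @export
coef.codon_fit <- function(object, ...) {
  c(kappa = object$kappa,
    stats::setNames(object$omegas, paste0("omega", seq_along(object$omegas) - 1)))
}

## terminal edge indices (rows of tree$edge) of the given tips
.tip_edges <- function(tree, tips) {
  match(match(tips, tree$tip.label), tree$edge[, 2])
}

## all edges in the clade rooted at `node` (edges descending from it)
.clade_edges <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    rows <- which(tree$edge[, 1] == nd)
    out <- c(out, rows)
    ch <- tree$edge[rows, 2]
    stack <- c(stack, ch[ch > length(tree$tip.label)])
  }
  out
}

new_lrt <- function(lnL0, lnL1, df, direction = "n/a", omegas0 = NULL,
                    omegas1 = NULL, test = "lrt") {
  stat <- max(2 * (lnL1 - lnL0), 0)
  structure(list(lnL_null = lnL0, lnL_alt = lnL1, statistic = stat,
                 df = df, p_raw = chi2_upper_tail(stat, df),
                 p_fdr = NA_real_, direction = direction,
                 omegas_null = omegas0, omegas_alt = omegas1, test = test),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("%s LRT: 2dlnL = %.4f, df = %d, p = %.4g", x$test,
              x$statistic, x$df, x$p_raw))
  if (x$direction != "n/a") cat(" (", x$direction, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio test for asymmetric paralog evolution
#'
#' Null: one background omega plus a single shared omega on the terminal
#' branches of all paralogs of the duplicated species. Alternative: a
#' distinct omega per paralog branch. df = number of paralogs - 1. The
#' dS filter is deliberately not applied here (recent duplications would
#' otherwise be discarded wholesale).
#'
#' @param tree gene tree (phylo, "SPECIES|GENE" tips).
#' @param aln named character vector of aligned in-frame sequences.
#' @param duplicated_species species carrying >= 2 paralogs.
#' @param kappa_init,omega_init optimizer starting values.
#' @return `"lrt_result"` (the alternative fit is started from the null
#'   solution, so the statistic is never negative).
#' @export
asymmetry_test <- function(tree, aln, duplicated_species,
                           kappa_init = 2, omega_init = 0.3,
                           extra_start = FALSE) {
  sp <- label_species(tree$tip.label)
  tips <- tree$tip.label[sp == duplicated_species]
  k <- length(tips)
  if (k < 2) stop("species '", duplicated_species, "' has < 2 paralogs")
  tips <- tips[order(tips)]
  pe <- .tip_edges(tree, tips)
  pi <- f3x4_frequencies(aln[tree$tip.label])

  cls0 <- rep(1L, nrow(tree$edge)); cls0[pe] <- 2L
  fit0 <- fit_codon_model(tree, aln, cls0, kappa_init,
                          c(omega_init, omega_init), pi = pi,
                          extra_start = extra_start)
  cls1 <- rep(1L, nrow(tree$edge))
  for (i in seq_len(k)) cls1[pe[i]] <- i + 1L
  ## started at the null solution, so lnL_alt >= lnL_null by construction
  fit1 <- fit_codon_model(fit0$tree, aln, cls1, fit0$kappa,
                          c(fit0$omegas[1], rep(fit0$omegas[2], k)),
                          pi = pi, extra_start = extra_start)
  res <- new_lrt(fit0$logL, fit1$logL, df = k - 1L,
                 omegas0 = fit0$omegas, omegas1 = fit1$omegas,
                 test = "asymmetry")
  res$species <- duplicated_species
  res
}

#' Likelihood-ratio test for post-duplication rate acceleration
#'
#' Null: one omega for every branch. Alternative: a background omega plus
#' one shared post-duplication omega on all branches descending from the
#' duplication node (the MRCA of the paralogs). df = 1; direction is
#' `"faster"` when the fitted post-duplication omega exceeds the
#' background.
#'
#' @inheritParams asymmetry_test
#' @return `"lrt_result"` with `direction`.
#' @export
acceleration_test <- function(tree, aln, duplicated_species,
                              kappa_init = 2, omega_init = 0.3,
                              extra_start = FALSE) {
  sp <- label_species(tree$tip.label)
  tips <- which(sp == duplicated_species)
  if (length(tips) < 2)
    stop("species '", duplicated_species, "' has < 2 paralogs")
  mrca <- ape::getMRCA(tree, tips)
  pe <- .clade_edges(tree, mrca)
  pi <- f3x4_frequencies(aln[tree$tip.label])

  fit0 <- fit_codon_model(tree, aln, rep(1L, nrow(tree$edge)), kappa_init,
                          omega_init, pi = pi, extra_start = extra_start)
  cls1 <- rep(1L, nrow(tree$edge)); cls1[pe] <- 2L
  fit1 <- fit_codon_model(fit0$tree, aln, cls1, fit0$kappa,
                          c(fit0$omegas[1], fit0$omegas[1]), pi = pi,
                          extra_start = extra_start)
  dir <- if (fit1$omegas[2] > fit1$omegas[1]) "faster" else "slower"
  res <- new_lrt(fit0$logL, fit1$logL, df = 1L,
                 omegas0 = fit0$omegas, omegas1 = fit1$omegas,
                 test = "acceleration")
  res$direction <- dir
  res$omega_ratio <- fit1$omegas[2] / fit1$omegas[1]
  res$species <- duplicated_species
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector in [0, 1].
#' @return Step-up adjusted p-values (monotone, capped at 1).
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's method for combining p-values
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @return List with `chi2` (-2 sum log p), `df` (2k) and `p` (upper
#'   chi-square tail).
#' @export
fisher_combine <- function(pvalues) {
  if (!length(pvalues)) stop("no p-values supplied")
  if (any(pvalues <= 0))
    stop("p-values must be > 0 (zero gives an infinite statistic)")
  if (any(pvalues > 1)) stop("p-values must be <= 1")
  chi2 <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(chi2 = chi2, df = df, p = chi2_upper_tail(chi2, df))
}

#' Upper tail of the chi-square distribution
#'
#' @param statistic test statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @export
chi2_upper_tail <- function(statistic, df) {
  if (any(statistic < 0)) stop("statistic must be >= 0")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' Exact two-sided binomial test p-value
#'
#' Sums the point probabilities of all outcomes no more probable than the
#' observed count (for p0 = 0.5 this equals twice the one-sided tail,
#' capped at 1).
#'
#' @param k successes; `n` trials; `p0` null success probability.
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  stats::binom.test(k, n, p = p0)$p.value
}
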