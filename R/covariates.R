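## Covariate analysis: Mann-Whitney group comparisons of dN/dS, LOWESS
## residualization of omega on a covariate, randomization significance for
## the change in p-value, dN~dS model selection, a two-sample 2D KDE test
## on residual space, and rank/product-moment correlations.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with mid-ranks and tie-corrected variance;
#' exact when both groups are small and untied, normal approximation with
#' continuity correction otherwise (the standard `wilcox.test` behaviour).
#'
#' @param a,b numeric vectors (both nonempty).
#' @return List with `W` and `p`.
#' @export
mwu_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' LOWESS fit and residuals
#'
#' Locally weighted regression (tricube weights, robustness iterations)
#' of y on x with span `f`; fitted values at the observed x are obtained
#' by linear interpolation of the smoothed curve, exactly the
#' `lowess()` + `approxfun()` idiom. A degenerate x (all values equal)
#' falls back to the mean of y.
#'
#' @param x,y paired finite numeric vectors (n >= 10).
#' @param f smoother span (default 0.3).
#' @param iter robustness iterations (default 3).
#' @return List with `fitted`, `residuals` and the smoothed `curve`.
#' @export
lowess_fit <- function(x, y, f = 0.3, iter = 3) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("need at least 10 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (diff(range(x)) == 0) {
    fit <- rep(mean(y), length(y))
    return(list(fitted = fit, residuals = y - fit, curve = NULL))
  }
  lw <- stats::lowess(x, y, f = f, iter = iter)
  fn <- stats::approxfun(lw$x, lw$y, rule = 2, ties = mean)
  fit <- fn(x)
  list(fitted = fit, residuals = y - fit, curve = lw)
}

#' Group comparison of omega before and after LOWESS residualization
#'
#' @param records data frame with columns `group` ("singleton"/
#'   "duplicable"), `omega`, and the covariate.
#' @param covariate_name column to residualize omega on.
#' @param f smoother span.
#' @return List with `p_uncorrected`, `p_residual`, the W statistics and
#'   the residuals.
#' @export
residual_group_test <- function(records, covariate_name, f = 0.3) {
  if (!covariate_name %in% names(records))
    stop("no covariate column '", covariate_name, "'")
  x <- records[[covariate_name]]
  if (any(is.na(x))) stop("covariate '", covariate_name, "' has missing values")
  dup <- records$group == "duplicable"
  raw <- mwu_test(records$omega[dup], records$omega[!dup])
  lf <- lowess_fit(x, records$omega, f = f)
  res <- mwu_test(lf$residuals[dup], lf$residuals[!dup])
  list(p_uncorrected = raw$p, p_residual = res$p,
       W_uncorrected = raw$W, W_residual = res$W,
       residuals = lf$residuals)
}

#' Randomization significance of a residual-corrected p-value change
#'
#' Permutes the covariate values without replacement, recomputes the
#' LOWESS residuals and the group Mann-Whitney p for each permutation, and
#' reports how often a simulant p is as extreme or more extreme than the
#' observed residual p, in the direction of the observed change (masking:
#' the corrected p decreased, so simulants with p <= observed count;
#' explaining: it increased, so simulants with p >= observed count). The
#' reported p is the count divided by the number of simulations.
#'
#' @inheritParams residual_group_test
#' @param n_sims number of permutations (>= 1).
#' @param direction `"auto"` (from the observed change), `"masking"` or
#'   `"explaining"`.
#' @param seed optional RNG seed, recorded in the result.
#' @return List of class `"randomization_result"`.
#' @export
covariate_randomization_test <- function(records, covariate_name,
                                         n_sims = 10000,
                                         direction = c("auto", "masking",
                                                       "explaining"),
                                         f = 0.3, seed = NULL) {
  direction <- match.arg(direction)
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- residual_group_test(records, covariate_name, f = f)
  if (direction == "auto") {
    direction <- if (obs$p_residual <= obs$p_uncorrected) "masking"
    else "explaining"
  }
  x <- records[[covariate_name]]
  dup <- records$group == "duplicable"
  sims <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    xs <- sample(x)                   # reuse the original values
    lf <- lowess_fit(xs, records$omega, f = f)
    sims[s] <- mwu_test(lf$residuals[dup], lf$residuals[!dup])$p
  }
  n_extreme <- if (direction == "masking") sum(sims <= obs$p_residual)
  else sum(sims >= obs$p_residual)
  structure(list(p_uncorrected = obs$p_uncorrected,
                 p_residual = obs$p_residual,
                 direction = direction,
                 n_sims = n_sims, n_as_extreme = n_extreme,
                 p_randomization = n_extreme / n_sims,
                 median_sim_p = stats::median(sims),
                 seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  lab <- if (x$n_as_extreme == 0)
    sprintf("< %g (0 of %d simulants as extreme)", 1 / x$n_sims, x$n_sims)
  else sprintf("%g (%d of %d)", x$p_randomization, x$n_as_extreme, x$n_sims)
  cat(sprintf(paste0("Covariate randomization test (%s)\n",
                     "  p uncorrected = %.4g, p residual = %.4g\n",
                     "  randomization p = %s; median simulant p = %.4g\n"),
              x$direction, x$p_uncorrected, x$p_residual, lab,
              x$median_sim_p))
  invisible(x)
}

#' Model selection for dN ~ dS with a duplication-status interaction
#'
#' Compares least-squares fits of dN on dS against dN on
#' dS + status + dS:status by AIC and a nested-model F test.
#'
#' @param records data frame with columns `dN`, `dS`, `group`.
#' @return List with `AIC_null`, `AIC_interaction`, `F`, `p` and the
#'   interaction coefficient.
#' @export
dn_ds_model_selection <- function(records) {
  for (g in c("singleton", "duplicable"))
    if (sum(records$group == g) < 3)
      stop("need at least 3 records per group")
  records$status <- factor(records$group,
                           levels = c("singleton", "duplicable"))
  m0 <- stats::lm(dN ~ dS, data = records)
  m1 <- stats::lm(dN ~ dS + status + dS:status, data = records)
  an <- stats::anova(m0, m1)
  list(AIC_null = stats::AIC(m0), AIC_interaction = stats::AIC(m1),
       F = an$F[2], p = an$`Pr(>F)`[2],
       interaction_coef = unname(stats::coef(m1)["dS:statusduplicable"]))
}

## closed-form integrated squared difference of two diagonal-bandwidth
## Gaussian KDEs: all cross terms are Gaussian convolutions
.kde2_ise <- function(a, b) {
  bw <- function(m) {
    n <- nrow(m)
    h <- apply(m, 2, stats::sd) * n^(-1 / 6)
    pmax(h, 1e-8)
  }
  ha <- bw(a); hb <- bw(b)
  cross <- function(x, y, h2) {
    ## mean over all pairs of the N(0, diag(h2)) density at x_i - y_j
    t1 <- outer(x[, 1], y[, 1], "-")
    t2 <- outer(x[, 2], y[, 2], "-")
    mean(stats::dnorm(t1, sd = sqrt(h2[1])) *
           stats::dnorm(t2, sd = sqrt(h2[2])))
  }
  cross(a, a, 2 * ha^2) + cross(b, b, 2 * hb^2) -
    2 * cross(a, b, ha^2 + hb^2)
}

#' Two-sample 2D kernel density test
#'
#' Statistic: integrated squared difference between the 2D Gaussian kernel
#' density estimates of the two samples (diagonal plug-in bandwidths,
#' sd * n^(-1/6) per dimension); significance by permutation of the group
#' labels over the pooled sample.
#'
#' @param a,b two-column numeric matrices (>= 5 rows each).
#' @param n_perms number of label permutations.
#' @param seed optional RNG seed.
#' @return List with `statistic` and permutation `p`.
#' @export
kde2_test <- function(a, b, n_perms = 999, seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 2 || ncol(b) != 2) stop("inputs must be 2D")
  if (nrow(a) < 5 || nrow(b) < 5) stop("need >= 5 points per group")
  if (any(apply(a, 2, stats::sd) == 0) || any(apply(b, 2, stats::sd) == 0))
    stop("degenerate (zero-variance) dimension")
  if (!is.null(seed)) set.seed(seed)
  obs <- .kde2_ise(a, b)
  pool <- rbind(a, b)
  na <- nrow(a)
  cnt <- 0L
  for (k in seq_len(n_perms)) {
    idx <- sample.int(nrow(pool), na)
    if (.kde2_ise(pool[idx, , drop = FALSE],
                  pool[-idx, , drop = FALSE]) >= obs) cnt <- cnt + 1L
  }
  list(statistic = obs, p = (cnt + 1) / (n_perms + 1), n_perms = n_perms)
}

#' Correlation with significance
#'
#' @param x,y numeric vectors (n >= 3).
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `estimate` and `p`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ht$estimate), p = ht$p.value)
}
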