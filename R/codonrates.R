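## Pairwise evolutionary-rate estimation between two aligned coding
## sequences: maximum likelihood under the Goldman-Yang codon model with
## F3x4 frequencies (the codeml pairwise mode), and the Nei-Gojobori (1986)
## counting method with Jukes-Cantor correction as an independent oracle.

.pair_patterns <- function(x, y, labels = c("seq1", "seq2")) {
  ix <- codon_states(x, labels[1])
  iy <- codon_states(y, labels[2])
  if (length(ix) != length(iy)) stop("sequences differ in codon length")
  keep <- !is.na(ix) & !is.na(iy)   # pairwise deletion of gap/ambiguity
  if (!any(keep)) stop("no usable ungapped codon columns in pair")
  ix <- ix[keep]; iy <- iy[keep]
  key <- (ix - 1L) * 61L + iy
  tab <- table(key)
  k <- as.integer(names(tab))
  list(i = (k - 1L) %/% 61L + 1L, j = (k - 1L) %% 61L + 1L,
       w = as.numeric(tab), n = sum(keep))
}

new_dnds <- function(dN, dS, omega, kappa, t, logL, n_codons, method,
                     flag = "ok") {
  structure(list(dN = dN, dS = dS, omega = omega, kappa = kappa, t = t,
                 logL = logL, n_codons = n_codons, method = method,
                 flag = flag),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf(
    "Pairwise rate estimate (%s%s)\n  dN = %.5f  dS = %.5f  dN/dS = %s\n",
    x$method, if (x$flag != "ok") paste0(", ", x$flag) else "",
    x$dN, x$dS, if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega)))
  if (!is.na(x$t))
    cat(sprintf("  t = %.5f  kappa = %.3f  logL = %.3f  (%d codons)\n",
                x$t, x$kappa, x$logL, x$n_codons))
  invisible(x)
}

#' @export
coef.dnds <- function(object, ...) {
  c(dN = object$dN, dS = object$dS, omega = object$omega,
    kappa = object$kappa, t = object$t)
}

#' @export
logLik.dnds <- function(object, ...) {
  structure(object$logL, df = 3L, class = "logLik")
}

#' Pairwise dN/dS by maximum likelihood
#'
#' Fits (t, kappa, omega) by maximum likelihood for two aligned in-frame
#' coding sequences under the Goldman-Yang codon model with F3x4
#' frequencies estimated jointly from the pair. Codon columns containing a
#' gap or ambiguity in either sequence are dropped (pairwise deletion).
#' dN and dS follow from the fitted parameters by the standard flux
#' decomposition, so omega = dN/dS equals the fitted ratio.
#'
#' @param x,y aligned nucleotide sequences (equal length, in frame).
#' @param labels optional labels used in error messages.
#' @return An object of class `"dnds"`.
#' @seealso [dnds_ng86()] for the counting oracle.
#' @export
dnds_ml <- function(x, y, labels = c("seq1", "seq2")) {
  pat <- .pair_patterns(x, y, labels)
  pi <- f3x4_frequencies(c(x, y))
  type <- codon_type_matrix()
  i0 <- pat$i - 1L; j0 <- pat$j - 1L

  if (all(pat$i == pat$j)) {
    ll <- sum(pat$w * log(pi[pat$i]))
    return(new_dnds(0, 0, NA_real_, NA_real_, 0, ll, pat$n, "ML_F3x4",
                    flag = "identical"))
  }

  negll <- function(par) {
    -cpp_pair_loglik(pi, exp(par[2]), exp(par[3]), exp(par[1]),
                     type, i0, j0, pat$w)
  }
  lower <- log(c(1e-6, 0.05, 1e-4))
  upper <- log(c(20, 100, 50))
  starts <- list(log(c(0.2, 2, 0.4)), log(c(0.05, 1.5, 0.1)),
                 log(c(0.6, 3, 1.0)))
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    fit <- try(stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(factr = 1e7, maxit = 300)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("pairwise ML optimization failed")
  t <- exp(best$par[1]); kappa <- exp(best$par[2]); omega <- exp(best$par[3])
  dec <- dnds_decompose(t, kappa, omega, pi)
  new_dnds(dec$dN, dec$dS, omega, kappa, t, -best$value, pat$n, "ML_F3x4",
           flag = if (conv) "ok" else "no_convergence")
}

## ---- Nei-Gojobori 1986 counting oracle -------------------------------

## synonymous site fraction per codon: at each position, fraction of
## non-stop single-nucleotide changes that are synonymous
.ng86_sites <- function() {
  if (!is.null(.codon_env$ng_sites)) return(.codon_env$ng_sites)
  codons <- sense_codons()
  aa <- codon_amino_acids()
  nt <- c("T", "C", "A", "G")
  gcode <- Biostrings::GENETIC_CODE
  s <- numeric(length(codons))
  for (k in seq_along(codons)) {
    cm <- strsplit(codons[k], "")[[1]]
    tot <- 0
    for (p in 1:3) {
      alts <- setdiff(nt, cm[p])
      nsyn <- 0; nvalid <- 0
      for (a in alts) {
        mut <- cm; mut[p] <- a
        mutc <- paste(mut, collapse = "")
        if (gcode[mutc] == "*") next
        nvalid <- nvalid + 1
        if (gcode[mutc] == aa[k]) nsyn <- nsyn + 1
      }
      if (nvalid > 0) tot <- tot + nsyn / nvalid
    }
    s[k] <- tot
  }
  .codon_env$ng_sites <- s
  s
}

## pathway-averaged synonymous and total differences between codon pairs;
## paths through stop codons are skipped unless all paths are blocked, in
## which case steps to or from a stop count as nonsynonymous
.ng86_diffs <- function() {
  if (!is.null(.codon_env$ng_diffs)) return(.codon_env$ng_diffs)
  codons <- sense_codons()
  gcode <- Biostrings::GENETIC_CODE
  n <- length(codons)
  sd <- matrix(0, n, n)
  nd <- matrix(0, n, n)
  path_counts <- function(c1, c2, allow_stop) {
    p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
    diffpos <- which(p1 != p2)
    perms <- switch(as.character(length(diffpos)),
                    "1" = list(diffpos),
                    "2" = list(diffpos, rev(diffpos)),
                    "3" = {
                      pm <- list()
                      for (a in diffpos) for (b in setdiff(diffpos, a))
                        pm[[length(pm) + 1]] <- c(a, b, setdiff(diffpos, c(a, b)))
                      pm
                    })
    res <- NULL
    for (ord in perms) {
      cur <- p1; syn <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- p2[pos]
        a1 <- gcode[paste(cur, collapse = "")]
        a2 <- gcode[paste(nxt, collapse = "")]
        if (a2 == "*" && paste(nxt, collapse = "") != c2 && !allow_stop) {
          ok <- FALSE; break
        }
        if (a1 == a2 && a1 != "*") syn <- syn + 1
        cur <- nxt
      }
      if (ok) res <- c(res, syn)
    }
    res
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ndiff <- sum(strsplit(codons[i], "")[[1]] != strsplit(codons[j], "")[[1]])
      syns <- path_counts(codons[i], codons[j], allow_stop = FALSE)
      if (is.null(syns)) syns <- path_counts(codons[i], codons[j], TRUE)
      sd[i, j] <- mean(syns)
      nd[i, j] <- ndiff - mean(syns)
    }
  }
  .codon_env$ng_diffs <- list(sd = sd, nd = nd)
  .codon_env$ng_diffs
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Counts synonymous and nonsynonymous sites (per-position fractions of
#' synonymous single-nucleotide changes, averaged over the two sequences)
#' and pathway-averaged synonymous/nonsynonymous differences, then applies
#' the Jukes-Cantor correction to each proportion. Serves as an
#' independent, optimization-free cross-check on [dnds_ml()].
#'
#' @inheritParams dnds_ml
#' @return An object of class `"dnds"`; `omega` is `NA` (flag
#'   `"undefined_omega"`) when dS = 0, and the estimate is flagged
#'   `"saturated"` when a proportion exceeds the Jukes-Cantor domain.
#' @export
dnds_ng86 <- function(x, y, labels = c("seq1", "seq2")) {
  pat <- .pair_patterns(x, y, labels)
  sites <- .ng86_sites()
  dif <- .ng86_diffs()
  S <- sum(pat$w * (sites[pat$i] + sites[pat$j]) / 2)
  N <- 3 * pat$n - S
  Sd <- sum(pat$w * dif$sd[cbind(pat$i, pat$j)])
  Nd <- sum(pat$w * dif$nd[cbind(pat$i, pat$j)])
  ps <- if (S > 0) Sd / S else 0   # no synonymous sites and none used
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(ps); dN <- jc(pn)
  flag <- "ok"
  if (is.na(dS) || is.na(dN)) flag <- "saturated"
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  if (flag == "ok" && is.na(omega)) flag <- "undefined_omega"
  new_dnds(dN, dS, omega, NA_real_, NA_real_, NA_real_, pat$n, "NG86", flag)
}

#' Filter rate estimates the way the rate analysis requires
#'
#' Retains estimates with dS >= `ds_min` and a defined omega <= `omega_max`
#' (low-dS pairs can carry wildly inflated dN/dS). Exclusions are logged
#' with a reason.
#'
#' @param rates data frame with columns `dS` and `omega`.
#' @param ds_min,omega_max filter thresholds.
#' @return List with `retained` and `excluded` (extra column `reason`).
#' @export
rate_filter <- function(rates, ds_min = 0.01, omega_max = 10) {
  reason <- rep(NA_character_, nrow(rates))
  reason[is.na(rates$omega)] <- "undefined_omega"
  reason[is.na(reason) & rates$dS < ds_min] <- "low_dS"
  reason[is.na(reason) & rates$omega > omega_max] <- "high_omega"
  keep <- is.na(reason)
  list(retained = rates[keep, , drop = FALSE],
       excluded = cbind(rates[!keep, , drop = FALSE],
                        reason = reason[!keep]))
}

#' Mean rate over the paralog-macaque pairs of a family
#'
#' For a duplicable family each paralog is compared with the macaque
#' ortholog; the family rate is the arithmetic mean of the per-paralog
#' dN, dS and omega.
#'
#' @param estimates list of `"dnds"` objects (or a data frame with columns
#'   dN, dS, omega).
#' @return An object of class `"dnds"` with method `"paralog_mean"`.
#' @export
paralog_mean_rate <- function(estimates) {
  if (is.data.frame(estimates)) {
    df <- estimates
  } else {
    if (!length(estimates)) stop("no paralog estimates supplied")
    df <- do.call(rbind, lapply(estimates, function(e)
      data.frame(dN = e$dN, dS = e$dS, omega = e$omega)))
  }
  if (!nrow(df)) stop("no paralog estimates supplied")
  new_dnds(mean(df$dN), mean(df$dS), mean(df$omega), NA_real_, NA_real_,
           NA_real_, NA_integer_, "paralog_mean")
}

#' GC content at third codon positions
#'
#' @param x nucleotide sequence (aligned; gapped codons ignored).
#' @return Percentage of G or C at third codon positions over ungapped
#'   codons.
#' @export
gc3 <- function(x) {
  cods <- split_codons(x)
  cods <- cods[!grepl("[^ACGT]", cods)]
  if (!length(cods)) stop("no ungapped codons")
  third <- substr(cods, 3, 3)
  100 * mean(third %in% c("G", "C"))
}

#' Mean macaque/gibbon GC3 for a family alignment
#'
#' @param aln named character vector of aligned sequences with
#'   "SPECIES|GENE" names.
#' @param species two species whose values are averaged.
#' @export
gc3_pair <- function(aln, species = c("macaque", "gibbon")) {
  sp <- label_species(names(aln))
  vals <- vapply(species, function(s) {
    idx <- which(sp == s)
    if (!length(idx)) stop("species '", s, "' missing from alignment")
    mean(vapply(aln[idx], gc3, numeric(1)))
  }, numeric(1))
  mean(vals)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino acid is replaced by the codon that encodes it in the
#' corresponding CDS, and each protein gap by `"---"`. The CDS must
#' translate exactly (standard code; one trailing stop codon tolerated) to
#' the ungapped protein.
#'
#' @param protein_aln named character vector of aligned protein sequences.
#' @param cds_map named character vector of unaligned nucleotide CDS,
#'   names matching `protein_aln`.
#' @return Named character vector of aligned nucleotide sequences (length
#'   3x the protein alignment).
#' @export
backtranslate <- function(protein_aln, cds_map) {
  out <- vapply(names(protein_aln), function(id) {
    prot <- strsplit(protein_aln[[id]], "")[[1]]
    cds <- cds_map[[id]]
    if (is.null(cds) || is.na(cds)) stop("no CDS for sequence '", id, "'")
    cods <- split_codons(cds)
    aa <- unname(Biostrings::GENETIC_CODE[cods])
    if (length(aa) && aa[length(aa)] == "*") {
      cods <- cods[-length(cods)]
      aa <- aa[-length(aa)]
    }
    res <- prot[prot != "-"]
    if (length(aa) != length(res))
      stop("CDS of '", id, "' has ", length(aa),
           " codons but protein has ", length(res), " residues")
    mism <- which(aa != res)
    if (length(mism))
      stop("translation mismatch in '", id, "' at residue ", mism[1],
           ": codon ", cods[mism[1]], " encodes ", aa[mism[1]],
           ", protein has ", res[mism[1]])
    codout <- character(length(prot))
    codout[prot == "-"] <- "---"
    codout[prot != "-"] <- cods
    paste(codout, collapse = "")
  }, character(1))
  names(out) <- names(protein_aln)
  out
}
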