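## Shared codon-model machinery: 61-codon state space (universal code),
## single-change classification, F3x4 frequencies, rate-matrix flux
## decomposition into dN and dS.

.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons (TCAG ordering, stop
#'   codons removed).
#' @export
sense_codons <- function() {
  if (is.null(.codon_env$codons)) .init_codon_tables()
  .codon_env$codons
}

#' Amino acid translation of the sense codons
#' @return Named character vector mapping codon to one-letter amino acid.
#' @export
codon_amino_acids <- function() {
  if (is.null(.codon_env$aa)) .init_codon_tables()
  .codon_env$aa
}

.init_codon_tables <- function() {
  nt <- c("T", "C", "A", "G")
  all64 <- as.vector(t(outer(
    as.vector(t(outer(nt, nt, paste0))), nt, paste0)))
  gc <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc[all64])
  keep <- aa64 != "*"
  codons <- all64[keep]
  aa <- aa64[keep]
  names(aa) <- codons

  n <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  type <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffpos <- which(cmat[i, ] != cmat[j, ])
      if (length(diffpos) != 1L) next
      ts <- is_ts(cmat[i, diffpos], cmat[j, diffpos])
      syn <- aa[i] == aa[j]
      code <- if (syn && !ts) 1L else if (syn && ts) 2L else
        if (!syn && !ts) 3L else 4L
      type[i, j] <- code
      type[j, i] <- code
    }
  }
  .codon_env$codons <- codons
  .codon_env$aa <- aa
  .codon_env$type <- type
  .codon_env$index <- stats::setNames(seq_len(n), codons)
  invisible(NULL)
}

codon_type_matrix <- function() {
  if (is.null(.codon_env$type)) .init_codon_tables()
  .codon_env$type
}

codon_index <- function() {
  if (is.null(.codon_env$index)) .init_codon_tables()
  .codon_env$index
}

#' Split a nucleotide string into codons
#'
#' @param x single nucleotide string, length divisible by 3.
#' @return Character vector of codons.
#' @export
split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3 != 0) stop("sequence length ", n, " is not divisible by 3")
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

## Integer codon states for one sequence: 1..61, NA for '---' or any codon
## containing a non-ACGT symbol. A partial-codon gap or an in-frame stop
## codon is a data error.
codon_states <- function(x, label = "sequence") {
  cods <- split_codons(x)
  idx <- unname(codon_index()[cods])
  gap <- cods == "---"
  amb <- !gap & grepl("[^ACGT]", cods)
  partial <- grepl("-", cods) & !gap
  if (any(partial)) {
    stop("partial-codon gap in ", label, " at codon ",
         which(partial)[1])
  }
  stopc <- is.na(idx) & !gap & !amb
  if (any(stopc)) {
    stop("in-frame stop codon '", cods[which(stopc)[1]], "' in ", label,
         " at codon ", which(stopc)[1])
  }
  idx[gap | amb] <- NA_integer_
  idx
}

#' F3x4 codon frequencies from sequences
#'
#' Position-specific nucleotide frequencies are tabulated over the ungapped
#' codons of all supplied sequences; codon frequencies are the product of
#' the three positional frequencies with stop codons removed and the vector
#' renormalized (the `CodonFreq = 2` convention of codon-model software).
#' Positional frequencies are floored at 1e-6 so that short sequences never
#' yield a degenerate rate matrix.
#'
#' @param seqs character vector of aligned nucleotide sequences.
#' @return Numeric vector of length 61 summing to 1.
#' @export
f3x4_frequencies <- function(seqs) {
  nt <- c("T", "C", "A", "G")
  counts <- matrix(0, 3, 4, dimnames = list(NULL, nt))
  for (s in seqs) {
    cods <- split_codons(s)
    cods <- cods[!grepl("[^ACGT]", cods)]
    if (!length(cods)) next
    m <- do.call(rbind, strsplit(cods, ""))
    for (p in 1:3) {
      tb <- table(factor(m[, p], levels = nt))
      counts[p, ] <- counts[p, ] + as.numeric(tb)
    }
  }
  freq <- counts / pmax(rowSums(counts), 1)
  freq <- pmax(freq, 1e-6)
  freq <- freq / rowSums(freq)
  codons <- sense_codons()
  cm <- do.call(rbind, strsplit(codons, ""))
  pi <- freq[1, cm[, 1]] * freq[2, cm[, 2]] * freq[3, cm[, 3]]
  pi <- pmax(pi, 1e-10)
  pi / sum(pi)
}

#' Codon substitution rate matrix
#'
#' Builds the 61x61 generator of the Goldman-Yang style codon model
#' (single-nucleotide changes only, transition/transversion ratio `kappa`,
#' nonsynonymous/synonymous ratio `omega`, target-codon frequencies `pi`),
#' scaled to one expected substitution per codon per unit time.
#'
#' @param pi codon frequency vector (length 61).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @return 61x61 rate matrix.
#' @export
codon_rate_matrix <- function(pi, kappa, omega) {
  stopifnot(length(pi) == 61, kappa > 0, omega >= 0)
  cpp_codon_Q(pi, kappa, omega, codon_type_matrix())
}

## Proportion of the substitution flux that is synonymous, at given
## (kappa, omega).
.syn_flux <- function(pi, kappa, omega) {
  Q <- cpp_codon_Q(pi, kappa, omega, codon_type_matrix())
  type <- codon_type_matrix()
  syn <- type == 1L | type == 2L
  sum((pi * Q)[syn])
}

#' Decompose a codon-model divergence into dN and dS
#'
#' Given ML parameters (t in expected substitutions per codon, kappa,
#' omega), computes dN and dS by the standard flux decomposition: the
#' proportions of synonymous and nonsynonymous substitutions under the
#' fitted model, normalized by the numbers of synonymous and nonsynonymous
#' sites (the same proportions computed at omega = 1).
#'
#' @param t divergence in substitutions per codon.
#' @param kappa,omega model parameters.
#' @param pi codon frequencies.
#' @return List with `dN`, `dS`, `S` and `N` (sites per codon, S + N = 3).
#' @export
dnds_decompose <- function(t, kappa, omega, pi) {
  rho_s1 <- .syn_flux(pi, kappa, 1)
  rho_s <- .syn_flux(pi, kappa, omega)
  S <- 3 * rho_s1
  N <- 3 - S
  list(dS = t * rho_s / S, dN = t * (1 - rho_s) / N, S = S, N = N)
}
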