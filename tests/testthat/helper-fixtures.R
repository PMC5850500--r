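# shared fixtures: small simulation configs and direct two-sequence
# simulators used across the test files

small_cfg <- function(seed = 1, n_families = 20, n_codons = 150, ...) {
  sim_config(n_families = n_families, seed = seed,
             n_codons = list(meanlog = log(n_codons), sdlog = 0,
                             slope = 0, group_offset = 0,
                             range = c(30, 3000)),
             ...)
}

default_pi <- function() {
  duplicability:::.pi_from_pos_freqs(duplicability:::.default_pos_freqs())
}

# evolve one pair of sequences at divergence t under (kappa, omega)
sim_pair <- function(t, kappa, omega, n_codons, pi = default_pi()) {
  type <- duplicability:::codon_type_matrix()
  root <- sample.int(61L, n_codons, TRUE, prob = pi)
  P <- duplicability:::cpp_pmatrix(pi, kappa, omega, type, t)
  y <- integer(n_codons)
  for (s in unique(root)) {
    idx <- which(root == s)
    y[idx] <- sample.int(61L, length(idx), TRUE, prob = P[s, ])
  }
  cods <- sense_codons()
  c(paste(cods[root], collapse = ""), paste(cods[y], collapse = ""))
}

# string of n identical codons
codon_rep <- function(codon, n) paste(rep(codon, n), collapse = "")
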