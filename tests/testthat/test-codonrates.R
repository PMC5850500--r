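test_that("back-translation maps residues to codons and gaps to ---", {
  expect_equal(unname(backtranslate(c(a = "M-K"), c(a = "ATGAAA"))),
               "ATG---AAA")
  # ungapped input returns the CDS itself (trailing stop tolerated)
  expect_equal(unname(backtranslate(c(a = "MK"), c(a = "ATGAAATAA"))),
               "ATGAAA")
  # translation mismatch names the sequence and position
  expect_error(backtranslate(c(bad = "MM"), c(bad = "ATGAAA")),
               "bad.*residue 2")
})

test_that("identical sequences give zero divergence under both methods", {
  s <- codon_rep("ATG", 30)
  ml <- dnds_ml(s, s)
  expect_equal(ml$dN, 0)
  expect_equal(ml$dS, 0)
  expect_equal(ml$t, 0)
  ng <- dnds_ng86(s, s)
  expect_equal(ng$dN, 0)
  expect_equal(ng$dS, 0)
  expect_true(is.na(ng$omega))
})

test_that("NG86 matches hand-computed site and difference counts", {
  # TTTGCGAAA vs TTAGCAAGA, derived by direct application of the counting
  # rules (stop codons excluded from both numerator and denominator of the
  # site fractions):
  #   syn sites: TTT 1/3, GCG 1, AAA 1/3 (seq1 = 5/3)
  #              TTA 2/3, GCA 1, AGA 5/6 (seq2 = 5/2); S = 25/12
  #   differences: TTT-TTA nonsyn, GCG-GCA syn, AAA-AGA nonsyn
  #   ps = 12/25, pn = 24/83; JC: dS = -3/4 log(0.36), dN = -3/4 log(1 - 32/83)
  est <- dnds_ng86("TTTGCGAAA", "TTAGCAAGA")
  expect_equal(est$dS, -0.75 * log(1 - (4 / 3) * (12 / 25)), tolerance = 1e-12)
  expect_equal(est$dN, -0.75 * log(1 - (4 / 3) * (24 / 83)), tolerance = 1e-12)

  # synonymous-only divergence: dN = 0, dS > 0 (kept inside the
  # Jukes-Cantor domain by changing a minority of codons)
  a <- codon_rep("GGC", 40)
  b <- paste0(codon_rep("GGT", 5), codon_rep("GGC", 35))
  est2 <- dnds_ng86(a, b)
  expect_equal(est2$dN, 0)
  expect_gt(est2$dS, 0)

  # two-position difference averages over pathways: AAA-GAG has one
  # synonymous step on either path (via GAA or AAG)
  est3 <- dnds_ng86(codon_rep("AAA", 10),
                    paste0(codon_rep("GAG", 2), codon_rep("AAA", 8)))
  dif <- duplicability:::.ng86_diffs()
  i <- which(sense_codons() == "AAA"); j <- which(sense_codons() == "GAG")
  expect_equal(dif$sd[i, j], 1)
  expect_equal(dif$nd[i, j], 1)
  expect_gt(est3$dN, 0)
  expect_gt(est3$dS, 0)
})

test_that("ML recovers simulated omega and is order-symmetric", {
  set.seed(31)
  p <- sim_pair(0.15, 2, 0.3, 4000)
  f1 <- dnds_ml(p[1], p[2])
  expect_gt(f1$omega, 0.2)
  expect_lt(f1$omega, 0.42)
  f2 <- dnds_ml(p[2], p[1])
  expect_equal(f1$omega, f2$omega, tolerance = 1e-6)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
})

test_that("ML optimum beats every point of a parameter grid", {
  set.seed(32)
  p <- sim_pair(0.2, 2.5, 0.5, 300)
  fit <- dnds_ml(p[1], p[2])
  pi <- f3x4_frequencies(p)
  pat <- duplicability:::.pair_patterns(p[1], p[2])
  type <- duplicability:::codon_type_matrix()
  grid <- expand.grid(t = c(0.05, 0.1, 0.2, 0.4, 0.8),
                      kappa = c(0.5, 1, 2, 4, 8),
                      omega = c(0.05, 0.2, 0.5, 1, 2))
  ll <- apply(grid, 1, function(g)
    duplicability:::cpp_pair_loglik(pi, g[2], g[3], g[1], type,
                                    pat$i - 1L, pat$j - 1L, pat$w))
  expect_gte(fit$logL, max(ll) - 1e-6)
})

test_that("neutral simulation is estimated near omega = 1 by both methods", {
  set.seed(33)
  oml <- numeric(12); ong <- numeric(12)
  for (r in 1:12) {
    p <- sim_pair(0.3, 2, 1, 500)
    oml[r] <- dnds_ml(p[1], p[2])$omega
    ong[r] <- dnds_ng86(p[1], p[2])$omega
  }
  for (v in list(oml, ong)) {
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - 1), 3 * se + 0.05)
  }
})

test_that("dN and dS increase monotonically along a divergence ladder", {
  set.seed(34)
  ts <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)
  est <- lapply(ts, function(t) {
    p <- sim_pair(t, 2, 0.3, 1500)
    dnds_ml(p[1], p[2])
  })
  dS <- vapply(est, `[[`, 1, "dS")
  dN <- vapply(est, `[[`, 1, "dN")
  expect_gt(cor(ts, dS, method = "spearman"), 0.9)
  expect_gt(cor(ts, dN, method = "spearman"), 0.9)
})

test_that("rate filter excludes low dS and high omega with reasons", {
  df <- data.frame(family_id = c("a", "b", "c", "d"),
                   dS = c(0.005, 0.08, 0.08, 0.05),
                   omega = c(0.3, 12, 0.3, NA))
  fl <- rate_filter(df)
  expect_equal(fl$retained$family_id, "c")
  expect_equal(fl$excluded$reason[fl$excluded$family_id == "a"], "low_dS")
  expect_equal(fl$excluded$reason[fl$excluded$family_id == "b"], "high_omega")
  expect_equal(fl$excluded$reason[fl$excluded$family_id == "d"],
               "undefined_omega")
})

test_that("paralog mean rate averages the per-paralog estimates", {
  df <- data.frame(dN = c(0.01, 0.02, 0.06), dS = c(0.1, 0.1, 0.1),
                   omega = c(0.1, 0.2, 0.6))
  m <- paralog_mean_rate(df)
  expect_equal(m$omega, 0.3)
  expect_equal(m$dN, 0.03)
  one <- paralog_mean_rate(df[1, ])
  expect_equal(one$omega, 0.1)
  expect_error(paralog_mean_rate(df[0, ]), "no paralog")
})

test_that("GC3 counts third positions and averages the species pair", {
  expect_equal(gc3("GGCGGG"), 100)
  expect_equal(gc3("GGAGGT"), 0)
  expect_equal(gc3("GGC---GGT"), 50)  # gapped codon ignored
  aln <- c("macaque|m" = "GGCGGGGGC", "gibbon|g" = "GGCGGAGGT",
           "human|h" = "GGAGGAGGA")
  # macaque 100, gibbon 1/3 of 100
  expect_equal(gc3_pair(aln), (100 + 100 / 3) / 2)
  expect_error(gc3_pair(aln[1]), "gibbon")
})

test_that("stop codons and frame errors are data errors, not silent drops", {
  expect_error(dnds_ng86(codon_rep("TAA", 5), codon_rep("AAA", 5)), "stop")
  expect_error(dnds_ml("ATGA", "ATGA"), "divisible")
  expect_error(duplicability:::codon_states("AT-GAA"), "partial-codon")
})
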