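test_that("configuration validation rejects invalid parameters", {
  expect_error(sim_config(fraction_duplicable = 1.2), "fraction_duplicable")
  expect_error(sim_config(kappa = -1), "kappa")
  expect_error(sim_config(dup_time_range = c(0.8, 0.2)), "dup_time_range")
  expect_error(sim_config(omega_singleton = list(meanlog = NA, sdlog = 1)),
               "omega distribution")
  bad_tree <- ape::read.tree(text = "(a:1,b:1);")
  expect_error(sim_config(species_tree = bad_tree), "six study species")
})

test_that("singleton families carry one gene per species, duplicables obey the distance rule", {
  cfg <- small_cfg()
  s <- simulate_family(cfg, "singleton", "S1", seed = 1, sequences = FALSE)
  expect_setequal(label_species(s$tree$tip.label), study_species())
  expect_equal(length(s$tree$tip.label), 6L)

  d <- simulate_family(cfg, "duplicable", "D1", seed = 2, sequences = FALSE)
  sp <- label_species(d$tree$tip.label)
  expect_equal(length(d$tree$tip.label), 7L)
  dupsp <- d$truth$dup_species
  expect_equal(sum(sp == dupsp), 2L)
  dm <- stats::cophenetic(d$tree)
  paralogs <- d$tree$tip.label[sp == dupsp]
  gib <- d$tree$tip.label[sp == "gibbon"]
  A <- dm[paralogs[1], paralogs[2]]
  expect_lt(A, dm[paralogs[1], gib])
  expect_lt(A, dm[paralogs[2], gib])
})

test_that("alignments are in-frame, stop-free, constant-length within family", {
  cfg <- small_cfg(n_codons = 80)
  for (cl in c("singleton", "duplicable")) {
    fam <- simulate_family(cfg, cl, "A1", seed = 5)
    aln <- fam$alignment
    expect_equal(sort(names(aln)), sort(fam$tree$tip.label))
    lens <- nchar(aln)
    expect_equal(length(unique(lens)), 1L)
    expect_equal(unique(lens) %% 3, 0)
    # codon_states errors on stops; success means none are present
    for (s in aln) expect_silent(duplicability:::codon_states(s))
  }
})

test_that("identical seed and config reproduce the dataset byte for byte", {
  cfg <- small_cfg(n_families = 6, n_codons = 60, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$alignments, d2$alignments)
  expect_identical(ape::write.tree(d1$families[[1]]),
                   ape::write.tree(d2$families[[1]]))
  expect_identical(d1$covariates, d2$covariates)

  dir1 <- tempfile(); dir2 <- tempfile()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  f2 <- list.files(dir2, recursive = TRUE)
  expect_identical(f1, f2)
  sums1 <- tools::md5sum(file.path(dir1, f1))
  sums2 <- tools::md5sum(file.path(dir2, f2))
  expect_identical(unname(sums1), unname(sums2))
})

test_that("written datasets round-trip through the plain-text formats", {
  cfg <- small_cfg(n_families = 4, n_codons = 50, seed = 10)
  ds <- simulate_dataset(cfg)
  dir <- tempfile()
  manifest <- write_dataset(ds, dir)
  expect_true(all(file.exists(manifest$path)))

  back <- read_dataset(dir)
  expect_setequal(names(back$families), names(ds$families))
  id <- names(ds$families)[1]
  # topology and branch lengths survive the Newick round trip
  expect_equal(stats::cophenetic(back$families[[id]]),
               stats::cophenetic(ds$families[[id]]), tolerance = 1e-8)
  # FASTA count equals leaf count; sequences identical
  expect_equal(length(back$alignments[[id]]),
               length(ds$families[[id]]$tip.label))
  expect_identical(back$alignments[[id]][names(ds$alignments[[id]])],
                   ds$alignments[[id]])
  expect_equal(back$covariates$expression, ds$covariates$expression,
               tolerance = 1e-8)
})

test_that("covariates carry the built-in correlation and group structure", {
  cfg <- sim_config(n_families = 1000, seed = 77)
  ds <- simulate_dataset(cfg, sequences = FALSE)
  tr <- ds$truth; cv <- ds$covariates
  dup <- tr$class == "duplicable"

  # omega-expression negative correlation (target magnitude ~0.35)
  ce <- correlate(tr$omega, cv$expression, "spearman")
  expect_lt(ce$estimate, 0)
  expect_lt(ce$p, 0.05)
  # CDS length negative correlation (weaker)
  cl <- correlate(tr$omega, cv$cds_length, "spearman")
  expect_lt(cl$estimate, 0)
  # duplicable genes shorter (rank test) and a bit more expressed
  expect_lt(suppressWarnings(
    stats::wilcox.test(cv$cds_length[dup], cv$cds_length[!dup],
                       alternative = "less"))$p.value, 0.05)
  expect_gt(mean(cv$expression[dup]), mean(cv$expression[!dup]))

  # zero slopes remove the correlations
  cfg0 <- sim_config(n_families = 600, seed = 78,
                     expression_model = list(mean = 2.7, sd = 1.5,
                                             slope = 0, group_offset = 0),
                     n_codons = list(meanlog = log(480), sdlog = 0.45,
                                     slope = 0, group_offset = 0,
                                     range = c(60, 2000)))
  ds0 <- simulate_dataset(cfg0, sequences = FALSE)
  r0 <- correlate(ds0$truth$omega, ds0$covariates$expression, "spearman")
  expect_lt(abs(r0$estimate), 0.1)
})

test_that("substitution counts scale with branch length and omega medians match", {
  # per-branch divergence of simulated pairs grows linearly with t
  set.seed(79)
  ts <- rep(c(0.02, 0.05, 0.1, 0.2, 0.3), each = 20)
  ndiff <- vapply(ts, function(t) {
    p <- sim_pair(t, 2, 0.3, 60)
    mean(strsplit(p[1], "")[[1]] != strsplit(p[2], "")[[1]])
  }, numeric(1))
  fit <- stats::lm(ndiff ~ ts)
  expect_gt(coef(fit)[2], 0)
  expect_lt(summary(fit)$coefficients[2, 4], 0.01)

  # group omega medians reflect the configured log-normals
  cfg <- sim_config(n_families = 1500, seed = 80)
  ds <- simulate_dataset(cfg, sequences = FALSE)
  med <- tapply(ds$truth$omega, ds$truth$class, median)
  expect_lt(abs(med[["singleton"]] - 0.27), 0.03)
  expect_lt(abs(med[["duplicable"]] - 0.36), 0.06)
})
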