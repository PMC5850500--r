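---
title: "Methods: rates, duplicability and the synthetic validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rates, duplicability and the synthetic validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Duplicated genes evolve faster than single-copy genes. The classical
reading is causal: duplication creates redundancy, selection relaxes, and
the paralogs accelerate. The alternative this package is built to test is
selectional: genes that duplicate successfully were already evolving
faster *before* they duplicated, because the same weak constraint that
tolerates sequence change also tolerates copy-number change.

Separating the two requires measuring a gene's evolutionary rate in a
lineage where it never duplicated. The design uses six primates: four
great apes (human, chimpanzee, gorilla, orangutan) in which duplication
status is scored, and an outgroup pair — gibbon and macaque — in which the
gene is required to be single-copy and in which the rate is measured. The
macaque–gibbon pairwise dN/dS is then a *proxy-ancestral* rate: an
estimate of the gene's rate uncontaminated by anything that happened after
the great-ape duplication.

## Family classification

Gene family trees (Newick, leaves labelled `SPECIES|GENEID`) are pruned to
the six study species; unary nodes are collapsed with branch lengths
summed, so patristic distances are untouched. A family is

* **excluded (missing)** if it lacks a macaque or gibbon gene;
* **split** into independent subfamilies when it carries several
  macaque/gibbon genes but decomposes into maximal clades with exactly one
  of each (a pre-primate duplication); if it does not decompose, it is
  excluded as ambiguous;
* **singleton** if every species has exactly one gene;
* otherwise tested species-by-species with the distance rule: for the two
  most closely related paralogs of a duplicated great ape, the patristic
  distance *A* between them must be strictly smaller than the distances
  *B* and *C* from each paralog to the gibbon ortholog. This is what a
  post-speciation duplication must look like; an ancestral duplication
  followed by loss in the outgroup fails it. Ties fail the rule —
  deliberately conservative, since the point of the rule is to *rule out*
  ancestral duplication. With more than two paralogs the closest pair is
  used, exact ties broken lexicographically by gene id so the choice is
  deterministic.

Trees are taken as rooted as supplied. The distance rule itself only uses
patristic distances, so the classification is invariant to leaf order and
to any rerooting that does not separate the paralogs from the gibbon leaf
(a property the test suite checks directly).

## Rate estimation

Pairwise dN/dS is estimated by maximum likelihood under a Goldman–Yang
style codon model: 61 sense codons of the universal code,
single-nucleotide exchanges only, transition/transversion ratio kappa,
nonsynonymous/synonymous ratio omega, and F3x4 codon frequencies computed
empirically from the two sequences jointly (the `CodonFreq = 2`
convention). The likelihood is maximized over (t, kappa, omega) by
bounded quasi-Newton on log parameters from a fixed schedule of three
starts, so estimates are deterministic. dN and dS follow from the fitted
parameters by the standard flux decomposition — the proportions of
synonymous and nonsynonymous flux under the fitted model, normalized by
the site proportions computed at omega = 1 — which makes dN/dS equal the
fitted omega exactly.

Numerical choices worth stating:

* codon columns with a gap or non-ACGT symbol in either sequence are
  dropped (pairwise deletion); in-frame stop codons are a hard error, not
  a silent drop;
* positional nucleotide frequencies are floored at 1e-6 before forming
  F3x4 products, so short sequences cannot produce a degenerate rate
  matrix;
* transition probabilities come from an eigendecomposition of the
  symmetrized generator (the model is reversible), with tiny negative
  round-off clamped at zero;
* identical sequences short-circuit to dN = dS = t = 0 with omega flagged
  undefined;
* estimates with dS < 0.01 or omega > 10 are excluded downstream
  (`rate_filter()`): at near-zero synonymous divergence the ratio is
  numerically meaningless.

An independent Nei–Gojobori (1986) counting estimator (`dnds_ng86()`)
serves as a cross-check oracle: per-position synonymous site fractions
(stop codons excluded from both numerator and denominator), pathway-
averaged difference counts, and a Jukes–Cantor correction per proportion.
It shares no code with the ML path and is expected to agree with it in
rank order (Spearman ≥ 0.9 on low-divergence simulated pairs) rather than
in absolute value.

For duplicable families, each paralog is compared with the macaque
ortholog and the per-family rate is the arithmetic mean across paralogs
(`paralog_mean_rate()`); the proxy-ancestral rate is always the
macaque–gibbon pair alone, so post-duplication artifacts (gene conversion
among paralogs, for instance) cannot leak into it.

## Branch models and the post-duplication tests

`codon_loglik()` evaluates the same codon model on a whole gene tree by
Felsenstein pruning, with one omega per *branch class*; transition
matrices are computed per class from a single eigendecomposition. Missing
codons marginalize over states. `fit_codon_model()` maximizes over all
branch lengths, kappa and the class omegas jointly; branch-length
gradients are analytic (bidirectional pruning), kappa/omega gradients by
finite differences.

Two likelihood-ratio tests address the causal model:

* **Asymmetry.** Null: background omega plus one shared omega on the
  paralog terminal branches. Alternative: one omega per paralog branch.
  df = number of paralogs − 1. The dS ≥ 0.01 filter is *not* applied
  here: recent duplications necessarily have low paralog divergence and
  filtering them would discard the entire test set.
* **Acceleration.** Null: a single omega everywhere. Alternative:
  background omega plus one shared post-duplication omega on every branch
  descending from the duplication node (the MRCA of the paralogs —
  mirroring the foreground labelling a codeml user would apply). df = 1,
  with the direction (faster/slower) read off the fitted omegas. Both
  filters apply. Where several paralogs exist the post-duplication omega
  is still a single shared rate; per-paralog rates belong to the
  asymmetry alternative only.

The alternative fit is always started from the null solution (plus one
perturbed restart), so the LRT statistic is non-negative by construction
rather than by luck. Meta-analysis uses Benjamini–Hochberg FDR across
families, Fisher's method (−2 Σ log p against chi-square with 2k df) for
the pooled null, and the exact two-sided binomial test for the
faster/slower split.

## Covariate analysis

Expression, CDS length, genomic length and GC3 all correlate with
evolutionary rate and could mask or explain a rate difference between
duplicable and singleton genes. For each covariate the analysis fits a
LOWESS curve (tricube weights, local linear fits, three robustness
iterations, span f = 0.3, fitted values by linear interpolation of the
smoothed curve — the `lowess()` + `approxfun()` idiom) of omega on the
covariate and compares the residuals between groups with a Mann–Whitney U
test. The change from the uncorrected p-value is then calibrated by
randomization: the covariate values are permuted without replacement,
the smooth and residuals recomputed, and the residual p re-extracted,
10,000 times by default; the reported p is the fraction of simulants as
extreme or more extreme than the observed residual p, in the direction of
the observed change. Because a permuted covariate has slope zero on
average, the median simulant p should sit near the uncorrected p — an
internal consistency property the tests assert. Two caveats the
implementation is explicit about:

* the direction (masking vs explaining) is chosen from the data, so the
  reported randomization p is one-sided post hoc; held fixed, the p is
  uniform under the null (the calibration test fixes it for exactly that
  reason);
* zero as-extreme simulants are reported as "< 1/n_sims" alongside the
  raw zero.

The dN–dS relationship between groups is compared by least squares
(dN ~ dS against dN ~ dS + status + dS:status) with AIC and a nested F
test, and the joint residual space (expression residuals × CDS-length
residuals) is compared between groups with a two-sample 2D kernel test:
integrated squared difference of diagonal-bandwidth Gaussian KDEs
(per-dimension plug-in bandwidth sd · n^(−1/6)), significance by label
permutation. The ISE has a closed form under Gaussian kernels, so no grid
integration is involved.

## The synthetic generator

Everything above is exercised end-to-end on synthetic data
(`simulate_dataset()`), generated under the conditions the analysis
assumes:

* a fixed six-species topology with branch lengths in expected
  substitutions per codon, calibrated so the macaque–gibbon pairwise dS
  falls in the 0.08–0.10 band typical of these taxa (the macaque–gibbon
  path is 0.135 substitutions/codon; there is no published
  substitutions-per-codon calibration for this pair, so the branch
  lengths are set from the synonymous-divergence band rather than from an
  external timetree);
* 400 families by default, ~5% carrying one recent duplication placed
  uniformly on the middle 20–80% of a great-ape terminal branch (at most
  one duplication per family; the placement keeps the duplication node
  strictly below the speciation, so the distance rule holds on true
  distances);
* per-family omega log-normal with medians 0.36 (duplicable) and 0.27
  (singleton). The dispersion, sdlog = 0.25, is a design choice: it is
  deliberately tighter than the spread of real gene-by-gene dN/dS, chosen
  so that the built-in group difference is reliably recoverable at the
  default design size — the generator is a validation instrument, and a
  default whose known signal is usually *not* recoverable would make
  every downstream check uninformative. Consequences of this choice are
  discussed under "What passing tests do and do not show";
* codon sequences evolved by the Goldman–Yang process (root codons from
  the F3x4 stationary distribution, matrix-exponential transition
  probabilities per branch, universal code, no indels), CDS lengths
  log-normal around 480 codons, truncated to [60, 2000];
* expression on a log2(RPKM)-like scale, decreasing in standardized log
  omega with a slope set for a Spearman magnitude near 0.35, plus a
  positive offset for duplicable families (slightly higher expression in
  duplicables — the masking configuration); CDS length decreasing in log
  omega with target Spearman magnitude near 0.1 and a negative
  duplicable offset (duplicables shorter, by about 0.15 log10 units);
  genomic length is CDS length times a log10-normal intron factor with no
  group structure; GC3 is a property of the simulated sequences
  themselves (the stationary frequencies put it near 56%) and carries no
  group structure;
* one master seed; per-family seeds are derived from it by a fixed
  sampling pass, so family *i* is reproducible in isolation and the whole
  dataset is byte-identical across reruns.

Problem sizes used by the validation suite — 10,000-codon pairs (20
replicates) for pairwise recovery, 500-codon families (200 replicates)
for LRT null calibration, 400-family datasets for the end-to-end
direction — are the package's chosen balance between Monte Carlo noise
and practical runtime.

## What passing tests do and do not show

The generator emulates the statistical *structure* the analysis assumes,
not real genomes. It has no indels or alignment error (sequences are
emitted aligned), no gene conversion, no rate variation among sites or
among lineages within a family, no WGD, a single expression value per
gene rather than a tissue panel, and group omega dispersion tighter than
reality. Passing the suite therefore demonstrates that the machinery is
correct and well calibrated — estimators unbiased, LRTs with nominal
type-I error, randomization tests internally consistent, classification
faithful when duplication nodes are separated from speciations — not that
the biological conclusions would reproduce on any particular real
dataset. On real data the group dispersion is wider and group sizes more
unbalanced, so power at a given design size will be lower than in the
synthetic default.

## Known limitations

* The pairwise estimator treats F3x4 frequencies as empirical constants,
  not free parameters; this matches common practice but slightly
  understates parameter uncertainty.
* The NG86 oracle's stop-codon convention (excluded from site
  denominators) follows one of several in circulation; counting-method
  absolute values differ across conventions, which is why the cross-check
  is rank-based.
* The acceleration test labels all branches below the duplication node as
  foreground; if the duplication node is misplaced by classification
  error, the labelling inherits the error.
* Split-family handling requires a clean decomposition into
  one-macaque/one-gibbon clades; interleaved topologies are excluded
  rather than reconciled (no duplication–loss reconciliation is
  attempted).
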