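---
title: "Methods: branch-wise dN/dS estimation and lineage constraint contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-wise dN/dS estimation and lineage constraint contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package answers

Given a set of protein-coding genes grouped into classes (for example,
genes associated with particular diseases) and orthologous coding
sequences from many species, `branchomega` asks whether the selective
constraint on a gene class differs between lineages of the species tree.
Constraint is measured as dN/dS (omega): the rate of nonsynonymous
substitution per nonsynonymous site relative to the synonymous rate per
synonymous site. Values far below 1 indicate purifying selection, values
near 1 neutrality, and values above 1 positive selection or relaxed
constraint.

The pipeline is: build in-frame codon alignments from protein
alignments; screen putative orthologs whose synonymous divergence from a
reference species is an extreme outlier; estimate per-branch dN and dS by
maximum likelihood under a codon substitution model; summarise each gene
class on each lineage with the ratio-of-means convention; and contrast
all lineage pairs with one-way ANOVA under Bonferroni correction.

# The substitution model

Estimation uses a Goldman-Yang-style Markov process on the 61 sense
codons. The instantaneous rate from codon *i* to codon *j* is zero if the
codons differ at more than one position and otherwise

    q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous],

where `pi` are stationary codon frequencies, `kappa` is the
transition/transversion rate ratio and `omega` is dN/dS. The generator is
rescaled so branch lengths are expected substitutions per codon. Codon
frequencies default to F3x4 (products of position-specific nucleotide
frequencies observed in the alignment), with F1x4 and equal frequencies
as options; frequencies are floored at 1e-10 and renormalised so the
reversible eigendecomposition stays defined when a nucleotide is missing
at a codon position.

Four model configurations are fitted per gene, mirroring the standard
branch-model repertoire:

* `SINGLE_RATIO` - one omega for every branch;
* `BRANCH_CATARRHINE` - catarrhine branches (foreground) versus all
  others;
* `BRANCH_CATARRHINE_CETACEAN` - catarrhine plus cetacean foreground;
* `FREE_RATIO` - an independent omega on every branch.

Foreground sets are expressed as named branch tags on the species tree; a
tag covers the tagged tips' terminal branches, the internal branches of
the clade they span, and its stem branch. When a gene lacks some species,
the tree is pruned to the species present and tags are recomputed on the
pruned tree; branches of absent species collapse into their neighbours,
which is reported per gene.

Likelihoods are computed by Felsenstein pruning over codon-site patterns
with per-pattern scaling; gap and ambiguous codons enter as missing data
(all-ones partial likelihoods), and the root is weighted by the
stationary frequencies. Because the model is reversible, the likelihood
does not depend on root placement; trees are unrooted internally for
estimation so the two root-adjacent branch lengths are not separately
(un)identifiable.

## Per-branch dN and dS

Site counts follow the model's mutational opportunity at omega = 1: with
synonymous and nonsynonymous rate flows `R_S` and `R_N` under the fitted
kappa and pi, a codon carries `S = 3 R_S / (R_S + R_N)` synonymous sites.
Each branch's expected substitutions are partitioned into synonymous and
nonsynonymous flow under that branch's omega and divided by the
respective site counts, so `dN/dS` equals the branch's fitted omega
exactly (a construction contract, tested to 1e-6 relative).

## Optimisation

Fits maximise the likelihood over kappa, the omega classes, and all
branch lengths (the species tree contributes topology only; its lengths,
where present, only seed the optimiser). The optimiser is bounded
quasi-Newton (`L-BFGS-B`) on log-transformed parameters with bounds kappa
in [0.01, 100], omega in [1e-4, 20], t in [1e-6, 50], convergence at
roughly 1e-6 relative tolerance on the log-likelihood, and seeded random
multi-starts (default 3; the first start is a heuristic or, when a nested
model's fit is supplied as `init`, that fit's optimum, which also
guarantees log-likelihood monotonicity across nested models). All
gradients are analytic: branch-length derivatives come from a combined
post-order/pre-order pruning pass, and kappa/omega derivatives from the
Frechet derivative of the matrix exponential in the pi^(1/2)-symmetrised
eigenbasis. The analytic gradient is validated against central
differences in the test suite; it makes free-ratio fits roughly an order
of magnitude faster than finite-difference gradients, which is what makes
the simulation-based calibration tests feasible on one CPU.

Matrix exponentials use the symmetrised eigendecomposition of the
reversible generator (stable, reusable across branch lengths); entries
that come out a rounding error below zero are clamped at zero.

# The counting method

`ng86_pairwise()` implements the classic Nei-Gojobori counting method as
a cross-check on the ML machinery and as the distance behind the ortholog
QC filter: per-position synonymous site fractions (single-base mutants
creating stop codons are excluded from both numerator and denominator),
pathway-averaged difference counts over all minimal substitution
orderings (paths through stop codons excluded), site counts averaged
between the two sequences, and Jukes-Cantor correction. Saturation
(p >= 3/4) yields a flagged `NA`, never a silent `NaN`; columns with
gaps, ambiguity, or no stop-free path are pairwise-deleted and counted.
The implementation is table-driven; the test suite checks every sense
codon and every codon pair within two differences against an independent
enumeration oracle, and checks estimator consistency on simulated data.

# Ortholog QC

Putative orthologs are screened per species on the reference-vs-species
synonymous distance: genes with `ds > median + k * SD` are flagged
(default k = 4, SD the ordinary sample standard deviation; a
median-absolute-deviation variant is available). The filter is one-sided
because the artifacts it targets - paralog capture and contamination -
inflate dS. Default policy is flag-only (curation stays with the
analyst); automatic removal of the flagged species, or of the whole gene,
is available for synthetic pipelines.

Two properties of this rule matter in practice and are covered by tests:

* a lone outlier among n-1 well-behaved genes sits about sqrt(n) sample
  standard deviations above the median, so columns with n <= k^2 genes
  (16 at the default k = 4) cannot flag it - small gene sets silently
  pass everything;
* across many species columns the rule is a 4-sigma test repeated
  thousands of times on skewed, near-Poisson distances, so it flags a
  fraction of a hairline false positive per run even on clean data. This
  is why flag-only is the default; the filter's sensitivity/specificity
  is characterised in the tests on its defining unit, a single
  reference-vs-species column with planted branch-elongated outliers.

# Class summaries and contrasts

The class-level constraint statistic is the ratio of means,
`mean(dN) / mean(dS)` over the genes of a class on a lineage, not the
mean of per-gene ratios: on short branches individual dS values sit
against the zero bound, where per-gene ratios are undefined or explosive,
while the ratio of means degrades gracefully; genes with dS = 0 are
deliberately included. Both conventions are reported side by side, and
they coincide exactly when all genes share the same dS. Uncertainty is
quantified by a seeded percentile bootstrap over genes (the resampling
unit is the gene).

Lineage contrasts run a one-way ANOVA (two groups) on per-gene free-ratio
omega for every unordered pair of lineages, Bonferroni-corrected by the
number of pairs actually testable within the class. Genes whose dS on a
branch falls below `ds_floor` are excluded from that lineage's sample.
The package default floor is 1e-6 (exclude only genuinely undefined
ratios), but for contrasts on short branches we recommend - and the
shipped analyses use - a floor around one synonymous substitution per
gene (e.g. 0.01 at 250-codon genes), because a gene with essentially no
synonymous signal has an omega estimate pinned near an optimiser bound,
and one such gene can dominate a group's variance and mask a real
difference. The default lineage set is all non-reference terminal
branches, with a configurable exclusion list for taxa without a
meaningful comparison partner; internal branches are labelled and
available but terminal branches are the default reporting unit, since
internal branches both collapse under missing orthologs and measure a
different mixture of polymorphism and divergence.

The ANOVA's replicate unit deserves a note: the per-gene free-ratio omega
is the only per-lineage quantity from which all-pairs tests within a
class are computable from the pipeline's outputs, so it is the default;
a counting-based per-gene omega table (reference-vs-species NG86) is
available as a fast alternative (`omega_source = "ng86"`).

# The simulator

`simulate_codon_alignment()` is the generative mirror of the estimation
model: root codons are drawn from pi and each branch evolves every site
under the GY94 generator for that branch's omega class. Evolution is
simulated by the exact jump chain of the Markov process (exponential
waiting times, jumps proportional to off-diagonal rates), so endpoint
states follow the model's transition probabilities exactly and the
recorded per-branch substitution counts are true event counts. Identical
seeds give byte-identical output.

`generate_gene_classes()` assembles whole study datasets: classes of
genes with their own branch-tag omega regimes, per-gene lengths, a
gene-class table, and optional planted dS outliers that replace one
species' sequence with one re-evolved along a branch elongated by a
chosen factor - elevated dS with proportionally elevated dN, i.e. shaped
like a real paralog rather than a shuffled decoy. The full generating
truth (seeds, omegas, realized substitution counts) is saved beside every
bundle.

What the generator deliberately does not emulate: indels (alignment is
then exact by construction; an aligner stress test is not the goal),
sequencing and assembly error, rate variation across sites, codon-usage
differences between lineages, and polymorphism segregating within
species. Passing tests therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not robustness to
real-data pathologies.

## Fixture trees

Three fixtures ship with the package: `TEST_6` (human, chimpanzee,
macaque, mouse, rat, dog - the smallest tree with a catarrhine/
sciurognath contrast), `PRIMATE_12` (eleven primates plus mouse), and
`FULL_45` (a 45-taxon mammal tree with `CATARRHINI`, `CETACEA` and
`SCIUROGNATHI` tags; tip-name-to-binomial mapping in
`inst/extdata/full45_species.tsv`). The topologies follow standard
mammalian taxonomy; branch lengths are synthetic, chosen in the
low-divergence regime (terminals 0.02-0.3 expected substitutions per
codon) where counting and ML methods agree well.

# Alignment stage

Protein alignment uses global affine-gap pairwise alignment (BLOSUM62,
gap open 11, extend 1 - a gap of length L costs open + L * extend)
merged by the center-star construction ("once a gap, always a gap"),
which is adequate for the high-identity ortholog sets this pipeline
targets; an externally produced protein alignment can be supplied
instead for real data. Codon alignments are produced by threading each
CDS through its protein row, which guarantees frame preservation and is
validated residue-by-residue. Best-hit ortholog assignment by global
alignment score is provided as a desk-scale stand-in for a database
search; ties break to the lexicographically smallest identifier and are
logged.

Isoform choice is left to the caller: the loader takes one CDS per
species per gene and does not attempt to pick among transcript variants.

# Numerical choices and degenerate inputs

* Codon order is lexicographic over T, C, A, G with stops removed, fixed
  so matrix indices are reproducible.
* Terminal stop codons are stripped on load; internal stops reject the
  record (the counting and likelihood machinery is defined on sense
  codons); N-containing codons are retained as missing data.
* Identical-sequence alignments drive all branch lengths to the lower
  bound; omega is then unidentifiable and reported at its starting
  value, with the fit flagged converged only if the optimiser reports
  success.
* Eigenvalue coincidences in the Frechet derivative use the stable
  divided-difference limit `t * exp(d t)`.
* The brute-force likelihood oracle in the tests enumerates all
  ancestral-state assignments (up to 61^3) and is entirely independent
  of the pruning implementation.

# Problem sizes in the shipped tests

The simulation-based checks use sizes chosen so the whole suite runs
comfortably on a single CPU while retaining statistical power, and all
study-design parameters were fixed by design-stage power analysis:
branch-model recovery uses 30 genes x 300 codons on `PRIMATE_12`; LRT
null calibration uses 200 replicates x 200 codons on `TEST_6`; the QC
filter characterisation uses 20 seeds x 500 genes x 500 codons on a
reference-chimpanzee pair with five 10x planted outliers; the end-to-end
directional analysis uses 20 seeds x two classes of 16 genes x 250
codons with catarrhine omega elevated from 0.1 to 0.4; family-wise error
control uses 50 null datasets of 60 genes. Bootstrap intervals default
to B = 1000.

# Known limitations

* Site-heterogeneous and branch-site models are out of scope; a class
  mixing a few positively selected genes with conserved ones is
  summarised, not decomposed.
* The center-star aligner is not a progressive MSA; for distant or
  indel-rich sequences supply an external protein alignment.
* Free-ratio omega on very short branches is weakly identified; use the
  ratio-of-means table (which is designed for that regime) and a
  sensible `ds_floor` for contrasts.
* The ANOVA treats genes as independent replicates and lineages as fixed
  groups; phylogenetically corrected contrasts (e.g. PGLS) are not
  implemented.
* P-values from all-pairs contrasts are conservative under Bonferroni
  and positively correlated samples; interpret borderline significance
  accordingly.
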