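---
title: "Comparing divergence-time estimates across clock models and calibration sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing divergence-time estimates across clock models and calibration sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronocompare)
```

## The problem

Bayesian molecular dating turns a phylogeny plus fossil calibrations into a
chronogram: a rooted ultrametric tree whose branch lengths are millions of
years, so that every internal node carries a divergence age. The age
estimates, however, depend heavily on two modelling choices that the data
rarely resolve: the relaxed clock model (autocorrelated models such as the
lognormal rate walk, CIR, or TK02 let rates drift along the tree, whereas
uncorrelated models draw each branch's rate independently from a lognormal
or gamma law) and the fossil calibration set (which nodes are constrained,
and how tightly). Studies that date the same alignment under several clocks
and calibration sets routinely see node-age shifts of hundreds of millions
of years between chronograms.

`chronocompare` quantifies those shifts. Given a panel of chronograms that
share most (not necessarily all) of their internal nodes, it matches nodes
across topologies, computes per-source and pairwise divergence statistics,
tests their significance, embeds the pairwise dissimilarities with
multidimensional scaling, and checks each chronogram against hard fossil
bounds.

## Node identity and the age matrix

A node is identified by its rooted clade — the set of leaf labels it
subtends. Two chronograms "share" a node when both contain an internal node
with exactly the same leaf set; ages of a shared node can then be compared
even when the trees disagree elsewhere. The root (all leaves) counts as a
node; leaves do not (their age is identically zero). For a binary rooted
tree on $L$ leaves there are $L-1$ internal nodes, so a panel of 108-taxon
chronograms has 107 candidate nodes per tree, and any topological
disagreement removes nodes from the shared set. We chose rooted clades
rather than unrooted bipartitions because a divergence age is a property of
a rooted split; the trees are used exactly as rooted in their files, and no
re-rooting is attempted.

Ages are derived from branch lengths alone: the root age is the maximum
root-to-leaf path length and each node's age is the root age minus its
path length. Annotation blocks in square brackets (`[&rate=...]`,
`[&height=...]` and the like, which the common dating programs attach) are
stripped before parsing, so the dialects of different programs are read
uniformly and "height" annotations are never trusted over the branch
lengths themselves. Leaves must reach the present within a relative
tolerance of $10^{-6}$ of the root age — enough to absorb formatting
precision, not enough to hide a genuinely non-ultrametric tree — and are
then snapped to exactly zero.

## The comparison statistics

Let $x_i(s)$ be the age of shared node $i$ in source $s$ (a source is one
chronogram, labeled by clock model and calibration set), and $n$ the number
of shared nodes.

**Deviation from the group mean.** For a group $G$ of sources (all
calibration sets of one clock, or all clocks under one calibration set),
with $\bar x_i$ the mean age of node $i$ over $G$:

$$D(s) = \frac{1}{n} \sum_{i=1}^{n} 100\,\frac{x_i(s) - \bar x_i}{\bar x_i}.$$

$D$ is signed; a source with $D = +5$ dates nodes 5% older than its group's
mean on average. Because the per-node deviations sum to zero over the
group, $\sum_{s \in G} D(s) = 0$ exactly — any table of $D$ values must
satisfy this identity up to rounding, which makes it a cheap audit of
published or recomputed tables. Magnitudes of the signed statistic, not a
separately defined absolute statistic, are what "largest deviation"
summaries report.

**Pairwise differences.** Between two sources $x$ and $y$:

$$P(x,y) = \frac{1}{n}\sum_i (x_i - y_i) \quad \text{(Myr)}, \qquad
  P\%(x,y) = \frac{1}{n}\sum_i 100\,\frac{x_i - y_i}{0.5\,(x_i+y_i)}.$$

$P\%$ uses the symmetric (mean-of-the-two) denominator, so it is bounded in
$(-200, 200)$ and antisymmetric, and a pure scale factor $b$ between two
chronograms gives exactly $P\% = 200(b-1)/(b+1)$ at every node — the closed
form the synthetic tests exploit. Both statistics exist in signed (default)
and absolute variants; the signed form is primary because only it obeys the
zero-sum identity and antisymmetry, while the absolute form feeds MDS,
which needs a symmetric dissimilarity.

**Inference.** Differences between two sources are tested with the paired
Wilcoxon signed-rank test, two-sided, pairing by node. Zero differences are
dropped and tied absolute differences mid-ranked. With 25 or fewer non-zero
differences the p-value is exact, computed by dynamic programming over the
observed rank multiset — this keeps the test exact under ties, which the
standard R implementation only offers for untied data; above 25 the normal
approximation with tie-corrected variance and continuity correction takes
over (the two branches agree with `wilcox.test`'s approximation when both
apply). All unordered source pairs of one analysis form a single
Benjamini–Hochberg family; no pooling across analyses is done.

**Ordination.** The absolute pairwise matrix (P in Myr by default, P% by
option — both are exposed because either is a defensible dissimilarity) is
embedded by classical Torgerson MDS: double-center the squared
dissimilarities, eigendecompose, and keep the top non-negative eigenpairs.
We use metric MDS rather than a stress-minimizing variant because it is
deterministic, needs no starting configuration, and reproduces Euclidean
configurations exactly; negative eigenvalues from non-Euclidean input are
truncated but reported so the user can judge the embedding quality.

## Calibration checking

A calibration set is a list of hard `[min, max]` age bounds (Myr) on named
nodes; the package ships three such sets used for dating plastid and
cyanobacterial evolution (17 constraints each, differing in the red-algal
and green-algal fossil minima). Bounds are treated as closed intervals,
since hard-bounded priors admit their endpoints. A chronogram produced
under a given set should satisfy that set post hoc, so
`check_calibrations()` resolves each constraint's node as the MRCA of a
user-supplied leaf set and reports every age outside its bounds. The
taxon sets defining each calibrated node are configuration (`mrca_map`),
not hard-coded taxonomy, because the constraint table names clades, and
which leaves represent a clade depends on the sampled taxa. If the mapped
leaves are not monophyletic in a particular tree, the spanning MRCA is
still used, with a warning — matching how dating software interprets
calibration taxa.

## What the synthetic generator emulates — and what it does not

`generate_panel()` builds a panel from one pure-birth (Yule) base tree —
the tree prior commonly favored for such data — then gives each source its
own distortion:

* a multiplicative **bias** $b$: every internal age becomes $b\,x$,
  emulating a clock model that systematically stretches or compresses the
  timescale;
* **lognormal age noise** of log-scale standard deviation $\sigma$: iid per
  node (as uncorrelated clocks distort ages) or accumulated root-to-tips as
  a Brownian walk on the log-error (so parent and child errors correlate,
  as under autocorrelated clocks);
* optional **topological disagreement**: nearest-neighbor-interchange moves
  that break an exact, known number of clades in designated sources, with
  the affected node ages redrawn uniformly between their children and
  parent.

Ages are perturbed directly, in age space, rather than simulating branch
rates and re-running a dating analysis: the comparison statistics consume
ages only, direct perturbation keeps closed-form expectations
($D = 100(b_s - \bar b)/\bar b$ at $\sigma = 0$, $P\%$ as above), and rate
simulation would re-import the whole MCMC dating machinery that this
package deliberately stays downstream of. Monotonicity after noise is
restored by capping each node just below its parent
(factor $1 - 10^{-9}$); the alternative, truncated resampling, would change
the noise law and destroy the closed forms. Every randomized operation
takes a seed, and panel generation derives one fixed stream per source from
the master seed, so a config reproduces its panel byte for byte on any
platform.

The generator emulates what the comparison machinery needs — known biases,
known noise structure, known topological disagreement — and nothing more.
It does not simulate sequence evolution, posterior uncertainty (credibility
intervals), the six named clock models' actual rate laws, or extinction.
Passing tests on synthetic panels therefore validate the statistics,
bookkeeping and inference, not the behaviour of any particular dating
program on real data.

## Numerical and design choices

* **Tolerances.** Ultrametricity: relative $10^{-6}$ of root age.
  Round-trip serialization: ages preserved to better than $10^{-9}$
  relative (15 significant digits are written). Zero-sum audit: $10^{-9}$.
* **Ordering.** Clades are ordered by lexicographically smallest leaf, then
  size, in C-locale radix order, making every table deterministic across
  platforms and locales.
* **Degenerate inputs.** Identical age vectors give a degenerate Wilcoxon
  result flagged as such with $p = 1$; a panel of identical trees yields an
  all-zero report rather than an error; groupings with a single member are
  skipped with a warning.
* **Problem sizes.** The bundled tests and the acceptance script run on
  panels of 20–108 taxa, up to 18 sources, and 20-replicate Monte-Carlo
  recovery runs at 200 taxa — sizes chosen so the whole suite completes in
  seconds while the Monte-Carlo standard errors stay well inside the
  asserted ±2-percentage-point recovery band.

## A full run

```{r full-run}
clocks <- rep(c("UCLNR", "IGR", "TK02", "CIR", "LN", "UGAM"), each = 3)
cals   <- rep(c("C1", "C2", "C3"), times = 6)
set.seed(1)
cfg <- synthetic_panel_config(
  n_taxa = 108, birth_rate = 0.02,
  sources = data.frame(clock = clocks, calibration = cals,
                       noise_model = "iid_lognormal", sigma = 0.05,
                       bias = runif(18, 0.8, 1.2)),
  broken_clades = 3, broken_sources = "LN:C2", seed = 7)
panel <- generate_panel(cfg)
report <- run_comparison(panel)
report
```

The 108-taxon panel has 107 internal nodes per tree; breaking 3 clades in
one source leaves 104 shared nodes, which the report logs. `D_by_clock`
rows and `D_by_calibration` columns each sum to zero, `P_signed` is
antisymmetric, and `report$mds$coordinates` gives the ordination in which
sources with similar biases cluster. `export_report()` writes the TSV/JSON
bundle; `read_report_summary()` restores the full-precision numbers.

## Using real chronogram panels

For chronograms estimated from data, list them in a manifest TSV (`source`,
`clock`, `calibration`, `file`, optional `format`) and call
`run_comparison("manifest.tsv")`, or use the `inst/cli/chronocompare`
script. Trees may be plain Newick or NEXUS with translate tables and
program annotations. For a deposited 18-chronogram panel of 108 taxa under
six clocks and three calibration sets, the same call reproduces the shared
node count, the two D tables, the pairwise P/P% summaries, and the MDS
layout directly from the tree files once they are on disk.

## Known limitations

* Node matching is exact; near-matches (one displaced taxon) count as
  different nodes. Panels with unequal taxon sets are an error by design.
* Credibility intervals are ignored — only point (mean/median) ages in the
  branch lengths are compared.
* The Wilcoxon test treats nodes as exchangeable pairs; phylogenetic
  non-independence of nodes is not modelled, which is why the package
  reports effect sizes (D, P, P%) alongside p-values rather than p-values
  alone.
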