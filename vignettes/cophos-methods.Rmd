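---
title: "Co-phosphorylation analysis for kinase-substrate association prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-phosphorylation analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophos)
```

This vignette documents the statistical model behind `cophos`, the
parameters that matter, the numerical choices made where the design was
genuinely open, what the synthetic generator does and does not emulate,
and the package's known limitations.

## The co-phosphorylation model

A phosphoproteomics experiment yields a matrix of fold-change
phosphorylation levels: rows are phosphosites (protein + residue +
position), columns are biological states (samples, conditions, tumors).
The row of a site is its *phosphorylation profile*. The working hypothesis
is that substrates of the same active kinase are phosphorylated
coherently, so their profiles correlate — and that this signal survives in
bulk data strongly enough to rank candidate kinases for sites with no
annotation at all.

### Edge weights: biweight midcorrelation

Profiles are correlated with the biweight midcorrelation. For a profile
$x$ of length $m$, with $\mathrm{med}(x)$ the median and
$\mathrm{mad}(x)$ the *unscaled* median absolute deviation (no 1.4826
consistency factor),

$$u_i = \frac{x_i - \mathrm{med}(x)}{9\,\mathrm{mad}(x)}, \qquad
  w_i = (1-u_i^2)^2\, \mathbf{1}(|u_i| < 1),$$

$$\tilde x_i = \frac{(x_i - \mathrm{med}(x))\,w_i}
  {\sqrt{\sum_j \left[(x_j - \mathrm{med}(x))\,w_j\right]^2}}, \qquad
  c_{xy} = \sum_i \tilde x_i \tilde y_i .$$

Observations more than nine MADs from the median get weight exactly zero
but remain in the normalisation sum with zero contribution; this keeps
$c_{xx} = 1$ and $|c_{xy}| \le 1$. The square root in the denominator is
the normalisation under which those two identities hold — the package
treats it as definitional, since every downstream distributional argument
presupposes weights in $[-1, 1]$. The practical payoff over Pearson
correlation is robustness: a single 10-sigma outlier (a common artefact of
ratio-based quantification) barely moves the estimate, which the test
suite verifies on 1,000 simulated pairs.

Degenerate profiles — `mad = 0`, which happens when more than half the
states share one value — cannot be standardised. They are *excluded from
the network* and reported, rather than silently falling back to Pearson:
mixing estimators inside one distribution would bias the tail models that
all scores share. Pearson is available as a whole-network alternative
(`method = "pearson"`).

The full network is computed by transforming each profile once and taking
inner products blockwise (`block_size` rows at a time, default 2048) to
bound memory; results do not depend on the block size.

### Tail models: background versus shared-kinase pairs

Two empirical distributions of edge weights drive the score:

* $A$ — all $n(n-1)/2$ pairs of measured sites (the background);
* $S$ — *shared-kinase pairs*: pairs annotated to at least one common
  kinase. Each unordered pair contributes once, however many kinases it
  shares. The annotation's set notation could also be read as "all pairs
  of annotated sites"; the package implements the shared-kinase reading,
  which is the one that makes $S$ informative.

Each distribution is summarised by its empirical survival function with an
add-one continuity correction,

$$\widehat{\Pr}(C > c) = \frac{\#\{v > c\} + 1}{n + 1},$$

clamped below by `epsilon` (default $1/(n+1)$ per distribution). The
correction keeps survival probabilities strictly positive above the sample
support, so the log-ratio below is always finite; the behaviour of the
raw ratio at the support extremes is otherwise undefined, and the add-one
rule is this package's choice. $S$ pools shared-kinase pairs over *all*
kinases into one global tail model rather than fitting per-kinase tails —
per-kinase tails would starve kinases with few substrates, and the
right-shift of $S$ is a property of shared-kinase pairs as a class.

### The score

For kinase $k$ with annotated substrate set $T_k$ and site $p$,

$$h(k,p) = \sum_{q \in (P \cap T_k),\, q \neq p}
  \log_2 \frac{\Pr(C_{pq} > c_{pq} \mid S)}{\Pr(C_{pq} > c_{pq} \mid A)}.$$

Each measured substrate of $k$ contributes positive evidence when its
co-phosphorylation with $p$ sits further out in the shared-kinase tail
than in the background tail. Sites on the same protein as $p$ are included
(there is no biological reason to exclude them); $q = p$ is excluded.
When $k$ has no measured substrate other than $p$ itself, there is no
evidence either way: the score is the sentinel `NA` ("unscorable"), never
0, because 0 is a meaningful value (evidence exactly balanced). Per site,
kinases are ranked by decreasing $h$ with ties broken by ascending kinase
name, so output is deterministic.

Only kinases with at least `min_substrates` annotated sites (default 2)
enter the analysis at all: a kinase known from a single substrate gives
ranking evidence too weak to trust, and cannot be evaluated by
cross-validation.

### Integration with static scores

When a static kinase–site table $x(k,p) > 0$ is available (sequence-motif
and interaction-network evidence in the style of KinomeXplorer), the
combined score is

$$M(k,p) = h(k,p) + \log_2 x(k,p).$$

$x$ enters raw — no rescaling before the logarithm — so users whose tool
reports on another scale can pre-normalise; a per-site multiplicative
rescaling of $x$ only shifts $M$ additively and leaves the ranking
unchanged (tested). Pairs missing either term are dropped, mirroring the
fact that integrated coverage is intrinsically limited to the static
tool's coverage; `static_fallback = TRUE` substitutes $h = 0$ instead, as
a static-only fallback. Non-positive static scores are rejected at load
because they have no logarithm.

## Permutation null models

Three schemes destroy profile structure at different granularities while
conserving the corresponding value multisets exactly: permuting values
across sites within each state column, permuting each site's profile
across states, and permuting the whole matrix. Pooling edge weights over
`n_perm` permuted replicates (default 100) gives the null
co-phosphorylation distribution; real data shows a visibly wider
distribution than any of the three nulls, which is the basic evidence that
co-phosphorylation is signal rather than noise. Distributions are compared
with the two-sample Kolmogorov–Smirnov test (exact null distribution below
50 observations, asymptotic otherwise; the package's uses of the test only
rely on "far below threshold" statements, so the asymptotic regime is not
load-bearing).

Replicate $r$ of an ensemble is seeded with `seed + r - 1`; this counter
scheme makes serial and any hypothetical parallel execution agree, and
makes the entire null-model pipeline bit-reproducible from one seed.

The dimension-adequacy diagnostic subsamples the state columns at each
dimension $d$ (`n_rep` replicates, default 100; the choice of default is
ours — no reference value exists) and tracks two quantities: the null
spread, which for Pearson on independent profiles follows the closed form
$1/\sqrt{d-1}$, and the KS distance between data and null, which grows
with $d$ when real structure is present. In practice correlation
estimates from fewer than 5 states are too noisy to rank kinases, which
is why the matrix constructor warns below that size (3 is the hard
minimum for the estimators to be defined at all).

## Evaluation protocols

**Leave-one-out cross-validation.** For every annotated association
$(k,p)$ with $p$ measured, that single association is hidden; all of
$p$'s other annotations and all of $k$'s other substrates remain. The
shared-kinase tail model is refit without the pairs that existed *only*
through the hidden association (pairs shared via another kinase stay),
and the rank of $k$ among all scorable kinases for $p$ is recorded.
Refitting the tails per fold is the leak-free choice: without it the
hidden edge's own weight would inflate $S$ in its own evaluation. The
refit is incremental — a precomputed per-pair share count makes each fold
a multiset subtraction, not a recomputation. Associations whose removal
leaves the kinase with no measured substrate are reported as unevaluable
rather than silently skipped. Sites with several annotated kinases
generate one record per association. Top-$k$ accuracy uses strict ranks
after the deterministic tie-break.

**Reproducibility and consensus.** Across two datasets, reproducibility
is the rate at which the top-ranked kinase is identical over common
sites, plus the rate at which one dataset's top pick is in the other's
top 5. Across several datasets, each site's agreement level is the modal
top-1 vote count (with an alphabetical tie-break for the modal kinase),
and sites are classified per the three-category scheme: consensus
prediction matches *any* annotated kinase of the site (category 1),
annotated but contradicted (category 2), unannotated (category 3);
precision is cat1/(cat1+cat2) per agreement level.

## The synthetic generator

Each kinase gets a latent activity vector over the $m$ states
(i.i.d. standard normal). A substrate of kinase $k$ is
$\sqrt{\rho}\,(\pm f_k) + \sqrt{1-\rho}\,\varepsilon$ with site-specific
noise $\varepsilon$, so two substrates of one kinase have expected
correlation $\rho$ and background sites (pure noise) are uncorrelated —
exactly the right-shifted shared-pair distribution the scoring exploits,
with closed-form expectations that the tests use as oracles. Sign-flipped
loadings (`negative_regulator_fraction`) emulate inhibitory
phosphorylation and phosphatase control; multi-kinase sites combine two
activity vectors scaled by $1/\sqrt{2}$, keeping unit variance ("average"
made precise). Static scores are
$x(k,p) = \exp(a\,z_{\mathrm{true}} + (1-a)\,z_{\mathrm{noise}})$ with
$z_{\mathrm{true}} = 2\cdot\mathbf{1}(\text{true KSA}) + N(0,1)$:
positive by construction, pure noise at $a = 0$, strongly but not
perfectly informative at $a = 1$.

Reference conditions — 20 states, 10 kinases with 20 substrates each, 200
background sites, $\rho = 0.7$, annotation fully known — are the
generator's defaults and the conditions under which the acceptance script
reports its numbers. They describe a comfortably powered mid-sized study;
the companion checks at $\rho = 0$ confirm that accuracy collapses to the
random baseline when there is no signal, i.e. that the evaluation leaks
nothing.

What the generator does **not** emulate: missing values and their
intensity dependence, ratio compression, batch structure, peptide-level
ambiguity (multiply phosphorylated peptides), or the heavy annotation bias
of real databases. Passing tests on synthetic data therefore demonstrate
the correctness of the machinery and the method's behaviour under its own
assumptions — not its accuracy on any particular real dataset.

## Numerical and interface choices

* Duplicate site rows in input (one site on several phosphopeptides) are
  aggregated by element-wise mean — symmetric and order-independent; the
  disambiguation used in any given upstream pipeline is unknowable here,
  so the rule is deliberately the simplest defensible one.
* Fold-change computation from raw intensities is out of scope; the input
  matrix is assumed pre-normalised, with an optional `log2` flag (which
  requires strictly positive values and errors otherwise, naming the row).
* Correlations are clamped to $[-1,1]$ against floating-point overshoot;
  the network matrix is symmetrised exactly and its diagonal set to 1.
* Site identity is (protein, residue, position); isoform suffixes are
  kept verbatim, not resolved. The canonical string `PROT_S123` parses
  from the right, so protein labels may themselves contain underscores.
* Prediction TSVs print scores with 17 significant digits so a
  write-read round-trip is bit-exact; run provenance records options and
  versions but no timestamps, so identical runs are byte-identical.
* The moment summary reports non-excess kurtosis (normal = 3) and the
  population-moment skewness, the conventions used for co-phosphorylation
  histograms.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the reference conditions
above (400-site networks, 200 LOOCV folds, up to 20 permutation
replicates) and complete in well under a minute on a single CPU; the
oracle-equivalence sweeps use 1,000 random vector pairs and families of
instances with at most 8 sites and 3 kinases, where exhaustive
reimplementation is feasible.

## Known limitations

* Indirect correlation is not removed: two substrates of different but
  co-activated kinases form a high edge weight; partial-correlation
  variants are out of scope here.
* The score treats substrate evidence additively (naive Bayes); strongly
  overlapping substrate sets between kinases make their scores correlated
  and the per-site ranking less informative than the raw $h$ gap
  suggests.
* Negative co-phosphorylation contributes through the same tail ratio as
  positive; no special handling of inhibitory relationships beyond what
  the distributions induce.
* Coverage of the integrated score is bounded by the static table;
  coverage of the base score is bounded only by network membership, which
  is the method's main practical advantage.
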