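---
title: "Switch-gene discovery by three-way liquid association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switch-gene discovery by three-way liquid association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(la3switch)
library(dplyr)
```

## The model

Pairwise co-expression treats the correlation between two genes as a fixed
property. The three-way ("liquid association") view lets that correlation
*depend on the cellular state*, summarised by the expression level of a third
gene X3, the **switch gene**: when X3 is low the pair (X1, X2) may be
negatively correlated, when X3 is high positively, and near the middle not at
all. Such switches are interesting precisely because they are invisible to
marginal statistics -- by construction, X1 and X2 can be pairwise
uncorrelated with each other and with X3.

`la3switch` scores a triplet with the binned modified liquid-association
(MLA) statistic. Samples are ordered by X3 and cut into $M$ contiguous,
near-equal bins; with $\hat\rho_i$ the Pearson correlation of (X1, X2)
inside bin $i$ and $\bar X_{3i}$ the mean X3 of bin $i$,

$$\widehat{\mathrm{MLA}} \;=\; \frac{1}{M}\sum_{i=1}^{M} \hat\rho_i\,\bar X_{3i}.$$

A correlation that rises with X3 makes positive products in the outer bins
and a large positive score; a flat correlation profile factorises into
$\bar\rho \cdot \sum_i \bar X_{3i}/M \approx 0$ for standardized X3. Before
scoring, every gene is passed through a rank-based normal quantile transform
(value of rank $r$ maps to $\Phi^{-1}(r/(n+1))$, average ranks on ties) and
standardized to mean 0, variance 1 -- the transform tames outliers, whose
leverage inside small bins would otherwise dominate the within-bin
correlations.

### Binning choices

* $M = 3$ by default: terciles are the coarsest partition that can express a
  sign flip with a quiet middle, and small studies (tens of samples) cannot
  afford many bins of at least a handful of samples each. `mla_score()`
  requires $n \ge 3M$.
* Bins are contiguous over the sorted X3 with sizes differing by at most
  one, larger bins at lower X3; ties in X3 are broken by sample index
  (stable), so results are reproducible on discretised data.
* A bin in which X1 or X2 is constant contributes $\hat\rho_i = 0$ rather
  than `NaN`.

## Significance

The reference null is a **permutation test**: X3 is permuted against the
fixed pair and the two-sided p-value is
$(1 + \#\{|s_{perm}| \ge |s_{obs}|\})/(B+1)$. Because sorting a permuted X3
reproduces the same per-bin X3 values, a permutation is equivalent to
randomly re-assigning samples to the fixed bins; `mla_pvalue()` exploits
this for speed, and `scan_triplets()` shares each candidate's $B$
permutations across all pairs, which makes exact per-triplet permutation
p-values affordable at scan scale.

A permutation p-value can never fall below $1/(B+1)$, so a screen that wants
a BH FDR below, say, $10^{-3}$ across thousands of retained triplets would
need infeasibly many permutations. For that regime `scan_triplets()` offers
an analytic normal approximation: under independence
$\mathrm{Var}(\hat\rho_i) \approx 1/(n_i - 1)$, hence
$\mathrm{sd}_0 = \sqrt{\sum_i \bar X_{3i}^2/(n_i-1)}\,/\,M$ and
$p = 2\Phi(-|s|/\mathrm{sd}_0)$. The approximation leans on the
near-normality that the quantile transform enforces; the permutation test
remains the reference and is the one whose type-I calibration the test
suite checks (empirical rejection at $\alpha = 0.05$ within $[0.03, 0.07]$).

The scan retains at most `top_k` triplets, ranked by ascending p, then
descending $|\mathrm{MLA}|$, then gene ids (a total order, for
reproducibility), and computes the BH FDR over the retained set -- the
FDR of a top-$K$ screen, not of the full triplet population.

## The downstream gates

**Event-rate diagnostic.** At a threshold $t$, the *random* event rate is
(significant triplets)/(examined genes) and the *observed* rate is
(significant triplets)/(unique X3 genes). Concentrated X3 occupancy --
few genes switching many pairs, the biological expectation -- drives the
observed rate far above the random one. The per-gene criterion is made
explicit as a one-sided binomial tail: under uniform occupancy a gene's
count among $T$ significant triplets is $\mathrm{Bin}(T, 1/G)$; genes with
BH-adjusted tail below $\alpha = 0.05$ are flagged. (The aggregate curves
alone do not define a per-gene rule, so the binomial formalisation is this
package's choice, applied consistently.)

**Random-forest importance.** A bootstrap ensemble (ranger backend;
10,000 trees and `mtry` $=\sqrt{\#\text{genes}}$ by default) classifies
invasive vs non-invasive samples; importance is the mean decrease in
out-of-bag accuracy (MDA) when a gene's values are permuted. The permutation
loop is implemented in this package -- one seeded permutation per gene,
evaluated on every tree's out-of-bag samples -- so the estimator is defined
by contract rather than by a backend's internals. The classifier itself is
summarised by the out-of-bag vote ROC: AUC by the trapezoid rule and
sensitivity/specificity at the Youden-optimal threshold (the operating point
had to be chosen; Youden is the conventional one).

**Enrichment and the shared-term rule.** Gene sets come from a user GMT
file; each term is tested by the right-sided hypergeometric tail with BH
correction, reported at $p < 0.05$ and FDR $< 0.1$, and -- when the GMT
descriptions carry `level=N` metadata -- restricted to ontology levels
$\ge 6$, dropping terms too generic to be informative. The *universe* is a
required argument: all measured genes, the DE genes, or the triplet genes
give materially different p-values, and no silent default should decide
that. A triplet is *biologically coherent* when X1 and X2 share at least one
enriched term. Kappa-statistic term clustering as done by GUI enrichment
tools is deliberately not reproduced: the shared-term rule needs only term
membership.

**Regulatory network.** An ARACNE-style network: pairwise mutual
information on equal-frequency 2-D histograms
($\lceil n^{1/3}\rceil$ bins per axis by default, minimum 3), permutation
p-values per edge (shared nulls across pairs), edges kept at $p < 0.05$,
then the data-processing inequality applied to every triangle -- the
weakest edge is removed when its MI falls below $(1 - \varepsilon)$ times
the smaller of the other two, with tolerance $\varepsilon = 0.1$. The
histogram estimator (rather than a kernel density) keeps the pipeline
deterministic and exactly testable: MI(x, x) on $k$ even bins is exactly
$\ln k$, and the Gaussian closed form $-\tfrac12\ln(1-\rho^2)$ is met within
the plug-in bias, which is $\approx (k-1)^2/(2n)$ and is the reason the
near-zero null checks use explicit bin counts. The network is undirected:
without a transcription-factor list there is no basis for orienting edges,
and path support reads the same either way. A triplet is
*network-supported* when X3 reaches X1 and X2 by paths of at most 2
intermediate genes each.

**Confirmation.** The pipeline (`run_pipeline()`) applies the gates
conjunctively, in order: DE filter, triplet scan, FDR gate, non-random-X3
flag, top-$k$ importance, shared-term, path support. *Confirmed* triplets
pass both of the last two. Clinic-pathological association (Kruskal-Wallis
on expression across feature groups, with volume binned at 20 cm³, age at
the median, and an explicit minimum-group-size adequacy flag) and
mean-expression-by-grade profiles against a seeded random baseline panel of
$\lceil 0.001 \cdot \#\text{genes}\rceil$ genes close the analysis.

## What the generator emulates -- and what it does not

`synthetic_config()` describes a study shaped like a two-class tumour
profiling experiment: ~40 samples in a 22:18 class split, grades I--III for
non-invasive and III--IV for invasive samples, thousands of genes on a log
scale. Planted switch triplets draw X3 first and then (X1, X2) bivariate
normal with correlation $+\rho$ / $0$ / $-\rho$ by X3 tercile -- the
construction that directly instantiates what MLA measures. The middle
tercile is set to zero correlation so the planted expectation is
analytically positive. Defaults (20 triplets, $\rho = 0.85$, 100 DE genes
at 1.5 SD) are calibration choices for a detectable-but-not-trivial regime;
no published effect sizes exist for real switch triplets.

Linked mode adds what the downstream gates need to see: several pairs per
switch gene (occupancy the binomial flag can detect), class shifts on
switch/pair genes (so they survive the DE filter and carry forest signal),
relay genes for network paths, and an optional recurrence link. Two
subtleties matter and are easy to get wrong:

* the conditional correlation is keyed to the switch gene's **latent**
  (class-free) component, with the class shift overlaid afterwards. Keying
  it to the shifted values would make every class-linked gene a partial
  ordering proxy for the switch gene, and each such proxy would "echo" the
  planted pairs as significant triplets of its own -- a forest of spurious
  switches. With latent keying the echo correlation is exactly zero, while
  binning by the emitted values still recovers the partition (ordering
  agreement $\approx 0.87$ at a 1.15 SD shift);
* relay genes are built from latent signals only, so they stay out of the
  DE set and appear exactly where they belong: in the network, not in the
  scan.

`simulate_confirmatory_study()` packages the full end-to-end design: two
switch genes with eight pairs each over 160 samples, annotation terms that
mark exactly the first pair of each switch (the term contains the pair plus
the *other* switch gene -- never the triplet's own X3, which would let
rotated triplets through the shared-term gate), decoy and shallow terms,
and relays for the first pairs only. Under
`confirmatory_pipeline_config()` the pipeline confirms exactly those two
triplets: the other pairs fall at the shared-term gate, rotated and echoed
triplets at the occupancy flag, and annotated-but-unlinked candidates would
fall at the path gate.

What the generator does **not** emulate: probe-level noise, two-colour
array artefacts and background correction (inputs are assumed
pre-normalised single-channel matrices; the package's quantile
normalization is the between-array step only), batch effects,
heavy-tailed or count-distributed expression, and correlated noise between
unplanted genes. Passing tests therefore demonstrate that the methods
recover the structure they define under Gaussian conditions at these sample
sizes -- not that any particular real dataset contains such structure.

## Numerical and degenerate-input policy

* Quantile normalization refuses missing values (imputation is out of
  scope) and is idempotent.
* IQR probe collapse breaks ties by the lexicographically smallest probe
  id.
* Zero-variance genes: the moderated-t shrinks their variance towards the
  prior ($\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g) > 0$); the
  quantile transform and standardization refuse constant vectors;
  `mutual_information()` returns 0 by convention.
* All-tied Kruskal-Wallis input returns $H = 0$, $p = 1$ (the tie
  correction is undefined there).
* Every stochastic step takes an explicit seed; the pipeline derives
  per-stage seeds from one global seed, and identical configurations give
  byte-identical output files.

## Problem sizes used in the checks

The test suite and the acceptance script run: formula equivalence on 1000
random triplets ($n$ 30--120, $M$ 3--5); permutation calibration at
$n = 60$, $B = 999$, 500 repeats; recovery of 20 planted triplets among 200
genes at $n = 120$ ($\approx 3.9$ million scored triplets per seed, 5
seeds); forest discrimination with 1 informative among 200 noise features
over 100 seeds; and the 300-gene, 160-sample confirmatory pipeline. These
sizes keep a complete run in minutes on one core while leaving each
statistic enough data to meet its stated tolerance.

## Known limitations

* The cubic scan is $O(G^2 \cdot C)$ in pairs times candidates; the
  candidate-X3 restriction is the intended lever at desk scale, and no
  distributed mode is provided.
* The normal approximation for scan p-values is an approximation; its
  extreme tail has not been validated beyond the regimes exercised here,
  and permutation remains the reference.
* MDA uses one shared permutation per gene rather than per-tree
  permutations; rankings agree, but absolute MDA values are smoother than
  classic per-tree estimates.
* The binomial occupancy flag assumes triplets are exchangeable draws of
  X3, which ignores the correlation between triplets sharing a pair; it is
  a declared formalisation, not a reconstruction of any published rule.
* Directionality of regulatory edges is not inferred.

## A worked miniature

```{r mini, eval = FALSE}
study <- simulate_confirmatory_study(seed = 1)
cfg <- confirmatory_pipeline_config(study, out_dir = tempfile("run"))
res <- run_pipeline(cfg)
res$confirmed[, c("x1_id", "x2_id", "x3_id", "mla", "bh_fdr", "shared_terms_str")]
autoplot(res$event_curve)
autoplot(res$oob)
plot_triplet_scatter(study$expression,
  res$confirmed$x1_id[1], res$confirmed$x2_id[1], res$confirmed$x3_id[1])
```
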