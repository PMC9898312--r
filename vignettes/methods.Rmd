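---
title: "Methods: pathway enrichment and network-based key-gene discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway enrichment and network-based key-gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pathkey` evaluates the joint, pathway-level behaviour of a prioritized
candidate-gene list against per-gene differential-expression evidence, and
then extracts the network-central "key" candidates.  This vignette is the
package's own account of the statistics it implements, the choices that
were genuinely open, and what its validation does and does not show.

## Gene-wise statistic scores

The per-gene input is a p-value $p_i \in (0,1]$ per condition (e.g. a
time point of a submergence treatment), taken as given from an upstream
differential-expression analysis.  The gene-wise statistic is the 10-based
logarithm score $t_i = -\log_{10} p_i \ge 0$: larger means stronger
expression change, and the transform is strictly decreasing in $p$.
p-values of exactly zero (possible in upstream exports) are clamped to a
configurable floor ($10^{-300}$ by default) with a warning rather than
producing infinities.  Under a global null ($p_i$ uniform), the score
distribution is already right-skewed (it is exponential up to the base
change); real stress-response datasets are far more so.  The
moment-coefficient skewness $g_1 = m_3 / m_2^{3/2}$ (population moments,
no small-sample correction — the simplest defensible form, and a
documented choice since bias-corrected variants differ only at tiny $n$)
is exposed to characterise this asymmetry.  The per-gene significance flag
uses a strict inequality $t_i > 3$: genes exactly on the conventional
$-\log_{10} p = 3$ line are *on* the threshold, not above it.

## Competitive test: hypergeometric over-representation

With a universe of $L$ measured genes containing $M$ candidates, a pathway
of $S$ genes and an observed candidate/pathway overlap $g$, the one-sided
over-representation p-value is

$$p = \sum_{x=g}^{\min(S,M)} \frac{\binom{S}{x}\binom{L-S}{M-x}}{\binom{L}{M}}.$$

The sum is accumulated from log-binomial coefficients (`lchoose`) with a
max-shift, so it is stable for $L$ in the tens of thousands; $g = 0$
returns exactly 1.  The background is a real modelling choice the input
formats do not fix: `pathkey` uses $L$ = genes present in the condition's
score table (after the pathway collection is intersected with it) and
$M$ = candidates within that universe, and records both in the result
attributes and the run manifest so any alternative background is
reproducible.  Pathway-size filtering (inclusive bounds, defaults 6 and
1500 — sets below 6 genes are uninformative, sets above 1500 are
near-background) and restriction to pathways containing at least one
candidate happen before testing.  Gene identifiers are lower-cased and
whitespace-stripped before any set operation, because Glyma-style
identifiers are case-inconsistent across annotation sources.

## Self-contained tests: SUMSTAT and SUMSQ

For a pathway with member scores $t_1,\dots,t_S$ the enrichment scores are
$ES_{\mathrm{SUMSTAT}} = \sum_i t_i$ and
$ES_{\mathrm{SUMSQ}} = \sum_i t_i^2$.  Genes outside the pathway never
enter the observed score.  The null is size-matched gene-label
resampling: random subsets of $S$ genes drawn without replacement from the
score universe.  Phenotype (sample-label) permutation is impossible here —
only gene-level summaries are available — so the scheme is necessarily
correlation-naive; this is a known simplification shared with the class of
methods it implements.

Three quantities are reported per pathway:

- the add-one empirical p-value $p = (1+b)/(1+B)$ with $b$ the number of
  permuted scores $\ge$ the observed one, so zero is never reported and
  the floor is $1/(B+1)$;
- the normalized ES, $z = (ES - \overline{ES}_{perm})/sd(ES_{perm})$;
- the asymptotic p-value $\Phi^{-1}$-free upper tail $1-\Phi(z)$, which
  resolves evidence *below* the empirical floor.

Significance calls use the empirical p-value (default threshold
$10^{-4}$, with Benjamini–Hochberg at 0.05 and Bonferroni reported
alongside); the asymptotic tail is reporting-only by default.  With
$B = 10{,}000$ the floor is $9.999\times10^{-5}$, i.e. a call at
$10^{-4}$ requires the observed score to beat every permutation — worth
knowing when interpreting published sub-floor values, which can only come
from a continuous tail.

**Null generation.**  One permutation draws a single without-replacement
prefix of $\max S$ genes; the null score of a size-$k$ pathway is the
statistic of the first $k$ drawn genes (a prefix of a uniform random
sequence is a uniform $k$-subset, so the marginal null per size is exactly
the subset-resampling null).  All pathway sizes are therefore served by
one $O(B \cdot \max S)$ pass, equal sizes share a null distribution, and
results do not depend on pathway iteration order.  Nulls across sizes
within one permutation are correlated, which affects nothing reported
per pathway.  The standalone `permutation_null()` primitive instead uses
an independent RNG stream derived from `(seed, statistic, size)`.  All
derived seeds stay below $2^{31}$.

## Consensus across conditions and methods

Per method, the consensus set is the pathways significant at *every*
condition (optionally: at least one).  Across methods the package emits
pairwise intersections, the all-method intersection, and the union
(`combined`).  The union is the headline combined result: competitive and
self-contained tests answer different null hypotheses, and their joint
report is the union of their calls — an intersection would discard
pathways detectable under only one null, exactly the complementarity that
motivates running both families.  SUMSQ in particular is noisy on
heavy-tailed $-\log_{10}$ scores (its null variance is dominated by
fourth moments), so its solo consensus set is typically small.

## Network analysis and key genes

The reference interactome is an undirected simple graph from a weighted
edge list (duplicate unordered edges keep the maximum weight; self-loops
are dropped with a warning).  Candidates from a consensus pathway set seed
a subnetwork: seeds present in the reference are retained, plus every
non-seed gene adjacent to at least `min_seed_links = 2` seeds — the
recruited *intermediate* genes that connect multiple candidates.  This
recruitment rule is a parameterised stand-in for proprietary
functional-module tools whose exact algorithms are unpublished; two seed
links is the weakest notion of "connects candidates".

Centrality is the unweighted degree (edge weights are carried but not
summed into centrality, keeping degrees integer and interpretable).  The
dense core is the set of nodes whose degree in the *parent* seeded network
falls in the inclusive band `[20, 30]`; band membership deliberately uses
parent degrees, not degrees recomputed on the induced core.  For display,
nodes of degree $\le 2$ can be collapsed into a single meta-node
(`Group0_2`) that merges member edges per retained neighbour (max weight,
multiplicity recorded) and is excluded from any selection.  The **key
genes** are the union over networks of core members that are candidates;
intermediates are never key genes, and provenance (which network
contributed each gene) is attached.

Group comparisons (key vs other candidates vs intermediates vs remaining
genes, a partition with candidate-over-intermediate precedence) use a
one-sided permutation test on the mean-score difference.  When the number
of label splits fits the resampling budget the test enumerates all splits
and is exact (no add-one); otherwise it draws `n_resamples` shuffles with
the add-one estimator.  Welch's *t* is available as the asymptotic
alternative, but the permutation test is the default because score
distributions are heavily skewed.  The generic pooled two-proportion
$z = (\hat p_1 - \hat p_2)/\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$ is
provided for comparing flag proportions between gene groups (e.g. the
share of conditions in which a gene clears the single-gene threshold
against the background share); it returns 0 with a degeneracy flag when
the pooled proportion is 0 or 1.

## What the synthetic data emulate

`synthetic_truth()` fixes every random choice as a pure function of the
seed, and the generators reproduce the dataset bitwise.  Defaults model a
four-condition stress-response study at desk scale:

- **Universe and pathways** — 5,000 genes; 200 pathways with sizes
  log-uniform on [6, 300] (log-uniform spans the realistic size range
  without letting giant sets dominate), memberships sampled independently
  so overlap arises naturally.
- **Planted enrichment** — 10 pathways drawn from sizes 20–50; *all* their
  members get $p \sim \mathrm{Beta}(a, 1)$ with $a = 0.1$ (stochastically
  smaller than uniform; $a = 1$ recovers the null) in every condition,
  since a multi-condition consensus needs persistent signal.  The eligible
  size window is a power consideration: below ~20 genes a
  fully-enriched pathway's score sum is not reliably separable from the
  permutation null once that null is itself contaminated by planted genes.
- **Candidates** — 144 genes (echoing a 144-gene prioritized list with its
  score cutoff of 42): 30% of each enriched pathway's members (at least 6)
  plus a uniform background fill.  The minimum of 6 keeps the
  hypergeometric p-value of the smallest planted pathway near $10^{-5}$
  under this background.
- **Network** — a preferential-attachment background over 300 non-candidate
  genes (3 edges per node, so background mean degree is near 7 with the
  heavy right tail typical of interactomes); ordinary candidates attach to
  two background nodes; each of 5 planted hub candidates is wired to
  20–28 planted-candidate neighbours, so hubs sit in the 20–30 band by
  construction while every other candidate stays below degree
  `n_hubs + 2`.

Not emulated: gene–gene correlation within pathways, condition-specific
enrichment onset (available as an option, off by default),
candidate genes missing from the interactome, and any read- or
count-level structure.  Passing tests therefore demonstrate the
*machinery* — calibration, exactness, recovery under the stated model —
not performance on correlated real transcriptomes.

## Validation design and problem sizes

The test suite checks, among others: hypergeometric agreement with
exhaustive enumeration over every feasible instance with $L \le 25$
(and a literal $\binom{20}{5}$ draw enumeration); type-I calibration and
normalized-ES moments of SUMSTAT under a global null (20 seeds,
$B = 2{,}000$, 200 pathways); recovery of all 10 planted pathways through
the combined consensus and full planted-vs-null ranking separation for
each method over 50 seeded studies at $B = 10{,}000$ (self-contained
methods ranked by mean normalized ES across conditions — the
cross-condition evidence, which is the stable ranking statistic for
SUMSQ); empirical p-values against the exact $\binom{5}{2}$ null;
BH/Bonferroni against their literal formulas on 1,000 random vectors;
exact recovery of planted hubs in 20/20 seeds with the handshake lemma on
every graph; exact-enumeration agreement and a 5% null rejection rate for
the group test; and byte-identical pipeline reruns.  These sizes keep the
full validation in the minutes range on a single core while leaving the
statistical margins wide (the design-stage separation margins for the
ranking checks exceeded 5 z-units for SUMSTAT and 1 z-unit for SUMSQ).
`scripts/acceptance.R` recomputes all of these from scratch for any seed.

## Known limitations

- The permutation scheme cannot account for inter-gene correlation;
  empirical p-values on correlated real data will be anti-conservative to
  a degree the package cannot estimate from gene-level summaries alone.
- The hypergeometric background ($L$, $M$) is a choice; results are only
  comparable across runs holding it fixed, which is why it is logged.
- Degree centrality is the only network-importance measure; betweenness or
  eigenvector centrality would rank connector genes differently.
- GO sets are used flat: no DAG propagation, ancestry, or evidence-code
  filtering.
- The intermediate-recruitment rule approximates, but is not, any specific
  interactome service's module extraction.
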