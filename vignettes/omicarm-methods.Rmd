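---
title: "Mining and ranking co-occurring gene alterations with omicarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and ranking co-occurring gene alterations with omicarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicarm)
```

## The problem and the model

Tumors accumulate molecular aberrations — differential expression,
hyper-/hypo-methylation, mutations — that recur *together* across patients,
and co-occurrence across samples or across regulation layers often points at
a shared mechanism. omicarm treats each patient sample as a *transaction*
and each altered gene as an *item*, and mines association rules
$X \Rightarrow Y$ (disjoint gene sets $X$, $Y$) from the binary
sample-by-gene alteration matrix $M_b$ with the Apriori algorithm. The
classical measures are computed exactly:

* $\mathrm{supp}(X \Rightarrow Y) = \Pr(X \cup Y)$, the fraction of samples
  in which every rule gene is altered;
* $\mathrm{conf}(X \Rightarrow Y) = \mathrm{supp}(X \cup Y)/\mathrm{supp}(X)$;
* $\mathrm{lift}(X \Rightarrow Y) = \mathrm{conf}(X \Rightarrow Y)/\mathrm{supp}(Y)$,
  enrichment over independence (1 = none).

Binarization, however, throws information away, and the cutoff it uses is
arbitrary. The package's central measure, **Lamda3**, therefore goes back to
the *continuous* matrix $M_c$ when judging a rule $A \Rightarrow C$. Using
$M_b$, samples are split into three parts: $M_c^2$ (both $A$ and $C$
altered), $M_c^0$ (both unaltered) and $M_c^1$ (inconsistent — computed and
reported for diagnostics, but not used by the score). Within each consistent
part the correlation-test p-value of $A$ and $C$ is compared with the median
p-value of $A$ against every other gene of the matrix:

$$
\mathrm{Lamda3} =
  \frac{\log_{10} P^2_{A,C} + \log_{10} P^0_{A,C}}
       {\log_{10} P^2 + \log_{10} P^0},
\qquad
P^k = \operatorname{median}_{g \neq A,C} P^k_{A,g},\; k \in \{2, 0\}.
$$

A value above 1 means the rule pair is more tightly coupled than the
background in both the dysregulated and the normal subpopulation; a value
near 1 means the rule is no better than an arbitrary gene pairing, however
high its support. Because Pearson correlation is scale-invariant, Lamda3 is
unchanged by positive per-gene rescaling — the discretization cutoff moves
the partition boundaries but not the continuous evidence inside them.

## Pipeline and tunable parameters

```{r pipeline, eval = FALSE}
m   <- read_omics_matrix("expr.tsv")                   # samples x genes
m   <- select_top_genes(drop_missing_genes(m), 50)     # variance fallback
b   <- discretize(m, discretization_spec("zscore", 1.96, "both"))
r   <- mine_rules(b, min_support = 0.3, min_confidence = 0.8)
r   <- score_rules(r, m, b)
rank_rules(r, "lamda3", top_k = 20)
```

| parameter | default | meaning |
|---|---|---|
| `min_support` | 0.3 | minimum fraction of samples carrying every rule gene |
| `min_confidence` | 0.8 | minimum conditional frequency of the consequent |
| `max_rhs` | 1 | maximum consequent size (classical single-consequent induction) |
| discretization | z-score, 1.96, both | two-sided 5% normal cut per gene |
| `top_k` | 20 | rules kept after ranking |
| correlation | Pearson | Spearman available via `method = "spearman"` |

The defaults mirror the thresholds routinely used for 50–100-gene cancer
panels (support 0.3, confidence 0.8, top 20 rules); at that scale exact
Apriori with per-item transaction vectors completes in milliseconds, so no
approximate mining is offered.

### Discretization methods

Five per-gene binarizations are provided (`discretization_spec()`): z-score
(`|z| >` threshold), empirical quantile (strictly below the $q$-th or above
the $(1-q)$-th quantile — ties at the boundary are deliberately 0, which
keeps the rule deterministic), top-fraction (the $\lceil f\,m \rceil$ samples
with largest $|x - \mathrm{median}|$), mean±SD, and a fixed absolute cut. In
every method `direction` restricts the *sign* of the selected deviation:
`"up"` keeps the upward half of the `"both"` selection and `"down"` the
downward half, so `up OR down == both` holds exactly for all five methods —
a uniform semantics that makes one-sided runs composable and testable.
Constant genes under z-score/mean±SD become all-zero columns with a warning
rather than an error, since dropping them silently would change gene counts
downstream.

## Numerical choices in Lamda3

* **p-value floor.** Correlation p-values are clamped to
  $[10^{-300}, 1]$ before taking $\log_{10}$, so perfect correlations give a
  finite, platform-stable score instead of $-\infty$.
* **Minimum partition size 3.** A correlation p-value on fewer than 3 points
  is meaningless; if either consistent partition is smaller, the rule's
  Lamda3 is `NA` rather than a guess. Constant vectors and length-2 inputs
  likewise contribute p = 1.
* **Zero denominator.** If both background medians equal 1 (e.g. a flat
  background), the denominator vanishes and the score is `NA` — nothing is
  fabricated.
* **Background set.** "Other genes" means every gene of the input matrix
  except $A$ and $C$, not merely genes appearing in mined rules; the
  background is a property of the dataset, not of the rule list.
* **Multi-gene rules.** The defining formula is a single-pair statement. For
  rules with several antecedent or consequent genes the package evaluates
  the formula on every (lhs gene, rhs gene) pair and reports the median pair
  value, with the breakdown of the median-achieving pair. This reduces
  exactly to the printed formula for 1→1 rules and degrades gracefully; it
  is an aggregation choice, clearly flagged here, not part of the measure's
  definition.
* **Aggregation by median.** Both the background summary and the multi-pair
  aggregation use the median, which is permutation-invariant and robust to a
  single extreme background gene.

**Weighted condensed support.** `wcs_score()` implements
$\mathrm{supp}(X \cup Y) \times \overline{w}_{X \cup Y}$ with gene weights
in $(0, 1]$; `rank_weights()` maps an external gene ranking to
$w_g = (n - \mathrm{rank}_g + 1)/n$. With unit weights (the default when no
ranking exists) wcs equals support exactly — which is also why wcs is not
informative when no ranking is available. This formula is the package's
documented interpretation of "rank-weighted support"; other weighting
schemes can be injected through the `weights` argument.

**Ranking.** `rank_rules()` sorts descending with `NA` last and a fixed tie
break (lift, then support, then lexicographic antecedent/consequent), so the
top-$k$ list is identical across platforms even when — as is common at these
thresholds — many rules tie on support and confidence.

## Two-layer integration

`combine_layers()` intersects the sample IDs of two layers (exact string
match after whitespace trimming; no barcode munging), suffixes gene IDs with
`.1` (layer 1, e.g. mRNA) and `.2` (layer 2, e.g. methylation) and
concatenates columns, identically for the continuous and binary matrices.
Rules mined from the combined matrix are restricted to cross-layer
associations by `filter_cross_omics()`. Its default `"span"` mode keeps a
rule when its items cover both layers; the stricter reading — no consequent
gene sharing a layer with any antecedent gene — is available as
`mode = "strict"`. Span is the default because mixed antecedents such as
{mRNA gene, methylation gene} ⇒ {mRNA gene} are exactly the mechanistic
patterns this analysis is after, and a strict rule would discard them.

## What the synthetic generator does and does not emulate

`generate_single_omics()` plants gene pairs that (i) share a latent factor,
so their continuous values correlate near `target_cor` (default 0.95) both
inside and outside the altered subset, and (ii) are jointly shifted upward
(default 3 SD) in a `fraction` (default 0.5) of samples, which the binary
matrix marks as their alteration pattern. All other genes are independent
Gaussian noise binarized at the default two-sided z-score cut, so they fire
in ≈5% of samples and essentially never assemble pair support ≥ 0.3. The
pair-noise SD is $\sqrt{(1-r)/r}$, which gives the latent-plus-noise sum the
target correlation $r$ exactly in expectation. `generate_paired_omics()`
repeats the construction across two layers with a configurable sample
overlap, and `toy_paired_layers()` is a fully deterministic block design for
exact-count tests.

This emulates what the measure needs — a coupled pair over a flat background
— and nothing more: marginal distributions are Gaussian rather than
count-like or beta-like, there are no batch effects, no correlated gene
modules beyond the planted pairs, and noise genes are independent. Passing
the planted-recovery tests therefore shows that the pipeline finds what it
is designed to find under its own assumptions, not that it will rank rules
well on any particular real cohort.

Default test and simulation sizes are kept deliberately small (60 samples ×
20 genes per run, 50 repetitions for recovery rates, ≤12-gene matrices for
the exhaustive mining oracle), which is ample for exact brute-force
cross-checks while keeping the whole suite under a minute.

## Known limitations

* Differential-expression/-methylation testing is out of scope: the package
  accepts any pre-ranked matrix and offers only the variance-based
  `select_top_genes()` fallback.
* No multiple-testing control is applied across rules; Lamda3 is a ranking
  measure, not a calibrated test statistic.
* Three-or-more-layer combination is not implemented.
* GO-based functional-similarity evaluation of rule quality requires
  external annotation data and is not part of the package; the ranking API
  is callback-friendly so such an evaluation harness can be attached.
* Rule visualization is limited to the bipartite network export
  (GraphML/DOT) and the grouped incidence table; the greedy
  exact-then-Jaccard antecedent grouping is a documented heuristic, chosen
  because it is deterministic and reproduces "families of rules sharing
  antecedent genes" on small rule lists, not the output of any particular
  clustering package.
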