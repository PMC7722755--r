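---
title: "Methods and design notes for microbe-set enrichment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for microbe-set enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msea)
```

## The model

Microbe-set enrichment analysis asks whether an input list of microbes —
typically taxa with differential abundance between conditions — overlaps a
curated microbe-set more than chance would allow. For input size $n$, set
size $K$, overlap $a$ and a universe of $N$ taxa, the test statistic is the
upper-tail hypergeometric probability

$$p = P(X \ge a), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),$$

i.e. the one-sided Fisher's exact test in the enrichment direction. The
test assumes members of the universe are exchangeable and that sets and
inputs are sampled independently from it; neither holds exactly for real
taxa (phylogenetic structure induces correlation), which is one reason the
rank correction below exists.

### The universe

$N$ is not the library union alone: it is the union of everything the
profiling pipeline could have reported and everything the library
annotates. `determine_universe()` takes a profiled-taxa list when the user
has one; otherwise it uses a fixed default of $N = 1000$, treating the
library union as the named portion and the remainder as unnamed profiling
capacity. The distinction matters operationally: with a fully enumerated
universe, input members outside it are dropped with a warning (profiling
pipelines emit taxa no library covers); with unnamed capacity, unknown
input members are assumed to occupy it and count toward the input margin
only. An explicit `size` smaller than the named members is an error rather
than a silent truncation.

### Rank correction and combined score

Fisher's test (and proportion tests generally) favors large sets. The
correction standardizes each set's *rank*: `null_rank_model()` draws
random inputs of the observed input's size uniformly without replacement
from the universe, scores every set by $p$, ranks ascending (average ranks
on ties), and repeats — 10,000 times by default — to get each set's null
mean and standard deviation of rank. The observed rank then yields

$$z = \frac{r_{\mathrm{obs}} - \bar r_{\mathrm{null}}}{s_{\mathrm{null}}},
\qquad c = \log_{10}(p)\cdot z .$$

Since $\log_{10}(p) \le 0$, a better-than-expected rank (negative $z$)
gives a positive combined score; $c = 0$ exactly when $p = 1$ or $z = 0$.
Both the $p$-ordering and the $c$-ordering of results are exposed
(`sort = "p"` is the default; nothing in the statistic privileges one for
"top tables", so the choice is left to the user).

## Library construction

**Taxonomy.** Greengenes-style lineages (`k__...;p__...;...;s__...`) are
parsed into a tree — one node per distinct (rank, name, lineage-prefix),
strains discarded, the Viruses and Viroids kingdoms dropped since 16S data
cannot contain them — and converted to a library by enumerating, for every
node at a chosen rank, the names of its leaf descendants. Species-rank
conversion is refused: every set would be a singleton of itself. Name
normalization strips rank prefixes and the `_noname` / `_unclassified`
suffixes, replaces underscores with spaces, and is idempotent; matching is
case-insensitive with first-seen capitalization kept for display.

**Literature.** From a corpus of documents with recognized microbe and
gene mentions, the strength of a (microbe, gene) association is the
Jaccard index of their mentioning-document sets,
$|co| / (|d_m| + |d_g| - |co|)$, with $0/0$ defined as 0. Associations are
binarized by keeping the top fraction of *all* grid pairs —
zero-score pairs included in the denominator, which is what makes the
default 0.1% a high quantile — with all pairs tied at the cut retained
(deterministic and order-independent) and zero-score pairs never
retained. The retained pairs invert into one microbe-set per gene.

The binarization fraction can be chosen by `select_threshold_by_taxonomy()`:
for each candidate it computes, over all microbe pairs, the Spearman rank
correlation between gene-profile Jaccard similarity and taxonomic
similarity (depth of the deepest shared ancestor divided by the tree's
maximum depth), and keeps the maximizing candidate. Both the statistic and
the tree similarity are one defensible instantiation of "correlation with
the taxonomy" among several; the statistic is therefore pluggable
(`similarity_fun`).

**Disbiome-style curation.** Disease–organism records collapse to one set
per disease with the direction of change (elevated/reduced) deliberately
ignored — a disease's set is every organism ever linked to it. Blank
organisms are skipped with a counted warning; an all-blank input errors.

## Reporting

`bipartite_graph()` draws one edge per (term, shared member) for the top
$k$ terms, weighted by combined score, node size = degree.
`overlap_network()` connects term pairs whose member overlap is
significant by the same one-sided Fisher test, BH-corrected over all pairs
(the correction method for the pairwise test is unstated territory; BH
matches the q-value convention used everywhere else in the package), with
edges at corrected $p < 0.01$ and an explicitly required background size.
`embed_tsne()` is an exact (dense) t-SNE written in-package — perplexity
calibrated per row by bisection, early exaggeration, momentum gradient
descent — suitable for the hundreds-of-rows matrices this package
produces; it is deterministic given its seed and refuses inputs with fewer
than $3\times$ perplexity rows.

## Numerical choices

- **Odds ratio**: $(ad)/(bc)$ with the Haldane–Anscombe $+0.5$ applied to
  every cell when any cell is zero.
- **q-values**: Benjamini–Hochberg step-up across the terms of one library
  per run.
- **Ties**: average ranks, both observed and in the null, so tied p-values
  cannot reorder results across runs.
- **Degenerate null** (`sd_rank = 0`): $z$ is set to 0 and flagged rather
  than propagating an infinity.
- **TF-IDF variant**: row-normalized term frequency with natural-log
  $\mathrm{idf} = \log(N/\mathrm{df})$ — a gene co-mentioned with every
  microbe gets an exactly zero column, making the "offset ubiquitous
  genes" rationale literal; microbes with all-zero rows stay all-zero.
- **RNG**: every stochastic routine takes a seed and restores the caller's
  RNG state, so library code never perturbs a user's random stream; seeds
  are echoed into result attributes and CLI manifests.

## The synthetic generators

The generators exist so that every pipeline stage is testable with planted
truth. `make_mention_corpus()` mentions each entity independently per
document at a background rate and co-inserts planted pairs at their own
rates — it emulates co-mention *counts*, not citation-count skew, topic
bursts, or NER errors of real literature. `make_planted_library()` draws
uniform random sets and rebuilds one to share an exact overlap with the
emitted input — real libraries have correlated, size-skewed sets.
`make_toy_taxonomy()` is a balanced tree; real taxonomies are ragged.
Passing the planted-recovery and calibration checks therefore demonstrates
the statistics are implemented correctly under their own assumptions, not
that real corpora are this clean.

Verification runs at desk scale: the exhaustive Fisher sweep covers all
2×2 tables with $N \le 60$ (~6×10⁵ tables); null calibration uses a
200-term library over a universe of 1000 with a 1000-repetition null and
100 evaluation inputs; planted recovery uses 100 seeded simulations at
universe 1000, 30 sets, input 20, overlap 10; the literature check uses
ten 500-document corpora on a 20×20 entity grid. These sizes make the
properties sharp (binomial noise well inside the asserted bounds) while
keeping a full run in tens of seconds.

## Known limitations

- Counting-based association ignores negation and context ("X does not
  induce Y" still co-mentions); a mention corpus of abstracts inherits
  every bias of its retrieval.
- Mixed genus- and species-level members coexist in one library and are
  treated as distinct universe elements, so a genus and its species can
  both count toward an overlap.
- The default $N = 1000$ is a convention, not an estimate; enrichment
  p-values shift with $N$, and users with a real profiled-taxa list should
  pass it.
- The exact t-SNE is $O(n^2)$ per iteration and is intended for the
  package's matrix sizes (hundreds to a few thousand rows), not bulk
  embedding.
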