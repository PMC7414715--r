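---
title: "Detecting recurrent sequence evolution between independently duplicated paralogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent sequence evolution between independently duplicated paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the unit of analysis

When a gene duplicates independently in several eukaryotic lineages, the two
copies may repeatedly settle into the same pair of *fates*: each copy
conserves its own distinctive set of residues (subfunctionalization), or one
copy acquires a new feature such as an N-terminal target peptide
(neofunctionalization by relocalization).  `refates` detects this recurrent
sequence evolution in a single family alignment containing one paralog pair
per species.

The unit of every statistic is the **quartet**: the two paralogs `a`, `b`
of species X aligned with the two paralogs `c`, `d` of species Y.  Four
homologous sequences admit three unrooted topologies,

* `Q = (a,b)|(c,d)` — each pair coalesces within its species: the pairs
  stem from two *independent* duplications;
* `R = (a,c)|(b,d)` and `S = (a,d)|(b,c)` — the copies group across
  species: either a single ancestral duplication, or (when `Q` is the true
  history) a secondary, fate-like correspondence.

Alignment columns with a clean `xxyy` split support one topology each
(`count_site_patterns()`).  Columns with a gap or ambiguous residue in any
of the four sequences are unusable; all-identical columns are usable but
uninformative.  This strict reading (degenerate patterns such as `AAAT` or
`AABC` support nothing two-sided) keeps the three categories disjoint; the
one-sided patterns `ABAC` and `ABCB` are tallied separately as `t` and `u`.

## Quartet statistics

**Duplication score.** Whether the two pairs share one duplication is
decided by likelihood, not by raw counts: per-site log-likelihoods of the
three topologies are computed with Felsenstein pruning under LG with
10 equal-probability discrete-gamma categories, branch lengths are fitted by
bounded coordinate ascent (five branches, tolerance `1e-6`, at most 20
sweeps, deterministic order), and the gamma shape is estimated once on the
best topology and shared.  Expected likelihood weights are then obtained by
RELL resampling: `B = 1000` replicates of `L` sites drawn with replacement,
softmax of the replicate totals, averaged.  The duplication score is
`D = 1 - w_Q`, the pooled weight of the two single-duplication topologies:
`D` near 0 means the pairs duplicated independently, `D` near 1 means they
share the ancestral duplication.  A pattern-share screening mode
(`parsimony_weights()`, `w_i = n_i / (n_Q + n_R + n_S)`) gives the same
ranking at a small fraction of the cost (Spearman correlation above 0.8 on
simulated quartets) and is what the validation suite uses for whole-family
runs.

**Fate similarity.** The secondary signal is an imbalance between the two
cross-species correspondences: `F = |n_R - n_S| / (n_Q + n_R + n_S)`.  Its
significance treats the pattern classes as multinomial outcomes along the
`l` usable columns, giving the exact variance of the count difference

```
V(dF) = n_R (1 - n_R/l) + n_S (1 - n_S/l) + 2 n_R n_S / l,
Z_F   = |n_R - n_S| / sqrt(V(dF)).
```

Two readings of the cross term are possible; the factor `2xy/l` (total, not
per ordered pair) is used because it makes `V` *exactly* the multinomial
variance of `n_R - n_S` — the suite checks this identity symbolically and
against 10^5 multinomial draws.  Likewise `l` counts usable columns rather
than raw alignment length, so counts and their sample space agree; both
choices are centralized in `bernoulli_variance()`.

**Asymmetry.** Within the resolved pairing, `t` counts columns where only
the first fate-matched side is conserved and `u` those where only the
second is; `Z_A = |t - u| / sqrt(V(dA))` is built exactly like `Z_F`.  A
tie (`n_R = n_S`) leaves the pairing, and hence the asymmetry, undefined;
such quartets contribute no fate edges.  No normalized asymmetry index is
reported — only `dA` and `Z_A`, whose construction is fully specified.

## Family integration

Species become nodes of a complete **duplication network** weighted by `D`.
Weighted cluster editing with threshold `theta = 0.6` partitions them into
blocks sharing one ancestral duplication: the signed similarity is
`s(i,j) = D(i,j) - theta`, so pairs with `D > theta` attract.  Up to 10
species the optimum is found by exhaustive enumeration of set partitions;
beyond that, a deterministic greedy pivot construction with several starts
plus single-node and block-merge local moves is used (it matched the
enumerated optimum on at least 95 of 100 random 4–7 node graphs and can
never report a cost below it).  Degenerate quartets contribute a neutral
edge at exactly `theta`.

Genes become nodes of a **fate network**: each non-tie quartet adds its two
fate-matched edges weighted by `F`, repeated observations of a gene pair
averaged so quartet-rich families are not inflated.  Markov clustering with
the strong settings inflation 10 / expansion 5 extracts fates.  Two
implementation details matter at these settings and are deliberate:

* *Self-loops are minimal* (`1e-6`, only so isolated nodes have a defined
  chain).  Any sizeable loop weight — e.g. the node's maximum incident
  weight — survives inflation 10 as the largest column entry and freezes
  every node into its own singleton; with minimal loops the clustering
  recovers simulated fates exactly.
* *Pruning operates on the column-normalized matrix.*  After expansion the
  entries of a 12-clique are near `1/12`, and raising them to the 10th
  power gives ~`3e-11`; pruning at `1e-8` before renormalization would
  empty whole columns.

Clusters are read off the limit matrix through its attractors (positive
diagonal), attractor systems merged when they attract one another, and every
node assigned to its strongest attractor (ties broken lexicographically).
Loop-free chains can also converge to a *periodic* limit — a bare two-node
edge oscillates and never builds diagonal mass — so nodes left without an
attractor are grouped by the weakly connected components of the limit
matrix, which reads such a pair correctly as one two-gene cluster.

## Bootstrap support, P and mean Z_F

Alignment columns are resampled with replacement to the original length 100
times; pattern counts, `F`, pairings, the fate network and its clustering
are recomputed per replicate.  The duplication clustering is *not*
recomputed: only the fate side is being assessed, and repeating the
likelihood topology tests per replicate would dominate the runtime without
changing what the bootstrap measures.  The robustness of a baseline fate
cluster is its mean best Jaccard match across replicates; clusters are kept
greedily by robustness (non-overlapping, cutoff 0.5).

**Pervasiveness** `P` is the number of duplication blocks whose every
member pair is split across one specific pair of robust fates; the pair
achieving the maximum is the prevailing differentiation (ties resolved by
the larger mean `Z_F`, then lexicographically).  A family where robust
fates exist but no pair covers any block reports `P = 0` with a flag rather
than an undefined value.  **Magnitude** is the mean `Z_F` over quartets
whose pairs lie in two different blocks counted in `P` — the quartets that
actually witness recurrent sequence evolution — and is reported only when
`P >= 2`.

## Downstream readouts

Quartets are categorized as independent-duplication (species in different
blocks) or single-duplication, the latter split into WGD and Other when an
ohnolog annotation table is supplied; conflicting annotations exclude the
quartet.  The categorical summaries operate on at most 200 quartets per
family (`sample_quartets()`, a seeded uniform subsample beyond the cap);
the clustering steps always use every quartet, since the networks need all
species pairs.  Asymmetry summaries report, per category, the fraction of
significantly asymmetric quartets (`|Z_A| > 1.96`) among significantly
fate-similar ones (`|Z_F| > 1.96`) with exact binomial standard errors.

Subcellular localization predictions (four compartments, reliability
classes 1–5) enter only for quartets where all four genes pass the strict
filter (class `< 3`).  Configurations are labeled in this order: `uniform`,
`consistent` (compartments follow the fate pairing and differ between
fates — recurrent relocalization), `inconsistent` (crossed), `single_distinct`
(exactly one deviating gene), `other`; the first two differing-compartment
labels are mutually exclusive by construction and the residual class is
explicit.

Finally the signal is mapped back onto columns: for every pair split across
the prevailing fates, each column is classified over all quartets linking
it to pairs of *other* blocks (two-sided match, one-sided match per side,
crossed counterparts), and colored warm when support outweighs
contradiction.  Gaps count as a 21st state here — and only here — so that a
shared presence/absence block such as a target peptide registers as a
recurrent element; ambiguous residues still void the column.  Because
per-pair majority calls fluctuate under neutral divergence,
`recurrent_columns()` summarizes at the family level and requires support
from a majority of pairs, which keeps spurious warm columns below ~5% in
simulations while retaining the injected diagnostic and extension columns.
Column indices are 1-based in every output.

## The simulator and what passing means

`simulate_family()` generates the study conditions used by the whole test
suite.  Defaults: 12 species in four clades of three (within-clade depth
0.3, long inter-clade branches), one duplication at each clade ancestor —
four independent duplications — 500 columns, root drawn from LG
frequencies, per-branch LG substitution, optional discrete-gamma site
rates.  Recurrence is injected at 30 diagnostic columns per fate: all genes
of the constrained fate, in *every* block, carry the same frozen residue,
while the other fate evolves freely (`one_sided` mode puts all constraints
on fate 1).  Optional features: an N-terminal extension block carried only
by fate-2 copies (gapped elsewhere) and per-fate localization labels.
These branch lengths keep within-species paralogs alignable while giving
cross-clade quartets a long internal branch, so the topology signal and
the injected fate signal are both realistic in size (cross-block quartets
have `n_Q` around 100 and a diagnostic `n_R` excess around 15–30 at the
defaults).

Hard-frozen diagnostics give sharp truth for recovery tests, but they
concentrate pattern probability in a fixed column set, which the
multinomial variance model does not assume; the practical consequence is
*conservative* `Z` statistics at such columns, never anticonservative ones.
The null calibration of `Z_A` is therefore measured on families without
injected recurrence, where one-sided patterns arise from the iid
substitution process and the statistic is exactly multinomial (observed
exceedance ~5% at 1.96); under hard symmetric constraints the suite checks
conservativeness instead.  The simulator also omits indels (beyond the
extension block), gene loss, extra duplications and gene conversion, so
passing tests demonstrate correct recovery under clean duplication
histories — not robustness to misalignment or to the paralog-number
filtering that precedes real analyses.

## Numerical and scale choices

Branch lengths live in `[1e-8, 10]`; likelihoods are floored at `1e-320`
before logging; the gamma shape is searched in `[0.05, 20]` (tolerance
`1e-3`), and a bound whose profile likelihood lies within half a log-unit
of the optimum is reported as a boundary solution (rate-homogeneous data
end at the upper bound).  Gamma categories use equal probabilities with the
exact within-bin mean rate, so rates average to 1.  The trimmed alignment
(gap fraction at most 0.5 per column) feeds only the duplication score;
fate statistics always use the untrimmed alignment, mirroring the dual use
of trimmed and untrimmed alignments for the two inferences.  Sequences
identical across paralogs pass intake unchanged — they simply yield no
informative patterns.  Validation sizes were chosen to exercise every code
path at desk scale: 200-column quartets for topology separation, the
12-species default family for end-to-end recovery, ten seeds per condition,
and the screening `D` for whole-family runs; the likelihood `D` is validated
separately on the simulated quartets.

## Known limitations

Likelihoods are exact only for quartets (no larger trees); species with one
or three-plus copies are ignored rather than modeled; fate assignments are
hard (no overlapping fates); the cluster-editing heuristic beyond 10
species is a local optimum with no guarantee; and the per-column coloring
is descriptive — it inherits whatever error the fate and duplication
clusterings carry.
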