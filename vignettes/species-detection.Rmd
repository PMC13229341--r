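---
title: "Species detection from marker-gene phylogenetic placements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species detection from marker-gene phylogenetic placements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Abundance profilers answer "what fraction of the sample is species s?",
and can afford to zero out rare taxa. Species *detection* asks the harder
presence/absence question, where exactly those rare taxa matter.
`markerdetect` implements a detection method that post-processes
maximum-likelihood phylogenetic placements of reads into single-copy
marker-gene reference taxonomies: the placement tool (pplacer, EPA-ng, or
a divide-and-conquer wrapper around them) reports, per read, the
top-supported edges of the gene's taxonomy with a `like_weight_ratio`
support for each, and everything downstream of that jplace file is this
package's job.

## The model

For a read placed in gene $g$, the **clade support** of edge $e$ is
$S(e) = \sum_{e' \in \mathrm{clade}(e)} w(e')$, the candidate mass falling
within the clade below $e$ (inclusive). $S$ is monotone non-decreasing
toward the root, so for any threshold $B > 0.5$ the edges with
$S(e) \ge B$ form a single root-anchored path; a read is labeled with the
lineage of the deepest such edge (possibly stopping at genus or above; $B$
defaults to 0.9 for pplacer-style supports, 0.95 for EPA-ng-style). Reads
whose placements put no mass inside any species clade are *ineligible* for
species scoring.

Two per-species scores aggregate eligible reads across genes. Both divide
by $m_s = |G_s|$, the number of marker genes whose reference tree contains
$s$ — a species absent from a gene's tree can never be supported by it.

* **Marker vote.** Each eligible read votes for its highest-support
  species; gene $g$ votes for $s$ if at least one of its reads does;
  $\mathrm{vote}(s)/m_s$ is the fraction of $s$'s genes voting for it.
* **Marker confidence** (the default). For each gene,
  $c(g,s)$ is the mean of the non-zero placement supports for $s$ over
  $g$'s eligible reads (0 if there are none), and
  $C_s = \sum_{g \in G_s} c(g,s) / |G_s|$.

A species is called present when its score reaches a threshold $T$;
$T \approx 0.2$ is the conservative preset (higher precision),
$T \approx 0.12$ the sensitive one (higher recall). The profiling-style
baseline — threshold the species-rank abundance profile, with a *strict*
comparison — is provided by `abundance_profile()` + `detect_by_abundance()`
for comparison.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `B` | 0.9 | clade-support threshold for read labeling; must exceed 0.5 for uniqueness |
| `T` | 0.2 / 0.12 | detection threshold on the score, conservative / sensitive |
| `method` | confidence | `"confidence"` ($C_s$) or `"vote"` ($\mathrm{vote}(s)/m_s$) |
| eligibility | `any_species_mass` | see below |
| renormalization | off | rescale each read's truncated top-k mass to sum 1 |

**Eligibility.** Two readings of "eligible for species classification"
are defensible: a read carries *any* positive species-level mass
(`any_species_mass`, the default), or its $B$-rule assignment actually
reaches species rank (`b_threshold`). Both are implemented; the default is
the more inclusive one because the confidence score is designed to use
*all* positive supports, not just confident best hits. Under
`b_threshold`, ineligible reads' species mass is excluded from $c(g,s)$
entirely.

**Renormalization.** Placement tools report truncated top-k supports, so
record mass can sum below 1. By default the supports are used exactly as
produced — the missing mass is informative (it went to edges the tool did
not trust). `renormalize()` rescales to unit mass when a user wants
posterior-style weights; it is a switch, never silently applied.

## Evaluation

`precision_recall_f1()` uses the TP/FP/FN conventions, with precision 1
for an empty detection (this anchors the high-threshold end of PR
curves) and F1 = 0 when both components are 0. `pr_curve()` sweeps the
descending unique positive scores plus an above-maximum sentinel, and
integrates AUPR with the right-continuous step rule
$\sum_i (R_i - R_{i-1}) P_i$ over points in ascending-recall order (ties
enter the sweep as one threshold, so duplicate scores cannot split a
step). `threshold_at_recall()` returns the largest threshold meeting a
target recall and the false positives it admits, signalling recall
targets that no threshold attains. `low_abundance_precision()` restricts
the *recall* computation to present species at or below an abundance cap
and reports the precision of the full detected set at the selected
threshold (the restricted-precision variant is a flag); an empty
restricted set is reported as `undefined`, distinctly from
`unattainable`. Truth species absent from the reference package are
permanent false negatives and are surfaced via the `unscored_truth`
attribute.

## The synthetic world

Read simulation and placement are external tools, so the simulator works
at the level the detection stage actually consumes: placement supports.
It emulates the structure of the two benchmark regimes — an
equal-abundance community of known genomes, and a CAMI-style community
whose abundances span several orders of magnitude.

* **Reference**: `n_species` (default 200) grouped uniformly at random
  into `ceiling(n/4)` genera and `ceiling(n_genera/4)` families under one
  root; each gene's tree keeps each species with probability
  `p_presence = 0.7`, with every species guaranteed one gene and every
  gene one species. The genus granularity (~4 species per genus) stands
  in for the high-ANI neighborhoods that drive real confusions.
* **Sample**: `n_present` species drawn uniformly; abundances equal
  (`uniform`) or log-normal with $\sigma = 2.5$, which reproduces a
  4+ order-of-magnitude spread. Reads per (present species, gene in
  $G_s$) are Poisson with mean `mean_reads × abundance × n_present`.
  In the equal-abundance world a floor of one read per pair
  (`min_reads_per_gene = 1`) reflects benchmark coverage where every
  marker of a present genome is sequenced; the log-normal preset drops
  the floor to 0 so rare species can contribute no reads at all, as the
  CAMI-style data do.
* **Noise**: with probability `p_ineligible` (0.1) a read carries only
  genus-level mass; otherwise a fraction $\delta \sim U(0, 0.3)$ of its
  mass leaks to a random same-genus neighbor (falling back to same
  family, then any species in the gene tree), and with probability
  `epsilon_mis` (0.05) the roles swap so the neighbor gets $1-\delta$.
  All randomness flows from one integer seed (`seed` for the reference
  stream, `seed + 1` for the sample stream), making regeneration
  byte-identical.

What a green test on this world does *not* establish: sequence-level
effects (chimeras, contamination, alignment failure), copy-number
violations of the single-copy marker assumption, correlated placement
errors across reads of one genome region, or real ANI structure —
neighbors here are uniformly confusable, real genera are not.

## Numerical and design choices

* Edge ids follow the jplace file when one is read (`{edge_num}` is
  authoritative); taxonomy trees built from tables number edges by
  preorder DFS with children in lexicographic id order, so ids are
  deterministic.
* Clade support is one bottom-up accumulation; the exhaustive per-edge
  enumeration exists only as a test oracle.
* Vote ties (two species with equal top support) break to the
  lexicographically smallest species id, for determinism.
* $T \le 0$ and $B \le 0.5$ are rejected rather than clamped; $T = 0$
  would detect every reference species and two sibling clades can tie at
  $B = 0.5$.
* Mass above species level is never redistributed to species (no LCA
  push-down).
* Comparisons use `>= T` for scores and `>` for the abundance baseline,
  each as its method defines.
* `nm` multiplicity entries in jplace expand to that many identical
  reads, so read-count-weighted averages see them correctly.

## Known limitations

The confidence score is an *average* of supports, so it is nearly
invariant to read depth: one leaked read per gene holds an absent
neighbor's $c(g,s)$ near $E[\delta]$, which places a hard floor under
false-positive scores in noisy samples — visible in this package's own
simulations as a small FP tail just above the conservative threshold.
Conversely $C_s$ divides by $m_s$, so a rare species whose few reads
cover $k$ of its $m_s$ genes scores about $0.85\,k/m_s$; species
contributing only one or two eligible reads sit well below the sensitive
preset and are missed. Both behaviors are inherent to the score's
definition, not artifacts of this implementation. The
`low_abundance_precision()` trend in the cap is exactly that — a trend;
re-selecting the threshold at a tighter cap can swap one false positive
for another, producing per-point wobbles of a few thousandths.
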