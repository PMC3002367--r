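---
title: "Reticular progressive alignment: model, scoring and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reticular progressive alignment: model, scoring and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retalign)
```

## The problem and the idea

Progressive alignment builds a multiple sequence alignment bottom-up along
a guide tree, aligning at each internal node the results of its two
children. Its classical weakness is "once a gap, always a gap": a single
alignment is committed at every node, and an early mistake — made on local
information only — can never be repaired higher up.

This package keeps, at every node, a *network* of optimal and suboptimal
alignments instead of one alignment. The network is a directed acyclic
graph whose vertices are alignment columns, with a unique source (`Start`)
and sink (`End`); every `Start -> End` path is a valid multiple alignment
of the node's sequences, and columns shared by many alignments are stored
once — which is what makes the structure reticulate and keeps it small
relative to the number of alignments it encodes. Networks are aligned
against networks with a generalised forward/backward dynamic programme,
and a single best alignment is extracted only at the root.

## The objective: the internal score

An alignment is scored by the sum of two terms, both over unordered row
pairs and optionally weighted by per-sequence weights:

* **Similarity.** For every column, the substitution score `s(x, y)`
  (BLOSUM62 by default) summed over all pairs of non-gap residues in the
  column, regardless of the column's insertion/deletion state.
* **Indels.** For every pair of *adjoining* columns, each row forms one of
  four patterns — `--`, `-*`, `*-`, `**` (gap/residue in the left and
  right column) — and each pair of rows contributes the entry of a 4x4
  pattern matrix. With opening score `OP` and extension score `EX` (both
  negative; defaults -10 and -1):

  | | `--` | `-*` | `*-` | `**` |
  |---|---|---|---|---|
  | `--` | 0 | OP/2 | OP/2 | EX |
  | `-*` | OP/2 | 0 | OP | OP/2 |
  | `*-` | OP/2 | OP | 0 | OP/2 |
  | `**` | EX | OP/2 | OP/2 | 0 |

  The matrix is symmetric (row order of a pair does not matter) and
  invariant under horizontally flipping both patterns, so the reverse of an
  alignment scores identically. An interior gap run of length `L` in one
  row of a pair collects `OP/2` on entry, `(L-1) * EX` inside, and `OP/2`
  on exit — exactly the affine cost `OP + (L-1) * EX`. The `--` versus
  one-sided entries are genuinely ambiguous (the right value depends on
  columns further away); `OP/2` is the default, with `EX` and `EX/2`
  available via `retalign_scheme(gap_cross = ...)`.

Terminal gaps are charged by scoring a virtual all-residue column before
the first and after the last column, which reproduces the affine cost of
leading and trailing gap runs. On two rows the internal score is *exactly*
the classical affine-gap pairwise score; on more rows it approximates the
sum-of-pairs score from adjoining columns only (the exact sum-of-pairs
multiple alignment problem is NP-hard precisely because gap opening versus
extension cannot always be decided locally). The score is independent of
the guide tree and of the order in which groups were aligned, so it can be
compared across runs.

## Forward, backward, and the best score through a column

For two sequences, `pairwise_forward()` computes the best score of an
alignment of the prefixes ending in a match (`M`), insertion (`I`) or
deletion (`D`); `pairwise_backward()` computes the mirror-image suffix
scores under a context convention: the suffix is scored as if preceded by
a match/insertion/deletion column, so a suffix starting with a gap is
charged the opening score after a match context and the extension score
after a matching gap context. The sum of the forward and backward cells of
the same state and indices is `b(alpha)`: the best score of any *complete*
alignment containing that column. Impossible cells carry `-Inf`, which is
absorbing under addition and never wins a maximum.

The **x-network** keeps exactly the columns with `b(alpha) >= opt - x`,
with an edge wherever one column can follow another in some alignment.
Every vertex of an x-network lies on a `Start -> End` path (if an
alignment scoring `b(alpha)` passes through `alpha`, all its columns score
at least as well), so the construction can never create dead ends;
`validate_network()` asserts this, along with acyclicity, unique
source/sink, and that all paths spell the input sequences exactly.

## Aligning a network against a network

At an internal node the two child networks play the role of the two
sequences. Cells are indexed by a vertex of each network plus a state:
match columns advance both networks; insertion columns advance only the
second network and carry an *anchor* — the last non-all-gap column on the
first side — as their first index (deletions mirror this). The forward
pass visits vertices in each network's linear extension (a total order in
which every edge points forward), maximising over graph predecessors
instead of `i-1`/`j-1`; the backward pass runs over successors. `b(alpha)`
and the network optimum follow as in the pairwise case. The produced
network stores its vertices in the lexicographic order (index in the first
network, index in the second, state `M < I < D`), which is provably a
linear extension of the result when the component orders are — this is
what lets the next level up consume it directly.

### Attributing gap costs: one matrix, two bookkeepings

The pattern matrix above splits `OP` half-and-half between a gap run's
entry and exit. A dynamic programme, however, is easiest to state (and to
compare with the pairwise recursions, whose boundary rows charge `OP +
(L-1) * EX` at the run's start) when the whole opening cost is charged at
the first gap character. The two bookkeepings are reconciled with a
potential shift: with `phi = -OP/2` on a row pair having exactly one gap
in a column and `phi = 0` otherwise, the transition matrix
`G4[p, q] = T4[p, q] + phi(left) - phi(right)` telescopes along any
complete path (the virtual boundary columns have `phi = 0`), so

* path totals under `G4` equal the internal score computed with `T4`
  exactly;
* `b(alpha) = forward + backward` is identical under either attribution;
* on single-sequence chains every forward and backward cell reproduces the
  classical pairwise tables cell for cell — which the test suite asserts
  against an independent pure-R implementation of those recursions.

The compiled kernel (`src/netdp.cpp`) uses `G4` with the count-based fast
pair summation (tally the four patterns per transition, then combine
tallies through the 4x4 matrix; weight sums replace counts when sequence
weighting is on). `internal_score()` and all user-facing scoring use `T4`.

## The threshold `t`

A fixed score slack `x` would make network sizes unpredictable. Instead,
the user sets `t`, and each node's network is capped at
`ceiling((1 + t/100) * L_opt)` vertices, where `L_opt` is the column count
of the node's deterministic best alignment. Candidate columns are grouped
by equal `b` (scores rounded to 1e-9 to avoid float-splintered groups) and
admitted group by group in descending score while the cap permits; the
optimal group is always admitted even if it alone exceeds the cap. The
admitted set is therefore `{alpha : b(alpha) >= opt - x_effective}` — a
genuine x-network with no dead ends — and is monotonically non-decreasing
in `t` at a fixed node.

* `t = 0` keeps only the columns of (co-)optimal alignments: the package's
  standard progressive mode (`progressive_align()`). Note that this
  retains *all* co-optimal columns, which is deliberately not the same as
  committing to one best alignment per node: the stricter single-chain
  baseline (`retalign(..., single_best = TRUE)`) occasionally scores worse
  at the root, because a co-optimal alternative at a lower node can enable
  a better-scoring parent alignment. On the validation sets the `t = 0`
  run never scored below the single-chain baseline.
* `t = Inf` disables the cap and performs an exhaustive search; on three
  short sequences the test suite verifies it attains the global optimum of
  the internal score computed by an independent three-dimensional dynamic
  programme.
* The root score is *not* guaranteed monotone in `t`: a larger network at
  one node can shift which alignments survive at the next, and the search
  spaces at different `t` are not nested. The validation suite asserts
  improvement of the mean (over replicates), never per case.

## Guide tree and sequence weights

Pairwise distances come from full dynamic-programming alignments:
`D_ij = S_ii + S_jj - 2 S_ij` from the optimal self- and cross-alignment
scores, clamped at zero (arbitrary matrices can make unrelated pairs score
high enough to push the formula negative; NJ/UPGMA expect
dissimilarities). Neighbour joining (default) or UPGMA builds the tree;
NJ trees are unrooted and are mid-point rooted — the root halves the
longest leaf-to-leaf path, minimising the maximum root-to-leaf depth,
which also tends to balance the two root networks. User trees in Newick
are accepted; multifurcations are resolved deterministically with
zero-length edges.

Sequence weights follow the ClustalW recipe: each branch length is divided
equally among the leaves below the branch, and a leaf's weight is the sum
of its shares along its root path, so members of overrepresented clades
share (and thus shrink) their deep contributions. Weights are rescaled to
mean 1 — the raw ClustalW weights have an arbitrary scale, and mean-1
normalisation keeps weighted and unweighted scores comparable — and are
computed once from the initial tree and used at every node.

## ClustalW-imitation mode

`retalign_scheme(mode = "clustalw")` switches both score terms: similarity
counts only cross-pairs between the two groups being aligned (so a full
insertion/deletion column scores zero), and a full-column
insertion/deletion event costs a single `OP` (or `EX` when the preceding
column is the same kind of event), regardless of gaps hidden inside the
groups' columns. This objective depends on which groups were aligned last,
so it is used only to steer the search; it is not an alignment-intrinsic
quality measure, and the hidden-gap anomaly it creates (suboptimal gappy
columns become cheap) is observable in this package exactly as in the
original tools. Gap penalties in this mode are not weight-scaled.

## The synthetic generator: what it emulates and what it does not

`synth_msa()` evolves a uniform-random root peptide down a tree:
substitutions hit each site with probability `1 - exp(-sub_rate * l)` per
branch of length `l`, replacements drawn with probability proportional to
`2^(s(a,b)/2)` (BLOSUM-biased, so conservative changes dominate); indel
events arrive Poisson at `indel_rate` per site per unit length, half
insertions half deletions, with geometric lengths (mean `mean_indel_len`)
and uniform positions. Homology columns are tracked through all events, so
the returned alignment is the true one, and a fixed seed reproduces the
family byte for byte.

The defaults are the validation conditions used throughout the package's
tests: 5 leaves on a random topology with branch lengths uniform on
[0.15, 0.5], root length 25, `sub_rate = 1.3`, `indel_rate = 0.06`, mean
indel length 2 — families at roughly 55–80% pairwise identity where
alignment is neither trivial nor hopeless. The generator has no rate
heterogeneity across sites, no domain structure or local motifs, no
hydrophobicity-dependent indel placement, and terminal extensions arise
only by chance; passing the recovery tests therefore demonstrates correct
optimisation of the objective under a homogeneous model, not benchmark
accuracy on real protein families.

## Numerical and design choices

* Gap scores are negative numbers *added* to the score; `OP <= EX <= 0` is
  enforced. `-Inf` is the impossible-cell sentinel (saturating, exact).
* Equal-score grouping rounds `b` to 9 decimals; `x_effective` below 1e-8
  is reported as exactly 0.
* All tie-breaking is deterministic: traceback prefers `M`, then `D`, then
  `I`, then the smaller predecessor; set iterations follow column ids;
  NJ/UPGMA ties resolve by label order. Identical inputs and configuration
  give byte-identical outputs.
* Degenerate inputs: a single sequence returns itself as a trivial
  alignment; an empty sequence yields the `Start -> End` network with a
  warning and is carried through the boundary code paths.
* The backward recursions are implemented exactly as the forward/backward
  pair demands under the left-attributed convention; an exhaustive
  enumeration oracle over all alignments of short sequence pairs confirms
  every cell, so no silent "corrections" were needed anywhere.
* Dense tables over vertex pairs put memory at `3 * |A| * |B|` cells per
  pass; the practical target is tens of sequences of moderate length (of
  the order of 30–50), not thousands. No checkpointing or linear-memory
  variant is implemented.

## Validation problem sizes

The suite checks every component against independent oracles at sizes
where exhaustive enumeration is exact: all alignments of sequence pairs up
to length 6 (200 random pairs for the optimum, every `b(alpha)`, and
x-network vertex sets), all cross-alignments of small two-sequence
networks (including weighted), the full three-sequence optimum by direct
dynamic programming (20 random triples), 20 synthetic five-sequence
families for the `t = 0` and `t = 200` limits and the mean-recovery trend,
and brute-force rooting/weighting checks on random trees. The
`scripts/acceptance.R` script reruns the synthetic study end to end from a
single seed.
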