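---
title: "Methods: analysing the evolution of RNA stem-loop structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing the evolution of RNA stem-loop structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemevol)
```

## The problem

Functional RNAs (tmRNA, RNase P RNA, telomerase RNA, ...) conserve their
secondary structure more strongly than their sequence, yet the double-helical
regions — the stems — do vary across species: stems appear and disappear as
whole blocks, and they shorten or lengthen when point mutations and
single-base indels create or destroy base pairs. `stemevol` quantifies these
two modes of structural change. Starting from a curated structural alignment
(aligned sequences plus one consensus structure line) and a rooted reference
phylogeny built from independent data (typically rRNA), it

1. annotates stems, loops and pseudoknots in the consensus structure and
   measures the *realized length* of every stem in every sequence;
2. maps stem lengths and stem presence onto the tree by parsimony and
   reconstructs ancestral sequences;
3. locates the clades where stems vary, classifies each change as a
   whole-stem insertion/deletion or a pairing change driven by
   substitutions/indels, and tabulates class frequencies per family;
4. summarises the substitution process inside variable stems as 5-state
   single-nucleotide and 24-state base-pair log-odds matrices;
5. summarises stem-length profiles across species with k-means clustering and
   covariance PCA.

A simulator of structured-RNA evolution along a tree provides ground truth
for end-to-end validation.

## Realized stem length and variability categories

A stem is an ordered list of paired alignment columns (i, j). The realized
length of a stem in one sequence is the number of its column pairs whose two
characters form a canonical pair — Watson–Crick plus the G·U wobble, the
standard pair set of comparative RNA analysis. Anything else "is no longer
able to pair" and does not count. Three conventions matter:

* `-` (gap) and `~` (non-sequenced) are distinct: a gap is evidence of
  absence, `~` is absence of evidence. Any `~` in a stem's columns makes that
  cell *unknown*; unknown cells are excluded from all downstream counting.
* IUPAC ambiguity codes make a pair uncountable: it is skipped entirely
  rather than scored as broken.
* Bulge columns (single-strand interruptions inside a helix) are not counted
  by default; `count_bulges = TRUE` adds their non-gap bases, because some
  annotation pipelines quote stem lengths "including the bulges". Both
  behaviours are exposed since published stem-length conventions differ.

Helices are split at internal loops of at least one column on both strands;
one-sided bulges keep a helix contiguous. This reproduces the named-stem
granularity of curated alignments. Pseudoknots are detected with the
arc-crossing rule: stems S and T cross iff some pair (i, j) of S and (k, l)
of T satisfy i < k < j < l.

Each stem receives a variability category from the share of species carrying
its modal length: 71–100% conserved, 41–70% intermediate, 1–40% variable.
Modal ties are resolved toward the larger length — conservative toward "stem
present".

## Ancestral reconstruction

Three reconstructions are run, all parsimony-based so they handle polytomies
and make no rate assumptions:

* **Continuous stem lengths** by unweighted squared-change parsimony: the
  internal values minimise the sum over branches of squared parent–child
  differences. At the optimum every internal node equals the mean of its
  neighbours, so the solution is an exact linear solve — deterministic, no
  iteration. Branch lengths are ignored.
* **Ancestral sequences** by unit-cost Sankoff parsimony per column over the
  five states {A, C, G, U, −}. The gap is a *regular fifth state*: this is
  what lets the method reconstruct an ancestor with no sequence in a region,
  the signature of a whole-stem insertion. (`gaps_as_missing = TRUE` switches
  to the 4-state treatment for comparison.) `~` and ambiguity codes allow
  their compatible states at no cost. At every internal node the full
  minimal-state set is computed from down- and up-pass costs; a tie is
  reported as `?` with the set preserved — ties are never sampled away.
* **Stem presence/absence** by two-state Sankoff; ties give `unresolved`.

Parsimony underestimates rare changes, so matrices comparing ancestral and
extant sequences are conservative; columns whose ancestral state is `?` are
skipped in all counting.

## Locating and classifying events

A stem is *variable at a clade* when at least two of the clade's child
subtrees disagree in their modal realized length (ties toward the larger;
children with only unknown cells are skipped). This "modal disagreement"
criterion was chosen over two alternatives that were considered: flagging
any node whose children's length *sets* differ re-reports the same deep
variation at every ancestor, while collapsing nested flags to the deepest one
can mask a deletion whose sister clade independently contains a zero. Modal
disagreement reports exactly one locus per independent point of between-branch
divergence and reduces to "the deviant species' parent clade" in the
single-outlier case.

Each (stem, clade) is classified from the reconstructed ancestral sequence at
the clade node, with `g_anc` the fraction of the stem's columns that are
definite gaps in the ancestor and `g_ext` the same per extant member:

* `whole_stem_insertion` — `g_anc >= theta_gap` and some descendant realizes
  the stem: no sequence at the ancestral node, so the block was gained below
  it.
* `whole_stem_deletion` — the ancestral region is populated (`g_anc <
  theta_gap`), the ancestor could realize at least one canonical pair, and
  some descendant's region is gapped out (`g_ext >= theta_gap`).
* `pairing_change_substitution_indel` — otherwise: the nucleotides are
  present but mutated or nicked so that pairing is altered.

`theta_gap = 0.9` by default: real "absent" regions may retain one or two
residual columns, so absence is defined as ≥90% gap rather than 100%.

Ancestral `?` columns are resolved toward presence: only definite `-` counts
in `g_anc`, and a pair whose ambiguous ends can still be resolved (within
their minimal state sets) to a canonical pair counts as potentially paired
for the deletion test. The consequence is deliberate: at a node where an
insertion below one branch and a deletion below the other are exactly equally
parsimonious (typically at the root), the call stays in the *whole-stem*
class — the dichotomy the frequency tables report — while the direction
carries the reconstruction's uncertainty. No tie is ever resolved by
sampling.

Species with `~` in the region are excluded from the call; if all clade
members are unknown the event is a no-call.

Family-level frequencies pool the two whole-stem classes against the
substitution/indel class; rate differences across families are tested with a
Pearson chi-square on the raw counts (never on percentages), df = r − 1 for
r families.

## Substitution matrices

Counts are collected inside variable stems only, in two comparisons:

* **extant/extant** — every unordered pair of clade members, stored
  fold-symmetrically (lower-triangle layout);
* **ancestral/extant** — the clade-node ancestor against each member,
  directional (ancestor rows → extant columns).

The counting unit is one tally per (sequence pair, column) for single
nucleotides and per (sequence pair, column pair) for base-pair duplets; the
unit is recorded in the run manifest because published event totals are not
comparable across units. Diagonal (no-change) cells are tallied. Columns with
`~`, ambiguity codes, or ancestral `?` are skipped; the empty duplet (−,−)
is excluded from the pair state space.

The log-odds transform is `log2(f_obs / f_exp)` in bits, with marginals taken
from the count matrix itself. For fold-symmetric counts the marginal of a
state is its involvement frequency (each tally involves two states) and the
expectation of an unordered off-diagonal cell uses both orderings,
`2 f_i f_j`; directional counts use row × column marginals. Cells with zero
observed count are undefined and written `NA` — never −∞ — and no pseudocount
is added by default (`pseudocount` is available). Two identities pin the
implementation down and are enforced in the tests: counts exactly
proportional to their marginal products give an all-zero matrix, and uniform
scaling of all counts leaves the matrix unchanged.

## Clustering and PCA

Species are clustered on their stem-length profiles by k-means (best of
`restarts` seeded starts; deterministic given the seed). k is a user choice;
a WCSS-versus-k side report supports comparing values of k without
automating the choice. Unknown cells are imputed with the stem's modal length
for clustering *only*.

PCA is run on the centered, unscaled length matrix — covariance PCA — because
all variables share one unit (base pairs) and longer variable stems *should*
contribute more variance; autoscaling is available as an option. Partial
sequences (any unknown cell) are excluded by default rather than imputed.
The report gives the variance share of the first two components and the
top-|loading| stem per component; the biplot payload flags outlier species
whose standardized score radius on the first two components exceeds 2.5.

## The simulator

`evolve()` simulates a structured RNA along a rooted tree. The root is a
series of canonical hairpins; per branch, events are drawn as Poisson counts
with rate × branch length:

| parameter | default | unit | what it emulates |
|---|---|---|---|
| `whole_stem_insertion_rate` | 0.02 | per branch-length unit | gain of a new hairpin (new alignment columns, gap-filled elsewhere) |
| `whole_stem_deletion_rate` | 0.02 | per stem per unit | loss of the whole block (pairs + enclosed loop) |
| `pair_substitution_rate` | 0.1 | per base pair per unit | stem point mutation |
| `compensation_probability` | 0.8 | — | chance the partner strand restores pairing (covariation) |
| `in_stem_indel_rate` | 0.02 | per base pair per unit | single-base deletion breaking one pair |
| `loop_substitution_rate` | 0.2 | per loop site per unit | background loop divergence |

The defaults describe a family of closely related species in which whole-stem
events are rare — about one per 12-leaf family at unit-scale branch lengths —
and most divergence is compensated pair substitution. This sparseness is not
cosmetic: when several whole-stem events hit the same stem in one family,
parsimony can (correctly, by its own criterion) prefer a cheaper alternative
history, e.g. reading two independent deletions as one insertion, and no
reconstruction method could recover the planted truth. Likewise an event on a
branch adjacent to the root is strictly unidentifiable in direction. The
defaults keep simulated families in the regime where the question "was this
a whole-stem event, and where?" has a recoverable answer; the remaining
root-adjacent ambiguity is absorbed by the class pooling described above.

Because insertions create fresh columns that are gap-filled in every other
lineage, the simulator emits a *true* multiple alignment — no aligner is
involved, removing a confound that curated input alignments side-step. A
masking option censors terminal regions of random leaves with `~` to exercise
the unknown-region logic. The same seed reproduces a family bit for bit.

What the simulator does **not** emulate: site-rate heterogeneity, GTR-style
exchangeabilities, alignment error, non-canonical but stable pairs, and
tertiary contacts. Passing the recovery benchmarks therefore shows the
pipeline is correct and well-calibrated on clean, sparse-event data; it does
not certify performance on saturated or poorly aligned real families.

## Numerical and degenerate-input choices

* Column indices are 0-based internally nowhere — R is 1-based throughout,
  and all reports/errors cite 1-based columns.
* Squared-change parsimony: exact linear solve; an error names any leaf
  without a value; leaves with unknown values are pruned first.
* Sankoff: integer unit costs; the "infinite" cost for a disallowed leaf
  state is 1e9, far above any attainable score.
* k-means refuses k larger than the number of distinct profiles; the WCSS
  profile truncates its k range accordingly.
* PCA refuses fewer than 2 complete species or an all-constant matrix, and
  flags (but allows) fewer species than stems.
* Empty count matrices refuse the log-odds transform; a family with no
  variable stems skips the matrices with a warning.
* Pipeline determinism: all stochastic steps (simulator, k-means restarts)
  are seeded; rerunning `run_pipeline` on the same inputs is byte-identical.

## Problem sizes used in validation

The shipped validation uses 200 random trees of ≤6 leaves against exhaustive
parsimony enumeration, 50 random ≤10-leaf trees (half with polytomies)
against a quasi-Newton optimizer for squared-change parsimony, 60 random
knotted structures against a naive arc-crossing oracle, and 20 simulated
12-leaf families at the default rates (plus 10 single-process control
families) for event recovery — sizes at which the exhaustive oracles are
exact and the whole suite runs in well under a minute on one core.
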