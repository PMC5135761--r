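---
title: "Detecting stem-loops and profiling their conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stem-loops and profiling their conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemloop)
```

## The problem

A stem-loop (hairpin) is the structure an inverted repeat can fold into: two
complementary arms form a double-stranded stem, closed by a single-stranded
loop. Conserved stem-loops near the 3′ ends of non-LTR retrotransposons
(LINEs such as human L1, and the SINEs they mobilise, such as Alu) are
recognition motifs for the retrotransposition machinery, so locating them —
and asking where in a sequence family they are conserved, and where their
stems are interrupted by bulges — is a recurring annotation task.

This package provides the three pieces of that workflow:

1. a **stem-loop scanner** based on a minimum-penalty dynamic-programming
   alignment of candidate arms,
2. **coverage profiles**: the fraction of sequences in a family whose
   (length-normalised) positions are covered by a detected stem-loop, and
3. **pairing–unpairing profiles**: where, counted in stem rungs from the
   loop, a collection of hairpin structures has unpaired bases.

## The search algorithm

### Minimum-penalty arm alignment

For a candidate loop span, the two flanking windows (each up to
`max_stem` bases, the left one reversed so both read loop-outward) are
aligned against each other under a penalty-minimising variant of
Needleman–Wunsch. A "match" is a *complementary* base pair (A·T or C·G;
no G·T wobble at the DNA level, and ambiguity codes such as N never pair).
Matches cost 0, mismatches and gaps cost 1 by default, so the matrix value

$$
M(i,j) = \min \begin{cases}
M(i-1,\,j-1) + S(i,j) & \text{(pair or mismatch)}\\
M(i,\,j-1) + w & \text{(gap in arm 1)}\\
M(i-1,\,j) + w & \text{(gap in arm 2)}
\end{cases}
$$

is the smallest number of mismatches-plus-gaps over all gapped alignments
of the two arm prefixes. The header row and column hold the substring
coordinates $0, 1, 2, \dots$, which under $w = 1$ are exactly the
cumulative gap penalties (for a general gap cost the package initialises
them as $j \cdot w$, the only initialisation consistent with the
recurrence). The matrix spans the full arm windows,
$(|a|+1)\times(|b|+1)$; the minimum stem length only gates which cells may
start a traceback.

### Start cell, traceback, and the loop-closing rung

Among interior cells with $M(i,j) \le$ `max_mismatch` and
$\min(i,j) - 1 \ge$ `min_stem`, the scanner picks the cell maximising
$\min(i,j)$ — the longest guaranteed stem within the error budget. The
traceback walks back to the origin, at each step taking a predecessor
consistent with the recurrence and of minimal value, preferring the
diagonal (which maximises paired rungs). An alignment whose first aligned
position — the rung that closes the loop — is not a complementary pair is
rejected outright, so stems never begin with a mismatch or a gap.

Two consequences of the $\max_{ij}\min(i,j)$ rule are worth knowing:

* **Budget-driven extension.** With the transposon-annotation defaults
  (stems 15–50 bp, up to 7 mismatches+gaps), a *perfect* 15-bp stem
  embedded in longer flanks is reported with its arms extended by
  additional, mostly mismatching rungs: appending $k \le 7$ mismatches
  still satisfies the budget and increases $\min(i,j)$. The reported
  footprint is therefore the *maximal* stem within the budget, not the
  minimal perfect core. Exact-coordinate recovery of a planted hairpin is
  only expected when the parameters match the planted geometry
  (`params_for_hairpin()`), or when the hairpin has no flanks to extend
  into.
* **Background hits are normal.** At the default stringency a random
  300-bp sequence contains on the order of a hundred qualifying
  stem-loops. Coverage profiles are informative through *differential*
  conservation across a family, not through absence of background — which
  is why the synthetic-family generator verifies template cleanliness at
  the stringent, geometry-matched settings rather than at the scan
  defaults.

### Tie-breaking, determinism, and strand symmetry

Ties are resolved deterministically: equal $\min(i,j)$ prefers lower
$M$, then lower $\max(i,j)$ (the shorter overhang). Any residual tie is
between a cell and (conceptually) its transpose, and a fixed "lower row
first" rule would break strand symmetry: on the reverse complement the
matrix transposes, and the mirrored scan would pick the other member of
the pair, yielding non-mirrored spans. The package instead compares the
two candidate cells by the lexicographically ordered *unordered pair* of
consumed prefixes \{arm A prefix, complement(arm B prefix)\} — a key that
transposes with the matrix — and falls back to the lower row only when
those strings are identical (in which case the two alignments are
sequence-identical). The same idea breaks up-vs-left ties in the
traceback. This makes hit spans on `reverse_complement(x)` exact
coordinate mirrors of the hits on `x`, which the test suite checks on
hundreds of random sequences. Nothing in the scanner is randomised.

### Loop enumeration and redundancy

`scan_stemloops()` proposes every loop span of length `min_loop` to
`max_loop` (inclusive) and keeps every accepted stem. `min_loop` defaults
to 3 because hairpin loops shorter than about three bases are sterically
impossible; it can be set to 0 to enumerate abutting arms. Two hits are
redundant when their loop-closing rungs occupy the same two sequence
positions; the longer-stem (then lower-penalty) one is kept. Overlapping
non-redundant hits are all retained, because the coverage statistic uses
the union of covered bases. Coordinates are 1-based and inclusive in R
(the Bioconductor convention); BED output is 0-based half-open.

## The two profile statistics

**Coverage profiles** (`coverage_profile()`): per sequence, the covered
set is the union of hit footprints — both arms and the loop. Base $i$ of a
length-$L$ sequence maps to bin $\lfloor (i-1) \cdot n / L\rfloor + 1$ of
$n$ (default 100, i.e. percent of normalised length); a bin is covered for
a sequence when at least one of its bases is. The profile value is the
fraction of sequences covered at that bin, so values multiplied by 100
read as "% of family members". A per-base mode (`n_bins = NULL`) is
available for equal-length families. Binning is conservative and
deterministic; mass is conserved (the sum of value·$n$ over bins equals
the number of sequence/covered-bin incidences) and the profile is
invariant under duplicating the family or permuting it.

**Pairing–unpairing profiles** (`pairing_profile()`): each structure must
contain exactly one hairpin loop (multi-loop structures are rejected, as
is anything with zero pairs). In the stem-anchored mode (`from_loop`),
rungs are numbered 0, 1, 2, … outward from the loop-closing pair; a
structure contributes 1 at offset $x$ when unpaired bases interrupt an arm
between rung $x-1$ and rung $x$. With `arms = "combined"` an interruption
of either arm counts once — a symmetric internal loop therefore counts
once, not twice — and `arms = "per_arm"` reports the 5′ and 3′ arms
separately. The normalised mode scales each structure to 100 bins and
counts structures with any unpaired base per bin (loop included).

Structures can come from three sources: imported Vienna dot-bracket files
(`read_dot_bracket()`), the hit's own arm alignment
(`hit_to_structure()`: pair events become base pairs, mismatch and gap
events stay unpaired), or the built-in fold.

## The fallback fold

`fold_max_pairs()` is a deterministic nested-structure fold that maximises
the number of admissible pairs (Watson–Crick, plus G·U when `rna = TRUE`)
subject to hairpin loops of at least `min_loop` bases — the classic
interval dynamic programme. It is *not* a thermodynamic model: it knows
nothing of stacking energies, dangles or temperature, admits no
pseudoknots, and will happily pair isolated bases that a free-energy model
would leave open. It exists so that pairing–unpairing profiles can be
computed without external fold output; when energy-realistic structures
matter, fold externally and import the dot-bracket file. Ties are broken
by pairing the leftmost base first with its nearest admissible partner,
so the output is reproducible.

## The synthetic-family generator

`make_hairpin()` draws a random left arm at a requested GC content, sets
the right arm to its exact reverse complement, and joins them with a
random loop whose terminal bases are chosen non-complementary so the
planted stem cannot silently grow into the loop. Optional bulges insert
extra bases between two specified rungs, chosen so they cannot pair with
the bases facing them — which pins the gap event (and hence the profile
offset) to the planted rung. `make_family()` emulates a transposon
subfamily: one random template, the hairpin written over it at a fixed
relative position in a chosen fraction of copies, and i.i.d. substitutions
everywhere (hairpin included — that is what makes planted-peak decay with
substitution rate mirror the decay of stem-loop conservation from young to
old subfamilies). The substitution-only model keeps planted coordinates
exact at every rate; substitution draws consume a rate-independent RNG
stream, so at a fixed seed the mutated positions are nested across rates
and peak degradation is monotone by construction. Templates are
rejection-sampled to contain no stem-loop under the geometry-matched
check parameters (see above). All randomness flows from the single seed;
equal seeds give byte-identical output.

What the generator does *not* emulate: insertions/deletions (available
truth-shifting realism was traded for exact truth spans), 5′ truncation of
LINE copies, subfamily phylogenetic structure, and non-uniform background
composition beyond a global GC fraction. Tests passing on these fixtures
therefore demonstrate correctness of the algorithms, not performance on
real genomic repeats.

## Problem sizes and numerical choices

The test suite cross-checks the compiled scanner against two independent
oracles written in plain R: an exhaustive recursion over all gapped
alignments (for the fill), and a full re-implementation of the
scan-select-traceback pipeline (for end-to-end equality on >200 random
sequences of 30–60 bp over a grid of stem/loop/mismatch settings). The
fold is checked against exhaustive enumeration of all nested structures
on 15-mers. Strand symmetry is verified on 100 random 300-bp sequences at
the default parameters; planted-hairpin recovery on 100 generated
hairpins. These sizes keep the whole suite under a minute or two on one
core while exercising every code path; the scanner itself handles
transposon-consensus-scale inputs (hundreds of bp to a few kb) in
milliseconds to seconds per sequence.

Degenerate inputs are defined rather than accidental: sequences shorter
than `2 * min_stem + min_loop` scan to an empty hit table (not an error);
homopolymers have no hits; empty arms, out-of-bounds loops, unbalanced
dot-brackets, crossing pairs, duplicate FASTA identifiers and non-IUPAC
characters are errors with informative messages.

## Known limitations

* The scanner reports, per loop span, the single best stem under the
  tie-break chain — not all co-optimal alignments.
* Penalties are integers; there is no affine gap model (a k-base bulge
  costs k), matching the simple mismatches-plus-gaps budget the search
  parameters express.
* The fallback fold maximises pair count, which systematically
  over-pairs relative to free-energy models.
* Coverage bins are covered-if-any-base-covered, which slightly inflates
  coverage at bin boundaries for coarse binnings.
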