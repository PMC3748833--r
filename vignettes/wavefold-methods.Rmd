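---
title: "Methods: the wavefold energy model, engine and verification design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the wavefold energy model, engine and verification design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavefold)
```

# The problem and the model

`wavefold` computes, for an RNA sequence s₁…sₙ, the nested (pseudoknot
free) set of base pairs minimizing total free energy under a
nearest-neighbor thermodynamic model. A secondary structure decomposes
uniquely into loops; the model assigns each loop an additive term and the
structure's energy is the sum. Admissible pairs are the six canonical
types AU, UA, CG, GC, GU, UG (restrictable per parameter set), and every
pair must enclose at least `h` unpaired bases (`h = 3` by default, the
usual steric bound).

This vignette records the exact energy rules, the recursion and its
scheduling contract, the deterministic tie-breaking, and the design
decisions taken where published engine descriptions are silent. Nothing
here states an empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

# Energy rules, exactly

All energies are integers in fixed decimal units of 0.01 kcal/mol. The
forbidden sentinel is 10⁸ centi-kcal, strictly larger than any achievable
structure energy, and saturates under addition, so a forbidden subterm
can never be "repaired" by favorable neighbors and no value can fall
between the largest finite energy and the sentinel. Exact integer
arithmetic makes ties — the engine's main source of cross-implementation
divergence — reproducible.

**Hairpin** closed by (i, j), loop length `len = j − i − 1 ≥ h`:
initiation by length, a terminal-mismatch term on the first and last
unpaired bases (applied whenever `len ≥ 2`), and the terminal AU/GU
penalty for non-CG/GC closings.

**Stack**: one table lookup on (outer pair type, inner pair type).

**Bulge** (one side empty, total length `t`): initiation by `t`; a
length-1 bulge keeps the stacking bonus of its flanking pairs (the helix
effectively continues); longer bulges instead pay the AU/GU penalty at
both closings.

**Internal loop** (both sides non-empty): initiation by total length, a
capped linear asymmetry penalty `min(asym_coeff · |l₁ − l₂|, asym_max)`,
and terminal mismatches at both closing pairs, the inner one viewed from
the loop side (pair (j′, i′) with flanks s_{j′+1}, s_{i′−1}). No
special-case tables (tetraloop bonuses, C-loops, 2×3 corrections) are
included: published parameter sets disagree on exactly these cases, they
are orthogonal to the engine's structure, and verification here is
parameter-agnostic by design — the enumeration oracle applies the same
rules.

**Multiloop**: the affine score `a + b·branches + c·unpaired`, with the
closing pair counted as a branch.

**Long loops**: lengths beyond `l_max` (default 30) extrapolate as
`init[l_max] + coeff · ln(len / l_max)`, with `coeff` stored in the
parameter file — the coefficient is data, not code. The product is
rounded to the nearest 0.01 kcal/mol via `floor(x + 0.5)` in both the R
and C++ paths so that fixed-decimal equality holds bit-for-bit.

**Helix ends** (`dangle` mode). Branches of multiloops and the exterior
loop can be scored in three modes. `none`: zero. `dangles`: the minimum
over inclusion subsets of the applicable 5′ and 3′ dangling-end terms
(`min(0, d5, d3, d5+d3)`), never positive. `mismatch`: a single
terminal-mismatch lookup requiring both flanks, otherwise omitted. Two
conventions are fixed deliberately:

* a flanking base is *available* iff its position exists in the sequence;
  its pairing status and loop membership are ignored. Each branch resolves
  competition for a shared unpaired base independently — there is no
  global assignment. This makes the end term a pure function of the pair
  and its sequence neighborhood, which the multiloop fragment recursion
  requires (fragment scores cannot depend on an enclosing context they
  cannot see), and it is itself one documented resolution of a rule on
  which published programs genuinely differ.
* a branch (i, j) is viewed from outside as the reversed pair (s_j, s_i)
  with flanks s_{i−1} (5′) and s_{j+1} (3′); a multiloop's closing pair is
  viewed from inside with flanks s_{j−1} and s_{i+1}. The two views are
  mirror images under strand reversal.

**Terminal AU/GU penalty** placement: hairpin closings, both closings of
bulges of length ≥ 2, the multiloop closing pair, every multiloop branch
and every exterior branch. Internal-loop closings are exempt (their
mismatch tables take that role), as are length-1 bulges.

**SHAPE pseudo-energies**: a reactivity profile maps to per-position
energies `m·ln(1 + r) + b` (missing values contribute zero), added once
for each paired position at pair-formation time, in `V(i,j)` and in the
re-scorer identically. `m` and `b` have no defaults: they are
experiment-calibration choices that belong to the user.

# Tables, recursion, wavefront schedule

Four tables are used. `V(i,j)` is the optimum with (i,j) paired. `WM1(i,j)`
is a multiloop fragment whose 5′ end starts a branch exactly at i, with
trailing unpaired bases charged `c` each; `WM(i,j)` is a fragment with at
least one branch and free leading/trailing placement. The split of the
standard single multiloop array into `WM`/`WM1` keeps the closing rule —
`V`'s multiloop case scans one split point between a `WM` and a `WM1`
region — O(n) per cell and O(n³) overall. `W(j)` assembles the exterior
loop; `W(n)` is the MFE (`W` is stored with a leading `W(0) = 0` entry).
Internal-loop enumeration is bounded by `max_internal_span` (default 30
total unpaired bases), the field's common practice; the bound is a
parameter, and short-sequence oracle comparisons are unaffected because
loops that long cannot occur there.

Cells are computed strictly in increasing subsequence length
`k = j − i + 1`. Within one anti-diagonal every cell depends only on
strictly shorter subsequences, so cells are mutually independent — the
property that makes fine-grained parallel filling possible. The `workers`
argument realizes the scheduling contract observably without threads: it
permutes the visiting order of each diagonal into `workers` round-robin
chunks. The contract is that tables are bit-identical for any worker
count, which the test suite and acceptance script check for 1, 2 and 4
workers; a sequential fill is simply the 1-worker schedule. Actual
threading is an implementation vehicle, not a semantic feature, and is
deliberately left out: correctness claims here are about the schedule's
independence structure, which the permutation exercises.

Lonely (isolated) pairs are allowed by default; `prefilter = TRUE` drops
candidate pairs lacking an admissible stacked neighbor at sequence level
(before constraints), the only isolation control. Forced pairs are always
retained.

# Constraints

Forced pairs, prohibited pairs and forced-single positions are enforced
*hard*: prohibited pairs and pairs touching forced-single positions leave
the candidate set; a forced pair (a, b) removes every pair sharing an
endpoint with it or crossing it, and marks a and b as must-pair positions
that no "leave unpaired" transition in `W`/`WM`/`WM1` and no unpaired
loop region may absorb. Energy-bonus constraint schemes guarantee nothing
structurally; cell forbidding does, and the soundness tests check the
returned structures, not the energies. Internally consistent forced sets
(non-crossing, position-disjoint, admissible, h-respecting) are always
realizable — at worst by the structure containing exactly the forced
pairs — so the constrained optimum exists and can only be ≥ the
unconstrained one.

# Deterministic traceback

The traceback re-derives each cell's minimizing case by re-evaluation
(no pointers are stored; memory stays at the four tables). Ties are
broken in a fixed documented order: in `V` — hairpin, then stack, then
internal/bulge lexicographically by (i′, j′), then multiloop with the
smallest split point; in `W`, `WM`, `WM1` — "position unpaired" before
"pair here", and the smallest 5′ partner first. Any total order would do;
this one is short to state and cheap to test. The returned structure is
certified: the independent re-scorer — which decomposes the pair set into
loops and sums the evaluators, never consulting the DP tables — must
reproduce `W(n)` exactly, in integer arithmetic, on every fold.

# Accuracy metrics

Sensitivity is `TP/(TP+FN)`; selectivity is `TP/(TP+(FP−ξ))`. A
false-positive pair counts toward ξ when it is *compatible* with the
reference: adding that single pair to the reference pair set violates
none of position uniqueness, non-crossing, or the hairpin bound. Each
false positive is tested independently against the reference alone —
whether ξ should also consider conflicts among false positives, or admit
±1 slipped pairs, is not settled usage; single-pair insertability is the
simplest reading, and it is checkable by a literal insert-and-revalidate
brute force, which the tests run on hundreds of random cases. Ratios with
zero denominators are flagged undefined (`NA`), never silent `NaN`.
Batch comparisons report per-sequence rows plus the (mean selectivity,
mean sensitivity) summary point, arithmetic means over sequences.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `h` | 3 | bases | minimum hairpin loop; steric limit |
| `l_max` | 30 | bases | largest tabulated loop length |
| `extrapolation` | 1.08 (toy) | kcal/mol | `≈ 1.75·RT` log-extrapolation slope |
| `asym_coeff`, `asym_max` | 0.5, 3.0 (toy) | kcal/mol | capped internal-loop asymmetry |
| `ml_a`, `ml_b`, `ml_c` | 3.4, 0.4, 0.4 (toy) | kcal/mol | affine multiloop score |
| `max_internal_span` | 30 | bases | internal-loop enumeration bound |
| `dangle` | `"none"` | — | helix-end treatment |
| `prefilter` | `FALSE` | — | lonely-pair filter off by default |

The bundled toy set uses round two-decimal numbers chosen so that worked
examples are hand-checkable: stacking strength ordered CG/GC > AU/UA >
GU/UG, gently increasing loop initiations, small negative mismatches and
dangles. The zero set makes every admissible loop score 0, so the MFE of
any sequence is 0 with massive ties — a stress test for tie handling and
termination, not a model.

# What the random-sequence generator emulates — and what it does not

`random_sequences()` draws i.i.d. residues with a single GC-bias
parameter (G and C each `gc/2`, A and U each `(1−gc)/2`), the classic
randomized cross-check device for folding engines, scaled to desk size:
the verification panels use ~200 sequences of length ≤ 25 for exhaustive
oracle comparison and 50 sequences of length 120 for scheduler
invariance, sizes at which enumeration is exact and the full suite runs
in minutes. Uniform random sequences have no phylogenetic structure, no
composition heterogeneity, and their MFE structures are shallower than
biological RNAs; with the toy tables, passing tests therefore demonstrate
*engine correctness* — exact agreement of the optimizer with exhaustive
search under identical scoring — and say nothing about predictive
accuracy on real molecules, which depends on parameter quality this
package deliberately does not bundle.

# Numerical and degenerate-input choices

* Fixed-decimal integers end-to-end; the only rounding is the long-loop
  logarithm, identical in both code paths.
* Sentinel saturation prevents wrap-around optima.
* Sequences shorter than `h + 2`: no pair can form; `V` is all-forbidden
  and `W ≡ 0` (the empty structure), and traceback returns it.
* `W(j) ≤ W(j−1)` holds on unconstrained folds (appending a free base
  never hurts); must-pair constraints legitimately break it, which is why
  the invariant is tested unconstrained.
* Empty structures are valid everywhere: scoring yields a single
  zero-term exterior loop.
* Parameter files must be complete; a missing section or table entry
  aborts the parse with file/line/field, and no partial object escapes.

# Known limitations

No partition function, base-pair probabilities, Boltzmann sampling or
suboptimal-structure bands; no coaxial stacking; no pseudoknots; no
special-case loop bonus tables; no attempt to reproduce any published
program's exact numbers (that requires their exact parameter files and
quirks). The enumeration oracle refuses sequences beyond its cap
(default 25) because the structure count grows exponentially; the cap is
an explicit override, not a hidden wall.
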