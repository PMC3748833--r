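# wavefold

Minimum free energy (MFE) RNA secondary structure prediction by wavefront
dynamic programming.

`wavefold` predicts the pseudoknot-free secondary structure of an RNA
sequence that minimizes total free energy under a nearest-neighbor
thermodynamic model (NNTM): every loop of a structure — stacked pair,
hairpin, bulge, internal loop, multiloop, exterior loop — contributes an
additive term read from empirical parameter tables, and the optimum over
all nested pair sets is found by dynamic programming. The tables are
filled in *anti-diagonal* (subsequence-length) order: all cells for
subsequences of length *k* depend only on strictly shorter subsequences,
so they are mutually independent and can be computed by any number of
workers in any order with bit-identical results. A deterministic traceback
recovers one optimal structure, and an independent loop-by-loop re-scorer
certifies its energy against the table optimum exactly.

The package is aimed at people who study folding *engines* rather than
folding answers: every component is verifiable end-to-end against a
brute-force enumeration oracle on short sequences, with no external data
or parameter downloads.

## The model

For a sequence s₁…sₙ, `V(i,j)` is the minimum energy over structures on
sᵢ…sⱼ in which (i,j) pairs:

    V(i,j) = min { hairpin(i,j);
                   stack(i,j) + V(i+1,j-1);
                   internal(i,j,i',j') + V(i',j')  over a bounded window;
                   a + b + ends(i,j) + multiloop fragments via WM/WM1 }

`W(j)`, the minimum over all structures on s₁…sⱼ, is assembled from `V`,
and `W(n)` is the MFE. Multiloops are scored affinely
(`a + b·branches + c·unpaired`). Helix ends in multiloops and the exterior
loop can be scored three ways (`--dangle none|dangles|mismatch`): not at
all, as the best admissible combination of 5′/3′ dangling ends, or as a
terminal-mismatch lookup — the treatment that distinguishes the major
folding programs. Energies are handled internally as exact integers in
units of 0.01 kcal/mol, so ties and totals are reproducible to the digit.

Also included:

* **Constraints** — forced pairs, prohibited pairs, forced single-stranded
  positions; enforced *hard* (conflicting DP cells are forbidden), never by
  energy bonuses.
* **SHAPE pseudo-energies** — per-position `m·ln(1+r) + b` added for each
  paired position.
* **Neighbor prefilter** — optionally drop candidate pairs with no
  admissible stacked neighbor (the lonely-pair filter).
* **Accuracy metrics** — base-pair sensitivity `TP/(TP+FN)` and
  selectivity `TP/(TP+(FP−ξ))`, where ξ counts false positives compatible
  with (insertable into) the reference structure.
* **Oracle** — exhaustive enumeration of all nested structures on short
  sequences, scored by the same independent re-scorer, used to verify the
  engine exactly.

The bundled parameter sets are a hand-written "toy" set with round numbers
(`toy_parameters()`, also shipped as `inst/extdata/params_toy.txt`) and an
all-zero null set (`zero_parameters()`). They are designed for verifiable
arithmetic, not biological realism; users supply their own Turner-style
tables in the documented plain-text dialect via `read_parameters()`.

## Worked example

```r
library(wavefold)
p <- toy_parameters()
f <- rna_fold("GGGCGCAAAAGCGCCCAAGCGAAACGC", p, dangle = "dangles")
f
#> <rna_fold> seq (n = 27)
#> GGGCGCAAAAGCGCCCAAGCGAAACGC
#> ((((((....))))))..(((...)))
#> MFE = -7.00 kcal/mol (9 pairs; dangle = dangles)

f$decomposition
#> <energy_decomposition> total = -7 kcal/mol
#> # A tibble: 10 x 6
#>    kind         i     j    ip    jp energy
#>  1 stack        1    16     2    15   -2.1
#>  ...
#>  6 hairpin      6    11    NA    NA    4.2
#>  9 hairpin     21    25    NA    NA    4
#> 10 external    NA    NA    NA    NA   -0.5
```

The fold is two hairpin helices: five CG/GC stacks at −2.1 kcal/mol each
close a tetraloop (+4.2), a second helix of two stacks closes a triloop
(+4.0), and the exterior-loop dangling ends contribute −0.5, giving the
certified total of −7.00 kcal/mol. Comparing against a reference that
contains only the first helix:

```r
ref <- from_dotbracket("((((((....))))))...........")
accuracy_report(f$structure, ref)
#> <accuracy_report> TP = 6, FN = 0, FP = 3, xi = 3
#>   sensitivity = 1.0000, selectivity = 1.0000
```

All six reference pairs are recovered (sensitivity 1); the three extra
predicted pairs are all insertable into the reference, so the ξ correction
leaves selectivity at 1. `tidy()` returns the same report as a one-row
tibble; `accuracy_table()` handles batches and adds the
(mean selectivity, mean sensitivity) summary point.

## Command line

A thin Rscript CLI ships at `inst/scripts/wavefold`
(`system.file("scripts", "wavefold", package = "wavefold")`):

```sh
wavefold fold input.fa --dangle dangles --ct out.ct
wavefold score input.fa structure.db
wavefold compare predicted.ct reference.ct
wavefold enumerate short.fa
wavefold selftest --seed 1
```

## File dialects

* **CT** (connect table): header `"<n> ENERGY = <kcal> <name>"` (energy
  clause optional), then `n` rows `"<i> <base> <i-1> <i+1|0> <partner|0> <i>"`,
  space-separated, 1-based, symmetric partner column.
* **Dot-bracket**: `(`, `)`, `.` only — structures are nested by
  construction.
* **Constraints**: lines `F i j` (force pair), `P i j` (prohibit pair),
  `S i` (force single-stranded); `#` comments.
* **SHAPE**: two columns, position and reactivity; `-999` means missing.
* **Parameters**: keyword-sectioned tables (STACK, HAIRPIN_INIT, ...,
  MULTILOOP, MISC), kcal/mol with two decimals; see `?read_parameters`.

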