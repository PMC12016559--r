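---
title: "Banded striped alignment: model, kernel and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Banded striped alignment: model, kernel and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandstripe)
```

## The alignment model

`bandstripe` computes global (Needleman–Wunsch) pairwise alignment of
nucleotide sequences under affine gap costs, in the standard three-matrix
(Gotoh) form. Writing `i` for query and `j` for reference positions, `S` for
the substitution score and `GapE`/`GapOE` for the gap-extension and combined
open-plus-extension penalties:

$$
\begin{aligned}
E_{i,j} &= \max(E_{i,j-1} + \mathrm{GapE},\; H_{i,j-1} + \mathrm{GapOE})\\
F_{i,j} &= \max(F_{i-1,j} + \mathrm{GapE},\; H_{i-1,j} + \mathrm{GapOE})\\
H_{i,j} &= \max(H_{i-1,j-1} + S_{i,j},\; E_{i,j},\; F_{i,j})
\end{aligned}
$$

`E` accumulates gaps that consume the reference (CIGAR `D`), `F` gaps that
consume the query (CIGAR `I`). The default scores are 2 / −4 for
match/mismatch and −4 / −2 for gap open/extension, so the first gap base
costs `GapOE` = −6. `N` never matches, not even another `N`; IUPAC codes
other than `N` are folded to `N` on input.

Three accelerations are combined, and each is implemented so that it is
*exact* — the full-width mode reproduces the Gotoh optimum bit for bit, and
a finite band equals the optimum whenever the optimal path stays inside the
band.

### 1. The adaptive band

Only `W` consecutive query cells are evaluated per reference row; cells
outside the band are walls holding a sentinel that never wins a maximum.
Between rows the band moves right by 0, 1 or 2 cells — favouring a vertical
gap, the diagonal, or a horizontal gap — chosen by comparing the summed
absolute scores of the band's first and last register. Near the end of the
sequences the decision is overridden so the terminal corner is guaranteed to
lie in the final band; `align_global()` reports how many rows were
overridden. The band always indexes the shorter sequence: when the query is
longer than the reference the roles are swapped internally and the CIGAR
transposed back, which also guarantees the corner is reachable with at most
two cells of advance per row.

Two variants of the shift statistic exist. The shipped default compares the
first and last *register* (strided samples across the whole band, cheap in
striped form); `shift_rule = "contiguous"` compares the leftmost and
rightmost `p` contiguous cells instead. Both are exposed because they are
natural readings of the same idea; the register rule is the one the striped
data structure gets for free, and it is what every shipped result uses.

### 2. The striped layout and the striped move

The `W` band cells are stored across `s_bar = W/p` registers of `p` lanes;
register `k`, lane `t` holds in-band offset `k + t·s_bar`
([normal_to_striped()]). Striping breaks the within-register dependency
chain of the row recurrence, which is what makes lane-parallel evaluation
possible. When the band shifts, the striped arrays are *not* rebuilt:
shifting the normal-order content left by 0–2 cells is realized as a
rotation of the register sequence plus a one-lane shift with sentinel fill
on each wrapped register ([striped_move()]) — O(`s_bar`) register
operations, independent of the shift. Lane semantics here are emulated with
wide (64-bit) integers and are width-agnostic: every result is identical for
every lane count `p`, which the tests assert. The default `p = 16` mirrors
128-bit registers of 8-bit lanes.

### 3. The difference recurrence relation

Instead of absolute scores the kernel carries per-cell differences:
`h = H[i,j] − H[i−1,j−1]`, `u = H[i,j] − H[i−1,j]`,
`v = H[i,j] − H[i,j−1]`, `e = E[i,j] − H[i,j−1]` and
`f = F[i,j] − H[i−1,j−1]` (note the deliberately asymmetric anchors of `e`
and `f`). Only `u` and `e` survive between rows. Substituting the
definitions into the Gotoh recurrences gives the row kernel

$$
\begin{aligned}
h_{i,j} &= \max(S_{i,j},\; e_{i,j} + u_{i,j-1},\; f_{i,j})\\
e_{i,j+1} &= \max(e_{i,j} + u_{i,j-1} - h_{i,j} + \mathrm{GapE},\;
                 \mathrm{GapOE})\\
f_{i+1,j} &= \max(f_{i,j} + \mathrm{GapE},\; h_{i,j} + \mathrm{GapOE})
             - u_{i,j-1}
\end{aligned}
$$

The trailing `− u` in the `f` propagation re-anchors the difference from
`H[i−1,j−1]` to `H[i,j−1]` and is forced by the definitions; the package
derives all three lines algebraically and verifies them against the
absolute-form oracle, cell for cell. Differences stay bounded by the score
parameters (at most `match + |GapOE|` in magnitude on real alignments — a
property the tests measure on mutated pairs), which is what makes 8-bit lane
packing feasible in a SIMD realization. This implementation keeps the
differences in 64-bit lanes and asserts the bound instead of exploiting it.

### 4. The active F-loop

In striped order the `f` chain is the one recurrence that still runs along
the row, and some cells are evaluated before the cells they depend on. The
classic remedy (lazy-F) re-sweeps the row until nothing changes, which
degrades with long insertions. The active F-loop costs exactly two passes
for every input:

1. **Initial pass.** Every segment's `f` is seeded with the sentinel and the
   row is evaluated register by register. All cells not influenced by a
   horizontal gap crossing a segment boundary are already final. The last
   F register — lane `t` holding the `f` leaving segment `t` — is saved.
2. **Correction.** One serial sweep over the segment-entry lanes replaces
   lane `t` by `max(lane t, lane t−1 + s_bar·GapE − ΔH)`, where `ΔH` is the
   previous row's absolute step across the segment (a prefix-sum of its `u`
   values). Because the sweep is serial, a gap penetrating any number of
   segments propagates in a single pass; re-opening a gap inside a
   penetrated segment can never beat pure extension (since
   `GapOE ≤ GapE`), so one sweep is sufficient — never iterated.
3. **Final pass.** The register recurrence is re-run once from the corrected
   seeds (shifted right one lane with a sentinel in lane 0). Its outputs are
   a fixed point: re-deriving seeds from its own exit register and running
   again changes nothing, which the tests assert.

The same two-pass kernel exists twice: as the compiled production aligner
and as plain R functions ([row_initial_pass()], [active_f_correct()],
[row_final_pass()]) whose only job is to make the algebra inspectable and
testable against [row_scalar_reference()], the left-to-right scalar
evaluation of the same row.

## Boundary semantics and numerics

Banded DP needs walls. All out-of-band and out-of-matrix cells hold the
sentinel `neg_inf_sentinel()` = −2^40 exactly, absolute row scores below
−2^39 are floored back to the sentinel, and `u` is stored as the *raw
difference of the walled scratch row* — including across dead cells — so
every difference telescopes exactly and no special case enters the
recurrences. The wall value is far below any reachable score (bounded by
sequence length times the largest score magnitude) yet leaves ample
headroom in 64-bit arithmetic for sums over a register and for the
`sentinel + penalty` chains that dead regions accumulate. One absolute row
is kept as scratch for the shift decision and the wall bookkeeping; no
score matrix is ever stored, and traceback uses two bits of direction plus
one gap-continuation bit per band cell.

Tie-breaking is fixed and shared by the striped kernel, the scalar banded
reference and the full-matrix oracle: diagonal beats the reference gap
beats the query gap, and gap extension beats re-opening. The striped and
scalar banded engines therefore produce byte-identical CIGARs, which the
tests assert on every compared pair.

Degenerate inputs: empty sequences are rejected; a requested band width is
rounded up to a multiple of the lane count; a band at least the query
length (plus the boundary column) is clamped to the full-width mode. The
full-width mode is not special-cased — it is the same striped kernel with
the shift pinned to zero.

## Edit-distance mode

`edit_distance()` solves the unit-cost version of the same problem with a
Myers-type block bit-vector engine: per 64-row block, two words carry the
±1 vertical deltas and one running score sits at the block's bottom row.
The *whole* mode computes the exact Levenshtein distance. The *limit* mode
takes a maximum distance `k`, confines work to the Ukkonen band of
diagonals that could still cost ≤ `k` (blocks outside it are never
computed; cells entering from outside are upper-bounded, which is safe
because any out-of-band cell provably exceeds `k`), and reports `EXCEEDED`
exactly when the true distance is larger than `k`. Traceback stores the
per-column block states and walks the bit deltas back from the corner; on
an optimal path every visited cell is provably exact, so the walk cannot
derail. The engine is compared against the Wagner–Fischer oracle over both
modes, with the examined-cell counters checked for the limit mode's work
reduction.

## What the simulator emulates — and what it does not

The generator draws uniform i.i.d. references ([random_reference()]) and
mutates each base independently with total probability `divergence`,
splitting events between substitutions, single-base insertions and
deletions by a configurable ratio ([mutation_profile()]); the named
profiles carry the published long-read ratios 6:50:54 (PacBio) and
23:31:46 (Nanopore). Long indels are injected explicitly
([inject_indel()]: one block at the midpoint ± 10% jitter) precisely
because an i.i.d. point process essentially never produces them. This
replaces sampling from a real genome and HMM-based error models with the
only parameters that are exactly reproducible — divergence and event
ratios. Consequences worth keeping in mind: simulated references lack the
repeat structure and compositional bias of real genomes, and errors are
unclustered. Recall measured here says the band *tracks the optimal path
under the stated divergence and indel sizes*; it does not certify behaviour
in low-complexity or repetitive regions, where any banded method can be
led astray.

[recall_experiment()] ties the pieces together: per replicate it builds a
reference, optionally injects an indel, mutates, and scores the banded
aligner against the full-matrix Gotoh optimum; recall of a band width is
the fraction of replicates with equal scores. Replicate `r` derives its
seed as `seed + r`, so every table is reproducible from one integer.

```{r recall-demo}
prof <- mutation_profile(0.2, "nanopore", seed = 71)
recall_experiment(8, 1200, prof,
                  indel = list(size = 100, kind = "deletion"),
                  band_widths = c(256, 64))$table
```

The band-width rule of thumb this reproduces: recall stays at 1.0 while the
band is at least about twice the indel size, and collapses once the band is
clearly smaller than the indel (the band cannot reach around the gap), with
the transition in between.

## Problem sizes used by the shipped checks

The test suite validates the kernels exhaustively at small scale (every
striped layout up to width 256; more than a thousand random rows across
lane/segment combinations; a thousand random pairs against the full-matrix
oracle; two thousand pairs for the edit engine) and the recall experiments
at a 3-kb reference scale with 24 replicates per condition (100 replicates
at 1 kb for the low-divergence case) — sizes chosen so the full-matrix
oracle, which is quadratic, remains comfortable on one CPU while leaving
the banded-vs-oracle comparisons statistically unambiguous (every shipped
condition lands on recall exactly 0 or 1). The same experiments at 10-kb
references give identical recall patterns and scale linearly in the band
mode; only the oracle cost grows quadratically.

## Known limitations

* Global alignment only; the Smith–Waterman implementation is a test oracle,
  not a production local-alignment mode.
* The band moves monotonically rightward by at most two cells per row, so
  pathological inputs whose optimal path drifts *left* faster than the band
  can compensate (long insertions very early against a much longer
  reference) are handled by the role swap, not by band reversal.
* Lane emulation is scalar under the hood: the package's value is
  correctness, inspectability and the recall methodology, not wall-clock
  parity with vectorized C implementations.
* The i.i.d. error model understates the difficulty of clustered errors;
  recall at a given divergence should be read as an upper bound for real
  reads at the same divergence.
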