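# bandstripe

Banded striped pairwise sequence alignment for nucleotide sequences, with a
bit-vector edit-distance mode, brute-force oracles, a long-read error
simulator and a band-width recall benchmarking harness.

## The problem

Exact global alignment (Needleman–Wunsch with Gotoh's affine gaps) is
quadratic in sequence length, which is prohibitive for long noisy reads.
Three classic accelerations attack this from different sides: *banded DP*
evaluates only a band of cells around the alignment diagonal; *striped
vector layouts* evaluate a row's cells lane-parallel; and the *difference
recurrence relation* stores cell-to-cell score differences instead of
absolute scores, so values stay small. Combining them is awkward — moving
the band invalidates the striped layout, and striping breaks the within-row
gap chain. `bandstripe` implements the combination exactly:

* the band follows the diagonal adaptively, shifting 0/1/2 cells per row by
  comparing the summed scores of its first and last register, with
  overrides near the ends so the terminal corner always stays in band;
* the per-row re-layout is a **striped move**: a rotation of the register
  sequence plus a one-lane shift with sentinel fill on wrapped registers —
  O(segments) register operations, never a rebuild;
* rows are evaluated in **difference form**. With
  `h = H[i,j] − H[i−1,j−1]`, `u = H[i,j] − H[i−1,j]`,
  `e = E[i,j] − H[i,j−1]`, `f = F[i,j] − H[i−1,j−1]`, only `u` and `e` are
  carried between rows and the row kernel is

  ```
  h[i]   = max(S[i], e[i] + u[i], f[i])
  e'[i]  = max(e[i] + u[i] − h[i] + GapE, GapOE)
  f[i+1] = max(f[i] + GapE, h[i] + GapOE) − u[i]
  ```

* the within-row `f` chain, which striping breaks, is repaired by an
  **active F-loop**: an initial pass with sentinel-seeded segments, one
  serial sweep over the segment-entry lanes that propagates gaps
  penetrating whole segments, and one final pass — exactly two passes per
  row for every input, long gaps included.

Full-width mode ("no band") is the same kernel with the shift pinned to
zero and reproduces the Gotoh optimum exactly; a finite band equals the
optimum whenever the optimal path stays inside the band. The package is
written for correctness and inspection (lanes are emulated with wide
integers and every layout gives identical results), not for wall-clock
racing; it ships its own full-matrix Gotoh, Smith–Waterman and
Wagner–Fischer oracles so that every claim is checked against independent
code.

An **edit mode** (`edit_distance()`) computes exact Levenshtein distances
with a Myers-style 64-bit block bit-vector engine, either over the whole
matrix or limited to a maximum distance `k` (Ukkonen band, `EXCEEDED` when
the true distance is larger), with optional traceback.

## Worked example

Simulate a 3-kb reference, plant a 200-bp insertion, mutate to 20%
divergence with the Nanopore 23:31:46 substitution:insertion:deletion
ratio, and align at two band widths:

```r
library(bandstripe)

ref    <- random_reference(3000, seed = 7)
varref <- inject_indel(ref, 200, "insertion", seed = 7)
qry    <- mutate(varref, mutation_profile(0.2, "nanopore", seed = 7))

align_score_only(qry, ref)                    # full width: 2036 (the optimum)
align_score_only(qry, ref, band_width = 512)  # 2036  -- band >= 2 x indel
align_score_only(qry, ref, band_width = 256)  # 1846  -- band misses the indel

align_global(qry, ref, band_width = 512)
#> <bandstripe_alignment> score 2036, band 512 (16 lanes), roles swapped
#>   query 0..3127, reference 0..3000, identity 0.7789
#>   cigar: 1=1D1=1X4=2D3=1X3=1I7=1D6=1I2=1X12=1I10=1I1=1X2=1I14=1D10...
```

The full-width score 2036 is the exact Gotoh optimum. A 512-bp band — at
least twice the 200-bp indel — recovers it; a 256-bp band cannot reach
around the insertion and returns a lower score (the banded score is always
a lower bound). `score` re-derives exactly from the CIGAR
(`rescore_cigar()`), and `identity` is the fraction of `=` columns.

The same pair in edit mode, with the search limited to distance 900:

```r
edit_distance(qry, ref, limit = 900)
#> <bandstripe_edit> distance 720
```

The limit mode examined 4.6M DP cells against 9.4M for the whole-matrix
mode (the `cells` field of the result).

`recall_experiment()` wraps the band-width experiment: per replicate it
simulates a pair, computes the full-matrix optimum and the banded scores,
and reports per band width the fraction of replicates whose banded score
equals the optimum.

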