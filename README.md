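# insertscan

Rigidity-based analysis of exhaustive double amino-acid insertion
mutagenesis.

## The problem

Inserting an amino acid into a protein elongates the chain by one residue
and can reshape the backbone far beyond the insertion site. For a protein
of *n* residues, the space of **double** insertions — two positions in the
elongated (*n*+2)-residue sequence plus two residue types — contains

```
C(n + 2, 2) x 20^2
```

distinct mutants: 451,200 for a 46-residue protein such as crambin, over
3 million for a 125-residue profilin. Exhaustive scans of this space ask
which inserted residue types, positions, residue sizes and secondary-
structure contexts most disturb a structure. `insertscan` provides the
complete analysis stack for such scans:

* **Mutant space** — counting, lexicographic enumeration, and annotation of
  every double insertion with its wildtype insertion gaps, amino-acid
  volume size class (VS/S/M/L/VL), and α-helix group (I_XX / I_XH / I_HH:
  neither, one, or both insertions inside a helix).
* **Structures** — PDB reading (ATOM + HELIX records, via bio3d) and
  writing, plus generators for ideal-geometry polypeptides.
* **Interactions** — geometric hydrogen-bond detection (distance + angle,
  with implicit-hydrogen donor typing for unprotonated files) and
  hydrophobic tethers.
* **Rigidity** — a body–bar–hinge mechanical model (locked bonds merge
  atoms into rigid bodies, rotatable bonds are 5-bar hinges, hydrogen
  bonds 5 bars, hydrophobic tethers 2 bars) analyzed by the (6,6) pebble
  game, which decides bar independence exactly for generic 3D body-bar
  frameworks and yields the rigid cluster decomposition.
* **Metrics** — per-structure stability scores: hydrogen bond count (HBC);
  cluster configuration entropy (CCE), the normalized Shannon entropy of
  the rigid-cluster size distribution in [0, 1]; and the rigidity order
  parameter (ROP), the largest-cluster atom fraction in (0, 1].
* **Statistics** — two-sided k·σ outlier sets; residue, pair and position
  frequency tallies; top-k pair rankings; Cohen's *d*
  (`d = (M1 - M2) / sqrt((s1^2 + s2^2) / 2)`) with pooled-variance
  two-sample *t*-tests; helix-group comparisons; and size-class
  normalized outlier rates.
* **Synthetic data** — simulated mutant metric ensembles with planted
  group effects (in Cohen's-*d* units) for validating the statistical
  layer, and random bar frameworks for cross-checking the pebble game
  against a rigidity-matrix rank oracle.

## Worked example

Score two 12-residue poly-alanine chains — an ideal α-helix and an
extended chain:

```r
library(insertscan)
metric_record(ideal_helix_structure(12))
#>        mutant_id hbc     cce       rop n_atoms
#> 1 ideal_helix_12   8 0.10049 0.9014085      71
metric_record(extended_chain_structure(12))
#>           mutant_id hbc       cce        rop n_atoms
#> 1 extended_chain_12   0 0.7326012 0.05633803      71
```

The helix carries the canonical N(i)→O(i−4) hydrogen-bond ladder (8 bonds
for 12 residues), which locks most of its atoms into one dominant rigid
cluster (ROP 0.90, CCE 0.10); the extended chain has no hydrogen bonds and
fragments into many small clusters (ROP 0.06, CCE 0.73).

Simulate a full crambin-scale mutant ensemble (n = 46, helices at
residues 7–17 and 23–30) with a planted −0.456 sd shift of the hydrogen
bond count when both insertions fall inside a helix, then recover it:

```r
cfg <- synthetic_ensemble_config(
  n_residues = 46, seed = 17,
  planted_effects = list(list(column = "helix_group", value = "I_HH",
                              metric = "hbc", shift = -0.456)))
ens <- simulate_metric_ensemble(
  cfg, helix_ranges = data.frame(start = c(7, 23), end = c(17, 30)))
nrow(ens)
#> [1] 451200
helix_group_comparison(ens, "hbc")$comparisons[, c("group1", "group2",
                                                   "n1", "n2", "d")]
#>   group1 group2     n1     n2        d
#> 1   I_XX   I_XH 186000 204000 -0.00116
#> 2   I_XX   I_HH 186000  61200  0.44435
#> 3   I_XH   I_HH 204000  61200  0.44615
```

The unshifted I_XX vs I_XH comparison stays null while both comparisons
against the shifted I_HH group recover Cohen's *d* ≈ 0.45 (the planted
0.456, attenuated marginally by integer rounding of the counts). Outlier
analysis on the same ensemble:

```r
os <- outliers(ens, "hbc")          # two-sided, k = 2 standard deviations
os
#> outlier_set: 22001 mutants with |hbc - 5.405| >= 2 * 1.546 (both)
top_pairs(outlier_pair_tally(ens, os, by = "aa"), k = 5)$pairs
#>   item1 item2 pair count
#> 1     N     Y   NY   147
#> 2     A     V   AV   133
#> 3     M     S   MS   133
#> 4     H     L   HL   132
#> 5     L     S   LS   131
```

`run_full_analysis(run_config(...))` chains these stages end to end and
writes every table plus a reproducibility manifest to an output directory.

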