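---
title: "Methods: rigidity analysis of exhaustive double-insertion mutant spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigidity analysis of exhaustive double-insertion mutant spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insertscan)
```

This vignette documents the models, conventions and numerical choices
behind `insertscan`, in the order the pipeline runs them: mutant-space
coordinates, interaction detection, the mechanical model and pebble game,
the three metrics, the statistical layer, and the synthetic-data
generators used for validation. Where a design was genuinely open we state
the choice made and why.

## 1. Mutant-space coordinates

A double insertion is located by the positions `pos1 < pos2` of the two
inserted residues **in the elongated (n+2)-residue sequence**, with the
residue types `aa1`, `aa2` attached to those positions. This coordinate
system makes the space size exactly `choose(n + 2, 2) * 400` and, unlike
gap-pair coordinates, counts two insertions into the *same* wildtype gap
once (they appear as adjacent elongated positions, and the two residue
orderings are distinct mutants).

Each elongated position maps back to a wildtype **insertion gap**
independently of the other insertion: `gap1 = pos1 - 1` and
`gap2 = pos2 - 2`, with gap `g` lying between wildtype residues `g` and
`g + 1` (gap 0 before the first residue, gap `n` after the last; every
structure has `n + 1` gaps). All per-position reporting uses wildtype gap
numbering, so positions are comparable across mutants.

A gap is *in* an α-helix only when **both** flanking residues belong to
the same annotated helix range: that is the only case where the insertion
interrupts the helix, and it makes terminal gaps never helical. Helix
annotations come from the structure's deposited HELIX records; the package
does not recompute secondary structure. The helix group of a mutant counts
its helical gaps: `I_XX` (0), `I_XH` (1), `I_HH` (2).

Amino-acid size classes partition the 20 residues by mean residue volume:
VS {G, A, S}, S {C, D, P, N, T}, M {E, V, Q, H}, L {M, I, L, K, R},
VL {F, Y, W} (60–89, 108–116, 138–153, 162–173, 189–227 Å³). Pair size
groups are unordered; homogeneous pairs use the compact labels
`VSVS` … `VLVL` and mixed pairs `"VS-VL"` style labels.

## 2. Interaction detection

Hydrogen bonds are detected **geometrically**, not energetically. A
donor–acceptor pair qualifies when:

* the donor is an N/O/S atom typed as a donor by the residue templates
  (backbone amide N of every non-proline residue; side-chain donors per
  standard chemistry), the acceptor an N/O/S template acceptor;
* the heavy-atom distance is at most `dist_cutoff` (default **3.5 Å**, a
  standard moderate-strength N/O donor–acceptor cutoff);
* if the donor carries an explicit hydrogen, some D–H⋯A angle is at least
  `h_angle` (default **120°**); otherwise every covalent heavy neighbour B
  of the donor must satisfy ∠(B–D⋯A) ≥ `antecedent_angle` (default
  **90°**), a proxy for "the acceptor sits on the hydrogen side of the
  donor";
* the pair is not covalently bonded and not a 1–3 pair.

All cutoffs are exposed as function arguments because different upstream
tools tally hydrogen bonds differently; absolute HBC values from this
detector are therefore comparable **within** a run but not with
energy-based counters. The implicit-hydrogen route is deliberately the
looser of the two: without the hydrogen position it cannot resolve
near-miss contacts (on an ideal helix it admits i→i−3 contacts that the
explicit-H angle rejects at ~109°), which is why generated fixtures carry
explicit amide hydrogens.

Hydrophobic tethers join carbon/sulfur atoms of different residues within
the sum of van der Waals radii (C 1.7 Å, S 1.8 Å) plus a slack of
**0.25 Å**. Pairs fewer than four covalent bonds apart are excluded: in
any polypeptide the backbone C(i)–CA(i+1) (1–3, ≈2.4 Å) and C(i)–C(i+1)
(1–4, ≈3.0 Å) pairs fall inside any sensible contact cutoff, and those
distances are covalent geometry, not hydrophobic association. This
exclusion is the package's own tightening of the bare "different
residues" rule and was verified numerically on ideal-geometry chains.

## 3. Mechanical model and pebble game

The body–bar–hinge model is built from the covalent topology plus the
detected interactions:

* **Locked bonds merge atoms into one rigid body**: peptide bonds, double
  and partial-double bonds (carbonyl, carboxylate, amide, guanidinium),
  ring systems (Pro, His, Phe, Tyr, Trp treated as rigid), bonds to
  hydrogens, and bonds to covalent-degree-1 heavy atoms. The last rule is
  a modelling convention: a point atom has no spin degree of freedom, and
  leaving terminal atoms as hinged singleton bodies would pollute the
  cluster-size distribution with physically meaningless singletons.
* **Rotatable single bonds** become 5-bar edges (a hinge: one remaining
  relative degree of freedom, the dihedral).
* **Hydrogen bonds contribute 5 bars, hydrophobic tethers 2 bars** —
  the standard body–bar–hinge multiplicities from the rigidity
  literature; both are configurable at the interaction table level.
* Parallel edges between one body pair are summed and capped at 6 bars
  (6 bars already remove all relative freedom).

Generic rigidity of such a 3D framework is combinatorial (Tay–Whiteley):
a bar set is independent iff every sub-multigraph on `n'` bodies spans at
most `6 n' − 6` bars. The **(6,6) pebble game** decides this exactly: each
body starts with 6 pebbles; a bar is accepted iff 7 free pebbles can be
gathered on its endpoints by reversing directed paths to free pebbles,
and acceptance consumes one pebble. Rejected bars are redundant. Hinges
are processed as 5 ordinary bars rather than special-cased, which is
equivalent for generic frameworks.

**Rigid clusters.** After the game, two adjacent bodies belong to one
cluster iff 7 free pebbles *cannot* be gathered on them — equivalently,
they are spanned by a (6,6)-tight subgraph. For sparsity count ℓ = k = 6,
two tight subgraphs sharing a body merge into a tight subgraph, so
clusters are a vertex partition; and tight subgraphs are connected, so
unioning over adjacent mutually-rigid pairs recovers every cluster. The
decomposition is a matroid invariant of the multigraph: the test suite
shuffles edge processing order and checks the partition is unchanged, and
cross-checks both the independent-bar count and the partition against an
independent randomized rigidity-matrix rank oracle (random generic
placements, one random bar attachment per bar; probe-bar rank tests for
cluster membership).

Determinism: edges are processed in lexicographic (u, v, kind) order with
sorted adjacency in the pebble searches, so identical inputs give
bit-identical outputs.

## 4. Metrics

With atom-level cluster sizes `s_c` summing to `N`:

* **CCE** `= −Σ (s_c/N) ln(s_c/N) / ln N`, defined as 0 when `N = 1`.
  It is 0 iff one cluster and 1 iff all singletons; merging any two
  clusters strictly decreases it. The size-weighted (atom-level) variant
  was chosen over count-weighted because the decomposition is atomic and
  the weighted form is the one whose extremes match the stated [0, 1]
  interpretation; the function accepts any size vector, so a
  residue-level variant is a one-line wrapper.
* **ROP** `= max(s_c) / N`, the largest-cluster atom fraction in (0, 1];
  merging clusters never decreases it, and `ROP = 1 ⇔ CCE = 0`.
* **HBC** is the hydrogen-bond count from the detector above.

Exact numeric parity with any specific external implementation of
entropy/order-parameter scores is not claimed; the definitions satisfy
every stated qualitative property (range, extremes, monotonicity,
stability ordering between an ideal helix and an extended chain).

## 5. Statistical layer

* **Outlier sets** are two-sided by default: `|x − mean| ≥ k·sd` with
  `k = 2`, mean and sd over the whole ensemble. One-sided variants are
  available via `side`. Sample (n−1) standard deviations are used
  throughout the package for consistency with the pooled effect-size
  formula; at ensemble scale (10⁵–10⁶ rows) the distinction is
  immaterial. Under a normal null the two-sided 2σ outlier fraction is
  the tail mass ≈ 4.55%, which the acceptance checks recover.
* **Cohen's d** uses the unweighted pooled standard deviation
  `sqrt((s1² + s2²)/2)` — the classical form paired with group standard
  deviations, not the df-weighted pooled estimator. It is antisymmetric
  and scale-invariant; 0.2/0.5/0.8 are the usual small/medium/large
  benchmarks.
* **t-tests** default to the classical pooled-variance Student test
  (matching the pooled-sd effect size); Welch is available via
  `welch = TRUE`. No multiple-testing correction is applied by default —
  the pairwise comparisons reported are few and are read as effect
  descriptions, not a screening procedure; `p.adjust` can be applied
  downstream.
* **Frequency tallies** count occurrences: each outlier contributes both
  inserted residues (a homotypic pair contributes 2 to one residue) and
  both gaps, so totals are exactly twice the outlier count. The pair
  matrix is symmetric with homotypic pairs on the diagonal counted once
  per mutant. Top-k rankings break count ties lexicographically by pair
  label so results are reproducible.
* **Size-group rates** divide outlier membership by group membership
  within the ensemble (singles: either inserted residue in the class;
  pairs: both). An alternative normalization against the wildtype
  structure's residue-class counts is available behind
  `denominator = "wildtype"`; it changes the scale but not the
  within-metric ranking when the ensemble covers the full space, and the
  within-group fraction was preferred as the default because it is
  well-defined for pair groups and independent of the wildtype
  composition.

## 6. Synthetic data: what it emulates, and what it does not

`simulate_metric_ensemble()` stands in for the structure-generation stage
of an exhaustive scan. It enumerates the real annotation structure of the
space — positions, gaps, size groups, helix groups for a given helix
layout — and draws the metrics from normal noise around base means, with
planted additive group shifts expressed in sd units (so a plant *is* a
target Cohen's d). Defaults: HBC mean 5.5, sd 1.5 (a realistic
small-protein bond count with wide mutant variability, rounded to
integers and floored at 0); CCE and ROP mean 0.5, sd 0.1 (mid-range,

3 sd or more from their bounds so clipping to [0, 1] introduces
negligible truncation bias; the planted-recovery acceptance checks
confirm recovery within ±0.05 at full-space scale). The default
simulated protein is 46 residues with helices 7–17 and 23–30, the helix
layout of a small two-helix protein at crambin scale; at that size the
full space has 451,200 mutants and helix groups of 186,000 / 204,000 /
61,200.

One global seed drives a single RNG stream drawn in the fixed
lexicographic mutant order (generation is not parallelized), so the same
config yields a byte-identical table.

What the generator deliberately does **not** emulate: correlations
between the three metrics, spatial correlation along the sequence,
position-dependent effects within a group, heavy tails, or any coupling
between a mutant's residues and its metrics beyond the planted group
shifts. Passing statistical-layer tests on these ensembles therefore
demonstrates correct *inference arithmetic* (group construction, effect
recovery, calibration), not that real mutant metric distributions are
normal.

The structural generators build poly-alanine chains by natural-extension
reference frame placement with standard bond lengths (N–CA 1.458,
CA–C 1.525, C–N 1.329, C=O 1.231, CA–CB 1.521, N–H 1.01 Å) and ideal
dihedrals: α-helix φ = −57°, ψ = −47° (producing the i→i−4 hydrogen-bond
ladder: `n − 4` bonds for an n-residue helix) and extended
φ = −120°, ψ = 120° (producing none). Amide hydrogens are placed
analytically in the peptide plane anti to the carbonyl oxygen.

## 7. Problem sizes used in validation

The shipped checks run the pebble-game/rank-oracle comparison on 200
random frameworks of up to 8 bodies and 30 bars (with partition
comparisons on a subset), metric monotonicity on 1,000 random partitions,
planted-d recovery on three full 451,200-row ensembles, the null outlier
fraction on 10⁵ draws, and t-test calibration on 10⁴ null replicates —
sizes chosen so each property is measured with standard error well below
its tolerance while the whole suite stays interactive.

## 8. Known limitations

* The hydrogen-bond detector is geometric; counts differ from energy-based
  tallies, so HBC comparisons should stay within one detector.
* Residue templates cover the 20 standard amino acids; modified residues
  and HETATM ligands are excluded at parse time, and a structure's
  interaction network ignores waters and ions.
* The pebble game is exact for *generic* frameworks; special geometric
  coincidences (e.g. exactly parallel bars) that a generic model cannot
  express are not detected.
* Multi-model/multi-chain files are reduced to the first model and one
  chain; inter-chain contacts are out of scope.
* `read_pdb` ignores insertion codes in HELIX records (rare) and maps
  helix bounds through author residue numbering.
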