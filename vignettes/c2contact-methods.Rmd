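---
title: "Predicting C2 homodimer interface contacts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting C2 homodimer interface contacts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Problem

Given the structure of one chain of a C2-symmetric homodimer and a
multiple sequence alignment (MSA) of its family, predict which residue
pairs `(i, j)` are in contact *across* the dimer interface: residue `i`
of chain A within 8 Å (any heavy-atom pair) of residue `j` of chain B.
Because the chains are identical, the target is an `L x L` matrix over
monomer positions, and the diagonal pair `(i, i)` — residue `i` of one
chain touching its own copy across the two-fold axis — is a legitimate
candidate. If `(i, j)` is a contact, so is `(j, i)`, which dictates the
symmetrization conventions used throughout.

## Model

### Sequential features (L x 31)

- **PSSM (20).** Sequence-weighted amino-acid frequencies per column with
  a pseudocount (`pssm()`). Sequence weights down-weight redundancy:
  `w_m = 1 / |{m' : identity(m, m') > 0.7}|`, the same reweighting whose
  sum defines the effective depth `Meff`.
- **Secondary structure (8).** One-hot DSSP-style 8-state labels. An
  internal assigner (`secondary_structure()`) implements the
  Kabsch–Sander electrostatic hydrogen-bond criterion
  (cutoff −0.5 kcal/mol), n-turns, bridges, bends; output of an external
  DSSP run can be ingested instead.
- **Hydrophobicity (3).** Shrake–Rupley and Lee–Richards solvent
  accessibility per residue plus the Wimley–White interface scale.

### Pairwise features (L x L x 4)

1. **Intra-monomer distance map**, clipped at 50 Å and scaled to
   `[0, 1]`. The clip value matters only as "far"; interface-relevant
   geometry lives well below it, and clipping keeps the channel on the
   same numeric scale as the others.
2. **Docking map**: union of inter-chain contacts over the top `T` poses
   of an exhaustive C2 rigid docking scan (below).
3. **Raw coupling scores** from mean-field direct-coupling analysis.
4. **APC-corrected coupling scores.**

Every pairwise channel is symmetrized by averaging with its transpose;
labels are symmetrized by OR.

### Coupling engine

21-state mean-field DCA: reweighted single and pair frequencies with
pseudocount fraction λ = 0.5, covariance over the 20 non-gap states,
matrix inversion, zero-sum gauge per pair block, Frobenius norm of the
amino-acid sub-block. APC subtracts `mean_i * mean_j / mean`, which
exactly cancels a rank-one product background. Externally computed score
matrices can be loaded with `load_couplings()`.

### Symmetry-constrained docking

A C2 dimer is generated from the monomer by a 180° rotation. Axes are
sampled on a Fibonacci hemisphere with count `round(2*pi / theta^2)`
(573 axes at the default 6° interval); each rotation is
`R = 2 u u' - I`. For each rotation, shape complementarity over all
translations is computed with one FFT correlation using the complex-grid
trick (`surface + i*sqrt(penalty)*core` for both grids): the real part of
the correlation equals `sum(surface_a * surface_b) - penalty *
sum(core_a * core_b)` in a single pass. Retained translations are
projected onto the plane perpendicular to the rotation axis, which makes
every pose an exact two-fold. The docking map is the OR-union of
inter-chain contact maps of the top `T = 100` poses over all rotations.
Grid spacing is 1.2 Å with a 1.5 Å surface shell — fine enough that an
8 Å contact shift is resolved, coarse enough that the FFT grid stays
small.

### Network

The `full` preset is the production-scale architecture: six 1D
pre-activation residual blocks (filters 35–60, kernel 17) over the
sequential features; the 1D output `v` is expanded to pairwise maps by
outer concatenation `[v_i ; v_j]`, each plane symmetrized by transpose
averaging (so the expansion itself cannot break pair symmetry);
thirty-six 2D residual blocks (filter schedule
32/32/48/64/64/64/48/32/32, four blocks each, kernel 3×3, ELU
activations, batch normalization); a 1×1 sigmoid head. The predicted map
is symmetrized at inference. Logits are clamped at ±30 before the
sigmoid so probabilities are always strictly inside (0, 1), which the
loss requires. The `tiny` preset (two 1D and four 2D blocks of 16
filters) keeps the identical code path trainable in minutes on a CPU.

Forward and backward passes are written in base R (im2col convolutions
via BLAS matrix products); gradients are verified against finite
differences in the test suite.

### Loss and optimization

Contacts are rare (a few pairs out of `L(L+1)/2`), so training uses the
focal loss `FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t)` with α = 0.25,
γ = 1.5, reduced as the *mean* over unmasked pairs so the loss scale is
independent of chain length. Optimization is Adam (learning rate 1e-3,
batch size 1) with L2 decay 1e-4 applied to convolution weights only,
a reduce-on-plateau schedule (factor 0.2, patience 2, floor 1e-6), and
random 400-residue crops for long chains. Masked pairs (unobserved
residues) receive zero gradient.

### Baselines and evaluation

`dca_baseline()` ranks coupling scores over pairs whose intra-monomer
distance exceeds 12 Å — strong couplings at short range are explained by
the monomer fold, not the interface. Metrics: precision@n, top-L/K
precision (with `max(1, floor(L/K))` so short chains are defined),
accuracy rate (fraction of targets with a hit in the top n), and
accuracy order (rank of the first hit over `L(L+1)/2`, per mille).
`filter_poses()` stably promotes docking poses that satisfy a predicted
contact.

## The fixture generator

Real training data would require PDB-scale curation, homology search
databases, and GPU-days of training. The package instead generates its
own study conditions:

- `make_c2_dimer()` builds an exact C2 dimer in which a chosen set of
  residue pairs — and only those — form inter-chain contacts. The
  construction is verified at generation time (the computed contact map
  must equal the planted set). The planted partners are placed so their
  *intra*-monomer distance exceeds the 12 Å baseline filter, since a C2
  interface pair must be a candidate for the baseline too.
- `make_synthetic_msa()` plants covariation: background-i.i.d. columns,
  except planted pairs, which are jointly drawn from compatible residue
  couples (salt bridges, conservative substitutions) with a configurable
  strength.

What the generator emulates: the geometry of a two-fold interface, MSAs
with genuine joint column statistics, and end-to-end learnability of the
feature-to-contact mapping. What it does not emulate: PDB-scale
diversity, alignment gaps and phylogenetic correlation, resolution
artifacts, or realistic secondary-structure composition. The desk-scale
problem sizes (L ≈ 40, M ≈ 200–300, tiny network preset) are this
package's own choice for reproducible CPU-scale experiments; they are
not a claim about production-scale accuracy.

## Numerical choices

- Frequencies use pseudocount fraction λ = 0.5 (mean-field DCA
  convention); the covariance matrix is inverted densely, which is exact
  and fast for `L <= ~500` (20L × 20L).
- The FFT translation scan is validated against a brute-force
  direct-space correlation to 1e-6; top-T selection uses partial sorting
  with deterministic `(z, y, x)` tie-breaking.
- SASA defaults to 960 Shrake–Rupley points (closed-form sphere area
  reproduced within 2%); Lee–Richards slicing (0.25 Å) is an independent
  cross-check.
- All stochastic steps (fixtures, MSA generation, initialization, crops,
  shuffling) are seed-controlled and reproducible.

## Limitations

- The mean-field coupling engine is the simplest member of the DCA
  family; pseudo-likelihood methods score better on hard families.
- The docking stage assumes a rigid monomer and exact C2 symmetry; there
  is no flexibility or off-symmetry refinement, and no pose clustering
  or CAPRI-style model quality assessment.
- Training at the `full` preset is supported but not practical without
  substantial compute and, above all, a large curated training set, which
  the synthetic generator does not provide.
- The internal secondary-structure assigner approximates DSSP; residues
  lacking backbone atoms fall back to coil.
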