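# barreldyn

Comparative intrinsic dynamics of TIM-barrel folds from coarse-grained
normal modes.

The TIM-barrel — eight parallel β-strands closing into a barrel, each
flanked by an outer α-helix — hosts enzymes of wildly different function on
one conserved shape. `barreldyn` asks what that shape alone implies for
flexibility: it builds a Cα elastic network for each structure, extracts
its normal modes, and quantifies (i) per-residue flexibility, (ii) which
distant residue pairs move together, (iii) how similar two structures'
dynamics are on their structurally aligned core, and (iv) how cheaply the
barrel core and the helix bundle can perform idealized collective motions.
It is aimed at structural bioinformaticians comparing dynamics across folds
or validating structure alignments dynamically, and ships a synthetic
barrel generator so the whole pipeline runs with known ground truth and no
downloads.

## The model

Residues are point masses at their Cα positions interacting through
harmonic springs with distance-dependent stiffness (the Hinsen Cα force
field, nm units):

    k(r0) = a·r0 − b        for r0 < d        a = 8.6e5, b = 2.39e5
    k(r0) = c·r0⁻⁶          for r0 ≥ d        c = 128,   d = 0.4 nm

Normal modes are eigenpairs of the mass-weighted Hessian of the total pair
potential; the six rigid-body modes are excluded everywhere. From the modes
the package computes:

* **normalised fluctuations** `F_i = Σ_m ‖[d_m]_i‖²/λ_m` (theoretical
  B-factors);
* **deformation energies** — local strain of each residue relative to its
  neighbours, zero for rigid motion;
* **dynamic cross-correlations** `C_ij ∈ [−1,1]`, significance-filtered by
  percentile rank (95th) and spatial distance (≥ 8 Å; strand-focused
  variant: 97.5th, ≥ 4 Å), grouped into connected stick "objects";
* **Bhattacharyya coefficients** `BC ∈ (0,1]` between trace-normalised,
  rank-reduced mode covariances restricted to the gap-free columns of a
  multiple structure alignment (95% per-structure variance, 75% joint),
  with average-linkage clustering of the BC matrix;
* **overlap scores** `Ω_w(z) = Σ_m λ_m (z·v_m)²` against idealized unit
  displacements — rotation/translation of the β-barrel or α-bundle along
  its principal inertia axis, and vertical / horizontal / tilt / bend
  motions of individual helices. Low `Ω_w` = motion carried by soft modes.

## Worked example

```r
library(barreldyn)

barrel <- make_barrel(barrel_spec(seed = 1))   # synthetic (βα)8 fold
barrel$model
#> <ca_model> synthetic_barrel_seed1: 240 Calpha atoms, 1 chain(s), masses: residue

modes <- normal_modes(build_network(barrel$model))
modes
#> <mode_set> synthetic_barrel_seed1: 720 modes (6 trivial), masses: residue, d: deweighted-renormalized

f  <- fluctuations(modes)
st <- sse_residues(barrel$sse, "strand")
he <- sse_residues(barrel$sse, "helix")
lo <- setdiff(seq_len(n_atoms(barrel$model)), c(st, he))
sprintf("strands %.2f | helices %.2f | loops %.2f",
        mean(f$values[st]), mean(f$values[he]), mean(f$values[lo]))
#> "strands 0.36 | helices 0.60 | loops 2.34"

ov <- overlap_report(modes, barrel$model, barrel$sse)
subset(ov, sse %in% c("barrel", "bundle"))
#>               structure            motion    sse ordinal  omega_w
#>  synthetic_barrel_seed1    group_rotation barrel      NA 42.84623
#>  synthetic_barrel_seed1 group_translation barrel      NA 40.18127
#>  synthetic_barrel_seed1    group_rotation bundle      NA 23.09160
#>  synthetic_barrel_seed1 group_translation bundle      NA 17.50580
```

Read: the strand core fluctuates least and the loops most (profile is
unit-mean, so 0.36 means strands move at ~1/3 of the structure-wide
average); and both rigid-group motions of the barrel cost roughly twice the
Ω_w of the corresponding bundle motions — the helix bundle is the mobile
shell around a rigid core. Real structures enter the same pipeline through
`read_pdb_ca()` (chain / residue-range / altloc aware) and
`read_alignment()` (FASTA, `-` or `.` gaps), and `run_pipeline()` chains
every stage and writes TSV/Newick/PyMOL outputs plus a JSON run manifest.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the full study on synthetic
data, each writing its tables under `results/`:

1. `01_generate_structures.R` — reference barrel, 5-member perturbed
   family, gapped FASTA alignment, ground-truth JSON;
2. `02_normal_modes.R` — elastic networks, mode sets (text format),
   fluctuation/deformation profiles;
3. `03_correlations.R` — correlation matrix, distant significant pairs,
   strand-focused short-range pairs, PyMOL stick scripts;
4. `04_bc_comparison.R` — BC matrix over conserved columns, Newick
   dendrogram, sub-alignment sensitivity check;
5. `05_overlaps.R` — the 44-row Ω_w table (4 group motions + 5 motions × 8
   helices).

Run them in order: `for s in analysis/0*.R; do Rscript "$s"; done`

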