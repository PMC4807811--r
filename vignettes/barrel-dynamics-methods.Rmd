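---
title: "Methods: comparative intrinsic dynamics of barrel folds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative intrinsic dynamics of barrel folds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`barreldyn` characterises the intrinsic (equilibrium, harmonic) dynamics of
TIM-barrel-like protein folds from coarse-grained normal modes, and compares
those dynamics across structure families. This vignette is the package's own
account of the model, its conventions, and the choices made where several
conventions were defensible.

## The elastic network model

Each residue is a point mass at its C&alpha; position. Two residues at
equilibrium separation $r^0_{ij}$ (nm) interact through a harmonic pair
potential

$$V_{ij} = \tfrac{k_{ij}}{2}\,(\lVert r_{ij}\rVert - \lVert r^0_{ij}\rVert)^2,
\qquad
k_{ij} = \begin{cases} a\,r^0_{ij} - b, & r^0_{ij} < d\\
c\,(r^0_{ij})^{-6}, & r^0_{ij} \ge d\end{cases}$$

with the published C&alpha; force-field constants $a = 8.6\times10^5$ kJ
mol$^{-1}$ nm$^{-3}$, $b = 2.39\times10^5$ kJ mol$^{-1}$ nm$^{-2}$,
$c = 128$ kJ mol$^{-1}$ nm$^{4}$, $d = 0.4$ nm. All internal lengths are
nanometres precisely so these constants can be used verbatim; PDB
&aring;ngstr&ouml;ms are converted on read, and the 8 / 4 &Aring;
significance thresholds appear internally as 0.8 / 0.4 nm.

Two deliberate edge conventions:

* **No interaction cutoff by default.** The $r^{-6}$ decay localises the
  network physically; truncation is offered (`ff_params(cutoff=)`) purely as
  a speed knob and is off unless asked for.
* **Clamping.** The linear branch goes negative below
  $r \approx 0.278$ nm; such force constants are clamped to zero with a
  warning rather than admitting a negative spring. Distances that short do
  not occur in reasonable C&alpha; models; the clamp only fires on heavily
  perturbed synthetic copies.

The normal modes are the eigenpairs of the mass-weighted Hessian
$M^{-1/2} H M^{-1/2}$ of the total potential, assembled analytically from
the per-pair rank-one blocks $k\,\hat u \hat u^{\mathsf T}$. Masses default
to full amino-acid residue masses lumped at the C&alpha; (a unit-mass switch
exists, `ca_model(..., masses = "unit")`, and the convention is recorded in
every `mode_set`). Because the absolute eigenvalue scale depends on that
choice, every descriptor the package reports is either normalised or used
comparatively; only the raw $\Omega_w$ scores carry the energy scale, and
they are only ever compared within one mass convention.

A connected model must have exactly six zero modes (rigid translations and
rotations). The trivial-mode threshold is $10^{-9}\,\lambda_{\max}$, which
separates the rigid-body cluster from the softest internal mode by several
orders of magnitude for 150-800-residue models in double precision. More
than six near-zero modes is diagnosed as disconnection (components are
named) or as degenerate geometry — a strictly collinear or planar network
has extra harmonic zero modes, which is why the synthetic sheet fixtures in
the tests are pleated.

**Displacement conventions.** The raw eigenvectors $v_m$ live in
mass-weighted coordinates. Cartesian displacement fields $d_m$ are obtained
by dividing componentwise by $\sqrt{m_i}$ and renormalising to unit length;
fluctuations and deformation energies use $d_m$, while correlations and
overlap scores use $v_m$. Both conventions are recorded in the `mode_set`
and its text serialisation, and the renormalisation can be switched off
(`normal_modes(..., renormalize = FALSE)`). Under unit masses the two spaces
coincide, which is how the test suite pins both against a single
pseudo-inverse covariance oracle.

## Per-residue descriptors

* **Fluctuations** $F_i = \sum_m \lVert [d_m]_i\rVert^2 / \lambda_m$ over
  non-trivial modes — the diagonal of the mode covariance ("theoretical
  B-factors"). The plotted profile is normalised; the default scheme
  divides by the profile mean (unit-mean preserves shape and makes profiles
  of different-sized structures comparable), with unit-sum and raw variants
  selectable. The scheme is written into the TSV header.
* **Deformation energies** measure local strain:
  $E_i = \frac{N}{\sum_j \lVert d_j\rVert^2}\cdot \tfrac12 \sum_j k_{ij}
  \big((d_i - d_j)\cdot \hat u_{ij}\big)^2$, averaged over non-trivial
  modes. Rigid translations and infinitesimal rotations give exactly zero.
  Alongside the raw profile a min-max copy in $[0,1]$ is emitted, matching
  a bounded colour scale for structure painting.
* **Correlations** $C_{ij}$ are the normalised 3&times;3-block traces of the
  mode covariance $\sum_m \lambda_m^{-1} v_m v_m^{\mathsf T}$, i.e. the
  expected inner product of the two residues' displacements, in $[-1,1]$
  with unit diagonal.

**Significance filtering.** Correlations of interest are selected by rank,
not by a hard value: the threshold is the nearest-rank percentile (no
interpolation — deterministic across platforms) of the multiset
$\{|C_{ij}|, i<j\}$, computed before any distance filtering. Retained pairs
must also be at least 8 &Aring; apart in the input configuration, removing
backbone-neighbour correlations; ties at either threshold are kept
($\ge$, not $>$). The strand-focused variant tightens the score rank to
97.5 and relaxes the distance floor to 4 &Aring; (the C&alpha; spacing of
adjacent strands), then keeps only pairs touching an annotated strand.
Retained pairs are partitioned into "objects": connected components of the
graph whose vertices are residues and whose edges are retained pairs, the
unit in which correlation networks are drawn as sticks.

## Comparing dynamics across structures

Structures are compared on the gap-free ("conserved") columns of a multiple
alignment; every sub-alignment recomputes its conserved set, because
restricting to fewer sequences can only free columns and reusing a
superset's column set silently changes the comparison.

For each structure a covariance $\sum_{m\le n} \lambda_m^{-1} v_m
v_m^{\mathsf T}$ is restricted to the conserved-column atoms and divided by
its trace. The mode count $n$ retains 95% of the "variance", measured as
cumulative $\lambda^{-1}$ over non-trivial modes — the natural reading when
variance is covariance trace, chosen here because the source convention is
not spelled out; the fraction is configurable (`bc_config`). The
Bhattacharyya coefficient of two such covariances is

$$\mathrm{BC} = \exp\!\Big(-\tfrac12 \ln \frac{|\tfrac12(\tilde A + \tilde
B)|}{\sqrt{|\tilde A||\tilde B|}}\Big)$$

after projecting both onto the $s$ leading eigenvectors of their average
that hold 75% of its variance. All determinants are evaluated as eigenvalue
log-sums: trace-normalised matrices at realistic dimension have
determinants far below double-precision underflow, so raw `det()` is never
used; eigenvalues below machine epsilon are clamped there. BC is 1 for
identical effective dynamics and decreases smoothly with structural
divergence (the tests assert monotonicity in perturbation noise over
seeds). Families of BC scores are clustered by average-linkage
agglomeration on $1-\mathrm{BC}$ (linkage unspecified upstream; average is
the default and is recorded in output metadata), with the dendrogram
emitted as Newick.

## Idealized displacements and the overlap score

Collective motions are probed by unit 3N vectors that encode one named
motion of one SSE group and are zero elsewhere:

* **Group rotation / translation** about / along the group's principal axis
  of inertia (smallest moment = long axis, sign fixed toward the
  C-terminal end of the selection). A near-degenerate inertia spectrum
  (relative gap below $10^{-6}$) is flagged with a warning: for a squat
  helix bundle the smallest-moment axis is genuinely in-plane, and the
  package reports that honestly rather than silently substituting the
  barrel axis.
* **Per-helix motions**: *vertical* (along the helix's own axis),
  *horizontal* (radial: structure centre of mass to helix centre of mass,
  orthogonalised against the barrel axis), *tilt* and *bend_N/bend_C*
  (radial displacement ramping linearly from the helix midpoint; tilt moves
  the two halves oppositely, bends move one half only). Halves split at the
  median residue with the extra residue going to the N-half. The ramp
  shape, half-split rule and radial bend direction are deterministic
  stand-in conventions — the source description of these vectors is not
  fully public — and they are isolated in one constructor
  (`helix_displacement`) so alternatives are drop-in swappable.

The overlap score is $\Omega_w(z) = \sum_m \lambda_m (z\cdot v_m)^2$ over
non-trivial modes: the energetic cost of imposing $z$. For any unit $z$
orthogonal to the trivial span this equals the Hessian quadratic form
$z^{\mathsf T} (M^{-1/2} H M^{-1/2}) z$, which the tests exploit as an
independent identity. Geometric constructors build $z$ in Cartesian space;
`omega_w` converts to the mass-weighted space of the eigenvectors and
renormalises before scoring (a `space` argument lets callers supply either
convention).

## The synthetic generator

`make_barrel` builds a parametric (&beta;&alpha;)$_8$ fold: eight parallel
strands (rise 0.33 nm/residue) on an inner cylinder, eight ideal
&alpha;-helical C&alpha; traces (rise 0.15 nm, 100&deg; per residue, 0.23 nm
trace radius) running antiparallel on an outer cylinder, joined by
quadratic B&eacute;zier loops sampled at equal arc length whose control
point bulges outward until consecutive residues are at least 0.36 nm apart.
The defaults — strand length 8, helix length 14, loop length 4, barrel
radius 0.6 nm (inter-strand spacing ~0.46 nm, as in parallel sheets),
helix axes at 1.35 nm — give a 240-residue fold whose dimensions sit in the
range of real barrel domains, and were fixed once as the package's study
conditions. Any two atoms closer than 0.25 nm trigger seeded-jitter
regeneration (bounded retries).

`make_family` derives homologues by Gaussian coordinate noise (per-member
&sigma;, default study conditions 0.01-0.05 nm — the range over which BC
spans high to moderate similarity) plus loop-confined residue deletions
(rate 0.08), so SSE annotations stay valid for every member, gaps land
where real families are diverse, and the alignment's gap-free column count
is known exactly by construction.

What the generator does *not* emulate: side chains, hydrogen-bond
anisotropy, strand tilt/shear, sequence realism, or oligomeric interfaces.
Passing tests therefore demonstrate the correctness of the machinery and
the robustness of shape-driven signatures (strand < helix < loop
flexibility; barrel core stiffer than the helix bundle under rigid-group
probes), not quantitative agreement with any real structure. Two synthetic
artefacts worth naming: the generated bundle is oblate, so its inertia
axis is in-plane (flagged degenerate, see above), and the uniform spring
geometry makes the *helices*, not the strands, carry the highest local
deformation energies even though the strand/helix/loop fluctuation
ordering matches real folds.

## Numerical choices

* Hessian assembly is exact (rank-one pair blocks), symmetrised, and
  validated against a central finite-difference of the potential at
  $10^{-6}$ nm steps to relative error $10^{-5}$.
* Eigendecomposition uses the symmetric path (`eigen(symmetric = TRUE)`);
  reported eigenvalues ascend, and negative values beyond
  $-10^{-9}\lambda_{\max}$ abort (not at a minimum).
* Percentiles are nearest-rank; hierarchical-clustering ties break by
  label order; the conserved-column rule is "gap-free in every sequence of
  the alignment under consideration".
* Problem sizes in the tests and acceptance script (240-residue default
  barrels, 152-residue family members, 10-15-atom finite-difference
  fixtures, 3-member families over 10 seeds) were chosen so each property
  runs in seconds while the asserted orderings remain stable across seeds.

## Known limitations

* Harmonic, C&alpha;-only, solvent-free: absolute scales are not physical
  observables; only normalised profiles and within-convention comparisons
  are meaningful.
* The per-helix displacement conventions are explicit stand-ins (above);
  results driven by ramp shape or half-splitting should be checked against
  the swappable constructor.
* `read_pdb_ca` handles PDB only (no mmCIF) and takes the first-listed or
  highest-occupancy altloc; structures whose residues lack C&alpha; atoms
  are rejected with the offenders listed rather than silently dropped.
* Alignments are consumed, never computed: a structure aligner (e.g.
  MUSTANG-class tools) sits upstream of `read_alignment`.
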