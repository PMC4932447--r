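---
title: "Essential collective dynamics: models, numerics and design choices"
author: "ecdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essential collective dynamics: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdyn)
```

## The analysis model

Essential collective dynamics (ECD) treats a protein trajectory segment as a
time series in the 3N-dimensional configuration space of a chosen atom
selection and derives *persistent* motion correlations from the principal
components of its covariance matrix,

$$C_{ij} = \langle (X_i(t) - \langle X_i\rangle)(X_j(t) - \langle
X_j\rangle)\rangle, \qquad i, j = 1,\dots,3N,$$

estimated over a subnanosecond segment.  The eigenvectors
$\vec E^k = (E^k_1,\dots,E^k_{3N})$, ordered by decreasing eigenvalue, serve
as essential coordinates.  For each atom $i$ a dimensionless *image*

$$\vec r_i = \left(E^1_{i,x}, E^1_{i,y}, E^1_{i,z},\; \dots,\;
E^{k_{\max}}_{i,x}, E^{k_{\max}}_{i,y}, E^{k_{\max}}_{i,z}\right)$$

collects the atom's triplets of eigenvector components over the first
$k_{\max}$ components.  Distances in image space are the descriptors:

* pair correlations $d_{ij} = |\vec r_i - \vec r_j|$ — small values mean
  atoms $i$ and $j$ move coherently, regardless of their separation in
  sequence or space;
* main-chain flexibility $F_{C\alpha}(i) = |\vec r_i^{\,C\alpha} -
  \vec\varepsilon\,|$ with $\vec\varepsilon$ the centroid of the C$\alpha$
  images only — low values mark residues locked to the collective main-chain
  motion.

Eigenvector orthonormality implies the conservation law
$\sum_i |\vec r_i|^2 = k_{\max}$, which the tests enforce together with
$\mathrm{tr}\,C = \sum_k \lambda_k$; both act as global self-checks on every
analysis.

Because a single short segment is noisy, descriptors are computed per
segment and averaged: the standard protocol cuts the trailing 10 ns of a
production run into fifty 200-ps segments (2000 conformations each at 0.1-ps
spacing), analyses each with $k_{\max} = 20$ heavy-atom principal
components, and reports the elementwise mean with the segment-to-segment
standard deviation.  These defaults are wired into `ecd()` but every number
is a visible argument.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `selection` | `"heavy"` | atoms entering the PCA (hydrogens excluded) |
| `k_max` | 20 | principal components per segment; 10–30 typically capture 90–95 % of an equilibrated segment's displacement variance |
| `window` | 200 ps | segment length |
| `take_last` | 10 ns | trailing analysis window |
| `superpose` | `TRUE` | rigid-body fit of every frame onto the segment mean before the PCA |

## Numerical choices

**Superposition.**  Whether rigid-body motion should be removed before the
covariance is estimated is a genuinely open choice: the descriptors are
already invariant to a rotation applied uniformly to *all* frames (the
images rotate triplet-wise, preserving image distances), but frame-to-frame
tumbling inflates the apparent covariance.  The package follows standard
essential-dynamics practice and superposes each frame onto the segment mean
(one fit–remean–refit iteration) by default, exposing `superpose = FALSE`
for sensitivity checks.  On synthetic harmonic trajectories, where
rigid-body drift is absent by construction, the unfitted analysis is exact
and is what the stationarity tests use; with fitting enabled, per-segment
references perturb large-amplitude floppy modes measurably, which is a
property of the superposition protocol, not a numerical defect.

**Covariance normalisation.**  Plain time average (population, $1/T$), not
$1/(T-1)$; immaterial at $T = 2000$ but fixed for bit-reproducibility.

**Eigenvector sign and degeneracy.**  Each eigenvector is flipped so its
largest-magnitude component is positive, with magnitude ties (exact or
within floating-point noise) broken to the lowest index.  Within a
numerically degenerate eigenvalue cluster the sign-fixed eigenvectors are
ordered lexicographically.  A global sign flip reflects all triplets
simultaneously and thus never changes $d_{ij}$ or $F_{C\alpha}$ (tested).
When `k_max` cuts through a degenerate cluster a warning is emitted, since
descriptors then depend on an arbitrary in-cluster rotation; descriptors
built from complete clusters are stable.

**Large selections.**  The covariance of $3N \le \max(1200, T)$ degrees of
freedom is eigendecomposed densely.  Beyond that the spectrum is obtained
from the $T \times T$ Gram matrix of centred frames — mathematically
identical for a rank-deficient sample covariance (the tests verify agreement
to $10^{-8}$) — and only the leading eigenvectors are materialised; the
3N×3N matrix is never stored.

**No weighting.**  Images use raw eigenvector components; no mass or
eigenvalue weighting anywhere.

## The synthetic-trajectory generator

Real MD at the scale behind published α-synuclein oligomer studies (60–100
ns, solvated, all-atom) is out of reach on a desk, so the package ships a
generator whose outputs have *known* statistics.  Sites sit on the C$\alpha$
atoms of a construct and interact through isotropic springs,
$V = \tfrac12 \sum_{(i,j)} k_{ij}\,|\vec u_i - \vec u_j|^2$, so the Hessian
is the spring-graph Laplacian acting identically on the three axes and its
null space is exactly the three rigid translations for a connected graph
(with the collinear reference geometries used here, an anisotropic bond-
vector network would be singular beyond the six rigid-body modes, which is
why the isotropic form is used).  The stationary covariance is the closed
form $kT\,H^{+}$ — the oracle for every sampling test.

The dynamics are overdamped Langevin,
$\gamma\,\mathrm d\vec u = -H \vec u\,\mathrm dt + \sqrt{2 kT \gamma}\,
\mathrm dW$.  Rather than an Euler–Maruyama discretisation, each Hessian
mode is advanced with the exact Ornstein–Uhlenbeck transition kernel and
started from the stationary distribution: sampling is then unbiased at any
step size and cannot diverge, so observed deviations from the closed form
are pure Monte-Carlo error.  The `burn_in_frames` argument is retained for
protocol compatibility but is redundant under the stationary start.

Architecture is planted explicitly: *rigid blocks* (dense springs, default
$k_\text{block} = 2000$ kJ mol⁻¹ nm⁻², all pairs within 10 Å), *linkers*
(chain-sequential springs, $k_\text{linker} = 40$), and *inter-chain
couplings* (each residue of a range tethered to its spatially nearest
partner in the paired range).  Non-C$\alpha$ heavy atoms of the construct
ride rigidly with their residue's site plus small isotropic jitter
(sd 0.005 nm) — a fixture feature that exercises the all-heavy-atom PCA
path, not physics.

The reference study condition (`default_dimer_model()`) is an HT2 dimer of
the packaged 140-residue α-synuclein sequence at 14 Å separation with blocks
1–60 and 75–140, linker 61–74 and an NAC-range (61–95) inter-chain coupling
at $k = 400$; $kT = 2.577$ kJ mol⁻¹ corresponds to the 310 K simulation
temperature of the motivating studies.  Two calibrations were fixed from the
closed form at design time: the stiffness contrast was chosen so the
stationary spectrum reproduces the 90–95 % variance coverage by ~20
components that equilibrated protein segments show (the closed-form value
for the default plan is 97 %, leaving headroom for finite-segment
sampling), and the drag $\gamma = 1.2$ kJ mol⁻¹ nm⁻² ps makes the slowest
network relaxation time $\gamma/\lambda_{\min} \approx 10$ ps, well inside a
200-ps segment, so the generator emulates an *equilibrated* trajectory
segment as the analysis presumes.

What the generator does **not** emulate: solvent friction memory,
anharmonicity, folding/unfolding transitions, or secondary-structure
formation.  Passing tests therefore demonstrate that the analysis machinery
recovers known correlation structure from stationary Gaussian fluctuations —
not that it would detect any particular feature of real MD data.

## Construct geometry

The unfolded starting constructs place each chain's backbone N–C$\alpha$–C
trace collinearly on its axis with standard bond lengths (backbone angles
opened to 180°), carbonyl oxygens and idealized heavy side chains extending
off-axis.  Making the C$\alpha$ trace exactly axial is a deliberate
trade-off against literal extended-chain dihedrals: the chain axis is then
exact by construction, the 14 Å axis-to-axis separation is reproduced to
$10^{-6}$ Å, the 180° roll distinguishing the "#2" dimer variants fixes the
backbone and moves only off-axis atoms, and the antiparallel flip maps
residue $i$ of one chain exactly opposite residue $n+1-i$ of the other.
Side-chain heavy atoms are generated from a per-residue bonded tree with a
generic 1.5 Å step — topologically correct atom counts and distinct
positions, not rotamer-accurate geometry; downstream analyses only require a
plausible, deterministic multi-chain scaffold.  The tetramer stacks two base
dimers (HT2 by default) orthogonally to the dimer separation, giving a 2×2
bundle with equal nearest-neighbour separations; the published six-pair
HH/HT classification emerges from axis directions alone.  Pair alignment is
classified by the sign of the dot product of N→C axis directions, with
near-perpendicular axes rejected as ambiguous.

## Secondary-structure statistics

The package never assigns secondary structure; it consumes per-frame
DSSP-style code tables (8-letter alphabet, blanks/`-`/`~` read as coil).
Occupancy is computed per residue and per class over a trailing window, and
stability is thresholded strictly: β-strand (E) occupancy must exceed 0.80,
helix occupancy (H, G and I separately) must exceed 0.50 — an occupancy of
exactly 80 % or 50 % is *not* stable, reading "more than X % of the time"
literally.  The per-residue reading of the β criterion (rather than
requiring all residues of a sheet to be simultaneously paired) is a
documented choice.  Stable flags are reported as maximal contiguous residue
runs and can be annotated with named regions (defaults: N-terminal 1–60,
NAC 61–95 with core 71–82, C-terminal 96–140).

## Chain-pair views

Flexibility profiles of a chain pair are overlaid after reversing the second
chain's residue axis for head-to-tail pairs and shifting it by an integer
offset.  The published presentation chooses the shift "by a certain number
of residues depending on which residues are in close proximity"; the package
formalises this as the offset minimising the mean inter-chain
C$\alpha$–C$\alpha$ distance between axis-paired residues in the construct's
reference geometry, with ties resolved toward the smallest magnitude.  A
planted 10-residue stagger is recovered exactly (tested).  The underlying
flexibility values are never modified by the view.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale, chosen to keep each check well inside interactive runtimes
while leaving the statistics decisive: hand-checkable two-atom segments for
the closed forms; a 4-site chain (50 000 frames) and a 30-site
block-and-linker chain (100 000 frames) against the stationary closed form;
a two-chain, 40-residue planted-architecture model (10 000 frames) for
parameter recovery; a 16-residue chain over 10 ns of 0.1-ps frames for the
fifty-segment averaging protocol; and the full 280-residue, ~2000-heavy-atom
dimer for one 200-ps segment of the heavy-atom PCA.  Every stochastic
result is seeded and bit-reproducible; `run_pipeline()` regenerates every
numeric artifact identically from its resolved YAML configuration and seed
(stage wall times go to a separate log outside the determinism contract).

## Known limitations

* No dynamic-domain segmentation of the correlation maps; C$\alpha$
  pair-correlation maps only (no side-chain maps).
* XTC trajectories are not read directly (no R reader available); use
  multi-model PDB or DCD.
* PDB insertion codes are rejected; alternate locations keep the first
  occurrence.
* The harmonic generator produces stationary fluctuations about a fixed
  reference — never conformational transitions — so occupancy statistics on
  synthetic data are only exercised through hand-written code tables.
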