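# ecdyn — essential collective dynamics analysis of MD trajectories

`ecdyn` implements essential collective dynamics (ECD) analysis for
molecular-dynamics trajectories of proteins, with α-synuclein
monomer/dimer/tetramer systems as the motivating application.  It is aimed at
structural bioinformaticians who want to extract *persistent* correlations of
atomic motion from short, subnanosecond trajectory segments rather than from
a single long simulation.

## The method

A trajectory segment of an N-atom selection is a time series in
3N-dimensional configuration space, X(t) = (X₁(t), …, X₃ₙ(t)).  The analysis
proceeds as:

1. **Segment covariance** — C_ij = ⟨(X_i(t) − ⟨X_i⟩)(X_j(t) − ⟨X_j⟩)⟩ over
   the frames of one subnanosecond segment (plain time average).
2. **Principal components** — eigenvectors Eᵏ of C, ordered by decreasing
   eigenvalue.  Around 10–30 components typically capture 90–95 % of the
   total displacement variance of an equilibrated segment.
3. **Projected images** — for each atom i, the image r_i concatenates the
   triplets (Eᵏ_{i,x}, Eᵏ_{i,y}, Eᵏ_{i,z}) of the atom's x, y, z eigenvector
   components over the first k_max principal components (default 20).
4. **Descriptors** —
   * pair correlations d(i,j) = |rᵢ − rⱼ| (dimensionless; small values mean
     the two atoms move coherently),
   * main-chain flexibility F_Cα(i) = |rᵢ − ε|, where ε is the centroid of
     all Cα images (low = strongly coupled to the collective main-chain
     motion).
5. **Segment averaging** — descriptors are averaged over fifty 200-ps
   segments cut from the trailing 10 ns of a production trajectory, with the
   segment-to-segment standard deviation retained.

The package also provides: a deterministic builder for unfolded
monomer/dimer (HH1, HH2, HT1, HT2)/tetramer starting constructs with
head-to-head / head-to-tail chain-pair classification; a harmonic-network
overdamped Langevin generator of synthetic fluctuation trajectories whose
stationary covariance is known in closed form (kT × pseudo-inverse of the
spring-graph Laplacian) — the oracle used throughout the tests; mean
shortest-distance maps; RMSD traces; and secondary-structure
occupancy/stability statistics (stable β: E occupancy > 80 %; stable
α/3₁₀/π helix: > 50 %) from externally assigned DSSP-style code tables.

## Worked example

Simulate 400 ps of the default synthetic study system — an HT2 α-synuclein
dimer (14 Å axis separation) carrying two rigid blocks per chain (residues
1–60, 75–140), a flexible linker (61–74), and an inter-chain coupling across
the NAC regions — then run the segment-averaged ECD analysis:

```r
library(ecdyn)

model <- default_dimer_model()
trj   <- simulate(model, seed = 42, n_frames = 4000, frame_interval = 0.1,
                  satellites = FALSE)          # C-alpha sites
fit   <- ecd(trj, selection = "calpha", k_max = 20,
             window = 200, take_last = 400)    # two 200-ps segments
summary(fit)
```

```
essential collective dynamics analysis
  2 segment(s) of 200 ps; k_max = 20; PCA selection: calpha
  variance captured by top 20 PCs: mean 95.5% (range 95.4-95.6%)
  chain A: F in [0.153, 0.703]; most rigid residue 107 (ALA),  most mobile residue 72 (THR)
  chain B: F in [0.155, 0.702]; most rigid residue 105 (GLU),  most mobile residue 72 (THR)
  pair correlations d_ij: median 0.334, min 0.008, max 1.121
```

The 20 leading principal components carry 95.5 % of the displacement
variance, and the flexibility profile recovers the planted architecture: the
most mobile residues (F ≈ 0.70 at residue 72) sit in the flexible linker,
while block residues are rigid — mean F is 0.50 over the linker versus 0.22
over the blocks.  `plot(fit, type = "flexibility")` and
`plot(fit, type = "map")` draw the profile and the d_ij heat map (chain-pair
quadrants separated by marker lines).

The same descriptors apply unchanged to real trajectories read with
`read_trajectory()` (multi-model PDB, or DCD plus a PDB topology), and
`run_pipeline("run.yaml")` drives the whole
construct → simulate → analyse → report chain from a single seeded YAML
configuration (see `inst/extdata/example_run.yaml`).

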