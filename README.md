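# hingelatch

Trajectory analysis for substrate-mediated allostery in ligand-bound
enzymes, built around the *hinge–latch* picture of binding: a peptide
substrate is pinned in its pocket by a small set of hydrogen bonds, the
receiving domain swings about a hinge between an open and a closed
orientation, and the substrate itself closes the latch that couples the
two. The package grew out of the analysis methodology used for the
bacterial oligosaccharyltransferase PglB, where the difference between a
threonine and a serine at the +2 position of the acceptor sequon decides
whether the periplasmic domain stays closed over the bound peptide.

It is a library for molecular-dynamics post-processing, for people who
have multi-replica trajectories of a ligand-bound protein and want to
quantify:

- **Hydrogen-bond state** — geometric H-bond detection (donor–acceptor
  distance < 3.5 Å, D–H–A angle 130–180°), per-bond occupancies with
  across-replica spreads, joint occupancies of bond subsets, and a
  hysteretic three-state classifier (fully bound / partially bound /
  unbound) driven by two groups of bonds with a persistence window
  ("lost for > 5 ns"), plus the four-distance termination metric that
  flags complete dissociation (sum > 80 Å).
- **Rigid-body geometry** — Kabsch superposition, stable-core
  identification by clustering the inter-residue distance-fluctuation
  matrix, time-averaged and most-populated structures (RMSF into the
  B-factor column), Cα–Cα distance-difference maps with per-domain block
  means, a hinge scan that locates the pivot of a domain motion by
  correlating each mobile residue's displacement with its distance from
  candidate residues, and latch-distance histograms.
- **Energetics** — exact pairwise Coulomb + Lennard-Jones interaction
  energies between atom groups (`E = k_e q_i q_j / r + ε[(r_m/r)^12 −
  2(r_m/r)^6]`), per-residue decompositions and condition differences,
  an optional 15 Å centre-of-mass prefilter, and jack-knife sampling
  checks.
- **Collective dynamics** — dynamic cross-correlation matrices of Cα
  fluctuations, Cartesian PCA with analytic variance accounting, RMSIP
  subspace comparison, projection densities, leave-one-replica-out PCA.
- **Allosteric networks** — residue graphs with edges where |C_ij| ≥ 0.7
  and weights −ln|C_ij|, greedy-modularity communities, community-level
  summary graphs (radius N_i/3; edge weight −ln|max C_ij|, divided by 4
  in the structure-overlay variant), degree and betweenness, k-shortest
  suboptimal paths between residue sets, and path-fraction statistics.

A first-class **synthetic-ensemble generator** (`synthetic_spec()`,
`simulate_ensemble()`) produces multi-replica ensembles with known ground
truth — programmed H-bond schedules, a rigid hinge driven by an
Ornstein–Uhlenbeck angle, blocks of correlated motion, scripted
unbinding events, Gaussian noise — so every estimator in the package is
validated by parameter recovery, not by eye.

## Worked example

A two-condition benchmark: a "tight" system with high bond occupancies
and a closed hinge versus a "loose" one with low occupancies and an
open, more mobile hinge.

```r
library(hingelatch)

spec <- synthetic_spec(n_replicas = 3, n_frames = 600, dt = 0.1, seed = 7)
sim  <- simulate_ensemble(spec)
sim$ensemble
#> ensemble: 3 replicas, 1800 total frames, 390 atoms

traces <- detect_hbonds_ensemble(sim$ensemble, sim$truth$hbonds)
hbond_probability(traces, frame_mask = lapply(sim$ensemble$trajectories,
                                              frames_in, from_ns = 5))
#>     label group  mean     sd n_frames
#> pA1   pA1     A 0.837 0.0292     1650
#> pA2   pA2     A 0.919 0.0246     1650
#> pA3   pA3     A 0.768 0.0845     1650
#> pB1   pB1     B 0.304 0.1494     1650
#> pB2   pB2     B 0.932 0.0433     1650
#> pB3   pB3     B 0.740 0.1161     1650
```

The `mean` column is the fraction of post-equilibration frames in which
each bond is formed (here recovering the programmed occupancies 0.83,
0.91, ...); `sd` is the spread of the per-replica means. Classifying the
binding state and feeding bound frames to the geometry stages:

```r
binding <- lapply(traces, classify_binding, persistence = 5)
table(binding$r1$state)
#> FULLY_BOUND
#>         600
```

The full pipeline (simulate → H-bonds → binding → geometry → energetics
→ PCA/correlation → networks → report) runs from one configuration list
and writes TSV/PDB/GraphML outputs plus a hashed manifest:

```r
report <- run_pipeline(config, out_dir = "out", seed = 7)
#> [simulate] 2 condition(s): tight, loose
#> [bind] bound frames: tight 1650, loose 1407
#> [pca] PC1 97.8%, PC2 0.3% of variance
#> [network] edges: tight 307, loose 225
```

In this benchmark the loose condition shows the full signature of a
destabilised substrate: the three pocket bonds are simultaneously
maintained in 53% of tight bound frames but only 22% of loose ones, the
latch distance distribution broadens (SD 0.33 Å vs 0.59 Å), the mean
interdomain Cα–Cα distance opens by ≈ 0.3 Å per residue pair, and the
correlation network loses every suboptimal path between the peptide and
the coupled core at the 0.7 threshold (500 paths vs 0).

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R` (`Rscript run_pipeline.R --config
config.yaml --out DIR --seed 7`).

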