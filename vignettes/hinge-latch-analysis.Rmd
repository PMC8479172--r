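---
title: "Hinge-latch trajectory analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hinge-latch trajectory analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingelatch)
```

## The problem this package addresses

Single-subunit oligosaccharyltransferases such as *Campylobacter lari*
PglB glycosylate an asparagine inside the sequon N-X-S/T. In the bound
state the acceptor peptide is pinned between a membrane-embedded
transmembrane (TM) domain and a periplasmic (PP) domain. The working
mechanical picture is a *hinge-latch*: the PP domain swings about a
hinge at the domain junction between an open and a closed orientation;
a handful of residues (the WWD motif, the EL5 C-terminus, a buried
isoleucine) form the latch; and the +2 side chain of the peptide itself
is the pin that keeps the latch shut. Whether the pin holds is read out
in four coupled observables: hydrogen-bond occupancies, domain
geometry, interaction energies, and the residue correlation network.

`hingelatch` implements that entire readout as a reusable pipeline. No
molecular dynamics engine is included or required: the package consumes
a structure (PDB), replica trajectories (DCD or a documented plain-text
format), and a configuration; or it simulates its own synthetic
ensembles with known ground truth for validation.

## Hydrogen bonds and the binding-state machine

A hydrogen bond is present in a frame when the donor-acceptor distance
is below 3.5 Å and the donor-hydrogen-acceptor angle, measured at the
hydrogen, lies in (130°, 180°). Bonds with chemically equivalent
acceptors (Asp Oδ1/Oδ2, Glu Oε1/Oε2) count as formed when *any*
acceptor qualifies, and the recorded distance is the minimum over the
set — occupancies of such bonds are combined probabilities.

Binding is classified from six bonds split into two groups: three
pocket bonds (group A) whose joint loss defines partial unbinding, and
three retention bonds (group B) that hold the peptide loosely
thereafter. The classifier is a hysteretic three-state machine:

* start `FULLY_BOUND` (trajectories begin from the bound pose);
* `UNBOUND` once **all six** bonds have been simultaneously absent for
  strictly longer than the persistence time (default 5 ns), absorbing;
* `PARTIALLY_BOUND` once **all three group-A** bonds have been
  simultaneously absent for strictly longer than the persistence time.

The rule table leaves two situations open, and we resolved both in
favour of a monotone, hysteresis-consistent reading. First, the state
when group A has been lost beyond the window while group B happens to
be absent *at that instant*: we do not gate the partial transition on
instantaneous group-B presence, because the unbound rule (checked
first) already covers the case where group B has also been lost beyond
the window — so when the partial transition fires, group B has
necessarily held within the window. Gating on the instant would also
break a desirable invariant: adding occupancy to a trace could then
*demote* a frame (an added B bond creating an earlier
fully-to-partially transition), whereas under the implemented rule
adding occupancy can only delay transitions. Second, re-binding:
brief group-A losses shorter than the window never leave
`FULLY_BOUND`, but once `PARTIALLY_BOUND` is entered the state stays
there by default even if group A returns — stable rebinding is treated
as something to detect, not assume. `allow_rebinding = TRUE` restores
the permissive behaviour.

Time handling: "lost for more than `persistence`" is evaluated as
(run length in frames) × dt > persistence, strictly. Frame indices in
the R API are 1-based throughout, the native R convention. The first
50 ns of each replica are excluded from statistics by default
(`frames_in(traj, from_ns = 50)`, a configuration knob) to allow for
structural equilibration; the synthetic benchmarks use shorter
exclusions matched to their shorter spans.

Dissociation is monitored by a four-term termination metric — the
three group-A donor–acceptor distances plus one heavy-atom proxy pair
for the buried van-der-Waals contact — with termination at the first
frame where the sum strictly exceeds 80 Å, evaluated per saved frame.

## Geometry: core, averages, maps, hinge

All comparative geometry assumes superposition on a *stable core*, the
residue set with least positional variation. The core is found by
hierarchical clustering (average linkage) of the inter-residue
distance-fluctuation matrix — the SD over frames of every pairwise
Cα–Cα distance — cut into `n_clusters` groups (default 5). Because the
measure is internal-distance based it cannot, by itself, distinguish
two mutually rigid domains; three safeguards make the selection
robust: (i) clusters whose mean internal fluctuation is within 1.5× of
the minimum are treated as equally rigid and the *largest* is kept
(more fit atoms stabilise the superposition), ties then break to the
lowest residue id; (ii) the selected cluster is trimmed of members
whose mean fluctuation against the rest exceeds 3× the member median,
which removes stray mobile residues that agglomeration attached;
(iii) ligand and ion residues are never admitted. The cluster count
must be at least the number of independently mobile groups plus one —
independently floppy residues may each need their own cluster. When a
declared core is scientifically preferable (e.g. the membrane-anchored
domain of a membrane protein, where the physical frame is known), the
pipeline accepts `core_residues` and skips detection; the rigid-body
degeneracy above is exactly why the configuration exposes this.

Average structures are arithmetic per-atom means over core-aligned
(bound) frames, with per-atom RMSF recorded and written to the
B-factor column. RMSD between two averages is computed directly in the
shared core frame, with no re-superposition. The most-populated
structure is located on a 2-D histogram of (inter-domain Cα–Cα
distance, backbone RMSD to a reference) with 0.5 Å × 0.25 Å bins; the
returned frame is the one nearest the modal bin centre, earliest frame
on ties. "Backbone" means N, Cα, C, O.

The hinge scan formalises the criterion that the displacement of a
rigidly moving domain grows with distance from the hinge: for each
candidate residue, the Pearson correlation between (distance of each
mobile residue's Cα from the candidate, in the reference average) and
(that residue's backbone RMSD between the two condition averages),
over the mobile set. Candidates default to the low-RMSD quartile,
optionally restricted to a declared interface; the mobile set must
contain at least 10 residues or the correlation is refused as
unstable. Binding-site residues should be excluded from both sets —
their atoms move with bond formation, not with the domain. Identical
averages make every correlation undefined; the report flags this
degenerate case rather than ranking noise.

Distance-difference maps are Δ⟨D_ij⟩ between conditions over all
Cα pairs (antisymmetric by construction, zero diagonal), summarised as
block means per domain-label pair — the per-residue-pair opening of
the TM–PP block is the single-number readout of domain opening. Latch
histograms share bin edges across conditions and are normalised to sum
to one, so conditions with different bound-frame counts are directly
comparable.

## Energetics

Interaction energies are exact pairwise sums over disjoint atom
groups: Coulomb `k_e q_i q_j / (ε_r r_ij)` with `k_e = 332.0636
kcal·Å·mol⁻¹·e⁻²` and relative dielectric 1 (the convention of
standard protein force fields), plus Lennard-Jones in the
ε/r_min parameterisation with Lorentz–Berthelot-style combination
(`ε_ij = √(ε_i ε_j)`, `r_min,ij = r_min,i/2 + r_min,j/2`). No cutoff
or switching is applied by default — exact sums are the reference
behaviour. The optional residue-level centre-of-mass prefilter (15 Å
mirrors common practice) is applied on the *time-averaged* COM
distance over the masked frames: a per-frame varying residue set would
make the per-residue decomposition ill-defined. Inter-atom distances
below 0.1 Å abort with an error — that is a broken system, not a
number. PDB files carry no force-field data, so charges and LJ
parameters come from a sidecar TSV keyed by residue and atom name.

Sampling adequacy uses the jack-knife identity: for replicas
`y_1..y_n`, the leave-one-out means satisfy `sd(m_i) = sd(y_i)/(n−1)`
exactly, so with 13 replicas the jack-knife spread sits at 1/12 —
"about one tenth" — of the replica spread when replicas are
exchangeable; large deviations indicate one replica dominates.

## Collective dynamics and networks

Cross-correlations `C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)` and
Cartesian PCA both operate on Cα atoms by default (backbone
selectable), on core-aligned bound frames, with the two conditions
pooled before PCA so their projections live in one space. Zero-
variance atoms get zeroed correlations plus a warning rather than NaN.
PCA is the eigendecomposition of the coordinate covariance
(`stats::prcomp`); RMSIP over the first k modes (default 10) measures
subspace overlap. Projection densities use a Gaussian kernel with the
normal-reference bandwidth on a shared grid, each condition normalised
to unit mass — a deliberate simplification of model-based clustering,
since only the density map and its spread summaries are consumed
downstream. The leave-one-replica-out PCA reports the RMSIP of the
first two components against the full model.

The residue network connects nodes with `|C_ij| ≥ 0.7` (motion vectors
within 45°) and weights edges `w_ij = −ln|C_ij|`, so perfectly
correlated residues communicate at zero cost; absolute values mean
anticorrelated pairs connect too. Communities come from greedy
modularity agglomeration with `|C_ij|` as edge strength, cutting the
merge tree at the modularity maximum (numerical ties resolve to fewer
communities). The community summary graph uses radius `R_i = N_i/3`
and edge weight `−ln|max C_ij|`, divided by 4 in the structure-overlay
variant so spheres do not obscure the fold; communities with no
inter-community edge are pruned. Betweenness counts weighted shortest
paths through a node (endpoints excluded) on the full residue network;
suboptimal paths are the k lowest-weight simple paths (default
k = 500), merged across all source–sink pairs and sorted by weight
with lexicographic tie-breaking, so `fraction_through()` can ask what
fraction of communication routes traverse the pin.

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` + `simulate_ensemble()` build a caricature protein
— a TM lattice block, a PP fan rising from an apex above it (so hinge
displacement grows steeply and monotonically with distance from the
pivot), and a peptide at the interface whose six H-bond acceptor
residues are translated into the pocket (≈ 4.4 Å donor–acceptor
separation when unformed). Programmed structure:

* **H-bond schedules** are two-state continuous-time Markov chains
  discretized with the exact transition kernel over dt, which
  preserves the stationary occupancy `p_on` at any dt (a naive
  rate-times-dt discretization biases occupancy low). `p_on` and the
  mean on-dwell fix both rates. When "on", the acceptor is placed at a
  donor–acceptor distance drawn from U[2.6, 3.3] Å with a D–H–A angle
  from U[150°, 180°], relative to the *noised* donor and hydrogen so
  detection fidelity is limited only by the long donor–acceptor lever
  arm; when "off" it hovers just outside the envelope (≥ 4.2 Å) while
  the peptide is in the pocket, and stays at its template position
  after an unbind event so separations grow with the drift. Only
  acceptor-group atoms are moved, decoupling H-bond statistics from
  backbone geometry.
* **Hinge**: the PP block rotates rigidly about the pivot's Cα along a
  fixed axis by an Ornstein–Uhlenbeck angle (mean, SD in degrees,
  correlation time in ns; stationary initialisation).
* **Correlated blocks** add a shared Gaussian latent displacement
  scaled to `noise_sd · √(ρ/(1−ρ))`, which yields pairwise correlation
  ρ against the independent noise. Note that rigid-body superposition
  *absorbs shared translations*: if block members sit inside the
  alignment core, core alignment will cancel the latent and the
  programmed correlation is not recoverable — the benchmarks therefore
  keep coupling blocks out of the declared core.
* **Unbinding** drifts the peptide at 0.5 Å/ns from the event time,
  forcing peptide bonds off (with a warning if one was scheduled
  always-on).
* **Noise** is isotropic Gaussian, default 0.1 Å, added to every atom.
* **Seeding**: one integer seed; replica r uses stream seed + r − 1,
  so replicas are independent but the whole ensemble is reproducible
  bit for bit.

What the generator does **not** emulate: physical force fields,
solvent, membranes, anharmonic side-chain dynamics, correlated
noise with realistic spatial structure, or real H-bond geometry
fluctuations. Passing the recovery tests therefore demonstrates that
the estimators are correct and well-calibrated on data satisfying
their own assumptions — not that those assumptions hold for any
particular real trajectory.

Defaults define the study conditions used throughout the tests: 3
replicas, 2000 frames at dt = 0.1 ns, TM = 40 / PP = 30 / peptide = 8
residues, six bonds with occupancies patterned on a tightly bound
substrate (0.83, 0.91, 0.78, 0.32, 0.92, 0.81), 5 ns dwells, hinge SD
4° with 5 ns correlation time, 0.1 Å noise. The two-condition
benchmark contrasts these "tight" settings against a "loose" variant
(occupancies 0.61, 0.68, 0.38, 0.16, 0.58, 0.36; hinge mean 12°, SD
5°; no peptide-core coupling block), the qualitative signature of a
destabilised substrate. Test and acceptance problem sizes (300–5000
frames, 1–3 replicas) were chosen as the smallest at which each
estimator's sampling error is comfortably inside the asserted
tolerance — e.g. occupancy recovery to ±0.03 needs hundreds of
independent dwell cycles, so that benchmark uses 1 ns dwells over a
500 ns span.

## File formats and interoperability

Structures are read and written as PDB via `bio3d` (first model, with
a warning on multi-model files; residue numbering preserved verbatim;
RMSF written to B-factors). Trajectories are read from DCD (`bio3d`)
or from a human-readable columnar text format (`write_text_trajectory`)
designed so test fixtures remain inspectable. XTC is not supported —
no installed R reader exists — and `read_trajectory()` says so
explicitly. The frame stride is not recoverable from trajectory files,
so `dt` is always a required input. Coordinates beyond ±9999.999 Å
exceed the fixed-width PDB field and are refused at write time.

## Known limitations

* H-bond detection is purely geometric; no periodic-image handling, no
  water-mediated bridges, no energy criterion.
* The stable-core detector cannot resolve the rigid-two-domain
  degeneracy without a declared core (see above).
* Betweenness uses weighted shortest paths; when multiple exact ties
  exist, igraph's fractional counting differs from a literal path
  count (irrelevant for generic real-valued weights).
* The energetics module computes bare nonbonded sums — no PME, no
  switching, no bonded exclusions; groups are assumed to be separate
  molecules.
* Runs with hundreds of thousands of frames will want the frame masks
  and the energy stage's built-in subsampling; the pairwise energy
  kernel is O(frames × |A| × |B|) in pure R.
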