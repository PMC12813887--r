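---
title: "Domain dynamics analysis of membrane receptor trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain dynamics analysis of membrane receptor trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardyn)
```

## The scientific problem

Second-generation chimeric antigen receptors (CARs) are single-chain
membrane proteins with an extracellular antigen-binding domain (AB, an
scFv), a hinge (HI), a transmembrane helix (TM), a costimulatory domain
(CS) and the CD3ζ signaling tail (SI) carrying three ITAMs separated by
polybasic regions. How antigen engagement outside the cell changes the
dynamics of the signaling tail inside the cell is the central mechanistic
question. One hypothesis — the *binding-induced domain dynamics switch*
(BIDDS) — treats the receptor as a coupled pendulum: in the unbound (apo)
state the AB head samples a wide extracellular arch while the SI tail is
conformationally restricted; antigen binding (holo) tethers the head and
the sampling redistributes, with AB narrowing and SI widening.

`cardyn` implements the trajectory-analysis protocol used to quantify
this picture, plus a coarse-grained generator of synthetic apo/holo
trajectories with the switch programmed in, so the full pipeline is
exercisable and testable without microsecond-scale all-atom simulations.

## The analysis protocol

All quantities are computed from multi-model PDB trajectories and a
*domain map* (YAML) naming the residue ranges of the five domains, the
polybasic/ITAM groups and the membrane atom convention.

**Superposition.** Every fitted quantity uses Kabsch superposition
(SVD of the cross-covariance with reflection correction). Fitting on the
TM domain defines the membrane frame: z is the membrane normal, x–y the
membrane plane, the slab centered at z = 0.

**Domain-decomposed Cα-RMSD.** For each domain two series are computed
against the reference (frame 1 by default — the protocol's plots are
"development of the RMSD" style, and the package accepts an explicit
reference structure where one exists):

* *overall* — fit on TM, measure the domain (contains inter-domain
  rearrangement plus internal deformation);
* *intra* — fit on the domain itself, measure the domain (internal
  deformation only).

The apo-vs-holo state difference of a series is the difference of its
post-equilibration means (holo − apo, signed; the equilibration cut is a
frame index supplied by the user). Subtracting the intra difference from
the overall difference isolates the inter-domain contribution:
`inter = overall − intra`, exactly, signed values permitted. Whether the
published protocol differenced time-averaged RMSDs or RMSDs of averaged
structures is ambiguous; difference of time-averaged means is implemented
because it reproduces the worked arithmetic of the AB row
(71.5 − 0.5 = 71.0 Å). Note the analogous published CS and SI rows are
not internally consistent (75.6 − 1.9 ≠ the printed 72.6); `cardyn`
always reports exact arithmetic.

**Other geometry.** Per-residue Cα-RMSF after TM fitting; radii of
gyration of the receptor and of the extracellular (AB+HI) and
intracellular (CS+SI) halves; AB–TM and SI–TM centroid distances;
end-to-end distance. A domain *center* is the unweighted centroid of its
Cα atoms — robust to missing side chains and resolution-independent.

**Sampling clouds and the switch score.** The per-frame domain centers in
the TM-aligned frame form a point cloud per domain. Its spread is
summarized by the covariance trace, principal extents, planar spread
(`sqrt(var x + var y)`), normal spread (sd of z) and convex-hull volume.
The switch statistic is

`score = ln(trace_AB_apo / trace_AB_holo) + ln(trace_SI_holo / trace_SI_apo)`

positive exactly when the switch signature is net present, and exactly
antisymmetric under swapping the state labels (it is computed as a
difference of logarithms, so the flip is bit-exact). The covariance
trace — not the hull volume — is scored because it is stable at small
frame counts; the hull volume is reported for reference only.

**Membrane contacts and burial.** Contacts are heavy-atom pairs between
a residue group and the membrane selection within 2.5 Å (the published
cutoff), counted per frame; pair counts, not residue counts, to match
the "average of nine contacts" reporting style, and heavy atoms only
since the protocol never states whether hydrogens were counted. Burial
depth of an atom set is `halfwidth − |z|` maximized over the set; a
positive post-equilibration mean flags insertion into the slab — the
test of the "safety-on/off" picture in which ITAM tyrosines would sit
buried in the bilayer until receptor engagement.

**Secondary structure.** The published analysis used a vendor tool; here
assignment is a deliberately simple, fully testable dihedral-window rule:
H iff φ ∈ (−120°, −30°) and ψ ∈ (−80°, −5°); E iff φ ∈ (−180°, −70°) and
ψ ∈ (90°, 180°] ∪ [−180°, −150°); else C; H/E runs shorter than 3
residues are smoothed to C. This diverges from DSSP-style hydrogen-bond
assignment by design: the rule is exact on the package's ideal
helix/strand fixtures, which is what the tests need. Per-domain H/E/C
fractions are time averages and always sum to 1.

**Clustering.** The published clustering algorithm is unnamed; `cardyn`
specifies a deterministic leader scan at a 2.5 Å Cα-RMSD cutoff (RMSD
after pairwise superposition): frames join the first representative
within the cutoff or found a new cluster. This makes results reproducible
and oracle-checkable; published cluster counts (38 holo / 33 apo) depend
on unavailable trajectories and are direction references only.

**Correlation network and communities.** Node displacements are
deviations from time-mean positions after TM fitting;
`C_ij = ⟨Δr_i·Δr_j⟩ / sqrt(⟨Δr_i²⟩⟨Δr_j²⟩)`. Edges join residues with any
heavy-atom pair within 4.5 Å in ≥ 75 % of frames (the convention of the
standard dynamical-network tooling, since the protocol states no
parameters; both are configuration keys), weighted `−log|C_ij|` and
capped at `−log(1e−6)` to avoid infinite weights. Community detection is
Girvan–Newman: repeatedly remove the edge of highest weighted (distance)
betweenness — ties broken deterministically by lowest edge index — and
return the partition along the dendrogram maximizing weighted Newman
modularity. The same edge weights serve as distances for betweenness and
as strengths for modularity, the convention of the cited tooling. igraph
supplies betweenness, components and the modularity function; the removal
loop, tie-break and dendrogram scan are the package's own.

## The synthetic generator

The generator emulates the *statistical structure* the analysis assumes,
not the receptor's chemistry: a chain of beads (AB blob — 3 HI beads —
5 TM beads — 3 CS beads — SI blob, 7.5 Å spacing) spanning a 15 Å
half-width membrane slab, integrated by overdamped Langevin
(Euler–Maruyama) dynamics in reduced units (kT = 1, γ = 1, dt = 1e-3):

`x ← x + (dt/γ)·F(x) + sqrt(2·kT·dt/γ)·η`

Forces: harmonic bonds (k = 15); harmonic anchors pinning TM beads to
their rest sites (k = 40) and, in the holo state, an AG bead bonded to AB
and anchored extracellularly (k = 2, the target-cell tether); half-harmonic
walls keeping non-TM beads out of the slab (k = 10); and a bending term.

**Bending is a discrete-curvature penalty** `½·k·|x_{i−1} − 2x_i +
x_{i+1}|²`, not an angle harmonic: at the straight rest state an
angle-harmonic force is singular (1/sin θ) and a cosine-harmonic is
quartic in the deflection, which would wash out the programmed stiffness
contrast. The second-difference form is exactly harmonic in transverse
deflection (a discretized worm-like chain), so stiffness ratios map
directly onto variance ratios and equipartition gives a clean closed-form
check. Its stiffness unit is therefore energy/Ų. Each joint takes the
*softest* stiffness among the three domains it touches, so the
membrane-exit joints flex like their linkers rather than like the rigid
TM rod — otherwise a state-independent pivot stiffness caps both arms'
swing and dilutes the contrast.

**Presets.** The switch is programmed through the linker stiffness:
apo k_HI = 0.5, k_CS = 4.8; holo k_HI = 3.0, k_CS = 0.8 (six-fold
contrasts), plus the holo AG tether. A four-fold contrast was considered
first — it is the natural minimal choice — but at the default run length
the measured SI covariance-trace ratio is diluted to ~2.7 by TM-fit
alignment noise and the finite-sampling variance of the soft intracellular
mode; the six-fold contrast keeps the *measured* equilibrium trace
contrast at or above four-fold with margin, which is the preset's
documented contract. All constants are overridable per run.

**Run length and seeds.** Default 2·10⁶ steps, frames every 10³ steps
(2000 frames ≈ 2000 reduced time units). The slowest programmed mode has
a relaxation time of ≈ 40 time units, so the default run covers ≈ 50
relaxation times; analyses of synthetic data discard the first 10 % of
frames (≈ 5 relaxation times from the at-rest start). One integer seed
drives R's RNG (the integrator draws its normals from it), giving
bit-identical repeat runs on the same build; cross-platform bit identity
is not promised. The stability bound dt·k_max/γ < 0.1 is enforced with
k_max the largest *effective* curvature (4·k_bond for the bond network,
16·k_bend for the bending operator, anchors and walls as given), since
the raw constants do not bound the Euler–Maruyama step.

**What passing tests show — and what they do not.** The generator
produces Gaussian-ish, harmonically tethered fluctuations of point
domains with a programmed contrast. Real receptor trajectories add
anharmonicity, disordered-region structure, lipid interactions,
glycosylation and sampling far from equilibrium. Recovery of the switch
from the presets therefore validates the *pipeline* (selections, fitting,
spread statistics, signs), not the biological hypothesis; the published
microsecond-scale values (e.g. per-domain RMSD means, 38/33 clusters,
25/23 communities, contact averages) are not reproducible from synthetic
data and are treated as direction references only.

## Numerical choices and degenerate inputs

* Kabsch refuses < 3 points and collinear/coincident configurations
  (second singular value below 1e-10 of scale) rather than returning an
  arbitrary rotation; the reflection branch is corrected so det(R) = +1.
* A 1- or 2-point domain superposes onto itself exactly, so the pipeline
  reports its fit-to-self (intra-domain) series as identically zero
  rather than failing.
* Hydrogens are parsed but excluded from every analysis by default.
* Alternate locations: first altloc wins; author residue numbering is
  used as-is, 1-based, inclusive ranges, no renumbering.
* PDB coordinates are fixed-column `%8.3f`; magnitudes ≥ 10000 Å (or
  ≤ −1000 Å) refuse to write rather than corrupt columns.
* The convex-hull volume uses an incremental hull with a relative
  tolerance of 1e-9 of the cloud extent; < 4 non-coplanar points give
  volume 0 by definition.
* Equilibration cuts default to 0 and are always explicit parameters;
  the published 4 µs / 5 µs flattening points correspond to frame
  indices chosen by the user for real data.
* Reports round to 1 decimal for Å quantities and 3 decimals for
  dimensionless scores, with a full-precision raw JSON alongside.

## Worked example

```{r example, eval = FALSE}
library(cardyn)

# synthetic apo/holo pair under the default study conditions
apo  <- simulate_receptor("apo",  seed = 1)
holo <- simulate_receptor("holo", seed = 1)
map_apo  <- simulated_domain_map(preset_config("apo",  seed = 1))
map_holo <- simulated_domain_map(preset_config("holo", seed = 1))

run_analyze(apo,  map_apo,  "out/apo",  equil_cut = 200)
run_analyze(holo, map_holo, "out/holo", equil_cut = 200)
report <- run_compare("out/apo", "out/holo", "out/report.json")

report$decomposition               # per-domain overall/intra/inter table
report$switch_report$switch_score  # > 0: switch signature present
```

The vignette is not pre-executed; the chunk above is the same flow the
package's test suite and acceptance script run, at the problem sizes
stated under *Run length and seeds*.

## Known limitations

* The SSE rule is dihedral-window based, not hydrogen-bond based; it
  will disagree with DSSP on borderline residues.
* The leader clustering depends on frame order by construction (that is
  what makes it deterministic and oracle-checkable).
* Girvan–Newman recomputes betweenness after every removal; fine for
  residue-level graphs (hundreds of nodes), not for atom-level ones.
* The generator's membrane is a static pseudo-atom lattice: contact
  stages run end-to-end on synthetic data but report near-zero counts;
  quantitative contact analysis needs real lipid trajectories.
* ITAM residue ranges must come from user configuration; only the
  polybasic regions have published construct numbering (395–399,
  406–410, 435–442) and default accordingly, and the motif scanner's
  spacer default 6–12 spans both published spacer conventions.
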