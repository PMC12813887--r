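# cardyn

Domain dynamics analysis of multi-domain membrane receptor trajectories,
built for the apo-versus-holo comparison protocol used on chimeric
antigen receptors (CARs): an antigen-binding scFv (AB), hinge (HI),
transmembrane helix (TM), costimulatory domain (CS) and CD3ζ signaling
tail (SI) crossing a lipid membrane.

The scientific question the protocol addresses: how does antigen binding
outside the cell redistribute the receptor's dynamics inside the cell?
The *binding-induced domain dynamics switch* (BIDDS) picture treats the
receptor as a coupled pendulum — in the apo state the AB head samples a
wide extracellular arch while the SI tail is restricted; upon binding the
contrast reverses. `cardyn` quantifies this from trajectories:

* **Domain-decomposed Cα-RMSD** — per-domain series fitted to TM
  ("overall") and to the domain itself ("intra"); the inter-domain
  contribution of an apo/holo difference is `inter = overall − intra`.
* **RMSF, radii of gyration, AB–TM / SI–TM distances, end-to-end
  distance** in the TM-aligned membrane frame (z = membrane normal).
* **Domain-center sampling clouds** with spread summaries (covariance
  trace, planar/normal spread, principal extents, convex-hull volume)
  and the switch score
  `ln(trace_AB_apo/trace_AB_holo) + ln(trace_SI_holo/trace_SI_apo)`
  (positive ⇔ switch signature present; exactly antisymmetric in the
  state labels).
* **Membrane contacts** (heavy-atom pairs within 2.5 Å) for the
  polybasic regions, ITAMs and ITAM tyrosines, plus a burial-depth test
  of the "safety-on/off" membrane-sequestration picture.
* **Secondary-structure fractions** (dihedral-window H/E/C with run
  smoothing), **leader clustering** at a 2.5 Å RMSD cutoff, and a
  **correlated-motion network** (4.5 Å / 75 % occupancy contacts,
  `−log|C_ij|` weights) with Girvan–Newman community detection.
* An **ITAM motif scanner** for the `Yxx(L/I)x{6–12}Yxx(L/I)` pattern.
* A **synthetic trajectory generator**: a bead-spring coupled-pendulum
  receptor spanning a membrane slab, integrated by overdamped Langevin
  (Euler–Maruyama) dynamics, with apo/holo presets that program the
  switch through linker bending stiffness — so the entire pipeline is
  testable at desk scale. Deterministic in a single integer seed.

Trajectories are multi-model PDB files; selections are driven by a YAML
*domain map* naming residue ranges (with the CD3ζ polybasic regions
defaulting to construct positions 395–399, 406–410, 435–442 when the SI
range covers them).

## Worked example

```r
library(cardyn)

apo  <- simulate_receptor("apo",  seed = 1)   # 2e6 steps, 2000 frames
holo <- simulate_receptor("holo", seed = 1)
map_apo  <- simulated_domain_map(preset_config("apo",  seed = 1))
map_holo <- simulated_domain_map(preset_config("holo", seed = 1))

run_analyze(apo,  map_apo,  "out/apo",  equil_cut = 200)
run_analyze(holo, map_holo, "out/holo", equil_cut = 200)
report <- run_compare("out/apo", "out/holo", "out/report.json")

report$decomposition
#>   domain overall_diff  intra_diff inter_diff
#> 1     AB  -8.72469550  0.00000000  -8.724696
#> 2     HI  -3.85697540 -0.02800265  -3.828973
#> 3     TM  -0.01974163 -0.01974163   0.000000
#> 4     CS   2.14839894  0.06036573   2.088033
#> 5     SI   4.13222492  0.00000000   4.132225
report$switch_report$switch_score
#> [1] 6.084248
```

Reading the output: the `overall_diff` column is the holo-minus-apo
difference of the mean fit-to-TM Cα-RMSD per domain; negative for AB
(binding narrows the extracellular head's excursions), positive for CS
and SI (the intracellular tail moves more). `intra_diff` is near zero
everywhere — the beads barely deform internally — so the change is
almost entirely inter-domain, and `inter_diff = overall − intra`
exactly. The switch score 6.084 is positive and large: the AB cloud's
covariance trace shrinks ~87-fold on binding while the SI trace grows
~5-fold (`report$switch_report` carries both ratios and the full spread
summaries). Rounded (1 decimal) and full-precision (`*_raw.json`)
reports are written side by side.

A command-line driver wraps the same functions:

```sh
Rscript inst/scripts/cardyn.R simulate --state apo --seed 1 --out out/sim_apo
Rscript inst/scripts/cardyn.R analyze --traj out/sim_apo/trajectory.pdb \
    --map out/sim_apo/domain_map.yaml --out out/apo
Rscript inst/scripts/cardyn.R compare --apo out/apo --holo out/holo --out out/report.json
```

Exit codes: 0 success, 2 usage/config error, 3 data/format error,
4 numerical failure.

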