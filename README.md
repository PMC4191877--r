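# lipidmix

Trajectory analysis for coarse-grained simulations of lipid raft phase
separation, for researchers studying how hydrophobic solutes remodel
liquid-ordered (L<sub>o</sub>) / liquid-disordered (L<sub>d</sub>) domains
in ternary DPPC / DLiPC / cholesterol bilayers.

## What it computes

The central observable is the **contact fraction**. For lipid mixing,

    f_mix = c(DLiPC, DPPC) / [ c(DLiPC, DPPC) + c(DLiPC, DLiPC) ]

where `c` counts contacts between PO4 headgroup beads within 1.1 nm under
the minimum-image convention; cross-species contacts count once per
molecule pair and same-species contacts once per ordered
(molecule, neighbor) pair. `f_mix` is 0 at complete phase separation and
reaches the DPPC molar fraction among phospholipids (828/1368 = 0.605,
printed as 0.61) at ideal mixing. Two partitioning analogues locate the
solute and cholesterol:

    f_X = c(X, DLiPC) / [ c(X, DLiPC) + c(X, DPPC) ]      X = solute, CHOL

using all beads of solute and lipids at 0.8 nm (solute) or ROH-PO4 beads
at 1.1 nm (cholesterol); the ideal-mixing value is the DLiPC molar
fraction 540/1368 = 0.39, and values near 0.5 on a phase-separated
membrane indicate interfacial (linactant) localization.

Around that core the package provides:

* GROMOS-87 `.gro` I/O, periodic-boundary geometry, leaflet assignment
  (`read_gro`, `minimum_image_distance`, `assign_leaflets`);
* per-frame contact-fraction series and block-averaged errors
  (`contact_fraction_series`, `block_average_error`);
* 50x50 planar landscapes: partial density, DLiPC density fraction
  (whose 0.5 level set is the domain interface), normalized solute
  density, interface localization and enrichment
  (`partial_density_landscape`, `interface_cells`,
  `solute_interface_enrichment`);
* gridded thickness maps, per-phase thickness by the most-frequent-value
  rule, and the L<sub>o</sub>-L<sub>d</sub> thickness mismatch
  (`thickness_landscape`, `phase_thickness`);
* a deterministic synthetic striped-membrane generator with known ground
  truth — composition, mixing degree λ, solute placement, per-phase
  thickness — standing in for microsecond MD trajectories
  (`generate_striped_membrane`, `mix_membrane`, `lattice_mixing_series`);
* a pipeline (`analyze`, `phase_plane`, `mixing_curve`) plus a thin CLI
  (`inst/cli/lipidmix.R`) with subcommands `generate`, `analyze`,
  `phaseplane`, `mixingcurve`.

## Worked example

```r
library(lipidmix)

# a phase-separated membrane with 48 octane-like solutes buried in the
# Ld stripe (the generator's defaults are the 540/828/576 reference
# composition on a 20 x 20 nm box)
spec <- synthetic_spec(composition = composition_spec(n_solute = 48),
                       solute_mode = "ld_partition", seed = 19)
ser <- lattice_mixing_series(spec, n_frames = 6,
                             schedule = list(type = "constant", lambda = 0))
res <- analyze(analysis_config(solute = "OCT"), ser$trajectory)
res$report[, c("n_solute", "molar_ratio", "f_mix", "solute_dlipc", "chol_dlipc")]
#>   n_solute molar_ratio f_mix solute_dlipc chol_dlipc
#> 1       48        2.47     0            1  0.1327122
res$thickness$phase_thickness
#>       Lo       Ld
#> 4.172918 3.858383
```

Read: the stripes are fully separated (`f_mix = 0`; the lipid-free
buffer exceeds the 1.1 nm cutoff), the solute sits entirely in the
DLiPC-rich phase (`solute_dlipc = 1`, the aromatic-solute signature),
cholesterol is mostly liquid-ordered (`chol_dlipc` ≈ 0.13), and the
per-phase thicknesses recover the generator's 4.2 / 3.8 nm ground truth
to within a few hundredths of a nm on this short series.
At full mixing (`mix_membrane(..., lambda = 1, ...)`) `f_mix` rises to
its analytic 0.605 limit, and `phase_plane()` on a two-stage
`lattice_mixing_series()` traces the linactant mechanism: solute first
to the interface (solute fraction crossing 0.5 at constant `f_mix`),
lipid mixing second.

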