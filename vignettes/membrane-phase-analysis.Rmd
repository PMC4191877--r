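---
title: "Contact fractions, landscapes and synthetic membranes: the methods behind lipidmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact fractions, landscapes and synthetic membranes: the methods behind lipidmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmix)
```

# The system and the observables

Ternary mixtures of a saturated phosphatidylcholine (DPPC), a doubly
unsaturated one (DLiPC) and cholesterol phase-separate into a
liquid-ordered phase (L~o~, DPPC- and cholesterol-rich) and a
liquid-disordered phase (L~d~, DLiPC-rich). In coarse-grained
simulations of the 540 DLiPC / 828 DPPC / 576 cholesterol reference
composition the two phases organize as stripes across the periodic box,
which makes simple planar statistics very informative. `lipidmix`
implements the analysis layer for such trajectories: contact-fraction
order parameters, planar density/thickness landscapes, and the
phase-plane view of the solute mechanism — together with a synthetic
membrane generator that provides ground-truth inputs at desk scale.

## Contact fractions

All three statistics are ratios of contact counts under the
minimum-image convention in a rectangular box, with inclusive cutoffs
(a pair at exactly the cutoff counts; the choice is measure-zero and
fixed for reproducibility).

**Lipid mixing, `f_mix`.** Contacts are evaluated between PO4 headgroup
beads only, within 1.1 nm. Cross-species DLiPC–DPPC contacts count once
per molecule pair; same-species DLiPC–DLiPC contacts count once per
ordered (molecule, neighbor) pair — i.e. twice per unordered pair. This
asymmetry is deliberate: writing $n_i^{DPPC}$ and $n_i^{DLiPC}$ for the
neighbor counts of DLiPC molecule $i$,

$$ f_{mix} = \frac{\sum_i n_i^{DPPC}}{\sum_i n_i^{DPPC} + \sum_i n_i^{DLiPC}}, $$

the average fraction of a DLiPC molecule's phospholipid neighbors that
are DPPC. At ideal mixing its expectation is the DPPC molar fraction
among phospholipids, $828/1368 = 0.605$; counting same-species pairs
once instead would push the ideal-mixing value to about 0.75, which
contradicts the known limit. At complete phase separation with an
interfacial gap wider than the cutoff, `f_mix` is exactly 0.

**Solute partitioning.** The solute–DLiPC fraction uses *every* bead of
the solute and of both phospholipids, with a 0.8 nm cutoff and plain
bead-pair counting. Because DPPC and DLiPC carry identical bead counts,
the ideal-mixing expectation is the DLiPC phospholipid molar fraction
$540/1368 = 0.39$. On a phase-separated membrane, values near 1
indicate L~d~ partitioning (the aromatic signature), values near 0.5 an
interfacial, linactant-like localization.

**Cholesterol partitioning.** Same ratio computed between the ROH bead
of cholesterol and lipid PO4 beads at 1.1 nm; low values mean
cholesterol resides in the L~o~ phase.

Whether one reports the average of the per-frame fraction or the
fraction of time-summed counts is a free choice for a stationary tail
window; this package averages the per-frame statistic, which pairs
naturally with block averaging.

## Block-averaged errors

Contact-fraction series are strongly autocorrelated, so the naive
standard error of the mean underestimates the uncertainty. The package
uses block averaging with block-length doubling: starting from block
length 1, the block standard error $s_b/\sqrt{n_b}$ is recorded and the
block length doubled while at least 4 blocks remain; the reported error
is the maximum over that progression. For white noise this reduces to
$\sigma/\sqrt{n}$, and for AR(1) noise with autocorrelation $\varphi$ it
converges to the effective-sample-size form
$\sigma\sqrt{(1+\varphi)/(1-\varphi)}/\sqrt{n}$; the test suite checks
both closed forms within a factor 1.5 (at $n = 4096$ and $n = 65536$
respectively). The averaging window defaults to the final 5000 ns of a
production run when frame times span that much, and to the final half of
the frames otherwise — short synthetic series need a relative rule.

## Landscapes

Planar maps use a fixed 50×50 grid (about 0.4×0.4 nm cells on a 20 nm
box). Binning is done in box-fractional coordinates so that frames with
fluctuating boxes share one grid, and densities divide the time-mean
cell count by the time-mean cell area; this makes the conservation
identity — grid sum × mean cell area = mean selected-bead count per
frame — hold exactly, and the tests assert it exactly. The default
window is the final 500 ns, or the final tenth of frames for short
series. Landscapes can be restricted per leaflet; the default is the
whole bilayer.

The DLiPC density fraction (DLiPC density over total PC density per
cell) runs from 0 in pure DPPC cells to 1 in pure DLiPC cells; cells
with no PC density at all (solvent gaps, the stripe buffer) are marked
undefined rather than given a value. The domain interface is its 0.5
level set. `interface_cells()` marks defined cells whose fraction
crosses 0.5 against a neighboring cell in any of the four periodic grid
directions; when the immediate neighbor is undefined the nearest defined
cell within `max_skip` cells (default 5) is compared instead, so the two
cells facing each other across a lipid-free gap are still recognized as
the interface, while large unsampled voids do not connect unrelated
regions. With contacting stripes this reduces to the plain 4-neighbor
rule and yields exactly two periodic bands.

The "normalized" solute landscape divides the solute density by its
spatial mean so the map averages to exactly 1 and enrichment reads
directly as values above 1. Mean-normalization was an open choice; it is
scale-free and keeps the enrichment ratio of
`solute_interface_enrichment()` dimensionless.

## Thickness

Per cell and frame, thickness is the mean z of upper-leaflet PO4 beads
minus the mean z of lower-leaflet PO4 beads, then averaged over the
window; cells that never see PO4 in both leaflets stay undefined —
nothing is extrapolated into unsampled grid cells. Leaflets are assigned
from a single global midplane (the mean PO4 z of the frame), which is
sufficient for the flat stripe membranes analyzed here; strongly curved
or flip-flopping systems would need a local midplane, which is out of
scope.

The characteristic thickness of a phase is the *most frequent* local
thickness: defined cells of a phase are histogrammed with a 0.02 nm bin
width and the center of the maximal bin is returned, with ties broken
toward the thicker bin. The 0.02 nm width resolves the ~0.2 nm
mismatch effects of interest while keeping tens of cells per bin; bin
centers are anchored at the sample minimum so a constant map returns
its own value for any bin width. Cells are attributed to phases by the
DLiPC density fraction at the 0.5 level (fraction ≥ 0.5 → L~d~), the
same criterion that defines the interface; raw per-cell values are used,
without smoothing. The mismatch is the signed difference
thickness(L~o~) − thickness(L~d~).

# The synthetic membrane generator

Microsecond coarse-grained trajectories are not reproducible at desk
scale, so every analysis stage is exercised on generated membranes with
known ground truth. The generator emulates the *geometry* of the
simulated systems, not their energetics:

* **Composition and box.** 540 DLiPC / 828 DPPC / 576 cholesterol on a
  20×20 nm box — 972 lipids per leaflet at ~0.41 nm² per lipid, a
  realistic area per coarse-grained lipid, and ~0.4 nm landscape cells
  at 50 bins. Solutes are added on top (count and species label are
  free; residue naming for solutes is force-field specific and therefore
  configurable).
* **Stripes.** Two stripes along x with areas proportional to their
  lipid counts, separated by a lipid-free buffer at both interfaces
  (default 1.2 nm, wider than the 1.1 nm cutoff so the λ = 0 membrane
  scores exactly `f_mix` = 0). At λ = 0 the L~d~ stripe holds all DLiPC
  plus 10% of the cholesterol — the `chol_ld_fraction` default emulates
  the solute-free cholesterol partitioning regime (`chol_dlipc` ≈ 0.11)
  without claiming to reproduce it.
* **Molecules.** Lipids are simplified bead stacks on jittered lattices:
  one PO4 (or ROH) bead at the leaflet surface, whose height comes from
  the per-phase thickness (defaults 4.2 / 3.8 nm), and the remaining
  beads stacked toward the midplane; both phospholipids carry 12 beads,
  which every implemented statistic requires (equal bead counts preserve
  the 0.39 limit), cholesterol 8. Positional jitter is Gaussian with
  σ = 0.05 nm. Solutes are single beads placed at the midplane: on a
  uniform grid, inside an interface band, or in the L~d~ stripe
  interior. Water is omitted — no implemented statistic touches it.
* **Mixing.** `mix_membrane()` selects a fraction λ of each phospholipid
  species per leaflet and randomly permutes the selected molecules over
  the selected sites. A relocated lipid adopts the full site geometry,
  including the local leaflet-surface height — permuting only the
  lateral coordinates would leave relocated lipids 0.2 nm off the local
  surface and systematically shave cross-species contacts. λ = 0 is the
  identity, λ = 1 a fully random arrangement with the exact 828/1368
  expectation, and E[`f_mix`] is monotone in λ in between.
* **Series.** `lattice_mixing_series()` builds each frame from the same
  ideal lattice with fresh jitter and an independently seeded mixing
  draw. The two-stage schedule moves solutes from the uniform grid to
  the interface band during stage A (relocation completes at 70% of the
  stage, so the trace shows an interfacial plateau at constant mixing
  before anything else happens) and then ramps λ during stage B —
  reproducing the linactant event order: solute relocation first, lipid
  mixing second.

Everything is deterministic given the spec's integer seed; derived
per-frame seeds are kept below 2³¹.

## What passing tests do and do not show

The generator reproduces the *combinatorial and geometric* content of
the analyses: molar fractions, contact-counting conventions, stripe
geometry, interface position, per-phase thickness. It does not diffuse
lipids, relax interfaces, or couple the solute to lipid mixing
energetically; domain boundaries are straight, jitter is isotropic
white noise, and the mixing degree is imposed rather than emergent. Test
results therefore validate the analysis pipeline — not the physics of
any force field — and quantitative MD observables (e.g. a solute-free
`f_mix` of 0.13 at 295 K, or solute-specific partitioning values) are
deliberately outside what the suite asserts. The mixing-curve utility
likewise ties λ to solute concentration through a user-supplied response
function, because the real response is an outcome of molecular dynamics.

## Numerical choices and degenerate inputs

* Distances are 3D Euclidean under the minimum-image convention; for
  PO4–PO4 contacts at 1.1 nm in a ~4 nm bilayer, cross-leaflet contacts
  are geometrically impossible, so 3D and lateral counting coincide for
  lipids, and 3D is the safer general contract. Positions are wrapped
  into [0, L) on read.
* A statistic whose denominator is zero (an isolated species, an empty
  window) raises a classed `undefined statistic` condition; series
  evaluation converts it to `NA` per frame rather than failing a whole
  trajectory.
* Boxes must be rectangular; triclinic box lines are rejected at parse
  time. Empty frames are legal and round-trip through the `.gro` writer.
* Problem sizes in the tests — full-composition frames for the analytic
  limits (50 seeds), 100 random ≤200-bead frames against the 27-image
  brute-force oracle, 25-frame series for thickness recovery — were
  chosen so each property is measured with comfortable statistical
  margin on a single CPU.
* Multi-frame input is a concatenation of `.gro` frames; compressed
  trajectory formats would need an external reader and the frame data
  model would be unchanged.

## Known limitations

A single global midplane per frame (no flip-flop tracking, no
curvature); no Voronoi or neighbor-graph mixing metrics, order
parameters, or line-tension estimates; phase attribution of grid cells
is binary at the 0.5 fraction level, with no uncertainty on the
interface position; mass-ratio bookkeeping of solute concentrations is
not computed, because it depends on a mass convention that cannot be
recovered reliably (molar ratios are exact and are computed instead).
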