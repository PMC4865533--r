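---
title: "A cellular Potts model of chemotaxis-driven radial intercalation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cellular Potts model of chemotaxis-driven radial intercalation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`epiboly` simulates a quasi-2D cross-section of the amphibian blastocoel
roof during the four hours of epiboly: a superficial epithelial monolayer
(SL) of ~100-site cuboidal cells sits on a one-site immutable basal layer;
beneath it lie two (or more) tiers of 64-site mesenchymal deep cells (DCs),
and below them the large cell-free blastocoel cavity. Superficial cells
secrete a chemoattractant; deep cells chemotax toward it; radial
intercalation, tissue thinning and lateral expansion emerge.

Cells are connected label domains on a 240 x 120 lattice (2.5 um per site)
evolved by Metropolis dynamics. A copy attempt picks a random site and
proposes the label of a random 8-neighbor; it is accepted with probability
`min(1, exp(-dH/T))`. The energy change sums:

* **Contact energy** `J(kindA, kindB)` per heterotypic pair over the
  4th-order (20-site) neighborhood. The J scale is therefore about five
  times smaller than 1st-order intuition suggests. The calibrated matrix
  makes both cell layers wet the basal layer (cell-separator J far below
  cell-cell J, bare separator expensive against cell-free space): the
  monolayer state is the wetting state, and chemotaxis drives the tissue
  toward it.
* **Volume constraint** `lambda_V (v - V_target)^2`. Released cells (see
  boundaries) are retargeted to volume 0 instead of having the term
  removed: with the term simply removed, an unconstrained cell can grow
  without bound along the tissue (cell-cell contact is cheaper than
  cell-cavity contact), which is clearly not the intended "shrink and be
  removed" behavior.
* **Chemotaxis** `-lambda_chem (c_target - c_source)` whenever the
  extending cell is an unfrozen deep cell. Up-gradient extensions are
  favored; extensions into the cavity, where concentration is lower, are
  suppressed - the membrane ratchet that directs cells toward the source.
* **Elastic links** between deep cells touching the basal layer and the
  superficial cell above them (spring energy on the centroid distance),
  and a **cohesion bias** pulling assigned SC neighbor pairs back together
  when their contact area drops below threshold.

### Chemoattractant field

Producing cells secrete at rate `k_decay * c0` per site; the field diffuses
(`D = 25` site^2/min), decays (`k_decay = 0.5`/min) and is integrated by an
explicit scheme with zero-flux borders. The steady level inside a wide
producing region is `c0`, and a boundary layer of width
`sqrt(D / k_decay)` (~7 sites, 18 um - a short-range gradient about one
cell diameter deep) forms wherever producing tissue meets cell-free space.
Rate secretion rather than a hard concentration clamp matters for one
scenario: with a Dirichlet clamp at every producing site, ubiquitous
expression has a mathematically flat field inside the tissue and no
internal gradient at all, so the cavity-edge ratchet that rescues
ubiquitous expression cannot operate. With rate secretion the interior
level is the same, but the bottom cell row sits inside the boundary-layer
gradient, which is exactly the mechanism the ubiquitous-expression
phenotype requires.

The diffusion substep is `dt_chem = 0.005` min (`D dt = 0.125`), well
inside the explicit-stability bound `D dt <= 0.25`. At the bound itself the
checkerboard mode has amplification factor -1: secretion noise at moving
cell boundaries then never decays and a site-scale oscillation of order
+/-0.1 units swamps the physical gradient. Halving the step removes it.

### Time resolution

One Monte Carlo sweep represents `mcs_min = 0.015` simulated minutes
(16000 sweeps per 240-minute run). Sweep-level housekeeping - field
substeps, link formation/breaking, SL cohesion checks, boundary rules -
runs on a fixed 0.1-minute tick so that the per-tick probabilities
(`p_form = 0.2`, `p_break = 0.02`) keep their meaning whatever the sweep
calibration. The resolution was chosen so that mechanical relaxation and
cell rearrangement are fast compared with the division and secretion
timescales; at a few thousand sweeps per run the tissue is kinetically
frozen and no intercalation occurs at any workable temperature.

### Connectivity

Cells must remain connected domains. Each retraction is screened by the
standard 3x3 simple-point test (exported as `local_connectivity_guard()`);
a failed test escalates to an exact reconnection check inside a 7x7 window
and the move is rejected only if the cell's neighbors do not reconnect
there. The escalation matters: rough, interdigitated interfaces fail the
local test almost always while the cell body reconnects a site or two
away. Because the constraint only vetoes retractions, locally-ambiguous
configurations are absorbing, and with the bare 3x3 test the dynamics
ratchets into them - in practice ~99% of retraction proposals end up
rejected, cells inflate ~18% above target volume, and mobility becomes
independent of temperature. Released (shrinking) cells are exempt and may
fragment while they disappear.

### Open lateral boundaries

The tissue spans the full grid width. Immutable anchor columns stand 30
sites in from each lateral border, so the outer strips are buffer tissue.
Superficial cells bond their assigned neighbors in a chain and bond an
anchor on contact; a superficial cell whose centroid passes outside an
anchor and is not itself anchor-bonded (or whose remaining neighbors all
are) is released: its bonds and links are cut, its volume constraint is
retargeted to zero, and it shrinks away. Deep cells outside the anchor
with no elastic link are released the same way. If the window below an
anchor empties of deep cells, a fresh target-volume deep cell is seeded
there. Together these rules absorb outflow without letting the tissue
collapse inward - the lateral boundary is neutral, and the measured region
between the anchors behaves like a window onto a much wider tissue.

### Divisions

Every initial cell divides exactly once, at a time drawn uniformly on
(20, 220) minutes - asynchronous, and clear of the first and last
equilibration windows. Division is a midline split: a random axis for deep
cells, always vertical for superficial cells so both daughters keep basal
contact. Daughter target volumes are half the mother's (no growth). One
daughter keeps the mother's id, which keeps single-cell tracks continuous
through division for the pair-expansion metric. The superficial neighbor
chain is repaired locally (daughters bond each other and inherit the
mother's left/right partners); a deep mother's elastic link is dropped and
re-forms within a few ticks through the normal formation rule.

## Calibrated parameters

| parameter | value | meaning |
|---|---|---|
| `temperature` | 10 | Metropolis fluctuation scale |
| `lambda_volume` | 1 | volume stiffness (energy/site^2) |
| `lambda_chem` | 400 | chemotaxis strength (energy per unit conc.) |
| `D`, `k_decay`, `c0` | 25, 0.5, 1 | field transport; decay length ~18 um |
| `p_form`, `p_break` | 0.2, 0.02 /tick | link kinetics (lifetime ~ minutes) |
| `k_spring` | 1.5 | DC-SC spring (energy/site^2) |
| `contact_threshold`, `k_coh` | 3 sites, 2 | SL cohesion restoration |
| `mcs_min` | 0.015 min | sweep time calibration |

The contact matrix is printed by `energy_params()$J`. These values were
fixed by a calibration against the control condition (thinning to about
two layers in 240 minutes with near-balanced bidirectional intercalation)
and then frozen; every scenario, test and the acceptance script uses the
same configuration.

## The in-silico experiments

`scenario_suite()` returns ready configurations: `control` (SL secretion,
chemotaxis on), `chem_off`, `inhibition` (no source anywhere),
`ubiquitous` (every cell secretes at the control level), `ubiquitous_1p3`
(the 1.3x rescue), `localized` (central third of the SL), `mosaic_sl`,
the secretion-level sweep (0.1x-3x), a cohesion sweep over `p_form`,
multilayer (3-5 tiers) and DC-depletion variants, and the two-explant
chemotaxis assays. The explant assays run in dish conditions: clearance is
slower than in the embryo (`k_decay = 0.1`/min), so the gradient spans the
75-um gap between explants; with embryonic clearance the signal would die
within one cell diameter of the source and no assay geometry of this size
could detect chemotaxis.

## What the generator emulates - and what it does not

The initial condition reproduces the tissue architecture the model needs:
one epithelial monolayer at target volume, rectangular deep cells in
regular tiers, a cavity much deeper than the tissue is thick. It does not
reproduce curvature of the real blastocoel roof (the section is flat),
interstitial gaps between loosely packed deep cells, cell-size
heterogeneity, yolk platelets, or any molecular detail of the C3a/C3aR
pathway; the chemoattractant is a single abstract species and the elastic
link stands for any mechanical resistance to DC-SC separation, not
specifically cadherin adhesion. Passing tests therefore show that the
*mechanism* - short-range chemotaxis toward a source-sink gradient plus
neutral open boundaries - produces thinning, expansion and near-balanced
bidirectional intercalation at the measured rates; they do not validate
molecular parameters against the embryo.

## Numerical choices and degenerate inputs

* Tie-breaks: a deep cell linking to "the SC above" uses the SC whose
  footprint covers its centroid column; failing that, the nearest SC
  centroid, then the smaller id.
* Deep-cell division retries a random axis up to 8 times, then falls back
  to a median split along the last axis; a 1-site cell skips division with
  a logged warning.
* `dc_layers = 0` builds an SL resting on the cavity and still runs.
* Measurement columns with no cells are excluded from thickness and layer
  counts (and logged by omission from the output).
* Band-crossing detection uses a hysteresis margin of 0.25 cell diameters
  so that boundary-hugging fluctuations are not double-counted.
* Problem sizes used by the test-suite: the full 240 x 120 section for the
  headline thickness/directionality numbers (10 replicates per condition)
  and a 160 x 90 section with identical cell-scale parameters for the
  ordering and robustness properties (4-10 replicates); the acceptance
  script runs the standard 30-replicate protocol at full size.

## Known limitations

* The tissue is a flat quasi-2D section; spherical-cap geometry, and with
  it any area dilution of the gradient, is not represented.
* The Out/In event fractions sum to exactly 1 by construction, so they
  cannot reproduce independently-normalized percentages that do not.
* The control-versus-ubiquitous thickness difference is small relative to
  replicate noise (~0.1 cell diameters against an SD of ~0.1), so its
  significance test needs the full replicate protocol; at a handful of
  replicates it may not resolve.
* Parameter coupling: `lambda_chem` moves the thinning endpoint and the
  Out/In asymmetry together, so the two observables constrain it from
  opposite sides; the secretion rate (through `k_decay`) sets the
  ubiquitous-expression ratchet and the control gradient at different
  rates, so the decay length cannot be shortened freely. The
  cohesion/link parameters mainly set how faithfully the SL follows the
  deep layer (the thickness ratio of the two), not the total thickness.
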