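---
title: "Methods: a hybrid multiscale virtual tumour"
author: "vtumour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid multiscale virtual tumour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vtumour)
```

# The model

`vtumour` simulates the growth of a vascularized tumour in a thin tissue
(a mouse-ear dermis scale) as a hybrid system of three coupled layers:

1. **A cellular automaton of tumour cells** on a 200 x 200 lattice of
   20 um elements (a 4 x 4 mm domain; one element holds at most one
   cell). Each cell is proliferative (P), quiescent (Q), apoptotic (A) or
   necrotic (N). The default state under physiological oxygen is P. A
   cell arrests (P to Q) when local oxygen falls below the quiescence
   threshold *while the cell is in G1*, its oxygen-sensitive phase; it
   reverts to P when oxygen returns to or above that threshold; any
   living cell necroses below the (much lower) necrosis threshold. Dead
   states are absorbing. P cells progress through G1/S/G2/M and divide on
   completing M if space allows: into a free Moore neighbour, or by
   pushing one neighbour a single step into the second ring; a cell that
   stays boxed in past a retry window enters apoptosis.

2. **A two-tier vasculature**: an *implicit capillary field* `E`
   (baseline `E_0` everywhere) that provides the physiological ground
   level of oxygen and is destroyed locally (set to 0, irreversibly)
   wherever the protease concentration produced by proliferating tumour
   cells exceeds a threshold; and a *discrete vessel network* living on
   the edges and diagonals of the grid elements, composed of the
   segmented microvessels of the initial image plus the neovessels formed
   by sprouting angiogenesis. The per-element vessel weight
   \(W_{ij} = \sum_v (L_b/2 + L_d) + E_{ij}\) couples the network to the
   continuum fields: it measures the local endothelial surface available
   for oxygen delivery and growth-factor uptake (edges are halved because
   they are shared by two elements).

3. **Four reaction--diffusion fields** on the same lattice: VEGF \(V\)
   (produced by quiescent/hypoxic cells, consumed by the vasculature with
   receptor saturation \(\min(V, V_{max})\)), oxygen \(O\) (exchanged
   with perfused vessels at rate \(\gamma_v W (O_v - O)\) and taken up at
   a state-dependent rate \(k_{ij}\): \(k_P = 2k_0\) for P cells,
   \(k_Q = k_0\) for Q, 0 for dead cells, \(k_0\) for normal tissue), and
   two protease species: \(p\) (from proliferating tumour cells,
   degrades the capillary field) and \(m\) (from migrating sprout
   endothelium, degrades the extracellular matrix).

Angiogenesis closes the loop: hypoxic (quiescent) cells secrete VEGF;
lattice nodes of perfused vessels where VEGF exceeds a threshold spawn
sprout tips (stochastically, with a rate increasing in VEGF and a minimum
spacing between origins); tips take biased random steps up the VEGF
gradient (with a preference for degraded matrix), laying neovessel
segments, branching where VEGF is high, and anastomosing on node contact.
Because every sprout is rooted on the perfused network, an anastomosis
(tip-to-vessel or tip-to-sprout) closes a loop that is connected to the
perfused network at both ends, so the joined path is marked perfused and
starts delivering oxygen. Unperfused sprout segments still consume VEGF
(they are endothelium) but deliver no oxygen. Oxygen returning to the
hypoxic regions reverts quiescent cells to the proliferative state, which
is what ultimately restarts growth.

# Units, normalization and two deliberate scale choices

The published parameter table that this model reproduces is internally
inconsistent in two places; both resolutions are explicit, logged, and
exposed in the configuration.

**Oxygen rate group.** The uptake rates (`k_0 = 2.4`, `k_P = 2 k_0`,
`k_Q = k_0`) and the permeability scale (`gamma_v_base = 4.8`, scaled per
segment by \(R/R_{min}\)) are printed in s^-1 while every sibling rate is
in h^-1, and taken literally they would give a capillary-field oxygen
screening length \(\sqrt{D_O/k_0}\) under one micron. Oxygen is therefore
treated as a normalized concentration: the printed numbers are stored
verbatim and multiplied by one conversion constant, `oxygen_rate_scale`
(default 1/24), wherever they enter the dynamics. The default makes the
screening length \(\sqrt{D_O / (k_0\,\mathrm{scale})} \approx 0.155\) mm
-- within the physiological 100--200 um oxygen diffusion
distance -- which is the regime in which a millimetre-scale tumour
develops a broad quiescent core with only marginal necrosis, the
behaviour this model family reports. The intravascular concentration
\(O_v\) is then fixed by requiring intact tissue to sit at \(O = 1\):
\(O_v = (\gamma E_0 + k_0)/(\gamma E_0) = 1.5\) (effective rates).

**Vessel lengths in the coupling.** `vessel_weight()` reproduces the
published formula verbatim in millimetres (one edge contributes
\(dx/2 = 0.01\) mm). Inside the reaction--diffusion coupling, however,
segment lengths are expressed in units of `dx` (edge 1/2, diagonal
\(\sqrt2\)): with lengths in mm and `E_0 = 1`, one vessel edge would
contribute 1% of the capillary baseline, making the entire discrete
vasculature -- and hence angiogenesis -- numerically inert, which
contradicts both the oxygen-above-normal haloes around vessels and the
angiogenic rescue that define this model's behaviour. On the element
scale, one 30 um vessel edge is commensurate with (and, weighted by
\(R/R_{min}\), larger than) the element's capillary bed, which is the
physically sensible ordering.

# Initialization

A virtual tumour is built from two image-like inputs, mirroring the
experimental pipeline:

* **Tumour density.** Three ascending intensity thresholds applied to a
  grayscale fluorescence-style image give three nested masks (low /
  medium / high density); the masks are resized to the computation grid
  by exact area averaging (not nearest neighbour, to preserve density);
  each region is filled stochastically by adding grey-level Gaussian
  noise and re-thresholding at the region's fill quantile, so the
  realized occupancy equals the configured fill rates (defaults
  0.3/0.6/0.9 -- the published procedure specifies the mechanism but not
  the rates). The three occupancy images are summed, only the bulk
  (largest connected component after a 2-element dilation) is kept --
  scattered cells are excluded from the initial tumour -- and every
  occupied element receives a proliferative cell with a uniformly random
  position in its cycle (a desynchronized population). Thresholds are
  per-case values: fluorescence intensity varies between tumours, so they
  are chosen per image, and the synthetic generator emits suggested ones.

* **Vasculature.** Segmented vessel centrelines (>= 30 um diameter) are
  rasterized onto lattice edges/diagonals as 8-connected chains. All
  vessels start at 30 um diameter except a designated reference vessel at
  80 um, whose radius stays fixed. A pressure of 13 kPa is imposed at the
  entry node of the reference vessel and 2 kPa at every vessel endpoint
  on the domain border; Poiseuille flow (conductance
  \(\pi R^4 / 8 \eta L\), constant viscosity) is solved on the graph and
  every free vessel adapts its diameter under a Pries-style stimulus --
  \(\log_{10}(\tau + \tau_{ref})\) for wall shear stress, a metabolic
  term \(k_{met}\log_{10}(Q_{ref}/|Q| + 1)\) favouring poorly perfused
  segments, and a constant shrinking tendency -- iterated to a steady
  state (relative change below 1e-4). The adapted network is the initial
  vascular condition; flow is not recomputed during growth (vessel
  regression and flow-coupled growth are out of scope for this model
  version). Units of flow and viscosity are arbitrary but consistent:
  only the two pressures are physically anchored.

**The synthetic case generator** stands in for the undeposited animal
images: a blob with three concentric intensity zones, an irregular
low-order-Fourier boundary, coarse fluorescence blotches (160 um
granules) and cell-scale speckle -- emulating the very granular, patchy
day-3 fluorescence texture, whose internal voids are what the early
gap-filling growth consumes -- plus a reference vessel crossing the
frame beside the blob with 2--4 secondary vessels branching off it
around the tumour, every polyline reaching the frame border (so the
flow system is well-posed) and one entry point on the border. The day-0
bulk radius is 0.6 mm +/- 10% across cases, consistent with the
millimetre scale of the imaged tumours it emulates. What it does *not* emulate: out-of-plane
fluorescence (the third dimension that makes real day-0 apparent areas
larger), dye leakage, imaging-day registration, or tissue deformation --
so passing tests show the model reproduces the *simulated* behaviours and
mechanisms, not that it would match any particular animal.

# Time stepping and numerics

* Automaton step 1 h. Per step, operators apply in fixed order: field
  update; capillary + matrix degradation; oxygen-driven state
  transitions; cycle progression and the division sweep (randomized cell
  order, to avoid lattice sweep artifacts); lysis of dead cells older
  than the lysis delay; sprout initiation and migration. The order is a
  modelling commitment of this implementation (the source model never
  specifies scheduling); all stochastic choices draw from one seeded RNG,
  so runs are bitwise reproducible.
* VEGF and the two proteases are integrated explicitly (forward Euler,
  5-point Laplacian, no-flux boundaries) with sub-steps at 0.9 x the
  stability limit \(\min(dx^2/4D, 1/\max(\mathrm{rates}))\); negatives
  are clamped after reactions. Explicit updates run on a support bounding
  box that truncates each field where it is dynamically inert (below
  1e-4 of its peak and far below any threshold acting on it) -- a pure
  run-time optimization.
* Oxygen kinetics (minutes) are far faster than cell dynamics (hours), so
  oxygen is solved quasi-steadily once per automaton step (red-black SOR,
  warm-started, tolerance 1e-9); full explicit integration is retained
  as a validation mode and agrees with the steady solve to well under
  0.5%.
* Degenerate inputs: an all-zero oxygen system (no exchange, no uptake)
  is singular and returns a uniform field with a warning; an empty
  occupancy mask has apparent area 0 with a warning; ties (division
  targets, sprout directions) break uniformly at random under the run
  RNG; the variability-minimum day breaks ties toward the earliest day.

# Calibration values and why they are what they are

The published table fixes the diffusion/production/decay/uptake rates;
the constants below are *not* published and are exposed in the config.
They were fixed once, against the source model's qualitative and
quantitative *statements* about its own behaviour, before the acceptance
suite was frozen:

* `O_quiescence = 0.65`, `O_necrosis = 0.05` (in units of the normalized
  physiological level). The arrest threshold sits deliberately just
  below the oxygen level of crowded, fully vascularized proliferative
  tissue: with \(k_P = 2k_0\), dense P tissue over an intact capillary
  bed equilibrates at \(O = 0.75\), so arrest is triggered specifically
  by loss of capillary support, not by crowding alone. With a much lower
  threshold (e.g. half-normal) the tumour's well-perfused fringe
  proliferates indefinitely and the deep avascular collapse this model
  family reports (two thirds of cells arrested within three days, ~90%
  at the avascular trough) cannot occur. Necrosis is an order of
  magnitude lower, making hypoxic cells dormant long before they die.
* `p_degrade = 4200`: the capillary field fails only where tumour
  protease accumulates to the level of a dense multi-row cell mass (a
  compact 3 x 3 mass saturates at p ~ 2000 under the published protease
  rates within its first day; 4200 corresponds to a compact mass of a
  few tens of cells). This puts capillary destruction downstream of
  local *densification*: sparse, freshly seeded regions keep their
  capillary support until gap-filling divisions crowd them, which is
  precisely the reported early behaviour (cells first fill the gaps,
  the tumour becomes denser, and the oxygen resource is exhausted under
  the introduced mass). The cascade of successive zones densifying and
  then choking is what stretches the proliferative-fraction decline
  over the first two weeks.
* `seg_weight_scale = 0.5`: the weight of one lattice-edge of discrete
  vessel relative to an element's capillary bed in the field coupling.
  At equal weight the 80 um reference vessel maintains a perivascular
  oxygen corridor above the arrest threshold that dominates tumour
  growth; at 0.5 a single vessel keeps its cuff of cells alive but
  quiescent, while a plexus of anastomosed neovessels still lifts oxygen
  above the threshold -- vessels rescue collectively, not singly.
* Sprouting constants (`V_sprout = 5e-3`, `sprout_init_rate = 0.004`
  per hour per eligible node at twice the threshold,
  `sprout_move_prob = 0.06` i.e. ~0.03 mm/day tip speed,
  `sprout_branch_prob = 0.12` above twice the sprouting threshold,
  origin spacing 4 elements): set so that angiogenic regulation starts
  to develop after about a week and reaches full effect about ten days
  later, the timing the source model reports for its angiogenic
  bottleneck.
* `R_neo = 12` um neovessel radius; together with the \(R/R_{min}\)
  permeability scaling and `seg_weight_scale` this makes a small plexus
  of neovessels (but not a single stray segment) sufficient to revert
  quiescent cells.
* Cycle: initial duration 24 h (a typical doubling time for the glioma
  line the model emulates), inherited variation sigma = 0.2 h applied to
  G1 only (G1 = mu - 13 h; S = 8, G2 = 4, M = 1 h); lysis delay 48 h;
  blocked division-ready cells retry for 48 h before committing to
  apoptosis -- mitotically arrested cells are still part of the
  proliferative pool while they wait, which is how the early
  proliferative fraction should be read.

# Open design points, resolved

* Oxygen sensing happens every automaton step while the cell is in G1
  (not only on G1 entry).
* Capillary degradation is binary and thresholded (`E` drops to 0), as
  the source model states; graded decay would be an alternative.
* Unperfused sprout segments count in the VEGF-consumption weight but
  not in the oxygen-delivery weight (the two roles of the vessel weight
  are split by perfusion status).
* The capillary field consumes VEGF along with the discrete vasculature
  (both are endothelium); a config switch can restrict consumption to
  segments.
* Pushes displace whatever occupies the neighbour element, including
  dead debris; only one displacement step is ever taken ("beyond the
  first row" read as a single-row push).
* Sprout-sprout fusions are perfused immediately (both partners are
  rooted on the perfused network); a flow solve on the grown network
  would refine which loops actually carry flow, but flow during growth
  is out of scope.

# Problem sizes used by the test suite

The full study conditions -- seven 200 x 200 cases run for 28 simulated
days -- are exercised once, by the acceptance checks and the acceptance
script (a few minutes per case). Unit and property tests run the same
code on reduced configurations (grids of 5--100 elements, days 0--28 on
small grids) chosen so each mechanism is still in its operating regime:
the division rule is checked exhaustively on 5 x 5 patches, flow on
~20-node networks against a dense solve, field properties on 20--40
element grids, and driver invariants (determinism, bookkeeping,
VEGF-gated angiogenesis, update-order robustness) on 100-element grids.

# Known limitations

* 2D only, one cell per element: no compaction, no pressure-modulated
  proliferation, no vaso-occlusion -- the model family's own stated next
  steps, out of scope here.
* The vasculature never regresses; flow is solved only at
  initialization.
* Perfusion-by-connectivity is a topological approximation (no
  hemodynamics on the growing network).
* The experimental fold-change numbers depend on unavailable animal
  images; the package's quantitative claims are about the simulated
  behaviours under the synthetic study conditions.
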