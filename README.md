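# vtumour

A hybrid multiscale simulator of vascularized tumour growth in thin
tissue, for computational oncologists studying the interplay between
hypoxia, angiogenesis and growth kinetics — in particular the
*angiogenic bottleneck*: the period in which tumours of different speeds
converge as angiogenic regulation compensates their differences.

## The model in brief

Three coupled layers on a 200×200 lattice (20 µm elements, 4×4 mm
domain):

* **Cellular automaton of tumour cells** — one cell per element, states
  P (proliferative), Q (quiescent/hypoxic), A (apoptotic), N (necrotic).
  P cells cycle through G1/S/G2/M (cycle time inherited with a truncated
  Gaussian, σ = 0.2 h, G1 absorbs the variation) and divide into a free
  Moore neighbour or by a one-step push; boxed-in cells eventually
  apoptose. Oxygen below a threshold arrests G1 cells (P→Q, reversible);
  far lower oxygen kills (→N).
* **Vasculature** — an implicit capillary density field E (destroyed
  locally and irreversibly by tumour proteases) plus a discrete vessel
  graph on element edges/diagonals. The per-element vessel weight

  $$W_{ij} = \sum_{v\in(i,j)} \left(\tfrac{L_b}{2} + L_d\right) + E_{ij}$$

  couples the network to the fields. Hypoxic cells secrete VEGF; vessel
  nodes above a VEGF threshold sprout; tips chemotax up the VEGF
  gradient and anastomose on contact, becoming perfused oxygen sources.
* **Reaction–diffusion fields** for VEGF V, oxygen O and two protease
  species p, m:

  $$\partial_t V = D_V\nabla^2V + \alpha_V Q_{ij} - \nu_V V - \lambda_V W_{ij}\min(V, V_{max})$$
  $$\partial_t O = D_O\nabla^2O + \gamma_v W_{ij}(O_v - O) - k_{ij}O$$
  $$\partial_t p = D_p\nabla^2p + \alpha_p P_{ij} - \nu_p p, \qquad
    \partial_t m = D_m\nabla^2m + \alpha_m n_{ij} - \nu_m m$$

  with state-dependent uptake $k_P = 2k_0 \ge k_0 \ge k_Q$ and $k = 0$
  for dead cells. Oxygen is solved quasi-steadily (red–black SOR); the
  other fields are integrated explicitly at 0.9× the stability limit.

Initialization mirrors an imaging pipeline: three-level intensity
thresholding of a fluorescence-style image → three cell-density classes
on the grid; vessel centrelines rasterized to the lattice, 13 kPa at the
entry node vs 2 kPa at the domain border, and Pries-style diameter
adaptation to a hemodynamic steady state. A built-in generator emits
synthetic cases (granular three-zone blob + a small vessel arcade) that
stand in for the undeposited animal images.

See `vignettes/virtual-tumour-methods.Rmd` for the full model account,
unit conventions and calibration rationale.

## Worked example

```r
library(vtumour)

params <- model_params()              # published defaults + calibration
case   <- generate_synthetic_case(1)  # granular blob + vessel arcade
run    <- run_simulation(simulation_spec(seed = 101, case = case,
                                         days = 28, params = params))
tail(run$record[, c("day", "n_P", "n_Q", "n_A", "n_N",
                    "effective_area_mm2", "apparent_area_mm2")], 3)
#>    day  n_P   n_Q  n_A n_N effective_area_mm2 apparent_area_mm2
#> 27  26 6350 23250 2398   0            11.8400           13.7956
#> 28  27 6608 23496 2338   0            12.0416           14.0492
#> 29  28 6664 23818 2551   0            12.1928           14.2804
```

Day 0 starts with every cell proliferative; the granular mass densifies,
destroys its capillary support and exhausts its oxygen within days (most
cells turn Q), VEGF from the hypoxic cells triggers sprouting from the
nearby vessels, and perfused neovessels progressively revert quiescent
cells. In this run the proliferative fraction `n_P/(n_P+n_Q)` falls from
100% to 37% by day 3 and bottoms at ~16% around day 14 before
angiogenesis lifts it again. Effective area is living cells × element
area; apparent area is the delineated (closed + hole-filled) outline,
always at least as large.

Batch analyses:

```r
batch <- run_batch(case_seeds = 1:7, seed = 1, days = 28)
pq <- pq_fraction_series(batch$records)       # mean ± SD P fraction by day
curves <- sapply(batch$records, function(r) r$n_P + r$n_Q)
nc <- normalize_curves(curves, days = 0:28)   # integral-normalized growth
bottleneck_day(nc)$day                        # SD-minimum day (the bottleneck)
```

A thin CLI wraps the same functions
(`inst/scripts/vtumour synth|init|simulate|analyze`).

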