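---
title: "Modeling leaf vein canalization with coupled PIN and plasmodesmata transport"
author: "veinsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling leaf vein canalization with coupled PIN and plasmodesmata transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinsim)
```

## The model

Leaf veins appear first as narrow tracks of high auxin concentration
that self-organize out of initially broad auxin distributions -
*canalization*. Two intercellular transport systems contribute: the
polar efflux carrier PIN, whose placement on individual cell faces is
itself regulated by auxin, and plasmodesmata (PD), symplastic pores
whose total cross-sectional area responds to the auxin flux through the
wall. `veinsim` integrates both on a polygonal cell tissue.

For cell $i$ with neighbors $j$, wall quantities $D_{ij}$ (total PD
area, symmetric) and $P_{ij}$ (membrane PIN of $i$ facing $j$,
directed), the four coupled ODE families are

$$\frac{dA_i}{dt} = \mathit{auxpr}\,A_{\mathrm{prec},i}
  - \mathit{auxdec}\,A_i
  + T \sum_j \left(P_{ji}\frac{A_j}{1+A_j} - P_{ij}\frac{A_i}{1+A_i}\right)
  + D \sum_j D_{ij}(A_j - A_i)$$

$$\frac{dD_{ij}}{dt} = \alpha\,\phi^2 + \beta - \gamma\,D_{ij}$$

$$\frac{dP_i}{dt} = \mathit{pinpr}\,A_i - \mathit{pindec}\,P_i
  - \sum_j \frac{dP_{ij}}{dt}$$

$$\frac{dP_{ij}}{dt} = k_U \frac{P_i\,f(A_j)}{1+P_i}
  + \frac{P_i}{1+P_i}\left(k_{Wq}\,\phi_+^2 + k_{Wl}\,\phi_+\right)
  - k_{\mathrm{off}} P_{ij}, \qquad f(A) = \frac{100A}{100+A}$$

The net wall flux $\phi$ (PIN-carried plus PD-carried) is *frozen at the
start of each time step* and every right-hand side is evaluated against
it. The PD equation feeds on $\phi^2$ (sign-independent: a wall
canalizes whichever way auxin flows through it); the with-the-flux (WTF)
PIN terms use the outward-rectified flux $\phi_+ = \max(0, \phi_{ij})$
for the membrane side $i \to j$, so only efflux recruits PIN to a face -
a signed linear term would strip PIN below zero from backflow faces, and
transporter-feedback models of this family allocate on efflux only. The
up-the-gradient (UTG) term ($k_U$) allocates PIN toward
higher-auxin neighbors and underlies convergence-point formation; both
allocation routes draw on the shared cytoplasmic pool $P_i$ through the
saturating factor $P_i/(1+P_i)$, which makes faces compete when the pool
runs low.

Auxin production is marginal: zone Z1 (distal, primary vein) carries
precursor $A_{\mathrm{prec}} = 0.5$ from $t = 0$, ramping by $10^{-4}$
per second; the lateral Z2 zones (secondary veins) switch on at
2 h 45 m with the same ramp. Basal sink cells, standing in for the
plant's existing vasculature, decay auxin at `auxdecSink` = 10/s - the
sources say only "strong" decay, so the value is configurable; 20x the
bulk rate is strong enough that sink cells stay near zero auxin without
dominating the global dynamics more than necessary.

Units are computational: seconds, amount/cell, cell widths (roughly
9 um in a developing leaf). Computational time maps to biological time
by about a factor of 10 (`timeScale`), used only in reporting. At the
reference parameters (see `?pinpdParams` for the full table) two
analytic anchors hold: the flux-free PD steady state is
$\beta/\gamma = 0.6$, and the background wall permeability is
$D \cdot \beta/\gamma = 0.48$ cell/s.

```{r anchors}
p <- pinpdParams()
pdSteadyState(p)
backgroundWallPermeability(p)
```

## Scenario presets

Biological perturbations enter as parameter changes
(`resolveScenario()`):

| scenario | change | biology |
|---|---|---|
| `WT` | none | normal development |
| `NPA_MODERATE`, `NPA_STRONG`, `PIN_PAT_I` | $T$ = 2, 1.5, 0 | graded pharmacological/genetic inhibition of PIN transport |
| `CALS3`, `GSL8` | $\beta/\gamma$ = 0.3, 1.2 | narrower / wider PD aperture mutants |
| `*_NPA` combos | both | aperture mutants under full transport inhibition |
| `IAA_*` | initial $A_\mathrm{prec} = 2$ | exogenous auxin application |

$\beta/\gamma$ targets are set through $\beta$ with $\gamma$ fixed, so
the PD relaxation timescale $1/\gamma$ is identical across genotypes and
only the background PD level differs.

## Numerical scheme

The integrator is explicit first-order (Euler) with the flux-freezing
rule above. The auxin transport operator is stiff: already at the
background wall permeability the Gershgorin row bound on a 4-neighbor
cell is $\mathit{auxdec} + 8 \cdot 0.48 \approx 4.3$/s, and canalized
walls reach PD areas tens to hundreds of times the background, so no
fixed step of order 1 s is stable. `advance()` therefore subdivides each
reporting step into equal Euler substeps sized so that
$h \cdot \lambda_\mathrm{max} \le 0.9$ with $\lambda_\mathrm{max}$
bounded row-wise by decay + outgoing + incoming transport rates
(the PIN term linearized as $T P_{ij}/(1+A_i)^2$). Keeping the
amplification factor of every mode positive avoids sign-alternating
transients, which matters here because the $\phi^2$ terms would rectify
oscillation noise into spurious PD and PIN growth. The flux is re-frozen
at each substep; `advance(adaptive = FALSE)` takes the literal single
Euler step and is what the test suite compares against an independent
straight-line transcription of the equations (agreement to 1e-12
relative per step). Non-finite state aborts with the offending cell or
wall named. All state variables are floored at zero after each substep:
concentrations and areas are physical quantities and an explicit step
can overshoot.

Initial conditions: auxin, cytoplasmic and membrane PIN all zero, every
wall at the flux-free PD level $\beta/\gamma$, so early transport is
isotropic and every anisotropy is an emergent property of the run.

## Tissues

Three representations, all built on shared nodes with polygonal cells,
walls derived from shared edge runs (collinear intermediate nodes merge
into a single wall of summed length), and an ordered margin cycle:

* `makeSquareGrid(nx, ny)` - unit cells, 4-neighbor walls. The standard
  *surrogate leaf* used in the tests is 21 x 20 with a 3-cell distal Z1,
  2-cell lateral Z2 pairs at 60% height and a 3-cell basal sink: the odd
  width gives the midvein a symmetric center column, and the ~19-cell
  source-to-sink path sits in the 15-20 cell range that the timing
  claims presume.
* `makeIrregularLeaf(nCells, seed)` - Voronoi tessellation of a leaf
  outline (tapered oval, 18 x 13 cell units) with Lloyd relaxation;
  areas vary about two-to-three-fold, edges shorter than 0.05 cell
  widths are collapsed (degenerate Voronoi slivers destabilize growth
  and carry no meaningful wall). Deterministic per seed.
* `importVirtualLeafXML(path)` - reads the nodes/cells XML dialect of
  VirtualLeaf-style geometry files, with zone labels from `cell_type`
  attributes or a zone rule.

Transport is deliberately *not* scaled by wall length: $P_{ij}$ and
$D_{ij}$ are per-wall totals, avoiding the artifact of favoring flow
through long walls that plagues length-proportional diffusion on
irregular meshes. Wall length is kept for geometry, rendering and
division bookkeeping only.

## Growth and division

Optional growth increases each cell's target area by its zone-class rate
(fraction of the birth area per computational hour: 0.2 for
auxin-producing cells, 1.4 for Z2 before activation, 0.6 elsewhere).
Node positions relax toward targets by a deterministic local scheme -
each cell pushes its nodes radially by the square-root area mismatch,
nodes average the pushes of the cells sharing them - with three
safeguards: short-edge repulsion, per-node displacement caps at a
fraction of the shortest incident edge, and step-damping until every
polygon stays simple (zero movement is the fallback for an event). The
relaxation is therefore conservative: under conflicting pushes cells
grow slower than their nominal rates, which affects timing, not the
patterning claims tested. Cells divide on doubling their birth area,
split through the centroid perpendicular to the longest principal axis;
daughters inherit the mother's per-cell values unchanged (state is
amount/cell; whether the original implementation dilutes on growth is
not stated, so no dilution is applied), outer-wall PD and directed PIN
partition length-proportionally, and the new wall starts at
$\beta/\gamma$ with no PIN.

## Metrics

The biological readouts are operationalized as follows; none of these
numeric rules is stated by the model's sources, so thresholds are
package choices and configurable.

* **Strand**: cells with $A \ge \theta \cdot \max A$ over cells that
  are neither source nor sink ($\theta = 0.3$), filtered to connected
  components touching a production zone. Sink cells are excluded because
  their auxin load is an inflow/decay balance at a boundary condition,
  not patterning.
* **Convergence points** (`detectCPs()`): prominent local maxima of
  auxin over the margin cycle near a zone, merged by prominence - a peak
  joins a higher one when a margin arc between them never dips more than
  5% (relative) below it. On near-symmetric tissues one convergence site
  shows two near-equal peaks flanking the drained vein head (shallow
  dip: one CP), genuinely split CPs are separated by deep dips, and
  low-amplitude margin ripples are absorbed. An earlier candidate rule -
  requiring net PIN flux toward the peak from both margin neighbors -
  proved inconsistent with the simulated dynamics: the convergence
  target of the PIN field is drained by its own vein, so the flux
  criterion and the auxin-maximum criterion never hold simultaneously.
* **Extension**: farthest strand cell's normalized projection on the
  axis from the Z1 centroid to the sink centroid; `timeToSink` is the
  first snapshot whose strand contains a sink-adjacent cell.
* **PD anisotropy**: mean PD area over strand-internal walls divided by
  mean over strand-boundary walls; exactly 1 for any fresh state.
* **Strand width**: mean strand-cell count per axis band one typical
  cell diameter deep.

## What the simulations reproduce

On the square surrogate (all deterministic, `dt = 1`): normal
conditions form one convergence point and a canalized midvein reaching
the sink at about 2.6 computational hours; quadrupled source precursor
splits the CP in two; PD-only transport leaves the sink untouched at
15 h with strands about 60% of the way down the axis and PD anisotropy
rising roughly 3.5-fold between 5 h and 15 h; the aperture series at
matched time orders anisotropy 0.3 > 0.6 > 1.2 (ratio
$\beta/\gamma$) with the 1.2 strands widest; and graded transport
inhibition slows sink contact monotonically (T = 6, 2, 1.5) while T = 2
shows an extra CP. These are the quantities `scripts/acceptance.R`
recomputes.

The margin PIN-efficiency constant $C = 0.833$ is inherited from the
predecessor PIN-only model without a stated placement. We examined three
placements on the surrogate: multiplying $T$ on producing-margin to
interior walls makes the source's flanks the cheap exits and produces
twin flanking veins with an auxin hole under the zone; multiplying on
all margin-interior walls turns the margin ring into a trapped highway
that carries auxin around the blade; damping margin-margin walls
stabilizes the midvein but suppresses the exogenous-auxin CP split.
Since no placement is clearly the inherited one and each distorts at
least one documented phenotype, the default is `cMarginPlacement =
"off"` with both placements available for exploration.

## Synthetic tissues versus real leaves

The generator reproduces the geometric features the dynamics care about
- cell-scale granularity, two-fold area variation, a closed margin,
zone layout and a source-to-sink path of 15-20 cells - but not
epidermis/mesophyll layering, realistic margin serration, anisotropic
cell shapes, or mechanical stress fields. Tests passing on these
tissues show the transport feedbacks self-organize as claimed under
idealized geometry; they do not validate the model against imaged
leaves, measured auxin levels or PD permeability profiles, and the
absolute timescale is calibrated only loosely (factor ~10) to
development.

## Known limitations

* Stochastic transport noise, apoplastic diffusion, influx carriers
  (AUX1/LAX, ABCB) and intracellular auxin signaling are out of scope.
* The sink-wall PD areas grow large late in sink-connected runs (all
  production funnels through a few walls); the adaptive substepping
  keeps this stable but such runs dominate compute time.
* The growth engine trades rate fidelity for robustness (see above) and
  uses simplified area-pressure relaxation, not vertex mechanics.
* Convergence-point counting near its 5% prominence threshold can be
  sensitive for conditions that sit close to a patterning bifurcation
  (the moderate-inhibition dip is ~6-7%).
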