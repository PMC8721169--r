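---
title: "Methods: hybrid logic-ODE simulation of Delta-Notch patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid logic-ODE simulation of Delta-Notch patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexnotch)
```

## The two-layer model

`hexnotch` simulates a fixed epithelial sheet as a hexagonal grid of cells.
Each cell carries a quantitative six-species ODE model of the Delta-Notch
cascade; the tissue couples cells through a discrete logic layer. The
coupling is deliberately coarse: a cell's Delta read-out `D` is binarized at
a quantization threshold `Th` (`C = 1` iff `D >= Th`), and the ligand input
`DE` a cell receives is a *quorum function* of the binarized values in its
neighbor ring — `DEmax` when at least `theta` cells at exact hexagonal
distance `dist` are Delta-positive, zero otherwise. The modeling assumptions
behind this design:

* receptor-ligand contact is effectively saturating: a cell either receives
  ligand (`DE = DEmax`) or does not, so the unknown binding kinetics between
  cells need not be parameterized;
* cells are fixed — no movement, division or death — and interact only
  through the logic layer;
* a position-only input (the Wnt field) may additionally modulate each
  cell's kinetics, constant in time.

Within one *epoch* (the interval between consecutive threshold crossings)
every `DE` is constant, so the tissue is a smooth block-diagonal ODE system.
The engine therefore advances all cells as one stacked system with a
stiff-capable solver (`deSolve::lsodar`), lets the solver's root finder
locate the earliest crossing of `D - Th` by any cell (either direction),
commits the crossing events, refreshes the logic matrix and all inputs, and
repeats. Because inputs are frozen within an epoch this is exact — not an
operator-splitting approximation — and it keeps all cells synchronized in
quantitative time (hours). This is also why the hybrid scheme scales: the
tissue never needs a smooth model of cell-cell communication, and the
per-epoch system, though large, is block-diagonal and non-stiff in the
reference parameter regime.

## Grid geometry

Cells are addressed externally by 0-based `(row, col)` pairs in the "odd-r"
offset convention (odd rows shifted half a cell right); internally
coordinates are axial, which makes graph distance a closed form and ring
enumeration cheap. An interior cell has `6 d` neighbors at distance `d` —
6, 12, 18 for `d` = 1, 2, 3.

Boundary conditions mitigate edge artifacts: `bounded` grids simply truncate
rings at the border; `cylindrical` grids (the default, used by all bundled
scenarios) join the lateral borders with a single fold; `toroidal` grids
join both pairs. Two choices here were genuinely open:

* **Cylindrical wrapping acts on the column axis** — the fold joins the
  lateral borders, so patterns are periodic across columns.
* **Toroidal grids require an even number of rows.** Wrapping an odd number
  of offset rows flips row parity across the seam and silently corrupts
  adjacency; such configs are rejected rather than patched.
* On small wrapped grids two lattice images can alias onto one cell; rings
  are deduplicated (a neighbor presents its ligand once) and membership is
  filtered by true wrapped distance.

## The intracellular cascade

The six equations are listed in the README and in `?dn_rhs`. Structural
points worth noting: total membrane Notch is conserved (`Ntot`), so the
cleavable pool is `Notch_free = Ntot - NC - NN VN/VC`; both transcription
terms are Hill functions with exponent `nH = 2` (activation of Hes by
nuclear NICD, repression of Delta by nuclear Hes); Delta mRNA is the final
read-out (translation would only delay the response); and the optional Wnt
input multiplies the Hes transcription term by the repression factor
`KW^nW/(KW^nW + W^nW)`, implementing a concentration-dependent inhibition of
NICD transcriptional activity. The functional form of this inhibition is a
package design choice (mechanism known, equation not); `nW = 2` mirrors the
model's other Hill coefficients.

A numerical guard: `Notch_free` is evaluated as written and may transiently
dip marginally below zero at coarse tolerance, so the cleavage flux uses
`max(Notch_free, 0)` — a negative excursion must not fabricate Notch.

## Parameters

The package ships a reference parameter set (`kinetic_params()`), in
consistent arbitrary concentration units (nominally nM) and hours. It is an
artifact-chosen set, fully config-overridable, not a measured one. It was
calibrated once, at design time, to satisfy four qualitative constraints
that define the lateral-inhibition regime:

1. **Threshold bracketing.** `Th = 3` sits strictly between the stimulated
   Delta fixed point (`~1.6e-4` under `DE = DEmax`) and the unstimulated one
   (`ktD/muD = 10`), so both crossing directions are reachable.
2. **Two-cell bistability.** With `dist = 1`, `theta = 1`, the asymmetric
   state (one Delta-positive, one Delta-negative cell) is a fixed point.
3. **Naïve transient.** Starting from random initial conditions the tissue
   should first pass through an all-Delta-negative state. This requires a
   separation of timescales: Delta must track its transcriptional target
   quickly (`muD = 1/h`) while the repressor arm clears slowly
   (`muN = muHmRNA = muHp = 0.3/h`). Then every cell with appreciable
   initial Hes/NICD load — or any Delta-positive neighbor — dips below `Th`
   within a couple of hours, and cells are released from repression only
   hours later, in the order of their Hes clearance, from which the
   salt-and-pepper pattern nucleates.
4. **Strong, sharp repression.** `KD = 0.1` (against a stimulated nuclear
   Hes level of ~25) makes Delta repression effectively switch-like, so
   fates are crisp.

The quorum rule's `DEmax = 10` and `Th` live with the kinetic parameters
and can be overridden per rule. The Hill exponent `nH` is fixed at 2 in the
reference model and exposed only for sensitivity exploration.

## Random initialization

`init_states()` draws every species of every cell independently and
uniformly from per-species `[low, high]` ranges, reproducibly from the run
seed. The default ranges span the envelope of the two cell-autonomous fixed
points (unstimulated and fully stimulated) — a biologically plausible
"anything between resting and fully signaled" prior. This generator emulates
an unsynchronized tissue with heterogeneous signaling histories. It does
*not* emulate spatially correlated initial conditions, stochastic gene
expression during the run, or parameter heterogeneity between cells —
passing tests therefore demonstrate the patterning logic of the model, not
robustness of real epithelia to those noise sources.

## Numerical choices

* **Tolerances.** Solver defaults `rtol = 1e-6`, `atol = 1e-9`; tests that
  compare against closed forms tighten them. Event location uses `lsodar`'s
  root finder, which refines crossings to solver precision.
* **Simultaneous crossings.** All armed cells with `|D - Th| <= 1e-8 Th` at
  the stopping time are committed in the same epoch (symmetric twins cross
  together). Ties are broken in the event *log* by row-major cell order
  only; the state update is order-independent.
* **Chattering guard.** A cell whose epoch starts inside the hysteresis
  band `|D - Th| < 1e-6 Th` (as right after its own crossing) is re-armed
  only on leaving the band, and its logic value is refreshed at the exit
  side. This prevents zero-length epochs at grazing contact and costs at
  most a `1e-6 Th`-wide displacement of a recrossing.
* **Equilibrium.** "Grid equilibrium" is declared after an event-free
  window of `equilibrium_window` hours (default 50) *and* a maximal state
  derivative below `1e-6 ktD` at the window's end; otherwise integration
  continues to `t_max` (default 500 h).
* **Degenerate inputs.** `t_max = 0` returns the initial state; a quorum
  exceeding the largest ring size warns (the rule can never fire) but runs;
  a one-row grid asked for a row-wise Wnt gradient gets a zero field with a
  warning; `Th >= ktD/muD` is rejected outright.

## Scenario presets and scale

The bundled presets use a 20 × 20 cylindrical grid: nearest-neighbor
lateral inhibition (`dist = 1`, `theta = 1`), a long-range quorum rule
(`dist = 3`, `theta = 10`), and the Wnt gradient. For the Wnt scenario the
amplitude `Wmax = 120` was derived from the fixed-point algebra: the
stimulated Delta steady state exceeds `Th` once the Wnt factor drops below
~0.0062 (`W > ~63` with `KW = 5`, `nW = 2`), so a linear 0–120 gradient puts
the transition mid-grid. High-Wnt rows cannot build the Hes repressor and
therefore end *uniformly Delta-positive* — undifferentiated in the sense
that no fate mosaic forms — while low-Wnt rows show the salt-and-pepper
independent-set structure; a boundary row pinned by its uniformly positive
neighbors stays Delta-negative. The package's tests assert exactly this
mechanism-consistent zone structure.

The test and acceptance workloads use 6 × 6 and 20 × 20 grids with five
seeds for the full-scale scenario and tiny (up to 2 × 2) tissues for
brute-force oracle comparisons; these sizes are the package's chosen
reference workloads and keep a full verification run in the minutes range
on a single core.

## Known limitations

* The logic layer is Boolean; logic values are stored as small integers so
  a multivalued extension would not change interfaces, but graded `DE`
  (e.g. proportional to the positive-neighbor count) is not implemented.
* Rules evaluate one exact ring, not a disk or an arbitrary Boolean formula
  per cell.
* No cell movement, division, stochastic kinetics, or asynchronous discrete
  updating — the engine's semantics are exactly the event-driven
  piecewise-smooth hybrid system described above.
* Long-range quorum rules (`dist = 3`, `theta = 10`) are reported by the
  pattern metrics but the maximal-independent-set interpretation is specific
  to `theta = 1`; for larger quorums the same conditions are checked with
  the quorum generalization (`< theta` positives around positives,
  `>= theta` around negatives).
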