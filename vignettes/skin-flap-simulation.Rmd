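---
title: "Simulating basic skin surgery on a two-tier mass-spring lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating basic skin surgery on a two-tier mass-spring lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flapsim)
```

## The model

flapsim simulates a rectangular patch of layered skin as a **two-tier
triangular-prism mass-spring lattice**. Three congruent triangulated point
grids represent the skin surface (SURFACE, z = 0), the dermis–fat interface
(INTERFACE, z = −2 mm by default) and the bottom of the subcutaneous fat
(BASE, z = −6 mm). Each surface triangle is extruded into a TOP prism
(epidermis + dermis) and a BOTTOM prism (fat). Springs are derived from the
prisms:

* **HORIZONTAL** springs along the triangle edges of each plane,
* **VERTICAL** springs between vertically corresponding vertices of
  adjacent planes,
* **DIAGONAL** springs along both diagonals of every rectangular prism side
  face (cross-bracing), deduplicated across shared faces.

Every spring is Hookean with axial viscous damping: for endpoints $x_a,
x_b$ with unit axis $\hat u$, the force on $a$ is

$$ f_a = \left[\,k\,(\lVert x_b-x_a\rVert - L_0) \;+\;
   c\,(\dot x_b-\dot x_a)\cdot\hat u\,\right]\hat u, \qquad f_b = -f_a . $$

Rest lengths $L_0$ equal the as-built distances, so a fresh lattice is in
exact equilibrium. All lengths are in millimetres; masses, stiffnesses and
damping are in consistent arbitrary units because only settled
(quasi-static) configurations are interpreted, never transient motion.

### Pre-tension: why wounds gape

Living skin is under tension, so incisions gape. The simulator reproduces
this by shortening the rest length of every SURFACE-plane horizontal
spring to 90% of its current length (`apply_pretension(lattice, 0.9)`).
The sheet then carries baseline tension; cutting releases it locally and
the wound edges retract. With factor 1.0 the mechanism is disabled and
cut edges barely move — a property the test suite checks explicitly.

### Integration and the quasi-static discipline

Dynamics use semi-implicit (symplectic) Euler: velocities are updated from
the accumulated forces, then positions from the new velocities. The
defaults (`sim_config()`): time step 0.005 s, velocity tolerance
10⁻³ mm/s, displacement tolerance 10⁻⁴ mm, at most 60 000 steps per
relaxation (a mobilized rotation flap creeps for roughly 45 000 steps
before settling below the velocity tolerance). Convergence requires both
tolerances to hold for ten consecutive steps; a single slow step can be
an oscillation turning point, not equilibrium. Axial spring damping does
not act on transverse (bending) motion, so a small global viscous drag
(2 s⁻¹ by default) is applied to velocities; it vanishes at rest and
therefore changes no equilibrium, only the settling time. With the
default constants (horizontal/vertical stiffness 100, diagonal 50,
damping 5, unit masses) the scheme is comfortably inside its stability
region and total mechanical energy decreases monotonically per step,
which the suite verifies on randomly perturbed lattices.

Every surgical action — a cut, a forceps move, one suture tightening
decrement — is followed by `relax()` before the state is inspected. The
package therefore reproduces settled behaviours (wound gaping, flap
movement, closure) and makes no attempt to match any particular real-time
transient.

## Surgical operations

**Vertical cutting** follows a planned SURFACE path. Each interior path
vertex (every vertex, for closed outlines) and its INTERFACE counterpart
are duplicated; prisms on one side of the path are reassigned to the
duplicates. The spring set is then re-derived from the elements: pairs no
longer backed by a prism are severed, newly required duplicate-side pairs
are created inheriting the ancestral spring's constants and (possibly
pre-tensioned) rest length. Cuts therefore reassign, never delete:
element counts are conserved and vertex ids are stable for the life of
the lattice (deleted entities are tombstoned, never renumbered, so event
scripts stay valid). Open-path endpoints are never duplicated — the cut
tapers, as a scalpel stroke does. `through_thickness` outlines also split
the fat tier and BASE plane, so a closed through cut turns the enclosed
block into its own connected component.

**Undermining** (the horizontal cut) frees a flap from its bed: every
INTERFACE vertex whose incident top-tier prisms all lie in the region is
duplicated, top prisms keep the original and bottom prisms take the copy.
The flap's underside is then free while its boundary — the pedicle —
remains attached.

**Excision and forceps.** `excise()` verifies by graph search that the
planned specimen (the excised block plus the fat directly beneath it) has
no remaining spring to the surrounding tissue, labels it detachable and
unpins its BASE vertices. Forceps interaction is a rigid handle: a grabbed
prism or specimen stores per-vertex offsets from a movable target point;
moving the handle translates all vertices rigidly while they are excluded
from force integration (kinematic, as if held). Removal tombstones the
specimen.

**Suturing.** A suture is a temporary spring of 10× horizontal stiffness
whose rest length steps down a strictly decreasing 5-stage schedule to a
closure epsilon of 0.05 mm, relaxing after each decrement. Damping of the
constraint is set near critical for the pair so each pull settles without
ringing. A pair is CLOSED once its distance is within the 0.1 mm closure
tolerance; closed pairs are permanently welded so later stages cannot
reopen them. If the elastic schedule alone cannot defeat the surrounding
tension, the final step ties the knot: the free vertex is pinned at the
anchor, the tissue relaxed, and the weld applied — the discrete analogue
of a surgeon holding the stitch while tying.

Two closure modes reflect how real flaps behave: in **simple elliptical
closure** both wound edges pull towards each other (BOTH_PULL). In the
rotation and H-flap procedures the defect edge is **fixed** and only the
free flap edge travels (ANCHOR_FIXED) — the anchor is pinned while the
constraint is active, so the defect edge stays put to within the
displacement tolerance over the whole closure.

**Rigidity** for apposition testing uses shape matching rather than stiff
springs: the chain's reference geometry is stored and, every step, the
chain is projected onto the best rigid fit (translation + rotation, via
the Kabsch/SVD solution) of that shape to the current positions. This
guarantees the isometry that "a rigid edge" implies, independent of the
time step. `apposition_test()` rigidifies the rotation flap's leading
edge, draws the flap toward the defect with reduced-stiffness trial
constraints, reports the residual gap per pair, and restores the prior
state.

## The three incision plans

Plans are parametric reconstructions laid on the lattice by sampling a
continuous template and snapping to surface vertices (nearest-vertex
sampling, shortest-path stitching over the horizontal spring graph, then
shortcut smoothing for open paths).

* **Elliptical (fusiform) closure** — closed outline with a 3:1
  long-to-short axis ratio (the standard excision convention), long axis
  along the Langer-line direction; opposing mid-wound vertices are paired
  for suturing, ordered wound-centre outward.
* **Bilateral advancement (H) flap** — a square defect with four limb
  incisions extending from its corners along the advancement axis; the
  two rectangles between limb pairs are undermined and advanced; the
  lateral defect edges appose across the defect and the limb incisions
  close vertex-to-duplicate. The non-advancing superior/inferior defect
  edges are the fixed edges.
* **Semicircular rotation flap** — an approximately triangular defect
  whose base lies on a circle of the arc radius, with an open arc
  incision (default sweep 180°) from the defect's base corner; the
  crescent between arc and defect is undermined and rotated; the leading
  edge (rigidified during apposition) sutures to the fixed far defect
  edge, and the donor arc closes vertex-to-duplicate.

Interaction gating mirrors guided training: each stage exposes only its
plan vertices (`interaction_gate()`), and off-plan or out-of-stage events
are rejected with feedback, leaving the tissue state hash untouched.
The staged controller runs ASSESS → MARK → INCISE → EXCISE_SPECIMEN →
UNDERMINE → REMOVE_SPECIMEN → APPOSE → SUTURE → COMPLETE, skipping stages
a plan does not need (elliptical closure has no undermining or apposition
test); stages auto-advance when their completion predicate holds, which
makes completion objective and testable.

## Design choices where the design was open

* **Triangulation.** The grid quads are split along alternating
  (union-jack) diagonals. A single consistent diagonal orientation makes
  the surface graph metric anisotropic: snapped paths running against the
  diagonal can only staircase, inflating a semicircular arc's polyline
  length by ~27%. With alternating diagonals plus shortcut smoothing the
  snapped arc is within ~5% of the continuous length on a 2.5 mm lattice.
  Spring derivation is from elements, so no other component depends on
  the split orientation.
* **BASE pinned.** The bottom of the fat is fixed by default; it anchors
  the patch the way deep tissue anchors skin, and stabilizes relaxation.
  Configurable at build time.
* **Suture pairs for incision-line closure** (H-flap limbs, rotation
  donor arc) are stored as a pair with `free == anchor`; the free side
  resolves to the vertex's cut-time duplicate when the suture is placed.
  Plans must reference vertices that exist at planning time, and the
  duplicates do not exist until the cut.
* **Welding closed pairs** trades a little physical fidelity (a real
  stitch is elastic) for unconditional stability of all later stages.
* **Degenerate springs.** Coincident endpoints (freshly duplicated cut
  vertices) have no defined axis; the force is zero for that step.
* **Event vocabulary.** Touch gestures are abstracted to discrete events
  (MARK, CUT, UNDERMINE, GRAB/MOVE/RELEASE/REMOVE, APPOSE, SUTURE_PLACE,
  SUTURE_TIGHTEN, ADVANCE, TOGGLE_LANGER) so whole sessions replay
  deterministically from JSON-lines scripts; the state hash quantizes
  positions at the displacement tolerance before digesting, making
  determinism checks robust to sub-tolerance floating-point jitter.

## Fixtures, problem sizes and what the tests show

`generate_fixture()` provides deterministic scenes: TINY (6×6 cells,
30 mm patch) sized so brute-force oracles — exhaustive spring
enumeration, BFS connected components, explicit set-membership gating —
stay exact and fast; DEFAULT (20×20 cells, 100 mm patch, 1323 vertices,
~9500 springs) exercises realistic flap geometry. Golden event scripts
replay each procedure end to end; the suite checks that they terminate in
COMPLETE with every suture closed and the specimen removed, twice, with
identical state hashes, and that deleting a required event stalls at
exactly the expected stage.

The generator emulates a flat pre-tensioned patch with idealized,
noise-free geometry. It does not model curved anatomy, skin
heterogeneity or anisotropy (Langer-line direction is a single constant
field per scene), viscoelastic creep, or self-collision of folded tissue.
Passing tests therefore demonstrate the mechanics and topology of the
simulator — gaping proportional to pre-tension, flap mobilization and
closure kinematics — not quantitative agreement with any particular
patient's tissue.

## Known limitations

* Forceps motion is translation-only; rotating grabbed tissue is not
  modelled.
* Arbitrary free-hand cuts are unsupported: cut paths must come from a
  plan, and gating enforces this.
* The integrator is explicit; extremely stiff user configurations can
  require a smaller time step (divergence is detected and reported, not
  raised).
* Suture mechanics are a constraint abstraction: no thread, knots or
  stitch-spacing physics, and no dehiscence.
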