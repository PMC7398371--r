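---
title: "Virtual deployment of braided flow-diverter stents: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual deployment of braided flow-diverter stents: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Braided, self-expanding intracranial stents (the LVIS family and similar
flow diverters) are deployed across wide-necked aneurysms to redirect
flow away from the sac.  Whether a given device in a given artery will
appose the wall and how densely its braid covers the neck are geometric
questions that must be answered *before* any hemodynamic (CFD)
simulation: the CFD mesh is built around the deployed wire geometry.
`fvstent` produces that geometry by a fast, kinematic virtual-stenting
procedure in three stages:

1. **Centerline.** A parent-artery centerline is extracted from the
   watertight lumen surface by maximal-inscribed-sphere marching.
2. **Expansion.** A cylindrical simplex-style deformable tube is
   initiated along the centerline and grown radially until it apposes
   the wall, with adaptive (geometric) step control.
3. **Braid mapping.** A 16-wire helical braid is laid out in the tube's
   (station, angle) parameter grid, mapped onto the deployed surface,
   and swept into watertight wire solids ready for CFD meshing.

Everything downstream of the lumen surface is deterministic: identical
inputs and configuration reproduce identical geometry bit for bit.

## Deployment model and its assumptions

The expansion is *kinematic*, not a mechanical force balance.  Published
simplex-mesh stenting methods drive the surface with internal/external
force terms; their exact force law is not reproducible from the device
facts alone, and a force balance adds solver state that is hard to make
deterministic.  This package instead contracts the observable behaviour
— expand until apposition — directly:

* **Phase 1 (adaptive).** All vertex radii grow by a fixed factor
  `growth_factor` (default 1.3) per step while every vertex is more than
  one step away from its wall.  The number of uniform steps is bounded
  by `ceil(log(R_wall / initial_radius) / log(growth_factor))`, which is
  what makes the method fast: a crimped 0.5 mm tube reaches a 2.25 mm
  vessel wall in at most 6 uniform steps.
* **Phase 2 (per-vertex).** Each active vertex advances radially by
  `min(remaining wall distance − contact_tolerance / 2, step)` and
  freezes ("contacted") once its wall gap is at or below
  `contact_tolerance`.  The half-tolerance approach target keeps the
  realized gap strictly inside the tolerance even though the wall is a
  chordally discretized triangle mesh.  A tangential Laplacian pass
  (weight `smoothing_weight`, over the three simplex neighbors: ring
  left, ring right, and one axial neighbor alternating with parity)
  regularizes the front; it only ever raises a lagging radius, so the
  per-vertex radius is non-decreasing across iterations and never
  penetrates the wall.
* **Free-diameter cap.** A braided stent opens no further than its
  labelled diameter, so radii are capped at `free_diameter / 2`
  (2.25 mm for the modelled 4.5 × 23 mm device).  In an oversized
  vessel the deployed diameter therefore equals the labelled diameter.
* **No foreshortening.** Real braids shorten axially as they expand.
  This model deliberately neglects foreshortening — stations stay fixed
  on the centerline — so the deployed axial length equals the labelled
  length exactly.  This mirrors the simplification commonly made in
  fast virtual stenting and is a known limitation.
* **Rigid wall.** The vessel does not deform (consistent with
  rigid-wall CFD downstream).

Contact queries are exact first-hit ray casts against the lumen
triangles.  Because each vertex moves along a fixed radial ray from its
station center, the wall coordinate per vertex is computed once and the
whole expansion reduces to monotone scalar updates — this is the main
reason a deployment takes well under a second.

## Centerline extraction

The lumen's medial curve is approximated by greedy
maximal-inscribed-sphere marching: from seed A toward seed B, each step
of length `0.5 × local inscribed radius` moves in the direction, inside
a 60° forward cone around the previous direction, whose landing point
maximizes the distance to the wall.  The polyline is then Laplacian
smoothed (10 iterations, weight 0.5) and finally *re-centered*: each
interior point is moved within the plane normal to its tangent by a
deterministic pattern search that maximizes wall distance.  Re-centering
runs after smoothing because smoothing alone leaves a small inward
chord bias on curved vessels (a polyline chord of a circular arc lies
inside the arc); recentering removes it, leaving mean deviations from
the analytic axis in the few-micron range on the test phantoms.

The forward cone is what keeps the path out of an aneurysm sac: turning
from the parent artery into the sac requires a turn sharper than the
cone admits in the neck region, and near the ostium the inscribed
radius *decreases* toward the neck (the aperture rim is closer than the
far wall), so the greedy objective itself prefers the parent lumen.

Tangent frames are rotation-minimizing (double-reflection method), so
the swept tube does not twist; on planar curves the frame rotates
exactly with the tangent and on helices its twist relative to the
Frenet frame matches the torsion integral (both are tested).

Termination triggers within one step of seed B, or within 0.75 of
seed B's own inscribed radius — a seed placed close to an end cap
otherwise repels the greedy march (radius maximization pulls away from
the cap).

## Braid model

The braid is laid out in parameter space: wire `j` of the clockwise
family follows `theta(t) = theta0_j + 2*pi*turns*t` over the stent
length, the counter-clockwise family uses `−turns`, and start angles
are uniformly spaced per family.  The counter-clockwise family is
staggered by half a carrier spacing, as on a braiding machine; without
the stagger each cw/ccw pair would start at a coincident point and the
exported wires would weld into 8 components instead of 16.  All wires
lie on one surface ("overlaying", no over/under weave): interleaving
would require contact resolution between wires that the kinematic model
does not represent.

Parameter points are mapped to 3D by bilinear interpolation of the four
surrounding deployed-surface grid vertices, so wire points lie exactly
on the triangulated deployed surface of a uniform tube.  Wires are
sampled at every station plus 4 sub-samples per station interval: at
station spacing alone, the polyline chord deficit of a 60° helix is
~0.4%, which would mask true length errors.  Before sweeping, each wire
centerline is offset radially inward by half the wire diameter so the
swept solid is tangent to the wall from inside.  Sweeping uses
rotation-minimizing frames, a circular cross-section polygon
(`n_sides`, default 8), and flat end caps; each wire is watertight and
the merged export is a plain concatenation — no Boolean union, which
downstream CFD meshers do not require and which is numerically fragile
on the thousands of wire crossings.

Device parameters not printed for the modelled device are exposed as
documented assumptions, not facts: wire diameter 0.06 mm and braid
angle 60° (from the stent axis at the free diameter) are typical of
low-profile braided stents and are configurable.  `turns = 0` is
accepted as a validation mode (wires become straight generators);
negative turns are rejected.

## Synthetic phantom world

The generators stand in for the patient geometry the original workflow
used, which is not distributable.  The reference phantom is:

* a 4.5 mm-diameter parent tube bent at radius 20 mm over 100° (34.9 mm
  of centerline, enough to host the 23 mm device with margin) —
  internal-carotid-like curvature;
* a wide-necked sidewall aneurysm on the outer side of the bend with
  neck width 12.27 mm and dome height 9.35 mm, the two morphometrics
  the study vessel is described by.

The dome is an ellipsoid clipped at the neck plane and blended onto the
tube with a polynomial smooth-min (blend width 0.3 mm).  The neck plane
sits 2/3 of the tube radius above the centerline: tangent to the tube
it would pinch the ostium to a point; deeper, it would distort the
parent lumen.  Given neck width `nw`, dome width `dw` and height `dh`,
the ellipsoid half-height is `c = dh / (1 + sqrt(1 - (nw/dw)^2))` with
its center `beta*c` above the plane, which makes the measured height and
the widest extent parallel to the plane reproduce `dh` and `dw` exactly
in the continuous limit; the blend and grid discretization perturb them
by well under the 2% verification tolerance.  Surfaces are extracted by
marching tetrahedra (Kuhn 6-tet decomposition, edge-keyed vertex
sharing) on a uniform grid at `mesh_resolution` (default 0.35 mm),
which guarantees watertight, consistently oriented output; field values
within 1e-4 of the iso level are snapped away from it (sign-preserving)
so no sliver triangles appear.

What the phantoms deliberately do not emulate: patient-specific sac
shapes (lobulations, blebs), tapering parent vessels, branch vessels,
and wall thickness.  A green test on the phantom therefore establishes
the pipeline's geometric contracts (apposition, cap, length, braid
layout, morphometrics) — not fidelity to any particular patient.

## Numerical choices

* Units are millimetres throughout; STL carries no units, so this is a
  package-wide convention matching device labelling.
* STL vertex welding tolerance 1e-6 mm on read (STL stores a triangle
  soup; downstream needs connectivity).
* Contact tolerance ("optimal apposition") defaults to 0.05 mm; no
  number is published for the original workflow, and 0.05 mm is about
  an order of magnitude below the wire scale.
* Defaults `rings = 32`, `stations_per_mm = 2` resolve the braid cells
  of a 16-wire device; tests that compare against continuous closed
  forms at 0.2% use 96 rings, because the 32-ring chordal radius
  deficit (~0.3%) is of the same order as the tolerance.
* Metal coverage is computed on the unrolled (arclength ×
  circumference) plane by rasterizing wire strips; crossings count
  once.  It is verified against an independent analytic-line
  Monte-Carlo oracle to 1%.
* The inside/outside test is ray parity along a fixed, slightly
  irrational direction, which avoids edge-grazing on axis-aligned
  fixtures.
* Degenerate inputs fail loudly and early: non-watertight vessels are
  rejected before expansion, kinked wire polylines name the wire and
  vertex, seeds outside the lumen are parameter errors.

## Known limitations

* No stent mechanics: no chronic outward force, no foreshortening, no
  wire-wire contact; deployment in strongly non-circular lumens is
  star-shaped per station (each vertex moves along a fixed radial ray).
* The braid angle, wire diameter and per-direction wire count of the
  real 4.5 × 23 device are assumptions (only the 16-wire count is a
  device fact).
* Centerline extraction handles a single unbranched parent artery.
* Timings are logged but never asserted: they are hardware-dependent.
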