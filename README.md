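# fvstent

Fast virtual stenting of braided flow-diverter devices in vessel
phantoms, in R.

## What it does, and for whom

Interventional neuroradiology treats wide-necked intracranial aneurysms
with braided, self-expanding stents (e.g. the LVIS family). Assessing a
device/vessel pairing computationally requires the *deployed* stent
geometry — 16 helical wires apposed to the lumen wall — as input to CFD
meshing. Building that geometry by finite-element stent mechanics takes
hours; `fvstent` implements the fast, kinematic alternative used in
virtual-stenting practice:

1. **Centerline** — maximal-inscribed-sphere marching through the
   watertight lumen surface (STL), re-centered and smoothed, with
   rotation-minimizing frames. At a point `p` the inscribed radius is
   `r(p) = min distance to wall`; the extracted curve greedily maximizes
   `r` inside a 60° forward cone.
2. **Deployment** — a cylindrical simplex tube (stations × rings, every
   interior vertex with exactly 3 neighbors) expands radially:
   multiplicative growth by factor `g` while far from the wall (at most
   `ceil(log(R_wall/r_0)/log g)` uniform steps), then per-vertex advance
   with contact freezing at wall gap ≤ `contact_tolerance`, capped at
   the device free radius. Foreshortening is neglected by design, so
   deployed length ≡ labelled length.
3. **Braid + sweep** — wire `j` follows `θ(t) = θ0_j ± 2π·k·t` on the
   deployed surface (`k = L·tan(α)/(π·d)` turns for braid angle α),
   8 clockwise + 8 counter-clockwise wires, swept into watertight
   circular-section solids and exported as STL for CFD meshing.

Parametric phantoms (straight tube, curved tube, wide-necked sidewall
aneurysm with neck width 12.27 mm and dome height 9.35 mm on a 4.5 mm
parent artery) provide analytic ground truth so the whole pipeline is
testable without patient data.

## Worked example

Deploy the modelled 4.5 × 23 mm, 16-wire device in the reference
aneurysm phantom and write all artifacts:

```r
library(fvstent)
run_pipeline(run_config(preset = "reference"), out_dir = "ref-run")
met <- jsonlite::read_json("ref-run/metrics.json")
cat(met$mean_diameter, met$stent_length_axial, met$metal_coverage, "\n")
```

Output of this run (stages logged as they execute):

```
[fvstent] stage: synthetic phantom (reference)
[fvstent] stage: vessel validation
[fvstent] stage: centerline extraction
[fvstent] stage: simplex tube initiation and expansion
[fvstent] stage: braid pattern mapping
[fvstent] stage: metrics
4.449776 23 0.1318109
```

and `ref-run/metrics.json` reports (abridged):

| quantity | value | meaning |
|---|---|---|
| `mean_diameter` | 4.450 mm | deployed diameter ≈ labelled 4.5 mm minus the contact gap |
| `max_diameter` | 4.466 mm | never exceeds the free-diameter cap |
| `stent_length_axial` | 23 mm | labelled length, exactly (no foreshortening) |
| `apposition_gap$max` | 8.59 mm | the stent scaffolds across the aneurysm neck — the "gap" there is the sac depth |
| `metal_coverage` | 0.132 | fraction of the deployed surface covered by wire strips |
| `braid_angle_measured` | 59.7° | close to the 60° design angle |
| `wire_lengths` | 45.5 mm each | helix length `sqrt(L² + (2πrk)²)` |

Artifacts written: `validation.json`, `centerline.csv`, `deployed.stl`,
`stent.stl`, `metrics.json`, plus `manifest.json` (config hash,
timings). Reruns with the same config are byte-identical.

The same pipeline is scriptable per stage (`make_phantom()`,
`extract_centerline()`, `init_simplex_tube()` / `expand()`,
`generate_wire_paths()` / `sweep_wires()`, `deployment_metrics()`), and
a command-line front-end is installed at `exec/fvs`
(`fvs synth|centerline|run … --set key=value`).

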