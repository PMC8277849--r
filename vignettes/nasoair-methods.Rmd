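---
title: "Methods: nasal airway morphometry and airflow post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nasal airway morphometry and airflow post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasoair)
```

## The measurement problem

The nasal airway is a pair of narrow, convoluted passages whose geometry
changes continuously — most dramatically when the erectile tissue of the
turbinates swells or shrinks (the nasal cycle, or pharmacological
decongestion). Characterizing such an airway means reducing a segmented
3-D lumen surface and a computed flow field to a small set of
anatomically registered quantities:

* a **centerline** from nostril to nasopharynx, with distance normalized to
  $\tilde{s} \in [0, 1]$ so different subjects can be compared station by
  station;
* **cross-sections** normal to the centerline, each summarized by its area
  $A$, perimeter $P$ and hydraulic diameter $d_h = 4A/P$, summed over every
  lumen loop the plane crosses (left plus right passage, plus any turbinate
  lobes) — the bilateral convention;
* whole-cavity and regional **surface area (SA)**, **cavity volume (CV)**
  and their ratio **SAVR** $= \mathrm{SA}/\mathrm{CV}$, the quantity that
  links air-conditioning capacity to flow resistance;
* **flow summaries** per cross-section: mass flow
  $\dot m = \rho \int \mathbf{u}\cdot\hat{\mathbf n}\, dA$, surface-averaged
  total pressure $\bar p_t = \overline{p + \tfrac12 \rho |\mathbf u|^2}$,
  and the perimeter-form Reynolds number
  $\mathrm{Re} = 4 \rho Q / (\mu P)$, which for a fixed flow rate depends
  on the perimeter alone;
* **resistance**: the drop in $\bar p_t$ between consecutive planes divided
  by the volumetric flow rate $Q$, accumulated from the nostril
  ($R_\mathrm{cum}(0)=0$), reported in $\mathrm{Pa\,s\,ml^{-1}}$, and split
  into anterior (nostril to plane 1V) and posterior (1V to the posterior
  septum) segments;
* the **partitioning** of plane mass flow and of integrated wall-shear
  loading $\sum \tau_w \, dA$ between the superior, middle and inferior
  cavity, delimited by two horizontal planes (1H, 2H);
* bilateral combination of per-side flow quantities by **mass-flow
  weighting**
  $\phi_\mathrm{bilateral} = (\dot m_L \phi_L + \dot m_R \phi_R)/(\dot m_L + \dot m_R)$.

Anatomical landmark planes are placed at fractions of normalized centerline
distance; the defaults are cohort means: nasal valve (NV) 0.12, anterior
septum (AS) 0.18, the three septal verticals 1V/2V/3V at 0.32/0.45/0.58,
posterior septum (PS) 0.72, with nostril and nasopharynx pinned at 0 and 1.

Paired cohorts (each subject measured in the normal and decongested state)
are compared metric by metric with the **exact Wilcoxon signed-rank test**
at a 95% confidence threshold, summarized by quartile boxplots.

## Geometric algorithms

**Slicing.** Plane/mesh intersection uses indexed edge crossings: each
intersection point is keyed by the mesh edge it lies on, so chaining the
per-triangle segments into closed loops is exact and tolerance-free.
Vertices closer than $10^{-9}$ mm to a cutting plane are nudged to its
positive side, which removes every degenerate incidence (vertex on plane,
coplanar triangle) at the cost of an error many orders below discretization
error. Loop area, perimeter and centroid come from the shoelace formulas in
an in-plane basis.

**Centerline.** No centerline algorithm is canonical for tubular anatomy;
the package marches one deterministically. Starting from the straight line
between the inlet- and outlet-cap centroids, it repeatedly (i) cuts planes
normal to the current polyline, (ii) replaces each station by the
area-weighted centroid of the cut loops, (iii) lightly smooths the interior
points with a (1,2,1)/4 kernel and resamples uniformly by arc length, until
the largest station displacement falls below 0.1 mm (at most 10 passes).
The smoothing/resampling step suppresses the zigzag instability of raw
centroid iteration on curved lumens; on a quarter-torus test duct the
recovered arc length is within 0.05% of $\pi R / 2$.

**Volumes and regions.** Whole-cavity CV uses the divergence theorem on the
closed mesh; SA sums wall-triangle areas only (caps and clip faces are not
mucosa). Regional metrics clip the mesh against half-spaces (1H/2H for the
vertical thirds; centerline-normal planes at 1V and PS for
anterior/posterior), splitting crossing triangles with edge-shared cut
vertices. The clipped region is closed virtually: each planar cap
contributes its polygon flux $(\bar{\mathbf x} \cdot \hat{\mathbf n}) A /3$,
so no cap triangulation is needed and the vertical thirds conserve SA and
CV to machine precision (asserted at 0.1%). Because 1H/2H are defined in
the source anatomy by skeletal landmarks invisible in a lumen-only mesh,
the default places them by splitting the lumen's vertical extent over the
turbinate region (1V–PS) into equal thirds; explicit planes can be given
instead.

## The synthetic phantom and its flow field

No subject geometries or CFD fields are redistributable, so the package
carries a parametric phantom that emulates the study conditions: a short
elliptical vestibule that splits into two mirror-image passages, a
nasal-valve constriction near $\tilde s = 0.12$, a multi-lobed turbinate
region, and a merge back into a single nasopharynx duct posterior to
$\tilde s = 0.72$. The bilateral CSA profile interpolates control values
(defaults, in cm²: nostril 1.5, valve 1.0, AS 2.2, plateau 2.8 normal /
3.8 decongested, post-merge 4.5, nasopharynx 3.5; centerline length
113 mm) with a monotone cubic spline. The congestion factor
$c \in [0, 1]$ morphs the area profile between the states **only between AS
and PS**, reflecting that decongestion acts on the turbinate mucosa, not
the cartilaginous anterior nose.

Two emulation targets drive the contour model $r(\theta) = r_0 (1 +
\varepsilon \cos k\theta)$ (default $k = 4$ lobes, $\varepsilon = 0.35$ in
the congested state): the plateau CSA must rise by the programmed ~35%
under decongestion while the **perimeter stays nearly constant** — the
anatomical reason the Reynolds number is insensitive to decongestion. The
generator solves, per station, for the cleft depth $\varepsilon$ that holds
the normal-state perimeter at the new area (shallower clefts, wider
passage); the emitted meshes change plateau perimeter by under 0.2%
between states. The passage split and merge are stitched as pair-of-pants
transitions whose septum trailing edge is a zero-thickness fold placed
0.05 mm inside the single-duct side, so no cross-sectional cut lands in a
topologically ambiguous zone; the transition walls are real (watertight,
orientable) surface.

`assign_analytic_flow()` attaches a deterministic laminar field standing in
for an external CFD solution: each loop carries the parabolic profile
$u = 2 \bar u (1 - t^2)$ in the star-shaped coordinate $t$ (continuum flux
exactly $\bar u A$ for any star-shaped section), flow splits between the
passages in proportion to their series laminar conductance, static
pressure integrates the local gradient $-128 \mu Q_\mathrm{loop} / (\pi
d_h^4)$ and *includes the Bernoulli exchange* $-\Delta\!\left(\tfrac23 \rho
\bar u^2\right)$ so that the plane-averaged total pressure decays by the
viscous loss alone, and wall shear stress is the parabolic wall gradient
$8 \mu \bar u / d_h$. On a straight tube the whole pipeline recovers the
Hagen–Poiseuille resistance $128 \mu L / (\pi d^4)$ within 0.3%
(asserted at 2%).

What the phantom does **not** emulate: true turbinate convolution. Real nasal
airways pack an order of magnitude more mucosal perimeter into narrow
clefts, so the phantom's absolute SAVR (~3 cm⁻¹ vs ~11 cm⁻¹ in vivo) and
absolute resistance (~0.004 vs ~0.03 Pa·s·ml⁻¹) are several-fold lower
than clinical values, it has no paranasal sinuses, no curved centerline
(the 90° nostril turn is exercised by the torus fixture instead), and no
secondary flows or entrance effects in its analytic fields. Passing the
package's tests therefore demonstrates correctness of the *measurement
pipeline*, and realistic *relative* effects (paired contrasts, fractions,
ratios), not clinical magnitudes.

## Plane integration of sampled fields

Field integration is mesh-agnostic: each cross-section loop is
fan-triangulated about its centroid, each fan triangle is subdivided once
(spreading quadrature radially), and the field is evaluated at the three
edge-midpoint nodes of every sub-triangle (a degree-2 rule) by
inverse-distance (power 2) interpolation from the 8 nearest samples,
pre-filtered to an axial slab around the cutting plane that widens until
enough candidates exist. The mean of the quartic dynamic-pressure profile
is the delicate integrand; the radial subdivision keeps its bias inside a
few tenths of a percent. Synthetic fields sample each station's loops on
16 uniform radial levels and 64 azimuthal directions, plus the centroid
and the full boundary polygon *and* its edge midpoints at zero velocity —
anchoring the no-slip layer for the interpolant. Analysis planes default to
the field's own stations (the usual CFD practice of extracting on solver
cut planes); with that alignment plane mass flow is conserved along the
two-passage phantom to better than 1%, and misaligned planes stay within
about 2%.

## Cohort simulation and statistics

Each subject of a paired cohort is a phantom whose caliber (all CSA
control values), valve size and length carry independent multiplicative
lognormal perturbations (default CVs 15%, 15%, 7% — set qualitatively from
the spread of published anatomical profiles and landmark tables, and
flagged as approximate); the decongestion response multiplies the plateau
CSA by the programmed effect ratio (default 1.348, i.e. +34.8%) with 5%
subject-level variability, and every reported metric receives 3%
multiplicative lognormal measurement noise per state. Setting
`resistance_effect` overrides the geometric resistance response with a
programmed ratio — the knob used to calibrate power at a 50% resistance
reduction. A null cohort (`effect_ratio = 1`, `effect_cv = 0`,
`resistance_effect = 1`) makes the two states exchangeable by
construction, which is what a type-I calibration requires.

Metrics are evaluated by a closed-form engine on the same section
parameterization the mesh generator discretizes (61 stations; perimeter
preservation applied as an identity, cleft depth inverted through a
memoized shape table). The mesh pipeline run on one subject agrees with the
closed-form engine to within ~1% on volumes and plateau CSA; wall areas
and SAVR differ by a few percent because the triangulated surface carries
real slant and junction-wall area that the idealized $\int P\,ds$ does
not, and resistances differ by up to ~10% through the discrete $d_h$
profile — both engines are kept, the closed-form one for Monte-Carlo
throughput, the mesh one as the reference implementation of the
measurement chain.

The Wilcoxon signed-rank test discards zero differences (the classical
convention; the source analyses do not state their choice), midranks ties,
and computes the exact two-sided p-value from the full distribution of the
positive rank sum over all $2^n$ sign assignments — evaluated by
convolution over the rank multiset, so $n = 25$ costs microseconds — with
a tie-corrected, continuity-corrected normal approximation above
$n = 25$. At the study's $n = 10$, ten concordant pairs give
$p = 2/2^{10} \approx 0.00195$. No multiple-testing correction is applied
by default (each panel is reported at its own 5% level, matching the
source convention); Holm adjustment is available. Monte-Carlo calibration
over 1000 null replicates puts the realized type-I error at ~0.043–0.05
(the exact test at $n = 10$ cannot reject at exactly 0.05, its largest
attainable level below 0.05 being $48/1024 \approx 0.047$), and power
against a 50% resistance reduction at n = 10 is ~1.0 over 200 replicates.
Replicate counts (1000 / 200) were chosen so the binomial standard error
(±0.007 on the type-I rate) is well inside the ±0.02 calibration band.

## Numerical choices and degenerate inputs

* Stations for geometry profiling default to 100, uniform in $\tilde s$ —
  enough to resolve the valve constriction; cumulative resistance changes
  by <1% when the station count is doubled.
* Cutting planes at $\tilde s = 0$ and 1 are nudged $10^{-3}$ of the
  length inward so they never coincide with the cap planes.
* Cross-sections report **all** loops the plane intersects; in strongly
  curved vestibules a plane may legitimately cut a passage twice, and the
  bilateral summation convention makes this the intended behaviour.
* Empty intersections, open intersection polylines (mesh defects), clip
  operations that empty a region, zero flow rate, zero total mass flow and
  degenerate (all-zero-difference) paired samples are all hard errors with
  specific messages, never silent results.
* Meshes are validated on construction: watertight (every edge in exactly
  two faces), consistently wound, positive volume, each cap one connected
  planar patch. Cap inference for unlabeled STL accepts only planar
  patches of at least 4 faces, so a closed surface without caps reports
  "expected 2 cap patches, found 0".
* All randomness flows from one master seed (subject draws, noise,
  replicate seeds); phantom meshing and flow assignment are fully
  deterministic, so identical specifications yield bit-identical meshes
  and metric tables.

## A worked fragment

```{r demo, eval = FALSE}
# one phantom, both states, profile + resistance at 15 L/min
spec <- phantom_spec()
ph <- make_phantom(spec, congestion = 1)
cl <- extract_centerline(ph)
lmk <- place_landmarks(cl, surface = ph)
prof <- profile_geometry(ph, cl, n_stations = 81)
fld <- assign_analytic_flow(ph, Q = flow_rate_lpm(15))
rp <- resistance_profile(fld, prof)
anterior_posterior_resistance(rp, lmk)

# the paired study, end to end
report <- run_study(run_config(seed = 1))
tidy(report)
autoplot(report$comparison)
```

## Known limitations

Absolute SAVR and resistance are phantom-scale, not clinical-scale (see
above). The anterior/posterior resistance split on the phantom attributes
some decongestion response to the anterior segment because the morph
begins at AS (0.18), upstream of 1V; in vivo the anterior response is
dominated by the rigid valve and is typically not significant. Imported
meshes are analyzed as given — no sinus removal or repair beyond cap
detection — and imported flow fields must cover every analysis plane with
samples. The closed-form cohort engine treats perimeter preservation as
exact; the meshes realize it to within 5% by construction.
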