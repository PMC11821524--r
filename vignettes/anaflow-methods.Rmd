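---
title: "Confined cytoplasmic flows and NER scaling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confined cytoplasmic flows and NER scaling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, how the defaults were chosen, the
numerical decisions, and what the synthetic-data tests do and do not
establish about real data.

# The timing model

Chromosomal Aurora-B substrates (phospho-histone H3 serine 10 is the
read-out) are phosphorylated at the midzone level at anaphase onset and
dephosphorylated exponentially. We model the normalized intensity as

$$ C(t) = \begin{cases} C_0 & t \le t_0 \\
C_0\, e^{-(t - t_0)/\tau} & t > t_0 \end{cases} $$

with an explicit onset $t_0$. A pure exponential from $t = 0$ cannot pass
through both measured anchor points — WGA recruitment at 113 s when the
normalized level is 75%, and NER at 271 s at 37% — because their
time/level ratios are inconsistent with a decay starting at anaphase
onset. Solving both anchor equations with $C_0 = 1$ gives $\tau = 223.6$ s
and $t_0 = 48.7$ s; an onset near 49 s is also consistent with the
normalization convention (traces are normalized to their maximum within
the first 80 s, which presumes an early plateau). `calibrateTwoPoint()`
performs this calibration in closed form; `fitDecay()` fits the same
three-parameter model to a trace by Levenberg–Marquardt least squares
(`minpack.lm`), reporting the dephosphorylation rate $1/\tau$.

Threshold crossing times are $t(\theta) = t_0 + \tau\log(C_0/\theta)$, and
`positionAtThreshold()` converts a time to a separation distance by linear
interpolation of the trajectory — adequate because $d(t)$ is smooth on the
5–20 s sampling used.

# Friction theory

Cytoplasmic viscosity is the single material parameter. The default,
`defaultViscosity()` $\approx 42.4$ Pa s, is *calibrated*, not measured:
it is the value at which a 1-µm-diameter sphere (a mitochondrion) has
Stokes friction $6\pi\eta r = 400$ pN s/µm, the coefficient reported for
this system. At that same viscosity the classical longitudinal
resistive-force coefficient of a slender rod,
$\xi_\parallel = 2\pi\eta L / (\ln(2L/d) - 1/2)$, evaluates to
$\approx 431$ pN s/µm for a 10-µm microtubule of 25 nm diameter —
within 8% of the sphere value, which is the quantitative sense in which
cargo and filament frictions are "similar" and why dragging cargo can
move the network: in an overdamped two-body system coupled by an internal
motor force the speed ratio is the inverse friction ratio
(`velocityRatio()`), so comparable frictions mean comparable speeds.

# The confined-flow solver

Creeping flow ($Re \approx 0$) in a planar domain is solved with
regularized Stokeslets. The kernel is the planar Stokeslet of the blob
$\phi_\varepsilon(r) = 3\varepsilon^3 / (2\pi (r^2 +
\varepsilon^2)^{5/2})$; writing $R = \sqrt{r^2 + \varepsilon^2}$,

$$ 4\pi\mu\, \mathbf{u} = -\mathbf{f}\left[\ln(R+\varepsilon) -
\frac{\varepsilon(R + 2\varepsilon)}{(R+\varepsilon)R}\right] +
(\mathbf{f}\cdot\mathbf{x})\,\mathbf{x}\,
\frac{R + 2\varepsilon}{(R+\varepsilon)^2 R}. $$

This field is exactly divergence-free and tends to the free-space 2D
Stokeslet as $\varepsilon \to 0$ (verified numerically in the test
suite). Two dimensions match the planar measurements the model is
compared against; the Stokes paradox does not arise because the domain is
bounded.

No-slip at the cell boundary is enforced by collocation: boundary
Stokeslets at nodes spaced uniformly in arc length, with weights solved by
truncated-SVD least squares so that the velocity vanishes at the nodes.
Numerical choices:

* **Boundary blob size** = 2 × node spacing (`BOUNDARY_EPS_FACTOR`).
  Smaller blobs leave slip between nodes; this value keeps the residual
  boundary speed below $10^{-3}$ of the peak interior speed at the shipped
  resolutions (tested at node midpoints, where the residual is largest).
* **Collocation count** default 192 (node spacing well under length/64).
  The boundary nodes are allocated per boundary segment so the node set is
  exactly mirror-symmetric; the simulation's symmetry properties rely on
  this.
* **Interior blob size** default 1.5 × grid spacing; a sensitivity check
  is part of the test suite via the refinement test (halved time step and
  doubled collocation change the NER position by <1%).
* **Truncated SVD** (cutoff $10^{-12}\sigma_1$) absorbs the known
  single-layer null density (a density along the boundary normal induces
  zero interior flow).
* The domain is a rounded rectangle (corner radius = width/4)
  approximating a blastomere cross-section; an ellipse is available.

`probeMobilityVsWall()` quantifies the no-slip confinement effect with a
cargo/anchor force *dipole* probe: single point forces have no
unbounded-domain reference in 2D, whereas the dipole's speed converges to
the free-space value far from walls. One caveat found while testing: in
the thin layer within ~w/10 of the wall, the speed in a smaller domain
can marginally exceed that in a larger one (recirculation); away from
that layer the larger domain is uniformly at least as mobile, and that is
the regime the property tests cover.

# The anaphase simulation

Anaphase A (0–100 s) is kinematic: the spindle, not flows, separates
chromosomes, at a constant rate $v_A$ = 0.35 µm/s (distance between the
two sets). This places the WGA event (113 s) at $\approx 37.9$ µm of
separation, matching the measured WGA position, and is deliberately not
flow-modelled.

Anaphase B is flow-driven. Each half-spindle is an asymmetric aster:

* Ray directions are sampled uniformly on the circle with stratified
  jitter (uniform in distribution, but with far lower directional
  sampling noise than i.i.d. draws — with i.i.d. rays the clipping-induced
  force asymmetry was noisy enough to make the force-response
  non-monotone).
* Rays are clipped at the spindle midzone plane (astral microtubules do
  not extend beyond it — the source of the asymmetry, quantified as
  anisotropy $d_a/r_a$) and at the cell boundary (2 µm clearance).
* Engaged cargos are placed along rays with **fixed linear density**
  (cargos per µm of microtubule), anchored so that `engagedCount` is the
  count on the nominal unclipped aster. Density, not total count, is held
  fixed across cell sizes, consistent with the observation that
  mitochondrial density and the engaged fraction do not change with cell
  size; a fixed total count would concentrate force unphysically when
  rays are clipped in small cells.
* Each cargo applies $\xi_{mito} v_d$ (times the duty ratio) to the fluid
  toward the aster centre; the reaction is carried by the network. On a
  clipped aster the short side carries fewer cargos, so the net reaction
  points poleward.

The aster, with its chromosome set, moves as a **rigid porous object**:
network nodes laid out on concentric rings across the clipped ray span
are constrained to a common rigid velocity, the node Stokeslet weights
must sum to the net motor reaction (force balance on a massless network),
and everything is solved in one linear system together with the no-slip
boundary. This choice resolves an open modelling question: advecting the
aster by the local flow at its centre point was implemented first and
rejected, because a centre point's mobility in a closed 2D domain is
almost independent of domain size (the logarithms cancel), so no
confinement scaling emerges, and the partner aster's contractile dipole
then pulls the asters *together* in small cells. The mobility of an
*extended* object, in contrast, collapses as the object approaches the
walls — which is precisely the no-slip confinement mechanism the model
exists to capture — and the rigid treatment matches the observation that
chromosomes and poles move together.

Aster geometry defaults (not printed in the available sources, chosen
once on physical grounds): radius $r_a$ = 70 µm at anaphase-B onset —
embryonic cleavage asters nearly span the blastomere half-width at the
4-cell stage — growing at 0.2 µm/s, reflecting measured anaphase aster
growth at a size-independent rate; growth sustains the midzone asymmetry
as the aster moves poleward and increases wall contact in small cells.
Network node spacing (12 µm) and node blob size (4 µm) are *physical*
porosity parameters of the sparse network, not numerical resolution
knobs: they set how strongly the aster entrains the fluid between
microtubule bundles.

**Calibration.** The single force knob is engagedCount × dutyRatio ×
$\xi_{mito}$ × $v_d$. It is spread over a large pool of transiently
engaged cargos (engagedCount = 2150 at dutyRatio = 0.1, i.e. ~215
full-duty cargo equivalents per aster) so that the discrete cargo
near-fields stay small compared with the mean flow; the mean dynamics are
linear in the product and insensitive to how it is partitioned. The knob
was tuned **once**, at the 4-cell stage (L = 300 µm), so the per-set
anaphase-B speed is ~0.11 µm/s. Every other cell length is then a
prediction: the simulated NER separation at L = 580 µm lands at ~92.7 µm
(measured: 91 ± 14 µm), and the scaling curve rises monotonically from
~31 µm at L = 70 µm with saturation at the large-cell end. In the
smallest cells (L = 70 µm) the aster is squeezed between midzone and
pole and the net reaction can transiently reverse, so the separation
relaxes slightly below its anaphase-A value toward a geometric
equilibrium; experimentally these cells also show essentially no
anaphase-B scaling contribution.

**Flow near the chromosomes.** At the chromosome plate edge (a few µm
from the set's centroid) the fluid moves with the chromosomes to within
~30%. Farther into the aster the porous network lets the fluid lag: the
model transports chromosomes by moving the network through the fluid and
only partially entrains the bulk. Consequently the simulated *fluid*
speed 10–20 µm out is below the chromosome speed — the measured
near-chromosome flow is likewise ~25% below the chromosome speed —
but the model should not be read as a quantitative predictor of the full
PIV flow amplitude map; the PIV module is validated against synthetic
ground truth instead.

**Time stepping** is explicit Euler with dt = 5 s (sub-stepped so a step
never exceeds the grid scale); halving dt changes the outcome by <2%,
and dt together with doubled collocation changes the NER position by
<1%, comfortably within the 5% refinement criterion.

# PIV

`pivSeries()` implements multipass FFT cross-correlation PIV:

* CLAHE preprocessing (EBImage), 64-px tiles, on frames normalized to
  [0, 1] — making the result invariant to global gain/offset.
* Three passes with 128/64/32-px windows at 50% overlap; each pass shifts
  the second frame's interrogation window by the rounded displacement
  predicted by the previous pass (no window deformation).
* Subpixel peaks by the 3-point Gaussian estimator; plateau peaks break
  ties toward the smallest displacement.
* Vectors are invalidated where the window centre falls in the chromosome
  mask (or the window is mostly masked, or outside the cell ROI).
* Outliers: vectors faster than 3 × the per-field median speed (the rule
  is per field, as a fixed absolute threshold cannot serve fields of
  different amplitude); smoothing is a single-pass 3×3 unweighted mean
  over valid vectors.
* Fields are averaged per node over the 100–200 s window, when flows are
  most prominent; the near-chromosome speed is the mean vector magnitude
  over nodes within 9 µm above and below the chromosome mask.

On synthetic movies the full pipeline recovers a uniform 0.08 µm/s flow
to within a few percent and a rigid rotation's vorticity ($2\omega$) to
within 10%.

# Track analysis

Tracks are segmented by a 3-sample rolling speed with threshold 0.4 µm/s
— the geometric midpoint between the fast (0.95 µm/s) and slow
(0.089 µm/s) regimes — and a minimum run of 4 samples (2.4 s at the
0.6 s interval); the original segmentation was manual, so any automated
rule is a package decision. Episodes of each kind are pooled into a
pair-count-weighted ensemble MSD with delays capped at 25% of episode
duration (standard practice to avoid the noisy long-delay tail), fitted
by weighted least squares to $\mathrm{MSD}(t) = 4Dt + v^2t^2$ with
$D, v \ge 0$ (a coefficient that would go negative is pinned at zero and
the other refitted). Pair-count weighting is an assumption; the exact
weighting of the original analysis tool is not documented.

# Synthetic data

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes, and carry their ground truth:

* `genPhosphoTraces()`: $C(t)$ + Gaussian noise (default sd 0.05),
  sampled every 20 s over [0, 400] s.
* `genTwoPhaseTracks()`: ballistic motion toward a virtual aster centre
  at 0.95 µm/s plus diffusion, switching once to drift at 0.089 µm/s in a
  common flow direction with $D$ = 0.017 µm²/s, at 0.6 s sampling.
* `genParticleMovie()`: particles advected semi-Lagrangianly by a known
  flow, rendered as Gaussian spots with Poisson shot noise and Gaussian
  read noise (a standard fluorescence noise model; the actual camera
  parameters are not documented, so the defaults — 0.65 µm/px, 512²
  frames — are plausible stand-ins for a 40× spinning-disk acquisition).
* `genStageFixture()`: stage→length mapping with anchors 580 µm (1-cell),
  300 µm (4-cell) and 70 µm (512-cell), geometric in between (cleavage
  halves the volume each cycle).

All generators are bit-reproducible under a fixed seed and restore the
global RNG state. What passing recovery tests establish: the pipeline
correctly inverts data *of the assumed structure* (single-exponential
decay, two-state motion, spot-like tracers advected by smooth flows).
What they do not establish: robustness to model violations in real data —
photobleaching and background drift in traces, state-switching more
complex than one fast→slow transition, tracer size heterogeneity,
out-of-plane motion, or spindle-region artefacts beyond a binary mask.

# Known limitations

* The flow model is two-dimensional; three-dimensional confinement will
  change absolute mobilities (the force calibration absorbs this at the
  4-cell stage, but the scaling exponent could differ).
* The cytoplasm is Newtonian; poroelasticity and the actin network's
  transient damping of early-anaphase flows are not modelled.
* Asters are rigid; network deformation, and therefore speckle-flow
  patterns as an independent read-out, are not simulated.
* Anaphase-A force generation, cytokinesis, and the marginal $v_A$
  scaling in the smallest cells are out of scope.
* The viscosity, cargo pool and aster geometry defaults are calibrated
  stand-ins (flagged as such in the configuration documentation), chosen
  once as described above; they are not independent measurements.
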