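---
title: "Models and methods behind footform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind footform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`footform` studies how plantar loading shapes foot bone form and density by
chaining four analyses — gait loading, bone shape comparison, quasi-static
finite elements and strain-adaptive remodelling — over three foot
archetypes: a typically developed foot (NF), a half-bound foot (HB, binding
released in youth, deformed toes and a milder arch) and a full-bound foot
(FB, lifelong binding, dome arch and near-vertical calcaneus). This
vignette explains the models, their parameters and units, the numerical
choices, and what the synthetic data generator can and cannot stand in for.

## The synthetic archetype generator

Real bound-foot subjects are nearly impossible to recruit, so every stage
is exercised on a parametric generator whose defaults encode the measured
study conditions: foot length x width of 214.06 x 84.17 mm (NF),
202.81 x 67.14 mm (HB) and 165.86 x 65.25 mm (FB); body masses 52.2, 49.1
and 47.5 kg; and regional load shares that reproduce the observed loading
patterns — the NF loads all eight plantar regions fairly evenly (45% of
the impulse on the rearfoot), the HB drops the lesser toes and midfoot and
shifts to the rearfoot (70%), and the FB additionally drops the hallux
(78% rearfoot). Arch height ratio (0.15/0.40/0.70 of a 0.25-foot-length
arch scale) and calcaneal inclination (20/45/65 degrees) grade the
flat-to-dome transition; neither is reported per subject, so they were
fixed once at values that reproduce the qualitative posture descriptions
(mild NF arch, extreme FB dome with near-vertical calcaneus).

Bones are **superellipsoids** (implicit form
$|x/a|^p + |y/b|^p + |z/c|^p = 1$) with two smooth asymmetric deformation
modes, a linear cross-section taper along the long axis and a quadratic
"banana" bend. Both exist for a scientific reason: real bones have no
mirror symmetries, and a mirror-symmetric primitive admits proper
$\pi$-rotation self-congruences that make rigid registration ill-posed
(ICP converges to a flipped local minimum). The taper/bend warps have
exact inverses, so the same primitive serves both as a triangulated
surface and as an implicit classifier for volume meshing. A small
seed-controlled jitter of primitive sizes and placements (±1.5% semiaxis
scale, ±0.3 mm placement) makes each seed a distinct "subject" while the
generator stays a pure function of `(params, seed)`. After assembly the
x/y coordinates are affinely fitted so the bounding box measures exactly
foot width x length.

Volume meshes come from a **structured lattice**: cells whose centres fall
inside the solid are split into six Kuhn tetrahedra around the cube
diagonal. Every element of an isotropic lattice then has scaled Jacobian
0.577, comfortably above the 0.3 quality gate, without an external mesh
generator; the price is a stair-stepped boundary within one cell of the
true surface and a re-voxelised (slightly different) geometry at each
resolution. For the assembled foot model, lattice cells are classified by
the bone implicits (inflated by 0.35 cell edges so thin metatarsals
survive coarse lattices), a 5 mm inflation supplies the encapsulating soft
tissue, a tarsal/plantar-arch bridge volume joins the talus region to the
metatarsal bases (no tarsal bone primitives exist), and soft "pad" columns
fill each footprint column down to a flat ground plane 6 mm below the
lowest bone. Floating lattice islands are removed; the mechanical model is
the single connected body. The default 9 mm lattice edge yields meshes of
roughly 6,000-9,000 tetrahedra — small enough that a 60-day remodelling
loop (60 assemblies and solves) runs in about a minute, which is the
problem size all shipped simulations and checks use.

Pressure series place a **two-peak stance template** (weight-acceptance
and push-off peaks scaled to 1.1 body weight, a typical walking value) on
a 16 x 6 grid of 10 x 10 mm cells at 50 Hz. Regional load curves use
heel-early/toes-late Gaussian time profiles, and a Sinkhorn-style
iterative proportional fit reconciles the two constraints: the
instantaneous grid total follows the template exactly while regional time
integrals match the prescribed shares (within well under the 2% contract).
Within a frame a region's force is spread uniformly over its cells, so the
centre of pressure of a single-region load sits exactly at that region's
centroid, and regions absent from a scheme are identically zero. Optional
multiplicative per-frame, per-region noise (default CV 0.005) emulates
trial-to-trial texture without disturbing the template contracts.

What the generator does **not** emulate: anatomically faithful bone
geometry (fidelity is metric/topological), tarsal bones, joint contact or
cartilage, hyperelastic soft tissue, sensor noise spatial correlation, or
inter-subject biological variability beyond the primitive jitter. Passing
tests on synthetic archetypes therefore demonstrate that the algorithms
are correct and that the qualitative archetype contrasts (orderings,
zeros, localisation) follow from the encoded loading and posture
differences — not that the pipeline reproduces any individual subject.

## Gait analytics

GRF conversion uses 1 kPa·mm² = 1e-3 N. Stance is delimited by the first
and last frame with GRF above 10 N (also the CoP validity threshold; the
event rule and threshold are this package's choices — the source protocol
does not state them). CoP is normalised per trial to percent foot
width/length from the loaded footprint's medial/posterior edge and
resampled to 101 percent-stance points by linear interpolation, then
trials may be averaged.

Curve groups are compared with the Maris-Oostenveld **permutation cluster
test**: pointwise pooled two-sample t statistics thresholded at the
two-sided parametric critical value for `alpha`, contiguous
supra-threshold runs scored by mass (summed exceedance), and cluster p
computed from the permutation distribution of the maximum cluster mass.
All label relabelings are enumerated when there are at most 500 (e.g. 20
for 3+3 trials, so the smallest attainable p is 0.05 — reported honestly
rather than hidden); otherwise 500 Monte-Carlo draws with a fixed seed.
At desk scale this attains 100% detection of a 10-SD late-stance offset
with 10+10 trials and a false-positive cluster rate consistent with the
nominal 5%.

## Shape comparison

Registration is rigid-only ICP (nearest-neighbour correspondences, Kabsch
update, monotone RMS). Initialisation tries centroid matching plus all
four proper sign assignments of the signed principal frame (covariance
eigenvectors with skewness-fixed signs); the best converged fit wins. This
removes flip local minima for near-symmetric shapes. Correspondence drapes
the template topology onto the target by exact point-to-triangle
projection (a centroid-radius bound prunes candidate triangles). With only
three feet a regression-based non-rigid fit would be under-determined, so
correspondence is geometric; the downstream surface (error maps, Hausdorff
summaries, PCA) is unchanged by that choice. Error maps are signed by the
reference outward normal (positive = outside = "bone growth"); an unsigned
closest-point mode exists for arbitrary mesh pairs, since either convention
can be matched to published colour maps. Shape PCA uses the sample
covariance (divisor n-1); with n shapes there are at most n-1 modes and
full-mode reconstruction is exact. Bones are aligned and compared per bone,
not as an articulated complex.

## Finite elements

Constant-strain (linear) tetrahedra with isotropic linear elasticity: bone
E = 7300 MPa, nu = 0.3; lumped soft tissue E = 0.15 MPa, nu = 0.45. Mean
stance pressure per region — not peak, which reflects a small region and
instant — loads the plantar boundary faces as consistent nodal forces
along inward normals. The plantar fascia is five 200 N/mm axial springs
from the calcaneus notch (anterior-inferior calcaneal node) to the five
metatarsal bases; anchors are the nearest nodes to those geometric
landmarks. The Achilles pull is 0.5 body weight shared equally over a
small posterior-superior calcaneal surface patch, directed at the fixed
proximal plane centroid: magnitude is prescribed, but direction,
distribution and patch size are this package's documented rules (a whole
posterior-quadrant distribution was rejected because spreading the pull
produced almost no insertion-site stress). The tibia/fibula proximal plane
is fixed. The solver is sparse Cholesky with a few iterative-refinement
steps (the 7300/0.15 modulus contrast leaves raw factorisation residuals
marginal); element stresses are constant per element with von Mises
reported.

Verification rests on problems with exact solutions: the patch test
(imposed linear displacement fields reproduced to machine precision — CST
elements are exact for constant strain), the uniaxial 7300 MPa bar under
7.3 MPa traction (strain exactly 1e-3), and global force balance.

## Remodelling

The daily stimulus is `psi = n^(1/m) * sigma_vm * (rho_max/rho)^2` in
MPa/day, with n = 10,000 cycles/day and m = 4 (so the cycle prefactor is
10); the squared density ratio converts the continuum stress to the
tissue level, making the stimulus strictly decreasing in density at fixed
stress. Density evolves by explicit Euler (dt = 1 day) with a lazy zone of
half-width w = 0.1 psi* around the setpoint psi* = 50 MPa/day, rate
constant c_r = 0.002 (g/cm^3)/(MPa/day·day), a 0.05 g/cm^3 per-step cap
for stability, and clamping to [0.05, 1.8] g/cm^3. Stiffness couples to
density as E = 3790·rho^3 MPa, so E(1.24 g/cm^3) = 7226 MPa, within 2% of
the 7300 MPa cortical modulus. All constants are arguments of
`remodel_params()`. The uniform initial density (default 0.8 g/cm^3)
matches the uniform-density modelling assumption for cortical and
trabecular bone. The exact published form of this adaptation law lives in
an unavailable supplement; the implementation is the standard
daily-stress-stimulus formulation with lazy zone and Carter-type coupling,
and should be read as a documented stand-in that reproduces the same
qualitative predictions (density retained/gained where von Mises stress is
high, resorption elsewhere). The FE system is re-solved every day by
default; `resolve_every = k` reuses the stress field for k days when speed
matters more than path accuracy (the endpoint of a converged run is
unchanged).

For a uniaxial bar the fixed point is analytic —
`rho* = rho_max * sqrt(n^(1/m) sigma / psi*)` — and the simulation
recovers it to well under 1% with the lazy zone disabled; with the zone
enabled the terminal stimulus lands inside `[psi*(1-w), psi*(1+w)]`
(approaching the band edge asymptotically). A bar loaded exactly at the
setpoint is a machine-precision fixed point, and an unloaded bar resorbs
to the floor.

## Known limitations and numerical caveats

- **Bending stiffness of linear tetrahedra.** CST elements are overly
  stiff in slender bending: a 10:1 cantilever still under-predicts the
  Euler-Bernoulli tip deflection by ~31% at three cells through the
  thickness and ~11% at six, and the pre-asymptotic decay defeats reliable
  Richardson extrapolation at desk scale. The shipped tests therefore
  assert monotone convergence toward beam theory rather than a small
  absolute error, and displacement-level verification relies on the exact
  patch/bar problems. Foot-model conclusions are drawn from stress
  patterns and orderings, not absolute deflections.
- **Peak stresses do not mesh-converge.** The lattice re-voxelises the
  geometry at every resolution, and nodal spring/tendon attachments are
  point loads on an elastic continuum, so the elementwise maximum von
  Mises stress grows under refinement (a well-known singularity artefact).
  Comparisons across archetypes are made at a fixed lattice resolution;
  region means and energy shares are the stable quantities.
- **Soft tissue is linear.** At stance pressures the 0.15 MPa linear soft
  tissue develops large nominal displacements (real tissue stiffens); the
  soft mesh is a load path, not a deformation prediction.
- **Lazy-zone band.** With w = 0.1 the terminal density is only defined up
  to the ±sqrt(1±w) band around the analytic fixed point; quantitative
  fixed-point checks disable the zone.
- **Tiny-sample inference.** With 3 trials per group the permutation test
  cannot produce p < 0.05; interval reports at that size are descriptive.
- **Determinism.** All generators are pure functions of `(params, seed)`;
  identical configurations reproduce pipeline outputs bitwise, which the
  test suite asserts on the serialized artefacts.
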