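# footform

Integrated form-and-function analysis of normal and bound feet: plantar
pressure gait analytics, bone shape comparison, quasi-static finite-element
simulation and strain-adaptive bone remodelling, exercised end to end on a
parametric synthetic foot generator.

## The problem

Lifelong foot binding reshapes the foot: a full-bound (FB) foot develops an
extreme dome arch and a vertically oriented calcaneus, a half-bound (HB)
foot (binding released in youth) keeps deformed toes and a milder arch, and
both differ markedly from the typically developed foot (NF) in plantar
loading, bone shape and bone density. `footform` implements the
computational chain needed to study how those altered loads drive skeletal
adaptation:

1. **Gait loading.** From stance-phase plantar pressure grids (Pedar-like,
   50 Hz, kPa): vertical ground reaction force `F(t) = Σ p_i a_i`, regional
   peak/mean pressures over anatomical region schemes (8 regions for NF, 5
   for HB, 4 for FB), and the centre-of-pressure trajectory
   `x_cop = Σ p_i a_i x_i / Σ p_i a_i`, normalised to percent foot
   width/length on a 101-point percent-stance base. Groups of stance
   curves are compared with a non-parametric permutation cluster test
   (pointwise two-sample t, supra-threshold clusters scored by mass,
   cluster p from the max-mass permutation distribution).
2. **Shape.** Rigid iterative-closest-point alignment (Kabsch updates,
   principal-axes initialisation), closest-point correspondence onto a
   template topology, centroid alignment, PCA statistical shape models,
   signed per-vertex error maps ("outside the reference" positive) and
   Hausdorff distance summaries with Gaussian (mean/sd) fits.
3. **Finite elements.** Linear elastic constant-strain tetrahedra; bone
   E = 7300 MPa, nu = 0.3; encapsulating soft tissue E = 0.15 MPa,
   nu = 0.45; mean stance pressures applied as consistent nodal loads on
   the plantar surface; five 200 N/mm plantar-fascia spring connectors;
   an Achilles pull of 0.5 body weight; tibia/fibula proximal plane fixed.
   Direct sparse Cholesky solve with iterative refinement; element quality
   gated at scaled Jacobian > 0.3.
4. **Remodelling.** Daily stress stimulus
   `psi = n^(1/m) sigma_vm (rho_max/rho)^2` (MPa/day) with a lazy zone of
   half-width `w` around the setpoint `psi*`, explicit-Euler density update
   `drho/dt = c_r (psi - psi*(1 ± w))` clamped to `[0.05, 1.8] g/cm^3`, and
   Carter-type stiffness coupling `E = B rho^beta` (B = 3790, beta = 3, so
   E(1.24 g/cm^3) ≈ 7226 MPa). The FE system is re-solved daily for 60
   simulated days.

Because the study subjects are three individuals, everything is testable on
a **synthetic data generator**: superellipsoid-based bone primitives
(calcaneus, talus, tibia, fibula, five metatarsals) positioned by arch
height and calcaneal inclination with the measured foot lengths/widths
(NF 214.06 x 84.17 mm, HB 202.81 x 67.14 mm, FB 165.86 x 65.25 mm), lattice
tetrahedral meshes with guaranteed element quality, two-peak (1.1 body
weight) stance pressure series with archetype-specific regional load
shares, and density phantoms (uniform, cortical shell, gradient).

## Worked example

```r
library(footform)

p <- default_archetype("FB", seed = 1)
bones <- generate_foot_bones(p)          # 9 watertight bone surfaces
mesh  <- generate_foot_model(bones)      # assembled bone + soft tissue mesh
ser   <- generate_pressure_series(p)     # 51-frame stance at 50 Hz

st <- regional_stats(ser, region_map(dim(ser$frames)[2:3], "FB"))
st
#>             region peak_kpa mean_kpa
#> 1 lateral_forefoot 138.4286 23.06546
#> 2 lateral_rearfoot 166.7110 63.88382
#> 3  medial_forefoot 139.5505 23.09089
#> 4  medial_rearfoot 175.6078 67.17464

nc <- normalize_cop(cop_trajectory(ser), p$foot_length, p$foot_width)
diff(range(nc$x_pct))                    # medial-lateral CoP range
#> 0.8   (% of foot width; the bound foot barely rolls medio-laterally)

lc  <- foot_load_case(mesh, setNames(st$mean_kpa, st$region),
                      p$body_mass * 9.81)
asm <- assemble_stiffness(mesh, default_materials())
K   <- add_connectors(asm$K, mesh, lc$connector_pairs, lc$connector_k)
sol <- fe_solve(K, lc$f, lc$fixed_nodes, mesh, asm$cache, asm$E, asm$nu)
max(sol$von_mises[mesh$element_sets$bone_calcaneus])
#> 7.20  (peak calcaneal von Mises stress, MPa)

hist <- run_remodelling(mesh, lc, 0.8, remodel_params(n_days = 60))
hist
#> remodel_history: 60 day(s), 1578 bone elements, not converged
#>   bone mass 149.77 -> 76.62 g
```

The regional stats show the bound-foot signature (no toe/midfoot load,
rearfoot-dominated pressure); the FE solve puts the stress peak in the
calcaneus; 60 days of remodelling resorb lightly loaded bone while the
talar articulation and Achilles insertion retain the most density — the
adaptation pattern expected for a vertically loaded rearfoot.

A YAML-driven pipeline (`run_pipeline()`) chains all stages and writes STL,
`.inp`, CSV, VTK and a `summary.json`; `inst/scripts/footform.R` exposes the
same stages as a command-line tool
(`Rscript inst/scripts/footform.R simulate-data --archetype FB --seed 1
--out out/`).

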