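# piezorbc

Quantitative machinery for studying how the mechanosensitive ion channel
**Piezo1 organizes on the red blood cell (RBC) membrane**, for membrane
biophysicists and quantitative microscopists.

Piezo1 deforms its local membrane into a dome — a spherical cap of area
S<sub>cap</sub> = 450 nm² with intrinsic radius R<sub>P0</sub> ≈ 42 nm.  The
RBC is a biconcave disk whose surface mean curvature H runs from +0.24 µm⁻¹
in the concave central dimple to −0.52 µm⁻¹ on the convex rim.  The package
implements the *curvature-coupling* model of Piezo1 organization: each
surface point is assigned the minimum Helfrich bending energy

&nbsp;&nbsp;&nbsp;&nbsp;G<sub>M</sub> = (K<sub>b</sub>/2) ∫ (c₁+c₂)² dA,&nbsp;&nbsp;K<sub>b</sub> ≈ 20 k<sub>B</sub>T,

of the free membrane of a closed vesicle of curvature radius 1/|H| that
contains the dome (axisymmetric shooting solution of the shape equations,
with the orientation rule per sign of H), and the Boltzmann distribution
P(x) ∝ exp(−G(H(x))/k<sub>B</sub>T) turns the energy landscape into a
predicted channel density and a dimple/rim fold enrichment.  Around that
core the package provides:

* a calibrated biconcave **discocyte geometry** (tangent sphere–torus
  construction; quartic profile also available) with principal/mean
  curvature fields, areas and dimple/rim segmentation;
* **dome flexing**: joint minimization of membrane and dome-flexure energy
  over the dome radius of curvature;
* **spot statistics**: Laplacian-of-Gaussian spot detection in synthetic 3D
  stacks, nearest-neighbour distances with edge masking, Monte-Carlo CSR
  envelopes (G-function), per-region densities;
* **single-particle tracking**: time-averaged MSD, macroscopic (5 s) and
  microscopic (50 ms) diffusion coefficients, confinement diameters, dimple
  occupancy, and the dispersion-time utility τ = x²/6D;
* **optimal-transport colocalization (OTC)**: exact transport plans between
  two-channel image sections (network flow in C++), OTC curves with 95%
  confidence bands;
* seeded **synthetic-data generators** for all of the above, plus trajectory
  CSV / TIFF stack / PLY mesh / YAML configuration I/O and a
  `run_pipeline()` orchestrator.

## Worked example

```r
library(piezorbc)

cc <- curvature_coupling()   # calibrate shape, solve G(H), map to density
cc
#> Curvature-coupling model of Piezo1 on the discocyte surface
#>   surface area 137.98 um^2, H in [-0.525, 0.240] 1/um
#>   G(H) spans 0.648 kBT over the surface curvature range
#>   predicted dimple/rim density ratio: 1.808 (curvature-sign segmentation)
```

The calibrated cell (diameter 8 µm, central thickness 1 µm, max thickness
2.5 µm) has 137.98 µm² of membrane and mean curvatures spanning −0.525 to
+0.240 µm⁻¹.  The bending-energy profile spans ≈ 0.65 k<sub>B</sub>T ≈ ln 2
across that range, so the Boltzmann map predicts ≈ 1.8-fold (i.e.
"approximately two-fold") higher Piezo1 density in the dimple than on the
rim — with no fitted parameters.  Sampling synthetic cells from the fitted
density and re-analyzing them recovers the same enrichment the way an
imaging experiment would:

```r
spots <- do.call(rbind, lapply(1:5, function(i)
  sample_spots(spot_gen_params(seed = i), cc$density, cell_id = i)))
class(spots) <- c("spot_set", "data.frame")
region_density(spots, cc$regions)
#> Dimple/rim density ratio: 1.88 +/- 0.31 (N = 5 cells)

flex_dome(0.24)$R_opt        # dome radius in the dimple
#> [1] 41.60823
flex_dome(-0.52)$R_opt       # dome radius at the rim
#> [1] 42.88866
```

Dome flexing across the whole cell stays below ~2 nm: resting-shape
curvature alone cannot open the channel, which is why Piezo1 acts as a
force-through-membrane sensor of curvature *and* tension.

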