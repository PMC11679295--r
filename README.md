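# thermotomo

Steady-state 3D thermal tomography for cylindrical phantoms: a
finite-difference forward model, sinogram synthesis of the observable
surface temperature, and a physics-informed 3D convolutional autoencoder
that reconstructs the internal temperature field from surface data.

## The problem

Internal "hot-spots" — regions of elevated thermal activity only a few
kelvin above ambient, as in tissue — leave a faint, diffusion-blurred
signature on the surface of the body that contains them. Recovering the
full 3D temperature field from surface measurements is a severely
ill-posed inverse problem, and it gets harder as the domain grows and the
measurements get noisier. `thermotomo` is for researchers studying this
inverse problem under controlled, simulated conditions: it generates the
physics ground truth, the measurements, and the learned reconstruction,
and quantifies exactly how much of the interior is recoverable.

## The model

**Forward physics.** In steady state, heat conduction with volumetric
sources S reduces to a Poisson equation for the excess temperature
ΔT = T − T∞:

∇²ΔT = −S/k,  with convective cooling  k ∂ΔT/∂n = −h ΔT

on the surface. The cylinder (diameter 10–50 cm, conductivity
k = 0.5 W/(m·K), convection h = 7.5 W/(m²·K)) is voxelized on a
64×64×40 grid and solved by Jacobi iteration (or an equivalent red–black
SOR accelerator) with a ghost-cell Robin closure at every exposed voxel
face.

**Measurement.** An orthographic detector orbits the phantom: for each of
40 axial slices and 64 view angles, the visible half of the lateral
surface is projected onto a 64-pixel line, giving a (40, 64, 64) sinogram
stack. Detector noise = 10% relative Gaussian noise plus a per-image
background offset in [0.05, 0.1] K.

**Inverse model.** A 3D convolutional residual autoencoder (encoder
16/32/64/128 filters with strided 3×3×3 convolutions, 256-filter
bottleneck at 8×8×10, mirrored transposed-convolution decoder, ReLU
output) maps sinogram stacks to ΔT volumes. Training regimes: plain;
noise-augmented (fresh input noise each epoch); and noise + a
physics-informed loss

L_total = L_data + λ·L_physics,  L_physics = mean((∇²_h ΔT_pred + S/k)²),

where ∇²_h is the same discrete Robin-closed Laplacian the solver uses, so
the loss vanishes at the true solution. λ is auto-balanced at
initialization.

**Evaluation.** SSIM, PSNR, MSE, NMSE (= Σ(ΔT_true−ΔT_pred)²/ΣΔT_true²),
MAE, Dice and IoU, computed globally and inside a dilated region of
interest around the sources, aggregated per hot-spot count, plus the
NMSE-vs-depth curve with its Spearman rank correlation.

## Worked example

Solve a phantom, look at what the detector sees, and reconstruct:

```r
library(thermotomo)
set.seed(1)

spec <- phantom_spec(diameter = 0.10, nx = 16, ny = 16, nz = 12)
grid <- discretize_phantom(spec)
grid
#> <thermo_grid> 16 x 16 x 12, 2496 interior voxels, 1184 exposed faces

src  <- source_spec(x = 0.062, y = 0.05, z = spec$height / 2,
                    radius = 0.008, height = 0.03, power = 5e4)
S    <- rasterize_sources(src, grid)
tf   <- solve_steady_state(S, grid, tol = 1e-4)
tf
#> <temperature_field> 16 x 16 x 12, peak excess 4.301 K, 1428 sweeps
energy_balance(tf, S, grid)
#> [1] 0.000109153

stack <- build_sinograms(tf, grid, n_angles = 16, n_det = 16)
dim(stack)
#> [1] 12 16 16
```

The peak excess of ~4.3 K sits inside the source; the energy balance says
that the 0.011% of generated power unaccounted for at the surface is
within the solver tolerance. A small end-to-end experiment (generate →
train → evaluate on noisy inputs) runs in minutes on one CPU:

```r
res <- run_experiment(experiment_preset("noisy_50cm_noise", "micro"),
                      seed = 1)
dplyr::filter(res$report, metric == "nmse", scope == "global")
tidy(res$fit)       # per-epoch training history
autoplot(res$depth) # NMSE vs source depth
```

The three-regime comparison of the training schemes on shared data:

```r
trio <- run_regime_comparison(scale = "micro", seed = 1)
trio$comparison
#> # A tibble: 3 × 6
#>   regime      nmse nmse_roi  ssim ssim_roi depth_rho
#>   <chr>      <dbl>    <dbl> <dbl>    <dbl>     <dbl>
#> 1 plain      0.296    0.210 0.702    0.660     0.379
#> 2 noise      0.193    0.127 0.804    0.805     0.501
#> 3 noise_pinn 0.248    0.177 0.734    0.673     0.375
```

Training with input noise clearly dominates the plain regime on noisy
test inputs (NMSE 0.296 → 0.193, SSIM 0.702 → 0.804, globally and in the
ROI). At this micro scale the additional physics-informed term lands
between the two — the coarse 16³ grid leaves the physics residual little
fine structure to constrain — and the depth-error correlation comes out
positive (deep sources have smooth, high-energy fields that are easy to
match in relative error). The methods vignette discusses both
scale effects; the full-scale presets that reproduce the original
experiment design are included (`experiment_preset(..., scale = "full")`)
but sized for GPU-class budgets.

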