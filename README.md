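# bat90

Dosimetry and radiobiological modelling for radio-ablation of the breast
tumour bed with a planar yttrium-90 device.

After breast-conserving surgery for ductal carcinoma in situ, most local
recurrences arise at the resection margins. One proposed treatment applies a
thin layer of ⁹⁰Y-loaded microspheres embedded in a surgical sealant
directly onto the tumour bed, delivering a radio-ablative dose (20 Gy is the
conventional endpoint) to the first few millimetres of tissue while the
steep beta fall-off spares everything beyond ~1 cm. `bat90` implements the
full planning chain for this setting:

1. **Dose engine** — a condensed-history Monte Carlo (Rcpp) transports the
   full ⁹⁰Y beta spectrum (allowed-shape Fermi spectrum, endpoint
   2.2801 MeV, mean ≈ 0.93 MeV) from a uniform cylindrical source of radius
   R and thickness t through a homogeneous bulk (water or ICRP adipose),
   scoring absorbed dose per decay on an 80 × 80 × 25 mm grid of 1 mm
   voxels with batch-based uncertainties. A point-kernel superposition
   backend provides a deterministic cross-check.
2. **Profile model** — the tissue-side depth dose is parameterized as
   d(z) = a₁·exp(a₂·(z − z₀)), z₀ = t/2, with d in Gy·cm²/MBq (dose per
   unit areal activity for complete decay). The planning relation
   D(z) = d(z)·A/S, S = πR²/100 cm², is inverted to find the activity that
   places a prescription isodose D\* at shell depth k.
3. **Radiobiology** — linear-quadratic survival under an exponentially
   decaying dose rate, SF(D) = exp(−αD − λβD²/(λ+μ)), integrated over a
   clonogen density ρ(z) (constant, or decreasing linearly to zero at the
   prescription depth) gives surviving cells Nₛ, the Poisson tumour control
   probability exp(−Nₛ), the equivalent uniform dose at 2 Gy per fraction
   EUD₂Gy = −ln SF/(α + 2β), and the logistic TCP
   1/(1 + (D₅₀/EUD)^{4γ}).
4. **Brachytherapy comparison** — TG-43-style transverse-axis fall-off
   f_X(r) = [G(r)/G(1 cm)]·g_X(r) for reference photon sources versus the
   device's exponential fall-off, both normalized at 1 cm.

## Worked example

Plan the reference treatment — a 30 mm radius tumour bed, 1 mm device
layer, 20 Gy prescribed at a 3 mm tissue shell — from the published water
profile coefficients, then evaluate its radiobiology:

```r
library(bat90)

fit <- ref_profile_fit(t_mm = 1)   # a1 = 115.7 Gy cm2/MBq, a2 = -0.67/mm
plan <- activity_for_isodose(D_star_Gy = 20, k_mm = 3, R_mm = 30, fit = fit)
plan
#> <isodose_plan> 20 Gy at k = 3 mm (t = 1 mm, R = 30 mm):
#>   S = 28.274 cm2, areal activity = 1.29 MBq/cm2, A = 36.48 MBq

p  <- radiobio_params(alpha = 0.3, alpha_beta = 3.6, mu_h = 0.5)
m  <- density_model("constant", rho0 = 1e6, z0_mm = fit$z0_mm, k_mm = 3)
evaluate_tcp(fit, A_MBq = 35, R_mm = 30, model = m, p = p)
#> <tcp_result> N0 = 8.482e+06, Ns = 858.3, SF = 0.0001012
#>   TCP(Poisson) = 0, EUD_2Gy = 19.71 Gy, TCP(logistic) = 0.3741
```

So ~36 MBq place the 20 Gy isodose 3 mm deep; at the nominal 35 MBq a
residual disease of 10⁶ cells/cm³ distributed uniformly through the shell
is not controlled (Nₛ ≈ 858 survivors), and the logistic model puts the
control probability at 0.37. With the linearly decreasing density model
(cells concentrated where the dose is highest) the same plan reaches
EUD₂Gy = 24.5 Gy and TCP ≈ 0.59.

Running the Monte Carlo engine instead of using published coefficients:

```r
grid <- simulate_dose_grid(source_geometry(R_mm = 30, t_mm = 0),
                           material_water(),
                           transport_config(n_histories = 1e6, seed = 42))
prof <- depth_dose_profile(grid)
fit_exponential_profile(prof[prof$z_mm >= 0, ], t_mm = 0)
#> <dose_profile_fit> t = 0 mm: d(z) = 173.5 * exp(-0.7176 (z - 0))  [Gy cm2/MBq, z in mm]
#>   95% CI a1: (170.4, 176.5), a2: (-0.7425, -0.6927)
```

which reproduces the published water coefficients (a₁ = 170.9, a₂ = −0.72
per mm) within ~2%.

A thin command-line front end over the same functions lives at
`inst/cli/bat90` (subcommands `simulate`, `fit`, `plan`, `tcp`, `compare`,
`fixture`; YAML configuration whose defaults reproduce the reference
setup).

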