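#' @useDynLib bat90, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx runif rnorm integrate coef vcov qnorm lm
#' @importFrom utils read.csv write.csv
NULL

# MeV per joule conversions used throughout the dose engine
.MEV_TO_J <- 1.602176634e-13

#' Define a radionuclide by its half-life
#'
#' @param name Nuclide label, e.g. `"Y-90"`.
#' @param half_life_h Physical half-life in hours (> 0).
#'
#' @return An object of class `nuclide` with fields `name`, `half_life_h`
#'   and the derived decay constant `lambda_h` (per hour).
#' @examples
#' y90()
#' @export
nuclide <- function(name, half_life_h) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L || half_life_h <= 0)
    stop("`half_life_h` must be a single positive number")
  structure(
    list(name = name, half_life_h = half_life_h,
         lambda_h = log(2) / half_life_h),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %g h, lambda = %.6g /h\n",
              x$name, x$half_life_h, x$lambda_h))
  invisible(x)
}

#' Yttrium-90
#'
#' Pure beta-minus emitter used by the planar radio-ablation device:
#' half-life 64.1 h, endpoint energy 2.2801 MeV (nuclear-data value; often
#' quoted rounded as 2.26 MeV), mean beta energy about 0.94 MeV.
#'
#' @return A [nuclide] object.
#' @export
y90 <- function() nuclide("Y-90", 64.1)

#' Total number of decays from complete decay of an administered activity
#'
#' For a source left in place until extinction the cumulated number of
#' disintegrations is A / lambda with the decay constant expressed per
#' second (1 MBq = 1e6 decays/s).
#'
#' @param activity_MBq Administered activity in MBq (>= 0).
#' @param nuc A [nuclide], default [y90()].
#' @return Number of decays.
#' @examples
#' cumulated_decays(1) # ~3.33e11 for Y-90
#' @export
cumulated_decays <- function(activity_MBq, nuc = y90()) {
  if (any(activity_MBq < 0)) stop("activity must be non-negative")
  lambda_s <- nuc$lambda_h / 3600
  activity_MBq * 1e6 / lambda_s
}

#' Fraction of the total dose delivered after a residence time
#'
#' Under the complete-decay assumption the delivered fraction at time t is
#' 1 - exp(-lambda t); about 91% of the dose is delivered in 9 days for
#' Y-90 and essentially all of it in three weeks.
#'
#' @param t_h Time since administration in hours (>= 0), vectorized.
#' @param nuc A [nuclide], default [y90()].
#' @return Fraction in `[0, 1]`.
#' @export
fraction_delivered <- function(t_h, nuc = y90()) {
  if (any(t_h < 0)) stop("time must be non-negative")
  1 - exp(-nuc$lambda_h * t_h)
}

#' Initial dose rate of a mono-exponentially decaying delivery
#'
#' A delivery integrating to `total_dose_Gy` with rate proportional to
#' exp(-lambda t) starts at rate lambda * total dose; a 20 Gy prescription
#' with Y-90 starts at about 0.2 Gy/h.
#'
#' @param total_dose_Gy Total absorbed dose in Gy (>= 0).
#' @param nuc A [nuclide], default [y90()].
#' @return Initial dose rate in Gy/h.
#' @export
initial_dose_rate <- function(total_dose_Gy, nuc = y90()) {
  if (any(total_dose_Gy < 0)) stop("total dose must be non-negative")
  nuc$lambda_h * total_dose_Gy
}

# ---------------------------------------------------------------------------
# Beta spectrum

#' Allowed-shape beta spectrum
#'
#' Fermi-theory allowed-transition shape N(E) ~ p W (Emax - E)^2 F(Z, W)
#' with the non-relativistic Fermi Coulomb correction, tabulated on a
#' uniform energy grid and normalized to unit integral. The default
#' parameters describe the Y-90 ground-state transition (daughter Z = 40,
#' endpoint 2.2801 MeV); the resulting mean energy is ~0.933 MeV.
#'
#' A measured or evaluated spectrum can be supplied instead via
#' `energies_MeV`/`density`, which is renormalized on the same grid.
#'
#' @param e_max_MeV Endpoint energy in MeV.
#' @param z_daughter Atomic number of the daughter nucleus.
#' @param n_grid Number of grid points for the tabulated density.
#' @param energies_MeV,density Optional user-supplied tabulated spectrum
#'   (overrides the analytic shape; will be renormalized).
#' @return An object of class `beta_spectrum` with fields `energy_MeV`
#'   (grid), `pdf` (normalized density), `e_max_MeV` and `mean_MeV`.
#' @examples
#' sp <- beta_spectrum()
#' sp$mean_MeV
#' @export
beta_spectrum <- function(e_max_MeV = 2.2801, z_daughter = 40, n_grid = 2048,
                          energies_MeV = NULL, density = NULL) {
  if (!is.null(energies_MeV)) {
    stopifnot(length(energies_MeV) == length(density), all(density >= 0))
    grid <- seq(min(energies_MeV), max(energies_MeV), length.out = n_grid)
    pdf <- approx(energies_MeV, density, xout = grid, rule = 2)$y
    e_max_MeV <- max(energies_MeV)
  } else {
    mec2 <- 0.51099895 # electron rest energy, MeV
    alpha_fs <- 1 / 137.035999
    grid <- seq(e_max_MeV / n_grid, e_max_MeV, length.out = n_grid)
    W <- grid / mec2 + 1                  # total energy, mc^2 units
    p <- sqrt(pmax(W^2 - 1, 0))           # momentum, mc units
    beta_v <- p / W
    eta <- alpha_fs * z_daughter * W / p  # beta-minus: attractive Coulomb
    fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
    pdf <- p * W * (e_max_MeV - grid)^2 * fermi
  }
  h <- grid[2] - grid[1]
  norm <- sum(pdf) * h # midpoint rule on the uniform grid
  pdf <- pdf / norm
  structure(
    list(energy_MeV = grid, pdf = pdf, e_max_MeV = e_max_MeV,
         mean_MeV = sum(grid * pdf) * h),
    class = "beta_spectrum"
  )
}

#' @export
print.beta_spectrum <- function(x, ...) {
  cat(sprintf("<beta_spectrum> Emax = %g MeV, mean = %.4f MeV, %d grid points\n",
              x$e_max_MeV, x$mean_MeV, length(x$energy_MeV)))
  invisible(x)
}

# Inverse-CDF lookup table used both by the R sampler and the C++ engine.
.spectrum_inverse_cdf <- function(spectrum) {
  h <- spectrum$energy_MeV[2] - spectrum$energy_MeV[1]
  cdf <- cumsum(spectrum$pdf) * h
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  list(u = c(0, cdf[keep]), e = c(0, spectrum$energy_MeV[keep]))
}

#' Sample beta decay energies
#'
#' Inverse-CDF sampling of the tabulated spectrum; reproducible for a fixed
#' seed. The sample mean converges to the spectrum mean (~0.933 MeV for the
#' built-in Y-90 shape).
#'
#' @param n Number of samples (>= 1).
#' @param spectrum A [beta_spectrum].
#' @param seed Integer seed.
#' @return Numeric vector of energies in MeV, in `(0, e_max]`.
#' @export
sample_beta_energies <- function(n, spectrum = beta_spectrum(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1")
  tab <- .spectrum_inverse_cdf(spectrum)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  u <- runif(n)
  approx(tab$u, tab$e, xout = u, rule = 2)$y
}

# ---------------------------------------------------------------------------
# Materials

# Elemental data for stopping-power and radiation-length mixture rules:
# Z, atomic mass, mean excitation energy I (eV; condensed-phase adjusted
# Berger-Seltzer values for use in compounds).
.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Cl", "Ar"),
  Z = c(1, 6, 7, 8, 11, 17, 18),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 35.453, 39.948),
  I_eV = c(19.2, 81.0, 82.0, 106.0, 168.0, 180.0, 188.0),
  stringsAsFactors = FALSE
)

#' Define a homogeneous material
#'
#' Computes the electron-transport mixture quantities needed by the dose
#' engine: effective Z/A, mean excitation energy I (Bragg additivity unless
#' overridden) and radiation length X0 (for the multiple-scattering model).
#'
#' @param name Material label.
#' @param density_g_cm3 Mass density in g/cm^3.
#' @param composition Named numeric vector of element mass fractions
#'   (must sum to 1 within 1e-6); element symbols from
#'   H, C, N, O, Na, Cl, Ar.
#' @param i_eV Optional mean excitation energy override in eV (e.g. the
#'   ICRU value 75 eV for liquid water).
#' @return An object of class `material` with fields `name`, `density`,
#'   `composition`, `z_over_a`, `i_eV`, `x0_g_cm2`.
#' @examples
#' material_water()
#' material_adipose()
#' @export
material <- function(name, density_g_cm3, composition, i_eV = NULL) {
  if (density_g_cm3 <= 0) stop("density must be positive")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", sum(composition), ")")
  idx <- match(names(composition), .ELEMENTS$symbol)
  if (anyNA(idx)) stop("unknown element(s): ",
                       paste(names(composition)[is.na(idx)], collapse = ", "))
  el <- .ELEMENTS[idx, ]
  w <- as.numeric(composition)
  z_over_a <- sum(w * el$Z / el$A)
  if (is.null(i_eV)) # Bragg additivity on ln I weighted by electron fraction
    i_eV <- exp(sum(w * el$Z / el$A * log(el$I_eV)) / z_over_a)
  # Tsai radiation lengths per element, mixture by mass fraction
  x0_el <- 716.408 * el$A / (el$Z * (el$Z + 1) * log(287 / sqrt(el$Z)))
  x0 <- 1 / sum(w / x0_el)
  structure(
    list(name = name, density = density_g_cm3,
         composition = composition, z_over_a = z_over_a,
         i_eV = i_eV, x0_g_cm2 = x0),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: rho = %g g/cm3, Z/A = %.4f, I = %.1f eV, X0 = %.2f g/cm2\n",
              x$name, x$density, x$z_over_a, x$i_eV, x$x0_g_cm2))
  invisible(x)
}

#' @rdname material
#' @export
material_water <- function() {
  material("water", 1.0,
           c(H = 0.111894, O = 0.888106),
           i_eV = 75) # ICRU-37 liquid water
}

#' @rdname material
#' @export
material_adipose <- function() {
  # ICRP adipose tissue composition
  material("adipose", 0.95,
           c(H = 0.114, C = 0.598, N = 0.007, O = 0.278,
             Na = 0.001, Cl = 0.001, Ar = 0.001))
}
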