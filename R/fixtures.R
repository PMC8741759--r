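# Synthetic dose-grid fixtures: exact exponential depth profiles with
# optional multiplicative Gaussian plane noise. These let the profile and
# radiobiology layers be exercised (and their estimators calibrated)
# without running the transport engine; they are labelled synthetic in
# their metadata.

#' Specification for a synthetic dose grid
#'
#' @param a1 Profile amplitude, Gy cm^2/MBq.
#' @param a2 Profile slope, mm^-1 (negative).
#' @param t_mm Source thickness (z0 = t/2).
#' @param R_mm Source radius in mm.
#' @param noise_rel Relative (multiplicative) Gaussian noise applied per
#'   plane; 0 gives the exact model.
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(a1 = 115.7, a2 = -0.67, t_mm = 1, R_mm = 30,
                         noise_rel = 0, seed = 1L) {
  if (noise_rel < 0) stop("`noise_rel` must be non-negative")
  structure(list(a1 = a1, a2 = a2, t_mm = t_mm, R_mm = R_mm,
                 noise_rel = noise_rel, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic dose grid
#'
#' Builds a [dose_grid] whose plateau depth-dose profile is exactly
#' a1 * exp(a2 * (z - z0)) in Gy cm^2/MBq (optionally perturbed by
#' multiplicative Gaussian noise applied plane-wise), so that
#' [depth_dose_profile()] + [fit_exponential_profile()] recover the input
#' coefficients. The per-plane relative uncertainty is set to `noise_rel`
#' (or a negligible placeholder when noiseless) so inverse-variance
#' weighting is well defined.
#'
#' @param spec A [fixture_spec].
#' @param nuc A [nuclide] for the areal-activity conversion.
#' @return A [dose_grid] with `mode = "fixture"` and a `synthetic = TRUE`
#'   marker in its metadata.
#' @export
generate_fixture <- function(spec = fixture_spec(), nuc = y90()) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- .GRID
  z0 <- spec$t_mm / 2
  s_cm2 <- pi * spec$R_mm^2 / 100
  conv <- cumulated_decays(1, nuc) * s_cm2 # Gy/decay -> Gy cm^2/MBq
  d_true <- spec$a1 * exp(spec$a2 * (abs(g$z) - z0)) # symmetric in z
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  fac <- if (spec$noise_rel > 0)
    pmax(1 + spec$noise_rel * rnorm(length(d_true)), 0.05) else
    rep(1, length(d_true))
  d_obs <- d_true * fac
  sig_rel <- if (spec$noise_rel > 0) spec$noise_rel else 1e-9
  rr <- sqrt(outer(g$x^2, g$y^2, "+"))
  inside <- rr < spec$R_mm
  dose <- array(0, dim = c(g$nx, g$ny, g$nz))
  sigma <- array(0, dim = dim(dose))
  for (k in seq_along(g$z)) {
    dose[, , k][inside] <- d_obs[k] / conv
    sigma[, , k][inside] <- sig_rel * d_obs[k] / conv
  }
  structure(
    list(dose = dose, sigma = sigma, x_mm = g$x, y_mm = g$y, z_mm = g$z,
         geometry = source_geometry(spec$R_mm, spec$t_mm),
         material = "synthetic", n_histories = 0, seed = spec$seed,
         mode = "fixture", n_batch = 0L, nuclide = nuc,
         energy_MeV = list(emitted = NA_real_, deposited = NA_real_,
                           escaped = NA_real_),
         warnings = character(), synthetic = TRUE, spec = spec),
    class = "dose_grid"
  )
}
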