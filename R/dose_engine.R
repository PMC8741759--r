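# Voxel grid layout shared by every backend: 1 mm cubic voxels, centers at
# integer mm, x,y in {-40..39}, z in {-12..12} (80 x 80 x 25 voxels covering
# the 80 x 80 x 25 mm bulk). A plane "z = k mm" is the voxel layer centered
# at k.
.GRID <- list(nx = 80L, ny = 80L, nz = 25L,
              x = -40:39, y = -40:39, z = -12:12)

#' Source geometry of the planar device
#'
#' A uniform cylindrical source of radius `R_mm` and thickness `t_mm`
#' centered at the origin with its axis along z. `t_mm = 0` is a true planar
#' (delta-layer) source: emission points are sampled exactly on the plane
#' z = 0, which makes the dose in the z = 0 voxel layer singularly large.
#'
#' @param R_mm Source radius in mm (> 0).
#' @param t_mm Source thickness in mm (0 to 5 is the modelled range; values
#'   outside it warn but are not forbidden).
#' @return An object of class `source_geometry`.
#' @export
source_geometry <- function(R_mm = 30, t_mm = 0) {
  if (R_mm <= 0) stop("`R_mm` must be positive")
  if (t_mm < 0) stop("`t_mm` must be non-negative")
  if (t_mm > 5) warning("`t_mm` outside the modelled 0-5 mm range")
  structure(list(R_mm = R_mm, t_mm = t_mm), class = "source_geometry")
}

#' Transport configuration
#'
#' @param n_histories Number of primary decays to simulate (default 1e7,
#'   the reference simulation size).
#' @param seed Integer RNG seed.
#' @param mode `"mc"` for direct condensed-history Monte Carlo, `"kernel"`
#'   for superposition of a point-source kernel over the source cylinder.
#' @param n_batch Number of statistically independent batches used for the
#'   per-voxel uncertainty estimate.
#' @param max_defrac Maximum fractional energy loss per condensed step.
#' @param max_step_mm Maximum geometric step length in mm.
#' @param cutoff_MeV Tracking cutoff; residual energy is deposited locally.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(n_histories = 1e7, seed = 20260101L,
                             mode = c("mc", "kernel"), n_batch = 20L,
                             max_defrac = 0.05, max_step_mm = 0.5,
                             cutoff_MeV = 0.01) {
  if (n_histories < 1) stop("`n_histories` must be >= 1")
  mode <- match.arg(mode)
  structure(list(n_histories = n_histories, seed = as.integer(seed),
                 mode = mode, n_batch = as.integer(n_batch),
                 max_defrac = max_defrac, max_step_mm = max_step_mm,
                 cutoff_MeV = cutoff_MeV),
            class = "transport_config")
}

#' Simulate the voxel dose grid of the planar source
#'
#' Transports beta electrons emitted isotropically from positions uniform in
#' the source cylinder through the homogeneous bulk and scores absorbed dose
#' per decay on the 80x80x25 voxel grid. In `"kernel"` mode the grid is
#' instead built by superposing a Monte Carlo point-source dose kernel over
#' the source cylinder (deterministic given the kernel).
#'
#' @param geometry A [source_geometry].
#' @param mat A [material], default water.
#' @param cfg A [transport_config].
#' @param spectrum A [beta_spectrum]; default the built-in Y-90 shape.
#' @param nuc A [nuclide] used for activity conversions downstream.
#' @param kernel Optional precomputed [point_kernel] for `"kernel"` mode.
#' @return An object of class `dose_grid`: 3-D arrays `dose` and `sigma`
#'   (Gy per decay), axis vectors `x_mm`, `y_mm`, `z_mm`, energy bookkeeping
#'   in `energy_MeV`, and the full provenance metadata.
#' @export
simulate_dose_grid <- function(geometry, mat = material_water(),
                               cfg = transport_config(),
                               spectrum = beta_spectrum(), nuc = y90(),
                               kernel = NULL) {
  stopifnot(inherits(geometry, "source_geometry"), inherits(mat, "material"),
            inherits(cfg, "transport_config"))
  g <- .GRID
  if (geometry$R_mm > max(g$x) || geometry$t_mm / 2 > max(g$z) + 0.5)
    stop("source geometry exceeds the 80 x 80 x 25 mm bulk")
  vox_mass_kg <- mat$density * 1e-6 # 1 mm^3 voxel
  warnings <- character()
  if (cfg$mode == "mc") {
    tab <- .spectrum_inverse_cdf(spectrum)
    raw <- cpp_mc_grid(cfg$n_histories, cfg$seed, cfg$n_batch,
                       geometry$R_mm, geometry$t_mm,
                       mat$density, mat$z_over_a, mat$i_eV, mat$x0_g_cm2,
                       tab$u, tab$e,
                       cfg$cutoff_MeV, cfg$max_defrac, cfg$max_step_mm,
                       g$nx, g$ny, g$nz, g$x[1], g$y[1], g$z[1])
    conv <- .MEV_TO_J / vox_mass_kg / cfg$n_histories
    dose <- raw$edep_MeV * conv
    sigma <- raw$sigma_MeV * conv
    energy <- list(emitted = raw$e_emitted_MeV,
                   deposited = raw$e_deposited_MeV,
                   escaped = raw$e_escaped_MeV)
    if (cfg$n_histories < 1e5)
      warnings <- c(warnings,
                    "n_histories < 1e5: per-voxel uncertainties are large")
  } else {
    if (is.null(kernel)) kernel <- point_kernel(mat, cfg, spectrum)
    r_t <- seq(0, ceiling(sqrt(2) * max(abs(g$x)) + 1), by = 0.5)
    nz_q <- if (geometry$t_mm > 0) max(8L, ceiling(geometry$t_mm * 8)) else 1L
    # 3-point Gauss-Legendre through the voxel thickness: the scored MC dose
    # is a voxel average, not a center-point value, and the profile varies
    # by exp(0.7/mm), a 2% within-voxel effect
    gl_node <- 0.5 * 0.774596669241483
    gl_w <- c(5, 8, 5) / 18
    z_sub <- as.numeric(outer(c(-gl_node, 0, gl_node), g$z, "+"))
    dz_sub <- cpp_kernel_superpose(kernel$r_mm, kernel$dose_Gy,
                                   geometry$R_mm, geometry$t_mm,
                                   r_t, z_sub,
                                   128L, 128L, nz_q)
    dz_mat <- matrix(0, nrow = length(r_t), ncol = g$nz)
    for (k in seq_len(g$nz)) {
      cols <- (k - 1L) * 3L + 1:3
      dz_mat[, k] <- dz_sub[, cols, drop = FALSE] %*% gl_w
    }
    dose <- array(0, dim = c(g$nx, g$ny, g$nz))
    rr <- sqrt(outer(g$x^2, g$y^2, "+"))
    for (k in seq_len(g$nz)) {
      dose[, , k] <- matrix(approx(r_t, dz_mat[, k], xout = rr, rule = 2)$y,
                            g$nx, g$ny)
    }
    sigma <- array(0, dim = dim(dose))
    energy <- list(emitted = kernel$energy_MeV$emitted / kernel$n_histories,
                   deposited = NA_real_, escaped = NA_real_)
  }
  structure(
    list(dose = dose, sigma = sigma,
         x_mm = g$x, y_mm = g$y, z_mm = g$z,
         geometry = geometry, material = mat$name,
         n_histories = cfg$n_histories, seed = cfg$seed, mode = cfg$mode,
         n_batch = cfg$n_batch, nuclide = nuc, energy_MeV = energy,
         warnings = warnings),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s, R = %g mm, t = %g mm, %s backend, %.3g histories, seed %d\n",
              x$material, x$geometry$R_mm, x$geometry$t_mm, x$mode,
              x$n_histories, x$seed))
  cat(sprintf("  %d x %d x %d voxels (1 mm), peak dose %.3g Gy/decay\n",
              length(x$x_mm), length(x$y_mm), length(x$z_mm), max(x$dose)))
  invisible(x)
}

#' Monte Carlo point-source dose kernel
#'
#' Dose per decay versus distance from an isotropic point source in an
#' unbounded homogeneous medium, scored in thin spherical shells. Used by
#' the `"kernel"` backend of [simulate_dose_grid()].
#'
#' @param mat A [material].
#' @param cfg A [transport_config]; `n_histories` and `seed` are used.
#' @param spectrum A [beta_spectrum].
#' @param dr_mm Shell thickness in mm.
#' @param r_max_mm Outer scoring radius in mm (beyond the 11 mm beta range).
#' @return An object of class `point_kernel`: `r_mm` (shell centers),
#'   `dose_Gy` (mean dose per decay in each shell) and energy bookkeeping.
#' @export
point_kernel <- function(mat = material_water(),
                         cfg = transport_config(n_histories = 2e5),
                         spectrum = beta_spectrum(),
                         dr_mm = 0.025, r_max_mm = 15) {
  tab <- .spectrum_inverse_cdf(spectrum)
  n_shell <- as.integer(ceiling(r_max_mm / dr_mm))
  raw <- cpp_mc_point_kernel(cfg$n_histories, cfg$seed,
                             mat$density, mat$z_over_a, mat$i_eV,
                             mat$x0_g_cm2, tab$u, tab$e,
                             cfg$cutoff_MeV, cfg$max_defrac, cfg$max_step_mm,
                             dr_mm, n_shell)
  edges <- seq(0, by = dr_mm, length.out = n_shell + 1)
  vol_mm3 <- 4 / 3 * pi * diff(edges^3)
  mass_kg <- mat$density * vol_mm3 * 1e-6
  structure(
    list(r_mm = (edges[-1] + edges[-(n_shell + 1)]) / 2,
         dose_Gy = raw$shell_MeV * .MEV_TO_J / mass_kg / cfg$n_histories,
         n_histories = cfg$n_histories, seed = cfg$seed,
         material = mat$name, dr_mm = dr_mm,
         energy_MeV = list(emitted = raw$e_emitted_MeV,
                           deposited = sum(raw$shell_MeV),
                           escaped = raw$e_escaped_MeV)),
    class = "point_kernel"
  )
}

#' Depth-dose profile averaged over the uniform plateau
#'
#' Per-plane mean dose over voxels with radial distance `r < r_max_mm`
#' (default `R - 5` mm, inside the uniform plateau of the planar source),
#' expressed both per decay and per unit areal activity for complete decay
#' (Gy cm^2/MBq, the planning unit). Planes inside the source layer
#' (`|z| <= t/2`) are flagged with `in_source = TRUE`; their doses belong
#' to the device, not the tissue.
#'
#' @param grid A [dose_grid].
#' @param r_max_mm Plateau averaging radius; must be below the source radius.
#' @return A data frame with columns `z_mm`, `dose_per_decay_Gy`,
#'   `sigma_per_decay_Gy`, `dose_Gy_cm2_MBq`, `sigma_Gy_cm2_MBq`,
#'   `in_source`.
#' @export
depth_dose_profile <- function(grid, r_max_mm = grid$geometry$R_mm - 5) {
  stopifnot(inherits(grid, "dose_grid"))
  if (r_max_mm >= grid$geometry$R_mm)
    stop("`r_max_mm` must be inside the source radius")
  rr <- sqrt(outer(grid$x_mm^2, grid$y_mm^2, "+"))
  sel <- rr < r_max_mm
  if (!any(sel)) stop("no voxels selected: increase `r_max_mm`")
  n <- sum(sel)
  dose_pd <- vapply(seq_along(grid$z_mm),
                    function(k) mean(grid$dose[, , k][sel]), numeric(1))
  sig_pd <- vapply(seq_along(grid$z_mm),
                   function(k) sqrt(sum(grid$sigma[, , k][sel]^2)) / n,
                   numeric(1))
  # Gy per decay -> Gy per (MBq/cm^2) of areal activity, complete decay:
  # 1 MBq/cm^2 over area S cm^2 is S MBq in total.
  s_cm2 <- pi * grid$geometry$R_mm^2 / 100
  conv <- cumulated_decays(1, grid$nuclide) * s_cm2
  data.frame(z_mm = grid$z_mm,
             dose_per_decay_Gy = dose_pd,
             sigma_per_decay_Gy = sig_pd,
             dose_Gy_cm2_MBq = dose_pd * conv,
             sigma_Gy_cm2_MBq = sig_pd * conv,
             in_source = abs(grid$z_mm) < grid$geometry$t_mm / 2)
}

#' Radial dose profile on one plane
#'
#' Voxel doses on the plane `z = z_mm` binned by radial distance
#' r = sqrt(x^2 + y^2) in 1 mm annuli. Shows the uniform plateau out to
#' about `R - 5` mm and the steep fall-off at the source edge.
#'
#' @param grid A [dose_grid].
#' @param z_mm Plane (integer mm within the grid).
#' @return Data frame with `r_mm` (bin center), `dose_per_decay_Gy`,
#'   `sigma_per_decay_Gy`, `n_voxels`.
#' @export
radial_dose_profile <- function(grid, z_mm = 1) {
  stopifnot(inherits(grid, "dose_grid"))
  k <- match(z_mm, grid$z_mm)
  if (is.na(k)) stop("`z_mm` outside the grid")
  rr <- sqrt(outer(grid$x_mm^2, grid$y_mm^2, "+"))
  bin <- floor(rr)
  d <- grid$dose[, , k]
  s <- grid$sigma[, , k]
  bins <- sort(unique(as.integer(bin)))
  out <- lapply(bins, function(b) {
    sel <- bin == b
    data.frame(r_mm = b + 0.5,
               dose_per_decay_Gy = mean(d[sel]),
               sigma_per_decay_Gy = sqrt(sum(s[sel]^2)) / sum(sel),
               n_voxels = sum(sel))
  })
  do.call(rbind, out)
}

#' Rescale a water depth-dose profile to another density
#'
#' Electrons have (to good approximation) a material-invariant range in mass
#' thickness, so the depth-dose profile in a medium of density rho is the
#' water profile stretched along z by rho_water / rho with unchanged
#' per-mass dose values: for ICRP adipose (0.95 g/cm^3) the stretch factor
#' is 1/0.95 = 1.053.
#'
#' @param profile A depth-dose profile data frame (from
#'   [depth_dose_profile()] or any frame with a `z_mm` column).
#' @param mat Target [material].
#' @param from_mat Material the profile was computed in (default water).
#' @return The profile with `z_mm` scaled; the stretch factor is attached as
#'   attribute `"scale_factor"`.
#' @export
density_scaled_profile <- function(profile, mat, from_mat = material_water()) {
  if (mat$density <= 0) stop("target density must be positive")
  f <- from_mat$density / mat$density
  profile$z_mm <- profile$z_mm * f
  attr(profile, "scale_factor") <- f
  profile
}

# ---------------------------------------------------------------------------
# Serialization: flat CSV of voxel values + JSON metadata sidecar

#' Write / read a dose grid
#'
#' The grid is stored as a flat CSV (`x_mm, y_mm, z_mm, dose, sigma`, doses
#' in Gy per decay) next to a JSON metadata sidecar recording material,
#' geometry, backend, history count and seed, so that a stored grid is fully
#' reproducible.
#'
#' @param grid A [dose_grid].
#' @param path_csv CSV path; the sidecar defaults to `<path_csv>.json`.
#' @param path_json Sidecar path.
#' @return `write_dose_grid()` returns the paths invisibly;
#'   `read_dose_grid()` returns the reconstructed [dose_grid].
#' @export
write_dose_grid <- function(grid, path_csv,
                            path_json = paste0(path_csv, ".json")) {
  stopifnot(inherits(grid, "dose_grid"))
  df <- expand.grid(x_mm = grid$x_mm, y_mm = grid$y_mm, z_mm = grid$z_mm,
                    KEEP.OUT.ATTRS = FALSE)
  df$dose <- as.vector(grid$dose)
  df$sigma <- as.vector(grid$sigma)
  write.csv(df, path_csv, row.names = FALSE)
  meta <- list(material = grid$material,
               R_mm = grid$geometry$R_mm, t_mm = grid$geometry$t_mm,
               n_histories = grid$n_histories, seed = grid$seed,
               mode = grid$mode, n_batch = grid$n_batch,
               nuclide = grid$nuclide$name,
               half_life_h = grid$nuclide$half_life_h,
               energy_MeV = grid$energy_MeV, warnings = grid$warnings)
  jsonlite::write_json(meta, path_json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path_csv, json = path_json))
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path_csv, path_json = paste0(path_csv, ".json")) {
  df <- read.csv(path_csv)
  meta <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  g <- .GRID
  stopifnot(nrow(df) == g$nx * g$ny * g$nz)
  df <- df[order(df$z_mm, df$y_mm, df$x_mm), ]
  dims <- c(g$nx, g$ny, g$nz)
  structure(
    list(dose = array(df$dose, dims), sigma = array(df$sigma, dims),
         x_mm = g$x, y_mm = g$y, z_mm = g$z,
         geometry = source_geometry(meta$R_mm, meta$t_mm),
         material = meta$material,
         n_histories = meta$n_histories, seed = meta$seed,
         mode = meta$mode, n_batch = meta$n_batch,
         nuclide = nuclide(meta$nuclide, meta$half_life_h),
         energy_MeV = meta$energy_MeV,
         warnings = meta$warnings %||% character()),
    class = "dose_grid"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
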