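# Shared Monte Carlo fixtures, built once per test run. Sizes are chosen so
# the whole suite stays desk-scale while plane-level statistics are a few
# tenths of a percent in the near field.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

water_grid_t0 <- function() cached("grid_t0", {
  simulate_dose_grid(source_geometry(R_mm = 30, t_mm = 0), material_water(),
                     transport_config(n_histories = 2e5, seed = 42))
})

water_kernel <- function() cached("kernel_water", {
  point_kernel(material_water(),
               transport_config(n_histories = 5e5, seed = 7))
})

water_grid_t0_kernel_mode <- function() cached("grid_t0_kernel", {
  simulate_dose_grid(source_geometry(R_mm = 30, t_mm = 0), material_water(),
                     transport_config(seed = 7, mode = "kernel"),
                     kernel = water_kernel())
})

# profiles and fits across thicknesses at modest statistics
water_profiles_by_t <- function() cached("profiles_by_t", {
  lapply(c(0, 1, 3, 5), function(t) {
    g <- simulate_dose_grid(source_geometry(30, t), material_water(),
                            transport_config(n_histories = 1.5e5,
                                             seed = 100L + t))
    depth_dose_profile(g)
  })
})

water_fits_by_t <- function() cached("fits_by_t", {
  mapply(function(prof, t) {
    fit_exponential_profile(
      prof[!prof$in_source & prof$z_mm >= 0,
           c("z_mm", "dose_Gy_cm2_MBq", "sigma_Gy_cm2_MBq")],
      t_mm = t)
  }, water_profiles_by_t(), c(0, 1, 3, 5), SIMPLIFY = FALSE)
})
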