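# Run configuration and pipeline stages. The defaults reproduce the
# reference study setup end to end: a 30 mm radius, 1 mm thick source in an
# 80 x 80 x 25 mm water bulk, 1e7 histories, a 20 Gy prescription at
# k = 3 mm, and the alpha-sweep / density scenarios of the radiobiological
# analysis.

#' Default run configuration
#'
#' @return A nested list (class `run_config`) with sections `geometry`,
#'   `material`, `transport`, `prescription`, `radiobiology`, `logistic`
#'   and `output_dir`.
#' @export
default_run_config <- function() {
  structure(list(
    geometry = list(R_mm = 30, t_mm = 1),
    material = "water",
    transport = list(n_histories = 1e7, seed = 20260101L, mode = "mc"),
    prescription = list(D_star_Gy = 20, k_mm = 3),
    radiobiology = list(
      alphas = seq(0.02, 0.90, by = 0.04),
      alpha_single = 0.3,
      alpha_beta = 3.6, mu_h = 0.5,
      rho0 = c(1e4, 1e5, 1e6, 1e7),
      density_kinds = c("constant", "linear")),
    logistic = list(d50_Gy = 22.39, gamma = 1.01),
    output_dir = "bat90-out"
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unspecified fields fall back to [default_run_config()]; unknown material
#' names or invalid fields raise an error naming the field.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_in(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_in(cfg, user)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg A `run_config` to validate.
#' @export
validate_run_config <- function(cfg) {
  if (!cfg$material %in% c("water", "adipose"))
    stop("config field `material` must be 'water' or 'adipose', got '",
         cfg$material, "'")
  if (cfg$geometry$R_mm <= 0) stop("config field `geometry.R_mm` must be > 0")
  if (cfg$geometry$t_mm < 0) stop("config field `geometry.t_mm` must be >= 0")
  if (cfg$transport$n_histories < 1)
    stop("config field `transport.n_histories` must be >= 1")
  if (!cfg$transport$mode %in% c("mc", "kernel"))
    stop("config field `transport.mode` must be 'mc' or 'kernel'")
  if (cfg$prescription$D_star_Gy <= 0)
    stop("config field `prescription.D_star_Gy` must be > 0")
  if (cfg$prescription$k_mm < 0)
    stop("config field `prescription.k_mm` must be >= 0")
  if (!all(cfg$radiobiology$density_kinds %in% c("constant", "linear")))
    stop("config field `radiobiology.density_kinds` must be constant/linear")
  invisible(cfg)
}

.material_by_name <- function(name) {
  switch(name, water = material_water(), adipose = material_adipose(),
         stop("unknown material '", name, "'"))
}

# Short deterministic content hash (131-polynomial mod 2^31-1) for audit
# trails; exact in double arithmetic
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage_log <- function(stage, cfg, ...) {
  extra <- list(...)
  msg <- paste0(sprintf("[%s] stage=%s config=%s seed=%s",
                        format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                        .config_hash(cfg), cfg$transport$seed),
                if (length(extra))
                  paste0(" ", paste(names(extra), unlist(extra),
                                    sep = "=", collapse = " ")) else "")
  message(msg)
  invisible(msg)
}

#' Pipeline stage: simulate the dose grid
#'
#' Runs the dose engine per the configuration and writes the grid CSV and
#' its JSON metadata sidecar into `output_dir`.
#'
#' @param cfg A `run_config`.
#' @return The [dose_grid], invisibly; files written to `cfg$output_dir`.
#' @export
run_simulate <- function(cfg = default_run_config()) {
  validate_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- simulate_dose_grid(
    source_geometry(cfg$geometry$R_mm, cfg$geometry$t_mm),
    .material_by_name(cfg$material),
    transport_config(n_histories = cfg$transport$n_histories,
                     seed = cfg$transport$seed, mode = cfg$transport$mode))
  paths <- write_dose_grid(grid, file.path(cfg$output_dir, "dose_grid.csv"))
  .stage_log("simulate", cfg, n_histories = cfg$transport$n_histories,
             mode = cfg$transport$mode, out = paths[["csv"]])
  invisible(grid)
}

#' Pipeline stage: fit the depth-dose profile
#'
#' @param cfg A `run_config`.
#' @param grid A [dose_grid] (from [run_simulate()] or a fixture).
#' @return The [dose_profile_fit], invisibly; coefficients written as JSON.
#' @export
run_fit <- function(cfg, grid) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- depth_dose_profile(grid)
  tissue <- prof[!prof$in_source & prof$z_mm >= 0, ]
  fit <- fit_exponential_profile(
    data.frame(z_mm = tissue$z_mm, dose = tissue$dose_Gy_cm2_MBq,
               sigma = tissue$sigma_Gy_cm2_MBq),
    t_mm = grid$geometry$t_mm)
  out <- file.path(cfg$output_dir,
                   sprintf("profile_fit_t%g.json", grid$geometry$t_mm))
  jsonlite::write_json(
    list(t_mm = fit$t_mm, z0_mm = fit$z0_mm, a1 = fit$a1, a2 = fit$a2,
         ci95_a1 = fit$ci95_a1, ci95_a2 = fit$ci95_a2,
         config_hash = .config_hash(cfg), seed = grid$seed),
    out, auto_unbox = TRUE, digits = NA)
  .stage_log("fit", cfg, t_mm = fit$t_mm, a1 = signif(fit$a1, 6),
             a2 = signif(fit$a2, 6))
  invisible(fit)
}

#' Pipeline stage: plan the activity
#'
#' @param cfg A `run_config`.
#' @param fit A [dose_profile_fit].
#' @return The [isodose_plan], invisibly; plan JSON and a planning-table CSV
#'   are written to `output_dir`.
#' @export
run_plan <- function(cfg, fit) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  plan <- activity_for_isodose(cfg$prescription$D_star_Gy,
                               cfg$prescription$k_mm,
                               cfg$geometry$R_mm, fit)
  jsonlite::write_json(
    list(R_mm = plan$R_mm, t_mm = plan$t_mm, k_mm = plan$k_mm,
         D_star_Gy = plan$D_star_Gy, S_cm2 = plan$S_cm2,
         areal_MBq_cm2 = plan$areal_MBq_cm2, A_MBq = plan$A_MBq,
         a1 = fit$a1, a2 = fit$a2,
         config_hash = .config_hash(cfg), seed = cfg$transport$seed),
    file.path(cfg$output_dir, "plan.json"), auto_unbox = TRUE, digits = NA)
  write.csv(tabulate_plan(list(fit), D_star_Gy = cfg$prescription$D_star_Gy),
            file.path(cfg$output_dir, "plan_table.csv"), row.names = FALSE)
  .stage_log("plan", cfg, A_MBq = signif(plan$A_MBq, 6))
  invisible(plan)
}

#' Read a plan JSON back
#' @param path Path to a `plan.json` written by [run_plan()].
#' @return An [isodose_plan].
#' @export
read_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  activity_for_isodose(p$D_star_Gy, p$k_mm, p$R_mm,
                       dose_profile_fit(p$a1, p$a2, p$t_mm))
}

#' Pipeline stage: radiobiological evaluation
#'
#' Writes one alpha-sweep CSV per (density kind, rho0) scenario plus the
#' single-point evaluation at `alpha_single` for both density kinds.
#'
#' @param cfg A `run_config`.
#' @param plan An [isodose_plan].
#' @return Named list of `tcp_result`s for the single-point evaluation,
#'   invisibly.
#' @export
run_tcp <- function(cfg, plan) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  rb <- cfg$radiobiology
  lp <- logistic_params(cfg$logistic$d50_Gy, cfg$logistic$gamma)
  fit <- plan$fit
  n_curves <- 0L
  for (kind in rb$density_kinds) {
    for (r0 in rb$rho0) {
      m <- density_model(kind, r0, z0_mm = fit$z0_mm, k_mm = plan$k_mm)
      sweep <- tcp_alpha_sweep(fit, plan$A_MBq, plan$R_mm, m,
                               alphas = rb$alphas, lp = lp,
                               alpha_beta = rb$alpha_beta, mu_h = rb$mu_h)
      write.csv(sweep,
                file.path(cfg$output_dir,
                          sprintf("tcp_sweep_%s_rho%.0e.csv", kind, r0)),
                row.names = FALSE)
      n_curves <- n_curves + 1L
    }
  }
  single <- lapply(rb$density_kinds, function(kind) {
    m <- density_model(kind, rb$rho0[[1]], z0_mm = fit$z0_mm,
                       k_mm = plan$k_mm)
    p <- radiobio_params(rb$alpha_single, rb$alpha_beta, rb$mu_h)
    evaluate_tcp(fit, plan$A_MBq, plan$R_mm, m, p, lp)
  })
  names(single) <- rb$density_kinds
  jsonlite::write_json(
    lapply(single, function(r) r[c("sf", "eud_2gy", "tcp_logistic",
                                   "tcp_poisson")]),
    file.path(cfg$output_dir, "tcp_single_point.json"),
    auto_unbox = TRUE, digits = NA)
  .stage_log("tcp", cfg, curves = n_curves)
  invisible(single)
}

#' Pipeline stage: brachytherapy fall-off comparison
#'
#' @param cfg A `run_config`.
#' @param fits Device profile fits to include.
#' @return The comparison data frame, invisibly; CSV written to
#'   `output_dir`.
#' @export
run_compare <- function(cfg, fits = lapply(c(0, 1, 3, 5), ref_profile_fit)) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- compare_falloff(fits = fits)
  write.csv(tab, file.path(cfg$output_dir, "falloff_comparison.csv"),
            row.names = FALSE)
  .stage_log("compare", cfg, radii = nrow(tab))
  invisible(tab)
}
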