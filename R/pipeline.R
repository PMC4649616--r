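# End-to-end demonstration pipeline with run provenance.

# tiny polynomial rolling hash for config provenance (no external digest
# dependency; stays within exact double-precision integer range)
.confighash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' The packaged demo configuration: microrheology roundtrips on the
#' reference creep and oscillatory parameter sets, a centrifugation-cohort
#' collapse, a spatial-statistics recovery, and a short 1000-g simulation.
#'
#' @return a named list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    creep_params = list(E = 0.14, eta2 = 0.15, eta1 = 1.7),
    oscillatory_params = list(E = 0.10, eta2 = 0.05, eta1 = 0.9),
    cohort = list(eta = 1.7, g_multiples = c(10, 100, 1000)),
    cloud = list(n_bodies = 500, target_z0 = 50, exponent = -1.5),
    sim = list(g_multiple = 1000, n_particles = 300, t_end = 600)
  )
}

#' Run the demonstration pipeline
#'
#' Generates synthetic inputs with known ground truth, runs every analysis
#' stage (creep refit, oscillatory refit, force-time collapse, asymmetry
#' and size statistics, a short sedimentation simulation) and aggregates
#' the results with a run manifest (config hash, seed, package version,
#' timestamps). Deterministic given `seed`.
#'
#' @param config named list as in [default_pipeline_config()].
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param out_dir optional directory; when given, the report and manifest
#'   are written there as JSON.
#' @return a list: `report` (per-stage results) and `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1,
                         out_dir = NULL) {
  t_start <- Sys.time()
  report <- list()

  pc <- config$creep_params
  p_creep <- viscoelastic_params(pc$E, pc$eta2, pc$eta1)
  traj <- synth_creep_trajectory(p_creep, seed = seed)
  curve <- compliance_from_step(traj, traj$meta$truth$F0, traj$bead_radius)
  fit_c <- fit_model_to_creep(curve, n_boot = 0)
  report$creep_fit <- list(E = fit_c$params$E, eta2 = fit_c$params$eta2,
                           eta1 = fit_c$params$eta1,
                           truth = unclass(p_creep))

  po <- config$oscillatory_params
  p_osc <- viscoelastic_params(po$E, po$eta2, po$eta1)
  spec <- synth_moduli_spectrum(p_osc, seed = seed)
  fit_o <- fit_model_to_moduli(spec, n_boot = 0, seed = seed)
  report$oscillatory_fit <- list(E = fit_o$params$E, eta2 = fit_o$params$eta2,
                                 eta1 = fit_o$params$eta1,
                                 truth = unclass(p_osc))

  co <- config$cohort
  cohort <- synth_cohort(g_multiples = co$g_multiples, eta = co$eta,
                         seed = seed + 1)
  col <- force_time_collapse(cohort)
  report$collapse <- list(eta = col$eta, eta_truth = co$eta,
                          eta_per_series = as.list(col$eta_per_series))

  cl <- config$cloud
  syn <- synth_nucleolus_cloud(n_bodies = cl$n_bodies,
                               target_z0 = cl$target_z0,
                               exponent = cl$exponent, seed = seed + 2)
  geom <- fit_ellipsoid(syn$geometry)
  aligned <- align_gravity_axis(normalize_to_sphere(syn$cloud, geom))
  pl <- fit_power_law(volume_from_radius(aligned$radii),
                      v_min = syn$cloud$meta$truth$v_min,
                      v_max = syn$cloud$meta$truth$v_max)
  report$spatial <- list(z0 = asymmetry_z0(aligned)$z0,
                         z0_truth = cl$target_z0,
                         exponent = pl$exponent,
                         exponent_truth = cl$exponent)

  sm <- config$sim
  cfg <- sim_config(g_multiple = sm$g_multiple, n_particles = sm$n_particles,
                    t_end = sm$t_end, seed = seed + 3)
  run <- run_sedimentation(cfg, n_samples = 20)
  last <- run$series[nrow(run$series), ]
  report$simulation <- list(delta_z_final = last$delta_z_um,
                            count_final = last$count,
                            r_median_final = last$r_median_um,
                            tau_star_100um = time_to_displacement(run, 100))

  manifest <- list(command = "run_pipeline",
                   config_hash = .confighash(config),
                   seed = seed,
                   tool_version = as.character(utils::packageVersion("gravicreep")),
                   started = format(t_start, usetz = TRUE),
                   finished = format(Sys.time(), usetz = TRUE),
                   defaulted = list(delta_rho_kg_m3 = 50,
                                    bead_radius_um = 1.4,
                                    box_side_um = cfg$box_side))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, manifest = manifest)
}
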