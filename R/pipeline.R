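#' Pipeline configuration
#'
#' Bundles every stage specification for [run_pipeline()]. A single seed
#' governs all stochastic stages and is logged in the report.
#'
#' @param transducer a [transducer_spec()] (default: the 250-kHz / 67-mm
#'   bowl with the assumed 32-mm aperture)
#' @param medium a [medium_spec()] (default water)
#' @param burst a [burst_spec()] (default 500 cycles / 20 ms)
#' @param stone a [stone_spec()] positioned relative to the focus, or
#'   NULL for stone-free mode; by default a 10-mm hemisphere with its
#'   south pole at the physical focus
#' @param pc_star cavitation threshold fraction (required, default 0.46)
#' @param sim a [sim_config()] for the scattering stage
#' @param field_grid list with `r` and `z` vectors for the analytic
#'   field map (m); defaults resolve the focal lobe
#' @param synthetic logical: run the synthetic-scene recovery stage
#' @param seed integer seed
#' @param out_dir optional directory for artifacts (report.json, CSVs)
#' @param verbose print per-stage progress
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(transducer = transducer_spec(250e3, 67e-3, 32e-3,
                                                         u0 = 1e-2),
                            medium = water(),
                            burst = burst_spec(500, 20e-3, 250e3),
                            stone = "auto",
                            pc_star = 0.46,
                            sim = sim_config(),
                            field_grid = list(r = seq(0, 12e-3, by = 0.2e-3),
                                              z = seq(15e-3, 110e-3,
                                                      by = 0.75e-3)),
                            synthetic = TRUE, seed = 1L, out_dir = NULL,
                            verbose = TRUE) {
  structure(list(transducer = transducer, medium = medium, burst = burst,
                 stone = stone, pc_star = pc_star, sim = sim,
                 field_grid = field_grid, synthetic = synthetic,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the field -> scattering -> regions -> optimum chain end to end
#'
#' Stages: (1) burst duty cycle; (2) analytic axial profile and physical
#' focus; (3) Rayleigh field map and focal-ellipsoid geometry (gamma_f,
#' l1, l2, alpha1, alpha2); (4) with a stone: time-domain scattering
#' simulation, supra-threshold region table, cap angle theta_p and
#' damage coefficient A1*, and the optimum source-to-stone distance z+;
#' (5) synthetic-scene recovery metrics (bubble census density, cloud
#' rise speed, theta_b/theta_d closed loop). Stone-free mode (stone =
#' NULL) skips stage 4 and its report keys. Any stage error aborts with
#' the stage name.
#'
#' @param config a [pipeline_config()]
#' @return the report as a named list (also written to
#'   `out_dir/report.json` when `out_dir` is set)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("[%s] running", name)
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  report <- list(seed = config$seed)

  report$duty_cycle_pct <- stage("burst", {
    burst_waveform(config$burst,
                   sample_rate = 20 * config$burst$carrier_frequency)$duty_cycle
  })

  axial <- stage("axial-field", {
    z <- seq(5e-3, 2 * config$transducer$focus, by = 0.05e-3)
    oneil_axial(config$transducer, config$medium, z)
  })
  gamma_f <- physical_focus(axial)
  report$gamma_f_mm <- gamma_f * 1e3

  geom <- stage("focal-geometry", {
    fm <- rayleigh_field(config$transducer, config$medium,
                         config$field_grid$r, config$field_grid$z)
    focal_geometry_fit(fm, config$transducer, config$medium)
  })
  # one gamma_f for the whole report: the finely sampled axial argmax
  geom$gamma_f <- gamma_f
  report$l1_mm <- geom$l1 * 1e3
  report$l2_mm <- geom$l2 * 1e3
  report$alpha1 <- geom$alpha1
  report$alpha2 <- geom$alpha2

  stone <- config$stone
  # solver coordinates: bowl apex at sim$source_z, so the rim-plane field
  # origin sits at source_z + h
  rim0 <- config$sim$source_z + bowl_geometry(config$transducer)$h
  if (identical(stone, "auto"))
    stone <- stone_spec("hemisphere", radius = 10e-3,
                        apex_z = rim0 + geom$gamma_f)
  if (!is.null(stone)) {
    sim_out <- stage("stone-scattering", {
      simulate_linear_field(config$transducer, config$medium, stone,
                            config$sim)
    })
    regs <- stage("regions", {
      nf <- normalize_field(sim_out,
                            focal_geometry(geom$gamma_f, geom$l1, geom$l2,
                                           pmax = max(sim_out$amplitude)))
      label_regions(threshold_mask(nf, config$pc_star), stone)
    })
    report$regions <- lapply(regs, function(rg)
      list(label = rg$label, n_pixels = rg$n_pixels,
           spanwise_diameter_mm = rg$spanwise_diameter * 1e3,
           attached = rg$attached_to_stone))
    pi1 <- Filter(function(rg) rg$label == "Pi1", regs)
    if (length(pi1)) {
      cm <- stage("cap-projection", cap_angle_of_region(pi1[[1]], stone))
      report$theta_p_deg <- cm$theta * 180 / pi
      report$A1_star <- cm$A_star
    }
    opt <- stage("optimum-distance", {
      refl_factor <- 2 * stone$impedance_ratio / (1 + stone$impedance_ratio)
      pc_pa <- config$pc_star * refl_factor * max(axial$p)
      optimal_distance(axial, geom, stone, pc_pa)
    })
    report$z_plus_mm <- opt$z_plus * 1e3
    report$z_plus_regime <- opt$regime
  }

  if (config$synthetic) {
    rec <- stage("synthetic-recovery", {
      sp <- scene_spec(density_mm3 = 30, n_frames = 4, seed = config$seed)
      bb <- synth_bubble_stack(sp)
      census <- bubble_census(bb$stack)
      dens <- number_density(census)
      csp <- scene_spec(shape = c(360, 120),
                        clouds = list(list(x0 = 0.45e-3, z0 = 0.6e-3,
                                           speed = 1.32, n_bubbles = 20,
                                           sigma = 60e-6, d = 50e-6)),
                        n_frames = 40, seed = config$seed + 1L)
      cs <- synth_cloud_stack(csp)
      tr <- track_clouds(cs$stack)
      uz <- rise_speed(tr[[which.max(vapply(tr, function(t)
        length(t$frames), 0L))]])
      ssp <- scene_spec(shape = c(220, 220),
                        stone = list(row = 60, col = 110, radius_px = 70),
                        seed = config$seed + 2L)
      ss <- synth_stone_scene(ssp)
      prof_b <- surface_intensity_profile(minip(ss$stack, ss$truth$phase1),
                                          ssp$stone, ss$arc_offset_px)
      prof_d <- surface_intensity_profile(minip(ss$stack, ss$truth$phase2),
                                          ssp$stone, ss$arc_offset_px)
      tb <- cap_angle_from_profile(prof_b, stone_radius = 10e-3,
                                   source_kind = "bubble-layer")
      td <- cap_angle_from_profile(prof_d, stone_radius = 10e-3,
                                   source_kind = "fragments")
      list(density_target_mm3 = sp$density_mm3,
           density_realized_mm3 = bb$truth$density_mm3,
           density_recovered_mm3 = dens,
           rise_speed_target_m_s = 1.32, rise_speed_recovered_m_s = uz,
           theta_b_target_deg = ss$truth$theta_b * 180 / pi,
           theta_b_recovered_deg = tb$theta * 180 / pi,
           theta_d_target_deg = ss$truth$theta_d * 180 / pi,
           theta_d_recovered_deg = td$theta * 180 / pi)
    })
    report$synthetic_recovery <- rec
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  report
}
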