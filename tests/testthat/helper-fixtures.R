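# Shared fixtures; slow objects are computed once per test run.
fixture_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

default_tx <- function(u0 = 1e-2)
  transducer_spec(250e3, 67e-3, 32e-3, u0 = u0)

fine_axial <- function() fx("fine_axial", {
  oneil_axial(default_tx(), water(), seq(5e-3, 120e-3, by = 0.05e-3))
})

gamma_f_default <- function() fx("gamma_f", physical_focus(fine_axial()))

# the focal-lobe Rayleigh field used for the focal-geometry constants
focal_field <- function() fx("focal_field", {
  rayleigh_field(default_tx(), water(),
                 r = seq(0, 12e-3, by = 0.2e-3),
                 z = seq(15e-3, 110e-3, by = 0.75e-3))
})

focal_geom <- function() fx("focal_geom", {
  focal_geometry_fit(focal_field(), default_tx(), water())
})

# solver-frame coordinate of the rim-plane origin
rim_origin <- function(sim = sim_config())
  sim$source_z + bowl_geometry(default_tx())$h

homog_sim <- function() fx("homog_sim", {
  simulate_linear_field(default_tx(), water(), NULL, sim_config())
})

hemi_stone <- function() fx("hemi_stone", {
  stone_spec("hemisphere", radius = 10e-3,
             apex_z = rim_origin() + gamma_f_default())
})

hemi_sim <- function() fx("hemi_sim", {
  simulate_linear_field(default_tx(), water(), hemi_stone(), sim_config())
})

# normalized field + labelled regions for the default hemisphere run
hemi_regions <- function() fx("hemi_regions", {
  out <- hemi_sim()
  geom <- focal_geom()
  nf <- normalize_field(out, focal_geometry(gamma_f_default(), geom$l1,
                                            geom$l2,
                                            pmax = max(out$amplitude)))
  label_regions(threshold_mask(nf, 0.46), hemi_stone())
})

# a clean stone-free cloud scene reused by tracking tests
cloud_scene <- function(seed = 3) {
  scene_spec(shape = c(360, 120),
             clouds = list(list(x0 = 0.45e-3, z0 = 0.6e-3, speed = 1.32,
                                n_bubbles = 20, sigma = 60e-6, d = 50e-6)),
             n_frames = 40, seed = seed)
}
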