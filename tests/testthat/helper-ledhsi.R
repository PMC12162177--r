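# Shared fixtures: everything is generated in code at test time.

flat_qe <- function(wavelength) rep(1, length(wavelength))

# Small noiseless-friendly camera for fast pipeline tests.
small_camera <- function(rows = 32, cols = 32, ...) {
  camera_model(rows = rows, cols = cols, bit_depth = 10, fps_max = 120,
               angular_fov = 70, dark_mean = 8, dark_sigma = 1,
               read_sigma = 2, ...)
}

# Camera whose forward model is exact: flat unit spectral response and no
# noise sources, so counts are integers whenever signals are.
exact_camera <- function(rows = 16, cols = 16, full_well_scale = 800) {
  camera_model(rows = rows, cols = cols, bit_depth = 16, fps_max = 120,
               angular_fov = 70, dark_mean = 10, dark_sigma = 0,
               read_sigma = 0, qe = flat_qe, full_well_scale = full_well_scale)
}

# Three-channel array reusing rows of the default LED table.
small_array <- function(viewing_angles = c(102, 86, 40),
                        relative_power = 1) {
  wl <- c(505, 660, 830)
  hw <- c(30, 18, 35)
  rp <- rep_len(relative_power, 3)
  led_array(lapply(1:3, function(i)
    led_channel(wl[i], hw[i], viewing_angles[i], position = c(0, 0),
                relative_power = rp[i])))
}

# One acquisition session (dark, white, tissue cube) in memory.
make_session <- function(rows = 32, cols = 32, n_tissues = 2, seed = 1L,
                         camera = small_camera(rows, cols),
                         array = led_array_default(),
                         geometry = geometry_config(70),
                         noise = FALSE) {
  phantom <- make_phantom(rows, cols, n_tissues = n_tissues, seed = seed)
  list(phantom = phantom, camera = camera, array = array, geometry = geometry,
       dark = acquire_dark(camera, noise = noise,
                           seed = if (noise) seed + 50L else NULL),
       white = acquire_white(array, camera, geometry, noise = noise,
                             seed = if (noise) seed + 60L else NULL),
       cube = acquire_hypercube(phantom, array, camera, geometry,
                                noise = noise,
                                seed = if (noise) seed + 70L else NULL))
}

# Signatures drawn around a base spectrum with iid per-band noise; used for
# the group-comparison tests.
random_signatures <- function(n, wavelengths, base, sd = 0.05, seed = 1L) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    spectral_signature(wavelengths,
                       base + rnorm(length(wavelengths), 0, sd))))
}

run_cli <- function(...) {
  script <- system.file("cli", "ledhsi.R", package = "ledhsi")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, ...), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(stdout = out, status = attr(out, "status") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
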