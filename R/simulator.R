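#' Synthetic scene phantom
#'
#' Builds a flat phantom scene: elliptical tissue regions with known smooth
#' reflectance spectra lying on a bright dish background (near-unity flat
#' reflectance, so the background appears hyperintense in every band), plus
#' small glare spots that saturate the sensor. The phantom is the ground truth
#' against which calibration, segmentation and signature extraction are
#' validated.
#'
#' @param rows,cols Scene size in pixels.
#' @param n_tissues Number of tissue regions (>= 1).
#' @param spectra Optional list of [reflectance_spectrum()], one per tissue;
#'   defaults to cycling through the built-in presets.
#' @param glare_spots Number of saturating glare spots (placed alternately on
#'   tissue and background).
#' @param glare_radius Glare spot radius, pixels.
#' @param background_reflectance Flat reflectance of the dish, default 0.95.
#' @param seed Seed controlling region placement; identical seeds give
#'   identical phantoms.
#' @return An object of class `scene_phantom` with elements `label_map`
#'   (integer matrix, 0 = background), `spectra` (list indexed by label),
#'   `background_reflectance`, `glare_mask` (logical matrix) and
#'   `ground_truth` (tissue x band reflectance at the default LED array's
#'   center wavelengths).
#' @export
make_phantom <- function(rows = 64, cols = 64, n_tissues = 2,
                         spectra = NULL, glare_spots = 2, glare_radius = 2,
                         background_reflectance = 0.95, seed = 1L) {
  if (n_tissues < 1) stop("n_tissues must be >= 1")
  stopifnot(rows >= 8, cols >= 8)
  if (is.null(spectra)) {
    presets <- tissue_preset_names()
    spectra <- lapply(seq_len(n_tissues), function(i)
      make_tissue_spectrum(presets[(i - 1L) %% length(presets) + 1L]))
  }
  stopifnot(length(spectra) == n_tissues)

  # lay tissues out on a near-square grid of cells, one ellipse per cell
  ncell <- ceiling(sqrt(n_tissues))
  cell_h <- rows / ncell
  cell_w <- cols / ceiling(n_tissues / ncell)
  if (min(cell_h, cell_w) * 0.35 < 2)
    stop("regions cannot fit: image too small for ", n_tissues, " tissues")

  label_map <- matrix(0L, rows, cols)
  rc <- row(label_map); cc <- col(label_map)
  centers <- withr::with_seed(seed, {
    lapply(seq_len(n_tissues), function(k) {
      i <- (k - 1L) %/% ncell; j <- (k - 1L) %% ncell
      c(r = (j + 0.5) * cell_h + rnorm(1, 0, cell_h * 0.03),
        c = (i + 0.5) * cell_w + rnorm(1, 0, cell_w * 0.03),
        a = cell_h * stats::runif(1, 0.28, 0.35),
        b = cell_w * stats::runif(1, 0.28, 0.35),
        th = stats::runif(1, 0, pi))
    })
  })
  for (k in seq_len(n_tissues)) {
    e <- centers[[k]]
    dr <- rc - e["r"]; dc <- cc - e["c"]
    u <- dr * cos(e["th"]) + dc * sin(e["th"])
    v <- -dr * sin(e["th"]) + dc * cos(e["th"])
    inside <- (u / e["a"])^2 + (v / e["b"])^2 <= 1
    label_map[inside] <- k
  }

  glare_mask <- matrix(FALSE, rows, cols)
  if (glare_spots > 0) {
    pos <- withr::with_seed(seed + 1L, {
      lapply(seq_len(glare_spots), function(g) {
        on_tissue <- g %% 2L == 1L
        cand <- which(if (on_tissue) label_map > 0 else label_map == 0)
        cand[1 + floor(stats::runif(1) * length(cand))]
      })
    })
    for (p in pos) {
      pr <- (p - 1L) %% rows + 1L; pc <- (p - 1L) %/% rows + 1L
      glare_mask[(rc - pr)^2 + (cc - pc)^2 <= glare_radius^2] <- TRUE
    }
  }

  wl <- LED_TABLE$wavelength
  gt <- t(vapply(spectra, eval_spectrum, numeric(length(wl)),
                 wavelengths = wl))
  dimnames(gt) <- list(paste0("tissue", seq_len(n_tissues)), wl)

  structure(list(label_map = label_map, spectra = spectra,
                 background_reflectance = background_reflectance,
                 glare_mask = glare_mask, ground_truth = gt,
                 seed = as.integer(seed)),
            class = "scene_phantom")
}

#' @export
print.scene_phantom <- function(x, ...) {
  cat(sprintf("<scene_phantom> %dx%d, %d tissue(s), %d glare pixel(s)\n",
              nrow(x$label_map), ncol(x$label_map),
              length(x$spectra), sum(x$glare_mask)))
  invisible(x)
}

# Effective band reflectance seen through one LED channel: the scene spectrum
# weighted by emission x sensor response over the wavelength grid. For spectra
# that vary within the LED line width this differs from the reflectance
# sampled at the center wavelength.
band_effective_reflectance <- function(spectrum_values, weights) {
  sum(weights * spectrum_values) / sum(weights)
}

# Per-band quantum-efficiency throughput: fraction of the emitted spectrum the
# sensor converts, relative to a perfect (qe = 1) sensor.
band_qe_gain <- function(channel, camera, grid = WAVELENGTH_GRID) {
  e <- emission_profile(channel, grid)
  sum(e * camera$qe(grid)) / sum(e)
}

#' Ground-truth band reflectance of a phantom
#'
#' Samples each tissue's spectrum per LED band, either at the channel center
#' wavelength (`effective = FALSE`) or as the emission-and-sensor-weighted
#' average over the channel's spectral line (`effective = TRUE`). The
#' effective value is what an ideal calibrated measurement converges to:
#' broad LED lines average the underlying spectrum over their width.
#'
#' @param phantom A [make_phantom()] scene.
#' @param array A [led_array()].
#' @param camera A [camera_model()] (used only for `effective = TRUE`).
#' @param effective Weight by emission x spectral response?
#' @return Matrix, tissues x bands.
#' @export
phantom_band_truth <- function(phantom, array = led_array_default(),
                               camera = camera_model(), effective = TRUE) {
  wl <- band_wavelengths(array)
  out <- matrix(NA_real_, length(phantom$spectra), length(wl),
                dimnames = list(paste0("tissue", seq_along(phantom$spectra)), wl))
  for (i in seq_along(phantom$spectra)) {
    if (effective) {
      rv <- eval_spectrum(phantom$spectra[[i]], WAVELENGTH_GRID)
      out[i, ] <- vapply(array$channels, function(ch) {
        w <- emission_profile(ch, WAVELENGTH_GRID) * camera$qe(WAVELENGTH_GRID)
        band_effective_reflectance(rv, w)
      }, numeric(1))
    } else {
      out[i, ] <- eval_spectrum(phantom$spectra[[i]], wl)
    }
  }
  out
}

round_half_up <- function(x) floor(x + 0.5)

# Fixed-pattern component of the dark offset, shared by all captures from the
# same camera object.
dark_pattern <- function(camera) {
  withr::with_seed(camera$fpn_seed,
    matrix(rnorm(camera$rows * camera$cols, 0, camera$dark_sigma),
           camera$rows, camera$cols))
}

quantize_counts <- function(x, camera) {
  fs <- full_scale(camera)
  x <- round_half_up(x)
  x[x < 0] <- 0
  x[x > fs] <- fs
  x
}

#' Capture a single-LED camera frame
#'
#' Forward model of one sequential-illumination frame. The per-pixel signal is
#' `full_well_scale * exposure * illumination(x, y) * g * R_eff(x, y)`, where
#' `g` is the channel's sensor-throughput (emission-weighted spectral
#' response) and `R_eff` the emission-and-response-weighted scene reflectance
#' for that band. Dark offset (with fixed-pattern variation when noise is on),
#' Poisson shot noise and Gaussian read noise are then added, and the frame is
#' quantized (round half up) and clipped to the bit depth. Glare pixels are
#' forced to full scale whenever the LED illuminates them.
#'
#' @param scene A [make_phantom()] scene, the string `"white"` (flat
#'   white-reference target) or `"dark"` (no light).
#' @param channel A [led_channel()]; ignored for `"dark"`.
#' @param camera A [camera_model()].
#' @param geometry A [geometry_config()].
#' @param exposure Exposure scale (> 0 for lit frames); 1 = nominal.
#' @param white_reflectance Reflectance of the white-reference target.
#' @param noise Add shot/read/fixed-pattern noise?
#' @param seed Seed for the noise draws (required when `noise = TRUE`).
#' @param stray_fraction Passed to [illumination_field()].
#' @return Integer-valued matrix of counts, rows x cols.
#' @export
capture_frame <- function(scene, channel = NULL, camera = camera_model(),
                          geometry = geometry_config(), exposure = 1,
                          white_reflectance = 0.99, noise = FALSE,
                          seed = NULL, stray_fraction = 0.02) {
  dark <- camera$dark_mean +
    if (noise) dark_pattern(camera) else 0
  is_dark <- identical(scene, "dark")
  if (!is_dark) {
    if (exposure <= 0) stop("exposure must be > 0 for lit frames")
    stopifnot(inherits(channel, "led_channel"))
    grid <- pixel_grid(camera, geometry)
    illum <- illumination_field(channel, geometry, grid, stray_fraction)
    g <- band_qe_gain(channel, camera)
    w <- emission_profile(channel, WAVELENGTH_GRID) * camera$qe(WAVELENGTH_GRID)
    if (identical(scene, "white")) {
      reff <- matrix(white_reflectance, camera$rows, camera$cols)
      glare <- NULL
    } else {
      stopifnot(inherits(scene, "scene_phantom"),
                nrow(scene$label_map) == camera$rows,
                ncol(scene$label_map) == camera$cols)
      per_label <- c(scene$background_reflectance,
                     vapply(scene$spectra, function(sp)
                       band_effective_reflectance(
                         eval_spectrum(sp, WAVELENGTH_GRID), w), numeric(1)))
      reff <- matrix(per_label[scene$label_map + 1L],
                     camera$rows, camera$cols)
      glare <- scene$glare_mask
    }
    signal <- camera$full_well_scale * exposure * illum * g * reff
  } else {
    signal <- matrix(0, camera$rows, camera$cols)
    glare <- NULL
  }

  if (noise) {
    if (is.null(seed)) stop("seed required when noise = TRUE")
    frame <- withr::with_seed(seed, {
      shot <- matrix(rpois(length(signal), lambda = as.vector(signal)),
                     camera$rows, camera$cols)
      shot + dark + matrix(rnorm(length(signal), 0, camera$read_sigma),
                           camera$rows, camera$cols)
    })
  } else {
    frame <- signal + dark
  }
  frame <- quantize_counts(frame, camera)
  if (!is.null(glare) && any(glare)) frame[glare] <- full_scale(camera)
  frame
}

new_raw_hypercube <- function(data, wavelengths, meta) {
  structure(list(data = data, band_wavelengths = wavelengths, meta = meta),
            class = "raw_hypercube")
}

#' @export
print.raw_hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raw_hypercube> %dx%dx%d, %g-%g nm, bit depth %d\n",
              d[1], d[2], d[3], min(x$band_wavelengths),
              max(x$band_wavelengths), x$meta$bit_depth))
  invisible(x)
}

#' Acquire a full hypercube by sequential LED scanning
#'
#' Fires the array's LEDs one at a time ([capture_frame()] per channel) and
#' stacks the frames into a raw hypercube in array (ascending wavelength)
#' order. Band start times follow the pulse-width/delay schedule: band k
#' starts at frame `(k - 1) * (pw + dt)`, and a whole cube spans
#' `n_channels * (pw + dt)` frame periods.
#'
#' @param scene A [make_phantom()] scene or `"white"`.
#' @param array A [led_array()].
#' @inheritParams capture_frame
#' @param timing A [timing_config()].
#' @param fps Frame rate used to timestamp the schedule; defaults to the
#'   camera's maximum.
#' @return A `raw_hypercube`: integer array rows x cols x bands plus
#'   `band_wavelengths` and acquisition metadata (exposure, timing,
#'   timestamps, seed, bit depth).
#' @export
acquire_hypercube <- function(scene, array = led_array_default(),
                              camera = camera_model(),
                              geometry = geometry_config(),
                              timing = timing_config(), exposure = 1,
                              white_reflectance = 0.99,
                              noise = FALSE, seed = NULL, fps = NULL,
                              stray_fraction = 0.02) {
  n <- length(array)
  cube <- array(0, dim = c(camera$rows, camera$cols, n))
  for (k in seq_len(n)) {
    cube[, , k] <- capture_frame(scene, array$channels[[k]], camera, geometry,
                                 exposure = exposure,
                                 white_reflectance = white_reflectance,
                                 noise = noise,
                                 seed = if (noise) seed + k else NULL,
                                 stray_fraction = stray_fraction)
  }
  fps <- if (is.null(fps)) camera$fps_max else fps
  period <- timing$pw_frames + timing$dt_frames
  ts <- (seq_len(n) - 1L) * period / fps
  meta <- list(exposure = exposure, pw_frames = timing$pw_frames,
               dt_frames = timing$dt_frames, fps = fps,
               band_start_s = ts, cube_period_s = n * period / fps,
               seed = if (noise) seed else NA_integer_,
               noise = noise, bit_depth = camera$bit_depth,
               kind = if (identical(scene, "white")) "white" else "tissue")
  new_raw_hypercube(cube, band_wavelengths(array), meta)
}

#' Simulate a flat shot-noise-limited field
#'
#' Captures a flat white target under perfectly diffuse illumination with a
#' noise-free-electronics camera (no dark offset, no read noise), so each
#' pixel is an independent Poisson draw with the requested mean. This
#' isolates the shot-noise limit of the forward model: the expected SNR is
#' `10 * log10(mean_counts)` dB.
#'
#' @param mean_counts Target mean counts per pixel.
#' @param rows,cols Field size, pixels.
#' @param seed Seed for the shot-noise draws.
#' @return Matrix of counts.
#' @export
simulate_flat_field <- function(mean_counts, rows = 100, cols = 100, seed = 1L) {
  stopifnot(mean_counts > 0)
  cam <- camera_model(rows = rows, cols = cols, bit_depth = 16,
                      dark_mean = 0, dark_sigma = 0, read_sigma = 0,
                      qe = function(w) rep(1, length(w)),
                      full_well_scale = mean_counts)
  capture_frame("white", led_channel(660, 18, 100), cam,
                geometry_config(100), white_reflectance = 1,
                noise = TRUE, seed = seed, stray_fraction = 1)
}

#' Acquire a dark-current frame
#'
#' A frame captured with every LED off; measures the additive sensor offset.
#'
#' @inheritParams acquire_hypercube
#' @return A `dark_frame` (matrix of counts with metadata attributes).
#' @export
acquire_dark <- function(camera = camera_model(), noise = FALSE, seed = NULL) {
  d <- capture_frame("dark", camera = camera, noise = noise, seed = seed)
  structure(list(data = d, meta = list(bit_depth = camera$bit_depth,
                                       noise = noise,
                                       seed = if (noise) seed else NA_integer_)),
            class = "dark_frame")
}

#' Acquire a white-reference stack
#'
#' Images a flat, near-unity diffuse reflector (Spectralon-like, reflectance
#' 0.99 by default) under every LED; the per-band result measures illumination
#' times sensor response and anchors the flat-field calibration.
#'
#' @inheritParams acquire_hypercube
#' @return A `white_stack` (same structure as a `raw_hypercube`).
#' @export
acquire_white <- function(array = led_array_default(), camera = camera_model(),
                          geometry = geometry_config(), exposure = 1,
                          white_reflectance = 0.99, noise = FALSE,
                          seed = NULL, stray_fraction = 0.02) {
  cube <- acquire_hypercube("white", array, camera, geometry,
                            exposure = exposure,
                            white_reflectance = white_reflectance,
                            noise = noise, seed = seed,
                            stray_fraction = stray_fraction)
  cube$meta$white_reflectance <- white_reflectance
  class(cube) <- c("white_stack", class(cube))
  cube
}
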