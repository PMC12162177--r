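#' Load an instrument description from a YAML config
#'
#' Builds the LED array, camera, timing, link and geometry objects from a
#' YAML file. The packaged default config
#' (`system.file("extdata", "default_instrument.yaml", package = "ledhsi")`)
#' reproduces the prototype instrument: the 18-channel LED array with its
#' data-sheet wavelengths, half widths and viewing angles, and the
#' 1280 x 720, 120 fps, 90-degree-FOV monochrome camera.
#'
#' @param path YAML file; `NULL` loads the packaged default.
#' @return List with `led_array`, `camera`, `timing`, `link`, `geometry` and
#'   the raw `config` list.
#' @export
load_instrument_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_instrument.yaml",
                        package = "ledhsi")
  cfg <- yaml::read_yaml(path)

  leds <- cfg$led_array$channels
  n <- length(leds)
  ring <- cfg$led_array$ring_radius_mm %||% 15
  ang <- 2 * pi * (seq_len(n) - 1) / n
  chans <- lapply(seq_len(n), function(i) {
    ch <- leds[[i]]
    led_channel(ch$wavelength, ch$half_width, ch$viewing_angle,
                position = if (!is.null(ch$position)) unlist(ch$position)
                           else ring * c(cos(ang[i]), sin(ang[i])),
                relative_power = ch$relative_power %||% 1)
  })
  cam <- cfg$camera
  camera <- camera_model(rows = cam$rows, cols = cam$cols,
                         bit_depth = cam$bit_depth, fps_max = cam$fps_max,
                         angular_fov = cam$angular_fov,
                         dark_mean = cam$dark_mean %||% 8,
                         dark_sigma = cam$dark_sigma %||% 1,
                         read_sigma = cam$read_sigma %||% 2,
                         full_well_scale = cam$full_well_scale %||% 900)
  list(led_array = led_array(chans),
       camera = camera,
       timing = timing_config(cfg$timing$pw_frames %||% 1,
                              cfg$timing$dt_frames %||% 1),
       link = link_config(cfg$link$rate_mbps %||% 400,
                          cfg$link$interpretation %||% "binary"),
       geometry = geometry_config(cfg$geometry$working_distance_mm %||% 70),
       config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete synthetic imaging session on disk
#'
#' Writes everything one acquisition session produces: a dark frame, a
#' white-reference stack, noiseless and noisy phantom cubes (two tissues plus
#' glare on a bright dish), the phantom's ground-truth spectra as CSV, and a
#' session manifest (JSON) listing files, seeds and band wavelengths. All
#' files are deterministic functions of the seed.
#'
#' @param output_dir Writable directory (created if missing).
#' @param seed Master seed; all noise seeds derive from it.
#' @param rows,cols Scene size, default 64 x 64.
#' @param format Cube format, `"envi"` or `"tiff"`.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
generate_fixtures <- function(output_dir, seed = 1L, rows = 64, cols = 64,
                              format = "envi") {
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE,
                                             showWarnings = FALSE)
  if (!ok || file.access(output_dir, 2) != 0)
    stop("output directory is not writable: ", output_dir)

  array <- led_array_default()
  camera <- camera_model(rows = rows, cols = cols)
  geometry <- geometry_config(70)
  phantom <- make_phantom(rows, cols, n_tissues = 2, seed = seed)

  dark <- acquire_dark(camera)
  white <- acquire_white(array, camera, geometry)
  cube0 <- acquire_hypercube(phantom, array, camera, geometry)
  cube1 <- acquire_hypercube(phantom, array, camera, geometry,
                             noise = TRUE, seed = seed + 100L)

  dark_cube <- new_raw_hypercube(array(dark$data, c(rows, cols, 1L)),
                                 0, list(bit_depth = camera$bit_depth))
  paths <- list(
    dark = file.path(output_dir, "dark"),
    white = file.path(output_dir, "white"),
    cube_noiseless = file.path(output_dir, "cube_noiseless"),
    cube_noisy = file.path(output_dir, "cube_noisy"))
  write_cube(dark_cube, paths$dark, format)
  write_cube(white, paths$white, format)
  write_cube(cube0, paths$cube_noiseless, format)
  write_cube(cube1, paths$cube_noisy, format)

  gt <- phantom_band_truth(phantom, array, camera, effective = TRUE)
  gt_df <- data.frame(wavelength = band_wavelengths(array), t(gt))
  gt_path <- file.path(output_dir, "ground_truth.csv")
  write.csv(gt_df, gt_path, row.names = FALSE)

  manifest <- list(
    files = lapply(paths, function(p) basename(p)),
    ground_truth = basename(gt_path),
    format = format,
    seed = seed,
    noise_seed = seed + 100L,
    rows = rows, cols = cols,
    n_bands = length(array),
    wavelengths = band_wavelengths(array),
    bit_depth = camera$bit_depth,
    white_reflectance = 0.99,
    background_reflectance = phantom$background_reflectance)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(output_dir, "manifest.json"))
  invisible(manifest)
}

#' Read and validate a session manifest
#'
#' Checks that every referenced file exists and that band counts agree.
#'
#' @param dir Session directory containing `manifest.json`.
#' @return The manifest list.
#' @export
read_manifest <- function(dir) {
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  ext <- if (mf$format == "envi") c(".hdr", ".img") else c(".tif", ".json")
  for (f in mf$files) for (e in ext) {
    p <- file.path(dir, paste0(f, e))
    if (!file.exists(p)) stop("manifest references a missing file: ", p)
  }
  if (length(mf$wavelengths) != mf$n_bands)
    stop("manifest wavelength count disagrees with n_bands")
  for (f in c("white", "cube_noiseless", "cube_noisy")) {
    cube <- read_cube(file.path(dir, mf$files[[f]]))
    if (dim(cube$data)[3] != mf$n_bands)
      stop("band count mismatch in ", f)
  }
  mf
}
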