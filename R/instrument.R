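# Wavelength grid used for all spectral integrals (nm, trapezoid rule).
WAVELENGTH_GRID <- seq(380, 1000, by = 1)

#' Single LED emitter channel
#'
#' Describes one narrowband LED of the illumination array: its emission peak,
#' spectral width (FWHM, called "half width" on LED data sheets), emission cone
#' (full viewing angle) and its physical position on the array plane relative
#' to the camera lens axis.
#'
#' @param center_wavelength Emission peak, nm. Must lie in \[350, 1100\].
#' @param half_width FWHM of the emission spectrum, nm (> 0).
#' @param viewing_angle Full emission cone angle, degrees, in (0, 180).
#' @param position Numeric length-2, (x, y) offset of the LED from the lens
#'   axis on the array plane, mm.
#' @param relative_power Peak irradiance scale relative to the brightest
#'   channel, in (0, 1].
#' @return An object of class `led_channel`.
#' @export
led_channel <- function(center_wavelength, half_width, viewing_angle,
                        position = c(0, 0), relative_power = 1) {
  stopifnot(is.numeric(center_wavelength), length(center_wavelength) == 1L)
  if (center_wavelength < 350 || center_wavelength > 1100)
    stop("center_wavelength must be in [350, 1100] nm")
  if (half_width <= 0) stop("half_width must be > 0")
  if (viewing_angle <= 0 || viewing_angle >= 180)
    stop("viewing_angle must be in (0, 180) degrees")
  if (relative_power <= 0) stop("relative_power must be > 0")
  structure(list(center_wavelength = center_wavelength,
                 half_width = half_width,
                 viewing_angle = viewing_angle,
                 position = as.numeric(position),
                 relative_power = relative_power),
            class = "led_channel")
}

#' LED array
#'
#' An ordered set of [led_channel()]s with strictly increasing center
#' wavelengths; one spectral band is acquired per channel.
#'
#' @param channels List of `led_channel` objects.
#' @return An object of class `led_array` with a `wavelengths` accessor via
#'   [band_wavelengths()].
#' @export
led_array <- function(channels) {
  stopifnot(length(channels) >= 1L,
            all(vapply(channels, inherits, logical(1), "led_channel")))
  wl <- vapply(channels, `[[`, numeric(1), "center_wavelength")
  if (any(diff(wl) <= 0))
    stop("channel center wavelengths must be strictly increasing")
  structure(list(channels = channels), class = "led_array")
}

# Data-sheet specifications of the 18 through-hole LEDs of the prototype
# illuminator: peak wavelength (nm), spectral half width / FWHM (nm) and full
# viewing angle (deg).
LED_TABLE <- data.frame(
  wavelength    = c(405, 420, 450, 470, 505, 525, 555, 590, 610,
                    630, 660, 700, 770, 800, 830, 850, 890, 910),
  half_width    = c(19, 16, 20, 25, 30, 30, 25, 13, 15,
                    15, 18, 21, 26, 29, 35, 40, 75, 47),
  viewing_angle = c(102, 26, 40, 80, 86, 18, 40, 64, 30,
                    60, 80, 80, 14, 88, 14, 26, 40, 30)
)

#' Default 18-channel LED array
#'
#' Reproduces the prototype's 18 through-hole LEDs spanning 405--910 nm with
#' their data-sheet half widths and viewing angles. LEDs are placed on a ring
#' around the lens axis (the array plane), one per wavelength.
#'
#' @param ring_radius_mm Radius of the ring on which the LEDs sit, mm.
#' @param relative_power Per-channel peak power scale; recycled to 18.
#' @return A `led_array` with 18 channels.
#' @export
led_array_default <- function(ring_radius_mm = 15, relative_power = 1) {
  n <- nrow(LED_TABLE)
  rp <- rep_len(relative_power, n)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  chans <- lapply(seq_len(n), function(i) {
    led_channel(LED_TABLE$wavelength[i], LED_TABLE$half_width[i],
                LED_TABLE$viewing_angle[i],
                position = ring_radius_mm * c(cos(ang[i]), sin(ang[i])),
                relative_power = rp[i])
  })
  led_array(chans)
}

#' Band center wavelengths of an LED array
#' @param array A `led_array`.
#' @return Numeric vector of center wavelengths, nm.
#' @export
band_wavelengths <- function(array) {
  vapply(array$channels, `[[`, numeric(1), "center_wavelength")
}

#' @export
print.led_array <- function(x, ...) {
  wl <- band_wavelengths(x)
  cat(sprintf("<led_array> %d channels, %g-%g nm\n", length(wl), min(wl), max(wl)))
  invisible(x)
}

#' @export
length.led_array <- function(x) length(x$channels)

# Default spectral response of an IR-filter-less monochrome CMOS sensor:
# broad, peaking in the green, with useful sensitivity kept into the NIR.
default_qe <- function(wavelength) {
  pmin(1, pmax(0, 0.75 * exp(-(wavelength - 560)^2 / (2 * 170^2)) + 0.10))
}

#' Monochrome camera model
#'
#' Sensor geometry, frame rate, digitization and noise parameters of the
#' monochrome camera used for single-LED frame capture.
#'
#' @param rows,cols Sensor size in pixels.
#' @param bit_depth ADC bit depth; one of 8, 10, 12, 16.
#' @param fps_max Maximum frame rate, frames/s.
#' @param angular_fov Full (diagonal) angular field of view, degrees.
#' @param dark_mean Mean dark offset, counts.
#' @param dark_sigma Standard deviation of the fixed-pattern spatial variation
#'   of the dark offset, counts.
#' @param read_sigma Gaussian read noise per frame, counts.
#' @param qe Spectral response function of wavelength (nm) returning values in
#'   \[0, 1\].
#' @param full_well_scale Signal level, in counts, produced by a reflectance-1
#'   target at unit exposure under peak illumination with a perfect (qe = 1)
#'   sensor.
#' @param fpn_seed Seed for the fixed-pattern dark variation, so that all
#'   captures with the same camera share one pattern.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(rows = 720, cols = 1280, bit_depth = 10,
                         fps_max = 120, angular_fov = 90,
                         dark_mean = 8, dark_sigma = 1, read_sigma = 2,
                         qe = default_qe, full_well_scale = 900,
                         fpn_seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, fps_max > 0, full_well_scale > 0,
            is.function(qe))
  if (!bit_depth %in% c(8L, 10L, 12L, 16L))
    stop("bit_depth must be one of 8, 10, 12, 16")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 bit_depth = as.integer(bit_depth), fps_max = fps_max,
                 angular_fov = angular_fov, dark_mean = dark_mean,
                 dark_sigma = dark_sigma, read_sigma = read_sigma,
                 qe = qe, full_well_scale = full_well_scale,
                 fpn_seed = as.integer(fpn_seed)),
            class = "camera_model")
}

full_scale <- function(camera) 2^camera$bit_depth - 1

#' Acquisition timing configuration
#'
#' The sequential illumination schedule: each channel is lit for a square pulse
#' of `pw_frames` camera frame periods (pulse width, PW), followed by
#' `dt_frames` dark frame periods (inter-channel delay, DT) before the next
#' channel fires.
#'
#' @param pw_frames Exposure frames per channel, integer >= 1.
#' @param dt_frames Delay frames between channels, integer >= 0.
#' @return An object of class `timing_config`.
#' @export
timing_config <- function(pw_frames = 1L, dt_frames = 1L) {
  if (pw_frames < 1) stop("pw_frames must be >= 1")
  if (dt_frames < 0) stop("dt_frames must be >= 0")
  structure(list(pw_frames = as.integer(pw_frames),
                 dt_frames = as.integer(dt_frames)),
            class = "timing_config")
}

#' Wireless data-link configuration
#'
#' @param rate_value Link rate in megabits per second.
#' @param interpretation `"binary"` (1 Mbit = 2^20 bits) or `"decimal"`
#'   (1 Mbit = 10^6 bits).
#' @return An object of class `link_config`.
#' @export
link_config <- function(rate_value = 400,
                        interpretation = c("binary", "decimal")) {
  if (rate_value <= 0) stop("rate_value must be > 0")
  interpretation <- match.arg(interpretation)
  structure(list(rate_value = rate_value, interpretation = interpretation),
            class = "link_config")
}

link_bits_per_second <- function(link) {
  link$rate_value * if (link$interpretation == "binary") 2^20 else 1e6
}

#' Imaging geometry configuration
#'
#' @param working_distance Distance from the lens/array plane to the (flat,
#'   axis-normal) target plane, mm.
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(working_distance = 70) {
  if (working_distance <= 0) stop("working_distance must be > 0")
  structure(list(working_distance = working_distance),
            class = "geometry_config")
}

#' LED spectral emission profile
#'
#' Gaussian emission line centered at the channel's peak wavelength with the
#' data-sheet FWHM ("half width"), normalized to peak 1.
#'
#' @param channel A [led_channel()].
#' @param wavelengths Strictly increasing grid of wavelengths, nm.
#' @return Numeric vector of spectral weights in \[0, 1\], peak value 1 at the
#'   center wavelength.
#' @export
emission_profile <- function(channel, wavelengths) {
  if (length(wavelengths) == 0L) stop("wavelength grid is empty")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  sigma <- channel$half_width / (2 * sqrt(2 * log(2)))
  exp(-(wavelengths - channel$center_wavelength)^2 / (2 * sigma^2))
}

#' Pixel-center coordinate grid on the target plane
#'
#' Maps sensor pixels to physical (x, y) positions (mm) on the target plane,
#' using pinhole geometry: the sensor's angular field of view opens onto a
#' rectangle at the working distance, split by the sensor aspect ratio. The
#' lens axis pierces the plane at (0, 0); x runs along columns, y along rows.
#'
#' @param camera A [camera_model()].
#' @param geometry A [geometry_config()].
#' @return List with matrices `x` and `y` (rows x cols, mm) and the extent.
#' @export
pixel_grid <- function(camera, geometry) {
  ext <- fov_extent(camera$angular_fov, geometry$working_distance,
                    aspect = c(camera$cols, camera$rows))
  xs <- (seq_len(camera$cols) - 0.5) / camera$cols * ext$width - ext$width / 2
  ys <- (seq_len(camera$rows) - 0.5) / camera$rows * ext$height - ext$height / 2
  list(x = matrix(xs, camera$rows, camera$cols, byrow = TRUE),
       y = matrix(ys, camera$rows, camera$cols),
       width = ext$width, height = ext$height)
}

#' Irradiance footprint of one LED on the target plane
#'
#' The emission cone of an LED at normal incidence paints a radially symmetric
#' Gaussian footprint on the target plane, centered at the LED's lateral
#' offset from the lens axis. The footprint's FWHM diameter is
#' `2 * d * tan(viewing_angle / 2)`: narrow viewing angles concentrate light
#' and cause strong falloff toward the image corners. A small uniform
#' stray-light floor (`stray_fraction` of the peak) models diffuse scatter
#' inside the imaging enclosure.
#'
#' @param channel A [led_channel()].
#' @param geometry A [geometry_config()].
#' @param grid A [pixel_grid()] (or any list with mm matrices `x`, `y`).
#' @param stray_fraction Uniform stray-light fraction of the peak, in \[0, 1).
#' @return Matrix of unitless irradiance, peak equal to `relative_power` at
#'   the footprint center.
#' @export
illumination_field <- function(channel, geometry, grid, stray_fraction = 0.02) {
  if (channel$viewing_angle >= 180) stop("viewing_angle must be < 180 degrees")
  d <- geometry$working_distance
  fwhm <- 2 * d * tan(channel$viewing_angle / 2 * pi / 180)
  r2 <- (grid$x - channel$position[1])^2 + (grid$y - channel$position[2])^2
  g <- exp(-4 * log(2) * r2 / fwhm^2)
  channel$relative_power * ((1 - stray_fraction) * g + stray_fraction)
}

#' Footprint FWHM diameter of an LED on the target plane
#' @inheritParams illumination_field
#' @return FWHM diameter in mm.
#' @export
footprint_fwhm <- function(channel, geometry) {
  if (channel$viewing_angle >= 180) stop("viewing_angle must be < 180 degrees")
  2 * geometry$working_distance * tan(channel$viewing_angle / 2 * pi / 180)
}

#' Hypercube acquisition rate
#'
#' One hypercube takes `n_channels * (pw_frames + dt_frames)` camera frame
#' periods, so the spectral imaging rate in hypercubes per second (hps) is
#' `fps / (n_channels * (pw + dt))`.
#'
#' @param fps Camera frame rate, frames/s (> 0).
#' @param n_channels Number of spectral channels (>= 1).
#' @param timing A [timing_config()].
#' @return Rate in hypercubes per second.
#' @export
hypercube_rate <- function(fps, n_channels, timing = timing_config()) {
  if (fps <= 0) stop("fps must be > 0")
  if (n_channels < 1) stop("n_channels must be >= 1")
  fps / (n_channels * (timing$pw_frames + timing$dt_frames))
}

#' Camera frame rate required for a target hypercube rate
#'
#' Inverse of [hypercube_rate()].
#'
#' @param n_channels Number of spectral channels (>= 1).
#' @param target_hps Desired hypercube rate, hps (> 0).
#' @param timing A [timing_config()].
#' @return Required camera frame rate, frames/s.
#' @export
required_fps <- function(n_channels, target_hps, timing = timing_config()) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (target_hps <= 0) stop("target_hps must be > 0")
  n_channels * (timing$pw_frames + timing$dt_frames) * target_hps
}

#' Hypercube throughput of a data link
#'
#' How many uncompressed hypercubes per second a link can carry:
#' link bits/s divided by `rows * cols * n_channels * bit_depth` bits per cube.
#'
#' @param link A [link_config()].
#' @param rows,cols Image size, pixels.
#' @param n_channels Number of spectral channels.
#' @param bit_depth Bits per pixel sample.
#' @return List with `hps` (raw rate) and `hps_floor` (whole cubes/s).
#' @export
transfer_rate <- function(link, rows, cols, n_channels, bit_depth) {
  stopifnot(rows >= 1, cols >= 1, n_channels >= 1, bit_depth >= 1)
  bits_per_cube <- as.numeric(rows) * cols * n_channels * bit_depth
  hps <- link_bits_per_second(link) / bits_per_cube
  list(hps = hps, hps_floor = floor(hps))
}

#' Physical pixel pitch on the target plane
#'
#' @param fov_extent_mm Field-of-view extent along one axis, mm.
#' @param n_pixels Pixel count along the same axis.
#' @return Pixel pitch in micrometers.
#' @export
pixel_pitch <- function(fov_extent_mm, n_pixels) {
  stopifnot(fov_extent_mm > 0, n_pixels > 0)
  fov_extent_mm / n_pixels * 1000
}

#' Field-of-view extent at a working distance
#'
#' Pinhole geometry: the diagonal extent of the field is
#' `2 * d * tan(angular_fov / 2)`; width and height follow from the sensor
#' aspect ratio.
#'
#' @param angular_fov Full diagonal angular field of view, degrees, in (0, 180).
#' @param working_distance Distance to the target plane, mm.
#' @param aspect Length-2 numeric `c(width, height)` aspect ratio, e.g.
#'   `c(16, 9)`; `c(1, 1)` for square.
#' @return List with `width`, `height`, `diagonal` in mm.
#' @export
fov_extent <- function(angular_fov, working_distance, aspect = c(1, 1)) {
  if (angular_fov <= 0 || angular_fov >= 180)
    stop("angular_fov must be in (0, 180) degrees")
  stopifnot(working_distance > 0, length(aspect) == 2L, all(aspect > 0))
  diag <- 2 * working_distance * tan(angular_fov / 2 * pi / 180)
  hyp <- sqrt(sum(aspect^2))
  list(width = diag * aspect[1] / hyp,
       height = diag * aspect[2] / hyp,
       diagonal = diag)
}
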