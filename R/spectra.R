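#' Smooth parametric reflectance spectrum
#'
#' A tissue-like reflectance spectrum modeled as a flat baseline plus a sum of
#' broad Gaussian bumps (positive or negative), clipped to \[0, 1\]. Bump
#' widths are constrained to >= 10 nm so that spectra stay smooth relative to
#' the LED emission lines.
#'
#' @param baseline Baseline reflectance in \[0, 1\].
#' @param bumps A data frame with columns `center` (nm), `width` (FWHM, nm,
#'   >= 10) and `amplitude` (signed), or `NULL` for a flat spectrum.
#' @param name Optional label.
#' @return An object of class `reflectance_spectrum`; evaluate it with
#'   [eval_spectrum()].
#' @export
reflectance_spectrum <- function(baseline, bumps = NULL, name = NULL) {
  if (baseline < 0 || baseline > 1)
    stop("baseline reflectance must be in [0, 1]")
  if (!is.null(bumps)) {
    stopifnot(is.data.frame(bumps),
              all(c("center", "width", "amplitude") %in% names(bumps)))
    if (any(bumps$width < 10))
      stop("bump widths must be >= 10 nm to keep spectra smooth")
  }
  structure(list(baseline = baseline, bumps = bumps, name = name),
            class = "reflectance_spectrum")
}

#' Evaluate a reflectance spectrum
#' @param spectrum A [reflectance_spectrum()].
#' @param wavelengths Wavelengths in nm.
#' @return Reflectance values in \[0, 1\].
#' @export
eval_spectrum <- function(spectrum, wavelengths) {
  r <- rep(spectrum$baseline, length(wavelengths))
  if (!is.null(spectrum$bumps)) {
    for (i in seq_len(nrow(spectrum$bumps))) {
      b <- spectrum$bumps[i, ]
      r <- r + b$amplitude *
        exp(-4 * log(2) * (wavelengths - b$center)^2 / b$width^2)
    }
  }
  pmin(1, pmax(0, r))
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %s baseline %.2f, %d bump(s)\n",
              if (is.null(x$name)) "" else paste0("'", x$name, "'"),
              x$baseline,
              if (is.null(x$bumps)) 0L else nrow(x$bumps)))
  invisible(x)
}

# Qualitative tissue presets. The kidney-like and tumor-like pair is designed
# with clear contrast at the 505 and 660 nm bands so planted group differences
# can be recovered by the per-band tests.
TISSUE_PRESETS <- list(
  "kidney-like" = list(baseline = 0.20, bumps = data.frame(
    center = c(630, 810), width = c(60, 90), amplitude = c(0.25, 0.15))),
  "tumor-like" = list(baseline = 0.20, bumps = data.frame(
    center = c(505, 660, 880), width = c(45, 40, 80),
    amplitude = c(0.28, -0.10, 0.10))),
  "liver-like" = list(baseline = 0.12, bumps = data.frame(
    center = 700, width = 80, amplitude = 0.30)),
  "heart-like" = list(baseline = 0.18, bumps = data.frame(
    center = c(560, 760), width = c(50, 100), amplitude = c(0.12, 0.22))),
  "muscle-like" = list(baseline = 0.25, bumps = data.frame(
    center = c(600, 850), width = c(70, 60), amplitude = c(0.18, 0.10)))
)

#' Construct a tissue-like reflectance spectrum
#'
#' Either returns a named preset (optionally with seeded random jitter of the
#' bump amplitudes, to emulate specimen-to-specimen variation) or builds a
#' spectrum from explicit baseline/bump parameters.
#'
#' @param preset One of `"kidney-like"`, `"tumor-like"`, `"liver-like"`,
#'   `"heart-like"`, `"muscle-like"`, or `NULL` to pass `baseline`/`bumps`
#'   directly.
#' @param baseline,bumps See [reflectance_spectrum()]; ignored when a preset
#'   is given.
#' @param jitter_sd Standard deviation of seeded Gaussian jitter applied to
#'   bump amplitudes (0 = none).
#' @param seed Seed for the jitter; required when `jitter_sd > 0`.
#' @return A [reflectance_spectrum()]. Deterministic for fixed arguments.
#' @export
make_tissue_spectrum <- function(preset = NULL, baseline = 0.3, bumps = NULL,
                                 jitter_sd = 0, seed = NULL) {
  if (!is.null(preset)) {
    if (!preset %in% names(TISSUE_PRESETS))
      stop("unknown preset: ", preset)
    p <- TISSUE_PRESETS[[preset]]
    baseline <- p$baseline
    bumps <- p$bumps
    name <- preset
  } else name <- NULL
  if (jitter_sd > 0 && !is.null(bumps)) {
    if (is.null(seed)) stop("seed required when jitter_sd > 0")
    bumps$amplitude <- withr::with_seed(seed,
      bumps$amplitude + rnorm(nrow(bumps), 0, jitter_sd))
  }
  reflectance_spectrum(baseline, bumps, name = name)
}

#' Names of the built-in tissue presets
#' @return Character vector.
#' @export
tissue_preset_names <- function() names(TISSUE_PRESETS)
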