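#' Flat-field calibration of a raw hypercube
#'
#' Converts raw counts to reflectance band by band using dark and
#' white-reference captures:
#' \deqn{\hat I(x, y, \lambda) = \frac{I(x, y, \lambda) - I_D(x, y)}
#'                                    {I_W(x, y, \lambda) - I_D(x, y)}}
#' This cancels both the spatial inhomogeneity of each LED's illumination and
#' the inter-channel differences in LED power and sensor response. Pixel-bands
#' whose white-minus-dark denominator falls at or below `eps` times full scale
#' carry essentially no illumination; they are marked invalid (masked, not
#' clamped or in-painted). Values above 1 (glare, specular highlights) are
#' preserved so that hyperintense-region segmentation can find them.
#'
#' @param raw A `raw_hypercube` from [acquire_hypercube()] or [read_cube()].
#' @param dark A `dark_frame`.
#' @param white A `white_stack` (or `raw_hypercube` of a white target).
#' @param eps Relative denominator floor, fraction of full scale (> 0).
#' @return An object of class `calibrated_cube`: `data` (double array,
#'   rows x cols x bands; `NA` where invalid), `validity_mask` (logical array
#'   of the same shape), `band_wavelengths`, and a per-band summary of values
#'   above 1.
#' @export
flat_field_calibrate <- function(raw, dark, white, eps = 1e-3) {
  if (eps <= 0) stop("eps must be > 0")
  d <- dim(raw$data)
  if (!identical(d, dim(white$data)))
    stop("raw and white stacks have different shapes")
  if (!identical(d[1:2], dim(dark$data)))
    stop("dark frame shape does not match the cube bands")
  if (!isTRUE(all.equal(raw$band_wavelengths, white$band_wavelengths)))
    stop("raw and white band wavelengths disagree")
  fs <- 2^raw$meta$bit_depth - 1

  denom <- sweep(white$data, 1:2, dark$data, `-`)
  valid <- denom > eps * fs
  numer <- sweep(raw$data, 1:2, dark$data, `-`)
  out <- numer / denom
  out[!valid] <- NA_real_

  for (k in seq_len(d[3])) {
    if (!any(valid[, , k]))
      warning(sprintf("band %d (%g nm): all pixels invalid after calibration",
                      k, raw$band_wavelengths[k]))
  }
  structure(list(data = out, validity_mask = valid,
                 band_wavelengths = raw$band_wavelengths,
                 meta = raw$meta, eps = eps),
            class = "calibrated_cube")
}

#' @export
print.calibrated_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<calibrated_cube> %dx%dx%d, %g-%g nm, %.1f%% invalid, %.1f%% > 1\n",
    d[1], d[2], d[3], min(x$band_wavelengths), max(x$band_wavelengths),
    100 * mean(!x$validity_mask), 100 * mean(x$data > 1, na.rm = TRUE)))
  invisible(x)
}

#' Per-band calibration summary
#'
#' Reports, for each band of a calibrated cube, the mean and standard
#' deviation of valid reflectance values, the percentage of invalid
#' pixel-bands and the percentage of hyperintense (> 1) values. Useful for
#' the before/after inspection of white-reference calibrations and for
#' spotting residual illumination artifacts.
#'
#' @param cal A [flat_field_calibrate()] result.
#' @return A data frame with one row per band: `band`, `wavelength`, `mean`,
#'   `sd`, `pct_invalid`, `pct_gt1`.
#' @export
calibration_report <- function(cal) {
  d <- dim(cal$data)
  rows <- lapply(seq_len(d[3]), function(k) {
    v <- cal$data[, , k]
    ok <- cal$validity_mask[, , k]
    data.frame(band = k, wavelength = cal$band_wavelengths[k],
               mean = mean(v[ok]), sd = sd(v[ok]),
               pct_invalid = 100 * mean(!ok),
               pct_gt1 = 100 * mean(v[ok] > 1))
  })
  do.call(rbind, rows)
}
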