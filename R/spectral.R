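#' Extract the spectral signature of an ROI
#'
#' Per-band mean and standard deviation of reflectance over the pixels of a
#' region of interest, using only valid pixel-bands. The per-band mean curve
#' S(lambda) is the tissue's spectral signature; averaging over the ROI
#' suppresses pixel-level imaging noise.
#'
#' @param cal A [flat_field_calibrate()] result.
#' @param roi An `roi_mask` (or logical matrix) matching the cube's spatial
#'   shape.
#' @return An object of class `spectral_signature`: data frame with columns
#'   `band`, `wavelength`, `mean`, `sd`, `n` (valid ROI pixels per band);
#'   `normalized` is absent until [normalize_signature()] is applied.
#' @export
extract_signature <- function(cal, roi) {
  d <- dim(cal$data)
  if (!identical(d[1:2], dim(roi)[1:2])) stop("ROI shape does not match cube")
  roi <- unclass(roi) & TRUE
  if (!any(roi)) stop("ROI is empty")
  rows <- lapply(seq_len(d[3]), function(k) {
    v <- cal$data[, , k]
    ok <- roi & cal$validity_mask[, , k]
    n <- sum(ok)
    data.frame(band = k, wavelength = cal$band_wavelengths[k],
               mean = if (n) mean(v[ok]) else NA_real_,
               sd = if (n > 1) sd(v[ok]) else if (n == 1) 0 else NA_real_,
               n = n)
  })
  new_spectral_signature(do.call(rbind, rows))
}

new_spectral_signature <- function(df) {
  structure(df, class = c("spectral_signature", "data.frame"))
}

#' Build a spectral signature from explicit per-band values
#'
#' Constructor for signatures that did not come from a cube ROI — e.g. one
#' specimen's summary curve in a group comparison.
#'
#' @param wavelengths Band center wavelengths, nm.
#' @param means Per-band mean reflectance.
#' @param sds Per-band standard deviations (default 0).
#' @param n Pixel count per band (default 1).
#' @return A `spectral_signature`.
#' @export
spectral_signature <- function(wavelengths, means, sds = 0, n = 1L) {
  stopifnot(length(wavelengths) == length(means))
  new_spectral_signature(data.frame(
    band = seq_along(wavelengths), wavelength = wavelengths,
    mean = means, sd = rep_len(sds, length(means)),
    n = rep_len(as.integer(n), length(means))))
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("<spectral_signature> %d bands, %g-%g nm%s\n",
              nrow(x), min(x$wavelength), max(x$wavelength),
              if ("normalized" %in% names(x)) ", normalized" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Min-max normalize a spectral signature
#'
#' Rescales the signature to \[0, 1\] across bands:
#' \deqn{\hat S(\lambda) = \frac{S(\lambda) - S_{min}}{S_{max} - S_{min}}}
#' where the minimum and maximum are taken over all wavelengths of the
#' original curve. Normalization removes overall brightness differences
#' between imaging systems and specimens so that curve shapes can be compared.
#'
#' @param sig A `spectral_signature` with >= 2 bands.
#' @return The signature with a `normalized` column; exactly one band is 0
#'   and one is 1 (up to ties).
#' @export
normalize_signature <- function(sig) {
  if (nrow(sig) < 2) stop("need at least 2 bands to normalize")
  s <- sig$mean
  smin <- min(s); smax <- max(s)
  if (smax == smin) stop("degenerate flat signature: Smax equals Smin")
  sig$normalized <- (s - smin) / (smax - smin)
  sig
}

#' Signal-to-noise ratio in dB
#'
#' The image-quality metric used for flat reference targets: the mean of the
#' ROI values divided by their standard deviation, in decibels,
#' `SNR_dB = 20 * log10(mu / sigma)`. For pure shot noise with mean N counts
#' this approaches `10 * log10(N)`.
#'
#' @param values Numeric vector (or matrix) of ROI values.
#' @return SNR in dB.
#' @export
snr_db <- function(values) {
  values <- as.numeric(values)
  mu <- mean(values); sigma <- sd(values)
  if (!is.finite(sigma) || sigma == 0) stop("infinite SNR: sigma is 0")
  if (mu <= 0) stop("SNR undefined: mean must be > 0")
  20 * log10(mu / sigma)
}

#' Per-band group comparison of spectral signatures
#'
#' Compares two groups of specimens band by band with two-sample Student
#' t-tests (pooled variance by default, Welch optional) on the signatures'
#' normalized values, flagging bands whose one-tailed p-value falls below
#' `alpha`. The sampling unit is one specimen's ROI-mean signature — not
#' individual pixels, which would pseudo-replicate. The tail direction must
#' be declared a priori; deriving it from the data inflates the type-I error
#' and is only available with an explicit warning.
#'
#' @param group_a,group_b Lists of `spectral_signature`s (>= 2 each) sharing
#'   the same bands.
#' @param direction `"greater"` (group A above group B in the tail),
#'   `"less"`, or `"auto"` (direction taken from the pooled mean difference;
#'   emits a warning).
#' @param alpha Per-band significance level, default 0.05.
#' @param correction Multiple-testing correction across bands: `"none"`
#'   (default), `"bonferroni"` or `"BH"`.
#' @param var_equal Pooled-variance Student test (`TRUE`, default) or Welch.
#' @param normalize Min-max normalize each signature before testing
#'   (default `TRUE`); set `FALSE` to compare raw reflectance.
#' @return An object of class `band_comparison`: data frame with per-band
#'   `wavelength`, `mean_a`, `mean_b`, `t`, `p` (one-tailed), `significant`.
#' @export
compare_groups <- function(group_a, group_b,
                           direction = c("greater", "less", "auto"),
                           alpha = 0.05,
                           correction = c("none", "bonferroni", "BH"),
                           var_equal = TRUE, normalize = TRUE) {
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 signatures")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")

  val <- function(sig) {
    if (normalize) {
      if (!"normalized" %in% names(sig)) sig <- normalize_signature(sig)
      sig$normalized
    } else sig$mean
  }
  wl <- group_a[[1]]$wavelength
  for (g in c(group_a, group_b))
    if (!isTRUE(all.equal(g$wavelength, wl)))
      stop("all signatures must share the same bands")
  A <- vapply(group_a, val, numeric(length(wl)))  # bands x specimens
  B <- vapply(group_b, val, numeric(length(wl)))

  if (direction == "auto") {
    warning("direction chosen from the data; one-tailed p-values are ",
            "anti-conservative (type-I error is inflated)")
    direction <- if (mean(rowMeans(A) - rowMeans(B)) >= 0) "greater" else "less"
  }

  res <- lapply(seq_along(wl), function(k) {
    tt <- t.test(A[k, ], B[k, ], alternative = direction,
                 var.equal = var_equal)
    data.frame(band = k, wavelength = wl[k],
               mean_a = mean(A[k, ]), mean_b = mean(B[k, ]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = switch(correction,
                                               none = "none",
                                               bonferroni = "bonferroni",
                                               BH = "BH"))
  out$significant <- out$p_adj < alpha
  structure(out, class = c("band_comparison", "data.frame"),
            direction = direction, alpha = alpha, correction = correction)
}

#' @export
print.band_comparison <- function(x, ...) {
  cat(sprintf("<band_comparison> %d bands, one-tailed '%s', alpha = %g, %d significant\n",
              nrow(x), attr(x, "direction"), attr(x, "alpha"),
              sum(x$significant)))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
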