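#' Segment hyperintense background and glare
#'
#' The imaging targets sit on a bright white dish, so the background — like
#' specular glare — is hyperintense in the calibrated cube. Both are removed
#' together by thresholding a per-pixel aggregate image (default: the maximum
#' reflectance across valid bands, since glare saturates in some bands only).
#' The threshold comes from histogram analysis (Otsu by default); pixels above
#' it, and pixels with no valid band, are excluded. An optional morphological
#' opening removes speckle. The retained pixels are the tissue ROI.
#'
#' @param cal A [flat_field_calibrate()] result.
#' @param method `"otsu"` (histogram threshold) or `"percentile"`.
#' @param cleanup_radius Radius (pixels) of the opening brush; 0 disables.
#' @param aggregate `"max"` (default) or `"mean"` across valid bands.
#' @param percentile Quantile used when `method = "percentile"`.
#' @param cap Ceiling applied to the aggregate before histogram analysis.
#'   Glare can reach tens of times full reflectance; beyond `cap` all values
#'   are equally hyperintense, and letting them stretch the histogram would
#'   push the threshold above the dish mode. Default 1.5.
#' @return An object of class `roi_mask`: logical matrix (TRUE = tissue ROI)
#'   with the threshold and method recorded as attributes.
#' @export
segment_hyperintense <- function(cal, method = c("otsu", "percentile"),
                                 cleanup_radius = 0, aggregate = c("max", "mean"),
                                 percentile = 0.5, cap = 1.5) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  d <- dim(cal$data)
  if (!any(cal$validity_mask)) stop("cube has no valid band")

  x <- cal$data
  if (aggregate == "max") {
    agg <- apply(x, 1:2, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  } else {
    agg <- apply(x, 1:2, function(v) mean(v, na.rm = TRUE))
  }
  agg <- pmin(agg, cap)
  finite <- is.finite(agg)
  rng <- range(agg[finite])
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    stop("no histogram separation: aggregate image is constant")

  if (method == "otsu") {
    scaled <- (agg - rng[1]) / diff(rng)
    scaled[!finite] <- 0
    thr_scaled <- EBImage::otsu(scaled, range = c(0, 1), levels = 256)
    thr <- rng[1] + thr_scaled * diff(rng)
  } else {
    thr <- quantile(agg[finite], percentile, names = FALSE)
  }

  mask <- finite & agg <= thr
  if (cleanup_radius > 0) {
    brush <- EBImage::makeBrush(2 * cleanup_radius + 1, shape = "disc")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  new_roi_mask(mask, threshold = thr, method = method, aggregate = aggregate)
}

new_roi_mask <- function(mask, ...) {
  structure(mask, class = c("roi_mask", "matrix", "array"),
            provenance = list(...))
}

#' @export
print.roi_mask <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("<roi_mask> %dx%d, %d pixels retained (%.1f%%)%s\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x),
              if (!is.null(p$threshold))
                sprintf(", threshold %.3f (%s)", p$threshold, p$method) else ""))
  invisible(x)
}

#' Rigid (similarity) image transform
#'
#' Translation, rotation and isotropic scaling about the image center — the
#' degrees of freedom needed to align hypercubes captured by two different
#' imaging systems.
#'
#' @param tx,ty Translation along rows (`tx`) and columns (`ty`), pixels.
#' @param theta Rotation, degrees (counter-clockwise in array coordinates).
#' @param s Isotropic scale factor (> 0).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, theta = 0, s = 1) {
  if (s <= 0) stop("scale s must be > 0")
  structure(list(tx = tx, ty = ty, theta = theta, s = s),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> tx=%g ty=%g theta=%g deg s=%g\n",
              x$tx, x$ty, x$theta, x$s))
  invisible(x)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  th <- -transform$theta
  s <- 1 / transform$s
  a <- th * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t_inv <- -s * (rot %*% c(transform$tx, transform$ty))
  rigid_transform(t_inv[1], t_inv[2], th, s)
}

# 3x2 affine matrix in EBImage's convention (points transform as
# cbind(x, y, 1) %*% m, pixel i centered at coordinate i - 0.5), rotating and
# scaling about the image center.
rigid_matrix <- function(transform, dims) {
  a <- transform$theta * pi / 180
  A <- transform$s * matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ctr <- dims / 2
  off <- ctr + c(transform$tx, transform$ty) - as.vector(A %*% ctr)
  rbind(t(A), off)
}

#' Apply a rigid transform to an image or mask
#'
#' Resamples about the image center: bilinear interpolation for intensity
#' images, nearest neighbor for masks (so they stay boolean). Pixels mapped
#' from outside the input extent are reported as invalid.
#'
#' @param x Numeric matrix, or an `roi_mask`.
#' @param transform A [rigid_transform()].
#' @param interpolation `"auto"` (bilinear for images, nearest for masks),
#'   `"bilinear"` or `"nearest"`.
#' @return List with `image` (transformed matrix; for masks a logical
#'   `roi_mask`) and `valid` (logical matrix, FALSE where out of bounds).
#' @export
apply_rigid <- function(x, transform,
                        interpolation = c("auto", "bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(x, "roi_mask") || is.logical(x)
  if (interpolation == "auto")
    interpolation <- if (is_mask) "nearest" else "bilinear"
  filt <- if (interpolation == "bilinear") "bilinear" else "none"

  m <- rigid_matrix(transform, dim(x))
  xin <- matrix(as.numeric(x), nrow(x), ncol(x))
  out <- EBImage::affine(xin, m, filter = filt, antialias = FALSE)
  valid <- EBImage::affine(matrix(1, nrow(x), ncol(x)), m, filter = "none",
                           antialias = FALSE) > 0.5
  out <- matrix(as.numeric(out), nrow(x), ncol(x))
  if (is_mask) {
    img <- new_roi_mask(out > 0.5, transform = unclass(transform),
                        source = attr(x, "provenance"))
    img[!valid] <- FALSE
  } else img <- out
  list(image = img, valid = valid)
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

#' Estimate a rigid transform by grid search
#'
#' Coarse grid search (optionally refined around the optimum) maximizing the
#' normalized cross-correlation (NCC) between the transformed moving image and
#' the fixed image over their common valid region. Ties are broken toward the
#' smallest transform, lexicographically on (|tx|, |ty|, |theta|, |s - 1|).
#' Intended as an automated convenience; alignment can equally be done with
#' manually chosen transforms.
#'
#' @param moving,fixed Numeric matrices of identical size.
#' @param tx_grid,ty_grid,theta_grid,s_grid Candidate values for each
#'   parameter.
#' @param refine Number of halving refinement passes around the coarse
#'   optimum (0 = coarse only).
#' @param ncc_floor Confidence floor; a warning is emitted if the best NCC
#'   falls below it.
#' @return The best [rigid_transform()], with attributes `ncc` (achieved
#'   correlation) and `confident` (NCC >= `ncc_floor`).
#' @export
estimate_rigid <- function(moving, fixed,
                           tx_grid = -4:4, ty_grid = -4:4,
                           theta_grid = seq(-10, 10, by = 5),
                           s_grid = c(0.9, 1, 1.1),
                           refine = 1, ncc_floor = 0.2) {
  stopifnot(identical(dim(moving), dim(fixed)))
  if (sd(moving) == 0 || sd(fixed) == 0)
    stop("cannot register flat (constant) images")

  score_one <- function(tr) {
    res <- apply_rigid(moving, tr, interpolation = "bilinear")
    ok <- res$valid
    if (sum(ok) < 16) return(NA_real_)
    ncc(res$image[ok], fixed[ok])
  }
  search <- function(txs, tys, ths, ss) {
    cand <- expand.grid(tx = txs, ty = tys, theta = ths, s = ss,
                        KEEP.OUT.ATTRS = FALSE)
    cand$score <- vapply(seq_len(nrow(cand)), function(i)
      score_one(rigid_transform(cand$tx[i], cand$ty[i],
                                cand$theta[i], cand$s[i])), numeric(1))
    cand <- cand[!is.na(cand$score), , drop = FALSE]
    if (nrow(cand) == 0) stop("no candidate transform kept enough overlap")
    best <- max(cand$score)
    tied <- cand[cand$score >= best - 1e-12, , drop = FALSE]
    tied <- tied[order(abs(tied$tx), abs(tied$ty), abs(tied$theta),
                       abs(tied$s - 1)), , drop = FALSE]
    tied[1, ]
  }

  b <- search(tx_grid, ty_grid, theta_grid, s_grid)
  step <- c(tx = step_of(tx_grid), ty = step_of(ty_grid),
            theta = step_of(theta_grid), s = step_of(s_grid))
  for (r in seq_len(refine)) {
    step <- step / 2
    b <- search(b$tx + step["tx"] * (-1:1), b$ty + step["ty"] * (-1:1),
                b$theta + step["theta"] * (-1:1), b$s + step["s"] * (-1:1))
  }
  out <- rigid_transform(b$tx, b$ty, b$theta, b$s)
  attr(out, "ncc") <- b$score
  attr(out, "confident") <- b$score >= ncc_floor
  if (b$score < ncc_floor)
    warning(sprintf("best NCC %.3f is below the confidence floor %.2f",
                    b$score, ncc_floor))
  out
}

step_of <- function(grid) if (length(grid) > 1) min(diff(sort(grid))) else 0

#' Intersection of two ROI masks
#'
#' The common region of interest of two (already aligned) systems: the logical
#' intersection of their segmentation masks.
#'
#' @param a,b `roi_mask` objects (or logical matrices) of identical shape.
#' @return An `roi_mask`; a warning is emitted when the overlap is empty.
#' @export
mask_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  out <- new_roi_mask(unclass(a) & unclass(b),
                      op = "overlap",
                      parents = list(attr(a, "provenance"),
                                     attr(b, "provenance")))
  if (!any(out)) warning("mask overlap is empty")
  out
}
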