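# Hypercube I/O.
#
# ENVI: classic header (.hdr) + flat binary (.img), BSQ interleave, little
# endian. Integer count cubes are stored as unsigned 16-bit (ENVI data type
# 12); calibrated reflectance cubes as 64-bit doubles (type 5), which
# round-trips bit-exactly. Validity masks travel as a companion
# <base>_mask.hdr/.img pair (8-bit, type 1).
#
# TIFF: one page per band in ascending wavelength order with a JSON sidecar
# (<base>.json) holding wavelengths, bit depth and metadata. Count cubes are
# stored as 16-bit pages (exact); reflectance cubes as 32-bit float pages
# with an affine offset/scale recorded in the sidecar, because TIFF float
# pages are clamped to [0, 1] by the reader.

envi_paths <- function(path) {
  base <- sub("\\.(hdr|img)$", "", path)
  list(hdr = paste0(base, ".hdr"), img = paste0(base, ".img"), base = base)
}

write_envi_raw <- function(data, path, wavelengths, data_type, extra = list()) {
  p <- envi_paths(path)
  d <- dim(data)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", data_type),
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = { ",
                  paste(format(wavelengths, trim = TRUE), collapse = ", "),
                  " }"))
  for (k in names(extra))
    hdr <- c(hdr, paste0(k, " = ", extra[[k]]))
  writeLines(hdr, p$hdr)

  con <- file(p$img, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    v <- as.vector(t(data[, , b]))  # line by line, sample fastest
    if (data_type == 12) {
      v <- as.integer(round(v))
      v[v > 32767] <- v[v > 32767] - 65536L  # two's complement for writeBin
      writeBin(v, con, size = 2, endian = "little")
    } else if (data_type == 5) {
      writeBin(as.numeric(v), con, size = 8, endian = "little")
    } else if (data_type == 1) {
      writeBin(as.raw(v), con)
    } else stop("unsupported ENVI data type: ", data_type)
  }
  invisible(p)
}

parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("not an ENVI header: ", hdr_path)
  # join { ... } blocks onto one line, then parse key = value
  txt <- gsub("\\{([^}]*)\\}", "\\{\\1\\}", txt)
  lines <- strsplit(txt, "\n")[[1]]
  vals <- list(); key <- NULL; buf <- ""
  for (ln in lines[-1]) {
    if (nzchar(buf)) { buf <- paste(buf, ln); }
    else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*", "", ln))
      buf <- trimws(sub("^[^=]*=", "", ln))
    } else next
    if (grepl("\\{", buf) && !grepl("\\}", buf)) next
    vals[[key]] <- trimws(gsub("[{}]", "", buf))
    buf <- ""
  }
  vals
}

read_envi_raw <- function(path) {
  p <- envi_paths(path)
  h <- parse_envi_header(p$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  if (!all(need %in% names(h)))
    stop("ENVI header missing fields: ",
         paste(setdiff(need, names(h)), collapse = ", "))
  if (tolower(h[["interleave"]]) != "bsq")
    stop("unknown interleave (only bsq is supported): ", h[["interleave"]])
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]]); dt <- as.integer(h[["data type"]])
  npix <- as.numeric(ns) * nl * nb
  size <- c(`1` = 1, `5` = 8, `12` = 2)[as.character(dt)]
  if (is.na(size)) stop("unsupported ENVI data type: ", dt)
  actual <- file.size(p$img)
  if (is.na(actual) || actual < npix * size)
    stop("truncated or missing ENVI data file: ", p$img)

  con <- file(p$img, "rb")
  on.exit(close(con))
  v <- if (dt == 12) {
    as.numeric(readBin(con, integer(), n = npix, size = 2, signed = FALSE,
                       endian = "little"))
  } else if (dt == 5) {
    readBin(con, numeric(), n = npix, size = 8, endian = "little")
  } else {
    as.numeric(readBin(con, raw(), n = npix))
  }
  data <- array(NA_real_, c(nl, ns, nb))
  for (b in seq_len(nb)) {
    off <- (b - 1L) * ns * nl
    data[, , b] <- matrix(v[off + seq_len(ns * nl)], nl, ns, byrow = TRUE)
  }
  wl <- if ("wavelength" %in% names(h))
    as.numeric(strsplit(h[["wavelength"]], ",")[[1]]) else NULL
  list(data = data, wavelengths = wl, header = h)
}

#' Write a hypercube to disk
#'
#' @param cube A `raw_hypercube`, `white_stack` or `calibrated_cube`.
#' @param path Output path; the extension is replaced per format (`.hdr` +
#'   `.img` for ENVI, `.tif` + `.json` sidecar for TIFF).
#' @param format `"envi"` (BSQ) or `"tiff"` (multi-page, ascending
#'   wavelength).
#' @return Invisibly, the paths written.
#' @export
write_cube <- function(cube, path, format = c("envi", "tiff")) {
  format <- match.arg(format)
  is_cal <- inherits(cube, "calibrated_cube")
  wl <- cube$band_wavelengths
  if (format == "envi") {
    if (is_cal) {
      data <- cube$data
      data[!cube$validity_mask] <- 0  # masked values carried by the mask file
      p <- write_envi_raw(data, path, wl, data_type = 5,
                          extra = list(`bit depth` = cube$meta$bit_depth,
                                       `ledhsi kind` = "reflectance"))
      write_envi_raw(array(as.numeric(cube$validity_mask), dim(cube$data)),
                     paste0(p$base, "_mask"), wl, data_type = 1,
                     extra = list(`ledhsi kind` = "mask"))
      invisible(c(p$hdr, p$img))
    } else {
      p <- write_envi_raw(cube$data, path, wl, data_type = 12,
                          extra = list(`bit depth` = cube$meta$bit_depth,
                                       `ledhsi kind` = "counts"))
      invisible(c(p$hdr, p$img))
    }
  } else {
    base <- sub("\\.(tif|tiff|json)$", "", path)
    tif <- paste0(base, ".tif"); side <- paste0(base, ".json")
    d <- dim(cube$data)
    meta <- list(wavelengths = wl, bit_depth = cube$meta$bit_depth,
                 kind = if (is_cal) "reflectance" else "counts",
                 rows = d[1], cols = d[2], bands = d[3])
    if (is_cal) {
      data <- cube$data
      data[!cube$validity_mask] <- 0
      off <- min(0, min(data)); sc <- max(max(data) - off, 1e-12)
      meta$offset <- off; meta$scale <- sc
      pages <- lapply(seq_len(d[3]), function(b) (data[, , b] - off) / sc)
      tiff::writeTIFF(pages, tif, bits.per.sample = 32)
      mask_pages <- lapply(seq_len(d[3]), function(b)
        cube$validity_mask[, , b] * 1)
      tiff::writeTIFF(mask_pages, paste0(base, "_mask.tif"),
                      bits.per.sample = 8)
    } else {
      pages <- lapply(seq_len(d[3]), function(b) cube$data[, , b] / 65535)
      tiff::writeTIFF(pages, tif, bits.per.sample = 16)
    }
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), side)
    invisible(c(tif, side))
  }
}

#' Read a hypercube from disk
#'
#' Counterpart of [write_cube()]; the format is inferred from the files
#' present at `path`.
#'
#' @param path Path used at write time (any of the written files, or the
#'   common base path).
#' @return A `raw_hypercube` (counts) or `calibrated_cube` (reflectance),
#'   matching what was written.
#' @export
read_cube <- function(path) {
  base <- sub("\\.(hdr|img|tif|tiff|json)$", "", path)
  if (file.exists(paste0(base, ".hdr"))) {
    r <- read_envi_raw(base)
    kind <- r$header[["ledhsi kind"]]
    bit_depth <- if ("bit depth" %in% names(r$header))
      as.integer(r$header[["bit depth"]]) else NA_integer_
    if (identical(kind, "reflectance")) {
      m <- read_envi_raw(paste0(base, "_mask"))
      valid <- m$data > 0.5
      data <- r$data
      data[!valid] <- NA_real_
      structure(list(data = data, validity_mask = valid,
                     band_wavelengths = r$wavelengths,
                     meta = list(bit_depth = bit_depth), eps = NA_real_),
                class = "calibrated_cube")
    } else {
      new_raw_hypercube(r$data, r$wavelengths, list(bit_depth = bit_depth))
    }
  } else if (file.exists(paste0(base, ".tif"))) {
    side <- paste0(base, ".json")
    if (!file.exists(side)) stop("TIFF band sidecar not found: ", side)
    meta <- jsonlite::fromJSON(side)
    pages <- tiff::readTIFF(paste0(base, ".tif"), all = TRUE)
    if (length(pages) != meta$bands)
      stop("band count mismatch between TIFF and sidecar")
    data <- array(NA_real_, c(meta$rows, meta$cols, meta$bands))
    if (identical(meta$kind, "reflectance")) {
      mp <- tiff::readTIFF(paste0(base, "_mask.tif"), all = TRUE)
      valid <- array(FALSE, dim(data))
      for (b in seq_len(meta$bands)) {
        data[, , b] <- pages[[b]] * meta$scale + meta$offset
        valid[, , b] <- mp[[b]] > 0.5
      }
      data[!valid] <- NA_real_
      structure(list(data = data, validity_mask = valid,
                     band_wavelengths = meta$wavelengths,
                     meta = list(bit_depth = meta$bit_depth), eps = NA_real_),
                class = "calibrated_cube")
    } else {
      for (b in seq_len(meta$bands))
        data[, , b] <- round(pages[[b]] * 65535)
      new_raw_hypercube(data, meta$wavelengths,
                        list(bit_depth = meta$bit_depth))
    }
  } else stop("no cube found at: ", path)
}

#' Write / read an ROI mask as PNG
#'
#' @param mask An `roi_mask` or logical matrix.
#' @param path PNG path.
#' @return `write_mask_png` returns the path invisibly; `read_mask_png`
#'   returns an `roi_mask`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(unclass(mask) * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  new_roi_mask(m > 0.5, source = path)
}

#' Write / read a rigid transform as JSON
#'
#' The center convention is recorded: rotation and scaling act about the
#' image center, pixel i being centered at coordinate i - 0.5.
#'
#' @param transform A [rigid_transform()].
#' @param path JSON path.
#' @export
write_transform_json <- function(transform, path) {
  writeLines(jsonlite::toJSON(c(unclass(transform),
                                list(center = "image center, pixel i at i - 0.5")),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  rigid_transform(j$tx, j$ty, j$theta, j$s)
}

#' Write / read spectral signatures as CSV
#'
#' @param sig A `spectral_signature` (or `band_comparison`).
#' @param path CSV path.
#' @export
write_signature_csv <- function(sig, path) {
  write.csv(as.data.frame(sig), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_csv
#' @export
read_signature_csv <- function(path) {
  new_spectral_signature(read.csv(path))
}
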