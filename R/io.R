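# Containers and raster I/O for hyperspectral cubes and label maps.
#
# Canonical in-memory layout is H x W x B (band-last), row-major origin
# top-left with (row, col) indexing; ENVI interleave conversion happens only
# at the file boundary.

#' Hyperspectral reflectance cube
#'
#' Bundles an `H x W x B` reflectance array with its per-band wavelengths
#' (nm, strictly increasing) and an optional no-data mask. Reflectance is
#' dimensionless, typically in `[0, 1]`.
#'
#' @param data numeric `H x W x B` array.
#' @param wavelengths numeric vector of length `B`, strictly increasing.
#'   May be `NULL` for band data with no spectral calibration; operations
#'   that need wavelengths then fail explicitly.
#' @param nodata_mask optional `H x W` logical matrix marking invalid pixels.
#' @return An object of class `spectral_cube`.
#' @examples
#' cube <- spectral_cube(array(runif(4 * 4 * 8), c(4, 4, 8)),
#'                       wavelengths = seq(400, 1000, length.out = 8))
#' dim(cube$data)
#' @export
spectral_cube <- function(data, wavelengths = NULL, nodata_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3-d H x W x B array, got dimensions [%s]",
          paste(dim(data), collapse = ", "))
  b <- dim(data)[3]
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != b)
      stopf("band axis mismatch: %d bands in `data` but %d wavelengths",
            b, length(wavelengths))
    if (any(diff(wavelengths) <= 0))
      stopf("wavelengths must be strictly increasing")
  }
  if (!is.null(nodata_mask)) {
    if (!identical(dim(nodata_mask), dim(data)[1:2]))
      stopf("nodata_mask must be H x W")
    valid3 <- array(rep(!nodata_mask, b), dim = dim(data))
    if (any(!is.finite(data[valid3])))
      stopf("non-finite reflectance outside the nodata mask")
  } else if (any(!is.finite(data))) {
    stopf("`data` contains non-finite values and no nodata_mask was given")
  }
  structure(list(data = data, wavelengths = wavelengths,
                 nodata_mask = nodata_mask),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  wl <- if (is.null(x$wavelengths)) "no wavelength metadata"
        else sprintf("%g-%g nm", min(x$wavelengths), max(x$wavelengths))
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%s)\n",
              d[1], d[2], d[3], wl))
  invisible(x)
}

#' Class scheme with a two-level hierarchy
#'
#' Maps dense integer class ids (1..C) to secondary-category names and to
#' first-level group names (e.g. Forest, Waters), mirroring the two-level
#' land-cover classification systems used for hyperspectral ground truth.
#'
#' @param classes character vector of class names; ids are their positions.
#' @param groups character vector of first-level group names, one per class.
#'   Defaults to one singleton group per class.
#' @return An object of class `class_scheme`.
#' @examples
#' class_scheme(c("willow", "rice", "water"),
#'              groups = c("Forest", "Low Vegetation", "Waters"))
#' @export
class_scheme <- function(classes, groups = classes) {
  if (length(classes) < 1) stopf("need at least one class")
  if (length(groups) != length(classes))
    stopf("`groups` must name a first-level group for every class")
  structure(list(classes = as.character(classes),
                 groups = as.character(groups)),
            class = "class_scheme")
}

n_classes <- function(scheme) length(scheme$classes)

#' Per-pixel label map
#'
#' An `H x W` integer raster of class ids with 0 reserved for unlabeled
#' pixels, plus the [class_scheme()] giving names and first-level groups.
#'
#' @param labels integer `H x W` matrix; non-negative; 0 = unlabeled.
#' @param scheme a [class_scheme()] covering every nonzero id present.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, scheme) {
  if (!is.matrix(labels)) stopf("`labels` must be an H x W matrix")
  if (any(labels != round(labels)) || any(labels < 0))
    stopf("labels must be non-negative integers (0 = unlabeled)")
  if (!inherits(scheme, "class_scheme")) stopf("`scheme` must be a class_scheme")
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(present) && max(present) > n_classes(scheme))
    stopf("label id %d not covered by the class scheme (%d classes)",
          max(present), n_classes(scheme))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, scheme = scheme), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d classes (%s)\n",
              nrow(x$labels), ncol(x$labels), n_classes(x$scheme),
              paste(head(x$scheme$classes, 5), collapse = ", ")))
  invisible(x)
}

## ---- ENVI header + binary ---------------------------------------------

envi_dtype <- c("4" = "float32", "5" = "float64")

write_envi_header <- function(path, H, W, B, interleave, wavelengths) {
  lines <- c(
    "ENVI",
    sprintf("samples = %d", W),
    sprintf("lines = %d", H),
    sprintf("bands = %d", B),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0")
  if (!is.null(wavelengths))
    lines <- c(lines, "wavelength units = Nanometers",
               sprintf("wavelength = { %s }",
                       paste(format(wavelengths, trim = TRUE), collapse = ", ")))
  writeLines(lines, paste0(path, ".hdr"))
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*([^\\n{]+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL
    else as.numeric(strsplit(gsub("\\s", "", m[2]), ",")[[1]])
  }
  list(samples = as.integer(get_scalar("samples")),
       lines = as.integer(get_scalar("lines")),
       bands = as.integer(get_scalar("bands")),
       dtype = get_scalar("data type"),
       interleave = tolower(get_scalar("interleave")),
       wavelengths = get_block("wavelength"))
}

# ENVI element order by interleave, expressed as aperm permutations of the
# canonical H x W x B array (writing direction).
envi_perm <- list(bsq = c(2, 1, 3), bil = c(2, 3, 1), bip = c(3, 2, 1))

#' Read a hyperspectral cube
#'
#' Supported formats: `"envi"` (header + flat binary, BSQ/BIL/BIP interleaves,
#' wavelengths from the header `wavelength` block) and `"rds"` (native
#' container with keys `data`, `wavelengths` and optionally `labels`). Band
#' order is preserved; no axis is reordered beyond interleave conversion.
#'
#' @param path file path. For ENVI, the binary file; a sibling `.hdr` must
#'   exist.
#' @param format `"envi"` or `"rds"`; default guesses from the extension.
#' @return A [spectral_cube()]. A missing wavelength block loads with a
#'   warning; wavelength-dependent operations then fail explicitly.
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, format = c("auto", "envi", "rds")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "envi"
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "rds") {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$data)) stopf("container lacks a `data` array")
    return(spectral_cube(obj$data, obj$wavelengths))
  }
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stopf("ENVI header not found: %s", hdr_path)
  h <- parse_envi_header(hdr_path)
  if (!h$interleave %in% names(envi_perm))
    stopf("unsupported interleave '%s'", h$interleave)
  if (!h$dtype %in% names(envi_dtype))
    stopf("unsupported ENVI data type %s (float32/float64 only)", h$dtype)
  n <- h$lines * h$samples * h$bands
  raw <- readBin(path, "double", n = n,
                 size = if (h$dtype == "4") 4L else 8L, endian = "little")
  if (length(raw) != n)
    stopf("binary length mismatch on the pixel axis: expected %d values, read %d",
          n, length(raw))
  perm <- envi_perm[[h$interleave]]
  arr <- aperm(array(raw, dim = c(h$lines, h$samples, h$bands)[perm]),
               order(perm))
  if (is.null(h$wavelengths)) {
    warnf("ENVI header has no wavelength block; cube loads without spectral calibration")
  } else if (length(h$wavelengths) != h$bands) {
    stopf("band axis mismatch: %d bands but %d wavelengths in header",
          h$bands, length(h$wavelengths))
  }
  spectral_cube(arr, h$wavelengths)
}

#' Write a hyperspectral cube
#'
#' Inverse of [read_cube()]: exact round-trip for double data.
#'
#' @param cube a [spectral_cube()].
#' @param path output path (ENVI binary, with `.hdr` written alongside, or
#'   `.rds` container).
#' @param format `"envi"` or `"rds"`.
#' @param interleave ENVI interleave: `"bsq"`, `"bil"` or `"bip"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "envi", "rds"),
                       interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(cube, "spectral_cube"))
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "envi"
  if (format == "rds") {
    saveRDS(list(data = cube$data, wavelengths = cube$wavelengths), path)
    return(invisible(path))
  }
  d <- dim(cube$data)
  write_envi_header(path, d[1], d[2], d[3], interleave, cube$wavelengths)
  writeBin(as.vector(aperm(cube$data, envi_perm[[interleave]])), path,
           size = 8L, endian = "little")
  invisible(path)
}

#' Read / write label rasters
#'
#' Labels travel as single-band integer rasters: 8-bit PNG (ids up to 255) or
#' the native `.rds` container; values are preserved exactly and 0 stays
#' "unlabeled". A floating-point raster is rejected: labels must be integral.
#'
#' @param path file path (`.png` or `.rds`).
#' @param scheme a [class_scheme()] covering the ids in the file.
#' @return A [label_map()].
#' @export
read_labels <- function(path, scheme) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    lab <- readRDS(path)
    if (is.list(lab)) lab <- lab$labels
    if (any(lab != round(lab)))
      stopf("label raster is floating point; labels must be integral")
    return(label_map(round(lab), scheme))
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  vals <- img * 255
  if (any(abs(vals - round(vals)) > 1e-6))
    stopf("label raster is floating point; labels must be integral")
  label_map(matrix(as.integer(round(vals)), nrow(img), ncol(img)), scheme)
}

#' @rdname read_labels
#' @param labels a [label_map()] (or bare integer matrix) to write.
#' @export
write_labels <- function(labels, path) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  if (any(lab != round(lab)) || any(lab < 0))
    stopf("labels must be non-negative integers")
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(list(labels = lab), path)
    return(invisible(path))
  }
  if (max(lab) > 255) stopf("PNG label export supports ids up to 255, got %d", max(lab))
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' Locate the band nearest a target wavelength
#'
#' Used to pick the near-infrared and red bands for NDVI. Ties break toward
#' the lower band index.
#'
#' @param cube a [spectral_cube()] with wavelength metadata.
#' @param target_nm target wavelength in nm.
#' @param tolerance_nm maximum allowed distance to the nearest band (default
#'   50 nm); beyond it the match is refused rather than silently wrong.
#' @return 1-based band index.
#' @examples
#' cube <- spectral_cube(array(0.5, c(2, 2, 3)), wavelengths = c(400, 600, 800))
#' select_band_by_wavelength(cube, 670)  # 2
#' @export
select_band_by_wavelength <- function(cube, target_nm, tolerance_nm = 50) {
  if (is.null(cube$wavelengths))
    stopf("cube has no wavelength metadata; supply band indices explicitly")
  d <- abs(cube$wavelengths - target_nm)
  i <- which.min(d)  # which.min already breaks ties toward the lower index
  if (d[i] > tolerance_nm)
    stopf("no band within %g nm of %g nm (nearest: %g nm)",
          tolerance_nm, target_nm, cube$wavelengths[i])
  i
}
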