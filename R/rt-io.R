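# Fraction bundles and radiotherapy I/O.
#
# A fraction bundle is the unit the evaluation pipeline moves around: one
# (patient, fraction, observer) worth of structures plus (optionally) the
# dose the observer's adapted plan delivers, all on one shared grid.  The
# portable on-disk form is a small versioned archive (JSON metadata +
# gzip-compressed mask/dose blocks); DICOM RTSTRUCT/RTDOSE are adapters on
# top so real exports can replace phantom data without code changes.

#' Construct a fraction bundle
#'
#' @param grid shared [voxel_grid] for all structures and dose.
#' @param structures named list of [structure_mask] objects (unique names,
#'   grids all compatible with `grid`).
#' @param dose optional [dose_grid] on `grid`.
#' @param patient_id,fraction_id,observer_id identifier strings.
#' @param prescription optional [prescription_spec].
#' @return an object of class `fraction_bundle`.
#' @export
fraction_bundle <- function(grid, structures = list(), dose = NULL,
                            patient_id = "P0", fraction_id = "F0",
                            observer_id = "OBS", prescription = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(structures) > 0) {
    nm <- vapply(structures, function(s) s$name, character(1))
    if (anyDuplicated(nm)) stop("structure names must be unique within a bundle")
    names(structures) <- nm
    for (s in structures) stop_if_incompatible(grid, s$grid)
  }
  if (!is.null(dose)) {
    stopifnot(inherits(dose, "dose_grid"))
    stop_if_incompatible(grid, dose$grid)
  }
  if (!is.null(prescription)) stopifnot(inherits(prescription, "prescription_spec"))
  structure(list(patient_id = as.character(patient_id),
                 fraction_id = as.character(fraction_id),
                 observer_id = as.character(observer_id),
                 grid = grid, structures = structures, dose = dose,
                 prescription = prescription),
            class = "fraction_bundle")
}

#' @export
print.fraction_bundle <- function(x, ...) {
  cat(sprintf("fraction_bundle %s/%s/%s: %d structure(s) [%s]%s\n",
              x$patient_id, x$fraction_id, x$observer_id,
              length(x$structures),
              paste(names(x$structures), collapse = ", "),
              if (is.null(x$dose)) ", no dose" else ", with dose"))
  invisible(x)
}

#' Fetch a structure from a bundle by name
#'
#' Matching is case-insensitive and honours an alias map (canonical name ->
#' accepted export names), since observer exports vary in capitalisation.
#' @param bundle a [fraction_bundle].
#' @param name canonical structure name.
#' @param aliases named list mapping canonical names to accepted aliases.
#' @return a [structure_mask]; error if absent.
#' @export
get_structure <- function(bundle, name, aliases = NULL) {
  stopifnot(inherits(bundle, "fraction_bundle"))
  find_structure(bundle$structures, name, aliases)
}

#' Add or replace a structure in a bundle
#' @param bundle a [fraction_bundle].
#' @param mask a [structure_mask] on a compatible grid.
#' @return the modified bundle.
#' @export
set_structure <- function(bundle, mask) {
  stopifnot(inherits(bundle, "fraction_bundle"), inherits(mask, "structure_mask"))
  stop_if_incompatible(bundle$grid, mask$grid)
  bundle$structures[[mask$name]] <- mask
  bundle
}

## ------------------------------------------------------------- bundle file

BUNDLE_MAGIC <- charToRaw("AQBN")
BUNDLE_VERSION <- 1L

#' Write / read a fraction bundle archive
#'
#' The archive is one file: a 4-byte magic, a length-prefixed JSON header
#' (schema version, ids, grid, structure names/roles, prescription, block
#' sizes) followed by gzip-compressed binary blocks (one byte per voxel for
#' masks, IEEE doubles for dose).  Round-trips are lossless: masks bit-exact
#' and dose bit-exact.  Corrupt or truncated files error; they are never
#' silently returned as shorter bundles.
#'
#' @param bundle a [fraction_bundle].
#' @param path file path to write / read.
#' @return `write_bundle` returns `path` invisibly; `read_bundle` returns a
#'   [fraction_bundle].
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "fraction_bundle"))
  blocks <- list()
  sinfo <- list()
  for (s in bundle$structures) {
    blk <- memCompress(as.raw(as.integer(s$occupancy)), type = "gzip")
    blocks[[length(blocks) + 1]] <- blk
    sinfo[[length(sinfo) + 1]] <- list(name = s$name, role = s$role,
                                       nbytes = length(blk))
  }
  dose_nbytes <- 0L
  if (!is.null(bundle$dose)) {
    blk <- memCompress(writeBin(as.numeric(bundle$dose$values), raw(),
                                size = 8, endian = "little"), type = "gzip")
    blocks[[length(blocks) + 1]] <- blk
    dose_nbytes <- length(blk)
  }
  header <- list(format = "adaptqa-bundle", version = BUNDLE_VERSION,
                 patient_id = bundle$patient_id,
                 fraction_id = bundle$fraction_id,
                 observer_id = bundle$observer_id,
                 # doubles as %.17g strings: JSON number emission keeps only
                 # 15 significant digits, which breaks exact grid round-trips
                 grid = list(origin = sprintf("%.17g", bundle$grid$origin),
                             spacing = sprintf("%.17g", bundle$grid$spacing),
                             shape = bundle$grid$shape),
                 structures = sinfo,
                 has_dose = !is.null(bundle$dose),
                 dose_nbytes = dose_nbytes,
                 prescription = if (is.null(bundle$prescription)) NULL else
                   list(dose_per_fraction = bundle$prescription$dose_per_fraction,
                        n_fractions = bundle$prescription$n_fractions))
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                                      null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(BUNDLE_MAGIC, con)
  writeBin(u32_raw(length(hjson)), con)
  writeBin(hjson, con)
  for (blk in blocks) writeBin(blk, con)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  n <- file.info(path)$size
  if (is.na(n)) stop("bundle file not found: ", path)
  raw <- readBin(path, "raw", n = n)
  if (length(raw) < 8 || !identical(raw[1:4], BUNDLE_MAGIC))
    stop("not an adaptqa bundle (bad magic): ", path)
  hlen <- read_u32(raw, 5)
  if (8 + hlen > length(raw)) stop("corrupt bundle (truncated header): ", path)
  header <- jsonlite::fromJSON(rawToChar(raw[9:(8 + hlen)]),
                               simplifyDataFrame = FALSE)
  if (!identical(as.integer(header$version), BUNDLE_VERSION))
    stop("unsupported bundle version: ", header$version)
  grid <- voxel_grid(as.numeric(unlist(header$grid$origin)),
                     as.numeric(unlist(header$grid$spacing)),
                     unlist(header$grid$shape))
  nvox <- prod(grid$shape)
  pos <- 9 + hlen
  take <- function(nbytes) {
    if (pos + nbytes - 1 > length(raw))
      stop("corrupt bundle (truncated data block): ", path)
    out <- raw[pos:(pos + nbytes - 1)]
    pos <<- pos + nbytes
    out
  }
  structures <- list()
  for (si in header$structures) {
    bytes <- memDecompress(take(si$nbytes), type = "gzip")
    if (length(bytes) != nvox)
      stop("corrupt bundle: mask '", si$name, "' has wrong voxel count")
    structures[[si$name]] <- structure_mask(grid, as.logical(as.integer(bytes)),
                                            si$name, si$role)
  }
  dose <- NULL
  if (isTRUE(header$has_dose)) {
    bytes <- memDecompress(take(header$dose_nbytes), type = "gzip")
    vals <- readBin(bytes, "double", n = length(bytes) / 8, size = 8,
                    endian = "little")
    if (length(vals) != nvox) stop("corrupt bundle: dose has wrong voxel count")
    dose <- dose_grid(grid, array(vals, dim = grid$shape))
  }
  rx <- NULL
  if (!is.null(header$prescription))
    rx <- prescription_spec(header$prescription$dose_per_fraction,
                            header$prescription$n_fractions)
  fraction_bundle(grid, structures, dose,
                  patient_id = header$patient_id,
                  fraction_id = header$fraction_id,
                  observer_id = header$observer_id,
                  prescription = rx)
}

## ------------------------------------------------------------ DICOM RTSTRUCT

#' Read an RT Structure Set into slice polygon sets
#'
#' Parses a DICOM RT Structure Set (little-endian transfer syntaxes) into
#' one [slice_polygon_set] per ROI, names preserved verbatim, coordinates in
#' patient mm.  A file of any other modality, or an ROI without a contour
#' sequence, is an error.
#' @param path path to the RTSTRUCT file.
#' @return named list of [slice_polygon_set] (empty for zero ROIs).
#' @export
read_rtstruct <- function(path) {
  f <- dcm_read_file(path)
  modality <- dcm_get(f$elements, "0008,0060")
  if (!identical(modality, "RTSTRUCT"))
    stop("not an RT Structure Set: modality is '", modality, "'")
  roi_seq <- dcm_get(f$elements, "3006,0020", required = FALSE) %||% list()
  contour_seq <- dcm_get(f$elements, "3006,0039", required = FALSE) %||% list()
  roi_names <- list()
  for (item in roi_seq) {
    num <- dcm_get(item, "3006,0022")
    roi_names[[as.character(num)]] <- dcm_get(item, "3006,0026")
  }
  out <- list()
  for (item in contour_seq) {
    ref <- as.character(dcm_get(item, "3006,0084"))
    nm <- roi_names[[ref]] %||% paste0("ROI_", ref)
    contours <- dcm_get(item, "3006,0040", required = FALSE)
    if (is.null(contours))
      stop("ROI '", nm, "' has no contour sequence")
    polys <- list()
    for (ci in contours) {
      dat <- dcm_get(ci, "3006,0050")
      if (length(dat) %% 3 != 0) stop("ROI '", nm, "': malformed contour data")
      m <- matrix(dat, ncol = 3, byrow = TRUE)
      polys[[length(polys) + 1]] <- list(z = m[1, 3], xy = m[, 1:2, drop = FALSE])
    }
    out[[nm]] <- slice_polygon_set(nm, polys)
  }
  out
}

#' Write slice polygon sets as an RT Structure Set
#'
#' Produces a minimal, standard-conformant RTSTRUCT (explicit VR little
#' endian) for interchange and round-trip testing.
#' @param polysets list of [slice_polygon_set].
#' @param path output path.
#' @param patient_id patient identifier string.
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(polysets, path, patient_id = "ANON") {
  roi_items <- list()
  contour_items <- list()
  for (i in seq_along(polysets)) {
    ps <- polysets[[i]]
    stopifnot(inherits(ps, "slice_polygon_set"))
    roi_items[[i]] <- c(dcm_elem_str(0x3006, 0x0022, "IS", i),
                        dcm_elem_str(0x3006, 0x0026, "LO", ps$name))
    citems <- list()
    for (p in ps$polygons) {
      xyz <- cbind(p$xy, p$z)
      dat <- paste(sprintf("%.8g", t(xyz)), collapse = "\\")
      citems[[length(citems) + 1]] <- c(
        dcm_elem_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_elem_str(0x3006, 0x0046, "IS", nrow(p$xy)),
        dcm_elem(0x3006, 0x0050, "DS", dcm_pad_string(dat)))
    }
    contour_items[[i]] <- c(
      dcm_elem(0x3006, 0x0040, "SQ", dcm_sq_payload(citems)),
      dcm_elem_str(0x3006, 0x0084, "IS", i))
  }
  uid <- dcm_new_uid(dcm_uid_suffix("2"))
  ds <- c(
    dcm_elem_str(0x0008, 0x0016, "UI", DCM_UID_RTSTRUCT),
    dcm_elem_str(0x0008, 0x0018, "UI", uid),
    dcm_elem_str(0x0008, 0x0020, "DA", format(Sys.Date(), "%Y%m%d")),
    dcm_elem_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_elem_str(0x0008, 0x0070, "LO", "adaptqa"),
    dcm_elem_str(0x0010, 0x0010, "PN", patient_id),
    dcm_elem_str(0x0010, 0x0020, "LO", patient_id),
    dcm_elem_str(0x0020, 0x000D, "UI", dcm_new_uid("3.1")),
    dcm_elem_str(0x0020, 0x000E, "UI", dcm_new_uid("3.2")),
    dcm_elem_str(0x3006, 0x0002, "SH", "adaptqa"),
    dcm_elem(0x3006, 0x0020, "SQ", dcm_sq_payload(roi_items)),
    dcm_elem(0x3006, 0x0039, "SQ", dcm_sq_payload(contour_items)))
  dcm_write_file(path, DCM_UID_RTSTRUCT, uid, ds)
}

## -------------------------------------------------------------- DICOM RTDOSE

#' Read an RT Dose file onto a voxel grid
#'
#' Reads a DICOM RT Dose (GY, uncompressed little endian), applies
#' `DoseGridScaling`, and checks the stored geometry against `grid`; any
#' mismatch errors with both geometries printed rather than resampling.
#' @param path path to the RTDOSE file.
#' @param grid the expected [voxel_grid].
#' @return a [dose_grid] on `grid`, values in Gy.
#' @export
read_rtdose <- function(path, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  f <- dcm_read_file(path)
  modality <- dcm_get(f$elements, "0008,0060")
  if (!identical(modality, "RTDOSE"))
    stop("not an RT Dose file: modality is '", modality, "'")
  rows <- dcm_get(f$elements, "0028,0010")
  cols <- dcm_get(f$elements, "0028,0011")
  frames <- as.integer(dcm_get(f$elements, "0028,0008"))
  ps <- dcm_get(f$elements, "0028,0030")       # (row spacing, col spacing)
  ipp <- dcm_get(f$elements, "0020,0032")
  offsets <- dcm_get(f$elements, "3004,000c")
  scaling <- dcm_get(f$elements, "3004,000e")
  bits <- dcm_get(f$elements, "0028,0100")
  dz <- if (length(offsets) > 1) diff(offsets) else grid$spacing[3]
  file_geom <- sprintf("shape %d x %d x %d, spacing %.6g x %.6g x %.6g, origin (%.6g, %.6g, %.6g)",
                       cols, rows, frames, ps[2], ps[1], mean(dz),
                       ipp[1], ipp[2], ipp[3])
  grid_geom <- sprintf("shape %d x %d x %d, spacing %.6g x %.6g x %.6g, origin (%.6g, %.6g, %.6g)",
                       grid$shape[1], grid$shape[2], grid$shape[3],
                       grid$spacing[1], grid$spacing[2], grid$spacing[3],
                       grid$origin[1], grid$origin[2], grid$origin[3])
  tol <- 1e-4
  ok <- cols == grid$shape[1] && rows == grid$shape[2] &&
    frames == grid$shape[3] &&
    abs(ps[2] - grid$spacing[1]) < tol && abs(ps[1] - grid$spacing[2]) < tol &&
    all(abs(dz - grid$spacing[3]) < tol) &&
    all(abs(ipp - grid$origin) < tol)
  if (!ok)
    stop("RT Dose geometry mismatch:\n  file: ", file_geom,
         "\n  grid: ", grid_geom)
  payload <- dcm_get(f$elements, "7fe0,0010")
  if (!is.raw(payload)) stop("unsupported pixel data encoding")
  nvox <- as.numeric(cols) * rows * frames
  if (bits == 16) {
    vals <- readBin(payload, "integer", n = nvox, size = 2, signed = FALSE,
                    endian = "little")
  } else if (bits == 32) {
    vals <- vapply(seq_len(nvox), function(i) read_u32(payload, 4 * (i - 1) + 1),
                   numeric(1))
  } else stop("unsupported BitsAllocated: ", bits)
  if (length(vals) < nvox) stop("RT Dose pixel data truncated")
  dose_grid(grid, array(vals * scaling, dim = grid$shape))
}

#' Write a dose grid as an RT Dose file
#'
#' Stores dose as 16-bit integers with an explicit `DoseGridScaling`
#' (quantisation below 1e-4 of the maximum dose), explicit VR little endian.
#' @param dose a [dose_grid].
#' @param path output path.
#' @param patient_id patient identifier string.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(dose, path, patient_id = "ANON") {
  stopifnot(inherits(dose, "dose_grid"))
  g <- dose$grid
  mx <- max(dose$values)
  scaling <- if (mx > 0) mx / 65000 else 1
  stored <- as.integer(round(dose$values / scaling))
  offsets <- (seq_len(g$shape[3]) - 1) * g$spacing[3]
  uid <- dcm_new_uid(dcm_uid_suffix("4"))
  ds <- c(
    dcm_elem_str(0x0008, 0x0016, "UI", DCM_UID_RTDOSE),
    dcm_elem_str(0x0008, 0x0018, "UI", uid),
    dcm_elem_str(0x0008, 0x0020, "DA", format(Sys.Date(), "%Y%m%d")),
    dcm_elem_str(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_elem_str(0x0008, 0x0070, "LO", "adaptqa"),
    dcm_elem_str(0x0010, 0x0010, "PN", patient_id),
    dcm_elem_str(0x0010, 0x0020, "LO", patient_id),
    dcm_elem_str(0x0020, 0x000D, "UI", dcm_new_uid("5.1")),
    dcm_elem_str(0x0020, 0x000E, "UI", dcm_new_uid("5.2")),
    dcm_elem_str(0x0020, 0x0032, "DS", sprintf("%.8g", g$origin)),
    dcm_elem_str(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    dcm_elem_us(0x0028, 0x0002, 1),
    dcm_elem_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_elem_str(0x0028, 0x0008, "IS", g$shape[3]),
    dcm_elem_us(0x0028, 0x0010, g$shape[2]),
    dcm_elem_us(0x0028, 0x0011, g$shape[1]),
    dcm_elem_str(0x0028, 0x0030, "DS",
                 sprintf("%.8g", c(g$spacing[2], g$spacing[1]))),
    dcm_elem_us(0x0028, 0x0100, 16),
    dcm_elem_us(0x0028, 0x0101, 16),
    dcm_elem_us(0x0028, 0x0102, 15),
    dcm_elem_us(0x0028, 0x0103, 0),
    dcm_elem_str(0x3004, 0x0002, "CS", "GY"),
    dcm_elem_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_elem_str(0x3004, 0x000C, "DS", sprintf("%.8g", offsets)),
    dcm_elem_str(0x3004, 0x000E, "DS", sprintf("%.10g", scaling)),
    dcm_elem(0x7FE0, 0x0010, "OW", u16_raw(stored)))
  dcm_write_file(path, DCM_UID_RTDOSE, uid, ds)
}
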