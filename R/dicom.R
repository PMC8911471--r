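# Minimal DICOM (PS3.10) primitives for RT Structure Set and RT Dose files.
#
# Scope: little-endian transfer syntaxes only (explicit 1.2.840.10008.1.2.1
# and implicit 1.2.840.10008.1.2), axis-aligned geometry, uncompressed pixel
# data.  This is an adapter for vanilla RTSTRUCT/RTDOSE exports, not a
# general DICOM toolkit; anything outside the subset errors loudly.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_IMPLICIT_LE <- "1.2.840.10008.1.2"
DCM_UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
DCM_UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
DCM_UID_ROOT <- "1.2.826.0.1.3680043.8.498"  # public test UID root

# tag -> VR dictionary covering every tag this adapter interprets
dcm_dict <- c(
  "0002,0002" = "UI", "0002,0003" = "UI", "0002,0010" = "UI", "0002,0012" = "UI",
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0020" = "DA", "0008,0030" = "TM",
  "0008,0060" = "CS", "0008,0070" = "LO", "0008,1030" = "LO",
  "0010,0010" = "PN", "0010,0020" = "LO",
  "0020,000d" = "UI", "0020,000e" = "UI", "0020,0032" = "DS", "0020,0037" = "DS",
  "0020,0011" = "IS", "0020,0013" = "IS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0008" = "IS",
  "0028,0010" = "US", "0028,0011" = "US", "0028,0030" = "DS",
  "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "3004,0002" = "CS", "3004,0004" = "CS", "3004,000c" = "DS", "3004,000e" = "DS",
  "3006,0002" = "SH", "3006,0020" = "SQ", "3006,0022" = "IS", "3006,0024" = "UI",
  "3006,0026" = "LO", "3006,0039" = "SQ", "3006,0040" = "SQ", "3006,0042" = "CS",
  "3006,0046" = "IS", "3006,0050" = "DS", "3006,0084" = "IS",
  "7fe0,0010" = "OW")

dcm_sq_tags <- c("3006,0020", "3006,0039", "3006,0040")

tag_key <- function(group, elem) sprintf("%04x,%04x", group, elem)

## ---------------------------------------------------------------- writing

u16_raw <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(x %% 256L, (x %/% 256L) %% 256L))
}

u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256,
               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

dcm_pad_string <- function(s, nul = FALSE) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, if (nul) as.raw(0) else charToRaw(" "))
  b
}

dcm_string_payload <- function(vr, values) {
  s <- paste(as.character(values), collapse = "\\")
  dcm_pad_string(s, nul = vr == "UI")
}

# serialize one data element (explicit VR little endian)
dcm_elem <- function(group, elem, vr, payload) {
  stopifnot(is.raw(payload))
  head <- c(u16_raw(group), u16_raw(elem), charToRaw(vr))
  hdr <- if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), u32_raw(length(payload)))
  } else {
    if (length(payload) > 65534) stop("element too long for short VR form")
    c(head, u16_raw(length(payload)))
  }
  c(hdr, payload)
}

dcm_elem_str <- function(group, elem, vr, values)
  dcm_elem(group, elem, vr, dcm_string_payload(vr, values))

dcm_elem_us <- function(group, elem, values)
  dcm_elem(group, elem, "US", u16_raw(values))

# sequence payload from a list of item payloads (defined lengths)
dcm_sq_payload <- function(items) {
  out <- raw(0)
  for (it in items)
    out <- c(out, u16_raw(0xFFFE), u16_raw(0xE000), u32_raw(length(it)), it)
  out
}

dcm_new_uid <- function(suffix) paste0(DCM_UID_ROOT, ".", suffix)

# process-unique UID suffix without touching the global RNG state
.dcm_uid_counter <- new.env(parent = emptyenv())
dcm_uid_suffix <- function(prefix) {
  n <- (get0("n", .dcm_uid_counter, ifnotfound = 0L)) + 1L
  assign("n", n, .dcm_uid_counter)
  paste0(prefix, ".", Sys.getpid() %% 100000L, ".",
         as.integer(Sys.time()) %% 1e7, ".", n)
}

# assemble a complete Part-10 file: preamble + file meta + dataset
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, dataset_raw) {
  meta <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem_str(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_elem_str(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_elem_str(0x0002, 0x0010, "UI", DCM_EXPLICIT_LE),
    dcm_elem_str(0x0002, 0x0012, "UI", dcm_new_uid("1")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_elem(0x0002, 0x0000, "UL", u32_raw(length(meta))), con)
  writeBin(meta, con)
  writeBin(dataset_raw, con)
  invisible(path)
}

## ---------------------------------------------------------------- reading

read_u16 <- function(raw, pos)
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1])

read_u32 <- function(raw, pos)
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1]) +
    65536 * as.numeric(raw[pos + 2]) + 16777216 * as.numeric(raw[pos + 3])

dcm_parse_value <- function(vr, payload) {
  if (is.na(vr) || vr %in% c("OB", "OW", "OF", "UN")) return(payload)
  if (vr %in% c("US")) {
    return(readBin(payload, "integer", n = length(payload) / 2, size = 2,
                   signed = FALSE, endian = "little"))
  }
  if (vr %in% c("UL")) {
    n <- length(payload) / 4
    return(vapply(seq_len(n), function(i) read_u32(payload, 4 * (i - 1) + 1),
                  numeric(1)))
  }
  if (vr %in% c("FL", "FD")) {
    sz <- if (vr == "FL") 4L else 8L
    return(readBin(payload, "double", n = length(payload) / sz, size = sz,
                   endian = "little"))
  }
  s <- rawToChar(payload[payload != as.raw(0)])
  s <- sub("[ ]+$", "", s)
  parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
  if (vr == "DS") return(as.numeric(parts))
  if (vr == "IS") return(as.integer(parts))
  parts
}

# parse one element; returns list(key, vr, value, next_pos)
dcm_parse_elem <- function(raw, pos, explicit) {
  group <- read_u16(raw, pos); elem <- read_u16(raw, pos + 2)
  key <- tag_key(group, elem)
  pos <- pos + 4
  if (explicit) {
    vr <- rawToChar(raw[pos:(pos + 1)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- read_u32(raw, pos + 4); pos <- pos + 8
    } else {
      len <- read_u16(raw, pos + 2); pos <- pos + 4
    }
  } else {
    vr <- unname(dcm_dict[key])
    if (!is.na(vr) && key %in% dcm_sq_tags) vr <- "SQ"
    len <- read_u32(raw, pos); pos <- pos + 4
  }
  undefined <- len >= 4294967295
  if (!is.na(vr) && vr == "SQ" || (undefined && !explicit)) {
    items <- list()
    if (undefined) {
      repeat {
        ig <- read_u16(raw, pos); ie <- read_u16(raw, pos + 2)
        ilen <- read_u32(raw, pos + 4); pos <- pos + 8
        if (ig == 0xFFFE && ie == 0xE0DD) break
        if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item tag")
        parsed <- dcm_parse_dataset(raw, pos,
                                    if (ilen >= 4294967295) NA else pos + ilen - 1,
                                    explicit, item_mode = ilen >= 4294967295)
        items[[length(items) + 1]] <- parsed$elements
        pos <- parsed$pos
      }
    } else {
      end <- pos + len - 1
      while (pos <= end) {
        ig <- read_u16(raw, pos); ie <- read_u16(raw, pos + 2)
        ilen <- read_u32(raw, pos + 4); pos <- pos + 8
        if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item tag")
        parsed <- dcm_parse_dataset(raw, pos,
                                    if (ilen >= 4294967295) NA else pos + ilen - 1,
                                    explicit, item_mode = ilen >= 4294967295)
        items[[length(items) + 1]] <- parsed$elements
        pos <- parsed$pos
      }
    }
    return(list(key = key, vr = "SQ", value = items, pos = pos))
  }
  if (undefined) stop("undefined-length element outside a sequence is not supported")
  payload <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
  pos <- pos + len
  if (is.na(vr)) vr <- unname(dcm_dict[key])
  list(key = key, vr = vr, value = dcm_parse_value(vr, payload), pos = pos)
}

# parse a dataset until `end` (inclusive), or until an item delimiter when
# item_mode is TRUE, or to the end of the buffer when end is NA
dcm_parse_dataset <- function(raw, pos, end, explicit, item_mode = FALSE) {
  elements <- list()
  limit <- if (is.na(end)) length(raw) else end
  while (pos <= limit && pos + 7 <= length(raw)) {
    g <- read_u16(raw, pos); e <- read_u16(raw, pos + 2)
    if (item_mode && g == 0xFFFE && e == 0xE00D) {  # item delimitation
      pos <- pos + 8
      return(list(elements = elements, pos = pos))
    }
    el <- dcm_parse_elem(raw, pos, explicit)
    elements[[el$key]] <- list(vr = el$vr, value = el$value)
    pos <- el$pos
  }
  if (item_mode) stop("unterminated sequence item (corrupt DICOM stream)")
  list(elements = elements, pos = pos)
}

# read and parse a Part-10 file; returns list(meta, elements)
dcm_read_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 140) stop("not a DICOM file (too short): ", path)
  raw <- readBin(path, "raw", n = n)
  if (rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM marker): ", path)
  pos <- 133
  meta <- list()
  while (pos + 7 <= length(raw) && read_u16(raw, pos) == 0x0002) {
    el <- dcm_parse_elem(raw, pos, explicit = TRUE)
    meta[[el$key]] <- list(vr = el$vr, value = el$value)
    pos <- el$pos
  }
  ts <- meta[["0002,0010"]]$value %||% DCM_IMPLICIT_LE
  if (ts == DCM_EXPLICIT_LE) explicit <- TRUE
  else if (ts == DCM_IMPLICIT_LE) explicit <- FALSE
  else stop("unsupported transfer syntax: ", ts,
            " (only little-endian uncompressed syntaxes are handled)")
  ds <- dcm_parse_dataset(raw, pos, NA, explicit)
  list(meta = meta, elements = ds$elements)
}

dcm_get <- function(elements, key, required = TRUE) {
  el <- elements[[tolower(key)]]
  if (is.null(el)) {
    if (required) stop("required DICOM element (", key, ") is missing")
    return(NULL)
  }
  el$value
}
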