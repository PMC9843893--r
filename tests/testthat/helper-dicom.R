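# Byte-level DICOM writer for test fixtures (explicit VR little endian,
# 16-bit monochrome). Written independently of the package's reader so the
# round trip is a genuine cross-check.

raw_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
raw_u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256,
                                (x %/% 16777216) %% 256))

dcm_elem_short <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  c(raw_u16(group), raw_u16(elem), charToRaw(vr),
    raw_u16(length(value_raw)), value_raw)
}

dcm_elem_long <- function(group, elem, vr, value_raw) {
  c(raw_u16(group), raw_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
    raw_u32(length(value_raw)), value_raw)
}

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

# stored: integer matrix [x, y] of raw stored values (signed 16-bit)
write_test_dicom <- function(path, stored, slope, intercept,
                             pixel_spacing_xy = c(1, 1), position_z = 0,
                             instance = 1) {
  nx <- nrow(stored)
  ny <- ncol(stored)
  meta <- dcm_elem_short(2L, 16L, "UI", dcm_str("1.2.840.10008.1.2.1"))
  meta <- c(dcm_elem_short(2L, 0L, "UL", raw_u32(length(meta))), meta)
  # PixelData row-major: row 1 (all x at y = 1) first
  stored_rowmajor <- as.integer(stored)  # [x, y] column-major == row-major
  px <- writeBin(stored_rowmajor, raw(), size = 2, endian = "little")
  body <- c(
    dcm_elem_short(0x0008, 0x0060, "CS", dcm_str("CT")),
    dcm_elem_short(0x0018, 0x0050, "DS", dcm_str("5")),
    dcm_elem_short(0x0020, 0x0013, "IS", dcm_str(as.character(instance))),
    dcm_elem_short(0x0020, 0x0032, "DS",
                   dcm_str(sprintf("0\\0\\%g", position_z))),
    dcm_elem_short(0x0028, 0x0002, "US", raw_u16(1)),
    dcm_elem_short(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
    dcm_elem_short(0x0028, 0x0010, "US", raw_u16(ny)),   # Rows
    dcm_elem_short(0x0028, 0x0011, "US", raw_u16(nx)),   # Columns
    dcm_elem_short(0x0028, 0x0030, "DS",
                   dcm_str(sprintf("%g\\%g", pixel_spacing_xy[2],
                                   pixel_spacing_xy[1]))),
    dcm_elem_short(0x0028, 0x0100, "US", raw_u16(16)),
    dcm_elem_short(0x0028, 0x0101, "US", raw_u16(16)),
    dcm_elem_short(0x0028, 0x0102, "US", raw_u16(15)),
    dcm_elem_short(0x0028, 0x0103, "US", raw_u16(1)),    # signed
    dcm_elem_short(0x0028, 0x1052, "DS", dcm_str(as.character(intercept))),
    dcm_elem_short(0x0028, 0x1053, "DS", dcm_str(as.character(slope))),
    dcm_elem_long(0x7FE0, 0x0010, "OW", px))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  invisible(path)
}
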