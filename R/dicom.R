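# Minimal DICOM series reader.
#
# Scope: uncompressed little-endian transfer syntaxes (implicit VR 1.2.840.
# 10008.1.2 and explicit VR 1.2.840.10008.1.2.1), monochrome 16-bit pixel
# data, no sequences with undefined length. This covers CT series exported
# without compression; anything else raises a format error. Stored values
# are converted to HU with HU = RescaleSlope * stored + RescaleIntercept.

dcm_u16 <- function(raw2) sum(as.integer(raw2) * c(1L, 256L))
dcm_u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

dcm_tag <- function(g, e) sprintf("%04X%04X", g, e)

# VRs whose explicit-VR length field is 4 bytes after 2 reserved bytes
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one DICOM file into a named list tag -> raw value.
parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop_pancrad(paste0("'", path, "' is not a DICOM part-10 file"),
                 "pancrad_format_error")
  pos <- 133L
  elems <- list()
  explicit <- TRUE   # file meta group is always explicit VR
  explicit_pending <- FALSE
  transfer <- NULL
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- dcm_u16(bytes[pos:(pos + 1L)])
    elem <- dcm_u16(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (!is.null(transfer) && group > 2L && explicit_pending) {
      # leaving the meta group: switch VR mode per transfer syntax
      explicit <- transfer != "1.2.840.10008.1.2"
      explicit_pending <- FALSE
    }
    if (explicit || group == 2L) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% .dcm_long_vrs) {
        len <- dcm_u32(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- dcm_u16(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      len <- dcm_u32(bytes[pos:(pos + 3L)])  # implicit VR: 4-byte length
      pos <- pos + 4L
    }
    if (len == 4294967295)
      stop_pancrad("undefined-length DICOM elements are not supported",
                   "pancrad_format_error")
    if (pos + len - 1L > n)
      stop_pancrad("truncated DICOM element", "pancrad_format_error")
    val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    elems[[dcm_tag(group, elem)]] <- val
    if (group == 2L && elem == 16L) {  # (0002,0010) TransferSyntaxUID
      transfer <- sub("\\s+$", "", rawToChar(val))
      transfer <- gsub("\\x00", "", transfer, useBytes = TRUE)
      if (!transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop_pancrad(paste("unsupported transfer syntax", transfer),
                     "pancrad_format_error")
      explicit_pending <- TRUE
    }
  }
  elems
}

dcm_string <- function(elems, tag, default = NULL) {
  v <- elems[[tag]]
  if (is.null(v)) return(default)
  s <- gsub("\\x00", "", rawToChar(v), useBytes = TRUE)
  sub("\\s+$", "", s)
}

dcm_numbers <- function(elems, tag, default = NULL) {
  s <- dcm_string(elems, tag)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

# Read one slice: list(pixels = matrix [x, y], position, spacing_xy, ...)
read_dicom_slice <- function(path) {
  el <- parse_dicom_file(path)
  rows <- dcm_u16(el[["00280010"]])
  cols <- dcm_u16(el[["00280011"]])
  bits <- dcm_u16(el[["00280100"]])
  if (bits != 16)
    stop_pancrad("only 16-bit DICOM pixel data is supported",
                 "pancrad_format_error")
  signed <- dcm_u16(el[["00280103"]] %||% as.raw(c(0, 0))) == 1
  slope <- dcm_numbers(el, "00281053", 1)
  intercept <- dcm_numbers(el, "00281052", 0)
  px_spacing <- dcm_numbers(el, "00280030")  # row spacing (y), col spacing (x)
  if (is.null(px_spacing))
    stop_pancrad("missing PixelSpacing", "pancrad_metadata_error")
  position <- dcm_numbers(el, "00200032", c(0, 0, 0))
  inst <- dcm_numbers(el, "00200013", NA_real_)
  pix <- el[["7FE00010"]]
  if (is.null(pix) || length(pix) < 2 * rows * cols)
    stop_pancrad("missing or short PixelData", "pancrad_format_error")
  stored <- readBin(pix, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
  if (!signed) stored <- as.numeric(stored) %% 65536
  hu <- slope * as.numeric(stored) + intercept
  # PixelData is row-major (fastest over image columns = x), so filling an
  # R matrix with nrow = cols yields [x, y] directly
  pixels <- matrix(hu, nrow = cols, ncol = rows)
  list(pixels = pixels, position = position, instance = inst,
       spacing_xy = c(px_spacing[2], px_spacing[1]),
       thickness = dcm_numbers(el, "00180050", NA_real_))
}

# Assemble a DICOM series directory into a volume, ordering slices by the z
# component of ImagePositionPatient (InstanceNumber as tie-break).
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop_pancrad("empty DICOM directory", "pancrad_format_error")
  slices <- lapply(files, read_dicom_slice)
  zs <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(zs, vapply(slices, function(s) s$instance, 0))
  slices <- slices[ord]
  zs <- zs[ord]
  dz <- if (length(zs) > 1) diff(zs)[1] else slices[[1]]$thickness
  if (!is.finite(dz) || dz <= 0)
    stop_pancrad("cannot determine slice spacing", "pancrad_metadata_error")
  vox <- simplify2array(lapply(slices, `[[`, "pixels"))
  if (length(dim(vox)) == 2) dim(vox) <- c(dim(vox), 1L)
  list(voxels = vox,
       spacing = c(slices[[1]]$spacing_xy, dz),
       origin = slices[[1]]$position)
}
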