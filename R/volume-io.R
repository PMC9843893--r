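#' CT volume and label mask containers
#'
#' `ct_volume()` wraps a 3D array of Hounsfield-unit voxels together with its
#' physical grid metadata (voxel spacing and origin, both in mm). The x-y
#' plane is the axial slice plane and z is the slice axis; coordinates are
#' 0-based voxel-center positions, so voxel `(i, j, k)` (0-based) sits at
#' `origin + c(i, j, k) * spacing`. `label_mask()` is the co-registered
#' integer mask over the same grid with labels 0 (background), 1 (pancreas)
#' and 2 (tumor).
#'
#' @param voxels 3D numeric array of HU values; all values must be finite.
#' @param spacing numeric length-3, voxel spacing (x, y, z) in mm, all > 0.
#' @param origin numeric length-3, physical position of the first voxel
#'   center in mm.
#' @return An object of class `ct_volume` (resp. `label_mask`).
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  voxels <- array(as.numeric(voxels), dim(voxels))  # strip foreign attrs
  if (length(dim(voxels)) == 2) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3)
    stop_pancrad("voxels must be a 3D array", "pancrad_input_error")
  if (!all(is.finite(voxels)))
    stop_pancrad("voxel values must be finite", "pancrad_input_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_pancrad("spacing must be three strictly positive values",
                 "pancrad_metadata_error")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @param labels 3D integer array with values in \{0, 1, 2\}.
#' @export
label_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  labels <- array(as.integer(round(as.numeric(labels))), dim(labels))
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1L)
  if (length(dim(labels)) != 3)
    stop_pancrad("labels must be a 3D array", "pancrad_input_error")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(0L, 1L, 2L)))
    stop_pancrad("labels must be in {0, 1, 2}", "pancrad_input_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop_pancrad("spacing must be three strictly positive values",
                 "pancrad_metadata_error")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "label_mask")
}

#' @exportS3Method base::print
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "x"), " mm, HU [",
      round(min(x$voxels)), ", ", round(max(x$voxels)), "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.label_mask <- function(x, ...) {
  tab <- tabulate(as.integer(x$labels) + 1L, 3)
  cat("<label_mask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, pancreas ", tab[2], ", tumor ", tab[3], "\n", sep = "")
  invisible(x)
}

#' Read a CT volume or label mask from disk
#'
#' Accepts a NIfTI file (`.nii`/`.nii.gz`) or a directory containing an
#' uncompressed little-endian DICOM series. DICOM stored values are rescaled
#' to HU with the per-slice rescale slope and intercept. Volumes are returned
#' with x-y as the in-plane axes and z as the slice axis.
#'
#' @param path file path to a NIfTI file or a DICOM series directory.
#' @return A [ct_volume].
#' @export
read_volume <- function(path) {
  v <- read_gridded(path)
  ct_volume(v$voxels, v$spacing, v$origin)
}

#' @rdname read_volume
#' @return `read_mask()` returns a [label_mask].
#' @export
read_mask <- function(path) {
  v <- read_gridded(path)
  label_mask(round(v$voxels), v$spacing, v$origin)
}

read_gridded <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path))
    stop_pancrad(paste0("cannot read '", path, "'"), "pancrad_format_error")
  if (file.info(path)$size == 0)
    stop_pancrad("empty file", "pancrad_format_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_pancrad(paste("unreadable NIfTI:",
                                       conditionMessage(e)),
                                 "pancrad_format_error"))
  vox <- as.array(img)
  # drop trailing singleton dims (e.g. a stored 4th dimension of length 1)
  d <- dim(vox)
  while (length(d) > 3 && d[length(d)] == 1) {
    d <- d[-length(d)]
    dim(vox) <- d
  }
  if (length(d) != 3)
    stop_pancrad("expected a 3D volume", "pancrad_format_error")
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_pancrad("missing or invalid voxel spacing in header",
                 "pancrad_metadata_error")
  orig <- tryCatch(as.numeric(RNifti::origin(img))[1:3],
                   error = function(e) c(0, 0, 0))
  if (any(!is.finite(orig))) orig <- c(0, 0, 0)
  list(voxels = vox, spacing = as.numeric(spacing), origin = orig)
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [ct_volume] or [label_mask].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "label_mask")) x$labels else x$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resampling specification
#'
#' The canonical analysis grid: 1 x 1 x 5 mm spacing, linear interpolation
#' for images and nearest-neighbor interpolation for label masks. The output
#' grid size per axis is `round(extent / target_spacing)` so physical extent
#' is preserved to within one voxel.
#'
#' @param target_spacing numeric length-3 target spacing in mm.
#' @param image_interpolation `"linear"` (images).
#' @param label_interpolation `"nearest"` (masks).
#' @return A `resample_spec` list.
#' @export
resample_spec <- function(target_spacing = c(1, 1, 5),
                          image_interpolation = "linear",
                          label_interpolation = "nearest") {
  stopifnot(length(target_spacing) == 3, all(target_spacing > 0))
  structure(list(target_spacing = as.numeric(target_spacing),
                 image_interpolation = match.arg(image_interpolation,
                                                 c("linear", "nearest")),
                 label_interpolation = match.arg(label_interpolation,
                                                 c("nearest"))),
            class = "resample_spec")
}

# Map target voxel-center coordinates (0-based) onto continuous source
# indices per axis. Same origin convention on both grids.
resample_axis_coords <- function(n_src, s_src, s_tgt) {
  n_tgt <- max(1L, as.integer(round(n_src * s_src / s_tgt)))
  src <- (seq_len(n_tgt) - 1) * s_tgt / s_src
  list(n = n_tgt, src = src)
}

# 1D linear interpolation along the first axis of a 3D array, vectorized
# over the remaining axes. `src` holds continuous 0-based source indices.
interp_axis_linear <- function(arr, src) {
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1])
  i0 <- pmin(pmax(floor(src), 0), d[1] - 1)
  f <- src - i0
  i1 <- pmin(i0 + 1, d[1] - 1)
  f[i1 == i0] <- 0
  out <- m[i0 + 1, , drop = FALSE] * (1 - f) + m[i1 + 1, , drop = FALSE] * f
  array(out, dim = c(length(src), d[2], d[3]))
}

interp_axis_nearest <- function(arr, src) {
  d <- dim(arr)
  i <- pmin(pmax(round(src), 0), d[1] - 1)
  m <- matrix(arr, nrow = d[1])
  array(m[i + 1, , drop = FALSE], dim = c(length(i), d[2], d[3]))
}

resample_array <- function(arr, spacing, target_spacing, method) {
  interp <- if (method == "linear") interp_axis_linear else interp_axis_nearest
  for (ax in 1:3) {
    cc <- resample_axis_coords(dim(arr)[1], spacing[ax], target_spacing[ax])
    arr <- interp(arr, cc$src)
    arr <- aperm(arr, c(2, 3, 1))  # rotate axes so each takes a turn first
  }
  arr
}

#' Resample a co-registered CT volume / mask pair onto the canonical grid
#'
#' The image is resampled with linear interpolation and the mask with
#' nearest-neighbor interpolation so the label set \{0, 1, 2\} is preserved.
#' Both outputs share the identical target grid.
#'
#' @param volume a [ct_volume].
#' @param mask the paired [label_mask] in the same physical frame.
#' @param spec a [resample_spec].
#' @return A list with elements `volume` and `mask`.
#' @export
resample_pair <- function(volume, mask, spec = resample_spec()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "label_mask"))
  check_coregistered(volume, mask)
  tgt <- spec$target_spacing
  v <- resample_array(volume$voxels, volume$spacing, tgt,
                      spec$image_interpolation)
  m <- resample_array(mask$labels, mask$spacing, tgt, spec$label_interpolation)
  list(volume = ct_volume(v, tgt, volume$origin),
       mask = label_mask(m, tgt, mask$origin))
}

check_coregistered <- function(volume, mask) {
  lo_v <- volume$origin
  hi_v <- volume$origin + (dim(volume$voxels) - 1) * volume$spacing
  lo_m <- mask$origin
  hi_m <- mask$origin + (dim(mask$labels) - 1) * mask$spacing
  if (any(hi_v < lo_m) || any(hi_m < lo_v))
    stop_pancrad("volume and mask occupy disjoint physical extents",
                 "pancrad_coregistration_error")
  invisible(TRUE)
}

#' Union of pancreas and tumor labels
#'
#' The volume of interest for the 3D analysis and the region of interest for
#' patch extraction is the union of pancreas (label 1) and tumor (label 2)
#' voxels. An all-background mask is permitted but flagged via the `"empty"`
#' attribute, mirroring study exclusion when upstream segmentation fails.
#'
#' @param mask a [label_mask].
#' @return A [label_mask] with labels in \{0, 1\}; attribute `"empty"` is
#'   `TRUE` when the union contains no voxels.
#' @export
roi_union <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  u <- array(as.integer(mask$labels > 0L), dim = dim(mask$labels))
  out <- label_mask(u, mask$spacing, mask$origin)
  attr(out, "empty") <- !any(u > 0L)
  out
}
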