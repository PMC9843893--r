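# Texture matrix construction and feature formulas.
#
# Matrices follow the IBSI-style definitions: GLCM distance 1 with
# symmetrization, features computed per angle then averaged (4 in-plane
# angles in 2D, 13 angles of the 26-neighborhood in 3D); GLRLM runs per
# direction, averaged the same way; GLSZM zones are connected regions of
# equal gray level (8-/26-connectivity); GLDM dependence counts neighbors
# within alpha = 0 of the center level, with dependence size j = count + 1
# so the center voxel counts itself; NGTDM accumulates |i - mean(valid
# neighbors)| per gray level. Neighbors outside the ROI never contribute.
#
# Degenerate conventions (regions too small for a family to be defined):
# GLCM correlation -> 1, NGTDM coarseness -> 1e6, busyness -> 0, first-order
# skewness -> 0, everything else -> 0.

#' Build a gray-level texture matrix
#'
#' @param indices integer array of gray-level indices, 0 outside the ROI
#'   (as returned by the internal discretizer); 2D matrices are treated as a
#'   single slice.
#' @param family one of `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`, `"ngtdm"`.
#' @param dimensionality `"2d"` (in-plane neighborhoods) or `"3d"`
#'   (26-neighborhood / 13 angles).
#' @param n_levels number of gray levels; defaults to the `"n_levels"`
#'   attribute of `indices` or the maximum index.
#' @return A `texture_matrix` object: the per-angle matrix list (GLCM,
#'   GLRLM) or single matrix, the gray-level count and the ROI voxel count.
#' @export
build_texture_matrix <- function(indices,
                                 family = c("glcm", "glrlm", "glszm",
                                            "gldm", "ngtdm"),
                                 dimensionality = c("3d", "2d"),
                                 n_levels = NULL) {
  family <- match.arg(family)
  dimensionality <- match.arg(dimensionality)
  idx <- as_array3(indices)
  storage.mode(idx) <- "integer"
  nlev <- as.integer(n_levels %||% attr(indices, "n_levels") %||%
                       max(idx, 1L))
  dims <- as.integer(dim(idx))
  threeD <- dimensionality == "3d"
  n_vox <- sum(idx > 0L)
  degenerate <- n_vox < 2L
  m <- switch(family,
    glcm = cpp_glcm(idx, dims, nlev, threeD),
    glrlm = cpp_glrlm(idx, dims, nlev, threeD),
    glszm = cpp_glszm(idx, dims, nlev, threeD),
    gldm = cpp_gldm(idx, dims, nlev, 0L, threeD),
    ngtdm = cpp_ngtdm(idx, dims, nlev, threeD))
  structure(list(family = family, matrix = m, n_levels = nlev,
                 n_voxels = n_vox, dimensionality = dimensionality,
                 degenerate = degenerate),
            class = "texture_matrix")
}

# ---- first order ------------------------------------------------------

.firstorder_ids <- c("mean", "median", "minimum", "maximum", "range",
                     "variance", "skewness", "mean_absolute_deviation",
                     "entropy", "root_mean_squared")

first_order_features <- function(values, bin_width = 16,
                                 ids = .firstorder_ids) {
  if (length(values) == 0)
    stop_pancrad("empty region", "pancrad_empty_roi_error")
  v <- cpp_firstorder(as.numeric(values), bin_width)
  names(v) <- .firstorder_ids
  v[ids]
}

# ---- family formulas --------------------------------------------------
# Thin wrappers over the compiled kernels; value order is fixed there.

.glcm_ids <- c("contrast", "correlation", "imc2", "inverse_variance",
               "inverse_difference_moment", "joint_entropy")

glcm_features <- function(tm, ids = .glcm_ids) {
  v <- cpp_glcm_feats(tm$matrix)
  names(v) <- .glcm_ids
  v[ids]
}

.glrlm_ids <- c("short_run_emphasis", "long_run_emphasis", "run_percentage",
                "gray_level_nonuniformity")

glrlm_features <- function(tm, ids = .glrlm_ids) {
  v <- cpp_glrlm_feats(tm$matrix, tm$n_voxels)
  names(v) <- .glrlm_ids
  v[ids]
}

.glszm_ids <- c("small_area_emphasis", "large_area_emphasis",
                "zone_percentage", "gray_level_nonuniformity")

glszm_features <- function(tm, ids = .glszm_ids) {
  v <- cpp_glszm_feats(tm$matrix, tm$n_voxels)
  names(v) <- .glszm_ids
  v[ids]
}

.gldm_ids <- c("small_dependence_emphasis", "large_dependence_emphasis",
               "gray_level_variance", "dependence_entropy",
               "dependence_nonuniformity")

gldm_features <- function(tm, ids = .gldm_ids) {
  v <- cpp_gldm_feats(tm$matrix)
  names(v) <- .gldm_ids
  v[ids]
}

.ngtdm_ids <- c("busyness", "coarseness", "contrast")

ngtdm_features <- function(tm, ids = .ngtdm_ids) {
  v <- cpp_ngtdm_feats(tm$matrix)
  names(v) <- .ngtdm_ids
  v[ids]
}

.family_ids <- list(firstorder = .firstorder_ids, glcm = .glcm_ids,
                    glrlm = .glrlm_ids, glszm = .glszm_ids,
                    gldm = .gldm_ids, ngtdm = .ngtdm_ids)

#' Compute a single radiomic feature
#'
#' @param x a `texture_matrix` (for texture features) or a numeric vector of
#'   raw region intensities (for first-order features).
#' @param feature_id string `"<family>_<feature>"`, e.g. `"glcm_correlation"`
#'   or `"firstorder_median"`.
#' @param bin_width bin width used by first-order entropy.
#' @return A single finite numeric value.
#' @export
compute_feature <- function(x, feature_id, bin_width = 16) {
  parts <- strsplit(feature_id, "_")[[1]]
  family <- parts[1]
  feat <- paste(parts[-1], collapse = "_")
  ids <- .family_ids[[family]]
  if (is.null(ids) || !feat %in% ids)
    stop_pancrad(paste("unknown feature id", feature_id),
                 "pancrad_config_error")
  if (family == "firstorder")
    return(unname(first_order_features(x, bin_width, ids = feat)))
  stopifnot(inherits(x, "texture_matrix"), x$family == family)
  fn <- switch(family, glcm = glcm_features, glrlm = glrlm_features,
               glszm = glszm_features, gldm = gldm_features,
               ngtdm = ngtdm_features)
  unname(fn(x, ids = feat))
}
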