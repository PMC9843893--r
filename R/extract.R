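# Feature manifests and the extraction engine.
#
# A manifest is the declarative cross-product of image filters and feature
# ids that defines a feature vector: one row per output feature, ordered
# deterministically, with the full feature name "<filter>_<family>_<feature>".
# The pipeline contract depends on names and ordering, not on any historical
# feature count, so manifests are config-driven and the defaults document
# their own sizes.

#' Build a feature manifest
#'
#' @param filters character vector of filter ids (`"original"`,
#'   `"wavelet-<band>"`, `"log-sigma-<s>-mm"`).
#' @param features character vector of feature ids
#'   (`"<family>_<feature>"`, see [compute_feature()]).
#' @return A data.frame with columns `filter`, `family`, `feature`, `name`.
#' @export
feature_manifest <- function(filters, features) {
  fam <- sub("_.*$", "", features)
  bad <- !mapply(function(f, id) {
    ids <- .family_ids[[f]]
    !is.null(ids) && sub("^[^_]+_", "", id) %in% ids
  }, fam, features)
  if (any(bad))
    stop_pancrad(paste("unknown feature id(s):",
                       paste(features[bad], collapse = ", ")),
                 "pancrad_config_error")
  g <- expand.grid(feature = features, filter = filters,
                   stringsAsFactors = FALSE)[, c("filter", "feature")]
  g$family <- sub("_.*$", "", g$feature)
  g$name <- paste(g$filter, g$feature, sep = "_")
  if (anyDuplicated(g$name))
    stop_pancrad("duplicate feature names in manifest",
                 "pancrad_config_error")
  g[, c("filter", "family", "feature", "name")]
}

all_feature_ids <- function() {
  unlist(lapply(names(.family_ids), function(f)
    paste(f, .family_ids[[f]], sep = "_")), use.names = FALSE)
}

#' Default manifests for the 3D and 2D branches
#'
#' The 3D manifest covers the original image, a 3 mm Laplacian-of-Gaussian
#' filter and all 8 single-level wavelet bands (290 features); the 2D patch
#' manifest covers the original image and the 4 in-plane wavelet bands
#' (145 features). Every feature family reported among the top-ranked
#' features of both branch models (first-order, GLCM, GLRLM, GLSZM, GLDM,
#' NGTDM) is included under every filter.
#'
#' @return A manifest data.frame (see [feature_manifest()]).
#' @export
default_manifest_3d <- function() {
  feature_manifest(
    filters = c("original", "log-sigma-3-mm",
                paste0("wavelet-", c("LLL", "HLL", "LHL", "HHL",
                                     "LLH", "HLH", "LHH", "HHH"))),
    features = all_feature_ids())
}

#' @rdname default_manifest_3d
#' @export
default_manifest_2d <- function() {
  feature_manifest(
    filters = c("original", paste0("wavelet-", c("LL", "HL", "LH", "HH"))),
    features = all_feature_ids())
}

# Precompiled extraction plan: per-filter groupings of manifest rows with
# target column indices, so the per-region kernel does no data.frame work.
manifest_plan <- function(manifest) {
  lapply(unique(manifest$filter), function(f) {
    rows <- which(manifest$filter == f)
    sub <- manifest[rows, ]
    fo <- sub$family == "firstorder"
    fams <- lapply(setdiff(unique(sub$family), "firstorder"), function(fam) {
      sel <- sub$family == fam
      list(fam = fam,
           ids = sub(paste0("^", fam, "_"), "", sub$feature[sel]),
           cols = rows[sel],
           fn = switch(fam, glcm = glcm_features, glrlm = glrlm_features,
                       glszm = glszm_features, gldm = gldm_features,
                       ngtdm = ngtdm_features))
    })
    list(filter = f,
         fo_ids = sub("^firstorder_", "", sub$feature[fo]),
         fo_cols = rows[fo], fams = fams)
  })
}

# Kernel shared by the 3D path and the per-patch hot path: images is a
# named list of arrays (one per filter), inside the ROI voxel indices.
extract_kernel <- function(images, inside, dims, plan, n_out, bin_width,
                           threeD) {
  out <- numeric(n_out)
  for (entry in plan) {
    vals <- images[[entry$filter]][inside]
    if (length(entry$fo_cols))
      out[entry$fo_cols] <- first_order_features(vals, bin_width,
                                                 ids = entry$fo_ids)
    if (length(entry$fams)) {
      idxarr <- integer(prod(dims))
      idx <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
      idxarr[inside] <- idx
      dim(idxarr) <- dims
      nlev <- max(idx)
      n_vox <- length(inside)
      for (fm in entry$fams) {
        m <- switch(fm$fam,
          glcm = cpp_glcm(idxarr, dims, nlev, threeD),
          glrlm = cpp_glrlm(idxarr, dims, nlev, threeD),
          glszm = cpp_glszm(idxarr, dims, nlev, threeD),
          gldm = cpp_gldm(idxarr, dims, nlev, 0L, threeD),
          ngtdm = cpp_ngtdm(idxarr, dims, nlev, threeD))
        tm <- list(family = fm$fam, matrix = m, n_levels = nlev,
                   n_voxels = n_vox)
        out[fm$cols] <- fm$fn(tm, ids = fm$ids)
      }
    }
  }
  out
}

# Fallback vector for an empty/degenerate region (documented conventions).
degenerate_vector <- function(manifest) {
  out <- stats::setNames(rep(0, nrow(manifest)), manifest$name)
  out[manifest$feature == "glcm_correlation"] <- 1
  out[manifest$feature == "ngtdm_coarseness"] <- 1e6
  attr(out, "degenerate") <- TRUE
  out
}

# Compute all manifest features for one region given precomputed filtered
# images (named list filter id -> array/matrix, all sharing the ROI grid).
extract_from_images <- function(images, roi, manifest, bin_width = 16,
                                dimensionality = c("3d", "2d")) {
  dimensionality <- match.arg(dimensionality)
  roi3 <- as_array3(roi) > 0
  inside <- which(roi3)
  if (length(inside) == 0) return(degenerate_vector(manifest))
  images <- lapply(images, as_array3)
  v <- extract_kernel(images, inside, as.integer(dim(roi3)),
                      manifest_plan(manifest), nrow(manifest), bin_width,
                      threeD = dimensionality == "3d")
  out <- stats::setNames(v, manifest$name)
  attr(out, "degenerate") <- length(inside) < 2
  out
}

# Filtered images for every unique filter in a manifest (wavelet bands are
# decomposed once and shared across band ids).
filter_image_set <- function(x, filters, spacing = c(1, 1, 5)) {
  bands <- if (any(startsWith(filters, "wavelet-"))) wavelet_bands(x) else NULL
  out <- list()
  for (f in filters)
    out[[f]] <- apply_filter(x, f, spacing = spacing, bands_cache = bands)
  out
}

#' Extract a radiomic feature vector from a volume of interest
#'
#' Computes every manifest feature over the union of pancreas and tumor
#' voxels (`mode = "3d"`, the whole-pancreas branch) or over an arbitrary
#' binary ROI. Inputs are expected on the canonical resampled grid. A region
#' of fewer than 2 voxels yields the documented fallback values and sets the
#' `"degenerate"` attribute.
#'
#' @param volume a [ct_volume] on the analysis grid.
#' @param roi a [label_mask]; any nonzero label is part of the region.
#' @param mode `"3d"` for volumetric neighborhoods.
#' @param manifest a manifest data.frame; default [default_manifest_3d()].
#' @param bin_width texture discretization width in HU (default 16).
#' @return Named numeric vector, one finite value per manifest row, in
#'   manifest order.
#' @export
extract_feature_vector <- function(volume, roi, mode = "3d",
                                   manifest = default_manifest_3d(),
                                   bin_width = 16) {
  stopifnot(inherits(volume, "ct_volume"), inherits(roi, "label_mask"))
  stopifnot(identical(dim(volume$voxels), dim(roi$labels)))
  mode <- match.arg(mode, c("3d", "2d"))
  imgs <- filter_image_set(volume$voxels, unique(manifest$filter),
                           spacing = volume$spacing)
  extract_from_images(imgs, roi$labels > 0, manifest, bin_width,
                      dimensionality = if (mode == "3d") "3d" else "2d")
}

#' Per-patch 2D feature matrix for one study
#'
#' Filters each axial slice once, then crops the stride-lattice windows and
#' computes the 2D manifest features over each patch's ROI pixels.
#'
#' @param volume a [ct_volume] on the analysis grid.
#' @param mask the paired [label_mask] (unused beyond grid checks; the ROI
#'   comes from the patch set).
#' @param patchset a `patch_set` from [generate_patches()].
#' @param manifest 2D feature manifest; default [default_manifest_2d()].
#' @param bin_width texture bin width in HU.
#' @return Numeric matrix, one row per patch in patch-set order.
#' @export
study_patch_features <- function(volume, mask, patchset,
                                 manifest = default_manifest_2d(),
                                 bin_width = 16) {
  stopifnot(inherits(volume, "ct_volume"))
  p <- patchset$patches
  ps <- patchset$patch_size
  out <- matrix(NA_real_, nrow = nrow(p), ncol = nrow(manifest),
                dimnames = list(NULL, manifest$name))
  if (nrow(p) == 0) return(out)
  roi_arr <- patchset_roi(patchset)
  filters <- unique(manifest$filter)
  plan <- manifest_plan(manifest)
  n_out <- nrow(manifest)
  dims <- c(ps, ps, 1L)
  slice_v <- p$slice
  x0 <- p$x0
  y0 <- p$y0
  for (z in unique(slice_v)) {
    sl <- volume$voxels[, , z + 1]
    imgs <- filter_image_set(sl, filters, spacing = volume$spacing[1:2])
    roi_sl <- roi_arr[, , z + 1]
    for (r in which(slice_v == z)) {
      xs <- x0[r] + seq_len(ps)
      ys <- y0[r] + seq_len(ps)
      inside <- which(roi_sl[xs, ys])
      win_imgs <- lapply(imgs, function(im) im[xs, ys])
      out[r, ] <- if (length(inside) == 0) degenerate_vector(manifest) else
        extract_kernel(win_imgs, inside, dims, plan, n_out, bin_width,
                       threeD = FALSE)
    }
  }
  out
}
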