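# Heatmap aggregation of patch probabilities and the high-risk-region area
# statistic. Each heatmap pixel is the arithmetic mean of the predicted
# probabilities of every valid patch whose window contains it; pixels
# covered by no patch are undefined and never join a high-risk region.
# The area statistic binarizes covered pixels at a strict > t threshold and
# takes the largest connected component within any single axial plane
# (8-connectivity, no cross-slice links by default), in mm^2 on the
# resampled grid (1 mm^2 per pixel at 1 x 1 mm in-plane spacing).

#' Aggregate scored patches into a per-slice heatmap
#'
#' @param patchset a `patch_set` whose `patches` carry a `probability`
#'   column in \[0, 1\] for every patch.
#' @return A `heatmap` object: 3D arrays `values` (NA where uncovered) and
#'   `coverage` (contributing patch count per pixel), plus `pixel_area_mm2`.
#' @export
build_heatmap <- function(patchset) {
  stopifnot(inherits(patchset, "patch_set"))
  p <- patchset$patches
  if (is.null(p$probability) || anyNA(p$probability))
    stop_pancrad("all valid patches must be scored before aggregation",
                 "pancrad_state_error")
  d <- patchset$dim
  acc <- array(0, dim = d)
  cov <- array(0L, dim = d)
  w <- patchset$patch_size
  for (r in seq_len(nrow(p))) {
    xs <- p$x0[r] + seq_len(w)
    ys <- p$y0[r] + seq_len(w)
    z <- p$slice[r] + 1L
    acc[xs, ys, z] <- acc[xs, ys, z] + p$probability[r]
    cov[xs, ys, z] <- cov[xs, ys, z] + 1L
  }
  vals <- acc / ifelse(cov > 0, cov, NA_integer_)
  structure(list(values = vals, coverage = cov,
                 pixel_area_mm2 = prod(patchset$spacing[1:2]),
                 study_id = patchset$study_id),
            class = "heatmap")
}

#' Area of the largest contiguous high-risk region
#'
#' Covered heatmap pixels with value strictly above the threshold are
#' high-risk; connected components are found within each axial plane
#' (8-connectivity; no linking across slices) and the largest component's
#' pixel count times the in-plane pixel area is returned. `connectivity =
#' "3d26"` switches to volumetric 26-connected regions.
#'
#' @param heatmap a `heatmap` from [build_heatmap()].
#' @param threshold pixel threshold t in \[0, 1\]; strict `> t`.
#' @param connectivity `"2d8"` (default), `"2d4"` or `"3d26"`.
#' @return A list: `threshold`, `area_mm2`, `n_pixels`, `slice` (0-based
#'   slice of the largest region, NA if none) and `pixels` (their linear
#'   indices in the heatmap array).
#' @export
largest_high_risk_area <- function(heatmap, threshold,
                                   connectivity = c("2d8", "2d4", "3d26")) {
  stopifnot(inherits(heatmap, "heatmap"),
            threshold >= 0, threshold <= 1)
  connectivity <- match.arg(connectivity)
  hot <- !is.na(heatmap$values) & heatmap$values > threshold
  if (!any(hot))
    return(list(threshold = threshold, area_mm2 = 0, n_pixels = 0L,
                slice = NA_integer_, pixels = integer(0)))
  lab <- cpp_label_components(as.logical(hot), as.integer(dim(hot)),
                              connectivity)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  pix <- which(lab == best)
  z0 <- (pix[1] - 1) %/% prod(dim(hot)[1:2])
  list(threshold = threshold,
       area_mm2 = sizes[best] * heatmap$pixel_area_mm2,
       n_pixels = sizes[best],
       slice = as.integer(z0),
       pixels = pix)
}

#' Search the high-risk pixel threshold on a validation cohort
#'
#' For every threshold on the grid 0.05, 0.06, ..., 0.95 (91 points), the
#' largest high-risk area of every study is computed and the AUC of area
#' versus case/control label recorded; the selected threshold attains the
#' maximum AUC (ties broken toward the smallest threshold).
#'
#' @param heatmaps list of `heatmap` objects, one per study.
#' @param labels binary study labels (1 = cancer) aligned with `heatmaps`.
#' @param connectivity passed to [largest_high_risk_area()].
#' @return A list: `threshold` (selected), `auc` (at the selection), `grid`
#'   (data.frame `threshold`, `auc`) and `areas` (study areas at the
#'   selected threshold).
#' @export
search_area_threshold <- function(heatmaps, labels,
                                  connectivity = "2d8") {
  y <- as_label01(labels)
  if (length(unique(y)) < 2)
    stop_pancrad("both classes are required for the threshold search",
                 "pancrad_input_error")
  stopifnot(length(heatmaps) == length(y))
  grid <- 0.05 + (0:90) * 0.01
  area_mat <- vapply(heatmaps, function(h) {
    vapply(grid, function(t)
      largest_high_risk_area(h, t, connectivity)$area_mm2, 0)
  }, numeric(length(grid)))
  aucs <- apply(area_mat, 1, function(a) auc_mw(a, y))
  best <- which.max(aucs)  # which.max takes the first (smallest t) on ties
  list(threshold = grid[best], auc = aucs[best],
       grid = data.frame(threshold = grid, auc = aucs),
       areas = area_mat[best, ])
}

#' Export a heatmap as a NIfTI probability volume
#'
#' Uncovered pixels are written as 0 so overlays render cleanly.
#'
#' @param heatmap a `heatmap`.
#' @param path output path; spacing metadata is not carried by this export.
#' @export
write_heatmap <- function(heatmap, path) {
  v <- heatmap$values
  v[is.na(v)] <- 0
  img <- RNifti::asNifti(v)
  RNifti::writeNifti(img, path)
  invisible(path)
}
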