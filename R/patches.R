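# Patch generation over the ROI: 20 x 20 pixel windows on a stride-5
# lattice over each axial slice. Windows use 0-based, half-open coordinates:
# the window at (x0, y0) covers pixels x0..x0+19, y0..y0+19. A window is a
# valid patch when strictly more than 5% of its 400 pixels (i.e. > 20
# pixels) overlap the ROI. The final lattice row/column is included flush
# with the slice border even when not stride-aligned, so ROI near the edge
# stays covered.

# 2D summed-area table; S[i+1, j+1] = sum of m[1..i, 1..j]
integral_image <- function(m) {
  s <- rbind(0, apply(m, 2, cumsum))
  cbind(0, t(apply(s, 1, cumsum)))
}

window_sums <- function(S, x0, y0, w) {
  S[cbind(x0 + w + 1, y0 + w + 1)] - S[cbind(x0 + 1, y0 + w + 1)] -
    S[cbind(x0 + w + 1, y0 + 1)] + S[cbind(x0 + 1, y0 + 1)]
}

lattice_starts <- function(n, w, stride) {
  if (n < w) return(integer(0))
  s <- seq(0L, n - w, by = stride)
  if (s[length(s)] != n - w) s <- c(s, n - w)  # flush-edge window
  s
}

#' Generate valid patches over a region of interest
#'
#' Enumerates all stride-lattice windows on every axial slice and keeps
#' those whose ROI overlap strictly exceeds `min_overlap_frac` of the window
#' area. Patches are ordered deterministically by (slice, y0, x0). An empty
#' ROI yields an empty patch set.
#'
#' @param roi a [label_mask]; any nonzero label counts as ROI (tumor pixels
#'   are part of the ROI).
#' @param patch_size window side in pixels (default 20).
#' @param stride lattice stride in pixels (default 5).
#' @param min_overlap_frac validity threshold as a fraction of window area
#'   (default 0.05; strict inequality).
#' @param study_id optional id carried through to tabular exports.
#' @return A `patch_set`: list with `patches` (data.frame `slice`, `x0`,
#'   `y0`, `roi_pixels`, plus `label`/`probability` once assigned), grid
#'   metadata and the binary ROI array for heatmap reconstruction.
#' @export
generate_patches <- function(roi, patch_size = 20L, stride = 5L,
                             min_overlap_frac = 0.05, study_id = NULL) {
  stopifnot(inherits(roi, "label_mask"))
  arr <- roi$labels > 0L
  d <- dim(arr)
  thr <- min_overlap_frac * patch_size^2
  xs <- lattice_starts(d[1], patch_size, stride)
  ys <- lattice_starts(d[2], patch_size, stride)
  res <- list()
  for (z in seq_len(d[3])) {
    sl <- arr[, , z]
    if (!any(sl)) next
    S <- integral_image(sl)
    grid <- expand.grid(x0 = xs, y0 = ys)     # varies x fastest
    ov <- window_sums(S, grid$x0, grid$y0, patch_size)
    keep <- ov > thr                           # strictly more than 5%
    if (!any(keep)) next
    g <- grid[keep, , drop = FALSE]
    ov_k <- ov[keep]
    ord <- order(g$y0, g$x0)                   # deterministic (slice, y, x)
    res[[length(res) + 1]] <- data.frame(slice = z - 1L, x0 = g$x0[ord],
                                         y0 = g$y0[ord],
                                         roi_pixels = ov_k[ord])
  }
  patches <- if (length(res)) do.call(rbind, res) else
    data.frame(slice = integer(0), x0 = integer(0), y0 = integer(0),
               roi_pixels = numeric(0))
  out <- structure(list(patches = patches, dim = d, spacing = roi$spacing,
                        patch_size = as.integer(patch_size),
                        stride = as.integer(stride),
                        study_id = study_id),
                   class = "patch_set")
  attr(out, "roi_arr") <- arr
  out
}

patchset_roi <- function(patchset) {
  attr(patchset, "roi_arr")
}

#' @exportS3Method base::print
print.patch_set <- function(x, ...) {
  cat("<patch_set> ", nrow(x$patches), " valid ", x$patch_size, "x",
      x$patch_size, " patches (stride ", x$stride, ") over ",
      length(unique(x$patches$slice)), " slices\n", sep = "")
  invisible(x)
}

#' Assign cancer labels to patches
#'
#' A patch is labeled `"cancerous"` when its window contains at least one
#' tumor pixel (label 2) — any portion of tumor suffices — and
#' `"non-cancerous"` otherwise. Used at training time only.
#'
#' @param patchset a `patch_set` from [generate_patches()].
#' @param mask the [label_mask] with tumor labels on the same grid.
#' @return The patch set with a `label` column filled in.
#' @export
label_patches <- function(patchset, mask) {
  stopifnot(inherits(patchset, "patch_set"), inherits(mask, "label_mask"))
  stopifnot(identical(dim(mask$labels), patchset$dim))
  p <- patchset$patches
  if (nrow(p) == 0) {
    patchset$patches$label <- character(0)
    return(patchset)
  }
  lab <- character(nrow(p))
  w <- patchset$patch_size
  for (z in unique(p$slice)) {
    tum <- mask$labels[, , z + 1] == 2L
    S <- integral_image(tum)
    rows <- which(p$slice == z)
    cnt <- window_sums(S, p$x0[rows], p$y0[rows], w)
    lab[rows] <- ifelse(cnt >= 1, "cancerous", "non-cancerous")
  }
  patchset$patches$label <- lab
  patchset
}

#' Tabular export of a patch set
#'
#' @param patchset a `patch_set`.
#' @return data.frame with `study_id`, `slice`, `x0`, `y0`, `roi_pixels`,
#'   and `label`/`probability` when present.
#' @export
patch_table <- function(patchset) {
  p <- patchset$patches
  cbind(study_id = patchset$study_id %||% NA_character_, p)
}
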