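#' Fixed-bin-width gray-level discretization
#'
#' Intensities inside a region are mapped to gray-level indices with a fixed
#' bin width anchored at the region minimum:
#' `index = floor((v - min) / bin_width) + 1`. The texture bin width for the
#' whole pipeline is fixed at 16 HU.
#'
#' @param values numeric vector of region intensities.
#' @param bin_width bin width in intensity units (> 0); default 16.
#' @param minimum anchor; defaults to `min(values)`.
#' @return Integer vector of gray-level indices >= 1. The attribute
#'   `"n_levels"` holds the number of gray levels (the maximum index).
#' @export
discretize <- function(values, bin_width = 16, minimum = NULL) {
  if (length(values) == 0)
    stop_pancrad("empty region", "pancrad_empty_roi_error")
  stopifnot(bin_width > 0)
  minimum <- minimum %||% min(values)
  idx <- as.integer(floor((values - minimum) / bin_width)) + 1L
  idx[idx < 1L] <- 1L
  attr(idx, "n_levels") <- max(idx)
  idx
}

# Discretize an image over a binary ROI, returning an integer array with 0
# outside the ROI and indices 1..n_levels inside (the form the texture
# matrix builders consume).
discretize_region <- function(arr, roi, bin_width = 16) {
  arr <- as_array3(arr)
  roi <- as_array3(roi)
  inside <- which(roi > 0)
  idx <- discretize(arr[inside], bin_width)
  out <- array(0L, dim = dim(arr))
  out[inside] <- as.integer(idx)
  attr(out, "n_levels") <- attr(idx, "n_levels")
  out
}
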