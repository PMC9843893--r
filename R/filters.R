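# Image filters used before feature extraction: single-level undecimated
# (stationary) coif1 wavelet decomposition and Laplacian-of-Gaussian with
# sigma in physical mm. Filters run on full slices/volumes; the ROI is
# applied afterwards during discretization.

# coif1 analysis lowpass filter (DC gain sqrt(2), the convention of the
# usual radiomics platforms); highpass is its quadrature mirror.
.coif1_dec_lo <- c(-0.01565572813546454, -0.0727326195128539,
                   0.38486484686420286, 0.8525720202122554,
                   0.33789766245780922, -0.07273261951285399)
.coif1_dec_hi <- (-1)^(0:5) * rev(.coif1_dec_lo)
.coif1_rec_lo <- rev(.coif1_dec_lo)

# Convolve along the first axis of a 3D array with symmetric (reflect)
# boundary handling, output length = input length. Vectorized over the
# remaining axes; the kernel center is at ceiling(k/2).
convolve_axis1 <- function(arr, kernel, center = (length(kernel) + 1L) %/% 2L) {
  d <- dim(arr)
  n <- d[1]
  k <- length(kernel)
  c0 <- center
  pad_l <- c0 - 1L
  pad_r <- k - c0
  idx <- c(rev(seq_len(min(pad_l, n))), seq_len(n),
           n + 1L - rev(seq_len(min(pad_r, n))))
  # if the pad exceeds n (tiny inputs), keep reflecting
  while (length(idx) < n + pad_l + pad_r)
    idx <- c(idx[1], idx, idx[length(idx)])
  m <- matrix(arr, nrow = n)[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_len(k))
    out <- out + kernel[j] * m[j:(j + n - 1L), , drop = FALSE]
  array(out, dim = d)
}

convolve_axis <- function(arr, kernel, axis,
                          center = (length(kernel) + 1L) %/% 2L) {
  if (axis == 1) return(convolve_axis1(arr, kernel, center))
  perm <- switch(axis, NULL, c(2, 1, 3), c(3, 2, 1))
  aperm(convolve_axis1(aperm(arr, perm), kernel, center), perm)
}

as_array3 <- function(x) {
  x <- as.array(x)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x
}

#' Undecimated single-level wavelet decomposition
#'
#' Decomposes an image into all lowpass/highpass sub-band combinations of a
#' single-level stationary coif1 transform: 4 bands (`LL`, `HL`, `LH`, `HH`)
#' for a 2D slice, 8 bands (`LLL` ... `HHH`) for a 3D volume. Band letters
#' apply to the (x, y, z) axes in order, so `HL` is highpass along x and
#' lowpass along y. Outputs keep the input resolution.
#'
#' @param x a matrix (2D) or 3D array.
#' @return Named list of arrays shaped like `x`.
#' @export
wavelet_bands <- function(x) {
  two_d <- length(dim(as.array(x))) == 2
  arr <- as_array3(x)
  if (any(dim(arr)[1:2] < 2))
    stop_pancrad("image smaller than the wavelet filter support",
                 "pancrad_filter_error")
  naxes <- if (two_d) 2 else 3
  combos <- expand.grid(rep(list(c("L", "H")), naxes),
                        stringsAsFactors = FALSE)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    band <- arr
    for (ax in seq_len(naxes)) {
      kern <- if (combos[r, ax] == "L") .coif1_dec_lo else .coif1_dec_hi
      band <- convolve_axis(band, kern, ax)
    }
    nm <- paste0(unlist(combos[r, ]), collapse = "")
    out[[nm]] <- if (two_d) band[, , 1] else band
  }
  out  # expand.grid order: LL, HL, LH, HH (and LLL ... HHH in 3D)
}

# Approximate inverse restricted to the all-lowpass band: used to check that
# the decomposition preserves smooth content (detail bands near zero).
wavelet_reconstruct_ll <- function(ll) {
  two_d <- length(dim(as.array(ll))) == 2
  arr <- as_array3(ll)
  naxes <- if (two_d) 2 else 3
  # even-tap kernels shift by half a sample per pass; centering the
  # synthesis pass one tap later cancels the analysis-pass bias
  for (ax in seq_len(naxes))
    arr <- convolve_axis(arr, .coif1_rec_lo, ax,
                         center = length(.coif1_rec_lo) %/% 2L + 1L) / 2
  if (two_d) arr[, , 1] else arr
}

#' Laplacian-of-Gaussian filter with physical sigma
#'
#' Convolves the image with the sampled analytic LoG kernel, implemented as
#' the separable sum of one second-derivative Gaussian per axis. The kernel
#' is sampled at the voxel spacing and normalized by the voxel measure so
#' sigma is in mm regardless of grid resolution; support is truncated at
#' 4 sigma. Boundary handling is symmetric reflection.
#'
#' @param x matrix (2D) or 3D array.
#' @param sigma_mm Gaussian scale in mm (> 0).
#' @param spacing voxel spacing in mm per axis (length 2 or 3 to match `x`).
#' @return Filtered array shaped like `x`.
#' @export
log_filter <- function(x, sigma_mm, spacing = c(1, 1, 5)) {
  stopifnot(sigma_mm > 0)
  two_d <- length(dim(as.array(x))) == 2
  arr <- as_array3(x)
  naxes <- if (two_d) 2 else 3
  spacing <- spacing[seq_len(naxes)]
  g <- list()
  g2 <- list()
  for (ax in seq_len(naxes)) {
    h <- spacing[ax]
    r <- max(1L, ceiling(4 * sigma_mm / h))
    t <- (-r:r) * h
    gauss <- exp(-t^2 / (2 * sigma_mm^2)) / (sigma_mm * sqrt(2 * pi))
    g[[ax]] <- gauss * h
    g2[[ax]] <- gauss * (t^2 - sigma_mm^2) / sigma_mm^4 * h
    if (dim(arr)[ax] < 2)
      stop_pancrad("image smaller than the LoG kernel support",
                   "pancrad_filter_error")
  }
  out <- array(0, dim = dim(arr))
  for (term in seq_len(naxes)) {
    part <- arr
    for (ax in seq_len(naxes)) {
      kern <- if (ax == term) g2[[ax]] else g[[ax]]
      part <- convolve_axis(part, kern, ax)
    }
    out <- out + part
  }
  if (two_d) out[, , 1] else out
}

# Evaluate the analytic (continuous) LoG kernel at physical offsets; the
# impulse response of log_filter equals this times the voxel measure.
log_kernel_analytic <- function(coords_mm, sigma_mm) {
  coords_mm <- as.matrix(coords_mm)
  d <- ncol(coords_mm)
  r2 <- rowSums(coords_mm^2)
  gauss <- exp(-r2 / (2 * sigma_mm^2)) / (sigma_mm * sqrt(2 * pi))^d
  gauss * (r2 - d * sigma_mm^2) / sigma_mm^4
}

# Resolve a filter id string into the corresponding filtered image.
# Supported ids: "original", "wavelet-<band>", "log-sigma-<s>-mm".
apply_filter <- function(x, filter_id, spacing = c(1, 1, 5),
                         bands_cache = NULL) {
  if (filter_id == "original") return(x)
  if (startsWith(filter_id, "wavelet-")) {
    band <- sub("^wavelet-", "", filter_id)
    bands <- bands_cache %||% wavelet_bands(x)
    if (is.null(bands[[band]]))
      stop_pancrad(paste("unknown wavelet band", band),
                   "pancrad_config_error")
    return(bands[[band]])
  }
  if (grepl("^log-sigma-[0-9.]+-mm$", filter_id)) {
    sigma <- as.numeric(sub("^log-sigma-([0-9.]+)-mm$", "\\1", filter_id))
    return(log_filter(x, sigma, spacing))
  }
  stop_pancrad(paste("unknown filter id", filter_id), "pancrad_config_error")
}
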