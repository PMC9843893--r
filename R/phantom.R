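# Seeded synthetic CT cohorts. Each study is a pancreas-like ellipsoid with
# a smoothly deformed boundary in a soft-tissue background; tumors are
# hypodense (lower median HU) and texturally busier (extra high-frequency
# noise) than the surrounding gland, matching the typical CT appearance of
# pancreatic adenocarcinoma. Texture is a Gaussian-smoothed random field
# (correlation length ~3 mm) with per-region variance scaling; HU values
# are quantized to integers as CT storage does.

#' Phantom cohort specification
#'
#' Defaults describe the study conditions used throughout the package's
#' experiments: portal-venous-like pancreas parenchyma around 100 HU with
#' 12 HU smoothly correlated texture (5 mm correlation length) plus 1 HU
#' voxel-scale scanner noise, tumors shifted -25 HU (hypodense) with a 5x
#' multiplier on the voxel-scale noise (heterogeneous, busier texture),
#' tumor diameters drawn log-normally around 2.5 cm (clamped to 8-45 mm)
#' and stratified at the < 2 / 2-4 / > 4 cm clinical cuts.
#'
#' @param n_cases,n_controls cohort composition.
#' @param shape volume dimensions in voxels (x, y, z).
#' @param spacing voxel spacing in mm; the canonical grid by default.
#' @param pancreas_axes_mm ellipsoid semi-axes of the gland in mm.
#' @param base_hu mean parenchyma attenuation (HU).
#' @param background_hu mean surrounding-tissue attenuation (HU).
#' @param texture_sd HU standard deviation of the correlated texture field.
#' @param correlation_mm texture correlation length (Gaussian sigma, mm).
#' @param tumor_shift_hu additive median HU shift of tumor voxels (< 0:
#'   hypodense).
#' @param fine_noise_sd HU standard deviation of voxel-scale (scanner)
#'   noise present everywhere.
#' @param tumor_heterogeneity multiplier (> 1) on the voxel-scale noise
#'   standard deviation inside the tumor; drives the busier tumor texture.
#' @param diameter_meanlog,diameter_sdlog log-normal tumor diameter draw
#'   (mm).
#' @param diameter_range_mm clamp for the drawn diameter.
#' @param seed root seed; every study derives its own stream from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_cases = 75L, n_controls = 75L,
                         shape = c(84L, 56L, 10L), spacing = c(1, 1, 5),
                         pancreas_axes_mm = c(32, 14, 11),
                         base_hu = 100, background_hu = -30,
                         texture_sd = 12, correlation_mm = 5,
                         tumor_shift_hu = -25, fine_noise_sd = 1,
                         tumor_heterogeneity = 5,
                         diameter_meanlog = log(25), diameter_sdlog = 0.45,
                         diameter_range_mm = c(8, 45), seed = 20230117L) {
  stopifnot(tumor_heterogeneity > 1, tumor_shift_hu < 0,
            all(pancreas_axes_mm > 0), all(spacing > 0))
  if (diameter_range_mm[2] > 2 * max(pancreas_axes_mm))
    stop_pancrad("tumor diameter range exceeds the pancreas",
                 "pancrad_spec_error")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 shape = as.integer(shape), spacing = as.numeric(spacing),
                 pancreas_axes_mm = pancreas_axes_mm, base_hu = base_hu,
                 background_hu = background_hu, texture_sd = texture_sd,
                 correlation_mm = correlation_mm,
                 tumor_shift_hu = tumor_shift_hu,
                 fine_noise_sd = fine_noise_sd,
                 tumor_heterogeneity = tumor_heterogeneity,
                 diameter_meanlog = diameter_meanlog,
                 diameter_sdlog = diameter_sdlog,
                 diameter_range_mm = diameter_range_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian smoothing of white noise, renormalized to unit sd
smoothed_field <- function(shape, spacing, sigma_mm) {
  f <- array(rnorm(prod(shape)), dim = shape)
  for (ax in 1:3) {
    h <- spacing[ax]
    r <- max(1L, ceiling(3 * sigma_mm / h))
    t <- (-r:r) * h
    k <- exp(-t^2 / (2 * sigma_mm^2))
    f <- convolve_axis(f, k / sum(k), ax)
  }
  f / sd(f)
}

size_stratum <- function(diameter_mm) {
  cut(diameter_mm, breaks = c(-Inf, 20, 40, Inf),
      labels = c("<2cm", "2-4cm", ">4cm"))
}

#' Generate one phantom study
#'
#' @param spec a [phantom_spec()].
#' @param case logical; draw a tumor?
#' @param seed integer stream for this study.
#' @return list: `volume` ([ct_volume]), `mask` ([label_mask]), `case`,
#'   `tumor_diameter_mm` (NA for controls), `stratum`.
#' @export
generate_phantom_study <- function(spec, case, seed) {
  set.seed(seed)
  d <- spec$shape
  sp <- spec$spacing
  # physical voxel-center coordinates, gland centered with mild jitter
  ctr <- (d - 1) / 2 * sp + rnorm(3, sd = c(2, 2, 1))
  ax <- spec$pancreas_axes_mm * runif(3, 0.9, 1.1)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  dist2 <- outer(outer(((xs - ctr[1]) / ax[1])^2,
                       ((ys - ctr[2]) / ax[2])^2, `+`),
                 ((zs - ctr[3]) / ax[3])^2, `+`)
  # smooth boundary deformation so the gland is not a perfect ellipsoid
  deform <- smoothed_field(d, sp, 3 * spec$correlation_mm) * 0.08
  pancreas <- dist2 <= (1 + deform)^2
  labels <- array(0L, dim = d)
  labels[pancreas] <- 1L
  # all gland/background fields are drawn before any tumor-specific draw,
  # so a case and a control generated from the same seed share the gland
  # exactly and differ only by the inserted tumor
  tex <- smoothed_field(d, sp, spec$correlation_mm) * spec$texture_sd
  vox <- array(spec$background_hu, dim = d) +
    smoothed_field(d, sp, 2 * spec$correlation_mm) * 15
  vox[pancreas] <- spec$base_hu + tex[pancreas]
  vox <- vox + array(rnorm(prod(d)), dim = d) * spec$fine_noise_sd
  diameter <- NA_real_
  if (case) {
    diameter <- min(max(rlnorm(1, spec$diameter_meanlog,
                               spec$diameter_sdlog),
                        spec$diameter_range_mm[1]),
                    spec$diameter_range_mm[2])
    # center drawn inside the eroded gland core so small tumors sit
    # strictly interior; large ones are clipped by the gland boundary
    core <- which(dist2 <= 0.5^2 & pancreas)
    if (length(core) == 0) core <- which(pancreas)
    cidx <- arrayInd(core[sample.int(length(core), 1)], d)
    cpos <- (as.numeric(cidx) - 1) * sp
    r_mm <- diameter / 2
    td2 <- outer(outer((xs - cpos[1])^2, (ys - cpos[2])^2, `+`),
                 (zs - cpos[3])^2, `+`)
    tumor <- td2 <= r_mm^2 & pancreas   # tumor stays a subset of the gland
    labels[tumor] <- 2L
    if (any(tumor)) {
      # extra voxel-scale noise raises the tumor fine-noise sd to
      # fine_noise_sd * tumor_heterogeneity (variances add)
      hf <- array(rnorm(prod(d)), dim = d) * spec$fine_noise_sd *
        sqrt(spec$tumor_heterogeneity^2 - 1)
      vox[tumor] <- vox[tumor] + spec$tumor_shift_hu + hf[tumor]
    }
  }
  vox <- round(vox)  # CT stores integer HU
  list(volume = ct_volume(vox, sp), mask = label_mask(labels, sp),
       case = case, tumor_diameter_mm = diameter,
       stratum = if (case) as.character(size_stratum(diameter))
                 else NA_character_)
}

#' Generate a seeded phantom cohort
#'
#' Deterministic given the spec seed: study k always draws from the same
#' derived stream regardless of cohort composition. Cases come first in the
#' returned list. Optionally writes NIfTI volume/mask pairs and a cohort
#' manifest CSV.
#'
#' @param spec a [phantom_spec()].
#' @param dir optional output directory for NIfTI pairs + `manifest.csv`.
#' @return A `phantom_cohort`: list of studies (see
#'   [generate_phantom_study()]) with a `manifest` data.frame attribute
#'   (`study_id`, `label`, `tumor_diameter_mm`, `stratum`, `seed`).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  n <- spec$n_cases + spec$n_controls
  is_case <- c(rep(TRUE, spec$n_cases), rep(FALSE, spec$n_controls))
  studies <- vector("list", n)
  man <- data.frame(study_id = sprintf("study%03d", seq_len(n)),
                    label = as.integer(is_case),
                    tumor_diameter_mm = rep(NA_real_, n),
                    stratum = rep(NA_character_, n),
                    seed = vapply(seq_len(n), function(k)
                      derive_seed(spec$seed, k), 0L))
  for (k in seq_len(n)) {
    st <- generate_phantom_study(spec, is_case[k], man$seed[k])
    man$tumor_diameter_mm[k] <- st$tumor_diameter_mm
    man$stratum[k] <- st$stratum
    studies[[k]] <- st
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n)) {
      write_volume(studies[[k]]$volume,
                   file.path(dir, paste0(man$study_id[k], "_ct.nii.gz")))
      write_volume(studies[[k]]$mask,
                   file.path(dir, paste0(man$study_id[k], "_mask.nii.gz")))
    }
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(studies = studies, manifest = man, spec = spec),
            class = "phantom_cohort")
}

#' @exportS3Method base::print
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", x$spec$n_cases, " cases / ", x$spec$n_controls,
      " controls, ", paste(x$spec$shape, collapse = "x"), " voxels at ",
      paste(x$spec$spacing, collapse = "x"), " mm\n", sep = "")
  invisible(x)
}
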