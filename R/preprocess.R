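#' Crop a spectra set to a wavelength window
#'
#' Keeps bands with `low <= wavelength <= high`, preserving order. Typical
#' use drops the noisy detector edges before modelling (e.g. cropping a
#' 348-1141 nm axis to 400-1100 nm).
#'
#' @param data A spectra set.
#' @param low,high Window bounds in nm, `low < high`.
#' @return A spectra set restricted to the window.
#' @export
crop_wavelengths <- function(data, low, high) {
  if (low >= high) abort("`low` must be below `high`.")
  wl <- wavelengths(data)
  keep <- wl >= low & wl <= high
  if (!any(keep)) {
    abort(sprintf("no bands inside [%g, %g] nm (axis spans %g-%g nm).",
                  low, high, min(wl), max(wl)))
  }
  m <- spectra_matrix(data)[, keep, drop = FALSE]
  spectra_set(m, wl[keep], spectra_labels(data), data$id)
}

#' Fit a multiplicative scatter correction reference
#'
#' The reference spectrum is the column mean of the training reflectance.
#' It is fitted on training data only and reused unchanged for the test set,
#' so no test information leaks into preprocessing.
#'
#' @param train A spectra set with at least two samples.
#' @return An `msc_reference` with fields `reference` and `wavelengths`.
#' @export
msc_fit <- function(train) {
  m <- spectra_matrix(train)
  if (nrow(m) < 2) abort("MSC needs >= 2 training samples for a meaningful reference.")
  structure(
    list(reference = colMeans(m), wavelengths = wavelengths(train)),
    class = "msc_reference"
  )
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum x is regressed on the reference by ordinary least squares,
#' `x = a + b * ref`, and replaced by `(x - a) / b`. This removes per-sample
#' additive offsets and multiplicative scaling exactly; for a purely affine
#' distortion of the reference the correction recovers the reference to
#' machine precision. Spectra whose slope magnitude falls below `tol`
#' (essentially flat spectra) are passed through unchanged with a warning.
#'
#' @param data A spectra set on the same band axis as `ref`.
#' @param ref An [msc_fit()] reference.
#' @param tol Minimum absolute slope; below it a spectrum is left uncorrected.
#' @return A corrected spectra set.
#' @export
msc_apply <- function(data, ref, tol = 1e-8) {
  stopifnot(inherits(ref, "msc_reference"))
  wl <- wavelengths(data)
  if (length(wl) != length(ref$wavelengths) ||
      max(abs(wl - ref$wavelengths)) > 1e-6) {
    abort("band axes of `data` and `ref` do not match.")
  }
  m <- spectra_matrix(data)
  r <- ref$reference
  rc <- r - mean(r)
  denom <- sum(rc^2)
  # slope/intercept of x ~ a + b*ref for every row at once
  b <- as.numeric((m - rowMeans(m)) %*% rc) / denom
  a <- rowMeans(m) - b * mean(r)
  flat <- abs(b) < tol
  if (any(flat)) {
    warn(sprintf("%d spectra had |slope| < %g and were passed through uncorrected.",
                 sum(flat), tol))
  }
  b_safe <- ifelse(flat, 1, b)
  a_safe <- ifelse(flat, 0, a)
  corrected <- (m - a_safe) / b_safe
  spectra_set(corrected, wl, spectra_labels(data), data$id)
}
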