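#' Construct a spectra set
#'
#' A spectra set is a tibble with one row per sample: an `id` column (unique
#' sample identifiers), a `label` column (factor with levels `NM`, `SH`, `MD`
#' for normal, starch-head and mildewed fruit) and one reflectance column per
#' wavelength, named `R<wavelength>` with the wavelength in nm printed to two
#' decimals (e.g. `R400.00`). Because all spectral information lives in
#' ordinary columns, dplyr verbs apply directly.
#'
#' @param reflectance Numeric matrix, samples x bands, reflectance in (0, 1.2).
#' @param wavelengths Strictly increasing numeric vector of band centres (nm),
#'   one per reflectance column.
#' @param labels Character or factor of class labels (`NM`/`SH`/`MD`).
#' @param ids Unique sample identifiers; generated as `s0001...` when `NULL`.
#' @return A `spectra_set` tibble.
#' @export
#' @examples
#' s <- spectra_set(matrix(runif(8, 0.2, 0.8), 2), c(500, 600, 700, 800),
#'                  labels = c("NM", "MD"))
#' wavelengths(s)
spectra_set <- function(reflectance, wavelengths, labels, ids = NULL) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(reflectance) != length(wavelengths)) {
    abort("`reflectance` must have one column per wavelength.")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing.")
  }
  labels <- as.character(labels)
  if (!all(labels %in% CLASS_LEVELS)) {
    abort(paste0("labels must be in {", paste(CLASS_LEVELS, collapse = ", "), "}."))
  }
  if (length(labels) != nrow(reflectance)) {
    abort("one label per sample required.")
  }
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(nrow(reflectance)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) abort("sample `ids` must be unique.")
  colnames(reflectance) <- band_names(wavelengths)
  out <- tibble(
    id = ids,
    label = factor(labels, levels = CLASS_LEVELS)
  )
  out <- dplyr::bind_cols(out, as_tibble(reflectance))
  class(out) <- c("spectra_set", class(out))
  out
}

band_names <- function(wavelengths) sprintf("R%.2f", wavelengths)

is_band_col <- function(nm) grepl("^R[0-9]+(\\.[0-9]+)?$", nm)

#' Wavelength axis of a spectra set
#'
#' Parsed from the `R<wavelength>` column names, so any data frame that keeps
#' the column layout (e.g. after dplyr verbs) still carries its axis.
#'
#' @param data A spectra set or data frame with `R<wavelength>` columns.
#' @return Numeric vector of wavelengths in nm.
#' @export
wavelengths <- function(data) {
  nm <- names(data)[is_band_col(names(data))]
  as.numeric(sub("^R", "", nm))
}

#' Extract the reflectance matrix from a spectra set
#'
#' @inheritParams wavelengths
#' @return Numeric matrix samples x bands with the sample ids as row names.
#' @export
spectra_matrix <- function(data) {
  cols <- names(data)[is_band_col(names(data))]
  if (length(cols) == 0) abort("no reflectance columns (R<wavelength>) found.")
  m <- as.matrix(data[, cols, drop = FALSE])
  if (!is.null(data[["id"]])) rownames(m) <- data[["id"]]
  m
}

spectra_labels <- function(data) {
  factor(as.character(data[["label"]]), levels = CLASS_LEVELS)
}

# rebuild a spectra_set from parts of an existing one
rebuild_spectra <- function(reflectance, wl, labels, ids) {
  spectra_set(reflectance, wl, labels, ids)
}

#' @export
print.spectra_set <- function(x, ...) {
  wl <- wavelengths(x)
  cat(sprintf(
    "# Spectra set: %d samples x %d bands (%.1f-%.1f nm)\n",
    nrow(x), length(wl), min(wl), max(wl)
  ))
  tab <- table(spectra_labels(x))
  cat("# Classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  NextMethod()
}

#' Write / read a spectra set as CSV
#'
#' Plain-text interchange format: header `id,label,R<wavelength>,...` with
#' wavelengths in nm to two decimals and `NM`/`SH`/`MD` label strings.
#'
#' @param data A spectra set.
#' @param path File path.
#' @return `write_spectra_csv()` returns `data` invisibly;
#'   `read_spectra_csv()` returns a `spectra_set`.
#' @export
write_spectra_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(data)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  spectra_set(spectra_matrix(df), wavelengths(df), df$label, df$id)
}
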