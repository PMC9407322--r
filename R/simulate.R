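#' Simulation settings for synthetic Vis-NIR jujube spectra
#'
#' The defaults emulate the study conditions of the motivating dataset:
#' 200 normal (NM), 302 starch-head (SH) and 98 mildewed (MD) dried jujubes,
#' 934 reflectance bands over 400-1100 nm, multiplicative/additive scatter on
#' every sample and the largest spectral dispersion in the mildewed class.
#'
#' @param class_counts Integer vector (NM, SH, MD) of samples per class.
#' @param n_bands Number of wavelength bands (>= 4).
#' @param band_range Wavelength range in nm, `c(low, high)`.
#' @param scatter Half-width of the centred-uniform multiplicative scatter
#'   coefficient a_i (each sample is scaled by 1 + a_i).
#' @param offset Half-width of the centred-uniform additive offset b_i.
#' @param noise_sd Per-class additive noise standard deviation (NM, SH, MD);
#'   must be non-decreasing from NM to MD.
#' @param md_scatter_mult Multiplier on `scatter` for the mildewed class,
#'   giving MD the widest deviation envelope.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(class_counts = c(NM = 200, SH = 302, MD = 98),
                       n_bands = 934,
                       band_range = c(400, 1100),
                       scatter = 0.15,
                       offset = 0.02,
                       noise_sd = c(NM = 0.010, SH = 0.012, MD = 0.020),
                       md_scatter_mult = 2,
                       seed = 1L) {
  class_counts <- as.integer(class_counts)
  if (length(class_counts) != 3 || any(class_counts < 0)) {
    abort("`class_counts` must be 3 non-negative integers (NM, SH, MD).")
  }
  if (band_range[1] >= band_range[2]) abort("`band_range` must satisfy low < high.")
  noise_sd <- as.numeric(noise_sd)
  if (noise_sd[3] < noise_sd[1]) {
    abort("noise_sd for MD must be >= noise_sd for NM.")
  }
  structure(
    list(
      class_counts = setNames(class_counts, CLASS_LEVELS),
      n_bands = as.integer(n_bands),
      band_range = as.numeric(band_range),
      scatter = scatter, offset = offset,
      noise_sd = setNames(noise_sd, CLASS_LEVELS),
      md_scatter_mult = md_scatter_mult,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Class curves share one smooth template — low visible-range reflectance, a
# steep "red edge" rise over 600-750 nm, absorption dips near 890 nm (C-H
# third overtone) and 990 nm (O-H second overtone, moisture) — but differ in
# overall amplitude (NM > SH > MD), red-edge position and absolute dip
# depths. The dips are NOT scaled with the amplitude: relative water-band
# depth is the chemistry signal that survives multiplicative scatter
# correction. Dip depths and edge position are drawn per SAMPLE from
# centred-uniform class distributions whose SH and MD ranges overlap
# (moisture and mildew degree vary fruit to fruit), so the starch-head and
# mildewed classes genuinely overlap while normal fruit stay well separated
# — the difficulty pattern seen in real defective-fruit spectra. The `jit`
# entries are the uniform half-widths of (edge, d890, d990); MD has the
# widest spread.
CLASS_SHAPE <- list(
  NM = list(amp = 1.00, edge = 672, d890 = 0.050, d990 = 0.080,
            jit = c(3, 0.015, 0.025)),
  SH = list(amp = 0.82, edge = 680, d890 = 0.068, d990 = 0.140,
            jit = c(6, 0.028, 0.050)),
  MD = list(amp = 0.68, edge = 682, d890 = 0.075, d990 = 0.160,
            jit = c(6, 0.028, 0.050))
)

# n per-sample curves for one class: rows are samples
class_sample_curves <- function(wl, cls, n) {
  p <- CLASS_SHAPE[[cls]]
  edge <- runif(n, p$edge - p$jit[1], p$edge + p$jit[1])
  d890 <- runif(n, p$d890 - p$jit[2], p$d890 + p$jit[2])
  d990 <- runif(n, p$d990 - p$jit[3], p$d990 + p$jit[3])
  g890 <- exp(-0.5 * ((wl - 890) / 15)^2)
  g990 <- exp(-0.5 * ((wl - 990) / 22)^2)
  t(vapply(seq_len(n), function(i) {
    p$amp * (0.15 + 0.55 * stats::plogis((wl - edge[i]) / 30)) -
      d890[i] * g890 - d990[i] * g990
  }, numeric(length(wl))))
}

#' Generate a synthetic three-class Vis-NIR spectra set
#'
#' Each sample i of class c is `(1 + a_i) * base_i(wl) + b_i + noise`, where
#' `base_i()` is a per-sample curve (logistic red-edge rise plus Gaussian
#' dips at 890 and 990 nm, with class-specific amplitude, edge position and
#' dip depths jittered per sample) and `a_i`, `b_i` are per-sample
#' multiplicative/additive scatter coefficients (so multiplicative scatter
#' correction has a real distortion to remove). Class mean amplitude is
#' ordered NM > SH > MD; the SH and MD dip-depth distributions overlap, and
#' the mildewed class receives the widest scatter, jitter and noise —
#' reproducing its larger deviation envelope and the SH/MD confusability of
#' real data.
#'
#' @param config A [sim_config()].
#' @return A [spectra_set()] with `sum(class_counts)` rows.
#' @export
#' @examples
#' s <- generate_spectra(sim_config(class_counts = c(20, 30, 10), n_bands = 50))
#' dim(spectra_matrix(s))
generate_spectra <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$class_counts
  if (sum(counts) == 0) abort("zero total samples requested.")
  if (config$n_bands < 4) abort("`n_bands` must be at least 4.")
  wl <- seq(config$band_range[1], config$band_range[2],
            length.out = config$n_bands)
  set.seed(config$seed)
  rows <- vector("list", 3)
  for (ci in seq_along(CLASS_LEVELS)) {
    cls <- CLASS_LEVELS[ci]
    n <- counts[[cls]]
    if (n == 0) next
    base <- class_sample_curves(wl, cls, n)
    s <- config$scatter * if (cls == "MD") config$md_scatter_mult else 1
    a <- runif(n, -s, s)
    b <- runif(n, -config$offset, config$offset)
    noise <- matrix(rnorm(n * length(wl), sd = config$noise_sd[[cls]]),
                    nrow = n)
    refl <- (1 + a) * base + b + noise
    rows[[ci]] <- list(refl = refl, labels = rep(cls, n))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  refl <- do.call(rbind, lapply(rows, `[[`, "refl"))
  labels <- unlist(lapply(rows, `[[`, "labels"))
  refl <- pmin(pmax(refl, 1e-4), 1.2)
  ids <- sprintf("%s%04d", labels, stats::ave(seq_along(labels), labels,
                                              FUN = seq_along))
  spectra_set(refl, wl, labels, ids)
}

#' Stratified train/test split
#'
#' Splits a spectra set class by class. The per-class training size is the
#' class count times `train_fraction`, rounded half-up; any residual against
#' the rounded overall total is absorbed by the largest class so the totals
#' match. With the study's class counts (200/302/98) and a 7:3 ratio this
#' reproduces the 140/211/69 training and 60/91/29 test partition.
#'
#' @param data A spectra set.
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly between 0 and 1.
#' @param seed Integer seed for the within-class shuffle.
#' @return A list with `spectra_set` elements `train` and `test`.
#' @export
stratified_split <- function(data, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  labels <- spectra_labels(data)
  counts <- table(labels)
  n_train <- round_half_up(as.numeric(counts) * train_fraction)
  total_target <- round_half_up(nrow(data) * train_fraction)
  resid <- total_target - sum(n_train)
  if (resid != 0) {
    big <- which.max(as.numeric(counts))
    n_train[big] <- n_train[big] + resid
  }
  names(n_train) <- names(counts)
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cls in names(counts)) {
    idx <- which(labels == cls)
    if (length(idx) == 1 && counts[[cls]] > 0) {
      warn(sprintf("class %s has a single sample; assigned to the training set.", cls))
      train_idx <- c(train_idx, idx)
      next
    }
    take <- min(length(idx), max(0, n_train[[cls]]))
    train_idx <- c(train_idx, sample(idx, take))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(data)), train_idx)
  wl <- wavelengths(data)
  m <- spectra_matrix(data)
  list(
    train = spectra_set(m[train_idx, , drop = FALSE], wl,
                        labels[train_idx], data$id[train_idx]),
    test = spectra_set(m[test_idx, , drop = FALSE], wl,
                       labels[test_idx], data$id[test_idx])
  )
}
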