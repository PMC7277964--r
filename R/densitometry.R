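# Attenuation histograms and densitometric indices.
#
# All indices are defined on an integer-binned HU histogram over the
# segmented lung: bins of width 1 HU from -1024 to +200 inclusive (1225
# bins); voxel HU is rounded half-away-from-zero to its bin. An upper
# lung-volume threshold (-200, 0 or +200 HU) restricts the histogram and
# provides the denominator for all percentage indices.

HIST_LO <- -1024L
HIST_HI <- 200L
N_BINS <- HIST_HI - HIST_LO + 1L  # 1225

#' Standard upper lung-volume thresholds (HU)
#' @export
LUNG_THRESHOLDS <- c(-200L, 0L, 200L)

#' Construct an attenuation histogram
#'
#' @param counts numeric non-negative vector of length 1225: voxel counts
#'   (or mixture weights) per 1-HU bin from -1024 to +200 HU inclusive.
#' @param voxel_volume_ml volume of one voxel in mL.
#' @return object of class `attenuation_histogram` with fields `bin_lo`,
#'   `counts`, `voxel_volume_ml`.
#' @export
attenuation_histogram <- function(counts, voxel_volume_ml = 1) {
  counts <- as.numeric(counts)
  if (length(counts) != N_BINS)
    stopf("`counts` must have %d bins (-1024..+200 HU), got %d",
          N_BINS, length(counts))
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("histogram counts must be finite and non-negative")
  structure(list(bin_lo = HIST_LO, counts = counts,
                 voxel_volume_ml = voxel_volume_ml),
            class = "attenuation_histogram")
}

#' @export
print.attenuation_histogram <- function(x, ...) {
  cat(sprintf("attenuation_histogram: %s voxels in [-1024, +200] HU, voxel %.4g mL\n",
              format(sum(x$counts)), x$voxel_volume_ml))
  invisible(x)
}

hist_bins <- function() seq(HIST_LO, HIST_HI)

#' Build the lung attenuation histogram
#'
#' Counts masked voxels into 1-HU bins from -1024 to +200 HU. Voxels above
#' +200 HU are excluded (outside the segmentation band by construction);
#' values are rounded half-away-from-zero to their bin.
#'
#' @param volume a [ct_volume].
#' @param mask a [seg_mask] congruent with `volume`, with at least 1 voxel.
#' @return an [attenuation_histogram].
#' @export
build_histogram <- function(volume, mask) {
  if (!identical(dim(mask$flags), dim(volume$voxels)))
    stopf("mask shape does not match volume shape")
  if (mask$voxel_count < 1L) stopf("empty mask: no voxels to histogram")
  hu <- round_hu(volume$voxels[mask$flags])
  hu <- pmax(hu, HIST_LO)
  hu <- hu[hu <= HIST_HI]
  counts <- tabulate(as.integer(hu - HIST_LO + 1L), nbins = N_BINS)
  attenuation_histogram(counts, voxel_volume_ml = voxel_volume_ml(volume))
}

#' Threshold configuration for lung-volume restriction
#'
#' @param upper_hu upper HU bound of the lung volume; one of -200, 0, +200.
#' @return a `threshold_config` list with `lower_hu = -1024` and `upper_hu`.
#' @export
threshold_config <- function(upper_hu) {
  upper_hu <- as.integer(upper_hu)
  if (!upper_hu %in% LUNG_THRESHOLDS)
    stopf("upper_hu must be one of %s", paste(LUNG_THRESHOLDS, collapse = ", "))
  structure(list(lower_hu = HIST_LO, upper_hu = upper_hu),
            class = "threshold_config")
}

restricted_counts <- function(hist, upper_hu) {
  hist$counts[seq_len(upper_hu - HIST_LO + 1L)]
}

#' Lung volume at an upper threshold
#'
#' @param hist an [attenuation_histogram].
#' @param t a [threshold_config] (or an upper HU value).
#' @return list with `voxels` (count in `[-1024, upper_hu]`) and `ml`.
#' @export
lung_volume_at <- function(hist, t) {
  if (!inherits(t, "threshold_config")) t <- threshold_config(t)
  n <- sum(restricted_counts(hist, t$upper_hu))
  list(voxels = n, ml = n * hist$voxel_volume_ml)
}

#' Percentage of lung volume inside a HU band
#'
#' `100 * count(band intersected with [-1024, upper]) / count([-1024, upper])`.
#' Bands are inclusive integer HU intervals. A band wholly above the upper
#' threshold yields 0.
#'
#' @param hist an [attenuation_histogram].
#' @param band integer length-2, inclusive HU bounds `c(lo, hi)`.
#' @param t a [threshold_config] (or upper HU value).
#' @return percentage in `[0, 100]`.
#' @export
band_fraction <- function(hist, band, t) {
  if (!inherits(t, "threshold_config")) t <- threshold_config(t)
  denom <- sum(restricted_counts(hist, t$upper_hu))
  if (denom <= 0)
    stopf("no voxels in [-1024, %d]: band fractions undefined", t$upper_hu)
  lo <- max(band[1], HIST_LO)
  hi <- min(band[2], t$upper_hu)
  if (lo > hi) return(0)
  num <- sum(hist$counts[(lo - HIST_LO + 1L):(hi - HIST_LO + 1L)])
  100 * num / denom
}

weighted_median_bin <- function(bins, w) {
  cw <- cumsum(w) / sum(w)
  bins[which(cw >= 0.5)[1]]
}

#' Densitometric feature set at one upper threshold
#'
#' Computes the standard histogram indices on the lung volume restricted to
#' `[-1024, upper_hu]`:
#' \describe{
#'   \item{nl_pct}{normally attenuated lung, band `[-950, -701]` HU.}
#'   \item{pff_pct}{pulmonary fibrosis fraction, the complement
#'     `100 - %[-1024, -700]` of the non-fibrotic fraction (which is also
#'     returned as `nonfibrotic_pct`).}
#'   \item{laa_pct}{low-attenuation area, HU below -960 (bins <= -961).}
#'   \item{haa_pct}{high-attenuation area, HU above -200 (bins >= -199);
#'     identically 0 at the -200 HU threshold, where the band lies wholly
#'     outside the lung volume.}
#'   \item{haa_a_pct}{alternative high-attenuation area, band
#'     `[-600, -250]` HU.}
#'   \item{mld, median_hu, variance_hu2, skewness, kurtosis}{moments of the
#'     restricted histogram; `kurtosis` is excess kurtosis (fourth
#'     standardized moment minus 3, zero for a normal distribution).}
#' }
#'
#' @param hist an [attenuation_histogram].
#' @param t a [threshold_config] (or upper HU value).
#' @return object of class `feature_set` (a named list, also containing
#'   `lung_volume_ml` and `threshold`).
#' @export
compute_features <- function(hist, t) {
  if (!inherits(t, "threshold_config")) t <- threshold_config(t)
  w <- restricted_counts(hist, t$upper_hu)
  n <- sum(w)
  if (n <= 0)
    stopf("no voxels in [-1024, %d]: features undefined", t$upper_hu)
  bins <- seq(HIST_LO, t$upper_hu)
  p <- w / n
  mld <- sum(bins * p)
  m2 <- sum((bins - mld)^2 * p)
  if (sum(w > 0) < 2L || m2 <= 0)
    stopf("degenerate histogram (single occupied bin): kurtosis and skewness undefined")
  m3 <- sum((bins - mld)^3 * p)
  m4 <- sum((bins - mld)^4 * p)
  nonfib <- band_fraction(hist, c(-1024, -700), t)
  structure(list(
    nl_pct = band_fraction(hist, c(-950, -701), t),
    pff_pct = 100 - nonfib,
    nonfibrotic_pct = nonfib,
    haa_pct = band_fraction(hist, c(-199, t$upper_hu), t),
    laa_pct = band_fraction(hist, c(-1024, -961), t),
    haa_a_pct = band_fraction(hist, c(-600, -250), t),
    kurtosis = m4 / m2^2 - 3,
    skewness = m3 / m2^1.5,
    mld = mld,
    median_hu = weighted_median_bin(bins, w),
    variance_hu2 = m2,
    lung_volume_ml = n * hist$voxel_volume_ml,
    threshold = t
  ), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set (upper threshold %+d HU):\n", x$threshold$upper_hu))
  for (f in c("nl_pct", "pff_pct", "haa_pct", "laa_pct", "haa_a_pct"))
    cat(sprintf("  %-10s %7.2f %%\n", f, x[[f]]))
  cat(sprintf("  kurtosis %7.3f  skewness %7.3f  MLD %7.1f HU\n",
              x$kurtosis, x$skewness, x$mld))
  invisible(x)
}

#' Feature sets at all standard thresholds
#'
#' @param hist an [attenuation_histogram].
#' @param thresholds integer vector of upper HU thresholds (subset of
#'   -200, 0, +200).
#' @return named list of [compute_features()] results, names like `"-200"`.
#' @export
compute_all_thresholds <- function(hist, thresholds = LUNG_THRESHOLDS) {
  out <- lapply(thresholds, function(u) compute_features(hist, u))
  names(out) <- as.character(thresholds)
  out
}

#' Excess kurtosis of a sample
#'
#' The population-moment estimator `m4 / m2^2 - 3` (fourth standardized
#' moment minus 3), which is zero for a perfectly normal distribution.
#'
#' @param x numeric vector (at least two distinct values).
#' @return scalar excess kurtosis.
#' @export
excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stopf("degenerate sample: kurtosis undefined")
  mean((x - m)^4) / m2^2 - 3
}

#' Tidy feature table for one or more patients
#'
#' @param feature_sets named list (by patient id) of
#'   [compute_all_thresholds()] outputs.
#' @return data.frame with columns `patient_id`, `threshold_hu`, `feature`,
#'   `value` (long format, suitable for CSV export).
#' @export
features_to_table <- function(feature_sets) {
  rows <- list()
  num_fields <- c("nl_pct", "pff_pct", "nonfibrotic_pct", "haa_pct",
                  "laa_pct", "haa_a_pct", "kurtosis", "skewness", "mld",
                  "median_hu", "variance_hu2", "lung_volume_ml")
  for (pid in names(feature_sets)) {
    for (th in names(feature_sets[[pid]])) {
      fs <- feature_sets[[pid]][[th]]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, threshold_hu = as.integer(th),
        feature = num_fields,
        value = vapply(num_fields, function(f) fs[[f]], numeric(1)),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
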