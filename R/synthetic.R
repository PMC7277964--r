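# Synthetic thorax phantoms and cohorts with analytic ground truth.
#
# A phantom is a voxel grid holding: background air (-1024 HU), an
# elliptic-cylinder body of soft tissue, one or two ellipsoidal lungs
# whose voxels carry a spatially blobby mixture of normal-lung / fibrotic /
# emphysematous tissue, a thin dense shell at the pleural interface (the
# chest wall's role: without it no finite HU band could stop region
# growing at the lung boundary), and a trachea of air open to the top of
# the grid. Every tissue's HU distribution is known, so band fractions and
# histogram moments have exact binned ground truth.

TISSUE_MODELS <- list(
  normal     = list(mu = -850, sd = 60,  lo = -Inf,  hi = Inf),
  fibrotic   = list(mu = -300, sd = 150, lo = -Inf,  hi = 200),
  emphysema  = list(mu = -990, sd = 12,  lo = -1024, hi = Inf),
  soft       = list(mu = 40,   sd = 20,  lo = -Inf,  hi = Inf),
  shell      = list(mu = 400,  sd = 30,  lo = 250,   hi = Inf),
  trachea    = list(mu = -1000, sd = 10, lo = -1024, hi = -950)
)

# Exact binned pmf of one tissue model on the histogram grid
# (-1024..+200, 1 HU bins): continuous truncation to [lo, hi], then values
# below -1023.5 clip into the -1024 bin and values above 199.5 fall into
# the +200 bin.
tissue_bin_pmf <- function(tm) {
  edges <- c(-Inf, seq(-1023.5, 199.5, by = 1), Inf)
  z <- stats::pnorm(tm$hi, tm$mu, tm$sd) - stats::pnorm(tm$lo, tm$mu, tm$sd)
  ce <- pmin(pmax(edges, tm$lo), tm$hi)
  diff(stats::pnorm(ce, tm$mu, tm$sd)) / z
}

# Truncated-normal sampler (inverse CDF).
rtnorm <- function(n, tm) {
  plo <- stats::pnorm(tm$lo, tm$mu, tm$sd)
  phi <- stats::pnorm(tm$hi, tm$mu, tm$sd)
  stats::qnorm(stats::runif(n, plo, phi), tm$mu, tm$sd)
}

#' Phantom specification
#'
#' @param grid_shape voxels per axis (default `c(96, 96, 64)`; the third
#'   axis is slices, increasing towards the head).
#' @param spacing_mm voxel size per axis in mm (default 3).
#' @param fibrosis_fraction,emphysema_fraction marginal fractions of lung
#'   voxels assigned fibrotic / emphysematous tissue (`f + e <= 1`).
#' @param n_lungs 1 or 2 ellipsoidal lungs.
#' @param blob_sigma_vox smoothing (voxels) of the Gaussian random field
#'   whose level sets place fibrotic and emphysematous blobs.
#' @param trachea_attached if `TRUE`, air branches connect the trachea to
#'   both lungs (one connected airway-lung air space); if `FALSE`
#'   (default) the airway is sealed from the lungs by soft tissue.
#' @param blur_sigma_vox optional Gaussian blur of the final HU volume
#'   (partial-volume emulation); 0 (default) disables it. Ground truth is
#'   defined pre-blur.
#' @param seed RNG seed; regeneration with the same spec is bit-identical.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 64L),
                         spacing_mm = c(3, 3, 3),
                         fibrosis_fraction = 0.3,
                         emphysema_fraction = 0.05,
                         n_lungs = 2L,
                         blob_sigma_vox = 2,
                         trachea_attached = FALSE,
                         blur_sigma_vox = 0,
                         seed = 1L) {
  f <- fibrosis_fraction; e <- emphysema_fraction
  if (f < 0 || e < 0 || f + e > 1)
    stopf("need fibrosis_fraction, emphysema_fraction >= 0 with sum <= 1")
  if (!n_lungs %in% c(1L, 2L)) stopf("n_lungs must be 1 or 2")
  if (any(grid_shape < 32L))
    stopf("grid_shape must be at least 32 voxels per axis")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 fibrosis_fraction = f, emphysema_fraction = e,
                 n_lungs = as.integer(n_lungs),
                 blob_sigma_vox = blob_sigma_vox,
                 trachea_attached = isTRUE(trachea_attached),
                 blur_sigma_vox = blur_sigma_vox,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Gaussian random field on an array via FFT (circular convolution).
smooth_field <- function(d, sigma, noise) {
  if (sigma <= 0) return(noise)
  k <- lapply(seq_along(d), function(i) {
    x <- c(0:(d[i] %/% 2), -((d[i] - 1) %/% 2):-1)
    exp(-x^2 / (2 * sigma^2))
  })
  kern <- outer(outer(k[[1]], k[[2]]), k[[3]])
  dim(kern) <- d
  kern <- kern / sum(kern)
  Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / prod(d)
}

# mm coordinates of voxel centres along each axis
axis_mm <- function(n, sp) (seq_len(n) - 0.5) * sp

phantom_geometry <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing_mm
  ext <- d * sp
  cx <- ext[1] / 2; cy <- ext[2] / 2
  # semi-axes (mm); lungs plus their dense shells stay inside the body
  lung_rad <- c(0.14 * ext[1], 0.26 * ext[2], 0.42 * ext[3])
  dzc <- 0.48 * ext[3]
  ly <- cy - 0.015 * ext[2]
  centers <- if (spec$n_lungs == 2L) {
    rbind(c(cx - 0.21 * ext[1], ly, dzc),
          c(cx + 0.21 * ext[1], ly, dzc))
  } else {
    rbind(c(cx - 0.21 * ext[1], ly, dzc))
  }
  list(ext = ext,
       body_center = c(cx, cy), body_rad = c(0.45 * ext[1], 0.42 * ext[2]),
       lung_centers = centers, lung_rad = lung_rad,
       trachea_center = c(cx, ly),
       trachea_radius = 8, trachea_wall = 3,
       trachea_zlo = 0.57 * ext[3],
       branch_radius = 6,
       branch_z = 0.52 * ext[3])
}

#' Generate a synthetic thorax phantom
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` (a [ct_volume]), `lung_mask` and
#'   `trachea_mask` (ground-truth [seg_mask]s; the trachea mask covers the
#'   lumen above the carina), `true_features` (exact
#'   [compute_all_thresholds()] on the binned tissue mixture), `true_pmf`
#'   (the mixture [attenuation_histogram] with unit mass), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  d <- spec$grid_shape; sp <- spec$spacing_mm
  g <- phantom_geometry(spec)
  xs <- axis_mm(d[1], sp[1]); ys <- axis_mm(d[2], sp[2]); zs <- axis_mm(d[3], sp[3])
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  body <- ((X - g$body_center[1]) / g$body_rad[1])^2 +
          ((Y - g$body_center[2]) / g$body_rad[2])^2 <= 1
  lung <- array(FALSE, d)
  shell <- array(FALSE, d)
  shell_mm <- 2 * max(sp)
  for (i in seq_len(nrow(g$lung_centers))) {
    cc <- g$lung_centers[i, ]
    q <- ((X - cc[1]) / g$lung_rad[1])^2 + ((Y - cc[2]) / g$lung_rad[2])^2 +
         ((Z - cc[3]) / g$lung_rad[3])^2
    lung <- lung | (q <= 1)
    qs <- ((X - cc[1]) / (g$lung_rad[1] + shell_mm))^2 +
          ((Y - cc[2]) / (g$lung_rad[2] + shell_mm))^2 +
          ((Z - cc[3]) / (g$lung_rad[3] + shell_mm))^2
    shell <- shell | (qs <= 1)
  }
  shell <- shell & !lung

  inplane_tr <- (X - g$trachea_center[1])^2 + (Y - g$trachea_center[2])^2
  trachea <- inplane_tr <= g$trachea_radius^2 & Z >= g$trachea_zlo
  wall <- inplane_tr <= (g$trachea_radius + g$trachea_wall)^2 &
    Z >= g$trachea_zlo & !trachea
  branch <- array(FALSE, d)
  if (spec$trachea_attached) {
    xmin <- min(g$lung_centers[, 1]); xmax <- max(g$lung_centers[, 1])
    inplane_br <- (Y - g$trachea_center[2])^2 + (Z - g$branch_z)^2
    branch <- inplane_br <= g$branch_radius^2 & X >= xmin & X <= xmax
    stem_ext <- inplane_tr <= g$trachea_radius^2 &
      Z >= g$branch_z & Z < g$trachea_zlo
    wall <- (wall & !branch) |
      (inplane_br <= (g$branch_radius + g$trachea_wall)^2 & !branch &
         X >= xmin & X <= xmax) |
      (inplane_tr <= (g$trachea_radius + g$trachea_wall)^2 &
         Z >= g$branch_z & !stem_ext & !branch)
    trachea <- trachea | stem_ext
  }

  # assemble HU
  v <- array(-1024, d)
  v[body] <- rtnorm(sum(body), TISSUE_MODELS$soft)
  v[shell] <- rtnorm(sum(shell), TISSUE_MODELS$shell)

  # blobby tissue labels inside the lungs with exact marginal counts
  nL <- sum(lung)
  field <- smooth_field(d, spec$blob_sigma_vox, array(stats::rnorm(prod(d)), d))
  fl <- field[lung]
  rk <- rank(fl, ties.method = "first")
  n_fib <- round(spec$fibrosis_fraction * nL)
  n_emp <- round(spec$emphysema_fraction * nL)
  lab <- rep("normal", nL)
  lab[rk <= n_fib] <- "fibrotic"
  lab[rk > nL - n_emp] <- "emphysema"
  hu_lung <- numeric(nL)
  for (tis in c("normal", "fibrotic", "emphysema")) {
    idx <- which(lab == tis)
    if (length(idx)) hu_lung[idx] <- rtnorm(length(idx), TISSUE_MODELS[[tis]])
  }
  v[lung] <- hu_lung

  wall <- wall & !lung  # the airway wall never intrudes into the lungs
  v[wall] <- rtnorm(sum(wall), TISSUE_MODELS$shell)
  air <- trachea | branch
  v[air] <- rtnorm(sum(air), TISSUE_MODELS$trachea)
  lung_gt <- lung & !air
  if (spec$blur_sigma_vox > 0)
    v <- smooth_field(d, spec$blur_sigma_vox, v)
  v <- pmin(v, 2000)

  vol <- ct_volume(v, spacing = sp)
  w <- c(1 - spec$fibrosis_fraction - spec$emphysema_fraction,
         spec$fibrosis_fraction, spec$emphysema_fraction)
  pmf <- w[1] * tissue_bin_pmf(TISSUE_MODELS$normal) +
         w[2] * tissue_bin_pmf(TISSUE_MODELS$fibrotic) +
         w[3] * tissue_bin_pmf(TISSUE_MODELS$emphysema)
  true_hist <- attenuation_histogram(pmf, voxel_volume_ml = voxel_volume_ml(vol))
  trach_gt <- inplane_tr <= g$trachea_radius^2 & Z >= g$trachea_zlo
  list(volume = vol,
       lung_mask = seg_mask(lung_gt, vol),
       trachea_mask = seg_mask(trach_gt, vol),
       true_features = compute_all_thresholds(true_hist),
       true_pmf = true_hist,
       spec = spec)
}

#' Exact densitometric ground truth for a tissue mixture
#'
#' Feature sets of the binned mixture distribution with the given marginal
#' weights, independent of any voxel grid.
#'
#' @param fibrosis_fraction,emphysema_fraction mixture weights.
#' @param thresholds upper HU thresholds.
#' @return named list of feature sets, as [compute_all_thresholds()].
#' @export
mixture_true_features <- function(fibrosis_fraction, emphysema_fraction = 0,
                                  thresholds = LUNG_THRESHOLDS) {
  w <- c(1 - fibrosis_fraction - emphysema_fraction,
         fibrosis_fraction, emphysema_fraction)
  if (any(w < 0)) stopf("fractions must be >= 0 and sum to <= 1")
  pmf <- w[1] * tissue_bin_pmf(TISSUE_MODELS$normal) +
         w[2] * tissue_bin_pmf(TISSUE_MODELS$fibrotic) +
         w[3] * tissue_bin_pmf(TISSUE_MODELS$emphysema)
  compute_all_thresholds(attenuation_histogram(pmf), thresholds)
}

#' Cohort specification
#'
#' Defaults emulate a small fibrosis cohort: 32 patients, male-skewed,
#' ages around the late 60s, disease severity (fibrosis fraction) varying
#' across patients, and lung function generated from a gamma distribution
#' whose log-mean increases with the true normally-attenuated-lung
#' percentage (healthier lungs, better spirometry).
#'
#' @param n_patients cohort size (>= 5; default 32).
#' @param fibrosis_beta shape parameters of the Beta distribution of the
#'   per-patient fibrosis fraction.
#' @param emphysema_beta shape parameters for the emphysema fraction.
#' @param p_male probability of male sex.
#' @param age_mean,age_sd,age_range age distribution (years), truncated.
#' @param fvc_link,dlco_link `c(a, b, shape)`: response ~
#'   Gamma(shape, mean = exp(a + b * NL_true_pct)) with `b > 0`.
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 32L,
                        fibrosis_beta = c(14, 30),
                        emphysema_beta = c(2, 38),
                        p_male = 26 / 32,
                        age_mean = 68.3, age_sd = 6.5, age_range = c(55, 82),
                        fvc_link = c(a = 3.8386, b = 0.010, shape = 25),
                        dlco_link = c(a = 3.1656, b = 0.015, shape = 20),
                        seed = 1L) {
  if (n_patients < 5L) stopf("n_patients must be >= 5")
  if (fvc_link[["b"]] < 0 || dlco_link[["b"]] < 0)
    stopf("lung-function links must have b >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 fibrosis_beta = fibrosis_beta,
                 emphysema_beta = emphysema_beta,
                 p_male = p_male, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range,
                 fvc_link = fvc_link, dlco_link = dlco_link,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rtrunc_norm_scalar <- function(n, mu, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mu, sd),
                            stats::pnorm(hi, mu, sd)), mu, sd)
}

#' Generate a synthetic cohort
#'
#' Draws per-patient severity, demographics and lung function, and returns
#' the clinical table (with GAP points/stage), a long feature table of the
#' exact densitometric ground truth per threshold, and per-patient
#' [phantom_spec()]s so matching volumes can be rendered on demand.
#'
#' @param spec a [cohort_spec].
#' @param measurement_sd absolute Gaussian measurement noise added to the
#'   percentage features in the feature table (HU-histogram estimation
#'   noise); kurtosis receives a tenth of it.
#' @return list with `clinical` (data.frame), `features` (long data.frame:
#'   patient_id, threshold_hu, feature columns, gap and lung function),
#'   `phantom_specs` (list), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), measurement_sd = 0.5) {
  set.seed(spec$seed)
  n <- spec$n_patients
  f <- stats::rbeta(n, spec$fibrosis_beta[1], spec$fibrosis_beta[2])
  e <- stats::rbeta(n, spec$emphysema_beta[1], spec$emphysema_beta[2])
  e <- pmin(e, 1 - f)
  sex <- ifelse(stats::runif(n) < spec$p_male, "male", "female")
  age <- round(rtrunc_norm_scalar(n, spec$age_mean, spec$age_sd,
                                  spec$age_range[1], spec$age_range[2]))
  nl_true <- vapply(seq_len(n), function(i)
    mixture_true_features(f[i], e[i], thresholds = -200L)[["-200"]]$nl_pct,
    numeric(1))
  fl <- spec$fvc_link; dl <- spec$dlco_link
  fvc <- stats::rgamma(n, shape = fl[["shape"]],
                       scale = exp(fl[["a"]] + fl[["b"]] * nl_true) / fl[["shape"]])
  dlco <- stats::rgamma(n, shape = dl[["shape"]],
                        scale = exp(dl[["a"]] + dl[["b"]] * nl_true) / dl[["shape"]])
  fvc <- pmin(pmax(fvc, 10), 199)
  dlco <- pmin(pmax(dlco, 10), 199)
  pid <- sprintf("P%03d", seq_len(n))
  gap <- gap_score(sex, age, fvc, dlco)
  clinical <- data.frame(patient_id = pid, sex = sex, age_years = age,
                         fvc_pct_pred = round(fvc, 2),
                         dlco_pct_pred = round(dlco, 2),
                         fibrosis_fraction = f, emphysema_fraction = e,
                         gap_points = gap$points, gap_stage = gap$stage)
  feat_cols <- c("nl_pct", "pff_pct", "haa_pct", "laa_pct", "haa_a_pct",
                 "kurtosis")
  rows <- list()
  for (i in seq_len(n)) {
    tf <- mixture_true_features(f[i], e[i])
    for (th in names(tf)) {
      fs <- tf[[th]]
      row <- data.frame(patient_id = pid[i], threshold_hu = as.integer(th))
      for (fc in feat_cols) {
        noise_sd <- if (fc == "kurtosis") measurement_sd / 10 else measurement_sd
        noisy <- fs[[fc]] + stats::rnorm(1, 0, noise_sd)
        if (fc != "kurtosis") noisy <- min(max(noisy, 0), 100)
        if (fc == "haa_pct" && as.integer(th) == -200L) noisy <- 0
        row[[fc]] <- noisy
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  features <- do.call(rbind, rows)
  features <- merge(features,
                    clinical[, c("patient_id", "gap_points", "gap_stage",
                                 "fvc_pct_pred", "dlco_pct_pred")],
                    by = "patient_id", sort = TRUE)
  features <- features[order(features$patient_id, features$threshold_hu), ]
  rownames(features) <- NULL
  phantom_specs <- lapply(seq_len(n), function(i)
    phantom_spec(fibrosis_fraction = f[i], emphysema_fraction = e[i],
                 seed = spec$seed * 1000L + i))
  list(clinical = clinical, features = features,
       phantom_specs = phantom_specs, spec = spec)
}

#' Simulate cohorts with a Poisson GAP response driven by one feature
#'
#' Generates a feature table whose GAP response is drawn as
#' `Poisson(exp(a + b * NL_true))`, for parameter-recovery and
#' feature-ranking studies. Competing features are the exact mixture
#' ground truth for the same patients plus small independent measurement
#' noise, so the generating feature carries strictly more information
#' about the response.
#'
#' @param n patients per cohort (default 32).
#' @param a,b intercept and slope of the log-linear GAP model on the true
#'   NL percentage (default `a = 3.7`, `b = -0.04`: more normally
#'   attenuated lung, fewer GAP points).
#' @param threshold upper HU threshold at which features are tabulated.
#' @param measurement_sd noise added to every feature column.
#' @param seed RNG seed.
#' @return data.frame with columns `patient_id`, `threshold_hu`, the
#'   feature columns, `nl_true` and `gap_points`.
#' @export
simulate_gap_cohort <- function(n = 32L, a = 3.7, b = -0.04,
                                threshold = -200L, measurement_sd = 0.5,
                                seed = 1L) {
  set.seed(seed)
  f <- stats::rbeta(n, 14, 30)
  e <- pmin(stats::rbeta(n, 2, 38), 1 - f)
  feat_cols <- c("nl_pct", "pff_pct", "laa_pct", "haa_a_pct", "kurtosis")
  rows <- lapply(seq_len(n), function(i) {
    fs <- mixture_true_features(f[i], e[i], thresholds = threshold)[[1]]
    vals <- vapply(feat_cols, function(fc) fs[[fc]], numeric(1))
    noise <- stats::rnorm(length(vals), 0,
                          ifelse(feat_cols == "kurtosis",
                                 measurement_sd / 10, measurement_sd))
    out <- as.list(vals + noise)
    names(out) <- feat_cols
    out$nl_true <- fs$nl_pct
    as.data.frame(out)
  })
  tbl <- do.call(rbind, rows)
  tbl$patient_id <- sprintf("S%03d", seq_len(n))
  tbl$threshold_hu <- as.integer(threshold)
  tbl$gap_points <- stats::rpois(n, exp(a + b * tbl$nl_true))
  tbl
}
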