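# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: flood fill by whole-array shifting to a fixed
# point, GLM log-likelihoods by direct numerical maximization, GAP by a
# literal hand-built lookup.

# --- flood fill oracle: iterate "dilate by one step AND stay in band" ----

shift_logical <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okz <- sz >= 1 & sz <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <-
    a[sx[okx], sy[oky], sz[okz], drop = FALSE]
  out
}

oracle_flood <- function(open, seed_idx, connectivity = 6L) {
  offs <- if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(g == 0) != 3, , drop = FALSE]
  }
  reach <- array(FALSE, dim(open))
  reach[seed_idx] <- open[seed_idx]
  repeat {
    grown <- reach
    for (i in seq_len(nrow(offs)))
      grown <- grown | shift_logical(reach, offs[i, 1], offs[i, 2], offs[i, 3])
    grown <- grown & open
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

# --- direct likelihood-surface oracles --------------------------------

oracle_poisson_loglik <- function(y, x) {
  xc <- x - mean(x)
  nll <- function(p) {
    mu <- exp(p[1] + p[2] * xc)
    -sum(stats::dpois(y, mu, log = TRUE))
  }
  o <- suppressWarnings(stats::optim(c(log(mean(y) + 0.5), 0), nll,
                                     method = "BFGS",
                                     control = list(reltol = 1e-15,
                                                    maxit = 1000)))
  o <- suppressWarnings(stats::optim(o$par, nll,
                                     control = list(reltol = 1e-15,
                                                    maxit = 5000)))
  -o$value
}

oracle_gamma_loglik <- function(y, x) {
  xc <- x - mean(x)
  nll <- function(p) {
    k <- exp(p[3])
    mu <- exp(p[1] + p[2] * xc)
    -sum(stats::dgamma(y, shape = k, scale = mu / k, log = TRUE))
  }
  o <- suppressWarnings(stats::optim(c(log(mean(y)), 0, log(5)), nll,
                                     method = "BFGS",
                                     control = list(reltol = 1e-15,
                                                    maxit = 1000)))
  o <- suppressWarnings(stats::optim(o$par, nll,
                                     control = list(reltol = 1e-15,
                                                    maxit = 10000)))
  -o$value
}

# --- hand-built GAP lookup --------------------------------------------

# Representative values, one per category of the published index.
gap_hand_cases <- function() {
  sexes <- c("female", "male");      sex_pts <- c(female = 0, male = 1)
  ages  <- c(58, 63, 70);            age_pts <- c(0, 1, 2)
  fvcs  <- c(85, 60, 40);            fvc_pts <- c(0, 1, 2)
  dlcos <- list(70, 45, 30, NA);     dlco_pts <- c(0, 1, 2, 3)
  rows <- list()
  for (si in seq_along(sexes)) for (ai in 1:3) for (fi in 1:3) for (di in 1:4) {
    pts <- sex_pts[[sexes[si]]] + age_pts[ai] + fvc_pts[fi] + dlco_pts[di]
    stage <- if (pts <= 3) 1L else if (pts <= 5) 2L else 3L
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sexes[si], age = ages[ai], fvc = fvcs[fi],
      dlco = if (is.na(dlcos[[di]])) NA_real_ else dlcos[[di]],
      points = pts, stage = stage)
  }
  do.call(rbind, rows)
}

# --- small fixtures ----------------------------------------------------

# Toy volume: a 1 x 1 x n row of given HU values, 1 mm spacing.
row_volume <- function(hu) {
  ct_volume(array(hu, c(1, 1, length(hu))), spacing = c(1, 1, 1))
}

toy_hist <- function(hu_values, counts = rep(1, length(hu_values)),
                     voxel_volume_ml = 1) {
  cts <- numeric(1225)
  cts[hu_values + 1025] <- counts
  attenuation_histogram(cts, voxel_volume_ml)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

small_phantom_spec <- function(seed, f = 0.3, e = 0.05, ...) {
  phantom_spec(grid_shape = c(64L, 64L, 48L), spacing_mm = c(4, 4, 4),
               fibrosis_fraction = f, emphysema_fraction = e,
               seed = seed, ...)
}
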