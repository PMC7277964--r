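# Lung isolation by region growing in a HU band, trachea removal and mask
# clean-up. The growth primitive is a multi-source flood fill on the voxel
# lattice, vectorised over the whole frontier; arrays are padded by one
# voxel of closed border so neighbour indexing never wraps.

conn_offsets <- function(connectivity, dp) {
  sxy <- dp[1] * dp[2]
  if (connectivity == 4L) {        # in-plane faces only (slice-wise ops)
    c(-1L, 1L, -dp[1], dp[1])
  } else if (connectivity == 6L) {
    c(-1L, 1L, -dp[1], dp[1], -sxy, sxy)
  } else if (connectivity == 26L) {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
    as.integer(g$dx + g$dy * dp[1] + g$dz * sxy)
  } else stopf("connectivity must be 6 or 26, got %s", connectivity)
}

# Flood fill from `seed_idx` (linear indices into `open`) through TRUE
# voxels of `open`. Returns a logical array of the reached set.
flood_fill <- function(open, seed_idx, connectivity = 6L) {
  d <- dim(open)
  dp <- d + 2L
  openp <- array(FALSE, dp)
  openp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- open
  openv <- as.logical(openp)
  ai <- arrayInd(as.integer(seed_idx), d)
  sp <- (ai[, 1] + 1L) + ai[, 2] * dp[1] + ai[, 3] * dp[1] * dp[2]
  offs <- conn_offsets(as.integer(connectivity), dp)
  visited <- logical(length(openv))
  frontier <- unique(sp[openv[sp]])
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, offs, `+`)))
    nb <- nb[openv[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  array(visited, dp)[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

# Label connected components of a logical array; returns an integer array
# (0 = background) and component sizes, largest first relabelled 1, 2, ...
# Single padded pass so many small components stay cheap.
label_components <- function(flags, connectivity = 6L) {
  d <- dim(flags)
  dp <- d + 2L
  openp <- array(FALSE, dp)
  openp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- flags
  openv <- as.logical(openp)
  offs <- conn_offsets(as.integer(connectivity), dp)
  labv <- integer(length(openv))
  todo <- which(openv)
  k <- 0L
  for (s in todo) {
    if (labv[s] != 0L) next
    k <- k + 1L
    labv[s] <- k
    frontier <- s
    while (length(frontier)) {
      nb <- as.vector(outer(frontier, offs, `+`))
      nb <- unique(nb[openv[nb] & labv[nb] == 0L])
      labv[nb] <- k
      frontier <- nb
    }
  }
  labels <- array(labv, dp)[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L),
                            drop = FALSE]
  sizes <- if (k > 0L) tabulate(labels[labels > 0L], nbins = k) else integer(0)
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  out <- labels
  out[labels > 0L] <- relab[labels[labels > 0L]]
  list(labels = out, sizes = sizes[ord])
}

#' Region-growing parameters
#'
#' @param lower,upper HU band bounds; growth is restricted to voxels with
#'   HU in `[lower, upper]`. Defaults -1024 and +200, the conventional band
#'   isolating aerated thorax from dense tissue.
#' @param connectivity voxel adjacency, 6 (faces) or 26 (faces, edges,
#'   corners). Face adjacency is the default: it avoids diagonal leakage
#'   through thin barriers on anisotropic CT grids.
#' @return a `region_grow_params` list.
#' @export
region_grow_params <- function(lower = -1024, upper = 200, connectivity = 6L) {
  if (!(lower < upper)) stopf("lower (%s) must be < upper (%s)", lower, upper)
  if (!connectivity %in% c(6L, 26L)) stopf("connectivity must be 6 or 26")
  structure(list(lower = lower, upper = upper,
                 connectivity = as.integer(connectivity)),
            class = "region_grow_params")
}

as_seed_matrix <- function(seeds, d) {
  if (is.list(seeds)) seeds <- do.call(rbind, seeds)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  bad <- seeds[, 1] < 1 | seeds[, 1] > d[1] |
         seeds[, 2] < 1 | seeds[, 2] > d[2] |
         seeds[, 3] < 1 | seeds[, 3] > d[3]
  if (any(bad))
    stopf("seed outside the volume grid: (%s)",
          paste(seeds[which(bad)[1], ], collapse = ", "))
  seeds
}

#' Region growing within a HU band
#'
#' Grows from the seed voxels through all voxels connected (under the given
#' connectivity) via voxels whose HU lies in `[lower, upper]`; the result is
#' the union of the band-connected components containing the seeds.
#'
#' @param volume a [ct_volume].
#' @param seeds integer matrix (n x 3) or list of integer voxel-coordinate
#'   triples; every seed must itself lie in the HU band.
#' @param params a [region_grow_params].
#' @return a [seg_mask].
#' @export
region_grow <- function(volume, seeds, params = region_grow_params()) {
  d <- dim(volume$voxels)
  seeds <- as_seed_matrix(seeds, d)
  idx <- seeds[, 1] + (seeds[, 2] - 1L) * d[1] + (seeds[, 3] - 1L) * d[1] * d[2]
  hu <- volume$voxels[idx]
  out_of_band <- hu < params$lower | hu > params$upper
  if (any(out_of_band)) {
    i <- which(out_of_band)[1]
    stopf("seed (%s) has HU %.1f outside the band [%s, %s]",
          paste(seeds[i, ], collapse = ", "), hu[i],
          params$lower, params$upper)
  }
  open <- volume$voxels >= params$lower & volume$voxels <= params$upper
  seg_mask(flood_fill(open, idx, params$connectivity), volume = volume)
}

#' Automatic lung seed discovery
#'
#' Finds up to two candidate lungs as the largest low-attenuation connected
#' components strictly interior to the body: voxels below `air_hu` that are
#' connected to a face of the grid (ambient air) are flood-filled away
#' first, and the centroid of each remaining large component is returned as
#' a seed.
#'
#' @param volume a [ct_volume].
#' @param air_hu HU ceiling defining candidate air-like voxels (default
#'   -400, comfortably above aerated lung and below soft tissue).
#' @param min_voxels smallest component size considered a lung candidate.
#' @return integer matrix of seed voxel coordinates, one row per candidate
#'   lung (1 or 2 rows).
#' @export
find_lung_seeds <- function(volume, air_hu = -400, min_voxels = 30L) {
  v <- volume$voxels
  d <- dim(v)
  low <- v < air_hu
  # ambient air is flood-filled from the lateral faces only: the superior
  # face is excluded because the airway opening would otherwise leak the
  # ambient label into the lungs through the trachea
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  bseed <- which(low & border)
  ambient <- if (length(bseed)) flood_fill(low, bseed, 6L) else array(FALSE, d)
  interior <- low & !ambient
  if (!any(interior)) stopf("no lung candidate found")
  lab <- label_components(interior, 6L)
  # a lung candidate must be large both absolutely and relative to the
  # largest component, so small airway remnants are never mistaken for a
  # second lung
  keep <- which(lab$sizes >= min_voxels & lab$sizes >= 0.2 * lab$sizes[1])
  if (!length(keep)) stopf("no lung candidate found")
  keep <- keep[seq_len(min(2L, length(keep)))]
  seeds <- t(vapply(keep, function(k) {
    ci <- arrayInd(which(lab$labels == k), d)
    cen <- round(colMeans(ci))
    lin <- cen[1] + (cen[2] - 1) * d[1] + (cen[3] - 1) * d[1] * d[2]
    if (lab$labels[lin] != k) {
      # non-convex component: snap to the component voxel nearest the centroid
      dist2 <- (ci[, 1] - cen[1])^2 + (ci[, 2] - cen[2])^2 + (ci[, 3] - cen[3])^2
      cen <- ci[which.min(dist2), ]
    }
    as.integer(cen)
  }, integer(3)))
  seeds
}

#' Remove the trachea and main bronchi from a lung mask
#'
#' Looks for a small near-air component in the most superior axial slices
#' (the trachea lumen), then tracks it slice-by-slice towards the lung
#' bases, stopping when the tracked cross-section explodes in area (the
#' carina, where the airway opens into the lungs). The tracked voxels are
#' removed from the mask. The slice axis is the third array axis, with the
#' last slice taken as the most superior.
#'
#' @param volume a [ct_volume].
#' @param lung_mask a [seg_mask] (typically from [region_grow()]).
#' @param air_hu HU ceiling for airway lumen voxels (default -900).
#' @param max_area_cm2 largest in-plane cross-section (cm^2) accepted as a
#'   trachea candidate (default 3).
#' @param top_slices number of most-superior slices searched for the
#'   candidate (default 3).
#' @param explosion_factor stop tracking when the cross-section grows by
#'   more than this factor from one slice to the next (default 3).
#' @return a [seg_mask]; always a subset of `lung_mask`. If no candidate is
#'   found the input mask is returned unchanged with a warning.
#' @export
remove_trachea <- function(volume, lung_mask, air_hu = -900,
                           max_area_cm2 = 3, top_slices = 3L,
                           explosion_factor = 3) {
  v <- volume$voxels
  d <- dim(v)
  if (!identical(dim(lung_mask$flags), d))
    stopf("mask shape does not match volume shape")
  area_mm2 <- volume$spacing[1] * volume$spacing[2]
  max_vox <- floor(max_area_cm2 * 100 / area_mm2)

  slice_components <- function(z) {
    sl <- array(v[, , z] < air_hu, c(d[1], d[2], 1L))
    label_components(sl, 6L)  # single-slice array: 4-connectivity in plane
  }

  start_z <- 0L
  start_comp <- NULL
  for (z in seq(d[3], by = -1L, length.out = min(top_slices, d[3]))) {
    lab <- slice_components(z)
    cand <- which(lab$sizes >= 1 & lab$sizes <= max_vox)
    if (length(cand)) {
      # exclude components touching the in-plane border (ambient air)
      for (k in cand) {
        m2 <- lab$labels[, , 1] == k
        if (any(m2[c(1, d[1]), ]) || any(m2[, c(1, d[2])])) next
        start_z <- z
        start_comp <- m2
        break
      }
    }
    if (start_z > 0L) break
  }
  if (start_z == 0L) {
    warnf("no trachea candidate found; mask returned unchanged")
    return(lung_mask)
  }

  removed <- array(FALSE, d)
  removed[, , start_z] <- start_comp
  prev <- start_comp
  prev_area <- sum(prev)
  zs <- if (start_z > 1L) seq(start_z - 1L, 1L) else integer(0)
  for (z in zs) {
    lab <- slice_components(z)
    nlab <- length(lab$sizes)
    if (nlab == 0L) break
    keep <- array(FALSE, c(d[1], d[2]))
    area <- 0L
    for (k in seq_len(nlab)) {
      m2 <- lab$labels[, , 1] == k
      if (any(m2 & prev)) {
        keep <- keep | m2
        area <- area + sum(m2)
      }
    }
    if (area == 0L) break
    if (area > explosion_factor * prev_area) break  # carina: airway opens up
    removed[, , z] <- keep
    prev <- keep
    prev_area <- area
  }
  seg_mask(lung_mask$flags & !removed)
}

#' Clean a segmentation mask
#'
#' Removes connected components smaller than `min_component_voxels` and
#' fills interior holes slice-wise (2-D holes not connected to the slice
#' border). Stands in for manual correction of coarse misrecognition.
#'
#' @param mask a [seg_mask].
#' @param min_component_voxels smallest component retained. The
#'   conventional default is the voxel count of 2 mL of tissue; pass the
#'   parent volume via `volume` to use it, otherwise specify directly.
#' @param volume optional [ct_volume] used to derive the default
#'   `min_component_voxels` from its voxel volume.
#' @param connectivity adjacency used for component analysis.
#' @return a [seg_mask].
#' @export
refine_mask <- function(mask, min_component_voxels = NULL, volume = NULL,
                        connectivity = 6L) {
  if (is.null(min_component_voxels)) {
    if (is.null(volume))
      stopf("supply min_component_voxels or a volume to derive it from")
    min_component_voxels <- max(1, round(2 / voxel_volume_ml(volume)))
  }
  d <- dim(mask$flags)
  flags <- mask$flags
  if (any(flags)) {
    lab <- label_components(flags, connectivity)
    small <- which(lab$sizes < min_component_voxels)
    if (length(small)) flags[lab$labels %in% small] <- FALSE
  }
  # slice-wise hole filling: background not reachable from the slice
  # border (one in-plane flood over all slices at once)
  bg <- !flags
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  bseed <- which(bg & border)
  reach <- if (length(bseed)) flood_fill(bg, bseed, 4L) else array(FALSE, d)
  seg_mask(flags | (bg & !reach))
}

#' One-call automatic lung segmentation
#'
#' [find_lung_seeds()], [region_grow()], [remove_trachea()] and
#' [refine_mask()] chained with their defaults.
#'
#' @param volume a [ct_volume].
#' @param params a [region_grow_params].
#' @param min_component_voxels passed to [refine_mask()]; default derives
#'   from the volume's voxel size (2 mL).
#' @return a [seg_mask] of lung parenchyma with the trachea excluded.
#' @export
segment_lungs <- function(volume, params = region_grow_params(),
                          min_component_voxels = NULL) {
  seeds <- find_lung_seeds(volume)
  mask <- region_grow(volume, seeds, params)
  mask <- withCallingHandlers(
    remove_trachea(volume, mask),
    warning = function(w) invokeRestart("muffleWarning"))
  refine_mask(mask, min_component_voxels = min_component_voxels,
              volume = volume)
}
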