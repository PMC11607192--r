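#' Segmentation configuration
#'
#' Parameters of the gradient-based star-convex segmenter. The delineation
#' principle follows the gradient class of PET segmentation methods: along
#' rays cast from the lesion centre, the boundary is placed at the most
#' negative directional derivative of the smoothed SUV profile, rather than
#' at a fixed SUV threshold.
#'
#' @param smoothing_sigma_mm Gaussian smoothing applied before gradient
#'   analysis (mm).
#' @param n_ray_subdivision Icosphere subdivision frequency; frequency `f`
#'   yields `10 f^2 + 2` quasi-uniform ray directions (default 3 -> 92 rays).
#' @param max_ray_length_mm Maximum boundary radius searched (mm).
#' @param min_seed_suv_multiple_of_liver Seed detection threshold as a
#'   multiple of the liver reference SUVmean.
#' @param background_fallback_threshold Absolute SUV threshold used for seed
#'   detection / seed validity when no liver reference is available.
#' @param ray_step_mm Sampling step along each ray (mm).
#' @param median_filter_neighbors Number of neighbouring ray directions
#'   (plus the ray itself) over which boundary radii are median filtered.
#' @param curvature_correction Correct each boundary radius for the inward
#'   shift of the maximum-gradient point that Gaussian smoothing induces on
#'   a curved interface (first order, `2 sigma^2 / r`), using the known
#'   smoothing sigma. On by default; only the self-applied smoothing is
#'   corrected, not the unknown scanner PSF.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(smoothing_sigma_mm = 2,
                                n_ray_subdivision = 3,
                                max_ray_length_mm = 40,
                                min_seed_suv_multiple_of_liver = 1.5,
                                background_fallback_threshold = 2.0,
                                ray_step_mm = 1,
                                median_filter_neighbors = 6,
                                curvature_correction = TRUE) {
  assert_scalar_num(smoothing_sigma_mm, "smoothing_sigma_mm", 0, strict = TRUE)
  assert_scalar_num(max_ray_length_mm, "max_ray_length_mm", 0, strict = TRUE)
  assert_scalar_num(min_seed_suv_multiple_of_liver,
                    "min_seed_suv_multiple_of_liver", 0, strict = TRUE)
  assert_scalar_num(background_fallback_threshold,
                    "background_fallback_threshold", 0, strict = TRUE)
  assert_scalar_num(ray_step_mm, "ray_step_mm", 0, strict = TRUE)
  structure(list(smoothing_sigma_mm = smoothing_sigma_mm,
                 n_ray_subdivision = as.integer(n_ray_subdivision),
                 max_ray_length_mm = max_ray_length_mm,
                 min_seed_suv_multiple_of_liver = min_seed_suv_multiple_of_liver,
                 background_fallback_threshold = background_fallback_threshold,
                 ray_step_mm = ray_step_mm,
                 median_filter_neighbors = as.integer(median_filter_neighbors),
                 curvature_correction = isTRUE(curvature_correction)),
            class = "segmentation_config")
}

#' Quasi-uniform ray directions from icosahedron subdivision
#'
#' Subdivides each face of a regular icosahedron into `freq^2` triangles and
#' projects the vertices onto the unit sphere, giving `10 freq^2 + 2`
#' quasi-uniform unit directions.
#'
#' @param freq Subdivision frequency (positive integer).
#' @return Matrix with one unit direction per row.
#' @export
icosphere_directions <- function(freq = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  pts <- list()
  for (f in seq_len(nrow(faces))) {
    a <- v[faces[f, 1], ]; b <- v[faces[f, 2], ]; c0 <- v[faces[f, 3], ]
    for (i in 0:freq) for (j in 0:(freq - i)) {
      k <- freq - i - j
      pts[[length(pts) + 1]] <- (i * a + j * b + k * c0) / freq
    }
  }
  m <- do.call(rbind, pts)
  m <- m / sqrt(rowSums(m^2))
  m <- unique(round(m, 9))
  m / sqrt(rowSums(m^2))
}

# k nearest neighbouring directions (by angle) for each row of dirs.
direction_neighbors <- function(dirs, k) {
  cs <- dirs %*% t(dirs)
  lapply(seq_len(nrow(dirs)), function(i) {
    ord <- order(cs[i, ], decreasing = TRUE)
    ord[ord != i][seq_len(min(k, nrow(dirs) - 1))]
  })
}

# Vectorized trilinear interpolation of a volume at continuous 0-based voxel
# coordinates (m x 3). Coordinates are clamped to the grid.
trilinear <- function(vol, coords) {
  d <- dim(vol)
  cx <- pmin(pmax(coords[, 1], 0), d[1] - 1)
  cy <- pmin(pmax(coords[, 2], 0), d[2] - 1)
  cz <- pmin(pmax(coords[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(cx), d[1] - 2); y0 <- pmin(floor(cy), d[2] - 2)
  z0 <- pmin(floor(cz), d[3] - 2)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  idx <- function(i, j, k) vol[cbind(i + 1, j + 1, k + 1)]
  v000 <- idx(x0, y0, z0);     v100 <- idx(x0 + 1, y0, z0)
  v010 <- idx(x0, y0 + 1, z0); v110 <- idx(x0 + 1, y0 + 1, z0)
  v001 <- idx(x0, y0, z0 + 1); v101 <- idx(x0 + 1, y0, z0 + 1)
  v011 <- idx(x0, y0 + 1, z0 + 1); v111 <- idx(x0 + 1, y0 + 1, z0 + 1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

smooth_image <- function(image, cfg) {
  gaussian_blur_3d(image$values, cfg$smoothing_sigma_mm, image$spacing,
                   normalize_edges = TRUE)
}

# 26-neighbourhood offsets (excluding the centre), as a 26 x 3 matrix.
neighborhood26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Detect candidate lesion seeds
#'
#' Finds strict local maxima (26-neighbourhood) of the Gaussian-smoothed SUV
#' volume whose smoothed SUV exceeds
#' `min_seed_suv_multiple_of_liver * liver_suv_mean` (or the absolute
#' `background_fallback_threshold` when no liver reference is supplied),
#' deduplicated greedily within one smoothing-kernel radius, and returned
#' sorted by smoothed SUV descending.
#'
#' @param image A [suv_image()].
#' @param liver A [liver_reference] (list with `liver_suv_mean`), or `NULL`.
#' @param cfg A [segmentation_config()].
#' @return Integer matrix of 0-based voxel indices, one seed per row, with a
#'   `suv` attribute holding the smoothed SUV at each seed.
#' @export
detect_candidate_seeds <- function(image, liver = NULL,
                                   cfg = segmentation_config()) {
  sm <- smooth_image(image, cfg)
  thr <- if (!is.null(liver)) {
    cfg$min_seed_suv_multiple_of_liver * liver$liver_suv_mean
  } else cfg$background_fallback_threshold
  d <- dim(sm)
  cand <- which(sm > thr)
  if (!length(cand)) return(empty_seed_matrix())
  arr <- arrayInd(cand, d)
  offs <- neighborhood26()
  is_max <- rep(TRUE, nrow(arr))
  for (m in seq_len(nrow(offs))) {
    nb <- sweep(arr, 2, offs[m, ], `+`)
    inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    vals <- rep(-Inf, nrow(arr))
    vals[inside] <- sm[nb[inside, , drop = FALSE]]
    is_max <- is_max & sm[arr] > vals
  }
  arr <- arr[is_max, , drop = FALSE]
  if (!nrow(arr)) return(empty_seed_matrix())
  suv <- sm[arr]
  ord <- order(suv, decreasing = TRUE)
  arr <- arr[ord, , drop = FALSE]; suv <- suv[ord]
  # greedy dedup within one smoothing-kernel radius
  world <- sweep(sweep(arr - 1, 2, image$spacing, `*`), 2, image$origin, `+`)
  keep <- logical(nrow(arr))
  r2 <- (4 * cfg$smoothing_sigma_mm)^2  # kernel truncation radius
  for (i in seq_len(nrow(arr))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dists <- rowSums(sweep(world[keep, , drop = FALSE], 2, world[i, ], `-`)^2)
    keep[i] <- all(dists > r2)
  }
  out <- arr[keep, , drop = FALSE] - 1L
  attr(out, "suv") <- suv[keep]
  out
}

empty_seed_matrix <- function() {
  out <- matrix(integer(), ncol = 3)
  attr(out, "suv") <- numeric()
  out
}

# Hill-climb a 0-based voxel index to the 26-neighbourhood local maximum of sm.
hill_climb <- function(sm, seed0) {
  d <- dim(sm)
  cur <- seed0 + 1L
  offs <- neighborhood26()
  repeat {
    nb <- sweep(offs, 2, cur, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    vals <- sm[nb]
    if (!length(vals) || max(vals) <= sm[matrix(cur, 1)]) break
    cur <- nb[which.max(vals), ]
  }
  cur - 1L
}

#' Segment one lesion by radial gradient analysis
#'
#' Builds a star-convex segment around a seed: the seed is first hill-climbed
#' to the local maximum of the smoothed SUV volume, then along each of the
#' icosphere ray directions the boundary radius is placed at the most
#' negative directional derivative of the smoothed SUV profile within
#' `max_ray_length_mm`. Radii are median-filtered over neighbouring
#' directions, voxels whose centre falls inside the resulting star-convex
#' region form the mask, and the 26-connected component containing the seed
#' is returned.
#'
#' Errors with `"not a lesion"` when at least half of the rays show no
#' negative-gradient extremum (flat region).
#'
#' @param image A [suv_image()].
#' @param seed 0-based voxel index (length 3).
#' @param cfg A [segmentation_config()].
#' @param lesion_id,patient_id,organ_label Metadata carried into the segment.
#' @param smoothed Optional precomputed smoothed volume (as from the same
#'   configuration), to avoid recomputation when segmenting many seeds.
#' @return A `lesion_segment`: list with `lesion_id`, `patient_id`,
#'   `organ_label`, `voxels` (n x 3, 0-based), `suv`, `volume_ml`, `seed`.
#' @export
segment_lesion <- function(image, seed, cfg = segmentation_config(),
                           lesion_id = 1L, patient_id = 1L,
                           organ_label = NA_character_, smoothed = NULL) {
  d <- dim(image$values)
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || any(seed < 0) || any(seed >= d))
    stopf("seed outside grid")
  sm <- smoothed %||% smooth_image(image, cfg)
  seed <- hill_climb(sm, seed)
  if (sm[matrix(seed + 1L, 1)] <= cfg$background_fallback_threshold)
    stopf("not a lesion: seed SUV below background threshold")
  center <- image$origin + seed * image$spacing

  dirs <- icosphere_directions(cfg$n_ray_subdivision)
  radii_grid <- seq(0, cfg$max_ray_length_mm, by = cfg$ray_step_mm)
  n_r <- length(radii_grid)
  # sample all rays at once: (n_dirs * n_r) x 3 voxel coords
  pts <- dirs[rep(seq_len(nrow(dirs)), each = n_r), ] *
    rep(radii_grid, nrow(dirs))
  pts <- sweep(pts, 2, center, `+`)
  vox <- sweep(pts, 2, image$origin, `-`)
  vox <- sweep(vox, 2, image$spacing, `/`)
  prof <- matrix(trilinear(sm, vox), nrow = n_r)  # one column per direction
  dprof <- (prof[-1, , drop = FALSE] - prof[-n_r, , drop = FALSE]) /
    cfg$ray_step_mm
  grad_tol <- 1e-8
  min_idx <- apply(dprof, 2, which.min)
  min_grad <- dprof[cbind(min_idx, seq_len(ncol(dprof)))]
  boundary <- ifelse(min_grad < -grad_tol,
                     radii_grid[min_idx] + cfg$ray_step_mm / 2, NA_real_)
  if (mean(is.na(boundary)) >= 0.5)
    stopf("not a lesion: no negative SUV gradient on >= 50%% of rays")
  # per-ray edge-blur estimate: for an erf edge of amplitude A the peak
  # gradient magnitude is A / (sigma * sqrt(2*pi))
  amp <- vapply(seq_len(ncol(prof)), function(d) {
    i <- min_idx[d]
    max(prof[seq_len(i), d]) - min(prof[i:n_r, d])
  }, numeric(1))
  sigma_d <- amp / (sqrt(2 * pi) * pmax(-min_grad, 1e-12))
  sigma_est <- stats::median(sigma_d[!is.na(boundary)], na.rm = TRUE)
  sigma_est <- min(max(sigma_est, cfg$smoothing_sigma_mm), 8)
  nbrs <- direction_neighbors(dirs, cfg$median_filter_neighbors)
  filtered <- vapply(seq_along(boundary), function(i) {
    vals <- c(boundary[i], boundary[nbrs[[i]]])
    stats::median(vals, na.rm = TRUE)
  }, numeric(1))
  filtered[is.na(filtered)] <- stats::median(filtered, na.rm = TRUE)
  if (cfg$curvature_correction) {
    # the max-gradient radius of a blurred sphere sits ~sigma^2 / R inside
    # the true boundary; invert r_obs = R - sigma^2 / R using the estimated
    # total edge blur (self-applied smoothing + scanner PSF)
    filtered <- (filtered + sqrt(filtered^2 + 4 * sigma_est^2)) / 2
  }

  # voxel membership: centre within the (direction-interpolated) boundary
  rmax <- max(filtered)
  lo <- pmax(floor((center - rmax - image$origin) / image$spacing), 0)
  hi <- pmin(ceiling((center + rmax - image$origin) / image$spacing), d - 1)
  grid <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                z = lo[3]:hi[3]))
  world <- voxel_to_world(image, grid)
  u <- sweep(world, 2, center, `-`)
  r <- sqrt(rowSums(u^2))
  inside <- r <= 1e-9
  far <- which(!inside & r <= rmax)
  if (length(far)) {
    un <- u[far, , drop = FALSE] / r[far]
    nearest <- max.col(un %*% t(dirs), ties.method = "first")
    inside[far] <- r[far] <= filtered[nearest]
  }
  vox_in <- grid[inside, , drop = FALSE]
  if (!nrow(vox_in)) vox_in <- matrix(seed, nrow = 1)
  if (!any(vox_in[, 1] == seed[1] & vox_in[, 2] == seed[2] &
           vox_in[, 3] == seed[3]))
    vox_in <- rbind(vox_in, seed)
  vox_in <- connected_component(vox_in, seed)
  suv <- image$values[vox_in + 1L]
  new_lesion_segment(lesion_id, patient_id, organ_label, vox_in, suv,
                     voxel_volume_ml(image), seed = seed)
}

new_lesion_segment <- function(lesion_id, patient_id, organ_label, voxels,
                               suv, vox_ml, seed = NULL) {
  structure(list(lesion_id = lesion_id, patient_id = patient_id,
                 organ_label = organ_label,
                 voxels = matrix(as.integer(voxels), ncol = 3),
                 suv = as.numeric(suv),
                 volume_ml = nrow(voxels) * vox_ml, seed = seed),
            class = "lesion_segment")
}

#' @export
print.lesion_segment <- function(x, ...) {
  cat(sprintf("<lesion_segment> id %s (%s): %d voxels, %.3f ml, SUVmax %.2f\n",
              x$lesion_id, x$organ_label, nrow(x$voxels), x$volume_ml,
              max(x$suv)))
  invisible(x)
}

# 26-connected component of a voxel set (n x 3, 0-based) containing `seed`.
connected_component <- function(voxels, seed) {
  if (nrow(voxels) <= 1L) return(voxels)
  lo <- apply(voxels, 2, min)
  dims <- apply(voxels, 2, max) - lo + 1L
  mask <- array(FALSE, dims)
  rel <- sweep(voxels, 2, lo, `-`) + 1L
  mask[rel] <- TRUE
  comp <- array(FALSE, dims)
  s <- seed - lo + 1L
  comp[matrix(s, 1)] <- TRUE
  offs <- neighborhood26()
  repeat {
    grown <- comp
    idx <- which(comp, arr.ind = TRUE)
    for (m in seq_len(nrow(offs))) {
      nb <- sweep(idx, 2, offs[m, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      grown[nb[mask[nb], , drop = FALSE]] <- TRUE
    }
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  out <- which(comp, arr.ind = TRUE)
  sweep(out, 2, lo, `+`) - 1L
}

#' Extract the liver reference region
#'
#' Computes the liver reference SUV statistics over a spherical volume of
#' interest (VOI, default 3 cm diameter) centred at the lesion-free liver
#' voxel deepest inside the lesion-free liver (maximal erosion depth, i.e.
#' farthest from both lesions and the liver boundary). If no sphere of the
#' requested size fits, all lesion-free liver voxels are used with a warning.
#'
#' @param image A [suv_image()].
#' @param liver_mask Logical array marking liver parenchyma.
#' @param lesion_mask Logical array (or `NULL`) marking lesion voxels to
#'   exclude.
#' @param voi_diameter_mm VOI diameter in mm.
#' @return A `liver_reference`: list with `liver_suv_mean`, `liver_suv_max`,
#'   `reference_voxel_count`, `used_fallback`.
#' @export
extract_liver_reference <- function(image, liver_mask, lesion_mask = NULL,
                                    voi_diameter_mm = 30) {
  free <- liver_mask
  if (!is.null(lesion_mask)) free <- free & !lesion_mask
  if (!any(free)) stopf("no lesion-free liver voxels")
  depth <- erosion_depth(free)
  center_idx <- which(depth == max(depth))[1]
  center <- arrayInd(center_idx, dim(free)) - 1L
  radius <- voi_diameter_mm / 2
  fits <- max(depth) * min(image$spacing) >= radius
  if (fits) {
    d <- dim(free)
    cw <- image$origin + center * image$spacing
    half <- ceiling(radius / image$spacing)
    lo <- pmax(center - half, 0); hi <- pmin(center + half, d - 1)
    grid <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                  z = lo[3]:hi[3]))
    world <- voxel_to_world(image, grid)
    sel <- rowSums(sweep(world, 2, cw, `-`)^2) <= radius^2
    grid <- grid[sel, , drop = FALSE]
    voi <- grid[free[grid + 1L], , drop = FALSE]
  } else {
    warnf("no lesion-free liver sphere of %.0f mm fits; using all lesion-free liver voxels",
          voi_diameter_mm)
    voi <- which(free, arr.ind = TRUE) - 1L
  }
  suv <- image$values[voi + 1L]
  new_liver_reference(mean(suv), max(suv), nrow(voi), !fits)
}

new_liver_reference <- function(mean, max, count, fallback = FALSE) {
  if (!is.finite(mean) || mean <= 0) stopf("liver reference SUVmean must be > 0")
  structure(list(liver_suv_mean = mean, liver_suv_max = max,
                 reference_voxel_count = count, used_fallback = fallback),
            class = "liver_reference")
}

#' Construct a liver reference directly from known statistics
#' @param liver_suv_mean,liver_suv_max Reference SUV statistics.
#' @param reference_voxel_count Voxel count backing the statistics.
#' @return A `liver_reference`.
#' @export
liver_reference <- function(liver_suv_mean, liver_suv_max = liver_suv_mean,
                            reference_voxel_count = NA_integer_) {
  if (liver_suv_max < liver_suv_mean)
    stopf("liver_suv_max must be >= liver_suv_mean")
  new_liver_reference(liver_suv_mean, liver_suv_max, reference_voxel_count)
}

# L-infinity erosion depth (in voxels) of a logical mask: the number of
# 26-neighbourhood erosions a voxel survives.
erosion_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  offs <- neighborhood26()
  d <- dim(mask)
  while (any(cur)) {
    depth[cur] <- depth[cur] + 1L
    idx <- which(cur, arr.ind = TRUE)
    keep <- rep(TRUE, nrow(idx))
    for (m in seq_len(nrow(offs))) {
      nb <- sweep(idx, 2, offs[m, ], `+`)
      inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      val <- rep(FALSE, nrow(idx))
      val[inside] <- cur[nb[inside, , drop = FALSE]]
      keep <- keep & val
    }
    nxt <- array(FALSE, d)
    nxt[idx[keep, , drop = FALSE]] <- TRUE
    cur <- nxt
  }
  depth
}

#' Build lesion segments from an integer label map
#'
#' The primary pipeline path when ground-truth (or externally supplied) label
#' maps are available: each positive label except [LIVER_LABEL] becomes one
#' lesion segment.
#'
#' @param image A [suv_image()].
#' @param label_map Integer array aligned with `image`.
#' @param organ_labels Optional named character vector / list mapping
#'   lesion id (as character) to organ label.
#' @param patient_id Patient identifier carried into each segment.
#' @return List of `lesion_segment` objects.
#' @export
lesions_from_labelmap <- function(image, label_map, organ_labels = NULL,
                                  patient_id = 1L) {
  stopifnot(all(dim(label_map) == dim(image$values)))
  ids <- sort(setdiff(unique(as.integer(label_map)), c(0L, LIVER_LABEL)))
  ids <- ids[ids > 0]
  vox_ml <- voxel_volume_ml(image)
  lapply(ids, function(id) {
    vox <- which(label_map == id, arr.ind = TRUE) - 1L
    organ <- if (!is.null(organ_labels)) {
      as.character(organ_labels[[as.character(id)]] %||% NA_character_)
    } else NA_character_
    new_lesion_segment(id, patient_id, organ, vox,
                       image$values[vox + 1L], vox_ml)
  })
}
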