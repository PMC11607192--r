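# Independent brute-force oracles and small fixture builders shared across
# the suite. These deliberately avoid the package's own computational paths.

# Plain-loop central-moment statistics (population SD).
brute_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  list(mean = m, max = max(x), sd = sqrt(m2),
       skewness = if (m2 > 0 && n >= 3) m3 / m2^1.5 else NA_real_,
       kurtosis = if (m2 > 0 && n >= 3) m4 / m2^2 - 3 else NA_real_,
       cv = if (m > 0) sqrt(m2) / m else NA_real_)
}

# Brute-force recomputation of all 14 intra-lesional indices from the raw
# voxel SUV list, lesion volume and liver reference.
brute_lesion_features <- function(suv, volume_ml, liver_mean, liver_max) {
  s <- brute_stats(suv)
  c(volume_ml = volume_ml, suv_mean = s$mean, suv_max = s$max, sd_suv = s$sd,
    skewness = s$skewness, kurtosis = s$kurtosis, cv_suv = s$cv,
    max_over_mean = s$max / s$mean,
    excess_over_mean = (s$max - s$mean) / s$mean,
    receptor_expression = volume_ml * s$mean,
    liver_corrected_receptor_expression = volume_ml * s$mean / liver_mean,
    liver_corrected_suv_mean = s$mean / liver_mean,
    liver_corrected_suv_max = s$max / liver_max,
    liver_corrected_suv_max_lmean = s$max / liver_mean)
}

# Double-loop IPCW concordance; weights from a supplied censoring survival
# function evaluated with left limits.
brute_uno_c <- function(time, event, score, tau) {
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gleft <- function(t) {
    idx <- which(cfit$time < t)
    if (!length(idx)) 1 else cfit$surv[max(idx)]
  }
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    w <- 1 / Gleft(time[i])^2
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      conc <- if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
      num <- num + w * conc
      den <- den + w
    }
  }
  if (den == 0) NA_real_ else num / den
}

dice_coef <- function(a, b) {
  ka <- paste(a[, 1], a[, 2], a[, 3])
  kb <- paste(b[, 1], b[, 2], b[, 3])
  2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
}

# Single-sphere phantom fixture (no liver) centred in a cubic grid.
sphere_phantom <- function(radius_mm, fwhm = 6, spacing = 2, grid = 48,
                           suv = 10, noise = 0.5, bg = 0.5, bg_sd = 0.1,
                           seed = 7, center = NULL) {
  center <- center %||% rep((grid - 1) * spacing / 2, 3)
  sp <- phantom_spec(grid_shape = rep(grid, 3), voxel_spacing = spacing,
                     background_suv_mean = bg, background_suv_sd = bg_sd,
                     liver_semi_axes = NULL, psf_fwhm_mm = fwhm,
                     lesions = list(lesion_spec(center = center,
                                                radius = radius_mm,
                                                target_suv_mean = suv,
                                                target_suv_sd = noise,
                                                organ_label = "soft_tissue")))
  generate_phantom(sp, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random lesion segment with a plausible SUV histogram.
random_segment <- function(id, n_vox = NULL, vox_ml = 0.027, pid = 1L) {
  n_vox <- n_vox %||% sample(5:200, 1)
  suv <- pmax(stats::rgamma(n_vox, shape = 4, rate = 0.5), 0)
  organ <- sample(c("liver", "bone", "node", "soft_tissue"), 1)
  vox <- cbind(seq_len(n_vox), 1L, 1L)
  ssthet:::new_lesion_segment(id, pid, organ, vox, suv, vox_ml)
}

# Proportional-hazards survival data with independent uniform censoring.
sim_ph_data <- function(n, beta, X = NULL, h0 = 0.05, cens_max = NULL,
                        seed = 1) {
  set.seed(seed)
  p <- length(beta)
  if (is.null(X)) X <- matrix(rnorm(n * p), n, p,
                              dimnames = list(NULL, paste0("f", seq_len(p))))
  lp <- as.numeric(X %*% beta)
  t_ev <- rexp(n, h0 * exp(lp))
  t_c <- if (is.null(cens_max)) rep(Inf, n) else runif(n, 0, cens_max)
  list(X = X, time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}
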