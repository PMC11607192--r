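#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic cohort: multi-lesion patients with
#' liver / bone / node / soft-tissue lesions (organ mix weighted toward
#' hepatic and osseous disease, as is typical for metastatic
#' well-differentiated neuroendocrine tumors), lesion sizes spanning the
#' metabolic-volume eligibility threshold, physiologic liver background,
#' scanner-like PSF blur, and proportional-hazards survival outcomes for a
#' 24-month time-to-progression endpoint and overall survival.
#'
#' @param n_patients Number of patients.
#' @param lesions_per_patient Integer range `c(min, max)`; patients need at
#'   least 2 lesions to be analysis-eligible (a single-lesion configuration
#'   is generated but flagged).
#' @param organ_probs Named sampling probabilities for the four organ labels.
#' @param lesion_radius_mm Range of lesion radii (mm).
#' @param lesion_suv_mean Range of lesion core SUVs.
#' @param lesion_suv_sd_frac Voxel noise SD as a fraction of the lesion SUV.
#' @param radial_gradient_range Range of core-to-rim SUV drop fractions.
#' @param phantom Baseline [phantom_spec()] providing grid, background,
#'   liver and PSF settings (its `lesions` field is ignored).
#' @param ttp_spec,os_spec [survival_sim_spec()] generators for the two
#'   endpoints.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 20,
                          lesions_per_patient = c(2, 8),
                          organ_probs = c(liver = 0.386, bone = 0.345,
                                          node = 0.135, soft_tissue = 0.133),
                          lesion_radius_mm = c(4, 16),
                          lesion_suv_mean = c(4, 25),
                          lesion_suv_sd_frac = 0.08,
                          radial_gradient_range = c(0, 0.3),
                          phantom = phantom_spec(),
                          ttp_spec = survival_sim_spec(
                            true_coefficients = c(
                              total_receptor_expression = log(1.75),
                              mean_liver_corrected_suv_mean = log(1.5)),
                            baseline_hazard = log(2) / 19,
                            censoring_max = 36,
                            admin_truncation_months = 24,
                            endpoint = "TTP24"),
                          os_spec = survival_sim_spec(
                            true_coefficients = c(
                              total_receptor_expression = log(1.5),
                              mean_skewness = log(1.5)),
                            baseline_hazard = 0.02,
                            censoring_max = 61,
                            endpoint = "OS")) {
  stopifnot(n_patients >= 1, length(lesions_per_patient) == 2,
            lesions_per_patient[1] >= 1,
            lesions_per_patient[2] >= lesions_per_patient[1])
  organ_probs <- organ_probs / sum(organ_probs)
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 organ_probs = organ_probs,
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_suv_mean = lesion_suv_mean,
                 lesion_suv_sd_frac = lesion_suv_sd_frac,
                 radial_gradient_range = radial_gradient_range,
                 phantom = phantom, ttp_spec = ttp_spec, os_spec = os_spec),
            class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#'
#' Maps a flat YAML document onto [cohort_config()]: top-level keys mirror
#' that function's arguments; the nested blocks `phantom`, `ttp` and `os`
#' mirror [phantom_spec()] and [survival_sim_spec()]. Keys that are absent
#' keep their defaults, so a minimal file like
#' `n_patients: 10` is valid.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), setdiff(names(formals(cohort_config)),
                                        c("phantom", "ttp_spec", "os_spec")))]
  if (!is.null(args$organ_probs)) args$organ_probs <- unlist(args$organ_probs)
  if (!is.null(y$phantom))
    args$phantom <- do.call(phantom_spec,
                            y$phantom[intersect(names(y$phantom),
                                                names(formals(phantom_spec)))])
  sub_spec <- function(block, endpoint) {
    a <- block[intersect(names(block), names(formals(survival_sim_spec)))]
    if (!is.null(a$true_coefficients))
      a$true_coefficients <- unlist(a$true_coefficients)
    a$endpoint <- endpoint
    do.call(survival_sim_spec, a)
  }
  if (!is.null(y$ttp)) args$ttp_spec <- sub_spec(y$ttp, "TTP24")
  if (!is.null(y$os)) args$os_spec <- sub_spec(y$os, "OS")
  do.call(cohort_config, args)
}

# Draw non-overlapping lesion specs for one patient; liver lesions are
# centred inside the liver ellipsoid, others outside it.
draw_lesion_specs <- function(config, n_lesions) {
  ph <- config$phantom
  extent <- (ph$grid_shape - 1) * ph$voxel_spacing
  specs <- list()
  centers <- matrix(numeric(), ncol = 3)
  radii <- numeric()
  organs <- sample(names(config$organ_probs), n_lesions, replace = TRUE,
                   prob = config$organ_probs)
  for (i in seq_len(n_lesions)) {
    r <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
    placed <- FALSE
    for (attempt in 1:300) {
      ctr <- if (organs[i] == "liver" && !is.null(ph$liver_center)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        rad <- runif(1)^(1 / 3) * 0.8
        ph$liver_center + u * rad * ph$liver_semi_axes
      } else {
        runif(3, r + ph$voxel_spacing, extent - r - ph$voxel_spacing)
      }
      if (any(ctr - r < 0) || any(ctr + r > extent)) next
      if (organs[i] != "liver" && !is.null(ph$liver_center)) {
        inl <- sum(((ctr - ph$liver_center) / (ph$liver_semi_axes + r))^2)
        if (inl <= 1) next
      }
      if (nrow(centers)) {
        dd <- sqrt(rowSums(sweep(centers, 2, ctr, `-`)^2))
        if (any(dd <= radii + r + max(ph$voxel_spacing))) next
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
      suv_mean <- runif(1, config$lesion_suv_mean[1], config$lesion_suv_mean[2])
      specs[[i]] <- lesion_spec(
        center = ctr, radius = r, organ_label = organs[i],
        target_suv_mean = suv_mean,
        target_suv_sd = suv_mean * config$lesion_suv_sd_frac,
        radial_gradient_fraction =
          runif(1, config$radial_gradient_range[1],
                config$radial_gradient_range[2]))
      placed <- TRUE
      break
    }
    if (!placed) stopf("could not place lesion %d without overlap", i)
  }
  specs
}

#' Generate a synthetic cohort with ground truth
#'
#' For each patient: draws lesion specifications, generates the PET phantom,
#' extracts lesion segments from the ground-truth label map, computes the
#' liver reference and the lesion feature table; then reduces to the
#' patient-level feature table (cohort-wide heterogeneity scaling) and
#' simulates the two survival endpoints from the configured
#' proportional-hazards models. Fully reproducible from `(config, seed)`.
#'
#' Patients generated with a single lesion are flagged ineligible
#' (`eligible_patient = FALSE`) with a warning: inter-lesional heterogeneity
#' is undefined for single-lesion patients, so they are excluded from the
#' modeled cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @param keep_images Keep the per-patient images / label maps in the bundle
#'   (set `FALSE` to save memory for large cohorts).
#' @return A `cohort_bundle`: list with `patients` (per-patient list of
#'   `image`, `label_map`, `liver_mask`, `truth`, `eligible_patient`),
#'   `lesion_table`, `patient_table`, `liver_refs`, `survival` (data frame,
#'   both endpoints), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            keep_images = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- vector("list", config$n_patients)
  lesion_tables <- vector("list", config$n_patients)
  liver_refs <- list()
  for (p in seq_len(config$n_patients)) {
    pseed <- derive_seed(seed, paste0("patient", p))
    res <- with_seed(pseed, {
      rng <- config$lesions_per_patient[1]:config$lesions_per_patient[2]
      n_les <- if (length(rng) == 1L) rng else sample(rng, 1)
      specs <- draw_lesion_specs(config, n_les)
      ph <- config$phantom
      ph$lesions <- specs
      phantom <- generate_phantom(ph, seed = derive_seed(pseed, "phantom"))
      organ_map <- setNames(as.list(phantom$truth$organ_label),
                            as.character(phantom$truth$lesion_id))
      segs <- lesions_from_labelmap(phantom$image, phantom$label_map,
                                    organ_labels = organ_map,
                                    patient_id = p)
      lesion_any <- phantom$label_map > 0L & phantom$label_map != LIVER_LABEL
      liver <- extract_liver_reference(phantom$image, phantom$liver_mask,
                                       lesion_any)
      list(phantom = phantom, segs = segs, liver = liver, n_les = n_les)
    })
    eligible_patient <- res$n_les >= 2
    if (!eligible_patient)
      warnf("patient %d has a single lesion and is flagged ineligible", p)
    lesion_tables[[p]] <- lesion_feature_table(res$segs, res$liver)
    liver_refs[[as.character(p)]] <- res$liver
    patients[[p]] <- list(
      patient_id = p,
      image = if (keep_images) res$phantom$image else NULL,
      label_map = if (keep_images) res$phantom$label_map else NULL,
      liver_mask = if (keep_images) res$phantom$liver_mask else NULL,
      truth = res$phantom$truth,
      eligible_patient = eligible_patient)
  }
  lesion_table <- do.call(rbind, lesion_tables)
  patient_table <- compute_patient_features(lesion_table, liver_refs)
  patient_table$eligible_patient <-
    vapply(patients, `[[`, logical(1), "eligible_patient")[
      match(patient_table$patient_id, seq_len(config$n_patients))]
  ttp <- simulate_survival(patient_table, config$ttp_spec,
                           seed = derive_seed(seed, "ttp"))
  os <- simulate_survival(patient_table, config$os_spec,
                          seed = derive_seed(seed, "os"))
  structure(list(patients = patients, lesion_table = lesion_table,
                 patient_table = patient_table, liver_refs = liver_refs,
                 survival = rbind(ttp, os), config = config, seed = seed),
            class = "cohort_bundle")
}

#' Write a cohort bundle to disk
#'
#' Writes per-patient SUV volumes and label maps as NIfTI, plus the lesion,
#' patient, truth and survival tables as CSV; tables are written atomically
#' and without row names so repeated runs are byte-identical.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (p in bundle$patients) {
    if (!is.null(p$image)) {
      f1 <- file.path(dir, sprintf("suv_p%03d.nii.gz", p$patient_id))
      write_suv_nifti(p$image, f1)
      f2 <- file.path(dir, sprintf("labels_p%03d.nii.gz", p$patient_id))
      write_labelmap_nifti(p$label_map, f2, p$image$spacing)
      paths <- c(paths, f1, f2)
    }
  }
  truth <- do.call(rbind, lapply(bundle$patients, function(p) {
    if (nrow(p$truth)) cbind(patient_id = p$patient_id, p$truth) else NULL
  }))
  tabs <- list(lesion_features.csv = bundle$lesion_table,
               patient_features.csv = bundle$patient_table,
               lesion_truth.csv = truth,
               survival.csv = bundle$survival)
  for (nm in names(tabs)) {
    f <- file.path(dir, nm)
    write_atomic(function(pth) write.csv(tabs[[nm]], pth, row.names = FALSE),
                 f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
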