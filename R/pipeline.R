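#' Validate pipeline inputs
#'
#' Checks NIfTI geometry agreement between an SUV image and its label map
#' (shape; spacing within 1e-4 mm), SUV nonnegativity, the organ-label
#' vocabulary, and the survival-table schema. Failures are collected into a
#' machine-readable report rather than raised.
#'
#' @param image A [suv_image()] or `NULL`.
#' @param label_map List with `values`/`spacing` (as from
#'   [read_labelmap_nifti()]) or an integer array, or `NULL`.
#' @param survival Survival data frame or `NULL`.
#' @param organ_labels Optional vector of organ labels to check against the
#'   vocabulary `liver`, `bone`, `node`, `soft_tissue`.
#' @return Data frame report: `check`, `ok`, `message`; attribute `ok` is
#'   `TRUE` when no check failed.
#' @export
validate_inputs <- function(image = NULL, label_map = NULL, survival = NULL,
                            organ_labels = NULL) {
  rep <- list()
  add <- function(check, ok, message = "") {
    rep[[length(rep) + 1]] <<- data.frame(check = check, ok = ok,
                                          message = message,
                                          stringsAsFactors = FALSE)
  }
  if (!is.null(image)) {
    add("suv_nonnegative", all(image$values >= 0),
        if (any(image$values < 0)) "negative SUV voxel(s)" else "")
    add("suv_finite", all(is.finite(image$values)),
        if (any(!is.finite(image$values))) "non-finite SUV voxel(s)" else "")
  }
  if (!is.null(image) && !is.null(label_map)) {
    lv <- if (is.list(label_map)) label_map$values else label_map
    lsp <- if (is.list(label_map)) label_map$spacing else image$spacing
    same_shape <- identical(dim(lv), dim(image$values))
    add("geometry_shape", same_shape,
        if (!same_shape) "geometry mismatch: image and label map shapes differ"
        else "")
    sp_ok <- all(abs(lsp - image$spacing) <= 1e-4)
    add("geometry_spacing", sp_ok,
        if (!sp_ok) "geometry mismatch: voxel spacings differ" else "")
  }
  if (!is.null(label_map)) {
    lv <- if (is.list(label_map)) label_map$values else label_map
    add("labels_integer", all(lv == round(lv)) && all(lv >= 0),
        "label map must contain nonnegative integers")
  }
  if (!is.null(organ_labels)) {
    vocab <- c("liver", "bone", "node", "soft_tissue")
    bad <- setdiff(stats::na.omit(unique(organ_labels)), vocab)
    add("organ_vocabulary", !length(bad),
        if (length(bad)) sprintf("unknown organ label(s): %s",
                                 paste(bad, collapse = ", ")) else "")
  }
  if (!is.null(survival)) {
    need <- c("patient_id", "endpoint", "time_months", "event")
    have <- all(need %in% names(survival))
    add("survival_schema", have,
        if (!have) sprintf("missing column(s): %s",
                           paste(setdiff(need, names(survival)),
                                 collapse = ", ")) else "")
    if (have) {
      add("survival_times_positive", all(survival$time_months > 0),
          "times must be > 0 months")
      add("survival_event_binary", all(survival$event %in% c(0, 1)),
          "event must be 0/1")
      ttp <- survival$time_months[survival$endpoint == "TTP24"]
      add("ttp_truncated", !length(ttp) || all(ttp <= 24),
          "TTP24 times must be <= 24 months")
    }
  }
  out <- do.call(rbind, rep)
  out$message[out$ok] <- ""
  attr(out, "ok") <- all(out$ok)
  out
}

#' Run the whole analysis pipeline on one cohort
#'
#' Orchestrates simulate (or ingest) -> features -> aggregate -> survival as
#' one reproducible run: generates (or loads) the cohort, writes the image
#' and table outputs, estimates the Kaplan-Meier curves, screens all
#' patient-level predictors univariably, selects the LASSO penalty by
#' repeated cross-validated concordance and reports the bootstrap
#' optimism-corrected concordance for each endpoint, and writes a manifest
#' recording row counts, conventions and the configuration hash.
#'
#' @param config A [cohort_config()] (synthetic mode).
#' @param seed Master seed; every stage derives its stream from it.
#' @param out_dir Output directory.
#' @param cv_iterations,n_folds,n_bootstrap Model-selection effort; the
#'   underlying functions default to 1000 repeated threefold CV iterations
#'   and 1000 bootstrap resamples, scaled down here for routine runs.
#' @param n_lambda Lambda grid size.
#' @param write_images Write per-patient NIfTI volumes.
#' @param endpoints Endpoints to model.
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         out_dir = tempfile("ssthet_run"),
                         cv_iterations = 50, n_folds = 3, n_bootstrap = 200,
                         n_lambda = 50, write_images = TRUE,
                         endpoints = c("TTP24", "OS")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  withCallingHandlers({
    bundle <- generate_cohort(config, seed = seed,
                              keep_images = write_images)
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (!write_images) {
    for (i in seq_along(bundle$patients)) bundle$patients[[i]]$image <- NULL
  }
  write_cohort(bundle, out_dir)

  feats <- bundle$patient_table
  fnames <- patient_feature_names()
  X_all <- as.matrix(feats[, fnames])
  X_all <- cbind(X_all, liver_dominant = as.numeric(feats$liver_dominant))
  models <- list()
  for (ep in endpoints) {
    sv <- bundle$survival[bundle$survival$endpoint == ep, , drop = FALSE]
    sv <- sv[match(feats$patient_id, sv$patient_id), , drop = FALSE]
    keep <- feats$eligible_patient & complete.cases(X_all) &
      !is.na(sv$time_months)
    X <- X_all[keep, , drop = FALSE]
    tm <- sv$time_months[keep]; ev <- sv$event[keep]
    tau <- if (ep == "TTP24") 24 else max(tm)

    km <- km_estimate(tm, ev)
    write_atomic(function(p) write.csv(as.data.frame(km), p,
                                       row.names = FALSE),
                 file.path(out_dir, sprintf("km_%s.csv", tolower(ep))))

    screen <- suppressWarnings(
      univariable_screen(as.data.frame(X), tm, ev, tau = tau))
    write_atomic(function(p) write.csv(screen, p, row.names = FALSE),
                 file.path(out_dir, sprintf("univariable_%s.csv",
                                            tolower(ep))))

    if (sum(ev) < n_folds) {
      warnings_log <- c(warnings_log, sprintf(
        "endpoint %s: only %d event(s); multivariable model skipped", ep,
        sum(ev)))
      next
    }
    grid <- cox_lambda_grid(X, tm, ev, n_lambda = n_lambda)
    cv <- suppressWarnings(select_lambda_cv(
      X, tm, ev, lambda = grid, n_iterations = cv_iterations,
      n_folds = n_folds, tau = tau,
      seed = derive_seed(seed, paste0("cv", ep))))
    model <- suppressWarnings(optimism_corrected_c(
      X, tm, ev, lambda_star = cv$lambda_star, n_bootstrap = n_bootstrap,
      tau = tau, seed = derive_seed(seed, paste0("boot", ep))))
    mj <- list(endpoint = ep, n = nrow(X), n_events = sum(ev),
               lambda = model$lambda,
               cv_iterations = cv$n_iterations, cv_folds = cv$n_folds,
               selected_features = as.list(model$coefficients),
               apparent_c = model$apparent_c,
               corrected_c = model$corrected_c,
               ci = model$ci, better_than_chance = model$better_than_chance,
               n_bootstrap = model$n_bootstrap, tau = tau, seed = seed)
    write_atomic(function(p) jsonlite::write_json(
      mj, p, auto_unbox = TRUE, digits = NA),
      file.path(out_dir, sprintf("model_%s.json", tolower(ep))))
    models[[ep]] <- model
  }

  cfg_file <- tempfile(fileext = ".rds")
  saveRDS(rapply(unclass(config), function(x) x, how = "replace"), cfg_file,
          version = 2)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  manifest <- list(
    artifact_version = as.character(utils::packageVersion("ssthet")),
    config_hash = cfg_hash,
    seed = seed,
    counts = list(
      patients = nrow(feats),
      eligible_patients = sum(feats$eligible_patient),
      lesions = nrow(bundle$lesion_table),
      eligible_lesions = sum(bundle$lesion_table$volume_ml >=
                               VOLUME_FILTER_CC),
      quantitative_features = length(fnames),
      models = length(models)),
    conventions = list(
      sd_divisor_voxel = "n", sd_divisor_lesion = "n-1",
      kurtosis = "excess", heterogeneity_scaling = "minmax",
      volume_filter_cc = VOLUME_FILTER_CC,
      liver_dominance_threshold = 0.5),
    warnings = warnings_log)
  write_atomic(function(p) jsonlite::write_json(
    manifest, p, auto_unbox = TRUE, digits = NA),
    file.path(out_dir, "manifest.json"))
  structure(c(manifest, list(out_dir = out_dir, models = models)),
            class = "run_manifest")
}

#' Load a provided-masks cohort
#'
#' Ingests externally supplied SUV volumes and lesion label maps together
#' with a finished survival table, checking referential integrity: every
#' imaged patient must appear in the survival table.
#'
#' @param patients Data frame with columns `patient_id`, `image_path`,
#'   `labelmap_path`.
#' @param survival Survival data frame (schema as [validate_inputs()]).
#' @param organ_labels Optional list per patient id mapping lesion id to
#'   organ label.
#' @return List with `lesion_table`, `liver_refs`, `patient_table`,
#'   `survival`.
#' @export
ingest_cohort <- function(patients, survival, organ_labels = NULL) {
  stopifnot(all(c("patient_id", "image_path", "labelmap_path") %in%
                  names(patients)))
  missing <- setdiff(patients$patient_id, survival$patient_id)
  if (length(missing))
    stopf("survival table is missing patient(s): %s",
          paste(missing, collapse = ", "))
  lesion_tables <- list()
  liver_refs <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    img <- read_suv_nifti(patients$image_path[i])
    lm <- read_labelmap_nifti(patients$labelmap_path[i])
    rep <- validate_inputs(img, lm)
    if (!attr(rep, "ok"))
      stopf("invalid inputs for patient %s: %s", pid,
            paste(rep$message[!rep$ok], collapse = "; "))
    segs <- lesions_from_labelmap(img, lm$values,
                                  organ_labels = organ_labels[[as.character(pid)]],
                                  patient_id = pid)
    liver_mask <- lm$values == LIVER_LABEL
    lesion_any <- lm$values > 0L & lm$values != LIVER_LABEL
    if (!any(liver_mask))
      stopf("patient %s has no liver label (%d) in the label map", pid,
            LIVER_LABEL)
    liver <- extract_liver_reference(img, liver_mask, lesion_any)
    lesion_tables[[as.character(pid)]] <- lesion_feature_table(segs, liver)
    liver_refs[[as.character(pid)]] <- liver
  }
  lesion_table <- do.call(rbind, lesion_tables)
  patient_table <- compute_patient_features(lesion_table, liver_refs)
  list(lesion_table = lesion_table, liver_refs = liver_refs,
       patient_table = patient_table, survival = survival)
}
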