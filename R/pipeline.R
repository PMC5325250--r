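#' Pipeline configuration
#'
#' Bundles every stage's parameters: acquisition, cohort, VOI extraction,
#' deconvolution, registration, model policies, seed and output directory.
#' A config plus its seed reproduces a run byte-identically for the
#' deterministic stages. The default imaging grid (24 x 24 x 10 voxels of
#' 2 x 2 x 5 mm) is a desk-scale reduction of the generator default;
#' percentile features are computed from hundreds of lesion voxels either
#' way.
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param seed master RNG seed; per-patient seeds are derived from it.
#' @param acq named list of [acquisition_config()] overrides.
#' @param cohort named list of [cohort_config()] overrides.
#' @param voi named list: `z_thr`, `connectivity`.
#' @param deconv named list: `lambda` (tSVD cutoff).
#' @param registration named list: `radius` (translation search, voxels).
#' @param tree_policy mixed-quadrant policy for the published tree.
#' @param fit_models also fit backward-stepwise logistic + tree on the
#'   measured cohort.
#' @param write_maps write per-patient parameter maps as NIfTI.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 20170222,
                            acq = list(noise_sigma = 2),
                            cohort = list(grid_dim = c(24, 24, 10)),
                            voi = list(z_thr = 2, connectivity = 26),
                            deconv = list(lambda = 0.15),
                            registration = list(radius = 1),
                            tree_policy = "logistic_fallback",
                            fit_models = TRUE,
                            write_maps = FALSE) {
  cfg <- list(out_dir = out_dir, seed = seed, acq = acq, cohort = cohort,
              voi = voi, deconv = deconv, registration = registration,
              tree_policy = tree_policy, fit_models = fit_models,
              write_maps = write_maps)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a config list to validate.
#' @export
validate_pipeline_config <- function(cfg) {
  required <- c("out_dir", "seed", "acq", "cohort", "voi", "deconv",
                "registration", "tree_policy", "fit_models", "write_maps")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0)
    stop("missing required config field: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!cfg$tree_policy %in% c("logistic_fallback", "root_cbv", "majority"))
    stop("unknown tree_policy: ", cfg$tree_policy, call. = FALSE)
  invisible(cfg)
}

# derived, 32-bit-safe per-patient seed
patient_seed <- function(master, i) as.integer((master + 7919 * i) %% .Machine$integer.max)

#' Process one patient's simulated volumes into a feature record
#'
#' The measurement half of the pipeline: signal to concentration, reference
#' curve, leakage fit, CBV ratio, Tmax, translation registration of the ADC
#' map onto the DSC grid, DWI-based VOI extraction, percentile features and
#' lesion volumes.
#'
#' @param truth a [tissue_truth()] object (supplies ADC/DWI volumes and the
#'   contralateral reference ROI; the lesion mask itself is *not* used —
#'   the VOI is re-derived from the DWI).
#' @param dsc a `dsc_series` for the same patient.
#' @param voi_par,deconv_par,reg_par stage parameter lists (see
#'   [pipeline_config()]).
#' @return list with `features` (named vector), `volumes` (list),
#'   `maps` ([parameter_maps()]), `voi`, `registration`, `qc`.
#' @export
process_patient <- function(truth, dsc,
                            voi_par = list(z_thr = 2, connectivity = 26),
                            deconv_par = list(lambda = 0.15),
                            reg_par = list(radius = 1)) {
  conc <- signal_to_concentration(dsc, truth$brain_mask)
  ref <- reference_curve(conc, truth$contralateral_mask)
  fit <- fit_leakage(conc, ref)
  cbv <- compute_cbv_ratio(conc, fit, truth$contralateral_mask)
  aif <- attr(dsc, "aif") %||% ref
  tmax <- compute_tmax(conc, aif)

  reg <- register_translation(truth$adc_map, cbv_for_reg(cbv),
                              search_radius = reg_par$radius)
  adc <- reg$aligned
  voi <- extract_voi(truth$dwi, truth$brain_mask, truth$contralateral_mask,
                     z_thr = voi_par$z_thr,
                     connectivity = voi_par$connectivity)
  maps <- parameter_maps(cbv, fit$k2, tmax, adc,
                         valid = fit$valid & !is.na(adc))
  feats <- percentile_features(maps, voi)
  vox_ml <- prod(truth$voxmm) / 1000
  core <- core_volume(adc, truth$brain_mask, vox_ml)
  tm <- tmax_volume_and_reperfusion(tmax, NULL, vox_ml,
                                    mask = truth$brain_mask)
  list(features = feats,
       volumes = list(core_volume_ml = core,
                      tmax6_volume_ml = tm$tmax6_volume_ml,
                      global_reperfusion = tm$global_reperfusion),
       maps = maps, voi = voi, registration = reg[c("shift", "mi",
                                                    "low_confidence")],
       qc = list(n_invalid = sum(!conc$valid[truth$brain_mask]),
                 n_negative_cbv = attr(cbv, "n_negative"),
                 reference_peak = max(ref)))
}

# registration target: the CBV map with NAs filled (MI needs finite values)
cbv_for_reg <- function(cbv) {
  x <- cbv
  x[!is.finite(x)] <- 0
  x
}

#' Run the full synthetic pipeline
#'
#' synth -> maps -> features -> predict -> evaluate. Generates the cohort,
#' simulates each patient's DSC series on the configured grid, measures the
#' percentile features and volumes back from the images, applies the
#' published logistic score and classification tree, optionally refits both
#' models on the measured cohort, and evaluates everything against the
#' ground-truth PH labels. All outputs are written under `cfg$out_dir`
#' (cohort CSV, model and report JSON, MANIFEST, log; per-patient NIfTI
#' maps when `write_maps`). On a stage failure the partial outputs are kept
#' and the MANIFEST records which stages completed.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with `cohort` (measured table), `predictions`,
#'   `report`, `fitted`, and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), complete = FALSE, seed = cfg$seed)
  logf <- file.path(cfg$out_dir, "log.txt")
  log_line <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                        sprintf(...)),
                                file = logf, append = TRUE)
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(flush_manifest())

  acq <- do.call(acquisition_config, cfg$acq)
  ccfg <- do.call(cohort_config, utils::modifyList(list(seed = cfg$seed),
                                                   cfg$cohort))
  tab <- generate_cohort(ccfg)
  truth_tab <- tab
  log_line("synth: %d patients, %d PH, grid %s, seed %d", nrow(tab),
           sum(tab$ph_label), paste(ccfg$grid_dim, collapse = "x"), cfg$seed)
  utils::write.csv(truth_tab, file.path(cfg$out_dir, "cohort_truth.csv"),
                   row.names = FALSE)
  manifest$stages$synth <- TRUE; flush_manifest()

  if (cfg$write_maps)
    dir.create(file.path(cfg$out_dir, "maps"), showWarnings = FALSE)
  for (i in seq_len(nrow(tab))) {
    set.seed(patient_seed(cfg$seed, i))
    radius <- stats::runif(1, ccfg$lesion_radius_range[1],
                           ccfg$lesion_radius_range[2])
    truth <- tissue_truth(dim = ccfg$grid_dim, voxmm = ccfg$voxmm,
                          cbv10 = truth_tab$cbv_p10[i],
                          adc10 = truth_tab$adc_p10[i],
                          k2_90 = truth_tab$k2_p90[i],
                          lesion_radius_mm = radius)
    dsc <- simulate_dsc_signal(truth, acq)
    res <- process_patient(truth, dsc, cfg$voi, cfg$deconv, cfg$registration)
    tab$cbv_p10[i] <- res$features[["cbv_p10"]]
    tab$adc_p10[i] <- res$features[["adc_p10"]]
    tab$k2_p90[i] <- res$features[["k2_p90"]]
    tab$core_volume_ml[i] <- res$volumes$core_volume_ml
    tab$tmax6_volume_ml[i] <- res$volumes$tmax6_volume_ml
    if (cfg$write_maps) {
      for (mp in c("cbv_ratio", "k2", "tmax", "adc")) {
        m <- res$maps[[mp]]
        m[!is.finite(m)] <- 0
        write_nifti(m, file.path(cfg$out_dir, "maps",
                                 sprintf("%s_%s.nii.gz", tab$patient_id[i], mp)),
                    voxdim = truth$voxmm, datatype = "float32")
      }
    }
  }
  log_line("maps+features: measured %d records", nrow(tab))
  utils::write.csv(tab, file.path(cfg$out_dir, "cohort.csv"),
                   row.names = FALSE)
  manifest$stages$features <- TRUE; flush_manifest()

  pred <- apply_published_models(tab, tree_policy = cfg$tree_policy)
  utils::write.csv(pred$predictions, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)
  write_model_json(published_logistic(),
                   file.path(cfg$out_dir, "published_logistic.json"))
  write_model_json(published_tree(cfg$tree_policy),
                   file.path(cfg$out_dir, "published_tree.json"))
  manifest$stages$predict <- TRUE; flush_manifest()

  fitted <- NULL
  if (isTRUE(cfg$fit_models)) {
    cand <- c("cbv_p10", "adc_p10", "k2_p90", "core_volume_ml",
              "tmax6_volume_ml", "penumbral_pattern",
              "age", "sex_male", "hypertension", "diabetes", "sbp", "nihss",
              "iv_tpa", "thrombectomy")
    fitted <- list(
      logistic = fit_logistic_backward(tab, cand),
      tree = fit_tree(tab, c("cbv_p10", "adc_p10", "k2_p90")))
    write_model_json(fitted$logistic,
                     file.path(cfg$out_dir, "fitted_logistic.json"))
    write_model_json(fitted$tree, file.path(cfg$out_dir, "fitted_tree.json"))
    log_line("fit: logistic retained {%s}",
             paste(names(fitted$logistic$coefficients), collapse = ", "))
  }

  report <- pred$report
  jsonlite::write_json(lapply(report, unclass),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("evaluate: logistic overall %.1f%%, tree overall %.1f%%",
           report$logistic$report$overall_accuracy,
           report$tree$report$overall_accuracy)
  manifest$stages$evaluate <- TRUE
  manifest$complete <- TRUE
  flush_manifest()
  invisible(list(cohort = tab, predictions = pred$predictions,
                 report = report, fitted = fitted, out_dir = cfg$out_dir))
}

unclass_model <- function(model) {
  out <- unclass(model)
  if (inherits(model, "ph_tree") && model$type == "fitted")
    out$root <- model$root                      # nested lists serialize as-is
  out
}

write_model_json <- function(model, path) {
  jsonlite::write_json(list(class = class(model), model = unclass_model(model)),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Apply the published models to a feature table
#'
#' Appends the published logistic score and label and the published-tree
#' label to each row; when a `ph_label` column is present, also returns the
#' accuracy reports of both models.
#'
#' @param features a data.frame or path to a CSV with (at least) `cbv_p10`
#'   and `k2_p90` columns.
#' @param out_csv optional path for the augmented predictions CSV.
#' @param tree_policy mixed-quadrant policy (see [published_tree()]).
#' @return list with `predictions` (data.frame) and `report` (list of
#'   `ph_eval` for `logistic` and `tree`, or `NULL` without labels).
#' @export
apply_published_models <- function(features, out_csv = NULL,
                                   tree_policy = "logistic_fallback") {
  if (is.character(features)) {
    features <- tryCatch(utils::read.csv(features),
                         error = function(e)
                           stop("malformed CSV: ", conditionMessage(e),
                                call. = FALSE))
  }
  for (col in c("cbv_p10", "k2_p90")) {
    if (!col %in% names(features))
      stop("feature CSV lacks required column: ", col, call. = FALSE)
    v <- features[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad) > 0)
      stop("non-numeric ", col, " at row ", bad[1], call. = FALSE)
    features[[col]] <- as.numeric(v)
  }
  if (nrow(features) == 0)
    return(list(predictions = features, report = NULL))

  lmod <- published_logistic()
  tmod <- published_tree(tree_policy)
  features$logit_score <- lmod$intercept +
    lmod$coefficients[["cbv_p10"]] * features$cbv_p10 +
    lmod$coefficients[["k2_p90"]] * features$k2_p90
  features$logistic_label <- as.integer(features$logit_score >= lmod$threshold)
  features$tree_label <- vapply(seq_len(nrow(features)), function(i)
    as.integer(tree_predict(features[i, ], tmod)), integer(1))
  features$tree_policy <- tree_policy

  report <- NULL
  if ("ph_label" %in% names(features) && !anyNA(features$ph_label)) {
    report <- list(
      logistic = evaluate(features$logistic_label, features$ph_label,
                          scores = features$logit_score),
      tree = evaluate(features$tree_label, features$ph_label))
  }
  if (!is.null(out_csv))
    utils::write.csv(features, out_csv, row.names = FALSE)
  list(predictions = features, report = report)
}
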