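# Formats and configuration: NIfTI volumes with b-value sidecars, CSV
# tables, YAML run configuration, and the end-to-end pipeline.

#' 4D DWI series container
#'
#' @param signal 4D numeric array (x, y, z, b); must be non-negative with
#'   the fourth axis matching the scheme length.
#' @param scheme a [bvalue_scheme].
#' @param voxel_dims optional voxel dimensions in mm.
#' @return list of class `"dwi_series"`.
#' @export
dwi_series <- function(signal, scheme, voxel_dims = c(1, 1, 1)) {
  scheme <- bvalue_scheme(scheme)
  if (!is.array(signal) || length(dim(signal)) != 4L)
    stop("'signal' must be a 4D array", call. = FALSE)
  if (dim(signal)[4] != length(scheme))
    stop("b axis length does not match the scheme", call. = FALSE)
  if (any(signal < 0))
    stop("signal must be non-negative (magnitude data)", call. = FALSE)
  structure(list(signal = signal, scheme = scheme, voxel_dims = voxel_dims),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("dwi_series: %s grid, %d b-values\n",
              paste(dim(x$signal)[1:3], collapse = "x"),
              dim(x$signal)[4]))
  invisible(x)
}

.sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read / write a 4D DWI series as NIfTI plus b-value sidecar
#'
#' The b-values travel in a JSON sidecar (`{"bvalues": [...]}`) next to
#' the NIfTI file; a whitespace-separated `.bval` file is accepted as a
#' fallback on reading. The round trip is lossless.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [dwi_series()].
#' @export
read_dwi_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D DWI volume", call. = FALSE)
  sc <- .sidecar_path(path)
  bval <- sub("\\.nii(\\.gz)?$", ".bval", path)
  if (file.exists(sc)) {
    b <- as.numeric(unlist(jsonlite::read_json(sc)$bvalues))
  } else if (file.exists(bval)) {
    b <- scan(bval, quiet = TRUE)
  } else stop("no b-value sidecar (.json or .bval) next to ", path,
              call. = FALSE)
  if (length(b) != d[4])
    stop(sprintf("sidecar has %d b-values but the volume has %d",
                 length(b), d[4]), call. = FALSE)
  pd <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) NULL)
  dwi_series(array(as.vector(img), dim = d), bvalue_scheme(b),
             voxel_dims = pd %||% c(1, 1, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_dwi_nifti
#' @param series a [dwi_series()].
#' @export
write_dwi_nifti <- function(series, path) {
  stopifnot(inherits(series, "dwi_series"))
  RNifti::writeNifti(RNifti::asNifti(series$signal,
                                     pixdim = c(series$voxel_dims, 1)), path)
  jsonlite::write_json(list(bvalues = as.numeric(series$scheme)),
                       .sidecar_path(path), digits = NA)
  invisible(path)
}

#' Read / write a 3D binary ROI mask as NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return 3D logical array.
#' @export
read_roi_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D mask", call. = FALSE)
  if (!all(as.vector(img) %in% c(0, 1)))
    stop("mask voxels must be 0/1", call. = FALSE)
  array(as.vector(img) > 0, dim(img))
}

#' @rdname read_roi_mask
#' @param mask 3D binary array.
#' @export
write_roi_mask <- function(mask, path) {
  mask <- .validate_mask(mask)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))),
                     path)
  invisible(path)
}

#' Write fitted parameter maps as NIfTI volumes
#'
#' One volume per map (NaN outside the ROI) plus the per-voxel fit
#' diagnostics as CSV.
#'
#' @param pm a `param_maps` object.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_param_maps <- function(pm, dir, prefix = "map") {
  stopifnot(inherits(pm, "param_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in names(pm$maps)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, m))
    RNifti::writeNifti(RNifti::asNifti(pm$maps[[m]]), p)
    paths <- c(paths, p)
  }
  if (!is.null(pm$diagnostics)) {
    p <- file.path(dir, sprintf("%s_diagnostics.csv", prefix))
    utils::write.csv(pm$diagnostics, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# ---- run configuration -----------------------------------------------------

#' Default pipeline configuration
#'
#' A complete, schema-valid run configuration: the nine-point b scheme,
#' the two built-in class specifications, cohort sizes 46/34, Rician noise
#' at 2% of baseline, 8:2 stratified split, two-reader ROI jitter 0.1, and
#' the statistical thresholds (screen 0.05, entry 0.05, VIF 5).
#'
#' @return nested list of class `"run_config"`.
#' @export
default_run_config <- function() {
  structure(list(
    scheme = c(0, 10, 20, 40, 80, 200, 400, 600, 1000),
    cohort = list(n_high = 46, n_low = 34, sigma = 2, model = "biexp",
                  grid_dim = c(16, 16, 6)),
    split = list(ratio = 0.8),
    readers = list(jitter = 0.1),
    fit = list(ivim_split_b = 200, dstar_bounds = c(3, 200),
               alpha_bounds = c(0.05, 1), refine = TRUE),
    stats = list(screen_p = 0.05, entry_p = 0.05, vif_threshold = 5),
    seed = 1), class = "run_config")
}

#' Validate a run configuration
#'
#' @param cfg a list as from [default_run_config()] or [read_run_config()].
#' @return the validated config (classed), or an error describing the
#'   offending field.
#' @export
validate_run_config <- function(cfg) {
  need <- c("scheme", "cohort", "split", "readers", "fit", "stats", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bvalue_scheme(cfg$scheme)  # validates b = 0 first, ordering, length
  with(cfg$cohort, {
    if (n_high < 1 || n_low < 1) stop("cohort sizes must be >= 1",
                                      call. = FALSE)
    if (sigma < 0) stop("noise sigma must be >= 0", call. = FALSE)
  })
  if (cfg$split$ratio <= 0 || cfg$split$ratio >= 1)
    stop("split ratio must lie in (0, 1): the test fraction cannot be 0",
         call. = FALSE)
  if (cfg$readers$jitter < 0 || cfg$readers$jitter >= 1)
    stop("reader jitter must lie in [0, 1)", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read / write the run configuration as YAML
#'
#' @param path YAML file path.
#' @return for reading, a validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg a run configuration list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

.cfg_fit_config <- function(cfg) {
  fit_config(ivim_split_b = cfg$fit$ivim_split_b,
             dstar_bounds = cfg$fit$dstar_bounds,
             alpha_bounds = cfg$fit$alpha_bounds,
             refine = cfg$fit$refine)
}

# ---- end-to-end pipeline ---------------------------------------------------

#' Run the full pipeline
#'
#' simulate -> fit -> features -> analyze: generates a seeded phantom
#' cohort, fits the three models voxelwise on the union of the two
#' readers' ROIs, extracts and reader-averages the histogram features,
#' computes inter-reader ICCs, splits train/test (stratified), fits the
#' diagnostic model on the training set and evaluates it on the test set.
#' Writes the feature table, screening/ICC/model summaries and a JSON run
#' manifest (config, seed, versions, output checksums) to `out_dir`.
#' Re-running with the same config and seed reproduces identical tables.
#'
#' @param cfg a validated run configuration.
#' @param out_dir output directory.
#' @param write_images also write the simulated NIfTI volumes and masks.
#' @return list of class `"pipeline_run"`: `features` (per-subject
#'   averaged feature table), `icc`, `model` (the training
#'   [ki67_model()]), `test_evaluation`, `split`, and `manifest`.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir = tempfile("run"),
                         write_images = FALSE) {
  cfg <- validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- bvalue_scheme(cfg$scheme)

  cohort <- generate_cohort(n_high = cfg$cohort$n_high,
                            n_low = cfg$cohort$n_low,
                            scheme = scheme, sigma = cfg$cohort$sigma,
                            seed = cfg$seed, model = cfg$cohort$model,
                            grid_dim = cfg$cohort$grid_dim)
  if (write_images) .write_cohort(cohort, file.path(out_dir, "images"))

  fc <- .cfg_fit_config(cfg)
  feats_a <- feats_b <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    mask_b <- simulate_second_reader(subj$mask, jitter = cfg$readers$jitter,
                                     seed = cfg$seed + i)
    union_mask <- subj$mask | mask_b
    pm <- suppressWarnings(fit_roi(subj$series, union_mask, fc))
    feats_a[[i]] <- suppressWarnings(roi_histogram_features(pm, subj$mask))
    feats_b[[i]] <- suppressWarnings(roi_histogram_features(pm, mask_b))
  }
  fa <- do.call(rbind, feats_a)
  fb <- do.call(rbind, feats_b)
  icc <- icc_agreement(fa, fb)
  averaged <- average_readers(fa, fb)
  records <- cohort_records(cohort)
  features <- cbind(records, averaged)

  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(features_long(reader_a = fa, reader_b = fb,
                                 subjects = records$subject),
                   file.path(out_dir, "features_long.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(feature = names(icc), icc = unname(icc)),
                   file.path(out_dir, "icc.csv"), row.names = FALSE)

  split <- split_train_test(features, ratio = cfg$split$ratio,
                            seed = cfg$seed)
  model <- ki67_model(split$train, screen_p = cfg$stats$screen_p,
                      entry_p = cfg$stats$entry_p,
                      vif_threshold = cfg$stats$vif_threshold)
  test_eval <- if (length(model$selected))
    evaluate_ki67_model(model, split$test) else NULL

  utils::write.csv(model$screening, file.path(out_dir, "screening.csv"),
                   row.names = FALSE)
  utils::write.csv(model$forward$coefficients,
                   file.path(out_dir, "model_coefficients.csv"),
                   row.names = FALSE)

  manifest <- .write_manifest(out_dir, cfg)
  structure(list(features = features, icc = icc, model = model,
                 test_evaluation = test_eval, split = split,
                 manifest = manifest, out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run: %d subjects -> %s\n", nrow(x$features),
              x$out_dir))
  print(x$model)
  invisible(x)
}

.write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort)) {
    id <- cohort[[i]]$record$subject
    write_dwi_nifti(cohort[[i]]$series,
                    file.path(dir, sprintf("%s_dwi.nii.gz", id)))
    write_roi_mask(cohort[[i]]$mask,
                   file.path(dir, sprintf("%s_mask.nii.gz", id)))
  }
  utils::write.csv(cohort_records(cohort), file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(dir)
}

.write_manifest <- function(out_dir, cfg) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "dwihist",
    version = as.character(utils::packageVersion("dwihist")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = lapply(files, function(f)
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
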