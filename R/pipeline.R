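# Orchestration and format plumbing: NIfTI and table round-trips, run
# configuration, and the end-to-end six-model pipeline with a reproducible
# manifest.

#' Write / read a DCE examination as NIfTI
#'
#' One `.nii.gz` file per series volume (`pre.nii.gz`, `post1.nii.gz`, ...),
#' with voxel spacing and origin encoded in the affine. The round-trip
#' preserves voxel data within float tolerance and geometry exactly.
#'
#' @param exam a [dce_series()].
#' @param dir output directory (created if needed).
#' @return `write_exam` returns `dir` invisibly; `read_exam` returns the
#'   reconstructed [dce_series()].
#' @export
write_exam <- function(exam, dir) {
  stopifnot(inherits(exam, "dce_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- c("pre", paste0("post", seq_len(n_post(exam))))
  for (i in seq_along(exam$volumes))
    write_volume(exam$volumes[[i]], exam$spacing, exam$origin,
                 file.path(dir, paste0(nm[i], ".nii.gz")))
  invisible(dir)
}

#' @rdname write_exam
#' @export
read_exam <- function(dir) {
  files <- list.files(dir, pattern = "^(pre|post[0-9]+)\\.nii\\.gz$",
                      full.names = TRUE)
  if (length(files) < 2) stop("malformed examination directory: ", dir)
  posts <- sort(as.integer(sub(".*post([0-9]+)\\.nii\\.gz$", "\\1",
                               grep("post", files, value = TRUE))))
  paths <- c(file.path(dir, "pre.nii.gz"),
             file.path(dir, paste0("post", posts, ".nii.gz")))
  vols <- lapply(paths, read_volume)
  dce_series(lapply(vols, `[[`, "data"),
             vols[[1]]$spacing, vols[[1]]$origin)
}

#' @noRd
write_volume <- function(vol, spacing, origin, path) {
  img <- RNifti::asNifti(vol)
  # encode geometry: scaled identity orientation with translation = origin
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- spacing     # qform assignment resets pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @noRd
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = abs(diag(aff)[1:3]),
       origin = as.numeric(aff[1:3, 4]))
}

#' Write / read a tumor mask as NIfTI
#' @param mask a [tumor_mask()].
#' @param path output `.nii.gz` path.
#' @return `read_mask` returns the [tumor_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tumor_mask"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_volume(mask$grid + 0, mask$spacing, mask$origin, path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  tumor_mask(v$data > 0.5, v$spacing, v$origin)
}

#' Write / read a tab-separated table with header
#' @param x data.frame.
#' @param path file path.
#' @return `read_table_tsv` returns the data.frame.
#' @export
write_table_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Pipeline run configuration
#'
#' @param out_dir run directory for artifacts and the manifest.
#' @param seed global seed; per-stage seeds are derived from it by a fixed
#'   mapping and logged in the manifest.
#' @param synth a [synthetic_config()] describing the cohort (the `simulate`
#'   stage); its seed is overridden by the derived stage seed.
#' @param target_spacing resampling target (mm); `NULL` = cohort median.
#' @param registration_backend see [register_series()]; `"none"` skips the
#'   registration stage.
#' @param models character vector of base models to run (any of
#'   `"unet3d"`, `"attn-unet2d"`, `"vqed2d"`, `"volume"`,
#'   `"volume-subtype"`); the ensemble stacks the three network models on
#'   the volume-subtype model when all four are present.
#' @param train_fraction fraction of patients used for training (the rest
#'   is the held-out test set).
#' @param n_seg_train exams used to train each segmentation network.
#' @param seg_epochs training epochs per network.
#' @param base_width,bottleneck_channels,codebook_size network sizes,
#'   see [seg_model()].
#' @param rf random forest search specification, see [rf_spec()].
#' @param stages stage list; must be an in-order subsequence of
#'   simulate, preprocess, segment, extract, train, evaluate.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, synth = synthetic_config(),
                       stages = c("simulate", "preprocess", "segment",
                                  "extract", "train", "evaluate"),
                       target_spacing = NULL,
                       registration_backend = "translation",
                       models = c("unet3d", "attn-unet2d", "vqed2d",
                                  "volume", "volume-subtype"),
                       train_fraction = 0.7, n_seg_train = 12L,
                       seg_epochs = 3L, base_width = 4L,
                       bottleneck_channels = 8L, codebook_size = 16L,
                       rf = rf_spec()) {
  known <- c("unet3d", "attn-unet2d", "vqed2d", "volume", "volume-subtype")
  if (!all(models %in% known))
    stop("unknown model(s): ", paste(setdiff(models, known), collapse = ", "))
  canonical <- c("simulate", "preprocess", "segment", "extract", "train",
                 "evaluate")
  if (!all(stages %in% canonical))
    stop("unknown stage(s): ", paste(setdiff(stages, canonical),
                                     collapse = ", "))
  pos <- match(stages, canonical)
  if (any(diff(pos) <= 0))
    stop("invalid stage ordering: '", stages[which(diff(pos) <= 0)[1] + 1],
         "' cannot run before '", stages[which(diff(pos) <= 0)[1]], "'")
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 stages = stages,
                 target_spacing = target_spacing,
                 registration_backend = registration_backend,
                 models = models, train_fraction = train_fraction,
                 n_seg_train = as.integer(n_seg_train),
                 seg_epochs = as.integer(seg_epochs),
                 base_width = as.integer(base_width),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 codebook_size = as.integer(codebook_size), rf = rf),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file with `run_config` fields (nested `synth` block
#'   passed to [synthetic_config()]).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synthetic_config, y$synth)
  if (!is.null(y$rf)) y$rf <- do.call(rf_spec, y$rf)
  do.call(run_config, y)
}

#' @noRd
log_stage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  message(msg)
  c(log, msg)
}

#' Run the full deep-radiomics RCB pipeline on a synthetic cohort
#'
#' Stages: simulate -> preprocess (crop, register, resample to the
#' training-set median spacing, carry forward to five post-contrast
#' series) -> segment (train the configured networks on training exams,
#' predict masks) -> extract (bottleneck features at mask-overlapping
#' coarse voxels; pre, post and delta sets) -> train (variance filter +
#' per-set PCA + random forest per network, clinical baselines, nonnegative
#' zero-intercept ensemble) -> evaluate (held-out test split). Every stage
#' writes artifacts under `out_dir` and the manifest records the config
#' hash, derived stage seeds, per-stage counts and output checksums, so a
#' rerun with an identical configuration is checksum-identical.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @return invisible list with the manifest, the evaluation report, the
#'   ensemble weights and per-model test predictions.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  manifest <- list(seed = config$seed,
                   stage_seeds = list(),
                   counts = list(), exclusions = list())

  # --- simulate ------------------------------------------------------------
  sseed <- derive_seed(config$seed, "simulate")
  manifest$stage_seeds$simulate <- sseed
  synth <- config$synth
  synth$seed <- sseed
  cohort <- generate_cohort(synth)
  tab <- cohort_table(cohort)
  write_table_tsv(tab, file.path(out, "cohort.tsv"))
  log <- log_stage(log, "simulate", nrow(tab), " patients generated")
  manifest$counts$simulate <- nrow(tab)

  # --- preprocess ----------------------------------------------------------
  # patients with a missing outcome are excluded before modeling
  keep <- !is.na(tab$rcb_score)
  if (any(!keep)) {
    manifest$exclusions$missing_outcome <- tab$patient_id[!keep]
    log <- log_stage(log, "simulate", "excluded (missing outcome): ",
                     paste(tab$patient_id[!keep], collapse = ", "))
    cohort$patients <- cohort$patients[keep]
    tab <- tab[keep, , drop = FALSE]
  }

  pre_exams <- lapply(cohort$patients, `[[`, "pre_exam")
  med <- config$target_spacing %||% median_spacing(pre_exams)
  process_side <- function(p, side) {
    exam <- p[[paste0(side, "_exam")]]
    mask <- p[[paste0(side, "_mask")]]
    exam <- crop_breast_region(exam, p$landmarks)
    mask <- crop_breast_region(mask, p$landmarks)
    if (!identical(config$registration_backend, "none"))
      exam <- register_series(exam, config$registration_backend)
    exam <- resample_to_spacing(exam, med)
    mask <- resample_to_spacing(mask, med)
    exam <- carry_forward(exam, 5L)
    list(exam = exam, mask = mask)
  }
  proc <- lapply(cohort$patients, function(p)
    list(pre = process_side(p, "pre"), post = process_side(p, "post"),
         id = p$clinical$patient_id))
  n_kept <- length(proc)
  log <- log_stage(log, "preprocess", n_kept,
                   " patients preprocessed, target spacing ",
                   paste(signif(med, 3), collapse = "x"))
  manifest$counts$preprocess <- n_kept
  manifest$target_spacing <- med

  # --- split ---------------------------------------------------------------
  n <- length(proc)
  n_train <- max(2L, round(config$train_fraction * n))
  train_idx <- seq_len(n_train)
  test_idx <- setdiff(seq_len(n), train_idx)
  y_train <- tab$rcb_score[train_idx]
  y_test <- tab$rcb_score[test_idx]

  # --- segment -------------------------------------------------------------
  net_names <- intersect(config$models,
                         c("unet3d", "attn-unet2d", "vqed2d"))
  seg_models <- list()
  seg_seed <- derive_seed(config$seed, "segment")
  manifest$stage_seeds$segment <- seg_seed
  n_fit <- min(config$n_seg_train, n_train)
  fit_exams <- lapply(proc[seq_len(n_fit)], function(q) q$pre$exam)
  fit_masks <- lapply(proc[seq_len(n_fit)], function(q) q$pre$mask)
  for (arch in net_names) {
    m <- seg_model(arch, base_width = config$base_width,
                   bottleneck_channels = config$bottleneck_channels,
                   codebook_size = config$codebook_size, seed = seg_seed)
    m <- seg_train(m, fit_exams, fit_masks, epochs = config$seg_epochs)
    seg_models[[arch]] <- m
    log <- log_stage(log, "segment", arch, " trained on ", n_fit,
                     " exams, final loss ",
                     signif(m$history[length(m$history)], 3))
  }
  manifest$counts$segment_training_exams <- n_fit

  # --- extract + train per network ----------------------------------------
  predictions_train <- list()
  predictions_test <- list()
  fitted <- list()
  for (arch in net_names) {
    m <- seg_models[[arch]]
    mode <- if (m$is_vector_quantized) "histogram" else "summary"
    fallbacks <- 0
    ext <- lapply(proc, function(q) {
      per_exam <- lapply(list(pre = q$pre, post = q$post), function(e) {
        pr <- seg_predict(m, e$exam)
        cm <- downsample_mask(pr$mask, pr$bottleneck)
        fv <- extract_features(pr$bottleneck, cm, mode = mode,
                               prob = pr$prob)
        fv
      })
      list(pre = per_exam$pre, post = per_exam$post)
    })
    names(ext) <- vapply(proc, `[[`, "", "id")
    fallbacks <- sum(vapply(ext, function(e)
      attr(e$post, "fallback") != "none", TRUE))
    fs <- build_feature_sets(ext)
    fs_train <- structure(lapply(fs[c("pre", "post", "delta")],
                                 function(M) M[train_idx, , drop = FALSE]),
                          class = "feature_set")
    fs_test <- structure(lapply(fs[c("pre", "post", "delta")],
                                function(M) M[test_idx, , drop = FALSE]),
                         class = "feature_set")
    red <- fit_reduction(fs_train)
    rf <- fit_rf_cv(red$X, y_train, config$rf)
    fitted[[arch]] <- list(reduction = red, rf = rf)
    predictions_train[[arch]] <- rf$oof
    predictions_test[[arch]] <- predict(rf, predict(red, fs_test))
    log <- log_stage(log, "extract", arch, ": ",
                     ncol(fs$pre), " features/set, ",
                     sum(vapply(red$sets, `[[`, 1L, "n_components")),
                     " components, ", fallbacks, " post-NAC fallbacks")
  }

  # --- clinical baselines --------------------------------------------------
  clin_train <- tab[train_idx, ]
  clin_test <- tab[test_idx, ]
  if ("volume" %in% config$models) {
    mv <- clinical_model(clin_train, y_train, with_subtype = FALSE,
                         spec = config$rf)
    predictions_train$volume <- mv$oof
    predictions_test$volume <- predict(mv, clinical_features(clin_test))
    fitted$volume <- mv
  }
  if ("volume-subtype" %in% config$models) {
    ms <- clinical_model(clin_train, y_train, with_subtype = TRUE,
                         spec = config$rf)
    predictions_train$`volume-subtype` <- ms$oof
    predictions_test$`volume-subtype` <-
      predict(ms, clinical_features(clin_test, TRUE))
    fitted$`volume-subtype` <- ms
  }
  log <- log_stage(log, "train", length(predictions_train), " base models fitted")

  # --- ensemble ------------------------------------------------------------
  ens_members <- c(net_names, "volume-subtype")
  weights <- NULL
  if (all(ens_members %in% names(predictions_train)) &&
      length(net_names) > 0) {
    P_train <- do.call(cbind, predictions_train[ens_members])
    colnames(P_train) <- ens_members
    ens <- fit_ensemble(P_train, y_train)
    weights <- ens$weights
    P_test <- do.call(cbind, predictions_test[ens_members])
    colnames(P_test) <- ens_members
    predictions_test$ensemble <- predict(ens, P_test)
    write_table_tsv(data.frame(model = names(weights),
                               weight = as.numeric(weights)),
                    file.path(out, "ensemble_weights.tsv"))
    log <- log_stage(log, "ensemble", "weights: ",
                     paste(sprintf("%s=%.3f", names(weights), weights),
                           collapse = ", "))
  }

  # --- evaluate ------------------------------------------------------------
  outcomes_test <- data.frame(rcb_score = y_test,
                              pcr = tab$pcr[test_idx],
                              responder = tab$responder[test_idx])
  report <- evaluation_report(predictions_test, outcomes_test,
                              reference = if ("volume" %in%
                                              names(predictions_test))
                                "volume" else names(predictions_test)[1])
  write_table_tsv(report, file.path(out, "evaluation_report.tsv"))
  pred_tab <- data.frame(patient_id = rep(tab$patient_id[test_idx],
                                          length(predictions_test)),
                         model = rep(names(predictions_test),
                                     each = length(test_idx)),
                         predicted_rcb = unlist(predictions_test,
                                                use.names = FALSE))
  write_table_tsv(pred_tab, file.path(out, "test_predictions.tsv"))
  log <- log_stage(log, "evaluate", length(test_idx),
                   " held-out patients, ", length(predictions_test),
                   " models")
  manifest$counts$test_patients <- length(test_idx)

  # --- manifest ------------------------------------------------------------
  cfg_copy <- config
  cfg_copy$out_dir <- NULL
  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(rapply(unclass(cfg_copy), unclass, how = "replace"),
                       cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest$config_md5 <- unname(tools::md5sum(cfg_json))
  outputs <- c("cohort.tsv", "evaluation_report.tsv", "test_predictions.tsv",
               "ensemble_weights.tsv")
  outputs <- outputs[file.exists(file.path(out, outputs))]
  manifest$checksums <- as.list(tools::md5sum(file.path(out, outputs)))
  names(manifest$checksums) <- outputs
  manifest$log <- log
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(manifest = manifest, report = report,
                 ensemble_weights = weights,
                 predictions_test = predictions_test,
                 fitted = fitted))
}
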