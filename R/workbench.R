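# Formats, configuration, seeding and end-to-end orchestration: NIfTI
# volume I/O, a single YAML run configuration, the cross-validated
# evaluation protocol, and the pipeline runner that writes every
# intermediate artifact plus a hash manifest.

#' Load a 3D volume from a NIfTI file
#'
#' Axis order is (height, width, depth) with depth as the slice axis.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return plain 3D array.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read volume: '%s' does not exist", path),
         call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop(sprintf("failed to read NIfTI '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- arr[, , , 1L]
  }
  if (length(dim(arr)) != 3L) {
    abort_domain(sprintf("expected a 3D volume, got %dD",
                         length(dim(arr))))
  }
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a 3D volume to a NIfTI file
#'
#' @param volume 3D array.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(length(dim(volume)) == 3L)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(volume),
                                           dim = dim(volume))), path)
  invisible(path)
}

#' Seed every stochastic component
#'
#' Sets the base RNG and records the seed; package functions derive
#' per-component streams from the seeds they are handed, so one integer
#' reproduces a whole run.
#'
#' @param seed integer seed.
#' @export
set_global_seed <- function(seed) {
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  options(attnmil.seed = seed)
  invisible(seed)
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Assemble a run configuration
#'
#' One document holds every module's settings; it round-trips through YAML
#' unchanged.
#'
#' @param out_dir run output directory.
#' @param seed global seed.
#' @param cohort a [cohort_config()] (synthetic runs) or NULL.
#' @param paths for non-synthetic runs: list with `volumes_dir`,
#'   `clinical`, `radiomics`, `labels` (CSV paths).
#' @param backbone a [backbone_config()].
#' @param stage1 a [stage1_config()].
#' @param mlp an [mlp_config()].
#' @param evaluation list with `test_fraction`, `folds`, `ci_reps`.
#' @param alpha clinical screening level.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       cohort = cohort_config(seed = seed),
                       paths = NULL,
                       backbone = backbone_config(seed = seed),
                       stage1 = stage1_config(lr = 1e-3, max_epochs = 25L,
                                              patience = 8L, seed = seed),
                       mlp = mlp_config(lr = 3e-3, seed = seed),
                       evaluation = list(test_fraction = 0.2, folds = 5L,
                                         ci_reps = 500L),
                       alpha = 0.05) {
  if (is.null(cohort) && is.null(paths)) {
    abort_domain("either a synthetic cohort config or input paths required")
  }
  if (!is.null(paths)) {
    need <- c("volumes_dir", "clinical", "radiomics", "labels")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      abort_domain(sprintf("missing input path(s): %s",
                           paste(miss, collapse = ", ")))
    }
    gone <- !vapply(paths[need], file.exists, logical(1))
    if (any(gone)) {
      abort_domain(sprintf("input path(s) do not exist: %s",
                           paste(unlist(paths[need])[gone], collapse = ", ")))
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 paths = paths, backbone = backbone, stage1 = stage1,
                 mlp = mlp, evaluation = evaluation, alpha = alpha),
            class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(strip_class(config)), path)
  invisible(path)
}

#' Read a run configuration back from YAML
#'
#' @param path YAML file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- if (!is.null(raw$cohort)) do.call(cohort_config, raw$cohort)
  backbone <- do.call(backbone_config, raw$backbone)
  stage1 <- do.call(stage1_config, raw$stage1)
  mlp <- do.call(mlp_config, raw$mlp)
  run_config(out_dir = raw$out_dir, seed = raw$seed, cohort = cohort,
             paths = raw$paths, backbone = backbone, stage1 = stage1,
             mlp = mlp, evaluation = raw$evaluation, alpha = raw$alpha)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", stage,
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  sprintf(...)))
}

#' Cross-validated evaluation of a fused predictor
#'
#' K stratified folds over the training patients: each round trains the
#' MLP on K-1 folds and scores the held-out fold; a final model trained on
#' all training patients is scored on the untouched test set. Mirrors the
#' two-block layout of a train-CV/independent-test results table.
#'
#' @param X feature matrix (all patients).
#' @param labels binary outcome (all patients).
#' @param split a [stratified_patient_split()] result.
#' @param K fold count.
#' @param mlp an [mlp_config()].
#' @param seed integer seed.
#' @param ci_reps bootstrap replicates for AUC intervals.
#' @return list with `report` (data.frame: one row per fold, a mean row, a
#'   test row), `model` (the final predictor), `folds`.
#' @export
evaluate_cv <- function(X, labels, split, K = 5L, mlp = mlp_config(),
                        seed = 1L, ci_reps = 500L) {
  tr <- split$train; te <- split$test
  folds <- kfold_plan(labels[tr], K = K, seed = stream_seed(seed, "cv-folds"))
  metric_row <- function(tag, y, s, ci_seed) {
    met <- compute_metrics(y, s, mlp$threshold)
    ci <- bootstrap_auc_ci(y, s, reps = ci_reps, seed = ci_seed)
    data.frame(fold = tag, TP = met$confusion["TP"], FP = met$confusion["FP"],
               TN = met$confusion["TN"], FN = met$confusion["FN"],
               accuracy = met$accuracy, precision = met$precision,
               recall = met$recall, f1 = met$f1, auc = met$auc,
               auc_low = ci["low"], auc_high = ci["high"], row.names = NULL)
  }
  report <- NULL
  for (k in seq_len(K)) {
    tr_k <- tr[folds != k]; va_k <- tr[folds == k]
    cfg <- mlp; cfg$seed <- stream_seed(seed, sprintf("cv-mlp-%d", k))
    fit <- train_mlp(X[tr_k, , drop = FALSE], labels[tr_k], cfg)
    pr <- predict(fit, X[va_k, , drop = FALSE])
    report <- rbind(report,
                    metric_row(sprintf("fold%d", k), labels[va_k],
                               pr$probability,
                               stream_seed(seed, sprintf("cv-ci-%d", k))))
  }
  mean_row <- report[1, ]
  mean_row$fold <- "mean"
  for (cn in setdiff(names(report), "fold")) {
    mean_row[[cn]] <- mean(report[[cn]])
  }
  cfg <- mlp; cfg$seed <- stream_seed(seed, "final-mlp")
  final <- train_mlp(X[tr, , drop = FALSE], labels[tr], cfg)
  pr <- predict(final, X[te, , drop = FALSE])
  report <- rbind(report, mean_row,
                  metric_row("test", labels[te], pr$probability,
                             stream_seed(seed, "test-ci")))
  list(report = report, model = final, folds = folds)
}

manifest_write <- function(out_dir, config) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  hashes <- as.character(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(seed = config$seed,
                   config = strip_class(config),
                   files = stats::setNames(as.list(hashes), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Run the full pipeline
#'
#' Generate (or ingest) a cohort, normalize volumes, train the stage-1 MIL
#' model, extract deep features, select features per modality on training
#' patients only, fuse, train and evaluate the MLP (K-fold CV plus an
#' untouched test set), export attention reports, and write every
#' intermediate table, the model checkpoint, the evaluation report and a
#' content-hash manifest.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly, with the manifest attached
#'   as an attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("volumes", "tables", "reports", "checkpoints")) {
    dir.create(file.path(out, sub), showWarnings = FALSE)
  }
  run_stage <- function(stage, expr) {
    stage_log(stage, "start")
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- run_stage("ingest", {
    if (!is.null(config$cohort)) {
      generate_cohort(config$cohort)
    } else {
      p <- config$paths
      clinical <- utils::read.csv(p$clinical, stringsAsFactors = FALSE)
      radiomics <- utils::read.csv(p$radiomics, stringsAsFactors = FALSE)
      lab_df <- utils::read.csv(p$labels, stringsAsFactors = FALSE)
      ids <- lab_df$patient_id
      vols <- lapply(ids, function(id) {
        load_volume(file.path(p$volumes_dir, paste0(id, ".nii.gz")))
      })
      names(vols) <- ids
      list(volumes = vols, clinical = clinical, radiomics = radiomics,
           ground_truth = list(patient_ids = ids,
                               bag_labels = stats::setNames(lab_df$label, ids),
                               instance_labels = NULL,
                               key_slice_indices = NULL))
    }
  })

  run_stage("write-inputs", {
    utils::write.csv(cohort$clinical,
                     file.path(out, "tables", "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$radiomics,
                     file.path(out, "tables", "radiomics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(patient_ids = cohort$ground_truth$patient_ids,
           bag_labels = as.integer(cohort$ground_truth$bag_labels),
           key_slice_indices = cohort$ground_truth$key_slice_indices),
      file.path(out, "ground_truth.json"), auto_unbox = FALSE, digits = NA)
    for (pid in cohort$ground_truth$patient_ids) {
      write_volume(cohort$volumes[[pid]],
                   file.path(out, "volumes", paste0(pid, ".nii.gz")))
    }
  })

  labels <- cohort$ground_truth$bag_labels
  ids <- cohort$ground_truth$patient_ids
  split <- stratified_patient_split(
    labels, config$evaluation$test_fraction,
    seed = stream_seed(config$seed, "pipeline-split"))

  model <- run_stage("stage1-train", {
    train_stage1(cohort$volumes[split$train], labels[split$train],
                 config$backbone, config$stage1)
  })

  deep <- run_stage("deep-features", {
    df <- extract_deep_features(model, cohort$volumes)
    utils::write.csv(df, file.path(out, "tables", "deep_features.csv"),
                     row.names = FALSE)
    df
  })

  blocks <- run_stage("feature-selection", {
    cd_sel <- suppressWarnings(select_clinical_block(
      cohort$clinical, labels, split$train, alpha = config$alpha,
      seed = stream_seed(config$seed, "cd-lasso")))
    rf_sel <- suppressWarnings(select_lasso_block(
      cohort$radiomics, labels, split$train,
      seed = stream_seed(config$seed, "rf-lasso")))
    ct_sel <- suppressWarnings(select_lasso_block(
      deep, labels, split$train,
      seed = stream_seed(config$seed, "ct-lasso")))
    sel <- list(
      clinical = list(names = cd_sel$names,
                      p_values = as.list(cd_sel$screen$p_values),
                      lambda = cd_sel$lambda),
      radiomics = list(names = rf_sel$names, lambda = rf_sel$lambda),
      deep = list(names = ct_sel$names, lambda = ct_sel$lambda))
    jsonlite::write_json(sel, file.path(out, "feature_selection.json"),
                         auto_unbox = TRUE, digits = NA)
    list(cd = block_df(cohort$clinical, ids, cd_sel$names),
         rf = block_df(cohort$radiomics, ids, rf_sel$names),
         ct = block_df(deep, ids, ct_sel$names))
  })

  fused <- run_stage("fuse", {
    fu <- fuse(clinical = blocks$cd, radiomics = blocks$rf, deep = blocks$ct)
    df <- data.frame(patient_id = fu$patient_ids, fu$features,
                     check.names = FALSE)
    utils::write.csv(df, file.path(out, "tables", "fused.csv"),
                     row.names = FALSE)
    fu
  })

  evalres <- run_stage("evaluate", {
    ord <- match(ids, fused$patient_ids)
    X <- fused$features[ord, , drop = FALSE]
    ev <- evaluate_cv(X, labels, split, K = config$evaluation$folds,
                      mlp = config$mlp, seed = config$seed,
                      ci_reps = config$evaluation$ci_reps)
    utils::write.csv(ev$report, file.path(out, "eval_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ev$report, file.path(out, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ev
  })

  run_stage("attention-reports", {
    dir.create(file.path(out, "reports", "attention"), showWarnings = FALSE)
    for (j in split$test) {
      pid <- ids[j]
      export_attention_report(
        model, cohort$volumes[[pid]], pid,
        path = file.path(out, "reports", "attention", paste0(pid, ".csv")))
    }
  })

  run_stage("checkpoint", {
    saveRDS(list(params = model_params(model), pooling = model$pooling,
                 M_inference = model$M_inference),
            file.path(out, "checkpoints", "stage1_model.rds"))
    saveRDS(evalres$model,
            file.path(out, "checkpoints", "mlp_predictor.rds"))
    jsonlite::write_json(
      list(seed = config$seed,
           backbone = strip_class(config$backbone),
           stage1 = strip_class(config$stage1),
           M_inference = model$M_inference,
           M_schedule = model$M_log),
      file.path(out, "checkpoints", "stage1_model.json"),
      auto_unbox = TRUE, digits = NA)
    write_run_config(config, file.path(out, "run_config.yaml"))
  })

  manifest <- run_stage("manifest", manifest_write(out, config))
  stage_log("done", "run complete: %s", out)
  structure(invisible(out), manifest = manifest)
}
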