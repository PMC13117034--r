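# Patient-level splitting, stratified K-fold plans, classification metrics
# with a Mann-Whitney AUC, stratified percentile-bootstrap AUC confidence
# intervals, the ablation harness, and the per-patient attention report.

#' Stratified patient-level train/test split
#'
#' Per-stratum allocation with round-half-up on the test count; every
#' patient's records live wholly on one side. Deterministic given the seed.
#'
#' @param labels stratification labels (one per patient).
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` integer index vectors.
#' @export
stratified_patient_split <- function(labels, test_fraction, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort_domain("`test_fraction` must lie strictly in (0, 1)")
  }
  strata <- split(seq_along(labels), labels)
  if (any(lengths(strata) < 2L)) {
    abort_domain("every stratum needs at least 2 patients")
  }
  test <- integer(0)
  set.seed(stream_seed(seed, "patient-split"))
  for (s in strata) {
    n_test <- round_half_up(length(s) * test_fraction)
    n_test <- max(1L, min(n_test, length(s) - 1L))
    test <- c(test, sample(s, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test,
       test_fraction = test_fraction, seed = as.integer(seed))
}

#' Stratified K-fold plan
#'
#' Assigns folds so that fold sizes differ by at most 1 and per-fold class
#' counts differ by at most 1 from exact proportionality.
#'
#' @param labels class labels of the units to fold.
#' @param K fold count (at most the smallest stratum size).
#' @param seed integer seed.
#' @return integer fold assignment (1..K) per unit.
#' @export
kfold_plan <- function(labels, K = 5L, seed = 1L) {
  n <- length(labels)
  K <- check_count(K, "K", min = 2L)
  if (K > n) abort_domain("K cannot exceed the number of units")
  strata <- split(seq_len(n), labels)
  if (K > min(lengths(strata))) {
    abort_domain("K cannot exceed the smallest stratum size")
  }
  folds <- integer(n)
  sizes <- integer(K)
  set.seed(stream_seed(seed, "kfold"))
  for (s in strata) {
    ord <- sample(s)
    base <- length(ord) %/% K
    extra <- length(ord) %% K
    # remainder goes to the currently smallest folds (random tie-break)
    take <- order(sizes + stats::runif(K) * 1e-9)[seq_len(extra)]
    counts <- rep(base, K)
    counts[take] <- counts[take] + 1L
    assign_vec <- rep(seq_len(K), counts)
    folds[ord] <- assign_vec
    sizes <- sizes + counts
  }
  folds
}

# Mann-Whitney AUC with half credit for ties
auc_mw <- function(y_true, scores) {
  y <- as.integer(y_true)
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics at a threshold
#'
#' The threshold is applied as `score >= threshold`; AUC is the
#' Mann-Whitney statistic (ties counted half). With a single-class truth
#' vector the AUC is undefined and returned as NA with a warning; the
#' thresholded metrics are still computed.
#'
#' @param y_true binary truth.
#' @param scores numeric scores or probabilities.
#' @param threshold decision threshold.
#' @return list with `confusion` (TP, FP, TN, FN), `accuracy`,
#'   `misclassification`, `precision`, `recall`, `f1`, `auc`, `threshold`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y <- as.integer(y_true)
  stopifnot(length(y) == length(scores))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  acc <- (tp + tn) / length(y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  auc <- auc_mw(y, scores)
  if (is.na(auc)) {
    warning("AUC undefined: only one class present in y_true", call. = FALSE)
  }
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = acc, misclassification = 1 - acc,
       precision = prec, recall = rec, f1 = f1, auc = auc,
       threshold = threshold)
}

#' Stratified percentile-bootstrap confidence interval for the AUC
#'
#' Cases are resampled with replacement within each class (so every
#' resample retains both classes); the interval is the percentile interval
#' of the bootstrap AUC distribution at the stated level.
#'
#' @param y_true binary truth.
#' @param scores numeric scores.
#' @param reps bootstrap replicates (a warning is issued below 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return named vector `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(y_true, scores, reps = 2000L, level = 0.95,
                             seed = 1L) {
  y <- as.integer(y_true)
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) {
    abort_domain("both classes required for an AUC interval")
  }
  if (reps < 100L) warning("fewer than 100 bootstrap replicates", call. = FALSE)
  set.seed(stream_seed(seed, "bootstrap-auc"))
  stat <- vapply(seq_len(reps), function(r) {
    ip <- sample(pos, replace = TRUE)
    in_ <- sample(neg, replace = TRUE)
    idx <- c(ip, in_)
    auc_mw(y[idx], scores[idx])
  }, numeric(1))
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(low = qs[1], high = qs[2])
}

#' Export the per-instance attention report for one patient
#'
#' Rows: instance index, slice provenance, first-layer weight `a`,
#' calibrated weight `D`, and the top-M selection flag. The `a` column sums
#' to 1 and exactly M rows are flagged.
#'
#' @param model trained `mil_model` (a warning is issued if untrained).
#' @param volume the patient's 3D array.
#' @param patient_id identifier written into the report.
#' @param path optional CSV output path.
#' @return the report data.frame (invisibly if written to `path`).
#' @export
export_attention_report <- function(model, volume, patient_id,
                                    path = NULL) {
  if (!isTRUE(model$trained)) {
    warning("model is untrained; attention scores are uninformative",
            call. = FALSE)
  }
  rep_df <- instance_attention(model, volume)
  rep_df <- cbind(patient_id = patient_id, rep_df)
  if (!is.null(path)) {
    utils::write.csv(rep_df, path, row.names = FALSE)
    return(invisible(rep_df))
  }
  rep_df
}

# --- modality selection helpers for the ablation harness --------------------

select_clinical_block <- function(clinical, labels, train_idx, alpha = 0.05,
                                  categorical = names(.clin_categorical),
                                  seed = 1L) {
  tr <- clinical[train_idx, , drop = FALSE]
  scr <- univariate_screen(tr, labels[train_idx], alpha = alpha,
                           categorical = categorical)
  cand <- scr$selected
  if (!length(cand)) {
    # small cohorts can leave the screen empty; keep the continuous
    # candidates so downstream fusion still sees the modality
    warning("univariate screen selected no clinical feature; ",
            "passing all continuous columns to LASSO", call. = FALSE)
    cand <- setdiff(names(tr), c("patient_id", categorical))
  }
  ztr <- zscore_table(tr[c("patient_id", cand)], categorical = categorical)
  keep_cols <- setdiff(names(ztr), "patient_id")
  X <- as.matrix(ztr[keep_cols])
  cv <- select_lambda_cv(X, labels[train_idx], seed = seed)
  fit <- lasso_fit(X, labels[train_idx], cv$lambda)
  nm <- fit$selected_names
  if (!length(nm)) {
    warning("LASSO kept no clinical feature; falling back to the screened set",
            call. = FALSE)
    nm <- keep_cols
  }
  list(names = nm, screen = scr, lambda = cv$lambda, fit = fit)
}

select_lasso_block <- function(table, labels, train_idx, seed = 1L) {
  tr <- table[train_idx, , drop = FALSE]
  ztr <- suppressWarnings(zscore_table(tr))
  cols <- setdiff(names(ztr), "patient_id")
  X <- as.matrix(ztr[cols])
  cv <- select_lambda_cv(X, labels[train_idx], seed = seed)
  fit <- lasso_fit(X, labels[train_idx], cv$lambda)
  nm <- fit$selected_names
  if (!length(nm)) {
    warning("LASSO kept no feature in this block; keeping all columns",
            call. = FALSE)
    nm <- cols
  }
  list(names = nm, lambda = cv$lambda, fit = fit)
}

block_df <- function(table, ids, cols) {
  out <- table[match(ids, table$patient_id), c("patient_id", cols),
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ablation harness over unimodal and fused variants
#'
#' Trains and evaluates up to six variants on one shared patient-level
#' split: clinical-only (`cd`), radiomics-only (`rf`), deep features from
#' the mean-pooling MIL baseline (`ct-mil`), deep features from the
#' dual-attention model (`ct-daae`), and the two fused models
#' (`fusion-mil`, `fusion-daae`). Feature selection uses training patients
#' only; each variant's predictor is a sigmoid MLP.
#'
#' @param cohort a [generate_cohort()] result.
#' @param variants subset of the six variant names.
#' @param seed integer seed driving the split, training and bootstrap.
#' @param backbone_cfg backbone for the MIL models.
#' @param stage1 a [stage1_config()]; the default desk-scale protocol uses
#'   a 1e-3 learning rate (random initialization), at most 25 epochs and
#'   patience 8.
#' @param mlp an [mlp_config()] for the per-variant predictors.
#' @param alpha screening level for the clinical chain.
#' @param test_fraction held-out fraction for the shared split.
#' @param ci_reps bootstrap replicates for the AUC interval.
#' @return data.frame, one row per variant (confusion counts, accuracy,
#'   precision, recall, F1, AUC and its CI), with the trained models and
#'   the split attached as attributes `models` and `split`.
#' @export
run_ablation <- function(cohort,
                         variants = c("cd", "rf", "ct-mil", "ct-daae",
                                      "fusion-mil", "fusion-daae"),
                         seed = 1L,
                         backbone_cfg = backbone_config(),
                         stage1 = stage1_config(lr = 1e-3, max_epochs = 25L,
                                                patience = 8L, seed = seed),
                         mlp = mlp_config(lr = 3e-3, seed = seed),
                         alpha = 0.05,
                         test_fraction = 0.2,
                         ci_reps = 500L) {
  known <- c("cd", "rf", "ct-mil", "ct-daae", "fusion-mil", "fusion-daae")
  bad <- setdiff(variants, known)
  if (length(bad)) {
    abort_domain(sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")))
  }
  labels <- cohort$ground_truth$bag_labels
  ids <- cohort$ground_truth$patient_ids
  split <- stratified_patient_split(labels, test_fraction,
                                    seed = stream_seed(seed, "ablation-split"))
  tr <- split$train; te <- split$test

  need_mil <- any(variants %in% c("ct-mil", "fusion-mil"))
  need_daae <- any(variants %in% c("ct-daae", "fusion-daae"))
  need_cd <- any(variants %in% c("cd", "fusion-mil", "fusion-daae"))
  need_rf <- any(variants %in% c("rf", "fusion-mil", "fusion-daae"))

  models <- list()
  deep_tables <- list()
  if (need_daae) {
    cfg <- stage1; cfg$pooling <- "daae"
    models$daae <- train_stage1(cohort$volumes[tr], labels[tr],
                                backbone_cfg, cfg)
    deep_tables$daae <- extract_deep_features(models$daae, cohort$volumes)
  }
  if (need_mil) {
    cfg <- stage1; cfg$pooling <- "mean"
    models$mean <- train_stage1(cohort$volumes[tr], labels[tr],
                                backbone_cfg, cfg)
    deep_tables$mean <- extract_deep_features(models$mean, cohort$volumes)
  }

  blocks <- list()
  if (need_cd) {
    sel <- select_clinical_block(cohort$clinical, labels, tr, alpha = alpha,
                                 seed = stream_seed(seed, "cd-lasso"))
    blocks$cd <- if (length(sel$names)) {
      block_df(cohort$clinical, ids, sel$names)
    } else NULL
    attr(blocks, "cd_selection") <- sel
  }
  if (need_rf) {
    sel <- select_lasso_block(cohort$radiomics, labels, tr,
                              seed = stream_seed(seed, "rf-lasso"))
    blocks$rf <- block_df(cohort$radiomics, ids, sel$names)
  }
  for (nm in names(deep_tables)) {
    sel <- select_lasso_block(deep_tables[[nm]], labels, tr,
                              seed = stream_seed(seed, paste0(nm, "-lasso")))
    blocks[[paste0("ct_", nm)]] <- block_df(deep_tables[[nm]], ids, sel$names)
  }

  variant_features <- function(v) {
    switch(v,
      "cd" = fuse(clinical = blocks$cd, allow_missing = TRUE),
      "rf" = fuse(radiomics = blocks$rf, allow_missing = TRUE),
      "ct-mil" = fuse(deep = blocks$ct_mean, allow_missing = TRUE),
      "ct-daae" = fuse(deep = blocks$ct_daae, allow_missing = TRUE),
      "fusion-mil" = fuse(clinical = blocks$cd, radiomics = blocks$rf,
                          deep = blocks$ct_mean, allow_missing = TRUE),
      "fusion-daae" = fuse(clinical = blocks$cd, radiomics = blocks$rf,
                           deep = blocks$ct_daae, allow_missing = TRUE))
  }

  rows <- NULL
  for (v in variants) {
    fu <- variant_features(v)
    stopifnot(identical(fu$patient_ids, sort(ids)))
    ord <- match(ids, fu$patient_ids)
    X <- fu$features[ord, , drop = FALSE]
    cfg <- mlp
    cfg$seed <- stream_seed(seed, paste0("mlp-", v))
    fit <- train_mlp(X[tr, , drop = FALSE], labels[tr], cfg)
    pr <- predict(fit, X[te, , drop = FALSE])
    met <- compute_metrics(labels[te], pr$probability, cfg$threshold)
    ci <- bootstrap_auc_ci(labels[te], pr$probability, reps = ci_reps,
                           seed = stream_seed(seed, paste0("ci-", v)))
    rows <- rbind(rows, data.frame(
      variant = v, TP = met$confusion["TP"], FP = met$confusion["FP"],
      TN = met$confusion["TN"], FN = met$confusion["FN"],
      accuracy = met$accuracy, precision = met$precision,
      recall = met$recall, f1 = met$f1, auc = met$auc,
      auc_low = ci["low"], auc_high = ci["high"],
      row.names = NULL))
  }
  attr(rows, "models") <- models
  attr(rows, "split") <- split
  attr(rows, "blocks") <- blocks
  rows
}
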