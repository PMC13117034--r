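# Tabular feature chain: Z-score standardization, univariate screening
# (t-test for continuous, chi-square for categorical features), LASSO
# selection with a CV-chosen penalty, and the radiomics feature-space
# accounting (shape + wavelet-filtered first-order/texture families).

feature_matrix <- function(table, cols = NULL) {
  stopifnot(is.data.frame(table), "patient_id" %in% names(table))
  if (anyDuplicated(table$patient_id)) abort_domain("duplicate patient ids")
  if (is.null(cols)) cols <- setdiff(names(table), "patient_id")
  as.matrix(table[cols])
}

#' Z-score standardization of continuous columns
#'
#' Transforms each continuous column to mean 0 and sample standard deviation
#' 1. Categorical columns pass through untouched. Zero-variance columns are
#' dropped with a warning.
#'
#' @param table data.frame with a `patient_id` column.
#' @param categorical character vector of column names to pass through.
#' @return a data.frame of the same layout (minus any dropped columns).
#' @export
zscore_table <- function(table, categorical = character()) {
  stopifnot(is.data.frame(table), "patient_id" %in% names(table))
  if (nrow(table) < 2L) abort_domain("standardization needs >= 2 rows")
  cont <- setdiff(names(table), c("patient_id", categorical))
  drop <- character()
  for (nm in cont) {
    x <- table[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      drop <- c(drop, nm)
      next
    }
    table[[nm]] <- (x - mean(x)) / s
  }
  if (length(drop)) {
    warning(sprintf("dropped zero-variance column(s): %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    table <- table[setdiff(names(table), drop)]
  }
  table
}

#' Univariate screening of features against a binary outcome
#'
#' Continuous columns are tested with a two-sample t-test (pooled variance by
#' default, Welch optional); categorical columns with a chi-square test on
#' the class-by-level contingency table (no continuity correction by
#' default). A feature is selected when p < alpha (strict inequality; set
#' `inclusive = TRUE` for p <= alpha).
#'
#' @param table data.frame with `patient_id`.
#' @param labels binary outcome aligned with rows.
#' @param alpha significance level.
#' @param categorical names of categorical columns.
#' @param var_equal pooled-variance t-test (default) vs Welch.
#' @param correct Yates continuity correction for chi-square.
#' @param inclusive use p <= alpha instead of p < alpha.
#' @return list with `p_values`, `test`, `alpha`, `selected` (column names).
#' @export
univariate_screen <- function(table, labels, alpha = 0.05,
                              categorical = character(),
                              var_equal = TRUE, correct = FALSE,
                              inclusive = FALSE) {
  stopifnot(is.data.frame(table))
  labels <- as.integer(labels)
  if (length(labels) != nrow(table)) abort_domain("labels must align with rows")
  if (length(unique(labels)) < 2L) {
    abort_domain("both classes must be present for screening")
  }
  cols <- setdiff(names(table), "patient_id")
  pv <- stats::setNames(rep(NA_real_, length(cols)), cols)
  test <- stats::setNames(rep(NA_character_, length(cols)), cols)
  for (nm in cols) {
    x <- table[[nm]]
    if (nm %in% categorical) {
      tab <- table(factor(labels), factor(x))
      test[nm] <- "chi-square"
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || ncol(tab) < 2L) {
        warning(sprintf("skipping '%s': degenerate contingency table", nm),
                call. = FALSE)
        next
      }
      pv[nm] <- suppressWarnings(
        stats::chisq.test(tab, correct = correct)$p.value)
    } else {
      test[nm] <- "t"
      if (stats::sd(x) == 0) {
        pv[nm] <- 1  # identical in both groups: no evidence against the null
        next
      }
      pv[nm] <- stats::t.test(x[labels == 1], x[labels == 0],
                              var.equal = var_equal)$p.value
    }
  }
  keep <- if (inclusive) pv <= alpha else pv < alpha
  keep[is.na(keep)] <- FALSE
  structure(list(p_values = pv, test = test, alpha = alpha,
                 selected = cols[keep]), class = "screen_result")
}

#' LASSO fit by cyclic coordinate descent
#'
#' Minimizes `(1/(2M)) * sum (y - b0 - X beta)^2 + lambda * ||beta||_1`
#' with M the sample count and an unpenalized intercept; convergence when
#' the largest coefficient change in a sweep falls below `tol`.
#'
#' @param X numeric matrix (typically standardized columns).
#' @param y response vector.
#' @param lambda nonnegative L1 penalty.
#' @param tol convergence tolerance on coefficient changes.
#' @param max_sweeps cap on coordinate sweeps.
#' @param warm optional warm-start list with `beta` and `b0`.
#' @return object of class `lasso_result`: intercept, coefficients, lambda,
#'   n_samples, selected index set, convergence info.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-7, max_sweeps = 1e5,
                      warm = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    abort_domain("`lambda` must be a single value >= 0")
  }
  if (nrow(X) != length(y)) abort_domain("rows of X must align with y")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort_domain("non-finite values in X or y")
  }
  beta0 <- if (is.null(warm)) rep(0, ncol(X)) else warm$beta
  b00 <- if (is.null(warm)) mean(y) else warm$b0
  fit <- lasso_cd(X, as.numeric(y), lambda, beta0, b00,
                  tol = tol, max_sweeps = as.integer(max_sweeps))
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(X)
  sel <- which(beta != 0)
  structure(list(
    intercept = fit$b0, coefficients = beta, lambda = lambda,
    n_samples = nrow(X), selected = sel,
    selected_names = colnames(X)[sel],
    sweeps = fit$sweeps, converged = fit$converged
  ), class = "lasso_result")
}

#' Default penalty grid for LASSO selection
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty that zeroes
#' every coefficient) down to `1e-4 * lambda_max`, always augmented with
#' 0.002 so the conventional operating point is reachable.
#'
#' @param X,y design and response (used only for `lambda_max`).
#' @param n grid length before augmentation.
#' @param ratio smallest grid value as a fraction of `lambda_max`.
#' @param include extra values merged into the grid.
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, n = 100L, ratio = 1e-4, include = 0.002) {
  X <- as.matrix(X)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  if (lam_max <= 0) lam_max <- 1
  g <- exp(seq(log(lam_max), log(ratio * lam_max), length.out = n))
  sort(unique(c(g, include)), decreasing = TRUE)
}

#' Choose the LASSO penalty by K-fold cross-validated MSE
#'
#' Returns the grid value with the smallest mean validation MSE across K
#' folds; ties break toward the larger penalty (the sparser model).
#'
#' @param X,y design and response.
#' @param K fold count (>= 2, <= number of samples).
#' @param grid candidate penalties; defaults to [lambda_grid()].
#' @param seed integer seed for the fold shuffle.
#' @return list with `lambda`, `grid`, `cv_mse` (mean MSE per grid value).
#' @export
select_lambda_cv <- function(X, y, K = 5L, grid = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- check_count(K, "K", min = 2L)
  if (K > n) abort_domain("K cannot exceed the number of samples")
  if (is.null(grid)) grid <- lambda_grid(X, y)
  if (!length(grid)) abort_domain("empty penalty grid")
  grid <- sort(grid, decreasing = TRUE)
  folds <- with_stream(seed, "lambda-cv",
                       sample(rep_len(seq_len(K), n)))
  mse <- matrix(NA_real_, length(grid), K)
  for (k in seq_len(K)) {
    tr <- folds != k
    warm <- NULL
    for (gi in seq_along(grid)) {
      fit <- lasso_fit(X[tr, , drop = FALSE], y[tr], grid[gi], warm = warm)
      warm <- list(beta = fit$coefficients, b0 = fit$intercept)
      pred <- fit$intercept + X[!tr, , drop = FALSE] %*% fit$coefficients
      mse[gi, k] <- mean((y[!tr] - pred)^2)
    }
  }
  mean_mse <- rowMeans(mse)
  best <- which(mean_mse <= min(mean_mse))[1]  # grid is decreasing: first = largest
  list(lambda = grid[best], grid = grid, cv_mse = mean_mse)
}

#' Radiomics feature-space schema
#'
#' Per-category feature counts of the engineered feature families: shape,
#' first-order, and the five texture-matrix families (GLCM, GLRLM, GLSZM,
#' NGTDM, GLDM), plus the number of one-level 3D wavelet sub-bands (all
#' high-/low-pass combinations over the three axes).
#'
#' @param shape,firstorder,glcm,glrlm,glszm,ngtdm,gldm per-family counts.
#' @param wavelet_levels wavelet decomposition levels (sub-bands = 2^3 per level).
#' @return object of class `radiomics_schema`.
#' @export
radiomics_schema <- function(shape = 14L, firstorder = 18L, glcm = 24L,
                             glrlm = 16L, glszm = 16L, ngtdm = 5L,
                             gldm = 14L, wavelet_levels = 1L) {
  counts <- c(shape = shape, firstorder = firstorder, glcm = glcm,
              glrlm = glrlm, glszm = glszm, ngtdm = ngtdm, gldm = gldm)
  if (any(counts < 0)) abort_domain("feature counts must be nonnegative")
  structure(list(counts = counts, wavelet_levels = as.integer(wavelet_levels)),
            class = "radiomics_schema")
}

#' Wavelet sub-band labels
#'
#' The 2^3 = 8 combinations of applying a low- (L) or high-pass (H) filter
#' along each of the three axes.
#'
#' @return character vector of 8 triplets, `LLL` through `HHH`.
#' @export
wavelet_subbands <- function() {
  g <- expand.grid(a = c("L", "H"), b = c("L", "H"), c = c("L", "H"),
                   stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c)
}

#' Enumerate the radiomics feature space
#'
#' One identifier per feature: shape features from the original image only;
#' first-order and texture features from each wavelet sub-band. With the
#' default schema this yields 14 + 8 * (18 + 75) = 758 identifiers.
#'
#' @param schema a [radiomics_schema()].
#' @return character vector of unique identifiers in deterministic order.
#' @export
enumerate_radiomics_space <- function(schema = radiomics_schema()) {
  stopifnot(inherits(schema, "radiomics_schema"))
  cn <- schema$counts
  ids <- sprintf("original_shape_%02d", seq_len(cn[["shape"]]))
  texture <- c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm")
  for (band in wavelet_subbands()) {
    for (fam in texture) {
      k <- cn[[fam]]
      if (k > 0) {
        ids <- c(ids, sprintf("wavelet-%s_%s_%02d", band, fam, seq_len(k)))
      }
    }
  }
  stopifnot(!anyDuplicated(ids))
  ids
}

#' Radiomics extraction adapter (external hook)
#'
#' Image-based radiomics computation is delegated to an external engine;
#' this package only fixes the feature-space schema and column naming. The
#' hook exists so a caller can plug a real extractor into [run_pipeline()].
#'
#' @param volume 3D array.
#' @param mask optional 3D mask.
#' @return never returns; always signals that no extractor is configured.
#' @export
extract_radiomics <- function(volume, mask = NULL) {
  stop("no radiomics extraction engine configured; supply a precomputed ",
       "feature table instead", call. = FALSE)
}
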