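test_that("zscore standardizes continuous columns with sample SD", {
  tab <- data.frame(patient_id = c("a", "b", "c"), x = c(1, 2, 3))
  z <- zscore_table(tab)
  expect_equal(z$x, c(-1, 0, 1))

  tab2 <- data.frame(patient_id = letters[1:8],
                     x = c(2, 4, 4, 4, 5, 5, 7, 9))
  z2 <- zscore_table(tab2)
  expect_equal(z2$x, (tab2$x - mean(tab2$x)) / sd(tab2$x), tolerance = 1e-12)
  expect_lt(abs(mean(z2$x)), 1e-9)
  expect_lt(abs(sd(z2$x) - 1), 1e-9)

  # degenerate variance is dropped with a warning
  tab3 <- data.frame(patient_id = c("a", "b", "c"), x = c(5, 5, 5),
                     y = c(1, 2, 4))
  expect_warning(z3 <- zscore_table(tab3), "zero-variance")
  expect_false("x" %in% names(z3))
  expect_true("y" %in% names(z3))

  # categorical pass-through
  tab4 <- data.frame(patient_id = c("a", "b", "c"), g = c(0, 1, 0),
                     x = c(1, 2, 3))
  z4 <- zscore_table(tab4, categorical = "g")
  expect_identical(z4$g, tab4$g)
})

test_that("zscore is idempotent on standardized columns", {
  set.seed(1)
  tab <- data.frame(patient_id = sprintf("p%02d", 1:20),
                    a = rnorm(20, 5, 3), b = runif(20))
  z1 <- zscore_table(tab)
  z2 <- zscore_table(z1)
  expect_equal(z1$a, z2$a, tolerance = 1e-9)
  expect_equal(z1$b, z2$b, tolerance = 1e-9)
})

test_that("univariate screen uses t for continuous and chi-square for categorical", {
  # feature identical in both groups: p = 1, excluded
  tab <- data.frame(patient_id = sprintf("p%02d", 1:10),
                    flat = rep(3, 10))
  scr <- univariate_screen(tab, labels = rep(c(0, 1), 5), alpha = 0.05)
  expect_equal(unname(scr$p_values["flat"]), 1)
  expect_false("flat" %in% scr$selected)

  # 2x2 contingency [[20,10],[10,20]]: chi-square without continuity
  # correction is n(ad-bc)^2/(r1 r2 c1 c2) = 6.667
  y <- rep(c(1, 0), c(30, 30))
  x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  tab2 <- data.frame(patient_id = sprintf("p%02d", 1:60), g = x)
  scr2 <- univariate_screen(tab2, y, alpha = 0.05, categorical = "g")
  chi_ref <- 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  expect_equal(unname(scr2$p_values["g"]),
               1 - pchisq(chi_ref, df = 1), tolerance = 1e-10)
  expect_equal(unname(scr2$p_values["g"]), 0.009823, tolerance = 1e-4)
  expect_true("g" %in% scr2$selected)
  expect_identical(unname(scr2$test["g"]), "chi-square")

  # strong continuous shift is selected
  set.seed(42)
  tab3 <- data.frame(patient_id = sprintf("p%03d", 1:100),
                     v = c(rnorm(50, 0, 1), rnorm(50, 2, 1)))
  scr3 <- univariate_screen(tab3, rep(c(0, 1), each = 50), alpha = 0.05)
  expect_true("v" %in% scr3$selected)
  expect_identical(unname(scr3$test["v"]), "t")
})

test_that("screen guards degenerate inputs", {
  tab <- data.frame(patient_id = c("a", "b"), x = c(1, 2))
  expect_error(univariate_screen(tab, c(1, 1)), "both classes")
  # single-level categorical: degenerate contingency table, skipped
  tab2 <- data.frame(patient_id = sprintf("p%d", 1:6), g = rep(1, 6))
  expect_warning(
    scr <- univariate_screen(tab2, rep(c(0, 1), 3), categorical = "g"),
    "degenerate")
  expect_true(is.na(scr$p_values["g"]))
  expect_false("g" %in% scr$selected)
})

test_that("pooled t is the default with a Welch option", {
  set.seed(8)
  x <- c(rnorm(12, 0, 1), rnorm(20, 1, 4))
  y <- rep(c(0, 1), c(12, 20))
  tab <- data.frame(patient_id = sprintf("p%02d", 1:32), v = x)
  p_pooled <- univariate_screen(tab, y)$p_values["v"]
  p_welch <- univariate_screen(tab, y, var_equal = FALSE)$p_values["v"]
  expect_equal(unname(p_pooled),
               t.test(x[y == 1], x[y == 0], var.equal = TRUE)$p.value)
  expect_equal(unname(p_welch),
               t.test(x[y == 1], x[y == 0])$p.value)
  expect_false(isTRUE(all.equal(p_pooled, p_welch)))
})

test_that("lasso_fit minimizes the 1/(2M) objective", {
  set.seed(3)
  n <- 60
  X <- scale(matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("x", 1:4)
  y <- rnorm(n)

  # infinite-penalty limit: empty support, intercept = mean(y)
  f <- lasso_fit(X, y, 1e6)
  expect_length(f$selected, 0)
  expect_equal(f$intercept, mean(y), tolerance = 1e-9)

  # single standardized predictor: coefficient equals the soft-thresholded
  # least-squares slope with threshold lambda * M / (X'X)
  x1 <- X[, 1, drop = FALSE]
  for (lam in c(0.02, 0.2, 2)) {
    f1 <- lasso_fit(x1, y, lam)
    ols <- sum(x1 * (y - mean(y))) / sum(x1^2)
    thr <- lam * n / sum(x1^2)
    ref <- sign(ols) * max(abs(ols) - thr, 0)
    expect_equal(unname(f1$coefficients), ref, tolerance = 1e-7)
  }

  expect_error(lasso_fit(X, y, -1), "lambda")
  expect_error(lasso_fit(X, c(y[-1], NA), 0.1), "non-finite")
})

test_that("lasso support recovery and selected-set bookkeeping", {
  set.seed(11)
  n <- 200; p <- 12
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("x", 1:p)
  y <- 2 * X[, 1] - 3 * X[, 4] + rnorm(n, 0, 0.1)
  f <- lasso_fit(X, y, 0.05)
  expect_true(all(c(1, 4) %in% f$selected))
  expect_identical(f$selected, which(f$coefficients != 0))
  expect_identical(f$selected_names, colnames(X)[f$selected])
  expect_identical(f$n_samples, as.integer(n))
})

test_that("support is nested along the path on an orthonormal design", {
  set.seed(4)
  M <- 32
  # orthonormal columns, each orthogonal to the intercept
  Q <- qr.Q(qr(scale(matrix(rnorm(M * 3), M, 3), scale = FALSE))) * sqrt(M)
  colnames(Q) <- paste0("q", 1:3)
  y <- Q %*% c(1.5, -0.6, 0.2) + rnorm(M, 0, 0.05)
  ols <- as.numeric(crossprod(Q, y - mean(y))) / M
  supp_prev <- NULL
  for (lam in c(2, 1, 0.5, 0.25, 0.1, 0.01)) {
    f <- lasso_fit(Q, as.numeric(y), lam)
    # closed-form soft thresholding is exact here
    expect_equal(unname(f$coefficients),
                 sign(ols) * pmax(abs(ols) - lam, 0), tolerance = 1e-6)
    if (!is.null(supp_prev)) expect_true(all(supp_prev %in% f$selected))
    supp_prev <- f$selected
  }
})

test_that("cross-validated lambda attains the minimum of the mean-MSE curve", {
  set.seed(21)
  n <- 60; p <- 6
  X <- scale(matrix(rnorm(n * p), n, p)); colnames(X) <- paste0("x", 1:p)
  y <- X[, 2] + rnorm(n, 0, 0.3)

  expect_equal(select_lambda_cv(X, y, grid = 0.3, seed = 1)$lambda, 0.3)
  expect_error(select_lambda_cv(X, y, K = 100, grid = 0.3), "exceed")

  grid <- c(1, 0.3, 0.1, 0.03, 0.01)
  res <- select_lambda_cv(X, y, K = 5, grid = grid, seed = 9)
  # independent exhaustive loop with the same fold plan
  folds <- with(list(), {
    set.seed(stream_seed(9, "lambda-cv"))
    sample(rep_len(1:5, n))
  })
  mse <- sapply(sort(grid, decreasing = TRUE), function(lam) {
    mean(sapply(1:5, function(k) {
      f <- lasso_fit(X[folds != k, ], y[folds != k], lam)
      mean((y[folds == k] - f$intercept -
              X[folds == k, ] %*% f$coefficients)^2)
    }))
  })
  expect_equal(res$cv_mse, mse, tolerance = 1e-6)
  expect_equal(res$lambda, sort(grid, decreasing = TRUE)[which.min(mse)])

  # the default grid always contains the conventional 0.002
  expect_true(0.002 %in% lambda_grid(X, y))
})

test_that("radiomics feature space enumerates to the closed-form count", {
  ids <- enumerate_radiomics_space()
  expect_length(ids, 758)
  expect_false(anyDuplicated(ids) > 0)
  expect_length(grep("^original_shape", ids), 14)
  expect_length(wavelet_subbands(), 8)
  expect_false(anyDuplicated(wavelet_subbands()) > 0)
  expect_true(all(nchar(wavelet_subbands()) == 3))

  # arbitrary schemas: enumeration equals arithmetic
  set.seed(2)
  for (i in 1:5) {
    cn <- sample(0:9, 7, replace = TRUE)
    sc <- radiomics_schema(shape = cn[1], firstorder = cn[2], glcm = cn[3],
                           glrlm = cn[4], glszm = cn[5], ngtdm = cn[6],
                           gldm = cn[7])
    expect_length(enumerate_radiomics_space(sc),
                  cn[1] + 8 * (cn[2] + sum(cn[3:7])))
  }
})

test_that("screening plus LASSO recovers dosimetric and rejects categorical features", {
  cats <- c("age_ge65", "smoking", "chemotherapy", "histology_scc",
            "t_stage_34", "n_stage_23")
  dosim <- c("lung_v5", "lung_v10", "lung_v20", "lung_v30", "lung_dmean")
  for (s in 1:5) {
    cfg <- cohort_config(n_patients = 3000L, prevalence = 0.4,
                         volume_shape = c(4L, 4L, 2L), n_radiomics = 2L,
                         n_radiomics_informative = 0L, seed = s)
    coh <- generate_cohort(cfg)
    y <- unname(coh$ground_truth$bag_labels)
    sel <- suppressWarnings(attnmil:::select_clinical_block(
      coh$clinical, y, seq_along(y), alpha = 0.05, seed = s))
    expect_true(all(dosim %in% sel$names),
                label = sprintf("seed %d dosimetric recovery", s))
    expect_false(any(cats %in% sel$names),
                 label = sprintf("seed %d categorical rejection", s))
  }
})
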