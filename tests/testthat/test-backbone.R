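test_that("min-max normalization maps to [0,1] as printed, with opt-in [-1,1]", {
  v <- array(c(0, 500, 1000, 250, 750, 500), c(1, 2, 3))
  z <- minmax_normalize(v)
  expect_equal(range(z), c(0, 1))
  expect_equal(z[1, 1, 1], 0)
  expect_equal(z[1, 1, 2], 1)
  expect_equal(z[1, 2, 3], 0.5)
  expect_true(attr(z, "normalized"))

  # HU-style oracle: min -1024, max 400, voxel -312 -> 0.5
  v2 <- array(c(-1024, 400, -312, 0), c(2, 2, 1))
  z2 <- minmax_normalize(v2)
  expect_equal(z2[1, 2, 1], (-312 + 1024) / 1424)
  expect_equal(z2[1, 2, 1], 0.5)

  s <- minmax_normalize(v, symmetric = TRUE)
  expect_equal(range(s), c(-1, 1))

  expect_error(minmax_normalize(array(7, c(2, 2, 2))), "degenerate")

  # bounds hold for arbitrary non-constant volumes
  set.seed(1)
  for (i in 1:20) {
    r <- minmax_normalize(array(rnorm(60, sd = 10^runif(1, -2, 3)), c(5, 4, 3)))
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("backbone construction is deterministic and headless", {
  cfg <- tiny_backbone(seed = 4)
  b1 <- build_backbone(cfg)
  b2 <- build_backbone(cfg)
  expect_identical(b1$params, b2$params)
  expect_error(backbone_config(classifier_head = TRUE), "classifier")
  expect_error(backbone_config(input_channels = 3), "channels")
})

test_that("feature-map shape follows the closed-form law", {
  cfg <- backbone_config(widths = c(8L, 16L), spatial_pool = c(2L, 2L),
                         depth_pool = c(2L, 2L), d = 8L)
  shp <- backbone_shape(cfg, c(32L, 32L, 16L))
  expect_equal(shp$k, 4L)             # 16 / (2*2)
  expect_equal(shp$map, c(8, 8, 4, 16))

  # incompatible downsampling rejected
  expect_error(backbone_shape(cfg, c(32L, 32L, 6L)), "does not divide")
  cfg2 <- backbone_config(widths = rep(4L, 3), spatial_pool = rep(2L, 3),
                          depth_pool = rep(2L, 3), d = 4L)
  expect_error(backbone_shape(cfg2, c(4L, 4L, 8L)), "")

  # shape law holds across random admissible configs
  set.seed(6)
  for (i in 1:10) {
    nb <- sample(1:3, 1)
    dp <- sample(c(1L, 2L), nb, replace = TRUE)
    cfgr <- backbone_config(widths = sample(2:6, nb), d = 5L,
                            spatial_pool = rep(1L, nb), depth_pool = dp)
    depth <- 8L * prod(dp)
    got <- backbone_shape(cfgr, c(6L, 6L, depth))
    expect_equal(got$k, depth / prod(dp))
  }
})

test_that("convolution matches a direct triple-loop reference", {
  set.seed(2)
  H <- 5L; W <- 4L; S <- 4L; C <- 2L; Cout <- 3L
  x <- array(rnorm(H * W * S * C), c(H, W, S, C))
  for (KD in c(1L, 3L)) {
    P <- attnmil:::im2col3(as.numeric(x), H, W, S, C, KD)
    K <- matrix(rnorm(9 * KD * C * Cout), 9 * KD * C, Cout)
    got <- array(P %*% K, c(H, W, S, Cout))
    rad <- (KD - 1L) %/% 2L
    ref <- array(0, c(H, W, S, Cout))
    for (co in 1:Cout) for (h in 1:H) for (w in 1:W) for (s in 1:S) {
      acc <- 0
      for (c in 1:C) for (dh in -1:1) for (dw in -1:1) for (ds in -rad:rad) {
        hh <- h + dh; ww <- w + dw; ss <- s + ds
        val <- if (hh >= 1 && hh <= H && ww >= 1 && ww <= W &&
                   ss >= 1 && ss <= S) x[hh, ww, ss, c] else 0
        kidx <- (c - 1) * 9 * KD + (ds + rad) * 9 + (dw + 1) * 3 + (dh + 1) + 1
        acc <- acc + val * K[kidx, co]
      }
      ref[h, w, s, co] <- acc
    }
    expect_equal(got, ref, tolerance = 1e-12)
    # col2im is the exact adjoint
    G <- matrix(rnorm(length(P)), nrow(P), ncol(P))
    expect_equal(sum(P * G),
                 sum(as.numeric(attnmil:::col2im3(G, H, W, S, C, KD)) *
                       as.numeric(x)),
                 tolerance = 1e-10)
  }
})

test_that("pooling matches an apply() reference for max and avg", {
  set.seed(3)
  x <- array(rnorm(8 * 6 * 4 * 3), c(8, 6, 4, 3))
  f <- c(2L, 3L, 2L)
  for (type in c("max", "avg")) {
    got <- attnmil:::pool_fwd(x, f, type)$y
    ref <- array(0, c(4, 2, 2, 3))
    fun <- if (type == "max") max else mean
    for (i in 1:4) for (j in 1:2) for (k in 1:2) for (c in 1:3) {
      ref[i, j, k, c] <- fun(x[(2 * i - 1):(2 * i), (3 * j - 2):(3 * j),
                               (2 * k - 1):(2 * k), c])
    }
    expect_equal(got, ref)
  }
})

test_that("instance extraction obeys granularity contracts", {
  cfg <- tiny_backbone(seed = 8)   # depth pool 2 x 1
  bb <- build_backbone(cfg)
  v <- minmax_normalize(array(rnorm(12 * 12 * 8), c(12, 12, 8)))

  inst <- extract_instances(v, bb)
  expect_s3_class(inst, "instance_features")
  expect_equal(inst$k, 4L)                      # 8 / 2
  expect_equal(ncol(inst$features), cfg$d)
  expect_equal(inst$provenance[[1]], c(from = 1L, to = 2L))
  expect_equal(inst$provenance[[4]], c(from = 7L, to = 8L))
  # provenance intervals ordered and non-overlapping
  froms <- vapply(inst$provenance, `[[`, numeric(1), "from")
  tos <- vapply(inst$provenance, `[[`, numeric(1), "to")
  expect_true(all(diff(froms) > 0))
  expect_true(all(froms[-1] > tos[-length(tos)]))

  # window granularity: window 1 on depth 8 gives one instance per slice
  instw <- extract_instances(v, bb, granularity = "per_slice_window",
                             window = 1L)
  expect_equal(instw$k, 8L)
  expect_equal(instw$provenance[[3]], c(from = 3L, to = 3L))

  # determinism
  inst2 <- extract_instances(v, bb)
  expect_identical(inst$features, inst2$features)

  # normalization guard with explicit bypass
  raw <- array(rnorm(12 * 12 * 8), c(12, 12, 8))
  expect_error(extract_instances(raw, bb), "not normalized")
  expect_silent(extract_instances(raw, bb, bypass_normalization = TRUE))
})

test_that("analytic gradients match central differences through the whole model", {
  shp <- c(6L, 6L, 4L)
  bc <- backbone_config(widths = c(3L, 4L), spatial_pool = c(2L, 1L),
                        depth_pool = c(2L, 1L), d = 5L, seed = 3)
  vol <- minmax_normalize(array(rnorm(prod(shp)), shp))
  y <- 1
  eps <- 1e-4
  for (pooling in c("daae", "mean")) {
    model <- init_mil_model(bc, shp, L = 4L, d_prime = 3L,
                            pooling = pooling, seed = 3)
    params <- attnmil:::model_params(model)
    fv <- attnmil:::model_forward_volume(model, vol, keep_cache = TRUE)
    g <- attnmil:::model_backward_volume(model, fv, fv$score - y)
    loss_of <- function(m) {
      attnmil:::bce_loss(attnmil:::model_forward_volume(m, vol)$score, y)
    }
    set.seed(99)
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
      for (i in idx) {
        pp <- params
        pp[[nm]][i] <- pp[[nm]][i] + eps
        up <- loss_of(attnmil:::set_model_params(model, pp))
        pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
        dn <- loss_of(attnmil:::set_model_params(model, pp))
        num <- (up - dn) / (2 * eps)
        expect_lt(abs(num - g[[nm]][i]) /
                    max(1e-6, abs(num) + abs(g[[nm]][i])), 1e-3,
                  label = sprintf("%s grad of %s[%d]", pooling, nm, i))
      }
    }
  }
})
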