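test_that("attention pooling normalizes and matches direct arithmetic", {
  # singleton softmax
  h <- matrix(c(0.3, -0.2), 1, 2)
  p <- random_attn_params(2, 3, seed = 1)
  ap <- attention_pool(h, p)
  expect_equal(ap$a, 1)
  expect_equal(ap$Z, as.numeric(h))

  # identical instances share the weight
  h2 <- rbind(c(1, 2), c(1, 2))
  ap2 <- attention_pool(h2, p)
  expect_equal(ap2$a, c(0.5, 0.5))

  # explicit small case against elementwise exp/tanh evaluation
  H <- matrix(c(0.1, -0.4, 0.7, 0.2, -0.3, 0.5), 3, 2)
  prm <- list(V = matrix(c(0.2, -0.1, 0.3, 0.4), 2, 2), w = c(0.5, -0.7))
  got <- attention_pool(H, prm)
  ref <- ref_attention(H, prm)
  expect_equal(got$a, ref$a, tolerance = 1e-12)
  expect_equal(got$Z, ref$Z, tolerance = 1e-12)
  expect_equal(sum(got$a), 1, tolerance = 1e-9)

  expect_error(attention_pool(H, list(V = matrix(0, 2, 3), w = c(1, 1))),
               "shapes")
})

test_that("top-M selection ranks by weight with stable index tie-break", {
  expect_identical(top_m_select(c(0.1, 0.5, 0.4), 2), c(2L, 3L))
  expect_identical(top_m_select(rep(0.25, 4), 2), c(1L, 2L))
  expect_error(top_m_select(c(0.4, 0.6), 3), "exceed")
  expect_error(top_m_select(c(0.4, 0.6), 0), "M")

  set.seed(12)
  for (i in 1:25) {
    a <- runif(sample(2:12, 1))
    M <- sample(seq_along(a), 1)
    got <- top_m_select(a, M)
    ref <- order(-a, seq_along(a))[1:M]   # full-sort reference
    expect_identical(got, ref)
    expect_equal(a[got], sort(a, decreasing = TRUE)[1:M])
  }
})

test_that("the adaptive-M controller follows sigma(MLP(p)) * k with clamping", {
  zero_ctrl <- m_controller(layers = list(list(W = matrix(0, 1, 8), b = 0)))
  expect_identical(update_m(rep(0.1, 5), 10, zero_ctrl), 5L)  # sigma(0) = 0.5

  low_ctrl <- m_controller(layers = list(list(W = matrix(0, 1, 8), b = -20)))
  expect_identical(update_m(rep(0.1, 5), 8, low_ctrl), 1L)    # lower clamp
  high_ctrl <- m_controller(layers = list(list(W = matrix(0, 1, 8), b = 20)))
  expect_identical(update_m(rep(0.1, 5), 8, high_ctrl), 8L)   # upper clamp

  # fixed 1-layer controller, p = (0.7, 0.3) padded to length 8:
  # hand arithmetic for the logit and the rounded count
  W <- matrix(c(1, -1, rep(0, 6)), 1, 8)
  ctrl <- m_controller(layers = list(list(W = W, b = 0.2)))
  scores <- c(log(0.7), log(0.3))   # softmax gives exactly (0.7, 0.3)
  logit <- 0.7 * 1 + 0.3 * (-1) + 0.2
  expect_identical(update_m(scores, 6, ctrl),
                   as.integer(min(max(floor(sigmoid(logit) * 6 + 0.5), 1), 6)))

  expect_error(update_m(c(0.5), 0, zero_ctrl), "bag size")
  expect_error(update_m(numeric(0), 4, zero_ctrl), "top score")

  # truncation renormalizes the distribution
  long <- rnorm(12)
  expect_true(update_m(long, 12, zero_ctrl) >= 1L)
})

test_that("query/value projection is a plain row-wise linear map", {
  H <- random_bag(4, 3, seed = 5)
  I3 <- diag(3)
  pj <- project_qv(H, list(Wq = I3, Wv = matrix(0, 3, 3)))
  expect_equal(pj$Q, H %*% t(I3))
  expect_true(all(pj$V == 0))

  set.seed(6)
  Wq <- matrix(rnorm(6), 2, 3); Wv <- matrix(rnorm(6), 2, 3)
  pj2 <- project_qv(H, list(Wq = Wq, Wv = Wv))
  expect_equal(pj2$Q, H %*% t(Wq), tolerance = 1e-12)
  expect_equal(pj2$V, H %*% t(Wv), tolerance = 1e-12)

  expect_error(project_qv(H, list(Wq = matrix(0, 2, 4), Wv = Wv)), "Wq")
  expect_error(project_qv(H, list(Wq = list(matrix(0, 2, 3), matrix(0, 3, 3)),
                                  Wv = Wv)), "head")
})

test_that("distance weights follow the printed normalizer and its alternative", {
  # singleton bag
  expect_equal(distance_weights(matrix(1, 1, 2), 1), 1)

  # identical queries: uniform softmax symmetry, printed normalizer
  Q <- matrix(1, 4, 2)
  D <- distance_weights(Q, c(1, 2))
  expect_equal(D, rep(2 / 16, 4))
  expect_equal(sum(D), 2 / 4)                  # M / k
  D2 <- distance_weights(Q, c(1, 2), normalizer = "critical")
  expect_equal(sum(D2), 1)

  # explicit inner-product/softmax evaluation
  Q3 <- matrix(c(0.5, -0.2, 0.8, 0.1, 0.4, -0.6), 3, 2)
  got <- distance_weights(Q3, 1)
  expect_equal(got, ref_distance(Q3, 1), tolerance = 1e-12)

  expect_error(distance_weights(Q3, integer(0)), "nonempty")
  expect_error(distance_weights(Q3, 9), "out of range")
})

test_that("bag embedding is the weighted sum of value rows", {
  v1 <- c(2, -1)
  expect_equal(bag_embed(1, matrix(v1, 1, 2))$B, v1)

  V <- rbind(c(3, 1), c(3, 1))
  expect_equal(bag_embed(c(0.5, 0.5), V)$B, c(3, 1))

  got <- bag_embed(c(0.25, 0.75), rbind(c(1, 0), c(0, 2)))
  expect_equal(got$B, c(0.25, 1.5))
  expect_identical(got$flat, got$B)
  expect_length(got$flat, length(got$B))

  expect_error(bag_embed(c(0.2, 0.8), matrix(1, 3, 2)), "length mismatch")
})

test_that("forward_bag composes the chain and handles degenerate bags", {
  bc <- tiny_backbone(seed = 2)
  model <- init_mil_model(bc, c(12L, 12L, 8L), L = 6L, d_prime = 4L, seed = 2)

  # k = 1 bag: M forced to 1, D = [1], B = v1
  h1 <- matrix(rnorm(8), 1, 8)
  fv <- forward_bag(h1, model)
  expect_equal(fv$state$M, 1L)
  expect_equal(fv$state$D, 1)
  expect_equal(fv$embedding$B, as.numeric(model$qv$Wv %*% h1[1, ]))
  expect_gt(fv$score, 0); expect_lt(fv$score, 1)

  # determinism
  H <- random_bag(4, 8, seed = 3)
  f1 <- forward_bag(H, model)
  f2 <- forward_bag(H, model)
  expect_identical(f1$score, f2$score)
  expect_identical(f1$state, f2$state)
})

test_that("permuting instances permutes a and D and leaves B invariant", {
  bc <- tiny_backbone(seed = 7)
  model <- init_mil_model(bc, c(12L, 12L, 8L), L = 6L, d_prime = 4L, seed = 7)
  set.seed(31)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    H <- matrix(rnorm(k * 8), k, 8)
    perm <- sample(k)
    f0 <- forward_bag(H, model)
    fp <- forward_bag(H[perm, , drop = FALSE], model)
    expect_equal(fp$state$a, f0$state$a[perm], tolerance = 1e-12)
    expect_equal(fp$state$D, f0$state$D[perm], tolerance = 1e-12)
    expect_equal(fp$embedding$B, f0$embedding$B, tolerance = 1e-12)
    expect_equal(fp$score, f0$score, tolerance = 1e-12)
  }
})

test_that("attention and distance weights keep their normalization invariants", {
  bc <- tiny_backbone(seed = 9)
  model <- init_mil_model(bc, c(12L, 12L, 8L), L = 6L, d_prime = 4L, seed = 9)
  modelc <- model; modelc$normalizer <- "critical"
  set.seed(17)
  for (i in 1:200) {
    k <- sample(1:9, 1)
    H <- matrix(rnorm(k * 8, sd = runif(1, 0.1, 2)), k, 8)
    f <- forward_bag(H, model)
    expect_equal(sum(f$state$a), 1, tolerance = 1e-9)
    expect_true(all(f$state$a >= 0))
    expect_equal(sum(f$state$D), f$state$M / k, tolerance = 1e-9)
    fc <- forward_bag(H, modelc)
    expect_equal(sum(fc$state$D), 1, tolerance = 1e-9)
  }
})
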