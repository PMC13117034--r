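# Shared fixtures: everything is generated in code at test time.

# a small cohort for harness-level tests (volumes stay tiny)
tiny_cohort <- function(n = 24, shape = c(12L, 12L, 8L), seed = 5) {
  generate_cohort(cohort_config(
    n_patients = n, volume_shape = shape, prevalence = 0.5,
    n_radiomics = 30L, n_radiomics_informative = 4L, seed = seed))
}

tiny_backbone <- function(seed = 5) {
  backbone_config(widths = c(4L, 8L), spatial_pool = c(2L, 2L),
                  depth_pool = c(2L, 1L), d = 8L, seed = seed)
}

tiny_stage1 <- function(seed = 5, max_epochs = 4L, patience = 4L, ...) {
  stage1_config(lr = 1e-3, max_epochs = max_epochs, patience = patience,
                L = 8L, d_prime = 4L, seed = seed, ...)
}

random_bag <- function(k, d, seed) {
  set.seed(seed)
  matrix(rnorm(k * d), k, d)
}

random_attn_params <- function(d, L, seed) {
  set.seed(seed)
  list(V = matrix(rnorm(L * d), L, d), w = rnorm(L))
}

# independent brute-force references used by the oracle-equivalence tests
ref_attention <- function(H, params) {
  k <- nrow(H)
  e <- numeric(k)
  for (i in seq_len(k)) {
    e[i] <- sum(params$w * tanh(params$V %*% H[i, ]))
  }
  a <- exp(e - max(e)); a <- a / sum(a)
  Z <- rep(0, ncol(H))
  for (i in seq_len(k)) Z <- Z + a[i] * H[i, ]
  list(a = a, Z = Z)
}

ref_distance <- function(Q, critical, normalizer = "bag") {
  k <- nrow(Q)
  D <- numeric(k)
  for (m in critical) {
    l <- numeric(k)
    for (n in seq_len(k)) l[n] <- sum(Q[n, ] * Q[m, ])
    s <- exp(l) / sum(exp(l))
    D <- D + s
  }
  D / if (normalizer == "bag") k else length(critical)
}
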