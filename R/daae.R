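# Dual-attention adaptive bag embedding: a first attention layer scores and
# pools instances; the top-M instances by attention become the critical set
# (M itself adapted by a small confidence controller); a second layer
# calibrates every instance by its inner-product softmax distance to the
# critical set and forms the bag embedding as the distance-weighted sum of
# value projections. Backward passes are hand-derived; the hard top-M index
# selection carries no gradient (stop-gradient), so gradients flow through
# the first-layer weights a (via the pooled vector) and through D only.

#' First-layer attention MIL pooling
#'
#' `a_k = softmax_k( w' tanh(V h_k') )`; the pooled bag vector is
#' `Z = sum_k a_k h_k`. Weights are nonnegative and sum to 1.
#'
#' @param features k x d instance matrix.
#' @param params list with `V` (L x d) and `w` (length L).
#' @return list with `a` (length k), `Z` (length d), and internals used by
#'   the backward pass (`tanh`, `logits`).
#' @export
attention_pool <- function(features, params) {
  features <- as.matrix(features)
  V <- params$V; w <- params$w
  if (ncol(features) != ncol(V) || nrow(V) != length(w)) {
    abort_domain("attention parameter shapes inconsistent with features")
  }
  Tm <- tanh(features %*% t(V))          # k x L
  e <- as.numeric(Tm %*% w)              # k
  a <- softmax(e)
  Z <- as.numeric(crossprod(features, a))
  list(a = a, Z = Z, tanh = Tm, logits = e)
}

#' Top-M instance selection
#'
#' Indices of the M largest attention scores, in descending score order;
#' ties break by ascending index (stable).
#'
#' @param a attention weights.
#' @param M number of critical instances, 1 <= M <= length(a).
#' @return integer index vector of length M.
#' @export
top_m_select <- function(a, M) {
  k <- length(a)
  M <- check_count(M, "M")
  if (M > k) abort_domain("M cannot exceed the bag size")
  order(-a, seq_len(k))[seq_len(M)]
}

#' Confidence controller (small MLP over the top-score distribution)
#'
#' @param input_len fixed controller input length (the top-score softmax is
#'   padded or truncated to this length).
#' @param hidden hidden width.
#' @param seed initialization seed.
#' @param layers optional explicit list of `list(W, b)` layers (overrides
#'   the random initialization; the last layer must output one logit).
#' @return object of class `m_controller`.
#' @export
m_controller <- function(input_len = 8L, hidden = 16L, seed = 1L,
                         layers = NULL) {
  if (is.null(layers)) {
    layers <- with_stream(seed, "controller-init", list(
      list(W = matrix(rnorm(hidden * input_len, sd = 0.1), hidden, input_len),
           b = rep(0, hidden)),
      list(W = matrix(rnorm(hidden, sd = 0.1), 1, hidden), b = 0)
    ))
  }
  structure(list(layers = layers, input_len = input_len),
            class = "m_controller")
}

controller_logit <- function(controller, p) {
  x <- p
  nl <- length(controller$layers)
  for (i in seq_len(nl)) {
    ly <- controller$layers[[i]]
    x <- as.numeric(ly$W %*% x + ly$b)
    if (i < nl) x <- tanh(x)
  }
  x[1]
}

#' Adaptive update of the critical-instance count M
#'
#' `p = softmax(top scores)` (padded with zeros or truncated-and-renormalized
#' to the controller's fixed input length); the next count is
#' `clamp(round(sigmoid(MLP(p)) * k), 1, k)` with round-half-up.
#'
#' @param top_scores attention scores of the current critical set.
#' @param k bag size.
#' @param controller an [m_controller()].
#' @return integer M' in `[1, k]`.
#' @export
update_m <- function(top_scores, k, controller) {
  if (k < 1) abort_domain("bag size must be >= 1")
  if (length(top_scores) < 1L) abort_domain("need at least one top score")
  p <- softmax(top_scores)
  len <- controller$input_len
  if (length(p) > len) {
    p <- p[seq_len(len)]
    p <- p / sum(p)
  } else if (length(p) < len) {
    p <- c(p, rep(0, len - length(p)))
  }
  val <- sigmoid(controller_logit(controller, p)) * k
  as.integer(min(max(round_half_up(val), 1), k))
}

#' Query/value projection of instance features
#'
#' Row-wise linear maps `q_k = Wq h_k`, `v_k = Wv h_k` (no nonlinearity).
#' With more than one head, `Wq` is a list of per-head matrices of equal
#' output dimension.
#'
#' @param features k x d instance matrix.
#' @param params list with `Wq` (d' x d, or list of such) and `Wv` (d' x d).
#' @return list with `Q` (k x d', or list per head) and `V` (k x d').
#' @export
project_qv <- function(features, params) {
  features <- as.matrix(features)
  Wq <- params$Wq
  if (!is.list(Wq)) Wq <- list(Wq)
  dims <- vapply(Wq, nrow, integer(1))
  if (length(unique(dims)) != 1L) {
    abort_domain("per-head query output dimensions must agree")
  }
  for (W in Wq) {
    if (ncol(W) != ncol(features)) abort_domain("Wq shape mismatch")
  }
  if (ncol(params$Wv) != ncol(features)) abort_domain("Wv shape mismatch")
  Q <- lapply(Wq, function(W) features %*% t(W))
  list(Q = if (length(Q) == 1L) Q[[1]] else Q,
       V = features %*% t(params$Wv))
}

#' Second-layer distance calibration weights
#'
#' For each instance k,
#' `D_k = (1/N) * sum_{m in critical} softmax_n(<q_n, q_cm>)[k]`,
#' where the softmax runs over all instances n. Under the printed
#' normalizer (`N` = bag size) the weights sum to `M/k` exactly; the
#' alternative `critical` normalizer (1/M) makes them sum to 1.
#'
#' @param Q k x d' query matrix.
#' @param critical nonempty critical-instance index vector.
#' @param normalizer `"bag"` (1/k, the printed form) or `"critical"` (1/M).
#' @return length-k nonnegative weight vector.
#' @export
distance_weights <- function(Q, critical, normalizer = c("bag", "critical")) {
  normalizer <- match.arg(normalizer)
  Q <- as.matrix(Q)
  k <- nrow(Q)
  if (length(critical) == 0L) abort_domain("critical set must be nonempty")
  if (any(critical < 1) || any(critical > k)) {
    abort_domain("critical index out of range")
  }
  D <- numeric(k)
  for (m in critical) {
    D <- D + softmax(as.numeric(Q %*% Q[m, ]))
  }
  D / if (normalizer == "bag") k else length(critical)
}

#' Bag embedding from calibrated weights
#'
#' `B = sum_k D_k v_k`; the flattened deep-feature vector equals the
#' embedding laid out as a plain numeric vector.
#'
#' @param D length-k weights.
#' @param Vvals k x d' value matrix.
#' @return object of class `bag_embedding` with `B` and `flat`.
#' @export
bag_embed <- function(D, Vvals) {
  Vvals <- as.matrix(Vvals)
  if (length(D) != nrow(Vvals)) abort_domain("weight/value length mismatch")
  B <- as.numeric(crossprod(Vvals, D))
  structure(list(B = B, flat = as.numeric(B)), class = "bag_embedding")
}

#' Initialize a MIL model (backbone + dual-attention head + classifier)
#'
#' @param backbone_cfg a [backbone_config()].
#' @param input_shape (H, W, S) the model will operate on (fixes the
#'   projection width and the bag size k).
#' @param L first-layer attention dimension.
#' @param d_prime query/value projection dimension.
#' @param pooling `"daae"` (dual-attention adaptive embedding) or `"mean"`
#'   (mean-pooling MIL baseline).
#' @param normalizer distance-weight normalizer, see [distance_weights()].
#' @param seed initialization seed.
#' @return object of class `mil_model`.
#' @export
init_mil_model <- function(backbone_cfg, input_shape, L = 32L, d_prime = 16L,
                           pooling = c("daae", "mean"),
                           normalizer = c("bag", "critical"), seed = 1L) {
  pooling <- match.arg(pooling)
  normalizer <- match.arg(normalizer)
  shp <- backbone_shape(backbone_cfg, input_shape)
  k <- shp$k
  flat_len <- prod(shp$map[c(1, 2, 4)])
  backbone <- build_backbone(backbone_cfg)
  backbone$params$proj <- init_projection(backbone, flat_len)
  d <- backbone_cfg$d
  head_params <- with_stream(seed, "head-init", list(
    attn = list(V = matrix(rnorm(L * d, sd = sqrt(1 / d)), L, d),
                w = rnorm(L, sd = sqrt(1 / L))),
    qv = list(Wq = matrix(rnorm(d_prime * d, sd = sqrt(1 / d)), d_prime, d),
              Wv = matrix(rnorm(d_prime * d, sd = sqrt(1 / d)), d_prime, d)),
    head = list(uZ = rnorm(d, sd = sqrt(1 / d)),
                uB = rnorm(d_prime, sd = sqrt(1 / d_prime)),
                b = 0)
  ))
  structure(list(
    backbone = backbone,
    attn = head_params$attn,
    qv = head_params$qv,
    head = head_params$head,
    controller = m_controller(seed = seed),
    pooling = pooling,
    normalizer = normalizer,
    input_shape = as.integer(input_shape),
    k = k, d = d, d_prime = d_prime, L = L,
    M_state = as.integer(ceiling(k / 2)),
    M_inference = NULL,
    M_log = integer(0),
    trained = FALSE,
    seed = as.integer(seed)
  ), class = "mil_model")
}

#' Forward pass over one bag of instance features
#'
#' Chains attention pooling, top-M selection (with the adaptive-M update in
#' training mode), query/value projection, distance calibration, bag
#' embedding and the linear-sigmoid classifier head. For the mean-pooling
#' baseline the bag representation is the instance mean and the second
#' layer is skipped.
#'
#' @param features an `instance_features` object or k x d matrix.
#' @param model a `mil_model`.
#' @param training update-M behaviour: in training mode the controller
#'   proposes the next M (returned as `new_M`); in inference mode the
#'   frozen M is used.
#' @return list with `score` (in (0,1)), `embedding` (a [bag_embed()]
#'   result), and `state` (attention weights a, top indices, M, D, k).
#' @export
forward_bag <- function(features, model, training = FALSE) {
  H <- if (inherits(features, "instance_features")) features$features
       else as.matrix(features)
  k <- nrow(H)
  if (model$pooling == "mean") {
    Z <- colMeans(H)
    z <- sum(model$head$uZ * Z) + model$head$b
    s <- sigmoid(z)
    emb <- structure(list(B = Z, flat = as.numeric(Z)),
                     class = "bag_embedding")
    return(list(score = s, embedding = emb,
                state = list(a = rep(1 / k, k), top_indices = integer(0),
                             M = NA_integer_, D = NULL, k = k),
                Z = Z, new_M = NA_integer_))
  }
  ap <- attention_pool(H, model$attn)
  M_use <- if (!training && !is.null(model$M_inference)) model$M_inference
           else model$M_state
  M_use <- max(1L, min(as.integer(M_use), k))
  idx <- top_m_select(ap$a, M_use)
  new_M <- if (training) update_m(ap$a[idx], k, model$controller)
           else NA_integer_
  pj <- project_qv(H, model$qv)
  Qs <- if (is.list(pj$Q)) pj$Q else list(pj$Q)
  Dh <- lapply(Qs, distance_weights, critical = idx,
               normalizer = model$normalizer)
  D <- Reduce(`+`, Dh) / length(Dh)
  emb <- bag_embed(D, pj$V)
  z <- sum(model$head$uZ * ap$Z) + sum(model$head$uB * emb$B) + model$head$b
  s <- sigmoid(z)
  list(score = s, embedding = emb,
       state = list(a = ap$a, top_indices = idx, M = M_use, D = D, k = k),
       Z = ap$Z, attn_cache = ap, Q = Qs[[1]], Vv = pj$V, new_M = new_M)
}

# Backward pass of the dual-attention head for one bag.
# dz is dLoss/dlogit of the classifier head. Returns parameter gradients
# and dH (k x d), the gradient flowing back into the instance features.
daae_backward <- function(model, H, fwd, dz) {
  k <- nrow(H)
  if (model$pooling == "mean") {
    gZ <- dz * model$head$uZ
    return(list(
      head = list(uZ = dz * fwd$Z, uB = NULL, b = dz),
      attn = NULL, qv = NULL,
      dH = matrix(rep(gZ / k, each = k), k, model$d)
    ))
  }
  a <- fwd$state$a
  D <- fwd$state$D
  idx <- fwd$state$top_indices
  Q <- fwd$Q
  Vv <- fwd$Vv
  Z <- fwd$Z
  B <- fwd$embedding$B
  guZ <- dz * Z
  guB <- dz * B
  gZ <- dz * model$head$uZ
  gB <- dz * model$head$uB
  # bag embedding: B = Vv' D
  dD <- as.numeric(Vv %*% gB)
  dVv <- outer(D, gB)
  gWv <- crossprod(dVv, H)
  dH <- dVv %*% model$qv$Wv
  # distance weights: D = (1/norm) sum_m softmax(Q q_m); indices are
  # stop-gradient constants
  norm <- if (model$normalizer == "bag") k else length(idx)
  dsm <- dD / norm
  dQ <- matrix(0, k, ncol(Q))
  for (m in idx) {
    sm <- softmax(as.numeric(Q %*% Q[m, ]))
    dl <- sm * (dsm - sum(sm * dsm))
    dQ <- dQ + outer(dl, Q[m, ])
    dQ[m, ] <- dQ[m, ] + as.numeric(crossprod(Q, dl))
  }
  gWq <- crossprod(dQ, H)
  dH <- dH + dQ %*% model$qv$Wq
  # pooled vector: Z = H' a
  da <- as.numeric(H %*% gZ)
  dH <- dH + outer(a, gZ)
  # softmax over attention logits
  de <- a * (da - sum(a * da))
  Tm <- fwd$attn_cache$tanh
  gw <- as.numeric(crossprod(Tm, de))
  dTm <- outer(de, model$attn$w)
  dpre <- dTm * (1 - Tm^2)
  gV <- crossprod(dpre, H)
  dH <- dH + dpre %*% model$attn$V
  list(head = list(uZ = guZ, uB = guB, b = dz),
       attn = list(V = gV, w = gw),
       qv = list(Wq = gWq, Wv = gWv),
       dH = dH)
}
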