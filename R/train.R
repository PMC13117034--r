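# Stage-1 training: backbone + dual-attention head + linear sigmoid
# classifier trained with binary cross-entropy on bag labels. Adam with
# decoupled-from-nothing L2 (weight decay added to the gradient, as in the
# reference Adam), mini-batches of bags, early stopping on validation loss.

#' Stage-1 training configuration
#'
#' Defaults follow the usual protocol for this kind of network: Adam with
#' initial learning rate 1e-4 and weight decay 1e-5, batch size 4, at most
#' 100 epochs with early stopping at patience 15 on validation loss.
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty added to gradients.
#' @param batch_size bags per optimizer step.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction fraction of bags held out for validation.
#' @param L attention dimension of the first layer.
#' @param d_prime query/value projection dimension.
#' @param pooling `"daae"` or `"mean"` (mean-pooling MIL baseline).
#' @param normalizer distance-weight normalizer (see [distance_weights()]).
#' @param pos_weight loss weight for positive bags (1 = unweighted).
#' @param seed seed for initialization, the validation split and shuffling.
#' @return list of class `stage1_config`.
#' @export
stage1_config <- function(lr = 1e-4, weight_decay = 1e-5, batch_size = 4L,
                          max_epochs = 100L, patience = 15L,
                          val_fraction = 0.2, L = 32L, d_prime = 16L,
                          pooling = c("daae", "mean"),
                          normalizer = c("bag", "critical"),
                          pos_weight = 1, seed = 1L) {
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, L = as.integer(L),
                 d_prime = as.integer(d_prime),
                 pooling = match.arg(pooling),
                 normalizer = match.arg(normalizer),
                 pos_weight = pos_weight, seed = as.integer(seed)),
            class = "stage1_config")
}

# --- parameter plumbing -----------------------------------------------------

model_params <- function(model) {
  p <- list()
  for (b in seq_along(model$backbone$params$blocks)) {
    p[[sprintf("conv%d.K", b)]] <- model$backbone$params$blocks[[b]]$K
    p[[sprintf("conv%d.b", b)]] <- model$backbone$params$blocks[[b]]$b
  }
  p[["proj.W"]] <- model$backbone$params$proj$W
  p[["proj.b"]] <- model$backbone$params$proj$b
  if (model$pooling == "daae") {
    p[["attn.V"]] <- model$attn$V
    p[["attn.w"]] <- model$attn$w
    p[["qv.Wq"]] <- model$qv$Wq
    p[["qv.Wv"]] <- model$qv$Wv
    p[["head.uB"]] <- model$head$uB
  }
  p[["head.uZ"]] <- model$head$uZ
  p[["head.b"]] <- model$head$b
  p
}

set_model_params <- function(model, p) {
  for (b in seq_along(model$backbone$params$blocks)) {
    model$backbone$params$blocks[[b]]$K <- p[[sprintf("conv%d.K", b)]]
    model$backbone$params$blocks[[b]]$b <- p[[sprintf("conv%d.b", b)]]
  }
  model$backbone$params$proj$W <- p[["proj.W"]]
  model$backbone$params$proj$b <- p[["proj.b"]]
  if (model$pooling == "daae") {
    model$attn$V <- p[["attn.V"]]
    model$attn$w <- p[["attn.w"]]
    model$qv$Wq <- p[["qv.Wq"]]
    model$qv$Wv <- p[["qv.Wv"]]
    model$head$uB <- p[["head.uB"]]
  }
  model$head$uZ <- p[["head.uZ"]]
  model$head$b <- p[["head.b"]]
  model
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# --- full-model forward / backward over one volume --------------------------

model_forward_volume <- function(model, volume, training = FALSE,
                                 keep_cache = FALSE) {
  if (!is_normalized(volume)) volume <- minmax_normalize(volume)
  cs <- conv_stack_forward(model$backbone, volume, keep_cache = keep_cache)
  flat <- flatten_positions(cs$map)
  H <- flat %*% t(model$backbone$params$proj$W)
  H <- sweep(H, 2, model$backbone$params$proj$b, `+`)
  fwd <- forward_bag(H, model, training = training)
  c(fwd, list(H = H, flat = flat, conv_cache = cs$cache,
              map_dim = dim(cs$map)))
}

model_backward_volume <- function(model, fv, dz) {
  hb <- daae_backward(model, fv$H, fv, dz)
  dH <- hb$dH
  gWp <- crossprod(dH, fv$flat)
  gbp <- colSums(dH)
  dflat <- dH %*% model$backbone$params$proj$W
  md <- fv$map_dim
  dmap <- array(0, md)
  for (t_ in seq_len(md[3])) {
    dmap[, , t_, ] <- array(dflat[t_, ], dim = md[c(1, 2, 4)])
  }
  cg <- conv_stack_backward(model$backbone, dmap, fv$conv_cache)
  g <- list()
  for (b in seq_along(cg$blocks)) {
    g[[sprintf("conv%d.K", b)]] <- cg$blocks[[b]]$K
    g[[sprintf("conv%d.b", b)]] <- cg$blocks[[b]]$b
  }
  g[["proj.W"]] <- gWp
  g[["proj.b"]] <- gbp
  if (model$pooling == "daae") {
    g[["attn.V"]] <- hb$attn$V
    g[["attn.w"]] <- hb$attn$w
    g[["qv.Wq"]] <- hb$qv$Wq
    g[["qv.Wv"]] <- hb$qv$Wv
    g[["head.uB"]] <- hb$head$uB
  }
  g[["head.uZ"]] <- hb$head$uZ
  g[["head.b"]] <- hb$head$b
  g
}

bce_loss <- function(score, y, pos_weight = 1) {
  eps <- 1e-12
  w <- ifelse(y == 1, pos_weight, 1)
  -w * (y * log(score + eps) + (1 - y) * log(1 - score + eps))
}

#' Train the stage-1 MIL model on bag labels
#'
#' Trains the 3D conv backbone, the dual-attention head and a linear
#' sigmoid classifier with binary cross-entropy on patient-level (bag)
#' labels. The hard top-M selection is a stop-gradient; the adaptive M is
#' updated once per bag per forward pass and frozen at its running median
#' for inference. Early stopping monitors validation loss.
#'
#' @param volumes list of 3D arrays (raw volumes are min-max normalized
#'   internally).
#' @param labels binary bag labels aligned with `volumes`.
#' @param backbone_cfg a [backbone_config()].
#' @param config a [stage1_config()].
#' @return a trained `mil_model` with a `log` data.frame (per-epoch train
#'   and validation loss and mean M) and `M_inference` fixed.
#' @export
train_stage1 <- function(volumes, labels, backbone_cfg = backbone_config(),
                         config = stage1_config()) {
  if (length(volumes) == 0L) abort_domain("empty cohort")
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(volumes))
  shp <- dim(volumes[[1]])
  model <- init_mil_model(backbone_cfg, shp, L = config$L,
                          d_prime = config$d_prime,
                          pooling = config$pooling,
                          normalizer = config$normalizer,
                          seed = config$seed)
  vols <- lapply(volumes, function(v) {
    if (is_normalized(v)) v else minmax_normalize(v)
  })

  split <- stratified_patient_split(labels, test_fraction = config$val_fraction,
                                    seed = stream_seed(config$seed, "val-split"))
  tr_idx <- split$train
  va_idx <- split$test

  params <- model_params(model)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, M = model$M_state, epoch = 0L)
  log <- NULL
  wait <- 0L
  M_log <- integer(0)

  set.seed(stream_seed(config$seed, "train-loop"))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    tr_loss <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      i <- i + config$batch_size
      acc <- NULL
      for (j in batch) {
        model <- set_model_params(model, params)
        fv <- model_forward_volume(model, vols[[j]], training = TRUE,
                                   keep_cache = TRUE)
        y <- labels[j]
        tr_loss <- tr_loss + bce_loss(fv$score, y, config$pos_weight)
        w <- if (y == 1) config$pos_weight else 1
        dz <- w * (fv$score - y)
        g <- model_backward_volume(model, fv, dz)
        acc <- if (is.null(acc)) g else {
          for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
          acc
        }
        if (model$pooling == "daae" && !is.na(fv$new_M)) {
          model$M_state <- fv$new_M
          M_log <- c(M_log, fv$new_M)
        }
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(batch)
      st <- adam_step(params, acc, opt, config$lr, config$weight_decay)
      params <- st$params
      opt <- st$state
    }
    tr_loss <- tr_loss / length(ord)
    model <- set_model_params(model, params)
    va_loss <- mean(vapply(va_idx, function(j) {
      fv <- model_forward_volume(model, vols[[j]], training = FALSE)
      bce_loss(fv$score, labels[j], config$pos_weight)
    }, numeric(1)))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                 val_loss = va_loss,
                                 M = model$M_state))
    if (va_loss < best$loss - 1e-8) {
      best <- list(loss = va_loss, params = params, M = model$M_state,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model <- set_model_params(model, best$params)
  model$M_state <- best$M
  model$M_log <- M_log
  model$M_inference <- if (length(M_log)) {
    max(1L, min(as.integer(round_half_up(stats::median(M_log))), model$k))
  } else model$M_state
  model$trained <- TRUE
  model$log <- log
  model$config <- config
  model
}

#' Extract flattened bag-embedding deep features
#'
#' One row per patient: the flattened bag embedding under the trained
#' dual-attention model (or the mean-pooled representation for the
#' mean-pooling baseline). Feeds the LASSO selection of the deep block.
#'
#' @param model a `mil_model` (a warning is issued if untrained; features
#'   are then a random-projection baseline).
#' @param volumes named list of 3D arrays.
#' @return data.frame with `patient_id` and stable `deep_##` columns.
#' @export
extract_deep_features <- function(model, volumes) {
  if (!isTRUE(model$trained)) {
    warning("model is untrained; features are a random-initialization baseline",
            call. = FALSE)
  }
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(volumes))
  rows <- t(vapply(volumes, function(v) {
    fv <- model_forward_volume(model, v, training = FALSE)
    fv$embedding$flat
  }, numeric(if (model$pooling == "daae") model$d_prime else model$d)))
  colnames(rows) <- sprintf("deep_%02d", seq_len(ncol(rows)))
  df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  df[colnames(rows)] <- as.data.frame(rows, row.names = NULL)
  rownames(df) <- NULL
  df
}

#' Per-instance attention scores for one volume
#'
#' @param model trained `mil_model`.
#' @param volume 3D array.
#' @return data.frame with instance index, slice provenance, first-layer
#'   weight `a`, calibrated weight `D`, and the top-M `selected` flag.
#' @export
instance_attention <- function(model, volume) {
  if (!is_normalized(volume)) volume <- minmax_normalize(volume)
  inst <- extract_instances(volume, model$backbone)
  fv <- model_forward_volume(model, volume, training = FALSE)
  st <- fv$state
  data.frame(
    instance = seq_len(st$k),
    slice_from = as.integer(vapply(inst$provenance, `[[`, numeric(1), "from")),
    slice_to = as.integer(vapply(inst$provenance, `[[`, numeric(1), "to")),
    a = st$a,
    D = if (is.null(st$D)) rep(NA_real_, st$k) else st$D,
    selected = seq_len(st$k) %in% st$top_indices
  )
}
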