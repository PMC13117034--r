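# Concatenation fusion of the selected clinical, radiomics and deep blocks,
# and the sigmoid MLP predictor trained on the fused vectors.

#' Fuse selected feature blocks by concatenation
#'
#' Row-wise concatenation in the fixed block order clinical, radiomics,
#' deep. Inputs are aligned by patient id (sorted), so row order in any
#' input is immaterial. A missing modality is allowed only under the
#' explicit ablation flag; the layout records which blocks are present.
#'
#' @param clinical,radiomics,deep data.frames with `patient_id` plus the
#'   selected feature columns (NULL for an ablated block).
#' @param allow_missing permit NULL blocks (ablation studies).
#' @return object of class `fused_features`: `features` matrix, `layout`
#'   (named column spans), `patient_ids`.
#' @export
fuse <- function(clinical = NULL, radiomics = NULL, deep = NULL,
                 allow_missing = FALSE) {
  blocks <- list(clinical = clinical, radiomics = radiomics, deep = deep)
  present <- !vapply(blocks, is.null, logical(1))
  if (!any(present)) abort_domain("at least one block must be provided")
  if (any(!present) && !allow_missing) {
    abort_domain("missing modality block; pass allow_missing = TRUE ",
                 "for an ablation run")
  }
  ids <- NULL
  for (b in blocks[present]) {
    stopifnot(is.data.frame(b), "patient_id" %in% names(b))
    bid <- sort(b$patient_id)
    if (is.null(ids)) ids <- bid
    else if (!identical(ids, bid)) abort_domain("patient id sets differ")
  }
  mats <- list()
  layout <- list()
  at <- 0L
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b)) {
      layout[[nm]] <- integer(0)
      next
    }
    b <- b[match(ids, b$patient_id), , drop = FALSE]
    m <- as.matrix(b[setdiff(names(b), "patient_id")])
    if (ncol(m)) colnames(m) <- paste0(nm, ".", colnames(m))
    mats[[nm]] <- m
    layout[[nm]] <- at + seq_len(ncol(m))
    at <- at + ncol(m)
  }
  structure(list(features = do.call(cbind, mats), layout = layout,
                 patient_ids = ids), class = "fused_features")
}

#' MLP predictor configuration
#'
#' One hidden layer of sigmoid units and a sigmoid output neuron, trained
#' with binary cross-entropy and Adam; inputs are re-standardized with
#' training statistics before the net (disable with `standardize = FALSE`).
#'
#' @param hidden hidden-layer width; 0 drops the hidden layer, leaving a
#'   single sigmoid neuron (logistic regression).
#' @param lr,weight_decay,batch_size,max_epochs,patience optimizer protocol.
#' @param val_fraction validation fraction for early stopping (0 disables
#'   the held-out monitor; training loss is monitored instead).
#' @param threshold decision threshold on the output probability.
#' @param standardize re-standardize inputs with training statistics.
#' @param seed initialization/shuffling seed.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = 32L, lr = 1e-4, weight_decay = 1e-5,
                       batch_size = 4L, max_epochs = 100L, patience = 15L,
                       val_fraction = 0.2, threshold = 0.5,
                       standardize = TRUE, seed = 1L) {
  if (threshold <= 0 || threshold >= 1) {
    abort_domain("`threshold` must lie in (0, 1)")
  }
  structure(list(hidden = as.integer(hidden), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, threshold = threshold,
                 standardize = standardize, seed = as.integer(seed)),
            class = "mlp_config")
}

fused_matrix <- function(features) {
  if (inherits(features, "fused_features")) features$features
  else as.matrix(features)
}

#' Train the sigmoid MLP predictor
#'
#' @param features a [fuse()] result or plain numeric matrix (one row per
#'   patient).
#' @param labels binary outcome.
#' @param config an [mlp_config()].
#' @return object of class `mlp_predictor`.
#' @export
train_mlp <- function(features, labels, config = mlp_config()) {
  X <- fused_matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) abort_domain("both classes required to train")
  mu <- rep(0, ncol(X)); sdv <- rep(1, ncol(X))
  if (config$standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu, `-`), 2, sdv, `/`)
  }
  p <- ncol(X); hdim <- config$hidden
  params <- if (hdim > 0L) {
    with_stream(config$seed, "mlp-init", list(
      W1 = matrix(rnorm(hdim * p, sd = sqrt(1 / p)), hdim, p),
      b1 = rep(0, hdim),
      w2 = rnorm(hdim, sd = sqrt(1 / hdim)),
      b2 = 0
    ))
  } else {
    with_stream(config$seed, "mlp-init",
                list(w2 = rnorm(p, sd = sqrt(1 / p)), b2 = 0))
  }
  opt <- adam_init(params)

  use_val <- config$val_fraction > 0 && all(table(y) >= 2 / config$val_fraction)
  if (use_val) {
    sp <- stratified_patient_split(y, config$val_fraction,
                                   seed = stream_seed(config$seed, "mlp-val"))
    tr <- sp$train; va <- sp$test
  } else {
    tr <- seq_along(y); va <- integer(0)
  }

  fwd <- function(pp, xm) {
    if (is.null(pp$W1)) {
      return(list(H = xm, s = sigmoid(as.numeric(xm %*% pp$w2) + pp$b2)))
    }
    Z1 <- sweep(xm %*% t(pp$W1), 2, pp$b1, `+`)
    Hh <- sigmoid(Z1)
    s <- sigmoid(as.numeric(Hh %*% pp$w2) + pp$b2)
    list(H = Hh, s = s)
  }
  best <- list(loss = Inf, params = params)
  wait <- 0L
  log <- NULL
  set.seed(stream_seed(config$seed, "mlp-loop"))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr)
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      i <- i + config$batch_size
      xb <- X[batch, , drop = FALSE]
      yb <- y[batch]
      f <- fwd(params, xb)
      dz2 <- (f$s - yb) / length(batch)
      gw2 <- as.numeric(crossprod(f$H, dz2))
      gb2 <- sum(dz2)
      g <- if (is.null(params$W1)) {
        list(w2 = gw2, b2 = gb2)
      } else {
        dH <- outer(dz2, params$w2)
        dZ1 <- dH * f$H * (1 - f$H)
        list(W1 = crossprod(dZ1, xb), b1 = colSums(dZ1),
             w2 = gw2, b2 = gb2)
      }
      st <- adam_step(params, g, opt, config$lr, config$weight_decay)
      params <- st$params
      opt <- st$state
    }
    mon_idx <- if (use_val) va else tr
    f <- fwd(params, X[mon_idx, , drop = FALSE])
    mon <- mean(bce_loss(f$s, y[mon_idx]))
    log <- rbind(log, data.frame(epoch = epoch, monitor_loss = mon))
    if (mon < best$loss - 1e-8) {
      best <- list(loss = mon, params = params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params, center = mu, scale = sdv,
                 input_width = p, threshold = config$threshold,
                 config = config, log = log), class = "mlp_predictor")
}

#' Predict probabilities and classes from a trained MLP
#'
#' @param object an `mlp_predictor`.
#' @param features matrix or [fuse()] result with matching width.
#' @param ... unused.
#' @return data.frame with `probability` (in (0,1)) and `class`
#'   (1 iff probability >= threshold).
#' @export
predict.mlp_predictor <- function(object, features, ...) {
  X <- fused_matrix(features)
  if (ncol(X) != object$input_width) {
    abort_domain(sprintf("feature width %d does not match the input layer (%d)",
                         ncol(X), object$input_width))
  }
  X <- sweep(sweep(X, 2, object$center, `-`), 2, object$scale, `/`)
  pp <- object$params
  s <- if (is.null(pp$W1)) {
    sigmoid(as.numeric(X %*% pp$w2) + pp$b2)
  } else {
    Hh <- sigmoid(sweep(X %*% t(pp$W1), 2, pp$b1, `+`))
    sigmoid(as.numeric(Hh %*% pp$w2) + pp$b2)
  }
  data.frame(probability = s,
             class = as.integer(s >= object$threshold))
}
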