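# Volume normalization and the compact 3D convolutional instance-level
# feature extractor. The extractor is headless: it maps a 1-channel volume
# to a feature map whose depth positions become MIL instances; a shared
# linear projection turns each depth position into a d-dimensional
# instance vector. Forward and backward passes are written out explicitly
# (im2col/col2im convolutions, average pooling, ReLU) so the stage-1
# trainer can backpropagate bag-level losses through the whole stack.

#' Min-max normalization of a volume
#'
#' Linearly maps intensities to `[0, 1]` via `(x - min) / (max - min)`; the
#' minimum maps to 0 and the maximum to 1. An opt-in flag rescales to
#' `[-1, 1]` via `x -> 2x - 1`.
#'
#' @param volume 3D array with non-constant values.
#' @param symmetric rescale the result to `[-1, 1]`.
#' @return normalized array, flagged with `attr(, "normalized") = TRUE`.
#' @export
minmax_normalize <- function(volume, symmetric = FALSE) {
  stopifnot(length(dim(volume)) == 3L, all(is.finite(volume)))
  lo <- min(volume)
  hi <- max(volume)
  if (hi == lo) abort_domain("degenerate volume: max equals min")
  out <- (volume - lo) / (hi - lo)
  if (symmetric) out <- 2 * out - 1
  attr(out, "normalized") <- TRUE
  out
}

is_normalized <- function(volume) isTRUE(attr(volume, "normalized"))

#' Backbone configuration
#'
#' A stack of conv blocks (3x3x3 kernels, zero padding 1, ReLU, average
#' pooling) followed by a per-depth-position linear projection to the
#' instance feature dimension `d`. The default is a deliberately small
#' three-block stack suited to desk-scale volumes; wider stacks are plain
#' configuration.
#'
#' @param widths per-block output channel counts.
#' @param spatial_pool per-block spatial pooling factors (height and width).
#' @param depth_pool per-block depth pooling factors.
#' @param d instance feature dimension.
#' @param pool pooling type between blocks: `"max"` (C3D-style, default)
#'   or `"avg"`.
#' @param kernel_depth per-block depth extent of the conv kernels (1 or 3).
#'   The default uses full 3x3x3 kernels in the first block (cross-slice
#'   context) and 3x3x1 afterwards, keeping each instance's depth receptive
#'   field close to its own slice interval so attention stays attributable
#'   to slices.
#' @param input_channels must be 1 (single-channel volumes).
#' @param classifier_head must be FALSE: the extractor carries no classifier.
#' @param seed parameter-initialization seed.
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(widths = c(8L, 16L, 32L),
                            spatial_pool = rep(2L, length(widths)),
                            depth_pool = c(2L, 2L, 1L)[seq_along(widths)],
                            d = 32L,
                            pool = c("max", "avg"),
                            kernel_depth = c(3L, rep(1L, length(widths) - 1L)),
                            input_channels = 1L,
                            classifier_head = FALSE,
                            seed = 1L) {
  pool <- match.arg(pool)
  if (length(kernel_depth) != length(widths) ||
      !all(kernel_depth %in% c(1L, 3L))) {
    abort_domain("`kernel_depth` must give 1 or 3 per block")
  }
  if (input_channels != 1L) abort_domain("input channels must be 1")
  if (isTRUE(classifier_head)) {
    abort_domain("the backbone is a headless feature extractor; ",
                 "classifier layers are not part of its contract")
  }
  if (length(spatial_pool) != length(widths) ||
      length(depth_pool) != length(widths)) {
    abort_domain("pooling factors must match the number of blocks")
  }
  d <- check_count(d, "d")
  structure(list(widths = as.integer(widths),
                 spatial_pool = as.integer(spatial_pool),
                 depth_pool = as.integer(depth_pool),
                 d = d, pool = pool, kernel_depth = as.integer(kernel_depth),
                 input_channels = 1L, seed = as.integer(seed)),
            class = "backbone_config")
}

#' Closed-form output shape of the backbone
#'
#' @param config a [backbone_config()].
#' @param input_shape (H, W, S) of the input volume.
#' @return list with `map` (h, w, s, channels) of the final feature map and
#'   `k` (instance count under per-depth-position granularity).
#' @export
backbone_shape <- function(config, input_shape) {
  h <- input_shape[1]; w <- input_shape[2]; s <- input_shape[3]
  for (b in seq_along(config$widths)) {
    sp <- config$spatial_pool[b]; dp <- config$depth_pool[b]
    if (h %% sp != 0 || w %% sp != 0 || s %% dp != 0) {
      abort_domain(sprintf(
        "block %d pooling (%dx%dx%d) does not divide the %dx%dx%d map",
        b, sp, sp, dp, h, w, s))
    }
    h <- h %/% sp; w <- w %/% sp; s <- s %/% dp
    if (h < 1 || w < 1 || s < 1) {
      abort_domain("downsampling collapses a dimension to zero")
    }
  }
  list(map = c(h, w, s, config$widths[length(config$widths)]), k = s)
}

#' Build a backbone (initialize parameters)
#'
#' He-initialized conv kernels and zero biases, deterministic given the
#' config seed. The per-depth-position projection is initialized on first
#' use (its width depends on the input volume's spatial size) from its own
#' seed stream, so results do not depend on call order.
#'
#' @param config a [backbone_config()].
#' @return object of class `mil_backbone`.
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  params <- with_stream(config$seed, "backbone-init", {
    cin <- 1L
    blocks <- lapply(seq_along(config$widths), function(b) {
      cout <- config$widths[b]
      fan_in <- 9L * config$kernel_depth[b] * cin
      K <- matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
      blk <- list(K = K, b = rep(0, cout))
      cin <<- cout
      blk
    })
    list(blocks = blocks, proj = NULL)
  })
  structure(list(config = config, params = params), class = "mil_backbone")
}

init_projection <- function(backbone, flat_len) {
  cfg <- backbone$config
  with_stream(cfg$seed, "proj-init", {
    list(W = matrix(rnorm(cfg$d * flat_len, sd = sqrt(1 / flat_len)),
                    cfg$d, flat_len),
         b = rep(0, cfg$d))
  })
}

# pooling by factors f = c(fh, fw, fs) over an (H, W, S, C) array;
# max pooling (the C3D-style default) keeps the argmax slab for the
# backward routing, average pooling spreads gradients uniformly
pool_fwd <- function(x, f, type = "max") {
  d <- dim(x)
  if (all(f == 1L)) {
    return(list(y = x, arg = NULL))
  }
  slabs <- expand.grid(a = seq_len(f[1]), b = seq_len(f[2]),
                       cc = seq_len(f[3]))
  if (type == "avg") {
    acc <- 0
    for (i in seq_len(nrow(slabs))) {
      acc <- acc + x[seq(slabs$a[i], d[1], f[1]), seq(slabs$b[i], d[2], f[2]),
                     seq(slabs$cc[i], d[3], f[3]), , drop = FALSE]
    }
    return(list(y = acc / prod(f), arg = NULL))
  }
  y <- NULL
  arg <- NULL
  for (i in seq_len(nrow(slabs))) {
    sl <- x[seq(slabs$a[i], d[1], f[1]), seq(slabs$b[i], d[2], f[2]),
            seq(slabs$cc[i], d[3], f[3]), , drop = FALSE]
    if (is.null(y)) {
      y <- sl
      arg <- array(1L, dim(sl))
    } else {
      upd <- sl > y
      y[upd] <- sl[upd]
      arg[upd] <- i
    }
  }
  list(y = y, arg = arg)
}

pool_bwd <- function(g, f, in_dim, type = "max", arg = NULL) {
  if (all(f == 1L)) return(g)
  out <- array(0, in_dim)
  slabs <- expand.grid(a = seq_len(f[1]), b = seq_len(f[2]),
                       cc = seq_len(f[3]))
  if (type == "avg") {
    gs <- g / prod(f)
    for (i in seq_len(nrow(slabs))) {
      out[seq(slabs$a[i], in_dim[1], f[1]), seq(slabs$b[i], in_dim[2], f[2]),
          seq(slabs$cc[i], in_dim[3], f[3]), ] <- gs
    }
    return(out)
  }
  for (i in seq_len(nrow(slabs))) {
    out[seq(slabs$a[i], in_dim[1], f[1]), seq(slabs$b[i], in_dim[2], f[2]),
        seq(slabs$cc[i], in_dim[3], f[3]), ] <- g * (arg == i)
  }
  out
}

# Forward pass through the conv stack; keep_cache retains everything the
# backward pass needs.
conv_stack_forward <- function(backbone, x, keep_cache = FALSE) {
  cfg <- backbone$config
  d3 <- dim(x)
  cur <- array(x, dim = c(d3, 1L))
  cache <- if (keep_cache) list(blocks = vector("list", length(cfg$widths)))
  for (b in seq_along(cfg$widths)) {
    dm <- dim(cur)
    P <- im2col3(as.numeric(cur), dm[1], dm[2], dm[3], dm[4],
                 cfg$kernel_depth[b])
    A <- P %*% backbone$params$blocks[[b]]$K
    A <- sweep(A, 2, backbone$params$blocks[[b]]$b, `+`)
    mask <- A > 0
    A[!mask] <- 0
    pre_pool <- array(A, dim = c(dm[1:3], ncol(A)))
    f <- c(cfg$spatial_pool[b], cfg$spatial_pool[b], cfg$depth_pool[b])
    if (any(dm[1:3] %% f != 0)) {
      abort_domain("pooling factors must divide the feature-map dimensions")
    }
    pl <- pool_fwd(pre_pool, f, type = cfg$pool)
    if (keep_cache) {
      cache$blocks[[b]] <- list(P = P, mask = mask, in_dim = dm,
                                pre_pool_dim = dim(pre_pool), f = f,
                                arg = pl$arg)
    }
    cur <- pl$y
  }
  list(map = cur, cache = cache)
}

conv_stack_backward <- function(backbone, dmap, cache) {
  cfg <- backbone$config
  grads <- vector("list", length(cfg$widths))
  g <- dmap
  for (b in rev(seq_along(cfg$widths))) {
    cb <- cache$blocks[[b]]
    g <- pool_bwd(g, cb$f, cb$pre_pool_dim, type = cfg$pool, arg = cb$arg)
    dA <- matrix(g, nrow = prod(cb$pre_pool_dim[1:3]))
    dA[!cb$mask] <- 0
    grads[[b]] <- list(K = crossprod(cb$P, dA), b = colSums(dA))
    dP <- dA %*% t(backbone$params$blocks[[b]]$K)
    g <- col2im3(dP, cb$in_dim[1], cb$in_dim[2], cb$in_dim[3], cb$in_dim[4],
                 cfg$kernel_depth[b])
  }
  list(blocks = grads)
}

flatten_positions <- function(map) {
  dm <- dim(map)
  # one row per depth position; (h, w, channel) flattened column-major
  t(apply(matrix(seq_len(dm[3])), 1, function(t_) as.numeric(map[, , t_, ])))
}

#' Extract instance features from a normalized volume
#'
#' Under `per_depth_position` granularity (the default) each depth position
#' of the final feature map is one instance, so `k` equals the feature-map
#' depth and each instance's provenance is the interval of input slices it
#' covers. Under `per_slice_window` the volume is cut into consecutive
#' depth windows; each window is passed through the stack (depth pooling
#' clamped to the window's remaining depth), averaged over its depth
#' positions, and projected, so `k` equals the number of windows.
#'
#' @param volume normalized 3D array (see [minmax_normalize()]).
#' @param extractor a [build_backbone()] object.
#' @param granularity instance granularity.
#' @param window window width (slices) for `per_slice_window`.
#' @param bypass_normalization skip the normalization guard.
#' @return object of class `instance_features`: `features` (k x d matrix),
#'   `k`, `provenance` (list of slice intervals).
#' @export
extract_instances <- function(volume, extractor,
                              granularity = c("per_depth_position",
                                              "per_slice_window"),
                              window = 1L,
                              bypass_normalization = FALSE) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(extractor, "mil_backbone"))
  if (!bypass_normalization && !is_normalized(volume)) {
    abort_domain("volume is not normalized; run minmax_normalize() first ",
                 "(or set bypass_normalization = TRUE)")
  }
  cfg <- extractor$config
  S <- dim(volume)[3]
  if (granularity == "per_depth_position") {
    fwd <- conv_stack_forward(extractor, volume)
    map <- fwd$map
    flat <- flatten_positions(map)
    if (is.null(extractor$params$proj)) {
      extractor$params$proj <- init_projection(extractor, ncol(flat))
    }
    H <- flat %*% t(extractor$params$proj$W)
    H <- sweep(H, 2, extractor$params$proj$b, `+`)
    f_total <- prod(cfg$depth_pool)
    prov <- lapply(seq_len(nrow(H)), function(t_) {
      c(from = (t_ - 1L) * f_total + 1L, to = t_ * f_total)
    })
  } else {
    window <- check_count(window, "window")
    if (S %% window != 0) abort_domain("window must divide the volume depth")
    starts <- seq(1L, S, by = window)
    # clamp depth pooling to what each window can support
    wcfg <- cfg
    sdepth <- window
    for (b in seq_along(wcfg$depth_pool)) {
      wcfg$depth_pool[b] <- min(wcfg$depth_pool[b], sdepth)
      if (sdepth %% wcfg$depth_pool[b] != 0) {
        abort_domain("depth pooling incompatible with the window width")
      }
      sdepth <- sdepth %/% wcfg$depth_pool[b]
    }
    wext <- extractor
    wext$config <- wcfg
    rows <- NULL
    for (s0 in starts) {
      sub <- volume[, , s0:(s0 + window - 1L), drop = FALSE]
      fwd <- conv_stack_forward(wext, sub)
      map <- fwd$map
      dm <- dim(map)
      avg <- apply(map, c(1, 2, 4), mean)  # average over depth positions
      flat <- matrix(as.numeric(avg), nrow = 1)
      if (is.null(extractor$params$proj)) {
        extractor$params$proj <- init_projection(extractor, ncol(flat))
      }
      rows <- rbind(rows, as.numeric(extractor$params$proj$W %*% t(flat)) +
                      extractor$params$proj$b)
    }
    H <- rows
    prov <- lapply(starts, function(s0) c(from = s0, to = s0 + window - 1L))
  }
  structure(list(features = H, k = nrow(H), provenance = prov,
                 granularity = granularity),
            class = "instance_features")
}
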