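#' Backbone configuration
#'
#' The feature extractor is a ShuffleNetV2-style network whose batch
#' normalization layers are all replaced by batch channel normalization and
#' whose units embed BCN-BiFormer attention blocks: a 3x3 stride-2 stem
#' convolution and 3x3 stride-2 max pool, four stages of modified units,
#' then a 1x1 convolution to `embed_dim`, global average pooling, dropout
#' and flattening to a one-dimensional feature vector.
#'
#' @param stage_channels channel widths of the four stages (all even;
#'   defaults follow the ShuffleNetV2 1x scaling).
#' @param units_per_stage number of basic units per stage (stages 2-4 are
#'   additionally entered through a downsampling unit).
#' @param embed_dim width of the 1x1 head convolution, i.e. the feature
#'   vector length.
#' @param dropout_rate dropout rate applied after global average pooling
#'   (training mode only).
#' @param input_size input image side in pixels; must be divisible by 32 so
#'   the stage-4 map is a whole number of region grids.
#' @param bra a [bra_config()] shared by every attention block.
#' @return a list of class `backbone_config`.
#' @export
backbone_config <- function(stage_channels = c(24, 116, 232, 464),
                            units_per_stage = c(1, 1, 1, 1),
                            embed_dim = 1024,
                            dropout_rate = 0.4,
                            input_size = 224,
                            bra = bra_config()) {
  stage_channels <- as.integer(stage_channels)
  units_per_stage <- as.integer(units_per_stage)
  stopifnot(length(stage_channels) == 4L, length(units_per_stage) == 4L)
  if (any(stage_channels %% 2L != 0L)) {
    stop("all stage channel counts must be even (channel split)",
         call. = FALSE)
  }
  if (input_size %% 32 != 0) {
    stop("input_size must be divisible by 32", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  if (any(units_per_stage < 1L)) {
    stop("units_per_stage must all be >= 1", call. = FALSE)
  }
  structure(list(stage_channels = stage_channels,
                 units_per_stage = units_per_stage,
                 embed_dim = as.integer(embed_dim),
                 dropout_rate = dropout_rate,
                 input_size = as.integer(input_size),
                 bra = bra),
            class = "backbone_config")
}

#' Spatial map sizes implied by a backbone configuration
#'
#' Two stride-2 stem operations then three stride-2 stage transitions: an
#' input of side `input_size` yields stage maps of side `input_size / 4`,
#' `/ 8`, `/ 16` and `/ 32`.
#'
#' @param config a [backbone_config()].
#' @return integer vector of the four stage map sides.
#' @export
feature_map_sizes <- function(config) {
  as.integer(config$input_size / c(4L, 8L, 16L, 32L))
}

## --- channel plumbing ------------------------------------------------------

#' Split a feature map into two channel halves
#'
#' @param x rank-4 feature map with an even channel count.
#' @return list of two maps with `C/2` channels each; concatenating them
#'   with [channel_concat()] restores `x` exactly.
#' @export
channel_split <- function(x) {
  d <- check_nchw(x)
  if (d[2] %% 2L != 0L) {
    stop(sprintf("channel_split: odd channel count %d", d[2]), call. = FALSE)
  }
  half <- d[2] %/% 2L
  list(x[, seq_len(half), , , drop = FALSE],
       x[, half + seq_len(half), , , drop = FALSE])
}

#' @rdname channel_split
#' @param a,b rank-4 maps with matching batch and spatial dimensions.
#' @export
channel_concat <- function(a, b) {
  da <- check_nchw(a); db <- check_nchw(b)
  if (!all(da[c(1, 3, 4)] == db[c(1, 3, 4)])) {
    stop("channel_concat: batch/spatial dimensions differ", call. = FALSE)
  }
  out <- array(0, c(da[1], da[2] + db[2], da[3], da[4]))
  out[, seq_len(da[2]), , ] <- a
  out[, da[2] + seq_len(db[2]), , ] <- b
  out
}

# permutation vector: channel at position (g, j) of a groups x (C/groups)
# grid moves to (j, g)
shuffle_perm <- function(channels, groups) {
  if (channels %% groups != 0L) {
    stop(sprintf("channel_shuffle: %d channels not divisible by %d groups",
                 channels, groups), call. = FALSE)
  }
  # channels laid out group-major (g, j); transposing the grid reads them
  # j-major: position (j, g) picks old channel (g-1)*(C/groups) + j
  as.vector(t(matrix(seq_len(channels), ncol = groups)))
}

#' Channel shuffle
#'
#' The fixed ShuffleNet permutation: reshape the channel axis to a
#' `groups x (C/groups)` grid, transpose, and flatten, interleaving the
#' groups so information mixes across branches.
#'
#' @param x rank-4 feature map.
#' @param groups number of groups; must divide the channel count.
#' @return feature map with permuted channels; shuffling with `groups = g`
#'   then `groups = C/g` is the identity.
#' @export
channel_shuffle <- function(x, groups) {
  d <- check_nchw(x)
  perm <- shuffle_perm(d[2], as.integer(groups))
  x[, perm, , , drop = FALSE]
}

## --- ShuffleNetV2-style units ----------------------------------------------

# transform branch shared by both unit types:
# 1x1 conv -> BCN+ReLU -> 3x3 dwconv (stride s) -> BCN -> 1x1 conv -> BCN+ReLU
new_transform_branch <- function(in_ch, out_ch, stride) {
  list(
    c1 = new_conv2d(in_ch, out_ch, k = 1L),
    n1 = new_bcn(out_ch),
    dw = new_dwconv2d(out_ch, k = 3L, stride = stride, pad = 1L),
    n2 = new_bcn(out_ch),
    c2 = new_conv2d(out_ch, out_ch, k = 1L),
    n3 = new_bcn(out_ch)
  )
}

transform_forward <- function(ch, pre, x, training) {
  f <- list()
  f$c1 <- nn_forward(ch[[paste0(pre, "c1")]], x, training)
  f$n1 <- nn_forward(ch[[paste0(pre, "n1")]], f$c1$out, training)
  r1 <- f$n1$out * (f$n1$out > 0); m1 <- f$n1$out > 0
  f$dw <- nn_forward(ch[[paste0(pre, "dw")]], r1, training)
  f$n2 <- nn_forward(ch[[paste0(pre, "n2")]], f$dw$out, training)
  f$c2 <- nn_forward(ch[[paste0(pre, "c2")]], f$n2$out, training)
  f$n3 <- nn_forward(ch[[paste0(pre, "n3")]], f$c2$out, training)
  out <- f$n3$out * (f$n3$out > 0); m3 <- f$n3$out > 0
  list(out = out, cache = list(f = f, m1 = m1, m3 = m3))
}

transform_backward <- function(ch, pre, cache, dout) {
  f <- cache$f
  g <- list()
  d <- dout * cache$m3
  b <- nn_backward(ch[[paste0(pre, "n3")]], f$n3$cache, d)
  g[[paste0(pre, "n3")]] <- b$grads
  b <- nn_backward(ch[[paste0(pre, "c2")]], f$c2$cache, b$dx)
  g[[paste0(pre, "c2")]] <- b$grads
  b <- nn_backward(ch[[paste0(pre, "n2")]], f$n2$cache, b$dx)
  g[[paste0(pre, "n2")]] <- b$grads
  b <- nn_backward(ch[[paste0(pre, "dw")]], f$dw$cache, b$dx)
  g[[paste0(pre, "dw")]] <- b$grads
  d <- b$dx * cache$m1
  b <- nn_backward(ch[[paste0(pre, "n1")]], f$n1$cache, d)
  g[[paste0(pre, "n1")]] <- b$grads
  b <- nn_backward(ch[[paste0(pre, "c1")]], f$c1$cache, b$dx)
  g[[paste0(pre, "c1")]] <- b$grads
  list(dx = b$dx, grads = g)
}

# basic unit: channel split; identity half untouched; transform half runs
# the conv stack, a patch-merging 1x1 projection and a BiFormer block;
# concat + channel shuffle (groups = 2)
new_basic_unit <- function(channels, bra_cfg, stage_index) {
  half <- channels %/% 2L
  ch <- new_transform_branch(half, half, stride = 1L)
  ch$pm <- new_conv2d(half, half, k = 1L)
  ch$bif <- new_biformer(half, bra_cfg$n_heads, bra_cfg$S,
                         topk = bra_cfg$topk_per_stage[stage_index],
                         e = bra_cfg$e)
  new_module("basic_unit", children = ch, channels = as.integer(channels))
}

#' @export
nn_forward.basic_unit <- function(mod, x, training = FALSE, ...) {
  halves <- channel_split(x)
  ch <- mod$children
  tb <- transform_forward(ch, "", halves[[2]], training)
  f_pm <- nn_forward(ch$pm, tb$out, training)
  f_bif <- nn_forward(ch$bif, f_pm$out, training)
  y <- channel_shuffle(channel_concat(halves[[1]], f_bif$out), 2L)
  list(out = y, cache = list(tb = tb$cache, pm = f_pm$cache,
                             bif = f_bif$cache, dims = dim(x)))
}

#' @export
nn_backward.basic_unit <- function(mod, cache, dout) {
  C <- cache$dims[2]
  half <- C %/% 2L
  inv <- order(shuffle_perm(C, 2L))
  dcat <- dout[, inv, , , drop = FALSE]
  d1 <- dcat[, seq_len(half), , , drop = FALSE]
  d2 <- dcat[, half + seq_len(half), , , drop = FALSE]
  ch <- mod$children
  b_bif <- nn_backward(ch$bif, cache$bif, d2)
  b_pm <- nn_backward(ch$pm, cache$pm, b_bif$dx)
  b_tb <- transform_backward(ch, "", cache$tb, b_pm$dx)
  dx <- channel_concat(d1, b_tb$dx)
  grads <- b_tb$grads
  grads$pm <- b_pm$grads
  grads$bif <- b_bif$grads
  list(dx = dx, grads = list(params = list(), children = grads))
}

# downsampling unit: two stride-2 branches. Left: 3x3 dwconv s2 -> BCN ->
# 1x1 conv -> BCN+ReLU. Right: the transform stack with stride-2 dwconv,
# then patch-merge + BiFormer + BCN. Concat doubles channels; shuffle mixes.
new_downsample_unit <- function(in_ch, out_ch, bra_cfg, stage_index) {
  half <- out_ch %/% 2L
  ch <- list(
    ldw = new_dwconv2d(in_ch, k = 3L, stride = 2L, pad = 1L),
    ln1 = new_bcn(in_ch),
    lc = new_conv2d(in_ch, half, k = 1L),
    ln2 = new_bcn(half)
  )
  rt <- new_transform_branch(in_ch, half, stride = 2L)
  names(rt) <- paste0("r", names(rt))
  ch <- c(ch, rt)
  ch$rpm <- new_conv2d(half, half, k = 1L)
  ch$rbif <- new_biformer(half, bra_cfg$n_heads, bra_cfg$S,
                          topk = bra_cfg$topk_per_stage[stage_index],
                          e = bra_cfg$e)
  ch$rn4 <- new_bcn(half)
  new_module("downsample_unit", children = ch,
             in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

#' @export
nn_forward.downsample_unit <- function(mod, x, training = FALSE, ...) {
  d <- check_nchw(x)
  if (d[3] %% 2L != 0L || d[4] %% 2L != 0L) {
    stop(sprintf("downsample_unit: odd spatial dims (%d, %d)", d[3], d[4]),
         call. = FALSE)
  }
  ch <- mod$children
  # left branch
  f_ldw <- nn_forward(ch$ldw, x, training)
  f_ln1 <- nn_forward(ch$ln1, f_ldw$out, training)
  f_lc <- nn_forward(ch$lc, f_ln1$out, training)
  f_ln2 <- nn_forward(ch$ln2, f_lc$out, training)
  left <- f_ln2$out * (f_ln2$out > 0); lm <- f_ln2$out > 0
  # right branch
  tb <- transform_forward(ch, "r", x, training)
  f_rpm <- nn_forward(ch$rpm, tb$out, training)
  f_rbif <- nn_forward(ch$rbif, f_rpm$out, training)
  f_rn4 <- nn_forward(ch$rn4, f_rbif$out, training)
  y <- channel_shuffle(channel_concat(left, f_rn4$out), 2L)
  list(out = y,
       cache = list(ldw = f_ldw$cache, ln1 = f_ln1$cache, lc = f_lc$cache,
                    ln2 = f_ln2$cache, lm = lm, tb = tb$cache,
                    rpm = f_rpm$cache, rbif = f_rbif$cache,
                    rn4 = f_rn4$cache))
}

#' @export
nn_backward.downsample_unit <- function(mod, cache, dout) {
  out_ch <- mod$out_ch
  half <- out_ch %/% 2L
  inv <- order(shuffle_perm(out_ch, 2L))
  dcat <- dout[, inv, , , drop = FALSE]
  dl <- dcat[, seq_len(half), , , drop = FALSE]
  dr <- dcat[, half + seq_len(half), , , drop = FALSE]
  ch <- mod$children
  g <- list()
  # left
  b <- nn_backward(ch$ln2, cache$ln2, dl * cache$lm)
  g$ln2 <- b$grads
  b <- nn_backward(ch$lc, cache$lc, b$dx)
  g$lc <- b$grads
  b <- nn_backward(ch$ln1, cache$ln1, b$dx)
  g$ln1 <- b$grads
  b <- nn_backward(ch$ldw, cache$ldw, b$dx)
  g$ldw <- b$grads
  dx <- b$dx
  # right
  b <- nn_backward(ch$rn4, cache$rn4, dr)
  g$rn4 <- b$grads
  b <- nn_backward(ch$rbif, cache$rbif, b$dx)
  g$rbif <- b$grads
  b <- nn_backward(ch$rpm, cache$rpm, b$dx)
  g$rpm <- b$grads
  b_tb <- transform_backward(ch, "r", cache$tb, b$dx)
  g <- c(g, b_tb$grads)
  dx <- dx + b_tb$dx
  list(dx = dx, grads = list(params = list(), children = g))
}

## --- unit-level functional wrappers ---------------------------------------

#' Run a single modified ShuffleNetV2 unit
#'
#' `basic_unit()` preserves shape: the input is channel-split, one half
#' passes untouched, the other runs 1x1 conv / BCN+ReLU / 3x3 depthwise /
#' BCN / 1x1 conv / BCN+ReLU, a patch-merging 1x1 projection and a
#' BCN-BiFormer block; the halves are concatenated and channel-shuffled.
#' `downsample_unit()` halves the spatial dimensions and changes the channel
#' count via two parallel stride-2 branches, the right one ending in a
#' BiFormer block and BCN.
#'
#' @param x rank-4 feature map.
#' @param params a unit built by `basic_unit_layer()` /
#'   `downsample_unit_layer()`; built fresh from `seed` when omitted.
#' @param bra a [bra_config()].
#' @param stage_index backbone stage (selects the attention top-k).
#' @param seed integer seed used when `params` is omitted.
#' @param training logical.
#' @return list with `out` and the unit used (`params`).
#' @export
basic_unit <- function(x, params = NULL, bra = bra_config(), stage_index = 1,
                       seed = 1, training = TRUE) {
  d <- check_nchw(x)
  if (is.null(params)) params <- basic_unit_layer(d[2], bra, stage_index, seed)
  res <- nn_forward(params, x, training = training)
  list(out = res$out, params = params)
}

#' @rdname basic_unit
#' @param channels input channel count (`basic_unit_layer`).
#' @export
basic_unit_layer <- function(channels, bra = bra_config(), stage_index = 1,
                             seed = 1) {
  withr::with_seed(seed, new_basic_unit(as.integer(channels), bra,
                                        as.integer(stage_index)))
}

#' @rdname basic_unit
#' @param out_ch output channel count of the downsampling unit.
#' @export
downsample_unit <- function(x, out_ch, params = NULL, bra = bra_config(),
                            stage_index = 2, seed = 1, training = TRUE) {
  d <- check_nchw(x)
  if (is.null(params)) {
    params <- downsample_unit_layer(d[2], out_ch, bra, stage_index, seed)
  }
  res <- nn_forward(params, x, training = training)
  list(out = res$out, params = params)
}

#' @rdname basic_unit
#' @param in_ch input channel count (`downsample_unit_layer`).
#' @export
downsample_unit_layer <- function(in_ch, out_ch, bra = bra_config(),
                                  stage_index = 2, seed = 1) {
  withr::with_seed(seed, new_downsample_unit(as.integer(in_ch),
                                             as.integer(out_ch), bra,
                                             as.integer(stage_index)))
}

## --- full backbone ---------------------------------------------------------

#' Build the feature-extraction backbone
#'
#' Assembles stem, four stages of modified units and the embedding head
#' described in [backbone_config()]. All parameters (including every BCN's
#' iota/gamma/beta, drawn from N(0,1)) are initialized from `seed`.
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for all parameter draws.
#' @return a model object usable with [extract_features()] and
#'   [pretrain()].
#' @export
build_backbone <- function(config = backbone_config(), seed = 1) {
  stopifnot(inherits(config, "backbone_config"))
  sizes <- feature_map_sizes(config)
  S <- config$bra$S
  bad <- sizes %% S != 0L
  if (any(bad)) {
    stop(sprintf(
      "stage map sides (%s) must be divisible by S=%d; offending: %s",
      paste(sizes, collapse = ", "), S,
      paste(sizes[bad], collapse = ", ")), call. = FALSE)
  }
  withr::with_seed(seed, {
    sc <- config$stage_channels
    ch <- list(
      stem_conv = new_conv2d(3L, sc[1], k = 3L, stride = 2L, pad = 1L),
      stem_bcn = new_bcn(sc[1]),
      stem_pool = new_maxpool(k = 3L, stride = 2L, pad = 1L)
    )
    plan <- character(0)
    for (s in 1:4) {
      if (s > 1) {
        nm <- sprintf("s%dd", s)
        ch[[nm]] <- new_downsample_unit(sc[s - 1], sc[s], config$bra, s)
        plan <- c(plan, nm)
      }
      for (u in seq_len(config$units_per_stage[s])) {
        nm <- sprintf("s%du%d", s, u)
        ch[[nm]] <- new_basic_unit(sc[s], config$bra, s)
        plan <- c(plan, nm)
      }
      plan <- c(plan, sprintf("<stage%d>", s))
    }
    ch$head_conv <- new_conv2d(sc[4], config$embed_dim, k = 1L)
    ch$gap <- new_gap()
    ch$drop <- new_dropout(config$dropout_rate)
    new_module("bbsnet_model", children = ch, plan = plan, config = config)
  })
}

# full forward; returns features (N x embed_dim), per-step caches and the
# recorded stage map dimensions
model_forward <- function(model, x, training = FALSE) {
  d <- check_nchw(x)
  if (d[3] != model$config$input_size || d[4] != model$config$input_size) {
    stop(sprintf("expected %dx%d input, got %dx%d",
                 model$config$input_size, model$config$input_size,
                 d[3], d[4]), call. = FALSE)
  }
  ch <- model$children
  caches <- list()
  f <- nn_forward(ch$stem_conv, x, training); caches$stem_conv <- f$cache
  f2 <- nn_forward(ch$stem_bcn, f$out, training); caches$stem_bcn <- f2$cache
  relu_mask <- f2$out > 0
  y <- f2$out * relu_mask
  caches$stem_relu_mask <- relu_mask
  f3 <- nn_forward(ch$stem_pool, y, training); caches$stem_pool <- f3$cache
  y <- f3$out

  stage_dims <- list()
  unit_caches <- list()
  for (step in model$plan) {
    if (grepl("^<stage", step)) {
      stage_dims[[length(stage_dims) + 1L]] <- dim(y)
      next
    }
    f <- nn_forward(ch[[step]], y, training)
    unit_caches[[step]] <- f$cache
    y <- f$out
  }
  caches$units <- unit_caches

  f <- nn_forward(ch$head_conv, y, training); caches$head_conv <- f$cache
  f3 <- nn_forward(ch$gap, f$out, training); caches$gap <- f3$cache
  f4 <- nn_forward(ch$drop, f3$out, training); caches$drop <- f4$cache
  list(features = f4$out, caches = caches, stage_dims = stage_dims)
}

model_backward <- function(model, caches, dfeat) {
  ch <- model$children
  g <- list()
  b <- nn_backward(ch$drop, caches$drop, dfeat)
  g$drop <- b$grads
  b <- nn_backward(ch$gap, caches$gap, b$dx)
  g$gap <- b$grads
  b <- nn_backward(ch$head_conv, caches$head_conv, b$dx)
  g$head_conv <- b$grads
  d <- b$dx
  for (step in rev(model$plan)) {
    if (grepl("^<stage", step)) next
    b <- nn_backward(ch[[step]], caches$units[[step]], d)
    g[[step]] <- b$grads
    d <- b$dx
  }
  b <- nn_backward(ch$stem_pool, caches$stem_pool, d)
  g$stem_pool <- b$grads
  d <- b$dx * caches$stem_relu_mask
  b <- nn_backward(ch$stem_bcn, caches$stem_bcn, d)
  g$stem_bcn <- b$grads
  b <- nn_backward(ch$stem_conv, caches$stem_conv, b$dx)
  g$stem_conv <- b$grads
  list(dx = b$dx, grads = list(params = list(), children = g))
}

#' Extract feature vectors from a batch of images
#'
#' Runs the full backbone. In eval mode (`training = FALSE`) dropout is
#' inactive and the BCN layers use their running statistics, so the output
#' is deterministic; eval mode before any training-mode forward raises an
#' error because the running statistics are uninitialized.
#'
#' @param images an `image_batch` (see [generate_images()]) or a rank-4
#'   array `(batch, 3, H, W)`.
#' @param model a model from [build_backbone()] or [pretrain()].
#' @param training logical; training mode enables dropout and batch
#'   statistics.
#' @param batch_size forward chunk size (memory control).
#' @return numeric matrix, one row of length `embed_dim` per image.
#' @export
extract_features <- function(images, model, training = FALSE,
                             batch_size = 16L) {
  x <- if (inherits(images, "image_batch")) images$pixels else images
  d <- check_nchw(x)
  n <- d[1]
  out <- matrix(0, n, model$config$embed_dim)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    out[sel, ] <- model_forward(model, x[sel, , , , drop = FALSE],
                                training = training)$features
  }
  out
}
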