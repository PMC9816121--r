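#' U-Net architecture configuration
#'
#' Describes the modified 2D U-Net: an encoder-decoder with skip connections
#' in which every level is a double 3x3 convolution block ('same' padding)
#' with group normalization, ReLU and dropout, 2x2 max-pooling on the way
#' down and 2x2 stride-2 transposed convolutions on the way up, closed by a
#' 1x1 convolution onto the two embedding fields. The network consumes five
#' adjacent axial slices on the channel axis and predicts the center slice.
#'
#' @param in_channels number of stacked input slices (5 for this method).
#' @param out_fields number of output embedding fields (2: endosteal,
#'   periosteal).
#' @param base_channels channels of the first encoder level; doubled at each
#'   deeper level.
#' @param depth number of down/upsampling levels.
#' @param groupnorm_groups groups used by group normalization;
#'   `base_channels` must be divisible by it.
#' @param dropout_p dropout probability inside the double-conv blocks.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(in_channels = 5L, out_fields = 2L,
                        base_channels = 32L, depth = 4L,
                        groupnorm_groups = 8L, dropout_p = 0.1) {
  if (depth < 1L) stop("depth must be >= 1")
  if (base_channels %% groupnorm_groups != 0L)
    stop("base_channels must be divisible by groupnorm_groups")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  structure(list(in_channels = as.integer(in_channels),
                 out_fields = as.integer(out_fields),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 groupnorm_groups = as.integer(groupnorm_groups),
                 dropout_p = dropout_p),
            class = "unet_config")
}

#' Build (initialize) an embedding U-Net
#'
#' Weights use He-normal initialization; group-norm scales start at one.
#'
#' @param cfg a [unet_config()].
#' @param seed integer seed for the weight initialization.
#' @return A list of class `embedding_unet` with `cfg` and `params`.
#' @export
build_unet <- function(cfg = unet_config(), seed = 0L) {
  stopifnot(inherits(cfg, "unet_config"))
  with_seed(seed, {
    params <- list()
    ch_in <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      ch_out <- cfg$base_channels * 2L^(i - 1L)
      params[[paste0("enc", i)]] <- double_conv_init(ch_in, ch_out, cfg)
      ch_in <- ch_out
    }
    ch_bot <- cfg$base_channels * 2L^cfg$depth
    params$bottleneck <- double_conv_init(ch_in, ch_bot, cfg)
    ch_prev <- ch_bot
    for (i in rev(seq_len(cfg$depth))) {
      ch_out <- cfg$base_channels * 2L^(i - 1L)
      params[[paste0("dec", i)]] <- c(
        list(up = upconv_init(ch_prev, ch_out)),
        double_conv_init(2L * ch_out, ch_out, cfg))
      ch_prev <- ch_out
    }
    params$final <- conv1x1_init(ch_prev, cfg$out_fields)
    structure(list(cfg = cfg, params = params), class = "embedding_unet")
  })
}

double_conv_init <- function(c_in, c_out, cfg) {
  list(conv1 = conv3x3_init(c_in, c_out),
       gn1 = gn_init(c_out),
       conv2 = conv3x3_init(c_out, c_out),
       gn2 = gn_init(c_out))
}

gn_groups_for <- function(cfg, channels) {
  min(cfg$groupnorm_groups, channels)
}

double_conv_fwd <- function(X, par, B, H, W, cfg, training) {
  g <- gn_groups_for(cfg, length(par$gn1$gamma))
  HW <- H * W
  c1 <- conv3x3_fwd(X, par$conv1, B, H, W)
  n1 <- gn_fwd(c1$out, par$gn1, B, HW, g)
  r1 <- relu_fwd(n1$out)
  d1 <- dropout_fwd(r1$out, cfg$dropout_p, training)
  c2 <- conv3x3_fwd(d1$out, par$conv2, B, H, W)
  n2 <- gn_fwd(c2$out, par$gn2, B, HW, g)
  r2 <- relu_fwd(n2$out)
  d2 <- dropout_fwd(r2$out, cfg$dropout_p, training)
  list(out = d2$out,
       cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                    d1 = d1$cache, c2 = c2$cache, n2 = n2$cache,
                    r2 = r2$cache, d2 = d2$cache, groups = g))
}

double_conv_bwd <- function(dY, par, cache, B, H, W) {
  HW <- H * W
  g <- cache$groups
  dY <- dropout_bwd(dY, cache$d2)
  dY <- relu_bwd(dY, cache$r2)
  gb2 <- gn_bwd(dY, par$gn2, cache$n2, B, HW, g)
  cb2 <- conv3x3_bwd(gb2$dX, par$conv2, cache$c2, B, H, W)
  dY <- dropout_bwd(cb2$dX, cache$d1)
  dY <- relu_bwd(dY, cache$r1)
  gb1 <- gn_bwd(dY, par$gn1, cache$n1, B, HW, g)
  cb1 <- conv3x3_bwd(gb1$dX, par$conv1, cache$c1, B, H, W)
  list(dX = cb1$dX,
       grads = list(conv1 = list(W = cb1$dW, b = cb1$db),
                    gn1 = list(gamma = gb1$dgamma, beta = gb1$dbeta),
                    conv2 = list(W = cb2$dW, b = cb2$db),
                    gn2 = list(gamma = gb2$dgamma, beta = gb2$dbeta)))
}

# forward over a batch matrix; returns output and (optionally) the cache
# needed for unet_backward_mat
unet_forward_mat <- function(model, X, B, H, W, training = FALSE,
                             keep_cache = training) {
  cfg <- model$cfg
  if (H %% 2L^cfg$depth != 0L || W %% 2L^cfg$depth != 0L)
    stop("in-plane extents must be divisible by 2^depth")
  p <- model$params
  caches <- list()
  skips <- list()
  dims <- list()
  h <- H; w <- W
  cur <- X
  for (i in seq_len(cfg$depth)) {
    blk <- double_conv_fwd(cur, p[[paste0("enc", i)]], B, h, w, cfg, training)
    skips[[i]] <- blk$out
    dims[[i]] <- c(h, w)
    caches[[paste0("enc", i)]] <- blk$cache
    pool <- maxpool_fwd(blk$out, B, h, w)
    caches[[paste0("pool", i)]] <- pool$cache
    cur <- pool$out
    h <- h %/% 2L; w <- w %/% 2L
  }
  blk <- double_conv_fwd(cur, p$bottleneck, B, h, w, cfg, training)
  caches$bottleneck <- blk$cache
  cur <- blk$out
  for (i in rev(seq_len(cfg$depth))) {
    up <- upconv_fwd(cur, p[[paste0("dec", i)]]$up, B, h, w)
    caches[[paste0("up", i)]] <- up$cache
    h <- h * 2L; w <- w * 2L
    cat_in <- cbind(up$out, skips[[i]])
    blk <- double_conv_fwd(cat_in, p[[paste0("dec", i)]], B, h, w, cfg,
                           training)
    caches[[paste0("dec", i)]] <- blk$cache
    cur <- blk$out
  }
  fin <- conv1x1_fwd(cur, p$final)
  caches$final <- fin$cache
  list(out = fin$out,
       cache = if (keep_cache) list(caches = caches, dims = dims,
                                    B = B, H = H, W = W) else NULL)
}

# full backward pass; returns parameter gradients with the same nesting as
# model$params
unet_backward_mat <- function(model, cache, dOut) {
  cfg <- model$cfg
  p <- model$params
  caches <- cache$caches
  B <- cache$B
  grads <- list()
  fb <- conv1x1_bwd(dOut, p$final, caches$final)
  grads$final <- list(W = fb$dW, b = fb$db)
  dcur <- fb$dX
  h <- cache$H; w <- cache$W
  dskips <- list()
  for (i in seq_len(cfg$depth)) {
    hw <- cache$dims[[i]]
    blk <- double_conv_bwd(dcur, p[[paste0("dec", i)]],
                           caches[[paste0("dec", i)]], B, hw[1], hw[2])
    grads[[paste0("dec", i)]] <- blk$grads
    ch_up <- cfg$base_channels * 2L^(i - 1L)
    d_up <- blk$dX[, seq_len(ch_up), drop = FALSE]
    dskips[[i]] <- blk$dX[, ch_up + seq_len(ch_up), drop = FALSE]
    ub <- upconv_bwd(d_up, p[[paste0("dec", i)]]$up,
                     caches[[paste0("up", i)]], B, hw[1] %/% 2L,
                     hw[2] %/% 2L)
    grads[[paste0("dec", i)]]$up <- list(W = ub$dW, b = ub$db)
    dcur <- ub$dX
  }
  hb <- cache$dims[[cfg$depth]]
  hb <- c(hb[1] %/% 2L, hb[2] %/% 2L)
  blk <- double_conv_bwd(dcur, p$bottleneck, caches$bottleneck, B,
                         hb[1], hb[2])
  grads$bottleneck <- blk$grads
  dcur <- blk$dX
  for (i in rev(seq_len(cfg$depth))) {
    hw <- cache$dims[[i]]
    ch <- cfg$base_channels * 2L^(i - 1L)
    dpool <- maxpool_bwd(dcur, caches[[paste0("pool", i)]], B,
                         hw[1], hw[2], ch)
    dpool <- dpool + dskips[[i]]
    blk <- double_conv_bwd(dpool, p[[paste0("enc", i)]],
                           caches[[paste0("enc", i)]], B, hw[1], hw[2])
    grads[[paste0("enc", i)]] <- blk$grads
    dcur <- blk$dX
  }
  grads
}

#' Predict embedding fields for one slice stack
#'
#' Runs the network in evaluation mode (dropout off, fully deterministic).
#' Output field order is (endosteal, periosteal).
#'
#' @param model an [build_unet()] model.
#' @param stack a [slice_stack()] whose in-plane extents are divisible by
#'   `2^depth`.
#' @return An [embedding_fields()] pair with the center slice's shape.
#' @export
unet_forward <- function(model, stack) {
  stopifnot(inherits(model, "embedding_unet"), inherits(stack, "slice_stack"))
  d <- dim(stack$slices)
  H <- d[2]; W <- d[3]
  X <- t(matrix(stack$slices, nrow = d[1]))
  out <- unet_forward_mat(model, X, 1L, H, W, training = FALSE,
                          keep_cache = FALSE)$out
  embedding_fields(endo = matrix(out[, 1], H, W),
                   peri = matrix(out[, 2], H, W))
}

#' Number of trainable parameters of a model
#'
#' @param model an `embedding_unet`.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_params(model$params), length, integer(1)))
}

#' @export
print.embedding_unet <- function(x, ...) {
  cat(sprintf(paste0("<embedding_unet> depth %d, base %d channels, ",
                     "%d -> %d fields, %s parameters\n"),
              x$cfg$depth, x$cfg$base_channels, x$cfg$in_channels,
              x$cfg$out_fields, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# flatten/rebuild nested parameter lists (used by the optimizer)
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], full))
    else out[[full]] <- p[[nm]]
  }
  out
}

assign_flat <- function(p, flat) {
  for (nm in names(flat)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    p[[path]] <- flat[[nm]]
  }
  p
}

#' Save / load a trained model
#'
#' Checkpoints are stored with R's native RDS serialization (configuration
#' and weights together).
#'
#' @param model an `embedding_unet`.
#' @param path file path.
#' @return `load_unet` returns the model; `save_unet` invisibly returns
#'   `path`.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "embedding_unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "embedding_unet")) stop("not an embedding_unet file")
  model
}
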