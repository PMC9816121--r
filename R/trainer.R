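#' Training protocol configuration
#'
#' Defaults follow the published protocol: 25 epochs of AdamW under a
#' one-cycle schedule with a 10-epoch half-cycle and 5 convergence epochs,
#' learning rate between 1e-4 and 1e-3, momentum (beta1) between 0.85 and
#' 0.95, and a batch size of 4 slices. Remaining optimizer constants are the
#' optimizer's canonical defaults (beta2 = 0.999, eps = 1e-8, decoupled
#' weight decay 0.01).
#'
#' @param epochs_halfcycle epochs in one half of the learning-rate cycle.
#' @param epochs_converge extra annealing epochs after the cycle.
#' @param lr_min,lr_max learning-rate extremes of the cycle.
#' @param momentum_max,momentum_min first-moment (beta1) extremes; momentum
#'   moves opposite to the learning rate.
#' @param batch_size_slices slices per optimization step.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param final_lr_fraction the convergence epochs anneal the learning rate
#'   from `lr_min` down to `lr_min * final_lr_fraction`.
#' @param seed seed controlling shuffling, dropout and initialization use.
#' @return A list of class `training_config`; `total_epochs` is
#'   `2 * epochs_halfcycle + epochs_converge`.
#' @export
training_config <- function(epochs_halfcycle = 10L, epochs_converge = 5L,
                            lr_min = 1e-4, lr_max = 1e-3,
                            momentum_max = 0.95, momentum_min = 0.85,
                            batch_size_slices = 4L, weight_decay = 0.01,
                            final_lr_fraction = 1 / 25, seed = 1L) {
  stopifnot(lr_min < lr_max, lr_min > 0,
            momentum_min > 0, momentum_min < momentum_max,
            momentum_max < 1, batch_size_slices >= 1,
            epochs_halfcycle >= 1, epochs_converge >= 0)
  structure(list(epochs_halfcycle = as.integer(epochs_halfcycle),
                 epochs_converge = as.integer(epochs_converge),
                 total_epochs = 2L * as.integer(epochs_halfcycle) +
                   as.integer(epochs_converge),
                 lr_min = lr_min, lr_max = lr_max,
                 momentum_max = momentum_max, momentum_min = momentum_min,
                 batch_size_slices = as.integer(batch_size_slices),
                 weight_decay = weight_decay,
                 final_lr_fraction = final_lr_fraction,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' One-cycle learning-rate and momentum schedule
#'
#' Linear super-convergence policy: the learning rate rises from `lr_min` to
#' `lr_max` over the first half-cycle, falls back to `lr_min` over the
#' second, then anneals linearly toward `lr_min * final_lr_fraction` during
#' the convergence epochs. Momentum mirrors the cycle inversely
#' (max -> min -> max) and stays at its maximum while annealing.
#'
#' @param cfg a [training_config()].
#' @param iteration 0-based iteration index.
#' @param total_iterations total number of optimizer steps in the run.
#' @return List with `lr` and `momentum`.
#' @export
#' @examples
#' one_cycle_schedule(training_config(), 0, 1000)       # lr 1e-4, mom 0.95
#' one_cycle_schedule(training_config(), 400, 1000)     # lr 1e-3, mom 0.85
one_cycle_schedule <- function(cfg, iteration, total_iterations) {
  stopifnot(inherits(cfg, "training_config"))
  if (iteration < 0 || iteration >= total_iterations)
    stop("iteration out of range")
  pos <- iteration / total_iterations * cfg$total_epochs
  half <- cfg$epochs_halfcycle
  if (pos <= half) {
    u <- pos / half
    list(lr = cfg$lr_min + (cfg$lr_max - cfg$lr_min) * u,
         momentum = cfg$momentum_max -
           (cfg$momentum_max - cfg$momentum_min) * u)
  } else if (pos <= 2 * half) {
    u <- (pos - half) / half
    list(lr = cfg$lr_max - (cfg$lr_max - cfg$lr_min) * u,
         momentum = cfg$momentum_min +
           (cfg$momentum_max - cfg$momentum_min) * u)
  } else {
    u <- (pos - 2 * half) / cfg$epochs_converge
    lr_final <- cfg$lr_min * cfg$final_lr_fraction
    list(lr = cfg$lr_min - (cfg$lr_min - lr_final) * u,
         momentum = cfg$momentum_max)
  }
}

#' Shuffled batch plan for one epoch
#'
#' Images are shuffled, then within each image the axial slices are shuffled
#' and consumed sequentially in batches; every batch contains slices of a
#' single image. A trailing partial batch is kept (a 168-slice image at
#' batch size 4 splits exactly into 42 batches).
#'
#' @param dataset list of samples, each a list with elements `volume` (a
#'   [normalized_volume()]) and `seg` (a [segmentation_pair()]).
#' @param cfg a [training_config()].
#' @param epoch_seed seed for this epoch's shuffling.
#' @return List of batches; each batch is `list(sample = i, slices = idx)`.
#' @export
iterate_batches <- function(dataset, cfg = training_config(),
                            epoch_seed = 0L) {
  if (length(dataset) == 0L) stop("empty dataset")
  with_seed(epoch_seed, {
    batches <- list()
    for (i in sample(length(dataset))) {
      n <- dim(dataset[[i]]$volume$voxels)[1]
      if (n < 1L) stop("volume with no slices")
      sl <- sample(n)
      starts <- seq(1L, n, by = cfg$batch_size_slices)
      for (s in starts) {
        idx <- sl[s:min(s + cfg$batch_size_slices - 1L, n)]
        batches[[length(batches) + 1L]] <- list(sample = i, slices = idx)
      }
    }
    batches
  })
}

#' Total optimizer iterations of a training run
#'
#' @param cfg a [training_config()].
#' @param n_images number of training images.
#' @param slices_per_image axial slices per image (168 for standard scans).
#' @return `total_epochs * n_images * ceiling(slices / batch)`; the published
#'   protocol (25 epochs, 1822 images, 42 batches) gives ~1.9 million.
#' @export
training_iteration_count <- function(cfg, n_images, slices_per_image = 168L) {
  cfg$total_epochs * n_images *
    ceiling(slices_per_image / cfg$batch_size_slices)
}

# assemble the (B*HW) x 5 input matrix and reference slices for one batch
batch_inputs <- function(sample, slices) {
  nv <- sample$volume
  d <- dim(nv$voxels)
  H <- d[2]; W <- d[3]
  B <- length(slices)
  X <- matrix(0, B * H * W, 5L)
  refs <- vector("list", B)
  for (b in seq_len(B)) {
    st <- make_slice_stack(nv, slices[b])
    X[(b - 1L) * H * W + seq_len(H * W), ] <- t(matrix(st$slices, nrow = 5L))
    refs[[b]] <- segmentation_slice(sample$seg, slices[b])
  }
  list(X = X, refs = refs, B = B, H = H, W = W)
}

# loss + gradient over one forward output; returns mean breakdown and dOut
batch_loss <- function(out, refs, B, H, W, w, want_grad = TRUE) {
  HW <- H * W
  terms <- NULL
  dOut <- if (want_grad) matrix(0, B * HW, 2L) else NULL
  for (b in seq_len(B)) {
    rows <- (b - 1L) * HW + seq_len(HW)
    fields <- embedding_fields(matrix(out[rows, 1], H, W),
                               matrix(out[rows, 2], H, W))
    lb <- total_loss(fields, refs[[b]], w)
    terms <- if (is.null(terms)) unlist(lb) else terms + unlist(lb)
    if (want_grad) {
      gr <- total_loss_gradient(fields, refs[[b]], w)
      dOut[rows, 1] <- as.vector(gr$endo) / B
      dOut[rows, 2] <- as.vector(gr$peri) / B
    }
  }
  list(breakdown = terms / B, dOut = dOut)
}

adamw_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adamw_step <- function(flat, grads, state, lr, beta1, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    flat[[nm]] <- flat[[nm]] - lr * (step + weight_decay * flat[[nm]])
  }
  list(flat = flat, state = state)
}

#' Train an embedding U-Net
#'
#' Runs the full protocol: per-epoch image and slice shuffling, single-image
#' batches, the combined embedding loss, AdamW with the one-cycle schedule,
#' and an inferential pass over the validation set at the end of every
#' epoch. Fully deterministic for a fixed `cfg$seed` on a single device.
#'
#' @param model an [build_unet()] model.
#' @param train_set,val_set lists of samples (`list(volume =, seg =)`); see
#'   [iterate_batches()].
#' @param cfg a [training_config()].
#' @param w a [loss_weights()] object.
#' @param verbose print per-epoch losses.
#' @return List of class `unet_fit` with elements `model` and `history`
#'   (per-iteration `lr`/`momentum`, per-epoch `train` and `validation`
#'   mean loss breakdowns).
#' @export
fit_unet <- function(model, train_set, val_set = list(),
                     cfg = training_config(), w = loss_weights(),
                     verbose = FALSE) {
  stopifnot(inherits(model, "embedding_unet"),
            inherits(cfg, "training_config"))
  if (length(train_set) == 0L) stop("empty training set")
  batches_per_epoch <- sum(vapply(train_set, function(s)
    ceiling(dim(s$volume$voxels)[1] / cfg$batch_size_slices), numeric(1)))
  total_iters <- cfg$total_epochs * batches_per_epoch
  flat <- flatten_params(model$params)
  state <- adamw_init(flat)
  hist <- list(lr = numeric(total_iters), momentum = numeric(total_iters),
               train = list(), validation = list())
  it <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$total_epochs)) {
      batches <- iterate_batches(train_set, cfg,
                                 epoch_seed = cfg$seed * 1000L + epoch)
      epoch_terms <- NULL
      for (bt in batches) {
        sched <- one_cycle_schedule(cfg, it, total_iters)
        inp <- batch_inputs(train_set[[bt$sample]], bt$slices)
        fwd <- unet_forward_mat(model, inp$X, inp$B, inp$H, inp$W,
                                training = TRUE)
        bl <- batch_loss(fwd$out, inp$refs, inp$B, inp$H, inp$W, w)
        if (!is.finite(bl$breakdown[["L_total"]]))
          stop(sprintf("non-finite loss at epoch %d iteration %d (%s)",
                       epoch, it, paste(round(bl$breakdown, 4),
                                        collapse = ", ")))
        grads <- flatten_params(unet_backward_mat(model, fwd$cache, bl$dOut))
        upd <- adamw_step(flat, grads, state, sched$lr, sched$momentum,
                          weight_decay = cfg$weight_decay)
        flat <- upd$flat
        state <- upd$state
        model$params <- assign_flat(model$params, flat)
        it <- it + 1L
        hist$lr[it] <- sched$lr
        hist$momentum[it] <- sched$momentum
        epoch_terms <- if (is.null(epoch_terms)) bl$breakdown
                       else epoch_terms + bl$breakdown
      }
      hist$train[[epoch]] <- epoch_terms / length(batches)
      if (length(val_set) > 0L)
        hist$validation[[epoch]] <- validate_unet(model, val_set, w)
      if (verbose) {
        v <- if (length(val_set) > 0L)
          sprintf(", val %.4f", hist$validation[[epoch]][["L_total"]])
        else ""
        message(sprintf("epoch %d/%d: train L_total %.4f%s", epoch,
                        cfg$total_epochs,
                        hist$train[[epoch]][["L_total"]], v))
      }
    }
  })
  structure(list(model = model, history = hist), class = "unet_fit")
}

#' Mean validation loss of a model
#'
#' One inferential (evaluation-mode) pass over a dataset; no parameter
#' updates.
#'
#' @param model an `embedding_unet`.
#' @param val_set list of samples (`list(volume =, seg =)`).
#' @param w a [loss_weights()] object.
#' @return Named numeric vector: mean of each loss term over all slices.
#' @export
validate_unet <- function(model, val_set, w = loss_weights()) {
  stopifnot(length(val_set) > 0L)
  terms <- NULL
  n_slices <- 0L
  for (s in val_set) {
    n <- dim(s$volume$voxels)[1]
    starts <- seq(1L, n, by = 4L)
    for (st in starts) {
      idx <- st:min(st + 3L, n)
      inp <- batch_inputs(s, idx)
      fwd <- unet_forward_mat(model, inp$X, inp$B, inp$H, inp$W,
                              training = FALSE)
      bl <- batch_loss(fwd$out, inp$refs, inp$B, inp$H, inp$W, w,
                       want_grad = FALSE)
      terms <- if (is.null(terms)) bl$breakdown * inp$B
               else terms + bl$breakdown * inp$B
      n_slices <- n_slices + inp$B
    }
  }
  terms / n_slices
}
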