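#' Training configuration
#'
#' The training recipe: binary cross-entropy loss and the Adam optimizer
#' with batch size 2, learning rate 1e-4 and 30 epochs by default.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Images per optimizer step (>= 1).
#' @param epochs Number of passes over the training set (>= 1).
#' @param seed Integer seed controlling weight init and epoch shuffling.
#' @param device Compute-target name; only `"cpu"` is available.
#' @param threshold Probability cutoff for binarizing predictions, in (0, 1).
#' @return A `museg_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 2L, epochs = 30L,
                         seed = 1L, device = "cpu", threshold = 0.5) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be > 0")
  }
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 device = device, threshold = threshold),
            class = "museg_train_config")
}

#' Binary cross-entropy loss
#'
#' Mean over all pixels of \eqn{-[t \log p + (1-t) \log(1-p)]}, with
#' predictions clamped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param pred Probability array.
#' @param target Binary array of the same shape.
#' @param eps Clamping epsilon (default 1e-7).
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target)) {
    stop("bce_loss: prediction shape (", paste(dim(pred), collapse = "x"),
         ") does not match target shape (", paste(dim(target), collapse = "x"), ")")
  }
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

## --- Adam -------------------------------------------------------------------

adam_new <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  layers <- collect_layers(model)
  layers <- layers[vapply(layers, function(l) length(l$ptensors) > 0, logical(1))]
  state <- lapply(layers, function(l) {
    s <- list()
    for (p in l$ptensors) s[[p]] <- list(m = zero_like(get(p, envir = l)),
                                         v = zero_like(get(p, envir = l)))
    s
  })
  env <- new.env(parent = emptyenv())
  env$layers <- layers; env$state <- state
  env$lr <- lr; env$beta1 <- beta1; env$beta2 <- beta2; env$eps <- eps
  env$t <- 0L
  env
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    for (p in l$ptensors) {
      g <- get(paste0("g", p), envir = l)
      st <- opt$state[[i]][[p]]
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
      opt$state[[i]][[p]] <- st
      upd <- opt$lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
      assign(p, get(p, envir = l) - upd, envir = l)
      assign(paste0("g", p), zero_like(g), envir = l)
    }
  }
  invisible(opt)
}

## --- data plumbing ----------------------------------------------------------

# Stack a list of samples into (H, W, C, N) image and (H, W, 1, N) mask arrays.
batch_arrays <- function(samples) {
  n <- length(samples)
  x1 <- to_model_input(samples[[1]]$image)  # (3, H, W)
  H <- dim(x1)[2]; W <- dim(x1)[3]
  xb <- array(0, c(H, W, 3L, n))
  tb <- array(0, c(H, W, 1L, n))
  for (i in seq_len(n)) {
    xi <- to_model_input(samples[[i]]$image)
    xb[, , , i] <- aperm(xi, c(2, 3, 1))
    tb[, , 1L, i] <- samples[[i]]$mask
  }
  list(x = xb, t = tb)
}

## --- training loop ----------------------------------------------------------

#' Train a segmentation model
#'
#' Runs seeded mini-batch training with BCE loss and Adam. After each epoch
#' the validation set (when given) is evaluated with pooled pixel counts,
#' and both the best-validation-Dice and the last state are checkpointed
#' when `checkpoint_dir` is set.
#'
#' @param model A `museg_model`.
#' @param train_set,val_set Lists of samples (each with `$image` 8-bit
#'   HxWx3 and `$mask` binary HxW); `val_set` may be `NULL`.
#' @param cfg A `museg_train_config`.
#' @param checkpoint_dir Directory for `best.rds` / `last.rds`, or `NULL`.
#' @param early_stop_dice Stop once validation Dice (percent) reaches this
#'   value, or `NULL` to always run all epochs.
#' @param verbose Print one line per epoch.
#' @return List with `history` (data frame: epoch, loss, steps, and
#'   validation precision/IoU/Dice when a validation set was given),
#'   `model`, `best_dice`, and `checkpoints` (paths or NULL).
#' @export
train_model <- function(model, train_set, val_set = NULL, cfg = train_config(),
                        checkpoint_dir = NULL, early_stop_dice = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "museg_model"), inherits(cfg, "museg_train_config"))
  if (length(train_set) == 0) stop("training set is empty")
  if (!is.null(val_set) && length(val_set) == 0) stop("validation set is empty")
  set.seed(cfg$seed)
  opt <- adam_new(model, cfg$learning_rate)
  n <- length(train_set)
  history <- NULL
  best_dice <- -Inf
  paths <- NULL
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(best = file.path(checkpoint_dir, "best.rds"),
                  last = file.path(checkpoint_dir, "last.rds"))
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    steps <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      ba <- batch_arrays(train_set[idx])
      p <- model_forward(model, ba$x, training = TRUE)
      loss <- bce_loss(p, ba$t)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ",
             steps + 1L, "; aborting")
      }
      dz <- (p - ba$t) / length(p)
      model_backward(model, dz)
      adam_step(opt)
      losses <- c(losses, loss)
      steps <- steps + 1L
    }
    row <- data.frame(epoch = epoch, loss = mean(losses), steps = steps)
    if (!is.null(val_set)) {
      ev <- evaluate(model, val_set, cfg$threshold)
      row$val_precision <- ev$precision
      row$val_iou <- ev$iou
      row$val_dice <- ev$dice
      if (ev$dice > best_dice) {
        best_dice <- ev$dice
        if (!is.null(paths)) save_checkpoint(model, paths$best, seed = cfg$seed)
      }
    }
    history <- rbind(history, row)
    if (verbose) {
      msg <- sprintf("epoch %d/%d loss %.5f", epoch, cfg$epochs, row$loss)
      if (!is.null(val_set)) {
        msg <- paste0(msg, sprintf(" | val Pre %.2f IoU %.2f Dice %.2f",
                                   row$val_precision, row$val_iou, row$val_dice))
      }
      message(msg)
    }
    if (!is.null(early_stop_dice) && !is.null(val_set) &&
        best_dice >= early_stop_dice) break
  }
  if (!is.null(paths)) save_checkpoint(model, paths$last, seed = cfg$seed)
  list(history = history, model = model, best_dice = best_dice,
       checkpoints = paths)
}

#' Predict a binary mask for one image
#'
#' @param object A `museg_model`.
#' @param image 8-bit HxWx3 image array (H, W divisible by 32).
#' @param threshold Probability cutoff in (0, 1).
#' @param ... Unused.
#' @return Binary HxW integer matrix.
#' @export
predict.museg_model <- function(object, image, threshold = 0.5, ...) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  x <- to_model_input(image)
  xb <- array(aperm(x, c(2, 3, 1)), c(dim(x)[2], dim(x)[3], 3L, 1L))
  p <- model_forward(object, xb, training = FALSE)
  mask <- (p[, , 1L, 1L] >= threshold) * 1L
  matrix(as.integer(mask), nrow = dim(p)[1])
}

## --- checkpointing ----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint records the full model state (weights and batch-norm
#' running statistics), the model configuration, and the training seed;
#' `load_checkpoint(save_checkpoint(m, p))` reproduces predictions exactly.
#'
#' @param model A `museg_model`.
#' @param path File path (.rds).
#' @param seed Seed to record alongside the state.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt `museg_model` with attributes `seed`.
#' @export
save_checkpoint <- function(model, path, seed = NA_integer_) {
  stopifnot(inherits(model, "museg_model"))
  obj <- list(state = collect_state(model), config = model$config,
              seed = seed, package_version = as.character(utils::packageVersion("museg")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint error: file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("checkpoint error: cannot read ", path, " (", conditionMessage(e), ")")
  })
  if (!is.list(obj) || is.null(obj$state) || is.null(obj$config)) {
    stop("checkpoint error: ", path, " does not contain a model state")
  }
  model <- seg_model(obj$config, seed = 1L)
  set_state(model, obj$state)
  attr(model, "seed") <- obj$seed
  model
}
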