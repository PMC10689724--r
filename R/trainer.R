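# End-to-end training loop: Adam, step-decayed learning rate, per-epoch
# training-set shuffling, batch-wise validation with a single shuffle, early
# stopping, and the dual checkpoint policy (every k-th epoch plus the
# best-so-far network).  Fine-tuning mode reuses the same loop with a low
# fixed-purpose configuration (lr 1e-5, save every 5th epoch, 20 epochs).

#' Training configuration
#'
#' Defaults follow the reference protocol: initial learning rate 3e-4
#' multiplied by 0.90 after every 300 batches, training/validation batch
#' sizes 15/50, early-stopping patience 200 epochs, a checkpoint every 3rd
#' epoch.  `fine_tune = TRUE` switches to the domain-adaptation protocol:
#' learning rate 1e-5, a checkpoint every 5th epoch, a 20-epoch budget.
#'
#' @param initial_lr,lr_decay_factor,lr_decay_every_n_batches Step-decay
#'   schedule parameters.
#' @param batch_size_train,batch_size_val Batch sizes.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param checkpoint_stride Save a checkpoint every this many epochs.
#' @param max_epochs Epoch budget.
#' @param seed Seed controlling shuffling (and augmentation draws).
#' @param augment `NULL` to disable augmentation, or an [augment_spec()].
#' @param fine_tune Logical; apply the fine-tuning overrides.
#' @export
train_config <- function(initial_lr = 3e-4, lr_decay_factor = 0.90,
                         lr_decay_every_n_batches = 300L,
                         batch_size_train = 15L, batch_size_val = 50L,
                         early_stop_patience = 200L,
                         checkpoint_stride = 3L, max_epochs = 1000L,
                         seed = 1L, augment = NULL, fine_tune = FALSE) {
  cfg <- list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
              lr_decay_every_n_batches = as.integer(lr_decay_every_n_batches),
              batch_size_train = as.integer(batch_size_train),
              batch_size_val = as.integer(batch_size_val),
              early_stop_patience = as.integer(early_stop_patience),
              checkpoint_stride = as.integer(checkpoint_stride),
              max_epochs = as.integer(max_epochs),
              seed = as.integer(seed), augment = augment,
              fine_tune = isTRUE(fine_tune))
  if (cfg$fine_tune) {
    cfg$initial_lr <- 1e-5
    cfg$checkpoint_stride <- 5L
    cfg$max_epochs <- 20L
  }
  stopifnot(cfg$initial_lr > 0, cfg$lr_decay_factor > 0,
            cfg$lr_decay_every_n_batches >= 1, cfg$batch_size_train >= 1,
            cfg$batch_size_val >= 1, cfg$early_stop_patience >= 1,
            cfg$checkpoint_stride >= 1, cfg$max_epochs >= 1)
  structure(cfg, class = "train_config")
}

#' Learning rate at a given batch index
#'
#' `lr = initial_lr * decay^floor(batch_index / decay_every)`; batch 0 is
#' the first batch.
#'
#' @param batch_index Non-negative integer (0-based global batch counter).
#' @param cfg A [train_config()].
#' @export
lr_at <- function(batch_index, cfg) {
  stopifnot(all(batch_index >= 0))
  cfg$initial_lr *
    cfg$lr_decay_factor^floor(batch_index / cfg$lr_decay_every_n_batches)
}

# assemble a named list of (256,256,1,N) input arrays + (256,256,1,N) target
records_to_batch <- function(records, input_names, single_input = FALSE) {
  n <- length(records)
  sz <- dim(records[[1]]$images[[1]])
  tgt <- array(0, c(sz, 1, n))
  if (single_input) {
    mods <- names(records[[1]]$images)
    x <- array(0, c(sz, length(mods), n))
    for (i in seq_len(n)) {
      for (j in seq_along(mods)) x[, , j, i] <- records[[i]]$images[[mods[j]]]
      if (!is.null(records[[i]]$label)) tgt[, , 1, i] <- records[[i]]$label
    }
    inputs <- list(stack = x)
  } else {
    inputs <- lapply(input_names, function(m) {
      x <- array(0, c(sz, 1, n))
      for (i in seq_len(n)) x[, , 1, i] <- records[[i]]$images[[m]]
      x
    })
    names(inputs) <- input_names
    for (i in seq_len(n))
      if (!is.null(records[[i]]$label)) tgt[, , 1, i] <- records[[i]]$label
  }
  list(inputs = inputs, target = tgt)
}

batch_indices <- function(n, size) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' Train a segmentation model
#'
#' @param model An `msseg_model` from [build_model()].
#' @param train_records,val_records Lists of labelled `slice_record`s.
#' @param cfg A [train_config()].
#' @param loss A [loss_spec()].
#' @param checkpoint_dir Directory for epoch checkpoints (created if
#'   needed); `NULL` keeps checkpoints in memory flags only.
#' @param verbose Print one line per epoch.
#' @return A list with the trained `model` (best-epoch weights restored
#'   when checkpoints are on disk), the `history` (a `loss_history` whose
#'   rows carry epoch, train/validation loss, learning rate and checkpoint
#'   flag) and `checkpoint_dir`.
#' @export
train <- function(model, train_records, val_records, cfg = train_config(),
                  loss = loss_spec(), checkpoint_dir = NULL,
                  verbose = FALSE) {
  if (length(train_records) == 0 || length(val_records) == 0)
    stop("empty record sets")
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  input_names <- model_input_names(model)
  single <- model$config$variant == "single_input"
  opt <- adam_state(model$params)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  # validation set is shuffled once at the start of evaluation
  val_order <- sample(length(val_records))
  val_batches <- batch_indices(length(val_records), cfg$batch_size_val)

  n_epochs <- 0L
  batch_counter <- 0L
  best_loss <- Inf
  best_epoch <- 0L
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(train_records))       # reshuffle every epoch
    tl <- 0; nb <- 0
    for (bi in batch_indices(length(ord), cfg$batch_size_train)) {
      recs <- train_records[ord[bi]]
      if (!is.null(cfg$augment))
        recs <- lapply(recs, augment, spec = cfg$augment)
      b <- records_to_batch(recs, input_names, single)
      lr <- lr_at(batch_counter, cfg)
      fwd <- predict_batch(model, b$inputs, training = TRUE)
      lg <- seg_loss(fwd$out, b$target, loss, gradient = TRUE)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch, "; aborting")
      grads <- backward_graph(model, fwd, lg$grad)
      adam_step(model$params, grads, opt, lr)
      tl <- tl + lg$loss; nb <- nb + 1
      batch_counter <- batch_counter + 1L
    }
    train_loss <- tl / nb

    vl <- 0; nv <- 0
    for (bi in val_batches) {
      b <- records_to_batch(val_records[val_order[bi]], input_names, single)
      p <- predict_batch(model, b$inputs, training = FALSE)
      vl <- vl + seg_loss(p, b$target, loss); nv <- nv + 1
    }
    val_loss <- vl / nv
    if (!is.finite(val_loss))
      stop("non-finite validation loss at epoch ", epoch, "; aborting")

    saved <- FALSE
    if (epoch %% cfg$checkpoint_stride == 0) {
      if (!is.null(checkpoint_dir))
        save_weights(model, file.path(checkpoint_dir,
                                      sprintf("epoch_%04d.rds", epoch)),
                     epoch = epoch)
      saved <- TRUE
    }
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_epoch <- epoch
      if (!is.null(checkpoint_dir))
        save_weights(model, file.path(checkpoint_dir, "best.rds"),
                     epoch = epoch)
    }
    hist[[epoch]] <- c(train_loss = train_loss, val_loss = val_loss,
                       lr = lr_at(batch_counter - 1L, cfg), saved = saved)
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", epoch, train_loss,
                      val_loss))
    n_epochs <- epoch
    if (epoch - best_epoch >= cfg$early_stop_patience) break
  }

  hm <- do.call(rbind, hist)
  cp <- hm[, "saved"] == 1
  cp[best_epoch] <- TRUE   # the best-so-far file survives at this epoch
  history <- as_loss_history(hm[, "val_loss"], checkpoint = cp,
                             train_loss = hm[, "train_loss"],
                             lr = hm[, "lr"])
  if (!is.null(checkpoint_dir)) {
    write_history_csv(history,
                      file.path(checkpoint_dir, "training_log.csv"))
    best_file <- file.path(checkpoint_dir, "best.rds")
    if (file.exists(best_file)) model <- load_weights(best_file, into = model)
  }
  list(model = model, history = history, checkpoint_dir = checkpoint_dir,
       best_epoch = best_epoch)
}

#' Fine-tune a pretrained model
#'
#' Domain-adaptation mode: continues training with a small fixed initial
#' learning rate (1e-5), checkpoints every 5th epoch and a 20-epoch budget.
#'
#' @param weights Path to saved weights, or an `msseg_model`.
#' @param train_records,val_records Labelled `slice_record`s from the new
#'   domain.
#' @param cfg A [train_config()]; its `fine_tune` flag is forced on.
#' @param ... Passed on to [train()].
#' @export
fine_tune <- function(weights, train_records, val_records,
                      cfg = train_config(fine_tune = TRUE), ...) {
  model <- if (inherits(weights, "msseg_model")) weights else
    load_weights(weights)
  if (!cfg$fine_tune) {
    cfg$fine_tune <- TRUE
    cfg$initial_lr <- 1e-5
    cfg$checkpoint_stride <- 5L
    cfg$max_epochs <- 20L
  }
  train(model, train_records, val_records, cfg, ...)
}

#' Write / read a training log
#'
#' CSV columns: epoch, train_loss, val_loss, lr, checkpoint.
#'
#' @param history A `loss_history`.
#' @param path CSV file path.
#' @export
write_history_csv <- function(history, path) {
  df <- as.data.frame(history)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path) {
  df <- utils::read.csv(path)
  as_loss_history(df$val_loss, checkpoint = df$checkpoint,
                  train_loss = df$train_loss, lr = df$lr)
}
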