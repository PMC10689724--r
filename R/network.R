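# Multi-branch 2D U-Net with per-modality encoders, multi-modal feature
# fusion (MMFF) and multi-scale feature upsampling (MSFU).
#
# Block internals were pinned by calibrating against the reference
# implementation's exact parameter counts (26,242,733 total / 26,213,223
# trainable / 29,510 non-trainable at n0 = 32 with three modalities); the
# resulting recipes are:
#
#   DS block i (filters f_i):  BN -> conv3x3(f_i)+ReLU -> BN ->
#                              conv3x3(f_i)+ReLU -> BN -> [skip] -> maxpool2x2
#   BTM block (16*n0):         BN -> 3 x [conv3x3+ReLU -> BN]
#   MMFF level i:              conv1x1(f_i)+ReLU per branch -> concat -> BN
#   MSFU level i:              upsample2x -> BN -> conv2x2(f_i)+ReLU ->
#                              conv3x3(f_i, no bias)+ReLU -> BN ->
#                              concat(MMFF) -> BN -> conv2x2(f_i)+ReLU ->
#                              conv3x3(f_i)+ReLU
#   head:                      conv1x1(n0)+ReLU -> conv1x1(1)+sigmoid
#
# The decoder's lowest-resolution input is the channel-wise concatenation of
# the three BTM outputs.

#' Network configuration
#'
#' Describes the segmentation architecture completely: the first-level filter
#' count `n0` (subsequent encoder levels use `n0 * 2^(i-1)`, the bottom block
#' `16 * n0`), the ordered modality list (one encoder branch each), the
#' variant, and the encoder depth.
#'
#' @param n0 Filter count of the first down-sampling block (default 32).
#' @param modalities Character vector naming the input branches, a subset of
#'   `c("FLAIR", "T1w", "T2w")` in any order.
#' @param variant One of `"full"` (MMFF + MSFU), `"no_mmff"` (skip fusion is
#'   a plain concatenation), `"no_msfu"` (upsampling path is a convolution
#'   followed by 2x upsampling and a concatenation), `"neither"` (both
#'   substitutions), `"single_input"` (a standard U-Net with one encoder that
#'   takes all modalities stacked as channels).
#' @param depth Number of down-sampling blocks per branch (default 4); one
#'   bottom block is always appended.
#' @param dropout Optional dropout rate in (0, 1) applied after every
#'   convolution block; `NULL` (default) disables dropout.
#' @return An object of class `net_config`.
#' @export
net_config <- function(n0 = 32L, modalities = c("FLAIR", "T1w", "T2w"),
                       variant = c("full", "no_mmff", "no_msfu", "neither",
                                   "single_input"),
                       depth = 4L, dropout = NULL) {
  variant <- match.arg(variant)
  stopifnot(n0 >= 1, depth >= 1, length(modalities) >= 1,
            length(modalities) <= 3, !anyDuplicated(modalities))
  if (!is.null(dropout)) stopifnot(dropout > 0, dropout < 1)
  structure(list(n0 = as.integer(n0), modalities = modalities,
                 variant = variant, depth = as.integer(depth),
                 dropout = dropout),
            class = "net_config")
}

#' @export
print.net_config <- function(x, ...) {
  cat(sprintf("<net_config> n0=%d variant=%s modalities=%s depth=%d\n",
              x$n0, x$variant, paste(x$modalities, collapse = "+"), x$depth))
  invisible(x)
}

filter_schedule <- function(cfg) {
  c(cfg$n0 * 2^(seq_len(cfg$depth) - 1L), cfg$n0 * 2^cfg$depth)
}

# one encoder branch; returns list(skips = node ids (pre-pool), bottom = id)
build_branch <- function(g, input_id, cfg) {
  f <- filter_schedule(cfg)
  depth <- cfg$depth
  skips <- integer(depth)
  cur <- input_id
  for (i in seq_len(depth)) {
    cur <- g_bn(g, cur)
    cur <- g_conv(g, cur, f[i], 3, act = "relu", bias = TRUE)
    cur <- g_bn(g, cur)
    cur <- g_conv(g, cur, f[i], 3, act = "relu", bias = TRUE)
    cur <- g_bn(g, cur)
    skips[i] <- cur
    cur <- g_pool(g, cur)
    if (!is.null(cfg$dropout)) cur <- g_dropout(g, cur, cfg$dropout)
  }
  fb <- f[depth + 1L]
  cur <- g_bn(g, cur)
  for (j in 1:3) {
    cur <- g_conv(g, cur, fb, 3, act = "relu", bias = TRUE)
    cur <- g_bn(g, cur)
  }
  list(skips = skips, bottom = cur)
}

# MMFF at one level: per-branch 1x1 conv, concat, BN.  With `fuse = FALSE`
# (ablation) the block degenerates to a plain concatenation.
build_mmff <- function(g, skip_ids, filters, fuse = TRUE) {
  if (length(skip_ids) == 1L && !fuse) return(skip_ids)
  if (fuse) {
    skip_ids <- vapply(skip_ids, function(s)
      g_conv(g, s, filters, 1, act = "relu", bias = TRUE), integer(1))
  }
  cur <- if (length(skip_ids) > 1L) g_concat(g, skip_ids) else skip_ids
  if (fuse) cur <- g_bn(g, cur)
  cur
}

# MSFU at one level: upsample the low-resolution stream, refine, merge with
# the fused high-resolution features, refine again.  With `fuse = FALSE`
# (ablation) the block is replaced by conv -> upsample -> concat.
build_msfu <- function(g, low_id, high_id, filters, fuse = TRUE) {
  if (fuse) {
    cur <- g_up(g, low_id)
    cur <- g_bn(g, cur)
    cur <- g_conv(g, cur, filters, 2, act = "relu", bias = TRUE)
    cur <- g_conv(g, cur, filters, 3, act = "relu", bias = FALSE)
    cur <- g_bn(g, cur)
    cur <- g_concat(g, c(cur, high_id))
    cur <- g_bn(g, cur)
    cur <- g_conv(g, cur, filters, 2, act = "relu", bias = TRUE)
    g_conv(g, cur, filters, 3, act = "relu", bias = TRUE)
  } else {
    cur <- g_conv(g, low_id, filters, 3, act = "relu", bias = TRUE)
    cur <- g_up(g, cur)
    g_concat(g, c(cur, high_id))
  }
}

#' Build a segmentation model
#'
#' Constructs the layer graph described by a [net_config()] and initializes
#' all weights (Glorot normal, seeded).  The returned model maps per-modality
#' `(H, W, 1, N)` arrays (or one stacked array for the `single_input`
#' variant) to an `(H, W, 1, N)` lesion-probability map; `H` and `W` must be
#' multiples of `2^depth`.
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `msseg_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  g <- build_model_skeleton(cfg)$graph
  ps <- init_params(g, seed)
  structure(list(config = cfg, graph = g, params = ps$params,
                 state = ps$state, seed = as.integer(seed)),
            class = "msseg_model")
}

#' Build an ablation or comparison variant
#'
#' Thin wrapper over [build_model()] for configurations whose `variant` is
#' not `"full"`; kept as a separate entry point to mirror the ablation study
#' (plain-concatenation skip fusion, convolution-plus-upsampling decoder,
#' both substitutions, and the single-input standard U-Net).
#'
#' @inheritParams build_model
#' @export
build_variant <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  if (cfg$variant == "full")
    stop("use build_model() for the full variant")
  build_model(cfg, seed = seed)
}

#' Run a model on a batch of slices
#'
#' @param model An `msseg_model`.
#' @param inputs Named list of `(H, W, 1, N)` arrays, one per modality (or
#'   `list(stack = ...)` with all modalities as channels for the
#'   `single_input` variant).
#' @param training Logical; `TRUE` uses batch statistics in the
#'   normalization layers and caches intermediates for a backward pass.
#' @return For `training = FALSE`, the `(H, W, 1, N)` probability array;
#'   otherwise a list with elements `out`, `vals` and `cache`.
#' @export
predict_batch <- function(model, inputs, training = FALSE) {
  expect <- model_input_names(model)
  miss <- setdiff(expect, names(inputs))
  if (length(miss))
    stop("missing model inputs: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(inputs), expect)
  if (model$config$variant == "single_input" && length(extra))
    stop("single_input variant takes one stacked input, not ",
         paste(names(inputs), collapse = ", "))
  fwd <- forward_graph(model, inputs, training = training)
  if (training) fwd else fwd$out
}

model_input_names <- function(model) {
  if (model$config$variant == "single_input") "stack" else
    model$config$modalities
}

#' Parameter counts of a model
#'
#' Counts trainable parameters (convolution weights and biases, batch-norm
#' scale and shift) and non-trainable parameters (the batch-norm moving mean
#' and variance).
#'
#' @param model An `msseg_model`, or a `net_config` (counted without
#'   allocating weights).
#' @return A list with `total_parameters`, `trainable_parameters`,
#'   `non_trainable_parameters` and `per_level_filters`.
#' @export
summarize <- function(model) {
  cfg <- if (inherits(model, "net_config")) model else model$config
  g <- if (inherits(model, "net_config")) build_graph_only(model) else
    model$graph
  trainable <- sum(vapply(g$param_shapes, prod, numeric(1)))
  non_trainable <- 0
  for (nd in g$nodes)
    if (nd$op == "bn") non_trainable <- non_trainable + 2 * nd$channels
  list(total_parameters = trainable + non_trainable,
       trainable_parameters = trainable,
       non_trainable_parameters = non_trainable,
       per_level_filters = filter_schedule(cfg))
}

# graph construction without weight allocation (for counting only)
build_graph_only <- function(cfg) {
  m <- build_model_skeleton(cfg)
  m$graph
}

build_model_skeleton <- function(cfg) {
  g <- new_graph()
  f <- filter_schedule(cfg)
  depth <- cfg$depth
  fuse_mmff <- cfg$variant %in% c("full", "no_msfu")
  fuse_msfu <- cfg$variant %in% c("full", "no_mmff")
  if (cfg$variant == "single_input") {
    inp <- g_input(g, "stack", length(cfg$modalities))
    br <- list(build_branch(g, inp, cfg))
  } else {
    br <- lapply(cfg$modalities, function(m)
      build_branch(g, g_input(g, m, 1L), cfg))
  }
  bottoms <- vapply(br, `[[`, integer(1), "bottom")
  low <- if (length(bottoms) > 1L) g_concat(g, bottoms) else bottoms
  for (i in rev(seq_len(depth))) {
    skips <- vapply(br, function(b) b$skips[i], integer(1))
    high <- build_mmff(g, skips, f[i],
                       fuse = fuse_mmff && cfg$variant != "single_input")
    low <- build_msfu(g, low, high, f[i], fuse = fuse_msfu)
  }
  cur <- g_conv(g, low, cfg$n0, 1, act = "relu", bias = TRUE)
  if (!is.null(cfg$dropout)) cur <- g_dropout(g, cur, cfg$dropout)
  out <- g_conv(g, cur, 1L, 1, act = "sigmoid", bias = TRUE)
  g$head_bias <- g$nodes[[out]]$b   # initialized to the background prior
  list(graph = g)
}

#' Save / load model weights
#'
#' Weights are stored in R's native serialization with a JSON manifest
#' (configuration, seed, epoch) next to them.
#'
#' @param model An `msseg_model`.
#' @param path File path for the weights (`.rds`).
#' @param epoch Optional epoch number recorded in the manifest.
#' @export
save_weights <- function(model, path, epoch = NA_integer_) {
  obj <- list(params = as.list(model$params), state = as.list(model$state),
              config = unclass(model$config), seed = model$seed)
  saveRDS(obj, path)
  manifest <- list(config = unclass(model$config), seed = model$seed,
                   epoch = epoch,
                   config_hash = config_hash(model$config))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_weights
#' @param into Optional existing model whose architecture must match; when
#'   supplied, weights are loaded into it (used for fine-tuning).
#' @export
load_weights <- function(path, into = NULL) {
  obj <- readRDS(path)
  cfg <- do.call(net_config, obj$config[c("n0", "modalities", "variant",
                                          "depth", "dropout")])
  model <- if (is.null(into)) build_model(cfg, seed = obj$seed) else into
  if (!identical(unclass(model$config), unclass(cfg)))
    stop("architecture mismatch between checkpoint and configuration")
  for (name in names(obj$params)) model$params[[name]] <- obj$params[[name]]
  for (name in names(obj$state)) model$state[[name]] <- obj$state[[name]]
  model
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  # small stable hash; avoids a digest dependency
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% 1e9
}

#' @export
print.msseg_model <- function(x, ...) {
  s <- summarize(x)
  cat(sprintf(
    "<msseg_model> %s n0=%d: %s total parameters (%s trainable, %s BN moving stats)\n",
    x$config$variant, x$config$n0,
    format(s$total_parameters, big.mark = ","),
    format(s$trainable_parameters, big.mark = ","),
    format(s$non_trainable_parameters, big.mark = ",")))
  invisible(x)
}
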