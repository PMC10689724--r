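# Compact reverse-mode engine for static 2D convolutional graphs.
#
# A graph is a list of nodes in topological order.  Feature maps are numeric
# arrays with dim (H, W, C, N).  Supported ops: input, conv (kernel 1/2/3,
# "same" padding, optional bias, relu/sigmoid/linear activation), bn (batch
# normalization over H, W and N per channel), pool (2x2 max), up (2x nearest
# upsampling), concat (channel-wise).  Parameters live in an environment so a
# model can be updated in place by the optimizer.

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$shapes <- list()    # channel count per node (spatial level tracked too)
  g$levels <- list()    # log2 downsampling level, for shape checking
  g$param_shapes <- list()
  g
}

add_node <- function(g, op, inputs = integer(0), ...) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- c(list(id = id, op = op, inputs = as.integer(inputs)),
                     list(...))
  id
}

g_input <- function(g, name, channels) {
  id <- add_node(g, "input", name = name, channels = channels)
  g$shapes[[id]] <- channels
  g$levels[[id]] <- 0L
  id
}

g_conv <- function(g, input, filters, kernel, act = "relu", bias = TRUE,
                   tag = "conv") {
  cin <- g$shapes[[input]]
  id <- add_node(g, "conv", input, cin = cin, cout = filters,
                 kernel = kernel, act = act, bias = bias)
  wname <- sprintf("%s%03d.w", tag, id)
  bname <- sprintf("%s%03d.b", tag, id)
  g$nodes[[id]]$w <- wname
  g$nodes[[id]]$b <- bname
  g$param_shapes[[wname]] <- c(kernel, kernel, cin, filters)
  if (bias) g$param_shapes[[bname]] <- filters
  g$shapes[[id]] <- filters
  g$levels[[id]] <- g$levels[[input]]
  id
}

g_bn <- function(g, input, tag = "bn") {
  ch <- g$shapes[[input]]
  id <- add_node(g, "bn", input, channels = ch)
  base <- sprintf("%s%03d", tag, id)
  g$nodes[[id]]$gamma <- paste0(base, ".gamma")
  g$nodes[[id]]$beta <- paste0(base, ".beta")
  g$nodes[[id]]$rmean <- paste0(base, ".rmean")
  g$nodes[[id]]$rvar <- paste0(base, ".rvar")
  g$param_shapes[[paste0(base, ".gamma")]] <- ch
  g$param_shapes[[paste0(base, ".beta")]] <- ch
  g$shapes[[id]] <- ch
  g$levels[[id]] <- g$levels[[input]]
  id
}

g_pool <- function(g, input) {
  id <- add_node(g, "pool", input)
  g$shapes[[id]] <- g$shapes[[input]]
  g$levels[[id]] <- g$levels[[input]] + 1L
  id
}

g_up <- function(g, input) {
  id <- add_node(g, "up", input)
  g$shapes[[id]] <- g$shapes[[input]]
  g$levels[[id]] <- g$levels[[input]] - 1L
  id
}

g_dropout <- function(g, input, rate) {
  id <- add_node(g, "dropout", input, rate = rate)
  g$shapes[[id]] <- g$shapes[[input]]
  g$levels[[id]] <- g$levels[[input]]
  id
}

g_concat <- function(g, inputs) {
  lv <- unique(unlist(g$levels[inputs]))
  stopifnot(length(lv) == 1L)
  id <- add_node(g, "concat", inputs)
  g$shapes[[id]] <- sum(unlist(g$shapes[inputs]))
  g$levels[[id]] <- lv
  id
}

# Glorot-normal initialization of all parameters (seeded, deterministic).
init_params <- function(g, seed) {
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (name in names(g$param_shapes)) {
    shp <- g$param_shapes[[name]]
    if (grepl("\\.w$", name)) {
      k <- shp[1]; cin <- shp[3]; cout <- shp[4]
      sd <- sqrt(2 / (k * k * cin + k * k * cout))
      params[[name]] <- array(stats::rnorm(prod(shp), sd = sd), dim = shp)
    } else if (grepl("\\.gamma$", name)) {
      params[[name]] <- rep(1, shp)
    } else {  # conv bias, bn beta
      params[[name]] <- if (length(shp) > 1) array(0, dim = shp) else rep(0, shp)
    }
  }
  if (!is.null(g$head_bias) && !is.null(params[[g$head_bias]]))
    params[[g$head_bias]][] <- -2   # background prior for the sigmoid head
  for (id in seq_along(g$nodes)) {
    nd <- g$nodes[[id]]
    if (nd$op == "bn") {
      state[[nd$rmean]] <- rep(0, nd$channels)
      state[[nd$rvar]] <- rep(1, nd$channels)
    }
  }
  list(params = params, state = state)
}

.bn_eps <- 1e-3
.bn_momentum <- 0.9    # moving-statistics momentum; 0.9 keeps inference
                       # statistics usable after short training runs

act_code <- function(act) switch(act, linear = 0L, relu = 1L, sigmoid = 2L)

#' @keywords internal
forward_graph <- function(model, inputs, training = FALSE) {
  g <- model$graph
  p <- model$params
  s <- model$state
  vals <- vector("list", length(g$nodes))
  cache <- vector("list", length(g$nodes))
  for (id in seq_along(g$nodes)) {
    nd <- g$nodes[[id]]
    out <- switch(nd$op,
      input = {
        x <- inputs[[nd$name]]
        if (is.null(x)) stop("missing input: ", nd$name)
        x
      },
      conv = {
        x <- vals[[nd$inputs]]
        b <- if (nd$bias) p[[nd$b]] else numeric(nd$cout)
        conv2d_fwd(x, p[[nd$w]], b, nd$bias, act_code(nd$act))
      },
      bn = {
        x <- vals[[nd$inputs]]
        if (training) {
          r <- bn_fwd(x, p[[nd$gamma]], p[[nd$beta]], NULL, NULL, .bn_eps)
          s[[nd$rmean]] <- .bn_momentum * s[[nd$rmean]] + (1 - .bn_momentum) * r$mu
          s[[nd$rvar]] <- .bn_momentum * s[[nd$rvar]] + (1 - .bn_momentum) * r$va
          cache[[id]] <- list(mu = r$mu, va = r$va)
          r$y
        } else {
          bn_fwd(x, p[[nd$gamma]], p[[nd$beta]], s[[nd$rmean]],
                 s[[nd$rvar]], .bn_eps)$y
        }
      },
      pool = {
        r <- maxpool2_fwd(vals[[nd$inputs]])
        cache[[id]] <- list(arg = r$arg, xdim = dim(vals[[nd$inputs]]))
        r$y
      },
      up = upsample2_fwd(vals[[nd$inputs]]),
      dropout = {
        x <- vals[[nd$inputs]]
        if (training) {
          keep <- 1 - nd$rate
          mask <- array(stats::rbinom(length(x), 1, keep) / keep, dim(x))
          cache[[id]] <- list(mask = mask)
          x * mask
        } else x
      },
      concat = concat_fwd(vals[nd$inputs]),
      stop("unknown op ", nd$op))
    vals[[id]] <- out
  }
  list(out = vals[[length(g$nodes)]], vals = vals, cache = cache)
}

#' @keywords internal
backward_graph <- function(model, fwd, dout) {
  g <- model$graph
  p <- model$params
  vals <- fwd$vals
  cache <- fwd$cache
  n <- length(g$nodes)
  dvals <- new.env(parent = emptyenv())
  dvals[[as.character(n)]] <- dout
  grads <- new.env(parent = emptyenv())
  for (id in rev(seq_len(n))) {
    nd <- g$nodes[[id]]
    dy <- dvals[[as.character(id)]]
    if (is.null(dy)) next
    rm(list = as.character(id), envir = dvals)   # release
    switch(nd$op,
      input = NULL,
      conv = {
        r <- conv2d_bwd(vals[[nd$inputs]], p[[nd$w]], dy, vals[[id]],
                        nd$bias, act_code(nd$act))
        acc_grad(grads, nd$w, r$dw)
        if (nd$bias) acc_grad(grads, nd$b, r$db)
        acc_dval(dvals, nd$inputs, r$dx)
      },
      bn = {
        cc <- cache[[id]]
        if (is.null(cc)) stop("bn backward requires a training-mode forward")
        r <- bn_bwd(vals[[nd$inputs]], dy, p[[nd$gamma]], cc$mu, cc$va,
                    .bn_eps)
        acc_grad(grads, nd$gamma, r$dgamma)
        acc_grad(grads, nd$beta, r$dbeta)
        acc_dval(dvals, nd$inputs, r$dx)
      },
      pool = {
        cc <- cache[[id]]
        acc_dval(dvals, nd$inputs, maxpool2_bwd(dy, cc$arg, cc$xdim))
      },
      dropout = {
        acc_dval(dvals, nd$inputs, dy * cache[[id]]$mask)
      },
      up = acc_dval(dvals, nd$inputs, upsample2_bwd(dy)),
      concat = {
        at <- 0L
        for (src in nd$inputs) {
          ch <- g$shapes[[src]]
          acc_dval(dvals, src, concat_slice(dy, at, ch))
          at <- at + ch
        }
      })
  }
  grads
}

acc_grad <- function(grads, name, g) {
  cur <- grads[[name]]
  grads[[name]] <- if (is.null(cur)) g else cur + g
}

acc_dval <- function(dvals, id, dx) {
  key <- as.character(id)
  cur <- dvals[[key]]
  dvals[[key]] <- if (is.null(cur)) dx else cur + dx
}

# --- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  for (name in ls(params)) {
    st[[paste0(name, ".m")]] <- params[[name]] * 0
    st[[paste0(name, ".v")]] <- params[[name]] * 0
  }
  st$t <- 0L
  st
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1L
  t <- opt$t
  for (name in ls(grads)) {
    gr <- grads[[name]]
    m <- beta1 * opt[[paste0(name, ".m")]] + (1 - beta1) * gr
    v <- beta2 * opt[[paste0(name, ".v")]] + (1 - beta2) * gr^2
    opt[[paste0(name, ".m")]] <- m
    opt[[paste0(name, ".v")]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    params[[name]] <- params[[name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(params)
}

# --- RNG helpers ------------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  code
}
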