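# Checkpoint selection by minimum-variance windowing: rather than taking
# the epoch with the lowest validation loss outright, the history's last
# `span` epochs are scanned with a moving `window`; the window with the
# smallest loss variance is preferred, and within it epochs are tried in
# order of ascending loss until one with a saved checkpoint is found.

#' Selection specification
#'
#' @param window Moving-window width in epochs (default 50).
#' @param span How far back from the end of the history the windows range
#'   (default 150); all windows lie fully inside the last `span` epochs and
#'   slide by one epoch.
#' @export
selection_spec <- function(window = 50L, span = 150L) {
  stopifnot(window >= 1, span >= window)
  structure(list(window = as.integer(window), span = as.integer(span)),
            class = "selection_spec")
}

#' Select the evaluation checkpoint from a loss history
#'
#' Every contiguous `window`-epoch window inside the last `span` epochs is
#' scored by the population variance of its validation losses.  Windows are
#' visited from the smallest variance up (ties broken toward the later
#' window); within a window, epochs are visited by ascending loss (ties
#' toward the later epoch); the first visited epoch whose checkpoint exists
#' is returned.
#'
#' @param history A `loss_history` (needs `val_loss` and `checkpoint`).
#' @param spec A [selection_spec()].
#' @return The selected epoch (1-based), with attribute `"window"` giving
#'   the chosen window's epoch range.
#' @export
select_checkpoint <- function(history, spec = selection_spec()) {
  loss <- history$val_loss
  cp <- history$checkpoint
  n <- length(loss)
  if (n < spec$span)
    stop("history shorter than the selection span (", spec$span, " epochs)")
  first <- n - spec$span + 1L
  starts <- first:(n - spec$window + 1L)
  pvar <- function(x) mean((x - mean(x))^2)
  vars <- vapply(starts, function(s) pvar(loss[s:(s + spec$window - 1L)]),
                 numeric(1))
  # ascending variance; later window first among ties
  win_order <- order(vars, -starts)
  for (w in win_order) {
    idx <- starts[w]:(starts[w] + spec$window - 1L)
    # ascending loss; later epoch first among ties
    cand <- idx[order(loss[idx], -idx)]
    hit <- cand[cp[cand]]
    if (length(hit))
      return(structure(hit[1],
                       window = c(starts[w], starts[w] + spec$window - 1L)))
  }
  stop("no saved checkpoint in the last ", spec$span,
       " epochs; fall back to the best-loss checkpoint")
}
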