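# Shared fixtures and independent brute-force oracles.  Everything is
# generated in code; no data files.

small_phantom <- function(seed = 7, n_lesions = 3, noise_sd = 2,
                          shape = c(48, 48, 48), radius = c(3, 6), ...) {
  make_phantom(phantom_spec(grid_shape = shape, n_lesions = n_lesions,
                            lesion_radius_range = radius,
                            noise_sd = noise_sd, seed = seed, ...))
}

random_mask <- function(shape, p = 0.2) {
  array(stats::rbinom(prod(shape), 1, p), shape)
}

# --- brute-force voxel metrics (set formulas evaluated directly) -----------

oracle_voxel_metrics <- function(pred, gt) {
  P <- which(pred > 0); G <- which(gt > 0)
  I <- intersect(P, G); U <- union(P, G)
  list(dsc = if (length(P) + length(G) > 0)
         2 * length(I) / (length(P) + length(G)) else NA_real_,
       jaccard = if (length(U) > 0) length(I) / length(U) else NA_real_,
       ppv = if (length(P) > 0) length(I) / length(P) else NA_real_,
       tpr = if (length(G) > 0) length(I) / length(G) else NA_real_,
       vd = if (length(G) > 0)
         abs(length(P) - length(G)) / length(G) else NA_real_)
}

# --- brute-force connected components (BFS over explicit neighbours) -------

oracle_label_components <- function(mask, connectivity = 18) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(offs))
  offs <- offs[manh > 0 & switch(as.character(connectivity),
                                 "6" = manh == 1, "18" = manh <= 2,
                                 "26" = manh <= 3), , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  idx2xyz <- function(i) {
    i0 <- i - 1L
    c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2])) + 1L
  }
  for (start in which(mask > 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      p <- idx2xyz(cur)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] > 0 && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue <- c(queue, q[1] + d[1] * (q[2] - 1L) +
                       d[1] * d[2] * (q[3] - 1L))
        }
      }
    }
  }
  lab
}

oracle_lesion_metrics <- function(pred, gt, connectivity = 18) {
  lg <- oracle_label_components(gt, connectivity)
  lp <- oracle_label_components(pred, connectivity)
  ng <- max(lg); np <- max(lp)
  detected <- 0L
  if (ng > 0) for (l in seq_len(ng))
    if (any(pred[lg == l] > 0)) detected <- detected + 1L
  fp <- 0L
  if (np > 0) for (l in seq_len(np))
    if (!any(gt[lp == l] > 0)) fp <- fp + 1L
  list(ltpr = if (ng > 0) detected / ng else NA_real_,
       lfpr = if (np > 0) fp / np else NA_real_,
       n_detected = detected, n_false_positive = fp,
       n_gt_lesions = ng, n_pred_lesions = np)
}

# --- brute-force checkpoint selection --------------------------------------

oracle_select_checkpoint <- function(history, window = 50, span = 150) {
  loss <- history$val_loss
  cp <- history$checkpoint
  n <- length(loss)
  starts <- (n - span + 1):(n - window + 1)
  wins <- lapply(starts, function(s) {
    idx <- s:(s + window - 1)
    x <- loss[idx]
    list(start = s, var = mean((x - mean(x))^2), idx = idx)
  })
  # full preference order: ascending variance, later window on ties
  ord <- order(vapply(wins, `[[`, numeric(1), "var"),
               -vapply(wins, `[[`, numeric(1), "start"))
  for (w in wins[ord]) {
    cand <- w$idx[order(loss[w$idx], -w$idx)]
    for (e in cand) if (cp[e]) return(e)
  }
  NA_integer_
}

# --- misc -------------------------------------------------------------------

dice_of <- function(pred_bin, gt) {
  s <- sum(pred_bin) + sum(gt)
  if (s == 0) return(1)
  2 * sum(pred_bin > 0 & gt > 0) / s
}

lesion_slice_records <- function(ph, plane = "axial", n = 6) {
  vol <- normalize_intensity(ph$volume)
  recs <- slice_volume(vol, ph$mask, plane)
  les <- Filter(function(r) any(r$label > 0), recs)
  nles <- vapply(les, function(r) sum(r$label), numeric(1))
  les[order(-nles)[seq_len(min(n, length(les)))]]
}
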