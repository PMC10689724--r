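# Synthetic multi-modal brain phantoms and synthetic validation-loss
# histories.  Phantoms emulate skull-stripped, co-registered challenge data:
# an ellipsoidal "brain" on a zero background, ellipsoidal lesions that are
# hyperintense on FLAIR and T2w, and an optional subset of lesions that are
# hypointense "black holes" on T1w, as seen for certain chronic lesions.

# Fixed tissue means (arbitrary intensity units); additive Gaussian noise on
# top.  No bias field or partial-volume modelling.
.tissue_means <- list(
  FLAIR = c(brain = 100, lesion = 180),
  T2w   = c(brain = 90,  lesion = 170),
  T1w   = c(brain = 120, lesion = 120, black_hole = 60)
)

#' Phantom specification
#'
#' @param grid_shape Integer vector of length 3, each `>= 32` (voxels).
#' @param n_lesions Non-negative lesion count.
#' @param lesion_radius_range Length-2 numeric, radii in voxels drawn
#'   uniformly per axis from `[min, max]`.
#' @param black_hole_fraction Fraction of lesions rendered hypointense on
#'   T1w (rounded down to a lesion count).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @param non_overlapping Logical; reject lesion placements that touch an
#'   already-placed lesion (bounded retries).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), n_lesions = 3,
                         lesion_radius_range = c(2.5, 5),
                         black_hole_fraction = 0.3, noise_sd = 2,
                         seed = 1L, non_overlapping = FALSE) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 32),
            n_lesions >= 0,
            length(lesion_radius_range) == 2,
            lesion_radius_range[1] <= lesion_radius_range[2],
            lesion_radius_range[1] > 0,
            black_hole_fraction >= 0, black_hole_fraction <= 1,
            noise_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 black_hole_fraction = black_hole_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 non_overlapping = isTRUE(non_overlapping)),
            class = "phantom_spec")
}

# ellipsoid membership mask on an integer grid
ellipsoid_mask <- function(shape, center, radii) {
  dx <- (seq_len(shape[1]) - center[1]) / radii[1]
  dy <- (seq_len(shape[2]) - center[2]) / radii[2]
  dz <- (seq_len(shape[3]) - center[3]) / radii[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
}

#' Generate a synthetic multi-modal phantom
#'
#' Draws an ellipsoidal brain region occupying ~70% of each axis, places
#' `n_lesions` axis-aligned ellipsoidal lesions fully inside the brain, and
#' renders FLAIR, T1w and T2w intensity volumes plus the binary lesion mask.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a `multimodal_volume`: named list of 3D
#'   arrays plus spacing), `mask` (binary 3D array) and `lesions` (per-lesion
#'   centers, radii, black-hole flags).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- spec$grid_shape
    brain_radii <- 0.35 * shape
    brain_center <- (shape + 1) / 2
    brain <- ellipsoid_mask(shape, brain_center, brain_radii)

    mask <- array(FALSE, shape)
    lesions <- list()
    n_bh <- floor(spec$n_lesions * spec$black_hole_fraction)
    for (i in seq_len(spec$n_lesions)) {
      placed <- FALSE
      for (try in 1:200) {
        radii <- stats::runif(3, spec$lesion_radius_range[1],
                              spec$lesion_radius_range[2])
        # sample a center keeping the lesion inside the brain ellipsoid:
        # sufficient condition ||(c - c0)/R|| <= 1 - max(r/R) - margin
        u <- stats::runif(3, -1, 1)
        allow <- 1 - max(radii / brain_radii) - 1 / min(brain_radii)
        if (allow <= 0) next
        center <- brain_center + u * allow * brain_radii / sqrt(3)
        if (sqrt(sum(((center - brain_center) / brain_radii)^2)) > allow)
          next
        les <- ellipsoid_mask(shape, center, radii)
        if (!any(les)) next
        if (spec$non_overlapping && any(les & mask)) next
        mask <- mask | les
        lesions[[i]] <- list(center = center, radii = radii,
                             black_hole = i <= n_bh)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place lesion ", i, " after 200 attempts")
    }

    bh_mask <- array(FALSE, shape)
    for (l in lesions)
      if (l$black_hole)
        bh_mask <- bh_mask | ellipsoid_mask(shape, l$center, l$radii)

    vols <- list()
    for (mod in c("FLAIR", "T1w", "T2w")) {
      mu <- .tissue_means[[mod]]
      v <- array(0, shape)
      v[brain] <- mu["brain"]
      if (mod == "T1w") {
        v[bh_mask] <- mu["black_hole"]
      } else {
        v[mask] <- mu["lesion"]
      }
      if (spec$noise_sd > 0)
        v[brain] <- v[brain] + stats::rnorm(sum(brain), sd = spec$noise_sd)
      vols[[mod]] <- v
    }
    list(volume = multimodal_volume(vols, spacing = c(1, 1, 1)),
         mask = array(as.integer(mask), shape),
         brain = brain,
         lesions = lesions)
  })
}

#' Loss-history specification
#'
#' @param n_epochs Positive epoch count (use `>= 150` when the history feeds
#'   the checkpoint-selection rule, whose default span is 150).
#' @param trend `"decreasing"` (exponential decay), `"plateau"` (decay that
#'   levels off) or `"noisy_spike"` (a plateau with a high-variance region
#'   containing one deceptively low loss value).
#' @param noise_sd Gaussian noise on the loss values.
#' @param checkpoint_stride Checkpoints are flagged at every
#'   `checkpoint_stride`-th epoch and at each running-best epoch.
#' @param seed Integer seed.
#' @export
loss_history_spec <- function(n_epochs = 300, trend = c("decreasing",
                              "plateau", "noisy_spike"), noise_sd = 0.01,
                              checkpoint_stride = 3, seed = 1L) {
  trend <- match.arg(trend)
  stopifnot(n_epochs >= 1, noise_sd >= 0, checkpoint_stride >= 1)
  structure(list(n_epochs = as.integer(n_epochs), trend = trend,
                 noise_sd = noise_sd,
                 checkpoint_stride = as.integer(checkpoint_stride),
                 seed = as.integer(seed)),
            class = "loss_history_spec")
}

#' Generate a synthetic validation-loss history
#'
#' Mirrors the trainer's checkpoint policy: a checkpoint flag at every
#' `checkpoint_stride`-th epoch and whenever a new best (lowest so far)
#' validation loss occurs.
#'
#' @param spec A [loss_history_spec()].
#' @return A `loss_history` object (see [as_loss_history()]).
#' @export
make_loss_history <- function(spec) {
  stopifnot(inherits(spec, "loss_history_spec"))
  with_seed(spec$seed, {
    n <- spec$n_epochs
    e <- seq_len(n)
    base <- switch(spec$trend,
      decreasing = 0.1 + 0.9 * exp(-3 * e / n),
      plateau = 0.1 + 0.9 * exp(-pmin(e, n / 3) * 6 / n),
      noisy_spike = {
        b <- 0.1 + 0.9 * exp(-pmin(e, n / 3) * 6 / n)
        # a turbulent stretch in the second half with one deep spike
        lo <- floor(n * 0.55); hi <- min(n, lo + max(20, n %/% 10))
        idx <- lo:hi
        b[idx] <- b[idx] + stats::rnorm(length(idx), sd = 0.08)
        b[floor((lo + hi) / 2)] <- 0.01
        b
      })
    loss <- base + if (spec$noise_sd > 0)
      stats::rnorm(n, sd = spec$noise_sd) else 0
    loss <- pmax(loss, 1e-4)
    # stride checkpoints plus the best epoch: the trainer's best-so-far file
    # is overwritten as training improves, so at termination one extra
    # checkpoint exists, at the overall best epoch
    cp <- (e %% spec$checkpoint_stride) == 0
    cp[which.min(loss)] <- TRUE
    as_loss_history(loss, checkpoint = cp)
  })
}

#' Construct a loss history
#'
#' @param val_loss Numeric vector of per-epoch validation losses.
#' @param checkpoint Logical vector flagging epochs with a saved checkpoint.
#' @param train_loss,lr Optional per-epoch training losses / learning rates.
#' @return A data frame of class `loss_history` with attribute `best_epoch`
#'   (the first epoch attaining the minimum validation loss).
#' @export
as_loss_history <- function(val_loss, checkpoint = NULL, train_loss = NULL,
                            lr = NULL) {
  n <- length(val_loss)
  if (is.null(checkpoint)) checkpoint <- rep(FALSE, n)
  stopifnot(length(checkpoint) == n)
  h <- data.frame(epoch = seq_len(n), val_loss = val_loss,
                  checkpoint = as.logical(checkpoint))
  if (!is.null(train_loss)) h$train_loss <- train_loss
  if (!is.null(lr)) h$lr <- lr
  structure(h, class = c("loss_history", "data.frame"),
            best_epoch = which.min(val_loss))
}
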