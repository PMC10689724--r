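# Conversion of 3D multi-modal volumes into normalized 256x256 slice sets
# along the three orthogonal planes, the training-slice selection rule, and
# inverse restacking used at inference time.
#
# Plane convention for an (x, y, z) array: "axial" slices are x-y planes
# indexed by z, "coronal" slices are x-z planes indexed by y, "sagittal"
# slices are y-z planes indexed by x.  Slice indices are 0-based in the
# record (provenance), 1-based in R code.

.planes <- c("axial", "coronal", "sagittal")
.target_size <- 256L

#' Multi-modal volume container
#'
#' @param data Named list of 3D numeric arrays (names from
#'   `c("FLAIR", "T1w", "T2w")`), all of identical shape.
#' @param spacing Voxel spacing in mm per axis (length 3).
#' @export
multimodal_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.list(data), length(data) >= 1, !is.null(names(data)),
            all(names(data) %in% c("FLAIR", "T1w", "T2w")))
  shp <- dim(data[[1]])
  stopifnot(length(shp) == 3)
  for (a in data) stopifnot(identical(dim(a), shp))
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  cat(sprintf("<multimodal_volume> %s, %s, spacing %s mm\n",
              paste(names(x$data), collapse = "+"),
              paste(dim(x$data[[1]]), collapse = "x"),
              paste(x$spacing, collapse = "x")))
  invisible(x)
}

vol_shape <- function(vol) dim(vol$data[[1]])

#' Min-max intensity normalization
#'
#' Maps each modality independently to `[0, 1]` by an affine transform of
#' its own minimum and maximum; voxel intensity order is preserved.
#'
#' @param vol A [multimodal_volume()].
#' @return The normalized volume.
#' @export
normalize_intensity <- function(vol) {
  stopifnot(inherits(vol, "multimodal_volume"))
  vol$data <- lapply(vol$data, function(a) {
    rng <- range(a)
    if (rng[1] == rng[2])
      stop("cannot normalize a constant-valued modality")
    (a - rng[1]) / (rng[2] - rng[1])
  })
  vol
}

slice_axis <- function(plane) c(axial = 3L, coronal = 2L, sagittal = 1L)[[plane]]

extract_slice <- function(a, plane, i) {
  switch(plane,
         axial = a[, , i],
         coronal = a[, i, ],
         sagittal = a[i, , ])
}

insert_slice <- function(a, plane, i, s) {
  switch(plane,
         axial = a[, , i] <- s,
         coronal = a[, i, ] <- s,
         sagittal = a[i, , ] <- s)
  a
}

resize_image <- function(img, w, h) {
  if (all(dim(img) == c(w, h))) return(img)
  EBImage::resize(img, w = w, h = h)          # bilinear
}

resize_label <- function(lab, w, h) {
  if (all(dim(lab) == c(w, h))) return(lab)
  EBImage::resize(lab, w = w, h = h, filter = "none")   # nearest neighbour
}

#' Slice a volume along one plane
#'
#' Produces one `slice_record` per index along the plane's axis.  Modality
#' images are resized to 256x256 with bilinear interpolation; labels with
#' nearest-neighbour interpolation (preserving binarity).  The source slice
#' dimensions are stored for exact inverse mapping.
#'
#' @param vol A normalized [multimodal_volume()].
#' @param mask Optional binary 3D array (lesion ground truth).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return List of `slice_record` objects.
#' @export
slice_volume <- function(vol, mask = NULL, plane) {
  stopifnot(inherits(vol, "multimodal_volume"))
  if (!plane %in% .planes)
    stop("unknown plane: ", plane, " (expected axial/coronal/sagittal)")
  shp <- vol_shape(vol)
  ax <- slice_axis(plane)
  n <- shp[ax]
  lapply(seq_len(n), function(i) {
    imgs <- lapply(vol$data, function(a) {
      s <- extract_slice(a, plane, i)
      resize_image(s, .target_size, .target_size)
    })
    lab <- NULL
    src_dim <- dim(extract_slice(vol$data[[1]], plane, i))
    if (!is.null(mask)) {
      s <- extract_slice(mask, plane, i)
      lab <- resize_label(s, .target_size, .target_size)
    }
    structure(list(images = imgs, label = lab, plane = plane,
                   slice_index = i - 1L, source_dim = src_dim),
              class = "slice_record")
  })
}

#' Training-slice selection
#'
#' Keeps every slice whose label contains at least one lesion pixel, plus
#' every 30th slice (1-based, counted within the ordered subsequence of
#' lesion-free slices) among the slices with an all-zero label.
#'
#' @param records List of `slice_record`s, each carrying a label.
#' @param empty_stride Stride through the lesion-free subsequence
#'   (default 30).
#' @return The selected sub-list, in the original order.
#' @export
select_training_slices <- function(records, empty_stride = 30L) {
  has_label <- vapply(records, function(r) !is.null(r$label), logical(1))
  if (!all(has_label)) stop("all records must carry a label")
  lesion <- vapply(records, function(r) any(r$label > 0), logical(1))
  keep <- lesion
  empty_pos <- cumsum(!lesion)
  keep[!lesion & (empty_pos %% empty_stride == 0)] <- TRUE
  records[keep]
}

#' Augmentation specification
#'
#' Default ranges: rotation +-15 degrees, width/height shift +-10%, zoom
#' +-10%, brightness +-20%, horizontal and vertical flips.
#'
#' @param rotation,shift,zoom,brightness Half-ranges of the uniform draws.
#' @param flip_h,flip_v Allow the respective flips (each applied with
#'   probability 1/2).
#' @export
augment_spec <- function(rotation = 15, shift = 0.10, zoom = 0.10,
                         brightness = 0.20, flip_h = TRUE, flip_v = TRUE) {
  stopifnot(rotation >= 0, shift >= 0, zoom >= 0, brightness >= 0)
  structure(list(rotation = rotation, shift = shift, zoom = zoom,
                 brightness = brightness, flip_h = flip_h, flip_v = flip_v),
            class = "augment_spec")
}

# affine matrix for EBImage::affine (maps output coords to input coords via
# the 3x2 matrix m: input = cbind(x, y, 1) %*% m)
affine_matrix <- function(angle, shift_xy, zoom, size) {
  c0 <- (size + 1) / 2
  a <- angle * pi / 180
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2) / zoom
  off <- c(c0, c0) - R %*% c(c0 + shift_xy[1], c0 + shift_xy[2])
  rbind(t(R), as.numeric(off))
}

#' Augment a slice record
#'
#' Applies one random geometric transform (rotation, shift, zoom, flips) to
#' every modality image and to the label, the same displacement field for
#' all of them, and an additional photometric brightness factor to the
#' images only.  The label is resampled nearest-neighbour and re-binarized.
#'
#' @param rec A `slice_record` with a label.
#' @param spec An [augment_spec()].
#' @param seed Optional seed for a deterministic draw.
#' @return The transformed `slice_record`.
#' @export
augment <- function(rec, spec = augment_spec(), seed = NULL) {
  stopifnot(inherits(rec, "slice_record"))
  if (is.null(rec$label)) stop("augment() expects a training record with label")
  draw <- function() {
    list(angle = stats::runif(1, -spec$rotation, spec$rotation),
         shift = stats::runif(2, -spec$shift, spec$shift) * .target_size,
         zoom = 1 + stats::runif(1, -spec$zoom, spec$zoom),
         bright = 1 + stats::runif(1, -spec$brightness, spec$brightness),
         fh = spec$flip_h && stats::runif(1) < 0.5,
         fv = spec$flip_v && stats::runif(1) < 0.5)
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())

  geom <- function(img, label = FALSE) {
    x <- img
    if (d$fh) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
    if (d$fv) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    if (d$angle != 0 || any(d$shift != 0) || d$zoom != 1) {
      m <- affine_matrix(d$angle, d$shift, d$zoom, .target_size)
      x <- EBImage::affine(x, m,
                           filter = if (label) "none" else "bilinear")
      x <- as.matrix(x)
    }
    if (label) (x > 0.5) * 1 else x
  }
  rec$images <- lapply(rec$images, function(im) pmin(pmax(
    geom(im) * d$bright, 0), 1))
  rec$label <- geom(rec$label, label = TRUE)
  rec
}

#' Restack per-slice 2D maps into a 3D volume
#'
#' Inverse of [slice_volume()]: each 256x256 map is resized back to its
#' source slice shape (bilinear for probabilities, nearest for labels) and
#' written at its original index.
#'
#' @param maps List of 2D matrices, one per slice, in slice order.
#' @param records The `slice_record`s the maps correspond to.
#' @param shape Target 3D shape.
#' @param label Logical; use nearest-neighbour resizing.
#' @return A 3D array of the given shape.
#' @export
restack_slices <- function(maps, records, shape, label = FALSE) {
  stopifnot(length(maps) == length(records))
  out <- array(0, shape)
  for (k in seq_along(maps)) {
    rec <- records[[k]]
    sd <- rec$source_dim
    m <- if (label) resize_label(maps[[k]], sd[1], sd[2]) else
      resize_image(maps[[k]], sd[1], sd[2])
    out <- insert_slice(out, rec$plane, rec$slice_index + 1L, m)
  }
  out
}
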