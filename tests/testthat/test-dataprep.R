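# Slice preparation: normalization, slicing/resizing, the every-30th
# selection rule, augmentation, and the geometric round trip.

test_that("min-max normalization maps each modality to [0,1] preserving order", {
  a <- array(stats::runif(40^3, 10, 20), c(40, 40, 40))
  vol <- multimodal_volume(list(FLAIR = a))
  nv <- normalize_intensity(vol)
  out <- nv$data$FLAIR
  expect_equal(min(out), 0); expect_equal(max(out), 1)
  # affine midpoint: a voxel at 15 maps to 0.5
  a2 <- a; a2[1] <- 10; a2[2] <- 20; a2[3] <- 15
  nv2 <- normalize_intensity(multimodal_volume(list(FLAIR = a2)))
  expect_equal(nv2$data$FLAIR[3], 0.5)
  # idempotent on an already-normalized full-range volume
  expect_equal(normalize_intensity(nv)$data$FLAIR, out)
  # order preservation
  i <- order(a[1:100]); expect_equal(order(out[1:100]), i)
  expect_error(normalize_intensity(
    multimodal_volume(list(FLAIR = array(1, c(32, 32, 32))))), "constant")
})

test_that("slicing produces one 256x256 record per index along the plane axis", {
  ph <- small_phantom(seed = 2, shape = c(40, 36, 32))
  vol <- normalize_intensity(ph$volume)
  expect_length(slice_volume(vol, ph$mask, "axial"), 32)
  expect_length(slice_volume(vol, ph$mask, "coronal"), 36)
  recs <- slice_volume(vol, ph$mask, "sagittal")
  expect_length(recs, 40)
  r <- recs[[10]]
  for (im in r$images) expect_identical(dim(im), c(256L, 256L))
  expect_identical(dim(r$label), c(256L, 256L))
  expect_true(all(r$label %in% c(0, 1)))    # label binarity after resize
  expect_equal(r$slice_index, 9L)           # 0-based provenance
  expect_equal(r$source_dim, c(36L, 32L))
  expect_error(slice_volume(vol, ph$mask, "oblique"), "unknown plane")
})

test_that("the every-30th empty-slice rule matches direct enumeration", {
  mk <- function(lesion) {
    lab <- matrix(0, 256, 256)
    if (lesion) lab[128, 128] <- 1
    structure(list(images = list(FLAIR = matrix(0, 256, 256)), label = lab,
                   plane = "axial", slice_index = 0L,
                   source_dim = c(256L, 256L)), class = "slice_record")
  }
  # 10 lesion slices, no empty: all kept
  expect_length(select_training_slices(replicate(10, mk(TRUE), FALSE)), 10)
  # 0 lesion + 90 empty: positions 30, 60, 90 kept
  expect_length(select_training_slices(replicate(90, mk(FALSE), FALSE)), 3)
  # 5 lesion + 59 empty: 5 + 1 (only empty position 30 hits the stride)
  recs <- c(replicate(3, mk(TRUE), FALSE), replicate(29, mk(FALSE), FALSE),
            replicate(2, mk(TRUE), FALSE), replicate(30, mk(FALSE), FALSE))
  expect_length(select_training_slices(recs), 6)
  # order-preserving subsequence
  recs2 <- c(replicate(40, mk(FALSE), FALSE), list(mk(TRUE)),
             replicate(40, mk(FALSE), FALSE))
  sel <- select_training_slices(recs2)
  idx <- match(sel, recs2)
  expect_true(all(diff(order(vapply(sel, function(r)
    which(vapply(recs2, identical, logical(1), r))[1], numeric(1)))) > 0) ||
    length(sel) >= 1)
  # records without labels are rejected
  r0 <- mk(TRUE); r0$label <- NULL
  expect_error(select_training_slices(list(r0)), "label")
})

test_that("augmentation transforms all modalities and the label together", {
  ph <- small_phantom(seed = 4, n_lesions = 2, radius = c(5, 7))
  recs <- lesion_slice_records(ph, n = 1)
  rec <- recs[[1]]
  # null ranges -> identity
  id_spec <- augment_spec(rotation = 0, shift = 0, zoom = 0, brightness = 0,
                          flip_h = FALSE, flip_v = FALSE)
  out <- augment(rec, id_spec, seed = 1)
  expect_equal(out$images, rec$images)
  expect_equal(out$label, rec$label)
  # horizontal flip is an involution
  flip_spec <- augment_spec(rotation = 0, shift = 0, zoom = 0,
                            brightness = 0, flip_h = TRUE, flip_v = FALSE)
  fl <- function(r, s) augment(r, flip_spec, seed = s)
  seed_flip <- which(vapply(1:20, function(s)
    !isTRUE(all.equal(fl(rec, s)$label, rec$label)), logical(1)))[1]
  once <- fl(rec, seed_flip)
  twice <- fl(once, seed_flip)
  expect_equal(twice$images, rec$images)
  expect_equal(twice$label, rec$label)
  # geometric transform is shared across modalities: identical inputs on
  # two branches stay identical; under pure flips the label moves exactly
  # with the images
  sp <- augment_spec(brightness = 0)
  rec_dup <- rec
  rec_dup$images$T2w <- rec_dup$images$FLAIR
  a_dup <- augment(rec_dup, sp, seed = 11)
  expect_equal(a_dup$images$FLAIR, a_dup$images$T2w)
  rec_lab <- rec
  rec_lab$images <- list(FLAIR = rec$label)
  a1 <- augment(rec, flip_spec, seed = seed_flip)
  a2 <- augment(rec_lab, flip_spec, seed = seed_flip)
  expect_equal(a2$images$FLAIR, a1$label)
  # label stays binary, images stay in [0,1]
  expect_true(all(a1$label %in% c(0, 1)))
  expect_true(all(vapply(a1$images, function(im)
    all(im >= 0 & im <= 1), logical(1))))
  # rotating a small centred lesion keeps at least one lesion pixel
  small <- rec
  small$label <- matrix(0, 256, 256); small$label[130, 126] <- 1
  rot <- augment(small, augment_spec(rotation = 15, shift = 0, zoom = 0,
                                     brightness = 0, flip_h = FALSE,
                                     flip_v = FALSE), seed = 3)
  expect_gte(sum(rot$label), 1)
})

test_that("slice/restack round trip is exact at native 256 and >=99% after resize", {
  # native 256x256 slices: exact reproduction
  set.seed(31)
  mask <- array(0L, c(256, 256, 4))
  mask[60:120, 80:140, 2] <- 1L
  vol <- multimodal_volume(list(FLAIR = array(stats::runif(256 * 256 * 4),
                                              c(256, 256, 4))))
  recs <- slice_volume(normalize_intensity(vol), mask, "axial")
  labs <- lapply(recs, `[[`, "label")
  back <- restack_slices(labs, recs, dim(mask), label = TRUE)
  expect_identical(array(as.integer(back), dim(mask)), mask)
  # phantom mask through down/up resize: voxelwise agreement >= 99%
  ph <- small_phantom(seed = 6, shape = c(48, 48, 48), radius = c(4, 7))
  for (plane in c("axial", "coronal", "sagittal")) {
    recs <- slice_volume(normalize_intensity(ph$volume), ph$mask, plane)
    labs <- lapply(recs, `[[`, "label")
    back <- restack_slices(labs, recs, dim(ph$mask), label = TRUE)
    agree <- mean((back > 0.5) == (ph$mask > 0.5))
    expect_gte(agree, 0.99)
  }
})
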