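# Voxel- and lesion-wise evaluation metrics.

test_that("voxel metrics reproduce the set formulas on a worked example", {
  # |P| = 6, |G| = 4, |P & G| = 2
  pred <- array(0L, c(4, 4, 2)); gt <- array(0L, c(4, 4, 2))
  pred[1:6] <- 1L
  gt[5:8] <- 1L
  vm <- voxel_metrics(pred, gt)
  expect_equal(vm$dsc, 0.4)
  expect_equal(vm$jaccard, 0.25)
  expect_equal(vm$ppv, 1 / 3)
  expect_equal(vm$tpr, 0.5)
  expect_equal(vm$vd, 0.5)
})

test_that("identical masks give perfect scores, disjoint masks zero DSC", {
  m <- random_mask(c(5, 5, 5), 0.3)
  m[1] <- 1L   # nonempty
  vm <- voxel_metrics(m, m)
  expect_equal(vm$dsc, 1); expect_equal(vm$jaccard, 1)
  expect_equal(vm$ppv, 1); expect_equal(vm$tpr, 1); expect_equal(vm$vd, 0)
  a <- array(0L, c(4, 4, 4)); b <- array(0L, c(4, 4, 4))
  a[1] <- 1L; b[64] <- 1L
  expect_equal(voxel_metrics(a, b)$dsc, 0)
})

test_that("empty masks yield flagged sentinels, not silent zeros", {
  z <- array(0L, c(3, 3, 3))
  m <- z; m[14] <- 1L
  vm <- voxel_metrics(m, z)      # empty ground truth
  expect_true(is.na(vm$tpr)); expect_true(is.na(vm$vd))
  expect_true(all(c("tpr", "vd") %in% attr(vm, "undefined")))
  vm2 <- voxel_metrics(z, m)     # empty prediction
  expect_true(is.na(vm2$ppv))
  expect_true("ppv" %in% attr(vm2, "undefined"))
  lm <- lesion_metrics(z, z)
  expect_true(is.na(lm$ltpr)); expect_true(is.na(lm$lfpr))
})

test_that("connectivity controls corner/edge adjacency of components", {
  # two voxels sharing a face: one component at any connectivity
  a <- array(0L, c(4, 4, 4)); a[2, 2, 2] <- a[3, 2, 2] <- 1L
  for (cn in c(6, 18, 26))
    expect_equal(max(lesion_components(a, cn)), 1)
  # sharing only an edge: separate at 6, joined at 18/26
  b <- array(0L, c(4, 4, 4)); b[2, 2, 2] <- b[3, 3, 2] <- 1L
  expect_equal(max(lesion_components(b, 6)), 2)
  expect_equal(max(lesion_components(b, 18)), 1)
  # sharing only a corner: joined only at 26
  d <- array(0L, c(4, 4, 4)); d[2, 2, 2] <- d[3, 3, 3] <- 1L
  expect_equal(max(lesion_components(d, 6)), 2)
  expect_equal(max(lesion_components(d, 18)), 2)
  expect_equal(max(lesion_components(d, 26)), 1)
  # two isolated voxels
  e <- array(0L, c(4, 4, 4)); e[1, 1, 1] <- e[4, 4, 4] <- 1L
  expect_equal(max(lesion_components(e, 26)), 2)
})

test_that("lesion-wise rates follow the one-voxel-overlap rule", {
  # GT: two separated blobs; prediction covers one exactly plus a disjoint blob
  gt <- array(0L, c(10, 10, 3))
  gt[2:3, 2:3, 2] <- 1L
  gt[7:8, 7:8, 2] <- 1L
  pred <- array(0L, c(10, 10, 3))
  pred[2:3, 2:3, 2] <- 1L
  pred[7:8, 2:3, 2] <- 1L
  lm <- lesion_metrics(pred, gt)
  expect_equal(lm$ltpr, 0.5)
  expect_equal(lm$lfpr, 0.5)
  expect_equal(lm$n_gt_lesions, 2); expect_equal(lm$n_pred_lesions, 2)
  # perfect prediction
  lm2 <- lesion_metrics(gt, gt)
  expect_equal(lm2$ltpr, 1); expect_equal(lm2$lfpr, 0)
  # one predicted lesion spanning two GT lesions detects both
  bridge <- array(0L, c(10, 10, 3))
  bridge[2:8, 2:3, 2] <- 1L
  gt2 <- array(0L, c(10, 10, 3))
  gt2[2:3, 2:3, 2] <- 1L; gt2[7:8, 2:3, 2] <- 1L
  lm3 <- lesion_metrics(bridge, gt2)
  expect_equal(lm3$ltpr, 1)
  expect_equal(lm3$lfpr, 0)
})

test_that("metrics agree with brute-force enumeration on random masks", {
  set.seed(202)
  for (case in 1:120) {
    shape <- sample(4:12, 3, replace = TRUE)
    p <- stats::runif(1, 0.02, 0.4)
    pred <- random_mask(shape, p)
    gt <- random_mask(shape, p)
    conn <- sample(c(6, 18, 26), 1)
    vm <- voxel_metrics(pred, gt)
    ov <- oracle_voxel_metrics(pred, gt)
    expect_equal(vm[c("dsc", "jaccard", "ppv", "tpr", "vd")], ov)
    lm <- lesion_metrics(pred, gt, conn)
    ol <- oracle_lesion_metrics(pred, gt, conn)
    expect_equal(lm$ltpr, ol$ltpr)
    expect_equal(lm$lfpr, ol$lfpr)
    expect_equal(lm$n_gt_lesions, ol$n_gt_lesions)
    expect_equal(lm$n_pred_lesions, ol$n_pred_lesions)
  }
})

test_that("metric symmetries and bounds hold on random masks", {
  set.seed(77)
  for (case in 1:40) {
    pred <- random_mask(c(8, 8, 8), 0.2)
    gt <- random_mask(c(8, 8, 8), 0.2)
    a <- voxel_metrics(pred, gt); b <- voxel_metrics(gt, pred)
    expect_equal(a$dsc, b$dsc)
    expect_equal(a$ppv, b$tpr)
    ok <- !is.na(a$dsc) && !is.na(a$jaccard)
    if (ok) expect_lte(a$jaccard, a$dsc)
    for (f in c("dsc", "jaccard", "ppv", "tpr"))
      if (!is.na(a[[f]])) expect_true(a[[f]] >= 0 && a[[f]] <= 1)
    if (!is.na(a$vd)) expect_gte(a$vd, 0)
    if (!is.na(a$jaccard))
      expect_equal(a$jaccard, a$dsc / (2 - a$dsc))
  }
})

test_that("ltpr is monotone under adding predicted voxels", {
  set.seed(5)
  gt <- random_mask(c(8, 8, 8), 0.15)
  pred <- random_mask(c(8, 8, 8), 0.1)
  prev <- lesion_metrics(pred, gt)$ltpr
  zeros <- which(pred == 0)
  for (step in 1:5) {
    add <- sample(zeros, 10)
    pred[add] <- 1L
    zeros <- setdiff(zeros, add)
    cur <- lesion_metrics(pred, gt)$ltpr
    if (!is.na(prev) && !is.na(cur)) expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("challenge score matches a hand-computed composite", {
  mk <- function(dsc, ppv, ltpr, lfpr, np, ng) {
    r <- list(dsc = dsc, ppv = ppv, ltpr = ltpr, lfpr = lfpr,
              n_pred = np, n_gt = ng)
    class(r) <- "metrics_report"
    r
  }
  reports <- list(mk(0.8, 0.9, 0.7, 0.2, 120, 100),
                  mk(0.6, 0.7, 0.5, 0.4, 60, 80),
                  mk(0.9, 0.95, 0.9, 0.1, 210, 200))
  # independent hand evaluation of the documented weighting
  per <- c(0.8 / 8 + 0.9 / 8 + 0.7 / 4 + 0.8 / 4,
           0.6 / 8 + 0.7 / 8 + 0.5 / 4 + 0.6 / 4,
           0.9 / 8 + 0.95 / 8 + 0.9 / 4 + 0.9 / 4)
  corr <- stats::cor(c(120, 60, 210), c(100, 80, 200))
  expect_equal(challenge_score(reports), 100 * (mean(per) + corr / 4))
  # perfect components across scans -> 100
  perfect <- list(mk(1, 1, 1, 0, 50, 50), mk(1, 1, 1, 0, 80, 80))
  expect_equal(challenge_score(perfect), 100)
  # all components at the floor, anticorrelated volumes -> minimum
  floor_reports <- list(mk(0, 0, 0, 1, 10, 90), mk(0, 0, 0, 1, 90, 10))
  expect_equal(challenge_score(floor_reports), -25)
  # single scan: correlation dropped, weights renormalized
  expect_warning(sc1 <- challenge_score(list(mk(1, 1, 1, 0, 5, 5))))
  expect_equal(sc1, 100)
})

test_that("aggregate_reports returns means with bootstrap intervals", {
  set.seed(3)
  reports <- lapply(1:6, function(i) {
    evaluate_pair(random_mask(c(6, 6, 6), 0.3), random_mask(c(6, 6, 6), 0.3))
  })
  agg <- aggregate_reports(reports, n_boot = 200, seed = 2)
  expect_setequal(agg$metric,
                  c("dsc", "jaccard", "ppv", "tpr", "vd", "ltpr", "lfpr"))
  ok <- !is.na(agg$mean)
  expect_true(all(agg$lo[ok] <= agg$mean[ok] + 1e-12))
  expect_true(all(agg$hi[ok] >= agg$mean[ok] - 1e-12))
})
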