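# OKS, sigma estimation and AP/AR, cross-checked against an independent
# brute-force evaluator written directly from the precision-recall
# definitions.

make_gt <- function(image_id, ann_id, joints, box = c(0, 0, 60, 40)) {
  tibble::tibble(annotation_id = ann_id, image_id = image_id,
                 bbox = list(box), area = box[3] * box[4],
                 posture = "standing", score = 1, joints = list(joints))
}

rand_joints <- function(v = 2) {
  cbind(x = runif(10, 5, 55), y = runif(10, 5, 35), v = rep(v, 10))
}

# Independent evaluator: explicit loops, exhaustive best-match search and
# the literal interpolated-precision definition p(r) = max over recall >= r.
oracle_evaluate <- function(preds, gts, sigmas, thresholds) {
  ap <- numeric(length(thresholds))
  rc <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    records <- NULL
    for (img in unique(gts$image_id)) {
      dts <- preds[preds$image_id == img, ]
      dts <- dts[order(dts$score, decreasing = TRUE), ]
      gimg <- gts[gts$image_id == img, ]
      taken <- rep(FALSE, nrow(gimg))
      for (a in seq_len(nrow(dts))) {
        best <- 0; bi <- 0
        for (b in seq_len(nrow(gimg))) {
          if (taken[b]) next
          o <- oks(dts$joints[[a]], gimg$joints[[b]], gimg$area[b], sigmas)
          if (!is.na(o) && o >= t && o > best) { best <- o; bi <- b }
        }
        if (bi > 0) taken[bi] <- TRUE
        records <- rbind(records, c(dts$score[a], bi > 0))
      }
    }
    n_gt <- nrow(gts)
    if (is.null(records)) { ap[ti] <- 0; rc[ti] <- 0; next }
    records <- records[order(-records[, 1]), , drop = FALSE]
    tp <- cumsum(records[, 2])
    prec <- tp / seq_along(tp)
    rec <- tp / n_gt
    pr_at <- function(r) {
      keep <- rec >= r - 1e-12
      if (!any(keep)) 0 else max(prec[keep])
    }
    ap[ti] <- mean(vapply(seq(0, 1, 0.01), pr_at, numeric(1)))
    rc[ti] <- max(rec)
  }
  list(AP = mean(ap), AR = mean(rc), ap_by_threshold = ap)
}

test_that("OKS is exact on closed-form cases and respects its bounds", {
  set.seed(61)
  gt <- rand_joints()
  area <- 60 * 40
  expect_equal(oks(gt, gt, area), 1.0)
  # single labeled joint at the distance that makes the exponent -1
  one <- gt
  one[, 3] <- 0
  one[4, 3] <- 2
  k <- 2 * pig_sigmas()[4]
  d <- sqrt(2 * area * k^2)
  pred <- one
  pred[4, 1] <- one[4, 1] + d
  expect_equal(oks(pred, one, area), exp(-1), tolerance = 1e-12)
  # infinitely distant predictions score 0
  far <- gt
  far[, 1:2] <- far[, 1:2] + 1e9
  expect_equal(oks(far, gt, area), 0)
  # monotone non-increasing as any one distance grows
  vals <- vapply(seq(0, 30, by = 3), function(d) {
    p <- gt
    p[3, 1] <- p[3, 1] + d
    oks(p, gt, area)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-15))
  expect_true(all(vals >= 0 & vals <= 1))
  # unlabeled joints do not affect the score wherever they are claimed to be
  gt0 <- gt
  gt0[c(2, 5), 3] <- 0
  p1 <- gt; p2 <- gt
  p2[c(2, 5), 1:2] <- -500
  expect_equal(oks(p1, gt0, area), oks(p2, gt0, area))
  # no labeled joints: skipped with a warning
  none <- gt
  none[, 3] <- 0
  expect_warning(expect_true(is.na(oks(gt, none, area))), "no labeled joints")
})

test_that("sigma estimation recovers a planted annotation noise", {
  g <- generate_synthetic_pigs(synth_spec(n_images = 40L,
                                          animals_per_image = c(3L, 3L),
                                          seed = 19L))
  # identical re-annotation: all sigmas zero
  expect_true(all(estimate_sigmas(g$instances, g$instances) == 0))
  # planted per-axis normalized std 0.01, ~1200 doubly labeled joints
  pert <- perturb_annotations(g$instances, 0.01, seed = 5L)
  sig <- estimate_sigmas(g$instances, pert)
  n <- sum(vapply(g$instances$joints, function(j) sum(j[, 3] > 0), numeric(1)))
  expect_gte(n, 1000)
  mc_tol <- 4 * 0.01 / sqrt(2 * n / 10) # ~4 standard errors per joint
  expect_true(all(abs(sig - 0.01) < mc_tol))
  # joints never labeled twice come back missing
  g1 <- g$instances
  for (i in seq_len(nrow(g1))) g1$joints[[i]][3, 3] <- 0
  expect_message(s2 <- estimate_sigmas(g1, pert), "never doubly labeled")
  expect_true(is.na(s2[3]) && !is.na(s2[4]))
})

test_that("the packaged pig sigma vector is the double-annotation estimate", {
  s <- pig_sigmas()
  expect_length(s, 10)
  expect_true(all(s > 0))
  expect_identical(names(s), joint_names())
  expect_equal(unname(s[1]), 0.005322321731521584)
  expect_equal(unname(s[10]), 0.00422832022133345)
  # shoulders and hips are the least repeatable joints
  expect_true(min(s[c(3, 4, 7, 8)]) > max(s[c(1, 2, 5, 6, 9, 10)]))
})

test_that("perfect predictions give AP = AR = 1 and half-coverage gives recall 0.5", {
  set.seed(62)
  gts <- do.call(rbind, lapply(1:4, function(i) make_gt(i, i, rand_joints())))
  preds <- tibble::tibble(image_id = gts$image_id, joints = gts$joints,
                          score = runif(4, 0.5, 1))
  ev <- evaluate_keypoints(preds, gts)
  expect_equal(ev$AP, 1.0)
  expect_equal(ev$AR, 1.0)
  expect_true(all(ev$ap_by_threshold == 1))
  # half the instances unpredicted, the rest perfect
  ev2 <- evaluate_keypoints(preds[1:2, ], gts)
  expect_equal(ev2$recall_by_threshold, rep(0.5, 10))
  expect_equal(ev2$AR, 0.5)
  expect_equal(ev2$AP, 51 / 101, tolerance = 1e-12) # precision 1 up to r = 0.5
  # AP is the mean of the per-threshold APs and non-increasing in threshold
  set.seed(63)
  noisy <- preds
  for (i in 1:4) {
    j <- noisy$joints[[i]]
    j[, 1:2] <- j[, 1:2] + rnorm(20, sd = 0.4)
    noisy$joints[[i]] <- j
  }
  ev3 <- evaluate_keypoints(noisy, gts)
  expect_equal(ev3$AP, mean(ev3$ap_by_threshold))
  expect_true(all(diff(ev3$ap_by_threshold) <= 1e-12))
  expect_gte(ev3$AP50, ev3$AP)
  # empty ground truth: metrics undefined
  empty <- gts[0, ]
  expect_warning(ev4 <- evaluate_keypoints(preds, empty), "undefined")
  expect_true(is.na(ev4$AP))
})

test_that("evaluation matches the brute-force oracle on a 5-image fixture", {
  set.seed(64)
  gts <- do.call(rbind, lapply(1:5, function(i) {
    rbind(make_gt(i, 2 * i - 1, rand_joints()),
          make_gt(i, 2 * i, rand_joints(), box = c(10, 5, 40, 30)))
  }))
  # predictions: jittered copies with varying scores, one duplicate, one miss
  preds <- NULL
  for (r in seq_len(nrow(gts))) {
    if (r == 7) next # miss one instance entirely
    j <- gts$joints[[r]]
    j[, 1:2] <- j[, 1:2] + rnorm(20, sd = 0.15 * sqrt(gts$area[r]) *
                                   mean(pig_sigmas()))
    preds <- rbind(preds, tibble::tibble(image_id = gts$image_id[r],
                                         joints = list(j),
                                         score = runif(1, 0.3, 1)))
  }
  dup <- preds[3, ]
  dup$score <- dup$score * 0.5
  preds <- rbind(preds, dup)
  thr <- seq(0.5, 0.95, by = 0.05)
  ev <- evaluate_keypoints(preds, gts, sigmas = pig_sigmas(), thresholds = thr)
  orc <- oracle_evaluate(preds, gts, pig_sigmas(), thr)
  expect_equal(ev$ap_by_threshold, orc$ap_by_threshold, tolerance = 1e-10)
  expect_equal(ev$AP, orc$AP, tolerance = 1e-10)
  expect_equal(ev$AR, orc$AR, tolerance = 1e-10)
})
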