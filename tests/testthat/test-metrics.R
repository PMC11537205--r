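test_that("identical maps match perfectly", {
  lab <- draw_disks(60, 60, rbind(c(15, 15), c(40, 40), c(15, 45)), c(6, 8, 5))
  m <- match_instances(instance_map(lab), instance_map(lab))
  expect_equal(nrow(m$pairs), 3L)
  expect_true(all(m$pairs$iou == 1))
  expect_length(m$unmatched_pred, 0L)
  expect_length(m$unmatched_gt, 0L)
})

test_that("a prediction overlapping two labels takes the higher-IoU one", {
  gt <- matrix(0L, 20, 20)
  gt[5:14, 3:8] <- 1L    # 60 px
  gt[5:14, 12:17] <- 2L  # 60 px
  pred <- matrix(0L, 20, 20)
  pred[5:14, 4:12] <- 1L # overlaps gt1 by 50, gt2 by 10
  m <- match_instances(instance_map(pred), instance_map(gt))
  expect_equal(m$pairs$gt_id, 1L)
  expect_equal(m$unmatched_gt, 2L)
  iou1 <- 50 / (90 + 60 - 50)
  expect_equal(m$pairs$iou, iou1)
})

test_that("IoU exactly at the threshold is not a match", {
  # pred 2 px, gt 3 px, intersection 1 px: IoU = 1/4 exactly
  pred <- matrix(0L, 4, 6); pred[2, 2:3] <- 1L
  gt <- matrix(0L, 4, 6); gt[2, 3:5] <- 1L
  m <- match_instances(instance_map(pred), instance_map(gt), 0.25)
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(m$unmatched_pred, 1L)
  expect_equal(m$unmatched_gt, 1L)
  # a hair under the threshold does match
  m2 <- match_instances(instance_map(pred), instance_map(gt), 0.2499)
  expect_equal(nrow(m2$pairs), 1L)
})

test_that("matching respects cardinality and threshold monotonicity", {
  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    gt <- draw_disks(64, 64, cbind(runif(k, 10, 54), runif(k, 10, 54)),
                     runif(k, 4, 8))
    pred <- draw_disks(64, 64, cbind(runif(k, 10, 54), runif(k, 10, 54)),
                       runif(k, 4, 8))
    prev <- Inf
    for (thr in c(0.1, 0.3, 0.5, 0.7)) {
      m <- match_instances(instance_map(pred), instance_map(gt), thr)
      np <- length(unique(pred[pred > 0])); ng <- length(unique(gt[gt > 0]))
      expect_lte(nrow(m$pairs), min(np, ng))
      expect_lte(nrow(m$pairs), prev)
      prev <- nrow(m$pairs)
      expect_true(all(m$pairs$iou > thr))
      expect_equal(anyDuplicated(m$pairs$pred_id), 0L)
      expect_equal(anyDuplicated(m$pairs$gt_id), 0L)
    }
  }
})

test_that("mismatched shapes are a dimension error", {
  expect_error(match_instances(instance_map(matrix(0L, 3, 3)),
                               instance_map(matrix(0L, 4, 3))), "shape")
})

test_that("detection metrics follow the counting arithmetic", {
  lab <- draw_disks(40, 40, rbind(c(10, 10), c(30, 30)), c(5, 6))
  perfect <- match_instances(instance_map(lab), instance_map(lab))
  expect_equal(unname(detection_metrics(perfect)), rep(1, 4))
  fake <- structure(list(
    pairs = data.frame(pred_id = 1:3, gt_id = 1:3, iou = c(0.5, 0.6, 0.7)),
    unmatched_pred = 4L, unmatched_gt = c(5L, 6L), iou_threshold = 0.25),
    class = "match_result")
  det <- detection_metrics(fake)
  expect_equal(det[["precision"]], 0.75)
  expect_equal(det[["recall"]], 0.6)
  expect_equal(det[["f1"]], 2 / (1 / 0.75 + 1 / 0.6))
  expect_equal(det[["mean_iou"]], 0.6)
  empty_pred <- structure(list(
    pairs = data.frame(pred_id = integer(), gt_id = integer(), iou = numeric()),
    unmatched_pred = integer(), unmatched_gt = 1:3, iou_threshold = 0.25),
    class = "match_result")
  expect_warning(det0 <- detection_metrics(empty_pred), "precision")
  expect_equal(det0[["precision"]], 0)
  expect_equal(det0[["recall"]], 0)
})

test_that("classification metrics equal a hand tally on a 10-instance toy", {
  gt <- c("a", "a", "a", "a", "b", "b", "b", "c", "c", "c")
  pr <- c("a", "a", "b", "c", "b", "b", "a", "c", "c", "b")
  got <- classification_metrics(pr, gt)$per_class
  # hand-tallied confusion: a: TP2 FP1 FN2 TN5; b: TP2 FP2 FN1 TN5; c: TP2 FP1 FN1 TN6
  expect_equal(got$ppv, c(2 / 3, 2 / 4, 2 / 3))
  expect_equal(got$npv, c(5 / 7, 5 / 6, 6 / 7))
  expect_equal(got$prevalence, c(0.4, 0.3, 0.3))
  expect_equal(got$accuracy, c(0.7, 0.7, 0.8))
  perfect <- classification_metrics(gt, gt)$per_class
  expect_true(all(perfect$ppv == 1 & perfect$npv == 1))
})

test_that("a class absent from gt has zero prevalence and full NPV support", {
  got <- classification_metrics(c("a", "a"), c("a", "a"),
                                classes = c("a", "ghost"))$per_class
  g <- got[got$class == "ghost", ]
  expect_equal(g$prevalence, 0)
  expect_equal(g$npv, 1)   # TN = 2, FN = 0
  expect_error(classification_metrics("x", "a", classes = "a"), "unknown")
})

test_that("bounded metrics equal hand-computed values on a 20-instance set", {
  mapping <- class_mapping(c(helper_t = "lymphocyte", cytotoxic_t = "lymphocyte",
                             enterocyte = "epithelial"))
  fine_pred <- c(rep("helper_t", 6), rep("cytotoxic_t", 4), rep("enterocyte", 10))
  parent_gt <- c(rep("lymphocyte", 4), "epithelial", "epithelial",  # helper preds
                 "lymphocyte", "lymphocyte", "epithelial", "epithelial",
                 rep("epithelial", 8), "lymphocyte", "lymphocyte")
  got <- bounded_metrics(fine_pred, parent_gt, mapping)
  h <- got[got$class == "helper_t", ]
  # ppv_upper = 4/6; negatives: 14, definite TN (parent != lymphocyte) = 10,
  # ambiguous = 4 of which 2 predicted as the sibling cytotoxic_t
  expect_equal(h$ppv_upper, 4 / 6)
  expect_equal(h$npv_lower, 10 / 14)
  expect_equal(h$npv_upper, 12 / 14)
  e <- got[got$class == "enterocyte", ]
  expect_equal(e$ppv_upper, 8 / 10)
  # negatives 10: definite TN = 6 (lymphocyte gt), ambiguous 4, no sibling
  # predictions exist for enterocyte, so both bounds coincide
  expect_equal(e$npv_lower, 6 / 10)
  expect_equal(e$npv_upper, 6 / 10)
})

test_that("all-correct predictions give unit upper PPV bounds", {
  mapping <- class_mapping(c(a = "P", b = "Q"))
  got <- bounded_metrics(c("a", "a", "b"), c("P", "P", "Q"), mapping)
  expect_true(all(got$ppv_upper == 1))
  a <- got[got$class == "a", ]
  expect_equal(a$npv_lower, 1)   # the one negative has parent Q
})

test_that("prevalence-normalized PPV handles the documented cases", {
  expect_equal(prevalence_normalized_ppv(0.25, 0.25), 1)
  expect_equal(prevalence_normalized_ppv(0.43, 0.21), 0.43 / 0.21)
  expect_true(is.na(prevalence_normalized_ppv(0.5, 0)))
})

test_that("DQ+ follows the panoptic detection-quality arithmetic", {
  lab <- draw_disks(60, 60, rbind(c(12, 12), c(40, 40), c(12, 45), c(45, 12)),
                    c(5, 6, 5, 5))
  m <- match_instances(instance_map(lab), instance_map(lab))
  cls <- setNames(c("a", "a", "b", "b"), 1:4)
  got <- dq_plus(m, cls, cls)
  expect_true(all(got$dq_plus == 1))
  # constructed counts: class a with TP=2, FP=1, FN=1
  fake <- structure(list(
    pairs = data.frame(pred_id = c(1L, 2L, 5L), gt_id = c(1L, 2L, 5L),
                       iou = rep(0.8, 3)),
    unmatched_pred = 3L, unmatched_gt = 4L, iou_threshold = 0.25),
    class = "match_result")
  pred_cls <- setNames(c("a", "a", "a", "b"), c(1, 2, 3, 5))
  gt_cls <- setNames(c("a", "a", "a", "b"), c(1, 2, 4, 5))
  got2 <- dq_plus(fake, pred_cls, gt_cls)
  a <- got2[got2$class == "a", ]
  expect_equal(c(a$tp, a$fp, a$fn), c(2, 1, 1))
  expect_equal(a$dq_plus, 2 / (2 + 0.5 + 0.5))
})

test_that("parent-mode DQ+ dominates fine-mode DQ+ on refinements", {
  mapping <- class_mapping(c(a1 = "A", a2 = "A", b1 = "B"))
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(4:10, 1)
    gt_fine <- sample(c("a1", "a2", "b1"), n, replace = TRUE)
    pred_fine <- sample(c("a1", "a2", "b1"), n, replace = TRUE)
    matched <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.8, 0.2))
    ids <- seq_len(n)
    pairs <- data.frame(pred_id = ids[matched], gt_id = ids[matched],
                        iou = runif(sum(matched), 0.3, 1))
    m <- structure(list(pairs = pairs, unmatched_pred = ids[!matched],
                        unmatched_gt = ids[!matched], iou_threshold = 0.25),
                   class = "match_result")
    pred_cls <- setNames(pred_fine, ids)
    fine <- dq_plus(m, pred_cls, setNames(gt_fine, ids))
    parent <- dq_plus(m, pred_cls,
                      setNames(apply_class_mapping(gt_fine, mapping), ids),
                      parent_mode = TRUE, mapping = mapping)
    for (cl in c("a1", "a2", "b1")) {
      f <- fine$dq_plus[fine$class == cl]
      p <- parent$dq_plus[parent$class == cl]
      if (!is.na(f) && !is.na(p)) expect_gte(p, f)
    }
  }
})

test_that("the Friedman statistic handles no-signal and permuted input", {
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)   # identical treatments
  same <- matrix(5, 4, 3)
  got <- friedman_test(same)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  set.seed(9)
  x <- matrix(rnorm(20), 5, 4)
  a <- friedman_test(x)
  b <- friedman_test(x[, c(3, 1, 4, 2)])
  expect_equal(a$statistic, b$statistic)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(friedman_test(matrix(1, 1, 3)), "at least 2")
})

test_that("the Friedman statistic agrees with stats::friedman.test", {
  set.seed(17)
  for (i in 1:10) {
    x <- matrix(rnorm(25), 5, 5)   # continuous, tie-free
    got <- friedman_test(x)
    ref <- stats::friedman.test(x)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, unname(ref$p.value))
  }
})
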