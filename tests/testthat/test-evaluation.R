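test_that("confusion counts and metric formulas follow the voxel-wise definitions", {
  # perfect prediction of an N-voxel class
  truth <- array(FALSE, c(5, 5, 4)); truth[1:2, 1:2, 1] <- TRUE
  cc <- confusion(truth, truth)
  expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]),
                   c(tp = 4L, tn = 96L, fp = 0L, fn = 0L))

  m <- class_metrics(list(tp = 8, tn = 88, fp = 2, fn = 2))
  expect_equal(unname(m), c(0.8, 0.8, 0.8, 8 / 12, 0.96))

  # agreement with a brute-force voxel loop on random masks
  set.seed(10)
  for (trial in 1:5) {
    p <- array(runif(15^3) < 0.3, c(15, 15, 15))
    t <- array(runif(15^3) < 0.3, c(15, 15, 15))
    cc <- confusion(p, t)
    tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(p)) {
      if (p[i] && t[i]) tp <- tp + 1L
      else if (p[i]) fp <- fp + 1L
      else if (t[i]) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]),
                     c(tp = tp, tn = tn, fp = fp, fn = fn))
  }
})

test_that("Dice identities reproduce the worked-example specimen arithmetic", {
  # from precision/recall: P 0.98, R 0.78 -> Dice 0.87 at 2 decimals
  expect_equal(round_report(dice_from_pr(0.98, 0.78), 2), 0.87)
  # from Jaccard: J 0.82 -> Dice 0.90
  expect_equal(round_report(dice_from_jaccard(0.82), 2), 0.90)
  # internal identity at full precision
  for (j in seq(0.05, 0.95, by = 0.1))
    expect_equal(dice_from_jaccard(j), 2 * j / (1 + j), tolerance = 1e-15)
})

test_that("degenerate confusion counts give absent metrics, never zero", {
  m <- class_metrics(list(tp = 0, tn = 100, fp = 0, fn = 0))
  expect_true(is.na(m[["precision"]]))
  expect_true(is.na(m[["recall"]]))
  expect_true(is.na(m[["dice"]]))
  expect_equal(m[["accuracy"]], 1)
})

test_that("macro averages reproduce the worked-example summary rows", {
  # left pelvic specimens: precision rows 0.98, 0.98, 0.95 -> macro 0.97
  left <- data.frame(precision = c(0.98, 0.98, 0.95),
                     recall = c(0.78, 0.84, 0.82),
                     dice = c(0.87, 0.90, 0.88),
                     jaccard = c(0.77, 0.82, 0.79),
                     accuracy = c(1, 1, 1), support = c(1, 1, 1))
  mac <- aggregate_metrics(left, "macro")
  expect_equal(round_report(mac[["precision"]], 2), 0.97)
  expect_equal(round_report(mac[["recall"]], 2), 0.81)
  expect_equal(round_report(mac[["dice"]], 2), 0.88)
  expect_equal(round_report(mac[["jaccard"]], 2), 0.79)

  # right pelvic specimens: recall rows 0.72, 0.64, 0.72 -> macro 0.69
  right <- data.frame(precision = c(0.99, 0.99, 1.00),
                      recall = c(0.72, 0.64, 0.72),
                      dice = c(0.83, 0.78, 0.84),
                      jaccard = c(0.71, 0.64, 0.72),
                      accuracy = c(1, 1, 1), support = c(1, 1, 1))
  mac <- aggregate_metrics(right, "macro")
  expect_equal(round_report(mac[["precision"]], 2), 0.99)
  expect_equal(round_report(mac[["recall"]], 2), 0.69)
  expect_equal(round_report(mac[["jaccard"]], 2), 0.69)

  # equal supports make the weighted average equal the macro average
  expect_equal(aggregate_metrics(left, "weighted"),
               aggregate_metrics(left, "macro"))
})

test_that("component matching attributes predictions by maximal overlap", {
  d <- c(12, 12, 6)
  truth <- array(0L, d); truth[2:5, 2:5, 2:4] <- 1L; truth[8:11, 8:11, 2:4] <- 2L
  pred <- array(0L, d)
  pred[3:5, 3:5, 2:4] <- 1L   # overlaps truth 1 only
  tm <- label_mask(truth); pm <- label_mask(pred)
  mm <- match_components(pm, tm)
  expect_identical(mm$truth_label, 1L)

  # a blob overlapping truth 1 by more voxels than truth 2 maps to 1
  pred2 <- array(0L, d)
  pred2[2:5, 2:5, 2:3] <- 1L       # 32 voxels on truth 1
  pred2[8:9, 8:11, 2] <- 1L        # 8 voxels on truth 2 (same component label)
  mm2 <- match_components(label_mask(pred2), tm)
  expect_identical(mm2$truth_label, 1L)

  # disjoint blob maps to none
  pred3 <- array(0L, d); pred3[6:7, 6:7, 5] <- 3L
  mm3 <- match_components(label_mask(pred3), tm)
  expect_true(is.na(mm3$truth_label))

  # identical masks give the identity mapping
  mmi <- match_components(tm, tm)
  expect_identical(mmi$truth_label, mmi$pred_label)
})

test_that("a perfect prediction scores 1.00 everywhere", {
  d <- c(10, 10, 10)
  truth <- array(0L, d); truth[2:4, 2:4, 2:4] <- 1L; truth[6:9, 6:9, 6:9] <- 2L
  tm <- label_mask(truth)
  rep <- evaluate(tm, tm)
  cols <- c("precision", "recall", "dice", "jaccard", "accuracy")
  expect_true(all(rep$per_class[cols] == 1))
  expect_true(all(rep$aggregates[cols] == 1))
  expect_identical(rep$unmatched_fp, 0L)
})

test_that("the report satisfies its internal identities and symmetry", {
  ph <- generate_phantom(small_phantom_spec(seed = 10L))
  res <- segment_nodes(ph$ct, segmentation_config(
    clustering = clustering_config(seed = 0, subsample = 200000L)))
  rep <- evaluate(res$mask, ph$truth)
  # dice = 2J/(1+J) row-wise at full precision
  expect_equal(rep$per_class$dice, dice_from_jaccard(rep$per_class$jaccard),
               tolerance = 1e-12)
  expect_equal(rep$per_class$dice,
               dice_from_pr(rep$per_class$precision, rep$per_class$recall),
               tolerance = 1e-12)
  # dice/jaccard symmetric in pred <-> truth
  rev <- evaluate(ph$truth, res$mask)
  expect_equal(sort(rep$per_class$dice), sort(rev$per_class$dice),
               tolerance = 1e-12)
  # near-equal node volumes put weighted within 0.05 of macro
  ag <- rep$aggregates
  expect_lt(abs(ag$dice[ag$average == "weighted"] -
                  ag$dice[ag$average == "macro"]), 0.05)
  # micro accuracy equals pooled accuracy by construction
  pc <- rep$per_class
  pooled <- class_metrics(list(tp = sum(pc$tp), tn = sum(pc$tn) - rep$unmatched_fp,
                               fp = sum(pc$fp) + rep$unmatched_fp,
                               fn = sum(pc$fn)))
  expect_equal(ag$accuracy[ag$average == "micro"], pooled[["accuracy"]])
})

test_that("unmatched predicted components contribute pooled false positives", {
  d <- c(10, 10, 4)
  truth <- array(0L, d); truth[2:4, 2:4, 2] <- 1L
  pred <- truth; pred[7:8, 7:8, 3] <- 2L  # spurious disjoint component
  rep <- evaluate(label_mask(pred), label_mask(truth))
  expect_identical(rep$unmatched_fp, 4L)
  ag <- rep$aggregates
  expect_lt(ag$precision[ag$average == "micro"], 1)
  expect_equal(ag$precision[ag$average == "macro"], 1)  # class 1 itself is perfect
})

test_that("metrics CSV has per-class rows then the three aggregate rows", {
  d <- c(8, 8, 4)
  truth <- array(0L, d); truth[2:4, 2:4, 2] <- 1L
  rep <- evaluate(label_mask(truth), label_mask(truth))
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rep, f)
  tab <- read.csv(f)
  expect_identical(tab$row, c("1", "micro", "macro", "weighted"))
  expect_true(all(tab$dice == 1))
})
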