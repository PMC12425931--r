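# Segmentation metrics against exhaustive pixel-loop oracles, plus the
# paired t-test.

test_that("confusion counts match an exhaustive per-pixel loop on random masks", {
  set.seed(1)
  for (rep in 1:20) {
    pred <- random_mask(4, 4)
    gt <- random_mask(4, 4)
    cc <- confusion_counts(pred, gt)
    oc <- oracle_confusion(pred, gt)
    expect_identical(cc[c("tp", "fp", "tn", "fn")], oc[c("tp", "fp", "tn", "fn")])
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 16L)
  }
  expect_error(confusion_counts(random_mask(4, 4), random_mask(4, 5)), "shapes differ")
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("the four metrics reproduce their closed-form examples", {
  all_tp <- confusion_counts(matrix(1, 4, 4), matrix(1, 4, 4))
  expect_equal(all_tp$tp, 16L)
  expect_equal(gpa(all_tp), 1)
  expect_equal(dice(all_tp), 1)
  expect_equal(sensitivity(all_tp), 1)

  cc <- structure(list(tp = 3, fp = 2, tn = 9, fn = 2), class = "confusion_counts")
  expect_equal(gpa(cc), 0.75)
  expect_equal(dice(structure(list(tp = 3, fp = 1, tn = 0, fn = 1),
                               class = "confusion_counts")), 0.75)
  expect_equal(sensitivity(structure(list(tp = 3, fp = 0, tn = 0, fn = 1),
                                     class = "confusion_counts")), 0.75)
  # disjoint non-empty masks -> Dice 0
  p <- matrix(c(1, 0, 0, 0), 2, 2); g <- matrix(c(0, 1, 1, 1), 2, 2)
  expect_equal(dice(confusion_counts(p, g)), 0)
  # foreground absent from the reference -> sensitivity undefined
  expect_error(sensitivity(confusion_counts(p, matrix(0, 2, 2))), "no foreground")
})

test_that("mean IoU averages one-vs-rest IoU and matches the set-ops oracle", {
  expect_equal(miou_masks(matrix(1, 3, 3), matrix(1, 3, 3)), 1)
  set.seed(2)
  for (rep in 1:20) {
    pred <- random_mask(8, 8)
    gt <- random_mask(8, 8)
    ref <- mean(c(oracle_iou(pred, gt, 0), oracle_iou(pred, gt, 1)))
    expect_equal(miou_masks(pred, gt), ref, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under jointly flipping pred and gt", {
  set.seed(3)
  pred <- random_mask(6, 8); gt <- random_mask(6, 8)
  f <- function(m) m[, ncol(m):1]
  expect_equal(gpa(confusion_counts(pred, gt)), gpa(confusion_counts(f(pred), f(gt))))
  expect_equal(dice(confusion_counts(pred, gt)), dice(confusion_counts(f(pred), f(gt))))
  expect_equal(miou_masks(pred, gt), miou_masks(f(pred), f(gt)))
  expect_equal(sensitivity(confusion_counts(pred, gt)),
               sensitivity(confusion_counts(f(pred), f(gt))))
})

test_that("Dice and foreground IoU satisfy Dice = 2 IoU / (1 + IoU)", {
  set.seed(4)
  for (rep in 1:20) {
    pred <- random_mask(8, 8); gt <- random_mask(8, 8)
    iou <- oracle_iou(pred, gt, 1)
    expect_equal(dice(confusion_counts(pred, gt)), 2 * iou / (1 + iou),
                 tolerance = 1e-12)
  }
})

test_that("dataset evaluation aggregates per-image metrics as mean and sample sd in percent", {
  # one perfect image
  ev1 <- evaluate_dataset(list(matrix(1, 2, 2)), list(matrix(1, 2, 2)))
  expect_equal(ev1$summary$mean, rep(100, 4))
  expect_equal(ev1$summary$sd, rep(0, 4))
  # two images with Dice 0.8 and 1.0 -> mean 90, sd = sample sd of {80, 100}
  gt <- matrix(0L, 2, 4); gt[1, 1:2] <- 1L
  p1 <- gt; p1[1, 3] <- 1L            # tp=2 fp=1 fn=0 -> dice 0.8
  ev2 <- evaluate_dataset(list(p1, gt), list(gt, gt))
  d <- ev2$summary[ev2$summary$metric == "dice", ]
  expect_equal(d$mean, 90)
  expect_equal(d$sd, stats::sd(c(80, 100)))
  # random pairs match a per-image loop
  set.seed(5)
  preds <- lapply(1:6, function(i) random_mask(8, 8, 0.6))
  gts <- lapply(1:6, function(i) random_mask(8, 8, 0.6))
  ev <- evaluate_dataset(preds, gts)
  per_dice <- vapply(1:6, function(i) 100 * dice(confusion_counts(preds[[i]], gts[[i]])), 0)
  expect_equal(ev$per_image$dice, per_dice)
  expect_equal(ev$summary$mean[ev$summary$metric == "dice"], mean(per_dice))
  expect_error(evaluate_dataset(list(), list()), "invalid input")
})

test_that("metric reports round-trip through CSV and JSON", {
  set.seed(6)
  ev <- evaluate_dataset(lapply(1:3, function(i) random_mask(6, 6, 0.6)),
                         lapply(1:3, function(i) random_mask(6, 6, 0.6)))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metric_report(ev, csv, js)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 4L)  # 3 images + summary row
  expect_equal(tab$dice[4], mean(tab$dice[1:3]))
  parsed <- jsonlite::read_json(js)
  expect_setequal(names(parsed), c("gpa", "dice", "miou", "sensitivity"))
  expect_equal(parsed$dice$mean, ev$summary$mean[ev$summary$metric == "dice"])
})

test_that("paired t-test matches the textbook statistic and flags degenerate input", {
  # differences {1, 1, 1, -1}: mean 0.5, sd 1 -> t = 1 on 3 df
  a <- c(2, 3, 4, 5); b <- a - c(1, 1, 1, -1)
  expect_equal(paired_t_test(a, b), 2 * stats::pt(-1, df = 3), tolerance = 1e-12)
  expect_error(paired_t_test(a, a), "degenerate")
  expect_error(paired_t_test(1:3, 1:4), "invalid input")
  # large shift vs small noise is detected with power
  set.seed(7)
  x <- rnorm(20); y <- x + 5 + rnorm(20, sd = 0.1)
  expect_lt(paired_t_test(y, x), 0.05)
})

test_that("metric computations are pure (bit-identical across calls)", {
  set.seed(8)
  pred <- random_mask(16, 16); gt <- random_mask(16, 16)
  cc1 <- confusion_counts(pred, gt); cc2 <- confusion_counts(pred, gt)
  expect_identical(dice(cc1), dice(cc2))
  expect_identical(miou_masks(pred, gt), miou_masks(pred, gt))
})
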