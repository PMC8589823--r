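test_that("activity IoU matches set arithmetic and boundary conventions", {
  p <- segmentation(c("a", "b"), c(0, 10), c(10, 20))
  t <- segmentation(c("b", "a", "b"), c(0, 5, 15), c(5, 15, 20))
  expect_equal(activityIoU(p, t, "a"), 5 / 15)      # overlap 5, union 15
  expect_equal(activityIoU(p, t, "a"), activityIoU(t, p, "a"))  # symmetry

  same <- segmentation(c("a", "b"), c(0, 4), c(4, 9))
  for (act in c("a", "b")) expect_equal(activityIoU(same, same, act), 1)

  # absent from both -> 1; absent from one -> 0
  expect_equal(activityIoU(p, t, "zz"), 1)
  onlyP <- segmentation(c("a", "c"), c(0, 10), c(10, 20))
  expect_equal(activityIoU(onlyP, t, "c"), 0)
  expect_error(activityIoU(p, segmentation("a", 0, 19), "a"), "same frame")
})

test_that("meanIoU reports mean and spread as conventionally printed", {
  expect_equal(meanIoU(c(0.1, 0.4, 0.7)), c(mean = 0.4, sd = 0.3))
  expect_equal(meanIoU(rep(1, 5)), c(mean = 1, sd = 0))
  expect_equal(meanIoU(c(0.2, 0.8))[["mean"]], 0.5)
  expect_equal(meanIoU(0.7), c(mean = 0.7, sd = 0))
  expect_equal(meanIoU(c(0.1, 0.4, 0.7), sample = FALSE)[["sd"]],
               sqrt(mean((c(0.1, 0.4, 0.7) - 0.4)^2)))
  expect_error(meanIoU(numeric(0)), "nonempty")
})

test_that("model evaluation reports per-activity summaries and frame accuracy", {
  truth <- list(segmentation(c("a", "b"), c(0, 5), c(5, 10)),
                segmentation(c("b", "a"), c(0, 4), c(4, 10)))
  perfect <- truth
  rep1 <- evaluateSegmentations(perfect, truth, model = "exact")
  expect_equal(rep1@frameAccuracy, 1)
  expect_true(all(rep1@summary$mean_iou == 1))

  off <- list(segmentation(c("a", "b"), c(0, 7), c(7, 10)),
              segmentation(c("b", "a"), c(0, 4), c(4, 10)))
  rep2 <- evaluateSegmentations(off, truth, model = "off")
  expect_lt(rep2@frameAccuracy, 1)
  expect_lt(rep2@summary$mean_iou[rep2@summary$activity == "b"], 1)
  expect_error(evaluateSegmentations(off[1], truth), "same length")
})

test_that("compareModels yields identical rows for identical decodings", {
  truth <- list(segmentation(c("a", "b"), c(0, 5), c(5, 10)))
  dec <- list(m1 = truth, m2 = truth)
  cmp <- compareModels(dec, truth, activities = c("a", "b"))
  expect_equal(cmp$table$m1_mean_iou, cmp$table$m2_mean_iou)
  expect_equal(cmp$table$m1_mean_iou, c(1, 1))
  expect_error(compareModels(list(truth), truth), "named")
})

test_that("reports and plots are written to disk", {
  truth <- list(segmentation(c("a", "b"), c(0, 5), c(5, 10)))
  rep1 <- evaluateSegmentations(truth, truth, model = "m")
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeEvalReport(rep1, csv, js)
  expect_true(file.exists(csv) && file.exists(js))
  expect_equal(read.csv(csv)$mean_iou, c(1, 1))

  png <- tempfile(fileext = ".png")
  plotSegmentations(list(truth = truth, model = truth), png,
                    states = c("a", "b"))
  expect_gt(file.size(png), 0)
})
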