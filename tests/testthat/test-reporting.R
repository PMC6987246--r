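test_that("metric formulas evaluate exactly with undefined guards", {
  m <- compute_metrics(confusion_counts(9, 1, 89, 1))
  expect_identical(m$precision, 0.9)
  expect_identical(m$recall, 0.9)
  expect_identical(m$accuracy, 0.98)

  g <- compute_metrics(confusion_counts(0, 0, 10, 0))
  expect_true(is.na(g$precision))
  expect_true(is.na(g$recall))
  expect_identical(g$accuracy, 1)

  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "at least")
  expect_error(confusion_counts(-1, 0, 0, 1), "nonnegative")
})

test_that("metrics match a brute-force recount on random vectors", {
  set.seed(12)
  for (rep in 1:200) {
    case <- random_confusion_case(sample(5:60, 1))
    conf <- confusion_from_labels(case$truth, case$pred)
    oracle <- brute_force_metrics(case$truth, case$pred)
    expect_identical(conf$tp, oracle$tp)
    expect_identical(conf$fp, oracle$fp)
    expect_identical(conf$tn, oracle$tn)
    expect_identical(conf$fn, oracle$fn)
    m <- compute_metrics(conf)
    expect_identical(m$precision, oracle$precision)
    expect_identical(m$recall, oracle$recall)
    expect_identical(m$accuracy, oracle$accuracy)
  }
})

test_that("slice reports count, order and join back exactly", {
  rep <- random_slice_report(3, 2, 10, seed = 4)
  expect_identical(nrow(rep), 60L)
  expect_identical(rep, slice_report(rep))  # ordering is idempotent

  shuffled <- rep[sample(nrow(rep)), ]
  expect_identical(slice_report(shuffled), rep)

  key <- paste(rep$volume_id, rep$view, rep$gradient_index,
               rep$slice_index)
  expect_identical(anyDuplicated(key), 0L)
  dup <- rbind(rep, rep[1, ])
  expect_error(slice_report(dup), "duplicate")
  expect_error(slice_report(rep[, 1:3]), "lack")
})

test_that("volume flags apply the at-least-T rule per gradient volume", {
  df <- data.frame(volume_id = "v1", view = "axial", gradient_index = 1L,
                   slice_index = 1:10,
                   probability = c(rep(0.9, 4), rep(0.1, 6)),
                   label = c(rep("artifactual", 4),
                             rep("artifact_free", 6)),
                   stringsAsFactors = FALSE)
  rep <- slice_report(df)
  expect_true(volume_flags(rep, 3, "axial")$flagged)
  expect_true(volume_flags(rep, 4, "axial")$flagged)
  expect_false(volume_flags(rep, 5, "axial")$flagged)
  expect_error(volume_flags(rep, 0, "axial"), ">= 1")
})

test_that("flagged sets are nested as the threshold grows", {
  rep <- random_slice_report(15, 2, 12, seed = 9)
  prev <- NULL
  for (T in c(1, 3, 5, 7, 10)) {
    vf <- volume_flags(rep, T, "axial")
    flagged <- paste(vf$volume_id, vf$gradient_index)[vf$flagged]
    if (!is.null(prev)) expect_true(all(flagged %in% prev))
    prev <- flagged
  }
})

test_that("threshold sweeps show non-increasing recall", {
  rep <- random_slice_report(20, 2, 12, seed = 5)
  set.seed(6)
  truth_df <- rep
  truth_df$label <- ifelse(runif(nrow(rep)) < 0.4, "artifactual",
                           "artifact_free")
  truth <- volume_truth(truth_df, "axial")
  sw <- sweep_thresholds(rep, truth)
  expect_identical(sw$threshold, c(1L, 3L, 5L, 7L, 10L))
  rec <- sw$recall[!is.na(sw$recall)]
  expect_true(all(diff(rec) <= 0))

  # saturated case: every volume has >= 10 artifactual slices
  rep_all <- rep
  rep_all$label <- "artifactual"
  truth_all <- volume_truth(rep_all, "axial")
  sw_all <- sweep_thresholds(slice_report(rep_all), truth_all)
  expect_true(all(sw_all$recall == 1))
})

test_that("the workload estimator reproduces the printed reductions", {
  ax <- estimate_inspection_reduction(4163, 557, 0.94, 0.98)
  expect_identical(ax$reduction_percent_display, 86.05)
  sg <- estimate_inspection_reduction(4163, 138, 0.97, 0.95)
  expect_identical(sg$reduction_percent_display, 96.75)

  none <- estimate_inspection_reduction(100, 0, 0.9, 0.8)
  expect_identical(none$expected_flagged, 0)
  expect_identical(none$reduction_percent, 100)

  expect_error(estimate_inspection_reduction(100, 10, 0, 0.9), "precision")
  expect_error(estimate_inspection_reduction(100, 200, 0.9, 0.9),
               "exceed")
})

test_that("volume reports serialize to CSV and JSON", {
  rep <- random_slice_report(4, 1, 8, seed = 2)
  vf <- volume_flags(rep, 2, "axial")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_volume_report(vf, csv, js)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(vf))
  j <- jsonlite::read_json(js)
  expect_identical(j$n_flagged, sum(vf$flagged))
})
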