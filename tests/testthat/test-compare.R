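# gt: 80 spikes 100 ms apart; sorted: 40 matched + 20 unmatched
test_that("agreement score follows n_matches / (n_gt + n_sorted - n_matches)", {
  gt_t <- seq(0.1, by = 0.1, length.out = 80)
  srt_t <- c(gt_t[1:40], seq(20, by = 0.1, length.out = 20))
  gt <- spike_tbl(rep(1, 80), gt_t, duration = 30)
  srt <- spike_tbl(rep(1, 60), sort(srt_t), duration = 30)
  sc <- agreement_scores(gt, srt, delta_ms = 0.4)
  expect_equal(sc[1, 1], 40 / (80 + 60 - 40))

  expect_equal(agreement_scores(gt, gt)[1, 1], 1)
  far <- spike_tbl(rep(1, 80), gt_t + 50, duration = 200)
  gt2 <- as_spike_trains(data.frame(unit_id = rep(1, 80), time = gt_t), 200)
  expect_equal(agreement_scores(gt2, far)[1, 1], 0)
})

test_that("agreement is symmetric and invariant to sub-window global shifts", {
  a <- generate_independent(1, 8, 30, seed = 1)
  b_raw <- a$time[runif(nrow(a)) < 0.8]
  b <- spike_tbl(rep(1, length(b_raw)), b_raw, 30)
  expect_equal(agreement_scores(a, b)[1, 1], agreement_scores(b, a)[1, 1])
  shift <- 0.0003  # < 0.4 ms
  b2 <- spike_tbl(rep(1, length(b_raw)), b_raw + shift, 31)
  expect_equal(agreement_scores(a, b2)[1, 1], agreement_scores(a, b)[1, 1])
})

test_that("spike labels conserve counts and unit metrics follow the formulas", {
  set.seed(5)
  gt_t <- sort(runif(120, 0, 60))
  gt_t <- prune_refractory(gt_t, 4)
  keep <- runif(length(gt_t)) < 0.7
  srt_t <- sort(c(gt_t[keep], runif(10, 61, 70)))
  lab <- label_spikes(gt_t, srt_t, 0.4)
  n_tp <- sum(lab$gt == "TP")
  expect_equal(n_tp + sum(lab$gt == "FN"), length(gt_t))
  expect_equal(n_tp + sum(lab$sorted == "FP"), length(srt_t))
  expect_equal(sum(lab$sorted == "TP"), n_tp)

  m <- unit_metrics(lab)
  expect_equal(m$accuracy, m$n_tp / (m$n_tp + m$n_fp + m$n_fn))

  # hand arithmetic: TP 8, FP 1, FN 1
  lab2 <- list(gt = c(rep("TP", 8), "FN"), sorted = c(rep("TP", 8), "FP"))
  m2 <- unit_metrics(lab2)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$precision, 8 / 9)
  expect_equal(m2$recall, 8 / 9)

  lab3 <- list(gt = character(0), sorted = character(0))
  expect_warning(m3 <- unit_metrics(lab3), "denominator")
  expect_equal(c(m3$accuracy, m3$precision, m3$recall), c(0, 0, 0))
})

test_that("the oracle sorter yields perfect scores, metrics and classes", {
  gt <- generate_independent(6, 8, 30, seed = 3)
  cmp <- compare_sortings(gt, oracle_sorter(gt))
  expect_equal(diag(unclass(cmp$agreement)), setNames(rep(1, 6), 1:6))
  expect_true(all(cmp$metrics$accuracy == 1))
  expect_true(all(cmp$metrics$precision == 1))
  expect_true(all(cmp$metrics$recall == 1))
  expect_true(all(cmp$classes$class == "well_detected"))
  expect_true(all(cmp$gt_labels$label == "TP"))
  g <- glance(cmp)
  expect_equal(g$accuracy, 1)
  expect_equal(g$n_false_positive + g$n_redundant + g$n_overmerged, 0L)
})

test_that("sorted-unit classes follow the score/accuracy rules", {
  # unit 1: matched with accuracy exactly 0.8 (8 TP, 1 FN, 1 FP) -> well_detected
  gt1 <- seq(1, by = 1, length.out = 9)
  srt1 <- c(gt1[1:8], 50.5)
  # unit 2: pure noise far from gt -> false positive (score < 0.2)
  srt2 <- seq(100, by = 1, length.out = 30)
  # gt unit 3 and its good match (sorted 3); sorted 4 duplicates it -> redundant
  gt3 <- seq(200, by = 1, length.out = 20)
  srt3 <- gt3
  srt4 <- gt3[1:10]
  gt <- spike_tbl(rep(c(1, 3), c(9, 20)), c(gt1, gt3), duration = 300)
  srt <- spike_tbl(rep(1:4, c(9, 30, 20, 10)), c(srt1, srt2, srt3, srt4),
                   duration = 300)
  cmp <- compare_sortings(gt, srt)
  cls <- setNames(cmp$classes$class, cmp$classes$sorted_unit)
  expect_equal(unname(cls["1"]), "well_detected")
  expect_equal(cmp$metrics$accuracy[cmp$metrics$gt_unit == 1], 0.8)
  expect_equal(unname(cls["2"]), "false_positive")
  expect_equal(unname(cls["3"]), "well_detected")
  expect_equal(unname(cls["4"]), "redundant")
})

test_that("a sorted unit merging two ground-truth units is overmerged", {
  gtA <- seq(1, by = 1, length.out = 20)
  gtB <- seq(1.5, by = 1, length.out = 20)
  gt <- spike_tbl(rep(1:2, each = 20), c(gtA, gtB), duration = 60)
  merged <- spike_tbl(rep(1, 40), sort(c(gtA, gtB)), duration = 60)
  cmp <- compare_sortings(gt, merged)
  # scores with both gt units are 20/40 = 0.5 >= 0.2
  expect_equal(unclass(cmp$agreement)[, 1], c(`1` = 0.5, `2` = 0.5))
  expect_equal(cmp$classes$class, "overmerged")
})

test_that("comparison export writes schema-complete JSON and label tables", {
  gt <- generate_independent(3, 5, 10, seed = 2)
  cmp <- compare_sortings(gt, oracle_sorter(gt))
  stem <- withr::local_tempfile()
  write_comparison(cmp, stem)
  j <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_named(j, c("delta_ms", "assignment", "metrics", "classes", "summary"))
  labs <- read.delim(paste0(stem, "_labels.tsv"))
  expect_setequal(unique(labs$side), c("gt", "sorted"))
  expect_equal(sum(labs$side == "gt"), nrow(gt))
})
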