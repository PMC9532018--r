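probe32 <- make_probe()

test_that("the oracle sorter is an identity up to unit relabeling", {
  gt <- generate_independent(4, 5, 20, seed = 1)
  srt <- oracle_sorter(gt)
  expect_equal(srt$time, gt$time)
  empty <- as_spike_trains(data.frame(unit_id = integer(), time = numeric()), 5)
  expect_equal(nrow(oracle_sorter(empty)), 0)
})

test_that("the degraded oracle respects its model exactly in expectation", {
  gt <- generate_correlated(10, 10, 0.2, duration = 60, seed = 2)
  ev <- find_synchronous_events(gt)

  # no degradation -> identical to the oracle
  mod0 <- degradation_model(p_drop = 0, jitter_ms = 0, fp_rate = 0, seed = 3)
  expect_equal(degraded_oracle(gt, ev, mod0)$time, gt$time)

  # p = 1 -> zero recall wherever events exist
  mod1 <- degradation_model(p_drop = 1, seed = 3)
  deg1 <- degraded_oracle(gt, ev, mod1)
  cmp1 <- compare_sortings(gt, deg1)
  prof1 <- collision_recall_by_lag(ev, cmp1)
  expect_true(all(prof1$recall[prof1$n_events > 0] == 0))

  # reproducible under the model seed; expected deletions = sum of p
  mod <- degradation_model(p_drop = 0.3, seed = 4)
  degA <- degraded_oracle(gt, ev, mod)
  degB <- degraded_oracle(gt, ev, mod)
  expect_identical(degA$time, degB$time)
  probs <- attr(degA, "deletion_probs")
  n_del <- nrow(gt) - nrow(degA)
  exp_del <- sum(probs$p)
  expect_lt(abs(n_del - exp_del), 3 * sqrt(sum(probs$p * (1 - probs$p))))

  # invalid probabilities rejected
  expect_error(degradation_model(p_drop = 1.2), class = "spikecollide_config_error")
  badf <- degradation_model(p_drop = function(l, s) l * 0 + 2)
  expect_error(degraded_oracle(gt, ev, badf), class = "spikecollide_config_error")
})

test_that("jitter and false positives are applied as configured", {
  gt <- generate_independent(3, 5, 30, seed = 5)
  ev <- find_synchronous_events(gt)
  mod <- degradation_model(p_drop = 0, jitter_ms = 0.3, fp_rate = 2, seed = 6)
  deg <- degraded_oracle(gt, ev, mod)
  # about fp_rate * duration * n_units extra spikes
  extra <- nrow(deg) - nrow(gt)
  expect_lt(abs(extra - 2 * 30 * 3), 3 * sqrt(2 * 30 * 3))
  # times perturbed but close
  cmp <- compare_sortings(gt, deg)
  expect_gt(glance(cmp)$recall, 0.7)
  expect_false(any(gt$time %in% deg$time))
})

test_that("greedy matching recovers a single clean spike exactly", {
  ts <- synthesize_templates(probe32, 3, seed = 7, similarity_span = c(1, -1))
  st <- spike_tbl(2, 0.5, duration = 1)
  rec <- assemble_recording(ts, st, noise_sd = 0, amp_mod_sd = 0, seed = 1)
  srt <- greedy_tm_sorter(rec, ts)
  expect_equal(nrow(srt), 1)
  expect_equal(srt$unit_id, 2L)
  expect_lte(abs(srt$time - 0.5), 1 / ts$sampling_rate)
  expect_lt(abs(srt$amp - 1), 1e-6)
})

test_that("two orthogonal templates colliding at zero lag are both recovered", {
  # templates on disjoint channel groups -> cosine similarity ~ 0
  tlen <- 160
  k <- -exp(-((1:tlen) - 48)^2 / (2 * 6^2)) + 0.3 * exp(-((1:tlen) - 70)^2 / (2 * 20^2))
  w1 <- matrix(0, tlen, 8); w1[, 1:3] <- k %o% c(80, 50, 30)
  w2 <- matrix(0, tlen, 8); w2[, 6:8] <- k %o% c(40, 90, 55)
  ts <- manual_templates(list(w1, w2), probe = make_probe(8, 2, 18, 22))
  st <- spike_tbl(c(1, 2), c(0.4, 0.4), duration = 1)
  rec <- assemble_recording(ts, st, noise_sd = 0, amp_mod_sd = 0, seed = 1)
  srt <- greedy_tm_sorter(rec, ts)
  expect_equal(sort(srt$unit_id), c(1L, 2L))
  expect_true(all(abs(srt$time - 0.4) <= 2 / ts$sampling_rate))
})

test_that("noise-only recordings yield no spikes at a 5 SD threshold", {
  ts <- synthesize_templates(probe32, 3, seed = 8, similarity_span = c(1, -1))
  empty <- as_spike_trains(data.frame(unit_id = integer(), time = numeric()), 10)
  rec <- assemble_recording(ts, empty, noise_sd = 5, seed = 9, duration = 10)
  srt <- greedy_tm_sorter(rec, ts, threshold = 5)
  expect_equal(nrow(srt), 0)
})

test_that("noiseless, collision-free recordings are sorted perfectly", {
  ts <- synthesize_templates(probe32, 20, seed = 10)
  st <- generate_independent(20, 5, 30, seed = 11)
  ev <- find_synchronous_events(st)
  collided <- paste(c(ev$unit_i, ev$unit_j), c(ev$t_i, ev$t_j))
  keep <- !(paste(st$unit_id, st$time) %in% collided) &
    st$time > 0.01 & st$time < 30 - 0.01
  stc <- as_spike_trains(st[keep, c("unit_id", "time")], duration = 30)
  rec <- assemble_recording(ts, stc, noise_sd = 0, amp_mod_sd = 0.05, seed = 12)
  srt <- greedy_tm_sorter(rec, ts)
  cmp <- compare_sortings(stc, srt)
  expect_equal(glance(cmp)$accuracy, 1)
  expect_true(all(tidy(cmp)$accuracy == 1))
})
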