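test_that("synchronous events are detected with an inclusive 2 ms window", {
  gt <- spike_tbl(c(1, 2), c(0.1, 0.1015), duration = 1)
  ev <- find_synchronous_events(gt)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$lag_ms, 1.5)
  expect_equal(c(ev$unit_i, ev$unit_j), c(1L, 2L))

  gt2 <- spike_tbl(c(1, 2), c(0.1, 0.1025), duration = 1)
  expect_equal(nrow(find_synchronous_events(gt2)), 0)

  # three units firing together: all three pairwise events, emitted once
  gt3 <- spike_tbl(1:3, c(0.2, 0.2005, 0.201), duration = 1)
  ev3 <- find_synchronous_events(gt3)
  expect_equal(nrow(ev3), 3)
  expect_equal(anyDuplicated(ev3[, c("unit_i", "unit_j")]), 0)

  # brute force O(n^2) oracle on a random set
  set.seed(41)
  st <- generate_independent(4, 20, 20, seed = 13)
  ev4 <- find_synchronous_events(st, window_ms = 2)
  tl <- split(st$time, st$unit_id)
  n_bf <- 0
  for (a in 1:3) for (b in (a + 1):4) {
    n_bf <- n_bf + sum(abs(outer(tl[[a]], tl[[b]], "-")) <= 0.002)
  }
  expect_equal(nrow(ev4), n_bf)
})

test_that("collision profiles use exactly 11 bins over [-2, 2] ms", {
  gt <- generate_correlated(5, 10, 0.2, duration = 60, seed = 14)
  ev <- find_synchronous_events(gt)
  cmp <- compare_sortings(gt, oracle_sorter(gt))
  prof <- collision_recall_by_lag(ev, cmp)
  edges <- attr(prof, "bin_edges_ms")
  expect_equal(length(edges), 12)
  expect_equal(edges[1], -2)
  expect_equal(edges[12], 2)
  expect_equal(diff(edges)[1], 4 / 11)
  expect_equal(sort(unique(prof$bin)), 1:11)
  # oracle: recall 1 wherever events exist, NA (never silent 0) otherwise
  expect_true(all(prof$recall[prof$n_events > 0] == 1))
  expect_true(all(is.na(prof$recall[prof$n_events == 0])))
  expect_true(all(prof$n_spikes == 2L * prof$n_events))
})

test_that("deleting collided spikes drives binned recall to zero", {
  gt <- generate_correlated(5, 10, 0.2, duration = 60, seed = 15)
  ev <- find_synchronous_events(gt)
  collided <- unique(rbind(cbind(ev$unit_i, ev$t_i), cbind(ev$unit_j, ev$t_j)))
  key <- paste(gt$unit_id, gt$time)
  drop <- key %in% paste(collided[, 1], collided[, 2])
  srt <- as_spike_trains(gt[!drop, c("unit_id", "time")], duration = 60)
  cmp <- compare_sortings(gt, srt)
  prof <- collision_recall_by_lag(ev, cmp)
  expect_true(all(prof$recall[prof$n_events > 0] == 0))
})

test_that("random deletion of collided spikes is recovered within binomial error", {
  gt <- generate_correlated(10, 10, 0.2, duration = 120, seed = 16)
  ev <- find_synchronous_events(gt)
  mod <- degradation_model(p_drop = 0.3, seed = 17)
  deg <- degraded_oracle(gt, ev, mod)
  cmp <- compare_sortings(gt, deg)
  prof <- collision_recall_by_lag(ev, cmp)
  agg <- prof |>
    dplyr::group_by(bin) |>
    dplyr::summarise(n = sum(n_spikes), tp = sum(n_tp))
  se <- sqrt(0.3 * 0.7 / agg$n)
  # cluster correction: a spike's observations are correlated across events
  expect_true(all(abs(agg$tp / agg$n - 0.7) < 3 * 2 * se))
})

test_that("pooling by similarity is an event-weighted average with flagged bins", {
  # fabricate two per-pair profiles on the same grid
  edges <- seq(-2, 2, length.out = 12)
  centers <- (edges[-1] + edges[-12]) / 2
  mk <- function(ui, uj, n_ev, n_tp) {
    tibble::tibble(unit_i = ui, unit_j = uj, bin = 1:11, lag_ms = centers,
                   n_events = n_ev, n_spikes = 2L * n_ev, n_tp = n_tp,
                   recall = ifelse(n_ev > 0, n_tp / (2 * n_ev), NA_real_))
  }
  # pair (1,2): recall 1 with 10 events/bin; pair (3,4): recall 0 with 30
  prof <- dplyr::bind_rows(mk(1, 2, 10L, 20L), mk(3, 4, 30L, 0L))
  attr(prof, "bin_edges_ms") <- edges
  class(prof) <- c("collision_profile", class(prof))
  sim <- manual_similarity(diag(4) * 0 + 0.5 + diag(4) * 0.5)

  pooled <- pool_profiles_by_similarity(prof, sim, seq(0, 1, by = 0.5))
  # both pairs in similarity bin [0.5, 1]: weighted recall = 20/80 = 0.25
  expect_true(all(abs(pooled$recall - 0.25) < 1e-12))
  expect_true(all(pooled$n_spikes == 80L))

  # identical recall pools to itself
  prof_r <- dplyr::bind_rows(mk(1, 2, 10L, 12L), mk(3, 4, 30L, 36L))
  attr(prof_r, "bin_edges_ms") <- edges
  class(prof_r) <- c("collision_profile", class(prof_r))
  pooled_r <- pool_profiles_by_similarity(prof_r, sim, seq(0, 1, by = 0.5))
  expect_true(all(abs(pooled_r$recall - 0.6) < 1e-12))

  # pooled recall bounded by constituents
  prof_m <- dplyr::bind_rows(mk(1, 2, 10L, 6L), mk(3, 4, 10L, 16L))
  attr(prof_m, "bin_edges_ms") <- edges
  class(prof_m) <- c("collision_profile", class(prof_m))
  pooled_m <- pool_profiles_by_similarity(prof_m, sim, seq(0, 1, by = 0.5))
  expect_true(all(pooled_m$recall >= 0.3 - 1e-12 & pooled_m$recall <= 0.8 + 1e-12))
})

test_that("recall vs similarity integrates the lag profile event-weighted", {
  edges <- seq(-2, 2, length.out = 12)
  centers <- (edges[-1] + edges[-12]) / 2
  # recall 1 in 10 bins, 0 in one bin, equal event counts -> 10/11
  prof <- tibble::tibble(
    unit_i = 1, unit_j = 2, bin = 1:11, lag_ms = centers,
    n_events = 5L, n_spikes = 10L,
    n_tp = c(rep(10L, 10), 0L),
    recall = c(rep(1, 10), 0)
  )
  attr(prof, "bin_edges_ms") <- edges
  class(prof) <- c("collision_profile", class(prof))
  sim <- manual_similarity(matrix(c(1, 0.9, 0.9, 1), 2))
  out <- collision_recall_by_similarity(prof, sim)
  expect_equal(out$recall, 10 / 11)

  # uniform recall r integrates to r; symmetrization keeps it
  prof$n_tp <- rep(6L, 11)
  prof$recall <- 0.6
  out2 <- collision_recall_by_similarity(prof, sim)
  expect_equal(out2$recall, 0.6)
  pooled <- pool_profiles_by_similarity(prof, sim)
  symm <- symmetrize_profile(pooled)
  expect_equal(nrow(symm), 6)
  expect_true(all(abs(symm$recall - 0.6) < 1e-12))
})
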