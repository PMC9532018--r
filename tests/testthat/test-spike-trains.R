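test_that("refractory pruning follows the sequential keep-the-earlier scan", {
  expect_equal(prune_refractory(c(0, 0.003, 0.010), 4), c(0, 0.010))
  expect_equal(prune_refractory(c(0, 0.003, 0.006), 4), c(0, 0.006))
  valid <- c(0, 0.005, 0.011, 0.020)
  expect_equal(prune_refractory(valid, 4), valid)
  expect_equal(prune_refractory(numeric(0), 4), numeric(0))
  expect_error(prune_refractory(c(0.01, 0), 4), class = "spikecollide_config_error")

  # property: equals the reference sequential scan on random trains,
  # including dense ones with long violation runs
  set.seed(99)
  for (i in 1:200) {
    n <- sample(0:60, 1)
    tt <- sort(runif(n, 0, 0.2))
    r <- sample(c(1, 2, 4, 8), 1)
    got <- prune_refractory(tt, r)
    expect_equal(got, seq_prune(tt, r))
    if (length(got) > 1) expect_gte(min(diff(got)), r / 1000 - 1e-12)
    expect_true(all(got %in% tt))
    expect_lte(length(got), length(tt))
  }
})

test_that("independent trains hit the nominal rate and refractory period", {
  st <- generate_independent(8, 5, 120, refractory_ms = 4, seed = 1)
  expect_s3_class(st, "spike_trains")
  # empirical rate close to nominal: 3 SE of the pooled Poisson count
  n <- nrow(st)
  expect_lt(abs(n / (8 * 120) - 5), 3 * sqrt(5 / (8 * 120)))
  isi <- unlist(lapply(split(st$time, st$unit_id), diff))
  expect_gte(min(isi), 0.004 - 1e-12)
  expect_true(all(st$time >= 0 & st$time <= 120))

  # determinism
  st2 <- generate_independent(8, 5, 120, refractory_ms = 4, seed = 1)
  expect_identical(st, st2)
})

test_that("degenerate and infeasible train configurations are handled", {
  expect_warning(st0 <- generate_independent(3, 5, 0), "zero duration")
  expect_equal(nrow(st0), 0)
  expect_error(generate_independent(2, 300, 10, refractory_ms = 4),
               class = "spikecollide_config_error")
  expect_error(generate_correlated(2, 5, 1.0, duration = 10),
               class = "spikecollide_config_error")
  expect_error(generate_correlated(2, 5, -0.1, duration = 10),
               class = "spikecollide_config_error")
})

test_that("independent trains have flat average cross-correlograms", {
  st <- generate_independent(2, 5, 600, seed = 4)
  cg <- compute_correlograms(st, bin_ms = 2, window_ms = 40)
  cc <- cg$counts[1, 2, ]
  # Poisson oracle: per-bin expected count r1*r2*bin*T, SD ~ sqrt(mean)
  mu <- mean(cc)
  expect_true(all(abs(cc - mu) < 4 * sqrt(mu)))
})

test_that("mixture process injects a Gaussian central excess matching the correlation", {
  rate <- 10; corr <- 0.2; dur <- 300
  st <- generate_correlated(10, rate, corr, jitter_ms = 0.5, duration = dur, seed = 8)
  # rate recovery
  expect_lt(abs(nrow(st) / (10 * dur) / rate - 1), 0.02)

  cg <- compute_correlograms(st, bin_ms = 0.5, window_ms = 20)
  n_pairs <- 10 * 9 / 2
  avg <- rep(0, dim(cg$counts)[3])
  for (i in 1:9) for (j in (i + 1):10) avg <- avg + cg$counts[i, j, ]
  avg <- avg / n_pairs
  centers <- (cg$bin_edges_ms[-1] + cg$bin_edges_ms[-length(cg$bin_edges_ms)]) / 2
  central <- abs(centers) <= 2
  baseline <- mean(avg[!central])
  excess <- sum(avg[central] - baseline)

  # oracle: shared mother spikes per pair = corr^2 * rate * T (jitter keeps
  # essentially all coincidences inside +/-2 ms); refractory pruning removes
  # a few percent, so compare at 3 SE of the per-pair count spread
  expected <- corr^2 * rate * dur
  expect_lt(abs(excess - expected), 3 * sqrt(expected / n_pairs) + 0.1 * expected)

  # monotonicity across correlation levels at fixed rate
  excess_at <- function(c_level, seed) {
    stx <- if (c_level > 0) {
      generate_correlated(10, rate, c_level, duration = dur, seed = seed)
    } else {
      generate_independent(10, rate, dur, seed = seed)
    }
    cgx <- compute_correlograms(stx, bin_ms = 0.5, window_ms = 20)
    a <- rep(0, dim(cgx$counts)[3])
    for (i in 1:9) for (j in (i + 1):10) a <- a + cgx$counts[i, j, ]
    a <- a / n_pairs
    sum(a[central] - mean(a[!central]))
  }
  e0 <- excess_at(0, 21); e1 <- excess_at(0.1, 22); e2 <- excess_at(0.2, 23)
  expect_lt(e0, e1)
  expect_lt(e1, e2)
})

test_that("zero correlation reduces to the independent generator", {
  a <- generate_correlated(4, 5, 0, duration = 60, seed = 9)
  b <- generate_independent(4, 5, 60, seed = 9)
  expect_equal(a$time, b$time)
  expect_identical(attr(a, "nominal_correlation"), 0)
  # determinism of the correlated path
  x <- generate_correlated(4, 8, 0.15, duration = 60, seed = 10)
  y <- generate_correlated(4, 8, 0.15, duration = 60, seed = 10)
  expect_identical(x, y)
})

test_that("spike train table round trips through TSV + sidecar", {
  st <- generate_correlated(3, 6, 0.1, duration = 30, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spike_trains(st, f)
  st2 <- read_spike_trains(f)
  expect_equal(st2$unit_id, st$unit_id)
  expect_equal(st2$time, st$time)
  expect_equal(attr(st2, "duration"), 30)
  expect_equal(attr(st2, "nominal_rate"), 6)
  expect_equal(attr(st2, "nominal_correlation"), 0.1)
})
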