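probe8 <- make_probe(8, 2, 18, 22)
tset <- synthesize_templates(probe8, 3, seed = 2, similarity_span = c(1, -1))

test_that("a single spike with no noise reproduces the template exactly", {
  st <- spike_tbl(1, 0.5, duration = 1)
  rec <- assemble_recording(tset, st, noise_sd = 0, amp_mod_sd = 0, seed = 1)
  tr <- get_traces(rec)
  pk <- spikecollide:::template_peak_index(tset)[1]
  smp <- round(0.5 * tset$sampling_rate) + 1
  tlen <- dim(tset$waveforms)[2]
  rows <- (smp - pk + 1):(smp - pk + tlen)
  expect_equal(tr[rows, ], matrix(tset$waveforms[1, , ], tlen), tolerance = 1e-12)
  # everything else is silent
  tr[rows, ] <- 0
  expect_equal(max(abs(tr)), 0)
})

test_that("simultaneous spikes superpose linearly", {
  st <- spike_tbl(c(1, 2), c(0.3, 0.3), duration = 1)
  rec <- assemble_recording(tset, st, noise_sd = 0, amp_mod_sd = 0, seed = 1)
  tr <- get_traces(rec)
  r1 <- get_traces(assemble_recording(tset, spike_tbl(1, 0.3, 1), 0, 0, seed = 1))
  r2 <- get_traces(assemble_recording(tset, spike_tbl(2, 0.3, 1), 0, 0, seed = 1))
  expect_equal(tr, r1 + r2, tolerance = 1e-12)
})

test_that("noise-only recordings have the configured SD, white across channels", {
  st <- as_spike_trains(data.frame(unit_id = integer(), time = numeric()),
                        duration = 2)
  rec <- assemble_recording(tset, st, noise_sd = 5, seed = 3, duration = 2)
  tr <- get_traces(rec)
  n <- nrow(tr)
  sds <- apply(tr, 2, sd)
  expect_true(all(abs(sds - 5) < 3 * 5 / sqrt(2 * n)))
  cors <- cor(tr)
  off <- cors[upper.tri(cors)]
  expect_true(all(abs(off) < 3 / sqrt(n)))
})

test_that("trace generation is deterministic and chunk-consistent", {
  st <- generate_independent(3, 5, 12, seed = 4)
  rec1 <- assemble_recording(tset, st, noise_sd = 5, seed = 9)
  rec2 <- assemble_recording(tset, st, noise_sd = 5, seed = 9)
  expect_identical(get_traces(rec1, 1, 5000), get_traces(rec2, 1, 5000))
  # a range straddling a chunk boundary equals the stitched per-chunk reads
  cs <- rec1$chunk_samples
  a <- get_traces(rec1, cs - 99, cs + 100)
  b <- rbind(get_traces(rec1, cs - 99, cs), get_traces(rec1, cs + 1, cs + 100))
  expect_identical(a, b)
  rec3 <- assemble_recording(tset, st, noise_sd = 5, seed = 10)
  expect_false(identical(get_traces(rec1, 1, 1000), get_traces(rec3, 1, 1000)))
})

test_that("recordings are linear over disjoint unit subsets", {
  stA <- generate_independent(2, 5, 6, seed = 5)
  stB0 <- generate_independent(3, 5, 6, seed = 6)
  stB <- spike_tbl(stB0$unit_id[stB0$unit_id == 3], stB0$time[stB0$unit_id == 3], 6)
  stAB <- spike_tbl(c(stA$unit_id, stB$unit_id), c(stA$time, stB$time), 6)
  tr_ab <- get_traces(assemble_recording(tset, stAB, 0, 0, seed = 1))
  tr_a <- get_traces(assemble_recording(tset, stA, 0, 0, seed = 1, duration = 6))
  tr_b <- get_traces(assemble_recording(tset, stB, 0, 0, seed = 1, duration = 6))
  expect_equal(tr_ab, tr_a + tr_b, tolerance = 1e-12)
})

test_that("spikes at the recording edge truncate instead of erroring", {
  st <- spike_tbl(1, 0.9999, duration = 1)
  rec <- assemble_recording(tset, st, noise_sd = 0, amp_mod_sd = 0, seed = 1)
  tr <- get_traces(rec)
  expect_equal(nrow(tr), 32000)
  expect_gt(max(abs(tr)), 0)
  # unit id not present in the template set errors
  bad <- spike_tbl(9, 0.5, duration = 1)
  expect_error(assemble_recording(tset, bad, 0, 0, seed = 1), "unit ids")
})

test_that("noise estimation is robust: MAD on noise, zeros and noise + spikes", {
  empty <- as_spike_trains(data.frame(unit_id = integer(), time = numeric()),
                           duration = 4)
  rec <- assemble_recording(tset, empty, noise_sd = 5, seed = 2, duration = 4)
  est <- estimate_noise(rec)
  expect_true(all(abs(est - 5) / 5 < 0.05))

  rec0 <- assemble_recording(tset, empty, noise_sd = 0, seed = 2, duration = 4)
  expect_equal(estimate_noise(rec0), rep(0, 8))

  # sparse spikes at 5 Hz on top of 5 uV noise: estimate within 10%
  probe <- make_probe()
  ts20 <- synthesize_templates(probe, 5, seed = 12, similarity_span = c(1, -1))
  st <- generate_independent(5, 5, 10, seed = 3)
  rec2 <- assemble_recording(ts20, st, noise_sd = 5, seed = 4)
  est2 <- estimate_noise(rec2)
  expect_true(all(abs(est2 - 5) / 5 < 0.10))
})

test_that("raw binary recording round trips bit-exactly with sidecar metadata", {
  st <- generate_independent(3, 5, 3, seed = 7)
  rec <- assemble_recording(tset, st, noise_sd = 5, seed = 8)
  f <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec, f)
  rec2 <- read_recording(f)
  expect_equal(rec2$sampling_rate, rec$sampling_rate)
  expect_equal(rec2$n_samples, rec$n_samples)
  expect_equal(rec2$n_channels, rec$n_channels)
  expect_equal(rec2$probe$x, rec$probe$x)
  f2 <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec2, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
  # float32 quantization only
  expect_lt(max(abs(get_traces(rec2, 1, 1000) - get_traces(rec, 1, 1000))), 1e-3)
})
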