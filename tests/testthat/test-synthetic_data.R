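glob_coupling <- function(m, g) {
  k <- matrix(g, m, m); diag(k) <- 0
  k
}

one_segment_sim <- function(m, g, freqs, dur = 6, sigma = 0, obs = 0,
                            fs = 250, seed = 5) {
  seg <- schedule_segment(0, dur, 1L, glob_coupling(m, g), freqs,
                          phase_noise_sd = sigma, obs_noise_sd = obs)
  simulate_recording(coupling_schedule(list(seg)), fs = fs, seed = seed)
}

median_offdiag_lambda <- function(rec, skip_s = 2) {
  conn <- sliding_connectivity(analytic_phase(rec))
  keep <- conn$window_centers_s >= skip_s
  mats <- conn$matrices[, , keep, drop = FALSE]
  median(apply(mats, 3, function(m) m[upper.tri(m)]))
}

test_that("uncoupled identical oscillators stay perfectly phase locked", {
  sim <- one_segment_sim(4, 0, rep(10, 4))
  conn <- sliding_connectivity(analytic_phase(sim$recording))
  expect_true(all(conn$matrices > 1 - 1e-6))
})

test_that("coupling above threshold locks, detuning without coupling does not", {
  # uncoupled, detuned by >= 1 Hz between neighbours: no locking
  weak <- one_segment_sim(8, 0, seq(9, 16, 1), sigma = 0.5, obs = 0.05)
  # pairwise coupling 2 (total pull 14 rad/s) against a 1-Hz spread: locks
  strong <- one_segment_sim(8, 2, seq(9, 10, length.out = 8), sigma = 0.5,
                            obs = 0.05)
  lam_w <- median_offdiag_lambda(weak$recording)
  lam_s <- median_offdiag_lambda(strong$recording)
  expect_gte(lam_s, 0.8)              # Kuramoto locking above critical
  expect_gte(lam_s - lam_w, 0.3)      # clear separation of regimes
})

test_that("median coherence is non-decreasing in global coupling gain", {
  freqs <- seq(9, 13, length.out = 6)
  for (seed in c(2, 9)) {
    lams <- vapply(c(0, 0.5, 1, 2), function(g) {
      median_offdiag_lambda(one_segment_sim(6, g, freqs, sigma = 0.3,
                                            obs = 0.05,
                                            seed = seed)$recording)
    }, 0)
    expect_true(all(diff(lams) > -0.05))
  }
})

test_that("simulation is deterministic in the seed and spares the caller RNG", {
  a <- small_fixture(seed = 4)
  b <- small_fixture(seed = 4)
  expect_identical(a$recording$data, b$recording$data)
  expect_false(identical(a$recording$data, small_fixture(seed = 5)$recording$data))

  set.seed(123); before <- rnorm(5)
  set.seed(123); invisible(small_fixture(seed = 4)); after <- rnorm(5)
  expect_identical(before, after)
})

test_that("the simulator validates rate and schedule consistency", {
  freqs <- rep(10, 3)
  seg <- schedule_segment(0, 1, 1L, glob_coupling(3, 0), freqs)
  expect_error(simulate_recording(coupling_schedule(list(seg)), fs = 30),
               "4 \\* max frequency")
  seg2 <- schedule_segment(2, 3, 1L, glob_coupling(3, 0), freqs)
  expect_error(coupling_schedule(list(seg, seg2)), "tile")
  expect_error(schedule_segment(0, 1, 1L, matrix(1, 3, 3), freqs),
               "zero-diagonal")
  asym <- glob_coupling(3, 1); asym[1, 2] <- 2
  expect_error(schedule_segment(0, 1, 1L, asym, freqs), "symmetric")
})

test_that("the seizure fixture plants the advertised structure", {
  sim <- small_fixture(seed = 2)
  rec <- sim$recording
  expect_equal(rec$onset_s, 8)
  expect_equal(rec$termination_s, 16)
  seg <- segment_periods(rec)
  deg <- degree_vectors(sliding_connectivity(analytic_phase(rec)))
  mps <- mean_phase_synchronization(deg)
  summ <- summarize_periods(mps, seg)
  s4 <- summ$mean_ps[summ$period == "S4"]
  expect_true(all(s4 > summ$mean_ps[summ$period %in%
                                      c("preS", "S1", "S2", "S3")]))

  # planted labels align with the schedule within one window step
  pl <- planted_states(sim$ground_truth, deg$window_centers_s)
  sched_changes <- with(sim$ground_truth$segments,
                        start_s[-1][diff(state_id) != 0])
  lab_changes <- pl$window_center_s[which(diff(pl$state_id) != 0) + 1]
  for (tc in lab_changes) {
    expect_lte(min(abs(sched_changes - tc)), 0.5 + 1e-9)
  }
  # boundary-straddling windows are flagged
  expect_true(all(pl$ambiguous[which(diff(pl$state_id) != 0)]))
})

test_that("fixtures round-trip through the plain-text format", {
  sim <- small_fixture(seed = 3)
  dir <- withr::local_tempdir()
  files <- write_fixture(sim, dir)
  expect_true(all(file.exists(files)))
  back <- read_recording(files[["recording"]])
  expect_equal(back$onset_s, sim$recording$onset_s)
  expect_equal(back$data, sim$recording$data, tolerance = 1e-6)
  gt <- jsonlite::read_json(files[["ground_truth"]], simplifyVector = TRUE)
  expect_equal(gt$planted_K, 5)
  expect_equal(nrow(gt$segments), nrow(sim$ground_truth$segments))
})
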