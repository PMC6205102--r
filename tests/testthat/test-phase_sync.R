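test_that("analytic phase tracks sinusoid frequency and quadrature", {
  fs <- 500
  rec <- sine_recording(10, fs = fs, dur_s = 4)
  ph <- analytic_phase(rec)
  inc <- diff(ph$phases[1, ])
  inc <- inc[ph$valid[-1] & ph$valid[-length(ph$valid)]]
  inc <- (inc + pi) %% (2 * pi) - pi  # unwrap single-step increments
  expect_lt(max(abs(inc - 2 * pi * 10 / fs)) / (2 * pi * 10 / fs), 0.01)

  # sin lags cos by pi/2
  t <- (0:1999) / fs
  both <- new_recording(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)),
                        fs = fs)
  ph2 <- analytic_phase(both)
  lag <- ph2$phases[1, ph2$valid] - ph2$phases[2, ph2$valid]
  lag <- (lag + pi) %% (2 * pi) - pi
  expect_equal(median(lag), pi / 2, tolerance = 1e-3)
})

test_that("analytic phase is bounded on noise and rejects flat channels", {
  ph <- analytic_phase(noise_recording(m = 3, dur_s = 2))
  expect_true(all(is.finite(ph$phases)))
  expect_true(all(abs(ph$phases) <= pi))

  rec <- noise_recording(m = 3, dur_s = 2)
  rec$data[2, ] <- 0.7
  expect_error(analytic_phase(rec), "ch2")
})

test_that("mean phase coherence hits its boundary cases exactly", {
  phi <- 2 * pi * 10 * (0:499) / 500
  expect_identical(mean_phase_coherence(phi, phi), 1)

  # phase differences forming the N-th roots of unity sum to zero
  n <- 500
  for (k in c(1, 7, 250, 499)) {
    phi2 <- 2 * pi * k * (0:(n - 1)) / n
    expect_lt(mean_phase_coherence(numeric(n), phi2), 1e-12)
  }

  # constant lag of any size still gives perfect locking
  for (lag in c(-2.5, 0.1, 3)) {
    expect_equal(mean_phase_coherence(phi, phi + lag), 1, tolerance = 1e-12)
  }

  expect_error(mean_phase_coherence(1:3, 1:4), "lengths differ")
  expect_error(mean_phase_coherence(numeric(0), numeric(0)), "empty")
  expect_error(mean_phase_coherence(c(1, NA), c(1, 2)), "non-finite")
})

test_that("mean phase coherence of random phases concentrates near zero", {
  # resultant length of N uniform unit vectors: E ~ sqrt(pi/4)/sqrt(N)
  set.seed(99)
  lams <- replicate(20, {
    mean_phase_coherence(runif(500, -pi, pi), runif(500, -pi, pi))
  })
  expect_lt(max(lams), 0.12)
  expect_lt(abs(mean(lams) - sqrt(pi / 4) / sqrt(500)), 0.02)
})

test_that("mean phase coherence is symmetric and offset-invariant", {
  set.seed(3)
  for (i in 1:5) {
    a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
    expect_equal(mean_phase_coherence(a, b), mean_phase_coherence(b, a))
    expect_equal(mean_phase_coherence(a + 1.3, b),
                 mean_phase_coherence(a, b), tolerance = 1e-12)
  }
})

test_that("window grid counts complete windows only", {
  g <- window_grid(5000, 500)
  expect_length(g$starts, 19)        # floor((5000 - 500)/250) + 1
  expect_equal(g$n_per_window, 500)  # 1 s at 500 Hz
  expect_equal(g$step, 250)
  expect_length(window_grid(5249, 500)$starts, 19)  # partial window dropped
  expect_error(window_grid(400, 500), "no complete")
  expect_error(window_grid(5000, 500, overlap = 1), "overlap")
})

test_that("connectivity matrices obey the lambda contracts", {
  fs <- 500
  rec <- sine_recording(c(10, 10, 11.5), fs = fs, dur_s = 10,
                        phases = c(0, 1.2, 0))
  conn <- sliding_connectivity(analytic_phase(rec))
  # identical-frequency pair: locked regardless of the constant lag
  expect_true(all(conn$matrices[1, 2, ] >= 0.99))
  # detuned pair (1.5 Hz apart): coherence far below locking in every window
  expect_true(all(conn$matrices[1, 3, ] < 0.5))
  # structural contracts
  for (w in seq_len(dim(conn$matrices)[3])) {
    m <- conn$matrices[, , w]
    expect_identical(m, t(m))
    expect_identical(diag(m), c(1, 1, 1))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("edge windows are dropped against the valid mask", {
  ph <- analytic_phase(noise_recording(m = 2, dur_s = 10),
                       edge_margin_s = 0.25)
  conn <- sliding_connectivity(ph)
  expect_equal(conn$dropped_windows, 2)  # one at each edge
  expect_equal(dim(conn$matrices)[3], 17)
  # centers exclude the first and last half-second windows
  expect_equal(min(conn$window_centers_s), 1)
  expect_equal(max(conn$window_centers_s), 9)
})

test_that("connectivity is amplitude-invariant and reproducible", {
  rec <- noise_recording(m = 4, dur_s = 6, seed = 21)
  base <- sliding_connectivity(analytic_phase(rec))
  scaled <- rec
  scaled$data[2, ] <- 7.3 * scaled$data[2, ]
  scaled$data[4, ] <- 0.01 * scaled$data[4, ]
  again <- sliding_connectivity(analytic_phase(scaled))
  expect_equal(base$matrices, again$matrices, tolerance = 1e-10)

  rerun <- sliding_connectivity(analytic_phase(rec))
  expect_identical(base$matrices, rerun$matrices)  # bit-reproducible
})

test_that("connectivity refuses degenerate inputs", {
  ph1 <- analytic_phase(noise_recording(m = 1, dur_s = 2))
  expect_error(sliding_connectivity(ph1), "2 channels")
  ph <- analytic_phase(noise_recording(m = 2, dur_s = 1),
                       edge_margin_s = 0.4)
  expect_error(sliding_connectivity(ph), "edge margin")
})
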