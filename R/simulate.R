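#' Coupling schedule for the phase-oscillator simulator
#'
#' A schedule is an ordered list of contiguous segments, each declaring the
#' coupling topology (state) active over a time span. Segments must tile the
#' timeline without gaps; coupling matrices are symmetric, non-negative, with
#' zero diagonal.
#'
#' @param segments list of segments built with [schedule_segment()].
#' @param onset_s,termination_s seizure annotations to plant on the simulated
#'   recording, in seconds (optional).
#' @return an object of class `coupling_schedule`.
#' @seealso [simulate_recording()], [make_seizure_fixture()]
#' @export
coupling_schedule <- function(segments, onset_s = NULL, termination_s = NULL) {
  stopifnot(is.list(segments), length(segments) >= 1)
  m <- length(segments[[1]]$freqs_hz)
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    stopifnot(inherits(s, "schedule_segment"))
    if (length(s$freqs_hz) != m || !all(dim(s$coupling) == m)) {
      stop("segment ", i, " has inconsistent channel count", call. = FALSE)
    }
    if (i > 1 && abs(s$start_s - segments[[i - 1]]$end_s) > 1e-9) {
      stop("segments must tile the timeline (gap before segment ", i, ")",
           call. = FALSE)
    }
  }
  structure(list(segments = segments, M = m,
                 start_s = segments[[1]]$start_s,
                 end_s = segments[[length(segments)]]$end_s,
                 onset_s = onset_s, termination_s = termination_s),
            class = "coupling_schedule")
}

#' @rdname coupling_schedule
#' @param start_s,end_s segment span in seconds (half-open).
#' @param state_id integer id of the planted network state this segment
#'   realizes (equal ids across segments mean the same coupling regime).
#' @param coupling symmetric non-negative M x M matrix of pairwise coupling
#'   strengths (rad/s per unit sine), zero diagonal.
#' @param freqs_hz per-channel natural frequencies in Hz.
#' @param phase_noise_sd per-channel phase-diffusion SD in rad/sqrt(s).
#' @param obs_noise_sd additive observation noise SD (signal units).
#' @export
schedule_segment <- function(start_s, end_s, state_id, coupling, freqs_hz,
                             phase_noise_sd = 0, obs_noise_sd = 0) {
  assert_scalar_number(start_s, "start_s")
  assert_scalar_number(end_s, "end_s")
  if (end_s <= start_s) stop("need end_s > start_s", call. = FALSE)
  coupling <- as.matrix(coupling)
  if (!isSymmetric(unname(coupling)) || any(coupling < 0) ||
      any(diag(coupling) != 0)) {
    stop("coupling must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  }
  structure(list(start_s = start_s, end_s = end_s,
                 state_id = as.integer(state_id), coupling = coupling,
                 freqs_hz = as.numeric(freqs_hz),
                 phase_noise_sd = phase_noise_sd,
                 obs_noise_sd = obs_noise_sd),
            class = "schedule_segment")
}

#' Simulate a multichannel recording from coupled phase oscillators
#'
#' Integrates Kuramoto-type stochastic phase dynamics
#' `d theta_i = 2 pi f_i dt + sum_j K_ij sin(theta_j - theta_i) dt
#' + sigma dW_i` by Euler-Maruyama at the sampling rate (step `1/fs`), and
#' observes `x_i(t) = sin(theta_i(t))` plus white observation noise. Mean
#' phase coherence responds monotonically to the coupling strength in this
#' model, which provides analytic anchors for pipeline validation: uncoupled
#' identical oscillators stay perfectly locked, uncoupled detuned oscillators
#' drift apart, and coupling above the locking threshold pulls lambda toward
#' 1. Phases are continuous across segment switches.
#'
#' @param schedule a [coupling_schedule()].
#' @param fs sampling rate in Hz; must satisfy `fs >= 4 * max frequency`.
#' @param seed integer seed; the run is bit-reproducible given the seed and
#'   leaves the caller's RNG state untouched.
#' @return list with `recording` (a [new_recording()], annotated when the
#'   schedule carries onset/termination) and `ground_truth` (class
#'   `ground_truth`: the segment table, `M`, `fs`, `seed`).
#' @export
simulate_recording <- function(schedule, fs, seed = 1) {
  stopifnot(inherits(schedule, "coupling_schedule"))
  m <- schedule$M
  fmax <- max(vapply(schedule$segments, function(s) max(s$freqs_hz), 0))
  if (fs < 4 * fmax) {
    stop("fs = ", fs, " Hz too low for oscillators up to ", fmax,
         " Hz (need fs >= 4 * max frequency)", call. = FALSE)
  }
  dt <- 1 / fs
  total <- round((schedule$end_s - schedule$start_s) * fs)
  x <- matrix(0, nrow = m, ncol = total)
  with_seed(seed, {
    theta <- stats::runif(m, -pi, pi)
    for (seg in schedule$segments) {
      i0 <- round((seg$start_s - schedule$start_s) * fs) + 1
      i1 <- round((seg$end_s - schedule$start_s) * fs)
      w <- 2 * pi * seg$freqs_hz
      ns <- sqrt(dt) * seg$phase_noise_sd
      coupled <- any(seg$coupling > 0)
      for (t in i0:i1) {
        if (coupled) {
          z <- exp(1i * theta)
          pull <- Im(Conj(z) * (seg$coupling %*% z))
          theta <- theta + (w + pull) * dt
        } else {
          theta <- theta + w * dt
        }
        if (ns > 0) theta <- theta + ns * stats::rnorm(m)
        x[, t] <- theta
      }
      if (any(!is.finite(theta))) {
        stop("unstable integration (non-finite phases); reduce coupling or ",
             "raise fs", call. = FALSE)
      }
    }
    x <- sin(x)
    for (seg in schedule$segments) {
      if (seg$obs_noise_sd > 0) {
        i0 <- round((seg$start_s - schedule$start_s) * fs) + 1
        i1 <- round((seg$end_s - schedule$start_s) * fs)
        x[, i0:i1] <- x[, i0:i1] +
          seg$obs_noise_sd * matrix(stats::rnorm(m * (i1 - i0 + 1)), m)
      }
    }
  })
  rec <- new_recording(x, fs = fs, onset_s = schedule$onset_s,
                       termination_s = schedule$termination_s,
                       t0_s = schedule$start_s)
  gt <- structure(
    list(segments = data.frame(
           start_s = vapply(schedule$segments, `[[`, 0, "start_s"),
           end_s = vapply(schedule$segments, `[[`, 0, "end_s"),
           state_id = vapply(schedule$segments, function(s)
             as.numeric(s$state_id), 0)),
         M = m, fs = fs, seed = seed,
         onset_s = schedule$onset_s, termination_s = schedule$termination_s),
    class = "ground_truth")
  list(recording = rec, ground_truth = gt)
}

#' Planted state labels on a window grid
#'
#' Maps ground-truth schedule segments onto analysis windows: each window gets
#' the state id of the segment containing its center. Windows that straddle a
#' segment boundary are flagged `ambiguous` — their samples mix two regimes
#' (plus the oscillators' relaxation after the switch), so no single planted
#' label describes them; recovery scores should be computed on the
#' unambiguous windows.
#'
#' @param gt a `ground_truth` from [simulate_recording()].
#' @param window_centers_s window centers in seconds.
#' @param window_s window length in seconds.
#' @return data frame with columns `window_center_s`, `state_id`, `ambiguous`.
#' @export
planted_states <- function(gt, window_centers_s, window_s = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  seg <- gt$segments
  find <- function(t) {
    i <- which(t >= seg$start_s & t < seg$end_s)
    if (length(i) == 0) NA_integer_ else seg$state_id[i[1]]
  }
  ids <- vapply(window_centers_s, find, 0)
  half <- window_s / 2
  # interior boundaries only
  bounds <- seg$start_s[-1]
  amb <- vapply(window_centers_s, function(t) {
    any(bounds > t - half & bounds < t + half)
  }, TRUE)
  data.frame(window_center_s = window_centers_s, state_id = ids,
             ambiguous = amb)
}

#' Canonical seizure-like fixture
#'
#' Generates the package's reference synthetic recording, emulating the
#' qualitative peri-seizure pattern seen in clinical ECoG: a fast-switching
#' moderately synchronized preseizure network, a single weakly synchronized
#' state through the first three quarters of the seizure, a strong global
#' synchronization rise in the last quarter (S4), and sustained high
#' synchronization with renewed switching after termination.
#'
#' Five network states are planted on an `M`-channel grid (default 48 = 6 x 8
#' electrodes at 500 Hz, seizure length 60 s, equal-length pre/post periods),
#' each defined by which channel subset is coupled above the locking
#' threshold (total pull 36 rad/s, split evenly over the subset's pairs) on
#' top of a sub-threshold background (total 1.4 rad/s):
#'
#' 1. first half of the channels locked (preseizure);
#' 2. second half locked (preseizure, alternating with state 1 every
#'    `switch_s` seconds);
#' 3. background coupling only, no locking (S1-S3 — the early-seizure
#'    synchronization dip);
#' 4. the front three quarters of the grid locked (S4, continuing into the
#'    postseizure period — the late-seizure synchronization rise);
#' 5. the back three quarters locked (postseizure, alternating with state 4).
#'
#' The hypersynchronized states recruit most but not all of the grid, so the
#' five degree-vector centroids are comparably separated rather than split
#' into one low- and one high-synchronization super-group. Channel natural
#' frequencies are spread over 8-16 Hz so that unlocked channels decohere
#' within a 1-s window. The planted mean-phase-synchronization ordering is
#' S4 above each of preS, S1, S2 and S3, and planted switching is faster in
#' the pre/postseizure periods than within the seizure.
#'
#' @param M channels (default 48).
#' @param fs sampling rate in Hz (default 500).
#' @param seizure_s seizure duration in seconds (default 60; pre and post
#'   periods have the same length).
#' @param switch_s pre/post state-switching period in seconds (default 10).
#' @param seed integer seed.
#' @return as [simulate_recording()]; the ground truth additionally records
#'   `planted_K = 5` and the expected S4-dominant ordering.
#' @export
make_seizure_fixture <- function(M = 48, fs = 500, seizure_s = 60,
                                 switch_s = 10, seed = 1) {
  if (M < 4) stop("fixture needs at least 4 channels", call. = FALSE)
  freqs <- 8 + 8 * (seq_len(M) - 1) / (M - 1)
  half1 <- seq_len(floor(M / 2))
  half2 <- setdiff(seq_len(M), half1)
  front <- seq_len(round(3 * M / 4))            # onset-zone-centred majority
  back <- setdiff(seq_len(M), seq_len(round(M / 4)))
  # Kuramoto-style size scaling: per-pair strength = total pull / (n - 1), so
  # a locked subset feels ~g_lock rad/s regardless of grid size. g_lock = 36
  # exceeds the widest subset's frequency half-spread (2*pi*3 ~ 18.9 rad/s);
  # the background total 1.4 is far below threshold.
  g_lock <- 36
  g_bg <- 1.4
  block <- function(idx, g) {
    K <- matrix(g_bg / (M - 1), M, M)
    if (length(idx) > 1) K[idx, idx] <- g / (length(idx) - 1)
    diag(K) <- 0
    K
  }
  K_state <- list(
    block(half1, g_lock),    # 1: first half locked (preseizure)
    block(half2, g_lock),    # 2: second half locked (preseizure)
    block(integer(), 0),     # 3: background only, no locking (S1-S3)
    block(front, g_lock),    # 4: strong coupling, front 3/4 (S4, post)
    block(back, g_lock)      # 5: strong coupling, back 3/4 (post)
  )
  sigma <- 0.3   # rad/sqrt(s) phase diffusion
  obs <- 0.1     # observation noise SD
  seg <- function(a, b, id) {
    schedule_segment(a, b, id, K_state[[id]], freqs, sigma, obs)
  }
  pre_s <- seizure_s
  post_s <- seizure_s
  onset <- pre_s
  term <- pre_s + seizure_s
  # State switches are offset a quarter second from the annotation grid:
  # clinical regime changes do not align with analysis windows, and exactly
  # half-mixed windows (boundary at a window center) have no meaningful
  # planted label.
  off <- 0.25
  segs <- list()
  # preseizure: alternate states 1 and 2
  t <- 0; id <- 1
  while (t < onset - 1e-9) {
    nxt <- min(t + switch_s + (t == 0) * off, onset + off)
    segs[[length(segs) + 1]] <- seg(t, nxt, id)
    id <- 3 - id
    t <- nxt
  }
  # seizure: S1-S3 unlocked, S4 strong partial-grid coupling
  s4_start <- onset + 0.75 * seizure_s + off
  segs[[length(segs) + 1]] <- seg(t, s4_start, 3)
  segs[[length(segs) + 1]] <- seg(s4_start, term, 4)
  # postseizure: sustained strong coupling with switching (states 4 and 5)
  t <- term; id <- 4
  while (t < term + post_s - 1e-9) {
    nxt <- min(t + switch_s + (t == term) * off, term + post_s)
    segs[[length(segs) + 1]] <- seg(t, nxt, id)
    id <- 9 - id
    t <- nxt
  }
  sched <- coupling_schedule(segs, onset_s = onset, termination_s = term)
  out <- simulate_recording(sched, fs = fs, seed = seed)
  out$ground_truth$planted_K <- 5L
  out$ground_truth$expected_ordering <-
    "mean_ps(S4) > mean_ps(p) for p in {preS, S1, S2, S3}"
  out
}

#' Write a simulated fixture to disk
#'
#' Writes the recording in the plain matrix format consumed by
#' [read_recording()] plus a JSON ground-truth sidecar.
#'
#' @param sim a [simulate_recording()] / [make_seizure_fixture()] result.
#' @param dir output directory (created if needed).
#' @param name file stem (default `"recording"`).
#' @return named character vector of the files written, invisibly.
#' @export
write_fixture <- function(sim, dir, name = "recording") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, paste0(name, ".txt"))
  write_recording(sim$recording, rec_path)
  gt_path <- file.path(dir, paste0(name, "_ground_truth.json"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(segments = gt$segments, M = gt$M, fs = gt$fs, seed = gt$seed,
         onset_s = gt$onset_s, termination_s = gt$termination_s,
         planted_K = gt$planted_K,
         expected_ordering = gt$expected_ordering),
    gt_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(recording = rec_path, sidecar = paste0(rec_path, ".yaml"),
              ground_truth = gt_path))
}
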