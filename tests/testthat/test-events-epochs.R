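test_that("inclusive-endpoint sample counts reproduce the standard windows", {
  expect_equal(n_samples(time_window(-250, 600)), 851L)
  expect_equal(n_samples(time_window(-200, 800)), 1001L)
  expect_equal(n_samples(time_window(-660, 1010)), 1671L)
  expect_equal(n_samples(time_window(-200, 1500)), 1701L)
  # and at other rates the grid follows fs
  expect_equal(n_samples(time_window(-250, 600, 200)), 171L)
  expect_error(time_window(100, 100), "greater than")
})

test_that("epochs index the recording exactly and edge cases are handled", {
  # impulse at lock + 100 ms lands at the right sample
  rec <- impulse_recording(impulse_abs_ms = 1100, amplitude = 7)
  ev <- fixation_events(1000)
  ep <- extract_epochs(rec, ev, "fixation", time_window(-250, 600))
  expect_equal(dim(ep$data), c(1L, 851L, 1L))
  idx_100 <- which(window_times(ep$window) == 100)
  expect_equal(ep$data[1, idx_100, 1], 7)
  expect_equal(sum(ep$data != 0), 1L)

  # epochs reproduce the covered recording segments sample for sample
  s <- toy_session()
  ep2 <- extract_epochs(s$recording, s$events, "fixation",
                        time_window(-250, 600))
  fs <- s$recording$sample_rate_hz
  for (i in c(1, 4)) {
    t_abs <- s$recording$trial_onset_ms[as.character(ep2$lock$trial_id[i])] +
      ep2$lock$onset_ms[i]
    first <- round((t_abs - 250) * fs / 1000) + 1
    expect_identical(ep2$data[i, , 1],
                     s$recording$data[1, first:(first + 850)])
  }

  # no lock events
  expect_error(extract_epochs(rec, ev, "stimulus", time_window(-250, 600)),
               "no events of lock class")
  # lock too close to the recording edge is rejected with a message
  ev_edge <- fixation_events(c(100, 1000))
  expect_message(
    ep3 <- extract_epochs(rec, ev_edge, "fixation", time_window(-250, 600)),
    "rejected 1")
  expect_equal(ep3$n_rejected, 1L)
  expect_equal(dim(ep3$data)[1], 1L)
  # sample-rate mismatch
  expect_error(extract_epochs(rec, ev, "fixation", time_window(-250, 600, 500)),
               "sample rate")
})

test_that("baseline correction zeroes the baseline and shifts a ramp by +150", {
  win <- time_window(-250, 600)
  bl <- time_window(-200, -100)
  # constant kernel -> all zero
  k_const <- efrp_kernel(matrix(3.3, 851, 2), win)
  expect_equal(baseline_correct(k_const, bl)$values, matrix(0, 851, 2))
  # ramp r(t) = t: mean over [-200,-100] is -150, output r + 150
  t <- window_times(win)
  k_ramp <- efrp_kernel(matrix(t, ncol = 1), win)
  expect_equal(baseline_correct(k_ramp, bl)$values[, 1], t + 150)
  # random input ends with zero baseline mean, per epoch and channel
  set.seed(42)
  s <- toy_session()
  ep <- extract_epochs(s$recording, s$events, "fixation", win)
  ep$data <- ep$data + array(rnorm(length(ep$data)), dim = dim(ep$data))
  epb <- baseline_correct(ep, bl)
  idx <- which(t >= -200 & t <= -100)
  for (i in seq_len(dim(epb$data)[1])) {
    expect_equal(mean(epb$data[i, idx, 1]), 0, tolerance = 1e-12)
  }
  # baseline outside the window names both windows
  expect_error(baseline_correct(k_const, time_window(-300, -250)),
               "not inside")
})

test_that("lag distributions match a brute-force counting oracle", {
  # all adjacent events at +300 -> unit mass at 300
  ev <- fixation_events(lapply(1:5, function(i) c(500, 800, 1100)))
  s <- toy_session()  # only for a recording long enough; re-render
  rec <- render_session(ev, list(fixation = s$kernel))
  ep <- extract_epochs(rec, ev, "fixation", time_window(-250, 600),
                       lock_events = ev[!is.na(ev$rank) & ev$rank == 2, ])
  qn <- lag_distribution(ep, "fixation", +1L)
  expect_equal(sum(qn$mass), 1)
  expect_equal(qn$lags_ms[which(qn$mass > 0)], 300)
  qp <- lag_distribution(ep, "fixation", -1L)
  expect_equal(sum(qp$mass), 1)
  expect_equal(qp$lags_ms[which(qp$mass > 0)], -300)

  # random synthetic events: mass equals count/E at every lag; sum <= 1
  fx <- make_fixture("mid_exploration", seed = 12, n_trials = 10)
  epf <- extract_epochs(fx$recording, fx$events, "fixation",
                        fx$windows$epoch, lock_events = fx$lock_events)
  for (f in c(-2L, -1L, 1L, 2L)) {
    q <- lag_distribution(epf, "fixation", f)
    expect_true(all(q$mass >= 0))
    expect_lte(sum(q$mass), 1 + 1e-12)
    # oracle: count rank-offset events epoch by epoch
    counts <- integer(0); lags <- numeric(0)
    for (i in seq_along(epf$events)) {
      e <- epf$events[[i]]
      hit <- e$rel_onset_ms[e$class == "fixation" & !is.na(e$rank) &
                              e$rank == epf$lock$rank[i] + f]
      if (length(hit) == 1) lags <- c(lags, hit)
    }
    expect_equal(sum(q$mass) * q$n_epochs, length(lags))
    for (l in unique(lags)) {
      expect_equal(q$mass[which(q$lags_ms == l)],
                   sum(lags == l) / q$n_epochs)
    }
  }
})

test_that("participant epoch window follows tau = mean(IFI) + sd(IFI)", {
  interest <- time_window(-250, 600)
  # all IFIs exactly 400 -> tau 400 -> [-650; 1000]
  ev <- fixation_events(lapply(1:3, function(i) seq(500, 2500, by = 400)))
  w <- epoch_window_for_participant(ev, interest)
  expect_equal(c(w$start_ms, w$end_ms), c(-650, 1000))
  # a tau of 406.37 rounds up to 410: [-660; 1010], 1671 samples
  w2 <- expand_window(interest, 406.37)
  expect_equal(c(w2$start_ms, w2$end_ms), c(-660, 1010))
  expect_equal(n_samples(w2), 1671L)
  # no IFIs computable
  ev1 <- fixation_events(lapply(1:3, function(i) 500))
  expect_error(epoch_window_for_participant(ev1, interest), "inter-fixation")
})

test_that("rank selection is uniform in range, reproducible, and skips short trials", {
  ev <- fixation_events(lapply(1:20, function(i) seq(400, 3900, by = 300)))
  # low = high = 3, one draw: exactly the third fixation of each trial
  sel <- select_ranks(ev, 3, 3, 1, seed = 1)
  expect_true(all(sel$rank == 3))
  expect_equal(nrow(sel), 20L)
  # defaults 3..9, three draws: ranks within range, deterministic under seed
  s1 <- select_ranks(ev, seed = 99)
  s2 <- select_ranks(ev, seed = 99)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(s1$rank >= 3 & s1$rank <= 9))
  # trial with max rank below `low` is skipped with a message
  ev_short <- fixation_events(list(c(400, 700), seq(400, 3900, by = 300)))
  expect_message(s3 <- select_ranks(ev_short, 3, 9, 3, seed = 5),
                 "skipped 1")
  expect_true(all(s3$trial_id == 2L))
})

test_that("event tables and recordings round-trip through their text formats", {
  ev <- fixation_events(list(c(400, 700, 1000), c(350, 800)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, p)
  expect_equal(as.data.frame(read_event_table(p)), as.data.frame(ev))
  rec <- impulse_recording(1234, amplitude = -2.5)
  pr <- withr::local_tempfile(fileext = ".txt")
  write_recording(rec, pr)
  rec2 <- read_recording(pr)
  expect_equal(rec2$data, rec$data)
  expect_equal(rec2$sample_rate_hz, rec$sample_rate_hz)
  expect_equal(rec2$trial_onset_ms, rec$trial_onset_ms)
})
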