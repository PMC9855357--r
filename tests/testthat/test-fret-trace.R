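test_that("proximity ratio is the raw acceptor fraction", {
  tr <- fret_trace(donor = c(0, 100, 300), acceptor = c(100, 100, 100))
  E <- proximity_ratio(tr)
  expect_equal(E, c(1.0, 0.5, 0.25))

  # zero-total frames are flagged, not fabricated
  tr0 <- fret_trace(donor = c(100, 0), acceptor = c(100, 0))
  E0 <- proximity_ratio(tr0)
  expect_true(is.na(E0[2]))
  expect_equal(attr(E0, "n_flagged"), 1L)
  expect_error(proximity_ratio(tr, upto = 9), "out of range")
})

test_that("proximity ratio is bounded for nonnegative intensities", {
  set.seed(1)
  iD <- runif(200, 0, 500); iA <- runif(200, 0, 500)
  E <- proximity_ratio(fret_trace(iD, iA))
  expect_true(all(E >= 0 & E <= 1, na.rm = TRUE))
})

test_that("step detection finds exact noiseless steps and no phantom ones", {
  x <- c(rep(100, 40), rep(10, 40))
  st <- detect_steps(x)
  expect_equal(nrow(st), 1L)
  expect_equal(st$index, 40L)
  expect_lt(st$size, 0)

  expect_equal(nrow(detect_steps(rep(55, 60))), 0L)

  set.seed(8)
  flat <- rnorm(300, 100, 5)
  expect_equal(nrow(detect_steps(flat)), 0L)
})

test_that("photobleach point is the last frame before the bleach step", {
  # constant trace: the whole trace is valid
  tr <- fret_trace(rep(200, 50), rep(300, 50))
  expect_equal(detect_photobleach(tr), 50L)

  # noiseless step to background at frame 31: last valid frame is 30
  tr2 <- fret_trace(c(rep(250, 30), rep(0, 30)),
                    c(rep(250, 30), rep(0, 30)))
  expect_equal(detect_photobleach(tr2), 30L)
  expect_error(detect_photobleach(fret_trace(rep(1, 5), rep(1, 5))),
               "10 frames")
})

test_that("noisy single-step bleaches are located within two frames", {
  spec <- fret_sim_spec(data.frame(mean_E = 0.5, fwhm = 0.1),
                        n_molecules = 200, n_frames = 200,
                        bleach_rate_donor = 0.1,
                        bleach_rate_acceptor = 0.05, seed = 21)
  traces <- simulate_fret_traces(spec)
  err <- vapply(traces, function(tr) {
    truth <- attr(tr, "truth")
    first <- min(truth$donor_bleach_frame, truth$acceptor_bleach_frame, 200)
    detect_photobleach(tr) - first
  }, 0)
  expect_gte(mean(abs(err) <= 2), 0.95)
})

test_that("single-pair selection accepts clean traces, rejects aggregates", {
  states <- data.frame(mean_E = 0.5, fwhm = 0.1)
  clean <- simulate_fret_traces(fret_sim_spec(
    states, n_molecules = 40, n_frames = 300,
    bleach_rate_donor = 0.05, bleach_rate_acceptor = 0.03, seed = 31))
  acc <- select_single_pairs(clean)
  expect_gte(length(acc) / length(clean), 0.8)

  # two donors bleach in two steps: aggregates must be rejected
  agg <- simulate_fret_traces(fret_sim_spec(
    states, n_molecules = 30, n_frames = 300,
    bleach_rate_donor = 0.15, bleach_rate_acceptor = 0,
    n_donors = 2L, seed = 32))
  sel <- attr(select_single_pairs(agg), "selection")
  two_step <- vapply(agg, function(tr)
    attr(tr, "truth")$n_donor_steps >= 2L, TRUE)
  expect_gte(mean(!sel$accepted[two_step]), 0.9)

  # no direct-excitation signal means no acceptor: rejected
  dark <- simulate_fret_traces(fret_sim_spec(
    states, n_molecules = 5, n_frames = 150, direct_intensity = 0,
    bleach_rate_donor = 0, bleach_rate_acceptor = 0, seed = 33))
  sel_dark <- attr(select_single_pairs(dark), "selection")
  expect_true(all(!sel_dark$accepted))
  expect_match(sel_dark$reason[1], "dark")

  expect_warning(out <- select_single_pairs(list()), "empty")
  expect_length(out, 0L)
})

test_that("dynamics classification needs anticorrelated transitions", {
  # steady trace: static
  set.seed(41)
  tr <- fret_trace(rnorm(100, 300, 8), rnorm(100, 200, 8))
  expect_equal(classify_dynamics(tr), "static")

  # two-state switching with dwell >> frame time: dynamic
  states <- data.frame(mean_E = c(0.25, 0.75), fwhm = c(0.1, 0.1))
  rates <- matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE)
  sw <- simulate_fret_traces(fret_sim_spec(
    states, rates = rates, n_molecules = 200, n_frames = 250,
    bleach_rate_donor = 0, bleach_rate_acceptor = 0, seed = 42))
  calls <- vapply(sw, classify_dynamics, "")
  expect_gte(mean(calls == "dynamic"), 0.95)

  # correlated two-channel drop (focus artifact) is not dynamics
  set.seed(43)
  d <- c(rnorm(60, 300, 6), rnorm(60, 180, 6))
  a <- c(rnorm(60, 300, 6), rnorm(60, 180, 6))
  expect_equal(classify_dynamics(fret_trace(d, a)), "static")

  expect_equal(classify_dynamics(tr, upto = 10), "indeterminate")
})

test_that("trace CSV round-trips through the tidy format", {
  states <- data.frame(mean_E = 0.4, fwhm = 0.12)
  traces <- simulate_fret_traces(fret_sim_spec(
    states, n_molecules = 3, n_frames = 40,
    bleach_rate_donor = 0, bleach_rate_acceptor = 0, seed = 5))
  csv <- tempfile(fileext = ".csv")
  write_fret_traces(traces, csv)
  back <- read_fret_traces(csv)
  expect_length(back, 3L)
  expect_equal(back[[1]]$donor, traces[[1]]$donor, tolerance = 1e-9)
  expect_equal(back[[2]]$direct_acceptor, traces[[2]]$direct_acceptor,
               tolerance = 1e-9)
})
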