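test_that("histogram accumulation pools frames into fixed bins", {
  # one molecule at constant E = 0.5: a single occupied bin
  tr <- fret_trace(rep(100, 30), rep(100, 30), rep(200, 30))
  h <- accumulate_histogram(list(tr), bins = 50)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$mids[which(h$counts > 0)], 0.51, tolerance = 0.011)

  # two molecules at E = 0.2 / 0.8 with equal lengths: two equal peaks
  lo <- fret_trace(rep(400, 25), rep(100, 25), rep(200, 25))
  hi <- fret_trace(rep(100, 25), rep(400, 25), rep(200, 25))
  h2 <- accumulate_histogram(list(lo, hi), bins = 10)
  occ <- which(h2$counts > 0)
  expect_length(occ, 2L)
  expect_equal(h2$counts[occ[1]], h2$counts[occ[2]])
})

test_that("histogram counts conserve the number of valid frames", {
  spec <- fret_sim_spec(data.frame(mean_E = c(0.3, 0.7),
                                   fwhm = c(0.12, 0.12)),
                        weights = c(0.5, 0.5), n_molecules = 25,
                        n_frames = 120, bleach_rate_donor = 0.1,
                        bleach_rate_acceptor = 0.05, seed = 55)
  traces <- simulate_fret_traces(spec)
  h <- accumulate_histogram(traces)
  valid <- sum(vapply(traces, detect_photobleach, 0L))
  expect_equal(sum(h$counts), valid)
  expect_equal(h$n_frames, valid)
  expect_error(accumulate_histogram(list()), "no traces")
})

test_that("a single narrow population is fit by one component", {
  spec <- fret_sim_spec(data.frame(mean_E = 0.45, fwhm = 0.08),
                        n_molecules = 300, n_frames = 25,
                        bleach_rate_donor = 0, bleach_rate_acceptor = 0,
                        seed = 61)
  h <- accumulate_histogram(simulate_fret_traces(spec))
  fit <- fit_mixture(h)
  expect_equal(fit$n_components, 1L)
  expect_equal(fit$means, 0.45, tolerance = 0.01)
})

test_that("two- and three-state populations are recovered", {
  # two broad overlapping states
  spec2 <- fret_sim_spec(data.frame(mean_E = c(0.2, 0.55),
                                    fwhm = c(0.33, 0.28)),
                         weights = c(0.2, 0.8), n_molecules = 1000,
                         n_frames = 20, bleach_rate_donor = 0,
                         bleach_rate_acceptor = 0, seed = 62)
  fit2 <- fit_mixture(accumulate_histogram(simulate_fret_traces(spec2)))
  expect_equal(fit2$n_components, 2L)
  expect_lte(max(abs(fit2$means - c(0.2, 0.55))), 0.02)
  expect_lte(max(abs(fit2$weights - c(0.2, 0.8))), 0.05)

  # three states, one dominant
  spec3 <- fret_sim_spec(data.frame(mean_E = c(0.21, 0.46, 0.85),
                                    fwhm = c(0.11, 0.17, 0.15)),
                         weights = c(0.24, 0.24, 0.52), n_molecules = 1000,
                         n_frames = 20, bleach_rate_donor = 0,
                         bleach_rate_acceptor = 0, seed = 63)
  fit3 <- fit_mixture(accumulate_histogram(simulate_fret_traces(spec3)))
  expect_equal(fit3$n_components, 3L)
  expect_lte(max(abs(fit3$means - c(0.21, 0.46, 0.85))), 0.02)
  expect_lte(max(abs(fit3$weights - c(0.24, 0.24, 0.52))), 0.05)
})

test_that("mixture weights are a simplex and widths are reported as FWHM", {
  spec <- fret_sim_spec(data.frame(mean_E = c(0.3, 0.7),
                                   fwhm = c(0.1, 0.14)),
                        weights = c(0.4, 0.6), n_molecules = 600,
                        n_frames = 20, bleach_rate_donor = 0,
                        bleach_rate_acceptor = 0, seed = 64)
  fit <- fit_mixture(accumulate_histogram(simulate_fret_traces(spec)))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$means >= 0 & fit$means <= 1))
  expect_true(all(fit$fwhm > 0))
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * fit$sds, tolerance = 1e-12)
  expect_error(fit_mixture(fret_histogram_from_values(rep(0.5, 10),
                                                      bins = 50)),
               "occupied bins")
})

test_that("binned fit agrees with an independent raw-sample mixture fit", {
  # mclust fits the unbinned samples; the binned multinomial fit should
  # land on the same solution within sampling error
  suppressMessages(library(mclust))
  set.seed(65)
  E <- c(rnorm(6000, 0.25, 0.05), rnorm(14000, 0.7, 0.06))
  E <- E[E >= 0 & E <= 1]
  fit <- fit_mixture(fret_histogram_from_values(E, bins = 50))
  ref <- Mclust(E, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$n_components, 2L)
  expect_equal(fit$means, as.numeric(ref$parameters$mean),
               tolerance = 0.01)
  expect_equal(fit$weights, as.numeric(ref$parameters$pro),
               tolerance = 0.02)
})
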