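# build a minimal CA-bead trajectory from a list of coordinate matrices
toy_traj <- function(frames, element = "C") {
  n <- nrow(frames[[1]])
  atoms <- data.frame(eleno = seq_len(n), elety = "CA", resid = "GLY",
                      chain = "A", resno = seq_len(n), element = element,
                      stringsAsFactors = FALSE)
  xyz <- array(NA_real_, c(n, 3L, length(frames)))
  for (f in seq_along(frames)) xyz[, , f] <- frames[[f]]
  conformer_trajectory(atoms, xyz)
}

test_that("radius of gyration matches closed-form geometries", {
  # two unit-mass points 2d apart: Rg = d
  d <- 3.7
  two <- toy_traj(list(rbind(c(0, 0, 0), c(2 * d, 0, 0))))
  expect_equal(radius_of_gyration(two)$values, d)

  # four points at the corners of a square of side a: Rg = a / sqrt(2)
  a <- 5
  sq <- toy_traj(list(rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0),
                            c(0, a, 0))))
  expect_equal(radius_of_gyration(sq)$values, a / sqrt(2))
})

test_that("Rg equals the pairwise-distance oracle on random clouds", {
  # independent identity: Rg^2 = (1 / 2N^2) * sum_ij |r_i - r_j|^2
  set.seed(19)
  frames <- lapply(1:25, function(i) matrix(rnorm(300, sd = 8), 100, 3))
  rg <- radius_of_gyration(toy_traj(frames))$values
  oracle <- vapply(frames, function(m) {
    sqrt(sum(as.matrix(dist(m))^2) / (2 * nrow(m)^2))
  }, 0)
  expect_equal(rg, oracle, tolerance = 1e-9)
  expect_true(all(rg > 0))
})

test_that("mass weighting shifts Rg toward heavy atoms", {
  atoms <- data.frame(eleno = 1:2, elety = c("CA", "O"), resid = "GLY",
                      chain = "A", resno = 1:2,
                      element = c("C", "O"), stringsAsFactors = FALSE)
  xyz <- array(c(0, 4, 0, 0, 0, 0), c(2, 3, 1))
  traj <- conformer_trajectory(atoms, xyz)
  mC <- 12.011; mO <- 15.999
  cm <- 4 * mO / (mC + mO)
  expected <- sqrt((mC * cm^2 + mO * (4 - cm)^2) / (mC + mO))
  expect_equal(radius_of_gyration(traj, mass_weighted = TRUE)$values,
               expected, tolerance = 1e-12)
})

test_that("Rg histogram is a proper density with a mode", {
  traj <- generate_chain_ensemble(chain_spec(30, "gaussian",
                                             n_frames = 200, seed = 3))
  rg <- radius_of_gyration(traj, bin_width = 0.5)
  expect_equal(sum(rg$density) * 0.5, 1, tolerance = 1e-9)
  expect_true(rg$mode >= min(rg$values) - 0.5 &&
                rg$mode <= max(rg$values) + 0.5)
})

test_that("contacts follow the heavy-atom cutoff rule exactly", {
  place <- function(d12, d13 = 40, d23 = 40) {
    toy_traj(list(rbind(c(0, 0, 0), c(d12, 0, 0), c(0, d13, 0))))
  }
  # residues 1 and 3 are the testable nonsequential pair
  within <- toy_traj(list(rbind(c(0, 0, 0), c(50, 0, 0), c(6.4, 0, 0))))
  m1 <- contact_frequency_map(within)
  expect_equal(m1$map["1", "3"], 1.0)

  beyond <- toy_traj(list(rbind(c(0, 0, 0), c(50, 0, 0), c(6.6, 0, 0))))
  expect_equal(contact_frequency_map(beyond)$map["1", "3"], 0.0)

  # adjacent residues are excluded even at contact distance
  adj <- toy_traj(list(rbind(c(0, 0, 0), c(3, 0, 0), c(50, 0, 0))))
  expect_equal(contact_frequency_map(adj)$map["1", "2"], 0.0)

  # hydrogens never count
  h_only <- toy_traj(list(rbind(c(0, 0, 0), c(50, 0, 0), c(6.4, 0, 0))),
                     element = "H")
  expect_error(contact_frequency_map(h_only), "no heavy atoms")
})

test_that("contact maps are symmetric probabilities with a zero band", {
  traj <- generate_chain_ensemble(chain_spec(20, "excluded_volume",
                                             n_frames = 30, seed = 4))
  cm <- contact_frequency_map(traj)
  expect_identical(cm$map, t(cm$map))
  expect_true(all(cm$map >= 0 & cm$map <= 1))
  expect_true(all(diag(cm$map) == 0))
  n <- cm$n_residues
  near <- abs(row(cm$map) - col(cm$map)) < 2 & row(cm$map) != col(cm$map)
  expect_true(all(cm$map[near] == 0))
})

test_that("growing the cutoff never removes contacts", {
  traj <- generate_chain_ensemble(chain_spec(25, "gaussian",
                                             n_frames = 40, seed = 5))
  maps <- lapply(c(4.5, 6.5, 8.5), function(cut)
    contact_frequency_map(traj, cutoff = cut)$map)
  expect_true(all(maps[[2]] >= maps[[1]]))
  expect_true(all(maps[[3]] >= maps[[2]]))
})
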