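#' Specify a stochastic FRET trace simulation
#'
#' Ground-truth generator for two-channel single-molecule traces: a
#' continuous-time Markov chain over conformational states is discretised at
#' the camera frame rate; each state has a true mean proximity ratio and a
#' peak width; donor and acceptor photobleach as single exponential steps.
#'
#' @param states Data frame (or list) with columns `mean_E` and `fwhm`, one
#'   row per state.
#' @param rates Square transition-rate matrix (per second, off-diagonals;
#'   diagonal ignored). A zero matrix yields static molecules whose state is
#'   drawn from `weights`.
#' @param weights Initial/stationary state probabilities; defaults to the
#'   stationary distribution of `rates` (uniform when all rates are zero).
#' @param n_molecules Number of molecules to simulate.
#' @param n_frames Maximum frames per molecule.
#' @param frame_rate Frames per second (default 10).
#' @param total_intensity Mean total emission intensity per frame (counts).
#' @param direct_intensity Mean direct-excitation acceptor intensity while
#'   the acceptor is alive.
#' @param noise Noise model: `"gaussian"` (camera-like, variance
#'   proportional to intensity plus a read-noise floor, the default) or
#'   `"poisson"`.
#' @param noise_scale Variance multiplier for the Gaussian noise model
#'   (`var = noise_scale * intensity + read_noise^2`).
#' @param read_noise Intensity-independent camera noise SD in counts
#'   (default 10), applied in the Gaussian model.
#' @param bleach_rate_donor,bleach_rate_acceptor Photobleach rates (per s);
#'   0 disables bleaching of that dye.
#' @param background Residual mean intensity after bleaching (counts).
#' @param n_donors,n_acceptors Number of active dyes; values > 1 produce
#'   multi-step bleaching (aggregates) for testing trace selection.
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @return A list of class `fret_sim_spec`.
#' @export
fret_sim_spec <- function(states, rates = NULL, weights = NULL,
                          n_molecules = 100L, n_frames = 400L,
                          frame_rate = 10, total_intensity = 500,
                          direct_intensity = 300,
                          noise = c("gaussian", "poisson"),
                          noise_scale = 1, read_noise = 10,
                          bleach_rate_donor = 0.05,
                          bleach_rate_acceptor = 0.05,
                          background = 0,
                          n_donors = 1L, n_acceptors = 1L, seed = 1L) {
  noise <- match.arg(noise)
  states <- as.data.frame(states)
  stopifnot(all(c("mean_E", "fwhm") %in% names(states)))
  k <- nrow(states)
  if (any(states$mean_E < 0 | states$mean_E > 1))
    stop("fret_sim_spec(): state mean_E must lie in [0, 1]")
  if (is.null(rates)) rates <- matrix(0, k, k)
  rates <- as.matrix(rates)
  if (!all(dim(rates) == k))
    stop("fret_sim_spec(): rate matrix must be ", k, "x", k)
  if (any(rates[row(rates) != col(rates)] < 0))
    stop("fret_sim_spec(): negative transition rate")
  diag(rates) <- 0
  if (is.null(weights)) weights <- stationary_distribution(rates)
  if (length(weights) != k || any(weights < 0))
    stop("fret_sim_spec(): bad state weights")
  weights <- weights / sum(weights)
  structure(list(states = states, rates = rates, weights = weights,
                 n_molecules = as.integer(n_molecules),
                 n_frames = as.integer(n_frames),
                 frame_rate = frame_rate,
                 total_intensity = total_intensity,
                 direct_intensity = direct_intensity,
                 noise = noise, noise_scale = noise_scale,
                 read_noise = read_noise,
                 bleach_rate_donor = bleach_rate_donor,
                 bleach_rate_acceptor = bleach_rate_acceptor,
                 background = background,
                 n_donors = as.integer(n_donors),
                 n_acceptors = as.integer(n_acceptors),
                 seed = as.integer(seed)),
            class = "fret_sim_spec")
}

#' Stationary distribution of a transition-rate matrix
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum \pi_i = 1} for the generator built from
#' the off-diagonal rates. All-zero rates give the uniform distribution.
#'
#' @param rates Square matrix of off-diagonal transition rates (per s).
#' @return Numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(rates) {
  k <- nrow(rates)
  if (k == 1L) return(1)
  Q <- rates
  diag(Q) <- 0
  if (all(Q == 0)) return(rep(1 / k, k))
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat / sum(pi_hat)
}

# Sample a CTMC state path at frame times: exact exponential sojourns.
sample_state_path <- function(rates, weights, n_frames, dt) {
  k <- nrow(rates)
  path <- integer(n_frames)
  s <- sample.int(k, 1L, prob = weights)
  if (k == 1L || all(rates == 0)) return(rep(s, n_frames))
  t_now <- 0
  out_rates <- rowSums(rates)
  t_end <- n_frames * dt
  t_next <- if (out_rates[s] > 0) rexp(1, out_rates[s]) else Inf
  for (f in seq_len(n_frames)) {
    t_frame <- (f - 0.5) * dt     # state sampled at the frame midpoint
    while (t_next < t_frame) {
      s <- sample.int(k, 1L, prob = rates[s, ])
      t_now <- t_next
      t_next <- t_now + if (out_rates[s] > 0) rexp(1, out_rates[s]) else Inf
    }
    path[f] <- s
  }
  path
}

# Truncated-normal draw on [0, 1] by rejection (falls back to clamping for
# extreme parameters; widths used here keep acceptance high). `mean` and
# `sd` recycle to length n.
rtnorm01 <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- ifelse(sd > 0, rnorm(n, mean, sd), mean)
  bad <- which(x < 0 | x > 1)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < 0 | x[bad] > 1]
    tries <- tries + 1L
  }
  pmin(pmax(x, 0), 1)
}

#' Simulate single-molecule FRET traces with known ground truth
#'
#' For each molecule a state path is drawn from the continuous-time Markov
#' chain and discretised at the frame rate; the per-frame proximity ratio is
#' the state mean plus truncated-Gaussian conformational jitter whose width
#' is chosen so that the *observed* peak width (conformational jitter plus
#' shot noise) matches the state's nominal FWHM. Donor and acceptor
#' intensities are split accordingly and carry shot noise; each dye bleaches
#' at an exponential single-step time (multiplied over `n_donors`/
#' `n_acceptors` steps for synthetic aggregates). The direct-excitation
#' channel tracks acceptor aliveness.
#'
#' @param spec A [fret_sim_spec()].
#' @return A list of [fret_trace()] objects; each carries a `truth`
#'   attribute with the state path, bleach frames and per-frame true E.
#' @export
simulate_fret_traces <- function(spec) {
  stopifnot(inherits(spec, "fret_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  dt <- 1 / spec$frame_rate
  k <- nrow(spec$states)
  itot <- spec$total_intensity
  # shot-noise contribution to the proximity-ratio width of each state, by
  # error propagation through E = I_A / (I_A + I_D):
  # var(E) = [(1-E)^2 var(I_A) + E^2 var(I_D)] / I_tot^2
  ns <- if (spec$noise == "gaussian") spec$noise_scale else 1
  r2 <- if (spec$noise == "gaussian") spec$read_noise^2 else 0
  Em <- spec$states$mean_E
  var_shot <- ((1 - Em)^2 * (ns * Em * itot + r2) +
                 Em^2 * (ns * (1 - Em) * itot + r2)) / itot^2
  sd_state <- pmax(spec$states$fwhm / (2 * sqrt(2 * log(2))), 0)
  # conformational jitter makes up the remainder of the nominal width
  sd_conf <- sqrt(pmax(sd_state^2 - var_shot, 0))

  lapply(seq_len(spec$n_molecules), function(m) {
    nf <- spec$n_frames
    path <- sample_state_path(spec$rates, spec$weights, nf, dt)
    E <- rtnorm01(nf, spec$states$mean_E[path], sd_conf[path])
    donor_bleach_frame <- bleach_frame(spec$bleach_rate_donor,
                                       spec$n_donors, dt, nf)
    acceptor_bleach_frame <- bleach_frame(spec$bleach_rate_acceptor,
                                          spec$n_acceptors, dt, nf)
    f <- seq_len(nf)
    # mean emitted intensities scale with the fraction of dyes still
    # alive, so each extra dye of an aggregate bleaches as its own step
    d_scale <- alive_fraction(f, donor_bleach_frame$all)
    a_scale <- alive_fraction(f, acceptor_bleach_frame$all)
    iA_mean <- itot * E * d_scale * a_scale
    iD_mean <- itot * d_scale * (1 - E * a_scale)
    dir_mean <- spec$direct_intensity * a_scale
    iA <- add_noise(iA_mean, spec) + spec$background
    iD <- add_noise(iD_mean, spec) + spec$background
    dir <- add_noise(dir_mean, spec) + spec$background
    tr <- fret_trace(iD, iA, dir, frame_rate = spec$frame_rate,
                     molecule_id = sprintf("mol%04d", m))
    attr(tr, "truth") <- list(
      state_path = path, true_E = E,
      donor_bleach_frame = donor_bleach_frame$first,
      acceptor_bleach_frame = acceptor_bleach_frame$first,
      n_donor_steps = sum(donor_bleach_frame$all <= nf),
      n_acceptor_steps = sum(acceptor_bleach_frame$all <= nf))
    tr
  })
}

# Exponential bleach times for n_dyes dyes; `first` is the first step,
# `all` every step frame (sorted), Inf when no bleaching.
bleach_frame <- function(rate, n_dyes, dt, nf) {
  if (rate <= 0) return(list(first = Inf, all = numeric(0)))
  t <- sort(rexp(n_dyes, rate))
  frames <- ceiling(t / dt)
  list(first = if (length(frames)) frames[1] else Inf, all = frames)
}

# Fraction of an aggregate's dyes still alive at each frame.
alive_fraction <- function(f, step_frames) {
  if (length(step_frames) == 0L) return(rep(1, length(f)))
  n <- length(step_frames)
  alive <- vapply(f, function(fr) sum(step_frames >= fr), 0) / n
  alive
}

add_noise <- function(mean_int, spec) {
  if (spec$noise == "poisson") {
    rpois_safe(mean_int)
  } else {
    mean_int + rnorm(length(mean_int), 0,
                     sqrt(spec$noise_scale * pmax(mean_int, 0) +
                            spec$read_noise^2))
  }
}

rpois_safe <- function(lambda) {
  out <- numeric(length(lambda))
  pos <- lambda > 0
  out[pos] <- stats::rpois(sum(pos), lambda[pos])
  out
}
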