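#' Accumulate proximity ratios into a population histogram
#'
#' Pools the per-frame proximity ratios of the accepted molecules, each
#' truncated at its photobleach point, into fixed bins on `[0, 1]`. Values
#' pushed marginally outside `[0, 1]` by detector noise are clamped into the
#' edge bins so that the bin counts conserve the number of accepted frames.
#'
#' @param traces List of accepted [fret_trace()] objects.
#' @param bins Number of equal-width bins on `[0, 1]` (default 50).
#' @param bleach_threshold Step threshold passed to [detect_photobleach()].
#' @return An object of class `fret_histogram` with `breaks`, `mids`,
#'   `counts`, `n_molecules`, `n_frames`.
#' @export
accumulate_histogram <- function(traces, bins = 50L, bleach_threshold = 3) {
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  if (length(traces) == 0L)
    stop("accumulate_histogram(): no traces supplied")
  E <- unlist(lapply(traces, function(tr) {
    upto <- detect_photobleach(tr, threshold = bleach_threshold)
    proximity_ratio(tr, upto)
  }), use.names = FALSE)
  E <- E[!is.na(E)]
  if (length(E) == 0L)
    stop("accumulate_histogram(): no valid frames before photobleaching")
  E <- pmin(pmax(E, 0), 1)
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(E, breaks, rightmost.closed = TRUE),
                          bins), nbins = bins)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-(bins + 1L)]) / 2,
                 counts = counts,
                 n_molecules = length(traces),
                 n_frames = length(E)),
            class = "fret_histogram")
}

#' Build a histogram directly from pooled proximity ratios
#'
#' @param E Numeric vector of proximity ratios.
#' @param bins Number of bins on `[0, 1]`.
#' @param n_molecules Number of molecules the values came from (metadata).
#' @return A `fret_histogram`.
#' @export
fret_histogram_from_values <- function(E, bins = 50L, n_molecules = NA_integer_) {
  E <- E[!is.na(E)]
  if (!length(E)) stop("fret_histogram_from_values(): no values")
  E <- pmin(pmax(E, 0), 1)
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(E, breaks, rightmost.closed = TRUE),
                          bins), nbins = bins)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-(bins + 1L)]) / 2,
                 counts = counts, n_molecules = n_molecules,
                 n_frames = length(E)),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("<fret_histogram> %d bins, %d frames from %s molecules\n",
              length(x$counts), x$n_frames,
              ifelse(is.na(x$n_molecules), "?", x$n_molecules)))
  invisible(x)
}

# Bin probabilities of a Gaussian mixture truncated to [0, 1]:
# p_i proportional to sum_j w_j [Phi((b_{i+1}-mu_j)/s_j) - Phi((b_i-mu_j)/s_j)],
# renormalised over the bins.
mixture_bin_probs <- function(breaks, w, mu, s) {
  k <- length(w)
  nb <- length(breaks) - 1L
  p <- numeric(nb)
  for (j in seq_len(k)) {
    cdf <- pnorm(breaks, mean = mu[j], sd = s[j])
    p <- p + w[j] * diff(cdf)
  }
  tot <- sum(p)
  if (tot <= 0) rep(1 / nb, nb) else p / tot
}

# Binned (multinomial) negative log-likelihood of a k-component mixture,
# parameterised unconstrained: mu via logit, sd via log, weights via logits.
SD_BOUNDS <- c(0.005, 0.5)

mixture_nll <- function(par, breaks, counts, k) {
  if (any(!is.finite(par))) return(1e10)
  mu <- plogis(par[seq_len(k)])
  s <- SD_BOUNDS[1] + diff(SD_BOUNDS) * plogis(par[k + seq_len(k)])
  w <- if (k == 1L) 1 else {
    eta <- c(0, par[2L * k + seq_len(k - 1L)])
    exp(eta) / sum(exp(eta))
  }
  p <- mixture_bin_probs(breaks, w, mu, s)
  if (any(!is.finite(p))) return(1e10)
  p <- pmax(p, 1e-12)
  -sum(counts * log(p))
}

# Expectation-maximisation on the binned data (bin-midpoint approximation),
# used to locate the optimum before the exact binned likelihood is polished
# by quasi-Newton iteration. Monotone and robust to poor starts.
mixture_em <- function(hist, mu, sdev, w = NULL, iter = 200L) {
  x <- hist$mids; cts <- hist$counts
  k <- length(mu)
  if (is.null(w)) w <- rep(1 / k, k)
  n <- sum(cts)
  for (it in seq_len(iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * dnorm(x, mu[j], sdev[j]), numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot <= 0] <- 1e-300
    r <- dens / tot
    nj <- colSums(cts * r)
    nj <- pmax(nj, 1e-9)
    w <- nj / n
    mu_new <- colSums(cts * r * x) / nj
    sd_new <- sqrt(colSums(cts * r * (x - rep(mu_new,
      each = length(x)))^2) / nj)
    sd_new <- pmin(pmax(sd_new, SD_BOUNDS[1]), SD_BOUNDS[2])
    moved <- max(abs(mu_new - mu), abs(sd_new - sdev))
    mu <- pmin(pmax(mu_new, 0), 1); sdev <- sd_new
    if (moved < 1e-8) break
  }
  list(mu = mu, s = sdev, w = w)
}

# Deterministic starting values: component means at quantiles of the binned
# distribution, spread-scaled widths, equal weights, plus shifted variants.
mixture_starts <- function(hist, k) {
  mids <- hist$mids; counts <- hist$counts
  cw <- cumsum(counts) / sum(counts)
  qat <- function(q) mids[which.min(abs(cw - q))]
  base_mu <- vapply((seq_len(k) - 0.5) / k, qat, 0)
  spread <- sqrt(sum(counts * mids^2) / sum(counts) -
                   (sum(counts * mids) / sum(counts))^2)
  s0 <- max(spread / max(k, 2), 0.02)
  starts <- list(list(mu = base_mu, s = rep(s0, k)))
  starts[[2]] <- list(mu = pmin(pmax(base_mu + 0.08, 0.02), 0.98),
                      s = rep(s0 * 1.5, k))
  starts[[3]] <- list(mu = pmin(pmax(base_mu - 0.08, 0.02), 0.98),
                      s = rep(max(s0 * 0.5, 0.01), k))
  # peak-seeded start: local maxima of the smoothed histogram
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  pk <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) < 0)
  if (length(pk) >= k) {
    pk <- pk[order(sm[pk], decreasing = TRUE)][seq_len(k)]
    starts[[4]] <- list(mu = sort(mids[pk]), s = rep(s0, k))
  }
  starts
}

#' Fit a multi-state Gaussian model to a FRET population histogram
#'
#' Fits mixtures of k = 1..`max_components` Gaussians (truncated to
#' `[0, 1]`) to the binned counts by maximum multinomial likelihood
#' (L-BFGS-B over deterministic multi-starts), then selects k by the
#' Bayesian information criterion on the binned likelihood, taking the
#' smallest k within 2 units of the minimum BIC (parsimony rule). Reported
#' peak widths are full widths at half maximum
#' (\eqn{2\sqrt{2\ln 2}\,\sigma}).
#'
#' @param hist A `fret_histogram`.
#' @param max_components Largest number of Gaussian states tried.
#' @param bic_margin Parsimony margin in BIC units (default 2).
#' @return A list of class `fret_mixture` with `n_components`, `weights`,
#'   `means`, `sds`, `fwhm`, `logLik`, `bic` (vector over k), and the
#'   histogram.
#' @export
fit_mixture <- function(hist, max_components = 4L, bic_margin = 2) {
  stopifnot(inherits(hist, "fret_histogram"))
  occupied <- sum(hist$counts > 0)
  if (occupied < 3L)
    stop("fit_mixture(): need at least 3 occupied bins, have ", occupied)
  n <- sum(hist$counts)
  fits <- vector("list", max_components)
  bic <- rep(NA_real_, max_components)
  for (k in seq_len(max_components)) {
    best <- NULL
    for (st in mixture_starts(hist, k)) {
      s0 <- pmin(pmax(st$s, SD_BOUNDS[1] * 1.2), SD_BOUNDS[2] * 0.9)
      em <- mixture_em(hist, st$mu, s0)
      par0 <- c(qlogis(pmin(pmax(em$mu, 1e-3), 1 - 1e-3)),
                qlogis((pmin(pmax(em$s, SD_BOUNDS[1] * 1.01),
                             SD_BOUNDS[2] * 0.99) - SD_BOUNDS[1]) /
                         diff(SD_BOUNDS)),
                if (k > 1L) log(pmax(em$w[-1L], 1e-6) /
                                  pmax(em$w[1L], 1e-6)))
      fit <- tryCatch(
        optim(par0, mixture_nll, breaks = hist$breaks,
              counts = hist$counts, k = k, method = "BFGS",
              control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) next
    npar <- 3L * k - 1L
    bic[k] <- 2 * best$value + npar * log(n)
    fits[[k]] <- best
  }
  if (all(is.na(bic)))
    stop("fit_mixture(): no mixture size converged")
  kbest <- which(bic <= min(bic, na.rm = TRUE) + bic_margin)[1L]
  par <- fits[[kbest]]$par
  k <- kbest
  mu <- plogis(par[seq_len(k)])
  s <- SD_BOUNDS[1] + diff(SD_BOUNDS) * plogis(par[k + seq_len(k)])
  w <- if (k == 1L) 1 else {
    eta <- c(0, par[2L * k + seq_len(k - 1L)])
    exp(eta) / sum(exp(eta))
  }
  ord <- order(mu)
  structure(list(n_components = k,
                 weights = w[ord], means = mu[ord], sds = s[ord],
                 fwhm = 2 * sqrt(2 * log(2)) * s[ord],
                 logLik = -fits[[kbest]]$value,
                 bic = bic,
                 histogram = hist),
            class = "fret_mixture")
}

#' @export
print.fret_mixture <- function(x, ...) {
  cat(sprintf("<fret_mixture> %d state(s), n = %d frames\n",
              x$n_components, x$histogram$n_frames))
  for (j in seq_len(x$n_components))
    cat(sprintf("  state %d: occupancy %.2f, mean %.3f, FWHM %.3f\n",
                j, x$weights[j], x$means[j], x$fwhm[j]))
  invisible(x)
}

#' Attach SAW-model distances to a fitted mixture
#'
#' Converts each state's mean proximity ratio to a mean dye separation with
#' [saw_mean_distance()].
#'
#' @param fit A `fret_mixture`.
#' @param model A [saw_model()].
#' @param report Distance convention, see [saw_mean_distance()].
#' @return A data frame with one row per state: `occupancy`, `mean`,
#'   `fwhm`, `R_DA_nm`.
#' @export
mixture_state_table <- function(fit, model = saw_model(),
                                report = c("rms", "mean")) {
  report <- match.arg(report)
  rda <- vapply(fit$means, function(e)
    saw_mean_distance(e, model, report = report)$r_report, 0)
  data.frame(state = seq_len(fit$n_components),
             occupancy = fit$weights,
             mean = fit$means,
             fwhm = fit$fwhm,
             R_DA_nm = rda)
}
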