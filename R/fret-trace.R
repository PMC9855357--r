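#' Single-molecule FRET intensity trace
#'
#' Per-frame donor and acceptor intensities for one surface-tethered
#' molecule, plus the direct-excitation acceptor channel recorded under
#' alternating illumination (used to verify an active acceptor).
#'
#' @param donor,acceptor,direct_acceptor Numeric vectors of equal length,
#'   intensities in camera counts.
#' @param frame_rate Frames per second (default 10).
#' @param molecule_id Optional identifier.
#' @return An object of class `fret_trace`.
#' @export
fret_trace <- function(donor, acceptor, direct_acceptor = NULL,
                       frame_rate = 10, molecule_id = NA_character_) {
  n <- length(donor)
  if (length(acceptor) != n)
    stop("fret_trace(): donor and acceptor must have equal length")
  if (!is.null(direct_acceptor) && length(direct_acceptor) != n)
    stop("fret_trace(): direct_acceptor length mismatch")
  if (frame_rate <= 0) stop("fret_trace(): frame_rate must be positive")
  if (!all(is.finite(donor)) || !all(is.finite(acceptor)))
    stop("fret_trace(): intensities must be finite")
  structure(list(donor = as.numeric(donor),
                 acceptor = as.numeric(acceptor),
                 direct_acceptor = if (is.null(direct_acceptor)) NULL
                                   else as.numeric(direct_acceptor),
                 frame_rate = frame_rate,
                 time = (seq_len(n) - 1) / frame_rate,
                 molecule_id = molecule_id),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %s: %d frames @ %g fps%s\n",
              x$molecule_id, length(x$donor), x$frame_rate,
              if (is.null(x$direct_acceptor)) "" else " (+direct channel)"))
  invisible(x)
}

n_frames <- function(trace) length(trace$donor)

#' Read FRET traces from a tidy CSV
#'
#' Expected columns: `molecule_id`, `frame`, `I_D`, `I_A` and optionally
#' `I_A_direct`; one row per frame per molecule.
#'
#' @param path CSV path.
#' @param frame_rate Frames per second of the recording.
#' @return A named list of [fret_trace()] objects.
#' @export
read_fret_traces <- function(path, frame_rate = 10) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "frame", "I_D", "I_A")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_fret_traces(): missing column(s): ",
         paste(miss, collapse = ", "))
  has_direct <- "I_A_direct" %in% names(d)
  out <- lapply(split(d, d$molecule_id), function(m) {
    m <- m[order(m$frame), ]
    fret_trace(m$I_D, m$I_A,
               if (has_direct) m$I_A_direct else NULL,
               frame_rate = frame_rate,
               molecule_id = as.character(m$molecule_id[1]))
  })
  out[order(names(out))]
}

#' Write FRET traces to a tidy CSV
#'
#' @param traces List of [fret_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fret_traces <- function(traces, path) {
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    id <- if (is.na(tr$molecule_id)) sprintf("mol%04d", i) else tr$molecule_id
    data.frame(molecule_id = id, frame = seq_len(n_frames(tr)),
               I_D = tr$donor, I_A = tr$acceptor,
               I_A_direct = if (is.null(tr$direct_acceptor)) NA
                            else tr$direct_acceptor)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Detect intensity steps by cumulative-sum change-point search
#'
#' Recursive binary segmentation: each candidate split is scored by the
#' standardised mean-shift statistic
#' \eqn{T(k) = \sqrt{k(n-k)/n}\,|\bar x_{1:k} - \bar x_{k+1:n}|/\hat\sigma},
#' where \eqn{\hat\sigma} is the robust noise scale estimated from the
#' median absolute deviation of first differences. A split is accepted when
#' `max T > threshold` *and* the mean shift itself exceeds
#' `threshold` times the robust noise SD (default 3x) - the size criterion
#' suppresses the spurious change points that pure scan statistics produce
#' on long noisy traces; segmentation then recurses into both halves.
#' Deterministic given the trace.
#'
#' @param x Numeric vector.
#' @param threshold Detection threshold in noise-SD units.
#' @param min_segment Smallest segment length considered (default 3).
#' @param sigma Optional noise scale override; estimated when `NULL`.
#' @return A data frame with one row per step: `index` (last frame before
#'   the step), `size` (signed change in segment mean), `stat`.
#' @export
detect_steps <- function(x, threshold = 3, min_segment = 3L, sigma = NULL) {
  n <- length(x)
  sigma_global <- sigma
  if (is.null(sigma_global)) {
    sigma_global <- mad(diff(x)) / sqrt(2)
    if (!is.finite(sigma_global) || sigma_global <= 0)
      # noiseless trace: any mean shift is infinitely significant, so use
      # a floor far below the data scale rather than the step-inflated SD
      sigma_global <- max(max(abs(x)) * 1e-9, .Machine$double.eps)
  }
  steps <- list()
  segment <- function(from, to) {
    m <- to - from + 1L
    if (m < 2L * min_segment) return(invisible())
    xs <- x[from:to]
    # local noise scale: noise can differ widely between segments (e.g.
    # background after a bleach), so the test uses this segment's noise
    s <- mad(diff(xs)) / sqrt(2)
    sigma <- if (!is.finite(s) || s <= 0) sigma_global else max(s, 1e-12)
    k <- seq_len(m - 1L)
    cum <- cumsum(xs)
    mean_l <- cum[k] / k
    mean_r <- (cum[m] - cum[k]) / (m - k)
    stat <- sqrt(k * (m - k) / m) * abs(mean_l - mean_r) / sigma
    ok <- k >= min_segment & (m - k) >= min_segment
    if (!any(ok)) return(invisible())
    stat[!ok] <- -Inf
    kbest <- which.max(stat)
    if (stat[kbest] > threshold &&
        abs(mean_r[kbest] - mean_l[kbest]) > threshold * sigma) {
      steps[[length(steps) + 1L]] <<- data.frame(
        index = from + kbest - 1L,
        size = mean_r[kbest] - mean_l[kbest],
        stat = stat[kbest])
      segment(from, from + kbest - 1L)
      segment(from + kbest, to)
    }
    invisible()
  }
  segment(1L, n)
  if (length(steps) == 0L)
    return(data.frame(index = integer(0), size = numeric(0),
                      stat = numeric(0)))
  out <- do.call(rbind, steps)
  out[order(out$index), , drop = FALSE]
}

#' Locate the photobleach point of a trace
#'
#' Returns the index of the last frame before the first photobleach step;
#' the full trace length when none is found. Frames after this index are
#' excluded from proximity-ratio accumulation.
#'
#' A donor bleach is detected as a downward step in the total intensity
#' (donor + acceptor). Conformational transitions conserve the total, so
#' they are not mistaken for bleaching; but so does an acceptor bleach
#' (the donor rises in compensation), which is instead detected as a
#' downward step in the direct-excitation acceptor channel - that channel
#' carries no conformational dynamics. When no direct-excitation channel
#' is present only the total is scanned (`channel = "total"` forces this).
#'
#' @param trace A [fret_trace()].
#' @param threshold Step-detection threshold in noise-SD units.
#' @param channel `"auto"` (default: total plus direct-excitation when
#'   present) or `"total"`.
#' @return Integer index of the last valid frame.
#' @export
detect_photobleach <- function(trace, threshold = 3,
                               channel = c("auto", "total")) {
  channel <- match.arg(channel)
  n <- n_frames(trace)
  if (n < 10L) stop("detect_photobleach(): trace shorter than 10 frames")
  first_down <- function(x) {
    st <- detect_steps(x, threshold = threshold)
    down <- st[st$size < 0, , drop = FALSE]
    if (nrow(down) == 0L) n else as.integer(down$index[1L])
  }
  out <- first_down(trace$donor + trace$acceptor)
  if (channel == "auto" && !is.null(trace$direct_acceptor))
    out <- min(out, first_down(trace$direct_acceptor))
  out
}

#' Per-frame proximity ratio
#'
#' The raw (uncorrected) FRET efficiency
#' \eqn{E_t = I_{A,t} / (I_{A,t} + I_{D,t})}; no gamma, crosstalk or
#' background corrections are applied anywhere in this package. Frames with
#' non-positive total intensity are returned as `NA` (flagged and skipped
#' downstream).
#'
#' @param trace A [fret_trace()].
#' @param upto Last frame to include, typically from [detect_photobleach()].
#' @return Numeric vector of proximity ratios of length `upto`.
#' @export
proximity_ratio <- function(trace, upto = n_frames(trace)) {
  if (upto < 1L || upto > n_frames(trace))
    stop("proximity_ratio(): 'upto' out of range")
  iD <- trace$donor[seq_len(upto)]
  iA <- trace$acceptor[seq_len(upto)]
  tot <- iD + iA
  E <- ifelse(tot > 0, iA / tot, NA_real_)
  if (anyNA(E))
    attr(E, "n_flagged") <- sum(is.na(E))
  E
}

#' Select traces with a single active donor-acceptor pair
#'
#' Applies the alternating-illumination acceptance rules: (a) the
#' direct-excitation acceptor channel must show real signal before its
#' bleach (proves an active acceptor); (b) donor, acceptor and
#' direct-excitation channels must each bleach in at most one step
#' (multi-step bleaching indicates an aggregate); (c) when the acceptor
#' bleaches before the donor, the donor intensity must rise at that frame
#' (anticorrelation expected for a true FRET pair).
#'
#' @param traces List of [fret_trace()] objects (each needs a
#'   direct-excitation channel).
#' @param direct_threshold Minimum mean direct-excitation signal, in units
#'   of its own robust noise SD (default 5).
#' @param threshold Step-detection threshold.
#' @return The accepted subset, with a data frame of per-trace decisions in
#'   attribute `"selection"`.
#' @export
select_single_pairs <- function(traces, direct_threshold = 5,
                                threshold = 3) {
  if (length(traces) == 0L) {
    warning("select_single_pairs(): empty input")
    out <- list(); attr(out, "selection") <-
      data.frame(molecule_id = character(0), accepted = logical(0),
                 reason = character(0))
    return(out)
  }
  decide <- function(tr) {
    if (is.null(tr$direct_acceptor))
      return("no direct-excitation channel")
    n <- n_frames(tr)
    dir <- tr$direct_acceptor
    dir_steps <- detect_steps(dir, threshold = threshold)
    dir_down <- dir_steps[dir_steps$size < 0, , drop = FALSE]
    dir_end <- if (nrow(dir_down)) dir_down$index[1L] else n
    noise <- mad(diff(dir)) / sqrt(2)
    if (!is.finite(noise) || noise <= 0) noise <- 1
    if (mean(dir[seq_len(dir_end)]) < direct_threshold * noise)
      return("no active acceptor (direct channel dark)")
    # bleach steps are counted on channels free of conformational
    # dynamics: the direct-excitation channel for the acceptor, the total
    # emission for the donor (transitions conserve the total; an acceptor
    # bleach does too, since the donor rises in compensation)
    if (nrow(dir_down) > 1L)
      return("multi-step acceptor bleach")
    total_steps <- detect_steps(tr$donor + tr$acceptor,
                                threshold = threshold)
    total_down <- total_steps[total_steps$size < 0, , drop = FALSE]
    if (nrow(total_down) > 1L) return("multi-step donor bleach")
    # acceptor bleaches while the donor is still alive: donor must rise
    if (nrow(dir_down) == 1L) {
      ak <- dir_down$index[1L]
      donor_alive <- nrow(total_down) == 0L || total_down$index[1L] > ak
      if (donor_alive) {
        d_steps <- detect_steps(tr$donor, threshold = threshold)
        up <- d_steps[d_steps$size > 0 & abs(d_steps$index - ak) <= 2L, ,
                      drop = FALSE]
        if (nrow(up) == 0L)
          return("no anticorrelated donor rise at acceptor bleach")
      }
    }
    "accepted"
  }
  reasons <- vapply(traces, decide, "")
  ids <- vapply(seq_along(traces), function(i) {
    id <- traces[[i]]$molecule_id
    if (is.na(id)) sprintf("mol%04d", i) else id
  }, "")
  accepted <- reasons == "accepted"
  out <- traces[accepted]
  attr(out, "selection") <- data.frame(
    molecule_id = ids, accepted = accepted, reason = reasons,
    stringsAsFactors = FALSE)
  out
}

#' Classify a molecule as static or dynamic
#'
#' A molecule is called dynamic when its proximity-ratio trace contains at
#' least one change point at which the donor and acceptor intensities step
#' in opposite directions while the total intensity is conserved (within
#' `total_tol` of its mean) - the signature of a genuine conformational
#' transition as opposed to focus drift (correlated steps) or bleaching
#' (total intensity drops).
#'
#' @param trace A [fret_trace()].
#' @param upto Last valid frame (before photobleaching).
#' @param threshold Step-detection threshold.
#' @param total_tol Allowed fractional change in total intensity across a
#'   transition (default 0.25).
#' @return `"static"`, `"dynamic"`, or `"indeterminate"` for traces shorter
#'   than 20 valid frames.
#' @export
classify_dynamics <- function(trace, upto = n_frames(trace), threshold = 3,
                              total_tol = 0.25) {
  if (upto < 20L) return("indeterminate")
  E <- proximity_ratio(trace, upto)
  ok <- !is.na(E)
  if (sum(ok) < 20L) return("indeterminate")
  e_steps <- detect_steps(E[ok], threshold = threshold)
  if (nrow(e_steps) == 0L) return("static")
  iD <- trace$donor[seq_len(upto)][ok]
  iA <- trace$acceptor[seq_len(upto)][ok]
  tot <- iD + iA
  mtot <- mean(tot)
  for (k in e_steps$index) {
    lo <- max(1L, k - 4L); hi <- min(length(iD), k + 4L)
    d_step <- mean(iD[(k + 1L):hi]) - mean(iD[lo:k])
    a_step <- mean(iA[(k + 1L):hi]) - mean(iA[lo:k])
    t_step <- mean(tot[(k + 1L):hi]) - mean(tot[lo:k])
    if (sign(d_step) * sign(a_step) < 0 &&
        abs(t_step) <= total_tol * mtot)
      return("dynamic")
  }
  "static"
}
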