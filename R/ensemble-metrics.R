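#' Radius-of-gyration distribution of an ensemble
#'
#' Per-frame \eqn{R_g = \sqrt{\sum_i w_i |r_i - r_{cm}|^2 / \sum_i w_i}}
#' with uniform weights by default or atomic masses when
#' `mass_weighted = TRUE` (the reference analyses do not state their
#' weighting; uniform is the default here).
#'
#' @param traj A [conformer_trajectory()].
#' @param mass_weighted Weight atoms by element mass.
#' @param bin_width Histogram bin width in Angstrom.
#' @return An object of class `rg_distribution` with per-frame `values`
#'   (Angstrom), histogram `breaks`/`density`, and the `mode` (midpoint of
#'   the densest bin).
#' @export
radius_of_gyration <- function(traj, mass_weighted = FALSE, bin_width = 1) {
  nf <- count_frames(traj)
  if (nf < 1L) stop("radius_of_gyration(): empty trajectory")
  n <- nrow(traj$atoms)
  if (n == 0L) stop("radius_of_gyration(): no atoms")
  w <- if (mass_weighted) {
    m <- ATOMIC_MASS[traj$atoms$element]
    if (anyNA(m))
      stop("radius_of_gyration(): unknown element(s): ",
           paste(unique(traj$atoms$element[is.na(m)]), collapse = ", "))
    m
  } else rep(1, n)
  w <- w / sum(w)
  values <- vapply(seq_len(nf), function(f) {
    xyz <- matrix(traj$xyz[, , f], ncol = 3L)
    cm <- colSums(xyz * w)
    d2 <- (xyz[, 1] - cm[1])^2 + (xyz[, 2] - cm[2])^2 +
      (xyz[, 3] - cm[3])^2
    sqrt(sum(w * d2))
  }, 0)
  breaks <- seq(floor(min(values)), ceiling(max(values)) + bin_width,
                by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  structure(list(values = values, breaks = h$breaks, density = h$density,
                 mode = h$mids[which.max(h$density)],
                 mass_weighted = mass_weighted),
            class = "rg_distribution")
}

#' @export
print.rg_distribution <- function(x, ...) {
  cat(sprintf(
    "<rg_distribution> %d frames: mode %.1f A, mean %.1f A, range %.1f-%.1f A\n",
    length(x$values), x$mode, mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Residue contact-frequency map
#'
#' Two residues are in contact in a frame when any pair of their heavy
#' atoms (element != H, main chain or side chain) lies within `cutoff`;
#' the map entry is the fraction of frames in contact. Sequential
#' neighbours (`|i - j| < min_separation`, default 2, i.e. nonsequential
#' residues only) are excluded and fixed at zero, as are diagonal entries.
#'
#' @param traj A [conformer_trajectory()].
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 6.5, i.e.
#'   0.65 nm).
#' @param min_separation Minimum residue-index separation (default 2).
#' @return An object of class `contact_map`: symmetric `n x n` probability
#'   matrix `map` plus parameters.
#' @export
contact_frequency_map <- function(traj, cutoff = 6.5, min_separation = 2L) {
  nf <- count_frames(traj)
  if (nf < 1L) stop("contact_frequency_map(): empty trajectory")
  heavy <- which(toupper(traj$atoms$element) != "H")
  if (length(heavy) == 0L)
    stop("contact_frequency_map(): no heavy atoms in roster")
  res_ids <- sort(unique(traj$atoms$resno))
  n_res <- length(res_ids)
  res_of <- match(traj$atoms$resno[heavy], res_ids)
  counts <- matrix(0, n_res, n_res)
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$xyz[, , f], ncol = 3L)[heavy, , drop = FALSE]
    d <- as.matrix(stats::dist(xyz))
    close_pairs <- which(d <= cutoff, arr.ind = TRUE)
    close_pairs <- close_pairs[close_pairs[, 1] < close_pairs[, 2], ,
                               drop = FALSE]
    if (nrow(close_pairs) == 0L) next
    ri <- res_of[close_pairs[, 1]]
    rj <- res_of[close_pairs[, 2]]
    keep <- abs(res_ids[ri] - res_ids[rj]) >= min_separation
    if (!any(keep)) next
    pr <- unique(cbind(pmin(ri[keep], rj[keep]),
                       pmax(ri[keep], rj[keep])))
    counts[pr] <- counts[pr] + 1
  }
  map <- counts / nf
  map <- map + t(map)       # computed once per unordered pair, mirrored
  dimnames(map) <- list(res_ids, res_ids)
  structure(list(map = map, n_residues = n_res, residues = res_ids,
                 cutoff = cutoff, min_separation = min_separation,
                 n_frames = nf),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %d residues, %d frames, cutoff %.2f A, |i-j| >= %d\n",
    x$n_residues, x$n_frames, x$cutoff, x$min_separation))
  cat(sprintf("  %d pairs with nonzero contact probability\n",
              sum(x$map[upper.tri(x$map)] > 0)))
  invisible(x)
}

#' Write a contact map as a square CSV matrix
#'
#' @param cmap A `contact_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cmap, path) {
  write.csv(as.data.frame(cmap$map), path, row.names = TRUE)
  invisible(path)
}
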