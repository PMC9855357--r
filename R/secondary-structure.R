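# Backbone atom bookkeeping: per-residue indices of N, H, CA, C, O atoms,
# residues ordered by (chain, resno).
backbone_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno)
  res <- unique(data.frame(chain = atoms$chain, resno = atoms$resno,
                           stringsAsFactors = FALSE))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rkey <- paste(res$chain, res$resno)
  pick <- function(name) {
    idx <- rep(NA_integer_, nrow(res))
    hit <- which(atoms$elety == name)
    idx[match(key[hit], rkey)] <- hit
    idx
  }
  res$N <- pick("N"); res$H <- pick("H"); res$CA <- pick("CA")
  res$C <- pick("C"); res$O <- pick("O")
  res
}

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vnorm(v)

# Reconstruct the amide hydrogen on the bisector from N, the preceding C
# and CA, at 1.01 A from N. Standard geometric placement; the chain's first
# residue has no amide-H donor.
place_amide_h <- function(N, C_prev, CA) {
  d <- unit(unit(N - C_prev) + unit(N - CA))
  N + 1.01 * d
}

#' Detect backbone hydrogen bonds in a conformer
#'
#' Geometric criterion: a hydrogen bond from the amide of residue i to the
#' carbonyl of residue j exists when the N...O distance is within 3.5
#' Angstrom and the N-H...O angle (at the hydrogen) exceeds 120 degrees.
#' The amide hydrogen is reconstructed on the N-H bisector when absent from
#' the coordinates; a chain's first residue has no donor, and the bonded
#' predecessor (j = i - 1) is excluded. Residues lacking backbone atoms are
#' skipped with a warning.
#'
#' @param traj A [conformer_trajectory()] with backbone atoms (N, CA, C, O;
#'   H optional).
#' @param frame Frame index (default 1).
#' @param dist_cutoff N...O distance cutoff in Angstrom.
#' @param angle_cutoff Minimum N-H...O angle in degrees.
#' @return Data frame with one row per bond: `donor`, `acceptor` (residue
#'   numbers), `donor_chain`, `acceptor_chain`, `distance`, `angle`.
#' @export
detect_hbonds <- function(traj, frame = 1L, dist_cutoff = 3.5,
                          angle_cutoff = 120) {
  xyz <- matrix(traj$xyz[, , frame], ncol = 3L)
  bb <- backbone_index(traj$atoms)
  incomplete <- is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O)
  if (any(incomplete))
    warning("detect_hbonds(): skipping ", sum(incomplete),
            " residue(s) with missing backbone atoms")
  n <- nrow(bb)
  # donor list: residue with N, CA and a predecessor in the same chain
  donors <- which(!is.na(bb$N) & !is.na(bb$CA))
  donors <- donors[donors > 1 &
                     bb$chain[donors] == bb$chain[pmax(donors - 1L, 1L)] &
                     !is.na(bb$C[pmax(donors - 1L, 1L)])]
  acceptors <- which(!is.na(bb$O) & !is.na(bb$C))
  out <- list()
  for (i in donors) {
    Ni <- xyz[bb$N[i], ]
    Hi <- if (!is.na(bb$H[i])) xyz[bb$H[i], ] else
      place_amide_h(Ni, xyz[bb$C[i - 1L], ], xyz[bb$CA[i], ])
    for (j in acceptors) {
      if (j == i) next
      if (bb$chain[j] == bb$chain[i] && j == i - 1L) next
      Oj <- xyz[bb$O[j], ]
      dNO <- vnorm(Ni - Oj)
      if (dNO > dist_cutoff) next
      v1 <- Ni - Hi; v2 <- Oj - Hi
      ang <- acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) *
        180 / pi
      if (ang > angle_cutoff)
        out[[length(out) + 1L]] <- data.frame(
          donor = bb$resno[i], acceptor = bb$resno[j],
          donor_chain = bb$chain[i], acceptor_chain = bb$chain[j],
          distance = dNO, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      donor_chain = character(0),
                      acceptor_chain = character(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, out)
}

#' Assign per-residue secondary structure in one frame
#'
#' Pattern-based assignment built on [detect_hbonds()], in the spirit of
#' the Kabsch-Sander rules: n-turns at residue i are hydrogen bonds from
#' the amide of residue i+n to the carbonyl of i (n = 3, 4, 5); two
#' consecutive 4-turns (or 3-/5-turns) make a helix; bridge patterns
#' between strands |i-j| > 2 make sheet; remaining n-turn spans are turn;
#' everything else coil. The 8-class repertoire is collapsed onto the four
#' reported classes ({H, G, I} -> helix, {E, B} -> sheet, {T} -> turn,
#' rest -> coil). Residues without backbone atoms are coil.
#'
#' @inheritParams detect_hbonds
#' @return Character vector over residues (ordered by chain, residue
#'   number) with values in `helix`, `sheet`, `turn`, `coil`; residue
#'   numbers as names.
#' @export
assign_secondary_structure <- function(traj, frame = 1L, dist_cutoff = 3.5,
                                       angle_cutoff = 120) {
  bb <- backbone_index(traj$atoms)
  n <- nrow(bb)
  hb <- withCallingHandlers(
    detect_hbonds(traj, frame, dist_cutoff, angle_cutoff),
    warning = function(w) invokeRestart("muffleWarning"))
  key <- paste(bb$chain, bb$resno)
  hmat <- matrix(FALSE, n, n)   # hmat[donor, acceptor]
  if (nrow(hb)) {
    di <- match(paste(hb$donor_chain, hb$donor), key)
    ai <- match(paste(hb$acceptor_chain, hb$acceptor), key)
    hmat[cbind(di, ai)] <- TRUE
  }
  # turn_n[i]: bond from amide of i+n to carbonyl of i, same chain
  turn_at <- function(nt) {
    v <- rep(FALSE, n)
    i <- seq_len(max(n - nt, 0L))
    ok <- bb$chain[i] == bb$chain[i + nt] &
      bb$resno[i + nt] - bb$resno[i] == nt
    v[i[ok]] <- hmat[cbind(i[ok] + nt, i[ok])]
    v
  }
  t3 <- turn_at(3L); t4 <- turn_at(4L); t5 <- turn_at(5L)
  ss <- rep("coil", n)
  mark <- function(ss, tv, nt, label) {
    for (i in which(tv)) {
      if (i > 1L && tv[i - 1L]) {
        span <- (i):(min(i + nt - 1L, n))
        ss[span][ss[span] == "coil"] <- label
      }
    }
    ss
  }
  ss <- mark(ss, t4, 4L, "helix")
  ss <- mark(ss, t3, 3L, "helix")   # 3-10
  ss <- mark(ss, t5, 5L, "helix")   # pi
  # bridges
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < 3L && bb$chain[i] == bb$chain[j]) next
      if (j <= i) next
      anti <- (hmat[i, j] && hmat[j, i]) ||
        (i > 1L && j < n && i + 1L <= n && j - 1L >= 1L &&
           hmat[i - 1L, j + 1L] && hmat[j - 1L, i + 1L])
      para <- (i > 1L && i + 1L <= n &&
                 hmat[j, i - 1L] && hmat[i + 1L, j]) ||
        (j > 1L && j + 1L <= n && hmat[i, j - 1L] && hmat[j + 1L, i])
      if (anti || para) {
        if (ss[i] == "coil" || ss[i] == "turn") ss[i] <- "sheet"
        if (ss[j] == "coil" || ss[j] == "turn") ss[j] <- "sheet"
      }
    }
  }
  # remaining turn spans
  for (nt in c(3L, 4L, 5L)) {
    tv <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(nt)]]
    for (i in which(tv)) {
      span <- (i + 1L):(i + nt - 1L)
      span <- span[span <= n]
      ss[span][ss[span] == "coil"] <- "turn"
    }
  }
  names(ss) <- bb$resno
  ss
}

#' Secondary-structure occupancy over an ensemble
#'
#' Per-residue frequencies of the four structure classes across frames.
#'
#' @param traj A [conformer_trajectory()].
#' @param ... Passed to [assign_secondary_structure()].
#' @return An object of class `ss_profile`: data frame with columns
#'   `residue`, `helix`, `sheet`, `turn`, `coil` (rows sum to 1).
#' @export
ss_occupancy <- function(traj, ...) {
  nf <- count_frames(traj)
  if (nf < 1L) stop("ss_occupancy(): empty trajectory")
  classes <- c("helix", "sheet", "turn", "coil")
  acc <- NULL
  for (f in seq_len(nf)) {
    ss <- assign_secondary_structure(traj, f, ...)
    m <- vapply(classes, function(cl) as.numeric(ss == cl),
                numeric(length(ss)))
    if (length(ss) == 1L) m <- matrix(m, nrow = 1L,
                                      dimnames = list(NULL, classes))
    acc <- if (is.null(acc)) m else acc + m
  }
  prof <- as.data.frame(acc / nf)
  prof <- cbind(residue = as.integer(names(
    assign_secondary_structure(trajectory_frame(traj, 1L)))), prof)
  structure(prof, class = c("ss_profile", "data.frame"))
}

#' Write a secondary-structure profile as CSV
#'
#' @param profile An `ss_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
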