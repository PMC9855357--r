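#' Conformer trajectory
#'
#' An ordered set of conformer frames sharing one atom roster, the container
#' for ensemble analysis (radius of gyration, contacts, secondary
#' structure). Interchange format is multi-model PDB with an optional
#' per-frame temperature sidecar (replica-exchange temperature label).
#'
#' @param atoms Data frame with one row per atom: `eleno`, `elety` (atom
#'   name, e.g. `"CA"`), `resid` (residue name), `chain`, `resno` (1-based
#'   residue index), `element`.
#' @param xyz Numeric array `c(n_atoms, 3, n_frames)` of coordinates in
#'   Angstrom.
#' @param temperature Optional numeric vector of per-frame temperatures (K).
#' @return An object of class `conformer_trajectory`.
#' @export
conformer_trajectory <- function(atoms, xyz, temperature = NULL) {
  stopifnot(is.data.frame(atoms), length(dim(xyz)) == 3L)
  if (dim(xyz)[1] != nrow(atoms) || dim(xyz)[2] != 3L)
    stop("conformer_trajectory(): xyz must be n_atoms x 3 x n_frames")
  if (!all(is.finite(xyz)))
    stop("conformer_trajectory(): non-finite coordinates")
  if (!is.null(temperature) && length(temperature) != dim(xyz)[3])
    stop("conformer_trajectory(): one temperature per frame required")
  need <- c("elety", "resno", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("conformer_trajectory(): atoms lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!"resid" %in% names(atoms)) atoms$resid <- "GLY"
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"eleno" %in% names(atoms)) atoms$eleno <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, xyz = xyz, temperature = temperature),
            class = "conformer_trajectory")
}

#' @export
print.conformer_trajectory <- function(x, ...) {
  cat(sprintf("<conformer_trajectory> %d frames, %d atoms, %d residues%s\n",
              count_frames(x), nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              if (is.null(x$temperature)) "" else " (temperature labels)"))
  invisible(x)
}

#' @rdname conformer_trajectory
#' @param x A `conformer_trajectory`.
#' @export
count_frames <- function(x) dim(x$xyz)[3]

# Coordinates of frame i as an n_atoms x 3 matrix.
frame_xyz <- function(traj, i) traj$xyz[, , i, drop = TRUE]

#' Extract one frame
#'
#' @param traj A [conformer_trajectory()].
#' @param i Frame index.
#' @return A single-frame `conformer_trajectory`.
#' @export
trajectory_frame <- function(traj, i) {
  conformer_trajectory(traj$atoms, traj$xyz[, , i, drop = FALSE],
                       if (!is.null(traj$temperature)) traj$temperature[i])
}

#' Write a trajectory as multi-model PDB
#'
#' Writes one `MODEL`/`ENDMDL` block per frame. Frame temperatures, when
#' present, are written both as `REMARK 250` records and to a sidecar CSV
#' (`<path>.temps.csv`, columns `model`, `temperature_K`) so downstream
#' tools that drop REMARKs keep the metadata.
#'
#' @param traj A [conformer_trajectory()].
#' @param path Output PDB path.
#' @param sidecar Write the temperature sidecar CSV (default `TRUE` when
#'   temperatures are present).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             sidecar = !is.null(traj$temperature)) {
  at <- traj$atoms
  nf <- count_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$temperature))
    writeLines(sprintf("REMARK 250 MODEL %5d TEMPERATURE %8.2f",
                       seq_len(nf), traj$temperature), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_xyz(traj, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$eleno, formatC(at$elety, width = 3, flag = "-"), at$resid,
      at$chain, at$resno, xyz[, 1], xyz[, 2], xyz[, 3], at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (sidecar && !is.null(traj$temperature))
    write.csv(data.frame(model = seq_len(nf),
                         temperature_K = traj$temperature),
              paste0(path, ".temps.csv"), row.names = FALSE)
  invisible(path)
}

# Cheap roster-consistency scan of a multi-model PDB: atom counts and atom
# name sequences must agree across models, reporting the first divergence.
check_pdb_rosters <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) <= 1L) return(invisible(TRUE))
  model_ends <- grep("^ENDMDL", lines)
  sig <- vapply(seq_along(model_starts), function(i) {
    blk <- lines[model_starts[i]:model_ends[i]]
    at <- blk[startsWith(blk, "ATOM") | startsWith(blk, "HETATM")]
    paste(substr(at, 13, 27), collapse = "|")
  }, "")
  div <- which(sig != sig[1])
  if (length(div))
    stop("inconsistent atom roster: model ", div[1],
         " differs from model 1")
  invisible(TRUE)
}

#' Load a multi-model PDB trajectory
#'
#' Frames are ordered by model number. Per-frame replica temperatures are
#' taken from `REMARK 250 MODEL n TEMPERATURE t` records, or from a sidecar
#' CSV (`model`, `temperature_K`) when given (the sidecar wins). The atom
#' roster must be identical across models; the first divergent model is
#' named otherwise.
#'
#' @param path Multi-model PDB path.
#' @param sidecar Optional path to a temperature sidecar CSV; defaults to
#'   `<path>.temps.csv` when that file exists.
#' @return A [conformer_trajectory()].
#' @export
load_trajectory <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("load_trajectory(): no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "ATOM")))
    stop("load_trajectory(): no ATOM records in ", path)
  check_pdb_rosters(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nf <- nrow(pdb$xyz)
  natoms <- nrow(at)
  xyz <- array(NA_real_, c(natoms, 3L, nf))
  for (f in seq_len(nf))
    xyz[, , f] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(eleno = at$eleno, elety = trimws(at$elety),
                      resid = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno, element = trimws(elem),
                      stringsAsFactors = FALSE)
  temperature <- NULL
  rem <- grep("^REMARK 250 MODEL", lines, value = TRUE)
  if (length(rem)) {
    md <- as.integer(sub("^REMARK 250 MODEL\\s+(\\d+).*$", "\\1", rem))
    tk <- as.numeric(sub("^.*TEMPERATURE\\s+([0-9.eE+-]+).*$", "\\1", rem))
    temperature <- rep(NA_real_, nf)
    temperature[md[md <= nf]] <- tk[md <= nf]
    if (all(is.na(temperature))) temperature <- NULL
  }
  if (is.null(sidecar) && file.exists(paste0(path, ".temps.csv")))
    sidecar <- paste0(path, ".temps.csv")
  if (!is.null(sidecar)) {
    sc <- read.csv(sidecar)
    stopifnot(all(c("model", "temperature_K") %in% names(sc)))
    temperature <- rep(NA_real_, nf)
    temperature[sc$model[sc$model <= nf]] <- sc$temperature_K[sc$model <= nf]
  }
  conformer_trajectory(atoms, xyz, temperature)
}

#' Select frames by replica temperature
#'
#' Keeps frames whose temperature label lies in `[t_min, t_max]`, order
#' preserved. No replica-exchange demultiplexing is attempted: selection is
#' purely by the per-frame label.
#'
#' @param traj A [conformer_trajectory()] with temperature metadata.
#' @param t_min,t_max Window bounds in K (default 300-310).
#' @return The windowed trajectory; empty windows return a 0-frame
#'   trajectory with a warning.
#' @export
select_temperature_window <- function(traj, t_min = 300, t_max = 310) {
  if (is.null(traj$temperature))
    stop("select_temperature_window(): trajectory has no temperature ",
         "metadata; skip window selection for unlabelled ensembles")
  keep <- which(!is.na(traj$temperature) &
                  traj$temperature >= t_min & traj$temperature <= t_max)
  if (length(keep) == 0L)
    warning("select_temperature_window(): no frames in [", t_min, ", ",
            t_max, "] K")
  conformer_trajectory(traj$atoms,
                       traj$xyz[, , keep, drop = FALSE],
                       traj$temperature[keep])
}
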