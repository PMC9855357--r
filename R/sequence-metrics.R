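#' Charge composition of a region
#'
#' Counts arginine and lysine as positive, aspartate and glutamate as
#' negative; histidine is treated as neutral at pH 7.4 and termini carry no
#' charge (regions are internal fragments).
#'
#' @param region A [protein_region()].
#' @return A list of class `charge_fractions` with `f_plus`, `f_minus`,
#'   `fcr` (fraction of charged residues, `f_plus + f_minus`) and `ncpr`
#'   (net charge per residue, `f_plus - f_minus`).
#' @examples
#' charge_fractions(protein_region("EKEK"))
#' @export
charge_fractions <- function(region) {
  ch <- region_chars(region)
  n <- length(ch)
  if (n == 0L) stop("charge_fractions(): empty sequence")
  f_plus <- sum(ch %in% AA_POSITIVE) / n
  f_minus <- sum(ch %in% AA_NEGATIVE) / n
  structure(list(f_plus = f_plus, f_minus = f_minus,
                 fcr = f_plus + f_minus, ncpr = f_plus - f_minus),
            class = "charge_fractions")
}

#' @export
print.charge_fractions <- function(x, ...) {
  cat(sprintf("f+ = %.3f  f- = %.3f  FCR = %.3f  NCPR = %+.3f\n",
              x$f_plus, x$f_minus, x$fcr, x$ncpr))
  invisible(x)
}

# Signed charge vector (+1 R/K, -1 D/E, 0 otherwise) for a sequence.
charge_vector <- function(chars) {
  q <- integer(length(chars))
  q[chars %in% AA_POSITIVE] <- 1L
  q[chars %in% AA_NEGATIVE] <- -1L
  q
}

# Per-window charge asymmetry sigma = (f+ - f-)^2 / (f+ + f-) for all
# sliding windows of size g, via cumulative sums. Windows without charges
# have sigma = 0.
window_sigma <- function(q, g) {
  n <- length(q)
  if (g > n) stop("window size ", g, " exceeds sequence length ", n)
  cp <- cumsum(c(0L, q > 0))
  cm <- cumsum(c(0L, q < 0))
  i <- seq_len(n - g + 1L)
  fp <- (cp[i + g] - cp[i]) / g
  fm <- (cm[i + g] - cm[i]) / g
  fcr <- fp + fm
  sig <- numeric(length(i))
  nz <- fcr > 0
  sig[nz] <- (fp[nz] - fm[nz])^2 / fcr[nz]
  sig
}

# Mean squared deviation of window sigma from the whole-sequence sigma.
blob_delta <- function(q, g) {
  n <- length(q)
  fp <- mean(q > 0); fm <- mean(q < 0)
  sig_seq <- if (fp + fm > 0) (fp - fm)^2 / (fp + fm) else 0
  mean((window_sigma(q, g) - sig_seq)^2)
}

# Reference set of maximally segregated arrangements for delta_max: all
# contiguous-block layouts [0^a][+ block][0^b][- block][0^c] with the
# neutral residues distributed over the three gaps (a + b + c = n_neutral).
# Reversal and sign exchange leave delta unchanged, so one orientation
# suffices. For long sequences the (a, b) grid is strided to bound the
# candidate count; the observed arrangement itself is always included,
# which keeps kappa <= 1 by construction.
delta_max_reference <- function(q, windows = c(5L, 6L), max_grid = 96L) {
  np <- sum(q > 0); nm <- sum(q < 0); nz <- sum(q == 0)
  grid_vals <- function(n) {
    if (n <= max_grid) 0:n
    else unique(round(seq(0, n, length.out = max_grid + 1L)))
  }
  candidates <- list(q)
  for (a in grid_vals(nz)) {
    for (b in grid_vals(nz - a)) {
      candidates[[length(candidates) + 1L]] <-
        c(rep(0L, a), rep(1L, np), rep(0L, b), rep(-1L, nm),
          rep(0L, nz - a - b))
    }
  }
  vapply(windows, function(g)
    max(vapply(candidates, blob_delta, 0, g = g)), 0)
}

#' Kappa charge-segregation statistic
#'
#' Implements the blob-based charge-patterning statistic of the diagram-of-
#' states framework: per-window charge asymmetry \eqn{\sigma =
#' (f_+-f_-)^2/(f_++f_-)} is computed over sliding windows of 5 and 6
#' residues; \eqn{\delta} is the mean squared deviation of window
#' \eqn{\sigma} from the whole-sequence value, and kappa is the mean of
#' \eqn{\delta/\delta_{max}} over the two window sizes, where
#' \eqn{\delta_{max}} is the largest \eqn{\delta} over a deterministic set of
#' maximally charge-segregated rearrangements of the same composition
#' (contiguous-block layouts; see [delta_max_reference]'s source). A value of
#' 1 indicates complete segregation of opposite charges, 0 perfect mixing.
#'
#' @param region A [protein_region()] (or a bare sequence string).
#' @param windows Integer vector of blob window sizes.
#' @return Kappa in `[0, 1]`, or `NA` with attribute `reason` when the
#'   region has fewer than two charged residues (kappa undefined).
#' @examples
#' kappa_charge(protein_region("EEEEEKKKKK"))   # fully blocky: 1
#' kappa_charge(protein_region("EKEKEKEKEK"))   # well mixed: small
#' @export
kappa_charge <- function(region, windows = c(5L, 6L)) {
  if (is.character(region)) region <- protein_region(region)
  q <- charge_vector(region_chars(region))
  if (sum(q != 0L) < 2L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 2 charged residues"
    return(out)
  }
  if (max(windows) > length(q))
    stop("kappa_charge(): sequence shorter than blob window")
  dmax <- delta_max_reference(q, windows)
  dobs <- vapply(windows, blob_delta, 0, q = q)
  mean(ifelse(dmax > 0, dobs / dmax, 0))
}

#' Windowed Kyte-Doolittle hydropathy
#'
#' Kyte-Doolittle values are rescaled linearly from \[-4.5, 4.5\] onto
#' \[0, 9\], averaged over sliding windows, and the window means averaged.
#' The 0-9 convention matches the magnitude of the reference hydropathy
#' values for the receptor tails (3.3-3.8).
#'
#' @param region A [protein_region()].
#' @param window Window size in residues (default 5).
#' @return Mean windowed hydropathy on the 0-9 scale.
#' @export
windowed_hydropathy <- function(region, window = 5L) {
  ch <- region_chars(region)
  n <- length(ch)
  if (window < 1L || window > n)
    stop("windowed_hydropathy(): window must be in [1, ", n, "]")
  h <- AA_KYTE_DOOLITTLE[ch] + 4.5
  cs <- cumsum(c(0, h))
  i <- seq_len(n - window + 1L)
  mean((cs[i + window] - cs[i]) / window)
}

#' Diagram-of-states conformational class
#'
#' Classifies a sequence by its charge fractions into the standard
#' polyampholyte/polyelectrolyte regions: weak polyampholyte (globule-prone,
#' FCR < 0.25), intermediate polyampholyte (boundary region,
#' 0.25 <= FCR < 0.35), strong polyampholyte (FCR >= 0.35 with neither
#' charge fraction dominating), or positive/negative polyelectrolyte
#' (one sign's fraction >= 0.35 while the other stays below). Boundary
#' values are assigned deterministically to the more-charged region.
#'
#' @param charges A `charge_fractions` object (or a [protein_region()],
#'   which is converted).
#' @return One of `"weak polyampholyte"`, `"intermediate polyampholyte"`,
#'   `"strong polyampholyte"`, `"positive polyelectrolyte"`,
#'   `"negative polyelectrolyte"`.
#' @export
classify_diagram_of_states <- function(charges) {
  if (inherits(charges, "protein_region")) charges <- charge_fractions(charges)
  fp <- charges$f_plus; fm <- charges$f_minus
  stopifnot(fp >= 0, fm >= 0, fp + fm <= 1)
  if (fm >= 0.35 && fp < 0.35) return("negative polyelectrolyte")
  if (fp >= 0.35 && fm < 0.35) return("positive polyelectrolyte")
  if (fp + fm >= 0.35) return("strong polyampholyte")
  if (fp + fm >= 0.25) return("intermediate polyampholyte")
  "weak polyampholyte"
}

#' Sequence metrics for one region
#'
#' Convenience wrapper bundling the charge fractions, kappa, windowed
#' hydropathy and diagram-of-states class for a region.
#'
#' @inheritParams windowed_hydropathy
#' @return A list of class `sequence_metrics`.
#' @export
sequence_metrics <- function(region, window = 5L) {
  charges <- charge_fractions(region)
  structure(
    list(region = region,
         charges = charges,
         kappa = kappa_charge(region),
         hydropathy = windowed_hydropathy(region, window),
         conformational_class = classify_diagram_of_states(charges)),
    class = "sequence_metrics")
}

#' @export
print.sequence_metrics <- function(x, ...) {
  cat(sprintf("<sequence_metrics> %s [%d-%d]\n", x$region$name,
              x$region$start, x$region$end))
  cat(sprintf("  kappa %.3f  FCR %.3f  NCPR %.3f  hydropathy %.1f  (%s)\n",
              x$kappa, x$charges$fcr, x$charges$ncpr, x$hydropathy,
              x$conformational_class))
  invisible(x)
}

#' Tabulate sequence metrics for several regions
#'
#' @param regions List of [protein_region()] objects.
#' @param window Hydropathy window size.
#' @return A data frame with one row per region and columns `Protein`,
#'   `Sequence`, `Kappa`, `FCR`, `NCPR`, `Hydropathy`, `Class`.
#' @export
sequence_metrics_table <- function(regions, window = 5L) {
  rows <- lapply(regions, function(r) {
    m <- sequence_metrics(r, window)
    data.frame(Protein = r$name,
               Sequence = sprintf("%d-%d", r$start, r$end),
               Kappa = round(m$kappa, 3),
               FCR = round(m$charges$fcr, 3),
               NCPR = round(m$charges$ncpr, 3),
               Hydropathy = round(m$hydropathy, 1),
               Class = m$conformational_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spacing between residues of a class
#'
#' Finds all occurrences of the pooled residue letters and returns the
#' separations (position differences) between consecutive occurrences, the
#' statistic used to compare arginine and aromatic patterning between
#' sequences.
#'
#' @param region A [protein_region()].
#' @param residue_class Character vector of residue letters to pool, e.g.
#'   `"R"` or `c("F", "Y")`.
#' @return A list of class `spacing_distribution` with `residue_class`,
#'   `positions`, `gaps`, `mean` and `sd` (the latter two `NA` when fewer
#'   than two occurrences).
#' @export
residue_spacing <- function(region, residue_class) {
  residue_class <- toupper(unlist(strsplit(residue_class, "")))
  if (length(residue_class) == 0L)
    stop("residue_spacing(): empty residue class")
  ch <- region_chars(region)
  pos <- which(ch %in% residue_class)
  gaps <- if (length(pos) >= 2L) diff(pos) else integer(0)
  structure(
    list(residue_class = paste(residue_class, collapse = "+"),
         positions = pos, gaps = gaps,
         mean = if (length(gaps)) mean(gaps) else NA_real_,
         sd = if (length(gaps) > 1L) sd(gaps) else NA_real_),
    class = "spacing_distribution")
}

#' Count arginines left unpaired by acidic residues
#'
#' Heuristic pairing arithmetic: acidic residues (D, E) are first paired
#' against lysines; any excess acidics then pair arginines; the return value
#' is the number of arginines left over, `max(0, nR - max(0, (nD+nE) - nK))`.
#' The rule is a reconstruction of a verbal description and is intentionally
#' simple; treat it as replaceable.
#'
#' @param region A [protein_region()].
#' @return Integer count of unpaired arginines.
#' @export
unpaired_arginine_count <- function(region) {
  ch <- region_chars(region)
  nR <- sum(ch == "R"); nK <- sum(ch == "K")
  nAcid <- sum(ch %in% AA_NEGATIVE)
  as.integer(max(0L, nR - max(0L, nAcid - nK)))
}

#' Global pairwise identity and similarity
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gaps
#' (open 10, extend 0.5). Identity is the fraction of alignment columns with
#' identical residues; similarity the fraction of columns whose aligned pair
#' has a positive BLOSUM62 score. Gap columns count in the denominator.
#'
#' @param a,b [protein_region()] objects.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A list with `identity`, `similarity`, `columns` and the aligned
#'   strings.
#' @export
pairwise_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  mat <- data_env$BLOSUM62
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$sequence), Biostrings::AAString(b$sequence),
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(pa)
  aligned <- pa != "-" & pb != "-"
  ident <- sum(aligned & pa == pb)
  simil <- sum(aligned & mat[cbind(
    match(pa[aligned], rownames(mat)), match(pb[aligned], colnames(mat)))] > 0)
  list(identity = ident / ncol_aln,
       similarity = simil / ncol_aln,
       columns = ncol_aln,
       aligned_a = paste(pa, collapse = ""),
       aligned_b = paste(pb, collapse = ""))
}
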