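#!/usr/bin/env Rscript
# Builds the SYNTHETIC surrogate CTD sequences shipped in inst/extdata/.
#
# The surrogates are not the natural GluN2A/GluN2B sequences: they are
# composition-matched stand-ins constructed so that each tabulated region
# reproduces the reference charge counts (FCR/NCPR exactly, given integer
# counts), the kappa charge-segregation values (by swap annealing), the
# arginine/aromatic consecutive-spacing means, and approximately the
# windowed hydropathy. Run from the repository root after installing the
# package; deterministic given the seeds below.

suppressMessages(library(idrctd))

KD1 <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2) + 4.5

# choose `n` of the sorted positions so the mean consecutive gap rounds to
# `target`: endpoints bracketing a span near target*(n-1), interior points
# drawn at random
pick_spaced <- function(positions, n, target) {
  positions <- sort(positions)
  m <- length(positions)
  if (is.null(target)) return(sort(sample(positions, n)))
  span_goal <- target * (n - 1)
  best <- NULL; best_err <- Inf
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    if (b - a - 1 < n - 2) next
    err <- abs((positions[b] - positions[a]) / (n - 1) - target)
    if (err < best_err) { best <- c(a, b); best_err <- err }
  }
  stopifnot(best_err < 0.45)
  interior <- sort(sample(positions[(best[1] + 1):(best[2] - 1)], n - 2))
  sort(c(positions[best[1]], interior, positions[best[2]]))
}

# tune the neutral filler towards a target windowed hydropathy by swapping
# polar residues for leucine (or the reverse)
tune_filler <- function(chars, free_idx, target) {
  h <- function() {
    reg <- protein_region(paste(chars, collapse = ""))
    windowed_hydropathy(reg)
  }
  for (it in 1:4000) {
    cur <- mean(KD1[chars])           # cheap proxy for the window mean
    if (abs(cur - target) < 0.01) break
    if (cur < target) {
      cand <- free_idx[chars[free_idx] %in% c("N", "Q", "S")]
      if (!length(cand)) break
      chars[sample(cand, 1)] <- sample(c("L", "A", "V"), 1)
    } else {
      cand <- free_idx[chars[free_idx] %in% c("L", "A", "V", "G", "T")]
      if (!length(cand)) break
      chars[sample(cand, 1)] <- sample(c("N", "Q"), 1)
    }
  }
  chars
}

# anneal the charge classes of the non-fixed positions towards a kappa
# target, keeping `fixed_pos` (the arginine layout) in place
anneal_charges <- function(q, fixed_pos, target, tol = 0.01,
                           max_iter = 1e5) {
  windows <- c(5L, 6L)
  dmax <- idrctd:::delta_max_reference(q, windows)
  energy <- function(qv)
    abs(idrctd:::kappa_given_dmax(qv, dmax, windows) - target)
  free <- setdiff(seq_along(q), fixed_pos)
  e <- energy(q); temp <- 0.02; cool <- 0.9995; it <- 0L
  while (e > tol && it < max_iter) {
    it <- it + 1L
    ij <- sample(free, 2L)
    if (q[ij[1]] == q[ij[2]]) next
    q2 <- q; q2[ij] <- q[rev(ij)]
    e2 <- energy(q2)
    if (e2 < e || runif(1) < exp((e - e2) / temp)) { q <- q2; e <- e2 }
    temp <- temp * cool
  }
  stopifnot(e <= tol)
  q
}

build_segment <- function(len, nR, nK, nD, nE, nY, nF, nH,
                          kappa_target, r_gap = NULL, aro_gap = NULL,
                          hydropathy = 3.6, seed = 1) {
  set.seed(seed)
  npos <- nR + nK; nneg <- nD + nE
  nneu <- len - npos - nneg
  # arginines first: their spacing is a hard constraint, so lay them out
  # before annealing the remaining charges around them
  if (!is.null(r_gap)) {
    span <- round(r_gap * (nR - 1))
    start <- sample(2:(len - span - 1), 1)
    interior <- sort(sample((start + 1):(start + span - 1), nR - 2))
    r_idx <- c(start, interior, start + span)
  } else {
    r_idx <- sort(sample(len, nR))
  }
  q <- integer(len)
  q[r_idx] <- 1L
  rest <- setdiff(seq_len(len), r_idx)
  fill_classes <- sample(c(rep(1L, nK), rep(-1L, nneg),
                           rep(0L, nneu)))
  q[rest] <- fill_classes
  q <- anneal_charges(q, r_idx, kappa_target)
  chars <- character(len)
  chars[r_idx] <- "R"
  pos_idx <- which(q > 0)
  neg_idx <- which(q < 0)
  neu_idx <- which(q == 0L)
  chars[setdiff(pos_idx, r_idx)] <- "K"
  d_idx <- sort(sample(neg_idx, nD))
  chars[d_idx] <- "D"
  chars[setdiff(neg_idx, d_idx)] <- "E"
  stopifnot(sum(chars == "R") == nR, sum(chars == "K") == nK)
  aro_idx <- pick_spaced(neu_idx, nY + nF, aro_gap)
  aro_letters <- sample(c(rep("Y", nY), rep("F", nF)))
  chars[aro_idx] <- aro_letters
  rest <- setdiff(neu_idx, aro_idx)
  h_idx <- sort(sample(rest, nH))
  chars[h_idx] <- "H"
  free_idx <- setdiff(rest, h_idx)
  base <- c(S = 0.30, N = 0.18, G = 0.14, T = 0.12, P = 0.08,
            Q = 0.08, A = 0.06, L = 0.04)
  fill <- sample(rep(names(base),
                     times = ceiling(base * length(free_idx) + 1)))
  chars[free_idx] <- fill[seq_along(free_idx)]
  chars <- tune_filler(chars, free_idx, hydropathy)
  paste(chars, collapse = "")
}

build_filler <- function(len, npos = 0, nneg = 0, hydropathy = 3.5,
                         seed = 1) {
  set.seed(seed)
  chars <- character(len)
  charged <- sample(len, npos + nneg)
  chars[charged[seq_len(npos)]] <-
    sample(c("R", "K"), npos, replace = TRUE)
  if (nneg > 0)
    chars[charged[npos + seq_len(nneg)]] <-
      sample(c("D", "E"), nneg, replace = TRUE)
  free_idx <- which(chars == "")
  base <- c(S = 0.26, N = 0.16, G = 0.14, T = 0.12, P = 0.08,
            Q = 0.08, A = 0.08, L = 0.05, Y = 0.03)
  fill <- sample(rep(names(base),
                     times = ceiling(base * length(free_idx) + 1)))
  chars[free_idx] <- fill[seq_along(free_idx)]
  chars <- tune_filler(chars, free_idx, hydropathy)
  paste(chars, collapse = "")
}

## --- surrogate GluN2A chain, 1464 residues -------------------------------
# region budget (charge counts chosen to reproduce the tabulated FCR/NCPR):
#   CTD1A 873-1211  (339 aa): 50+/47-  kappa 0.138, hydropathy 3.3
#   CTD2A 1243-1464 (222 aa): 30+/28-  kappa 0.204, hydropathy 3.6,
#         R spacing mean 10, aromatic (F+Y) spacing mean 21, Y-dominated
#   linkers 838-872 + 1212-1242 (66 aa): 8+/2-
pre_a   <- build_filler(837, 0, 0, 3.5, seed = 2001)
link_a1 <- build_filler(35, 4, 1, 3.5, seed = 2002)
ctd1a   <- build_segment(339, nR = 18, nK = 32, nD = 21, nE = 26,
                         nY = 6, nF = 3, nH = 6, kappa_target = 0.138,
                         hydropathy = 3.3, seed = 2003)
link_a2 <- build_filler(31, 4, 1, 3.5, seed = 2004)
ctd2a   <- build_segment(222, nR = 19, nK = 11, nD = 14, nE = 14,
                         nY = 8, nF = 2, nH = 4, kappa_target = 0.204,
                         r_gap = 10, aro_gap = 21,
                         hydropathy = 3.6, seed = 2005)
glun2a <- paste0(pre_a, link_a1, ctd1a, link_a2, ctd2a)
stopifnot(nchar(glun2a) == 1464)

## --- surrogate GluN2B chain, 1482 residues -------------------------------
#   CTD1B 874-1212  (339 aa): 51+/48-  kappa 0.176, hydropathy 3.4
#   CTD2B 1250-1482 (233 aa): 27+/21-  kappa 0.221, hydropathy 3.8,
#         R spacing mean 19, aromatic spacing mean 22, F-dominated
#   linkers 838-873 + 1213-1249 (73 aa): 9+/2-
pre_b   <- build_filler(837, 0, 0, 3.5, seed = 3001)
link_b1 <- build_filler(36, 5, 1, 3.5, seed = 3002)
ctd1b   <- build_segment(339, nR = 20, nK = 31, nD = 22, nE = 26,
                         nY = 5, nF = 4, nH = 6, kappa_target = 0.176,
                         hydropathy = 3.4, seed = 3003)
link_b2 <- build_filler(37, 4, 1, 3.5, seed = 3004)
ctd2b   <- build_segment(233, nR = 12, nK = 15, nD = 10, nE = 11,
                         nY = 3, nF = 7, nH = 4, kappa_target = 0.221,
                         r_gap = 19, aro_gap = 22,
                         hydropathy = 3.8, seed = 3005)
glun2b <- paste0(pre_b, link_b1, ctd1b, link_b2, ctd2b)
stopifnot(nchar(glun2b) == 1482)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
regs <- list(
  protein_region(glun2a, "GluN2A_synthetic", 1),
  protein_region(glun2b, "GluN2B_synthetic", 1))
seqs <- Biostrings::AAStringSet(c(glun2a, glun2b))
names(seqs) <- c(
  paste("GluN2A_synthetic SYNTHETIC surrogate of rat GluN2A (cf. UniProt",
        "Q00959): composition-matched stand-in, not the natural sequence"),
  paste("GluN2B_synthetic SYNTHETIC surrogate of rat GluN2B (cf. UniProt",
        "Q00960): composition-matched stand-in, not the natural sequence"))
Biostrings::writeXStringSet(seqs, "inst/extdata/synthetic_ctd_sequences.fasta",
                            width = 60)

regions <- data.frame(
  name = c("GluN2A_CTD", "GluN2B_CTD", "CTD1A", "CTD1B", "CTD2A", "CTD2B"),
  source = "synthetic_ctd_sequences.fasta",
  record = c(1, 2, 1, 2, 1, 2),
  start = c(838, 838, 873, 874, 1243, 1250),
  end = c(1464, 1482, 1211, 1212, 1464, 1482))
write.csv(regions, "inst/extdata/ctd_regions.csv", row.names = FALSE)

# quick self-check
for (i in seq_len(nrow(regions))) {
  r <- read_fasta_region("inst/extdata/synthetic_ctd_sequences.fasta",
                         regions$start[i], regions$end[i],
                         name = regions$name[i], record = regions$record[i])
  m <- sequence_metrics(r)
  cat(sprintf("%-12s kappa %.3f FCR %.3f NCPR %.3f hyd %.2f  %s\n",
              r$name, m$kappa, m$charges$fcr, m$charges$ncpr, m$hydropathy,
              m$conformational_class))
}
for (nm in c("CTD2A", "CTD2B")) {
  i <- match(nm, regions$name)
  r <- read_fasta_region("inst/extdata/synthetic_ctd_sequences.fasta",
                         regions$start[i], regions$end[i], name = nm,
                         record = regions$record[i])
  cat(sprintf("%s: R gap %.2f  aromatic gap %.2f\n", nm,
              residue_spacing(r, "R")$mean,
              residue_spacing(r, c("F", "Y"))$mean))
}
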