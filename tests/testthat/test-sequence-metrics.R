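test_that("charge fractions count R/K as positive and D/E as negative", {
  cf <- charge_fractions(protein_region("EKEK"))
  expect_equal(cf$f_plus, 0.5)
  expect_equal(cf$f_minus, 0.5)
  expect_equal(cf$fcr, 1.0)
  expect_equal(cf$ncpr, 0.0)

  cf0 <- charge_fractions(protein_region("GGGG"))
  expect_equal(cf0$fcr, 0)
  expect_equal(cf0$ncpr, 0)

  # histidine is neutral
  cfh <- charge_fractions(protein_region("HHHH"))
  expect_equal(cfh$fcr, 0)
})

test_that("charge fractions satisfy their identities on random sequences", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_aa(sample(10:80, 1))
    cf <- charge_fractions(protein_region(s))
    ch <- strsplit(s, "")[[1]]
    # independent recount
    expect_equal(cf$f_plus, (sum(ch == "R") + sum(ch == "K")) / nchar(s))
    expect_equal(cf$f_minus, (sum(ch == "D") + sum(ch == "E")) / nchar(s))
    expect_equal(cf$fcr, cf$f_plus + cf$f_minus)
    expect_equal(cf$ncpr, cf$f_plus - cf$f_minus)
    expect_lte(abs(cf$ncpr), cf$fcr)
    expect_lte(cf$fcr, 1)
  }
})

test_that("kappa is 1 for fully segregated charge blocks", {
  expect_equal(kappa_charge("EEEEEEEEEEKKKKKKKKKK"), 1.0, tolerance = 1e-12)
  expect_equal(kappa_charge("KKKKKEEEEE"), 1.0, tolerance = 1e-12)
})

test_that("alternating charges give near-minimal kappa", {
  alt <- kappa_charge("EKEKEKEKEKEKEKEKEKEK")
  expect_lt(alt, 0.01)
  # 12-residue analogue against the independent block-layout oracle
  q_alt <- idrctd:::charge_vector(strsplit("EKEKEKEKEKEK", "")[[1]])
  d_alt <- vapply(c(5L, 6L), idrctd:::blob_delta, 0, q = q_alt)
  dmax <- block_layout_delta_max(6, 6, 12)
  expect_equal(kappa_charge("EKEKEKEKEKEK"), mean(d_alt / dmax),
               tolerance = 1e-9)
})

test_that("the delta_max reference matches independent block enumeration", {
  # the reference convention is the maximum delta over all arrangements in
  # which each charge sign forms one contiguous block; the test enumerates
  # those arrangements by block start positions, independently of the
  # implementation's gap-grid construction
  cases <- list(c(np = 3, nm = 2, L = 10),
                c(np = 2, nm = 2, L = 12),
                c(np = 4, nm = 2, L = 11),
                c(np = 3, nm = 3, L = 12))
  for (cs in cases) {
    q0 <- c(rep(1L, cs["np"]), rep(-1L, cs["nm"]),
            rep(0L, cs["L"] - cs["np"] - cs["nm"]))
    ref <- idrctd:::delta_max_reference(q0, c(5L, 6L))
    oracle <- block_layout_delta_max(cs["np"], cs["nm"], cs["L"])
    expect_equal(ref, oracle, tolerance = 1e-9,
                 label = paste(names(cs), cs, collapse = " "))
  }
})

test_that("kappa lies in [0, 1] for every arrangement of a composition", {
  # exhaustive over all 2520 placements of 3 positive / 2 negative charges
  # in 10 positions
  pos_sets <- utils::combn(10, 3, simplify = FALSE)
  for (ps in pos_sets) {
    rest <- setdiff(1:10, ps)
    for (ns in utils::combn(7, 2, simplify = FALSE)) {
      ch <- rep("G", 10)
      ch[ps] <- "K"
      ch[rest[ns]] <- "E"
      k <- kappa_charge(paste(ch, collapse = ""))
      expect_gte(k, 0)
      expect_lte(k, 1)
    }
  }
})

test_that("kappa is invariant under sequence reversal and bounded by 1", {
  set.seed(7)
  for (i in 1:25) {
    s <- random_aa(sample(15:60, 1))
    k1 <- kappa_charge(s)
    if (is.na(k1)) next
    k2 <- kappa_charge(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(k1, k2, tolerance = 1e-12)
    expect_gte(k1, 0)
    expect_lte(k1, 1)
  }
})

test_that("kappa is undefined below two charges and errors on short input", {
  k <- kappa_charge("GGGGGGGGGR")
  expect_true(is.na(k))
  expect_match(attr(k, "reason"), "charged")
  expect_error(kappa_charge("EKEK"), "shorter than")
})

test_that("windowed hydropathy spans the rescaled 0-9 range", {
  expect_equal(windowed_hydropathy(protein_region("IIIIIIIIII")), 9.0)
  expect_equal(windowed_hydropathy(protein_region("RRRRRRRRRR")), 0.0)
  expect_error(windowed_hydropathy(protein_region("MKTAY"), window = 0),
               "window")
  expect_error(windowed_hydropathy(protein_region("MKTAY"), window = 6),
               "window")
  # single-window degenerate case equals the plain mean
  r <- protein_region("MKTAY")
  kd <- c(M = 1.9, K = -3.9, T = -0.7, A = 1.8, Y = -1.3) + 4.5
  expect_equal(windowed_hydropathy(r, window = 5), mean(kd))
})

test_that("diagram-of-states classification covers the simplex", {
  cls <- function(fp, fm) classify_diagram_of_states(
    structure(list(f_plus = fp, f_minus = fm, fcr = fp + fm,
                   ncpr = fp - fm), class = "charge_fractions"))
  expect_equal(cls(0.5, 0.0), "positive polyelectrolyte")
  expect_equal(cls(0.0, 0.5), "negative polyelectrolyte")
  expect_equal(cls(0.1, 0.1), "weak polyampholyte")
  expect_equal(cls(0.15, 0.15), "intermediate polyampholyte")
  expect_equal(cls(0.2, 0.2), "strong polyampholyte")
  expect_equal(cls(0.4, 0.4), "strong polyampholyte")
  # deterministic boundary rule: boundaries go to the more-charged region
  expect_equal(cls(0.125, 0.125), "intermediate polyampholyte")
  expect_equal(cls(0.175, 0.175), "strong polyampholyte")
  expect_equal(cls(0.35, 0.1), "positive polyelectrolyte")
  # totality on a grid
  for (fp in seq(0, 1, by = 0.05)) for (fm in seq(0, 1 - fp, by = 0.05)) {
    expect_true(cls(fp, fm) %in%
                  c("weak polyampholyte", "intermediate polyampholyte",
                    "strong polyampholyte", "positive polyelectrolyte",
                    "negative polyelectrolyte"))
  }
})

test_that("residue spacing returns consecutive-occurrence gaps", {
  sp <- residue_spacing(protein_region("RGGRGGR"), "R")
  expect_equal(sp$gaps, c(3L, 3L))
  expect_equal(sp$mean, 3)
  expect_equal(sp$sd, 0)

  sp2 <- residue_spacing(protein_region("RR"), "R")
  expect_equal(sp2$gaps, 1L)
  expect_equal(sp2$mean, 1)

  none <- residue_spacing(protein_region("GGGG"), "R")
  expect_length(none$gaps, 0L)
  expect_true(is.na(none$mean))

  pooled <- residue_spacing(protein_region("FGGYGGF"), c("F", "Y"))
  expect_equal(pooled$gaps, c(3L, 3L))
})

test_that("spacing gaps telescope to the occupied span on random strings", {
  set.seed(11)
  for (i in 1:60) {
    s <- random_aa(sample(10:60, 1))
    sp <- residue_spacing(protein_region(s), "R")
    if (length(sp$gaps) == 0L) next
    expect_equal(sum(sp$gaps),
                 max(sp$positions) - min(sp$positions))
    expect_true(all(sp$gaps >= 1L))
    expect_equal(length(sp$gaps), length(sp$positions) - 1L)
  }
})

test_that("unpaired arginine pairing arithmetic follows the stated rule", {
  expect_equal(unpaired_arginine_count(protein_region("RRRR")), 4L)
  expect_equal(unpaired_arginine_count(protein_region("RRDE")), 0L)
  expect_equal(unpaired_arginine_count(protein_region("RRKDE")), 1L)
  expect_equal(unpaired_arginine_count(protein_region("GGGG")), 0L)
  # 4 acidics first neutralise 2 lysines, the excess 2 pair 2 arginines
  expect_equal(unpaired_arginine_count(protein_region("RRRKKDDDD")), 1L)
})

test_that("global alignment identity and similarity behave as expected", {
  a <- protein_region("MKTAY")
  expect_equal(pairwise_identity(a, a)$identity, 1.0)
  expect_equal(pairwise_identity(protein_region("AAAA"),
                                 protein_region("GGGG"))$identity, 0.0)
  pi <- pairwise_identity(a, protein_region("MKSAY"))
  expect_equal(pi$identity, 0.8)
  expect_gte(pi$similarity, pi$identity)  # T/S substitution scores positive
})

test_that("sequence metrics table mirrors the per-region report layout", {
  regions <- read_region_config(fixture_path("ctd_regions.csv"))
  tab <- sequence_metrics_table(regions)
  expect_equal(nrow(tab), 6L)
  expect_named(tab, c("Protein", "Sequence", "Kappa", "FCR", "NCPR",
                      "Hydropathy", "Class"))
})
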