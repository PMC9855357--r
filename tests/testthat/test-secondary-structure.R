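# explicit three-residue construction: donor residue 3 (with predecessor
# C for the amide geometry), acceptor residue 1 at a tunable N...O distance
hb_probe <- function(d_no, angle_deg = 180) {
  mk <- function(elety, resno, x, y, z) {
    data.frame(eleno = NA, elety = elety, resid = "ALA", chain = "A",
               resno = resno, element = substr(elety, 1, 1), x = x,
               y = y, z = z, stringsAsFactors = FALSE)
  }
  # donor N at origin, H at (1,0,0); O placed on the ray from H that makes
  # the requested N-H...O angle with H->N = (-1,0,0), scaled so |N-O| = d_no
  dir <- c(cos(pi - angle_deg * pi / 180), sin(pi - angle_deg * pi / 180), 0)
  f <- function(t) sqrt(sum((c(1, 0, 0) + t * dir)^2)) - d_no
  t <- uniroot(f, c(0.1, 10))$root
  O <- c(1, 0, 0) + t * dir
  at <- rbind(
    mk("N", 1, O[1] + 10, O[2], O[3]),      # far-away scaffolding
    mk("CA", 1, O[1] + 11, O[2], O[3]),
    mk("C", 1, O[1] + 1.2, O[2] + 0.5, O[3]),
    mk("O", 1, O[1], O[2], O[3]),
    mk("N", 2, 20, 20, 0), mk("CA", 2, 21, 20, 0), mk("C", 2, -1.3, 0.9, 0),
    mk("O", 2, 22, 20, 0),
    mk("N", 3, 0, 0, 0), mk("H", 3, 1, 0, 0), mk("CA", 3, -0.9, -1.1, 0),
    mk("C", 3, -2.3, -1.2, 0), mk("O", 3, -2.9, -2.2, 0))
  xyz <- array(unlist(t(at[, c("x", "y", "z")])), c(3, nrow(at), 1))
  xyz <- aperm(xyz, c(2, 1, 3))
  conformer_trajectory(at[, 1:6], xyz)
}

test_that("the geometric hydrogen-bond criterion applies both thresholds", {
  hb <- detect_hbonds(hb_probe(3.4, 150))
  expect_true(any(hb$donor == 3 & hb$acceptor == 1))

  # distance fails at 3.6 A even with ideal alignment
  hb2 <- detect_hbonds(hb_probe(3.6, 170))
  expect_false(any(hb2$donor == 3 & hb2$acceptor == 1))

  # angle fails at 100 degrees even when close
  hb3 <- detect_hbonds(hb_probe(3.0, 100))
  expect_false(any(hb3$donor == 3 & hb3$acceptor == 1))
})

test_that("an ideal helix shows the i+4 -> i backbone ladder", {
  traj <- generate_chain_ensemble(chain_spec(12, "ideal_helix"))
  hb <- detect_hbonds(traj)
  sep <- hb$donor - hb$acceptor
  expect_true(all(sep == 4))
  expect_equal(sort(hb$acceptor), 1:8)  # every i -> i+4 pair present
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(hb$angle > 120))
})

test_that("hydrogen-bond detection matches an exhaustive geometric scan", {
  traj <- generate_chain_ensemble(chain_spec(10, "ideal_helix"))
  hb <- detect_hbonds(traj)
  # independent O(N^2) scan straight off the coordinates
  at <- traj$atoms
  xyz <- traj$xyz[, , 1]
  res <- sort(unique(at$resno))
  found <- character(0)
  for (i in res) for (j in res) {
    if (j == i || j == i - 1) next
    Ni <- xyz[which(at$resno == i & at$elety == "N"), ]
    Hi <- xyz[which(at$resno == i & at$elety == "H"), ]
    Oj <- xyz[which(at$resno == j & at$elety == "O"), ]
    if (!length(Hi) || !length(Ni) || !length(Oj)) next
    dNO <- sqrt(sum((Ni - Oj)^2))
    v1 <- Ni - Hi; v2 <- Oj - Hi
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (dNO <= 3.5 && ang > 120) found <- c(found, paste(i, j))
  }
  expect_setequal(paste(hb$donor, hb$acceptor), found)
})

test_that("reconstructed amide hydrogens support helix detection", {
  traj <- generate_chain_ensemble(chain_spec(10, "ideal_helix"))
  keep <- traj$atoms$elety != "H"
  bare <- conformer_trajectory(traj$atoms[keep, ],
                               traj$xyz[keep, , , drop = FALSE])
  hb <- detect_hbonds(bare)
  expect_true(all(hb$donor - hb$acceptor == 4))
  expect_gte(nrow(hb), 5L)
})

test_that("secondary-structure classes match the fixture geometries", {
  helix <- generate_chain_ensemble(chain_spec(20, "ideal_helix"))
  ss <- assign_secondary_structure(helix)
  interior <- ss[3:18]
  expect_gte(mean(interior == "helix"), 0.9)

  extended <- generate_chain_ensemble(chain_spec(12, "extended"))
  expect_true(all(assign_secondary_structure(extended) == "coil"))

  strands <- generate_chain_ensemble(chain_spec(8, "paired_strands"))
  ss_sheet <- assign_secondary_structure(strands)
  interior <- ss_sheet[!names(ss_sheet) %in% c("1", "9")]
  expect_true(all(interior == "sheet"))
})

test_that("occupancy profiles average assignments over frames", {
  helix1 <- generate_chain_ensemble(chain_spec(14, "ideal_helix"))
  prof <- ss_occupancy(generate_chain_ensemble(
    chain_spec(14, "ideal_helix", n_frames = 3)))
  expect_true(all(abs(rowSums(prof[, c("helix", "sheet", "turn",
                                       "coil")]) - 1) < 1e-9))
  expect_true(all(prof$helix[4:11] == 1))

  # half helix frames, half extended frames: occupancy 0.5 exactly
  ext <- generate_chain_ensemble(chain_spec(14, "extended"))
  xyz <- array(NA_real_, c(nrow(helix1$atoms), 3, 4))
  xyz[, , c(1, 3)] <- helix1$xyz[, , 1]
  xyz[, , c(2, 4)] <- ext$xyz[, , 1]
  mixed <- conformer_trajectory(helix1$atoms, xyz)
  prof2 <- ss_occupancy(mixed)
  helix_res <- which(prof2$helix > 0)
  expect_true(all(prof2$helix[helix_res] == 0.5))

  # CA-only random walks carry no backbone: pure coil
  walk <- generate_chain_ensemble(chain_spec(15, "gaussian", n_frames = 5))
  prof3 <- ss_occupancy(walk)
  expect_true(all(prof3$coil == 1))
})
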