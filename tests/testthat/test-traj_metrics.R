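# small builders
toy_traj <- function(frames, elety = NULL, resid = NULL) {
  n <- nrow(frames[[1]])
  top <- data.frame(
    elety = if (is.null(elety)) rep("CA", n) else elety,
    resid = if (is.null(resid)) rep("ALA", n) else resid,
    resno = seq_len(n))
  trajectory(top, frames)
}

test_that("superposition matches the quaternion oracle and is symmetric", {
  set.seed(1)
  for (rep in 1:10) {
    A <- matrix(rnorm(12, sd = 3), 4, 3)
    B <- matrix(rnorm(12, sd = 3), 4, 3)
    sp <- superpose(A, B)
    expect_equal(sp$rmsd, quaternion_rmsd(A, B), tolerance = 1e-6)
    expect_equal(sp$rmsd, superpose(B, A)$rmsd, tolerance = 1e-6)
    expect_equal(det(sp$R), 1, tolerance = 1e-9)
  }
  # congruent configurations superpose to zero
  A <- matrix(rnorm(30), 10, 3)
  rt <- random_rigid(7)
  B <- sweep(A %*% t(rt$R), 2, rt$t, "+")
  expect_lt(superpose(B, A)$rmsd, 1e-6)
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("RMSD series: static zero and planted ligand drift", {
  set.seed(5)
  base <- matrix(runif(30, 0, 10), 10, 3)
  static <- toy_traj(list(base, base, base))
  expect_equal(rmsd_series(static, "all")$rmsd, rep(0, 3), tolerance = 1e-9)

  # protein fixed, ligand translated +1 A in x per frame
  top <- data.frame(elety = c(rep("CA", 10), rep("C1", 4)),
                    resid = c(rep("ALA", 10), rep("LIG", 4)),
                    resno = c(1:10, rep(11, 4)))
  lig0 <- matrix(runif(12, 20, 24), 4, 3)
  frames <- lapply(0:3, function(k)
    rbind(base, sweep(lig0, 2, c(k, 0, 0), "+")))
  tr <- trajectory(top, frames)
  lr <- rmsd_series(tr, fit_sel = "protein", measure_sel = "ligand")
  expect_equal(lr$rmsd, 0:3, tolerance = 1e-6)
})

test_that("RMSF closed forms hold", {
  set.seed(6)
  base <- matrix(runif(60, 0, 10), 20, 3)
  static <- toy_traj(list(base, base))
  expect_equal(static |> rmsf(sel = "all") |> (`[[`)("rmsf"),
               rep(0, 20), tolerance = 1e-12)
  # one atom oscillating +/- a in x, others fixed (pre-aligned: fit off)
  a <- 0.7
  f1 <- base; f1[3, 1] <- base[3, 1] + a
  f2 <- base; f2[3, 1] <- base[3, 1] - a
  tr <- toy_traj(list(f1, f2, f1, f2))
  vals <- rmsf(tr, sel = "all", fit = FALSE)$rmsf
  expect_equal(vals[3], a, tolerance = 1e-12)
  expect_equal(vals[-3], rep(0, 19), tolerance = 1e-12)
  # isotropic Gaussian jitter: RMSF -> sigma * sqrt(3)
  sig <- 0.2
  set.seed(8)
  frames <- lapply(1:800, function(i)
    base + matrix(rnorm(60, 0, sig), 20, 3))
  jit <- toy_traj(frames)
  mean_rmsf <- mean(rmsf(jit, sel = "all", fit = FALSE)$rmsf)
  expect_equal(mean_rmsf, sig * sqrt(3), tolerance = 0.05)
  # by-residue aggregation returns one row per residue
  expect_equal(nrow(rmsf(jit, sel = "all", by_residue = TRUE)), 20)
  expect_warning(rmsf(toy_traj(list(base)), sel = "all"), "single frame")
})

test_that("radius of gyration matches closed forms and the direct oracle", {
  one <- toy_traj(list(matrix(c(1, 2, 3), 1, 3)))
  expect_equal(radius_of_gyration(one, "all")$average, 0)
  two <- toy_traj(list(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(radius_of_gyration(two, "all")$average, 0.1)  # 1 A in nm
  # uniform ring of radius R
  R <- 3.5
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  ring <- cbind(R * cos(th), R * sin(th), 0)
  expect_equal(radius_of_gyration(toy_traj(list(ring)), "all")$average,
               R / 10, tolerance = 1e-12)
  # mass-weighted definition against a direct oracle with unequal masses
  set.seed(2)
  xyz <- matrix(runif(15, 0, 8), 5, 3)
  top <- data.frame(elety = c("C1", "O1", "N1", "C2", "S1"), resid = "LIG",
                    resno = 1, element = c("C", "O", "N", "C", "S"))
  tr <- trajectory(top, list(xyz))
  m <- tr$topology$mass
  com <- colSums(xyz * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m)) / 10
  expect_equal(radius_of_gyration(tr, "all")$average, oracle,
               tolerance = 1e-9)
  expect_error(radius_of_gyration(tr, "protein"), "empty selection")
})

test_that("Shrake-Rupley agrees with analytic sphere formulas", {
  # isolated atom
  sr <- shrake_rupley(matrix(0, 1, 3), 1.7)
  expect_equal(sr$total, 4 * pi * 3.1^2, tolerance = 1e-9)
  # two equal spheres at varying separation vs the cap formula
  R <- 1.7 + 1.4
  for (d in c(1.0, 2.5, 4.0)) {
    sr2 <- shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.7, 1.7))
    expect_equal(sr2$atom_area[1], two_sphere_exposed_area(R, d),
                 tolerance = 0.02 * two_sphere_exposed_area(R, d))
  }
  # buried atom inside a tight octahedral cage
  cage <- rbind(c(0, 0, 0),
                c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                c(0, 0, 2), c(0, 0, -2))
  srb <- shrake_rupley(cage, c(0.8, rep(2.5, 6)))
  expect_equal(srb$atom_area[1], 0)
  # point-count convergence on a 50-atom toy
  set.seed(13)
  xyz <- matrix(rnorm(150, sd = 4), 50, 3)
  t1 <- shrake_rupley(xyz, rep(1.7, 50), n_points = 960)$total
  t2 <- shrake_rupley(xyz, rep(1.7, 50), n_points = 4000)$total
  expect_lt(abs(t1 - t2) / t2, 0.02)
})

test_that("H-bond distances and occupancy follow their definitions", {
  base <- matrix(c(0, 0, 0, 3, 0, 0, 9, 9, 9), 3, 3, byrow = TRUE)
  tr <- toy_traj(list(base, base))
  pairs <- data.frame(donor = 1, acceptor = 2, label = "d12")
  hb <- hbond_series(tr, pairs)
  expect_equal(hb$d12, c(3, 3))
  expect_equal(hbond_occupancy(hb$d12), 100)
  expect_equal(hbond_occupancy(rep(5, 10)), 0)
  # window edges are inclusive
  expect_equal(hbond_occupancy(c(2.3, 3.2, 4)), 200 / 3)
  expect_error(hbond_occupancy(numeric(0)), "empty")
  expect_error(hbond_series(tr, data.frame(donor = 1, acceptor = 99)),
               "invalid atom id")
  expect_error(hbond_series(tr, data.frame(donor = 1, acceptor = 1)),
               "must differ")
  # distances equal brute-force recomputation
  g <- gen_trajectory(n_frames = 25, seed = 5)
  hb2 <- hbond_series(g$traj, g$hbond_pair)
  brute <- vapply(g$traj$coords, function(m)
    sqrt(sum((m[g$hbond_pair$donor, ] - m[g$hbond_pair$acceptor, ])^2)), 0)
  expect_equal(hb2$planted, brute)
  # occupancy is frame-order invariant
  expect_equal(hbond_occupancy(rev(hb2$planted)),
               hbond_occupancy(hb2$planted))
})

test_that("torsion series unwraps as specified", {
  g <- gen_trajectory(n_frames = 10, torsion_schedule = c(-90), seed = 2)
  ts <- torsion_series(g$traj, g$torsion_atoms)
  expect_equal(ts$X, rep(-90, 10), tolerance = 1e-6)
  expect_equal(ts$Y, rep(270, 10), tolerance = 1e-6)
  expect_equal(ts$Z[1:9], rep(0, 9), tolerance = 1e-6)
  expect_true(is.na(ts$Z[10]))
  # planar cis arrangement: X = Y = 0
  p <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(dihedral(p), 0)
  # general rule: Y = X + 360 exactly when X < 0
  g2 <- gen_trajectory(n_frames = 8,
                       torsion_schedule = c(-150, -10, 20, 170), seed = 3)
  t2 <- torsion_series(g2$traj, g2$torsion_atoms)
  expect_equal(t2$Y, ifelse(t2$X < 0, t2$X + 360, t2$X), tolerance = 1e-9)
  expect_true(all(t2$Y >= 0 & t2$Y < 360))
  # degenerate middle bond is NA, not an error
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_true(is.na(dihedral(lin)))
  expect_error(torsion_series(g$traj, c(1, 2, 3, 3)), "distinct")
})

test_that("GROMOS clustering matches the exhaustive neighbour oracle", {
  # two rigid conformations, 60/40 split
  set.seed(3)
  confA <- matrix(runif(30, 0, 10), 10, 3)
  confB <- matrix(runif(30, 0, 10), 10, 3)  # a different internal geometry
  frames <- c(replicate(12, confA +
                          matrix(rnorm(30, 0, 0.05), 10, 3),
                        simplify = FALSE),
              replicate(8, confB + matrix(rnorm(30, 0, 0.05), 10, 3),
                        simplify = FALSE))
  tr <- toy_traj(frames)
  cl <- cluster_frames(tr, cutoff = 1.0, sel = "all")
  expect_length(cl$clusters, 2)
  expect_lte(cl$representative, 12)  # from the 60% conformation
  expect_equal(sort(cl$clusters[[1]]), 1:12)

  # exhaustive oracle on the same <= 20 frames
  D <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) if (j > i)
    D[i, j] <- D[j, i] <- quaternion_rmsd(frames[[i]], frames[[j]])
  active <- rep(TRUE, 20); oracle_clusters <- list()
  while (any(active)) {
    counts <- vapply(1:20, function(i)
      if (active[i]) sum(D[i, active] <= 1.0) else -1L, 0L)
    c0 <- which.max(counts)
    mem <- which(active & D[c0, ] <= 1.0)
    oracle_clusters[[length(oracle_clusters) + 1]] <- mem
    active[mem] <- FALSE
  }
  expect_equal(cl$clusters, oracle_clusters)

  # identical frames: one cluster, first frame representative
  same <- toy_traj(replicate(5, confA, simplify = FALSE))
  cls <- cluster_frames(same, cutoff = 0.5, sel = "all")
  expect_length(cls$clusters, 1)
  expect_equal(cls$representative, 1)
  expect_error(cluster_frames(tr, window = c(99, 100)), "empty time window")
  # window restricts to late frames and reports the timestamp
  clw <- cluster_frames(tr, window = c(tr$times[15], tr$times[20]),
                        cutoff = 1.0, sel = "all")
  expect_gte(clw$representative, 15)
  expect_equal(clw$representative_time, tr$times[clw$representative])
})

test_that("per-frame metrics are invariant under a global rigid transform", {
  g <- gen_trajectory(n_frames = 12, jitter_sigma = 0.2, seed = 9)
  tr <- g$traj
  rt <- random_rigid(31)
  tr2 <- transform_traj(tr, rt)
  expect_equal(rmsd_series(tr2, "protein")$rmsd,
               rmsd_series(tr, "protein")$rmsd, tolerance = 1e-6)
  expect_equal(radius_of_gyration(tr2, "protein")$series$rg,
               radius_of_gyration(tr, "protein")$series$rg,
               tolerance = 1e-9)
  s1 <- sasa_series(tr, "ligand", frames = 1)$average
  s2 <- sasa_series(tr2, "ligand", frames = 1)$average
  expect_equal(s1, s2, tolerance = 0.02 * s1)
  hb1 <- hbond_series(tr, g$hbond_pair)$planted
  hb2 <- hbond_series(tr2, g$hbond_pair)$planted
  expect_equal(hb1, hb2, tolerance = 1e-9)
})

test_that("trajectory I/O round-trips and validates atom counts", {
  g <- gen_trajectory(n_frames = 5, seed = 4)
  f <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(g$traj, f)
  back <- read_trajectory(f)
  expect_equal(n_frames(back), 5)
  expect_equal(back$coords[[3]], g$traj$coords[[3]], tolerance = 1e-3)
  expect_equal(sum(back$topology$is_ligand), 5)
  expect_equal(sum(back$topology$is_protein), 20)
  # mismatched coordinate file
  g2 <- gen_trajectory(n_frames = 2, n_res = 7, seed = 4)
  f2 <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(g2$traj, f2)
  expect_error(read_trajectory(f, coords_path = f2), "atom-count mismatch")
  expect_error(read_trajectory(f, coords_path = "x.xtc"), "unsupported")
})

test_that("secondary structure classifies ideal fixtures correctly", {
  fx <- gen_ss_fixtures()
  ss_h <- secondary_structure(fx$helix)
  expect_gte(sum(ss_h$classes[1, ] == "H"), 8)
  ss_s <- secondary_structure(fx$sheet)
  cls <- ss_s$classes[1, ]
  # central residues of both strands are sheet
  expect_true(all(cls[c(4, 5)] == "E"))
  expect_true(all(cls[c(11, 12)] == "E"))
  ss_e <- secondary_structure(fx$extended)
  expect_false(any(ss_e$classes[1, ] %in% c("H", "E")))
  # fractions form a proper composition
  for (ss in list(ss_h, ss_s, ss_e))
    expect_equal(rowSums(ss$fractions[, c("H", "E", "T", "S", "C")]),
                 rep(1, nrow(ss$classes)), tolerance = 1e-9)
})

test_that("selection mini-language resolves tags and fields", {
  g <- gen_trajectory(n_frames = 2, n_res = 6, seed = 1)
  tr <- g$traj
  expect_equal(length(select_atoms(tr, "protein")), 6)
  expect_equal(length(select_atoms(tr, "ligand")), 5)
  expect_equal(select_atoms(tr, "resid 3"), 3L)
  expect_equal(select_atoms(tr, "ligand name O1"), 7L)
  expect_equal(select_atoms(tr, c(5, 2, 2)), c(2L, 5L))
  expect_error(select_atoms(tr, "bogus"), "unknown selection")
  helix <- gen_ss_fixtures()$helix
  expect_equal(length(select_atoms(helix, "calpha")), 12)
  expect_equal(length(select_atoms(helix, "backbone")), 36)
  expect_equal(length(select_atoms(helix, "mainchain")), 48)
})
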