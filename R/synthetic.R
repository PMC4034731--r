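#' Generate a planted descriptor-activity table
#'
#' Emulates the structure of the screening training data: `n_rows` pseudo
#' ligands with the ten descriptors drawn uniformly from plausible physical
#' ranges (counts 0-10, E-state sums 0-20, areas 0-200 Angstrom^2, CHI_2
#' 0-10, energies -100-0 kcal/mol, lengths 0-20 Angstrom), and
#' pIC50 = intercept + sum(beta * d) + Normal(0, sigma) with the planted
#' coefficients beta supported on `active`. Rows are split into train/test
#' sets (default 30/7). Deterministic per seed; the ground truth is returned
#' (and optionally serialized) beside the table.
#'
#' @param n_rows number of pseudo ligands.
#' @param active names of descriptors carrying true signal.
#' @param beta true coefficients (same length as `active`).
#' @param intercept true intercept.
#' @param sigma Gaussian noise standard deviation (pIC50 units).
#' @param n_train training-set size (remaining rows are the test set).
#' @param seed RNG seed.
#' @param truth_path optional JSON path for the ground-truth sidecar.
#' @return list with `table` (data.frame: `id`, ten descriptors, `pIC50`,
#'   `split`) and `truth`.
#' @export
gen_qsar_table <- function(n_rows = 37,
                           active = c("ES_Count_aaCH", "CHI_2",
                                      "Shadow_Ylength"),
                           beta = c(0.8, -1.2, 0.5),
                           intercept = 5.0, sigma = 0.1, n_train = 30,
                           seed = 1, truth_path = NULL) {
  stopifnot(length(active) == length(beta), sigma >= 0, n_train <= n_rows)
  nm <- descriptor_names()
  if (!all(active %in% nm)) stop("unknown descriptor in `active`")
  ranges <- list(
    ES_Count_aaCH = c(0, 10), ES_Count_sOH = c(0, 10),
    ES_Sum_aaCH = c(0, 20), ES_Sum_sssN = c(0, 20),
    Num_Rings6 = c(0, 6), Molecular_PolarSurfaceArea = c(0, 200),
    CHI_2 = c(0, 10), Jurs_TPSA = c(0, 200),
    Minimized_Energy = c(-100, 0), Shadow_Ylength = c(0, 20))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  X <- vapply(nm, function(v)
    stats::runif(n_rows, ranges[[v]][1], ranges[[v]][2]), numeric(n_rows))
  colnames(X) <- nm
  y <- intercept + as.numeric(X[, active, drop = FALSE] %*% beta) +
    stats::rnorm(n_rows, 0, sigma)
  split <- rep("test", n_rows)
  split[sample.int(n_rows, n_train)] <- "train"
  table <- cbind(data.frame(id = sprintf("syn%03d", seq_len(n_rows))),
                 as.data.frame(X), data.frame(pIC50 = y, split = split))
  truth <- list(active = active,
                beta = stats::setNames(as.list(beta), active),
                intercept = intercept, sigma = sigma, seed = seed)
  if (!is.null(truth_path))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(table = table, truth = truth)
}

#' Generate a random candidate score table
#'
#' Valid input for the consensus-screening stage: `n` candidates with
#' random SVM/MLR/Bayesian-network pIC50 predictions (uniform 4-9) and dock
#' scores (uniform 50-90), plus a designated control row. The printed
#' screening table itself ships as a fixture via [published_scores()].
#'
#' @param n number of candidates.
#' @param seed RNG seed.
#' @return score table data.frame (see [read_scores()]).
#' @export
gen_score_table <- function(n = 10, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  df <- data.frame(name = sprintf("cand%02d", seq_len(n)),
                   svm = stats::runif(n, 4, 9),
                   mlr = stats::runif(n, 4, 9),
                   bn = stats::runif(n, 4, 9),
                   dock = stats::runif(n, 50, 90),
                   is_control = FALSE)
  rbind(df, data.frame(name = "control", svm = stats::runif(1, 4, 9),
                       mlr = stats::runif(1, 4, 9), bn = stats::runif(1, 4, 9),
                       dock = stats::runif(1, 50, 90), is_control = TRUE))
}

# NeRF internal-coordinate atom placement: position d with |d-c| = bond,
# angle(b,c,d) = ang (deg), dihedral(a,b,c,d) = tor (deg)
nerf_place <- function(a, b, c, bond, ang, tor) {
  th <- ang * pi / 180; ph <- tor * pi / 180
  d2 <- c(-bond * cos(th), bond * cos(ph) * sin(th), bond * sin(ph) * sin(th))
  bc <- unitv(c - b)
  ab <- b - a
  n <- unitv(c(ab[2] * bc[3] - ab[3] * bc[2],
               ab[3] * bc[1] - ab[1] * bc[3],
               ab[1] * bc[2] - ab[2] * bc[1]))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  M <- cbind(bc, m2, n)
  as.numeric(c + M %*% d2)
}

#' Build an ideal poly-alanine backbone from phi/psi angles
#'
#' Standard backbone geometry (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O
#' 1.231 Angstrom; trans peptide bonds). Returns backbone atoms N, CA, C, O
#' per residue.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals in degrees (recycled).
#' @param chain chain identifier.
#' @param resno_start first residue number.
#' @return topology/coordinate list consumable by [trajectory()].
#' @export
build_peptide <- function(n_res, phi = -57, psi = -47, chain = "A",
                          resno_start = 1) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(th), sin(th), 0)
  for (r in 2:n_res) {
    N[r, ]  <- nerf_place(N[r - 1, ], CA[r - 1, ], C[r - 1, ],
                          1.329, 116.2, psi[r - 1])
    CA[r, ] <- nerf_place(CA[r - 1, ], C[r - 1, ], N[r, ], 1.458, 121.7, 180)
    C[r, ]  <- nerf_place(C[r - 1, ], N[r, ], CA[r, ], 1.525, 111.2, phi[r])
  }
  for (r in seq_len(n_res)) {
    O[r, ] <- nerf_place(N[r, ], CA[r, ], C[r, ], 1.231, 120.8, psi[r] + 180)
  }
  top <- data.frame(
    elety = rep(c("N", "CA", "C", "O"), n_res),
    resid = "ALA",
    resno = rep(resno_start + seq_len(n_res) - 1, each = 4),
    chain = chain)
  xyz <- matrix(NA_real_, 4 * n_res, 3)
  for (r in seq_len(n_res)) {
    xyz[(r - 1) * 4 + 1, ] <- N[r, ]
    xyz[(r - 1) * 4 + 2, ] <- CA[r, ]
    xyz[(r - 1) * 4 + 3, ] <- C[r, ]
    xyz[(r - 1) * 4 + 4, ] <- O[r, ]
  }
  list(topology = top, xyz = xyz)
}

.rot180 <- function(axis) {
  switch(axis,
         x = diag(c(1, -1, -1)),
         y = diag(c(-1, 1, -1)),
         z = diag(c(-1, -1, 1)))
}

#' Ideal secondary-structure coordinate fixtures
#'
#' Three single-frame trajectories built from standard backbone geometry: a
#' 12-residue poly-alanine alpha-helix (phi = -57, psi = -47), an
#' antiparallel two-strand sheet (phi = -139, psi = 135; the second strand
#' is a rigid copy placed by a deterministic grid search over offsets and
#' 180-degree flips that maximizes the number of inter-strand backbone
#' H-bonds), and a fully extended chain (phi = psi = 180).
#'
#' @param dir optional directory; when given, each fixture is also written
#'   as a PDB file (`helix.pdb`, `sheet.pdb`, `extended.pdb`).
#' @return named list of [trajectory] objects `helix`, `sheet`, `extended`.
#' @export
gen_ss_fixtures <- function(dir = NULL) {
  helix <- build_peptide(12, phi = -57, psi = -47)
  t_helix <- trajectory(helix$topology, helix$xyz)
  ext <- build_peptide(10, phi = 180, psi = 180)
  t_ext <- trajectory(ext$topology, ext$xyz)

  s1 <- build_peptide(7, phi = -139, psi = 135, chain = "A")
  best <- NULL; best_n <- -1L
  for (axis in c("x", "y", "z")) for (dy in seq(3.8, 5.6, by = 0.2))
    for (dx in seq(-3, 3, by = 0.5)) {
      R <- .rot180(axis)
      xyz2 <- s1$xyz %*% t(R)
      xyz2 <- sweep(xyz2, 2, c(dx, dy, 0) - colMeans(xyz2) + colMeans(s1$xyz),
                    "+")
      top2 <- s1$topology; top2$chain <- "B"
      top2$resno <- top2$resno + 20
      tr <- trajectory(rbind(s1$topology, top2), rbind(s1$xyz, xyz2))
      ne <- sum(secondary_structure(tr)$classes[1, ] == "E")
      if (ne > best_n) { best_n <- ne; best <- tr }
    }
  out <- list(helix = t_helix, sheet = best, extended = t_ext)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_trajectory_pdb(out$helix, file.path(dir, "helix.pdb"))
    write_trajectory_pdb(out$sheet, file.path(dir, "sheet.pdb"))
    write_trajectory_pdb(out$extended, file.path(dir, "extended.pdb"))
  }
  out
}

#' Generate a toy trajectory with planted ground truth
#'
#' A rigid random base structure (pseudo protein of `n_res` CA-only
#' residues plus a small ligand) with per-frame isotropic Gaussian jitter.
#' Two planted observables are exact by construction: the distance between
#' a designated protein-ligand pair is placed inside the 2.3-3.2 Angstrom
#' H-bond window in the first `round(hbond_frac * n_frames)` frames and at
#' 4.5 Angstrom otherwise, and a designated ligand torsion follows
#' `torsion_schedule` (degrees, recycled over frames). Jitter is not
#' applied to the planted atoms.
#'
#' @param n_frames number of frames.
#' @param n_res pseudo-protein residues (one CA per residue).
#' @param jitter_sigma per-coordinate Gaussian jitter (Angstrom).
#' @param hbond_frac planted in-window fraction (0-1).
#' @param torsion_schedule planted dihedral angles in degrees.
#' @param dt frame spacing (ns).
#' @param seed RNG seed.
#' @return list with `traj`, `hbond_pair` (donor/acceptor indices),
#'   `torsion_atoms`, and the planted values (`hbond_frac_realized`,
#'   `torsion_schedule`).
#' @export
gen_trajectory <- function(n_frames = 100, n_res = 20, jitter_sigma = 0.1,
                           hbond_frac = 0.5, torsion_schedule = c(-90),
                           dt = 0.01, seed = 1) {
  stopifnot(hbond_frac >= 0, hbond_frac <= 1, n_frames >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  base_prot <- matrix(stats::runif(n_res * 3, 0, 12), ncol = 3)
  # ligand: donor partner atom + torsion quartet, well separated
  lig_anchor <- c(20, 6, 6)
  torsion_base <- rbind(c(25, 0, 0), c(26.5, 0, 0), c(27.0, 1.4, 0))
  top <- data.frame(
    elety = c(rep("CA", n_res), "O1", "C1", "C2", "C3", "C4"),
    resid = c(rep("ALA", n_res), rep("LIG", 5)),
    resno = c(seq_len(n_res), rep(n_res + 1, 5)),
    chain = c(rep("A", n_res), rep("B", 5)),
    element = c(rep("C", n_res), "O", "C", "C", "C", "C"))
  donor <- 1L                      # protein CA of residue 1
  acceptor <- n_res + 1L           # ligand O1
  tors_atoms <- n_res + 2:5
  sched <- rep_len(torsion_schedule, n_frames)
  m_in <- round(hbond_frac * n_frames)
  coords <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    prot <- base_prot +
      matrix(stats::rnorm(n_res * 3, 0, jitter_sigma), ncol = 3)
    prot[donor, ] <- base_prot[donor, ]   # planted pair stays exact
    d <- if (f <= m_in) 2.75 else 4.5
    acc <- base_prot[donor, ] + d * unitv(lig_anchor - base_prot[donor, ])
    t4 <- nerf_place(torsion_base[1, ], torsion_base[2, ], torsion_base[3, ],
                     1.5, 109.5, sched[f])
    coords[[f]] <- rbind(prot, acc, torsion_base, matrix(t4, 1))
  }
  list(traj = trajectory(top, coords, dt = dt),
       hbond_pair = data.frame(donor = donor, acceptor = acceptor,
                               label = "planted"),
       torsion_atoms = n_res + 2:5,
       hbond_frac_realized = m_in / n_frames,
       torsion_schedule = sched)
}
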