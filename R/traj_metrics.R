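#' RMSD time series
#'
#' Frame 0 is the reference. Each frame is rigid-body fitted (Kabsch) on
#' `fit_sel` and the unweighted RMSD is measured over `measure_sel`; ligand
#' RMSD is the conventional fit-on-protein, measure-on-ligand combination.
#'
#' @param traj a [trajectory].
#' @param fit_sel selection used for superposition.
#' @param measure_sel selection the deviation is measured over (default:
#'   the fit selection).
#' @return data.frame with `time` (ns) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, fit_sel = "protein", measure_sel = fit_sel) {
  fi <- select_atoms(traj, fit_sel)
  mi <- select_atoms(traj, measure_sel)
  if (!length(fi) || !length(mi)) stop("empty selection")
  ref <- traj$coords[[1]]
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    sp <- superpose(traj$coords[[f]], ref, idx = fi)
    raw_rmsd(sp$transform(traj$coords[[f]][mi, , drop = FALSE]),
             ref[mi, , drop = FALSE])
  }, 0)
  data.frame(time = traj$times, rmsd = out)
}

#' Root-mean-square fluctuation
#'
#' All frames are iteratively superposed (on the selection) to their average
#' structure; RMSF_i is the RMS deviation of atom i about its mean position.
#'
#' @param traj a [trajectory].
#' @param sel atom selection.
#' @param by_residue average atom RMSF within each residue.
#' @param fit superpose frames before measuring (set `FALSE` for
#'   pre-aligned trajectories).
#' @return data.frame with atom (or residue) labels and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, sel = "calpha", by_residue = FALSE, fit = TRUE) {
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stop("empty selection")
  nf <- n_frames(traj)
  X <- lapply(traj$coords, function(m) m[idx, , drop = FALSE])
  if (nf == 1) {
    warning("single frame: RMSF is identically zero")
    vals <- rep(0, length(idx))
  } else {
    # fit all frames to frame 1, then refine against the running average;
    # selections too small to superpose are measured in place
    ref <- X[[1]]
    if (fit && length(idx) >= 3) for (it in 1:2) {
      X <- lapply(X, function(m) superpose(m, ref)$transform(m))
      ref <- Reduce(`+`, X) / nf
    } else ref <- Reduce(`+`, X) / nf
    mean_pos <- ref
    vals <- sqrt(Reduce(`+`, lapply(X, function(m)
      rowSums((m - mean_pos)^2))) / nf)
  }
  top <- traj$topology[idx, , drop = FALSE]
  out <- data.frame(resno = top$resno, resid = top$resid, elety = top$elety,
                    rmsf = vals)
  if (by_residue) {
    agg <- stats::aggregate(rmsf ~ resno + resid, data = out, FUN = mean)
    agg[order(agg$resno), ]
  } else out
}

#' Radius of gyration time series
#'
#' Mass-weighted RMS distance from the centre of mass,
#' \eqn{R_g = \sqrt{\sum m_i |r_i - r_{com}|^2 / \sum m_i}}, reported in nm.
#'
#' @param traj a [trajectory].
#' @param sel atom selection.
#' @return list with `series` (data.frame `time`, `rg` in nm), `average`
#'   and `maximum`.
#' @export
radius_of_gyration <- function(traj, sel = "protein") {
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stop("empty selection")
  m <- traj$topology$mass[idx]
  rg <- vapply(traj$coords, function(xyz) {
    x <- xyz[idx, , drop = FALSE]
    com <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m)) / 10  # Angstrom->nm
  }, 0)
  list(series = data.frame(time = traj$times, rg = rg),
       average = mean(rg), maximum = max(rg))
}

#' Solvent-accessible surface area of one frame or a series
#'
#' Shrake-Rupley SASA over the selection (neighbours restricted to the
#' selection). Totals are reported in nm^2; per-atom areas in Angstrom^2.
#'
#' @param traj a [trajectory].
#' @param sel atom selection.
#' @param probe probe radius (Angstrom).
#' @param n_points test points per atom.
#' @param frames frame indices (default all).
#' @return list with `series` (data.frame `time`, `sasa` in nm^2),
#'   `average`, and `atom_area` (Angstrom^2, last computed frame).
#' @export
sasa_series <- function(traj, sel = "protein", probe = 1.4, n_points = 960,
                        frames = seq_len(n_frames(traj))) {
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stop("empty selection")
  radii <- traj$topology$vdw[idx]
  if (anyNA(radii)) {
    warning("missing vdW radii replaced from the element table")
    radii[is.na(radii)] <- element_vdw(traj$topology$element[idx][is.na(radii)])
  }
  last <- NULL
  tot <- vapply(frames, function(f) {
    sr <- shrake_rupley(traj$coords[[f]][idx, , drop = FALSE], radii,
                        probe = probe, n_points = n_points)
    last <<- sr$atom_area
    sr$total / 100  # Angstrom^2 -> nm^2
  }, 0)
  list(series = data.frame(time = traj$times[frames], sasa = tot),
       average = mean(tot), atom_area = last)
}

#' Hydrogen-bond distance series
#'
#' Donor-acceptor heavy-atom distance per frame for each listed pair
#' (optionally hydrogen-acceptor with `use_hydrogen = TRUE` when a hydrogen
#' atom id is given).
#'
#' @param traj a [trajectory].
#' @param pairs data.frame with columns `donor`, `acceptor` (atom indices),
#'   optional `hydrogen` and `label`.
#' @param use_hydrogen measure from the hydrogen instead of the donor heavy
#'   atom.
#' @return data.frame with `time` plus one distance column (Angstrom) per
#'   pair.
#' @export
hbond_series <- function(traj, pairs, use_hydrogen = FALSE) {
  n <- nrow(traj$topology)
  check <- c(pairs$donor, pairs$acceptor,
             if (use_hydrogen) pairs$hydrogen)
  if (any(is.na(check)) || any(check < 1 | check > n))
    stop("invalid atom id in H-bond pair list")
  if (any(pairs$donor == pairs$acceptor))
    stop("donor and acceptor must differ")
  out <- data.frame(time = traj$times)
  for (k in seq_len(nrow(pairs))) {
    a <- if (use_hydrogen) pairs$hydrogen[k] else pairs$donor[k]
    b <- pairs$acceptor[k]
    out[[if (!is.null(pairs$label)) pairs$label[k] else paste0("pair", k)]] <-
      vapply(traj$coords, function(m) vnorm(m[a, ] - m[b, ]), 0)
  }
  out
}

#' Hydrogen-bond occupancy
#'
#' Percentage of frames whose distance lies inside the bonding window
#' (default 2.3-3.2 Angstrom, the optimum-H-bond range; the common
#' donor-acceptor <= 3.5 Angstrom criterion is available by setting
#' `lo = 0, hi = 3.5`).
#'
#' @param distances numeric distance series (Angstrom).
#' @param lo,hi window bounds (inclusive).
#' @return occupancy in percent.
#' @export
hbond_occupancy <- function(distances, lo = 2.3, hi = 3.2) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) stop("empty distance series")
  100 * mean(distances >= lo & distances <= hi)
}

#' Torsion-angle series with unwrapping
#'
#' Per frame: the signed dihedral X in (-180, 180]; the unwrapped angle
#' Y = X + 360 when X < 0 (so Y lies in [0, 360)); and the frame-to-frame
#' increment Z_i = Y_{i+1} - Y_i. A degenerate (collinear) middle bond
#' yields `NA` for that frame.
#'
#' @param traj a [trajectory].
#' @param atoms four distinct atom indices defining the torsion.
#' @param label torsion label.
#' @return data.frame with `time`, `X`, `Y` and `Z` (last `Z` is `NA`).
#' @export
torsion_series <- function(traj, atoms, label = "torsion") {
  atoms <- as.integer(atoms)
  if (length(atoms) != 4 || anyDuplicated(atoms))
    stop("a torsion needs four distinct atoms")
  X <- vapply(traj$coords, function(m) dihedral(m[atoms, , drop = FALSE]), 0)
  Y <- ifelse(X < 0, X + 360, X)
  Z <- c(diff(Y), NA_real_)
  structure(data.frame(time = traj$times, X = X, Y = Y, Z = Z),
            label = label)
}

#' GROMOS conformational clustering
#'
#' Pairwise superposed RMSD matrix over the chosen time window; then
#' repeatedly the frame with the most neighbours within `cutoff` becomes a
#' cluster centre and the cluster is removed. The representative is the
#' centre of the largest cluster (earliest such centre on ties), reported
#' with its timestamp.
#'
#' @param traj a [trajectory].
#' @param window length-2 time range in ns (default: all frames).
#' @param cutoff RMSD cutoff in Angstrom.
#' @param sel atom selection for fitting/measuring.
#' @return list with `clusters` (list of frame-index vectors, original
#'   frame numbering), `centers`, `representative` (frame index) and
#'   `representative_time` (ns).
#' @export
cluster_frames <- function(traj, window = NULL, cutoff = 1.0,
                           sel = "protein") {
  idx <- select_atoms(traj, sel)
  frames <- seq_len(n_frames(traj))
  if (!is.null(window))
    frames <- frames[traj$times >= window[1] & traj$times <= window[2]]
  if (!length(frames)) stop("empty time window")
  nf <- length(frames)
  X <- lapply(frames, function(f) traj$coords[[f]][idx, , drop = FALSE])
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) if (j > i)
    D[i, j] <- D[j, i] <- superpose(X[[i]], X[[j]])$rmsd
  active <- rep(TRUE, nf)
  clusters <- list(); centers <- integer(0)
  while (any(active)) {
    counts <- vapply(seq_len(nf), function(i)
      if (active[i]) sum(D[i, active] <= cutoff) else -1L, 0L)
    c0 <- which.max(counts)   # earliest frame on ties
    members <- which(active & D[c0, ] <= cutoff)
    clusters[[length(clusters) + 1L]] <- frames[members]
    centers <- c(centers, frames[c0])
    active[members] <- FALSE
  }
  sizes <- lengths(clusters)
  top <- which.max(sizes)   # earliest largest cluster on ties
  list(clusters = clusters, centers = centers,
       representative = centers[top],
       representative_time = traj$times[centers[top]])
}
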