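.standard_residues <- c(
  "ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU","LYS",
  "MET","PHE","PRO","SER","THR","TRP","TYR","VAL","HSD","HSE","HSP","MSE")
.solvent_residues <- c("HOH","WAT","TIP","TIP3","SOL","NA","CL","SOD","CLA",
                       "K","MG","CA2")

#' Construct a trajectory
#'
#' Time-ordered frames of labeled atom coordinates over a fixed topology.
#'
#' @param topology data.frame with columns `elety` (atom name), `resid`
#'   (residue name), `resno` (residue number) and optionally `chain`,
#'   `element`, `mass` (Da), `vdw` (Angstrom). Element, mass and radius are
#'   inferred from atom names when absent. The `ligand` tag is inferred as
#'   any non-standard, non-solvent residue.
#' @param coords list of n_atoms x 3 matrices (Angstrom), one per frame, or
#'   a single matrix for a one-frame trajectory.
#' @param times frame times in ns (strictly increasing; default
#'   `0, dt, 2 dt, ...`).
#' @param dt frame spacing in ns used when `times` is absent.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, dt = 0.01) {
  if (is.matrix(coords)) coords <- list(coords)
  n_atoms <- nrow(topology)
  if (!all(vapply(coords, nrow, 0L) == n_atoms))
    stop("every frame must have the topology's atom count")
  if (is.null(times)) times <- (seq_along(coords) - 1) * dt
  if (length(times) != length(coords) ||
      (length(times) > 1 && any(diff(times) <= 0)))
    stop("times must be strictly increasing, one per frame")
  if (is.null(topology$chain)) topology$chain <- "A"
  if (is.null(topology$element))
    topology$element <- .guess_element(topology$elety)
  if (is.null(topology$mass)) topology$mass <- element_mass(topology$element)
  if (is.null(topology$vdw)) topology$vdw <- element_vdw(topology$element)
  if (any(topology$mass <= 0)) stop("masses must be positive")
  topology$is_protein <- topology$resid %in% .standard_residues
  topology$is_ligand <- !topology$is_protein &
    !topology$resid %in% .solvent_residues
  structure(list(topology = topology,
                 coords = lapply(coords, function(m) {
                   m <- as.matrix(m); dimnames(m) <- NULL; m
                 }),
                 times = as.numeric(times)),
            class = "trajectory")
}

.guess_element <- function(elety) {
  nm <- toupper(trimws(elety))
  two <- substr(nm, 1, 2)
  out <- substr(nm, 1, 1)
  out[two %in% c("CL", "BR", "NA", "MG", "FE", "ZN")] <-
    c(CL = "Cl", BR = "Br", NA. = "Na", MG = "Mg", FE = "Fe", ZN = "Zn")[
      match(two[two %in% c("CL", "BR", "NA", "MG", "FE", "ZN")],
            c("CL", "BR", "NA", "MG", "FE", "ZN"))]
  # leading digits (e.g. 1HB) -> element is the first letter
  digit <- grepl("^[0-9]", nm)
  out[digit] <- substr(gsub("^[0-9]+", "", nm[digit]), 1, 1)
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms, %.4g-%.4g ns\n",
              length(x$coords), nrow(x$topology),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(t) length(t$coords)

#' Atom selection mini-language
#'
#' Resolves a selection to atom indices. Accepted forms: an integer or
#' logical index vector; or a string of space-separated terms, AND-combined:
#' `all`, `protein`, `ligand`, `backbone` (N, CA, C), `mainchain`
#' (N, CA, C, O), `sidechain`, `calpha`, `heavy`, `resid <n>`, `name <x>`.
#'
#' @param traj a [trajectory].
#' @param sel selection (default `"all"`).
#' @return sorted integer vector of atom indices.
#' @export
select_atoms <- function(traj, sel = "all") {
  top <- traj$topology
  n <- nrow(top)
  if (is.logical(sel)) return(which(sel))
  if (is.numeric(sel)) return(sort(unique(as.integer(sel))))
  keep <- rep(TRUE, n)
  toks <- strsplit(trimws(sel), "\\s+")[[1]]
  i <- 1
  bb <- c("N", "CA", "C")
  while (i <= length(toks)) {
    tk <- tolower(toks[i])
    keep <- keep & switch(tk,
      all = rep(TRUE, n),
      protein = top$is_protein,
      ligand = top$is_ligand,
      backbone = top$is_protein & top$elety %in% bb,
      mainchain = top$is_protein & top$elety %in% c(bb, "O", "OXT"),
      sidechain = top$is_protein & !top$elety %in% c(bb, "O", "OXT"),
      calpha = top$is_protein & top$elety == "CA",
      heavy = top$element != "H",
      resid = { i <- i + 1; top$resno == as.integer(toks[i]) },
      name = { i <- i + 1; top$elety == toks[i] },
      stop("unknown selection term: ", toks[i]))
    i <- i + 1
  }
  which(keep)
}

#' Read a trajectory from disk
#'
#' The topology is a PDB file; coordinates come from the same multi-model
#' PDB or from a separate DCD file (both read with bio3d). Selection tags
#' are inferred from residue names (ligand = any non-standard, non-solvent
#' residue).
#'
#' @param topology_path PDB file (single- or multi-model).
#' @param coords_path optional DCD (or multi-model PDB) with the frames; by
#'   default the topology file's own models are used.
#' @param dt frame spacing in ns.
#' @return a [trajectory].
#' @export
read_trajectory <- function(topology_path, coords_path = NULL, dt = 0.01) {
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE)
  atom <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  top <- data.frame(elety = atom$elety, resid = atom$resid,
                    resno = atom$resno, chain = ifelse(is.na(atom$chain), "A",
                                                       atom$chain))
  if (!is.null(atom$elesy) && !all(is.na(atom$elesy)) &&
      !all(atom$elesy == ""))
    top$element <- ifelse(is.na(atom$elesy) | atom$elesy == "",
                          .guess_element(atom$elety), trimws(atom$elesy))
  xyz <- pdb$xyz
  if (is.null(coords_path)) {
    M <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  } else {
    ext <- tolower(tools::file_ext(coords_path))
    if (ext == "dcd") M <- bio3d::read.dcd(coords_path, verbose = FALSE)
    else if (ext == "pdb") {
      p2 <- bio3d::read.pdb(coords_path, multi = TRUE)
      M <- if (is.matrix(p2$xyz)) p2$xyz else matrix(p2$xyz, nrow = 1)
    } else stop("unsupported coordinate format '", ext,
                "': use multi-model PDB or DCD")
  }
  if (ncol(M) != 3 * nrow(top))
    stop("atom-count mismatch between topology (", nrow(top),
         ") and coordinates (", ncol(M) / 3, ")")
  coords <- lapply(seq_len(nrow(M)), function(i)
    matrix(M[i, ], ncol = 3, byrow = TRUE))
  trajectory(top, coords, dt = dt)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory].
#' @param path output file.
#' @export
write_trajectory_pdb <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- traj$coords[[f]]
    rec <- ifelse(top$is_protein, "ATOM  ", "HETATM")
    lines <- sprintf(
      "%s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(nrow(top)),
      ifelse(nchar(top$elety) < 4, paste0(" ", top$elety), top$elety),
      top$resid, substr(top$chain, 1, 1), top$resno,
      m[, 1], m[, 2], m[, 3], 1, 0, substr(top$element, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
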