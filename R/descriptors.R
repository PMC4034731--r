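#' @name descriptors
#' @title The ten screening descriptors
#' @description
#' The screening model uses ten descriptors: two E-state atom-type counts
#' (`ES_Count_aaCH`, `ES_Count_sOH`), two E-state sums (`ES_Sum_aaCH`,
#' `ES_Sum_sssN`), the number of six-membered rings (`Num_Rings6`), the
#' fragment-based 2D topological polar surface area
#' (`Molecular_PolarSurfaceArea`, Angstrom^2), the second-order connectivity
#' index (`CHI_2`), the 3D polar solvent-accessible surface area
#' (`Jurs_TPSA`, Angstrom^2), a caller-supplied minimized conformer energy
#' (`Minimized_Energy`, kcal/mol) and the molecular extent along the second
#' principal axis including van der Waals radii (`Shadow_Ylength`, Angstrom).
NULL

#' Names of the ten screening descriptors, in canonical order
#' @export
descriptor_names <- function() {
  c("ES_Count_aaCH", "ES_Count_sOH", "ES_Sum_aaCH", "ES_Sum_sssN",
    "Num_Rings6", "Molecular_PolarSurfaceArea", "CHI_2", "Jurs_TPSA",
    "Minimized_Energy", "Shadow_Ylength")
}

# Ertl fragment contributions for N and O environments (Angstrom^2),
# matched on element, aromaticity, attached-H count, formal charge,
# bond-class counts and 3-ring membership. S/P contributions are available
# behind include_sp (the 2D TPSA default sums N/O only).
.ertl_contribution <- function(el, arom, nH, chg, ns, nd, nt, na_, in3) {
  if (el == "O") {
    if (arom && na_ >= 2) return(13.14)
    if (chg == -1 && ns == 1) return(23.06)
    if (nH >= 1) return(20.23)
    if (nd >= 1) return(17.07)
    if (ns == 2 && in3) return(12.53)
    if (ns == 2) return(9.23)
    return(0)
  }
  if (el == "N") {
    if (arom) {
      if (chg == 1) {
        if (nH >= 1) return(14.14)
        if (ns >= 1) return(3.88)
        return(4.10)
      }
      if (nH >= 1) return(15.79)
      if (na_ >= 3) return(4.41)
      if (ns >= 1) return(4.93)
      if (nd >= 1) return(8.39)
      return(12.89)
    }
    if (chg == 1) {
      if (nH == 3) return(27.64)
      if (nH == 2 && nd == 1) return(25.59)
      if (nH == 2) return(16.61)
      if (nH == 1 && nd == 1) return(13.97)
      if (nH == 1) return(4.44)
      if (nt == 1) return(4.36)
      if (nd == 1) return(3.01)
      return(0.00)
    }
    if (nH >= 2) return(26.02)
    if (nH == 1) {
      if (nd >= 1) return(23.85)
      if (in3) return(21.94)
      return(12.03)
    }
    if (nt == 1 && nd == 1) return(13.60)
    if (nt == 1) return(23.79)
    if (nd == 2) return(11.68)
    if (nd == 1) return(12.36)
    if (in3) return(3.01)
    return(3.24)
  }
  if (el == "S") {
    if (arom && nd >= 1) return(21.70)
    if (arom) return(28.24)
    if (nH >= 1) return(38.80)
    if (nd == 1 && ns == 0) return(32.09)
    if (ns == 2 && nd == 2) return(8.38)
    if (ns == 2 && nd == 1) return(19.21)
    if (ns == 2) return(25.30)
    return(0)
  }
  if (el == "P") {
    if (nH >= 1 && nd == 1) return(23.47)
    if (ns == 3 && nd == 1) return(9.81)
    if (nd == 1) return(34.14)
    if (ns == 3) return(13.59)
    return(0)
  }
  0
}

.bond_class_counts <- function(mol) {
  n <- nrow(mol$atoms)
  ns <- nd <- nt <- na_ <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    ab <- c(mol$bonds$a1[k], mol$bonds$a2[k])
    if (isTRUE(mol$bonds$aromatic[k]) || mol$bonds$order[k] == 4)
      na_[ab] <- na_[ab] + 1L
    else if (mol$bonds$order[k] == 3) nt[ab] <- nt[ab] + 1L
    else if (mol$bonds$order[k] == 2) nd[ab] <- nd[ab] + 1L
    else ns[ab] <- ns[ab] + 1L
  }
  list(ns = ns, nd = nd, nt = nt, na_ = na_)
}

#' Fragment-based topological polar surface area (Ertl)
#'
#' Sum of published fragment contributions over nitrogen and oxygen
#' environments (optionally sulfur/phosphorus). A 2D descriptor: no
#' coordinates needed.
#'
#' @param mol a [molecule].
#' @param include_sp also add S and P contributions (off by default,
#'   matching the common TPSA definition).
#' @return TPSA in Angstrom^2.
#' @export
tpsa <- function(mol, include_sp = FALSE) {
  bc <- .bond_class_counts(mol)
  in3 <- logical(nrow(mol$atoms))
  for (r in mol$rings) if (length(r) == 3) in3[r] <- TRUE
  elems <- if (include_sp) c("N", "O", "S", "P") else c("N", "O")
  tot <- 0
  for (i in which(mol$atoms$element %in% elems)) {
    tot <- tot + .ertl_contribution(
      mol$atoms$element[i], isTRUE(mol$atoms$aromatic[i]), mol$atoms$nH[i],
      mol$atoms$charge[i], bc$ns[i], bc$nd[i], bc$nt[i], bc$na_[i], in3[i])
  }
  tot
}

#' Second-order molecular connectivity index
#'
#' \eqn{^2\chi = \sum_{i-j-k} (\delta_i\delta_j\delta_k)^{-1/2}} over all
#' two-edge paths of the heavy-atom graph, with \eqn{\delta} the heavy-atom
#' degree.
#'
#' @param mol a [molecule].
#' @return the index (dimensionless, >= 0).
#' @export
chi2_index <- function(mol) {
  adj <- adjacency_list(mol)
  deg <- lengths(adj)
  tot <- 0
  for (j in seq_along(adj)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) for (b in seq((a + 1), length(nb))) {
      i <- nb[a]; k <- nb[b]
      tot <- tot + 1 / sqrt(deg[i] * deg[j] * deg[k])
    }
  }
  tot
}

# coordinates (heavy + explicit H) with radii, for surface descriptors
.mol_coords <- function(mol, with_h = TRUE) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  radii <- mol$atoms$vdw
  polar <- mol$atoms$element %in% c("N", "O")
  if (with_h && !is.null(mol$hydrogens) && nrow(mol$hydrogens)) {
    hxyz <- as.matrix(mol$hydrogens[, c("x", "y", "z")])
    xyz <- rbind(xyz, hxyz)
    radii <- c(radii, rep(element_vdw("H"), nrow(hxyz)))
    polar <- c(polar, polar[mol$hydrogens$parent])
  }
  list(xyz = xyz, radii = radii, polar = polar)
}

#' Polar solvent-accessible surface area (3D)
#'
#' Shrake-Rupley SASA of the whole molecule, restricted to nitrogen, oxygen
#' and hydrogens attached to them (probe 1.4 Angstrom). Requires 3D
#' coordinates.
#'
#' @param mol a [molecule] with coordinates.
#' @param probe probe radius (Angstrom).
#' @param n_points test points per atom.
#' @return polar SASA in Angstrom^2.
#' @export
jurs_tpsa <- function(mol, probe = 1.4, n_points = 960) {
  if (!mol_has_3d(mol)) stop("Jurs_TPSA requires 3D coordinates")
  cc <- .mol_coords(mol)
  sr <- shrake_rupley(cc$xyz, cc$radii, probe = probe, n_points = n_points)
  sum(sr$atom_area[cc$polar])
}

#' Molecular extent along the second principal axis
#'
#' Principal axes of the coordinate covariance are ordered by descending
#' variance; the shadow length is the extent (max minus min projection,
#' inflated by van der Waals radii) along the second axis. Invariant under
#' rigid rotation/translation of the input.
#'
#' @param mol a [molecule] with coordinates.
#' @return length in Angstrom.
#' @export
shadow_ylength <- function(mol) {
  if (!mol_has_3d(mol)) stop("Shadow_Ylength requires 3D coordinates")
  cc <- .mol_coords(mol)
  xyz <- sweep(cc$xyz, 2, colMeans(cc$xyz))
  if (nrow(xyz) == 1) return(2 * cc$radii[1])
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)
  axis2 <- ev$vectors[, 2]
  p <- as.vector(xyz %*% axis2)
  max(p + cc$radii) - min(p - cc$radii)
}

#' Compute the ten screening descriptors for one molecule
#'
#' E-state counts/sums come from [estate_atom_types()] and
#' [estate_indices()]; `Num_Rings6` counts six-membered rings in the
#' smallest set of smallest rings; `Molecular_PolarSurfaceArea` is the 2D
#' Ertl TPSA; `CHI_2` the second-order connectivity index; `Jurs_TPSA` and
#' `Shadow_Ylength` need 3D coordinates and are `NA` when absent (or an
#' error with `need_3d = TRUE`); `Minimized_Energy` is passed through from
#' the caller (any forcefield minimizer may supply it).
#'
#' @param mol a [molecule].
#' @param energy optional minimized energy (kcal/mol), passed through.
#' @param need_3d error (rather than `NA`) when 3D descriptors cannot be
#'   computed.
#' @return named numeric vector over [descriptor_names()].
#' @export
compute_descriptors <- function(mol, energy = NA_real_, need_3d = FALSE) {
  types <- estate_atom_types(mol)
  S <- estate_indices(mol)
  has3d <- mol_has_3d(mol)
  if (need_3d && !has3d)
    stop("requires-3D: molecule ", mol$name, " has no coordinates")
  d <- c(
    ES_Count_aaCH = sum(types == "aaCH"),
    ES_Count_sOH  = sum(types == "sOH"),
    ES_Sum_aaCH   = sum(S[types == "aaCH"]),
    ES_Sum_sssN   = sum(S[types == "sssN"]),
    Num_Rings6    = sum(lengths(mol$rings) == 6),
    Molecular_PolarSurfaceArea = tpsa(mol),
    CHI_2         = chi2_index(mol),
    Jurs_TPSA     = if (has3d) jurs_tpsa(mol) else NA_real_,
    Minimized_Energy = as.numeric(energy),
    Shadow_Ylength = if (has3d) shadow_ylength(mol) else NA_real_
  )
  d[descriptor_names()]
}

#' Descriptor table for a list of molecules
#'
#' @param mols list of [molecule] objects.
#' @param energies optional numeric vector of minimized energies, one per
#'   molecule (kcal/mol).
#' @param path optional CSV output path (columns: `id` plus the ten
#'   descriptor names).
#' @return data.frame with one row per molecule.
#' @export
compute_descriptor_table <- function(mols, energies = NULL, path = NULL) {
  if (is.null(energies)) energies <- rep(NA_real_, length(mols))
  rows <- lapply(seq_along(mols), function(i)
    compute_descriptors(mols[[i]], energy = energies[i]))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(id = vapply(mols, function(m) m$name, ""), out)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
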