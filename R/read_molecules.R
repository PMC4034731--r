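#' Read small molecules from a SMILES or SDF file
#'
#' SMILES files carry one molecule per line, optionally followed by a tab and
#' a name. SDF files are V2000. Records that fail to parse are skipped with a
#' warning; parsing uses ChemmineR (SMILES conversion additionally requires
#' ChemmineOB/OpenBabel). Aromaticity is perceived with ChemmineR's ring
#' perception; descriptor values that depend on aromatic typing therefore
#' follow that model.
#'
#' @param path input file.
#' @param format `"smiles"` or `"sdf"`.
#' @return list of [molecule] objects.
#' @export
read_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no parseable records in ", path)
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("SMILES input requires the ChemmineOB package")
    mols <- list(); failed <- 0L
    for (ln in lines) {
      parts <- strsplit(ln, "[\t ]+")[[1]]
      smi <- parts[1]
      nm <- if (length(parts) > 1) parts[2] else smi
      sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)[[1]]),
                      error = function(e) NULL)
      m <- if (is.null(sdf)) NULL else
        tryCatch(mol_from_sdf(sdf, name = nm), error = function(e) NULL)
      if (is.null(m)) failed <- failed + 1L else mols[[length(mols) + 1L]] <- m
    }
    if (failed > 0) warning(failed, " record(s) failed to parse and were skipped")
    if (!length(mols)) stop("no parseable records in ", path)
    return(mols)
  }
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) stop("cannot read SDF: ",
                                              conditionMessage(e)))
  if (length(sdfset) == 0) stop("no parseable records in ", path)
  ok <- suppressWarnings(ChemmineR::validSDF(sdfset))
  if (any(!ok)) warning(sum(!ok), " record(s) failed to parse and were skipped")
  sdfset <- sdfset[ok]
  if (length(sdfset) == 0) stop("no parseable records in ", path)
  mols <- list()
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    nm <- tryCatch(ChemmineR::sdfid(sdf), error = function(e) NULL)
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("mol", i)
    m <- tryCatch(mol_from_sdf(sdf, name = nm), error = function(e) NULL)
    if (is.null(m)) warning("record ", i, " could not be converted; skipped")
    else mols[[length(mols) + 1L]] <- m
  }
  if (!length(mols)) stop("no parseable records in ", path)
  mols
}

# V2000 atom-block charge codes: 1..7 -> +3,+2,+1,radical,-1,-2,-3
.sdf_charge <- function(code) {
  map <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)
  ifelse(code >= 1 & code <= 7, map[pmax(1L, pmin(7L, code))], 0L)
}

#' Convert a ChemmineR SDF object to a molecule
#'
#' Explicit hydrogens are folded into heavy-atom `nH` counts; their
#' coordinates are retained for surface descriptors. Aromatic rings are
#' perceived with [ChemmineR::rings()].
#'
#' @param sdf a `ChemmineR::SDF` object.
#' @param name molecule identifier.
#' @return a [molecule].
#' @export
mol_from_sdf <- function(sdf, name = "mol") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  xyz <- ab[, 1:3, drop = FALSE]
  charge_code <- if (ncol(ab) >= 5) as.integer(ab[, 5]) else rep(0L, nrow(ab))
  bonds_all <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                          order = as.integer(bb[, 3]))
  heavy <- which(elements != "H")
  if (!length(heavy)) stop("molecule has no heavy atoms")
  idx_map <- integer(length(elements)); idx_map[heavy] <- seq_along(heavy)
  nH_explicit <- integer(length(heavy))
  hyd <- NULL
  is_h_bond <- elements[bonds_all$a1] == "H" | elements[bonds_all$a2] == "H"
  for (k in which(is_h_bond)) {
    h  <- if (elements[bonds_all$a1[k]] == "H") bonds_all$a1[k] else bonds_all$a2[k]
    hv <- if (h == bonds_all$a1[k]) bonds_all$a2[k] else bonds_all$a1[k]
    if (elements[hv] == "H") next  # H2: ignore
    nH_explicit[idx_map[hv]] <- nH_explicit[idx_map[hv]] + 1L
    hyd <- rbind(hyd, data.frame(parent = idx_map[hv], x = xyz[h, 1],
                                 y = xyz[h, 2], z = xyz[h, 3]))
  }
  bonds <- bonds_all[!is_h_bond, , drop = FALSE]
  bonds$a1 <- idx_map[bonds$a1]; bonds$a2 <- idx_map[bonds$a2]
  # 2D files (z all zero) and 3D files both carry coordinates; treat
  # all-zero z with all-zero x as "no coordinates"
  coords_present <- any(abs(xyz) > 1e-8)
  atoms <- data.frame(element = elements[heavy],
                      charge = .sdf_charge(charge_code[heavy]),
                      nH = NA_integer_,
                      x = if (coords_present) xyz[heavy, 1] else NA_real_,
                      y = if (coords_present) xyz[heavy, 2] else NA_real_,
                      z = if (coords_present) xyz[heavy, 3] else NA_real_)
  # implicit H from valence minus Kekule bond sum, then add explicit H on top
  bsum <- bond_order_sums(length(heavy), bonds)
  val <- .elem_lookup(atoms$element, "valence", 0) + atoms$charge
  atoms$nH <- pmax(0L, as.integer(round(val - bsum)))
  atoms$nH <- pmax(atoms$nH, nH_explicit)
  mol <- molecule(atoms, bonds, name = name, hydrogens = hyd)
  # aromaticity from ChemmineR ring perception on the original SDF
  ar <- tryCatch(ChemmineR::rings(sdf, upper = 20, type = "all", arom = TRUE),
                 error = function(e) NULL)
  if (!is.null(ar) && length(ar$RINGS)) {
    for (r in seq_along(ar$RINGS)) {
      if (!isTRUE(ar$AROMATIC[[r]])) next
      ring_idx0 <- as.integer(sub("^.*_", "", ar$RINGS[[r]]))
      ring_idx <- idx_map[ring_idx0]
      if (any(ring_idx == 0)) next
      mol$atoms$aromatic[ring_idx] <- TRUE
      in_ring <- mol$bonds$a1 %in% ring_idx & mol$bonds$a2 %in% ring_idx
      mol$bonds$aromatic[in_ring] <- TRUE
    }
  }
  mol
}
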