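#' Construct a small-molecule graph
#'
#' A `molecule` is the substrate for descriptor computation: a heavy-atom
#' graph with per-atom element, formal charge, attached-hydrogen count and
#' optional 3D coordinates, plus a bond list and perceived ring information.
#' Hydrogens are folded into the `nH` count of their heavy neighbour; explicit
#' hydrogen coordinates (needed for 3D polar surface area) may be kept in the
#' `hydrogens` table.
#'
#' @param atoms data.frame with columns `element` (symbol), and optionally
#'   `charge` (formal charge, default 0), `nH` (attached hydrogens; computed
#'   from default valences when `NA`), `x`,`y`,`z` (Angstrom; all present or
#'   all absent), `aromatic` (logical).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices) and
#'   `order` (1, 2 or 3); may have zero rows.
#' @param name molecule identifier.
#' @param hydrogens optional data.frame of explicit hydrogens with columns
#'   `parent` (heavy-atom index), `x`, `y`, `z`.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = data.frame(a1 = integer(), a2 = integer(),
                                               order = integer()),
                     name = "mol", hydrogens = NULL) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  n <- nrow(atoms)
  if (n == 0L) stop("molecule must contain at least one atom")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$x)) atoms$x <- NA_real_
  if (is.null(atoms$y)) atoms$y <- NA_real_
  if (is.null(atoms$z)) atoms$z <- NA_real_
  has3d <- !is.na(atoms$x)
  if (any(has3d) && !all(has3d))
    stop("either all atoms carry 3D coordinates or none do")
  if (nrow(bonds) > 0) {
    if (any(bonds$a1 == bonds$a2)) stop("self-bonds are not allowed")
    if (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n))
      stop("bond endpoints must reference existing atoms")
  }
  if (is.null(bonds$aromatic)) bonds$aromatic <- rep(FALSE, nrow(bonds))
  atoms$vdw  <- element_vdw(atoms$element)
  atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$nH)) atoms$nH <- NA_integer_
  miss <- is.na(atoms$nH)
  if (any(miss)) {
    bsum <- bond_order_sums(n, bonds)
    val  <- .elem_lookup(atoms$element, "valence", 0) + atoms$charge
    atoms$nH[miss] <- pmax(0L, as.integer(round(val - bsum)))[miss]
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, name = name,
                        hydrogens = hydrogens),
                   class = "molecule")
  mol$rings <- sssr(mol)
  mol
}

# total bond order incident to each heavy atom (aromatic input orders kept
# as their Kekule values; SDF type 4 is treated as order 1.5)
bond_order_sums <- function(n, bonds) {
  bsum <- numeric(n)
  if (nrow(bonds) == 0) return(bsum)
  ord <- ifelse(bonds$order == 4, 1.5, bonds$order)
  for (k in seq_len(nrow(bonds))) {
    bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + ord[k]
    bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + ord[k]
  }
  bsum
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d heavy atoms, %d bonds, %d rings%s\n",
              x$name, nrow(x$atoms), nrow(x$bonds), length(x$rings),
              if (mol_has_3d(x)) ", 3D" else ""))
  invisible(x)
}

mol_has_3d <- function(mol) nrow(mol$atoms) > 0 && !anyNA(mol$atoms$x)

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# all-pairs shortest path lengths on the heavy-atom graph (BFS per atom;
# molecules are small). Disconnected pairs are Inf.
graph_distances <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.infinite(D[s, w])) {
        D[s, w] <- D[s, v] + 1
        queue <- c(queue, w)
      }
    }
  }
  D
}

# Smallest set of smallest rings via shortest-cycle-through-each-bond
# candidates and GF(2) independence on edge incidence vectors.
sssr <- function(mol) {
  n <- nrow(mol$atoms); m <- nrow(mol$bonds)
  if (m == 0) return(list())
  adj <- adjacency_list(mol)
  comp <- integer(n); cid <- 0L
  for (s in seq_len(n)) if (comp[s] == 0L) {
    cid <- cid + 1L; comp[s] <- cid; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  n_rings <- m - n + cid
  if (n_rings <= 0) return(list())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  eindex <- structure(seq_len(m),
                      names = mapply(ekey, mol$bonds$a1, mol$bonds$a2))
  cands <- list()
  for (k in seq_len(m)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    # BFS from a to b avoiding the direct edge
    prev <- integer(n); seen <- logical(n); seen[a] <- TRUE; queue <- a
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) {
          seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w)
          if (w == b) { found <- TRUE; break }
        }
      }
    }
    if (!found) next
    path <- b; v <- b
    while (v != a) { v <- prev[v]; path <- c(v, path) }
    cands[[length(cands) + 1L]] <- path    # cycle = path a..b plus edge b-a
  }
  if (!length(cands)) return(list())
  cands <- cands[!duplicated(lapply(cands, function(p) sort(p)))]
  cands <- cands[order(lengths(cands))]
  basis <- matrix(0L, 0, m)
  rings <- list()
  for (ring in cands) {
    if (length(rings) == n_rings) break
    cyc <- c(ring, ring[1])
    vec <- integer(m)
    for (i in seq_len(length(ring)))
      vec[eindex[[ekey(cyc[i], cyc[i + 1])]]] <- 1L
    red <- vec
    for (r in seq_len(nrow(basis))) {
      piv <- which(basis[r, ] == 1L)[1]
      if (red[piv] == 1L) red <- (red + basis[r, ]) %% 2L
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      # keep pivot order: sort rows by pivot position
      basis <- basis[order(apply(basis, 1, function(v) which(v == 1L)[1])), ,
                     drop = FALSE]
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}
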