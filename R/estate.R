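#' Kier-Hall E-state atom types
#'
#' Assigns each heavy atom the conventional electrotopological-state type
#' string: bond symbols in the order triple (`t`), double (`d`), aromatic
#' (`a`), single (`s`), followed by the element symbol and the attached
#' hydrogen count (e.g. `aaCH` for an aromatic CH, `sOH` for a hydroxyl
#' oxygen, `sssN` for an amine nitrogen with three single bonds). Elements
#' outside the lookup tables are typed `"other"` rather than failing.
#'
#' @param mol a [molecule].
#' @return character vector of per-atom type labels.
#' @export
estate_atom_types <- function(mol) {
  n <- nrow(mol$atoms)
  types <- character(n)
  nt <- nd <- na_ <- ns <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (isTRUE(mol$bonds$aromatic[k]) || mol$bonds$order[k] == 4) {
      na_[a] <- na_[a] + 1L; na_[b] <- na_[b] + 1L
    } else if (mol$bonds$order[k] == 3) {
      nt[a] <- nt[a] + 1L; nt[b] <- nt[b] + 1L
    } else if (mol$bonds$order[k] == 2) {
      nd[a] <- nd[a] + 1L; nd[b] <- nd[b] + 1L
    } else {
      ns[a] <- ns[a] + 1L; ns[b] <- ns[b] + 1L
    }
  }
  for (i in seq_len(n)) {
    el <- mol$atoms$element[i]
    if (!el %in% .element_table$symbol) { types[i] <- "other"; next }
    h <- mol$atoms$nH[i]
    hpart <- if (h <= 0) "" else if (h == 1) "H" else paste0("H", h)
    types[i] <- paste0(strrep("t", nt[i]), strrep("d", nd[i]),
                       strrep("a", na_[i]), strrep("s", ns[i]), el, hpart)
  }
  types
}

#' Kier-Hall electrotopological state indices
#'
#' For heavy atom i the intrinsic state is
#' \deqn{I_i = ((2/N_i)^2 \delta^v_i + 1)/\delta_i}
#' with N the principal quantum number, \eqn{\delta^v} the valence-electron
#' count minus attached hydrogens, and \eqn{\delta} the heavy-atom degree.
#' The E-state adds the field perturbation
#' \eqn{S_i = I_i + \sum_j (I_i - I_j)/d_{ij}^2}, where d is the graph
#' distance plus one. Perturbations cancel pairwise, so \eqn{\sum S = \sum I}.
#' Hydrogens are folded into attached-H counts; an isolated heavy atom has
#' its degree clamped to 1 (S = I).
#'
#' @param mol a [molecule].
#' @return numeric vector of per-atom E-state values.
#' @export
estate_indices <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    deg[mol$bonds$a1[k]] <- deg[mol$bonds$a1[k]] + 1L
    deg[mol$bonds$a2[k]] <- deg[mol$bonds$a2[k]] + 1L
  }
  zv <- .elem_lookup(mol$atoms$element, "zv", NA_real_)
  nq <- .elem_lookup(mol$atoms$element, "nquant", NA_real_)
  dv <- zv - mol$atoms$nH
  delta <- pmax(deg, 1L)  # isolated heavy atom: S = I with delta clamped
  I <- ((2 / nq)^2 * dv + 1) / delta
  I[is.na(I)] <- 0  # unsupported elements contribute nothing
  if (n == 1L) return(I)
  D <- graph_distances(mol) + 1
  S <- I
  for (i in seq_len(n)) {
    j <- setdiff(which(is.finite(D[i, ])), i)
    if (length(j)) S[i] <- I[i] + sum((I[i] - I[j]) / D[i, j]^2)
  }
  S
}
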