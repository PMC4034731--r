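#' Read a protein-ligand interaction table
#'
#' CSV dialect: first column ligand names, remaining columns residue labels
#' (e.g. `Tyr113`); cells are `-` (or an em dash, or empty) for no contact,
#' or slash-joined interaction kinds among `H` (hydrogen bond), `Hb`
#' (hydrophobic) and `Pi` (pi-pi stacking), e.g. `Pi/Hb`. Unknown kind
#' tokens are an error naming the offending cell.
#'
#' @param path CSV file.
#' @return object of class `interaction_table`: list with `ligands`,
#'   `residues` and `cells` (list-matrix of character vectors of kinds).
#' @export
read_interactions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("interaction table needs ligand + residue columns")
  ligands <- as.character(df[[1]])
  residues <- names(df)[-1]
  if (anyDuplicated(residues)) stop("residue labels must be unique")
  known <- c("H", "Hb", "Pi")
  cells <- matrix(vector("list", length(ligands) * length(residues)),
                  nrow = length(ligands),
                  dimnames = list(ligands, residues))
  for (i in seq_along(ligands)) for (j in seq_along(residues)) {
    raw <- trimws(as.character(df[i, j + 1]))
    if (is.na(raw) || raw %in% c("", "-", "—", "–")) {
      cells[[i, j]] <- character(0)
    } else {
      kinds <- trimws(strsplit(raw, "/", fixed = TRUE)[[1]])
      bad <- setdiff(kinds, known)
      if (length(bad))
        stop(sprintf("unknown interaction kind '%s' at %s x %s",
                     bad[1], ligands[i], residues[j]))
      cells[[i, j]] <- unique(kinds)
    }
  }
  structure(list(ligands = ligands, residues = residues, cells = cells),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d ligands x %d residues\n",
              length(x$ligands), length(x$residues)))
  invisible(x)
}

#' The bundled docking interaction table
#'
#' The recorded docking contacts of the Tacrolimus control and the three
#' selected candidates with ten FKBP52 binding-site residues.
#'
#' @return an `interaction_table`.
#' @export
published_interactions <- function() {
  read_interactions(system.file("extdata", "docking_interactions.csv",
                                package = "cvscreen", mustWork = TRUE))
}

.contact_matrix <- function(t)
  matrix(lengths(t$cells) > 0, nrow = length(t$ligands),
         dimnames = dimnames(t$cells))

#' Per-ligand interaction totals
#'
#' By default counts recorded interactions, so a multi-kind cell (e.g.
#' `Pi/Hb`) contributes one per kind — this is the convention the bundled
#' docking table's printed totals follow. `count = "residues"` instead
#' counts residues with any contact (a multi-kind cell counts once), the
#' convention the per-residue percentages use.
#'
#' @param t an `interaction_table`.
#' @param count `"interactions"` (default) or `"residues"`.
#' @return named integer vector (one entry per ligand).
#' @export
ligand_totals <- function(t, count = c("interactions", "residues")) {
  count <- match.arg(count)
  if (!length(t$ligands)) stop("empty interaction table")
  if (count == "residues") return(rowSums(.contact_matrix(t)))
  out <- rowSums(matrix(lengths(t$cells), nrow = length(t$ligands)))
  names(out) <- t$ligands
  out
}

#' Per-residue interaction percentages
#'
#' 100 x (number of ligands contacting the residue) / (number of ligands in
#' the table).
#'
#' @param t an `interaction_table`.
#' @return named numeric vector of percentages in [0, 100].
#' @export
residue_percentages <- function(t) {
  if (!length(t$ligands)) stop("empty interaction table")
  100 * colSums(.contact_matrix(t)) / length(t$ligands)
}

#' Compare candidate contact sets against a control ligand
#'
#' Set algebra on interacting-residue sets: per candidate, the residues
#' shared with the control, the candidate-only residues and the
#' control-only residues.
#'
#' @param t an `interaction_table`.
#' @param control control ligand name (must be in the table).
#' @return named list per candidate with elements `shared`,
#'   `candidate_only`, `control_only`.
#' @export
compare_to_control <- function(t, control) {
  if (!control %in% t$ligands) stop("unknown control ligand: ", control)
  cm <- .contact_matrix(t)
  ctrl_set <- t$residues[cm[control, ]]
  out <- list()
  for (lig in setdiff(t$ligands, control)) {
    lig_set <- t$residues[cm[lig, ]]
    out[[lig]] <- list(shared = intersect(ctrl_set, lig_set),
                       candidate_only = setdiff(lig_set, ctrl_set),
                       control_only = setdiff(ctrl_set, lig_set))
  }
  out
}
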