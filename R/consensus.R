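#' Candidate score tables
#'
#' A score table is a data.frame with columns `name`, `svm`, `mlr`, `bn`
#' (predicted pIC50 from the three models), `dock` (dock score, higher is
#' better) and logical `is_control`. [read_scores()] reads/validates the CSV
#' form; [published_scores()] returns the bundled screening table of the ten
#' FKBP52 candidates plus the Tacrolimus control.
#'
#' @param path CSV file.
#' @return validated score table.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("name", "svm", "mlr", "bn", "dock")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$is_control)) df$is_control <- FALSE
  df$is_control <- as.logical(df$is_control)
  for (col in c("svm", "mlr", "bn", "dock")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname read_scores
#' @export
published_scores <- function() {
  read_scores(system.file("extdata", "candidate_scores.csv",
                          package = "cvscreen", mustWork = TRUE))
}

#' Dock-score gate against the control
#'
#' Candidates whose dock score falls strictly below the control's are
#' eliminated (ties with the control survive); order is preserved. An empty
#' survivor set is a warning, not an error.
#'
#' @param candidates score table rows (control excluded).
#' @param control single-row score table for the control ligand.
#' @return filtered score table.
#' @export
dock_gate <- function(candidates, control) {
  if (!is.finite(control$dock[1])) stop("control dock score must be finite")
  keep <- candidates$dock >= control$dock[1]
  out <- candidates[keep, , drop = FALSE]
  if (!nrow(out)) warning("no candidates survive the dock gate")
  out
}

# vote indicator: top-3 by descending value, inclusive at rank-3 ties
.top3_vote <- function(x) {
  if (length(x) < 3) return(rep(TRUE, length(x)))
  thr <- sort(x, decreasing = TRUE)[3]
  x >= thr
}

#' Consensus voting over the four screening metrics
#'
#' The three highest-scoring candidates per metric receive that metric's
#' vote: weight 1 for dock score, SVM and MLR predictions, weight 2 for the
#' Bayesian-network prediction. Ties spanning rank 3 all receive the vote,
#' so voting is invariant under input order. With fewer than three
#' candidates every candidate receives every vote. Control rows (flagged
#' `is_control`) are excluded from voting and get `NA` votes.
#'
#' @param scores score table (see [read_scores()]).
#' @return the table with columns `vote_svm`, `vote_mlr`, `vote_bn`,
#'   `vote_dock` and `vote_sum` added.
#' @export
consensus_vote <- function(scores) {
  cand <- !scores$is_control
  if (sum(cand) == 0) stop("no candidate rows to vote on")
  if (sum(cand) < 3)
    message("fewer than 3 candidates: every candidate receives every vote")
  v <- function(col, w) {
    out <- rep(NA_integer_, nrow(scores))
    out[cand] <- as.integer(.top3_vote(scores[[col]][cand])) * w
    out
  }
  scores$vote_svm  <- v("svm", 1L)
  scores$vote_mlr  <- v("mlr", 1L)
  scores$vote_bn   <- v("bn", 2L)
  scores$vote_dock <- v("dock", 1L)
  scores$vote_sum  <- with(scores, vote_svm + vote_mlr + vote_bn + vote_dock)
  scores
}

#' Select the top-k consensus candidates
#'
#' Sort by vote sum (descending), break ties by dock score (descending) then
#' name (ascending); return the first k candidates. Control rows are never
#' selected.
#'
#' @param scores voted score table (from [consensus_vote()]).
#' @param k number of candidates to return.
#' @return the selected rows, in rank order.
#' @export
select_candidates <- function(scores, k = 3) {
  if (is.null(scores$vote_sum)) stop("votes not computed; run consensus_vote()")
  cand <- scores[!scores$is_control, , drop = FALSE]
  if (k > nrow(cand)) {
    message("k exceeds the number of candidates; returning all")
    k <- nrow(cand)
  }
  ord <- order(-cand$vote_sum, -cand$dock, cand$name)
  cand[ord[seq_len(k)], , drop = FALSE]
}

#' Run the full screening stage on a score table
#'
#' Optional dock gate against the flagged control, consensus voting, then
#' top-k selection.
#'
#' @param scores score table with exactly one `is_control` row if
#'   `gate = TRUE`.
#' @param k candidates to select.
#' @param gate apply the dock-score gate before voting.
#' @return list with `voted` (full voted table) and `selected` (top-k rows).
#' @export
screen_candidates <- function(scores, k = 3, gate = TRUE) {
  ctrl <- scores[scores$is_control, , drop = FALSE]
  cand <- scores[!scores$is_control, , drop = FALSE]
  if (gate) {
    if (nrow(ctrl) != 1) stop("dock gate needs exactly one control row")
    cand <- dock_gate(cand, ctrl)
  }
  voted <- consensus_vote(rbind(cand, ctrl))
  list(voted = voted, selected = select_candidates(voted, k = k))
}
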