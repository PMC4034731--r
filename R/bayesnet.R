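#' Equal-frequency discretization edges
#'
#' Interior cut points at the k-quantiles of each variable (at most
#' `max_bins` bins); duplicate quantiles are merged, so the realized bin
#' count may be smaller. A constant column yields no edges (one bin).
#'
#' @param x numeric vector, or a data.frame (each numeric column is
#'   discretized).
#' @param max_bins 2..5 target bins.
#' @return for a vector: sorted numeric vector of strictly increasing
#'   interior edges; for a data.frame: named list of such vectors.
#' @export
discretize_edges <- function(x, max_bins = 5) {
  if (max_bins < 2 || max_bins > 5) stop("max_bins must be in 2..5")
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, TRUE)
    return(lapply(x[num], discretize_edges, max_bins = max_bins))
  }
  probs <- seq_len(max_bins - 1) / max_bins
  e <- unique(as.numeric(stats::quantile(x, probs, type = 7, names = FALSE)))
  e <- e[e > min(x) & e < max(x)]
  sort(unique(e))
}

# bin assignment: values outside all bins clamp to the nearest (edge rule)
bin_assign <- function(x, edges) findInterval(x, edges) + 1L

# mixed-radix index of parent configurations (1-based)
.pa_index <- function(Dpa, r_pa) {
  if (!length(r_pa)) return(rep(1L, nrow(Dpa)))
  idx <- rep(0L, nrow(Dpa))
  for (j in seq_along(r_pa)) idx <- idx * r_pa[j] + (Dpa[, j] - 1L)
  idx + 1L
}

# BDeu family score (equivalent sample size ess) for node v given parents pa
.bdeu_family <- function(D, v, pa, r, ess = 1) {
  rv <- r[v]
  q <- if (length(pa)) prod(r[pa]) else 1L
  aj <- ess / q; ajk <- ess / (q * rv)
  j <- .pa_index(D[, pa, drop = FALSE], r[pa])
  N <- matrix(0, q, rv)
  for (i in seq_len(nrow(D))) N[j[i], D[i, v]] <- N[j[i], D[i, v]] + 1
  Nj <- rowSums(N)
  sum(lgamma(aj) - lgamma(aj + Nj)) + sum(lgamma(ajk + N) - lgamma(ajk))
}

.is_acyclic <- function(A) {
  # A[i, j] = TRUE means edge i -> j
  n <- nrow(A); indeg <- colSums(A)
  queue <- which(indeg == 0); seen <- 0L
  A2 <- A
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    ch <- which(A2[v, ])
    A2[v, ch] <- FALSE
    indeg[ch] <- indeg[ch] - 1L
    queue <- c(queue, ch[indeg[ch] == 0])
  }
  seen == n
}

#' Greedy Bayesian-network structure learning (BDeu hill climbing)
#'
#' Hill climbing over single-edge additions, deletions and reversals,
#' maximizing the decomposable BDeu score (equivalent sample size 1), with
#' random restarts from sparse random DAGs. Acyclicity and a parent-count
#' cap are enforced. Deterministic given the seed.
#'
#' @param D integer matrix of discretized states (rows = cases, columns =
#'   variables, states 1..r).
#' @param seed RNG seed.
#' @param max_parents parent cap per node.
#' @param restarts random restarts beyond the empty-graph start.
#' @param ess BDeu equivalent sample size.
#' @return adjacency matrix (`A[i, j]` TRUE means an edge i -> j), with the
#'   achieved score in attribute `"score"`.
#' @export
learn_structure <- function(D, seed = 1, max_parents = 3, restarts = 2,
                            ess = 1) {
  D <- as.matrix(D)
  storage.mode(D) <- "integer"
  p <- ncol(D)
  if (p < 1) stop("need at least one variable")
  r <- pmax(apply(D, 2, max), 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (p == 1) {
    A <- matrix(FALSE, 1, 1, dimnames = list(colnames(D), colnames(D)))
    attr(A, "score") <- .bdeu_family(D, 1L, integer(0), r, ess)
    return(A)
  }
  fam_cache <- new.env(parent = emptyenv())
  fam <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = ","))
    got <- fam_cache[[key]]
    if (!is.null(got)) return(got)
    s <- .bdeu_family(D, v, sort(pa), r, ess)
    fam_cache[[key]] <- s
    s
  }
  climb <- function(A) {
    node_sc <- vapply(seq_len(p), function(v) fam(v, which(A[, v])), 0)
    repeat {
      best_gain <- 1e-9; best <- NULL
      for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        if (!A[i, j]) {
          if (sum(A[, j]) >= max_parents || A[j, i]) next
          A[i, j] <- TRUE; ok <- .is_acyclic(A); A[i, j] <- FALSE
          if (!ok) next
          gain <- fam(j, c(which(A[, j]), i)) - node_sc[j]
          if (gain > best_gain) { best_gain <- gain; best <- c(1L, i, j) }
        } else {
          gain <- fam(j, setdiff(which(A[, j]), i)) - node_sc[j]
          if (gain > best_gain) { best_gain <- gain; best <- c(2L, i, j) }
          if (sum(A[, i]) < max_parents) {  # reversal i->j to j->i
            A[i, j] <- FALSE; A[j, i] <- TRUE
            ok <- .is_acyclic(A)
            A[j, i] <- FALSE; A[i, j] <- TRUE
            if (ok) {
              gain <- (fam(j, setdiff(which(A[, j]), i)) - node_sc[j]) +
                      (fam(i, c(which(A[, i]), j)) - node_sc[i])
              if (gain > best_gain) { best_gain <- gain; best <- c(3L, i, j) }
            }
          }
        }
      }
      if (is.null(best)) break
      i <- best[2]; j <- best[3]
      if (best[1] == 1L) A[i, j] <- TRUE
      else if (best[1] == 2L) A[i, j] <- FALSE
      else { A[i, j] <- FALSE; A[j, i] <- TRUE }
      node_sc[j] <- fam(j, which(A[, j]))
      if (best[1] == 3L) node_sc[i] <- fam(i, which(A[, i]))
    }
    list(A = A, score = sum(node_sc))
  }
  empty <- matrix(FALSE, p, p, dimnames = list(colnames(D), colnames(D)))
  best <- climb(empty)
  for (rs in seq_len(restarts)) {
    A0 <- empty
    n_try <- sample.int(p, 1)
    for (k in seq_len(n_try)) {
      ij <- sample.int(p, 2)
      if (sum(A0[, ij[2]]) >= max_parents) next
      A0[ij[1], ij[2]] <- TRUE
      if (!.is_acyclic(A0)) A0[ij[1], ij[2]] <- FALSE
    }
    cand <- climb(A0)
    if (cand$score > best$score) best <- cand
  }
  structure(best$A, score = best$score)
}

# per-category regression with a ridge fallback for degenerate designs
.category_fit <- function(table, vars) {
  fit <- if (nrow(table) > length(vars) + 1) .ls_fit(table, vars) else NULL
  if (!is.null(fit))
    return(linear_model(fit$intercept, fit$coefficients, r_squared = fit$r2))
  X <- cbind(1, as.matrix(table[, vars, drop = FALSE]))
  y <- table$pIC50
  lam <- diag(1e-6, ncol(X)); lam[1, 1] <- 0
  beta <- tryCatch(solve(crossprod(X) + lam, crossprod(X, y)),
                   error = function(e) c(mean(y), rep(0, length(vars))))
  linear_model(beta[1], stats::setNames(as.numeric(beta[-1]), vars))
}

#' Fit the discretized Bayesian-network pIC50 predictor
#'
#' Descriptors and pIC50 are discretized into at most five equal-frequency
#' categories; a network over the discretized variables is learned by BDeu
#' hill climbing; conditional probability tables are estimated with add-one
#' (Dirichlet) smoothing; and a per-category linear regression maps a query
#' to a continuous pIC50 within its most probable category.
#'
#' @param table training table as in [fit_mlr()].
#' @param descriptors descriptor columns.
#' @param max_bins maximum categories per variable (2..5).
#' @param seed RNG seed for structure search.
#' @param max_parents parent cap in the network.
#' @param combine `"map"` (default): evaluate the MAP category's regression
#'   (ties break to the lower category); `"posterior"`: posterior-weighted
#'   mean of all category regressions.
#' @return object of class `bn_model`.
#' @export
fit_bn <- function(table, descriptors = NULL, max_bins = 5, seed = 1,
                   max_parents = 3, combine = c("map", "posterior")) {
  combine <- match.arg(combine)
  if (is.null(descriptors)) {
    descriptors <- intersect(descriptor_names(), names(table))
    if (!length(descriptors))
      descriptors <- setdiff(names(table), c("id", "pIC50", "split"))
  }
  if (!is.null(table$split)) table <- table[table$split == "train", , drop = FALSE]
  vars <- c(descriptors, "pIC50")
  edges <- lapply(table[vars], discretize_edges, max_bins = max_bins)
  D <- vapply(vars, function(v) bin_assign(table[[v]], edges[[v]]),
              integer(nrow(table)))
  colnames(D) <- vars
  r <- pmax(apply(D, 2, max), 1L)
  A <- learn_structure(D, seed = seed, max_parents = max_parents)
  cpts <- lapply(seq_along(vars), function(v) {
    pa <- which(A[, v])
    q <- if (length(pa)) prod(r[pa]) else 1L
    N <- matrix(1, q, r[v])  # add-one smoothing
    j <- .pa_index(D[, pa, drop = FALSE], r[pa])
    for (i in seq_len(nrow(D))) N[j[i], D[i, v]] <- N[j[i], D[i, v]] + 1
    N / rowSums(N)
  })
  names(cpts) <- vars
  ycat <- D[, "pIC50"]
  category_models <- lapply(seq_len(r[["pIC50"]]), function(k) {
    rows <- table[ycat == k, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    .category_fit(rows, descriptors)
  })
  structure(list(descriptors = descriptors, edges = edges, dag = A,
                 cpts = cpts, r = r, category_models = category_models,
                 combine = combine, seed = seed),
            class = "bn_model")
}

#' @export
print.bn_model <- function(x, ...) {
  cat(sprintf(
    "Bayesian-network pIC50 model: %d descriptors, %d pIC50 categories, %d edge(s)\n",
    length(x$descriptors), x$r[["pIC50"]], sum(x$dag)))
  invisible(x)
}

# posterior over pIC50 categories given fully observed descriptor bins
.bn_posterior <- function(model, bins) {
  vars <- c(model$descriptors, "pIC50")
  ry <- model$r[["pIC50"]]
  logp <- numeric(ry)
  for (k in seq_len(ry)) {
    st <- c(bins, pIC50 = k)
    lp <- 0
    for (v in seq_along(vars)) {
      pa <- which(model$dag[, v])
      j <- .pa_index(matrix(st[vars[pa]], nrow = 1), model$r[vars[pa]])
      lp <- lp + log(model$cpts[[v]][j, st[[vars[v]]]])
    }
    logp[k] <- lp
  }
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' @export
predict.bn_model <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  vapply(seq_len(nrow(newdata)), function(i) {
    d <- unlist(newdata[i, object$descriptors, drop = TRUE])
    bins <- stats::setNames(vapply(object$descriptors, function(v)
      bin_assign(d[[v]], object$edges[[v]]), 1L), object$descriptors)
    post <- .bn_posterior(object, bins)
    if (object$combine == "posterior") {
      preds <- vapply(seq_along(post), function(k) {
        cm <- object$category_models[[k]]
        if (is.null(cm)) 0 else evaluate_linear(cm, d)
      }, 0)
      ok <- !vapply(object$category_models, is.null, TRUE)
      return(sum(post[ok] * preds[ok]) / sum(post[ok]))
    }
    # MAP with deterministic lower-category tie-break over non-empty cats
    ok <- !vapply(object$category_models, is.null, TRUE)
    post[!ok] <- -Inf
    k <- which(post == max(post))[1]
    evaluate_linear(object$category_models[[k]], d)
  }, 0)
}

#' Posterior over pIC50 categories for one query
#'
#' @param model a fitted `bn_model`.
#' @param d named descriptor vector.
#' @return numeric probability vector over categories (sums to 1).
#' @export
bn_posterior <- function(model, d) {
  if (is.data.frame(d)) d <- unlist(d[1, , drop = TRUE])
  bins <- stats::setNames(vapply(model$descriptors, function(v)
    bin_assign(d[[v]], model$edges[[v]]), 1L), model$descriptors)
  .bn_posterior(model, bins)
}
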