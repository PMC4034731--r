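#' Linear scoring model
#'
#' A plain intercept-plus-weights model over named descriptors, the unit all
#' three predictors and the bundled screening equation share.
#'
#' @param intercept intercept (pIC50 units).
#' @param coefficients named numeric vector of descriptor weights.
#' @param r_squared optional training R^2.
#' @return object of class `linear_model`.
#' @export
linear_model <- function(intercept, coefficients = numeric(0),
                         r_squared = NA_real_) {
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named by descriptor")
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 r_squared = r_squared,
                 term_count = length(coefficients)),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat("Linear pIC50 model:", x$term_count, "term(s)")
  if (!is.na(x$r_squared)) cat(sprintf(", training R^2 = %.4f", x$r_squared))
  cat("\n  intercept:", format(x$intercept), "\n")
  if (x$term_count)
    for (nm in names(x$coefficients))
      cat(sprintf("  %+.5g x %s\n", x$coefficients[[nm]], nm))
  invisible(x)
}

#' @export
coef.linear_model <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' Evaluate a linear model on a descriptor vector
#'
#' @param model a [linear_model].
#' @param d named numeric vector (or single-row data.frame) containing at
#'   least the model's descriptors.
#' @return predicted pIC50.
#' @export
evaluate_linear <- function(model, d) {
  if (is.data.frame(d)) d <- unlist(d[1, , drop = TRUE])
  need <- names(model$coefficients)
  missing_d <- setdiff(need, names(d))
  if (length(missing_d))
    stop("descriptor(s) missing from input: ", paste(missing_d, collapse = ", "))
  model$intercept + sum(model$coefficients * as.numeric(d[need]))
}

#' @param newdata data.frame of descriptors (one row per molecule) or a
#'   named vector.
#' @rdname evaluate_linear
#' @param object a [linear_model].
#' @param ... unused.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) return(evaluate_linear(object, newdata))
  vapply(seq_len(nrow(newdata)),
         function(i) evaluate_linear(object, unlist(newdata[i, , drop = TRUE])),
         0)
}

#' The bundled published screening equation
#'
#' The ten-descriptor linear pIC50 model reported for the FKBP52 ligand set
#' (intercept 14.911), usable without retraining: the original training
#' ligands are not publicly deposited, so the printed coefficients ship with
#' the package.
#'
#' @return a [linear_model].
#' @export
eq1_model <- function() {
  linear_model(
    intercept = 14.911,
    coefficients = c(
      ES_Count_aaCH =  80.578,
      ES_Count_sOH  = -27.224,
      ES_Sum_aaCH   = -44.517,
      ES_Sum_sssN   =  16.799,
      Num_Rings6    = -27.187,
      Molecular_PolarSurfaceArea = 0.90601,
      CHI_2         = -9.6615,
      Jurs_TPSA     = -0.13155,
      Minimized_Energy = -1.1131,
      Shadow_Ylength = 13.232),
    r_squared = 0.9402)
}

#' Squared Pearson correlation
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return R^2 in [0, 1].
#' @export
r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("need two equal-length vectors of length >= 2")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("undefined R^2: zero variance")
  stats::cor(observed, predicted)^2
}

# Friedman lack-of-fit for a p-term linear model on n points:
# LOF = SSE / (n (1 - (c + d p)/n)^2), c = p + 1, smoothing d
friedman_lof <- function(sse, n, p, d = 1.0) {
  denom <- n * (1 - ((p + 1) + d * p) / n)^2
  if (denom <= 0) return(Inf)
  sse / denom
}

# least-squares fit of y on the named columns; NULL on a degenerate design
.ls_fit <- function(table, vars) {
  X <- cbind(1, as.matrix(table[, vars, drop = FALSE]))
  y <- table$pIC50
  if (qr(X)$rank < ncol(X)) return(NULL)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(intercept = beta[1],
       coefficients = stats::setNames(beta[-1], vars),
       sse = sse,
       r2 = if (sst > 0) 1 - sse / sst else NA_real_)
}

#' Genetic Function Approximation over descriptor subsets
#'
#' Evolves fixed-size descriptor subsets with tournament selection (k = 2),
#' one-point subset crossover, swap mutation and single-model elitism. Each
#' individual is scored by the Friedman lack-of-fit of its least-squares fit
#' (smaller is better; fitness is its negation); collinear subsets receive
#' fitness -Inf. Deterministic for a given seed.
#'
#' @param table training table: data.frame with descriptor columns, a
#'   `pIC50` column and optionally a `split` column (only `"train"` rows are
#'   fitted).
#' @param n_terms subset size.
#' @param population number of individuals (>= 2).
#' @param generations evolution steps (0 returns the ranked random initial
#'   population).
#' @param seed RNG seed.
#' @param descriptors candidate descriptor columns (default: the ten
#'   canonical names present in `table`).
#' @param mutation_rate per-offspring probability of swapping one descriptor.
#' @param lof_d Friedman smoothing parameter.
#' @return object of class `gfa_result`: ranked list of [linear_model]s
#'   (best first) with fitness attributes.
#' @export
gfa <- function(table, n_terms, population = 50, generations = 50, seed = 1,
                descriptors = NULL, mutation_rate = 0.1, lof_d = 1.0) {
  if (is.null(descriptors)) {
    descriptors <- intersect(descriptor_names(), names(table))
    if (!length(descriptors))
      descriptors <- setdiff(names(table), c("id", "pIC50", "split"))
  }
  if (n_terms > length(descriptors))
    stop("n_terms exceeds the number of candidate descriptors")
  if (population < 2) stop("population must be >= 2")
  if (!is.null(table$split)) table <- table[table$split == "train", , drop = FALSE]
  n <- nrow(table)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  score <- function(vars) {
    fit <- .ls_fit(table, vars)
    if (is.null(fit)) return(list(fitness = -Inf, fit = NULL))
    list(fitness = -friedman_lof(fit$sse, n, length(vars), d = lof_d),
         fit = fit)
  }
  pop <- replicate(population, sort(sample(descriptors, n_terms)),
                   simplify = FALSE)
  fits <- lapply(pop, score)
  fitness <- vapply(fits, `[[`, 0, "fitness")

  if (generations > 0) for (g in seq_len(generations)) {
    newpop <- list(pop[[which.max(fitness)]])  # elitism of 1
    while (length(newpop) < population) {
      pick <- function() {
        c2 <- sample.int(population, 2)
        pop[[c2[which.max(fitness[c2])]]]
      }
      p1 <- pick(); p2 <- pick()
      cut <- sample.int(n_terms, 1)
      child <- unique(c(p1[seq_len(cut)], p2))[seq_len(n_terms)]
      child <- child[!is.na(child)]
      while (length(child) < n_terms)
        child <- unique(c(child, sample(descriptors, 1)))
      if (stats::runif(1) < mutation_rate) {
        out_pool <- setdiff(descriptors, child)
        if (length(out_pool))
          child[sample.int(n_terms, 1)] <- sample(out_pool, 1)
      }
      newpop[[length(newpop) + 1L]] <- sort(child)
    }
    pop <- newpop
    fits <- lapply(pop, score)
    fitness <- vapply(fits, `[[`, 0, "fitness")
  }

  ord <- order(fitness, decreasing = TRUE)
  models <- lapply(ord, function(i) {
    f <- fits[[i]]
    m <- if (is.null(f$fit)) linear_model(NA_real_, stats::setNames(
      rep(NA_real_, n_terms), pop[[i]])) else
      linear_model(f$fit$intercept, f$fit$coefficients, r_squared = f$fit$r2)
    attr(m, "fitness") <- f$fitness
    attr(m, "descriptors") <- pop[[i]]
    m
  })
  structure(list(models = models, seed = seed, n_terms = n_terms),
            class = "gfa_result")
}

#' @export
print.gfa_result <- function(x, ...) {
  cat(sprintf("GFA search: %d ranked %d-term models (seed %d)\n",
              length(x$models), x$n_terms, x$seed))
  best <- x$models[[1]]
  cat(sprintf("Best fitness %.6g; R^2 = %.4f; terms: %s\n",
              attr(best, "fitness"), best$r_squared,
              paste(names(best$coefficients), collapse = ", ")))
  invisible(x)
}

#' Serialize / restore a linear model as JSON
#'
#' @param model a [linear_model].
#' @param path output file.
#' @param metadata optional named list stored alongside.
#' @export
write_linear_model <- function(model, path, metadata = NULL) {
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              r_squared = model$r_squared,
              metadata = metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linear_model
#' @export
read_linear_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_model(obj$intercept, unlist(obj$coefficients),
               r_squared = if (is.null(obj$r_squared)) NA_real_ else obj$r_squared)
}

# save/restore global RNG state so fitters are polite library citizens
.Random.seed_save <- function()
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
      envir = globalenv()) else NULL
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
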