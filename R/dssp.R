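#' Backbone secondary-structure assignment (Kabsch-Sander)
#'
#' Per frame, backbone H-bonds are assigned from the electrostatic energy
#' \deqn{E = 0.084 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) \times 332}
#' (kcal/mol; bond when E < -0.5). Patterns are reduced to five classes:
#' two consecutive n -> n+4 turns give alpha-helix (`H`), bridge patterns
#' give beta-sheet (`E`), n -> n+3/n+5 turns give turn (`T`), a C-alpha
#' curvature above 70 degrees over i +/- 2 gives bend (`S`), everything else
#' `C`. Priority H > E > T > S. Amide hydrogens are taken from the topology
#' when present, otherwise imputed 1.0 Angstrom from N along the previous
#' residue's C=O direction. Residues missing backbone atoms are classed `C`
#' with a warning.
#'
#' @param traj a [trajectory] with protein backbone atoms (N, CA, C, O per
#'   residue).
#' @return object of class `ss_timeline`: list with `classes` (frames x
#'   residues character matrix), `fractions` (data.frame: `time` plus
#'   per-class fraction columns summing to 1) and `resno`.
#' @export
secondary_structure <- function(traj) {
  top <- traj$topology
  prot <- which(top$is_protein)
  if (!length(prot)) stop("no protein residues in topology")
  key <- paste(top$chain[prot], top$resno[prot])
  res_keys <- unique(key)
  nres <- length(res_keys)
  find_atom <- function(k, name) {
    i <- prot[key == k & top$elety[prot] == name]
    if (length(i)) i[1] else NA_integer_
  }
  Ni  <- vapply(res_keys, find_atom, 0L, name = "N")
  CAi <- vapply(res_keys, find_atom, 0L, name = "CA")
  Ci  <- vapply(res_keys, find_atom, 0L, name = "C")
  Oi  <- vapply(res_keys, find_atom, 0L, name = "O")
  Hi  <- vapply(res_keys, find_atom, 0L, name = "H")
  complete <- !(is.na(Ni) | is.na(CAi) | is.na(Ci) | is.na(Oi))
  if (any(!complete))
    warning(sum(!complete), " residue(s) missing backbone atoms; classed C")
  chain_of <- vapply(res_keys, function(k) strsplit(k, " ")[[1]][1], "")
  resno_of <- as.integer(vapply(res_keys,
                                function(k) strsplit(k, " ")[[1]][2], ""))
  # consecutive-in-chain flag between residue r-1 and r
  linked <- c(FALSE, chain_of[-1] == chain_of[-nres] &
                     diff(resno_of) == 1)

  nf <- n_frames(traj)
  classes <- matrix("C", nf, nres)
  for (f in seq_len(nf)) {
    m <- traj$coords[[f]]
    # amide H positions
    Hpos <- matrix(NA_real_, nres, 3)
    for (r in seq_len(nres)) {
      if (!complete[r]) next
      if (!is.na(Hi[r])) { Hpos[r, ] <- m[Hi[r], ]; next }
      if (r > 1 && linked[r] && complete[r - 1]) {
        dir <- unitv(m[Ci[r - 1], ] - m[Oi[r - 1], ])
        Hpos[r, ] <- m[Ni[r], ] + dir
      }
    }
    # KS[i, j]: CO of residue i bonded to NH of residue j
    KS <- matrix(FALSE, nres, nres)
    for (i in which(complete)) for (j in which(complete)) {
      if (abs(i - j) < 2 || anyNA(Hpos[j, ])) next
      rON <- vnorm(m[Oi[i], ] - m[Ni[j], ])
      rCH <- vnorm(m[Ci[i], ] - Hpos[j, ])
      rOH <- vnorm(m[Oi[i], ] - Hpos[j, ])
      rCN <- vnorm(m[Ci[i], ] - m[Ni[j], ])
      if (min(rON, rCH, rOH, rCN) < 0.5) next  # clashing geometry
      E <- 0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
      if (E < -0.5) KS[i, j] <- TRUE
    }
    seg <- cumsum(!linked)  # chain-break segments: turns never span breaks
    turn <- function(d) vapply(seq_len(nres), function(i)
      i + d <= nres && seg[i] == seg[i + d] && KS[i, i + d], TRUE)
    t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
    cls <- rep("C", nres)
    # bend: C-alpha curvature over i +/- 2
    for (i in 3:(nres - 2)) {
      if (nres < 5) break
      if (!all(complete[(i - 2):(i + 2)])) next
      if (seg[i - 2] != seg[i + 2]) next
      v1 <- m[CAi[i], ] - m[CAi[i - 2], ]
      v2 <- m[CAi[i + 2], ] - m[CAi[i], ]
      ang <- acos(pmin(1, pmax(-1, sum(unitv(v1) * unitv(v2))))) * 180 / pi
      if (ang > 70) cls[i] <- "S"
    }
    # turns (3- and 5-turns, and isolated 4-turns)
    for (d in c(3, 4, 5)) for (i in which(turn(d)))
      for (k in (i + 1):(i + d - 1)) cls[k] <- "T"
    # beta bridges
    for (i in which(complete)) for (j in which(complete)) {
      if (j - i < 3) next
      par <- (i > 1 && i < nres && KS[i - 1, j] && KS[j, i + 1]) ||
             (j > 1 && j < nres && KS[j - 1, i] && KS[i, j + 1])
      anti <- (KS[i, j] && KS[j, i]) ||
              (i > 1 && i < nres && j > 1 && j < nres &&
               KS[i - 1, j + 1] && KS[j - 1, i + 1])
      if (par || anti) { cls[i] <- "E"; cls[j] <- "E" }
    }
    # alpha helix: two consecutive 4-turns
    for (i in seq_len(nres)) if (i > 1 && t4[i - 1] && t4[i])
      for (k in i:(i + 3)) cls[k] <- "H"
    cls[!complete] <- "C"
    classes[f, ] <- cls
  }
  lv <- c("H", "E", "T", "S", "C")
  frac <- t(apply(classes, 1, function(row)
    as.numeric(table(factor(row, levels = lv))) / nres))
  colnames(frac) <- lv
  structure(list(classes = classes,
                 fractions = cbind(data.frame(time = traj$times),
                                   as.data.frame(frac)),
                 resno = resno_of),
            class = "ss_timeline")
}

#' @export
print.ss_timeline <- function(x, ...) {
  avg <- colMeans(x$fractions[, c("H", "E", "T", "S", "C")])
  cat(sprintf(
    "<ss_timeline> %d frames x %d residues; mean H %.1f%%, E %.1f%%, T %.1f%%, S %.1f%%, C %.1f%%\n",
    nrow(x$classes), ncol(x$classes),
    100 * avg["H"], 100 * avg["E"], 100 * avg["T"], 100 * avg["S"],
    100 * avg["C"]))
  invisible(x)
}
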