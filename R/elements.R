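# Element lookup tables used across the package: masses (Da), Bondi-style
# van der Waals radii (Angstrom), valence electron counts, default valences
# and principal quantum numbers for the organic subset plus common halogens.

.element_table <- data.frame(
  symbol  = c("H","B","C","N","O","F","Na","Mg","P","S","Cl","K","Ca",
              "Br","I"),
  mass    = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
              30.974, 32.066, 35.453, 39.098, 40.078, 79.904, 126.904),
  vdw     = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.27, 1.73,
              1.80, 1.80, 1.75, 2.75, 2.31, 1.85, 1.98),
  zv      = c(1, 3, 4, 5, 6, 7, 1, 2, 5, 6, 7, 1, 2, 7, 7),
  nquant  = c(1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 3, 4, 4, 4, 5),
  valence = c(1, 3, 4, 3, 2, 1, 1, 2, 3, 2, 1, 1, 2, 1, 1),
  stringsAsFactors = FALSE
)

.elem_lookup <- function(symbols, field, default = NA_real_) {
  i <- match(symbols, .element_table$symbol)
  out <- .element_table[[field]][i]
  out[is.na(i)] <- default
  out
}

element_mass <- function(symbols) .elem_lookup(symbols, "mass", 12.011)
element_vdw  <- function(symbols) .elem_lookup(symbols, "vdw", 1.7)
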