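test_that("molecule reading handles SMILES, corrupt records and empty input", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1\tbenzene", "CCO\tethanol", "not_a_smiles((("), f)
  expect_warning(mols <- read_molecules(f, "smiles"), "skipped")
  expect_length(mols, 2)
  expect_equal(mols[[1]]$name, "benzene")
  expect_equal(nrow(mols[[1]]$atoms), 6)
  expect_equal(sum(lengths(mols[[1]]$rings) == 6), 1)

  empty <- tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  expect_error(read_molecules(empty, "smiles"), "no parseable")
  expect_error(read_molecules(tempfile(), "smiles"), "cannot read")
})

test_that("SDF round trip keeps structure and skips corrupt records", {
  sdf_path <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(ChemmineR::smiles2sdf(c(a = "c1ccccc1", b = "CCO")),
                       sdf_path)
  mols <- read_molecules(sdf_path, "sdf")
  expect_length(mols, 2)
  expect_equal(nrow(mols[[1]]$atoms), 6)
})

test_that("E-state atom typing matches canonical definitions", {
  m <- mols_from_smiles(c("c1ccccc1", "Oc1ccccc1", "CN(C)C"))
  expect_equal(estate_atom_types(m[[1]]), rep("aaCH", 6))
  tp <- estate_atom_types(m[[2]])
  expect_equal(sum(tp == "aaCH"), 5)
  expect_equal(sum(tp == "aasC"), 1)
  expect_equal(sum(tp == "sOH"), 1)
  tn <- estate_atom_types(m[[3]])
  expect_equal(tn[m[[3]]$atoms$element == "N"], "sssN")
})

test_that("E-state indices match hand evaluation on propane and symmetry", {
  pr <- mols_from_smiles("CCC")[[1]]
  S <- estate_indices(pr)
  # intrinsic states: CH3 I = 2, CH2 I = 1.5; perturbations over d in {2,3}
  term <- 2 + (2 - 1.5) / 4 + (2 - 2) / 9
  cent <- 1.5 + 2 * (1.5 - 2) / 4
  deg <- tabulate(c(pr$bonds$a1, pr$bonds$a2), nrow(pr$atoms))
  expect_equal(sort(S[deg == 1]), c(term, term), tolerance = 1e-12)
  expect_equal(S[deg == 2], cent, tolerance = 1e-12)

  et <- mols_from_smiles("CC")[[1]]
  expect_equal(estate_indices(et)[1], estate_indices(et)[2])

  # single heavy atom: no perturbation, S = I with degree clamped
  meth <- molecule(data.frame(element = "C", nH = 4))
  expect_equal(estate_indices(meth), ((2 / 2)^2 * 0 + 1) / 1)
})

test_that("E-state sum is conserved and zero-count implies zero-sum", {
  mols <- mols_from_smiles(c("c1ccccc1", "Oc1ccccc1", "CC(=O)Nc1ccccc1",
                             "CCN(CC)CC", "OCC(O)CO"))
  for (m in mols) {
    S <- estate_indices(m)
    deg <- pmax(tabulate(c(m$bonds$a1, m$bonds$a2), nrow(m$atoms)), 1)
    zv <- cvscreen:::.elem_lookup(m$atoms$element, "zv")
    nq <- cvscreen:::.elem_lookup(m$atoms$element, "nquant")
    I <- ((2 / nq)^2 * (zv - m$atoms$nH) + 1) / deg
    expect_equal(sum(S), sum(I), tolerance = 1e-9)
    d <- compute_descriptors(m)
    if (d[["ES_Count_aaCH"]] == 0) expect_equal(d[["ES_Sum_aaCH"]], 0)
    if (d[["ES_Count_sOH"]] == 0) expect_identical(unname(d["ES_Count_sOH"]), 0)
  }
})

test_that("fragment TPSA reproduces published contributions", {
  # expected values computed once with an independent reference
  # implementation of the Ertl fragment scheme
  cases <- c("Oc1ccccc1" = 20.23, "Nc1ccccc1" = 26.02, "c1ccncc1" = 12.89,
             "CC(=O)O" = 37.30, "CN(C)C" = 3.24, "O=C(N)c1ccccc1" = 43.09,
             "CCOC" = 9.23, "c1ccc2[nH]ccc2c1" = 15.79,
             "C[N+](C)(C)C" = 0.00, "CC#N" = 23.79)
  mols <- mols_from_smiles(names(cases))
  for (i in seq_along(cases))
    expect_equal(tpsa(mols[[i]]), unname(cases[i]), tolerance = 1e-8,
                 label = names(cases)[i])
})

test_that("CHI_2 matches hand enumeration and is order-invariant", {
  pr <- mols_from_smiles("CCC")[[1]]
  expect_equal(chi2_index(pr), 1 / sqrt(2), tolerance = 1e-12)
  # isobutane: three 2-paths through the central carbon, all (1,3,1)
  ib <- mols_from_smiles("CC(C)C")[[1]]
  expect_equal(chi2_index(ib), 3 / sqrt(3), tolerance = 1e-12)
  # reorder atoms of propane by hand
  perm <- c(3, 1, 2)
  atoms2 <- pr$atoms[perm, c("element", "charge", "nH")]
  inv <- order(perm)
  bonds2 <- data.frame(a1 = inv[pr$bonds$a1], a2 = inv[pr$bonds$a2],
                       order = pr$bonds$order)
  expect_equal(chi2_index(molecule(atoms2, bonds2)), chi2_index(pr))
})

test_that("descriptor vector for benzene and 3D requirements behave", {
  b <- mols_from_smiles("c1ccccc1")[[1]]
  d <- compute_descriptors(b)
  expect_equal(unname(d["Num_Rings6"]), 1)
  expect_equal(unname(d["ES_Count_sOH"]), 0)
  expect_equal(unname(d["Molecular_PolarSurfaceArea"]), 0)
  expect_equal(unname(d["ES_Count_aaCH"]), 6)
  expect_identical(names(d), descriptor_names())
  # molecule with no coordinates: 3D descriptors absent, or an error on demand
  flat <- molecule(data.frame(element = c("C", "C"), nH = c(3, 3)),
                   data.frame(a1 = 1, a2 = 2, order = 1))
  d2 <- compute_descriptors(flat)
  expect_true(is.na(d2[["Jurs_TPSA"]]) && is.na(d2[["Shadow_Ylength"]]))
  expect_error(compute_descriptors(flat, need_3d = TRUE), "requires-3D")
  # energy passthrough
  expect_equal(unname(compute_descriptors(b, energy = -42)["Minimized_Energy"]),
               -42)
})

test_that("shadow length is rigid-invariant and polar SASA bounded by total", {
  set.seed(11)
  atoms <- data.frame(element = c("C", "C", "O", "N", "C", "O"),
                      nH = c(3, 1, 1, 2, 2, 0),
                      x = runif(6, -3, 3), y = runif(6, -3, 3),
                      z = runif(6, -3, 3))
  bonds <- data.frame(a1 = 1:5, a2 = 2:6, order = c(1, 1, 1, 1, 2))
  m <- molecule(atoms, bonds)
  sy <- shadow_ylength(m)
  rt <- random_rigid(4)
  atoms2 <- atoms
  xyz2 <- sweep(as.matrix(atoms[, c("x", "y", "z")]) %*% t(rt$R), 2, rt$t, "+")
  atoms2[, c("x", "y", "z")] <- xyz2
  expect_equal(shadow_ylength(molecule(atoms2, bonds)), sy, tolerance = 1e-6)

  cc <- cvscreen:::.mol_coords(m)
  total <- shrake_rupley(cc$xyz, cc$radii)$total
  expect_lte(jurs_tpsa(m), total + 1e-9)
  expect_gt(jurs_tpsa(m), 0)
})

test_that("descriptor tables are written with canonical columns", {
  mols <- mols_from_smiles(c("c1ccccc1", "CCO"))
  f <- tempfile(fileext = ".csv")
  tab <- compute_descriptor_table(mols, energies = c(-10, -20), path = f)
  expect_equal(names(tab), c("id", descriptor_names()))
  back <- read.csv(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$Minimized_Energy, c(-10, -20))
})
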