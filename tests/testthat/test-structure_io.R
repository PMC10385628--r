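test_that("PDB write/read round-trips coordinates and records", {
  # minimal two-atom model
  cx <- make_two_atom_complex("C", 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cx$a, f)
  m <- read_structure(f)
  expect_equal(coords(m), coords(cx$a), tolerance = 1e-9)
  expect_equal(m$atoms$resno, cx$a$atoms$resno)

  # synthetic protonated residue round-trips to format precision
  gly <- place_hydrogens(glycine_model())
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(gly, f2)
  m2 <- read_structure(f2)
  expect_equal(n_atoms(m2), n_atoms(gly))
  expect_lt(max(abs(coords(m2) - coords(gly))), 5e-4)

  # multi-model files come back as ensembles with matching frames
  ens <- make_gaussian_ensemble(cx$a, 0.1, 3, seed = 5)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, f3)
  back <- read_structure(f3)
  expect_s3_class(back, "mol_ensemble")
  expect_equal(n_frames(back), 3)
  expect_lt(max(abs(back$xyz - ens$xyz)), 5e-4)
})

test_that("altloc records are retained on read and reduced by occupancy", {
  txt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       0.500   0.000   0.000  0.60 10.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, f)
  m <- read_structure(f)
  expect_equal(n_atoms(m), 2)
  expect_setequal(m$atoms$alt, c("A", "B"))
  one <- filter_altloc(m)
  expect_equal(n_atoms(one), 1)
  expect_equal(one$atoms$alt, "B")  # higher occupancy wins
})

test_that("interaction typing follows the bonded-atom rules", {
  gly <- assign_interaction_types(glycine_model())
  ty <- setNames(gly$atoms$type, gly$atoms$name)
  expect_equal(unname(ty[c("HA2", "HA3")]), c("Hc", "Hc"))
  expect_equal(unname(ty["H"]), "Ho/n")
  expect_equal(unname(ty["O"]), "O")
  expect_equal(unname(ty["N"]), "N")

  # water oxygen types W even without hydrogens
  w <- assign_interaction_types(water_model())
  expect_equal(w$atoms$type, "W")

  # guanidinium: NH hydrogens Ho/n, nitrogens N (hydrophobic class)
  g <- assign_interaction_types(guanidinium_model())
  tg <- setNames(g$atoms$type, g$atoms$name)
  expect_equal(unname(tg["HH11"]), "Ho/n")
  expect_true(all(tg[c("NH1", "NH2", "NE")] == "N"))

  # the six types partition the atom set
  expect_equal(sum(table(factor(gly$atoms$type, contact_types()))),
               n_atoms(gly))

  # a stranded hydrogen is an error naming the atom
  bad <- glycine_model()
  bad$atoms$x[5] <- 50
  expect_error(assign_interaction_types(bad), "no bonded heavy atom")
})

test_that("residue contacts match a brute-force scan and are symmetric", {
  a <- carbon_model(c(0, 0, 0))
  b <- carbon_model(c(3, 0, 0), side = "b", chain = "B", id0 = 10L)
  rc <- residue_contacts(a, b, cutoff = 4)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$min_distance, 3)
  expect_equal(nrow(residue_contacts(a, b, cutoff = 2.5)), 0)
  expect_error(residue_contacts(a, b, cutoff = -1), "cutoff")

  # 3x3 residue grids with known spacing vs an all-pairs oracle
  g1 <- as.matrix(expand.grid(x = c(0, 2, 4), y = c(0, 2, 4), z = 0))
  g2 <- sweep(g1, 2, c(1.5, 1, 5))
  ma <- carbon_model(g1)
  mb <- carbon_model(g2, side = "b", chain = "B", id0 = 20L)
  rc <- residue_contacts(ma, mb, cutoff = 4)
  oracle <- 0L
  for (i in seq_len(nrow(g1))) for (j in seq_len(nrow(g2)))
    if (sqrt(sum((g1[i, ] - g2[j, ])^2)) < 4) oracle <- oracle + 1L
  expect_equal(nrow(rc), oracle)

  swapped <- residue_contacts(mb, ma, cutoff = 4)
  key1 <- sort(paste(rc$resno_a, rc$resno_b, round(rc$min_distance, 9)))
  key2 <- sort(paste(swapped$resno_b, swapped$resno_a,
                     round(swapped$min_distance, 9)))
  expect_equal(key1, key2)
})

test_that("isoelectric point behaves like a titration midpoint", {
  # two-group system: closed-form midpoint of the pKa values
  expect_equal(isoelectric_point("GG", pka = c(Nterm = 9.6, Cterm = 2.34)),
               (9.6 + 2.34) / 2, tolerance = 1e-3)
  # composition-only dependence
  s <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(isoelectric_point(s),
               isoelectric_point(paste(rev(strsplit(s, "")[[1]]),
                                       collapse = "")))
  # side-chain charge sign ordering and monotone residue effects
  expect_gt(isoelectric_point("K"), isoelectric_point("D"))
  base <- isoelectric_point("GGGG")
  expect_gte(isoelectric_point("GGGGK"), base)
  expect_lte(isoelectric_point("GGGGD"), base)
  expect_error(isoelectric_point("GXZ"), "unknown residue")
})

test_that("placed hydrogens sit at the expected bond lengths", {
  heavy <- model_subset(glycine_model(), 1:4)
  prot <- place_hydrogens(heavy)
  added <- prot$atoms[prot$atoms$element == "H", ]
  expect_gt(nrow(added), 0)
  bonds <- derive_bonds(prot)
  xyz <- coords(prot)
  for (i in which(prot$atoms$element == "H")) {
    j <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    j <- j[prot$atoms$element[j] != "H"]
    expect_equal(length(j), 1)
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    expected <- c(C = 1.083, N = 1.009, O = 0.967)[[prot$atoms$element[j]]]
    expect_equal(d, expected, tolerance = 1e-6)
  }
  # typing works on the protonated result
  expect_silent(assign_interaction_types(prot))
})
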