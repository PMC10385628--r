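ref <- kdkppr_reference_composition()

test_that("surface composition and contact proportions sum over facet areas", {
  p <- make_random_patches(500, c(C = 60, O = 40), c(Hc = 50, `Ho/n` = 50),
                           seed = 2, area = runif(500, 0.5, 2))
  S_a <- surface_composition(p, "a")
  S_b <- surface_composition(p, "b")
  C <- contact_proportions(p)
  expect_equal(sum(S_a), 100, tolerance = 1e-9)
  expect_equal(sum(S_b), 100, tolerance = 1e-9)
  expect_equal(sum(C), 100, tolerance = 1e-9)
  # brute-force per-facet tally oracle
  hand_S <- 100 * sum(p$area[p$type_in == "C"]) / p$total_area
  expect_equal(unname(S_a["C"]), hand_S, tolerance = 1e-9)
  hand_C <- 100 * sum(p$area[(p$type_in == "C" & p$type_out == "Hc") |
                               (p$type_in == "Hc" & p$type_out == "C")]) /
    p$total_area
  expect_equal(unname(C["C|Hc"]), hand_C, tolerance = 1e-9)
  # single-type cases
  p1 <- make_random_patches(10, c(O = 100), c(`Ho/n` = 100), seed = 1)
  expect_equal(unname(surface_composition(p1, "a")["O"]), 100)
  expect_equal(unname(contact_proportions(p1)["Ho/n|O"]), 100)
})

test_that("random contacts are probability products that renormalize", {
  R <- random_contacts(c(C = 100), c(O = 100))
  expect_equal(unname(R["C|O"]), 100)
  expect_equal(sum(R), 100)
  # printed-composition example
  R2 <- random_contacts(ref$S_a, ref$S_b)
  expect_equal(unname(R2["Ho/n|O"]), (20.1 * 15.6 + 22.9 * 15.9) / 100,
               tolerance = 1e-12)
  expect_equal(sum(R2), sum(ref$S_a) * sum(ref$S_b) / 100, tolerance = 1e-9)
  expect_error(random_contacts(c(C = -5, Hc = 105), c(C = 100)), ">= 0")
})

test_that("enrichment is C/R with undefined pairs flagged, not zeroed", {
  R <- random_contacts(c(C = 50, O = 50), c(C = 50, O = 50))
  E <- enrichment(R, R)  # perfect random mixing
  defined <- !is.na(E)
  expect_true(all(abs(E[defined] - 1) < 1e-12))
  # R below the definability floor comes back NA (or 0 on request)
  E2 <- enrichment(c(`C|C` = 0.1), setNames(c(0.01, 99.99), c("C|C", "C|O")))
  expect_true(is.na(E2["C|C"]))
  expect_equal(unname(enrichment(c(`C|C` = 0.1),
                                 setNames(c(0.01, 99.99), c("C|C", "C|O")),
                                 undefined = "zero")["C|C"]), 0)
})

test_that("reference complex: recomputed enrichments match the published table", {
  tbl <- contact_table_from_composition(ref$S_a, ref$S_b, ref$C)
  # headline contacts reproduce to +/- 0.02 (one-decimal input rounding)
  expect_equal(unname(tbl$E["Ho/n|O"]), 2.58, tolerance = 0.02)
  expect_equal(unname(tbl$E["C|Hc"]), 1.80, tolerance = 0.02)
  expect_equal(unname(tbl$E["Hc|O"]), 1.20, tolerance = 0.02)
  expect_equal(unname(tbl$E["Hc|Hc"]), 0.81, tolerance = 0.02)
  expect_equal(unname(tbl$E["Ho/n|W"]), 1.88, tolerance = 0.02)
  # the full published E triangle is consistent within the +/- 0.05 envelope
  # implied by one-decimal rounding of all printed inputs
  printed <- c(`C|C` = 0.75, `C|Hc` = 1.80, `C|N` = 1.02, `C|Ho/n` = 0.54,
               `C|O` = 0.08, `C|W` = 0.73, `Hc|Hc` = 0.81, `Hc|N` = 1.62,
               `Hc|Ho/n` = 0.53, `Hc|O` = 1.20, `Hc|W` = 0.70,
               `N|Ho/n` = 0.40, `N|O` = 0.17, `N|W` = 1.44,
               `Ho/n|Ho/n` = 0.44, `Ho/n|O` = 2.58, `Ho/n|W` = 1.88,
               `O|O` = 0.09, `O|W` = 0.64)
  expect_true(all(abs(tbl$E[names(printed)] - printed) <= 0.05))
  # repulsive self-contacts are absent
  expect_equal(unname(tbl$C["N|N"]), 0)
})

test_that("hydrophobic grouping sums members and reapplies the formulas", {
  tbl <- contact_table_from_composition(ref$S_a, ref$S_b, ref$C)
  g <- tbl$grouped
  expect_equal(unname(g$S_b["Hphob"]), 21.4 + 30.0 + 1.2)  # = 52.6 exactly
  expect_equal(unname(g$S_a["Hphob"]), 8.8 + 42.7 + 5.5)
  expect_equal(sum(g$C), sum(tbl$C), tolerance = 1e-9)
  expect_equal(unname(g$E["Hphob|Hphil"]), 0.69, tolerance = 0.02)
  expect_equal(unname(g$E["Hphob|Hphob"]), 1.26, tolerance = 0.02)
  expect_equal(unname(g$E["Hphil|Hphil"]), 1.38, tolerance = 0.02)
  # degenerate grouping (one group per type) reproduces the ungrouped table
  solo <- setNames(as.list(contact_types()), contact_types())
  gd <- group_hydrophobic(tbl, grouping = solo)
  remap <- function(keys) vapply(strsplit(keys, "|", fixed = TRUE),
                                 function(p) contactzones:::pair_key(p[1], p[2]),
                                 character(1))
  expect_equal(unname(gd$C[order(remap(names(gd$C)))]),
               unname(tbl$C[order(names(tbl$C))]), tolerance = 1e-12)
  # non-partition grouping is rejected
  expect_error(group_hydrophobic(tbl, grouping = list(A = c("C", "Hc"))),
               "partition")
})

test_that("null calibration: independent draws give enrichment near one", {
  p <- make_random_patches(50000, ref$S_a, ref$S_b, seed = 9)
  tbl <- contact_table(p)
  e <- tbl$E[!is.na(tbl$E) & tbl$R > 2]
  expect_true(all(e > 0.9 & e < 1.1))
  expect_equal(sum(tbl$C), 100, tolerance = 1e-9)
})

test_that("contact table serialization round-trips the numbers", {
  tbl <- contact_table_from_composition(ref$S_a, ref$S_b, ref$C)
  fj <- withr::local_tempfile(fileext = ".json")
  write_contact_table(tbl, fj, format = "json")
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$E[["Ho/n|O"]], round(unname(tbl$E["Ho/n|O"]), 4))
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_contact_table(tbl, ft)
  ln <- readLines(ft)
  expect_true(any(startsWith(ln, "surface_a")))
  expect_true(any(ln == "E_XY"))
})
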