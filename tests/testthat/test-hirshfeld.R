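# Interface construction tests run at 0.25 A spacing to stay quick; the
# finer-grid convergence study lives in the acceptance suite.

test_that("homonuclear interface is the bisector plane", {
  cx <- make_two_atom_complex("C", 3)
  p <- build_interface(cx$a, cx$b, spacing = 0.25)
  expect_gt(n_facets(p), 0)
  expect_lt(max(abs(p$verts[, 1])), 0.25)           # within one grid spacing
  expect_equal(p$total_area, sum(p$area))
  expect_true(all(p$area > 0))
  # every facet joins the unique atom pair
  expect_true(all(p$atom_in == 1L))
  expect_true(all(p$atom_out == 2L))
  expect_true(all(p$type_in == "C"))
})

test_that("raising the density cutoff shrinks the retained area", {
  cx <- make_two_atom_complex("C", 3)
  a1 <- build_interface(cx$a, cx$b, spacing = 0.25)$total_area
  a2 <- build_interface(cx$a, cx$b, spacing = 0.25,
                        density_cutoff = 0.0013 * 3)$total_area
  a3 <- build_interface(cx$a, cx$b, spacing = 0.25,
                        density_cutoff = 0.0013 * 10)$total_area
  expect_lt(a2, a1)
  expect_lte(a3, a2)
  # wider separation decays the density, shrinking the retained disc
  far <- make_two_atom_complex("C", 6)
  a_far <- build_interface(far$a, far$b, spacing = 0.25)$total_area
  expect_lt(a_far, a1)
})

test_that("swapping sides yields the same facets with roles exchanged", {
  cx <- make_two_atom_complex("C", 3)
  p <- build_interface(cx$a, cx$b, spacing = 0.25)
  q <- build_interface(cx$b, cx$a, spacing = 0.25)
  expect_equal(q$total_area, p$total_area, tolerance = 1e-9)
  expect_equal(sort(q$area), sort(p$area), tolerance = 1e-9)
  expect_equal(unique(q$atom_in), unique(p$atom_out))
})

test_that("total area is invariant under rigid motion", {
  cx <- make_two_atom_complex("C", 3)
  p <- build_interface(cx$a, cx$b, spacing = 0.25)
  R <- rotation_z(0.61) %*% rbind(c(1, 0, 0),
                                  c(0, cos(0.3), -sin(0.3)),
                                  c(0, sin(0.3), cos(0.3)))
  a2 <- build_interface(rotate_model(cx$a, R, c(0.3, -0.2, 0.15)),
                        rotate_model(cx$b, R, c(0.3, -0.2, 0.15)),
                        spacing = 0.25)
  expect_equal(a2$total_area, p$total_area, tolerance = 0.06)
  expect_equal(unique(a2$atom_in), unique(p$atom_in))
})

test_that("facet-atom assignment equals the per-midpoint argmax oracle", {
  a <- carbon_model(rbind(c(-1.5, -1, 0), c(-1.5, 1, 0)), side = "a")
  b <- carbon_model(c(1.5, 0, 0), side = "b", chain = "B", id0 = 10L)
  p <- build_interface(a, b, spacing = 0.25)
  expect_gt(n_facets(p), 0)
  contrib <- promolecule_at(a, p$midpoint, per_atom = TRUE)
  oracle <- a$atoms$id[apply(contrib, 1, which.max)]
  expect_equal(p$atom_in, oracle)
  expect_setequal(unique(p$atom_in), c(1L, 2L))
  # the nearest-atom alternative is available and recorded
  pn <- build_interface(a, b, spacing = 0.25, assign_rule = "nearest")
  expect_equal(pn$meta$assign_rule, "nearest")
})

test_that("degenerate inputs are handled as contracted", {
  cx <- make_two_atom_complex("C", 3)
  expect_error(build_interface(cx$a, cx$b, spacing = -0.1), "spacing")
  # impossible cutoff: empty interface is flagged, not an error
  p <- build_interface(cx$a, cx$b, spacing = 0.3, density_cutoff = 10)
  expect_equal(n_facets(p), 0)
  expect_true(p$meta$empty)
  expect_equal(p$total_area, 0)
})

test_that("mesh exports are consistent with the facet list", {
  cx <- make_two_atom_complex("C", 3)
  p <- build_interface(cx$a, cx$b, spacing = 0.3)
  fo <- withr::local_tempfile(fileext = ".obj")
  write_obj(p, fo)
  ln <- readLines(fo)
  expect_equal(sum(startsWith(ln, "v ")), 3 * n_facets(p))
  expect_equal(sum(startsWith(ln, "f ")), n_facets(p))
  fp <- withr::local_tempfile(fileext = ".ply")
  write_ply(p, fp)
  expect_true(any(grepl(sprintf("element face %d", n_facets(p)),
                        readLines(fp))))
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_patch_tsv(p, ft)
  tab <- read.delim(ft)
  expect_equal(nrow(tab), n_facets(p))
  expect_equal(sum(tab$area), p$total_area, tolerance = 1e-6)
})
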