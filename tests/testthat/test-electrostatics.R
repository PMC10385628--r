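test_that("charge assignment honors table precedence and overrides", {
  w <- water_model()
  m <- assign_charges(assign_interaction_types(w),
                      charge_table = data.frame(resname = "*", name = "*",
                                                type = "W", element = "*",
                                                charge = -0.8))
  expect_equal(m$atoms$charge, -0.8)
  # override beats the table
  m2 <- assign_charges(assign_interaction_types(w),
                       charge_table = data.frame(resname = "*", name = "*",
                                                 type = "W", element = "*",
                                                 charge = -0.8),
                       overrides = c(`1` = 0.25))
  expect_equal(m2$atoms$charge, 0.25)
  # full residue against a hand-built expectation (packaged generic set)
  gly <- assign_interaction_types(glycine_model())
  mg <- assign_charges(gly)
  want <- c(N = -0.45, C = 0.05, C = 0.05, O = -0.55, `Ho/n` = 0.35,
            Hc = 0.09, Hc = 0.09)
  expect_equal(mg$atoms$charge, unname(want))
  expect_equal(attr(mg, "total_charge"), sum(want))
  # strict mode flags unmatched atoms
  tbl0 <- data.frame(resname = "ZZZ", name = "*", type = "*", element = "*",
                     charge = 1)
  expect_error(assign_charges(gly, tbl0, strict = TRUE), "no charge rule")
  expect_warning(assign_charges(gly, tbl0), "defaulting to charge 0")
})

test_that("potential and field follow the Coulomb form", {
  mono <- make_charge_system(rbind(c(0, 0, 0)), -1)
  ce <- contactzones:::coulomb_at(matrix(c(1, 0, 0), 1), coords(mono), -1)
  expect_equal(ce$phi, -1)
  # dipole: potential vanishes on the perpendicular bisector plane
  dip <- make_charge_system(rbind(c(0, 0, 1), c(0, 0, -1)), c(1, -1))
  pts <- cbind(runif(20, -3, 3), runif(20, -3, 3), 0)
  phi <- contactzones:::coulomb_at(pts, coords(dip), dip$atoms$charge)$phi
  expect_lt(max(abs(phi)), 1e-12)
  # analytic field matches central differences away from sources
  set.seed(31)
  sys <- make_charge_system(matrix(runif(60, -3, 3), 20, 3),
                            runif(20, -1, 1))
  test_pts <- matrix(runif(30, 4, 6), 10, 3)  # outside the charge cloud
  h <- 1e-4
  for (k in 1:3) {
    dp <- dm <- test_pts
    dp[, k] <- dp[, k] + h
    dm[, k] <- dm[, k] - h
    fd <- -(contactzones:::coulomb_at(dp, coords(sys), sys$atoms$charge)$phi -
              contactzones:::coulomb_at(dm, coords(sys), sys$atoms$charge)$phi) / (2 * h)
    an <- contactzones:::coulomb_at(test_pts, coords(sys),
                                    sys$atoms$charge)$E[, k]
    expect_equal(fd, an, tolerance = 1e-4)
  }
})

test_that("potential grids superpose and mask singular voxels", {
  spec <- grid_spec(c(-2, -2, -2), 1, c(5, 5, 5))
  q1 <- make_charge_system(rbind(c(0.3, 0.2, 0.1)), 1)
  q2 <- make_charge_system(rbind(c(-0.4, 0.3, -0.2)), -0.5)
  both <- make_charge_system(rbind(c(0.3, 0.2, 0.1), c(-0.4, 0.3, -0.2)),
                             c(1, -0.5))
  p1 <- potential_and_field(q1, spec)$phi$values
  p2 <- potential_and_field(q2, spec)$phi$values
  p12 <- potential_and_field(both, spec)$phi$values
  expect_equal(p12, p1 + p2, tolerance = 1e-12)
  # voxel on top of a source is masked
  at_source <- make_charge_system(rbind(c(0, 0, 0)), 1)
  pm <- potential_and_field(at_source, spec)$phi$values
  expect_true(is.na(pm[3, 3, 3]))
  expect_error(potential_and_field(q1, spec, exclude = 1), "no source atoms")
  # mirror-symmetric charges give a mirror-symmetric potential
  mir <- make_charge_system(rbind(c(-1.3, 0, 0), c(1.3, 0, 0)), c(-1, -1))
  pv <- potential_and_field(mir, spec)$phi$values
  expect_equal(pv, pv[rev(seq_len(dim(pv)[1])), , ], tolerance = 1e-10)
})

test_that("field lines terminate per the monopole/dipole/mirror contracts", {
  mono <- make_charge_system(rbind(c(0, 0, 0)), -1)
  fl <- trace_field_line(c(2, 1, 0.5), mono)
  expect_equal(fl$terminal, "atom")
  expect_equal(fl$atom, 1L)
  # dipole: a start near the axis midpoint runs to the negative charge;
  # the default step agrees with a 10x denser integration
  dip <- make_charge_system(rbind(c(0, 0, 1), c(0, 0, -1)), c(1, -1))
  f1 <- trace_field_line(c(0.5, 0, 0), dip, step = 0.05)
  f2 <- trace_field_line(c(0.5, 0, 0), dip, step = 0.005)
  expect_equal(f1$terminal, "atom")
  expect_equal(f1$atom, 2L)
  expect_equal(f2$atom, 2L)
  # mirror-paired starts hit mirror-paired sinks
  two <- make_charge_system(rbind(c(-1.5, 0, 0), c(1.5, 0, 0)), c(-1, -1))
  res <- trace_field_lines(rbind(c(-0.8, 0.4, 0.2), c(0.8, 0.4, 0.2)), two)
  expect_equal(res$terminal, c("atom", "atom"))
  expect_equal(res$atom, c(1L, 2L))
  # zero-field start stagnates immediately
  quad <- make_charge_system(rbind(c(-1, 0, 0), c(1, 0, 0)), c(-1, -1))
  r0 <- trace_field_lines(matrix(c(0, 0, 0), 1), quad)
  expect_equal(r0$terminal, "stagnated")
})

test_that("NIZ basins partition the seeds and respect symmetry", {
  spec <- grid_spec(c(-3.75, -3.75, -3.75), 0.5, c(16, 16, 16))
  mono <- make_charge_system(rbind(c(0, 0, 0)), -1)
  nm <- niz_map(mono, targets = 1, spec = spec)
  expect_equal(nm$volumes$fraction_of_seeds, 1)
  # two equal sinks: equal basin volumes, disjoint and exhaustive labels
  two <- make_charge_system(rbind(c(-1.5, 0, 0), c(1.5, 0, 0)), c(-1, -1))
  nm2 <- niz_map(two, targets = c(1, 2), spec = spec)
  expect_equal(nm2$volumes$volume[1], nm2$volumes$volume[2],
               tolerance = 0.02)
  lab <- nm2$labels[nm2$labels != "source"]
  expect_equal(sum(lab == "1") + sum(lab == "2") +
                 sum(lab %in% c("other", "escaped", "stagnated")),
               nm2$n_seeds)
  # a remote perturbing charge does not relabel interior voxels
  three <- make_charge_system(rbind(c(-1.5, 0, 0), c(1.5, 0, 0),
                                    c(40, 0, 0)), c(-1, -1, 0.5))
  nm3 <- niz_map(three, targets = c(1, 2), spec = spec)
  core <- abs(voxel_centers(spec)[, 1]) > 0.75  # away from the separatrix
  same <- nm2$labels[array(core, spec$dims)] == nm3$labels[array(core, spec$dims)]
  expect_gt(mean(same), 0.99)
})

test_that("NIZ export writes label cube and volume summary", {
  mono <- make_charge_system(rbind(c(0, 0, 0)), -1)
  spec <- grid_spec(c(-1.75, -1.75, -1.75), 0.5, c(8, 8, 8))
  nm <- niz_map(mono, targets = 1, spec = spec)
  fc <- withr::local_tempfile(fileext = ".cube")
  fj <- withr::local_tempfile(fileext = ".json")
  write_niz(nm, cube_path = fc, json_path = fj)
  expect_true(file.exists(fc))
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(js$volumes$voxels, nm$volumes$voxels)
  expect_match(js$model, "point-charge")
})
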