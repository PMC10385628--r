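test_that("Kabsch superposition nulls rigid motion and resists reflection", {
  set.seed(13)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  R <- rotation_z(1.1)
  moved <- x %*% R + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(moved, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$xyz, x, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  # near-planar point set that would invite an improper solution
  flat <- cbind(matrix(rnorm(8), 4, 2), 0)
  mirr <- flat %*% diag(c(1, 1, -1))
  expect_equal(det(kabsch_superpose(mirr, flat)$rotation), 1,
               tolerance = 1e-12)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(x, x[1:5, ]), "matching dimensions")
})

test_that("Kabsch minimum matches an independent optimizer search", {
  # 4-point fixture with one point displaced: compare against a general
  # optimizer over Euler angles (centroid translation handled analytically)
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mob <- ref
  mob[4, ] <- mob[4, ] + c(1, 0, 0)
  mob <- mob %*% rotation_z(0.4) + 1.5
  euler_rmsd <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    R <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    X <- scale(mob, scale = FALSE) %*% R
    Y <- scale(ref, scale = FALSE)
    sqrt(mean(rowSums((X - Y)^2)))
  }
  starts <- expand.grid(a = c(0, pi / 2, pi, -pi / 2),
                        b = c(0, pi / 2, -pi / 2), c = c(0, pi))
  best <- min(apply(starts, 1, function(s)
    optim(as.numeric(s), euler_rmsd, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 5000))$value))
  expect_equal(kabsch_superpose(mob, ref)$rmsd, best, tolerance = 1e-3)
})

test_that("RMSD series scale with ensemble noise", {
  base <- carbon_model(matrix(rnorm(60, sd = 4), 20, 3))
  static <- make_gaussian_ensemble(base, 0, 5, seed = 1)
  expect_equal(rmsd_series(static), rep(0, 5), tolerance = 1e-12)
  e1 <- make_gaussian_ensemble(base, 0.1, 120, seed = 2)
  e2 <- make_gaussian_ensemble(base, 0.2, 120, seed = 2)
  r1 <- mean(rmsd_series(e1, reference = contactzones:::ensemble_frame(e1, 1)))
  r2 <- mean(rmsd_series(e2, reference = contactzones:::ensemble_frame(e2, 1)))
  skip_if_not(r1 > 0)
  expect_equal(r2 / r1, 2, tolerance = 0.2)
  expect_error(rmsd_series(e1, selection = integer(0)), "empty selection")
})

test_that("RMSF recovers the generating sigma of a Gaussian ensemble", {
  base <- carbon_model(matrix(rnorm(150, sd = 5), 50, 3))
  ens <- make_gaussian_ensemble(base, 0.2, 800, seed = 4)
  prof <- rmsf(ens, align = FALSE)
  expect_equal(mean(prof$value), 0.2 * sqrt(3), tolerance = 0.05)
  # static ensemble: all zeros; single frame: error
  ens0 <- make_gaussian_ensemble(base, 0, 3, seed = 1)
  expect_equal(rmsf(ens0, align = FALSE)$value, rep(0, 50), tolerance = 1e-12)
  expect_error(rmsf(mol_ensemble(base$atoms,
                                 array(coords(base), c(50, 3, 1)))),
               "at least 2")
  # two sigma groups: RMSF ratio tracks the sigma ratio
  sig <- rep(c(0.1, 0.3), each = 25)
  ens2 <- make_gaussian_ensemble(base, sig, 800, seed = 6)
  p2 <- rmsf(ens2, align = FALSE)
  expect_equal(mean(p2$value[26:50]) / mean(p2$value[1:25]), 3,
               tolerance = 0.15)
})

test_that("RMSTD conversion is exact and invertible", {
  expect_equal(rmstd_from_b(8 * pi^2), 1)
  expect_equal(rmstd_from_b(0), 0)
  expect_equal(rmstd_from_b(25.55), 0.569, tolerance = 1e-3)
  b <- c(0, 5, 25.55, 80)
  expect_equal(b_from_rmstd(rmstd_from_b(b)), b, tolerance = 1e-12)
  expect_error(rmstd_from_b(-1), ">= 0")
})

test_that("profile correlation is Pearson r with its invariances", {
  set.seed(8)
  p1 <- runif(30)
  expect_equal(correlate_profiles(p1, 2 * p1 + 1), 1, tolerance = 1e-12)
  expect_equal(correlate_profiles(p1, -p1), -1, tolerance = 1e-12)
  p2 <- runif(30)
  hand <- sum((p1 - mean(p1)) * (p2 - mean(p2))) /
    sqrt(sum((p1 - mean(p1))^2) * sum((p2 - mean(p2))^2))
  expect_equal(correlate_profiles(p1, p2), hand, tolerance = 1e-12)
  expect_equal(correlate_profiles(p1, p2), correlate_profiles(p2, p1))
  expect_error(correlate_profiles(p1, p2[1:10]), "length")
  expect_error(correlate_profiles(rep(1, 10), runif(10)), "zero variance")
})
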