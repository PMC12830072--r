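blood_matrix <- function() {
  build_extinction_matrix(spectral_library(), c(532, 545, 558, 571),
                          c("HbO2", "Hb"))
}

test_that("NNLS recovers consistent systems and matches the grid oracle", {
  A <- blood_matrix()
  x0 <- c(0.3, 0.7)
  sol <- nnls_solve(A, unclass(A) %*% x0)
  expect_equal(unname(sol$x), x0, tolerance = 1e-8)
  expect_true(all(nnls_solve(A, rep(0, 4))$x == 0))

  # b chosen so the unconstrained least-squares solution goes negative
  set.seed(17)
  for (i in 1:5) {
    b <- as.numeric(unclass(A) %*% c(runif(1, 0.5, 1.5), 0)) +
      rnorm(4, sd = 2)
    ls <- qr.solve(unclass(A), b)
    if (all(ls >= 0)) next
    sol <- nnls_solve(A, b)
    expect_true(all(sol$x >= 0))
    oracle <- grid_nnls(unclass(A), b, upper = 3, step = 0.002)
    expect_lte(sol$residual, oracle$residual + 1e-9)
    expect_equal(unname(sol$x), oracle$x, tolerance = 0.01)
  }
  expect_error(nnls_solve(A, c(1, NA, 1, 1)), "non-finite")
})

test_that("Tikhonov-NNLS reduces to NNLS at lambda 0 and to 0 at huge lambda", {
  A <- blood_matrix()
  set.seed(5)
  for (i in 1:5) {
    b <- abs(rnorm(4, mean = 10))
    plain <- nnls_solve(A, b)
    reg0 <- tikhonov_nnls(A, b, 0)
    expect_identical(reg0$x, plain$x)          # bit-for-bit
    expect_identical(reg0$residual, plain$residual)
    big <- tikhonov_nnls(A, b, 1e9)
    expect_lt(max(big$x), 1e-8)
  }

  # grid oracle for the penalized objective at lambda = 1
  b <- c(30, 34, 31, 29)
  sol <- tikhonov_nnls(A, b, 1)
  oracle <- grid_tikhonov(unclass(A), b, 1, upper = 2, step = 0.002)
  obj_sol <- sol$residual^2 + sol$seminorm^2
  expect_lte(obj_sol, oracle$objective + 1e-6)
  expect_equal(unname(sol$x), oracle$x, tolerance = 0.01)
})

test_that("solution seminorm is non-increasing along the lambda grid", {
  A <- blood_matrix()
  set.seed(23)
  b <- as.numeric(unclass(A) %*% c(0.6, 0.4)) + rnorm(4, sd = 0.5)
  grid <- sort(paunmix:::default_lambda_grid(A))
  sem <- sapply(grid, function(l) tikhonov_nnls(A, b, l)$seminorm)
  expect_true(all(diff(sem) <= 1e-10))
})

test_that("L-curve selection honors its contracts", {
  A <- blood_matrix()
  grid <- paunmix:::default_lambda_grid(A)

  # noiseless consistent system: residual-dominated, smallest lambda
  b0 <- as.numeric(unclass(A) %*% c(0.8, 0.2))
  expect_equal(lcurve_select(A, b0), min(grid))

  # fixed mode bypasses selection
  expect_identical(lcurve_select(A, b0, regularization_config("fixed", lambda = 0.37)),
                   0.37)

  # joint rescaling of A and b moves the selection by the same factor
  set.seed(31)
  b <- b0 + rnorm(4, sd = 0.02 * max(b0))
  l1 <- lcurve_select(A, b)
  l2 <- lcurve_select(unclass(A) * 50, b * 50)
  expect_equal(l2 / l1, 50, tolerance = 1e-9)

  expect_error(regularization_config(lambda_grid = c(1, 2, 3)))
})

test_that("split unmixing recovers phantom truth at zero noise", {
  # dermal-only phantom
  acq <- acquisition_spec(samples_per_aline = 1024L, noise_sigma = 0,
                          energy_jitter = 0, seed = 13L)
  ph <- make_phantom("mixture_1", grid = c(12L, 12L))
  stack <- build_spectral_stack(simulate_frameset(ph, acq))
  part <- partition_regions(matrix(FALSE, 12, 12), masking_config(pixel_pitch_um = 60))
  maps <- split_unmix(stack, part)
  rel <- compute_relative(maps)
  expect_equal(as.vector(rel$melanin_rel), rep(1, 144), tolerance = 1e-6)
  expect_equal(as.vector(rel$collagen_rel), rep(99, 144), tolerance = 1e-6)
  expect_true(all(is.na(maps$HbO2)))

  # vascular phantom with the true vessel mask as partition
  env <- demo_stack()
  part2 <- partition_regions(!is.na(env$truth$so2),
                             masking_config(pixel_pitch_um = 60))
  maps2 <- split_unmix(env$stack, part2)
  so2 <- compute_so2(maps2)
  truth <- 100 * env$truth$so2
  on_vessel <- part2$vessel
  expect_equal(so2[on_vessel], truth[on_vessel], tolerance = 1e-8)
  # HbO2 : Hb ratio matches the phantom composition
  idx <- which(on_vessel & abs(truth - 97) < 1e-9)
  expect_equal(maps2$HbO2[idx] / maps2$Hb[idx], rep(97 / 3, length(idx)),
               tolerance = 1e-6)
  # buffer pixels carry the undefined sentinel in all four maps
  expect_true(all(is.na(maps2$HbO2[part2$buffer])))
  expect_true(all(is.na(maps2$Hb[part2$buffer])))
  expect_true(all(is.na(maps2$collagen[part2$buffer])))
  expect_true(all(is.na(maps2$melanin[part2$buffer])))
})

test_that("unmixing refuses uncompensated stacks unless forced", {
  env <- demo_stack()
  raw <- build_spectral_stack(env$frames, compensation = "none")
  part <- partition_regions(matrix(FALSE, 32, 32), masking_config(pixel_pitch_um = 60))
  expect_error(split_unmix(raw, part), "not energy-compensated")
  expect_s3_class(suppressWarnings(split_unmix(raw, part, force = TRUE)),
                  "concentration_maps")
})

test_that("functional maps follow their defining formulas", {
  maps <- structure(list(HbO2 = matrix(c(1, 1, 3, 0), 2),
                         Hb = matrix(c(0, 1, 1, 0), 2),
                         collagen = matrix(c(99, 1, 0, NA), 2),
                         melanin = matrix(c(1, 1, 0, NA), 2)),
                    class = "concentration_maps")
  so2 <- compute_so2(maps)
  expect_equal(so2[1, 1], 100)
  expect_equal(so2[2, 1], 50)
  expect_equal(so2[1, 2], 75)
  expect_true(is.na(so2[2, 2]))  # zero total hemoglobin
  rel <- compute_relative(maps)
  expect_equal(rel$collagen_rel[1, 1], 99)
  expect_equal(rel$melanin_rel[1, 1], 1)
  expect_equal(rel$collagen_rel[2, 1], 50)
  expect_true(is.na(rel$collagen_rel[1, 2]))  # zero denominator
  ok <- !is.na(rel$collagen_rel)
  expect_equal(rel$collagen_rel[ok] + rel$melanin_rel[ok],
               rep(100, sum(ok)))
})

test_that("estimation error is the absolute percent difference", {
  expect_equal(estimation_error(5, 5), 0)
  expect_equal(estimation_error(100, 99), 1)
  expect_equal(estimation_error(1, 1.0015), 0.15)
  expect_error(estimation_error(0, 1), "> 0")
})

test_that("unmixing is equivariant to a global intensity scale", {
  env <- demo_stack()
  part <- partition_regions(!is.na(env$truth$so2), masking_config(pixel_pitch_um = 60))
  m1 <- split_unmix(env$stack, part)
  scaled <- env$stack
  scaled$auc <- scaled$auc * 7.3
  m2 <- split_unmix(scaled, part)
  expect_equal(m2$HbO2, m1$HbO2 * 7.3, tolerance = 1e-8)
  expect_equal(compute_so2(m2), compute_so2(m1), tolerance = 1e-9)
  r1 <- compute_relative(m1); r2 <- compute_relative(m2)
  expect_equal(r2$collagen_rel, r1$collagen_rel, tolerance = 1e-9)
})

test_that("mixture validation errors shrink with error-free acquisition", {
  rep0 <- run_mixture_validation(melanin_pct = c(1, 20), grid = c(8L, 8L))
  expect_s3_class(rep0, "validation_report")
  expect_lt(attr(rep0, "max_error_pct"), 1e-4)

  repq <- run_mixture_validation(melanin_pct = c(1, 20), grid = c(8L, 8L),
                                 noise_sigma = 0.005, bit_depth = 16L)
  expect_true(all(is.finite(repq$error_pct)))
  expect_true(all(repq$error_pct >= 0))
})

test_that("feasibility study flags the ill-conditioned non-blood set", {
  fz <- feasibility_study()
  kap <- tapply(fz$condition_number, fz$set, unique)
  expect_equal(unname(kap[["blood"]]), 7.5, tolerance = 0.01)
  expect_equal(unname(kap[["dermal"]]), 41, tolerance = 0.01)
  expect_gte(unname(kap[["nonblood"]]), 6e7)
  # at 16-bit depth the weak absorbers are not recoverable, the pigments are
  err <- function(set, ch) fz$error_pct[fz$set == set & fz$chromophore == ch]
  expect_lt(err("dermal", "collagen"), 1)
  expect_gt(max(err("nonblood", "lipid"), err("nonblood", "water")), 50)
})
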