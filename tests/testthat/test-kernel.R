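test_that("sigma/FWHM conversion matches the Gaussian relation", {
  expect_equal(round(sigma_from_fwhm(20), 1), 8.5)
  expect_equal(round(fwhm_from_sigma(4), 1), 9.4)
  expect_equal(sigma_from_fwhm(1), 1 / (2 * sqrt(2 * log(2))))
  expect_equal(fwhm_from_sigma(sigma_from_fwhm(13.7)), 13.7)
  expect_error(sigma_from_fwhm(0), "positive")
  expect_error(fwhm_from_sigma(-2), "positive")
})

test_that("gaussian_value follows the un-normalised kernel", {
  s <- sigma_from_fwhm(20)
  expect_equal(gaussian_value(0, s, 0.7), 0.7)                 # D = 0
  expect_equal(gaussian_value(20, s, 0.8), 0.8 / 16)           # D = FWHM
  expect_equal(gaussian_value(s, s, 1), exp(-0.5))
  expect_equal(gaussian_value(Inf, s, 1), 0)
  # strictly decreasing, sign preserving
  d <- seq(0, 30, by = 0.5)
  expect_true(all(diff(gaussian_value(d, s, 1)) < 0))
  expect_true(all(gaussian_value(d, s, -2) <= 0))
  expect_error(gaussian_value(-1, s, 1), "non-negative")
  expect_error(gaussian_value(1, 0, 1), "positive")
})

test_that("deformed_step interpolates Euclidean and correlation distance", {
  expect_equal(deformed_step(1, 8.5, 1, 2), 0)
  expect_equal(deformed_step(0.3, 8.5, 0, 2), 2)       # alpha 0: Euclidean
  expect_equal(deformed_step(NA, 8.5, 0, 2), 2)        # rho ignored at 0
  expect_equal(deformed_step(0.5, 8.5, 1, 2),
               sqrt(2 * 8.5^2 * log(2)))
  expect_equal(round(deformed_step(0.5, 8.5, 1, 2), 2), 10.01)
  expect_identical(deformed_step(0, 8.5, 1, 2), Inf)
  expect_identical(deformed_step(-0.4, 8.5, 1, 2), Inf)
  expect_identical(deformed_step(NA, 8.5, 1, 2), Inf)
  expect_error(deformed_step(1.01, 8.5, 1, 2), "above 1")
  expect_error(deformed_step(0.5, 8.5, 1.2, 2), "alpha")
})

test_that("per-step consistency: kernel of D equals rho_iso^(1-a) rho^a", {
  set.seed(5)
  for (trial in 1:200) {
    rho <- runif(1, 0.01, 1)
    alpha <- runif(1)
    sigma <- runif(1, 1, 15)
    dreal <- runif(1, 0.5, 5)
    D <- deformed_step(rho, sigma, alpha, dreal)
    rho_iso <- exp(-dreal^2 / (2 * sigma^2))
    expect_equal(exp(-D^2 / (2 * sigma^2)),
                 rho_iso^(1 - alpha) * rho^alpha, tolerance = 1e-12)
  }
})

uniform_template <- function(shape, rho, tissue = 1, vox = 2) {
  correlation_template(array(rho, c(shape, 13)),
                       volume_grid(array(tissue, shape),
                                   voxel_size = rep(vox, 3)))
}

test_that("propagate: single-edge distances equal deformed_step", {
  tpl <- uniform_template(c(5, 5, 5), rho = 0.9)
  cfg <- kernel_config(fwhm_mm = 40, alpha = 0.7)
  fld <- propagate(tpl, c(3, 3, 3), cfg)
  expect_equal(fld$distance$data[3, 3, 3], 0)
  no <- neighbor_offsets()
  for (r in seq_len(26)) {
    o <- no$offsets[r, ]
    dreal <- sqrt(sum((o * 2)^2))
    expect_equal(fld$distance$data[3 + o[1], 3 + o[2], 3 + o[3]],
                 deformed_step(0.9, cfg$sigma_mm, 0.7, dreal),
                 tolerance = 1e-12)
  }
})

test_that("propagate: detour through high correlation beats low direct edge", {
  # 3x3x1 grid: block the direct edges around the seed except through a
  # corridor; exhaustive relaxation oracle gives the reference distances.
  shape <- c(3, 3, 1)
  set.seed(99)
  rho <- array(runif(prod(shape) * 13, 0.05, 0.95), c(shape, 13))
  tpl <- correlation_template(rho, volume_grid(array(1, shape),
                                               voxel_size = c(2, 2, 2)))
  cfg <- kernel_config(fwhm_mm = 60, alpha = 1)
  fld <- propagate(tpl, c(1, 1, 1), cfg)
  oracle <- oracle_distances(tpl, c(1, 1, 1), cfg)
  expect_equal(fld$distance$data, oracle, tolerance = 1e-9)
})

test_that("propagate equals the relaxation oracle on random small grids", {
  set.seed(314)
  for (trial in 1:20) {
    shape <- sample(2:5, 3, replace = TRUE)
    tpl <- random_template(shape, seed = 1000 + trial)
    alpha <- sample(c(0, 1, runif(1)), 1)
    cfg <- kernel_config(fwhm_mm = runif(1, 10, 60), alpha = alpha)
    seed <- sapply(shape, function(m) sample(m, 1))
    fld <- propagate(tpl, seed, cfg)
    oracle <- oracle_distances(tpl, seed, cfg)
    expect_equal(fld$distance$data, oracle, tolerance = 1e-9)
  }
})

test_that("zero correlation around the seed blocks all propagation", {
  tpl <- uniform_template(c(4, 4, 4), rho = 0)
  fld <- propagate(tpl, c(2, 2, 2), kernel_config(20, alpha = 1))
  expect_equal(sum(is.finite(fld$distance$data)), 1L)
  expect_equal(fld$distance$data[2, 2, 2], 0)
  expect_error(propagate(tpl, c(9, 1, 1), kernel_config(20, 1)), "outside")
})

test_that("recreation: peak value kept, cutoff at FWHM, |v| <= |d_peak|", {
  tpl <- tiny_dataset()$template
  cfg <- kernel_config(fwhm_mm = 20, alpha = 0.5)
  pk <- peak(voxel_to_world(tpl$tissue_prob, c(3, 5, 5)), -1.4, "d")
  rec <- recreate_from_peak(tpl, pk, cfg, return_weight = TRUE)
  expect_equal(rec$value$data[4, 6, 6], -1.4)   # seed voxel (1-based)
  expect_true(all(abs(rec$value$data) <= 1.4 + 1e-12))
  # beyond-cutoff voxels are exactly 0; reached voxels >= d/16 in magnitude
  reached <- rec$weight$data > 0
  expect_true(all(rec$value$data[!reached] == 0))
  expect_true(all(abs(rec$value$data[reached]) >= 1.4 / 16 - 1e-9))
  expect_error(
    recreate_from_peak(tpl, peak(c(500, 0, 0), 1, "d"), cfg),
    "outside")
})

test_that("full anisotropy makes recreation independent of FWHM", {
  tpl <- tiny_dataset()$template
  pk <- peak(voxel_to_world(tpl$tissue_prob, c(3, 5, 5)), 1, "d")
  maps <- lapply(c(10, 20, 100), function(f)
    recreate_from_peak(tpl, pk, kernel_config(fwhm_mm = f, alpha = 1))$data)
  expect_equal(maps[[1]], maps[[2]], tolerance = 1e-9)
  expect_equal(maps[[2]], maps[[3]], tolerance = 1e-9)
})

test_that("alpha 0 reproduces the classical isotropic kernel", {
  # open uniform grid: geodesic along axes equals straight-line distance
  tpl <- uniform_template(c(9, 9, 9), rho = 0.5, vox = 2)
  cfg <- kernel_config(fwhm_mm = 30, alpha = 0)
  fld <- propagate(tpl, c(5, 5, 5), cfg)
  for (m in 0:4) {
    expect_equal(fld$distance$data[5 + m, 5, 5], 2 * m, tolerance = 1e-12)
    expect_equal(fld$distance$data[5, 5, 5 + m], 2 * m, tolerance = 1e-12)
  }
  # and the kernel value is the closed-form Gaussian of Euclidean distance
  val <- gaussian_value(fld$distance$data[9, 5, 5], cfg$sigma_mm, 2)
  expect_equal(val, exp(-8^2 / (2 * cfg$sigma_mm^2)) * 2)
})

test_that("monotonicity: raising one edge's correlation never raises distances", {
  set.seed(21)
  shape <- c(4, 4, 2)
  tpl <- random_template(shape, seed = 77, rho_range = c(0.05, 0.9),
                         tissue_range = c(1, 1))
  cfg <- kernel_config(fwhm_mm = 50, alpha = 1)
  base <- propagate(tpl, c(2, 2, 1), cfg)$distance$data
  for (trial in 1:10) {
    tpl2 <- tpl
    idx <- c(sample(4, 1), sample(4, 1), sample(2, 1), sample(13, 1))
    tpl2$rho[idx[1], idx[2], idx[3], idx[4]] <-
      min(1, tpl$rho[idx[1], idx[2], idx[3], idx[4]] + 0.09)
    upd <- propagate(tpl2, c(2, 2, 1), cfg)$distance$data
    expect_true(all(upd <= base + 1e-9 | (is.infinite(upd) & is.infinite(base))))
  }
})

test_that("combine_peak_maps is the documented weighted average", {
  g <- function(v) volume_grid(array(v, c(2, 1, 1)), voxel_size = c(1, 1, 1))
  # single peak unchanged
  one <- combine_peak_maps(list(g(c(0.3, 0.1))), list(g(c(1, 0.5))))
  expect_equal(one$data, g(c(0.3, 0.1))$data)
  # coincident equal peaks: same map
  two <- combine_peak_maps(list(g(c(0.3, 0.1)), g(c(0.3, 0.1))),
                           list(g(c(1, 0.5)), g(c(1, 0.5))))
  expect_equal(two$data, g(c(0.3, 0.1))$data)
  # hand-evaluated weighted average: w1=0.5,v1=0.5; w2=0.25,v2=0.5 -> 0.5
  mix <- combine_peak_maps(list(g(c(0.5 * 1.0, 0)), g(c(0.25 * 2.0, 0))),
                           list(g(c(0.5, 0)), g(c(0.25, 0))))
  expect_equal(mix$data[1, 1, 1], 0.5)
  expect_equal(mix$data[2, 1, 1], 0)  # no weight anywhere -> 0
  expect_error(
    combine_peak_maps(list(g(0)), list(volume_grid(array(0, c(3, 1, 1))))),
    "mismatch")
})

test_that("kernel_config validates and derives sigma", {
  cfg <- kernel_config(20, 0.4)
  expect_equal(cfg$sigma_mm, 20 / (2 * sqrt(2 * log(2))))
  expect_equal(cfg$cutoff_mm, 20)
  expect_error(kernel_config(-1, 0.5), "positive")
  expect_error(kernel_config(20, 1.5), "alpha")
})
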