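test_that("make_phantom rasterizes regions deterministically", {
  # empty region list: uniform background
  ph0 <- make_phantom(phantom_spec(grid_shape = c(8, 8, 8),
                                   regions = list(), background = 0.3,
                                   boundary_sigma_mm = 3))
  expect_equal(ph0$tissue_prob$data, array(0.3, c(8, 8, 8)),
               tolerance = 1e-12)
  expect_true(all(ph0$labels$data == 0))

  # radius-0 sphere: a single voxel
  ph1 <- make_phantom(phantom_spec(grid_shape = c(8, 8, 8),
                                   regions = list(list(label = 1,
                                                       shape = "sphere",
                                                       center = c(4, 4, 4),
                                                       radius = 0,
                                                       tissue = 1)),
                                   boundary_sigma_mm = 0))
  expect_equal(sum(ph1$labels$data == 1), 1)

  # labeled count equals brute-force enumeration of centers within radius
  r <- 5
  ph2 <- make_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                   regions = list(list(label = 1,
                                                       shape = "sphere",
                                                       center = c(16, 16, 16),
                                                       radius = r,
                                                       tissue = 1))))
  cnt <- 0
  for (i in 1:32) for (j in 1:32) for (k in 1:32)
    if ((i - 16)^2 + (j - 16)^2 + (k - 16)^2 <= r^2) cnt <- cnt + 1
  expect_equal(sum(ph2$labels$data == 1), cnt)

  # overlapping regions: last wins, with a warning
  spec_ov <- phantom_spec(grid_shape = c(8, 8, 8),
                          regions = list(
                            list(label = 1, shape = "box", center = c(4, 4, 4),
                                 half_width = c(2, 2, 2), tissue = 0.5),
                            list(label = 2, shape = "sphere",
                                 center = c(4, 4, 4), radius = 1,
                                 tissue = 0.9)))
  expect_warning(ph3 <- make_phantom(spec_ov), "overlap")
  expect_equal(ph3$labels$data[4, 4, 4], 2)
  expect_error(phantom_spec(regions = list(list(label = 1, shape = "sphere",
                                                center = c(90, 1, 1),
                                                radius = 1, tissue = 1))),
               "outside")
})

test_that("simulate_subjects is deterministic with per-subject streams", {
  ph <- make_phantom(phantom_spec(grid_shape = c(10, 10, 10),
                                  regions = small_regions()[1]))
  p <- simulation_params(n_subjects = 5, seed = 17, smoothing_sigma_mm = 2)
  v1 <- simulate_subjects(ph, p)
  v2 <- simulate_subjects(ph, p)
  for (s in 1:5) expect_identical(v1[[s]]$data, v2[[s]]$data)
  # subject i does not depend on how many subjects follow
  p4 <- simulation_params(n_subjects = 4, seed = 17, smoothing_sigma_mm = 2)
  v4 <- simulate_subjects(ph, p4)
  expect_identical(v4[[2]]$data, v1[[2]]$data)
  expect_error(simulation_params(n_subjects = 2), "n_subjects")
  expect_error(simulation_params(noise_sigma = 0), "noise_sigma")
})

test_that("latent factor drives within-region correlation", {
  ph <- make_phantom(phantom_spec(grid_shape = c(12, 12, 12),
                                  regions = list(
                                    list(label = 1, shape = "sphere",
                                         center = c(6, 6, 6), radius = 4,
                                         tissue = 0.9)),
                                  boundary_sigma_mm = 0))
  # vanishing noise, full latent weight: in-region neighbor rho -> 1
  # (uniform in-region tissue so value clamping preserves equality)
  p <- simulation_params(n_subjects = 8, latent_weight = 1,
                         noise_sigma = 1e-9, smoothing_sigma_mm = 0,
                         voxel_noise_sigma = 0, seed = 17)
  vols <- simulate_subjects(ph, p)
  tpl <- neighbor_correlations(vols)
  core <- ph$labels$data == 1
  # all 13 offsets, voxels whose neighbor is also in the region
  rr <- c()
  no <- neighbor_offsets()
  for (h in 1:13) {
    o <- no$unique_half[h, ]
    idx <- which(core, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      w <- idx[r, ] + o
      if (any(w < 1) || any(w > 12)) next
      if (!core[w[1], w[2], w[3]]) next
      rr <- c(rr, tpl$rho[idx[r, 1], idx[r, 2], idx[r, 3], h])
    }
  }
  expect_true(all(rr > 1 - 1e-6))

  # default-parameter ordering: within-region beats across-boundary
  # (soft tissue boundary so across-boundary voxels have signal to
  # correlate at all)
  ph <- make_phantom(phantom_spec(grid_shape = c(12, 12, 12),
                                  regions = list(
                                    list(label = 1, shape = "sphere",
                                         center = c(6, 6, 6), radius = 4,
                                         tissue = 0.9))))
  p2 <- simulation_params(n_subjects = 20, seed = 17,
                          smoothing_sigma_mm = 2)
  vols2 <- simulate_subjects(ph, p2)
  tpl2 <- neighbor_correlations(vols2)
  lab <- ph$labels$data
  within <- c(); across <- c()
  for (h in 1:13) {
    o <- no$unique_half[h, ]
    for (i in 1:12) for (j in 1:12) for (k in 1:12) {
      w <- c(i, j, k) + o
      if (any(w < 1) || any(w > 12)) next
      r <- tpl2$rho[i, j, k, h]
      if (is.na(r)) next
      inA <- lab[i, j, k] == 1; inB <- lab[w[1], w[2], w[3]] == 1
      if (inA && inB) within <- c(within, r)
      else if (xor(inA, inB)) across <- c(across, r)
    }
  }
  expect_gt(mean(within), mean(across))
})

test_that("inject_group_effect adds a calibrated, confined effect", {
  ds <- tiny_dataset()
  vols <- ds$volumes
  lab <- ds$phantom$labels
  grp <- rep(c(0, 1), length.out = length(vols))

  # d = 0: bitwise unchanged
  same <- inject_group_effect(vols, lab, 1, 0, grp)
  expect_identical(same, vols)
  expect_error(inject_group_effect(vols, lab, 99, 1, grp), "unknown region")

  mod <- inject_group_effect(vols, lab, 1, 1.5, grp)
  out_vox <- lab$data != 1
  for (s in seq_along(vols))
    expect_identical(mod[[s]]$data[out_vox], vols[[s]]$data[out_vox])

  # realized in-region Cohen's d close to the target
  vox <- which(lab$data == 1)
  g1 <- sapply(mod[grp == 1], function(v) mean(v$data[vox]))
  g0 <- sapply(mod[grp == 0], function(v) mean(v$data[vox]))
  vals <- sapply(mod, function(v) v$data[vox])
  sd_pool <- mean(apply(vals, 1, sd))
  realized <- (mean(g1) - mean(g0)) / sd_pool
  expect_lt(abs(realized - 1.5), 0.3)
})

test_that("the packaged validation dataset has the promised structure", {
  ds <- .fixtures[["val_small"]]  # reuse the validation fixture if built
  if (is.null(ds))
    ds <- simulate_validation_dataset(n_subjects = 24, k = 2, d = 1.2,
                                      seed = 5,
                                      spec = phantom_spec(
                                        grid_shape = c(16, 16, 16),
                                        regions = small_regions()),
                                      params = simulation_params(
                                        n_subjects = 24,
                                        smoothing_sigma_mm = 2, seed = 5))
  expect_equal(ds$splits$k, 2)
  expect_length(ds$volumes, 24)
  # split j sees its own region's effect as a large |t|
  for (j in 1:2) {
    g <- ds$splits$assignments[j, ]
    tm <- two_sample_t_map(ds$volumes[g == 0], ds$volumes[g == 1])
    vox <- ds$phantom$labels$data == ds$effect_regions[j]
    other <- ds$phantom$labels$data == ds$effect_regions[3 - j]
    expect_gt(mean(abs(tm$t$data[vox])), 3)
    expect_lt(mean(abs(tm$t$data[other]), na.rm = TRUE),
              mean(abs(tm$t$data[vox])))
  }
})
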