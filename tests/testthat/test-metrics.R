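test_that("efficiency and uniformity follow their defining formulas", {
  expect_equal(uniformity(c(0.8, 0.4)), 2 / 3)
  expect_equal(uniformity(c(1, 0)), 0)
  expect_equal(uniformity(rep(0.37, 6)), 1)
  expect_equal(efficiency(c(0.8, 0.4)), 1.2)
  expect_equal(efficiency(rep(0, 3)), 0)
  expect_error(uniformity(rep(0, 3)), "undefined")
  expect_error(efficiency(c(0.2, -0.1)), "non-negative")
  expect_error(uniformity(numeric(0)), "numeric vector")
})

test_that("uniformity is scale invariant and metrics stay in [0, 1]", {
  cfg <- benchmark_config(32)
  for (s in 1:5) {
    sp <- field_spots(6, 32, seed = s)
    fit <- cgh(sp, cfg, method = c("rs", "gs", "cs-gs")[s %% 3 + 1],
               iterations = 5, seed = s)
    I <- fit$intensities
    expect_true(fit$efficiency >= 0 && fit$efficiency <= 1 + 1e-9)
    expect_true(fit$uniformity >= 0 && fit$uniformity <= 1)
    expect_equal(uniformity(I * 7.3), uniformity(I), tolerance = 1e-12)
  }
})

test_that("metrics agree with the brute-force intensity oracle", {
  cfg <- benchmark_config(32)
  sp <- field_spots(4, 32, seed = 9)
  fit <- cgh(sp, cfg, method = "gs", iterations = 10, seed = 2)
  I_oracle <- oracle_intensities(cfg, fit$phase, sp)
  expect_equal(fit$efficiency, sum(I_oracle), tolerance = 1e-10)
  expect_equal(fit$uniformity,
               1 - (max(I_oracle) - min(I_oracle)) / (max(I_oracle) + min(I_oracle)),
               tolerance = 1e-10)
})

test_that("random spot clouds respect their bounding box", {
  sp <- random_spot_cloud(100, 80, 40, seed = 1)
  expect_equal(nrow(sp), 100L)
  expect_true(all(abs(sp$x_um) <= 80 & abs(sp$y_um) <= 80 & abs(sp$z_um) <= 40))
  expect_identical(random_spot_cloud(100, 80, 40, seed = 1), sp)
  planar <- random_spot_cloud(10, 50, 0, seed = 2)
  expect_true(all(planar$z_um == 0))
  expect_error(random_spot_cloud(0), "at least 1")
})

test_that("grid patterns form a centred lattice in the focal plane", {
  g10 <- grid_pattern(10, 10, 20)
  expect_equal(nrow(g10), 100L)
  expect_true(all(g10$z_um == 0))
  expect_equal(unlist(grid_pattern(1, 1)), c(x_um = 0, y_um = 0, z_um = 0))
  g23 <- grid_pattern(2, 3, spacing_um = 7)
  expect_equal(range(g23$x_um), c(-7, 7))
  expect_equal(range(g23$y_um), c(-3.5, 3.5))
})

test_that("glyph patterns sample letter strokes deterministically", {
  sp <- glyph_pattern("TUD", n_points = 25, extent_um = 500)
  expect_equal(nrow(sp), 25L)
  expect_true(all(sp$z_um == 0))
  expect_equal(max(sp$x_um) - min(sp$x_um), 500)
  expect_identical(glyph_pattern("TUD", 25, 500), sp)
  one <- glyph_pattern("TUD", n_points = 1)
  expect_equal(nrow(one), 1L)
  expect_error(glyph_pattern("T?D"), "supported")
  expect_error(glyph_pattern(""), "non-empty")
})

test_that("evaluate_hologram composes intensities with both metrics", {
  cfg <- benchmark_config(32)
  sp1 <- spot_set(5, 2, 0)
  q1 <- evaluate_hologram(cgh(sp1, cfg, method = "rs", seed = 1))
  expect_equal(q1$efficiency, 1, tolerance = 1e-9)
  expect_equal(q1$uniformity, 1, tolerance = 1e-9)

  # duplicated spots receive identical intensities, so uniformity is 1
  dup <- spot_set(c(4, 4), c(-3, -3), c(10, 10))
  qd <- evaluate_hologram(cgh(dup, cfg, method = "rs", seed = 2))
  expect_equal(qd$intensities[1], qd$intensities[2], tolerance = 1e-12)
  expect_equal(qd$uniformity, 1, tolerance = 1e-9)

  fit <- cgh(field_spots(4, 32, seed = 1), cfg, method = "gs",
             iterations = 5, seed = 1)
  q <- evaluate_hologram(fit)
  expect_equal(q$efficiency, sum(q$intensities))
  expect_equal(q$intensities, fit$intensities)
})

test_that("compression sweeps report replicate statistics per level", {
  cfg <- benchmark_config(32)
  sp <- field_spots(5, 32, seed = 2)
  sw <- compression_sweep(sp, cfg, method = "cs-gs", iterations = 5,
                          c_levels = c(1, 1 / 2), replicates = 2, seed = 10)
  expect_s3_class(sw, "cgh_sweep")
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$replicates, c(2L, 2L))
  expect_true(all(is.finite(sw$efficiency_sd)))
  expect_equal(sw$inv_c, c(1, 2))

  # c = 1 reproduces the plain GS statistics for the same replicate seeds
  e_manual <- sapply(1:2, function(r)
    cgh(sp, cfg, method = "gs", iterations = 5, seed = 10 + r)$efficiency)
  expect_equal(sw$efficiency_mean[1], mean(e_manual), tolerance = 1e-12)
  expect_error(compression_sweep(sp, cfg, replicates = 1), "at least 2")
})

test_that("convergence traces have one row per iteration", {
  cfg <- benchmark_config(32)
  sp <- field_spots(5, 32, seed = 3)
  tr1 <- convergence_curves(sp, cfg, method = "rs", iterations = 1, seed = 1)
  expect_equal(nrow(tr1), 1L)
  trg <- convergence_curves(sp, cfg, method = "gs", iterations = 6, seed = 4)
  trc <- convergence_curves(sp, cfg, method = "cs-gs", iterations = 6,
                            compression = 1, seed = 4)
  expect_equal(trg, trc)
  expect_equal(nrow(trg), 6L)
  expect_true(all(trg$efficiency >= 0 & trg$efficiency <= 1 + 1e-9))
})

test_that("the final weighted iteration lifts cs-wgs uniformity abruptly", {
  cfg <- benchmark_config(64)
  sp <- field_spots(15, 64, axial_um = 20, seed = 5)
  tr <- convergence_curves(sp, cfg, method = "cs-wgs", iterations = 15,
                           compression = 1 / 8, seed = 1)
  K <- nrow(tr)
  expect_gt(tr$uniformity[K], tr$uniformity[K - 1])
})
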