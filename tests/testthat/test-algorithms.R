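test_that("random offsets are uniform on [0, 2*pi) and reproducible", {
  expect_identical(random_offsets(10, seed = 5), random_offsets(10, seed = 5))
  x1 <- random_offsets(1, seed = 2)
  expect_true(x1 >= 0 && x1 < 2 * pi)
  x <- random_offsets(1e4, seed = 1)
  expect_true(all(x >= 0 & x < 2 * pi))
  # empirical mean within 5 standard errors of pi under the uniform null
  se <- (2 * pi / sqrt(12)) / sqrt(1e4)
  expect_lt(abs(mean(x) - pi), 5 * se)
})

test_that("superposition reduces correctly and matches the scalar oracle", {
  cfg <- benchmark_config(8)
  g <- pupil_grid(cfg)

  # N = 1: hologram is the spot phase plus the offset, modulo 2*pi
  sp1 <- spot_set(1.5, -0.5, 6)
  th <- 2.1
  ph <- superpose(g, sp1, theta = th, omega = 0.3)
  expect_lt(max(wrap_diff(ph, spot_phase(g, 1.5, -0.5, 6) + th)), 1e-12)

  # destructive interference stays finite; an exactly zero field maps to
  # phase 0 (the Arg(0) convention)
  sp2 <- spot_set(c(1.5, 1.5), c(-0.5, -0.5), c(6, 6))
  ph0 <- superpose(g, sp2, theta = c(0, pi))
  expect_true(all(is.finite(ph0)))
  expect_identical(Arg(0 + 0i), 0)

  # three spots vs the naive loop
  sp3 <- field_spots(3, 8, seed = 3)
  th3 <- random_offsets(3, seed = 8)
  expect_equal(superpose(g, sp3, th3), oracle_superpose(cfg, sp3, th3),
               tolerance = 1e-12)

  expect_error(superpose(g, sp3, th3, omega = c(0, 0, 0)), "degenerate")
  expect_error(superpose(g, sp3, th3[1:2]), "one entry per spot")
})

test_that("pupil subset sampling honours the compression factor", {
  g <- pupil_grid(benchmark_config(32))
  full <- sample_pupil_subset(g, 1)
  expect_identical(as.integer(full), seq_len(g$M))
  s <- sample_pupil_subset(g, 1 / 8, seed = 3)
  expect_length(s, round(g$M / 8))
  expect_false(any(duplicated(s)))
  expect_true(all(s >= 1 & s <= g$M))
  expect_identical(sample_pupil_subset(g, 1 / 8, seed = 3), s)
  expect_error(sample_pupil_subset(g, 0), "in \\(0, 1\\]")
  expect_error(sample_pupil_subset(g, 1.2), "in \\(0, 1\\]")

  # full-size SLM at c = 1/32
  gf <- pupil_grid(optical_config())
  expect_length(sample_pupil_subset(gf, 1 / 32, seed = 1), 69120L)
})

test_that("every variant is deterministic given a seed", {
  cfg <- benchmark_config(32)
  sp <- field_spots(6, 32, seed = 2)
  for (m in c("rs", "gs", "wgs", "cs-gs", "cs-wgs")) {
    f1 <- cgh(sp, cfg, method = m, iterations = 5, compression = 1 / 4, seed = 7)
    f2 <- cgh(sp, cfg, method = m, iterations = 5, compression = 1 / 4, seed = 7)
    expect_identical(f1$phase, f2$phase, label = m)
    expect_identical(f1$omega, f2$omega, label = m)
  }
  # the ambient RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(cgh(sp, cfg, method = "cs-gs", iterations = 3, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("reduction chain: cs variants collapse onto gs and rs", {
  cfg <- benchmark_config(32)
  sp <- field_spots(6, 32, seed = 4)

  gs <- cgh(sp, cfg, method = "gs", iterations = 10, seed = 5)
  csgs1 <- cgh(sp, cfg, method = "cs-gs", iterations = 10, compression = 1, seed = 5)
  expect_identical(csgs1$phase, gs$phase)

  rs <- cgh(sp, cfg, method = "rs", seed = 5)
  expect_identical(cgh(sp, cfg, method = "gs", iterations = 1, seed = 5)$phase,
                   rs$phase)
  expect_identical(cgh(sp, cfg, method = "cs-gs", iterations = 1,
                       compression = 1 / 4, seed = 5)$phase,
                   rs$phase)
  # wgs with one spot or one iteration is plain gs
  expect_identical(cgh(sp, cfg, method = "wgs", iterations = 1, seed = 5)$phase,
                   rs$phase)
})

test_that("cs-wgs with c = 1 is gs(K-1) followed by one weighted iteration", {
  cfg <- benchmark_config(32)
  g <- pupil_grid(cfg)
  sp <- field_spots(5, 32, seed = 6)
  K <- 8
  cw <- cgh(sp, cfg, method = "cs-wgs", iterations = K, compression = 1, seed = 2)

  # compose the reference by hand from exported primitives
  base <- cgh(sp, cfg, method = "gs", iterations = K - 1, seed = 2)
  a <- spot_amplitudes(base, sp)
  theta <- Arg(a)
  m <- pmax(Mod(a) / sqrt(rep(1 / 5, 5)), 1e-12)
  omega <- base$omega * pmin(mean(m) / m, 10)
  omega <- omega / sum(omega)
  ref <- superpose(g, sp, theta, omega)
  expect_lt(max(wrap_diff(cw$phase, ref)), 1e-10)
  expect_equal(cw$omega, omega, tolerance = 1e-12)
})

test_that("weight update leaves equal amplitudes unchanged and caps boosts", {
  omega <- rep(1 / 4, 4)
  tgt <- sqrt(rep(1 / 4, 4))
  a_eq <- rep(0.3 + 0.1i, 4)
  expect_equal(csgs:::.cgh_update_weights(omega, a_eq, tgt), omega)

  # a collapsed spot's boost factor is clamped at 10x before renormalization:
  # moduli (0, .3, .3, .3)/tgt -> ratios (clamped 10, .75, .75, .75)
  a_bad <- c(0 + 0i, 0.3, 0.3, 0.3)
  w2 <- csgs:::.cgh_update_weights(omega, a_bad, tgt)
  expect_true(all(is.finite(w2) & w2 > 0))
  expect_equal(sum(w2), 1)
  expect_equal(w2, c(10, 0.75, 0.75, 0.75) / 12.25, tolerance = 1e-9)
})

test_that("single-spot holograms are exact for every variant", {
  cfg <- benchmark_config(32)
  sp <- spot_set(4, -6, 15)
  for (m in c("rs", "gs", "wgs", "cs-gs", "cs-wgs")) {
    fit <- cgh(sp, cfg, method = m, iterations = 4, compression = 1 / 2, seed = 3)
    expect_equal(fit$efficiency, 1, tolerance = 1e-9, label = m)
    expect_equal(fit$uniformity, 1, tolerance = 1e-9, label = m)
  }
})

test_that("iterative refinement beats random superposition on paired seeds", {
  cfg <- benchmark_config(64)
  sp <- field_spots(10, 64, axial_um = 20, seed = 1)
  wins <- 0L
  for (s in 1:10) {
    e_rs <- cgh(sp, cfg, method = "rs", seed = s)$efficiency
    e_gs <- cgh(sp, cfg, method = "gs", iterations = 20, seed = s)$efficiency
    wins <- wins + (e_gs > e_rs)
  }
  expect_gte(wins, 9L)
})

test_that("weighting improves uniformity on a regular grid pattern", {
  cfg <- benchmark_config(64)
  sp <- grid_pattern(6, 6, spacing_um = 8)
  wins <- 0L
  for (s in 1:10) {
    u_gs <- cgh(sp, cfg, method = "gs", iterations = 20, seed = s)$uniformity
    u_wgs <- cgh(sp, cfg, method = "wgs", iterations = 20, seed = s)$uniformity
    wins <- wins + (u_wgs > u_gs)
  }
  expect_gte(wins, 9L)
})

test_that("gs efficiency reaches a plateau within a few tens of iterations", {
  cfg <- benchmark_config(128)
  sp <- random_spot_cloud(50, 80, 30, seed = 3)
  tr <- cgh(sp, cfg, method = "gs", iterations = 50, seed = 1, trace = TRUE)$trace
  d <- abs(diff(tr$efficiency))
  expect_lt(max(tail(d, 5)), 1e-3)
  expect_lt(mean(tail(d, 5)), mean(head(d, 5)) / 5)
})

test_that("compressed runs warn below the compressive-sensing regime", {
  cfg <- benchmark_config(16)          # M = 256
  sp <- field_spots(20, 16, seed = 1)
  expect_warning(cgh(sp, cfg, method = "cs-gs", iterations = 3,
                     compression = 1 / 32, seed = 1),
                 "compressive-sensing regime")
  expect_error(cgh(sp, cfg, method = "cs-wgs", iterations = 1, seed = 1),
               "at least 2")
})

test_that("subset resampling keeps the cost model and changes the path", {
  cfg <- benchmark_config(32)
  sp <- field_spots(5, 32, seed = 8)
  fixed <- cgh(sp, cfg, method = "cs-gs", iterations = 6, compression = 1 / 8,
               seed = 2)
  res <- cgh(sp, cfg, method = "cs-gs", iterations = 6, compression = 1 / 8,
             seed = 2, resample_subset = TRUE)
  expect_identical(res$op_count, fixed$op_count)
  expect_false(identical(res$phase, fixed$phase))
})
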