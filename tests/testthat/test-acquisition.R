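# Rotation schedule, gate tagging, projector physics, scatter emulation,
# DEW correction and the Poisson noise pathway.

test_that("default schedule reproduces the continuous-rotation arithmetic", {
  sch <- build_schedule()
  expect_equal(attr(sch, "frames_per_rotation"), 720L)
  expect_equal(attr(sch, "rotation_period"), 90)
  expect_equal(attr(sch, "total_duration"), 360)
  expect_equal(nrow(sch), 2880L)
  expect_equal(sch$head2_angle, (sch$head1_angle + 180) %% 360)
  expect_equal(diff(sch$head1_angle[1:10]), rep(0.5, 9))
  expect_error(build_schedule(dtheta = 0.7), "integer")
})

test_that("gate_of_time uses left-closed sub-phase intervals", {
  g <- gate_of_time(c(0, 0.5, 90, 4.99, 0.124, 0.125))
  expect_equal(g$q, c(1L, 5L, 1L, 8L, 1L, 2L))
  expect_equal(g$r, c(1L, 1L, 1L, 5L, 1L, 1L))
})

test_that("projection of a single voxel is the scaled path length", {
  det <- toy_detector(32)
  vol <- array(0, c(32, 32, 1)); vol[16, 16, 1] <- 2.5
  mu0 <- array(0, c(32, 32, 1))
  p <- forward_project(vol, mu0, 0, det, 4.4, dt = 2, psf = FALSE)
  expect_equal(sum(p > 1e-12), 1)
  expect_equal(max(p), 2.5 * 4.4 * 2, tolerance = 1e-12)
  expect_true(all(forward_project(vol * 0, mu0, 30, det, 4.4) == 0))
})

test_that("attenuation follows Beer-Lambert through a uniform slab", {
  det <- toy_detector(32)
  vol <- array(0, c(32, 32, 1)); vol[16, 16, 1] <- 1
  mu0 <- array(0, c(32, 32, 1))
  mu1 <- mu0; mu1[, 20:27, ] <- 0.155   # slab between source and detector
  p0 <- forward_project(vol, mu0, 0, det, 4.4, psf = FALSE)
  p1 <- forward_project(vol, mu1, 0, det, 4.4, psf = FALSE)
  expect_rel_equal(max(p1) / max(p0), exp(-0.155 * 8 * 0.44), 0.01)
})

test_that("forward and adjoint are an exactly matched pair", {
  set.seed(7)
  det <- detector_model(n_bins_trans = 20L, n_bins_axial = 8L,
                        sensitivity_scale = 2.5)
  x <- array(runif(20 * 16 * 5), c(20, 16, 5))
  y <- matrix(runif(20 * 8), 20, 8)
  mu <- array(runif(20 * 16 * 5) * 0.1, c(20, 16, 5))
  for (th in c(0, 17.3, 101, 245.5)) {
    a <- sum(forward_project(x, mu, th, det, 4.4) * y)
    b <- sum(x * project_adjoint(y, mu, th, det, 4.4))
    expect_rel_equal(a, b, 1e-6)
  }
})

test_that("expected counts scale linearly with sensitivity and frame duration", {
  vol <- toy_disc(16, 4); mu <- vol * 0.1
  d1 <- toy_detector(16)
  d2 <- toy_detector(16, sensitivity_scale = 3)
  p1 <- forward_project(vol, mu, 40, d1, 4.4, dt = 1)
  p2 <- forward_project(vol, mu, 40, d2, 4.4, dt = 2)
  expect_equal(p2, 6 * p1, tolerance = 1e-12)
})

test_that("scatter emulation preserves totals and the DEW identity", {
  set.seed(2)
  prim <- matrix(rpois(64 * 64, 20), 64, 64) * 1.0
  es <- emulate_scatter(prim, scatter_fraction = 0.3, kernel_fwhm_mm = 40,
                        bin_mm = 4.4, dew_k = 0.5)
  expect_equal(sum(es$main), 1.3 * sum(prim), tolerance = 1e-12)
  # main - k * scatter_window recovers the primary exactly in expectation
  expect_equal(es$main - 0.5 * es$scatter_window, prim, tolerance = 1e-12)
  es0 <- emulate_scatter(prim, scatter_fraction = 0)
  expect_equal(es0$main, prim)
  expect_true(all(es0$scatter_window == 0))
})

test_that("dew_correct subtracts, clips and records clipping", {
  main <- matrix(c(10, 1), 1, 2)
  scat <- matrix(c(4, 4), 1, 2)
  out <- dew_correct(main, scat, 0.5)
  expect_equal(as.numeric(out), c(8, 0))
  expect_equal(attr(out, "clipped_frac"), 0.5)
  expect_equal(dew_correct(main, main * 0), main, ignore_attr = TRUE)
  expect_error(dew_correct(main, matrix(0, 2, 2)), "shapes differ")
})

test_that("acquisition is deterministic under a fixed seed and zero at zero sensitivity", {
  cfg <- micro_config()
  states <- generate_sequence(cfg)
  ts <- assemble_tacset(1, volumes_ml = tissue_volumes_ml(cfg))
  sch <- build_schedule(n_rotations = 1)
  det <- micro_detector()
  gates <- tibble::tibble(q = 1L, r = 1L)
  cache <- new_projection_cache()
  a1 <- simulate_acquisition(states, ts, sch, det, seed = 11, gates = gates,
                             cache = cache)
  a2 <- simulate_acquisition(states, ts, sch, det, seed = 11, gates = gates,
                             cache = cache)
  expect_identical(a1$main, a2$main)
  expect_identical(a1$scatter, a2$scatter)
  a3 <- simulate_acquisition(states, ts, sch, det, seed = 12, gates = gates,
                             cache = cache)
  expect_false(identical(a1$main, a3$main))
  det0 <- micro_detector(sensitivity_scale = 0)
  a0 <- simulate_acquisition(states, ts, sch, det0, seed = 11, gates = gates)
  expect_true(all(a0$main == 0) && all(a0$scatter == 0))
})

test_that("per-bin counts are Poisson: dispersion matches the mean", {
  cfg <- micro_config()
  states <- generate_sequence(cfg)
  ts <- assemble_tacset(1, volumes_ml = tissue_volumes_ml(cfg))
  sch <- build_schedule(n_rotations = 1)
  sch1 <- sch[sch$t_start == 300 * 0.125, ]   # one mid-scan frame
  det <- micro_detector(sensitivity_scale = 0.5)
  cache <- new_projection_cache()
  reps <- vapply(1:200, function(s) {
    a <- simulate_acquisition(states, ts, sch1, det, seed = 1000 + s,
                              gates = NULL, cache = cache)
    a$main[12, 6, 1]
  }, numeric(1))
  m <- mean(reps)
  expect_gt(m, 3)  # informative bin
  disp <- sum((reps - m)^2) / m        # ~ chi-square(199) under Poisson
  p <- stats::pchisq(disp, df = length(reps) - 1)
  expect_gt(min(p, 1 - p), 0.005)     # two-sided at the 1% level
})

test_that("DEW-corrected frames are unbiased for the primary in expectation", {
  cfg <- micro_config()
  states <- generate_sequence(cfg)
  ts <- assemble_tacset(1, volumes_ml = tissue_volumes_ml(cfg))
  sch <- build_schedule(n_rotations = 1)
  det <- micro_detector(sensitivity_scale = 0.5)
  cache <- new_projection_cache()
  gates <- tibble::tibble(q = 1L, r = 1L)
  a <- simulate_acquisition(states, ts, sch, det, seed = 5, gates = gates,
                            cache = cache, keep_expected = TRUE)
  # unbiasedness of the DEW combination itself (before the zero clip)
  lin <- a$main - det$dew_k * a$scatter
  primary <- a$expected_main - det$dew_k * a$expected_scatter
  diffs <- lin - primary
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se)
  # the clipped estimate matches where clipping is improbable
  corr <- dew_correct(a$main * 1.0, a$scatter * 1.0, det$dew_k)
  hot <- primary > 25
  expect_gt(sum(hot), 100)
  dh <- corr[hot] - primary[hot]
  se_h <- stats::sd(dh) / sqrt(length(dh))
  expect_lt(abs(mean(dh)), 2 * se_h + 0.05)
})

test_that("calibrated sensitivity reproduces the last-minute count level", {
  cfg <- phantom_config()
  states <- generate_sequence(cfg)
  ts <- assemble_tacset(1, volumes_ml = tissue_volumes_ml(cfg))
  sch <- build_schedule()
  last <- sch[sch$t_start >= 300, ]
  a <- simulate_acquisition(states, ts, last, detector_model(), seed = 3)
  total <- sum(as.numeric(a$main))
  # 2.1e6 counts at the full 2.2 mm grid, scaled by the voxel-area ratio
  expect_lt(abs(total - 8.4e6) / 8.4e6, 0.2)
})
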