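# Temporal basis, per-gate system matrices, spatiotemporal MLEM and the
# post-filter, on small 2D/3D toys with independent oracles.

test_that("clamped cubic basis is a partition of unity with local support", {
  tt <- seq(0, 360, by = 0.125)
  b <- build_bspline_basis(NULL, tt)
  expect_equal(b$n_basis, 9L)
  expect_equal(ncol(b$matrix), 9L)
  expect_true(all(abs(rowSums(b$matrix) - 1) < 1e-10))
  expect_true(all(b$matrix >= 0))
  # local support: the first basis vanishes beyond its knot span
  expect_true(all(eval_basis(b, c(150, 250, 359))[, 1] == 0))
  expect_error(eval_basis(b, 400), "domain")
  expect_error(build_bspline_basis(c(400), tt), "inside the domain")
  # order-1 basis: single indicator on a knotless domain
  b1 <- build_bspline_basis(numeric(0), tt, order = 1)
  expect_equal(b1$n_basis, 1L)
  expect_true(all(b1$matrix == 1))
})

test_that("gate system matrix matches forward_project and its adjoint", {
  set.seed(3)
  det <- toy_detector(20)
  mu <- toy_disc(20, 7, value = 0.12)
  sysm <- build_gate_system_matrix(c(10, 130, 250), mu, det, 4.4, dt = 0.5)
  vol <- array(runif(20 * 20), c(20, 20, 1))
  for (ai in 1:3) {
    direct <- forward_project(vol, mu, sysm$angles[ai], det, 4.4, dt = 0.5)
    expect_equal(sysm$forward(vol, ai), direct, tolerance = 1e-12)
    y <- matrix(runif(20), 20, 1)
    a <- sum(sysm$forward(vol, ai) * y)
    b <- sum(vol * sysm$adjoint(y, ai))
    expect_rel_equal(a, b, 1e-6)
  }
  expect_error(build_gate_system_matrix(numeric(0), mu, det), "empty")
})

# Shared noiseless 2D toy: static disc, full angular sampling.
static_toy <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      det <- toy_detector(24)
      mu <- toy_disc(24, 9, value = 0.1)
      act <- toy_disc(24, 6, value = 3)
      states <- toy_sequence(list(mu))
      frames <- tibble::tibble(gate = 1L, angle = seq(0, 354, by = 6),
                               t_start = seq(0, 59, length.out = 60))
      basis <- build_bspline_basis(numeric(0), frames$t_start, order = 1,
                                   domain = c(0, 60))
      gs <- toy_sinogram(frames, function(g, t) act, states, det)
      val <<- list(det = det, mu = mu, act = act, states = states,
                   frames = frames, basis = basis, gs = gs)
    }
    val
  }
})

test_that("EM log-likelihood is non-decreasing and recovers a static disc", {
  toy <- static_toy()
  img <- mlem_spatiotemporal(toy$gs, toy$states, toy$basis, n_iter = 120,
                             detector = toy$det)
  ll <- img$ll[[1]]
  expect_true(all(diff(ll) >= -abs(ll[-1]) * 1e-9))
  vol <- evaluate_activity(img, 1, 1, 30)
  expect_true(all(vol >= 0))
  inner <- toy_disc(24, 4) > 0   # interior of the disc, away from the edge
  expect_lt(abs(mean(vol[inner]) - 3) / 3, 0.05)
})

test_that("all-zero counts drive the coefficients to zero", {
  toy <- static_toy()
  gs0 <- toy$gs
  gs0$gates[[1]]$y <- gs0$gates[[1]]$y * 0
  img <- mlem_spatiotemporal(gs0, toy$states, toy$basis, n_iter = 2,
                             detector = toy$det)
  expect_lt(max(img$coeff[[1]]), 1e-10)
})

test_that("a dynamic toy recovers the simulated TAC within 10% RMSE", {
  det <- toy_detector(24)
  mu <- toy_disc(24, 9, value = 0.1)
  states <- toy_sequence(list(mu))
  tac <- function(t) 2 + 1.5 * sin(pi * t / 60)       # smooth, positive
  frames <- tibble::tibble(gate = 1L,
                           angle = rep(seq(0, 354, by = 6), 3),
                           t_start = seq(0, 60, length.out = 180))
  basis <- build_bspline_basis(c(15, 30, 45), frames$t_start,
                               domain = c(0, 60))
  gs <- toy_sinogram(frames, function(g, t) {
    a <- toy_disc(24, 6); a * tac(t)
  }, states, det)
  img <- mlem_spatiotemporal(gs, states, basis, n_iter = 250, detector = det)
  ts <- seq(2, 58, by = 2)
  rec <- vapply(ts, function(t) evaluate_activity(img, 1, 1, t)[12, 12, 1],
                numeric(1))
  truth <- tac(ts)
  expect_lt(sqrt(mean((rec - truth)^2)) / mean(truth), 0.10)
})

test_that("sustained EM iteration approaches the direct ML optimum on a tiny toy", {
  det <- toy_detector(16)
  mu <- toy_disc(16, 6, value = 0.08)
  states <- toy_sequence(list(mu))
  act <- toy_disc(16, 4, value = 2)
  tacf <- function(t) 1 + t / 30
  frames <- tibble::tibble(gate = 1L,
                           angle = rep(seq(0, 345, by = 15), 2),
                           t_start = seq(0, 30, length.out = 48))
  basis <- build_bspline_basis(numeric(0), frames$t_start, order = 2,
                               domain = c(0, 30))   # 2 linear bases
  gs <- toy_sinogram(frames, function(g, t) act * tacf(t), states, det,
                     psf = FALSE)
  img <- mlem_spatiotemporal(gs, states, basis, n_iter = 600,
                             detector = det, psf = FALSE)
  mask <- as.logical(mu > 0)
  a_em <- img$coeff[[1]][mask, ]

  # independent oracle: direct bounded likelihood maximisation over the
  # same coefficients with analytic gradients
  nu <- det$n_bins_trans
  Vmat <- eval_basis(basis, frames$t_start)
  nb <- basis$n_basis
  nm <- sum(mask)
  y <- gs$gates[[1]]$y
  proj_list <- NULL
  nll <- function(par) {
    a <- matrix(0, 16 * 16, nb); a[mask, ] <- par
    v <- 0
    for (j in seq_len(nrow(frames))) {
      x <- array(a %*% Vmat[j, ], c(16, 16, 1))
      yb <- forward_project(x, mu, frames$angle[j], det, 4.4, psf = FALSE)
      v <- v - sum(y[, , j] * log(yb + 1e-12) - yb)
    }
    v
  }
  gnll <- function(par) {
    a <- matrix(0, 16 * 16, nb); a[mask, ] <- par
    g <- matrix(0, 16 * 16, nb)
    for (j in seq_len(nrow(frames))) {
      x <- array(a %*% Vmat[j, ], c(16, 16, 1))
      yb <- forward_project(x, mu, frames$angle[j], det, 4.4, psf = FALSE)
      bp <- project_adjoint(1 - y[, , j] / (yb + 1e-12), mu,
                            frames$angle[j], det, 4.4, psf = FALSE)
      g <- g + as.double(bp) %o% Vmat[j, ]
    }
    g[mask, ]
  }
  opt <- optim(rep(1, nm * nb), nll, gnll, method = "L-BFGS-B",
               lower = 0, control = list(maxit = 2000, factr = 10))
  a_opt <- matrix(opt$par, nm, nb)
  relerr <- sqrt(sum((a_em - a_opt)^2)) / sqrt(sum(a_opt^2))
  expect_lt(relerr, 0.01)
})

test_that("evaluate_activity is the basis expansion of the coefficients", {
  toy <- static_toy()
  b4 <- build_bspline_basis(c(20, 40), seq(0, 60, 1), domain = c(0, 60))
  img <- structure(list(
    coeff = list(q1_r1 = matrix(2.5, 24 * 24, b4$n_basis)),
    basis = b4, dims = c(24L, 24L, 1L), voxel_mm = 4.4,
    gates = tibble::tibble(q = 1L, r = 1L, state_index = 1L),
    detector = toy$det), class = "gated_dynamic_image")
  # constant coefficients: partition of unity gives the constant anywhere
  for (t in c(0, 19.9, 20.1, 33, 60)) {
    expect_equal(max(abs(evaluate_activity(img, 1, 1, t) - 2.5)), 0,
                 tolerance = 1e-10)
  }
  # continuity across a knot
  v1 <- evaluate_activity(img, 1, 1, 20 - 1e-6)
  v2 <- evaluate_activity(img, 1, 1, 20 + 1e-6)
  expect_equal(v1, v2, tolerance = 1e-5)
  expect_error(evaluate_activity(img, 2, 1, 10), "not reconstructed")
})

test_that("postfilter reproduces its kernel on a delta and conserves mass", {
  vol <- array(0, c(15, 15, 15)); vol[8, 8, 8] <- 1
  f <- postfilter(vol, fwhm_mm = 4.5, kernel = 9, voxel_mm = 4.4)
  kern <- dnorm(-4:4, sd = 4.5 / (2 * sqrt(2 * log(2))) / 4.4)
  kern <- kern / sum(kern)
  expect_equal(f[8, 8, 8], max(kern)^3, tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-12)          # interior source
  u <- array(2, c(15, 15, 15))
  fu <- postfilter(u, voxel_mm = 4.4)
  expect_equal(fu[8, 8, 8], 2, tolerance = 1e-9)       # away from edges
  expect_error(postfilter(array(0, c(3, 3, 3)), kernel = 9), "kernel")
})

test_that("gated reconstruction matches ungated on a static scene and beats it on a moving one", {
  det <- toy_detector(24)
  mu <- toy_disc(24, 10, value = 0.1)
  ring <- function(cx) toy_disc(24, 7, center = c(cx, 0), inner = 4.5,
                                value = 3)
  angles <- seq(0, 354, by = 6)

  # moving annulus: two respiratory gates displaced by 3 voxels
  shift <- c(-1.5, 1.5)
  states2 <- toy_sequence(list(mu, mu))
  frames2 <- tibble::tibble(gate = rep(1:2, each = 60),
                            angle = rep(angles, 2),
                            t_start = seq(0, 59.5, by = 0.5))
  basis <- build_bspline_basis(numeric(0), frames2$t_start, order = 1,
                               domain = c(0, 60))
  gs2 <- toy_sinogram(frames2, function(g, t) ring(shift[g]), states2, det)
  img_gated <- mlem_spatiotemporal(gs2, states2, basis, n_iter = 60,
                                   detector = det)

  # pooled (ungated) reconstruction of the same frames
  nu <- det$n_bins_trans
  n <- nrow(frames2)
  y <- array(0, c(nu, 1, n))
  for (j in seq_len(n)) {
    g <- frames2$gate[j]
    key <- sprintf("q1_r%d", g)
    sub <- gs2$gates[[key]]
    jj <- which(sub$meta$t_start == frames2$t_start[j])
    y[, , j] <- sub$y[, , jj[1]]
  }
  acq <- structure(list(
    meta = tibble::tibble(frame_index = seq_len(n), head = 1L,
                          t_start = frames2$t_start, angle = frames2$angle,
                          q = 1L, r = frames2$gate),
    main = y, scatter = y * 0, detector = det, dt = 1, seed = 0L
  ), class = "acq_frames")
  img_pooled <- recon_ungated_4d(acq, mu, basis, n_iter = 60, detector = det)

  # wall profile along the motion axis through the annulus centre
  prof_gated <- evaluate_activity(img_gated, 1, 1, 30)[, 12, 1]
  prof_pooled <- evaluate_activity(img_pooled, NA, NA, 30)[, 12, 1]
  expect_gt(profile_fwhm(prof_pooled), profile_fwhm(prof_gated))

  # static scene: gated and pooled agree in the ROI mean
  states1 <- toy_sequence(list(mu))
  frames1 <- tibble::tibble(gate = 1L, angle = angles,
                            t_start = seq(0, 59, length.out = 60))
  gs1 <- toy_sinogram(frames1, function(g, t) ring(0), states1, det)
  img_g1 <- mlem_spatiotemporal(gs1, states1, basis, n_iter = 50,
                                detector = det)
  y1 <- array(0, c(nu, 1, 60))
  for (j in 1:60) y1[, , j] <- gs1$gates[[1]]$y[, , j]
  acq1 <- structure(list(
    meta = tibble::tibble(frame_index = 1:60, head = 1L,
                          t_start = frames1$t_start, angle = frames1$angle,
                          q = 1L, r = 1L),
    main = y1, scatter = y1 * 0, detector = det, dt = 1, seed = 0L
  ), class = "acq_frames")
  img_p1 <- recon_ungated_4d(acq1, mu, basis, n_iter = 50, detector = det)
  roi <- as.logical(toy_disc(24, 7, inner = 4.5))
  m_g <- mean(evaluate_activity(img_g1, 1, 1, 30)[roi])
  m_p <- mean(evaluate_activity(img_p1, NA, NA, 30)[roi])
  expect_lt(abs(m_g - m_p) / m_g, 0.02)

  # zero iterations returns the initialisation
  img0 <- recon_ungated_4d(acq1, mu, basis, n_iter = 0, detector = det)
  expect_true(all(img0$coeff$pooled %in% c(0, 1)))
})
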