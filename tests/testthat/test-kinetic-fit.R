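# ROI TAC extraction and 1TCM parameter estimation.

test_that("extract_tacs returns the ROI means of the expanded coefficients", {
  tt <- seq(0, 60, by = 0.5)
  basis <- build_bspline_basis(c(20, 40), tt, domain = c(0, 60))
  nvox <- 12 * 12
  img <- structure(list(
    coeff = list(q1_r1 = matrix(1.8, nvox, basis$n_basis)),
    basis = basis, dims = c(12L, 12L, 1L), voxel_mm = 4.4,
    gates = tibble::tibble(q = 1L, r = 1L, state_index = 1L),
    detector = toy_detector(12)), class = "gated_dynamic_image")
  roi1 <- array(FALSE, c(12, 12, 1)); roi1[3:5, 3:5, 1] <- TRUE
  roi2 <- array(FALSE, c(12, 12, 1)); roi2[8:10, 8:10, 1] <- TRUE
  tac <- extract_tacs(img, roi1, roi2, sample_times = tt)
  expect_equal(nrow(tac), length(tt))
  expect_true(all(abs(tac$myocardium - 1.8) < 1e-10))
  expect_true(all(abs(tac$blood - 1.8) < 1e-10))
  expect_error(extract_tacs(img, roi1 & FALSE, roi2, tt), "empty ROI")
})

test_that("closed loop: painting the generator TACs reproduces them", {
  # a "reconstruction" whose coefficients are fit to the true TACs is
  # evaluated back through extract_tacs
  ts <- assemble_tacset(1, volumes_ml = tissue_volumes_ml(micro_config()))
  tt <- ts$time_s
  basis <- build_bspline_basis(seq(15, 345, by = 15), tt)  # dense knots
  B <- eval_basis(basis, tt)
  cf_m <- qr.solve(crossprod(B), crossprod(B, ts$myocardium))
  cf_b <- qr.solve(crossprod(B), crossprod(B, ts$blood))
  nvox <- 6 * 6
  coeff <- matrix(0, nvox, basis$n_basis)
  roi_m <- array(FALSE, c(6, 6, 1)); roi_m[1:3, , 1] <- TRUE
  roi_b <- array(FALSE, c(6, 6, 1)); roi_b[4:6, , 1] <- TRUE
  coeff[as.logical(roi_m), ] <- matrix(cf_m, sum(roi_m), basis$n_basis,
                                       byrow = TRUE)
  coeff[as.logical(roi_b), ] <- matrix(cf_b, sum(roi_b), basis$n_basis,
                                       byrow = TRUE)
  img <- structure(list(
    coeff = list(q1_r1 = coeff), basis = basis,
    dims = c(6L, 6L, 1L), voxel_mm = 4.4,
    gates = tibble::tibble(q = 1L, r = 1L, state_index = 1L),
    detector = toy_detector(6)), class = "gated_dynamic_image")
  tac <- extract_tacs(img, roi_m, roi_b, sample_times = tt)
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(rel(tac$myocardium, ts$myocardium), 0.02)
  expect_lt(rel(tac$blood, ts$blood), 0.02)
})

test_that("noiseless 1TCM self-consistency across a parameter grid", {
  times <- seq(0, 360, by = 0.125)
  blood <- blood_input(input_function_params(washout_rate = 0.45), times)
  for (K1 in c(0.1, 0.33, 1.0)) {
    for (k2 in c(0.05, 0.21, 0.5)) {
      for (VL in c(0, 0.4, 0.6)) {
        myo <- tissue_tac_1tcm(kinetic_params(K1, k2, VL), blood, times)
        f <- fit_1tcm(myo, blood, times)
        expect_lt(abs(f$params$K1 - K1) / max(K1, 0.01), 0.02)
        expect_lt(abs(f$params$k2 - k2) / max(k2, 0.01), 0.02)
        expect_lt(abs(f$params$VL - VL), 0.01)
      }
    }
  }
})

test_that("pure spillover drives K1 to zero and VL to the blood fraction", {
  times <- seq(0, 360, by = 0.25)
  blood <- blood_input(input_function_params(), times)
  f <- fit_1tcm(0.4 * blood, blood, times)
  expect_lt(f$params$K1, 1e-3)
  expect_equal(f$params$VL, 0.4, tolerance = 1e-3)
})

test_that("the fit is invariant to joint rescaling of both TACs", {
  times <- seq(0, 360, by = 0.25)
  blood <- blood_input(input_function_params(washout_rate = 0.45), times)
  myo <- tissue_tac_1tcm(kinetic_params(0.33, 0.21, 0.4), blood, times)
  f1 <- fit_1tcm(myo, blood, times)
  f2 <- fit_1tcm(17 * myo, 17 * blood, times)
  expect_equal(f1$params$K1, f2$params$K1, tolerance = 1e-4)
  expect_equal(f1$params$k2, f2$params$k2, tolerance = 1e-4)
  expect_equal(f1$params$VL, f2$params$VL, tolerance = 1e-4)
})

test_that("noisy replicates recover K1 with small median error", {
  times <- seq(0, 360, by = 0.5)
  blood <- blood_input(input_function_params(washout_rate = 0.45), times)
  truth <- kinetic_params(0.33, 0.21, 0.40)
  myo0 <- tissue_tac_1tcm(truth, blood, times)
  set.seed(42)
  k1s <- vapply(1:50, function(i) {
    noisy <- myo0 + rnorm(length(myo0), sd = 0.05 * max(myo0))
    fit_1tcm(pmax(noisy, 0), blood, times)$params$K1
  }, numeric(1))
  bias <- mean(k1s) - truth$K1
  rmse <- sqrt(mean((k1s - truth$K1)^2))
  expect_lt(abs(median(k1s) - truth$K1) / truth$K1, 0.10)
  expect_lt(rmse, 0.15)
})

test_that("tidy and glance expose the estimates", {
  times <- seq(0, 120, by = 0.5)
  blood <- blood_input(input_function_params(), times)
  myo <- tissue_tac_1tcm(kinetic_params(0.5, 0.3, 0.2), blood, times)
  f <- fit_1tcm(myo, blood, times, gate = "systole")
  td <- tidy(f)
  expect_equal(td$term, c("K1", "k2", "VL"))
  gl <- glance(f)
  expect_equal(gl$gate, "systole")
  expect_true(gl$residual_rms >= 0)
})
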