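# One-tissue compartment fitting of reconstructed TACs: ROI extraction
# from the coefficient field and bounded multi-start least squares for
# (K1, k2, VL), with the reconstructed LV blood pool as input function.

#' Extract ROI time-activity curves from a reconstruction
#'
#' ROI-mean activity at each sample time, per reconstructed gate. Because
#' the activity is linear in the basis, the ROI mean equals the ROI mean
#' of the coefficients expanded through the basis.
#'
#' @param img A `gated_dynamic_image`.
#' @param roi_myo,roi_blood Logical ROI arrays on the reconstruction grid.
#' @param sample_times Times (s) at which to sample.
#' @param gates Optional tibble (`q`, `r`) restricting the gates.
#' @return Tibble with columns `q`, `r`, `time_s`, `myocardium`, `blood`.
#' @export
extract_tacs <- function(img, roi_myo, roi_blood,
                         sample_times = seq(0, 360, by = 0.125),
                         gates = NULL) {
  if (!any(roi_myo) || !any(roi_blood)) abort("empty ROI")
  gt <- img$gates
  if (!is.null(gates)) {
    gt <- dplyr::semi_join(gt, as_tibble(gates), by = c("q", "r"))
    if (!nrow(gt)) abort("requested gates not in the image")
  }
  B <- eval_basis(img$basis, sample_times)           # nt x nb
  mi <- which(as.logical(roi_myo)); bi <- which(as.logical(roi_blood))
  purrr::pmap_dfr(gt, function(q, r, state_index) {
    key <- if (is.na(q)) "pooled" else gate_key(q, r)
    cf <- img$coeff[[key]]
    tibble(q = q, r = r, time_s = sample_times,
           myocardium = as.double(B %*% colMeans(cf[mi, , drop = FALSE])),
           blood = as.double(B %*% colMeans(cf[bi, , drop = FALSE])))
  })
}

default_1tcm_starts <- function() {
  list(c(0.3, 0.2, 0.3), c(0.8, 0.5, 0.2), c(0.1, 0.05, 0.5),
       c(1.5, 1.0, 0.1), c(0.5, 0.3, 0.6))
}

#' Fit the one-tissue compartment model with spillover
#'
#' Bounded least-squares fit of `(K1, k2, VL)` to a myocardial TAC with
#' the blood TAC as input, by multi-start local minimisation (deterministic
#' fixed starts, best residual kept).
#'
#' @param myo Myocardial TAC.
#' @param blood Blood (input) TAC on the same grid.
#' @param times Sample times (s).
#' @param lower,upper Parameter bounds `(K1, k2, VL)`.
#' @param starts List of start vectors; default 5 fixed starts.
#' @param weights Optional per-sample weights (default unweighted).
#' @param gate Optional label (e.g. `"systole"`, `"diastole"` or a gate
#'   index) carried into the result.
#' @return A `fit_1tcm` object: `params` ([kinetic_params()]),
#'   `residual_rms`, `converged`, `gate`, and the per-start summary.
#' @export
fit_1tcm <- function(myo, blood, times,
                     lower = c(0, 0, 0), upper = c(3, 3, 1),
                     starts = default_1tcm_starts(),
                     weights = NULL, gate = NA) {
  stopifnot(length(myo) == length(times), length(blood) == length(times))
  w <- weights %||% rep(1, length(times))
  obj <- function(p) {
    pred <- tissue_tac_1tcm(kinetic_params(p[1], p[2], p[3]), blood, times)
    sum(w * (myo - pred)^2)
  }
  runs <- lapply(starts, function(s0) {
    s0 <- pmin(pmax(s0, lower), upper)
    tryCatch(
      optim(s0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) list(par = s0, value = obj(s0), convergence = 99L)
    )
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  p <- best$par
  structure(list(
    params = kinetic_params(p[1], p[2], p[3]),
    residual_rms = sqrt(best$value / sum(w)),
    converged = best$convergence == 0L,
    gate = gate,
    starts = tibble(
      start = seq_along(runs),
      K1 = vapply(runs, function(r) r$par[1], numeric(1)),
      k2 = vapply(runs, function(r) r$par[2], numeric(1)),
      VL = vapply(runs, function(r) r$par[3], numeric(1)),
      sse = vals,
      convergence = vapply(runs, function(r) as.integer(r$convergence),
                           integer(1))
    ),
    data = tibble(time_s = times, myocardium = myo, blood = blood)
  ), class = "fit_1tcm")
}

#' @export
print.fit_1tcm <- function(x, ...) {
  cat("<fit_1tcm> K1 =", signif(x$params$K1, 4), "ml/g/min, k2 =",
      signif(x$params$k2, 4), "/min, VL =",
      signif(100 * x$params$VL, 4), "%, residual RMS =",
      signif(x$residual_rms, 4), "\n")
  invisible(x)
}

#' Tidy a 1TCM fit
#'
#' @param x A `fit_1tcm` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `units`.
#' @export
tidy.fit_1tcm <- function(x, ...) {
  tibble(term = c("K1", "k2", "VL"),
         estimate = c(x$params$K1, x$params$k2, x$params$VL),
         units = c("ml/g/min", "1/min", "fraction"))
}

#' One-row fit summary
#'
#' @param x A `fit_1tcm` object.
#' @param ... Unused.
#' @return One-row tibble: estimates, residual RMS, convergence.
#' @export
glance.fit_1tcm <- function(x, ...) {
  tibble(K1 = x$params$K1, k2 = x$params$k2, VL = x$params$VL,
         residual_rms = x$residual_rms, converged = x$converged,
         gate = as.character(x$gate))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
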