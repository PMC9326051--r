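# Continuous-rotation dual-head acquisition: rotation/gating schedule,
# attenuated forward projection with depth-dependent collimator response,
# scatter emulation in two energy windows, Poisson noise, DEW correction.

#' Detector and acquisition model
#'
#' Dual-head gamma camera with an LEHR parallel-hole collimator. The
#' geometric response FWHM at distance `d` from the collimator face is
#' `hole_diameter * (hole_length + d) / hole_length`, combined in
#' quadrature with the intrinsic FWHM. `sensitivity_scale` is the single
#' global calibration converting (concentration x path length x s) into
#' expected counts; its default is calibrated once so that the Case-1
#' main-window totals over the last minute of the scan land at the
#' modelled system's 2.1e6-count level scaled by the desk-grid
#' voxel-area ratio (8.4e6 at 4.4 mm voxels).
#'
#' @param hole_diameter,hole_length,septal_thickness Collimator geometry (mm).
#' @param intrinsic_fwhm Intrinsic detector blur FWHM (mm).
#' @param radius_of_rotation Collimator-face radius of rotation (mm).
#' @param energy_window_main,energy_window_scatter Energy windows (keV),
#'   informative only (scatter is emulated, not transported).
#' @param dew_k Dual-energy-window scatter multiplication factor.
#' @param sensitivity_scale Counts per (uCi/ml x mm x s).
#' @param n_bins_trans,n_bins_axial Detector bins (transaxial x axial).
#' @param bin_mm Detector bin size (mm); must equal the voxel size used in
#'   projection.
#' @param scatter_fraction Scatter-to-primary fraction in the main window.
#' @param scatter_kernel_fwhm Gaussian FWHM (mm) of the scatter emulation.
#' @return A `detector_model` list.
#' @export
detector_model <- function(hole_diameter = 1.5, hole_length = 35,
                           septal_thickness = 0.2, intrinsic_fwhm = 2.5,
                           radius_of_rotation = 320,
                           energy_window_main = c(126, 154),
                           energy_window_scatter = c(100, 125),
                           dew_k = 0.5,
                           sensitivity_scale = 0.122,
                           n_bins_trans = 64L, n_bins_axial = 64L,
                           bin_mm = 4.4,
                           scatter_fraction = 0.3,
                           scatter_kernel_fwhm = 40) {
  stopifnot(hole_diameter > 0, hole_length > 0, intrinsic_fwhm >= 0,
            radius_of_rotation > 0, dew_k > 0, dew_k <= 1,
            scatter_fraction >= 0, scatter_fraction < 1)
  structure(list(
    hole_diameter = hole_diameter, hole_length = hole_length,
    septal_thickness = septal_thickness, intrinsic_fwhm = intrinsic_fwhm,
    radius_of_rotation = radius_of_rotation,
    energy_window_main = energy_window_main,
    energy_window_scatter = energy_window_scatter,
    dew_k = dew_k, sensitivity_scale = sensitivity_scale,
    n_bins_trans = as.integer(n_bins_trans),
    n_bins_axial = as.integer(n_bins_axial),
    bin_mm = bin_mm,
    scatter_fraction = scatter_fraction,
    scatter_kernel_fwhm = scatter_kernel_fwhm
  ), class = "detector_model")
}

#' Cardiac/respiratory gate of a time point
#'
#' Left-closed right-open sub-phase intervals:
#' `q = floor(mod(t, Tc) / (Tc / n_cardiac)) + 1`, likewise for `r`.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param cardiac_period,resp_period Periods (s).
#' @param n_cardiac,n_resp Gate counts.
#' @return Tibble with integer columns `q`, `r`.
#' @export
gate_of_time <- function(t, cardiac_period = 1, resp_period = 5,
                         n_cardiac = 8L, n_resp = 5L) {
  stopifnot(all(t >= 0))
  eps <- 1e-9
  q <- floor((t %% cardiac_period) / (cardiac_period / n_cardiac) + eps) %% n_cardiac + 1L
  r <- floor((t %% resp_period) / (resp_period / n_resp) + eps) %% n_resp + 1L
  tibble(q = as.integer(q), r = as.integer(r))
}

#' Build the continuous-rotation acquisition schedule
#'
#' One binned frame per `dt` with the heads advancing `dtheta` per frame;
#' head 2 opposes head 1 at 180 degrees (H-mode). Defaults give 720 frames
#' per rotation per head, a 90 s rotation period and a 360 s scan.
#'
#' @param dt Frame duration (s).
#' @param dtheta Angle increment per frame (deg); `360 / dtheta` must be
#'   integral.
#' @param n_rotations Number of rotations per head.
#' @param cardiac_period,resp_period,n_cardiac,n_resp Gating structure.
#' @return An `acq_schedule` tibble (one row per time frame) with columns
#'   `frame_index`, `t_start`, `head1_angle`, `head2_angle`,
#'   `cardiac_gate`, `resp_gate`, and attributes `dt`, `dtheta`,
#'   `n_rotations`, `frames_per_rotation`, `rotation_period`,
#'   `total_duration`, `n_heads`, and the gating parameters.
#' @export
build_schedule <- function(dt = 0.125, dtheta = 0.5, n_rotations = 4,
                           cardiac_period = 1, resp_period = 5,
                           n_cardiac = 8L, n_resp = 5L) {
  stopifnot(dt > 0, dtheta > 0)
  fpr <- 360 / dtheta
  if (abs(fpr - round(fpr)) > 1e-9) {
    abort("360 / dtheta must be an integer number of frames per rotation")
  }
  fpr <- as.integer(round(fpr))
  n_frames <- fpr * n_rotations
  frame_index <- seq_len(n_frames)
  t_start <- (frame_index - 1) * dt
  a1 <- ((frame_index - 1) * dtheta) %% 360
  gates <- gate_of_time(t_start, cardiac_period, resp_period,
                        n_cardiac, n_resp)
  out <- tibble(
    frame_index = frame_index, t_start = t_start,
    head1_angle = a1, head2_angle = (a1 + 180) %% 360,
    cardiac_gate = gates$q, resp_gate = gates$r
  )
  structure(out, class = c("acq_schedule", class(out)),
            dt = dt, dtheta = dtheta, n_rotations = n_rotations,
            frames_per_rotation = fpr,
            rotation_period = fpr * dt,
            total_duration = n_frames * dt,
            n_heads = 2L,
            cardiac_period = cardiac_period, resp_period = resp_period,
            n_cardiac = as.integer(n_cardiac), n_resp = as.integer(n_resp))
}

# Depth-dependent total blur variance (bin^2) per depth sample; depth index
# increases towards the detector.
psf_sig2_bins <- function(detector, nd, vx) {
  cd <- 0.5 * (nd - 1)
  kc <- (seq_len(nd) - 1 - cd) * vx
  dist <- pmax(detector$radius_of_rotation - kc, 0)
  fg <- detector$hole_diameter *
    (detector$hole_length + dist) / detector$hole_length
  (detector$intrinsic_fwhm^2 + fg^2) / (8 * log(2)) / vx^2
}

# Depth sample counts are kept odd so the depth positions
# (k - (nd-1)/2) * vx always fall on the voxel grid: a trimmed depth range
# then samples the same physical planes as the full one, and operators
# built with different nd agree exactly on supported volumes.
make_odd <- function(n) { n <- as.integer(n); if (n %% 2L == 0L) n + 1L else n }

depth_samples <- function(dims) {
  make_odd(ceiling(sqrt(dims[1]^2 + dims[2]^2)) + 2)
}

# Depth samples needed to cover the transaxial support of a volume at any
# rotation angle (diameter of the smallest centred circle containing all
# nonzero voxels, plus margin).
support_depth_samples <- function(vol, dims = dim(vol)) {
  sup <- vol > 0
  dim(sup) <- c(dims[1] * dims[2], dims[3])
  flat <- rowSums(sup) > 0
  if (!any(flat)) return(9L)
  dim(flat) <- dims[1:2]
  xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2)
  ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2)
  r2 <- outer(xs^2, ys^2, `+`)
  make_odd(2L * ceiling(sqrt(max(r2[flat]))) + 6L)
}

#' Attenuated forward projection at one head angle
#'
#' Line integrals of the activity orthogonal to the detector face, each
#' emission point attenuated by `exp(-integral mu dl)` along its exit path
#' and blurred by the depth-dependent detector response, scaled by
#' `sensitivity_scale * dt`.
#'
#' @param activity Activity volume (3D array, concentration units).
#' @param mu Attenuation volume (1/cm), same grid.
#' @param angle_deg Head angle (deg).
#' @param detector A [detector_model()]; `bin_mm` must equal the voxel size.
#' @param voxel_mm Voxel size (mm).
#' @param dt Frame duration (s).
#' @param psf Apply the detector response blur?
#' @param attf Optional precomputed attenuation factors (from
#'   [att_factors()]) to avoid recomputation across calls.
#' @return Expected-count matrix (`n_bins_trans` x `n_bins_axial`).
#' @export
forward_project <- function(activity, mu, angle_deg, detector,
                            voxel_mm = detector$bin_mm, dt = 1,
                            psf = TRUE, attf = NULL) {
  dims <- dim(activity)
  if (!identical(dims, dim(mu))) abort("activity and mu grids differ")
  if (abs(voxel_mm - detector$bin_mm) > 1e-9) {
    abort("detector bin size must equal the voxel size")
  }
  nd <- depth_samples(dims)
  nu <- detector$n_bins_trans; nv <- detector$n_bins_axial
  if (nv < dims[3]) abort("detector axial extent smaller than the volume")
  if (is.null(attf)) {
    attf <- cpp_att_factors(as.double(mu), as.integer(dims), angle_deg,
                            nu, nd, voxel_mm)
  }
  sig2 <- psf_sig2_bins(detector, nd, voxel_mm)
  p <- cpp_forward(as.double(activity), as.integer(dims), attf, angle_deg,
                   nu, nv, nd, voxel_mm, sig2, isTRUE(psf))
  p * detector$sensitivity_scale * dt
}

#' @rdname forward_project
#' @param proj Projection matrix to backproject.
#' @description `project_adjoint()` is the exact matched adjoint of
#'   `forward_project()` (same attenuation, blur and sampling weights),
#'   as required by the MLEM update.
#' @export
project_adjoint <- function(proj, mu, angle_deg, detector,
                            voxel_mm = detector$bin_mm, dt = 1,
                            psf = TRUE, attf = NULL) {
  dims <- dim(mu)
  nd <- depth_samples(dims)
  nu <- detector$n_bins_trans; nv <- detector$n_bins_axial
  stopifnot(nrow(proj) == nu, ncol(proj) == nv)
  if (is.null(attf)) {
    attf <- cpp_att_factors(as.double(mu), as.integer(dims), angle_deg,
                            nu, nd, voxel_mm)
  }
  sig2 <- psf_sig2_bins(detector, nd, voxel_mm)
  v <- cpp_adjoint(proj, as.integer(dims), attf, angle_deg,
                   nu, nv, nd, voxel_mm, sig2, isTRUE(psf))
  array(v * detector$sensitivity_scale * dt, dim = dims)
}

#' Precompute attenuation factors for an angle
#'
#' @inheritParams forward_project
#' @return Opaque numeric array consumed by [forward_project()] /
#'   [project_adjoint()] via their `attf` argument.
#' @export
att_factors <- function(mu, angle_deg, detector,
                        voxel_mm = detector$bin_mm) {
  dims <- dim(mu)
  cpp_att_factors(as.double(mu), as.integer(dims), angle_deg,
                  detector$n_bins_trans, depth_samples(dims), voxel_mm)
}

gaussian_kernel <- function(fwhm_mm, bin_mm, half_width = NULL) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / bin_mm
  h <- half_width %||% max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-h, h), sd = max(sigma, 1e-6))
  k / sum(k)
}

#' Emulate scatter in the two energy windows
#'
#' Scatter in the main window is a broad Gaussian blur of the primary
#' projection scaled by `scatter_fraction`; the scatter-window expectation
#' is that same component divided by `dew_k`, so that
#' `main - dew_k * scatter_window = primary` holds exactly in expectation.
#' The blur conserves total counts exactly (mass-conserving boundary).
#'
#' @param primary Expected primary projection (matrix).
#' @param scatter_fraction Scatter-to-primary fraction in the main window.
#' @param kernel_fwhm_mm Gaussian FWHM of the scatter kernel (mm).
#' @param bin_mm Detector bin size (mm).
#' @param dew_k DEW scatter multiplication factor.
#' @return List with matrices `main` and `scatter_window`.
#' @export
emulate_scatter <- function(primary, scatter_fraction = 0.3,
                            kernel_fwhm_mm = 40, bin_mm = 4.4,
                            dew_k = 0.5) {
  stopifnot(scatter_fraction >= 0, scatter_fraction < 1)
  if (scatter_fraction == 0) {
    return(list(main = primary, scatter_window = primary * 0))
  }
  kern <- gaussian_kernel(kernel_fwhm_mm, bin_mm)
  sc <- scatter_fraction * cpp_blur2d(primary, kern)
  list(main = primary + sc, scatter_window = sc / dew_k)
}

#' Dual-energy-window scatter correction
#'
#' `corrected = max(0, main - dew_k * scatter)`; the fraction of bins
#' clipped at zero is recorded in the `"clipped_frac"` attribute.
#'
#' @param main,scatter Count matrices (or arrays of matching shape).
#' @param dew_k Scatter multiplication factor.
#' @return Corrected counts, same shape.
#' @export
dew_correct <- function(main, scatter, dew_k = 0.5) {
  if (!identical(dim(main), dim(scatter))) abort("frame shapes differ")
  raw <- main - dew_k * scatter
  out <- pmax(raw, 0)
  attr(out, "clipped_frac") <- mean(raw < 0)
  out
}

# -- tissue-projection cache -------------------------------------------------
#
# Projection is linear in activity and each gate maps to one phantom state,
# so every expected frame is a TAC-weighted sum of the four tissue-indicator
# projections of its gate's state at its angle. The cache holds, per
# (state, angle), the primary tissue projections and their scatter blurs.

tissue_names <- c("myocardium", "blood", "liver", "background")

tissue_indicator <- function(state, tissue) {
  lab <- state$labels
  if (tissue == "background") {
    ind <- lab == tissue_labels[["background"]] | lab == tissue_labels[["lung"]]
  } else {
    ind <- lab == tissue_labels[[tissue]]
  }
  array(as.double(ind), dim = dim(lab))
}

#' Create a projection cache
#'
#' Holds the expected tissue-indicator projections per (state, angle).
#' These are deterministic, so one cache can be shared across seeds and
#' across TAC cases that use the same phantom geometry.
#'
#' @return An environment usable as the `cache` argument of
#'   [simulate_acquisition()].
#' @export
new_projection_cache <- function() new.env(parent = emptyenv())

tissue_projection <- function(cache, states, state_index, angle, detector, dt) {
  key <- sprintf("s%d_a%.4f", state_index, angle)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  st <- states[[state_index]]
  attf <- att_factors(st$mu_map, angle, detector, st$voxel_mm)
  kern <- gaussian_kernel(detector$scatter_kernel_fwhm, detector$bin_mm)
  prim <- lapply(tissue_names, function(tn) {
    forward_project(tissue_indicator(st, tn), st$mu_map, angle, detector,
                    st$voxel_mm, dt = dt, attf = attf)
  })
  blur <- lapply(prim, function(p) cpp_blur2d(p, kern))
  names(prim) <- names(blur) <- tissue_names
  val <- list(primary = prim, blurred = blur)
  cache[[key]] <- val
  val
}

#' Simulate a continuous-rotation acquisition
#'
#' For every schedule frame the tissue TAC values at the frame start are
#' painted onto the phantom state matching the frame's gate tag, forward
#' projected for each head, scatter is emulated in the two energy windows,
#' and Poisson counts are drawn. Both heads and both windows are returned;
#' each head-frame carries its gate tag.
#'
#' @param states A `phantom_sequence` (indexed by `state_index`).
#' @param tacset A [assemble_tacset()] result on the schedule's time grid.
#' @param schedule A [build_schedule()] tibble.
#' @param detector A [detector_model()].
#' @param seed Integer seed for the Poisson draws.
#' @param gates Optional tibble/data frame with columns `q`, `r`: restrict
#'   the simulated frames to these gates (the untouched frames are simply
#'   not binned; the schedule itself is unchanged).
#' @param cache Optional projection cache (see [new_projection_cache()]);
#'   expected tissue projections are deterministic and can be shared
#'   across seeds and cases.
#' @return An `acq_frames` object: `meta` tibble (one row per head-frame:
#'   `frame_index`, `head`, `t_start`, `angle`, `q`, `r`) plus integer
#'   count arrays `main` and `scatter` of dim (nu, nv, n_head_frames).
#' @export
simulate_acquisition <- function(states, tacset, schedule, detector,
                                 seed = 1L, gates = NULL, cache = NULL,
                                 keep_expected = FALSE) {
  stopifnot(inherits(states, "phantom_sequence"))
  n_cardiac <- attr(schedule, "n_cardiac")
  dt <- attr(schedule, "dt")
  if (is.null(cache)) cache <- new_projection_cache()

  meta <- tidyr::pivot_longer(
    schedule,
    cols = c("head1_angle", "head2_angle"),
    names_to = "head", values_to = "angle"
  )
  meta <- dplyr::mutate(
    meta,
    head = ifelse(.data$head == "head1_angle", 1L, 2L),
    q = .data$cardiac_gate, r = .data$resp_gate,
    state_index = (.data$resp_gate - 1L) * n_cardiac + .data$cardiac_gate
  )
  meta <- dplyr::select(meta, "frame_index", "head", "t_start", "angle",
                        "q", "r", "state_index")
  if (!is.null(gates)) {
    keep <- paste(meta$q, meta$r) %in% paste(gates$q, gates$r)
    meta <- meta[keep, ]
  }
  n <- nrow(meta)
  nu <- detector$n_bins_trans; nv <- detector$n_bins_axial
  nb <- nu * nv
  sf <- detector$scatter_fraction

  # TAC weights per frame (rows: frames, cols: tissues)
  w <- vapply(tissue_names, function(nm) {
    stats::approx(tacset$time_s, tacset[[nm]], xout = meta$t_start,
                  rule = 2)$y
  }, numeric(n))

  main_mu <- matrix(0, nb, n)
  scat_mu <- matrix(0, nb, n)
  combos <- split(seq_len(n), paste(meta$state_index, meta$angle))
  for (idx in combos) {
    si <- meta$state_index[idx[1]]
    ang <- meta$angle[idx[1]]
    tp <- tissue_projection(cache, states, si, ang, detector, dt)
    P <- vapply(tp$primary, as.double, numeric(nb))   # nb x 4
    B <- vapply(tp$blurred, as.double, numeric(nb))
    wf <- w[idx, , drop = FALSE]                       # nf x 4
    prim <- P %*% t(wf)
    blur <- B %*% t(wf)
    main_mu[, idx] <- prim + sf * blur
    scat_mu[, idx] <- sf * blur / detector$dew_k
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  main_cts <- rpois(length(main_mu), main_mu)
  scat_cts <- rpois(length(scat_mu), scat_mu)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  out <- list(
    meta = meta,
    main = array(as.integer(main_cts), dim = c(nu, nv, n)),
    scatter = array(as.integer(scat_cts), dim = c(nu, nv, n)),
    detector = detector, dt = dt, seed = as.integer(seed)
  )
  if (keep_expected) {
    out$expected_main <- array(main_mu, dim = c(nu, nv, n))
    out$expected_scatter <- array(scat_mu, dim = c(nu, nv, n))
  }
  structure(out, class = "acq_frames")
}

#' @export
print.acq_frames <- function(x, ...) {
  cat("<acq_frames>", nrow(x$meta), "head-frames,",
      paste(dim(x$main)[1:2], collapse = "x"), "bins, seed", x$seed, "\n")
  invisible(x)
}
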