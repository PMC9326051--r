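# Deformable cardiac-torso phantom: labelled tissue volumes plus matched
# attenuation maps for each of the 40 cardiac-respiratory motion states.
#
# The anatomy is deliberately analytic (ellipsoidal organs) so every motion
# law can be verified in closed form: the LV myocardium is a prolate
# ellipsoidal shell whose endocardial semi-axes contract linearly from
# end-diastole to end-systole with the wall volume conserved; the whole
# heart and the liver translate along the body axis with a raised-cosine
# respiratory profile; the anterior chest wall expands in synchrony.

#' Phantom configuration
#'
#' Builds the configuration of the deformable torso phantom. Defaults give
#' the desk-scale grid (90 x 60 x 55 voxels of 4.4 mm, equal to the
#' reconstruction voxel size); `grid = "full"` doubles the resolution
#' (180 x 120 x 110 at 2.2 mm).
#'
#' @param grid `"desk"` or `"full"`, or leave as is and override
#'   `grid_dims`/`voxel_mm` directly.
#' @param grid_dims Integer vector of voxel counts per axis (x right-left,
#'   y posterior-anterior, z inferior-superior).
#' @param voxel_mm Isotropic voxel size in mm.
#' @param cardiac_period,resp_period Cardiac and respiratory periods (s).
#' @param ed_to_es Duration from end-diastole to end-systole (s).
#' @param ap_expansion_cm Anterior-posterior chest expansion at full
#'   inhalation (cm).
#' @param diaphragm_amp_cm Inferior-superior displacement amplitude of the
#'   heart and liver over the respiratory cycle (cm).
#' @param n_cardiac,n_resp Number of cardiac and respiratory gates.
#' @param es_endo_scale Endocardial semi-axis scale factor at end-systole
#'   (0.737 gives a ~60% ejection fraction).
#' @param lv_center LV centre (mm, volume-centred coordinates).
#' @param lv_endo,lv_epi Endo/epicardial semi-axes at end-diastole (mm).
#' @param wall_mode `"uniform"` or `"non-uniform"` (a thinned angular
#'   sector of the wall).
#' @param defect_azimuth_deg Azimuthal extent (deg, measured in the x-y
#'   plane from +x) of the thinned sector when `wall_mode = "non-uniform"`.
#' @param defect_fraction Fractional wall-thickness reduction in the sector.
#' @param body_semiaxes Transaxial semi-axes (mm) of the elliptic-cylinder
#'   body; the anterior semi-axis grows by the AP expansion at inhalation.
#' @param lung_centers,lung_semiaxes Centres (list of mm triples) and
#'   semi-axes of the two lung ellipsoids.
#' @param liver_center,liver_semiaxes Centre and semi-axes of the liver
#'   half-ellipsoid (the dome above the centre plane is kept).
#' @param mu_table Named attenuation coefficients (1/cm at 140 keV), one
#'   entry per tissue label name.
#'
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(grid = c("desk", "full"),
                           grid_dims = NULL, voxel_mm = NULL,
                           cardiac_period = 1.0, resp_period = 5.0,
                           ed_to_es = 0.325,
                           ap_expansion_cm = 1.2, diaphragm_amp_cm = 2.0,
                           n_cardiac = 8L, n_resp = 5L,
                           es_endo_scale = 0.737,
                           lv_center = c(30, 20, 10),
                           lv_endo = c(24, 24, 40),
                           lv_epi = c(34, 34, 52),
                           wall_mode = c("uniform", "non-uniform"),
                           defect_azimuth_deg = c(0, 90),
                           defect_fraction = 0.4,
                           body_semiaxes = c(130, 95),
                           lung_centers = list(c(-65, 10, 20), c(65, 10, 20)),
                           lung_semiaxes = c(38, 55, 85),
                           liver_center = c(-45, 5, -50),
                           liver_semiaxes = c(60, 50, 45),
                           mu_table = c(air = 0, background = 0.155,
                                        lung = 0.045, liver = 0.155,
                                        myocardium = 0.155, blood = 0.155)) {
  grid <- match.arg(grid)
  if (is.null(grid_dims)) {
    grid_dims <- if (grid == "full") c(180L, 120L, 110L) else c(90L, 60L, 55L)
  }
  if (is.null(voxel_mm)) voxel_mm <- if (grid == "full") 2.2 else 4.4
  wall_mode <- match.arg(wall_mode)

  cfg <- structure(list(
    grid_dims = as.integer(grid_dims), voxel_mm = voxel_mm,
    cardiac_period = cardiac_period, resp_period = resp_period,
    ed_to_es = ed_to_es,
    ap_expansion_cm = ap_expansion_cm, diaphragm_amp_cm = diaphragm_amp_cm,
    n_cardiac = as.integer(n_cardiac), n_resp = as.integer(n_resp),
    es_endo_scale = es_endo_scale,
    lv_center = lv_center, lv_endo = lv_endo, lv_epi = lv_epi,
    wall_mode = wall_mode,
    defect_azimuth_deg = defect_azimuth_deg,
    defect_fraction = defect_fraction,
    body_semiaxes = body_semiaxes,
    lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
    liver_center = liver_center, liver_semiaxes = liver_semiaxes,
    mu_table = mu_table
  ), class = "phantom_config")

  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$voxel_mm > 0, length(cfg$grid_dims) == 3,
            all(cfg$grid_dims > 0),
            cfg$cardiac_period > 0, cfg$resp_period > 0,
            cfg$ed_to_es > 0, cfg$ed_to_es < cfg$cardiac_period,
            cfg$diaphragm_amp_cm >= 0, cfg$ap_expansion_cm >= 0,
            cfg$es_endo_scale > 0, cfg$es_endo_scale <= 1,
            cfg$defect_fraction >= 0, cfg$defect_fraction < 1)
  # periods must tile the 0.125 s sub-phase structure of the gating scheme
  sub_c <- cfg$cardiac_period / cfg$n_cardiac
  if (abs(cfg$resp_period / cfg$cardiac_period -
          round(cfg$resp_period / cfg$cardiac_period)) > 1e-9) {
    abort("resp_period must be an integer multiple of cardiac_period")
  }
  # degenerate geometry: the scaled endocardium must stay inside the
  # epicardium at every cardiac phase (the extremes suffice: linear law)
  for (s in c(1, cfg$es_endo_scale)) {
    lam <- epi_scale_for(cfg, s)
    if (any(lam * cfg$lv_epi <= s * cfg$lv_endo)) {
      abort("degenerate LV geometry: endocardium reaches the epicardium")
    }
  }
  invisible(cfg)
}

# Epicardial common scale factor conserving the myocardial wall volume when
# the endocardial semi-axes are scaled by s.
epi_scale_for <- function(cfg, s) {
  ven0 <- prod(cfg$lv_endo)
  vep0 <- prod(cfg$lv_epi)
  ((s^3 * ven0 + (vep0 - ven0)) / vep0)^(1 / 3)
}

# Raised-cosine respiratory fraction in [0, 1]; 0 at end-exhale (t = 0).
resp_fraction <- function(t, resp_period) (1 - cos(2 * pi * t / resp_period)) / 2

# Endocardial scale: linear contraction over [0, ed_to_es], linear
# relaxation over the remainder of the beat.
cardiac_scale <- function(t, cfg) {
  t <- t %% cfg$cardiac_period
  s_es <- cfg$es_endo_scale
  ifelse(t <= cfg$ed_to_es,
         1 - (1 - s_es) * t / cfg$ed_to_es,
         s_es + (1 - s_es) * (t - cfg$ed_to_es) /
           (cfg$cardiac_period - cfg$ed_to_es))
}

# Phase midpoint times used to freeze gate q / r into a discrete state.
gate_phase_times <- function(cfg, q, r) {
  list(t_card = (q - 0.5) * cfg$cardiac_period / cfg$n_cardiac,
       t_resp = (r - 0.5) * cfg$resp_period / cfg$n_resp)
}

# World coordinates (mm, centred) of voxel centres along each axis.
grid_axes <- function(cfg) {
  d <- cfg$grid_dims
  vx <- cfg$voxel_mm
  lapply(d, function(n) (seq_len(n) - (n + 1) / 2) * vx)
}

#' Generate one phantom motion state
#'
#' Builds the labelled tissue volume and matched attenuation map for
#' cardiac gate `q` and respiratory gate `r`. The LV shell is deformed by
#' the cardiac phase at the gate's midpoint time (radial endocardial
#' contraction from end-diastole to end-systole with the wall volume
#' conserved, so the wall thickens at systole); the heart and liver are
#' translated inferiorly by the raised-cosine respiratory displacement; the
#' anterior chest expands in synchrony. Labels are mutually exclusive and
#' exhaustive (air fills the remainder).
#'
#' @param config A [phantom_config()].
#' @param q Cardiac gate index (1..`n_cardiac`).
#' @param r Respiratory gate index (1..`n_resp`).
#' @return A `phantom_state`: list with integer array `labels`, double
#'   array `mu_map` (1/cm), `cardiac_gate`, `resp_gate`, `state_index`,
#'   `voxel_mm`, and the generating `config`.
#' @export
generate_state <- function(config, q, r) {
  stopifnot(inherits(config, "phantom_config"))
  if (length(q) != 1 || q < 1 || q > config$n_cardiac || q != round(q)) {
    abort("cardiac gate index out of range")
  }
  if (length(r) != 1 || r < 1 || r > config$n_resp || r != round(r)) {
    abort("respiratory gate index out of range")
  }
  q <- as.integer(q); r <- as.integer(r)
  ph <- gate_phase_times(config, q, r)

  s <- cardiac_scale(ph$t_card, config)
  lam <- epi_scale_for(config, s)
  if (any(lam * config$lv_epi <= s * config$lv_endo)) {
    abort("degenerate LV geometry at this gate")
  }
  phi <- resp_fraction(ph$t_resp, config$resp_period)
  dz <- -config$diaphragm_amp_cm * 10 * phi    # inferior at inhalation
  ap <- config$ap_expansion_cm * 10 * phi      # anterior chest expansion

  d <- config$grid_dims
  ax <- grid_axes(config)
  X <- array(rep(ax[[1]], times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), dim = d)

  labels <- array(tissue_labels[["air"]], dim = d)

  # body: elliptic cylinder, anterior semi-axis grown by the AP expansion
  ba <- config$body_semiaxes[1]
  bp <- config$body_semiaxes[2]
  b_eff <- ifelse(Y > 0, bp + ap, bp)
  body <- (X / ba)^2 + (Y / b_eff)^2 <= 1
  labels[body] <- tissue_labels[["background"]]

  inside_ellipsoid <- function(ctr, semi) {
    ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
      ((Z - ctr[3]) / semi[3])^2 <= 1
  }

  for (lc in config$lung_centers) {
    labels[inside_ellipsoid(lc, config$lung_semiaxes) & body] <-
      tissue_labels[["lung"]]
  }

  liv_ctr <- config$liver_center + c(0, 0, dz)
  liver <- inside_ellipsoid(liv_ctr, config$liver_semiaxes) &
    Z >= liv_ctr[3] & body
  labels[liver] <- tissue_labels[["liver"]]

  lv_ctr <- config$lv_center + c(0, 0, dz)
  endo <- s * config$lv_endo
  epi <- lam * config$lv_epi
  in_epi <- inside_ellipsoid(lv_ctr, epi)
  if (config$wall_mode == "non-uniform") {
    # thinned sector: epicardium pulled towards the endocardium
    azim <- atan2(Y - lv_ctr[2], X - lv_ctr[1]) * 180 / pi
    azim <- (azim + 360) %% 360
    lo <- config$defect_azimuth_deg[1]; hi <- config$defect_azimuth_deg[2]
    sector <- azim >= lo & azim <= hi
    epi_d <- endo + (epi - endo) * (1 - config$defect_fraction)
    in_epi <- (in_epi & !sector) | (inside_ellipsoid(lv_ctr, epi_d) & sector)
  }
  in_endo <- inside_ellipsoid(lv_ctr, endo)
  labels[in_epi & body] <- tissue_labels[["myocardium"]]
  labels[in_endo & body] <- tissue_labels[["blood"]]

  structure(list(
    labels = labels,
    mu_map = attenuation_map(labels, config$mu_table),
    cardiac_gate = q, resp_gate = r,
    state_index = (r - 1L) * config$n_cardiac + q,
    voxel_mm = config$voxel_mm,
    config = config
  ), class = "phantom_state")
}

#' Generate the full periodic motion sequence
#'
#' All `n_cardiac * n_resp` states (default 40: 8 cardiac gates x 5
#' heartbeats per 5 s respiratory cycle), ordered by time. The sequence is
#' periodic: the state following the last one is again the first.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_sequence`: list of `phantom_state`s indexed by
#'   `state_index = (r - 1) * n_cardiac + q`.
#' @export
generate_sequence <- function(config) {
  n <- config$n_cardiac * config$n_resp
  states <- vector("list", n)
  for (i in seq_len(n)) {
    q <- (i - 1L) %% config$n_cardiac + 1L
    r <- (i - 1L) %/% config$n_cardiac + 1L
    states[[i]] <- generate_state(config, q, r)
  }
  structure(states, class = "phantom_sequence", config = config)
}

#' Attenuation map from a label volume
#'
#' Voxelwise lookup of narrow-beam attenuation coefficients at 140 keV.
#'
#' @param labels Integer array of tissue label codes (see [tissue_labels]).
#' @param mu_table Named vector of attenuation coefficients (1/cm), one per
#'   label name.
#' @return Double array on the same grid.
#' @export
attenuation_map <- function(labels,
                            mu_table = c(air = 0, background = 0.155,
                                         lung = 0.045, liver = 0.155,
                                         myocardium = 0.155, blood = 0.155)) {
  codes <- sort(unique(as.integer(labels)))
  known <- tissue_labels[names(mu_table)]
  if (any(is.na(known))) abort("mu_table names must be tissue label names")
  missing <- setdiff(codes, known)
  if (length(missing)) {
    abort(paste0("no attenuation entry for label code(s): ",
                 paste(missing, collapse = ", ")))
  }
  lut <- numeric(max(known) + 1L)
  lut[known + 1L] <- mu_table
  mu <- lut[as.integer(labels) + 1L]
  array(mu, dim = dim(labels))
}

#' Centroid of the LV myocardium
#'
#' @param x A `phantom_state` or an integer label array.
#' @param voxel_mm Voxel size (taken from the state if available).
#' @return Length-3 point (mm, volume-centred coordinates).
#' @export
lv_center <- function(x, voxel_mm = NULL) {
  if (inherits(x, "phantom_state")) {
    labels <- x$labels; voxel_mm <- x$voxel_mm
  } else {
    labels <- x
    if (is.null(voxel_mm)) abort("voxel_mm required for a bare label array")
  }
  idx <- which(labels == tissue_labels[["myocardium"]], arr.ind = TRUE)
  if (nrow(idx) == 0) abort("myocardium label is empty")
  d <- dim(labels)
  ctr <- colMeans(idx)
  (ctr - (d + 1) / 2) * voxel_mm
}

#' Analytic tissue volumes of the phantom (ml)
#'
#' Closed-form organ volumes of the configured geometry at end-diastole,
#' used to convert tissue concentrations into total activity. Background
#' includes everything inside the body that is not heart or liver (the
#' lungs carry background activity).
#'
#' @param config A [phantom_config()].
#' @return Named numeric vector (ml): myocardium, blood, liver, background.
#' @export
tissue_volumes_ml <- function(config) {
  v_ell <- function(semi) 4 / 3 * pi * prod(semi)
  blood <- v_ell(config$lv_endo)
  myo <- v_ell(config$lv_epi) - blood
  liver <- v_ell(config$liver_semiaxes) / 2
  body <- pi * prod(config$body_semiaxes) *
    config$grid_dims[3] * config$voxel_mm
  background <- body - myo - blood - liver
  c(myocardium = myo, blood = blood, liver = liver,
    background = background) / 1000
}

#' @export
print.phantom_state <- function(x, ...) {
  cat("<phantom_state> gate q=", x$cardiac_gate, " r=", x$resp_gate,
      " (state ", x$state_index, "), grid ",
      paste(dim(x$labels), collapse = "x"), " @ ", x$voxel_mm, " mm\n",
      sep = "")
  invisible(x)
}

#' @export
print.phantom_sequence <- function(x, ...) {
  cat("<phantom_sequence> of", length(x), "states\n")
  invisible(x)
}

# Morphological helpers on logical masks (6-connectivity).
shift_mask <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okz <- sz >= 1 & sz <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <- m[sx[okx], sy[oky], sz[okz]]
  out
}

#' Erode or dilate a logical mask
#'
#' 6-connectivity morphological erosion/dilation, applied `n` times.
#'
#' @param mask Logical 3D array.
#' @param n Number of passes.
#' @return Logical array.
#' @export
erode_mask <- function(mask, n = 1) {
  for (i in seq_len(n)) {
    out <- mask
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      out <- out & shift_mask(mask, s[1], s[2], s[3])
    }
    mask <- out
  }
  mask
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, n = 1) {
  for (i in seq_len(n)) {
    out <- mask
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      out <- out | shift_mask(mask, s[1], s[2], s[3])
    }
    mask <- out
  }
  mask
}

#' Ground-truth regions of interest
#'
#' Myocardial (or blood-pool) ROI from a phantom state's labels, optionally
#' eroded to limit partial-volume edge effects.
#'
#' @param state A `phantom_state`.
#' @param tissue Label name, e.g. `"myocardium"` or `"blood"`.
#' @param erode Erosion passes (default 1).
#' @return Logical array.
#' @export
roi_from_state <- function(state, tissue = "myocardium", erode = 1) {
  m <- state$labels == tissue_labels[[tissue]]
  if (erode > 0) m <- erode_mask(m, erode)
  if (!any(m)) abort("ROI is empty after erosion")
  m
}
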