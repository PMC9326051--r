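# Shared fixtures: a miniature torso configuration (same gating structure
# as the desk phantom, much smaller grid), 2D toy objects for the
# reconstruction tests, and small utilities. Everything is generated in
# code at test time.

micro_config <- function(...) {
  phantom_config(
    grid_dims = c(24L, 20L, 14L), voxel_mm = 4.4,
    lv_center = c(8, 2, 0), lv_endo = c(9, 9, 11), lv_epi = c(22, 22, 26),
    body_semiaxes = c(44, 34),
    lung_centers = list(c(-20, 4, 2), c(22, 4, 2)),
    lung_semiaxes = c(10, 14, 16),
    liver_center = c(-14, 0, -10), liver_semiaxes = c(16, 14, 10),
    diaphragm_amp_cm = 0.5, ap_expansion_cm = 0.3,
    ...
  )
}

micro_detector <- function(sensitivity_scale = 0.05, ...) {
  detector_model(n_bins_trans = 24L, n_bins_axial = 16L,
                 sensitivity_scale = sensitivity_scale, ...)
}

# 2D toy volume (n x n x 1): disc or annulus.
toy_disc <- function(n = 24, radius = 5, center = c(0, 0), value = 1,
                     inner = 0) {
  xs <- seq_len(n) - (n + 1) / 2
  X <- matrix(xs, n, n)
  Y <- t(X)
  r2 <- (X - center[1])^2 + (Y - center[2])^2
  m <- r2 <= radius^2 & r2 >= inner^2
  array(value * m, dim = c(n, n, 1))
}

toy_detector <- function(n = 24, sensitivity_scale = 1, ...) {
  detector_model(n_bins_trans = as.integer(n), n_bins_axial = 1L,
                 sensitivity_scale = sensitivity_scale,
                 scatter_fraction = 0, ...)
}

# Minimal phantom sequence wrapping explicit states: each element of
# `vols` is a list(labels=, mu=) on the same grid.
toy_sequence <- function(mus, labels = NULL, voxel_mm = 4.4,
                         n_cardiac = 1L, n_resp = length(mus)) {
  states <- lapply(seq_along(mus), function(i) {
    mu <- mus[[i]]
    lab <- if (is.null(labels)) {
      array(ifelse(mu > 0, tissue_labels[["background"]],
                   tissue_labels[["air"]]), dim = dim(mu))
    } else labels[[i]]
    structure(list(labels = lab, mu_map = mu,
                   cardiac_gate = 1L, resp_gate = as.integer(i),
                   state_index = as.integer(i), voxel_mm = voxel_mm),
              class = "phantom_state")
  })
  structure(states, class = "phantom_sequence",
            config = list(n_cardiac = as.integer(n_cardiac),
                          n_resp = as.integer(n_resp)))
}

# Hand-built gated sinogram from noiseless forward projections of per-gate
# activity volumes. `frames` is a tibble with columns gate (state index),
# angle, t_start; activity_fn(gate, t) returns the activity volume.
toy_sinogram <- function(frames, activity_fn, states, det, dt = 1,
                         psf = TRUE) {
  nu <- det$n_bins_trans; nv <- det$n_bins_axial
  gates <- list()
  for (gi in sort(unique(frames$gate))) {
    sub <- frames[frames$gate == gi, ]
    st <- states[[gi]]
    y <- array(0, c(nu, nv, nrow(sub)))
    for (j in seq_len(nrow(sub))) {
      act <- activity_fn(gi, sub$t_start[j])
      y[, , j] <- forward_project(act, st$mu_map, sub$angle[j], det,
                                  st$voxel_mm, dt = dt, psf = psf)
    }
    key <- sprintf("q%d_r%d", st$cardiac_gate, st$resp_gate)
    gates[[key]] <- list(
      meta = tibble::tibble(frame_index = seq_len(nrow(sub)), head = 1L,
                            t_start = sub$t_start, angle = sub$angle),
      y = y, main = y, scatter = y * 0,
      q = st$cardiac_gate, r = st$resp_gate, clipped_frac = 0
    )
  }
  structure(list(gates = gates,
                 views = tibble::tibble(q = NA, r = NA, n_views = NA),
                 detector = det, dt = dt),
            class = "gated_sinogram")
}

# Width at half maximum of a 1D profile, by linear interpolation around
# the global peak.
profile_fwhm <- function(p) {
  i <- which.max(p)
  h <- p[i] / 2
  left <- i
  while (left > 1 && p[left - 1] > h) left <- left - 1
  right <- i
  while (right < length(p) && p[right + 1] > h) right <- right + 1
  xl <- if (left == 1) left else
    (left - 1) + (h - p[left - 1]) / (p[left] - p[left - 1])
  xr <- if (right == length(p)) right else
    right + (p[right] - h) / (p[right] - p[right + 1])
  xr - xl
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
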