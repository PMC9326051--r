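# Image-quality metrics (MSA, SNR, Bias), respiratory motion-fidelity
# traces and simple significance testing between simulation conditions.
#
# MSA is the ROI-mean activity averaged over evaluation times in the
# stabilisation window (the last minute by default); SNR divides the MSA
# by the spatial standard deviation over ROI voxels of the time-averaged
# activity; Bias is the percent deviation of the MSA from the ground-truth
# myocardial TAC mean over the same window.

msa_eval_times <- function(window, by = 5) seq(window[1], window[2], by = by)

# Time-averaged evaluated volume over the window (optionally post-filtered).
window_average_volume <- function(img, q, r, window, filter = TRUE,
                                  eval_by = 5) {
  ts <- msa_eval_times(window, eval_by)
  acc <- 0
  for (t in ts) {
    v <- evaluate_activity(img, q, r, t)
    if (filter) v <- postfilter(v, voxel_mm = img$voxel_mm)
    acc <- acc + v
  }
  acc / length(ts)
}

#' Mean stabilised activity (MSA)
#'
#' @param img A `gated_dynamic_image`.
#' @param roi_myo Logical ROI array.
#' @param q,r Gate indices (`NA` for a pooled image).
#' @param window Stabilisation window (s).
#' @param filter Apply the spatial post-filter before measuring?
#' @param eval_by Spacing (s) of evaluation times within the window.
#' @return MSA (reconstruction activity units).
#' @export
compute_msa <- function(img, roi_myo, q = img$gates$q[1], r = img$gates$r[1],
                        window = c(300, 360), filter = FALSE, eval_by = 5) {
  if (!any(roi_myo)) abort("empty ROI")
  v <- window_average_volume(img, q, r, window, filter, eval_by)
  mean(v[as.logical(roi_myo)])
}

#' Signal-to-noise ratio over the ROI
#'
#' MSA divided by the spatial standard deviation of the time-averaged
#' activity over ROI voxels. A zero-variance field returns `Inf` with a
#' `"flag"` attribute.
#'
#' @inheritParams compute_msa
#' @return SNR (dimensionless).
#' @export
compute_snr <- function(img, roi_myo, q = img$gates$q[1], r = img$gates$r[1],
                        window = c(300, 360), filter = FALSE, eval_by = 5) {
  if (!any(roi_myo)) abort("empty ROI")
  v <- window_average_volume(img, q, r, window, filter, eval_by)
  vals <- v[as.logical(roi_myo)]
  s <- sd(vals)
  if (s == 0) {
    out <- Inf
    attr(out, "flag") <- "zero spatial variance"
    return(out)
  }
  mean(vals) / s
}

#' Percent bias of the MSA against the ground truth
#'
#' `100 * (MSA - mean truth) / mean truth`, the truth being the generator
#' myocardial TAC averaged over the same window.
#'
#' @inheritParams compute_msa
#' @param truth Either a `tacset` (its `myocardium` column is used) or a
#'   numeric TAC sampled on `truth_times`.
#' @param truth_times Times (s) for a numeric `truth`.
#' @return Bias (percent).
#' @export
compute_bias <- function(img, truth, roi_myo,
                         q = img$gates$q[1], r = img$gates$r[1],
                         window = c(300, 360), filter = FALSE, eval_by = 5,
                         truth_times = NULL) {
  if (inherits(truth, "tacset")) {
    tt <- truth$time_s; tv <- truth$myocardium
  } else {
    if (is.null(truth_times)) abort("truth_times required for a numeric truth")
    tt <- truth_times; tv <- truth
  }
  ts <- msa_eval_times(window, eval_by)
  tm <- mean(stats::approx(tt, tv, xout = ts, rule = 2)$y)
  if (tm == 0) abort("zero truth mean")
  msa <- compute_msa(img, roi_myo, q, r, window, filter, eval_by)
  100 * (msa - tm) / tm
}

#' Respiratory displacement trace of the reconstructed LV
#'
#' Inferior-superior displacement of the reconstructed LV activity
#' centroid per respiratory gate, relative to end-exhale (r = 1). The
#' centroid is activity-weighted over voxels above a fractional threshold
#' of the gate's maximum, optionally restricted to a heart mask to
#' exclude the liver.
#'
#' @param img A `gated_dynamic_image` holding gates `(q, r)` for each
#'   requested `r`.
#' @param resp_gates Respiratory gates to trace.
#' @param q Cardiac gate held fixed.
#' @param t_eval Evaluation time (s).
#' @param threshold Fractional activity threshold for segmentation.
#' @param mask Optional logical array — or a list of arrays indexed by
#'   respiratory gate, e.g. from [gate_heart_masks()] — restricting the
#'   segmentation (the per-gate ground-truth heart region keeps the
#'   nearby liver out of the centroid).
#' @return A `displacement_trace` tibble: `resp_gate`,
#'   `displacement_mm` (relative to r = 1), `z_mm` (absolute centroid).
#' @export
displacement_trace <- function(img, resp_gates = 1:5, q = 1, t_eval = 330,
                               threshold = 0.5, mask = NULL) {
  zc <- vapply(resp_gates, function(r) {
    v <- evaluate_activity(img, q, r, t_eval)
    m <- if (is.list(mask)) mask[[as.character(r)]] %||% mask[[r]] else mask
    if (!is.null(m)) {
      # inside a ground-truth gate mask the activity-weighted centroid is
      # used directly: a max-based threshold would lock onto noise spikes
      v <- v * as.logical(m)
    } else {
      vm <- max(v)
      if (vm <= 0) abort("empty segmentation")
      v <- v * (v >= threshold * vm)
    }
    if (max(v) <= 0) abort("empty segmentation")
    w <- v
    d <- dim(v)
    zidx <- rep(seq_len(d[3]), each = d[1] * d[2])
    zbar <- sum(w * zidx) / sum(w)
    (zbar - (d[3] + 1) / 2) * img$voxel_mm
  }, numeric(1))
  out <- tibble(resp_gate = as.integer(resp_gates), z_mm = zc,
                displacement_mm = zc - zc[resp_gates == 1][1])
  class(out) <- c("displacement_trace", class(out))
  out
}

#' Heart masks from the ground-truth sequence
#'
#' `heart_mask()`: union of the myocardium and blood labels across all
#' states, dilated. `gate_heart_masks()`: one dilated heart mask per
#' respiratory gate at a fixed cardiac gate — the form
#' [displacement_trace()] expects, since a union mask would admit liver
#' activity at inhalation.
#'
#' @param states A `phantom_sequence`.
#' @param dilate Dilation passes.
#' @return Logical array (`heart_mask`) or a list of logical arrays
#'   indexed by respiratory gate (`gate_heart_masks`).
#' @export
heart_mask <- function(states, dilate = 2) {
  m <- array(FALSE, dim(states[[1]]$labels))
  for (st in states) {
    m <- m | st$labels == tissue_labels[["myocardium"]] |
      st$labels == tissue_labels[["blood"]]
  }
  dilate_mask(m, dilate)
}

#' @rdname heart_mask
#' @param q Cardiac gate of the per-gate masks.
#' @param resp_gates Respiratory gates to cover.
#' @export
gate_heart_masks <- function(states, q = 1, resp_gates = 1:5, dilate = 1) {
  cfg <- attr(states, "config")
  out <- lapply(resp_gates, function(r) {
    st <- states[[(r - 1L) * cfg$n_cardiac + q]]
    m <- st$labels == tissue_labels[["myocardium"]] |
      st$labels == tissue_labels[["blood"]]
    dilate_mask(m, dilate)
  })
  names(out) <- as.character(resp_gates)
  out
}

#' Two-tailed t-test between per-seed metric samples
#'
#' @param sample_a,sample_b Numeric vectors (at least 3 replicates each).
#' @return Two-sided p-value. Degenerate zero-variance pairs return 1 when
#'   the means agree and 0 otherwise.
#' @export
compare_msa_ttest <- function(sample_a, sample_b) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    abort("need at least 3 replicates per sample")
  }
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    return(as.numeric(isTRUE(all.equal(mean(sample_a), mean(sample_b)))))
  }
  t.test(sample_a, sample_b, var.equal = FALSE)$p.value
}

#' Per-gate metrics report
#'
#' Convenience wrapper computing MSA, SNR and bias for each reconstructed
#' gate of an image.
#'
#' @param img A `gated_dynamic_image`.
#' @param tacset The generating `tacset` (truth for the bias).
#' @param states The `phantom_sequence` (per-gate ground-truth ROIs,
#'   eroded by one voxel).
#' @param window Stabilisation window (s).
#' @param erode ROI erosion passes.
#' @return Tibble: `q`, `r`, `msa`, `snr`, `bias_percent`, `n_roi_voxels`.
#' @export
metrics_report <- function(img, tacset, states, window = c(300, 360),
                           erode = 1) {
  cfg <- attr(states, "config")
  purrr::pmap_dfr(img$gates, function(q, r, state_index) {
    roi <- roi_from_state(states[[state_index]], "myocardium", erode)
    tibble(
      q = q, r = r,
      msa = compute_msa(img, roi, q, r, window),
      snr = compute_snr(img, roi, q, r, window),
      bias_percent = compute_bias(img, tacset, roi, q, r, window),
      n_roi_voxels = sum(roi)
    )
  })
}
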