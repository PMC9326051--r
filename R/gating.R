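# Regroup continuously acquired frames into per-gate projection sets.
# Frames are atomic: the frame start time determines the gate, and the
# 0.125 s frame duration equals the gating sub-phase duration, so no frame
# straddles a gate boundary by construction.

gate_key <- function(q, r) sprintf("q%d_r%d", q, r)

#' Bin acquired frames by cardiac-respiratory gate
#'
#' Partitions the head-frames by their `(q, r)` gate tag. Counts are
#' preserved exactly (no reweighting); DEW-corrected counts are attached
#' per gate for reconstruction.
#'
#' @param frames An `acq_frames` object from [simulate_acquisition()].
#' @return A `gated_sinogram`: named list `gates` (key `"q{q}_r{r}"`), each
#'   holding `meta` (tibble of `frame_index`, `head`, `t_start`, `angle`),
#'   count arrays `main`, `scatter` and DEW-corrected `y`
#'   (nu x nv x n_views), plus a `views` summary tibble.
#' @export
bin_by_gate <- function(frames) {
  stopifnot(inherits(frames, "acq_frames"))
  meta <- frames$meta
  if (any(is.na(meta$q)) || any(is.na(meta$r))) abort("untagged frame")
  det <- frames$detector
  keys <- gate_key(meta$q, meta$r)
  idx_by_gate <- split(seq_len(nrow(meta)), keys)

  gates <- lapply(idx_by_gate, function(idx) {
    gmeta <- meta[idx, ]
    main <- frames$main[, , idx, drop = FALSE]
    scat <- frames$scatter[, , idx, drop = FALSE]
    y <- dew_correct(main * 1.0, scat * 1.0, det$dew_k)
    list(meta = gmeta, main = main, scatter = scat, y = y,
         q = gmeta$q[1], r = gmeta$r[1],
         clipped_frac = attr(y, "clipped_frac"))
  })

  views <- dplyr::count(meta, .data$q, .data$r, name = "n_views")
  structure(list(gates = gates, views = views, detector = det,
                 dt = frames$dt),
            class = "gated_sinogram")
}

#' Angular coverage of a gate
#'
#' Sorted unique head angles (deg, mod 360) seen by one gate across all
#' rotations and heads.
#'
#' @param gs A `gated_sinogram`.
#' @param q,r Gate indices.
#' @return Sorted numeric vector of angles.
#' @export
gate_angle_coverage <- function(gs, q, r) {
  g <- gs$gates[[gate_key(q, r)]]
  if (is.null(g)) abort("unknown gate")
  sort(unique(g$meta$angle %% 360))
}

#' @export
print.gated_sinogram <- function(x, ...) {
  cat("<gated_sinogram>", length(x$gates), "gates,",
      sum(x$views$n_views), "head-frames\n")
  invisible(x)
}
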