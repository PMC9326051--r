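# On-disk artifacts: NIfTI phantom states, CSV tables, JSON manifests and
# RDS containers for count frames and coefficient fields.

#' Write a phantom sequence as NIfTI volumes
#'
#' One pair of files per state (`state_<i>_labels.nii.gz`,
#' `state_<i>_mu.nii.gz`; the affine encodes the voxel size) plus a JSON
#' manifest mapping state indices to gates and filenames.
#'
#' @param states A `phantom_sequence`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_sequence_nifti <- function(states, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(seq_along(states), function(i) {
    st <- states[[i]]
    fl <- sprintf("state_%02d_labels.nii.gz", i)
    fm <- sprintf("state_%02d_mu.nii.gz", i)
    vx <- st$voxel_mm
    lab_im <- RNifti::asNifti(st$labels * 1.0)
    RNifti::pixdim(lab_im) <- c(vx, vx, vx)
    RNifti::writeNifti(lab_im, file.path(dir, fl))
    mu_im <- RNifti::asNifti(st$mu_map)
    RNifti::pixdim(mu_im) <- c(vx, vx, vx)
    RNifti::writeNifti(mu_im, file.path(dir, fm))
    list(state_index = i, cardiac_gate = st$cardiac_gate,
         resp_gate = st$resp_gate, labels = fl, mu = fm)
  })
  jsonlite::write_json(manifest, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write or read a TAC set as CSV
#'
#' Columns `time_s`, `myocardium`, `blood`, `liver`, `background`.
#'
#' @param tacset A `tacset` tibble.
#' @param path CSV path.
#' @return `write_tacset_csv()` returns the path invisibly;
#'   `read_tacset_csv()` a plain tibble.
#' @export
write_tacset_csv <- function(tacset, path) {
  readr::write_csv(as_tibble(tacset), path)
  invisible(path)
}

#' @rdname write_tacset_csv
#' @export
read_tacset_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Evaluate and export a reconstruction as 4D NIfTI
#'
#' Evaluates one gate of a dynamic image at a series of times and writes
#' an (x, y, z, t) NIfTI volume.
#'
#' @param img A `gated_dynamic_image`.
#' @param q,r Gate indices.
#' @param times Evaluation times (s).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_dynamic_nifti <- function(img, q, r, times, path) {
  vols <- lapply(times, function(t) evaluate_activity(img, q, r, t))
  arr <- array(unlist(vols), dim = c(img$dims, length(times)))
  vx <- img$voxel_mm
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- c(vx, vx, vx, 1)
  RNifti::writeNifti(im, path)
  invisible(path)
}

# Stage outputs of a case run.
write_case_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tacset_csv(run$tacset, file.path(dir, "tacs.csv"))
  readr::write_csv(run$metrics, file.path(dir, "metrics.csv"))
  if (!is.null(run$fits)) {
    readr::write_csv(run$fits, file.path(dir, "kinetic_fits.csv"))
  }
  if (!is.null(run$trace)) {
    readr::write_csv(as_tibble(run$trace), file.path(dir, "trace.csv"))
  }
  saveRDS(run$image %||% run$image_stabilized, file.path(dir, "recon.rds"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [case_config()] (`case`,
#' `grid`, `seed`, `n_iter`, `recon_gates` as a list of `{q, r}` pairs,
#' `knot_times`, `out_dir`).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    case = y$case %||% 1, grid = y$grid %||% "desk",
    seed = y$seed %||% 1L, n_iter = y$n_iter %||% 30,
    knot_times = y$knot_times, out_dir = y$out_dir
  )
  if (!is.null(y$recon_gates)) {
    args$recon_gates <- dplyr::bind_rows(lapply(y$recon_gates, as_tibble))
  }
  do.call(case_config, args)
}
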