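# Configuration-driven end-to-end orchestration:
# phantom -> TACs -> acquisition -> gating -> reconstruction -> fitting
# -> metrics, with reproducible seeds and optional stage outputs on disk.

#' Build a run configuration for a simulation case
#'
#' @param case Simulation case 1..5 (sets the TBR, the LV wall mode and
#'   the diaphragm amplitude).
#' @param grid `"desk"` (90 x 60 x 55 at 4.4 mm) or `"full"`.
#' @param seed Integer seed for the acquisition noise.
#' @param n_iter MLEM iterations. The default 150 places quantitative runs
#'   in the converged regime of the myocardial activity recovery (see the
#'   methods vignette); exploratory runs can use fewer.
#' @param recon_gates Tibble (`q`, `r`) of gates to reconstruct; default
#'   diastole (q = 1) and systole (q = 3, the gate containing the
#'   end-systolic time) at end-exhale.
#' @param knot_times Interior B-spline knots (s); `NULL` for the default.
#' @param detector A [detector_model()].
#' @param out_dir Optional output directory for stage artifacts.
#' @param keep_frames Keep the raw frames in the returned object?
#' @param fit_kinetics Fit the 1TCM to the reconstructed gates?
#' @param phantom Optional [phantom_config()] overriding the case default
#'   (the case still sets the TACs).
#' @return A `run_config` list.
#' @export
case_config <- function(case = 1, grid = c("desk", "full"), seed = 1L,
                        n_iter = 150,
                        recon_gates = tibble(q = c(1L, 3L), r = c(1L, 1L)),
                        knot_times = NULL,
                        detector = detector_model(),
                        out_dir = NULL, keep_frames = FALSE,
                        fit_kinetics = TRUE, phantom = NULL) {
  grid <- match.arg(grid)
  row <- tac_case_table()
  row <- row[row$case == case, ]
  if (!nrow(row)) abort("case must be one of 1..5")
  pcfg <- phantom %||% phantom_config(grid = grid,
                                      wall_mode = row$wall_mode,
                                      diaphragm_amp_cm = row$diaphragm_cm)
  structure(list(
    case = case, grid = grid, seed = as.integer(seed), n_iter = n_iter,
    recon_gates = as_tibble(recon_gates),
    knot_times = knot_times, detector = detector,
    phantom = pcfg, out_dir = out_dir, keep_frames = keep_frames,
    fit_kinetics = fit_kinetics
  ), class = "run_config")
}

systole_diastole_label <- function(q, cfg) {
  n <- cfg$n_cardiac
  q_es <- floor(cfg$ed_to_es / (cfg$cardiac_period / n)) + 1
  if (q == 1) "diastole" else if (q == q_es) "systole" else paste0("gate", q)
}

#' Run a full simulation-reconstruction-analysis case
#'
#' Executes every stage for one configuration: phantom sequence, TAC set,
#' continuous-acquisition simulation, gating, gated spatiotemporal MLEM,
#' 1TCM fitting of the reconstructed TACs and the image-quality metrics.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A [case_config()].
#' @param cache Optional projection cache shared across runs (the expected
#'   tissue projections do not depend on the seed or the TAC case as long
#'   as the phantom geometry is unchanged).
#' @param quiet Suppress progress messages?
#' @return A `case_run` list: `states`, `tacset`, the sinogram views
#'   table, the stabilized-window reconstruction (`image_stabilized`,
#'   driving `metrics` and `trace`), the full-scan spline reconstruction
#'   (`image`, driving `fits`; `NULL` when `fit_kinetics = FALSE`), and a
#'   `manifest`. The `trace` is present when every respiratory gate was
#'   reconstructed.
#' @export
run_case <- function(config, cache = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  say("phantom: generating ", config$phantom$n_cardiac *
        config$phantom$n_resp, " states")
  states <- generate_sequence(config$phantom)

  say("tacs: case ", config$case)
  tacset <- assemble_tacset(config$case,
                            volumes_ml = tissue_volumes_ml(config$phantom))

  schedule <- build_schedule(cardiac_period = config$phantom$cardiac_period,
                             resp_period = config$phantom$resp_period,
                             n_cardiac = config$phantom$n_cardiac,
                             n_resp = config$phantom$n_resp)
  say("acquire: ", nrow(schedule), " frames, seed ", config$seed)
  acqf <- simulate_acquisition(states, tacset, schedule, config$detector,
                               seed = config$seed, cache = cache)
  gs <- bin_by_gate(acqf)

  say("reconstruct: ", nrow(config$recon_gates), " gates, ",
      config$n_iter, " iterations")
  # stabilized-window reconstruction: the image-quality metrics and the
  # motion trace are read from the last minute of data (static over the
  # window); the full-scan spline reconstruction drives the kinetics
  img_stab <- recon_stabilized(gs, states, config$detector,
                               n_iter = config$n_iter,
                               gates = config$recon_gates)
  metrics <- metrics_report(img_stab, tacset, states)

  img <- NULL
  fits <- NULL
  if (isTRUE(config$fit_kinetics)) {
    basis <- build_bspline_basis(config$knot_times, schedule$t_start)
    img <- mlem_spatiotemporal(gs, states, basis, n_iter = config$n_iter,
                               detector = config$detector,
                               gates = config$recon_gates)
    say("fit: 1TCM per gate")
    fits <- purrr::pmap_dfr(img$gates, function(q, r, state_index) {
      st <- states[[state_index]]
      tac <- extract_tacs(img,
                          roi_from_state(st, "myocardium", 1),
                          roi_from_state(st, "blood", 1),
                          gates = tibble(q = q, r = r))
      f <- fit_1tcm(tac$myocardium, tac$blood, tac$time_s,
                    gate = systole_diastole_label(q, config$phantom))
      dplyr::mutate(glance(f), case = config$case, q = q, r = r,
                    .before = 1)
    })
  }

  trace <- NULL
  rg <- sort(unique(config$recon_gates$r))
  if (identical(rg, seq_len(config$phantom$n_resp))) {
    qs <- config$recon_gates$q[config$recon_gates$r == 1][1]
    trace <- displacement_trace(img_stab, resp_gates = rg, q = qs,
                                mask = gate_heart_masks(states, qs, rg))
  }

  manifest <- list(
    case = config$case, grid = config$grid, seed = config$seed,
    n_iter = config$n_iter,
    recon_gates = as.data.frame(config$recon_gates),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_frames = nrow(acqf$meta),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  out <- list(states = states, tacset = tacset, sinogram_views = gs$views,
              image = img, image_stabilized = img_stab,
              metrics = metrics, fits = fits, trace = trace,
              manifest = manifest)
  if (config$keep_frames) out$frames <- acqf

  if (!is.null(config$out_dir)) write_case_run(out, config$out_dir)
  structure(out, class = "case_run")
}

#' @export
print.case_run <- function(x, ...) {
  cat("<case_run> case", x$manifest$case, "seed", x$manifest$seed, "\n")
  print(x$metrics)
  invisible(x)
}
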