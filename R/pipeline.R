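## End-to-end pipeline: simulate (or load) -> orientation -> TACF -> decay
## fits -> heterogeneity, driven by a single YAML config, with every
## default filled in and echoed so that reports are reproducible from the
## config + seed alone. Reports deliberately contain no timestamps: the
## same config and seed must produce byte-identical output.

pipeline_defaults <- list(
  tacf = list(origin_stride = 1L, max_lag_fraction = 0.5),
  fit = list(max_modes = 6L, modes = "auto", n_points = 200L,
             noise_floor = 0, seed = 20200330L))

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or takes an equivalent named list), checks the
#' full schema, fills documented defaults, and either returns the
#' normalized config or raises one error listing every problem found.
#'
#' Top-level keys: `seed` (required integer), `label`, `output_dir`,
#' exactly one of `synthetic` (a mixture or rotational-diffusion spec) or
#' `trajectory` (`xyz` + `system` file paths and `vector_kind`), and
#' optional `tacf`, `fit`, `heterogeneity` sections. Unknown keys are
#' errors, not warnings. Input coordinates must already be unwrapped
#' (continuous molecule images); the pipeline performs no periodic-image
#' reconstruction.
#'
#' @param config path to a YAML file, or a named list.
#' @return A normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_ringhet("config file not found: ", config,
                   class = "ringhet_config_error")
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))
  known <- c("seed", "label", "output_dir", "synthetic", "trajectory",
             "tacf", "fit", "heterogeneity")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    note("unknown top-level key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed) || !is_scalar_number(config$seed))
    note("'seed' is required and must be an integer")
  has_syn <- !is.null(config$synthetic)
  has_trj <- !is.null(config$trajectory)
  if (has_syn == has_trj)
    note("exactly one of 'synthetic' or 'trajectory' must be given")
  if (has_syn) {
    s <- config$synthetic
    kind <- s$kind %||% "mixture"
    if (!kind %in% c("mixture", "rotdiff"))
      note("synthetic.kind must be 'mixture' or 'rotdiff'")
    for (f in c("n_molecules", "dt_ns", "n_frames")) {
      v <- s[[f]]
      if (!is_scalar_number(v %||% NA_real_) || v <= 0)
        note("synthetic.", f, " must be a positive number")
    }
    if (kind == "mixture" && is.null(s$populations))
      note("synthetic.populations is required for a mixture")
    if (kind == "rotdiff" &&
        (!is_scalar_number(s$D_r %||% NA_real_) || s$D_r <= 0))
      note("synthetic.D_r must be a positive number")
  }
  if (has_trj) {
    tr <- config$trajectory
    for (f in c("xyz", "system")) {
      if (!is_scalar_string(tr[[f]] %||% NA_character_))
        note("trajectory.", f, " must be a file path")
      else if (!file.exists(tr[[f]]))
        note("trajectory.", f, " does not exist: ", tr[[f]])
    }
    vk <- tr$vector_kind %||% "auto"
    if (!vk %in% c("auto", "end_to_end", "diameter"))
      note("trajectory.vector_kind must be auto, end_to_end or diameter")
  }
  tacf <- utils::modifyList(pipeline_defaults$tacf, config$tacf %||% list())
  if (tacf$max_lag_fraction <= 0 || tacf$max_lag_fraction > 1)
    note("tacf.max_lag_fraction must lie in (0, 1]")
  if (tacf$origin_stride < 1)
    note("tacf.origin_stride must be >= 1")
  fit <- utils::modifyList(pipeline_defaults$fit, config$fit %||% list())
  if (!identical(fit$modes, "auto") &&
      (!is_scalar_number(fit$modes) || fit$modes < 1))
    note("fit.modes must be 'auto' or a positive integer")
  ## assembled by hand (not modifyList) so an explicit null reference time
  ## survives normalization unchanged
  het_in <- config$heterogeneity %||% list()
  het <- list(bin_width = het_in$bin_width %||% 0.1,
              thresholds = het_in$thresholds %||% c(1, 2),
              reference_time_ns = het_in$reference_time_ns)
  if (het$bin_width <= 0) note("heterogeneity.bin_width must be positive")
  if (!is.null(het$reference_time_ns) &&
      (!is_scalar_number(het$reference_time_ns) || het$reference_time_ns <= 0))
    note("heterogeneity.reference_time_ns must be positive when given")
  if (length(errs))
    stop(errorCondition(paste0("invalid pipeline config:\n  - ",
                               paste(errs, collapse = "\n  - ")),
                        errors = errs,
                        class = c("ringhet_config_error", "ringhet_error")))
  structure(list(seed = as.integer(config$seed),
                 label = config$label %||% "",
                 output_dir = config$output_dir,
                 synthetic = config$synthetic,
                 trajectory = config$trajectory,
                 tacf = tacf, fit = fit, heterogeneity = het),
            class = "pipeline_config")
}

pipeline_series <- function(config) {
  if (!is.null(config$synthetic)) {
    s <- config$synthetic
    if ((s$kind %||% "mixture") == "rotdiff") {
      spec <- rotdiff_spec(s$n_molecules, s$D_r, s$dt_ns, s$n_frames,
                           seed = config$seed)
      list(series = generate_rotational_diffusion(spec), ground_truth = NULL)
    } else {
      pops <- lapply(s$populations, function(p)
        list(weight = p$weight, kind = p$kind %||% "exponential",
             tau_ns = p$tau_ns, beta = p$beta))
      spec <- mixture_spec(pops, s$n_molecules, s$dt_ns, s$n_frames,
                           seed = config$seed)
      generate_mixture_ensemble(spec)
    }
  } else {
    sys <- read_system_spec(config$trajectory$system)
    traj <- read_xyz_trajectory(config$trajectory$xyz, sys)
    vk <- config$trajectory$vector_kind %||% "auto"
    series <- lapply(seq_len(nrow(sys$molecules)), function(i) {
      id <- sys$molecules$molecule_id[i]
      kind <- sys$molecules$kind[i]
      use <- if (vk == "auto") {
        if (kind == "ring") "diameter" else "end_to_end"
      } else vk
      if (use == "diameter") diameter_series(traj, id)
      else end_to_end_series(traj, id)
    })
    list(series = series, ground_truth = NULL)
  }
}

#' Run the full relaxation-heterogeneity pipeline
#'
#' Executes simulate/load -> per-molecule TACFs -> ensemble TACF -> KWW
#' and multi-exponential fits -> per-molecule terminal times ->
#' heterogeneity statistics, writing per-stage CSV/JSON artifacts under
#' `output_dir` (when set) and returning a machine-readable report. A
#' stage failure is recorded in the report (with the error message) and
#' downstream stages are skipped; the function itself does not throw for
#' stage errors. Given the same config and seed the report is
#' byte-identical across runs.
#'
#' When `heterogeneity.reference_time_ns` is null, the reference time is
#' this run's own ensemble KWW terminal time (self-normalization), the
#' convention used to compare blends against a pure-melt reference
#' computed in a separate run.
#'
#' @param config a [validate_config()] result, a named list, or a YAML
#'   file path.
#' @param quiet suppress stage progress messages on stderr.
#' @return A report list of class `pipeline_report` (also written as
#'   `report.json` under `output_dir` when set).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) message("[ringhet] ", ...)
  report <- list(label = config$label, seed = config$seed,
                 config = unclass(config), stages = list(), results = list())
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  failed <- FALSE
  stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    say("stage ", name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
      say("stage ", name, " FAILED: ", conditionMessage(res))
      return(NULL)
    }
    report$stages[[name]] <<- list(status = "ok")
    res
  }

  inputs <- stage("input", function() pipeline_series(config))
  curves <- stage("tacf", function() {
    lapply(inputs$series, molecule_tacf,
           origin_stride = config$tacf$origin_stride,
           max_lag_fraction = config$tacf$max_lag_fraction)
  })
  ens_curve <- stage("ensemble_tacf", function() ensemble_tacf(curves))
  fits <- stage("fit", function() {
    kctl <- kww_control(noise_floor = config$fit$noise_floor,
                        n_points = config$fit$n_points,
                        seed = config$fit$seed)
    mctl <- multiexp_control(n_points = config$fit$n_points,
                             max_modes = config$fit$max_modes,
                             seed = config$fit$seed)
    kww <- fit_kww(ens_curve, kctl)
    mex <- if (identical(config$fit$modes, "auto")) {
      sel <- select_num_modes(ens_curve, config$fit$max_modes, mctl)
      sel$fit
    } else fit_multiexp(ens_curve, as.integer(config$fit$modes), mctl)
    list(kww = kww, multiexp = mex)
  })
  het <- stage("heterogeneity", function() {
    relax <- lapply(curves, tau0_numeric)
    ref <- config$heterogeneity$reference_time_ns %||% fits$kww$tau0
    ens <- build_ensemble(relax, ref, label = config$label)
    ths <- config$heterogeneity$thresholds
    list(ensemble = ens,
         median = ensemble_median(ens),
         tails = stats::setNames(
           vapply(ths, function(th) tail_fraction(ens, th), 0),
           paste0("gt_", ths)),
         histogram = relaxation_histogram(
           ens, bin_width = config$heterogeneity$bin_width))
  })

  if (!failed) {
    report$results <- list(
      n_molecules = length(inputs$series),
      kww = list(tau_kww_ns = fits$kww$tau_kww, beta = fits$kww$beta,
                 tau0_ns = fits$kww$tau0,
                 rms_residual = fits$kww$rms_residual,
                 converged = fits$kww$converged),
      multiexp = list(n_m = fits$multiexp$n_m,
                      tau_ns = fits$multiexp$modes$tau_ns,
                      amplitude = fits$multiexp$modes$amplitude,
                      rms_residual = fits$multiexp$rms_residual,
                      converged = fits$multiexp$converged),
      heterogeneity = list(reference_time_ns = het$ensemble$reference_time,
                           median = het$median,
                           tail_fractions = as.list(het$tails),
                           histogram = het$histogram))
    if (!is.null(out_dir)) {
      utils::write.csv(as.data.frame(ens_curve),
                       file.path(out_dir, "ensemble_tacf.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(het$ensemble),
                       file.path(out_dir, "molecules.csv"),
                       row.names = FALSE)
      if (!is.null(inputs$ground_truth))
        utils::write.csv(inputs$ground_truth,
                         file.path(out_dir, "ground_truth.csv"),
                         row.names = FALSE)
    }
  }
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report", if (nzchar(x$label)) paste0(" '", x$label, "'"),
      " (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages))
    cat("  ", nm, ": ", x$stages[[nm]]$status,
        if (!is.null(x$stages[[nm]]$error)) paste0(" - ", x$stages[[nm]]$error),
        "\n", sep = "")
  if (length(x$results)) {
    k <- x$results$kww
    cat(sprintf("  ensemble KWW: tau_KWW = %.4g ns, beta = %.3f, tau0 = %.4g ns\n",
                k$tau_kww_ns, k$beta, k$tau0_ns))
    m <- x$results$multiexp
    cat(sprintf("  multi-exp: n_m = %d, taus = %s ns\n", m$n_m,
                paste(signif(m$tau_ns, 3), collapse = ", ")))
    h <- x$results$heterogeneity
    cat(sprintf("  heterogeneity: median = %.3f, tail(>1) = %.1f%%\n",
                h$median, 100 * h$tail_fractions[[1]]))
  }
  invisible(x)
}
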