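#' Read a 3-column scattering curve file
#'
#' Whitespace-delimited (q, I, sigma) text with '#'-prefixed header
#' lines; 2-column theoretical curves are accepted (sigma absent).
#'
#' @param path File path.
#' @param radiation "xray" or "neutron" (stored on the curve).
#' @return `sas_curve`.
#' @export
read_dat <- function(path, radiation = "xray") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  vals <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (length(v) < 2 || any(is.na(v)))
      stop("malformed curve line ", i, ": '", lines[i], "'")
    v
  })
  ncols <- min(vapply(vals, length, integer(1)))
  m <- t(vapply(vals, function(v) v[seq_len(min(ncols, 3))], numeric(min(ncols, 3))))
  sigma <- if (ncol(m) >= 3) m[, 3] else NULL
  if (!is.null(sigma) && any(sigma <= 0))
    stop("non-positive sigma values in ", path)
  sas_curve(m[, 1], m[, 2], sigma, radiation = radiation,
            meta = list(source = path))
}

#' Write a scattering curve as 3-column text
#'
#' @param curve `sas_curve`.
#' @param path Output path.
#' @param label Header comment.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path, label = "sasflex curve") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", label), con)
  writeLines(sprintf("# %d points, radiation = %s", length(curve$q),
                     curve$radiation), con)
  if (is.null(curve$sigma)) {
    writeLines(sprintf("%.8e %.8e", curve$q, curve$I), con)
  } else {
    writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$I, curve$sigma), con)
  }
  invisible(path)
}

#' Write a GNOM-style P(r) report
#'
#' Plain-text block with the q / I_exp / I_fit table followed by the
#' r / P(r) table, plus a machine-readable JSON sidecar.
#'
#' @param pr `sas_pr`.
#' @param curve The fitted `sas_curve`.
#' @param path Output path (`.json` sidecar written alongside).
#' @return `path`, invisibly.
#' @export
write_pr_report <- function(pr, curve, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# P(r) by regularized IFT: dmax = %.2f A, alpha = %.4g, chi2 = %.4g",
                       pr$dmax, pr$alpha, pr$chi2),
               "# q I_exp I_fit"), con)
  writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$I, pr$fit$I), con)
  writeLines("# r P(r)", con)
  writeLines(sprintf("%.6f %.8e", pr$r, pr$pr), con)
  close(con)
  m <- pr_moments(pr)
  jsonlite::write_json(list(dmax = pr$dmax, alpha = pr$alpha, chi2 = pr$chi2,
                            rg = m$rg, i0 = m$i0, r = pr$r, pr = pr$pr),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' End-to-end pipeline over a run configuration
#'
#' Executes the full analysis chain on synthetic or file inputs:
#' generate/load and orient the model, attach the detergent belt,
#' compute forward curves, run Guinier / P(r) / Kratky analysis, and
#' (optionally) ensemble and mixture fits. Deterministic given the
#' configuration; writes a JSON report plus the resolved configuration
#' next to the results.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `outdir`; optional `seed`; optional `data` (path to a .dat curve);
#'   `solvent` (list: nacl_M, d2o_fraction); `radiation`; `model`
#'   (toy_model_spec arguments); `belt` (belt_spec arguments or NULL);
#'   `guinier` (qrg_max); `pr` (dmax, alpha); `ensemble` (list: run,
#'    rms_deg, n_conformers, angle_step); `mixture` (list: run,
#'    trimer_fraction, radial_offset).
#' @return Report list (also written as `report.json` in `outdir`).
#' @export
sas_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(outdir = tempfile("sasflex_run_"), seed = 1,
                   radiation = "xray",
                   solvent = list(nacl_M = 0.15, d2o_fraction = 0),
                   model = list(), belt = NULL,
                   guinier = list(qrg_max = 1.3),
                   pr = list(dmax = NULL, alpha = "auto"),
                   ensemble = list(run = FALSE, rms_deg = 55,
                                   n_conformers = 2000, angle_step = 30),
                   mixture = list(run = FALSE, trimer_fraction = 0.36,
                                  radial_offset = 40))
  cfg <- modifyList(defaults, config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  solvent <- stage("solvent",
                   solvent_model(cfg$solvent$nacl_M, cfg$solvent$d2o_fraction))
  dimer <- stage("model", {
    spec <- do.call(toy_model_spec, c(cfg$model, list(seed = cfg$seed)))
    make_toy_dimer(spec)
  })
  if (!is.null(cfg$belt)) {
    dimer_b <- stage("belt", build_belt(dimer, do.call(belt_spec, cfg$belt)))
  } else dimer_b <- dimer
  curve <- if (!is.null(cfg$data)) {
    stage("load", read_dat(cfg$data, radiation = cfg$radiation))
  } else {
    stage("simulate",
          simulate_curve(dimer_b, solvent, cfg$radiation,
                         noise = noise_spec(seed = cfg$seed)))
  }
  write_dat(curve, file.path(cfg$outdir, "curve.dat"))
  gu <- stage("guinier", guinier_fit(curve, qrg_max = cfg$guinier$qrg_max))
  dmax <- cfg$pr$dmax
  if (is.null(dmax)) dmax <- 3.5 * gu$rg
  pr <- stage("pr", ift_pr(curve, dmax = dmax, alpha = cfg$pr$alpha))
  mom <- pr_moments(pr)
  kr <- stage("kratky", kratky_dimensionless(curve, gu$rg, gu$i0))
  report$stages$guinier <- list(rg = gu$rg, i0 = gu$i0, qrg = gu$qrg)
  report$stages$pr <- list(dmax = dmax, alpha = pr$alpha, chi2 = pr$chi2,
                           rg = mom$rg, i0 = mom$i0,
                           peaks = pr_peaks(pr))
  report$stages$kratky <- list(peak_qrg = kr$qrg[which.max(kr$kratky)])
  write_pr_report(pr, curve, file.path(cfg$outdir, "pr.txt"))
  if (isTRUE(cfg$ensemble$run)) {
    ens <- stage("ensemble", {
      grid <- seq(-90, 90, by = cfg$ensemble$angle_step)
      ds <- make_ensemble_dataset(dimer, rms_deg = cfg$ensemble$rms_deg,
                                  n_conformers = cfg$ensemble$n_conformers,
                                  noise = noise_spec(seed = cfg$seed),
                                  seed = cfg$seed,
                                  angle_grid = grid, solvent = solvent,
                                  radiation = cfg$radiation)
      fit <- tikhonov_nnls(ds$basis, ds$curve)
      list(truth_rms = ds$rms_truth, fitted_rms = fit$rms_angles,
           chi2 = fit$chi2, alpha = fit$alpha)
    })
    report$stages$ensemble <- ens
  }
  if (isTRUE(cfg$mixture$run)) {
    mx <- stage("mixture", {
      trimer <- assemble_c3(dimer, cfg$mixture$radial_offset, "tripod")
      ds <- make_mixture_dataset(dimer_b,
                                 if (!is.null(cfg$belt))
                                   build_belt(trimer, do.call(belt_spec, cfg$belt))
                                 else trimer,
                                 trimer_fraction = cfg$mixture$trimer_fraction,
                                 noise = noise_spec(seed = cfg$seed),
                                 solvent = solvent, radiation = cfg$radiation)
      fit <- mixture_fractions(ds$components, ds$curve)
      list(truth = ds$truth, fractions = as.list(fit$fractions),
           se = as.list(fit$se), chi2 = fit$chi2)
    })
    report$stages$mixture <- mx
  }
  report$versions <- list(sasflex = as.character(utils::packageVersion("sasflex")),
                          R = R.version.string)
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config.yaml"))
  invisible(report)
}
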