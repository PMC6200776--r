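plate_columns <- function() {
  c("experiment_id", "mode", "well_id", "well_type", "probe_conc_nM",
    "competitor_conc_nM", "time_min", "donor_em", "acceptor_em",
    "bret_ratio")
}

#' Read a long-format plate table from CSV
#'
#' The dialect is one row per well (or well-read, for kinetic plates) with
#' columns `experiment_id, mode, well_id, well_type, probe_conc_nM,
#' competitor_conc_nM, time_min, donor_em, acceptor_em, bret_ratio`.
#' Inapplicable fields are empty; concentrations are nM at the file
#' boundary; times are minutes. A file may carry either raw emission
#' channels, precomputed ratios, or both (the ratio can be filled
#' downstream with [compute_bret_ratio()]).
#'
#' @param path Path to a CSV file conforming to the dialect.
#' @return A validated plate table `data.frame`.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(plate_columns(), names(tab))
  if (length(missing_cols) > 0L)
    stop(sprintf("plate CSV is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tab <- tab[, plate_columns()]
  for (col in c("experiment_id", "mode", "well_id", "well_type"))
    tab[[col]] <- as.character(tab[[col]])
  for (col in c("probe_conc_nM", "competitor_conc_nM", "time_min",
                "donor_em", "acceptor_em", "bret_ratio"))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  bad_mode <- !tab$mode %in% plate_modes()
  if (any(bad_mode)) {
    off <- unique(tab$mode[bad_mode])
    hint <- if ("kinetic" %in% off) " (did you mean 'association'?)" else ""
    stop(sprintf("invalid mode value(s) %s at row(s) %s%s",
                 paste(sQuote(off), collapse = ", "),
                 paste(utils::head(which(bad_mode), 5), collapse = ", "),
                 hint), call. = FALSE)
  }
  bad_type <- !tab$well_type %in% c("total", "nsb", "vehicle")
  if (any(bad_type))
    stop(sprintf("invalid well_type at row(s): %s",
                 paste(utils::head(which(bad_type), 5), collapse = ", ")),
         call. = FALSE)
  bad_conc <- is.na(tab$probe_conc_nM) | tab$probe_conc_nM < 0
  if (any(bad_conc))
    stop(sprintf("missing or negative probe_conc_nM at row(s): %s",
                 paste(utils::head(which(bad_conc), 5), collapse = ", ")),
         call. = FALSE)
  tab
}

#' Write a plate table to CSV
#'
#' Writes the dialect described in [read_plate_csv()] with a deterministic
#' column and row order (experiment, well type, concentrations, time), so
#' repeated writes of the same table are byte-identical. Numeric values are
#' written with 15 significant digits; inapplicable fields are empty cells.
#'
#' @param table A plate table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_plate_csv <- function(table, path) {
  missing_cols <- setdiff(plate_columns(), names(table))
  if (length(missing_cols) > 0L)
    stop(sprintf("table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tab <- table[, plate_columns()]
  key_i <- ifelse(is.na(tab$competitor_conc_nM), 0, tab$competitor_conc_nM)
  key_t <- ifelse(is.na(tab$time_min), 0, tab$time_min)
  tab <- tab[order(tab$experiment_id, tab$well_type, tab$probe_conc_nM,
                   key_i, key_t, tab$well_id), ]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x)
    ifelse(is.na(x), "", formatC(x, digits = 15, format = "g")))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full simulate-and-fit pipeline from a configuration
#'
#' A config is a list (or path to a JSON file) with fields:
#' * `mode` — assay mode;
#' * `simulate` — optional list of [simulation_design()] arguments other
#'   than `mode`/`ground_truth`, plus a `ground_truth` block (see Details);
#' * `input` — path to a plate CSV (required when `simulate` is absent);
#' * `probe_kd_nM` — required for competition fits;
#' * `free_hill` — optional flag for competition/concentration-response;
#' * `output_dir` — where the results bundle is written (optional).
#'
#' Stages run in order: simulate (optional), ratio computation, baseline
#' correction (association mode), the mode-appropriate fit, aggregation.
#' Each stage is logged; a failure aborts with the failing stage named.
#' The JSON bundle includes a provenance block (config hash, seed, package
#' and R versions) sufficient to reproduce the run.
#'
#' In a JSON config the `ground_truth` block uses plain numbers in nM and
#' per-minute units: for saturation `{kd_nM, bmax, ns_slope_per_nM,
#' baseline}`; for association `{kon_per_M_min, koff_per_min, bmax,
#' baseline}`; for competition `{probe: {...saturation fields...}, ki_nM}`;
#' for concentration_response `{ec50_nM, emax, basal}`.
#'
#' @param config A list or path to a JSON config file.
#' @return A list with elements `table`, `fit`, and `provenance`, invisibly
#'   written to `output_dir` when given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  known <- c("mode", "simulate", "input", "probe_kd_nM", "free_hill",
             "output_dir", "verbose")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(config$mode) || !config$mode %in% plate_modes())
    stop("config must set 'mode' to a valid assay mode", call. = FALSE)
  verbose <- !isFALSE(config$verbose)
  log_stage <- function(...) if (verbose) message("[bretfit] ", sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  table <- if (!is.null(config$simulate)) {
    stage("simulate", {
      args <- config$simulate
      args$ground_truth <- parse_ground_truth(config$mode, args$ground_truth)
      args$mode <- config$mode
      design <- do.call(simulation_design, args)
      log_stage("simulate: mode=%s seed=%d n_experiments=%d noise_sd=%g",
                design$mode, design$seed, design$n_experiments,
                design$noise_sd)
      simulate_plate(design)
    })
  } else if (!is.null(config$input)) {
    stage("read", {
      log_stage("read: %s", config$input)
      read_plate_csv(config$input)
    })
  } else stop("config needs either a 'simulate' block or an 'input' path",
              call. = FALSE)

  table <- stage("ratio", compute_bret_ratio(table))
  if (config$mode == "association")
    table <- stage("baseline", baseline_correct(table))

  fit <- stage("fit", switch(config$mode,
    saturation = fit_saturation(table),
    association = fit_association_global(table),
    competition = {
      if (is.null(config$probe_kd_nM))
        stop("competition fits require 'probe_kd_nM'", call. = FALSE)
      fit_competition(table, config$probe_kd_nM,
                      free_hill = isTRUE(config$free_hill))
    },
    concentration_response =
      fit_concentration_response(table,
                                 free_hill = isTRUE(config$free_hill))))
  log_stage("fit: mode=%s done", config$mode)

  provenance <- list(
    config_md5 = unname(config_hash(config)),
    seed = config$simulate$seed,
    package_version = as.character(utils::packageVersion("bretfit")),
    r_version = R.version.string)

  result <- list(table = table, fit = fit, provenance = provenance)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_plate_csv(table, file.path(config$output_dir, "plate.csv"))
    jsonlite::write_json(summarize_fit(fit, provenance),
                         file.path(config$output_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    log_stage("wrote results to %s", config$output_dir)
  }
  invisible(result)
}

parse_ground_truth <- function(mode, gt) {
  if (is.null(gt)) stop("simulate block needs a 'ground_truth'",
                        call. = FALSE)
  # already-constructed parameter objects pass through (programmatic use)
  if (inherits(gt, c("eq_binding_params", "cr_params")) ||
      (is.list(gt) && (inherits(gt$rates, "kinetic_rates") ||
                       inherits(gt$probe, "eq_binding_params"))))
    return(gt)
  eq_from <- function(g)
    eq_binding_params(kd = g$kd_nM * 1e-9, bmax = g$bmax,
                      ns_slope = null_default(g$ns_slope_per_nM, 0) * 1e9,
                      baseline = null_default(g$baseline, 0))
  switch(mode,
    saturation = eq_from(gt),
    association = list(rates = kinetic_rates(gt$kon_per_M_min,
                                             gt$koff_per_min),
                       bmax = gt$bmax,
                       baseline = null_default(gt$baseline, 0)),
    competition = list(probe = eq_from(gt$probe), ki = gt$ki_nM * 1e-9),
    concentration_response = cr_params(ec50 = gt$ec50_nM * 1e-9,
                                       emax = gt$emax,
                                       basal = null_default(gt$basal, 0)))
}

null_default <- function(x, default) if (is.null(x)) default else x

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  tools::md5sum(tf)
}

summarize_fit <- function(fit, provenance) {
  body <- if (inherits(fit, "bret_aggregate")) {
    list(kind = "aggregate", n_experiments = fit$n,
         mean = as.list(fit$mean), sem = as.list(fit$sem),
         per_experiment = lapply(fit$per_experiment, function(f)
           list(experiment_id = f$experiment_id, converged = f$converged,
                residual_sd = f$residual_sd, n_points = f$n_points,
                parameters = as.list(f$parameters),
                standard_errors = as.list(f$standard_errors))))
  } else if (inherits(fit, "competition_result")) {
    list(kind = "competition", pooled_pki = fit$pooled_pki,
         pki_sem = fit$pki_sem, n_experiments = fit$n_experiments,
         probe_kd_nM = fit$probe_kd_nM, per_experiment_pki = as.list(fit$pki),
         regression = fit$regression,
         per_curve = fit$per_experiment)
  } else list(kind = class(fit)[1])
  c(body, list(provenance = provenance))
}
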