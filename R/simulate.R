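#' Specify a simulated plate experiment
#'
#' A `simulation_design` captures everything needed to generate a synthetic
#' plate table for one of the four assay modes: the ground-truth binding
#' parameters, the concentration/time sampling scheme, the replication
#' structure, the noise level on the ratio scale, and the seed. Concentrations
#' are given in nM (the plate-file convention); they are converted to molar
#' internally when the binding models are evaluated.
#'
#' Defaults mirror the standard live-cell NanoBRET designs: duplicate wells,
#' five independent experiments, association time courses sampled every 30 s
#' for 20 min, saturation endpoints read at 60 min with paired
#' non-specific-binding (NSB) wells defined by 100 nM unlabeled ligand.
#'
#' @param mode One of `"saturation"`, `"association"`, `"competition"`,
#'   `"concentration_response"`.
#' @param ground_truth Mode-dependent ground truth:
#'   * saturation: an [eq_binding_params()] object;
#'   * association: a list with elements `rates` ([kinetic_rates()]),
#'     `bmax` and `baseline` (ratio units);
#'   * competition: a list with elements `probe` ([eq_binding_params()]) and
#'     `ki` (competitor Ki, M);
#'   * concentration_response: a [cr_params()] object.
#' @param probe_concs_nM Labeled-ligand concentrations, nM.
#' @param competitor_concs_nM Competitor dilution series, nM
#'   (competition mode only; may include 0 for probe-only wells).
#' @param timepoints_min Read times, min (association mode only).
#' @param replicates Wells per condition (default 2, duplicate wells).
#' @param n_experiments Independent experiments (default 5).
#' @param noise_sd Standard deviation of additive Gaussian well noise on the
#'   ratio scale. Default `NULL` means 5% of the specific amplitude
#'   (`bmax`, or `emax - basal`).
#' @param seed Integer seed; a fixed seed yields bit-identical tables.
#'   Each experiment consumes its own derived stream, so increasing
#'   `n_experiments` leaves earlier experiments' data untouched.
#' @param include_nsb Saturation mode: generate paired NSB wells.
#' @param include_vehicle Association mode: generate ligand-free vehicle
#'   wells used downstream for baseline correction.
#'
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(mode,
                              ground_truth,
                              probe_concs_nM,
                              competitor_concs_nM = NULL,
                              timepoints_min = seq(0, 20, by = 0.5),
                              replicates = 2L,
                              n_experiments = 5L,
                              noise_sd = NULL,
                              seed = 1L,
                              include_nsb = TRUE,
                              include_vehicle = TRUE) {
  mode <- match.arg(mode, plate_modes())
  min_conc_ok <- if (mode == "concentration_response") 0 else 1e-300
  if (length(probe_concs_nM) == 0L || any(probe_concs_nM < min_conc_ok))
    stop("'probe_concs_nM' must be a nonempty vector of positive values",
         call. = FALSE)
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  if (n_experiments < 1L) stop("'n_experiments' must be >= 1", call. = FALSE)

  gt <- validate_ground_truth(mode, ground_truth)
  if (mode == "competition") {
    if (is.null(competitor_concs_nM) || length(competitor_concs_nM) == 0L)
      stop("competition designs require a 'competitor_concs_nM' series",
           call. = FALSE)
    if (any(competitor_concs_nM < 0))
      stop("'competitor_concs_nM' must be non-negative", call. = FALSE)
  }
  if (mode == "association" && length(probe_concs_nM) < 2L)
    warning(paste("fewer than 2 probe concentrations: k_on and k_off will",
                  "not be separately identifiable downstream"), call. = FALSE)

  if (is.null(noise_sd)) noise_sd <- 0.05 * design_amplitude(mode, gt)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)

  structure(list(mode = mode, ground_truth = gt,
                 probe_concs_nM = as.numeric(probe_concs_nM),
                 competitor_concs_nM = competitor_concs_nM,
                 timepoints_min = timepoints_min,
                 replicates = as.integer(replicates),
                 n_experiments = as.integer(n_experiments),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 include_nsb = isTRUE(include_nsb),
                 include_vehicle = isTRUE(include_vehicle)),
            class = "simulation_design")
}

plate_modes <- function() {
  c("saturation", "association", "competition", "concentration_response")
}

validate_ground_truth <- function(mode, gt) {
  ok <- switch(mode,
    saturation = inherits(gt, "eq_binding_params"),
    association = is.list(gt) && inherits(gt$rates, "kinetic_rates") &&
      is.numeric(gt$bmax) && is.numeric(gt$baseline),
    competition = is.list(gt) && inherits(gt$probe, "eq_binding_params") &&
      is.numeric(gt$ki) && gt$ki > 0,
    concentration_response = inherits(gt, "cr_params"))
  if (!ok)
    stop(sprintf("ground_truth has the wrong type for mode '%s'", mode),
         call. = FALSE)
  gt
}

design_amplitude <- function(mode, gt) {
  switch(mode,
    saturation = gt$bmax,
    association = gt$bmax,
    competition = gt$probe$bmax,
    concentration_response = abs(gt$emax - gt$basal))
}

#' Simulate a plate table from a design
#'
#' Dispatches to the mode-specific generator
#' ([simulate_saturation_plate()], [simulate_association_plate()],
#' [simulate_competition_plate()], [simulate_cr_plate()]).
#'
#' @param design A [simulation_design()].
#' @return A plate table (`data.frame`) in the standard long format; see
#'   [read_plate_csv()] for the column dialect.
#' @export
simulate_plate <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  switch(design$mode,
    saturation = simulate_saturation_plate(design),
    association = simulate_association_plate(design),
    competition = simulate_competition_plate(design),
    concentration_response = simulate_cr_plate(design))
}

# Evaluate fn per experiment under that experiment's private RNG stream.
# Streams are a deterministic function of (seed, experiment index) so adding
# experiments never perturbs earlier ones. RNG state is restored on exit.
per_experiment <- function(design, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  out <- vector("list", design$n_experiments)
  for (i in seq_len(design$n_experiments)) {
    # derived stream per experiment, kept inside the 32-bit integer range
    set.seed(as.integer((as.numeric(design$seed) * 1000 + i) %% 2147483647))
    out[[i]] <- fn(sprintf("exp%02d", i))
  }
  do.call(rbind, out)
}

new_plate_rows <- function(experiment_id, mode, well_type, probe_conc_nM,
                           competitor_conc_nM = NA_real_,
                           time_min = NA_real_, expected, noise_sd) {
  n <- length(expected)
  data.frame(
    experiment_id = experiment_id,
    mode = mode,
    well_id = NA_character_,
    well_type = well_type,
    probe_conc_nM = probe_conc_nM,
    competitor_conc_nM = competitor_conc_nM,
    time_min = time_min,
    donor_em = NA_real_,
    acceptor_em = NA_real_,
    bret_ratio = expected + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd)
                            else 0,
    stringsAsFactors = FALSE)
}

finalize_plate <- function(tab) {
  key_i <- ifelse(is.na(tab$competitor_conc_nM), 0, tab$competitor_conc_nM)
  key_t <- ifelse(is.na(tab$time_min), 0, tab$time_min)
  tab <- tab[order(tab$experiment_id, tab$well_type, tab$probe_conc_nM,
                   key_i, key_t), ]
  rownames(tab) <- NULL
  tab$well_id <- sprintf("w%04d", seq_len(nrow(tab)))
  tab
}

#' Simulate a saturation binding plate
#'
#' One endpoint record per (experiment, probe concentration, replicate,
#' well type). Total wells follow the full one-site model
#' ([total_signal_eq()]); NSB wells, emulating co-addition of 100 nM
#' unlabeled ligand, follow the baseline-plus-linear model. Independent
#' Gaussian noise of sd `noise_sd` is added on the ratio scale.
#'
#' @param design A saturation-mode [simulation_design()].
#' @return A plate table `data.frame`.
#' @export
simulate_saturation_plate <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$mode != "saturation")
    stop("design mode must be 'saturation'", call. = FALSE)
  p <- design$ground_truth
  L <- rep(design$probe_concs_nM, each = design$replicates)
  per_experiment(design, function(eid) {
    tot <- new_plate_rows(eid, "saturation", "total", L,
                          expected = total_signal_eq(L * 1e-9, p),
                          noise_sd = design$noise_sd)
    out <- if (design$include_nsb) {
      nsb <- new_plate_rows(eid, "saturation", "nsb", L,
                            expected = total_signal_eq(L * 1e-9, p,
                                                       nsb = TRUE),
                            noise_sd = design$noise_sd)
      rbind(tot, nsb)
    } else tot
    finalize_plate(out)
  })
}

#' Simulate an association kinetics plate
#'
#' Time-series records per (experiment, probe concentration, replicate,
#' timepoint). Specific wells follow `baseline + association_signal(...)`;
#' vehicle wells (probe concentration 0) carry the baseline only. Time zero
#' is the moment of ligand addition.
#'
#' @param design An association-mode [simulation_design()] whose
#'   `ground_truth` is `list(rates = kinetic_rates(...), bmax =, baseline =)`.
#' @return A plate table `data.frame`.
#' @export
simulate_association_plate <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$mode != "association")
    stop("design mode must be 'association'", call. = FALSE)
  gt <- design$ground_truth
  tt <- design$timepoints_min
  grid <- expand.grid(t = tt,
                      L = rep(design$probe_concs_nM,
                              each = design$replicates))
  per_experiment(design, function(eid) {
    mu <- gt$baseline +
      association_signal(grid$t, grid$L * 1e-9, gt$rates, gt$bmax)
    tot <- new_plate_rows(eid, "association", "total", grid$L,
                          time_min = grid$t, expected = mu,
                          noise_sd = design$noise_sd)
    out <- if (design$include_vehicle) {
      vt <- rep(tt, times = design$replicates)
      veh <- new_plate_rows(eid, "association", "vehicle", 0,
                            time_min = vt,
                            expected = rep(gt$baseline, length(vt)),
                            noise_sd = design$noise_sd)
      rbind(tot, veh)
    } else tot
    finalize_plate(out)
  })
}

#' Simulate a competition binding plate
#'
#' Endpoint records per (experiment, probe concentration, competitor
#' concentration, replicate). The expected signal at each probe
#' concentration is a one-site displacement curve whose IC50 follows the
#' Cheng-Prusoff relation ([ic50_from_ki()]), whose top is the probe-only
#' signal ([total_signal_eq()]) and whose bottom is the non-specific level.
#'
#' @param design A competition-mode [simulation_design()] whose
#'   `ground_truth` is `list(probe = eq_binding_params(...), ki = <M>)`.
#' @return A plate table `data.frame`.
#' @export
simulate_competition_plate <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$mode != "competition")
    stop("design mode must be 'competition'", call. = FALSE)
  gt <- design$ground_truth
  grid <- expand.grid(I = rep(design$competitor_concs_nM,
                              each = design$replicates),
                      L = design$probe_concs_nM)
  curves <- lapply(design$probe_concs_nM, function(Ln) {
    Lm <- Ln * 1e-9
    competition_curve_params(
      ic50 = ic50_from_ki(gt$ki, Lm, gt$probe$kd),
      top = total_signal_eq(Lm, gt$probe),
      bottom = total_signal_eq(Lm, gt$probe, nsb = TRUE))
  })
  mu <- unlist(lapply(seq_along(design$probe_concs_nM), function(j) {
    Im <- grid$I[grid$L == design$probe_concs_nM[j]] * 1e-9
    competition_signal(Im, curves[[j]])
  }))
  per_experiment(design, function(eid) {
    finalize_plate(new_plate_rows(eid, "competition", "total", grid$L,
                                  competitor_conc_nM = grid$I,
                                  expected = mu,
                                  noise_sd = design$noise_sd))
  })
}

#' Simulate a concentration-response plate
#'
#' Endpoint records following [logistic_response()] plus additive noise; a
#' probe concentration of 0 is allowed and yields the basal response.
#'
#' @param design A concentration_response-mode [simulation_design()] whose
#'   `ground_truth` is a [cr_params()] object. Unlike binding modes, zero
#'   concentrations may be included via `probe_concs_nM`.
#' @return A plate table `data.frame`.
#' @export
simulate_cr_plate <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$mode != "concentration_response")
    stop("design mode must be 'concentration_response'", call. = FALSE)
  p <- design$ground_truth
  L <- rep(design$probe_concs_nM, each = design$replicates)
  per_experiment(design, function(eid) {
    finalize_plate(new_plate_rows(eid, "concentration_response", "total", L,
                                  expected = logistic_response(L * 1e-9, p),
                                  noise_sd = design$noise_sd))
  })
}

#' Back-fill donor and acceptor emission channels
#'
#' Given a plate table with BRET ratios, synthesises raw emission channels:
#' donor counts scatter around `donor_level` (multiplicative Gaussian with
#' coefficient of variation `donor_cv`) and acceptor counts are defined as
#' `bret_ratio * donor_em`, so recomputing the ratio from the channels
#' reproduces the stored ratio exactly whatever the donor noise.
#'
#' @param table A plate table with a filled `bret_ratio` column.
#' @param donor_level Mean donor (luminescence) counts; must be positive.
#' @param donor_cv Coefficient of variation of donor counts (0 = no noise).
#' @param seed Integer seed for the donor noise.
#' @return The table with `donor_em` and `acceptor_em` filled.
#' @export
emit_channels <- function(table, donor_level = 1e6, donor_cv = 0, seed = 1L) {
  if (!is.numeric(donor_level) || donor_level <= 0)
    stop("'donor_level' must be positive", call. = FALSE)
  if (any(is.na(table$bret_ratio)))
    stop("table must have a filled 'bret_ratio' column", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fac <- if (donor_cv > 0)
    pmax(0.1, 1 + stats::rnorm(nrow(table), 0, donor_cv)) else 1
  table$donor_em <- donor_level * fac
  table$acceptor_em <- table$bret_ratio * table$donor_em
  table
}
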