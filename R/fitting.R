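#' Compute BRET ratios from raw emission channels
#'
#' Fills the `bret_ratio` column as acceptor (fluorescence) over donor
#' (luminescence) emission. Rows whose donor signal is missing or
#' non-positive are excluded with a warning. Tables that already carry a
#' ratio and no channels pass through unchanged.
#'
#' @param table A plate table with `donor_em`/`acceptor_em` columns, a
#'   `bret_ratio` column, or both.
#' @return The table with `bret_ratio` filled.
#' @export
compute_bret_ratio <- function(table) {
  has_channels <- all(c("donor_em", "acceptor_em") %in% names(table)) &&
    any(!is.na(table$donor_em))
  has_ratio <- "bret_ratio" %in% names(table) && any(!is.na(table$bret_ratio))
  if (!has_channels) {
    if (!has_ratio)
      stop("table has neither emission channels nor a bret_ratio column",
           call. = FALSE)
    return(table)
  }
  bad <- is.na(table$donor_em) | table$donor_em <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d row(s) with non-positive donor emission",
                    sum(bad)), call. = FALSE)
    table <- table[!bad, , drop = FALSE]
  }
  table$bret_ratio <- table$acceptor_em / table$donor_em
  rownames(table) <- NULL
  table
}

#' Baseline-correct association traces to vehicle at time zero
#'
#' For each experiment, subtracts the mean ratio of that experiment's
#' vehicle wells at the earliest timepoint from every ratio in the
#' experiment, so corrected traces start at zero signal on average. The
#' correction is invariant to any constant offset in the raw ratios.
#'
#' @param table An association-mode plate table containing vehicle wells.
#' @return The table with corrected `bret_ratio` values.
#' @export
baseline_correct <- function(table) {
  if (!all(table$mode == "association"))
    stop("baseline_correct expects an association-mode table", call. = FALSE)
  out <- lapply(split(table, table$experiment_id), function(d) {
    veh <- d[d$well_type == "vehicle", , drop = FALSE]
    if (nrow(veh) == 0L)
      stop(sprintf("experiment '%s' has no vehicle wells",
                   d$experiment_id[1]), call. = FALSE)
    t0 <- min(veh$time_min)
    d$bret_ratio <- d$bret_ratio - mean(veh$bret_ratio[veh$time_min == t0])
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- nonlinear least-squares backbone ---------------------------------------

# Levenberg-Marquardt with box bounds and a deterministic fallback start
# grid. `residual` maps a named parameter vector to the residual vector;
# `starts` is a list of named start vectors tried in order; the converged
# fit with the lowest deviance wins. No randomness. Standard errors come
# from the Gauss-Newton Hessian at the optimum.
nls_multistart <- function(residual, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = residual,
                         lower = lower[names(st)], upper = upper[names(st)],
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(out) && out$info %in% 1:4) {
      if (is.null(best) || out$deviance < best$deviance) best <- out
      if (best$deviance <= 1e-20) break
    }
  }
  if (is.null(best)) return(NULL)
  n <- length(residual(best$par))
  p <- length(best$par)
  sigma <- sqrt(best$deviance / max(1L, n - p))
  se <- tryCatch(sqrt(pmax(diag(solve(best$hessian)), 0)) * sigma,
                 error = function(e) rep(NA_real_, p))
  names(se) <- names(best$par)
  list(par = best$par, se = se, sigma = sigma, n_points = n,
       converged = TRUE)
}

new_fit_result <- function(parameters, standard_errors, residual_sd,
                           n_points, converged, experiment_id) {
  structure(list(parameters = parameters,
                 standard_errors = standard_errors,
                 residual_sd = residual_sd, n_points = n_points,
                 converged = converged, experiment_id = experiment_id),
            class = "bret_fit")
}

#' @export
print.bret_fit <- function(x, ...) {
  cat(sprintf("fit [%s] %s, n = %d, residual sd = %.3g\n", x$experiment_id,
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$residual_sd))
  print(rbind(estimate = x$parameters, se = x$standard_errors))
  invisible(x)
}

fit_from_nls <- function(fit, data_n, experiment_id, transform) {
  if (is.null(fit))
    return(new_fit_result(parameters = NULL, standard_errors = NULL,
                          residual_sd = NA_real_, n_points = data_n,
                          converged = FALSE, experiment_id = experiment_id))
  out <- transform(fit$par, fit$se)
  new_fit_result(parameters = out$parameters,
                 standard_errors = out$standard_errors,
                 residual_sd = fit$sigma, n_points = data_n,
                 converged = all(is.finite(out$parameters)),
                 experiment_id = experiment_id)
}

# ---- saturation -------------------------------------------------------------

#' Fit one-site saturation binding with joint non-specific wells
#'
#' For each experiment, total and NSB wells are fitted jointly: total wells
#' follow `baseline + bmax * L/(L + KD) + ns * L`, NSB wells share the same
#' `baseline` and `ns` with the specific term suppressed. KD is fitted as
#' log10(KD) for positivity and conditioning; the aggregate reports KD on
#' the linear nM scale, matching the usual tabulation.
#'
#' @param table A saturation-mode plate table with `total` and `nsb` wells
#'   at 4 or more probe concentrations.
#' @return An object of class `bret_aggregate`: per-experiment fits plus
#'   cross-experiment mean and SEM of `kd_nM`, `bmax`, `ns_slope_per_nM` and
#'   `baseline`.
#' @export
fit_saturation <- function(table) {
  table <- compute_bret_ratio(table)
  if (!any(table$well_type == "total"))
    stop("saturation table contains no total wells", call. = FALSE)
  fits <- lapply(split(table, table$experiment_id), function(d) {
    if (length(unique(d$probe_conc_nM[d$well_type == "total"])) < 4L)
      stop("need at least 4 probe concentrations per experiment",
           call. = FALSE)
    d <- d[d$well_type %in% c("total", "nsb"), , drop = FALSE]
    d$is_total <- as.numeric(d$well_type == "total")
    y <- d$bret_ratio
    amp0 <- max(y) - min(y)
    lkd_grid <- log10(c(stats::median(d$probe_conc_nM),
                        min(d$probe_conc_nM), max(d$probe_conc_nM)))
    starts <- lapply(lkd_grid, function(lk)
      c(baseline = min(y), bmax = max(amp0, 1e-6), ns = 1e-6, lkd = lk))
    residual <- function(p)
      y - (p[["baseline"]] + p[["ns"]] * d$probe_conc_nM +
             d$is_total * p[["bmax"]] * d$probe_conc_nM /
               (d$probe_conc_nM + 10^p[["lkd"]]))
    fit <- nls_multistart(residual, starts = starts,
                          lower = c(baseline = -Inf, bmax = 0, ns = 0,
                                    lkd = -4),
                          upper = c(baseline = Inf, bmax = Inf, ns = Inf,
                                    lkd = 5))
    fit_from_nls(fit, nrow(d), d$experiment_id[1], function(est, se) {
      kd <- 10^est[["lkd"]]
      list(parameters = c(kd_nM = kd, bmax = est[["bmax"]],
                          ns_slope_per_nM = est[["ns"]],
                          baseline = est[["baseline"]]),
           standard_errors = c(kd_nM = log(10) * kd * se[["lkd"]],
                               bmax = se[["bmax"]],
                               ns_slope_per_nM = se[["ns"]],
                               baseline = se[["baseline"]]))
    })
  })
  aggregate_parameters(unname(fits))
}

# ---- association kinetics ---------------------------------------------------

#' Fit a single-concentration exponential association curve
#'
#' Least-squares fit of `B_eq * (1 - exp(-k_obs * t))` to one
#' baseline-corrected time course. The observed rate is fitted as
#' log10(k_obs).
#'
#' @param time Times in minutes (>= 5 points recommended, spanning at least
#'   one half-time).
#' @param signal Baseline-corrected specific BRET ratios.
#' @param experiment_id Label carried into the result.
#' @return A `bret_fit` with parameters `b_eq` and `k_obs_per_min`. A flat
#'   or non-spanning curve yields `converged = FALSE` with a warning.
#' @export
fit_association_single <- function(time, signal, experiment_id = "curve") {
  stopifnot(length(time) == length(signal), length(time) >= 5L)
  d <- data.frame(t = time, y = signal)
  amp <- max(d$y)
  if (!is.finite(amp) || diff(range(d$y)) < 1e-10) {
    warning("flat curve: observed rate not identifiable", call. = FALSE)
    return(new_fit_result(c(b_eq = 0, k_obs_per_min = NA_real_),
                          c(b_eq = NA_real_, k_obs_per_min = NA_real_),
                          residual_sd = stats::sd(d$y), n_points = nrow(d),
                          converged = FALSE, experiment_id = experiment_id))
  }
  # start rate from the time at which the trace first crosses half-plateau
  t_half <- suppressWarnings(min(d$t[d$y >= amp / 2 & d$t > 0]))
  lk0 <- if (is.finite(t_half)) log10(log(2) / t_half) else 0
  if (is.finite(t_half) && max(d$t) < t_half)
    warning("time window does not span one half-time", call. = FALSE)
  starts <- lapply(c(lk0, lk0 - 1, lk0 + 1), function(lk)
    c(beq = amp, lk = lk))
  residual <- function(p) d$y - p[["beq"]] * (1 - exp(-10^p[["lk"]] * d$t))
  fit <- nls_multistart(residual, starts = starts,
                        lower = c(beq = 0, lk = -5),
                        upper = c(beq = Inf, lk = 3))
  fit_from_nls(fit, nrow(d), experiment_id, function(est, se) {
    k <- 10^est[["lk"]]
    list(parameters = c(b_eq = est[["beq"]], k_obs_per_min = k),
         standard_errors = c(b_eq = se[["beq"]],
                             k_obs_per_min = log(10) * k * se[["lk"]]))
  })
}

#' Globally fit association kinetics across ligand concentrations
#'
#' For each experiment, all concentrations' baseline-corrected time courses
#' are fitted simultaneously with shared k_on, k_off and a single shared
#' amplitude `bmax`: the trace at concentration L follows
#' `bmax * L/(L + koff/kon) * (1 - exp(-(kon*L + koff) * t))`. Rates are
#' fitted as log10 with bounds k_on in \[1e3, 1e12\] M^-1 min^-1 and k_off
#' in \[1e-5, 1e2\] min^-1. The kinetically derived KD (`koff/kon`) is
#' computed per experiment before aggregation.
#'
#' @param table A baseline-corrected association-mode plate table with at
#'   least two probe concentrations.
#' @return A `bret_aggregate` over parameters `kon_per_M_min`,
#'   `koff_per_min`, `bmax` and `kinetic_kd_nM`.
#' @export
fit_association_global <- function(table) {
  table <- compute_bret_ratio(table)
  spec <- table[table$well_type != "vehicle" & table$probe_conc_nM > 0, ,
                drop = FALSE]
  if (length(unique(spec$probe_conc_nM)) < 2L)
    stop(paste("a single probe concentration cannot identify k_on and",
               "k_off separately; use fit_association_single"),
         call. = FALSE)
  fits <- lapply(split(spec, spec$experiment_id), function(d) {
    d$L <- d$probe_conc_nM * 1e-9
    bm0 <- max(d$bret_ratio)
    starts <- list(c(lkon = 7, lkoff = -1, bmax = bm0),
                   c(lkon = 6, lkoff = -2, bmax = bm0),
                   c(lkon = 8, lkoff = 0, bmax = bm0))
    residual <- function(p)
      d$bret_ratio - p[["bmax"]] * d$L /
        (d$L + 10^(p[["lkoff"]] - p[["lkon"]])) *
        (1 - exp(-(10^p[["lkon"]] * d$L + 10^p[["lkoff"]]) * d$time_min))
    fit <- nls_multistart(residual, starts = starts,
                          lower = c(lkon = 3, lkoff = -5, bmax = 0),
                          upper = c(lkon = 12, lkoff = 2, bmax = Inf))
    fit_from_nls(fit, nrow(d), d$experiment_id[1], function(est, se) {
      kon <- 10^est[["lkon"]]; koff <- 10^est[["lkoff"]]
      list(parameters = c(kon_per_M_min = kon, koff_per_min = koff,
                          bmax = est[["bmax"]],
                          kinetic_kd_nM = koff / kon * 1e9),
           standard_errors = c(kon_per_M_min = log(10) * kon * se[["lkon"]],
                               koff_per_min = log(10) * koff * se[["lkoff"]],
                               bmax = se[["bmax"]],
                               kinetic_kd_nM = NA_real_))
    })
  })
  aggregate_parameters(unname(fits))
}

# ---- competition ------------------------------------------------------------

#' Fit competition binding curves and derive Ki estimates
#'
#' For each (experiment, probe concentration), fits a one-site displacement
#' curve with unit Hill slope (IC50 on the log10 scale, free top and
#' bottom), converts the IC50 to a Ki via the Cheng-Prusoff relation using
#' the supplied probe KD, and pools per-curve Ki values as
#' `pKi = -log10(mean Ki)`. Across probe concentrations the linear
#' IC50-versus-probe regression ([fit_ic50_regression()]) provides an
#' internal-consistency estimate of the competitor Ki (intercept) and probe
#' KD (intercept/slope).
#'
#' @param table A competition-mode plate table.
#' @param probe_kd_nM Probe equilibrium dissociation constant in nM,
#'   typically taken from a saturation analysis.
#' @param free_hill If `TRUE`, the Hill slope of each displacement curve is
#'   fitted rather than fixed at 1.
#' @return A list of class `competition_result`:
#'   `per_experiment` (data frame of per-curve IC50 and Ki in nM),
#'   `pki` (per-experiment pooled pKi), `pooled_pki`/`pki_sem`
#'   (cross-experiment mean and SEM), and `regression` (the
#'   IC50-versus-probe fit on per-probe mean IC50s).
#' @export
fit_competition <- function(table, probe_kd_nM, free_hill = FALSE) {
  check_positive(probe_kd_nM, "probe_kd_nM")
  table <- compute_bret_ratio(table)
  kd_M <- probe_kd_nM * 1e-9
  rows <- list()
  for (d in split(table, table$experiment_id)) {
    for (dd in split(d, d$probe_conc_nM)) {
      cv <- fit_competition_curve(dd, free_hill)
      ic50_nM <- cv$parameters[["ic50_nM"]]
      ki_M <- if (is.finite(ic50_nM))
        cheng_prusoff_ki(ic50_nM * 1e-9, dd$probe_conc_nM[1] * 1e-9, kd_M)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = dd$experiment_id[1],
        probe_conc_nM = dd$probe_conc_nM[1],
        ic50_nM = ic50_nM, ki_nM = ki_M * 1e9,
        converged = cv$converged,
        nonphysical = isTRUE(cv$parameters[["top"]] <
                               cv$parameters[["bottom"]]))
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  ok <- per[per$converged & is.finite(per$ki_nM), , drop = FALSE]
  pki <- vapply(split(ok, ok$experiment_id),
                function(d) -log10(mean(d$ki_nM) * 1e-9), numeric(1))
  mean_ic50 <- stats::aggregate(ic50_nM ~ probe_conc_nM, data = ok, FUN = mean)
  reg <- fit_ic50_regression(mean_ic50$probe_conc_nM, mean_ic50$ic50_nM)
  structure(list(per_experiment = per, pki = pki,
                 pooled_pki = mean(pki),
                 pki_sem = if (length(pki) > 1)
                   stats::sd(pki) / sqrt(length(pki)) else NA_real_,
                 n_experiments = length(pki), regression = reg,
                 probe_kd_nM = probe_kd_nM),
            class = "competition_result")
}

fit_competition_curve <- function(dd, free_hill) {
  if (length(unique(dd$competitor_conc_nM)) < 4L)
    warning(sprintf("probe %g nM: fewer than 4 competitor concentrations",
                    dd$probe_conc_nM[1]), call. = FALSE)
  y <- dd$bret_ratio
  I <- dd$competitor_conc_nM
  pos <- sort(unique(I[I > 0]))
  lic_grid <- log10(c(stats::median(pos), min(pos), max(pos)))
  starts <- lapply(lic_grid, function(li) {
    st <- c(top = max(y), bottom = min(y), lic50 = li)
    if (free_hill) st <- c(st, h = 1)
    st
  })
  lower <- c(top = -Inf, bottom = -Inf, lic50 = log10(min(pos)) - 4)
  upper <- c(top = Inf, bottom = Inf, lic50 = log10(max(pos)) + 4)
  if (free_hill) {
    lower <- c(lower, h = 0.1); upper <- c(upper, h = 10)
  }
  lI <- ifelse(I > 0, log10(I), -Inf)
  residual <- function(p) {
    h <- if (free_hill) p[["h"]] else 1
    frac <- ifelse(I > 0, 10^(h * (lI - p[["lic50"]])), 0)
    y - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) / (1 + frac))
  }
  fit <- nls_multistart(residual, starts = starts, lower = lower,
                        upper = upper)
  res <- fit_from_nls(fit, length(y), dd$experiment_id[1], function(est, se) {
    ic <- 10^est[["lic50"]]
    p <- c(ic50_nM = ic, top = est[["top"]], bottom = est[["bottom"]])
    s <- c(ic50_nM = log(10) * ic * se[["lic50"]], top = se[["top"]],
           bottom = se[["bottom"]])
    if (free_hill) {
      p <- c(p, hill = est[["h"]]); s <- c(s, hill = se[["h"]])
    }
    list(parameters = p, standard_errors = s)
  })
  if (res$converged && res$parameters[["top"]] < res$parameters[["bottom"]])
    warning("fitted top below bottom: curve flagged non-physical",
            call. = FALSE)
  res
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf("competition: pooled pKi = %.2f +/- %.2f (n = %d), probe KD = %.3g nM\n",
              x$pooled_pki, x$pki_sem, x$n_experiments, x$probe_kd_nM))
  cat(sprintf("IC50 regression: intercept (Ki) = %.3g nM, slope = %.3g, R^2 = %.3f, KD est = %.3g nM\n",
              x$regression$intercept_nM, x$regression$slope,
              x$regression$r_squared, x$regression$kd_estimate_nM))
  invisible(x)
}

#' Linear regression of IC50 on probe concentration
#'
#' Under competitive mass action, `IC50 = Ki + (Ki/KD) * L`: ordinary
#' least squares of fitted IC50s on probe concentration returns the
#' competitor Ki as intercept, `Ki/KD` as slope, and hence `intercept/slope`
#' as an estimate of the probe KD.
#'
#' @param probe_conc_nM Probe concentrations, nM (>= 3 points).
#' @param ic50_nM Fitted IC50s, nM.
#' @return A list with `slope`, `intercept_nM`, `r_squared`, `p_value` and
#'   `kd_estimate_nM` (`NA` with a warning when the slope is not positive).
#' @export
fit_ic50_regression <- function(probe_conc_nM, ic50_nM) {
  stopifnot(length(probe_conc_nM) == length(ic50_nM))
  if (length(probe_conc_nM) < 3L)
    stop("need at least 3 (probe, IC50) points", call. = FALSE)
  fit <- stats::lm(ic50_nM ~ probe_conc_nM)
  # summary.lm warns on zero-residual (exactly collinear) input, which is a
  # legitimate case here (noiseless evaluation of the affine relation)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  kd_est <- kd_se <- NA_real_
  if (slope > 0) {
    kd_est <- intercept / slope
    # first-order (delta-method) standard error of the ratio
    V <- suppressWarnings(stats::vcov(fit))
    g <- c(1 / slope, -intercept / slope^2)
    kd_se <- sqrt(drop(t(g) %*% V %*% g))
  } else {
    warning("non-positive slope: probe-KD estimate undefined", call. = FALSE)
  }
  list(slope = slope, intercept_nM = intercept,
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       kd_estimate_nM = kd_est, kd_se_nM = kd_se)
}

# ---- concentration-response -------------------------------------------------

#' Fit sigmoidal concentration-response curves
#'
#' Per experiment, fits `basal + (emax - basal) * C^h / (C^h + EC50^h)` with
#' the Hill slope fixed at 1 by default and EC50 on the log10 scale.
#' Reports pEC50 (-log10 of EC50 in M) alongside emax and basal.
#'
#' @param table A concentration_response-mode plate table with at least five
#'   concentrations.
#' @param free_hill If `TRUE`, the Hill slope is fitted.
#' @return A `bret_aggregate` over `pec50`, `ec50_nM`, `emax` and `basal`.
#' @export
fit_concentration_response <- function(table, free_hill = FALSE) {
  table <- compute_bret_ratio(table)
  fits <- lapply(split(table, table$experiment_id), function(d) {
    if (length(unique(d$probe_conc_nM)) < 5L)
      stop("need at least 5 concentrations per experiment", call. = FALSE)
    y <- d$bret_ratio
    pos <- sort(unique(d$probe_conc_nM[d$probe_conc_nM > 0]))
    grid <- log10(c(stats::median(pos), min(pos), max(pos)))
    starts <- lapply(grid, function(le) {
      st <- c(basal = min(y), emax = max(y), lec = le)
      if (free_hill) st <- c(st, h = 1)
      st
    })
    lower <- c(basal = -Inf, emax = -Inf, lec = log10(min(pos)) - 4)
    upper <- c(basal = Inf, emax = Inf, lec = log10(max(pos)) + 4)
    if (free_hill) {
      lower <- c(lower, h = 0.1); upper <- c(upper, h = 10)
    }
    lc <- ifelse(d$probe_conc_nM > 0, log10(d$probe_conc_nM), NA_real_)
    residual <- function(p) {
      h <- if (free_hill) p[["h"]] else 1
      frac <- ifelse(is.na(lc), Inf, 10^(h * (p[["lec"]] - lc)))
      mu <- p[["basal"]] + (p[["emax"]] - p[["basal"]]) / (1 + frac)
      y - mu
    }
    fit <- nls_multistart(residual, starts = starts,
                          lower = lower, upper = upper)
    fit_from_nls(fit, nrow(d), d$experiment_id[1], function(est, se) {
      ec_nM <- 10^est[["lec"]]
      p <- c(pec50 = 9 - est[["lec"]], ec50_nM = ec_nM,
             emax = est[["emax"]], basal = est[["basal"]])
      s <- c(pec50 = se[["lec"]], ec50_nM = log(10) * ec_nM * se[["lec"]],
             emax = se[["emax"]], basal = se[["basal"]])
      if (free_hill) {
        p <- c(p, hill = est[["h"]]); s <- c(s, hill = se[["h"]])
      }
      list(parameters = p, standard_errors = s)
    })
  })
  aggregate_parameters(unname(fits))
}

# ---- aggregation ------------------------------------------------------------

#' Aggregate per-experiment fits to mean and SEM
#'
#' Summarises a list of per-experiment fits as mean +/- SEM per parameter,
#' the convention for reporting binding parameters over independent
#' experiments. Parameters can be averaged on the log10 scale (geometric
#' aggregation, appropriate for p-scale affinities) via `scale`.
#' Non-converged fits are excluded with a warning.
#'
#' @param fits A list of `bret_fit` objects.
#' @param scale Named character vector mapping parameter names to
#'   `"linear"` (default) or `"log"`.
#' @return An object of class `bret_aggregate` with elements
#'   `per_experiment`, `mean`, `sem` and `n`. With fewer than two converged
#'   fits the SEM is reported as `NA`.
#' @export
aggregate_parameters <- function(fits, scale = character()) {
  stopifnot(is.list(fits))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    warning(sprintf("excluding %d non-converged fit(s) from aggregation",
                    sum(!conv)), call. = FALSE)
  used <- fits[conv]
  if (length(used) == 0L)
    stop("no converged fits to aggregate", call. = FALSE)
  pars <- do.call(rbind, lapply(used, function(f) f$parameters))
  n <- nrow(pars)
  mean_sem <- function(x, log_scale) {
    if (log_scale) x <- log10(x)
    m <- mean(x)
    s <- if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
    if (log_scale) c(mean = 10^m, sem = NA_real_, log_mean = m, log_sem = s)
    else c(mean = m, sem = s, log_mean = NA_real_, log_sem = NA_real_)
  }
  stats_tab <- vapply(colnames(pars), function(p) {
    mean_sem(pars[, p], identical(unname(scale[p]), "log"))
  }, numeric(4))
  row_of <- function(r) stats::setNames(stats_tab[r, ], colnames(stats_tab))
  structure(list(per_experiment = fits,
                 mean = row_of("mean"),
                 sem = row_of("sem"),
                 log_mean = row_of("log_mean"),
                 log_sem = row_of("log_sem"),
                 n = n),
            class = "bret_aggregate")
}

#' @export
print.bret_aggregate <- function(x, ...) {
  cat(sprintf("aggregate over %d experiment(s): mean +/- SEM\n", x$n))
  print(rbind(mean = x$mean, sem = x$sem))
  invisible(x)
}

# ---- design-level statistics ------------------------------------------------

#' Power to detect a pKi shift between two fluorescent probes
#'
#' Power of a two-sample, two-sided Student t test to detect a difference
#' `delta` in mean pKi between two groups of `n_per_group` independent
#' experiments, computed from the noncentral t distribution (both rejection
#' tails retained, so `delta = 0` returns exactly `alpha`).
#'
#' @param n_per_group Experiments per group (>= 2).
#' @param sd Anticipated between-experiment standard deviation of pKi
#'   (log10 units).
#' @param delta Difference in mean pKi to detect (log10 units).
#' @param alpha Two-sided significance level.
#' @return Power as a fraction in \[alpha, 1\].
#' @export
power_delta_pki <- function(n_per_group, sd, delta, alpha = 0.05) {
  if (!is.numeric(n_per_group) || n_per_group < 2)
    stop("'n_per_group' must be >= 2", call. = FALSE)
  check_positive(sd, "sd")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  df <- 2 * n_per_group - 2
  ncp <- abs(delta) / (sd * sqrt(2 / n_per_group))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp) + stats::pt(crit, df, ncp, lower.tail = FALSE)
}

#' Test probe dependence of pKi estimates
#'
#' One-way fixed-effects ANOVA of per-experiment pKi values across probe
#' concentrations (or across fluorescent probes); under simple competitive
#' mass action the pKi of an unlabeled competitor should not depend on the
#' probe used.
#'
#' @param pki Per-curve pKi values.
#' @param probe Factor identifying the probe (concentration or ligand) for
#'   each value.
#' @return A list with the ANOVA `f_statistic`, `p_value`, and df.
#' @export
test_probe_dependence <- function(pki, probe) {
  stopifnot(length(pki) == length(probe))
  fit <- stats::aov(pki ~ factor(probe))
  tab <- summary(fit)[[1]]
  list(f_statistic = tab[1, "F value"], p_value = tab[1, "Pr(>F)"],
       df_between = tab[1, "Df"], df_within = tab[2, "Df"])
}
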