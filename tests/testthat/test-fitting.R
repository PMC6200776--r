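test_that("BRET ratios are computed from channels and bad rows dropped", {
  tab <- simulate_plate(sat_design(2.03, n_experiments = 1))
  chan <- emit_channels(tab, donor_level = 1e6, donor_cv = 0.02, seed = 5)
  chan$bret_ratio <- NA_real_
  out <- compute_bret_ratio(chan)
  expect_equal(out$bret_ratio, tab$bret_ratio, tolerance = 1e-15)
  chan$donor_em[3] <- 0
  expect_warning(out2 <- compute_bret_ratio(chan), "non-positive donor")
  expect_equal(nrow(out2), nrow(chan) - 1)
  bad <- tab; bad$bret_ratio <- NA_real_
  expect_error(compute_bret_ratio(bad), "neither")
})

test_that("baseline correction anchors vehicle wells and is shift-invariant", {
  tab <- simulate_plate(assoc_design(rates_nrp1(), n_experiments = 2,
                                     seed = 4))
  cor1 <- baseline_correct(tab)
  for (d in split(cor1, cor1$experiment_id)) {
    veh0 <- d$bret_ratio[d$well_type == "vehicle" & d$time_min == 0]
    expect_equal(mean(veh0), 0, tolerance = 1e-12)
  }
  shifted <- tab
  shifted$bret_ratio <- shifted$bret_ratio + 0.37
  cor2 <- baseline_correct(shifted)
  expect_equal(cor2$bret_ratio, cor1$bret_ratio, tolerance = 1e-12)
  # noiseless corrected traces equal the closed-form specific signal
  clean <- baseline_correct(simulate_plate(assoc_design(rates_nrp1(),
                                                        noise_sd = 0,
                                                        n_experiments = 1)))
  spec <- clean[clean$well_type == "total", ]
  expect_equal(spec$bret_ratio,
               association_signal(spec$time_min, spec$probe_conc_nM * 1e-9,
                                  rates_nrp1(), 0.02),
               tolerance = 1e-12)
  noveh <- tab[tab$well_type != "vehicle", ]
  expect_error(baseline_correct(noveh), "exp01")
})

test_that("saturation fits recover noiseless ground truths exactly", {
  for (kd in c(truth$vegfr2_165a$sat_kd_nM, truth$nrp1_165a$sat_kd_nM)) {
    fit <- fit_saturation(simulate_plate(sat_design(kd, noise_sd = 0,
                                                    n_experiments = 2)))
    expect_equal(unname(fit$mean[["kd_nM"]]), kd, tolerance = 1e-6)
    expect_equal(unname(fit$mean[["bmax"]]), 0.02, tolerance = 1e-6)
    expect_equal(unname(fit$mean[["baseline"]]), 0.05, tolerance = 1e-6)
    # data generated without non-specific binding fit a null slope
    expect_lt(abs(fit$mean[["ns_slope_per_nM"]]), 1e-6 * 0.02 / kd)
  }
  # and with a genuine non-specific component
  fit <- fit_saturation(simulate_plate(sat_design(4.41, noise_sd = 0,
                                                  n_experiments = 1,
                                                  ns_slope = 2e5)))
  expect_equal(unname(fit$mean[["kd_nM"]]), 4.41, tolerance = 1e-6)
  expect_equal(unname(fit$mean[["ns_slope_per_nM"]]), 2e5 * 1e-9,
               tolerance = 1e-4)
})

test_that("single-curve association fits recover k_obs and its linearity", {
  r <- rates_vegfr2()
  t <- seq(0, 20, by = 0.5)
  y <- association_signal(t, 1e-9, r, 0.02)
  fit <- fit_association_single(t, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters[["k_obs_per_min"]]), 0.0754,
               tolerance = 1e-6)
  # k_obs regressed on L across single fits returns kon and koff
  L <- c(1, 2.5, 5, 10, 20) * 1e-9
  kobs_hat <- vapply(L, function(Lm) {
    f <- fit_association_single(t, association_signal(t, Lm, r, 0.02))
    f$parameters[["k_obs_per_min"]]
  }, numeric(1))
  line <- stats::lm(kobs_hat ~ L)
  expect_equal(unname(stats::coef(line)[2]), r$kon, tolerance = 1e-4)
  expect_equal(unname(stats::coef(line)[1]), r$koff, tolerance = 1e-4)
  # flat curve is flagged rather than fitted
  expect_warning(flat <- fit_association_single(t, rep(0, length(t))),
                 "flat")
  expect_false(flat$converged)
})

test_that("global association fits recover rates and are order-invariant", {
  tab <- baseline_correct(simulate_plate(assoc_design(rates_nrp1(),
                                                      noise_sd = 0,
                                                      n_experiments = 2)))
  fit <- fit_association_global(tab)
  expect_equal(unname(fit$mean[["kon_per_M_min"]]), 7.11e7,
               tolerance = 1e-4)
  expect_equal(unname(fit$mean[["koff_per_min"]]), 0.26, tolerance = 1e-4)
  expect_equal(unname(fit$mean[["kinetic_kd_nM"]]), 0.26 / 7.11e7 * 1e9,
               tolerance = 1e-4)
  # per-experiment kinetic KD at the VEGFR2 rates equals koff/kon = 3.9 nM
  tabv <- baseline_correct(simulate_plate(assoc_design(rates_vegfr2(),
                                                       noise_sd = 0,
                                                       n_experiments = 1)))
  fitv <- fit_association_global(tabv)
  expect_equal(unname(fitv$mean[["kinetic_kd_nM"]]), 0.06 / 1.54e7 * 1e9,
               tolerance = 1e-4)
  # permuting row order leaves estimates unchanged
  set.seed(9)
  perm <- tab[sample(nrow(tab)), ]
  fit2 <- fit_association_global(perm)
  expect_equal(fit2$mean, fit$mean, tolerance = 1e-10)
  one <- tab[tab$probe_conc_nM %in% c(0, 5), ]
  expect_error(fit_association_global(one), "single probe concentration")
})

test_that("competition fits recover per-curve IC50s and the pooled pKi", {
  ki <- 10^-9.54
  tab <- simulate_plate(comp_design(ki, 4.41, noise_sd = 0,
                                    n_experiments = 2))
  fit <- fit_competition(tab, probe_kd_nM = 4.41)
  expect_equal(fit$pooled_pki, 9.54, tolerance = 0.001)
  # per-curve ic50s equal the closed-form evaluations
  for (i in seq_len(nrow(fit$per_experiment))) {
    row <- fit$per_experiment[i, ]
    expect_equal(row$ic50_nM,
                 ic50_from_ki(ki, row$probe_conc_nM * 1e-9, 4.41e-9) * 1e9,
                 tolerance = 1e-6)
  }
  # regression consistency: intercept ~ Ki, intercept/slope ~ probe KD
  expect_equal(fit$regression$intercept_nM, ki * 1e9, tolerance = 1e-4)
  expect_equal(fit$regression$kd_estimate_nM, 4.41, tolerance = 1e-4)
  expect_equal(fit$regression$r_squared, 1, tolerance = 1e-9)
})

test_that("IC50-versus-probe regression returns the published arithmetic", {
  L <- c(0.5, 1, 2, 3, 5)
  ic50 <- 0.10 + 0.09 * L  # the reported intercept and slope
  reg <- fit_ic50_regression(L, ic50)
  expect_equal(reg$intercept_nM, 0.10, tolerance = 1e-10)
  expect_equal(reg$slope, 0.09, tolerance = 1e-10)
  expect_equal(reg$kd_estimate_nM, 0.10 / 0.09, tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  expect_warning(bad <- fit_ic50_regression(L, 1 - 0.09 * L), "slope")
  expect_true(is.na(bad$kd_estimate_nM))
  expect_error(fit_ic50_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("concentration-response fits recover pEC50 and scale equivariantly", {
  p <- cr_params(ec50 = 10^-8.16, emax = 100, basal = 2)
  des <- simulation_design("concentration_response", p,
                           probe_concs_nM = c(0, 10^seq(-1.5, 2.5, 0.5)),
                           noise_sd = 0, n_experiments = 2, seed = 1)
  tab <- simulate_plate(des)
  fit <- fit_concentration_response(tab)
  expect_equal(unname(fit$mean[["pec50"]]), 8.16, tolerance = 1e-6)
  expect_equal(unname(fit$mean[["emax"]]), 100, tolerance = 1e-5)
  # doubling all responses doubles emax and leaves pEC50 unchanged
  tab2 <- tab; tab2$bret_ratio <- 2 * tab2$bret_ratio
  fit2 <- fit_concentration_response(tab2)
  expect_equal(unname(fit2$mean[["pec50"]]), 8.16, tolerance = 1e-6)
  expect_equal(unname(fit2$mean[["emax"]]), 200, tolerance = 1e-4)
})

test_that("aggregation reports mean and SEM with the sd/sqrt(n) identity", {
  mk <- function(val, id) bretfit:::new_fit_result(
    parameters = c(kd_nM = val), standard_errors = c(kd_nM = 0.1),
    residual_sd = 0.001, n_points = 10, converged = TRUE,
    experiment_id = id)
  agg <- aggregate_parameters(list(mk(2, "a"), mk(4, "b")))
  expect_equal(unname(agg$mean[["kd_nM"]]), 3)
  expect_equal(unname(agg$sem[["kd_nM"]]), 1)
  same <- aggregate_parameters(list(mk(3, "a"), mk(3, "b"), mk(3, "c")))
  expect_equal(unname(same$sem[["kd_nM"]]), 0)
  # single fit: SEM undefined
  single <- aggregate_parameters(list(mk(2, "a")))
  expect_true(is.na(single$sem[["kd_nM"]]))
  # non-converged fits are excluded with a warning
  bad <- bretfit:::new_fit_result(NULL, NULL, NA_real_, 10, FALSE, "z")
  expect_warning(agg2 <- aggregate_parameters(list(mk(2, "a"), mk(4, "b"),
                                                   bad)),
                 "non-converged")
  expect_equal(agg2$n, 2)
  # log-scale aggregation matches by-hand geometric stats
  vals <- c(1e-9, 2e-9, 4e-9)
  fits <- mapply(mk, vals, c("a", "b", "c"), SIMPLIFY = FALSE)
  lg <- aggregate_parameters(fits, scale = c(kd_nM = "log"))
  expect_equal(unname(lg$log_mean[["kd_nM"]]), mean(log10(vals)))
  expect_equal(unname(lg$log_sem[["kd_nM"]]),
               stats::sd(log10(vals)) / sqrt(3))
})

test_that("SEM shrinks as 1/sqrt(n) over replicate experiments", {
  mk <- function(val, id) bretfit:::new_fit_result(
    parameters = c(kd_nM = val), standard_errors = c(kd_nM = 0.1),
    residual_sd = 0.001, n_points = 10, converged = TRUE,
    experiment_id = id)
  set.seed(42)
  draws <- 2 + 0.3 * stats::rnorm(400)
  fits <- mapply(mk, draws, paste0("e", seq_along(draws)), SIMPLIFY = FALSE)
  # mean SEM over disjoint groups of 100 versus the SEM of all 400:
  # expected ratio 2 under 1/sqrt(n) scaling
  sem100 <- mean(vapply(split(seq_along(fits), (seq_along(fits) - 1) %/% 100),
                        function(ix)
                          aggregate_parameters(fits[ix])$sem[["kd_nM"]],
                        numeric(1)))
  sem400 <- aggregate_parameters(fits)$sem[["kd_nM"]]
  expect_equal(sem100 / sem400, 2, tolerance = 0.15)
  # exact identity against per-parameter sd
  expect_equal(sem400, stats::sd(draws) / sqrt(400))
})

test_that("recovery at the study design is nearly unbiased", {
  # 5 experiments, duplicate wells, noise at 5% of the specific amplitude
  sat <- fit_saturation(simulate_plate(sat_design(4.41, seed = 11)))
  expect_lt(abs(sat$mean[["kd_nM"]] - 4.41) / 4.41, 0.10)
  kin <- fit_association_global(baseline_correct(
    simulate_plate(assoc_design(rates_nrp1(), replicates = 2, seed = 12))))
  expect_lt(abs(kin$mean[["kon_per_M_min"]] - 7.11e7) / 7.11e7, 0.10)
  expect_lt(abs(kin$mean[["koff_per_min"]] - 0.26) / 0.26, 0.10)
})

test_that("pKi recovery from noisy competition stays within 3 SEM", {
  ki <- 10^-9.54
  fit <- fit_competition(simulate_plate(comp_design(ki, 4.41, seed = 13)),
                         probe_kd_nM = 4.41)
  expect_lt(abs(fit$pooled_pki - 9.54), 3 * max(fit$pki_sem, 0.02))
})

test_that("power calculation matches its Monte-Carlo oracle", {
  # null case: two-sided test rejects at exactly alpha
  expect_equal(power_delta_pki(5, sd = 0.1, delta = 0), 0.05)
  # study design: n = 5 experiments, detect 0.3 log-unit shift
  p <- power_delta_pki(5, sd = 0.1, delta = 0.3)
  mc <- mc_power_ttest(1e5, n = 5, sd = 0.1, delta = 0.3, seed = 21)
  expect_lt(abs(p - mc), 0.01)
  # monotone in n
  ns <- c(3, 5, 8, 12, 20)
  pw <- vapply(ns, function(n) power_delta_pki(n, 0.15, 0.2), numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(power_delta_pki(5, 0.1, 0.3, alpha = 1.2), "alpha")
})

test_that("probe dependence ANOVA behaves under null and alternative", {
  set.seed(31)
  probe <- rep(c(0.5, 1, 2, 3, 5), each = 5)
  null_pki <- 9.5 + stats::rnorm(length(probe), 0, 0.1)
  res <- test_probe_dependence(null_pki, probe)
  expect_gt(res$p_value, 0.001)
  expect_equal(res$df_between, 4)
  shifted <- null_pki + 0.8 * (probe > 2)
  expect_lt(test_probe_dependence(shifted, probe)$p_value, 0.01)
})
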