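#' Kinetic rate parameters for a one-site mass-action interaction
#'
#' Bundles the association and dissociation rate constants of a bimolecular
#' ligand-receptor interaction. All downstream kinetic quantities (observed
#' rate, half-time, residence time, kinetically derived KD) are pure functions
#' of these two constants.
#'
#' @param kon Association rate constant, in M^-1 min^-1. Must be positive.
#' @param koff Dissociation rate constant, in min^-1. Must be positive.
#'
#' @return An object of class `kinetic_rates` with elements `kon` and `koff`.
#' @examples
#' r <- kinetic_rates(kon = 7.11e7, koff = 0.26)
#' kinetic_kd(r) * 1e9  # nM
#' @export
kinetic_rates <- function(kon, koff) {
  check_positive(kon, "kon")
  check_positive(koff, "koff")
  structure(list(kon = kon, koff = koff), class = "kinetic_rates")
}

#' Equilibrium parameters of a one-site saturation binding curve
#'
#' Describes the expected endpoint BRET signal of a saturation experiment:
#' a ligand-independent baseline, a saturable specific component with
#' dissociation constant `kd` and ceiling `bmax`, and a non-specific
#' component linear in ligand concentration.
#'
#' @param kd Equilibrium dissociation constant, in M. Must be positive.
#' @param bmax Maximal specific signal, in BRET-ratio units. Non-negative.
#' @param ns_slope Non-specific signal per molar ligand (ratio / M).
#'   Non-negative.
#' @param baseline Ligand-independent signal (ratio units).
#'
#' @return An object of class `eq_binding_params`.
#' @export
eq_binding_params <- function(kd, bmax, ns_slope = 0, baseline = 0) {
  check_positive(kd, "kd")
  check_nonnegative(bmax, "bmax")
  check_nonnegative(ns_slope, "ns_slope")
  stopifnot(is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  structure(list(kd = kd, bmax = bmax, ns_slope = ns_slope,
                 baseline = baseline),
            class = "eq_binding_params")
}

#' Parameters of a one-site competition (displacement) curve
#'
#' @param ic50 Half-maximal inhibitory concentration of the competitor, in M.
#' @param top Uninhibited signal (ratio units).
#' @param bottom Fully inhibited signal (ratio units); must not exceed `top`.
#' @param hill Slope factor; defaults to 1 for a simple mass-action
#'   interaction.
#'
#' @return An object of class `competition_curve_params`.
#' @export
competition_curve_params <- function(ic50, top, bottom, hill = 1) {
  check_positive(ic50, "ic50")
  check_positive(hill, "hill")
  if (top < bottom) stop("'top' must be >= 'bottom'", call. = FALSE)
  structure(list(ic50 = ic50, top = top, bottom = bottom, hill = hill),
            class = "competition_curve_params")
}

#' Parameters of a sigmoidal concentration-response curve
#'
#' @param ec50 Half-maximal effective concentration, in M.
#' @param emax Maximal response (response units).
#' @param basal Response at zero ligand (response units).
#' @param hill Slope factor; defaults to 1.
#'
#' @return An object of class `cr_params`.
#' @export
cr_params <- function(ec50, emax, basal = 0, hill = 1) {
  check_positive(ec50, "ec50")
  check_positive(hill, "hill")
  structure(list(ec50 = ec50, emax = emax, basal = basal, hill = hill),
            class = "cr_params")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf("kinetic rates: kon = %.3g M^-1 min^-1, koff = %.3g min^-1\n",
              x$kon, x$koff))
  cat(sprintf("  kinetic KD = %.3g nM, residence time = %.2f min\n",
              kinetic_kd(x) * 1e9, residence_time(x)))
  invisible(x)
}

#' @export
print.eq_binding_params <- function(x, ...) {
  cat(sprintf(
    "one-site equilibrium: KD = %.3g nM, Bmax = %.3g, NS = %.3g/nM, baseline = %.3g\n",
    x$kd * 1e9, x$bmax, x$ns_slope * 1e-9, x$baseline))
  invisible(x)
}

# ---- closed-form models -----------------------------------------------------

#' Fractional receptor occupancy at equilibrium
#'
#' Mass-action occupancy `L / (L + kd)` of a one-site interaction.
#'
#' @param L Free ligand concentration, in M (vectorised, non-negative).
#' @param kd Equilibrium dissociation constant, in M (positive scalar).
#' @return Occupancy fraction in \[0, 1\].
#' @export
fractional_occupancy <- function(L, kd) {
  check_positive(kd, "kd")
  check_nonnegative_vec(L, "L")
  L / (L + kd)
}

#' Expected endpoint signal of a saturation binding well
#'
#' Total wells follow `baseline + bmax * L/(L + kd) + ns_slope * L`;
#' non-specific (NSB) wells, in which the specific site is blocked by excess
#' unlabeled ligand, follow `baseline + ns_slope * L`.
#'
#' @param L Ligand concentration, in M (vectorised).
#' @param p An [eq_binding_params()] object.
#' @param nsb If `TRUE`, return the NSB-well model (specific term suppressed).
#' @return Expected signal in BRET-ratio units.
#' @export
total_signal_eq <- function(L, p, nsb = FALSE) {
  stopifnot(inherits(p, "eq_binding_params"))
  check_nonnegative_vec(L, "L")
  ns <- p$baseline + p$ns_slope * L
  if (nsb) ns else ns + p$bmax * fractional_occupancy(L, p$kd)
}

#' Observed association rate constant
#'
#' For a mono-exponential approach to equilibrium the observed rate is
#' `kobs = kon * L + koff`.
#'
#' @param L Ligand concentration, in M (vectorised).
#' @param r A [kinetic_rates()] object.
#' @return Observed rate in min^-1 (always `>= koff`).
#' @export
kobs <- function(L, r) {
  stopifnot(inherits(r, "kinetic_rates"))
  check_nonnegative_vec(L, "L")
  r$kon * L + r$koff
}

#' Specific binding signal during association
#'
#' Exponential association to the equilibrium plateau:
#' `B_eq(L) * (1 - exp(-kobs(L) * t))` with
#' `B_eq(L) = bmax * L / (L + koff/kon)`.
#'
#' @param t Time since ligand addition, in min (vectorised, non-negative).
#' @param L Ligand concentration, in M (scalar or same length as `t`).
#' @param r A [kinetic_rates()] object.
#' @param bmax Maximal specific signal (ratio units).
#' @return Specific signal in ratio units; 0 at `t = 0`, approaching
#'   `B_eq(L)` as `t` grows.
#' @export
association_signal <- function(t, L, r, bmax) {
  stopifnot(inherits(r, "kinetic_rates"))
  check_nonnegative_vec(t, "t")
  check_nonnegative_vec(L, "L")
  beq <- bmax * L / (L + kinetic_kd(r))
  beq * (1 - exp(-kobs(L, r) * t))
}

#' Association half-time
#'
#' Time for the specific signal to reach half of its plateau:
#' `t1/2 = ln(2) / (kon * L + koff)`. Strictly decreasing in `L`.
#'
#' @inheritParams kobs
#' @return Half-time in minutes.
#' @export
half_time <- function(L, r) {
  k <- kobs(L, r)
  if (any(k <= 0)) stop("observed rate must be positive", call. = FALSE)
  log(2) / k
}

#' Residence time of the ligand-receptor complex
#'
#' The mean lifetime of the bound complex, `1 / koff`.
#'
#' @param r A [kinetic_rates()] object (or a positive `koff` value).
#' @return Residence time in minutes.
#' @export
residence_time <- function(r) {
  koff <- if (inherits(r, "kinetic_rates")) r$koff else r
  if (!is.numeric(koff) || any(koff <= 0))
    stop("koff must be positive", call. = FALSE)
  1 / koff
}

#' Kinetically derived equilibrium dissociation constant
#'
#' `KD = koff / kon`, the equilibrium constant implied by the rate constants.
#'
#' @param r A [kinetic_rates()] object.
#' @return KD in M.
#' @export
kinetic_kd <- function(r) {
  stopifnot(inherits(r, "kinetic_rates"))
  r$koff / r$kon
}

#' Cheng-Prusoff conversion of an IC50 to a competitor Ki
#'
#' For a competitive mass-action interaction probed at concentration `L` with
#' a probe of affinity `kd`, `Ki = IC50 / (1 + L / kd)`. Exact inverse of
#' [ic50_from_ki()].
#'
#' @param ic50 Fitted half-maximal inhibitory concentration, in M.
#' @param L Probe (labeled-ligand) concentration, in M.
#' @param kd Probe equilibrium dissociation constant, in M.
#' @return Competitor Ki in M.
#' @export
cheng_prusoff_ki <- function(ic50, L, kd) {
  check_positive(kd, "kd")
  check_nonnegative_vec(L, "L")
  if (any(ic50 <= 0)) stop("ic50 must be positive", call. = FALSE)
  ic50 / (1 + L / kd)
}

#' Expected IC50 at a given probe concentration
#'
#' The Cheng-Prusoff relation read forwards:
#' `IC50 = Ki * (1 + L/kd) = Ki + (Ki/kd) * L`, affine in the probe
#' concentration with intercept `Ki` and slope `Ki/kd`. This is the basis of
#' the IC50-versus-probe-concentration regression, whose intercept estimates
#' the competitor Ki and whose slope estimates `Ki/KD`.
#'
#' @param ki Competitor equilibrium dissociation constant, in M.
#' @param L Probe concentration, in M (vectorised).
#' @param kd Probe equilibrium dissociation constant, in M.
#' @return Expected IC50 in M.
#' @export
ic50_from_ki <- function(ki, L, kd) {
  check_positive(kd, "kd")
  check_positive(ki, "ki")
  check_nonnegative_vec(L, "L")
  ki * (1 + L / kd)
}

#' Expected signal of a competition (displacement) well
#'
#' Four-parameter inhibition curve with fixed or free slope:
#' `bottom + (top - bottom) / (1 + (I / ic50)^hill)`.
#'
#' @param I Competitor concentration, in M (vectorised, non-negative).
#' @param c A [competition_curve_params()] object.
#' @return Expected signal in ratio units; equals `top` at `I = 0` and
#'   approaches `bottom` as `I` grows.
#' @export
competition_signal <- function(I, c) {
  stopifnot(inherits(c, "competition_curve_params"))
  check_nonnegative_vec(I, "I")
  c$bottom + (c$top - c$bottom) / (1 + (I / c$ic50)^c$hill)
}

#' Sigmoidal concentration-response curve
#'
#' `basal + (emax - basal) * conc^hill / (conc^hill + ec50^hill)`; equals
#' `basal` at zero ligand and approaches `emax` at saturating ligand.
#'
#' @param conc Agonist concentration, in M (vectorised, non-negative).
#' @param p A [cr_params()] object.
#' @return Expected response in response units.
#' @export
logistic_response <- function(conc, p) {
  stopifnot(inherits(p, "cr_params"))
  check_nonnegative_vec(conc, "conc")
  ch <- conc^p$hill
  p$basal + (p$emax - p$basal) * ch / (ch + p$ec50^p$hill)
}

# ---- validation helpers -----------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  invisible(x)
}

check_nonnegative_vec <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be non-negative and finite", name), call. = FALSE)
  invisible(x)
}
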