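#' Hepatic glucose production rate
#'
#' Hill-type dependence of hepatic glucose production on the bound-receptor
#' fraction: `b_G + V_1 * r_e^n / (K1'^n + r_e^n)`. The bound receptor is the
#' species activating the cAMP-mediated glycogenolysis pathway, so the rate
#' saturates in the bound fraction, not in blood glucagon itself.
#'
#' @param r_e bound-receptor fraction (dimensionless, >= 0); vectorized.
#' @param params a [subject_params()].
#' @return Production rate (g/L/h), bounded by `b_G + V_1`, non-decreasing
#'   in `r_e`.
#' @examples
#' p <- cohort_average_params()
#' hgp_rate(0, p)          # baseline term only
#' hgp_rate(p$K1_prime, p) # half-maximal glucagon-driven production
#' @export
hgp_rate <- function(r_e, params) {
  if (any(!is.finite(r_e)) || any(r_e < 0))
    stop("'r_e' must be finite and >= 0", call. = FALSE)
  if (params$K1_prime <= 0) stop("'K1_prime' must be > 0", call. = FALSE)
  n <- params$hill_n
  params$b_G + params$V_1 * r_e^n / (params$K1_prime^n + r_e^n)
}

#' Receptor steady state at constant glucagon
#'
#' Closed-form unique attracting steady state of the free/bound receptor
#' fractions when the hepatic glucagon amount `V_h * E` is held constant.
#'
#' @param E_bar blood glucagon concentration (pmol/L, >= 0).
#' @param params a [subject_params()] (uses `k_in`, `V_h`).
#' @param fixed a [fixed_kinetics()].
#' @return A list with `r_bar` (free fraction) and `re_bar` (bound fraction);
#'   both in `[0, 1]` with `r_bar + re_bar <= 1`.
#' @examples
#' receptor_steady_state(14.3, cohort_average_params(), fixed_kinetics())
#' @export
receptor_steady_state <- function(E_bar, params, fixed = fixed_kinetics()) {
  if (!is.finite(E_bar) || E_bar < 0) stop("'E_bar' must be >= 0", call. = FALSE)
  a <- fixed$k_on * params$V_h * E_bar
  den <- (fixed$k_in_free + fixed$k_rec) * (fixed$k_off + params$k_in) +
    (params$k_in + fixed$k_rec) * a
  if (den == 0)
    stop("degenerate receptor model: all kinetic rates zero", call. = FALSE)
  list(r_bar = (fixed$k_off + params$k_in) * fixed$k_rec / den,
       re_bar = fixed$k_rec * a / den)
}

#' Receptor subsystem right-hand side
#'
#' Time derivatives of the free (`r`) and bound (`r_e`) receptor fractions,
#' with the internalized fraction eliminated through conservation
#' `r + r_e + r_i = 1`. Glucagon enters as the hepatic-interstitial amount
#' `V_h * E(t)`, an input decoupled from the receptor state.
#'
#' @param r free-receptor fraction (>= 0).
#' @param r_e bound-receptor fraction (>= 0).
#' @param E blood glucagon concentration (pmol/L, >= 0).
#' @param params a [subject_params()].
#' @param fixed a [fixed_kinetics()].
#' @return A list with `dr` and `dre` (1/h). By construction
#'   `d(r + r_e + r_i)/dt = 0`.
#' @export
receptor_rhs <- function(r, r_e, E, params, fixed = fixed_kinetics()) {
  if (any(r < 0) || any(r_e < 0) || any(E < 0))
    stop("'r', 'r_e' and 'E' must be >= 0", call. = FALSE)
  bind <- fixed$k_on * params$V_h * E * r
  list(dr = -bind + fixed$k_off * r_e - fixed$k_in_free * r +
         fixed$k_rec * (1 - r - r_e),
       dre = bind - fixed$k_off * r_e - params$k_in * r_e)
}

#' Analytic hormone trajectory during the challenge test
#'
#' During the infusion phase endogenous secretion is clamped off, so insulin
#' and glucagon follow first-order turnover with constant input and the
#' concentration relaxes exponentially from its baseline to the infusion
#' plateau `Q / (V * k_deg)`. Before `t_switch` the baseline holds.
#'
#' @param t time (h), vectorized.
#' @param baseline baseline concentration (same units as the output).
#' @param Q infusion rate during the challenge phase (amount/h).
#' @param V distribution volume (L, > 0).
#' @param k_deg first-order clearance (1/h, > 0).
#' @param t_switch challenge start (h).
#' @return Concentration at `t`; continuous at `t_switch`, monotone between
#'   baseline and plateau.
#' @examples
#' pr <- protocol()
#' hormone_trajectory(c(3, 4, 6), 14.3, pr$Q_E, pr$V_E, 5.73)
#' @export
hormone_trajectory <- function(t, baseline, Q, V, k_deg, t_switch = 3) {
  if (!is.finite(k_deg) || k_deg <= 0) stop("'k_deg' must be > 0", call. = FALSE)
  if (!is.finite(V) || V <= 0) stop("'V' must be > 0", call. = FALSE)
  c_inf <- Q / (V * k_deg)
  out <- rep(baseline, length(t))
  ph2 <- t >= t_switch
  out[ph2] <- c_inf + (baseline - c_inf) * exp(-k_deg * (t[ph2] - t_switch))
  out
}

#' Glucose balance right-hand side
#'
#' `dG/dt = Q_G(t)/V_G + F_hgp(r_e) - V_ii G/(K_ii+G) - V_id I G/(K_id+G)`:
#' infusion, Hill-type hepatic production, and Michaelis-Menten
#' insulin-independent and insulin-dependent consumption.
#'
#' @param G blood glucose (g/L, > 0 — required because `K_ii` may be 0,
#'   making the insulin-independent term discontinuous at 0).
#' @param I blood insulin (mU/L).
#' @param r_e bound-receptor fraction.
#' @param params a [subject_params()].
#' @param prot a [protocol()] (for the infusion term).
#' @param t time (h); determines whether the glucose infusion is on.
#' @param fixed a [fixed_kinetics()] (for `K_ii`).
#' @return dG/dt (g/L/h).
#' @export
glucose_rhs <- function(G, I, r_e, params, prot = protocol(), t = 0,
                        fixed = fixed_kinetics()) {
  if (any(G <= 0) && fixed$K_ii == 0)
    stop("'G' must be > 0 when K_ii = 0", call. = FALSE)
  if (any(G < 0)) stop("'G' must be >= 0", call. = FALSE)
  q <- infusion_rates(prot, t)
  q$Q_G / prot$V_G + hgp_rate(r_e, params) -
    params$V_ii * G / (fixed$K_ii + G) -
    params$V_id * I * G / (params$K_id + G)
}

#' Full system right-hand side
#'
#' Stacked derivatives of `(G, I, E, r, r_e)`. Hormones follow first-order
#' turnover (infusion plus clearance; one-way coupling — they drive glucose
#' and the receptor but are not affected by them). When a `baseline` is
#' supplied and `t < t_switch`, basal endogenous secretion terms
#' `F_I = k_degI * I_bar` and `F_E = k_degE * E_bar` are included, so the
#' baseline state is an exact steady state of the baseline-phase model.
#'
#' @param state named numeric vector or list with `G`, `I`, `E`, `r`, `r_e`.
#' @param t time (h).
#' @param params a [subject_params()].
#' @param prot a [protocol()].
#' @param fixed a [fixed_kinetics()].
#' @param baseline optional [baseline_state()]; enables the basal secretion
#'   terms during the baseline phase.
#' @return Named numeric vector of derivatives `(dG, dI, dE, dr, dre)`.
#' @export
system_rhs <- function(state, t, params, prot = protocol(),
                       fixed = fixed_kinetics(), baseline = NULL) {
  state <- as.list(state)
  q <- infusion_rates(prot, t)
  FI <- 0
  FE <- 0
  if (!is.null(baseline) && t < prot$t_switch) {
    FI <- baseline$F_I_bar
    FE <- baseline$F_E_bar
  }
  dI <- q$Q_I / prot$V_I + FI - params$k_degI * state$I
  dE <- q$Q_E / prot$V_E + FE - params$k_degE * state$E
  rec <- receptor_rhs(state$r, state$r_e, state$E, params, fixed)
  dG <- glucose_rhs(state$G, state$I, state$r_e, params, prot, t, fixed)
  c(dG = dG, dI = dI, dE = dE, dr = rec$dr, dre = rec$dre)
}

#' Eliminate baseline-constrained parameters
#'
#' The baseline steady state of the glucose balance ties two parameters to
#' the others: given the basal production rate `Fhgp_bar`, the baseline
#' production/clearance balance yields
#' `b_G = Fhgp_bar - V_1 re_bar^n / (K1'^n + re_bar^n)` and
#' `V_ii = (Fhgp_bar - V_id I_bar G_bar/(K_id+G_bar)) * (K_ii+G_bar)/G_bar`.
#' Substituting them back makes the baseline glucose equation hold
#' identically, which is how the estimator enforces the steady-state
#' constraints exactly rather than as penalties.
#'
#' @param baseline a [baseline_state()].
#' @param params a [subject_params()] supplying the free parameters
#'   (`V_1`, `K1_prime`, `V_id`, `K_id`, `hill_n`).
#' @param fixed a [fixed_kinetics()] (for `K_ii`).
#' @return A list with `b_G` and `V_ii`. A warning (not an error) is raised
#'   if either eliminated value is negative, a sign that the free parameters
#'   are inconsistent with the measured baseline.
#' @export
eliminate_baseline_params <- function(baseline, params, fixed = fixed_kinetics()) {
  if (params$K_id + baseline$G_bar <= 0)
    stop("'K_id + G_bar' must be > 0", call. = FALSE)
  if (baseline$G_bar <= 0) stop("baseline glucose must be > 0", call. = FALSE)
  n <- params$hill_n
  re <- baseline$re_bar
  b_G <- baseline$Fhgp_bar -
    params$V_1 * re^n / (params$K1_prime^n + re^n)
  id_clear <- params$V_id * baseline$I_bar * baseline$G_bar /
    (params$K_id + baseline$G_bar)
  V_ii <- (baseline$Fhgp_bar - id_clear) *
    (fixed$K_ii + baseline$G_bar) / baseline$G_bar
  if (b_G < 0 || V_ii < 0)
    warning("eliminated baseline parameter negative (b_G = ",
            signif(b_G, 4), ", V_ii = ", signif(V_ii, 4), ")", call. = FALSE)
  list(b_G = b_G, V_ii = V_ii)
}

#' Baseline steady state of the full model
#'
#' Assembles the baseline (first 3 h) steady state: measured baseline
#' concentrations, receptor fractions from the closed-form steady state at
#' the baseline glucagon level, the basal hepatic glucose production rate,
#' and the derived basal secretion rates `F_I = k_degI * I_bar`,
#' `F_E = k_degE * E_bar` (present only in the baseline phase, never fitted).
#'
#' @param G_bar baseline glucose (g/L).
#' @param I_bar baseline insulin (mU/L).
#' @param E_bar baseline glucagon (pmol/L).
#' @param params a [subject_params()].
#' @param fixed a [fixed_kinetics()].
#' @param Fhgp_bar basal hepatic glucose production (g/h/L); if `NULL`,
#'   computed self-consistently from the model as `hgp_rate(re_bar)`.
#' @return An object of class `baseline_state` with fields `G_bar`, `I_bar`,
#'   `E_bar`, `r_bar`, `re_bar`, `Fhgp_bar`, `F_I_bar`, `F_E_bar`.
#' @examples
#' baseline_state(0.9, 10, 14.3, cohort_average_params())
#' @export
baseline_state <- function(G_bar, I_bar, E_bar, params,
                           fixed = fixed_kinetics(), Fhgp_bar = NULL) {
  if (any(c(G_bar, I_bar, E_bar) < 0))
    stop("baseline concentrations must be >= 0", call. = FALSE)
  ss <- receptor_steady_state(E_bar, params, fixed)
  if (is.null(Fhgp_bar)) Fhgp_bar <- hgp_rate(ss$re_bar, params)
  if (Fhgp_bar <= 0) stop("'Fhgp_bar' must be > 0", call. = FALSE)
  structure(list(G_bar = G_bar, I_bar = I_bar, E_bar = E_bar,
                 r_bar = ss$r_bar, re_bar = ss$re_bar,
                 Fhgp_bar = Fhgp_bar,
                 F_I_bar = params$k_degI * I_bar,
                 F_E_bar = params$k_degE * E_bar),
            class = "baseline_state")
}

#' @export
print.baseline_state <- function(x, ...) {
  cat("Baseline steady state:\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Population-average kinetic parameters of the reference cohort
#'
#' Convenience constructor: the before-treatment cohort-average parameter
#' vector used as the default center of the synthetic population and as a
#' generic initial guess for estimation.
#'
#' @param visit `"before"` (default) or `"after"` treatment averages.
#' @return A [subject_params()].
#' @export
cohort_average_params <- function(visit = c("before", "after")) {
  visit <- match.arg(visit)
  if (visit == "before")
    subject_params(b_G = 0.0804, V_1 = 5.63, K1_prime = 0.00501,
                   V_ii = 0.896, V_id = 1.52, K_id = 11,
                   k_degI = 30.5, k_degE = 5.73, k_in = 21.5, V_h = 4.65)
  else
    subject_params(b_G = 0.18, V_1 = 6.81, K1_prime = 0.0109,
                   V_ii = 0.936, V_id = 1.66, K_id = 10.3,
                   k_degI = 30.9, k_degE = 5.76, k_in = 12.1, V_h = 4.96)
}
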