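#' Default observation schedule
#'
#' The study's sampling grid: 16 time points from 135 to 360 minutes (four
#' baseline-phase samples, twelve infusion-phase samples). The fourth time is
#' 179 min, as in the study design.
#'
#' @param times_min strictly increasing sampling times in minutes.
#' @return An object of class `observation_schedule`.
#' @export
observation_schedule <- function(times_min = c(135, 150, 165, 179, 195, 210,
                                               225, 240, 255, 270, 285, 300,
                                               315, 330, 345, 360)) {
  if (any(diff(times_min) <= 0))
    stop("'times_min' must be strictly increasing", call. = FALSE)
  structure(list(times_min = times_min, times_h = times_min / 60),
            class = "observation_schedule")
}

#' Measurement-noise model
#'
#' Independent multiplicative Gaussian noise per channel:
#' `observed = value * (1 + CV * z)`, `z ~ N(0,1)`. Proportional noise
#' matches typical assay behavior and keeps channels positive at these CVs.
#'
#' @param cv_G,cv_I,cv_E,cv_Fhgp,cv_Rd coefficient of variation per channel.
#' @param seed optional integer; if set, [observe()] draws are reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_G = 0.05, cv_I = 0.10, cv_E = 0.10,
                        cv_Fhgp = 0.10, cv_Rd = 0.10, seed = NULL) {
  cvs <- c(cv_G = cv_G, cv_I = cv_I, cv_E = cv_E, cv_Fhgp = cv_Fhgp, cv_Rd = cv_Rd)
  if (any(cvs < 0)) stop("coefficients of variation must be >= 0", call. = FALSE)
  structure(list(cv_G = cv_G, cv_I = cv_I, cv_E = cv_E,
                 cv_Fhgp = cv_Fhgp, cv_Rd = cv_Rd, seed = seed),
            class = "noise_model")
}

#' Forward-simulate one challenge-test visit
#'
#' Phase 1 (baseline) is the exact steady state, held constant; phase 2
#' integrates the coupled glucose/hormone/receptor system from the baseline
#' initial conditions with a stiff-capable adaptive integrator (the receptor
#' subsystem mixes rates from 0.18/h to ~36/h). The hepatic glucose
#' production rate and the disposal rate are evaluated along the trajectory
#' as the model's derived observables.
#'
#' @param params a [subject_params()].
#' @param prot a [protocol()].
#' @param fixed a [fixed_kinetics()].
#' @param baseline a [baseline_state()]; if `NULL`, built self-consistently
#'   from `G_bar`, `I_bar`, `E_bar`.
#' @param G_bar,I_bar,E_bar baseline concentrations used when `baseline` is
#'   `NULL`.
#' @param dense_grid output times (h); defaults to a 0.01 h grid over the
#'   whole test.
#' @param rtol,atol integrator tolerances.
#' @return A data frame of class `gct_trajectory` with columns `time_h`,
#'   `G`, `I`, `E`, `r`, `r_e`, `r_i`, `F_hgp`, `Rd`.
#' @examples
#' tr <- simulate_subject(cohort_average_params(), E_bar = 14.3)
#' max(tr$G)
#' @export
simulate_subject <- function(params, prot = protocol(),
                             fixed = fixed_kinetics(), baseline = NULL,
                             G_bar = 0.9, I_bar = 10, E_bar = 14.3,
                             dense_grid = NULL,
                             rtol = 1e-10, atol = 1e-12) {
  if (is.null(baseline))
    baseline <- baseline_state(G_bar, I_bar, E_bar, params, fixed)
  if (is.null(dense_grid))
    dense_grid <- seq(0, prot$t_end, by = 0.01)
  # a protocol without any infusion means the clamp never starts: endogenous
  # secretion continues and the baseline steady state persists throughout
  null_protocol <- prot$Q_G == 0 && prot$Q_I == 0 && prot$Q_E == 0
  t_switch <- if (null_protocol) Inf else prot$t_switch
  dense_grid <- sort(unique(c(dense_grid,
                              if (!null_protocol) prot$t_switch)))
  t1 <- dense_grid[dense_grid < t_switch]
  t2 <- dense_grid[dense_grid >= t_switch]

  # phase 1: exact steady state (basal secretion balances clearance)
  mk_const <- function(tt) data.frame(
    time_h = tt,
    G = rep(baseline$G_bar, length(tt)), I = rep(baseline$I_bar, length(tt)),
    E = rep(baseline$E_bar, length(tt)), r = rep(baseline$r_bar, length(tt)),
    r_e = rep(baseline$re_bar, length(tt)))
  ph1 <- mk_const(t1)

  if (length(t2)) {
    y0 <- c(G = baseline$G_bar, I = baseline$I_bar, E = baseline$E_bar,
            r = baseline$r_bar, r_e = baseline$re_bar)
    dfun <- function(t, y, parms) {
      list(unname(system_rhs(y, t, params, prot, fixed, baseline)))
    }
    sol <- tryCatch(
      deSolve::lsoda(y0, times = t2, func = dfun, parms = NULL,
                     rtol = rtol, atol = atol),
      warning = function(w) stop("integrator failure: ", conditionMessage(w),
                                 call. = FALSE)
    )
    ph2 <- as.data.frame(sol)
    names(ph2)[1] <- "time_h"
    out <- rbind(ph1, ph2[, c("time_h", "G", "I", "E", "r", "r_e")])
  } else {
    out <- ph1
  }
  out$r_i <- 1 - out$r - out$r_e
  out$F_hgp <- hgp_rate(pmax(out$r_e, 0), params)
  out$Rd <- params$V_ii * out$G / (fixed$K_ii + out$G) +
    params$V_id * out$I * out$G / (params$K_id + out$G)
  attr(out, "params") <- params
  attr(out, "baseline") <- baseline
  attr(out, "protocol") <- prot
  attr(out, "fixed") <- fixed
  class(out) <- c("gct_trajectory", "data.frame")
  out
}

#' Sample a noiseless trajectory into a noisy observation record
#'
#' Evaluates each observable channel of a simulated trajectory at the
#' schedule times (linear interpolation on the dense grid) and applies the
#' multiplicative noise model. Zero CVs reproduce the model exactly; an
#' identical seed reproduces identical draws.
#'
#' @param trajectory a `gct_trajectory` from [simulate_subject()].
#' @param schedule an [observation_schedule()].
#' @param noise a [noise_model()].
#' @param subject_id identifier stored in the record.
#' @param visit `"before"` or `"after"`.
#' @return An object of class `subject_record`: a list with `subject_id`,
#'   `visit`, `time_min`, the observed series `G`, `I`, `E`, `F_hgp`, `Rd`,
#'   and (for synthetic data) `true_params`/`true_baseline` attributes.
#' @export
observe <- function(trajectory, schedule = observation_schedule(),
                    noise = noise_model(), subject_id = "S01",
                    visit = c("before", "after")) {
  visit <- match.arg(visit)
  th <- schedule$times_h
  if (min(th) < min(trajectory$time_h) || max(th) > max(trajectory$time_h))
    stop("schedule outside the simulated time span", call. = FALSE)
  chan <- function(col) approx(trajectory$time_h, trajectory[[col]], th)$y
  vals <- list(G = chan("G"), I = chan("I"), E = chan("E"),
               F_hgp = chan("F_hgp"), Rd = chan("Rd"))
  cvs <- c(G = noise$cv_G, I = noise$cv_I, E = noise$cv_E,
           F_hgp = noise$cv_Fhgp, Rd = noise$cv_Rd)
  draw <- function() {
    for (nm in names(vals))
      vals[[nm]] <<- vals[[nm]] * (1 + cvs[[nm]] * rnorm(length(th)))
  }
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(noise$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    draw()
  } else draw()
  structure(list(subject_id = subject_id, visit = visit,
                 time_min = schedule$times_min,
                 G = vals$G, I = vals$I, E = vals$E,
                 F_hgp = vals$F_hgp, Rd = vals$Rd,
                 true_params = attr(trajectory, "params"),
                 true_baseline = attr(trajectory, "baseline")),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject record %s (%s): %d samples, %g-%g min\n",
              x$subject_id, x$visit, length(x$time_min),
              min(x$time_min), max(x$time_min)))
  invisible(x)
}

#' Synthetic-cohort specification
#'
#' Population distribution of the per-subject parameters (independent
#' truncated normals) and the treatment effect. Defaults are the
#' before-treatment cohort averages and standard deviations of the reference
#' study; the default treatment multiplies the apparent dissociation
#' constant `K1_prime` by 0.0109/0.00501 (~2.18), i.e. roughly halves the
#' total receptor number, and leaves all other parameters untouched.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param param_mean,param_sd named numeric vectors of population means and
#'   SDs for the drawn parameters (`V_1`, `K1_prime`, `V_id`, `K_id`,
#'   `k_degI`, `k_degE`, `k_in`, `V_h`, `b_G`) and baselines (`G_bar`,
#'   `I_bar`, `E_bar`).
#' @param treatment_K1prime_multiplier multiplicative after/before change of
#'   `K1_prime` (> 0).
#' @param treatment_effects optional named list of additional multiplicative
#'   effects on other drawn parameters (default: none).
#' @param seed integer cohort seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 8,
                        param_mean = NULL, param_sd = NULL,
                        treatment_K1prime_multiplier = 0.0109 / 0.00501,
                        treatment_effects = NULL,
                        seed = 1L) {
  def_mean <- c(V_1 = 5.63, K1_prime = 0.00501, V_id = 1.52, K_id = 11,
                k_degI = 30.5, k_degE = 5.73, k_in = 21.5, V_h = 4.65,
                b_G = 0.0804, G_bar = 0.9, I_bar = 10, E_bar = 14.3)
  def_sd <- c(V_1 = 1.97, K1_prime = 0.00257, V_id = 0.963, K_id = 6.62,
              k_degI = 8.27, k_degE = 1.84, k_in = 15.2, V_h = 2.28,
              b_G = 0.228, G_bar = 0.09, I_bar = 1.0, E_bar = 1.4)
  pm <- def_mean
  ps <- def_sd
  if (!is.null(param_mean)) pm[names(param_mean)] <- param_mean
  if (!is.null(param_sd)) ps[names(param_sd)] <- param_sd
  if (n_subjects < 2) stop("'n_subjects' must be >= 2", call. = FALSE)
  if (treatment_K1prime_multiplier <= 0)
    stop("'treatment_K1prime_multiplier' must be > 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 param_mean = pm, param_sd = ps,
                 treatment_K1prime_multiplier = treatment_K1prime_multiplier,
                 treatment_effects = treatment_effects,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# one positive draw from a truncated normal, by rejection
rtruncpos <- function(mean, sd, lower = 1e-12, tries = 1000L) {
  for (i in seq_len(tries)) {
    x <- rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
  stop("failed to draw a positive parameter (mean = ", mean,
       ", sd = ", sd, ")", call. = FALSE)
}

# basal production rate for a parameter set at a baseline glucagon level
.basal_hgp <- function(p, E_bar, fixed)
  hgp_rate(receptor_steady_state(E_bar, p, fixed)$re_bar, p)

# draw one self-consistent subject: kinetics and baselines from the
# population distribution. The before-visit insulin-independent clearance
# V_ii closes the baseline balance. For the after visit all parameters
# except the treated K1_prime are held fixed and the fasting glucose
# re-equilibrates to the new basal production (the physiological response
# to a change in receptor number); when the required fasting level falls
# outside a +/-30% physiological window, the baseline is clamped to the
# window edge and V_ii absorbs the remainder. Draws with a non-positive
# clearance are rejected.
draw_subject <- function(spec, fixed, tries = 200L) {
  pm <- spec$param_mean
  ps <- spec$param_sd
  for (i in seq_len(tries)) {
    d <- setNames(vapply(names(pm), function(nm) {
      lower <- if (nm == "b_G") 0 else 1e-12
      if (ps[[nm]] == 0) pm[[nm]] else rtruncpos(pm[[nm]], ps[[nm]], lower)
    }, numeric(1)), names(pm))
    p <- subject_params(b_G = d[["b_G"]], V_1 = d[["V_1"]],
                        K1_prime = d[["K1_prime"]], V_ii = 0,
                        V_id = d[["V_id"]], K_id = d[["K_id"]],
                        k_degI = d[["k_degI"]], k_degE = d[["k_degE"]],
                        k_in = d[["k_in"]], V_h = d[["V_h"]])
    p_after <- p
    p_after$K1_prime <- p$K1_prime * spec$treatment_K1prime_multiplier
    if (!is.null(spec$treatment_effects))
      for (nm in names(spec$treatment_effects))
        p_after[[nm]] <- p_after[[nm]] * spec$treatment_effects[[nm]]
    id_clear <- function(G) d[["V_id"]] * d[["I_bar"]] * G /
      (d[["K_id"]] + G)
    V_ii <- .basal_hgp(p, d[["E_bar"]], fixed) - id_clear(d[["G_bar"]])
    if (V_ii <= 0) next
    p$V_ii <- V_ii
    Fa <- .basal_hgp(p_after, d[["E_bar"]], fixed)
    cc <- Fa - V_ii
    G_after <- if (cc > 0 && cc < d[["V_id"]] * d[["I_bar"]])
      cc * d[["K_id"]] / (d[["V_id"]] * d[["I_bar"]] - cc) else
        (if (cc <= 0) 0 else Inf)
    G_lo <- 0.7 * d[["G_bar"]]
    G_hi <- 1.3 * d[["G_bar"]]
    V_ii_a <- V_ii
    if (G_after < G_lo || G_after > G_hi) {
      G_after <- if (G_after < G_lo) G_lo else G_hi
      V_ii_a <- Fa - id_clear(G_after)
      if (V_ii_a <= 0) next
    }
    p_after$V_ii <- V_ii_a
    return(list(params = p, params_after = p_after,
                G_bar = d[["G_bar"]], G_bar_after = G_after,
                I_bar = d[["I_bar"]], E_bar = d[["E_bar"]]))
  }
  stop("cohort generation failure: could not draw a subject with ",
       "physiological steady states at both visits", call. = FALSE)
}

#' Generate a seeded paired before/after cohort
#'
#' Draws one parameter vector per subject from the population distribution,
#' applies the treatment effect to the after-visit parameters, re-derives the
#' after-visit baseline balance (the basal production rate changes when
#' `K1_prime` changes), simulates both visits, and samples them through the
#' noise model. Ground truth is retained for recovery studies.
#'
#' @param spec a [cohort_spec()].
#' @param prot a [protocol()].
#' @param fixed a [fixed_kinetics()].
#' @param noise a [noise_model()]; per-record observation seeds are derived
#'   from the cohort seed, so a fixed cohort seed gives a bitwise-identical
#'   cohort.
#' @return A list of class `paired_cohort`: one element per subject, each a
#'   list with `before` and `after` [observe()] records; the ground-truth
#'   parameter table is in `attr(, "ground_truth")`.
#' @examples
#' \donttest{
#' coh <- generate_paired_cohort(cohort_spec(n_subjects = 2, seed = 7))
#' coh[[1]]$before
#' }
#' @export
generate_paired_cohort <- function(spec = cohort_spec(), prot = protocol(),
                                   fixed = fixed_kinetics(),
                                   noise = noise_model()) {
  set.seed(spec$seed)
  schedule <- observation_schedule()
  grid <- sort(unique(c(seq(0, prot$t_end, by = 0.01), schedule$times_h)))
  subjects <- vector("list", spec$n_subjects)
  truth <- list()
  for (s in seq_len(spec$n_subjects)) {
    dr <- draw_subject(spec, fixed)
    id <- sprintf("S%02d", s)
    p_before <- dr$params
    p_after <- dr$params_after
    recs <- list()
    for (v in c("before", "after")) {
      p <- if (v == "before") p_before else p_after
      tr <- simulate_subject(p, prot, fixed,
                             G_bar = if (v == "before") dr$G_bar else
                               dr$G_bar_after,
                             I_bar = dr$I_bar, E_bar = dr$E_bar,
                             dense_grid = grid)
      nz <- noise
      nz$seed <- (spec$seed * 1000L + s * 2L +
                    (if (v == "after") 1L else 0L)) %% .Machine$integer.max
      recs[[v]] <- observe(tr, schedule, nz, subject_id = id, visit = v)
    }
    subjects[[s]] <- recs
    truth[[length(truth) + 1L]] <- data.frame(
      subject_id = id, visit = c("before", "after"),
      rbind(as.data.frame(unclass(p_before)), as.data.frame(unclass(p_after))),
      G_bar = c(dr$G_bar, dr$G_bar_after), I_bar = dr$I_bar,
      E_bar = dr$E_bar)
  }
  structure(subjects, class = "paired_cohort",
            ground_truth = do.call(rbind, truth), spec = spec)
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("Paired synthetic cohort: %d subjects x 2 visits\n", length(x)))
  invisible(x)
}
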