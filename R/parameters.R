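#' Fixed receptor-kinetic constants
#'
#' Rate constants of the glucagon-receptor cycle that are not fitted per
#' subject: association/dissociation of glucagon and free receptor, recycling
#' of internalized receptor, internalization of *free* receptor, and the
#' Michaelis-Menten constant of insulin-independent glucose consumption.
#' Defaults are literature values for a GPCR of this class; `k_in_free` and
#' `K_ii` default to zero (both collapse to zero during estimation and are
#' kept as fields only so the pre-collapse model remains expressible).
#'
#' @param k_on association rate of glucagon and free receptor (1/pmol/h).
#' @param k_off dissociation rate of the glucagon-receptor complex (1/h).
#' @param k_rec recycling rate of internalized receptor to the surface (1/h).
#' @param k_in_free internalization rate of free receptor (1/h).
#' @param K_ii Michaelis-Menten constant of insulin-independent glucose
#'   consumption (g/L).
#' @return An object of class `fixed_kinetics`.
#' @examples
#' fixed_kinetics()
#' @export
fixed_kinetics <- function(k_on = 3.6e-3, k_off = 14.4, k_rec = 0.18,
                           k_in_free = 0, K_ii = 0) {
  fk <- list(k_on = k_on, k_off = k_off, k_rec = k_rec,
             k_in_free = k_in_free, K_ii = K_ii)
  for (nm in names(fk)) {
    v <- fk[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single non-negative finite number", call. = FALSE)
  }
  structure(fk, class = "fixed_kinetics")
}

#' Per-subject kinetic parameters
#'
#' The parameter vector fitted per subject and visit. Rates carry units of
#' g/L/h (`b_G`, `V_1`, `V_ii`), (g/L/h)/(mU/L) (`V_id`) or 1/h (clearances,
#' internalization); `K1_prime` is the apparent dissociation constant of the
#' Hill-type hepatic-glucose-production response, equal to the binding
#' constant scaled by the total receptor number, hence dimensionless on the
#' bound-fraction scale and inversely proportional to the receptor count.
#' The Hill coefficient is fixed at 2 by default; freeing it makes the model
#' strongly nonlinear in the parameter and is not supported by the estimator.
#'
#' @param b_G baseline (receptor-independent) hepatic glucose production
#'   rate (g/L/h).
#' @param V_1 maximal glucagon-dependent hepatic glucose production (g/L/h).
#' @param K1_prime apparent dissociation constant on the bound-receptor
#'   fraction scale (dimensionless, > 0).
#' @param V_ii maximal insulin-independent glucose consumption (g/L/h).
#' @param V_id maximal insulin-dependent glucose consumption
#'   ((g/L/h)/(mU/L)).
#' @param K_id Michaelis-Menten constant of insulin-dependent consumption
#'   (g/L).
#' @param k_degI first-order insulin clearance (1/h).
#' @param k_degE first-order glucagon clearance (1/h).
#' @param k_in internalization rate of the bound receptor (1/h).
#' @param V_h apparent volume of the hepatic interstitial space (L).
#' @param hill_n Hill coefficient (fixed 2 unless explicitly overridden).
#' @return An object of class `subject_params`.
#' @examples
#' subject_params(b_G = 0.0804, V_1 = 5.63, K1_prime = 0.00501,
#'                V_ii = 0.896, V_id = 1.52, K_id = 11, k_degI = 30.5,
#'                k_degE = 5.73, k_in = 21.5, V_h = 4.65)
#' @export
subject_params <- function(b_G, V_1, K1_prime, V_ii, V_id, K_id,
                           k_degI, k_degE, k_in, V_h, hill_n = 2) {
  p <- list(b_G = b_G, V_1 = V_1, K1_prime = K1_prime, V_ii = V_ii,
            V_id = V_id, K_id = K_id, k_degI = k_degI, k_degE = k_degE,
            k_in = k_in, V_h = V_h, hill_n = hill_n)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single non-negative finite number", call. = FALSE)
  }
  if (K1_prime <= 0) stop("'K1_prime' must be > 0", call. = FALSE)
  structure(p, class = "subject_params")
}

#' Challenge-test protocol
#'
#' Infusion rates, distribution volumes and phase timing of the 6 h test.
#' Infusions are zero during the baseline phase (`t < t_switch`) and constant
#' afterwards. The default glucagon distribution volume is 19.6 L, the value
#' consistent with the designed 2-3-fold glucagon rise at the default
#' clearance rate; it is configurable.
#'
#' @param Q_G glucose infusion rate during the challenge phase (g/h).
#' @param Q_I insulin infusion rate (mU/h).
#' @param Q_E glucagon infusion rate (pmol/h).
#' @param V_G,V_I,V_E distribution volumes (L) of glucose, insulin, glucagon.
#' @param t_switch start of the infusion phase (h).
#' @param t_end end of the test (h).
#' @return An object of class `protocol`.
#' @examples
#' protocol()
#' @export
protocol <- function(Q_G = 0.24, Q_I = 480, Q_E = 4134.7,
                     V_G = 4.44, V_I = 1.52, V_E = 19.6,
                     t_switch = 3, t_end = 6) {
  pr <- list(Q_G = Q_G, Q_I = Q_I, Q_E = Q_E,
             V_G = V_G, V_I = V_I, V_E = V_E,
             t_switch = t_switch, t_end = t_end)
  for (nm in names(pr)) {
    v <- pr[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single non-negative finite number", call. = FALSE)
  }
  if (any(c(V_G, V_I, V_E) <= 0)) stop("distribution volumes must be > 0", call. = FALSE)
  if (t_end <= t_switch) stop("'t_end' must exceed 't_switch'", call. = FALSE)
  structure(pr, class = "protocol")
}

#' Infusion rates at a given time
#'
#' @param prot a [protocol()].
#' @param t time (h), vectorized.
#' @return A list with components `Q_G`, `Q_I`, `Q_E` (same length as `t`):
#'   zero before `t_switch`, the protocol constants afterwards.
#' @export
infusion_rates <- function(prot, t) {
  on <- as.numeric(t >= prot$t_switch)
  list(Q_G = prot$Q_G * on, Q_I = prot$Q_I * on, Q_E = prot$Q_E * on)
}

#' @export
print.subject_params <- function(x, ...) {
  cat("Subject kinetic parameters:\n")
  print(unlist(x), ...)
  invisible(x)
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("Challenge-test protocol: baseline 0-%g h, infusion %g-%g h\n",
              x$t_switch, x$t_switch, x$t_end))
  cat(sprintf("  Q_G=%g g/h, Q_I=%g mU/h, Q_E=%g pmol/h\n", x$Q_G, x$Q_I, x$Q_E))
  cat(sprintf("  V_G=%g L, V_I=%g L, V_E=%g L\n", x$V_G, x$V_I, x$V_E))
  invisible(x)
}
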