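test_that("Hill-type production rate has the right anchors and shape", {
  p <- cohort_average_params()

  expect_equal(hgp_rate(0, p), p$b_G)                       # term vanishes
  expect_equal(hgp_rate(p$K1_prime, p), p$b_G + p$V_1 / 2)  # half-max at K1'
  # frozen value from direct evaluation of b + V*re^2/(K'^2+re^2) at the
  # reference averages and the baseline bound fraction
  expect_equal(hgp_rate(0.0037, p), 2.06736832439205, tolerance = 1e-9)

  re <- seq(0, 0.05, length.out = 200)
  f <- hgp_rate(re, p)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f <= p$b_G + p$V_1))

  expect_error(hgp_rate(-0.1, p), "r_e")
  p_bad <- p
  p_bad$K1_prime <- 0
  expect_error(hgp_rate(0.1, p_bad), "K1_prime")
})

test_that("receptor steady state matches its closed form and the ODE limit", {
  p <- cohort_average_params()
  fk <- fixed_kinetics()

  # no ligand, no free-receptor internalization: all receptor on the surface
  ss0 <- receptor_steady_state(0, p, fk)
  expect_equal(ss0$r_bar, 1)
  expect_equal(ss0$re_bar, 0)

  # reference baseline: frozen against long-horizon integration at constant
  # glucagon (oracle rerun below at lower precision)
  ss <- receptor_steady_state(14.3, p, fk)
  expect_equal(ss$r_bar, 0.5546, tolerance = 1e-3)
  expect_equal(ss$re_bar, 0.0037, tolerance = 1e-2)

  # rhs vanishes at the fixed point, fractions conserved
  d <- receptor_rhs(ss$r_bar, ss$re_bar, 14.3, p, fk)
  expect_equal(d$dr, 0, tolerance = 1e-14)
  expect_equal(d$dre, 0, tolerance = 1e-14)
  expect_true(ss$r_bar + ss$re_bar <= 1)

  # oracle: integrate the receptor equations (written out independently)
  # from several initial conditions to the attractor
  rhs <- function(t, y, parms) {
    bind <- fk$k_on * p$V_h * 14.3 * y[1]
    list(c(-bind + fk$k_off * y[2] + fk$k_rec * (1 - y[1] - y[2]),
           bind - fk$k_off * y[2] - p$k_in * y[2]))
  }
  for (y0 in list(c(1, 0), c(0.2, 0.1), c(0, 0))) {
    out <- deSolve::lsoda(y0, c(0, 200), rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(out[2, 2]), ss$r_bar, tolerance = 1e-7)
    expect_equal(unname(out[2, 3]), ss$re_bar, tolerance = 1e-7)
  }

  expect_error(
    receptor_steady_state(5, subject_params(b_G = 0, V_1 = 0, K1_prime = 1,
                                            V_ii = 0, V_id = 0, K_id = 1,
                                            k_degI = 1, k_degE = 1, k_in = 0,
                                            V_h = 0),
                          fixed_kinetics(k_on = 0, k_off = 0, k_rec = 0)),
    "degenerate")
})

test_that("hormone trajectories are continuous, monotone and hit the plateau", {
  pr <- protocol()

  # continuity at the switch and the baseline before it
  expect_equal(hormone_trajectory(c(0, 1, 3), 14.3, pr$Q_E, pr$V_E, 5.73),
               rep(14.3, 3))
  # frozen plateaus: Q/(V k); glucagon ~36.8 pmol/L (2.6x baseline),
  # insulin ~10.35 mU/L (the clamp target)
  expect_equal(hormone_trajectory(1e3, 14.3, pr$Q_E, pr$V_E, 5.73),
               36.8157, tolerance = 1e-4)
  expect_equal(hormone_trajectory(1e3, 10, pr$Q_I, pr$V_I, 30.5),
               10.3537, tolerance = 1e-4)

  tt <- seq(3, 6, by = 0.01)
  e <- hormone_trajectory(tt, 14.3, pr$Q_E, pr$V_E, 5.73)
  expect_true(all(diff(e) > 0))
  expect_true(all(e >= 14.3 & e <= 36.816))

  expect_error(hormone_trajectory(1, 10, 480, 1.52, 0), "k_deg")
  expect_error(hormone_trajectory(1, 10, 480, 0, 30.5), "V")
})

test_that("hormone closed forms agree with numerical integration", {
  pr <- protocol()
  for (ch in list(list(b = 14.3, Q = pr$Q_E, V = pr$V_E, k = 5.73),
                  list(b = 10, Q = pr$Q_I, V = pr$V_I, k = 30.5))) {
    rhs <- function(t, y, parms) list(ch$Q / ch$V - ch$k * y)
    tt <- seq(3, 6, by = 0.25)
    num <- deSolve::lsoda(ch$b, tt, rhs, parms = NULL,
                          rtol = 1e-11, atol = 1e-13)[, 2]
    ana <- hormone_trajectory(tt, ch$b, ch$Q, ch$V, ch$k)
    expect_equal(num, ana, tolerance = 1e-8)
  }
})

test_that("baseline elimination closes the steady state exactly", {
  p <- avg_subject()
  fk <- fixed_kinetics()
  bl <- baseline_state(0.9, 10, 14.3, p, fk)

  # round trip: generating b_G is recovered from the model-consistent Fhgp
  el <- eliminate_baseline_params(bl, p, fk)
  expect_equal(el$b_G, p$b_G, tolerance = 1e-12)
  expect_equal(el$V_ii, p$V_ii, tolerance = 1e-12)

  # degenerate reductions
  p0 <- p
  p0$V_1 <- 0
  expect_equal(eliminate_baseline_params(bl, p0, fk)$b_G, bl$Fhgp_bar)
  p0 <- p
  p0$V_id <- 0
  expect_equal(eliminate_baseline_params(bl, p0, fk)$V_ii, bl$Fhgp_bar)

  # negative eliminated value warns, never errors
  p_neg <- p
  p_neg$V_id <- 50
  expect_warning(eliminate_baseline_params(bl, p_neg, fk), "negative")

  # with the eliminated parameters in place the full rhs is the zero vector
  state <- c(G = bl$G_bar, I = bl$I_bar, E = bl$E_bar,
             r = bl$r_bar, r_e = bl$re_bar)
  d <- system_rhs(state, 1, p, protocol(), fk, baseline = bl)
  expect_equal(unname(d), rep(0, 5), tolerance = 1e-12)
})

test_that("glucose balance rejects non-positive glucose when K_ii = 0", {
  p <- avg_subject()
  expect_error(glucose_rhs(0, 10, 0.004, p), "K_ii")
  # with a positive K_ii the origin is regular
  expect_silent(glucose_rhs(0, 10, 0.004, p, fixed = fixed_kinetics(K_ii = 0.1)))
})

test_that("full system reproduces the analytic hormones and the receptor limit", {
  p <- avg_subject()
  fk <- fixed_kinetics()
  pr <- protocol()
  bl <- baseline_state(0.9, 10, 14.3, p, fk)
  y0 <- c(G = bl$G_bar, I = bl$I_bar, E = bl$E_bar,
          r = bl$r_bar, r_e = bl$re_bar)
  tt <- seq(3, 6, by = 0.1)
  sol <- deSolve::lsoda(y0, tt, function(t, y, parms)
    list(unname(system_rhs(y, t, p, pr, fk))), parms = NULL,
    rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[, "I"]),
               hormone_trajectory(tt, bl$I_bar, pr$Q_I, pr$V_I, p$k_degI),
               tolerance = 1e-7)
  expect_equal(unname(sol[, "E"]),
               hormone_trajectory(tt, bl$E_bar, pr$Q_E, pr$V_E, p$k_degE),
               tolerance = 1e-7)

  # long-horizon receptor state converges to the steady state at the clamp
  # plateau concentration
  e_inf <- pr$Q_E / (pr$V_E * p$k_degE)
  sol2 <- deSolve::lsoda(y0, c(3, 300), function(t, y, parms)
    list(unname(system_rhs(y, t, p, pr, fk))), parms = NULL,
    rtol = 1e-10, atol = 1e-12)
  ss_inf <- receptor_steady_state(e_inf, p, fk)
  expect_equal(unname(sol2[2, "r"]), ss_inf$r_bar, tolerance = 1e-6)
  expect_equal(unname(sol2[2, "r_e"]), ss_inf$re_bar, tolerance = 1e-6)
})

test_that("kinetic constants are mutually consistent", {
  fk <- fixed_kinetics()
  # equilibrium dissociation constant of the binding step
  expect_equal(fk$k_off / fk$k_on, 4000)
  # the dissociation rate corresponds to 0.24/min
  expect_equal(fk$k_off, 0.24 * 60)
})
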