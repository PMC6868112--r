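test_that("baseline estimation averages the pre-infusion samples", {
  coh <- small_cohort(seed = 3)
  rec <- coh[[1]]$before
  truth <- rec$true_params
  bl <- estimate_baselines(rec, truth)
  tb <- rec$true_baseline
  expect_equal(bl$G_bar, tb$G_bar, tolerance = 1e-10)
  expect_equal(bl$I_bar, tb$I_bar, tolerance = 1e-10)
  expect_equal(bl$E_bar, tb$E_bar, tolerance = 1e-10)
  expect_equal(bl$Fhgp_bar, tb$Fhgp_bar, tolerance = 1e-10)
  expect_equal(bl$re_bar, tb$re_bar, tolerance = 1e-10)

  # mean of constants
  rec2 <- rec
  rec2$G[rec2$time_min / 60 < 3] <- 0.9
  expect_equal(estimate_baselines(rec2, truth)$G_bar, 0.9)

  # too little baseline data
  rec3 <- rec
  rec3$time_min <- rec3$time_min + 120
  expect_error(estimate_baselines(rec3, truth), "insufficient")
})

test_that("baseline glucose error scales as the standard error of the mean", {
  tr <- simulate_subject(avg_subject(), E_bar = 14.3)
  set.seed(4)
  g <- replicate(300, {
    rec <- observe(tr, noise = noise_model(cv_G = 0.05))
    estimate_baselines(rec, cohort_average_params())$G_bar
  })
  # 4 baseline samples at 5% CV: SE = 0.05/sqrt(4) = 2.5%
  expect_equal(sd(g) / mean(g), 0.025, tolerance = 0.25)
})

test_that("hormone clearances are recovered exactly from noiseless records", {
  coh <- small_cohort(seed = 3)
  rec <- coh[[1]]$before
  truth <- rec$true_params
  bl <- estimate_baselines(rec, truth)
  hf <- fit_hormone_params(rec, bl)
  expect_equal(hf$k_degI, truth$k_degI, tolerance = 1e-3)
  expect_equal(hf$k_degE, truth$k_degE, tolerance = 1e-3)
  expect_false(hf$weak_I || hf$weak_E)
})

test_that("a constant hormone series is flagged as weakly identified", {
  coh <- small_cohort(seed = 3)
  rec <- coh[[1]]$before
  truth <- rec$true_params
  bl <- estimate_baselines(rec, truth)
  pr <- protocol()
  # force the insulin series to sit exactly on a plateau equal to baseline
  rec$I[] <- bl$I_bar
  expect_warning(fit_hormone_params(rec, bl, pr), "weakly identified")
})

test_that("noisy hormone fits recover the glucagon clearance", {
  p <- avg_subject()
  tr <- simulate_subject(p, E_bar = 14.3)
  set.seed(7)
  errs <- replicate(50, {
    rec <- observe(tr, noise = noise_model(cv_E = 0.10))
    bl <- estimate_baselines(rec, p)
    abs(fit_hormone_params(rec, bl)$k_degE - p$k_degE) / p$k_degE
  })
  expect_lt(median(errs), 0.15)
})

test_that("inner collocation reaches the ODE-consistent interpolant at large lambda", {
  coh <- small_cohort(seed = 3)
  rec <- coh[[1]]$before
  truth <- rec$true_params
  fixed <- fixed_kinetics()
  pr <- protocol()
  bl <- estimate_baselines(rec, truth)
  th <- rec$time_min / 60
  ph2 <- th >= 3
  basis <- spline_basis(th[ph2])
  Ifun <- function(t) hormone_trajectory(t, bl$I_bar, pr$Q_I, pr$V_I, truth$k_degI)
  Efun <- function(t) hormone_trajectory(t, bl$E_bar, pr$Q_E, pr$V_E, truth$k_degE)
  data <- list(t_obs = th[ph2], G = rec$G[ph2], F_hgp = rec$F_hgp[ph2],
               Rd = rec$Rd[ph2], I_obs = Ifun(th[ph2]),
               I_q = Ifun(basis$t_q), E_q = Efun(basis$t_q))
  w <- c(G = 1 / bl$G_bar^2, F_hgp = 1 / bl$Fhgp_bar^2, Rd = 1 / bl$Fhgp_bar^2)
  scales <- c(G = 1, r = 1, r_e = 0.01)
  # warm start by projecting the exact trajectory onto the basis, as the
  # profiling loop does (the inner problem is nonconvex from a cold start)
  tr <- simulate_subject(truth, pr, fixed,
                         G_bar = bl$G_bar, I_bar = bl$I_bar, E_bar = bl$E_bar,
                         dense_grid = sort(c(seq(3, 6, 0.05), basis$t_q)))
  proj <- function(y) qr.coef(qr(basis$B_q), approx(tr$time_h, y, basis$t_q)$y)
  c0 <- c(proj(tr$G), proj(tr$r), proj(tr$r_e))

  sm <- inner_smooth(data, truth, 1e4, w, basis, fixed, pr, scales, c0)
  # spline glucose tracks the exact trajectory in sup norm, up to the
  # basis-resolution floor set by the fast receptor boundary layer
  G_spline <- drop(basis$B_q %*% sm$cG)
  G_exact <- approx(tr$time_h, tr$G, basis$t_q)$y
  expect_lt(max(abs(G_spline - G_exact)), 0.01)

  # lambda -> 0 with positive weights: the data are interpolated
  sm0 <- inner_smooth(data, truth, 1e-10, w, basis, fixed, pr, scales, c0)
  expect_lt(sum((data$G - drop(basis$B_obs %*% sm0$cG))^2), 1e-10)

  # w = 0: any exact ODE solution minimizes; the penalty evaluates to ~0
  w0 <- c(G = 0, F_hgp = 0, Rd = 0)
  smw <- inner_smooth(data, truth, 1e3, w0, basis, fixed, pr, scales, c0)
  expect_lt(smw$penalty, 1e-3)
})

test_that("freeing the unidentifiable binding pair is rejected", {
  expect_error(smoothing_config(free = c("K_1", "R_tot")), "identifiable")
  expect_error(smoothing_config(free = c("V_1", "nonsense")), "unknown")
})

test_that("profiling is a fixed point at the truth on noiseless data", {
  coh <- small_cohort(seed = 3)
  rec <- coh[[1]]$before
  truth <- rec$true_params
  fit <- profile_fit(rec, quick_cfg(), init = truth)
  expect_true(fit$convergence)
  expect_true(all(rel_err(fit, truth) < 0.01))
  # the returned estimate satisfies the baseline balance identically
  bl <- fit$baseline_hat
  el <- eliminate_baseline_params(bl, fit$theta_hat)
  expect_equal(el$b_G, fit$theta_hat$b_G, tolerance = 1e-10)
  expect_equal(el$V_ii, fit$theta_hat$V_ii, tolerance = 1e-10)
})

test_that("paired noiseless fits recover the treatment ratio", {
  coh <- small_cohort(seed = 12)
  cfg <- quick_cfg()
  fb <- suppressWarnings(profile_fit(coh[[2]]$before, cfg))
  fa <- suppressWarnings(profile_fit(coh[[2]]$after, cfg))
  ratio <- fa$theta_hat$K1_prime / fb$theta_hat$K1_prime
  expect_equal(ratio, 0.0109 / 0.00501, tolerance = 0.02)
})
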