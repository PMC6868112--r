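test_that("steady state persists without infusions", {
  p <- avg_subject()
  pr0 <- protocol(Q_G = 0, Q_I = 0, Q_E = 0)
  tr <- simulate_subject(p, pr0, E_bar = 14.3)
  for (ch in c("G", "I", "E", "r", "r_e", "F_hgp", "Rd"))
    expect_equal(diff(range(tr[[ch]])), 0, tolerance = 1e-7)
})

test_that("default simulation reproduces the designed challenge phenotype", {
  tr <- simulate_subject(avg_subject(), E_bar = 14.3)

  # phase 1 flat at baseline
  ph1 <- tr$time_h < 3
  expect_equal(diff(range(tr$G[ph1])), 0)

  # glucagon rises towards ~2.6x its baseline (the 2-3-fold design target)
  expect_gt(max(tr$E) / 14.3, 2)
  expect_lt(max(tr$E) / 14.3, 3)

  # receptor conservation along the trajectory
  expect_lt(max(abs(tr$r + tr$r_e + tr$r_i - 1)), 1e-9)

  # production rate: initial rise (abundant glucagon) then slow decay
  # (internalization tolerance)
  ph2 <- tr$time_h >= 3
  f <- tr$F_hgp[ph2]
  i_max <- which.max(f)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(f))
  expect_lt(f[length(f)], max(f))
  # glucose peaks during the challenge then declines
  g <- tr$G[ph2]
  expect_gt(max(g), g[1])
  expect_lt(g[length(g)], max(g))
})

test_that("observation model is exact at zero noise and seeded", {
  tr <- simulate_subject(avg_subject(), E_bar = 14.3)
  sched <- observation_schedule()

  rec0 <- observe(tr, sched, noiseless())
  expect_equal(rec0$G, approx(tr$time_h, tr$G, sched$times_h)$y)
  expect_equal(rec0$F_hgp, approx(tr$time_h, tr$F_hgp, sched$times_h)$y)

  r1 <- observe(tr, sched, noise_model(seed = 99))
  r2 <- observe(tr, sched, noise_model(seed = 99))
  expect_identical(r1$G, r2$G)
  expect_identical(r1$Rd, r2$Rd)

  expect_error(observe(tr, observation_schedule(c(100, 500))),
               "span")
})

test_that("multiplicative noise has the nominal coefficient of variation", {
  tr <- simulate_subject(avg_subject(), E_bar = 14.3)
  sched <- observation_schedule()
  set.seed(1)
  g16 <- replicate(1000, observe(tr, sched, noise_model(cv_G = 0.05))$G[16])
  expect_equal(sd(g16) / mean(g16), 0.05, tolerance = 0.15)
})

test_that("paired cohorts are deterministic and carry ground truth", {
  c1 <- small_cohort(seed = 7)
  c2 <- small_cohort(seed = 7)
  expect_identical(c1[[1]]$before$G, c2[[1]]$before$G)
  expect_identical(c1[[2]]$after$E, c2[[2]]$after$E)

  gt <- attr(c1, "ground_truth")
  expect_equal(nrow(gt), 4)  # 2 subjects x 2 visits
  expect_setequal(unique(gt$visit), c("before", "after"))

  # null treatment, zero noise: visits identical
  c0 <- generate_paired_cohort(
    cohort_spec(n_subjects = 2, seed = 5, treatment_K1prime_multiplier = 1),
    noise = noiseless())
  expect_equal(c0[[1]]$before$G, c0[[1]]$after$G, tolerance = 1e-12)

  # the default treatment doubles the apparent dissociation constant
  m <- gt$K1_prime[gt$visit == "after"] / gt$K1_prime[gt$visit == "before"]
  expect_equal(m, rep(0.0109 / 0.00501, 2))
})

test_that("treatment lowers the peak glucose in most subjects and seeds", {
  n_lower <- 0L
  n_tot <- 0L
  med_b <- med_a <- numeric(0)
  for (seed in 1:20) {
    coh <- generate_paired_cohort(cohort_spec(n_subjects = 2, seed = seed),
                                  noise = noiseless())
    for (s in coh) {
      gb <- gmax(s$before)
      ga <- gmax(s$after)
      med_b <- c(med_b, gb)
      med_a <- c(med_a, ga)
      n_tot <- n_tot + 1L
      if (ga < gb) n_lower <- n_lower + 1L
    }
  }
  expect_lt(median(med_a), median(med_b))
  expect_gt(n_lower / n_tot, 0.5)
})
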