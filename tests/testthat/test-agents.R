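test_that("true effort SV is linear in load with amount sensitivity", {
  expect_equal(true_effort_sv(agent_params(kappa = 0.3), 1, 2), 1.0)
  expect_equal(true_effort_sv(agent_params(kappa = 0), 5, 2), 1.0)
  expect_equal(true_effort_sv(agent_params(kappa = 0.17, gamma = 0), 4, 2),
               0.49) # 1 - 0.17 * 3
  # decreasing in level, increasing in base when gamma > 0
  p <- agent_params(kappa = 0.2, gamma = 0.5)
  svs <- true_effort_sv(p, 1:6, 2)
  expect_true(all(diff(svs) <= 0))
  expect_gt(true_effort_sv(p, 4, 5), true_effort_sv(p, 4, 1))
  # clamped to [0, 1]
  expect_equal(true_effort_sv(agent_params(kappa = 1), 6, 1), 0)
})

test_that("delayed value is hyperbolic with a magnitude effect", {
  p <- agent_params(k_delay = 0.001, k_mag_exp = 0)
  expect_equal(true_delay_value(p, 1000, 0), 1000)
  expect_equal(true_delay_value(p, 1000, 1000), 500)
  expect_equal(true_delay_value(agent_params(k_delay = 0), 750, 3650), 750)
  # $25,000 discounted at a lower rate than $1,000
  pm <- agent_params(k_delay = 0.01, k_mag_exp = 0.2)
  v1 <- true_delay_value(pm, 1000, 365) / 1000
  v25 <- true_delay_value(pm, 25000, 365) / 25000
  expect_gt(v25, v1)
})

test_that("deterministic choices maximize value with EASY ties", {
  p0 <- agent_params(kappa = 0, tau = 0)
  expect_equal(agent_choose(p0, 1, 2, condition = 3), "HARD")
  # exact equality resolves to EASY
  expect_equal(agent_choose(p0, 2, 2, condition = 3), "EASY")
  # logistic midpoint: P(HARD) ~ 0.5 when the easy offer equals value(HARD)
  pn <- agent_params(kappa = 0.25, tau = 0.1)
  v_hard <- true_effort_sv(pn, 3, 2) * 2
  picks <- withr::with_seed(5, replicate(2000, {
    agent_choose(pn, v_hard, 2, condition = 3)
  }))
  expect_equal(mean(picks == "HARD"), 0.5, tolerance = 0.05)
})

test_that("a noiseless agent titrates to within one grid step of its true value", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      p <- agent_params(kappa = runif(1, 0.02, 0.45), tau = 0)
      lev <- sample(2:6, 1)
      rec <- run_titration(agent_callback(p), lev, 2)
      v_true <- true_effort_sv(p, lev, 2) * 2
      expect_lte(abs(rec$indifference_amount - clamp(v_true, 0.015625, 1.984375)),
                 0.015625)
    }
  })
})

test_that("simulated performance declines with load", {
  p_clean <- agent_params(delta = 0, sigma_dprime = 0, sigma_rt = 0)
  perf <- simulate_performance(p_clean, 1:6)
  expect_equal(perf$d_prime, rep(p_clean$d0, 6))
  p_lin <- agent_params(d0 = 3.42, delta = 0.59, sigma_dprime = 0,
                        sigma_rt = 0)
  expect_equal(simulate_performance(p_lin, 4)$d_prime, 1.65)
  # fitted d-prime-vs-level slope is negative on average under defaults
  slopes <- withr::with_seed(17, replicate(100, {
    dp <- simulate_performance(agent_params(), 1:4)$d_prime
    coef(lm(dp ~ seq_along(dp)))[2]
  }))
  expect_lt(mean(slopes), -0.3)
})

test_that("cohort simulation matches the design arithmetic and is reproducible", {
  spec <- cohort_spec(n_per_group = 4)
  sim <- simulate_cohort(spec, experiment_config("exp1"), seed = 9)
  # YA titrate levels 2-6, OA 2-4, all at one $2 base; anchor adds level 1
  sv_ya <- sim$sv[sim$sv$age_group == 0, ]
  sv_oa <- sim$sv[sim$sv$age_group == 1, ]
  expect_equal(nrow(sv_ya), 4 * 6)
  expect_equal(nrow(sv_oa), 4 * 4)
  expect_true(all(sim$sv$sv[sim$sv$level == 1] == 1))
  expect_equal(nrow(sim$trials), 4 * 30 + 4 * 18)

  sim2 <- simulate_cohort(spec, experiment_config("exp1"), seed = 9)
  expect_identical(sim$sv, sim2$sv)
  expect_identical(sim$trials, sim2$trials)
  sim3 <- simulate_cohort(spec, experiment_config("exp1"), seed = 10)
  expect_false(identical(sim$sv$sv, sim3$sv$sv))
})

test_that("noise-free cohorts recover every true SV within titration resolution", {
  spec <- cohort_spec(n_per_group = 6, ya = list(tau = 0), oa = list(tau = 0))
  sim <- simulate_cohort(spec, experiment_config("exp1"), seed = 23)
  meas <- sim$sv[sim$sv$level > 1, ]
  grid_step <- 0.015625 / 2 # in SV units on a $2 base
  truth <- clamp(meas$true_sv, 0.015625 / 2, 1.984375 / 2)
  expect_true(all(abs(meas$sv - truth) <= grid_step + 1e-12))
})

test_that("SV recovery error shrinks as choice noise vanishes", {
  err_for_tau <- function(tau, seed) {
    spec <- cohort_spec(n_per_group = 15, ya = list(tau = tau),
                        oa = list(tau = tau))
    sim <- simulate_cohort(spec, experiment_config("exp1"), seed = seed)
    meas <- sim$sv[sim$sv$level > 1, ]
    mean(abs(meas$sv - meas$true_sv))
  }
  expect_lt(err_for_tau(0.02, 37), err_for_tau(0.5, 37))
})

test_that("a costlier older group yields lower group AUC", {
  spec <- cohort_spec(n_per_group = 15)
  sim <- simulate_cohort(spec, experiment_config("exp1"), seed = 41)
  aucs <- auc_table(dplyr::rename(sim$sv, condition = level),
                    conditions = 2:4)
  aucs <- dplyr::left_join(aucs, sim$covariates[, c("participant_id", "age_group")],
                           by = "participant_id")
  by_grp <- tapply(aucs$auc, aucs$age_group, mean)
  expect_gt(by_grp[["0"]], by_grp[["1"]])
})
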