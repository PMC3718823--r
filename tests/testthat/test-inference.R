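test_that("exactly linear SV data are recovered with zero residual variance", {
  d <- withr::with_seed(3, make_mlm_data(n_participants = 10, slope = -0.1,
                                         sd_intercept = 0, sd_resid = 0))
  d$sv <- 1 - 0.1 * (d$level - 1) # force the exact line, no noise at all
  fit <- fit_sv_mlm(d, include_anchor = TRUE)
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "n_c"], -0.1, tolerance = 1e-6)
  expect_lt(max(fit$residual_sd), 1e-4)
})

test_that("the documented df convention reproduces the within/between split", {
  d <- withr::with_seed(5, make_mlm_data(n_participants = 25))
  fit <- fit_sv_mlm(d)
  cf <- fit$coefficients
  # 100 observations - 25 participants - 3 within slopes = 72
  expect_equal(cf$df[cf$term == "n_c"], 72)
  expect_equal(cf$df[cf$term == "d_prime"], 72)
  expect_equal(cf$df[cf$term == "mean_rt"], 72)

  d2 <- withr::with_seed(6, dplyr::bind_rows(
    make_mlm_data(25, age_group = 0L),
    make_mlm_data(25, slope = -0.24, age_group = 1L) |>
      dplyr::mutate(participant_id = sub("P", "Q", participant_id))
  ))
  fit2 <- fit_sv_mlm(d2, age_terms = TRUE)
  cf2 <- fit2$coefficients
  # 200 - 50 - 4 within terms = 146; between: 50 - 1 - 1 = 48
  expect_equal(cf2$df[cf2$term == "n_c"], 146)
  expect_equal(cf2$df[cf2$term == "age_group"], 48)
  expect_equal(cf2$df[cf2$term == "n_c:age_group"], 146)
})

test_that("REML load-slope estimates are unbiased in a recovery simulation", {
  ests <- withr::with_seed(11, replicate(60, {
    d <- make_mlm_data(n_participants = 25, slope = -0.13,
                       sd_intercept = 0.15, sd_resid = 0.1)
    cf <- fit_sv_mlm(d)$coefficients
    cf$estimate[cf$term == "n_c"]
  }))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - (-0.13)), 2 * mc_se + 1e-8)
})

test_that("age-steeper cohorts show negative age and interaction terms", {
  d <- withr::with_seed(19, dplyr::bind_rows(
    make_mlm_data(25, slope = -0.10, age_group = 0L),
    make_mlm_data(25, slope = -0.22, age_group = 1L) |>
      dplyr::mutate(participant_id = sub("P", "Q", participant_id),
                    sv = sv - 0.15)
  ))
  cf <- fit_sv_mlm(d, age_terms = TRUE)$coefficients
  expect_lt(cf$estimate[cf$term == "age_group"], 0)
  expect_lt(cf$estimate[cf$term == "n_c:age_group"], 0)
})

test_that("the age-by-load interaction hinges on the anchored reference level", {
  # older group whose extra drop happens only between N = 1 and N > 1
  make_drop_data <- function(n, drop, tag) {
    rows <- lapply(seq_len(n), function(j) {
      level <- 1:4
      sv <- 1 - drop - 0.1 * (level - 1) + rnorm(4, 0, 0.04)
      sv[level == 1] <- 1
      tibble::tibble(
        participant_id = sprintf("%s%02d", tag, j),
        age_group = as.integer(tag == "O"), level = level,
        d_prime = 3.4 - 0.6 * (level - 1) + rnorm(4, 0, 0.3),
        mean_rt = 0.6 + 0.04 * (level - 1) + rnorm(4, 0, 0.05),
        sv = sv
      )
    })
    dplyr::bind_rows(rows)
  }
  d <- withr::with_seed(29, dplyr::bind_rows(
    make_drop_data(25, drop = 0.00, tag = "Y"),
    make_drop_data(25, drop = 0.30, tag = "O")
  ))
  with_anchor <- fit_sv_mlm(d, include_anchor = TRUE, age_terms = TRUE)
  without <- fit_sv_mlm(d, include_anchor = FALSE, age_terms = TRUE)
  ia_with <- with_anchor$coefficients[
    with_anchor$coefficients$term == "n_c:age_group", ]
  ia_without <- without$coefficients[
    without$coefficients$term == "n_c:age_group", ]
  expect_lt(ia_with$p, 0.01)   # interaction driven by the N=1 -> N>1 drop
  expect_gt(ia_without$p, 0.2) # vanishes once the anchor is excluded
  expect_gt(abs(ia_with$estimate), abs(ia_without$estimate) + 0.02)
  # the age main effect survives anchor exclusion
  age_without <- without$coefficients[
    without$coefficients$term == "age_group", ]
  expect_lt(age_without$p, 0.01)
})

test_that("heterogeneous residual variance never fits worse than homogeneous", {
  for (seed in c(43, 44, 45)) {
    d <- withr::with_seed(seed, dplyr::bind_rows(
      make_mlm_data(20, sd_resid = 0.05, age_group = 0L),
      make_mlm_data(20, sd_resid = 0.18, age_group = 1L) |>
        dplyr::mutate(participant_id = sub("P", "Q", participant_id))
    ))
    fit <- fit_sv_mlm(d, age_terms = TRUE, heterogeneous_by_age = TRUE)
    expect_gte(fit$lrt_heterogeneous$statistic, 0)
    expect_equal(length(fit$residual_sd), 2L)
  }
  # with a real variance gap the LRT detects it
  expect_lt(fit_sv_mlm(
    withr::with_seed(46, dplyr::bind_rows(
      make_mlm_data(25, sd_resid = 0.04, age_group = 0L),
      make_mlm_data(25, sd_resid = 0.25, age_group = 1L) |>
        dplyr::mutate(participant_id = sub("P", "Q", participant_id))
    )),
    age_terms = TRUE, heterogeneous_by_age = TRUE
  )$lrt_heterogeneous$p, 0.05)
})

test_that("ratio-predictor refit drops the anchor and constant ratios", {
  d <- withr::with_seed(51, make_mlm_data(n_participants = 20, slope = -0.15))
  fit <- fit_sv_mlm_ratio(d)
  expect_equal(fit$n_obs, 20 * 3) # levels 2-4 only
  cf <- fit$coefficients
  expect_lt(cf$estimate[cf$term == "n_c"], 0)
  expect_true(all(c("ratio_dprime", "ratio_rt") %in% cf$term))

  # constant performance makes the ratios collinear with the intercept
  d_const <- d
  d_const$d_prime <- 2.5
  d_const$mean_rt <- 0.7
  w <- capture_warnings(fit_c <- fit_sv_mlm_ratio(d_const))
  expect_length(w, 2L)
  expect_match(w, "constant", all = TRUE)
  cf_c <- fit_c$coefficients
  expect_false("ratio_dprime" %in% cf_c$term)
  # dropping the collinear ratios leaves the load slope at the
  # within-participant value (fixed-effects oracle on the same rows)
  sub <- d_const[d_const$level %in% 2:4, ]
  within_slope <- coef(lm(sv ~ factor(participant_id) + I(level - 3),
                          data = sub))[["I(level - 3)"]]
  expect_equal(cf_c$estimate[cf_c$term == "n_c"], within_slope,
               tolerance = 1e-6)

  expect_error(fit_sv_mlm_ratio(d[d$level > 1, ]), "baseline")
})

test_that("rank-deficient fixed-effect designs are rejected explicitly", {
  d <- withr::with_seed(52, make_mlm_data(10))
  d$mean_rt <- d$d_prime # perfectly collinear predictors
  expect_error(fit_sv_mlm(d), "rank-deficient")
})

test_that("linear contrast matches an independent split-contrast oracle", {
  # hand-checkable table: 4 participants x 3 conditions
  y <- c(1.0, 0.9, 1.1, 1.2, 0.7, 0.8, 0.6, 0.7, 0.3, 0.2, 0.45, 0.4)
  cond <- rep(1:3, each = 4)
  res <- linear_contrast(y, cond)
  f <- factor(cond)
  contrasts(f) <- stats::contr.poly(3)
  oracle <- summary.aov(stats::aov(y ~ f),
                        split = list(f = list(linear = 1)))[[1]]
  rownames(oracle) <- trimws(rownames(oracle))
  expect_equal(res$F, unname(oracle["f: linear", "F value"]), tolerance = 1e-10)
  expect_equal(res$p, unname(oracle["f: linear", "Pr(>F)"]), tolerance = 1e-10)
  expect_equal(res$df2, unname(oracle["Residuals", "Df"]))
  ss_total <- oracle["f", "Sum Sq"] + oracle["Residuals", "Sum Sq"]
  expect_equal(res$eta_squared,
               unname(oracle["f: linear", "Sum Sq"] / ss_total),
               tolerance = 1e-10)
})

test_that("linear contrast handles constant and near-perfect-linear data", {
  res0 <- linear_contrast(rep(2, 12), rep(1:3, 4))
  expect_equal(res0$F, 0)
  expect_equal(res0$eta_squared, 0)
  lin <- rep(c(3, 2, 1), each = 5) + rnorm(15, 0, 1e-6)
  expect_gt(linear_contrast(lin, rep(1:3, each = 5))$eta_squared, 0.999)
})

test_that("linear contrast agrees with the oracle on random tables", {
  withr::with_seed(57, {
    for (rep in 1:20) {
      y <- rnorm(12)
      cond <- rep(1:3, each = 4)
      res <- linear_contrast(y, cond)
      f <- factor(cond)
      contrasts(f) <- stats::contr.poly(3)
      oracle <- summary.aov(stats::aov(y ~ f),
                            split = list(f = list(linear = 1)))[[1]]
      rownames(oracle) <- trimws(rownames(oracle))
      expect_equal(res$F, unname(oracle["f: linear", "F value"]), tolerance = 1e-8)
    }
  })
})

test_that("group comparison reproduces the exact rank-sum tail for separation", {
  x <- 1:10
  y <- 21:30
  res <- group_compare(x, y)
  # fully separated samples: two-sided exact p = 2 / choose(20, 10)
  expect_equal(res$wilcoxon_p, 2 / choose(20, 10))
  same <- group_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$wilcoxon_p, 0.9)
})

test_that("group comparison has power at the observed effect size", {
  rej <- withr::with_seed(61, replicate(200, {
    ya <- pmin(1, pmax(0, rnorm(25, 0.72, 0.25)))
    oa <- pmin(1, pmax(0, rnorm(25, 0.36, 0.25)))
    group_compare(ya, oa)$wilcoxon_p < 0.05
  }))
  expect_gt(mean(rej), 0.8)
})

test_that("hierarchical increment is zero for a duplicated predictor", {
  d <- withr::with_seed(63, tibble::tibble(x = rnorm(40), y = rnorm(40) + x))
  d$x2 <- d$x
  res <- hierarchical_delta_r2(d, "y", "x", "x2")
  expect_equal(res$delta_r2, 0, tolerance = 1e-12)
})

test_that("the age increment beyond a covariate is detected reliably", {
  hits <- withr::with_seed(67, replicate(100, {
    n <- 50
    age <- rep(0:1, each = n / 2)
    ncs <- rnorm(n, 62, 9)
    auc <- 0.72 - 0.36 * age + 0.002 * (ncs - 62) + rnorm(n, 0, 0.2)
    d <- tibble::tibble(age_group = age, ncs = ncs, auc_effort = auc)
    hierarchical_delta_r2(d, "auc_effort", "ncs", "age_group")$p < 0.01
  }))
  expect_gt(mean(hits), 0.8)
})

test_that("logistic separation is surfaced as a warning", {
  d <- tibble::tibble(age_group = rep(0:1, each = 10),
                      auc_effort = c(seq(0.6, 0.9, length.out = 10),
                                     seq(0.1, 0.4, length.out = 10)),
                      ntlx = rnorm(20, 10, 2))
  expect_warning(res <- covariate_regressions(d), "separation")
  expect_true(attr(res$age_logistic, "separated"))
})

test_that("the regression battery dissociates income (delay) from age (effort)", {
  spec <- cohort_spec(n_per_group = 40)
  run <- run_pipeline(experiment_config("exp2"), spec, seed = 101)
  regs <- run$regressions
  expect_true(all(c("effort_income", "delay_income", "age_domain_income")
                  %in% names(regs)))
  eff <- regs$effort_income
  del <- regs$delay_income
  t_of <- function(tbl, term) abs(tbl$statistic[tbl$term == term])
  # age dominates income for effort discounting; income dominates for delay
  expect_gt(t_of(eff, "age_group"), t_of(eff, "income_bin"))
  expect_gt(t_of(del, "income_bin"), t_of(del, "age_group"))
  expect_lt(eff$p[eff$term == "age_group"], 0.05)
  expect_lt(del$p[del$term == "income_bin"], 0.05)
})
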