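# Multilevel models of subjective value, linear-contrast ANOVA, group
# comparisons, and the covariate regression battery.

# tidy coefficient table from an lm fit
tidy_lm <- function(fit) {
  s <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], se = s[, 2],
    statistic = s[, 3], p = s[, 4]
  )
}

# denominator df convention for fixed-effect t tests: terms that vary within
# participants are tested against n_obs - n_participants - p_within; terms
# constant within participants (and the intercept) against
# n_participants - 1 - p_between.
mlm_df_table <- function(terms, within, n_obs, n_groups) {
  p_within <- sum(within)
  p_between <- sum(!within & terms != "(Intercept)")
  ifelse(within,
         n_obs - n_groups - p_within,
         n_groups - 1 - p_between)
}

# shared REML fitting engine for the subjective-value multilevel models
mlm_engine <- function(d, rhs, heterogeneous_by_age = FALSE) {
  fixed <- as.formula(paste("sv ~", paste(rhs, collapse = " + ")))
  mm <- stats::model.matrix(fixed, d)
  if (qr(mm)$rank < ncol(mm)) {
    stop("rank-deficient fixed-effects design: ",
         paste(colnames(mm), collapse = ", "), call. = FALSE)
  }
  weights <- NULL
  if (heterogeneous_by_age) {
    if (!"age_group" %in% names(d)) {
      stop("heterogeneous_by_age requires an age_group column", call. = FALSE)
    }
    d$age_f <- factor(d$age_group)
    weights <- nlme::varIdent(form = ~ 1 | age_f)
  }
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | participant_id, data = d,
              method = "REML", weights = weights,
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         returnObject = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # degenerate data (e.g. exactly linear SV) can defeat the REML iteration;
    # if an OLS fit is numerically exact, report it with zero variances
    ols <- lm(fixed, data = d)
    if (sd(stats::resid(ols)) < 1e-8) {
      return(list(fit = NULL, ols = ols, d = d, fixed = fixed))
    }
    stop("multilevel model failed to converge: ", conditionMessage(fit),
         call. = FALSE)
  }
  list(fit = fit, ols = NULL, d = d, fixed = fixed)
}

mlm_result <- function(eng, heterogeneous_by_age = FALSE, lrt = NULL) {
  d <- eng$d
  n_obs <- nrow(d)
  n_groups <- length(unique(d$participant_id))
  if (is.null(eng$fit)) {
    cf <- coef(eng$ols)
    se <- suppressWarnings(sqrt(diag(stats::vcov(eng$ols))))
    terms <- names(cf)
    sig_int <- 0
    sig_res <- 0
    ll <- NA_real_; aic <- NA_real_; bic <- NA_real_
  } else {
    tt <- summary(eng$fit)$tTable
    cf <- tt[, "Value"]
    se <- tt[, "Std.Error"]
    terms <- rownames(tt)
    vc <- nlme::VarCorr(eng$fit)
    sig_int <- as.numeric(vc["(Intercept)", "StdDev"])
    sig_res <- eng$fit$sigma
    if (heterogeneous_by_age) {
      w <- eng$fit$modelStruct$varStruct
      ratios <- coef(w, unconstrained = FALSE, allCoef = TRUE)
      sig_res <- sig_res * ratios
    }
    ll <- as.numeric(logLik(eng$fit))
    aic <- AIC(eng$fit); bic <- BIC(eng$fit)
  }
  mm <- stats::model.matrix(eng$fixed, d)
  within <- vapply(seq_along(terms), function(j) {
    any(tapply(mm[, terms[j]], d$participant_id,
               function(v) max(v) - min(v)) > 1e-10)
  }, logical(1))
  df <- mlm_df_table(terms, within, n_obs, n_groups)
  tval <- cf / se
  structure(
    list(
      coefficients = tibble::tibble(
        term = terms, estimate = unname(cf), se = unname(se),
        df = df, t = unname(tval),
        p = 2 * pt(-abs(unname(tval)), df)
      ),
      random_intercept_sd = sig_int,
      residual_sd = sig_res,
      logLik = ll, AIC = aic, BIC = bic,
      lrt_heterogeneous = lrt,
      n_obs = n_obs, n_participants = n_groups,
      model = eng$fit
    ),
    class = "coged_mlm"
  )
}

#' @export
print.coged_mlm <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Random-intercept model of subjective value (%d obs, %d participants, REML)\n",
    x$n_obs, x$n_participants
  ))
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  cat(sprintf("Random intercept SD: %.4g; residual SD: %s\n",
              x$random_intercept_sd,
              paste(format(x$residual_sd, digits = 4), collapse = ", ")))
  if (!is.null(x$lrt_heterogeneous)) {
    cat(sprintf("LRT heterogeneous vs homogeneous variance: %.3f (df 1, p = %.3g)\n",
                x$lrt_heterogeneous$statistic, x$lrt_heterogeneous$p))
  }
  invisible(x)
}

#' Random-intercept multilevel model of subjective value
#'
#' Fits, by restricted maximum likelihood, a linear mixed model of SV on
#' signal-detection performance (d'), mean correct-trial RT (seconds), and
#' centered load level, with a normally distributed subject-specific
#' intercept. Load is centered at 2.5 so levels 1-4 code as -1.5 to 1.5.
#' Optionally the anchored reference level N = 1 is included: its rows carry
#' the observed performance, with SV filled in as the theoretical value 1
#' where the table leaves it missing; with `include_anchor = FALSE` the
#' N = 1 rows are dropped. Age main and interaction terms can be added, and
#' the residual variance can be stratified by age group (with a
#' restricted-likelihood-ratio test against the homogeneous fit).
#'
#' Fixed-effect t tests use the within/between denominator-df convention:
#' terms varying within participants are tested on
#' `n_obs - n_participants - p_within` df, participant-constant terms on
#' `n_participants - 1 - p_between` df.
#'
#' @param data Long SV table with columns `participant_id`, `level`, `sv`,
#'   `d_prime`, `mean_rt`, and `age_group` when age terms or heterogeneous
#'   variance are requested.
#' @param include_anchor Include the theoretical SV = 1 rows at N = 1
#'   (default `TRUE`); when `FALSE`, N = 1 rows are dropped.
#' @param heterogeneous_by_age Stratify residual variance by age group.
#' @param age_terms Add `age_group` and `age_group:n_c` fixed effects.
#' @param levels Levels entering the fit (default 1:4).
#' @param center Centering constant for load (default 2.5).
#' @return A `coged_mlm` object; see [print.coged_mlm()].
#' @export
fit_sv_mlm <- function(data, include_anchor = TRUE,
                       heterogeneous_by_age = FALSE, age_terms = FALSE,
                       levels = 1:4, center = 2.5) {
  d <- tibble::as_tibble(data)
  stopifnot(all(c("participant_id", "level", "sv", "d_prime", "mean_rt")
                %in% names(d)))
  d <- d[d$level %in% levels, ]
  if (include_anchor) {
    d$sv[d$level == 1 & is.na(d$sv)] <- 1
  } else {
    d <- d[d$level != 1, ]
  }
  if (min(table(d$participant_id)) < 2L) {
    stop("every participant needs at least 2 levels", call. = FALSE)
  }
  d$n_c <- d$level - center
  rhs <- c("d_prime", "mean_rt", "n_c")
  if (age_terms) rhs <- c(rhs, "age_group", "age_group:n_c")
  eng <- mlm_engine(d, rhs, heterogeneous_by_age)
  lrt <- NULL
  if (heterogeneous_by_age && !is.null(eng$fit)) {
    hom <- mlm_engine(d, rhs, heterogeneous_by_age = FALSE)
    if (!is.null(hom$fit)) {
      stat <- max(0, 2 * (as.numeric(logLik(eng$fit)) -
                            as.numeric(logLik(hom$fit))))
      lrt <- list(statistic = stat, df = 1L,
                  p = pchisq(stat, df = 1, lower.tail = FALSE))
    }
  }
  mlm_result(eng, heterogeneous_by_age, lrt)
}

#' Ratio-predictor multilevel model without the anchored reference level
#'
#' Refits the subjective-value model on levels 2-4 only (excluding the
#' theoretical SV = 1 point), replacing raw performance with each level's
#' performance expressed as a ratio to the participant's own N = 1 value, so
#' the performance drop relative to baseline is retained. Load is centered
#' at 3. Ratio predictors that are constant across the data (e.g. when
#' performance does not vary with load) are dropped with a warning.
#'
#' @param data Long SV table as for [fit_sv_mlm()], which must contain N = 1
#'   rows carrying each participant's baseline `d_prime` and `mean_rt`.
#' @param heterogeneous_by_age,age_terms As in [fit_sv_mlm()].
#' @return A `coged_mlm` object.
#' @export
fit_sv_mlm_ratio <- function(data, heterogeneous_by_age = FALSE,
                             age_terms = FALSE) {
  d <- tibble::as_tibble(data)
  base <- d[d$level == 1, c("participant_id", "d_prime", "mean_rt")]
  if (!all(unique(d$participant_id) %in% base$participant_id)) {
    stop("N = 1 baseline performance missing for some participants",
         call. = FALSE)
  }
  base <- base[!duplicated(base$participant_id), ]
  names(base)[2:3] <- c("d_prime_1", "mean_rt_1")
  d <- d[d$level %in% 2:4, ]
  d <- dplyr::left_join(d, base, by = "participant_id")
  d$ratio_dprime <- d$d_prime / d$d_prime_1
  d$ratio_rt <- d$mean_rt / d$mean_rt_1
  d$n_c <- d$level - 3
  rhs <- c("ratio_dprime", "ratio_rt", "n_c")
  for (v in c("ratio_dprime", "ratio_rt")) {
    if (var(d[[v]]) < 1e-12) {
      warning("predictor ", v,
              " is constant (collinear with intercept); dropped",
              call. = FALSE)
      rhs <- setdiff(rhs, v)
    }
  }
  if (age_terms) rhs <- c(rhs, "age_group", "age_group:n_c")
  eng <- mlm_engine(d, rhs, heterogeneous_by_age)
  mlm_result(eng, heterogeneous_by_age, NULL)
}

#' Linear-contrast ANOVA over ordered conditions
#'
#' Tests the linear trend of a response across ordered conditions: contrast
#' weights are the centered condition coordinates, the contrast sum of
#' squares is tested against the within-condition mean square on
#' `n_obs - k` df, and the effect size is `eta^2 = SS_contrast / SS_total`.
#' Constant data return F = 0 rather than an error.
#'
#' @param values Numeric response vector.
#' @param conditions Ordered condition coordinates (numeric), same length.
#' @return A list with `F`, `df1`, `df2`, `p`, `eta_squared`, and the
#'   contrast sum of squares.
#' @export
linear_contrast <- function(values, conditions) {
  stopifnot(length(values) == length(conditions))
  conditions <- as.numeric(conditions)
  levs <- sort(unique(conditions))
  if (length(levs) < 2L) stop("need at least 2 conditions", call. = FALSE)
  m <- tapply(values, conditions, mean)[as.character(levs)]
  n_g <- tapply(values, conditions, length)[as.character(levs)]
  w <- levs - mean(levs)
  ss_contrast <- sum(w * m)^2 / sum(w^2 / n_g)
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  ss_error <- sum((values - m[as.character(conditions)])^2)
  df2 <- length(values) - length(levs)
  if (ss_contrast < 1e-14) {
    return(list(F = 0, df1 = 1L, df2 = df2, p = 1, eta_squared = 0,
                ss_contrast = 0))
  }
  f <- ss_contrast / (ss_error / df2)
  list(
    F = f, df1 = 1L, df2 = df2, p = pf(f, 1, df2, lower.tail = FALSE),
    eta_squared = ss_contrast / ss_total, ss_contrast = ss_contrast
  )
}

#' Compare two groups by rank and t tests
#'
#' Wilcoxon rank-sum (unpaired) or signed-rank (paired) test together with
#' the corresponding t test and group means.
#'
#' @param x,y Numeric samples.
#' @param paired Paired comparison?
#' @return List with `mean_x`, `mean_y`, `wilcoxon_p`, `t_p`.
#' @export
group_compare <- function(x, y, paired = FALSE) {
  w <- suppressWarnings(wilcox.test(x, y, paired = paired))
  tt <- tryCatch(t.test(x, y, paired = paired),
                 error = function(e) list(p.value = NA_real_))
  list(
    mean_x = mean(x), mean_y = mean(y),
    wilcoxon_p = w$p.value, t_p = tt$p.value
  )
}

#' Hierarchical regression increment
#'
#' R-squared increment from adding `added_terms` to a base OLS model, with
#' the incremental F test. A duplicated predictor adds exactly zero.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param base_terms Character vector of base predictors.
#' @param added_terms Character vector of added predictors.
#' @return List with `r2_base`, `r2_full`, `delta_r2`, `F`, `df1`, `df2`, `p`.
#' @export
hierarchical_delta_r2 <- function(data, response, base_terms, added_terms) {
  f_base <- as.formula(paste(response, "~", paste(base_terms, collapse = "+")))
  f_full <- as.formula(paste(response, "~",
                             paste(c(base_terms, added_terms), collapse = "+")))
  m_base <- lm(f_base, data = data)
  m_full <- lm(f_full, data = data)
  r2b <- summary(m_base)$r.squared
  r2f <- summary(m_full)$r.squared
  an <- stats::anova(m_base, m_full)
  list(
    r2_base = r2b, r2_full = r2f, delta_r2 = r2f - r2b,
    F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2], p = an$`Pr(>F)`[2],
    model_full = m_full
  )
}

# logistic regression with complete-separation surfaced as a warning
logistic_fit <- function(formula, data) {
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    warning("possible complete separation in logistic regression",
            call. = FALSE)
  }
  attr(fit, "separated") <- separated
  fit
}

#' Covariate regression battery
#'
#' Assembles the individual-difference analyses around the discounting
#' metrics: NCS predicted by effort-discounting AUC (alone and controlling
#' for the NTLX composite), the hierarchical age increment in AUC beyond
#' NCS, logistic prediction of age group from AUC and NTLX, AUC on age and
#' amount ratings, income models of effort and delay AUC, the age-by-domain
#' interaction with and without the income covariate, and the
#' conscientiousness (score-rating) control. Models whose columns are absent
#' from `table` are skipped.
#'
#' @param table Per-participant tibble with (subsets of) columns
#'   `age_group`, `auc_effort`, `auc_delay`, `ncs`, `ntlx`, `income_bin`,
#'   `amount_rating`, `score_rating`.
#' @return Named list of fitted summaries; OLS entries are tidy coefficient
#'   tibbles, hierarchical entries are [hierarchical_delta_r2()] lists, the
#'   logistic entry is a `glm` fit with a `separated` attribute.
#' @export
covariate_regressions <- function(table) {
  d <- tibble::as_tibble(table)
  has <- function(...) all(c(...) %in% names(d))
  out <- list()
  if (has("ncs", "auc_effort")) {
    out$ncs_on_auc <- tidy_lm(lm(ncs ~ auc_effort, data = d))
  }
  if (has("ncs", "auc_effort", "ntlx")) {
    out$ncs_on_auc_ntlx <- tidy_lm(lm(ncs ~ auc_effort + ntlx, data = d))
  }
  if (has("auc_effort", "ncs", "age_group")) {
    out$age_increment_beyond_ncs <- hierarchical_delta_r2(
      d, "auc_effort", "ncs", "age_group"
    )
  }
  if (has("age_group", "auc_effort", "ntlx")) {
    out$age_logistic <- logistic_fit(age_group ~ auc_effort + ntlx, d)
  }
  if (has("auc_effort", "age_group", "amount_rating")) {
    out$auc_on_age_amount_rating <-
      tidy_lm(lm(auc_effort ~ age_group + amount_rating, data = d))
  }
  if (has("auc_effort", "age_group", "income_bin")) {
    out$effort_income <-
      tidy_lm(lm(auc_effort ~ age_group + income_bin, data = d))
  }
  if (has("auc_delay", "age_group", "income_bin")) {
    out$delay_income <-
      tidy_lm(lm(auc_delay ~ age_group + income_bin, data = d))
  }
  if (has("auc_effort", "auc_delay", "age_group")) {
    long <- tidyr::pivot_longer(
      d, c("auc_effort", "auc_delay"),
      names_to = "domain", values_to = "auc", names_prefix = "auc_"
    )
    long$domain_effort <- as.integer(long$domain == "effort")
    out$age_domain <- tidy_lm(
      lm(auc ~ age_group * domain_effort, data = long)
    )
    if (has("income_bin")) {
      out$age_domain_income <- tidy_lm(
        lm(auc ~ age_group * domain_effort + income_bin, data = long)
      )
    }
  }
  if (has("auc_effort", "age_group", "score_rating")) {
    out$age_beyond_score_rating <- hierarchical_delta_r2(
      d, "auc_effort", "score_rating", "age_group"
    )
  }
  out
}
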