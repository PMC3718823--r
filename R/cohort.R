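#' Per-group parameter distributions for a synthetic cohort
#'
#' Default latent-parameter distributions emulating the study populations:
#' younger adults (YA) with a mean effort cost of 0.175 per load step and
#' older adults (OA) with a mean cost of 0.35 — chosen so that, after cost
#' truncation at zero and SV clamping, the implied group means land near the
#' observed effort-discounting statistics (YA mean AUC about 0.72, mean SV
#' at N = 4 about 0.49; OA about 0.36 and 0.20); d' intercepts and slopes
#' matching the observed performance
#' decline with load; OA slower overall; income distributions shifted higher
#' for OA (retirees' pre-retirement income), which drives their shallower
#' delay discounting through an income-dependent discount rate.
#'
#' @param age_group 0 for YA, 1 for OA.
#' @return A named list of distribution parameters, suitable for overriding
#'   field by field in [cohort_spec()].
#' @export
cohort_group_defaults <- function(age_group) {
  if (age_group == 0) {
    list(
      kappa_mean = 0.175, kappa_sd = 0.12, gamma = 0.12, tau = 0.05,
      d0_mean = 3.42, d0_sd = 0.5, delta_mean = 0.59, delta_sd = 0.10,
      rt0_mean = 0.592, rt0_sd = 0.10, rt_slope = 0.040,
      sigma_dprime = 0.30, sigma_rt = 0.05,
      income_probs = c(2, 3, 4, 5, 4, 3, 2, 1, 1),
      log_k_delay = log(0.010), k_income_slope = 0.25, k_sd = 0.5,
      k_mag_exp = 0.2,
      amount_rating_mean = 7.7, score_rating_mean = 4.9, rating_sd = 2.0,
      ncs_intercept = 50, ncs_slope = 20, ncs_sd = 9
    )
  } else {
    list(
      kappa_mean = 0.35, kappa_sd = 0.15, gamma = 0.12, tau = 0.05,
      d0_mean = 3.13, d0_sd = 0.5, delta_mean = 0.58, delta_sd = 0.10,
      rt0_mean = 0.785, rt0_sd = 0.10, rt_slope = 0.025,
      sigma_dprime = 0.30, sigma_rt = 0.05,
      income_probs = c(1, 1, 2, 3, 4, 5, 4, 3, 2),
      log_k_delay = log(0.010), k_income_slope = 0.25, k_sd = 0.5,
      k_mag_exp = 0.2,
      amount_rating_mean = 5.8, score_rating_mean = 6.6, rating_sd = 2.0,
      ncs_intercept = 50, ncs_slope = 20, ncs_sd = 9
    )
  }
}

#' Specify a synthetic cohort
#'
#' @param n_per_group Agents per age group (default 25).
#' @param ya,oa Named lists overriding fields of [cohort_group_defaults()]
#'   for each group.
#' @param seed Cohort-level RNG seed; per-agent substreams are derived from
#'   it, so the whole cohort is reproducible from this one integer.
#' @return A list of class `coged_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 25L, ya = list(), oa = list(),
                        seed = NULL) {
  stopifnot(n_per_group >= 1L)
  ya_full <- utils::modifyList(cohort_group_defaults(0), ya)
  oa_full <- utils::modifyList(cohort_group_defaults(1), oa)
  stopifnot(ya_full$kappa_sd >= 0, oa_full$kappa_sd >= 0,
            ya_full$tau >= 0, oa_full$tau >= 0)
  structure(
    list(n_per_group = as.integer(n_per_group), ya = ya_full, oa = oa_full,
         seed = seed),
    class = "coged_cohort_spec"
  )
}

# draw one agent's latent parameters from a group's distributions
draw_agent <- function(g, age_group, seed) {
  with_optional_seed(seed, {
    income_bin <- sample(1:9, 1, prob = g$income_probs)
    k_delay <- exp(g$log_k_delay - g$k_income_slope * (income_bin - 5) +
                     rnorm(1, 0, g$k_sd))
    params <- agent_params(
      kappa = max(0, rnorm(1, g$kappa_mean, g$kappa_sd)),
      gamma = g$gamma, tau = g$tau,
      k_delay = k_delay, k_mag_exp = g$k_mag_exp,
      age_group = age_group,
      d0 = rnorm(1, g$d0_mean, g$d0_sd),
      delta = max(0, rnorm(1, g$delta_mean, g$delta_sd)),
      rt0 = max(0.3, rnorm(1, g$rt0_mean, g$rt0_sd)),
      rt_slope = g$rt_slope,
      sigma_dprime = g$sigma_dprime, sigma_rt = g$sigma_rt,
      seed = seed
    )
    covars <- list(
      income_bin = income_bin,
      amount_rating = clamp(round(rnorm(1, g$amount_rating_mean, g$rating_sd)), 1, 10),
      score_rating = clamp(round(rnorm(1, g$score_rating_mean, g$rating_sd)), 1, 10),
      ncs_noise = rnorm(1, 0, g$ncs_sd)
    )
    list(params = params, covars = covars)
  })
}

# walk a randomized schedule, maintaining one staircase per
# (condition, base_amount), and log every choice trial
titrate_schedule <- function(params, schedule, domain, participant_id,
                             n_choices, start_frac = 0.5, step_frac = 0.25) {
  keys <- unique(schedule[, c("condition", "base_amount")])
  states <- list()
  for (r in seq_len(nrow(keys))) {
    key <- paste(keys$condition[r], keys$base_amount[r], sep = "|")
    states[[key]] <- titration_state(
      base_amount = keys$base_amount[r],
      start_amount = keys$base_amount[r] * start_frac,
      initial_step = keys$base_amount[r] * step_frac,
      max_choices = n_choices, condition = keys$condition[r]
    )
  }
  n <- nrow(schedule)
  offered <- numeric(n)
  chosen <- character(n)
  rts <- numeric(n)
  for (r in seq_len(n)) {
    key <- paste(schedule$condition[r], schedule$base_amount[r], sep = "|")
    st <- states[[key]]
    offered[r] <- st$variable_amount
    ch <- agent_choose(params, st$variable_amount, st$base_amount,
                       st$condition, domain = domain)
    chosen[r] <- ch
    rts[r] <- exp(rnorm(1, log(1.8), 0.3))
    states[[key]] <- apply_choice(st, ch)
  }
  trials <- tibble::tibble(
    participant_id = participant_id,
    phase = paste0(domain, "_discounting"),
    condition = schedule$condition,
    base_amount = schedule$base_amount,
    choice_index = schedule$choice_index,
    offered_amount = offered,
    choice = chosen,
    rt = rts
  )
  records <- dplyr::bind_rows(lapply(states, function(st) {
    tibble::tibble(
      participant_id = participant_id,
      condition = st$condition,
      base_amount = st$base_amount,
      indifference_amount = st$variable_amount,
      n_choices = st$choices_made
    )
  }))
  list(trials = trials, records = records)
}

#' Simulate a full synthetic cohort through the paradigm
#'
#' Draws latent parameters for `n_per_group` agents per age group, runs each
#' agent through the experiment design (N-back practice performance, effort
#' discounting titrations, and delay discounting titrations when the design
#' includes delays), and assembles the tidy tables the valuation and
#' inference modules consume.
#'
#' @param spec A [cohort_spec()].
#' @param config An [experiment_config()] (default the Experiment 1 preset).
#' @param seed Cohort seed; overrides `spec$seed` when given. All per-agent
#'   randomness derives from it.
#' @return A list of class `coged_cohort` with tibbles:
#'   \describe{
#'   \item{params}{true latent parameters per agent (for recovery checks)}
#'   \item{trials}{choice-level log (participant, phase, condition,
#'     base_amount, choice_index, offered_amount, choice, rt)}
#'   \item{sv}{long effort SV table: participant_id, age_group, level,
#'     base_amount, sv, true_sv, d_prime, mean_rt; level 1 rows carry the
#'     theoretical anchor SV = 1 with measured performance}
#'   \item{delay_sv}{long delay SV table (when delays are in the design)}
#'   \item{performance}{simulated run performance per practice level}
#'   \item{covariates}{per-participant age_group, ncs, income_bin, ratings}
#'   }
#' @export
simulate_cohort <- function(spec, config = experiment_config("exp1"),
                            seed = NULL) {
  stopifnot(inherits(spec, "coged_cohort_spec"))
  seed <- seed %||% spec$seed %||% 1L
  groups <- list(list(age = 0L, g = spec$ya, tag = "YA"),
                 list(age = 1L, g = spec$oa, tag = "OA"))
  params_rows <- list(); trials <- list(); sv_rows <- list()
  delay_rows <- list(); perf_rows <- list(); cov_rows <- list()
  idx <- 0L
  for (grp in groups) {
    levels_grp <- if (grp$age == 0L) config$levels_ya else config$levels_oa
    practice_grp <- seq_len(max(levels_grp))
    for (a in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", grp$tag, a)
      aseed <- substream_seed(seed, idx)
      drawn <- draw_agent(grp$g, grp$age, aseed)
      p <- drawn$params

      out <- with_optional_seed(substream_seed(aseed, 1), {
        perf <- simulate_performance(p, practice_grp)
        sched <- build_schedule(levels_grp, config$base_amounts,
                                n_choices = config$n_choices)
        eff <- titrate_schedule(p, sched, "effort", pid, config$n_choices)
        del <- NULL
        if (length(config$delays) > 0L) {
          dsched <- build_schedule(config$delays, config$delay_amounts,
                                   n_choices = config$n_choices)
          del <- titrate_schedule(p, dsched, "delay", pid, config$n_choices)
        }
        list(perf = perf, eff = eff, del = del)
      })

      perf_rows[[idx]] <- tibble::tibble(
        participant_id = pid, age_group = grp$age, level = practice_grp,
        d_prime = out$perf$d_prime, mean_rt = out$perf$mean_rt
      )
      trials[[length(trials) + 1L]] <- out$eff$trials

      rec <- out$eff$records
      sv_meas <- tibble::tibble(
        participant_id = pid, age_group = grp$age,
        level = rec$condition, base_amount = rec$base_amount,
        sv = subjective_value(rec$indifference_amount, rec$base_amount),
        true_sv = true_effort_sv(p, rec$condition, rec$base_amount)
      )
      anchor <- tibble::tibble(
        participant_id = pid, age_group = grp$age, level = 1,
        base_amount = config$base_amounts, sv = 1, true_sv = 1
      )
      sv_all <- dplyr::bind_rows(anchor, sv_meas)
      pf <- perf_rows[[idx]]
      sv_all$d_prime <- pf$d_prime[match(sv_all$level, pf$level)]
      sv_all$mean_rt <- pf$mean_rt[match(sv_all$level, pf$level)]
      sv_rows[[idx]] <- dplyr::arrange(sv_all, base_amount, level)

      if (!is.null(out$del)) {
        trials[[length(trials) + 1L]] <- out$del$trials
        drec <- out$del$records
        delay_rows[[idx]] <- tibble::tibble(
          participant_id = pid, age_group = grp$age,
          delay_days = drec$condition, base_amount = drec$base_amount,
          sv = subjective_value(drec$indifference_amount, drec$base_amount)
        )
      }

      auc_true <- 1 - 2 * p$kappa # linear-SV AUC over levels 2-4
      cov_rows[[idx]] <- tibble::tibble(
        participant_id = pid, age_group = grp$age,
        ncs = grp$g$ncs_intercept + grp$g$ncs_slope * clamp(auc_true, 0, 1) +
          drawn$covars$ncs_noise,
        income_bin = drawn$covars$income_bin,
        amount_rating = drawn$covars$amount_rating,
        score_rating = drawn$covars$score_rating
      )
      params_rows[[idx]] <- tibble::tibble(
        participant_id = pid, age_group = grp$age,
        kappa = p$kappa, gamma = p$gamma, tau = p$tau,
        k_delay = p$k_delay, k_mag_exp = p$k_mag_exp,
        d0 = p$d0, delta = p$delta, rt0 = p$rt0, rt_slope = p$rt_slope,
        seed = aseed
      )
    }
  }
  structure(
    list(
      params = dplyr::bind_rows(params_rows),
      trials = dplyr::bind_rows(trials),
      sv = dplyr::bind_rows(sv_rows),
      delay_sv = if (length(delay_rows)) dplyr::bind_rows(delay_rows) else NULL,
      performance = dplyr::bind_rows(perf_rows),
      covariates = dplyr::bind_rows(cov_rows),
      seed = seed,
      config = config
    ),
    class = "coged_cohort"
  )
}

#' @export
print.coged_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic COG-ED cohort: %d participants, %d choice trials, seed %s\n",
    nrow(x$covariates), nrow(x$trials), format(x$seed)
  ))
  invisible(x)
}
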