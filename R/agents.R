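#' Latent parameters of a synthetic participant
#'
#' A synthetic agent values the hard N-back option by a linear-in-load
#' effort cost and delayed rewards by a hyperbolic discount with a magnitude
#' effect, chooses with logistic noise, and produces load-dependent task
#' performance.
#'
#' @param kappa Effort cost per load step, as a fraction of the base amount
#'   per unit of (N - 1) at the reference base (>= 0).
#' @param gamma Amount-sensitivity exponent (>= 0): the per-step cost scales
#'   as `base^-gamma`, so gamma > 0 yields proportionally less discounting of
#'   larger offers.
#' @param k_delay Hyperbolic discount rate per day at a $1,000 reward.
#' @param k_mag_exp Magnitude-effect exponent (>= 0): the delay discount rate
#'   at amount A is `k_delay * (A / 1000)^-k_mag_exp`, so larger amounts are
#'   discounted at a lower rate.
#' @param tau Choice temperature in dollars (0 = deterministic; ties go EASY).
#' @param age_group 0 for younger adults, 1 for older adults.
#' @param d0 d' intercept at N = 1. @param delta d' decline per load step.
#' @param rt0 Mean correct-trial RT (seconds) at N = 1.
#' @param rt_slope RT increase per load step (seconds).
#' @param sigma_dprime,sigma_rt Performance noise SDs.
#' @param seed Per-agent RNG seed.
#' @param convex_cost If `TRUE`, effort cost grows quadratically in
#'   (N - 1) instead of linearly.
#' @return A list of class `coged_agent_params`.
#' @export
agent_params <- function(kappa = 0.14, gamma = 0, k_delay = 0.01,
                         k_mag_exp = 0.2, tau = 0.05, age_group = 0L,
                         d0 = 3.42, delta = 0.59, rt0 = 0.592,
                         rt_slope = 0.04, sigma_dprime = 0.3,
                         sigma_rt = 0.05, seed = NULL,
                         convex_cost = FALSE) {
  stopifnot(kappa >= 0, tau >= 0, gamma >= 0, k_delay >= 0, k_mag_exp >= 0)
  structure(
    list(
      kappa = kappa, gamma = gamma, k_delay = k_delay, k_mag_exp = k_mag_exp,
      tau = tau, age_group = as.integer(age_group), d0 = d0, delta = delta,
      rt0 = rt0, rt_slope = rt_slope, sigma_dprime = sigma_dprime,
      sigma_rt = sigma_rt, seed = seed, convex_cost = isTRUE(convex_cost)
    ),
    class = "coged_agent_params"
  )
}

#' True subjective value of a load level for an agent
#'
#' SV = clamp(1 - kappa * (N - 1) * base^-gamma, 0, 1): the reference level
#' N = 1 always has SV 1, SV decreases linearly in load (quadratically if
#' `convex_cost`), and with gamma > 0 larger base amounts are discounted
#' proportionally less.
#'
#' @param params A `coged_agent_params`.
#' @param level Load level N (>= 1).
#' @param base Base amount in dollars.
#' @return SV fraction in `[0, 1]`.
#' @examples
#' true_effort_sv(agent_params(kappa = 0.17), level = 4, base = 2) # 0.49
#' @export
true_effort_sv <- function(params, level, base) {
  stopifnot(all(level >= 1))
  steps <- if (params$convex_cost) (level - 1)^2 else (level - 1)
  clamp(1 - params$kappa * steps * base^(-params$gamma), 0, 1)
}

#' Present value of a delayed reward for an agent
#'
#' Hyperbolic discounting with a magnitude effect:
#' `V = A / (1 + k(A) * D)` with `k(A) = k_delay * (A / 1000)^-k_mag_exp`,
#' so the discount rate at $25,000 never exceeds the rate at $1,000.
#'
#' @param params A `coged_agent_params`.
#' @param amount Delayed reward in dollars.
#' @param delay_days Delay in days (>= 0).
#' @return Present value in dollars.
#' @export
true_delay_value <- function(params, amount, delay_days) {
  stopifnot(all(delay_days >= 0))
  k <- params$k_delay * (amount / 1000)^(-params$k_mag_exp)
  amount / (1 + k * delay_days)
}

#' One discounting choice by a synthetic agent
#'
#' The agent values the hard option at `SV(condition) * hard_offer` (effort)
#' or at its hyperbolically discounted present value (delay), and the easy
#' option at its face amount. With temperature 0 the higher-valued option is
#' chosen deterministically (exact ties go EASY); otherwise
#' `P(HARD) = logistic((value_hard - value_easy) / tau)`.
#'
#' @param params A `coged_agent_params`.
#' @param easy_offer Variable (easy / immediate) offer in dollars.
#' @param hard_offer Fixed (hard / delayed) offer in dollars.
#' @param condition Load level (effort) or delay in days (delay).
#' @param domain `"effort"` or `"delay"`.
#' @return `"HARD"` or `"EASY"`.
#' @export
agent_choose <- function(params, easy_offer, hard_offer, condition,
                         domain = c("effort", "delay")) {
  domain <- match.arg(domain)
  stopifnot(easy_offer >= 0, hard_offer >= 0)
  v_hard <- if (domain == "effort") {
    true_effort_sv(params, condition, hard_offer) * hard_offer
  } else {
    true_delay_value(params, hard_offer, condition)
  }
  if (params$tau == 0) {
    if (v_hard > easy_offer) "HARD" else "EASY"
  } else {
    p_hard <- plogis((v_hard - easy_offer) / params$tau)
    if (runif(1) < p_hard) "HARD" else "EASY"
  }
}

#' Agent as a titration choice callback
#'
#' Wraps an agent into the `(easy_offer, condition, base_amount)` callback
#' signature expected by [run_titration()].
#'
#' @param params A `coged_agent_params`.
#' @param domain `"effort"` or `"delay"`.
#' @return A choice function.
#' @export
agent_callback <- function(params, domain = c("effort", "delay")) {
  domain <- match.arg(domain)
  function(easy_offer, condition, base_amount) {
    agent_choose(params, easy_offer, base_amount, condition, domain = domain)
  }
}

#' Simulate N-back performance at one load level
#'
#' d' declines linearly with load (`d0 - delta * (N - 1)` plus Gaussian
#' noise, floored at 0) and mean correct-trial RT grows linearly with load
#' (floored at 0.2 s). Older-adult offsets enter through the agent's own
#' `d0`, `delta`, `rt0`, `rt_slope` (set by the cohort spec per age group).
#'
#' @param params A `coged_agent_params`.
#' @param level Load level N.
#' @return A list with `d_prime` and `mean_rt` (seconds).
#' @export
simulate_performance <- function(params, level) {
  dp <- params$d0 - params$delta * (level - 1) +
    rnorm(length(level), 0, params$sigma_dprime)
  rt <- params$rt0 + params$rt_slope * (level - 1) +
    rnorm(length(level), 0, params$sigma_rt)
  list(d_prime = pmax(dp, 0), mean_rt = pmax(rt, 0.2))
}
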