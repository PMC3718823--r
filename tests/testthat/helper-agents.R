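# deterministic choice callbacks used across tests

# agent indifferent at easy offer v_star: prefers HARD while the easy offer
# is below v_star, EASY at or above it (ties resolve EASY)
threshold_agent <- function(v_star) {
  function(easy_offer, condition, base_amount) {
    if (easy_offer < v_star) "HARD" else "EASY"
  }
}

always_hard <- function(easy_offer, condition, base_amount) "HARD"
always_easy <- function(easy_offer, condition, base_amount) "EASY"

# enumerate the staircase endpoint for one explicit choice path
trace_titration <- function(choices, start = 1, step = 0.5) {
  v <- start
  s <- step
  for (ch in choices) {
    v <- v + if (ch == "HARD") s else -s
    s <- s / 2
  }
  v
}

# all 2^n HARD/EASY paths as a list of character vectors
all_choice_paths <- function(n = 6L) {
  grid <- expand.grid(rep(list(c("HARD", "EASY")), n),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# long SV table generated directly from the random-intercept model (not via
# titration): sv = b0_j + slope * (level - center) + coefficients on
# performance + residual noise
make_mlm_data <- function(n_participants = 25, slope = -0.13,
                          sd_intercept = 0.15, sd_resid = 0.1,
                          b_dprime = 0, b_rt = 0, center = 2.5,
                          age_group = 0L) {
  rows <- lapply(seq_len(n_participants), function(j) {
    b0 <- 0.7 + rnorm(1, 0, sd_intercept)
    level <- 1:4
    d_prime <- 3.4 - 0.6 * (level - 1) + rnorm(4, 0, 0.3)
    mean_rt <- 0.6 + 0.04 * (level - 1) + rnorm(4, 0, 0.05)
    tibble::tibble(
      participant_id = sprintf("P%02d", j), age_group = age_group,
      level = level, d_prime = d_prime, mean_rt = mean_rt,
      sv = b0 + slope * (level - center) + b_dprime * d_prime +
        b_rt * mean_rt + rnorm(4, 0, sd_resid)
    )
  })
  dplyr::bind_rows(rows)
}
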