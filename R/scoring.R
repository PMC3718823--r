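#' Signal-detection sensitivity (d')
#'
#' Computes d' = z(H) - z(F) from hit and false-alarm counts. Extreme rates
#' are clamped into `[1/(2n), 1 - 1/(2n)]` of their respective trial counts
#' before the normal-quantile transform, so perfect scores yield a finite
#' value.
#'
#' @param hits Number of targets answered "target".
#' @param n_targets Number of target trials (> 0).
#' @param fas Number of non-targets answered "target" (false alarms).
#' @param n_nontargets Number of non-target trials (> 0).
#' @return Numeric d' value.
#' @examples
#' dprime(12, 16, 12, 48) # z(0.75) - z(0.25)
#' @export
dprime <- function(hits, n_targets, fas, n_nontargets) {
  stopifnot(n_targets > 0, n_nontargets > 0, hits >= 0, fas >= 0)
  h <- clamp(hits / n_targets, 1 / (2 * n_targets), 1 - 1 / (2 * n_targets))
  f <- clamp(fas / n_nontargets, 1 / (2 * n_nontargets), 1 - 1 / (2 * n_nontargets))
  qnorm(h) - qnorm(f)
}

#' Score an N-back run
#'
#' Scores per-item responses against a stimulus list's roles. Targets are the
#' items matching at exactly lag N; every other item (lures and fillers alike)
#' counts as a non-target. The first N positions can never be targets and so
#' never enter the hit-rate denominator. A missing response (`"none"`) is
#' incorrect for targets and non-targets alike, since a response was required
#' for every item; mean RT is taken over correct responded trials only.
#'
#' Run feedback is `"Good job!"` when both the percent-of-targets-correct and
#' percent-of-non-targets-correct scores exceed 50, and
#' `"Please try harder!"` otherwise.
#'
#' @param sl A `coged_stimulus_list`.
#' @param responses Character vector aligned with `sl$items`, each element
#'   one of `"target"`, `"nontarget"`, `"none"`.
#' @param rts Optional numeric vector of response times in seconds, aligned
#'   with `responses` (NA where no response was made).
#' @return A list of class `coged_run_performance` with elements `hit_rate`,
#'   `fa_rate`, `d_prime`, `mean_rt`, `pct_targets_correct`,
#'   `pct_nontargets_correct`, `n_targets`, `n_nontargets`, `feedback`.
#' @export
score_run <- function(sl, responses, rts = NULL) {
  n <- length(sl$items)
  if (length(responses) != n) {
    stop(sprintf(
      "responses (%d) not aligned with stimulus items (%d)",
      length(responses), n
    ), call. = FALSE)
  }
  if (!is.null(rts) && length(rts) != n) {
    stop("rts not aligned with stimulus items", call. = FALSE)
  }
  bad <- setdiff(unique(responses), c("target", "nontarget", "none"))
  if (length(bad) > 0L) {
    stop("invalid response tokens: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  is_target <- sl$roles == "target"
  n_targets <- sum(is_target)
  n_nontargets <- sum(!is_target)

  hits <- sum(is_target & responses == "target")
  fas <- sum(!is_target & responses == "target")
  hit_rate <- if (n_targets > 0L) hits / n_targets else NA_real_
  fa_rate <- if (n_nontargets > 0L) fas / n_nontargets else NA_real_

  pct_t <- 100 * hit_rate
  pct_nt <- if (n_nontargets > 0L) {
    100 * mean(responses[!is_target] == "nontarget")
  } else {
    NA_real_
  }

  dp <- if (n_targets > 0L && n_nontargets > 0L) {
    dprime(hits, n_targets, fas, n_nontargets)
  } else {
    NA_real_
  }

  correct <- (is_target & responses == "target") |
    (!is_target & responses == "nontarget")
  mean_rt <- if (!is.null(rts) && any(correct & !is.na(rts))) {
    mean(rts[correct], na.rm = TRUE)
  } else {
    NA_real_
  }

  feedback <- if (isTRUE(pct_t > 50) && isTRUE(pct_nt > 50)) {
    "Good job!"
  } else {
    "Please try harder!"
  }

  structure(
    list(
      hit_rate = hit_rate, fa_rate = fa_rate, d_prime = dp, mean_rt = mean_rt,
      pct_targets_correct = pct_t, pct_nontargets_correct = pct_nt,
      n_targets = n_targets, n_nontargets = n_nontargets, feedback = feedback
    ),
    class = "coged_run_performance"
  )
}

#' @export
print.coged_run_performance <- function(x, ...) {
  cat(sprintf(
    "N-back run: %.0f%% targets, %.0f%% non-targets correct; d' = %.2f; %s\n",
    x$pct_targets_correct, x$pct_nontargets_correct, x$d_prime, x$feedback
  ))
  invisible(x)
}
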