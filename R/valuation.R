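#' Relative subjective value of a discounted offer
#'
#' The subjective value (SV) of performing the harder (or waiting for the
#' later) option is the indifference amount expressed as a fraction of the
#' fixed base offer: SV = indifference / base. SV = 1 means no discounting.
#'
#' @param indifference Indifference amount in dollars.
#' @param base Base (fixed) offer in dollars (> 0).
#' @return SV fraction.
#' @examples
#' subjective_value(0.98, 2.00) # 0.49
#' @export
subjective_value <- function(indifference, base) {
  if (any(base <= 0)) stop("base amount must be positive", call. = FALSE)
  indifference / base
}

#' Effort (or delay) premium implied by a subjective value
#'
#' The extra payment a participant demands to take the hard option rather
#' than the easy reference: `base * (1 - sv)`. A YA with SV = 0.49 on a
#' $2.00 offer requires an additional $1.02 to perform the 4-back instead of
#' the 1-back.
#'
#' @param sv Subjective value fraction in `[0, 1]`.
#' @param base Base offer in dollars.
#' @return Dollar premium.
#' @examples
#' extra_payment(0.49, 2.00) # 1.02
#' @export
extra_payment <- function(sv, base) {
  stopifnot(all(sv >= 0), all(sv <= 1))
  base * (1 - sv)
}

# normalize x to [0,1]; constant x is an error upstream
normalize_axis <- function(x) (x - min(x)) / (max(x) - min(x))

#' Default condition axes for discounting AUC
#'
#' Effort discounting uses load levels N = 2-4; delay discounting uses
#' delays of one week, six months, and 1, 3, 5 and 10 years, in days
#' (six months = 182.5 days, a year = 365 days).
#'
#' @param domain `"effort"` or `"delay"`.
#' @return Numeric vector of condition coordinates.
#' @export
default_conditions <- function(domain = c("effort", "delay")) {
  domain <- match.arg(domain)
  if (domain == "effort") 2:4 else c(7, 182.5, 365, 1095, 1825, 3650)
}

#' Area under the discounting curve
#'
#' Trapezoid integral of subjective value against the condition axis (load
#' level for effort, delay in days for delay), with the axis rescaled to
#' total width 1 so that the AUC lies in `[0, 1]` whenever all SVs do, and
#' equals 1 for a non-discounter. The normalization makes the AUC invariant
#' to affine rescaling of the raw axis.
#'
#' @param sv Numeric vector of subjective values, ordered by condition.
#' @param conditions Numeric condition coordinates, strictly increasing;
#'   defaults to [default_conditions()] for `domain` when lengths agree.
#' @param domain `"effort"` or `"delay"` (used only to pick the default axis).
#' @return AUC value.
#' @examples
#' discount_auc(c(0.8, 0.5, 0.2)) # 0.5
#' @export
discount_auc <- function(sv, conditions = NULL,
                         domain = c("effort", "delay")) {
  domain <- match.arg(domain)
  if (length(sv) < 2L) {
    stop("at least 2 subjective values are needed for an AUC", call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- default_conditions(domain)
    if (length(conditions) != length(sv)) {
      stop("supply `conditions` when sv does not span the default axis",
           call. = FALSE)
    }
  }
  if (length(conditions) != length(sv)) {
    stop("conditions and sv lengths differ", call. = FALSE)
  }
  if (any(diff(conditions) <= 0)) {
    stop("conditions must be strictly increasing", call. = FALSE)
  }
  trapz_integral(normalize_axis(conditions), sv)
}

#' Per-participant discounting AUC table
#'
#' Computes one AUC per participant and base amount from a long table of
#' subjective values, restricted to the conditions in `conditions` so that
#' every AUC is computed on the same basis.
#'
#' @param sv_tbl Tibble with columns `participant_id`, `base_amount`,
#'   `condition`, `sv` (and optionally others, carried along if constant
#'   within participant x amount is not assumed).
#' @param conditions Conditions to use (default effort levels 2-4).
#' @param domain `"effort"` or `"delay"`.
#' @return Tibble with columns `participant_id`, `base_amount`, `auc`,
#'   `n_conditions`.
#' @export
auc_table <- function(sv_tbl, conditions = default_conditions(domain),
                      domain = c("effort", "delay")) {
  domain <- match.arg(domain)
  sv_tbl |>
    dplyr::filter(condition %in% conditions) |>
    dplyr::arrange(participant_id, base_amount, condition) |>
    dplyr::group_by(participant_id, base_amount) |>
    dplyr::summarise(
      auc = discount_auc(sv, conditions = condition, domain = domain),
      n_conditions = dplyr::n(),
      .groups = "drop"
    )
}

#' NASA-TLX composite workload score
#'
#' Computes, for each of the six NASA Task Load Index scales (mental demand,
#' physical demand, temporal demand, failure, effort, frustration), the
#' trapezoid area under the raw 0-21 ratings across load levels on a
#' normalized level axis, then averages the six per-scale AUCs into a single
#' composite. Ratings are left in raw rating units, so a participant rating
#' every scale 21 at every level gets a composite of 21.
#'
#' @param ratings Tibble/data frame with columns `scale_name`, `level`,
#'   `rating` (0-21).
#' @param scales Required scale names; every one must be present.
#' @return Composite score (mean of per-scale AUCs, in rating units).
#' @export
ntlx_composite <- function(ratings,
                           scales = c("mental", "physical", "temporal",
                                      "failure", "effort", "frustration")) {
  ratings <- tibble::as_tibble(ratings)
  stopifnot(all(c("scale_name", "level", "rating") %in% names(ratings)))
  missing <- setdiff(scales, unique(ratings$scale_name))
  if (length(missing) > 0L) {
    stop("missing NTLX scale(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(ratings$rating < 0 | ratings$rating > 21)) {
    stop("NTLX ratings must lie in [0, 21]", call. = FALSE)
  }
  per_scale <- vapply(scales, function(s) {
    d <- ratings[ratings$scale_name == s, ]
    d <- d[order(d$level), ]
    if (nrow(d) < 2L) {
      stop(sprintf("NTLX scale '%s' needs ratings at >= 2 levels", s),
           call. = FALSE)
    }
    trapz_integral(normalize_axis(d$level), d$rating)
  }, numeric(1))
  mean(per_scale)
}

#' Amount (magnitude) effect on effort discounting
#'
#' Compares per-participant AUCs between two base amounts: larger offers are
#' typically discounted proportionally less. Reports mean AUC per amount, a
#' paired Wilcoxon signed-rank test across participants with both amounts,
#' and per-condition mean discounted dollar values (`sv * base`) with their
#' decrements (`base - sv * base`).
#'
#' @param sv_tbl Long SV table with columns `participant_id`, `base_amount`,
#'   `condition`, `sv`, containing exactly two base amounts.
#' @param conditions Conditions used for the AUCs (default levels 2-4).
#' @return A list with `mean_auc` (tibble amount x mean), `wilcoxon_p`,
#'   `n_pairs`, `n_dropped`, `auc_by_participant` (wide tibble), and
#'   `condition_values` (per amount x condition mean discounted value and
#'   decrement). When all paired differences are zero the p-value is `NA`.
#' @export
amount_effect <- function(sv_tbl, conditions = default_conditions("effort")) {
  amounts <- sort(unique(sv_tbl$base_amount))
  if (length(amounts) != 2L) {
    stop("amount_effect needs exactly two base amounts, got ",
         length(amounts), call. = FALSE)
  }
  aucs <- auc_table(sv_tbl, conditions = conditions, domain = "effort")
  wide <- tidyr::pivot_wider(aucs[, c("participant_id", "base_amount", "auc")],
                             names_from = base_amount, values_from = auc)
  lo <- as.character(amounts[1])
  hi <- as.character(amounts[2])
  paired <- wide[complete.cases(wide[, c(lo, hi)]), ]
  n_dropped <- nrow(wide) - nrow(paired)
  if (n_dropped > 0L) {
    warning(n_dropped, " participant(s) without both amounts dropped",
            call. = FALSE)
  }
  diffs <- paired[[hi]] - paired[[lo]]
  wp <- if (length(diffs) == 0L || all(diffs == 0)) {
    NA_real_
  } else {
    suppressWarnings(wilcox.test(paired[[hi]], paired[[lo]],
                                 paired = TRUE)$p.value)
  }
  cond_vals <- sv_tbl |>
    dplyr::filter(condition %in% conditions) |>
    dplyr::group_by(base_amount, condition) |>
    dplyr::summarise(
      mean_sv = mean(sv),
      mean_discounted_value = mean(sv) * base_amount[1],
      mean_decrement = base_amount[1] * (1 - mean(sv)),
      .groups = "drop"
    )
  list(
    mean_auc = tibble::tibble(
      base_amount = amounts,
      mean_auc = c(mean(paired[[lo]]), mean(paired[[hi]]))
    ),
    wilcoxon_p = wp,
    n_pairs = nrow(paired),
    n_dropped = n_dropped,
    auc_by_participant = wide,
    condition_values = cond_vals
  )
}
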