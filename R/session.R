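#' Experiment configuration presets
#'
#' `"exp1"`: N-back practice then effort discounting at a single $2.00 base;
#' younger adults titrate levels 2-6, older adults levels 2-4, six choices
#' per level (30 and 18 choices respectively). `"exp2"`: both groups titrate
#' levels 2-4 at $1 and $5 bases (36 effort choices) plus delay discounting
#' over one week, six months, and 1, 3, 5, 10 years at $1,000 and $25,000
#' (72 delay choices).
#'
#' The variable offer starts at half the base with a first adjustment of a
#' quarter of the base, halving each choice; with a $2.00 base this is the
#' $1.00 start / $0.50 first step whose sixth adjustment is $0.015625.
#'
#' @param preset `"exp1"` or `"exp2"`.
#' @param ... Named fields overriding the preset (e.g. `n_choices`,
#'   `base_amounts`, `repetitions_paid`).
#' @return A list of class `coged_experiment_config`.
#' @export
experiment_config <- function(preset = c("exp1", "exp2"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "exp1") {
    list(
      preset = "exp1",
      levels_ya = 2:6, levels_oa = 2:4,
      base_amounts = 2,
      delays = numeric(0), delay_amounts = numeric(0),
      n_choices = 6L, start_frac = 0.5, step_frac = 0.25,
      repetitions_paid = 4L,
      run_length = 64L, n_targets = 16L, practice_runs_per_level = 3L,
      response_window_s = 1.5, inter_item_interval_s = 3.5
    )
  } else {
    list(
      preset = "exp2",
      levels_ya = 2:4, levels_oa = 2:4,
      base_amounts = c(1, 5),
      delays = c(7, 182.5, 365, 1095, 1825, 3650),
      delay_amounts = c(1000, 25000),
      n_choices = 6L, start_frac = 0.5, step_frac = 0.25,
      repetitions_paid = 4L,
      run_length = 64L, n_targets = 16L, practice_runs_per_level = 3L,
      response_window_s = 1.5, inter_item_interval_s = 3.5
    )
  }
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg <- utils::modifyList(cfg, overrides)
  }
  structure(cfg, class = "coged_experiment_config")
}

#' Randomly select and pay one discounting choice
#'
#' One trial is drawn uniformly from the choice log; the participant repeats
#' the chosen option's task and is paid its amount once per repetition. The
#' paid amount is the easy offer shown on that trial if the participant
#' chose EASY, and the base amount if they chose HARD.
#'
#' @param trial_log Tibble with at least columns `choice`, `offered_amount`,
#'   `base_amount` (and typically `condition`, `participant_id`).
#' @param repetitions Paid repetitions (default 4).
#' @param seed Optional seed for the draw.
#' @return A list of class `coged_payment_outcome` with the selected `trial`
#'   (one-row tibble), `amount_per_repetition`, `repetitions`, `payout`.
#' @export
select_payment <- function(trial_log, repetitions = 4L, seed = NULL) {
  trial_log <- tibble::as_tibble(trial_log)
  if (nrow(trial_log) == 0L) {
    stop("cannot select a payment from an empty trial log", call. = FALSE)
  }
  stopifnot(repetitions >= 0L)
  row <- with_optional_seed(seed, sample.int(nrow(trial_log), 1L))
  trial <- trial_log[row, ]
  amount <- if (trial$choice == "EASY") {
    trial$offered_amount
  } else {
    trial$base_amount
  }
  structure(
    list(
      trial = trial,
      amount_per_repetition = amount,
      repetitions = as.integer(repetitions),
      payout = amount * repetitions
    ),
    class = "coged_payment_outcome"
  )
}

#' @export
print.coged_payment_outcome <- function(x, ...) {
  cat(sprintf(
    "Selected %s choice at $%.4f x %d repetitions = $%.4f payout\n",
    x$trial$choice, x$amount_per_repetition, x$repetitions, x$payout
  ))
  invisible(x)
}

#' Run the full simulation-to-inference pipeline
#'
#' Simulates a cohort through the configured design, computes subjective
#' values and discounting AUCs, fits the multilevel models (per-group and
#' pooled with age terms and heterogeneous variance), and writes all tables
#' as CSV plus a JSON manifest (seed, config, file checksums) to `out_dir`.
#' Identical seeds produce byte-identical CSV outputs.
#'
#' @param config An [experiment_config()].
#' @param cohort A [cohort_spec()].
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return A list of class `coged_run` with elements `cohort`, `auc`,
#'   `mlm_by_group` (list), `mlm_pooled`, `covariates`, `manifest`, and
#'   `paths` (when written).
#' @export
run_pipeline <- function(config, cohort, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(config, "coged_experiment_config"),
            inherits(cohort, "coged_cohort_spec"))
  sim <- simulate_cohort(cohort, config = config, seed = seed)

  aucs <- auc_table(sim$sv |> dplyr::rename(condition = level),
                    conditions = 2:4, domain = "effort")
  delay_aucs <- NULL
  if (!is.null(sim$delay_sv)) {
    delay_aucs <- auc_table(
      sim$delay_sv |> dplyr::rename(condition = delay_days),
      conditions = config$delays, domain = "delay"
    )
  }

  first_base <- config$base_amounts[1]
  sv_first <- sim$sv[sim$sv$base_amount == first_base, ]
  mlm_by_group <- lapply(c(YA = 0, OA = 1), function(a) {
    fit_sv_mlm(sv_first[sv_first$age_group == a, ], include_anchor = TRUE)
  })
  mlm_pooled <- fit_sv_mlm(sv_first, include_anchor = TRUE,
                           age_terms = TRUE, heterogeneous_by_age = TRUE)

  cov_tbl <- sim$covariates
  eff <- aucs |>
    dplyr::filter(base_amount == first_base) |>
    dplyr::select(participant_id, auc_effort = auc)
  cov_tbl <- dplyr::left_join(cov_tbl, eff, by = "participant_id")
  if (!is.null(delay_aucs)) {
    del <- delay_aucs |>
      dplyr::group_by(participant_id) |>
      dplyr::summarise(auc_delay = mean(auc), .groups = "drop")
    cov_tbl <- dplyr::left_join(cov_tbl, del, by = "participant_id")
  }
  regs <- covariate_regressions(cov_tbl)

  manifest <- list(
    package = "coged",
    version = as.character(utils::packageVersion("coged")),
    seed = seed,
    config = unclass(config),
    n_participants = nrow(sim$covariates),
    n_trials = nrow(sim$trials)
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tbl, name) {
      p <- file.path(out_dir, name)
      readr::write_csv(tbl, p)
      p
    }
    paths <- c(
      trials = wr(sim$trials, "trials.csv"),
      sv = wr(sim$sv, "sv.csv"),
      performance = wr(sim$performance, "performance.csv"),
      covariates = wr(cov_tbl, "covariates.csv"),
      auc = wr(aucs, "auc_effort.csv")
    )
    if (!is.null(delay_aucs)) {
      paths <- c(paths, auc_delay = wr(delay_aucs, "auc_delay.csv"))
    }
    coef_tbl <- dplyr::bind_rows(
      lapply(names(mlm_by_group), function(nm) {
        dplyr::mutate(mlm_by_group[[nm]]$coefficients, model = nm,
                      .before = 1)
      }),
      dplyr::mutate(mlm_pooled$coefficients, model = "pooled", .before = 1)
    )
    paths <- c(paths, mlm = wr(coef_tbl, "mlm_coefficients.csv"))
    manifest$files <- as.list(tools::md5sum(unname(paths)))
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths <- c(paths, manifest = mp)
  }
  structure(
    list(
      cohort = sim, auc = aucs, delay_auc = delay_aucs,
      mlm_by_group = mlm_by_group, mlm_pooled = mlm_pooled,
      covariates = cov_tbl, regressions = regs,
      manifest = manifest, paths = paths
    ),
    class = "coged_run"
  )
}

#' Read a trial log written by the pipeline
#'
#' @param path CSV path with the shared trial-log schema.
#' @return Tibble of trials.
#' @export
read_trial_log <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    phase = readr::col_character(),
                    choice = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
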