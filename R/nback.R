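#' N-back consonant alphabet
#'
#' The 20 uppercase English consonants used as N-back stimuli. Y is excluded
#' as ambiguous between vowel and consonant.
#'
#' @return Character vector of 20 single letters.
#' @export
nback_alphabet <- function() {
  setdiff(LETTERS, c("A", "E", "I", "O", "U", "Y"))
}

#' Default lure counts by N-back load level
#'
#' Lures are items that repeat at a lag within N+2 positions of their last
#' presentation, but not at exactly lag N, and are included to make runs
#' harder by eliciting false alarms. The default per-level counts are
#' 8 (N = 1), 6 (N = 2), 5 (N = 3) and 3 (N = 4, 5, 6).
#'
#' @param level Integer load level N.
#' @return Integer lure count.
#' @export
default_lure_count <- function(level) {
  counts <- c(`1` = 8L, `2` = 6L, `3` = 5L, `4` = 3L, `5` = 3L, `6` = 3L)
  if (as.character(level) %in% names(counts)) {
    counts[[as.character(level)]]
  } else {
    3L
  }
}

# lags at which a repeat counts as a lure (all lags <= N+2 except N itself)
lure_lags <- function(level) setdiff(seq_len(level + 2L), level)

#' Generate a constrained N-back stimulus list
#'
#' Builds an ordered sequence of consonants for one N-back run such that it
#' contains exactly `n_targets` targets (items matching the item N positions
#' back) and exactly `n_lures` lures (items matching a previous item at some
#' lag of at most N+2, but not exactly N). All remaining items are fillers
#' that match no previous item at any lag up to N+2.
#'
#' Construction places target and lure positions at random, then fills items
#' left to right under the local matching constraints; infeasible placements
#' are rejected and resampled up to `max_attempts` times.
#'
#' @param level Integer load level N (>= 1).
#' @param length Number of items in the run (default 64).
#' @param n_targets Number of targets (default 16).
#' @param n_lures Number of lures; defaults to [default_lure_count()] for the
#'   level.
#' @param seed Optional integer seed; a fixed seed reproduces the same list.
#' @param max_attempts Cap on rejection-sampling attempts (default 10000).
#' @return An object of class `coged_stimulus_list`: a list with elements
#'   `level`, `items` (character vector), `roles` (character vector in
#'   `"target"`, `"lure"`, `"filler"`), `length`, `n_targets`, `n_lures`,
#'   `seed`, and display metadata (`response_window_s = 1.5`,
#'   `inter_item_interval_s = 3.5`).
#' @examples
#' sl <- generate_stimulus_list(level = 2, seed = 7)
#' table(sl$roles)
#' @export
generate_stimulus_list <- function(level, length = 64L, n_targets = 16L,
                                   n_lures = default_lure_count(level),
                                   seed = NULL, max_attempts = 10000L) {
  level <- as.integer(level)
  length <- as.integer(length)
  n_targets <- as.integer(n_targets)
  n_lures <- as.integer(n_lures)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  if (length <= level) stop("length must exceed level", call. = FALSE)

  target_eligible <- seq.int(level + 1L, length)
  min_lure_lag <- min(lure_lags(level))
  lure_eligible <- seq_len(length)[seq_len(length) > min_lure_lag]
  if (n_targets > base::length(target_eligible)) {
    stop(sprintf(
      "infeasible constraints: %d targets requested but only %d positions allow a lag-%d match",
      n_targets, base::length(target_eligible), level
    ), call. = FALSE)
  }
  if (n_targets + n_lures > length - level) {
    stop(sprintf(
      "infeasible constraints: %d targets + %d lures exceed the %d placeable positions",
      n_targets, n_lures, length - level
    ), call. = FALSE)
  }

  with_optional_seed(seed, {
    alphabet <- nback_alphabet()
    lags_l <- lure_lags(level)
    for (attempt in seq_len(max_attempts)) {
      roles <- rep("filler", length)
      tpos <- if (n_targets > 0L) sample(target_eligible, n_targets) else integer(0)
      roles[tpos] <- "target"
      lpool <- setdiff(lure_eligible, tpos)
      if (n_lures > base::length(lpool)) next
      lpos <- if (n_lures > 0L) sample(lpool, n_lures) else integer(0)
      roles[lpos] <- "lure"

      items <- character(length)
      ok <- TRUE
      for (i in seq_len(length)) {
        prev_lags <- seq_len(min(i - 1L, level + 2L))
        if (roles[i] == "target") {
          items[i] <- items[i - level]
        } else if (roles[i] == "lure") {
          ll <- lags_l[lags_l < i]
          cand <- unique(items[i - ll])
          if (i > level) cand <- setdiff(cand, items[i - level])
          if (base::length(cand) == 0L) {
            ok <- FALSE
            break
          }
          items[i] <- if (base::length(cand) == 1L) cand else sample(cand, 1L)
        } else {
          forbidden <- items[i - prev_lags]
          items[i] <- sample(setdiff(alphabet, forbidden), 1L)
        }
      }
      if (!ok) next

      sl <- structure(
        list(
          level = level, items = items, roles = roles, length = length,
          n_targets = n_targets, n_lures = n_lures, seed = seed,
          response_window_s = 1.5, inter_item_interval_s = 3.5
        ),
        class = "coged_stimulus_list"
      )
      counts <- validate_stimulus_list(sl)
      if (counts$targets == n_targets && counts$lures == n_lures) {
        return(sl)
      }
    }
    stop(sprintf(
      "could not satisfy stimulus constraints (level %d, %d targets, %d lures) after %d attempts",
      level, n_targets, n_lures, max_attempts
    ), call. = FALSE)
  })
}

#' Recount stimulus roles by brute-force lag scan
#'
#' Independently re-derives the role of every item in a stimulus list by
#' scanning all lags up to N+2, without using the generator's stored labels:
#' an item is a target if it matches the item exactly N back, otherwise a
#' lure if it matches any earlier item at a lag of at most N+2, otherwise a
#' filler. Matching is case-insensitive.
#'
#' @param sl A `coged_stimulus_list`, or a list with `items` and `level`.
#' @return A list with integer counts `targets`, `lures`, `fillers` and the
#'   recomputed per-item `roles` vector.
#' @export
validate_stimulus_list <- function(sl) {
  items <- toupper(sl$items)
  level <- as.integer(sl$level)
  n <- length(items)
  if (n == 0L) stop("stimulus list is empty", call. = FALSE)
  roles <- character(n)
  for (i in seq_len(n)) {
    lags <- seq_len(min(i - 1L, level + 2L))
    hit <- lags[items[i] == items[i - lags]]
    roles[i] <- if (level %in% hit) {
      "target"
    } else if (length(hit) > 0L) {
      "lure"
    } else {
      "filler"
    }
  }
  list(
    targets = sum(roles == "target"),
    lures = sum(roles == "lure"),
    fillers = sum(roles == "filler"),
    roles = roles
  )
}

#' Convert a stimulus list to a data frame
#'
#' @param x A `coged_stimulus_list`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `item`, `role`, `level`.
#' @export
as.data.frame.coged_stimulus_list <- function(x, ...) {
  as.data.frame(tibble::tibble(
    position = seq_along(x$items),
    item = x$items,
    role = x$roles,
    level = x$level
  ))
}

#' @export
print.coged_stimulus_list <- function(x, ...) {
  cat(sprintf(
    "N-back stimulus list: level %d, %d items (%d targets, %d lures, %d fillers)\n",
    x$level, x$length, x$n_targets, x$n_lures,
    x$length - x$n_targets - x$n_lures
  ))
  cat(paste(x$items, collapse = " "), "\n")
  invisible(x)
}

#' Write a stimulus list to CSV or JSON
#'
#' @param sl A `coged_stimulus_list`.
#' @param path Output file path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return The path, invisibly.
#' @export
write_stimulus_list <- function(sl, path) {
  df <- as.data.frame(sl)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(
        level = sl$level, n_targets = sl$n_targets, n_lures = sl$n_lures,
        items = sl$items, roles = sl$roles
      ),
      path,
      auto_unbox = TRUE, pretty = TRUE
    )
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}
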