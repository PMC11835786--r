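#' Contextual prefilter configuration
#'
#' @param recency_window Days of look-back for the repetition filter
#'   (default 3: a meal put forward in the previous 3 days is held back
#'   to enhance variety).
#' @param recency_source Which history feeds the repetition filter:
#'   shown recommendation lists (default), orders, or both.
#' @param strict_composite_mode When `TRUE` (default), a meal containing
#'   an unresolved composite ingredient is treated as unsafe for any user
#'   with at least one allergy — unknown contents count as unsafe.
#' @param min_candidates If fewer meals than this survive, recency
#'   exclusions (never safety ones) are restored, most stale first.
#' @return A `filter_config` list.
#' @export
filter_config <- function(recency_window = 3,
                          recency_source = c("recommendations", "orders", "both"),
                          strict_composite_mode = TRUE,
                          min_candidates = 3) {
  recency_source <- match.arg(recency_source)
  stopifnot(recency_window >= 0, min_candidates >= 1)
  structure(list(recency_window = recency_window,
                 recency_source = recency_source,
                 strict_composite_mode = strict_composite_mode,
                 min_candidates = min_candidates),
            class = "filter_config")
}

#' Does a meal trigger a user's allergies?
#'
#' A meal is unsafe when any of its meal-level or ingredient-level
#' allergen tags intersects the user's allergies, or — in strict
#' composite mode — when the meal contains an unresolved composite
#' ingredient and the user has any allergy at all (unknown contents are
#' treated as unsafe).
#'
#' @param m A [meal()].
#' @param allergies User allergy tag set.
#' @param strict_composite Strict composite mode flag.
#' @return `TRUE` if the meal is unsafe for this user.
#' @export
allergen_match <- function(m, allergies, strict_composite = TRUE) {
  if (length(allergies) == 0) return(FALSE)
  if (length(intersect(meal_all_allergens(m), allergies)) > 0) return(TRUE)
  isTRUE(strict_composite) && meal_has_opaque_composite(m)
}

#' Has a meal been put forward within the recency window?
#'
#' The window is calendar-based: a meal is excluded iff it appears in the
#' configured history source on any of the `recency_window` days strictly
#' before `today` (i.e. dates in `[today - recency_window, today - 1]`).
#' A window of 0 never excludes anything.
#'
#' @param meal_id Meal identifier.
#' @param history Event list ([read_events()] shape) for the user.
#' @param today Reference date.
#' @param config A [filter_config()].
#' @return `TRUE` if the meal falls inside the window.
#' @export
recency_excluded <- function(meal_id, history, today, config = filter_config()) {
  !is.na(last_seen_in_window(meal_id, history, today, config))
}

# Most recent date (within the window) on which the meal was shown or
# ordered, NA if never; used both for exclusion and for most-stale-first
# restoration.
last_seen_in_window <- function(meal_id, history, today, config) {
  today <- as.Date(today)
  if (config$recency_window == 0) return(as.Date(NA))
  lo <- today - config$recency_window
  hi <- today - 1
  dates <- as.Date(character())
  if (config$recency_source %in% c("recommendations", "both")) {
    r <- history$recommendations
    if (!is.null(r) && nrow(r)) {
      hit <- vapply(r$meal_ids, function(ids) meal_id %in% ids, logical(1))
      dates <- c(dates, r$date[hit])
    }
  }
  if (config$recency_source %in% c("orders", "both")) {
    o <- history$orders
    if (!is.null(o) && nrow(o)) dates <- c(dates, o$date[o$meal_id == meal_id])
  }
  dates <- dates[dates >= lo & dates <= hi]
  if (length(dates) == 0) as.Date(NA) else max(dates)
}

meal_lifestyle_conflict <- function(m, preferences) {
  req <- intersect(preferences, required_diet_tags())
  if (length(setdiff(req, m$lifestyle_tags)) > 0) return(TRUE)
  avoid <- setdiff(preferences, required_diet_tags())
  length(intersect(avoid, m$lifestyle_tags)) > 0
}

#' Apply the contextual prefilter to a daily menu
#'
#' Restricts the menu to safe, relevant, non-repetitive candidates before
#' any scoring, applying in order: location match, allergen safety,
#' lifestyle constraints (required diet tags must be present, avoidance
#' tags absent), and the recency window. If fewer than
#' `config$min_candidates` meals survive, recency exclusions are restored
#' most-stale-first until the floor is met; safety or lifestyle
#' exclusions are never restored. Every removal is recorded with its
#' first triggering reason.
#'
#' @param mnu A [menu()].
#' @param user A [user_profile()].
#' @param today Reference date (defaults to the menu date).
#' @param history Event list for this user ([read_events()] shape).
#' @param config A [filter_config()].
#' @return A `candidate_set` list: `date`, `user_id`, `meals` (named list
#'   of surviving meals, menu order), and `exclusion_log` (tibble
#'   `meal_id`, `reason`).
#' @export
apply_prefilter <- function(mnu, user, today = mnu$date,
                            history = empty_events(),
                            config = filter_config()) {
  if (length(mnu$meals) == 0) stop("empty menu", call. = FALSE)
  today <- as.Date(today)
  ids <- names(mnu$meals)
  reason <- stats::setNames(rep(NA_character_, length(ids)), ids)
  last_seen <- stats::setNames(rep(as.Date(NA), length(ids)), ids)

  for (id in ids) {
    m <- mnu$meals[[id]]
    if (!identical(m$location, user$location)) {
      reason[id] <- "location"
    } else if (allergen_match(m, user$allergies, config$strict_composite_mode)) {
      reason[id] <- "allergen"
    } else if (meal_lifestyle_conflict(m, user$preferences)) {
      reason[id] <- "lifestyle"
    } else {
      seen <- last_seen_in_window(id, history, today, config)
      if (!is.na(seen)) {
        reason[id] <- "recency"
        last_seen[id] <- seen
      }
    }
  }

  kept <- ids[is.na(reason)]
  if (length(kept) < config$min_candidates) {
    restorable <- ids[!is.na(reason) & reason == "recency"]
    restorable <- restorable[order(last_seen[restorable], restorable)]
    n_needed <- config$min_candidates - length(kept)
    restore <- utils::head(restorable, n_needed)
    reason[restore] <- NA_character_
    kept <- ids[is.na(reason)]
  }

  excluded <- ids[!is.na(reason)]
  structure(list(
    date = today,
    user_id = user$user_id,
    meals = mnu$meals[kept],
    exclusion_log = tibble::tibble(meal_id = excluded,
                                   reason = unname(reason[excluded]))
  ), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> user %s on %s: %d candidates, %d excluded\n",
              x$user_id, format(x$date), length(x$meals),
              nrow(x$exclusion_log)))
  invisible(x)
}
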