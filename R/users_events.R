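#' Construct a user profile
#'
#' @param user_id Pseudonym string.
#' @param allergies Subset of the allergen vocabulary.
#' @param preferences Subset of the preference vocabulary. Tags among
#'   vegan/vegetarian/halal/kosher are treated downstream as required
#'   diet tags (meals must carry them); all others as avoidance tags
#'   (meals must not carry them).
#' @param location Restaurant location string the user orders from.
#' @param vocab Vocabularies for validation; unknown tags are rejected.
#' @return A `user_profile` S3 list.
#' @export
user_profile <- function(user_id, allergies = character(),
                         preferences = character(), location = "main",
                         vocab = load_vocabularies()) {
  stopifnot(is.character(user_id), length(user_id) == 1, nzchar(user_id))
  allergies <- normalize_tag(allergies)
  preferences <- normalize_tag(preferences)
  if (!is.null(vocab)) {
    assert_tags_in_vocab(allergies, vocab$allergens, "allergen")
    assert_tags_in_vocab(preferences, vocab$preferences, "preference")
  }
  structure(list(user_id = user_id, allergies = allergies,
                 preferences = preferences, location = location),
            class = "user_profile")
}

#' Read user profiles from JSON
#'
#' Expects a JSON array of objects with fields `user_id`, `allergies`,
#' `preferences`, `location`.
#'
#' @param path JSON file path.
#' @param vocab Vocabularies for validation.
#' @return Named list of [user_profile()] objects.
#' @export
read_users <- function(path, vocab = load_vocabularies()) {
  x <- jsonlite::read_json(path)
  users <- lapply(x, function(u) {
    user_profile(u$user_id,
                 allergies = unlist(u$allergies, use.names = FALSE) %||% character(),
                 preferences = unlist(u$preferences, use.names = FALSE) %||% character(),
                 location = u$location %||% "main", vocab = vocab)
  })
  stats::setNames(users, vapply(users, `[[`, character(1), "user_id"))
}

#' Write user profiles to JSON
#' @param users Named list of [user_profile()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_users <- function(users, path) {
  out <- lapply(unname(users), function(u) {
    list(user_id = u$user_id, allergies = as.list(u$allergies),
         preferences = as.list(u$preferences), location = u$location)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

empty_events <- function() {
  list(
    orders = tibble::tibble(user_id = character(), meal_id = character(),
                            date = as.Date(character())),
    feedback = tibble::tibble(user_id = character(), meal_id = character(),
                              date = as.Date(character()), polarity = character(),
                              disliked_ingredients = list(), text = character()),
    recommendations = tibble::tibble(user_id = character(),
                                     date = as.Date(character()),
                                     meal_ids = list())
  )
}

#' Read an event log CSV
#'
#' The CSV has header
#' `event_type,user_id,meal_id,date,polarity,disliked_ingredients,text`.
#' `event_type` is one of `order`, `feedback`, `recommendation`. For
#' recommendation rows, `meal_id` holds the `|`-joined ranked list shown;
#' `disliked_ingredients` is `|`-joined and only allowed on thumbs-down
#' feedback. Events are returned sorted by date.
#'
#' @param path CSV file path.
#' @param today Optional reference date; events dated after it are kept
#'   but flagged with a warning.
#' @param known_users Optional character vector; events from unknown
#'   users are flagged with a warning, never dropped.
#' @return List of tibbles `orders`, `feedback`, `recommendations`.
#' @export
read_events <- function(path, today = NULL, known_users = NULL) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("event_type", "user_id", "meal_id", "date", "polarity",
            "disliked_ingredients", "text")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("events CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("invalid date in events CSV", call. = FALSE)
  bad_type <- setdiff(unique(df$event_type), c("order", "feedback", "recommendation"))
  if (length(bad_type)) {
    stop("unknown event_type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if (!is.null(today) && any(df$date > as.Date(today))) {
    warning(sum(df$date > as.Date(today)),
            " event(s) dated after the reference date; retained", call. = FALSE)
  }
  if (!is.null(known_users)) {
    unk <- setdiff(unique(df$user_id), known_users)
    if (length(unk)) {
      warning("events reference unknown user(s): ",
              paste(unk, collapse = ", "), call. = FALSE)
    }
  }
  df <- df[order(df$date), , drop = FALSE]

  ord <- df[df$event_type == "order", , drop = FALSE]
  fb <- df[df$event_type == "feedback", , drop = FALSE]
  rec <- df[df$event_type == "recommendation", , drop = FALSE]

  if (nrow(fb)) {
    bad_pol <- setdiff(unique(fb$polarity), c("up", "down"))
    if (length(bad_pol)) {
      stop("unknown feedback polarity: ", paste(bad_pol, collapse = ", "),
           call. = FALSE)
    }
    if (any(fb$polarity == "up" & nzchar(fb$disliked_ingredients))) {
      stop("thumbs-up feedback must not carry disliked_ingredients",
           call. = FALSE)
    }
  }
  list(
    orders = tibble::tibble(user_id = ord$user_id, meal_id = ord$meal_id,
                            date = ord$date),
    feedback = tibble::tibble(
      user_id = fb$user_id, meal_id = fb$meal_id, date = fb$date,
      polarity = fb$polarity,
      disliked_ingredients = lapply(fb$disliked_ingredients, split_field, sep = "|"),
      text = fb$text
    ),
    recommendations = tibble::tibble(
      user_id = rec$user_id, date = rec$date,
      meal_ids = lapply(rec$meal_id, split_field, sep = "|")
    )
  )
}

#' Write an event log CSV
#' @param events List of tibbles as returned by [read_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  row <- function(type, user_id, meal_id, date, polarity = "",
                  disliked = "", text = "") {
    data.frame(event_type = type, user_id = user_id, meal_id = meal_id,
               date = format(date), polarity = polarity,
               disliked_ingredients = disliked, text = text,
               stringsAsFactors = FALSE)
  }
  parts <- list()
  o <- events$orders
  if (nrow(o)) parts[[length(parts) + 1]] <- row("order", o$user_id, o$meal_id, o$date)
  f <- events$feedback
  if (nrow(f)) {
    parts[[length(parts) + 1]] <- row(
      "feedback", f$user_id, f$meal_id, f$date, f$polarity,
      vapply(f$disliked_ingredients, paste, character(1), collapse = "|"),
      f$text)
  }
  r <- events$recommendations
  if (nrow(r)) {
    parts[[length(parts) + 1]] <- row(
      "recommendation", r$user_id,
      vapply(r$meal_ids, paste, character(1), collapse = "|"), r$date)
  }
  out <- if (length(parts)) do.call(rbind, parts) else
    row(character(), character(), character(), as.Date(character()))
  out <- out[order(out$date), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
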