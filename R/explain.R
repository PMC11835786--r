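#' Load explanation sentence templates
#'
#' Templates live in per-locale YAML files; the bundled English defaults
#' are the deployment's three tooltip sentences. Keeping the sentences in
#' config (with `{pct}` / `{frac}` placeholders) means every rendered
#' number is derived from the configured weights, never hard-coded.
#'
#' @param locale Locale code; only `"en"` ships by default.
#' @param path Optional explicit template file overriding the bundled
#'   one.
#' @return Named list of template strings.
#' @export
load_templates <- function(locale = "en", path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config",
                        paste0("templates_", locale, ".yaml"),
                        package = "mealrec")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("no explanation templates for locale: ", locale, call. = FALSE)
  }
  yaml::read_yaml(path)
}

render_pct <- function(template, pct, frac = NULL) {
  out <- gsub("{pct}", format(as.integer(round(pct))), template, fixed = TRUE)
  if (!is.null(frac)) {
    out <- gsub("{frac}", format(as.integer(round(frac))), out, fixed = TRUE)
  }
  out
}

new_payload <- function(kind, meal_id, headline, details) {
  structure(list(kind = kind, meal_id = meal_id, headline = headline,
                 details = details),
            class = "explanation_payload")
}

#' @export
print.explanation_payload <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$kind, x$headline))
  invisible(x)
}

#' @export
format.explanation_payload <- function(x, ...) {
  lines <- c(sprintf("[%s] %s", x$kind, x$headline))
  if (x$kind == "nutritional_alignment" && nrow(x$details$rows)) {
    r <- x$details$rows
    lines <- c(lines, sprintf("  %s (%s, weight %g): normalized %0.3f -> %+0.3f",
                              r$nutrient, r$status, r$weight,
                              r$normalized_amount, r$contribution))
  }
  if (x$kind == "past_choices" && nrow(x$details$similar_meals)) {
    s <- x$details$similar_meals
    lines <- c(lines, sprintf("  %s (similarity %0.3f)", s$meal_id, s$similarity))
  }
  if (x$kind == "popularity" && !is.null(x$details$sentence)) {
    lines <- c(lines, paste0("  ", x$details$sentence))
  }
  paste(lines, collapse = "\n")
}

#' Explain a recommendation's nutritional alignment
#'
#' The knowledge-based explanation: the headline renders the knowledge
#' component weight as an integer percent, and the detail rows break the
#' meal's raw knowledge score down per nutrient — one row per nutrient
#' whose weight under the user's status is nonzero, each with the status,
#' the weight, the normalized amount and their product (the
#' contribution), sorted by absolute contribution. The rows sum exactly
#' to the meal's raw knowledge score.
#'
#' @param meal_id Meal being explained.
#' @param profile Status vector ([classify_status()]).
#' @param table Weight table.
#' @param meal_norm The meal's normalized nutrient row.
#' @param weights [hybrid_weights()].
#' @param templates [load_templates()].
#' @return An `explanation_payload` of kind `nutritional_alignment`.
#' @export
explain_nutritional <- function(meal_id, profile,
                                table = default_weight_table(),
                                meal_norm, weights = hybrid_weights(),
                                templates = load_templates()) {
  pct <- 100 * weights$knowledge
  w <- vapply(scored_nutrients(), function(n) table[n, profile[[n]]],
              numeric(1))
  nz <- scored_nutrients()[w != 0]
  rows <- tibble::tibble(
    nutrient = nz,
    status = unname(vapply(nz, function(n) profile[[n]], character(1))),
    weight = unname(w[nz]),
    normalized_amount = unname(meal_norm[nz]),
    contribution = unname(w[nz] * meal_norm[nz])
  )
  rows <- rows[order(-abs(rows$contribution), rows$nutrient), ]
  new_payload("nutritional_alignment", meal_id,
              headline = render_pct(templates$nutritional_headline, pct),
              details = list(component_percent = pct, rows = rows,
                             raw_knowledge_score = sum(rows$contribution)))
}

#' Explain a recommendation through past choices
#'
#' The content-based explanation: lists the user's `m` previously ordered
#' or liked meals most similar (binary ingredient cosine) to the
#' recommended one. A cold user gets an empty list and the fallback
#' sentence.
#'
#' @param m The recommended [meal()].
#' @param orders,feedback The user's event tibbles.
#' @param meal_archive Named meal list resolving historic meal ids.
#' @param top_m How many past meals to list (default 3).
#' @param templates [load_templates()].
#' @return An `explanation_payload` of kind `past_choices`.
#' @export
explain_past_choices <- function(m, orders, feedback, meal_archive,
                                 top_m = 3, templates = load_templates()) {
  liked <- character()
  if (!is.null(feedback) && nrow(feedback)) {
    liked <- feedback$meal_id[feedback$polarity == "up"]
  }
  past_ids <- unique(c(if (!is.null(orders)) orders$meal_id else character(),
                       liked))
  past_ids <- past_ids[past_ids %in% names(meal_archive)]
  if (length(past_ids) == 0) {
    return(new_payload("past_choices", m$meal_id,
                       headline = templates$past_fallback,
                       details = list(similar_meals = tibble::tibble(
                         meal_id = character(), similarity = numeric()))))
  }
  this_ings <- meal_ingredient_names(m)
  sims <- vapply(past_ids, function(id) {
    other <- meal_ingredient_names(meal_archive[[id]])
    keys <- union(this_ings, other)
    s <- cosine(as.numeric(keys %in% this_ings), as.numeric(keys %in% other))
    if (is.na(s)) 0 else s
  }, numeric(1))
  ord <- order(-sims, past_ids)
  top <- utils::head(ord, top_m)
  new_payload("past_choices", m$meal_id,
              headline = templates$past_headline,
              details = list(similar_meals = tibble::tibble(
                meal_id = past_ids[top], similarity = unname(sims[top]))))
}

#' Explain a recommendation's popularity component
#'
#' The collaborative explanation: renders the collaborative weight as an
#' integer percent inside the caveat sentence (popular is not the same
#' as healthy), plus the neighbour count and the fraction of neighbours
#' who ordered the meal. Before activation the payload states that
#' popularity is not yet taken into account.
#'
#' @param meal_id Meal being explained.
#' @param neighbor_info List with `active` (logical), `n_neighbors`,
#'   `fraction_ordered`.
#' @param weights [hybrid_weights()].
#' @param templates [load_templates()].
#' @return An `explanation_payload` of kind `popularity`.
#' @export
explain_popularity <- function(meal_id, neighbor_info,
                               weights = hybrid_weights(),
                               templates = load_templates()) {
  pct <- 100 * weights$collaborative
  headline <- render_pct(templates$popularity_headline, pct)
  if (!isTRUE(neighbor_info$active)) {
    details <- list(component_percent = pct, active = FALSE,
                    n_neighbors = 0L, fraction_ordered = 0,
                    sentence = templates$popularity_inactive)
  } else {
    frac_pct <- 100 * neighbor_info$fraction_ordered
    details <- list(component_percent = pct, active = TRUE,
                    n_neighbors = as.integer(neighbor_info$n_neighbors),
                    fraction_ordered = neighbor_info$fraction_ordered,
                    sentence = render_pct(templates$popularity_detail, pct,
                                          frac = frac_pct))
  }
  new_payload("popularity", meal_id, headline = headline, details = details)
}

#' Build all three explanation payloads for one recommended meal
#'
#' @param scores One row of [hybrid_rank()] output for the meal.
#' @param candidates The candidate set the ranking was computed on.
#' @param profile,table,taste,all_orders,today As passed to
#'   [hybrid_rank()].
#' @param feedback The user's feedback tibble.
#' @param meal_archive Named meal list covering the user's history.
#' @param weights,k,activation_days,templates Engine configuration.
#' @return List of three `explanation_payload`s, in the fixed order
#'   nutritional alignment, past choices, popularity.
#' @export
explain_recommendation <- function(scores, candidates, profile,
                                   table = default_weight_table(),
                                   taste = numeric(0), all_orders = NULL,
                                   feedback = NULL, meal_archive = list(),
                                   today = candidates$date,
                                   weights = hybrid_weights(), k = 5,
                                   activation_days = 14,
                                   templates = load_templates()) {
  meal_id <- scores$meal_id
  m <- candidate_meals(candidates)[[meal_id]]
  if (is.null(m)) stop("meal not in candidate set: ", meal_id, call. = FALSE)
  norm <- normalize_nutrients(candidates)
  active <- !is.null(all_orders) &&
    collaborative_active(all_orders, today, activation_days) &&
    candidates$user_id %in% all_orders$user_id
  nb <- if (active) nearest_neighbors(candidates$user_id, all_orders, k)
        else character()
  frac <- if (length(nb)) {
    mean(vapply(nb, function(u) {
      any(all_orders$meal_id[all_orders$user_id == u] == meal_id)
    }, logical(1)))
  } else 0
  user_orders <- if (!is.null(all_orders)) {
    all_orders[all_orders$user_id == candidates$user_id, , drop = FALSE]
  } else NULL
  user_feedback <- if (!is.null(feedback) && nrow(feedback)) {
    feedback[feedback$user_id == candidates$user_id, , drop = FALSE]
  } else feedback
  list(
    explain_nutritional(meal_id, profile, table, norm[meal_id, ], weights,
                        templates),
    explain_past_choices(m, user_orders, user_feedback, meal_archive,
                         templates = templates),
    explain_popularity(meal_id,
                       list(active = active && length(nb) > 0,
                            n_neighbors = length(nb),
                            fraction_ordered = frac),
                       weights, templates)
  )
}
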