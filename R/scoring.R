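#' The default nutrient weight table
#'
#' The dietitian-curated mapping (nutrient, intake status) -> scoring
#' weight behind the knowledge-based scorer. A positive weight under
#' "Low" boosts meals rich in a nutrient the user lacks (e.g. fiber: 5);
#' a negative weight under "High" discounts meals adding to an already
#' high intake (e.g. polyunsaturated fat: -0.5). "Normal" status always
#' weighs 0: a nutrient at recommended intake neither boosts nor
#' penalizes.
#'
#' @return Data frame with row names the scored nutrients and columns
#'   `Low`, `Normal`, `High`.
#' @export
default_weight_table <- function() {
  tbl <- data.frame(
    Low    = c(5, 2, 3, 5, 1, 3, 3, -1, 5, 2, 0, 3),
    Normal = rep(0, 12),
    High   = c(0, 0, 0, 0, 0, -0.5, -0.3, -1, 0, 0, -1, -0.5),
    row.names = scored_nutrients()
  )
  tbl
}

#' Read a nutrient weight table from YAML
#'
#' YAML mapping `nutrient: {Low: w, Normal: w, High: w}`; missing
#' statuses default to 0.
#'
#' @param path YAML path.
#' @return Weight table data frame as in [default_weight_table()].
#' @export
read_weight_table <- function(path) {
  raw <- yaml::read_yaml(path)
  missing <- setdiff(scored_nutrients(), names(raw))
  if (length(missing)) {
    stop("weight table missing nutrient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  get <- function(status) vapply(scored_nutrients(), function(n) {
    as.numeric(raw[[n]][[status]] %||% 0)
  }, numeric(1))
  data.frame(Low = get("Low"), Normal = get("Normal"), High = get("High"),
             row.names = scored_nutrients())
}

#' Hybrid component weights
#'
#' The fixed mixing weights of the three scorers: the nutritional
#' (knowledge-based) component accounts for 65% of the final score, the
#' ingredient (content-based) component for 25%, and meal popularity
#' (collaborative) for 10%.
#'
#' @param knowledge,content,collaborative Non-negative weights summing
#'   to 1.
#' @return A `hybrid_weights` list.
#' @export
hybrid_weights <- function(knowledge = 0.65, content = 0.25,
                           collaborative = 0.10) {
  w <- c(knowledge = knowledge, content = content,
         collaborative = collaborative)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    stop("hybrid weights must be >= 0 and sum to 1", call. = FALSE)
  }
  structure(as.list(w), class = "hybrid_weights")
}

minmax_col <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] == 0) rep(0.5, length(x)) else (x - rng[1]) / (rng[2] - rng[1])
}

#' Min-max normalize candidate nutrient values
#'
#' Scales each scored nutrient to `[0, 1]` across the post-filter
#' candidate set — today's actual options, not a global archive — so the
#' knowledge scorer compares meals that are really on offer. A constant
#' column maps to 0.5 everywhere (no information, neutral value).
#'
#' @param candidates A `candidate_set` from [apply_prefilter()], or a
#'   bare list of meals.
#' @return Numeric matrix (meals x scored nutrients) with meal_id row
#'   names, entries in `[0, 1]`.
#' @export
normalize_nutrients <- function(candidates) {
  meals <- candidate_meals(candidates)
  if (length(meals) == 0) stop("no candidates to normalize", call. = FALSE)
  raw <- do.call(rbind, lapply(meals, function(m) m$nutrients[scored_nutrients()]))
  rownames(raw) <- unname(vapply(meals, `[[`, character(1), "meal_id"))
  apply_cols <- vapply(seq_len(ncol(raw)), function(j) minmax_col(raw[, j]),
                       numeric(nrow(raw)))
  norm <- matrix(apply_cols, nrow = nrow(raw),
                 dimnames = list(rownames(raw), scored_nutrients()))
  norm
}

candidate_meals <- function(candidates) {
  if (inherits(candidates, "candidate_set")) candidates$meals
  else if (inherits(candidates, "menu")) candidates$meals
  else candidates
}

#' Raw knowledge score of one meal
#'
#' The profile-weighted sum over nutrients: each nutrient's normalized
#' amount times the weight-table entry for the user's status on that
#' nutrient. A user low in fiber sees fiber-rich meals boosted (weight
#' 5 per unit of normalized fiber); a user high in polyunsaturated fat
#' sees high-PUFA meals discounted (-0.5 per unit).
#'
#' @param meal_norm Normalized nutrient row (values in `[0, 1]`, named).
#' @param profile Status vector from [classify_status()].
#' @param table Weight table ([default_weight_table()]).
#' @return Single raw (unrescaled) score.
#' @export
knowledge_raw <- function(meal_norm, profile, table = default_weight_table()) {
  missing <- setdiff(scored_nutrients(), rownames(table))
  if (length(missing)) {
    stop("weight table missing nutrient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w <- vapply(scored_nutrients(),
              function(n) table[n, profile[[n]]], numeric(1))
  sum(w * meal_norm[scored_nutrients()])
}

#' Knowledge scores for a candidate set
#'
#' Computes each candidate's raw profile-weighted score and min-max
#' rescales the raw scores to `[0, 1]` across the candidate set (an
#' order-preserving map; all-equal raw scores — e.g. an all-Normal
#' profile — rescale to the neutral 0.5).
#'
#' @param candidates Candidate set or meal list.
#' @param profile Status vector from [classify_status()].
#' @param table Weight table.
#' @param meal_norm Optional precomputed [normalize_nutrients()] matrix.
#' @return Tibble `meal_id`, `raw`, `score`.
#' @export
knowledge_score <- function(candidates, profile,
                            table = default_weight_table(),
                            meal_norm = normalize_nutrients(candidates)) {
  raw <- vapply(rownames(meal_norm),
                function(id) knowledge_raw(meal_norm[id, ], profile, table),
                numeric(1))
  tibble::tibble(meal_id = rownames(meal_norm), raw = as.numeric(raw),
                 score = minmax_col(as.numeric(raw)))
}

#' Build a user's ingredient taste vector
#'
#' Aggregates the user's history into per-ingredient weights: each
#' ordered meal and each thumbs-up adds +1 to every ingredient of that
#' meal; each thumbs-down adds -2, but only to the ingredients the user
#' named as contributing to the dislike. The -2 (vs +1) makes one
#' explicit dislike outweigh one like: negative feedback is rarer and
#' stronger. Events on meals absent from the archive are skipped with a
#' warning.
#'
#' @param orders,feedback Tibbles in [read_events()] shape (one user's
#'   rows).
#' @param meal_archive Named list of meals (id -> meal) covering the
#'   history.
#' @return Named numeric vector of ingredient weights (possibly empty:
#'   the cold-user zero vector).
#' @export
build_taste_vector <- function(orders, feedback, meal_archive) {
  taste <- numeric(0)
  bump <- function(taste, ingredients, delta) {
    for (ing in ingredients) {
      taste[ing] <- (if (ing %in% names(taste)) taste[[ing]] else 0) + delta
    }
    taste
  }
  unknown <- character(0)
  if (!is.null(orders) && nrow(orders)) {
    for (i in seq_len(nrow(orders))) {
      m <- meal_archive[[orders$meal_id[i]]]
      if (is.null(m)) { unknown <- c(unknown, orders$meal_id[i]); next }
      taste <- bump(taste, meal_ingredient_names(m), +1)
    }
  }
  if (!is.null(feedback) && nrow(feedback)) {
    for (i in seq_len(nrow(feedback))) {
      m <- meal_archive[[feedback$meal_id[i]]]
      if (is.null(m)) { unknown <- c(unknown, feedback$meal_id[i]); next }
      if (feedback$polarity[i] == "up") {
        taste <- bump(taste, meal_ingredient_names(m), +1)
      } else {
        taste <- bump(taste, normalize_tag(feedback$disliked_ingredients[[i]]), -2)
      }
    }
  }
  if (length(unknown)) {
    warning("event(s) on unknown meal(s) ignored: ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  taste
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

ingredient_cosine <- function(ings_a, taste) {
  keys <- union(ings_a, names(taste))
  if (length(keys) == 0) return(NA_real_)
  a <- as.numeric(keys %in% ings_a)
  b <- vapply(keys, function(k) {
    if (k %in% names(taste)) taste[[k]] else 0
  }, numeric(1))
  cosine(a, b)
}

#' Content-based score of one meal
#'
#' Cosine similarity between the meal's binary ingredient-presence
#' vector and the user's taste vector, mapped from `[-1, 1]` to
#' `[0, 1]` via `(c + 1) / 2`. A cold user (zero taste vector) gets the
#' neutral 0.5 for every meal.
#'
#' @param m A [meal()].
#' @param taste Taste vector from [build_taste_vector()].
#' @return Score in `[0, 1]`.
#' @export
content_score <- function(m, taste) {
  if (length(taste) == 0 || all(taste == 0)) return(0.5)
  c_sim <- ingredient_cosine(meal_ingredient_names(m), taste)
  if (is.na(c_sim)) return(0.5)
  (c_sim + 1) / 2
}

order_count_matrix <- function(all_orders) {
  users <- sort(unique(all_orders$user_id))
  meals <- sort(unique(all_orders$meal_id))
  mat <- matrix(0, nrow = length(users), ncol = length(meals),
                dimnames = list(users, meals))
  for (i in seq_len(nrow(all_orders))) {
    mat[all_orders$user_id[i], all_orders$meal_id[i]] <-
      mat[all_orders$user_id[i], all_orders$meal_id[i]] + 1
  }
  mat
}

#' Nearest-neighbour users by order-history similarity
#'
#' Cosine similarity over meal-order-count vectors; the top `k` other
#' users, ties broken by alphabetical user id.
#'
#' @param user_id The target user.
#' @param all_orders Order tibble across all users.
#' @param k Neighbour count (default 5).
#' @return Character vector of neighbour user ids (possibly shorter than
#'   `k`).
#' @export
nearest_neighbors <- function(user_id, all_orders, k = 5) {
  stopifnot(k >= 1)
  if (is.null(all_orders) || nrow(all_orders) == 0) return(character())
  mat <- order_count_matrix(all_orders)
  if (!user_id %in% rownames(mat)) return(character())
  others <- setdiff(rownames(mat), user_id)
  if (length(others) == 0) return(character())
  sims <- vapply(others, function(u) {
    s <- cosine(mat[user_id, ], mat[u, ])
    if (is.na(s)) 0 else s
  }, numeric(1))
  others <- others[order(-sims, others)]
  utils::head(others, k)
}

#' Collaborative (popularity-among-peers) score of one meal
#'
#' Rank-neutral 0 during cold start: before `activation_days` (default
#' 14 — two weeks of data collection) of system order history, or when
#' the user has no orders of their own. Once active, the score is the
#' fraction of the user's `k` nearest neighbours (cosine similarity over
#' order counts) who ever ordered the meal.
#'
#' @param meal_id Meal to score.
#' @param user_id Target user.
#' @param all_orders Order tibble across all users.
#' @param today Reference date.
#' @param k Neighbour count (default 5).
#' @param activation_days Days of history required (default 14).
#' @param neighbors Optional precomputed neighbour set.
#' @return Score in `[0, 1]`.
#' @export
collaborative_score <- function(meal_id, user_id, all_orders, today,
                                k = 5, activation_days = 14,
                                neighbors = NULL) {
  if (!collaborative_active(all_orders, today, activation_days)) return(0)
  if (!user_id %in% all_orders$user_id) return(0)
  if (is.null(neighbors)) neighbors <- nearest_neighbors(user_id, all_orders, k)
  if (length(neighbors) == 0) return(0)
  ordered <- vapply(neighbors, function(u) {
    any(all_orders$meal_id[all_orders$user_id == u] == meal_id)
  }, logical(1))
  mean(ordered)
}

#' Is the collaborative component active yet?
#'
#' Active once the system has at least `activation_days` days of order
#' history: the number of calendar days from the earliest order through
#' `today` (inclusive) reaches the threshold.
#'
#' @inheritParams collaborative_score
#' @return Logical.
#' @export
collaborative_active <- function(all_orders, today, activation_days = 14) {
  if (is.null(all_orders) || nrow(all_orders) == 0) return(FALSE)
  days <- as.integer(as.Date(today) - min(all_orders$date)) + 1L
  days >= activation_days
}

#' Rank a candidate set with the hybrid scorer
#'
#' Combines the three component scores per meal as
#' `final = w_k * knowledge + w_c * content + w_f * collaborative`
#' (defaults 0.65 / 0.25 / 0.10) and sorts descending; ties broken by
#' higher knowledge score, then lexicographic meal_id, so identical
#' inputs always give identical rankings.
#'
#' @param candidates Candidate set from [apply_prefilter()].
#' @param profile Nutrient-status vector ([classify_status()]).
#' @param taste Taste vector ([build_taste_vector()]).
#' @param all_orders Order tibble across all users.
#' @param today Reference date (defaults to the candidate set's date).
#' @param weights [hybrid_weights()].
#' @param table Weight table.
#' @param k,activation_days Collaborative parameters.
#' @return Tibble `rank`, `meal_id`, `knowledge`, `content`,
#'   `collaborative`, `final`, plus `knowledge_raw` (needed by the
#'   explainer), one row per candidate.
#' @export
hybrid_rank <- function(candidates, profile, taste = numeric(0),
                        all_orders = NULL, today = NULL,
                        weights = hybrid_weights(),
                        table = default_weight_table(),
                        k = 5, activation_days = 14) {
  meals <- candidate_meals(candidates)
  if (length(meals) == 0) stop("no candidates to rank", call. = FALSE)
  if (is.null(today)) {
    today <- if (inherits(candidates, "candidate_set")) candidates$date
             else meals[[1]]$date
  }
  user_id <- if (inherits(candidates, "candidate_set")) candidates$user_id else ""
  norm <- normalize_nutrients(candidates)
  ks <- knowledge_score(candidates, profile, table, meal_norm = norm)
  cs <- vapply(meals, function(m) content_score(m, taste), numeric(1))
  active <- !is.null(all_orders) &&
    collaborative_active(all_orders, today, activation_days)
  nb <- if (active) nearest_neighbors(user_id, all_orders, k) else character()
  fs <- vapply(meals, function(m) {
    if (!active) 0
    else collaborative_score(m$meal_id, user_id, all_orders, today,
                             k = k, activation_days = activation_days,
                             neighbors = nb)
  }, numeric(1))
  final <- weights$knowledge * ks$score + weights$content * cs +
    weights$collaborative * fs
  out <- tibble::tibble(
    meal_id = ks$meal_id,
    knowledge = ks$score, content = as.numeric(cs),
    collaborative = as.numeric(fs), final = as.numeric(final),
    knowledge_raw = ks$raw
  )
  out <- out[order(-out$final, -out$knowledge, out$meal_id), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "meal_id", "knowledge", "content", "collaborative",
          "final", "knowledge_raw")]
}
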