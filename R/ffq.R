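#' The fixed FFQ food-group enumeration
#' @return Character vector of the ten food groups.
#' @export
food_groups <- function() {
  c("vegetables", "fruit", "potatoes_rice_pasta", "bread_savory_biscuits",
    "dairy", "meat_fish", "fats_spreads", "sweets_snacks", "drinks", "other")
}

#' Read the FFQ item bank
#'
#' CSV with header `item_id,food_name,food_group,portion_g`. `portion_g`
#' is the standard portion mass in grams; `food_group` must come from
#' [food_groups()].
#'
#' @param path CSV path.
#' @return Tibble with one row per questionnaire item.
#' @export
read_ffq_items <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "food_name", "food_group", "portion_g")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("FFQ item CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$food_group), food_groups())
  if (length(bad)) stop("unknown food_group: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(df$item_id)) stop("duplicate item_id in item bank",
                                      call. = FALSE)
  if (any(!is.finite(df$portion_g)) || any(df$portion_g <= 0)) {
    stop("portion_g must be finite and > 0", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read the food-composition table (per 100 g)
#'
#' CSV with header `item_id,fiber,...,carbohydrate`: one column per
#' scored nutrient, values per 100 g of the food, NUBEL-style.
#'
#' @param path CSV path.
#' @return Tibble, one row per item, all nutrient values non-negative.
#' @export
read_composition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("item_id", scored_nutrients()), names(df))
  if (length(missing)) {
    stop("composition CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, scored_nutrients()])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("composition values must be finite and >= 0", call. = FALSE)
  }
  tibble::as_tibble(df[, c("item_id", scored_nutrients())])
}

#' Read FFQ responses
#'
#' CSV with header
#' `user_id,timepoint,item_id,frequency_per_day,portion_multiplier`.
#' `timepoint` is `baseline` or `post`.
#'
#' @param path CSV path.
#' @return Tibble of answer rows.
#' @export
read_ffq_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", "timepoint", "item_id", "frequency_per_day",
            "portion_multiplier")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("FFQ response CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$timepoint), c("baseline", "post"))
  if (length(bad)) stop("unknown timepoint: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(!is.finite(df$frequency_per_day)) || any(df$frequency_per_day < 0)) {
    stop("frequency_per_day must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(df$portion_multiplier)) || any(df$portion_multiplier <= 0)) {
    stop("portion_multiplier must be finite and > 0", call. = FALSE)
  }
  tibble::as_tibble(df)
}

resolve_answers <- function(answers, items, composition) {
  unknown <- setdiff(answers$item_id,
                     intersect(items$item_id, composition$item_id))
  if (length(unknown)) {
    stop("FFQ answer references unknown item_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  i_item <- match(answers$item_id, items$item_id)
  i_comp <- match(answers$item_id, composition$item_id)
  list(portion_g = items$portion_g[i_item],
       group = items$food_group[i_item],
       comp = as.matrix(composition[i_comp, scored_nutrients()]))
}

#' Estimate daily nutrient intake from one FFQ response
#'
#' Standard FFQ arithmetic: for each answered item, daily consumption is
#' `frequency_per_day x portion_multiplier x portion_g`, and nutrient
#' intake is that mass times the per-100 g composition. Intakes are
#' additive over items.
#'
#' @param answers Tibble of answer rows for one user/timepoint
#'   (`item_id`, `frequency_per_day`, `portion_multiplier`).
#' @param items FFQ item bank ([read_ffq_items()]).
#' @param composition Composition table ([read_composition()]).
#' @return Named numeric vector of daily intake per scored nutrient
#'   (nutrient units/day).
#' @examples
#' items <- tibble::tibble(item_id = "i1", food_name = "bread",
#'                         food_group = "bread_savory_biscuits", portion_g = 200)
#' comp <- tibble::tibble(item_id = "i1")
#' for (n in scored_nutrients()) comp[[n]] <- 0
#' comp$fiber <- 2
#' ans <- tibble::tibble(item_id = "i1", frequency_per_day = 1,
#'                       portion_multiplier = 1)
#' compute_intake(ans, items, comp)[["fiber"]]  # 4 g/day
#' @export
compute_intake <- function(answers, items, composition) {
  if (nrow(answers) == 0) {
    return(stats::setNames(numeric(length(scored_nutrients())),
                           scored_nutrients()))
  }
  res <- resolve_answers(answers, items, composition)
  mass <- answers$frequency_per_day * answers$portion_multiplier *
    res$portion_g / 100
  intake <- colSums(res$comp * mass)
  stats::setNames(as.numeric(intake), scored_nutrients())
}

#' Read the per-nutrient reference ranges
#'
#' YAML mapping `nutrient: {lower, upper}` in intake units per day. The
#' bundled defaults are dietary-reference-value style placeholders for a
#' generic adult and are not clinical thresholds.
#'
#' @param path YAML path; default the bundled file.
#' @return Named list of `c(lower, upper)` per scored nutrient.
#' @export
read_reference_ranges <- function(path = system.file("extdata", "config",
                                                     "reference_ranges.yaml",
                                                     package = "mealrec")) {
  raw <- yaml::read_yaml(path)
  missing <- setdiff(scored_nutrients(), names(raw))
  if (length(missing)) {
    stop("reference ranges missing nutrient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(raw[scored_nutrients()], function(r) {
    if (!is.numeric(r$lower) || !is.numeric(r$upper) || r$lower >= r$upper) {
      stop("each reference range needs lower < upper", call. = FALSE)
    }
    c(lower = r$lower, upper = r$upper)
  })
  out
}

#' Classify estimated intake as Low / Normal / High per nutrient
#'
#' Low iff intake is strictly below the lower bound, High iff strictly
#' above the upper bound, Normal otherwise — the bounds themselves
#' classify as Normal, so a user at exactly the recommended intake is
#' never flagged.
#'
#' @param intake Named intake vector from [compute_intake()].
#' @param ranges Ranges from [read_reference_ranges()].
#' @return Named character vector (`"Low"`, `"Normal"`, `"High"`), one
#'   status per scored nutrient.
#' @export
classify_status <- function(intake, ranges = read_reference_ranges()) {
  missing <- setdiff(scored_nutrients(), names(ranges))
  if (length(missing)) {
    stop("no reference range for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  missing_in <- setdiff(scored_nutrients(), names(intake))
  if (length(missing_in)) {
    stop("intake missing nutrient(s): ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  }
  status <- vapply(scored_nutrients(), function(n) {
    r <- ranges[[n]]
    x <- intake[[n]]
    if (x < r[["lower"]]) "Low" else if (x > r[["upper"]]) "High" else "Normal"
  }, character(1))
  status
}

#' Food-group contributions to a macronutrient
#'
#' Splits one FFQ response's total intake of a macronutrient across the
#' ten food groups, as percentages summing to 100, and reports the top
#' contributing group (ties broken alphabetically).
#'
#' @param answers,items,composition As for [compute_intake()].
#' @param macronutrient One of `"carbohydrate"`, `"protein"`,
#'   `"total_fat"`.
#' @return List with `percent` (named numeric over all ten groups) and
#'   `top_group`.
#' @export
food_group_contributions <- function(answers, items, composition,
                                     macronutrient = c("total_fat",
                                                       "carbohydrate",
                                                       "protein")) {
  macronutrient <- match.arg(macronutrient)
  res <- resolve_answers(answers, items, composition)
  mass <- answers$frequency_per_day * answers$portion_multiplier *
    res$portion_g / 100
  per_item <- res$comp[, macronutrient] * mass
  total <- sum(per_item)
  if (!isTRUE(total > 0)) {
    stop("total ", macronutrient,
         " intake is zero; group contributions are undefined", call. = FALSE)
  }
  by_group <- tapply(per_item, factor(res$group, levels = food_groups()), sum,
                     default = 0)
  percent <- 100 * as.numeric(by_group) / total
  names(percent) <- food_groups()
  ord <- food_groups()[order(-percent, food_groups())]
  list(percent = percent, top_group = ord[1])
}

#' Compare top contributing food groups between two timepoints
#'
#' Given each user's top contributing group at baseline and after the
#' intervention, counts per group how many users top that group at each
#' timepoint (the shape of a dietary-shift table). Users present at only
#' one timepoint are excluded with a warning.
#'
#' @param baseline,post Named character vectors `user_id -> food group`.
#' @return Tibble with columns `food_group`, `baseline`, `post`; counts
#'   in each column sum to the number of shared users.
#' @export
compare_profiles <- function(baseline, post) {
  shared <- intersect(names(baseline), names(post))
  dropped <- setdiff(union(names(baseline), names(post)), shared)
  if (length(dropped)) {
    warning("user(s) present at only one timepoint excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  count <- function(x) {
    as.numeric(table(factor(x[shared], levels = food_groups())))
  }
  tibble::tibble(food_group = food_groups(),
                 baseline = count(baseline),
                 post = count(post))
}
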