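#' Construct an ingredient record
#'
#' @param name Ingredient name (normalized lowercase).
#' @param allergens Character vector of allergen tags carried by this
#'   ingredient.
#' @param sub_ingredients Optional character vector of constituent
#'   ingredient names, for resolved composites.
#' @param composite_opaque Logical; `TRUE` marks an unresolved composite
#'   (e.g. a sauce whose constituents are unknown). An opaque composite
#'   carries no sub-ingredients; under the prefilter's strict mode it is
#'   treated as potentially unsafe for any user with allergies.
#' @return An `ingredient` S3 list.
#' @export
ingredient <- function(name, allergens = character(), sub_ingredients = character(),
                       composite_opaque = FALSE) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (isTRUE(composite_opaque) && length(sub_ingredients) > 0) {
    stop("an opaque composite ingredient cannot list sub-ingredients",
         call. = FALSE)
  }
  structure(list(
    name = normalize_tag(name),
    allergens = normalize_tag(allergens),
    sub_ingredients = normalize_tag(sub_ingredients),
    composite_opaque = isTRUE(composite_opaque)
  ), class = "ingredient")
}

meal_courses <- function() c("soup", "salad", "main", "side", "dessert", "sandwich")

#' Construct a meal
#'
#' A menu item with a per-portion nutrient vector, an ingredient list,
#' allergen and lifestyle tags from the controlled vocabularies, and a
#' Nutri-Score letter (consumed as metadata, never computed here).
#'
#' @param meal_id Opaque identifier, unique within a menu.
#' @param name Display name.
#' @param course One of soup, salad, main, side, dessert, sandwich.
#' @param date Serving date (coerced with [as.Date()]).
#' @param location Opaque restaurant/location string.
#' @param nutrients Named numeric per-portion nutrient vector; see
#'   [nutrient_vector()].
#' @param ingredients List of [ingredient()] records (bare character
#'   names are promoted).
#' @param allergen_tags,lifestyle_tags Tag subsets of the respective
#'   vocabularies.
#' @param nutriscore Letter A-E.
#' @param vocab Vocabularies used for validation; `NULL` skips the check
#'   (the readers always validate).
#' @return A `meal` S3 list.
#' @export
meal <- function(meal_id, name, course, date, location, nutrients,
                 ingredients = list(), allergen_tags = character(),
                 lifestyle_tags = character(), nutriscore = "C",
                 vocab = NULL) {
  stopifnot(is.character(meal_id), length(meal_id) == 1, nzchar(meal_id))
  course <- match.arg(course, meal_courses())
  nutriscore <- toupper(nutriscore)
  if (!nutriscore %in% c("A", "B", "C", "D", "E")) {
    stop("nutriscore must be one of A-E, got: ", nutriscore, call. = FALSE)
  }
  ingredients <- lapply(ingredients, function(ing) {
    if (inherits(ing, "ingredient")) ing else ingredient(as.character(ing))
  })
  allergen_tags <- normalize_tag(allergen_tags)
  lifestyle_tags <- normalize_tag(lifestyle_tags)
  if (!is.null(vocab)) {
    assert_tags_in_vocab(allergen_tags, vocab$allergens, "allergen")
    assert_tags_in_vocab(lifestyle_tags, vocab$preferences, "preference")
    for (ing in ingredients) {
      assert_tags_in_vocab(ing$allergens, vocab$allergens, "allergen")
    }
  }
  structure(list(
    meal_id = meal_id,
    name = name,
    course = course,
    date = as.Date(date),
    location = location,
    nutrients = nutrient_vector(nutrients),
    ingredients = ingredients,
    allergen_tags = allergen_tags,
    lifestyle_tags = lifestyle_tags,
    nutriscore = nutriscore
  ), class = "meal")
}

#' All ingredient names of a meal, including resolved sub-ingredients
#' @param m A [meal()].
#' @return Character vector of unique normalized ingredient names.
#' @export
meal_ingredient_names <- function(m) {
  unique(unlist(lapply(m$ingredients, function(ing) {
    c(ing$name, ing$sub_ingredients)
  }), use.names = FALSE))
}

meal_has_opaque_composite <- function(m) {
  any(vapply(m$ingredients, function(ing) ing$composite_opaque, logical(1)))
}

meal_all_allergens <- function(m) {
  unique(c(m$allergen_tags,
           unlist(lapply(m$ingredients, `[[`, "allergens"), use.names = FALSE)))
}

#' Construct a daily menu
#'
#' @param date Menu date; all meals must share it.
#' @param location Menu location; all meals must share it.
#' @param meals List of [meal()] objects, 1-50 of them, with unique ids.
#' @return A `menu` S3 list whose `meals` element is named by meal_id.
#' @export
menu <- function(date, location, meals) {
  date <- as.Date(date)
  if (length(meals) < 1 || length(meals) > 50) {
    stop("a menu holds between 1 and 50 meals, got ", length(meals),
         call. = FALSE)
  }
  ids <- vapply(meals, `[[`, character(1), "meal_id")
  if (anyDuplicated(ids)) {
    stop("duplicate meal_id within menu: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (m in meals) {
    if (m$date != date || m$location != location) {
      stop("meal ", m$meal_id, " does not share the menu date/location",
           call. = FALSE)
    }
  }
  structure(list(date = date, location = location,
                 meals = stats::setNames(meals, ids)),
            class = "menu")
}

#' @export
print.menu <- function(x, ...) {
  cat(sprintf("<menu> %s @ %s: %d meals\n",
              format(x$date), x$location, length(x$meals)))
  invisible(x)
}

# ---- serialization -------------------------------------------------------

meal_to_list <- function(m) {
  list(
    meal_id = m$meal_id, name = m$name, course = m$course,
    date = format(m$date), location = m$location,
    nutrients = as.list(m$nutrients),
    ingredients = lapply(m$ingredients, function(ing) {
      out <- list(name = ing$name)
      if (length(ing$allergens)) out$allergens <- as.list(ing$allergens)
      if (length(ing$sub_ingredients)) out$sub_ingredients <- as.list(ing$sub_ingredients)
      if (ing$composite_opaque) out$composite_opaque <- TRUE
      out
    }),
    allergen_tags = as.list(m$allergen_tags),
    lifestyle_tags = as.list(m$lifestyle_tags),
    nutriscore = m$nutriscore
  )
}

meal_from_list <- function(x, vocab) {
  ings <- lapply(x$ingredients, function(ing) {
    ingredient(ing$name,
               allergens = unlist(ing$allergens, use.names = FALSE) %||% character(),
               sub_ingredients = unlist(ing$sub_ingredients, use.names = FALSE) %||% character(),
               composite_opaque = isTRUE(ing$composite_opaque))
  })
  meal(x$meal_id, x$name, x$course, x$date, x$location,
       nutrients = unlist(x$nutrients),
       ingredients = ings,
       allergen_tags = unlist(x$allergen_tags, use.names = FALSE) %||% character(),
       lifestyle_tags = unlist(x$lifestyle_tags, use.names = FALSE) %||% character(),
       nutriscore = x$nutriscore, vocab = vocab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a daily menu from JSON or flat CSV
#'
#' The JSON format carries the full meal structure (nested ingredient
#' records, sub-ingredients, composite flags). The flat CSV holds one row
#' per meal with `;`-joined ingredient names (a trailing `*` marks an
#' opaque composite) and `|`-joined tag fields; nested sub-ingredients are
#' JSON-only. Unknown nutrient columns are ignored with a warning; a
#' missing scored nutrient is an error naming the column.
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; inferred from the extension by
#'   default.
#' @param vocab Vocabularies to validate against (default: bundled).
#' @return A [menu()].
#' @export
read_menu <- function(path, format = c("auto", "json", "csv"),
                      vocab = load_vocabularies()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("menu file not found: ", path, call. = FALSE)
  if (format == "json") {
    x <- jsonlite::read_json(path)
    meals <- lapply(x$meals, meal_from_list, vocab = vocab)
    menu(x$date, x$location, meals)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    meta <- c("meal_id", "name", "course", "date", "location",
              "ingredients", "allergen_tags", "lifestyle_tags", "nutriscore")
    missing_meta <- setdiff(meta, names(df))
    if (length(missing_meta)) {
      stop("menu CSV missing column(s): ", paste(missing_meta, collapse = ", "),
           call. = FALSE)
    }
    nutr_cols <- setdiff(names(df), meta)
    missing_nutr <- setdiff(scored_nutrients(), nutr_cols)
    if (length(missing_nutr)) {
      stop("menu CSV missing scored nutrient column(s): ",
           paste(missing_nutr, collapse = ", "), call. = FALSE)
    }
    meals <- lapply(seq_len(nrow(df)), function(i) {
      row <- df[i, , drop = FALSE]
      ing_names <- split_field(row$ingredients, ";")
      ings <- lapply(ing_names, function(nm) {
        if (grepl("\\*$", nm)) {
          ingredient(sub("\\*$", "", nm), composite_opaque = TRUE)
        } else {
          ingredient(nm)
        }
      })
      meal(row$meal_id, row$name, row$course, row$date, row$location,
           nutrients = unlist(row[intersect(c(scored_nutrients(), "energy"),
                                            nutr_cols)]),
           ingredients = ings,
           allergen_tags = split_field(row$allergen_tags, "|"),
           lifestyle_tags = split_field(row$lifestyle_tags, "|"),
           nutriscore = row$nutriscore, vocab = vocab)
    })
    extra <- setdiff(nutr_cols, c(scored_nutrients(), "energy"))
    if (length(extra)) {
      warning("ignoring unknown nutrient column(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    menu(df$date[1], df$location[1], meals)
  }
}

split_field <- function(x, sep) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, sep, fixed = TRUE)[[1]])
}

#' Write a menu to JSON or flat CSV
#'
#' Meals are written in lexicographic meal_id order (the canonical
#' ordering under which write-then-read round-trips are identities).
#'
#' @param x A [menu()].
#' @param path Output path.
#' @param format `"json"` or `"csv"` (inferred by default).
#' @return `path`, invisibly.
#' @export
write_menu <- function(x, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  meals <- x$meals[order(names(x$meals))]
  if (format == "json") {
    out <- list(date = format(x$date), location = x$location,
                meals = lapply(unname(meals), meal_to_list))
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    rows <- lapply(meals, function(m) {
      ing_field <- paste(vapply(m$ingredients, function(ing) {
        paste0(ing$name, if (ing$composite_opaque) "*" else "")
      }, character(1)), collapse = ";")
      base <- data.frame(
        meal_id = m$meal_id, name = m$name, course = m$course,
        date = format(m$date), location = m$location,
        ingredients = ing_field,
        allergen_tags = paste(m$allergen_tags, collapse = "|"),
        lifestyle_tags = paste(m$lifestyle_tags, collapse = "|"),
        nutriscore = m$nutriscore,
        stringsAsFactors = FALSE
      )
      nutr <- m$nutrients[intersect(names(m$nutrients), scored_nutrients())]
      cbind(base, as.data.frame(as.list(nutr)))
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}
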