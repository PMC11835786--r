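#' Configuration for the synthetic world generator
#'
#' Defaults emulate the study conditions of a workplace catering
#' deployment: daily menus of 10-20 meals with roughly 15% vegan
#' options, a multi-week (5-week) observation window, and heterogeneous
#' users of whom about a third carry at least one allergy.
#'
#' @param seed Master seed; every sub-generator derives its own stream
#'   from it, so adding users never perturbs the menus.
#' @param n_users Number of users (default 20).
#' @param n_days Number of consecutive menu days (default 35).
#' @param meals_per_day Integer range `c(min, max)` (default 10-20).
#' @param fraction_vegan_meals Fraction of meals tagged vegan (default
#'   0.15, matching the observed 1-2 vegan options out of 10-20 meals).
#' @param allergy_prevalence Probability a user has >= 1 allergy
#'   (default 0.3).
#' @param ffq_items Number of regular FFQ bank items (default 50, spread
#'   over all ten food groups; 12 single-nutrient synthetic anchor items
#'   are always added on top for analytic profile planting).
#' @param start_date First menu date.
#' @param location Location string shared by menus and users.
#' @param planted_profile Optional named list `user_id -> status vector`
#'   fixing the nutrient-status profile the FFQ responses must recover;
#'   unnamed users get a randomly drawn profile.
#' @param planted_taste Optional named list `user_id -> character vector`
#'   of preferred ingredient names; order histories are biased toward
#'   meals containing them.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1, n_users = 20, n_days = 35,
                             meals_per_day = c(10, 20),
                             fraction_vegan_meals = 0.15,
                             allergy_prevalence = 0.3,
                             ffq_items = 50,
                             start_date = as.Date("2022-01-17"),
                             location = "main",
                             planted_profile = NULL,
                             planted_taste = NULL) {
  stopifnot(n_users >= 1, n_days >= 1, length(meals_per_day) == 2,
            meals_per_day[1] >= 1, meals_per_day[2] >= meals_per_day[1],
            meals_per_day[2] <= 50,
            fraction_vegan_meals >= 0, fraction_vegan_meals <= 1,
            allergy_prevalence >= 0, allergy_prevalence <= 1,
            ffq_items >= 10)
  structure(list(seed = as.integer(seed), n_users = n_users, n_days = n_days,
                 meals_per_day = meals_per_day,
                 fraction_vegan_meals = fraction_vegan_meals,
                 allergy_prevalence = allergy_prevalence,
                 ffq_items = ffq_items, start_date = as.Date(start_date),
                 location = location, planted_profile = planted_profile,
                 planted_taste = planted_taste),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# Ingredient pool: name, allergen tags, lifestyle tags implied by the
# ingredient, and whether it is vegan-compatible.
ingredient_pool <- function() {
  ing <- function(name, allergens = character(), lifestyle = character(),
                  vegan = TRUE) {
    list(name = name, allergens = allergens, lifestyle = lifestyle,
         vegan = vegan)
  }
  list(
    ing("tomato"), ing("lettuce"), ing("carrot", lifestyle = "carrot"),
    ing("broccoli"), ing("zucchini"), ing("apple"), ing("beans"),
    ing("lentils"), ing("rice"), ing("potato"),
    ing("pasta", allergens = c("gluten", "wheat")),
    ing("bread", allergens = c("gluten", "wheat")),
    ing("cheese", allergens = c("lactose", "milk dairy"), vegan = FALSE),
    ing("cream", allergens = c("lactose", "milk dairy"), vegan = FALSE),
    ing("egg", allergens = "egg", vegan = FALSE),
    ing("chicken", lifestyle = "poultry meat", vegan = FALSE),
    ing("pork", lifestyle = "pig meat", vegan = FALSE),
    ing("beef", lifestyle = "beef", vegan = FALSE),
    ing("salmon", allergens = "fish", vegan = FALSE),
    ing("shrimp", allergens = "shellfish", vegan = FALSE),
    ing("peanut sauce", allergens = "peanut"),
    ing("sesame oil", allergens = "sesame"),
    ing("walnuts", allergens = "walnuts"),
    ing("soy sauce", allergens = "soy"),
    ing("coriander", lifestyle = "coriander"),
    ing("coffee", lifestyle = "caffeine"),
    ing("chocolate", lifestyle = "cacao"),
    ing("onion"), ing("garlic"), ing("olive oil")
  )
}

per_portion_ranges <- function() {
  list(fiber = c(1, 12), vitamin_a = c(50, 600), vitamin_b12 = c(0, 3),
       vitamin_c = c(5, 80), monounsaturated_fat = c(1, 15),
       polyunsaturated_fat = c(0.5, 10), protein = c(5, 40),
       total_fat = c(3, 35), calcium = c(50, 500), iron = c(0.5, 6),
       saturated_fat = c(1, 12), carbohydrate = c(10, 90))
}

#' Generate the daily menus of a synthetic world
#'
#' Menus are drawn from a stable recipe pool (about twice the maximum
#' daily menu size) so that dishes recur across days, as they do on real
#' catering menus — recurrence is what gives the repetition filter and
#' the collaborative scorer something to work with. Vegan recipes are
#' kept at roughly `fraction_vegan_meals` of each day's offer.
#'
#' @param config A [generator_config()].
#' @return List of [menu()] objects, one per day.
#' @export
generate_menus <- function(config) {
  with_seed(config$seed + 101L, {
    n_recipes <- max(2 * config$meals_per_day[2], config$meals_per_day[2] + 5)
    n_vegan_recipes <- max(2, round(config$fraction_vegan_meals * n_recipes))
    recipes <- lapply(seq_len(n_recipes), function(i) {
      generate_recipe(sprintf("r%03d", i), vegan = i <= n_vegan_recipes)
    })
    vegan_ids <- seq_len(n_vegan_recipes)
    other_ids <- setdiff(seq_len(n_recipes), vegan_ids)
    lapply(seq_len(config$n_days) - 1L, function(d) {
      date <- config$start_date + d
      n_meals <- sample(seq(config$meals_per_day[1], config$meals_per_day[2]), 1)
      n_vegan <- min(round(config$fraction_vegan_meals * n_meals),
                     n_vegan_recipes)
      pick <- c(sample(vegan_ids, n_vegan),
                sample(other_ids, n_meals - n_vegan))
      meals <- lapply(recipes[sort(pick)], function(r) {
        meal(r$meal_id, r$name, r$course, date, config$location,
             nutrients = r$nutrients, ingredients = r$ingredients,
             allergen_tags = r$allergen_tags,
             lifestyle_tags = r$lifestyle_tags, nutriscore = r$nutriscore)
      })
      menu(date, config$location, meals)
    })
  })
}

generate_recipe <- function(meal_id, vegan = FALSE) {
  pool <- ingredient_pool()
  src <- if (vegan) Filter(function(p) p$vegan, pool) else pool
  ranges <- per_portion_ranges()
  picks <- sample(src, size = sample(3:5, 1))
  ings <- lapply(picks, function(p) ingredient(p$name, allergens = p$allergens))
  if (!vegan && stats::runif(1) < 0.1) {
    ings <- c(ings, list(ingredient("house sauce", composite_opaque = TRUE)))
  }
  lifestyle <- unique(unlist(lapply(picks, `[[`, "lifestyle")))
  vegetarian <- all(vapply(picks, function(p) {
    p$vegan || p$name %in% c("cheese", "cream", "egg")
  }, logical(1)))
  if (vegan) lifestyle <- c(lifestyle, "vegan", "vegetarian")
  else if (vegetarian) lifestyle <- c(lifestyle, "vegetarian")
  nutr <- round(vapply(ranges, function(r) stats::runif(1, r[1], r[2]),
                       numeric(1)), 2)
  list(
    meal_id = meal_id,
    name = paste(vapply(utils::head(picks, 2), `[[`, character(1), "name"),
                 collapse = " & "),
    course = sample(meal_courses(), 1),
    nutrients = nutr, ingredients = ings,
    allergen_tags = unique(unlist(lapply(picks, `[[`, "allergens"))) %||% character(),
    lifestyle_tags = unique(lifestyle),
    nutriscore = sample(c("A", "B", "C", "D", "E"), 1,
                        prob = c(0.2, 0.3, 0.3, 0.15, 0.05))
  )
}

#' Generate synthetic user profiles
#'
#' @param config A [generator_config()].
#' @param vocab Vocabularies.
#' @return Named list of [user_profile()] objects.
#' @export
generate_users <- function(config, vocab = load_vocabularies()) {
  with_seed(config$seed + 202L, {
    users <- lapply(seq_len(config$n_users), function(i) {
      id <- sprintf("u%03d", i)
      allergies <- character()
      if (stats::runif(1) < config$allergy_prevalence) {
        allergies <- sample(c("peanut", "lactose", "gluten", "fish",
                              "shellfish", "egg", "soy", "walnuts"),
                            sample(1:2, 1))
      }
      preferences <- character()
      r <- stats::runif(1)
      if (r < 0.1) preferences <- "vegan"
      else if (r < 0.25) preferences <- "vegetarian"
      else if (r < 0.35) preferences <- sample(c("coriander", "caffeine",
                                                 "pig meat", "cacao"), 1)
      user_profile(id, allergies = allergies, preferences = preferences,
                   location = config$location, vocab = vocab)
    })
    stats::setNames(users, vapply(users, `[[`, character(1), "user_id"))
  })
}

group_composition_ranges <- function() {
  list(
    vegetables = list(fiber = c(2, 4), vitamin_a = c(50, 400), vitamin_b12 = c(0, 0),
                      vitamin_c = c(10, 60), monounsaturated_fat = c(0, 0.2),
                      polyunsaturated_fat = c(0, 0.3), protein = c(1, 3),
                      total_fat = c(0.1, 0.5), calcium = c(20, 80), iron = c(0.3, 1.5),
                      saturated_fat = c(0, 0.1), carbohydrate = c(3, 10)),
    fruit = list(fiber = c(1.5, 3), vitamin_a = c(10, 100), vitamin_b12 = c(0, 0),
                 vitamin_c = c(20, 60), monounsaturated_fat = c(0, 0.2),
                 polyunsaturated_fat = c(0, 0.2), protein = c(0.3, 1),
                 total_fat = c(0.1, 0.4), calcium = c(5, 30), iron = c(0.1, 0.5),
                 saturated_fat = c(0, 0.1), carbohydrate = c(10, 15)),
    potatoes_rice_pasta = list(fiber = c(1, 3), vitamin_a = c(0, 10), vitamin_b12 = c(0, 0),
                               vitamin_c = c(0, 10), monounsaturated_fat = c(0, 1),
                               polyunsaturated_fat = c(0, 1), protein = c(2, 6),
                               total_fat = c(0.2, 2), calcium = c(5, 30), iron = c(0.3, 1.5),
                               saturated_fat = c(0, 0.5), carbohydrate = c(15, 30)),
    bread_savory_biscuits = list(fiber = c(3, 7), vitamin_a = c(0, 5), vitamin_b12 = c(0, 0),
                                 vitamin_c = c(0, 1), monounsaturated_fat = c(0.5, 2),
                                 polyunsaturated_fat = c(0.5, 2), protein = c(7, 12),
                                 total_fat = c(1, 6), calcium = c(20, 100), iron = c(1, 3),
                                 saturated_fat = c(0.3, 1.5), carbohydrate = c(40, 60)),
    dairy = list(fiber = c(0, 0), vitamin_a = c(30, 300), vitamin_b12 = c(0.2, 1.5),
                 vitamin_c = c(0, 2), monounsaturated_fat = c(0.5, 8),
                 polyunsaturated_fat = c(0.1, 1), protein = c(3, 25),
                 total_fat = c(1, 30), calcium = c(100, 800), iron = c(0, 0.5),
                 saturated_fat = c(1, 18), carbohydrate = c(2, 6)),
    meat_fish = list(fiber = c(0, 0), vitamin_a = c(0, 50), vitamin_b12 = c(0.5, 8),
                     vitamin_c = c(0, 0), monounsaturated_fat = c(2, 8),
                     polyunsaturated_fat = c(0.5, 4), protein = c(18, 28),
                     total_fat = c(3, 20), calcium = c(5, 30), iron = c(0.5, 3),
                     saturated_fat = c(1, 7), carbohydrate = c(0, 1)),
    fats_spreads = list(fiber = c(0, 0), vitamin_a = c(0, 800), vitamin_b12 = c(0, 0),
                        vitamin_c = c(0, 0), monounsaturated_fat = c(20, 60),
                        polyunsaturated_fat = c(5, 40), protein = c(0, 1),
                        total_fat = c(80, 100), calcium = c(0, 20), iron = c(0, 0.5),
                        saturated_fat = c(10, 50), carbohydrate = c(0, 1)),
    sweets_snacks = list(fiber = c(0.5, 3), vitamin_a = c(0, 50), vitamin_b12 = c(0, 0.3),
                         vitamin_c = c(0, 0), monounsaturated_fat = c(5, 15),
                         polyunsaturated_fat = c(1, 5), protein = c(3, 8),
                         total_fat = c(15, 30), calcium = c(20, 150), iron = c(0.5, 3),
                         saturated_fat = c(8, 18), carbohydrate = c(50, 65)),
    drinks = list(fiber = c(0, 0.5), vitamin_a = c(0, 20), vitamin_b12 = c(0, 0),
                  vitamin_c = c(0, 30), monounsaturated_fat = c(0, 0),
                  polyunsaturated_fat = c(0, 0), protein = c(0, 1),
                  total_fat = c(0, 0.5), calcium = c(5, 20), iron = c(0, 0.2),
                  saturated_fat = c(0, 0.2), carbohydrate = c(3, 12)),
    other = list(fiber = c(0, 2), vitamin_a = c(0, 100), vitamin_b12 = c(0, 1),
                 vitamin_c = c(0, 10), monounsaturated_fat = c(0, 5),
                 polyunsaturated_fat = c(0, 3), protein = c(1, 10),
                 total_fat = c(1, 10), calcium = c(10, 100), iron = c(0.2, 2),
                 saturated_fat = c(0.5, 4), carbohydrate = c(5, 30))
  )
}

# Per-100 g nutrient density of each single-nutrient anchor item, sized
# so that topping a typical adult target up takes a frequency of order 1.
anchor_density <- function(ranges) {
  vapply(scored_nutrients(), function(n) {
    lo <- ranges[[n]][["lower"]]
    if (lo > 0) lo else ranges[[n]][["upper"]] / 2
  }, numeric(1))
}

#' Generate the FFQ item bank and composition table
#'
#' Regular items are spread round-robin over the ten food groups with
#' NUBEL-plausible per-100 g composition drawn from group-specific
#' ranges. Twelve synthetic single-nutrient "anchor" items (ids
#' `anchor_<nutrient>`) are appended; they let [generate_ffq_responses()]
#' plant any attainable nutrient-status profile analytically.
#'
#' @param config A [generator_config()].
#' @param ranges Reference ranges (sets the anchor densities).
#' @return List `items` (tibble) and `composition` (tibble).
#' @export
generate_item_bank <- function(config, ranges = read_reference_ranges()) {
  grp_ranges <- group_composition_ranges()
  with_seed(config$seed + 303L, {
    groups <- rep(food_groups(), length.out = config$ffq_items)
    items <- tibble::tibble(
      item_id = sprintf("f%03d", seq_len(config$ffq_items)),
      food_name = sprintf("synthetic %s food %d", groups,
                          seq_len(config$ffq_items)),
      food_group = groups,
      portion_g = round(stats::runif(config$ffq_items, 30, 300))
    )
    comp_rows <- lapply(seq_len(config$ffq_items), function(i) {
      r <- grp_ranges[[groups[i]]]
      vals <- vapply(scored_nutrients(), function(n) {
        round(stats::runif(1, r[[n]][1], r[[n]][2]), 3)
      }, numeric(1))
      as.data.frame(c(list(item_id = items$item_id[i]), as.list(vals)))
    })
    composition <- tibble::as_tibble(do.call(rbind, comp_rows))

    dens <- anchor_density(ranges)
    anchors <- tibble::tibble(
      item_id = paste0("anchor_", scored_nutrients()),
      food_name = paste("synthetic", gsub("_", " ", scored_nutrients()),
                        "anchor"),
      food_group = "other",
      portion_g = 100
    )
    anchor_comp <- do.call(rbind, lapply(seq_along(scored_nutrients()),
      function(i) {
        vals <- stats::setNames(as.list(numeric(12)), scored_nutrients())
        vals[[scored_nutrients()[i]]] <- dens[[i]]
        as.data.frame(c(list(item_id = anchors$item_id[i]), vals))
      }))
    list(items = rbind(items, anchors),
         composition = rbind(composition, tibble::as_tibble(anchor_comp)))
  })
}

sample_status_profile <- function(ranges) {
  vapply(scored_nutrients(), function(n) {
    can_low <- ranges[[n]][["lower"]] > 0
    probs <- if (can_low) c(0.3, 0.5, 0.2) else c(0, 0.7, 0.3)
    sample(c("Low", "Normal", "High"), 1, prob = probs)
  }, character(1))
}

status_target <- function(status, range) {
  lo <- range[["lower"]]; hi <- range[["upper"]]
  switch(status,
         Low = 0.5 * lo,
         Normal = 0.5 * (lo + hi),
         High = 1.3 * hi)
}

#' Generate FFQ responses that recover planted status profiles exactly
#'
#' For each user and timepoint a small random baseline response over the
#' regular bank items is drawn, scaled down (if needed) so every
#' nutrient stays strictly below its per-nutrient target, and the twelve
#' single-nutrient anchor items top each nutrient up to a target placed
#' well inside the planted Low/Normal/High band. Running
#' [compute_intake()] then [classify_status()] on the result recovers
#' the planted profile exactly, by construction.
#'
#' @param config A [generator_config()].
#' @param bank Item bank from [generate_item_bank()].
#' @param ranges Reference ranges.
#' @return List `responses` (answer tibble over users and timepoints)
#'   and `planted` (named list `user_id -> status vector`).
#' @export
generate_ffq_responses <- function(config, bank, ranges = read_reference_ranges()) {
  items <- bank$items
  composition <- bank$composition
  regular <- items$item_id[!startsWith(items$item_id, "anchor_")]
  targets_for <- function(profile) {
    vapply(scored_nutrients(), function(n) {
      if (profile[[n]] == "Low" && ranges[[n]][["lower"]] <= 0) {
        stop("cannot plant Low status for ", n,
             ": its reference lower bound is 0", call. = FALSE)
      }
      status_target(profile[[n]], ranges[[n]])
    }, numeric(1))
  }
  user_ids <- sprintf("u%03d", seq_len(config$n_users))
  planted <- stats::setNames(vector("list", config$n_users), user_ids)
  rows <- list()
  for (i in seq_len(config$n_users)) {
    uid <- user_ids[i]
    profile <- config$planted_profile[[uid]]
    with_seed(config$seed + 404L + i, {
      if (is.null(profile)) profile <- sample_status_profile(ranges)
      planted[[uid]] <- profile
      targets <- targets_for(profile)
      for (tp in c("baseline", "post")) {
        picks <- sample(regular, sample(8:15, 1))
        ans <- tibble::tibble(
          user_id = uid, timepoint = tp, item_id = picks,
          frequency_per_day = round(stats::runif(length(picks), 0.05, 0.6), 4),
          portion_multiplier = round(stats::runif(length(picks), 0.5, 1.5), 4)
        )
        base_intake <- compute_intake(ans, items, composition)
        # scale the baseline down until it sits strictly below every target
        ratio <- base_intake / targets
        ratio[!is.finite(ratio)] <- 0
        if (max(ratio) > 0.9) {
          ans$frequency_per_day <- ans$frequency_per_day * 0.9 / max(ratio)
          base_intake <- base_intake * 0.9 / max(ratio)
        }
        dens <- anchor_density(ranges)
        anchor_freq <- (targets - base_intake) / dens  # portion 100 g => /100*100g
        anchor_rows <- tibble::tibble(
          user_id = uid, timepoint = tp,
          item_id = paste0("anchor_", scored_nutrients()),
          frequency_per_day = as.numeric(anchor_freq),
          portion_multiplier = 1
        )
        rows[[length(rows) + 1]] <- rbind(ans, anchor_rows)
      }
    })
  }
  list(responses = do.call(rbind, rows), planted = planted)
}

#' Generate multi-week order, feedback and recommendation histories
#'
#' Each user orders on about 80% of days, choosing among the day's meals
#' with probability proportional to `1 + 3 x (preferred-ingredient
#' overlap)` when the user has a planted taste, uniformly otherwise.
#' Thumbs-up feedback follows ~15% of orders; ~5% of days produce a
#' thumbs-down on a random non-ordered meal, naming one of its
#' ingredients (never a preferred one). A shown-recommendation record of
#' three meal ids is logged per user-day.
#'
#' @param config A [generator_config()].
#' @param menus Menus from [generate_menus()].
#' @return Event list (`orders`, `feedback`, `recommendations` tibbles).
#' @export
generate_events <- function(config, menus) {
  user_ids <- sprintf("u%03d", seq_len(config$n_users))
  with_seed(config$seed + 505L, {
    orders <- list(); feedback <- list(); recs <- list()
    for (mnu in menus) {
      ids <- names(mnu$meals)
      for (uid in user_ids) {
        taste <- config$planted_taste[[uid]]
        rec_ids <- sample(ids, min(3, length(ids)))
        recs[[length(recs) + 1]] <- tibble::tibble(
          user_id = uid, date = mnu$date, meal_ids = list(rec_ids))
        if (stats::runif(1) > 0.8) next
        w <- rep(1, length(ids))
        if (!is.null(taste)) {
          overlap <- vapply(ids, function(id) {
            length(intersect(meal_ingredient_names(mnu$meals[[id]]), taste))
          }, numeric(1))
          w <- 1 + 3 * overlap
        }
        pick <- sample(ids, 1, prob = w)
        orders[[length(orders) + 1]] <- tibble::tibble(
          user_id = uid, meal_id = pick, date = mnu$date)
        if (stats::runif(1) < 0.15) {
          feedback[[length(feedback) + 1]] <- tibble::tibble(
            user_id = uid, meal_id = pick, date = mnu$date, polarity = "up",
            disliked_ingredients = list(character()), text = "")
        }
        if (stats::runif(1) < 0.05 && length(ids) > 1) {
          other <- sample(setdiff(ids, pick), 1)
          ings <- meal_ingredient_names(mnu$meals[[other]])
          if (!is.null(taste)) ings <- setdiff(ings, taste)
          if (length(ings)) {
            feedback[[length(feedback) + 1]] <- tibble::tibble(
              user_id = uid, meal_id = other, date = mnu$date,
              polarity = "down",
              disliked_ingredients = list(sample(ings, 1)), text = "")
          }
        }
      }
    }
    ev <- empty_events()
    if (length(orders)) ev$orders <- do.call(rbind, orders)
    if (length(feedback)) ev$feedback <- do.call(rbind, feedback)
    if (length(recs)) ev$recommendations <- do.call(rbind, recs)
    ev
  })
}

#' Generate a complete synthetic world
#'
#' Deterministic in `config$seed`: the same configuration always yields
#' byte-identical serialized output.
#'
#' @param config A [generator_config()].
#' @param vocab Vocabularies.
#' @param ranges Reference ranges.
#' @return List `config`, `menus`, `users`, `items`, `composition`,
#'   `responses`, `planted_profiles`, `events`, `meal_archive` (all
#'   meals across days, keyed by id).
#' @export
generate_world <- function(config = generator_config(),
                           vocab = load_vocabularies(),
                           ranges = read_reference_ranges()) {
  menus <- generate_menus(config)
  names(menus) <- vapply(menus, function(m) format(m$date), character(1))
  users <- generate_users(config, vocab)
  bank <- generate_item_bank(config, ranges)
  ffq <- generate_ffq_responses(config, bank, ranges)
  events <- generate_events(config, menus)
  archive <- unlist(lapply(menus, `[[`, "meals"), recursive = FALSE)
  names(archive) <- vapply(archive, `[[`, character(1), "meal_id")
  archive <- archive[!duplicated(names(archive))]
  list(config = config, menus = menus, users = users,
       items = bank$items, composition = bank$composition,
       responses = ffq$responses, planted_profiles = ffq$planted,
       events = events, meal_archive = archive)
}

#' Write a synthetic world to a data directory
#'
#' Lays out the interchange formats the readers understand:
#' `menus/menu_<date>.json`, `users.json`, `ffq_items.csv`,
#' `composition.csv`, `ffq_responses.csv`, `events.csv`.
#'
#' @param world From [generate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(file.path(dir, "menus"), recursive = TRUE, showWarnings = FALSE)
  for (mnu in world$menus) {
    write_menu(mnu, file.path(dir, "menus",
                              sprintf("menu_%s.json", format(mnu$date))))
  }
  write_users(world$users, file.path(dir, "users.json"))
  utils::write.csv(world$items, file.path(dir, "ffq_items.csv"),
                   row.names = FALSE)
  utils::write.csv(world$composition, file.path(dir, "composition.csv"),
                   row.names = FALSE)
  utils::write.csv(world$responses, file.path(dir, "ffq_responses.csv"),
                   row.names = FALSE)
  write_events(world$events, file.path(dir, "events.csv"))
  invisible(dir)
}

#' A fixed, fully hand-checkable worked example
#'
#' Two users and one three-meal menu in which every intermediate
#' quantity is documented and verifiable by hand. The meals share every
#' nutrient value except fiber (2, 6 and 4 g), so for the low-fiber user
#' `u1` the normalized fiber values are 0, 1 and 0.5, the raw knowledge
#' scores 0, 5 and 2.5 (fiber Low weight 5), and the rescaled knowledge
#' scores 0, 1 and 0.5. Both users are cold (content 0.5, collaborative
#' 0), so u1's final scores are `0.65 k + 0.25 x 0.5`: 0.125, 0.775 and
#' 0.45, ranking bean stew > cheese toast > apple salad. User `u2` is
#' Normal in every nutrient: all knowledge scores rescale to the neutral
#' 0.5 and every final is 0.45, so the ranking falls back to the
#' lexicographic meal-id tie-break.
#'
#' @return List `menu`, `users`, `profiles`, and `expected` (a tibble of
#'   the documented final scores per user).
#' @export
generate_toy_worked_example <- function() {
  shared <- c(vitamin_a = 100, vitamin_b12 = 1, vitamin_c = 10,
              monounsaturated_fat = 5, polyunsaturated_fat = 2,
              protein = 10, total_fat = 10, calcium = 100, iron = 2,
              saturated_fat = 3, carbohydrate = 40)
  mk <- function(id, name, course, fiber, ings, ns) {
    meal(id, name, course, "2022-02-01", "main",
         nutrients = c(fiber = fiber, shared),
         ingredients = lapply(ings, ingredient), nutriscore = ns)
  }
  mnu <- menu("2022-02-01", "main", list(
    mk("toy_apple_salad", "apple salad", "salad", 2,
       c("apple", "lettuce"), "A"),
    mk("toy_bean_stew", "bean stew", "main", 6, c("beans", "tomato"), "B"),
    mk("toy_cheese_toast", "cheese toast", "sandwich", 4,
       c("bread", "cheese"), "C")
  ))
  all_normal <- stats::setNames(rep("Normal", 12), scored_nutrients())
  low_fiber <- all_normal
  low_fiber[["fiber"]] <- "Low"
  users <- list(u1 = user_profile("u1"), u2 = user_profile("u2"))
  expected <- tibble::tibble(
    user_id = rep(c("u1", "u2"), each = 3),
    meal_id = rep(c("toy_apple_salad", "toy_bean_stew",
                    "toy_cheese_toast"), 2),
    final = c(0.125, 0.775, 0.45, 0.45, 0.45, 0.45)
  )
  list(menu = mnu, users = users,
       profiles = list(u1 = low_fiber, u2 = all_normal),
       expected = expected)
}

#' Build a response whose top contributor for a macronutrient is a given
#' food group
#'
#' Utility for planting dietary-shift patterns: a heavy answer on the
#' group's richest item plus a light random background guarantees the
#' group tops the contribution table.
#'
#' @param user_id,timepoint Response identity.
#' @param group Target [food_groups()] entry.
#' @param bank Item bank list from [generate_item_bank()].
#' @param macronutrient Macronutrient to dominate (default total fat).
#' @param seed Seed for the background draw.
#' @return Answer tibble.
#' @export
generate_group_dominant_response <- function(user_id, timepoint, group, bank,
                                             macronutrient = "total_fat",
                                             seed = 1) {
  items <- bank$items; composition <- bank$composition
  in_group <- items$item_id[items$food_group == group &
                              !startsWith(items$item_id, "anchor_")]
  if (length(in_group) == 0) stop("no bank items in group ", group,
                                  call. = FALSE)
  comp_val <- composition[[macronutrient]][match(in_group, composition$item_id)]
  heavy <- in_group[order(-comp_val, in_group)][1]
  if (comp_val[match(heavy, in_group)] <= 0) {
    stop("group ", group, " has no ", macronutrient, " in the bank",
         call. = FALSE)
  }
  with_seed(seed, {
    others <- sample(setdiff(items$item_id[!startsWith(items$item_id, "anchor_")],
                             heavy), 3)
    tibble::tibble(
      user_id = user_id, timepoint = timepoint,
      item_id = c(heavy, others),
      frequency_per_day = c(25, stats::runif(3, 0.05, 0.2)),
      portion_multiplier = 1
    )
  })
}
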