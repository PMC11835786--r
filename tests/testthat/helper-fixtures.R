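# Small programmatic fixtures shared across test files.

base_nutrients <- function(...) {
  x <- c(fiber = 4, vitamin_a = 100, vitamin_b12 = 1, vitamin_c = 10,
         monounsaturated_fat = 5, polyunsaturated_fat = 2, protein = 10,
         total_fat = 10, calcium = 100, iron = 2, saturated_fat = 3,
         carbohydrate = 40)
  over <- c(...)
  x[names(over)] <- over
  x
}

make_meal <- function(id, ..., ingredients = c("tomato", "rice"),
                      allergen_tags = character(),
                      lifestyle_tags = character(), nutriscore = "B",
                      date = "2022-02-01", location = "main",
                      course = "main", opaque = FALSE) {
  ings <- lapply(ingredients, mealrec::ingredient)
  if (opaque) {
    ings <- c(ings, list(mealrec::ingredient("mystery sauce",
                                             composite_opaque = TRUE)))
  }
  mealrec::meal(id, paste("meal", id), course, date, location,
                nutrients = base_nutrients(...), ingredients = ings,
                allergen_tags = allergen_tags,
                lifestyle_tags = lifestyle_tags, nutriscore = nutriscore)
}

all_normal_profile <- function() {
  stats::setNames(rep("Normal", 12), scored_nutrients())
}

profile_with <- function(...) {
  p <- all_normal_profile()
  over <- c(...)
  p[names(over)] <- over
  p
}

# random small scoring instance: n meals, random nutrients/ingredients,
# random profile/taste/orders spanning >= 15 days
random_instance <- function(n_meals = 5, n_users = 4, seed = 1) {
  set.seed(seed)
  ing_names <- c("tomato", "rice", "cheese", "beans", "pasta", "salmon",
                 "lettuce", "egg", "onion", "walnuts")
  meals <- lapply(seq_len(n_meals), function(i) {
    nv <- stats::setNames(round(stats::runif(12, 0, 50), 3),
                          scored_nutrients())
    mealrec::meal(sprintf("rm%02d", i), paste("meal", i), "main",
                  "2022-02-01", "main", nutrients = nv,
                  ingredients = lapply(sample(ing_names, sample(2:4, 1)),
                                       mealrec::ingredient))
  })
  names(meals) <- vapply(meals, `[[`, character(1), "meal_id")
  profile <- stats::setNames(
    sample(c("Low", "Normal", "High"), 12, replace = TRUE),
    scored_nutrients())
  taste <- stats::setNames(round(stats::rnorm(5), 3),
                           sample(ing_names, 5))
  users <- sprintf("user%02d", seq_len(n_users))
  orders <- tibble::tibble(
    user_id = sample(users, 30, replace = TRUE),
    meal_id = sample(names(meals), 30, replace = TRUE),
    date = as.Date("2022-01-15") + sample(0:16, 30, replace = TRUE)
  )
  cs <- structure(list(date = as.Date("2022-02-01"), user_id = users[1],
                       meals = meals,
                       exclusion_log = tibble::tibble(meal_id = character(),
                                                      reason = character())),
                  class = "candidate_set")
  list(candidates = cs, meals = meals, profile = profile, taste = taste,
       orders = orders, user_id = users[1], today = as.Date("2022-02-01"))
}
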