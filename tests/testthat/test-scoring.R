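two_meal_candidates <- function(nutrient, lo = 2, hi = 6) {
  args_lo <- stats::setNames(list(lo), nutrient)
  args_hi <- stats::setNames(list(hi), nutrient)
  meals <- list(do.call(make_meal, c(list("mlo"), args_lo)),
                do.call(make_meal, c(list("mhi"), args_hi)))
  menu("2022-02-01", "main", meals)
}

test_that("min-max normalization hits the endpoints and the constant rule", {
  mnu <- two_meal_candidates("fiber")
  norm <- normalize_nutrients(mnu)
  expect_equal(norm["mlo", "fiber"], 0)
  expect_equal(norm["mhi", "fiber"], 1)
  # all other nutrients identical across meals -> 0.5
  expect_true(all(norm[, setdiff(scored_nutrients(), "fiber")] == 0.5))

  identical_menu <- menu("2022-02-01", "main",
                         list(make_meal("a"), make_meal("b"), make_meal("c")))
  expect_true(all(normalize_nutrients(identical_menu) == 0.5))
})

test_that("each normalized column spans [0, 1] on random candidate sets", {
  inst <- random_instance(n_meals = 10, seed = 4)
  norm <- normalize_nutrients(inst$candidates)
  for (j in seq_len(ncol(norm))) {
    expect_equal(min(norm[, j]), 0)
    expect_equal(max(norm[, j]), 1)
    expect_true(all(norm[, j] >= 0 & norm[, j] <= 1))
  }
})

test_that("an all-Normal profile gives zero raw scores rescaled to 0.5", {
  mnu <- two_meal_candidates("fiber")
  ks <- knowledge_score(mnu, all_normal_profile())
  expect_equal(ks$raw, c(0, 0))
  expect_equal(ks$score, c(0.5, 0.5))
})

test_that("the fiber-Low weight of 5 is the raw score gap on a two-meal menu", {
  mnu <- two_meal_candidates("fiber")
  ks <- knowledge_score(mnu, profile_with(fiber = "Low"))
  gap <- ks$raw[ks$meal_id == "mhi"] - ks$raw[ks$meal_id == "mlo"]
  expect_equal(gap, 5)
  expect_gt(ks$score[ks$meal_id == "mhi"], ks$score[ks$meal_id == "mlo"])
  # fiber already High: no further emphasis, zero gap
  ks_high <- knowledge_score(mnu, profile_with(fiber = "High"))
  expect_equal(diff(ks_high$raw), 0)
})

test_that("high polyunsaturated-fat intake discounts PUFA-rich meals at -0.5", {
  mnu <- two_meal_candidates("polyunsaturated_fat")
  ks <- knowledge_score(mnu, profile_with(polyunsaturated_fat = "High"))
  gap <- ks$raw[ks$meal_id == "mhi"] - ks$raw[ks$meal_id == "mlo"]
  expect_equal(gap, -0.5)
  ks_low <- knowledge_score(mnu, profile_with(polyunsaturated_fat = "Low"))
  expect_equal(ks_low$raw[ks_low$meal_id == "mhi"] -
                 ks_low$raw[ks_low$meal_id == "mlo"], 3)
})

test_that("the default weight table matches the dietitian weights row by row", {
  tbl <- default_weight_table()
  expect_equal(tbl["fiber", "Low"], 5)
  expect_equal(tbl["fiber", "High"], 0)
  expect_equal(tbl["vitamin_a", "Low"], 2)
  expect_equal(tbl["vitamin_b12", "Low"], 3)
  expect_equal(tbl["vitamin_c", "Low"], 5)
  expect_equal(tbl["monounsaturated_fat", "Low"], 1)
  lowhigh <- function(n) unname(unlist(tbl[n, c("Low", "High")]))
  expect_equal(lowhigh("polyunsaturated_fat"), c(3, -0.5))
  expect_equal(lowhigh("protein"), c(3, -0.3))
  expect_equal(lowhigh("total_fat"), c(-1, -1))
  expect_equal(tbl["calcium", "Low"], 5)
  expect_equal(tbl["iron", "Low"], 2)
  expect_equal(lowhigh("saturated_fat"), c(0, -1))
  expect_equal(lowhigh("carbohydrate"), c(3, -0.5))
  expect_true(all(tbl$Normal == 0))
})

test_that("taste vectors accumulate +1 per ingredient and -2 per named dislike", {
  archive <- list(
    m1 = make_meal("m1", ingredients = c("pasta", "tomato")),
    m2 = make_meal("m2", ingredients = c("rice", "coriander", "chicken"))
  )
  no_events <- build_taste_vector(NULL, NULL, archive)
  expect_length(no_events, 0)

  orders <- tibble::tibble(user_id = "u1", meal_id = "m1",
                           date = as.Date("2022-02-01"))
  t1 <- build_taste_vector(orders, NULL, archive)
  expect_equal(t1[["pasta"]], 1)
  expect_equal(t1[["tomato"]], 1)

  fb <- tibble::tibble(user_id = "u1", meal_id = "m2",
                       date = as.Date("2022-02-02"), polarity = "down",
                       disliked_ingredients = list("coriander"), text = "")
  t2 <- build_taste_vector(orders, fb, archive)
  expect_equal(t2[["coriander"]], -2)
  expect_false("rice" %in% names(t2))     # only the named ingredient
  expect_false("chicken" %in% names(t2))

  fb_up <- tibble::tibble(user_id = "u1", meal_id = "m1",
                          date = as.Date("2022-02-03"), polarity = "up",
                          disliked_ingredients = list(character()), text = "")
  t3 <- build_taste_vector(orders, fb_up, archive)
  expect_equal(t3[["pasta"]], 2)

  orders_bad <- tibble::tibble(user_id = "u1", meal_id = "ghost",
                               date = as.Date("2022-02-01"))
  expect_warning(t4 <- build_taste_vector(orders_bad, NULL, archive), "ghost")
  expect_length(t4, 0)
})

test_that("content score is cosine mapped to [0,1] with a 0.5 neutral", {
  m <- make_meal("m1", ingredients = c("pasta", "tomato", "cheese"))
  own <- stats::setNames(c(1, 1, 1), c("pasta", "tomato", "cheese"))
  expect_equal(content_score(m, own), 1)
  disjoint <- stats::setNames(c(2, 1), c("beans", "rice"))
  expect_equal(content_score(m, disjoint), 0.5)
  expect_equal(content_score(m, numeric(0)), 0.5)
  expect_equal(content_score(m, stats::setNames(0, "pasta")), 0.5)

  # 3-ingredient worked case against hand-computed dot/norm arithmetic
  taste <- stats::setNames(c(2, -1, 3), c("pasta", "tomato", "beans"))
  keys <- c("pasta", "tomato", "cheese", "beans")
  a <- c(1, 1, 1, 0)
  b <- c(2, -1, 0, 3)
  expected <- (sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2))) + 1) / 2
  expect_equal(content_score(m, taste), expected, tolerance = 1e-12)
})

test_that("collaborative scoring waits out the two-week cold start", {
  orders <- tibble::tibble(
    user_id = rep(c("u1", "u2", "u3"), each = 4),
    meal_id = rep(c("m1", "m2", "m1", "m3"), 3),
    date = as.Date("2022-01-17") + rep(0:3, 3))
  # day 5 of data collection: inactive, every meal scores 0
  expect_false(collaborative_active(orders, as.Date("2022-01-21"), 14))
  expect_equal(collaborative_score("m1", "u1", orders,
                                   as.Date("2022-01-21")), 0)
  # day 14: active
  expect_true(collaborative_active(orders, as.Date("2022-01-30"), 14))
  expect_false(collaborative_active(orders, as.Date("2022-01-29"), 14))
  # every neighbour ordered m1 -> score 1
  s <- collaborative_score("m1", "u1", orders, as.Date("2022-01-30"), k = 2)
  expect_equal(s, 1)
  # a user with no orders stays at 0 even when the system is active
  expect_equal(collaborative_score("m1", "u9", orders,
                                   as.Date("2022-01-30")), 0)
})

test_that("neighbour sets and scores match an all-pairs similarity oracle", {
  set.seed(77)
  for (rep in 1:10) {
    inst <- random_instance(n_meals = 5, n_users = 5, seed = 1000 + rep)
    got_nb <- nearest_neighbors(inst$user_id, inst$orders, k = 3)
    # oracle via helper-oracle machinery on a single meal
    for (id in names(inst$meals)[1:2]) {
      got <- collaborative_score(id, inst$user_id, inst$orders, inst$today,
                                 k = 3)
      want <- oracle_collab(id, inst$user_id, inst$orders, inst$today,
                            k = 3, activation_days = 14)
      expect_equal(got, want)
    }
    expect_lte(length(got_nb), 3)
  }
})

test_that("a single candidate ranks first whatever its scores", {
  mnu <- menu("2022-02-01", "main", list(make_meal("only")))
  rk <- hybrid_rank(mnu, all_normal_profile())
  expect_equal(rk$meal_id, "only")
  expect_equal(rk$rank, 1)
})

test_that("with neutral components every final is 0.65*0.5 + 0.25*0.5 = 0.45", {
  mnu <- menu("2022-02-01", "main",
              lapply(c("a", "b", "c"), function(id) {
                make_meal(id, fiber = match(id, c("a", "b", "c")))
              }))
  rk <- hybrid_rank(mnu, all_normal_profile())
  expect_equal(rk$final, rep(0.45, 3), tolerance = 1e-12)
  # fully tie-broken: lexicographic meal ids
  expect_equal(rk$meal_id, c("a", "b", "c"))
})

test_that("the final score is the exact weighted component combination", {
  for (rep in 1:10) {
    inst <- random_instance(n_meals = 6, seed = 200 + rep)
    rk <- hybrid_rank(inst$candidates, inst$profile, inst$taste,
                      inst$orders, inst$today)
    expect_equal(rk$final,
                 0.65 * rk$knowledge + 0.25 * rk$content +
                   0.10 * rk$collaborative,
                 tolerance = 1e-12)
    w <- hybrid_weights(0.4, 0.35, 0.25)
    rk2 <- hybrid_rank(inst$candidates, inst$profile, inst$taste,
                       inst$orders, inst$today, weights = w)
    expect_equal(rk2$final,
                 0.4 * rk2$knowledge + 0.35 * rk2$content +
                   0.25 * rk2$collaborative,
                 tolerance = 1e-12)
  }
})

test_that("full-pipeline rankings equal the brute-force oracle", {
  for (rep in 1:20) {
    inst <- random_instance(n_meals = sample(2:6, 1), seed = 300 + rep)
    got <- hybrid_rank(inst$candidates, inst$profile, inst$taste,
                       inst$orders, inst$today)
    want <- oracle_rank(inst$meals, inst$profile, inst$taste, inst$orders,
                        inst$user_id, inst$today)
    expect_equal(got$meal_id, want$meal_id)
    expect_equal(got$final, want$final, tolerance = 1e-12)
    expect_equal(got$knowledge_raw, want$raw, tolerance = 1e-12)
  }
})

test_that("for a low-fiber user more fiber never lowers a meal's rank", {
  set.seed(55)
  profile <- profile_with(fiber = "Low")
  for (rep in 1:10) {
    inst <- random_instance(n_meals = 5, seed = 400 + rep)
    rk1 <- hybrid_rank(inst$candidates, profile, inst$taste)
    target <- names(inst$meals)[3]
    boosted <- inst$meals
    boosted[[target]]$nutrients[["fiber"]] <-
      boosted[[target]]$nutrients[["fiber"]] + stats::runif(1, 1, 20)
    cs <- inst$candidates; cs$meals <- boosted
    rk2 <- hybrid_rank(cs, profile, inst$taste)
    expect_lte(rk2$rank[rk2$meal_id == target],
               rk1$rank[rk1$meal_id == target])
  }
})

test_that("hybrid weights must be a simplex point", {
  expect_error(hybrid_weights(0.7, 0.25, 0.10), "sum to 1")
  expect_error(hybrid_weights(-0.1, 1.0, 0.1), ">= 0")
  w <- hybrid_weights()
  expect_equal(w$knowledge + w$content + w$collaborative, 1)
})
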