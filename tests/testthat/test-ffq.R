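make_bank <- function(...) {
  # each argument: list(id, group, portion_g, <nutrient overrides per 100 g>)
  specs <- list(...)
  items <- tibble::tibble(
    item_id = vapply(specs, `[[`, character(1), "id"),
    food_name = vapply(specs, `[[`, character(1), "id"),
    food_group = vapply(specs, `[[`, character(1), "group"),
    portion_g = vapply(specs, `[[`, numeric(1), "portion")
  )
  comp <- do.call(rbind, lapply(specs, function(s) {
    vals <- stats::setNames(as.list(numeric(12)), scored_nutrients())
    for (n in intersect(names(s), scored_nutrients())) vals[[n]] <- s[[n]]
    as.data.frame(c(list(item_id = s$id), vals))
  }))
  list(items = items, composition = tibble::as_tibble(comp))
}

answers <- function(ids, freq = 1, mult = 1) {
  tibble::tibble(user_id = "u1", timepoint = "baseline", item_id = ids,
                 frequency_per_day = freq, portion_multiplier = mult)
}

test_that("intake follows frequency x portion x composition arithmetic", {
  b <- make_bank(list(id = "i1", group = "bread_savory_biscuits",
                      portion = 200, fiber = 2))
  # 1/day x 1 x 200 g x 2 g/100 g = 4 g/day, by hand
  intake <- compute_intake(answers("i1"), b$items, b$composition)
  expect_equal(intake[["fiber"]], 4)
  expect_equal(sum(intake), 4)  # all other nutrients zero
})

test_that("intake is zero on empty answers and linear in the answer rows", {
  b <- make_bank(list(id = "i1", group = "dairy", portion = 150,
                      calcium = 120, protein = 3.4),
                 list(id = "i2", group = "fruit", portion = 120,
                      vitamin_c = 45, fiber = 2.2))
  empty <- answers(character(0))
  expect_equal(unname(compute_intake(empty[0, ], b$items, b$composition)),
               rep(0, 12))
  a <- answers(c("i1", "i2"), freq = c(0.5, 2), mult = c(1, 1.25))
  one <- compute_intake(a, b$items, b$composition)
  doubled <- compute_intake(rbind(a, a), b$items, b$composition)
  expect_equal(doubled, 2 * one)
  shuffled <- compute_intake(a[2:1, ], b$items, b$composition)
  expect_equal(shuffled, one)
})

test_that("unresolvable item ids error naming the id", {
  b <- make_bank(list(id = "i1", group = "other", portion = 100))
  expect_error(compute_intake(answers("nope"), b$items, b$composition),
               "nope")
})

test_that("status classification is Low/Normal/High with Normal bounds", {
  ranges <- read_reference_ranges()
  intake <- stats::setNames(
    vapply(ranges, function(r) mean(r), numeric(1)), scored_nutrients())
  intake[["fiber"]] <- 10  # fiber range is [25, 40]
  st <- classify_status(intake, ranges)
  expect_equal(st[["fiber"]], "Low")
  intake[["fiber"]] <- 25  # exactly at the lower bound
  expect_equal(classify_status(intake, ranges)[["fiber"]], "Normal")
  intake[["fiber"]] <- 40.0001
  expect_equal(classify_status(intake, ranges)[["fiber"]], "High")
})

test_that("classification matches a per-nutrient brute-force comparison", {
  ranges <- read_reference_ranges()
  set.seed(99)
  for (rep in 1:25) {
    intake <- stats::setNames(
      vapply(ranges, function(r) stats::runif(1, 0, 2 * r[["upper"]]),
             numeric(1)), scored_nutrients())
    st <- classify_status(intake, ranges)
    for (n in scored_nutrients()) {
      expected <- if (intake[[n]] < ranges[[n]][["lower"]]) "Low"
        else if (intake[[n]] > ranges[[n]][["upper"]]) "High" else "Normal"
      expect_identical(st[[n]], expected)
    }
  }
})

test_that("classification is monotone in intake", {
  ranges <- read_reference_ranges()
  lvl <- c(Low = 1, Normal = 2, High = 3)
  set.seed(7)
  base <- stats::setNames(
    vapply(ranges, function(r) stats::runif(1, 0, 2 * r[["upper"]]),
           numeric(1)), scored_nutrients())
  st0 <- classify_status(base, ranges)
  for (n in scored_nutrients()) {
    bumped <- base
    bumped[[n]] <- bumped[[n]] * 1.5 + 1
    st1 <- classify_status(bumped, ranges)
    expect_gte(lvl[[st1[[n]]]], lvl[[st0[[n]]]])
  }
})

test_that("food-group contributions sum to 100 and tie-break alphabetically", {
  b <- make_bank(list(id = "veg", group = "vegetables", portion = 100,
                      carbohydrate = 10),
                 list(id = "fru", group = "fruit", portion = 100,
                      carbohydrate = 10))
  only_veg <- food_group_contributions(answers("veg"), b$items,
                                       b$composition, "carbohydrate")
  expect_equal(only_veg$percent[["vegetables"]], 100)
  expect_equal(only_veg$top_group, "vegetables")

  both <- food_group_contributions(answers(c("veg", "fru")), b$items,
                                   b$composition, "carbohydrate")
  expect_equal(both$percent[["vegetables"]], 50)
  expect_equal(both$percent[["fruit"]], 50)
  expect_equal(both$top_group, "fruit")  # alphabetical among the tied
  expect_equal(sum(both$percent), 100, tolerance = 1e-9)
})

test_that("contributions match an independent per-item summation oracle", {
  cfg <- generator_config(seed = 23, n_users = 1, ffq_items = 30)
  bank <- generate_item_bank(cfg)
  regular <- bank$items$item_id[!startsWith(bank$items$item_id, "anchor_")]
  set.seed(5)
  a <- answers(regular, freq = round(stats::runif(30, 0.05, 1), 3),
               mult = round(stats::runif(30, 0.5, 1.5), 3))
  got <- food_group_contributions(a, bank$items, bank$composition, "total_fat")
  # oracle: loop items, accumulate fat per group
  acc <- stats::setNames(numeric(10), food_groups())
  for (i in seq_len(nrow(a))) {
    it <- match(a$item_id[i], bank$items$item_id)
    ic <- match(a$item_id[i], bank$composition$item_id)
    fat <- a$frequency_per_day[i] * a$portion_multiplier[i] *
      bank$items$portion_g[it] / 100 * bank$composition$total_fat[ic]
    g <- bank$items$food_group[it]
    acc[[g]] <- acc[[g]] + fat
  }
  expect_equal(got$percent, 100 * acc / sum(acc))
  expect_equal(got$top_group, names(which.max(acc)))
  # scale invariance: uniform rescaling of frequencies changes nothing
  a2 <- a; a2$frequency_per_day <- a2$frequency_per_day * 7
  expect_equal(food_group_contributions(a2, bank$items, bank$composition,
                                        "total_fat")$percent,
               got$percent)
})

test_that("zero total macronutrient intake is an error", {
  b <- make_bank(list(id = "water", group = "drinks", portion = 200))
  expect_error(food_group_contributions(answers("water"), b$items,
                                        b$composition, "total_fat"),
               "zero")
})

test_that("profile comparison counts users per top group at each timepoint", {
  base <- c(u1 = "vegetables", u2 = "vegetables", u3 = "meat_fish")
  post <- c(u1 = "vegetables", u2 = "vegetables", u3 = "vegetables")
  tab <- compare_profiles(base, post)
  expect_equal(tab$baseline[tab$food_group == "vegetables"], 2)
  expect_equal(tab$post[tab$food_group == "vegetables"], 3)
  expect_equal(tab$baseline[tab$food_group == "meat_fish"], 1)
  expect_equal(tab$post[tab$food_group == "meat_fish"], 0)
  expect_equal(sum(tab$baseline), 3)
  expect_equal(sum(tab$post), 3)
  expect_warning(compare_profiles(c(base, u9 = "dairy"), post), "u9")
})

test_that("planted dietary switches in a 41-user cohort are recovered", {
  cfg <- generator_config(seed = 31, n_users = 1, ffq_items = 40)
  bank <- generate_item_bank(cfg)
  # plant: 17 users topping meat_fish at baseline, 13 after; the rest
  # fats_spreads (shape of a fat-contribution shift table)
  plan_base <- rep(c("meat_fish", "fats_spreads"), c(17, 24))
  plan_post <- rep(c("meat_fish", "fats_spreads"), c(13, 28))
  uid <- sprintf("s%02d", 1:41)
  top_of <- function(uid, tp, group, seed) {
    a <- generate_group_dominant_response(uid, tp, group, bank, seed = seed)
    food_group_contributions(a, bank$items, bank$composition,
                             "total_fat")$top_group
  }
  base <- stats::setNames(
    mapply(top_of, uid, "baseline", plan_base, seq_along(uid)), uid)
  post <- stats::setNames(
    mapply(top_of, uid, "post", plan_post, 100 + seq_along(uid)), uid)
  tab <- compare_profiles(base, post)
  expect_equal(tab$baseline[tab$food_group == "meat_fish"], 17)
  expect_equal(tab$post[tab$food_group == "meat_fish"], 13)
  expect_equal(tab$baseline[tab$food_group == "fats_spreads"], 24)
  expect_equal(tab$post[tab$food_group == "fats_spreads"], 28)
})
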