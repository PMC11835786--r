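# Independent brute-force recomputation of the full ranking pipeline,
# written loop-by-loop from the definitions; shares no code with the
# package internals it checks.

oracle_minmax <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(rep(0.5, length(v)))
  (v - lo) / (hi - lo)
}

oracle_cosine <- function(a, b) {
  den <- sqrt(sum(a * a)) * sqrt(sum(b * b))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

oracle_content <- function(meal_obj, taste) {
  if (length(taste) == 0 || all(taste == 0)) return(0.5)
  ings <- unique(unlist(lapply(meal_obj$ingredients, function(g) {
    c(g$name, g$sub_ingredients)
  })))
  keys <- unique(c(ings, names(taste)))
  a <- numeric(length(keys)); b <- numeric(length(keys))
  for (i in seq_along(keys)) {
    if (keys[i] %in% ings) a[i] <- 1
    if (keys[i] %in% names(taste)) b[i] <- taste[[keys[i]]]
  }
  cs <- oracle_cosine(a, b)
  if (is.na(cs)) 0.5 else (cs + 1) / 2
}

oracle_collab <- function(meal_id, user_id, orders, today, k, activation_days) {
  if (nrow(orders) == 0) return(0)
  if (as.integer(as.Date(today) - min(orders$date)) + 1 < activation_days) return(0)
  if (!user_id %in% orders$user_id) return(0)
  users <- sort(unique(orders$user_id))
  meals <- sort(unique(orders$meal_id))
  counts <- matrix(0, length(users), length(meals),
                   dimnames = list(users, meals))
  for (i in seq_len(nrow(orders))) {
    counts[orders$user_id[i], orders$meal_id[i]] <-
      counts[orders$user_id[i], orders$meal_id[i]] + 1
  }
  others <- setdiff(users, user_id)
  if (length(others) == 0) return(0)
  sims <- sapply(others, function(u) {
    s <- oracle_cosine(counts[user_id, ], counts[u, ])
    if (is.na(s)) 0 else s
  })
  nb <- others[order(-sims, others)]
  nb <- nb[seq_len(min(k, length(nb)))]
  frac <- 0
  for (u in nb) {
    if (meal_id %in% orders$meal_id[orders$user_id == u]) frac <- frac + 1
  }
  frac / length(nb)
}

oracle_rank <- function(meals, profile, taste, orders, user_id, today,
                        w_k = 0.65, w_c = 0.25, w_f = 0.10,
                        table = default_weight_table(), k = 5,
                        activation_days = 14) {
  ids <- names(meals)
  nmat <- sapply(scored_nutrients(), function(n) {
    oracle_minmax(sapply(meals, function(m) m$nutrients[[n]]))
  })
  if (is.null(dim(nmat))) nmat <- matrix(nmat, nrow = 1)
  raw <- numeric(length(ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(scored_nutrients())) {
      n <- scored_nutrients()[j]
      raw[i] <- raw[i] + table[n, profile[[n]]] * nmat[i, j]
    }
  }
  kscore <- oracle_minmax(raw)
  cscore <- sapply(meals, function(m) oracle_content(m, taste))
  fscore <- sapply(ids, function(id) {
    oracle_collab(id, user_id, orders, today, k, activation_days)
  })
  final <- w_k * kscore + w_c * cscore + w_f * fscore
  ord <- order(-final, -kscore, ids)
  data.frame(meal_id = ids[ord], final = final[ord],
             knowledge = kscore[ord], content = unname(cscore[ord]),
             collaborative = unname(fscore[ord]), raw = raw[ord],
             stringsAsFactors = FALSE)
}
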