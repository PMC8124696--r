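random_factors <- function(seed, n_factors = 3, n_levels = 3) {
  set.seed(seed)
  labs <- c("High", "Medium", "Low")[seq_len(n_levels)]
  lapply(seq_len(n_factors), function(i) {
    g <- rgamma(n_levels, 1)
    level_distribution(paste0("f", i), setNames(g / sum(g), labs))
  })
}

random_map <- function(seed, factors,
                       cats = c("High", "Medium", "Low")) {
  set.seed(seed + 1000)
  lv <- lapply(factors, function(f) f$levels)
  names(lv) <- vapply(factors, `[[`, "", "factor_name")
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  grid$consequence <- sample(cats, nrow(grid), replace = TRUE)
  grid
}

test_that("path enumeration has the right cardinality and unit mass", {
  f <- random_factors(1)
  tree <- event_tree(f, random_map(1, f))
  paths <- enumerate_paths(tree)
  expect_equal(nrow(paths), 27)  # 3 factors x 3 levels, deterministic map
  expect_equal(sum(paths$probability), 1, tolerance = 1e-9)

  one <- event_tree(
    list(level_distribution("f", c(High = 1, Medium = 0, Low = 0))),
    data.frame(f = c("High", "Medium", "Low"),
               consequence = c("High", "Medium", "Low")))
  p1 <- enumerate_paths(one)
  expect_equal(sum(p1$probability[p1$probability > 0]), 1)
  expect_equal(p1$probability[p1$f == "High"], 1)
})

test_that("probabilistic leaf maps fan out and conserve mass", {
  f <- list(level_distribution("f", c(High = 0.6, Low = 0.4)))
  map <- data.frame(f = c("High", "Low"), High = c(0.7, 0.1),
                    Low = c(0.3, 0.9))
  tree <- event_tree(f, map, categories = c("High", "Low"))
  paths <- enumerate_paths(tree)
  expect_equal(nrow(paths), 4)
  expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
  d <- consequence_distribution(tree)
  expect_equal(unname(unclass(d)), c(0.6 * 0.7 + 0.4 * 0.1,
                                     0.6 * 0.3 + 0.4 * 0.9))
})

test_that("consequence distribution equals the enumeration oracle", {
  for (seed in 1:25) {
    f <- random_factors(seed)
    map <- random_map(seed, f)
    tree <- event_tree(f, map)
    oracle <- joint_table_oracle(f, map)
    want <- vapply(c("High", "Medium", "Low"), function(k)
      sum(oracle$probability[oracle$consequence == k]), 0)
    got <- consequence_distribution(tree)
    expect_equal(unclass(got), want, tolerance = 1e-9)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("conditionals match P(f and c) / P(f) from joint enumeration", {
  for (seed in 1:10) {
    f <- random_factors(seed)
    map <- random_map(seed, f)
    tree <- event_tree(f, map)
    oracle <- joint_table_oracle(f, map)
    fac <- f[[2]]
    for (l in fac$levels) {
      if (fac$prob[[l]] <= 0) next
      got <- conditional_consequence_given_factor(tree, "f2", l)
      sub <- oracle[oracle$f2 == l, ]
      want <- vapply(c("High", "Medium", "Low"), function(k)
        sum(sub$probability[sub$consequence == k]) / fac$prob[[l]], 0)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("law of total probability holds for explicit-map trees", {
  for (seed in 1:10) {
    f <- random_factors(seed)
    tree <- event_tree(f, random_map(seed, f))
    marg <- consequence_distribution(tree)
    for (fac in f) {
      total <- 0 * unclass(marg)
      for (l in fac$levels)
        total <- total + fac$prob[[l]] *
          conditional_consequence_given_factor(tree, fac$factor_name, l)
      expect_equal(total, unclass(marg), tolerance = 1e-9)
    }
  }
})

test_that("factor order does not change marginal or conditional results", {
  f <- random_factors(7)
  map <- random_map(7, f)
  t1 <- event_tree(f, map)
  t2 <- event_tree(rev(f), map)
  expect_equal(consequence_distribution(t1),
               consequence_distribution(t2), tolerance = 1e-12)
  expect_equal(conditional_consequence_given_factor(t1, "f1", "High"),
               conditional_consequence_given_factor(t2, "f1", "High"),
               tolerance = 1e-12)
})

test_that("Bayes inversion reproduces the published risk rating", {
  expect_equal(round(as.numeric(bayes_invert(0.41, 0.50, 0.49)), 4),
               0.4184)
  # independence: P(c | f) = P(c) implies P(f | c) = P(f)
  expect_equal(as.numeric(bayes_invert(0.3, 0.6, 0.3)), 0.6)
  expect_error(bayes_invert(0.5, 0.5, 0), "must be > 0")
  expect_warning(out <- bayes_invert(0.9, 0.9, 0.1), "clipped")
  expect_equal(as.numeric(out), 1)
})

test_that("Bayes formula agrees with direct joint enumeration", {
  for (seed in 1:10) {
    f <- random_factors(seed)
    map <- random_map(seed, f)
    tree <- event_tree(f, map)
    marg <- consequence_distribution(tree)
    oracle <- joint_table_oracle(f, map)
    fac <- f[[1]]
    for (l in fac$levels) {
      p_f <- fac$prob[[l]]
      if (p_f <= 0) next
      p_c_given_f <- conditional_consequence_given_factor(tree, "f1", l)
      for (k in c("High", "Medium", "Low")) {
        p_c <- unclass(marg)[[k]]
        if (p_c <= 0) next
        direct <- sum(oracle$probability[oracle$f1 == l &
                                           oracle$consequence == k]) / p_c
        expect_equal(as.numeric(bayes_invert(p_c_given_f[[k]], p_f, p_c)),
                     direct, tolerance = 1e-12)
      }
    }
  }
})

test_that("conditional risk table is internally Bayes-consistent", {
  f <- random_factors(3)
  tree <- event_tree(f, random_map(3, f))
  tab <- conditional_risk_table(tree)
  marg <- consequence_distribution(tree)
  for (i in seq_len(nrow(tab$inverse))) {
    row <- tab$inverse[i, ]
    fwd <- tab$forward[tab$forward$factor == row$factor &
                         tab$forward$level == row$level &
                         tab$forward$consequence == row$consequence, ]
    fac <- f[[match(row$factor, vapply(f, `[[`, "", "factor_name"))]]
    expect_equal(row$probability,
                 fwd$probability * fac$prob[[row$level]] /
                   unclass(marg)[[row$consequence]],
                 tolerance = 1e-12)
  }
})

test_that("critical-factor selection is an argmax with stable ties", {
  inv <- data.frame(
    factor = c("population growth", "economic growth",
               "temperature increase"),
    level = "High", consequence = "High",
    probability = c(0.4184, 0.608, 0.1976), stringsAsFactors = FALSE)
  fwd <- inv  # content irrelevant for selection
  tab <- new_conditional_risk_table(fwd, inv)
  got <- select_critical_factor(tab)
  expect_equal(as.character(got), "economic growth")
  expect_equal(attr(got, "probability"), 0.608)

  tie <- inv; tie$probability <- c(0.5, 0.5, 0.2)
  expect_message(
    got2 <- select_critical_factor(new_conditional_risk_table(fwd, tie)),
    "tie")
  expect_equal(as.character(got2), "population growth")
  expect_equal(attr(got2, "ties"),
               c("population growth", "economic growth"))

  # random tables equal a linear max scan
  for (seed in 1:10) {
    set.seed(seed)
    inv$probability <- runif(3)
    tab <- new_conditional_risk_table(fwd, inv)
    expect_equal(as.character(select_critical_factor(tab)),
                 inv$factor[which.max(inv$probability)])
  }
})

test_that("degenerate and invalid conditionals raise errors", {
  f <- list(level_distribution("f", c(High = 1, Medium = 0, Low = 0)))
  tree <- event_tree(f, data.frame(f = c("High", "Medium", "Low"),
                                   consequence = c("High", "Medium",
                                                   "Low")))
  expect_error(conditional_consequence_given_factor(tree, "f", "Low"),
               "undefined")
  expect_error(conditional_consequence_given_factor(tree, "g", "High"),
               "unknown factor")
  # unmapped tuple: map missing a row
  bad <- event_tree(f, data.frame(f = c("High", "Medium"),
                                  consequence = c("High", "Medium")))
  expect_error(enumerate_paths(bad), "no unique row")
})
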