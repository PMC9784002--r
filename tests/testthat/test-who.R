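test_that("the two-level map is a bijection on the 8 corner triples", {
  grid <- expand.grid(n = c("High", "Low"), u = c("High", "Low"),
                      r = c("High", "Low"), stringsAsFactors = FALSE)
  types <- who_type_2level(grid$n, grid$u, grid$r)
  expect_setequal(types, LETTERS[1:8])
  expect_equal(who_type_2level("High", "High", "High"), "A")
  expect_equal(who_type_2level("Low", "Low", "Low"), "H")
  expect_error(who_type_2level("Medium", "High", "High"), "invalid grade")
})

test_that("the three-level map is total and restricts to the two-level map", {
  g3 <- c("Low", "Medium", "High")
  grid <- expand.grid(n = g3, u = g3, r = g3, stringsAsFactors = FALSE)
  types <- who_type_3level(grid$n, grid$u, grid$r)
  expect_equal(length(types), 27)
  expect_true(all(types %in% LETTERS[1:8]))
  # all-Medium is the balanced centre cell
  expect_equal(who_type_3level("Medium", "Medium", "Medium"), "A")
  # on Low/High corners the 27-cell map agrees with the WHO 2x2x2 table
  corner <- grid$n != "Medium" & grid$u != "Medium" & grid$r != "Medium"
  expect_equal(types[corner],
               who_type_2level(grid$n[corner], grid$u[corner], grid$r[corner]))
  expect_error(who_type_3level("Medium", "Middling", "High"), "invalid grade")
})

test_that("types group into the five policy categories", {
  expect_equal(who_category(c("A", "H", "F")), rep("relative_balance", 3))
  expect_equal(who_category("B"), "low_input")
  expect_equal(who_category("D"), "resource_shortage")
  expect_equal(who_category("E"), "overutilization")
  expect_equal(who_category(c("C", "G")), rep("resource_waste", 2))
  # total on A..H
  expect_true(all(who_category(LETTERS[1:8]) %in% policy_categories()))
  expect_error(who_category("Z"), "unknown WHO type")
})

test_that("classification joins per-dimension grades and conserves counts", {
  units <- paste0("u", 1:6)
  needs <- setNames(rep("Medium", 6), units)
  util <- setNames(c("High", "Medium", "Low", "Medium", "Medium", "Medium"), units)
  res <- setNames(c("Medium", "Medium", "Medium", "High", "Low", "Medium"), units)
  cls <- classify_regions(needs, util, res)
  expect_equal(sum(category_counts(cls)), 6)
  expect_equal(cls$type[cls$unit == "u6"], "A")  # all Medium
  expect_equal(cls$type[cls$unit == "u1"], "F")  # Medium needs, High util
  # all-Medium everywhere: everyone balanced
  all_med <- classify_regions(needs, needs, needs)
  expect_equal(unname(category_counts(all_med)["relative_balance"]), 6L)
  # mismatched unit sets are rejected
  expect_error(classify_regions(needs, util[-1], res), "unit sets differ")
})

test_that("pipeline grade triples map to the published example types", {
  ev09 <- rsr_evaluate(2009)
  bj <- ev09$classification[ev09$classification$unit == "Beijing", ]
  expect_equal(unname(unlist(bj[, c("needs", "utilization", "resources")])),
               c("Low", "High", "High"))
  expect_equal(bj$type, "E")
  expect_equal(bj$category, "overutilization")
  ev19 <- rsr_evaluate(2019)
  tj <- ev19$classification[ev19$classification$unit == "Tianjin", ]
  expect_equal(tj$type, "B")
  expect_equal(tj$category, "low_input")
})

test_that("transitions are conservative and counted descriptively", {
  ev09 <- rsr_evaluate(2009)$classification
  ev19 <- rsr_evaluate(2019)$classification
  tr <- transitions(ev09, ev19)
  expect_equal(rowSums(tr$matrix), category_counts(ev09),
               ignore_attr = TRUE)
  expect_equal(colSums(tr$matrix), category_counts(ev19),
               ignore_attr = TRUE)
  expect_equal(sum(tr$matrix), 31)

  # identical inputs: diagonal matrix, no moves
  tr0 <- transitions(ev09, ev09)
  expect_equal(nrow(tr0$moves), 0)
  expect_equal(sum(tr0$matrix) - sum(diag(tr0$matrix)), 0)
  expect_equal(tr0$into_balance, 0)

  # a single flipped category shows as exactly one off-diagonal entry
  mod <- ev09
  i <- which(mod$category == "low_input")[1]
  mod$category[i] <- "relative_balance"
  tr1 <- transitions(ev09, mod)
  expect_equal(sum(tr1$matrix) - sum(diag(tr1$matrix)), 1)
  expect_equal(tr1$into_balance, 1)
  expect_error(transitions(ev09, ev19[-3, ]), "unit sets differ")
})
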