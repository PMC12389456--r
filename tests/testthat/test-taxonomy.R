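tax <- load_taxonomy()

test_that("packaged taxonomy has the 22 signed groups with their item counts", {
  expect_s3_class(tax, "hpds_taxonomy")
  expect_equal(nrow(tax$groups), 22L)
  expect_equal(sum(tax$groups$direction == 1L), 11L)
  expect_equal(sum(tax$groups$direction == -1L), 11L)
  counts <- setNames(tax$groups$n_items, tax$groups$group_id)
  expect_equal(counts[["wholegrains"]], 14L)
  expect_equal(counts[["fruits"]], 20L)
  expect_equal(counts[["nonstarchy_vegetables"]], 26L)
  expect_false(anyDuplicated(tax$items$item_id) > 0)
  expect_true(all(tax$groups$serve_size_g > 0))
})

test_that("an item listed in two groups is a structural error naming both", {
  bad <- list(
    list(group_id = "a", direction = 1, serve_size_g = 10,
         items = list("Potatoes", "Carrots")),
    list(group_id = "b", direction = -1, serve_size_g = 10,
         items = list("Potatoes"))
  )
  err <- expect_error(toy_taxonomy(bad), class = "hpds_structural_error")
  expect_match(conditionMessage(err), "potatoes")
  expect_match(conditionMessage(err), "a")
  expect_match(conditionMessage(err), "b")
})

test_that("group count and direction balance are enforced for the full score", {
  small <- list(list(group_id = "a", direction = 1, serve_size_g = 10,
                     items = list("X")))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(groups = small), path)
  expect_error(load_taxonomy(path), class = "hpds_taxonomy_error")
  expect_s3_class(load_taxonomy(path, check_group_count = FALSE),
                  "hpds_taxonomy")
})

test_that("a single recall aggregates to grams/week with a factor of 7", {
  recalls <- data.frame(
    participant_id = "p1", recall_index = 1L,
    item_id = c("porridge", "apple"), amount_g = c(30, 80)
  )
  m <- aggregate_group_intake(recalls, tax)
  expect_equal(unname(m["p1", "wholegrains"]), 210)
  expect_equal(unname(m["p1", "fruits"]), 560)
  expect_equal(sum(m["p1", ]), 770)  # every other group zero
})

test_that("the earliest-recall policy ignores later occasions", {
  recalls <- data.frame(
    participant_id = "p1", recall_index = c(1L, 2L),
    item_id = "apple", amount_g = c(80, 9999)
  )
  m <- aggregate_group_intake(recalls, tax, recall_policy = "earliest")
  expect_equal(unname(m["p1", "fruits"]), 560)
  # a participant whose first occasion is 3 still contributes that occasion
  recalls2 <- data.frame(participant_id = "p2", recall_index = 3L,
                         item_id = "apple", amount_g = 40)
  m2 <- aggregate_group_intake(recalls2, tax)
  expect_equal(unname(m2["p2", "fruits"]), 280)
})

test_that("mean-of-first-k matches a hand-computed toy table", {
  # 3 participants, 2 items, occasions 1..3; k = 2 so occasion 3 is unused.
  recalls <- data.frame(
    participant_id = c("a", "a", "a", "a", "b", "b", "c"),
    recall_index   = c(1L,  1L,  2L,  3L,  1L,  2L,  2L),
    item_id        = c("apple", "porridge", "apple", "apple", "apple", "apple", "porridge"),
    amount_g       = c(100, 50, 60, 999, 30, 50, 20)
  )
  m <- aggregate_group_intake(recalls, tax, recall_policy = "mean_of_first_k", k = 2)
  # a: fruits (7*100 + 7*60)/2 = 560; wholegrains (7*50 + 0)/2 = 175
  expect_equal(unname(m["a", "fruits"]), 560)
  expect_equal(unname(m["a", "wholegrains"]), 175)
  # b: two occasions of apple -> 7*(30+50)/2 = 280
  expect_equal(unname(m["b", "fruits"]), 280)
  # c: only occasion 2 available -> 7*20
  expect_equal(unname(m["c", "wholegrains"]), 140)
})

test_that("unmapped items error; ignored items change nothing", {
  recalls <- data.frame(participant_id = "p1", recall_index = 1L,
                        item_id = c("apple", "unknown_item"), amount_g = c(80, 10))
  err <- expect_error(aggregate_group_intake(recalls, tax),
                      class = "hpds_mapping_error")
  expect_match(conditionMessage(err), "unknown_item")

  base <- aggregate_group_intake(
    data.frame(participant_id = "p1", recall_index = 1L,
               item_id = "apple", amount_g = 80), tax)
  with_ignored <- aggregate_group_intake(
    data.frame(participant_id = "p1", recall_index = 1L,
               item_id = c("apple", "red_wine", "salted_nuts"),
               amount_g = c(80, 200, 30)), tax)
  expect_equal(unclass(with_ignored), unclass(base))
})

test_that("aggregation conserves mass and is row-order invariant", {
  set.seed(5)
  sim <- simulate_cohort(sim_config(n = 40, seed = 5), tax)
  recalls <- sim$recalls
  m <- aggregate_group_intake(recalls, tax)
  # conservation: weekly total per participant = 7 x mapped grams used
  used <- recalls[recalls$recall_index == 1, ]
  totals <- tapply(used$amount_g, used$participant_id, sum)
  expect_equal(rowSums(m)[names(totals)], 7 * totals,
               tolerance = 1e-10, ignore_attr = TRUE)
  # permutation invariance
  shuffled <- recalls[sample(nrow(recalls)), ]
  expect_equal(unclass(aggregate_group_intake(shuffled, tax)), unclass(m))
})

test_that("recall validation rejects negatives and duplicate keys", {
  expect_error(validate_recalls(
    data.frame(participant_id = "p", recall_index = 1L,
               item_id = "apple", amount_g = -1)),
    class = "hpds_recall_error")
  expect_error(validate_recalls(
    data.frame(participant_id = "p", recall_index = 1L,
               item_id = c("apple", "apple"), amount_g = c(1, 2))),
    class = "hpds_recall_error")
})
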