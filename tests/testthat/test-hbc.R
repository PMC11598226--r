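test_that("truth-table scan matches the brute-force oracle on every 6-bit word", {
  tab <- posture_truth_table()
  for (w in all_64_words())
    expect_identical(classify_by_table(w, tab), oracle_classify(w), info = w)
})

test_that("table scan handles don't-cares and non-matching words", {
  expect_identical(classify_by_table("011111"), "SP")
  expect_identical(classify_by_table("111100"), "FP")
  expect_identical(classify_by_table("101101"), "UNKNOWN")
})

test_that("ambiguous truth tables are rejected", {
  expect_error(posture_truth_table(c(A = "111111", B = "1111XX")),
               class = "somno_config_error")
  expect_error(posture_truth_table(c(A = "11110")), class = "somno_config_error")
})

test_that("compiled tree has the expected leg-pair leaves", {
  tree <- build_tree()
  expect_identical(tree$branches[["00"]]$label, "FP")
  expect_identical(tree$branches[["11"]]$label, "SP")
  expect_identical(tree$branches[["01"]]$fetal, "LF")
  expect_identical(tree$branches[["10"]]$fetal, "RF")
})

test_that("worked bit patterns classify to their postures", {
  tree <- build_tree()
  expect_identical(classify("111101", tree), "LF")
  expect_identical(classify("010101", tree), "LLP")
  expect_identical(classify("111010", tree), "LY")
})

test_that("early-exit vs strict mode differ exactly off the table", {
  tree <- build_tree()
  # legs 00 exits to frog even though the full frog pattern is 111100
  expect_identical(classify("000000", tree, strict = FALSE), "FP")
  expect_identical(classify("000000", tree, strict = TRUE), "UNKNOWN")
})

test_that("tree agrees with the table oracle on all matching words, in both modes", {
  tree <- build_tree()
  words <- matching_words()
  expect_length(words, 11L)
  for (i in seq_along(words)) {
    expect_identical(classify(words[[i]], tree, strict = FALSE), names(words)[i])
    expect_identical(classify(words[[i]], tree, strict = TRUE), names(words)[i])
    expect_identical(classify_by_table(words[[i]]), names(words)[i])
  }
})

test_that("early-exit classification is total and deterministic over all 64 words", {
  tree <- build_tree()
  lab1 <- vapply(all_64_words(), classify, character(1), tree = tree)
  lab2 <- vapply(all_64_words(), classify, character(1), tree = tree)
  expect_true(all(lab1 %in% names(TABLE_ROWS)))
  expect_identical(lab1, lab2)
})

test_that("strict mode returns UNKNOWN on every word off the table", {
  tree <- build_tree()
  off <- setdiff(all_64_words(), unname(matching_words()))
  expect_length(off, 53L)
  for (w in off)
    expect_identical(classify(w, tree, strict = TRUE), "UNKNOWN", info = w)
})

test_that("unoccupied words are UNKNOWN with an unoccupied reason", {
  tree <- build_tree()
  w <- fusion_word("111101", pir = 0)
  res <- classify(w, tree)
  expect_identical(as.character(res), "UNKNOWN")
  expect_identical(attr(res, "reason"), "unoccupied")
})

test_that("fusion words validate their bits", {
  expect_error(fusion_word("10101"), class = "somno_data_error")
  expect_error(fusion_word(c(1, 0, 2, 1, 0, 1)), class = "somno_data_error")
  expect_identical(word_string(fusion_word(c(0, 1, 0, 1, 0, 1))), "010101")
})
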