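test_that("three identical pushes make the FIFO stable, anything else not", {
  f <- match_fifo()
  r <- push_and_check_stable(f, "110101")
  expect_false(r$stable)
  r <- push_and_check_stable(r$fifo, "110101")
  expect_false(r$stable)
  r <- push_and_check_stable(r$fifo, "110101")
  expect_true(r$stable)
  # a differing third word breaks stability
  r <- list(fifo = match_fifo())
  for (w in c("110101", "110101", "111010"))
    r <- push_and_check_stable(r$fifo, w)
  expect_false(r$stable)
  # the FIFO slides: three equal words after a differing one become stable
  r <- push_and_check_stable(r$fifo, "111010")
  r <- push_and_check_stable(r$fifo, "111010")
  expect_true(r$stable)
  expect_error(push_and_check_stable(match_fifo(), fusion_word("110101", pir = 0)),
               class = "somno_data_error")
})

test_that("generic learning stores table words under their label and is idempotent", {
  p <- subject_profile("s1", now = 0)
  p <- register_posture(p, "110101")
  expect_identical(p$learned[["RY"]], "110101")
  p2 <- register_posture(p, "110101")
  expect_identical(p2, p)
  # re-learning a label overwrites its pattern (supine expansion example)
  p <- register_posture(p, "001111")
  p <- register_posture(p, "111111")
  expect_identical(p$learned[["SP"]], "111111")
  expect_length(p$adaptive, 0L)
})

test_that("novel words fill adaptive slots lowest-first, bounded at eight", {
  p <- subject_profile("s2", now = 0)
  p <- register_posture(p, "100110")  # no table row matches
  expect_identical(oracle_classify("100110"), "UNKNOWN")
  expect_identical(p$adaptive[["New_1"]], "100110")
  # same pattern again is not duplicated
  p <- register_posture(p, "100110")
  expect_length(p$adaptive, 1L)
  novel <- setdiff(all_64_words(), unname(matching_words()))
  for (w in novel[2:8]) p <- register_posture(p, w)
  expect_identical(names(p$adaptive), paste0("New_", 1:8))
  expect_error(register_posture(p, novel[9]), class = "somno_capacity_error")
  expect_error(register_posture(p, novel[9]), regexp = "s2")
})

test_that("the store evicts the least-recently-used subject at capacity", {
  st <- profile_store()
  for (i in 1:8)
    st <- match_or_create_subject(st, paste0("subj", i), now = i)$store
  expect_length(st$subjects, 8L)
  # refresh subj1 so subj2 is now the oldest
  st <- match_or_create_subject(st, "subj1", now = 100)$store
  st <- match_or_create_subject(st, "subj9", now = 101)$store
  expect_length(st$subjects, 8L)
  expect_false("subj2" %in% names(st$subjects))
  expect_true(all(c("subj1", "subj9") %in% names(st$subjects)))
})

test_that("capacity bounds hold under randomized operation sequences", {
  set.seed(5)
  st <- profile_store()
  novel <- setdiff(all_64_words(), unname(matching_words()))
  for (i in 1:200) {
    id <- paste0("s", sample(12, 1))
    res <- match_or_create_subject(st, id, now = i)
    st <- res$store
    prof <- res$profile
    w <- sample(all_64_words(), 1)
    prof <- tryCatch(register_posture(prof, w),
                     somno_capacity_error = function(e) prof)
    st$subjects[[id]] <- prof
    expect_lte(length(st$subjects), 8L)
    for (p in st$subjects) {
      expect_lte(length(p$adaptive), 8L)
      expect_lte(length(p$learned), 8L)
      expect_true(all(names(p$adaptive) %in% paste0("New_", 1:8)))
    }
  }
})

test_that("a zero-noise stream of each posture learns the exact table pattern", {
  for (lab in STANDARD_POSTURES) {
    st <- generate_stream(one_segment_scenario(lab, dur = 2))
    res <- learn_words(fuse_stream(st), subject_profile("rt", now = 0))
    expected <- chartr("X", "1", TABLE_ROWS[[lab]])  # head present under don't-cares
    expect_identical(res$profile$learned[[lab]], expected)
    expect_gt(res$n_stable, 0L)
  }
})

test_that("the profile store persists losslessly as JSON", {
  st <- profile_store()
  res <- match_or_create_subject(st, "alice", now = 1700000000)
  prof <- register_posture(res$profile, "110101")
  prof <- register_posture(prof, "100110")
  st <- res$store
  st$subjects[["alice"]] <- prof
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_store(st, path)
  back <- read_profile_store(path)
  expect_identical(back$subjects$alice$learned, prof$learned)
  expect_identical(back$subjects$alice$adaptive, prof$adaptive)
  expect_equal(back$subjects$alice$last_used, prof$last_used, tolerance = 1e-3)
})

test_that("the Hamming heuristic finds the closest stored pattern", {
  st <- profile_store()
  res <- match_or_create_subject(st, "a", now = 1)
  st <- res$store
  st$subjects$a <- register_posture(res$profile, "110101")
  res <- match_or_create_subject(st, "b", now = 2)
  st <- res$store
  st$subjects$b <- register_posture(res$profile, "111010")
  hit <- best_match_subject(st, "110111")  # one bit from RY
  expect_identical(hit$subject_id, "a")
  expect_identical(hit$label, "RY")
  expect_identical(hit$distance, 1L)
})
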