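period <- 1 / 6

test_that("a constant stream yields one segment and no transition", {
  ev <- evaluate_labels(rep("LY", 60))
  expect_identical(ev$kind, "SEGMENT")
  expect_identical(ev$label, "LY")
  expect_equal(ev$duration, 10, tolerance = period)
  expect_equal(ev$start, 0)
})

test_that("an UNKNOWN gap becomes the transition duration", {
  ev <- evaluate_labels(c(rep("LY", 60), rep("UNKNOWN", 30), rep("RY", 60)))
  expect_identical(ev$kind, c("SEGMENT", "TRANSITION", "SEGMENT"))
  tr <- ev[ev$kind == "TRANSITION", ]
  expect_identical(tr$from, "LY")
  expect_identical(tr$to, "RY")
  expect_equal(tr$duration, 30 * period, tolerance = period)
})

test_that("label runs shorter than the debounce threshold emit nothing", {
  ev <- evaluate_labels(c(rep("LY", 60), "RY", rep("LY", 60)), count_step1 = 3)
  expect_false(any(ev$label %in% "RY", na.rm = TRUE))
  expect_false(any(ev$to %in% "RY", na.rm = TRUE))
  expect_identical(nrow(ev[ev$kind == "SEGMENT", ]), 1L)
  # two-frame flicker still below the threshold
  ev2 <- evaluate_labels(c(rep("LY", 10), "RY", "RY", rep("LY", 10)),
                         count_step1 = 3)
  expect_identical(unique(ev2$label[ev2$kind == "SEGMENT"]), "LY")
})

test_that("count_step1 = 1 degenerates to edge detection", {
  ev <- evaluate_labels(c(rep("SP", 5), rep("FP", 5), rep("SP", 5)),
                        count_step1 = 1)
  expect_identical(ev$label[ev$kind == "SEGMENT"], c("SP", "FP", "SP"))
  expect_identical(sum(ev$kind == "TRANSITION"), 2L)
  expect_true(all(abs(ev$duration[ev$kind == "TRANSITION"]) < 1e-9))
})

test_that("pose period differences are signed subtraction", {
  expect_equal(pose_period_difference(10, 10), 0)
  expect_equal(pose_period_difference(21.44, 10), 11.44)
  expect_equal(pose_period_difference(5, 10), -5)
})

test_that("finalize closes the open segment and nothing else", {
  st <- eval_state()
  for (i in 0:9) st <- eval_step(st, "SP", i * period)$state
  ev <- eval_finalize(st, t_end = 30)
  expect_identical(ev$label, "SP")
  expect_equal(ev$start, 0)
  expect_equal(ev$end, 30)
  expect_identical(nrow(eval_finalize(eval_state())), 0L)
})

test_that("two segments produce exactly two SEGMENTs and one TRANSITION", {
  ev <- evaluate_labels(c(rep("SP", 30), rep("FP", 30)))
  expect_identical(sum(ev$kind == "SEGMENT"), 2L)
  expect_identical(sum(ev$kind == "TRANSITION"), 1L)
})

test_that("non-increasing timestamps are rejected", {
  st <- eval_step(eval_state(), "SP", 1)$state
  expect_error(eval_step(st, "SP", 1), class = "somno_data_error")
  expect_error(eval_step(st, "SP", 0.5), class = "somno_data_error")
})

test_that("durations conserve the occupied span on randomized streams", {
  set.seed(21)
  labs_pool <- c("SP", "FP", "LY", "RY", "UNKNOWN")
  for (rep in 1:10) {
    runs <- sample(3:25, 8, replace = TRUE)
    labels <- unlist(mapply(rep, sample(labs_pool, 8, replace = TRUE), runs))
    ev <- evaluate_labels(labels, count_step1 = 3)
    if (nrow(ev) == 0) next
    span <- max(ev$end) - min(ev$start)
    total <- sum(ev$duration)
    # one sample period of slack per boundary between events
    expect_lte(abs(total - span), (nrow(ev) + 1) * (1 / 6) + 1e-9)
    expect_true(all(ev$end >= ev$start))
    expect_equal(ev$duration, ev$end - ev$start)
  }
})

test_that("clock-tick parity matches the 100 MHz device clock", {
  expect_equal(clock_ticks(1), 100e6)
  expect_equal(clock_ticks(370e-9), 37)
})
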