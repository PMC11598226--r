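test_that("posture_to_distances applies the bit-to-distance rule", {
  d <- posture_to_distances("LLP")
  expect_equal(unname(d), c(2.4, 2.15, 2.4, 2.15, 2.4, 2.15))
  expect_equal(unname(posture_to_distances("OFF_BED")), rep(2.4, 6))
  # supine don't-care head bits are emitted as present (head is on the bed)
  expect_equal(unname(posture_to_distances("SP")), rep(2.15, 6))
  expect_error(posture_to_distances("HEADSTAND"), class = "somno_config_error")
})

test_that("echo time inverts the range equation", {
  expect_equal(echo_from_distance(0), 0)
  expect_equal(echo_from_distance(1.7, speed = 340), 0.01)
  expect_error(echo_from_distance(1, speed = 0), class = "somno_config_error")
  d <- c(0, 0.3, 1.234, 2.7)
  expect_equal(tof_to_distance(echo_from_distance(d)), d)
})

test_that("stream covers the schedule at the sample period", {
  expect_equal(nrow(generate_stream(one_segment_scenario("SP"))), 60L)
  empty <- scenario(data.frame(label = character(0), start = numeric(0),
                               end = numeric(0)))
  expect_equal(nrow(generate_stream(empty)), 0L)
})

test_that("identical scenario and seed give bit-identical streams", {
  sc <- random_scenario(5, seed = 42)
  expect_identical(generate_stream(sc), generate_stream(sc))
  sc2 <- random_scenario(5, seed = 43)
  expect_false(identical(generate_stream(sc), generate_stream(sc2)))
})

test_that("zero-noise streams fuse back to each posture's table word", {
  for (lab in STANDARD_POSTURES) {
    st <- generate_stream(one_segment_scenario(lab, dur = 2))
    words <- unique(fuse_stream(st)$word)
    expect_length(words, 1L)
    expect_true(oracle_match(words, TABLE_ROWS[[lab]]),
                info = sprintf("%s fused to %s", lab, words))
    expect_identical(oracle_classify(words), lab)
  }
})

test_that("PIR follows occupancy and UNDEFINED emits the all-zeros pattern", {
  sc <- scenario(data.frame(label = c("OFF_BED", "UNDEFINED", "SP"),
                            start = c(0, 2, 4), end = c(2, 4, 6)),
                 noise_sd = 0)
  f <- fuse_stream(generate_stream(sc))
  expect_true(all(f$pir[f$t < 2] == 0))
  expect_true(all(f$word[f$t >= 2 & f$t < 4] == "000000"))
  expect_true(all(f$pir[f$t >= 2] == 1))
})

test_that("invalid schedules are rejected", {
  expect_error(scenario(data.frame(label = "SP", start = 5, end = 3)),
               class = "somno_config_error")
  expect_error(scenario(data.frame(label = c("SP", "FP"), start = c(0, 3),
                                   end = c(5, 8))),
               class = "somno_config_error")
  expect_error(scenario(data.frame(label = "NAP", start = 0, end = 1)),
               class = "somno_config_error")
})

test_that("scenario files round-trip through YAML and JSON", {
  sc <- random_scenario(4, seed = 9, noise_sd = 0.01)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_scenario(sc, path)
    back <- read_scenario(path)
    expect_equal(back$schedule, sc$schedule)
    expect_equal(back$noise_sd, sc$noise_sd)
    expect_equal(back$sample_period, sc$sample_period)
    expect_identical(generate_stream(back), generate_stream(sc))
  }
})
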