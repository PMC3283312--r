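test_that("the one-sided worked example reproduces the published event trace", {
  st <- table1_state()
  # final sequence: zeros at -5..2 and 4..7 on the -7..8 window
  expect_equal(st$g, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1))
  ev <- st$events
  expect_equal(ev$realized, c(3, 1, 4, 4))
  expect_equal(ev$deleted_positions[[4]], c(-5, -3, -2, 2) + 7)
  runs <- extract_runs(st)
  single <- runs[runs$kind == "single_copy", ]
  expect_equal(single$length, c(8, 4))
  expect_equal(single$r, c(3, 1))
  expect_silent(validate_genome_state(st))
})

test_that("the two-sided worked example truncates event 4 at a single-copy gene", {
  st <- table2_state()
  ev <- st$events[4, ]
  expect_equal(ev$requested, 4L)
  expect_equal(ev$realized, 3L)
  expect_equal(ev$truncated, "single_copy")
  expect_equal(ev$deleted_positions[[1]], c(-5, -3, -2) + 7)
  runs <- extract_runs(st)
  single <- runs[runs$kind == "single_copy", ]
  expect_equal(single$length, c(7, 4))
  expect_equal(single$r, c(3, 1))
  expect_silent(validate_genome_state(st))
})

test_that("event preconditions and boundary truncation are enforced", {
  st <- new_genome_state(100, "one_sided")
  st1 <- apply_one_sided_event(st, 10, 1)
  expect_equal(which(st1$g == 0L) - 1L, 10)
  expect_error(apply_one_sided_event(st1, 10, 1), "already deleted")
  expect_error(apply_one_sided_event(st, 10, 0), ">= 1")
  # an event reaching the boundary with budget remaining is flagged
  st2 <- apply_one_sided_event(st, 98, 5)
  expect_equal(st2$events$realized, 2L)
  expect_equal(st2$events$truncated, "boundary")
  expect_equal(st2$events$deleted_positions[[1]], c(98, 99))
  # two-sided: deletion stops before a single-copy position
  tw <- new_genome_state(100, "two_sided")
  tw <- apply_two_sided_event(tw, "H", 5, 1)       # h(5) = 0
  tw <- apply_two_sided_event(tw, "G", 3, 10)
  expect_equal(tw$events$realized[2], 2L)
  expect_equal(tw$events$deleted_positions[[2]], c(3, 4))
  expect_equal(tw$events$truncated[2], "single_copy")
  expect_error(apply_two_sided_event(tw, "G", 3, 1), "not duplicated")
  # untruncated interior deletion
  tw2 <- apply_two_sided_event(new_genome_state(100, "two_sided"), "G", 0, 3)
  expect_equal(tw2$events$deleted_positions[[1]], 0:2)
  expect_equal(tw2$events$truncated, "none")
})

test_that("simulations are deterministic under a seed and stop at theta_target = 1 untouched", {
  s1 <- simulate_fractionation(N = 5000, mu = 3, theta_target = 0.4, seed = 9)
  s2 <- simulate_fractionation(N = 5000, mu = 3, theta_target = 0.4, seed = 9)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$g, s2$g)
  s3 <- simulate_fractionation(N = 5000, mu = 3, theta_target = 0.4, seed = 10)
  expect_false(identical(s1$events, s3$events))
  s0 <- simulate_fractionation(N = 1000, mu = 2, theta_target = 1, seed = 1)
  expect_equal(nrow(s0$events), 0L)
  expect_equal(state_theta(s0), 1)
})

test_that("the C++ event log replays identically through the R appliers", {
  for (model in c("one_sided", "two_sided")) {
    st <- simulate_fractionation(N = 1500, mu = 2.5, theta_target = 0.45,
                                 model = model, seed = 31)
    rp <- replay_log(st)
    expect_identical(rp$g, st$g)
    expect_identical(rp$h, st$h)
    expect_equal(rp$events$realized, st$events$realized)
    expect_equal(rp$events$truncated, st$events$truncated)
    expect_identical(rp$events$deleted_positions, st$events$deleted_positions)
    if (model == "one_sided")
      expect_equal(rp$events$type, st$events$type)
  }
})

test_that("no locus ever loses both copies and the log accounts for every zero", {
  for (seed in 1:5) {
    st <- simulate_fractionation(N = 3000, mu = 4, theta_target = 0.25,
                                 model = "two_sided", seed = seed)
    expect_true(all(st$g + st$h >= 1L))
    expect_silent(validate_genome_state(st))
  }
  st1 <- simulate_fractionation(N = 3000, mu = 4, theta_target = 0.25,
                                model = "one_sided", seed = 77)
  expect_equal(sum(st1$events$realized), sum(st1$g == 0L))
  expect_silent(validate_genome_state(st1))
})

test_that("achieved theta lands at the target with at most one event of overshoot", {
  st <- simulate_fractionation(N = 50000, mu = 6, theta_target = 0.5, seed = 4)
  th <- attr(st, "theta_achieved")
  expect_lte(th, 0.5)
  expect_gt(th, 0.5 - 10 * 6 / 50000)  # overshoot bounded by one event
  expect_equal(th, state_theta(st))
})

test_that("state round-trips through TSV serialization", {
  st <- simulate_fractionation(N = 400, mu = 2, theta_target = 0.6,
                               model = "two_sided", seed = 12)
  prefix <- file.path(withr::local_tempdir(), "sim")
  write_genome_state(st, prefix, comment = c(seed = 12))
  st2 <- read_genome_state(prefix)
  expect_identical(st2$g, st$g)
  expect_identical(st2$h, st$h)
  expect_equal(st2$events$deleted_positions, st$events$deleted_positions)
  expect_equal(st2$events$anchor, st$events$anchor)
})
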