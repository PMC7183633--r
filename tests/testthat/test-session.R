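enr_t <- "2026-01-05 08:00"

test_that("enrollment issues 8-digit ids, allocates, and expands schedules", {
  p <- build_fixture("rct_waitlist")
  st <- enroll(p, enr_t, master_seed = 42, horizon_days = 30L)
  expect_match(st$participant_id, "^[0-9]{8}$")
  expect_true(st$condition %in% p$conditions)
  expect_gt(nrow(st$occurrences), 0)
  # deterministic given (protocol, seed, key)
  st2 <- enroll(p, enr_t, master_seed = 42, horizon_days = 30L)
  expect_identical(st$participant_id, st2$participant_id)
  expect_identical(st$condition, st2$condition)
  expect_identical(st$occurrences, st2$occurrences)
  # distinct keys give (almost surely) distinct ids; collisions redraw
  st3 <- enroll(p, enr_t, master_seed = 42, participant_key = 2L,
                taken_ids = st$participant_id)
  expect_false(st3$participant_id == st$participant_id)
})

test_that("a sticky baseline module is open immediately at enrollment", {
  st <- enroll(build_fixture("static"), enr_t, 1, horizon_days = 7L)
  hr <- home_refresh(st, enr_t)
  expect_true("diary" %in% hr$tasks$module_id)
  expect_true(all(hr$tasks$status == "open"))
})

test_that("home refresh caps pending notifications at the rolling window", {
  p <- daily_modules_protocol(5, duration_days = 365L)
  st <- enroll(p, enr_t, 7, horizon_days = 365L)
  hr <- home_refresh(st, enr_t)
  expect_equal(nrow(hr$pending), 30)
  # idempotent at a fixed instant
  hr2 <- home_refresh(hr$state, enr_t)
  expect_identical(hr$pending, hr2$pending)
  expect_identical(hr$tasks, hr2$tasks)
})

test_that("opening draws a fresh render plan per access", {
  st <- enroll(build_fixture("mrt"), enr_t, 3, horizon_days = 14L)
  picks <- character(0)
  for (i in 1:30) {
    op <- open_module(st, "support", enr_t)
    st <- op$state
    picks <- c(picks, op$instance$plan$group_choice$arm)
  }
  expect_setequal(unique(picks), c("arm_control", "arm_active"))
})

test_that("submission enforces required elements and timeout windows", {
  st <- enroll(build_fixture("ema"), enr_t, 5, horizon_days = 7L)
  occ <- st$occurrences[1, ]
  t_open <- occ$alert_time + minutes(5)
  op <- open_module(st, "prompt", t_open)
  # required slider missing
  expect_error(submit(op$state, op$instance, list(alone = TRUE), t_open),
               "required element\\(s\\) unanswered: mood")
  # in-window submission succeeds
  res <- submit(op$state, op$instance, list(mood = 4, alone = TRUE), t_open)
  expect_equal(res$record$responses$mood, 4)
  expect_equal(res$record$alert_time, fmt_iso(occ$alert_time))
  expect_equal(res$record$response_time, fmt_iso(t_open))
  # late submission of an instance opened in time is rejected
  st2 <- enroll(build_fixture("ema"), enr_t, 6, horizon_days = 7L)
  occ2 <- st2$occurrences[1, ]
  op2 <- open_module(st2, "prompt", occ2$alert_time + minutes(5))
  late <- occ2$close_time + minutes(1)
  expect_error(submit(op2$state, op2$instance, list(mood = 2, alone = FALSE),
                      late), "timed out")
  # opening after expiry is unavailable
  expect_error(open_module(st2, "prompt", occ2$close_time + minutes(31)),
               "not open")
})

test_that("non-sticky occurrences disappear after response; sticky repeat", {
  p <- build_fixture("static")
  st <- enroll(p, enr_t, 9, horizon_days = 7L)
  for (i in 1:2) {
    op <- open_module(st, "diary", enr_t)
    res <- submit(op$state, op$instance, list(wb = 5 + i), enr_t)
    st <- res$state
  }
  expect_equal(unname(st$completions["diary"]), 2L)     # repeatable
  expect_true("diary" %in% home_refresh(st, enr_t)$tasks$module_id)

  st2 <- enroll(build_fixture("cross_sectional"), enr_t, 9, horizon_days = 3L)
  t1 <- parse_dt("2026-01-05 10:05")
  op <- open_module(st2, "survey", t1)
  res <- submit(op$state, op$instance,
                list(age = 30, health = 6, smoker = FALSE), t1)
  expect_false("survey" %in% home_refresh(res$state, t1)$tasks$module_id)
  expect_error(open_module(res$state, "survey", t1), "not open")
})

test_that("hidden and non-input elements never reach the submitted record", {
  st <- enroll(build_fixture("jitai"), enr_t, 11, horizon_days = 14L)
  occ <- st$occurrences[1, ]
  t1 <- occ$alert_time + minutes(2)
  op <- open_module(st, "checkin", t1)
  # high mood: intervention hidden; a stray answer to it is dropped
  res <- submit(op$state, op$instance, list(mood = 7, tip = "x"), t1)
  expect_named(res$record$responses, "mood")
})

test_that("offline submissions queue and flush preserves FIFO and timestamps", {
  sink <- memory_sink()
  st <- enroll(build_fixture("static"), enr_t, 13, horizon_days = 7L)
  t <- parse_dt(enr_t)
  for (i in 1:3) {
    op <- open_module(st, "diary", t + minutes(i))
    res <- submit(op$state, op$instance, list(wb = i), t + minutes(i),
                  network_up = FALSE, sink = sink)
    st <- res$state
  }
  expect_length(st$queue, 3)
  expect_length(st$uploaded, 0)
  expect_length(sink$records, 0)
  # network restored: FIFO drain, response_time preserved
  fl <- flush_queue(st, sink, network_up = TRUE)
  expect_equal(fl$n_uploaded, 3L)
  expect_length(fl$state$queue, 0)
  got <- vapply(sink$records, function(r) r$responses$wb, numeric(1))
  expect_equal(got, c(1, 2, 3))
  expect_equal(sink$records[[1]]$response_time,
               fmt_iso(t + minutes(1)))
  # network down flushes nothing
  expect_equal(flush_queue(fl$state, sink, network_up = FALSE)$n_uploaded, 0L)
})

test_that("a sink failing mid-flush loses nothing and duplicates nothing", {
  sink <- faulty_sink(fail_after = 2)
  st <- enroll(build_fixture("static"), enr_t, 17, horizon_days = 7L)
  t <- parse_dt(enr_t)
  for (i in 1:3) {
    op <- open_module(st, "diary", t)
    res <- submit(op$state, op$instance, list(wb = i), t,
                  network_up = FALSE, sink = sink)
    st <- res$state
  }
  fl <- flush_queue(st, sink, network_up = TRUE)
  expect_equal(fl$n_uploaded, 2L)
  expect_length(fl$state$queue, 1)
  expect_length(fl$state$uploaded, 2)
  # retry after recovery: the remaining record goes once, no re-delivery
  sink$remaining <- 10
  fl2 <- flush_queue(fl$state, sink, network_up = TRUE)
  expect_equal(fl2$n_uploaded, 1L)
  vals <- vapply(sink$records, function(r) r$responses$wb, numeric(1))
  expect_equal(vals, c(1, 2, 3))
  # conservation throughout: completed = queued + uploaded
  expect_equal(sum(fl2$state$completions),
               length(fl2$state$queue) + length(fl2$state$uploaded))
})

test_that("withdrawal deletes the queue, keeps uploads, closes the study", {
  sink <- memory_sink()
  st <- enroll(build_fixture("static"), enr_t, 19, horizon_days = 7L)
  t <- parse_dt(enr_t)
  for (i in 1:5) {
    op <- open_module(st, "diary", t)
    res <- submit(op$state, op$instance, list(wb = i), t,
                  network_up = i <= 3, sink = sink)   # last 2 offline
    st <- res$state
  }
  expect_length(st$uploaded, 3)
  expect_length(st$queue, 2)
  st <- withdraw(st)
  expect_true(st$withdrawn)
  expect_length(st$queue, 0)              # unsent responses deleted
  expect_length(st$uploaded, 3)           # uploaded records untouched
  expect_false(any(st$occurrences$status %in% c("open", "future")))
  # terminal state: all session operations rejected; withdrawal idempotent
  expect_error(home_refresh(st, t), "withdrawn")
  expect_error(open_module(st, "diary", t), "withdrawn")
  expect_identical(withdraw(st)$uploaded, st$uploaded)
})

test_that("identical seeds and event scripts yield byte-identical records", {
  run_once <- function() {
    sink <- memory_sink()
    st <- enroll(build_fixture("ema"), enr_t, 23, horizon_days = 7L)
    t1 <- st$occurrences$alert_time[1] + minutes(3)
    op <- open_module(st, "prompt", t1)
    res <- submit(op$state, op$instance, list(mood = 5, alone = FALSE), t1,
                  sink = sink)
    vapply(sink$records, function(r) {
      as.character(jsonlite::toJSON(unclass(r), auto_unbox = TRUE,
                                    digits = NA))
    }, character(1))
  }
  expect_identical(run_once(), run_once())
})
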