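enr <- parse_dt("2026-01-05 08:00")

test_that("interval schedules expand one occurrence per day and clock time", {
  sp <- interval_schedule(times = "09:00", duration_days = 3L)
  occ <- expand_schedule(sp, "m1", enr, 30L)
  expect_equal(nrow(occ), 3)
  expect_equal(fmt_iso(occ$anchor_time),
               c("2026-01-05T09:00:00", "2026-01-06T09:00:00",
                 "2026-01-07T09:00:00"))
  expect_equal(occ$alert_time, occ$anchor_time)
  expect_true(all(is.na(occ$close_time)))
  expect_equal(occ$occurrence_index, 0:2)

  # several clock times per day, sorted by anchor
  sp2 <- interval_schedule(times = c("21:00", "09:00"), duration_days = 2L)
  occ2 <- expand_schedule(sp2, "m1", enr, 30L)
  expect_equal(nrow(occ2), 4)
  expect_false(is.unsorted(occ2$anchor_time))
})

test_that("zero-width jitter is byte-identical to no jitter", {
  sp_plain <- interval_schedule(duration_days = 5L)
  sp_rand0 <- interval_schedule(duration_days = 5L, random = TRUE,
                                random_offset_minutes = 0L)
  a <- expand_schedule(sp_plain, "m1", enr, 30L, rng_stream(11))
  b <- expand_schedule(sp_rand0, "m1", enr, 30L, rng_stream(11))
  b$random <- NULL
  expect_identical(a$alert_time, b$alert_time)
  expect_identical(fmt_iso(a$anchor_time), fmt_iso(b$anchor_time))
})

test_that("a fixed (sticky) module is open from the day prior to enrollment", {
  sp <- interval_schedule(times = character(0), sticky = TRUE,
                          start_offset_days = -1L)
  occ <- expand_schedule(sp, "m1", enr, 30L)
  expect_equal(nrow(occ), 1)
  expect_equal(fmt_iso(occ$anchor_time), "2026-01-04T00:00:00")
  expect_equal(occ$status, "open")
  expect_false(occ$has_alert)
  # earlier offsets floor at the day prior
  sp2 <- interval_schedule(times = character(0), sticky = TRUE,
                           start_offset_days = -10L)
  expect_equal(fmt_iso(expand_schedule(sp2, "m1", enr, 30L)$anchor_time),
               "2026-01-04T00:00:00")
})

test_that("jitter offsets are uniform on [-m, +m] minutes", {
  sp <- interval_schedule(times = "12:00", duration_days = 1L,
                          random = TRUE, random_offset_minutes = 60L)
  rng <- rng_stream(2024)
  offsets <- replicate(10000, {
    occ <- expand_schedule(sp, "m1", enr, 30L, rng)
    as.numeric(difftime(occ$alert_time, occ$anchor_time, units = "mins"))
  })
  expect_true(all(abs(offsets) <= 60))
  expect_true(all(offsets == round(offsets)))
  # KS against the continuous envelope of the discrete uniform
  ks <- suppressWarnings(stats::ks.test(offsets + stats::runif(10000) - 0.5,
                                        "punif", -60.5, 60.5))
  expect_gt(ks$p.value, 0.01)
  expect_gt(max(offsets), 30)   # both tails reached
  expect_lt(min(offsets), -30)
})

test_that("jitter is frozen per expansion and reproducible by seed", {
  sp <- interval_schedule(duration_days = 10L, random = TRUE,
                          random_offset_minutes = 45L)
  a <- expand_schedule(sp, "m1", enr, 30L, rng_stream(5))
  b <- expand_schedule(sp, "m1", enr, 30L, rng_stream(5))
  c <- expand_schedule(sp, "m1", enr, 30L, rng_stream(6))
  expect_identical(a, b)
  expect_false(identical(a$alert_time, c$alert_time))
})

test_that("horizon truncation warns and drops only late occurrences", {
  sp <- interval_schedule(duration_days = 10L)
  expect_warning(occ <- expand_schedule(sp, "m1", enr, 4L), "truncated")
  expect_equal(nrow(occ), 4)
  # monotonicity: growing the duration never removes earlier occurrences
  o3 <- expand_schedule(interval_schedule(duration_days = 3L), "m1", enr, 30L)
  o7 <- expand_schedule(interval_schedule(duration_days = 7L), "m1", enr, 30L)
  expect_identical(o7$anchor_time[1:3], o3$anchor_time)
})

test_that("the pending set is the 30 earliest future alerts", {
  p <- daily_modules_protocol(5, duration_days = 365L)
  occ <- expand_protocol(p, "all", enr, 365L)
  expect_equal(nrow(occ), 5 * 365)
  pending <- refresh_pending(occ, enr)
  expect_equal(nrow(pending), 30)
  expect_false(is.unsorted(pending$alert_time))
  # below the cap the full set is returned
  few <- occ[occ$alert_time <= parse_dt("2026-01-05 23:59"), ]
  expect_equal(nrow(refresh_pending(few, enr)), 5)
  # cap is configurable
  expect_equal(nrow(refresh_pending(occ, enr, cap = 7L)), 7)
})

test_that("simultaneous alerts tie-break by module document order", {
  p <- daily_modules_protocol(31, duration_days = 1L)  # 31-way tie at 09:00
  occ <- expand_protocol(p, "all", enr, 30L)
  pending <- refresh_pending(occ, enr)
  expect_equal(nrow(pending), 30)
  expect_equal(pending$module_id, paste0("m", 1:30))  # m31 loses the tie
})

test_that("status transitions follow alert, timeout and response rules", {
  sp <- interval_schedule(times = "09:00", duration_days = 1L,
                          timeout = TRUE, timeout_minutes = 30L)
  occ <- expand_schedule(sp, "m1", enr, 30L)
  expect_equal(fmt_iso(occ$close_time), "2026-01-05T09:30:00")
  expect_equal(update_status(occ, parse_dt("2026-01-05 08:59"))$status, "future")
  expect_equal(update_status(occ, parse_dt("2026-01-05 09:15"))$status, "open")
  expect_equal(update_status(occ, parse_dt("2026-01-05 09:31"))$status, "expired")
  done <- update_status(occ, parse_dt("2026-01-05 09:15"), responded = TRUE)
  expect_equal(done$status, "completed")
  # a completed occurrence never later expires
  expect_equal(update_status(done, parse_dt("2026-01-05 10:00"))$status,
               "completed")
  # a non-timeout open occurrence stays open indefinitely
  plain <- expand_schedule(interval_schedule(duration_days = 1L), "m1", enr, 30L)
  expect_equal(update_status(plain, parse_dt("2027-06-01 00:00"))$status, "open")
  # sticky occurrences never leave open
  st <- expand_schedule(interval_schedule(times = character(0), sticky = TRUE),
                        "m1", enr, 30L)
  expect_equal(update_status(st, enr + 1e6, responded = TRUE)$status, "open")
})

test_that("the task list shows open occurrences with elapsed-minute labels", {
  p <- daily_modules_protocol(2, duration_days = 1L)
  occ <- expand_protocol(p, "all", enr, 30L)
  now <- parse_dt("2026-01-05 09:21")
  occ <- update_status(occ, now)
  tl <- task_list(occ, now)
  expect_equal(nrow(tl), 2)
  expect_equal(tl$elapsed, c("21 minutes ago", "21 minutes ago"))
  # asc and desc are exact reverses
  expect_equal(task_list(occ, now, "desc")$module_id,
               rev(tl$module_id))
  # expired occurrences are absent
  sp <- interval_schedule(times = "09:00", duration_days = 1L,
                          timeout = TRUE, timeout_minutes = 5L)
  lapsed <- update_status(expand_schedule(sp, "late", enr, 30L), now)
  expect_equal(nrow(task_list(lapsed, now)), 0)
})

test_that("no occurrence is ever both completed and expired", {
  sp <- interval_schedule(duration_days = 30L, timeout = TRUE,
                          timeout_minutes = 10L)
  occ <- expand_schedule(sp, "m1", enr, 30L)
  occ$status[3] <- "completed"
  for (h in c(0, 5, 50, 5000)) {
    upd <- update_status(occ, enr + minutes(h * 60))
    expect_false(any(upd$status == "completed" & upd$status == "expired"))
    expect_equal(upd$status[3], "completed")
  }
})
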