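# Shared builders and oracles for the suite. Fixtures are constructed in
# code; nothing here touches the network or the wall clock.

minimal_protocol_json <- function(element = NULL) {
  el <- element %||% '{"id":"e1","type":"instruction","text":"Welcome"}'
  sprintf('{
    "study_id": "mini", "study_name": "Minimal",
    "support_email": "a@b.c", "post_url": "https://x/post.php",
    "conditions": ["all"],
    "modules": [{
      "id": "m1", "type": "survey", "name": "Entry",
      "schedule": {"sticky": true},
      "sections": [{"name": "s", "elements": [%s]}]
    }]
  }', el)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# protocol with `k` interval modules, one daily alert each, for testing the
# rolling notification window
daily_modules_protocol <- function(k, duration_days = 365L,
                                   times = "09:00") {
  mods <- lapply(seq_len(k), function(i) {
    list(id = paste0("m", i), module_type = "survey",
         name = paste("Daily", i), condition = "*",
         schedule = list(times = times, start_offset_days = 0L,
                         duration_days = as.integer(duration_days),
                         random = FALSE, random_offset_minutes = 0L,
                         sticky = FALSE, timeout = FALSE,
                         timeout_minutes = 0L,
                         alert_title = paste("Daily", i),
                         alert_message = "ready"),
         graph = NULL, shuffle_sections = FALSE,
         sections = list(list(name = "s", shuffle = FALSE, elements = list(
           list(id = paste0("q", i), etype = "yesno", text = "ok?",
                required = FALSE, rand_group = NULL, hide_id = NULL,
                hide_value = NULL, hide_if_matched = NULL)))))
  })
  structure(list(study_id = "daily", study_name = "Daily",
                 instructions = "", banner_url = "", support_email = "",
                 support_url = "", ethics_statement = "", post_url = "",
                 cache_media = FALSE, conditions = "all", modules = mods),
            class = "study_protocol")
}

# single-module protocol wrapping an arbitrary schedule/section list
wrap_module <- function(schedule, sections, conditions = "all",
                        shuffle_sections = FALSE, graph = NULL) {
  structure(list(study_id = "wrap", study_name = "Wrap",
                 instructions = "", banner_url = "", support_email = "",
                 support_url = "", ethics_statement = "", post_url = "",
                 cache_media = FALSE, conditions = conditions,
                 modules = list(list(id = "m1", module_type = "survey",
                                     name = "Wrapped", condition = "*",
                                     schedule = schedule, graph = graph,
                                     shuffle_sections = shuffle_sections,
                                     sections = sections))),
            class = "study_protocol")
}

interval_schedule <- function(times = "09:00", start_offset_days = 0L,
                              duration_days = 3L, random = FALSE,
                              random_offset_minutes = 0L, sticky = FALSE,
                              timeout = FALSE, timeout_minutes = 0L) {
  if (sticky) { duration_days <- 1L; timeout <- FALSE; timeout_minutes <- 0L }
  list(times = times, start_offset_days = as.integer(start_offset_days),
       duration_days = as.integer(duration_days), random = random,
       random_offset_minutes = as.integer(random_offset_minutes),
       sticky = sticky, timeout = timeout,
       timeout_minutes = as.integer(timeout_minutes),
       alert_title = "t", alert_message = "m")
}

mk_element <- function(id, etype, required = FALSE, rand_group = NULL,
                       hide_id = NULL, hide_value = NULL,
                       hide_if_matched = FALSE, ...) {
  c(list(id = id, etype = etype, text = id, required = required,
         rand_group = rand_group, hide_id = hide_id,
         hide_value = hide_value,
         hide_if_matched = if (is.null(hide_id)) NULL else hide_if_matched),
    list(...))
}

mk_section <- function(elements, shuffle = FALSE, name = "s") {
  list(name = name, shuffle = shuffle, elements = elements)
}

yesno_el <- function(id, ...) mk_element(id, "yesno", ...)
slider_el2 <- function(id, min = 0L, max = 10L, ...) {
  mk_element(id, "slider", min = as.integer(min), max = as.integer(max),
             hint_left = "", hint_right = "", ...)
}

# Independent visibility oracle: recursive recomputation from scratch,
# structurally different from the engine's forward document-order pass.
oracle_visibility <- function(m, responses, plan) {
  els <- module_elements(m)
  ids <- vapply(els, `[[`, character(1), "id")
  by_id <- stats::setNames(els, ids)
  vis_one <- function(id) {
    el <- by_id[[id]]
    if (id %in% plan$hidden_by_group) return(FALSE)
    if (is.null(el$hide_id)) return(TRUE)
    if (!vis_one(el$hide_id)) return(FALSE)
    mt <- branch_matches(by_id[[el$hide_id]], responses[[el$hide_id]],
                         el$hide_value)
    if (is.na(mt)) return(FALSE)
    if (isTRUE(el$hide_if_matched)) !mt else mt
  }
  stats::setNames(vapply(ids, vis_one, logical(1)), ids)
}

# validator pass over simulated records: every invariant a record must obey
check_records <- function(records, protocol) {
  for (rec in records) {
    expect_match(rec$user_id, "^[0-9]{8}$")
    rt <- parse_dt(rec$response_time); at <- parse_dt(rec$alert_time)
    expect_gte(as.numeric(rt - at), 0)
    m <- Find(function(x) x$id == rec$module_id, protocol$modules)
    expect_false(is.null(m))
    if (isTRUE(m$schedule$timeout)) {
      expect_lte(as.numeric(difftime(rt, at, units = "mins")),
                 m$schedule$timeout_minutes)
    }
    els <- module_elements(m)
    ids <- vapply(els, `[[`, character(1), "id")
    types <- stats::setNames(vapply(els, `[[`, character(1), "etype"), ids)
    for (eid in names(rec$responses)) {
      expect_true(eid %in% ids)
      expect_false(types[[eid]] %in% c("instruction", "media"))
    }
    expect_true(rec$condition %in% protocol$conditions)
    expect_true(rec$platform %in% c("android", "ios"))
  }
  invisible(TRUE)
}

random_branch_module <- function(n_el, rng) {
  # random dag of yes/no and slider elements; each non-root may reference
  # any earlier source with a random rule
  els <- list()
  for (i in seq_len(n_el)) {
    is_slider <- stream_runif(rng, 1) < 0.4
    id <- paste0("e", i)
    hide_id <- NULL; hide_value <- NULL; him <- FALSE
    if (i > 1 && stream_runif(rng, 1) < 0.75) {
      j <- stream_sample(rng, seq_len(i - 1), size = 1)
      hide_id <- paste0("e", j)
      src_slider <- attr(els[[j]], "is_slider")
      hide_value <- if (src_slider) {
        thr <- stream_sample(rng, 2:8, size = 1)
        stream_sample(rng, c(paste0(">", thr), paste0("<", thr), thr), size = 1)
      } else stream_sample(rng, c(TRUE, FALSE), size = 1)
      him <- stream_runif(rng, 1) < 0.5
    }
    e <- if (is_slider) {
      slider_el2(id, hide_id = hide_id, hide_value = hide_value,
                 hide_if_matched = him)
    } else {
      yesno_el(id, hide_id = hide_id, hide_value = hide_value,
               hide_if_matched = him)
    }
    attr(e, "is_slider") <- is_slider
    els[[i]] <- e
  }
  wrap_module(interval_schedule(sticky = TRUE),
              list(mk_section(els)))$modules[[1]]
}

response_domain <- function(el, m) {
  # unanswered plus a domain cover: yes/no exhaustively; sliders at their
  # bounds and at threshold +/- 1 for every rule that references them
  if (el$etype == "yesno") return(list(NULL, TRUE, FALSE))
  thrs <- numeric(0)
  for (d in module_elements(m)) {
    if (identical(d$hide_id, el$id)) {
      num <- suppressWarnings(as.numeric(gsub("[<>]", "",
                                              as.character(d$hide_value))))
      if (!is.na(num)) thrs <- c(thrs, num - 1, num, num + 1)
    }
  }
  vals <- unique(pmin(pmax(c(el$min, el$max, thrs), el$min), el$max))
  c(list(NULL), as.list(vals))
}

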