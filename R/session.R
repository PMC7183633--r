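#' @title Participant session runtime
#'
#' @description
#' Drives a participant's lifecycle — enrollment (identifier draw,
#' condition allocation, schedule expansion), home-screen refreshes,
#' opening and submitting module instances, offline queueing of completed
#' responses with at-least-once upload, and withdrawal. Functions are
#' functional: each returns the updated state (alongside any value), never
#' mutating its argument.
#'
#' @name session
NULL

#' Response sinks
#'
#' The upload endpoint is abstracted as a sink object with a
#' \code{deliver(record)} function; the engine never requires a network.
#' \code{memory_sink()} accumulates records in memory;
#' \code{file_sink(path)} appends one JSON object per line;
#' \code{faulty_sink(fail_after)} delivers \code{fail_after} records then
#' raises, for exercising mid-flush failure.
#'
#' @param path file to append JSON-Lines records to.
#' @param fail_after number of successful deliveries before failing.
#' @return a \code{response_sink} object; for \code{memory_sink}, its
#'   \code{records} field holds the delivered records.
#' @export
memory_sink <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  env$deliver <- function(rec) env$records[[length(env$records) + 1]] <- rec
  class(env) <- "response_sink"
  env
}

#' @rdname memory_sink
#' @export
file_sink <- function(path) {
  env <- new.env(parent = emptyenv())
  env$path <- path
  env$deliver <- function(rec) {
    con <- file(path, open = "a", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(record_json(rec), con)
  }
  class(env) <- "response_sink"
  env
}

#' @rdname memory_sink
#' @export
faulty_sink <- function(fail_after) {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  env$remaining <- fail_after
  env$deliver <- function(rec) {
    if (env$remaining <= 0) stop("sink unavailable")
    env$remaining <- env$remaining - 1
    env$records[[length(env$records) + 1]] <- rec
  }
  class(env) <- "response_sink"
  env
}

record_json <- function(rec) {
  jsonlite::toJSON(unclass(rec), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

draw_participant_id <- function(rng, taken = character(0)) {
  repeat {
    id <- paste(stream_sample(rng, 0:9, size = 8, replace = TRUE),
                collapse = "")
    if (!id %in% taken) return(id)   # unique within a run; redrawn on clash
  }
}

participant_streams <- function(study_id, key, master_seed) {
  mk <- function(purpose) {
    rng_stream(derive_seed(study_id, key, purpose, master_seed))
  }
  list(id = mk("id"), allocation = mk("allocation"), jitter = mk("jitter"),
       render = mk("render"), behavior = mk("behavior"))
}

#' Enroll a participant into a study
#'
#' Draws a fresh anonymous 8-decimal-digit participant identifier (leading
#' zeros allowed), allocates the condition uniformly, expands every
#' in-condition module schedule over the horizon, and computes the initial
#' pending-notification set. Seed streams are derived from
#' (study id, participant key, master seed) per purpose, so adding modules
#' or participants never perturbs another stream.
#'
#' @param p a validated \code{study_protocol}.
#' @param now enrollment instant (POSIXct or ISO string).
#' @param master_seed integer master seed.
#' @param platform \code{"android"} or \code{"ios"} (simulation metadata).
#' @param horizon_days expansion horizon in days.
#' @param participant_key index distinguishing participants under one
#'   master seed.
#' @param taken_ids identifiers already issued in this run (collisions are
#'   redrawn).
#' @return a \code{participant_state}.
#' @export
enroll <- function(p, now, master_seed, platform = c("android", "ios"),
                   horizon_days = 365L, participant_key = 1L,
                   taken_ids = character(0)) {
  platform <- match.arg(platform)
  if (is.character(now)) now <- parse_dt(now)
  streams <- participant_streams(p$study_id, participant_key, master_seed)
  pid <- draw_participant_id(streams$id, taken_ids)
  condition <- allocate_condition(p, streams$allocation)
  occs <- expand_protocol(p, condition, now, horizon_days, streams$jitter)
  occs <- update_statuses(occs, now)
  state <- structure(list(
    participant_id = pid,
    enrollment = now,
    condition = condition,
    protocol = p,
    platform = platform,
    horizon_days = horizon_days,
    streams = streams,
    occurrences = occs,
    completions = integer(0),   # named per module_id, counts submissions
    queue = list(),
    uploaded = list(),
    withdrawn = FALSE
  ), class = "participant_state")
  state
}

stop_if_withdrawn <- function(state) {
  if (state$withdrawn) {
    stop("participant ", state$participant_id,
         " has withdrawn: no further study activity is possible",
         call. = FALSE)
  }
}

#' Home-screen refresh
#'
#' Updates every occurrence status to \code{now}, recomputes the rolling
#' pending-notification set (capped) and the open task list. Idempotent at
#' a fixed instant.
#'
#' @param state a \code{participant_state}.
#' @param now current instant.
#' @param cap pending-notification cap.
#' @return list with the updated \code{state}, the open \code{tasks}
#'   data.frame, and the \code{pending} notification data.frame.
#' @export
home_refresh <- function(state, now, cap = NOTIFICATION_CAP) {
  stop_if_withdrawn(state)
  if (is.character(now)) now <- parse_dt(now)
  state$occurrences <- update_statuses(state$occurrences, now)
  list(state = state,
       tasks = task_list(state$occurrences, now),
       pending = refresh_pending(state$occurrences, now, cap))
}

#' Open a module instance
#'
#' Requires an open occurrence of the module at \code{now}. Every access
#' draws a fresh render plan (new shuffles and group choices) and
#' evaluates visibility against empty responses.
#'
#' @param state a \code{participant_state}.
#' @param module_id id of the module to open.
#' @param now current instant.
#' @return list with \code{state} and the rendered \code{instance}
#'   (module, occurrence row, plan, initial visibility).
#' @export
open_module <- function(state, module_id, now) {
  stop_if_withdrawn(state)
  if (is.character(now)) now <- parse_dt(now)
  state$occurrences <- update_statuses(state$occurrences, now)
  occs <- state$occurrences
  idx <- which(occs$module_id == module_id & occs$status == "open" &
               occs$alert_time <= now)
  if (length(idx) == 0) {
    stop("module '", module_id, "' is not open at ", fmt_iso(now),
         call. = FALSE)
  }
  idx <- idx[[1]]
  m <- Find(function(x) x$id == module_id, state$protocol$modules)
  plan <- make_render_plan(m, state$streams$render)
  instance <- list(module = m, occurrence = occs[idx, , drop = FALSE],
                   occurrence_row = idx, plan = plan,
                   visibility = evaluate_visibility(m, list(), plan),
                   opened_at = now)
  list(state = state, instance = instance)
}

build_record <- function(state, instance, responses, now) {
  m <- instance$module
  vis <- evaluate_visibility(m, responses, instance$plan)
  els <- module_elements(m)
  keep <- list()
  for (el in els) {
    v <- responses[[el$id]]
    if (is.null(v) || length(v) == 0) next
    if (!vis$visible[[el$id]]) next          # hidden answers never submitted
    if (el$etype %in% c("instruction", "media")) next  # no response value
    keep[[el$id]] <- v
  }
  structure(list(
    user_id = state$participant_id,
    module_id = m$id,
    module_name = m$name,
    module_index = instance$occurrence$occurrence_index,
    responses = keep,
    response_time = fmt_iso(now),
    alert_time = fmt_iso(instance$occurrence$alert_time),
    platform = state$platform,
    condition = state$condition
  ), class = "response_record")
}

#' Submit a completed module instance
#'
#' Rejects if any required visible element is unanswered (listing the
#' offending ids) or if the occurrence is no longer open — a timeout
#' occurrence cannot be submitted after its close time even if it was
#' opened before. On success the response record (answered visible
#' elements only; media and instructions contribute no value) is stamped
#' with the response and alert times, the occurrence is marked completed
#' (sticky occurrences stay open and repeatable), and the record joins the
#' offline queue; with the network up the queue is flushed immediately.
#'
#' @param state a \code{participant_state}.
#' @param instance rendered instance from \code{\link{open_module}}.
#' @param responses named list, element id -> value.
#' @param now submission instant.
#' @param network_up is a connection available?
#' @param sink the upload sink.
#' @return list with updated \code{state} and the \code{record}.
#' @export
submit <- function(state, instance, responses, now,
                   network_up = TRUE, sink = memory_sink()) {
  stop_if_withdrawn(state)
  if (is.character(now)) now <- parse_dt(now)
  occ <- instance$occurrence
  if (!occ$sticky && occ$timeout && !is.na(occ$close_time) &&
      now > occ$close_time) {
    stop("module '", occ$module_id, "' timed out at ",
         fmt_iso(occ$close_time), " and can no longer be submitted",
         call. = FALSE)
  }
  cur <- occurrence_status(state$occurrences[instance$occurrence_row, ], now)
  if (cur != "open") {
    stop("module '", occ$module_id, "' is not open (status: ", cur, ")",
         call. = FALSE)
  }
  vis <- evaluate_visibility(instance$module, responses, instance$plan)
  missing <- required_missing(instance$module, responses, vis)
  if (length(missing)) {
    stop("required element(s) unanswered: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  record <- build_record(state, instance, responses, now)
  i <- instance$occurrence_row
  if (!state$occurrences$sticky[i]) state$occurrences$status[i] <- "completed"
  mid <- occ$module_id
  prev <- if (mid %in% names(state$completions)) state$completions[[mid]] else 0L
  state$completions[mid] <- prev + 1L
  state$queue[[length(state$queue) + 1]] <- record
  if (network_up) {
    flushed <- flush_queue(state, sink, network_up = TRUE)
    state <- flushed$state
  }
  list(state = state, record = record)
}

#' Flush the offline response queue
#'
#' With the network up, queued records are delivered to the sink in FIFO
#' order and moved to the uploaded list. If the sink fails mid-flush,
#' already-delivered records stay uploaded and the remainder stays queued
#' (at-least-once, no loss, no duplication across retries). Response
#' timestamps are preserved through delayed flushes.
#'
#' @param state a \code{participant_state}.
#' @param sink a \code{response_sink}.
#' @param network_up is a connection available?
#' @return list with updated \code{state} and \code{n_uploaded}.
#' @export
flush_queue <- function(state, sink, network_up = TRUE) {
  if (!network_up || length(state$queue) == 0) {
    return(list(state = state, n_uploaded = 0L))
  }
  n <- 0L
  while (length(state$queue) > 0) {
    rec <- state$queue[[1]]
    ok <- tryCatch({ sink$deliver(rec); TRUE }, error = function(e) FALSE)
    if (!ok) break
    state$queue <- state$queue[-1]
    state$uploaded[[length(state$uploaded) + 1]] <- rec
    n <- n + 1L
  }
  list(state = state, n_uploaded = n)
}

#' Withdraw from the study
#'
#' Data collection stops: pending (not yet uploaded) responses are deleted
#' without delivery, already-uploaded records are untouched, and all open
#' or future occurrences are closed. Idempotent; any subsequent session
#' operation raises a terminal-state error.
#'
#' @param state a \code{participant_state}.
#' @return the withdrawn state.
#' @export
withdraw <- function(state) {
  state$withdrawn <- TRUE
  state$queue <- list()
  live <- state$occurrences$status %in% c("open", "future")
  state$occurrences$status[live] <- "expired"
  state
}

#' @export
print.participant_state <- function(x, ...) {
  cat(sprintf("<participant_state> id=%s condition=%s enrolled=%s%s\n",
              x$participant_id, x$condition, fmt_iso(x$enrollment),
              if (x$withdrawn) " [withdrawn]" else ""))
  tab <- table(x$occurrences$status)
  cat("  occurrences:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat(sprintf("  queue=%d uploaded=%d\n", length(x$queue), length(x$uploaded)))
  invisible(x)
}
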