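#' @title Notification scheduling
#'
#' @description
#' Expands each module's schedule into concrete availability occurrences
#' relative to the enrollment instant. Scheduling semantics:
#' \itemize{
#'  \item \emph{Fixed (sticky)}: a single occurrence, permanently available
#'    and repeatable; with \code{start_offset_days = -1} it is available from
#'    the day prior to enrollment.
#'  \item \emph{Interval}: one occurrence per (day, clock time) pair, for
#'    \code{duration_days} days starting \code{start_offset_days} after the
#'    enrollment date; occurrences remain open until responded.
#'  \item \emph{Random}: each alert time is jittered by an integer number of
#'    minutes drawn uniformly on \code{[-m, +m]} around the nominal time.
#'  \item \emph{Timeout}: an occurrence expires if unanswered
#'    \code{timeout_minutes} after its alert.
#'  \item \emph{Mixed}: random and timeout combine freely.
#' }
#' Day boundaries are local midnight; offsets count calendar days from the
#' enrollment date, not 24-hour blocks.
#'
#' @name scheduling
NULL

#' Rolling notification cap
#'
#' Mobile platforms limit how many local notifications an app may have
#' scheduled, so the engine maintains only the next
#' \code{NOTIFICATION_CAP} pending alerts, recomputed at every home-screen
#' refresh.
#' @export
NOTIFICATION_CAP <- 30L

empty_occurrences <- function() {
  data.frame(module_id = character(0), module_order = integer(0),
             occurrence_index = integer(0),
             anchor_time = parse_dt(character(0)),
             alert_time = parse_dt(character(0)),
             close_time = parse_dt(character(0)),
             has_alert = logical(0), sticky = logical(0),
             timeout = logical(0),
             alert_title = character(0), alert_message = character(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' Expand a module schedule into occurrences
#'
#' @param spec a schedule spec (from a parsed module).
#' @param module_id module identifier carried on each occurrence.
#' @param enrollment enrollment instant (POSIXct or ISO string).
#' @param horizon_days number of days after enrollment to expand; schedules
#'   longer than the horizon are truncated with a warning.
#' @param rng an \code{rng_stream}; consumed only when \code{random} with a
#'   positive jitter width. Jitter is frozen at expansion.
#' @param module_order document-order rank of the module (tie-break key).
#' @return data.frame of occurrences sorted by anchor time, one row per
#'   (day, clock time); statuses start \code{"future"} (\code{"open"} for
#'   sticky).
#' @export
expand_schedule <- function(spec, module_id, enrollment, horizon_days,
                            rng = rng_stream(0), module_order = 1L) {
  if (is.character(enrollment)) enrollment <- parse_dt(enrollment)

  if (spec$sticky) {
    day <- local_day(enrollment, max(spec$start_offset_days, -1L))
    anchor <- if (length(spec$times)) at_clock_time(day, spec$times[[1]]) else day
    occ <- data.frame(module_id = module_id, module_order = module_order,
                      occurrence_index = 0L,
                      anchor_time = anchor, alert_time = anchor,
                      close_time = as.POSIXct(NA, tz = "UTC"),
                      has_alert = length(spec$times) > 0, sticky = TRUE,
                      timeout = FALSE,
                      alert_title = spec$alert_title,
                      alert_message = spec$alert_message,
                      status = "open", stringsAsFactors = FALSE)
    return(occ)
  }

  days <- seq(spec$start_offset_days,
              length.out = max(spec$duration_days, 0L))
  in_horizon <- days < horizon_days
  if (any(!in_horizon)) {
    warning(sprintf("module '%s': schedule truncated at %d-day horizon",
                    module_id, horizon_days), call. = FALSE)
    days <- days[in_horizon]
  }
  grid <- expand.grid(time = spec$times, day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  if (n == 0) return(empty_occurrences())

  anchor <- as.POSIXct(vapply(seq_len(n), function(i) {
    at_clock_time(local_day(enrollment, grid$day[i]), grid$time[i])
  }, numeric(1)), tz = "UTC", origin = "1970-01-01")
  ord <- order(anchor)
  anchor <- anchor[ord]

  alert <- anchor
  if (spec$random && spec$random_offset_minutes > 0) {
    m <- spec$random_offset_minutes
    jit <- stream_sample(rng, seq.int(-m, m), size = n, replace = TRUE)
    alert <- anchor + minutes(jit)
  }
  close <- if (spec$timeout) alert + minutes(spec$timeout_minutes) else
    as.POSIXct(rep(NA_real_, n), tz = "UTC", origin = "1970-01-01")

  data.frame(module_id = module_id, module_order = module_order,
             occurrence_index = seq_len(n) - 1L,
             anchor_time = anchor, alert_time = alert, close_time = close,
             has_alert = TRUE, sticky = FALSE, timeout = spec$timeout,
             alert_title = spec$alert_title,
             alert_message = spec$alert_message,
             status = "future", stringsAsFactors = FALSE)
}

#' Expand every module of a protocol for one participant
#'
#' @param p a validated \code{study_protocol}.
#' @param condition the participant's allocated arm; only modules assigned
#'   to it (or to the wildcard \code{"*"}) are expanded.
#' @inheritParams expand_schedule
#' @param jitter_rng stream for schedule jitter.
#' @return combined occurrence data.frame.
#' @export
expand_protocol <- function(p, condition, enrollment, horizon_days,
                            jitter_rng = rng_stream(0)) {
  mods <- modules_for(p, condition)
  keep <- vapply(p$modules, function(m)
    m$condition == "*" || m$condition == condition, logical(1))
  orders <- which(keep)
  out <- lapply(seq_along(mods), function(i) {
    expand_schedule(mods[[i]]$schedule, mods[[i]]$id, enrollment,
                    horizon_days, jitter_rng, module_order = orders[i])
  })
  do.call(rbind, c(out, list(empty_occurrences())))
}

#' Update the status of a single occurrence
#'
#' Transitions run only forward along future -> open -> completed/expired.
#' An occurrence is \code{future} before its alert, \code{completed} once
#' responded (sticky occurrences stay \code{open} and can be completed
#' repeatedly), \code{expired} when a timeout window lapses unanswered, and
#' \code{open} otherwise — an open non-timeout occurrence remains open
#' indefinitely until responded.
#'
#' @param occ a one-row occurrence data.frame.
#' @param now current instant.
#' @param responded has the participant submitted this occurrence?
#' @return the occurrence with its status updated.
#' @export
update_status <- function(occ, now, responded = FALSE) {
  if (nrow(occ) > 1) {
    stopifnot(identical(responded, FALSE))
    return(update_statuses(occ, now))
  }
  occ$status <- occurrence_status(occ, now, responded)
  occ
}

occurrence_status <- function(occ, now, responded = FALSE) {
  if (occ$sticky) return("open")
  if (isTRUE(responded) || occ$status == "completed") return("completed")
  if (occ$status == "expired") return("expired")
  if (now < occ$alert_time) return("future")
  if (occ$timeout && !is.na(occ$close_time) && now > occ$close_time) {
    return("expired")
  }
  "open"
}

update_statuses <- function(occs, now) {
  if (nrow(occs) == 0) return(occs)
  st <- occs$status
  settled <- st %in% c("completed", "expired") | occs$sticky
  lapsed <- occs$timeout & !is.na(occs$close_time) & now > occs$close_time
  fresh <- ifelse(now < occs$alert_time, "future",
                  ifelse(lapsed, "expired", "open"))
  st[!settled] <- fresh[!settled]
  st[occs$sticky] <- "open"
  occs$status <- st
  occs
}

#' Recompute the pending-notification set
#'
#' Returns the earliest future alerts across all modules, capped at
#' \code{cap} (the rolling window recomputed at every home-screen access),
#' sorted ascending by alert time with ties broken by module document order
#' then occurrence index. Deterministic given the occurrence set.
#'
#' @param occurrences occurrence data.frame, statuses current as of
#'   \code{now}.
#' @param now current instant.
#' @param cap maximum pending alerts (default \code{NOTIFICATION_CAP}).
#' @return data.frame with module_id, alert_time, title, message.
#' @export
refresh_pending <- function(occurrences, now, cap = NOTIFICATION_CAP) {
  fut <- occurrences[occurrences$has_alert &
                     occurrences$status %in% c("future", "open") &
                     occurrences$alert_time > now, , drop = FALSE]
  ord <- order(fut$alert_time, fut$module_order, fut$occurrence_index)
  fut <- fut[ord, , drop = FALSE]
  fut <- utils::head(fut, cap)
  data.frame(module_id = fut$module_id, alert_time = fut$alert_time,
             title = fut$alert_title, message = fut$alert_message,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' The participant's task list
#'
#' Open occurrences only, annotated with the whole minutes elapsed since
#' each became available (e.g. \code{"21 minutes ago"}), sortable by
#' scheduled time earliest-to-latest or the reverse.
#'
#' @param occurrences occurrence data.frame with statuses updated to
#'   \code{now}.
#' @param now current instant.
#' @param sort_order \code{"asc"} or \code{"desc"}.
#' @return data.frame of open occurrences with an \code{elapsed} column.
#' @export
task_list <- function(occurrences, now, sort_order = c("asc", "desc")) {
  sort_order <- match.arg(sort_order)
  open <- occurrences[occurrences$status == "open" &
                      occurrences$alert_time <= now, , drop = FALSE]
  ord <- order(open$alert_time, open$module_order, open$occurrence_index)
  if (sort_order == "desc") ord <- rev(ord)
  open <- open[ord, , drop = FALSE]
  mins <- pmax(elapsed_minutes(open$alert_time, now), 0)
  open$elapsed <- sprintf("%d minute%s ago", mins, ifelse(mins == 1, "", "s"))
  row.names(open) <- NULL
  open
}
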