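#' @title Reference study designs
#'
#' @description
#' \code{build_fixture()} constructs a validated protocol embodying one of
#' six canonical mobile-health study designs, used throughout the test
#' suite and available as worked examples:
#' \describe{
#'  \item{static}{permanently available (sticky) information and survey
#'    modules; participants respond whenever and as often as they wish.}
#'  \item{cross_sectional}{a one-shot survey available on the enrollment
#'    day.}
#'  \item{ema}{ecological momentary assessment: six prompts per day for a
#'    week, each jittered randomly around its nominal time and expiring 30
#'    minutes after the alert.}
#'  \item{rct_waitlist}{a two-arm waitlist-controlled trial: baseline and
#'    follow-up surveys at fixed offsets in both arms, daily intervention
#'    content in the intervention arm only.}
#'  \item{jitai}{just-in-time adaptive intervention: a daily mood prompt
#'    whose low responses reveal intervention content via branching.}
#'  \item{mrt}{micro-randomised trial: a context prompt plus a
#'    permanently-available intervention module in which a randomisation
#'    group selects the control or the intervention element uniformly at
#'    every access.}
#' }
#'
#' @name fixtures
NULL

el <- function(id, etype, text = "", required = FALSE, ...) {
  base <- list(id = id, etype = etype, text = text, required = required,
               rand_group = NULL, hide_id = NULL, hide_value = NULL,
               hide_if_matched = NULL)
  extra <- list(...)
  base[names(extra)] <- extra
  base
}

slider_el <- function(id, text, min = 0L, max = 10L, required = TRUE, ...) {
  el(id, "slider", text, required, min = min, max = max,
     hint_left = "low", hint_right = "high", ...)
}

sec <- function(name, elements, shuffle = FALSE) {
  list(name = name, shuffle = shuffle, elements = elements)
}

sched <- function(times = character(0), start_offset_days = 0L,
                  duration_days = 1L, random = FALSE,
                  random_offset_minutes = 0L, sticky = FALSE,
                  timeout = FALSE, timeout_minutes = 0L,
                  alert_title = "Task available",
                  alert_message = "You have a new task") {
  list(times = times, start_offset_days = as.integer(start_offset_days),
       duration_days = as.integer(duration_days), random = random,
       random_offset_minutes = as.integer(random_offset_minutes),
       sticky = sticky, timeout = timeout,
       timeout_minutes = as.integer(timeout_minutes),
       alert_title = alert_title, alert_message = alert_message)
}

mod <- function(id, name, sections, schedule = sched(sticky = TRUE),
                module_type = "survey", condition = "*", graph = NULL,
                shuffle_sections = FALSE) {
  list(id = id, module_type = module_type, name = name,
       condition = condition, schedule = schedule, graph = graph,
       shuffle_sections = shuffle_sections, sections = sections)
}

proto <- function(study_id, study_name, modules,
                  conditions = "all") {
  structure(list(
    study_id = study_id, study_name = study_name,
    instructions = "<p>Thank you for taking part.</p>",
    banner_url = "https://example.org/banner.png",
    support_email = "study@example.org",
    support_url = "https://example.org",
    ethics_statement = "Approved by the example ethics board.",
    post_url = "https://example.org/post.php",
    cache_media = FALSE,
    conditions = conditions, modules = modules
  ), class = "study_protocol")
}

#' Build a reference study-design protocol
#'
#' @param design one of \code{"static"}, \code{"cross_sectional"},
#'   \code{"ema"}, \code{"rct_waitlist"}, \code{"jitai"}, \code{"mrt"}.
#' @return a validated \code{study_protocol} (zero diagnostics).
#' @examples
#' p <- build_fixture("ema")
#' nrow(validate_protocol(p))  # 0
#' @export
build_fixture <- function(design = c("static", "cross_sectional", "ema",
                                     "rct_waitlist", "jitai", "mrt")) {
  design <- match.arg(design)
  p <- switch(design,
    static = proto("static-demo", "Always-on wellbeing check", list(
      mod("about", "About this study",
          list(sec("About", list(el("a1", "instruction",
                                    "<b>Welcome</b> to the study.")))),
          module_type = "info", schedule = sched(sticky = TRUE)),
      mod("diary", "Wellbeing diary",
          list(sec("Diary", list(
            slider_el("wb", "How is your wellbeing right now?"),
            el("note", "text", "Anything to add?")))),
          schedule = sched(sticky = TRUE, start_offset_days = -1L),
          graph = list(display = TRUE, variable = "wb",
                       title = "Wellbeing", blurb = "Your recent ratings",
                       graph_type = "line", max_points = 10L))
    )),
    cross_sectional = proto("xsect-demo", "One-off community survey", list(
      mod("survey", "Community survey",
          list(sec("Demographics", list(
                 el("age", "number", "Your age", required = TRUE),
                 el("nick", "text", "A nickname"))),
               sec("Health", list(
                 slider_el("health", "Rate your overall health"),
                 el("smoker", "yesno", "Do you smoke?", required = TRUE)))),
          schedule = sched(times = "10:00", duration_days = 1L))
    )),
    ema = proto("ema-demo", "Momentary mood sampling", list(
      mod("prompt", "Mood check-in",
          list(sec("Now", list(
            slider_el("mood", "How is your mood right now?"),
            el("alone", "yesno", "Are you alone?")))),
          schedule = sched(times = c("09:00", "11:00", "13:00", "15:00",
                                     "17:00", "19:00"),
                           duration_days = 7L, random = TRUE,
                           random_offset_minutes = 30L, timeout = TRUE,
                           timeout_minutes = 30L,
                           alert_title = "Mood check-in",
                           alert_message = "How are you feeling?"),
          graph = list(display = TRUE, variable = "mood",
                       title = "Mood", blurb = "Your recent mood",
                       graph_type = "line", max_points = 10L))
    )),
    rct_waitlist = proto("rct-demo", "Waitlist-controlled trial", list(
      mod("baseline", "Baseline assessment",
          list(sec("Baseline", list(
            slider_el("k10", "Distress over the past week"),
            el("employed", "yesno", "Are you employed?", required = TRUE)))),
          schedule = sched(times = "09:00", duration_days = 1L)),
      mod("lesson", "Daily skill lesson",
          list(sec("Lesson", list(
            el("content", "instruction", "<p>Today's skill ...</p>"),
            el("useful", "yesno", "Was this useful?")))),
          condition = "intervention",
          schedule = sched(times = "18:00", start_offset_days = 1L,
                           duration_days = 7L)),
      mod("followup", "Follow-up assessment",
          list(sec("Follow-up", list(
            slider_el("k10_fu", "Distress over the past week")))),
          schedule = sched(times = "09:00", start_offset_days = 28L,
                           duration_days = 1L))
    ), conditions = c("intervention", "waitlist")),
    jitai = proto("jitai-demo", "Adaptive mood support", list(
      mod("checkin", "Mood check-in",
          list(sec("Check-in", list(
            slider_el("mood", "How is your mood right now?"),
            el("tip", "instruction",
               "<p>Try this 2-minute breathing exercise.</p>",
               hide_id = "mood", hide_value = "<4",
               hide_if_matched = FALSE),
            el("calm_video", "media", "A short relaxation video",
               subtype = "video", src = "https://example.org/calm.mp4",
               hide_id = "mood", hide_value = "<4",
               hide_if_matched = FALSE)))),
          schedule = sched(times = c("11:00", "16:00"), duration_days = 14L,
                           random = TRUE, random_offset_minutes = 60L))
    )),
    mrt = proto("mrt-demo", "Micro-randomised support prompts", list(
      mod("context", "Context check",
          list(sec("Context", list(
            slider_el("stress", "How stressed are you?"),
            el("busy", "yesno", "Are you busy right now?")))),
          schedule = sched(times = c("10:00", "14:00", "18:00"),
                           duration_days = 14L, random = TRUE,
                           random_offset_minutes = 45L, timeout = TRUE,
                           timeout_minutes = 45L)),
      mod("support", "Support moment",
          list(sec("Support", list(
            el("arm_control", "instruction",
               "<p>Take a short break.</p>", rand_group = "arm"),
            el("arm_active", "instruction",
               "<p>Try this guided exercise now.</p>", rand_group = "arm"),
            el("helpful", "yesno", "Was this helpful?")))),
          schedule = sched(sticky = TRUE))
    ))
  )
  p
}
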