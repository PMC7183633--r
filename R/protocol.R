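#' @title Study-protocol dialect: parsing and validation
#'
#' @description
#' A study protocol is a single JSON document describing study metadata, a
#' list of condition labels, and an ordered list of modules. Each module is
#' a scheduled task (survey, info, video or audio) composed of sections of
#' elements; elements carry ids, display text (a basic HTML subset, stored
#' verbatim and never interpreted), optional branching rules and optional
#' randomisation-group membership. The field names accepted here are the
#' canonical dialect for this engine; a machine-readable JSON-Schema copy
#' ships in \code{inst/extdata/protocol.schema.json}.
#'
#' @name protocol
NULL

MODULE_TYPES <- c("survey", "info", "video", "audio")
ELEMENT_TYPES <- c("instruction", "text", "number", "datetime", "slider",
                   "checkbox", "radio", "yesno", "media")
BRANCH_SOURCE_TYPES <- c("slider", "yesno", "checkbox", "radio")
GRAPH_TYPES <- c("bar", "line")
DATETIME_SUBTYPES <- c("date", "time", "datetime")
MEDIA_SUBTYPES <- c("image", "video", "audio")

KNOWN_KEYS <- list(
  protocol = c("study_id", "study_name", "instructions", "banner_url",
               "support_email", "support_url", "ethics_statement",
               "post_url", "cache_media", "conditions", "modules"),
  module = c("id", "type", "name", "condition", "schedule", "graph",
             "shuffle_sections", "sections"),
  schedule = c("times", "start_offset_days", "duration_days", "random",
               "random_offset_minutes", "sticky", "timeout",
               "timeout_minutes", "alert_title", "alert_message"),
  section = c("name", "shuffle", "elements"),
  element = c("id", "type", "text", "required", "rand_group", "hide_id",
              "hide_value", "hide_if_matched", "min", "max", "hint_left",
              "hint_right", "options", "subtype", "src", "thumb"),
  graph = c("display", "variable", "title", "blurb", "type", "max_points")
)

schema_error <- function(path, msg) {
  stop(structure(class = c("protocol_schema_error", "error", "condition"),
                 list(message = sprintf("%s: %s", path, msg), call = NULL)))
}

need_field <- function(obj, key, path) {
  if (is.null(obj[[key]])) schema_error(path, paste0("missing mandatory field '", key, "'"))
  obj[[key]]
}

as_scalar <- function(x, path, what = "value") {
  if (length(x) != 1 || is.list(x)) schema_error(path, paste(what, "must be a scalar"))
  x
}

get_str <- function(obj, key, path, default = NULL) {
  v <- obj[[key]]
  if (is.null(v)) {
    if (is.null(default)) schema_error(path, paste0("missing mandatory field '", key, "'"))
    return(default)
  }
  as.character(as_scalar(v, paste0(path, ".", key), "string"))
}

get_bool <- function(obj, key, path, default = FALSE) {
  v <- obj[[key]]
  if (is.null(v)) return(default)
  v <- as_scalar(v, paste0(path, ".", key), "boolean")
  if (!is.logical(v)) schema_error(paste0(path, ".", key), "must be true or false")
  v
}

get_int <- function(obj, key, path, default = NULL) {
  v <- obj[[key]]
  if (is.null(v)) {
    if (is.null(default)) schema_error(path, paste0("missing mandatory field '", key, "'"))
    return(default)
  }
  v <- as_scalar(v, paste0(path, ".", key), "integer")
  if (!is.numeric(v) || v != round(v)) {
    schema_error(paste0(path, ".", key), "must be an integer")
  }
  as.integer(v)
}

check_keys <- function(obj, kind, path, strict) {
  unknown <- setdiff(names(obj), KNOWN_KEYS[[kind]])
  if (length(unknown)) {
    msg <- sprintf("%s: unknown key(s) %s", path,
                   paste(sQuote(unknown, q = FALSE), collapse = ", "))
    if (strict) schema_error(path, paste("unknown key(s):",
                                         paste(unknown, collapse = ", ")))
    warning(msg, call. = FALSE)
  }
}

#' Parse a study-protocol JSON document
#'
#' Parses protocol text (or a file) into a typed tree with all defaults
#' applied: \code{required = FALSE}, \code{shuffle = FALSE},
#' \code{condition = "*"}, \code{cache_media = FALSE}. Parsing is pure —
#' identical text yields an identical tree with no clock or RNG access.
#'
#' @param json_text protocol document as a single string, or a file path.
#' @param strict reject unknown keys (default: warn).
#' @return An object of class \code{study_protocol}.
#' @examples
#' p <- parse_protocol('{"study_id":"s1","study_name":"Demo",
#'   "instructions":"<p>Hi</p>","banner_url":"","support_email":"a@b.c",
#'   "support_url":"","ethics_statement":"","post_url":"",
#'   "conditions":["control"],
#'   "modules":[{"id":"m1","type":"survey","name":"Entry",
#'     "schedule":{"sticky":true},
#'     "sections":[{"name":"s","elements":[
#'       {"id":"e1","type":"instruction","text":"Welcome"}]}]}]}')
#' p$study_id
#' @export
parse_protocol <- function(json_text, strict = FALSE) {
  if (length(json_text) == 1 && !grepl("[{[]", substr(json_text, 1, 1)) &&
      file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.list(doc)) schema_error("$", "protocol must be a JSON object")
  check_keys(doc, "protocol", "$", strict)

  conditions <- need_field(doc, "conditions", "$")
  conditions <- vapply(conditions, as.character, character(1),
                       USE.NAMES = FALSE)
  modules_raw <- need_field(doc, "modules", "$")
  modules <- lapply(seq_along(modules_raw), function(i) {
    parse_module(modules_raw[[i]], sprintf("modules[%d]", i - 1), strict)
  })

  p <- structure(list(
    study_id = get_str(doc, "study_id", "$"),
    study_name = get_str(doc, "study_name", "$"),
    instructions = get_str(doc, "instructions", "$", ""),
    banner_url = get_str(doc, "banner_url", "$", ""),
    support_email = get_str(doc, "support_email", "$", ""),
    support_url = get_str(doc, "support_url", "$", ""),
    ethics_statement = get_str(doc, "ethics_statement", "$", ""),
    post_url = get_str(doc, "post_url", "$", ""),
    cache_media = get_bool(doc, "cache_media", "$", FALSE),
    conditions = conditions,
    modules = modules
  ), class = "study_protocol")
  p
}

parse_module <- function(m, path, strict) {
  check_keys(m, "module", path, strict)
  mtype <- get_str(m, "type", path)
  if (!mtype %in% MODULE_TYPES) {
    schema_error(paste0(path, ".type"),
                 sprintf("unknown module type '%s' (expected %s)", mtype,
                         paste(MODULE_TYPES, collapse = "/")))
  }
  sections_raw <- need_field(m, "sections", path)
  sections <- lapply(seq_along(sections_raw), function(i) {
    parse_section(sections_raw[[i]], sprintf("%s.sections[%d]", path, i - 1),
                  strict)
  })
  graph <- NULL
  if (!is.null(m$graph)) {
    gp <- paste0(path, ".graph")
    check_keys(m$graph, "graph", gp, strict)
    gtype <- get_str(m$graph, "type", gp, "line")
    if (!gtype %in% GRAPH_TYPES) {
      schema_error(paste0(gp, ".type"), "graph type must be 'bar' or 'line'")
    }
    graph <- list(display = get_bool(m$graph, "display", gp, TRUE),
                  variable = get_str(m$graph, "variable", gp),
                  title = get_str(m$graph, "title", gp, ""),
                  blurb = get_str(m$graph, "blurb", gp, ""),
                  graph_type = gtype,
                  max_points = get_int(m$graph, "max_points", gp, 10L))
  }
  list(id = get_str(m, "id", path),
       module_type = mtype,
       name = get_str(m, "name", path),
       condition = get_str(m, "condition", path, "*"),
       schedule = parse_schedule(m$schedule %||% list(),
                                 paste0(path, ".schedule"), strict),
       graph = graph,
       shuffle_sections = get_bool(m, "shuffle_sections", path, FALSE),
       sections = sections)
}

parse_schedule <- function(s, path, strict) {
  check_keys(s, "schedule", path, strict)
  times <- s$times %||% list()
  times <- vapply(times, as.character, character(1), USE.NAMES = FALSE)
  bad <- !grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", times)
  if (any(bad)) {
    schema_error(paste0(path, ".times"),
                 sprintf("invalid clock time '%s' (expected HH:MM)", times[bad][1]))
  }
  list(times = times,
       start_offset_days = get_int(s, "start_offset_days", path, 0L),
       duration_days = get_int(s, "duration_days", path, 1L),
       random = get_bool(s, "random", path, FALSE),
       random_offset_minutes = get_int(s, "random_offset_minutes", path, 0L),
       sticky = get_bool(s, "sticky", path, FALSE),
       timeout = get_bool(s, "timeout", path, FALSE),
       timeout_minutes = get_int(s, "timeout_minutes", path, 0L),
       alert_title = get_str(s, "alert_title", path, ""),
       alert_message = get_str(s, "alert_message", path, ""))
}

parse_section <- function(s, path, strict) {
  check_keys(s, "section", path, strict)
  elements_raw <- need_field(s, "elements", path)
  elements <- lapply(seq_along(elements_raw), function(i) {
    parse_element(elements_raw[[i]], sprintf("%s.elements[%d]", path, i - 1),
                  strict)
  })
  list(name = get_str(s, "name", path, ""),
       shuffle = get_bool(s, "shuffle", path, FALSE),
       elements = elements)
}

parse_element <- function(e, path, strict) {
  check_keys(e, "element", path, strict)
  etype <- get_str(e, "type", path)
  if (!etype %in% ELEMENT_TYPES) {
    schema_error(paste0(path, ".type"),
                 sprintf("unknown element type '%s' (expected %s)", etype,
                         paste(ELEMENT_TYPES, collapse = "/")))
  }
  el <- list(id = get_str(e, "id", path),
             etype = etype,
             text = get_str(e, "text", path, ""),
             required = get_bool(e, "required", path, FALSE),
             rand_group = if (!is.null(e$rand_group)) get_str(e, "rand_group", path),
             hide_id = if (!is.null(e$hide_id)) get_str(e, "hide_id", path),
             hide_value = NULL, hide_if_matched = NULL)
  if (!is.null(el$hide_id)) {
    el$hide_value <- as_scalar(need_field(e, "hide_value", path),
                               paste0(path, ".hide_value"))
    el$hide_if_matched <- get_bool(e, "hide_if_matched", path, FALSE)
  } else if (!is.null(e$hide_value) || !is.null(e$hide_if_matched)) {
    schema_error(path, "hide_value/hide_if_matched present without hide_id")
  }
  if (etype == "slider") {
    el$min <- get_int(e, "min", path)
    el$max <- get_int(e, "max", path)
    el$hint_left <- get_str(e, "hint_left", path, "")
    el$hint_right <- get_str(e, "hint_right", path, "")
  } else if (etype %in% c("checkbox", "radio")) {
    opts <- need_field(e, "options", path)
    el$options <- vapply(opts, as.character, character(1),
                         USE.NAMES = FALSE)
    if (length(el$options) < 1) {
      schema_error(paste0(path, ".options"), "needs at least one option")
    }
  } else if (etype == "datetime") {
    sub <- get_str(e, "subtype", path, "datetime")
    if (!sub %in% DATETIME_SUBTYPES) {
      schema_error(paste0(path, ".subtype"), "must be date/time/datetime")
    }
    el$subtype <- sub
  } else if (etype == "media") {
    sub <- get_str(e, "subtype", path)
    if (!sub %in% MEDIA_SUBTYPES) {
      schema_error(paste0(path, ".subtype"), "must be image/video/audio")
    }
    el$subtype <- sub
    el$src <- get_str(e, "src", path)
    el$thumb <- if (!is.null(e$thumb)) get_str(e, "thumb", path)
  }
  el
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' List every element of a module in document order
#' @param module a module from a parsed protocol.
#' @return list of element specs, flattened across sections.
#' @export
module_elements <- function(module) {
  unlist(lapply(module$sections, `[[`, "elements"), recursive = FALSE)
}

diag_row <- function(severity, path, message) {
  data.frame(severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a parsed protocol
#'
#' Returns structural and referential diagnostics rather than raising:
#' unique ids, resolvable condition labels, graph variables and branching
#' sources, branching sources restricted to slider/yesno/checkbox/radio and
#' occurring earlier in document order, randomisation groups confined to a
#' single section with at least two members (a singleton group is a
#' warning: it is semantically a no-op), schedule consistency (jitter width
#' positive when random; sticky modules warn if duration/timeout set).
#'
#' @param p a \code{study_protocol}.
#' @return data.frame with columns severity ("error"/"warning"), path,
#'   message; zero rows iff the protocol is clean.
#' @export
validate_protocol <- function(p) {
  stopifnot(inherits(p, "study_protocol"))
  d <- list()
  add <- function(sev, path, msg) d[[length(d) + 1]] <<- diag_row(sev, path, msg)

  if (length(p$conditions) < 1) add("error", "$.conditions", "must be non-empty")
  if (anyDuplicated(p$conditions)) {
    add("error", "$.conditions", "condition labels must be unique")
  }
  mids <- vapply(p$modules, `[[`, character(1), "id")
  if (anyDuplicated(mids)) {
    add("error", "$.modules", sprintf("duplicate module id(s): %s",
        paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  }

  for (mi in seq_along(p$modules)) {
    m <- p$modules[[mi]]
    mp <- sprintf("modules[%d]", mi - 1)
    if (m$condition != "*" && !m$condition %in% p$conditions) {
      add("error", paste0(mp, ".condition"),
          sprintf("'%s' is not a declared condition", m$condition))
    }
    if (length(m$sections) == 0) add("error", paste0(mp, ".sections"), "must be non-empty")

    sch <- m$schedule
    sp <- paste0(mp, ".schedule")
    if (sch$random && sch$random_offset_minutes <= 0) {
      add("error", paste0(sp, ".random_offset_minutes"),
          "must be > 0 when random is true")
    }
    if (sch$timeout && sch$timeout_minutes <= 0) {
      add("error", paste0(sp, ".timeout_minutes"),
          "must be > 0 when timeout is true")
    }
    if (sch$sticky && (sch$timeout || sch$duration_days > 1)) {
      add("warning", sp, "duration_days/timeout are ignored for sticky modules")
    }
    if (!sch$sticky && length(sch$times) == 0) {
      add("error", paste0(sp, ".times"),
          "must be non-empty unless the module is sticky")
    }
    if (sch$duration_days < 0) {
      add("error", paste0(sp, ".duration_days"), "must be non-negative")
    }

    els <- module_elements(m)
    eids <- vapply(els, `[[`, character(1), "id")
    if (anyDuplicated(eids)) {
      add("error", mp, sprintf("duplicate element id(s): %s",
          paste(unique(eids[duplicated(eids)]), collapse = ", ")))
    }
    etypes <- vapply(els, `[[`, character(1), "etype")
    names(etypes) <- eids

    if (!is.null(m$graph)) {
      gv <- m$graph$variable
      if (!gv %in% eids) {
        add("error", paste0(mp, ".graph.variable"),
            sprintf("'%s' does not name an element of this module", gv))
      } else if (!etypes[[gv]] %in% c("slider", "number", "yesno")) {
        add("error", paste0(mp, ".graph.variable"),
            "graph variable must be numeric (slider/number/yesno)")
      }
      if (m$graph$max_points < 1) {
        add("error", paste0(mp, ".graph.max_points"), "must be >= 1")
      }
    }

    # per-element checks in document order
    seen <- character(0)
    ei <- 0
    for (si in seq_along(m$sections)) {
      sec <- m$sections[[si]]
      if (length(sec$elements) == 0) {
        add("error", sprintf("%s.sections[%d].elements", mp, si - 1),
            "must be non-empty")
      }
      for (el in sec$elements) {
        ep <- sprintf("%s.sections[%d].elements[%d]", mp, si - 1, ei)
        ei <- ei + 1
        if (el$etype == "slider" && el$min >= el$max) {
          add("error", ep, "slider min must be < max")
        }
        if (el$etype %in% c("checkbox", "radio") &&
            anyDuplicated(el$options)) {
          add("error", paste0(ep, ".options"), "options must be unique")
        }
        if (el$etype %in% c("instruction", "media") && isTRUE(el$required)) {
          add("error", paste0(ep, ".required"),
              sprintf("%s elements cannot be required", el$etype))
        }
        if (!is.null(el$hide_id)) {
          if (!el$hide_id %in% eids) {
            add("error", paste0(ep, ".hide_id"),
                sprintf("'%s' does not name an element of this module", el$hide_id))
          } else if (!el$hide_id %in% seen) {
            add("error", paste0(ep, ".hide_id"),
                "branching source must appear earlier in document order")
          } else if (!etypes[[el$hide_id]] %in% BRANCH_SOURCE_TYPES) {
            add("error", paste0(ep, ".hide_id"),
                "branching source must be slider/yesno/checkbox/radio")
          } else if (etypes[[el$hide_id]] == "slider" &&
                     is.character(el$hide_value) &&
                     !grepl("^[<>]?-?[0-9]+$", el$hide_value)) {
            add("error", paste0(ep, ".hide_value"),
                "slider comparator must be a number or '>n'/'<n'")
          }
        }
        seen <- c(seen, el$id)
      }
      ei <- ei  # section boundary
    }

    # rand_group membership: within one section, >= 2 members
    group_section <- list()
    for (si in seq_along(m$sections)) {
      for (el in m$sections[[si]]$elements) {
        g <- el$rand_group
        if (is.null(g)) next
        group_section[[g]] <- c(group_section[[g]], si)
      }
    }
    for (g in names(group_section)) {
      secs <- group_section[[g]]
      if (length(unique(secs)) > 1) {
        add("error", mp, sprintf(
          "rand_group '%s' spans multiple sections (rendering is per page)", g))
      }
      if (length(secs) < 2) {
        add("warning", mp, sprintf(
          "rand_group '%s' has a single member (randomisation is a no-op)", g))
      }
    }
  }

  if (length(d) == 0) {
    return(data.frame(severity = character(0), path = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, d)
}

#' Serialise a protocol back to canonical JSON
#'
#' The output re-parses to a tree equal to the input (round-trip property).
#' Defaults are written explicitly so serialisation is canonical.
#'
#' @param p a \code{study_protocol}.
#' @return a JSON string.
#' @export
serialize_protocol <- function(p) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- x[!vapply(x, is.null, logical(1))]
      lapply(x, strip)
    } else x
  }
  body <- unclass(p)
  body$modules <- lapply(body$modules, function(m) {
    m$type <- m$module_type; m$module_type <- NULL
    if (!is.null(m$graph)) m$graph$type <- m$graph$graph_type
    if (!is.null(m$graph)) m$graph$graph_type <- NULL
    m$sections <- lapply(m$sections, function(s) {
      s$elements <- lapply(s$elements, function(e) {
        e$type <- e$etype; e$etype <- NULL
        e
      })
      s
    })
    m
  })
  jsonlite::toJSON(strip(body), auto_unbox = TRUE, pretty = TRUE,
                   digits = NA)
}

#' @export
print.study_protocol <- function(x, ...) {
  cat(sprintf("<study_protocol> %s (%s)\n", x$study_name, x$study_id))
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  for (m in x$modules) {
    n_el <- length(module_elements(m))
    cat(sprintf("  module %-12s [%s] cond=%s sections=%d elements=%d\n",
                m$id, m$module_type, m$condition, length(m$sections), n_el))
  }
  invisible(x)
}
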