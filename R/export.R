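#' @title Analysis-ready exports
#'
#' @description
#' Transforms uploaded response records into a tidy long table (one row
#' per answered element; checkbox responses exploded to one row per
#' selected option) and computes feedback-graph series exactly as the app
#' would display them (the numeric values of the graphed element across a
#' module's completions, truncated to the most recent \code{max_points}).
#'
#' @name export
NULL

strip_html <- function(x) {
  # whitelist b/i/u/br/p: drop those tags, escape survives verbatim
  gsub("</?(b|i|u|br|p)\\s*/?>", "", x, ignore.case = TRUE)
}

serialise_value <- function(v) {
  if (is.logical(v)) return(list(value = ifelse(v, "true", "false"),
                                 tag = "boolean"))
  if (is.numeric(v)) return(list(value = as.character(v), tag = "number"))
  list(value = as.character(v), tag = "string")
}

#' Flatten response records into a long table
#'
#' One row per (record, answered visible element); checkbox responses
#' contribute one row per selected option, with \code{value_set_size}
#' recording how many options that response selected so the set can be
#' reconstructed. Rows are sorted by (user, response time, element
#' document order). Latency is reported in fractional minutes from alert
#' to response and is never negative.
#'
#' @param records list of response records (as uploaded).
#' @param protocol optionally, the protocol — used to recover element
#'   types and document order; without it types are inferred from values.
#' @return data.frame with columns user_id, condition, module_id,
#'   module_name, occurrence_index, element_id, element_type, value,
#'   value_tag, value_set_size, response_time, alert_time,
#'   latency_minutes, platform.
#' @export
to_long_table <- function(records, protocol = NULL) {
  etype_of <- function(mid, eid) {
    if (is.null(protocol)) return(NA_character_)
    m <- Find(function(x) x$id == mid, protocol$modules)
    if (is.null(m)) return(NA_character_)
    e <- Find(function(x) x$id == eid, module_elements(m))
    if (is.null(e)) NA_character_ else e$etype
  }
  doc_rank <- function(mid, eid) {
    if (is.null(protocol)) return(NA_integer_)
    m <- Find(function(x) x$id == mid, protocol$modules)
    if (is.null(m)) return(NA_integer_)
    ids <- vapply(module_elements(m), `[[`, character(1), "id")
    match(eid, ids)
  }

  rows <- list()
  for (rec in records) {
    lat <- max(as.numeric(difftime(parse_dt(rec$response_time),
                                   parse_dt(rec$alert_time),
                                   units = "mins")), 0)
    for (eid in names(rec$responses)) {
      v <- rec$responses[[eid]]
      vals <- if (length(v) > 1) as.list(v) else list(v)
      for (one in vals) {
        sv <- serialise_value(one)
        rows[[length(rows) + 1]] <- data.frame(
          user_id = rec$user_id, condition = rec$condition,
          module_id = rec$module_id, module_name = rec$module_name,
          occurrence_index = rec$module_index,
          element_id = eid, element_type = etype_of(rec$module_id, eid),
          value = sv$value, value_tag = sv$tag,
          value_set_size = length(vals),
          response_time = rec$response_time, alert_time = rec$alert_time,
          latency_minutes = lat, platform = rec$platform,
          doc_rank = doc_rank(rec$module_id, eid),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(user_id = character(0), condition = character(0),
                      module_id = character(0), module_name = character(0),
                      occurrence_index = integer(0),
                      element_id = character(0),
                      element_type = character(0), value = character(0),
                      value_tag = character(0), value_set_size = integer(0),
                      response_time = character(0),
                      alert_time = character(0),
                      latency_minutes = numeric(0),
                      platform = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$user_id, out$response_time,
               ifelse(is.na(out$doc_rank), 0L, out$doc_rank))
  out <- out[ord, setdiff(names(out), "doc_rank"), drop = FALSE]
  row.names(out) <- NULL
  out
}

numeric_response <- function(v, etype) {
  if (identical(etype, "yesno") || is.logical(v)) {
    return(as.numeric(as_yesno_value(v)))   # no -> 0, yes -> 1
  }
  as.numeric(v)
}

#' Feedback-graph series for a module
#'
#' The numeric values of the module's graphed element across that module's
#' completions, in chronological order, truncated to the most recent
#' \code{max_points} — the series the participant's progress tab would
#' plot. Yes/no responses are coded no = 0, yes = 1; sliders and numbers
#' as-is (other types are rejected at validation).
#'
#' @param records list of response records (any modules; filtered here).
#' @param module the module spec, whose \code{graph} must be present.
#' @return list with element_id, graph_type, title, blurb and a
#'   \code{points} data.frame (response_time, value), chronologically
#'   ascending, at most \code{max_points} rows.
#' @export
graph_series <- function(records, module) {
  if (is.null(module$graph)) stop("module '", module$id, "' has no graph")
  g <- module$graph
  etype <- Find(function(e) e$id == g$variable, module_elements(module))$etype
  recs <- Filter(function(r) r$module_id == module$id &&
                   !is.null(r$responses[[g$variable]]), records)
  times <- vapply(recs, `[[`, character(1), "response_time")
  vals <- vapply(recs, function(r)
    numeric_response(r$responses[[g$variable]], etype), numeric(1))
  ord <- order(times)
  times <- times[ord]; vals <- vals[ord]
  keep <- utils::tail(seq_along(vals), g$max_points)
  list(element_id = g$variable, graph_type = g$graph_type,
       title = strip_html(g$title), blurb = strip_html(g$blurb),
       points = data.frame(response_time = times[keep], value = vals[keep],
                           stringsAsFactors = FALSE))
}

#' Write export artifacts
#'
#' Writes \code{records.csv} (RFC-4180, header fixed to the long-table
#' column order), \code{records.jsonl} (one upload payload object per
#' line) and \code{graphs.json} under \code{destination}.
#'
#' @param rows long table from \code{\link{to_long_table}}.
#' @param records the raw record list (for the JSON-Lines file).
#' @param series list of graph series (possibly empty).
#' @param destination output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(rows, records, series, destination) {
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(destination, "records.csv")
  utils::write.csv(rows, csv, row.names = FALSE, quote = TRUE, na = "")
  jsonl <- file.path(destination, "records.jsonl")
  con <- file(jsonl, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) writeLines(record_json(rec), con)
  gj <- file.path(destination, "graphs.json")
  jsonlite::write_json(series, gj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, jsonl = jsonl, graphs = gj))
}

#' Read a JSON-Lines record file back into record objects
#' @param path records.jsonl path.
#' @return list of response records.
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    rec$responses <- lapply(rec$responses, function(v) {
      if (is.list(v)) unlist(v) else v
    })
    structure(rec, class = "response_record")
  })
}
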