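#' @title Branching (skip-logic) engine
#'
#' @description
#' An element may reference an earlier slider, yes/no, checkbox or radio
#' element (\code{hide_id}) together with a trigger value
#' (\code{hide_value}) and a polarity flag (\code{hide_if_matched}):
#' \code{TRUE} hides the element when the source response matches the
#' value, \code{FALSE} shows it on match and hides it otherwise. A
#' dependent of an unanswered or hidden source is hidden (content appears
#' only once triggered), and hiding cascades down chains of rules. Because
#' validation forces every branching source to occur earlier in document
#' order, a single document-order pass reaches the fixpoint.
#'
#' @name branching
NULL

#' Does a response trigger a branching rule?
#'
#' Yes/no and radio sources compare by equality; checkbox sources match
#' when the trigger value is among the selected options; slider sources
#' accept a bare number (equality) or a strict comparator string
#' \code{">n"} / \code{"<n"}.
#'
#' @param source the source element spec.
#' @param response_value the source's current response, or NULL if
#'   unanswered.
#' @param hide_value the trigger value from the dependent element.
#' @return TRUE/FALSE, or NA when the source is unanswered.
#' @export
branch_matches <- function(source, response_value, hide_value) {
  if (is.null(response_value) || length(response_value) == 0) return(NA)
  switch(source$etype,
    yesno = isTRUE(as.logical(response_value) ==
                   as_yesno_value(hide_value)),
    radio = isTRUE(as.character(response_value) == as.character(hide_value)),
    checkbox = as.character(hide_value) %in% as.character(response_value),
    slider = slider_matches(as.numeric(response_value), hide_value),
    stop("element type '", source$etype, "' cannot trigger branching")
  )
}

as_yesno_value <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  tolower(as.character(v)) %in% c("true", "yes", "1")
}

slider_matches <- function(resp, hide_value) {
  if (is.numeric(hide_value)) return(isTRUE(resp == hide_value))
  hv <- as.character(hide_value)
  if (grepl("^>", hv)) return(isTRUE(resp > as.numeric(sub("^>", "", hv))))
  if (grepl("^<", hv)) return(isTRUE(resp < as.numeric(sub("^<", "", hv))))
  isTRUE(resp == as.numeric(hv))
}

#' Evaluate element visibility for a rendered module
#'
#' Computes, for every element, whether it is visible given the current
#' (possibly partial) responses and the access's render plan, with a
#' reason code: \code{default} (visible or no rule), \code{group_hidden}
#' (lost its randomisation-group draw — branching can never reveal such an
#' element), \code{branch_hidden} (its rule evaluated to hidden, or its
#' source is itself hidden) or \code{source_unanswered}.
#'
#' The evaluation is idempotent and a pure function of (module, responses,
#' plan); answering an element never changes the visibility of elements
#' earlier in document order.
#'
#' @param m module spec.
#' @param responses named list, element id -> response value (partial).
#' @param plan render plan for this access.
#' @return list with named logical \code{visible} and named character
#'   \code{reason}, one entry per element of the module.
#' @export
evaluate_visibility <- function(m, responses, plan = make_render_plan(m, rng_stream(0))) {
  els <- module_elements(m)
  ids <- vapply(els, `[[`, character(1), "id")
  by_id <- stats::setNames(els, ids)
  visible <- stats::setNames(rep(TRUE, length(ids)), ids)
  reason <- stats::setNames(rep("default", length(ids)), ids)

  for (id in ids) {
    el <- by_id[[id]]
    if (id %in% plan$hidden_by_group) {
      visible[[id]] <- FALSE
      reason[[id]] <- "group_hidden"
      next
    }
    if (is.null(el$hide_id)) next
    src <- el$hide_id
    if (!visible[[src]]) {           # hidden source cascades
      visible[[id]] <- FALSE
      reason[[id]] <- "branch_hidden"
      next
    }
    matched <- branch_matches(by_id[[src]], responses[[src]], el$hide_value)
    if (is.na(matched)) {
      visible[[id]] <- FALSE
      reason[[id]] <- "source_unanswered"
    } else if (isTRUE(el$hide_if_matched)) {
      if (matched) { visible[[id]] <- FALSE; reason[[id]] <- "branch_hidden" }
    } else {
      if (!matched) { visible[[id]] <- FALSE; reason[[id]] <- "branch_hidden" }
    }
  }
  list(visible = visible, reason = reason)
}

#' Required elements still unanswered
#'
#' Ids (document order) of elements that are required, currently visible,
#' and unanswered; submission of the module instance is permitted exactly
#' when this list is empty. Hidden elements impose no requirement.
#'
#' @param m module spec.
#' @param responses named list of responses.
#' @param vis visibility state from \code{\link{evaluate_visibility}}.
#' @return character vector of element ids.
#' @export
required_missing <- function(m, responses, vis = evaluate_visibility(m, responses)) {
  els <- module_elements(m)
  ids <- vapply(els, `[[`, character(1), "id")
  req <- vapply(els, function(e) isTRUE(e$required), logical(1))
  unanswered <- vapply(ids, function(id) {
    v <- responses[[id]]
    is.null(v) || length(v) == 0
  }, logical(1))
  ids[req & vis$visible[ids] & unanswered]
}
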