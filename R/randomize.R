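#' @title Randomisation engine
#'
#' @description
#' All stochastic protocol behaviour other than schedule jitter: uniform
#' allocation of each participant to a study condition at enrollment
#' (double-blind — neither researcher nor participant influences the draw),
#' shuffling of sections within a module and of questions within a section
#' at every access, and per-access uniform selection of one element from
#' each randomisation group, hiding the other group members.
#'
#' @name randomisation
NULL

#' Allocate a participant to a study condition
#'
#' A uniform draw over the protocol's condition labels; recorded once at
#' enrollment and immutable thereafter.
#'
#' @param p a \code{study_protocol}.
#' @param rng the participant's allocation stream.
#' @return a condition label.
#' @export
allocate_condition <- function(p, rng) {
  stopifnot(length(p$conditions) >= 1)
  if (length(p$conditions) == 1) return(p$conditions[[1]])
  stream_sample(rng, p$conditions, size = 1)
}

#' Modules visible to a condition
#'
#' A module assigned the wildcard \code{"*"} is available in all arms;
#' otherwise only in its own. Document order is preserved.
#'
#' @param p a \code{study_protocol}.
#' @param condition a condition label.
#' @return list of module specs.
#' @export
modules_for <- function(p, condition) {
  stopifnot(condition %in% p$conditions)
  Filter(function(m) m$condition == "*" || m$condition == condition,
         p$modules)
}

#' Build a render plan for one module access
#'
#' Drawn fresh at every access: a uniform permutation of sections when the
#' module shuffles sections (identity otherwise), a uniform permutation of
#' each section's elements when the section shuffles (identity otherwise),
#' and one uniformly chosen element per randomisation group — the other
#' group members are hidden for this access. Shuffling never adds, drops or
#' duplicates elements.
#'
#' @param m a module spec.
#' @param rng the participant's render stream.
#' @return list with \code{module_id}, \code{section_order},
#'   \code{element_order} (one permutation per section, in original section
#'   indexing), \code{group_choice} (named: group -> chosen element id) and
#'   \code{hidden_by_group} (character vector of hidden element ids).
#' @export
make_render_plan <- function(m, rng) {
  ns <- length(m$sections)
  section_order <- if (isTRUE(m$shuffle_sections) && ns > 1) {
    stream_sample(rng, seq_len(ns))
  } else seq_len(ns)

  element_order <- lapply(m$sections, function(sec) {
    ne <- length(sec$elements)
    if (isTRUE(sec$shuffle) && ne > 1) stream_sample(rng, seq_len(ne))
    else seq_len(ne)
  })

  groups <- list()
  for (sec in m$sections) {
    for (el in sec$elements) {
      if (!is.null(el$rand_group)) {
        groups[[el$rand_group]] <- c(groups[[el$rand_group]], el$id)
      }
    }
  }
  group_choice <- lapply(groups, function(ids) {
    if (length(ids) == 1) ids else stream_sample(rng, ids, size = 1)
  })
  hidden <- unlist(lapply(names(groups), function(g) {
    setdiff(groups[[g]], group_choice[[g]])
  }), use.names = FALSE)

  list(module_id = m$id,
       section_order = section_order,
       element_order = element_order,
       group_choice = group_choice,
       hidden_by_group = if (is.null(hidden)) character(0) else hidden)
}

#' Element ids of a rendered module in display order
#'
#' Applies the plan's section and element permutations; group-hidden
#' elements are retained in the sequence (visibility is decided by the
#' branching engine, which consults the plan).
#'
#' @param m module spec.
#' @param plan a render plan for \code{m}.
#' @return character vector of element ids in display order.
#' @export
rendered_order <- function(m, plan) {
  unlist(lapply(plan$section_order, function(si) {
    sec <- m$sections[[si]]
    vapply(sec$elements[plan$element_order[[si]]], `[[`, character(1), "id")
  }), use.names = FALSE)
}
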