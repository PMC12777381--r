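# Set-semantics evaluation of expression constraints over a concept graph.
#
# SELF -> {c}; < / << -> (reflexive-)transitive descendants; > / >> dually;
# wildcard -> all active concepts; AND/OR/MINUS -> intersection/union/
# difference; a refinement filters the focus set concept by concept.
# Evaluation works on the materialized relationship view only: attributes
# are never inherited down the hierarchy at query time.

eval_error <- function(msg) {
  errorCondition(msg, class = c("eclkit_eval_error", "eclkit_error"))
}

unsupported_error <- function(msg) {
  errorCondition(msg, class = c("eclkit_unsupported_error", "eclkit_error"))
}

#' Evaluate an expression constraint
#'
#' Computes the set of active concepts an ECL query selects, in ascending
#' SCTID order. `ecl_count()` is the size of that set (the number a live
#' results dashboard would display); `evaluate_ecl()` accepts either an
#' `ecl_expression` or raw ECL text.
#'
#' @param e an `ecl_expression` or a single ECL string.
#' @param g a [concept_graph()].
#' @return character vector of concept ids (ascending SCTID order).
#' @examples
#' fx <- demo_fixture()
#' ecl_count("<< 64572001", fx$graph)
#' @export
evaluate_ecl <- function(e, g) {
  if (is.character(e)) e <- parse_ecl(e)
  stopifnot(inherits(e, "ecl_expression"), inherits(g, "concept_graph"))
  eval_expr(normalize_expr(e), g)
}

#' @rdname evaluate_ecl
#' @export
ecl_count <- function(e, g) {
  length(evaluate_ecl(e, g))
}

eval_expr <- function(e, g) {
  if (e$kind == "compound") {
    sets <- lapply(e$operands, eval_expr, g = g)
    out <- switch(e$op,
      AND = Reduce(intersect, sets),
      OR = Reduce(union, sets),
      MINUS = setdiff(sets[[1]], sets[[2]]))
    return(sct_sort(out))
  }
  base <- eval_focus(e$focus, g)
  members <- apply_operator(e$op, base, g)
  if (!is.null(e$refinement)) {
    members <- filter_refinement(members, e$refinement, g)
  }
  sct_sort(members)
}

eval_focus <- function(f, g) {
  switch(f$kind,
    wildcard = graph_active(g),
    nested = eval_expr(f$expr, g),
    concept = {
      if (!graph_has(g, f$id)) {
        stop(eval_error(sprintf("unknown concept in expression: %s", f$id)))
      }
      if (is_active(g, f$id)) f$id else character()
    })
}

apply_operator <- function(op, base, g) {
  if (op == "self") return(base)
  include_self <- op %in% c("<<", ">>")
  fun <- if (op %in% c("<", "<<")) descendants else ancestors
  out <- unlist(lapply(base, fun, g = g, include_self = include_self),
                use.names = FALSE)
  unique(out %||% character())
}

# Pre-evaluates every attribute-type set and value set once, then tests each
# candidate concept. Exported as concept_matches() for single concepts.
filter_refinement <- function(members, r, g) {
  if (!length(members)) return(character())
  pre <- precompute_refinement(r, g)
  keep <- vapply(members, function(c_id) refinement_holds(c_id, r, g, pre),
                 logical(1), USE.NAMES = FALSE)
  members[keep]
}

#' Does one concept satisfy a refinement?
#'
#' The per-concept membership test behind refinement filtering. An
#' ungrouped constraint `[m..n] A cmp V` holds when the number of the
#' concept's relationships (any role-group number) whose type is in the
#' attribute set and whose target lies inside (`=`) or outside (`!=`) the
#' value set falls within `[m..n]`. A role group with group cardinality
#' `[p..q]` holds when the number of distinct role groups (numbered >= 1;
#' ungrouped relationships never satisfy a braces-enclosed constraint)
#' within which all its connective-combined constraints hold — counts taken
#' per group — lies in `[p..q]`. A reverse constraint `R A cmp V` counts
#' incoming relationships: sources `z` with a type-matching relationship
#' targeting the concept, with `z` inside (`=`) or outside (`!=`) the value
#' set.
#'
#' @param c_id an active concept id.
#' @param r an `ecl_refinement`.
#' @param g a [concept_graph()].
#' @return logical scalar.
#' @export
concept_matches <- function(c_id, r, g) {
  stopifnot(inherits(r, "ecl_refinement"))
  if (!graph_has(g, c_id)) stop(lookup_error(c_id))
  refinement_holds(c_id, r, g, precompute_refinement(r, g))
}

precompute_refinement <- function(r, g) {
  lapply(r$items, function(it) {
    if (inherits(it, "ecl_group")) {
      lapply(it$constraints, precompute_attr, g = g)
    } else {
      precompute_attr(it, g)
    }
  })
}

precompute_attr <- function(a, g) {
  if (a$reverse && a$attr_focus$kind == "wildcard") {
    stop(unsupported_error("reverse constraints with a wildcard attribute are not supported"))
  }
  type_expr <- structure(list(kind = "simple", op = a$attr_op,
                              focus = a$attr_focus, refinement = NULL),
                         class = "ecl_expression")
  list(types = eval_expr(type_expr, g), values = eval_expr(a$value, g))
}

refinement_holds <- function(c_id, r, g, pre) {
  outcomes <- vapply(seq_along(r$items), function(i) {
    it <- r$items[[i]]
    if (inherits(it, "ecl_group")) {
      group_holds(c_id, it, g, pre[[i]])
    } else {
      rels <- g$relationships[if (it$reverse) g$relationships$target == c_id
                              else g$relationships$source == c_id, , drop = FALSE]
      attr_holds(it, rels, pre[[i]])
    }
  }, logical(1))
  if (r$connective == "AND") all(outcomes) else any(outcomes)
}

attr_holds <- function(a, rels, pre) {
  rels <- rels[rels$type %in% pre$types, , drop = FALSE]
  other <- if (a$reverse) rels$source else rels$target
  inside <- other %in% pre$values
  k <- if (a$comparator == "=") sum(inside) else sum(!inside)
  a$cardinality$min <= k && k <= a$cardinality$max
}

group_holds <- function(c_id, grp, g, pre) {
  rels <- g$relationships[g$relationships$source == c_id, , drop = FALSE]
  groups <- setdiff(unique(rels$group), 0L)
  n_ok <- 0L
  for (gn in groups) {
    in_group <- rels[rels$group == gn, , drop = FALSE]
    outcomes <- vapply(seq_along(grp$constraints), function(j) {
      cst <- grp$constraints[[j]]
      if (cst$reverse) {
        # reverse direction has no role group on the target side; evaluate
        # against the concept's incoming relationships as usual
        inc <- g$relationships[g$relationships$target == c_id, , drop = FALSE]
        attr_holds(cst, inc, pre[[j]])
      } else {
        attr_holds(cst, in_group, pre[[j]])
      }
    }, logical(1))
    ok <- if (grp$connective == "AND") all(outcomes) else any(outcomes)
    if (ok) n_ok <- n_ok + 1L
  }
  grp$cardinality$min <= n_ok && n_ok <= grp$cardinality$max
}

#' Serialize an evaluation result
#'
#' Writes the members of a result set as newline-delimited `id<TAB>fsn`
#' lines or as a JSON array of `{id, fsn}` objects, in ascending SCTID
#' order.
#'
#' @param ids character vector of concept ids (as from [evaluate_ecl()]).
#' @param g a [concept_graph()].
#' @param format `"tsv"` or `"json"`.
#' @return a character vector of lines (`tsv`) or a JSON string.
#' @export
format_result_set <- function(ids, g, format = c("tsv", "json")) {
  format <- match.arg(format)
  ids <- sct_sort(ids)
  if (format == "tsv") {
    sprintf("%s\t%s", ids, graph_fsn(g, ids))
  } else {
    as.character(jsonlite::toJSON(
      lapply(ids, function(i) list(id = i, fsn = graph_fsn(g, i))),
      auto_unbox = TRUE))
  }
}
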