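# Abstract syntax of the implemented ECL subset.
#
# An expression constraint is a list of class "ecl_expression" with
#   kind = "simple":   op, focus, refinement (NULL or ecl_refinement)
#   kind = "compound": op ("AND"|"OR"|"MINUS"), operands (list; MINUS binary)
# A focus is kind = "concept" (id, term), "wildcard", or "nested" (expr).
# Refinements hold items (attribute constraints or role groups) joined by a
# single homogeneous connective; mixing AND and OR at one level requires
# explicit parentheses, which in ECL means a nested expression.

ECL_OPERATORS <- c("self", "<", "<<", ">", ">>")

#' Cardinality bound for attributes and role groups
#'
#' `[min..max]`, with `Inf` for an unbounded maximum. The ECL default is
#' `[1..*]` — at least one instance, no upper limit; `[0..0]` expresses
#' negation (the attribute must not occur).
#'
#' @param min non-negative integer.
#' @param max non-negative integer or `Inf`.
#' @return an `ecl_cardinality` object.
#' @export
ecl_cardinality <- function(min = 1L, max = Inf) {
  min <- as.numeric(min); max <- as.numeric(max)
  if (is.na(min) || min < 0 || min != floor(min)) stop(model_error("cardinality min must be a non-negative integer"))
  if (is.na(max) || (is.finite(max) && (max != floor(max) || max < min))) {
    stop(model_error("cardinality max must be an integer >= min, or Inf"))
  }
  structure(list(min = min, max = max), class = "ecl_cardinality")
}

card_default <- function() ecl_cardinality(1, Inf)

is_default_card <- function(card) card$min == 1 && is.infinite(card$max)

model_error <- function(msg) {
  errorCondition(msg, class = c("eclkit_model_error", "eclkit_error"))
}

#' Focus constructors
#'
#' `ecl_concept()` names a single concept (the term annotation inside pipes
#' is carried but semantically inert); `ecl_wildcard()` is `*`, matching
#' every active concept; a nested focus wraps a parenthesized expression.
#'
#' @param id a SCTID string.
#' @param term optional human-readable term.
#' @return a focus object for use in [ecl_constraint()].
#' @export
ecl_concept <- function(id, term = NULL) {
  assert_sctid(id)
  structure(list(kind = "concept", id = as.character(id), term = term),
            class = "ecl_focus")
}

#' @rdname ecl_concept
#' @export
ecl_wildcard <- function() {
  structure(list(kind = "wildcard"), class = "ecl_focus")
}

as_focus <- function(x) {
  if (inherits(x, "ecl_focus")) return(x)
  if (inherits(x, "ecl_expression")) {
    return(structure(list(kind = "nested", expr = x), class = "ecl_focus"))
  }
  if (is.character(x) && length(x) == 1L) return(ecl_concept(x))
  stop(model_error("focus must be an ecl_focus, ecl_expression or SCTID string"))
}

#' Build an expression constraint
#'
#' The simple form of an ECL query: a constraint operator applied to a
#' focus, optionally refined by attribute constraints. `operator` is one of
#' `"self"` (implied when absent in text), `"<"` (descendants), `"<<"`
#' (descendants or self), `">"` (ancestors), `">>"` (ancestors or self).
#'
#' @param focus an [ecl_concept()], [ecl_wildcard()], SCTID string, or a
#'   whole expression (which becomes a parenthesized nested focus).
#' @param operator constraint operator.
#' @param refinement optional [ecl_refinement()] (a bare [ecl_attribute()]
#'   or [ecl_group()] is wrapped automatically).
#' @return an `ecl_expression`.
#' @examples
#' render(ecl_constraint("64572001", "<<"))
#' @export
ecl_constraint <- function(focus, operator = "self", refinement = NULL) {
  operator <- match.arg(operator, ECL_OPERATORS)
  focus <- as_focus(focus)
  if (!is.null(refinement)) refinement <- as_refinement(refinement)
  normalize_expr(structure(list(kind = "simple", op = operator, focus = focus,
                                refinement = refinement),
                           class = "ecl_expression"))
}

#' Attribute constraint
#'
#' One `attribute comparator value` clause of a refinement, e.g.
#' `116676008 |Associated morphology| = << 55641003 |Infarct|`. The
#' attribute side is itself a (refinement-free) subexpression over
#' attribute-type concepts; `reverse = TRUE` flips the direction so the
#' constraint selects the *values* pointed at by matching relationships.
#' A reverse constraint with a wildcard attribute is rejected as
#' unsupported.
#'
#' @param attribute SCTID string, [ecl_concept()] or refinement-free
#'   `ecl_expression` naming the attribute(s).
#' @param value an `ecl_expression` (or SCTID string) constraining values.
#' @param comparator `"="` or `"!="`.
#' @param cardinality an [ecl_cardinality()]; default `[1..*]`.
#' @param reverse logical; reverse-flag (`R`) semantics.
#' @return an `ecl_attribute`.
#' @export
ecl_attribute <- function(attribute, value, comparator = "=",
                          cardinality = NULL, reverse = FALSE) {
  comparator <- match.arg(comparator, c("=", "!="))
  if (is.null(cardinality)) cardinality <- card_default()
  attr_sub <- as_subexpression(attribute)
  value <- as_expression(value)
  structure(list(cardinality = cardinality, reverse = isTRUE(reverse),
                 attr_op = attr_sub$op, attr_focus = attr_sub$focus,
                 comparator = comparator, value = value),
            class = "ecl_attribute")
}

# a subexpression = operator + focus, no refinement
as_subexpression <- function(x) {
  if (is.character(x)) return(list(op = "self", focus = ecl_concept(x)))
  if (inherits(x, "ecl_focus")) return(list(op = "self", focus = x))
  if (inherits(x, "ecl_expression") && x$kind == "simple" && is.null(x$refinement)) {
    return(list(op = x$op, focus = x$focus))
  }
  stop(model_error("attribute must be a concept id or a refinement-free simple expression"))
}

as_expression <- function(x) {
  if (inherits(x, "ecl_expression")) return(x)
  if (is.character(x) && length(x) == 1L) return(ecl_constraint(x))
  if (inherits(x, "ecl_focus")) return(ecl_constraint(x))
  stop(model_error("expected an ecl_expression or SCTID string"))
}

#' Role group
#'
#' A braces-enclosed set of attribute constraints that must be satisfied by
#' relationships sharing one role-group number. The group-level cardinality
#' bounds how many distinct role groups may satisfy the constraints.
#'
#' @param constraints list of [ecl_attribute()] (a single one may be given
#'   bare).
#' @param connective `"AND"` or `"OR"`, joining the constraints.
#' @param cardinality group-level [ecl_cardinality()]; default `[1..*]`.
#' @return an `ecl_group`.
#' @export
ecl_group <- function(constraints, connective = "AND", cardinality = NULL) {
  if (inherits(constraints, "ecl_attribute")) constraints <- list(constraints)
  if (!length(constraints) || !all(vapply(constraints, inherits, logical(1), "ecl_attribute"))) {
    stop(model_error("a role group needs at least one ecl_attribute"))
  }
  connective <- match.arg(connective, c("AND", "OR"))
  if (is.null(cardinality)) cardinality <- card_default()
  structure(list(cardinality = cardinality, constraints = constraints,
                 connective = connective),
            class = "ecl_group")
}

#' Refinement
#'
#' The part after `:` restricting a focus set. Items are attribute
#' constraints (ungrouped) and role groups, joined by one homogeneous
#' connective; ECL requires parentheses to mix AND and OR.
#'
#' @param items list of [ecl_attribute()] / [ecl_group()] objects.
#' @param connective `"AND"` or `"OR"`.
#' @return an `ecl_refinement`.
#' @export
ecl_refinement <- function(items, connective = "AND") {
  if (inherits(items, "ecl_attribute") || inherits(items, "ecl_group")) items <- list(items)
  ok <- vapply(items, function(x) inherits(x, "ecl_attribute") || inherits(x, "ecl_group"),
               logical(1))
  if (!length(items) || !all(ok)) {
    stop(model_error("refinement items must be attribute constraints or role groups"))
  }
  connective <- match.arg(connective, c("AND", "OR"))
  structure(list(items = items, connective = connective), class = "ecl_refinement")
}

as_refinement <- function(x) {
  if (inherits(x, "ecl_refinement")) return(x)
  ecl_refinement(x)
}

#' Compound expressions
#'
#' Combine expression constraints with set logic: `ecl_and()` intersection,
#' `ecl_or()` union, `ecl_minus()` (binary) difference. Operands that are
#' themselves compound, or carry a refinement, render parenthesized.
#'
#' @param ... two or more expressions (SCTID strings accepted).
#' @return an `ecl_expression` of kind compound.
#' @export
ecl_and <- function(...) ecl_compound("AND", list(...))

#' @rdname ecl_and
#' @export
ecl_or <- function(...) ecl_compound("OR", list(...))

#' @rdname ecl_and
#' @param a,b left and right operand of the difference.
#' @export
ecl_minus <- function(a, b) ecl_compound("MINUS", list(a, b))

ecl_compound <- function(op, operands) {
  op <- match.arg(op, c("AND", "OR", "MINUS"))
  operands <- lapply(operands, as_expression)
  if (length(operands) < 2L) stop(model_error("a compound expression needs >= 2 operands"))
  if (op == "MINUS" && length(operands) != 2L) {
    stop(model_error("MINUS is binary; chain with nested expressions"))
  }
  normalize_expr(structure(list(kind = "compound", op = op, operands = operands),
                           class = "ecl_expression"))
}

# Canonicalization applied by every constructor and by the parser:
# * missing cardinalities become the explicit [1..*] default,
# * a SELF-operator nested focus with no refinement is unwrapped (the
#   parentheses were purely syntactic),
# * same-operator AND/OR children of an AND/OR node are flattened.
normalize_expr <- function(e) {
  if (e$kind == "simple") {
    if (e$focus$kind == "nested") {
      e$focus$expr <- normalize_expr(e$focus$expr)
      if (e$op == "self" && is.null(e$refinement)) return(e$focus$expr)
    }
    if (!is.null(e$refinement)) e$refinement <- normalize_refinement(e$refinement)
    return(e)
  }
  e$operands <- lapply(e$operands, normalize_expr)
  if (e$op %in% c("AND", "OR")) {
    flat <- list()
    for (o in e$operands) {
      if (o$kind == "compound" && o$op == e$op) flat <- c(flat, o$operands)
      else flat <- c(flat, list(o))
    }
    e$operands <- flat
  }
  e
}

normalize_refinement <- function(r) {
  r$items <- lapply(r$items, function(it) {
    if (inherits(it, "ecl_attribute")) {
      it$value <- normalize_expr(it$value)
    } else {
      it$constraints <- lapply(it$constraints, function(cst) {
        cst$value <- normalize_expr(cst$value)
        cst
      })
      # the connective is inert with a single constraint
      if (length(it$constraints) == 1L) it$connective <- "AND"
    }
    it
  })
  if (length(r$items) == 1L) r$connective <- "AND"
  r
}

#' Render an expression constraint as canonical ECL text
#'
#' Canonical form: single spaces around operators and comparators, terms
#' emitted from the graph FSN when `graph` is given (else from the stored
#' annotation, else omitted), brackets only for non-default cardinalities,
#' braces around role groups, and parentheses exactly where the structure
#' requires them. Rendered text re-parses to a structurally equal AST.
#'
#' @param e an `ecl_expression`.
#' @param graph optional [concept_graph()] used to refresh term annotations.
#' @return a single ECL string.
#' @examples
#' render(ecl_constraint(ecl_concept("64572001", "Disease (disorder)"), "<<"))
#' @export
render <- function(e, graph = NULL) {
  stopifnot(inherits(e, "ecl_expression"))
  render_expr(normalize_expr(e), graph)
}

render_expr <- function(e, graph) {
  if (e$kind == "compound") {
    parts <- vapply(e$operands, function(o) {
      txt <- render_expr(o, graph)
      if (needs_parens(o)) paste0("(", txt, ")") else txt
    }, character(1))
    return(paste(parts, collapse = paste0(" ", e$op, " ")))
  }
  out <- paste0(op_token(e$op), render_focus(e$focus, graph))
  if (!is.null(e$refinement)) {
    out <- paste0(out, " : ", render_refinement(e$refinement, graph))
  }
  out
}

needs_parens <- function(o) {
  o$kind == "compound" || !is.null(o$refinement)
}

op_token <- function(op) if (op == "self") "" else paste0(op, " ")

render_focus <- function(f, graph) {
  switch(f$kind,
    wildcard = "*",
    nested = paste0("(", render_expr(f$expr, graph), ")"),
    concept = {
      term <- f$term
      if (!is.null(graph) && graph_has(graph, f$id)) term <- graph_fsn(graph, f$id)
      if (is.null(term) || is.na(term)) f$id else sprintf("%s |%s|", f$id, term)
    })
}

render_card <- function(card) {
  if (is_default_card(card)) return("")
  maxtok <- if (is.infinite(card$max)) "*" else format(card$max)
  sprintf("[%d..%s] ", as.integer(card$min), maxtok)
}

render_refinement <- function(r, graph) {
  parts <- vapply(r$items, function(it) {
    if (inherits(it, "ecl_group")) render_group(it, graph) else render_attribute(it, graph)
  }, character(1))
  paste(parts, collapse = paste0(" ", r$connective, " "))
}

render_group <- function(grp, graph) {
  inner <- vapply(grp$constraints, render_attribute, character(1), graph = graph)
  paste0(render_card(grp$cardinality), "{ ",
         paste(inner, collapse = paste0(" ", grp$connective, " ")), " }")
}

render_attribute <- function(a, graph) {
  value_txt <- render_expr(a$value, graph)
  if (needs_parens(a$value)) value_txt <- paste0("(", value_txt, ")")
  paste0(render_card(a$cardinality),
         if (a$reverse) "R " else "",
         op_token(a$attr_op), render_focus(a$attr_focus, graph),
         " ", a$comparator, " ", value_txt)
}

#' Structural equality of expression constraints
#'
#' Two ASTs are structurally equal when they coincide after normalization:
#' default cardinalities and implied SELF operators are made explicit, and
#' term annotations inside pipes are ignored entirely (they are
#' human-readable decoration, not semantics).
#'
#' @param a,b `ecl_expression` objects.
#' @return logical scalar.
#' @examples
#' structural_equals(parse_ecl("64572001"), parse_ecl("64572001 |Disease|"))
#' @export
structural_equals <- function(a, b) {
  identical(strip_terms(normalize_expr(a)), strip_terms(normalize_expr(b)))
}

strip_terms <- function(x) {
  if (inherits(x, "ecl_focus") && x$kind == "concept") {
    x$term <- NULL
    return(x)
  }
  if (is.list(x)) {
    attrs <- attributes(x)
    x <- lapply(x, strip_terms)
    attributes(x) <- attrs
  }
  x
}

#' @export
print.ecl_expression <- function(x, ...) {
  cat(render(x), "\n")
  invisible(x)
}

#' @export
format.ecl_cardinality <- function(x, ...) {
  sprintf("[%d..%s]", as.integer(x$min), if (is.infinite(x$max)) "*" else format(x$max))
}

#' Convert an expression constraint to a plain list
#'
#' For JSON export of parsed queries (the CLI's AST dump).
#'
#' @param e an `ecl_expression`.
#' @return a nested plain list mirroring the AST.
#' @export
ecl_as_list <- function(e) {
  unclass_rec <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, unclass_rec)
      attributes(x) <- list(names = names(x))
      if (length(x) && is.null(names(x))) x <- unname(x)
    } else if (is.numeric(x) && length(x) == 1L && is.infinite(x)) {
      x <- "*"
    }
    x
  }
  unclass_rec(e)
}
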