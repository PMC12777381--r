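# Independent brute-force oracle: tests one concept at a time against the
# semantic definitions, walking parent edges directly from the edge list.
# Deliberately shares no closure or evaluation code with the package.

oracle_ancestors <- function(g, id) {
  seen <- character()
  frontier <- g$parents$parent[g$parents$child == id]
  while (length(frontier)) {
    nxt <- setdiff(frontier, seen)
    seen <- c(seen, nxt)
    frontier <- g$parents$parent[g$parents$child %in% nxt]
  }
  unique(seen)
}

oracle_is_descendant <- function(g, c_id, of) {
  of %in% oracle_ancestors(g, c_id)
}

oracle_active <- function(g) g$concepts$id[g$concepts$active]

# membership of c_id in the set denoted by the expression
oracle_member <- function(g, c_id, e) {
  if (!c_id %in% oracle_active(g)) return(FALSE)
  if (e$kind == "compound") {
    hits <- vapply(e$operands, function(o) oracle_member(g, c_id, o), logical(1))
    return(switch(e$op,
                  AND = all(hits),
                  OR = any(hits),
                  MINUS = hits[1] && !hits[2]))
  }
  base_has <- function(f) {
    switch(f$kind,
      wildcard = function(x) TRUE,
      concept = function(x) x == f$id && x %in% oracle_active(g),
      nested = function(x) oracle_member(g, x, f$expr))
  }
  inb <- base_has(e$focus)
  in_scope <- switch(e$op,
    self = inb(c_id),
    "<" = any(vapply(oracle_ancestors(g, c_id), inb, logical(1))),
    "<<" = inb(c_id) || any(vapply(oracle_ancestors(g, c_id), inb, logical(1))),
    ">" = {
      below <- oracle_active(g)[vapply(oracle_active(g), function(x)
        c_id %in% oracle_ancestors(g, x), logical(1))]
      any(vapply(below, inb, logical(1)))
    },
    ">>" = {
      below <- oracle_active(g)[vapply(oracle_active(g), function(x)
        c_id %in% oracle_ancestors(g, x), logical(1))]
      inb(c_id) || any(vapply(below, inb, logical(1)))
    })
  if (!in_scope) return(FALSE)
  if (is.null(e$refinement)) return(TRUE)
  oracle_refinement(g, c_id, e$refinement)
}

oracle_refinement <- function(g, c_id, r) {
  hits <- vapply(r$items, function(it) {
    if (inherits(it, "ecl_group")) oracle_group(g, c_id, it)
    else oracle_attr(g, c_id, it, rel_subset = NULL)
  }, logical(1))
  if (r$connective == "AND") all(hits) else any(hits)
}

oracle_set <- function(g, e) {
  act <- oracle_active(g)
  act[vapply(act, function(x) oracle_member(g, x, e), logical(1))]
}

oracle_attr <- function(g, c_id, a, rel_subset = NULL) {
  type_expr <- structure(list(kind = "simple", op = a$attr_op,
                              focus = a$attr_focus, refinement = NULL),
                         class = "ecl_expression")
  types <- oracle_set(g, type_expr)
  values <- oracle_set(g, a$value)
  rels <- if (is.null(rel_subset)) {
    if (a$reverse) g$relationships[g$relationships$target == c_id, , drop = FALSE]
    else g$relationships[g$relationships$source == c_id, , drop = FALSE]
  } else rel_subset
  rels <- rels[rels$type %in% types, , drop = FALSE]
  other <- if (a$reverse) rels$source else rels$target
  k <- if (a$comparator == "=") sum(other %in% values) else sum(!other %in% values)
  a$cardinality$min <= k && k <= a$cardinality$max
}

oracle_group <- function(g, c_id, grp) {
  rels <- g$relationships[g$relationships$source == c_id, , drop = FALSE]
  n_ok <- 0L
  for (gn in setdiff(unique(rels$group), 0L)) {
    sub <- rels[rels$group == gn, , drop = FALSE]
    hits <- vapply(grp$constraints, function(cst) {
      if (cst$reverse) oracle_attr(g, c_id, cst, rel_subset = NULL)
      else oracle_attr(g, c_id, cst, rel_subset = sub)
    }, logical(1))
    ok <- if (grp$connective == "AND") all(hits) else any(hits)
    n_ok <- n_ok + ok
  }
  grp$cardinality$min <= n_ok && n_ok <= grp$cardinality$max
}

# --- grammar sampler -------------------------------------------------------
# Random ASTs over a pool of concept ids, via the public constructors, for
# round-trip and oracle-equivalence property tests.

sample_focus_id <- function(ids) ids[sample.int(length(ids), 1L)]

sample_card <- function() {
  u <- stats::runif(1)
  if (u < 0.25) ecl_cardinality(0, 0)
  else if (u < 0.5) ecl_cardinality(sample(0:2, 1), Inf)
  else {
    mn <- sample(0:2, 1)
    ecl_cardinality(mn, mn + sample(0:2, 1))
  }
}

sample_attr <- function(ids, depth) {
  value <- if (depth > 0L && stats::runif(1) < 0.25) {
    op <- c("AND", "OR")[sample.int(2L, 1L)]
    ecl_compound(op, list(ecl_constraint(sample_focus_id(ids)),
                          ecl_constraint(sample_focus_id(ids))))
  } else {
    ecl_constraint(sample_focus_id(ids),
                   operator = c("self", "<", "<<")[sample.int(3L, 1L)])
  }
  ecl_attribute(
    attribute = ecl_constraint(sample_focus_id(ids),
                               operator = c("self", "<<")[sample.int(2L, 1L)]),
    value = value,
    comparator = if (stats::runif(1) < 0.2) "!=" else "=",
    cardinality = if (stats::runif(1) < 0.35) sample_card() else NULL,
    reverse = stats::runif(1) < 0.12)
}

sample_refinement <- function(ids, depth) {
  n <- sample.int(2L, 1L)
  items <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.45) {
      m <- sample.int(2L, 1L)
      ecl_group(lapply(seq_len(m), function(j) sample_attr(ids, depth)),
                connective = c("AND", "OR")[sample.int(2L, 1L)],
                cardinality = if (stats::runif(1) < 0.25) sample_card() else NULL)
    } else {
      sample_attr(ids, depth)
    }
  })
  ecl_refinement(items, connective = c("AND", "OR")[sample.int(2L, 1L)])
}

sample_simple <- function(ids, depth) {
  u <- stats::runif(1)
  focus <- if (u < 0.08) {
    ecl_wildcard()
  } else if (u < 0.2 && depth > 0L) {
    sample_ecl_ast(ids, depth - 1L)
  } else {
    ecl_concept(sample_focus_id(ids),
                term = if (stats::runif(1) < 0.3) "Some term (synthetic)")
  }
  op <- ECL_OPS[sample.int(5L, 1L)]
  refinement <- if (stats::runif(1) < 0.35) sample_refinement(ids, depth)
  ecl_constraint(focus, operator = op, refinement = refinement)
}

ECL_OPS <- c("self", "<", "<<", ">", ">>")

sample_ecl_ast <- function(ids, depth = 3L) {
  if (depth > 0L && stats::runif(1) < 0.3) {
    op <- c("AND", "OR", "MINUS")[sample.int(3L, 1L)]
    n <- if (op == "MINUS") 2L else sample(2:3, 1L)
    ecl_compound(op, lapply(seq_len(n), function(i) sample_simple(ids, depth - 1L)))
  } else {
    sample_simple(ids, depth)
  }
}
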