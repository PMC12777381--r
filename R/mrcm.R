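# Processed machine-readable concept model (MRCM): per-domain applicable
# attributes with cardinalities and ECL-defined value ranges. The JSON
# schema consumed here:
#   {"edition": "...",
#    "domains": [{"id", "name", "constraint",
#                 "attributes": [{"id", "name", "grouped",
#                                 "cardinality": [min, max|-1],
#                                 "inGroupCardinality": [min, max|-1],
#                                 "range"}]}]}
# -1 encodes an unbounded maximum.

mrcm_error <- function(msg) {
  errorCondition(msg, class = c("eclkit_mrcm_error", "eclkit_error"))
}

card_from_json <- function(x, where) {
  if (is.null(x)) return(card_default())
  x <- unlist(x)
  if (length(x) != 2L) stop(mrcm_error(sprintf("%s: cardinality must be [min, max]", where)))
  ecl_cardinality(x[1], if (x[2] < 0) Inf else x[2])
}

card_to_json <- function(card) {
  c(card$min, if (is.infinite(card$max)) -1 else card$max)
}

#' Construct a processed concept model in code
#'
#' @param domains list of domain definitions as produced by `mrcm_domain()`.
#' @param edition free-text edition label echoed in outputs.
#' @return a `processed_mrcm`.
#' @export
processed_mrcm <- function(domains, edition = "synthetic") {
  if (!length(domains)) stop(mrcm_error("a concept model needs at least one domain"))
  ids <- vapply(domains, `[[`, character(1), "domain_id")
  if (anyDuplicated(ids)) stop(mrcm_error("duplicate domain ids"))
  structure(list(domains = domains, edition_label = edition), class = "processed_mrcm")
}

#' @rdname processed_mrcm
#' @param domain_id,name domain concept id and display name.
#' @param constraint ECL text delimiting the domain's concept set.
#' @param attributes list of `mrcm_attribute()` rules.
#' @export
mrcm_domain <- function(domain_id, name, constraint, attributes = list()) {
  assert_sctid(domain_id, "domain id")
  parsed <- tryCatch(parse_ecl(constraint), error = function(e) {
    stop(mrcm_error(sprintf("domain %s (%s): unparseable constraint: %s",
                            domain_id, name, conditionMessage(e))))
  })
  att_ids <- vapply(attributes, `[[`, character(1), "attribute_id")
  if (anyDuplicated(att_ids)) {
    stop(mrcm_error(sprintf("domain %s: duplicate attribute ids", domain_id)))
  }
  structure(list(domain_id = domain_id, name = name,
                 domain_constraint_ecl = constraint, constraint_ast = parsed,
                 attributes = attributes),
            class = "mrcm_domain")
}

#' @rdname processed_mrcm
#' @param attribute_id attribute concept id.
#' @param grouped logical; must the attribute be used inside a role group?
#' @param attribute_cardinality,in_group_cardinality [ecl_cardinality()]
#'   bounds for the attribute overall and within one role group.
#' @param range_ecl ECL text defining the permissible value set.
#' @export
mrcm_attribute <- function(attribute_id, name, range_ecl, grouped = TRUE,
                           attribute_cardinality = ecl_cardinality(0, Inf),
                           in_group_cardinality = ecl_cardinality(0, 1)) {
  assert_sctid(attribute_id, "attribute id")
  parsed <- tryCatch(parse_ecl(range_ecl), error = function(e) {
    stop(mrcm_error(sprintf("attribute %s (%s): unparseable range ECL: %s",
                            attribute_id, name, conditionMessage(e))))
  })
  structure(list(attribute_id = attribute_id, name = name, grouped = isTRUE(grouped),
                 attribute_cardinality = attribute_cardinality,
                 in_group_cardinality = in_group_cardinality,
                 range_ecl = range_ecl, range_ast = parsed),
            class = "mrcm_attribute")
}

#' @export
print.processed_mrcm <- function(x, ...) {
  cat(sprintf("<processed_mrcm> edition '%s', %d domain(s)\n",
              x$edition_label, length(x$domains)))
  for (d in x$domains) {
    cat(sprintf("  %s %s [%d attribute(s)]\n", d$domain_id, d$name,
                length(d$attributes)))
  }
  invisible(x)
}

#' Load a processed concept model from JSON
#'
#' All embedded ECL (domain constraints and attribute ranges) is parsed
#' eagerly; a malformed fragment fails the load with the offending domain
#' and attribute named.
#'
#' @param path path to a processed-MRCM JSON document.
#' @return a `processed_mrcm`.
#' @export
load_mrcm <- function(path) {
  if (!file.exists(path)) stop(mrcm_error(sprintf("file not found: %s", path)))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(doc$domains)) stop(mrcm_error("concept model document has no domains"))
  domains <- lapply(doc$domains, function(d) {
    atts <- lapply(d$attributes %||% list(), function(a) {
      mrcm_attribute(as.character(a$id), a$name %||% as.character(a$id),
                     range_ecl = a$range %||% "*",
                     grouped = isTRUE(a$grouped),
                     attribute_cardinality = card_from_json(a$cardinality,
                       sprintf("attribute %s", a$id)),
                     in_group_cardinality = card_from_json(a$inGroupCardinality,
                       sprintf("attribute %s", a$id)))
    })
    mrcm_domain(as.character(d$id), d$name %||% as.character(d$id),
                d$constraint %||% "*", atts)
  })
  processed_mrcm(domains, edition = doc$edition %||% "unlabelled")
}

#' Serialize a processed concept model to JSON
#'
#' @param m a `processed_mrcm`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrcm_json <- function(m, path) {
  doc <- list(
    edition = m$edition_label,
    domains = lapply(m$domains, function(d) {
      list(id = d$domain_id, name = d$name, constraint = d$domain_constraint_ecl,
           attributes = lapply(d$attributes, function(a) {
             list(id = a$attribute_id, name = a$name, grouped = a$grouped,
                  cardinality = card_to_json(a$attribute_cardinality),
                  inGroupCardinality = card_to_json(a$in_group_cardinality),
                  range = a$range_ecl)
           }))
    }))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE), path,
             useBytes = TRUE)
  invisible(path)
}

domain_members <- function(g, d) evaluate_ecl(d$constraint_ast, g)

#' Determine the concept-model domain of a focus concept
#'
#' A subsumption-based procedure: every domain whose evaluated constraint
#' set contains the focus is a candidate, and the most specific candidate
#' wins — the one whose constraint set is a subset of every other
#' candidate's set; ties are broken by smaller set size, then by domain id.
#'
#' @param g a [concept_graph()].
#' @param m a `processed_mrcm`.
#' @param focus an active concept id.
#' @return the matching `mrcm_domain`.
#' @export
domain_for <- function(g, m, focus) {
  if (!graph_has(g, focus)) stop(lookup_error(focus))
  sets <- lapply(m$domains, domain_members, g = g)
  idx <- which(vapply(sets, function(s) focus %in% s, logical(1)))
  if (!length(idx)) {
    stop(errorCondition(sprintf("no concept-model domain covers concept %s", focus),
                        class = c("eclkit_no_domain_error", "eclkit_error")))
  }
  ids <- vapply(m$domains, `[[`, character(1), "domain_id")
  ord <- idx[order(lengths(sets[idx]), nchar(ids[idx]), ids[idx], method = "radix")]
  for (i in ord) {
    if (all(vapply(idx, function(j) all(sets[[i]] %in% sets[[j]]), logical(1)))) {
      return(m$domains[[i]])
    }
  }
  m$domains[[ord[1]]]
}

#' Attributes applicable in a domain
#'
#' The domain's attribute rules in a stable order (grouped rules first,
#' then by name, then id), so builder menus are deterministic across runs.
#'
#' @param m a `processed_mrcm`.
#' @param d one of its `mrcm_domain`s.
#' @return list of `mrcm_attribute` rules.
#' @export
applicable_attributes <- function(m, d) {
  ids <- vapply(m$domains, `[[`, character(1), "domain_id")
  if (!d$domain_id %in% ids) stop(mrcm_error("domain does not belong to this concept model"))
  atts <- d$attributes
  if (!length(atts)) return(atts)
  grouped <- vapply(atts, `[[`, logical(1), "grouped")
  nm <- vapply(atts, `[[`, character(1), "name")
  aid <- vapply(atts, `[[`, character(1), "attribute_id")
  atts[order(!grouped, nm, aid, method = "radix")]
}

#' Permissible values of an attribute rule
#'
#' Simply the evaluation of the rule's range ECL over the graph: the set
#' of concepts allowed as values of the attribute.
#'
#' @param g a [concept_graph()].
#' @param rule an `mrcm_attribute`.
#' @return character vector of concept ids.
#' @export
allowed_values <- function(g, rule) {
  evaluate_ecl(rule$range_ast, g)
}

violation <- function(code, path, message) {
  list(code = code, path = path, message = message)
}

#' Semantic (concept-model) validation of an expression constraint
#'
#' Checks a query against the processed concept model: every attribute
#' constraint must use an attribute applicable in the focus concept's
#' domain (`ATTRIBUTE_NOT_IN_DOMAIN`), every concept selected by its value
#' expression must lie in the attribute's range (`VALUE_OUT_OF_RANGE`,
#' naming a witness concept), attributes the model marks as grouped must
#' appear inside a role group (`GROUPING_VIOLATION`), and a declared
#' cardinality must be `[1..*]`, `[0..0]` or lie within the rule's bounds
#' (`CARDINALITY_VIOLATION`). A focus outside every domain yields
#' `NO_DOMAIN`. Wildcard (and nested) foci skip the domain-dependent
#' checks, as do reverse constraints, whose direction the domain model
#' does not describe. A compound top level is validated per operand.
#'
#' @param e an `ecl_expression` or ECL text.
#' @param g a [concept_graph()].
#' @param m a `processed_mrcm`.
#' @return a `validation_report`: list with `valid` flag and `violations`,
#'   each violation carrying `code`, `path` (AST locator) and `message`.
#' @examples
#' fx <- demo_fixture()
#' validate_ecl("<< 64572001 : { 116676008 = << 55641003 }", fx$graph, fx$mrcm)$valid
#' @export
validate_ecl <- function(e, g, m) {
  if (is.character(e)) e <- parse_ecl(e)
  violations <- validate_node(normalize_expr(e), g, m, path = "e")
  structure(list(valid = length(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("valid\n")
  } else {
    cat(sprintf("invalid: %d violation(s)\n", length(x$violations)))
    for (v in x$violations) {
      cat(sprintf("  [%s] at %s: %s\n", v$code, v$path, v$message))
    }
  }
  invisible(x)
}

validate_node <- function(e, g, m, path) {
  if (e$kind == "compound") {
    out <- list()
    for (i in seq_along(e$operands)) {
      out <- c(out, validate_node(e$operands[[i]], g, m,
                                  sprintf("%s$operands[[%d]]", path, i)))
    }
    return(out)
  }
  if (is.null(e$refinement)) return(list())
  if (e$focus$kind != "concept") {
    # wildcard or nested focus: no single domain to gate against
    return(list())
  }
  focus <- e$focus$id
  if (!graph_has(g, focus)) {
    stop(eval_error(sprintf("unknown concept in expression: %s", focus)))
  }
  dom <- tryCatch(domain_for(g, m, focus), eclkit_no_domain_error = function(err) NULL)
  if (is.null(dom)) {
    return(list(violation("NO_DOMAIN", path,
                          sprintf("no concept-model domain covers focus %s", focus))))
  }
  out <- list()
  r <- e$refinement
  for (i in seq_along(r$items)) {
    it <- r$items[[i]]
    if (inherits(it, "ecl_group")) {
      for (j in seq_along(it$constraints)) {
        out <- c(out, validate_attr(it$constraints[[j]], g, dom, grouped_use = TRUE,
                                    sprintf("%s$refinement$items[[%d]]$constraints[[%d]]",
                                            path, i, j)))
      }
    } else {
      out <- c(out, validate_attr(it, g, dom, grouped_use = FALSE,
                                  sprintf("%s$refinement$items[[%d]]", path, i)))
    }
  }
  out
}

validate_attr <- function(a, g, dom, grouped_use, path) {
  if (a$reverse) return(list())
  if (a$attr_focus$kind != "concept") return(list())
  attr_id <- a$attr_focus$id
  rules <- dom$attributes
  rule <- NULL
  for (rr in rules) if (rr$attribute_id == attr_id) rule <- rr
  if (is.null(rule)) {
    return(list(violation("ATTRIBUTE_NOT_IN_DOMAIN", path,
      sprintf("attribute %s is not applicable in domain %s (%s)",
              attr_id, dom$domain_id, dom$name))))
  }
  out <- list()
  if (rule$grouped && !grouped_use) {
    out <- c(out, list(violation("GROUPING_VIOLATION", path,
      sprintf("attribute %s must be used inside a role group", attr_id))))
  }
  # a bare wildcard value names no concrete concept, so there is nothing
  # to hold against the range (the usual case is [0..0] A = *, "A absent")
  bare_wildcard <- a$value$kind == "simple" && a$value$op == "self" &&
    a$value$focus$kind == "wildcard" && is.null(a$value$refinement)
  stray <- if (bare_wildcard) character() else {
    setdiff(evaluate_ecl(a$value, g), allowed_values(g, rule))
  }
  if (length(stray)) {
    out <- c(out, list(violation("VALUE_OUT_OF_RANGE", path,
      sprintf("value %s (%s) is outside the range of attribute %s",
              stray[1], graph_fsn(g, stray[1]), attr_id))))
  }
  card <- a$cardinality
  is_negation <- card$min == 0 && card$max == 0
  bound <- if (grouped_use) rule$in_group_cardinality else rule$attribute_cardinality
  within <- card$min >= bound$min && card$max <= bound$max
  if (!is_default_card(card) && !is_negation && !within) {
    out <- c(out, list(violation("CARDINALITY_VIOLATION", path,
      sprintf("cardinality %s of attribute %s exceeds the model's %s",
              format(card), attr_id, format(bound)))))
  }
  out
}

#' Choices a guided query builder may offer next
#'
#' The builder-soundness contract: every option returned keeps
#' [validate_ecl()] green. With only a resolved focus, returns the
#' attribute rules of the focus concept's domain; given one of those
#' rules, returns the permissible value concepts and the range ECL they
#' come from.
#'
#' @param g a [concept_graph()].
#' @param m a `processed_mrcm`.
#' @param partial an `ecl_expression` (or ECL text) whose focus is a
#'   resolved concept.
#' @param attribute optional attribute id already chosen from the offered
#'   list.
#' @return a list with `domain` and `attributes`, plus `values` and
#'   `values_constraint` when `attribute` is given.
#' @export
builder_next_choices <- function(g, m, partial, attribute = NULL) {
  if (is.character(partial)) partial <- parse_ecl(partial)
  stopifnot(inherits(partial, "ecl_expression"))
  e <- normalize_expr(partial)
  if (e$kind != "simple" || e$focus$kind != "concept") {
    stop(mrcm_error("the builder needs a single resolved focus concept"))
  }
  dom <- domain_for(g, m, e$focus$id)
  rules <- applicable_attributes(m, dom)
  out <- list(domain = dom, attributes = rules)
  if (!is.null(attribute)) {
    rule <- NULL
    for (rr in rules) if (rr$attribute_id == attribute) rule <- rr
    if (is.null(rule)) {
      stop(mrcm_error(sprintf("attribute %s was not offered for domain %s",
                              attribute, dom$domain_id)))
    }
    out$values <- allowed_values(g, rule)
    out$values_constraint <- rule$range_ecl
  }
  out
}

#' Random guided-builder walk
#'
#' Simulates a user who only ever picks from the options
#' [builder_next_choices()] offers: a focus covered by some domain, then
#' one to `max_attributes` applicable attributes, values drawn from each
#' attribute's permissible set (one value, or two joined by a
#' parenthesized connective), grouped rules placed inside a role group,
#' occasional `[0..0]` negation and `!=` comparators. By construction the
#' result must validate; the soundness harness asserts exactly that.
#'
#' @param g a [concept_graph()].
#' @param m a `processed_mrcm`.
#' @param seed integer seed making the walk reproducible.
#' @param max_attributes most attributes to refine with.
#' @return an `ecl_expression`.
#' @export
builder_random_query <- function(g, m, seed, max_attributes = 3L) {
  with_seed(seed, {
    covered <- sct_sort(unique(unlist(lapply(m$domains, domain_members, g = g))))
    if (!length(covered)) stop(mrcm_error("no concept is covered by any domain"))
    focus <- sample_one(covered)
    partial <- ecl_constraint(focus, operator = sample_one(c("self", "<<", "<<", "<")))
    choices <- builder_next_choices(g, m, partial)
    rules <- choices$attributes
    usable <- Filter(function(rr) length(allowed_values(g, rr)) > 0, rules)
    if (!length(usable)) return(partial)
    n_att <- sample.int(min(max_attributes, length(usable)), 1L)
    picked <- usable[sample.int(length(usable), n_att)]
    constraints <- lapply(picked, function(rule) {
      vals <- builder_next_choices(g, m, partial, rule$attribute_id)$values
      value <- if (length(vals) > 1L && stats::runif(1) < 0.3) {
        two <- sample(vals, 2L)
        ecl_compound(sample_one(c("AND", "OR")),
                     list(ecl_constraint(two[1]), ecl_constraint(two[2])))
      } else {
        ecl_constraint(sample_one(vals))
      }
      card <- if (stats::runif(1) < 0.15) ecl_cardinality(0, 0) else NULL
      cmp <- if (stats::runif(1) < 0.15) "!=" else "="
      ecl_attribute(rule$attribute_id, value, comparator = cmp, cardinality = card)
    })
    grouped <- vapply(picked, `[[`, logical(1), "grouped")
    items <- list()
    if (any(grouped)) {
      items <- c(items, list(ecl_group(constraints[grouped], connective = "AND")))
    }
    items <- c(items, constraints[!grouped])
    ecl_constraint(partial$focus, operator = partial$op,
                   refinement = ecl_refinement(items, connective = "AND"))
  })
}

sample_one <- function(x) x[[sample.int(length(x), 1L)]]

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
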