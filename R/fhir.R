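# Local, in-process implementations of the FHIR R4 terminology operations
# ($lookup, $expand, $subsumes) over a concept_graph, plus the
# ECL -> FHIR-search cohort step: expand a query, comma-join the codes as a
# token search parameter, and scan Condition-like resources for matches.

SCT_SYSTEM <- "http://snomed.info/sct"

not_found_error <- function(code) {
  errorCondition(sprintf("code not found: %s", code),
                 class = c("eclkit_not_found_error", "eclkit_error"))
}

#' Concept lookup ($lookup)
#'
#' Retrieves the display name (FSN), designations and structural
#' properties — direct parents, direct children and defining attribute
#' relationships — of a concept, as a FHIR `$lookup` would.
#'
#' @param g a [concept_graph()].
#' @param code a concept id present in the graph.
#' @return a `lookup_result`: list with `code`, `display`, `active`,
#'   `designations`, `parents`, `children` and `relationships`.
#' @export
op_lookup <- function(g, code) {
  if (!graph_has(g, code)) stop(not_found_error(code))
  rel <- g$relationships[g$relationships$source == code, , drop = FALSE]
  structure(list(
    code = code,
    display = graph_fsn(g, code),
    active = is_active(g, code),
    designations = g$descriptions$term[g$descriptions$concept_id == code],
    parents = sct_sort(g$parents$parent[g$parents$child == code]),
    children = sct_sort(g$parents$child[g$parents$parent == code]),
    relationships = rel[order(rel$group, nchar(rel$type), rel$type,
                              method = "radix"), c("type", "target", "group")]
  ), class = "lookup_result")
}

#' ValueSet expansion ($expand)
#'
#' Resolves an ECL-defined ValueSet into the concrete, ascending-id list
#' of codes it selects, with offset/count paging over the stable order.
#'
#' @param g a [concept_graph()].
#' @param ecl ECL text or an `ecl_expression`.
#' @param offset first index (0-based) of the returned page.
#' @param count page size; `Inf` returns everything.
#' @param version_uri optional "system/version" URI echoed in the
#'   expansion metadata (it does not alter local semantics).
#' @return an `expansion`: list with `total`, `offset`, `version` and a
#'   `contains` data.frame (`system`, `code`, `display`).
#' @export
op_expand <- function(g, ecl, offset = 0L, count = Inf, version_uri = NULL) {
  stopifnot(offset >= 0, count >= 0)
  members <- tryCatch(evaluate_ecl(ecl, g), ecl_parse_error = function(e) {
    stop(errorCondition(paste0("invalid ECL in ValueSet: ", conditionMessage(e)),
                        class = c("eclkit_invalid_request_error", "eclkit_error")))
  })
  total <- length(members)
  page <- if (offset >= total) character() else {
    members[seq.int(offset + 1L, min(total, offset + count))]
  }
  contains <- data.frame(system = rep(SCT_SYSTEM, length(page)), code = page,
                         display = if (length(page)) graph_fsn(g, page) else character(),
                         stringsAsFactors = FALSE)
  structure(list(total = total, offset = as.integer(offset),
                 version = version_uri, contains = contains),
            class = "expansion")
}

#' @export
print.expansion <- function(x, ...) {
  cat(sprintf("<expansion> total %d, offset %d, %d code(s) in page\n",
              x$total, x$offset, nrow(x$contains)))
  invisible(x)
}

#' Subsumption testing ($subsumes)
#'
#' FHIR outcome codes: `equivalent` when the codes are identical,
#' `subsumes` when code B is a descendant of code A, `subsumed-by` for the
#' converse, `not-subsumed` otherwise.
#'
#' @param g a [concept_graph()].
#' @param code_a,code_b concept ids present in the graph.
#' @return one of `"equivalent"`, `"subsumes"`, `"subsumed-by"`,
#'   `"not-subsumed"`.
#' @export
op_subsumes <- function(g, code_a, code_b) {
  if (!graph_has(g, code_a)) stop(not_found_error(code_a))
  if (!graph_has(g, code_b)) stop(not_found_error(code_b))
  if (code_a == code_b) return("equivalent")
  if (subsumes(g, code_a, code_b)) return("subsumes")
  if (subsumes(g, code_b, code_a)) return("subsumed-by")
  "not-subsumed"
}

#' FHIR token search parameter from an expansion
#'
#' Comma-joined `system|code` entries in ascending code order — the FHIR
#' search dialect in which the comma means OR. The expansion must be
#' unpaged (contain its full code set).
#'
#' @param exp an `expansion` from [op_expand()].
#' @return a single string; empty expansion gives `""`.
#' @examples
#' fx <- demo_fixture()
#' build_search_param(op_expand(fx$graph, "22298006"))
#' @export
build_search_param <- function(exp) {
  stopifnot(inherits(exp, "expansion"))
  if (nrow(exp$contains) != exp$total) {
    stop(eval_error("build_search_param needs an unpaged (full) expansion"))
  }
  if (!exp$total) return("")
  codes <- sct_sort(exp$contains$code)
  paste(paste0(SCT_SYSTEM, "|", codes), collapse = ",")
}

#' Map a concept-model domain to FHIR resource types
#'
#' `default_domain_resource_map()` sends finding/disorder/situation-like
#' domains to `Condition` first, then `Observation`,
#' `AllergyIntolerance`, `Procedure` and `FamilyMemberHistory`;
#' procedure-like domains to `Procedure`. An unmapped domain falls back to
#' the full list of mapped types with a warning.
#'
#' @param map a named list: domain name -> character vector of FHIR
#'   resource type names.
#' @param domain an `mrcm_domain` (or its name as a string).
#' @return character vector of resource type names.
#' @export
resource_types_for <- function(map, domain) {
  name <- if (inherits(domain, "mrcm_domain")) domain$name else as.character(domain)
  key <- match_domain_key(names(map), name)
  if (is.na(key)) {
    warning(sprintf("no resource-type mapping for domain '%s'; falling back to all mapped types",
                    name), call. = FALSE)
    return(sort(unique(unlist(map))))
  }
  map[[key]]
}

match_domain_key <- function(keys, name) {
  lname <- tolower(name)
  hit <- which(vapply(keys, function(k) grepl(tolower(k), lname, fixed = TRUE) ||
                        tolower(k) == lname, logical(1)))
  if (length(hit)) keys[hit[1]] else NA_character_
}

#' @rdname resource_types_for
#' @export
default_domain_resource_map <- function() {
  clinical <- c("Condition", "Observation", "AllergyIntolerance", "Procedure",
                "FamilyMemberHistory")
  list(
    "clinical finding" = clinical,
    "disease" = clinical,
    "finding" = clinical,
    "situation" = clinical,
    "procedure" = c("Procedure", "ServiceRequest")
  )
}

#' Lightweight Condition resources
#'
#' `condition_lite()` is the minimal slice of a FHIR Condition this
#' package needs: a resource id, the patient reference, and the codings.
#' `read_conditions_ndjson()` parses one JSON resource per line (or a
#' Bundle of type collection/searchset via `read_conditions_bundle()`);
#' malformed entries are skipped with a warning and counted in the
#' `n_skipped` attribute.
#'
#' @param resource_id resource id string.
#' @param patient_ref patient reference, e.g. `"Patient/p001"`.
#' @param codings data.frame with columns `system` and `code` (at least
#'   one row).
#' @param resource_type FHIR resource type name (default `"Condition"`).
#' @return a `condition_lite` object.
#' @export
condition_lite <- function(resource_id, patient_ref, codings,
                           resource_type = "Condition") {
  if (!nrow(codings)) stop(graph_error("a Condition needs at least one coding"))
  structure(list(resource_id = as.character(resource_id),
                 patient_ref = as.character(patient_ref),
                 resource_type = resource_type,
                 codings = codings[, c("system", "code"), drop = FALSE]),
            class = "condition_lite")
}

parse_condition <- function(res) {
  if (is.null(res$resourceType) || is.null(res$id)) return(NULL)
  codings <- res$code$coding %||% list()
  if (!length(codings)) return(NULL)
  df <- data.frame(
    system = vapply(codings, function(cc) as.character(cc$system %||% ""), character(1)),
    code = vapply(codings, function(cc) as.character(cc$code %||% ""), character(1)),
    stringsAsFactors = FALSE)
  df <- df[nzchar(df$code), , drop = FALSE]
  if (!nrow(df)) return(NULL)
  condition_lite(res$id, res$subject$reference %||% "", df,
                 resource_type = res$resourceType)
}

#' @rdname condition_lite
#' @param path NDJSON (one resource per line) or Bundle JSON file.
#' @export
read_conditions_ndjson <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  skipped <- 0L
  for (ln in lines) {
    res <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                    error = function(e) NULL)
    cl <- if (is.null(res)) NULL else parse_condition(res)
    if (is.null(cl)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- cl
  }
  if (skipped) warning(sprintf("skipped %d malformed resource(s)", skipped),
                       call. = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}

#' @rdname condition_lite
#' @export
read_conditions_bundle <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$resourceType, "Bundle")) {
    stop(graph_error("not a FHIR Bundle document"))
  }
  out <- list()
  skipped <- 0L
  for (entry in doc$entry %||% list()) {
    cl <- parse_condition(entry$resource %||% list())
    if (is.null(cl)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- cl
  }
  if (skipped) warning(sprintf("skipped %d malformed resource(s)", skipped),
                       call. = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}

#' Cohort retrieval over coded resources
#'
#' A resource matches when its type is among `types` and at least one of
#' its codings uses the SNOMED CT system with a code inside the
#' expansion. Every matched code of a matching resource is reported; the
#' result is sorted by resource id and is invariant to input order.
#' `cohort_patients()` aggregates to the patient level: a patient matches
#' when at least one of their resources does.
#'
#' @param resources list of [condition_lite()] objects.
#' @param exp an unpaged `expansion` from [op_expand()].
#' @param types character vector of admissible resource type names.
#' @return data.frame with columns `resource_id`, `patient_ref`, `code`.
#' @export
cohort_search <- function(resources, exp, types = "Condition") {
  stopifnot(inherits(exp, "expansion"))
  codes <- exp$contains$code
  rows <- lapply(resources, function(res) {
    if (!res$resource_type %in% types) return(NULL)
    hit <- res$codings$system == SCT_SYSTEM & res$codings$code %in% codes
    if (!any(hit)) return(NULL)
    data.frame(resource_id = res$resource_id, patient_ref = res$patient_ref,
               code = unique(res$codings$code[hit]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(resource_id = character(),
                                          patient_ref = character(),
                                          code = character(),
                                          stringsAsFactors = FALSE)),
                          rows))
  out <- out[order(out$resource_id, out$code, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname cohort_search
#' @param matches the data.frame returned by `cohort_search()`.
#' @return `cohort_patients()`: sorted character vector of patient
#'   references with at least one matching resource.
#' @export
cohort_patients <- function(matches) {
  sort(unique(matches$patient_ref))
}

#' FHIR JSON shapes for the terminology operations
#'
#' Convert operation results into the FHIR R4 resource shapes a server
#' would return: a `Parameters` resource for `$lookup` and `$subsumes`, a
#' `ValueSet` with an `expansion` element for `$expand`, and an
#' `OperationOutcome` for errors. The returned lists serialize directly
#' with `jsonlite::toJSON(x, auto_unbox = TRUE)`.
#'
#' @param x a `lookup_result`, `expansion`, or outcome string.
#' @return a plain list in the corresponding FHIR shape.
#' @export
fhir_lookup_parameters <- function(x) {
  stopifnot(inherits(x, "lookup_result"))
  props <- c(
    lapply(x$parents, function(p) list(name = "property", part = list(
      list(name = "code", valueCode = "parent"),
      list(name = "value", valueCode = p)))),
    lapply(x$children, function(p) list(name = "property", part = list(
      list(name = "code", valueCode = "child"),
      list(name = "value", valueCode = p)))))
  list(resourceType = "Parameters", parameter = c(
    list(list(name = "name", valueString = "SNOMED CT"),
         list(name = "display", valueString = x$display),
         list(name = "inactive", valueBoolean = !x$active)),
    lapply(x$designations, function(d) list(name = "designation", part = list(
      list(name = "value", valueString = d)))),
    props))
}

#' @rdname fhir_lookup_parameters
#' @export
fhir_expansion_valueset <- function(x) {
  stopifnot(inherits(x, "expansion"))
  contains <- lapply(seq_len(nrow(x$contains)), function(i) {
    entry <- list(system = x$contains$system[i], code = x$contains$code[i],
                  display = x$contains$display[i])
    if (!is.null(x$version)) entry$version <- x$version
    entry
  })
  list(resourceType = "ValueSet",
       expansion = list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                        total = x$total, offset = x$offset, contains = contains))
}

#' @rdname fhir_lookup_parameters
#' @param outcome a subsumption outcome string from [op_subsumes()].
#' @export
fhir_subsumes_parameters <- function(outcome) {
  list(resourceType = "Parameters",
       parameter = list(list(name = "outcome", valueCode = outcome)))
}

#' @rdname fhir_lookup_parameters
#' @param severity,code,diagnostics OperationOutcome issue fields.
#' @export
fhir_operation_outcome <- function(severity, code, diagnostics) {
  list(resourceType = "OperationOutcome",
       issue = list(list(severity = severity, code = code,
                         diagnostics = diagnostics)))
}
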