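#' @importFrom igraph graph_from_data_frame is_dag subcomponent V make_empty_graph
NULL

#' Construct a concept graph
#'
#' The in-memory representation of a (mini) SNOMED CT-like ontology: active
#' and inactive concepts, their descriptions, stated is-a parents, and the
#' fully materialized defining attribute relationships with role-group
#' numbers. The is-a edges must form a DAG. Relationships are stored as the
#' post-inheritance ("inferred view") a terminology server would query;
#' evaluation never propagates attributes down the hierarchy itself.
#'
#' @param concepts data.frame with columns `id`, `fsn`, `active` (logical).
#' @param parents data.frame with columns `child`, `parent` (is-a edges).
#' @param descriptions data.frame with columns `concept_id`, `term`, `is_fsn`.
#' @param relationships data.frame with columns `source`, `type`, `target`,
#'   `group` (integer, 0 = ungrouped).
#' @return an object of class `concept_graph`.
#' @export
concept_graph <- function(concepts,
                          parents = data.frame(child = character(), parent = character()),
                          descriptions = NULL,
                          relationships = data.frame(source = character(), type = character(),
                                                     target = character(), group = integer())) {
  concepts$id <- as.character(concepts$id)
  assert_sctid(concepts$id)
  if (anyDuplicated(concepts$id)) {
    stop(graph_error(sprintf("duplicate concept id: %s",
                             concepts$id[duplicated(concepts$id)][1])))
  }
  if (is.null(descriptions)) {
    descriptions <- data.frame(concept_id = concepts$id, term = concepts$fsn,
                               is_fsn = TRUE, stringsAsFactors = FALSE)
  }
  for (col in c("child", "parent")) parents[[col]] <- as.character(parents[[col]])
  for (col in c("source", "type", "target")) relationships[[col]] <- as.character(relationships[[col]])
  relationships$group <- as.integer(relationships$group)
  descriptions$concept_id <- as.character(descriptions$concept_id)

  known <- concepts$id
  check_ref <- function(ids, what) {
    missing <- setdiff(ids, known)
    if (length(missing)) {
      stop(graph_error(sprintf("%s references unknown concept: %s",
                               what, missing[1])))
    }
  }
  check_ref(parents$child, "is-a edge")
  check_ref(parents$parent, "is-a edge")
  check_ref(relationships$source, "relationship")
  check_ref(relationships$type, "relationship type")
  check_ref(relationships$target, "relationship target")
  check_ref(descriptions$concept_id, "description")
  if (any(!nzchar(descriptions$term))) stop(graph_error("empty description term"))
  if (any(relationships$group < 0L)) stop(graph_error("negative role group number"))

  # is-a edges child -> parent; a DAG is required
  if (nrow(parents)) {
    ig <- igraph::graph_from_data_frame(parents, directed = TRUE,
                                        vertices = data.frame(name = known))
    if (!igraph::is_dag(ig)) {
      stop(graph_error(paste0("is-a hierarchy contains a cycle: ",
                              paste(find_cycle(parents), collapse = " -> "))))
    }
  } else {
    ig <- igraph::graph_from_data_frame(
      data.frame(child = character(), parent = character()),
      directed = TRUE, vertices = data.frame(name = known))
  }

  g <- structure(list(concepts = concepts, parents = parents,
                      descriptions = descriptions, relationships = relationships,
                      ig = ig),
                 class = "concept_graph")
  g
}

# one cycle through DFS on the child->parent edge list, for the loader error
find_cycle <- function(parents) {
  adj <- split(parents$parent, parents$child)
  state <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = state, ifnotfound = list(0L))[[1]]
    if (st == 1L) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == 2L) return()
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) visit(w)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in unique(parents$child)) {
    visit(v)
    if (!is.null(found)) break
  }
  found %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

graph_error <- function(msg) {
  errorCondition(msg, class = c("eclkit_graph_error", "eclkit_error"))
}

lookup_error <- function(id) {
  errorCondition(sprintf("unknown concept: %s", id),
                 class = c("eclkit_lookup_error", "eclkit_error"))
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf("<concept_graph> %d concepts (%d active), %d is-a edges, %d relationships\n",
              nrow(x$concepts), sum(x$concepts$active), nrow(x$parents),
              nrow(x$relationships)))
  invisible(x)
}

graph_has <- function(g, id) id %in% g$concepts$id

graph_active <- function(g) g$concepts$id[g$concepts$active]

graph_fsn <- function(g, id) {
  g$concepts$fsn[match(id, g$concepts$id)]
}

is_active <- function(g, id) {
  isTRUE(g$concepts$active[match(id, g$concepts$id)])
}

#' Load a concept graph from the compact JSON ontology format
#'
#' Expected schema:
#' `{"concepts": [{"id", "fsn", "active", "parents": [...],`
#' `"descriptions": [{"term","fsn"}], "relationships": [{"type","target","group"}]}]}`.
#' Inactive concepts are retained (for lookup display) but excluded from all
#' closure and query results.
#'
#' @param path path to a JSON file.
#' @return a [concept_graph()].
#' @export
load_ontology_json <- function(path) {
  if (!file.exists(path)) stop(graph_error(sprintf("file not found: %s", path)))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$concepts)) stop(graph_error("JSON ontology missing 'concepts' array"))
  ids <- character(); fsns <- character(); actives <- logical()
  pr_child <- character(); pr_parent <- character()
  d_cid <- character(); d_term <- character(); d_fsn <- logical()
  r_src <- character(); r_type <- character(); r_tgt <- character(); r_grp <- integer()
  for (cpt in doc$concepts) {
    if (is.null(cpt$id) || is.null(cpt$fsn)) {
      stop(graph_error(sprintf("concept entry missing id or fsn (near id '%s')",
                               cpt$id %||% "?")))
    }
    id <- as.character(cpt$id)
    if (!is_sctid(id)) stop(graph_error(sprintf("invalid concept id: %s", id)))
    ids <- c(ids, id)
    fsns <- c(fsns, as.character(cpt$fsn))
    actives <- c(actives, isTRUE(cpt$active %||% TRUE))
    for (p in cpt$parents %||% list()) {
      pr_child <- c(pr_child, id); pr_parent <- c(pr_parent, as.character(p))
    }
    descs <- cpt$descriptions %||% list()
    if (!length(descs)) descs <- list(list(term = cpt$fsn, fsn = TRUE))
    n_fsn_desc <- 0L
    for (d in descs) {
      d_cid <- c(d_cid, id)
      d_term <- c(d_term, as.character(d$term %||% ""))
      isf <- isTRUE(d$fsn %||% FALSE)
      n_fsn_desc <- n_fsn_desc + isf
      d_fsn <- c(d_fsn, isf)
    }
    if (n_fsn_desc > 1L) {
      stop(graph_error(sprintf("concept %s has more than one preferred FSN", id)))
    }
    for (r in cpt$relationships %||% list()) {
      r_src <- c(r_src, id)
      r_type <- c(r_type, as.character(r$type))
      r_tgt <- c(r_tgt, as.character(r$target))
      r_grp <- c(r_grp, as.integer(r$group %||% 0L))
    }
  }
  concept_graph(
    concepts = data.frame(id = ids, fsn = fsns, active = actives, stringsAsFactors = FALSE),
    parents = data.frame(child = pr_child, parent = pr_parent, stringsAsFactors = FALSE),
    descriptions = data.frame(concept_id = d_cid, term = d_term, is_fsn = d_fsn,
                              stringsAsFactors = FALSE),
    relationships = data.frame(source = r_src, type = r_type, target = r_tgt,
                               group = r_grp, stringsAsFactors = FALSE))
}

#' Load a concept graph from simplified RF2-style snapshot tables
#'
#' Reads three headered tab-separated files: concepts (`id`, `active`),
#' descriptions (`conceptId`, `term`, `typeId`) and relationships
#' (`sourceId`, `destinationId`, `typeId`, `relationshipGroup`, `active`).
#' Relationship rows whose `typeId` equals `isa_type_id` become is-a parent
#' edges; all other active rows become defining attribute relationships.
#' Active flags may be logical or the RF2 `0`/`1` convention.
#'
#' @param concept_tsv,description_tsv,relationship_tsv file paths.
#' @param isa_type_id the relationship type identifier treated as is-a
#'   (default the SNOMED CT "Is a" concept, 116680003).
#' @param fsn_type_id the description type identifier treated as FSN.
#' @return a [concept_graph()], structurally identical to what
#'   [load_ontology_json()] yields on equivalent content.
#' @export
load_rf2_snapshot <- function(concept_tsv, description_tsv, relationship_tsv,
                              isa_type_id = "116680003",
                              fsn_type_id = "900000000000003001") {
  read_tsv <- function(path, required) {
    if (!file.exists(path)) stop(graph_error(sprintf("file not found: %s", path)))
    df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "")
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(graph_error(sprintf("%s: missing column(s): %s", path,
                               paste(missing, collapse = ", "))))
    }
    df
  }
  as_flag <- function(x) x %in% c("1", "true", "TRUE", "True")

  con <- read_tsv(concept_tsv, c("id", "active"))
  des <- read_tsv(description_tsv, c("conceptId", "term", "typeId"))
  rel <- read_tsv(relationship_tsv, c("sourceId", "destinationId", "typeId",
                                      "relationshipGroup", "active"))
  rel <- rel[as_flag(rel$active), , drop = FALSE]
  isa <- rel[rel$typeId == isa_type_id, , drop = FALSE]
  att <- rel[rel$typeId != isa_type_id, , drop = FALSE]

  des$is_fsn <- des$typeId == fsn_type_id
  fsn_term <- des$term[des$is_fsn][match(con$id, des$conceptId[des$is_fsn])]
  fsn_term[is.na(fsn_term)] <- con$id[is.na(fsn_term)]

  concept_graph(
    concepts = data.frame(id = con$id, fsn = fsn_term, active = as_flag(con$active),
                          stringsAsFactors = FALSE),
    parents = data.frame(child = isa$sourceId, parent = isa$destinationId,
                         stringsAsFactors = FALSE),
    descriptions = data.frame(concept_id = des$conceptId, term = des$term,
                              is_fsn = des$is_fsn, stringsAsFactors = FALSE),
    relationships = data.frame(source = att$sourceId, type = att$typeId,
                               target = att$destinationId,
                               group = as.integer(att$relationshipGroup),
                               stringsAsFactors = FALSE))
}

closure <- function(g, id, mode, include_self) {
  if (!graph_has(g, id)) stop(lookup_error(id))
  # edges run child -> parent: "out" reaches ancestors, "in" descendants
  ids <- names(igraph::subcomponent(g$ig, id, mode = mode))
  if (!include_self) ids <- setdiff(ids, id)
  sct_sort(intersect(ids, graph_active(g)))
}

#' Transitive closure queries over the is-a hierarchy
#'
#' `descendants()` returns every active concept reachable downwards from
#' `id` (its transitive specializations); `ancestors()` the dual. With
#' `include_self = TRUE` the closure is reflexive, matching the `<<` / `>>`
#' ECL operators; without, it matches `<` / `>`.
#'
#' @param g a [concept_graph()].
#' @param id a concept identifier present in `g`.
#' @param include_self include `id` itself in the result.
#' @return character vector of concept ids in ascending SCTID order.
#' @export
descendants <- function(g, id, include_self = FALSE) {
  closure(g, id, "in", include_self)
}

#' @rdname descendants
#' @export
ancestors <- function(g, id, include_self = FALSE) {
  closure(g, id, "out", include_self)
}

#' Is-a subsumption test
#'
#' `subsumes(g, a, b)` is `TRUE` iff `b` is `a` itself or one of its
#' descendants — the hierarchical relationship FHIR's `$subsumes` reports.
#'
#' @param g a [concept_graph()].
#' @param a,b concept identifiers.
#' @return logical scalar.
#' @export
subsumes <- function(g, a, b) {
  if (!graph_has(g, a)) stop(lookup_error(a))
  if (!graph_has(g, b)) stop(lookup_error(b))
  b %in% closure(g, a, "in", include_self = TRUE)
}

#' Word-prefix concept search
#'
#' A description matches when every whitespace-separated query token is a
#' case-insensitive prefix of some word of the description, in any order —
#' so `"dis"` finds both "Disease" and "Optic disc normal", and
#' `"disc optic"` still finds the latter. Description words are split on
#' whitespace and hyphens. If the query is itself a valid SCTID present in
#' the graph, that exact concept is returned first. Only active concepts
#' are searched. Results are ordered by (term length, term, id) and
#' truncated at `limit`.
#'
#' @param g a [concept_graph()].
#' @param query search text; at least `min_chars` characters.
#' @param limit maximum number of rows returned.
#' @param min_chars minimum query length (default 2).
#' @return data.frame with columns `id` and `term`.
#' @export
search_concepts <- function(g, query, limit = 50L, min_chars = 2L) {
  query <- trimws(query)
  if (nchar(query) < min_chars) {
    stop(errorCondition(sprintf("query must have at least %d characters", min_chars),
                        class = c("eclkit_input_error", "eclkit_error")))
  }
  active <- graph_active(g)
  hits <- data.frame(id = character(), term = character(), stringsAsFactors = FALSE)
  if (is_sctid(query) && query %in% active) {
    hits <- data.frame(id = query, term = graph_fsn(g, query), stringsAsFactors = FALSE)
  }
  tokens <- tolower(strsplit(query, "[[:space:]]+")[[1]])
  tokens <- tokens[nzchar(tokens)]
  d <- g$descriptions[g$descriptions$concept_id %in% active, , drop = FALSE]
  if (length(tokens) && nrow(d)) {
    words <- strsplit(tolower(d$term), "[[:space:]-]+")
    match_row <- vapply(words, function(w) {
      w <- w[nzchar(w)]
      all(vapply(tokens, function(tk) any(startsWith(w, tk)), logical(1)))
    }, logical(1))
    m <- d[match_row, , drop = FALSE]
    m <- m[order(nchar(m$term), m$term, m$concept_id, method = "radix"), , drop = FALSE]
    hits <- rbind(hits, data.frame(id = m$concept_id, term = m$term,
                                   stringsAsFactors = FALSE))
    hits <- hits[!duplicated(paste(hits$id, hits$term)), , drop = FALSE]
  }
  rownames(hits) <- NULL
  utils::head(hits, limit)
}

#' Serialize a concept graph to the compact JSON ontology format
#'
#' Output is deterministic: concepts, parents, descriptions and
#' relationships are emitted in a fixed sort order, so identical graphs
#' produce byte-identical files.
#'
#' @param g a [concept_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_json <- function(g, path) {
  ids <- sct_sort(g$concepts$id)
  concepts <- lapply(ids, function(id) {
    row <- g$concepts[g$concepts$id == id, ]
    pars <- sct_sort(g$parents$parent[g$parents$child == id])
    des <- g$descriptions[g$descriptions$concept_id == id, , drop = FALSE]
    des <- des[order(!des$is_fsn, des$term, method = "radix"), , drop = FALSE]
    rel <- g$relationships[g$relationships$source == id, , drop = FALSE]
    rel <- rel[order(rel$group, nchar(rel$type), rel$type,
                     nchar(rel$target), rel$target, method = "radix"), , drop = FALSE]
    list(id = id, fsn = row$fsn, active = row$active,
         parents = as.list(pars),
         descriptions = lapply(seq_len(nrow(des)), function(i)
           list(term = des$term[i], fsn = des$is_fsn[i])),
         relationships = lapply(seq_len(nrow(rel)), function(i)
           list(type = rel$type[i], target = rel$target[i], group = rel$group[i])))
  })
  json <- jsonlite::toJSON(list(concepts = concepts), auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
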