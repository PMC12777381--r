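# Seeded generators for ontologies, consistent concept models and
# SNOMED-coded FHIR cohorts, plus the deterministic curated demo fixture.
#
# Synthetic identifiers are drawn from a reserved 9-prefixed 9-digit range
# (900000xxx) so no invented id can be mistaken for a real SCTID; every
# generated concept's FSN carries a "(synthetic)"-style semantic tag.

param_error <- function(msg) {
  errorCondition(msg, class = c("eclkit_param_error", "eclkit_error"))
}

synthetic_id <- function(k) sprintf("9%08d", k)

#' Generate a random ontology
#'
#' Produces a single-rooted DAG of exactly `n_concepts` active concepts.
#' Non-root concepts are placed on levels `1..depth` and draw 1 to
#' `max_parents` parents from strictly shallower levels, which guarantees
#' acyclicity. When `n_attribute_types > 0` an attribute subtree (one
#' branch root plus that many attribute-type concepts) is carved out of
#' the concept budget, and defining attribute relationships are assigned
#' to the remaining concepts: each relationship gets a role-group number
#' of 1 or 2 with probability `group_probability` (0 = ungrouped
#' otherwise), and children repeat their parents' defining relationships
#' (materialized inheritance) before adding their own. The same seed
#' always yields a byte-identical serialized graph.
#'
#' @param n_concepts total number of concepts (>= 1).
#' @param max_parents most is-a parents a concept may have.
#' @param depth number of hierarchy levels below the root.
#' @param n_attribute_types number of attribute-type concepts.
#' @param group_probability probability a relationship is grouped.
#' @param seed integer seed.
#' @return a [concept_graph()].
#' @export
generate_ontology <- function(n_concepts, max_parents = 2L, depth = 3L,
                              n_attribute_types = 2L, group_probability = 0.5,
                              seed = 1L) {
  if (n_concepts < 1L) stop(param_error("n_concepts must be >= 1"))
  if (depth < 1L || max_parents < 1L) stop(param_error("depth and max_parents must be >= 1"))
  n_attr_block <- if (n_attribute_types > 0L) n_attribute_types + 1L else 0L
  n_hier <- n_concepts - 1L - n_attr_block
  if (n_hier < 0L) stop(param_error("n_concepts too small for the attribute subtree"))
  if (n_concepts > 1L && depth > n_hier + n_attr_block) {
    stop(param_error("depth exceeds the number of non-root concepts"))
  }
  with_seed(seed, {
    next_id <- 0L
    new_id <- function() {
      next_id <<- next_id + 1L
      synthetic_id(next_id)
    }
    root <- new_id()
    ids <- root
    fsns <- "Synthetic root concept (synthetic)"
    level <- c(0L)
    pr_child <- character(); pr_parent <- character()

    attr_ids <- character()
    if (n_attribute_types > 0L) {
      attr_root <- new_id()
      ids <- c(ids, attr_root)
      fsns <- c(fsns, "Synthetic attribute (attribute)")
      level <- c(level, 1L)
      pr_child <- c(pr_child, attr_root); pr_parent <- c(pr_parent, root)
      for (k in seq_len(n_attribute_types)) {
        aid <- new_id()
        attr_ids <- c(attr_ids, aid)
        ids <- c(ids, aid)
        fsns <- c(fsns, sprintf("Synthetic attribute %d (attribute)", k))
        level <- c(level, 2L)
        pr_child <- c(pr_child, aid); pr_parent <- c(pr_parent, attr_root)
      }
    }

    hier_ids <- character()
    if (n_hier > 0L) {
      # guarantee the requested depth with one chain, then fill levels randomly
      lv <- integer(n_hier)
      chain <- seq_len(min(depth, n_hier))
      lv[chain] <- chain
      if (n_hier > length(chain)) {
        lv[(length(chain) + 1L):n_hier] <-
          sample.int(depth, n_hier - length(chain), replace = TRUE)
      }
      lv <- sort(lv)
      for (k in seq_len(n_hier)) {
        cid <- new_id()
        pool <- c(root, hier_ids)
        pool_lv <- c(0L, lv[seq_len(k - 1L)])
        pool <- pool[pool_lv < lv[k]]
        n_par <- sample.int(min(max_parents, length(pool)), 1L)
        pars <- if (length(pool) == 1L) pool else sample(pool, n_par)
        pr_child <- c(pr_child, rep(cid, length(pars)))
        pr_parent <- c(pr_parent, pars)
        hier_ids <- c(hier_ids, cid)
        ids <- c(ids, cid)
        fsns <- c(fsns, sprintf("Synthetic concept %s (synthetic)", cid))
        level <- c(level, lv[k])
      }
    }

    # defining relationships with materialized inheritance, assigned in
    # level order so children can copy their parents' view
    rel <- list()
    rel_of <- new.env(parent = emptyenv())
    ord <- order(level[match(c(root, hier_ids), ids)])
    targets_pool <- c(root, hier_ids)
    for (cid in c(root, hier_ids)[ord]) {
      inherited <- data.frame(type = character(), target = character(),
                              group = integer(), stringsAsFactors = FALSE)
      pars <- pr_parent[pr_child == cid]
      for (p in intersect(pars, c(root, hier_ids))) {
        pv <- mget(p, envir = rel_of, ifnotfound = list(NULL))[[1]]
        if (!is.null(pv)) inherited <- rbind(inherited, pv)
      }
      own <- inherited
      if (length(attr_ids) && cid != root && stats::runif(1) < 0.5) {
        n_new <- sample.int(2L, 1L)
        for (j in seq_len(n_new)) {
          grp <- if (stats::runif(1) < group_probability) sample.int(2L, 1L) else 0L
          own <- rbind(own, data.frame(
            type = sample_one(attr_ids),
            target = sample_one(targets_pool),
            group = grp, stringsAsFactors = FALSE))
        }
      }
      own <- own[!duplicated(own), , drop = FALSE]
      assign(cid, own, envir = rel_of)
      if (nrow(own)) {
        rel[[length(rel) + 1L]] <- cbind(data.frame(source = rep(cid, nrow(own)),
                                                    stringsAsFactors = FALSE), own)
      }
    }
    relationships <- if (length(rel)) do.call(rbind, rel) else
      data.frame(source = character(), type = character(), target = character(),
                 group = integer(), stringsAsFactors = FALSE)

    descriptions <- data.frame(
      concept_id = c(ids, ids),
      term = c(fsns, sub(" \\((synthetic|attribute)\\)$", "", fsns)),
      is_fsn = c(rep(TRUE, length(ids)), rep(FALSE, length(ids))),
      stringsAsFactors = FALSE)

    concept_graph(
      concepts = data.frame(id = ids, fsn = fsns, active = TRUE,
                            stringsAsFactors = FALSE),
      parents = data.frame(child = pr_child, parent = pr_parent,
                           stringsAsFactors = FALSE),
      descriptions = descriptions,
      relationships = relationships)
  })
}

#' Generate a concept model consistent with a graph
#'
#' Picks `n_domains` distinct internal concepts (the root first) as domain
#' roots with constraints `<< root_i`, and equips every domain with
#' attribute rules whose ranges (`<< subtree`) are non-empty in the graph,
#' so each (domain, attribute, range) triple admits at least one valid
#' query. Attribute types are taken from the graph's attribute-tagged
#' concepts.
#'
#' @param g a [concept_graph()] (typically from [generate_ontology()]).
#' @param n_domains number of domains.
#' @param seed integer seed.
#' @return a `processed_mrcm`.
#' @export
generate_mrcm <- function(g, n_domains = 1L, seed = 1L) {
  attr_ids <- g$concepts$id[grepl("\\(attribute\\)$", g$concepts$fsn)]
  attr_root <- attr_ids[!attr_ids %in% g$parents$child[g$parents$parent %in% attr_ids]]
  attr_types <- setdiff(attr_ids, g$concepts$id[g$concepts$fsn == "Synthetic attribute (attribute)"])
  if (!length(attr_types)) stop(param_error("graph has no attribute-type concepts"))
  internal <- unique(g$parents$parent)
  internal <- setdiff(internal, attr_ids)
  if (length(internal) < n_domains) {
    stop(param_error("graph has too few internal concepts for the requested domains"))
  }
  with_seed(seed, {
    root <- setdiff(internal, g$parents$child)
    others <- setdiff(internal, root)
    roots <- c(root, if (n_domains > 1L) sample(others, n_domains - 1L))
    roots <- roots[seq_len(n_domains)]
    range_roots <- internal
    domains <- lapply(seq_along(roots), function(i) {
      rid <- roots[i]
      n_att <- sample.int(min(3L, length(attr_types)), 1L)
      atts <- sample(attr_types, n_att)
      rules <- lapply(seq_along(atts), function(j) {
        rr <- sample_one(range_roots)
        mrcm_attribute(atts[j], sprintf("Synthetic attribute %s", atts[j]),
                       range_ecl = paste0("<< ", rr),
                       grouped = stats::runif(1) < 0.5,
                       attribute_cardinality = ecl_cardinality(0, Inf),
                       in_group_cardinality = ecl_cardinality(0, 1))
      })
      mrcm_domain(rid, sprintf("Synthetic domain %s", rid),
                  constraint = paste0("<< ", rid), attributes = rules)
    })
    processed_mrcm(domains, edition = sprintf("synthetic-seed-%d", seed))
  })
}

#' Generate a synthetic SNOMED-coded cohort
#'
#' `n_patients` patients each receive a number of Condition resources
#' drawn uniformly from `codes_per_patient`, with codes sampled from the
#' graph's active concepts under `prevalence_bias` weights (uniform by
#' default). Deterministic per seed; serializable to NDJSON with
#' [write_conditions_ndjson()] byte-identically.
#'
#' @param g a [concept_graph()].
#' @param n_patients number of patients (>= 0).
#' @param codes_per_patient integer range (length-2) of resources per
#'   patient.
#' @param prevalence_bias optional named numeric vector of non-negative
#'   sampling weights over concept ids (missing concepts get weight 0).
#' @param seed integer seed.
#' @return list of [condition_lite()] objects.
#' @export
generate_cohort <- function(g, n_patients, codes_per_patient = c(1L, 3L),
                            prevalence_bias = NULL, seed = 1L) {
  if (n_patients < 0L) stop(param_error("n_patients must be >= 0"))
  pool <- graph_active(g)
  w <- rep(1, length(pool))
  if (!is.null(prevalence_bias)) {
    if (any(prevalence_bias < 0) || !length(names(prevalence_bias))) {
      stop(param_error("prevalence_bias must be a named non-negative weight vector"))
    }
    w <- as.numeric(prevalence_bias[pool])
    w[is.na(w)] <- 0
    if (sum(w) <= 0) stop(param_error("prevalence_bias assigns no weight to any active concept"))
  }
  with_seed(seed, {
    out <- list()
    serial <- 0L
    for (p in seq_len(n_patients)) {
      pref <- sprintf("Patient/p%04d", p)
      k <- sample(seq.int(codes_per_patient[1], codes_per_patient[2]), 1L)
      for (j in seq_len(k)) {
        serial <- serial + 1L
        code <- sample(pool, 1L, prob = w)
        out[[serial]] <- condition_lite(
          sprintf("cond-%05d", serial), pref,
          data.frame(system = SCT_SYSTEM, code = code, stringsAsFactors = FALSE))
      }
    }
    out
  })
}

#' @rdname generate_cohort
#' @param resources list of [condition_lite()] objects.
#' @param path output NDJSON path (one Condition JSON object per line).
#' @export
write_conditions_ndjson <- function(resources, path) {
  lines <- vapply(resources, function(res) {
    doc <- list(resourceType = res$resource_type, id = res$resource_id,
                subject = list(reference = res$patient_ref),
                code = list(coding = lapply(seq_len(nrow(res$codings)), function(i) {
                  list(system = res$codings$system[i], code = res$codings$code[i])
                })))
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Curated demonstration fixture
#'
#' A deterministic hand-authored mini-ontology and matching concept model
#' covering the classic cardiology/morphology examples: Disease,
#' Myocardial infarction, Infarct, Associated morphology, Due to, Finding
#' site, Lung structure and its parts, and Procedure, with 9-prefixed
#' synthetic filler concepts (a clinical-finding analog, body structures,
#' a chromium-cobalt-alloy analog excluded from the morphology range, and
#' several disorders). Relationships are arranged so that the infarct
#' refinement query
#' `<< 64572001 : { 116676008 = << 55641003 OR 42752001 = << 22298006 }`
#' and the lung-site query
#' `<< 64572001 : { 363698007 = << 119199005 }`
#' are satisfiable and discriminate between fixture disorders.
#'
#' @return list with elements `graph` (a [concept_graph()]) and `mrcm`
#'   (a `processed_mrcm`).
#' @examples
#' fx <- demo_fixture()
#' ecl_count("<< 64572001", fx$graph)
#' @export
demo_fixture <- function() {
  cc <- function(id, fsn) data.frame(id = id, fsn = fsn, active = TRUE,
                                     stringsAsFactors = FALSE)
  concepts <- rbind(
    cc("900000001", "Synthetic root concept (synthetic)"),
    cc("900000002", "Clinical finding analog (finding)"),
    cc("64572001",  "Disease (disorder)"),
    cc("22298006",  "Myocardial infarction (disorder)"),
    cc("900000021", "Cerebral infarction analog (disorder)"),
    cc("900000022", "Ventricular aneurysm after myocardial infarction analog (disorder)"),
    cc("900000023", "Lobar pneumonia analog (disorder)"),
    cc("900000024", "Pulmonary disease analog (disorder)"),
    cc("900000025", "Fracture disorder analog (disorder)"),
    cc("900000026", "Split-group disorder analog (disorder)"),
    cc("900000027", "Same-group disorder analog (disorder)"),
    cc("900000003", "Body structure analog (body structure)"),
    cc("39607008",  "Lung structure (body structure)"),
    cc("119199005", "Lung part (body structure)"),
    cc("900000017", "Upper lobe of lung analog (body structure)"),
    cc("900000015", "Heart structure analog (body structure)"),
    cc("900000004", "Morphologically abnormal structure analog (morphologic abnormality)"),
    cc("55641003",  "Infarct (morphologic abnormality)"),
    cc("900000011", "Embolic infarct analog (morphologic abnormality)"),
    cc("900000016", "Aneurysm analog (morphologic abnormality)"),
    cc("900000018", "Fracture analog (morphologic abnormality)"),
    cc("900000005", "Substance analog (substance)"),
    cc("900000012", "Chromium-cobalt alloy analog (substance)"),
    cc("900000006", "Synthetic attribute (attribute)"),
    cc("116676008", "Associated morphology (attribute)"),
    cc("42752001",  "Due to (attribute)"),
    cc("363698007", "Finding site (attribute)"),
    cc("900000014", "Procedure site analog (attribute)"),
    cc("71388002",  "Procedure (procedure)"),
    cc("900000013", "Lung biopsy analog (procedure)"))

  pp <- function(child, parent) data.frame(child = child, parent = parent,
                                           stringsAsFactors = FALSE)
  parents <- rbind(
    pp("900000002", "900000001"),
    pp("64572001",  "900000002"),
    pp("22298006",  "64572001"),
    pp("900000021", "64572001"),
    pp("900000022", "64572001"),
    pp("900000023", "64572001"),
    pp("900000024", "64572001"),
    pp("900000025", "64572001"),
    pp("900000026", "64572001"),
    pp("900000027", "64572001"),
    pp("900000003", "900000001"),
    pp("39607008",  "900000003"),
    pp("119199005", "39607008"),
    pp("900000017", "119199005"),
    pp("900000015", "900000003"),
    pp("900000004", "900000003"),
    pp("55641003",  "900000004"),
    pp("900000011", "55641003"),
    pp("900000016", "900000004"),
    pp("900000018", "900000004"),
    pp("900000005", "900000001"),
    pp("900000012", "900000005"),
    pp("900000006", "900000001"),
    pp("116676008", "900000006"),
    pp("42752001",  "900000006"),
    pp("363698007", "900000006"),
    pp("900000014", "900000006"),
    pp("71388002",  "900000001"),
    pp("900000013", "71388002"))

  rr <- function(source, type, target, group) {
    data.frame(source = source, type = type, target = target,
               group = as.integer(group), stringsAsFactors = FALSE)
  }
  relationships <- rbind(
    # myocardial infarction: infarct morphology in the heart
    rr("22298006",  "116676008", "55641003",  1L),
    rr("22298006",  "363698007", "900000015", 1L),
    # cerebral infarction analog: embolic infarct morphology
    rr("900000021", "116676008", "900000011", 1L),
    # aneurysm after MI: aneurysm morphology, due to MI
    rr("900000022", "116676008", "900000016", 1L),
    rr("900000022", "42752001",  "22298006",  1L),
    # lobar pneumonia analog: sited in a lung part
    rr("900000023", "363698007", "900000017", 1L),
    # pulmonary disease analog: sited in the whole lung structure
    rr("900000024", "363698007", "39607008",  1L),
    # fracture analog: non-infarct morphology
    rr("900000025", "116676008", "900000018", 1L),
    # split-group vs same-group pair for role-group semantics
    rr("900000026", "116676008", "55641003",  1L),
    rr("900000026", "363698007", "900000015", 2L),
    rr("900000027", "116676008", "55641003",  1L),
    rr("900000027", "363698007", "900000015", 1L),
    # a procedure with a site, outside the clinical-finding domain
    rr("900000013", "900000014", "39607008",  1L))

  synonyms <- data.frame(
    concept_id = c("64572001", "64572001", "900000024", "22298006"),
    term = c("Disease", "Disorder", "Optic disc normal analog", "Heart attack"),
    is_fsn = FALSE, stringsAsFactors = FALSE)
  descriptions <- rbind(
    data.frame(concept_id = concepts$id, term = concepts$fsn, is_fsn = TRUE,
               stringsAsFactors = FALSE),
    synonyms)

  graph <- concept_graph(concepts, parents, descriptions, relationships)

  mrcm <- processed_mrcm(list(
    mrcm_domain("900000002", "Clinical finding", "<< 900000002", list(
      mrcm_attribute("116676008", "Associated morphology",
                     range_ecl = "<< 900000004", grouped = TRUE,
                     attribute_cardinality = ecl_cardinality(0, Inf),
                     in_group_cardinality = ecl_cardinality(0, 1)),
      mrcm_attribute("42752001", "Due to",
                     range_ecl = "<< 900000002", grouped = FALSE,
                     attribute_cardinality = ecl_cardinality(0, Inf),
                     in_group_cardinality = ecl_cardinality(0, 1)),
      mrcm_attribute("363698007", "Finding site",
                     range_ecl = "<< 900000003", grouped = TRUE,
                     attribute_cardinality = ecl_cardinality(0, Inf),
                     in_group_cardinality = ecl_cardinality(0, 1)))),
    mrcm_domain("71388002", "Procedure", "<< 71388002", list(
      mrcm_attribute("900000014", "Procedure site",
                     range_ecl = "<< 900000003", grouped = TRUE,
                     attribute_cardinality = ecl_cardinality(0, Inf),
                     in_group_cardinality = ecl_cardinality(0, 1))))),
    edition = "demo-fixture")

  list(graph = graph, mrcm = mrcm)
}
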