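fx <- demo_fixture()

test_that("lookup returns display, designations and direct neighbours", {
  res <- op_lookup(fx$graph, "64572001")
  expect_equal(res$display, "Disease (disorder)")
  expect_true("Disease" %in% res$designations)
  expect_equal(res$parents, "900000002")
  expect_true(all(c("22298006", "900000021") %in% res$children))
  expect_error(op_lookup(fx$graph, "999999999"), class = "eclkit_not_found_error")
  # parents/children are exactly the direct is-a edges, for every concept
  for (id in fx$graph$concepts$id) {
    r <- op_lookup(fx$graph, id)
    expect_setequal(r$parents, fx$graph$parents$parent[fx$graph$parents$child == id])
    expect_setequal(r$children, fx$graph$parents$child[fx$graph$parents$parent == id])
  }
  p <- fhir_lookup_parameters(res)
  expect_equal(p$resourceType, "Parameters")
})

test_that("expansion totals, paging and FHIR shape are coherent", {
  exp_all <- op_expand(fx$graph, "<< 64572001")
  expect_equal(exp_all$total, ecl_count("<< 64572001", fx$graph))
  expect_equal(exp_all$contains$code, evaluate_ecl("<< 64572001", fx$graph))
  expect_true(all(exp_all$contains$system == "http://snomed.info/sct"))
  # empty result
  exp_empty <- op_expand(fx$graph, "< 900000012")
  expect_equal(exp_empty$total, 0L)
  expect_equal(nrow(exp_empty$contains), 0L)
  # offset beyond total
  expect_equal(nrow(op_expand(fx$graph, "<< 64572001", offset = 100)$contains), 0L)
  # page concatenation reproduces the full set without duplicates
  pages <- character()
  off <- 0L
  repeat {
    pg <- op_expand(fx$graph, "<< 64572001", offset = off, count = 3L)
    if (!nrow(pg$contains)) break
    pages <- c(pages, pg$contains$code)
    off <- off + 3L
  }
  expect_identical(pages, exp_all$contains$code)
  # parse failures surface as invalid-request, not crashes
  expect_error(op_expand(fx$graph, "<<<"), class = "eclkit_invalid_request_error")
  vs <- fhir_expansion_valueset(op_expand(fx$graph, "22298006",
                                          version_uri = "http://snomed.info/sct/900000000000207008/version/20250101"))
  expect_equal(vs$resourceType, "ValueSet")
  expect_equal(vs$expansion$contains[[1]]$version,
               "http://snomed.info/sct/900000000000207008/version/20250101")
})

test_that("subsumption outcomes cover all four cases and match closure subsumption", {
  g <- fx$graph
  expect_equal(op_subsumes(g, "64572001", "64572001"), "equivalent")
  expect_equal(op_subsumes(g, "64572001", "22298006"), "subsumes")
  expect_equal(op_subsumes(g, "22298006", "64572001"), "subsumed-by")
  expect_equal(op_subsumes(g, "64572001", "71388002"), "not-subsumed")
  expect_error(op_subsumes(g, "64572001", "999999999"),
               class = "eclkit_not_found_error")
  rg <- generate_ontology(20, n_attribute_types = 0L, seed = 31)
  for (a in rg$concepts$id) for (b in rg$concepts$id) {
    out <- op_subsumes(rg, a, b)
    expect_equal(out == "equivalent", a == b)
    if (a != b) {
      expect_equal(out == "subsumes", subsumes(rg, a, b))
      expect_equal(out == "subsumed-by", subsumes(rg, b, a))
    }
  }
})

test_that("token search parameters follow the comma-joined system|code dialect", {
  one <- op_expand(fx$graph, "22298006")
  expect_equal(build_search_param(one), "http://snomed.info/sct|22298006")
  two <- op_expand(fx$graph, "22298006 OR 64572001")
  expect_equal(build_search_param(two),
               "http://snomed.info/sct|22298006,http://snomed.info/sct|64572001")
  empty <- op_expand(fx$graph, "< 900000012")
  expect_equal(build_search_param(empty), "")
  # a paged expansion is refused
  expect_error(build_search_param(op_expand(fx$graph, "<< 64572001", count = 1L)),
               class = "eclkit_eval_error")
  # injective on distinct expansions
  expect_false(build_search_param(one) == build_search_param(two))
})

test_that("domain-to-resource-type mapping prefers Condition for findings", {
  map <- default_domain_resource_map()
  d <- domain_for(fx$graph, fx$mrcm, "64572001")
  types <- resource_types_for(map, d)
  expect_equal(types[1], "Condition")
  expect_true(all(c("Observation", "AllergyIntolerance", "Procedure",
                    "FamilyMemberHistory") %in% types))
  expect_true("Procedure" %in% resource_types_for(map, "Procedure"))
  expect_warning(all_types <- resource_types_for(map, "Pharmaceutical"),
                 "falling back")
  expect_true("Condition" %in% all_types)
})

test_that("cohort search matches the linear-scan oracle and ignores other systems", {
  cohort <- generate_cohort(fx$graph, 50, codes_per_patient = c(1L, 3L), seed = 7)
  q <- paste("<< 64572001 : { 116676008 = << 55641003 OR",
             "42752001 = << 22298006 }")
  exp <- op_expand(fx$graph, q)
  hits <- cohort_search(cohort, exp)
  # linear-scan oracle over the raw resources
  want <- character()
  for (res in cohort) {
    m <- res$codings$code[res$codings$system == "http://snomed.info/sct" &
                            res$codings$code %in% exp$contains$code]
    if (length(m)) want <- c(want, res$resource_id)
  }
  expect_setequal(hits$resource_id, want)
  expect_true(all(hits$code %in% exp$contains$code))
  # invariant to input order
  hits_rev <- cohort_search(rev(cohort), exp)
  expect_identical(hits, hits_rev)
  # empty expansion yields no matches
  expect_equal(nrow(cohort_search(cohort, op_expand(fx$graph, "< 900000012"))), 0L)
  # non-SNOMED codings never match
  alien <- condition_lite("cond-x", "Patient/px",
                          data.frame(system = "http://loinc.org",
                                     code = exp$contains$code[1],
                                     stringsAsFactors = FALSE))
  expect_equal(nrow(cohort_search(list(alien), exp)), 0L)
  # resource-type restriction applies
  proc <- condition_lite("cond-y", "Patient/py",
                         data.frame(system = "http://snomed.info/sct",
                                    code = exp$contains$code[1],
                                    stringsAsFactors = FALSE),
                         resource_type = "Procedure")
  expect_equal(nrow(cohort_search(list(proc), exp, types = "Condition")), 0L)
  expect_equal(nrow(cohort_search(list(proc), exp,
                                  types = c("Condition", "Procedure"))), 1L)
})

test_that("NDJSON and Bundle readers parse Condition resources, skipping junk", {
  cohort <- generate_cohort(fx$graph, 5, seed = 3)
  path <- tempfile(fileext = ".ndjson")
  write_conditions_ndjson(cohort, path)
  back <- read_conditions_ndjson(path)
  expect_length(back, length(cohort))
  expect_equal(back[[1]]$resource_id, cohort[[1]]$resource_id)
  expect_equal(back[[1]]$codings$code, cohort[[1]]$codings$code)
  # malformed lines are skipped with a warning and counted
  writeLines(c(readLines(path), "{not json", '{"resourceType": "Condition"}'), path)
  expect_warning(back2 <- read_conditions_ndjson(path), "skipped 2")
  expect_equal(attr(back2, "n_skipped"), 2L)
  expect_length(back2, length(cohort))
  # bundle form
  bpath <- tempfile(fileext = ".json")
  entries <- lapply(cohort, function(res) list(resource = list(
    resourceType = res$resource_type, id = res$resource_id,
    subject = list(reference = res$patient_ref),
    code = list(coding = lapply(seq_len(nrow(res$codings)), function(i)
      list(system = res$codings$system[i], code = res$codings$code[i]))))))
  writeLines(as.character(jsonlite::toJSON(
    list(resourceType = "Bundle", type = "collection", entry = entries),
    auto_unbox = TRUE)), bpath)
  bundle <- read_conditions_bundle(bpath)
  expect_length(bundle, length(cohort))
  # patient aggregation
  exp <- op_expand(fx$graph, "*")
  pats <- cohort_patients(cohort_search(cohort, exp))
  expect_true(all(grepl("^Patient/", pats)))
})
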