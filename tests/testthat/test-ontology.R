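test_that("SCTID validation is syntactic, with optional Verhoeff strict mode", {
  expect_equal(is_sctid(c("64572001", "900000001", "123456789012345678")),
               c(TRUE, TRUE, TRUE))
  expect_false(is_sctid("012345"))     # leading zero
  expect_false(is_sctid("12345"))      # too short
  expect_false(is_sctid(strrep("9", 19)))  # too long
  expect_false(is_sctid("64572O01"))   # letter
  # real SCTIDs carry a valid Verhoeff check digit; a tampered one fails
  expect_true(is_sctid("64572001", strict = TRUE))
  expect_false(is_sctid("64572002", strict = TRUE))
})

test_that("a single-concept document loads to a one-node graph", {
  path <- tempfile(fileext = ".json")
  writeLines('{"concepts": [{"id": "900000001", "fsn": "Root (synthetic)", "active": true}]}',
             path)
  g <- load_ontology_json(path)
  expect_equal(nrow(g$concepts), 1L)
  expect_equal(nrow(g$parents), 0L)
  expect_equal(descendants(g, "900000001", include_self = TRUE), "900000001")
})

test_that("cyclic parentage is rejected with a cycle in the message", {
  path <- tempfile(fileext = ".json")
  writeLines(paste0('{"concepts": [',
    '{"id": "900000001", "fsn": "A (synthetic)", "active": true, "parents": ["900000002"]},',
    '{"id": "900000002", "fsn": "B (synthetic)", "active": true, "parents": ["900000001"]}]}'),
    path)
  err <- expect_error(load_ontology_json(path), class = "eclkit_graph_error")
  expect_match(conditionMessage(err), "cycle")
  expect_match(conditionMessage(err), "900000001")
})

test_that("schema violations name the offending concept", {
  path <- tempfile(fileext = ".json")
  writeLines('{"concepts": [{"id": "123", "fsn": "Bad (synthetic)"}]}', path)
  expect_error(load_ontology_json(path), "123", class = "eclkit_graph_error")
  writeLines(paste0('{"concepts": [{"id": "900000001", "fsn": "A (synthetic)",',
                    '"relationships": [{"type": "900000001", "target": "999999999", "group": 0}]}]}'),
             path)
  expect_error(load_ontology_json(path), "999999999", class = "eclkit_graph_error")
})

test_that("the bundled demo fixture contains the documented concept ids", {
  fx <- demo_fixture()
  expected <- c("64572001", "55641003", "22298006", "116676008", "42752001",
                "363698007", "119199005", "39607008", "71388002")
  expect_true(all(expected %in% fx$graph$concepts$id))
  filler <- setdiff(fx$graph$concepts$id, expected)
  expect_true(all(startsWith(filler, "9")))  # synthetic ids use the reserved range
  expect_equal(fx$graph$concepts$fsn[fx$graph$concepts$id == "55641003"],
               "Infarct (morphologic abnormality)")
})

test_that("RF2-lite and JSON loaders produce structurally equal graphs", {
  files <- write_mini_rf2()
  g_rf2 <- load_rf2_snapshot(files$concepts, files$descriptions, files$relationships)
  g_json <- load_ontology_json(write_fixture_json(mini_graph()))
  norm <- function(g) {
    list(concepts = g$concepts[order(g$concepts$id), c("id", "fsn", "active")],
         parents = g$parents[order(g$parents$child, g$parents$parent), ],
         relationships = g$relationships[order(g$relationships$source), ])
  }
  a <- norm(g_rf2); b <- norm(g_json)
  rownames(a$concepts) <- rownames(b$concepts) <- NULL
  rownames(a$parents) <- rownames(b$parents) <- NULL
  expect_equal(a$concepts, b$concepts)
  expect_equal(a$parents, b$parents)
})

test_that("RF2 loader reports missing columns and dangling references", {
  files <- write_mini_rf2()
  bad <- tempfile()
  writeLines(c("id", "900000101"), bad)  # no 'active' column
  expect_error(load_rf2_snapshot(bad, files$descriptions, files$relationships),
               "active", class = "eclkit_graph_error")
  badrel <- tempfile()
  utils::write.table(
    data.frame(sourceId = "900000101", destinationId = "999999999",
               typeId = "116680003", relationshipGroup = "0", active = "1"),
    badrel, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_rf2_snapshot(files$concepts, files$descriptions, badrel),
               "999999999", class = "eclkit_graph_error")
})

test_that("closures match direct enumeration on the mini graph", {
  g <- mini_graph()
  ids <- mini_ids()
  expect_equal(descendants(g, ids[["leaf"]], include_self = TRUE),
               unname(ids[["leaf"]]))
  expect_equal(descendants(g, ids[["leaf"]], include_self = FALSE), character())
  # a: children a1, a2; grandchild leaf
  expect_setequal(descendants(g, ids[["a"]]), unname(ids[c("a1", "a2", "leaf")]))
  expect_setequal(descendants(g, ids[["a"]], include_self = TRUE),
                  unname(ids[c("a", "a1", "a2", "leaf")]))
  expect_equal(ancestors(g, ids[["root"]]), character())
  expect_equal(ancestors(g, ids[["root"]], include_self = TRUE),
               unname(ids[["root"]]))
  # depth-3 chain root > a > a1 > leaf
  expect_setequal(ancestors(g, ids[["leaf"]]), unname(ids[c("a1", "a", "root")]))
  expect_error(descendants(g, "999999999"), class = "eclkit_lookup_error")
})

test_that("descendants/ancestors duality and subsumption order hold on random graphs", {
  for (seed in 1:5) {
    g <- generate_ontology(25, max_parents = 3L, depth = 4L,
                           n_attribute_types = 0L, seed = seed)
    ids <- g$concepts$id
    for (a in ids) {
      desc <- descendants(g, a, include_self = FALSE)
      for (b in desc) expect_true(a %in% ancestors(g, b))
      # reflexivity and antisymmetry
      expect_true(subsumes(g, a, a))
    }
    # subsumes agrees with an independent parent-walk oracle on all pairs
    for (a in ids) for (b in ids) {
      expected <- a == b || oracle_is_descendant(g, b, of = a)
      expect_identical(subsumes(g, a, b), expected)
    }
    # antisymmetry: mutual subsumption only when equal
    for (a in ids) for (b in setdiff(ids, a)) {
      expect_false(subsumes(g, a, b) && subsumes(g, b, a))
    }
  }
})

test_that("word-prefix search matches any word, in any token order", {
  g <- concept_graph(data.frame(
    id = c("900000201", "900000202", "900000203"),
    fsn = c("Disease", "Optic disc normal", "Heart structure"),
    active = TRUE, stringsAsFactors = FALSE))
  hits <- search_concepts(g, "dis")
  expect_equal(hits$term, c("Disease", "Optic disc normal"))
  expect_equal(search_concepts(g, "zzz")$term, character())
  expect_equal(search_concepts(g, "disc optic")$term, "Optic disc normal")
  expect_equal(search_concepts(g, "norm disc")$term, "Optic disc normal")
  expect_error(search_concepts(g, "d"), class = "eclkit_input_error")
  # an exact id query returns that concept first
  expect_equal(search_concepts(g, "900000203")$term, "Heart structure")
  # limit truncates the (length, term, id)-ordered list
  expect_equal(nrow(search_concepts(g, "dis", limit = 1L)), 1L)
  expect_equal(search_concepts(g, "dis", limit = 1L)$term, "Disease")
})

test_that("inactive concepts are excluded from closures and search but retained", {
  g <- concept_graph(
    concepts = data.frame(id = c("900000301", "900000302", "900000303"),
                          fsn = c("Root (synthetic)", "Gone (synthetic)", "Leaf (synthetic)"),
                          active = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE),
    parents = data.frame(child = c("900000302", "900000303"),
                         parent = c("900000301", "900000302"),
                         stringsAsFactors = FALSE))
  # closure passes through the inactive node but never reports it
  expect_setequal(descendants(g, "900000301"), "900000303")
  expect_false("900000302" %in% search_concepts(g, "gone")$id)
  expect_equal(op_lookup(g, "900000302")$display, "Gone (synthetic)")
})
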