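fx <- demo_fixture()

test_that("concept-model JSON round-trips through load and write", {
  path <- tempfile(fileext = ".json")
  write_mrcm_json(fx$mrcm, path)
  m2 <- load_mrcm(path)
  expect_equal(length(m2$domains), length(fx$mrcm$domains))
  expect_equal(m2$domains[[1]]$domain_id, fx$mrcm$domains[[1]]$domain_id)
  expect_equal(m2$domains[[1]]$attributes[[1]]$range_ecl,
               fx$mrcm$domains[[1]]$attributes[[1]]$range_ecl)
  # a one-domain document with one attribute loads
  writeLines(paste0('{"edition": "t", "domains": [{"id": "900000001", ',
                    '"name": "All", "constraint": "*", "attributes": ',
                    '[{"id": "116676008", "name": "Morph", "grouped": true, ',
                    '"cardinality": [0, -1], "inGroupCardinality": [0, 1], ',
                    '"range": "*"}]}]}'), path)
  m3 <- load_mrcm(path)
  expect_length(m3$domains, 1L)
  expect_true(is.infinite(m3$domains[[1]]$attributes[[1]]$attribute_cardinality$max))
})

test_that("unparseable embedded ECL fails the load naming the attribute", {
  path <- tempfile(fileext = ".json")
  writeLines(paste0('{"domains": [{"id": "900000001", "name": "X", "constraint": "*", ',
                    '"attributes": [{"id": "116676008", "name": "Morph", ',
                    '"range": "<<<"}]}]}'), path)
  err <- expect_error(load_mrcm(path), class = "eclkit_mrcm_error")
  expect_match(conditionMessage(err), "116676008")
})

test_that("domain determination is subsumption-based and picks the most specific", {
  expect_equal(domain_for(fx$graph, fx$mrcm, "64572001")$name, "Clinical finding")
  # a domain's own root concept maps to that domain
  expect_equal(domain_for(fx$graph, fx$mrcm, "900000002")$domain_id, "900000002")
  expect_equal(domain_for(fx$graph, fx$mrcm, "71388002")$domain_id, "71388002")
  # no domain covers the substance branch
  expect_error(domain_for(fx$graph, fx$mrcm, "900000012"),
               class = "eclkit_no_domain_error")
  # nested domains: the narrower constraint set wins for concepts under both
  m_nested <- processed_mrcm(list(
    mrcm_domain("900000002", "General", "<< 900000002", list()),
    mrcm_domain("64572001", "Specific", "<< 64572001", list())),
    edition = "test")
  expect_equal(domain_for(fx$graph, m_nested, "22298006")$name, "Specific")
  expect_equal(domain_for(fx$graph, m_nested, "900000002")$name, "General")
  # deterministic: repeated calls agree
  expect_identical(domain_for(fx$graph, m_nested, "22298006")$domain_id,
                   domain_for(fx$graph, m_nested, "22298006")$domain_id)
})

test_that("applicable attributes come in a stable grouped-then-name order", {
  d <- domain_for(fx$graph, fx$mrcm, "64572001")
  rules <- applicable_attributes(fx$mrcm, d)
  ids <- vapply(rules, `[[`, character(1), "attribute_id")
  expect_setequal(ids, c("116676008", "42752001", "363698007"))
  grouped <- vapply(rules, `[[`, logical(1), "grouped")
  expect_false(is.unsorted(rev(grouped)))  # grouped rules first
  expect_identical(ids, vapply(applicable_attributes(fx$mrcm, d), `[[`,
                               character(1), "attribute_id"))
  empty <- mrcm_domain("900000005", "Empty", "<< 900000005", list())
  expect_length(applicable_attributes(processed_mrcm(list(empty)), empty), 0L)
})

test_that("allowed values are the evaluated range, excluding out-of-range analogs", {
  d <- domain_for(fx$graph, fx$mrcm, "64572001")
  morph <- Filter(function(r) r$attribute_id == "116676008", d$attributes)[[1]]
  vals <- allowed_values(fx$graph, morph)
  expect_true("55641003" %in% vals)
  expect_false("900000012" %in% vals)  # chromium-cobalt alloy analog excluded
  expect_equal(vals, evaluate_ecl(morph$range_ecl, fx$graph))
  star <- mrcm_attribute("116676008", "Any", range_ecl = "*")
  expect_setequal(allowed_values(fx$graph, star), graph_active_test(fx$graph))
})

test_that("the infarct and lung queries validate against the concept model", {
  q <- paste("<< 64572001 : { 116676008 = << 55641003 OR",
             "42752001 = << 22298006 }")
  expect_true(validate_ecl(q, fx$graph, fx$mrcm)$valid)
  expect_true(validate_ecl("<< 64572001 : { 363698007 = << 119199005 }",
                           fx$graph, fx$mrcm)$valid)
})

test_that("violations carry codes, paths and witness concepts", {
  # attribute from the procedure domain used on a clinical finding
  r1 <- validate_ecl("<< 64572001 : { 900000014 = 39607008 }", fx$graph, fx$mrcm)
  expect_false(r1$valid)
  expect_equal(r1$violations[[1]]$code, "ATTRIBUTE_NOT_IN_DOMAIN")
  # value outside the morphology range, with the witness named
  r2 <- validate_ecl("<< 64572001 : { 116676008 = 900000012 }", fx$graph, fx$mrcm)
  expect_equal(r2$violations[[1]]$code, "VALUE_OUT_OF_RANGE")
  expect_match(r2$violations[[1]]$message, "900000012")
  stray <- setdiff(evaluate_ecl("900000012", fx$graph),
                   allowed_values(fx$graph, fx$mrcm$domains[[1]]$attributes[[1]]))
  expect_gt(length(stray), 0L)
  # grouped-only attribute used outside braces
  r3 <- validate_ecl("<< 64572001 : 116676008 = << 55641003", fx$graph, fx$mrcm)
  expect_equal(r3$violations[[1]]$code, "GROUPING_VIOLATION")
  # cardinality outside the model's in-group bound
  r4 <- validate_ecl("<< 64572001 : { [2..5] 116676008 = << 55641003 }",
                     fx$graph, fx$mrcm)
  expect_true("CARDINALITY_VIOLATION" %in%
                vapply(r4$violations, `[[`, character(1), "code"))
  # [0..0] and the default are always admissible
  expect_true(validate_ecl("<< 64572001 : { [0..0] 116676008 = * }",
                           fx$graph, fx$mrcm)$valid)
  # focus outside every domain
  r5 <- validate_ecl("900000012 : { 116676008 = 55641003 }", fx$graph, fx$mrcm)
  expect_equal(r5$violations[[1]]$code, "NO_DOMAIN")
  # wildcard focus skips domain checks
  expect_true(validate_ecl("* : 116676008 = 55641003", fx$graph, fx$mrcm)$valid)
  # compound tops are validated per operand
  r6 <- validate_ecl(paste("(<< 64572001 : { 900000014 = 39607008 }) OR",
                           "(<< 71388002 : { 900000014 = 39607008 })"),
                     fx$graph, fx$mrcm)
  expect_length(r6$violations, 1L)
  expect_match(r6$violations[[1]]$path, "operands")
})

test_that("builder choices are gated by the focus domain", {
  ch <- builder_next_choices(fx$graph, fx$mrcm, "<< 64572001")
  expect_equal(ch$domain$name, "Clinical finding")
  ids <- vapply(ch$attributes, `[[`, character(1), "attribute_id")
  expect_true("116676008" %in% ids)
  expect_false("900000014" %in% ids)
  vals <- builder_next_choices(fx$graph, fx$mrcm, "<< 64572001", "116676008")
  expect_true("55641003" %in% vals$values)
  expect_false("900000012" %in% vals$values)
  expect_equal(vals$values_constraint, "<< 900000004")
  expect_error(builder_next_choices(fx$graph, fx$mrcm, "900000012"),
               class = "eclkit_no_domain_error")
  expect_error(builder_next_choices(fx$graph, fx$mrcm, "<< 64572001", "900000014"),
               class = "eclkit_mrcm_error")
})

test_that("random builder walks always produce validator-green queries", {
  # fixture model
  for (s in 1:30) {
    q <- builder_random_query(fx$graph, fx$mrcm, seed = s)
    expect_true(validate_ecl(q, fx$graph, fx$mrcm)$valid)
  }
  # generated graph/model pairs
  g <- generate_ontology(35, n_attribute_types = 3L, seed = 17)
  m <- generate_mrcm(g, n_domains = 3L, seed = 17)
  for (s in 1:30) {
    q <- builder_random_query(g, m, seed = 100L + s)
    expect_true(validate_ecl(q, g, m)$valid)
  }
})
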