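Package: eclkit
Title: SNOMED CT Expression Constraint Language Engine with Concept-Model
    Validation and FHIR Terminology Operations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse, render, validate and evaluate SNOMED CT Expression
    Constraint Language (ECL) queries against an in-memory concept graph.
    Provides loaders for a compact JSON ontology format and simplified
    RF2-style snapshot tables, transitive-closure and subsumption queries,
    word-prefix concept search, a recursive-descent ECL parser with typed
    offset-carrying errors, set-semantics evaluation including role groups,
    cardinalities, reverse attributes and negation, machine-readable
    concept-model (MRCM) driven semantic validation and guided query
    building, local FHIR R4 terminology operations (lookup, expand,
    subsumes), ECL-to-FHIR-search cohort retrieval over Condition
    resources, and seeded generators for synthetic ontologies, concept
    models and SNOMED-coded FHIR cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
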