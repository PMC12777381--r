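# eclkit

An R engine for the SNOMED CT **Expression Constraint Language (ECL)**:
parsing, canonical rendering, set-semantics evaluation over a concept
graph, machine-readable concept model (MRCM) validation with a guided
query builder, and local FHIR R4 terminology operations with
ECL-to-FHIR-search cohort retrieval.

It is aimed at people who build or test terminology tooling — query
builders, terminology services, cohort-selection pipelines — and want the
computational core to be fully inspectable and testable on small
in-memory ontologies, without a licensed SNOMED CT release or a running
terminology server.

## What it computes

An ECL expression denotes a set of concepts. For a concept graph
G = (C, ≤) with is-a partial order ≤ and materialized defining
relationships rel(c) = {(type, target, group)}:

- `c`, `< c`, `<< c`, `> c`, `>> c` denote {c}, its strict descendants
  {x : x < c}, descendants-or-self, strict ancestors, ancestors-or-self;
  `*` denotes all active concepts; `AND` / `OR` / `MINUS` are ∩ / ∪ / ∖.
- A refinement `F : [m..n] A cmp V` keeps x ∈ F when the number of
  relationships (type ∈ ⟦A⟧, target ∈ ⟦V⟧ for `=`, target ∉ ⟦V⟧ for `!=`)
  lies in [m..n]. The default is `[1..*]`; `[0..0]` expresses negation.
- A role group `{ … }` requires its constraints to hold within one shared
  relationship-group number; the group cardinality bounds how many
  distinct groups qualify. `R A = V` reverses the direction (incoming
  relationships).

On top of that, the MRCM layer gates queries semantically: the focus
concept's *domain* is found by subsumption testing against per-domain ECL
constraints, only that domain's attributes are applicable, and each
attribute's *range* (also ECL) bounds the admissible values — the same
rules a guided builder uses to make invalid queries unconstructable. The
FHIR layer implements `$lookup`, `$expand` (with paging) and `$subsumes`
over the same graph and turns expansions into comma-joined
`system|code` token parameters for searching Condition resources.

## Worked example

The bundled curated fixture (`demo_fixture()`) is a 30-concept
mini-ontology with a two-domain concept model. The classic "disorders
with an infarct morphology or due to myocardial infarction" query:

```r
library(eclkit)
fx <- demo_fixture()

intro <- "<< 64572001 |Disease (disorder)| :
  { 116676008 |Associated morphology (attribute)| = << 55641003 |Infarct (morphologic abnormality)|
    OR 42752001 |Due to (attribute)| = << 22298006 |Myocardial infarction (disorder)| }"

writeLines(format_result_set(evaluate_ecl(intro, fx$graph), fx$graph))
#> 22298006	Myocardial infarction (disorder)
#> 900000021	Cerebral infarction analog (disorder)
#> 900000022	Ventricular aneurysm after myocardial infarction analog (disorder)
#> 900000026	Split-group disorder analog (disorder)
#> 900000027	Same-group disorder analog (disorder)
```

Five of the fixture's nine disorders match: they either carry an
infarct-kind morphology in some role group or are due to a myocardial
infarction; the pneumonia, pulmonary-disease and fracture analogs do
not. The concept-model validator accepts this query
(`validate_ecl(intro, fx$graph, fx$mrcm)$valid` is `TRUE`) and rejects
semantic errors with located, coded violations:

```r
validate_ecl("<< 64572001 : { 116676008 = 900000012 }", fx$graph, fx$mrcm)
#> invalid: 1 violation(s)
#>   [VALUE_OUT_OF_RANGE] at e$refinement$items[[1]]$constraints[[1]]: value
#>   900000012 (Chromium-cobalt alloy analog (substance)) is outside the range
#>   of attribute 116676008
```

Domain determination and the FHIR-search token for cohort retrieval:

```r
domain_for(fx$graph, fx$mrcm, "64572001")$name
#> [1] "Clinical finding"
build_search_param(op_expand(fx$graph, "22298006 OR 64572001"))
#> [1] "http://snomed.info/sct|22298006,http://snomed.info/sct|64572001"
```

The comma means OR in FHIR token search; `cohort_search()` applies such
an expansion to Condition resources read from NDJSON or a Bundle.

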