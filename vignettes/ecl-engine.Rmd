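---
title: "An ECL engine with concept-model validation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ECL engine with concept-model validation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eclkit)
```

## The problem

SNOMED CT is both a clinical terminology and a formal ontology: concepts are
arranged in a directed acyclic is-a hierarchy and carry defining attribute
relationships (for instance, a disorder may point at a morphology through
*Associated morphology* and at an anatomical site through *Finding site*).
The Expression Constraint Language (ECL) selects *sets* of concepts from
this structure — by hierarchy (`<< 64572001` is "Disease and everything
below it"), by attribute (`: 116676008 = << 55641003` keeps only concepts
whose associated morphology is some kind of infarct), and by set logic
(`AND`, `OR`, `MINUS`).

Writing correct ECL requires fluency in its grammar *and* in the SNOMED CT
concept model, which prescribes which attributes may describe which
concepts and which values those attributes may take. `eclkit` packages the
computational core that query-building tools need: parsing and rendering,
set-semantics evaluation over a concept graph, machine-readable concept
model (MRCM) validation and guided building, and the FHIR terminology
operations (`$lookup`, `$expand`, `$subsumes`) plus token-search cohort
retrieval that connect ECL to patient-level FHIR data. Everything runs
in-process over synthetic or user-supplied mini-ontologies, so every step
is testable without a licensed SNOMED CT release or a terminology server.

## The implemented ECL subset

The grammar covers: the constraint operators `<`, `<<`, `>`, `>>` and the
implied SELF; the wildcard `*`; parenthesized nested expressions;
compounds with `AND`, `OR` and binary `MINUS`; refinements with ungrouped
attribute constraints and braces-enclosed role groups; attribute and group
cardinalities `[m..n]` (with `*` for an unbounded maximum); the `=` and
`!=` comparators; and the reverse flag `R`. Description/member/concept
filters, history supplements, `memberOf` (`^`) and dotted notation are out
of scope.

Parsing is a hand-rolled recursive descent over a small tokenizer. The
subset is compact and error *locations* matter more than raw speed: every
failure is a typed condition carrying a 1-based character offset, the
expected and found lexemes, and a code such as `AMBIGUOUS_OPERATORS`,
`MALFORMED_CARDINALITY` or `UNBALANCED_BRACES`. Nothing is auto-repaired.
Notable syntax decisions:

* Two different connectives at one level require parentheses; the parser
  rejects `a AND b OR c` rather than inventing a precedence.
* `MINUS` is binary and left-associative; chains parse as
  `(a MINUS b) MINUS c`.
* Operators must be contiguous (`< <` is not `<<`); keywords are
  case-insensitive; a comma inside a refinement is an input synonym for
  `AND` and is never emitted.
* Identifiers must look like SCTIDs (6–18 digits, no leading zero);
  anything else is an `INVALID_SCTID` error at its offset. A strict mode
  of `is_sctid()` additionally verifies the Verhoeff check digit real
  SCTIDs carry; it is off by default because synthetic fixture ids do not
  encode one.

### Canonical form and normalization

`render()` emits one canonical text per AST: single spaces, uppercase
connectives, brackets only for non-default cardinalities, terms refreshed
from the graph when one is supplied, parentheses exactly where structure
requires them (compound operands and refined operands of compounds).
Constructors and parser funnel through one normalization: default
cardinalities become an explicit `[1..*]`, purely syntactic parentheses
(`(x)` with SELF operator and no refinement) unwrap, same-operator
`AND`/`OR` children flatten, and the connective of a single-item
refinement or group is canonicalized to `AND` since it joins nothing.
`structural_equals()` compares normalized ASTs with term annotations
stripped — terms inside pipes are human-readable decoration, not
semantics. These choices make the round-trip property exact:
`parse(render(x))` is structurally equal to `x`, and render∘parse is
idempotent on any accepted input.

## Evaluation semantics

`evaluate_ecl()` returns the active-concept set in ascending SCTID order.
Because 18-digit SCTIDs exceed double precision, "numeric" order is
implemented as (length, lexicographic) on the digit strings, which is
exact for identifiers without leading zeros.

The graph stores each concept's *materialized* defining relationships —
the inferred, post-inheritance view a snapshot-serving terminology server
queries. The evaluator therefore never propagates attributes down the
hierarchy at query time; the synthetic generator (or the upstream source)
is responsible for materialization. This keeps refinement checking local
to one concept and makes the brute-force test oracle trivial to state.

An ungrouped constraint `[m..n] A cmp V` holds for concept *c* when the
number of *c*'s relationships — any role-group number — whose type is in
the evaluation of `A` and whose target lies inside (`=`) or outside
(`!=`) the evaluation of `V` falls within `[m..n]`. So `!=` is a
relationship-level complement combined with cardinality exactly like `=`;
concept-level absence ("has no such attribute") is written `[0..0] A = V`,
and the identity `X : [0..0] A = V  =  X MINUS (X : A = V)` holds and is
property-tested.

A role group `[p..q] { … }` counts the distinct role-group numbers ≥ 1
within which *all* of its connective-combined constraints hold, with each
constraint's cardinality evaluated against that group's relationships
only; the count must fall within `[p..q]`. Two strictness decisions were
genuinely open and are fixed here: ungrouped (group-0) relationships
never satisfy a braces-enclosed constraint, and a single ungrouped
relationship is not treated as a self-group. Reverse constraints inside a
group fall back to the concept's incoming relationships, since the
grouped view belongs to the source side.

A reverse constraint `R A cmp V` holds for *c* when the count of sources
*z* with a relationship (*z*, type ∈ `A`, target = *c*) and *z* inside
(`=`) / outside (`!=`) `V` satisfies the cardinality. Reverse with a
wildcard attribute is rejected as unsupported — it quantifies over every
relationship type at once, which is rarely meaningful and easy to write
accidentally.

## Concept-model validation and the guided builder

The processed MRCM is consumed as JSON: per domain an identifying
concept, a name, a domain constraint in ECL, and attribute rules with
grouped flags, attribute and in-group cardinalities, and an ECL range.
All embedded ECL is parsed eagerly at load, so a broken range fails fast
with the attribute named.

`domain_for()` determines a focus concept's domain by subsumption: every
domain whose evaluated constraint set contains the focus is a candidate,
and the *most specific* candidate wins. Specificity is defined by
constraint-set inclusion rather than hierarchy depth, because domains
need not be rooted in top-level hierarchies; ties break by smaller set,
then domain id, making the procedure total and deterministic over covered
concepts.

`validate_ecl()` then checks each attribute constraint of a refinement:
the attribute must be among the domain's rules
(`ATTRIBUTE_NOT_IN_DOMAIN`); every concept the value expression evaluates
to must lie within the rule's range (`VALUE_OUT_OF_RANGE`, naming a
witness), range conformance being set-containment of the whole evaluated
value expression rather than a per-leaf check; grouped-only attributes
must appear inside braces (`GROUPING_VIOLATION`); and a declared
cardinality must be `[1..*]`, `[0..0]`, or lie within the rule's bound
(`CARDINALITY_VIOLATION`). Decisions where the design was open:

* Attribute rules are looked up by the attribute subexpression's focus
  concept id. A wildcard or nested attribute focus skips the domain gate,
  as does a reverse constraint — the domain model describes the forward
  direction only.
* A wildcard or nested *focus* skips domain checks entirely (there is no
  single focus concept to classify); compound top levels are validated
  per operand.
* A bare wildcard value (`[0..0] A = *`, "A absent") skips the range
  check: it names no concrete concept that could be out of range, and
  flagging it would make the standard negation idiom unvalidatable.

`builder_next_choices()` inverts validation into guidance: given a
resolved focus it offers exactly the domain's attribute rules, and given
a chosen rule, exactly the evaluated range. The builder-soundness
contract — no sequence of offered choices can produce a query the
validator rejects — is exercised by `builder_random_query()`, a simulated
user who picks uniformly among offered foci, attributes, values,
occasional `[0..0]` cardinalities and `!=` comparators; 300 such walks
over generated graph/model pairs are asserted valid in the test suite.

## FHIR facade and cohort retrieval

The facade is an in-process engine, not an HTTP server: `op_lookup()`
returns display, designations and direct neighbours; `op_expand()`
resolves an ECL-defined ValueSet with offset/count paging over the stable
id order; `op_subsumes()` reports the four FHIR outcome codes. Helper
shapers emit the corresponding `Parameters`, `ValueSet` and
`OperationOutcome` JSON structures. A version URI in the
`system/version/YYYYMMDD` form is echoed in expansion metadata and does
not alter local semantics.

Cohort retrieval follows the expand-then-search pattern:
`build_search_param()` joins `system|code` tokens with commas (comma = OR
in FHIR token search) in ascending code order, and `cohort_search()`
linearly scans lightweight Condition resources (NDJSON or Bundle),
matching on SNOMED-system codings inside the expansion, restricted to the
resource types a domain maps to (`Condition` first for finding-like
domains). Results sort by resource id, so they are invariant to input
order; `cohort_patients()` aggregates to patients.

## Synthetic data: what it emulates and what it does not

`generate_ontology()` emulates the structural features evaluation
depends on: a single-rooted DAG with configurable depth and multi-parent
fan-in, an attribute subtree providing attribute-type concepts, grouped
and ungrouped defining relationships, and materialized inheritance
(children repeat parental relationships before adding their own).
Defaults are modest (tens of concepts, `max_parents = 2`, depth 3, group
probability 0.5) — large enough to exercise multi-parent closures and
grouping, small enough that the brute-force oracle stays exact and fast.
Synthetic ids come from a reserved 9-prefixed range and synthetic FSNs
carry semantic tags, so no invented id or name masquerades as real
content. The generators are pure functions of their parameters including
the seed; equal seeds give byte-identical serializations.

What the generator does *not* emulate: SNOMED CT's scale (hundreds of
thousands of concepts), its description richness, realistic disease
prevalences, inactive-concept churn, or refset-defined domains. Passing
tests therefore demonstrate semantic correctness of the engine, not
performance or coverage claims about a licensed release; counts such as
the well-known infarct example's 283 concepts in the International
Edition depend on licensed content and are deliberately not reproduced.

`demo_fixture()` is the curated counterpart: a 30-concept ontology and
two-domain concept model arranged so the flagship infarct and lung-site
queries are satisfiable and *discriminating* (each selects a non-empty
strict subset of `<< 64572001`), a substance-branch concept sits outside
the morphology range to exercise `VALUE_OUT_OF_RANGE`, and a
procedure-only attribute exercises `ATTRIBUTE_NOT_IN_DOMAIN`.

```{r fixture}
fx <- demo_fixture()
intro <- "<< 64572001 : { 116676008 = << 55641003 OR 42752001 = << 22298006 }"
evaluate_ecl(intro, fx$graph)
validate_ecl(intro, fx$graph, fx$mrcm)$valid
```

## Numerical and procedural choices

* **Ordering everywhere.** Evaluation results, expansions, search
  results, builder menus and serializations all have fixed sort orders
  (SCTID order; (length, term, id) for search; grouped-then-name for
  attribute menus), so equal inputs give byte-equal outputs.
* **Search.** Word-prefix matching tokenizes on whitespace and hyphens,
  case-insensitively; every query token must prefix some description
  word, in any order. The minimum query length is 2 characters. An exact
  id query returns that concept first — id search is explicitly
  supported, partial-id matching is not.
* **Degenerate inputs.** Empty queries, empty expansions, offsets beyond
  totals, zero-patient cohorts and single-concept ontologies are all
  defined, tested cases rather than errors; cyclic hierarchies and
  dangling references fail loading with the offending cycle or id named.
* **Problem sizes in the test suite.** Round-trip: 1,000 sampled ASTs
  plus a 34-query corpus. Oracle equivalence: 200 random graph/query
  pairs with graphs of 8–40 concepts and ASTs of depth ≤ 4, checked
  against an independently written per-concept membership oracle that
  walks raw parent edges. Builder soundness: 300 walks. Subsumption:
  all 400 ordered pairs of a 20-concept graph. Cohort recovery: 20
  seeds, 40 patients each, 10 planted. These sizes keep the whole suite
  under a minute while exhausting every code path several times over.

## Limitations

The engine evaluates eagerly and memoizes nothing beyond per-refinement
set precomputation; it is built for correctness on mini-ontologies, not
for the full International Edition. The MRCM schema is the compact form
described above, not the RF2 MRCM reference sets or Expression Template
Language, which are expected to be processed upstream. Multiple focus
concepts are representable and parseable but the guided builder emits
single-focus queries only. The remote-terminology-server mode common in
production tools is out of scope: the three operations are implemented
locally so their semantics stay testable offline.
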