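# Small graphs built in code, shared across test files.

# root -> {a, b}; a -> {a1, a2}; b -> {b1}; a1 -> {leaf}  (ids are synthetic)
mini_graph <- function() {
  ids <- c(root = "900000101", a = "900000102", b = "900000103",
           a1 = "900000104", a2 = "900000105", b1 = "900000106",
           leaf = "900000107")
  concept_graph(
    concepts = data.frame(id = unname(ids),
                          fsn = paste0("Node ", names(ids), " (synthetic)"),
                          active = TRUE, stringsAsFactors = FALSE),
    parents = data.frame(
      child = unname(ids[c("a", "b", "a1", "a2", "b1", "leaf")]),
      parent = unname(ids[c("root", "root", "a", "a", "b", "a1")]),
      stringsAsFactors = FALSE))
}

mini_ids <- function() {
  c(root = "900000101", a = "900000102", b = "900000103",
    a1 = "900000104", a2 = "900000105", b1 = "900000106", leaf = "900000107")
}

graph_active_test <- function(g) g$concepts$id[g$concepts$active]

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# ascending numeric SCTID order, computed independently of the package sort
sort_ids_test <- function(ids) {
  ids <- unique(ids)
  ids[order(nchar(ids), ids)]
}

corpus_queries <- function() {
  path <- system.file("extdata", "ecl-corpus.txt", package = "eclkit")
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
}

write_fixture_json <- function(g) {
  path <- tempfile(fileext = ".json")
  write_ontology_json(g, path)
  path
}

# the same content as mini_graph() in RF2-lite TSV form
write_mini_rf2 <- function() {
  ids <- mini_ids()
  dir <- tempfile()
  dir.create(dir)
  con <- file.path(dir, "concepts.tsv")
  des <- file.path(dir, "descriptions.tsv")
  rel <- file.path(dir, "relationships.tsv")
  g <- mini_graph()
  utils::write.table(data.frame(id = g$concepts$id, active = "1"),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(conceptId = g$concepts$id, term = g$concepts$fsn,
                                typeId = "900000000000003001"),
                     des, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sourceId = g$parents$child,
                                destinationId = g$parents$parent,
                                typeId = "116680003", relationshipGroup = "0",
                                active = "1"),
                     rel, sep = "\t", quote = FALSE, row.names = FALSE)
  list(concepts = con, descriptions = des, relationships = rel)
}
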