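# Two-model corpus shared across the query tests (built once; SPARQL
# evaluation shells out per query).
qfx_a <- generate_model(fixture_spec(seed = 101, n_species = 3, n_reactions = 2,
  annotation_density = 1))
qfx_b <- generate_model(fixture_spec(seed = 102, n_species = 5, n_reactions = 0,
  annotation_density = 0, curated = FALSE))
qg_a <- convert_model(parse_sbml(qfx_a$xml), curated = TRUE)
qg_b <- convert_model(parse_sbml(qfx_b$xml), curated = FALSE)
qstore <- fixture_store(qg_a, qg_b)

test_that("the store has set semantics", {
  expect_equal(n_triples(rdf_store()), 0)
  once <- store_load(rdf_store(), qg_a)
  twice <- store_load(once, qg_a)
  expect_equal(n_triples(twice), n_triples(once))

  # loading two disjoint graphs sums their line counts
  path_a <- withr::local_tempfile(fileext = ".nt")
  path_b <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(qg_a, path_a)
  write_ntriples(qg_b, path_b)
  both <- store_load(rdf_store(), c(path_a, path_b))
  expect_equal(n_triples(both),
    length(readLines(path_a)) + length(readLines(path_b)))
  expect_error(store_load(rdf_store(), "/nonexistent/file.nt"), "not found")
})

test_that("species listing matches the fixture and leaves unnamed species unbound", {
  res <- species_in_model(qstore, qfx_a$model_id)
  expect_equal(nrow(res), qfx_a$ledger$n_species)
  res_b <- species_in_model(qstore, qfx_b$model_id)
  expect_equal(nrow(res_b), qfx_b$ledger$n_species)
  expect_equal(nrow(species_in_model(qstore, "NOSUCHMODEL")), 0)

  # names are optional bindings: unnamed species still appear
  model_b <- parse_sbml(qfx_b$xml)
  n_named <- sum(vapply(model_b$species, function(s) !is.null(s$name), logical(1)))
  expect_equal(sum(!is.na(res_b$name)), n_named)
  if (n_named < nrow(res_b)) expect_true(any(is.na(res_b$name)))
})

test_that("annotation lookup returns one row per qualifier triple", {
  links <- qfx_a$ledger$links
  concept <- links$uri[1]
  res <- elements_by_annotation(qstore, concept)
  expect_equal(nrow(res), sum(!duplicated(links[links$uri == concept, ])))
  expect_true(all(startsWith(res$qualifier, "http://biomodels.net/")))
  expect_equal(nrow(elements_by_annotation(qstore,
    "http://identifiers.org/go/GO:9999999")), 0)
})

test_that("an element annotated twice with one concept yields two rows", {
  xml <- wrap_sbml(paste0(
    "<listOfSpecies><species id=\"s1\" metaid=\"ms1\">",
    bag_annotation("ms1", list(
      list(ns = "bqbiol", local = "is",
        uris = "http://identifiers.org/chebi/CHEBI:29108"),
      list(ns = "bqbiol", local = "isVersionOf",
        uris = "http://identifiers.org/chebi/CHEBI:29108"))),
    "</species></listOfSpecies>"), model_id = "DOUBLEANN")
  store <- fixture_store(convert_model(parse_sbml(xml)))
  res <- elements_by_annotation(store, "http://identifiers.org/chebi/CHEBI:29108")
  expect_equal(nrow(res), 2)
  expect_setequal(res$qualifier, c(
    "http://biomodels.net/biology-qualifiers/is",
    "http://biomodels.net/biology-qualifiers/isVersionOf"))
  expect_equal(unique(res$model),
    "http://identifiers.org/biomodels.db/DOUBLEANN")
})

test_that("collection pattern-matching recovers ledger-predicted counts", {
  links <- qfx_a$ledger$links
  reactome <- sum(startsWith(links$uri, "http://identifiers.org/reactome/"))
  res <- elements_by_collection(qstore, "http://identifiers.org/reactome/")
  expect_equal(nrow(res), reactome)

  # the broadest prefix returns every cross-reference link
  all_rows <- elements_by_collection(qstore, "http://identifiers.org/")
  expect_equal(nrow(all_rows),
    qfx_a$ledger$n_annotation_links + qfx_b$ledger$n_annotation_links)

  expect_equal(nrow(elements_by_collection(qstore, "http://nosuch.example/")), 0)

  # containment: concept rows are a subset of their collection's rows
  concept <- links$uri[1]
  by_conc <- elements_by_annotation(qstore, concept)
  by_coll <- elements_by_collection(qstore,
    sub("^(http://identifiers\\.org/[^/]+/).*$", "\\1", concept))
  expect_true(all(by_conc$element %in% by_coll$element))
})

test_that("conjunctive concept search requires every concept in the model", {
  rat <- "http://identifiers.org/taxonomy/10114"
  cytosol <- "http://identifiers.org/go/GO:0005829"
  calcium <- "http://identifiers.org/chebi/CHEBI:29108"
  model_a <- wrap_sbml(paste0(
    "<listOfSpecies><species id=\"s1\" metaid=\"ms1\">",
    bag_annotation("ms1", list(
      list(ns = "bqbiol", local = "is", uris = c(calcium, cytosol)))),
    "</species><species id=\"s2\" metaid=\"ms2\"/></listOfSpecies>",
    "<listOfReactions><reaction id=\"r1\" metaid=\"mr1\">",
    bag_annotation("mr1", list(
      list(ns = "bqbiol", local = "occursIn", uris = rat))),
    "<listOfReactants><speciesReference species=\"s1\"/></listOfReactants>",
    "</reaction></listOfReactions>"), model_id = "CONJA")
  model_b <- wrap_sbml(paste0(
    "<listOfSpecies><species id=\"s1\" metaid=\"ms1\">",
    bag_annotation("ms1", list(
      list(ns = "bqbiol", local = "is", uris = rat))),
    "</species></listOfSpecies>"), model_id = "CONJB")
  store <- fixture_store(
    convert_model(parse_sbml(model_a), curated = TRUE),
    convert_model(parse_sbml(model_b), curated = TRUE))

  hit <- models_with_all_concepts(store, c(rat, cytosol, calcium))
  expect_equal(hit$model, "http://identifiers.org/biomodels.db/CONJA")

  with_rx <- models_with_all_concepts(store, c(rat, cytosol, calcium),
    reactions = TRUE)
  expect_equal(with_rx$reaction,
    "http://identifiers.org/biomodels.db/CONJA#mr1")

  # single concept reduces to the annotation lookup's model set
  single <- models_with_all_concepts(store, rat)
  ann_models <- unique(elements_by_annotation(store, rat)$model)
  expect_setequal(single$model, ann_models)

  # concepts annotated in disjoint models intersect to nothing
  expect_equal(nrow(models_with_all_concepts(store,
    c(cytosol, "http://identifiers.org/go/GO:9999999"))), 0)
  expect_error(models_with_all_concepts(store, character()), "at least one")
})

test_that("the generic engine evaluates ad-hoc SPARQL", {
  empty <- rdf_store()
  res <- run_sparql(empty, paste0(
    "PREFIX sbmlrdf: <http://identifiers.org/biomodels.vocabulary#>\n",
    "SELECT (COUNT(?x) AS ?c) WHERE { ?x a sbmlrdf:Species }"))
  expect_equal(res$c, "0")

  five <- generate_model(fixture_spec(seed = 77, n_species = 5, n_reactions = 0,
    annotation_density = 0))
  store <- fixture_store(convert_model(parse_sbml(five$xml)))
  counted <- run_sparql(store, system.file("queries", "count_species.rq",
    package = "sbml2rdf"))
  expect_equal(counted$count, "5")

  expect_error(run_sparql(empty, "SELEKT ?x WHERE { ?x ?p ?o }"),
    "syntax error")
})

test_that("canned queries equal their documented SPARQL text run generically", {
  tmpl <- function(name, subs) {
    path <- system.file("queries", paste0(name, ".rq"), package = "sbml2rdf")
    text <- paste(readLines(path), collapse = "\n")
    for (k in names(subs)) text <- gsub(paste0("%", k, "%"), subs[[k]], text,
      fixed = TRUE)
    text
  }
  as_multiset <- function(df) {
    sort(apply(as.data.frame(df), 1, paste, collapse = "\x1f"), method = "radix")
  }
  expect_equal(
    as_multiset(species_in_model(qstore, qfx_a$model_id)),
    as_multiset(run_sparql(qstore, tmpl("species_in_model",
      list(MODEL_URI = model_uri(qfx_a$model_id))))))
  concept <- qfx_a$ledger$links$uri[1]
  expect_equal(
    as_multiset(elements_by_annotation(qstore, concept)),
    as_multiset(run_sparql(qstore, tmpl("elements_by_annotation",
      list(CONCEPT_URI = concept)))))
  expect_equal(
    as_multiset(elements_by_collection(qstore, "http://identifiers.org/go/")),
    as_multiset(run_sparql(qstore, tmpl("elements_by_collection",
      list(COLLECTION_PREFIX = "http://identifiers.org/go/")))))
  expect_equal(
    as_multiset(models_with_all_concepts(qstore, concept)),
    as_multiset(run_sparql(qstore, build_all_concepts_query(concept))))
})
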