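test_that("an empty model converts to exactly the model-level statements", {
  model <- parse_sbml(wrap_sbml("", model_id = "EMPTY01"))
  g <- convert_model(model, curated = TRUE)
  # rule enumeration by hand: one type triple, one curated literal
  expect_equal(sorted_nt(g), sort(c(
    paste0("<http://identifiers.org/biomodels.db/EMPTY01> ",
      "<http://identifiers.org/biomodels.vocabulary#curated> ",
      "\"true\"^^<http://www.w3.org/2001/XMLSchema#boolean> ."),
    paste0("<http://identifiers.org/biomodels.db/EMPTY01> ",
      "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type> ",
      "<http://identifiers.org/biomodels.vocabulary#SBMLModel> .")
  ), method = "radix"))
})

test_that("species attributes become typed property triples", {
  xml <- wrap_sbml(paste0(
    '<listOfCompartments><compartment id="c1" metaid="mc1"/></listOfCompartments>',
    '<listOfSpecies><species id="s1" metaid="ms1" name="calcium pool"',
    ' compartment="c1" initialConcentration="0.25"/></listOfSpecies>'),
    model_id = "SPTEST")
  df <- as.data.frame(convert_model(parse_sbml(xml), curated = FALSE))
  s_uri <- "http://identifiers.org/biomodels.db/SPTEST#ms1"
  expect_true(any(df$subject == s_uri &
    df$predicate == "http://identifiers.org/biomodels.vocabulary#name" &
    df$object == "calcium pool" & df$object_kind == "literal"))
  conc <- df[df$subject == s_uri &
    df$predicate == "http://identifiers.org/biomodels.vocabulary#initialConcentration", ]
  expect_equal(nrow(conc), 1)
  expect_equal(conc$object, "0.25")
  expect_equal(conc$datatype, "http://www.w3.org/2001/XMLSchema#double")
  # compartment attribute resolves to the compartment resource
  comp <- df[df$subject == s_uri &
    df$predicate == "http://identifiers.org/biomodels.vocabulary#compartment", ]
  expect_equal(comp$object, "http://identifiers.org/biomodels.db/SPTEST#mc1")
  expect_equal(comp$object_kind, "uri")
})

test_that("reactions link to species references that name their species", {
  g <- convert_model(parse_sbml(paper_fragment()), curated = TRUE)
  df <- as.data.frame(g)
  rx <- "http://identifiers.org/biomodels.db/BIOMD0000000001#_000017"
  sbmlrdf <- "http://identifiers.org/biomodels.vocabulary#"
  reactants <- df$object[df$subject == rx & df$predicate == paste0(sbmlrdf, "reactant")]
  products <- df$object[df$subject == rx & df$predicate == paste0(sbmlrdf, "product")]
  expect_length(reactants, 1)
  expect_length(products, 1)
  expect_equal(
    df$object[df$subject == reactants & df$predicate == paste0(sbmlrdf, "species")],
    "http://identifiers.org/biomodels.db/BIOMD0000000001#_000003")
  expect_equal(
    df$object[df$subject == products & df$predicate == paste0(sbmlrdf, "species")],
    "http://identifiers.org/biomodels.db/BIOMD0000000001#_000004")
  # species references are typed, not blank
  for (ref in c(reactants, products)) {
    expect_true(any(df$subject == ref &
      df$object == paste0(sbmlrdf, "SpeciesReference")))
  }
})

test_that("math renders to a notes string on its element, or nothing", {
  model <- assign_metaids(parse_sbml(paper_fragment()))
  rx <- model$reactions[[1]]
  t <- convert_math(rx, model$model_id)
  expect_equal(t$predicate, "http://identifiers.org/biomodels.vocabulary#notes")
  # token multiset check against an independent MathML walk
  tokens <- sort(regmatches(t$object, gregexpr("[A-Za-z_0-9]+", t$object))[[1]])
  independent <- sort(trimws(xml2::xml_text(xml2::xml_find_all(
    xml2::read_xml(rx$math), "//*[local-name()='ci']"))))
  expect_equal(tokens, independent)

  no_math <- model$reactions[[1]]
  no_math$math <- NULL
  expect_null(convert_math(no_math, model$model_id))
})

test_that("assignment rules carry their formula as a notes string", {
  xml <- wrap_sbml(paste0(
    '<listOfParameters><parameter id="k1" metaid="mk1" value="2"/></listOfParameters>',
    '<listOfRules><assignmentRule metaid="mr1" variable="k1">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><plus/><ci>a</ci><ci>b</ci></apply></math></assignmentRule></listOfRules>"),
    model_id = "RULETEST")
  df <- as.data.frame(convert_model(parse_sbml(xml), curated = FALSE))
  notes <- df[df$subject == "http://identifiers.org/biomodels.db/RULETEST#mr1" &
    df$predicate == "http://identifiers.org/biomodels.vocabulary#notes", ]
  expect_equal(nrow(notes), 1)
  expect_true(grepl("a", notes$object) && grepl("b", notes$object))
})

test_that("unresolvable species references and duplicate metaids are errors", {
  bad_ref <- wrap_sbml(paste0(
    '<listOfSpecies><species id="s1" metaid="ms1"/></listOfSpecies>',
    '<listOfReactions><reaction id="r1" metaid="mr1">',
    '<listOfReactants><speciesReference species="ghost"/></listOfReactants>',
    "</reaction></listOfReactions>"))
  expect_error(convert_model(parse_sbml(bad_ref)), "r1")

  dup <- wrap_sbml(paste0(
    '<listOfSpecies><species id="s1" metaid="dup"/>',
    '<species id="s2" metaid="dup"/></listOfSpecies>'))
  expect_error(convert_model(parse_sbml(dup)), "duplicate metaid")
})

ntriples_lines_for_test <- function(df) {
  obj <- ifelse(df$object_kind == "uri", paste0("<", df$object, ">"),
    paste0('"', df$object, '"',
      ifelse(is.na(df$datatype), "", paste0("^^<", df$datatype, ">"))))
  paste0("<", df$subject, "> <", df$predicate, "> ", obj, " .")
}

test_that("serialization is deterministic and round-trips", {
  fx <- generate_model(fixture_spec(seed = 31))
  g1 <- convert_model(parse_sbml(fx$xml), curated = TRUE)
  g2 <- convert_model(parse_sbml(fx$xml), curated = TRUE)
  nt1 <- serialize_graph(g1, "ntriples")
  expect_identical(nt1, serialize_graph(g2, "ntriples"))

  expect_identical(serialize_graph(rdf_graph(), "ntriples"), "")
  expect_error(serialize_graph(g1, "rdfxml"), "unknown serialization format")

  # native N-Triples round-trip is exact
  expect_identical(serialize_graph(parse_ntriples(nt1), "ntriples"), nt1)

  # Turtle round-trip through the rdflib engine preserves the triple
  # set; double literals may be value-normalized (e.g. "0" -> "0.0")
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(serialize_graph(g1, "turtle"), path, sep = "", useBytes = TRUE)
  back <- as.data.frame(read_rdf_file(path))
  orig <- as.data.frame(g1)
  canon <- function(df) {
    dbl <- !is.na(df$datatype) & df$datatype == "http://www.w3.org/2001/XMLSchema#double"
    df$object[dbl] <- as.character(as.numeric(df$object[dbl]))
    sort(ntriples_lines_for_test(df), method = "radix")
  }
  expect_identical(canon(back), canon(orig))
})

test_that("converter output matches the rule-enumeration oracle on varied fixtures", {
  for (seed in c(2, 8, 15)) {
    for (coverage in c(1, 0.5)) {
      fx <- generate_model(fixture_spec(seed = seed, n_species = 6,
        n_reactions = 3, annotation_density = 0.7, metaid_coverage = coverage))
      model <- parse_sbml(fx$xml)
      got <- sorted_nt(convert_model(model, curated = fx$curated))
      expect_identical(got, oracle_ntriples(model, fx$curated))
    }
  }
})

test_that("count conservation holds against the fixture ledger", {
  fx <- generate_model(fixture_spec(seed = 40, annotation_density = 1))
  model <- parse_sbml(fx$xml)
  df <- as.data.frame(convert_model(model, curated = TRUE))
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  n_typed <- function(cls) {
    sum(df$predicate == rdf_type &
      df$object == paste0("http://identifiers.org/biomodels.vocabulary#", cls))
  }
  expect_equal(n_typed("Species"), fx$ledger$n_species)
  expect_equal(n_typed("Reaction"), fx$ledger$n_reactions)
  expect_equal(n_typed("SpeciesReference"), fx$ledger$n_species_references)
  qualifier <- startsWith(df$predicate, "http://biomodels.net/")
  expect_equal(sum(qualifier), fx$ledger$n_annotation_links)
})
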