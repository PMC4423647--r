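test_that("a minimal document parses to empty element lists", {
  model <- parse_sbml(wrap_sbml(
    '<listOfCompartments><compartment id="c1" constant="true"/></listOfCompartments>'))
  expect_s3_class(model, "sbml_model")
  expect_equal(model$model_id, "TESTMODEL")
  expect_length(model$compartments, 1)
  expect_length(model$species, 0)
  expect_length(model$reactions, 0)
})

test_that("the BIOMD0000000001-style fragment parses with its metaids intact", {
  model <- parse_sbml(paper_fragment())
  expect_equal(model$model_id, "BIOMD0000000001")
  rx <- model$reactions[[1]]
  expect_equal(rx$metaid, "_000017")
  expect_length(rx$children$reactants, 1)
  expect_length(rx$children$products, 1)
  expect_equal(model$species[[1]]$metaid, "_000003")
  expect_equal(rx$children$reactants[[1]]$species, "BasalACh")
})

test_that("malformed and non-SBML inputs fail loudly", {
  expect_error(parse_sbml("<sbml><model id='x'"), "parse error")
  expect_error(parse_sbml("<notSBML><model id='x'/></notSBML>"),
    "unsupported format")
  l1 <- '<sbml xmlns="http://www.sbml.org/sbml/level1" level="1" version="2"><model id="m"/></sbml>'
  expect_error(parse_sbml(l1), "unsupported SBML level")
})

test_that("attributes are typed per the declared scheme and nothing is injected", {
  xml <- wrap_sbml(paste0(
    '<listOfCompartments><compartment id="c1" size="1.5" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="s1" compartment="c1" initialConcentration="0.25"',
    ' boundaryCondition="false"/></listOfSpecies>'))
  model <- parse_sbml(xml)
  sp <- model$species[[1]]
  expect_identical(sp$attributes$initialConcentration, 0.25)
  expect_identical(sp$attributes$boundaryCondition, FALSE)
  expect_identical(sp$attributes$compartment, "c1")
  expect_identical(sp$attributes_raw[["initialConcentration"]], "0.25")
  # only attributes present in the source; id is held in its own field
  expect_setequal(names(sp$attributes),
    c("compartment", "initialConcentration", "boundaryCondition"))
  cp <- model$compartments[[1]]
  expect_identical(cp$attributes$size, 1.5)
  expect_identical(cp$attributes$constant, TRUE)
})

test_that("XHTML notes are flattened to whitespace-collapsed text", {
  xml <- wrap_sbml(paste0(
    "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
    "<p>A  model\n   of <b>something</b></p></body></notes>"))
  model <- parse_sbml(xml)
  expect_equal(model$notes_text, "A model of something")
})

test_that("element counts match an independent XML node scan", {
  counts_by_scan <- function(xml) {
    doc <- xml2::read_xml(xml)
    count <- function(tag) {
      length(xml2::xml_find_all(doc, paste0("//*[local-name()='", tag, "']")))
    }
    c(
      compartment = count("compartment"),
      species = count("species"),
      reaction = count("reaction"),
      parameter = count("parameter"),
      unit_definition = count("unitDefinition"),
      speciesref = count("speciesReference") + count("modifierSpeciesReference")
    )
  }
  for (seed in c(3, 11, 27)) {
    fx <- generate_model(fixture_spec(seed = seed,
      n_species = 5 + seed %% 4, n_reactions = 3, annotation_density = 0.5))
    model <- parse_sbml(fx$xml)
    scan <- counts_by_scan(fx$xml)
    expect_equal(length(model$compartments), unname(scan["compartment"]))
    expect_equal(length(model$species), unname(scan["species"]))
    expect_equal(length(model$reactions), unname(scan["reaction"]))
    expect_equal(length(model$parameters), unname(scan["parameter"]))
    expect_equal(length(model$unit_definitions), unname(scan["unit_definition"]))
    n_refs <- sum(vapply(model$reactions, function(rx) {
      length(rx$children$reactants) + length(rx$children$products) +
        length(rx$children$modifiers)
    }, integer(1)))
    expect_equal(n_refs, unname(scan["speciesref"]))
  }
})

test_that("parsing is deterministic and no ListOf kind survives", {
  fx <- generate_model(fixture_spec(seed = 5))
  m1 <- parse_sbml(fx$xml)
  m2 <- parse_sbml(fx$xml)
  expect_identical(m1, m2)
  kinds <- vapply(all_elements_of(m1), function(e) e$kind, character(1))
  expect_false(any(grepl("list", kinds, ignore.case = TRUE)))
  expect_true(all(kinds %in% c("compartment", "species", "reaction",
    "parameter", "unit_definition", "rule")))
})

test_that("annotation bags flatten to ordered qualifier-resource pairs", {
  expect_equal(nrow(extract_annotations("<annotation/>")), 0)
  expect_equal(nrow(extract_annotations(
    "<annotation><p>no rdf here</p></annotation>")), 0)

  one <- extract_annotations(paste0(
    '<annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
    '<rdf:Description rdf:about="#m1"><bqbiol:is><rdf:Bag>',
    '<rdf:li rdf:resource="http://identifiers.org/taxonomy/10114"/>',
    "</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>"))
  expect_equal(one$ns, "bqbiol")
  expect_equal(one$local, "is")
  expect_equal(one$uri, "http://identifiers.org/taxonomy/10114")

  # three-entry bag: order preserved, verified against a generic XML walk
  uris <- paste0("http://identifiers.org/go/GO:000000", 1:3)
  xml <- paste0(
    '<annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
    '<rdf:Description rdf:about="#m1"><bqbiol:isVersionOf><rdf:Bag>',
    paste0('<rdf:li rdf:resource="', uris, '"/>', collapse = ""),
    "</rdf:Bag></bqbiol:isVersionOf></rdf:Description></rdf:RDF></annotation>")
  links <- extract_annotations(xml)
  independent <- xml2::xml_attr(
    xml2::xml_find_all(xml2::read_xml(xml), "//*[local-name()='li']"),
    "resource")
  expect_equal(links$uri, independent)
  expect_equal(links$local, rep("isVersionOf", 3))
})

test_that("unrecognized qualifier namespaces are kept and flagged", {
  xml <- paste0(
    '<annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:myq="http://example.org/qualifiers/">',
    '<rdf:Description rdf:about="#m1"><myq:relatesTo><rdf:Bag>',
    '<rdf:li rdf:resource="http://identifiers.org/go/GO:0000001"/>',
    "</rdf:Bag></myq:relatesTo></rdf:Description></rdf:RDF></annotation>")
  expect_message(links <- extract_annotations(xml), "unrecognized namespace")
  expect_equal(nrow(links), 1)
  expect_equal(links$ns, "http://example.org/qualifiers/")
  expect_equal(links$local, "relatesTo")
})

test_that("species references always resolve in generated fixtures", {
  fx <- generate_model(fixture_spec(seed = 9, n_species = 4, n_reactions = 6))
  model <- parse_sbml(fx$xml)
  ids <- vapply(model$species, function(s) s$sbml_id, character(1))
  for (rx in model$reactions) {
    for (ref in c(rx$children$reactants, rx$children$products,
        rx$children$modifiers)) {
      expect_true(ref$species %in% ids)
    }
  }
})
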