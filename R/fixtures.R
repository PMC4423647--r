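# Deterministic synthetic SBML generator. Every other module is testable
# against the ground-truth ledger recorded while the document is built:
# element counts per kind, every annotation link drawn, and the distinct
# annotation-signature counts the statistics engine must reproduce.
# Identical specs produce byte-identical documents: randomness comes
# only from the spec seed, names from a fixed word list, and numbers are
# formatted with fixed precision.

.FIXTURE_WORDS <- c(
  "calcium", "cyclin", "kinase", "receptor", "ligand", "channel", "complex",
  "phosphate", "glucose", "pyruvate", "lactate", "insulin", "cascade",
  "dimer", "promoter", "repressor", "transporter", "synthase", "oxidase",
  "membrane", "cytosolic", "nuclear", "active", "inactive", "bound", "free"
)

#' Default concept pool for generated annotations
#'
#' A small cross-section of the Identifiers.org collections most used
#' to annotate curated models: GO terms, ChEBI entities, UniProt
#' proteins, NCBI taxa and Reactome pathways.
#'
#' @return Character vector of Identifiers.org URIs.
#' @export
default_concept_pool <- function() {
  c(
    "http://identifiers.org/go/GO:0005892",
    "http://identifiers.org/go/GO:0005829",
    "http://identifiers.org/go/GO:0006096",
    "http://identifiers.org/chebi/CHEBI:29108",
    "http://identifiers.org/chebi/CHEBI:15355",
    "http://identifiers.org/chebi/CHEBI:17234",
    "http://identifiers.org/uniprot/P12345",
    "http://identifiers.org/uniprot/P04637",
    "http://identifiers.org/taxonomy/10114",
    "http://identifiers.org/taxonomy/9606",
    "http://identifiers.org/reactome/REACT_152",
    "http://identifiers.org/reactome/REACT_1046"
  )
}

#' Specification of one synthetic model
#'
#' The defaults describe a typical curated literature model: a dozen
#' species in two compartments, eight reactions, and annotations on
#' most elements (curated models are extensively cross-referenced).
#'
#' @param seed integer RNG seed; together with the other fields it
#'   fully determines the generated bytes.
#' @param n_species,n_reactions,n_compartments,n_parameters,n_rules,n_unit_definitions
#'   element counts.
#' @param annotation_density probability in `[0, 1]` that an
#'   annotatable element (compartment, species, reaction) carries an
#'   annotation bag.
#' @param concept_pool Identifiers.org URIs annotations are drawn from.
#' @param curated curated-branch flag recorded in manifests.
#' @param model_id model identifier; default derives from the seed.
#' @param metaid_coverage fraction of elements given an explicit
#'   metaid in the XML (species references included); the default 1
#'   mirrors curated models, lower values exercise metaid minting.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_species = 12L, n_reactions = 8L,
                         n_compartments = 2L, n_parameters = 2L, n_rules = 1L,
                         n_unit_definitions = 1L, annotation_density = 0.8,
                         concept_pool = default_concept_pool(), curated = TRUE,
                         model_id = sprintf("SYNM%07d", seed),
                         metaid_coverage = 1) {
  stopifnot(
    n_species >= 0, n_reactions >= 0, n_compartments >= 0, n_parameters >= 0,
    n_rules >= 0, n_unit_definitions >= 0,
    annotation_density >= 0, annotation_density <= 1,
    metaid_coverage >= 0, metaid_coverage <= 1
  )
  if (n_reactions > 0 && n_species == 0) {
    stop("cannot generate reactions without species", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    n_reactions = as.integer(n_reactions),
    n_compartments = as.integer(n_compartments),
    n_parameters = as.integer(n_parameters), n_rules = as.integer(n_rules),
    n_unit_definitions = as.integer(n_unit_definitions),
    annotation_density = annotation_density, concept_pool = concept_pool,
    curated = isTRUE(curated), model_id = model_id,
    metaid_coverage = metaid_coverage
  ), class = "fixture_spec")
}

with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Generate a synthetic SBML model with its ground-truth ledger
#'
#' Emits a well-formed SBML Level 3 Version 1 core document whose
#' reactions reference existing species and whose annotations are
#' written in the standard `rdf:Bag` form under bqbiol qualifiers
#' (plus one model-level bqmodel link); bags occasionally carry several
#' `rdf:li` entries and a second qualifier, so annotation flattening is
#' exercised. The returned ledger records exactly what was drawn, so
#' parser, converter, query and statistics results can be checked
#' against it independently.
#'
#' @param spec a [fixture_spec()].
#' @return List with elements `xml` (single string), `ledger` (counts,
#'   the full link table, and annotation-signature sets), `model_id`
#'   and `curated`.
#' @export
generate_model <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, build_fixture_model(spec))
}

build_fixture_model <- function(spec) {
  meta_counter <- 0L
  next_meta <- function() {
    meta_counter <<- meta_counter + 1L
    sprintf("_%06d", meta_counter)
  }
  maybe_meta <- function() {
    if (stats::runif(1) <= spec$metaid_coverage) next_meta() else NA_character_
  }
  meta_attr <- function(m) if (is.na(m)) "" else sprintf(' metaid="%s"', m)
  word_name <- function() {
    paste(sample(.FIXTURE_WORDS, 2L), collapse = " ")
  }

  links <- list()
  record_link <- function(owner, kind, ns, local, uri) {
    links[[length(links) + 1L]] <<- data.frame(
      element = owner, kind = kind, ns = ns, local = local, uri = uri,
      stringsAsFactors = FALSE
    )
  }

  # rdf:Bag annotation block for one element; records every link drawn
  annotation_block <- function(owner_meta, kind, about, bqmodel_self = NULL) {
    quals <- character()
    if (!is.null(bqmodel_self)) {
      quals <- c(quals, bag_xml("bqmodel", "is", bqmodel_self))
      record_link(owner_meta, kind, "bqmodel", "is", bqmodel_self)
    }
    if (is.null(bqmodel_self)) {
      pool <- spec$concept_pool
      k <- sample(seq_len(min(3L, length(pool))), 1L)
      drawn <- sample(pool, k)
      quals <- c(quals, bag_xml("bqbiol", "is", drawn))
      for (u in drawn) record_link(owner_meta, kind, "bqbiol", "is", u)
      if (length(pool) > 1 && stats::runif(1) < 0.3) {
        k2 <- sample(seq_len(min(2L, length(pool))), 1L)
        drawn2 <- sample(pool, k2)
        quals <- c(quals, bag_xml("bqbiol", "isVersionOf", drawn2))
        for (u in drawn2) record_link(owner_meta, kind, "bqbiol", "isVersionOf", u)
      }
    }
    paste0(
      "<annotation><rdf:RDF",
      " xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
      " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\"",
      " xmlns:bqmodel=\"http://biomodels.net/model-qualifiers/\">",
      "<rdf:Description rdf:about=\"#", about, "\">",
      paste(quals, collapse = ""),
      "</rdf:Description></rdf:RDF></annotation>"
    )
  }
  bag_xml <- function(prefix, local, uris) {
    paste0(
      "<", prefix, ":", local, "><rdf:Bag>",
      paste0("<rdf:li rdf:resource=\"", uris, "\"/>", collapse = ""),
      "</rdf:Bag></", prefix, ":", local, ">"
    )
  }

  model_meta <- next_meta()
  model_ann <- annotation_block(model_meta, "model", model_meta,
    bqmodel_self = paste0("http://identifiers.org/biomodels.db/", spec$model_id))

  compartment_ids <- sprintf("comp%d", seq_len(max(spec$n_compartments, 1L)))
  compartments <- vapply(seq_len(spec$n_compartments), function(i) {
    m <- maybe_meta()
    ann <- if (stats::runif(1) < spec$annotation_density && length(spec$concept_pool)) {
      annotation_block(if (is.na(m)) compartment_ids[i] else m, "compartment",
        if (is.na(m)) compartment_ids[i] else m)
    } else ""
    sprintf(
      '<compartment id="%s"%s name="%s" size="%s" constant="true">%s</compartment>',
      compartment_ids[i], meta_attr(m), xml_escape(word_name()),
      sprintf("%.4f", stats::runif(1, 0.5, 2)), ann
    )
  }, character(1))

  species_ids <- sprintf("S%d", seq_len(spec$n_species))
  species <- vapply(seq_len(spec$n_species), function(i) {
    m <- maybe_meta()
    named <- stats::runif(1) < 0.7
    amount_attr <- if (stats::runif(1) < 0.67) {
      sprintf(' initialConcentration="%.4f"', stats::runif(1, 0, 10))
    } else {
      sprintf(' initialAmount="%.4f"', stats::runif(1, 0, 100))
    }
    ann <- if (stats::runif(1) < spec$annotation_density && length(spec$concept_pool)) {
      annotation_block(if (is.na(m)) species_ids[i] else m, "species",
        if (is.na(m)) species_ids[i] else m)
    } else ""
    sprintf(
      '<species id="%s"%s%s compartment="%s"%s boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false">%s</species>',
      species_ids[i], meta_attr(m),
      if (named) sprintf(' name="%s"', xml_escape(word_name())) else "",
      sample(compartment_ids[seq_len(max(spec$n_compartments, 1L))], 1L),
      amount_attr, ann
    )
  }, character(1))

  parameter_ids <- sprintf("k%d", seq_len(spec$n_parameters))
  parameters <- vapply(seq_len(spec$n_parameters), function(i) {
    sprintf('<parameter id="%s"%s value="%s" constant="true"/>',
      parameter_ids[i], meta_attr(maybe_meta()),
      sprintf("%.4f", stats::runif(1, 0, 5)))
  }, character(1))

  sref <- function(role_tag, sp) {
    paste0("<", role_tag, sprintf(' species="%s"', sp), meta_attr(maybe_meta()),
      sprintf(' stoichiometry="%d" constant="true"/>', sample(1:2, 1L)))
  }
  n_sref <- 0L
  reactions <- vapply(seq_len(spec$n_reactions), function(i) {
    m <- maybe_meta()
    rid <- sprintf("R%d", i)
    n_reactants <- sample(1:min(2L, spec$n_species), 1L)
    n_products <- sample(1:min(2L, spec$n_species), 1L)
    reactants <- sample(species_ids, n_reactants)
    products <- sample(species_ids, n_products)
    modifier <- if (spec$n_species > 2 && stats::runif(1) < 0.4) {
      sample(species_ids, 1L)
    } else {
      character()
    }
    n_sref <<- n_sref + n_reactants + n_products + length(modifier)
    ann <- if (stats::runif(1) < spec$annotation_density && length(spec$concept_pool)) {
      annotation_block(if (is.na(m)) rid else m, "reaction", if (is.na(m)) rid else m)
    } else ""
    math <- if (spec$n_parameters > 0 && stats::runif(1) < 0.7) {
      paste0(
        "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
        "<apply><times/><ci> ", sample(parameter_ids, 1L), " </ci><ci> ",
        reactants[1], " </ci></apply></math></kineticLaw>"
      )
    } else ""
    paste0(
      sprintf('<reaction id="%s"%s reversible="%s" fast="false">', rid,
        meta_attr(m), if (stats::runif(1) < 0.3) "true" else "false"),
      ann,
      "<listOfReactants>",
      paste(vapply(reactants, function(s) sref("speciesReference", s),
        character(1)), collapse = ""),
      "</listOfReactants><listOfProducts>",
      paste(vapply(products, function(s) sref("speciesReference", s),
        character(1)), collapse = ""),
      "</listOfProducts>",
      if (length(modifier)) paste0("<listOfModifiers>",
        sref("modifierSpeciesReference", modifier), "</listOfModifiers>") else "",
      math,
      "</reaction>"
    )
  }, character(1))

  unit_definitions <- vapply(seq_len(spec$n_unit_definitions), function(i) {
    sprintf(paste0(
      '<unitDefinition id="ud%d"%s name="per second">',
      '<listOfUnits><unit kind="second" exponent="-1" scale="0" multiplier="1"/>',
      "</listOfUnits></unitDefinition>"), i, meta_attr(maybe_meta()))
  }, character(1))

  rules <- vapply(seq_len(spec$n_rules), function(i) {
    target <- if (spec$n_parameters > 0) parameter_ids[1] else "unused"
    operand <- if (spec$n_species > 0) species_ids[1] else "1"
    sprintf(paste0(
      '<assignmentRule%s variable="%s">',
      '<math xmlns="http://www.w3.org/1998/Math/MathML">',
      "<apply><plus/><ci> %s </ci><cn> 1 </cn></apply></math></assignmentRule>"),
      meta_attr(maybe_meta()), target, operand)
  }, character(1))

  list_of <- function(tag, items) {
    if (!length(items)) "" else paste0("<", tag, ">",
      paste(items, collapse = ""), "</", tag, ">")
  }
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" level=\"3\" version=\"1\">",
    sprintf('<model id="%s" metaid="%s" name="%s">', spec$model_id, model_meta,
      xml_escape(paste("Synthetic model", spec$model_id))),
    model_ann,
    list_of("listOfUnitDefinitions", unit_definitions),
    list_of("listOfCompartments", compartments),
    list_of("listOfSpecies", species),
    list_of("listOfParameters", parameters),
    list_of("listOfRules", rules),
    list_of("listOfReactions", reactions),
    "</model></sbml>\n"
  )

  link_tab <- if (length(links)) do.call(rbind, links) else
    data.frame(element = character(), kind = character(), ns = character(),
      local = character(), uri = character(), stringsAsFactors = FALSE)
  ledger <- build_ledger(spec, link_tab, n_sref)
  list(xml = xml, ledger = ledger, model_id = spec$model_id,
    curated = spec$curated)
}

signature_set <- function(link_tab, kind) {
  rows <- link_tab[link_tab$kind == kind & link_tab$ns == "bqbiol", , drop = FALSE]
  if (!nrow(rows)) return(character())
  vapply(split(rows$uri, rows$element),
    function(u) paste(sort_c(unique(u)), collapse = "\n"), character(1))
}

build_ledger <- function(spec, link_tab, n_sref) {
  species_sigs <- signature_set(link_tab, "species")
  reaction_sigs <- signature_set(link_tab, "reaction")
  list(
    model_id = spec$model_id,
    curated = spec$curated,
    n_compartments = spec$n_compartments,
    n_species = spec$n_species,
    n_reactions = spec$n_reactions,
    n_parameters = spec$n_parameters,
    n_unit_definitions = spec$n_unit_definitions,
    n_rules = spec$n_rules,
    n_species_references = n_sref,
    links = link_tab,
    n_annotation_links = nrow(link_tab),
    n_distinct_concepts = length(unique(link_tab$uri)),
    species_signatures = species_sigs,
    reaction_signatures = reaction_sigs,
    n_distinct_species_signatures = length(unique(species_sigs)),
    n_distinct_reaction_signatures = length(unique(reaction_sigs))
  )
}

#' Aggregate per-model ledgers into corpus-level expectations
#'
#' Mirrors how [compute_stats()] counts a loaded corpus: totals are
#' sums, distinct concepts the union, and distinct annotated
#' species/reactions the number of unique annotation signatures across
#' all models.
#'
#' @param ledgers list of ledgers from [generate_model()].
#' @return Named list of expected corpus counts.
#' @export
aggregate_ledgers <- function(ledgers) {
  pull <- function(field) vapply(ledgers, function(l) l[[field]], numeric(1))
  all_links <- do.call(rbind, lapply(ledgers, `[[`, "links"))
  list(
    n_species = sum(pull("n_species")),
    n_reactions = sum(pull("n_reactions")),
    n_crossref_triples = if (is.null(all_links)) 0L else nrow(all_links),
    n_distinct_concepts = if (is.null(all_links)) 0L else
      length(unique(all_links$uri)),
    n_distinct_annotated_species = length(unique(unlist(
      lapply(ledgers, `[[`, "species_signatures")))),
    n_distinct_reactions_by_annotation = length(unique(unlist(
      lapply(ledgers, `[[`, "reaction_signatures"))))
  )
}

#' Generate a multi-model corpus with manifest
#'
#' @param n_models number of models.
#' @param seed base seed; model `i` uses `seed + i`.
#' @param dir when given, each model is written to
#'   `<dir>/<model_id>.xml` and a `manifest.tsv` alongside.
#' @param ... passed to [fixture_spec()] (all models share these).
#' @return List with `models` (each a [generate_model()] result),
#'   `manifest` data.frame, and `paths`/`manifest_path` when `dir` was
#'   given.
#' @export
generate_corpus <- function(n_models, seed = 1L, dir = NULL, ...) {
  fixed <- list(...)
  models <- lapply(seq_len(n_models), function(i) {
    args <- c(list(seed = seed + i,
      model_id = sprintf("SYNM%07d", seed + i),
      curated = i %% 2 == 1), fixed)
    generate_model(do.call(fixture_spec, args))
  })
  manifest <- data.frame(
    model_id = vapply(models, `[[`, character(1), "model_id"),
    curated = vapply(models, `[[`, logical(1), "curated"),
    stringsAsFactors = FALSE
  )
  out <- list(models = models, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$paths <- vapply(models, function(m) {
      p <- file.path(dir, paste0(m$model_id, ".xml"))
      writeLines(m$xml, p, useBytes = TRUE)
      p
    }, character(1))
    out$manifest_path <- file.path(dir, "manifest.tsv")
    writeLines(sprintf("%s\t%s", manifest$model_id,
      tolower(as.character(manifest$curated))), out$manifest_path,
      useBytes = TRUE)
  }
  out
}

#' Minimal hand-built model echoing the first curated BioModels entry
#'
#' A synthetic fragment shaped like the acetylcholine receptor model
#' BIOMD0000000001 (Edelstein1996): a species `BasalACh` carrying
#' metaid `_000003`, a reversible reaction with metaid `_000017`
#' converting `BasalACh` to `BasalACh2` (one reactant, one product,
#' species references without metaids), GO channel-complex annotations,
#' and a mass-action kinetic law. Used to pin the URI contract of the
#' conversion.
#'
#' @return SBML document as a single string.
#' @export
paper_fragment <- function() {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" level=\"2\" version=\"4\">",
    "<model id=\"BIOMD0000000001\" metaid=\"_000001\" name=\"Edelstein1996 - EPSP ACh event\">",
    "<annotation><rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    " xmlns:bqmodel=\"http://biomodels.net/model-qualifiers/\"",
    " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">",
    "<rdf:Description rdf:about=\"#_000001\">",
    "<bqmodel:is><rdf:Bag>",
    "<rdf:li rdf:resource=\"http://identifiers.org/biomodels.db/BIOMD0000000001\"/>",
    "</rdf:Bag></bqmodel:is>",
    "<bqbiol:hasTaxon><rdf:Bag>",
    "<rdf:li rdf:resource=\"http://identifiers.org/taxonomy/7787\"/>",
    "</rdf:Bag></bqbiol:hasTaxon>",
    "</rdf:Description></rdf:RDF></annotation>",
    "<listOfCompartments>",
    "<compartment id=\"comp1\" metaid=\"_000002\" name=\"compartment\" size=\"1e-16\"/>",
    "</listOfCompartments>",
    "<listOfSpecies>",
    "<species id=\"BasalACh\" metaid=\"_000003\" name=\"BasalACh\"",
    " compartment=\"comp1\" initialAmount=\"0\">",
    "<annotation><rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">",
    "<rdf:Description rdf:about=\"#_000003\">",
    "<bqbiol:is><rdf:Bag>",
    "<rdf:li rdf:resource=\"http://identifiers.org/go/GO:0005892\"/>",
    "<rdf:li rdf:resource=\"http://identifiers.org/chebi/CHEBI:15355\"/>",
    "</rdf:Bag></bqbiol:is>",
    "</rdf:Description></rdf:RDF></annotation>",
    "</species>",
    "<species id=\"BasalACh2\" metaid=\"_000004\" name=\"BasalACh2\"",
    " compartment=\"comp1\" initialAmount=\"0\">",
    "<annotation><rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">",
    "<rdf:Description rdf:about=\"#_000004\">",
    "<bqbiol:is><rdf:Bag>",
    "<rdf:li rdf:resource=\"http://identifiers.org/go/GO:0005892\"/>",
    "</rdf:Bag></bqbiol:is>",
    "</rdf:Description></rdf:RDF></annotation>",
    "</species>",
    "</listOfSpecies>",
    "<listOfParameters>",
    "<parameter id=\"kf_0\" metaid=\"_000005\" value=\"3000\"/>",
    "</listOfParameters>",
    "<listOfReactions>",
    "<reaction id=\"React0\" metaid=\"_000017\" reversible=\"true\">",
    "<listOfReactants><speciesReference species=\"BasalACh\"/></listOfReactants>",
    "<listOfProducts><speciesReference species=\"BasalACh2\"/></listOfProducts>",
    "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    "<apply><times/><ci> kf_0 </ci><ci> BasalACh </ci></apply>",
    "</math></kineticLaw>",
    "</reaction>",
    "</listOfReactions>",
    "</model></sbml>\n"
  )
}
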