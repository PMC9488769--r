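SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# Identifier sanitization: non-alphanumeric characters become underscores and
# a role prefix is applied (R_/M_/G_), common SBML convention.
sanitize_id <- function(x, prefix) {
  clean <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl(paste0("^", prefix), clean), clean, paste0(prefix, clean))
}

#' Write a model as SBML Level 3 with fbc
#'
#' Serializes the model as SBML Level 3 Version 1 with the fbc version 2
#' package: parameters carry the flux bounds, the objective is an
#' fbc:listOfObjectives entry, genes become fbc:geneProduct elements and each
#' reaction's flat-OR gene set an fbc:geneProductAssociation. Systems Biology
#' Ontology terms are attached to every gene (SBO:0000243), reaction
#' (SBO:0000375) and species (SBO:0000247) element. EC links, provenance and
#' gap-fill penalties are recorded in reaction notes. Identifiers are
#' sanitized (non-alphanumerics to underscore, R_/M_/G_ prefixes); the
#' original-to-sanitized mapping is returned invisibly.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return invisibly, a data.frame mapping original to sanitized ids.
#' @export
write_sbml <- function(model, path) {
  mets <- metabolites(model)
  rxn_ids <- names(model$reactions)
  genes <- sort(unique(unlist(lapply(model$reactions, `[[`, "genes"))))
  m_id <- stats::setNames(sanitize_id(mets, "M_"), mets)
  r_id <- stats::setNames(sanitize_id(rxn_ids, "R_"), rxn_ids)
  g_id <- stats::setNames(sanitize_id(genes, "G_"), genes)
  if (anyDuplicated(c(m_id, r_id, g_id)))
    stop("identifier sanitization produced duplicates")

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">',
            sanitize_id(model$id, "")),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>')

  lines <- c(lines, '    <listOfSpecies>')
  for (m in mets) {
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="c" ',
             'sboTerm="SBO:0000247" hasOnlySubstanceUnits="false" ',
             'boundaryCondition="false" constant="false"/>'),
      m_id[[m]], m))
  }
  lines <- c(lines, '    </listOfSpecies>')

  # one parameter per distinct bound value
  bvals <- sort(unique(unlist(lapply(model$reactions,
                                     function(r) c(r$lower, r$upper)))))
  pname <- stats::setNames(
    paste0("bnd_", gsub("[^0-9A-Za-z]", "_", format(bvals, trim = TRUE))),
    format(bvals, trim = TRUE))
  lines <- c(lines, '    <listOfParameters>')
  for (v in bvals)
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      pname[[format(v, trim = TRUE)]],
      format(v, digits = 17, trim = TRUE)))
  lines <- c(lines, '    </listOfParameters>')

  lines <- c(lines, '    <listOfReactions>')
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" sboTerm="SBO:0000375" ',
             'reversible="%s" fast="false" fbc:lowerFluxBound="%s" ',
             'fbc:upperFluxBound="%s">'),
      r_id[[r$id]], r$name, if (r$lower < 0) "true" else "false",
      pname[[format(r$lower, trim = TRUE)]],
      pname[[format(r$upper, trim = TRUE)]]))
    lines <- c(lines,
      '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('          <p>PROVENANCE: %s</p>', r$provenance),
      sprintf('          <p>EC: %s</p>', paste(r$ecs, collapse = ";")),
      sprintf('          <p>PENALTY: %s</p>',
              format(r$penalty, digits = 17)),
      '        </body></notes>')
    subs <- r$stoichiometry[r$stoichiometry < 0]
    prods <- r$stoichiometry[r$stoichiometry > 0]
    if (length(subs)) {
      lines <- c(lines, '        <listOfReactants>')
      for (m in names(subs))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          m_id[[m]], format(abs(subs[[m]]), digits = 17)))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prods)) {
      lines <- c(lines, '        <listOfProducts>')
      for (m in names(prods))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          m_id[[m]], format(prods[[m]], digits = 17)))
      lines <- c(lines, '        </listOfProducts>')
    }
    if (length(r$genes)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>')
      refs <- sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>',
                      g_id[r$genes])
      if (length(refs) > 1)
        refs <- c("<fbc:or>", paste0("  ", refs), "</fbc:or>")
      lines <- c(lines, paste0("          ", refs),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')

  if (!is.null(model$objective)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                     'fbc:coefficient="1"/>'), r_id[[model$objective]]),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  } else {
    warning("model has no objective; SBML written without an objective element")
  }

  if (length(genes)) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>')
    for (g in genes)
      lines <- c(lines, sprintf(
        paste0('      <fbc:geneProduct fbc:id="%s" fbc:label="%s" ',
               'sboTerm="SBO:0000243"/>'), g_id[[g]], g))
    lines <- c(lines, '    </fbc:listOfGeneProducts>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
  # parse once to guarantee well-formed XML
  invisible({
    xml2::read_xml(path)
    data.frame(original = c(mets, rxn_ids, genes),
               sanitized = c(m_id, r_id, g_id), row.names = NULL,
               stringsAsFactors = FALSE)
  })
}

#' Read an SBML Level 3 (fbc) model
#'
#' Round-trip companion of [write_sbml()]: recovers stoichiometry, bounds,
#' gene associations, the active objective, and the provenance / EC / penalty
#' notes.
#'
#' @param path SBML file.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  if (!identical(xml2::xml_attr(doc, "level"), "3"))
    stop("unsupported SBML level (only Level 3 is read)")
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  model <- metabolic_model(xml2::xml_attr(mdl, "id") %||% "model")

  par_nodes <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  sp_name <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
           xml2::xml_attr(sp_nodes, "id"), xml2::xml_attr(sp_nodes, "name")),
    xml2::xml_attr(sp_nodes, "id"))
  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:geneProduct", ns)
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           xml2::xml_attr(gp_nodes, "id"), xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  note_field <- function(rx, key) {
    ps <- trimws(xml2::xml_text(
      xml2::xml_find_all(rx, ".//s:notes//*[local-name()='p']", ns)))
    hit <- ps[startsWith(ps, paste0(key, ": "))]
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, ": "), "", hit[1])
  }

  for (rx in xml2::xml_find_all(doc, ".//s:reaction", ns)) {
    rid <- xml2::xml_attr(rx, "id")
    rname <- xml2::xml_attr(rx, "name") %||% rid
    lo <- pars[[xml2::xml_attr(rx, "lowerFluxBound")]]
    hi <- pars[[xml2::xml_attr(rx, "upperFluxBound")]]
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns))
      st[sp_name[[xml2::xml_attr(sr, "species")]]] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns))
      st[sp_name[[xml2::xml_attr(sr, "species")]]] <-
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    grefs <- xml2::xml_find_all(rx, ".//fbc:geneProductRef", ns)
    genes <- unname(gp_label[xml2::xml_attr(grefs, "geneProduct")])
    ecs <- note_field(rx, "EC")
    ecs <- if (is.na(ecs) || ecs == "") character()
           else strsplit(ecs, ";")[[1]]
    pen <- suppressWarnings(as.numeric(note_field(rx, "PENALTY")))
    prov <- note_field(rx, "PROVENANCE")
    model <- add_reaction(model, if (is.na(rname)) rid else rname,
                          st, lo, hi, genes = genes, ecs = ecs,
                          provenance = if (is.na(prov)) "user" else prov,
                          penalty = pen, name = rname)
  }
  fo <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  if (!inherits(fo, "xml_missing")) {
    obj_rid <- xml2::xml_attr(fo, "reaction")
    rx <- xml2::xml_find_first(
      doc, sprintf(".//s:reaction[@id='%s']", obj_rid), ns)
    obj_name <- xml2::xml_attr(rx, "name") %||% obj_rid
    model <- set_objective(model, if (is.na(obj_name)) obj_rid else obj_name)
  }
  model
}

#' Write a model in tabular (spreadsheet) form
#'
#' Emits three TSV sheets next to `path` (suffixes `_reactions.tsv`,
#' `_metabolites.tsv`, `_objective.tsv`): reactions with equation, bounds,
#' genes, EC links, provenance and gap-fill penalty; the metabolite list; and
#' the objective.
#'
#' @param model a `metabolic_model`.
#' @param path path prefix for the sheet files.
#' @return invisibly, the vector of files written.
#' @export
write_tabular <- function(model, path) {
  rxn <- do.call(rbind, lapply(model$reactions, function(r) data.frame(
    id = r$id,
    equation = format_equation(r$stoichiometry, r$lower < 0),
    lower = r$lower, upper = r$upper,
    genes = paste(r$genes, collapse = ";"),
    ecs = paste(r$ecs, collapse = ";"),
    provenance = r$provenance, penalty = r$penalty,
    stringsAsFactors = FALSE)))
  met <- data.frame(id = metabolites(model), compartment = "c",
                    stringsAsFactors = FALSE)
  obj <- data.frame(reaction_id = model$objective %||% NA_character_,
                    coefficient = 1, direction = "maximize",
                    stringsAsFactors = FALSE)
  files <- paste0(path, c("_reactions.tsv", "_metabolites.tsv",
                          "_objective.tsv"))
  utils::write.table(rxn, files[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(met, files[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(obj, files[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(files)
}
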