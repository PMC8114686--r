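## CellDesigner (extended SBML) import, read only.  The supported subset is
## what the conceptual model needs: compartments, species and included
## species (with CellDesigner species classes and modification states),
## complexes rebuilt from included species, reactions with reactants,
## products and modifiers, and external database annotations.  Layout, fonts
## and notes markup are discarded with a logged warning entry in the parse
## report.

CD_CLASS_TO_EPN <- c(
  "PROTEIN" = "macromolecule", "GENERIC" = "macromolecule",
  "RECEPTOR" = "macromolecule", "TRUNCATED" = "macromolecule",
  "SIMPLE_MOLECULE" = "simple-chemical", "ION" = "simple-chemical",
  "GENE" = "nucleic-acid-feature", "RNA" = "nucleic-acid-feature",
  "ANTISENSE_RNA" = "nucleic-acid-feature",
  "COMPLEX" = "complex",
  "UNKNOWN" = "unspecified",
  "DEGRADED" = "source-sink",
  "DRUG" = "perturbing-agent")

CD_STATE_TO_VALUE <- c(
  "phosphorylated" = "P", "acetylated" = "Ac", "ubiquitinated" = "Ub",
  "methylated" = "Me", "hydroxylated" = "OH", "glycosylated" = "G",
  "myristoylated" = "My", "palmytoylated" = "Pa", "prenylated" = "Pr",
  "protonated" = "H", "sulfated" = "S", "don't care" = "",
  "unknown" = "?")

CD_MOD_TO_CLASS <- c(
  "CATALYSIS" = "catalysis", "UNKNOWN_CATALYSIS" = "catalysis",
  "INHIBITION" = "inhibition", "UNKNOWN_INHIBITION" = "inhibition",
  "PHYSICAL_STIMULATION" = "stimulation",
  "TRIGGER" = "necessary-stimulation",
  "MODULATION" = "modulation")

CD_RXN_TO_CLASS <- c(
  "STATE_TRANSITION" = "generic", "KNOWN_TRANSITION_OMITTED" = "omitted",
  "UNKNOWN_TRANSITION" = "uncertain",
  "HETERODIMER_ASSOCIATION" = "association", "DISSOCIATION" = "dissociation",
  "TRANSPORT" = "generic", "TRANSLATION" = "generic",
  "TRANSCRIPTION" = "generic", "DEGRADATION" = "generic",
  "TRUNCATION" = "generic")

cd_annotations <- function(node) {
  res <- xml2::xml_find_all(node, ".//*[local-name()='li']")
  out <- list()
  for (li in res) {
    uri <- xml2::xml_attr(li, "resource")
    if (is.na(uri)) next
    if (grepl("^https?://identifiers\\.org/", uri)) {
      rest <- sub("^https?://identifiers\\.org/", "", uri)
      parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
      if (length(parts) >= 2)
        out[[length(out) + 1L]] <- c(parts[1], paste(parts[-1], collapse = "/"))
    } else if (grepl("^urn:miriam:", uri)) {
      parts <- strsplit(sub("^urn:miriam:", "", uri), ":", fixed = TRUE)[[1]]
      if (length(parts) >= 2)
        out[[length(out) + 1L]] <- c(parts[1], paste(parts[-1], collapse = ":"))
    }
  }
  out
}

#' Read a CellDesigner (extended SBML) map
#'
#' Species become entity pools (the CellDesigner species class mapped onto
#' the SBGN entity-pool classes, modification residues onto state variables),
#' complex species are reconstructed from their included species, reactions
#' become processes and reaction modifiers become modulation arcs.  External
#' database links (identifiers.org / MIRIAM URNs) are preserved as
#' (database, identifier) annotation pairs.
#'
#' @param path a CellDesigner SBML file.
#' @return a \code{pd_map}; the parse report (attribute
#'   \code{"parse_report"}) records species/reaction counts and any skipped
#'   or re-classed elements.
#' @export
read_celldesigner <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing"))
    stop("not an SBML file (no <model>): ", path)
  if (!length(xml2::xml_find_all(doc, "//*[local-name()='speciesIdentity']")))
    stop("unsupported dialect: no CellDesigner extension found in ", path)

  comp_nodes <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  comp_labels <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           xml2::xml_attr(comp_nodes, "id"),
           xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))

  # residue id -> site name, per protein id
  residue_site <- character()
  for (pr in xml2::xml_find_all(doc, "//*[local-name()='listOfProteins']/*[local-name()='protein']")) {
    for (r in xml2::xml_find_all(pr, ".//*[local-name()='modificationResidue']")) {
      rid <- xml2::xml_attr(r, "id")
      nm <- xml2::xml_attr(r, "name")
      residue_site[rid] <- if (is.na(nm)) "" else nm
    }
  }

  warn_notes <- character()
  parse_identity <- function(sp_node, label) {
    ident <- xml2::xml_find_first(sp_node, ".//*[local-name()='speciesIdentity']")
    cls_node <- xml2::xml_find_first(ident, ".//*[local-name()='class']")
    cd_class <- if (inherits(cls_node, "xml_missing")) "UNKNOWN"
                else xml2::xml_text(cls_node)
    epn <- CD_CLASS_TO_EPN[cd_class]
    if (is.na(epn)) {
      warning("unmapped CellDesigner species class ", cd_class,
              "; using class 'unspecified'")
      warn_notes <<- c(warn_notes, paste0("class:", cd_class))
      epn <- "unspecified"
    }
    svs <- list()
    counts <- new.env(parent = emptyenv())
    for (md in xml2::xml_find_all(ident, ".//*[local-name()='listOfModifications']/*[local-name()='modification']")) {
      st <- xml2::xml_attr(md, "state")
      value <- if (!is.na(st) && st %in% names(CD_STATE_TO_VALUE))
        CD_STATE_TO_VALUE[[st]] else if (is.na(st)) "" else st
      rid <- xml2::xml_attr(md, "residue")
      site <- if (!is.na(rid) && !is.na(residue_site[rid]))
        unname(residue_site[rid]) else ""
      if (!nzchar(value) && !nzchar(site)) next
      ck <- paste(value, site, sep = "@")
      ord <- if (is.null(counts[[ck]])) 1L else counts[[ck]] + 1L
      counts[[ck]] <- ord
      svs[[length(svs) + 1L]] <- state_variable(value, site, ord)
    }
    list(epn = unname(epn), svs = svs)
  }

  # included species, grouped by owning complex species id
  included <- list()
  for (isp in xml2::xml_find_all(doc, "//*[local-name()='listOfIncludedSpecies']/*[local-name()='species']")) {
    owner <- xml2::xml_attr(isp, "complexSpecies")
    if (is.na(owner)) {
      cs <- xml2::xml_find_first(isp, ".//*[local-name()='complexSpecies']")
      if (!inherits(cs, "xml_missing")) owner <- xml2::xml_text(cs)
    }
    if (is.na(owner)) next
    nm <- xml2::xml_attr(isp, "name")
    pid <- parse_identity(isp, nm)
    ent <- entity_pool(pid$epn, if (is.na(nm)) "" else nm,
                       state_variables = pid$svs)
    included[[owner]] <- c(included[[owner]], list(ent))
  }

  map <- pd_map(unname(comp_labels))
  species_entity <- list()
  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  n_species <- length(sp_nodes)
  for (sp in sp_nodes) {
    sid <- xml2::xml_attr(sp, "id")
    nm <- xml2::xml_attr(sp, "name")
    comp <- xml2::xml_attr(sp, "compartment")
    comp_lab <- if (!is.na(comp) && !is.na(comp_labels[comp]))
      unname(comp_labels[comp]) else NULL
    pid <- parse_identity(sp, nm)
    subs <- if (pid$epn == "complex" && !is.null(included[[sid]]))
      lapply(included[[sid]], function(su) { su$compartment <- comp_lab; su })
    else list()
    ent <- entity_pool(pid$epn, if (is.na(nm)) sid else nm, comp_lab,
                       state_variables = pid$svs, subunits = subs)
    species_entity[[sid]] <- ent
    if (ent$epn_class != "source-sink") {
      map <- add_entity(map, ent)
      for (ann in cd_annotations(sp))
        map <- add_annotation(map, ent, ann[1], ann[2])
    }
  }

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  n_assoc <- 0L
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    rt_node <- xml2::xml_find_first(rx, ".//*[local-name()='reactionType']")
    rt <- if (inherits(rt_node, "xml_missing")) "STATE_TRANSITION"
          else xml2::xml_text(rt_node)
    pcls <- CD_RXN_TO_CLASS[rt]
    if (is.na(pcls)) {
      warning("unmapped CellDesigner reaction type ", rt,
              "; using class 'generic'")
      warn_notes <- c(warn_notes, paste0("reaction:", rt))
      pcls <- "generic"
    }
    if (pcls == "association") n_assoc <- n_assoc + 1L
    getsp <- function(xp) {
      refs <- xml2::xml_attr(xml2::xml_find_all(rx, xp), "species")
      ents <- lapply(refs, function(s) species_entity[[s]])
      Filter(function(e) !is.null(e) && e$epn_class != "source-sink", ents)
    }
    map <- add_process(map, process_node(
      rid, reactants = getsp("./listOfReactants/speciesReference"),
      products = getsp("./listOfProducts/speciesReference"),
      process_class = unname(pcls)))
    mods <- xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference")
    cd_mods <- xml2::xml_find_all(rx, ".//*[local-name()='listOfModification']/*[local-name()='modification']")
    cd_type <- stats::setNames(xml2::xml_attr(cd_mods, "type"),
                               xml2::xml_attr(cd_mods, "modifiers"))
    for (mo in mods) {
      sid <- xml2::xml_attr(mo, "species")
      ent <- species_entity[[sid]]
      if (is.null(ent) || ent$epn_class == "source-sink") next
      ty <- cd_type[sid]
      mcls <- if (!is.na(ty) && ty %in% names(CD_MOD_TO_CLASS))
        CD_MOD_TO_CLASS[[ty]] else "modulation"
      map <- add_modulation(map, modulation(mcls, ent, rid))
    }
    for (ann in cd_annotations(rx))
      map <- add_annotation(map, rid, ann[1], ann[2])
  }
  n_links <- sum(lengths(map$annotations))
  attr(map, "parse_report") <- list(
    n_species = n_species, n_reactions = length(rx_nodes),
    n_associations = n_assoc, n_external_links = n_links,
    notes = warn_notes)
  validate_pd_map(map)
  map
}
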