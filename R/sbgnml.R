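## SBGN-ML (0.2/0.3) reading and writing of the conceptual map content.
## Layout is discarded on read and auto-generated as placeholder coordinates
## on write; glyphs that are structurally equal collapse to a single entity
## pool.  Empty reactant/product sets are represented in the file by explicit
## "source and sink" glyphs.

SBGNML_NS <- c("0.2" = "http://sbgn.org/libsbgn/0.2",
               "0.3" = "http://sbgn.org/libsbgn/0.3")

EPN_TO_GLYPH <- c("macromolecule" = "macromolecule",
                  "simple-chemical" = "simple chemical",
                  "nucleic-acid-feature" = "nucleic acid feature",
                  "complex" = "complex",
                  "unspecified" = "unspecified entity",
                  "source-sink" = "source and sink",
                  "perturbing-agent" = "perturbing agent")
GLYPH_TO_EPN <- stats::setNames(names(EPN_TO_GLYPH), EPN_TO_GLYPH)

PROC_TO_GLYPH <- c("generic" = "process", "association" = "association",
                   "dissociation" = "dissociation", "phenotype" = "phenotype",
                   "omitted" = "omitted process",
                   "uncertain" = "uncertain process")
GLYPH_TO_PROC <- stats::setNames(names(PROC_TO_GLYPH), PROC_TO_GLYPH)

MOD_TO_ARC <- c("modulation" = "modulation", "stimulation" = "stimulation",
                "inhibition" = "inhibition",
                "necessary-stimulation" = "necessary stimulation",
                "catalysis" = "catalysis")
ARC_TO_MOD <- stats::setNames(names(MOD_TO_ARC), MOD_TO_ARC)

LOGIC_TO_GLYPH <- c(AND = "and", OR = "or", NOT = "not")
GLYPH_TO_LOGIC <- stats::setNames(names(LOGIC_TO_GLYPH), LOGIC_TO_GLYPH)

#' Write a PD map to SBGN-ML
#'
#' Emits SBGN-ML with placeholder layout coordinates.  The output
#' round-trips: \code{read_sbgnml(write_sbgnml(m))} is structurally equal to
#' \code{m}.  Absolute-inhibition arcs have no SBGN-ML encoding and are
#' written as plain inhibitions with a warning.
#'
#' @param map a \code{pd_map}.
#' @param path output file path.
#' @param version SBGN-ML dialect, \code{"0.2"} (default) or \code{"0.3"}.
#' @return invisibly \code{path}.
#' @export
write_sbgnml <- function(map, path, version = "0.2") {
  stopifnot(inherits(map, "pd_map"))
  ns <- SBGNML_NS[[match.arg(version, names(SBGNML_NS))]]
  doc <- xml2::xml_new_root("sbgn", xmlns = ns)
  mp <- xml2::xml_add_child(doc, "map", language = "process description")
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  next_id <- function(prefix) {
    counter$n <- counter$n + 1L
    paste0(prefix, counter$n)
  }
  bbox <- function(node) {
    counter$n <- counter$n + 1L
    xml2::xml_add_child(node, "bbox", x = as.character(20 * counter$n),
                        y = "0", w = "40", h = "20")
  }
  comp_ids <- character()
  for (cm in sort(map$compartments)) {
    id <- next_id("comp")
    g <- xml2::xml_add_child(mp, "glyph", class = "compartment", id = id)
    lb <- xml2::xml_add_child(g, "label", text = cm)
    bbox(g)
    comp_ids[cm] <- id
  }
  add_entity_glyph <- function(parent, e, id) {
    args <- list(parent, "glyph", class = EPN_TO_GLYPH[[e$epn_class]], id = id)
    if (!is.null(e$compartment) && !is.na(comp_ids[e$compartment]))
      args$compartmentRef <- comp_ids[[e$compartment]]
    g <- do.call(xml2::xml_add_child, args)
    xml2::xml_add_child(g, "label", text = e$label)
    bbox(g)
    for (sv in e$state_variables) {
      sg <- xml2::xml_add_child(g, "glyph", class = "state variable",
                                id = next_id("sv"))
      xml2::xml_add_child(sg, "state", value = sv$value, variable = sv$site)
      bbox(sg)
    }
    for (su in e$subunits)
      add_entity_glyph(g, su, next_id("sub"))
    g
  }
  ent_glyph <- character()
  for (k in sort(as.character(names(map$entities)), method = "radix")) {
    id <- next_id("epn")
    add_entity_glyph(mp, map$entities[[k]], id)
    ent_glyph[k] <- id
  }
  arcs <- list()
  add_arc <- function(class, source, target)
    arcs[[length(arcs) + 1L]] <<- c(class = class, source = source,
                                    target = target)
  proc_glyph <- character()
  for (pid in sort(as.character(names(map$processes)), method = "radix")) {
    p <- map$processes[[pid]]
    g <- xml2::xml_add_child(mp, "glyph", class = PROC_TO_GLYPH[[p$process_class]],
                             id = pid)
    bbox(g)
    proc_glyph[pid] <- pid
    if (!length(p$reactants)) {
      ss <- next_id("ss")
      sg <- xml2::xml_add_child(mp, "glyph", class = "source and sink", id = ss)
      bbox(sg)
      add_arc("consumption", ss, pid)
    } else for (r in p$reactants)
      add_arc("consumption", ent_glyph[[entity_key(r)]], pid)
    if (!length(p$products)) {
      ss <- next_id("ss")
      sg <- xml2::xml_add_child(mp, "glyph", class = "source and sink", id = ss)
      bbox(sg)
      add_arc("production", pid, ss)
    } else for (pr in p$products)
      add_arc("production", pid, ent_glyph[[entity_key(pr)]])
  }
  emit_source <- function(s) {
    if (inherits(s, "sbgn_logic")) {
      id <- next_id("op")
      g <- xml2::xml_add_child(mp, "glyph",
                               class = LOGIC_TO_GLYPH[[s$operator]], id = id)
      bbox(g)
      for (ch in s$children)
        add_arc("logic arc", emit_source(ch), id)
      id
    } else ent_glyph[[entity_key(s)]]
  }
  for (m in map$modulations) {
    cls <- m$mod_class
    if (cls == "absolute-inhibition") {
      warning("absolute inhibition has no SBGN-ML arc class; written as ",
              "inhibition")
      cls <- "inhibition"
    }
    add_arc(MOD_TO_ARC[[cls]], emit_source(m$source), m$target)
  }
  for (a in arcs) {
    an <- xml2::xml_add_child(mp, "arc", class = a[["class"]],
                              source = a[["source"]], target = a[["target"]],
                              id = next_id("arc"))
    xml2::xml_add_child(an, "start", x = "0", y = "0")
    xml2::xml_add_child(an, "end", x = "0", y = "0")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_entity_glyph <- function(g, comp_labels) {
  cls <- GLYPH_TO_EPN[[xml2::xml_attr(g, "class")]]
  lab <- xml2::xml_attr(xml2::xml_find_first(g, "./label"), "text")
  if (is.na(lab)) lab <- ""
  compref <- xml2::xml_attr(g, "compartmentRef")
  comp <- if (!is.na(compref) && !is.na(comp_labels[compref]))
    unname(comp_labels[compref]) else NULL
  svs <- list()
  counts <- new.env(parent = emptyenv())
  for (sg in xml2::xml_find_all(g, "./glyph[@class='state variable']")) {
    st <- xml2::xml_find_first(sg, "./state")
    value <- xml2::xml_attr(st, "value"); site <- xml2::xml_attr(st, "variable")
    if (is.na(value)) value <- ""
    if (is.na(site)) site <- ""
    if (!nzchar(value) && !nzchar(site)) next
    ck <- paste(value, site, sep = "@")
    ord <- if (is.null(counts[[ck]])) 1L else counts[[ck]] + 1L
    counts[[ck]] <- ord
    svs[[length(svs) + 1L]] <- state_variable(value, site, ord)
  }
  sub_nodes <- xml2::xml_find_all(
    g, "./glyph[@class!='state variable' and @class!='unit of information']")
  subs <- lapply(sub_nodes, parse_entity_glyph, comp_labels = comp_labels)
  entity_pool(cls, lab, comp, state_variables = svs, subunits = subs)
}

#' Read a PD map from SBGN-ML
#'
#' Parses the conceptual content of an SBGN-ML 0.2/0.3 Process Description
#' file: layout is discarded and structurally equal glyphs collapse to one
#' entity pool.  Unknown glyph/arc classes are skipped with a warning and
#' recorded in the parse report (attribute \code{"parse_report"}), which also
#' carries the element counts of all supported classes so that silent drops
#' are detectable.
#'
#' @param path an SBGN-ML file.
#' @return a \code{pd_map}.
#' @export
read_sbgnml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mp <- xml2::xml_find_first(doc, "./map")
  if (inherits(mp, "xml_missing")) stop("no <map> element in ", path)
  lang <- xml2::xml_attr(mp, "language")
  if (!is.na(lang) && lang != "process description")
    stop("unsupported SBGN language: ", lang,
         " (only process description is supported)")
  glyphs <- xml2::xml_find_all(mp, "./glyph")
  classes <- xml2::xml_attr(glyphs, "class")
  gids <- xml2::xml_attr(glyphs, "id")

  comp_labels <- character()
  for (i in which(classes == "compartment")) {
    lab <- xml2::xml_attr(xml2::xml_find_first(glyphs[[i]], "./label"), "text")
    comp_labels[gids[i]] <- if (is.na(lab)) gids[i] else lab
  }
  map <- pd_map(unname(comp_labels))

  skipped <- character()
  glyph_entity <- list()   # glyph id -> entity (or "source-sink" marker)
  logic_nodes <- list()    # glyph id -> operator
  proc_ids <- character()  # glyph id -> process class
  port_owner <- character()
  for (i in seq_along(glyphs)) {
    g <- glyphs[[i]]; cls <- classes[i]; id <- gids[i]
    for (pt in xml2::xml_find_all(g, ".//port"))
      port_owner[xml2::xml_attr(pt, "id")] <- id
    if (cls == "compartment") next
    if (cls %in% names(GLYPH_TO_EPN)) {
      glyph_entity[[id]] <- parse_entity_glyph(g, comp_labels)
    } else if (cls %in% names(GLYPH_TO_PROC)) {
      proc_ids[id] <- GLYPH_TO_PROC[[cls]]
    } else if (cls %in% names(GLYPH_TO_LOGIC)) {
      logic_nodes[[id]] <- GLYPH_TO_LOGIC[[cls]]
    } else {
      warning("skipping glyph of unknown class: ", cls)
      skipped <- c(skipped, paste0("glyph:", cls))
    }
  }
  arcs <- xml2::xml_find_all(mp, "./arc")
  a_cls <- xml2::xml_attr(arcs, "class")
  deref <- function(x) if (!is.na(port_owner[x])) unname(port_owner[x]) else x
  a_src <- vapply(xml2::xml_attr(arcs, "source"), deref, "")
  a_tgt <- vapply(xml2::xml_attr(arcs, "target"), deref, "")

  is_ss <- function(gid) !is.null(glyph_entity[[gid]]) &&
    glyph_entity[[gid]]$epn_class == "source-sink"

  reactants <- stats::setNames(vector("list", length(proc_ids)), names(proc_ids))
  products <- stats::setNames(vector("list", length(proc_ids)), names(proc_ids))
  logic_children <- list()
  mod_arcs <- list()
  n_supported_arcs <- 0L
  for (i in seq_along(arcs)) {
    cls <- a_cls[i]; src <- a_src[i]; tgt <- a_tgt[i]
    if (cls == "consumption") {
      if (!is.null(reactants[[tgt]]) || tgt %in% names(proc_ids)) {
        if (!is_ss(src))
          reactants[[tgt]] <- c(reactants[[tgt]], list(glyph_entity[[src]]))
        n_supported_arcs <- n_supported_arcs + 1L
      }
    } else if (cls == "production") {
      if (src %in% names(proc_ids)) {
        if (!is_ss(tgt))
          products[[src]] <- c(products[[src]], list(glyph_entity[[tgt]]))
        n_supported_arcs <- n_supported_arcs + 1L
      }
    } else if (cls == "logic arc") {
      logic_children[[tgt]] <- c(logic_children[[tgt]], src)
      n_supported_arcs <- n_supported_arcs + 1L
    } else if (cls %in% names(ARC_TO_MOD)) {
      mod_arcs[[length(mod_arcs) + 1L]] <-
        list(cls = ARC_TO_MOD[[cls]], src = src, tgt = tgt)
      n_supported_arcs <- n_supported_arcs + 1L
    } else {
      warning("skipping arc of unknown class: ", cls)
      skipped <- c(skipped, paste0("arc:", cls))
    }
  }
  for (id in names(glyph_entity))
    if (!is_ss(id)) map <- add_entity(map, glyph_entity[[id]])
  for (pid in names(proc_ids))
    map <- add_process(map, process_node(pid, reactants = reactants[[pid]],
                                         products = products[[pid]],
                                         process_class = proc_ids[[pid]]))
  resolve_source <- function(gid) {
    if (!is.null(logic_nodes[[gid]]))
      logical_function(logic_nodes[[gid]],
                       lapply(logic_children[[gid]], resolve_source))
    else glyph_entity[[gid]]
  }
  for (ma in mod_arcs)
    map <- add_modulation(map, modulation(ma$cls, resolve_source(ma$src),
                                          ma$tgt))
  attr(map, "parse_report") <- list(
    n_glyphs = length(glyphs), n_arcs = length(arcs),
    n_supported_arcs = n_supported_arcs,
    n_processes = length(proc_ids),
    n_modulations = length(mod_arcs),
    skipped = skipped)
  validate_pd_map(map)
  map
}
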