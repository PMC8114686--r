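#' @keywords internal
"_PACKAGE"

EPN_CLASSES <- c("macromolecule", "simple-chemical", "nucleic-acid-feature",
                 "complex", "unspecified", "source-sink", "perturbing-agent")
PROCESS_CLASSES <- c("generic", "association", "dissociation", "phenotype",
                     "omitted", "uncertain")
MODULATION_CLASSES <- c("modulation", "stimulation", "inhibition",
                        "necessary-stimulation", "catalysis",
                        "absolute-inhibition")
LOGIC_OPS <- c("AND", "OR", "NOT")

#' State variable of an entity pool
#'
#' A state variable records a (usually post-translational) decoration on an
#' entity pool, e.g. a phosphorylation at a given residue.  Either the value
#' (e.g. \code{"P"}, \code{"Ac"}, \code{"ADPr"}) or the site (e.g.
#' \code{"Thr172"}) may be empty, but not both.  Two variables with the same
#' value and no site on one entity are told apart by their ordinal.
#'
#' @param value modification value, e.g. \code{"P"}; may be \code{""}.
#' @param site residue/site, e.g. \code{"Thr172"}; may be \code{""}.
#' @param ordinal integer used to distinguish repeated identical decorations.
#' @return an object of class \code{sbgn_state_variable}.
#' @export
state_variable <- function(value = "", site = "", ordinal = 1L) {
  value <- as.character(value); site <- as.character(site)
  if (!nzchar(value) && !nzchar(site))
    stop("state variable needs a non-empty value or site")
  structure(list(value = value, site = site, ordinal = as.integer(ordinal)),
            class = "sbgn_state_variable")
}

#' Entity pool node
#'
#' An entity pool is a set of identical molecules in a compartment, possibly
#' decorated with state variables; complexes carry an ordered list of subunit
#' entity pools.
#'
#' @param epn_class one of \code{"macromolecule"}, \code{"simple-chemical"},
#'   \code{"nucleic-acid-feature"}, \code{"complex"}, \code{"unspecified"},
#'   \code{"source-sink"}, \code{"perturbing-agent"}.
#' @param label entity label; may be \code{""} for anonymous complexes.
#' @param compartment compartment label or \code{NULL}.
#' @param state_variables list of [state_variable()] objects.
#' @param subunits list of entity pools; only allowed for complexes.
#' @return an object of class \code{sbgn_entity}.
#' @export
entity_pool <- function(epn_class, label = "", compartment = NULL,
                        state_variables = list(), subunits = list()) {
  epn_class <- match.arg(epn_class, EPN_CLASSES)
  if (length(subunits) && epn_class != "complex")
    stop("subunits are only allowed on complexes")
  structure(list(epn_class = epn_class, label = as.character(label),
                 compartment = if (is.null(compartment)) NULL else as.character(compartment),
                 state_variables = state_variables, subunits = subunits),
            class = "sbgn_entity")
}

#' Logical function over entity pools
#'
#' @param operator \code{"AND"}, \code{"OR"} or \code{"NOT"}.
#' @param children list of entity pools and/or nested logical functions;
#'   \code{NOT} takes exactly one child, \code{AND}/\code{OR} at least two.
#' @return an object of class \code{sbgn_logic}.
#' @export
logical_function <- function(operator, children) {
  operator <- match.arg(operator, LOGIC_OPS)
  if (operator == "NOT" && length(children) != 1L)
    stop("NOT takes exactly one child")
  if (operator != "NOT" && length(children) < 2L)
    stop(operator, " takes at least two children")
  structure(list(operator = operator, children = children), class = "sbgn_logic")
}

#' Process node
#'
#' @param id identifier, unique within a map.
#' @param reactants,products lists of entity pools; a source process has no
#'   reactants, a sink process no products.
#' @param process_class one of \code{"generic"}, \code{"association"},
#'   \code{"dissociation"}, \code{"phenotype"}, \code{"omitted"},
#'   \code{"uncertain"}.
#' @return an object of class \code{sbgn_process}.
#' @export
process_node <- function(id, reactants = list(), products = list(),
                         process_class = "generic") {
  process_class <- match.arg(process_class, PROCESS_CLASSES)
  structure(list(process_class = process_class, reactants = reactants,
                 products = products, id = as.character(id)),
            class = "sbgn_process")
}

#' Modulation arc
#'
#' @param mod_class one of \code{"modulation"}, \code{"stimulation"},
#'   \code{"inhibition"}, \code{"necessary-stimulation"}, \code{"catalysis"},
#'   \code{"absolute-inhibition"}.  Absolute inhibition is never produced by
#'   parsing; it can only be set explicitly.
#' @param source an entity pool or a [logical_function()].
#' @param target id of the modulated process.
#' @return an object of class \code{sbgn_modulation}.
#' @export
modulation <- function(mod_class, source, target) {
  mod_class <- match.arg(mod_class, MODULATION_CLASSES)
  structure(list(mod_class = mod_class, source = source,
                 target = as.character(target)),
            class = "sbgn_modulation")
}

## ---- canonicalization and structural equality -------------------------------

sv_key <- function(sv) paste(sv$value, sv$site, sv$ordinal, sep = "\x01")

canonical_entity <- function(e) {
  if (length(e$state_variables)) {
    keys <- vapply(e$state_variables, sv_key, "")
    e$state_variables <- e$state_variables[order(keys, method = "radix")]
  }
  if (length(e$subunits)) {
    e$subunits <- lapply(e$subunits, canonical_entity)
    e$subunits <- e$subunits[order(vapply(e$subunits, entity_key, ""),
                                   method = "radix")]
  }
  e
}

#' Structural identity key of an entity pool
#'
#' Two entity pools are structurally equal iff they have the same class,
#' label, compartment, multiset of state variables and (recursively) the same
#' set of subunits.  The key is a canonical string encoding that identity;
#' it is what the package uses to deduplicate pools and to match concepts
#' across maps.
#'
#' @param e an entity pool.
#' @return a character scalar.
#' @export
entity_key <- function(e) {
  e <- canonical_entity(e)
  svs <- if (length(e$state_variables))
    paste(vapply(e$state_variables, sv_key, ""), collapse = "\x02") else ""
  subs <- if (length(e$subunits))
    paste(vapply(e$subunits, entity_key, ""), collapse = "\x03") else ""
  paste(e$epn_class, if (is.null(e$compartment)) "" else e$compartment,
        e$label, svs, subs, sep = "\x04")
}

#' Test structural equality of two entity pools
#' @param a,b entity pools.
#' @return logical scalar.
#' @export
entity_equal <- function(a, b) identical(entity_key(a), entity_key(b))

process_key <- function(p) {
  paste(p$process_class,
        paste(sort(vapply(p$reactants, entity_key, "")), collapse = "\x02"),
        paste(sort(vapply(p$products, entity_key, "")), collapse = "\x02"),
        sep = "\x05")
}

source_key <- function(s) {
  if (inherits(s, "sbgn_logic"))
    paste0("L", s$operator, "(",
           paste(sort(vapply(s$children, source_key, "")), collapse = "\x02"), ")")
  else paste0("E", entity_key(s))
}

modulation_key <- function(m, process_keys) {
  tk <- if (!is.null(process_keys[[m$target]])) process_keys[[m$target]] else m$target
  paste(m$mod_class, source_key(m$source), tk, sep = "\x06")
}

## ---- PD map container -------------------------------------------------------

#' Create an empty PD map
#'
#' A \code{pd_map} holds the conceptual content of an SBGN Process Description
#' map: compartments, entity pools, processes, modulation arcs and external
#' annotations.  Layout is never represented.  Entity pools are stored
#' deduplicated under their structural key; processes under their identifier.
#'
#' @param compartments character vector of compartment labels.
#' @return an object of class \code{pd_map}.
#' @export
pd_map <- function(compartments = character()) {
  structure(list(compartments = unique(as.character(compartments)),
                 entities = list(), processes = list(),
                 modulations = list(), annotations = list()),
            class = "pd_map")
}

#' Add an entity pool to a map
#'
#' Structurally equal pools collapse to one; the compartment is registered.
#'
#' @param map a \code{pd_map}.
#' @param e an entity pool.
#' @return the updated map (maps are immutable values; reassign the result).
#' @export
add_entity <- function(map, e) {
  stopifnot(inherits(map, "pd_map"), inherits(e, "sbgn_entity"))
  e <- canonical_entity(e)
  k <- entity_key(e)
  if (is.null(map$entities[[k]])) map$entities[[k]] <- e
  if (!is.null(e$compartment) && !(e$compartment %in% map$compartments))
    map$compartments <- c(map$compartments, e$compartment)
  map
}

#' Add a process to a map
#'
#' Participants are added to the entity inventory as a side effect.
#'
#' @param map a \code{pd_map}.
#' @param p a process.
#' @return the updated map.
#' @export
add_process <- function(map, p) {
  stopifnot(inherits(map, "pd_map"), inherits(p, "sbgn_process"))
  if (!is.null(map$processes[[p$id]]))
    stop("duplicate process identifier: ", p$id)
  p$reactants <- lapply(p$reactants, canonical_entity)
  p$products <- lapply(p$products, canonical_entity)
  for (e in c(p$reactants, p$products)) map <- add_entity(map, e)
  map$processes[[p$id]] <- p
  map
}

logic_entities <- function(s) {
  if (inherits(s, "sbgn_logic")) unlist(lapply(s$children, logic_entities),
                                        recursive = FALSE)
  else list(s)
}

#' Add a modulation arc to a map
#'
#' @param map a \code{pd_map}.
#' @param m a modulation; its target process must already be in the map.
#' @return the updated map.
#' @export
add_modulation <- function(map, m) {
  stopifnot(inherits(map, "pd_map"), inherits(m, "sbgn_modulation"))
  if (is.null(map$processes[[m$target]]))
    stop("modulation targets unknown process: ", m$target)
  for (e in logic_entities(m$source)) map <- add_entity(map, e)
  map$modulations <- c(map$modulations, list(m))
  map
}

#' Attach an external annotation to a map concept
#'
#' @param map a \code{pd_map}.
#' @param concept an entity pool (matched structurally) or a process id.
#' @param database,identifier the external reference, e.g.
#'   \code{"uniprot"}, \code{"P12345"}.
#' @return the updated map.
#' @export
add_annotation <- function(map, concept, database, identifier) {
  key <- if (inherits(concept, "sbgn_entity")) entity_key(concept)
         else as.character(concept)
  map$annotations[[key]] <- unique(c(map$annotations[[key]],
                                     paste(database, identifier, sep = "|")))
  map
}

#' Check internal consistency of a PD map
#'
#' Verifies that all process participants and modulation sources/targets are
#' members of the map and that no two structurally equal pools coexist.
#'
#' @param map a \code{pd_map}.
#' @return invisibly \code{TRUE}; stops with a message on violation.
#' @export
validate_pd_map <- function(map) {
  stopifnot(inherits(map, "pd_map"))
  ks <- names(map$entities)
  if (anyDuplicated(ks)) stop("duplicate structural entity keys")
  for (k in ks) if (!identical(entity_key(map$entities[[k]]), k))
    stop("entity stored under wrong structural key")
  for (p in map$processes)
    for (e in c(p$reactants, p$products))
      if (is.null(map$entities[[entity_key(e)]]))
        stop("process ", p$id, " references an entity missing from the map")
  for (m in map$modulations) {
    if (is.null(map$processes[[m$target]]))
      stop("modulation targets missing process ", m$target)
    for (e in logic_entities(m$source))
      if (is.null(map$entities[[entity_key(e)]]))
        stop("modulation source entity missing from the map")
  }
  invisible(TRUE)
}

#' @export
print.pd_map <- function(x, ...) {
  cat("SBGN PD map:", length(x$entities), "entity pools,",
      length(x$processes), "processes,",
      length(x$modulations), "modulations,",
      length(x$compartments), "compartments\n")
  invisible(x)
}

## ---- marker grammar ---------------------------------------------------------

grammar_error <- function(msg, offset) {
  stop(structure(class = c("sbgndyn_grammar_error", "error", "condition"),
                 list(message = sprintf("%s (at offset %d)", msg, offset),
                      call = NULL, offset = offset)))
}

#' Parse the textual entity grammar used by marker tables
#'
#' The grammar renders entity pools compactly: subunits of a complex are
#' joined with \code{":"}, state variables follow the label in parentheses
#' separated by \code{"|"}, and a variable is written \code{value@site} (the
#' site may be omitted).  Examples: \code{"WEE1(P@Ser53)"},
#' \code{"CCND1:CDK6(P@Thr):CDKN1B"}, \code{"pRB(P|P)"}.
#'
#' Every \code{":"} is treated as a subunit separator; names such as
#' \code{"SWI:SNF"} therefore parse as two subunits and are reconciled against
#' a concrete map by [find_entity()]'s label-sequence fallback.  Parsing is
#' case-sensitive; grammar errors report 0-based character offsets.
#'
#' @param text entity text.
#' @param compartment compartment label attached to the result, or \code{NULL}.
#' @param epn_class class given to non-complex entities
#'   (default \code{"macromolecule"}).
#' @return an entity pool.
#' @export
parse_entity_text <- function(text, compartment = NULL,
                              epn_class = "macromolecule") {
  raw <- as.character(text)
  n <- nchar(raw)
  chars <- if (n) strsplit(raw, "", fixed = TRUE)[[1]] else character()
  # split into subunit chunks at depth-0 ":"
  depth <- 0L
  chunk_start <- 1L
  chunks <- list()  # list of (text, offset0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) grammar_error("unbalanced ')'", i - 1L)
    } else if (ch == ":" && depth == 0L) {
      chunks[[length(chunks) + 1L]] <-
        list(text = substr(raw, chunk_start, i - 1L), offset = chunk_start - 1L)
      chunk_start <- i + 1L
    }
    i <- i + 1L
  }
  if (depth > 0L) grammar_error("unbalanced '('", n - 1L)
  chunks[[length(chunks) + 1L]] <-
    list(text = substr(raw, chunk_start, n), offset = chunk_start - 1L)

  parse_one <- function(txt, off) {
    txt2 <- trimws(txt)
    off <- off + (nchar(txt) - nchar(sub("^\\s+", "", txt)))
    m <- regexpr("(", txt2, fixed = TRUE)
    if (m == -1L) {
      label <- txt2; svtxt <- NULL
    } else {
      if (substr(txt2, nchar(txt2), nchar(txt2)) != ")")
        grammar_error("expected ')' to close state-variable list",
                      off + nchar(txt2) - 1L)
      label <- substr(txt2, 1L, m - 1L)
      svtxt <- substr(txt2, m + 1L, nchar(txt2) - 1L)
    }
    if (!nzchar(trimws(label))) grammar_error("empty entity label", off)
    svs <- list()
    if (!is.null(svtxt)) {
      parts <- strsplit(svtxt, "|", fixed = TRUE)[[1]]
      if (!length(parts) || any(!nzchar(trimws(parts))))
        grammar_error("empty state variable", off + m)
      counts <- new.env(parent = emptyenv())
      for (p in parts) {
        p <- trimws(p)
        at <- regexpr("@", p, fixed = TRUE)
        if (at == -1L) { value <- p; site <- "" }
        else { value <- substr(p, 1L, at - 1L); site <- substr(p, at + 1L, nchar(p)) }
        ck <- paste(value, site, sep = "@")
        ord <- if (is.null(counts[[ck]])) 1L else counts[[ck]] + 1L
        counts[[ck]] <- ord
        svs[[length(svs) + 1L]] <- state_variable(value, site, ord)
      }
    }
    entity_pool(epn_class, label = trimws(label), compartment = compartment,
                state_variables = svs)
  }

  units <- lapply(chunks, function(cc) parse_one(cc$text, cc$offset))
  if (length(units) == 1L) units[[1L]]
  else entity_pool("complex", label = "", compartment = compartment,
                   subunits = units)
}

#' Render an entity pool in the marker grammar
#'
#' Inverse of [parse_entity_text()] up to canonical state-variable order.
#'
#' @param e an entity pool.
#' @return a character scalar.
#' @export
render_entity_text <- function(e) {
  one <- function(u) {
    sv <- ""
    if (length(u$state_variables)) {
      parts <- vapply(u$state_variables, function(s)
        if (nzchar(s$site)) paste0(s$value, "@", s$site) else s$value, "")
      sv <- paste0("(", paste(parts, collapse = "|"), ")")
    }
    paste0(u$label, sv)
  }
  if (e$epn_class == "complex" && length(e$subunits))
    paste(vapply(e$subunits, render_entity_text, ""), collapse = ":")
  else one(e)
}

# depth-0 ":" tokenization of a rendered entity text
split_top_colons <- function(txt) {
  n <- nchar(txt)
  if (!n) return(character())
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L; start <- 1L; out <- character()
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == ":" && depth == 0L) {
      out <- c(out, substr(txt, start, i - 1L)); start <- i + 1L
    }
  }
  c(out, substr(txt, start, n))
}

entity_token_signature <- function(e)
  paste(sort(split_top_colons(render_entity_text(e)), method = "radix"),
        collapse = ":")

#' Find an entity pool in a map
#'
#' Looks up the structurally equal pool; character queries are parsed with
#' [parse_entity_text()] first.  When exact structural lookup of a complex
#' fails (the marker grammar cannot tell a \code{":"} inside a subunit name,
#' e.g. \code{"SWI:SNF"}, from a subunit separator), the query falls back to
#' matching the rendered subunit-label sequence against the map's complex
#' inventory.
#'
#' @param map a \code{pd_map}.
#' @param query an entity pool or a marker string.
#' @param compartment compartment attached to a string query.
#' @param fuzzy if \code{TRUE}, an ambiguous fallback match raises an error
#'   listing the candidates instead of returning the first.
#' @return the matching entity pool, or \code{NULL}.
#' @export
find_entity <- function(map, query, compartment = NULL, fuzzy = FALSE) {
  stopifnot(inherits(map, "pd_map"))
  e <- if (is.character(query)) parse_entity_text(query, compartment) else query
  hit <- map$entities[[entity_key(e)]]
  if (!is.null(hit)) return(hit)
  # fallback: compare sorted depth-0 token multisets of the rendered text, so
  # the match is insensitive to subunit grouping ("SWI:SNF" as one label or
  # two subunits) and subunit order
  want <- entity_token_signature(e)
  wantc <- e$compartment
  cand <- Filter(function(u) {
    identical(entity_token_signature(u), want) &&
      (is.null(wantc) || identical(u$compartment, wantc))
  }, map$entities)
  if (!length(cand)) return(NULL)
  if (length(cand) > 1L && fuzzy)
    stop("ambiguous entity query '", want, "': ",
         paste(vapply(cand, render_entity_text, ""), collapse = "; "))
  cand[[1L]]
}
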