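## Programmatic harmonization and merging of PD maps.  Harmonization applies
## an explicit, serializable, replayable edit script; merging takes the union
## of two maps under structural equality of concepts, so shared concepts
## appear once.  Both are pure transformations: input maps are never touched.

#' Edit-script steps
#'
#' Constructors for the edit operations understood by [harmonize()]:
#' \itemize{
#'   \item \code{edit_rename_label(old, new)} — relabel every entity (also as
#'     a complex subunit) whose label is \code{old};
#'   \item \code{edit_set_compartment(query, compartment)} — move top-level
#'     pools matching the marker-grammar \code{query} to a compartment;
#'   \item \code{edit_add_state_variable(query, value, site)} — decorate every
#'     matching entity unit, including subunits inside complexes;
#'   \item \code{edit_delete_entity(query)} — remove matching top-level pools
#'     (an edit leaving a dangling process/modulation reference is an
#'     integrity error);
#'   \item \code{edit_delete_process(id)} — remove a process and the
#'     modulation arcs targeting it;
#'   \item \code{edit_add_process(p)}, \code{edit_add_modulation(m)} — insert
#'     new concepts.
#' }
#' Edits matching no concept are applied as no-ops and reported as such.
#'
#' @param old,new,query,compartment,value,site,id character scalars.
#' @param p a [process_node()]; \code{m} a [modulation()].
#' @return an object of class \code{pd_edit}.
#' @name pd_edit
NULL

pd_edit <- function(op, ...) structure(list(op = op, ...), class = "pd_edit")

#' @rdname pd_edit
#' @export
edit_rename_label <- function(old, new) pd_edit("rename-label", old = old, new = new)
#' @rdname pd_edit
#' @export
edit_set_compartment <- function(query, compartment)
  pd_edit("set-compartment", query = query, compartment = compartment)
#' @rdname pd_edit
#' @export
edit_add_state_variable <- function(query, value, site = "")
  pd_edit("add-state-variable", query = query, value = value, site = site)
#' @rdname pd_edit
#' @export
edit_delete_entity <- function(query) pd_edit("delete-entity", query = query)
#' @rdname pd_edit
#' @export
edit_delete_process <- function(id) pd_edit("delete-process", id = id)
#' @rdname pd_edit
#' @export
edit_add_process <- function(p) pd_edit("add-process", process = p)
#' @rdname pd_edit
#' @export
edit_add_modulation <- function(m) pd_edit("add-modulation", modulation = m)

#' Bundle edits into a script
#' @param ... [pd_edit] objects (or a single list of them).
#' @return an object of class \code{edit_script}.
#' @export
edit_script <- function(...) {
  edits <- list(...)
  if (length(edits) == 1L && !inherits(edits[[1L]], "pd_edit"))
    edits <- edits[[1L]]
  stopifnot(all(vapply(edits, inherits, FALSE, "pd_edit")))
  structure(edits, class = "edit_script")
}

# rebuild a map after transforming every entity unit with f (applied to
# subunits first, then the containing entity); returns list(map, n_matches)
transform_entities <- function(map, f) {
  n <- 0L
  tf <- function(e) {
    if (length(e$subunits)) e$subunits <- lapply(e$subunits, tf)
    e2 <- f(e)
    if (!identical(entity_key(e2), entity_key(e))) n <<- n + 1L
    e2
  }
  out <- pd_map(map$compartments)
  old_keys <- names(map$entities)
  new_ents <- lapply(map$entities, tf)
  for (e in new_ents) out <- add_entity(out, e)
  keymap <- stats::setNames(vapply(new_ents, entity_key, ""), old_keys)
  for (p in map$processes) {
    p$reactants <- lapply(p$reactants, tf)
    p$products <- lapply(p$products, tf)
    out <- add_process(out, p)
  }
  tf_src <- function(s) {
    if (inherits(s, "sbgn_logic")) { s$children <- lapply(s$children, tf_src); s }
    else tf(s)
  }
  for (m in map$modulations) {
    m$source <- tf_src(m$source)
    out <- add_modulation(out, m)
  }
  for (k in names(map$annotations)) {
    nk <- if (!is.na(keymap[k])) keymap[[k]] else k
    out$annotations[[nk]] <- unique(c(out$annotations[[nk]],
                                      map$annotations[[k]]))
  }
  list(map = out, n = n)
}

apply_edit <- function(map, ed) {
  switch(ed$op,
    "rename-label" = {
      hits <- 0L
      r <- transform_entities(map, function(e) {
        if (identical(e$label, ed$old)) { hits <<- hits + 1L; e$label <- ed$new }
        e
      })
      list(map = r$map, n = hits)
    },
    "add-state-variable" = {
      hits <- 0L
      r <- transform_entities(map, function(e) {
        txt <- if (e$epn_class == "complex") NULL else render_entity_text(e)
        if (!is.null(txt) && identical(txt, ed$query)) {
          hits <<- hits + 1L
          svs <- e$state_variables
          ck <- vapply(svs, function(s) paste(s$value, s$site, sep = "@"), "")
          ord <- sum(ck == paste(ed$value, ed$site, sep = "@")) + 1L
          e$state_variables <- c(svs, list(state_variable(ed$value, ed$site,
                                                          ord)))
        }
        e
      })
      list(map = r$map, n = hits)
    },
    "set-compartment" = {
      hits <- 0L
      out <- pd_map(unique(c(map$compartments, ed$compartment)))
      reloc <- function(e) {
        if (identical(render_entity_text(e), ed$query)) {
          hits <<- hits + 1L; e$compartment <- ed$compartment
        }
        e
      }
      for (e in map$entities) out <- add_entity(out, reloc(e))
      for (p in map$processes) {
        p$reactants <- lapply(p$reactants, reloc)
        p$products <- lapply(p$products, reloc)
        out <- add_process(out, p)
      }
      reloc_src <- function(s) {
        if (inherits(s, "sbgn_logic")) { s$children <- lapply(s$children, reloc_src); s }
        else reloc(s)
      }
      for (m in map$modulations) {
        m$source <- reloc_src(m$source)
        out <- add_modulation(out, m)
      }
      out$annotations <- map$annotations
      list(map = out, n = hits)
    },
    "delete-entity" = {
      victims <- Filter(function(e)
        identical(render_entity_text(e), ed$query), map$entities)
      vkeys <- vapply(victims, entity_key, "")
      if (length(vkeys)) {
        for (p in map$processes) {
          pk <- vapply(c(p$reactants, p$products), entity_key, "")
          if (any(pk %in% vkeys))
            stop("integrity error in delete-entity('", ed$query,
                 "'): entity participates in process ", p$id)
        }
        for (m in map$modulations) {
          sk <- vapply(logic_entities(m$source), entity_key, "")
          if (any(sk %in% vkeys))
            stop("integrity error in delete-entity('", ed$query,
                 "'): entity is a modulation source")
        }
        map$entities[vkeys] <- NULL
        map$annotations[intersect(names(map$annotations), vkeys)] <- NULL
      }
      list(map = map, n = length(vkeys))
    },
    "delete-process" = {
      if (is.null(map$processes[[ed$id]])) return(list(map = map, n = 0L))
      map$processes[[ed$id]] <- NULL
      map$modulations <- Filter(function(m) !identical(m$target, ed$id),
                                map$modulations)
      list(map = map, n = 1L)
    },
    "add-process" = list(map = add_process(map, ed$process), n = 1L),
    "add-modulation" = list(map = add_modulation(map, ed$modulation), n = 1L),
    stop("unknown edit op: ", ed$op))
}

#' Apply an edit script to a map
#'
#' Edits are applied in order; the input map value is untouched.  The report
#' attribute lists per-edit match counts (a zero count is a no-op, not an
#' error).
#'
#' @param map a \code{pd_map}.
#' @param script an [edit_script()].
#' @return the edited map, with a per-edit report data frame in attribute
#'   \code{"report"}.
#' @export
harmonize <- function(map, script) {
  stopifnot(inherits(map, "pd_map"), inherits(script, "edit_script"))
  rows <- list()
  for (i in seq_along(script)) {
    r <- apply_edit(map, script[[i]])
    map <- r$map
    rows[[i]] <- data.frame(step = i, op = script[[i]]$op, matches = r$n)
  }
  validate_pd_map(map)
  attr(map, "report") <- if (length(rows)) do.call(rbind, rows)
                         else data.frame(step = integer(), op = character(),
                                         matches = integer())
  map
}

#' Merge two PD maps
#'
#' Union of compartments, entity pools, processes, modulations and
#' annotations under structural equality; structurally equal concepts appear
#' once.  Process-identifier collisions between structurally different
#' processes are resolved by re-identification (suffixing), recorded in
#' attribute \code{"relabelled"}.  Merging is total, idempotent and
#' commutative up to structural equality.
#'
#' @param a,b \code{pd_map} objects (already harmonized: shared concepts
#'   structurally equal).
#' @return the merged \code{pd_map}.
#' @export
merge_maps <- function(a, b) {
  stopifnot(inherits(a, "pd_map"), inherits(b, "pd_map"))
  out <- pd_map(unique(c(a$compartments, b$compartments)))
  for (e in a$entities) out <- add_entity(out, e)
  for (e in b$entities) out <- add_entity(out, e)
  pkeys <- vapply(a$processes, process_key, "")
  for (p in a$processes) out$processes[[p$id]] <- p
  relabelled <- character()
  id_remap <- character()
  for (p in b$processes) {
    k <- process_key(p)
    hit <- names(pkeys)[match(k, pkeys)]
    if (!is.na(hit)) { id_remap[p$id] <- hit; next }  # same process exists
    new_id <- p$id
    while (!is.null(out$processes[[new_id]]))
      new_id <- paste0(new_id, "_m")
    if (!identical(new_id, p$id)) {
      relabelled <- c(relabelled,
                      sprintf("%s -> %s", p$id, new_id))
      id_remap[p$id] <- new_id
      p$id <- new_id
    } else id_remap[p$id] <- p$id
    out$processes[[p$id]] <- p
    pkeys[p$id] <- k
  }
  proc_keys_out <- vapply(out$processes, process_key, "")
  seen <- character()
  push_mod <- function(m) {
    mk <- modulation_key(m, as.list(proc_keys_out))
    if (!(mk %in% seen)) {
      seen <<- c(seen, mk)
      out$modulations[[length(out$modulations) + 1L]] <<- m
    }
  }
  for (m in a$modulations) push_mod(m)
  for (m in b$modulations) {
    if (!is.na(id_remap[m$target])) m$target <- unname(id_remap[m$target])
    push_mod(m)
  }
  for (k in names(a$annotations))
    out$annotations[[k]] <- unique(c(out$annotations[[k]], a$annotations[[k]]))
  for (k in names(b$annotations)) {
    nk <- if (!is.na(id_remap[k])) unname(id_remap[k]) else k
    out$annotations[[nk]] <- unique(c(out$annotations[[nk]],
                                      b$annotations[[k]]))
  }
  validate_pd_map(out)
  attr(out, "relabelled") <- relabelled
  out
}

## ---- edit-script serialization ----------------------------------------------

edit_to_list <- function(ed) {
  x <- unclass(ed)
  if (!is.null(x$process)) {
    p <- x$process
    x$process <- list(id = p$id, class = p$process_class,
                      reactants = vapply(p$reactants, render_entity_text, ""),
                      products = vapply(p$products, render_entity_text, ""),
                      compartment = {
                        cs <- unlist(lapply(c(p$reactants, p$products),
                                            function(e) e$compartment))
                        if (length(cs)) cs[[1L]] else NULL
                      })
  }
  if (!is.null(x$modulation)) {
    m <- x$modulation
    if (inherits(m$source, "sbgn_logic"))
      stop("logical-function modulation sources are not serializable in ",
           "edit scripts; add them programmatically")
    x$modulation <- list(class = m$mod_class,
                         source = render_entity_text(m$source),
                         compartment = m$source$compartment,
                         target = m$target)
  }
  x
}

list_to_edit <- function(x) {
  if (!is.null(x$process)) {
    p <- x$process
    comp <- p$compartment
    x$process <- process_node(p$id,
      reactants = lapply(p$reactants, parse_entity_text, compartment = comp),
      products = lapply(p$products, parse_entity_text, compartment = comp),
      process_class = p$class)
  }
  if (!is.null(x$modulation)) {
    m <- x$modulation
    x$modulation <- modulation(m$class,
                               parse_entity_text(m$source, m$compartment),
                               m$target)
  }
  do.call(pd_edit, x)
}

#' Read/write edit scripts as YAML
#'
#' Scripts are serialized as a YAML list of edit records, with process and
#' modulation participants written in the textual entity grammar, so that a
#' harmonization can be replayed on updated input maps.
#'
#' @param script an [edit_script()].
#' @param path file path.
#' @return \code{write_edit_script} returns \code{path} invisibly;
#'   \code{read_edit_script} returns an \code{edit_script}.
#' @export
write_edit_script <- function(script, path) {
  yaml::write_yaml(lapply(script, edit_to_list), path)
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  edit_script(lapply(yaml::read_yaml(path), list_to_edit))
}
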