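## General (permissive) qualitative semantics of PD maps.
##
## Each entity pool becomes a binary automaton (0 = absent, 1 = present) and
## each process a binary automaton (0 = switched off, 1 = switched on).
## Transitions are guarded:
##   process 0->1 : all reactants present, all necessary stimulations active,
##                  all absolute inhibitions inactive, and -- when the process
##                  carries any plain stimulation/catalysis/modulation or
##                  inhibition arc -- at least one stimulation active or one
##                  inhibition inactive;
##   process 1->0 : all products present;
##   entity  0->1 : some producing process switched on;
##   entity  1->0 : some consuming process switched on with all its products
##                  present.
## Updates are asynchronous: exactly one automaton changes per step.

## guard expression trees ------------------------------------------------------

g_const <- function(val) list(type = "const", val = val)
g_at <- function(i, val) list(type = "at", aut = i, val = val)
g_not <- function(g) list(type = "not", arg = g)
g_and <- function(args) {
  args <- args[!vapply(args, function(g) identical(g$type, "const") && g$val, FALSE)]
  if (!length(args)) g_const(TRUE)
  else if (length(args) == 1L) args[[1L]]
  else list(type = "and", args = args)
}
g_or <- function(args) {
  if (!length(args)) g_const(FALSE)
  else if (length(args) == 1L) args[[1L]]
  else list(type = "or", args = args)
}

eval_guard <- function(g, s) {
  switch(g$type,
         const = g$val,
         at = s[[g$aut]] == g$val,
         not = !eval_guard(g$arg, s),
         and = { for (a in g$args) if (!eval_guard(a, s)) return(FALSE); TRUE },
         or = { for (a in g$args) if (eval_guard(a, s)) return(TRUE); FALSE },
         stop("bad guard node"))
}

guard_refs <- function(g) {
  switch(g$type,
         const = integer(),
         at = g$aut,
         not = guard_refs(g$arg),
         and = ,
         or = unique(unlist(lapply(g$args, guard_refs))),
         stop("bad guard node"))
}

## automaton naming ------------------------------------------------------------

# Deterministic readable ids for entity automata: the marker-grammar rendering,
# disambiguated by compartment when two pools render identically.
an_entity_ids <- function(map) {
  ents <- map$entities[!vapply(map$entities, function(e)
    e$epn_class == "source-sink", FALSE)]
  if (!length(ents)) return(character())
  keys <- sort(names(ents), method = "radix")
  base <- vapply(keys, function(k) render_entity_text(ents[[k]]), "")
  dup <- base %in% base[duplicated(base)]
  ids <- base
  ids[dup] <- vapply(which(dup), function(i) {
    comp <- ents[[keys[i]]]$compartment
    paste0(base[i], "@", if (is.null(comp)) "?" else comp)
  }, "")
  names(ids) <- keys
  ids
}

## rule (iv) evaluated directly on the map -------------------------------------

#' Evaluate a modulation source against a global state
#'
#' An entity source is satisfied iff the entity is present; logical functions
#' are evaluated with present = true.
#'
#' @param source an entity pool or [logical_function()].
#' @param state a named 0/1 vector whose names include the entity automaton
#'   ids of the map (see [translate()]).
#' @param map the \code{pd_map} the source belongs to (used to resolve entity
#'   automaton ids).
#' @return logical scalar.
#' @export
eval_modulation <- function(source, state, map) {
  ids <- an_entity_ids(map)
  ev <- function(s) {
    if (inherits(s, "sbgn_logic")) {
      vals <- vapply(s$children, ev, FALSE)
      switch(s$operator, AND = all(vals), OR = any(vals), NOT = !vals[1L])
    } else {
      id <- ids[entity_key(s)]
      if (is.na(id) || !(id %in% names(state)))
        stop("modulation source entity has no automaton in the state: ",
             render_entity_text(s))
      state[[id]] == 1
    }
  }
  ev(source)
}

#' Can a process switch on in a given state?
#'
#' Direct evaluation of the permissive firing condition: all reactants
#' present, all necessary stimulations active, all absolute inhibitions
#' inactive, and, if the process carries any plain stimulation, catalysis,
#' generic modulation or inhibition arc, at least one of those stimulations
#' active or one of those inhibitions inactive.  A process with no plain arcs
#' satisfies the last clause vacuously, so unmodulated processes with present
#' reactants can always fire.
#'
#' @param map a \code{pd_map}.
#' @param p a process or a process id.
#' @param state a named 0/1 vector over the map's entity automaton ids
#'   (process coordinates, if present, are ignored).
#' @return logical scalar.
#' @export
can_switch_on <- function(map, p, state) {
  if (is.character(p)) p <- map$processes[[p]]
  stopifnot(inherits(p, "sbgn_process"))
  ids <- an_entity_ids(map)
  for (r in p$reactants) {
    id <- ids[[entity_key(r)]]
    if (!is.null(id) && state[[id]] != 1) return(FALSE)
  }
  mods <- Filter(function(m) identical(m$target, p$id), map$modulations)
  plain_sat <- NA
  for (m in mods) {
    act <- eval_modulation(m$source, state, map)
    if (m$mod_class == "necessary-stimulation") {
      if (!act) return(FALSE)
    } else if (m$mod_class == "absolute-inhibition") {
      if (act) return(FALSE)
    } else if (m$mod_class == "inhibition") {
      plain_sat <- isTRUE(plain_sat) || !act
    } else {  # stimulation, catalysis, generic modulation
      plain_sat <- isTRUE(plain_sat) || act
    }
  }
  is.na(plain_sat) || plain_sat
}

## translation -----------------------------------------------------------------

#' Translate a PD map into an asynchronous automata network
#'
#' One binary automaton per entity pool (source/sink pools excluded) and one
#' per process, with guarded transition rules as described above.  Catalysis
#' and generic modulation arcs are treated as stimulations (logged via
#' \code{attr(, "arc_notes")}).  Directions with no enabling condition (e.g.
#' an entity no process produces) simply lack a rule.  Translation is
#' deterministic: automata are ordered canonically (entities by structural
#' key, then processes by id).
#'
#' @param map a \code{pd_map}.
#' @return an object of class \code{automata_network} with fields \code{ids},
#'   \code{kind}, \code{rules} (each rule: automaton index, from, to, guard)
#'   and \code{provenance}.
#' @export
translate <- function(map) {
  stopifnot(inherits(map, "pd_map"))
  eids <- an_entity_ids(map)
  pids0 <- sort(as.character(names(map$processes)), method = "radix")
  pids <- pids0
  clash <- pids %in% eids
  pids[clash] <- paste0("proc:", pids[clash])
  ids <- c(unname(eids), pids)
  kind <- c(rep("entity", length(eids)), rep("process", length(pids)))
  idx <- seq_along(ids); names(idx) <- ids
  ent_idx <- function(key) {
    id <- eids[[key]]
    if (is.null(id)) NA_integer_ else idx[[id]]
  }
  proc_idx <- idx[length(eids) + seq_along(pids)]
  names(proc_idx) <- pids0

  src_guard <- function(s) {
    if (inherits(s, "sbgn_logic")) {
      gs <- lapply(s$children, src_guard)
      switch(s$operator, AND = g_and(gs), OR = g_or(gs), NOT = g_not(gs[[1L]]))
    } else g_at(ent_idx(entity_key(s)), 1L)
  }

  rules <- list()
  notes <- character()
  add_rule <- function(aut, from, to, guard)
    rules[[length(rules) + 1L]] <<- list(aut = aut, from = from, to = to,
                                         guard = guard)

  mods_by_target <- split(map$modulations,
                          vapply(map$modulations, function(m) m$target, ""))

  for (pid in pids0) {
    p <- map$processes[[pid]]
    pi <- proc_idx[[pid]]
    conj <- list()
    rkeys <- unique(vapply(p$reactants, entity_key, ""))
    for (k in rkeys) {
      i <- ent_idx(k)
      if (!is.na(i)) conj[[length(conj) + 1L]] <- g_at(i, 1L)
    }
    plain <- list()
    for (m in mods_by_target[[pid]]) {
      g <- src_guard(m$source)
      if (m$mod_class == "necessary-stimulation")
        conj[[length(conj) + 1L]] <- g
      else if (m$mod_class == "absolute-inhibition")
        conj[[length(conj) + 1L]] <- g_not(g)
      else if (m$mod_class == "inhibition")
        plain[[length(plain) + 1L]] <- g_not(g)
      else {
        if (m$mod_class != "stimulation")
          notes <- c(notes, sprintf("%s arc on %s treated as stimulation",
                                    m$mod_class, pid))
        plain[[length(plain) + 1L]] <- g
      }
    }
    if (length(plain)) conj[[length(conj) + 1L]] <- g_or(plain)
    add_rule(pi, 0L, 1L, g_and(conj))
    pconj <- list()
    for (k in unique(vapply(p$products, entity_key, ""))) {
      i <- ent_idx(k)
      if (!is.na(i)) pconj[[length(pconj) + 1L]] <- g_at(i, 1L)
    }
    add_rule(pi, 1L, 0L, g_and(pconj))
  }

  for (k in names(eids)) {
    i <- idx[[eids[[k]]]]
    producers <- list(); consumers <- list()
    for (pid in pids0) {
      p <- map$processes[[pid]]
      pkeys <- vapply(p$products, entity_key, "")
      rkeys <- vapply(p$reactants, entity_key, "")
      if (k %in% pkeys)
        producers[[length(producers) + 1L]] <- g_at(proc_idx[[pid]], 1L)
      if (k %in% rkeys) {
        sat <- lapply(unique(pkeys), function(kk) {
          j <- ent_idx(kk); if (is.na(j)) NULL else g_at(j, 1L)
        })
        sat <- sat[!vapply(sat, is.null, FALSE)]
        consumers[[length(consumers) + 1L]] <-
          g_and(c(list(g_at(proc_idx[[pid]], 1L)), sat))
      }
    }
    if (length(producers)) add_rule(i, 0L, 1L, g_or(producers))
    if (length(consumers)) add_rule(i, 1L, 0L, g_or(consumers))
  }

  prov <- c(lapply(names(eids), function(k)
              list(kind = "entity", key = k,
                   text = render_entity_text(map$entities[[k]]),
                   compartment = map$entities[[k]]$compartment)),
            lapply(pids0, function(pid) list(kind = "process", id = pid)))
  names(prov) <- c(unname(eids), pids)

  an <- structure(list(ids = ids, kind = kind, rules = rules,
                       provenance = prov),
                  class = "automata_network")
  attr(an, "arc_notes") <- notes
  an
}

#' @export
print.automata_network <- function(x, ...) {
  cat("Automata network:", sum(x$kind == "entity"), "entity +",
      sum(x$kind == "process"), "process automata;",
      length(x$rules), "transition rules\n")
  invisible(x)
}

#' Asynchronous successor states
#'
#' Returns one successor per enabled transition rule; each successor differs
#' from \code{state} in exactly one automaton.  The dynamics are
#' non-deterministic: which successor is taken is left to the caller.
#'
#' @param an an \code{automata_network}.
#' @param state a named 0/1 vector over \code{an$ids} (a global state).
#' @return a list of global states (possibly empty, if the state is a
#'   deadlock).
#' @export
step <- function(an, state) {
  s <- as.integer(state[an$ids])
  succ <- step_idx(an, s)
  lapply(succ, function(v) stats::setNames(v, an$ids))
}

# unnamed integer-vector engine used by the explorers
step_idx <- function(an, s) {
  out <- list()
  for (r in an$rules) {
    if (s[r$aut] == r$from && eval_guard(r$guard, s)) {
      s2 <- s; s2[r$aut] <- r$to
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

enabled_rules <- function(an, s) {
  which(vapply(an$rules, function(r)
    s[r$aut] == r$from && eval_guard(r$guard, s), FALSE))
}

## plain-text exchange format --------------------------------------------------

render_guard <- function(g, ids) {
  switch(g$type,
         const = if (g$val) "true" else "false",
         at = sprintf("\"%s\"=%d", ids[g$aut], g$val),
         not = paste0("not ", render_guard(g$arg, ids)),
         and = paste0("(", paste(vapply(g$args, render_guard, "", ids = ids),
                                 collapse = " and "), ")"),
         or = paste0("(", paste(vapply(g$args, render_guard, "", ids = ids),
                                collapse = " or "), ")"))
}

#' Write an automata network to a plain-text exchange file
#'
#' One automaton declaration per line
#' (\code{automaton "id" entity|process}) followed by one guarded transition
#' per line (\code{"id" 0 -> 1 when <guard>}), guards written with
#' \code{and}/\code{or}/\code{not} over \code{"id"=value} literals.
#' Provenance can be exported separately with [write_an_provenance()].
#'
#' @param an an \code{automata_network}.
#' @param path output file path.
#' @return invisibly \code{path}.
#' @export
write_an <- function(an, path) {
  lines <- c(sprintf("automaton \"%s\" %s", an$ids, an$kind),
             vapply(an$rules, function(r)
               sprintf("\"%s\" %d -> %d when %s", an$ids[r$aut], r$from, r$to,
                       render_guard(r$guard, an$ids)), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Export automata provenance as JSON
#'
#' @param an an \code{automata_network}.
#' @param path output file path.
#' @return invisibly \code{path}.
#' @export
write_an_provenance <- function(an, path) {
  jsonlite::write_json(an$provenance, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
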