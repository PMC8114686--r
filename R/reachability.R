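## Exact explicit-state reachability on automata networks.  States are 0/1
## integer vectors in the network's canonical automaton order; breadth-first
## search with a visited set yields minimal-length witnesses, and exploration
## is capped by an explicit state budget with "budget-exceeded" as a third
## verdict, never conflated with "unreachable".

state_key <- function(s) intToUtf8(s + 48L)

#' Reachability goal
#'
#' @param present,absent disjoint sets of entity automaton ids required to be
#'   1 resp. 0 in a satisfying state.
#' @return an object of class \code{goal_spec}.
#' @export
goal_spec <- function(present = character(), absent = character()) {
  present <- unique(as.character(present)); absent <- unique(as.character(absent))
  if (length(intersect(present, absent)))
    stop("goal present/absent sets overlap: ",
         paste(intersect(present, absent), collapse = ", "))
  structure(list(present = present, absent = absent), class = "goal_spec")
}

#' LoF/GoF mutation
#'
#' A loss-of-function (LoF) mutation makes an entity impossible to be present;
#' a gain-of-function (GoF) mutation forces its presence.
#'
#' @param entity entity automaton id.
#' @param kind \code{"LoF"} or \code{"GoF"}.
#' @return an object of class \code{an_mutation}.
#' @export
an_mutation <- function(entity, kind = c("LoF", "GoF")) {
  kind <- match.arg(kind)
  structure(list(entity = as.character(entity), kind = kind),
            class = "an_mutation")
}

goal_idx <- function(an, goal) {
  idx <- seq_along(an$ids); names(idx) <- an$ids
  unknown <- setdiff(c(goal$present, goal$absent), an$ids)
  if (length(unknown)) stop("unknown automata in goal: ",
                            paste(unknown, collapse = ", "))
  list(p = unname(idx[goal$present]), a = unname(idx[goal$absent]))
}

goal_sat <- function(gi, s) {
  (!length(gi$p) || all(s[gi$p] == 1L)) &&
    (!length(gi$a) || all(s[gi$a] == 0L))
}

#' Initial global state of a network
#'
#' All processes are switched off; exactly the listed entities are present.
#' Mutations previously applied with [apply_mutations()] are honoured: a GoF
#' entity is forced present, and listing a LoF entity as present is an error.
#'
#' @param an an \code{automata_network}.
#' @param present character vector of entity automaton ids.
#' @return a named 0/1 integer vector over \code{an$ids}.
#' @export
initial_state <- function(an, present = character()) {
  present <- unique(as.character(present))
  unknown <- setdiff(present, an$ids[an$kind == "entity"])
  if (length(unknown))
    stop("unknown entity ids: ", paste(unknown, collapse = ", "))
  s <- stats::setNames(integer(length(an$ids)), an$ids)
  s[present] <- 1L
  forced <- attr(an, "forced")
  if (!is.null(forced)) {
    lof <- names(forced)[forced == 0L]
    bad <- intersect(lof, present)
    if (length(bad))
      stop("entities under LoF cannot be initially present: ",
           paste(bad, collapse = ", "))
    s[names(forced)] <- forced
  }
  s
}

#' Apply LoF/GoF mutations to a network
#'
#' LoF removes the entity's 0 to 1 rules (and forces it absent in initial
#' states built from the mutated network); GoF removes its 1 to 0 rules and
#' forces it present.  Guards referencing the entity are unchanged.
#'
#' @param an an \code{automata_network}.
#' @param muts a list of [an_mutation()] objects (or a single one).
#' @return the mutated network.
#' @export
apply_mutations <- function(an, muts) {
  if (inherits(muts, "an_mutation")) muts <- list(muts)
  if (!length(muts)) return(an)
  ents <- vapply(muts, function(m) m$entity, "")
  kinds <- vapply(muts, function(m) m$kind, "")
  if (anyDuplicated(ents)) {
    dups <- unique(ents[duplicated(ents)])
    for (d in dups)
      if (length(unique(kinds[ents == d])) > 1L)
        stop("conflicting LoF and GoF on entity ", d)
  }
  idx <- seq_along(an$ids); names(idx) <- an$ids
  unknown <- setdiff(ents, an$ids[an$kind == "entity"])
  if (length(unknown))
    stop("mutations name unknown entities: ", paste(unknown, collapse = ", "))
  forced <- attr(an, "forced")
  if (is.null(forced)) forced <- stats::setNames(integer(0), character(0))
  drop_dir <- function(rules, i, from) {
    Filter(function(r) !(r$aut == i && r$from == from), rules)
  }
  for (j in seq_along(muts)) {
    i <- idx[[ents[j]]]
    if (kinds[j] == "LoF") {
      if (!is.na(forced[ents[j]]) && identical(unname(forced[ents[j]]), 1L))
        stop("conflicting LoF and GoF on entity ", ents[j])
      an$rules <- drop_dir(an$rules, i, 0L)
      forced[ents[j]] <- 0L
    } else {
      if (!is.na(forced[ents[j]]) && identical(unname(forced[ents[j]]), 0L))
        stop("conflicting LoF and GoF on entity ", ents[j])
      an$rules <- drop_dir(an$rules, i, 1L)
      forced[ents[j]] <- 1L
    }
  }
  attr(an, "forced") <- forced
  an
}

#' Disable a set of phase markers
#'
#' Equivalent to applying a LoF mutation to every marker: the markers can
#' never become present.  Building an initial state in which a disabled
#' marker is present raises an error.
#'
#' @param an an \code{automata_network}.
#' @param markers character vector of entity automaton ids.
#' @return the modified network.
#' @export
disable_markers <- function(an, markers) {
  if (!length(markers)) return(an)
  apply_mutations(an, lapply(markers, an_mutation, kind = "LoF"))
}

## ---- BFS --------------------------------------------------------------------

#' Is a goal state reachable?
#'
#' Breadth-first exploration of the asynchronous state graph from
#' \code{init}.  Returns \code{"reachable"} with a minimal-length witness
#' trajectory, \code{"unreachable"} only when the full reachable set was
#' exhausted, or \code{"budget-exceeded"} when more than \code{budget} states
#' were visited — never reported as unreachable.
#'
#' @param an an \code{automata_network}.
#' @param init a global state (named 0/1 vector over \code{an$ids}).
#' @param goal a [goal_spec()].
#' @param budget maximum number of distinct states to visit.
#' @return a list with elements \code{verdict} (one of \code{"reachable"},
#'   \code{"unreachable"}, \code{"budget-exceeded"}), \code{trajectory} (list
#'   of global states, \code{NULL} unless reachable), \code{fired} (indices
#'   into \code{an$rules}) and \code{n_visited}.
#' @export
reachable <- function(an, init, goal, budget = 5e6) {
  stopifnot(budget > 0)
  gi <- goal_idx(an, goal)
  s0 <- as.integer(init[an$ids])
  res <- bfs_search(an, list(s0), function(s) goal_sat(gi, s), budget)
  if (res$verdict == "reachable") {
    tr <- bfs_backtrack(res, res$hit)
    list(verdict = "reachable",
         trajectory = lapply(tr$states, function(v) stats::setNames(v, an$ids)),
         fired = tr$fired, n_visited = res$n_visited)
  } else {
    list(verdict = res$verdict, trajectory = NULL, fired = NULL,
         n_visited = res$n_visited)
  }
}

# Multi-source BFS.  stop_first: stop at first satisfying state (reachable());
# otherwise explores the whole reachable set (capped) and records all
# satisfying states (sequence layers).
bfs_search <- function(an, sources, sat, budget, stop_first = TRUE) {
  visited <- new.env(hash = TRUE, parent = emptyenv())
  states <- vector("list", 1024L)
  parent <- integer(1024L); via <- integer(1024L)
  n <- 0L
  push <- function(s, par, rule) {
    n <<- n + 1L
    if (n > length(states)) {
      length(states) <<- 2L * length(states)
      length(parent) <<- 2L * length(parent)
      length(via) <<- 2L * length(via)
    }
    states[[n]] <<- s; parent[n] <<- par; via[n] <<- rule
    n
  }
  hits <- integer()
  for (s in sources) {
    k <- state_key(s)
    if (is.null(visited[[k]])) {
      visited[[k]] <- push(s, 0L, 0L)
      if (sat(s)) {
        if (stop_first)
          return(list(verdict = "reachable", states = states, parent = parent,
                      via = via, hit = visited[[k]], n_visited = n))
        hits <- c(hits, visited[[k]])
      }
    }
  }
  head <- 1L
  while (head <= n) {
    if (n > budget)
      return(list(verdict = "budget-exceeded", states = states,
                  parent = parent, via = via, hits = hits, n_visited = n))
    s <- states[[head]]
    ridx <- enabled_rules(an, s)
    for (ri in ridx) {
      r <- an$rules[[ri]]
      s2 <- s; s2[r$aut] <- r$to
      k <- state_key(s2)
      if (is.null(visited[[k]])) {
        id <- push(s2, head, ri)
        visited[[k]] <- id
        if (sat(s2)) {
          if (stop_first)
            return(list(verdict = "reachable", states = states,
                        parent = parent, via = via, hit = id, n_visited = n))
          hits <- c(hits, id)
        }
      }
    }
    head <- head + 1L
  }
  list(verdict = if (length(hits)) "reachable" else "unreachable",
       states = states, parent = parent, via = via, hits = hits,
       n_visited = n)
}

bfs_backtrack <- function(res, id) {
  states <- list(); fired <- integer()
  while (id != 0L) {
    states <- c(list(res$states[[id]]), states)
    if (res$via[id] != 0L) fired <- c(res$via[id], fired)
    id <- res$parent[id]
  }
  list(states = states, fired = fired)
}

#' Is an ordered sequence of goals reachable along one trajectory?
#'
#' Layered frontier search: the first frontier is \code{init}; frontier k+1
#' is the set of states satisfying goal k+1 reachable from frontier k.  A
#' state satisfying goal k may itself already satisfy goal k+1 (adjacent
#' satisfaction is allowed).  The empty goal list is trivially reachable.
#'
#' @inheritParams reachable
#' @param goals list of [goal_spec()] objects, in the order they must be met.
#' @return as [reachable()]; the witness trajectory visits each goal in
#'   order.  \code{budget} caps the total states visited across layers.
#' @export
sequence_reachable <- function(an, init, goals, budget = 5e6) {
  s0 <- as.integer(init[an$ids])
  if (!length(goals))
    return(list(verdict = "reachable",
                trajectory = list(stats::setNames(s0, an$ids)),
                n_visited = 1L))
  frontier <- list(s0)
  layers <- list()
  spent <- 0L
  for (g in goals) {
    gi <- goal_idx(an, g)
    res <- bfs_search(an, frontier, function(s) goal_sat(gi, s),
                      budget - spent, stop_first = FALSE)
    spent <- spent + res$n_visited
    if (res$verdict == "budget-exceeded")
      return(list(verdict = "budget-exceeded", trajectory = NULL,
                  n_visited = spent))
    if (!length(res$hits))
      return(list(verdict = "unreachable", trajectory = NULL,
                  n_visited = spent))
    layers[[length(layers) + 1L]] <- res
    frontier <- lapply(res$hits, function(i) res$states[[i]])
  }
  # witness: backtrack layer by layer, stitching segments at frontier states
  segs <- list()
  # pick any hit in the last layer, then find, in each earlier layer, the hit
  # whose state equals the segment's start
  target_id <- layers[[length(layers)]]$hits[1L]
  for (l in rev(seq_along(layers))) {
    tr <- bfs_backtrack(layers[[l]], target_id)
    segs[[length(segs) + 1L]] <- tr$states
    if (l > 1L) {
      start_key <- state_key(tr$states[[1L]])
      prev <- layers[[l - 1L]]
      match_id <- NULL
      for (h in prev$hits)
        if (identical(state_key(prev$states[[h]]), start_key)) {
          match_id <- h; break
        }
      target_id <- match_id
    }
  }
  segs <- rev(segs)
  states <- segs[[1L]]
  if (length(segs) > 1L)
    for (l in 2L:length(segs)) states <- c(states, segs[[l]][-1L])
  list(verdict = "reachable",
       trajectory = lapply(states, function(v) stats::setNames(v, an$ids)),
       n_visited = spent)
}

## ---- structural over-approximation ------------------------------------------

#' Producibility closure, ignoring modulations
#'
#' Least fixpoint of: the seeded entities are producible; products of source
#' processes are producible; products of any process whose reactants are all
#' producible are producible.  Modulation arcs are ignored entirely, so the
#' closure over-approximates the set of entities reachable under the full
#' semantics: an entity outside the closure is certified unreachable.
#'
#' @param map a \code{pd_map}.
#' @param seed character vector of entity automaton ids (or a list of entity
#'   pools) initially present.
#' @return character vector of entity automaton ids in the closure.
#' @export
unreachability_overapprox <- function(map, seed = character()) {
  ids <- an_entity_ids(map)
  if (is.list(seed)) seed <- vapply(seed, function(e) ids[[entity_key(e)]], "")
  seed <- unique(as.character(seed))
  unknown <- setdiff(seed, unname(ids))
  if (length(unknown)) stop("unknown entities in seed: ",
                            paste(unknown, collapse = ", "))
  keys <- names(ids)
  inR <- stats::setNames(keys %in% names(ids)[match(seed, ids)], keys)
  procs <- lapply(map$processes, function(p)
    list(r = intersect(unique(vapply(p$reactants, entity_key, "")), keys),
         p = intersect(unique(vapply(p$products, entity_key, "")), keys)))
  repeat {
    changed <- FALSE
    for (pr in procs) {
      if (all(inR[pr$r]) && !all(inR[pr$p])) {
        inR[pr$p] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(ids[names(inR)[inR]])
}

#' @rdname unreachability_overapprox
#' @export
closure <- unreachability_overapprox
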