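## Minimal precursor states.
##
## A precursor state is a set of entities whose initial presence lets every
## entity of the map be produced when modulation arcs are ignored (the
## producibility closure).  Among all such sets, the optimal ones are selected
## under lexicographic objectives: least cardinality, then fewest state
## variables set to a value (counted recursively through complex subunits),
## then fewest complexes.  Catalysts are modulations and hence invisible to
## the closure, so enzymes with no producing process sit in every precursor.

#' Objective configuration for precursor-state computation
#'
#' @param required entities that every precursor state must contain: a
#'   character vector of marker strings / entity automaton ids, or a list of
#'   entity pools.
#' @param objectives ordered subset of \code{"min-cardinality"},
#'   \code{"min-state-variables"}, \code{"min-complexes"}; the listed order is
#'   the lexicographic priority.
#' @return an object of class \code{precursor_config}.
#' @export
precursor_config <- function(required = character(),
                             objectives = c("min-cardinality",
                                            "min-state-variables",
                                            "min-complexes")) {
  objectives <- as.character(objectives)
  allowed <- c("min-cardinality", "min-state-variables", "min-complexes")
  if (!length(objectives) || anyDuplicated(objectives) ||
      !all(objectives %in% allowed))
    stop("objectives must be a non-empty duplicate-free subset of: ",
         paste(allowed, collapse = ", "))
  structure(list(required = required, objectives = objectives),
            class = "precursor_config")
}

resolve_required <- function(map, required, ids) {
  if (!length(required)) return(character())
  if (is.list(required))
    return(vapply(required, function(e) {
      hit <- find_entity(map, e)
      if (is.null(hit)) stop("required entity not in map: ",
                             render_entity_text(e))
      ids[[entity_key(hit)]]
    }, ""))
  vapply(as.character(required), function(q) {
    if (q %in% ids) return(q)
    hit <- find_entity(map, q)
    if (is.null(hit)) stop("required entity not in map: ", q)
    ids[[entity_key(hit)]]
  }, "", USE.NAMES = FALSE)
}

n_set_svars <- function(e) {
  own <- sum(vapply(e$state_variables, function(s) nzchar(s$value), FALSE))
  own + sum(vapply(e$subunits, n_set_svars, 0))
}

precursor_score <- function(map, ids, sol, objectives) {
  keys <- names(ids)[match(sol, ids)]
  ents <- map$entities[keys]
  vapply(objectives, function(ob) switch(ob,
    "min-cardinality" = length(sol),
    "min-state-variables" = sum(vapply(ents, n_set_svars, 0)),
    "min-complexes" = sum(vapply(ents, function(e)
      e$epn_class == "complex", FALSE))), 0)
}

#' Enumerate all optimal precursor states of a map
#'
#' Exact search: entities with no producing process (map inputs) are forced
#' into every solution, the remaining entities are searched exhaustively, each
#' candidate set is checked against the producibility closure
#' ([unreachability_overapprox()]), and all lexicographically optimal
#' solutions under the configured objectives are returned.
#'
#' @param map a \code{pd_map}.
#' @param config a [precursor_config()].
#' @param max_free maximum number of non-forced entities the exact search will
#'   enumerate over (guards against combinatorial blow-up).
#' @return a list of precursor states, each a sorted character vector of
#'   entity automaton ids; the list is sorted canonically and carries the
#'   attained objective values as attribute \code{"objective"}.
#' @export
compute_precursors <- function(map, config = precursor_config(),
                               max_free = 20L) {
  stopifnot(inherits(map, "pd_map"), inherits(config, "precursor_config"))
  ids <- an_entity_ids(map)
  all_ids <- unname(ids)
  req <- resolve_required(map, config$required, ids)
  # entities never produced by any process must be seeded
  produced <- unique(unlist(lapply(map$processes, function(p)
    vapply(p$products, entity_key, ""))))
  inputs <- unname(ids[setdiff(names(ids), produced)])
  forced <- union(inputs, req)
  free <- setdiff(all_ids, forced)
  # feasibility: with every entity seeded the closure is trivially complete;
  # report any entity that even the full seed cannot cover (defensive)
  full <- unreachability_overapprox(map, all_ids)
  missing <- setdiff(all_ids, full)
  if (length(missing))
    stop("infeasible: entities unreachable even from the full seed: ",
         paste(missing, collapse = ", "))
  if (length(free) > max_free)
    stop("exact precursor search over ", length(free),
         " free entities exceeds max_free = ", max_free)
  feasible <- function(sol)
    length(unreachability_overapprox(map, sol)) == length(all_ids)

  card_first <- config$objectives[1L] == "min-cardinality"
  sols <- list()
  if (card_first) {
    for (k in 0:length(free)) {
      subs <- if (k == 0L) list(integer(0))
              else utils::combn(length(free), k, simplify = FALSE)
      for (ss in subs) {
        sol <- sort(c(forced, free[ss]))
        if (feasible(sol)) sols[[length(sols) + 1L]] <- sol
      }
      if (length(sols)) break
    }
  } else {
    nf <- length(free)
    for (mask in 0:(2^nf - 1)) {
      ss <- which(bitwAnd(mask, 2^(seq_len(nf) - 1L)) > 0L)
      sol <- sort(c(forced, free[ss]))
      if (feasible(sol)) sols[[length(sols) + 1L]] <- sol
    }
  }
  if (!length(sols)) stop("infeasible: no precursor state exists")
  scores <- lapply(sols, precursor_score, map = map, ids = ids,
                   objectives = config$objectives)
  best <- seq_along(sols)
  for (j in seq_along(config$objectives)) {
    vals <- vapply(scores[best], `[`, 0, j)
    best <- best[vals == min(vals)]
  }
  out <- sols[best]
  out <- out[!duplicated(vapply(out, paste, "", collapse = "\x01"))]
  out <- out[order(vapply(out, paste, "", collapse = "\x01"), method = "radix")]
  attr(out, "objective") <- scores[[best[1L]]]
  out
}

#' Verify the precursor-state invariant
#'
#' Checks independently that the closure of \code{entities} covers the whole
#' map and that all required entities are included.
#'
#' @param map a \code{pd_map}.
#' @param entities character vector of entity automaton ids.
#' @param required as in [precursor_config()].
#' @return logical scalar.
#' @export
is_precursor_state <- function(map, entities, required = character()) {
  ids <- an_entity_ids(map)
  req <- resolve_required(map, required, ids)
  all(req %in% entities) &&
    setequal(unreachability_overapprox(map, entities), unname(ids))
}
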