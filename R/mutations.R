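## Screens for LoF/GoF mutation sets that block a checkpoint marker, and an
## existential trajectory-reliance analysis.  The screens are exhaustive
## within their declared bounds (candidate set and maximal set size), and
## every reported set is independently re-verified by a fresh reachability
## query on the mutated network.

mutation_set_label <- function(ms)
  paste(sort(vapply(ms, function(m) paste0(m$kind, "(", m$entity, ")"), "")),
        collapse = " + ")

#' Exhaustive screen for blocking mutation sets
#'
#' Enumerates all subset-minimal sets of at most \code{max_size} LoF/GoF
#' mutations over \code{candidates} whose application makes \code{marker_goal}
#' unreachable from the precursor-derived initial state.  The initial state is
#' rebuilt per mutated network: LoF entities are dropped from the present set,
#' GoF entities are forced present.
#'
#' @param an an \code{automata_network}.
#' @param present character vector of initially present entity ids (the
#'   precursor state).
#' @param marker_goal a [goal_spec()]; must be reachable in the unmutated
#'   network (otherwise every set blocks trivially).
#' @param max_size maximal number of simultaneous mutations per set.
#' @param candidates entity ids eligible for mutation.
#' @param budget state budget per reachability query.
#' @return a list of blocking mutation sets (each a list of [an_mutation()]),
#'   minimal by construction; sets whose verification exceeded the budget are
#'   returned in attribute \code{"unknown"} instead.
#' @export
blocking_mutations <- function(an, present, marker_goal, max_size = 1L,
                               candidates, budget = 5e6) {
  candidates <- unique(as.character(candidates))
  unknown_c <- setdiff(candidates, an$ids[an$kind == "entity"])
  if (length(unknown_c))
    stop("candidates are not entity automata: ",
         paste(unknown_c, collapse = ", "))
  base <- reachable(an, initial_state(an, present), marker_goal, budget)
  if (base$verdict == "unreachable")
    stop("marker goal is unreachable before any mutation; ",
         "every mutation set would block trivially")
  if (base$verdict == "budget-exceeded")
    stop("baseline reachability check exceeded the state budget")
  atoms <- unlist(lapply(candidates, function(e)
    list(an_mutation(e, "LoF"), an_mutation(e, "GoF"))), recursive = FALSE)
  blocks <- function(ms) {
    an2 <- apply_mutations(an, ms)
    lof <- vapply(ms, function(m) m$entity, "")[
      vapply(ms, function(m) m$kind, "") == "LoF"]
    init2 <- initial_state(an2, setdiff(present, lof))
    reachable(an2, init2, marker_goal, budget)$verdict
  }
  found <- list(); unknown <- list()
  if (max_size < 1L) return(found)
  covered_by_found <- function(ms) {
    lab <- vapply(ms, function(m) paste0(m$kind, m$entity), "")
    for (f in found) {
      flab <- vapply(f, function(m) paste0(m$kind, m$entity), "")
      if (all(flab %in% lab)) return(TRUE)
    }
    FALSE
  }
  for (k in seq_len(max_size)) {
    if (k > length(atoms)) break
    for (comb in utils::combn(length(atoms), k, simplify = FALSE)) {
      ms <- atoms[comb]
      ents <- vapply(ms, function(m) m$entity, "")
      if (anyDuplicated(ents)) next               # LoF+GoF clash
      if (covered_by_found(ms)) next              # not subset-minimal
      v <- blocks(ms)
      if (v == "unreachable") {
        # independent re-verification on a freshly mutated network
        if (blocks(ms) != "unreachable")
          stop("internal error: blocking set failed re-verification")
        found[[length(found) + 1L]] <- ms
      } else if (v == "budget-exceeded") {
        unknown[[length(unknown) + 1L]] <- ms
      }
    }
  }
  attr(found, "unknown") <- unknown
  found
}

#' Summarise blocking screens across markers
#'
#' Groups, per target marker, the entities appearing in at least one blocking
#' mutation set, annotated with the mutation kind and the source-map tag of
#' the entity (its provenance partition).  Entities appearing in several sets
#' are listed once per (entity, kind).
#'
#' @param results named list: target marker name -> list of blocking mutation
#'   sets as returned by [blocking_mutations()].
#' @param partition named character vector mapping entity ids to source-map
#'   tags (e.g. \code{"clock"} / \code{"cycle"}); unmapped entities are
#'   tagged \code{NA}.
#' @return a data frame (marker, entity, kind, source) in deterministic
#'   order, of class \code{control_report}.
#' @export
control_summary <- function(results, partition = character()) {
  rows <- do.call(rbind, lapply(names(results), function(tg) {
    sets <- results[[tg]]
    if (!length(sets)) return(NULL)
    ent <- unlist(lapply(sets, function(ms) vapply(ms, function(m) m$entity, "")))
    kind <- unlist(lapply(sets, function(ms) vapply(ms, function(m) m$kind, "")))
    unique(data.frame(marker = tg, entity = ent, kind = kind,
                      source = unname(partition[ent])))
  }))
  if (is.null(rows))
    rows <- data.frame(marker = character(), entity = character(),
                       kind = character(), source = character())
  rows <- rows[order(rows$marker, rows$entity, rows$kind), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("control_report", "data.frame")
  rows
}

#' Does some trajectory to a goal rely on an entity?
#'
#' Existential surrogate for causal reliance: returns \code{"relies"} iff
#' there exists a trajectory from the initial state that visits a state where
#' the entity is present no later than goal satisfaction — decided by staged
#' (layered) reachability of "entity present" then the goal.  An entity
#' already present initially relies trivially.
#'
#' @param an an \code{automata_network}.
#' @param present character vector of initially present entity ids.
#' @param goal a [goal_spec()]; must be reachable from the initial state.
#' @param entity entity automaton id.
#' @param budget state budget per query.
#' @return \code{"relies"}, \code{"does-not-rely"} or \code{"unknown"}
#'   (budget exhaustion).
#' @export
trajectory_reliance <- function(an, present, goal, entity, budget = 5e6) {
  if (!entity %in% an$ids[an$kind == "entity"])
    stop("unknown entity: ", entity)
  init <- initial_state(an, present)
  base <- reachable(an, init, goal, budget)
  if (base$verdict != "reachable")
    stop("goal must be reachable from the initial state (got: ",
         base$verdict, ")")
  if (init[[entity]] == 1L) return("relies")
  staged <- sequence_reachable(an, init,
                               list(goal_spec(present = entity), goal),
                               budget)
  switch(staged$verdict,
         reachable = "relies",
         unreachable = "does-not-rely",
         "unknown")
}
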