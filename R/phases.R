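## Phase-marker bookkeeping and progression validation.
##
## A cycle is an ordered (cyclic) list of phases; each phase carries one or
## more marker entities.  The model is "in" a phase when at least one marker
## of that phase is present and all markers of all other phases of the same
## cycle are absent.  Progression is validated with three analyses per
## precursor state: (A) individual marker reachability, (B) phase
## reachability, (C) phase reachability with the directly preceding phase
## disabled, plus reachability of the repeated cyclic phase sequence.

#' Phase marker
#' @param text marker entity in the textual grammar of [parse_entity_text()].
#' @param compartment compartment label, or \code{NULL}.
#' @return an object of class \code{phase_marker}.
#' @export
marker <- function(text, compartment = NULL) {
  structure(list(text = as.character(text), compartment = compartment,
                 entity = parse_entity_text(text, compartment)),
            class = "phase_marker")
}

#' Phase of a cycle
#' @param name phase name.
#' @param markers non-empty list of [marker()] objects.
#' @return an object of class \code{cycle_phase}.
#' @export
phase <- function(name, markers) {
  if (!length(markers)) stop("a phase needs at least one marker")
  structure(list(name = as.character(name), markers = markers),
            class = "cycle_phase")
}

#' Cycle specification
#'
#' @param name cycle name.
#' @param phases ordered list of [phase()] objects (cyclic order).  Marker
#'   texts must be disjoint across phases.
#' @return an object of class \code{cycle_spec}.
#' @export
cycle_spec <- function(name, phases) {
  if (!length(phases)) stop("a cycle needs at least one phase")
  texts <- unlist(lapply(phases, function(p)
    vapply(p$markers, function(m) m$text, "")))
  if (anyDuplicated(texts))
    stop("marker shared across phases: ",
         paste(unique(texts[duplicated(texts)]), collapse = ", "))
  structure(list(name = as.character(name), phases = phases),
            class = "cycle_spec")
}

marker_id <- function(map, m) {
  hit <- find_entity(map, m$entity, fuzzy = FALSE)
  if (is.null(hit))
    stop("marker does not resolve in the map: ", m$text,
         if (!is.null(m$compartment)) paste0(" [", m$compartment, "]") else "")
  an_entity_ids(map)[[entity_key(hit)]]
}

cycle_marker_ids <- function(map, cycle) {
  lapply(cycle$phases, function(p) vapply(p$markers, marker_id, "", map = map))
}

#' Goal for being in a phase via one of its markers
#'
#' Requires the marker's entity present and all markers of all other phases
#' of the same cycle absent.
#'
#' @param map the \code{pd_map} the markers resolve against.
#' @param cycle a [cycle_spec()].
#' @param phase_name name of the phase the marker belongs to.
#' @param m a [marker()] of that phase (or its text).
#' @return a [goal_spec()].
#' @export
phase_goal <- function(map, cycle, phase_name, m) {
  pn <- vapply(cycle$phases, function(p) p$name, "")
  pi <- match(phase_name, pn)
  if (is.na(pi)) stop("unknown phase: ", phase_name)
  ph <- cycle$phases[[pi]]
  if (is.character(m)) {
    mi <- match(m, vapply(ph$markers, function(x) x$text, ""))
    if (is.na(mi)) stop("marker ", m, " not in phase ", phase_name)
    m <- ph$markers[[mi]]
  }
  present <- marker_id(map, m)
  others <- unlist(lapply(cycle$phases[-pi], function(p)
    vapply(p$markers, marker_id, "", map = map)))
  goal_spec(present = present, absent = others)
}

# disjunctive per-phase goals for the sequence search
phase_any_goals <- function(map, cycle, pi) {
  lapply(cycle$phases[[pi]]$markers, function(m)
    phase_goal(map, cycle, cycle$phases[[pi]]$name, m))
}

# sequence search where each element is a disjunction of goal_specs
sequence_reachable_any <- function(an, init, goal_groups, budget = 5e6) {
  s0 <- as.integer(init[an$ids])
  if (!length(goal_groups))
    return(list(verdict = "reachable", n_visited = 1L))
  frontier <- list(s0)
  spent <- 0L
  for (grp in goal_groups) {
    gis <- lapply(grp, goal_idx, an = an)
    sat <- function(s) { for (gi in gis) if (goal_sat(gi, s)) return(TRUE); FALSE }
    res <- bfs_search(an, frontier, sat, budget - spent, stop_first = FALSE)
    spent <- spent + res$n_visited
    if (res$verdict == "budget-exceeded")
      return(list(verdict = "budget-exceeded", n_visited = spent))
    if (!length(res$hits))
      return(list(verdict = "unreachable", n_visited = spent))
    frontier <- lapply(res$hits, function(i) res$states[[i]])
  }
  list(verdict = "reachable", n_visited = spent)
}

#' Seeded random-walk reachability probe
#'
#' Non-exhaustive fallback for goals whose exact exploration exceeds the
#' state budget: repeated random walks from \code{init}.  Can only return
#' \code{"reachable"} (a walk hit the goal) or \code{"unknown"} — absence of
#' a hit proves nothing.
#'
#' @inheritParams reachable
#' @param steps walk length.
#' @param restarts number of independent walks.
#' @param seed integer seed.
#' @return list with \code{verdict} (\code{"reachable"} or \code{"unknown"})
#'   and \code{exhaustive = FALSE}.
#' @export
random_walk_reach <- function(an, init, goal, steps = 1000L, restarts = 20L,
                              seed = 1L) {
  gi <- goal_idx(an, goal)
  s0 <- as.integer(init[an$ids])
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      s <- s0
      for (i in seq_len(steps)) {
        if (goal_sat(gi, s))
          return(list(verdict = "reachable", exhaustive = FALSE))
        en <- enabled_rules(an, s)
        if (!length(en)) break
        rule <- an$rules[[en[sample.int(length(en), 1L)]]]
        s[rule$aut] <- rule$to
      }
      if (goal_sat(gi, s))
        return(list(verdict = "reachable", exhaustive = FALSE))
    }
    list(verdict = "unknown", exhaustive = FALSE)
  })
}

verdict3 <- function(v) switch(v, reachable = TRUE, unreachable = FALSE, NA)

#' Validate phase progression of a cycle
#'
#' For each precursor state: (A) reachability of every individual marker;
#' (B) reachability of every phase (a phase is reachable iff the goal of at
#' least one of its markers is reachable); (C) analysis B re-run with all
#' markers of the directly preceding phase disabled; and reachability of the
#' cyclic phase sequence repeated \code{repeats} times.  Budget-exceeded
#' verdicts are reported as \code{NA} ("unknown"), never as \code{FALSE}.
#'
#' @param an the \code{automata_network} translated from \code{map}.
#' @param map the source \code{pd_map} (used to resolve markers).
#' @param precursors list of character vectors of entity automaton ids (one
#'   per precursor state).
#' @param cycle a [cycle_spec()].
#' @param repeats number of times the phase sequence must repeat (default 4).
#' @param budget state budget per reachability query.
#' @return an object of class \code{progression_report}: a list with one
#'   element per precursor state, each containing data frames \code{A},
#'   \code{B}, \code{C} and the \code{sequence} verdict.
#' @export
validate_progression <- function(an, map, precursors, cycle, repeats = 4L,
                                 budget = 5e6) {
  stopifnot(inherits(cycle, "cycle_spec"))
  if (is.character(precursors)) precursors <- list(precursors)
  ids_per_phase <- cycle_marker_ids(map, cycle)  # errors early if unresolvable
  pn <- vapply(cycle$phases, function(p) p$name, "")
  np <- length(pn)
  out <- lapply(precursors, function(pre) {
    init <- initial_state(an, pre)
    A <- do.call(rbind, lapply(seq_len(np), function(pi) {
      sapply_df(cycle$phases[[pi]]$markers, function(m) {
        r <- reachable(an, init, goal_spec(present = marker_id(map, m)),
                       budget)
        data.frame(phase = pn[pi], marker = m$text,
                   reachable = verdict3(r$verdict))
      })
    }))
    phase_B <- function(an2, init2, pi) {
      verdicts <- vapply(phase_any_goals(map, cycle, pi), function(g) {
        reachable(an2, init2, g, budget)$verdict
      }, "")
      if (any(verdicts == "reachable")) TRUE
      else if (all(verdicts == "unreachable")) FALSE
      else NA
    }
    B <- data.frame(phase = pn,
                    reachable = vapply(seq_len(np), function(pi)
                      phase_B(an, init, pi), NA))
    C <- do.call(rbind, lapply(seq_len(np), function(pi) {
      prev <- if (pi == 1L) np else pi - 1L
      an2 <- disable_markers(an, ids_per_phase[[prev]])
      init2 <- initial_state(an2, setdiff(pre, ids_per_phase[[prev]]))
      data.frame(phase = pn[pi], disabled = pn[prev],
                 reachable = phase_B(an2, init2, pi))
    }))
    seq_verdict <- if (repeats == 0L) TRUE else {
      groups <- lapply(rep(seq_len(np), repeats), function(pi)
        phase_any_goals(map, cycle, pi))
      verdict3(sequence_reachable_any(an, init, groups, budget)$verdict)
    }
    list(precursor = pre, A = A, B = B, C = C, sequence = seq_verdict)
  })
  structure(list(cycle = cycle$name, repeats = repeats, results = out),
            class = "progression_report")
}

sapply_df <- function(xs, f) do.call(rbind, lapply(xs, f))

#' @export
print.progression_report <- function(x, ...) {
  cat("Progression report for cycle '", x$cycle, "' (", length(x$results),
      " precursor state(s), ", x$repeats, " repeats)\n", sep = "")
  for (i in seq_along(x$results)) {
    r <- x$results[[i]]
    cat("\nPrecursor", i, ":", paste(r$precursor, collapse = ", "), "\n")
    agg <- stats::aggregate(reachable ~ phase, r$A,
                            function(v) sprintf("%d/%d", sum(v %in% TRUE),
                                                length(v)))
    cat("(A) markers reachable: ",
        paste(agg$phase, agg$reachable, collapse = "; "), "\n")
    cat("(B) phases reachable: ",
        paste(r$B$phase, ifelse(is.na(r$B$reachable), "unknown",
                                r$B$reachable), collapse = "; "), "\n")
    cat("(C) with predecessor disabled: ",
        paste(sprintf("%s(-%s)=%s", r$C$phase, r$C$disabled,
                      ifelse(is.na(r$C$reachable), "unknown",
                             r$C$reachable)), collapse = "; "), "\n")
    cat("sequence x", x$repeats, ": ",
        if (is.na(r$sequence)) "unknown" else r$sequence, "\n", sep = "")
  }
  invisible(x)
}

#' Convert a progression report to a data frame
#' @param x a \code{progression_report}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a long-format data frame (precursor, analysis, phase, marker,
#'   disabled, reachable).
#' @export
as.data.frame.progression_report <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x$results), function(i) {
    r <- x$results[[i]]
    rbind(
      data.frame(precursor = i, analysis = "A", phase = r$A$phase,
                 marker = r$A$marker, disabled = NA,
                 reachable = r$A$reachable),
      data.frame(precursor = i, analysis = "B", phase = r$B$phase,
                 marker = NA, disabled = NA, reachable = r$B$reachable),
      data.frame(precursor = i, analysis = "C", phase = r$C$phase,
                 marker = NA, disabled = r$C$disabled,
                 reachable = r$C$reachable),
      data.frame(precursor = i, analysis = "sequence", phase = NA, marker = NA,
                 disabled = NA, reachable = r$sequence))
  }))
}

## ---- packaged marker tables -------------------------------------------------

read_marker_table <- function(file, name) {
  path <- system.file("extdata", file, package = "sbgndyn", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  phases <- lapply(unique(tab$phase), function(ph) {
    rows <- tab[tab$phase == ph, , drop = FALSE]
    phase(ph, lapply(seq_len(nrow(rows)), function(i)
      marker(rows$marker[i], rows$compartment[i])))
  })
  cycle_spec(name, phases)
}

#' Packaged phase-marker table of the mammalian cell cycle
#'
#' Six phases (early G1, late G1, early S, late S, G2, M) with their marker
#' complexes and compartments, in the textual grammar of
#' [parse_entity_text()].
#'
#' @return a \code{cycle_spec}.
#' @export
cell_cycle_phases <- function() {
  read_marker_table("cell_cycle_markers.tsv", "cell-cycle")
}

#' Packaged phase-marker table of the circadian clock
#'
#' Four phases named after activity peaks of core clock entities: RORG,
#' SIRT1, ARNTL-CLOCK and PER-CRY.
#'
#' @return a \code{cycle_spec}.
#' @export
circadian_clock_phases <- function() {
  read_marker_table("circadian_clock_markers.tsv", "circadian-clock")
}
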