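# Independent brute-force interpreter of the permissive qualitative
# semantics.  It re-derives enabled state changes directly from the PD map
# (firing condition, product completion, production, consumption) without
# going through the package's translated rule objects, and serves as the
# oracle the engine is checked against.  States are named 0/1 vectors using
# the same automaton naming as translate() (naming shared, dynamics not).

oracle_naming <- function(map) {
  an <- translate(map)
  prov <- an$provenance
  ent_ids <- an$ids[an$kind == "entity"]
  key_of <- vapply(ent_ids, function(id) prov[[id]]$key, "")
  proc_ids <- an$ids[an$kind == "process"]
  pid_of <- vapply(proc_ids, function(id) prov[[id]]$id, "")
  key2id <- setNames(ent_ids, key_of)
  # static structure (which process consumes/produces which entity) is
  # precomputed; the firing/update conditions are re-evaluated per state
  rkeys <- lapply(map$processes, function(p)
    unique(vapply(p$reactants, entity_key, "")))
  pkeys <- lapply(map$processes, function(p)
    unique(vapply(p$products, entity_key, "")))
  prod_ids <- lapply(pkeys, function(ks) unname(key2id[intersect(ks, key_of)]))
  producers_of <- lapply(key_of, function(k)
    proc_ids[vapply(pid_of, function(pid) k %in% pkeys[[pid]], FALSE)])
  consumers_of <- lapply(key_of, function(k)
    proc_ids[vapply(pid_of, function(pid) k %in% rkeys[[pid]], FALSE)])
  names(producers_of) <- names(consumers_of) <- ent_ids
  list(ids = an$ids, ent_ids = ent_ids, key2id = key2id,
       proc_ids = proc_ids, pid_of = setNames(pid_of, proc_ids),
       prod_ids = prod_ids, producers_of = producers_of,
       consumers_of = consumers_of)
}

oracle_mod_active <- function(src, state, key2id) {
  if (inherits(src, "sbgn_logic")) {
    vals <- vapply(src$children, oracle_mod_active, FALSE,
                   state = state, key2id = key2id)
    switch(src$operator, AND = all(vals), OR = any(vals), NOT = !vals[1])
  } else state[[key2id[[entity_key(src)]]]] == 1
}

# firing condition of the permissive interpretation, re-derived
oracle_can_fire <- function(map, p, state, key2id) {
  for (r in p$reactants) {
    id <- key2id[entity_key(r)]
    if (!is.na(id) && state[[id]] != 1) return(FALSE)
  }
  mods <- Filter(function(m) identical(m$target, p$id), map$modulations)
  plain <- logical()
  for (m in mods) {
    act <- oracle_mod_active(m$source, state, key2id)
    if (m$mod_class == "necessary-stimulation" && !act) return(FALSE)
    if (m$mod_class == "absolute-inhibition" && act) return(FALSE)
    if (m$mod_class == "inhibition") plain <- c(plain, !act)
    if (m$mod_class %in% c("stimulation", "catalysis", "modulation"))
      plain <- c(plain, act)
  }
  !length(plain) || any(plain)
}

# all asynchronous successors of a named state; clamps: named 0/1 vector of
# automata whose value may never change (mutations)
oracle_successors <- function(map, state, naming = oracle_naming(map),
                              clamps = integer()) {
  key2id <- naming$key2id
  succ <- list()
  flip <- function(id, v) {
    if (id %in% names(clamps)) return()
    s2 <- state; s2[[id]] <- v
    succ[[length(succ) + 1L]] <<- s2
  }
  prods_present <- function(pid) {
    ids <- naming$prod_ids[[pid]]
    !length(ids) || all(state[ids] == 1)
  }
  for (aid in naming$proc_ids) {
    pid <- naming$pid_of[[aid]]
    p <- map$processes[[pid]]
    if (state[[aid]] == 0 && oracle_can_fire(map, p, state, key2id))
      flip(aid, 1L)
    if (state[[aid]] == 1 && prods_present(pid))
      flip(aid, 0L)
  }
  for (eid in naming$ent_ids) {
    prod_auts <- naming$producers_of[[eid]]
    cons_auts <- naming$consumers_of[[eid]]
    if (state[[eid]] == 0 && length(prod_auts) && any(state[prod_auts] == 1))
      flip(eid, 1L)
    if (state[[eid]] == 1 && length(cons_auts) &&
        any(vapply(cons_auts, function(aid)
          state[[aid]] == 1 && prods_present(naming$pid_of[[aid]]), FALSE)))
      flip(eid, 0L)
  }
  succ
}

state_label <- function(s) paste(s, collapse = "")

# full reachable state set by oracle BFS (index-based queue)
oracle_reach_set <- function(map, init, naming = oracle_naming(map),
                             clamps = integer()) {
  seen <- new.env(parent = emptyenv())
  states <- vector("list", 256L)
  states[[1L]] <- init
  n <- 1L
  seen[[state_label(init)]] <- TRUE
  head <- 1L
  while (head <= n) {
    s <- states[[head]]
    for (s2 in oracle_successors(map, s, naming, clamps)) {
      k <- state_label(s2)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        n <- n + 1L
        if (n > length(states)) length(states) <- 2L * length(states)
        states[[n]] <- s2
      }
    }
    head <- head + 1L
  }
  states[seq_len(n)]
}

# all entity ids presentable somewhere in the oracle's reachable set
oracle_reachable_entities <- function(map, present,
                                      naming = oracle_naming(map),
                                      clamps = integer()) {
  init <- setNames(integer(length(naming$ids)), naming$ids)
  init[present] <- 1L
  init[names(clamps)] <- clamps
  rs <- oracle_reach_set(map, init, naming, clamps)
  hit <- Reduce(`|`, lapply(rs, function(s) s[naming$ent_ids] == 1))
  naming$ent_ids[hit]
}

oracle_entity_reachable <- function(map, present, entity,
                                    naming = oracle_naming(map)) {
  entity %in% oracle_reachable_entities(map, present, naming)
}

all_states <- function(n) {
  if (n == 0) return(list(integer()))
  lapply(0:(2^n - 1), function(mask)
    as.integer(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0))
}

# independent producibility fixpoint on entity keys
oracle_closure <- function(map, seed_ids, naming = oracle_naming(map)) {
  have <- naming$ent_ids %in% seed_ids
  names(have) <- names(naming$key2id)
  repeat {
    changed <- FALSE
    for (p in map$processes) {
      rk <- intersect(vapply(p$reactants, entity_key, ""), names(have))
      pk <- intersect(vapply(p$products, entity_key, ""), names(have))
      if (all(have[rk]) && !all(have[pk])) { have[pk] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  unname(naming$key2id[names(have)[have]])
}

# exhaustive precursor enumeration (all subsets, lexicographic filter)
oracle_precursors <- function(map, required = character(),
                              objectives = c("min-cardinality",
                                             "min-state-variables",
                                             "min-complexes")) {
  naming <- oracle_naming(map)
  ids <- naming$ent_ids
  n <- length(ids)
  stopifnot(n <= 15)
  keyed <- setNames(names(naming$key2id), naming$key2id)
  n_sv <- function(e) {
    sum(vapply(e$state_variables, function(s) nzchar(s$value), FALSE)) +
      sum(vapply(e$subunits, n_sv, 0))
  }
  score <- function(sol) {
    ents <- lapply(keyed[sol], function(k) map$entities[[k]])
    vapply(objectives, function(ob) switch(ob,
      "min-cardinality" = length(sol),
      "min-state-variables" = sum(vapply(ents, n_sv, 0)),
      "min-complexes" = sum(vapply(ents, function(e)
        e$epn_class == "complex", FALSE))), 0)
  }
  feas <- list()
  for (mask in 0:(2^n - 1)) {
    sol <- sort(ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
    if (!all(required %in% sol)) next
    if (length(oracle_closure(map, sol, naming)) == n)
      feas[[length(feas) + 1L]] <- sol
  }
  scores <- lapply(feas, score)
  best <- seq_along(feas)
  for (j in seq_along(objectives)) {
    vals <- vapply(scores[best], `[`, 0, j)
    best <- best[vals == min(vals)]
  }
  out <- feas[best]
  out[order(vapply(out, paste, "", collapse = "\x01"), method = "radix")]
}

# small random-map corpus shared by the property suites
corpus_params <- function(seeds, n_entities = 4, n_processes = 4)
  lapply(seeds, function(s)
    generator_params(n_entities, n_processes, modulation_density = 1,
                     frac_necessary = 0.2, frac_inhibition = 0.3, seed = s))
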