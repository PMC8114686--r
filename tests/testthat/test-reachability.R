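test_that("initial states present the listed entities and switch every process off", {
  an <- translate(make_nad_motif())
  s <- initial_state(an, c("NMN", "NMNAT"))
  expect_equal(sum(s), 2)
  expect_true(all(s[c("NMN", "NMNAT")] == 1))
  expect_true(all(s[an$ids[an$kind == "process"]] == 0))
  expect_equal(sum(initial_state(an)), 0)
  expect_error(initial_state(an, "NOPE"), "unknown entity")
  expect_error(initial_state(an, "p1"), "unknown entity")  # processes refused
})

test_that("BFS verdicts match the fixture dynamics, with minimal witnesses", {
  an <- translate(make_toy_clock())
  r <- reachable(an, initial_state(an), goal_spec(present = "B"), 1e5)
  expect_equal(r$verdict, "reachable")
  # goal already satisfied at init: length-1 witness
  r0 <- reachable(an, initial_state(an, "A"), goal_spec(present = "A"), 1e5)
  expect_equal(length(r0$trajectory), 1)

  ann <- translate(make_nad_motif())
  expect_equal(reachable(ann, initial_state(ann, c("NAM", "NMNAT")),
                         goal_spec(present = "M"), 1e6)$verdict, "unreachable")
  expect_equal(reachable(ann, initial_state(ann, c("NMN", "NMNAT")),
                         goal_spec(present = "M"), 1e6)$verdict, "reachable")
  # witness states are consecutive under step()
  tr <- reachable(ann, initial_state(ann, c("NMN", "NMNAT")),
                  goal_spec(present = "M"), 1e6)$trajectory
  for (i in seq_len(length(tr) - 1)) {
    succs <- vapply(step(ann, tr[[i]]), state_label, "")
    expect_true(state_label(tr[[i + 1]]) %in% succs)
  }
})

test_that("budget exhaustion is a distinct verdict, never reported as unreachable", {
  an <- translate(make_toy_coupled())
  r <- reachable(an, initial_state(an), goal_spec(present = "X3"), budget = 3)
  expect_equal(r$verdict, "budget-exceeded")
  expect_null(r$trajectory)
})

test_that("reachable agrees with the oracle's full state-graph on every init of small maps", {
  maps <- c(list(make_toy_clock(), make_nad_motif()),
            lapply(corpus_params(21:26), random_map))
  maps <- Filter(function(m) length(translate(m)$ids) <= 12, maps)
  expect_gte(length(maps), 5)
  for (m in maps) {
    an <- translate(m)
    naming <- oracle_naming(m)
    ents <- an$ids[an$kind == "entity"]
    # a handful of seeded initial entity subsets per map
    set.seed(7)
    inits <- unique(c(list(character()),
                      replicate(4, sample(ents, sample(0:length(ents), 1)),
                                simplify = FALSE)))
    for (init in inits) {
      want <- oracle_reachable_entities(m, init, naming)
      for (target in ents) {
        got <- reachable(an, initial_state(an, init),
                         goal_spec(present = target), 1e6)$verdict
        expect_identical(got == "reachable", target %in% want)
      }
    }
  }
})

test_that("every state visited by a seeded random walk is BFS-reachable", {
  m <- make_toy_coupled()
  an <- translate(m)
  init <- initial_state(an)
  res <- sbgndyn:::bfs_search(an, list(as.integer(init)),
                              function(s) FALSE, 1e6, stop_first = FALSE)
  seen <- vapply(seq_len(res$n_visited), function(i)
    state_label(res$states[[i]]), "")
  set.seed(99)
  s <- as.integer(init)
  for (i in 1:300) {
    en <- sbgndyn:::enabled_rules(an, s)
    if (!length(en)) break
    r <- an$rules[[en[sample.int(length(en), 1)]]]
    s[r$aut] <- r$to
    expect_true(state_label(s) %in% seen)
  }
})

test_that("mutations edit rules and initial states as declared", {
  an <- translate(make_toy_clock())
  lof <- apply_mutations(an, an_mutation("A", "LoF"))
  a_i <- match("A", an$ids)
  expect_false(any(vapply(lof$rules, function(r)
    r$aut == a_i && r$from == 0, FALSE)))
  expect_error(initial_state(lof, "A"), "LoF")
  gof <- apply_mutations(an, an_mutation("B", "GoF"))
  expect_false(any(vapply(gof$rules, function(r)
    r$aut == match("B", an$ids) && r$from == 1, FALSE)))
  expect_equal(unname(initial_state(gof)["B"]), 1L)
  # under GoF(B) the inhibited source process of A can never switch on
  expect_equal(reachable(gof, initial_state(gof), goal_spec(present = "A"),
                         1e5)$verdict, "unreachable")
  expect_error(apply_mutations(an, list(an_mutation("A", "LoF"),
                                        an_mutation("A", "GoF"))),
               "conflicting")
  # empty mutation set is the identity
  expect_identical(apply_mutations(an, list()), an)
})

test_that("disabling markers makes them permanently unreachable", {
  an <- translate(make_toy_clock())
  d <- disable_markers(an, "B")
  expect_equal(reachable(d, initial_state(d), goal_spec(present = "B"),
                         1e5)$verdict, "unreachable")
  expect_identical(disable_markers(an, character()), an)
})

test_that("mutated reachable sets shrink monotonically with more mutations", {
  m <- make_toy_coupled()
  an <- translate(m)
  r1 <- reachable(apply_mutations(an, an_mutation("W", "LoF")),
                  initial_state(apply_mutations(an, an_mutation("W", "LoF"))),
                  goal_spec(present = "X2"), 1e6)
  r2an <- apply_mutations(an, list(an_mutation("W", "LoF"),
                                   an_mutation("X1", "LoF")))
  r2 <- reachable(r2an, initial_state(r2an), goal_spec(present = "X2"), 1e6)
  expect_equal(r1$verdict, "reachable")
  expect_equal(r2$verdict, "unreachable")
})

test_that("phase sequences are reachable exactly when a layered trajectory exists", {
  m <- make_toy_clock()
  an <- translate(m)
  p1 <- goal_spec(present = "A", absent = "B")
  p2 <- goal_spec(present = "B", absent = "A")
  goals <- rep(list(p1, p2), 4)
  res <- sequence_reachable(an, initial_state(an), goals, 1e6)
  expect_equal(res$verdict, "reachable")
  # the witness satisfies the goals in order
  gi <- lapply(goals, sbgndyn:::goal_idx, an = an)
  pos <- 1L
  for (g in gi) {
    while (pos <= length(res$trajectory) &&
           !sbgndyn:::goal_sat(g, as.integer(res$trajectory[[pos]])))
      pos <- pos + 1L
    expect_lte(pos, length(res$trajectory))
  }
  # empty goal list is trivially reachable; LoF(A) kills the sequence
  expect_equal(sequence_reachable(an, initial_state(an), list(), 10)$verdict,
               "reachable")
  anl <- apply_mutations(an, an_mutation("A", "LoF"))
  expect_equal(sequence_reachable(anl, initial_state(anl), list(p1),
                                  1e6)$verdict, "unreachable")
})

test_that("the producibility closure is computed exactly on the metabolic motif", {
  nm <- make_nad_motif()
  expect_setequal(unreachability_overapprox(nm), c("M", "NAMPT"))
  expect_setequal(unreachability_overapprox(nm, c("NAM", "NMNAT")),
                  c("NAM", "NMN", "NAD", "NMNAT", "NAMPT", "M"))
  # seeding everything is a fixpoint; monotone in the seed
  all_ids <- sbgndyn:::an_entity_ids(nm)
  expect_setequal(unreachability_overapprox(nm, unname(all_ids)),
                  unname(all_ids))
  small <- unreachability_overapprox(nm, "NMN")
  big <- unreachability_overapprox(nm, c("NMN", "NAM"))
  expect_true(all(small %in% big))
})

test_that("the closure soundly over-approximates BFS-reachable entities", {
  maps <- c(list(make_toy_clock(), make_nad_motif(), make_toy_coupled()),
            lapply(corpus_params(31:40), random_map))
  for (m in maps) {
    an <- translate(m)
    ents <- an$ids[an$kind == "entity"]
    set.seed(5)
    init <- sample(ents, min(2, length(ents)))
    cl <- unreachability_overapprox(m, init)
    for (target in ents) {
      if (reachable(an, initial_state(an, init), goal_spec(present = target),
                    1e6)$verdict == "reachable")
        expect_true(target %in% cl)
    }
  }
})
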