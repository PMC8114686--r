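test_that("the coupled-map screen finds exactly the three size-1 blockers of X3", {
  an <- translate(make_toy_coupled())
  sets <- blocking_mutations(an, character(), goal_spec(present = "X3"),
                             max_size = 1, candidates = c("A", "B", "W"),
                             budget = 1e6)
  labels <- vapply(sets, sbgndyn:::mutation_set_label, "")
  expect_setequal(labels, c("LoF(A)", "GoF(B)", "LoF(W)"))
})

test_that("a single upstream LoF blocks the toy-clock target and max_size 0 yields nothing", {
  an <- translate(make_toy_clock())
  sets <- blocking_mutations(an, character(), goal_spec(present = "B"),
                             max_size = 1, candidates = "A", budget = 1e5)
  expect_length(sets, 1)
  expect_equal(sbgndyn:::mutation_set_label(sets[[1]]), "LoF(A)")
  expect_length(blocking_mutations(an, character(), goal_spec(present = "B"),
                                   max_size = 0, candidates = "A",
                                   budget = 1e5), 0)
  expect_error(blocking_mutations(an, character(), goal_spec(present = "ZZ"),
                                  1, "A", 1e5), "not entity automata|unknown")
})

test_that("screening a goal that is already unreachable is refused", {
  an <- translate(make_nad_motif())
  expect_error(blocking_mutations(an, c("NAM", "NMNAT"),
                                  goal_spec(present = "M"), 1,
                                  c("NAD"), 1e6),
               "unreachable before any mutation")
})

test_that("every reported blocking set blocks under the independent oracle, and no non-blocker is reported", {
  m <- make_toy_coupled()
  an <- translate(m)
  naming <- oracle_naming(m)
  cands <- c("A", "B", "W")
  sets <- blocking_mutations(an, character(), goal_spec(present = "X3"),
                             max_size = 1, candidates = cands, budget = 1e6)
  reported <- vapply(sets, sbgndyn:::mutation_set_label, "")
  for (e in cands) for (kind in c("LoF", "GoF")) {
    clamps <- stats::setNames(if (kind == "LoF") 0L else 1L, e)
    blocked <- !("X3" %in% oracle_reachable_entities(m, character(), naming,
                                                     clamps))
    lab <- paste0(kind, "(", e, ")")
    expect_identical(lab %in% reported, blocked)
  }
})

test_that("reported sets are subset-minimal and supersets of blockers still block", {
  an <- translate(make_toy_coupled())
  sets <- blocking_mutations(an, character(), goal_spec(present = "X3"),
                             max_size = 2, candidates = c("A", "B", "W"),
                             budget = 1e6)
  labs <- lapply(sets, function(ms)
    sort(vapply(ms, function(m) paste0(m$kind, m$entity), "")))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i != j) expect_false(all(labs[[i]] %in% labs[[j]]))
  }
  # a superset of a found blocker (not itself reported) still blocks
  an2 <- apply_mutations(an, list(an_mutation("W", "LoF"),
                                  an_mutation("X1", "LoF")))
  expect_equal(reachable(an2, initial_state(an2), goal_spec(present = "X3"),
                         1e6)$verdict, "unreachable")
})

test_that("control summaries group blocking entities per marker with provenance tags", {
  an <- translate(make_toy_coupled())
  sets <- blocking_mutations(an, character(), goal_spec(present = "X3"),
                             max_size = 1, candidates = c("A", "B", "W"),
                             budget = 1e6)
  part <- attr(make_toy_coupled(), "provenance")
  rep <- control_summary(list(X3 = sets), part)
  expect_s3_class(rep, "data.frame")
  clock_side <- rep[rep$source == "clock", ]
  expect_setequal(paste(clock_side$entity, clock_side$kind),
                  c("A LoF", "B GoF"))
  # empty input and deduplication
  expect_equal(nrow(control_summary(list())), 0)
  dup <- control_summary(list(X3 = c(sets, sets)), part)
  expect_equal(nrow(dup), nrow(rep))
})

test_that("trajectory reliance distinguishes necessary, possible and initial entities", {
  nm <- make_nad_motif()
  ann <- translate(nm)
  # every route to M passes through NAD
  expect_equal(trajectory_reliance(ann, c("NMN", "NMNAT"),
                                   goal_spec(present = "M"), "NAD", 1e6),
               "relies")
  # B is not needed for A but can be produced en route: existential reliance
  an <- translate(make_toy_clock())
  expect_equal(trajectory_reliance(an, character(), goal_spec(present = "A"),
                                   "B", 1e6), "relies")
  # an entity present at init relies trivially
  expect_equal(trajectory_reliance(ann, c("NMN", "NMNAT"),
                                   goal_spec(present = "M"), "NMNAT", 1e6),
               "relies")
  # an entity that can never be present before the goal does not
  anl <- apply_mutations(an, an_mutation("B", "LoF"))
  expect_equal(trajectory_reliance(anl, character(), goal_spec(present = "A"),
                                   "B", 1e6), "does-not-rely")
  # unreachable goals are a precondition error
  expect_error(trajectory_reliance(ann, c("NAM", "NMNAT"),
                                   goal_spec(present = "M"), "NAD", 1e6),
               "must be reachable")
})
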