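test_that("phase goals demand the marker present and all other phases' markers absent", {
  m <- make_toy_clock()
  cyc <- toy_clock_phases()
  g <- phase_goal(m, cyc, "P1", "A")
  expect_equal(g$present, "A")
  expect_equal(g$absent, "B")
  # two-phase cycle with one marker each: a single absent entity
  expect_length(phase_goal(m, cyc, "P2", "B")$absent, 1)
  expect_error(phase_goal(m, cyc, "P3", "A"), "unknown phase")
  expect_error(phase_goal(m, cyc, "P1", "B"), "not in phase")
})

test_that("packaged marker tables parse, stay disjoint, and carry the expected phases", {
  cc <- cell_cycle_phases()
  expect_equal(vapply(cc$phases, function(p) p$name, ""),
               c("early G1", "late G1", "early S", "late S", "G2", "M"))
  expect_equal(vapply(cc$phases, function(p) length(p$markers), 0L),
               c(5L, 2L, 1L, 1L, 4L, 4L))
  ck <- circadian_clock_phases()
  expect_equal(vapply(ck$phases, function(p) p$name, ""),
               c("RORG", "SIRT1", "ARNTL-CLOCK", "PER-CRY"))
  # the SIRT1 phase goal must exclude the three other phases' markers;
  # check against a map carrying all four clock markers
  m <- pd_map("Nucleoplasm")
  for (ph in ck$phases)
    for (mk in ph$markers)
      m <- add_entity(m, mk$entity)
  g <- phase_goal(m, ck, "SIRT1", ck$phases[[2]]$markers[[1]])
  expect_length(g$absent, 3)
  # disjointness is enforced at construction
  expect_error(cycle_spec("bad", list(phase("x", list(marker("A"))),
                                      phase("y", list(marker("A"))))),
               "shared across phases")
})

test_that("unresolvable markers fail validation before any model checking", {
  m <- make_toy_clock()
  an <- translate(m)
  badcycle <- cycle_spec("bad", list(phase("P1", list(marker("NOT_THERE")))))
  expect_error(validate_progression(an, m, list(character()), badcycle),
               "does not resolve")
})

test_that("progression analysis reproduces the toy-clock A/B/C pattern and 4-repeat cycle", {
  m <- make_toy_clock()
  an <- translate(m)
  rep <- validate_progression(an, m, list(character()), toy_clock_phases(),
                              repeats = 4, budget = 1e6)
  r <- rep$results[[1]]
  expect_true(all(r$A$reachable))                       # A: 2/2
  expect_true(all(r$B$reachable))                       # B: both phases
  cP1 <- r$C[r$C$phase == "P1", ]
  cP2 <- r$C[r$C$phase == "P2", ]
  expect_true(cP1$reachable)                            # P1 without P2 first
  expect_false(cP2$reachable)                           # P2 needs P1
  expect_true(r$sequence)
  # C implies B: anything reachable under disabling is reachable without
  expect_true(all(!r$C$reachable | r$B$reachable[match(r$C$phase, r$B$phase)]))
  # repeats = 0 is vacuously true
  rep0 <- validate_progression(an, m, list(character()), toy_clock_phases(),
                               repeats = 0, budget = 1e6)
  expect_true(rep0$results[[1]]$sequence)
})

test_that("the metabolic dichotomy shows up as 0/1 vs 1/1 marker reachability", {
  nm <- make_nad_motif()
  ann <- translate(nm)
  mcycle <- cycle_spec("metab", list(phase("Mphase", list(marker("M", "cell")))))
  rep <- validate_progression(ann, nm,
                              list(c("NAM", "NMNAT"), c("NMN", "NMNAT")),
                              mcycle, repeats = 0, budget = 1e6)
  expect_false(rep$results[[1]]$A$reachable)   # NAM precursor: 0/1
  expect_true(rep$results[[2]]$A$reachable)    # NMN precursor: 1/1
})

test_that("on the coupled map a phase whose only route consumes its predecessor flips under disabling", {
  tc <- make_toy_coupled()
  antc <- translate(tc)
  rep <- validate_progression(antc, tc, list(character()),
                              toy_coupled_phases(), repeats = 1,
                              budget = 1e6)
  r <- rep$results[[1]]
  expect_true(all(r$B$reachable))
  c2 <- r$C[r$C$phase == "C2", ]
  expect_equal(c2$disabled, "C1")
  expect_false(c2$reachable)       # X2 only comes from X1
  c3 <- r$C[r$C$phase == "C3", ]
  expect_false(c3$reachable)       # X3 only comes from X2
})

test_that("progression reports convert to a long data frame and print", {
  m <- make_toy_clock()
  an <- translate(m)
  rep <- validate_progression(an, m, list(character()), toy_clock_phases(),
                              repeats = 1, budget = 1e6)
  df <- as.data.frame(rep)
  expect_setequal(unique(df$analysis), c("A", "B", "C", "sequence"))
  expect_output(print(rep), "Progression report")
})

test_that("the random-walk probe finds easy goals and never claims exhaustiveness", {
  an <- translate(make_toy_clock())
  res <- random_walk_reach(an, initial_state(an), goal_spec(present = "B"),
                           steps = 200, restarts = 5, seed = 3)
  expect_equal(res$verdict, "reachable")
  expect_false(res$exhaustive)
  anl <- apply_mutations(an, an_mutation("B", "LoF"))
  res2 <- random_walk_reach(anl, initial_state(anl), goal_spec(present = "B"),
                            steps = 50, restarts = 2, seed = 3)
  expect_equal(res2$verdict, "unknown")
})
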