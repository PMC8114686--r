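test_that("modulation sources evaluate by presence, with full truth tables for logic", {
  m <- make_toy_clock()
  an <- translate(m)
  A <- parse_entity_text("A", "cell"); B <- parse_entity_text("B", "cell")
  st <- initial_state(an)
  expect_false(eval_modulation(B, st, m))
  expect_true(eval_modulation(logical_function("NOT", list(B)), st, m))
  # truth table of AND(A, NOT B) over all four entity valuations
  f <- logical_function("AND", list(A, logical_function("NOT", list(B))))
  for (a in 0:1) for (b in 0:1) {
    s <- st; s["A"] <- a; s["B"] <- b
    expect_identical(eval_modulation(f, s, m), a == 1 && b == 0)
  }
  expect_error(eval_modulation(parse_entity_text("Q", "cell"), st, m),
               "no automaton")
})

test_that("the permissive firing condition handles all modulation classes", {
  tc <- make_toy_clock()
  an <- translate(tc)
  st <- initial_state(an)
  # unmodulated process with (vacuously) present reactants can fire
  expect_true(can_switch_on(tc, "dB", `[<-`(st, "B", 1L)))
  expect_false(can_switch_on(tc, "dB", st))   # reactant B absent
  # single inhibitor: blocked iff inhibitor present
  expect_true(can_switch_on(tc, "tA", st))
  expect_false(can_switch_on(tc, "tA", `[<-`(st, "B", 1L)))
  # necessary stimulation gates the source process of the metabolic motif
  nm <- make_nad_motif()
  ann <- translate(nm)
  s <- initial_state(ann)
  expect_false(can_switch_on(nm, "p3", s))
  expect_true(can_switch_on(nm, "p3", `[<-`(s, "NAD", 1L)))
})

test_that("translation yields one automaton per pool and per process with rule-counts by construction", {
  expect_length(translate(pd_map())$ids, 0)
  an <- translate(make_toy_clock())
  expect_equal(sum(an$kind == "entity"), 2)
  expect_equal(sum(an$kind == "process"), 4)
  expect_length(an$rules, 12)
  # NAM can only be produced by p5
  ann <- translate(make_nad_motif())
  nam_i <- match("NAM", ann$ids)
  up <- Filter(function(r) r$aut == nam_i && r$to == 1L, ann$rules)
  expect_length(up, 1)
  refs <- sbgndyn:::guard_refs(up[[1]]$guard)
  expect_identical(ann$ids[refs], "p5")
  # a guard never references its own automaton
  for (r in an$rules)
    expect_false(r$aut %in% sbgndyn:::guard_refs(r$guard))
})

test_that("translation is deterministic and independent of insertion order", {
  a1 <- translate(make_toy_coupled())
  a2 <- translate(make_toy_coupled())
  expect_identical(a1$ids, a2$ids)
  expect_identical(a1$rules, a2$rules)
})

test_that("asynchronous successors flip exactly one automaton", {
  an <- translate(make_toy_coupled())
  s <- initial_state(an, c("A", "X1"))
  for (p in corpus_params(11:13)) {
    m <- random_map(p)
    anr <- translate(m)
    set.seed(p$seed)
    for (i in 1:5) {
      st <- stats::setNames(sample(0:1, length(anr$ids), replace = TRUE),
                            anr$ids)
      for (s2 in step(anr, st))
        expect_equal(sum(s2 != st), 1)
    }
  }
  # all-zero toy clock has exactly one enabled transition
  expect_length(step(translate(make_toy_clock()),
                     initial_state(translate(make_toy_clock()))), 1)
})

test_that("the rule engine agrees with the brute-force interpreter on all states", {
  maps <- c(list(make_toy_clock(), make_nad_motif()),
            lapply(corpus_params(1:8), random_map))
  # the comparison is exhaustive over the full state space, so restrict the
  # corpus to networks small enough to enumerate
  maps <- Filter(function(m) length(translate(m)$ids) <= 12, maps)
  expect_gte(length(maps), 5)
  for (m in maps) {
    an <- translate(m)
    n <- length(an$ids)
    naming <- oracle_naming(m)
    for (s in all_states(n)) {
      st <- stats::setNames(s, an$ids)
      eng <- sort(vapply(step(an, st), state_label, ""))
      orc <- sort(vapply(oracle_successors(m, st, naming), state_label, ""))
      expect_identical(eng, orc)
    }
  }
})

test_that("removing an inhibition or adding a stimulation never removes successors", {
  base <- make_toy_clock()
  an0 <- translate(base)
  # drop the inhibition on tA
  relaxed <- base
  relaxed$modulations <- Filter(function(x)
    !(x$mod_class == "inhibition" && x$target == "tA"), relaxed$modulations)
  an1 <- translate(relaxed)
  # add a stimulation to a process that already carries a plain arc (tA has
  # an inhibition); the firing disjunction only gains an alternative.  (For a
  # previously unmodulated process the vacuous disjunct would flip from
  # always-true to conditional, so monotonicity holds only in this case.)
  stimmed <- add_modulation(base, modulation("stimulation",
                                             parse_entity_text("A", "cell"),
                                             "tA"))
  an2 <- translate(stimmed)
  for (s in all_states(length(an0$ids))) {
    st <- stats::setNames(s, an0$ids)
    s0 <- vapply(step(an0, st), state_label, "")
    s1 <- vapply(step(an1, st), state_label, "")
    s2 <- vapply(step(an2, st[an2$ids]), function(x)
      state_label(x[an0$ids]), "")
    expect_true(all(s0 %in% s1))
    expect_true(all(s0 %in% s2))
  }
})

test_that("networks export to the plain-text exchange format with provenance", {
  an <- translate(make_nad_motif())
  f <- withr::local_tempfile(fileext = ".an")
  write_an(an, f)
  lines <- readLines(f)
  expect_length(grep("^automaton ", lines), length(an$ids))
  expect_length(grep(" -> ", lines), length(an$rules))
  pf <- withr::local_tempfile(fileext = ".json")
  write_an_provenance(an, pf)
  prov <- jsonlite::read_json(pf)
  expect_setequal(names(prov), an$ids)
})
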