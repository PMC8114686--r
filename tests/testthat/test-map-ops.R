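test_that("harmonize applies edits in order, reports counts, leaves input untouched", {
  m <- make_toy_clock()
  before <- length(m$entities)
  m2 <- harmonize(m, edit_script(edit_rename_label("B", "BMAL1")))
  rep <- attr(m2, "report")
  expect_gt(rep$matches[1], 0)
  expect_false(is.null(find_entity(m2, "BMAL1")))
  expect_null(find_entity(m2, "B"))
  # pure transformation: original untouched
  expect_false(is.null(find_entity(m, "B")))
  expect_equal(length(m$entities), before)
  # empty script is the identity with an empty report
  m3 <- harmonize(m, edit_script())
  expect_setequal(names(m3$entities), names(m$entities))
  expect_equal(nrow(attr(m3, "report")), 0)
})

test_that("adding a state variable reaches subunits inside every containing complex", {
  m <- pd_map("cell")
  cplx1 <- parse_entity_text("CCND1:CDK6:CDKN1B", "cell")
  cplx2 <- parse_entity_text("CDK6:INK4", "cell")
  m <- add_entity(m, cplx1)
  m <- add_entity(m, cplx2)
  m <- add_entity(m, parse_entity_text("CDK6", "cell"))
  m2 <- harmonize(m, edit_script(edit_add_state_variable("CDK6", "P", "Thr")))
  expect_equal(attr(m2, "report")$matches[1], 3)
  expect_false(is.null(find_entity(m2, "CCND1:CDK6(P@Thr):CDKN1B")))
  expect_false(is.null(find_entity(m2, "CDK6(P@Thr):INK4")))
  expect_false(is.null(find_entity(m2, "CDK6(P@Thr)")))
})

test_that("a rename and its inverse restore the original map", {
  m <- make_nad_motif()
  fwd <- edit_script(edit_rename_label("NAM", "nicotinamide"))
  bwd <- edit_script(edit_rename_label("nicotinamide", "NAM"))
  m2 <- harmonize(harmonize(m, fwd), bwd)
  expect_setequal(names(m2$entities), names(m$entities))
  expect_setequal(unname(vapply(m2$processes, sbgndyn:::process_key, "")),
                  unname(vapply(m$processes, sbgndyn:::process_key, "")))
})

test_that("deleting a referenced entity is an integrity error; a free one succeeds", {
  m <- make_toy_clock()
  expect_error(harmonize(m, edit_script(edit_delete_entity("A"))),
               "integrity error")
  m2 <- add_entity(m, parse_entity_text("ORPHAN", "cell"))
  m3 <- harmonize(m2, edit_script(edit_delete_entity("ORPHAN")))
  expect_null(find_entity(m3, "ORPHAN"))
  # deleting a process also drops its modulation arcs
  m4 <- harmonize(m, edit_script(edit_delete_process("tA")))
  expect_length(m4$processes, 3)
  expect_false(any(vapply(m4$modulations, function(x) x$target == "tA", FALSE)))
})

test_that("edit scripts serialize to YAML and replay identically", {
  sc <- edit_script(
    edit_rename_label("B", "BMAL1"),
    edit_add_state_variable("A", "P", "S42"),
    edit_add_process(process_node("new1",
      reactants = list(parse_entity_text("A", "cell")),
      products = list(parse_entity_text("A(P@S42)", "cell")))))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_edit_script(sc, f)
  sc2 <- read_edit_script(f)
  m <- make_toy_clock()
  m1 <- harmonize(m, sc)
  m2 <- harmonize(m, sc2)
  expect_setequal(names(m1$entities), names(m2$entities))
  expect_equal(attr(m1, "report")$matches, attr(m2, "report")$matches)
})

test_that("merge is idempotent, commutative and unions concepts structurally", {
  a <- make_toy_clock(); b <- make_nad_motif()
  self <- merge_maps(a, a)
  expect_setequal(names(self$entities), names(a$entities))
  expect_length(self$processes, length(a$processes))
  expect_length(self$modulations, length(a$modulations))

  ab <- merge_maps(a, b); ba <- merge_maps(b, a)
  expect_setequal(names(ab$entities), names(ba$entities))
  expect_length(ab$entities, length(a$entities) + length(b$entities))
  expect_setequal(unname(vapply(ab$processes, sbgndyn:::process_key, "")),
                  unname(vapply(ba$processes, sbgndyn:::process_key, "")))
  expect_length(ab$processes, length(a$processes) + length(b$processes))
})

test_that("merging maps sharing an entity keeps it once and keeps all processes", {
  a <- make_toy_clock()
  b <- pd_map("cell")
  b <- add_process(b, process_node("w1",
    reactants = list(parse_entity_text("A", "cell")),
    products = list(parse_entity_text("WEE1", "cell"))))
  ab <- merge_maps(a, b)
  expect_length(ab$entities, length(a$entities) + 1)  # A shared, WEE1 new
  expect_length(ab$processes, 5)
})

test_that("process-id collisions between different processes are re-identified", {
  a <- pd_map("cell")
  a <- add_process(a, process_node("p1", products = list(parse_entity_text("A", "cell"))))
  b <- pd_map("cell")
  b <- add_process(b, process_node("p1", products = list(parse_entity_text("B", "cell"))))
  b <- add_modulation(b, modulation("stimulation", parse_entity_text("A", "cell"), "p1"))
  ab <- merge_maps(a, b)
  expect_length(ab$processes, 2)
  expect_length(attr(ab, "relabelled"), 1)
  # the modulation followed its process to the new id
  tgt <- ab$modulations[[1]]$target
  expect_true(tgt %in% names(ab$processes))
  expect_equal(render_entity_text(ab$processes[[tgt]]$products[[1]]), "B")
})
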