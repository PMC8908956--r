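test_that("social, individual and creative events update the right sets", {
  state <- new_state <- rafnet:::new_lineage_state()
  # social transmission from a teacher lands in the actor's foodset
  state <- apply_event(state, lineage_event(1, "social", "i",
                                            outputs = "M_i", inputs = "M_g",
                                            source = "g"))
  expect_true("M_i" %in% state$individuals$i$foodset)
  expect_equal(state$mrs$M_i$provenance, "social")
  expect_equal(state$mrs$M_i$source, "g")
  # individual learning also grows the foodset
  state <- apply_event(state, lineage_event(2, "individual", "i",
                                            outputs = "n_i"))
  expect_true("n_i" %in% state$individuals$i$foodset)
  # catalysed creative thought grows the derived set instead
  state <- apply_event(state, lineage_event(3, "creative", "i",
                                            inputs = "M_i",
                                            catalysts = "n_i",
                                            outputs = "musM_i"))
  expect_true("musM_i" %in% state$individuals$i$derived)
  expect_false("musM_i" %in% state$individuals$i$foodset)
  expect_equal(state$mrs$musM_i$catalyzed_by, "n_i")
  expect_equal(state$mrs$musM_i$derived_from, "M_i")
})

test_that("a creative product transmitted socially enters the recipient's foodset", {
  state <- rafnet:::new_lineage_state()
  state <- apply_event(state, lineage_event(1, "individual", "i",
                                            outputs = c("a_i", "n_i")))
  state <- apply_event(state, lineage_event(2, "creative", "i",
                                            inputs = "a_i", catalysts = "n_i",
                                            outputs = "c_i"))
  expect_true("c_i" %in% state$individuals$i$derived)
  state <- apply_event(state, lineage_event(3, "social", "j",
                                            outputs = "c_j", inputs = "c_i",
                                            source = "i"))
  # re-tagging: creative for the sender, foodset for the recipient
  expect_true("c_j" %in% state$individuals$j$foodset)
  expect_equal(state$mrs$c_j$provenance, "social")
  expect_length(state$individuals$j$derived, 0)
})

test_that("unreachable streams of thought and absent source MRs error", {
  state <- rafnet:::new_lineage_state()
  state <- apply_event(state, lineage_event(1, "individual", "i",
                                            outputs = "n_i"))
  expect_error(
    apply_event(state, lineage_event(2, "creative", "i", inputs = "ghost",
                                     catalysts = "n_i", outputs = "x_i")),
    "unreachable stream")
  expect_error(
    apply_event(state, lineage_event(2, "social", "j", outputs = "y_j",
                                     inputs = "ghost", source = "i")),
    "does not possess")
  # duplicate MR ids are rejected
  expect_error(
    apply_event(state, lineage_event(2, "individual", "i", outputs = "n_i")),
    "already in use")
})

test_that("run_lineage on the six-step musician lineage satisfies the model", {
  run <- musician_run()
  expect_s3_class(run, "lineage_run")
  expect_equal(length(unique(vapply(run$events, function(e) e$step,
                                    integer(1)))), 6)
  slt <- run$state$individuals$SLT
  # the creator's derived set is exactly the four transferred
  # through-lines plus the finished piece
  expect_setequal(slt$derived, c("musLH_SLT", "musS_SLT", "musD_SLT",
                                 "musW_SLT", "musL_SLT"))
  # the listener possesses the piece as foodset knowledge, creates nothing
  expect_equal(run$state$individuals$j$foodset, "musF_j")
  expect_length(run$state$individuals$j$derived, 0)
  # foodset and derived sets stay disjoint for everyone
  for (ind in run$state$individuals) {
    expect_length(intersect(ind$foodset, ind$derived), 0)
  }
  # ledger provenance tags partition as expected
  led <- run$ledger
  expect_setequal(led$provenance[led$owner == "SLT" &
                                   led$mr %in% slt$derived], "creative")
  expect_equal(led$provenance[led$mr == "musF_j"], "social")
})

test_that("event order matters: cross-domain transfer before transmission fails", {
  tls <- select_through_lines(load_theme_matrix(), 2L, retained = "S")
  ev <- build_lineage_fixture(tls, creator = "SLT", audience = "j")
  steps <- vapply(ev, function(e) e$step, integer(1))
  # move the step-4 transfers before the step-3 transmission
  ev_bad <- ev
  for (k in which(steps == 4)) ev_bad[[k]]$step <- 2L
  expect_error(run_lineage(ev_bad), "step 2.*unreachable")
})

test_that("empty event lists and event tables round-trip", {
  empty <- run_lineage(list())
  expect_length(empty$state$individuals, 0)
  expect_equal(nrow(empty$ledger), 0)
  # TSV round trip preserves events
  ev <- build_lineage_fixture(c("LH", "D"), creator = "SLT", audience = "j")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lineage_tsv(ev, path)
  back <- read_lineage_tsv(path)
  expect_equal(back, ev)
})

test_that("the creator's conceptual CRS supports all creative reactions", {
  run <- musician_run()
  net <- lineage_to_crs(run, "SLT")
  expect_setequal(net$food, run$state$individuals$SLT$foodset)
  expect_length(net$reactions, 5)
  mr <- max_raf(net)
  expect_setequal(mr$reaction_ids, names(net$reactions))
  # every derived MR lies in the producible closure of the maxRAF
  cl <- producible_closure(net, mr$reaction_ids)
  expect_true(all(run$state$individuals$SLT$derived %in% cl))
  # the listener created nothing: empty reaction set, empty maxRAF
  net_j <- lineage_to_crs(run, "j")
  expect_length(net_j$reactions, 0)
  expect_true(max_raf(net_j)$is_empty)
  expect_error(lineage_to_crs(run, "nobody"), "unknown actor")
})

test_that("trace_origin walks creative ancestry back to the foodset", {
  run <- musician_run()
  tr <- trace_origin(run, "musL_SLT")
  expect_equal(tr$mr[tr$depth == 0], "musL_SLT")
  expect_setequal(tr$mr[tr$depth == 1],
                  c("musLH_SLT", "musS_SLT", "musD_SLT", "musW_SLT"))
  expect_setequal(tr$mr[tr$depth == 2],
                  c("LH_SLT", "S_SLT", "D_SLT", "W_SLT"))
  expect_true(all(tr$provenance[tr$depth == 2] == "social"))
  expect_equal(max(tr$depth), 2)
  # chains terminate only at foodset provenances
  deepest <- tr[tr$depth == max(tr$depth), ]
  expect_true(all(deepest$provenance %in%
                    c("innate", "social", "individual")))
  # a foodset MR has a chain of length zero
  tr0 <- trace_origin(run, "LH_SLT")
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$depth, 0)
  expect_error(trace_origin(run, "nope"), "unknown mental representation")
})

test_that("traced chains are acyclic on varied small lineages", {
  for (s in 1:10) {
    k <- 1 + s %% 3
    tls <- c("LH", "S", "D", "W")[seq_len(k)]
    run <- run_lineage(build_lineage_fixture(tls, creator = "C",
                                             audience = c("j", "k")))
    for (mr in run$ledger$mr) {
      tr <- trace_origin(run, mr)
      expect_false(any(duplicated(tr$mr)))
      expect_lte(max(tr$depth), 2)
    }
  }
})
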