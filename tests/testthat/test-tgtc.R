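test_that("a single-step schedule adds one control place, token path and arc", {
  net <- bare_net("t1")
  aug <- tgtc_augment(net, sched_seq("t1"))
  ctrl <- aug$control
  expect_named(ctrl$control_places, "t1")
  expect_length(ctrl$added_places, 2L)          # start place + cp_t1
  expect_identical(ctrl$added_transitions, "t_start")
  m <- tgtc_seed(aug$net, cpn_marking(aug$net), ctrl)
  tr <- cpn_run(aug$net, m, seed = 1)
  expect_identical(trace_transitions(tr), c("t_start", "t1"))
})

test_that("parallel branches realize exactly the linear extensions of the schedule", {
  # two concurrent 2-chains followed by a single closing step
  sched <- sched_seq(sched_par(sched_seq("t1", "t2"), sched_seq("t6", "t7")),
                     sched_step("t5"))
  ids <- schedule_transitions(sched)
  aug <- tgtc_augment(bare_net(ids), sched)
  m <- tgtc_seed(aug$net, cpn_marking(aug$net), aug$control)
  runs <- reachable_sequences(aug$net, m, depth = 10L)
  got <- vapply(runs, function(s) seq_key(s[-1L]), "")  # drop t_start
  want <- vapply(interleavings(c("t1", "t2"), c("t6", "t7")),
                 function(s) seq_key(c(s, "t5")), "")
  expect_setequal(got, want)
  expect_length(got, choose(4, 2))
  # the closing step never precedes the end of either branch
  expect_true(all(vapply(runs, verify_order, TRUE, schedule = sched)))
})

test_that("verify_order accepts exactly the order-respecting prefixes", {
  sched <- two_chain_schedule()
  expect_true(verify_order(
    c("t1", "t6", "t2", "t7", "t3", "t8", "t5", "t4", "t10", "t9"), sched))
  expect_false(verify_order(c("t2", "t1"), sched))       # Seq violated
  expect_true(verify_order(character(), sched))          # empty prefix
  expect_true(verify_order(c("t1", "t6", "t7"), sched))  # incomplete prefix
  expect_false(verify_order(c("t1", "t1"), sched))       # duplicate firing
  expect_false(verify_order(c("t5", "t1"), sched))       # tail before join
  # unscheduled transitions are ignored
  expect_true(verify_order(c("x", "t1", "y", "t2"), sched))
})

test_that("stripping the control layer restores the original net exactly", {
  net <- cpn_net(
    places = list(cpn_place("d1", "REAL"), cpn_place("d2", "REAL")),
    transitions = list(cpn_transition("t1"), cpn_transition("t2")),
    arcs = list(cpn_arc("d1", "t1", "x"), cpn_arc("t1", "d2", "x + 1"),
                cpn_arc("d2", "t2", "y"), cpn_arc("t2", "d1", "y")))
  aug <- tgtc_augment(net, sched_seq("t1", "t2"))
  expect_gt(length(aug$net$places), length(net$places))
  back <- tgtc_strip(aug$net, aug$control)
  expect_identical(names(back$places), names(net$places))
  expect_identical(names(back$transitions), names(net$transitions))
  expect_identical(lapply(back$arcs, `[`, c("src", "dst", "kind")),
                   lapply(net$arcs, `[`, c("src", "dst", "kind")))
  # data arcs of the augmented net are untouched (non-interference at the
  # structural level)
  data_arcs <- Filter(function(a) a$src %in% names(net$places) ||
                        a$dst %in% names(net$places), aug$net$arcs)
  expect_length(data_arcs, length(net$arcs))
})

test_that("random series-parallel schedules are sound and complete", {
  set.seed(402)
  for (rep in 1:8) {
    ids <- paste0("t", 1:6)
    sched <- random_schedule(ids)
    aug <- tgtc_augment(bare_net(ids), sched)
    m <- tgtc_seed(aug$net, cpn_marking(aug$net), aug$control)
    runs <- reachable_sequences(aug$net, m, depth = 20L)
    # soundness: every full firing sequence respects the partial order
    expect_true(all(vapply(runs, verify_order, TRUE, schedule = sched)))
    # completeness: the realized orders are exactly the linear extensions
    got <- vapply(runs, function(s)
      seq_key(s[s %in% ids]), "")
    want <- vapply(linear_extensions(ids, schedule_order(sched)), seq_key, "")
    expect_setequal(got, want)
  }
})

test_that("nested parallel blocks re-split through a synthetic join", {
  # par followed directly by par: the joined token must be re-split
  sched <- sched_seq(sched_par("a", "b"), sched_par("c", "d"), "e")
  ids <- schedule_transitions(sched)
  aug <- tgtc_augment(bare_net(ids), sched)
  expect_true(any(grepl("^tj_", aug$control$added_transitions)))
  m <- tgtc_seed(aug$net, cpn_marking(aug$net), aug$control)
  runs <- reachable_sequences(aug$net, m, depth = 20L)
  got <- vapply(runs, function(s) seq_key(s[s %in% ids]), "")
  want <- vapply(linear_extensions(ids, schedule_order(sched)), seq_key, "")
  expect_setequal(got, want)   # 2 * 2 = 4 orders
})

test_that("schedules must match the net and name each transition once", {
  expect_error(tgtc_augment(bare_net(c("t1", "t2")), sched_seq("t1", "zz")),
               "missing from net")
  expect_error(sched_seq("t1", sched_par("t2", "t1")) |>
                 tgtc_augment(net = bare_net(c("t1", "t2"))),
               "more than once")
})

test_that("schedule files round-trip through JSON", {
  sched <- two_chain_schedule()
  json <- write_schedule(sched)
  back <- read_schedule(json)
  expect_identical(schedule_transitions(back), schedule_transitions(sched))
  expect_identical(schedule_order(back), schedule_order(sched))
  path <- tempfile(fileext = ".json")
  write_schedule(sched, path)
  expect_identical(schedule_order(read_schedule(path)),
                   schedule_order(sched))
})
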