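test_that("enabling honors tokens, inhibitors and guards", {
  net <- cpn_net(
    places = list(cpn_place("p"), cpn_place("q"),
                  cpn_place("r", "REAL")),
    transitions = list(cpn_transition("t"),
                       cpn_transition("t_inh"),
                       cpn_transition("t_guard", guard = "x > 3")),
    arcs = list(cpn_arc("p", "t", 1L),
                cpn_arc("p", "t_inh", 1L),
                cpn_arc("q", "t_inh", kind = "inhibitor"),
                cpn_arc("r", "t_guard", "x")))

  m <- cpn_marking(net, list(p = list(unit_token()),
                             q = list(unit_token()),
                             r = list(2.0)))
  expect_length(enabled(net, m, "t"), 1L)        # one empty binding
  expect_identical(enabled(net, m, "t")[[1L]], stats::setNames(list(), character()))
  expect_length(enabled(net, m, "t_inh"), 0L)    # inhibited by q
  expect_length(enabled(net, m, "t_guard"), 0L)  # 2.0 fails x > 3

  m2 <- cpn_marking(net, list(q = list(), p = list(unit_token()),
                              r = list(4.5)))
  expect_length(enabled(net, m2, "t_inh"), 1L)
  bs <- enabled(net, m2, "t_guard")
  expect_length(bs, 1L)
  expect_equal(bs[[1L]]$x, 4.5)
  expect_error(enabled(net, m, "nope"), "unknown transition")
})

test_that("firing moves tokens, applies expressions, and never mutates its input", {
  net <- cpn_net(
    places = list(cpn_place("p", "REAL"), cpn_place("q", "REAL")),
    transitions = list(cpn_transition("t")),
    arcs = list(cpn_arc("p", "t", "x"), cpn_arc("t", "q", "2 * x")))
  m0 <- cpn_marking(net, list(p = list(3.0)))
  m1 <- fire(net, m0, "t", list(x = 3.0))
  expect_identical(m1$p, list())
  expect_identical(m1$q, list(6.0))
  # value semantics: m0 untouched
  expect_identical(m0$p, list(3.0))
  expect_identical(m0$q, list())
  # firing without the token is a contract violation
  expect_error(fire(net, m1, "t", list(x = 3.0)), "not enabled")
})

test_that("a shared input token yields exactly two maximal runs", {
  net <- cpn_net(
    places = list(cpn_place("p"), cpn_place("a"), cpn_place("b")),
    transitions = list(cpn_transition("ta"), cpn_transition("tb")),
    arcs = list(cpn_arc("p", "ta"), cpn_arc("p", "tb"),
                cpn_arc("ta", "a"), cpn_arc("tb", "b")))
  m0 <- cpn_marking(net, list(p = list(unit_token())))
  runs <- reachable_sequences(net, m0, depth = 5L)
  expect_setequal(vapply(runs, seq_key, ""), c("ta", "tb"))
  # after firing one, the other is disabled
  m1 <- fire(net, m0, "ta")
  expect_length(enabled(net, m1, "tb"), 0L)
})

test_that("firing conserves tokens according to the arc algebra", {
  net <- cpn_net(
    places = list(cpn_place("p", "REAL"), cpn_place("q", "REAL"),
                  cpn_place("out", "REAL")),
    transitions = list(cpn_transition("t")),
    arcs = list(cpn_arc("p", "t", "x"), cpn_arc("q", "t", "y"),
                cpn_arc("t", "p", "x"),              # x returned
                cpn_arc("t", "out", c("x + y", "x - y"))))
  m0 <- cpn_marking(net, list(p = list(5), q = list(2, 7)))
  bs <- enabled(net, m0, "t")
  for (b in bs) {
    m1 <- fire(net, m0, "t", b)
    # delta on each place = outputs - inputs under this binding
    expect_identical(sort(unlist(m1$p)), sort(unlist(m0$p)))
    expect_identical(length(m1$q), length(m0$q) - 1L)
    expect_setequal(unlist(m1$out), c(b$x + b$y, b$x - b$y))
  }
})

test_that("runs are seeded-deterministic and respect structure", {
  # dead initial marking -> empty trace
  chain <- cpn_net(
    places = list(cpn_place("p1"), cpn_place("p2"), cpn_place("p3")),
    transitions = list(cpn_transition("t1"), cpn_transition("t2")),
    arcs = list(cpn_arc("p1", "t1"), cpn_arc("t1", "p2"),
                cpn_arc("p2", "t2"), cpn_arc("t2", "p3")))
  dead <- cpn_marking(chain, list())
  expect_length(cpn_run(chain, dead, seed = 1)$steps, 0L)

  m0 <- cpn_marking(chain, list(p1 = list(unit_token())))
  for (s in c(1L, 99L)) {
    expect_identical(trace_transitions(cpn_run(chain, m0, seed = s)),
                     c("t1", "t2"))
  }
  expect_length(cpn_run(chain, m0, max_steps = 0L, seed = 1)$steps, 0L)

  # a net with real choice: identical seeds give identical traces
  fork <- cpn_net(
    places = list(cpn_place("p")),
    transitions = list(cpn_transition("ta"), cpn_transition("tb")),
    arcs = list(cpn_arc("p", "ta"), cpn_arc("p", "tb")))
  mf <- cpn_marking(fork, list(p = list(unit_token(), unit_token(),
                                        unit_token())))
  tr1 <- cpn_run(fork, mf, seed = 42)
  tr2 <- cpn_run(fork, mf, seed = 42)
  expect_identical(trace_transitions(tr1), trace_transitions(tr2))
  # priority policy is deterministic without a seed
  trp <- cpn_run(fork, mf, policy = "priority", priority = c("tb", "ta"))
  expect_identical(trace_transitions(trp), c("tb", "tb", "tb"))
})

test_that("enabled() agrees with the brute-force binding enumerator", {
  # several small nets with up to 3 variables, guards and multi-token arcs
  net1 <- cpn_net(
    places = list(cpn_place("p", "REAL"), cpn_place("q", "REAL"),
                  cpn_place("z", "REAL")),
    transitions = list(cpn_transition("t", guard = "x + y > 4")),
    arcs = list(cpn_arc("p", "t", "x"), cpn_arc("q", "t", "y"),
                cpn_arc("t", "z", "x * y")))
  m1 <- cpn_marking(net1, list(p = list(1, 2, 3), q = list(2, 4)))

  net2 <- cpn_net(
    places = list(cpn_place("p", "REAL"), cpn_place("s", "REAL")),
    transitions = list(cpn_transition("t")),
    arcs = list(cpn_arc("p", "t", c("x", "y")),   # two tokens, one place
                cpn_arc("t", "s", "x + y")))
  m2 <- cpn_marking(net2, list(p = list(1, 1, 2)))

  net3 <- cpn_net(
    places = list(cpn_place("a", "REAL"), cpn_place("b", "REAL"),
                  cpn_place("c", "REAL"), cpn_place("z", "REAL")),
    transitions = list(cpn_transition("t", guard = "x < y & y < z")),
    arcs = list(cpn_arc("a", "t", "x"), cpn_arc("b", "t", "y"),
                cpn_arc("c", "t", "z"), cpn_arc("t", "z", "x")))
  m3 <- cpn_marking(net3, list(a = list(1, 2), b = list(2, 3),
                               c = list(3, 4)))

  for (case in list(list(net1, m1), list(net2, m2), list(net3, m3))) {
    got <- enabled(case[[1]], case[[2]], "t")
    want <- brute_force_enabled(case[[1]], case[[2]], "t")
    expect_identical(binding_keys(got), binding_keys(want))
    expect_gt(length(got), 0L)
  }
})

test_that("color safety is enforced on markings and firings", {
  net <- cpn_net(
    places = list(cpn_place("p", "REAL"), cpn_place("n", "INT")),
    transitions = list(cpn_transition("t")),
    arcs = list(cpn_arc("p", "t", "x"), cpn_arc("t", "n", "x / 2")))
  expect_error(cpn_marking(net, list(n = list(2.5))), "violates color set")
  expect_error(cpn_marking(net, list(p = list("a"))), "violates color set")
  m <- cpn_marking(net, list(p = list(3)))
  expect_error(fire(net, m, "t", list(x = 3)), "violating color set")
  m2 <- cpn_marking(net, list(p = list(4)))
  expect_identical(fire(net, m2, "t", list(x = 4))$n, list(2))
})

test_that("the expression mini-language rejects anything beyond arithmetic", {
  expect_error(parse_cpn_expr("system('ls')"), "disallowed")
  expect_error(parse_cpn_expr("x[1]"), "disallowed")
  expect_error(parse_cpn_expr("x <- 3"), "disallowed")
  expect_error(parse_cpn_expr("exp(x)"), "disallowed")
  expect_error(parse_cpn_expr("x > 3"), "disallowed")  # comparison: guards only
  expect_silent(parse_cpn_expr("min(3, max(0, abs(x - 1) / 2))"))
  expect_silent(parse_cpn_expr("x >= 3 & !(y == 2)", guard = TRUE))
  expect_setequal(cpn_expr_vars("0.1 * a + b / c"), c("a", "b", "c"))
})

test_that("nets and markings serialize to structured text and back", {
  net <- cpn_net(
    places = list(cpn_place("p", "REAL", label = "state"),
                  cpn_place("q", "REAL"), cpn_place("g")),
    transitions = list(cpn_transition("t", guard = "x > 1"),
                       cpn_transition("u")),
    arcs = list(cpn_arc("p", "t", "x"), cpn_arc("t", "q", "x / 2"),
                cpn_arc("g", "u", 2L), cpn_arc("q", "u", kind = "inhibitor")))
  m <- cpn_marking(net, list(p = list(3.5),
                             g = list(unit_token(), unit_token())))
  path <- tempfile(fileext = ".json")
  write_cpn_net(net, path, marking = m)
  back <- read_cpn_net(path)
  expect_identical(names(back$net$places), names(net$places))
  expect_identical(names(back$net$transitions), names(net$transitions))
  expect_length(back$net$arcs, length(net$arcs))
  expect_identical(back$marking$p, list(3.5))
  # behavior preserved: same enabled bindings, same firing result
  expect_identical(binding_keys(enabled(back$net, back$marking, "t")),
                   binding_keys(enabled(net, m, "t")))
  expect_identical(fire(back$net, back$marking, "t", list(x = 3.5))$q,
                   fire(net, m, "t", list(x = 3.5))$q)
})

test_that("reachable_sequences enforces its exploration budget", {
  fork <- cpn_net(
    places = list(cpn_place("p")),
    transitions = lapply(paste0("t", 1:4), cpn_transition),
    arcs = lapply(paste0("t", 1:4), function(t) cpn_arc("p", t)))
  m <- cpn_marking(fork, list(p = rep(list(unit_token()), 4L)))
  expect_error(reachable_sequences(fork, m, depth = 4L, max_nodes = 3L),
               "budget exceeded")
  runs <- reachable_sequences(fork, m, depth = 10L)
  expect_length(runs, 256L)  # 4 indistinguishable tokens, 4 choices each

})
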