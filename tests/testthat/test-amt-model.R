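p0 <- amt_params()

test_that("the five-viscera stage reproduces hand-computed updates", {
  # all viscera at the healthy target stay put (g - r + s = 1)
  st <- amt_state()
  expect_equal(step_viscera(st, p0), st)
  # excess generator raises the generated viscus: liver 5 -> heart
  st <- amt_state(liver = 5)
  expect_equal(step_viscera(st, p0)[["heart"]], 3.30)
  # excess restrictor lowers it: kidney 5 -| heart
  st <- amt_state(kidney = 5)
  expect_equal(step_viscera(st, p0)[["heart"]], 2.90)
  # bowels and pericardium untouched
  st <- amt_state(liver = 5, stomach = 2, pericardium = 2.2)
  out <- step_viscera(st, p0)
  expect_identical(out[["stomach"]], 2)
  expect_identical(out[["pericardium"]], 2.2)
})

test_that("viscus-bowel coupling matches hand arithmetic in both directions", {
  # fixed point: c + s = 1
  st <- amt_state(); prev <- amt_state()
  expect_equal(step_viscera_to_bowels(st, prev, p0), st)
  # heart at 3.3 pulls the small intestine up
  st <- amt_state(heart = 3.3)
  expect_equal(step_viscera_to_bowels(st, prev, p0)[["small_intestine"]],
               3.03)
  # a deficient bowel recovers toward its viscus
  prev2 <- amt_state(small_intestine = 1)
  expect_equal(step_viscera_to_bowels(amt_state(), prev2,
                                      p0)[["small_intestine"]], 1.2)
  # feedback direction
  st <- amt_state(heart = 3.3, small_intestine = 3.03)
  expect_equal(step_bowels_to_viscera(st, p0)[["heart"]], 3.273)
  st <- amt_state(heart = 3, small_intestine = 1.2)
  expect_equal(step_bowels_to_viscera(st, p0)[["heart"]], 2.82)
})

test_that("stimulation potentials follow the configured functional form", {
  expect_identical(stimulus(0, p0), 0)
  expect_equal(stimulus(3, p0), 7.5)           # linear: mu * e * v
  expect_equal(stimulus(-3, p0), -7.5)         # odd symmetry
  psat <- amt_params(stimulus = "saturating")
  expect_equal(stimulus(3, psat), 0.6)         # 3 * 2.5 / 12.5
  expect_equal(stimulus(-3, psat), -0.6)
  pfun <- amt_params(stimulus = function(mu, params) mu^3)
  expect_equal(stimulus(2, pfun), 8)
  expect_error(stimulus(6, p0))
})

test_that("the stimulation stage routes potentials to the mapped organs", {
  # empty protocol: no change
  st <- amt_state(kidney = 1)
  expect_identical(apply_stimulation(st, amt_protocol(integer()), p0), st)
  # additive + saturating reconstruction: one point at +3 on a balanced
  # organ adds w * fp = 0.01 * 0.6
  padd <- amt_params(stimulus = "saturating", response = "additive")
  out <- apply_stimulation(amt_state(), amt_protocol(c(KI3 = 3)), padd)
  expect_equal(out[["kidney"]], 3.006)
  # deviation response: effect scales with distance from the target and
  # vanishes at balance
  pdev <- p0
  out <- apply_stimulation(amt_state(kidney = 1),
                           amt_protocol(c(KI3 = 3)), pdev)
  expect_equal(out[["kidney"]], 1 + 0.01 * 7.5 * 2)
  out <- apply_stimulation(amt_state(), amt_protocol(c(KI3 = 3)), pdev)
  expect_equal(out[["kidney"]], 3)
  # opposite-sign points on one meridian organ cancel (sum aggregation)
  out <- apply_stimulation(amt_state(gallbladder = 4),
                           amt_protocol(c(GB20 = -3, GB39 = 3)), pdev)
  expect_equal(out[["gallbladder"]], 4)
  # purgation lowers an excess organ
  out <- apply_stimulation(amt_state(gallbladder = 4),
                           amt_protocol(c(GB20 = -3)), pdev)
  expect_lt(out[["gallbladder"]], 4)
  # vessel points split over the five viscera by default, droppable
  pot <- protocol_potentials(amt_protocol(c(GV20 = 3)), p0)
  expect_equal(unname(pot[c("liver", "heart", "spleen", "lung", "kidney")]),
               rep(7.5 / 5, 5))
  pnone <- amt_params(vessel_routing = "none")
  expect_identical(sum(abs(protocol_potentials(amt_protocol(c(GV20 = 3)),
                                               pnone))), 0)
})

test_that("substance generation, transport and absorption close the healthy loop", {
  st <- amt_state()
  fi <- substance_generation(st, p0)
  expect_equal(unname(fi), c(3, 3, 3))
  del <- substance_transport(fi, st, p0)
  expect_equal(unname(del), c(0.3, 0.3, 0.3))
  # absorption reconstitutes the healthy level exactly
  expect_equal(substance_absorption(st, del, p0), st)
  # excess generator organ suppresses production: spleen at 5
  st5 <- amt_state(spleen = 5)
  fi5 <- substance_generation(st5, p0)
  expect_equal(unname(fi5["qi"]), 3 * (34 / 36) * (1 / 3))
  # negative bracketed factors floor at zero: with target h = 1, the
  # all-3 state is maximally unbalanced and production stops entirely
  plow <- amt_params(h = 1)
  expect_equal(unname(substance_generation(amt_state(params = p0), plow)),
               c(0, 0, 0))
  # zero pools deliver nothing
  expect_equal(unname(substance_transport(c(qi = 0, blood = 0, fluid = 0),
                                          st, p0)), c(0, 0, 0))
  # transporter organ at 5 scales delivery by 1/3
  stue <- amt_state(lung = 5)
  delue <- substance_transport(c(qi = 3, blood = 3, fluid = 3), stue, p0)
  bal <- (36 - 2) / 36
  expect_equal(delue[["qi"]], 0.3 * bal * (1 / 3))
  # pure decay without deliveries, and clamping at the ceiling
  expect_equal(substance_absorption(st, c(qi = 0, blood = 0, fluid = 0), p0),
               st * 0.999)
  hot <- amt_state(); hot["liver"] <- 5.5
  expect_equal(substance_absorption(hot, c(qi = 1e6, blood = 0, fluid = 0),
                                    p0)[["liver"]], 5.5)
})

test_that("the all-healthy state is a machine-precision fixed point", {
  traj <- amt_simulate(amt_state(), steps = 1000L)
  st <- trajectory_states(traj)
  expect_lt(max(abs(st - 3)), 1e-9)
  expect_lt(max(abs(as.matrix(traj[, c("qi", "blood", "fluid")]) - 3)), 1e-9)
})

test_that("trajectories start at the initial condition and have T+1 rows", {
  init <- meniere_initial_state()
  traj <- amt_simulate(init, meniere_reference_protocol(), steps = 7)
  expect_identical(nrow(traj), 8L)
  expect_identical(traj$tau, 0:7)
  expect_equal(trajectory_states(traj)[1L, ], init)
  traj0 <- amt_simulate(init, steps = 0)
  expect_identical(nrow(traj0), 1L)
})

test_that("organ states stay within bounds for any protocol", {
  set.seed(11)
  cond <- meniere_condition()
  for (i in 1:6) {
    cfg <- generation_config(sample(c("R", "M", "C"), 1L))
    prot <- generate_protocol(cond, cfg)
    init <- amt_state(stats::setNames(stats::runif(12, 0.5, 5.5),
                                      amt_organs()$organ))
    traj <- amt_simulate(init, prot, steps = 30)
    st <- trajectory_states(traj)
    expect_true(all(st >= 0.5 & st <= 5.5))
  }
})

test_that("a treated organ's first-cycle state increases strictly with the level", {
  vals <- vapply(-5:5, function(mu) {
    prot <- if (mu == 0) amt_protocol(integer()) else amt_protocol(c(KI3 = mu))
    traj <- amt_simulate(amt_state(kidney = 1), prot, steps = 1)
    trajectory_states(traj)[2L, "kidney"]
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("the stage order matters: swapping the pair stages changes the outcome", {
  init <- amt_state(spleen = 1)
  straight <- amtsim:::amt_cycle_direct(init, amt_protocol(integer()),
                                        p0)$states
  # swapped order: bowel feedback computed before the bowels are updated
  swapped <- local({
    prev <- init
    st <- step_viscera(init, p0)
    st <- step_bowels_to_viscera(st, p0)
    st <- step_viscera_to_bowels(st, prev, p0)
    fi <- substance_generation(st, p0)
    substance_absorption(st, substance_transport(fi, st, p0), p0)
  })
  expect_false(isTRUE(all.equal(straight[["spleen"]], swapped[["spleen"]])))
})

test_that("the built net mirrors the protocol and obeys its schedule", {
  built0 <- build_amt_net(amt_protocol(integer()))
  expect_length(built0$acupoint_places, 0L)
  built <- build_amt_net(meniere_reference_protocol(),
                         initial = meniere_initial_state())
  expect_length(built$acupoint_places, 6L)
  m <- tgtc_seed(built$net, built$marking, built$control)
  tr <- cpn_run(built$net, m, seed = 5)
  expect_true(verify_order(tr, built$schedule))
  expect_identical(trace_transitions(tr)[1L], "t_start")
  # all 22 data transitions fire exactly once per cycle
  fired <- trace_transitions(tr)
  expect_identical(sort(fired[fired %in% schedule_transitions(built$schedule)]),
                   sort(schedule_transitions(built$schedule)))
})

test_that("direct and net execution produce the same trajectories", {
  init <- meniere_initial_state()
  prot <- meniere_reference_protocol()
  t_direct <- amt_simulate(init, prot, steps = 12)
  t_cpn <- amt_simulate(init, prot, steps = 12, mode = "cpn", seed = 3)
  expect_lt(max(abs(trajectory_states(t_direct) - trajectory_states(t_cpn))),
            1e-9)
  # and on a couple of generated protocols with random starts
  set.seed(21)
  cond <- meniere_condition()
  for (i in 1:2) {
    prot <- generate_protocol(cond, generation_config("M"))
    init <- amt_state(stats::setNames(stats::runif(12, 1, 5),
                                      amt_organs()$organ))
    a <- amt_simulate(init, prot, steps = 8)
    b <- amt_simulate(init, prot, steps = 8, mode = "cpn", seed = i)
    expect_lt(max(abs(trajectory_states(a) - trajectory_states(b))), 1e-9)
  }
})
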