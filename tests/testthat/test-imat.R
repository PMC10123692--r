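test_that("the iMAT program has the documented shape", {
  m <- branched_model()
  st <- make_state(RH = c("R1", "R2"), RL = "R3")
  p <- buildImat(m, st, epsilon = 1)
  mm <- FluxActivity:::.imatMatrices(p)
  # 2 binaries per R_H member plus 1 per R_L member
  expect_equal(sum(mm$int == 1), 2 * 2 + 1)
  expect_equal(sum(mm$c), 5)
  # empty R_H/R_L: pure feasibility problem with constant objective 0
  p0 <- buildImat(m, make_state(character(), character()))
  sol0 <- solveImat(p0)
  expect_equal(sol0@objective, 0)
  expect_equal(sol0@status, "optimal")
  expect_error(buildImat(m, make_state("missing", character())),
               "not in model")
  expect_error(buildImat(m, make_state("R1", "R1")), "disjoint")
})

test_that("the forward-activity constraint reduces to v >= eps when y+ = 1", {
  # chain EX_A => A -> B => EX_B with R_H = {R1}, bounds +/-10:
  # substituting y+ = 1 into the row -v + y+(eps - lb) <= -lb gives v >= eps
  m <- modelFromEquations(
    c(EX_A = "A ->", R1 = "A -> B", EX_B = "B ->"),
    lower_bound = c(-10, -10, -10), upper_bound = 10)
  p <- buildImat(m, make_state("R1", character()), epsilon = 1)
  mm <- FluxActivity:::.imatMatrices(p)
  j <- match("R1", mm$ids)
  row <- mm$Aub[1, ]  # Eq (4) row
  # with y+ = 1: row gives -v + (eps - lb) <= -lb  <=>  v >= eps
  expect_equal(row[j], -1)
  expect_equal(row[mm$n + 1], 1 - (-10))
  expect_equal(mm$bub[1], 10)
})

test_that("solveImat matches the exhaustive enumeration oracle on the toy
           chain", {
  m <- branched_model()
  st <- make_state(RH = c("R1", "R2"), RL = "R3")
  sol <- solveImat(buildImat(m, st, epsilon = 1))
  expect_equal(sol@objective, 3)
  enum <- oracle_enumerate(m, st$RH, st$RL, 1)
  expect_equal(sol@objective, enum$optimum)
  # indicator bookkeeping
  expect_equal(unname(sol@indicators$y_plus + sol@indicators$y_minus),
               c(1, 1))
  expect_equal(unname(sol@indicators$x), 1)
  expect_equal(sol@objective,
               sum(sol@indicators$y_plus) + sum(sol@indicators$y_minus) +
                 sum(sol@indicators$x))
  # all bounds zero: only the inactivity targets are satisfiable
  m0 <- m
  m0 <- setFluxBounds(m0, reactionIds(m0), 0, 0)
  sol0 <- solveImat(buildImat(m0, st, epsilon = 1))
  expect_equal(sol0@objective, length(st$RL))
  expect_equal(sol0@objective, oracle_enumerate(m0, st$RH, st$RL, 1)$optimum)
})

test_that("solveImat equals brute force on random small instances", {
  for (seed in 1:8) {
    inst <- random_imat_instance(seed)
    st <- make_state(inst$RH, inst$RL)
    sol <- solveImat(buildImat(inst$model, st, epsilon = inst$epsilon))
    enum <- oracle_enumerate(inst$model, inst$RH, inst$RL, inst$epsilon)
    expect_equal(sol@objective, enum$optimum,
                 label = paste("instance", seed))
  }
})

test_that("sensitivity calls classify the branched chain correctly", {
  m <- branched_model()
  st <- make_state(RH = c("R1", "R2"), RL = "R3")
  calls <- sensitivityCalls(m, st, epsilon = 1)
  # R3 active would sacrifice its own inactivity credit: forced-active
  # objective 2 < 3, forced-inactive 3
  expect_equal(unname(calls@calls["R3"]), "inactive")
  expect_equal(unname(calls@objActive["R3"]), 2)
  expect_equal(unname(calls@objInactive["R3"]), 3)
  # R1 is needed by both activity targets
  expect_equal(unname(calls@calls["R1"]), "active")
  expect_lt(calls@objInactive["R1"], 3)
  # forced objectives never exceed the unconstrained optimum
  expect_true(all(calls@objActive <= calls@optimum + 1e-6))
  expect_true(all(calls@objInactive <= calls@optimum + 1e-6))
})

test_that("two parallel sufficient routes are undetermined", {
  # B -> C twice in parallel; either route alone satisfies everything
  m <- modelFromEquations(
    c(EX_A = "A ->", R1 = "A -> B", Ra = "B -> C", Rb = "B -> C",
      EX_C = "C ->"),
    lower_bound = c(-10, 0, 0, 0, 0), upper_bound = 10)
  st <- make_state(RH = "R1", RL = character())
  calls <- sensitivityCalls(m, st, epsilon = 1)
  expect_equal(unname(calls@calls[c("Ra", "Rb")]),
               c("undetermined", "undetermined"))
  expect_equal(unname(calls@calls["R1"]), "active")
})

test_that("sensitivity calls match enumeration of all optimal assignments", {
  for (seed in c(3, 14)) {
    inst <- random_imat_instance(seed)
    st <- make_state(inst$RH, inst$RL)
    calls <- sensitivityCalls(inst$model, st, epsilon = inst$epsilon)
    forced <- oracle_forced_objectives(inst$model, inst$RH, inst$RL,
                                       inst$epsilon)
    expect_equal(unname(calls@calls), unname(oracle_calls(forced)),
                 label = paste("instance", seed))
  }
})

test_that("the corrected reverse-activity direction forces real reverse
           flux while the printed one hands out free credit", {
  # reverse-only reaction: the corrected constraint earns its credit by
  # carrying v <= -eps
  m <- modelFromEquations(
    c(EX_A = "A ->", R1 = "B -> A", EX_B = "B ->"),
    lower_bound = c(-10, -10, -10), upper_bound = c(10, 0, 10))
  st <- make_state(RH = "R1", RL = character())
  sol_c <- solveImat(buildImat(m, st, epsilon = 1, eq5 = "corrected"))
  expect_equal(sol_c@objective, 1)
  expect_lte(sol_c@fluxes[["R1"]], -1)
  # a blocked reaction can never be honestly active, yet the literal
  # printed inequality (v + y-(vmax + eps) >= vmax) is satisfied by v = 0
  # with y- = 1, i.e. it awards activity credit without flux
  mb <- modelFromEquations(c(R1 = "X -> Y", EX_Y = "Y ->"),
                           lower_bound = 0, upper_bound = 10)
  stb <- make_state(RH = "R1", RL = character())
  expect_equal(solveImat(buildImat(mb, stb, eq5 = "corrected"))@objective, 0)
  expect_equal(solveImat(buildImat(mb, stb, eq5 = "printed"))@objective, 1)
})

test_that("robustness consensus keeps only unanimous determinate calls", {
  mk <- function(calls, pair) {
    methods::new("ActivityCallSet",
                 calls = calls,
                 objActive = stats::setNames(rep(NA_real_, length(calls)),
                                             names(calls)),
                 objInactive = stats::setNames(rep(NA_real_, length(calls)),
                                               names(calls)),
                 optimum = NA_real_, thresholds = pair,
                 fluxes = stats::setNames(rep(0, length(calls)),
                                          names(calls)),
                 epsilon = 1)
  }
  r <- c(r1 = "active", r2 = "active", r3 = "active")
  cs1 <- mk(c(r1 = "active", r2 = "active", r3 = "active"), c(30, 70))
  cs2 <- mk(c(r1 = "active", r2 = "inactive", r3 = "undetermined"),
            c(33, 66))
  cs3 <- mk(c(r1 = "active", r2 = "active", r3 = "active"), c(40, 60))
  cons <- robustnessConsensus(list(cs1, cs2, cs3))
  expect_equal(unname(cons@calls["r1"]), "active")        # unanimity
  expect_equal(unname(cons@calls["r2"]), "undetermined")  # conflict
  expect_equal(unname(cons@calls["r3"]), "undetermined")  # undetermined member
  expect_equal(dim(attr(cons, "perPair")), c(3L, 3L))
  expect_error(robustnessConsensus(list(cs1)), "at least two")
  cs_bad <- mk(c(q1 = "active"), c(30, 70))
  expect_error(robustnessConsensus(list(cs1, cs_bad)), "different reaction")
})

test_that("identical problems yield identical objectives across repeat
           solves", {
  inst <- random_imat_instance(5)
  st <- make_state(inst$RH, inst$RL)
  p <- buildImat(inst$model, st)
  o1 <- solveImat(p, seed = 1)@objective
  o2 <- solveImat(p, seed = 1)@objective
  o3 <- solveImat(p, seed = 99)@objective
  expect_identical(o1, o2)
  expect_identical(o1, o3)
})
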