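mk_calls <- function(calls, pair = c(33, 66)) {
  methods::new("ActivityCallSet",
               calls = calls,
               objActive = stats::setNames(rep(NA_real_, length(calls)),
                                           names(calls)),
               objInactive = stats::setNames(rep(NA_real_, length(calls)),
                                             names(calls)),
               optimum = NA_real_, thresholds = pair,
               fluxes = stats::setNames(rep(0, length(calls)), names(calls)),
               epsilon = 1)
}

mk_model <- function(subsys) {
  n <- length(subsys)
  eq <- stats::setNames(paste0("m", seq_len(n), " ->"),
                        paste0("r", seq_len(n)))
  modelFromEquations(eq, lower_bound = -10, upper_bound = 10,
                     subsystem = subsys)
}

test_that("pathway activity is the active fraction per subsystem", {
  m <- mk_model(c(rep("P1", 4), rep("P2", 3), ""))
  calls <- mk_calls(stats::setNames(
    c("active", "active", "active", "undetermined",
      "inactive", "inactive", "inactive", "active"),
    paste0("r", 1:8)))
  act <- pathwayActivity(calls, m)
  expect_equal(act$ratio[act$subsystem == "P1"], 0.75)  # 3 of 4
  expect_equal(act$ratio[act$subsystem == "P2"], 0)
  expect_equal(act$ratio[act$subsystem == "unassigned"], 1)
  expect_equal(sum(act$n_total), 8L)
  # hand-tallied counts on the toy fixture
  toy <- generateToyGem(3, 4, 0, seed = 13)
  cl <- mk_calls(stats::setNames(
    rep(c("active", "inactive"), length.out = nrow(reactions(toy$model))),
    reactionIds(toy$model)))
  act2 <- pathwayActivity(cl, toy$model)
  ss <- reactions(toy$model)$subsystem
  for (s in unique(ss)) {
    expect_equal(act2$n_active[act2$subsystem == s],
                 sum(cl@calls[ss == s] == "active"))
  }
})

test_that("fisherExact2x2 matches direct hypergeometric summation", {
  # ~0.0230: exact value of the two-sided hypergeometric summation
  expect_equal(fisherExact2x2(8, 2, 2, 8), 0.02301413, tolerance = 1e-6)
  expect_equal(fisherExact2x2(5, 5, 5, 5), 1)
  expect_equal(fisherExact2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_equal(fisherExact2x2(0, 0, 0, 0), 1)
  expect_error(fisherExact2x2(-1, 0, 0, 0), "non-negative")
  # agreement with the oracle over all tables with margins <= 30
  set.seed(5)
  for (i in 1:200) {
    cells <- stats::rbinom(4, 8, 0.5)
    expect_equal(fisherExact2x2(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12,
                 label = paste(cells, collapse = ","))
  }
})

test_that("differential pathways require both the 10% and the p-value rule", {
  m <- mk_model(c(rep("big", 10), rep("other", 10)))
  ids <- reactionIds(m)
  callsA <- lapply(list(c(30, 70), c(33, 66), c(40, 60)), function(pr) {
    mk_calls(stats::setNames(c(rep("active", 8), rep("inactive", 2),
                               rep("active", 5), rep("inactive", 5)), ids), pr)
  })
  callsB <- lapply(list(c(30, 70), c(33, 66), c(40, 60)), function(pr) {
    mk_calls(stats::setNames(c(rep("active", 2), rep("inactive", 8),
                               rep("active", 5), rep("inactive", 5)), ids), pr)
  })
  out <- differentialPathways(callsA, callsB, m)
  big <- out[out$subsystem == "big", ]
  expect_equal(big$diff, 0.6)
  # Fisher 8/2 vs 2/8 gives ~0.0230, Bonferroni factor 2
  expect_equal(big$max_bonferroni_p, 2 * fisherExact2x2(8, 2, 2, 8),
               tolerance = 1e-9)
  expect_true(big$differential)
  expect_false(out$differential[out$subsystem == "other"])

  # identical conditions: no pathway differential, p = 1
  null <- differentialPathways(callsA, callsA, m)
  expect_true(all(null$diff == 0))
  expect_true(all(!null$differential))
  expect_true(all(null$max_bonferroni_p == 1))

  # a small difference with a tiny p still fails the 10% rule
  m2 <- mk_model(rep("s", 100))
  idsm <- reactionIds(m2)
  cA <- lapply(1:3, function(i) mk_calls(stats::setNames(
    c(rep("active", 54), rep("inactive", 46)), idsm), c(30 + i, 70 - i)))
  cB <- lapply(1:3, function(i) mk_calls(stats::setNames(
    c(rep("active", 46), rep("inactive", 54)), idsm), c(30 + i, 70 - i)))
  out2 <- differentialPathways(cA, cB, m2)
  expect_equal(out2$diff, 0.08)
  expect_false(out2$differential)

  # swapping conditions flips the sign of diff only
  sw <- differentialPathways(callsB, callsA, m)
  expect_equal(sw$diff, -out$diff)
  expect_equal(sw$max_bonferroni_p, out$max_bonferroni_p)
  expect_equal(sw$differential, out$differential)

  expect_error(differentialPathways(callsA[1:2], callsB, m), "different")
})

test_that("differential reactions require opposite determinate consensus", {
  cons_a <- mk_calls(c(r1 = "active", r2 = "active", r3 = "inactive",
                       r4 = "undetermined"))
  cons_b <- mk_calls(c(r1 = "inactive", r2 = "undetermined", r3 = "active",
                       r4 = "inactive"))
  dr <- differentialReactions(cons_a, cons_b)
  expect_equal(dr$reaction[dr$active_in == "A"], "r1")
  expect_equal(dr$reaction[dr$active_in == "B"], "r3")
  expect_false("r2" %in% dr$reaction)  # undetermined on one side
  expect_false("r4" %in% dr$reaction)
  # planted flips on the toy generator are recovered exactly
  toy <- generateToyGem(seed = 17)
  red <- reduceModel(toy$model)$model
  ex <- generateExpression(toy$model, toy$truth, flip_fraction = 0,
                           seed = 17)
  cons <- lapply(c("A", "B"), function(cond) {
    robustnessConsensus(lapply(list(c(30, 70), c(33, 66), c(40, 60)),
                               function(pr) {
      cls <- classifyGenes(ex[[cond]], pr[1], pr[2])
      sensitivityCalls(red, reactionStates(red, cls))
    }))
  })
  found <- differentialReactions(cons[[1]], cons[[2]])
  tr <- toy$truth
  planted_A <- names(tr$state_A)[tr$state_A == "active" &
                                   tr$state_B == "inactive"]
  planted_B <- names(tr$state_A)[tr$state_A == "inactive" &
                                   tr$state_B == "active"]
  expect_setequal(found$reaction[found$active_in == "A"], planted_A)
  expect_setequal(found$reaction[found$active_in == "B"], planted_B)
})
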