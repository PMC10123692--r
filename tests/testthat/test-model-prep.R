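test_that("lipid boundary expansion adds the expected entities", {
  m <- modelFromEquations(
    c(EX_A = "A ->", R1 = "A -> L_c", R2 = "L_c -> L_m", EX_W = "L_m ->"),
    lower_bound = c(-10, -10, -10, 0), upper_bound = 10,
    met_compartment = c("c", "c", "m"))
  # lipid L in compartments {c, m}: 1 boundary metabolite, 2 transports,
  # 1 sink
  ex <- expandLipidBoundary(m, list(L = c("c", "m")))
  expect_equal(nrow(metabolites(ex)) - nrow(metabolites(m)), 1L)
  expect_equal(sum(reactions(ex)$kind == "transport-to-boundary"), 2L)
  expect_equal(sum(reactions(ex)$kind == "sink"), 1L)
  expect_true("bnd" %in% compartments(ex))
  expect_true(all(reactions(ex)$provenance[reactions(ex)$kind == "sink"] ==
                    "lipid-boundary-expansion"))
  # added reactions are reversible so measured bounds of either sign fit
  added <- reactions(ex)[reactions(ex)$kind %in%
                           c("sink", "transport-to-boundary"), ]
  expect_true(all(added$lower_bound < 0 & added$upper_bound > 0))

  # lipid in exactly one compartment: no transports, one sink
  ex1 <- expandLipidBoundary(m, list(L = "c"))
  expect_equal(sum(reactions(ex1)$kind == "transport-to-boundary"), 0L)
  expect_equal(sum(reactions(ex1)$kind == "sink"), 1L)
  expect_equal(nrow(metabolites(ex1)), nrow(metabolites(m)))

  # empty list: no-op; unknown lipid: lookup error naming it
  expect_identical(nrow(reactions(expandLipidBoundary(m, list()))),
                   nrow(reactions(m)))
  expect_error(expandLipidBoundary(m, list(Q = "c")), "Q")
})

test_that("expansion adds one boundary met per multi-compartment lipid and
           one sink per measured lipid", {
  m <- modelFromEquations(
    c(EX_A = "A ->", R1 = "A -> P_c", R2 = "P_c -> P_m", R3 = "P_m -> Q_c",
      EX_Q = "Q_c ->"),
    lower_bound = -10, upper_bound = 10,
    met_compartment = c("c", "c", "m", "c"))
  lip <- list(P = c("c", "m"), Q = "c")
  ex <- expandLipidBoundary(m, lip)
  n_multi <- 1; n_instances <- 2; n_lipids <- 2
  expect_equal(nrow(metabolites(ex)) - nrow(metabolites(m)), n_multi)
  expect_equal(sum(reactions(ex)$kind == "transport-to-boundary"),
               n_instances)
  expect_equal(sum(reactions(ex)$kind == "sink"), n_lipids)
})

test_that("flux variability brackets interior reactions correctly", {
  m <- chain3_model()
  fva <- fluxVariability(m)
  r1 <- fva[fva$reaction == "R1", ]
  expect_equal(c(r1$min_flux, r1$max_flux), c(0, 10), tolerance = 1e-7)
  # reaction whose substrate has no producer is pinned to zero
  m2 <- modelFromEquations(c(R1 = "X -> Y", EX_Y = "Y ->"),
                           lower_bound = 0, upper_bound = 10)
  fva2 <- fluxVariability(m2)
  expect_equal(max(abs(c(fva2$min_flux, fva2$max_flux))), 0)
  # closed system: every reaction in a loop-free network is pinned to zero
  m3 <- setFluxBounds(m, c("EX_A", "EX_B"), 0, 0)
  fva3 <- fluxVariability(m3)
  expect_true(all(abs(fva3$min_flux) < 1e-9 & abs(fva3$max_flux) < 1e-9))
  # infeasible base model errors before any per-reaction solve
  m4 <- setFluxBounds(m, "EX_A", -10, -5)  # force uptake, block export
  m4 <- setFluxBounds(m4, "EX_B", 0, 0)
  expect_error(fluxVariability(m4), "infeasible")
})

test_that("blocked-reaction removal matches an exhaustive LP oracle", {
  toy <- generateToyGem(4, 5, 3, seed = 21)
  m <- toy$model
  # oracle: two LPs per reaction at tolerance 1e-9
  fva <- fluxVariability(m)
  oracle_blocked <- fva$reaction[abs(fva$min_flux) < 1e-9 &
                                   abs(fva$max_flux) < 1e-9]
  res <- removeBlocked(m)
  expect_setequal(res$report$removed_blocked, oracle_blocked)
  expect_setequal(res$report$removed_blocked, paste0("BLK_", 1:3))
  # surviving reactions keep their original bounds
  surv <- reactions(res$model)
  orig <- reactions(m)[match(surv$id, reactions(m)$id), ]
  expect_equal(surv$lower_bound, orig$lower_bound)
  expect_equal(surv$upper_bound, orig$upper_bound)
  # idempotence
  res2 <- removeBlocked(res$model)
  expect_length(res2$report$removed_blocked, 0)
  # no-op on a fully open network
  open <- chain3_model()
  expect_length(removeBlocked(open)$report$removed_blocked, 0)
})

test_that("dead-end metabolite removal iterates to a fixed point", {
  toy <- generateToyGem(3, 4, 2, seed = 31)
  red <- removeBlocked(toy$model)
  # the DEAD_* metabolites are orphaned by blocked-reaction removal
  dd <- removeDeadEndMetabolites(red$model)
  expect_setequal(dd$report$removed_dead_end, c("DEAD_1", "DEAD_2"))
  expect_false(any(c("DEAD_1", "DEAD_2") %in% metaboliteIds(dd$model)))
  # no orphans: unchanged
  again <- removeDeadEndMetabolites(dd$model)
  expect_length(again$report$removed_dead_end, 0)
  expect_identical(metaboliteIds(again$model), metaboliteIds(dd$model))
})

test_that("reduction preserves the projected feasible space", {
  toy <- generateToyGem(3, 6, 3, seed = 41)   # ~21 reactions, 3 blocked
  m <- toy$model
  red <- reduceModel(m)
  keep <- reactionIds(red$model)
  sk_full <- list(Aeq = as.matrix(stoichiometricMatrix(m)),
                  beq = rep(0, nrow(stoichiometricMatrix(m))))
  sk_red <- list(Aeq = as.matrix(stoichiometricMatrix(red$model)),
                 beq = rep(0, nrow(stoichiometricMatrix(red$model))))
  n <- nrow(reactions(m))
  set.seed(1)
  probs <- lapply(1:25, function(i) {
    list(c = stats::rnorm(n), maximize = TRUE,
         lb = reactions(m)$lower_bound, ub = reactions(m)$upper_bound,
         group = 1)
  })
  sols <- solveMILPBatch(probs, list(sk_full))
  ok_fwd <- vapply(sols, function(s) {
    v <- stats::setNames(unlist(s$x), reactionIds(m))
    # restriction satisfies the reduced model's constraints numerically
    all(abs(sk_red$Aeq %*% v[keep]) < 1e-6) &&
      all(v[keep] >= reactions(red$model)$lower_bound - 1e-6) &&
      all(v[keep] <= reactions(red$model)$upper_bound + 1e-6)
  }, logical(1))
  expect_true(all(ok_fwd))
  # and vice versa: reduced-model vertices extend by zeros to full vectors
  nr <- nrow(reactions(red$model))
  probs2 <- lapply(1:25, function(i) {
    list(c = stats::rnorm(nr), maximize = TRUE,
         lb = reactions(red$model)$lower_bound,
         ub = reactions(red$model)$upper_bound, group = 1)
  })
  sols2 <- solveMILPBatch(probs2, list(sk_red))
  ok_bwd <- vapply(sols2, function(s) {
    v_full <- stats::setNames(rep(0, n), reactionIds(m))
    v_full[keep] <- unlist(s$x)
    all(abs(sk_full$Aeq %*% v_full) < 1e-6) &&
      all(v_full >= reactions(m)$lower_bound - 1e-6) &&
      all(v_full <= reactions(m)$upper_bound + 1e-6)
  }, logical(1))
  expect_true(all(ok_bwd))
})
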