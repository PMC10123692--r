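# Independent oracles. These deliberately take brute-force routes
# (exhaustive enumeration, direct summation, hand-walked loops) that share
# no code with the implementation paths they check.

# GPR oracle: translate the tree into a literal R expression with min()/
# max() and evaluate it.
oracle_gpr_eval <- function(gpr, values) {
  to_expr <- function(node) {
    if (is.null(node)) return("0")
    if (is.character(node)) {
      v <- if (node %in% names(values)) values[[node]] else 0
      return(as.character(v))
    }
    fn <- if (node$op == "and") "min" else "max"
    paste0(fn, "(", paste(vapply(node$args, to_expr, character(1)),
                          collapse = ","), ")")
  }
  eval(parse(text = to_expr(gpr)))
}

# Stoichiometric-matrix oracle: entry-by-entry assembly from the JSON
# serialization of the model.
oracle_stoich <- function(model) {
  doc <- jsonlite::fromJSON(modelToJSON(model), simplifyVector = FALSE)
  mets <- vapply(doc$metabolites, `[[`, character(1), "id")
  rxns <- vapply(doc$reactions, `[[`, character(1), "id")
  M <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in doc$reactions) {
    for (met in names(r$stoichiometry)) {
      M[met, r$id] <- M[met, r$id] + r$stoichiometry[[met]]
    }
  }
  M
}

# Fisher oracle: two-sided p by direct summation of hypergeometric point
# probabilities not exceeding the observed one.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand-walked enrichment score: plain loop over the ranked list.
oracle_es <- function(genes, scores, set, p = 1) {
  n <- length(genes)
  hits <- genes %in% set
  nh <- sum(hits)
  denom_hit <- sum(abs(scores[hits])^p)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      run <- run + if (denom_hit > 0) abs(scores[i])^p / denom_hit else 1 / nh
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# --- iMAT enumeration oracle ------------------------------------------------
# Enumerates every indicator assignment (per R_H member: forward / reverse /
# off; per R_L member: x = 1 / 0), encodes each as pure box bounds, and
# checks steady-state feasibility by LP. Returns the per-assignment
# feasibility, score, and (optionally) per-reaction flux ranges.

oracle_assignments <- function(nH, nL) {
  opts <- c(vector("list", nH), vector("list", nL))
  grid <- expand.grid(c(rep(list(0:2), nH), rep(list(0:1), nL)),
                      KEEP.OUT.ATTRS = FALSE)
  as.matrix(grid)
}

# Box bounds implied by one assignment row.
oracle_bounds <- function(model, RH, RL, eps, assign_row) {
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  ids <- model@reactions$id
  nH <- length(RH)
  for (k in seq_along(RH)) {
    j <- match(RH[k], ids)
    if (assign_row[k] == 1) lb[j] <- max(lb[j], eps)        # forward active
    if (assign_row[k] == 2) ub[j] <- min(ub[j], -eps)       # reverse active
  }
  for (k in seq_along(RL)) {
    j <- match(RL[k], ids)
    if (assign_row[nH + k] == 1) { lb[j] <- 0; ub[j] <- 0 } # inactive
  }
  list(lb = lb, ub = ub)
}

# Feasibility + score of every assignment, via one batched LP call.
oracle_enumerate <- function(model, RH, RL, eps) {
  nH <- length(RH); nL <- length(RL)
  A <- oracle_assignments(nH, nL)
  sk <- list(Aeq = as.matrix(stoichiometricMatrix(model)),
             beq = rep(0, nrow(stoichiometricMatrix(model))))
  n <- length(model@reactions$id)
  probs <- lapply(seq_len(nrow(A)), function(i) {
    bb <- oracle_bounds(model, RH, RL, eps, A[i, ])
    list(c = rep(0, n), maximize = FALSE, lb = bb$lb, ub = bb$ub, group = 1)
  })
  res <- solveMILPBatch(probs, list(sk))
  feas <- vapply(res, function(r) identical(r$status, "optimal"), logical(1))
  score <- vapply(seq_len(nrow(A)), function(i) {
    ai <- A[i, ]
    sum(ai[seq_len(nH)] > 0) + if (nL) sum(ai[nH + seq_len(nL)] == 1) else 0
  }, numeric(1))
  list(assignments = A, feasible = feas, score = score,
       optimum = if (any(feas)) max(score[feas]) else -Inf)
}

# Per-reaction flux ranges within each feasible assignment (FVA over the
# assignment's box), then the forced-active / forced-inactive objectives:
# the best score among feasible assignments whose range allows |v_r| >= eps
# (either direction) resp. v_r = 0.
oracle_forced_objectives <- function(model, RH, RL, eps, enum = NULL) {
  if (is.null(enum)) enum <- oracle_enumerate(model, RH, RL, eps)
  ids <- model@reactions$id
  n <- length(ids)
  feas_idx <- which(enum$feasible)
  sk <- list(Aeq = as.matrix(stoichiometricMatrix(model)),
             beq = rep(0, nrow(stoichiometricMatrix(model))))
  probs <- list()
  for (i in feas_idx) {
    bb <- oracle_bounds(model, RH, RL, eps, enum$assignments[i, ])
    for (j in seq_len(n)) {
      cj <- rep(0, n); cj[j] <- 1
      probs[[length(probs) + 1]] <- list(c = cj, maximize = FALSE,
                                         lb = bb$lb, ub = bb$ub, group = 1)
      probs[[length(probs) + 1]] <- list(c = cj, maximize = TRUE,
                                         lb = bb$lb, ub = bb$ub, group = 1)
    }
  }
  res <- solveMILPBatch(probs, list(sk))
  objA <- stats::setNames(rep(-Inf, n), ids)
  objI <- stats::setNames(rep(-Inf, n), ids)
  pos <- 0
  for (i in feas_idx) {
    sc <- enum$score[i]
    for (j in seq_len(n)) {
      vmin <- res[[pos + 2 * j - 1]]$objective
      vmax <- res[[pos + 2 * j]]$objective
      if (vmax >= eps - 1e-9 || vmin <= -eps + 1e-9) {
        objA[j] <- max(objA[j], sc)
      }
      if (vmin <= 1e-9 && vmax >= -1e-9) {
        objI[j] <- max(objI[j], sc)
      }
    }
    pos <- pos + 2 * n
  }
  list(objActive = objA, objInactive = objI, optimum = enum$optimum)
}

oracle_calls <- function(forced, tol = 1e-6) {
  atA <- forced$objActive >= forced$optimum - tol
  atI <- forced$objInactive >= forced$optimum - tol
  out <- rep("undetermined", length(atA))
  out[atA & !atI] <- "active"
  out[atI & !atA] <- "inactive"
  stats::setNames(out, names(forced$objActive))
}
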